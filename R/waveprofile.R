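# Ring-frame density estimation, sigmoid arrival-time fits and wave metrics.

#' Equal-area concentric half-annuli
#'
#' Ring boundaries follow r_k = r_max * sqrt(k/N) so that every half-annulus
#' in the fungal half-plane has the same area.
#'
#' @param origin Barrier crossing point (x_um, y_um), default c(0, 0).
#' @param r_max_mm Outer radius in mm.
#' @param n_rings Number of rings (default 15).
#' @return List of class `ring_frame`: origin_um, boundaries_mm (outer radii),
#'   mids_mm (area-weighted ring radii), area_mm2 (per ring).
#' @export
make_rings <- function(origin = c(0, 0), r_max_mm = 45, n_rings = 15) {
  if (n_rings < 2) stop("n_rings must be >= 2", call. = FALSE)
  stopifnot(r_max_mm > 0)
  k <- seq_len(n_rings)
  b <- r_max_mm * sqrt(k / n_rings)
  structure(list(origin_um = origin, boundaries_mm = b,
                 mids_mm = (c(0, b[-n_rings]) + b) / 2,
                 n_rings = n_rings, r_max_mm = r_max_mm,
                 area_mm2 = pi * r_max_mm^2 / (2 * n_rings)),
            class = "ring_frame")
}

#' Per-ring filament and tip densities over time
#'
#' Filament density rho = clipped polyline length within the ring divided by
#' ring area (um/mm^2); tip density n = growing runner-hypha tip count per
#' ring area (mm^-2). Edges are clipped to rings by exact polyline-circle
#' intersection so lengths are conserved across boundaries.
#'
#' @param series A `network_series`.
#' @param rings A [make_rings()] frame.
#' @param tip_filter "growing_rh" (default: growing tips classified as runner
#'   hyphae), "growing" (all growing tips) or a function(series, t) returning
#'   tip node ids.
#' @return data.frame(t_h, ring, r_mm, rho_um_mm2, n_mm2).
#' @export
ring_densities <- function(series, rings, tip_filter = "growing_rh") {
  tp <- series$timepoints
  if (!length(tp) || nrow(series$edges) == 0)
    warning("empty series: returning all-zero profiles")
  bnd_um <- rings$boundaries_mm * 1000
  tips_fun <- if (is.function(tip_filter)) tip_filter else {
    labels <- if (identical(tip_filter, "growing_rh"))
      classify_tips_rh_bas(series) else NULL
    function(series, t) {
      g <- growing_tips(series, t)
      if (!is.null(labels)) g <- g[labels[g] %in% "RH"]
      g
    }
  }
  out <- list()
  for (t in tp) {
    sn <- snapshot(series, t, check = FALSE)
    lens <- numeric(rings$n_rings + 1L)
    for (i in seq_len(nrow(sn$edges)))
      lens <- lens + clip_length_radial(sn$edges$realized_polyline[[i]],
                                        rings$origin_um, bnd_um)
    ids <- tips_fun(series, t)
    ntip <- numeric(rings$n_rings)
    if (length(ids)) {
      pos <- sn$nodes[sn$nodes$node_id %in% ids, , drop = FALSE]
      rr <- sqrt((pos$x_um - rings$origin_um[1])^2 +
                   (pos$y_um - rings$origin_um[2])^2)
      bins <- findInterval(rr, bnd_um) + 1L
      for (b in bins[bins <= rings$n_rings]) ntip[b] <- ntip[b] + 1L
    }
    out[[length(out) + 1L]] <- data.frame(
      t_h = t, ring = seq_len(rings$n_rings), r_mm = rings$mids_mm,
      rho_um_mm2 = lens[seq_len(rings$n_rings)] / rings$area_mm2,
      n_mm2 = ntip / rings$area_mm2)
  }
  do.call(rbind, out)
}

#' Bootstrap uncertainty of a ring density
#'
#' Splits the half-annulus into `n_cells` equal-area radial-angular cells,
#' computes per-cell filament densities and bootstraps the mean `n_boot`
#' times (reported uncertainty bands are 2 s.d. of these resampled means).
#' The equal-area cells stand in for equal-area "rectangles" used in the field, which
#' cannot tile an annulus exactly.
#'
#' @param series A `network_series`.
#' @param rings A [make_rings()] frame.
#' @param ring Ring index.
#' @param t Timepoint.
#' @param n_cells,n_boot Partition and resampling sizes (defaults 10000, 100).
#' @param seed RNG seed for the resampling.
#' @return List with `sd` (bootstrap s.d. of the mean density, um/mm^2),
#'   `mean`, and the per-cell density vector.
#' @export
bootstrap_density_sd <- function(series, rings, ring, t, n_cells = 10000,
                                 n_boot = 100, seed = 1) {
  stopifnot(ring >= 1, ring <= rings$n_rings)
  sn <- snapshot(series, t, check = FALSE)
  r0 <- if (ring == 1) 0 else rings$boundaries_mm[ring - 1] * 1000
  r1 <- rings$boundaries_mm[ring] * 1000
  n_r <- max(2L, round(sqrt(n_cells / 4)))
  n_th <- max(2L, round(n_cells / n_r))
  rb <- sqrt(seq(r0^2, r1^2, length.out = n_r + 1L))  # equal-area radii
  cell_area_mm2 <- rings$area_mm2 / (n_r * n_th)
  counts <- matrix(0, n_r, n_th)
  for (i in seq_len(nrow(sn$edges))) {
    xy <- sn$edges$realized_polyline[[i]]
    if (nrow(xy) < 2) next
    # resample polyline into short steps and bin by midpoint
    seglen <- sqrt(rowSums(diff(xy)^2))
    for (k in which(seglen > 0)) {
      nsub <- max(1L, ceiling(seglen[k] / 25))
      f0 <- (seq_len(nsub) - 1) / nsub; f1 <- seq_len(nsub) / nsub
      mx <- xy[k, 1] + (f0 + f1) / 2 * (xy[k + 1, 1] - xy[k, 1]) -
        rings$origin_um[1]
      my <- xy[k, 2] + (f0 + f1) / 2 * (xy[k + 1, 2] - xy[k, 2]) -
        rings$origin_um[2]
      rr <- sqrt(mx^2 + my^2)
      th <- atan2(my, mx)  # [0, pi] in the half-plane
      inside <- rr >= r0 & rr < r1 & th >= 0 & th <= pi
      if (!any(inside)) next
      ri <- findInterval(rr[inside], rb, rightmost.closed = TRUE)
      ri[ri < 1] <- 1; ri[ri > n_r] <- n_r
      ti <- pmin(pmax(ceiling(th[inside] / pi * n_th), 1L), n_th)
      ww <- seglen[k] / nsub
      for (j in seq_along(ri))
        counts[ri[j], ti[j]] <- counts[ri[j], ti[j]] + ww
    }
  }
  dens <- as.vector(counts) / cell_area_mm2
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b)
    mean(sample(dens, replace = TRUE)), 0)
  list(sd = stats::sd(boot), mean = mean(dens), cells = dens)
}

#' Colony radius from the convex-hull semicircle approximation
#'
#' r = sqrt(2A/pi) with A the convex-hull area of all node positions.
#'
#' @param snap A `network_snapshot`.
#' @return Radius in mm.
#' @export
colony_radius <- function(snap) {
  xy <- cbind(snap$nodes$x_um, snap$nodes$y_um)
  A <- convex_hull_area(xy)
  if (A <= 0) stop("degenerate convex hull: need >= 3 non-collinear nodes",
                   call. = FALSE)
  sqrt(2 * A / pi) / 1000
}

sigmoid_rho <- function(t, K1, lambda, t_n) K1 / (1 + exp(lambda * (t_n - t)))
sigmoid_tip <- function(t, K2, lambda, t_n) {
  e <- exp(lambda * (t_n - t))
  K2 * e / (1 + e)^2
}

sigmoid_init <- function(t, y) {
  K <- max(y)
  half <- which(y >= K / 2)
  t_n <- t[half[1]]
  t10 <- t[which(y >= 0.1 * K)[1]]
  t90 <- t[which(y >= 0.9 * K)[1]]
  lam <- if (isTRUE(t90 > t10)) 4 / (t90 - t10) else 0.5
  list(K = K, lambda = lam, t_n = t_n)
}

#' Sigmoid fits of per-ring density dynamics
#'
#' Filament density follows rho(t) = K1 / (1 + exp(lambda (t_n - t))); the
#' arrival time t_n is the half-maximum time. Tip density follows the
#' sigmoid-derivative pulse n(t) = K2 exp(lambda (t_n'-t)) /
#' (1 + exp(lambda (t_n'-t)))^2. Confidence intervals come from residual
#' bootstrap refits.
#'
#' @param t,y Time (h) and density vectors.
#' @param n_boot Residual-bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return List of class `sigmoid_fit`: K, lambda, t_n, their bootstrap 95%
#'   CIs (`ci`, a 2 x 3 matrix), `converged`, and the fitted model.
#' @export
fit_sigmoid_rho <- function(t, y, n_boot = 1000, seed = 1) {
  fit_sigmoid_impl(t, y, sigmoid_rho, n_boot, seed, tip = FALSE)
}

#' @rdname fit_sigmoid_rho
#' @export
fit_sigmoid_tip <- function(t, y, n_boot = 1000, seed = 1) {
  fit_sigmoid_impl(t, y, sigmoid_tip, n_boot, seed, tip = TRUE)
}

fit_sigmoid_impl <- function(t, y, fun, n_boot, seed, tip) {
  stopifnot(length(t) == length(y), length(t) >= 4)
  if (max(y) <= 0) stop("all-zero density series: nothing to fit",
                        call. = FALSE)
  if (max(y) < 2 * max(min(y), 1e-12) && !tip)
    stop("series does not span the density rise (max < 2x min)",
         call. = FALSE)
  if (!tip && stats::cor(t, y) < 0)
    stop("monotone-decreasing input: not a rising front", call. = FALSE)
  init <- sigmoid_init(t, y)
  K0 <- if (tip) 4 * max(y) else init$K
  t0 <- if (tip) t[which.max(y)] else init$t_n
  df <- data.frame(t = t, y = y)
  fit <- try(minpack.lm::nlsLM(
    y ~ fun(t, K, lambda, t_n), data = df,
    start = list(K = K0, lambda = init$lambda, t_n = t0),
    lower = c(1e-9, 1e-4, min(t) - diff(range(t))),
    upper = c(Inf, 100, max(t) + diff(range(t))),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(structure(list(converged = FALSE,
                          diagnostics = attr(fit, "condition")$message),
                     class = "sigmoid_fit"))
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  pred <- stats::fitted(fit)
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, 3)
  for (b in seq_len(n_boot)) {
    yb <- pred + sample(res, replace = TRUE)
    fb <- try(minpack.lm::nlsLM(
      yb ~ fun(t, K, lambda, t_n), data = data.frame(t = t, yb = yb),
      start = as.list(cf), lower = c(1e-9, 1e-4, min(t) - diff(range(t))),
      upper = c(Inf, 100, max(t) + diff(range(t))),
      control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
    if (!inherits(fb, "try-error")) boot[b, ] <- stats::coef(fb)
  }
  ci <- apply(boot, 2, stats::quantile, c(0.025, 0.975), na.rm = TRUE)
  colnames(ci) <- c("K", "lambda", "t_n")
  structure(list(K = unname(cf["K"]), lambda = unname(cf["lambda"]),
                 t_n = unname(cf["t_n"]), ci = ci, converged = TRUE,
                 fit = fit, boot = boot), class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$converged) cat("<sigmoid_fit> not converged:", x$diagnostics, "\n")
  else cat(sprintf("<sigmoid_fit> K=%.3g lambda=%.3g t_n=%.2f h\n",
                   x$K, x$lambda, x$t_n))
  invisible(x)
}

#' Arrival times per ring from sigmoid fits
#'
#' @param profiles Output of [ring_densities()].
#' @param n_boot Bootstrap replicates per fit.
#' @return data.frame(ring, r_mm, t_n_h, K1, lambda, converged).
#' @export
arrival_times <- function(profiles, n_boot = 200) {
  out <- lapply(split(profiles, profiles$ring), function(d) {
    f <- try(fit_sigmoid_rho(d$t_h, d$rho_um_mm2, n_boot = n_boot),
             silent = TRUE)
    ok <- !inherits(f, "try-error") && isTRUE(f$converged)
    data.frame(ring = d$ring[1], r_mm = d$r_mm[1],
               t_n_h = if (ok) f$t_n else NA_real_,
               K1 = if (ok) f$K else NA_real_,
               lambda = if (ok) f$lambda else NA_real_, converged = ok)
  })
  do.call(rbind, out)
}

#' Wavefront speed from front positions or arrival times
#'
#' Linear least squares of position (mm) against time (h); returns the slope
#' in um/h with a bootstrap confidence interval.
#'
#' @param t_h Times (h).
#' @param r_mm Front positions (mm).
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed.
#' @return List: c_um_h, ci (95%), fit.
#' @export
wavefront_speed <- function(t_h, r_mm, n_boot = 1000, seed = 1) {
  ok <- is.finite(t_h) & is.finite(r_mm)
  t_h <- t_h[ok]; r_mm <- r_mm[ok]
  if (length(t_h) < 4)
    stop("need at least 4 front positions", call. = FALSE)
  fit <- stats::lm(r_mm ~ t_h)
  set.seed(seed)
  n <- length(t_h)
  boot <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, replace = TRUE)
    if (length(unique(t_h[i])) < 2) return(NA_real_)
    stats::coef(stats::lm(r_mm[i] ~ t_h[i]))[2]
  }, 0)
  list(c_um_h = unname(stats::coef(fit)[2]) * 1000,
       ci = unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE)) * 1000,
       fit = fit)
}

#' Saturating density versus ring radius
#'
#' Linear fit of the per-ring sigmoid plateau K1 against ring radius; a
#' near-zero slope indicates a spatially constant saturation density
#' (self-regulation).
#'
#' @param fits Output of [arrival_times()] (needs r_mm, K1, converged).
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed.
#' @return List: slope, intercept, ci (95% on the slope),
#'   relative_span = |slope| * range(r) / mean(K1).
#' @export
saturating_density_vs_radius <- function(fits, n_boot = 1000, seed = 1) {
  d <- fits[fits$converged & is.finite(fits$K1), , drop = FALSE]
  if (nrow(d) < nrow(fits))
    warning(sprintf("%d ring fit(s) excluded (failed)", nrow(fits) - nrow(d)))
  if (nrow(d) < 3) stop("need >= 3 successful ring fits", call. = FALSE)
  fit <- stats::lm(K1 ~ r_mm, data = d)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(nrow(d), replace = TRUE)
    if (length(unique(d$r_mm[i])) < 2) return(NA_real_)
    stats::coef(stats::lm(K1 ~ r_mm, data = d[i, ]))[2]
  }, 0)
  slope <- unname(stats::coef(fit)[2])
  list(slope = slope, intercept = unname(stats::coef(fit)[1]),
       ci = unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE)),
       relative_span = abs(slope) * diff(range(d$r_mm)) / mean(d$K1),
       fit = fit)
}

#' Puller tips at the growth front
#'
#' Growing tips that are vertices of the colony's convex hull at both `t`
#' and the next timepoint; their mean speed is the pulled-wave speed proxy.
#'
#' @param series A `network_series`.
#' @param t A timepoint with a successor.
#' @return List: ids, v_p_um_h (mean puller speed over [t, t+1]),
#'   speeds (per puller).
#' @export
puller_tips <- function(series, t) {
  tp <- series$timepoints
  i <- which(abs(tp - t) < 1e-9)
  if (!length(i) || i == length(tp))
    stop("t must be an observed timepoint with a successor", call. = FALSE)
  t2 <- tp[i + 1]
  gt <- growing_tips(series, t2)  # moved over [t, t+1]
  hull_ids <- function(tt) {
    pos <- node_positions_at(series, tt)
    xy <- cbind(pos$x_um, pos$y_um)
    if (nrow(unique(xy)) < 3) return(pos$node_id)
    pos$node_id[grDevices::chull(xy)]
  }
  on_hull <- intersect(hull_ids(t), hull_ids(t2))
  ids <- intersect(gt, on_hull)
  if (length(ids) < 1) {
    warning("fewer than 3 tips on the hull: returning all growing tips")
    ids <- gt
  }
  p1 <- node_positions_at(series, t)
  p2 <- node_positions_at(series, t2)
  sp <- vapply(ids, function(id) {
    a <- as.numeric(p1[match(id, p1$node_id), c("x_um", "y_um")])
    b <- as.numeric(p2[match(id, p2$node_id), c("x_um", "y_um")])
    sqrt(sum((b - a)^2)) / (t2 - t)
  }, 0)
  list(ids = ids, v_p_um_h = mean(sp), speeds = sp)
}
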