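# Tracking-based classification and event detection.
#
# Everything here consumes the tracked `network_series` (persistent node
# ids, per-frame positions and degrees); nothing touches raw images.

#' Classify edges into BAS and runner hyphae
#'
#' An edge is a branched absorbing structure (BAS) when any criterion holds:
#' (1) length < 400 um; (2) length < 1000 um and one endpoint is a tip
#' (degree 1); (3) mean width < 7 um and width x length < 9000 um^2.
#' Everything else is runner hypha (RH).
#'
#' @param snap A `network_snapshot`.
#' @param thresholds [am_thresholds()] list.
#' @return data.frame(edge_id, label, criterion) with criterion in
#'   {1, 2, 3, NA}; attribute `summary` holds L_BAS, L_RH and
#'   rho_BAS = L_BAS / (L_RH + L_BAS).
#' @export
classify_edges_bas_rh <- function(snap, thresholds = am_thresholds()) {
  ed <- snap$edges
  deg <- snap$nodes$degree[match(ed$node_a, snap$nodes$node_id)]
  degb <- snap$nodes$degree[match(ed$node_b, snap$nodes$node_id)]
  len <- ed$realized_length_um
  wid <- ed$width_um
  crit <- rep(NA_integer_, nrow(ed))
  c1 <- len < thresholds$bas_len_um
  c2 <- len < thresholds$bas_tip_len_um & (deg == 1 | degb == 1)
  if (anyNA(wid)) {
    warning(sprintf("%d edge(s) without width: criterion 3 skipped for them",
                    sum(is.na(wid))))
  }
  c3 <- !is.na(wid) & wid < thresholds$bas_width_um &
    wid * len < thresholds$bas_width_len_um2
  crit[which(c3)] <- 3L
  crit[which(c2)] <- 2L
  crit[which(c1)] <- 1L
  label <- ifelse(is.na(crit), "RH", "BAS")
  out <- data.frame(edge_id = ed$edge_id, label = label, criterion = crit,
                    stringsAsFactors = FALSE)
  lb <- sum(len[label == "BAS"]); lr <- sum(len[label == "RH"])
  attr(out, "summary") <- list(L_BAS_um = lb, L_RH_um = lr,
                               rho_BAS = lb / (lb + lr))
  out
}

# degree of every node at a timepoint from the stored (tracked) table
stored_degrees <- function(series, t) {
  nd <- series$nodes[series$nodes$t_h == t, , drop = FALSE]
  stats::setNames(nd$degree, nd$node_id)
}

#' Growing tips at a timepoint
#'
#' Degree-1 tracked nodes displaced by at least 40 pixels from their
#' position at the previous frame.
#'
#' @param series A `network_series`.
#' @param t Timepoint; at the first frame there is no displacement baseline
#'   and no tip counts as growing.
#' @param thresholds [am_thresholds()]; the pixel pitch in
#'   `series$meta$pixel_size_um` takes precedence if present.
#' @return Character vector of node ids.
#' @export
growing_tips <- function(series, t, thresholds = NULL) {
  if (is.null(thresholds)) {
    px <- series$meta$pixel_size_um
    thresholds <- if (is.null(px)) am_thresholds() else am_thresholds(px)
  }
  tp <- series$timepoints
  i <- which(abs(tp - t) < 1e-9)
  if (!length(i) || i == 1L) return(character())
  cur <- series$nodes[series$nodes$t_h == tp[i], , drop = FALSE]
  prev <- series$nodes[series$nodes$t_h == tp[i - 1L], , drop = FALSE]
  cand <- cur[cur$degree == 1, , drop = FALSE]
  j <- match(cand$node_id, prev$node_id)
  disp <- sqrt((cand$x_um - prev$x_um[j])^2 + (cand$y_um - prev$y_um[j])^2)
  cand$node_id[!is.na(disp) & disp >= thresholds$growing_tip_um]
}

# per-node first frame, and whether the node ever moves like a growing tip
tip_candidates <- function(series, thresholds = NULL) {
  if (is.null(thresholds)) {
    px <- series$meta$pixel_size_um
    thresholds <- if (is.null(px)) am_thresholds() else am_thresholds(px)
  }
  nd <- series$nodes[order(series$nodes$node_id, series$nodes$t_h), ]
  sp <- split(nd, nd$node_id)
  res <- lapply(sp, function(d) {
    step <- if (nrow(d) > 1)
      sqrt(diff(d$x_um)^2 + diff(d$y_um)^2) else numeric()
    net <- sqrt((d$x_um - d$x_um[1])^2 + (d$y_um - d$y_um[1])^2)
    deg <- d$degree
    fuses <- nrow(d) > 1 && any(deg[-length(deg)] == 1 & deg[-1] == 3)
    data.frame(node_id = d$node_id[1], first_t = d$t_h[1],
               first_degree = d$degree[1], x0 = d$x_um[1], y0 = d$y_um[1],
               moves = any(step >= thresholds$growing_tip_um) || fuses,
               max_net_um = max(net), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify growing tips into RH and BAS tips
#'
#' A tip whose net displacement from its initial position ever exceeds
#' 2.5 mm is a runner-hypha tip; otherwise a BAS tip.
#'
#' @param series A `network_series`.
#' @param thresholds [am_thresholds()].
#' @return Named character vector ("RH"/"BAS") over all mobile degree-1
#'   nodes.
#' @export
classify_tips_rh_bas <- function(series, thresholds = NULL) {
  if (is.null(thresholds)) {
    px <- series$meta$pixel_size_um
    thresholds <- if (is.null(px)) am_thresholds() else am_thresholds(px)
  }
  tc <- tip_candidates(series, thresholds)
  tc <- tc[!is.na(tc$first_degree) & tc$first_degree == 1 & tc$moves, ,
           drop = FALSE]
  stats::setNames(
    ifelse(tc$max_net_um > thresholds$rh_tip_net_displacement_mm * 1000,
           "RH", "BAS"), tc$node_id)
}

#' Detect anastomosis (tip annihilation) events
#'
#' A tracked node whose degree jumps from 1 to 3 and never reverts to 1 is
#' an anastomosis; the event time is the last frame at which the node had
#' degree 1 and the position is the junction position. Nodes whose degree
#' does revert to 1 are crossings.
#'
#' @param series A `network_series`.
#' @return data.frame(event_type, t_h, x_um, y_um, node_id) with
#'   event_type in {"anastomosis", "crossing"}.
#' @export
detect_anastomoses <- function(series) {
  nd <- series$nodes[order(series$nodes$node_id, series$nodes$t_h), ]
  sp <- split(nd, nd$node_id)
  rows <- list()
  for (d in sp) {
    if (nrow(d) < 2) next
    deg <- d$degree
    jump <- which(deg[-length(deg)] == 1 & deg[-1] == 3)
    if (!length(jump)) next
    j <- jump[1]
    reverts <- any(deg[(j + 1):length(deg)] == 1)
    rows[[length(rows) + 1L]] <- data.frame(
      event_type = if (reverts) "crossing" else "anastomosis",
      t_h = d$t_h[j],                      # last degree-1 timestep
      x_um = d$x_um[j + 1], y_um = d$y_um[j + 1],  # junction position
      node_id = d$node_id[1], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(event_type = character(), t_h = numeric(),
                      x_um = numeric(), y_um = numeric(),
                      node_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Detect branching events
#'
#' Branchings are growing tips appearing for the first time after the
#' initial frame: degree-1 at first appearance and subsequently displaced
#' like a growing tip. The event is timed and positioned at the first
#' appearance.
#'
#' @param series A `network_series`.
#' @return data.frame(event_type="branching", t_h, x_um, y_um, node_id).
#' @export
detect_branchings <- function(series) {
  tc <- tip_candidates(series)
  t0 <- min(series$timepoints)
  tc <- tc[!is.na(tc$first_degree) & tc$first_degree == 1 & tc$moves &
             tc$first_t > t0, , drop = FALSE]
  data.frame(event_type = rep("branching", nrow(tc)), t_h = tc$first_t,
             x_um = tc$x0, y_um = tc$y0, node_id = tc$node_id,
             stringsAsFactors = FALSE)
}

#' Ring-binned event rates
#'
#' Counts events per ring and frame interval and divides by ring area and
#' interval length, giving rates in mm^-2 h^-1.
#'
#' @param events data.frame with t_h, x_um, y_um, event_type.
#' @param rings A [make_rings()] frame.
#' @param timepoints Frame times bounding the intervals.
#' @return data.frame(t_h (interval start), ring, r_mm, b_mm2_h, a_mm2_h).
#' @export
ring_event_rates <- function(events, rings, timepoints) {
  bnd_um <- rings$boundaries_mm * 1000
  tp <- sort(timepoints)
  grid <- expand.grid(ring = seq_len(rings$n_rings),
                      ti = seq_len(length(tp) - 1L))
  grid$t_h <- tp[grid$ti]
  grid$r_mm <- rings$mids_mm[grid$ring]
  grid$b_mm2_h <- 0; grid$a_mm2_h <- 0
  if (nrow(events)) {
    rr <- sqrt((events$x_um - rings$origin_um[1])^2 +
                 (events$y_um - rings$origin_um[2])^2)
    ring <- findInterval(rr, bnd_um) + 1L
    ti <- findInterval(events$t_h, tp, rightmost.closed = TRUE)
    ti[ti < 1] <- 1; ti[ti >= length(tp)] <- length(tp) - 1L
    ok <- ring <= rings$n_rings
    for (k in which(ok)) {
      i <- which(grid$ring == ring[k] & grid$ti == ti[k])
      dt <- tp[ti[k] + 1L] - tp[ti[k]]
      w <- 1 / (rings$area_mm2 * dt)
      if (events$event_type[k] == "branching")
        grid$b_mm2_h[i] <- grid$b_mm2_h[i] + w
      else if (events$event_type[k] == "anastomosis")
        grid$a_mm2_h[i] <- grid$a_mm2_h[i] + w
    }
  }
  grid[, c("t_h", "ring", "r_mm", "b_mm2_h", "a_mm2_h")]
}

#' Estimate the branching and annihilation coefficients
#'
#' alpha is the zero-intercept slope of the branching rate b on the tip
#' density n; beta the slope of the anastomosis rate a on the density
#' product n*rho, reported in the um/h convention (a = beta * 1e-6 * n *
#' rho). Slopes are exposure-weighted ratio estimators (total events over
#' total density exposure) - the Poisson maximum-likelihood rate, immune to
#' the errors-in-variables attenuation that an unweighted per-frame
#' regression suffers from small per-ring tip counts. Confidence intervals
#' by bootstrap over rings.
#'
#' @param rates Output of [ring_event_rates()].
#' @param profiles Output of [ring_densities()] on the same ring frame.
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed.
#' @return List: alpha_per_h, beta_um_h, their 95% CIs, correlations
#'   cor_b_n and cor_a_nrho, and the merged data.
#' @export
estimate_alpha_beta <- function(rates, profiles, n_boot = 500, seed = 1) {
  d <- merge(rates, profiles, by = c("t_h", "ring", "r_mm"))
  if (!nrow(d)) stop("rates and profiles do not align", call. = FALSE)
  d$nrho <- d$n_mm2 * d$rho_um_mm2 * 1e-6
  if (stats::var(d$n_mm2) == 0 || stats::var(d$nrho) == 0)
    stop("degenerate variance: no density variation to regress on",
         call. = FALSE)
  slope0 <- function(x, y) sum(y) / sum(x)
  alpha <- slope0(d$n_mm2, d$b_mm2_h)
  beta <- slope0(d$nrho, d$a_mm2_h)
  set.seed(seed)
  rings <- unique(d$ring)
  boot <- t(vapply(seq_len(n_boot), function(b) {
    rs <- sample(rings, replace = TRUE)
    db <- do.call(rbind, lapply(rs, function(r) d[d$ring == r, ]))
    c(slope0(db$n_mm2, db$b_mm2_h), slope0(db$nrho, db$a_mm2_h))
  }, numeric(2)))
  list(alpha_per_h = alpha, beta_um_h = beta,
       alpha_ci = unname(stats::quantile(boot[, 1], c(0.025, 0.975),
                                         na.rm = TRUE)),
       beta_ci = unname(stats::quantile(boot[, 2], c(0.025, 0.975),
                                        na.rm = TRUE)),
       cor_b_n = suppressWarnings(stats::cor(d$b_mm2_h, d$n_mm2)),
       cor_a_nrho = suppressWarnings(stats::cor(d$a_mm2_h, d$nrho)),
       data = d)
}

#' Ring-averaged dynamics in the wave frame
#'
#' Shifts every ring's time axis by its arrival time (half-maximum crossing
#' of the ring's filament density), bins the shifted series, and averages
#' branching rate, anastomosis rate, tip density and the density product
#' n*rho across rings. This is the travelling-wave-frame view in which the
#' rate laws b = alpha n and a = beta n rho appear as shape-matched pulses.
#'
#' @param rates Output of [ring_event_rates()].
#' @param profiles Output of [ring_densities()] on the same rings.
#' @param bin_h Width of the relative-time bins (hours).
#' @param min_support Minimum number of ring-frames contributing to a bin;
#'   under-supported bins (the extremes, covered by one or two rings only)
#'   are dropped rather than reported as unstable means.
#' @return List: `profiles` data.frame(t_rel, b, n, a, nrho, support) of
#'   ring-averaged binned means, and `cor_b_n`, `cor_a_nrho` (Pearson
#'   correlations of the aligned mean profiles).
#' @export
wave_frame_profiles <- function(rates, profiles, bin_h = 5,
                                min_support = 20) {
  d <- merge(rates, profiles, by = c("t_h", "ring", "r_mm"))
  arr <- vapply(split(profiles, profiles$ring), function(p) {
    p <- p[order(p$t_h), ]
    peak <- max(p$rho_um_mm2)
    if (peak <= 0) return(NA_real_)
    p$t_h[which(p$rho_um_mm2 >= peak / 2)[1]]
  }, 0)
  d$t_rel <- d$t_h - arr[as.character(d$ring)]
  d <- d[is.finite(d$t_rel), ]
  d$bin <- floor(d$t_rel / bin_h) * bin_h + bin_h / 2
  agg <- stats::aggregate(
    cbind(b = d$b_mm2_h, a = d$a_mm2_h, n = d$n_mm2,
          nrho = d$n_mm2 * d$rho_um_mm2 * 1e-6),
    by = list(t_rel = d$bin), FUN = mean)
  agg$support <- as.vector(table(factor(d$bin, levels = agg$t_rel)))
  agg <- agg[agg$support >= min_support, , drop = FALSE]
  # bin means carry sampling variance ~ 1/support, so the correlations are
  # support-weighted
  wcor <- function(x, y, w) {
    mx <- sum(w * x) / sum(w); my <- sum(w * y) / sum(w)
    sum(w * (x - mx) * (y - my)) /
      sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
  }
  list(profiles = agg,
       cor_b_n = wcor(agg$b, agg$n, agg$support),
       cor_a_nrho = wcor(agg$a, agg$nrho, agg$support))
}

#' Anastomosis density over time
#'
#' Cumulative independent-loop count (Euler formula on each snapshot)
#' normalized by total network length (loops per mm; an area normalization
#' is available behind the `normalization` flag).
#'
#' @param series A `network_series`.
#' @param normalization "length" (default) or "area" (per colony hull mm^2).
#' @return data.frame(t_h, loops, total_length_mm, rho_A).
#' @export
anastomosis_density <- function(series, normalization = c("length", "area")) {
  normalization <- match.arg(normalization)
  out <- lapply(series$timepoints, function(t) {
    sn <- snapshot(series, t, check = FALSE)
    loops <- suppressWarnings(euler_loop_count(sn))
    len_mm <- sum(sn$edges$realized_length_um) / 1000
    denom <- if (normalization == "length") len_mm else
      convex_hull_area(cbind(sn$nodes$x_um, sn$nodes$y_um)) / 1e6
    data.frame(t_h = t, loops = loops, total_length_mm = len_mm,
               rho_A = if (denom > 0) loops / denom else NA_real_)
  })
  do.call(rbind, out)
}
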