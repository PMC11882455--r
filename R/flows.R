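# Kymograph synthesis and classical trajectory extraction, velocity
# statistics, the immotile-object filter, and mapping of flow samples onto
# the network (distance to tip, betweenness centrality) with linear fits.
#
# Trajectory extraction in this field often uses learned kymograph tracers; here
# a classical tracer (per-frame peak detection + nearest-neighbour linking
# with velocity continuity + robust slope fit) fills the same contract:
# trajectories of at least 10 consecutive frames, velocities capped at the
# distance resolvable in 10 frames.

#' Synthesize a kymograph
#'
#' Renders particles moving at constant signed velocity along a 20-um line
#' ROI into a space x time intensity array with Gaussian point-spread and
#' background noise. Positive velocity is tipward (+x).
#'
#' @param particles data.frame(v_um_s, x0_um, t0_s, intensity); particles
#'   leaving the ROI are rendered partially.
#' @param duration_s Recording length (default 20 s).
#' @param dx_um Pixel pitch along the ROI (default 20/144 um).
#' @param dt_s Frame interval (default 1/20 s).
#' @param noise_sd Background Gaussian noise s.d. (intensity units).
#' @param psf_um Gaussian point-spread sigma.
#' @param seed RNG seed (noise only; the geometry is deterministic).
#' @return List of class `kymograph`: `img` (space x time matrix), `dx_um`,
#'   `dt_s`, `x_um`, `t_s`.
#' @export
synthesize_kymograph <- function(particles, duration_s = 20,
                                 dx_um = 20 / 144, dt_s = 1 / 20,
                                 noise_sd = 0.1, psf_um = 0.3, seed = 1) {
  roi <- am_thresholds()$kymo_roi_um
  x <- seq(dx_um / 2, roi - dx_um / 2, by = dx_um)
  tt <- seq(0, duration_s - dt_s, by = dt_s)
  set.seed(seed)
  img <- matrix(stats::rnorm(length(x) * length(tt), 0, noise_sd),
                length(x), length(tt))
  for (i in seq_len(nrow(particles))) {
    p <- particles[i, ]
    xpos <- p$x0_um + p$v_um_s * (tt - p$t0_s)
    live <- tt >= p$t0_s & xpos >= 0 & xpos <= roi
    for (j in which(live)) {
      prof <- p$intensity * exp(-(x - xpos[j])^2 / (2 * psf_um^2))
      img[, j] <- img[, j] + prof
    }
  }
  structure(list(img = img, dx_um = dx_um, dt_s = dt_s, x_um = x, t_s = tt),
            class = "kymograph")
}

#' Write a kymograph as 16-bit TIFF plus JSON sidecar
#'
#' @param kymo A `kymograph`.
#' @param path Output TIFF path; the sidecar replaces the extension with
#'   `.json`.
#' @param meta Extra sidecar fields (plate_id, x_um, y_um, ...).
#' @export
save_kymograph <- function(kymo, path, meta = list()) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required to write TIFF kymographs",
         call. = FALSE)
  img <- kymo$img
  img <- (img - min(img)) / max(max(img) - min(img), 1e-12)
  tiff::writeTIFF(img, path, bits.per.sample = 16)
  side <- c(list(dx_um = kymo$dx_um, dt_s = kymo$dt_s), meta)
  jsonlite::write_json(side, sub("\\.tiff?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a TIFF + JSON kymograph
#' @param path TIFF path written by [save_kymograph()].
#' @export
load_kymograph <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required to read TIFF kymographs",
         call. = FALSE)
  img <- tiff::readTIFF(path)
  side <- jsonlite::read_json(sub("\\.tiff?$", ".json", path),
                              simplifyVector = TRUE)
  x <- seq(side$dx_um / 2, by = side$dx_um, length.out = nrow(img))
  tt <- seq(0, by = side$dt_s, length.out = ncol(img))
  structure(c(list(img = img, x_um = x, t_s = tt), side),
            class = "kymograph")
}

#' Extract particle trajectories from a kymograph
#'
#' Per-frame intensity peaks are linked across frames by nearest-neighbour
#' association with constant-velocity prediction; tracks shorter than
#' `min_frames` are discarded and the velocity (robust line-fit slope) is
#' capped at the speed of an object traversing the full ROI in
#' `min_frames` frames.
#'
#' @param kymo A `kymograph`.
#' @param min_frames Minimum track duration in frames (default 10).
#' @param peak_snr Peak detection threshold in units of the image noise
#'   (MAD-based).
#' @param max_jump_um Maximum unexplained per-frame displacement when
#'   linking.
#' @return data.frame(traj_id, t0_s, duration_frames, v_um_s) with one row
#'   per accepted trajectory; empty (with a warning) for a featureless
#'   image.
#' @export
extract_trajectories <- function(kymo, min_frames = am_thresholds()$min_traj_frames,
                                 peak_snr = 2.5, max_jump_um = 1.5) {
  img <- kymo$img
  nt <- ncol(img)
  noise <- stats::mad(img)
  if (noise == 0 || stats::sd(as.vector(img)) == 0) {
    warning("flat kymograph: no trajectories")
    return(data.frame(traj_id = integer(), t0_s = numeric(),
                      duration_frames = integer(), v_um_s = numeric()))
  }
  thr <- stats::median(img) + peak_snr * noise
  peaks <- vector("list", nt)
  for (j in seq_len(nt)) {
    v <- img[, j]
    is_pk <- v > thr &
      v >= c(-Inf, v[-length(v)]) & v >= c(v[-1], -Inf)
    idx <- which(is_pk)
    # subpixel refinement by parabolic interpolation
    xs <- vapply(idx, function(i) {
      if (i <= 1 || i >= length(v)) return(kymo$x_um[i])
      denom <- v[i - 1] - 2 * v[i] + v[i + 1]
      d <- if (abs(denom) > 1e-12) 0.5 * (v[i - 1] - v[i + 1]) / denom else 0
      kymo$x_um[i] + max(min(d, 0.5), -0.5) * kymo$dx_um
    }, 0)
    peaks[[j]] <- xs
  }
  # greedy linking with constant-velocity prediction
  tracks <- list()   # each: list(x = positions, t = frame indices, vel)
  active <- list()
  for (j in seq_len(nt)) {
    xs <- peaks[[j]]
    used <- rep(FALSE, length(xs))
    if (length(active)) {
      pred <- vapply(active, function(tr) {
        tr$x[length(tr$x)] + tr$vel * kymo$dt_s *
          (j - tr$t[length(tr$t)])
      }, 0)
      ord <- order(vapply(active, function(tr) -length(tr$x), 0))
      for (a in ord) {
        if (!length(xs)) break
        d <- abs(xs - pred[a])
        d[used] <- Inf
        k <- which.min(d)
        if (length(k) && is.finite(d[k]) && d[k] <= max_jump_um) {
          tr <- active[[a]]
          dtj <- (j - tr$t[length(tr$t)]) * kymo$dt_s
          newvel <- (xs[k] - tr$x[length(tr$x)]) / dtj
          # orientation-consistent linking: an established track must not
          # adopt the velocity of a crossing antiparallel line
          if (length(tr$x) >= 5 && abs(newvel - tr$vel) > 3) next
          tr$vel <- if (length(tr$x) < 3) newvel else
            0.7 * tr$vel + 0.3 * newvel
          tr$x <- c(tr$x, xs[k]); tr$t <- c(tr$t, j)
          active[[a]] <- tr
          used[k] <- TRUE
        }
      }
    }
    # close tracks not extended for 2 frames
    if (length(active)) {
      stale <- vapply(active, function(tr) j - tr$t[length(tr$t)] > 2, TRUE)
      tracks <- c(tracks, active[stale])
      active <- active[!stale]
    }
    for (k in which(!used))
      active[[length(active) + 1L]] <- list(x = xs[k], t = j, vel = 0)
  }
  tracks <- c(tracks, active)
  cap <- am_thresholds()$kymo_roi_um / (min_frames * kymo$dt_s)
  rows <- list()
  for (tr in tracks) {
    if (length(tr$t) < min_frames) next
    tt <- tr$t * kymo$dt_s
    # Theil-Sen slope: robust to residual mislinks at line crossings
    n <- length(tt)
    ij <- utils::combn(n, 2)
    dts <- tt[ij[2, ]] - tt[ij[1, ]]
    sl <- (tr$x[ij[2, ]] - tr$x[ij[1, ]]) / dts
    v <- stats::median(sl[dts > 0])
    if (abs(v) > cap) next
    rows[[length(rows) + 1L]] <- data.frame(
      t0_s = tt[1], duration_frames = length(tr$t), v_um_s = v)
  }
  if (!length(rows))
    return(data.frame(traj_id = integer(), t0_s = numeric(),
                      duration_frames = integer(), v_um_s = numeric()))
  out <- do.call(rbind, rows)
  out <- cbind(traj_id = seq_len(nrow(out)), out)
  out
}

#' Filter immotile objects
#'
#' Removes trajectories slower than the diffusion-limited threshold: the
#' average apparent speed of a 35-nm particle diffusing in water for the
#' video duration, v = sqrt(D / dt) with D = kT / (6 pi eta r). The
#' field-standard threshold of 0.8 um/s is the default; the recomputed formula
#' value (about 0.6 um/s at 298 K, 0.89 mPa s) is reported alongside.
#'
#' @param traj data.frame with `v_um_s`.
#' @param threshold_um_s Speed cutoff (default 0.8).
#' @param dt_video_s Video duration for the formula (default 20 s).
#' @param T_K,eta_Pa_s,r_m Temperature, viscosity and particle radius for
#'   the formula report.
#' @return The filtered data.frame; attribute `formula_threshold_um_s`
#'   carries the recomputed value.
#' @export
immotile_filter <- function(traj, threshold_um_s = am_thresholds()$immotile_um_s,
                            dt_video_s = 20, T_K = 298,
                            eta_Pa_s = 0.89e-3, r_m = 35e-9) {
  kB <- 1.380649e-23
  D_m2_s <- kB * T_K / (6 * pi * eta_Pa_s * r_m)
  v_formula <- sqrt(D_m2_s / dt_video_s) * 1e6  # m -> um
  out <- traj[abs(traj$v_um_s) >= threshold_um_s, , drop = FALSE]
  attr(out, "formula_threshold_um_s") <- v_formula
  out
}

#' Direction-partitioned velocity statistics
#'
#' @param v Signed velocities (um/s; + tipward, - rootward) after
#'   filtering.
#' @param n_boot Bootstrap replicates for the s.e.m.
#' @param seed RNG seed.
#' @return List: u_plus, u_minus (means), ratio = |u_plus/u_minus|,
#'   max_plus, max_minus, sem_plus, sem_minus, n_plus, n_minus. The ratio
#'   is NA (flagged) for one-sided samples.
#' @export
velocity_stats <- function(v, n_boot = 500, seed = 1) {
  vp <- v[v > 0]; vm <- v[v < 0]
  boot_sem <- function(x) {
    if (length(x) < 2) return(NA_real_)
    stats::sd(vapply(seq_len(n_boot), function(b)
      mean(sample(x, replace = TRUE)), 0))
  }
  set.seed(seed)
  up <- if (length(vp)) mean(vp) else NA_real_
  um <- if (length(vm)) mean(vm) else NA_real_
  list(u_plus = up, u_minus = um,
       ratio = if (length(vp) && length(vm)) abs(up / um) else NA_real_,
       max_plus = if (length(vp)) max(vp) else NA_real_,
       max_minus = if (length(vm)) min(vm) else NA_real_,
       sem_plus = boot_sem(vp), sem_minus = boot_sem(vm),
       n_plus = length(vp), n_minus = length(vm))
}

#' Diffusion length scale
#'
#' L = 2 D / v_g: the distance from a growing tip within which cytoplasmic
#' diffusion outruns tip growth.
#'
#' @param D_um2_s Cytoplasmic diffusivity (um^2/s).
#' @param v_g_um_h Tip growth speed (um/h).
#' @return Length in mm (Inf, flagged with a warning, for v_g = 0).
#' @export
diffusion_length <- function(D_um2_s, v_g_um_h) {
  if (v_g_um_h == 0) {
    warning("v_g = 0: diffusion length infinite")
    return(Inf)
  }
  v_um_s <- v_g_um_h / 3600
  2 * D_um2_s / v_um_s / 1000
}

#' Map video positions onto the network
#'
#' Snaps each sample position to the nearest edge (within the 100-um
#' alignment budget), computes the curvilinear distance to that hypha's tip
#' along the edge polyline and attaches the host edge's betweenness
#' centrality.
#'
#' @param samples data.frame(x_um, y_um, ...).
#' @param snap A `network_snapshot`.
#' @param bc Result of [betweenness_to_root()] (parent_bc used).
#' @param tol_um Snapping tolerance (default 100).
#' @return `samples` with edge_id, d_tip_mm, bc and snap_dist_um columns;
#'   unmapped rows keep NA and are flagged in a warning.
#' @export
map_flow_to_network <- function(samples, snap, bc,
                                tol_um = am_thresholds()$flow_map_tol_um) {
  ed <- snap$edges
  samples$edge_id <- NA_character_
  samples$d_tip_mm <- NA_real_
  samples$bc <- NA_real_
  samples$snap_dist_um <- NA_real_
  for (k in seq_len(nrow(samples))) {
    p <- c(samples$x_um[k], samples$y_um[k])
    best <- NULL
    for (i in seq_len(nrow(ed))) {
      xy <- ed$realized_polyline[[i]]
      if (nrow(xy) < 2) next
      bb_ok <- p[1] >= min(xy[, 1]) - tol_um & p[1] <= max(xy[, 1]) + tol_um &
        p[2] >= min(xy[, 2]) - tol_um & p[2] <= max(xy[, 2]) + tol_um
      if (!bb_ok) next
      pr <- project_point_polyline(xy, p)
      if (is.null(best) || pr$dist < best$dist) {
        best <- pr; best$i <- i
      }
    }
    if (is.null(best) || best$dist > tol_um) next
    i <- best$i
    samples$edge_id[k] <- ed$edge_id[i]
    # curvilinear distance to the tip end (node_b) of the host hypha
    samples$d_tip_mm[k] <- (ed$realized_length_um[i] - best$s) / 1000
    samples$bc[k] <- as.numeric(bc$parent_bc[ed$edge_id[i]])
    samples$snap_dist_um[k] <- best$dist
  }
  if (anyNA(samples$edge_id))
    warning(sprintf("%d sample(s) farther than %g um from any edge: unmapped",
                    sum(is.na(samples$edge_id)), tol_um))
  samples
}

#' Linear fits of flow speed against a network covariate
#'
#' Separate ordinary least-squares fits of the tipward and rootward mean
#' speeds against `d_tip` or `bc`, with bootstrap 95% confidence intervals
#' on slope and intercept.
#'
#' @param samples data.frame with u_plus_um_s, u_minus_um_s and the
#'   covariate column (d_tip_mm or bc).
#' @param covariate "d_tip_mm" or "bc".
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed.
#' @return List with `plus` and `minus` sublists: slope, intercept,
#'   slope_ci, intercept_ci.
#' @export
flow_gradient_fits <- function(samples, covariate = c("d_tip_mm", "bc"),
                               n_boot = 1000, seed = 1) {
  covariate <- match.arg(covariate)
  x <- samples[[covariate]]
  ok <- is.finite(x)
  if (sum(ok) < 5 || stats::sd(x[ok]) == 0)
    stop("need >= 5 samples spanning the covariate", call. = FALSE)
  fit_one <- function(y) {
    sel <- ok & is.finite(y)
    f <- stats::lm(y[sel] ~ x[sel])
    set.seed(seed)
    n <- sum(sel)
    boot <- t(vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, replace = TRUE)
      if (stats::sd(x[sel][i]) == 0) return(c(NA_real_, NA_real_))
      stats::coef(stats::lm(y[sel][i] ~ x[sel][i]))
    }, numeric(2)))
    list(slope = unname(stats::coef(f)[2]),
         intercept = unname(stats::coef(f)[1]),
         slope_ci = unname(stats::quantile(boot[, 2], c(0.025, 0.975),
                                           na.rm = TRUE)),
         intercept_ci = unname(stats::quantile(boot[, 1], c(0.025, 0.975),
                                               na.rm = TRUE)))
  }
  list(plus = fit_one(samples$u_plus_um_s),
       minus = fit_one(samples$u_minus_um_s))
}
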