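# Branching-annihilating range expansion (BARE) wave model.
#
# Coupled fields on a 1D grid (Cartesian or radial):
#   dn/dt  = alpha*n - beta*n*rho + div(J),  J = D_n grad(n) - v n rhat
#   drho/dt = v * n
# with n the growing-tip density [mm^-2], rho the filament length density
# [um mm^-2], v the tip advection speed [um/h]. beta is given in the field's
# um/h convention, i.e. the annihilation rate per tip is
# beta * rho * 1e-6 h^-1 (the um^2/mm^2 factor), so that
# beta * rho_sat ~ 2%/h at the measured parameters.
#
# Optional phosphorus extension (declared model assumption, first order in
# rho and P):  dP/dt = D_P lap(P) - k_up * rho * P, absorbed P accumulated
# exactly so that medium + absorbed is conserved by construction.

#' BARE wave model parameters
#'
#' @param alpha_per_h Tip branching rate (h^-1).
#' @param beta_um_per_h Annihilation coefficient in the um/h convention
#'   (rate = beta * rho * 1e-6 per hour with rho in um/mm^2).
#' @param v_um_per_h Tip advection speed (um/h).
#' @param D_n_um2_per_h Tip diffusivity inside the flux J. The default keeps
#'   the pulled-front correction 2*sqrt(alpha*D_n) below 2% of v.
#' @param geometry "cartesian" or "radial" 1D.
#' @param r_max_mm Domain size (mm).
#' @param dr_um Grid spacing (um).
#' @param courant Courant number v*dt/dr; at 1 the upwind transport step is
#'   exact (zero numerical diffusion), which is the default.
#' @param k_up Phosphorus uptake coefficient (per (um/mm^2) per hour, i.e.
#'   uptake rate = k_up * rho).
#' @param D_P_um2_per_h Phosphorus diffusivity.
#' @param P0 Initial uniform phosphorus concentration (arbitrary units).
#' @param carbon_cost_per_um Carbon cost per um of filament (gamma).
#' @return List of class `bare_params`.
#' @export
bare_params <- function(alpha_per_h = 0.04, beta_um_per_h = 23,
                        v_um_per_h = 280, D_n_um2_per_h = 12,
                        geometry = c("cartesian", "radial"),
                        r_max_mm = 60, dr_um = 50, courant = 1,
                        k_up = 0, D_P_um2_per_h = 3600, P0 = 1,
                        carbon_cost_per_um = 1) {
  geometry <- match.arg(geometry)
  p <- list(alpha = alpha_per_h, beta = beta_um_per_h, v = v_um_per_h,
            D_n = D_n_um2_per_h, geometry = geometry,
            r_max_um = r_max_mm * 1000, dr = dr_um, courant = courant,
            k_up = k_up, D_P = D_P_um2_per_h, P0 = P0,
            gamma = carbon_cost_per_um)
  stopifnot(p$alpha >= 0, p$beta >= 0, p$v > 0, p$D_n >= 0, p$dr > 0,
            p$courant > 0, p$courant <= 1)
  class(p) <- "bare_params"
  p
}

#' Integrate the BARE wave equations
#'
#' Conservative first-order upwind advection (exact at Courant number 1),
#' explicit central diffusion, explicit reaction, forward Euler in time.
#'
#' @param params A [bare_params()] list.
#' @param t_max_h Integration time (hours).
#' @param n0 Optional initial tip density profile (defaults to a compact
#'   pulse of height 1 mm^-2 over the first 0.5 mm).
#' @param rho0 Optional initial filament density (defaults to 0).
#' @param save_every_h Interval at which fields are stored.
#' @param phosphorus Couple the phosphorus field (requires `k_up`, `P0`).
#' @return A `wave_solution`: list with `r_um`, `t_h`, matrices `n`, `rho`
#'   (space x time) and, with phosphorus, `P`, `P_flux` and the cumulative
#'   absorbed amount `absorbed`, plus `params`.
#' @export
integrate_bare <- function(params = bare_params(), t_max_h = 200,
                           n0 = NULL, rho0 = NULL, save_every_h = 2,
                           phosphorus = FALSE) {
  p <- params
  r <- seq(p$dr / 2, p$r_max_um - p$dr / 2, by = p$dr)  # cell centres
  m <- length(r)
  dt <- p$courant * p$dr / p$v
  # radial upwind outflux scales with (r + dr/2)/r, largest in the first
  # cell (factor 2): shrink dt so the update stays positivity-preserving
  if (p$geometry == "radial") dt <- dt * 0.45
  # explicit diffusion stability
  if (p$D_n * dt / p$dr^2 > 0.5)
    stop(sprintf("CFL violation for diffusion: need dt <= %.4g h (have %.4g)",
                 0.5 * p$dr^2 / p$D_n, dt), call. = FALSE)
  if (phosphorus && p$D_P * dt / p$dr^2 > 0.5)
    stop(sprintf("CFL violation for P diffusion: need dt <= %.4g h",
                 0.5 * p$dr^2 / p$D_P), call. = FALSE)
  n <- if (is.null(n0)) ifelse(r <= 500, 1, 0) else n0
  rho <- if (is.null(rho0)) numeric(m) else rho0
  P <- rep(p$P0, m)
  absorbed <- 0
  stopifnot(length(n) == m, length(rho) == m)

  nt <- floor(t_max_h / dt)
  save_steps <- unique(c(0, seq(0, nt, by = max(1L, round(save_every_h / dt))),
                         nt))
  save_steps <- sort(save_steps)
  t_out <- save_steps * dt
  N <- matrix(0, m, length(save_steps))
  RHO <- matrix(0, m, length(save_steps))
  PP <- if (phosphorus) matrix(0, m, length(save_steps)) else NULL
  PF <- if (phosphorus) matrix(0, m, length(save_steps)) else NULL
  ABS <- numeric(length(save_steps))
  ksave <- 1L
  store <- function(k) {
    N[, ksave] <<- n; RHO[, ksave] <<- rho
    if (phosphorus) {
      PP[, ksave] <<- P
      PF[, ksave] <<- p$k_up * 1e-6 * rho * P
      ABS[ksave] <<- absorbed
    }
    ksave <<- ksave + 1L
  }
  store(0)

  # radial geometry factors (finite volume): faces at r_i +- dr/2
  if (p$geometry == "radial") {
    rf_lo <- r - p$dr / 2
    rf_hi <- r + p$dr / 2
  }
  cfl <- p$v * dt / p$dr

  for (k in seq_len(nt)) {
    # advection (outward, upwind): influx from the left neighbour
    nin <- c(0, n[-m])
    if (p$geometry == "cartesian") {
      n_adv <- n + cfl * (nin - n)
    } else {
      # conservative radial divergence of v*n
      n_adv <- n + dt * p$v * (c(0, rf_lo[-1] * n[-m])[1:m] - rf_hi * n) /
        (r * p$dr)
    }
    # diffusion (zero-flux boundaries)
    if (p$D_n > 0) {
      if (p$geometry == "cartesian") {
        lap <- (c(n_adv[1], n_adv[-m]) - 2 * n_adv +
                  c(n_adv[-1], n_adv[m])) / p$dr^2
      } else {
        gl <- c(0, (n_adv[-1] - n_adv[-m]) / p$dr)   # flux at lower faces
        gh <- c(gl[-1], 0)
        lap <- (rf_hi * gh - rf_lo * gl) / (r * p$dr)
      }
      n_adv <- n_adv + dt * p$D_n * lap
    }
    n_adv[n_adv < 0] <- 0  # roundoff guard at the radial origin
    # reaction
    growth <- p$alpha - p$beta * 1e-6 * rho
    n_new <- n_adv * (1 + dt * growth)
    if (any(n_new < -1e-12))
      stop("negative tip density: unstable step (reduce dt or beta)",
           call. = FALSE)
    n_new[n_new < 0] <- 0
    rho <- rho + dt * p$v * n_new
    n <- n_new
    if (phosphorus) {
      if (p$D_P > 0) {
        if (p$geometry == "cartesian") {
          lapP <- (c(P[1], P[-m]) - 2 * P + c(P[-1], P[m])) / p$dr^2
        } else {
          gl <- c(0, (P[-1] - P[-m]) / p$dr)
          gh <- c(gl[-1], 0)
          lapP <- (rf_hi * gh - rf_lo * gl) / (r * p$dr)
        }
        P <- P + dt * p$D_P * lapP
      }
      dup <- dt * p$k_up * 1e-6 * rho * P
      dup <- pmin(dup, P)
      P <- P - dup
      vol <- if (p$geometry == "radial") pi * (rf_hi^2 - rf_lo^2) / 2 else p$dr
      absorbed <- absorbed + sum(dup * vol)
    }
    if (ksave <= length(save_steps) && k == save_steps[ksave]) store(k)
  }
  structure(list(r_um = r, t_h = t_out, n = N, rho = RHO, P = PP, P_flux = PF,
                 absorbed = ABS, params = p, dt_h = dt,
                 phosphorus = phosphorus),
            class = "wave_solution")
}

#' Integrate the phosphorus-coupled BARE model
#'
#' Convenience wrapper around [integrate_bare()] with `phosphorus = TRUE`.
#' @inheritParams integrate_bare
#' @export
integrate_bare_phosphorus <- function(params, t_max_h = 200, ...) {
  if (params$P0 <= 0) stop("P0 must be positive", call. = FALSE)
  integrate_bare(params, t_max_h = t_max_h, phosphorus = TRUE, ...)
}

#' Total phosphorus (medium + absorbed) over time
#'
#' @param sol A phosphorus-coupled `wave_solution`.
#' @return Numeric vector over saved times; constant to discretization error.
#' @export
total_phosphorus <- function(sol) {
  stopifnot(sol$phosphorus)
  p <- sol$params
  r <- sol$r_um
  vol <- if (p$geometry == "radial")
    pi * ((r + p$dr / 2)^2 - (r - p$dr / 2)^2) / 2 else p$dr
  colSums(sol$P * vol) + sol$absorbed
}

#' Measure travelling-wave metrics from a solution
#'
#' Front position per time = outermost half-maximum crossing of the filament
#' density (linearly interpolated); wave speed c = slope of a linear fit of
#' front position over the final half of the run; rho_sat = mean plateau
#' density well behind the final front.
#'
#' @param sol A `wave_solution` (or any list with `r_um`, `t_h`, `rho`).
#' @return List with `c_um_h`, `rho_sat`, `front_width_um` (10-90% width at
#'   the final time) and the `front_position_um` series.
#' @export
measure_wave <- function(sol) {
  r <- sol$r_um; tt <- sol$t_h; RHO <- sol$rho
  last_prof <- RHO[, ncol(RHO)]
  ref <- max(last_prof)
  if (ref <= 0) stop("no filament front in solution", call. = FALSE)
  if (ref - min(last_prof) < 1e-9 * ref)
    stop("solution is flat: no front to measure", call. = FALSE)
  cross_at <- function(prof, level) {
    # outermost downward crossing of `level`
    above <- prof >= level
    if (!any(above)) return(NA_real_)
    i <- max(which(above))
    if (i == length(prof)) return(NA_real_)  # front at boundary
    f <- (prof[i] - level) / (prof[i] - prof[i + 1])
    r[i] + f * (r[i + 1] - r[i])
  }
  half <- apply(RHO, 2, function(prof) cross_at(prof, max(prof) / 2))
  if (is.na(half[length(half)]))
    stop("front reached the domain boundary: increase r_max_mm",
         call. = FALSE)
  sel <- which(tt >= max(tt) / 2 & !is.na(half))
  if (length(sel) < 4 || stats::sd(half[sel]) == 0)
    stop("no advancing front: solution appears flat", call. = FALSE)
  fit <- stats::lm(half[sel] ~ tt[sel])
  c_um_h <- unname(stats::coef(fit)[2])
  fp <- half[length(half)]
  plateau <- RHO[r < 0.5 * fp, ncol(RHO)]
  rho_sat <- if (length(plateau)) mean(plateau) else NA_real_
  prof <- RHO[, ncol(RHO)]
  w <- cross_at(prof, 0.1 * max(prof)) - cross_at(prof, 0.9 * max(prof))
  list(c_um_h = c_um_h, rho_sat = rho_sat, front_width_um = w,
       front_position_um = half, t_h = tt)
}

#' Carbon cost per unit of absorbed phosphorus
#'
#' gamma * (total filament length) / (cumulative absorbed P) as a time
#' series. Undefined (NA) wherever nothing has been absorbed.
#'
#' @param sol A phosphorus-coupled `wave_solution`.
#' @param params The `bare_params` used (for gamma); defaults to
#'   `sol$params`.
#' @return data.frame(t_h, total_length, absorbed, cost_per_P).
#' @export
cost_per_phosphorus <- function(sol, params = sol$params) {
  stopifnot(sol$phosphorus)
  p <- sol$params
  r <- sol$r_um
  vol <- if (p$geometry == "radial")
    pi * ((r + p$dr / 2)^2 - (r - p$dr / 2)^2) / 2 else p$dr
  total_len <- colSums(sol$rho * vol)    # um * mm^2/mm^2 aggregate
  cost <- params$gamma * total_len / ifelse(sol$absorbed > 0, sol$absorbed, NA)
  data.frame(t_h = sol$t_h, total_length = total_len, absorbed = sol$absorbed,
             cost_per_P = cost)
}
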