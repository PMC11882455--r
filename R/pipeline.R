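# End-to-end orchestration: one seeded configuration drives simulate ->
# profile -> events -> metrics -> pde -> flows and writes CSV/JSON reports.
# The numbered scripts under analysis/ are thin drivers over this function.

#' Default pipeline configuration
#'
#' @param seed Master seed; every stochastic stage derives its own stream
#'   from it.
#' @param out_dir Output directory for reports (NULL: nothing written).
#' @param sim A [sim_params()] list.
#' @param bare A [bare_params()] list.
#' @param n_rings Ring count for the density frame.
#' @param stages Character subset of
#'   c("simulate", "profile", "events", "metrics", "pde", "flows").
#' @return A config list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL,
                            sim = NULL, bare = bare_params(),
                            n_rings = 15,
                            stages = c("simulate", "profile", "events",
                                       "metrics", "pde", "flows")) {
  if (is.null(seed)) stop("config must provide a seed", call. = FALSE)
  seed <- as.integer(seed)
  if (is.null(sim)) sim <- sim_params(seed = seed)
  else sim$seed <- seed
  list(seed = seed, out_dir = out_dir, sim = sim, bare = bare,
       n_rings = n_rings, stages = stages)
}

#' Run the analysis pipeline
#'
#' @param config A [pipeline_config()] list.
#' @param quiet Suppress progress messages.
#' @return List of stage results (sim, profiles, fits, rates, alpha_beta,
#'   metrics, wave, flows), invisibly writing CSVs/JSON under
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  res <- list(config = config)
  outd <- config$out_dir
  if (!is.null(outd)) dir.create(outd, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name) name %in% config$stages

  if (stage("simulate") || any(c("profile", "events", "metrics", "flows")
                               %in% config$stages)) {
    say("simulate: agent-based colony (seed %d)", config$seed)
    sim <- simulate_colony(config$sim)
    sim <- decorate_bas(sim, config$sim)
    sim <- inject_spores(sim, config$sim)
    res$sim <- sim
    if (!is.null(outd)) save_series(sim$series, file.path(outd, "bundle"))
  }
  if (stage("profile")) {
    say("profile: ring densities and wave metrics")
    r_max <- max(sqrt(res$sim$series$nodes$x_um^2 +
                        res$sim$series$nodes$y_um^2)) / 1000
    rings <- make_rings(c(0, 0), r_max_mm = r_max * 1.02,
                        n_rings = config$n_rings)
    prof <- ring_densities(res$sim$series, rings)
    fits <- arrival_times(prof, n_boot = 100)
    res$rings <- rings; res$profiles <- prof; res$fits <- fits
    ok <- fits[fits$converged, ]
    if (nrow(ok) >= 4)
      res$wave_speed <- wavefront_speed(ok$t_n_h, ok$r_mm)
    if (!is.null(outd)) {
      utils::write.csv(prof, file.path(outd, "profiles.csv"),
                       row.names = FALSE)
      utils::write.csv(fits, file.path(outd, "fits.csv"), row.names = FALSE)
    }
  }
  if (stage("events")) {
    say("events: detection and rate scaling")
    det <- rbind(detect_branchings(res$sim$series),
                 detect_anastomoses(res$sim$series))
    rates <- ring_event_rates(det, res$rings, res$sim$series$timepoints)
    res$detected <- det; res$rates <- rates
    res$alpha_beta <- try(estimate_alpha_beta(rates, res$profiles,
                                              n_boot = 200), silent = TRUE)
    if (!is.null(outd)) {
      utils::write.csv(det, file.path(outd, "events_detected.csv"),
                       row.names = FALSE)
      utils::write.csv(rates, file.path(outd, "rates.csv"),
                       row.names = FALSE)
      if (!inherits(res$alpha_beta, "try-error"))
        jsonlite::write_json(
          res$alpha_beta[c("alpha_per_h", "beta_um_h", "alpha_ci",
                           "beta_ci")],
          file.path(outd, "alpha_beta.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  if (stage("metrics")) {
    say("metrics: BC, efficiencies, MST/DT normalization")
    tl <- max(res$sim$series$timepoints)
    sn <- snapshot(res$sim$series, tl)
    bc <- betweenness_to_root(sn)
    res$bc <- bc
    res$metrics <- normalized_metrics(sn)
    res$rho_A <- anastomosis_density(res$sim$series)
    if (!is.null(outd)) {
      jsonlite::write_json(unclass(res$metrics),
                           file.path(outd, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      utils::write.csv(res$rho_A, file.path(outd, "anastomosis_density.csv"),
                       row.names = FALSE)
    }
  }
  if (stage("pde")) {
    say("pde: BARE wave integration")
    sol <- integrate_bare(config$bare, t_max_h = 200)
    res$wave <- measure_wave(sol)
    if (!is.null(outd)) {
      utils::write.csv(
        data.frame(t_h = res$wave$t_h,
                   front_position_um = res$wave$front_position_um),
        file.path(outd, "front_position.csv"), row.names = FALSE)
      jsonlite::write_json(res$wave[c("c_um_h", "rho_sat",
                                      "front_width_um")],
                           file.path(outd, "wave_metrics.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  if (stage("flows")) {
    say("flows: kymograph fixtures and velocity recovery")
    tl <- max(res$sim$series$timepoints)
    sn <- snapshot(res$sim$series, tl)
    bc <- res$bc
    if (is.null(bc)) bc <- betweenness_to_root(sn)
    field <- synthesize_flow_field(sn, bc$parent_bc, k1 = 0, k2 = 0.3)
    res$flow_field <- field
    # render a handful of kymographs on the longest hyphae and recover
    cand <- order(-sn$edges$realized_length_um)[seq_len(min(8, nrow(sn$edges)))]
    samp <- list()
    for (i in cand) {
      tr <- field[field$edge_id == sn$edges$edge_id[i], ]
      if (tr$u_plus_um_s <= 0) next
      parts <- kymo_particles(tr$u_plus_um_s, tr$u_minus_um_s,
                              n_each = 6, seed = config$seed + i)
      kym <- synthesize_kymograph(parts, seed = config$seed + i)
      traj <- immotile_filter(extract_trajectories(kym))
      st <- velocity_stats(traj$v_um_s)
      mid <- point_at_arclength(sn$edges$realized_polyline[[i]],
                                sn$edges$realized_length_um[i] / 2)
      samp[[length(samp) + 1L]] <- data.frame(
        edge_id = sn$edges$edge_id[i], x_um = mid[1], y_um = mid[2],
        u_plus_um_s = st$u_plus, u_minus_um_s = st$u_minus,
        true_plus = tr$u_plus_um_s, true_minus = tr$u_minus_um_s)
    }
    res$flow_samples <- if (length(samp)) do.call(rbind, samp) else NULL
    if (!is.null(outd) && !is.null(res$flow_samples))
      utils::write.csv(res$flow_samples, file.path(outd, "flows.csv"),
                       row.names = FALSE)
  }
  say("pipeline complete")
  invisible(res)
}

#' Particle list for a two-stream kymograph fixture
#'
#' @param u_plus,u_minus Mean tipward / rootward speeds (um/s; u_minus < 0).
#' @param n_each Particles per direction.
#' @param spread Relative s.d. of per-particle speeds.
#' @param seed RNG seed.
#' @return data.frame(v_um_s, x0_um, t0_s, intensity).
#' @export
kymo_particles <- function(u_plus, u_minus, n_each = 6, spread = 0.05,
                           seed = 1) {
  set.seed(seed)
  roi <- am_thresholds()$kymo_roi_um
  v <- c(stats::rnorm(n_each, u_plus, abs(u_plus) * spread),
         stats::rnorm(n_each, u_minus, abs(u_minus) * spread))
  data.frame(v_um_s = v,
             x0_um = stats::runif(2 * n_each, 0.1 * roi, 0.9 * roi),
             t0_s = stats::runif(2 * n_each, 0, 6),
             intensity = stats::runif(2 * n_each, 0.8, 1.2))
}
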