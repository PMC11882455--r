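#!/usr/bin/env Rscript
# Stage 2: ring-frame density profiles, sigmoid arrival times, wavefront
# speed and puller-tip speeds for the bundled colony of stage 1.

suppressPackageStartupMessages(library(amwave))

out <- "results"
series <- load_series(file.path(out, "bundle"), check_degrees = "none")

r_max <- max(sqrt(series$nodes$x_um^2 + series$nodes$y_um^2)) / 1000
rings <- make_rings(c(0, 0), r_max_mm = r_max * 1.02, n_rings = 15)
message(sprintf("15 equal-area rings out to %.1f mm (ring area %.1f mm^2)",
                rings$r_max_mm, rings$area_mm2))

profiles <- ring_densities(series, rings)
utils::write.csv(profiles, file.path(out, "profiles.csv"),
                 row.names = FALSE)

fits <- arrival_times(profiles, n_boot = 200)
utils::write.csv(fits, file.path(out, "fits.csv"), row.names = FALSE)
ok <- fits[fits$converged, ]
message(sprintf("%d/%d ring fits converged", nrow(ok), nrow(fits)))

if (nrow(ok) >= 4) {
  ws <- wavefront_speed(ok$t_n_h, ok$r_mm)
  message(sprintf("wavefront speed from arrival times: %.0f um/h (95%% CI %.0f-%.0f)",
                  ws$c_um_h, ws$ci[1], ws$ci[2]))
  sat <- saturating_density_vs_radius(fits, n_boot = 500)
  message(sprintf(
    "saturating density vs radius: slope %.1f um mm^-2 per mm (relative span %.2f)",
    sat$slope, sat$relative_span))
  jsonlite::write_json(list(c_um_h = ws$c_um_h, c_ci = ws$ci,
                            K1_slope = sat$slope,
                            K1_relative_span = sat$relative_span),
                       file.path(out, "wave_speed.json"),
                       auto_unbox = TRUE, digits = NA)
}

ts <- series$timepoints
ts <- ts[ts >= max(ts) * 0.6 & ts < max(ts)]
vp <- vapply(ts[seq(1, length(ts), by = 5)], function(t)
  suppressWarnings(puller_tips(series, t))$v_p_um_h, 0)
message(sprintf("mean puller-tip speed: %.0f um/h", mean(vp)))

radii <- vapply(ts, function(t) colony_radius(snapshot(series, t)), 0)
slope <- unname(coef(lm(radii ~ ts))[2]) * 1000
message(sprintf("colony radius growth (hull semicircle): %.0f um/h", slope))
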