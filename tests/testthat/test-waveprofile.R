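test_that("equal-area rings have the closed-form boundaries", {
  rings <- make_rings(c(0, 0), r_max_mm = 45, n_rings = 15)
  expect_equal(rings$boundaries_mm[1], 45 * sqrt(1 / 15), tolerance = 1e-12)
  expect_equal(rings$area_mm2, pi * 45^2 / (2 * 15))
  areas <- diff(c(0, rings$boundaries_mm^2)) * pi / 2
  expect_true(all(abs(areas - rings$area_mm2) < 1e-6 * rings$area_mm2))
  two <- make_rings(c(0, 0), 45, 2)
  expect_equal(two$boundaries_mm, c(45 / sqrt(2), 45))
  expect_error(make_rings(c(0, 0), 45, 1), "n_rings")
})

test_that("a fully interior edge yields its length over the ring area", {
  ser <- toy_series(t_max = 2, speed = 500)  # 1000 um straight hypha
  rings <- make_rings(c(0, 0), r_max_mm = 10, n_rings = 2)
  prof <- ring_densities(ser, rings, tip_filter = "growing")
  last <- prof[prof$t_h == 2 & prof$ring == 1, ]
  expect_equal(last$rho_um_mm2, 1000 / rings$area_mm2, tolerance = 1e-9)
  expect_equal(prof[prof$t_h == 2 & prof$ring == 2, ]$rho_um_mm2, 0)
})

test_that("clipped ring densities conserve total filament length", {
  sim <- sim_fixture()
  ser <- sim$series
  t <- max(ser$timepoints)
  rings <- make_rings(c(0, 0), r_max_mm = 40, n_rings = 10)
  prof <- ring_densities(ser, rings, tip_filter = "growing")
  sn <- snapshot(ser, t)
  inside <- sum(vapply(sn$edges$realized_polyline, function(xy)
    sum(clip_length_radial(xy, c(0, 0), 40000)[1]), 0))
  got <- sum(prof$rho_um_mm2[prof$t_h == t] * rings$area_mm2)
  expect_equal(got, inside, tolerance = 1e-6)
})

test_that("bootstrap density s.d. shrinks for uniform fields and is seeded",
{
  # uniform grid of short vertical segments across the first ring
  xs <- seq(-9000, 9000, by = 600)
  ys <- seq(500, 9000, by = 600)
  grid <- expand.grid(x = xs, y = ys)
  nodes <- list(); edges <- list()
  for (k in seq_len(nrow(grid))) {
    poly <- cbind(c(grid$x[k], grid$x[k]), c(grid$y[k], grid$y[k] + 200))
    nodes[[k]] <- data.frame(
      node_id = paste0(c("a", "b"), k), t_h = 0,
      x_um = poly[, 1], y_um = poly[, 2], degree = 1)
    edges[[k]] <- list(edge_id = paste0("e", k),
                       node_a = paste0("a", k), node_b = paste0("b", k),
                       birth_t_h = 0, length_um = 200, width_um = 5,
                       label = "RH", polyline = poly)
  }
  ed <- do.call(rbind, lapply(edges, function(e)
    data.frame(e[setdiff(names(e), "polyline")],
               stringsAsFactors = FALSE)))
  ed$polyline <- lapply(edges, `[[`, "polyline")
  ser <- network_series(do.call(rbind, nodes), ed,
                        meta = list(root_anchors =
                                      data.frame(node_id = character(),
                                                 x_um = numeric(),
                                                 y_um = numeric())),
                        validate = FALSE)
  rings <- make_rings(c(0, 0), r_max_mm = 12, n_rings = 2)
  coarse <- bootstrap_density_sd(ser, rings, ring = 1, t = 0,
                                 n_cells = 100, n_boot = 60, seed = 4)
  fine <- bootstrap_density_sd(ser, rings, ring = 1, t = 0,
                               n_cells = 2500, n_boot = 60, seed = 4)
  expect_lt(fine$sd / fine$mean, 0.25)
  again <- bootstrap_density_sd(ser, rings, ring = 1, t = 0,
                                n_cells = 2500, n_boot = 60, seed = 4)
  expect_identical(fine$sd, again$sd)
  expect_equal(fine$mean, coarse$mean, tolerance = 0.05)
})

test_that("bootstrap s.d. tracks the analytic sampling error of a Poisson
           line process", {
  set.seed(8)
  # N segments of length L dropped uniformly in the half-disc r < 12 mm
  R <- 12000; L <- 400; N <- 400
  rr <- R * sqrt(runif(N)); th <- runif(N, 0, pi)
  x0 <- rr * cos(th); y0 <- rr * sin(th)
  ang <- runif(N, 0, 2 * pi)
  nodes <- list(); edges <- list()
  for (k in seq_len(N)) {
    poly <- cbind(c(x0[k], x0[k] + L * cos(ang[k])),
                  c(y0[k], y0[k] + L * sin(ang[k])))
    nodes[[k]] <- data.frame(node_id = paste0(c("a", "b"), k), t_h = 0,
                             x_um = poly[, 1], y_um = poly[, 2], degree = 1)
    edges[[k]] <- list(edge_id = paste0("e", k), node_a = paste0("a", k),
                       node_b = paste0("b", k), birth_t_h = 0,
                       length_um = L, width_um = 5, label = "RH",
                       polyline = poly)
  }
  ed <- do.call(rbind, lapply(edges, function(e)
    data.frame(e[setdiff(names(e), "polyline")], stringsAsFactors = FALSE)))
  ed$polyline <- lapply(edges, `[[`, "polyline")
  ser <- network_series(do.call(rbind, nodes), ed,
                        meta = list(root_anchors =
                                      data.frame(node_id = character(),
                                                 x_um = numeric(),
                                                 y_um = numeric())),
                        validate = FALSE)
  rings <- make_rings(c(0, 0), r_max_mm = 12, n_rings = 2)
  bs <- bootstrap_density_sd(ser, rings, ring = 1, t = 0, n_cells = 900,
                             n_boot = 100, seed = 1)
  # analytic: mean density = N_in * L / A; sampling sd of the mean over a
  # Poisson number of segments ~ sqrt(N_in) * L / A
  A <- rings$area_mm2
  n_in <- bs$mean * A / L
  analytic_sd <- sqrt(n_in) * L / A
  expect_lt(abs(bs$sd - analytic_sd) / analytic_sd, 0.30)
})

test_that("colony radius inverts the semicircle area formula", {
  # half-disc of radius 10 mm sampled densely on its boundary
  th <- seq(0, pi, length.out = 200)
  nodes <- data.frame(node_id = paste0("n", seq_along(th)), t_h = 0,
                      x_um = 10000 * cos(th), y_um = 10000 * sin(th),
                      degree = 0)
  ed <- data.frame(edge_id = character(), node_a = character(),
                   node_b = character(), birth_t_h = numeric(),
                   length_um = numeric(), width_um = numeric(),
                   label = character(), stringsAsFactors = FALSE)
  ed$polyline <- list()
  ser <- network_series(nodes, ed, meta = list(), validate = FALSE)
  sn <- snapshot(ser, 0, check = FALSE)
  expect_equal(colony_radius(sn), 10, tolerance = 1e-3)
})

test_that("colony radius grows at the puller speed on simulated colonies", {
  sim <- memo("sim100_1", function()
    simulate_colony(sim_params(seed = 1, t_max_h = 100)))
  ser <- sim$series
  tt <- ser$timepoints[ser$timepoints >= 40]
  rr <- vapply(tt, function(t) colony_radius(snapshot(ser, t)), 0)
  slope <- unname(coef(stats::lm(rr ~ tt))[2]) * 1000
  vp <- mean(vapply(seq(60, 95, 5), function(t)
    puller_tips(ser, t)$v_p_um_h, 0))
  expect_equal(slope, vp, tolerance = 0.10)
})

test_that("sigmoid fits recover noiseless parameters to 0.1%", {
  tt <- seq(0, 100, by = 2)
  y <- 2000 / (1 + exp(0.1 * (50 - tt)))
  f <- fit_sigmoid_rho(tt, y, n_boot = 20)
  expect_equal(f$K, 2000, tolerance = 1e-3)
  expect_equal(f$lambda, 0.1, tolerance = 1e-3)
  expect_equal(f$t_n, 50, tolerance = 1e-3)
  ytip <- 4 * 80 * exp(0.1 * (50 - tt)) / (1 + exp(0.1 * (50 - tt)))^2 / 4
  ft <- fit_sigmoid_tip(tt, ytip, n_boot = 20)
  expect_equal(ft$t_n, 50, tolerance = 1e-3)
  expect_error(fit_sigmoid_rho(tt, rep(0, length(tt))), "all-zero")
  expect_error(fit_sigmoid_rho(tt, 2000 - 15 * tt), "monotone-decreasing")
})

test_that("noisy sigmoid arrival times fall inside their bootstrap CI", {
  tt <- seq(0, 100, by = 2)
  mu <- 2000 / (1 + exp(0.1 * (50 - tt)))
  hits <- 0; n_rep <- 100
  for (k in seq_len(n_rep)) {
    set.seed(200 + k)
    y <- mu + rnorm(length(tt), 0, 100)  # 5% of the plateau
    f <- fit_sigmoid_rho(tt, y, n_boot = 100, seed = k)
    if (f$converged && f$ci[1, "t_n"] <= 50 && 50 <= f$ci[2, "t_n"])
      hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("wavefront speed fits a line through front positions", {
  tt <- seq(10, 60, by = 5)
  ws <- wavefront_speed(tt, 0.28 * tt)
  expect_equal(ws$c_um_h, 280, tolerance = 1e-9)
  ws0 <- wavefront_speed(tt, rep(3, length(tt)))
  expect_equal(ws0$c_um_h, 0, tolerance = 1e-9)
  expect_error(wavefront_speed(1:3, 1:3), "at least 4")
})

test_that("saturating density regression recovers ramps and flats", {
  fits <- data.frame(ring = 1:8, r_mm = seq(2, 16, by = 2),
                     t_n_h = NA, K1 = 1000, lambda = 0.1, converged = TRUE)
  flat <- saturating_density_vs_radius(fits, n_boot = 100)
  expect_equal(flat$slope, 0, tolerance = 1e-9)
  fits$K1 <- 100 + 25 * fits$r_mm
  ramp <- saturating_density_vs_radius(fits, n_boot = 100)
  expect_equal(ramp$slope, 25, tolerance = 1e-9)
  fits$converged[1:6] <- FALSE
  expect_error(suppressWarnings(
    saturating_density_vs_radius(fits, n_boot = 10)), ">= 3")
})

test_that("a lone straight hypha's tip is its only puller", {
  ser <- toy_series(t_max = 5, speed = 500)
  out <- suppressWarnings(puller_tips(ser, 3))
  expect_true("tip" %in% out$ids)
  expect_equal(out$v_p_um_h, 500, tolerance = 1e-9)
})

test_that("puller tips run faster than the population average", {
  sim <- memo("sim100_1", function()
    simulate_colony(sim_params(seed = 1, t_max_h = 100)))
  ser <- sim$series
  ts <- seq(60, 95, 5)
  vp <- mean(vapply(ts, function(t) puller_tips(ser, t)$v_p_um_h, 0))
  # population: mean per-frame displacement of all growing tips
  pop <- unlist(lapply(ts, function(t) {
    ids <- growing_tips(ser, t)
    p1 <- node_positions_at(ser, t - 1)
    p2 <- node_positions_at(ser, t)
    i <- match(ids, p2$node_id); j <- match(ids, p1$node_id)
    sqrt((p2$x_um[i] - p1$x_um[j])^2 + (p2$y_um[i] - p1$y_um[j])^2)
  }))
  expect_gt(vp, mean(pop))
})
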