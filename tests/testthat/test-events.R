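snap_with_edges <- function(lens, widths, tip_end = FALSE) {
  # minimal snapshot stand-in for the edge classifier
  n <- length(lens)
  nodes <- data.frame(node_id = c(paste0("a", 1:n), paste0("b", 1:n)),
                      x_um = 0, y_um = 0,
                      degree = c(rep(3, n), rep(ifelse(tip_end, 1, 3), n)),
                      stringsAsFactors = FALSE)
  edges <- data.frame(edge_id = paste0("e", 1:n), node_a = paste0("a", 1:n),
                      node_b = paste0("b", 1:n), birth_t_h = 0,
                      length_um = lens, width_um = widths, label = "RH",
                      realized_length_um = lens, stringsAsFactors = FALSE)
  structure(list(t = 0, nodes = nodes, edges = edges),
            class = "network_snapshot")
}

test_that("BAS criteria fire exactly as printed", {
  # criterion 1: short edge, any width
  out <- classify_edges_bas_rh(snap_with_edges(300, 20))
  expect_equal(out$label, "BAS"); expect_equal(out$criterion, 1L)
  # criterion 2: < 1000 um with a tip endpoint
  out <- classify_edges_bas_rh(snap_with_edges(800, 20, tip_end = TRUE))
  expect_equal(out$label, "BAS"); expect_equal(out$criterion, 2L)
  # same length without a tip endpoint stays RH
  out <- classify_edges_bas_rh(snap_with_edges(800, 20, tip_end = FALSE))
  expect_equal(out$label, "RH")
  # criterion 3: thin and small width x length product
  out <- classify_edges_bas_rh(snap_with_edges(1200, 5))
  expect_equal(out$label, "BAS"); expect_equal(out$criterion, 3L)
  # thin but large product: no criterion fires
  out <- classify_edges_bas_rh(snap_with_edges(5000, 10))
  expect_equal(out$label, "RH")
  # boundary cases are strict inequalities
  out <- classify_edges_bas_rh(snap_with_edges(c(400, 1000), c(7, 7)))
  expect_equal(out$label, c("RH", "RH"))
  # missing width skips criterion 3 with a warning
  expect_warning(out <- classify_edges_bas_rh(snap_with_edges(1200, NA)),
                 "width")
  expect_equal(out$label, "RH")
})

test_that("classifier summary reports the BAS length fraction", {
  out <- classify_edges_bas_rh(snap_with_edges(c(300, 5000), c(20, 10)))
  s <- attr(out, "summary")
  expect_equal(s$L_BAS_um, 300)
  expect_equal(s$L_RH_um, 5000)
  expect_equal(s$rho_BAS, 300 / 5300)
})

test_that("growing tips need degree 1 and a 40-pixel displacement", {
  px <- 3.25
  hist <- list(fast = c(1, 1, 1), slow = c(1, 1, 1), junction = c(3, 3, 3))
  ser <- degree_history_series(hist, step_um = 50 * px)  # 50 px per frame
  slow <- ser$nodes$node_id == "slow"
  ser$nodes$x_um[slow] <- ser$nodes$t_h[slow] * 10 * px  # 10 px per frame
  expect_setequal(growing_tips(ser, 1), "fast")
  expect_false("junction" %in% growing_tips(ser, 2))
  expect_length(growing_tips(ser, 0), 0)
})

test_that("runner-hypha tips are separated from BAS tips at 2.5 mm", {
  hist <- list(far = rep(1, 11), near = rep(1, 11))
  ser <- degree_history_series(hist, step_um = 500)  # far: 5 mm net
  near <- ser$nodes$node_id == "near"
  # near oscillates in >40 px steps (a growing tip) but stays within 1 mm
  ser$nodes$x_um[near] <- (ser$nodes$t_h[near] %% 2) * 200
  lab <- classify_tips_rh_bas(ser)
  expect_equal(unname(lab["far"]), "RH")
  expect_equal(unname(lab["near"]), "BAS")
})

test_that("long-running simulated runner tips classify as RH", {
  sim <- sim_fixture_dense()
  ser <- sim$series
  t_end <- max(ser$timepoints)
  lab <- classify_tips_rh_bas(ser)
  # runners: born with >= 20 h to grow, never annihilated (degree 1 at the
  # end) and never stopped by the domain boundary
  tips <- ser$edges$node_b[ser$edges$label == "RH"]
  born <- ser$edges$birth_t_h[match(tips, ser$edges$node_b)]
  fin <- stored_degrees(ser, t_end)
  pos <- node_positions_at(ser, t_end)
  y <- pos$y_um[match(tips, pos$node_id)]
  r <- sqrt(pos$x_um^2 + pos$y_um^2)[match(tips, pos$node_id)]
  runners <- tips[!is.na(born) & born <= t_end - 20 & fin[tips] == 1 &
                    y > 1 & r < ser$meta$sim_params$roi_radius_mm * 1000 - 1000]
  runners <- runners[!is.na(runners)]
  expect_gte(length(runners), 20)
  expect_gte(mean(lab[runners] == "RH", na.rm = TRUE), 0.95)
})

test_that("degree histories separate anastomoses from crossings", {
  hist <- list(fuse = c(1, 1, 3, 3, 3), cross = c(1, 3, 1, 1, 1),
               tip = c(1, 1, 1, 1, 1), late = c(3, 3, 3, 3, 3))
  ser <- degree_history_series(hist)
  ev <- detect_anastomoses(ser)
  expect_equal(nrow(ev), 2)
  an <- ev[ev$event_type == "anastomosis", ]
  expect_equal(an$node_id, "fuse")
  expect_equal(an$t_h, 1)  # last degree-1 timestep
  cr <- ev[ev$event_type == "crossing", ]
  expect_equal(cr$node_id, "cross")
})

test_that("detectors reproduce the simulator ground truth exactly", {
  sim <- sim_fixture_dense()
  ser <- sim$series
  gt <- sim$events
  dt <- diff(ser$timepoints)[1]

  det_b <- detect_branchings(ser)
  gt_b <- gt[gt$event_type == "branching", ]
  expect_equal(nrow(det_b), nrow(gt_b))
  expect_setequal(det_b$node_id, gt_b$node_id)
  m <- match(det_b$node_id, gt_b$node_id)
  expect_true(all(abs(det_b$t_h - gt_b$t_h[m]) <= dt + 1e-9))
  expect_true(all(sqrt((det_b$x_um - gt_b$x_um[m])^2 +
                         (det_b$y_um - gt_b$y_um[m])^2) <= 1e-6))

  det_a <- detect_anastomoses(ser)
  det_a <- det_a[det_a$event_type == "anastomosis", ]
  gt_a <- gt[gt$event_type == "anastomosis", ]
  expect_equal(nrow(det_a), nrow(gt_a))
  expect_setequal(det_a$node_id, gt_a$node_id)
  m <- match(det_a$node_id, gt_a$node_id)
  expect_true(all(abs(det_a$t_h - gt_a$t_h[m]) <= dt + 1e-9))
  step_um <- 280 * dt
  expect_true(all(sqrt((det_a$x_um - gt_a$x_um[m])^2 +
                         (det_a$y_um - gt_a$y_um[m])^2) <= step_um))
})

test_that("no branchings are detected when branching is off", {
  sim <- memo("noalpha", function()
    simulate_colony(sim_params(alpha_per_h = 0, seed = 6, t_max_h = 25,
                               n_anchors = 3)))
  expect_equal(nrow(detect_branchings(sim$series)), 0)
  # the founding tips at t = 0 are pre-existing, not branching events
  expect_equal(sum(sim$events$event_type == "branching"), 0)
})

test_that("ring event rates normalize by area and interval", {
  rings <- make_rings(c(0, 0), r_max_mm = 10, n_rings = 2)
  # 4 events in ring 1 over one 2-h interval
  ev <- data.frame(event_type = "anastomosis", t_h = c(2, 2.5, 3, 3.9),
                   x_um = 1000, y_um = 1000, node_id = "x")
  rates <- ring_event_rates(ev, rings, timepoints = c(0, 2, 4))
  got <- rates$a_mm2_h[rates$ring == 1 & rates$t_h == 2]
  expect_equal(got, 4 / (rings$area_mm2 * 2))
  # conservation: sum rate * area * dt = event count
  expect_equal(sum(rates$a_mm2_h * rings$area_mm2 * 2), 4)
})

test_that("rate scaling recovers alpha and a beta near the realized one", {
  sim <- sim_fixture_dense()
  ser <- sim$series
  rings <- make_rings(c(0, 0), r_max_mm = 30, n_rings = 8)
  det <- rbind(detect_branchings(ser), detect_anastomoses(ser))
  det <- det[det$event_type != "crossing", ]
  rates <- ring_event_rates(det, rings, ser$timepoints)
  prof <- ring_densities(ser, rings, tip_filter = "growing")
  est <- estimate_alpha_beta(rates, prof, n_boot = 200)
  expect_gt(est$alpha_per_h, 0.03)
  expect_lt(est$alpha_per_h, 0.05)
  # single-replicate beta suffers errors-in-variables attenuation from the
  # small per-ring tip counts; the quantitative check pools replicates
  pooled <- pooled_rates_fixture()
  est3 <- estimate_alpha_beta(pooled$rates, pooled$prof, n_boot = 200)
  expect_gt(est3$alpha_per_h, 0.03)
  expect_lt(est3$alpha_per_h, 0.05)
  expect_equal(est3$beta_um_h, pooled$beta_eff, tolerance = 0.25)
  # shape matching in the aligned wave frame: rates track densities
  wf <- wave_frame_profiles(rates, prof)
  expect_gt(wf$cor_b_n, 0.85)
  expect_gt(wf$cor_a_nrho, 0.8)
  wf3 <- wave_frame_profiles(pooled$rates, pooled$prof)
  expect_gt(wf3$cor_b_n, 0.9)
  expect_gt(wf3$cor_a_nrho, 0.9)
})

test_that("beta is indistinguishable from zero without fusion", {
  sim <- memo("nofuse", function()
    simulate_colony(sim_params(p_fuse = 0, seed = 12, t_max_h = 40,
                               n_anchors = 6)))
  ser <- sim$series
  rings <- make_rings(c(0, 0), r_max_mm = 25, n_rings = 6)
  det <- rbind(detect_branchings(ser), detect_anastomoses(ser))
  rates <- ring_event_rates(det[det$event_type != "crossing", ], rings,
                            ser$timepoints)
  prof <- ring_densities(ser, rings, tip_filter = "growing")
  est <- estimate_alpha_beta(rates, prof, n_boot = 100)
  expect_equal(est$beta_um_h, 0, tolerance = 1e-9)
  expect_lte(est$beta_ci[1], 0)
})

test_that("anastomosis density counts loops per network length", {
  ser <- toy_series()  # a tree at all times
  ad <- anastomosis_density(ser)
  expect_true(all(ad$loops == 0))
  expect_true(all(ad$rho_A == 0 | is.na(ad$rho_A)))
  sim <- sim_fixture_dense()
  ad2 <- anastomosis_density(sim$series)
  last <- ad2[nrow(ad2), ]
  expect_equal(last$rho_A, last$loops / last$total_length_mm)
  expect_true(!is.unsorted(ad2$loops))
})

test_that("euler count reconciles with fusions plus loop-closing crossings",
{
  sim <- sim_fixture_dense()
  ser <- sim$series
  t <- max(ser$timepoints)
  loops <- euler_loop_count(snapshot(ser, t))
  n_fuse <- sum(sim$events$event_type == "anastomosis")
  n_cross <- sum(sim$events$event_type == "crossing")
  n_anchor <- sim$series$meta$sim_params$n_anchors
  # each fusion or crossing closes a face unless it merges two components
  expect_gte(loops, n_fuse - (n_anchor - 1))
  expect_lte(loops, n_fuse + n_cross)
})
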