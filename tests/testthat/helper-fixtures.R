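# Shared fixtures, built in code and memoized for the test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# medium radial colony used by most estimator tests
sim_fixture <- function() {
  memo("sim60", function() {
    simulate_colony(sim_params(seed = 42, t_max_h = 60))
  })
}

# decorated + spored version of the same colony
sim_fixture_full <- function() {
  memo("sim60full", function() {
    p <- sim_params(seed = 42, t_max_h = 60)
    inject_spores(decorate_bas(sim_fixture(), p), p)
  })
}

# dense barrier-seeded colony with many anastomoses (rate-scaling tests)
dense_params <- function(seed = 11) {
  sim_params(seed = seed, t_max_h = 65, n_anchors = 25,
             anchor_spacing_um = 1500)
}

sim_fixture_dense <- function() {
  memo("simdense", function() simulate_colony(dense_params(11)))
}

# pooled ring-frame rates and densities over three dense colonies; ring ids
# are offset per replicate so bootstrap-over-rings treats them independently
pooled_rates_fixture <- function() {
  memo("pooled", function() {
    pool_r <- list(); pool_p <- list(); beffs <- numeric()
    for (s in c(11, 12, 13)) {
      sim <- if (s == 11) sim_fixture_dense() else
        simulate_colony(dense_params(s))
      beffs <- c(beffs, sim$report$beta_eff_um_h)
      ser <- sim$series
      rings <- make_rings(c(0, 0), r_max_mm = 28, n_rings = 8)
      det <- rbind(detect_branchings(ser), detect_anastomoses(ser))
      det <- det[det$event_type != "crossing", ]
      rates <- ring_event_rates(det, rings, ser$timepoints)
      prof <- ring_densities(ser, rings, tip_filter = "growing")
      rates$ring <- rates$ring + s * 100
      prof$ring <- prof$ring + s * 100
      pool_r[[as.character(s)]] <- rates
      pool_p[[as.character(s)]] <- prof
    }
    list(rates = do.call(rbind, pool_r), prof = do.call(rbind, pool_p),
         beta_eff = mean(beffs))
  })
}

# hand-built two-node, one-edge series: a straight hypha growing in +y
# at `speed` um/h from (0, 0), observed at integer hours
toy_series <- function(t_max = 5, speed = 500) {
  tt <- 0:t_max
  anchors <- data.frame(node_id = "a", x_um = 0, y_um = 0,
                        stringsAsFactors = FALSE)
  nodes <- rbind(
    data.frame(node_id = "a", t_h = tt, x_um = 0, y_um = 0, degree = 1),
    data.frame(node_id = "tip", t_h = tt, x_um = 0, y_um = speed * tt,
               degree = 1))
  poly <- cbind(x_um = c(0, 0), y_um = c(0, speed * t_max))
  edges <- data.frame(edge_id = "e1", node_a = "a", node_b = "tip",
                      birth_t_h = 0, length_um = speed * t_max,
                      width_um = 10, label = "RH", stringsAsFactors = FALSE)
  edges$polyline <- list(poly)
  network_series(nodes, edges,
                 meta = list(roi = list(barrier_offset_mm = 6,
                                        radius_mm = 45),
                             pixel_size_um = 3.25, root_anchors = anchors),
                 check_degrees = "none")
}

# series with prescribed per-frame degree histories for detector tests;
# positions move so that displacement thresholds are exercised
degree_history_series <- function(histories, step_um = 300) {
  tt <- seq_len(length(histories[[1]])) - 1
  nodes <- do.call(rbind, lapply(names(histories), function(id) {
    deg <- histories[[id]]
    data.frame(node_id = id, t_h = tt,
               x_um = step_um * tt, y_um = match(id, names(histories)) * 1000,
               degree = deg, stringsAsFactors = FALSE)
  }))
  edges <- data.frame(edge_id = character(), node_a = character(),
                      node_b = character(), birth_t_h = numeric(),
                      length_um = numeric(), width_um = numeric(),
                      label = character(), stringsAsFactors = FALSE)
  edges$polyline <- list()
  network_series(nodes, edges,
                 meta = list(pixel_size_um = 3.25,
                             root_anchors = data.frame(node_id = character(),
                                                       x_um = numeric(),
                                                       y_um = numeric())),
                 validate = FALSE)
}

# independent cycle-basis size by brute force: count edges outside a
# depth-first spanning forest (cycle rank), derived from first principles
# via spanning-forest construction rather than the Euler formula
brute_cycle_rank <- function(edge_list, n_vertices) {
  parent <- seq_len(n_vertices)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  extra <- 0L
  for (k in seq_len(nrow(edge_list))) {
    a <- find(edge_list[k, 1]); b <- find(edge_list[k, 2])
    if (a == b) extra <- extra + 1L else parent[a] <- b
  }
  extra
}

# random small igraph with coordinates (for loop-count oracles)
random_small_graph <- function(n_edges, seed) {
  set.seed(seed)
  nv <- sample(2:10, 1)
  el <- cbind(sample.int(nv, n_edges, replace = TRUE),
              sample.int(nv, n_edges, replace = TRUE))
  el <- el[el[, 1] != el[, 2], , drop = FALSE]
  el <- unique(t(apply(el, 1, sort)))
  g <- igraph::make_empty_graph(nv, directed = FALSE)
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  list(graph = g, edges = el, n = nv)
}
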