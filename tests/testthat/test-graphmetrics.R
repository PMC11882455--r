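star_snapshot <- function(k = 5) {
  # k leaves joined to a hub; the hub hangs from one anchor by a trunk edge
  ids <- c("anchor", "hub", paste0("leaf", seq_len(k)))
  th <- seq(0, pi, length.out = k)
  nodes <- data.frame(node_id = ids,
                      x_um = c(0, 0, 800 * cos(th)),
                      y_um = c(0, 500, 500 + 800 * sin(th)),
                      degree = c(1, k + 1, rep(1, k)),
                      stringsAsFactors = FALSE)
  g <- igraph::make_empty_graph(length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  igraph::V(g)$x <- nodes$x_um; igraph::V(g)$y <- nodes$y_um
  el <- rbind(c("anchor", "hub"),
              cbind("hub", paste0("leaf", seq_len(k))))
  g <- igraph::add_edges(g, t(el))
  igraph::E(g)$weight <- c(500, rep(800, k))
  igraph::E(g)$parent <- paste0("e", seq_len(k + 1))
  igraph::E(g)$width_um <- 10
  igraph::E(g)$label <- "RH"
  structure(list(t = 0, nodes = nodes, graph = g,
                 meta = list(root_anchors = data.frame(
                   node_id = "anchor", x_um = 0, y_um = 0))),
            class = "network_snapshot")
}

test_that("trunk BC equals the number of nodes behind it", {
  k <- 7
  sn <- star_snapshot(k)
  bc <- betweenness_to_root(sn)
  trunk <- which(igraph::E(sn$graph)$parent == "e1")
  expect_equal(bc$edge_bc[trunk], k + 1)  # hub + k leaves
  leaf_edges <- setdiff(seq_len(k + 1), trunk)
  expect_true(all(bc$edge_bc[leaf_edges] == 1))
})

test_that("BC increases monotonically toward the root along a path", {
  ids <- c("anchor", paste0("n", 1:5))
  nodes <- data.frame(node_id = ids, x_um = 0 + 0:5 * 100, y_um = 0,
                      degree = c(1, rep(2, 4), 1))
  g <- igraph::make_empty_graph(6, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  igraph::V(g)$x <- nodes$x_um; igraph::V(g)$y <- nodes$y_um
  g <- igraph::add_edges(g, t(cbind(ids[-6], ids[-1])))
  igraph::E(g)$weight <- 100
  igraph::E(g)$parent <- paste0("e", 1:5)
  sn <- structure(list(t = 0, nodes = nodes, graph = g,
                       meta = list(root_anchors = data.frame(
                         node_id = "anchor", x_um = 0, y_um = 0))),
                  class = "network_snapshot")
  bc <- betweenness_to_root(sn)
  expect_equal(bc$edge_bc, 5:1)
})

test_that("a single edge carries one path", {
  ids <- c("anchor", "n1")
  nodes <- data.frame(node_id = ids, x_um = c(0, 100), y_um = 0,
                      degree = 1)
  g <- igraph::make_graph(~ anchor - n1)
  igraph::V(g)$x <- nodes$x_um; igraph::V(g)$y <- nodes$y_um
  igraph::E(g)$weight <- 100
  igraph::E(g)$parent <- "e1"
  sn <- structure(list(t = 0, nodes = nodes, graph = g,
                       meta = list(root_anchors = data.frame(
                         node_id = "anchor", x_um = 0, y_um = 0))),
                  class = "network_snapshot")
  expect_equal(betweenness_to_root(sn)$edge_bc, 1)
})

test_that("tree BC conserves the total root-path edge count", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(8:30, 1)
    g <- igraph::sample_tree(n)
    igraph::V(g)$name <- paste0("v", seq_len(n))
    xy <- matrix(runif(2 * n, 0, 1000), n, 2)
    igraph::V(g)$x <- xy[, 1]; igraph::V(g)$y <- xy[, 2]
    igraph::E(g)$weight <- runif(igraph::ecount(g), 1, 10)
    igraph::E(g)$parent <- paste0("e", seq_len(igraph::ecount(g)))
    sn <- structure(list(t = 0, graph = g,
                         nodes = data.frame(node_id = igraph::V(g)$name,
                                            x_um = xy[, 1], y_um = xy[, 2],
                                            degree = igraph::degree(g)),
                         meta = list(root_anchors = data.frame(
                           node_id = "v1", x_um = xy[1, 1],
                           y_um = xy[1, 2]))),
                    class = "network_snapshot")
    bc <- betweenness_to_root(sn)
    # oracle: on a tree the unique root path of each node is enumerable
    total <- sum(vapply(2:n, function(v) {
      length(igraph::shortest_paths(g, from = "v1",
                                    to = paste0("v", v),
                                    output = "epath")$epath[[1]])
    }, 0))
    expect_equal(sum(bc$edge_bc), total)
  }
})

test_that("geometric efficiency matches hand enumeration", {
  ids <- c("a", "b", "c")
  xy <- rbind(c(0, 0), c(1000, 0), c(1000, 1000))
  g <- igraph::make_graph(~ a - b - c)
  igraph::V(g)$x <- xy[, 1]; igraph::V(g)$y <- xy[, 2]
  igraph::E(g)$weight <- 1000
  eg <- geometric_efficiency(g, "global")
  expect_equal(eg, (1 + 1 + sqrt(2) / 2) / 3, tolerance = 1e-12)
  # collinear chain endpoints: geodesic equals Euclidean
  g2 <- igraph::make_graph(~ a - b - c)
  igraph::V(g2)$x <- c(0, 500, 1000); igraph::V(g2)$y <- 0
  igraph::E(g2)$weight <- 500
  expect_equal(geometric_efficiency(g2, "global"), 1, tolerance = 1e-12)
  expect_error(geometric_efficiency(igraph::make_empty_graph(1,
                                                             directed = FALSE),
                                    "global"), "single node")
})

test_that("efficiency never exceeds one on simulated snapshots", {
  sim <- sim_fixture()
  sn <- snapshot(sim$series, 60)
  expect_lte(geometric_efficiency(sn, "global"), 1 + 1e-9)
  expect_lte(suppressWarnings(geometric_efficiency(sn, "root")), 1 + 1e-9)
})

test_that("reference networks on the unit square are exact", {
  xy <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  refs <- reference_networks(xy)
  expect_equal(refs$mst_length, 3)
  expect_equal(igraph::ecount(refs$dt), 5)
  expect_equal(refs$dt_length, 4 + sqrt(2), tolerance = 1e-9)
  expect_equal(euler_loop_count(refs$mst), 0)
  expect_error(reference_networks(cbind(0:4, 0:4)), "collinear")
})

test_that("MST length bounds hold against brute force on small sets", {
  for (seed in 1:5) {
    set.seed(seed)
    xy <- matrix(runif(12, 0, 100), 6, 2)
    refs <- reference_networks(xy)
    # brute force: minimum over many random spanning trees via Prim from
    # the full distance matrix
    d <- as.matrix(stats::dist(xy))
    n <- nrow(xy)
    intree <- 1L; best <- numeric(0)
    dist_to <- d[1, ]; dist_to[1] <- Inf
    total <- 0
    for (step in seq_len(n - 1)) {
      j <- which.min(dist_to)
      total <- total + dist_to[j]
      intree <- c(intree, j)
      dist_to <- pmin(dist_to, d[j, ]); dist_to[intree] <- Inf
    }
    expect_equal(refs$mst_length, unname(total), tolerance = 1e-9)
  }
})

test_that("network efficiency sits between MST and DT on colonies", {
  sim <- sim_fixture()
  for (t in c(30, 45, 60)) {
    sn <- snapshot(sim$series, t)
    comp <- igraph::components(sn$graph)
    skip_if(comp$no > 3, "fragmented snapshot")
    refs <- reference_networks(sn)
    eg <- suppressWarnings(geometric_efficiency(sn, "global"))
    eg_mst <- geometric_efficiency(refs$mst, "global")
    eg_dt <- geometric_efficiency(refs$dt, "global")
    expect_lte(eg_mst, eg + 0.02)
    expect_lte(eg, eg_dt + 1e-9)
    expect_lte(refs$mst_length, sum(sn$edges$realized_length_um) + 1e-6)
    expect_lte(refs$mst_length, refs$dt_length)
  }
})

test_that("normalization endpoints give 0 at the MST and 1 at the DT", {
  set.seed(3)
  xy <- matrix(runif(30, 0, 5000), 15, 2)
  ids <- paste0("v", 1:15)
  refs <- reference_networks(xy, ids)
  as_snap <- function(g) {
    ed <- igraph::as_data_frame(g)
    structure(list(
      t = 0, graph = g,
      nodes = data.frame(node_id = ids, x_um = xy[, 1], y_um = xy[, 2],
                         degree = igraph::degree(g)),
      edges = data.frame(edge_id = paste0("e", seq_len(nrow(ed))),
                         realized_length_um = ed$weight),
      meta = list(root_anchors = data.frame(node_id = "v1",
                                            x_um = xy[1, 1],
                                            y_um = xy[1, 2]))),
      class = "network_snapshot")
  }
  m_mst <- normalized_metrics(as_snap(refs$mst))
  expect_equal(m_mst$E_g_hat, 0, tolerance = 1e-9)
  expect_equal(m_mst$C_hat, 0, tolerance = 1e-9)
  m_dt <- normalized_metrics(as_snap(refs$dt))
  expect_equal(m_dt$E_g_hat, 1, tolerance = 1e-9)
  expect_equal(m_dt$C_hat, 1, tolerance = 1e-9)
})

test_that("colonies stay cheap while efficiency climbs with loops", {
  sim <- sim_fixture_dense()
  ts <- sim$series$timepoints
  ts <- ts[ts %in% c(25, 40, 55)]
  met <- lapply(ts, function(t)
    suppressWarnings(normalized_metrics(snapshot(sim$series, t))))
  chat <- vapply(met, `[[`, 0, "C_hat")
  eghat <- vapply(met, `[[`, 0, "E_g_hat")
  expect_true(all(chat < 0.35))
  expect_gt(eghat[length(eghat)], eghat[1] - 0.02)
})

test_that("width-BC correlation responds to constructed couplings", {
  sim <- sim_fixture()
  sn <- snapshot(sim$series, 60)
  bc <- betweenness_to_root(sn)
  g <- sn$graph
  igraph::E(g)$width_um <- 5 + bc$edge_bc
  sn_pos <- sn; sn_pos$graph <- g
  expect_gt(width_bc_correlation(sn_pos, bc, n_boot = 100)$rho, 0.95)
  igraph::E(g)$width_um <- 5 + max(bc$edge_bc) - bc$edge_bc
  sn_neg <- sn; sn_neg$graph <- g
  expect_lt(width_bc_correlation(sn_neg, bc, n_boot = 100)$rho, -0.95)
  set.seed(1)
  igraph::E(g)$width_um <- sample(5 + bc$edge_bc)
  sn_null <- sn; sn_null$graph <- g
  ci <- width_bc_correlation(sn_null, bc, n_boot = 300)$ci
  expect_lte(ci[1], 0); expect_gte(ci[2], 0)
  igraph::E(g)$width_um <- 7
  sn_const <- sn; sn_const$graph <- g
  expect_warning(out <- width_bc_correlation(sn_const, bc), "constant")
  expect_true(is.na(out$rho))
})

test_that("balanced-tree BC is heavy tailed, star BC is two-valued", {
  # balanced binary tree anchored at its root
  depth <- 7
  g <- igraph::make_tree(2^depth - 1, children = 2, mode = "undirected")
  igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  set.seed(2)
  igraph::V(g)$x <- runif(igraph::vcount(g), 0, 1000)
  igraph::V(g)$y <- runif(igraph::vcount(g), 0, 1000)
  igraph::E(g)$weight <- 1
  igraph::E(g)$parent <- paste0("e", seq_len(igraph::ecount(g)))
  sn <- structure(list(t = 0, graph = g,
                       nodes = data.frame(node_id = igraph::V(g)$name),
                       meta = list(root_anchors = data.frame(
                         node_id = "v1", x_um = 0, y_um = 0))),
                  class = "network_snapshot")
  bc <- betweenness_to_root(sn)
  # closed form per level: an edge below the root carries 2^(depth-1) - 1
  # descendants plus itself
  expect_equal(sort(unique(bc$edge_bc), decreasing = TRUE)[1],
               2^(depth - 1) - 1)
  dist <- bc_distribution(bc)
  expect_gt(dist$loglik_ratio, 0)  # heavier than exponential
  star <- star_snapshot(30)
  bc_star <- betweenness_to_root(star)
  expect_warning(out <- bc_distribution(bc_star), "histogram only")
  expect_setequal(unique(bc_star$edge_bc), c(1, 31))
})

test_that("adding an edge never lowers efficiency", {
  set.seed(5)
  xy <- matrix(runif(20, 0, 1000), 10, 2)
  refs <- reference_networks(xy, paste0("v", 1:10))
  g <- refs$mst
  e_before <- geometric_efficiency(g, "global")
  # add the longest DT edge missing from the MST
  dtd <- igraph::as_data_frame(refs$dt)
  mstd <- igraph::as_data_frame(refs$mst)
  key <- function(d) paste(pmin(d$from, d$to), pmax(d$from, d$to))
  cand <- dtd[!(key(dtd) %in% key(mstd)), ]
  g2 <- igraph::add_edges(g, t(as.matrix(cand[1, c("from", "to")])))
  igraph::E(g2)$weight[igraph::ecount(g2)] <- cand$weight[1]
  e_after <- geometric_efficiency(g2, "global")
  expect_gte(e_after, e_before - 1e-12)
})
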