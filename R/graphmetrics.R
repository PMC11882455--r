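# Transport-topology metrics: root-anchored betweenness centrality,
# geometric efficiencies, and normalization against minimum-spanning-tree
# and Delaunay-triangulation reference networks built on the same node set.

#' Betweenness centrality toward the root compartment
#'
#' For every node one length-weighted shortest path to its nearest root
#' anchor is traced; an edge's BC is the number of such paths traversing
#' it. Ties between equal-length paths are broken deterministically by the
#' traversal order of node ids.
#'
#' @param snap A `network_snapshot`.
#' @param root_anchors Node ids of the barrier crossing points (default:
#'   `snap$meta$root_anchors$node_id`).
#' @return List: `edge_bc` (numeric per split-graph edge, also set as edge
#'   attribute `bc` on a copy of the graph returned as `graph`),
#'   `parent_bc` (max BC per parent edge_id), `unreachable` (node ids not
#'   connected to any anchor).
#' @export
betweenness_to_root <- function(snap, root_anchors = NULL) {
  g <- snap$graph
  if (is.null(root_anchors))
    root_anchors <- snap$meta$root_anchors$node_id
  root_anchors <- intersect(root_anchors, igraph::V(g)$name)
  if (!length(root_anchors))
    stop("no root anchor present in the snapshot", call. = FALSE)
  # virtual super-root joined to every anchor by a zero-ish weight edge
  g2 <- igraph::add_vertices(g, 1, name = ".root")
  g2 <- igraph::add_edges(g2, rbind(".root", root_anchors))
  nadd <- length(root_anchors)
  igraph::E(g2)$weight[(igraph::ecount(g2) - nadd + 1):igraph::ecount(g2)] <-
    1e-9
  dist <- igraph::distances(g2, v = ".root")[1, ]
  reach <- names(dist)[is.finite(dist) & names(dist) != ".root"]
  unreachable <- setdiff(igraph::V(g)$name, reach)
  if (length(unreachable))
    warning(sprintf("%d node(s) unreachable from root anchors",
                    length(unreachable)))
  paths <- igraph::shortest_paths(g2, from = ".root",
                                  to = sort(reach), output = "epath")
  bc <- numeric(igraph::ecount(g))
  for (ep in paths$epath) {
    ids <- as.integer(ep)
    ids <- ids[ids <= igraph::ecount(g)]  # drop virtual edges
    bc[ids] <- bc[ids] + 1
  }
  gg <- g
  igraph::E(gg)$bc <- bc
  parent <- igraph::E(g)$parent
  parent_bc <- tapply(bc, parent, max)
  list(edge_bc = bc, parent_bc = parent_bc, graph = gg,
       unreachable = unreachable)
}

#' Geometric transport efficiency
#'
#' Mean over node pairs of the ratio between Euclidean distance and
#' along-network shortest-path distance. `mode = "global"` samples node
#' pairs uniformly (all pairs when few nodes); `mode = "root"` pairs every
#' node with its nearest root anchor.
#'
#' @param snap A `network_snapshot` (or an igraph with x, y vertex
#'   attributes and edge weights).
#' @param mode "global" or "root".
#' @param root_anchors Anchor node ids for `mode = "root"`.
#' @param max_pairs Use all pairs up to this many nodes, else sample
#'   `n_sample` random pairs.
#' @param n_sample Number of sampled pairs for large graphs.
#' @param seed RNG seed for pair sampling.
#' @return Mean efficiency in (0, 1].
#' @export
geometric_efficiency <- function(snap, mode = c("global", "root"),
                                 root_anchors = NULL, max_pairs = 2000,
                                 n_sample = 1e5, seed = 1) {
  mode <- match.arg(mode)
  g <- if (inherits(snap, "network_snapshot")) snap$graph else snap
  comp <- igraph::components(g)
  if (comp$no > 1) {
    warning("graph disconnected: using largest component")
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  n <- igraph::vcount(g)
  if (n < 2) stop("efficiency undefined for a single node", call. = FALSE)
  xy <- cbind(igraph::V(g)$x, igraph::V(g)$y)
  if (mode == "root") {
    if (is.null(root_anchors) && inherits(snap, "network_snapshot"))
      root_anchors <- snap$meta$root_anchors$node_id
    root_anchors <- intersect(root_anchors, igraph::V(g)$name)
    if (!length(root_anchors))
      stop("no root anchor in (largest component of) graph", call. = FALSE)
    d_sp <- igraph::distances(g, v = root_anchors)
    nearest <- apply(d_sp, 2, which.min)
    dsp <- d_sp[cbind(nearest, seq_len(n))]
    axy <- xy[match(root_anchors, igraph::V(g)$name), , drop = FALSE]
    de <- sqrt((xy[, 1] - axy[nearest, 1])^2 + (xy[, 2] - axy[nearest, 2])^2)
    sel <- dsp > 0 & is.finite(dsp)
    return(mean(de[sel] / dsp[sel]))
  }
  if (n <= max_pairs) {
    dsp <- igraph::distances(g)
    de <- as.matrix(stats::dist(xy))
    ut <- upper.tri(dsp)
    sel <- ut & is.finite(dsp) & dsp > 0
    return(mean(de[sel] / dsp[sel]))
  }
  set.seed(seed)
  i <- sample.int(n, n_sample, replace = TRUE)
  j <- sample.int(n, n_sample, replace = TRUE)
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  # batch by source vertex
  acc <- c()
  for (src in unique(i)) {
    cols <- j[i == src]
    dsp <- igraph::distances(g, v = src)[1, cols]
    de <- sqrt((xy[src, 1] - xy[cols, 1])^2 + (xy[src, 2] - xy[cols, 2])^2)
    sel <- is.finite(dsp) & dsp > 0
    acc <- c(acc, de[sel] / dsp[sel])
  }
  mean(acc)
}

#' Euclidean MST and Delaunay reference networks
#'
#' Builds, over a given node set, the Euclidean minimum spanning tree (the
#' cheapest connected network) and the Delaunay triangulation (a near
#' maximal planar mesh); edge weights are Euclidean lengths. The MST is
#' computed on the Delaunay edge set (which always contains it).
#'
#' @param xy n x 2 matrix of node coordinates (or a `network_snapshot`).
#' @param ids Optional node names.
#' @return List with igraphs `mst` and `dt`, and their total lengths
#'   `mst_length`, `dt_length`.
#' @export
reference_networks <- function(xy, ids = NULL) {
  if (inherits(xy, "network_snapshot")) {
    ids <- xy$nodes$node_id
    xy <- cbind(xy$nodes$x_um, xy$nodes$y_um)
  }
  keep <- !duplicated(round(xy, 6))
  xy <- xy[keep, , drop = FALSE]
  if (!is.null(ids)) ids <- ids[keep]
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 nodes", call. = FALSE)
  rx <- diff(range(xy[, 1])); ry <- diff(range(xy[, 2]))
  if (rx == 0 || ry == 0 ||
      abs(stats::cor(xy[, 1], xy[, 2])) > 1 - 1e-12)
    stop("collinear node set: Delaunay triangulation undefined",
         call. = FALSE)
  dd <- deldir::deldir(xy[, 1], xy[, 2], suppressMsge = TRUE)
  es <- dd$delsgs
  w <- sqrt((xy[es$ind1, 1] - xy[es$ind2, 1])^2 +
              (xy[es$ind1, 2] - xy[es$ind2, 2])^2)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  dt <- igraph::make_empty_graph(n = n, directed = FALSE)
  dt <- igraph::set_vertex_attr(dt, "name", value = ids)
  igraph::V(dt)$x <- xy[, 1]; igraph::V(dt)$y <- xy[, 2]
  dt <- igraph::add_edges(dt, rbind(ids[es$ind1], ids[es$ind2]))
  igraph::E(dt)$weight <- w
  mst <- igraph::mst(dt, weights = igraph::E(dt)$weight)
  list(mst = mst, dt = dt,
       mst_length = sum(igraph::E(mst)$weight),
       dt_length = sum(igraph::E(dt)$weight))
}

#' Normalized transport efficiencies and cost
#'
#' Computes global and root efficiencies and carbon cost (gamma x total
#' length) for the network and for its MST and DT references on the same
#' node set, then normalizes X to (X - X_MST) / (X_DT - X_MST): 0 means
#' MST-like (cheap, inefficient), 1 means DT-like (expensive, efficient).
#'
#' @param snap A `network_snapshot`.
#' @param root_anchors Anchor node ids (default from meta).
#' @param gamma Carbon cost per um of filament.
#' @param ... Passed to [geometric_efficiency()].
#' @return List of class `efficiency_report` with E_g, E_r, C and their
#'   MST/DT counterparts and normalized values E_g_hat, E_r_hat, C_hat.
#' @export
normalized_metrics <- function(snap, root_anchors = NULL, gamma = 1, ...) {
  if (is.null(root_anchors))
    root_anchors <- snap$meta$root_anchors$node_id
  refs <- reference_networks(snap)
  eg <- geometric_efficiency(snap, "global", ...)
  er <- geometric_efficiency(snap, "root", root_anchors = root_anchors, ...)
  C <- gamma * sum(snap$edges$realized_length_um)
  vals <- list(net = c(E_g = eg, E_r = er, C = C))
  for (ref in c("mst", "dt")) {
    gref <- refs[[ref]]
    vals[[ref]] <- c(
      E_g = geometric_efficiency(gref, "global", ...),
      E_r = geometric_efficiency(gref, "root", root_anchors = root_anchors,
                                 ...),
      C = gamma * sum(igraph::E(gref)$weight))
  }
  norm1 <- function(x, lo, hi) {
    if (abs(hi - lo) < 1e-12) return(NA_real_)
    (x - lo) / (hi - lo)
  }
  out <- list(
    E_g = vals$net[["E_g"]], E_r = vals$net[["E_r"]], C = vals$net[["C"]],
    E_g_mst = vals$mst[["E_g"]], E_g_dt = vals$dt[["E_g"]],
    E_r_mst = vals$mst[["E_r"]], E_r_dt = vals$dt[["E_r"]],
    C_mst = vals$mst[["C"]], C_dt = vals$dt[["C"]],
    E_g_hat = norm1(vals$net[["E_g"]], vals$mst[["E_g"]], vals$dt[["E_g"]]),
    E_r_hat = norm1(vals$net[["E_r"]], vals$mst[["E_r"]], vals$dt[["E_r"]]),
    C_hat = norm1(vals$net[["C"]], vals$mst[["C"]], vals$dt[["C"]]))
  class(out) <- "efficiency_report"
  out
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<efficiency_report>\n  E_g %.3f (MST %.3f, DT %.3f) -> E_g_hat %.3f\n",
    "  E_r %.3f (MST %.3f, DT %.3f) -> E_r_hat %.3f\n",
    "  C %.3g (MST %.3g, DT %.3g) -> C_hat %.3f\n"),
    x$E_g, x$E_g_mst, x$E_g_dt, x$E_g_hat,
    x$E_r, x$E_r_mst, x$E_r_dt, x$E_r_hat,
    x$C, x$C_mst, x$C_dt, x$C_hat))
  invisible(x)
}

#' Correlation between hyphal width and betweenness centrality
#'
#' Spearman rank correlation of edge width against edge BC with a bootstrap
#' confidence interval.
#'
#' @param snap A `network_snapshot`.
#' @param bc Result of [betweenness_to_root()] (its `edge_bc` is used).
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed.
#' @return List: rho (Spearman), ci (95%).
#' @export
width_bc_correlation <- function(snap, bc, n_boot = 1000, seed = 1) {
  w <- igraph::E(snap$graph)$width_um
  b <- bc$edge_bc
  if (stats::sd(w) == 0) {
    warning("constant widths: correlation undefined")
    return(list(rho = NA_real_, ci = c(NA_real_, NA_real_)))
  }
  rho <- stats::cor(w, b, method = "spearman")
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(k) {
    i <- sample.int(length(w), replace = TRUE)
    suppressWarnings(stats::cor(w[i], b[i], method = "spearman"))
  }, 0)
  list(rho = rho, ci = unname(stats::quantile(boot, c(0.025, 0.975),
                                              na.rm = TRUE)))
}

#' Betweenness-centrality distribution and tail fit
#'
#' Log-binned histogram of positive BC values plus a maximum-likelihood
#' power-law tail exponent (continuous Pareto MLE above `x_min`) and a
#' likelihood-ratio comparison against an exponential tail.
#'
#' @param bc Result of [betweenness_to_root()] or a numeric vector.
#' @param x_min Tail threshold (default: median of positive values).
#' @param n_bins Number of logarithmic bins.
#' @return List: histogram data.frame(mid, density), alpha_hat (tail
#'   exponent), x_min, n_tail, loglik_ratio (power law minus exponential;
#'   positive favours the power law). With < 100 values only the histogram.
#' @export
bc_distribution <- function(bc, x_min = NULL, n_bins = 20) {
  x <- if (is.list(bc)) bc$edge_bc else bc
  x <- x[x > 0]
  brk <- exp(seq(log(min(x)), log(max(x) + 1), length.out = n_bins + 1))
  h <- graphics::hist(x, breaks = unique(brk), plot = FALSE)
  hist_df <- data.frame(mid = h$mids, density = h$density)
  if (length(x) < 100) {
    warning("fewer than 100 edges: histogram only")
    return(list(histogram = hist_df, alpha_hat = NA_real_))
  }
  if (is.null(x_min)) x_min <- stats::median(x)
  tail <- x[x >= x_min]
  n <- length(tail)
  alpha <- 1 + n / sum(log(tail / x_min))
  ll_pl <- n * log((alpha - 1) / x_min) - alpha * sum(log(tail / x_min))
  lam <- 1 / mean(tail - x_min)
  ll_exp <- n * log(lam) - lam * sum(tail - x_min)
  list(histogram = hist_df, alpha_hat = alpha, x_min = x_min, n_tail = n,
       loglik_ratio = ll_pl - ll_exp)
}
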