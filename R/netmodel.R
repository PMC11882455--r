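# Data model for time-resolved planar spatial networks.
#
# A `network_series` stores a growing colony as:
#   * timepoints: strictly increasing observation times (hours),
#   * nodes: long table (node_id, t_h, x_um, y_um, degree) - one row per node
#     per timepoint at which the node exists; tips move, junctions do not,
#   * edges: one row per edge (edge_id, node_a, node_b, birth_t_h, length_um,
#     width_um, label, polyline) with the FINAL polyline geometry,
#   * events, spores, meta (ROI, pixel pitch, root anchors).
#
# Growing hyphae are represented as a single edge from their origin node to
# their (mobile) tip node; a snapshot at time t truncates the polyline at the
# tip's tracked position at t. Junction nodes created by branching, crossing
# or anastomosis may lie on the interior of an edge's polyline; snapshots
# detect these "pass-through" incidences geometrically and split the edge
# into sub-edges, so node degrees and graph topology are exact at every
# timepoint while the edge table itself never rewires or deletes elements.

PASS_TOL_UM <- 0.05  # coincidence tolerance for a node lying on a polyline

#' Construct a network series
#'
#' @param nodes data.frame with columns node_id, t_h, x_um, y_um and
#'   optionally degree (recomputed if absent).
#' @param edges data.frame with columns edge_id, node_a, node_b, birth_t_h,
#'   length_um, width_um, label and a list-column `polyline` of n x 2
#'   matrices (or a `polyline_wkt` character column).
#' @param events data.frame (event_type, t_h, x_um, y_um, node_id) or NULL.
#' @param spores data.frame (spore_id, t_h, x_um, y_um, radius_um) or NULL.
#' @param meta list with `roi` (list barrier_offset_mm, radius_mm),
#'   `pixel_size_um`, and `root_anchors` (data.frame node_id, x_um, y_um).
#' @param validate Check invariants on construction (default TRUE).
#' @param check_degrees One of "none", "last", "all": at which timepoints to
#'   verify that stored degrees match the recomputed planar incidences.
#' @return An object of class `network_series`.
#' @export
network_series <- function(nodes, edges, events = NULL, spores = NULL,
                           meta = list(), validate = TRUE,
                           check_degrees = "last") {
  if (is.null(events))
    events <- data.frame(event_type = character(), t_h = numeric(),
                         x_um = numeric(), y_um = numeric(),
                         node_id = character(), stringsAsFactors = FALSE)
  if (is.null(spores))
    spores <- data.frame(spore_id = character(), t_h = numeric(),
                         x_um = numeric(), y_um = numeric(),
                         radius_um = numeric(), stringsAsFactors = FALSE)
  if (!is.null(edges[["polyline_wkt"]]) && is.null(edges[["polyline"]]))
    edges[["polyline"]] <- lapply(edges[["polyline_wkt"]],
                                  parse_wkt_linestring)
  edges[["polyline_wkt"]] <- NULL
  ser <- structure(list(
    timepoints = sort(unique(nodes$t_h)),
    nodes = nodes, edges = edges, events = events, spores = spores,
    meta = meta
  ), class = "network_series")
  if (is.null(ser$nodes$degree)) ser$nodes$degree <- NA_real_
  if (validate) validate_series(ser, check_degrees = check_degrees)
  ser
}

#' @export
print.network_series <- function(x, ...) {
  cat(sprintf(
    "<network_series> %d timepoints (%.1f..%.1f h), %d nodes, %d edges, %d events\n",
    length(x$timepoints), min(x$timepoints), max(x$timepoints),
    length(unique(x$nodes$node_id)), nrow(x$edges), nrow(x$events)))
  invisible(x)
}

series_error <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Validate the invariants of a network series
#'
#' Checks strictly increasing timepoints, referential integrity of edge
#' endpoints, edge length at least the Euclidean end-to-end distance, event
#' times within the observed window, and (optionally) that stored per-node
#' degrees equal the degrees recomputed from the planar-embedded snapshot.
#'
#' @param series A `network_series`.
#' @inheritParams network_series
#' @return The series, invisibly; errors name the offending table and row.
#' @export
validate_series <- function(series, check_degrees = "last") {
  tp <- series$timepoints
  if (length(tp) == 0) series_error("series has no timepoints")
  if (any(diff(tp) <= 0)) series_error("timepoints are not strictly increasing")
  known <- unique(series$nodes$node_id)
  for (col in c("node_a", "node_b")) {
    bad <- which(!(series$edges[[col]] %in% known))
    if (length(bad))
      series_error("edges row %d: %s '%s' is not a known node_id",
                   bad[1], col, series$edges[[col]][bad[1]])
  }
  need <- c("edge_id", "node_a", "node_b", "birth_t_h", "length_um",
            "width_um", "label")
  miss <- setdiff(need, names(series$edges))
  if (length(miss)) series_error("edges table missing column '%s'", miss[1])
  # length >= Euclidean distance between final endpoint positions
  fin <- node_positions_at(series, max(tp))
  for (i in seq_len(nrow(series$edges))) {
    a <- fin[match(series$edges$node_a[i], fin$node_id), c("x_um", "y_um")]
    b <- fin[match(series$edges$node_b[i], fin$node_id), c("x_um", "y_um")]
    if (anyNA(a) || anyNA(b)) next
    eu <- sqrt(sum((as.numeric(a) - as.numeric(b))^2))
    if (series$edges$length_um[i] < eu - 1e-6)
      series_error("edges row %d ('%s'): length_um %.2f < endpoint distance %.2f",
                   i, series$edges$edge_id[i], series$edges$length_um[i], eu)
  }
  if (nrow(series$events)) {
    bad <- which(series$events$t_h < min(tp) - 1e-9 |
                   series$events$t_h > max(tp) + 1e-9)
    if (length(bad))
      series_error("events row %d: time %.2f outside series window", bad[1],
                   series$events$t_h[bad[1]])
  }
  times <- switch(check_degrees, none = numeric(), last = max(tp), all = tp)
  for (t in times) {
    snap <- snapshot(series, t, check = FALSE)
    stored <- series$nodes[series$nodes$t_h == t, c("node_id", "degree")]
    stored <- stored[!is.na(stored$degree), ]
    if (!nrow(stored)) next
    got <- snap$nodes$degree[match(stored$node_id, snap$nodes$node_id)]
    off <- which(abs(got - stored$degree) > 0)
    if (length(off))
      series_error("node '%s' at t=%.2f: stored degree %d != recomputed %d",
                   stored$node_id[off[1]], t, stored$degree[off[1]],
                   got[off[1]])
  }
  invisible(series)
}

# positions of every node existing at time t (one row per node)
node_positions_at <- function(series, t) {
  nd <- series$nodes[series$nodes$t_h == t, , drop = FALSE]
  nd[!duplicated(nd$node_id), c("node_id", "x_um", "y_um"), drop = FALSE]
}

#' Static planar graph of the colony at one timepoint
#'
#' Returns the network as it existed at time `t`: edges born after `t` are
#' dropped, growing edges are truncated at their tip's tracked position, and
#' junctions lying on edge interiors split those edges so that the returned
#' graph's incidences are exact.
#'
#' @param series A `network_series`.
#' @param t A time in `series$timepoints`.
#' @param check Error if `t` is not an observed timepoint (default TRUE).
#' @return A `network_snapshot`: list with `t`, `nodes` (id, x, y, degree),
#'   `edges` (edge table with realized_length_um and realized polylines),
#'   `graph` (an igraph whose vertices are node ids and whose edges carry
#'   `parent` edge ids and `weight` = length in um).
#' @export
snapshot <- function(series, t, check = TRUE) {
  if (check && !any(abs(series$timepoints - t) < 1e-9))
    series_error("t=%s is not an observed timepoint; available: %s", t,
                 paste(signif(series$timepoints, 6), collapse = ", "))
  pos <- node_positions_at(series, t)
  ed <- series$edges[series$edges$birth_t_h <= t + 1e-9, , drop = FALSE]
  ed <- ed[ed$node_a %in% pos$node_id & ed$node_b %in% pos$node_id, ,
           drop = FALSE]
  # realized polylines: truncate at mobile endpoint's current position
  real <- vector("list", nrow(ed))
  rlen <- numeric(nrow(ed))
  for (i in seq_len(nrow(ed))) {
    xy <- ed$polyline[[i]]
    pb <- as.numeric(pos[match(ed$node_b[i], pos$node_id), c("x_um", "y_um")])
    endd <- sqrt(sum((xy[nrow(xy), ] - pb)^2))
    if (endd > PASS_TOL_UM) {
      pr <- project_point_polyline(xy, pb)
      xy <- truncate_polyline(xy, pr$s)
    }
    real[[i]] <- xy
    rlen[i] <- polyline_length(xy)
  }
  # pass-through junction detection via a spatial hash of realized segments
  att <- data.frame(edge_i = integer(), node_id = character(), s = numeric(),
                    stringsAsFactors = FALSE)
  if (nrow(ed) && nrow(pos)) {
    h <- seg_hash_new(cell_um = 1000)
    for (i in seq_len(nrow(ed))) seg_hash_add(h, real[[i]], as.character(i))
    for (j in order(pos$node_id)) {
      p <- c(pos$x_um[j], pos$y_um[j])
      q <- seg_hash_query(h, p - PASS_TOL_UM, p + PASS_TOL_UM)
      if (!length(q$idx)) next
      cand <- unique(as.integer(q$meta$edge_id))
      for (i in cand) {
        if (ed$node_a[i] == pos$node_id[j] || ed$node_b[i] == pos$node_id[j])
          next
        pr <- project_point_polyline(real[[i]], p)
        if (pr$dist <= PASS_TOL_UM && pr$s > PASS_TOL_UM &&
            pr$s < rlen[i] - PASS_TOL_UM) {
          # two coincident nodes (e.g. a just-born daughter tip sitting on
          # its branch junction) must not both split the edge: the first in
          # id order (creation order) is the structural junction
          dup <- att$edge_i == i & abs(att$s - pr$s) <= 2 * PASS_TOL_UM
          if (!any(dup))
            att <- rbind(att, data.frame(edge_i = i,
                                         node_id = pos$node_id[j],
                                         s = pr$s, stringsAsFactors = FALSE))
        }
      }
    }
  }
  # split edges at attachments -> igraph
  from <- character(); to <- character(); w <- numeric()
  parent <- character(); widths <- numeric(); labels <- character()
  sub_s0 <- numeric(); sub_s1 <- numeric()
  for (i in seq_len(nrow(ed))) {
    cuts <- att[att$edge_i == i, , drop = FALSE]
    cuts <- cuts[order(cuts$s), , drop = FALSE]
    vs <- c(ed$node_a[i], cuts$node_id, ed$node_b[i])
    ss <- c(0, cuts$s, rlen[i])
    for (k in seq_len(length(vs) - 1L)) {
      from <- c(from, vs[k]); to <- c(to, vs[k + 1L])
      w <- c(w, ss[k + 1L] - ss[k])
      parent <- c(parent, ed$edge_id[i])
      widths <- c(widths, ed$width_um[i]); labels <- c(labels, ed$label[i])
      sub_s0 <- c(sub_s0, ss[k]); sub_s1 <- c(sub_s1, ss[k + 1L])
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(pos), name = pos$node_id,
                            x = pos$x_um, y = pos$y_um)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
    igraph::E(g)$weight <- pmax(w, 1e-9)
    igraph::E(g)$parent <- parent
    igraph::E(g)$width_um <- widths
    igraph::E(g)$label <- labels
    igraph::E(g)$s0 <- sub_s0
    igraph::E(g)$s1 <- sub_s1
  }
  nodes <- pos
  nodes$degree <- as.numeric(igraph::degree(g)[nodes$node_id])
  ed$realized_length_um <- rlen
  ed$realized_polyline <- real
  structure(list(t = t, nodes = nodes, edges = ed, graph = g,
                 attachments = att, meta = series$meta),
            class = "network_snapshot")
}

#' @export
print.network_snapshot <- function(x, ...) {
  cat(sprintf("<network_snapshot> t=%.2f h: %d nodes, %d edges (%.0f um total)\n",
              x$t, nrow(x$nodes), nrow(x$edges), sum(x$realized_length_um %||%
                x$edges$realized_length_um)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of independent loops of a planar-embedded graph
#'
#' Cycle rank e - v + c (edges minus vertices plus connected components): for
#' a planar-embedded graph this equals the number of bounded faces, which is
#' the cumulative anastomosis count (every fusion or loop-closing crossing
#' adds exactly one face).
#'
#' @param g An igraph, or a `network_snapshot` (its split graph is used).
#' @return Integer loop count; 0 with a warning for an empty graph.
#' @export
euler_loop_count <- function(g) {
  if (inherits(g, "network_snapshot")) g <- g$graph
  v <- igraph::vcount(g); e <- igraph::ecount(g)
  if (v == 0 && e == 0) {
    warning("empty graph: loop count 0")
    return(0L)
  }
  comps <- igraph::components(g)$no
  as.integer(e - v + comps)
}

# ---- bundle I/O ------------------------------------------------------------

#' Write a network series to a CSV/JSON bundle directory
#'
#' Emits `nodes.csv`, `edges.csv` (polylines as WKT LINESTRINGs),
#' `events.csv`, `spores.csv` and `meta.json`.
#'
#' @param series A `network_series`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_series <- function(series, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  nd <- series$nodes[, c("node_id", "t_h", "x_um", "y_um", "degree")]
  utils::write.csv(nd, file.path(path, "nodes.csv"), row.names = FALSE)
  ed <- series$edges
  out <- data.frame(edge_id = ed$edge_id, node_a = ed$node_a,
                    node_b = ed$node_b, birth_t_h = ed$birth_t_h,
                    length_um = ed$length_um, width_um = ed$width_um,
                    label = ed$label,
                    polyline_wkt = vapply(ed$polyline, wkt_linestring, ""),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, file.path(path, "edges.csv"), row.names = FALSE)
  utils::write.csv(series$events, file.path(path, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(series$spores, file.path(path, "spores.csv"),
                   row.names = FALSE)
  jsonlite::write_json(series$meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Load a network series from a bundle directory
#'
#' @param path Directory written by [save_series()] (or following the same
#'   dialect: UTF-8 CSV, comma separators, '.' decimal, mandatory header).
#' @param ... Passed to [network_series()] (e.g. `check_degrees`).
#' @return A validated `network_series`.
#' @export
load_series <- function(path, ...) {
  req <- c("nodes.csv", "edges.csv", "meta.json")
  for (f in req)
    if (!file.exists(file.path(path, f)))
      series_error("bundle '%s' is missing %s", path, f)
  read1 <- function(f, cols) {
    d <- utils::read.csv(file.path(path, f), stringsAsFactors = FALSE)
    miss <- setdiff(cols, names(d))
    if (length(miss))
      series_error("%s: missing column '%s'", f, miss[1])
    d
  }
  nodes <- read1("nodes.csv", c("node_id", "t_h", "x_um", "y_um", "degree"))
  edges <- read1("edges.csv", c("edge_id", "node_a", "node_b", "birth_t_h",
                                "length_um", "width_um", "label",
                                "polyline_wkt"))
  ev <- if (file.exists(file.path(path, "events.csv")))
    utils::read.csv(file.path(path, "events.csv"), stringsAsFactors = FALSE,
                    colClasses = c(node_id = "character")) else NULL
  if (!is.null(ev) && !nrow(ev)) ev <- NULL
  sp <- if (file.exists(file.path(path, "spores.csv")))
    utils::read.csv(file.path(path, "spores.csv"), stringsAsFactors = FALSE)
  else NULL
  if (!is.null(sp) && !nrow(sp)) sp <- NULL
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  network_series(nodes, edges, events = ev, spores = sp, meta = meta, ...)
}

#' Export a snapshot as GraphML
#'
#' Node attributes x, y; edge attributes length_um, width_um, label and, if
#' present on the graph, bc.
#' @param snap A `network_snapshot`.
#' @param path Output file.
#' @export
export_graphml <- function(snap, path) {
  igraph::write_graph(snap$graph, path, format = "graphml")
  invisible(path)
}
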