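# Agent-based generator of synthetic colonies with ground truth.
#
# Tips are off-lattice agents that advect at a persistent speed with heading
# noise, duplicate by branching close to the apex, and on contact with an
# existing filament either fuse (anastomosis: the tip is annihilated and its
# tracked node becomes a degree-3 junction) or cross (a degree-4 junction is
# created and the tip continues). Every event is logged as ground truth so
# the tracking-based detectors can be validated exactly.

#' Simulation parameters
#'
#' Defaults are the measured study conditions: branching rate
#' \eqn{\alpha = 0.04\,h^{-1}} per tip, tip speeds from a truncated normal
#' with mean 240 and maximum 280 um/h (the front "puller" subpopulation
#' emerges from the fastest draws), and a fusion probability of 0.15 chosen
#' once so that the realized annihilation coefficient
#' \eqn{\beta_{eff} \approx p_{fuse}\, v\, \langle|\sin\theta|\rangle}
#' reproduces the measured \eqn{\beta \approx 23} um/h.
#'
#' @param alpha_per_h Branching rate per tip per hour.
#' @param p_fuse Probability that a filament contact fuses (anastomosis)
#'   rather than crosses.
#' @param v_mean_um_h,v_sd_um_h,v_min_um_h,v_puller_um_h Tip speed
#'   distribution: truncated normal mean, sd and truncation bounds (um/h).
#'   The upper bound is the speed of the fastest (puller) tips.
#' @param heading_noise_rad Per-step heading noise s.d. (radians).
#' @param branch_setback_um Maximum distance behind the apex at which a
#'   daughter tip is placed.
#' @param branch_angle_deg Range of the absolute daughter heading offset.
#' @param self_avoid_um Contacts closer than this (arc distance) to the tip's
#'   own origin are ignored, preventing instant self-fusion after branching.
#' @param dt_h Time step = observation frame interval (hours).
#' @param t_max_h Total simulated time (hours).
#' @param n_anchors Number of barrier-crossing points seeding the colony.
#' @param anchor_spacing_um Spacing of anchors along the barrier line y = 0.
#' @param roi_radius_mm Semicircular ROI radius (fungal half-plane y > 0).
#' @param bas_fraction_target Target BAS length fraction for [decorate_bas()].
#' @param spore_rate_per_mm_h Sporulation rate per mm of filament per hour.
#' @param width_rh_um,width_bas_um Ranges for runner-hypha and BAS widths.
#' @param seed Integer RNG seed; fixed seed gives bit-identical output.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(alpha_per_h = 0.04, p_fuse = 0.12,
                       v_mean_um_h = 240, v_sd_um_h = 25,
                       v_min_um_h = 160, v_puller_um_h = 280,
                       heading_noise_rad = 0.02,
                       branch_setback_um = 100,
                       branch_angle_deg = c(30, 90),
                       self_avoid_um = 60,
                       dt_h = 1, t_max_h = 100,
                       n_anchors = 3, anchor_spacing_um = 2000,
                       roi_radius_mm = 45,
                       bas_fraction_target = 0.3,
                       spore_rate_per_mm_h = 5e-4,
                       width_rh_um = c(8, 12), width_bas_um = c(2, 6),
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$alpha_per_h >= 0, p$p_fuse >= 0, p$p_fuse <= 1,
            p$dt_h > 0, p$t_max_h > 0, p$bas_fraction_target < 1,
            p$v_min_um_h > 0, p$v_puller_um_h >= p$v_mean_um_h)
  # stability: one step must be short relative to the inter-hypha spacing
  # set by saturation (rho_sat ~ 1e3 um/mm^2 => spacing ~ 1 mm)
  if (p$v_puller_um_h * p$dt_h > 1500)
    stop(sprintf(
      "dt_h too large: tips move %.0f um per step; use dt_h <= %.2f",
      p$v_puller_um_h * p$dt_h, 1500 / p$v_puller_um_h), call. = FALSE)
  class(p) <- "sim_params"
  p
}

rtrunc_speed <- function(n, p) {
  v <- stats::rnorm(n, p$v_mean_um_h, p$v_sd_um_h)
  bad <- which(v < p$v_min_um_h | v > p$v_puller_um_h)
  while (length(bad)) {
    v[bad] <- stats::rnorm(length(bad), p$v_mean_um_h, p$v_sd_um_h)
    bad <- which(v < p$v_min_um_h | v > p$v_puller_um_h)
  }
  v
}

#' Simulate a colony
#'
#' Runs the agent-based model and assembles a `network_series` plus the
#' ground-truth event log and a summary report. Deterministic for a fixed
#' seed.
#'
#' @param params A [sim_params()] list.
#' @return List with `series` (a `network_series`), `events` (ground-truth
#'   data.frame: branching rows name the daughter tip node, anastomosis rows
#'   the annihilated tip node, crossing rows the degree-4 junction node), and
#'   `report` (counts, realized beta_eff, per-frame front radius and
#'   RH length).
#' @export
simulate_colony <- function(params = sim_params()) {
  p <- params
  set.seed(p$seed)
  roi_um <- p$roi_radius_mm * 1000
  frames <- seq(0, p$t_max_h, by = p$dt_h)

  # --- mutable state ---
  tips <- list()        # per tip: id, alive, speed, heading, path (matrix),
                        # origin_node, origin_pos, birth
  nodes_static <- list()  # id -> list(x, y, birth)
  hash <- seg_hash_new(cell_um = 800)
  events <- list()
  tippos <- list()      # per tip id: data.frame(t, x, y)
  contact_sins <- numeric()
  next_node <- 0L
  new_node_id <- function() {
    next_node <<- next_node + 1L
    sprintf("n%05d", next_node)
  }

  anchors <- data.frame(node_id = character(), x_um = numeric(),
                        y_um = numeric(), stringsAsFactors = FALSE)
  offset <- (seq_len(p$n_anchors) - (p$n_anchors + 1) / 2) * p$anchor_spacing_um
  for (ax in offset) {
    aid <- new_node_id()
    nodes_static[[aid]] <- list(x = ax, y = 0, birth = 0)
    anchors <- rbind(anchors, data.frame(node_id = aid, x_um = ax, y_um = 0,
                                         stringsAsFactors = FALSE))
    tid <- new_node_id()
    tips[[tid]] <- list(id = tid, alive = TRUE,
                        speed = rtrunc_speed(1, p),
                        heading = stats::runif(1, 0.1 * pi, 0.9 * pi),
                        path = matrix(c(ax, 0), 1, 2),
                        origin_node = aid, origin_pos = c(ax, 0), birth = 0)
    tippos[[tid]] <- list(t = 0, x = ax, y = 0)
  }

  record_pos <- function(tid, t, x, y) {
    tp <- tippos[[tid]]
    tippos[[tid]] <<- list(t = c(tp$t, t), x = c(tp$x, x), y = c(tp$y, y))
  }

  for (t in frames[-1]) {
    live <- names(tips)[vapply(tips, `[[`, TRUE, "alive")]
    for (tid in live) {
      tip <- tips[[tid]]
      tip$heading <- tip$heading + stats::rnorm(1, 0, p$heading_noise_rad)
      p0 <- tip$path[nrow(tip$path), ]
      step <- tip$speed * p$dt_h
      remaining <- step
      fused <- FALSE
      while (remaining > 1e-9 && !fused) {
        p1 <- p0 + remaining * c(cos(tip$heading), sin(tip$heading))
        # stop at ROI boundary
        if (p1[2] < 0 || sqrt(sum(p1^2)) > roi_um) {
          tip$alive <- FALSE
          # clamp the final point inside
          if (p1[2] < 0) p1[2] <- 0
          r1 <- sqrt(sum(p1^2))
          if (r1 > roi_um) p1 <- p1 * (roi_um / r1)
          tip$path <- rbind(tip$path, p1)
          remaining <- 0
          break
        }
        q <- seg_hash_query(hash, p0, p1)
        hit <- NULL
        if (length(q$idx)) {
          xs <- segment_intersections(p0, p1, q$segs)
          if (nrow(xs)) {
            xs$edge_id <- q$meta$edge_id[xs$idx]
            # ignore own hypha and contacts near the tip's own origin
            keep <- xs$edge_id != tid &
              sqrt((xs$x - tip$origin_pos[1])^2 +
                     (xs$y - tip$origin_pos[2])^2) > p$self_avoid_um
            xs <- xs[keep, , drop = FALSE]
            if (nrow(xs)) {
              xs <- xs[order(xs$t), , drop = FALSE]
              # skip a contact at the very start of the sub-step (already
              # processed crossing point)
              xs <- xs[xs$t > 1e-9, , drop = FALSE]
              if (nrow(xs)) hit <- xs[1, ]
            }
          }
        }
        if (is.null(hit)) {
          tip$path <- rbind(tip$path, p1)
          p0 <- p1
          remaining <- 0
        } else {
          qpt <- c(hit$x, hit$y)
          # encounter angle between step direction and target segment
          seg <- q$segs[hit$idx, ]
          tang <- c(seg[3] - seg[1], seg[4] - seg[2])
          tang <- tang / sqrt(sum(tang^2))
          dirv <- c(cos(tip$heading), sin(tip$heading))
          contact_sins <- c(contact_sins, abs(dirv[1] * tang[2] -
                                                dirv[2] * tang[1]))
          if (stats::runif(1) < p$p_fuse) {
            # anastomosis: tip annihilated; its node becomes the junction
            tip$path <- rbind(tip$path, qpt)
            tip$alive <- FALSE
            fused <- TRUE
            events[[length(events) + 1L]] <- data.frame(
              event_type = "anastomosis", t_h = t, x_um = qpt[1],
              y_um = qpt[2], node_id = tid, stringsAsFactors = FALSE)
          } else {
            # crossing: static degree-4 junction on both polylines
            xid <- new_node_id()
            nodes_static[[xid]] <- list(x = qpt[1], y = qpt[2], birth = t)
            tip$path <- rbind(tip$path, qpt)
            travelled <- sqrt(sum((qpt - p0)^2))
            remaining <- remaining - travelled
            p0 <- qpt
            events[[length(events) + 1L]] <- data.frame(
              event_type = "crossing", t_h = t, x_um = qpt[1],
              y_um = qpt[2], node_id = xid, stringsAsFactors = FALSE)
          }
        }
      }
      end <- tip$path[nrow(tip$path), ]
      record_pos(tid, t, end[1], end[2])
      tips[[tid]] <- tip
      # commit this step's new segments to the collision structure
      np <- nrow(tip$path)
      k0 <- attr(tip$path, "committed")
      if (is.null(k0)) k0 <- 1L
      if (np > k0) {
        seg_hash_add(hash, tip$path[k0:np, , drop = FALSE], tid)
        attr(tips[[tid]]$path, "committed") <- np
      }
      # branching (after movement), Poisson with rate alpha; none on the
      # final frame (a daughter born after the last observation would be
      # invisible to any tracking)
      tip_pos <- tips[[tid]]$path[nrow(tips[[tid]]$path), ]
      near_edge <- tip_pos[2] < 600 ||
        sqrt(sum(tip_pos^2)) > roi_um - 600
      if (tip$alive && !near_edge && t < max(frames) - 1e-9 &&
          stats::runif(1) < 1 - exp(-p$alpha_per_h * p$dt_h)) {
        path <- tips[[tid]]$path
        cs <- cum_arclength(path)
        total <- cs[length(cs)]
        setback <- min(stats::runif(1, 0, p$branch_setback_um), total / 2)
        bp <- point_at_arclength(path, total - setback)
        jid <- new_node_id()
        nodes_static[[jid]] <- list(x = bp[1], y = bp[2], birth = t)
        did <- new_node_id()
        ang <- stats::runif(1, p$branch_angle_deg[1] * pi / 180,
                            p$branch_angle_deg[2] * pi / 180) *
          sample(c(-1, 1), 1)
        tips[[did]] <- list(id = did, alive = TRUE,
                            speed = rtrunc_speed(1, p),
                            heading = tips[[tid]]$heading + ang,
                            path = matrix(bp, 1, 2),
                            origin_node = jid, origin_pos = bp, birth = t)
        tippos[[did]] <- list(t = t, x = bp[1], y = bp[2])
        events[[length(events) + 1L]] <- data.frame(
          event_type = "branching", t_h = t, x_um = bp[1], y_um = bp[2],
          node_id = did, stringsAsFactors = FALSE)
      }
    }
  }

  # --- assemble the network series ---
  ev <- if (length(events)) do.call(rbind, events) else NULL
  edge_rows <- list()
  for (tid in names(tips)) {
    tip <- tips[[tid]]
    attr(tip$path, "committed") <- NULL
    edge_rows[[tid]] <- list(
      edge_id = paste0("e_", tid), node_a = tip$origin_node, node_b = tid,
      birth_t_h = tip$birth, length_um = polyline_length(tip$path),
      width_um = stats::runif(1, p$width_rh_um[1], p$width_rh_um[2]),
      label = "RH", polyline = tip$path)
  }
  edges <- data.frame(
    edge_id = vapply(edge_rows, `[[`, "", "edge_id"),
    node_a = vapply(edge_rows, `[[`, "", "node_a"),
    node_b = vapply(edge_rows, `[[`, "", "node_b"),
    birth_t_h = vapply(edge_rows, `[[`, 0, "birth_t_h"),
    length_um = vapply(edge_rows, `[[`, 0, "length_um"),
    width_um = vapply(edge_rows, `[[`, 0, "width_um"),
    label = vapply(edge_rows, `[[`, "", "label"),
    stringsAsFactors = FALSE)
  edges$polyline <- lapply(edge_rows, `[[`, "polyline")

  # nodes long table: static nodes constant from birth; tips tracked, and
  # frozen at their final position after annihilation (the tracked node
  # continues as the junction)
  nd <- list()
  for (nid in names(nodes_static)) {
    ns <- nodes_static[[nid]]
    tt <- frames[frames >= ns$birth]
    nd[[nid]] <- data.frame(node_id = nid, t_h = tt, x_um = ns$x, y_um = ns$y,
                            stringsAsFactors = FALSE)
  }
  for (tid in names(tips)) {
    tp <- tippos[[tid]]
    tt <- frames[frames >= tips[[tid]]$birth]
    x <- tp$x[match(tt, tp$t)]; y <- tp$y[match(tt, tp$t)]
    # after death the node stays at its last position
    lastx <- tp$x[length(tp$x)]; lasty <- tp$y[length(tp$y)]
    x[is.na(x)] <- lastx; y[is.na(y)] <- lasty
    nd[[tid]] <- data.frame(node_id = tid, t_h = tt, x_um = x, y_um = y,
                            stringsAsFactors = FALSE)
  }
  nodes <- do.call(rbind, nd)
  rownames(nodes) <- NULL
  nodes$degree <- NA_real_

  meta <- list(roi = list(barrier_offset_mm = 6, radius_mm = p$roi_radius_mm),
               pixel_size_um = am_thresholds()$pixel_size_um,
               root_anchors = anchors,
               sim_params = p[setdiff(names(p), character())])
  ser <- network_series(nodes, edges, events = ev, meta = meta,
                        validate = FALSE)
  # fill stored degrees from the recomputed snapshots
  for (t in ser$timepoints) {
    sn <- snapshot(ser, t, check = FALSE)
    idx <- which(ser$nodes$t_h == t)
    ser$nodes$degree[idx] <-
      sn$nodes$degree[match(ser$nodes$node_id[idx], sn$nodes$node_id)]
  }
  validate_series(ser, check_degrees = "last")

  counts <- table(factor(ser$events$event_type,
                         levels = c("branching", "anastomosis", "crossing",
                                    "sporulation")))
  # front position = maximum perpendicular distance from the barrier line
  front <- vapply(ser$timepoints, function(t) {
    pos <- node_positions_at(ser, t)
    max(pos$y_um)
  }, 0)
  rh_len <- vapply(ser$timepoints, function(t) {
    sn <- snapshot(ser, t, check = FALSE)
    sum(sn$edges$realized_length_um[sn$edges$label == "RH"])
  }, 0)
  report <- list(
    n_branching = as.integer(counts[["branching"]]),
    n_anastomosis = as.integer(counts[["anastomosis"]]),
    n_crossing = as.integer(counts[["crossing"]]),
    n_spores = 0L,
    mean_abs_sin = if (length(contact_sins)) mean(contact_sins) else NA_real_,
    beta_eff_um_h = if (length(contact_sins))
      p$p_fuse * p$v_mean_um_h * mean(contact_sins) else NA_real_,
    front_radius_um = front, rh_length_um = rh_len,
    timepoints = ser$timepoints)
  list(series = ser, events = ser$events, report = report)
}

#' Decorate a simulated colony with branched absorbing structures
#'
#' Appends short (< 400 um), thin lateral edges behind the advancing front so
#' that the BAS length fraction \eqn{\rho_{BAS} = L_{BAS}/(L_{RH}+L_{BAS})}
#' tracks the target (default 0.3, the measured constant investment).
#'
#' @param sim Result of [simulate_colony()].
#' @param params The [sim_params()] used (for the target fraction and seed).
#' @param front_lag_h BAS are only attached to filament deposited at least
#'   this long ago (they grow behind the front).
#' @return `sim` with an updated `series` (BAS edges and nodes appended).
#' @export
decorate_bas <- function(sim, params = sim_params(), front_lag_h = 5) {
  p <- params
  if (p$bas_fraction_target >= 1)
    stop("bas_fraction_target must be < 1", call. = FALSE)
  ser <- sim$series
  if (p$bas_fraction_target <= 0) return(sim)
  set.seed(p$seed + 1000003L)
  frames <- ser$timepoints
  rh <- ser$edges
  # deposited arc length of each RH edge at each frame (from tip positions)
  dep <- matrix(0, nrow(rh), length(frames))
  for (i in seq_len(nrow(rh))) {
    xy <- rh$polyline[[i]]
    for (j in seq_along(frames)) {
      if (rh$birth_t_h[i] > frames[j]) next
      nb <- ser$nodes[ser$nodes$node_id == rh$node_b[i] &
                        ser$nodes$t_h == frames[j], ]
      if (!nrow(nb)) next
      pr <- project_point_polyline(xy, c(nb$x_um[1], nb$y_um[1]))
      dep[i, j] <- pr$s
    }
  }
  target_ratio <- p$bas_fraction_target / (1 - p$bas_fraction_target)
  new_nodes <- list(); new_edges <- list()
  l_bas <- 0
  nxt <- 0L
  for (j in seq_along(frames)) {
    t <- frames[j]
    jlag <- which(frames <= t - front_lag_h)
    if (!length(jlag)) next
    avail <- dep[, max(jlag)]           # filament old enough to decorate
    want <- target_ratio * sum(dep[, j]) - l_bas
    while (want > 0 && sum(avail) > 0) {
      len <- stats::runif(1, 60, 390)
      i <- sample.int(nrow(rh), 1, prob = avail)
      s <- stats::runif(1, 0, avail[i])
      ap <- point_at_arclength(rh$polyline[[i]], s)
      # lateral heading ~ perpendicular to the local tangent
      eps <- min(10, avail[i] - s)
      ap2 <- point_at_arclength(rh$polyline[[i]], s + max(eps, 1))
      tang <- atan2(ap2[2] - ap[2], ap2[1] - ap[1])
      side <- sample(c(-1, 1), 1)
      ang <- tang + side * (pi / 2 + stats::rnorm(1, 0, 0.3))
      nseg <- 4L
      steps <- ang + cumsum(stats::rnorm(nseg, 0, 0.2))
      poly <- rbind(ap,
                    cbind(ap[1] + cumsum(cos(steps)) * (len / nseg),
                          ap[2] + cumsum(sin(steps)) * (len / nseg)))
      nxt <- nxt + 1L
      aid <- sprintf("bA%05d", nxt)   # attachment junction on the RH
      bid <- sprintf("bT%05d", nxt)   # BAS tip
      new_nodes[[length(new_nodes) + 1L]] <-
        data.frame(node_id = c(aid, bid), t = t,
                   x = c(ap[1], poly[nrow(poly), 1]),
                   y = c(ap[2], poly[nrow(poly), 2]),
                   stringsAsFactors = FALSE)
      new_edges[[length(new_edges) + 1L]] <- list(
        edge_id = sprintf("e_bas%05d", nxt), node_a = aid, node_b = bid,
        birth_t_h = t, length_um = polyline_length(poly),
        width_um = stats::runif(1, p$width_bas_um[1], p$width_bas_um[2]),
        label = "BAS", polyline = poly)
      l_bas <- l_bas + polyline_length(poly)
      want <- want - len
    }
  }
  if (length(new_edges)) {
    ne <- data.frame(
      edge_id = vapply(new_edges, `[[`, "", "edge_id"),
      node_a = vapply(new_edges, `[[`, "", "node_a"),
      node_b = vapply(new_edges, `[[`, "", "node_b"),
      birth_t_h = vapply(new_edges, `[[`, 0, "birth_t_h"),
      length_um = vapply(new_edges, `[[`, 0, "length_um"),
      width_um = vapply(new_edges, `[[`, 0, "width_um"),
      label = vapply(new_edges, `[[`, "", "label"),
      stringsAsFactors = FALSE)
    ne$polyline <- lapply(new_edges, `[[`, "polyline")
    nn <- do.call(rbind, new_nodes)
    rows <- do.call(rbind, lapply(seq_len(nrow(nn)), function(k) {
      tt <- frames[frames >= nn$t[k]]
      # degrees are known analytically: the attachment junction passes
      # through its runner hypha (2) and anchors the BAS edge (1); the BAS
      # tip terminates it (1); nothing ever attaches to a BAS afterwards
      deg <- if (grepl("^bA", nn$node_id[k])) 3 else 1
      data.frame(node_id = nn$node_id[k], t_h = tt, x_um = nn$x[k],
                 y_um = nn$y[k], degree = deg, stringsAsFactors = FALSE)
    }))
    ser$edges <- rbind(ser$edges, ne)
    ser$nodes <- rbind(ser$nodes, rows)
  }
  sim$series <- ser
  sim
}

#' Place spores on the network
#'
#' Spores appear as a Poisson process with intensity proportional to the
#' locally deposited filament length (rate per mm of filament per hour).
#'
#' @param sim Result of [simulate_colony()] (optionally BAS-decorated).
#' @param params The [sim_params()] used.
#' @return `sim` with `series$spores` filled and sporulation events appended.
#' @export
inject_spores <- function(sim, params = sim_params()) {
  p <- params
  ser <- sim$series
  if (p$spore_rate_per_mm_h <= 0) return(sim)
  set.seed(p$seed + 2000003L)
  frames <- ser$timepoints
  rows <- list()
  nxt <- 0L
  for (j in seq_along(frames)[-1]) {
    t <- frames[j]
    sn <- snapshot(ser, t, check = FALSE)
    lens <- sn$edges$realized_length_um
    total_mm <- sum(lens) / 1000
    lam <- p$spore_rate_per_mm_h * total_mm * (frames[j] - frames[j - 1])
    k <- stats::rpois(1, lam)
    if (k == 0) next
    for (q in seq_len(k)) {
      i <- sample.int(length(lens), 1, prob = pmax(lens, 0))
      s <- stats::runif(1, 0, lens[i])
      pt <- point_at_arclength(sn$edges$realized_polyline[[i]], s)
      nxt <- nxt + 1L
      rows[[nxt]] <- data.frame(
        spore_id = sprintf("sp%04d", nxt), t_h = t, x_um = pt[1],
        y_um = pt[2], radius_um = stats::runif(1, 30, 60),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) {
    sp <- do.call(rbind, rows)
    ser$spores <- sp
    ser$events <- rbind(ser$events, data.frame(
      event_type = "sporulation", t_h = sp$t_h, x_um = sp$x_um,
      y_um = sp$y_um, node_id = sp$spore_id, stringsAsFactors = FALSE))
  }
  sim$series <- ser
  sim$report$n_spores <- nrow(ser$spores)
  sim
}

#' Assign ground-truth bidirectional flow speeds to edges
#'
#' Gives every edge a mean tipward and rootward cytoplasmic speed as a
#' declared function of its betweenness centrality and distance to the tip:
#' `|u| = k1 * BC + k2 * d_tip`, capped. Tipward speeds are `bias` times
#' faster than rootward ones.
#'
#' @param snap A `network_snapshot` whose graph carries edge BC (see
#'   [betweenness_to_root()]), or a list with per-edge `bc`.
#' @param bc Named numeric: BC per edge_id (parent edges).
#' @param k1 Speed per unit BC ((um/s) per path count).
#' @param k2 Speed per mm of tip distance ((um/s)/mm).
#' @param cap Maximum |u| (um/s).
#' @param bias Tipward/rootward asymmetry (default 1.3: tipward ~30% faster).
#' @return data.frame(edge_id, d_tip_mm, bc, u_plus_um_s, u_minus_um_s).
#' @export
synthesize_flow_field <- function(snap, bc, k1 = 0, k2 = 0.3, cap = 8,
                                  bias = 1.3) {
  ed <- snap$edges
  if (is.null(bc)) stop("BC attribute missing: compute betweenness_to_root first",
                        call. = FALSE)
  d_tip <- numeric(nrow(ed))
  for (i in seq_len(nrow(ed))) {
    # midpoint distance to the tip end of the edge's own hypha
    d_tip[i] <- ed$realized_length_um[i] / 2 / 1000
  }
  bcv <- as.numeric(bc[ed$edge_id])
  bcv[is.na(bcv)] <- 0
  base <- pmin(k1 * bcv + k2 * d_tip, cap)
  data.frame(edge_id = ed$edge_id, d_tip_mm = d_tip, bc = bcv,
             u_plus_um_s = base * sqrt(bias),
             u_minus_um_s = -base / sqrt(bias),
             stringsAsFactors = FALSE)
}
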