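# Low-level planar geometry for polyline-embedded networks.
# Polylines are n x 2 numeric matrices of (x_um, y_um) vertices.

#' Arc length of a polyline
#' @param xy An n x 2 matrix of vertices.
#' @return Total length in the same units as the coordinates.
#' @export
polyline_length <- function(xy) {
  if (is.null(xy) || nrow(xy) < 2) return(0)
  sum(sqrt(rowSums(diff(xy)^2)))
}

# cumulative arc length at each vertex (first = 0)
cum_arclength <- function(xy) {
  if (nrow(xy) < 2) return(0)
  c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
}

#' Point on a polyline at a given arc length
#' @keywords internal
point_at_arclength <- function(xy, s) {
  cs <- cum_arclength(xy)
  s <- max(0, min(s, cs[length(cs)]))
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- min(i, nrow(xy) - 1L)
  seg <- cs[i + 1L] - cs[i]
  f <- if (seg > 0) (s - cs[i]) / seg else 0
  xy[i, ] + f * (xy[i + 1L, ] - xy[i, ])
}

# truncate polyline at arc length s (keeps [0, s])
truncate_polyline <- function(xy, s) {
  cs <- cum_arclength(xy)
  total <- cs[length(cs)]
  if (s >= total) return(xy)
  if (s <= 0) return(xy[c(1L, 1L), , drop = FALSE])
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  p <- point_at_arclength(xy, s)
  rbind(xy[seq_len(i), , drop = FALSE], p)
}

# distance from point p to polyline; returns list(dist, s) with s the arc
# length of the closest point
project_point_polyline <- function(xy, p) {
  if (is.null(xy) || nrow(xy) < 2)
    return(list(dist = Inf, s = 0, point = c(NA_real_, NA_real_)))
  a <- xy[-nrow(xy), , drop = FALSE]
  b <- xy[-1L, , drop = FALSE]
  d <- b - a
  len2 <- rowSums(d^2)
  t <- ((p[1] - a[, 1]) * d[, 1] + (p[2] - a[, 2]) * d[, 2]) / pmax(len2, 1e-300)
  t <- pmin(pmax(t, 0), 1)
  qx <- a[, 1] + t * d[, 1]
  qy <- a[, 2] + t * d[, 2]
  dist2 <- (qx - p[1])^2 + (qy - p[2])^2
  i <- which.min(dist2)
  cs <- cum_arclength(xy)
  list(dist = sqrt(dist2[i]), s = cs[i] + t[i] * sqrt(len2[i]),
       point = c(qx[i], qy[i]))
}

# Intersections of segment (p0, p1) with a set of segments given as a matrix
# with columns x1,y1,x2,y2. Returns data.frame(idx, t, u, x, y) where t is the
# parameter along (p0,p1) and u along the candidate segment; open-interval
# touching at endpoints is included (u,t in [0,1]).
segment_intersections <- function(p0, p1, segs) {
  if (is.null(segs) || nrow(segs) == 0)
    return(data.frame(idx = integer(), t = numeric(), u = numeric(),
                      x = numeric(), y = numeric()))
  rx <- p1[1] - p0[1]; ry <- p1[2] - p0[2]
  sx <- segs[, 3] - segs[, 1]; sy <- segs[, 4] - segs[, 2]
  denom <- rx * sy - ry * sx
  qpx <- segs[, 1] - p0[1]; qpy <- segs[, 2] - p0[2]
  t <- (qpx * sy - qpy * sx) / denom
  u <- (qpx * ry - qpy * rx) / denom
  ok <- is.finite(t) & is.finite(u) & t >= 0 & t <= 1 & u >= 0 & u <= 1 &
    abs(denom) > 1e-12
  idx <- which(ok)
  data.frame(idx = idx, t = t[idx], u = u[idx],
             x = p0[1] + t[idx] * rx, y = p0[2] + t[idx] * ry)
}

#' Write and parse WKT LINESTRING geometries
#'
#' Minimal well-known-text support for the bundle's `polyline_wkt` column.
#' @param xy An n x 2 matrix of coordinates.
#' @return `wkt_linestring()` returns a character scalar;
#'   `parse_wkt_linestring()` returns an n x 2 matrix.
#' @export
wkt_linestring <- function(xy) {
  xy <- rbind(xy)
  paste0("LINESTRING (",
         paste(sprintf("%.6f %.6f", xy[, 1], xy[, 2]), collapse = ", "), ")")
}

#' @rdname wkt_linestring
#' @param wkt A WKT `LINESTRING (...)` string.
#' @export
parse_wkt_linestring <- function(wkt) {
  body <- sub("^\\s*LINESTRING\\s*\\(", "", wkt)
  body <- sub("\\)\\s*$", "", body)
  parts <- strsplit(trimws(strsplit(body, ",")[[1]]), "\\s+")
  m <- t(vapply(parts, function(p) as.numeric(p[1:2]), numeric(2)))
  colnames(m) <- c("x_um", "y_um")
  m
}

# Exact split of a polyline's length into radial bins around `origin`.
# boundaries: increasing vector of outer radii (first bin is [0, b1]).
# Returns numeric vector of length length(boundaries) + 1 (last = beyond).
clip_length_radial <- function(xy, origin, boundaries) {
  nb <- length(boundaries)
  out <- numeric(nb + 1L)
  if (is.null(xy) || nrow(xy) < 2) return(out)
  a <- sweep(xy[-nrow(xy), , drop = FALSE], 2, origin)
  b <- sweep(xy[-1L, , drop = FALSE], 2, origin)
  for (k in seq_len(nrow(a))) {
    p <- a[k, ]; q <- b[k, ]
    d <- q - p
    L <- sqrt(sum(d^2))
    if (L == 0) next
    # radius along the segment: |p + t d|; find crossings with each boundary
    tcuts <- c(0, 1)
    A <- sum(d^2); B <- 2 * sum(p * d)
    for (r in boundaries) {
      C <- sum(p^2) - r^2
      disc <- B^2 - 4 * A * C
      if (disc > 0) {
        rt <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
        rt <- rt[rt > 0 & rt < 1]
        tcuts <- c(tcuts, rt)
      }
    }
    tcuts <- sort(unique(tcuts))
    for (j in seq_len(length(tcuts) - 1L)) {
      tm <- (tcuts[j] + tcuts[j + 1L]) / 2
      rm <- sqrt(sum((p + tm * d)^2))
      bin <- findInterval(rm, boundaries) + 1L  # 1..nb inside, nb+1 beyond
      bin <- min(bin, nb + 1L)
      out[bin] <- out[bin] + (tcuts[j + 1L] - tcuts[j]) * L
    }
  }
  out
}

# area of the convex hull of points (n x 2); 0 if degenerate
convex_hull_area <- function(xy) {
  xy <- unique(rbind(xy))
  if (nrow(xy) < 3) return(0)
  h <- grDevices::chull(xy)
  v <- xy[h, , drop = FALSE]
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# --- spatial hash over segments (uniform grid, environment-backed) ---------
# Segment store is preallocated with capacity doubling; grid cells map to
# integer segment indices via the environment's own hash table.

seg_hash_new <- function(cell_um = 500) {
  e <- new.env(parent = emptyenv(), hash = TRUE)
  e$.cell <- cell_um
  e$.segs <- matrix(NA_real_, 256, 4)
  e$.edge <- character(256)
  e$.n <- 0L
  e$.grid <- new.env(parent = emptyenv(), hash = TRUE)
  e
}

seg_hash_keys <- function(cell, x1, y1, x2, y2) {
  ix <- floor(sort(c(x1, x2)) / cell)
  iy <- floor(sort(c(y1, y2)) / cell)
  as.vector(outer(ix[1]:ix[2], iy[1]:iy[2],
                  function(a, b) paste(a, b, sep = ":")))
}

seg_hash_add <- function(h, xy, edge_id) {
  if (nrow(xy) < 2) return(invisible(h))
  segs <- cbind(xy[-nrow(xy), 1], xy[-nrow(xy), 2], xy[-1L, 1], xy[-1L, 2])
  need <- h$.n + nrow(segs)
  while (need > nrow(h$.segs)) {
    h$.segs <- rbind(h$.segs, matrix(NA_real_, nrow(h$.segs), 4))
    h$.edge <- c(h$.edge, character(length(h$.edge)))
  }
  idx <- h$.n + seq_len(nrow(segs))
  h$.segs[idx, ] <- segs
  h$.edge[idx] <- edge_id
  h$.n <- need
  g <- h$.grid
  for (k in seq_len(nrow(segs))) {
    keys <- seg_hash_keys(h$.cell, segs[k, 1], segs[k, 2], segs[k, 3],
                          segs[k, 4])
    for (key in keys) {
      cur <- if (exists(key, envir = g, inherits = FALSE))
        get(key, envir = g) else integer()
      assign(key, c(cur, idx[k]), envir = g)
    }
  }
  invisible(h)
}

seg_hash_query <- function(h, p0, p1) {
  keys <- seg_hash_keys(h$.cell, p0[1], p0[2], p1[1], p1[2])
  g <- h$.grid
  idx <- unique(unlist(lapply(keys, function(key)
    if (exists(key, envir = g, inherits = FALSE)) get(key, envir = g)
    else integer())))
  list(idx = seq_along(idx), segs = h$.segs[idx, , drop = FALSE],
       meta = data.frame(edge_id = h$.edge[idx], stringsAsFactors = FALSE))
}
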