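# Independent oracles used across the test files. Each is deliberately
# implemented with a different algorithm than the package code it checks.

# --- brute-force single-source Dijkstra on an arc list ----------------------
# arcs: data.frame(from, to, w) of directed arcs (two-way edges appear twice).
# Returns named vector of distances from `src` to every node id in `nodes`.
oracle_dijkstra <- function(arcs, nodes, src) {
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[src] <- 0
  visited <- setNames(rep(FALSE, length(nodes)), nodes)
  repeat {
    cand <- which(!visited & is.finite(dist))
    if (!length(cand)) break
    u <- names(cand)[which.min(dist[cand])]
    visited[u] <- TRUE
    out <- arcs[arcs$from == u, ]
    if (nrow(out)) {
      # parallel arcs: take the per-target minimum before relaxing
      best <- tapply(dist[u] + out$w, out$to, min)
      upd <- best < dist[names(best)]
      dist[names(best)[upd]] <- best[upd]
    }
  }
  dist
}

# arc list (both directions for two-way edges) from an edge table
edges_to_arcs <- function(edges) {
  fw <- data.frame(from = edges$from_node, to = edges$to_node,
                   w = edges$length_km, stringsAsFactors = FALSE)
  bk <- fw[edges$oneway == 0L, c("to", "from", "w")]
  names(bk) <- c("from", "to", "w")
  rbind(fw, bk)
}

# per-pair nearest-facility distances by brute force
oracle_nearest <- function(edges, nodes, origin_nodes, facility_nodes) {
  arcs <- edges_to_arcs(edges)
  vapply(origin_nodes, function(o) {
    d <- oracle_dijkstra(arcs, nodes, o)
    min(d[facility_nodes])
  }, numeric(1))
}

# reachability closure by BFS over an adjacency list (independent of igraph)
oracle_strongly_connected <- function(edges, nodes) {
  arcs <- edges_to_arcs(edges)
  reach <- function(arcs, start) {
    seen <- start
    frontier <- start
    while (length(frontier)) {
      nxt <- unique(arcs$to[arcs$from %in% frontier])
      frontier <- setdiff(nxt, seen)
      seen <- c(seen, frontier)
    }
    seen
  }
  fwd <- reach(arcs, nodes[1L])
  rev_arcs <- data.frame(from = arcs$to, to = arcs$from, stringsAsFactors = FALSE)
  bwd <- reach(rev_arcs, nodes[1L])
  length(fwd) == length(nodes) && length(bwd) == length(nodes)
}

# random strongly connected graph: ring backbone (guarantees strong
# connectivity) plus random chords, >= 10% one-way
random_strong_graph <- function(n_nodes, n_extra, seed) {
  set.seed(seed)
  ids <- sprintf("v%03d", seq_len(n_nodes))
  xy <- matrix(runif(2 * n_nodes, 0, 10000), ncol = 2L)
  nodes <- data.frame(node_id = ids, easting_m = xy[, 1L], northing_m = xy[, 2L],
                      stringsAsFactors = FALSE)
  ring_from <- seq_len(n_nodes)
  ring_to <- c(seq_len(n_nodes)[-1L], 1L)
  ch_from <- sample.int(n_nodes, n_extra, replace = TRUE)
  ch_to <- sample.int(n_nodes, n_extra, replace = TRUE)
  keep <- ch_from != ch_to
  from <- c(ring_from, ch_from[keep]); to <- c(ring_to, ch_to[keep])
  m <- length(from)
  oneway <- integer(m)
  oneway[seq_len(n_nodes)] <- 1L                      # ring arcs are one-way
  oneway[sample(which(oneway == 0L), ceiling(0.1 * m))] <- 1L
  list(edges = data.frame(
         edge_id = sprintf("e%04d", seq_len(m)),
         from_node = ids[from], to_node = ids[to],
         length_km = round(runif(m, 0.1, 5), 6), oneway = oneway,
         stringsAsFactors = FALSE),
       nodes = nodes)
}

# --- Monte-Carlo buffer/green intersection area -----------------------------
# Samples in the bounding box of the buffer disc; a point counts when it is
# inside the circle AND inside at least one green polygon (even-odd rule,
# re-implemented here without package code).
oracle_mc_green_area <- function(cx, cy, r, rings, n_samples, seed) {
  set.seed(seed)
  px <- runif(n_samples, cx - r, cx + r)
  py <- runif(n_samples, cy - r, cy + r)
  in_circle <- (px - cx)^2 + (py - cy)^2 <= r^2
  pip <- function(px, py, m) {
    n <- nrow(m); inside <- rep(FALSE, length(px)); j <- n
    for (i in seq_len(n)) {
      xi <- m[i, 1L]; yi <- m[i, 2L]; xj <- m[j, 1L]; yj <- m[j, 2L]
      cr <- (yi > py) != (yj > py)
      if (any(cr)) {
        xin <- (xj - xi) * (py - yi) / (yj - yi) + xi
        inside <- xor(inside, cr & (px < xin))
      }
      j <- i
    }
    inside
  }
  in_green <- rep(FALSE, n_samples)
  for (m in rings) in_green <- in_green | pip(px, py, m)
  (2 * r)^2 * mean(in_circle & in_green)
}

# --- fine-rasterisation zonal mean oracle ----------------------------------
# Rasterises the zone at `fine_m` resolution; a coarse cell contributes when
# at least one fine-cell centre inside the zone falls within it.
oracle_zone_mean_fine <- function(grid, ring, fine_m = 10) {
  s <- grid$cellsize_m
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  bb <- c(min(ring[, 1L]), min(ring[, 2L]), max(ring[, 1L]), max(ring[, 2L]))
  fx <- seq(bb[1L] + fine_m / 2, bb[3L], by = fine_m)
  fy <- seq(bb[2L] + fine_m / 2, bb[4L], by = fine_m)
  pts <- expand.grid(x = fx, y = fy)
  inside <- ahah::point_in_polygon(pts$x, pts$y, ring)
  pts <- pts[inside, ]
  cj <- floor((pts$x - grid$xll) / s) + 1L
  ci <- nr - floor((pts$y - grid$yll) / s)
  ok <- cj >= 1L & cj <= nc & ci >= 1L & ci <= nr
  cells <- unique(cbind(ci[ok], cj[ok]))
  vals <- grid$values[cells]
  vals <- vals[!is.na(vals)]
  mean(vals)
}

# Draw a random polygonal zone in general position w.r.t. the oracle's 10 m
# quantisation: every raster cell either misses the zone or overlaps it by
# more than 200 m^2, so a 10 m fine grid cannot miss a genuine overlap. Zones
# with sub-resolution slivers are outside the oracle's validity domain and
# are redrawn (deterministically, by advancing the sub-seed).
sample_generic_zone <- function(grid, seed, centre_range, n_vertices = 6,
                                rad_range = c(700, 2200)) {
  s <- grid$cellsize_m
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  for (attempt in 0:50) {
    set.seed(seed + 1000L * attempt)
    cx <- runif(1, centre_range[1], centre_range[2])
    cy <- runif(1, centre_range[1], centre_range[2])
    th <- sort(runif(n_vertices, 0, 2 * pi))
    rad <- runif(n_vertices, rad_range[1], rad_range[2])
    ring <- cbind(cx + rad * cos(th), cy + rad * sin(th))
    ok <- TRUE
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        x0 <- grid$xll + (j - 1) * s; y0 <- grid$yll + (nr - i) * s
        cell <- cbind(c(x0, x0 + s, x0 + s, x0), c(y0, y0, y0 + s, y0 + s))
        clp <- ahah::clip_polygon(ring, cell)
        a <- if (nrow(clp) >= 3L) ahah::polygon_area(clp) else 0
        if (a > 1e-6 && a < 200) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) return(ring)
  }
  stop("could not draw a generic zone")
}

# --- high-precision standard normal quantile -------------------------------
# Inverts pnorm by bisection + Newton polish; independent of qnorm.
oracle_qnorm <- function(p, tol = 1e-13) {
  vapply(p, function(pp) {
    lo <- -10; hi <- 10
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (pnorm(mid) < pp) lo <- mid else hi <- mid
    }
    x <- (lo + hi) / 2
    for (i in 1:5) x <- x - (pnorm(x) - pp) / dnorm(x)
    x
  }, numeric(1))
}

# --- misc -------------------------------------------------------------------
# independent group-by mean (environment-based accumulation)
oracle_group_mean <- function(values, groups) {
  sums <- new.env(); cnts <- new.env()
  for (i in seq_along(values)) {
    g <- groups[i]
    sums[[g]] <- (if (is.null(sums[[g]])) 0 else sums[[g]]) + values[i]
    cnts[[g]] <- (if (is.null(cnts[[g]])) 0 else cnts[[g]]) + 1
  }
  gs <- sort(ls(sums))
  setNames(vapply(gs, function(g) sums[[g]] / cnts[[g]], numeric(1)), gs)
}

# a small shared region for tests that need a realistic instance (generated
# once per test run; cached in the testthat process)
tiny_region <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- ahah::region_config(seed = 42L, extent_km = 8, n_zones = 16L,
                                 postcodes_per_zone = c(3L, 6L),
                                 n_green_polygons = 40L)
      cache <<- ahah::generate_region(cfg)
    }
    cache
  }
})
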