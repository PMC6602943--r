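# Graph construction, snapping and nearest-facility routing, including the
# brute-force Dijkstra oracle equivalence on random strongly connected graphs.

mk_nodes <- function(ids, x, y) {
  data.frame(node_id = ids, easting_m = x, northing_m = y, stringsAsFactors = FALSE)
}
mk_edges <- function(from, to, len, oneway = 0L) {
  data.frame(edge_id = sprintf("e%d", seq_along(from)), from_node = from,
             to_node = to, length_km = len,
             oneway = rep(as.integer(oneway), length.out = length(from)),
             stringsAsFactors = FALSE)
}

test_that("build_graph honours one-way semantics and validates input", {
  nodes <- mk_nodes(c("A", "B", "C"), c(0, 1000, 2000), c(0, 0, 0))
  net <- build_graph(mk_edges(c("A", "B"), c("B", "C"), c(1, 2)), nodes)
  expect_equal(igraph::ecount(net$graph), 4L)   # 2 two-way edges -> 4 arcs
  net1 <- build_graph(mk_edges(c("A", "B"), c("B", "C"), c(1, 2), c(1L, 0L)), nodes)
  expect_equal(igraph::ecount(net1$graph), 3L)

  expect_error(build_graph(mk_edges("A", "B", 0), nodes), "nonpositive length")
  expect_error(build_graph(mk_edges("A", "D", 1), nodes), "unknown node")
  expect_error(build_graph(mk_edges("A", "A", 1), nodes), "self-loop")
  expect_error(build_graph(mk_edges(character(0), character(0), numeric(0)), nodes),
               "empty")
})

test_that("snap_to_network picks nearest node with smallest-id tie-break", {
  nodes <- mk_nodes(c("5", "9"), c(0, 100), c(0, 0))
  net <- build_graph(mk_edges("5", "9", 0.1), nodes)
  # exactly on a node
  s <- snap_to_network(c(0, 0), net)
  expect_equal(s$node_id, "5"); expect_equal(s$snap_distance_m, 0)
  # equidistant -> smallest node_id
  s <- snap_to_network(c(50, 30), net)
  expect_equal(s$node_id, "5")
  expect_equal(s$snap_distance_m, sqrt(50^2 + 30^2))
  # brute-force nearest scan on a larger instance
  g <- random_strong_graph(100, 150, seed = 31)
  net2 <- build_graph(g$edges, g$nodes)
  set.seed(17)
  for (i in 1:20) {
    p <- runif(2, 0, 10000)
    d <- sqrt((g$nodes$easting_m - p[1])^2 + (g$nodes$northing_m - p[2])^2)
    expect_equal(snap_to_network(p, net2)$node_id,
                 g$nodes$node_id[which.min(d)])
  }
})

test_that("nearest_facility_distances matches path enumeration on small graphs", {
  # path graph A-B(1.0)-C(2.0) two-way; facility at C, origin at A -> 3.0 km
  nodes <- mk_nodes(c("A", "B", "C"), c(0, 1000, 3000), c(0, 0, 0))
  net <- build_graph(mk_edges(c("A", "B"), c("B", "C"), c(1, 2)), nodes)
  res <- nearest_facility_distances(
    net,
    data.frame(pcd = "P1", easting_m = 0, northing_m = 0),
    data.frame(site_id = "f1", category = "gp", easting_m = 3000, northing_m = 0))
  expect_equal(res$distance_km, 3.0)
  expect_equal(res$snapped_facility_node, "C")

  # facility snapped to the origin node -> 0 km
  res0 <- nearest_facility_distances(
    net, data.frame(pcd = "P1", easting_m = 10, northing_m = 0),
    data.frame(site_id = "f1", category = "gp", easting_m = 0, northing_m = 5))
  expect_equal(res0$distance_km, 0)

  # one-way detour: B->A one-way (toward A only), A-C 5.0 and C-B 1.0 two-way;
  # origin A, facility B must route A->C->B = 6.0 km
  nodes2 <- mk_nodes(c("A", "B", "C"), c(0, 1000, 500), c(0, 0, 800))
  edges2 <- data.frame(edge_id = c("e1", "e2", "e3"),
                       from_node = c("B", "A", "C"), to_node = c("A", "C", "B"),
                       length_km = c(1, 5, 1), oneway = c(1L, 0L, 0L),
                       stringsAsFactors = FALSE)
  net2 <- build_graph(edges2, nodes2)
  res2 <- nearest_facility_distances(
    net2, data.frame(pcd = "P1", easting_m = 0, northing_m = 0),
    data.frame(site_id = "f1", category = "gp", easting_m = 1000, northing_m = 0))
  expect_equal(res2$distance_km, 6.0)

  # error contracts
  expect_error(nearest_facility_distances(
    net, data.frame(pcd = "P1", easting_m = 0, northing_m = 0),
    data.frame(), category = "gambling"), "gambling")
})

test_that("unreachable origins error by default and flag Inf when allowed", {
  # A -> B one-way: B cannot reach A
  nodes <- mk_nodes(c("A", "B"), c(0, 1000), c(0, 0))
  net <- build_graph(mk_edges("A", "B", 1, 1L), nodes)
  origins <- data.frame(pcd = "P1", easting_m = 1000, northing_m = 0)
  fac <- data.frame(site_id = "f", category = "gp", easting_m = 0, northing_m = 0)
  expect_error(nearest_facility_distances(net, origins, fac), "P1")
  res <- nearest_facility_distances(net, origins, fac, allow_unreachable = TRUE)
  expect_true(is.infinite(res$distance_km))
})

test_that("routing equals brute-force per-pair minima on random graphs", {
  # a lighter version of the acceptance sweep: 5 seeded graphs
  for (seed in 1:5) {
    g <- random_strong_graph(60, 80, seed = 100 + seed)
    net <- build_graph(g$edges, g$nodes)
    set.seed(200 + seed)
    o_idx <- sample.int(60, 12)
    f_idx <- sample.int(60, 4)
    origins <- data.frame(pcd = sprintf("P%02d", seq_along(o_idx)),
                          easting_m = g$nodes$easting_m[o_idx],
                          northing_m = g$nodes$northing_m[o_idx])
    fac <- data.frame(site_id = sprintf("f%d", seq_along(f_idx)), category = "gp",
                      easting_m = g$nodes$easting_m[f_idx],
                      northing_m = g$nodes$northing_m[f_idx])
    res <- nearest_facility_distances(net, origins, fac)
    expected <- oracle_nearest(g$edges, g$nodes$node_id,
                               g$nodes$node_id[o_idx], g$nodes$node_id[f_idx])
    expect_equal(res$distance_km, unname(expected), tolerance = 1e-12)
  }
})

test_that("adding a facility never increases any distance (monotonicity)", {
  g <- random_strong_graph(80, 100, seed = 55)
  net <- build_graph(g$edges, g$nodes)
  origins <- data.frame(pcd = sprintf("P%02d", 1:15),
                        easting_m = g$nodes$easting_m[1:15],
                        northing_m = g$nodes$northing_m[1:15])
  fac1 <- data.frame(site_id = "f1", category = "gp",
                     easting_m = g$nodes$easting_m[40], northing_m = g$nodes$northing_m[40])
  fac2 <- rbind(fac1, data.frame(site_id = "f2", category = "gp",
                                 easting_m = g$nodes$easting_m[60],
                                 northing_m = g$nodes$northing_m[60]))
  d1 <- nearest_facility_distances(net, origins, fac1)$distance_km
  d2 <- nearest_facility_distances(net, origins, fac2)$distance_km
  expect_true(all(d2 <= d1 + 1e-12))
})

test_that("with no one-way edges, forward and reversed routing agree", {
  g <- random_strong_graph(60, 80, seed = 77)
  g$edges$oneway <- 0L
  net <- build_graph(g$edges, g$nodes)
  rev_edges <- g$edges
  rev_edges$from_node <- g$edges$to_node
  rev_edges$to_node <- g$edges$from_node
  net_rev <- build_graph(rev_edges, g$nodes)
  origins <- data.frame(pcd = sprintf("P%02d", 1:10),
                        easting_m = g$nodes$easting_m[1:10],
                        northing_m = g$nodes$northing_m[1:10])
  fac <- data.frame(site_id = "f", category = "gp",
                    easting_m = g$nodes$easting_m[30], northing_m = g$nodes$northing_m[30])
  expect_equal(nearest_facility_distances(net, origins, fac)$distance_km,
               nearest_facility_distances(net_rev, origins, fac)$distance_km)
})

test_that("lattice network distances dominate Euclidean separation", {
  reg <- tiny_region()
  net <- reg$network
  origins <- reg$postcodes[1:20, ]
  fac <- reg$services$gp
  res <- nearest_facility_distances(net, origins, fac)
  for (i in seq_len(nrow(res))) {
    a <- net$nodes[net$nodes$node_id == res$snapped_origin_node[i], ]
    b <- net$nodes[net$nodes$node_id == res$snapped_facility_node[i], ]
    eucl_km <- sqrt((a$easting_m - b$easting_m)^2 + (a$northing_m - b$northing_m)^2) / 1000
    expect_gte(res$distance_km[i], eucl_km - 1e-9)
  }
})
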