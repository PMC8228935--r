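path_graph <- function(K) graph_obj(K, data.frame(i = 1:(K - 1), j = 2:K))
star_graph <- function(leaves) graph_obj(leaves + 1,
                                         data.frame(i = 1, j = 2:(leaves + 1)))

test_that("degree counts incident edges", {
  expect_equal(degree_centrality(graph_obj(3, data.frame(i = integer(),
                                                         j = integer()))),
               c(0, 0, 0))
  tri <- graph_obj(3, data.frame(i = c(1, 2, 1), j = c(2, 3, 3)))
  expect_equal(degree_centrality(tri), c(2, 2, 2))
  st <- star_graph(4)
  expect_equal(degree_centrality(st), c(4, 1, 1, 1, 1))
  expect_equal(sum(degree_centrality(st)), 2 * nrow(st$edges))
})

test_that("hop distances match closed forms and Floyd-Warshall", {
  p3 <- path_graph(3)
  expect_equal(shortest_path_lengths(p3, 1), c(0, 1, 2))
  disc <- graph_obj(4, data.frame(i = 1, j = 2))
  expect_equal(shortest_path_lengths(disc, 1), c(0, 1, Inf, Inf))
  expect_error(shortest_path_lengths(p3, 9), "unknown source")
  set.seed(77)
  ed <- random_graph(12, 0.3, seed = 77)
  g <- graph_obj(12, ed)
  D <- oracle_distances(12, ed)
  for (s in 1:12) expect_equal(shortest_path_lengths(g, s), D[s, ])
})

test_that("closeness follows its defining formula on closed-form graphs", {
  p3 <- path_graph(3)
  cc <- closeness_centrality(p3)
  expect_equal(cc[2], 1)          # [(1+1)/2]^-1
  expect_equal(cc[1], 2 / 3)      # [(1+2)/2]^-1
  expect_equal(cc[3], 2 / 3)
  k5 <- graph_obj(5, as.data.frame(t(utils::combn(5, 2))) |>
                    stats::setNames(c("i", "j")))
  expect_equal(closeness_centrality(k5), rep(1, 5))
  expect_error(closeness_centrality(graph_obj(1, data.frame(i = integer(),
                                                            j = integer()))),
               "single-node")
})

test_that("betweenness matches closed forms on path and star", {
  cb3 <- betweenness_centrality(path_graph(3))
  expect_equal(cb3, c(0, 1, 0))
  cb_star <- betweenness_centrality(star_graph(3))
  expect_equal(cb_star, c(1, 0, 0, 0))
  expect_error(betweenness_centrality(path_graph(2)), "K < 3")
})

test_that("path-graph betweenness equals the closed-form profile", {
  K <- 10
  cb <- betweenness_centrality(path_graph(K))
  i <- 0:(K - 1)
  expect_equal(cb, 2 * i * (K - 1 - i) / ((K - 1) * (K - 2)), tolerance = 1e-14)
})

test_that("centralities equal the exhaustive path-enumeration oracle", {
  # 50 random graphs up to K = 12, exact agreement
  for (seed in 1:50) {
    K <- 5 + (seed %% 8)
    ed <- random_graph(K, 0.3, seed = 1000 + seed)
    g <- graph_obj(K, ed)
    oracle <- oracle_centralities(K, ed)
    expect_equal(betweenness_centrality(g), oracle$C_B, tolerance = 1e-12)
    expect_equal(closeness_centrality(g), oracle$C_C, tolerance = 1e-12)
  }
})

test_that("centralities agree with igraph on random graphs", {
  for (seed in c(3, 14)) {
    K <- 11
    ed <- random_graph(K, 0.35, seed = seed)
    g <- graph_obj(K, ed)
    ig <- igraph::graph_from_edgelist(as.matrix(ed), directed = FALSE)
    ig <- igraph::add_vertices(ig, K - igraph::vcount(ig))
    expect_equal(betweenness_centrality(g),
                 igraph::betweenness(ig, normalized = TRUE), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(degree_centrality(g), igraph::degree(ig), ignore_attr = TRUE)
  }
})

test_that("centralities are invariant under node relabelling", {
  K <- 9
  ed <- random_graph(K, 0.4, seed = 5)
  g <- graph_obj(K, ed)
  perm <- c(4, 9, 1, 7, 2, 8, 3, 6, 5)
  ed2 <- data.frame(i = pmin(perm[ed$i], perm[ed$j]),
                    j = pmax(perm[ed$i], perm[ed$j]))
  g2 <- graph_obj(K, ed2)
  expect_equal(betweenness_centrality(g2)[perm], betweenness_centrality(g),
               tolerance = 1e-12)
  expect_equal(closeness_centrality(g2)[perm], closeness_centrality(g),
               tolerance = 1e-12)
})

test_that("disconnected graphs follow the documented conventions", {
  # two separate edges: betweenness 0 everywhere, closeness scaled by
  # reachable-set size (Wasserman-Faust)
  g <- graph_obj(4, data.frame(i = c(1, 3), j = c(2, 4)))
  expect_equal(betweenness_centrality(g), rep(0, 4))
  expect_equal(closeness_centrality(g), rep((1 / 3) * 1, 4))
  expect_equal(closeness_centrality(graph_obj(2, data.frame(i = 1, j = 2))),
               c(1, 1))
  # isolated node gets closeness 0
  g2 <- graph_obj(3, data.frame(i = 1, j = 2))
  expect_equal(closeness_centrality(g2)[3], 0)
})

test_that("betweenness is bounded and maximal at a star centre", {
  for (seed in 1:10) {
    K <- 8
    g <- graph_obj(K, random_graph(K, 0.4, seed = 300 + seed))
    cb <- betweenness_centrality(g)
    expect_true(all(cb >= 0 & cb <= 1 + 1e-12))
  }
  expect_equal(max(betweenness_centrality(star_graph(5))), 1)
})

test_that("centrality tables and hot-spot thresholds are inclusive", {
  s <- make_structure(synthetic_spec(10, "ideal_helix"))
  net <- build_network(s)
  ct <- centrality_table(net, state = "apo")
  expect_equal(ct$C_D, degree_centrality(net))
  expect_equal(ct$C_B, betweenness_centrality(net))

  fake <- ct
  fake$C_B <- c(0.06, 0.04, 0.05, rep(0.01, 7))
  hs <- hotspots(fake, threshold = 0.05)
  expect_setequal(hs$label, fake$label[c(1, 3)])      # 0.05 boundary included
  expect_equal(hs$C_B, sort(hs$C_B, decreasing = TRUE))
  none <- fake; none$C_B <- rep(0.01, 10)
  expect_equal(nrow(hotspots(none)), 0L)
})

test_that("state-difference reports are inclusive and outer-join residues", {
  s <- make_structure(synthetic_spec(8, "ideal_helix"))
  ct <- centrality_table(build_network(s), state = "a")
  expect_equal(nrow(delta_hotspots(ct, ct)), 0L)
  ct2 <- ct
  ct2$C_B[3] <- ct$C_B[3] + 0.03
  ct2$C_B[5] <- ct$C_B[5] + 0.02
  dr <- delta_hotspots(ct, ct2)
  expect_setequal(dr$label, ct$label[c(3, 5)])        # 0.02 boundary included
  # missing residues enter at zero with a warning
  ct3 <- ct[1:6, ]
  class(ct3) <- class(ct)
  expect_warning(dr2 <- delta_hotspots(ct, ct3), "differ in residue sets")
  expect_true(all(ct$label[7:8][ct$C_B[7:8] >= 0.02] %in% dr2$label))
})
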