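block_ensemble <- function(seed, n_res = 30, n_frames = 500,
                           rho_within = 0.9, rho_between = 0) {
  spec <- synthetic_spec(n_res, "ideal_helix", n_frames = n_frames,
                         sigma = 0.4, seed = seed,
                         blocks = list(seq_len(n_res / 2),
                                       (n_res / 2 + 1):n_res),
                         rho_within = rho_within, rho_between = rho_between)
  make_ensemble(spec, make_structure(spec))
}

test_that("cross-correlation has unit diagonal and detects rigid co-motion", {
  spec <- synthetic_spec(6, n_frames = 20, sigma = 0.3, seed = 2)
  ens <- make_ensemble(spec, make_structure(spec))
  cij <- cross_correlation(ens, fit = FALSE)
  expect_equal(diag(unclass(cij)), rep(1, 6), ignore_attr = TRUE)
  expect_true(all(abs(cij) <= 1 + 1e-12))
  expect_equal(unclass(cij), t(unclass(cij)))

  # two residues translated identically in every frame correlate at +1;
  # oppositely at -1
  spec0 <- synthetic_spec(4, n_frames = 50, sigma = 0)
  s <- make_structure(spec0)
  ens0 <- make_ensemble(spec0, s)
  set.seed(1)
  shift <- stats::rnorm(50, sd = 1)
  ridx <- s$atoms$resindex
  for (f in 1:50) {
    for (r in c(1, 2)) {
      cols <- 3 * (which(ridx == r) - 1) + 1
      ens0$xyz[f, cols] <- ens0$xyz[f, cols] + shift[f]
    }
    cols3 <- 3 * (which(ridx == 3) - 1) + 1
    ens0$xyz[f, cols3] <- ens0$xyz[f, cols3] - shift[f]
    cols4 <- 3 * (which(ridx == 4) - 1) + 2
    ens0$xyz[f, cols4] <- ens0$xyz[f, cols4] + stats::rnorm(1, sd = 0.5)
  }
  cij0 <- cross_correlation(ens0, fit = FALSE)
  expect_equal(cij0[1, 2], 1, tolerance = 1e-9)
  expect_equal(cij0[1, 3], -1, tolerance = 1e-9)
})

test_that("zero-fluctuation residues are zeroed off-diagonal with a warning", {
  spec0 <- synthetic_spec(4, n_frames = 30, sigma = 0)
  s <- make_structure(spec0)
  ens <- make_ensemble(spec0, s)
  set.seed(3)
  cols <- 3 * (which(s$atoms$resindex == 1) - 1) + 1
  for (f in 1:30) ens$xyz[f, cols] <- ens$xyz[f, cols] + stats::rnorm(1)
  expect_warning(cij <- cross_correlation(ens, fit = FALSE),
                 "zero-fluctuation")
  expect_equal(cij[2, 3], 0)
  expect_equal(diag(unclass(cij)), rep(1, 4), ignore_attr = TRUE)
})

test_that("planted block correlations are recovered within 0.1", {
  ens <- block_ensemble(seed = 6)
  cij <- unclass(cross_correlation(ens, fit = FALSE))
  w1 <- cij[1:15, 1:15][upper.tri(diag(15))]
  w2 <- cij[16:30, 16:30][upper.tri(diag(15))]
  b <- cij[1:15, 16:30]
  expect_lt(abs(mean(c(w1, w2)) - 0.9), 0.1)
  expect_lt(abs(mean(b)), 0.1)
})

test_that("correlation-network thresholding is inclusive with -log weights", {
  C <- diag(3)
  expect_equal(nrow(build_correlation_network(C, 0.5)$edges), 0L)
  C[1, 2] <- C[2, 1] <- 1
  C[1, 3] <- C[3, 1] <- 0.5
  C[2, 3] <- C[3, 2] <- -0.6
  g <- build_correlation_network(C, 0.5)
  expect_equal(nrow(g$edges), 3L)                     # 0.5 boundary included
  e12 <- g$edges[g$edges$i == 1 & g$edges$j == 2, ]
  expect_equal(e12$weight, 0)                         # |c| = 1 -> weight 0
  e23 <- g$edges[g$edges$i == 2 & g$edges$j == 3, ]
  expect_equal(e23$weight, -log(0.6), tolerance = 1e-12)
  expect_equal(e23$strength, 0.6)
  expect_error(build_correlation_network(C, 0), "cutoff")
  expect_error(build_correlation_network(C, 1), "cutoff")
})

test_that("two disconnected cliques partition with modularity one half", {
  cl <- function(off) {
    p <- t(utils::combn(4, 2))
    data.frame(i = p[, 1] + off, j = p[, 2] + off)
  }
  g <- list(K = 8, edges = rbind(cl(0), cl(4)))
  part <- detect_communities(g)
  expect_equal(part$n_communities, 2L)
  expect_equal(part$modularity, 0.5, tolerance = 1e-12)
  expect_equal(part$membership[1:4], rep(part$membership[1], 4))
  expect_equal(part$membership[5:8], rep(part$membership[5], 4))
})

test_that("a single clique stays one community and empty graphs are singletons", {
  p <- t(utils::combn(5, 2))
  one <- detect_communities(list(K = 5, edges = data.frame(i = p[, 1],
                                                           j = p[, 2])))
  expect_equal(one$n_communities, 1L)
  none <- detect_communities(list(K = 4, edges = data.frame(i = integer(),
                                                            j = integer())))
  expect_equal(none$n_communities, 4L)
  expect_equal(none$modularity, 0)
})

test_that("the returned cut is at least as modular as the trivial partition", {
  set.seed(10)
  for (seed in 1:5) {
    ed <- random_graph(10, 0.3, seed = 400 + seed)
    if (!nrow(ed)) next
    g <- list(K = 10, edges = ed)
    part <- detect_communities(g)
    q_trivial <- allomap:::modularity_q(10, ed, rep(1L, 10))
    expect_gte(part$modularity, q_trivial - 1e-12)
  }
})

test_that("girvan-newman with modularity cut matches igraph on a two-clique bridge", {
  p <- t(utils::combn(4, 2))
  edges <- rbind(data.frame(i = p[, 1], j = p[, 2]),
                 data.frame(i = p[, 1] + 4, j = p[, 2] + 4),
                 data.frame(i = 4, j = 5))
  part <- detect_communities(list(K = 8, edges = edges))
  ig <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
  ip <- igraph::cluster_edge_betweenness(ig)
  expect_equal(part$n_communities, length(unique(igraph::membership(ip))))
  expect_equal(part$modularity,
               igraph::modularity(ig, igraph::membership(ip)),
               tolerance = 1e-12)
  same <- outer(part$membership, part$membership, "==")
  same_ig <- outer(as.integer(igraph::membership(ip)),
                   as.integer(igraph::membership(ip)), "==")
  expect_equal(same, same_ig)
})

test_that("the planted two-block ensemble is recovered end to end", {
  ens <- block_ensemble(seed = 19)
  cij <- cross_correlation(ens, fit = FALSE)
  part <- detect_communities(build_correlation_network(cij, 0.5))
  expect_equal(part$n_communities, 2L)
  expect_equal(part$membership[1:15], rep(part$membership[1], 15))
  expect_equal(part$membership[16:30], rep(part$membership[16], 15))
})

test_that("community networks aggregate crossing edges", {
  # two communities joined by one weighted edge
  edges <- data.frame(i = c(1, 2, 3, 4, 2), j = c(2, 3, 1, 5, 4),
                      weight = c(1, 1, 1, 1, 0.7),
                      strength = c(1, 1, 1, 1, 0.4))
  g <- list(K = 5, edges = edges)
  part <- structure(list(membership = c(1, 1, 1, 2, 2), n_communities = 2,
                         modularity = 0, labels = NULL),
                    class = "community_partition")
  cn <- community_network(part, g)
  expect_equal(cn$communities$size, c(3L, 2L))
  expect_equal(nrow(cn$edges), 1L)
  expect_equal(cn$edges$weight, 0.7)
  expect_equal(cn$edges$strength, 0.4)
  # fully separated communities share no edges
  g2 <- list(K = 4, edges = data.frame(i = c(1, 3), j = c(2, 4)))
  part2 <- structure(list(membership = c(1, 1, 2, 2), n_communities = 2,
                          modularity = 0, labels = NULL),
                     class = "community_partition")
  expect_equal(nrow(community_network(part2, g2)$edges), 0L)
  # singleton partition: one node, no edges
  part3 <- structure(list(membership = rep(1, 4), n_communities = 1,
                          modularity = 0, labels = NULL),
                     class = "community_partition")
  cn3 <- community_network(part3, g2)
  expect_equal(nrow(cn3$communities), 1L)
  expect_equal(nrow(cn3$edges), 0L)
})

test_that("rigid collective motion yields all-one correlations", {
  spec0 <- synthetic_spec(5, n_frames = 40, sigma = 0)
  s <- make_structure(spec0)
  ens <- make_ensemble(spec0, s)
  set.seed(12)
  for (f in 1:40) {
    d <- stats::rnorm(3)
    ens$xyz[f, ] <- ens$xyz[f, ] + rep(d, ncol(ens$xyz) / 3)
  }
  cij <- cross_correlation(ens, fit = FALSE)
  expect_equal(unclass(cij), matrix(1, 5, 5), tolerance = 1e-9,
               ignore_attr = TRUE)
})
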