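test_that("signed modularity matches the direct-summation oracle", {
  # all-positive graph, one module, gamma 1: exact zero
  W <- two_cliques(3)
  g <- signed_graph(W)
  expect_equal(modularity_q(g, rep(1, 6)), 0, tolerance = 1e-12)

  # planted two-module split on disconnected cliques equals the oracle
  memb <- rep(1:2, each = 3)
  expect_equal(modularity_q(g, memb), q_oracle(W, memb), tolerance = 1e-12)

  # arbitrary partitions on random signed graphs
  for (s in 1:10) {
    W2 <- random_signed_graph(6, seed = s)
    g2 <- signed_graph(W2)
    memb2 <- sample(1:3, 6, replace = TRUE)
    expect_equal(modularity_q(g2, memb2), q_oracle(W2, memb2),
                 tolerance = 1e-12)
    # gamma enters the null term
    g2g <- signed_graph(W2, gamma = 1.7)
    expect_equal(modularity_q(g2g, memb2), q_oracle(W2, memb2, gamma = 1.7),
                 tolerance = 1e-12)
    # label permutation invariance
    expect_equal(modularity_q(g2, memb2), modularity_q(g2, 4 - memb2),
                 tolerance = 1e-12)
  }
  expect_error(signed_graph(matrix(0, 3, 3)),
               class = "ccflow_degenerate_input")
})

test_that("consensus Louvain recovers planted structure deterministically", {
  W <- two_cliques(4)
  g <- signed_graph(W)
  for (s in 1:5) {
    p <- louvain_consensus(g, n_runs = 20, seed = s)
    expect_equal(p$n_modules, 2)
    expect_equal(length(unique(p$membership[1:4])), 1)
    expect_equal(length(unique(p$membership[5:8])), 1)
  }
  # determinism: same seed, same partition and Q
  p1 <- louvain_consensus(g, n_runs = 15, seed = 42)
  p2 <- louvain_consensus(g, n_runs = 15, seed = 42)
  expect_identical(p1$membership, p2$membership)
  expect_identical(p1$q, p2$q)
  expect_error(louvain_consensus(g, n_runs = 0),
               class = "ccflow_invalid_argument")
})

test_that("consensus never scores below trivial baselines and matches igraph
           on an all-positive graph", {
  for (s in 1:8) {
    W <- random_signed_graph(7, seed = 100 + s)
    g <- signed_graph(W)
    p <- louvain_consensus(g, n_runs = 30, seed = s)
    expect_gte(p$q, modularity_q(g, seq_len(7)) - 1e-12)   # singletons
    expect_gte(p$q, modularity_q(g, rep(1, 7)) - 1e-12)    # one module
  }
  skip_if_not_installed("igraph")
  W <- two_cliques(5, weight = 2)
  p <- louvain_consensus(signed_graph(W), n_runs = 20, seed = 1)
  ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE)
  cl <- igraph::cluster_louvain(ig)
  expect_equal(length(unique(p$membership)), length(unique(cl$membership)))
  expect_equal(modularity_q(signed_graph(W), cl$membership), p$q,
               tolerance = 1e-9)
})

test_that("gamma stability is 1 for planted cliques and bounded in general", {
  W <- two_cliques(4)
  g <- signed_graph(W)
  gs <- gamma_stability(g, gammas = c(0.5, 0.8, 1.1), n_runs = 8, seed = 2)
  expect_true(all(gs$stability >= -1 & gs$stability <= 1))
  expect_true(all(abs(gs$stability - 1) < 1e-12))
  expect_true(attr(gs, "best_gamma") %in% gs$gamma)
  expect_error(gamma_stability(g, gammas = 1),
               class = "ccflow_invalid_argument")
})

test_that("participation coefficient matches its closed forms", {
  # all links within own module: PC = 0
  W <- two_cliques(3)
  pc <- participation_coefficient(signed_graph(W), rep(1:2, each = 3))
  expect_equal(unname(pc), rep(0, 6))

  # node with equal strength to exactly 2 modules: PC = 0.5
  W2 <- matrix(0, 5, 5)
  W2[1, 2] <- W2[2, 1] <- 1
  W2[1, 4] <- W2[4, 1] <- 1
  W2[2, 3] <- W2[3, 2] <- 0.5
  W2[4, 5] <- W2[5, 4] <- 0.5
  pc2 <- participation_coefficient(signed_graph(W2), c(3, 1, 1, 2, 2))
  expect_equal(unname(pc2[1]), 0.5)

  # uniform over m modules: PC = 1 - 1/m, approaching 1
  for (m in c(2, 4, 8)) {
    Wm <- matrix(0, m + 1, m + 1)
    Wm[1, 2:(m + 1)] <- Wm[2:(m + 1), 1] <- 1
    pcm <- participation_coefficient(signed_graph(Wm), c(m + 1, seq_len(m)))
    expect_equal(unname(pcm[1]), 1 - 1 / m, tolerance = 1e-12)
  }

  # negative connections discarded; zero positive strength gives PC 0
  W3 <- matrix(0, 4, 4)
  W3[1, 2] <- W3[2, 1] <- -1
  W3[3, 4] <- W3[4, 3] <- 1
  pc3 <- participation_coefficient(signed_graph(W3), c(1, 2, 1, 2))
  expect_equal(unname(pc3[1]), 0)
  # label permutation invariance
  pc3b <- participation_coefficient(signed_graph(W3), c(2, 1, 2, 1))
  expect_equal(pc3, pc3b)
})

test_that("PC task comparison computes F, BH rejections and the dual map r", {
  # identical PC across conditions: F = 0
  m <- matrix(0.5, 6, 3, dimnames = list(NULL, c("balance", "calculation",
                                                 "dual")))
  r <- compare_pc_across_tasks(m)
  expect_equal(r$anova$F, 0)
  expect_equal(r$anova$df1, 2)
  expect_equal(r$anova$df2, 15)  # 3n - 3 with n = 6

  # BH step-up on {0.01, 0.02, 0.04, 0.5} at q = 0.05: thresholds k/4 * 0.05
  # are 0.0125/0.025/0.0375/0.05, so the largest k with p_(k) <= threshold is
  # 2 and exactly the first two are rejected
  padj <- p.adjust(c(0.01, 0.02, 0.04, 0.5), method = "BH")
  expect_identical(padj < 0.05, c(TRUE, TRUE, FALSE, FALSE))

  # planted ordering recovered in group means
  set.seed(6)
  base <- matrix(rnorm(10 * 3, 0, 0.01), 10, 3)
  pcm <- sweep(base, 2, c(0.3, 0.5, 0.4), "+")
  colnames(pcm) <- c("balance", "calculation", "dual")
  r2 <- compare_pc_across_tasks(pcm)
  expect_true(all(diff(r2$group_means[c("balance", "dual",
                                        "calculation")]) > 0))
  expect_lt(r2$anova$p, 0.01)
  expect_error(compare_pc_across_tasks(pcm[, 1:2]),
               class = "ccflow_invalid_argument")
})

test_that("exhaustive enumeration confirms consensus optimality on tiny
           graphs", {
  # a reduced in-suite version of the broader optimality property
  set.seed(31)
  for (k in 1:8) {
    n <- sample(5:6, 1)
    W <- random_signed_graph(n, seed = 300 + k)
    parts <- all_partitions(n)
    qmax <- max(vapply(parts, function(p) q_oracle(W, p), 0))
    p <- louvain_consensus(signed_graph(W), n_runs = 60, seed = k)
    expect_equal(p$q, qmax, tolerance = 1e-10)
  }
})
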