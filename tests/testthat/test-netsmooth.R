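two_node_A <- function() {
  adj <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  degree_normalize(adj)
}

test_that("degree normalization yields a column-stochastic operator", {
  A <- two_node_A()
  expect_equal(unname(A), matrix(c(0, 1, 1, 0), 2, 2))
  tri <- matrix(1, 3, 3) - diag(3)
  dimnames(tri) <- list(letters[1:3], letters[1:3])
  At <- degree_normalize(tri)
  expect_equal(unique(At[At > 0]), 0.5)
  expect_equal(unname(colSums(At)), rep(1, 3))
  iso <- rbind(cbind(tri, 0), 0)
  dimnames(iso) <- list(letters[1:4], letters[1:4])
  expect_warning(Ai <- degree_normalize(iso), "isolated")
  expect_equal(unname(Ai[, 4]), rep(0, 4))
  expect_error(degree_normalize(-tri), "non-negative")
  asym <- tri; asym[1, 2] <- 2
  expect_error(degree_normalize(asym), "symmetric")
})

test_that("the two-node walk converges to its hand-derived fixed point", {
  A <- two_node_A()
  F0 <- matrix(c(1, 0), 2, 1)
  expect_equal(smooth_closed(F0, A, 0.5), matrix(c(2 / 3, 1 / 3), 2, 1),
               tolerance = 1e-12, ignore_attr = TRUE)
  it <- smooth_iterative(F0, A, smoothing_config(0.5, tol = 1e-14,
                                                 max_iter = 10000))
  expect_equal(it, matrix(c(2 / 3, 1 / 3), 2, 1), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("alpha = 0 is the restart-only identity", {
  A <- two_node_A()
  F0 <- matrix(rnorm(4), 2, 2)
  expect_equal(smooth_closed(F0, A, 0), F0)
  expect_equal(smooth_iterative(F0, A, smoothing_config(0)), F0)
  expect_error(smooth_closed(F0, A, 1), "alpha")
})

random_graph <- function(n, seed) {
  set.seed(seed)
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.3)
  adj <- adj + t(adj)
  # ensure no isolated nodes for mass-conservation checks
  for (i in which(rowSums(adj) == 0)) {
    j <- if (i == 1) 2 else 1
    adj[i, j] <- adj[j, i] <- 1
  }
  dimnames(adj) <- list(paste0("g", 1:n), paste0("g", 1:n))
  adj
}

test_that("iterative and closed-form solutions agree, conserve mass and stay non-negative", {
  worst <- 0
  for (seed in 1:20) {
    n <- sample(5:30, 1)
    adj <- random_graph(n, seed)
    A <- degree_normalize(adj)
    F0 <- matrix(runif(n * 3), n, 3)
    alpha <- sample(c(0.1, 0.5, 0.7, 0.9), 1)
    cf <- smooth_closed(F0, A, alpha)
    it <- smooth_iterative(F0, A, smoothing_config(alpha, tol = 1e-12,
                                                   max_iter = 50000))
    worst <- max(worst, max(abs(cf - it)))
    expect_true(all(cf >= -1e-12))
    expect_equal(colSums(cf), colSums(F0), tolerance = 1e-10)
  }
  expect_lt(worst, 1e-8)
})

test_that("a 1,000-step brute-force iteration matches the solver", {
  adj <- random_graph(12, 99)
  A <- degree_normalize(adj)
  F0 <- matrix(runif(12), 12, 1)
  Ft <- F0
  for (i in 1:1000) Ft <- 0.6 * A %*% Ft + 0.4 * F0   # oracle by definition
  expect_equal(smooth_closed(F0, A, 0.6), Ft, tolerance = 1e-10)
})

test_that("the per-step residual is non-increasing", {
  adj <- random_graph(15, 5)
  A <- degree_normalize(adj)
  set.seed(2)
  F0 <- matrix(runif(15), 15, 1)
  alpha <- 0.8
  Ft <- F0
  res <- numeric(30)
  for (i in 1:30) {
    Fn <- alpha * A %*% Ft + (1 - alpha) * F0
    res[i] <- max(abs(Fn - Ft))
    Ft <- Fn
  }
  expect_true(all(diff(res) <= 1e-12))
})

test_that("genes absent from the network pass through unchanged", {
  adj <- random_graph(6, 3)
  g <- suppressWarnings(ppi_graph(adj))
  vals <- matrix(runif(8 * 4), 8, 4,
                 dimnames = list(c(paste0("g", 1:6), "x1", "x2"),
                                 paste0("s", 1:4)))
  x <- omics_matrix(vals, "expression")
  sm <- netsmooth(x, g, smoothing_config(0.5))
  expect_identical(sort(sm$passthrough_genes), c("x1", "x2"))
  expect_equal(unclass(sm$smoothed)[c("x1", "x2"), ], vals[c("x1", "x2"), ])
  expect_identical(rownames(sm$smoothed), rownames(vals))
  disjoint <- omics_matrix(matrix(1, 2, 2,
                                  dimnames = list(c("zz1", "zz2"),
                                                  c("s1", "s2"))),
                           "expression")
  expect_error(netsmooth(disjoint, g), "namespace")
})

test_that("smoothed binary mutations keep the mutation modality", {
  adj <- random_graph(5, 8)
  g <- suppressWarnings(ppi_graph(adj))
  mv <- matrix(rbinom(5 * 3, 1, 0.4), 5, 3,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  sm <- netsmooth(omics_matrix(mv, "mutation"), g)
  expect_identical(modality(sm$smoothed), "mutation")
  expect_true(all(unclass(sm$smoothed) >= 0))
})

test_that("one-standard-error alpha selection prefers less smoothing", {
  expect_equal(select_alpha(c(0.1, 0.5, 0.7), c(0.50, 0.70, 0.71),
                            c(0.01, 0.01, 0.02)), 0.5)
  expect_equal(select_alpha(c(0.2, 0.5, 0.8), rep(0.6, 3), rep(0.01, 3)), 0.2)
  expect_equal(select_alpha(0.7, 0.9, 0.1), 0.7)
  expect_error(select_alpha(numeric(), numeric(), numeric()), "empty")
})

test_that("true-network smoothing beats a degree-matched shuffled network at ranking module genes", {
  skip_if_not_installed("igraph")
  diffs <- vapply(1:20, function(seed) {
    g <- generate_ppi(60, n_modules = 4, p_in = 0.4, p_out = 0.02,
                      seed = seed)
    F0 <- plant_module_mutations(g, module = 1L, n_samples = 40,
                                 rate_in = 0.15, rate_out = 0.02,
                                 seed = seed + 100)
    in_mod <- g$modules == 1L
    score_with <- function(adj) {
      A <- suppressWarnings(degree_normalize(adj))
      rowMeans(smooth_closed(F0, A, 0.7))
    }
    auc_true <- roc_auc(score_with(g$adjacency), in_mod)
    ig <- igraph::graph_from_adjacency_matrix(g$adjacency, "undirected")
    set.seed(seed)
    shuf <- igraph::rewire(ig, igraph::keeping_degseq(niter = 2000))
    adj_s <- as.matrix(igraph::as_adjacency_matrix(shuf))
    dimnames(adj_s) <- dimnames(g$adjacency)
    auc_true - roc_auc(score_with(adj_s), in_mod)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.7)
})
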