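test_that("k-means on separated clouds recovers the planted partition", {
  set.seed(1)
  Z <- rbind(matrix(rnorm(100, 0, 0.2), 50, 2),
             matrix(rnorm(100, 20, 0.2), 50, 2))
  rownames(Z) <- paste0("s", 1:100)
  truth <- rep(0:1, each = 50)
  cl <- kmeans_cluster(Z, 2, n_init = 20, seed = 3)
  expect_equal(ami(cl$labels, truth), 1.0)
  expect_setequal(unique(cl$labels), 0:1)
  # K = 1: single label, WCSS equals total sum of squares
  k1 <- kmeans_cluster(Z, 1, n_init = 1, seed = 3)
  expect_equal(unique(k1$labels), 0L)
  expect_equal(k1$wcss, sum(scale(Z, scale = FALSE)^2))
  # determinism
  expect_identical(kmeans_cluster(Z, 2, n_init = 20, seed = 3)$labels,
                   cl$labels)
  expect_error(kmeans_cluster(Z, 0), "K must")
  # more restarts can only improve (never worsen) the best WCSS
  set.seed(8)
  Zh <- matrix(rnorm(240), 80, 3)
  rownames(Zh) <- paste0("h", 1:80)
  expect_lte(kmeans_cluster(Zh, 5, n_init = 50, seed = 11)$wcss,
             kmeans_cluster(Zh, 5, n_init = 1, seed = 11)$wcss + 1e-9)
})

test_that("adjusted mutual information is chance-corrected and symmetric", {
  a <- c(0, 0, 0, 1, 1, 1, 2, 2, 2, 0, 1, 2, 0, 1)
  b <- c(1, 1, 0, 0, 2, 2, 2, 2, 1, 0, 0, 2, 1, 0)
  # frozen oracle value computed with scikit-learn's AMI (arithmetic mean)
  expect_equal(ami(a, b), 0.28881702549, tolerance = 1e-9)
  expect_equal(ami(a, a), 1.0)
  # invariance to relabeling
  expect_equal(ami(c(0, 0, 1, 1, 2, 2), c(2, 2, 0, 0, 1, 1)), 1.0)
  expect_equal(ami(a, b), ami(b, a))
  expect_error(ami(a, b[-1]), "equal length")
})

test_that("ROC area follows the rank convention", {
  expect_equal(roc_auc(c(0.9, 0.5, 0.1), c(1, 1, 0)), 1.0)
  expect_equal(roc_auc(c(0.1, 0.5, 0.9), c(1, 1, 0)), 0.0)
  expect_equal(roc_auc(rep(0.3, 6), rep(c(0, 1), 3)), 0.5)
  set.seed(3)
  s <- rnorm(50); y <- rbinom(50, 1, 0.4)
  expect_equal(roc_auc(s, y) + roc_auc(-s, y), 1)
  expect_error(roc_auc(s, rep(1, 50)), "both classes")
})

test_that("ROC area agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- rnorm(80); y <- rbinom(80, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(s, y), ref, tolerance = 1e-10)
})

test_that("ROC curves are anchored and macro-averaging integrates to the AUC", {
  cv <- roc_curve(c(3, 2, 1), c(1, 1, 0))
  expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[1], 0)
  expect_equal(tail(cv$fpr, 1), 1); expect_equal(tail(cv$tpr, 1), 1)
  set.seed(4)
  n <- 60
  labels <- sample(c("A", "B"), n, replace = TRUE)
  scores <- cbind(A = rnorm(n) + 3 * (labels == "A"),
                  B = rnorm(n) + 3 * (labels == "B"))
  mr <- mean_roc(scores, labels)
  expect_length(mr$grid, 101L)
  expect_equal(mr$auc, mean(mr$per_class_auc), tolerance = 0.05)
  perfect <- cbind(A = ifelse(labels == "A", 1, 0),
                   B = ifelse(labels == "B", 1, 0))
  expect_equal(mean_roc(perfect, labels)$per_class_auc,
               c(A = 1, B = 1))
})

test_that("differential expression flags the planted shift and controls nulls", {
  set.seed(12)
  n1 <- 40; n2 <- 120
  genes <- 400
  vals <- matrix(rnorm(genes * (n1 + n2)), genes,
                 dimnames = list(sprintf("g%03d", 1:genes),
                                 sprintf("s%03d", 1:(n1 + n2))))
  vals["g001", 1:n1] <- vals["g001", 1:n1] + 3      # 3-sd shift in cluster 1
  vals["g002", ] <- 5                                # zero variance
  labels <- rep(c("c1", "c2"), c(n1, n2))
  de <- differential_expression(omics_matrix(vals, "expression"), labels)
  hit <- de[de$gene == "g001" & de$cluster == "c1", ]
  expect_true(hit$de)
  expect_equal(hit$direction, 1)
  expect_true(all(de$skipped[de$gene == "g002"]))
  nulls <- de[de$cluster == "c1" & !de$gene %in% c("g001", "g002"), ]
  expect_lt(mean(nulls$p < 0.05, na.rm = TRUE), 0.12)  # ~5% raw positives
  expect_equal(sum(nulls$de), 0L)                      # none survive BH
})

test_that("the compound benchmark is the arithmetic mean of its parts", {
  bs <- compound_benchmark(1.0, 1.0, 0.001, 1.0)
  expect_equal(bs$compound, 1.5)
  expect_equal(bs$auroc, 1.0)
  expect_equal(bs$neg_log10_logrank_p, 3)
  expect_equal(compound_benchmark(0.5, 0.0, 1, 0.5)$compound, 0.25)
  expect_warning(clamped <- compound_benchmark(1, 1, 0, 1), "clamped")
  expect_true(is.finite(clamped$compound))
})

test_that("nested-CV SVM separates separable classes through a latent trainer", {
  set.seed(30)
  n_per <- 30; k <- 4
  vals <- matrix(rnorm(40 * n_per * k, sd = 0.3), 40)
  for (cl in seq_len(k)) {
    rows <- ((cl - 1) * 10 + 1):(cl * 10)
    cols <- ((cl - 1) * n_per + 1):(cl * n_per)
    vals[rows, cols] <- vals[rows, cols] + 3
  }
  dimnames(vals) <- list(sprintf("f%02d", 1:40), sprintf("s%03d", 1:(n_per * k)))
  labels <- rep(paste0("C", 1:k), each = n_per)
  res <- svm_label_cv(vals, labels, latent_trainer = pca_latent_trainer(6),
                      outer_folds = 5, inner_folds = 3,
                      C_grid = c(0.1, 1, 10), seed = 2)
  expect_gte(res$auroc, 0.99)
  expect_gt(mean(res$predicted == res$labels), 0.95)
  expect_length(res$chosen_C, 5L)
})

test_that("the latent trainer only ever sees training columns", {
  set.seed(31)
  vals <- matrix(rnorm(10 * 40), 10,
                 dimnames = list(paste0("f", 1:10), paste0("s", 1:40)))
  labels <- rep(c("A", "B"), each = 20)
  seen <- list()
  spy_trainer <- function(train_vals) {
    seen[[length(seen) + 1]] <<- colnames(train_vals)
    function(v) t(v)
  }
  res <- svm_label_cv(vals, labels, latent_trainer = spy_trainer,
                      outer_folds = 4, inner_folds = 2, C_grid = 1, seed = 7)
  expect_length(seen, 4L)
  for (cols in seen) expect_lt(length(cols), 40L)
  # every sample is held out exactly once overall
  expect_equal(sort(unique(unlist(seen))), sort(colnames(vals)))
})

test_that("the model-selection grid scores every cell deterministically", {
  gen <- small_cohort()
  stack <- scaled_stack(gen)
  surv <- generate_survival(gen$truth, beta_star = 1, seed = 71)
  labels <- paste0("C", gen$truth$clusters)
  run <- function() {
    suppressWarnings(grid_search(stack, surv, labels,
                                 hidden_grid = c(16, 32), latent_grid = c(4, 8),
                                 seed = 3, epochs = 10, batch_size = 60, K = 3,
                                 svm_outer_folds = 3, svm_inner_folds = 2,
                                 kmeans_starts = 10))
  }
  g1 <- run()
  expect_equal(nrow(g1$surface), 4L)
  expect_identical(names(g1$surface),
                   c("n_hidden", "n_latent", "auroc", "ami", "neglog10p",
                     "cindex", "compound"))
  expect_equal(nrow(g1$best), 1L)
  expect_equal(g1$best$compound, max(g1$surface$compound))
  g2 <- run()
  expect_equal(g1$surface, g2$surface)
})
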