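#' k-means clustering with many restarts
#'
#' Lloyd's algorithm from `n_init` seeded random initializations, keeping the
#' restart with the lowest within-cluster sum of squares. 1,000 restarts is
#' the convention used for the subtype clustering analyses.
#'
#' @param Z a `latent_space` or samples x dims matrix.
#' @param K number of clusters.
#' @param n_init number of random restarts.
#' @param seed RNG seed; identical seeds give identical labelings.
#' @return a `cluster_result`: list with `labels` (0-based integers, named by
#'   sample), `K`, `wcss`, `centers`, `n_init`, `seed`.
#' @export
kmeans_cluster <- function(Z, K, n_init = 1000L, seed = 1L) {
  Z <- as.matrix(Z)
  assert_that(K >= 1, "K must be >= 1")
  assert_that(K <= nrow(Z), "K exceeds the number of samples")
  assert_that(nrow(Z) > 0, "empty latent space")
  fit <- with_seed(seed, suppressWarnings(
    stats::kmeans(Z, centers = K, nstart = n_init, iter.max = 100L,
                  algorithm = "Lloyd")))
  labels <- fit$cluster - 1L
  names(labels) <- rownames(Z)
  structure(list(labels = labels, K = K, wcss = fit$tot.withinss,
                 centers = fit$centers, n_init = as.integer(n_init),
                 seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> K=%d, wcss=%.4g, sizes: %s\n", x$K, x$wcss,
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Adjusted mutual information between two labelings
#'
#' Mutual information corrected for chance agreement under the
#' permutation (hypergeometric) model and normalized by the arithmetic mean
#' of the two entropies: `(MI - E[MI]) / (mean(H(a), H(b)) - E[MI])`.
#' Identical partitions (up to relabeling) score 1; independent labelings
#' score about 0.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return adjusted mutual information.
#' @export
ami <- function(a, b) {
  assert_that(length(a) == length(b), "labelings must have equal length")
  n <- length(a)
  ct <- table(a, b)
  ai <- rowSums(ct); bj <- colSums(ct)
  pij <- ct / n
  pi_ <- ai / n; pj_ <- bj / n
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  ha <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hb <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  emi <- expected_mi(ai, bj, n)
  denom <- (ha + hb) / 2 - emi
  if (abs(denom) < 1e-12) {
    # both partitions are single clusters (or degenerate): agreement is exact
    return(if (abs(mi - emi) < 1e-12) 1 else 0)
  }
  (mi - emi) / denom
}

# Expected MI under random contingency tables with fixed margins
# (hypergeometric model).
expected_mi <- function(ai, bj, n) {
  emi <- 0
  for (i in seq_along(ai)) {
    a <- ai[i]
    for (j in seq_along(bj)) {
      b <- bj[j]
      lo <- max(1, a + b - n)
      hi <- min(a, b)
      if (hi < lo) next
      nij <- lo:hi
      w <- stats::dhyper(nij, a, n - a, b)
      emi <- emi + sum((nij / n) * log(n * nij / (a * b)) * w)
    }
  }
  emi
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: ties in scores contribute one half, so
#' constant scores give exactly 0.5.
#'
#' @param scores numeric decision scores (larger = more positive).
#' @param labels binary labels (0/1 or logical).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  assert_that(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Stepwise false/true positive rates over decreasing score thresholds,
#' anchored at (0, 0) and (1, 1).
#'
#' @inheritParams roc_auc
#' @return data frame with columns `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  assert_that(n1 > 0 && n0 > 0, "both classes must be present")
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # one point per distinct threshold
  data.frame(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1))
}

# Interpolate a step ROC onto a fixed FPR grid (max tpr at duplicated fpr).
interp_roc <- function(curve, grid) {
  agg <- tapply(curve$tpr, curve$fpr, max)
  fx <- as.numeric(names(agg)); fy <- as.numeric(agg)
  if (fx[length(fx)] < 1) { fx <- c(fx, 1); fy <- c(fy, 1) }
  stats::approx(fx, fy, xout = grid, rule = 2, ties = max)$y
}

#' Macro-averaged one-vs-rest ROC
#'
#' Each class's ROC is interpolated onto a fixed 101-point false-positive-
#' rate grid and the true-positive rates averaged; the area under this mean
#' ROC is the headline multi-class auROC.
#'
#' @param scores samples x classes matrix of decision scores.
#' @param labels factor/character class labels aligned with rows.
#' @return list with `grid` (fpr), `mean_tpr`, `per_class` (tpr matrix),
#'   `per_class_auc` and `auc` (area under the mean ROC).
#' @export
mean_roc <- function(scores, labels) {
  labels <- as.character(labels)
  classes <- colnames(scores) %||% sort(unique(labels))
  grid <- seq(0, 1, length.out = 101L)
  tprs <- sapply(classes, function(cl) {
    interp_roc(roc_curve(scores[, cl], labels == cl), grid)
  })
  aucs <- vapply(classes, function(cl)
    roc_auc(scores[, cl], labels == cl), numeric(1))
  mean_tpr <- rowMeans(tprs)
  auc <- sum(diff(grid) * (utils::head(mean_tpr, -1) + utils::tail(mean_tpr, -1)) / 2)
  list(grid = grid, mean_tpr = mean_tpr, per_class = tprs,
       per_class_auc = aucs, auc = auc)
}

# Stratified fold assignment by class label.
class_folds <- function(labels, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (lev in unique(labels)) {
      idx <- which(labels == lev)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    fold
  })
}

# One-vs-rest linear SVM decision scores for each class.
ovr_svm_scores <- function(train_x, train_y, test_x, cost) {
  classes <- sort(unique(as.character(train_y)))
  scores <- matrix(NA_real_, nrow(test_x), length(classes),
                   dimnames = list(NULL, classes))
  for (cl in classes) {
    yb <- factor(ifelse(train_y == cl, "pos", "neg"), levels = c("pos", "neg"))
    fit <- e1071::svm(train_x, yb, kernel = "linear", cost = cost,
                      scale = FALSE)
    pr <- stats::predict(fit, test_x, decision.values = TRUE)
    dvm <- attr(pr, "decision.values")
    dv <- dvm[, 1L]
    # orient so larger means more likely the positive class
    if (!startsWith(colnames(dvm)[1L], "pos")) dv <- -dv
    scores[, cl] <- dv
  }
  scores
}

#' Nested cross-validated SVM prediction of sample labels
#'
#' Two levels of cross-validation: the outer loop holds out 1/`outer_folds`
#' of the samples, fits the latent model and the one-vs-rest linear SVM on
#' the remaining samples only, and predicts the held-out part; the SVM
#' regularization parameter is chosen by an inner `inner_folds`-fold CV on
#' the outer training split (by mean one-vs-rest AUC). Out-of-sample
#' decision scores are pooled to build one ROC per class and their
#' macro-average ([mean_roc()]). The latent model is re-fitted inside every
#' outer fold, so no test-fold information reaches it.
#'
#' @param stack an `omics_stack` (scaled to \[0, 1\]) or features x samples
#'   matrix.
#' @param labels class labels per sample (samples with `NA` are excluded).
#' @param latent_trainer function(values features x samples) returning a
#'   function(values) that maps features x samples data to a samples x k
#'   latent matrix. See [pca_latent_trainer()] and [vae_latent_trainer()].
#' @param outer_folds,inner_folds CV depths (reduced with a warning when a
#'   class is too small).
#' @param C_grid SVM cost grid.
#' @param seed fold-assignment seed.
#' @return list with `scores` (pooled out-of-sample decision scores),
#'   `predicted` (argmax class per sample), `roc` (the [mean_roc()] result),
#'   `auroc` and `chosen_C` per outer fold.
#' @export
svm_label_cv <- function(stack, labels, latent_trainer = pca_latent_trainer(10L),
                         outer_folds = 10L, inner_folds = 10L,
                         C_grid = c(0.01, 0.1, 1, 10, 100), seed = 1L) {
  vals <- stack_values(stack)
  labels <- as.character(labels)
  keep <- !is.na(labels)
  vals <- vals[, keep, drop = FALSE]
  labels <- labels[keep]
  min_class <- min(table(labels))
  if (min_class < outer_folds) {
    warnf("smallest class (%d) < outer_folds (%d); reducing folds",
          min_class, outer_folds)
    outer_folds <- max(2L, min_class)
  }
  fold <- class_folds(labels, outer_folds, seed)
  n <- length(labels)
  classes <- sort(unique(labels))
  scores <- matrix(NA_real_, n, length(classes),
                   dimnames = list(colnames(vals), classes))
  chosen_C <- numeric(outer_folds)
  for (f in seq_len(outer_folds)) {
    tr <- fold != f; te <- !tr
    project <- latent_trainer(vals[, tr, drop = FALSE])
    Ztr <- project(vals[, tr, drop = FALSE])
    Zte <- project(vals[, te, drop = FALSE])
    ytr <- labels[tr]
    ifolds <- min(inner_folds, min(table(ytr)))
    if (ifolds < 2L) ifolds <- 2L
    ifold <- class_folds(ytr, ifolds, derive_seed(seed, f))
    cv_auc <- vapply(C_grid, function(C) {
      aucs <- vapply(seq_len(ifolds), function(g) {
        itr <- ifold != g; ite <- !itr
        if (length(unique(ytr[itr])) < length(classes)) return(NA_real_)
        sc <- ovr_svm_scores(Ztr[itr, , drop = FALSE], ytr[itr],
                             Ztr[ite, , drop = FALSE], C)
        mean(vapply(colnames(sc), function(cl) {
          yy <- ytr[ite] == cl
          if (all(yy) || !any(yy)) return(NA_real_)
          roc_auc(sc[, cl], yy)
        }, numeric(1)), na.rm = TRUE)
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    C_best <- C_grid[which.max(cv_auc)]
    chosen_C[f] <- C_best
    sc <- ovr_svm_scores(Ztr, ytr, Zte, C_best)
    scores[te, colnames(sc)] <- sc
  }
  if (anyNA(scores)) {
    stopf("a class was absent from some training fold; use fewer folds")
  }
  roc <- mean_roc(scores, labels)
  predicted <- classes[max.col(scores)]
  list(scores = scores, predicted = predicted, labels = labels, roc = roc,
       auroc = roc$auc, chosen_C = chosen_C)
}

#' Latent trainer factories
#'
#' `pca_latent_trainer(k)` is a fast linear baseline trainer (principal
#' components fitted on the training split); `vae_latent_trainer(config)`
#' trains the stacked VAE of [train_vae()] inside each fold. Both return a
#' closure suitable for [svm_label_cv()] / [grid_search()].
#'
#' @param k number of principal components.
#' @return a function(values) returning a projection function.
#' @export
pca_latent_trainer <- function(k = 10L) {
  function(train_vals) {
    k_use <- min(k, nrow(train_vals), ncol(train_vals) - 1L)
    pc <- stats::prcomp(t(train_vals), center = TRUE, scale. = FALSE,
                        rank. = k_use)
    function(vals) {
      sweep(t(vals), 2L, pc$center, "-") %*% pc$rotation
    }
  }
}

#' @rdname pca_latent_trainer
#' @param config a [vae_config()].
#' @export
vae_latent_trainer <- function(config = vae_config()) {
  function(train_vals) {
    fit <- train_vae(train_vals, config)
    function(vals) unclass(vae_transform(fit$model, vals))
  }
}

#' Per-cluster differential expression
#'
#' For every cluster, Welch two-sample t-tests of each gene in the cluster
#' versus all other samples, Benjamini-Hochberg adjusted across genes within
#' the cluster; genes with adjusted p below `alpha` are marked
#' differentially expressed. Genes with zero variance in both groups have no
#' defined t statistic and are skipped with a flag.
#'
#' @param expr an [omics_matrix()] (genes x samples).
#' @param cluster_labels cluster assignment per sample.
#' @param alpha adjusted-p threshold for the DE call.
#' @return data frame with columns `gene`, `cluster`, `t`, `p`, `p_adj`,
#'   `direction` (+1 up in cluster, -1 down), `de`, `skipped`.
#' @export
differential_expression <- function(expr, cluster_labels, alpha = 0.05) {
  vals <- unclass(expr)
  labels <- as.character(cluster_labels)
  assert_that(length(labels) == ncol(vals), "labels must align with samples")
  out <- list()
  for (cl in sort(unique(labels))) {
    sel <- labels == cl
    assert_that(sum(sel) >= 2 && sum(!sel) >= 2,
                "cluster %s has fewer than 2 samples on one side", cl)
    res <- apply(vals, 1L, function(v) {
      if (stats::var(v[sel]) == 0 && stats::var(v[!sel]) == 0) {
        return(c(NA_real_, NA_real_))
      }
      tt <- stats::t.test(v[sel], v[!sel])
      c(unname(tt$statistic), tt$p.value)
    })
    tab <- data.frame(gene = rownames(vals), cluster = cl,
                      t = res[1L, ], p = res[2L, ], stringsAsFactors = FALSE)
    tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
    tab$direction <- sign(tab$t)
    tab$de <- !is.na(tab$p_adj) & tab$p_adj < alpha
    tab$skipped <- is.na(tab$t)
    out[[cl]] <- tab
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Compound benchmark score
#'
#' The average of four component scores of a latent representation: the
#' auROC of supervised label prediction, the AMI of unsupervised clustering
#' against the labels, `-log10(p)` of the multivariate log-rank test for
#' differential survival between clusters, and Harrell's c-index of the Cox
#' survival model.
#'
#' @param auroc,ami_score,cindex component scores.
#' @param logrank_p log-rank p-value in (0, 1\]; exact zeros are clamped to
#'   the smallest positive double with a warning.
#' @return a `benchmark_score`: list of the components plus `compound`.
#' @export
compound_benchmark <- function(auroc, ami_score, logrank_p, cindex) {
  if (logrank_p <= 0) {
    warnf("log-rank p of 0 clamped to the smallest positive double")
    logrank_p <- .Machine$double.xmin
  }
  assert_that(logrank_p <= 1, "logrank_p must be in (0, 1]")
  neg_log10_p <- -log10(logrank_p)
  structure(list(auroc = auroc, ami = ami_score,
                 neg_log10_logrank_p = neg_log10_p, cindex = cindex,
                 compound = mean(c(auroc, ami_score, neg_log10_p, cindex))),
            class = "benchmark_score")
}

#' @export
print.benchmark_score <- function(x, ...) {
  cat(sprintf(paste0("<benchmark_score> compound=%.4f (auroc=%.3f, ami=%.3f, ",
                     "-log10p=%.3f, c=%.3f)\n"),
              x$compound, x$auroc, x$ami, x$neg_log10_logrank_p, x$cindex))
  invisible(x)
}

#' Benchmark one latent representation
#'
#' Computes the four components of [compound_benchmark()] for a given latent
#' space: nested-CV SVM auROC against `labels`, k-means AMI at `K`, the
#' multivariate log-rank p between the k-means clusters, and the
#' cross-validated c-index over clinically relevant factors (falling back to
#' all factors when none pass selection).
#'
#' @param Z samples x factors latent matrix.
#' @param labels reference subtype labels (NA allowed).
#' @param surv a [survival_table()] aligned with `Z`.
#' @param K number of clusters for the unsupervised component.
#' @param kmeans_starts restarts for [kmeans_cluster()].
#' @param svm_outer_folds,svm_inner_folds CV depths for the supervised
#'   component.
#' @param seed RNG seed.
#' @return a `benchmark_score`.
#' @export
benchmark_latent <- function(Z, labels, surv, K = 6L, kmeans_starts = 100L,
                             svm_outer_folds = 5L, svm_inner_folds = 3L,
                             seed = 1L) {
  Z <- as.matrix(Z)
  labs <- as.character(labels)
  keep <- !is.na(labs)
  svm <- svm_label_cv(t(Z), labs,
                      latent_trainer = function(tr) function(v) t(v),
                      outer_folds = svm_outer_folds,
                      inner_folds = svm_inner_folds, seed = seed)
  cl_lab <- kmeans_cluster(Z[keep, , drop = FALSE], K,
                           n_init = kmeans_starts, seed = seed)
  ami_score <- ami(cl_lab$labels, labs[keep])
  cl_all <- kmeans_cluster(Z, K, n_init = kmeans_starts, seed = seed)
  lr <- logrank_multivariate(surv, cl_all$labels)
  rel <- clinically_relevant_factors(Z, surv)
  Zrel <- if (length(rel$selected)) Z[, rel$selected, drop = FALSE] else Z
  cv <- cv_cindex(Zrel, surv, seed = seed)
  compound_benchmark(svm$auroc, ami_score, lr$p, cv$best_mean_c)
}

#' End-to-end cluster-recovery benchmark
#'
#' The package's core integration check: simulate a four-cluster multi-omics
#' cohort (400 samples; 1,000 expression + 200 mutation + 100 copy-number
#' features), scale and stack it, train the stacked VAE, cluster the latent
#' space with k-means (K = 4, 100 restarts) and score the adjusted mutual
#' information against the planted clusters. On well-separated data the AMI
#' is expected to reach at least 0.8.
#'
#' @param seed master seed for the generator, the training and the
#'   clustering.
#' @param epochs training epochs (200 keeps the run short while converging
#'   on this problem size).
#' @param n_hidden,n_latent architecture (reference defaults).
#' @return list with `ami`, `Z`, `clusters`, `truth` and the training
#'   `history`.
#' @export
recovery_benchmark <- function(seed = 1L, epochs = 200L, n_hidden = 1100L,
                               n_latent = 100L) {
  gen <- generate_multiomics(n_samples = 400L, n_clusters = 4L, k_star = 4L,
                             n_expr = 1000L, n_mut = 200L, n_cnv = 100L,
                             separation = 3, noise_sd = 0.5,
                             seed = derive_seed(seed, 1L))
  scaled <- lapply(gen$matrices, function(m) scale_features(m)$scaled)
  stack <- stack_modalities(unname(scaled))
  fit <- train_vae(stack, vae_config(n_hidden = n_hidden,
                                     n_latent = n_latent, epochs = epochs,
                                     batch_size = 100L,
                                     seed = derive_seed(seed, 2L)))
  Z <- vae_transform(fit$model, stack)
  cl <- kmeans_cluster(Z, 4L, n_init = 100L, seed = derive_seed(seed, 3L))
  list(ami = ami(cl$labels, gen$truth$clusters), Z = Z, clusters = cl,
       truth = gen$truth, history = fit$history)
}

#' Model-selection grid over (n_hidden, n_latent)
#'
#' Trains one VAE per grid cell on the same stacked input, computes the
#' compound benchmark for each, and returns the full score surface plus the
#' argmax configuration. Cells whose training fails are recorded and scored
#' as missing.
#'
#' @param stack scaled `omics_stack`.
#' @param surv a [survival_table()] aligned with the stack's samples.
#' @param labels reference labels per sample (NA allowed).
#' @param hidden_grid,latent_grid integer grids.
#' @param seed master seed (training and benchmarking are derived from it).
#' @param epochs,batch_size training schedule applied to every cell.
#' @param K clusters for the unsupervised component.
#' @param ... passed to [benchmark_latent()].
#' @return list with `surface` (data frame: n_hidden, n_latent, auroc, ami,
#'   neglog10p, cindex, compound) and `best` (row of the argmax).
#' @export
grid_search <- function(stack, surv, labels, hidden_grid, latent_grid,
                        seed = 1L, epochs = 100L, batch_size = 100L, K = 6L,
                        ...) {
  assert_that(length(hidden_grid) >= 1 && length(latent_grid) >= 1,
              "grids must be non-empty")
  rows <- list()
  for (h in hidden_grid) {
    for (k in latent_grid) {
      cell <- tryCatch({
        cfg <- vae_config(n_hidden = h, n_latent = k, epochs = epochs,
                          batch_size = batch_size, seed = seed)
        fit <- train_vae(stack, cfg)
        Z <- vae_transform(fit$model, stack)
        bs <- benchmark_latent(Z, labels, surv, K = K,
                               seed = derive_seed(seed, h * 1000L + k), ...)
        data.frame(n_hidden = h, n_latent = k, auroc = bs$auroc,
                   ami = bs$ami, neglog10p = bs$neg_log10_logrank_p,
                   cindex = bs$cindex, compound = bs$compound)
      }, error = function(e) {
        warnf("grid cell (%d, %d) failed: %s", h, k, conditionMessage(e))
        data.frame(n_hidden = h, n_latent = k, auroc = NA_real_,
                   ami = NA_real_, neglog10p = NA_real_, cindex = NA_real_,
                   compound = NA_real_)
      })
      rows[[length(rows) + 1L]] <- cell
    }
  }
  surface <- do.call(rbind, rows)
  best <- surface[which.max(surface$compound), , drop = FALSE]
  list(surface = surface, best = best)
}
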