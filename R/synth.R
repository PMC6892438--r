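#' Generate a synthetic multi-omics cohort with planted structure
#'
#' Emulates the statistical shape of a multi-omics tumor cohort: samples
#' fall into clusters shared across modalities; a non-negative true latent
#' matrix `Z*` (rectified Gaussians around per-cluster centroids, matching
#' the model's non-negative latent space) drives all three modalities
#' through sparse loadings in which each factor loads on a disjoint gene
#' block. Expression and copy number are linear read-outs plus Gaussian
#' noise (copy number quantized to 0.1, mimicking segment-mean granularity);
#' mutations are Bernoulli draws through a logistic link whose intercept is
#' calibrated to the requested mean mutation rate. The generator is a pure
#' function of its parameters and seed.
#'
#' @param n_samples number of samples.
#' @param n_clusters number of planted clusters.
#' @param k_star true latent dimensionality.
#' @param n_expr,n_mut,n_cnv feature counts per modality.
#' @param separation distance scale of cluster centroids (0 = no signal).
#' @param noise_sd Gaussian noise standard deviation for expression/CNV.
#' @param mutation_base_rate target mean mutation frequency.
#' @param seed RNG seed.
#' @return list with `stack` (an unscaled `omics_stack`), `matrices` (the
#'   three `omics_matrix` objects) and `truth` (a `synthetic_truth`: `Z`,
#'   `loadings`, `clusters`, `mutation_intercept`, `params`, `seed`).
#' @export
generate_multiomics <- function(n_samples = 400L, n_clusters = 4L,
                                k_star = 4L, n_expr = 1000L, n_mut = 200L,
                                n_cnv = 100L, separation = 3,
                                noise_sd = 0.5, mutation_base_rate = 0.05,
                                seed = 1L) {
  assert_that(all(c(n_samples, n_clusters, k_star, n_expr, n_mut, n_cnv) > 0),
              "all counts must be positive")
  assert_that(separation >= 0, "`separation` must be >= 0")
  with_seed(seed, {
    sample_ids <- sprintf("s%03d", seq_len(n_samples))
    clusters <- sample.int(n_clusters, n_samples, replace = TRUE)
    # non-negative centroids with minimum pairwise distance = separation:
    # each cluster gets its own factor axis when it can, so `separation`
    # is the centroid spacing relative to the unit within-cluster spread
    centroids <- if (n_clusters <= k_star) {
      separation * diag(k_star)[seq_len(n_clusters), , drop = FALSE]
    } else {
      raw <- matrix(abs(stats::rnorm(n_clusters * k_star)), n_clusters)
      raw <- raw / sqrt(rowSums(raw^2))
      raw * (separation / max(min(stats::dist(raw)), 1e-8))
    }
    Z <- pmax(centroids[clusters, , drop = FALSE] +
                matrix(stats::rnorm(n_samples * k_star), n_samples), 0)
    rownames(Z) <- sample_ids

    W_e <- block_loadings(n_expr, k_star, signed = TRUE)
    W_c <- block_loadings(n_cnv, k_star, signed = TRUE)
    W_m <- block_loadings(n_mut, k_star, signed = FALSE)

    expr <- W_e %*% t(Z) + matrix(stats::rnorm(n_expr * n_samples,
                                               sd = noise_sd), n_expr)
    dimnames(expr) <- list(sprintf("expr_g%04d", seq_len(n_expr)), sample_ids)

    cnv <- W_c %*% t(Z) + matrix(stats::rnorm(n_cnv * n_samples,
                                              sd = noise_sd), n_cnv)
    cnv <- round(cnv * 10) / 10            # segment-mean-like 0.1 grid
    dimnames(cnv) <- list(sprintf("cnv_g%04d", seq_len(n_cnv)), sample_ids)

    eta <- W_m %*% t(Z)
    b <- calibrate_logit_intercept(eta, mutation_base_rate)
    mut <- matrix(stats::rbinom(n_mut * n_samples, 1L,
                                stats::plogis(eta + b)), n_mut)
    dimnames(mut) <- list(sprintf("mut_g%04d", seq_len(n_mut)), sample_ids)

    matrices <- list(expression = omics_matrix(expr, "expression"),
                     mutation = omics_matrix(mut, "mutation"),
                     cnv = omics_matrix(cnv, "cnv"))
    truth <- structure(list(Z = Z,
                            loadings = list(expression = W_e, mutation = W_m,
                                            cnv = W_c),
                            clusters = clusters,
                            mutation_intercept = b,
                            params = list(n_samples = n_samples,
                                          n_clusters = n_clusters,
                                          k_star = k_star, n_expr = n_expr,
                                          n_mut = n_mut, n_cnv = n_cnv,
                                          separation = separation,
                                          noise_sd = noise_sd,
                                          mutation_base_rate =
                                            mutation_base_rate),
                            centroids = centroids,
                            seed = seed),
                       class = "synthetic_truth")
    list(stack = stack_modalities(unname(matrices)), matrices = matrices,
         truth = truth)
  })
}

# Sparse loadings: factor j loads only on its own contiguous gene block.
block_loadings <- function(n_genes, k, signed = TRUE) {
  W <- matrix(0, n_genes, k)
  block <- split(seq_len(n_genes),
                 cut(seq_len(n_genes), k, labels = FALSE))
  for (j in seq_len(k)) {
    w <- stats::runif(length(block[[j]]), 0.5, 1.5)
    if (signed) w <- w * sample(c(-1, 1), length(w), replace = TRUE)
    W[block[[j]], j] <- w
  }
  W
}

calibrate_logit_intercept <- function(eta, rate) {
  f <- function(b) mean(stats::plogis(eta + b)) - rate
  stats::uniroot(f, c(-50, 50))$root
}

#' Generate proportional-hazards survival outcomes for a synthetic cohort
#'
#' Event times are exponential with hazard
#' `baseline_rate * exp(beta_star %*% z)`; censoring is independent uniform
#' on `(0, c_max)` with `c_max` calibrated so the realized censoring
#' fraction matches the request. Clinical covariates (age, sex, stage) are
#' drawn independently of risk.
#'
#' @param truth a `synthetic_truth` from [generate_multiomics()].
#' @param beta_star hazard log-coefficients on the true factors (padded with
#'   zeros up to `k_star`).
#' @param baseline_rate baseline exponential hazard (per day).
#' @param censor_fraction target fraction censored, in \[0, 1).
#' @param seed RNG seed.
#' @return a [survival_table()] with a `risk` attribute holding the true
#'   linear predictor.
#' @export
generate_survival <- function(truth, beta_star, baseline_rate = 0.001,
                              censor_fraction = 0.3, seed = 1L) {
  assert_that(censor_fraction >= 0 && censor_fraction < 1,
              "`censor_fraction` must lie in [0, 1)")
  k <- ncol(truth$Z)
  assert_that(length(beta_star) <= k, "beta_star longer than k_star")
  beta <- c(beta_star, rep(0, k - length(beta_star)))
  with_seed(seed, {
    n <- nrow(truth$Z)
    lp <- as.numeric(truth$Z %*% beta)
    T_ <- stats::rexp(n, rate = baseline_rate * exp(lp))
    if (censor_fraction == 0) {
      time <- T_; event <- rep(1L, n)
    } else {
      U <- stats::runif(n)
      frac <- function(cmax) mean(cmax * U < T_) - censor_fraction
      lo <- min(T_) / 2; hi <- max(T_) * 100
      cmax <- tryCatch(stats::uniroot(frac, c(lo, hi))$root, error = function(e) hi)
      C <- cmax * U
      event <- as.integer(T_ <= C)
      time <- pmin(T_, C)
    }
    st <- survival_table(rownames(truth$Z), pmax(time, 1e-8), event,
                         age = round(stats::rnorm(n, 65, 10)),
                         sex = stats::rbinom(n, 1L, 0.5),
                         stage = sample(1:4, n, replace = TRUE))
    attr(st, "risk") <- lp
    st
  })
}

#' Generate a stochastic-block-model PPI network
#'
#' Genes are split evenly into modules; within-module edges appear with
#' probability `p_in` and between-module edges with `p_out`. The adjacency
#' is symmetric with a zero diagonal and module membership is recorded.
#'
#' @param n_genes number of genes.
#' @param n_modules number of functional modules.
#' @param p_in,p_out edge probabilities with `p_in > p_out >= 0`.
#' @param seed RNG seed.
#' @param gene_ids optional gene names (default `ppi_g0001...`).
#' @return a [ppi_graph()] with an extra `modules` field (integer module
#'   per gene).
#' @export
generate_ppi <- function(n_genes, n_modules = 4L, p_in = 0.3, p_out = 0.01,
                         seed = 1L, gene_ids = NULL) {
  assert_that(p_in >= 0 && p_in <= 1 && p_out >= 0 && p_out <= 1,
              "probabilities must lie in [0, 1]")
  assert_that(p_in > p_out, "`p_in` must exceed `p_out`")
  if (is.null(gene_ids)) gene_ids <- sprintf("ppi_g%04d", seq_len(n_genes))
  with_seed(seed, {
    modules <- sort(rep_len(seq_len(n_modules), n_genes))  # contiguous blocks
    adj <- matrix(0, n_genes, n_genes, dimnames = list(gene_ids, gene_ids))
    same <- outer(modules, modules, "==")
    probs <- ifelse(same, p_in, p_out)
    up <- upper.tri(adj)
    adj[up] <- stats::rbinom(sum(up), 1L, probs[up])
    adj <- adj + t(adj)
    g <- suppressWarnings(ppi_graph(adj))
    g$modules <- modules
    g
  })
}

#' Plant binary mutations preferentially inside one PPI module
#'
#' Supports recovery tests of the network smoother: module genes mutate at
#' `rate_in` and all other genes at `rate_out` in every sample.
#'
#' @param graph a [generate_ppi()] result.
#' @param module module index to enrich.
#' @param n_samples number of samples.
#' @param rate_in,rate_out per-gene mutation probabilities.
#' @param seed RNG seed.
#' @return genes x samples binary matrix aligned with `graph$gene_ids`.
#' @export
plant_module_mutations <- function(graph, module = 1L, n_samples = 20L,
                                   rate_in = 0.4, rate_out = 0.02,
                                   seed = 1L) {
  with_seed(seed, {
    in_mod <- graph$modules == module
    p <- ifelse(in_mod, rate_in, rate_out)
    F0 <- matrix(stats::rbinom(length(p) * n_samples, 1L, rep(p, n_samples)),
                 length(p), n_samples,
                 dimnames = list(graph$gene_ids,
                                 sprintf("s%03d", seq_len(n_samples))))
    F0
  })
}

#' Generate pseudo-cell-lines from a synthetic cohort
#'
#' Cell lines are copies of randomly chosen tumors' true latent vectors plus
#' one shared "culture adaptation" offset of norm `culture_offset`,
#' re-decoded through the cohort's loadings. With offset 0 the lines are
#' statistically indistinguishable from tumors; with an offset much larger
#' than the cluster spread they form their own cell-line cluster.
#'
#' @param truth a `synthetic_truth` from [generate_multiomics()].
#' @param n_celllines number of lines to generate.
#' @param culture_offset Euclidean norm of the shared offset vector.
#' @param noise_sd read-out noise (defaults to the cohort's).
#' @param seed RNG seed.
#' @return list with `Z` (cell-line latent matrix, ids `cl001...`),
#'   `matrices` (expression/mutation/cnv `omics_matrix` objects),
#'   `is_cellline` (named flags), `tumor_origin` (source tumor ids) and
#'   `offset` (the shared vector).
#' @export
generate_celllines <- function(truth, n_celllines, culture_offset = 6,
                               noise_sd = NULL, seed = 1L) {
  assert_that(n_celllines >= 0, "`n_celllines` must be >= 0")
  noise_sd <- noise_sd %||% truth$params$noise_sd
  with_seed(seed, {
    k <- ncol(truth$Z)
    ids <- sprintf("cl%03d", seq_len(n_celllines))
    if (n_celllines == 0L) {
      return(list(Z = matrix(numeric(), 0L, k), matrices = NULL,
                  is_cellline = logical(), tumor_origin = character(),
                  offset = numeric(k)))
    }
    # non-negative direction: culture adaptation raises factor activities,
    # so the rectified latent space realizes the full offset norm
    dir <- abs(stats::rnorm(k))
    offset <- if (culture_offset > 0) dir / sqrt(sum(dir^2)) * culture_offset
              else numeric(k)
    origin <- sample.int(nrow(truth$Z), n_celllines, replace = TRUE)
    Zcl <- pmax(truth$Z[origin, , drop = FALSE] +
                  matrix(offset, n_celllines, k, byrow = TRUE), 0)
    rownames(Zcl) <- ids
    W <- truth$loadings
    expr <- W$expression %*% t(Zcl) +
      matrix(stats::rnorm(nrow(W$expression) * n_celllines, sd = noise_sd),
             nrow(W$expression))
    cnv <- round((W$cnv %*% t(Zcl) +
                    matrix(stats::rnorm(nrow(W$cnv) * n_celllines,
                                        sd = noise_sd), nrow(W$cnv))) * 10) / 10
    eta <- W$mutation %*% t(Zcl) + truth$mutation_intercept
    mut <- matrix(stats::rbinom(length(eta), 1L, stats::plogis(eta)),
                  nrow(eta))
    dimnames(expr) <- list(sprintf("expr_g%04d", seq_len(nrow(expr))), ids)
    dimnames(cnv) <- list(sprintf("cnv_g%04d", seq_len(nrow(cnv))), ids)
    dimnames(mut) <- list(sprintf("mut_g%04d", seq_len(nrow(mut))), ids)
    list(Z = Zcl,
         matrices = list(expression = omics_matrix(expr, "expression"),
                         mutation = omics_matrix(mut, "mutation"),
                         cnv = omics_matrix(cnv, "cnv")),
         is_cellline = stats::setNames(rep(TRUE, n_celllines), ids),
         tumor_origin = rownames(truth$Z)[origin],
         offset = offset)
  })
}
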