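#' Associate latent factors with input features
#'
#' Spearman rank correlation of every latent factor with every stacked input
#' feature, with two-sided p-values and a Benjamini-Hochberg adjustment
#' across all (factor, feature) pairs. Two significance conventions are
#' common for this table — raw `p < 0.001` for calling an association and
#' `p_adj < 0.01` for display — so both columns are returned and the
#' threshold is left to the caller. Constant factors or features have no
#' defined rank correlation and are excluded with a flag rather than
#' reported as zero.
#'
#' @param Z a `latent_space` (samples x factors).
#' @param stack an `omics_stack` (or features x samples matrix) over the same
#'   samples.
#' @param p_cut raw p-value threshold used to set the `associated` flag.
#' @return list with `table` (factor, feature, modality, rho, p, p_adj,
#'   associated) and `excluded` (constant factors/features).
#' @export
associate_factors <- function(Z, stack, p_cut = 0.001) {
  Z <- as.matrix(Z)
  vals <- stack_values(stack)
  assert_that(nrow(Z) == ncol(vals), "sample counts differ between Z and stack")
  n <- nrow(Z)
  assert_that(n >= 3, "need at least 3 samples for rank correlation")
  feats <- t(vals)                                   # samples x features
  const_f <- apply(feats, 2L, function(v) length(unique(v)) == 1L)
  const_z <- apply(Z, 2L, function(v) length(unique(v)) == 1L)
  excluded <- list(
    factors = colnames(Z)[const_z] %||% which(const_z),
    features = (if (is_omics_stack(stack)) stack$feature_ids else
      rownames(vals))[const_f])
  rz <- apply(Z[, !const_z, drop = FALSE], 2L, rank)
  rf <- apply(feats[, !const_f, drop = FALSE], 2L, rank)
  rho <- stats::cor(rz, rf)                          # Pearson on ranks
  rho <- pmin(pmax(rho, -1), 1)
  p <- spearman_p(rho, n)
  fid <- (if (is_omics_stack(stack)) stack$feature_ids else rownames(vals))
  mods <- if (is_omics_stack(stack)) stack$modality_of_row else
    rep(NA_character_, nrow(vals))
  tab <- data.frame(
    factor = rep(rownames(rho) %||% paste0("LF", seq_len(nrow(rho))),
                 times = ncol(rho)),
    feature = rep(fid[!const_f], each = nrow(rho)),
    modality = rep(mods[!const_f], each = nrow(rho)),
    rho = as.vector(rho), p = as.vector(p),
    stringsAsFactors = FALSE)
  tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  tab$associated <- tab$p < p_cut
  list(table = tab, excluded = excluded)
}

# Two-sided Spearman p via the t approximation; for very small n an exact
# permutation p is available through spearman_p_exact().
spearman_p <- function(rho, n) {
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Exact permutation p-value for Spearman's rho
#'
#' Enumerates all `n!` permutations; only sensible for `n < 10`.
#' @param x,y numeric vectors.
#' @return two-sided exact p-value.
#' @export
spearman_p_exact <- function(x, y) {
  n <- length(x)
  assert_that(n >= 3 && n < 10, "exact permutation p is for 3 <= n < 10")
  obs <- abs(stats::cor(x, y, method = "spearman"))
  perms <- all_permutations(n)
  ry <- rank(y)
  rhos <- apply(perms, 1L, function(p) stats::cor(rank(x)[p], ry))
  mean(abs(rhos) >= obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    block <- cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Select clinically relevant latent factors
#'
#' Fits one Cox proportional-hazards model per latent factor — the factor
#' plus the clinical covariates age, sex and tumor stage — with Efron ties,
#' adjusts the factor coefficients' p-values across factors by
#' Benjamini-Hochberg, and keeps factors with `p_adj < alpha`. Factors are
#' standardized (zero mean, unit variance) by default so hazard ratios are
#' per standard deviation.
#'
#' @param Z a `latent_space` or samples x factors matrix.
#' @param surv a [survival_table()] with complete age/sex/stage covariates,
#'   aligned with `Z`.
#' @param alpha adjusted-p threshold.
#' @param standardize scale factors before fitting.
#' @return list with `selected` (factor ids), `table` (factor, beta, se,
#'   lower, upper, p, p_adj) and `fits` (per-factor `cox_fit` objects for
#'   the selected factors).
#' @export
clinically_relevant_factors <- function(Z, surv, alpha = 0.05,
                                        standardize = TRUE) {
  Z <- as.matrix(Z)
  assert_that(nrow(Z) == nrow(surv), "Z and survival table must align")
  assert_that(sum(surv$event) >= 1, "no events in the data")
  covs <- c("age", "sex", "stage")
  have <- covs[covs %in% names(surv)]
  ids <- colnames(Z) %||% paste0("LF", seq_len(ncol(Z)))
  rows <- vector("list", ncol(Z))
  fits <- list()
  for (j in seq_len(ncol(Z))) {
    z <- Z[, j]
    if (stats::var(z) == 0) {
      rows[[j]] <- data.frame(factor = ids[j], beta = NA_real_, se = NA_real_,
                              lower = NA_real_, upper = NA_real_, p = NA_real_)
      next
    }
    if (standardize) z <- as.numeric(scale(z))
    X <- cbind(factor = z,
               as.matrix(as.data.frame(surv)[, have, drop = FALSE]))
    fit <- cox_fit(X, surv)
    fits[[ids[j]]] <- fit
    fr <- fit$coefficients[1L, ]
    rows[[j]] <- data.frame(factor = ids[j], beta = fr$beta, se = fr$se,
                            lower = fr$lower, upper = fr$upper, p = fr$p)
  }
  tab <- do.call(rbind, rows)
  tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  selected <- tab$factor[!is.na(tab$p_adj) & tab$p_adj < alpha]
  list(selected = selected, table = tab, fits = fits[selected])
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then member genes.
#' @param path path to a .gmt file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1))
  sets
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of observing
#' at least the seen overlap between the query list and the set, drawing
#' `length(gene_list)` genes from the universe without replacement;
#' Benjamini-Hochberg adjustment across sets. Gene sets are intersected with
#' the universe first; sets disjoint from the universe are skipped with a
#' warning.
#'
#' @param gene_list character vector of query genes (must be a subset of
#'   `universe`).
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of all assayed genes.
#' @return data frame with columns `set`, `overlap`, `set_size`,
#'   `list_size`, `universe_size`, `p`, `p_adj`.
#' @export
hypergeometric_ora <- function(gene_list, gene_sets, universe) {
  universe <- unique(universe)
  assert_that(length(universe) > 0, "empty universe")
  gene_list <- unique(gene_list)
  extra <- setdiff(gene_list, universe)
  assert_that(length(extra) == 0, "gene list contains genes outside the universe: %s",
              paste(utils::head(extra, 5L), collapse = ", "))
  if (length(gene_list) == 0L) {
    warnf("empty gene list; returning an empty table")
    return(data.frame(set = character(), overlap = integer(),
                      set_size = integer(), list_size = integer(),
                      universe_size = integer(), p = numeric(),
                      p_adj = numeric()))
  }
  N <- length(universe); n <- length(gene_list)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    if (length(set) == 0L) {
      warnf("gene set '%s' is disjoint from the universe; skipped", nm)
      return(NULL)
    }
    k <- length(intersect(gene_list, set))
    K <- length(set)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, list_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(), overlap = integer(),
                      set_size = integer(), list_size = integer(),
                      universe_size = integer(), p = numeric(),
                      p_adj = numeric()))
  }
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
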