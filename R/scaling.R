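#' Median-absolute-deviation feature selection
#'
#' Ranks features by the raw median absolute deviation (median of absolute
#' deviations from the feature median, no consistency constant) computed on
#' unscaled values, and keeps the `n_top` most variable ones. The original
#' feature order is preserved within the selection; ties at the selection
#' boundary are broken lexicographically by feature id so the choice is
#' deterministic.
#'
#' @param x an [omics_matrix()].
#' @param n_top number of features to keep; must not exceed `nrow(x)`.
#' @return an `omics_matrix` with `n_top` rows.
#' @export
select_features_mad <- function(x, n_top) {
  assert_that(is.numeric(n_top) && length(n_top) == 1L && n_top > 0,
              "`n_top` must be a positive integer")
  assert_that(n_top <= nrow(x), "`n_top` (%d) exceeds feature count (%d)",
              as.integer(n_top), nrow(x))
  mads <- feature_mad(x)
  ord <- order(-mads, rownames(x))           # ties: lexicographic feature id
  keep <- sort(ord[seq_len(n_top)])          # preserve original feature order
  omics_matrix(unclass(x)[keep, , drop = FALSE], modality(x))
}

#' @rdname select_features_mad
#' @return `feature_mad()`: named numeric vector of per-feature raw MADs.
#' @export
feature_mad <- function(x) {
  apply(unclass(x), 1L, function(v) stats::median(abs(v - stats::median(v))))
}

new_scaling_model <- function(center, spread, zmin, zmax, feature_ids, modality) {
  structure(list(center = center, spread = spread, zmin = zmin, zmax = zmax,
                 feature_ids = feature_ids, modality = modality),
            class = "scaling_model")
}

fit_unit_scaler <- function(values, modality = "expression") {
  n <- ncol(values)
  center <- rowMeans(values)
  # population (denominator n) standard deviation, a documented fixed choice
  spread <- sqrt(rowMeans((values - center)^2))
  z <- (values - center) / ifelse(spread > 0, spread, 1)
  zmin <- apply(z, 1L, min)
  zmax <- apply(z, 1L, max)
  new_scaling_model(center, spread, zmin, zmax, rownames(values), modality)
}

apply_unit_scaler <- function(model, values) {
  spread <- ifelse(model$spread > 0, model$spread, 1)
  z <- (values - model$center) / spread
  rng <- model$zmax - model$zmin
  degenerate <- model$spread <= 0 | rng <= 0
  s <- (z - model$zmin) / ifelse(rng > 0, rng, 1)
  s[degenerate, ] <- 0.5
  s
}

#' Scale features to the unit interval
#'
#' Each feature is z-scored (center = mean, spread = population standard
#' deviation) and then mapped affinely to \[0, 1\] so that scaled values are
#' valid soft targets for a cross-entropy reconstruction loss. Zero-variance
#' features map to 0.5 everywhere instead of being dropped, keeping feature
#' indices aligned with network and gene-set annotations. The returned
#' `scaling_model` freezes the training statistics so new samples can be
#' mapped consistently via [apply_scaling()].
#'
#' @param x an [omics_matrix()] with at least two samples.
#' @return list with elements `scaled` (an `omics_matrix` in \[0,1\]) and
#'   `model` (a `scaling_model`).
#' @export
scale_features <- function(x) {
  assert_that(ncol(x) >= 2L, "scaling needs at least 2 samples")
  model <- fit_unit_scaler(unclass(x), modality(x))
  scaled <- apply_unit_scaler(model, unclass(x))
  list(scaled = omics_matrix(scaled, modality(x), check_binary = FALSE), model = model)
}

#' Apply a stored scaling model to new data
#'
#' @param model a `scaling_model` or `joint_scaling_model`.
#' @param x an `omics_matrix` (or plain matrix) whose features match the
#'   model's training features.
#' @param cohort for joint models, which cohort's first-step statistics to
#'   use (`"a"` or `"b"`).
#' @return scaled `omics_matrix` in \[0,1\].
#' @export
apply_scaling <- function(model, x, cohort = c("a", "b")) {
  vals <- unclass(x)
  mod <- if (inherits(x, "omics_matrix")) modality(x) else "expression"
  if (inherits(model, "joint_scaling_model")) {
    cohort <- match.arg(cohort)
    step1 <- if (cohort == "a") model$step1_a else model$step1_b
    check_features(step1$feature_ids, rownames(vals))
    z1 <- apply_unit_scaler(step1, vals)
    return(omics_matrix(apply_unit_scaler(model$step2, z1), mod, check_binary = FALSE))
  }
  check_features(model$feature_ids, rownames(vals))
  omics_matrix(apply_unit_scaler(model, vals), mod, check_binary = FALSE)
}

check_features <- function(expected, got) {
  if (!identical(expected, got)) {
    missing <- setdiff(expected, got)
    extra <- setdiff(got, expected)
    stopf("feature mismatch with scaling model%s%s",
          if (length(missing)) paste0("; missing: ",
            paste(utils::head(missing, 5L), collapse = ", ")) else "",
          if (length(extra)) paste0("; unseen: ",
            paste(utils::head(extra, 5L), collapse = ", ")) else "")
  }
}

#' Jointly scale two cohorts of the same features
#'
#' Two-step cohort harmonisation: each cohort is scaled per feature
#' individually (removing per-cohort location/scale, i.e. the gross batch
#' offset between cohorts), the scaled columns are concatenated
#' (cohort a first), and the combined matrix is scaled per feature again.
#' The returned `joint_scaling_model` stores the full two-step transform so
#' new samples of either cohort map consistently onto the joint space.
#'
#' @param cohort_a,cohort_b [omics_matrix()] objects with identical
#'   `feature_ids` (and the same modality).
#' @return list with `scaled` (combined `omics_matrix`, columns a then b) and
#'   `model` (a `joint_scaling_model`).
#' @export
joint_scale <- function(cohort_a, cohort_b) {
  if (!identical(rownames(cohort_a), rownames(cohort_b))) {
    stopf("cohorts must share identical feature ids in identical order")
  }
  a <- unclass(cohort_a); b <- unclass(cohort_b)
  s1a <- fit_unit_scaler(a, modality(cohort_a))
  s1b <- fit_unit_scaler(b, modality(cohort_b))
  za <- apply_unit_scaler(s1a, a)
  zb <- apply_unit_scaler(s1b, b)
  combined <- cbind(za, zb)
  s2 <- fit_unit_scaler(combined, modality(cohort_a))
  scaled <- apply_unit_scaler(s2, combined)
  model <- structure(list(step1_a = s1a, step1_b = s1b, step2 = s2),
                     class = c("joint_scaling_model", "scaling_model"))
  list(scaled = omics_matrix(scaled, modality(cohort_a), check_binary = FALSE),
       model = model)
}

#' Stack omics modalities into one model input
#'
#' Row-wise concatenation of per-modality matrices sharing identical sample
#' ids, in the stable order expression, mutation, cnv. The mapping from
#' stacked row to source modality is recorded so downstream interpretation can
#' attribute latent-factor associations to the right data type.
#'
#' @param matrices list of [omics_matrix()] objects with identical sample ids.
#' @return an `omics_stack`: list with `values` (stacked matrix),
#'   `feature_ids`, `modality_of_row` and `sample_ids`.
#' @export
stack_modalities <- function(matrices) {
  assert_that(length(matrices) >= 1L, "`matrices` must be a non-empty list")
  sample_ids <- colnames(matrices[[1L]])
  for (m in matrices) {
    if (!identical(colnames(m), sample_ids)) {
      stopf("all matrices must share identical sample ids in identical order")
    }
  }
  mods <- vapply(matrices, modality, character(1))
  ord <- order(match(mods, c("expression", "mutation", "cnv")))
  matrices <- matrices[ord]
  mods <- mods[ord]
  values <- do.call(rbind, lapply(matrices, unclass))
  modality_of_row <- rep(mods, vapply(matrices, nrow, integer(1)))
  structure(list(values = values,
                 feature_ids = unlist(lapply(matrices, rownames), use.names = FALSE),
                 modality_of_row = modality_of_row,
                 sample_ids = sample_ids),
            class = "omics_stack")
}

#' @export
print.omics_stack <- function(x, ...) {
  tab <- table(factor(x$modality_of_row, c("expression", "mutation", "cnv")))
  cat(sprintf("<omics_stack> %d features x %d samples (%s)\n",
              nrow(x$values), length(x$sample_ids),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @rdname stack_modalities
#' @param x an `omics_stack`.
#' @export
is_omics_stack <- function(x) inherits(x, "omics_stack")
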