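#' Survival metadata tables
#'
#' A `survival_table` is a data frame with columns `sample` (id), `time`
#' (positive, days), `event` (0 = censored, 1 = death) and the clinical
#' covariates `age` (years), `sex` (binary indicator) and `stage` (ordinal
#' integer).
#'
#' @param sample character sample ids.
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param age,sex,stage optional clinical covariates.
#' @return a `survival_table` data frame.
#' @export
survival_table <- function(sample, time, event, age = NULL, sex = NULL,
                           stage = NULL) {
  assert_that(all(time > 0), "`time` must be strictly positive")
  assert_that(all(event %in% c(0, 1)), "`event` must be 0/1")
  df <- data.frame(sample = as.character(sample), time = as.numeric(time),
                   event = as.integer(event), stringsAsFactors = FALSE)
  if (!is.null(age)) df$age <- as.numeric(age)
  if (!is.null(sex)) df$sex <- as.integer(sex)
  if (!is.null(stage)) df$stage <- as.integer(stage)
  if (anyNA(df)) stopf("survival table contains missing values")
  class(df) <- c("survival_table", "data.frame")
  df
}

#' Read a survival metadata TSV
#'
#' Columns: sample, time, event, and optionally age, sex, stage.
#' @param path file path.
#' @return a [survival_table()].
#' @export
read_survival_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  survival_table(tab$sample, tab$time, tab$event,
                 age = tab$age, sex = tab$sex, stage = tab$stage)
}

#' Fit a Cox proportional-hazards model
#'
#' Thin wrapper around [survival::coxph()] with Efron handling of tied event
#' times, returning coefficients, Wald statistics and confidence intervals in
#' a tidy structure. With `ridge_penalty > 0` all supplied covariates are
#' ridge-penalized (penalty `ridge_penalty / 2 * sum(beta^2)`).
#'
#' @param covariates numeric matrix (samples x covariates) with column names.
#' @param surv a [survival_table()] aligned row-for-row with `covariates`.
#' @param ridge_penalty non-negative ridge strength.
#' @param conf_level Wald confidence level.
#' @return a `cox_fit`: list with `coefficients` data frame (term, beta, se,
#'   lower, upper, p), `loglik` (partial log-likelihood at the estimate and
#'   at zero), `ties` and `flags`.
#' @export
cox_fit <- function(covariates, surv, ridge_penalty = 0, conf_level = 0.95) {
  covariates <- as.matrix(covariates)
  assert_that(nrow(covariates) == nrow(surv),
              "covariates and survival table must align")
  assert_that(sum(surv$event) >= 1, "no events in the data")
  const <- apply(covariates, 2L, function(v) stats::var(v) == 0)
  if (any(const)) {
    stopf("constant covariate(s): %s",
          paste(colnames(covariates)[const], collapse = ", "))
  }
  y <- survival::Surv(surv$time, surv$event)
  flags <- character()
  fit <- withCallingHandlers({
    if (ridge_penalty > 0) {
      survival::coxph(y ~ survival::ridge(covariates, theta = ridge_penalty,
                                          scale = FALSE),
                      ties = "efron")
    } else {
      survival::coxph(y ~ covariates, ties = "efron")
    }
  }, warning = function(w) {
    if (grepl("coefficient may be infinite|did not converge|beta may be infinite",
              conditionMessage(w))) {
      flags <<- c(flags, "possible_separation")
      invokeRestart("muffleWarning")
    }
  })
  beta <- unname(stats::coef(fit))
  se <- sqrt(diag(stats::vcov(fit)))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  zstat <- beta / se
  coefs <- data.frame(term = colnames(covariates), beta = beta, se = se,
                      lower = beta - zq * se, upper = beta + zq * se,
                      p = 2 * stats::pnorm(-abs(zstat)),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 loglik = c(null = fit$loglik[1L],
                            fitted = fit$loglik[length(fit$loglik)]),
                 ties = "efron", ridge_penalty = ridge_penalty,
                 flags = flags, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> efron ties, ridge=%g%s\n", x$ridge_penalty,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Harrell's concordance index
#'
#' The fraction of comparable subject pairs (the member with the shorter
#' observed time experienced the event) in which the higher predicted risk
#' accompanies the shorter survival; risk ties count one half.
#'
#' @param risk numeric risk scores (higher = worse prognosis).
#' @param surv a [survival_table()] aligned with `risk`.
#' @return concordance in \[0, 1\].
#' @export
concordance_index <- function(risk, surv) {
  assert_that(length(risk) == nrow(surv), "risk and survival must align")
  time <- surv$time; event <- surv$event
  n <- length(risk)
  conc <- 0; comp <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # comparable iff the earlier observed time is an event
      if (time[i] == time[j]) {
        if (event[i] == 1 && event[j] == 1) next  # tied event times: skip
        next
      }
      short <- if (time[i] < time[j]) i else j
      long <- if (short == i) j else i
      if (event[short] != 1) next
      comp <- comp + 1
      if (risk[short] > risk[long]) conc <- conc + 1
      else if (risk[short] == risk[long]) conc <- conc + 0.5
    }
  }
  assert_that(comp > 0, "no comparable pairs")
  conc / comp
}

#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator via [survival::survfit()], exported as one step
#' table per group. Censored subjects leave the risk set without a death
#' step, so the curve is a non-increasing right-continuous step function.
#'
#' @param surv a [survival_table()].
#' @param groups group labels aligned with `surv` (single group if omitted).
#' @return named list of data frames with columns `time`, `n_risk`,
#'   `n_event`, `surv`.
#' @export
km_estimate <- function(surv, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", nrow(surv))
  groups <- as.character(groups)
  assert_that(length(groups) == nrow(surv), "groups and survival must align")
  out <- list()
  for (g in unique(groups)) {
    sel <- groups == g
    assert_that(any(sel), "empty group %s", g)
    fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                             data = surv[sel, , drop = FALSE])
    out[[g]] <- data.frame(time = fit$time, n_risk = fit$n.risk,
                           n_event = fit$n.event, surv = fit$surv)
  }
  out
}

#' Multivariate (k-sample) log-rank test
#'
#' Tests the null hypothesis that all groups share one survival function;
#' the statistic is chi-square with `k - 1` degrees of freedom.
#'
#' @param surv a [survival_table()].
#' @param groups group labels (>= 2 distinct values).
#' @return list with `chisq`, `df`, `p`.
#' @export
logrank_multivariate <- function(surv, groups) {
  groups <- as.character(groups)
  assert_that(length(unique(groups)) >= 2L, "log-rank needs >= 2 groups")
  df_ <- data.frame(time = surv$time, event = surv$event, g = groups)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = df_)
  k <- length(sd_$n)
  list(chisq = unname(sd_$chisq), df = k - 1L,
       p = stats::pchisq(sd_$chisq, k - 1L, lower.tail = FALSE))
}

#' Event-stratified cross-validation folds
#' @noRd
stratified_folds <- function(event, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(event))
    for (lev in unique(event)) {
      idx <- which(event == lev)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    fold
  })
}

#' Cross-validated concordance of a ridge-penalized Cox model
#'
#' For each penalty in the grid, fits a ridge-penalized Cox model on the
#' training part of each of `folds` event-stratified splits and scores
#' Harrell's C on the held-out part; returns the best penalty's mean
#' out-of-fold concordance. The factor matrix should already be restricted
#' to clinically relevant factors (see [clinically_relevant_factors()]).
#'
#' @param Z samples x factors matrix of latent factor values.
#' @param surv a [survival_table()] aligned with `Z`.
#' @param penalties ridge grid; default the standard sweep
#'   `c(1, 10, 100, 1000, 10000)`.
#' @param folds number of CV folds.
#' @param seed fold-assignment seed.
#' @return list with `best_penalty`, `best_mean_c`, `per_fold` (matrix
#'   penalties x folds) and `mean_c` per penalty.
#' @export
cv_cindex <- function(Z, surv, penalties = c(1, 10, 100, 1000, 10000),
                      folds = 5L, seed = 1L) {
  Z <- as.matrix(Z)
  assert_that(nrow(Z) == nrow(surv), "Z and survival table must align")
  fold <- stratified_folds(surv$event, folds, seed)
  redraws <- 0L
  while (any(vapply(seq_len(folds), function(f)
    sum(surv$event[fold != f]) == 0, logical(1))) && redraws < 10L) {
    warnf("a fold had no training events; re-drawing stratified folds")
    redraws <- redraws + 1L
    fold <- stratified_folds(surv$event, folds, seed + redraws)
  }
  per_fold <- matrix(NA_real_, length(penalties), folds,
                     dimnames = list(as.character(penalties), NULL))
  for (pi in seq_along(penalties)) {
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      fit <- cox_fit(Z[tr, , drop = FALSE], surv[tr, , drop = FALSE],
                     ridge_penalty = penalties[pi])
      risk <- as.numeric(Z[te, , drop = FALSE] %*% fit$coefficients$beta)
      per_fold[pi, f] <- concordance_index(risk, surv[te, , drop = FALSE])
    }
  }
  mean_c <- rowMeans(per_fold)
  best <- which.max(mean_c)
  list(best_penalty = penalties[best], best_mean_c = unname(mean_c[best]),
       per_fold = per_fold, mean_c = mean_c)
}
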