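# Shared fixtures, all generated in code.

tiny_matrix <- function(n_feat = 6, n_samp = 5, modality = "expression",
                        seed = 1) {
  set.seed(seed)
  vals <- matrix(round(stats::rexp(n_feat * n_samp, 0.2), 3), n_feat, n_samp,
                 dimnames = list(sprintf("g%02d", seq_len(n_feat)),
                                 sprintf("s%02d", seq_len(n_samp))))
  omics_matrix(vals, modality)
}

# a small multi-omics cohort shared by several test files (built once)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_multiomics(n_samples = 120, n_clusters = 3,
                                    k_star = 3, n_expr = 60, n_mut = 24,
                                    n_cnv = 15, separation = 4,
                                    noise_sd = 0.5, seed = 7)
    }
    cache
  }
})

scaled_stack <- function(gen) {
  stack_modalities(unname(lapply(gen$matrices,
                                 function(m) scale_features(m)$scaled)))
}

# proportional-hazards data with a known risk covariate
simulate_ph <- function(n = 300, beta = 1, censor = 0.3, seed = 1,
                        baseline = 0.01) {
  set.seed(seed)
  x <- stats::rnorm(n)
  T_ <- stats::rexp(n, rate = baseline * exp(beta * x))
  if (censor > 0) {
    U <- stats::runif(n)
    cmax <- tryCatch(stats::uniroot(function(cm) mean(cm * U < T_) - censor,
                                    c(min(T_) / 2, max(T_) * 100))$root,
                     error = function(e) max(T_) * 100)
    C <- cmax * U
    time <- pmin(T_, C); event <- as.integer(T_ <= C)
  } else {
    time <- T_; event <- rep(1L, n)
  }
  list(x = x,
       surv = survival_table(sprintf("p%04d", seq_len(n)), pmax(time, 1e-8),
                             event,
                             age = round(stats::rnorm(n, 65, 10)),
                             sex = stats::rbinom(n, 1, 0.5),
                             stage = sample(1:4, n, replace = TRUE)))
}

# Efron partial log-likelihood for a single covariate (independent oracle,
# direct transcription of the definition)
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sum_D <- sum(exp(beta * x[D]))
    sum_R <- sum(exp(beta * x[R]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_R - l / d * sum_D)
    }
  }
  ll
}
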