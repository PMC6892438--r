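#' Configuration of the stacked variational autoencoder
#'
#' Defaults follow the reference training recipe for the multi-omics
#' integration model: one ReLU hidden layer of 1,100 units on each side of a
#' 100-dimensional latent code, 600 epochs of minibatches of 100 samples,
#' Adam at learning rate 1e-3, and a KL warm-up increment `kappa = 0.01` per
#' epoch (the KL weight beta reaches 1 at epoch 100).
#'
#' @param n_hidden hidden-layer width.
#' @param n_latent number of latent factors.
#' @param epochs training epochs.
#' @param batch_size minibatch size; shrunk with a warning when it exceeds
#'   the sample count.
#' @param kappa per-epoch increment of the KL weight beta, in (0, 1].
#' @param learning_rate Adam step size.
#' @param seed integer seed controlling weight initialization, minibatch
#'   shuffling and the reparametrization noise.
#' @return a `vae_config` list.
#' @export
vae_config <- function(n_hidden = 1100L, n_latent = 100L, epochs = 600L,
                       batch_size = 100L, kappa = 0.01, learning_rate = 1e-3,
                       seed = 42L) {
  assert_that(n_hidden >= 1 && n_latent >= 1 && epochs >= 1 && batch_size >= 1,
              "n_hidden, n_latent, epochs and batch_size must be positive")
  assert_that(kappa > 0 && kappa <= 1, "`kappa` must lie in (0, 1]")
  assert_that(learning_rate > 0, "`learning_rate` must be positive")
  if (kappa * epochs < 1) {
    warnf("kappa * epochs < 1: the KL weight never reaches 1 during training")
  }
  structure(list(n_hidden = as.integer(n_hidden), n_latent = as.integer(n_latent),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 kappa = kappa, learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "vae_config")
}

#' Closed-form KL divergence from a diagonal Gaussian to the standard normal
#'
#' `0.5 * sum(mu^2 + sigma^2 - 1 - log(sigma^2))` over latent dimensions,
#' the KL term of the evidence lower bound for a `N(mu, diag(sigma^2))`
#' posterior and `N(0, I)` prior.
#'
#' @param mu,sigma numeric vectors or samples x dimensions matrices;
#'   `sigma` must be strictly positive.
#' @return per-sample KL (scalar for vector input, vector for matrix input).
#' @export
kl_term <- function(mu, sigma) {
  if (any(sigma <= 0)) stopf("`sigma` must be strictly positive")
  v <- mu^2 + sigma^2 - 1 - log(sigma^2)
  if (is.matrix(mu)) 0.5 * rowSums(v) else 0.5 * sum(v)
}

#' Binary cross-entropy reconstruction loss
#'
#' `-sum(x * log(xhat) + (1 - x) * log(1 - xhat))` over features, with the
#' reconstruction clamped to `[eps, 1 - eps]`. Inputs scaled to the unit
#' interval act as soft targets.
#'
#' @param x targets in \[0, 1\] (vector or samples x features matrix).
#' @param xhat reconstructions in (0, 1), same shape.
#' @param eps clamp margin.
#' @return per-sample loss (scalar for vectors, vector for matrices).
#' @export
reconstruction_term <- function(x, xhat, eps = 1e-7) {
  assert_that(all(x >= 0 & x <= 1), "targets must lie in [0, 1]")
  xh <- pmin(pmax(xhat, eps), 1 - eps)
  v <- -(x * log(xh) + (1 - x) * log(1 - xh))
  if (is.matrix(x)) rowSums(v) else sum(v)
}

#' KL warm-up schedule
#'
#' The KL weight starts at 0 and grows by `kappa` per epoch until it reaches
#' 1: `beta = min(1, epoch * kappa)` for a 0-based epoch index. With the
#' default `kappa = 0.01` the weight saturates at epoch 100.
#'
#' @param epoch 0-based epoch index (vectorized).
#' @param kappa per-epoch increment.
#' @return beta in \[0, 1\].
#' @export
warmup_beta <- function(epoch, kappa) {
  assert_that(all(epoch >= 0), "`epoch` must be >= 0")
  pmin(1, epoch * kappa)
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Build an untrained stacked VAE
#'
#' Encoder: input -> dense(n_hidden) -> batch-norm -> ReLU -> (mu, log
#' sigma^2); decoder: z -> dense(n_hidden) -> batch-norm -> ReLU -> dense ->
#' sigmoid over all input features. Weights are Glorot-uniform from the
#' seeded RNG, so two builds with the same seed are identical.
#'
#' @param n_features stacked input dimension.
#' @param config a [vae_config()].
#' @return a `vae_model` (untrained).
#' @export
build_vae <- function(n_features, config = vae_config()) {
  if (n_features < config$n_latent) {
    warnf("n_features (%d) < n_latent (%d): model is over-complete",
          n_features, config$n_latent)
  }
  h <- config$n_hidden; k <- config$n_latent; d <- n_features
  params <- with_seed(config$seed, list(
    W1 = glorot(d, h), b1 = numeric(h), g1 = rep(1, h), be1 = numeric(h),
    Wmu = glorot(h, k), bmu = numeric(k),
    Wlv = glorot(h, k), blv = numeric(k),
    W2 = glorot(k, h), b2 = numeric(h), g2 = rep(1, h), be2 = numeric(h),
    W3 = glorot(h, d), b3 = numeric(d)
  ))
  running <- list(mean1 = numeric(h), var1 = rep(1, h),
                  mean2 = numeric(h), var2 = rep(1, h))
  structure(list(params = params, running = running, config = config,
                 n_features = as.integer(d), feature_ids = NULL,
                 modality_of_row = NULL, scaling = NULL, trained = FALSE),
            class = "vae_model")
}

#' @export
print.vae_model <- function(x, ...) {
  npar <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<vae_model> %d features -> %d hidden -> %d latent (%s, %s parameters)\n",
              x$n_features, x$config$n_hidden, x$config$n_latent,
              if (x$trained) "trained" else "untrained",
              format(npar, big.mark = ",")))
  invisible(x)
}

bn_eps <- 1e-5

bn_forward_train <- function(a, gamma, beta) {
  m <- colMeans(a)
  v <- colMeans(a^2) - m^2
  inv_std <- 1 / sqrt(v + bn_eps)
  xhat <- sweep(sweep(a, 2L, m, "-"), 2L, inv_std, "*")
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(y = y, xhat = xhat, inv_std = inv_std, mean = m, var = v)
}

bn_forward_eval <- function(a, gamma, beta, mean, var) {
  xhat <- sweep(sweep(a, 2L, mean, "-"), 2L, 1 / sqrt(var + bn_eps), "*")
  sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
}

bn_backward <- function(dy, cache, gamma) {
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, gamma, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  da <- sweep(sweep(dxhat, 2L, m1, "-") - sweep(cache$xhat, 2L, m2, "*"),
              2L, cache$inv_std, "*")
  list(da = da, dgamma = dgamma, dbeta = dbeta)
}

lin <- function(x, W, b) sweep(x %*% W, 2L, b, "+")

sigmoid <- function(x) 1 / (1 + exp(-x))

# Full training-mode forward + loss + gradients for one minibatch.
# X: samples x features in [0,1]; eps: samples x n_latent standard normals.
vae_loss_and_grads <- function(params, X, eps, beta) {
  m <- nrow(X)
  a1 <- lin(X, params$W1, params$b1)
  bn1 <- bn_forward_train(a1, params$g1, params$be1)
  h1 <- pmax(bn1$y, 0)
  mu <- lin(h1, params$Wmu, params$bmu)
  lv <- lin(h1, params$Wlv, params$blv)
  sig <- exp(0.5 * lv)
  z <- mu + sig * eps
  # the latent representation is non-negative by construction: the decoder
  # sees the rectified code, so training places signal in the positive range
  zr <- pmax(z, 0)
  a2 <- lin(zr, params$W2, params$b2)
  bn2 <- bn_forward_train(a2, params$g2, params$be2)
  h2 <- pmax(bn2$y, 0)
  logits <- lin(h2, params$W3, params$b3)
  xhat <- sigmoid(logits)

  rec <- mean(reconstruction_term(X, xhat))
  kl <- mean(kl_term(mu, sig))
  loss <- rec + beta * kl

  # ----- backward -----
  dlogits <- (xhat - X) / m
  gW3 <- crossprod(h2, dlogits); gb3 <- colSums(dlogits)
  dh2 <- tcrossprod(dlogits, params$W3)
  dbn2 <- dh2 * (bn2$y > 0)
  bb2 <- bn_backward(dbn2, bn2, params$g2)
  da2 <- bb2$da
  gW2 <- crossprod(zr, da2); gb2 <- colSums(da2)
  dz <- tcrossprod(da2, params$W2) * (z > 0)
  dmu <- dz + beta * mu / m
  dlv <- dz * eps * 0.5 * sig + beta * 0.5 * (exp(lv) - 1) / m
  gWmu <- crossprod(h1, dmu); gbmu <- colSums(dmu)
  gWlv <- crossprod(h1, dlv); gblv <- colSums(dlv)
  dh1 <- tcrossprod(dmu, params$Wmu) + tcrossprod(dlv, params$Wlv)
  dbn1 <- dh1 * (bn1$y > 0)
  bb1 <- bn_backward(dbn1, bn1, params$g1)
  da1 <- bb1$da
  gW1 <- crossprod(X, da1); gb1 <- colSums(da1)

  grads <- list(W1 = gW1, b1 = gb1, g1 = bb1$dgamma, be1 = bb1$dbeta,
                Wmu = gWmu, bmu = gbmu, Wlv = gWlv, blv = gblv,
                W2 = gW2, b2 = gb2, g2 = bb2$dgamma, be2 = bb2$dbeta,
                W3 = gW3, b3 = gb3)
  list(loss = loss, rec = rec, kl = kl, grads = grads,
       batch_stats = list(mean1 = bn1$mean, var1 = bn1$var,
                          mean2 = bn2$mean, var2 = bn2$var))
}

# Training-mode loss only (used by finite-difference gradient checks).
vae_loss_only <- function(params, X, eps, beta) {
  vae_loss_and_grads(params, X, eps, beta)$loss
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

stack_values <- function(stack) {
  if (is_omics_stack(stack)) stack$values else unclass(stack)
}

#' Train the stacked VAE
#'
#' Minimizes reconstruction cross-entropy plus `beta * KL`, with `beta`
#' following the per-epoch warm-up schedule of [warmup_beta()]. Minibatches
#' are reshuffled every epoch from the seeded RNG; batch-norm layers run in
#' training mode (per-minibatch statistics) and accumulate running statistics
#' for inference. The reconstruction term is summed over features and the KL
#' term over latent dimensions, both averaged over the minibatch.
#'
#' @param stack an `omics_stack` (or features x samples matrix) scaled to
#'   \[0, 1\], e.g. by [scale_features()].
#' @param config a [vae_config()].
#' @param scaling optional `scaling_model` stored with the checkpoint so new
#'   samples can be mapped identically.
#' @return list with `model` (a trained `vae_model`) and `history` (one row
#'   per epoch: `epoch`, `beta`, `loss`, `reconstruction`, `kl`).
#' @export
train_vae <- function(stack, config = vae_config(), scaling = NULL) {
  X <- t(stack_values(stack))                 # samples x features
  rng <- range(X)
  assert_that(rng[1] >= 0 && rng[2] <= 1,
              "training data must be scaled to [0, 1] (see scale_features())")
  n <- nrow(X); d <- ncol(X)
  bs <- config$batch_size
  if (bs > n) {
    warnf("batch_size (%d) > sample count (%d); shrinking", bs, n)
    bs <- n
    config$batch_size <- n
  }
  model <- build_vae(d, config)
  params <- model$params
  running <- model$running
  opt <- adam_init(params)
  momentum <- 0.9
  hist <- data.frame(epoch = seq_len(config$epochs) - 1L, beta = NA_real_,
                     loss = NA_real_, reconstruction = NA_real_, kl = NA_real_)

  with_seed(derive_seed(config$seed, 1L), {
    for (ep in seq_len(config$epochs)) {
      beta <- warmup_beta(ep - 1L, config$kappa)
      perm <- sample.int(n)
      starts <- seq(1L, n, by = bs)
      # avoid a trailing singleton batch (batch-norm needs >= 2 samples)
      if (length(starts) > 1L && n - starts[length(starts)] + 1L < 2L) {
        starts <- starts[-length(starts)]
      }
      ep_loss <- ep_rec <- ep_kl <- 0; nb <- 0L
      for (s in starts) {
        idx <- perm[s:min(s + bs - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        eps <- matrix(stats::rnorm(length(idx) * config$n_latent),
                      length(idx), config$n_latent)
        out <- vae_loss_and_grads(params, Xb, eps, beta)
        if (!is.finite(out$loss)) {
          stopf(paste0("non-finite loss at epoch %d; try a lower ",
                       "learning_rate or check input scaling"), ep - 1L)
        }
        upd <- adam_step(params, out$grads, opt, config$learning_rate)
        params <- upd$params; opt <- upd$state
        bs_ <- out$batch_stats
        running$mean1 <- momentum * running$mean1 + (1 - momentum) * bs_$mean1
        running$var1 <- momentum * running$var1 + (1 - momentum) * bs_$var1
        running$mean2 <- momentum * running$mean2 + (1 - momentum) * bs_$mean2
        running$var2 <- momentum * running$var2 + (1 - momentum) * bs_$var2
        ep_loss <- ep_loss + out$loss; ep_rec <- ep_rec + out$rec
        ep_kl <- ep_kl + out$kl; nb <- nb + 1L
      }
      hist$beta[ep] <- beta
      hist$loss[ep] <- ep_loss / nb
      hist$reconstruction[ep] <- ep_rec / nb
      hist$kl[ep] <- ep_kl / nb
    }
  })

  model$params <- params
  model$running <- running
  model$trained <- TRUE
  model$scaling <- scaling
  if (is_omics_stack(stack)) {
    model$feature_ids <- stack$feature_ids
    model$modality_of_row <- stack$modality_of_row
  } else {
    model$feature_ids <- rownames(stack_values(stack))
  }
  list(model = model, history = hist)
}

#' Map samples to the latent factor space
#'
#' Deterministic inference: latent factors are `ReLU(mu(x))` — the rectified
#' posterior means, with no sampling and batch-norm in inference mode using
#' the running statistics from training. All factor values are therefore
#' non-negative, which is what makes the factors sparse and interpretable.
#'
#' @param model a trained `vae_model`.
#' @param newdata an `omics_stack` or features x samples matrix, scaled with
#'   the same `scaling_model` as the training data, with features matching
#'   the training features.
#' @return a `latent_space`: samples x n_latent non-negative matrix with
#'   factor columns `LF1..LFk`.
#' @export
vae_transform <- function(model, newdata) {
  assert_that(inherits(model, "vae_model"), "`model` must be a vae_model")
  vals <- stack_values(newdata)
  if (!is.null(model$feature_ids) && !is.null(rownames(vals)) &&
      !is_omics_stack(newdata)) {
    if (!identical(rownames(vals), model$feature_ids)) {
      bad <- setdiff(rownames(vals), model$feature_ids)
      stopf("features do not match the training features%s",
            if (length(bad)) paste0("; unseen: ",
              paste(utils::head(bad, 5L), collapse = ", ")) else "")
    }
  }
  if (is_omics_stack(newdata) && !is.null(model$feature_ids) &&
      !identical(newdata$feature_ids, model$feature_ids)) {
    bad <- setdiff(newdata$feature_ids, model$feature_ids)
    stopf("features do not match the training features%s",
          if (length(bad)) paste0("; unseen: ",
            paste(utils::head(bad, 5L), collapse = ", ")) else "")
  }
  assert_that(nrow(vals) == model$n_features,
              "expected %d features, got %d", model$n_features, nrow(vals))
  X <- t(vals)
  p <- model$params; r <- model$running
  a1 <- lin(X, p$W1, p$b1)
  h1 <- pmax(bn_forward_eval(a1, p$g1, p$be1, r$mean1, r$var1), 0)
  mu <- lin(h1, p$Wmu, p$bmu)
  Z <- pmax(mu, 0)
  dimnames(Z) <- list(colnames(vals) %||% (if (is_omics_stack(newdata))
    newdata$sample_ids else NULL),
    paste0("LF", seq_len(ncol(Z))))
  if (is_omics_stack(newdata)) rownames(Z) <- newdata$sample_ids
  structure(Z, class = c("latent_space", "matrix", "array"))
}

#' Reconstruct inputs from latent coordinates
#'
#' Runs the decoder in inference mode; mostly useful for diagnostics.
#'
#' @param model a trained `vae_model`.
#' @param Z samples x n_latent matrix.
#' @return samples x features matrix of reconstructions in (0, 1).
#' @export
vae_decode <- function(model, Z) {
  p <- model$params; r <- model$running
  a2 <- lin(pmax(unclass(Z), 0), p$W2, p$b2)
  h2 <- pmax(bn_forward_eval(a2, p$g2, p$be2, r$mean2, r$var2), 0)
  sigmoid(lin(h2, p$W3, p$b3))
}

#' Save / load a VAE checkpoint
#'
#' The checkpoint is a single JSON file holding weights, running batch-norm
#' statistics, the configuration, feature ordering and (optionally) the
#' scaling model — everything needed to map new samples.
#'
#' @param model a trained `vae_model`.
#' @param path file path for the checkpoint.
#' @return `path` (save) or a `vae_model` (load).
#' @export
save_vae <- function(model, path) {
  payload <- list(schema = "latentomics-vae-1",
                  config = unclass(model$config),
                  n_features = model$n_features,
                  feature_ids = model$feature_ids,
                  modality_of_row = model$modality_of_row,
                  params = model$params,
                  running = model$running,
                  scaling = if (!is.null(model$scaling))
                    lapply(unclass(model$scaling), unclass) else NULL,
                  trained = model$trained)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_vae
#' @export
load_vae <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  assert_that(identical(p$schema, "latentomics-vae-1"),
              "unrecognized checkpoint schema")
  cfg <- do.call(vae_config, p$config)
  model <- build_vae(p$n_features, cfg)
  for (nm in names(model$params)) {
    stored <- p$params[[nm]]
    if (is.matrix(model$params[[nm]])) {
      stored <- matrix(as.numeric(stored), nrow(model$params[[nm]]),
                       ncol(model$params[[nm]]))
    } else {
      stored <- as.numeric(stored)
    }
    model$params[[nm]] <- stored
  }
  model$running <- lapply(p$running, as.numeric)
  model$feature_ids <- p$feature_ids
  model$modality_of_row <- p$modality_of_row
  model$trained <- isTRUE(p$trained)
  if (!is.null(p$scaling)) {
    model$scaling <- structure(p$scaling, class = "scaling_model")
  }
  model
}
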