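test_that("closed-form KL matches hand-derived values", {
  expect_equal(kl_term(0, 1), 0)
  expect_equal(kl_term(1, 1), 0.5)
  expect_equal(kl_term(0, 2), 0.5 * (4 - 1 - log(4)), tolerance = 1e-12)
  expect_equal(kl_term(matrix(c(0, 1), 2, 1), matrix(1, 2, 1)), c(0, 0.5))
  expect_error(kl_term(0, 0), "positive")
})

test_that("cross-entropy reconstruction behaves at its reference points", {
  expect_equal(reconstruction_term(0.5, 0.5), log(2), tolerance = 1e-12)
  expect_equal(reconstruction_term(1, 0.5), log(2), tolerance = 1e-12)
  # perfect-reconstruction limit (up to the clamp)
  expect_lt(reconstruction_term(1, 1), 1e-6)
  expect_lt(reconstruction_term(0, 0), 1e-6)
  expect_true(is.finite(reconstruction_term(1, 0)))  # clamped, not -Inf
  m <- matrix(c(0.5, 1), 1, 2)
  expect_equal(reconstruction_term(m, m * 0 + 0.5), 2 * log(2),
               tolerance = 1e-12)
})

test_that("the KL warm-up ramps linearly and saturates at one", {
  expect_equal(warmup_beta(0, 0.01), 0)
  expect_equal(warmup_beta(100, 0.01), 1)
  expect_equal(warmup_beta(400, 0.01), 1)
  expect_equal(warmup_beta(50, 0.01), 0.5)
  expect_equal(warmup_beta(0:3, 0.5), c(0, 0.5, 1, 1))
})

test_that("model building is seed-deterministic with the stated shapes", {
  cfg <- vae_config(n_hidden = 7, n_latent = 3, seed = 12, epochs = 10,
                    batch_size = 4, kappa = 0.2)
  m1 <- build_vae(20, cfg)
  m2 <- build_vae(20, cfg)
  expect_identical(m1$params, m2$params)
  expect_equal(dim(m1$params$W1), c(20L, 7L))
  expect_equal(dim(m1$params$Wmu), c(7L, 3L))  # mu head
  expect_equal(dim(m1$params$Wlv), c(7L, 3L))  # log-variance head
  expect_equal(dim(m1$params$W3), c(7L, 20L))
  # decoding any latent point lands strictly inside (0, 1)
  out <- vae_decode(m1, matrix(0, 2, 3))
  expect_true(all(out > 0 & out < 1))
  expect_warning(build_vae(2, cfg), "over-complete")
})

test_that("analytic gradients match finite differences through every layer", {
  set.seed(71)
  d <- 8; m <- 6; k <- 3
  model <- build_vae(d, vae_config(n_hidden = 5, n_latent = k, seed = 4,
                                   epochs = 10, batch_size = 4, kappa = 0.2))
  params <- model$params
  X <- matrix(runif(m * d), m, d)
  eps <- matrix(rnorm(m * k), m, k)
  beta <- 0.6
  out <- latentomics:::vae_loss_and_grads(params, X, eps, beta)
  h <- 1e-6
  for (nm in names(params)) {
    for (trial in 1:3) {
      idx <- sample(length(params[[nm]]), 1)
      p1 <- params; p1[[nm]][idx] <- p1[[nm]][idx] + h
      p2 <- params; p2[[nm]][idx] <- p2[[nm]][idx] - h
      num <- (latentomics:::vae_loss_only(p1, X, eps, beta) -
                latentomics:::vae_loss_only(p2, X, eps, beta)) / (2 * h)
      expect_equal(out$grads[[nm]][idx], num, tolerance = 1e-4)
    }
  }
})

tiny_training_stack <- function(seed = 7) {
  gen <- small_cohort()
  scaled_stack(gen)
}

test_that("training reduces the loss and is seed-reproducible", {
  stack <- tiny_training_stack()
  cfg <- vae_config(n_hidden = 32, n_latent = 8, epochs = 40,
                    batch_size = 40, kappa = 0.05, seed = 2)
  fit <- train_vae(stack, cfg)
  expect_lt(mean(tail(fit$history$loss, 10)),
            mean(head(fit$history$loss, 10)))
  # warm-up column: 0 at epoch 0, 1 from epoch ceil(1/kappa) onward
  expect_equal(fit$history$beta[1], 0)
  expect_true(all(fit$history$beta[fit$history$epoch >= 20] == 1))
  fit2 <- train_vae(stack, cfg)
  expect_equal(tail(fit$history$loss, 1), tail(fit2$history$loss, 1))
  expect_identical(fit$model$params$W1, fit2$model$params$W1)
  expect_warning(train_vae(stack_modalities(list(
    scale_features(tiny_matrix(10, 8, seed = 2))$scaled)),
    vae_config(n_hidden = 6, n_latent = 2, epochs = 3, batch_size = 50,
               kappa = 0.5, seed = 1)), "shrinking")
})

test_that("with the KL weight held near zero the model is a plain autoencoder", {
  stack <- tiny_training_stack()
  base <- vae_config(n_hidden = 32, n_latent = 8, epochs = 40,
                     batch_size = 40, kappa = 0.05, seed = 2)
  warm <- train_vae(stack, base)
  plain_cfg <- base; plain_cfg$kappa <- 1e-12
  plain <- suppressWarnings(train_vae(stack, plain_cfg))
  expect_lte(mean(tail(plain$history$reconstruction, 5)),
             mean(tail(warm$history$reconstruction, 5)))
})

test_that("transform is deterministic, non-negative and feature-checked", {
  stack <- tiny_training_stack()
  cfg <- vae_config(n_hidden = 32, n_latent = 8, epochs = 20,
                    batch_size = 40, kappa = 0.05, seed = 2)
  fit <- train_vae(stack, cfg)
  Z <- vae_transform(fit$model, stack)
  expect_equal(dim(Z), c(length(stack$sample_ids), 8L))
  expect_true(all(Z >= 0))
  expect_identical(colnames(Z), paste0("LF", 1:8))
  # a duplicated sample maps to an identical latent row
  dup <- cbind(stack$values, stack$values[, 1, drop = FALSE])
  colnames(dup)[ncol(dup)] <- "dup"
  rownames(dup) <- fit$model$feature_ids
  Zd <- vae_transform(fit$model, dup)
  expect_equal(unclass(Zd)[ncol(dup), ], unclass(Zd)[1, ])
  # unseen features are rejected by name
  bad <- stack$values
  rownames(bad) <- c("weird_feature", fit$model$feature_ids[-1])
  expect_error(vae_transform(fit$model, bad), "weird_feature")
})

test_that("checkpoints round-trip through disk", {
  stack <- tiny_training_stack()
  cfg <- vae_config(n_hidden = 16, n_latent = 4, epochs = 10,
                    batch_size = 40, kappa = 0.1, seed = 3)
  fit <- train_vae(stack, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_vae(fit$model, path)
  re <- load_vae(path)
  expect_equal(unclass(vae_transform(re, stack)),
               unclass(vae_transform(fit$model, stack)), tolerance = 1e-12)
})

test_that("latent spaces from two training seeds agree on cluster structure", {
  gen <- generate_multiomics(n_samples = 200, n_clusters = 4, k_star = 4,
                             n_expr = 200, n_mut = 50, n_cnv = 30,
                             separation = 3, noise_sd = 0.5, seed = 21)
  stack <- scaled_stack(gen)
  part <- lapply(c(5, 6), function(s) {
    fit <- train_vae(stack, vae_config(n_hidden = 128, n_latent = 16,
                                       epochs = 150, batch_size = 50,
                                       seed = s))
    kmeans_cluster(vae_transform(fit$model, stack), 4, n_init = 50,
                   seed = 9)$labels
  })
  expect_gte(ami(part[[1]], part[[2]]), 0.6)
})
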