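pipeline_schema <- list(
  seed = NULL, out_dir = NULL, stages = NULL,
  simulate = c("n_samples", "n_clusters", "k_star", "n_expr", "n_mut",
               "n_cnv", "separation", "noise_sd", "mutation_base_rate",
               "beta_star", "baseline_rate", "censor_fraction",
               "n_celllines", "culture_offset"),
  inputs = c("expression", "mutations", "cnv", "network", "survival"),
  smooth = c("enabled", "alpha", "tol", "max_iter"),
  vae = c("n_hidden", "n_latent", "epochs", "batch_size", "kappa",
          "learning_rate"),
  cluster = c("K", "n_init"),
  interpret = c("p_cut", "alpha"),
  celllines = c("K", "threshold")
)

#' Read and validate a pipeline configuration
#'
#' Configurations are YAML mappings with blocks `simulate` (or `inputs`),
#' `smooth`, `vae`, `cluster`, `interpret`, `celllines`, plus `seed`,
#' `out_dir` and optional `stages`. Unknown keys are rejected before any
#' computation.
#'
#' @param path YAML file path, or a list already parsed.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  unknown <- setdiff(names(cfg), names(pipeline_schema))
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  for (blk in names(cfg)) {
    allowed <- pipeline_schema[[blk]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[blk]]), allowed)
    if (length(bad)) {
      stopf("unknown key(s) in `%s`: %s", blk, paste(bad, collapse = ", "))
    }
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg
}

log_stage <- function(stage, ...) {
  message(sprintf("[latentomics] %s: %s", stage, sprintf(...)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full integration pipeline
#'
#' Wires the package end to end: simulate (or load) the per-modality
#' matrices, optionally network-smooth the mutations, scale and stack, train
#' the VAE, map samples to latent factors, interpret the factors, cluster
#' the samples with a survival read-out, and score cell lines. All stage
#' seeds derive from the single master `seed`. Artifacts are written to
#' `out_dir` along with a manifest recording the configuration hash, seed
#' and package version.
#'
#' @param config a config list or YAML path (see [read_run_config()]).
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  out_dir <- cfg$out_dir %||% stopf("config needs `out_dir`")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  stages <- cfg$stages %||% c("simulate", "smooth", "train", "transform",
                              "interpret", "cluster", "celllines")
  results <- list()

  # ---- inputs ----
  if ("simulate" %in% stages || !is.null(cfg$simulate)) {
    sp <- cfg$simulate %||% list()
    log_stage("simulate", "seed=%d", derive_seed(seed, 10L))
    gen <- do.call(generate_multiomics, c(
      sp[intersect(names(sp), c("n_samples", "n_clusters", "k_star",
                                "n_expr", "n_mut", "n_cnv", "separation",
                                "noise_sd", "mutation_base_rate"))],
      list(seed = derive_seed(seed, 10L))))
    mats <- gen$matrices
    surv <- generate_survival(gen$truth,
                              beta_star = sp$beta_star %||% 1,
                              baseline_rate = sp$baseline_rate %||% 0.001,
                              censor_fraction = sp$censor_fraction %||% 0.3,
                              seed = derive_seed(seed, 11L))
    results$truth <- gen$truth
    results$surv <- surv
    for (m in names(mats)) {
      write_omics_matrix(mats[[m]], file.path(out_dir, paste0(m, ".tsv")))
    }
    write_tsv(as.data.frame(surv), file.path(out_dir, "survival.tsv"))
  } else {
    inp <- cfg$inputs %||% stopf("config needs `simulate` or `inputs`")
    log_stage("load", "reading matrices")
    mats <- list(
      expression = read_omics_matrix(inp$expression, "expression"),
      mutation = read_omics_matrix(inp$mutations, "mutation"),
      cnv = read_omics_matrix(inp$cnv, "cnv"))
    surv <- if (!is.null(inp$survival)) read_survival_table(inp$survival)
    results$surv <- surv
  }

  # ---- smoothing ----
  if ("smooth" %in% stages && isTRUE(cfg$smooth$enabled %||% FALSE)) {
    graph <- if (!is.null(cfg$inputs$network)) {
      read_edge_list(cfg$inputs$network)
    } else {
      generate_ppi(nrow(mats$mutation),
                   gene_ids = rownames(mats$mutation),
                   seed = derive_seed(seed, 20L))
    }
    sc <- smoothing_config(alpha = cfg$smooth$alpha %||% 0.7,
                           tol = cfg$smooth$tol %||% 1e-6,
                           max_iter = cfg$smooth$max_iter %||% 10000L)
    log_stage("smooth", "alpha=%.2f over %d genes", sc$alpha,
              nrow(mats$mutation))
    mats$mutation <- netsmooth(mats$mutation, graph, sc)$smoothed
  }

  # ---- scale + stack + train ----
  scaled <- lapply(mats, function(m) scale_features(m)$scaled)
  stack <- stack_modalities(unname(scaled))
  vp <- cfg$vae %||% list()
  vcfg <- vae_config(n_hidden = vp$n_hidden %||% 256L,
                     n_latent = vp$n_latent %||% 32L,
                     epochs = vp$epochs %||% 200L,
                     batch_size = vp$batch_size %||% 100L,
                     kappa = vp$kappa %||% 0.01,
                     learning_rate = vp$learning_rate %||% 1e-3,
                     seed = derive_seed(seed, 30L))
  log_stage("train", "%d features, %d samples, %d epochs",
            nrow(stack$values), length(stack$sample_ids), vcfg$epochs)
  fit <- train_vae(stack, vcfg)
  save_vae(fit$model, file.path(out_dir, "model.json"))
  write_tsv(fit$history, file.path(out_dir, "history.tsv"))

  Z <- vae_transform(fit$model, stack)
  results$Z <- Z
  write_tsv(data.frame(sample = rownames(Z), unclass(Z),
                       check.names = FALSE),
            file.path(out_dir, "latent.tsv"))

  # ---- interpret ----
  if ("interpret" %in% stages) {
    log_stage("interpret", "factor-feature associations")
    assoc <- associate_factors(Z, stack,
                               p_cut = cfg$interpret$p_cut %||% 0.001)
    write_tsv(assoc$table, file.path(out_dir, "associations.tsv"))
    results$associations <- assoc
    if (!is.null(results$surv)) {
      rel <- clinically_relevant_factors(Z, results$surv,
                                         alpha = cfg$interpret$alpha %||% 0.05)
      write_tsv(rel$table, file.path(out_dir, "relevant_factors.tsv"))
      results$relevant <- rel
    }
  }

  # ---- cluster + survival read-out ----
  if ("cluster" %in% stages) {
    K <- cfg$cluster$K %||% 6L
    cl <- kmeans_cluster(Z, K, n_init = cfg$cluster$n_init %||% 100L,
                         seed = derive_seed(seed, 40L))
    log_stage("cluster", "K=%d, wcss=%.3g", K, cl$wcss)
    write_tsv(data.frame(sample = names(cl$labels), cluster = cl$labels),
              file.path(out_dir, "clusters.tsv"))
    results$clusters <- cl
    if (!is.null(results$surv)) {
      lr <- logrank_multivariate(results$surv, cl$labels)
      km <- km_estimate(results$surv, cl$labels)
      km_tab <- do.call(rbind, lapply(names(km), function(g)
        cbind(group = g, km[[g]])))
      write_tsv(km_tab, file.path(out_dir, "km_curves.tsv"))
      jsonlite::write_json(lr, file.path(out_dir, "logrank.json"),
                           auto_unbox = TRUE, digits = NA)
      results$logrank <- lr
    }
  }

  # ---- cell lines ----
  if ("celllines" %in% stages && !is.null(results$truth) &&
      !is.null(cfg$simulate$n_celllines) && cfg$simulate$n_celllines > 0) {
    ncl <- cfg$simulate$n_celllines
    cls <- generate_celllines(results$truth, ncl,
                              culture_offset = cfg$simulate$culture_offset %||% 6,
                              seed = derive_seed(seed, 50L))
    scaled_cl <- Map(function(m, tr) apply_scaling(scale_features(tr)$model, m),
                     cls$matrices, mats[names(cls$matrices)])
    stack_cl <- stack_modalities(unname(scaled_cl))
    Zcl <- vae_transform(fit$model, stack_cl)
    Zall <- rbind(unclass(Z), unclass(Zcl))
    is_cl <- c(rep(FALSE, nrow(Z)), rep(TRUE, nrow(Zcl)))
    rep_ <- reject_celllines(
      neighbor_profile(Zall, is_cl, K = cfg$celllines$K %||% 5L),
      threshold = cfg$celllines$threshold %||% 0.95)
    log_stage("celllines", "%d/%d rejected", sum(rep_$rejected), nrow(rep_))
    write_tsv(rep_, file.path(out_dir, "cellline_report.tsv"))
    results$cellline_report <- rep_
  }

  # ---- manifest ----
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    package = "latentomics",
    version = as.character(utils::packageVersion("latentomics")),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    stages = stages,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(results)
}
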