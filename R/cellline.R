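#' Nearest-neighbor profile of cell lines in latent space
#'
#' For every cell line, finds its `K` nearest neighbors (Euclidean distance
#' over latent factors, self excluded, distance ties broken by sample id)
#' among all samples — tumors and cell lines alike — and reports the
#' proportion of those neighbors that are cell lines. Cell lines sitting in
#' a "cell-line cluster" (proportion near 1) resemble other cultures more
#' than tumors and are unlikely to be good tumor models.
#'
#' @param Z a `latent_space` or samples x factors matrix over tumors and
#'   cell lines, with sample ids as row names.
#' @param is_cellline logical per sample.
#' @param K number of neighbors (default 5).
#' @return a `neighbor_report` data frame: `sample`, `K`, `proportion`,
#'   `neighbors` (comma-joined ids); one row per cell line.
#' @export
neighbor_profile <- function(Z, is_cellline, K = 5L) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  assert_that(length(is_cellline) == n, "is_cellline must align with Z")
  assert_that(K >= 1 && K < n, "K must satisfy 1 <= K < sample count")
  assert_that(any(!is_cellline), "at least one tumor must be present")
  ids <- rownames(Z) %||% paste0("s", seq_len(n))
  D <- as.matrix(stats::dist(Z))
  cl_idx <- which(is_cellline)
  rows <- lapply(cl_idx, function(i) {
    d <- D[i, -i]
    other_ids <- ids[-i]
    ord <- order(d, other_ids)[seq_len(K)]
    nb <- other_ids[ord]
    prop <- mean(is_cellline[-i][ord])
    data.frame(sample = ids[i], K = K, proportion = prop,
               neighbors = paste(nb, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("neighbor_report", "data.frame")
  out
}

#' Partition cell lines into rejected and retained
#'
#' A cell line is rejected when its cell-line neighbor proportion exceeds
#' `threshold`; at the default `threshold = 0.95` and `K = 5` this is
#' exactly the rule "all five nearest neighbors are other cell lines".
#'
#' @param report a [neighbor_profile()] result.
#' @param threshold rejection threshold on the proportion.
#' @return the report with a logical `rejected` column added.
#' @export
reject_celllines <- function(report, threshold = 0.95) {
  report$rejected <- report$proportion > threshold
  report
}

#' Artificial-contamination experiment
#'
#' Repeatedly spikes a random sample of known-foreign cell lines
#' ("contaminants") into the pool of tumors and target cell lines, runs the
#' nearest-neighbor rejection, and measures the recall — the fraction of
#' contaminants rejected. Contaminants count as cell lines and as potential
#' neighbors of the target cell lines during each draw.
#'
#' @param Z_tumors,Z_target_cl,Z_contaminant_pool latent matrices (samples x
#'   factors) for tumors, the cell lines under assessment, and the pool of
#'   foreign cell lines to draw contaminants from.
#' @param n_contaminants contaminants per draw (sampled without
#'   replacement).
#' @param n_draws number of random draws.
#' @param K neighbors per sample.
#' @param threshold rejection threshold.
#' @param seed RNG seed.
#' @return list with `per_draw` (data frame: draw, recall,
#'   target_rejected_fraction), `mean_recall` and
#'   `mean_target_rejected_fraction`.
#' @export
contamination_experiment <- function(Z_tumors, Z_target_cl,
                                     Z_contaminant_pool,
                                     n_contaminants = 60L, n_draws = 100L,
                                     K = 5L, threshold = 0.95, seed = 1L) {
  assert_that(n_draws >= 1, "n_draws must be >= 1")
  assert_that(nrow(Z_contaminant_pool) >= n_contaminants,
              "contaminant pool smaller than n_contaminants")
  per_draw <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_draws), function(d) {
      pick <- sample.int(nrow(Z_contaminant_pool), n_contaminants)
      Z <- rbind(Z_tumors, Z_target_cl,
                 Z_contaminant_pool[pick, , drop = FALSE])
      rownames(Z) <- c(paste0("tumor", seq_len(nrow(Z_tumors))),
                       paste0("cl", seq_len(nrow(Z_target_cl))),
                       paste0("contam", seq_len(n_contaminants)))
      is_cl <- c(rep(FALSE, nrow(Z_tumors)),
                 rep(TRUE, nrow(Z_target_cl) + n_contaminants))
      rep_ <- reject_celllines(neighbor_profile(Z, is_cl, K), threshold)
      is_contam <- grepl("^contam", rep_$sample)
      data.frame(draw = d,
                 recall = mean(rep_$rejected[is_contam]),
                 target_rejected_fraction = mean(rep_$rejected[!is_contam]))
    }))
  })
  list(per_draw = per_draw, mean_recall = mean(per_draw$recall),
       mean_target_rejected_fraction =
         mean(per_draw$target_rejected_fraction))
}

#' Recall of contaminant rejection across neighborhood sizes
#'
#' Re-runs the rejection rule for every `K` in `K_range` on one fixed pooled
#' latent space, reporting the contaminant recall at each `K`. On
#' well-separated data the recall is expected to be insensitive to `K`.
#'
#' @param Z pooled latent matrix (tumors + cell lines + contaminants).
#' @param is_cellline logical per sample (contaminants included).
#' @param is_contaminant logical per sample.
#' @param K_range neighborhood sizes to sweep.
#' @param threshold rejection threshold.
#' @return data frame with columns `K`, `recall`.
#' @export
sweep_k <- function(Z, is_cellline, is_contaminant, K_range = 1:20,
                    threshold = 0.95) {
  assert_that(max(K_range) < nrow(as.matrix(Z)),
              "max K must be below the sample count")
  do.call(rbind, lapply(K_range, function(K) {
    rep_ <- reject_celllines(neighbor_profile(Z, is_cellline, K), threshold)
    contam <- is_contaminant[match(rep_$sample,
                                   rownames(as.matrix(Z)) %||%
                                     paste0("s", seq_along(is_cellline)))]
    data.frame(K = K, recall = mean(rep_$rejected[contam]))
  }))
}

#' Assign retained cell lines to tumor clusters
#'
#' Clusters the union of tumors and retained cell lines by k-means and
#' reports each cell line's cluster, plus the full cell-line membership per
#' cluster. Rejected cell lines must be excluded before calling.
#'
#' @param Z_tumors,Z_retained_cl latent matrices with sample ids as row
#'   names.
#' @param K_clusters number of clusters.
#' @param n_init k-means restarts.
#' @param seed RNG seed.
#' @return list with `assignments` (data frame: sample, cluster),
#'   `clusters` (the full `cluster_result`) and `membership` (named list of
#'   cell lines per cluster).
#' @export
assign_celllines <- function(Z_tumors, Z_retained_cl, K_clusters,
                             n_init = 100L, seed = 1L) {
  if (nrow(Z_retained_cl) == 0L) {
    warnf("no retained cell lines to assign")
    return(list(assignments = data.frame(sample = character(),
                                         cluster = integer()),
                clusters = NULL, membership = list()))
  }
  Z <- rbind(as.matrix(Z_tumors), as.matrix(Z_retained_cl))
  res <- kmeans_cluster(Z, K_clusters, n_init = n_init, seed = seed)
  cl_ids <- rownames(as.matrix(Z_retained_cl))
  assignments <- data.frame(
    sample = cl_ids,
    cluster = unname(res$labels[cl_ids]),
    stringsAsFactors = FALSE)
  membership <- split(assignments$sample, assignments$cluster)
  list(assignments = assignments, clusters = res, membership = membership)
}
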