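#' Protein-protein interaction graphs
#'
#' A `ppi_graph` holds gene ids, a symmetric non-negative adjacency matrix
#' with zero diagonal and the column-stochastic degree-normalized operator
#' `A` used by the random-walk-with-restarts smoother. Isolated genes yield
#' all-zero columns in `A` and are reported.
#'
#' @param adjacency symmetric non-negative numeric matrix with gene ids as
#'   dimnames.
#' @return a `ppi_graph`.
#' @export
ppi_graph <- function(adjacency) {
  assert_that(is.matrix(adjacency) && is.numeric(adjacency),
              "`adjacency` must be a numeric matrix")
  assert_that(!is.null(rownames(adjacency)),
              "`adjacency` needs gene ids as dimnames")
  diag(adjacency) <- 0
  A <- degree_normalize(adjacency)
  structure(list(gene_ids = rownames(adjacency),
                 adjacency = adjacency,
                 operator = A),
            class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("<ppi_graph> %d genes, %d edges\n", length(x$gene_ids),
              sum(x$adjacency[upper.tri(x$adjacency)] > 0)))
  invisible(x)
}

#' Read an undirected weighted edge list
#'
#' Tab-separated columns `gene_a`, `gene_b` and optional `weight`
#' (default 1). Duplicated edges keep the maximum weight; self-loops are
#' dropped.
#'
#' @param path path to the edge-list file.
#' @param delimiter field delimiter.
#' @return a [ppi_graph()].
#' @export
read_edge_list <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE)
  assert_that(all(c("gene_a", "gene_b") %in% names(tab)),
              "edge list needs columns gene_a, gene_b")
  w <- if ("weight" %in% names(tab)) as.numeric(tab$weight) else rep(1, nrow(tab))
  genes <- sort(unique(c(tab$gene_a, tab$gene_b)))
  adj <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  for (i in seq_len(nrow(tab))) {
    a <- tab$gene_a[i]; b <- tab$gene_b[i]
    if (a == b) next
    adj[a, b] <- max(adj[a, b], w[i])
    adj[b, a] <- adj[a, b]
  }
  ppi_graph(adj)
}

#' Degree-normalize an adjacency matrix
#'
#' Divides every column by its sum, producing the column-stochastic operator
#' of a random walk on the graph. Columns of isolated nodes remain all-zero
#' and trigger a warning.
#'
#' @param adjacency symmetric non-negative matrix.
#' @param tol asymmetry tolerance.
#' @return column-stochastic matrix of the same dimension.
#' @export
degree_normalize <- function(adjacency, tol = 1e-8) {
  if (any(adjacency < 0)) stopf("adjacency weights must be non-negative")
  if (max(abs(adjacency - t(adjacency))) > tol) {
    stopf("adjacency matrix is not symmetric")
  }
  degs <- colSums(adjacency)
  isolated <- degs == 0
  if (any(isolated)) {
    warnf("%d isolated node(s) in the network (all-zero columns kept)",
          sum(isolated))
  }
  sweep(adjacency, 2L, ifelse(isolated, 1, degs), "/")
}

#' Smoothing configuration
#'
#' @param alpha random-walk continuation probability in \[0, 1); `1 - alpha`
#'   is the restart rate. Default 0.7, the usual rule of thumb for smoothing
#'   mutation profiles.
#' @param tol convergence tolerance on the max-abs change per iteration.
#' @param max_iter iteration cap.
#' @return a `smoothing_config` list.
#' @export
smoothing_config <- function(alpha = 0.7, tol = 1e-6, max_iter = 10000L) {
  assert_that(alpha >= 0 && alpha < 1, "`alpha` must lie in [0, 1)")
  assert_that(tol > 0 && max_iter >= 1, "invalid tol/max_iter")
  structure(list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter)),
            class = "smoothing_config")
}

#' Random walks with restarts, iterated to convergence
#'
#' Iterates `F[t+1] = alpha * A %*% F[t] + (1 - alpha) * F0` until the
#' max-abs change drops below `config$tol`, returning the (approximate) fixed
#' point `(1 - alpha) * solve(I - alpha * A) %*% F0`. With `alpha = 0` the
#' input is returned after a single restart-only step.
#'
#' @param F0 genes x samples matrix, rows aligned with the rows of `A`.
#' @param A column-stochastic operator (see [degree_normalize()]).
#' @param config a [smoothing_config()].
#' @return smoothed matrix of the same shape as `F0`.
#' @export
smooth_iterative <- function(F0, A, config = smoothing_config()) {
  alpha <- config$alpha
  assert_that(nrow(F0) == nrow(A), "F0 rows must align with the operator")
  if (alpha == 0) return(F0)              # restart-only limit
  Ft <- F0
  for (iter in seq_len(config$max_iter)) {
    Fn <- alpha * (A %*% Ft) + (1 - alpha) * F0
    delta <- max(abs(Fn - Ft))
    Ft <- Fn
    if (delta < config$tol) return(Ft)
  }
  warnf("smoothing did not converge in %d iterations (residual %.3g)",
        config$max_iter, delta)
  Ft
}

#' Closed-form solution of the restart walk
#'
#' The fixed point of the iterative process,
#' `(1 - alpha) * solve(I - alpha * A) %*% F0`, exact for `alpha < 1` and
#' column-stochastic `A`. When no node is isolated the per-sample column sums
#' of the result equal those of `F0` (the walk conserves mass).
#'
#' @inheritParams smooth_iterative
#' @param alpha continuation probability in \[0, 1).
#' @return smoothed matrix.
#' @export
smooth_closed <- function(F0, A, alpha = 0.7) {
  assert_that(alpha >= 0 && alpha < 1, "`alpha` must lie in [0, 1)")
  if (alpha == 0) return(F0)
  n <- nrow(A)
  (1 - alpha) * solve(diag(n) - alpha * A, F0)
}

#' Smooth an omics matrix over a PPI network
#'
#' Genes present in both the matrix and the network are smoothed; genes
#' absent from the network pass through unchanged. Row order of the input is
#' preserved. The closed form is used when the shared gene count is at most
#' `closed_form_limit`, otherwise the iterative solver.
#'
#' @param x [omics_matrix()] (typically the binary mutation matrix).
#' @param graph a [ppi_graph()].
#' @param config a [smoothing_config()].
#' @param closed_form_limit gene-count cutoff for the direct solve.
#' @return list with `smoothed` (an omics_matrix of the same modality; binary
#'   mutation indicators become continuous mutation scores),
#'   `smoothed_genes` and `passthrough_genes`.
#' @export
netsmooth <- function(x, graph, config = smoothing_config(),
                      closed_form_limit = 5000L) {
  shared <- intersect(rownames(x), graph$gene_ids)
  if (length(shared) == 0L) {
    stopf(paste0("no genes shared between the matrix and the network; ",
                 "check that both use the same identifier namespace"))
  }
  vals <- unclass(x)
  idx_net <- match(shared, graph$gene_ids)
  # re-normalize the induced subgraph so columns remain stochastic
  A <- degree_normalize_quiet(graph$adjacency[idx_net, idx_net, drop = FALSE])
  F0 <- vals[shared, , drop = FALSE]
  sm <- if (length(shared) <= closed_form_limit) {
    smooth_closed(F0, A, config$alpha)
  } else {
    smooth_iterative(F0, A, config)
  }
  out <- vals
  out[shared, ] <- sm
  list(smoothed = omics_matrix(out, modality(x), check_binary = FALSE),
       smoothed_genes = shared,
       passthrough_genes = setdiff(rownames(x), shared))
}

degree_normalize_quiet <- function(adjacency) {
  suppressWarnings(degree_normalize(adjacency))
}

#' One-standard-error selection of the restart parameter
#'
#' Given a grid of `alpha` values with a cross-validated score (larger is
#' better) and the score's standard deviation across folds, returns the
#' smallest `alpha` whose score is within one standard deviation of the best
#' score — preferring less smoothing when performance is statistically
#' indistinguishable.
#'
#' @param alphas numeric grid in \[0, 1).
#' @param scores mean score per alpha.
#' @param sds per-alpha standard deviation across folds.
#' @return the selected alpha.
#' @export
select_alpha <- function(alphas, scores, sds) {
  assert_that(length(alphas) >= 1L, "empty alpha grid")
  assert_that(length(alphas) == length(scores) && length(scores) == length(sds),
              "alphas, scores and sds must have equal length")
  best <- which.max(scores)
  ok <- scores >= scores[best] - sds[best]
  min(alphas[ok])
}
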