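#' Omics matrices
#'
#' An `omics_matrix` is a numeric features x samples matrix (rows are genes or
#' other features, columns are samples) carrying a modality tag, one of
#' `"expression"`, `"mutation"` or `"cnv"`. Mutation matrices must be binary
#' before scaling; expression values are FPKM/RPKM-like non-negative values and
#' copy-number values are real-valued gene-level segment means.
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   unique row and column names.
#' @param modality one of `"expression"`, `"mutation"`, `"cnv"`.
#' @param check_binary enforce 0/1 values for the mutation modality. Network
#'   smoothing turns binary mutation indicators into continuous mutation
#'   scores of the same modality, which are constructed with this check off.
#' @return An object of class `omics_matrix` (a matrix with a `modality`
#'   attribute).
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' omics_matrix(m, "expression")
#' @export
omics_matrix <- function(values, modality = c("expression", "mutation", "cnv"),
                         check_binary = TRUE) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values)))) {
    stopf("omics matrices need feature (row) and sample (column) names")
  }
  dup_f <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_f)) stopf("duplicated feature id(s): %s", paste(unique(dup_f), collapse = ", "))
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s)) stopf("duplicated sample id(s): %s", paste(unique(dup_s), collapse = ", "))
  if (anyNA(values)) stopf("omics matrix contains missing values")
  if (check_binary && modality == "mutation" && !all(values %in% c(0, 1))) {
    stopf("mutation matrices must be binary (0/1) before scaling")
  }
  structure(values, modality = modality, class = c("omics_matrix", "matrix", "array"))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> modality=%s, %d features x %d samples\n",
              modality(x), nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(5L, ncol(x))), drop = FALSE],
                    5L), ...)
  invisible(x)
}

#' @rdname omics_matrix
#' @param x an `omics_matrix`.
#' @export
modality <- function(x) attr(x, "modality") %||% "expression"

#' Read a delimited omics matrix
#'
#' Reads a features x samples table: first row holds sample ids, first column
#' holds feature ids. Duplicated ids and non-numeric cells are rejected.
#'
#' @param path path to a delimited text file.
#' @inheritParams omics_matrix
#' @param delimiter field delimiter, tab by default.
#' @return an [omics_matrix()].
#' @export
read_omics_matrix <- function(path, modality = c("expression", "mutation", "cnv"),
                              delimiter = "\t") {
  modality <- match.arg(modality)
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = delimiter, row.names = NULL,
                           check.names = FALSE, colClasses = NA,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stopf("expected a feature-id column plus >=1 sample column")
  ids <- as.character(tab[[1L]])
  num <- tab[, -1L, drop = FALSE]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad)) {
    stopf("non-numeric values in column(s): %s", paste(names(num)[bad], collapse = ", "))
  }
  values <- as.matrix(num)
  rownames(values) <- ids
  omics_matrix(values, modality)
}

#' Write an omics matrix as delimited text
#'
#' Inverse of [read_omics_matrix()]; round-trips numeric content at full
#' printed precision (17 significant digits).
#'
#' @param x an `omics_matrix` or plain matrix with dimnames.
#' @param path output path.
#' @param delimiter field delimiter.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(x, path, delimiter = "\t") {
  df <- data.frame(feature = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- "feature"
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     con, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default set of variant effects treated as nonsynonymous
#'
#' A simplified variant-effect vocabulary covering the usual MAF
#' classifications that alter the protein product.
#' @return character vector of effect labels.
#' @export
nonsynonymous_effects <- function() {
  c("missense", "missense_mutation", "nonsense", "nonsense_mutation",
    "frameshift", "frame_shift_del", "frame_shift_ins", "in_frame_del",
    "in_frame_ins", "splice_site", "nonstop_mutation",
    "translation_start_site", "stop_gained", "stop_lost", "start_lost")
}

#' Build a binary mutation matrix from a long variant table
#'
#' An entry is 1 iff the gene carries at least one variant whose effect is in
#' the nonsynonymous set for that sample; synonymous (and other excluded)
#' records are dropped, and repeated hits do not accumulate.
#'
#' @param records data frame with columns `gene`, `sample`, `effect`.
#' @param samples ordered character vector of sample ids defining the columns.
#' @param effects variant-effect strings counted as nonsynonymous
#'   (case-insensitive); defaults to [nonsynonymous_effects()].
#' @param genes optional ordered feature ids; defaults to the genes observed
#'   among retained records.
#' @return an [omics_matrix()] with modality `"mutation"`.
#' @export
binarize_mutations <- function(records, samples,
                               effects = nonsynonymous_effects(),
                               genes = NULL) {
  need <- c("gene", "sample", "effect")
  assert_that(all(need %in% names(records)),
              "`records` needs columns gene, sample, effect")
  if (nrow(records) == 0L) {
    warnf("empty mutation record table; returning an empty matrix")
    vals <- matrix(0, 0L, length(samples),
                   dimnames = list(character(), samples))
    return(omics_matrix(vals, "mutation"))
  }
  unknown <- setdiff(unique(as.character(records$sample)), samples)
  if (length(unknown)) {
    stopf("mutation records reference unknown sample id(s): %s",
          paste(unknown, collapse = ", "))
  }
  keep <- tolower(as.character(records$effect)) %in% tolower(effects)
  rec <- records[keep, , drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(as.character(rec$gene)))
  vals <- matrix(0, length(genes), length(samples),
                 dimnames = list(genes, samples))
  if (nrow(rec)) {
    idx <- cbind(match(as.character(rec$gene), genes),
                 match(as.character(rec$sample), samples))
    idx <- idx[stats::complete.cases(idx), , drop = FALSE]
    vals[idx] <- 1
  }
  omics_matrix(vals, "mutation")
}
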