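#' EMT positivity call per cell
#'
#' A cell is EMT-positive when its total raw UMI count over the EMT
#' program genes present in the matrix (Snai1, Twist1, Zeb1, Zeb2 by
#' default) reaches `min_umi`. Detection-based calling on raw UMIs is
#' the parameter-free reading of a binary "positive cells" report; the
#' threshold is configurable.
#'
#' @param counts cells x genes raw count matrix (retained cells).
#' @param emt_genes EMT gene panel.
#' @param min_umi minimum summed UMI count for positivity (default 1).
#' @return logical vector per cell, with the summed EMT UMI count
#'   attached as attribute `emt_umi`.
#' @export
emt_call <- function(counts, emt_genes = c("Snai1", "Twist1", "Zeb1",
                                           "Zeb2"), min_umi = 1L) {
  present <- intersect(emt_genes, colnames(counts))
  if (!length(present)) {
    stop("no EMT gene present in the matrix; missing: ",
         paste(emt_genes, collapse = ", "))
  }
  tot <- Matrix::rowSums(counts[, present, drop = FALSE])
  structure(unname(tot >= min_umi), emt_umi = unname(tot))
}

#' Single-gene positivity call per cell
#'
#' @param counts cells x genes raw count matrix.
#' @param gene gene to call (default S100a4).
#' @param min_umi minimum UMI count for positivity (default 1).
#' @return logical vector per cell.
#' @export
gene_positive_call <- function(counts, gene = "S100a4", min_umi = 1L) {
  if (!gene %in% colnames(counts)) {
    stop("gene '", gene, "' absent from the matrix")
  }
  unname(counts[, gene] >= min_umi)
}

#' Continuous EMT score (sum of normalized expression)
#'
#' Companion diagnostic to [emt_call()]: the per-cell sum of normalized
#' log2 expression over the EMT genes. Not used for the binary call.
#'
#' @param norm a `normalized_matrix` or cells x genes numeric matrix.
#' @param emt_genes EMT gene panel.
#' @return numeric score per cell.
#' @export
emt_score <- function(norm, emt_genes = c("Snai1", "Twist1", "Zeb1",
                                          "Zeb2")) {
  values <- if (inherits(norm, "normalized_matrix")) norm$values else
    as.matrix(norm)
  present <- intersect(emt_genes, colnames(values))
  if (!length(present)) stop("no EMT gene present in the matrix")
  unname(rowSums(values[, present, drop = FALSE]))
}

#' Per-sample signature positivity percentages
#'
#' Aggregates per-cell positive calls into per-sample percentages, with
#' multiplet cells excluded from numerator and denominator, and a
#' per-(sample, supercluster) stratified view.
#'
#' @param positive logical per-cell call (e.g. from [emt_call()]).
#' @param samples per-cell sample labels.
#' @param superclusters per-cell supercluster labels; cells labeled
#'   `"multiplet"` are excluded. Optional (no exclusion or
#'   stratification when NULL).
#' @return list with `per_sample` (sample, n_cells, n_positive,
#'   percent) and `per_sample_supercluster` (the stratified table, NULL
#'   when `superclusters` is NULL).
#' @export
signature_percentages <- function(positive, samples,
                                  superclusters = NULL) {
  stopifnot(length(positive) == length(samples))
  if (!is.null(superclusters)) {
    stopifnot(length(superclusters) == length(samples))
    keep <- superclusters != "multiplet"
    positive <- positive[keep]
    samples <- samples[keep]
    superclusters <- superclusters[keep]
  }
  summarize <- function(pos, key) {
    n <- tapply(pos, key, length)
    npos <- tapply(pos, key, sum)
    data.frame(key = names(n), n_cells = as.integer(n),
               n_positive = as.integer(npos),
               percent = 100 * as.numeric(npos) / as.numeric(n),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  per_sample <- summarize(positive, samples)
  names(per_sample)[1L] <- "sample"
  strat <- NULL
  if (!is.null(superclusters)) {
    key <- paste(samples, superclusters, sep = "\r")
    strat <- summarize(positive, key)
    parts <- strsplit(strat$key, "\r", fixed = TRUE)
    strat$sample <- vapply(parts, `[[`, character(1L), 1L)
    strat$supercluster <- vapply(parts, `[[`, character(1L), 2L)
    strat$key <- NULL
    strat <- strat[, c("sample", "supercluster", "n_cells",
                       "n_positive", "percent")]
  }
  list(per_sample = per_sample, per_sample_supercluster = strat)
}
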