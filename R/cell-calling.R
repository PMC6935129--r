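#' Sample-specific minimum-transcript cutoff
#'
#' The cutoff is `factor` times the total transcript count of the
#' barcode at descending-total rank `rank_anchor` (1-based). With the
#' defaults this is 0.1 times the total of the 30th-ranked barcode, the
#' 99th-percentile anchor for a 3000-cell run. Barcode order does not
#' affect the result; tied totals are resolved by a stable sort on
#' barcode name, which leaves the rank-anchor value unchanged.
#'
#' @param totals named numeric vector of per-barcode transcript totals.
#' @param rank_anchor 1-based rank of the anchor barcode (default 30).
#' @param factor multiplier applied to the anchor total (default 0.1).
#' @param adaptive_anchor if TRUE, use
#'   `max(rank_anchor, ceiling(0.01 * expected_cells))` as the anchor.
#' @param expected_cells expected number of cells (only used when
#'   `adaptive_anchor` is TRUE).
#' @return numeric cutoff (transcript count scale).
#' @export
compute_cell_cutoff <- function(totals, rank_anchor = 30L, factor = 0.1,
                                adaptive_anchor = FALSE,
                                expected_cells = NULL) {
  if (adaptive_anchor) {
    if (is.null(expected_cells)) {
      stop("expected_cells is required when adaptive_anchor = TRUE")
    }
    rank_anchor <- max(rank_anchor, ceiling(0.01 * expected_cells))
  }
  if (length(totals) < rank_anchor) {
    stop(sprintf(
      "only %d barcodes but rank_anchor = %d; use a smaller anchor",
      length(totals), rank_anchor))
  }
  nm <- names(totals) %||% as.character(seq_along(totals))
  ord <- order(-totals, nm, method = "radix")
  unname(factor * totals[ord[rank_anchor]])
}

#' Filter a count matrix to barcodes exceeding a cutoff
#'
#' Retains barcodes whose total transcript count strictly exceeds the
#' cutoff ("exceed" means `>`; a barcode exactly at the cutoff is
#' removed). The gene set is unchanged.
#'
#' @param counts barcodes x genes count matrix.
#' @param cutoff minimum-transcript cutoff (see [compute_cell_cutoff()]).
#' @return the filtered matrix, with attribute `cutoff` recording the
#'   threshold used.
#' @export
filter_cells <- function(counts, cutoff) {
  totals <- Matrix::rowSums(counts)
  keep <- totals > cutoff
  if (!any(keep)) {
    warning("no barcode exceeds the cutoff; returning an empty matrix")
  }
  out <- counts[keep, , drop = FALSE]
  attr(out, "cutoff") <- cutoff
  out
}

#' Rank-based cell calling on a count matrix
#'
#' Convenience wrapper computing the cutoff from the matrix's own
#' barcode totals and filtering it.
#'
#' @inheritParams compute_cell_cutoff
#' @param counts barcodes x genes count matrix.
#' @return list with `counts` (filtered matrix), `cutoff`, and
#'   `retained_barcodes`.
#' @export
call_cells <- function(counts, rank_anchor = 30L, factor = 0.1) {
  totals <- setNames(Matrix::rowSums(counts), rownames(counts))
  cutoff <- compute_cell_cutoff(totals, rank_anchor = rank_anchor,
                                factor = factor)
  filtered <- filter_cells(counts, cutoff)
  list(counts = filtered, cutoff = cutoff,
       retained_barcodes = rownames(filtered))
}

#' Scale-factor normalization with log2 transform
#'
#' Divides each cell's counts by its scale factor (cell total divided by
#' the median total across cells) and applies `log2(x + 1)`. Applied
#' after cell calling, so the median is computed over retained cells.
#'
#' @param counts cells x genes count matrix (post-filter).
#' @return list of class `normalized_matrix`: `values` (dense cells x
#'   genes matrix of normalized log2 expression), `scale_factors`,
#'   `median_total`.
#' @export
normalize_counts <- function(counts) {
  totals <- Matrix::rowSums(counts)
  if (nrow(counts) == 0L || all(totals == 0)) {
    stop("normalization requires at least one cell with positive total")
  }
  if (any(totals == 0)) {
    stop("zero-total cell(s) present: scale factor undefined; ",
         "filter cells first")
  }
  med <- median(totals)
  sf <- totals / med
  values <- log2(as.matrix(counts) / sf + 1)
  dimnames(values) <- dimnames(counts)
  structure(list(values = values,
                 scale_factors = setNames(sf, rownames(counts)),
                 median_total = med),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("Normalized expression matrix:", nrow(x$values), "cells x",
      ncol(x$values), "genes\n")
  cat("  median total:", x$median_total,
      "| scale factor range:",
      paste(signif(range(x$scale_factors), 4), collapse = " - "), "\n")
  invisible(x)
}
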