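#' Select the most variable genes
#'
#' Ranks genes by the variance of their normalized log2 expression
#' across cells, descending, with ties broken lexicographically by gene
#' name, and returns the top `n`.
#'
#' @param norm a `normalized_matrix` (see [normalize_counts()]) or a
#'   cells x genes numeric matrix.
#' @param n number of genes to keep (default 1000; truncated to the
#'   number of available genes).
#' @return character vector of gene names, most variable first.
#' @export
select_variable_genes <- function(norm, n = 1000L) {
  values <- if (inherits(norm, "normalized_matrix")) norm$values else norm
  if (ncol(values) == 0L) return(character(0))
  v <- apply(values, 2L, var)
  nm <- colnames(values) %||% as.character(seq_len(ncol(values)))
  ord <- order(-v, nm, method = "radix")
  nm[ord][seq_len(min(n, length(ord)))]
}

#' PCA embedding of normalized expression
#'
#' Centers each gene to mean zero across cells and computes the top
#' principal components. Component signs are fixed deterministically by
#' forcing the largest-magnitude loading of each component positive.
#'
#' @param norm a `normalized_matrix` or cells x genes numeric matrix,
#'   typically restricted to variable genes.
#' @param genes optional gene subset (e.g. from
#'   [select_variable_genes()]).
#' @param n_components number of components to keep (default 20).
#' @return list of class `pca_embedding`: `scores` (cells x components),
#'   `loadings` (genes x components, orthonormal columns),
#'   `explained_variance` (per-component variance), `center`, `hvg`.
#' @export
run_pca <- function(norm, genes = NULL, n_components = 20L) {
  values <- if (inherits(norm, "normalized_matrix")) norm$values else norm
  if (!is.null(genes)) values <- values[, genes, drop = FALSE]
  if (nrow(values) < n_components) {
    stop("fewer cells than requested components")
  }
  if (ncol(values) < n_components) {
    stop("fewer genes than requested components")
  }
  pc <- prcomp(values, center = TRUE, scale. = FALSE, rank. = n_components)
  flip <- apply(pc$rotation, 2L, function(col) {
    sign(col[which.max(abs(col))])
  })
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = pc$sdev[seq_len(n_components)]^2,
                 center = pc$center,
                 hvg = colnames(values)),
            class = "pca_embedding")
}

#' @export
print.pca_embedding <- function(x, ...) {
  ev <- x$explained_variance
  cat("PCA embedding:", nrow(x$scores), "cells x", ncol(x$scores),
      "components over", length(x$hvg), "genes\n")
  cat("  variance explained by PC1-3:",
      paste(signif(ev[seq_len(min(3, length(ev)))], 3), collapse = ", "),
      "\n")
  invisible(x)
}
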