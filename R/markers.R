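# two-sided Wilcoxon rank-sum p for one gene given the in-group rank sum.
# Exact null (pwilcox) for small tie-free groups; tie-corrected,
# continuity-corrected normal approximation otherwise.
wilcoxon_p <- function(u, n1, n2, tie_sizes, exact_limit = 12L) {
  no_ties <- all(tie_sizes == 1L)
  if (no_ties && n1 + n2 <= exact_limit) {
    p <- 2 * min(pwilcox(u, n1, n2), 1 - pwilcox(u - 1, n1, n2))
    return(min(1, p))
  }
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  cc <- sign(u - mu) * 0.5
  z <- (u - mu - cc) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' One-vs-rest Wilcoxon marker enrichment per cluster
#'
#' For every cluster and gene, tests in-cluster versus all other cells
#' with a two-sided Wilcoxon rank-sum test on normalized expression
#' (midranks for ties; exact null for small tie-free comparisons, normal
#' approximation with tie and continuity corrections otherwise).
#' P-values are Benjamini-Hochberg adjusted within each cluster's gene
#' list. The rank-sum effect size auc = U / (n1 n2) is the probability
#' that a random in-cluster cell exceeds a random out-cluster cell.
#'
#' @param norm a `normalized_matrix` or cells x genes numeric matrix.
#' @param labels integer cluster labels per cell.
#' @param genes optional gene subset to test.
#' @return data frame with columns cluster, gene, u_statistic, auc,
#'   p_value, adjusted_p, mean_in, mean_out.
#' @export
cluster_markers <- function(norm, labels, genes = NULL) {
  values <- if (inherits(norm, "normalized_matrix")) norm$values else
    as.matrix(norm)
  if (!is.null(genes)) values <- values[, genes, drop = FALSE]
  stopifnot(nrow(values) == length(labels))
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L) {
    stop("marker testing needs at least two clusters")
  }
  n <- nrow(values)
  gene_names <- colnames(values) %||% as.character(seq_len(ncol(values)))

  # midranks and tie structure per gene, shared across clusters
  ranks <- apply(values, 2L, rank)  # average (mid) ranks
  ties <- lapply(seq_len(ncol(values)), function(j) {
    as.integer(table(values[, j]))
  })

  out <- list()
  for (cl in clusters) {
    in_cl <- labels == cl
    n1 <- sum(in_cl); n2 <- n - n1
    if (n1 < 2L) {
      warning(sprintf("cluster %s has fewer than 2 cells; skipped", cl))
      next
    }
    r1 <- if (n1 == 1L) ranks[in_cl, ] else colSums(ranks[in_cl, ,
                                                          drop = FALSE])
    u <- r1 - n1 * (n1 + 1) / 2
    auc <- u / (n1 * n2)
    p <- vapply(seq_along(u), function(j) {
      wilcoxon_p(u[j], n1, n2, ties[[j]])
    }, numeric(1L))
    out[[length(out) + 1L]] <- data.frame(
      cluster = cl, gene = gene_names, u_statistic = unname(u),
      auc = unname(auc), p_value = p,
      adjusted_p = p.adjust(p, method = "BH"),
      mean_in = unname(colMeans(values[in_cl, , drop = FALSE])),
      mean_out = unname(colMeans(values[!in_cl, , drop = FALSE])),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no cluster had at least 2 cells")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default lineage marker panels
#'
#' Canonical marker genes for the four expected lineages: epithelial
#' (Epcam, Krt18, Krt5), stromal (Col3a1, Vim, Bgn), T (Cd3e, Cd3d) and
#' myeloid (Itgam, Mrc1, Lyz2).
#'
#' @return named list of character vectors.
#' @export
default_marker_panels <- function() {
  list(epithelial = c("Epcam", "Krt18", "Krt5"),
       stromal    = c("Col3a1", "Vim", "Bgn"),
       T          = c("Cd3e", "Cd3d"),
       myeloid    = c("Itgam", "Mrc1", "Lyz2"))
}

#' Merge clusters into lineage superclusters via marker panels
#'
#' Formalizes marker inspection: each cluster is scored against each
#' lineage panel by the mean auc of the panel's genes for that cluster.
#' The cluster joins the top-scoring lineage when that score exceeds
#' `auc_threshold`; it is flagged `multiplet` when two or more panels
#' exceed the threshold (markers of two lineages at once), and
#' `unassigned` when none does.
#'
#' @param markers marker table from [cluster_markers()].
#' @param panels named list of lineage -> marker gene vectors (disjoint);
#'   see [default_marker_panels()].
#' @param labels integer cluster labels per cell.
#' @param auc_threshold minimum panel score for assignment (default 0.7).
#' @return object of class `supercluster_assignment`: `cluster_map`
#'   (named cluster -> label), `cell_labels` (per-cell supercluster),
#'   `panel_scores` (clusters x panels matrix), `auc_threshold`.
#' @export
merge_superclusters <- function(markers, panels = default_marker_panels(),
                                labels, auc_threshold = 0.7) {
  if (!length(panels)) stop("panels must be non-empty")
  all_panel_genes <- unlist(panels, use.names = FALSE)
  if (anyDuplicated(all_panel_genes)) {
    stop("panel gene sets must be disjoint")
  }
  present <- unique(markers$gene)
  missing <- setdiff(all_panel_genes, present)
  if (length(missing)) {
    warning("panel genes absent from marker table: ",
            paste(missing, collapse = ", "),
            "; scoring over present genes")
  }
  clusters <- sort(unique(markers$cluster))
  scores <- matrix(NA_real_, length(clusters), length(panels),
                   dimnames = list(as.character(clusters), names(panels)))
  for (pn in names(panels)) {
    pg <- intersect(panels[[pn]], present)
    if (!length(pg)) {
      stop("no gene of panel '", pn, "' is present in the data")
    }
    sub <- markers[markers$gene %in% pg, ]
    agg <- tapply(sub$auc, sub$cluster, mean)
    scores[names(agg), pn] <- agg
  }
  cluster_map <- apply(scores, 1L, function(s) {
    hits <- which(s > auc_threshold)
    if (length(hits) >= 2L) "multiplet"
    else if (length(hits) == 1L) names(s)[hits]
    else "unassigned"
  })
  cell_labels <- unname(cluster_map[as.character(labels)])
  structure(list(cluster_map = cluster_map, cell_labels = cell_labels,
                 panel_scores = scores, auc_threshold = auc_threshold),
            class = "supercluster_assignment")
}

#' @export
print.supercluster_assignment <- function(x, ...) {
  cat("Supercluster assignment (auc threshold ", x$auc_threshold, ")\n",
      sep = "")
  tab <- table(x$cluster_map)
  cat("  clusters:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  tab2 <- table(x$cell_labels)
  cat("  cells:", paste(names(tab2), tab2, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-sample supercluster composition
#'
#' Counts and percentages of each supercluster per sample, plus the
#' multiplet-excluded view used by all downstream signature reports
#' (multiplet clusters are dropped and percentages renormalized).
#'
#' @param cell_labels per-cell supercluster labels (from
#'   [merge_superclusters()] `$cell_labels`, or any character vector).
#' @param samples per-cell sample labels.
#' @return list with `full` and `excluding_multiplets`, each a data
#'   frame (sample, supercluster, count, percent); percentages sum to
#'   100 within each sample.
#' @export
composition_summary <- function(cell_labels, samples) {
  stopifnot(length(cell_labels) == length(samples), !anyNA(samples))
  build <- function(lab, smp) {
    tab <- as.data.frame(table(sample = smp, supercluster = lab),
                         stringsAsFactors = FALSE)
    names(tab)[3L] <- "count"
    tab <- tab[tab$count > 0 | TRUE, ]
    totals <- tapply(tab$count, tab$sample, sum)
    tab$percent <- 100 * tab$count / as.numeric(totals[tab$sample])
    tab[order(tab$sample, tab$supercluster), ]
  }
  keep <- cell_labels != "multiplet"
  list(full = build(cell_labels, samples),
       excluding_multiplets = build(cell_labels[keep], samples[keep]))
}
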