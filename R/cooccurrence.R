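as_alteration_matrix <- function(table) {
  m <- as.matrix(table)
  if (!is.logical(m)) {
    if (!all(m %in% c(0, 1))) stop("alteration entries must be 0/1")
    m <- m == 1
  }
  if (anyDuplicated(rownames(m))) stop("duplicate sample ids")
  m
}

check_genes <- function(m, genes) {
  missing <- setdiff(genes, colnames(m))
  if (length(missing)) {
    stop("gene(s) not in the alteration table: ",
         paste(missing, collapse = ", "))
  }
}

#' Marginal alteration frequencies
#'
#' Per-gene altered-sample counts and frequencies over a samples x genes
#' boolean alteration table. Percentages are formatted as printed in
#' reports: integer, rounding half away from zero (e.g. 2763/4485 =
#' 61.6% prints as 62%).
#'
#' @param table samples x genes boolean alteration matrix (or 0/1).
#' @param genes genes to report (default: all columns).
#' @return data frame with gene, count, n, frequency, percent_printed.
#' @export
alteration_frequencies <- function(table, genes = NULL) {
  m <- as_alteration_matrix(table)
  genes <- genes %||% colnames(m)
  check_genes(m, genes)
  count <- colSums(m[, genes, drop = FALSE])
  n <- nrow(m)
  data.frame(gene = genes, count = as.integer(count), n = n,
             frequency = as.numeric(count) / n,
             percent_printed = format_percent(count / n),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Joint and conditional alteration frequency for a gene pair
#'
#' The joint frequency is the fraction of samples altered in both
#' genes; the conditional frequency is P(gene_b altered | gene_a
#' altered) = joint count / gene_a count.
#'
#' @param table samples x genes boolean alteration matrix.
#' @param gene_a,gene_b the two genes.
#' @return list with joint_count, joint_frequency, conditional
#'   (P(b|a)), their printed percent strings, and n.
#' @export
joint_frequency <- function(table, gene_a, gene_b) {
  m <- as_alteration_matrix(table)
  check_genes(m, c(gene_a, gene_b))
  a <- m[, gene_a]; b <- m[, gene_b]
  joint <- sum(a & b)
  n_a <- sum(a)
  n <- nrow(m)
  cond <- if (n_a == 0) {
    stop("conditional frequency undefined: no sample altered in ",
         gene_a)
  } else joint / n_a
  list(joint_count = joint, n = n,
       joint_frequency = joint / n,
       joint_percent_printed = format_percent(joint / n),
       conditional = cond,
       conditional_percent_printed = format_percent(cond))
}

#' Co-occurrence test for a gene pair
#'
#' Builds the 2x2 contingency table (both / a-only / b-only / neither)
#' and reports the sample odds ratio ad/bc (with the Haldane 0.5
#' correction when a zero cell exists) and the exact two-sided Fisher
#' p-value (sum of hypergeometric tables no more probable than the
#' observed one).
#'
#' @param table samples x genes boolean alteration matrix.
#' @param gene_a,gene_b the two genes.
#' @return list with contingency (2x2 matrix), odds_ratio, p_value.
#' @export
cooccurrence_test <- function(table, gene_a, gene_b) {
  m <- as_alteration_matrix(table)
  check_genes(m, c(gene_a, gene_b))
  x <- m[, gene_a]; y <- m[, gene_b]
  tab <- matrix(c(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y)),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("a_altered", "a_wild"),
                                c("b_altered", "b_wild")))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    warning("degenerate margins (a gene is altered in all or no ",
            "samples); p = 1")
    p <- 1
  } else {
    p <- fisher.test(tab)$p.value
  }
  or <- if (min(a, b, c_, d) == 0) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  list(contingency = tab, odds_ratio = or, p_value = p)
}

#' Full co-occurrence summary for a gene pair
#'
#' Combines marginal, joint and conditional frequencies with the
#' co-occurrence test into one report.
#'
#' @inheritParams cooccurrence_test
#' @return object of class `cooccurrence_summary`.
#' @export
cooccurrence_summary <- function(table, gene_a, gene_b) {
  marg <- alteration_frequencies(table, c(gene_a, gene_b))
  jnt <- joint_frequency(table, gene_a, gene_b)
  tst <- cooccurrence_test(table, gene_a, gene_b)
  structure(list(gene_a = gene_a, gene_b = gene_b, marginals = marg,
                 joint = jnt, test = tst),
            class = "cooccurrence_summary")
}

#' @export
print.cooccurrence_summary <- function(x, ...) {
  m <- x$marginals
  cat("Alteration co-occurrence:", x$gene_a, "and", x$gene_b, "(n =",
      m$n[1], "samples )\n")
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %s altered in %s (%d/%d)\n", m$gene[i],
                m$percent_printed[i], m$count[i], m$n[i]))
  }
  cat(sprintf("  both altered in %s (%d/%d)\n",
              x$joint$joint_percent_printed, x$joint$joint_count,
              x$joint$n))
  cat(sprintf("  of %s-altered samples, %s also carry %s (%d/%d)\n",
              x$gene_a, x$joint$conditional_percent_printed, x$gene_b,
              x$joint$joint_count, m$count[m$gene == x$gene_a]))
  cat(sprintf("  odds ratio %.3f, Fisher exact p = %.3g\n",
              x$test$odds_ratio, x$test$p_value))
  invisible(x)
}

#' Read / write an alteration table as TSV
#'
#' First column holds the sample id; remaining columns are 0/1 gene
#' indicators.
#'
#' @param path file path.
#' @param table samples x genes boolean matrix (for writing).
#' @return for reading, a logical samples x genes matrix with sample-id
#'   rownames.
#' @export
read_alteration_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  as_alteration_matrix(m)
}

#' @rdname read_alteration_table
#' @export
write_alteration_table <- function(table, path) {
  m <- as_alteration_matrix(table)
  df <- data.frame(sample = rownames(m) %||%
                     sprintf("S%06d", seq_len(nrow(m))),
                   m * 1L, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
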