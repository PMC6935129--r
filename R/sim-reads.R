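#' Simulate gene-tagged reads from a UMI count matrix
#'
#' Expands each counted molecule into one or more reads tagged with its
#' droplet barcode, a UMI distinct within its (barcode, gene) pair, and
#' its gene. Duplicate reads of a molecule may carry a UMI mutated at one
#' position (Hamming distance 1), emulating sequencing errors in the UMI;
#' the first read of every molecule always carries the true UMI.
#'
#' @param counts droplets x genes integer matrix (sparse or dense) with
#'   barcode rownames and gene colnames.
#' @param reads_per_umi_mean mean reads per molecule (>= 1 emitted each);
#'   extra reads are Poisson distributed around `reads_per_umi_mean - 1`.
#' @param umi_error_rate probability that a duplicate read carries a
#'   distance-1 UMI error.
#' @param antisense_fraction fraction of reads emitted in antisense
#'   orientation (these do not count toward transcripts downstream).
#' @param umi_length UMI length in bases.
#' @param seed integer seed.
#' @return data frame of reads: barcode, umi, gene, orientation.
#' @export
simulate_tagged_reads <- function(counts, reads_per_umi_mean = 1,
                                  umi_error_rate = 0,
                                  antisense_fraction = 0,
                                  umi_length = 10L, seed = 1L) {
  if (reads_per_umi_mean <= 0) stop("reads_per_umi_mean must be positive")
  stopifnot(umi_error_rate >= 0, umi_error_rate <= 1,
            antisense_fraction >= 0, antisense_fraction < 1)
  set.seed(derive_seed(seed, "simulate_tagged_reads"))

  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "TsparseMatrix")
  if (any(m@x != round(m@x)) || any(m@x < 0)) {
    stop("counts must be non-negative integers")
  }
  bc <- rownames(m)[m@i + 1L]
  gene <- colnames(m)[m@j + 1L]
  nmol <- as.integer(m@x)

  umi_space <- 4L^umi_length
  # distinct UMIs per molecule within each (barcode, gene) pair
  umis <- unlist(lapply(nmol, function(k) {
    sample.int(umi_space, k) - 1L
  }), use.names = FALSE)
  umis <- index_to_seq(umis, umi_length)

  mol_bc <- rep(bc, nmol)
  mol_gene <- rep(gene, nmol)
  n_mol_total <- length(umis)
  if (n_mol_total == 0L) {
    return(data.frame(barcode = character(0), umi = character(0),
                      gene = character(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  }

  extra <- rpois(n_mol_total, max(reads_per_umi_mean - 1, 0))
  first <- data.frame(barcode = mol_bc, umi = umis, gene = mol_gene,
                      stringsAsFactors = FALSE)
  dup_idx <- rep(seq_len(n_mol_total), extra)
  dup_umi <- umis[dup_idx]
  if (length(dup_idx) && umi_error_rate > 0) {
    err <- runif(length(dup_idx)) < umi_error_rate
    if (any(err)) {
      dup_umi[err] <- vapply(dup_umi[err], function(u) {
        pos <- sample.int(umi_length, 1L)
        ch <- strsplit(u, "", fixed = TRUE)[[1L]]
        ch[pos] <- sample(BASES[BASES != ch[pos]], 1L)
        paste0(ch, collapse = "")
      }, character(1L))
    }
  }
  dups <- data.frame(barcode = mol_bc[dup_idx], umi = dup_umi,
                     gene = mol_gene[dup_idx], stringsAsFactors = FALSE)
  reads <- rbind(first, dups)
  n_reads <- nrow(reads)
  reads$orientation <- "sense"
  if (antisense_fraction > 0) {
    anti <- runif(n_reads) < antisense_fraction
    reads$orientation[anti] <- "antisense"
  }
  rownames(reads) <- NULL
  reads
}

#' Simulate a sample x gene alteration table with exact counts
#'
#' Builds a boolean pathogenic-alteration table for two genes with
#' deterministic joint structure: exactly `round(n * joint)` samples
#' altered in both, `round(n * freq_a) - joint` in A only, and likewise
#' for B; the remainder carry neither. Row order is randomized.
#'
#' @param n_samples number of samples.
#' @param freq_a,freq_b marginal alteration fractions for the two genes.
#' @param joint fraction altered in both genes; must satisfy
#'   `max(0, freq_a + freq_b - 1) <= joint <= min(freq_a, freq_b)`.
#' @param genes character vector of two gene names.
#' @param seed integer seed (used only to shuffle sample order).
#' @return an `alteration_table`: logical samples x genes matrix with
#'   sample-id rownames.
#' @export
simulate_alteration_table <- function(n_samples, freq_a, freq_b, joint,
                                      genes = c("PIK3CA", "TP53"),
                                      seed = 1L) {
  stopifnot(n_samples >= 1, length(genes) == 2L)
  if (joint > min(freq_a, freq_b) + 1e-12 ||
      joint < max(0, freq_a + freq_b - 1) - 1e-12) {
    stop(sprintf(
      "infeasible joint fraction %.4g: must lie in [%.4g, %.4g]",
      joint, max(0, freq_a + freq_b - 1), min(freq_a, freq_b)))
  }
  n_ab <- round_half_up(n_samples * joint)
  n_a <- round_half_up(n_samples * freq_a) - n_ab
  n_b <- round_half_up(n_samples * freq_b) - n_ab
  n_none <- n_samples - n_ab - n_a - n_b
  if (min(n_a, n_b, n_none) < 0) {
    stop("rounded counts are inconsistent; adjust the fractions")
  }
  a <- rep(c(TRUE, TRUE, FALSE, FALSE), c(n_ab, n_a, n_b, n_none))
  b <- rep(c(TRUE, FALSE, TRUE, FALSE), c(n_ab, n_a, n_b, n_none))
  tab <- cbind(a, b)
  colnames(tab) <- genes
  rownames(tab) <- sprintf("S%06d", seq_len(n_samples))
  set.seed(derive_seed(seed, "simulate_alteration_table"))
  tab <- tab[sample.int(n_samples), , drop = FALSE]
  class(tab) <- c("alteration_table", class(tab))
  tab
}
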