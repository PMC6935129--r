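#' Demultiplex tagged reads by exact barcode match
#'
#' Retains reads whose droplet barcode matches a whitelist entry exactly;
#' there is no barcode error correction. Barcode lengths must agree
#' between reads and whitelist.
#'
#' @param reads data frame with columns barcode, umi, gene, orientation.
#' @param whitelist character vector of expected barcodes.
#' @return the retained reads with `barcode` turned into a factor whose
#'   levels are the whitelist (so empty groups are preserved); the number
#'   of discarded reads is attached as attribute `n_discarded`.
#' @export
demultiplex <- function(reads, whitelist) {
  if (length(whitelist) == 0L) stop("whitelist must be non-empty")
  if (anyDuplicated(whitelist)) stop("whitelist contains duplicates")
  wl_len <- unique(nchar(whitelist))
  rd_len <- unique(nchar(reads$barcode))
  if (length(wl_len) != 1L ||
      (length(rd_len) > 0L && !identical(rd_len, wl_len))) {
    stop("barcode length mismatch between reads and whitelist")
  }
  keep <- reads$barcode %in% whitelist
  out <- reads[keep, , drop = FALSE]
  out$barcode <- factor(out$barcode, levels = whitelist)
  rownames(out) <- NULL
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Count transcripts by collapsing UMIs within one mismatch
#'
#' Returns the number of distinct molecules supported by a set of UMI
#' reads: the connected components of the graph whose vertices are the
#' distinct UMI sequences and whose edges join pairs at Hamming distance
#' less than or equal to 1. Collapsing is transitive, so a chain
#' A-B-C where consecutive UMIs differ by one base counts once.
#'
#' @param umis character vector of UMI sequences (one entry per read;
#'   duplicates allowed).
#' @return integer transcript count.
#' @export
collapse_umis <- function(umis) {
  if (length(umis) == 0L) return(0L)
  if (length(unique(nchar(umis))) != 1L) {
    stop("UMIs must all have the same length")
  }
  u <- unique(umis)
  n <- length(u)
  if (n == 1L) return(1L)
  # union-find over distance-<=1 pairs, found by neighbor hashing
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- seq_len(n)
  names(idx) <- u
  for (i in seq_len(n)) {
    for (nb in hamming1_neighbors(u[i])) {
      j <- idx[nb]
      if (!is.na(j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1L))))
}

#' Build a UMI count matrix from demultiplexed reads
#'
#' For every (barcode, gene) pair, counts transcripts by collapsing the
#' UMIs of sense-orientation reads assigned to that gene; antisense reads
#' and reads without a gene assignment contribute nothing (they are
#' tallied in the `n_dropped` attribute).
#'
#' @param reads demultiplexed reads (see [demultiplex()]); `barcode`
#'   may be a factor carrying the whitelist as levels.
#' @param genes optional gene universe for the matrix columns; defaults
#'   to the sorted genes observed among counted reads.
#' @return sparse barcodes x genes integer count matrix. Barcode rows
#'   follow the whitelist (factor levels) when available.
#' @export
count_transcripts <- function(reads, genes = NULL) {
  barcodes <- if (is.factor(reads$barcode)) levels(reads$barcode) else
    sort(unique(as.character(reads$barcode)))
  usable <- reads$orientation == "sense" & !is.na(reads$gene)
  n_dropped <- sum(!usable)
  rd <- reads[usable, , drop = FALSE]
  gene_chr <- as.character(rd$gene)
  if (is.null(genes)) genes <- sort(unique(gene_chr))

  key <- paste(as.character(rd$barcode), gene_chr, sep = "\r")
  per_pair <- split(rd$umi, key)
  counts <- vapply(per_pair, collapse_umis, integer(1L))
  parts <- strsplit(names(per_pair), "\r", fixed = TRUE)
  bc_i <- match(vapply(parts, `[[`, character(1L), 1L), barcodes)
  gn_j <- match(vapply(parts, `[[`, character(1L), 2L), genes)
  if (anyNA(gn_j)) stop("reads contain genes outside the given gene set")

  mat <- Matrix::sparseMatrix(i = bc_i, j = gn_j, x = counts,
                              dims = c(length(barcodes), length(genes)),
                              dimnames = list(barcodes, genes))
  attr(mat, "n_dropped") <- n_dropped
  mat
}

#' Quantify a tagged-read stream into a count matrix
#'
#' Convenience wrapper chaining [demultiplex()] and [count_transcripts()],
#' with a stats list (reads seen / retained / dropped / total transcripts)
#' attached.
#'
#' @param reads data frame of tagged reads.
#' @param whitelist expected barcodes.
#' @param genes optional gene universe.
#' @return list with `counts` and `stats`.
#' @export
quantify_reads <- function(reads, whitelist, genes = NULL) {
  demuxed <- demultiplex(reads, whitelist)
  counts <- count_transcripts(demuxed, genes = genes)
  stats <- list(reads_seen = nrow(reads),
                reads_retained = nrow(demuxed),
                reads_discarded_barcode = attr(demuxed, "n_discarded"),
                reads_dropped_orientation_or_gene = attr(counts, "n_dropped"),
                transcripts = sum(counts))
  list(counts = counts, stats = stats)
}

#' Indel allele frequency at a target locus
#'
#' The fraction of reads aligning to the on-target position that carry an
#' indel event, used to confirm CRISPR knockouts from RNA-seq read
#' support.
#'
#' @param n_reads_with_indel reads carrying an indel at the locus.
#' @param n_reads_at_locus total reads aligning to the locus (> 0).
#' @return fraction in `[0, 1]`.
#' @export
indel_allele_frequency <- function(n_reads_with_indel, n_reads_at_locus) {
  if (n_reads_at_locus <= 0) {
    stop("no reads at locus: allele frequency is undefined, not 0")
  }
  if (n_reads_with_indel < 0 || n_reads_with_indel > n_reads_at_locus) {
    stop("n_reads_with_indel must lie in [0, n_reads_at_locus]")
  }
  n_reads_with_indel / n_reads_at_locus
}
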