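#' @keywords internal
"_PACKAGE"

#' @importFrom stats rpois rnbinom rlnorm runif rnorm median var prcomp
#'   kmeans p.adjust pwilcox pnorm fisher.test setNames
#' @importFrom utils head tail read.delim write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib tumorhet, .registration = TRUE
NULL

# round half away from zero (R's round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# percent string as printed in reports: integer, half away from zero
format_percent <- function(frac) {
  paste0(round_half_up(100 * frac), "%")
}

# Deterministic per-stage seed substream: fold a stage name into the run
# seed via a small string hash, keeping the result a valid 32-bit seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 31 + cp) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}

# log(sum(exp(x))) by row for a matrix, guarded against underflow
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

BASES <- c("A", "C", "G", "T")

# integer index (0-based) -> fixed-length ACGT string
index_to_seq <- function(idx, width) {
  out <- character(length(idx))
  chars <- matrix("", nrow = length(idx), ncol = width)
  for (pos in width:1) {
    chars[, pos] <- BASES[idx %% 4L + 1L]
    idx <- idx %/% 4L
  }
  apply(chars, 1L, paste0, collapse = "")
}

# Hamming distance between two equal-length strings
hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# all sequences at Hamming distance exactly 1 from `s` over ACGT
hamming1_neighbors <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  out <- character(3L * length(ch))
  j <- 0L
  for (pos in seq_along(ch)) {
    for (b in BASES[BASES != ch[pos]]) {
      tmp <- ch
      tmp[pos] <- b
      j <- j + 1L
      out[j] <- paste0(tmp, collapse = "")
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
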