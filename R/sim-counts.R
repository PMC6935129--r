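EMT_GENES <- c("Snai1", "Twist1", "Zeb1", "Zeb2")
S100A4_GENE <- "S100a4"

# distinct random ACGT barcodes of the given width
random_barcodes <- function(n, width) {
  draw <- function(m) {
    apply(matrix(sample(BASES, m * width, replace = TRUE), nrow = m),
          1L, paste0, collapse = "")
  }
  bc <- draw(n)
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- draw(length(dup))
  }
  bc
}

# count noise: NB(mu, dispersion) with Poisson limit at dispersion = 0
draw_counts <- function(mu, dispersion) {
  if (dispersion <= 0) return(rpois(length(mu), mu))
  rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

# plant exactly round(frac * n) flags among `eligible` indices
plant_flags <- function(n, eligible, frac) {
  flag <- logical(n)
  k <- round_half_up(frac * length(eligible))
  if (k > 0) flag[sample(eligible, k)] <- TRUE
  flag
}

#' Simulate a droplet scRNA-seq count matrix with known ground truth
#'
#' Draws singlet cells from per-lineage expression programs (negative
#' binomial counts scaled by a log-normal per-cell library factor),
#' cross-lineage doublets as sums of two independently drawn cells, and
#' ambient-only empty droplets from the library-size-weighted mixture of
#' the lineage programs. An EMT program (Snai1/Twist1/Zeb1/Zeb2) is
#' planted in an exact fraction of epithelial/stromal singlets and
#' S100a4 expression in exact per-lineage fractions.
#'
#' @param config a [sim_config()] object.
#' @return list with `counts` (sparse droplets x genes integer matrix,
#'   rownames = barcodes) and `truth` (per-droplet data frame: barcode,
#'   droplet_class cell/doublet/empty, lineage, lineage2, emt_flag,
#'   s100a4_flag, library_factor, true_total, sample).
#' @export
simulate_tumor_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "simulate_tumor_counts"))

  lineages <- names(config$programs)
  genes <- c(names(config$programs[[1L]]), EMT_GENES, S100A4_GENE)
  n_genes <- length(genes)

  # full per-lineage rate vectors over the complete gene universe
  base_rates <- vapply(lineages, function(lin) {
    r <- setNames(numeric(n_genes), genes)
    r[names(config$programs[[lin]])] <- config$programs[[lin]]
    r
  }, numeric(n_genes))  # genes x lineages

  n_cells <- config$n_real_cells
  r <- config$doublet_rate
  n_doublets <- if (n_cells > 0L) round_half_up(n_cells * r / (1 - r)) else 0L

  p <- config$lineage_proportions
  lineage <- if (n_cells > 0L) {
    sample(lineages, n_cells, replace = TRUE, prob = p)
  } else character(0)

  eligible <- which(lineage %in% c("epithelial", "stromal"))
  emt_flag <- plant_flags(n_cells, eligible, config$emt_fraction)
  s100_flag <- logical(n_cells)
  for (lin in lineages) {
    idx <- which(lineage == lin)
    s100_flag <- s100_flag |
      plant_flags(n_cells, idx, config$s100a4_fraction[[lin]])
  }

  cell_rate_matrix <- function(lin, emt, s100) {
    m <- t(base_rates[, lin, drop = FALSE])  # cells x genes
    m[emt, EMT_GENES] <- m[emt, EMT_GENES] + config$emt_program_rate
    m[s100, S100A4_GENE] <- m[s100, S100A4_GENE] +
      config$s100a4_rates[lin][s100]
    m
  }

  draw_cells <- function(lin, emt, s100) {
    k <- length(lin)
    if (k == 0L) {
      return(list(counts = matrix(0L, 0L, n_genes),
                  lib = numeric(0), total = numeric(0)))
    }
    sigma <- config$library_size_dispersion
    lib <- if (sigma > 0) rlnorm(k, -sigma^2 / 2, sigma) else rep(1, k)
    mu <- cell_rate_matrix(lin, emt, s100) * lib
    cts <- matrix(draw_counts(as.numeric(mu), config$nb_dispersion),
                  nrow = k, ncol = n_genes)
    list(counts = cts, lib = lib, total = rowSums(mu))
  }

  singlets <- draw_cells(lineage, emt_flag, s100_flag)

  # cross-lineage doublets: unordered pair drawn with prob proportional
  # to p_i * p_j, i != j
  if (n_doublets > 0L) {
    l1 <- sample(lineages, n_doublets, replace = TRUE, prob = p)
    l2 <- vapply(l1, function(a) {
      q <- p[lineages != a]
      sample(names(q), 1L, prob = q)
    }, character(1L))
    da <- draw_cells(l1, rep(FALSE, n_doublets), rep(FALSE, n_doublets))
    db <- draw_cells(l2, rep(FALSE, n_doublets), rep(FALSE, n_doublets))
    doublets <- list(counts = da$counts + db$counts,
                     lib = (da$lib + db$lib) / 2,
                     total = da$total + db$total)
  } else {
    l1 <- l2 <- character(0)
    doublets <- list(counts = matrix(0L, 0L, n_genes),
                     lib = numeric(0), total = numeric(0))
  }

  # ambient profile: library-size-weighted lineage mixture including the
  # planted programs' expected contribution, rescaled to the ambient mean
  ambient <- as.numeric(base_rates %*% p)
  names(ambient) <- genes
  elig_frac <- sum(p[c("epithelial", "stromal")])
  ambient[EMT_GENES] <- ambient[EMT_GENES] +
    config$emt_fraction * elig_frac * config$emt_program_rate
  ambient[S100A4_GENE] <- ambient[S100A4_GENE] +
    sum(p * config$s100a4_fraction * config$s100a4_rates)
  if (sum(ambient) > 0 && config$n_empty_droplets > 0L) {
    ambient <- ambient / sum(ambient) * config$ambient_total_mean
    empty_counts <- matrix(
      rpois(config$n_empty_droplets * n_genes,
            rep(ambient, each = config$n_empty_droplets)),
      nrow = config$n_empty_droplets, ncol = n_genes)
  } else {
    empty_counts <- matrix(0L, config$n_empty_droplets, n_genes)
  }

  n_total <- n_cells + n_doublets + config$n_empty_droplets
  barcodes <- random_barcodes(max(n_total, 1L), config$barcode_length)[
    seq_len(n_total)]

  counts <- rbind(singlets$counts, doublets$counts, empty_counts)
  dimnames(counts) <- list(barcodes, genes)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")

  truth <- data.frame(
    barcode = barcodes,
    droplet_class = rep(c("cell", "doublet", "empty"),
                        c(n_cells, n_doublets, config$n_empty_droplets)),
    lineage = c(lineage, l1, rep(NA_character_, config$n_empty_droplets)),
    lineage2 = c(rep(NA_character_, n_cells), unname(l2),
                 rep(NA_character_, config$n_empty_droplets)),
    emt_flag = c(emt_flag, rep(FALSE, n_doublets),
                 rep(FALSE, config$n_empty_droplets)),
    s100a4_flag = c(s100_flag, rep(FALSE, n_doublets),
                    rep(FALSE, config$n_empty_droplets)),
    library_factor = c(singlets$lib, doublets$lib,
                       rep(NA_real_, config$n_empty_droplets)),
    true_total = c(singlets$total, doublets$total,
                   rep(config$ambient_total_mean,
                       config$n_empty_droplets)),
    sample = config$sample_id,
    stringsAsFactors = FALSE
  )
  list(counts = counts, truth = truth)
}
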