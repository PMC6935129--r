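#' Default per-lineage expression programs
#'
#' Builds the gene-level mean UMI rates for the four lineages found in the
#' mammary tumors: epithelial, stromal, T and myeloid cells. Each lineage
#' expresses a panel of exclusive marker genes (led by the canonical markers
#' Epcam/Krt18/Krt5, Col3a1/Vim/Bgn, Cd3e/Cd3d and Itgam/Mrc1/Lyz2) on top
#' of a shared housekeeping background, so that lineages are separable the
#' way immune/stromal/epithelial compartments are in real droplet data.
#'
#' @param n_background number of shared housekeeping genes.
#' @param n_specific number of lineage-exclusive genes per lineage
#'   (including the named markers).
#' @param background_total total mean UMIs contributed by the shared
#'   background program.
#' @param specific_total total mean UMIs contributed by each lineage's
#'   exclusive program.
#' @return named list of numeric rate vectors (gene -> mean UMI rate),
#'   one per lineage. All four share the same gene universe.
#' @export
default_lineage_programs <- function(n_background = 60L, n_specific = 15L,
                                     background_total = 600,
                                     specific_total = 600) {
  markers <- list(
    epithelial = c("Epcam", "Krt18", "Krt5"),
    stromal    = c("Col3a1", "Vim", "Bgn"),
    T          = c("Cd3e", "Cd3d"),
    myeloid    = c("Itgam", "Mrc1", "Lyz2")
  )
  bg_genes <- sprintf("Hk%03d", seq_len(n_background))
  # fixed decreasing background profile (Zipf-like, as in real libraries)
  bg_rates <- 1 / seq_len(n_background)^0.6
  bg_rates <- bg_rates / sum(bg_rates) * background_total
  names(bg_rates) <- bg_genes

  programs <- list()
  for (lin in names(markers)) {
    extra <- sprintf("%s.g%02d", c(epithelial = "Epi", stromal = "Str",
                                   T = "Tc", myeloid = "Mye")[[lin]],
                     seq_len(max(0L, n_specific - length(markers[[lin]]))))
    spec_genes <- c(markers[[lin]], extra)
    spec_rates <- 1 / seq_along(spec_genes)^0.5
    spec_rates <- spec_rates / sum(spec_rates) * specific_total
    names(spec_rates) <- spec_genes
    programs[[lin]] <- spec_rates
  }
  # unify gene universe: every program covers every gene (0 where silent)
  all_genes <- c(unlist(lapply(programs, names), use.names = FALSE), bg_genes)
  lapply(programs, function(p) {
    full <- setNames(numeric(length(all_genes)), all_genes)
    full[names(p)] <- p
    full[bg_genes] <- bg_rates
    full
  })
}

#' Simulation configuration for synthetic droplet scRNA-seq data
#'
#' Captures one tumor sample's generative conditions: lineage mixture,
#' per-lineage expression programs, empty (ambient-only) droplets,
#' cross-lineage doublets, a planted EMT program (Snai1/Twist1/Zeb1/Zeb2)
#' in a fraction of epithelial/stromal cells, and per-lineage S100a4
#' expression. Defaults mirror the pooled study composition: lineage
#' proportions 0.488/0.078/0.135/0.300 (epithelial/stromal/T/myeloid,
#' i.e. 2313/369/638/1423 of 4743 singlets) and a doublet share of
#' 252/4995 of non-empty droplets.
#'
#' @param n_real_cells number of real (singlet) cells before doublets.
#' @param lineage_proportions named fractions over
#'   epithelial/stromal/T/myeloid; must sum to 1.
#' @param doublet_rate fraction of non-empty droplets that are
#'   cross-lineage doublets, in `[0, 1)`.
#' @param n_empty_droplets number of ambient-only droplets.
#' @param ambient_total_mean expected total UMIs in an empty droplet.
#' @param programs per-lineage gene -> mean UMI rate maps
#'   (see [default_lineage_programs()]).
#' @param emt_fraction fraction of EMT-eligible cells (epithelial +
#'   stromal) carrying the EMT program; planted as an exact count.
#' @param emt_program_rate mean UMI rate added for each of
#'   Snai1/Twist1/Zeb1/Zeb2 in EMT-program cells.
#' @param s100a4_fraction named per-lineage fraction of cells expressing
#'   S100a4 (planted as exact counts within lineage).
#' @param s100a4_rates named per-lineage mean S100a4 UMI rate among
#'   expressing cells.
#' @param library_size_dispersion log-normal sd of the per-cell library
#'   size factor (0 = all cells share the same expected depth).
#' @param nb_dispersion negative-binomial dispersion of per-gene counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson noise.
#' @param barcode_length,umi_length droplet barcode and UMI lengths
#'   (10x v2 geometry by default).
#' @param sample_id sample label attached to every droplet.
#' @param seed integer seed; all randomness in the generator flows from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_real_cells = 4743L,
                       lineage_proportions = c(epithelial = 2313 / 4743,
                                               stromal = 369 / 4743,
                                               T = 638 / 4743,
                                               myeloid = 1423 / 4743),
                       doublet_rate = 252 / 4995,
                       n_empty_droplets = 10000L,
                       ambient_total_mean = 40,
                       programs = default_lineage_programs(),
                       emt_fraction = 0.2,
                       emt_program_rate = 2.5,
                       s100a4_fraction = c(epithelial = 0.4, stromal = 0.4,
                                           T = 0.4, myeloid = 0.4),
                       s100a4_rates = c(epithelial = 8, stromal = 8,
                                        T = 8, myeloid = 8),
                       library_size_dispersion = 0.35,
                       nb_dispersion = 0.05,
                       barcode_length = 16L,
                       umi_length = 10L,
                       sample_id = "sample1",
                       seed = 1L) {
  lineages <- names(programs)
  lineage_proportions <- lineage_proportions / 1  # keep names
  if (is.null(names(lineage_proportions)) ||
      !setequal(names(lineage_proportions), lineages)) {
    stop("lineage_proportions must be named for lineages: ",
         paste(lineages, collapse = ", "))
  }
  lineage_proportions <- lineage_proportions[lineages]
  if (any(lineage_proportions < 0)) {
    stop("lineage_proportions must be non-negative and sum to 1")
  }
  if (abs(sum(lineage_proportions) - 1) > 1e-9) {
    stop("lineage_proportions must sum to 1 (got ",
         format(sum(lineage_proportions)), ")")
  }
  rates <- unlist(programs, use.names = FALSE)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("expression program rates must be finite and non-negative")
  }
  if (doublet_rate < 0 || doublet_rate >= 1) {
    stop("doublet_rate must be in [0, 1)")
  }
  stopifnot(n_real_cells >= 0, n_empty_droplets >= 0,
            ambient_total_mean >= 0, emt_fraction >= 0, emt_fraction <= 1,
            emt_program_rate >= 0, library_size_dispersion >= 0,
            nb_dispersion >= 0)
  if (any(s100a4_fraction < 0) || any(s100a4_fraction > 1) ||
      any(s100a4_rates < 0)) {
    stop("s100a4_fraction must lie in [0,1] and s100a4_rates must be >= 0")
  }
  cfg <- list(n_real_cells = as.integer(n_real_cells),
              lineage_proportions = lineage_proportions,
              doublet_rate = doublet_rate,
              n_empty_droplets = as.integer(n_empty_droplets),
              ambient_total_mean = ambient_total_mean,
              programs = programs,
              emt_fraction = emt_fraction,
              emt_program_rate = emt_program_rate,
              s100a4_fraction = s100a4_fraction[lineages],
              s100a4_rates = s100a4_rates[lineages],
              library_size_dispersion = library_size_dispersion,
              nb_dispersion = nb_dispersion,
              barcode_length = as.integer(barcode_length),
              umi_length = as.integer(umi_length),
              sample_id = sample_id,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic droplet simulation config (sample ", x$sample_id, ")\n",
      sep = "")
  cat("  real cells:", x$n_real_cells,
      "| doublet rate:", signif(x$doublet_rate, 3),
      "| empty droplets:", x$n_empty_droplets, "\n")
  cat("  lineage proportions:",
      paste(names(x$lineage_proportions),
            signif(x$lineage_proportions, 3), collapse = ", "), "\n")
  cat("  EMT fraction (epithelial+stromal):", x$emt_fraction,
      "| S100a4 fractions:",
      paste(signif(x$s100a4_fraction, 3), collapse = "/"), "\n")
  cat("  genes:", length(x$programs[[1]]) + 5L, "| seed:", x$seed, "\n")
  invisible(x)
}

#' Preset configurations for the two-sample tumor comparison
#'
#' Returns configs for a malignant-like tumor (EMT-program fraction 0.37,
#' S100a4-expressing fraction 0.51) and a benign fibroadenoma-like tumor
#' (0.11 and 0.26), the planted analogue of the malignant-vs-benign
#' contrast reported for these signatures.
#'
#' @param n_cells cells per sample.
#' @param seed base seed; the second sample uses a derived substream.
#' @return named list of two `sim_config` objects.
#' @export
tumor_presets <- function(n_cells = 1500L, seed = 1L) {
  list(
    malignant = sim_config(
      n_real_cells = n_cells, emt_fraction = 0.37,
      s100a4_fraction = c(epithelial = 0.51, stromal = 0.51,
                          T = 0.51, myeloid = 0.51),
      n_empty_droplets = 2000L, sample_id = "malignant",
      seed = derive_seed(seed, "malignant")),
    fibroadenoma = sim_config(
      n_real_cells = n_cells, emt_fraction = 0.11,
      s100a4_fraction = c(epithelial = 0.26, stromal = 0.26,
                          T = 0.26, myeloid = 0.26),
      n_empty_droplets = 2000L, sample_id = "fibroadenoma",
      seed = derive_seed(seed, "fibroadenoma"))
  )
}
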