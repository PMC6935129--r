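#' Pipeline configuration
#'
#' Bundles every stage's parameters in one validated, auditable object.
#' All randomness flows from the single `seed` through per-stage
#' substreams derived by hashing the stage name.
#'
#' @param sim a [sim_config()] for the synthetic input (or NULL to start
#'   from `counts_dir`).
#' @param outdir output directory for all stage artifacts.
#' @param seed master run seed.
#' @param read_level simulate tagged reads and re-quantify them (TRUE)
#'   or use the simulated count matrix directly (FALSE).
#' @param reads_per_umi_mean,umi_error_rate read-level simulation
#'   parameters (see [simulate_tagged_reads()]).
#' @param rank_anchor,factor cell-calling parameters
#'   (see [compute_cell_cutoff()]).
#' @param n_hvg,n_pcs embedding parameters.
#' @param k_max,models mixture-selection parameters (see [select_gmm()]).
#' @param panels,auc_threshold annotation parameters
#'   (see [merge_superclusters()]).
#' @param emt_genes,target_gene,min_umi signature parameters.
#' @param counts_dir optional pre-existing count matrix directory used
#'   when `sim` is NULL.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), outdir = tempfile("run"),
                            seed = 1L, read_level = TRUE,
                            reads_per_umi_mean = 1.5,
                            umi_error_rate = 0.02,
                            rank_anchor = 30L, factor = 0.1,
                            n_hvg = 1000L, n_pcs = 20L, k_max = 20L,
                            models = GMM_MODELS,
                            panels = default_marker_panels(),
                            auc_threshold = 0.7,
                            emt_genes = c("Snai1", "Twist1", "Zeb1",
                                          "Zeb2"),
                            target_gene = "S100a4", min_umi = 1L,
                            counts_dir = NULL) {
  stopifnot(factor > 0, rank_anchor >= 1, n_hvg >= 1, n_pcs >= 1,
            k_max >= 1, auc_threshold > 0, auc_threshold < 1,
            min_umi >= 1)
  if (is.null(sim) && is.null(counts_dir)) {
    stop("either a sim config or counts_dir must be given")
  }
  structure(list(sim = sim, outdir = outdir, seed = as.integer(seed),
                 read_level = read_level,
                 reads_per_umi_mean = reads_per_umi_mean,
                 umi_error_rate = umi_error_rate,
                 rank_anchor = as.integer(rank_anchor), factor = factor,
                 n_hvg = as.integer(n_hvg), n_pcs = as.integer(n_pcs),
                 k_max = as.integer(k_max), models = models,
                 panels = panels, auc_threshold = auc_threshold,
                 emt_genes = emt_genes, target_gene = target_gene,
                 min_umi = as.integer(min_umi), counts_dir = counts_dir),
            class = "pipeline_config")
}

pipeline_log <- function(stage, msg, ...) {
  message(sprintf("[%s] %s", stage, sprintf(msg, ...)))
}

#' Run the full heterogeneity pipeline
#'
#' Executes simulate -> quantify -> callcells -> cluster -> annotate ->
#' score sequentially, writing each stage's artifacts under
#' `config$outdir` plus a machine-readable `manifest.json` (stage,
#' parameters, outputs with md5 checksums, durations, warnings).
#' Rerunning with an identical config reproduces identical outputs. A
#' stage failure aborts with the stage name and leaves a `.failed`
#' marker file.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list with the in-memory stage results (`sim`, `counts`,
#'   `called`, `norm`, `embedding`, `fit`, `labels`, `markers`,
#'   `assignment`, `composition`, `signatures`) and `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$outdir)) dir.create(config$outdir,
                                             recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  res <- list()
  say <- if (quiet) function(...) invisible() else pipeline_log

  run_stage <- function(name, params, fun) {
    t0 <- proc.time()[["elapsed"]]
    warns <- character(0)
    out <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        writeLines(conditionMessage(e),
                   file.path(config$outdir, paste0(name, ".failed")))
        stop(sprintf("pipeline stage '%s' failed: %s", name,
                     conditionMessage(e)), call. = FALSE)
      }),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    files <- out$files %||% character(0)
    manifest$stages[[name]] <<- list(
      stage = name, parameters = params,
      outputs = as.list(if (length(files))
        setNames(as.character(tools::md5sum(files)), basename(files))
        else setNames(list(), character(0))),
      warnings = warns,
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    say(name, "done in %.1fs", proc.time()[["elapsed"]] - t0)
    out$value
  }

  # -- simulate ------------------------------------------------------
  sim <- run_stage("simulate",
                   list(seed = config$seed,
                        read_level = config$read_level), function() {
    if (is.null(config$sim)) {
      counts <- read_count_matrix(config$counts_dir)
      return(list(value = list(counts = counts, truth = NULL),
                  files = character(0)))
    }
    cfg <- config$sim
    cfg$seed <- derive_seed(config$seed, "simulate")
    simres <- simulate_tumor_counts(cfg)
    dir_raw <- file.path(config$outdir, "raw_counts")
    write_count_matrix(simres$counts, dir_raw)
    truth_path <- file.path(config$outdir, "truth.tsv")
    write.table(simres$truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(file.path(dir_raw, c("matrix.mtx", "barcodes.tsv",
                                    "features.tsv")), truth_path)
    if (config$read_level) {
      reads <- simulate_tagged_reads(
        simres$counts, reads_per_umi_mean = config$reads_per_umi_mean,
        umi_error_rate = config$umi_error_rate,
        umi_length = cfg$umi_length,
        seed = derive_seed(config$seed, "reads"))
      rp <- file.path(config$outdir, "reads.tsv.gz")
      write_tagged_reads(reads, rp)
      simres$reads <- reads
      files <- c(files, rp)
    }
    list(value = simres, files = files)
  })
  res$sim <- sim

  # -- quantify ------------------------------------------------------
  counts <- run_stage("quantify", list(read_level = config$read_level),
                      function() {
    if (config$read_level && !is.null(sim$reads)) {
      q <- quantify_reads(sim$reads, whitelist = rownames(sim$counts),
                          genes = colnames(sim$counts))
      qd <- file.path(config$outdir, "quant_counts")
      write_count_matrix(q$counts, qd)
      sp <- file.path(config$outdir, "quantify_stats.json")
      jsonlite::write_json(q$stats, sp, auto_unbox = TRUE)
      list(value = q$counts,
           files = c(file.path(qd, c("matrix.mtx", "barcodes.tsv",
                                     "features.tsv")), sp))
    } else {
      list(value = sim$counts, files = character(0))
    }
  })
  res$counts <- counts

  # -- callcells -----------------------------------------------------
  called <- run_stage("callcells",
                      list(rank_anchor = config$rank_anchor,
                           factor = config$factor), function() {
    cc <- call_cells(counts, rank_anchor = config$rank_anchor,
                     factor = config$factor)
    fd <- file.path(config$outdir, "filtered_counts")
    write_count_matrix(cc$counts, fd)
    qc <- file.path(config$outdir, "callcells_qc.json")
    norm <- normalize_counts(cc$counts)
    jsonlite::write_json(list(cutoff = cc$cutoff,
                              n_retained = nrow(cc$counts),
                              median_total = norm$median_total),
                         qc, auto_unbox = TRUE, digits = NA)
    list(value = list(called = cc, norm = norm),
         files = c(file.path(fd, c("matrix.mtx", "barcodes.tsv",
                                   "features.tsv")), qc))
  })
  res$called <- called$called
  res$norm <- called$norm

  # -- cluster -------------------------------------------------------
  clust <- run_stage("cluster",
                     list(n_hvg = config$n_hvg, n_pcs = config$n_pcs,
                          k_max = config$k_max,
                          models = paste(config$models,
                                         collapse = ",")), function() {
    hvg <- select_variable_genes(res$norm, n = config$n_hvg)
    emb <- run_pca(res$norm, genes = hvg,
                   n_components = config$n_pcs)
    fit <- select_gmm(emb$scores, k_max = config$k_max,
                      models = config$models,
                      seed = derive_seed(config$seed, "cluster"))
    labels <- assign_clusters(fit)
    lp <- file.path(config$outdir, "cluster_labels.tsv")
    write.table(data.frame(barcode = rownames(res$norm$values),
                           cluster = labels),
                lp, sep = "\t", quote = FALSE, row.names = FALSE)
    mp <- file.path(config$outdir, "model_selection.tsv")
    write.table(fit$bic_table, mp, sep = "\t", quote = FALSE,
                row.names = FALSE)
    sp <- file.path(config$outdir, "pca_scores.tsv")
    write.table(round(emb$scores, 6), sp, sep = "\t", quote = FALSE,
                col.names = NA)
    list(value = list(embedding = emb, fit = fit, labels = labels),
         files = c(lp, mp, sp))
  })
  res$embedding <- clust$embedding
  res$fit <- clust$fit
  res$labels <- clust$labels
  if (isTRUE(res$fit$boundary_k)) {
    manifest$stages$cluster$warnings <- unique(c(
      manifest$stages$cluster$warnings,
      sprintf("selected k = %d equals k_max", res$fit$k)))
  }

  # -- annotate ------------------------------------------------------
  ann <- run_stage("annotate",
                   list(auc_threshold = config$auc_threshold),
                   function() {
    markers <- cluster_markers(res$norm, res$labels)
    assignment <- merge_superclusters(markers, panels = config$panels,
                                      labels = res$labels,
                                      auc_threshold =
                                        config$auc_threshold)
    cell_samples <- cell_sample_labels(res$sim$truth,
                                       rownames(res$norm$values))
    comp <- composition_summary(assignment$cell_labels, cell_samples)
    mk <- file.path(config$outdir, "markers.tsv")
    write.table(markers, mk, sep = "\t", quote = FALSE,
                row.names = FALSE)
    ap <- file.path(config$outdir, "superclusters.tsv")
    write.table(data.frame(cluster = names(assignment$cluster_map),
                           supercluster = assignment$cluster_map),
                ap, sep = "\t", quote = FALSE, row.names = FALSE)
    cp <- file.path(config$outdir, "composition.tsv")
    write.table(comp$full, cp, sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(value = list(markers = markers, assignment = assignment,
                      composition = comp, samples = cell_samples),
         files = c(mk, ap, cp))
  })
  res$markers <- ann$markers
  res$assignment <- ann$assignment
  res$composition <- ann$composition

  # -- score ---------------------------------------------------------
  sig <- run_stage("score", list(min_umi = config$min_umi), function() {
    cm <- res$called$counts
    emt <- emt_call(cm, emt_genes = config$emt_genes,
                    min_umi = config$min_umi)
    s100 <- gene_positive_call(cm, gene = config$target_gene,
                               min_umi = config$min_umi)
    pcts_emt <- signature_percentages(emt, ann$samples,
                                      ann$assignment$cell_labels)
    pcts_s100 <- signature_percentages(s100, ann$samples,
                                       ann$assignment$cell_labels)
    calls <- data.frame(barcode = rownames(cm), sample = ann$samples,
                        supercluster = ann$assignment$cell_labels,
                        emt_positive = as.logical(emt),
                        target_positive = s100)
    cp <- file.path(config$outdir, "signature_calls.tsv")
    write.table(calls, cp, sep = "\t", quote = FALSE,
                row.names = FALSE)
    summ <- rbind(cbind(signature = "EMT", pcts_emt$per_sample),
                  cbind(signature = config$target_gene,
                        pcts_s100$per_sample))
    sp <- file.path(config$outdir, "signature_summary.tsv")
    write.table(summ, sp, sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = list(emt = pcts_emt, target = pcts_s100,
                      calls = calls), files = c(cp, sp))
  })
  res$signatures <- sig

  mp <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  res$manifest_path <- mp
  res
}

# map retained barcodes to their sample labels via the simulation truth
# (falls back to a single unnamed sample when truth is absent)
cell_sample_labels <- function(truth, barcodes) {
  if (is.null(truth)) return(rep("sample1", length(barcodes)))
  idx <- match(barcodes, truth$barcode)
  smp <- truth$sample[idx]
  smp[is.na(smp)] <- "unknown"
  smp
}
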