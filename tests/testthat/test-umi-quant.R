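test_that("demultiplexing keeps exact barcode matches only", {
  reads <- data.frame(
    barcode = c("AAAA", "AAAT", "CCCC", "AAAA"),
    umi = c("AC", "AC", "GG", "TT"),
    gene = "g1", orientation = "sense", stringsAsFactors = FALSE)
  out <- demultiplex(reads, whitelist = c("AAAA", "CCCC"))
  expect_equal(nrow(out), 3L)
  expect_equal(attr(out, "n_discarded"), 1L)  # AAAT is distance 1: dropped
  expect_false("AAAT" %in% out$barcode)

  empty <- demultiplex(reads[0, ], whitelist = c("AAAA", "CCCC"))
  expect_equal(nrow(empty), 0L)
  expect_equal(levels(empty$barcode), c("AAAA", "CCCC"))

  expect_error(demultiplex(reads, whitelist = "AAAAA"), "length mismatch")
  expect_error(demultiplex(reads, whitelist = character(0)), "non-empty")
})

test_that("UMI collapsing follows the one-mismatch component rule", {
  expect_equal(collapse_umis(character(0)), 0L)
  expect_equal(collapse_umis(c("ACGT", "ACGT")), 1L)
  expect_equal(collapse_umis(c("AAAA", "AAAT", "TTTT")), 2L)
  # transitive chaining: AAAA-AAAT-AATT is one component
  expect_equal(collapse_umis(c("AAAA", "AAAT", "AATT")), 1L)
  expect_error(collapse_umis(c("AAA", "AAAA")), "same length")
})

test_that("UMI collapsing matches the brute-force component oracle", {
  set.seed(77)
  for (i in 1:400) {
    umis <- random_umis(sample(1:12, 1), 4L)
    expect_equal(collapse_umis(umis), oracle_umi_components(umis),
                 info = paste(umis, collapse = ","))
  }
})

test_that("transcript counting deduplicates and filters orientation", {
  one <- data.frame(barcode = "AAAA", umi = "ACGTACGTAC", gene = "geneX",
                    orientation = "sense", stringsAsFactors = FALSE)
  m <- count_transcripts(one)
  expect_equal(as.numeric(m["AAAA", "geneX"]), 1)

  dup <- one[rep(1, 10), ]
  expect_equal(as.numeric(count_transcripts(dup)["AAAA", "geneX"]), 1)

  mixed <- rbind(one,
                 data.frame(barcode = "AAAA", umi = "TTTTTTTTTT",
                            gene = "geneX", orientation = "antisense",
                            stringsAsFactors = FALSE))
  expect_equal(as.numeric(count_transcripts(mixed)["AAAA", "geneX"]), 1)
  expect_equal(attr(count_transcripts(mixed), "n_dropped"), 1L)

  nogene <- rbind(one, data.frame(barcode = "AAAA", umi = "GGGGGGGGGG",
                                  gene = NA_character_,
                                  orientation = "sense",
                                  stringsAsFactors = FALSE))
  expect_equal(sum(count_transcripts(nogene)), 1)
})

test_that("reads round-trip to the true counts without UMI errors", {
  s <- simulate_tumor_counts(small_sim(n_cells = 40L, n_empty = 30L,
                                       seed = 19L))
  # 16-base UMIs keep the UMI space far from saturated at these depths
  reads <- simulate_tagged_reads(s$counts, reads_per_umi_mean = 1,
                                 umi_error_rate = 0, umi_length = 16L,
                                 seed = 4L)
  q <- quantify_reads(reads, whitelist = rownames(s$counts),
                      genes = colnames(s$counts))
  expect_equal(as.matrix(q$counts), as.matrix(s$counts))
  expect_equal(q$stats$reads_discarded_barcode, 0L)
})

test_that("distance-1 UMI errors collapse back to the true counts", {
  s <- simulate_tumor_counts(small_sim(n_cells = 25L, n_empty = 10L,
                                       seed = 29L))
  expect_gt(sum(s$counts), 1000)
  reads <- simulate_tagged_reads(s$counts, reads_per_umi_mean = 4,
                                 umi_error_rate = 0.2, umi_length = 16L,
                                 seed = 6L)
  expect_gt(nrow(reads), sum(s$counts))
  q <- quantify_reads(reads, whitelist = rownames(s$counts),
                      genes = colnames(s$counts))
  expect_equal(as.matrix(q$counts), as.matrix(s$counts))
})

test_that("total counted transcripts never exceed retained sense reads", {
  s <- simulate_tumor_counts(small_sim(n_cells = 30L, n_empty = 10L,
                                       seed = 37L))
  reads <- simulate_tagged_reads(s$counts, reads_per_umi_mean = 2,
                                 umi_error_rate = 0.1,
                                 antisense_fraction = 0.2, seed = 8L)
  q <- quantify_reads(reads, whitelist = rownames(s$counts),
                      genes = colnames(s$counts))
  n_sense <- sum(reads$orientation == "sense")
  expect_lte(sum(q$counts), n_sense)
})

test_that("tagged-read simulation validates inputs", {
  s <- simulate_tumor_counts(small_sim(n_cells = 5L, n_empty = 0L,
                                       seed = 3L))
  expect_error(simulate_tagged_reads(s$counts, reads_per_umi_mean = 0),
               "positive")
  one_mol <- Matrix::sparseMatrix(i = 1, j = 1, x = 1,
                                  dimnames = list("AAAA", "geneX"))
  r <- simulate_tagged_reads(one_mol, reads_per_umi_mean = 5, seed = 2L)
  expect_gte(nrow(r), 1L)
  expect_true(all(r$barcode == "AAAA" & r$gene == "geneX"))
})

test_that("indel allele frequency is a guarded ratio", {
  expect_equal(indel_allele_frequency(93, 100), 0.93)
  expect_equal(indel_allele_frequency(0, 50), 0)
  af <- indel_allele_frequency(999, 1000)
  expect_equal(af, 0.999)
  expect_true(af >= 0.932 && af <= 0.999)  # knockout-confirmation range
  expect_error(indel_allele_frequency(1, 0), "undefined")
  expect_error(indel_allele_frequency(5, 3), "lie in")
})
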