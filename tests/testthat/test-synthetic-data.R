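test_that("sim_config validates its invariants", {
  expect_error(sim_config(lineage_proportions = c(epithelial = 0.5,
                                                  stromal = 0.5,
                                                  T = 0.1,
                                                  myeloid = -0.1)),
               "sum to 1")
  expect_error(sim_config(doublet_rate = 1), "doublet_rate")
  bad <- default_lineage_programs()
  bad$epithelial[1] <- -1
  expect_error(sim_config(programs = bad), "non-negative")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("no-cells and zero-EMT configurations behave as stated", {
  cfg <- sim_config(n_real_cells = 0L, n_empty_droplets = 5L,
                    doublet_rate = 0, seed = 3L)
  s <- simulate_tumor_counts(cfg)
  expect_equal(nrow(s$counts), 5L)
  expect_true(all(is.na(s$truth$lineage)))
  expect_true(all(s$truth$droplet_class == "empty"))

  cfg2 <- small_sim(emt_fraction = 0, seed = 11L)
  s2 <- simulate_tumor_counts(cfg2)
  emt_cols <- intersect(c("Snai1", "Twist1", "Zeb1", "Zeb2"),
                        colnames(s2$counts))
  expect_equal(sum(s2$counts[, emt_cols]), 0)
  expect_false(any(s2$truth$emt_flag))
})

test_that("lineage counts fall within binomial sampling bounds", {
  cfg <- sim_config(n_real_cells = 4743L, doublet_rate = 0,
                    n_empty_droplets = 0L, seed = 17L)
  s <- simulate_tumor_counts(cfg)
  tab <- table(s$truth$lineage)
  n <- 4743
  for (lin in names(cfg$lineage_proportions)) {
    p <- cfg$lineage_proportions[[lin]]
    expect_lt(abs(tab[[lin]] - n * p), 3 * sqrt(n * p * (1 - p)))
  }
})

test_that("planted EMT and S100a4 fractions are exact over eligible cells", {
  cfg <- small_sim(n_cells = 500L, emt_fraction = 0.37, seed = 23L)
  s <- simulate_tumor_counts(cfg)
  singl <- s$truth[s$truth$droplet_class == "cell", ]
  elig <- singl$lineage %in% c("epithelial", "stromal")
  expect_equal(sum(singl$emt_flag[elig]), floor(0.37 * sum(elig) + 0.5))
  expect_false(any(singl$emt_flag[!elig]))
  for (lin in unique(singl$lineage)) {
    idx <- singl$lineage == lin
    expect_equal(sum(singl$s100a4_flag[idx]),
                 floor(cfg$s100a4_fraction[[lin]] * sum(idx) + 0.5))
  }
})

test_that("fixed seed gives bit-identical simulations", {
  s1 <- simulate_tumor_counts(small_sim(seed = 9L))
  s2 <- simulate_tumor_counts(small_sim(seed = 9L))
  expect_identical(as.matrix(s1$counts), as.matrix(s2$counts))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_tumor_counts(small_sim(seed = 10L))
  expect_false(identical(as.matrix(s1$counts), as.matrix(s3$counts)))
})

test_that("per-gene singlet means converge to program rates", {
  cfg <- sim_config(n_real_cells = 3000L, doublet_rate = 0,
                    n_empty_droplets = 0L, emt_fraction = 0,
                    library_size_dispersion = 0, nb_dispersion = 0.05,
                    seed = 31L)
  s <- simulate_tumor_counts(cfg)
  lin <- "epithelial"
  idx <- s$truth$lineage == lin
  rates <- cfg$programs[[lin]]
  top <- names(sort(rates, decreasing = TRUE))[1:5]
  for (g in top) {
    obs <- s$counts[idx, g]
    se <- sd(obs) / sqrt(sum(idx))
    expect_lt(abs(mean(obs) - rates[[g]]), 3 * se + 1e-9)
  }
})

test_that("doublets carry two distinct lineages and cells carry one", {
  s <- simulate_tumor_counts(small_sim(seed = 13L))
  tr <- s$truth
  dbl <- tr$droplet_class == "doublet"
  expect_true(all(!is.na(tr$lineage2[dbl])))
  expect_true(all(tr$lineage[dbl] != tr$lineage2[dbl]))
  expect_true(all(is.na(tr$lineage2[tr$droplet_class == "cell"])))
  expect_true(all(is.na(tr$lineage[tr$droplet_class == "empty"])))
})

test_that("alteration table reproduces exact deterministic counts", {
  # the breast-cancer contingency: 4485 samples, 1389 PIK3CA,
  # 2763 TP53, 678 double-positive
  tab <- simulate_alteration_table(4485, 1389 / 4485, 2763 / 4485,
                                   678 / 4485, seed = 2L)
  expect_equal(sum(tab[, "PIK3CA"] & tab[, "TP53"]), 678)
  expect_equal(unname(colSums(tab)), c(1389, 2763))
  expect_equal(nrow(tab), 4485)

  tab2 <- simulate_alteration_table(10, 0.5, 0.5, 0, genes = c("A", "B"))
  expect_equal(sum(tab2[, "A"] & tab2[, "B"]), 0)
  expect_equal(unname(colSums(tab2)), c(5, 5))
})

test_that("infeasible joint fractions are rejected with the bound", {
  expect_error(simulate_alteration_table(100, 0.2, 0.3, 0.25),
               "must lie in")
  expect_error(simulate_alteration_table(100, 0.9, 0.9, 0.5),
               "must lie in")
})

test_that("column sums equal rounded marginal counts for random tables", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(50:500, 1)
    fa <- runif(1, 0.1, 0.9)
    fb <- runif(1, 0.1, 0.9)
    joint <- runif(1, max(0, fa + fb - 1), min(fa, fb))
    tab <- tryCatch(simulate_alteration_table(n, fa, fb, joint, seed = i),
                    error = function(e) NULL)
    if (is.null(tab)) next  # rounding inconsistency rejected explicitly
    expect_equal(unname(colSums(tab)), floor(c(n * fa, n * fb) + 0.5))
  }
})
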