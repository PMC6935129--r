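make_two_cluster_values <- function(x_in, x_out, gene = "g") {
  values <- matrix(c(x_in, x_out), ncol = 1,
                   dimnames = list(NULL, gene))
  list(values = values, labels = rep(c(1L, 2L),
                                     c(length(x_in), length(x_out))))
}

test_that("the separated 3-vs-3 case gives U = 0 and exact p = 0.1", {
  d <- make_two_cluster_values(c(1, 2, 3), c(4, 5, 6))
  mk <- cluster_markers(d$values, d$labels)
  row1 <- mk[mk$cluster == 1, ]
  expect_equal(row1$u_statistic, 0)
  expect_equal(row1$auc, 0)
  expect_equal(row1$p_value, 0.1)
  # complementary cluster sees the mirrored effect
  row2 <- mk[mk$cluster == 2, ]
  expect_equal(row2$auc, 1)
  expect_equal(row2$p_value, 0.1)
})

test_that("constant genes give p = 1 and auc = 0.5", {
  values <- cbind(flat = rep(3.3, 12), sig = c(rep(5, 6), rep(0, 6)))
  labels <- rep(c(1L, 2L), each = 6)
  mk <- cluster_markers(values, labels)
  flat <- mk[mk$gene == "flat", ]
  expect_true(all(flat$p_value == 1))
  expect_true(all(flat$auc == 0.5))
})

test_that("exact p matches exhaustive enumeration on tie-free data", {
  set.seed(149)
  for (i in 1:60) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    x_in <- sample(seq_len(50), n1)
    x_out <- sample(setdiff(seq_len(50), x_in), n2)
    d <- make_two_cluster_values(x_in, x_out)
    mk <- cluster_markers(d$values, d$labels)
    p_pkg <- mk$p_value[mk$cluster == 1]
    expect_equal(p_pkg, oracle_wilcoxon_exact(x_in, x_out),
                 info = paste(c(x_in, "|", x_out), collapse = " "))
  }
})

test_that("normal approximation stays close to the exact p", {
  set.seed(151)
  rel_err <- replicate(50, {
    x_in <- sample(seq_len(100), 6)
    x_out <- sample(setdiff(seq_len(100), x_in), 6)
    r <- rank(c(x_in, x_out))
    u <- sum(r[1:6]) - 6 * 7 / 2
    p_norm <- tumorhet:::wilcoxon_p(u, 6, 6, rep(1L, 12),
                                    exact_limit = 0L)
    p_exact <- oracle_wilcoxon_exact(x_in, x_out)
    abs(p_norm - p_exact) / p_exact
  })
  expect_lt(median(rel_err), 0.1)
  expect_lt(max(rel_err), 0.35)
})

test_that("auc is antisymmetric between the two groups", {
  set.seed(157)
  values <- matrix(rnorm(40 * 3), 40, 3,
                   dimnames = list(NULL, c("a", "b", "c")))
  labels <- rep(c(1L, 2L), each = 20)
  mk <- cluster_markers(values, labels)
  for (g in c("a", "b", "c")) {
    a1 <- mk$auc[mk$cluster == 1 & mk$gene == g]
    a2 <- mk$auc[mk$cluster == 2 & mk$gene == g]
    expect_equal(a1 + a2, 1)
  }
})

test_that("BH adjustment is applied within each cluster", {
  set.seed(163)
  values <- matrix(rnorm(30 * 8), 30, 8,
                   dimnames = list(NULL, paste0("g", 1:8)))
  labels <- rep(c(1L, 2L, 3L), each = 10)
  mk <- cluster_markers(values, labels)
  for (cl in 1:3) {
    sub <- mk[mk$cluster == cl, ]
    expect_equal(sub$adjusted_p, p.adjust(sub$p_value, "BH"))
    expect_true(all(sub$adjusted_p >= sub$p_value))
  }
})

test_that("tiny clusters are skipped with a warning", {
  values <- matrix(rnorm(11 * 2), 11, 2,
                   dimnames = list(NULL, c("a", "b")))
  labels <- c(rep(1L, 5), rep(2L, 5), 3L)
  expect_warning(mk <- cluster_markers(values, labels), "fewer than 2")
  expect_false(3 %in% mk$cluster)
})

fake_marker_table <- function(aucs) {
  # aucs: named list cluster -> named gene auc vector
  do.call(rbind, lapply(names(aucs), function(cl) {
    data.frame(cluster = as.integer(cl), gene = names(aucs[[cl]]),
               u_statistic = NA_real_, auc = unname(aucs[[cl]]),
               p_value = 0.01, adjusted_p = 0.02, mean_in = 1,
               mean_out = 0, stringsAsFactors = FALSE)
  }))
}

panel_genes <- unlist(default_marker_panels(), use.names = FALSE)

test_that("supercluster merging follows the panel-auc decision rule", {
  base <- setNames(rep(0.4, length(panel_genes)), panel_genes)
  epi <- base; epi[c("Epcam", "Krt18", "Krt5")] <- c(0.95, 0.9, 0.85)
  dbl <- base; dbl[c("Epcam", "Krt18", "Krt5")] <- 0.9
  dbl[c("Cd3e", "Cd3d")] <- 0.85
  none <- base
  mk <- fake_marker_table(list(`1` = epi, `2` = dbl, `3` = none))
  labels <- rep(c(1L, 2L, 3L), each = 4)
  asg <- merge_superclusters(mk, labels = labels)
  expect_equal(unname(asg$cluster_map[c("1", "2", "3")]),
               c("epithelial", "multiplet", "unassigned"))
  expect_equal(asg$cell_labels,
               rep(c("epithelial", "multiplet", "unassigned"), each = 4))
})

test_that("panel scoring averages only present genes and errors when all are absent", {
  present <- setdiff(panel_genes, "Krt5")
  base <- setNames(rep(0.4, length(present)), present)
  epi <- base; epi[c("Epcam", "Krt18")] <- 0.9
  mk <- fake_marker_table(list(`1` = epi, `2` = base))
  expect_warning(asg <- merge_superclusters(mk, labels = rep(1:2, 3)),
                 "Krt5")
  expect_equal(unname(asg$panel_scores["1", "epithelial"]), 0.9)
  onlyT <- fake_marker_table(list(`1` = c(Cd3e = 0.9, Cd3d = 0.9)))
  expect_error(suppressWarnings(
    merge_superclusters(onlyT, labels = rep(1L, 3))), "panel")
})

test_that("assignment is invariant to cluster relabeling", {
  base <- setNames(rep(0.3, length(panel_genes)), panel_genes)
  a <- base; a[c("Epcam", "Krt18", "Krt5")] <- 0.9
  b <- base; b[c("Cd3e", "Cd3d")] <- 0.95
  mk12 <- fake_marker_table(list(`1` = a, `2` = b))
  mk21 <- fake_marker_table(list(`1` = b, `2` = a))
  lab <- rep(c(1L, 2L), each = 5)
  asg12 <- merge_superclusters(mk12, labels = lab)
  asg21 <- merge_superclusters(mk21, labels = 3L - lab)
  expect_equal(asg12$cell_labels, asg21$cell_labels)
})

test_that("composition sums match the printed pooled totals", {
  sizes <- c(epithelial = 2313L, stromal = 369L, T = 638L,
             myeloid = 1423L, multiplet = 252L)
  cell_labels <- rep(names(sizes), sizes)
  samples <- rep("pooled", sum(sizes))
  comp <- composition_summary(cell_labels, samples)
  expect_equal(sum(comp$full$count), 4995L)
  expect_equal(sum(comp$full$percent), 100, tolerance = 1e-8)
  excl <- comp$excluding_multiplets
  expect_equal(sum(excl$count), 4995L - 252L)
  expect_false("multiplet" %in% excl$supercluster)
  expect_equal(sum(excl$percent), 100, tolerance = 1e-8)
})

test_that("single-label samples report 100 percent", {
  comp <- composition_summary(rep("epithelial", 7), rep("s1", 7))
  expect_equal(comp$full$percent, 100)
})

test_that("per-sample percentages always sum to 100", {
  set.seed(167)
  labs <- sample(c("epithelial", "stromal", "T", "myeloid", "multiplet"),
                 300, replace = TRUE)
  smps <- sample(c("a", "b", "c"), 300, replace = TRUE)
  comp <- composition_summary(labs, smps)
  sums <- tapply(comp$full$percent, comp$full$sample, sum)
  expect_true(all(abs(sums - 100) < 1e-8))
})
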