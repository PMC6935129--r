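# shared fixtures and independent oracles

# adjusted Rand index (independent of any clustering code under test)
ari <- function(a, b) {
  t <- table(a, b)
  n <- length(a)
  si <- sum(choose(rowSums(t), 2))
  sj <- sum(choose(colSums(t), 2))
  sij <- sum(choose(t, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# brute-force connected-component count over the Hamming<=1 graph,
# via pairwise distances and repeated flood fill (independent of the
# neighbor-hashing union-find in the package)
oracle_umi_components <- function(umis) {
  u <- unique(umis)
  n <- length(u)
  if (n == 0L) return(0L)
  hd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- hd(u[i], u[j]) <= 1
  }
  seen <- rep(FALSE, n)
  comps <- 0L
  for (i in seq_len(n)) {
    if (seen[i]) next
    comps <- comps + 1L
    frontier <- i
    while (length(frontier)) {
      seen[frontier] <- TRUE
      frontier <- which(apply(adj[frontier, , drop = FALSE], 2, any) &
                          !seen)
    }
  }
  comps
}

random_umis <- function(n, width) {
  apply(matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
               nrow = n), 1, paste0, collapse = "")
}

# exact two-sided Wilcoxon p by exhaustive enumeration over all
# assignments of n1 values to the in-group (doubling rule)
oracle_wilcoxon_exact <- function(x_in, x_out) {
  vals <- c(x_in, x_out)
  n1 <- length(x_in)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(length(vals), n1)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# exact two-sided Fisher p by enumeration of hypergeometric tables
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b
  n <- c_ + d
  k <- a + c_
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small Gaussian cluster generator for mixture tests
make_gaussian_clusters <- function(n, k, d, sep, seed) {
  set.seed(seed)
  means <- matrix(0, k, d)
  for (j in seq_len(k)) means[j, 1L] <- sep * (j - 1)
  lab <- sample.int(k, n, replace = TRUE)
  list(x = means[lab, , drop = FALSE] + matrix(rnorm(n * d), n, d),
       labels = lab, means = means)
}

small_sim <- function(n_cells = 300L, n_empty = 600L, seed = 5L, ...) {
  sim_config(n_real_cells = n_cells, n_empty_droplets = n_empty,
             seed = seed, ...)
}
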