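test_that("parameter counts match the closed formulas and mclust", {
  # VVV, k=2, d=3: (k-1) + k*d + k*d(d+1)/2 = 1 + 6 + 12 = 19
  expect_equal(tumorhet:::gmm_n_params("VVV", 2, 3), 19)
  expect_equal(tumorhet:::gmm_n_params("EII", 3, 5), 2 + 15 + 1)
  expect_equal(tumorhet:::gmm_n_params("VEV", 4, 6),
               3 + 24 + (4 + 5 + 4 * 15))
  skip_if_not_installed("mclust")
  for (m in c("EII", "VII", "EEE", "VEV", "VVV")) {
    for (k in c(1, 2, 5)) {
      for (d in c(2, 7)) {
        expect_equal(tumorhet:::gmm_n_params(m, k, d),
                     mclust::nMclustParams(m, d, k),
                     info = paste(m, k, d))
      }
    }
  }
})

test_that("k = 1 spherical fit matches the closed-form MLE", {
  set.seed(83)
  x <- matrix(rnorm(500 * 3, mean = 2, sd = 1.7), 500, 3)
  fit <- fit_gmm(x, k = 1, model = "EII", seed = 1)
  mu_hat <- colMeans(x)
  expect_equal(unname(fit$means[1, ]), unname(mu_hat), tolerance = 1e-8)
  lam_hat <- sum(sweep(x, 2, mu_hat)^2) / (nrow(x) * ncol(x))
  expect_equal(fit$covariance$lambda, lam_hat, tolerance = 1e-8)
  ll_closed <- sum(dnorm(sweep(x, 2, mu_hat), sd = sqrt(lam_hat),
                         log = TRUE))
  expect_equal(fit$loglik, ll_closed, tolerance = 1e-6)
  expect_equal(fit$bic, -2 * ll_closed + 4 * log(500), tolerance = 1e-6)
})

test_that("duplicating the data doubles the log-likelihood exactly", {
  set.seed(89)
  x <- rbind(matrix(rnorm(100 * 2), 100, 2),
             matrix(rnorm(100 * 2, mean = 12), 100, 2))
  for (m in c("EII", "VVV")) {
    f1 <- fit_gmm(x, k = 2, model = m, seed = 3)
    f2 <- fit_gmm(rbind(x, x), k = 2, model = m, seed = 3)
    expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-4)
    o1 <- order(f1$means[, 1])
    o2 <- order(f2$means[, 1])
    expect_equal(f2$means[o2, ], f1$means[o1, ], tolerance = 1e-4)
    expect_equal(f2$weights[o2], f1$weights[o1], tolerance = 1e-6)
  }
})

test_that("well-separated clusters are recovered by every model", {
  g <- make_gaussian_clusters(n = 400, k = 2, d = 3, sep = 10, seed = 97)
  for (m in c("EII", "VII", "EEE", "VEV", "VVV")) {
    fit <- fit_gmm(g$x, k = 2, model = m, seed = 2)
    z <- fit$responsibilities
    expect_true(all(pmax(z[, 1], z[, 2]) > 0.999))
    o <- order(fit$means[, 1])
    expect_lt(max(abs(fit$means[o, ] - g$means)), 0.1)
    expect_equal(ari(assign_clusters(fit), g$labels), 1)
  }
})

test_that("compiled and reference EM engines agree", {
  g <- make_gaussian_clusters(n = 250, k = 3, d = 4, sep = 8, seed = 101)
  for (m in c("EII", "VII", "EEE", "VEV", "VVV")) {
    fc <- fit_gmm(g$x, k = 3, model = m, seed = 7, engine = "cpp")
    fr <- fit_gmm(g$x, k = 3, model = m, seed = 7, engine = "R")
    expect_equal(fc$loglik, fr$loglik, tolerance = 1e-6, info = m)
    expect_equal(fc$weights[order(fc$means[, 1])],
                 fr$weights[order(fr$means[, 1])], tolerance = 1e-6)
  }
})

test_that("EM log-likelihood is monotone non-decreasing", {
  set.seed(103)
  x <- rbind(matrix(rnorm(150 * 3), 150, 3),
             matrix(rnorm(150 * 3, mean = 2.5), 150, 3))
  for (m in c("EII", "VII", "EEE", "VEV", "VVV")) {
    fit <- fit_gmm(x, k = 3, model = m, seed = 5)
    expect_true(all(diff(fit$loglik_trace) >
                      -1e-6 * (1 + abs(fit$loglik))), info = m)
  }
})

test_that("fit agrees with mclust on a shared fixture", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  g <- make_gaussian_clusters(n = 600, k = 3, d = 4, sep = 9, seed = 107)
  for (m in c("EEE", "VEV", "VVV")) {
    ours <- fit_gmm(g$x, k = 3, model = m, seed = 11)
    mc <- mclust::Mclust(g$x, G = 3, modelNames = m, verbose = FALSE)
    # same optimum on clean data; mclust maximizes 2*ll - p*log(n)
    expect_equal(ours$loglik, mc$loglik, tolerance = 1e-4, info = m)
    expect_equal(ours$bic, -as.numeric(mc$bic), tolerance = 1e-3,
                 info = m)
    expect_equal(sort(ours$weights),
                 sort(mc$parameters$pro), tolerance = 1e-3)
  }
})

test_that("BIC selection finds one component in homogeneous data", {
  set.seed(109)
  x <- matrix(rnorm(1000 * 2), 1000, 2)
  fit <- suppressWarnings(select_gmm(x, k_max = 5, seed = 13))
  expect_equal(fit$k, 1L)
})

test_that("BIC selection recovers four separated clusters", {
  g <- make_gaussian_clusters(n = 1200, k = 4, d = 6, sep = 9, seed = 113)
  fit <- suppressWarnings(select_gmm(g$x, k_max = 8, seed = 17))
  expect_equal(fit$k, 4L)
  expect_gt(ari(assign_clusters(fit), g$labels), 0.95)
  tab <- fit$bic_table
  expect_equal(nrow(tab), 5 * 8)
  ok <- tab[tab$status == "ok", ]
  expect_equal(min(ok$bic), fit$bic)
})

test_that("nested models never beat freer models on log-likelihood", {
  g <- make_gaussian_clusters(n = 500, k = 2, d = 3, sep = 8, seed = 127)
  fE <- fit_gmm(g$x, 2, "EII", seed = 3)
  fV <- fit_gmm(g$x, 2, "VVV", seed = 3)
  expect_lte(fE$loglik, fV$loglik + 1e-6)
  expect_lt(fE$n_params, fV$n_params)
})

test_that("selection warns when the winner sits on the k_max boundary", {
  g <- make_gaussian_clusters(n = 600, k = 4, d = 4, sep = 10, seed = 131)
  expect_warning(select_gmm(g$x, k_max = 3, models = "EII", seed = 19),
                 "k_max")
})

test_that("cluster assignment takes the max with ties to lower index", {
  fake <- structure(list(responsibilities = rbind(c(0.9, 0.1),
                                                  c(0.5, 0.5),
                                                  c(0.2, 0.8))),
                    class = "gmm_fit")
  expect_equal(assign_clusters(fake), c(1L, 1L, 2L))
})

test_that("predict reproduces training responsibilities and labels", {
  g <- make_gaussian_clusters(n = 300, k = 2, d = 3, sep = 9, seed = 137)
  fit <- fit_gmm(g$x, 2, "VEV", seed = 23)
  z <- predict(fit, newdata = g$x, type = "responsibility")
  expect_equal(z, fit$responsibilities, tolerance = 1e-6)
  expect_equal(predict(fit, type = "class"), assign_clusters(fit))
  expect_error(predict(fit, newdata = g$x[, 1:2]), "columns")
})

test_that("simulate draws from the fitted mixture", {
  g <- make_gaussian_clusters(n = 500, k = 2, d = 3, sep = 12, seed = 139)
  fit <- fit_gmm(g$x, 2, "EEE", seed = 29)
  s <- simulate(fit, nsim = 4000, seed = 31)
  expect_equal(dim(s$x), c(4000L, 3L))
  for (j in 1:2) {
    drawn <- colMeans(s$x[s$component == j, ])
    expect_lt(max(abs(drawn - fit$means[j, ])), 0.15)
  }
  expect_lt(max(abs(tabulate(s$component, 2) / 4000 - fit$weights)),
            0.03)
})

test_that("degenerate requests fail with clear errors", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_gmm(x, k = 10), "more observations")
  expect_error(fit_gmm(x, k = 2, model = "ABC"))
})
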