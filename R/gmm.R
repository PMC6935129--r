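GMM_MODELS <- c("EII", "VII", "EEE", "VEV", "VVV")

# free-parameter count: mixing weights + means + covariance parameters
gmm_n_params <- function(model, k, d) {
  cov_p <- switch(model,
    EII = 1,
    VII = k,
    EEE = d * (d + 1) / 2,
    VEV = k + (d - 1) + k * d * (d - 1) / 2,
    VVV = k * d * (d + 1) / 2,
    stop("unknown model: ", model))
  (k - 1) + k * d + cov_p
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  if (k > 1L) for (j in 2:k) {
    prob <- if (sum(d2) > 0) d2 else rep(1, n)
    idx <- sample.int(n, 1L, prob = prob)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

# hard one-hot responsibilities from k-means++ (with a short k-means polish)
init_responsibilities <- function(x, k) {
  centers <- kmeanspp_centers(x, k)
  lab <- tryCatch({
    km <- suppressWarnings(kmeans(x, centers = centers, iter.max = 10L))
    km$cluster
  }, error = function(e) {
    # duplicate centers etc.: assign to nearest seeded center
    d2 <- vapply(seq_len(k), function(j) {
      rowSums(sweep(x, 2L, centers[j, ])^2)
    }, numeric(nrow(x)))
    max.col(-d2, ties.method = "first")
  })
  z <- matrix(0, nrow(x), k)
  z[cbind(seq_len(nrow(x)), lab)] <- 1
  z
}

# per-component log densities, n x k
gmm_logdens <- function(x, means, covp, model) {
  n <- nrow(x); d <- ncol(x); k <- nrow(means)
  ld <- matrix(0, n, k)
  cst <- d * log(2 * pi)
  for (j in seq_len(k)) {
    xc <- sweep(x, 2L, means[j, ])
    if (model %in% c("EII", "VII")) {
      lam <- if (model == "EII") covp$lambda else covp$lambda[j]
      maha <- rowSums(xc^2) / lam
      logdet <- d * log(lam)
    } else if (model == "EEE") {
      maha <- colSums(forwardsolve(covp$L, t(xc))^2)
      logdet <- covp$logdet
    } else if (model == "VEV") {
      proj <- xc %*% covp$orientation[[j]]
      scale2 <- covp$lambda[j] * covp$shape
      maha <- rowSums(sweep(proj^2, 2L, scale2, `/`))
      logdet <- d * log(covp$lambda[j]) + sum(log(covp$shape))
    } else {  # VVV
      maha <- colSums(forwardsolve(covp$L[[j]], t(xc))^2)
      logdet <- covp$logdet[j]
    }
    ld[, j] <- -0.5 * (cst + logdet + maha)
  }
  ld
}

# lower-triangular Cholesky with eigenvalue flooring on failure
safe_chol <- function(S, floor) {
  S <- (S + t(S)) / 2
  L <- tryCatch(t(chol(S)), error = function(e) NULL)
  if (is.null(L) || any(diag(L)^2 < floor)) {
    e <- eigen(S, symmetric = TRUE)
    vals <- pmax(e$values, floor)
    S <- e$vectors %*% (vals * t(e$vectors))
    L <- t(chol((S + t(S)) / 2))
  }
  L
}

# M-step covariance update; W = list of weighted scatter matrices,
# nk = component masses
gmm_mstep_cov <- function(W, nk, model, d, floor, shape_tol = 1e-8,
                          shape_iter = 50L) {
  n <- sum(nk)
  k <- length(nk)
  if (model == "EII") {
    lam <- max(sum(vapply(W, function(w) sum(diag(w)), numeric(1))) /
                 (n * d), floor)
    list(lambda = lam)
  } else if (model == "VII") {
    lam <- pmax(vapply(seq_len(k), function(j) {
      sum(diag(W[[j]])) / (nk[j] * d)
    }, numeric(1)), floor)
    list(lambda = lam)
  } else if (model == "EEE") {
    S <- Reduce(`+`, W) / n
    L <- safe_chol(S, floor)
    list(Sigma = S, L = L, logdet = 2 * sum(log(diag(L))))
  } else if (model == "VEV") {
    eig <- lapply(W, function(w) eigen((w + t(w)) / 2, symmetric = TRUE))
    omega <- lapply(eig, function(e) pmax(e$values, floor * 1e-2))
    D <- lapply(eig, `[[`, "vectors")
    a <- rep(1, d)
    lam <- vapply(seq_len(k), function(j) {
      max(sum(omega[[j]]) / (nk[j] * d), floor)
    }, numeric(1))
    for (it in seq_len(shape_iter)) {
      b <- Reduce(`+`, lapply(seq_len(k), function(j) omega[[j]] / lam[j]))
      a_new <- b / exp(mean(log(b)))
      lam_new <- pmax(vapply(seq_len(k), function(j) {
        sum(omega[[j]] / a_new) / (nk[j] * d)
      }, numeric(1)), floor)
      delta <- max(abs(a_new - a) / (abs(a) + 1e-12),
                   abs(lam_new - lam) / (lam + 1e-12))
      a <- a_new; lam <- lam_new
      if (delta < shape_tol) break
    }
    list(lambda = lam, shape = a, orientation = D)
  } else {  # VVV
    S <- lapply(seq_len(k), function(j) W[[j]] / nk[j])
    L <- lapply(S, safe_chol, floor = floor)
    list(Sigma = S, L = L,
         logdet = vapply(L, function(l) 2 * sum(log(diag(l))),
                         numeric(1)))
  }
}

# EM driver: compiled engine by default, with the plain-R implementation
# retained as an independent reference ("R" engine)
gmm_em <- function(x, k, model, z, tol, max_iter, floor,
                   engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  if (engine == "R") return(gmm_em_once(x, k, model, z, tol, max_iter,
                                        floor))
  r <- .gmm_em_cpp(x, z, model, tol, as.integer(max_iter), floor,
                   1e-8, 50L)
  if (r$failed && identical(r$reason, "loglik_decreased")) {
    stop(sprintf("EM log-likelihood decreased for model %s, k=%d",
                 model, k))
  }
  if (r$failed) return(list(failed = TRUE, reason = r$reason))
  trace <- as.numeric(r$loglik_trace)
  list(failed = FALSE, loglik = r$loglik, loglik_trace = trace,
       weights = as.numeric(r$weights), means = r$means,
       covp = r$covp, responsibilities = r$responsibilities,
       iterations = r$iterations,
       converged = r$iterations < max_iter ||
         (length(trace) >= 2 && diff(tail(trace, 2)) < tol))
}

gmm_em_once <- function(x, k, model, z, tol, max_iter, floor) {
  n <- nrow(x); d <- ncol(x)
  loglik_trace <- numeric(0)
  ll_old <- -Inf
  means <- NULL; covp <- NULL; w <- NULL
  for (iter in seq_len(max_iter)) {
    nk <- colSums(z)
    if (any(nk < 2)) {
      return(list(failed = TRUE,
                  reason = "degenerate component (mass < 2 cells)"))
    }
    w <- nk / n
    means <- crossprod(z, x) / nk
    W <- lapply(seq_len(k), function(j) {
      xc <- sweep(x, 2L, means[j, ])
      crossprod(xc * sqrt(z[, j]))
    })
    covp <- gmm_mstep_cov(W, nk, model, d, floor)

    ld <- gmm_logdens(x, means, covp, model)
    lw <- sweep(ld, 2L, log(w), `+`)
    lse <- logsumexp_rows(lw)
    ll <- sum(lse)
    if (!is.finite(ll)) {
      return(list(failed = TRUE, reason = "non-finite log-likelihood"))
    }
    if (ll < ll_old - 1e-6 * (1 + abs(ll_old))) {
      stop(sprintf(
        "EM log-likelihood decreased (%.8g -> %.8g) for model %s, k=%d",
        ll_old, ll, model, k))
    }
    loglik_trace <- c(loglik_trace, ll)
    z <- exp(lw - lse)
    if (ll - ll_old < tol) {
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(failed = FALSE, loglik = ll_old, loglik_trace = loglik_trace,
       weights = w, means = means, covp = covp, responsibilities = z,
       iterations = length(loglik_trace),
       converged = length(loglik_trace) < max_iter ||
         (length(loglik_trace) >= 2 &&
            diff(tail(loglik_trace, 2)) < tol))
}

#' Fit a Gaussian mixture with a constrained covariance parameterization
#'
#' Fits a k-component multivariate Gaussian mixture by EM under one of
#' five classical covariance constraints: `EII` (spherical, equal
#' volume), `VII` (spherical, variable volume), `EEE` (shared full
#' covariance), `VEV` (variable volume, equal shape, variable
#' orientation: `Sigma_k = lambda_k D_k A D_k'` with `det(A) = 1`) and
#' `VVV` (fully free). Initialization is k-means++ with `nstart`
#' restarts; each restart is run through a short EM burn-in and the best
#' log-likelihood is continued to convergence. Covariance eigenvalues
#' are floored at `1e-8` of the total data variance. The EM
#' log-likelihood is checked to be non-decreasing at every iteration.
#'
#' @param x numeric cells x dimensions matrix (e.g. PCA scores).
#' @param k number of mixture components (`1 <= k < nrow(x)`).
#' @param model covariance model name, one of
#'   `"EII", "VII", "EEE", "VEV", "VVV"`.
#' @param seed integer seed for initialization.
#' @param tol EM convergence tolerance on the log-likelihood gain.
#' @param max_iter maximum EM iterations.
#' @param nstart number of k-means++ restarts.
#' @param burn_iter EM iterations used to rank restarts before the best
#'   is run to convergence.
#' @param restart_budget extra re-initializations allowed when a
#'   component degenerates (responsibility mass below 2 cells).
#' @param engine `"cpp"` for the compiled EM core (default) or `"R"`
#'   for the plain-R reference implementation of the same algorithm.
#' @return an object of class `gmm_fit` with elements `model_name`, `k`,
#'   `weights`, `means`, `covariance` (model-specific parameters),
#'   `loglik`, `loglik_trace`, `n_params`, `bic`
#'   (`-2 loglik + n_params log n`, minimized), `responsibilities`,
#'   `data`, `converged`, `iterations`.
#' @seealso [select_gmm()] for BIC model selection,
#'   [assign_clusters()], and the `predict`, `simulate`, `plot`,
#'   `summary` methods.
#' @export
fit_gmm <- function(x, k, model = "VVV", seed = 1L, tol = 1e-6,
                    max_iter = 500L, nstart = 5L, burn_iter = 15L,
                    restart_budget = 3L, engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  x <- as.matrix(x)
  model <- match.arg(model, GMM_MODELS)
  stopifnot(k >= 1L)
  if (nrow(x) <= k) stop("need more observations than components")
  d <- ncol(x)
  floor_val <- 1e-8 * mean(apply(x, 2L, var))
  if (!is.finite(floor_val) || floor_val <= 0) floor_val <- 1e-12

  for (attempt in 0:restart_budget) {
    set.seed(derive_seed(seed + 1000L * attempt, paste0("gmm_", model, k)))
    runs <- vector("list", nstart)
    for (s in seq_len(nstart)) {
      z0 <- init_responsibilities(x, k)
      runs[[s]] <- gmm_em(x, k, model, z0, tol,
                          min(burn_iter, max_iter), floor_val, engine)
    }
    ok <- !vapply(runs, `[[`, logical(1L), "failed")
    if (!any(ok)) next
    best <- runs[ok][[which.max(vapply(runs[ok], `[[`, numeric(1L),
                                       "loglik"))]]
    fit <- gmm_em(x, k, model, best$responsibilities, tol,
                  max_iter, floor_val, engine)
    if (fit$failed) next
    fit$loglik_trace <- c(head(best$loglik_trace, -1L), fit$loglik_trace)
    np <- gmm_n_params(model, k, d)
    out <- structure(list(
      model_name = model, k = k, d = d, n = nrow(x),
      weights = unname(fit$weights), means = unname(as.matrix(fit$means)),
      covariance = fit$covp, loglik = fit$loglik,
      loglik_trace = fit$loglik_trace, n_params = np,
      bic = -2 * fit$loglik + np * log(nrow(x)),
      responsibilities = unname(fit$responsibilities),
      converged = fit$converged, iterations = fit$iterations,
      data = x, seed = seed), class = "gmm_fit")
    return(out)
  }
  stop(sprintf(
    "mixture fit failed for model %s, k=%d: %s after %d restart(s)",
    model, k, "degenerate components", restart_budget))
}

#' Full covariance matrices of a fitted mixture
#'
#' @param fit a `gmm_fit`.
#' @return list of k dimension x dimension covariance matrices.
#' @export
gmm_covariances <- function(fit) {
  d <- fit$d; k <- fit$k; cp <- fit$covariance
  switch(fit$model_name,
    EII = rep(list(diag(cp$lambda, d)), k),
    VII = lapply(seq_len(k), function(j) diag(cp$lambda[j], d)),
    EEE = rep(list(cp$Sigma), k),
    VEV = lapply(seq_len(k), function(j) {
      D <- cp$orientation[[j]]
      cp$lambda[j] * D %*% (cp$shape * t(D))
    }),
    VVV = cp$Sigma)
}

#' MAP cluster labels from a fitted mixture
#'
#' Assigns each cell to the component with the largest responsibility;
#' ties go to the lower component index.
#'
#' @param fit a `gmm_fit`.
#' @return integer vector of labels in `1..k`.
#' @export
assign_clusters <- function(fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  max.col(fit$responsibilities, ties.method = "first")
}

#' Select a mixture model and cluster number by minimal BIC
#'
#' Fits every combination of covariance model and component number
#' `k = 1..k_max` and returns the fit with the smallest BIC
#' (`-2 loglik + n_params log n`); ties are broken toward smaller k,
#' then toward fewer parameters. Combinations whose EM degenerates are
#' skipped with a warning; selection fails only if every combination
#' fails. A warning is recorded when the winning k sits on the `k_max`
#' boundary.
#'
#' @param x numeric cells x dimensions matrix.
#' @param k_max largest number of components considered (default 20).
#' @param models covariance model names to consider.
#' @param seed integer seed.
#' @param ... passed to [fit_gmm()].
#' @return the winning `gmm_fit`, with `bic_table` (one row per
#'   model/k: loglik, n_params, bic, status) and `boundary_k`
#'   (logical) added.
#' @export
select_gmm <- function(x, k_max = 20L, models = GMM_MODELS, seed = 1L,
                       ...) {
  stopifnot(k_max >= 1L)
  models <- match.arg(models, GMM_MODELS, several.ok = TRUE)
  fits <- list()
  rows <- list()
  for (model in models) {
    for (k in seq_len(k_max)) {
      fit <- tryCatch(fit_gmm(x, k, model, seed = seed, ...),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        warning(sprintf("skipping model %s, k=%d: %s", model, k,
                        conditionMessage(fit)), call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          model = model, k = k, loglik = NA_real_,
          n_params = gmm_n_params(model, k, ncol(x)), bic = NA_real_,
          status = "failed", stringsAsFactors = FALSE)
      } else {
        fits[[paste(model, k)]] <- fit
        rows[[length(rows) + 1L]] <- data.frame(
          model = model, k = k, loglik = fit$loglik,
          n_params = fit$n_params, bic = fit$bic, status = "ok",
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  if (!length(fits)) stop("all model/k combinations failed")
  ok <- tab[tab$status == "ok", ]
  ord <- order(ok$bic, ok$k, ok$n_params)
  win <- ok[ord[1L], ]
  best <- fits[[paste(win$model, win$k)]]
  best$bic_table <- tab
  best$boundary_k <- win$k == k_max
  if (best$boundary_k && k_max > 1L) {
    warning(sprintf(
      "selected k = %d equals k_max; the optimum may lie beyond", win$k),
      call. = FALSE)
  }
  best
}
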