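#' @export
print.gmm_fit <- function(x, ...) {
  cat("Gaussian mixture fit (", x$model_name, ", k = ", x$k, ", d = ",
      x$d, ", n = ", x$n, ")\n", sep = "")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      "| parameters:", x$n_params,
      "| BIC:", format(x$bic, digits = 8), "\n")
  cat("  mixing weights:", paste(signif(x$weights, 3), collapse = ", "),
      "\n")
  if (!is.null(x$bic_table)) {
    nok <- sum(x$bic_table$status == "ok")
    cat("  selected by minimal BIC over", nrow(x$bic_table),
        "model/k combinations (", nok, "fitted )\n")
  }
  invisible(x)
}

#' @export
summary.gmm_fit <- function(object, ...) {
  lab <- assign_clusters(object)
  out <- list(model_name = object$model_name, k = object$k,
              d = object$d, n = object$n, loglik = object$loglik,
              n_params = object$n_params, bic = object$bic,
              weights = object$weights,
              cluster_sizes = tabulate(lab, object$k),
              converged = object$converged,
              iterations = object$iterations,
              bic_table = object$bic_table)
  class(out) <- "summary.gmm_fit"
  out
}

#' @export
print.summary.gmm_fit <- function(x, ...) {
  cat("Gaussian mixture model summary\n")
  cat("  model:", x$model_name, "| components:", x$k,
      "| dimensions:", x$d, "| n:", x$n, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      "| BIC:", format(x$bic, digits = 8),
      "| converged:", x$converged,
      "(", x$iterations, "iterations )\n")
  cat("  cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  cat("  weights:", paste(signif(x$weights, 3), collapse = ", "), "\n")
  if (!is.null(x$bic_table)) {
    ok <- x$bic_table[x$bic_table$status == "ok", ]
    top <- ok[order(ok$bic), ][seq_len(min(5L, nrow(ok))), ]
    cat("  best 5 by BIC:\n")
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.gmm_fit <- function(object, ...) {
  list(weights = object$weights, means = object$means,
       covariances = gmm_covariances(object))
}

#' @export
logLik.gmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' Posterior responsibilities or MAP labels for (new) data
#'
#' @param object a `gmm_fit`.
#' @param newdata optional matrix on the fit's dimensions; defaults to
#'   the training data.
#' @param type `"class"` for MAP labels, `"responsibility"` for the
#'   cells x k posterior matrix.
#' @param ... unused.
#' @return labels or responsibility matrix.
#' @export
predict.gmm_fit <- function(object, newdata = NULL,
                            type = c("class", "responsibility"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    z <- object$responsibilities
  } else {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != object$d) {
      stop("newdata must have ", object$d, " columns")
    }
    ld <- gmm_logdens(newdata, object$means, object$covariance,
                      object$model_name)
    lw <- sweep(ld, 2L, log(object$weights), `+`)
    z <- exp(lw - logsumexp_rows(lw))
  }
  if (type == "responsibility") z else
    max.col(z, ties.method = "first")
}

#' Simulate draws from a fitted mixture
#'
#' @param object a `gmm_fit`.
#' @param nsim number of observations to draw.
#' @param seed integer seed.
#' @param ... unused.
#' @return list with `x` (nsim x d matrix) and `component` (integer
#'   source component per row).
#' @export
simulate.gmm_fit <- function(object, nsim = 1L, seed = 1L, ...) {
  set.seed(derive_seed(seed, "simulate_gmm"))
  comp <- sample.int(object$k, nsim, replace = TRUE,
                     prob = object$weights)
  covs <- gmm_covariances(object)
  chols <- lapply(covs, function(S) t(chol((S + t(S)) / 2)))
  x <- matrix(0, nsim, object$d)
  for (j in seq_len(object$k)) {
    idx <- which(comp == j)
    if (!length(idx)) next
    zn <- matrix(rnorm(length(idx) * object$d), object$d)
    x[idx, ] <- t(object$means[j, ] + chols[[j]] %*% zn)
  }
  list(x = x, component = comp)
}

#' Plot a fitted mixture
#'
#' With a model-selection table (from [select_gmm()]), draws BIC versus
#' number of components per covariance model; otherwise scatters the
#' first two dimensions of the training data colored by MAP cluster.
#'
#' @param x a `gmm_fit`.
#' @param which `"bic"` or `"clusters"` (default: BIC curve when a
#'   selection table is present).
#' @param ... passed to the underlying plotting function.
#' @export
plot.gmm_fit <- function(x, which = NULL, ...) {
  which <- which %||% if (!is.null(x$bic_table)) "bic" else "clusters"
  if (which == "bic" && !is.null(x$bic_table)) {
    tab <- x$bic_table[x$bic_table$status == "ok", ]
    models <- unique(tab$model)
    graphics::plot(range(tab$k), range(tab$bic), type = "n",
                   xlab = "number of components k", ylab = "BIC",
                   main = "Model selection by minimal BIC", ...)
    for (i in seq_along(models)) {
      sub <- tab[tab$model == models[i], ]
      graphics::lines(sub$k, sub$bic, col = i, type = "b", pch = i)
    }
    graphics::legend("topright", legend = models, col = seq_along(models),
                     pch = seq_along(models), bty = "n")
    graphics::points(x$k, x$bic, pch = 8, cex = 1.5)
  } else {
    lab <- assign_clusters(x)
    graphics::plot(x$data[, 1L], x$data[, 2L], col = lab, pch = 16,
                   cex = 0.5, xlab = "dim 1", ylab = "dim 2",
                   main = sprintf("%s mixture, k = %d", x$model_name,
                                  x$k), ...)
  }
  invisible(x)
}
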