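#' Fit a two-population demographic model to a folded joint SFS
#'
#' User-facing front end to [optimize_model()]: looks the model up in
#' [model_registry()] and runs the multi-round randomized optimization of
#' the Poisson composite likelihood.
#'
#' @param data a folded [jsfs()].
#' @param model model name (see [model_registry()]) or a `model_spec`.
#' @param ... passed on to [optimize_model()] (`rounds`, `perturb_folds`,
#'   `seed`, `engine_replicates`, ...).
#' @return A `demfit` object; see [optimize_model()].
#' @examples
#' \donttest{
#' truth <- c(nu1 = 1, nu2 = 2, T1 = 0.5)
#' sim <- simulate_jsfs(sim_config("no_mig", truth, theta = 100,
#'                                 n_hap = c(6, 6), seed = 2))
#' fit <- fit_demography(sim, "no_mig", rounds = c(4, 4), seed = 3,
#'                       engine_replicates = 2000, final_replicates = 5000)
#' coef(fit)
#' }
#' @export
fit_demography <- function(data, model, ...) {
  optimize_model(model, data, ...)
}

#' @export
print.demfit <- function(x, ...) {
  cat(sprintf("Demographic model fit: %s (%s)\n",
              x$model_name, x$spec$category))
  cat(sprintf("  log-likelihood %.3f, theta_hat %.3f, AIC %.3f (k = %d)\n",
              x$loglik, x$theta_hat, x$aic, x$k))
  cat("  estimates:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.demfit <- function(object, ...) {
  per_round <- tapply(object$trace$loglik, object$trace$round,
                      max, na.rm = TRUE)
  lo <- object$spec$bounds["lower", ]; hi <- object$spec$bounds["upper", ]
  at_bound <- names(object$coefficients)[
    object$coefficients <= lo * 1.001 | object$coefficients >= hi * 0.999]
  structure(list(fit = object, best_by_round = per_round,
                 at_bound = at_bound,
                 n_replicates = nrow(object$trace)),
            class = "summary.demfit")
}

#' @export
print.summary.demfit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d optimization replicates over %d round(s)\n",
              x$n_replicates, length(x$best_by_round)))
  cat("  best log-likelihood by round: ",
      paste(sprintf("%.2f", x$best_by_round), collapse = ", "), "\n")
  if (length(x$at_bound))
    cat("  note: estimate(s) at a bound: ",
        paste(x$at_bound, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.demfit <- function(object, ...) object$coefficients

#' @export
logLik.demfit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = sum(!object$data$mask),
            class = "logLik")
}

#' Expected counts under a fitted model
#'
#' Returns the folded expected joint SFS at the fitted parameters, scaled
#' by the fitted theta, i.e. the per-cell Poisson means.
#'
#' @param object a `demfit`.
#' @param ... unused.
#' @return A folded [jsfs()] of expected counts.
#' @export
predict.demfit <- function(object, ...) {
  jsfs(object$theta_hat * object$fitted$values, folded = TRUE,
       mask = object$fitted$mask, pop_labels = object$data$pop_labels)
}

#' Pearson residuals of a fitted model
#'
#' `(observed - mu) / sqrt(mu)` per unmasked cell, with `mu` the fitted
#' Poisson mean; masked cells are `NA`.
#'
#' @param object a `demfit`.
#' @param ... unused.
#' @return A matrix of residuals.
#' @export
residuals.demfit <- function(object, ...) {
  mu <- object$theta_hat * object$fitted$values
  r <- (object$data$counts - mu) / sqrt(pmax(mu, 1e-12))
  r[object$data$mask | object$fitted$mask] <- NA
  r
}

#' Simulate spectra from a fitted model
#'
#' Draws independent Poisson counts for every unmasked cell around the
#' fitted means, i.e. parametric-bootstrap replicates of the data spectrum.
#'
#' @param object a `demfit`.
#' @param nsim number of spectra.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `nsim` folded [jsfs()] objects.
#' @export
simulate.demfit <- function(object, nsim = 1, seed = 1, ...) {
  mu <- object$theta_hat * object$fitted$values
  mask <- object$data$mask | object$fitted$mask
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    cnt <- matrix(rpois(length(mu), mu), nrow(mu), ncol(mu))
    cnt[mask] <- 0
    jsfs(cnt, folded = TRUE, mask = mask, pop_labels = object$data$pop_labels)
  }))
}

#' Plot observed, fitted and residual spectra
#'
#' Three image panels on a log scale: observed counts, fitted Poisson
#' means, and Pearson residuals.
#'
#' @param x a `demfit`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.demfit <- function(x, ...) {
  obs <- x$data$counts
  mu <- x$theta_hat * x$fitted$values
  res <- residuals(x)
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  img <- function(m, main) {
    graphics::image(0:(nrow(m)), 0:(ncol(m)), log1p(pmax(m, 0)),
                    xlab = x$data$pop_labels[1], ylab = x$data$pop_labels[2],
                    main = main, useRaster = TRUE)
  }
  img(obs, "observed")
  img(mu, sprintf("fitted (%s)", x$model_name))
  res[is.na(res)] <- 0
  graphics::image(0:(nrow(res)), 0:(ncol(res)), res,
                  xlab = x$data$pop_labels[1], ylab = x$data$pop_labels[2],
                  main = "Pearson residuals", useRaster = TRUE)
  invisible(x)
}
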