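check_compatible <- function(data, model_rel) {
  if (data$n1 != model_rel$n1 || data$n2 != model_rel$n2)
    stop("data and model spectra have different shapes")
  if (!identical(data$folded, model_rel$folded))
    stop("data and model spectra differ in fold state")
}

#' Optimal theta for a Poisson composite likelihood
#'
#' The per-cell Poisson means are `theta * model_rel`; profiling theta out
#' analytically gives the maximum-likelihood scale
#' `theta_hat = sum(data) / sum(model_rel)` over unmasked cells.
#'
#' @param data a [jsfs()] of observed counts.
#' @param model_rel an `expected_spectrum` on the per-unit-theta scale.
#' @return The scalar `theta_hat` (0 with a warning for all-zero data).
#' @export
optimal_theta <- function(data, model_rel) {
  stopifnot(inherits(data, "jsfs"), inherits(model_rel, "expected_spectrum"))
  check_compatible(data, model_rel)
  keep <- !(data$mask | model_rel$mask)
  denom <- sum(model_rel$values[keep])
  if (denom <= 0) stop("model spectrum has no mass on unmasked cells")
  num <- sum(data$counts[keep])
  if (num == 0) warning("all-zero data spectrum; theta_hat = 0")
  num / denom
}

#' Poisson composite log-likelihood of a joint SFS
#'
#' Treats unmasked cells as independent Poisson counts with means
#' `theta_hat * model_rel` (theta profiled out via [optimal_theta()]) and
#' returns `sum(d * log(mu) - mu)`; the log-factorial term, constant in the
#' parameters, is dropped. Model cells below 1e-12 are clamped to 1e-12.
#'
#' @inheritParams optimal_theta
#' @param theta optional fixed theta; default `NULL` profiles it out.
#' @return The composite log-likelihood (a real number).
#' @export
poisson_loglik <- function(data, model_rel, theta = NULL) {
  stopifnot(inherits(data, "jsfs"), inherits(model_rel, "expected_spectrum"))
  check_compatible(data, model_rel)
  if (is.null(theta)) theta <- optimal_theta(data, model_rel)
  keep <- !(data$mask | model_rel$mask)
  mu <- pmax(theta * model_rel$values[keep], 1e-12)
  d <- data$counts[keep]
  sum(d * log(mu) - mu)
}

#' Akaike weights for a set of fitted models
#'
#' `Delta_i = AIC_i - min(AIC)`; `w_i = exp(-Delta_i / 2)` normalized to
#' sum to one.
#'
#' @param fits a list of `demfit` objects, or a numeric vector of AIC
#'   values (optionally named).
#' @return Named numeric vector of weights summing to 1.
#' @export
aic_weights <- function(fits) {
  if (is.numeric(fits)) {
    aics <- fits
  } else {
    aics <- vapply(fits, function(f) f$aic, numeric(1))
    if (is.null(names(aics)))
      names(aics) <- vapply(fits, function(f) f$model_name, character(1))
  }
  if (!length(aics)) stop("need at least one fit")
  delta <- aics - min(aics)
  w <- exp(-delta / 2)
  w / sum(w)
}

# Bounded Nelder-Mead in log-parameter space with a hard cap on objective
# evaluations. Tracks the best point seen (including cap overruns) so the
# cap cannot lose a good evaluation.
local_search <- function(start, objective, lower, upper, max_eval = 300,
                         ftol = 1e-4) {
  nev <- 0L
  best_val <- Inf
  best_par <- start
  wrapped <- function(logp) {
    p <- pmin(pmax(exp(logp), lower), upper)
    nev <<- nev + 1L
    if (nev > max_eval) stop(structure(class = c("eval_cap", "error",
                                                 "condition"),
                                       list(message = "cap", call = NULL)))
    v <- -objective(p)
    if (is.finite(v) && v < best_val) {
      best_val <<- v
      best_par <<- p
    }
    if (!is.finite(v)) 1e12 else v
  }
  tryCatch(
    optim(log(start), wrapped, method = "Nelder-Mead",
          control = list(maxit = 10 * max_eval, reltol = ftol)),
    eval_cap = function(e) NULL)
  list(par = best_par, loglik = -best_val, n_eval = min(nev, max_eval))
}

#' Multi-round randomized optimization of one model
#'
#' Fits a registry model to a folded joint SFS by maximizing the Poisson
#' composite likelihood over the model parameters, with the expected
#' spectrum supplied by the Monte-Carlo coalescent engine. Round 1 draws
#' starting points log-uniformly within the parameter bounds; each later
#' round perturbs the incumbent best by up to the round's fold factor per
#' parameter. Every replicate runs a bounded Nelder-Mead search in
#' log-parameter space with a fixed engine seed (common random numbers),
#' and the best point is re-evaluated at `final_replicates` for reporting.
#'
#' @param spec a `model_spec` (or model name) from [model_registry()].
#' @param data a folded [jsfs()].
#' @param rounds integer vector of replicate counts per round
#'   (default `c(60, 70, 70, 80)`).
#' @param perturb_folds per-round maximal perturbation fold for start
#'   points (default `c(3, 2, 2, 1)`; round 1's entry is unused).
#' @param seed integer master seed; fixes start draws and engine streams.
#' @param engine_replicates coalescent replicates per objective evaluation
#'   during the search (default 20000).
#' @param final_replicates coalescent replicates for the final
#'   re-evaluation of the best point (default 200000).
#' @param max_eval cap on objective evaluations per replicate (default 200).
#' @param ftol relative convergence tolerance of the local search
#'   (default 1e-4).
#' @param screen candidate starting points drawn and evaluated once per
#'   replicate; the local search starts from the best of them (default 20,
#'   1 disables screening).
#' @param event_factor compute guard: an objective evaluation may simulate
#'   at most `event_factor * engine_replicates` coalescent/migration
#'   events (default 500 per genealogy on average); dearer points are
#'   treated as infeasible. Typical demographies need well under 100.
#' @param max_lineages passed to [expected_jsfs()].
#' @return A `demfit` object: `model_name`, `coefficients`, `loglik`,
#'   `theta_hat`, `aic`, `k`, `trace` (one row per replicate), `fitted`
#'   (folded expected spectrum at the optimum, per-unit-theta scale),
#'   `data`, `seed` and the engine configuration.
#' @export
optimize_model <- function(spec, data, rounds = c(60, 70, 70, 80),
                           perturb_folds = c(3, 2, 2, 1), seed = 1,
                           engine_replicates = 20000,
                           final_replicates = 200000,
                           max_eval = 200, ftol = 1e-4, screen = 20,
                           event_factor = 500, max_lineages = 60) {
  if (is.character(spec)) spec <- get_model_spec(spec)
  stopifnot(inherits(spec, "model_spec"), inherits(data, "jsfs"))
  if (!data$folded) stop("data spectrum must be folded before fitting")
  if (length(rounds) != length(perturb_folds))
    stop("rounds and perturb_folds must have the same length")

  lower <- spec$bounds["lower", ]; upper <- spec$bounds["upper", ]
  k <- spec$k

  budget <- event_factor * engine_replicates
  make_objective <- function(engine_seed) {
    function(p) {
      names(p) <- spec$param_names
      tryCatch({
        dem <- build_demography(spec$name, p)
        es <- fold_expected(expected_jsfs(dem, data$n1, data$n2,
                                          n_replicates = engine_replicates,
                                          seed = engine_seed,
                                          max_lineages = max_lineages,
                                          event_budget = budget))
        poisson_loglik(data, es)
      }, error = function(e) -Inf)
    }
  }

  trace <- vector("list", sum(rounds))
  tr_i <- 0L
  best <- list(par = NULL, loglik = -Inf)

  screen <- max(as.integer(screen), 1L)
  for (r in seq_along(rounds)) {
    starts <- with_seed(derive_seed(seed, 1000L, r), {
      if (r == 1L || is.null(best$par)) {
        replicate(rounds[r] * screen,
                  exp(runif(k, log(lower), log(upper))), simplify = FALSE)
      } else {
        fold <- max(perturb_folds[r], 1)
        lapply(seq_len(rounds[r] * screen), function(i)
          pmin(pmax(best$par *
                      exp(runif(k, -log(fold), log(fold))), lower), upper))
      }
    })
    for (i in seq_len(rounds[r])) {
      engine_seed <- derive_seed(seed, r, i)
      obj <- make_objective(engine_seed)
      cand <- starts[((i - 1L) * screen + 1L):(i * screen)]
      if (screen > 1L) {
        vals <- vapply(cand, obj, numeric(1))
        start_i <- cand[[which.max(vals)]]
      } else {
        start_i <- cand[[1L]]
      }
      res <- local_search(start_i, obj,
                          lower, upper, max_eval = max_eval, ftol = ftol)
      tr_i <- tr_i + 1L
      trace[[tr_i]] <- data.frame(
        round = r, replicate = i,
        t(setNames(start_i, paste0("start_", spec$param_names))),
        loglik = res$loglik, n_eval = res$n_eval)
      if (is.finite(res$loglik) && res$loglik > best$loglik)
        best <- res
    }
  }
  trace <- do.call(rbind, trace)
  if (!is.finite(best$loglik)) {
    cond <- simpleError(paste0("no replicate achieved a finite likelihood ",
                               "for model ", spec$name))
    cond$trace <- trace
    stop(cond)
  }

  # final refit of the best point at high replicates
  par <- setNames(best$par, spec$param_names)
  dem <- build_demography(spec$name, par)
  es <- fold_expected(expected_jsfs(dem, data$n1, data$n2,
                                    n_replicates = final_replicates,
                                    seed = derive_seed(seed, 0L, 0L),
                                    max_lineages = max_lineages))
  theta_hat <- optimal_theta(data, es)
  ll <- poisson_loglik(data, es, theta = theta_hat)
  structure(
    list(model_name = spec$name, spec = spec, coefficients = par,
         loglik = ll, theta_hat = theta_hat, aic = 2 * k - 2 * ll, k = k,
         trace = trace, fitted = es, data = data, seed = seed,
         engine = list(search_replicates = engine_replicates,
                       final_replicates = final_replicates,
                       max_eval = max_eval, ftol = ftol),
         rounds = rounds, perturb_folds = perturb_folds),
    class = "demfit")
}

#' Serialize a fit to JSON / its trace to TSV
#'
#' @param fit a `demfit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "demfit"))
  obj <- list(model = fit$model_name, params = as.list(fit$coefficients),
              loglik = fit$loglik, theta_hat = fit$theta_hat,
              aic = fit$aic, k = fit$k, seed = fit$seed,
              rounds = fit$rounds, engine = fit$engine)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname fit_json
#' @export
trace_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "demfit"))
  write.table(fit$trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
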