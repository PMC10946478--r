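#' Default model sets for the hierarchical comparisons
#'
#' The species-level comparison screens founder-event and vicariance-style
#' scenarios (is the derived entity a peripheral isolate?); the
#' within-species comparisons against the two mainland subgroups screen
#' divergence-with-gene-flow scenarios: isolation, ancient or continuous
#' migration, secondary contact, and size changes.
#'
#' @param which `"founder_set"` or `"sec_contact_set"`.
#' @return Character vector of registry model names.
#' @export
model_set <- function(which = c("founder_set", "sec_contact_set")) {
  which <- match.arg(which)
  if (which == "founder_set")
    c("no_mig", "sym_mig", "asym_mig", "vic_no_mig",
      "founder_nomig", "founder_sym", "founder_asym",
      "founder_sec_contact_asym_two_epoch")
  else
    c("no_mig", "sym_mig", "asym_mig", "anc_sym_mig", "anc_asym_mig",
      "sec_contact_sym_mig", "sec_contact_asym_mig",
      "sec_contact_sym_mig_size", "sec_contact_asym_mig_size",
      "sec_contact_sym_mig_size_three_epoch",
      "sec_contact_asym_mig_size_three_epoch")
}

#' Fit and rank a set of models on one joint SFS
#'
#' Fits every named model with [optimize_model()] (independent derived
#' seeds per model), ranks by AIC with ties broken by fewer parameters and
#' then name order, and computes Akaike weights. A model whose fit errors
#' is recorded as failed and excluded from the weights (with a warning);
#' the run continues.
#'
#' @param data a folded [jsfs()].
#' @param model_names character vector of registry model names.
#' @param pair_label label for the population pair (metadata).
#' @param config list of [optimize_model()] arguments (`rounds`,
#'   `perturb_folds`, `seed`, `engine_replicates`, `final_replicates`,
#'   `max_eval`, `ftol`, `max_lineages`); missing entries use the
#'   optimizer defaults.
#' @return A `demcmp` object: `table` (model, k, loglik, AIC, dAIC,
#'   weight), `winner`, `fits`, `failed`, `pair_label`, `config`, `seed`.
#' @export
run_comparison <- function(data, model_names, pair_label = "pair",
                           config = list()) {
  stopifnot(inherits(data, "jsfs"))
  reg <- model_registry()
  unknown <- setdiff(model_names, names(reg))
  if (length(unknown))
    stop("unknown model(s): ", paste(unknown, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else config$seed
  opt_args <- config[intersect(names(config),
                               c("rounds", "perturb_folds",
                                 "engine_replicates", "final_replicates",
                                 "max_eval", "ftol", "screen",
                                 "event_factor", "max_lineages"))]
  default_rounds <- eval(formals(optimize_model)$rounds)
  low_effort <- !is.null(config$rounds) &&
    sum(config$rounds) < sum(default_rounds)

  fits <- vector("list", length(model_names))
  names(fits) <- model_names
  failed <- character(0)
  for (mi in seq_along(model_names)) {
    m <- model_names[mi]
    res <- tryCatch(
      do.call(optimize_model,
              c(list(spec = reg[[m]], data = data,
                     seed = derive_seed(seed, match(m, names(reg)), mi)),
                opt_args)),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("model '", m, "' failed: ", conditionMessage(res))
      failed <- c(failed, m)
    } else {
      fits[[mi]] <- res
    }
  }
  ok <- !vapply(fits, is.null, logical(1))
  fits <- fits[ok]
  if (!length(fits)) stop("every model failed for pair ", pair_label)

  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "model_name"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    row.names = NULL)
  ord <- order(tab$aic, tab$k, tab$model)
  tab <- tab[ord, ]
  if (nrow(tab) > 1L && tab$aic[1] == tab$aic[2])
    message("AIC tie for pair ", pair_label,
            "; broken by k then name order: ", tab$model[1],
            " over ", tab$model[2])
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab$weight <- as.numeric(aic_weights(setNames(tab$aic, tab$model)))
  rownames(tab) <- NULL

  structure(list(pair_label = pair_label, table = tab,
                 winner = tab$model[1], fits = fits, failed = failed,
                 config = config, seed = seed, low_effort = low_effort),
            class = "demcmp")
}

#' @export
print.demcmp <- function(x, ...) {
  cat(sprintf("Model comparison for %s%s\n", x$pair_label,
              if (isTRUE(x$low_effort)) " [low-effort settings]" else ""))
  tab <- x$table
  tab$loglik <- round(tab$loglik, 3)
  tab$aic <- round(tab$aic, 3)
  tab$delta_aic <- round(tab$delta_aic, 3)
  tab$weight <- round(tab$weight, 4)
  print(tab)
  if (length(x$failed))
    cat("  failed fits (excluded from weights):",
        paste(x$failed, collapse = ", "), "\n")
  cat(sprintf("  winner: %s (Akaike weight %.4f)\n",
              x$winner, x$table$weight[1]))
  invisible(x)
}

#' Hierarchical three-comparison model selection
#'
#' Runs the pairwise design used to localise a population split: the
#' species-level pair is screened with the founder/vicariance set (testing
#' the peripheral-isolate hypothesis, the derived entity as "island" and
#' the ancestral as "mainland"), and each within-species pair with the
#' secondary-contact/isolation/size-change set.
#'
#' @param datasets named list of exactly three folded [jsfs()] objects;
#'   names are the pair labels and are propagated verbatim.
#' @param config as in [run_comparison()]; `model_sets` may override the
#'   per-comparison model sets as a list of three character vectors.
#' @return A list with one `demcmp` per dataset plus a `summary`
#'   data.frame covering every model attempted in every comparison.
#' @export
run_hierarchical <- function(datasets, config = list()) {
  if (length(datasets) != 3L || is.null(names(datasets)) ||
      any(!nzchar(names(datasets))))
    stop("datasets must be a named list of three folded spectra")
  sets <- config$model_sets
  if (is.null(sets))
    sets <- list(model_set("founder_set"),
                 model_set("sec_contact_set"),
                 model_set("sec_contact_set"))
  if (length(sets) != 3L) stop("model_sets must list three model vectors")
  seed <- if (is.null(config$seed)) 1L else config$seed

  reports <- vector("list", 3L)
  names(reports) <- names(datasets)
  for (i in 1:3) {
    cfg <- config
    cfg$seed <- derive_seed(seed, 7L, i)
    reports[[i]] <- run_comparison(datasets[[i]], sets[[i]],
                                   pair_label = names(datasets)[i],
                                   config = cfg)
  }
  summary <- do.call(rbind, lapply(names(reports), function(lbl) {
    tab <- reports[[lbl]]$table
    cbind(pair = lbl, tab)
  }))
  rownames(summary) <- NULL
  c(reports, list(summary = summary))
}

#' Serialize a comparison report to JSON
#'
#' @param cmp a `demcmp`.
#' @param path optional output path.
#' @return JSON text (invisibly when written).
#' @export
comparison_json <- function(cmp, path = NULL) {
  stopifnot(inherits(cmp, "demcmp"))
  obj <- list(pair_label = cmp$pair_label, winner = cmp$winner,
              seed = cmp$seed, low_effort = isTRUE(cmp$low_effort),
              failed = cmp$failed, table = cmp$table,
              estimates = lapply(cmp$fits, function(f)
                as.list(f$coefficients)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
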