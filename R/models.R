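#' Registry of two-population diversification models
#'
#' Named catalogue of the divergence scenarios considered when testing how
#' two populations split: plain vicariance-style splits with or without
#' continuous, ancient or secondary-contact gene flow (optionally with
#' per-epoch size changes), and founder-event models in which the derived
#' ("island") population is established by a fraction `s` of the ancestral
#' ("mainland") population and grows exponentially.
#'
#' Population ordering convention: population 1 is the derived/island
#' entity, population 2 the ancestral/mainland entity. Migration rate
#' `m12` is forward-in-time gene flow from population 1 into population 2
#' (scaled by 2*N_ref), `m21` the reverse.
#'
#' All sizes are in units of the reference effective size N_ref, times in
#' units of 2*N_ref generations.
#'
#' @return A named list of `model_spec` objects with fields `name`,
#'   `category`, `param_names`, `bounds` (2 x k matrix: lower, upper) and
#'   `k` (number of free parameters).
#' @export
model_registry <- function() {
  b_size <- c(1e-3, 100)
  b_time <- c(1e-3, 10)
  b_mig  <- c(1e-3, 20)
  b_s    <- c(0.01, 0.5)
  bound_of <- function(p) {
    if (p %in% c("nuA", "nu1", "nu2", "nu1a", "nu2a", "nu1b", "nu2b")) b_size
    else if (p %in% c("T1", "T2", "T3")) b_time
    else if (p %in% c("m", "m12", "m21")) b_mig
    else if (p == "s") b_s
    else stop("unknown parameter: ", p)
  }
  spec <- function(name, category, params) {
    bounds <- vapply(params, bound_of, numeric(2))
    rownames(bounds) <- c("lower", "upper")
    structure(list(name = name, category = category, param_names = params,
                   bounds = bounds, k = length(params)),
              class = "model_spec")
  }
  specs <- list(
    spec("no_mig", "vicariance", c("nu1", "nu2", "T1")),
    spec("sym_mig", "vicariance", c("nu1", "nu2", "m", "T1")),
    spec("asym_mig", "vicariance", c("nu1", "nu2", "m12", "m21", "T1")),
    spec("anc_sym_mig", "vicariance", c("nu1", "nu2", "m", "T1", "T2")),
    spec("anc_asym_mig", "vicariance",
         c("nu1", "nu2", "m12", "m21", "T1", "T2")),
    spec("vic_no_mig", "vicariance", c("nuA", "nu1", "nu2", "T1")),
    spec("sec_contact_sym_mig", "secondary_contact",
         c("nu1", "nu2", "m", "T1", "T2")),
    spec("sec_contact_asym_mig", "secondary_contact",
         c("nu1", "nu2", "m12", "m21", "T1", "T2")),
    spec("sec_contact_sym_mig_size", "secondary_contact",
         c("nu1a", "nu2a", "nu1b", "nu2b", "m", "T1", "T2")),
    spec("sec_contact_asym_mig_size", "secondary_contact",
         c("nu1a", "nu2a", "nu1b", "nu2b", "m12", "m21", "T1", "T2")),
    spec("sec_contact_sym_mig_size_three_epoch", "secondary_contact",
         c("nu1a", "nu2a", "nu1b", "nu2b", "m", "T1", "T2", "T3")),
    spec("sec_contact_asym_mig_size_three_epoch", "secondary_contact",
         c("nu1a", "nu2a", "nu1b", "nu2b", "m12", "m21", "T1", "T2", "T3")),
    spec("founder_nomig", "founder", c("nuA", "nu1", "nu2", "T1", "s")),
    spec("founder_sym", "founder", c("nuA", "nu1", "nu2", "m", "T1", "s")),
    spec("founder_asym", "founder",
         c("nuA", "nu1", "nu2", "m12", "m21", "T1", "s")),
    spec("founder_sec_contact_asym_two_epoch", "old_founder",
         c("nuA", "nu1", "nu2", "m12", "m21", "T1", "T2", "s"))
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(names(specs))) stop("duplicate model name in registry")
  specs
}

get_model_spec <- function(name) {
  reg <- model_registry()
  if (!name %in% names(reg))
    stop("unknown model: ", name, " (see model_registry())")
  reg[[name]]
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model '%s' (%s), k = %d\n  parameters: %s\n",
              x$name, x$category, x$k, paste(x$param_names, collapse = ", ")))
  invisible(x)
}

check_params <- function(spec, params) {
  if (!setequal(names(params), spec$param_names))
    stop("model '", spec$name, "' needs exactly parameters: ",
         paste(spec$param_names, collapse = ", "), "; got: ",
         paste(names(params), collapse = ", "))
  params <- params[spec$param_names]
  lo <- spec$bounds["lower", ]; hi <- spec$bounds["upper", ]
  bad <- params < lo | params > hi
  if (any(bad))
    stop("parameter(s) out of bounds for '", spec$name, "': ",
         paste(spec$param_names[bad], collapse = ", "))
  params
}

# one forward-time epoch: sizes may differ at start and end (exponential
# trajectory in between); migration constant within the epoch
epoch <- function(duration, n1_start, n1_end, n2_start, n2_end, m12, m21) {
  list(duration = duration, n1 = c(n1_start, n1_end),
       n2 = c(n2_start, n2_end), m12 = m12, m21 = m21)
}

#' Translate a named model and parameter vector into a piecewise demography
#'
#' The demography lists forward-time epochs (oldest first) after the split
#' of an ancestral population of size `nuA` (or 1 when the model has no
#' `nuA`). In founder models the derived population (population 1) is
#' founded by a fraction `s` of the ancestral population, i.e. at size
#' `s * nuA`, and grows exponentially within the first epoch; in vicariance
#' models both descendants start at their epoch sizes.
#'
#' @param name model name from [model_registry()].
#' @param params named numeric vector supplying exactly the model's
#'   parameters, within bounds.
#' @return An object of class `demography`: `root_size`, `split_fraction`
#'   (`NA` for non-founder models) and a list of epochs with per-population
#'   size trajectories and a migration pair.
#' @export
build_demography <- function(name, params) {
  spec <- get_model_spec(name)
  p <- as.list(check_params(spec, params))
  root <- if ("nuA" %in% spec$param_names) p$nuA else 1
  s <- if ("s" %in% spec$param_names) p$s else NA_real_
  if (!is.na(s) && (s <= 0 || s > 0.5))
    stop("founding fraction s must lie in (0, 0.5]")

  eps <- switch(
    name,
    no_mig = list(epoch(p$T1, p$nu1, p$nu1, p$nu2, p$nu2, 0, 0)),
    sym_mig = list(epoch(p$T1, p$nu1, p$nu1, p$nu2, p$nu2, p$m, p$m)),
    asym_mig = list(epoch(p$T1, p$nu1, p$nu1, p$nu2, p$nu2, p$m12, p$m21)),
    anc_sym_mig = list(
      epoch(p$T1, p$nu1, p$nu1, p$nu2, p$nu2, p$m, p$m),
      epoch(p$T2, p$nu1, p$nu1, p$nu2, p$nu2, 0, 0)),
    anc_asym_mig = list(
      epoch(p$T1, p$nu1, p$nu1, p$nu2, p$nu2, p$m12, p$m21),
      epoch(p$T2, p$nu1, p$nu1, p$nu2, p$nu2, 0, 0)),
    vic_no_mig = list(epoch(p$T1, p$nu1, p$nu1, p$nu2, p$nu2, 0, 0)),
    sec_contact_sym_mig = list(
      epoch(p$T1, p$nu1, p$nu1, p$nu2, p$nu2, 0, 0),
      epoch(p$T2, p$nu1, p$nu1, p$nu2, p$nu2, p$m, p$m)),
    sec_contact_asym_mig = list(
      epoch(p$T1, p$nu1, p$nu1, p$nu2, p$nu2, 0, 0),
      epoch(p$T2, p$nu1, p$nu1, p$nu2, p$nu2, p$m12, p$m21)),
    sec_contact_sym_mig_size = list(
      epoch(p$T1, p$nu1a, p$nu1a, p$nu2a, p$nu2a, 0, 0),
      epoch(p$T2, p$nu1b, p$nu1b, p$nu2b, p$nu2b, p$m, p$m)),
    sec_contact_asym_mig_size = list(
      epoch(p$T1, p$nu1a, p$nu1a, p$nu2a, p$nu2a, 0, 0),
      epoch(p$T2, p$nu1b, p$nu1b, p$nu2b, p$nu2b, p$m12, p$m21)),
    sec_contact_sym_mig_size_three_epoch = list(
      epoch(p$T1, p$nu1a, p$nu1a, p$nu2a, p$nu2a, 0, 0),
      epoch(p$T2, p$nu1b, p$nu1b, p$nu2b, p$nu2b, p$m, p$m),
      epoch(p$T3, p$nu1b, p$nu1b, p$nu2b, p$nu2b, 0, 0)),
    sec_contact_asym_mig_size_three_epoch = list(
      epoch(p$T1, p$nu1a, p$nu1a, p$nu2a, p$nu2a, 0, 0),
      epoch(p$T2, p$nu1b, p$nu1b, p$nu2b, p$nu2b, p$m12, p$m21),
      epoch(p$T3, p$nu1b, p$nu1b, p$nu2b, p$nu2b, 0, 0)),
    founder_nomig = list(
      epoch(p$T1, s * root, p$nu1, p$nu2, p$nu2, 0, 0)),
    founder_sym = list(
      epoch(p$T1, s * root, p$nu1, p$nu2, p$nu2, p$m, p$m)),
    founder_asym = list(
      epoch(p$T1, s * root, p$nu1, p$nu2, p$nu2, p$m12, p$m21)),
    founder_sec_contact_asym_two_epoch = list(
      epoch(p$T1, s * root, p$nu1, p$nu2, p$nu2, 0, 0),
      epoch(p$T2, p$nu1, p$nu1, p$nu2, p$nu2, p$m12, p$m21)),
    stop("no demography builder for model: ", name)
  )
  for (ep in eps) {
    if (ep$duration <= 0) stop("epoch durations must be positive")
    if (any(c(ep$n1, ep$n2) <= 0)) stop("population sizes must be positive")
  }
  structure(list(model = name, params = unlist(p), root_size = root,
                 split_fraction = s, epochs = eps),
            class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat(sprintf("Demography '%s': root size %.4g, %d epoch(s)%s\n",
              x$model, x$root_size, length(x$epochs),
              if (!is.na(x$split_fraction))
                sprintf(", founding fraction %.3g", x$split_fraction)
              else ""))
  for (i in seq_along(x$epochs)) {
    ep <- x$epochs[[i]]
    cat(sprintf(
      "  epoch %d: T=%.4g, nu1 %.4g->%.4g, nu2 %.4g->%.4g, m12=%.3g m21=%.3g\n",
      i, ep$duration, ep$n1[1], ep$n1[2], ep$n2[1], ep$n2[2], ep$m12, ep$m21))
  }
  invisible(x)
}

#' Total duration of a demography since the split
#' @param dem a [build_demography()] result.
#' @return Sum of epoch durations (2*N_ref generations).
#' @export
demography_duration <- function(dem) {
  sum(vapply(dem$epochs, `[[`, numeric(1), "duration"))
}

#' Serialize the model registry or a demography to JSON
#'
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON text (invisibly when written to `path`).
#' @export
registry_json <- function(path = NULL) {
  reg <- model_registry()
  obj <- lapply(reg, function(s)
    list(name = s$name, category = s$category, param_names = s$param_names,
         lower = unname(s$bounds["lower", ]),
         upper = unname(s$bounds["upper", ]), k = s$k))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname registry_json
#' @param dem a `demography` object.
#' @export
demography_json <- function(dem, path = NULL) {
  stopifnot(inherits(dem, "demography"))
  obj <- list(model = dem$model, params = as.list(dem$params),
              root_size = dem$root_size,
              split_fraction = if (is.na(dem$split_fraction)) NULL
                               else dem$split_fraction,
              epochs = lapply(dem$epochs, function(ep)
                list(duration = ep$duration, nu1 = ep$n1, nu2 = ep$n2,
                     m12 = ep$m12, m21 = ep$m21)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
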