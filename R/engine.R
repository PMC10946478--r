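# Convert a forward-time demography into the backward-time epoch matrix the
# C++ simulator consumes. Within an epoch the backward-local size of deme k
# is A_k * exp(B_k * u); A is the forward end size, B = log(start/end)/T.
# Backward per-lineage migration rates: a lineage sampled in deme j traces
# to deme i at rate m_ij / 2 (m_ij = forward flow from i into j).
demography_to_epochs <- function(dem) {
  eps <- rev(dem$epochs)  # most recent first
  rows <- lapply(eps, function(ep) {
    Tt <- ep$duration
    c(duration = Tt,
      A1 = ep$n1[2], B1 = log(ep$n1[1] / ep$n1[2]) / Tt,
      A2 = ep$n2[2], B2 = log(ep$n2[1] / ep$n2[2]) / Tt,
      r1 = ep$m21 / 2, r2 = ep$m12 / 2)
  })
  root <- c(duration = Inf, A1 = dem$root_size, B1 = 0,
            A2 = dem$root_size, B2 = 0, r1 = 0, r2 = 0)
  do.call(rbind, c(rows, list(root)))
}

#' Expected joint SFS under a demography (Monte-Carlo coalescent)
#'
#' Estimates the theta-free expected joint site-frequency spectrum by
#' simulating structured-coalescent genealogies of `n1 + n2` sampled
#' lineages under the piecewise demography: exponential waiting times for
#' migration, time-rescaled coalescence under exponential size
#' trajectories, and classification of every branch by the number of
#' sampled descendants it subtends in each population. Cell `(i, j)` is the
#' mean total branch length subtending `i` population-1 and `j`
#' population-2 samples, divided by 2, i.e. the expected number of
#' segregating sites with that configuration per unit of
#' theta = 4*N_ref*mu*L.
#'
#' @param dem a [build_demography()] result.
#' @param n1,n2 haploid sample sizes (>= 1 each, `n1 + n2 >= 2`).
#' @param n_replicates number of simulated genealogies (default 20000).
#' @param seed integer seed; identical seeds give identical output.
#' @param max_lineages guard on `n1 + n2` (default 60); raise explicitly
#'   for larger spectra.
#' @param event_budget cap on the total number of simulated coalescent/
#'   migration events (default `Inf`). Near-panmictic corners of the
#'   parameter space (large migration sustained over long epochs) cost
#'   orders of magnitude more events than typical demographies; when a
#'   finite budget is exhausted the call errors. The optimizer uses this
#'   as a compute guard, treating such corners as infeasible.
#' @return An object of class `expected_spectrum`: `values` matrix
#'   (`(n1+1) x (n2+1)`), `mc_se` matrix of Monte-Carlo standard errors on
#'   the same scale, `n1`, `n2`, `folded`, `mask` (fixed cells masked),
#'   `n_replicates`, `seed`.
#' @export
expected_jsfs <- function(dem, n1, n2, n_replicates = 20000, seed = 1,
                          max_lineages = 60, event_budget = Inf) {
  stopifnot(inherits(dem, "demography"))
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 1 || n2 < 1 || n1 + n2 < 2) stop("need n1, n2 >= 1 and n1+n2 >= 2")
  if (n1 + n2 > max_lineages)
    stop("n1 + n2 = ", n1 + n2, " exceeds max_lineages = ", max_lineages,
         "; raise max_lineages explicitly for large spectra")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  epochs <- demography_to_epochs(dem)
  res <- .sim_jsfs_cpp(epochs, n1, n2, as.integer(n_replicates),
                       as.numeric(seed %% 2^31), event_budget)
  if (isTRUE(res$truncated))
    stop("simulation event budget exhausted (near-panmictic corner?)")
  values <- res$mean_bl / 2
  mc_se <- res$se / 2
  mask <- matrix(FALSE, n1 + 1L, n2 + 1L)
  mask[1, 1] <- TRUE
  mask[n1 + 1L, n2 + 1L] <- TRUE
  values[mask] <- 0
  structure(list(values = values, mc_se = mc_se, n1 = n1, n2 = n2,
                 folded = FALSE, mask = mask,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed %% 2^31)),
            class = "expected_spectrum")
}

#' Fold an expected spectrum
#'
#' Applies the same complement-merging rule as [fold_jsfs()]; by linearity
#' the folded expectation equals the expectation of folded data. Standard
#' errors combine in quadrature (conservatively ignoring the negative
#' covariance of merged cells).
#'
#' @param es an unfolded `expected_spectrum`.
#' @return The folded `expected_spectrum`.
#' @export
fold_expected <- function(es) {
  stopifnot(inherits(es, "expected_spectrum"))
  if (es$folded) stop("expected spectrum is already folded")
  f <- fold_matrix(es$values, es$mask)
  f_var <- fold_matrix(es$mc_se^2, es$mask)
  es$values <- f$counts
  es$mc_se <- sqrt(f_var$counts)
  es$mask <- f$mask
  es$values[es$mask] <- 0
  es$folded <- TRUE
  es
}

#' @export
print.expected_spectrum <- function(x, ...) {
  cat(sprintf(
    "Expected jSFS: %d x %d (%s), %d coalescent replicates (seed %d)\n",
    x$n1 + 1L, x$n2 + 1L, if (x$folded) "folded" else "unfolded",
    x$n_replicates, x$seed))
  cat(sprintf("  total per-theta mass (unmasked): %.5g\n",
              sum(x$values[!x$mask])))
  invisible(x)
}

#' Write an expected spectrum in plain-text SFS format
#'
#' Same layout as [write_sfs()]; a `.se` sidecar file with the Monte-Carlo
#' standard errors is written alongside.
#'
#' @param es an `expected_spectrum`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_expected_sfs <- function(es, path) {
  stopifnot(inherits(es, "expected_spectrum"))
  write_sfs(jsfs(es$values, folded = es$folded, mask = es$mask), path)
  write_sfs(jsfs(es$mc_se, folded = es$folded, mask = es$mask),
            paste0(path, ".se"))
  invisible(path)
}
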