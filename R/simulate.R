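#' Configuration for synthetic RAD-style data
#'
#' Describes a generating scenario: a registry model with its parameters,
#' an absolute scale (theta or a site count), haploid sample sizes, and the
#' nuisance structure of RAD data — per-genotype missingness and a
#' negative-binomial read-depth distribution.
#'
#' @param model_name registry model name.
#' @param params named numeric vector of model parameters (within bounds).
#' @param theta composite scale 4*N_ref*mu*L setting expected SNP counts;
#'   exactly one of `theta` / `L` must be given.
#' @param L number of RAD loci (one usable SNP each) for VCF simulation;
#'   when `theta` is given, `L` defaults to the realised SNP count.
#' @param n_hap haploid sample sizes `c(n1, n2)` (must be even; default
#'   `c(8, 8)`, i.e. 4 diploids per population).
#' @param missingness per-genotype missing probability in `[0, 1)`
#'   (default 0.1).
#' @param depth_mean,depth_dispersion negative-binomial per-genotype depth
#'   (mean 20, size 5 by default).
#' @param seed integer seed.
#' @param engine_replicates coalescent replicates used for the generating
#'   expected spectrum (default 200000).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(model_name, params, theta = NULL, L = NULL,
                       n_hap = c(8, 8), missingness = 0.1,
                       depth_mean = 20, depth_dispersion = 5, seed = 1,
                       engine_replicates = 200000) {
  spec <- get_model_spec(model_name)
  params <- check_params(spec, params)
  if (is.null(theta) && is.null(L))
    stop("supply theta or L")
  if (!is.null(L) && L < 1) stop("L must be >= 1")
  if (missingness < 0 || missingness >= 1)
    stop("missingness must lie in [0, 1)")
  if (any(n_hap < 2) || any(n_hap %% 2 != 0))
    stop("n_hap must be even haploid counts >= 2")
  structure(list(model_name = model_name, params = params, theta = theta,
                 L = L, n_hap = as.integer(n_hap),
                 missingness = missingness, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 seed = as.integer(seed),
                 engine_replicates = as.integer(engine_replicates)),
            class = "sim_config")
}

# folded expected spectrum (per-unit-theta scale) at the config's truth
expected_for_config <- function(cfg, max_lineages = 60) {
  dem <- build_demography(cfg$model_name, cfg$params)
  fold_expected(expected_jsfs(dem, cfg$n_hap[1], cfg$n_hap[2],
                              n_replicates = cfg$engine_replicates,
                              seed = derive_seed(cfg$seed, 42L),
                              max_lineages = max_lineages))
}

#' Simulate a folded joint SFS under a registry model
#'
#' Computes the folded expected spectrum at the configured parameters,
#' scales it by theta, and draws each unmasked cell independently from a
#' Poisson distribution — the sampling model the composite likelihood
#' assumes.
#'
#' @param cfg a [sim_config()] with `theta` set.
#' @return A folded [jsfs()] of integer counts, with the generating truth
#'   attached as attribute `"truth"` (expected spectrum, theta, params).
#' @export
simulate_jsfs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$theta)) stop("simulate_jsfs needs theta in the config")
  es <- expected_for_config(cfg)
  mu <- cfg$theta * es$values
  mu[es$mask] <- 0
  cnt <- with_seed(derive_seed(cfg$seed, 7L), {
    matrix(rpois(length(mu), mu), nrow(mu), ncol(mu))
  })
  out <- jsfs(cnt, folded = TRUE, mask = es$mask)
  attr(out, "truth") <- list(model = cfg$model_name, params = cfg$params,
                             theta = cfg$theta, expected = es)
  out
}

#' Simulate a RAD-style VCF under a registry model
#'
#' Draws `L` unlinked loci carrying one biallelic SNP each. Per-site minor
#' allele configurations are drawn from the folded expected spectrum;
#' allele copies are assigned to diploid genotypes by random union of
#' gametes; genotypes are masked missing at the configured rate and given
#' negative-binomial depths. Writes a VCF 4.2 file (locus id in CHROM,
#' GT:DP) and a JSON sidecar with the generating truth.
#'
#' @param cfg a [sim_config()]; the site count is `L` when given, else a
#'   Poisson draw at the configured theta.
#' @param path output VCF path; the sidecar goes to `paste0(path, ".truth.json")`.
#' @return Invisibly, a list with the written `path`, the `pop_map`, and
#'   the per-site drawn configurations.
#' @export
simulate_vcf <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  es <- expected_for_config(cfg)
  keep <- !es$mask & es$values > 0
  cells <- which(keep, arr.ind = TRUE)
  pr <- es$values[keep]
  pr <- pr / sum(pr)

  n1 <- cfg$n_hap[1]; n2 <- cfg$n_hap[2]
  d1 <- n1 %/% 2L; d2 <- n2 %/% 2L
  inds <- c(sprintf("p1_%02d", seq_len(d1)), sprintf("p2_%02d", seq_len(d2)))
  pop_map <- setNames(rep(c("pop1", "pop2"), c(d1, d2)), inds)

  out <- with_seed(derive_seed(cfg$seed, 13L), {
    L <- if (!is.null(cfg$L)) cfg$L
         else rpois(1, cfg$theta * sum(es$values[!es$mask]))
    if (L < 1) L <- 1
    pick <- sample.int(nrow(cells), L, replace = TRUE, prob = pr)
    conf <- cells[pick, , drop = FALSE] - 1L  # minor copies (i, j)
    geno <- matrix(NA_integer_, L, d1 + d2, dimnames = list(NULL, inds))
    for (sgl in seq_len(L)) {
      # random union of gametes: distribute i minor copies over 2*d hap slots
      g1 <- integer(n1); if (conf[sgl, 1] > 0)
        g1[sample.int(n1, conf[sgl, 1])] <- 1L
      g2 <- integer(n2); if (conf[sgl, 2] > 0)
        g2[sample.int(n2, conf[sgl, 2])] <- 1L
      geno[sgl, ] <- c(colSums(matrix(g1, nrow = 2)),
                       colSums(matrix(g2, nrow = 2)))
    }
    miss <- matrix(runif(length(geno)) < cfg$missingness,
                   nrow(geno), ncol(geno))
    geno[miss] <- NA_integer_
    depth <- matrix(rnbinom(length(geno), mu = cfg$depth_mean,
                            size = cfg$depth_dispersion),
                    nrow(geno), ncol(geno))
    depth[is.na(geno)] <- 0L
    list(L = L, conf = conf, geno = geno, depth = depth)
  })

  vt <- variant_table(out$geno, locus = sprintf("locus_%05d", seq_len(out$L)),
                      pos = rep(1L, out$L), pop_map = pop_map,
                      depth = out$depth)
  write_vcf(vt, path)
  truth <- list(model = cfg$model_name, params = as.list(cfg$params),
                theta = cfg$theta, L = out$L, n_hap = cfg$n_hap,
                missingness = cfg$missingness, seed = cfg$seed,
                site_config = unname(apply(out$conf, 1, as.list)))
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
             paste0(path, ".truth.json"))
  invisible(list(path = path, pop_map = pop_map, site_config = out$conf,
                 variant_table = vt))
}
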