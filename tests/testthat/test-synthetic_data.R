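test_that("jSFS simulation is seeded, Poisson around theta times expectation", {
  cfg <- sim_config("no_mig", c(nu1 = 1, nu2 = 1, T1 = 0.5), theta = 100,
                    n_hap = c(6, 6), seed = 5, engine_replicates = 20000)
  a <- simulate_jsfs(cfg)
  b <- simulate_jsfs(cfg)
  expect_identical(a$counts, b$counts)
  expect_true(a$folded)
  expect_true(all(a$counts == floor(a$counts)))

  # theta = 0 gives the empty spectrum
  cfg0 <- sim_config("no_mig", c(nu1 = 1, nu2 = 1, T1 = 0.5), theta = 0,
                     n_hap = c(6, 6), seed = 5, engine_replicates = 5000)
  expect_equal(sum(simulate_jsfs(cfg0)$counts), 0)
})

test_that("large theta obeys the law of large numbers cellwise", {
  cfg <- sim_config("no_mig", c(nu1 = 1, nu2 = 1, T1 = 0.5), theta = 1e6,
                    n_hap = c(6, 6), seed = 8, engine_replicates = 100000)
  sim <- simulate_jsfs(cfg)
  es <- attr(sim, "truth")$expected
  keep <- !sim$mask & (1e6 * es$values) >= 1e5
  rel <- abs(sim$counts[keep] / 1e6 - es$values[keep]) / es$values[keep]
  expect_true(all(rel < 0.01))
  expect_equal(sum(sim$counts[!sim$mask]) / 1e6,
               sum(es$values[!es$mask]), tolerance = 5e-3)
})

test_that("simulated VCFs round-trip through the import and SFS pipeline", {
  cfg <- sim_config("sym_mig", c(nu1 = 1, nu2 = 1.5, m = 1, T1 = 0.6),
                    L = 120, n_hap = c(8, 8), missingness = 0, seed = 3,
                    engine_replicates = 20000)
  path <- withr::local_tempfile(fileext = ".vcf")
  out <- simulate_vcf(cfg, path)
  vt <- read_vcf(path, out$pop_map)
  expect_equal(n_sites_of(vt), 120)
  # with no missingness at full size, the unfolded spectrum tabulates the
  # drawn per-site configurations exactly
  sp <- build_jsfs(vt, c(8, 8))
  tab <- matrix(0, 9, 9)
  for (r in seq_len(nrow(out$site_config))) {
    ij <- out$site_config[r, ] + 1L
    tab[ij[1], ij[2]] <- tab[ij[1], ij[2]] + 1
  }
  tab[sp$mask] <- 0
  expect_equal(sp$counts, tab)

  # the truth sidecar is valid JSON carrying the generating parameters
  truth <- jsonlite::fromJSON(paste0(path, ".truth.json"))
  expect_equal(truth$model, "sym_mig")
  expect_equal(truth$L, 120)
})

test_that("missingness interacts with the export filters as binomial tails", {
  cfg <- sim_config("no_mig", c(nu1 = 1, nu2 = 1, T1 = 0.5), L = 400,
                    n_hap = c(10, 10), missingness = 0.6, seed = 6,
                    engine_replicates = 10000)
  path <- withr::local_tempfile(fileext = ".vcf")
  simulate_vcf(cfg, path)
  vt <- read_vcf(path, setNames(rep(c("pop1", "pop2"), each = 5),
                                c(sprintf("p1_%02d", 1:5),
                                  sprintf("p2_%02d", 1:5))))
  kept <- filter_variants(vt, max_missing = 0.5, min_mean_depth = 0)
  # site removed when more than 5 of 10 genotypes are missing
  p_keep <- pbinom(5, 10, 0.6)
  frac <- n_sites_of(kept) / n_sites_of(vt)
  expect_equal(frac, p_keep, tolerance = 0.08)

  # a depth distribution centred below the threshold removes everything
  cfg2 <- sim_config("no_mig", c(nu1 = 1, nu2 = 1, T1 = 0.5), L = 50,
                     n_hap = c(6, 6), missingness = 0, depth_mean = 2,
                     depth_dispersion = 1e6, seed = 7,
                     engine_replicates = 5000)
  path2 <- withr::local_tempfile(fileext = ".vcf")
  simulate_vcf(cfg2, path2)
  vt2 <- read_vcf(path2, setNames(rep(c("pop1", "pop2"), each = 3),
                                  c(sprintf("p1_%02d", 1:3),
                                    sprintf("p2_%02d", 1:3))))
  expect_equal(n_sites_of(filter_variants(vt2, 0.5, 5)), 0L)
})

test_that("configuration guards hold", {
  expect_error(sim_config("no_mig", c(nu1 = 1, nu2 = 1, T1 = 0.5)),
               "theta or L")
  expect_error(sim_config("no_mig", c(nu1 = 1, nu2 = 1, T1 = 0.5),
                          theta = 10, missingness = 1), "missingness")
  expect_error(sim_config("no_mig", c(nu1 = 1, nu2 = 1, T1 = 0.5),
                          theta = 10, n_hap = c(7, 8)), "even")
  expect_error(sim_config("no_mig", c(nu1 = 200, nu2 = 1, T1 = 0.5),
                          theta = 10), "out of bounds")
})

test_that("the full pipeline is seed-reproducible end to end", {
  run_once <- function() {
    cfg <- sim_config("no_mig", c(nu1 = 1, nu2 = 2, T1 = 0.5), L = 250,
                      n_hap = c(8, 8), missingness = 0.15, seed = 12,
                      engine_replicates = 20000)
    path <- withr::local_tempfile(fileext = ".vcf")
    out <- simulate_vcf(cfg, path)
    vt <- thin_one_snp_per_locus(
      filter_variants(read_vcf(path, out$pop_map), 0.5, 0), seed = 4)
    sp <- fold_jsfs(build_jsfs(vt, c(6, 6)))
    fit <- do.call(fit_demography,
                   c(list(sp, "no_mig", seed = 19), fast_fit_args()))
    list(counts = sp$counts, coef = coef(fit), ll = fit$loglik)
  }
  r1 <- run_once()
  r2 <- run_once()
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$coef, r2$coef)
  expect_identical(r1$ll, r2$ll)
  # and the recovered sizes keep the generating order nu2 > nu1
  expect_gt(r1$coef[["nu2"]], r1$coef[["nu1"]])
})
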