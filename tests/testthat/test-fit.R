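make_pair <- function(seed = 1, n1 = 3, n2 = 3) {
  # a matched (data, model) pair on the folded grid
  dem <- build_demography("sym_mig", c(nu1 = 1, nu2 = 1.5, m = 0.8,
                                       T1 = 0.6))
  es <- fold_expected(expected_jsfs(dem, n1, n2, n_replicates = 20000,
                                    seed = seed))
  data <- with_seed_local(seed, {
    cnt <- matrix(rpois(length(es$values), 50 * es$values),
                  nrow(es$values), ncol(es$values))
    cnt[es$mask] <- 0
    jsfs(cnt, folded = TRUE, mask = es$mask)
  })
  list(data = data, model = es)
}

with_seed_local <- function(seed, expr) demsel:::with_seed(seed, expr)

test_that("profiled theta is the ratio of unmasked sums and maximizes the likelihood", {
  pr <- make_pair(4)
  # exact proportionality
  prop <- pr$data
  prop$counts <- 3 * pr$model$values
  prop$counts[prop$mask] <- 0
  expect_equal(optimal_theta(prop, pr$model), 3)

  # all-zero data
  zero <- pr$data
  zero$counts[] <- 0
  expect_warning(th0 <- optimal_theta(zero, pr$model), "all-zero")
  expect_equal(th0, 0)

  # brute-force 1-D scan oracle
  th <- optimal_theta(pr$data, pr$model)
  grid <- seq(0.5 * th, 1.5 * th, length.out = 2001)
  lls <- vapply(grid, function(t) poisson_loglik(pr$data, pr$model, theta = t),
                numeric(1))
  expect_equal(grid[which.max(lls)], th, tolerance = 1e-3)
  expect_true(all(poisson_loglik(pr$data, pr$model) >= lls))
})

test_that("the composite log-likelihood matches manual summation", {
  pr <- make_pair(5)
  th <- optimal_theta(pr$data, pr$model)
  keep <- !(pr$data$mask | pr$model$mask)
  mu <- pmax(th * pr$model$values[keep], 1e-12)
  manual <- sum(pr$data$counts[keep] * log(mu) - mu)
  expect_equal(poisson_loglik(pr$data, pr$model), manual)

  # saturated value when data equal theta * model exactly
  sat <- pr$data
  sat$counts <- 2 * pr$model$values
  sat$counts[sat$mask] <- 0
  d <- sat$counts[keep]
  expect_equal(poisson_loglik(sat, pr$model),
               sum(d * log(pmax(d, 1e-12)) - d))

  # shape mismatch is an error
  small <- jsfs(matrix(1, 2, 2), folded = TRUE)
  expect_error(poisson_loglik(small, pr$model), "shape")
})

test_that("Akaike weights follow the closed form", {
  expect_equal(unname(aic_weights(c(a = 10))), 1)
  w <- aic_weights(c(m1 = 100, m2 = 102))
  expect_equal(unname(round(w, 4)), c(0.7311, 0.2689))
  expect_equal(sum(w), 1)
  # shift invariance
  expect_equal(unname(aic_weights(c(0, 2, 7))),
               unname(aic_weights(c(50, 52, 57))))
})

test_that("optimization is deterministic and records the full restart trace", {
  cfg <- sim_config("no_mig", c(nu1 = 1, nu2 = 2, T1 = 0.5), theta = 120,
                    n_hap = c(6, 6), seed = 31)
  sim <- simulate_jsfs(cfg)
  args <- fast_fit_args()
  f1 <- do.call(fit_demography, c(list(sim, "no_mig", seed = 8), args))
  f2 <- do.call(fit_demography, c(list(sim, "no_mig", seed = 8), args))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$loglik, f2$loglik)
  expect_equal(nrow(f1$trace), sum(args$rounds))
  # the search objective uses fewer engine replicates than the final
  # refit, so the trace optimum sits above the honest final value by the
  # selection bias of the Monte-Carlo noise
  expect_lt(max(f1$trace$loglik, na.rm = TRUE), f1$loglik + 40)
  expect_equal(f1$aic, 2 * 3 - 2 * f1$loglik)
  expect_error(fit_demography(jsfs(matrix(1, 7, 7)), "no_mig"),
               "folded")
})

test_that("the four-round schedule books 280 restarts", {
  cfg <- sim_config("no_mig", c(nu1 = 1, nu2 = 1, T1 = 0.3), theta = 40,
                    n_hap = c(4, 4), seed = 2, engine_replicates = 5000)
  sim <- simulate_jsfs(cfg)
  fit <- fit_demography(sim, "no_mig", rounds = c(60, 70, 70, 80),
                        perturb_folds = c(3, 2, 2, 1), seed = 3,
                        engine_replicates = 150, final_replicates = 2000,
                        max_eval = 4)
  expect_equal(nrow(fit$trace), 280)
  expect_equal(as.vector(table(fit$trace$round)), c(60, 70, 70, 80))
})

test_that("a richer model never fits worse than its nested submodel", {
  cfg <- sim_config("sym_mig", c(nu1 = 0.8, nu2 = 1.6, m = 1.2, T1 = 0.5),
                    theta = 150, n_hap = c(6, 6), seed = 17)
  sim <- simulate_jsfs(cfg)
  args <- fast_fit_args()
  lls <- vapply(c("no_mig", "sym_mig", "asym_mig"), function(m)
    do.call(fit_demography, c(list(sim, m, seed = 5), args))$loglik,
    numeric(1))
  # nesting chain no_mig < sym_mig < asym_mig, allowing noise from the
  # stochastic objective
  slack <- 2
  expect_gte(lls["sym_mig"], lls["no_mig"] - slack)
  expect_gte(lls["asym_mig"], lls["sym_mig"] - slack)
})

test_that("fit serialization writes JSON and a TSV trace", {
  cfg <- sim_config("no_mig", c(nu1 = 1, nu2 = 2, T1 = 0.5), theta = 80,
                    n_hap = c(4, 4), seed = 31)
  sim <- simulate_jsfs(cfg)
  fit <- do.call(fit_demography,
                 c(list(sim, "no_mig", seed = 8), fast_fit_args()))
  js <- jsonlite::fromJSON(fit_json(fit))
  expect_equal(js$model, "no_mig")
  expect_equal(js$aic, fit$aic)
  path <- withr::local_tempfile(fileext = ".tsv")
  trace_tsv(fit, path)
  tr <- read.delim(path)
  expect_equal(nrow(tr), nrow(fit$trace))
})
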