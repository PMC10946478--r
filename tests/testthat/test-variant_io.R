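test_that("VCF round-trip preserves genotypes, depth and missingness", {
  vt <- toy_variant_table(c(0, 1, 2, 1,
                            1, NA, 0, 2,
                            2, 2, 1, 0),
                          depth = matrix(7L, 3, 4))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vt, path)
  back <- read_vcf(path, toy_pop_map())
  expect_equal(back$geno, vt$geno)
  expect_equal(unname(back$depth[!is.na(back$geno)]),
               rep(7, sum(!is.na(vt$geno))))
  expect_true(is.na(back$geno[2, "i2"]))  # ./. parsed as missing
  expect_equal(back$locus, vt$locus)
})

test_that("samples absent from the population map are a configuration error", {
  vt <- toy_variant_table(c(0, 1, 2, 1))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vt, path)
  expect_error(read_vcf(path, toy_pop_map()[1:3]), "absent from pop_map")
  expect_error(variant_table(vt$geno, vt$locus, vt$pos, toy_pop_map()[1:2]),
               "absent from pop_map")
})

test_that("missingness and mean-depth filters follow the export rules", {
  # site 1: 3 of 4 missing (75%) -> removed; site 2: 50% missing -> kept
  vt <- toy_variant_table(c(NA, NA, NA, 1,
                            NA, NA, 1, 1,
                            0, 1, 1, 2,
                            0, 1, 1, 2),
                          depth = matrix(c(9, 9, 9, 9,
                                           9, 9, 9, 9,
                                           4, 4, 4, 4,
                                           5, 5, 5, 5), 4, 4, byrow = TRUE))
  out <- filter_variants(vt, max_missing = 0.5, min_mean_depth = 5)
  # site 3 has mean depth 4 < 5 -> removed; site 4 mean 5 -> kept
  expect_equal(out$locus, c("L2", "L4"))

  # vacuous thresholds are the identity
  same <- filter_variants(vt, max_missing = 1, min_mean_depth = 0)
  expect_equal(same$geno, vt$geno)

  # mean depth is computed over called genotypes only
  vt2 <- toy_variant_table(c(NA, NA, 1, 1),
                           depth = matrix(c(0, 0, 6, 6), 1, 4, byrow = TRUE))
  expect_equal(n_sites_of(filter_variants(vt2, 0.5, 5)), 1L)
})

test_that("filtering is idempotent and matches a brute-force recount", {
  set.seed(42)
  n <- 40
  geno <- matrix(sample(c(0:2, NA), n * 4, replace = TRUE,
                        prob = c(.3, .2, .2, .3)), n, 4,
                 dimnames = list(NULL, names(toy_pop_map())))
  depth <- matrix(rpois(n * 4, 6), n, 4)
  vt <- variant_table(geno, sprintf("L%d", 1:n), 1:n, toy_pop_map(), depth)
  once <- filter_variants(vt)
  twice <- suppressWarnings(filter_variants(once))
  expect_equal(twice$geno, once$geno)

  keep_brute <- sapply(1:n, function(s) {
    g <- geno[s, ]
    mean(is.na(g)) <= 0.5 && mean(depth[s, !is.na(g)]) >= 5
  })
  expect_equal(n_sites_of(once), sum(keep_brute))
})

test_that("optional presence filter mirrors a minimum-presence export", {
  vt <- toy_variant_table(c(NA, NA, 1, 1,   # present in 50%
                            NA, 0, 1, 1))   # present in 75%
  out <- filter_variants(vt, max_missing = 1, min_mean_depth = 0,
                         min_presence = 0.6)
  expect_equal(out$locus, "L2")
})

test_that("thinning keeps one uniformly chosen SNP per locus, reproducibly", {
  locus <- rep(c("a", "b", "c"), each = 5)
  geno <- matrix(1L, 15, 4, dimnames = list(NULL, names(toy_pop_map())))
  vt <- variant_table(geno, locus, 1:15, toy_pop_map())
  thin1 <- thin_one_snp_per_locus(vt, seed = 5)
  expect_equal(n_sites_of(thin1), 3L)
  expect_equal(unique(thin1$locus), c("a", "b", "c"))
  expect_identical(thin_one_snp_per_locus(vt, seed = 5)$pos, thin1$pos)

  # a single-SNP locus is always retained; a 10-SNP locus varies with seed
  single <- toy_variant_table(c(0, 1, 2, 1), locus = "only")
  for (s in 0:9)
    expect_equal(thin_one_snp_per_locus(single, s)$pos, 1L)
  big <- variant_table(matrix(1L, 10, 4,
                              dimnames = list(NULL, names(toy_pop_map()))),
                       rep("x", 10), 1:10, toy_pop_map())
  picks <- vapply(0:99, function(s) thin_one_snp_per_locus(big, s)$pos,
                  integer(1))
  expect_gt(length(unique(picks)), 1)
})

test_that("per-site filters commute with thinning", {
  set.seed(7)
  geno <- matrix(sample(c(0:2, NA), 120, replace = TRUE), 30, 4,
                 dimnames = list(NULL, names(toy_pop_map())))
  vt <- variant_table(geno, rep(sprintf("L%d", 1:10), each = 3), 1:30,
                      toy_pop_map())
  a <- filter_variants(thin_one_snp_per_locus(vt, 3), max_missing = 0.25,
                       min_mean_depth = 0)
  b <- thin_one_snp_per_locus(filter_variants(vt, max_missing = 0.25,
                                              min_mean_depth = 0), 3)
  # same per-locus survivor sets imply the same retained positions when the
  # filter is per-site and the thin draw conditions on the same seed only
  # through the surviving site lists; compare the filtered universe instead
  expect_true(all(a$pos %in% vt$pos[rowMeans(is.na(vt$geno)) <= 0.25]))
  expect_true(all(b$pos %in% vt$pos[rowMeans(is.na(vt$geno)) <= 0.25]))
})

test_that("empty tables filter with a warning and thin to themselves", {
  vt <- toy_variant_table(c(0, 1, 2, 1))
  empty <- subset_sites_of(vt, integer(0))
  expect_warning(out <- filter_variants(empty), "empty")
  expect_equal(n_sites_of(out), 0L)
  expect_equal(n_sites_of(thin_one_snp_per_locus(empty, 1)), 0L)
})

test_that("the shipped synthetic example VCF loads and filters cleanly", {
  vcf <- system.file("extdata", "synthetic_example.vcf", package = "demsel")
  pm <- read.delim(system.file("extdata", "synthetic_example.popmap.tsv",
                               package = "demsel"))
  vt <- read_vcf(vcf, setNames(pm$population, pm$individual))
  expect_equal(n_sites_of(vt), 60L)
  expect_equal(length(unique(vt$pop_map)), 2L)
  kept <- filter_variants(vt)
  expect_lte(n_sites_of(kept), 60L)
  expect_gt(n_sites_of(kept), 0L)
  sp <- fold_jsfs(build_jsfs(kept, choose_projection(kept)))
  expect_true(sp$folded)
  expect_gt(segregating_sites(sp), 0)
})
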