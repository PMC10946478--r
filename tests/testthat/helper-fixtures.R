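# shared fixtures: tiny variant tables and spectra built in code

# four individuals, two per population
toy_pop_map <- function() {
  setNames(c("A", "A", "B", "B"), c("i1", "i2", "i3", "i4"))
}

# geno rows are sites; entries alt-allele copies or NA
toy_variant_table <- function(geno, locus = NULL, depth = NULL) {
  geno <- matrix(as.integer(geno), ncol = 4, byrow = TRUE,
                 dimnames = list(NULL, names(toy_pop_map())))
  if (is.null(locus)) locus <- sprintf("L%d", seq_len(nrow(geno)))
  variant_table(geno, locus = locus, pos = seq_len(nrow(geno)),
                pop_map = toy_pop_map(), depth = depth)
}

# independent complement-pairing fold, written as a direct enumeration
brute_fold <- function(counts) {
  n1 <- nrow(counts) - 1L; n2 <- ncol(counts) - 1L
  out <- matrix(0, n1 + 1L, n2 + 1L)
  for (i in 0:n1) for (j in 0:n2) {
    ci <- n1 - i; cj <- n2 - j
    tot <- i + j; ctot <- ci + cj
    if (tot < ctot || (tot == ctot && (i < ci || (i == ci && j <= cj)))) {
      out[i + 1, j + 1] <- counts[i + 1, j + 1] +
        if (i == ci && j == cj) 0 else counts[ci + 1, cj + 1]
    }
  }
  out
}

# Table-style parameter vector for the two-epoch founder model used in
# recovery experiments
founder_truth <- function() {
  c(nuA = 0.683, nu1 = 0.431, nu2 = 6.017, m12 = 1.664, m21 = 0.547,
    T1 = 0.092, T2 = 0.647, s = 0.113)
}

fast_fit_args <- function() {
  list(rounds = c(3, 3), perturb_folds = c(3, 2),
       engine_replicates = 2000, final_replicates = 8000)
}

n_sites_of <- function(vt) nrow(vt$geno)
subset_sites_of <- function(vt, keep) demsel:::subset_sites(vt, keep)
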