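#' Joint site-frequency spectrum container
#'
#' A `jsfs` holds a (n1+1) x (n2+1) matrix of (possibly fractional) site
#' counts indexed by the number of derived/minor allele copies observed in
#' each of two populations, together with the haploid sample sizes, a folded
#' flag, a logical mask (`TRUE` = cell excluded from all likelihoods), and
#' the population labels.
#'
#' @param counts numeric matrix, dimensions `(n1+1) x (n2+1)`, non-negative.
#' @param folded logical; has the spectrum been folded to minor-allele
#'   configurations?
#' @param mask logical matrix of the same dimensions (`TRUE` = masked), or
#'   `NULL` for no masking.
#' @param pop_labels character vector of length 2.
#' @return An object of class `jsfs`.
#' @export
jsfs <- function(counts, folded = FALSE, mask = NULL,
                 pop_labels = c("pop1", "pop2")) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("jsfs counts must be finite and non-negative")
  if (is.null(mask)) mask <- matrix(FALSE, nrow(counts), ncol(counts))
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(counts)))
    stop("mask dimensions must match counts")
  structure(
    list(counts = counts, n1 = nrow(counts) - 1L, n2 = ncol(counts) - 1L,
         folded = folded, mask = mask,
         pop_labels = as.character(pop_labels)),
    class = "jsfs")
}

#' @export
print.jsfs <- function(x, ...) {
  cat(sprintf("Joint SFS: %d x %d (%s), pops %s / %s\n",
              x$n1 + 1L, x$n2 + 1L,
              if (x$folded) "folded" else "unfolded",
              x$pop_labels[1], x$pop_labels[2]))
  cat(sprintf("  segregating sites (unmasked): %.4g; masked cells: %d\n",
              segregating_sites(x), sum(x$mask)))
  invisible(x)
}

#' Hypergeometric projection of one site to a smaller sample size
#'
#' Distributes a site observed as `derived` copies out of `total` sampled
#' haploid alleles over all possible derived counts in a subsample of size
#' `target`, with hypergeometric weights. This is the per-site
#' downprojection used to absorb missing genotypes while retaining sites.
#'
#' @param derived integer, derived-allele copies observed (0..total).
#' @param total integer, haploid alleles successfully genotyped at the site.
#' @param target integer, haploid subsample size, `1 <= target <= total`.
#' @return Numeric weight vector of length `target + 1`; sums to 1.
#' @examples
#' project_site(1, 4, 2)  # c(0.5, 0.5, 0)
#' @export
project_site <- function(derived, total, target) {
  if (target < 1 || target > total)
    stop("target must satisfy 1 <= target <= total")
  if (derived < 0 || derived > total)
    stop("derived must lie in [0, total]")
  dhyper(0:target, m = derived, n = total - derived, k = target)
}

#' Build an unfolded joint SFS from a variant table
#'
#' Each biallelic site contributes the outer product of its per-population
#' hypergeometric projection weights ([project_site()]) on a grid of
#' haploid target sizes. Sites with fewer successfully genotyped haploid
#' alleles than the target in either population are dropped. The absorbing
#' cells (0,0) and (n1,n2) are masked.
#'
#' @param vt a [variant_table()].
#' @param target_sizes integer vector `c(n1, n2)` of haploid target sizes.
#' @param pops optional character vector of length 2 selecting and ordering
#'   the two populations; defaults to the order of first appearance in the
#'   population map.
#' @return An unfolded [jsfs()] with fixed cells masked.
#' @export
build_jsfs <- function(vt, target_sizes, pops = NULL) {
  stopifnot(inherits(vt, "variant_table"))
  if (length(target_sizes) != 2L || any(target_sizes < 1))
    stop("target_sizes must be two positive haploid counts")
  if (is.null(pops)) pops <- unique(unname(vt$pop_map))
  if (length(pops) != 2L)
    stop("exactly two populations are required; got: ",
         paste(pops, collapse = ", "))
  n1 <- as.integer(target_sizes[1]); n2 <- as.integer(target_sizes[2])
  idx1 <- which(vt$pop_map[vt$individuals] == pops[1])
  idx2 <- which(vt$pop_map[vt$individuals] == pops[2])
  if (2L * length(idx1) < n1 || 2L * length(idx2) < n2)
    stop("target size exceeds available haploid alleles in a population")
  counts <- matrix(0, n1 + 1L, n2 + 1L)
  if (nrow(vt$geno) > 0L) {
    for (s in seq_len(nrow(vt$geno))) {
      g1 <- vt$geno[s, idx1]; g2 <- vt$geno[s, idx2]
      t1 <- 2L * sum(!is.na(g1)); t2 <- 2L * sum(!is.na(g2))
      if (t1 < n1 || t2 < n2) next
      w1 <- project_site(sum(g1, na.rm = TRUE), t1, n1)
      w2 <- project_site(sum(g2, na.rm = TRUE), t2, n2)
      counts <- counts + outer(w1, w2)
    }
  }
  mask_fixed(jsfs(counts, folded = FALSE, pop_labels = pops))
}

#' Choose downprojection target sizes
#'
#' Default heuristic for the haploid target sizes of [build_jsfs()]:
#' maximize `target1 + target2` subject to retaining at least
#' `min_retain` of the sites (a site is retained when both populations
#' have at least the target number of successfully genotyped haploid
#' alleles). Ties prefer the more balanced pair.
#'
#' @param vt a [variant_table()].
#' @param min_retain minimum fraction of sites the projection must keep
#'   (default 0.8).
#' @param pops optional pair of population labels (order respected).
#' @return Integer vector `c(n1, n2)` of haploid target sizes.
#' @export
choose_projection <- function(vt, min_retain = 0.8, pops = NULL) {
  stopifnot(inherits(vt, "variant_table"))
  if (n_sites_int(vt) == 0L) stop("empty variant table")
  if (is.null(pops)) pops <- unique(unname(vt$pop_map))
  if (length(pops) != 2L) stop("exactly two populations required")
  idx1 <- which(vt$pop_map[vt$individuals] == pops[1])
  idx2 <- which(vt$pop_map[vt$individuals] == pops[2])
  called1 <- 2L * rowSums(!is.na(vt$geno[, idx1, drop = FALSE]))
  called2 <- 2L * rowSums(!is.na(vt$geno[, idx2, drop = FALSE]))
  best <- NULL
  for (t1 in seq_len(2L * length(idx1))) {
    for (t2 in seq_len(2L * length(idx2))) {
      retained <- mean(called1 >= t1 & called2 >= t2)
      if (retained >= min_retain) {
        cand <- c(t1, t2)
        if (is.null(best) || sum(cand) > sum(best) ||
            (sum(cand) == sum(best) &&
             abs(diff(cand)) < abs(diff(best))))
          best <- cand
      }
    }
  }
  if (is.null(best))
    stop("no projection retains ", min_retain, " of the sites")
  best
}

n_sites_int <- function(vt) nrow(vt$geno)

# fold rule shared by data spectra and expected spectra: cell (i, j) merges
# with (n1-i, n2-j); kept cell is the one with smaller total i+j, ties
# resolved toward the lexicographically smaller index; cells strictly above
# the fold line end up zeroed and masked.
fold_matrix <- function(counts, mask) {
  n1 <- nrow(counts) - 1L; n2 <- ncol(counts) - 1L
  out <- matrix(0, n1 + 1L, n2 + 1L)
  outmask <- matrix(FALSE, n1 + 1L, n2 + 1L)
  half <- (n1 + n2) / 2
  for (i in 0:n1) for (j in 0:n2) {
    ci <- n1 - i; cj <- n2 - j
    tot <- i + j
    keep <-
      if (tot < half) TRUE
      else if (tot > half) FALSE
      else (i < ci || (i == ci && j <= cj))  # tie: lexicographically smaller
    if (!keep) { outmask[i + 1, j + 1] <- TRUE; next }
    if (i == ci && j == cj) {  # self-complement
      out[i + 1, j + 1] <- counts[i + 1, j + 1]
      outmask[i + 1, j + 1] <- mask[i + 1, j + 1]
    } else {
      out[i + 1, j + 1] <- counts[i + 1, j + 1] + counts[ci + 1, cj + 1]
      outmask[i + 1, j + 1] <- mask[i + 1, j + 1] || mask[ci + 1, cj + 1]
    }
  }
  list(counts = out, mask = outmask)
}

#' Fold a joint SFS to minor-allele configurations
#'
#' Merges every cell with its allele-label complement `(n1-i, n2-j)`,
#' zeroing and masking cells strictly above the fold line. Unmasked mass is
#' conserved. Folding an already folded spectrum is an error.
#'
#' @param x an unfolded [jsfs()].
#' @return The folded [jsfs()].
#' @export
fold_jsfs <- function(x) {
  stopifnot(inherits(x, "jsfs"))
  if (x$folded) stop("spectrum is already folded")
  f <- fold_matrix(x$counts, x$mask)
  jsfs(f$counts, folded = TRUE, mask = f$mask, pop_labels = x$pop_labels)
}

#' Mask the absorbing (fixed) cells of a joint SFS
#'
#' Cells (0,0) and (n1,n2) do not correspond to segregating sites and are
#' excluded from every likelihood. Idempotent.
#'
#' @param x a [jsfs()].
#' @return The same spectrum with the two fixed cells masked.
#' @export
mask_fixed <- function(x) {
  stopifnot(inherits(x, "jsfs"))
  x$mask[1, 1] <- TRUE
  x$mask[x$n1 + 1L, x$n2 + 1L] <- TRUE
  x
}

#' Number of segregating sites in a joint SFS
#'
#' @param x a [jsfs()].
#' @return Sum of counts over unmasked cells (possibly fractional after
#'   projection).
#' @export
segregating_sites <- function(x) {
  stopifnot(inherits(x, "jsfs"))
  sum(x$counts[!x$mask])
}

#' Write / read a joint SFS in plain-text SFS format
#'
#' The format is dadi-compatible: a header line `"(n1+1) (n2+1) folded|unfolded"`,
#' one line of row-major counts, and one line of row-major mask indicators
#' (1 = masked).
#'
#' @param x a [jsfs()].
#' @param path file path.
#' @return `write_sfs` returns `path` invisibly; `read_sfs` returns a
#'   [jsfs()].
#' @export
write_sfs <- function(x, path) {
  stopifnot(inherits(x, "jsfs"))
  header <- sprintf("%d %d %s", x$n1 + 1L, x$n2 + 1L,
                    if (x$folded) "folded" else "unfolded")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(format(as.vector(t(x$counts)), digits = 17,
                          scientific = TRUE, trim = TRUE), collapse = " "),
             con)
  writeLines(paste(as.integer(as.vector(t(x$mask))), collapse = " "), con)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed SFS file: ", path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  d1 <- as.integer(hdr[1]); d2 <- as.integer(hdr[2])
  folded <- identical(hdr[3], "folded")
  cnt <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
  msk <- as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]])
  if (length(cnt) != d1 * d2 || length(msk) != d1 * d2)
    stop("malformed SFS file: ", path)
  jsfs(matrix(cnt, d1, d2, byrow = TRUE), folded = folded,
       mask = matrix(msk == 1L, d1, d2, byrow = TRUE))
}
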