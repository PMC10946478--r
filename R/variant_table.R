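#' Biallelic SNP genotype table
#'
#' Container for diploid genotypes at biallelic sites: an integer matrix of
#' derived/alt-allele copy numbers (0, 1, 2 or `NA` for missing), a
#' matching per-genotype sequencing depth matrix, locus identifiers,
#' positions, and a population map.
#'
#' @param geno integer matrix, sites x individuals; entries 0/1/2/`NA`.
#' @param locus character vector of locus identifiers (one per site,
#'   non-empty); several sites may share a locus.
#' @param pos integer vector of positions (one per site).
#' @param pop_map named character vector mapping individual -> population
#'   label; every column of `geno` must appear.
#' @param depth optional non-negative numeric matrix of per-genotype depths,
#'   same dimensions as `geno`.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(geno, locus, pos, pop_map, depth = NULL) {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno))) stop("geno must have individual column names")
  if (!all(geno %in% c(0L, 1L, 2L, NA)))
    stop("genotypes must be 0, 1, 2 or NA")
  if (length(locus) != nrow(geno) || any(!nzchar(locus)))
    stop("locus must be a non-empty id per site")
  if (length(pos) != nrow(geno)) stop("pos must have one entry per site")
  missing_ind <- setdiff(colnames(geno), names(pop_map))
  if (length(missing_ind))
    stop("individuals absent from pop_map: ",
         paste(missing_ind, collapse = ", "))
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!identical(dim(depth), dim(geno)))
      stop("depth dimensions must match geno")
  }
  structure(
    list(geno = geno, depth = depth, locus = as.character(locus),
         pos = as.integer(pos), individuals = colnames(geno),
         pop_map = pop_map[colnames(geno)]),
    class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf(
    "Variant table: %d sites (%d loci), %d individuals, %d populations\n",
    nrow(x$geno), length(unique(x$locus)), ncol(x$geno),
    length(unique(x$pop_map))))
  invisible(x)
}

n_sites <- function(vt) nrow(vt$geno)

subset_sites <- function(vt, keep) {
  variant_table(vt$geno[keep, , drop = FALSE], vt$locus[keep], vt$pos[keep],
                vt$pop_map,
                depth = if (!is.null(vt$depth)) vt$depth[keep, , drop = FALSE])
}

#' Read biallelic SNPs from a VCF file
#'
#' Parses GT (required) and DP (optional) FORMAT fields into a
#' [variant_table()]. Diploid genotypes are coded as alt-allele copy
#' numbers; `./.` (or any genotype containing `.`) becomes missing.
#' De-novo RAD catalogues place the locus identifier either in the CHROM
#' column or in the ID column, selectable via `locus_from`.
#'
#' @param path path to a VCF 4.x file.
#' @param pop_map named character vector individual -> population; all
#'   sample names in the VCF must be present.
#' @param locus_from `"chrom"` (default) or `"id"`: column providing the
#'   locus identifier.
#' @param multiallelic `"skip"` (default) to drop sites with more than one
#'   ALT allele, or `"error"`.
#' @return A [variant_table()]; site order follows the file.
#' @examples
#' vcf <- system.file("extdata", "synthetic_example.vcf", package = "demsel")
#' pm <- read.delim(system.file("extdata", "synthetic_example.popmap.tsv",
#'                              package = "demsel"))
#' vt <- read_vcf(vcf, setNames(pm$population, pm$individual))
#' vt
#' @export
read_vcf <- function(path, pop_map, locus_from = c("chrom", "id"),
                     multiallelic = c("skip", "error")) {
  locus_from <- match.arg(locus_from)
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  samples <- colnames(v@gt)[-1]
  absent <- setdiff(samples, names(pop_map))
  if (length(absent))
    stop("VCF samples absent from pop_map: ", paste(absent, collapse = ", "))

  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi) && multiallelic == "error")
    stop("multiallelic site(s) at row(s): ",
         paste(which(multi), collapse = ", "))
  keep <- !multi

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  gt <- matrix(gt, nrow = nrow(fix),
               dimnames = list(NULL, samples))[keep, , drop = FALSE]
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt),
                 dimnames = list(NULL, samples))
  alleles <- gsub("\\|", "/", gt)
  ok <- !is.na(alleles) & grepl("^[01]/[01]$", alleles)
  geno[ok] <- as.integer(substr(alleles[ok], 1, 1)) +
    as.integer(substr(alleles[ok], 3, 3))

  depth <- NULL
  fmt_has_dp <- any(grepl("DP", v@gt[, 1], fixed = TRUE))
  if (fmt_has_dp) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    depth <- matrix(dp, nrow = nrow(fix),
                    dimnames = list(NULL, samples))[keep, , drop = FALSE]
    depth[is.na(depth)] <- 0
  }

  locus <- if (locus_from == "chrom") fix[keep, "CHROM"] else fix[keep, "ID"]
  if (any(is.na(locus) | !nzchar(locus)))
    stop("empty locus identifier in column ", toupper(locus_from))
  variant_table(geno, locus, as.integer(fix[keep, "POS"]), pop_map,
                depth = depth)
}

#' Filter sites on missingness and mean depth
#'
#' A site is retained iff its fraction of missing genotypes is at most
#' `max_missing` and its mean sequencing depth, computed over non-missing
#' genotypes only, is at least `min_mean_depth`. Mirrors the vcftools
#' `--max-missing` / `--min-meanDP` export filters. When the table carries
#' no depth information the depth filter is skipped with a warning.
#'
#' @param vt a [variant_table()].
#' @param max_missing maximum tolerated fraction of missing genotypes
#'   (default 0.5; retention uses `<=`).
#' @param min_mean_depth minimum mean depth over called genotypes
#'   (default 5).
#' @param min_presence optional fraction R: additionally require the site
#'   to be present (non-missing) in at least R of all individuals. `NULL`
#'   (default) disables the extra filter.
#' @return The filtered [variant_table()], site order preserved.
#' @export
filter_variants <- function(vt, max_missing = 0.5, min_mean_depth = 5,
                            min_presence = NULL) {
  stopifnot(inherits(vt, "variant_table"))
  if (max_missing < 0 || max_missing > 1) stop("max_missing must be in [0,1]")
  if (min_mean_depth < 0) stop("min_mean_depth must be >= 0")
  if (n_sites(vt) == 0L) {
    warning("filtering an empty variant table")
    return(vt)
  }
  miss_frac <- rowMeans(is.na(vt$geno))
  keep <- miss_frac <= max_missing
  if (!is.null(min_presence))
    keep <- keep & (1 - miss_frac >= min_presence)
  if (min_mean_depth > 0) {
    if (is.null(vt$depth)) {
      warning("no depth information; mean-depth filter skipped")
    } else {
      d <- vt$depth
      d[is.na(vt$geno)] <- NA
      mean_dp <- rowMeans(d, na.rm = TRUE)
      mean_dp[is.nan(mean_dp)] <- 0  # all-missing rows
      keep <- keep & (mean_dp >= min_mean_depth)
    }
  }
  subset_sites(vt, keep)
}

#' Thin to one randomly chosen SNP per locus
#'
#' Retains exactly one uniformly chosen site per distinct locus identifier,
#' emulating a random-SNP export that avoids linked sites within a locus.
#' Deterministic for a fixed seed; site order is preserved.
#'
#' @param vt a [variant_table()].
#' @param seed integer seed governing the per-locus choice.
#' @return The thinned [variant_table()].
#' @export
thin_one_snp_per_locus <- function(vt, seed) {
  stopifnot(inherits(vt, "variant_table"))
  if (n_sites(vt) == 0L) return(vt)
  keep <- with_seed(seed, {
    chosen <- vapply(split(seq_len(n_sites(vt)), vt$locus), function(ix) {
      if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
    }, integer(1))
    sort(unname(chosen))
  })
  subset_sites(vt, keep)
}

#' Write a variant table to VCF
#'
#' Emits a minimal VCF 4.2 file with GT (and DP when available) FORMAT
#' fields; the locus identifier goes to CHROM. Heterozygotes are written
#' `0/1`, missing genotypes `./.`.
#'
#' @param vt a [variant_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=demsel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$individuals), collapse = "\t")), con)
  gt_str <- c("0/0", "0/1", "1/1")
  has_dp <- !is.null(vt$depth)
  for (s in seq_len(n_sites(vt))) {
    g <- vt$geno[s, ]
    cells <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    if (has_dp)
      cells <- paste(cells, as.integer(round(vt$depth[s, ])), sep = ":")
    writeLines(paste(c(vt$locus[s], vt$pos[s], ".", "A", "T", ".", "PASS",
                       ".", if (has_dp) "GT:DP" else "GT", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Per-site report of filter statistics
#'
#' @param vt a [variant_table()].
#' @return A data.frame with locus, position, missing fraction and mean
#'   depth over called genotypes (NA when no depth is stored).
#' @export
site_report <- function(vt) {
  stopifnot(inherits(vt, "variant_table"))
  miss <- rowMeans(is.na(vt$geno))
  mdp <- rep(NA_real_, n_sites(vt))
  if (!is.null(vt$depth)) {
    d <- vt$depth
    d[is.na(vt$geno)] <- NA
    mdp <- rowMeans(d, na.rm = TRUE)
  }
  data.frame(locus = vt$locus, pos = vt$pos, missing_fraction = miss,
             mean_depth = mdp)
}
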