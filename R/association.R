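#' Alternate-allele frequency from phenotype counts at one site
#'
#' The count of the principal (highest-total) non-reference nucleotide
#' divided by the total retained nucleotide count.
#'
#' @param counts named numeric vector of allele counts (names among
#'   A, C, G, T).
#' @param ref the reference base at the site.
#' @return frequency of the principal alternate allele in `[0, 1]`.
#' @examples
#' alt_allele_frequency(c(A = 30, C = 70), ref = "A") # 0.7
#' @export
alt_allele_frequency <- function(counts, ref) {
  stopifnot(ref %in% BASES)
  tot <- sum(counts)
  if (tot == 0) stop("zero depth: alternate frequency undefined")
  alt <- counts[setdiff(names(counts), ref)]
  if (length(alt) == 0L) return(0)
  unname(max(alt) / tot)
}

#' Heterogeneity chi-square between two phenotypes at one site
#'
#' Pearson chi-square on the 2 x k phenotype-by-allele table, where k is
#' the number of distinct alleles with a nonzero total at the site;
#' df = k - 1. Alleles absent from both phenotypes are dropped before
#' computing, so no expected cell is zero. No continuity correction is
#' applied.
#'
#' @param phenA_counts,phenB_counts named numeric vectors of allele counts
#'   for the two phenotypes (replicates already summed).
#' @return list with `chi2`, `df`, `p` and `log10_p`.
#' @examples
#' heterogeneity_chi2(c(A = 90, C = 10), c(A = 50, C = 50))
#' @export
heterogeneity_chi2 <- function(phenA_counts, phenB_counts) {
  alleles <- union(names(phenA_counts), names(phenB_counts))
  a <- setNames(rep(0, length(alleles)), alleles)
  b <- a
  a[names(phenA_counts)] <- phenA_counts
  b[names(phenB_counts)] <- phenB_counts
  if (sum(a) == 0 || sum(b) == 0)
    stop("both phenotypes need positive total counts")
  tab <- rbind(a, b)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L)
    stop("heterogeneity test undefined: fewer than 2 alleles present")
  res <- pearson_chi2(tab)
  res[c("chi2", "df", "p", "log10_p")]
}

#' Expected heterozygosity of an allele-frequency spectrum
#'
#' Nei's gene diversity `H_exp = 1 - sum(p_i^2)` over the allele
#' frequencies at a site. Bounded by `1 - 1/k` for k alleles and maximized
#' at equal frequencies.
#'
#' @param p numeric vector of allele frequencies summing to 1 (within
#'   1e-9), or a matrix with one spectrum per row.
#' @return `H_exp` (vector for matrix input).
#' @examples
#' expected_heterozygosity(c(0.93, 0.07)) # 0.1302
#' @export
expected_heterozygosity <- function(p) {
  if (is.matrix(p)) {
    if (any(abs(rowSums(p) - 1) > 1e-9) || any(p < 0))
      stop("each frequency spectrum must be non-negative and sum to 1")
    return(1 - rowSums(p^2))
  }
  if (abs(sum(p) - 1) > 1e-9 || any(p < 0))
    stop("frequencies must be non-negative and sum to 1")
  1 - sum(p^2)
}

#' Run one pairwise phenotype comparison
#'
#' Orchestrates a comparison from raw counts through the LOD: depth and
#' quality filtering, polymorphic-site detection, the replicate
#' goodness-of-fit screen (a site must pass, p > threshold, in both
#' phenotypes), summing replicate counts per phenotype, the per-site
#' heterogeneity chi-square with df = (alleles - 1), LOD (computed in log
#' space so underflowing tails stay finite), and expected heterozygosity
#' per phenotype and for the pooled spectrum. Significance is left to
#' [bh_by_chromosome()].
#'
#' @param counts a [pool_counts()] object holding all libraries.
#' @param cfg a [filter_config()].
#' @param comparison character vector of the two phenotype labels, e.g.
#'   `c("kdr", "recovered")`.
#' @return data.frame of SNP records (class `snp_records`): `chrom`, `pos`,
#'   `ref`, `alt`, `alts`, `alt_freq_a`, `alt_freq_b`, `chi2`, `df`, `p`,
#'   `lod`, `het_a`, `het_b`, `het_total`. Attributes `comparison` and
#'   `stage_counts` record the phenotype pair and per-stage site tallies.
#' @export
run_comparison <- function(counts, cfg = filter_config(), comparison) {
  stopifnot(length(comparison) == 2L)
  filt <- filter_sites(counts, cfg, comparison)
  n_common <- nrow(filt$sites)
  poly <- detect_polymorphic(filt, comparison)
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), alts = character(),
                      alt_freq_a = numeric(), alt_freq_b = numeric(),
                      chi2 = numeric(), df = integer(), p = numeric(),
                      lod = numeric(), het_a = numeric(), het_b = numeric(),
                      het_total = numeric(), stringsAsFactors = FALSE)
  stage <- c(common = n_common, polymorphic = nrow(poly),
             replicate_pass = 0L, tested = 0L)
  if (nrow(poly) == 0L)
    return(snp_records(empty, comparison, stage))
  sub <- subset_counts(filt, site_idx = poly$site_idx)

  # replicate screen per phenotype; undefined tests (single replicate or
  # single allele) pass: no evidence of discordance
  p1 <- replicate_screen_p(sub, comparison[1])
  p2 <- replicate_screen_p(sub, comparison[2])
  pass <- (is.na(p1) | p1 > cfg$replicate_p_threshold) &
          (is.na(p2) | p2 > cfg$replicate_p_threshold)
  stage["replicate_pass"] <- sum(pass)
  if (!any(pass)) return(snp_records(empty, comparison, stage))
  sub <- subset_counts(sub, site_idx = which(pass))
  poly <- poly[pass, , drop = FALSE]

  a <- base_counts(sub, libs_of(sub, comparison[1]))
  b <- base_counts(sub, libs_of(sub, comparison[2]))
  ht <- chi2_2xk_rows(a, b)
  ok <- !is.na(ht$chi2)
  stage["tested"] <- sum(ok)

  alt_col <- match(poly$alt, BASES)
  n <- nrow(poly)
  ii <- cbind(seq_len(n), alt_col)
  fa <- a[ii] / rowSums(a)
  fb <- b[ii] / rowSums(b)
  pa <- a / rowSums(a)
  pb <- b / rowSums(b)
  pt <- (a + b) / rowSums(a + b)
  rec <- data.frame(
    chrom = poly$chrom, pos = poly$pos, ref = poly$ref, alt = poly$alt,
    alts = poly$alts,
    alt_freq_a = fa, alt_freq_b = fb,
    chi2 = ht$chi2, df = ht$df, p = ht$p,
    lod = -ht$log10_p,
    het_a = 1 - rowSums(pa^2), het_b = 1 - rowSums(pb^2),
    het_total = 1 - rowSums(pt^2),
    stringsAsFactors = FALSE
  )[ok, , drop = FALSE]
  rownames(rec) <- NULL
  snp_records(rec, comparison, stage)
}

snp_records <- function(df, comparison, stage_counts) {
  attr(df, "comparison") <- comparison
  attr(df, "stage_counts") <- stage_counts
  class(df) <- c("snp_records", "data.frame")
  df
}
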