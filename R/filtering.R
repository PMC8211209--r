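#' Site-filter configuration
#'
#' Depth, base-quality and replicate-concordance thresholds. Defaults
#' follow the exome pool-seq pipeline conventions: minimum coverage 25,
#' maximum coverage 1000 (sites above are treated as repetitive DNA),
#' minimum base quality 30, replicate goodness-of-fit p-threshold 0.05.
#' Sites with depth exactly 25 or exactly 1000 are retained (the exclusion
#' clauses are "fewer than 25 reads" and "coverage > 1000").
#'
#' @param min_depth minimum per-library coverage (default 25).
#' @param max_depth maximum per-library coverage (default 1000).
#' @param min_base_quality minimum mean Phred base quality (default 30).
#' @param replicate_p_threshold replicate-screen p-value threshold
#'   (default 0.05; sites pass when p > threshold in both phenotypes).
#' @param alpha per-chromosome Benjamini-Hochberg level (default 0.01).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(min_depth = 25, max_depth = 1000,
                          min_base_quality = 30,
                          replicate_p_threshold = 0.05,
                          alpha = 0.01) {
  stopifnot(min_depth > 0, min_depth <= max_depth,
            replicate_p_threshold > 0, replicate_p_threshold < 1,
            alpha > 0, alpha < 1)
  structure(list(min_depth = min_depth, max_depth = max_depth,
                 min_base_quality = min_base_quality,
                 replicate_p_threshold = replicate_p_threshold,
                 alpha = alpha),
            class = "filter_config")
}

#' Apply depth and quality filters across a comparison's libraries
#'
#' Retains exactly the sites where, in every library of the two compared
#' phenotypes, coverage lies within `[min_depth, max_depth]` (coverage
#' above `max_depth` marks repetitive DNA) and the mean base quality is at
#' least `min_base_quality`. When the count set carries no quality channel
#' the quality filter is treated as satisfied upstream and this is logged
#' once. The returned object keeps only the comparison's libraries.
#'
#' @param counts a [pool_counts()] object.
#' @param cfg a [filter_config()].
#' @param comparison character vector of the two phenotype labels.
#' @return a filtered [pool_counts()]; attribute `n_retained` records the
#'   retained-site count.
#' @export
filter_sites <- function(counts, cfg = filter_config(), comparison) {
  stopifnot(inherits(counts, "pool_counts"), length(comparison) == 2L)
  lib_idx <- which(counts$libraries$phenotype %in% comparison)
  if (length(lib_idx) == 0L)
    stop("no libraries for phenotypes: ", paste(comparison, collapse = ", "))
  depth <- lib_depths(counts, lib_idx)
  keep <- rowSums(depth >= cfg$min_depth & depth <= cfg$max_depth) ==
    length(lib_idx)
  if (is.null(counts$qual)) {
    message("no base-quality channel: quality filter treated as satisfied upstream")
  } else {
    q <- counts$qual[, lib_idx, drop = FALSE]
    keep <- keep & rowSums(q >= cfg$min_base_quality) == length(lib_idx)
  }
  out <- subset_counts(counts, site_idx = which(keep), lib_idx = lib_idx)
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Detect polymorphic sites against the reference
#'
#' A site is a SNP for a comparison iff, summed over the comparison's
#' libraries, at least one non-reference nucleotide has a positive count
#' and the site is not fixed for a single allele (sites fixed for one
#' alternate carry no frequency contrast and are excluded). Alternate
#' alleles are recorded in descending total count.
#'
#' @param counts a filtered [pool_counts()] (e.g. from [filter_sites()]).
#' @param comparison the two phenotype labels; defaults to all libraries
#'   present.
#' @return data.frame with `site_idx`, `chrom`, `pos`, `ref`, `alt`
#'   (principal alternate) and `alts` (comma-separated, by descending
#'   count).
#' @export
detect_polymorphic <- function(counts,
                               comparison = unique(counts$libraries$phenotype)) {
  lib_idx <- which(counts$libraries$phenotype %in% comparison)
  tot <- base_counts(counts, lib_idx)               # n x 4, A C G T
  ref_col <- match(counts$sites$ref, BASES)
  nonref <- tot
  nonref[cbind(seq_len(nrow(tot)), ref_col)] <- 0
  n_alleles <- rowSums(tot > 0)
  is_snp <- rowSums(nonref > 0) >= 1L & n_alleles >= 2L
  idx <- which(is_snp)
  alts <- character(length(idx))
  alt1 <- character(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    nz <- which(nonref[i, ] > 0)
    nz <- nz[order(nonref[i, nz], decreasing = TRUE)]
    alt1[j] <- BASES[nz[1]]
    alts[j] <- paste(BASES[nz], collapse = ",")
  }
  data.frame(site_idx = idx,
             chrom = counts$sites$chrom[idx],
             pos = counts$sites$pos[idx],
             ref = counts$sites$ref[idx],
             alt = alt1, alts = alts,
             stringsAsFactors = FALSE)
}

#' Replicate-concordance goodness-of-fit test at one site
#'
#' Pearson homogeneity chi-square on the 2 x k table of the two biological
#' replicates' allele counts (alleles with a nonzero total), with no
#' continuity correction. A site passes when p exceeds the configured
#' threshold; within a pairwise comparison a site must pass in both
#' phenotypes to proceed to the association test.
#'
#' @param rep1_counts,rep2_counts named numeric vectors of allele counts
#'   for the two replicates (names among A, C, G, T).
#' @param cfg a [filter_config()] supplying `replicate_p_threshold`.
#' @return list with `chi2`, `df`, `p`, and logical `pass`.
#' @examples
#' replicate_consistency(c(A = 80, C = 20), c(A = 40, C = 10)) # chi2 = 0
#' @export
replicate_consistency <- function(rep1_counts, rep2_counts,
                                  cfg = filter_config()) {
  alleles <- union(names(rep1_counts), names(rep2_counts))
  if (is.null(alleles)) stop("counts must be named by allele")
  r1 <- setNames(rep(0, length(alleles)), alleles)
  r2 <- r1
  r1[names(rep1_counts)] <- rep1_counts
  r2[names(rep2_counts)] <- rep2_counts
  tab <- rbind(rep1 = r1, rep2 = r2)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L)
    stop("replicate test undefined: fewer than 2 alleles with nonzero counts")
  res <- pearson_chi2(tab)
  list(chi2 = res$chi2, df = res$df, p = res$p,
       pass = res$p > cfg$replicate_p_threshold)
}

# Vectorized replicate screen for one phenotype across all sites: returns
# the per-site p-value of the 2 x k replicate homogeneity test (NA when
# the test is undefined, treated as pass: no evidence of discordance).
replicate_screen_p <- function(counts, phenotype) {
  idx <- libs_of(counts, phenotype)
  if (length(idx) < 2L)
    return(rep(NA_real_, nrow(counts$sites)))
  r1 <- counts$counts[, BASES, idx[1], drop = TRUE]
  r2 <- counts$counts[, BASES, idx[2], drop = TRUE]
  if (is.null(dim(r1))) { r1 <- matrix(r1, nrow = 1); r2 <- matrix(r2, nrow = 1) }
  chi2_2xk_rows(r1, r2)$p
}
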