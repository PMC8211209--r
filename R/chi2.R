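#' Pearson chi-square on a contingency table
#'
#' Plain Pearson chi-square, sum((O - E)^2 / E), with no continuity
#' correction. Rows or columns whose marginal total is zero are dropped
#' before computing (they contribute no information and would make expected
#' counts zero); the degrees of freedom are (r - 1)(c - 1) on the reduced
#' table. This single statistic underlies the replicate-concordance screen,
#' the between-phenotype heterogeneity test, and the genotype contingency
#' analysis.
#'
#' @param tab numeric matrix of non-negative observed counts.
#' @param warn_dropped warn when zero-margin rows/columns are removed.
#' @return list with `chi2`, `df`, `p` (upper tail), `log10_p` (computed in
#'   log space, finite for any representable statistic), `expected` matrix,
#'   and the reduced `observed` matrix.
#' @examples
#' pearson_chi2(rbind(c(90, 10), c(50, 50)))
#' @export
pearson_chi2 <- function(tab, warn_dropped = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || anyNA(tab)) stop("counts must be non-negative and non-missing")
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (warn_dropped && (!all(keep_r) || !all(keep_c)))
    warning("dropping rows/columns with zero marginal totals")
  tab <- tab[keep_r, keep_c, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("chi-square undefined: fewer than 2 non-empty rows or columns")
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(
    chi2 = chi2,
    df = df,
    p = stats::pchisq(chi2, df, lower.tail = FALSE),
    log10_p = stats::pchisq(chi2, df, lower.tail = FALSE, log.p = TRUE) / log(10),
    expected = expected,
    observed = tab
  )
}

# Vectorized 2 x k Pearson chi-square across many sites.
#
# a, b: n_sites x k matrices of counts for the two groups (columns =
# alleles). Alleles absent from both groups at a site are dropped from that
# site's table; df = (number of non-empty allele columns) - 1. Sites where
# either group has zero total, or with < 2 non-empty alleles, get NA.
# Returns list(chi2, df, p, log10_p) of per-site vectors.
chi2_2xk_rows <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(identical(dim(a), dim(b)))
  ta <- rowSums(a); tb <- rowSums(b)
  ct <- a + b                      # per-allele column totals
  n <- ta + tb
  ea <- ct * (ta / n)
  eb <- ct * (tb / n)
  da <- (a - ea)^2 / ea
  db <- (b - eb)^2 / eb
  nz <- ct > 0
  da[!nz] <- 0; db[!nz] <- 0
  da[is.nan(da)] <- 0; db[is.nan(db)] <- 0
  chi2 <- rowSums(da) + rowSums(db)
  df <- rowSums(nz) - 1L
  bad <- ta == 0 | tb == 0 | df < 1L
  chi2[bad] <- NA_real_
  df[bad] <- NA_integer_
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  l10 <- stats::pchisq(chi2, df, lower.tail = FALSE, log.p = TRUE) / log(10)
  list(chi2 = chi2, df = df, p = p, log10_p = l10)
}

#' LOD transform of a p-value
#'
#' The association score used throughout the scan: -log10 of the chi-square
#' tail probability. For p-values at or below double underflow the LOD is
#' computed from the log-space tail instead (see [run_comparison()]), so
#' representable statistics never give infinite LODs.
#'
#' @param p p-value(s) in (0, 1].
#' @return -log10(p).
#' @examples
#' lod(0.05) # 1.301
#' @export
lod <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]; for underflowing tails use the log-space path")
  -log10(p)
}
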