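#' Construct a phenotype x genotype count table
#'
#' Integer genotype counts for one locus, with phenotypes as rows and the
#' three genotype classes as columns: resistant homozygote (`RR`),
#' heterozygote (`RS`), wild-type homozygote (`SS`).
#'
#' @param counts integer matrix (phenotypes x 3 genotypes) with dimnames.
#' @param locus optional locus label (e.g. `"V410L"`).
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(counts, locus = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  if (ncol(counts) != 3L)
    stop("expected 3 genotype columns (RR, RS, SS)")
  if (is.null(colnames(counts))) colnames(counts) <- c("RR", "RS", "SS")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("phen", seq_len(nrow(counts)))
  structure(list(counts = counts, locus = locus), class = "genotype_table")
}

#' Reconstruct a genotype table from printed percentages
#'
#' Publications often report per-phenotype genotype composition as
#' percentages of the genotyped sample. This helper converts percentages
#' back to integer counts (nearest-integer rounding) and verifies each row
#' recovers its sample size exactly.
#'
#' @param percent matrix of genotype percentages (phenotypes x 3), each row
#'   summing to 100.
#' @param n_per_phenotype integer vector of genotyped individuals per
#'   phenotype.
#' @param locus optional locus label.
#' @return a [genotype_table()].
#' @examples
#' v410l <- genotype_table_from_percent(
#'   rbind(kdr = c(90, 10, 0), recovered = c(8, 80, 12), dead = c(0, 36, 64)),
#'   n_per_phenotype = c(50, 50, 50), locus = "V410L")
#' allele_freq_from_genotypes(v410l)
#' @export
genotype_table_from_percent <- function(percent, n_per_phenotype,
                                        locus = NULL) {
  percent <- as.matrix(percent)
  stopifnot(length(n_per_phenotype) == nrow(percent))
  if (any(abs(rowSums(percent) - 100) > 1e-6))
    stop("each percentage row must sum to 100")
  counts <- round(percent / 100 * n_per_phenotype)
  bad <- abs(rowSums(counts) - n_per_phenotype) > 0
  if (any(bad))
    stop("rounded counts do not recover sample size for row(s): ",
         paste(rownames(percent)[bad], collapse = ", "))
  if (is.null(colnames(counts))) colnames(counts) <- c("RR", "RS", "SS")
  genotype_table(counts, locus = locus)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("Genotype table%s (%d phenotypes x %d genotypes)\n",
              if (is.null(x$locus)) "" else paste0(" at ", x$locus),
              nrow(x$counts), ncol(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Phenotype x genotype chi-square test of independence
#'
#' Plain Pearson chi-square on the contingency table, df =
#' (rows - 1)(columns - 1). Rows or columns with a zero marginal total are
#' dropped with a warning and the degrees of freedom adjusted.
#'
#' @param table a [genotype_table()] or plain count matrix.
#' @return list with `chi2`, `df`, `p`, `expected`, `observed`.
#' @export
genotype_chi2 <- function(table) {
  tab <- if (inherits(table, "genotype_table")) table$counts else as.matrix(table)
  pearson_chi2(tab, warn_dropped = TRUE)[c("chi2", "df", "p",
                                           "expected", "observed")]
}

#' Pearson residuals of a phenotype x genotype table
#'
#' Per-cell `(observed - expected) / sqrt(expected)` under independence.
#' A positive residual marks a positive phenotype-genotype association;
#' the squared residuals sum to the table's chi-square exactly.
#'
#' @param table a [genotype_table()] or plain count matrix.
#' @return numeric matrix of residuals (cells with expected count zero are
#'   `NaN` and flagged with a warning).
#' @export
pearson_residuals <- function(table) {
  tab <- if (inherits(table, "genotype_table")) table$counts else as.matrix(table)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected == 0)) warning("cells with expected count 0 are undefined")
  (tab - expected) / sqrt(expected)
}

#' Resistance-allele frequency from genotype counts
#'
#' For each phenotype row, `q = (2 n_RR + n_het) / (2 N)` where `N` is the
#' row total: the frequency of the resistance allele among the genotyped
#' chromosomes.
#'
#' @param table a [genotype_table()], or a numeric vector of one row's
#'   counts in (RR, RS, SS) order.
#' @return named numeric vector of allele frequencies (a single value for a
#'   vector input).
#' @examples
#' allele_freq_from_genotypes(c(45, 5, 0)) # 0.95
#' @export
allele_freq_from_genotypes <- function(table) {
  if (inherits(table, "genotype_table")) {
    tab <- table$counts
  } else if (is.matrix(table)) {
    tab <- table
  } else {
    tab <- matrix(table, nrow = 1)
  }
  tot <- rowSums(tab)
  if (any(tot == 0)) stop("row total must be positive")
  q <- (2 * tab[, 1] + tab[, 2]) / (2 * tot)
  if (nrow(tab) == 1L && is.null(rownames(tab))) unname(q) else q
}
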