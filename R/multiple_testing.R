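#' Benjamini-Hochberg selection on one chromosome's p-values
#'
#' Standard step-up rule at level `alpha`: sort the m p-values ascending,
#' find the largest i with `p(i) <= i * alpha / m`, and declare every site
#' with `p <= p(i)` significant (ties at the cutoff are all significant).
#' The LOD cutoff is `-log10` of the largest significant p-value and is
#' reported only when there is at least one discovery.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param alpha false-discovery-rate level (default 0.01).
#' @return list with `m`, `n_significant`, `cutoff_p`, `cutoff_lod` (both
#'   `NA` with zero discoveries) and the logical `significant` vector in
#'   input order.
#' @examples
#' bh_select(c(0.0001, 0.02, 0.03, 0.5), alpha = 0.05) # 3 discoveries
#' @export
bh_select <- function(p, alpha = 0.01) {
  if (length(p) == 0L)
    return(list(m = 0L, n_significant = 0L, cutoff_p = NA_real_,
                cutoff_lod = NA_real_, significant = logical()))
  stopifnot(all(p > 0 & p <= 1))
  sig <- stats::p.adjust(p, method = "BH") <= alpha
  cutoff_p <- if (any(sig)) max(p[sig]) else NA_real_
  list(m = length(p),
       n_significant = sum(sig),
       cutoff_p = cutoff_p,
       cutoff_lod = if (is.na(cutoff_p)) NA_real_ else -log10(cutoff_p),
       significant = sig)
}

#' Per-chromosome Benjamini-Hochberg significance calling
#'
#' Applies [bh_select()] to each chromosome's p-values independently (the
#' pipeline's multiple-testing convention) and flags significant records.
#'
#' @param records SNP records from [run_comparison()] (need `chrom` and
#'   `p` columns).
#' @param alpha FDR level (default 0.01).
#' @return the records with a `significant` logical column added;
#'   attribute `bh` holds the per-chromosome summary data.frame (`chrom`,
#'   `m`, `n_significant`, `cutoff_p`, `cutoff_lod`).
#' @export
bh_by_chromosome <- function(records, alpha = 0.01) {
  records$significant <- logical(nrow(records))
  chroms <- unique(records$chrom)
  summ <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    idx <- which(records$chrom == chroms[i])
    res <- bh_select(records$p[idx], alpha)
    records$significant[idx] <- res$significant
    summ[[i]] <- data.frame(chrom = chroms[i], m = res$m,
                            n_significant = res$n_significant,
                            cutoff_p = res$cutoff_p,
                            cutoff_lod = res$cutoff_lod)
  }
  attr(records, "bh") <- if (length(summ)) do.call(rbind, summ) else
    data.frame(chrom = character(), m = integer(), n_significant = integer(),
               cutoff_p = numeric(), cutoff_lod = numeric())
  attr(records, "alpha") <- alpha
  records
}
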