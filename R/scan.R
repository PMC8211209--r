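#' Full pool-seq association scan for one phenotype pair
#'
#' One-call orchestrator: site filtering, polymorphic-site detection,
#' replicate screening, per-site heterogeneity chi-square and LOD,
#' per-chromosome Benjamini-Hochberg significance calling, effect
#' annotation of the significant SNPs against gene models, resistance
#' categorization, and selection-direction calls.
#'
#' @param counts a [pool_counts()] with the comparison's libraries.
#' @param comparison character vector of two phenotype labels.
#' @param models optional [gene_models()] with sequences (or a
#'   `sim_genome`); when absent, annotation is skipped.
#' @param cfg a [filter_config()] (depth/quality/replicate/alpha settings).
#' @param category_map optional gene-category map (see
#'   [read_category_map()]).
#' @param resistant which phenotype plays the resistant role for selection
#'   calls (default the first of `comparison`).
#' @return object of class `pool_scan`: list with `records` (annotated SNP
#'   records incl. `significant`), `bh` (per-chromosome summary),
#'   `selection` (direction/frequency-bin calls for significant SNPs),
#'   `comparison`, `resistant`, `cfg`, `stage_counts`.
#' @export
pool_scan <- function(counts, comparison, models = NULL,
                      cfg = filter_config(), category_map = NULL,
                      resistant = comparison[1]) {
  stopifnot(resistant %in% comparison)
  rec <- run_comparison(counts, cfg, comparison)
  rec <- bh_by_chromosome(rec, alpha = cfg$alpha)
  if (!is.null(models))
    rec <- annotate_snps(rec, models, category_map, only_significant = TRUE)
  sel <- NULL
  sig <- which(rec$significant)
  if (length(sig)) {
    fr <- if (resistant == comparison[1]) rec$alt_freq_a[sig]
          else rec$alt_freq_b[sig]
    fc <- if (resistant == comparison[1]) rec$alt_freq_b[sig]
          else rec$alt_freq_a[sig]
    sel <- cbind(rec[sig, c("chrom", "pos", "ref", "alt", "lod")],
                 classify_selection(fr, fc))
    if (!is.null(rec$gene_id)) sel$gene_id <- rec$gene_id[sig]
    rownames(sel) <- NULL
  }
  structure(list(records = rec, bh = attr(rec, "bh"), selection = sel,
                 comparison = comparison, resistant = resistant, cfg = cfg,
                 stage_counts = attr(rec, "stage_counts")),
            class = "pool_scan")
}

#' @export
print.pool_scan <- function(x, ...) {
  s <- x$stage_counts
  cat(sprintf("Pool-seq scan: %s vs %s\n", x$comparison[1], x$comparison[2]))
  cat(sprintf("  sites passing depth/quality filters: %d\n", s["common"]))
  cat(sprintf("  polymorphic: %d; replicate-consistent: %d; tested: %d\n",
              s["polymorphic"], s["replicate_pass"], s["tested"]))
  cat(sprintf("  significant (BH per chromosome, alpha = %g): %d\n",
              x$cfg$alpha, sum(x$records$significant)))
  if (nrow(x$bh)) {
    cat("  per-chromosome LOD cutoffs:\n")
    for (i in seq_len(nrow(x$bh)))
      cat(sprintf("    %s: m = %d, discoveries = %d, LOD cutoff = %s\n",
                  x$bh$chrom[i], x$bh$m[i], x$bh$n_significant[i],
                  ifelse(is.na(x$bh$cutoff_lod[i]), "-",
                         sprintf("%.2f", x$bh$cutoff_lod[i]))))
  }
  invisible(x)
}

#' @export
summary.pool_scan <- function(object, ...) {
  rec <- object$records
  sig <- rec[rec$significant, , drop = FALSE]
  out <- list(
    comparison = object$comparison,
    stage_counts = object$stage_counts,
    bh = object$bh,
    n_significant = nrow(sig),
    lod_range = if (nrow(sig)) range(sig$lod) else c(NA, NA),
    lod_mean = if (nrow(sig)) mean(sig$lod) else NA,
    lod_q95 = if (nrow(sig)) unname(quantile(sig$lod, 0.95)) else NA,
    feature_classes = if (!is.null(sig$feature_class) && nrow(sig))
      feature_class_counts(sig) else NULL,
    selection = if (!is.null(object$selection))
      table(object$selection$direction, object$selection$frequency_bin)
    else NULL
  )
  class(out) <- "summary.pool_scan"
  out
}

#' @export
print.summary.pool_scan <- function(x, ...) {
  cat(sprintf("Scan %s vs %s: %d significant SNPs\n",
              x$comparison[1], x$comparison[2], x$n_significant))
  if (x$n_significant) {
    cat(sprintf("  LOD range %.2f-%.2f, mean %.2f, 95th quantile %.2f\n",
                x$lod_range[1], x$lod_range[2], x$lod_mean, x$lod_q95))
  }
  print(x$bh)
  if (!is.null(x$feature_classes)) {
    cat("\nPrimary feature classes of significant SNPs:\n")
    print(x$feature_classes$primary)
  }
  if (!is.null(x$selection)) {
    cat("\nSelection direction x frequency bin:\n")
    print(x$selection)
  }
  invisible(x)
}

#' Manhattan-style LOD plot of a scan
#'
#' LOD against genomic position, one panel track per chromosome laid
#' end-to-end, with the per-chromosome Benjamini-Hochberg LOD cutoff drawn
#' as a dashed line and significant SNPs highlighted.
#'
#' @param x a `pool_scan`.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.pool_scan <- function(x, ...) {
  rec <- x$records
  if (nrow(rec) == 0L) {
    plot.new(); return(invisible(x))
  }
  chroms <- unique(rec$chrom)
  offset <- setNames(numeric(length(chroms)), chroms)
  run <- 0
  for (ch in chroms) {
    offset[ch] <- run
    run <- run + max(rec$pos[rec$chrom == ch]) * 1.05
  }
  gx <- rec$pos + offset[rec$chrom]
  col <- ifelse(rec$significant, "firebrick",
                c("grey40", "grey65")[(match(rec$chrom, chroms) %% 2) + 1])
  plot(gx, rec$lod, pch = 20, cex = 0.5, col = col,
       xlab = "genomic position", ylab = "LOD", xaxt = "n",
       main = sprintf("%s vs %s", x$comparison[1], x$comparison[2]), ...)
  axis(1, at = offset + tapply(rec$pos, rec$chrom, max)[chroms] / 2,
       labels = chroms)
  for (i in seq_len(nrow(x$bh)))
    if (!is.na(x$bh$cutoff_lod[i])) {
      ch <- x$bh$chrom[i]
      xs <- range(gx[rec$chrom == ch])
      graphics::segments(xs[1], x$bh$cutoff_lod[i], xs[2],
                         x$bh$cutoff_lod[i], lty = 2)
    }
  invisible(x)
}
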