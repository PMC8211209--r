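#' Draw per-site true allele frequencies for a synthetic genome
#'
#' Picks `n_sites` distinct positions across the genome, assigns each a
#' reference base (read from the emitted sequence), a single alternate
#' base, and a true alternate-allele frequency per phenotype. Null sites
#' share one frequency across phenotypes (drawn uniformly on
#' [0.05, 0.95]); planted sites take the phenotype-specific frequencies in
#' `config$effect_sizes`. A `repeat_fraction` of sites is flagged
#' repetitive and later emitted with coverage above 1000.
#'
#' @param genome a `sim_genome` from [generate_genome()].
#' @param config the same [sim_config()].
#' @return a `sim_truth` data.frame: `chrom`, `pos`, `ref`, `alt`,
#'   `planted`, `repeat_flag`, plus one `freq_<phenotype>` column per
#'   phenotype.
#' @export
sim_truth <- function(genome, config) {
  validate_sim_config(config)
  with_seed(stage_seed(config$seed, 2L), {
    chroms <- names(genome$seq)
    lens <- Biostrings::width(genome$seq)
    n <- config$n_sites
    ch_idx <- sample(seq_along(chroms), n, replace = TRUE,
                     prob = lens / sum(lens))
    pos <- integer(n)
    for (i in seq_along(chroms)) {
      sel <- ch_idx == i
      if (any(sel))
        pos[sel] <- sample(seq_len(lens[i]), sum(sel), replace = FALSE)
    }
    ord <- order(ch_idx, pos)
    ch_idx <- ch_idx[ord]; pos <- pos[ord]
    ref <- character(n)
    for (i in seq_along(chroms)) {
      sel <- ch_idx == i
      if (any(sel)) {
        s <- as.character(genome$seq[[i]])
        ref[sel] <- substring(s, pos[sel], pos[sel])
      }
    }
    # alternate: one of the three other bases, uniformly
    shift <- sample(1:3, n, replace = TRUE)
    alt <- BASES[((match(ref, BASES) - 1L + shift) %% 4L) + 1L]

    planted <- rep(FALSE, n)
    if (config$n_planted_sites > 0)
      planted[sample(n, config$n_planted_sites)] <- TRUE
    rep_flag <- rep(FALSE, n)
    n_rep <- round(config$repeat_fraction * n)
    if (n_rep > 0) rep_flag[sample(which(!planted), n_rep)] <- TRUE

    freq <- matrix(NA_real_, n, length(config$phenotypes),
                   dimnames = list(NULL, config$phenotypes))
    null_f <- runif(n, 0.05, 0.95)
    for (ph in config$phenotypes) freq[, ph] <- null_f
    if (any(planted)) {
      eff <- effect_matrix(config)
      eff <- eff[, config$phenotypes, drop = FALSE]
      idx <- which(planted)
      for (j in seq_along(idx))
        freq[idx[j], colnames(eff)] <-
          eff[((j - 1L) %% nrow(eff)) + 1L, ]
    }
    out <- data.frame(chrom = chroms[ch_idx], pos = pos, ref = ref, alt = alt,
                      planted = planted, repeat_flag = rep_flag,
                      stringsAsFactors = FALSE, row.names = NULL)
    for (ph in config$phenotypes) out[[paste0("freq_", ph)]] <- freq[, ph]
    class(out) <- c("sim_truth", "data.frame")
    out
  })
}

#' Generate pooled read counts from a truth table
#'
#' Two-stage sampling per library and site. Stage 1 (pool): draw the number
#' of alternate allele copies among the `2 * pool_size` chromosomes of the
#' library's pool from a binomial at the phenotype's true frequency; the
#' realized pool frequency is that count over `2 * pool_size` (each
#' individual contributes equal DNA). Stage 2 (reads): draw the site's
#' depth from a negative binomial around `mean_depth` (repeat-flagged sites
#' instead draw depth uniformly on 1001-3000), then draw alternate reads
#' binomially at the realized pool frequency. Miscalls are applied at
#' `error_rate`, each targeting a uniformly random other base, and a mean
#' Phred base quality is attached per site and library. With
#' `pool_size = Inf` the pool stage is skipped and reads are drawn at the
#' true frequency (the heterogeneity test's own null; used for
#' calibration).
#'
#' @param truth a `sim_truth` table (its phenotype columns must match
#'   `config$phenotypes`).
#' @param config the [sim_config()].
#' @return a [pool_counts()] object with one library per phenotype and
#'   replicate, named `<phenotype><replicate>` (e.g. `kdr1`).
#' @export
generate_pool_counts <- function(truth, config) {
  validate_sim_config(config)
  need <- paste0("freq_", config$phenotypes)
  if (!all(need %in% names(truth)))
    stop("truth lacks frequency column(s) for phenotype(s): ",
         paste(config$phenotypes[!(need %in% names(truth))], collapse = ", "))
  with_seed(stage_seed(config$seed, 3L), {
    n <- nrow(truth)
    libs <- expand.grid(replicate = seq_len(config$n_replicates),
                        phenotype = config$phenotypes,
                        stringsAsFactors = FALSE)[, 2:1]
    libs$library_id <- paste0(libs$phenotype, libs$replicate)
    n_lib <- nrow(libs)
    counts <- array(0, dim = c(n, 6L, n_lib),
                    dimnames = list(NULL, SYNC_COLS, libs$library_id))
    qual <- matrix(NA_real_, n, n_lib)
    ref_i <- match(truth$ref, BASES)
    alt_i <- match(truth$alt, BASES)
    for (l in seq_len(n_lib)) {
      q <- truth[[paste0("freq_", libs$phenotype[l])]]
      depth <- rnbinom(n, size = config$depth_dispersion,
                       mu = config$mean_depth)
      depth <- pmax(depth, 2L)
      if (any(truth$repeat_flag))
        depth[truth$repeat_flag] <-
          sample(1001:3000, sum(truth$repeat_flag), replace = TRUE)
      if (is.finite(config$pool_size)) {
        copies <- rbinom(n, 2L * config$pool_size, q)
        f <- copies / (2L * config$pool_size)
      } else {
        f <- q
      }
      alt_reads <- rbinom(n, depth, f)
      ref_reads <- depth - alt_reads
      # miscalls: each true read flips to a uniformly random other base
      mat <- matrix(0, n, 4L, dimnames = list(NULL, BASES))
      for (src in list(list(idx = ref_i, reads = ref_reads),
                       list(idx = alt_i, reads = alt_reads))) {
        err <- rbinom(n, src$reads, config$error_rate)
        keep <- src$reads - err
        mat[cbind(seq_len(n), src$idx)] <-
          mat[cbind(seq_len(n), src$idx)] + keep
        has <- which(err > 0)
        for (i in has) {
          targets <- setdiff(1:4, src$idx[i])
          split <- rmultinom(1, err[i], rep(1 / 3, 3))[, 1]
          mat[i, targets] <- mat[i, targets] + split
        }
      }
      counts[, BASES, l] <- mat
      qual[, l] <- rnorm(n, config$base_quality_mean,
                         config$base_quality_sd / sqrt(pmax(depth, 1)))
    }
    pool_counts(libraries = libs[, c("library_id", "phenotype", "replicate")],
                sites = data.frame(chrom = truth$chrom, pos = truth$pos,
                                   ref = truth$ref, stringsAsFactors = FALSE),
                counts = counts, qual = qual)
  })
}

#' Generate an individual-genotype count table
#'
#' Builds a phenotype x genotype table (resistant homozygote,
#' heterozygote, wild-type homozygote) either by Hardy-Weinberg sampling at
#' each phenotype's allele frequency or from explicit genotype proportions.
#'
#' @param q_per_phenotype named numeric vector of resistance-allele
#'   frequencies, one per phenotype (Hardy-Weinberg mode), or a 3-column
#'   matrix of explicit genotype proportions with phenotypes as rows.
#' @param n_per_phenotype named integer vector of individuals genotyped per
#'   phenotype.
#' @param mode `"hardy_weinberg"` (default) or `"explicit_proportions"`.
#' @param seed integer seed.
#' @return a [genotype_table()].
#' @export
generate_genotype_table <- function(q_per_phenotype, n_per_phenotype,
                                    mode = c("hardy_weinberg",
                                             "explicit_proportions"),
                                    seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(n_per_phenotype > 0))
  with_seed(stage_seed(seed, 4L), {
    if (mode == "hardy_weinberg") {
      q <- q_per_phenotype
      stopifnot(all(q >= 0 & q <= 1))
      phen <- if (is.null(names(q))) paste0("phen", seq_along(q)) else names(q)
      tab <- t(vapply(seq_along(q), function(i) {
        copies <- rbinom(n_per_phenotype[i], 2L, q[i])
        c(sum(copies == 2L), sum(copies == 1L), sum(copies == 0L))
      }, integer(3)))
    } else {
      pr <- as.matrix(q_per_phenotype)
      if (ncol(pr) != 3L) stop("explicit proportions need 3 genotype columns")
      if (any(abs(rowSums(pr) - 1) > 1e-9))
        stop("explicit genotype proportions must sum to 1 per phenotype")
      phen <- if (is.null(rownames(pr))) paste0("phen", seq_len(nrow(pr)))
              else rownames(pr)
      tab <- round(pr * n_per_phenotype)
      if (any(abs(rowSums(tab) - n_per_phenotype) > 0))
        stop("rounded genotype counts do not sum to the per-phenotype totals")
    }
    dimnames(tab) <- list(phen, c("RR", "RS", "SS"))
    genotype_table(tab)
  })
}
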