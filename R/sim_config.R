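#' Configuration for the synthetic pooled-sequencing generator
#'
#' Bundles every parameter of the simulated study design. Defaults mirror
#' the pooled exome design the pipeline was built for: three phenotype
#' groups (knockdown-resistant `kdr`, `recovered`, `dead`), two biological
#' replicate pools per phenotype, 25 diploid individuals per pool, and
#' overdispersed sequencing depth around 240 reads (the middle of the
#' 196-288x range such libraries achieve). Planted sites default to the
#' frequency pattern observed at a strong target-site resistance locus
#' (high in kdr, intermediate in recovered, low in dead).
#'
#' @param n_chromosomes number of chromosomes (default 3).
#' @param chrom_length length of each chromosome in bases (default 100000).
#' @param n_genes protein-coding genes per genome (default 24).
#' @param n_ncrna non-coding RNA genes per genome (default 3).
#' @param pool_size diploid individuals per library pool (default 25). Use
#'   `Inf` to skip the pool-sampling stage so reads are drawn directly at
#'   the phenotype's true frequency (the heterogeneity test's own null;
#'   used for calibration studies).
#' @param n_replicates biological replicate pools per phenotype (default 2).
#' @param phenotypes phenotype labels (default kdr, recovered, dead).
#' @param mean_depth mean per-library read depth (default 240).
#' @param depth_dispersion negative-binomial size parameter for depth
#'   overdispersion (default 8; smaller = heavier tail).
#' @param error_rate per-base miscall probability (default 0.002).
#' @param base_quality_mean,base_quality_sd per-base Phred quality score
#'   distribution parameters (default 36 +/- 3).
#' @param n_sites total polymorphic sites of interest to emit (default 2000).
#' @param n_planted_sites sites given phenotype-dependent frequencies
#'   (default 20).
#' @param effect_sizes named numeric vector (or matrix with one row per
#'   planted site) of true alternate-allele frequencies per phenotype at
#'   planted sites. Default c(kdr = 0.9, recovered = 0.5, dead = 0.1).
#' @param repeat_fraction fraction of sites flagged as repetitive DNA,
#'   emitted with coverage > 1000 (default 0.02).
#' @param seed master integer seed; all stages derive their own streams
#'   from it deterministically.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chromosomes = 3,
                       chrom_length = 100000,
                       n_genes = 24,
                       n_ncrna = 3,
                       pool_size = 25,
                       n_replicates = 2,
                       phenotypes = c("kdr", "recovered", "dead"),
                       mean_depth = 240,
                       depth_dispersion = 8,
                       error_rate = 0.002,
                       base_quality_mean = 36,
                       base_quality_sd = 3,
                       n_sites = 2000,
                       n_planted_sites = 20,
                       effect_sizes = c(kdr = 0.9, recovered = 0.5, dead = 0.1),
                       repeat_fraction = 0.02,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes),
    n_ncrna = as.integer(n_ncrna),
    pool_size = pool_size,
    n_replicates = as.integer(n_replicates),
    phenotypes = as.character(phenotypes),
    mean_depth = mean_depth,
    depth_dispersion = depth_dispersion,
    error_rate = error_rate,
    base_quality_mean = base_quality_mean,
    base_quality_sd = base_quality_sd,
    n_sites = as.integer(n_sites),
    n_planted_sites = as.integer(n_planted_sites),
    effect_sizes = effect_sizes,
    repeat_fraction = repeat_fraction,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_chromosomes >= 1, cfg$chrom_length >= 1000,
    cfg$n_genes >= 0, cfg$n_ncrna >= 0,
    cfg$pool_size > 0, cfg$n_replicates >= 1,
    length(cfg$phenotypes) >= 2, !anyDuplicated(cfg$phenotypes),
    cfg$mean_depth > 0, cfg$depth_dispersion > 0,
    cfg$error_rate >= 0, cfg$error_rate < 1,
    cfg$base_quality_mean > 0, cfg$base_quality_sd >= 0,
    cfg$n_sites >= 0, cfg$n_planted_sites >= 0,
    cfg$n_planted_sites <= cfg$n_sites,
    cfg$repeat_fraction >= 0, cfg$repeat_fraction < 1
  )
  eff <- effect_matrix(cfg)
  if (cfg$n_planted_sites > 0 && !all(cfg$phenotypes %in% colnames(eff)))
    stop("effect_sizes must name a frequency for every phenotype")
  if (any(eff < 0 | eff > 1)) stop("effect frequencies must lie in [0, 1]")
  invisible(cfg)
}

# Effect sizes as an n_planted x n_phenotypes matrix (recycled if a vector).
effect_matrix <- function(cfg) {
  e <- cfg$effect_sizes
  if (is.matrix(e)) {
    m <- e
  } else {
    m <- matrix(e, nrow = max(cfg$n_planted_sites, 1L), ncol = length(e),
                byrow = TRUE, dimnames = list(NULL, names(e)))
  }
  m
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic pool-seq design\n")
  cat(sprintf("  genome: %d chromosome(s) x %d bp, %d coding + %d ncRNA genes\n",
              x$n_chromosomes, x$chrom_length, x$n_genes, x$n_ncrna))
  cat(sprintf("  pools: %s individuals x %d replicate(s) x {%s}\n",
              format(x$pool_size), x$n_replicates,
              paste(x$phenotypes, collapse = ", ")))
  cat(sprintf("  depth ~ NB(mu = %g, size = %g), error rate %g, Q ~ N(%g, %g)\n",
              x$mean_depth, x$depth_dispersion, x$error_rate,
              x$base_quality_mean, x$base_quality_sd))
  cat(sprintf("  sites: %d (%d planted, repeat fraction %g), seed %d\n",
              x$n_sites, x$n_planted_sites, x$repeat_fraction, x$seed))
  invisible(x)
}
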