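test_that("alternate-allele frequency is the principal non-reference fraction", {
  expect_equal(alt_allele_frequency(c(A = 50, C = 50), "A"), 0.5)
  expect_equal(alt_allele_frequency(c(A = 100, C = 0), "A"), 0)
  expect_equal(alt_allele_frequency(c(A = 30, C = 70), "A"), 0.7)
  # principal = highest-count alternate when several segregate
  expect_equal(alt_allele_frequency(c(A = 50, C = 10, G = 40), "A"), 0.4)
  expect_error(alt_allele_frequency(c(A = 0, C = 0), "A"), "zero depth")
})

test_that("heterogeneity chi-square matches hand-computed tables", {
  id <- heterogeneity_chi2(c(A = 60, C = 40), c(A = 30, C = 20))
  expect_equal(id$chi2, 0)
  expect_equal(id$p, 1)
  # (90,10) vs (50,50): expected 70/30 per row -> chi2 = 800/70 + 800/30
  h <- heterogeneity_chi2(c(A = 90, C = 10), c(A = 50, C = 50))
  expect_equal(h$chi2, 800 / 70 + 800 / 30, tolerance = 1e-9)
  expect_equal(h$chi2, 38.095, tolerance = 1e-3)
  expect_equal(h$df, 1)
  # independent tail evaluation for the LOD
  expect_equal(-h$log10_p, -log10(pchisq(h$chi2, 1, lower.tail = FALSE)),
               tolerance = 1e-9)
  expect_equal(-h$log10_p, 9.18, tolerance = 0.01)
  # three alleles present -> df = 2 (alleles - 1)
  h3 <- heterogeneity_chi2(c(A = 60, C = 30, G = 10), c(A = 40, C = 30, G = 30))
  expect_equal(h3$df, 2)
  # absent-everywhere alleles are dropped before testing
  h2 <- heterogeneity_chi2(c(A = 60, C = 30, G = 0, T = 0),
                           c(A = 40, C = 30, G = 0, T = 0))
  expect_equal(h2$df, 1)
})

test_that("expected heterozygosity follows 1 - sum(p^2)", {
  expect_equal(expected_heterozygosity(c(0.5, 0.5)), 0.5)
  expect_equal(expected_heterozygosity(1.0), 0)
  expect_equal(expected_heterozygosity(c(0.93, 0.07)), 0.1302,
               tolerance = 1e-9)
  # bounded by 1 - 1/k and maximized at equal frequencies
  set.seed(5)
  for (k in 2:4) {
    p <- runif(k); p <- p / sum(p)
    h <- expected_heterozygosity(p)
    expect_lte(h, 1 - 1 / k + 1e-12)
    expect_lte(h, expected_heterozygosity(rep(1 / k, k)) + 1e-12)
  }
})

test_that("run_comparison produces uniform p-values on a null genome", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 60000, n_genes = 0,
                    n_ncrna = 0, n_sites = 1500, n_planted_sites = 0,
                    error_rate = 0, repeat_fraction = 0, pool_size = Inf,
                    phenotypes = c("kdr", "dead"), seed = 29)
  g <- generate_genome(cfg)
  pc <- generate_pool_counts(sim_truth(g, cfg), cfg)
  rec <- run_comparison(pc, filter_config(), c("kdr", "dead"))
  expect_gt(nrow(rec), 1000)
  # QQ agreement with uniform order statistics over the bulk of the
  # distribution (chi-square discreteness perturbs the extreme tail)
  p_sorted <- sort(rec$p)
  m <- length(p_sorted)
  expected_q <- (seq_len(m) - 0.5) / m
  bulk <- p_sorted > 0.01 & p_sorted < 0.99
  expect_lt(max(abs(p_sorted - expected_q)[bulk]), 0.05)
  expect_equal(rec$lod, -log10(rec$p), tolerance = 1e-9)
})

test_that("a strongly planted site ranks at the top of its chromosome", {
  hits <- 0
  for (s in 1:5) {
    cfg <- sim_config(n_chromosomes = 1, chrom_length = 30000, n_genes = 0,
                      n_ncrna = 0, n_sites = 300, n_planted_sites = 1,
                      effect_sizes = c(kdr = 0.9, recovered = 0.5, dead = 0.1),
                      error_rate = 0, repeat_fraction = 0, pool_size = Inf,
                      seed = 100 + s)
    g <- generate_genome(cfg)
    tr <- sim_truth(g, cfg)
    pc <- generate_pool_counts(tr, cfg)
    rec <- run_comparison(pc, filter_config(), c("kdr", "dead"))
    planted_pos <- tr$pos[tr$planted]
    rank_of <- rank(-rec$lod)[rec$pos == planted_pos]
    if (length(rank_of) == 1 && rank_of <= 3) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("empty input gives empty output with the stage trail intact", {
  sites <- data.frame(chrom = character(), pos = integer(), ref = character())
  cl <- lapply(1:4, function(i)
    matrix(numeric(), 0, 4, dimnames = list(NULL, c("A", "C", "G", "T"))))
  x <- make_counts(sites, cl, std_libs())
  rec <- suppressMessages(run_comparison(x, filter_config(), c("kdr", "dead")))
  expect_equal(nrow(rec), 0)
  expect_equal(unname(attr(rec, "stage_counts")["common"]), 0)
})

test_that("power rises with effect size and depth", {
  det_rate <- function(delta, depth, seed) {
    cfg <- sim_config(n_chromosomes = 1, chrom_length = 30000, n_genes = 0,
                      n_ncrna = 0, n_sites = 200, n_planted_sites = 30,
                      effect_sizes = c(kdr = 0.5 + delta / 2,
                                       recovered = 0.5,
                                       dead = 0.5 - delta / 2),
                      mean_depth = depth, error_rate = 0,
                      repeat_fraction = 0, pool_size = Inf, seed = seed)
    g <- generate_genome(cfg)
    tr <- sim_truth(g, cfg)
    pc <- generate_pool_counts(tr, cfg)
    rec <- bh_by_chromosome(run_comparison(pc, filter_config(), c("kdr", "dead")),
                            alpha = 0.01)
    key <- paste(tr$chrom, tr$pos)[tr$planted]
    mean(rec$significant[paste(rec$chrom, rec$pos) %in% key])
  }
  weak <- det_rate(0.15, 60, 51)
  strong <- det_rate(0.5, 60, 51)
  deep <- det_rate(0.15, 600, 51)
  expect_gte(strong, weak)
  expect_gte(deep, weak)
  expect_gt(strong, 0.8)
})
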