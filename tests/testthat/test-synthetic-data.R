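test_that("generators are byte-identical under the same seed", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 15000, n_genes = 4,
                    n_sites = 50, n_planted_sites = 2, seed = 7)
  g1 <- generate_genome(cfg); g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$seq), as.character(g2$seq))
  expect_identical(g1$models$features, g2$models$features)
  t1 <- sim_truth(g1, cfg); t2 <- sim_truth(g2, cfg)
  expect_identical(t1, t2)
  c1 <- generate_pool_counts(t1, cfg); c2 <- generate_pool_counts(t2, cfg)
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$qual, c2$qual)
  # serialized forms too
  f1 <- tempfile(); f2 <- tempfile()
  write_genome_fasta(g1, f1); write_genome_fasta(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
  write_gff3(g1, f1); write_gff3(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
  g3 <- generate_genome(sim_config(n_chromosomes = 1, chrom_length = 15000,
                                   n_genes = 4, n_sites = 50,
                                   n_planted_sites = 2, seed = 8))
  expect_false(identical(as.character(g1$seq), as.character(g3$seq)))
})

test_that("a gene-free genome is all intergenic and annotates as such", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 5000, n_genes = 0,
                    n_ncrna = 0, n_sites = 10, n_planted_sites = 0, seed = 3)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$models$transcripts), 0)
  cl <- classify_site("chr1", 2500, g$models)
  expect_equal(cl$primary$class, "intergenic")
})

test_that("every emitted CDS length is divisible by 3 under independent GFF3 re-parse", {
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_genome_fasta(fix_genome, fa)
  write_gff3(fix_genome, gff)
  # independent re-parse: raw read of the GFF3 text, no package parser
  raw <- read.table(gff, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  cds <- raw[raw$V3 == "CDS", ]
  parent <- sub("^Parent=", "", cds$V9)
  lens <- tapply(cds$V5 - cds$V4 + 1, parent, sum)
  expect_true(all(lens %% 3 == 0))
  expect_gt(length(lens), 0)
  # plus- and minus-strand genes, UTRs, >= 2 CDS exons, ncRNA all present
  expect_setequal(unique(raw$V7[raw$V3 == "gene"]), c("+", "-"))
  expect_true(all(table(parent) >= 2))
  expect_true(all(c("five_prime_UTR", "three_prime_UTR", "ncRNA") %in% raw$V3))
  # intergenic space >= 20% of the genome
  spans <- raw[raw$V3 == "gene", ]
  genic <- sum(spans$V5 - spans$V4 + 1)
  expect_lt(genic / sum(fix_cfg$chrom_length * fix_cfg$n_chromosomes), 0.8)
})

test_that("pool counts hit the boundary cases and conserve depth", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 5000, n_genes = 0,
                    n_ncrna = 0, n_sites = 40, n_planted_sites = 0,
                    error_rate = 0, repeat_fraction = 0.25, seed = 5)
  g <- generate_genome(cfg)
  tr <- sim_truth(g, cfg)
  tr$freq_kdr <- 1; tr$freq_recovered <- 1; tr$freq_dead <- 1
  pc <- generate_pool_counts(tr, cfg)
  for (l in seq_len(nrow(pc$libraries))) {
    alt_n <- pc$counts[cbind(seq_len(40), match(tr$alt, colnames(pc$counts)), l)]
    ref_n <- pc$counts[cbind(seq_len(40), match(tr$ref, colnames(pc$counts)), l)]
    depth <- rowSums(pc$counts[, c("A", "C", "G", "T", "del"), l])
    expect_equal(alt_n, depth)   # true freq 1, no error: all reads alternate
    expect_true(all(ref_n == 0))
  }
  # repeat-flagged sites carry coverage > 1000
  d <- rowSums(pc$counts[, c("A", "C", "G", "T", "del"), 1])
  expect_true(all(d[tr$repeat_flag] > 1000))
  expect_true(all(d[!tr$repeat_flag] <= 1000))
})

test_that("unknown phenotype in truth is rejected", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 5000, n_genes = 0,
                    n_ncrna = 0, n_sites = 5, n_planted_sites = 0, seed = 5)
  g <- generate_genome(cfg)
  tr <- sim_truth(g, cfg)
  names(tr)[names(tr) == "freq_kdr"] <- "freq_mystery"
  expect_error(generate_pool_counts(tr, cfg), "kdr")
})

test_that("frequency-estimate spread matches the two-stage sampling model", {
  # 8000 null sites at true frequency 0.5; compare the spread of per-library
  # estimates with a direct Monte-Carlo of the pool-then-read model, and
  # check it exceeds the read-only binomial spread
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 50000, n_genes = 0,
                    n_ncrna = 0, n_sites = 8000, n_planted_sites = 0,
                    error_rate = 0, repeat_fraction = 0,
                    phenotypes = c("kdr", "dead"), seed = 21)
  g <- generate_genome(cfg)
  tr <- sim_truth(g, cfg)
  for (ph in cfg$phenotypes) tr[[paste0("freq_", ph)]] <- 0.5
  pc <- generate_pool_counts(tr, cfg)
  alt_i <- match(tr$alt, colnames(pc$counts))
  depth <- rowSums(pc$counts[, c("A", "C", "G", "T"), 1])
  f_hat <- pc$counts[cbind(seq_len(nrow(tr)), alt_i, 1)] / depth
  set.seed(404)
  f_mc <- brute_two_stage(8000, 0.5, 2 * cfg$pool_size,
                          round(cfg$mean_depth))
  expect_equal(mean(abs(f_hat - 0.5)), mean(abs(f_mc - 0.5)),
               tolerance = 0.05)
  var_read_only <- 0.25 * mean(1 / depth)
  expect_gt(var(f_hat), 1.5 * var_read_only)
  # closed form: var = pq/(2N) + E[pq/depth] adjusted for pool stage
  var_closed <- 0.25 / (2 * cfg$pool_size) + 0.25 * mean(1 / depth)
  expect_equal(var(f_hat), var_closed, tolerance = 0.1)
})

test_that("planted sites separate phenotypes more than null sites", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 30000, n_genes = 0,
                    n_ncrna = 0, n_sites = 400, n_planted_sites = 40,
                    error_rate = 0, repeat_fraction = 0, seed = 31)
  g <- generate_genome(cfg)
  tr <- sim_truth(g, cfg)
  pc <- generate_pool_counts(tr, cfg)
  alt_i <- match(tr$alt, colnames(pc$counts))
  f <- sapply(c("kdr", "dead"), function(ph) {
    idx <- which(pc$libraries$phenotype == ph)
    tot <- pc$counts[, c("A", "C", "G", "T"), idx[1]] +
      pc$counts[, c("A", "C", "G", "T"), idx[2]]
    tot[cbind(seq_len(nrow(tr)), alt_i)] / rowSums(tot)
  })
  gap <- abs(f[, 1] - f[, 2])
  expect_gt(mean(gap[tr$planted]), mean(gap[!tr$planted]))
})

test_that("genotype-table generator honors its modes and boundaries", {
  # explicit proportions reproduce printed percentage splits exactly
  gt <- generate_genotype_table(
    rbind(kdr = c(0.9, 0.1, 0.0)), n_per_phenotype = 50,
    mode = "explicit_proportions")
  expect_equal(unname(gt$counts["kdr", ]), c(45, 5, 0))
  expect_error(generate_genotype_table(rbind(c(0.9, 0.2, 0.0)), 50,
                                       mode = "explicit_proportions"),
               "sum to 1")
  # q = 0 gives only wild-type homozygotes
  gt0 <- generate_genotype_table(c(a = 0), n_per_phenotype = 30, seed = 2)
  expect_equal(unname(gt0$counts["a", ]), c(0, 0, 30))
  # Hardy-Weinberg at q = 0.5: heterozygote fraction within 4 SE of 0.5
  n <- 1e5
  gth <- generate_genotype_table(c(a = 0.5), n_per_phenotype = n, seed = 9)
  het <- gth$counts["a", "RS"] / n
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(het - 0.5), 4 * se)
  expect_equal(sum(gth$counts), n)
})
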