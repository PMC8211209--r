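toy <- make_toy()

test_that("sites are classified by feature with CDS-first precedence", {
  # no overlapping feature -> intergenic
  expect_equal(classify_site("chrT", 3500, toy)$primary$class, "intergenic")
  # 5'UTR and 3'UTR of the plus-strand gene
  expect_equal(classify_site("chrT", 80, toy)$primary$class, "five_prime_UTR")
  expect_equal(classify_site("chrT", 1450, toy)$primary$class, "three_prime_UTR")
  # minus-strand intron (between the gene's two exons), strand reported
  cl <- classify_site("chrT", 2150, toy)
  expect_equal(cl$primary$class, "intron")
  expect_equal(cl$primary$strand, "-")
  # CDS of txm, intron of the overlapping txo -> primary from CDS, both kept
  cl2 <- classify_site("chrT", 2090, toy)
  expect_equal(cl2$primary$class, "CDS")
  expect_equal(cl2$primary$transcript_id, "txm")
  expect_setequal(cl2$memberships$transcript_id, c("txm", "txo"))
  expect_setequal(cl2$memberships$class, c("CDS", "intron"))
  expect_error(classify_site("chrT", 99999, toy), "off the end")
})

test_that("ncRNA exons classify as ncRNA below intron precedence", {
  cfg0 <- sim_config(n_chromosomes = 1, chrom_length = 8000, n_genes = 0,
                     n_ncrna = 2, n_sites = 5, n_planted_sites = 0, seed = 19)
  g <- generate_genome(cfg0)
  nc <- g$models$features[g$models$features$type == "exon", ][1, ]
  cl <- classify_site("chr1", nc$start, g$models)
  expect_equal(cl$primary$class, "ncRNA")
})

test_that("position in gene counts from the transcription start", {
  # plus-strand gene starts at 61
  expect_equal(classify_site("chrT", 101, toy)$primary$position_in_gene, 41L)
  # minus-strand gene span 2000..2300; transcription starts at 2300
  expect_equal(classify_site("chrT", 2300, toy)$primary$position_in_gene, 1L)
  expect_equal(classify_site("chrT", 2298, toy)$primary$position_in_gene, 3L)
})

test_that("coding effects translate correctly on the plus strand", {
  # codon 410 is GTG (Val); G->T at its first position gives TTG (Leu)
  eff <- predict_effect("chrT", 1328, "G", "T", "txp", toy)
  expect_equal(eff$feature_class, "nonsynonymous")
  expect_equal(eff$residue, "V410L")
  expect_equal(eff$codon_number, 410L)
  expect_equal(eff$position_in_codon, 1L)
  expect_equal(eff$ref_codon, "GTG")
  expect_equal(eff$alt_codon, "TTG")
  # codon 30 GGA -> GGG: fourfold-degenerate third position, synonymous
  eff2 <- predict_effect("chrT", 190, "A", "G", "txp", toy)
  expect_equal(eff2$feature_class, "synonymous")
  expect_equal(eff2$ref_aa, eff2$alt_aa)
  # codon 23 CAA -> TAA: stop gain labeled with *
  eff3 <- predict_effect("chrT", 167, "C", "T", "txp", toy)
  expect_equal(eff3$alt_aa, "*")
  expect_equal(eff3$residue, "Q23*")
  expect_equal(eff3$feature_class, "nonsynonymous")
})

test_that("minus-strand effects complement the alternate base", {
  # first CDS base in transcription order sits at genomic 2298 (codon 1 = ATG)
  eff <- predict_effect("chrT", 2298, as.character(
    Biostrings::subseq(toy$seq[["chrT"]], 2298, 2298)), "A", "txm", toy)
  expect_equal(eff$codon_number, 1L)
  expect_equal(eff$ref_codon, "ATG")
  # mutated protein translation agrees with the call, via the full oracle
  prot_ref <- translate_str(oracle_spliced_cds(toy, toy$seq, "txm"))
  mut_seq <- toy$seq
  s <- as.character(mut_seq[["chrT"]])
  for (pos in c(2050, 2090, 2250, 2295)) {
    ref <- substr(s, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    eff <- predict_effect("chrT", pos, ref, alt, "txm", toy)
    s2 <- s
    substr(s2, pos, pos) <- alt
    mseq <- Biostrings::DNAStringSet(s2); names(mseq) <- "chrT"
    prot_mut <- translate_str(oracle_spliced_cds(toy, mseq, "txm"))
    same <- prot_ref == prot_mut
    expect_equal(eff$feature_class == "synonymous", same)
    if (!same) {
      d <- which(strsplit(prot_ref, "")[[1]] != strsplit(prot_mut, "")[[1]])
      expect_equal(eff$codon_number, d)
    }
  }
})

test_that("a reference-base mismatch is an error naming the site", {
  expect_error(predict_effect("chrT", 1328, "A", "T", "txp", toy),
               "reference mismatch.*1328")
  expect_error(predict_effect("chrT", 1500, "A", "T", "txp", toy),
               "not in the CDS")
})

test_that("annotation of a scan partitions SNPs into exactly one primary class", {
  cfg <- sim_config(seed = 57, n_sites = 400, n_planted_sites = 0)
  g <- generate_genome(cfg)
  pc <- generate_pool_counts(sim_truth(g, cfg), cfg)
  rec <- run_comparison(pc, filter_config(), c("kdr", "recovered"))
  rec <- annotate_snps(rec, g)
  expect_true(all(!is.na(rec$feature_class)))
  expect_true(all(rec$feature_class %in%
    c("intergenic", "five_prime_UTR", "three_prime_UTR", "intron",
      "synonymous", "nonsynonymous", "ncRNA")))
  fc <- feature_class_counts(rec)
  expect_equal(sum(fc$primary$n), nrow(rec))
  # membership tally can exceed the primary tally (overlapping features)
  expect_gte(sum(fc$membership$n), sum(fc$primary$n))
  # codon fields exactly for coding SNPs
  coding <- rec$feature_class %in% c("synonymous", "nonsynonymous")
  expect_true(all(!is.na(rec$residue[coding])))
  expect_true(all(is.na(rec$residue[!coding])))
  expect_true(all((rec$ref_aa != rec$alt_aa)[rec$feature_class == "nonsynonymous"]))
  expect_true(all((rec$ref_aa == rec$alt_aa)[rec$feature_class == "synonymous"]))
})
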