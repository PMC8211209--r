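test_that("count tables round-trip through the sync format", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 5000, n_genes = 0,
                    n_ncrna = 0, n_sites = 60, n_planted_sites = 0, seed = 13)
  g <- generate_genome(cfg)
  pc <- generate_pool_counts(sim_truth(g, cfg), cfg)
  sync <- tempfile(); man <- tempfile(); qual <- tempfile()
  write_counts(pc, sync, man, qual)
  pc2 <- read_counts(sync, man, qual)
  expect_identical(pc$counts, pc2$counts)
  expect_identical(pc$sites, pc2$sites)
  expect_equal(pc$qual, pc2$qual, tolerance = 1e-3)  # serialized at 3 dp
  expect_identical(pc$libraries$phenotype, pc2$libraries$phenotype)
})

test_that("sync columns parse in A:T:C:G:N:del order", {
  f <- tempfile()
  writeLines("chr1\t100\tA\t10:0:5:0:0:0\t12:0:3:0:0:0", f)
  man <- data.frame(library_id = c("kdr1", "kdr2"), phenotype = "kdr",
                    replicate = 1:2, column_index = 1:2)
  pc <- read_counts(f, man)
  expect_equal(pc$sites$pos, 100L)
  expect_equal(pc$sites$ref, "A")
  expect_equal(unname(pc$counts[1, c("A", "T", "C", "G"), "kdr1"]),
               c(10, 0, 5, 0))
  expect_equal(unname(pc$counts[1, c("A", "T", "C", "G"), "kdr2"]),
               c(12, 0, 3, 0))
})

test_that("malformed sync input errors name the offending line", {
  man <- data.frame(library_id = c("a", "b"), phenotype = "kdr",
                    replicate = 1:2, column_index = 1:2)
  f <- tempfile()
  writeLines(c("chr1\t1\tA\t1:0:0:0:0:0\t1:0:0:0:0:0",
               "chr1\t2\tA\t1:0:0:0:0\t1:0:0:0:0:0"), f)
  expect_error(read_counts(f, man), "line 2.*5 fields")
  writeLines(c("chr1\t1\tA\t1:0:0:0:0:0\t1:0:0:0:0:0",
               "chr1\t2\tA\t1:0:x:0:0:0\t1:0:0:0:0:0"), f)
  expect_error(read_counts(f, man), "line 2.*count")
  writeLines("chr1\t1\tA\t1:0:0:0:0:0", f)
  expect_error(read_counts(f, man), "expected 5 fields|expected")
  # reference-N lines are skipped with a logged count
  writeLines(c("chr1\t1\tN\t1:0:0:0:0:0\t1:0:0:0:0:0",
               "chr1\t2\tA\t5:0:1:0:0:0\t4:0:2:0:0:0"), f)
  expect_message(pc <- read_counts(f, man), "1 line")
  expect_equal(nrow(pc$sites), 1)
})

test_that("gene models survive the FASTA/GFF3 round trip with zero warnings", {
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_genome_fasta(fix_genome, fa)
  write_gff3(fix_genome, gff)
  expect_no_warning(gm <- read_gene_models(gff, fa))
  expect_identical(as.character(gm$seq), as.character(fix_genome$seq))
  m0 <- fix_genome$models
  expect_setequal(gm$transcripts$transcript_id, m0$transcripts$transcript_id)
  for (id in m0$transcripts$transcript_id) {
    a <- m0$features[m0$features$transcript_id == id & m0$features$type == "CDS", ]
    b <- gm$features[gm$features$transcript_id == id & gm$features$type == "CDS", ]
    expect_equal(sort(a$start), sort(b$start))
    expect_equal(sort(a$end), sort(b$end))
  }
})

test_that("minus-strand CDS concatenates in transcription order for translation", {
  toy <- make_toy()
  s <- oracle_spliced_cds(toy, toy$seq, "txm")
  prot <- translate_str(s)
  expect_equal(substr(prot, 1, 1), "M")
  expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
  expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
})

test_that("unresolvable Parent links are an error", {
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_genome_fasta(fix_genome, fa)
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t1\t500\t.\t+\t.\tID=geneA",
               "chr1\tx\tmRNA\t1\t500\t.\t+\t.\tID=txA;Parent=geneMISSING",
               "chr1\tx\texon\t1\t500\t.\t+\t.\tParent=txA"), gff)
  expect_error(read_gene_models(gff, fa), "missing gene")
})

test_that("CDS not divisible by 3 is reported with the transcript named", {
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_genome_fasta(fix_genome, fa)
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t1\t500\t.\t+\t.\tID=geneA",
               "chr1\tx\tmRNA\t1\t500\t.\t+\t.\tID=txA;Parent=geneA",
               "chr1\tx\texon\t1\t500\t.\t+\t.\tParent=txA",
               "chr1\tx\tCDS\t10\t30\t.\t+\t0\tParent=txA",
               "chr1\tx\tCDS\t100\t110\t.\t+\t0\tParent=txA"), gff)
  expect_error(read_gene_models(gff, fa), "txA")
})

test_that("SNP tables round-trip and serialize residue labels as <refAA><pos><altAA>", {
  rec <- data.frame(
    gene_id = "gene001", chrom = "chr3", pos = 316080722L, ref = "G",
    alt = "T", alt_freq_a = 0.93, alt_freq_b = 0.15, lod = 25.73,
    het_a = 0.13, het_b = 0.26, het_total = 0.34, strand = "+",
    position_class = "nonsynonymous", substitution = "replacement",
    position_in_codon = 1L, codon_number = 410L, ref_codon = "GTG",
    alt_codon = "TTG", ref_aa = "V", alt_aa = "L", residue = "V410L",
    description = "voltage-gated sodium channel", category = "target_site",
    stringsAsFactors = FALSE)
  f <- tempfile()
  write_snp_table(rec, f)
  back <- read_snp_table(f)
  expect_equal(nrow(back), 1)
  for (col in names(rec)) expect_equal(back[[col]], rec[[col]], info = col)
  expect_match(back$residue, "^[A-Z*]\\d+[A-Z*]$")
  # empty record list -> header-only file
  write_snp_table(rec[0, ], f)
  expect_equal(length(readLines(f)), 1)
  expect_equal(nrow(read_snp_table(f)), 0)
})
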