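# Shared small synthetic genome, built once per test run.
fix_cfg <- sim_config(n_chromosomes = 2, chrom_length = 30000, n_genes = 10,
                      n_ncrna = 2, n_sites = 300, n_planted_sites = 6,
                      seed = 42L)
fix_genome <- generate_genome(fix_cfg)
fix_models <- local({
  m <- fix_genome$models
  m$seq <- fix_genome$seq
  m
})

# Hand-built toy gene models on a designed 2 kb sequence:
#  - txp: plus-strand gene, one long CDS exon, >= 410 codons, codon 410 = GTG
#  - txm: minus-strand 2-exon gene (CDS split across an intron)
#  - txo: plus-strand gene overlapping txm's span (for precedence checks)
make_toy <- function() {
  set.seed(99)
  base <- sample(c("A", "C", "G", "T"), 4000, replace = TRUE)
  # plus-strand CDS at 101..1420 (440 codons): ATG, sense codons, stop;
  # codon 410 forced to GTG (Val) and codon 23 to CAA (Gln)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  codons <- c("ATG", sample(sense, 438, replace = TRUE), "TAA")
  codons[410] <- "GTG"
  codons[23] <- "CAA"
  codons[30] <- "GGA"   # Gly with fourfold-degenerate third position
  base[101:1420] <- unlist(strsplit(codons, ""))
  # minus-strand gene: CDS pieces 2001..2100 and 2201..2298 (intron
  # between); the coding sequence reads 2298->2201 then 2100->2001, so the
  # ascending genomic concatenation is the reverse complement of it
  m_coding <- c("ATG", sample(sense, 64, replace = TRUE), "TGA") # 66 codons = 198 nt
  m_genomic <- rev(unname(c(A = "T", C = "G", G = "C", T = "A")[
    unlist(strsplit(m_coding, ""))]))
  base[2001:2100] <- m_genomic[1:100]
  base[2201:2298] <- m_genomic[101:198]
  seq <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(seq) <- "chrT"
  tx <- data.frame(
    transcript_id = c("txm", "txo", "txp"),
    gene_id = c("gm", "go", "gp"),
    chrom = "chrT", strand = c("-", "+", "+"),
    biotype = "coding",
    description = c("minus-strand toy", "overlap toy", "plus-strand toy"))
  ft <- rbind(
    data.frame(transcript_id = "txp", type = "exon", start = 61, end = 1480,
               phase = NA),
    data.frame(transcript_id = "txp", type = "five_prime_UTR", start = 61,
               end = 100, phase = NA),
    data.frame(transcript_id = "txp", type = "CDS", start = 101, end = 1420,
               phase = 0),
    data.frame(transcript_id = "txp", type = "three_prime_UTR", start = 1421,
               end = 1480, phase = NA),
    data.frame(transcript_id = "txm", type = "exon",
               start = c(2000, 2201), end = c(2100, 2300), phase = NA),
    data.frame(transcript_id = "txm", type = "CDS",
               start = c(2001, 2201), end = c(2100, 2298), phase = c(1, 0)),
    data.frame(transcript_id = "txm", type = "three_prime_UTR", start = 2000,
               end = 2000, phase = NA),
    data.frame(transcript_id = "txm", type = "five_prime_UTR", start = 2299,
               end = 2300, phase = NA),
    data.frame(transcript_id = "txo", type = "exon",
               start = c(2050, 2250), end = c(2080, 2278), phase = NA),
    data.frame(transcript_id = "txo", type = "CDS",
               start = c(2050, 2250), end = c(2080, 2278), phase = c(0, 2)))
  m <- gene_models(tx, ft, seqlengths = c(chrT = 4000L))
  m$seq <- seq
  m
}

# Four-library count set built directly from per-site count matrices.
# counts_list: list per library of n x 4 matrices (A, C, G, T columns).
make_counts <- function(sites, counts_list, libraries, qual = NULL) {
  arr <- array(0, dim = c(nrow(sites), 6, length(counts_list)),
               dimnames = list(NULL, c("A", "T", "C", "G", "N", "del"),
                               libraries$library_id))
  for (l in seq_along(counts_list)) {
    m <- counts_list[[l]]
    arr[, "A", l] <- m[, "A"]; arr[, "T", l] <- m[, "T"]
    arr[, "C", l] <- m[, "C"]; arr[, "G", l] <- m[, "G"]
  }
  pool_counts(libraries, sites, arr, qual = qual)
}

std_libs <- function(phenotypes = c("kdr", "dead")) {
  data.frame(library_id = paste0(rep(phenotypes, each = 2), 1:2),
             phenotype = rep(phenotypes, each = 2),
             replicate = rep(1:2, 2))
}
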