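#' Read gene models from GFF3 and a reference FASTA
#'
#' Parses a GFF3 annotation (via \pkg{rtracklayer}) into a [gene_models()]
#' set and attaches the reference sequences needed for codon-aware effect
#' prediction. `Parent` links must resolve within the file; every
#' referenced chromosome must be present in the FASTA; CDS intervals
#' outside chromosome bounds and CDS totals not divisible by 3 raise an
#' error naming the transcript.
#'
#' @param gff3_path GFF3 annotation path.
#' @param fasta_path reference FASTA path.
#' @return a [gene_models()] object with a `seq` element (a
#'   [Biostrings::DNAStringSet]).
#' @export
read_gene_models <- function(gff3_path, fasta_path) {
  seq <- Biostrings::readDNAStringSet(fasta_path)
  names(seq) <- sub("\\s.*$", "", names(seq))
  gr <- rtracklayer::import(gff3_path)
  type <- as.character(gr$type)
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parent <- if (!is.null(gr$Parent))
    vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  else rep(NA_character_, length(gr))

  is_gene <- type == "gene"
  gene_ids <- id[is_gene]
  gene_desc <- if (!is.null(gr$description))
    setNames(as.character(gr$description)[is_gene], gene_ids)
  else setNames(rep("", sum(is_gene)), gene_ids)

  is_tx <- type %in% c("mRNA", "transcript", "ncRNA")
  if (!all(parent[is_tx] %in% gene_ids)) {
    bad <- id[is_tx][!(parent[is_tx] %in% gene_ids)]
    stop("transcript Parent points to missing gene: ",
         paste(bad, collapse = ", "))
  }
  tx_chrom <- as.character(GenomicRanges::seqnames(gr))[is_tx]
  if (!all(tx_chrom %in% names(seq)))
    stop("FASTA lacks chromosome(s): ",
         paste(setdiff(tx_chrom, names(seq)), collapse = ", "))
  transcripts <- data.frame(
    transcript_id = id[is_tx],
    gene_id = parent[is_tx],
    chrom = tx_chrom,
    strand = as.character(GenomicRanges::strand(gr))[is_tx],
    biotype = ifelse(type[is_tx] == "ncRNA", "ncRNA", "coding"),
    description = unname(gene_desc[parent[is_tx]]),
    stringsAsFactors = FALSE
  )
  transcripts$description[is.na(transcripts$description)] <- ""

  is_ft <- type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  if (!all(parent[is_ft] %in% transcripts$transcript_id)) {
    bad <- unique(parent[is_ft][!(parent[is_ft] %in% transcripts$transcript_id)])
    stop("feature Parent points to missing transcript: ",
         paste(bad, collapse = ", "))
  }
  phase <- rep(NA_integer_, length(gr))
  if (!is.null(gr$phase)) phase <- suppressWarnings(as.integer(gr$phase))
  features <- data.frame(
    transcript_id = parent[is_ft],
    type = type[is_ft],
    start = GenomicRanges::start(gr)[is_ft],
    end = GenomicRanges::end(gr)[is_ft],
    phase = phase[is_ft],
    stringsAsFactors = FALSE
  )
  obj <- gene_models(transcripts, features,
                     seqlengths = setNames(Biostrings::width(seq), names(seq)))
  obj$seq <- seq
  obj
}

# Canonical SNP-table column set: the superset schema (codon detail
# included); tables for non-coding SNPs carry NA in the codon fields.
SNP_TABLE_COLS <- c(
  "gene_id", "chrom", "pos", "ref", "alt",
  "alt_freq_a", "alt_freq_b", "lod",
  "het_a", "het_b", "het_total",
  "strand", "position_class", "substitution",
  "position_in_codon", "codon_number",
  "ref_codon", "alt_codon", "ref_aa", "alt_aa", "residue",
  "description", "category"
)

#' Write annotated SNP records as a TSV
#'
#' Emits one row per SNP with the full annotation schema: gene ID, site,
#' alternate frequency in both phenotypes, LOD, per-phenotype and total
#' expected heterozygosity, reference/alternate nucleotide, gene
#' orientation, feature class, synonymous/replacement flag, codon detail,
#' residue label (`<refAA><codon><altAA>`, e.g. `V410L`), chromosome, gene
#' description, and resistance category. Missing fields (e.g. codon detail
#' for non-coding SNPs) are written as `NA`.
#'
#' @param records data.frame of SNP records (from [run_comparison()] /
#'   [annotate_snps()]); an empty data.frame yields a header-only file.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(records, path) {
  out <- as.data.frame(records)
  for (col in SNP_TABLE_COLS) if (is.null(out[[col]])) out[[col]] <- NA
  out <- out[, SNP_TABLE_COLS, drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a SNP table written by [write_snp_table()]
#'
#' @param path TSV path.
#' @return data.frame with the canonical SNP-table columns.
#' @export
read_snp_table <- function(path) {
  chr_cols <- c("gene_id", "chrom", "ref", "alt", "strand", "position_class",
                "substitution", "ref_codon", "alt_codon", "ref_aa", "alt_aa",
                "residue", "description", "category")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = "NA",
             colClasses = setNames(rep("character", length(chr_cols)),
                                   chr_cols))
}
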