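#' Generate a synthetic reference genome with gene models
#'
#' Emits random chromosome sequences and a structured gene annotation:
#' plus- and minus-strand protein-coding genes, each with a 5'UTR, at least
#' two CDS exons separated by introns, and a 3'UTR; plus a few single- or
#' two-exon ncRNA genes. Coding sequences are built from sense codons with
#' an ATG initiator and a single terminal stop, so reference proteins have
#' no internal stops. Genes are placed left-to-right with random intergenic
#' gaps; at least 20% of each chromosome remains intergenic by
#' construction (gene placement aborts rather than exceed 80% occupancy).
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_genome`: list with `seq` (a
#'   [Biostrings::DNAStringSet]) and `models` (a [gene_models()] set).
#' @examples
#' g <- generate_genome(sim_config(n_chromosomes = 1, chrom_length = 20000,
#'                                 n_genes = 4, seed = 7))
#' g$models
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  with_seed(stage_seed(config$seed, 1L), {
    chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
    seqs <- lapply(chroms, function(ch)
      sample(BASES, config$chrom_length, replace = TRUE))
    names(seqs) <- chroms

    # round-robin gene assignment to chromosomes
    gene_chrom <- chroms[((seq_len(config$n_genes) - 1L) %% length(chroms)) + 1L]
    ncrna_chrom <- if (config$n_ncrna > 0)
      chroms[((seq_len(config$n_ncrna) - 1L) %% length(chroms)) + 1L] else character()

    tx_rows <- list(); ft_rows <- list()
    gi <- 0L
    for (ch in chroms) {
      cursor <- sample(100:300, 1L)
      budget <- floor(0.8 * config$chrom_length)  # keep >= 20% intergenic
      used <- 0L
      ids <- which(gene_chrom == ch)
      nc_ids <- which(ncrna_chrom == ch)
      for (g in ids) {
        gi <- gi + 1L
        plan <- plan_coding_gene()
        if (plan$span > config$chrom_length)
          stop(sprintf("gene of span %d exceeds chromosome length %d",
                       plan$span, config$chrom_length))
        if (cursor + plan$span - 1L > config$chrom_length ||
            used + plan$span > budget)
          stop(sprintf(
            "cannot place gene %d: span %d exceeds remaining space on %s",
            g, plan$span, ch))
        strand <- sample(c("+", "-"), 1L)
        gid <- sprintf("gene%03d", g)
        tid <- sprintf("tx%03d", g)
        built <- realize_gene(plan, cursor, strand, gid, tid, ch)
        tx_rows[[length(tx_rows) + 1L]] <- built$tx
        ft_rows[[length(ft_rows) + 1L]] <- built$ft
        # design coding sequence and burn it into the chromosome
        cds <- built$ft[built$ft$type == "CDS", ]
        cds <- cds[order(cds$start), ]
        coding <- design_cds(sum(cds$end - cds$start + 1L) / 3L)
        genomic <- if (strand == "+") coding else revcomp_chars(coding)
        off <- 0L
        for (i in seq_len(nrow(cds))) {
          w <- cds$end[i] - cds$start[i] + 1L
          seqs[[ch]][cds$start[i]:cds$end[i]] <- genomic[(off + 1L):(off + w)]
          off <- off + w
        }
        cursor <- cursor + plan$span + sample(80:250, 1L)
        used <- used + plan$span
      }
      for (g in nc_ids) {
        span <- sample(120:300, 1L)
        if (cursor + span - 1L > config$chrom_length || used + span > budget)
          stop(sprintf("cannot place ncRNA gene %d on %s", g, ch))
        gid <- sprintf("ncgene%02d", g)
        tid <- sprintf("nctx%02d", g)
        strand <- sample(c("+", "-"), 1L)
        n_ex <- sample(1:2, 1L)
        if (n_ex == 1L) {
          ex <- data.frame(start = cursor, end = cursor + span - 1L)
        } else {
          e1 <- as.integer(span * 0.4)
          ex <- data.frame(start = c(cursor, cursor + e1 + 60L),
                           end = c(cursor + e1 - 1L, cursor + span - 1L))
        }
        tx_rows[[length(tx_rows) + 1L]] <- data.frame(
          transcript_id = tid, gene_id = gid, chrom = ch, strand = strand,
          biotype = "ncRNA", description = "non-coding RNA")
        ft_rows[[length(ft_rows) + 1L]] <- data.frame(
          transcript_id = tid, type = "exon", start = ex$start, end = ex$end,
          phase = NA_integer_)
        cursor <- cursor + span + sample(80:250, 1L)
        used <- used + span
      }
    }

    seq <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
    names(seq) <- chroms
    transcripts <- if (length(tx_rows)) do.call(rbind, tx_rows) else
      data.frame(transcript_id = character(), gene_id = character(),
                 chrom = character(), strand = character(),
                 biotype = character(), description = character())
    features <- if (length(ft_rows)) do.call(rbind, ft_rows) else
      data.frame(transcript_id = character(), type = character(),
                 start = integer(), end = integer(), phase = integer())
    models <- if (nrow(transcripts) > 0)
      gene_models(transcripts, features,
                  seqlengths = setNames(Biostrings::width(seq), chroms))
    else
      structure(list(transcripts = transcripts, features = features,
                     seqlengths = setNames(Biostrings::width(seq), chroms)),
                class = "gene_models")
    structure(list(seq = seq, models = models, config = config),
              class = "sim_genome")
  })
}

# Random exon/intron layout for a coding gene, in local coordinates.
plan_coding_gene <- function() {
  n_codons <- sample(40:140, 1L)          # incl. initiator and stop
  n_cds_ex <- sample(2:4, 1L)
  cds_len <- 3L * n_codons
  # composition of cds_len into n_cds_ex parts, each >= 12 nt
  cuts <- sort(sample(seq(12L, cds_len - 12L), n_cds_ex - 1L))
  parts <- diff(c(0L, cuts, cds_len))
  while (any(parts < 12L)) {
    cuts <- sort(sample(seq(12L, cds_len - 12L), n_cds_ex - 1L))
    parts <- diff(c(0L, cuts, cds_len))
  }
  u_left <- sample(30:80, 1L)
  u_right <- sample(30:80, 1L)
  introns <- sample(40:120, n_cds_ex - 1L, replace = TRUE)
  span <- u_left + u_right + cds_len + sum(introns)
  list(n_codons = n_codons, cds_parts = parts, introns = introns,
       u_left = u_left, u_right = u_right, span = span)
}

# Lay a planned gene down at genomic `start`; the left terminal UTR is the
# 5'UTR on the plus strand and the 3'UTR on the minus strand.
realize_gene <- function(plan, start, strand, gid, tid, ch) {
  k <- length(plan$cds_parts)
  cds_start <- integer(k); cds_end <- integer(k)
  pos <- start + plan$u_left
  for (i in seq_len(k)) {
    cds_start[i] <- pos
    cds_end[i] <- pos + plan$cds_parts[i] - 1L
    pos <- cds_end[i] + 1L + if (i < k) plan$introns[i] else 0L
  }
  gene_end <- cds_end[k] + plan$u_right
  # exons: first = left UTR + first CDS chunk; last = last CDS chunk + right UTR
  ex_start <- c(start, cds_start[-1L])
  ex_end <- c(cds_end[-k], gene_end)
  if (k == 1L) { ex_start <- start; ex_end <- gene_end }
  utr_left <- c(start, start + plan$u_left - 1L)
  utr_right <- c(cds_end[k] + 1L, gene_end)
  type_left <- if (strand == "+") "five_prime_UTR" else "three_prime_UTR"
  type_right <- if (strand == "+") "three_prime_UTR" else "five_prime_UTR"
  # CDS phase in transcription order
  ord <- if (strand == "+") seq_len(k) else rev(seq_len(k))
  lens <- plan$cds_parts[ord]
  phase_tx <- (3L - (cumsum(c(0L, lens[-k])) %% 3L)) %% 3L
  phase <- integer(k); phase[ord] <- phase_tx
  ft <- rbind(
    data.frame(transcript_id = tid, type = "exon",
               start = ex_start, end = ex_end, phase = NA_integer_),
    data.frame(transcript_id = tid, type = "CDS",
               start = cds_start, end = cds_end, phase = phase),
    data.frame(transcript_id = tid, type = type_left,
               start = utr_left[1], end = utr_left[2], phase = NA_integer_),
    data.frame(transcript_id = tid, type = type_right,
               start = utr_right[1], end = utr_right[2], phase = NA_integer_)
  )
  tx <- data.frame(transcript_id = tid, gene_id = gid, chrom = ch,
                   strand = strand, biotype = "coding",
                   description = sprintf("synthetic protein %s", gid))
  list(tx = tx, ft = ft)
}

# A coding sequence of n_codons codons: ATG, sense codons, one stop.
design_cds <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  stops <- names(code)[code == "*"]
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  unlist(strsplit(c("ATG", body, sample(stops, 1L)), ""), use.names = FALSE)
}

revcomp_chars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev(unname(comp[x]))
}

#' Write a genome's sequences as 60-column wrapped FASTA
#'
#' @param genome a `sim_genome` (or any named [Biostrings::DNAStringSet] via
#'   the `seq` element).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seq <- if (inherits(genome, "sim_genome")) genome$seq else genome
  Biostrings::writeXStringSet(seq, path, width = 60L)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA`/`ncRNA`, `exon`, `CDS`, `five_prime_UTR` and
#' `three_prime_UTR` features (1-based inclusive) with `ID`/`Parent`
#' attributes resolvable within the file.
#'
#' @param models a [gene_models()] set (or a `sim_genome`).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(models, path) {
  if (inherits(models, "sim_genome")) models <- models$models
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  tx <- models$transcripts
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    f <- models$features[models$features$transcript_id == t$transcript_id, ]
    f <- f[order(f$start, f$type), ]
    g_start <- min(f$start); g_end <- max(f$end)
    tx_type <- if (t$biotype == "coding") "mRNA" else "ncRNA"
    lines <- c(
      sprintf("%s\tpoolkdr\tgene\t%d\t%d\t.\t%s\t.\tID=%s;description=%s",
              t$chrom, g_start, g_end, t$strand, t$gene_id, t$description),
      sprintf("%s\tpoolkdr\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              t$chrom, tx_type, g_start, g_end, t$strand,
              t$transcript_id, t$gene_id),
      sprintf("%s\tpoolkdr\t%s\t%d\t%d\t.\t%s\t%s\tParent=%s",
              t$chrom, f$type, f$start, f$end, t$strand,
              ifelse(is.na(f$phase), ".", as.character(f$phase)),
              t$transcript_id)
    )
    writeLines(lines, con)
  }
  invisible(path)
}
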