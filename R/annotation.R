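# Feature-class precedence when one site overlaps several features:
# coding sequence wins, then UTRs, then introns, then ncRNA exons.
CLASS_PRECEDENCE <- c("CDS" = 1, "five_prime_UTR" = 2, "three_prime_UTR" = 3,
                      "exon" = 4, "intron" = 5, "ncRNA" = 6, "intergenic" = 7)

# All (site, transcript) feature memberships for a vector of positions on
# one chromosome set. Returns a data.frame: site_i, transcript_id, gene_id,
# strand, class, position_in_gene (1-based offset in transcription
# direction within the transcript span).
site_memberships <- function(chrom, pos, models) {
  tx <- models$transcripts
  ft <- models$features
  out <- list()
  sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  if (nrow(tx) == 0L)
    return(data.frame(site_i = integer(), transcript_id = character(),
                      gene_id = character(), strand = character(),
                      class = character(), position_in_gene = integer()))
  span_start <- tapply(ft$start, ft$transcript_id, min)[tx$transcript_id]
  span_end <- tapply(ft$end, ft$transcript_id, max)[tx$transcript_id]
  spans <- GenomicRanges::GRanges(tx$chrom,
                                  IRanges::IRanges(span_start, span_end))
  hits <- GenomicRanges::findOverlaps(sites, spans, ignore.strand = TRUE)
  si <- S4Vectors::queryHits(hits)
  ti <- S4Vectors::subjectHits(hits)
  for (h in seq_along(si)) {
    i <- si[h]; t <- ti[h]
    tid <- tx$transcript_id[t]
    f <- ft[ft$transcript_id == tid, ]
    p <- pos[i]
    in_type <- f$type[f$start <= p & f$end >= p]
    cls <- if ("CDS" %in% in_type) "CDS"
      else if ("five_prime_UTR" %in% in_type) "five_prime_UTR"
      else if ("three_prime_UTR" %in% in_type) "three_prime_UTR"
      else if ("exon" %in% in_type)
        (if (tx$biotype[t] == "ncRNA") "ncRNA" else "exon")
      else "intron"
    pig <- if (tx$strand[t] == "+") p - span_start[t] + 1L
           else span_end[t] - p + 1L
    out[[length(out) + 1L]] <- data.frame(
      site_i = i, transcript_id = tid, gene_id = tx$gene_id[t],
      strand = tx$strand[t], class = cls,
      position_in_gene = as.integer(pig), stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(site_i = integer(), transcript_id = character(),
               gene_id = character(), strand = character(),
               class = character(), position_in_gene = integer())
}

#' Classify a genomic site by gene-model features
#'
#' Returns every overlapping transcript's feature membership (coding
#' sequence, 5'/3' UTR, intron, ncRNA) and a single primary class chosen
#' by precedence CDS > UTR > intron > ncRNA > intergenic, breaking ties by
#' lowest transcript id. Sites overlapping no feature are intergenic.
#'
#' @param chrom chromosome name.
#' @param position 1-based position.
#' @param models a [gene_models()] set.
#' @return list with `primary` (one-row data.frame: class, transcript_id,
#'   gene_id, strand, position_in_gene) and `memberships` (all overlapping
#'   transcripts).
#' @export
classify_site <- function(chrom, position, models) {
  if (!is.null(models$seqlengths)) {
    lim <- models$seqlengths[chrom]
    if (!is.na(lim) && (position < 1 || position > lim))
      stop(sprintf("position %d off the end of %s (length %d)",
                   position, chrom, lim))
  }
  mem <- site_memberships(chrom, position, models)
  if (nrow(mem) == 0L) {
    primary <- data.frame(class = "intergenic", transcript_id = NA_character_,
                          gene_id = NA_character_, strand = NA_character_,
                          position_in_gene = NA_integer_,
                          stringsAsFactors = FALSE)
  } else {
    ord <- order(CLASS_PRECEDENCE[mem$class], mem$transcript_id)
    primary <- mem[ord[1], c("class", "transcript_id", "gene_id", "strand",
                             "position_in_gene")]
    rownames(primary) <- NULL
  }
  list(primary = primary, memberships = mem)
}

#' Predict the coding effect of an alternate base
#'
#' Locates the site's codon in the spliced, strand-oriented CDS of a
#' transcript, substitutes the alternate base (complemented for
#' minus-strand genes), and translates both codons under the standard
#' nuclear genetic code. Stop gains carry `*` as the alternate amino acid.
#' The residue label follows the `<refAA><codon_number><altAA>` convention
#' (e.g. `V410L`), with codons numbered from the initiator methionine.
#'
#' @param chrom,pos site coordinates (1-based).
#' @param ref,alt reference and alternate base as given in the count table.
#' @param transcript_id a coding transcript whose CDS contains the site.
#' @param models a [gene_models()] set carrying reference sequences
#'   (from [read_gene_models()] or a `sim_genome`'s models plus its `seq`).
#' @param seq optional [Biostrings::DNAStringSet] overriding `models$seq`.
#' @return one-row data.frame: `feature_class` (`synonymous` or
#'   `nonsynonymous`), `codon_number`, `position_in_codon`, `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa`, `residue`.
#' @export
predict_effect <- function(chrom, pos, ref, alt, transcript_id, models,
                           seq = NULL) {
  if (is.null(seq)) seq <- models$seq
  if (is.null(seq)) stop("reference sequences required for effect prediction")
  tx <- models$transcripts[models$transcripts$transcript_id == transcript_id, ]
  if (nrow(tx) != 1L) stop("unknown transcript: ", transcript_id)
  cds <- cds_intervals(models, transcript_id)   # transcription order
  widths <- cds$end - cds$start + 1L
  hit <- which(cds$start <= pos & cds$end >= pos)
  if (length(hit) != 1L)
    stop(sprintf("site %s:%d is not in the CDS of %s", chrom, pos,
                 transcript_id))
  off_before <- if (hit > 1L) sum(widths[seq_len(hit - 1L)]) else 0L
  within <- if (tx$strand == "+") pos - cds$start[hit] + 1L
            else cds$end[hit] - pos + 1L
  idx <- off_before + within                     # 1-based in spliced CDS

  pieces <- vapply(seq_len(nrow(cds)), function(i)
    as.character(Biostrings::subseq(seq[[chrom]], cds$start[i], cds$end[i])),
    "")
  if (tx$strand == "-")
    pieces <- vapply(pieces, function(s)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))), "")
  spliced <- paste(pieces, collapse = "")

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref_coding <- if (tx$strand == "+") ref else unname(comp[ref])
  alt_coding <- if (tx$strand == "+") alt else unname(comp[alt])
  if (substr(spliced, idx, idx) != ref_coding)
    stop(sprintf(
      "reference mismatch at %s:%d: FASTA has %s on the coding strand, count table implies %s",
      chrom, pos, substr(spliced, idx, idx), ref_coding))

  codon_number <- (idx - 1L) %/% 3L + 1L
  pos_in_codon <- (idx - 1L) %% 3L + 1L
  cstart <- (codon_number - 1L) * 3L + 1L
  ref_codon <- substr(spliced, cstart, cstart + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- alt_coding
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  codon_number <- as.integer(unname(codon_number))
  pos_in_codon <- as.integer(unname(pos_in_codon))
  data.frame(
    feature_class = if (ref_aa == alt_aa) "synonymous" else "nonsynonymous",
    codon_number = codon_number, position_in_codon = pos_in_codon,
    ref_codon = ref_codon, alt_codon = alt_codon,
    ref_aa = ref_aa, alt_aa = alt_aa,
    residue = sprintf("%s%d%s", ref_aa, codon_number, alt_aa),
    stringsAsFactors = FALSE)
}

#' Annotate SNP records against gene models
#'
#' Adds the effect annotation to each record: primary feature class
#' (intergenic, 5'/3' UTR, intron, ncRNA, or - for coding sites - the
#' synonymous/nonsynonymous call with codon detail and residue label),
#' the gene and transcript, strand, position in gene, all overlapping
#' memberships (as `tx:class` pairs), and the resistance category from an
#' optional gene-category map.
#'
#' @param records SNP records (need `chrom`, `pos`, `ref`, `alt`).
#' @param models a [gene_models()] set with sequences attached (or pass a
#'   `sim_genome` whose models and seq are used).
#' @param category_map optional gene-to-category map (see
#'   [read_category_map()]).
#' @param only_significant annotate only rows with `significant == TRUE`
#'   (others get NA annotation); default FALSE.
#' @return the records with annotation columns added.
#' @export
annotate_snps <- function(records, models, category_map = NULL,
                          only_significant = FALSE) {
  if (inherits(models, "sim_genome")) {
    seq <- models$seq
    models$models$seq <- seq
    models <- models$models
  }
  n <- nrow(records)
  ann <- data.frame(
    feature_class = rep(NA_character_, n), gene_id = NA_character_,
    transcript_id = NA_character_, strand = NA_character_,
    position_in_gene = NA_integer_, codon_number = NA_integer_,
    position_in_codon = NA_integer_, ref_codon = NA_character_,
    alt_codon = NA_character_, ref_aa = NA_character_,
    alt_aa = NA_character_, residue = NA_character_,
    memberships = NA_character_, description = NA_character_,
    stringsAsFactors = FALSE)
  todo <- if (only_significant && !is.null(records$significant))
    which(records$significant) else seq_len(n)
  desc <- setNames(models$transcripts$description,
                   models$transcripts$transcript_id)
  for (i in todo) {
    cl <- classify_site(records$chrom[i], records$pos[i], models)
    pr <- cl$primary
    ann$feature_class[i] <- pr$class
    ann$gene_id[i] <- pr$gene_id
    ann$transcript_id[i] <- pr$transcript_id
    ann$strand[i] <- pr$strand
    ann$position_in_gene[i] <- pr$position_in_gene
    if (nrow(cl$memberships))
      ann$memberships[i] <- paste(cl$memberships$transcript_id,
                                  cl$memberships$class,
                                  sep = ":", collapse = ";")
    if (!is.na(pr$transcript_id)) ann$description[i] <- desc[pr$transcript_id]
    if (identical(pr$class, "CDS")) {
      eff <- predict_effect(records$chrom[i], records$pos[i],
                            records$ref[i], records$alt[i],
                            pr$transcript_id, models)
      ann$feature_class[i] <- eff$feature_class
      ann$codon_number[i] <- eff$codon_number
      ann$position_in_codon[i] <- eff$position_in_codon
      ann$ref_codon[i] <- eff$ref_codon
      ann$alt_codon[i] <- eff$alt_codon
      ann$ref_aa[i] <- eff$ref_aa
      ann$alt_aa[i] <- eff$alt_aa
      ann$residue[i] <- eff$residue
    }
  }
  out <- cbind(records, ann)
  out$category <- assign_category(out$gene_id, category_map)
  for (a in c("comparison", "stage_counts", "bh", "alpha"))
    attr(out, a) <- attr(records, a)
  class(out) <- class(records)
  out
}

#' Tally SNP feature classes
#'
#' Two denominators are reported: the primary-class tally (one class per
#' SNP; counts partition the set) and the per-membership tally (a SNP
#' overlapping several transcripts counts once per membership class, so
#' percentages can exceed 100 in total).
#'
#' @param records annotated SNP records.
#' @return list of two data.frames, `primary` and `membership`, each with
#'   `class`, `n`, `percent`.
#' @export
feature_class_counts <- function(records) {
  n <- nrow(records)
  prim <- table(records$feature_class)
  mem_classes <- unlist(lapply(strsplit(records$memberships[
    !is.na(records$memberships)], ";"), function(x) sub("^.*:", "", x)))
  mem_classes <- c(mem_classes,
                   rep("intergenic", sum(is.na(records$memberships))))
  mem_classes[mem_classes == "CDS"] <- "coding"
  mem <- table(mem_classes)
  list(
    primary = data.frame(class = names(prim), n = as.integer(prim),
                         percent = round(100 * as.integer(prim) / n, 1)),
    membership = data.frame(class = names(mem), n = as.integer(mem),
                            percent = round(100 * as.integer(mem) / n, 1))
  )
}
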