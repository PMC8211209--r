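#' Construct a gene-model set
#'
#' Transcript-centric container for gene models: each transcript carries its
#' strand, biotype and ordered exon/CDS/UTR intervals (1-based inclusive)
#' against a reference sequence set.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand` (`+`/`-`), `biotype` (`coding` or `ncRNA`) and
#'   optionally `description`.
#' @param features data.frame with columns `transcript_id`, `type` (one of
#'   `exon`, `CDS`, `five_prime_UTR`, `three_prime_UTR`), `start`, `end`,
#'   `phase` (integer for CDS, `NA` otherwise).
#' @param seqlengths optional named integer vector of chromosome lengths,
#'   used to validate feature bounds.
#' @return an object of class `gene_models`.
#' @export
gene_models <- function(transcripts, features, seqlengths = NULL) {
  stopifnot(all(c("transcript_id", "gene_id", "chrom", "strand", "biotype")
                %in% names(transcripts)),
            all(c("transcript_id", "type", "start", "end") %in% names(features)))
  if (is.null(features$phase)) features$phase <- NA_integer_
  if (is.null(transcripts$description)) transcripts$description <- ""
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(transcripts$biotype %in% c("coding", "ncRNA")))
    stop("biotype must be 'coding' or 'ncRNA'")
  bad <- !(features$transcript_id %in% transcripts$transcript_id)
  if (any(bad))
    stop("features reference unknown transcript(s): ",
         paste(unique(features$transcript_id[bad]), collapse = ", "))
  if (any(features$end < features$start))
    stop("feature intervals must have non-negative length")
  obj <- structure(list(transcripts = transcripts, features = features,
                        seqlengths = seqlengths),
                   class = "gene_models")
  validate_gene_models(obj)
  obj
}

# CDS total divisible by 3, CDS within exons, CDS within chromosome bounds.
validate_gene_models <- function(x) {
  tx <- x$transcripts
  ft <- x$features
  if (!is.null(x$seqlengths)) {
    chr_of <- setNames(tx$chrom, tx$transcript_id)
    lim <- x$seqlengths[chr_of[ft$transcript_id]]
    over <- !is.na(lim) & (ft$start < 1 | ft$end > lim)
    if (any(over & ft$type == "CDS"))
      stop("CDS outside chromosome bounds for transcript(s): ",
           paste(unique(ft$transcript_id[over & ft$type == "CDS"]),
                 collapse = ", "))
  }
  for (id in tx$transcript_id[tx$biotype == "coding"]) {
    f <- ft[ft$transcript_id == id, ]
    cds <- f[f$type == "CDS", ]
    if (nrow(cds) == 0L) stop("coding transcript without CDS: ", id)
    len <- sum(cds$end - cds$start + 1L)
    if (len %% 3L != 0L)
      stop("CDS length not divisible by 3 for transcript ", id,
           " (", len, " nt)")
    ex <- f[f$type == "exon", ]
    in_exon <- vapply(seq_len(nrow(cds)), function(i)
      any(ex$start <= cds$start[i] & ex$end >= cds$end[i]), logical(1))
    if (!all(in_exon)) stop("CDS not contained in exons for transcript ", id)
  }
  invisible(x)
}

#' @export
print.gene_models <- function(x, ...) {
  tx <- x$transcripts
  cat(sprintf("Gene models: %d transcripts (%d coding, %d ncRNA) on %d chromosome(s)\n",
              nrow(tx), sum(tx$biotype == "coding"), sum(tx$biotype == "ncRNA"),
              length(unique(tx$chrom))))
  invisible(x)
}

# Ordered CDS intervals of a transcript in transcription (5'->3') order.
cds_intervals <- function(models, transcript_id) {
  tx <- models$transcripts[models$transcripts$transcript_id == transcript_id, ]
  if (nrow(tx) != 1L) stop("unknown transcript: ", transcript_id)
  cds <- models$features[models$features$transcript_id == transcript_id &
                           models$features$type == "CDS", ]
  cds <- cds[order(cds$start), ]
  if (tx$strand == "-") cds <- cds[rev(seq_len(nrow(cds))), ]
  cds
}
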