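#' Write pooled counts as a sync-style table
#'
#' One line per site: chromosome, 1-based position, reference base, then
#' one `A:T:C:G:N:del` column per library in manifest order. Optionally
#' writes the library manifest (`library_id  phenotype  replicate
#' column_index`) and a sidecar mean-base-quality table alongside.
#'
#' @param x a [pool_counts()] object.
#' @param path output sync file path.
#' @param manifest_path optional path for the library manifest TSV.
#' @param qual_path optional path for the per-site per-library mean quality
#'   TSV (written only when the object carries a quality channel).
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, manifest_path = NULL, qual_path = NULL) {
  stopifnot(inherits(x, "pool_counts"))
  n_lib <- nrow(x$libraries)
  cols <- vapply(seq_len(n_lib), function(l)
    apply(x$counts[, , l, drop = FALSE], 1, function(v)
      paste(format(v, trim = TRUE, scientific = FALSE), collapse = ":")),
    character(nrow(x$sites)))
  if (is.null(dim(cols))) cols <- matrix(cols, nrow = nrow(x$sites))
  lines <- do.call(paste, c(list(x$sites$chrom, x$sites$pos, x$sites$ref),
                            lapply(seq_len(n_lib), function(l) cols[, l]),
                            sep = "\t"))
  writeLines(lines, path)
  if (!is.null(manifest_path)) {
    man <- data.frame(library_id = x$libraries$library_id,
                      phenotype = x$libraries$phenotype,
                      replicate = x$libraries$replicate,
                      column_index = seq_len(n_lib))
    write.table(man, manifest_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(qual_path) && !is.null(x$qual)) {
    q <- as.data.frame(round(x$qual, 3))
    names(q) <- x$libraries$library_id
    write.table(cbind(x$sites[c("chrom", "pos")], q), qual_path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a library manifest
#'
#' @param path TSV with columns `library_id`, `phenotype`, `replicate`,
#'   `column_index`.
#' @return the manifest data.frame, ordered by `column_index`.
#' @export
read_manifest <- function(path) {
  man <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("library_id", "phenotype", "replicate", "column_index")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  man[order(man$column_index), ]
}

#' Read a sync-style count table
#'
#' Parses `chromosome  position  reference  A:T:C:G:N:del ...` lines into a
#' [pool_counts()] object. Lines whose reference base is `N` are skipped
#' and their number logged once. Ragged rows, malformed count columns
#' (anything but six `:`-separated non-negative integers) and non-integer
#' counts raise an error naming the offending line.
#'
#' @param path sync file path.
#' @param manifest a manifest data.frame (see [read_manifest()]) or a path
#'   to one; maps count columns to `(library_id, phenotype, replicate)`.
#' @param qual_path optional sidecar mean-quality TSV written by
#'   [write_counts()].
#' @return a [pool_counts()] object.
#' @export
read_counts <- function(path, manifest, qual_path = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n_lib <- nrow(manifest)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  len <- lengths(parts)
  if (any(len != 3L + n_lib))
    stop(sprintf("line %d: expected %d fields, found %d",
                 which(len != 3L + n_lib)[1], 3L + n_lib,
                 len[which(len != 3L + n_lib)[1]]))
  m <- matrix(unlist(parts), ncol = 3L + n_lib, byrow = TRUE)
  chrom <- m[, 1]
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos))
    stop(sprintf("line %d: position is not an integer", which(is.na(pos))[1]))
  ref <- toupper(m[, 3])
  skip <- ref == "N"
  if (any(skip))
    message(sum(skip), " line(s) with reference base N skipped")
  keep <- which(!skip)
  if (!all(ref[keep] %in% BASES)) {
    bad <- keep[!(ref[keep] %in% BASES)][1]
    stop(sprintf("line %d: invalid reference base '%s'", bad, ref[bad]))
  }
  n <- length(keep)
  counts <- array(0, dim = c(n, 6L, n_lib))
  for (l in seq_len(n_lib)) {
    field <- strsplit(m[keep, 3L + manifest$column_index[l]], ":", fixed = TRUE)
    flen <- lengths(field)
    if (any(flen != 6L))
      stop(sprintf("line %d: count column has %d fields, expected 6",
                   keep[which(flen != 6L)[1]], flen[which(flen != 6L)[1]]))
    v <- suppressWarnings(as.numeric(unlist(field)))
    bad_v <- is.na(v) | v != floor(v) | v < 0
    if (any(bad_v))
      stop(sprintf("line %d: non-integer or negative count",
                   keep[ceiling(which(bad_v)[1] / 6)]))
    counts[, , l] <- matrix(v, ncol = 6L, byrow = TRUE)
  }
  qual <- NULL
  if (!is.null(qual_path)) {
    qt <- read.table(qual_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    qual <- as.matrix(qt[!skip, manifest$library_id, drop = FALSE])
    dimnames(qual) <- NULL
  }
  pool_counts(
    libraries = manifest[, c("library_id", "phenotype", "replicate")],
    sites = data.frame(chrom = chrom[keep], pos = pos[keep], ref = ref[keep],
                       stringsAsFactors = FALSE),
    counts = counts, qual = qual
  )
}
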