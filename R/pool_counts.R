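#' Construct a per-library nucleotide count set
#'
#' The central count container: per-site A/T/C/G/N/del read counts for each
#' sequenced library, each library labeled by phenotype and replicate.
#'
#' @param libraries data.frame with columns `library_id`, `phenotype`,
#'   `replicate` (integer), one row per library, in column order of `counts`.
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`
#'   (reference base, one of A/C/G/T). Positions must be strictly
#'   increasing within each chromosome.
#' @param counts numeric array `[n_sites, 6, n_libraries]`; the 6 allele
#'   columns follow the sync convention A:T:C:G:N:del.
#' @param qual optional `[n_sites, n_libraries]` matrix of mean Phred base
#'   quality per site per library; `NULL` when the quality channel is
#'   absent.
#' @return an object of class `pool_counts`.
#' @export
pool_counts <- function(libraries, sites, counts, qual = NULL) {
  stopifnot(is.data.frame(libraries),
            all(c("library_id", "phenotype", "replicate") %in% names(libraries)),
            is.data.frame(sites),
            all(c("chrom", "pos", "ref") %in% names(sites)))
  counts <- unclass(counts)
  if (length(dim(counts)) != 3L || dim(counts)[2] != 6L)
    stop("counts must be an [n_sites, 6, n_libraries] array")
  if (dim(counts)[1] != nrow(sites) || dim(counts)[3] != nrow(libraries))
    stop("counts dimensions disagree with sites/libraries")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!all(sites$ref %in% BASES))
    stop("reference base must be one of A, C, G, T")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (!is.null(qual)) {
    qual <- as.matrix(qual)
    stopifnot(nrow(qual) == nrow(sites), ncol(qual) == nrow(libraries))
  }
  dimnames(counts) <- list(NULL, SYNC_COLS, libraries$library_id)
  structure(list(libraries = libraries, sites = sites,
                 counts = counts, qual = qual),
            class = "pool_counts")
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("Pooled count set: %d sites x %d libraries (%s)\n",
              nrow(x$sites), nrow(x$libraries),
              paste(x$libraries$library_id, collapse = ", ")))
  cat(sprintf("  chromosomes: %s; quality channel: %s\n",
              paste(unique(x$sites$chrom), collapse = ", "),
              if (is.null(x$qual)) "absent" else "present"))
  invisible(x)
}

# Row-subset a pool_counts by site index and/or library index.
subset_counts <- function(x, site_idx = NULL, lib_idx = NULL) {
  if (is.null(site_idx)) site_idx <- seq_len(nrow(x$sites))
  if (is.null(lib_idx)) lib_idx <- seq_len(nrow(x$libraries))
  pool_counts(
    libraries = x$libraries[lib_idx, , drop = FALSE],
    sites = x$sites[site_idx, , drop = FALSE],
    counts = x$counts[site_idx, , lib_idx, drop = FALSE],
    qual = if (is.null(x$qual)) NULL else x$qual[site_idx, lib_idx, drop = FALSE]
  )
}

# Per-site coverage per library: all sequenced bases plus deletions; the N
# column is ignored throughout.
lib_depths <- function(x, lib_idx = seq_len(nrow(x$libraries))) {
  apply(x$counts[, c(BASES, "del"), lib_idx, drop = FALSE], c(1, 3), sum)
}

# n_sites x 4 matrix of nucleotide counts summed over the given libraries.
base_counts <- function(x, lib_idx) {
  m <- x$counts[, BASES, lib_idx, drop = FALSE]
  out <- apply(m, c(1, 2), sum)
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(NULL, BASES))
  out
}

# Library indices for a phenotype (optionally a single replicate).
libs_of <- function(x, phenotype, replicate = NULL) {
  i <- which(x$libraries$phenotype == phenotype)
  if (!is.null(replicate))
    i <- i[x$libraries$replicate[i] == replicate]
  i
}
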