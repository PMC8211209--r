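#' Read a gene-to-resistance-category map
#'
#' Curated TSV with columns `gene_id` and `category`; categories are
#' `cuticle`, `detoxification`, `target_site`, or `other`. Duplicate rows
#' that agree are collapsed; conflicting duplicates are an error.
#'
#' @param path TSV path.
#' @return data.frame with `gene_id`, `category`.
#' @export
read_category_map <- function(path) {
  map <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "category") %in% names(map)))
    stop("category map needs columns gene_id and category")
  validate_category_map(map)
}

validate_category_map <- function(map) {
  ok <- c("cuticle", "detoxification", "target_site", "other")
  if (!all(map$category %in% ok))
    stop("unknown category value(s): ",
         paste(setdiff(map$category, ok), collapse = ", "))
  map <- unique(map[, c("gene_id", "category")])
  dup <- map$gene_id[duplicated(map$gene_id)]
  if (length(dup))
    stop("conflicting category entries for gene(s): ",
         paste(unique(dup), collapse = ", "))
  map
}

#' Assign genes to resistance categories
#'
#' Deterministic lookup in the curated map; genes absent from the map (or
#' `NA` gene ids, e.g. intergenic SNPs) fall in `other`.
#'
#' @param gene_id character vector of gene ids.
#' @param map category map data.frame (`gene_id`, `category`) or a TSV
#'   path; `NULL` assigns everything to `other`.
#' @return character vector of categories.
#' @export
assign_category <- function(gene_id, map = NULL) {
  if (is.null(map)) return(rep("other", length(gene_id)))
  if (is.character(map) && length(map) == 1L) map <- read_category_map(map)
  map <- validate_category_map(map)
  cat <- map$category[match(gene_id, map$gene_id)]
  cat[is.na(cat)] <- "other"
  cat
}

#' Per-category LOD summary with one-way ANOVA across comparisons
#'
#' Within each resistance category, summarizes the LOD scores of
#' significant SNPs per pairwise comparison (N, mean, standard error, 95th
#' quantile) and tests equality of the mean LODs across comparisons with a
#' one-way fixed-effects ANOVA. Groups with fewer than two observations
#' are excluded with a warning; with fewer than two remaining groups no F
#' statistic is reported.
#'
#' @param records annotated SNP records carrying `lod`, `category` and a
#'   `comparison` column (combine comparisons with
#'   [combine_comparisons()]).
#' @param categories categories to summarize (default: those present).
#' @return object of class `category_summary`: data.frame with one row per
#'   category x comparison (`category`, `comparison`, `n`, `mean_lod`,
#'   `se_lod`, `q95_lod`) plus attribute `anova` (per-category `F` and
#'   `p`).
#' @export
category_anova <- function(records,
                           categories = sort(unique(records$category))) {
  stopifnot(!is.null(records$comparison), !is.null(records$lod))
  rows <- list(); av <- list()
  for (cat in categories) {
    r <- records[records$category == cat & !is.na(records$lod), ]
    grp <- split(r$lod, r$comparison)
    for (cmp in names(grp)) {
      x <- grp[[cmp]]
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat, comparison = cmp, n = length(x),
        mean_lod = mean(x),
        se_lod = if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_,
        q95_lod = unname(quantile(x, 0.95)))
    }
    small <- names(grp)[lengths(grp) < 2L]
    if (length(small)) {
      warning("category ", cat, ": group(s) with < 2 LOD values excluded: ",
              paste(small, collapse = ", "))
      grp <- grp[lengths(grp) >= 2L]
    }
    if (length(grp) >= 2L) {
      dat <- data.frame(lod = unlist(grp),
                        comparison = rep(names(grp), lengths(grp)))
      a <- anova(lm(lod ~ comparison, data = dat))
      av[[length(av) + 1L]] <- data.frame(
        category = cat, F = a$`F value`[1], p = a$`Pr(>F)`[1])
    } else {
      av[[length(av) + 1L]] <- data.frame(category = cat, F = NA_real_,
                                          p = NA_real_)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(), comparison = character(),
               n = integer(), mean_lod = numeric(), se_lod = numeric(),
               q95_lod = numeric())
  rownames(out) <- NULL
  attr(out, "anova") <- do.call(rbind, av)
  class(out) <- c("category_summary", "data.frame")
  out
}

#' @export
print.category_summary <- function(x, ...) {
  cat("Per-category LOD summary\n")
  print.data.frame(x, digits = 4)
  cat("\nOne-way ANOVA of mean LOD across comparisons:\n")
  print.data.frame(attr(x, "anova"), digits = 4)
  invisible(x)
}

#' Stack several comparisons' records for joint summaries
#'
#' @param ... annotated `snp_records` (each carries its comparison
#'   attribute), or a named list of them.
#' @return one data.frame with a `comparison` label column
#'   (`"phenA_vs_phenB"`).
#' @export
combine_comparisons <- function(...) {
  lst <- list(...)
  if (length(lst) == 1L && is.list(lst[[1]]) && !is.data.frame(lst[[1]]))
    lst <- lst[[1]]
  out <- lapply(lst, function(r) {
    cmp <- attr(r, "comparison")
    r <- as.data.frame(r)
    r$comparison <- if (!is.null(cmp)) paste(cmp, collapse = "_vs_")
                    else "comparison"
    r
  })
  do.call(rbind, out)
}

#' Classify selection direction and frequency bin for a SNP
#'
#' A SNP whose alternate-allele frequency is higher in the resistant-role
#' phenotype of the comparison is labeled `directional` (potentially
#' beneficial under insecticide exposure); higher in the susceptible-role
#' phenotype, `purifying`; equal frequencies are `ambiguous`. The favored
#' (higher-frequency) phenotype's frequency is binned `low` [0, 0.4)
#' (probably novel mutations), `moderate` [0.4, 0.8), or `high` [0.8, 1].
#'
#' @param freq_resistant alternate frequency in the resistant-role
#'   phenotype (kdr in kdr-vs-recovered and kdr-vs-dead; recovered in
#'   recovered-vs-dead).
#' @param freq_comparator alternate frequency in the other phenotype.
#' @param bins numeric cut points between low/moderate and moderate/high
#'   (default `c(0.4, 0.8)`).
#' @return data.frame with `direction` and `frequency_bin` (vectorized).
#' @examples
#' classify_selection(0.9, 0.3) # directional, high
#' @export
classify_selection <- function(freq_resistant, freq_comparator,
                               bins = c(0.4, 0.8)) {
  stopifnot(all(freq_resistant >= 0 & freq_resistant <= 1),
            all(freq_comparator >= 0 & freq_comparator <= 1),
            length(bins) == 2L, bins[1] < bins[2])
  direction <- ifelse(freq_resistant > freq_comparator, "directional",
                      ifelse(freq_resistant < freq_comparator, "purifying",
                             "ambiguous"))
  favored <- pmax(freq_resistant, freq_comparator)
  frequency_bin <- ifelse(favored < bins[1], "low",
                          ifelse(favored < bins[2], "moderate", "high"))
  data.frame(direction = direction, frequency_bin = frequency_bin,
             stringsAsFactors = FALSE)
}
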