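# Independent oracles, deliberately coded with plain loops so they share
# nothing with the package's vectorized implementations.

# Brute-force Pearson chi-square: explicit double loop over cells.
brute_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  list(chi2 = stat, df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

# Hand-coded one-way ANOVA F from sums of squares.
brute_anova_F <- function(groups) {
  all_x <- unlist(groups)
  gm <- mean(all_x)
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df_b <- length(groups) - 1
  df_w <- length(all_x) - length(groups)
  (ss_between / df_b) / (ss_within / df_w)
}

# Hand-coded Benjamini-Hochberg step-up: returns logical significance in
# input order.
brute_bh <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  thresh <- alpha * seq_len(m) / m
  k <- max(c(0, which(ps <= thresh)))
  sig <- rep(FALSE, m)
  if (k > 0) sig[p <= ps[k]] <- TRUE
  sig
}

# Direct Monte-Carlo of the two-stage pool-then-read sampling model:
# returns estimated alternate frequencies for n_sim independent libraries.
brute_two_stage <- function(n_sim, true_freq, pool_n_chrom, depth) {
  f_hat <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    copies <- sum(runif(pool_n_chrom) < true_freq)
    f_pool <- copies / pool_n_chrom
    reads <- sum(runif(depth) < f_pool)
    f_hat[i] <- reads / depth
  }
  f_hat
}

# Reverse-complement a genome and its gene models: coordinates are mapped
# x -> L - x + 1 and strands flipped. Used for the strand-symmetry check.
flip_genome <- function(models, seq) {
  lens <- setNames(Biostrings::width(seq), names(seq))
  fseq <- Biostrings::reverseComplement(seq)
  tx <- models$transcripts
  tx$strand <- ifelse(tx$strand == "+", "-", "+")
  ft <- models$features
  L <- lens[tx$chrom[match(ft$transcript_id, tx$transcript_id)]]
  new_start <- L - ft$end + 1L
  new_end <- L - ft$start + 1L
  ft$start <- as.integer(new_start)
  ft$end <- as.integer(new_end)
  m <- gene_models(tx, ft, seqlengths = lens)
  m$seq <- fseq
  m
}

# Spliced CDS of a transcript extracted directly from a sequence set,
# independent of the package's codon bookkeeping.
oracle_spliced_cds <- function(models, seq, transcript_id) {
  tx <- models$transcripts[models$transcripts$transcript_id == transcript_id, ]
  cds <- models$features[models$features$transcript_id == transcript_id &
                           models$features$type == "CDS", ]
  cds <- cds[order(cds$start), ]
  s <- paste(vapply(seq_len(nrow(cds)), function(i)
    as.character(Biostrings::subseq(seq[[tx$chrom]], cds$start[i], cds$end[i])),
    ""), collapse = "")
  if (tx$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

translate_str <- function(s) {
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X"))
}
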