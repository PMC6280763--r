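# Independent oracles and fixture builders used across the suite.

# O(n^2) single-linkage oracle: two CTSSs are in the same cluster iff they
# are connected by a chain of same-chrom, same-strand neighbours each at
# most max_gap apart. Returns a canonical partition signature.
brute_linkage <- function(chrom, pos, strand, max_gap) {
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && chrom[i] == chrom[j] && strand[i] == strand[j] &&
          abs(pos[i] - pos[j]) <= max_gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(paste(chrom, pos, strand), roots)
}

# canonical partition signature: sorted list of sorted member keys
partition_signature <- function(groups) {
  sig <- sort(vapply(groups, function(g) paste(sort(g), collapse = ";"),
                     character(1)))
  unname(sig)
}

# all-window brute-force PWM scorer over a character sequence; returns the
# best score over windows starting at 1..(nchar - L + 1), NA windows skipped
brute_pwm_best <- function(pwm, seq) {
  L <- pwm$length
  n <- nchar(seq)
  best <- -Inf
  for (s in seq_len(n - L + 1L)) {
    b <- strsplit(substr(seq, s, s + L - 1L), "")[[1]]
    idx <- match(b, c("A", "C", "G", "T"))
    if (anyNA(idx)) next
    best <- max(best, sum(pwm$matrix[cbind(idx, seq_along(idx))]))
  }
  if (is.infinite(best)) NA_real_ else best
}

# tiny ctss table shortcut (single chromosome, plus strand by default)
tbl <- function(pos, count, chrom = "chr1", strand = "+", tpm = NULL) {
  ctss_table(rep(chrom, length(pos)), pos, rep(strand, length(pos)),
             count, tpm)
}

# overlap-pair synthetic truth dominants with recovered clusters
pair_clusters_to_truth <- function(clusters, truth_df) {
  gr_cl <- GenomicRanges::GRanges(
    clusters$chrom, IRanges::IRanges(clusters$start, clusters$end),
    strand = clusters$strand)
  gr_tr <- GenomicRanges::GRanges(
    truth_df$chrom,
    IRanges::IRanges(truth_df$dominant_pos, truth_df$dominant_pos),
    strand = truth_df$strand)
  hit <- GenomicRanges::findOverlaps(gr_cl, gr_tr)
  data.frame(cluster = S4Vectors::queryHits(hit),
             promoter = S4Vectors::subjectHits(hit))
}
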