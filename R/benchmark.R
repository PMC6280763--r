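# Benchmarking a query CAGE library against a reference: CTSS-level
# correlation on raw expression, ROC curves at the CTSS and tag-cluster
# level, dominant-TSS distance summaries, positional expression-ratio
# heatmaps, and permutation similarity testing of positional matrices.

ctss_key <- function(table) paste(table$chrom, table$pos, table$strand)

# align two tables on the union of keys, absent positions imputed as 0
union_vectors <- function(a, b) {
  ka <- ctss_key(a); kb <- ctss_key(b)
  keys <- union(ka, kb)
  va <- vb <- numeric(length(keys))
  va[match(ka, keys)] <- expr_col(a)
  vb[match(kb, keys)] <- expr_col(b)
  list(a = va, b = vb, keys = keys)
}

#' Correlate two CTSS libraries
#'
#' Pearson (and optionally Spearman) correlation of per-CTSS expression over
#' the union of (chrom, pos, strand) keys; a position absent from one
#' library contributes 0 there, so missed positions are penalized.
#' Correlation is computed on raw, non-log-transformed expression.
#'
#' @param a,b normalized [ctss_table()]s.
#' @param spearman also report Spearman's rank correlation (default FALSE).
#' @return Named list with `pearson` (and `spearman` when requested) and
#'   `n` (union size).
#' @export
correlate_ctss <- function(a, b, spearman = FALSE) {
  assert_ctss(a); assert_ctss(b)
  u <- union_vectors(a, b)
  if (stats::sd(u$a) == 0 || stats::sd(u$b) == 0) {
    stop("zero-variance expression vector; correlation undefined")
  }
  out <- list(pearson = stats::cor(u$a, u$b), n = length(u$keys))
  if (spearman) out$spearman <- stats::cor(u$a, u$b, method = "spearman")
  out
}

#' ROC curve of a query library against reference-defined truth
#'
#' The reference defines truth: at the CTSS level, reference positions with
#' expression at or above `truth_tpm`; at the cluster level, reference tag
#' cluster regions. Query entities (CTSSs or clusters) are ranked by
#' descending expression; each is a true positive when it matches the truth
#' set (exact key at CTSS level, same-strand overlap at cluster level). The
#' curve steps over the rank threshold with TPR = cumulative true positives
#' over total query true positives and FPR likewise for false positives;
#' AUC is the trapezoid area. A query with no false positives gets AUC 1.
#'
#' @param query,reference normalized [ctss_table()]s (CTSS level) or
#'   [cluster_ctss()] results (cluster level).
#' @param level `"ctss"` or `"cluster"`.
#' @param truth_tpm minimum reference expression defining a true CTSS
#'   (default 1; ignored at cluster level).
#' @return List with `fpr`, `tpr` (step curve, starting at (0,0)), `auc`,
#'   `n_truth`, `n_query`.
#' @export
roc_vs_reference <- function(query, reference, level = c("ctss", "cluster"),
                             truth_tpm = 1) {
  level <- match.arg(level)
  if (level == "ctss") {
    assert_ctss(query); assert_ctss(reference)
    truth <- ctss_key(reference)[expr_col(reference) >= truth_tpm]
    if (length(truth) == 0L) stop("empty truth set")
    score <- expr_col(query)
    is_tp <- ctss_key(query) %in% truth
  } else {
    truth_gr <- clusters_granges(reference)
    if (length(truth_gr) == 0L) stop("empty truth set")
    score <- query$total_tpm
    is_tp <- IRanges::overlapsAny(clusters_granges(query), truth_gr)
    truth <- seq_along(truth_gr)
  }
  o <- order(score, decreasing = TRUE)
  is_tp <- is_tp[o]
  n_pos <- sum(is_tp)
  n_neg <- sum(!is_tp)
  tp <- cumsum(is_tp)
  fp <- cumsum(!is_tp)
  tpr <- c(0, if (n_pos > 0) tp / n_pos else rep(0, length(tp)))
  fpr <- c(0, if (n_neg > 0) fp / n_neg else rep(0, length(fp)))
  if (n_neg == 0L) {
    # perfect query: curve rises at FPR 0, close the square
    fpr <- c(fpr, 1); tpr <- c(tpr, max(tpr))
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc,
       n_truth = length(truth), n_query = length(is_tp))
}

#' Pair clusters and summarize dominant-TSS distances
#'
#' Pairs query and reference tag clusters by reciprocal same-strand
#' overlap: among overlapping candidates, each query cluster's best partner
#' is the reference cluster of highest expression and vice versa, and only
#' mutual-best pairs are kept (so a promoter fragmented into several query
#' clusters contributes one pair, through its strongest fragment). Reports
#' the absolute distance between paired dominant CTSSs, the fraction
#' identical (distance 0) and the fraction within 10 bp.
#'
#' @param query,reference [cluster_ctss()] results.
#' @param within_bp distance bound for the headline fraction (default 10).
#' @return List with `distances` (one per pair), `n_pairs`,
#'   `fraction_identical`, `fraction_within` and `within_bp`.
#' @export
dominant_distance_stats <- function(query, reference, within_bp = 10) {
  hit <- GenomicRanges::findOverlaps(clusters_granges(query),
                                     clusters_granges(reference))
  qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
  if (length(qh)) {
    best_ref_of_q <- tapply(seq_along(qh), qh, function(ii) {
      sh[ii][which.max(reference$total_tpm[sh[ii]])]
    })
    best_q_of_ref <- tapply(seq_along(sh), sh, function(ii) {
      qh[ii][which.max(query$total_tpm[qh[ii]])]
    })
    q_idx <- as.integer(names(best_ref_of_q))
    r_idx <- as.integer(best_ref_of_q)
    mutual <- as.integer(best_q_of_ref[as.character(r_idx)]) == q_idx
    qh <- q_idx[mutual]; sh <- r_idx[mutual]
  }
  d <- abs(query$dominant_pos[qh] - reference$dominant_pos[sh])
  list(distances = d, n_pairs = length(d),
       fraction_identical = if (length(d)) mean(d == 0) else NA_real_,
       fraction_within = if (length(d)) mean(d <= within_bp) else NA_real_,
       within_bp = within_bp)
}

#' Positional expression-ratio heatmap around reference dominant CTSSs
#'
#' For every reference tag cluster, looks at CTSS positions within
#' `window` bp of the reference dominant CTSS (offsets oriented 5'-to-3' on
#' the cluster strand). Where a CTSS is present in both libraries the cell
#' holds `log2(query tpm / reference tpm)`; where it is present only in the
#' reference, its reference expression is recorded in the companion
#' missing-value matrix. Rows are ordered within four reference-expression
#' quartile blocks (quartile 4 = most expressed, on top).
#'
#' @param query,reference normalized [ctss_table()]s.
#' @param reference_clusters [cluster_ctss()] result for the reference;
#'   computed with defaults when `NULL`.
#' @param window half-width of the offset grid in bp (default 100).
#' @return Object of class `ratio_heatmap`: list with matrices
#'   `values_common` and `values_missing` (rows = reference clusters in
#'   quartile-block order, columns = offsets -window..window), `offsets`,
#'   and `quartile` (per row).
#' @export
ratio_heatmap <- function(query, reference, reference_clusters = NULL,
                          window = 100) {
  assert_ctss(query, normalized = TRUE)
  assert_ctss(reference, normalized = TRUE)
  if (window <= 0) stop("window must be positive")
  if (is.null(reference_clusters)) reference_clusters <- cluster_ctss(reference)
  cl <- as.data.frame(reference_clusters)
  qtl <- ceiling(4 * rank(cl$total_tpm, ties.method = "first") / nrow(cl))
  o <- order(-qtl, -cl$total_tpm)
  cl <- cl[o, , drop = FALSE]; qtl <- qtl[o]
  offsets <- -window:window
  n <- nrow(cl)
  common <- missing_m <- matrix(NA_real_, n, length(offsets),
                                dimnames = list(NULL, offsets))
  qk <- ctss_key(query); rk <- ctss_key(reference)
  qv <- stats::setNames(query$tpm, qk)
  for (i in seq_len(n)) {
    sgn <- if (cl$strand[i] == "+") 1L else -1L
    gpos <- cl$dominant_pos[i] + sgn * offsets
    keys <- paste(cl$chrom[i], gpos, cl$strand[i])
    in_ref <- match(keys, rk)
    has_ref <- !is.na(in_ref)
    r_tpm <- reference$tpm[in_ref[has_ref]]
    q_tpm <- qv[keys[has_ref]]
    both <- !is.na(q_tpm)
    common[i, which(has_ref)[both]] <- log2(q_tpm[both] / r_tpm[both])
    missing_m[i, which(has_ref)[!both]] <- r_tpm[!both]
  }
  out <- list(values_common = common, values_missing = missing_m,
              offsets = offsets, quartile = qtl)
  class(out) <- "ratio_heatmap"
  out
}

#' Permutation similarity test for positional matrices
#'
#' Tests whether two positional matrices (e.g. dinucleotide density maps
#' from two libraries) share column (positional) structure. The statistic
#' is the Pearson correlation of the two column-mean profiles. The null is
#' generated by independently permuting the column order within each row of
#' the second matrix, which preserves every row's value distribution while
#' destroying positional structure; the p-value is
#' `(1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param matA,matB numeric matrices on the same column grid.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return List with `statistic`, `p_value`, `null` (null statistics).
#' @export
permutation_similarity <- function(matA, matB, n_perm = 1000, seed = 1L) {
  stopifnot(is.matrix(matA), is.matrix(matB), ncol(matA) == ncol(matB))
  if (n_perm < 1) stop("n_perm must be >= 1")
  col_profile <- function(m) colMeans(m, na.rm = TRUE)
  obs <- stats::cor(col_profile(matA), col_profile(matB))
  pa <- col_profile(matA)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    shuffled <- t(apply(matB, 1, sample))
    stats::cor(pa, col_profile(shuffled))
  }, numeric(1)))
  list(statistic = obs,
       p_value = (1 + sum(null >= obs)) / (1 + n_perm),
       null = null)
}

#' One-call benchmark summary of a query library against a reference
#'
#' @param query,reference normalized [ctss_table()]s.
#' @param query_clusters,reference_clusters optional precomputed
#'   [cluster_ctss()] results.
#' @return List of class `benchmark_summary`: `pearson_raw`,
#'   `shared_ctss_fraction` (fraction of reference CTSSs present in the
#'   query), `shared_cluster_fraction`, `dominant_same_fraction`,
#'   `dominant_within_10bp_fraction`, `auc_ctss`, `auc_cluster`.
#' @export
benchmark_summary <- function(query, reference, query_clusters = NULL,
                              reference_clusters = NULL) {
  if (is.null(query_clusters)) query_clusters <- cluster_ctss(query)
  if (is.null(reference_clusters)) reference_clusters <- cluster_ctss(reference)
  shared_ctss <- mean(ctss_key(reference) %in% ctss_key(query))
  shared_cluster <- mean(IRanges::overlapsAny(
    clusters_granges(reference_clusters), clusters_granges(query_clusters)))
  dd <- dominant_distance_stats(query_clusters, reference_clusters)
  out <- list(pearson_raw = correlate_ctss(query, reference)$pearson,
              shared_ctss_fraction = shared_ctss,
              shared_cluster_fraction = shared_cluster,
              dominant_same_fraction = dd$fraction_identical,
              dominant_within_10bp_fraction = dd$fraction_within,
              auc_ctss = roc_vs_reference(query, reference, "ctss")$auc,
              auc_cluster = roc_vs_reference(query_clusters,
                                             reference_clusters,
                                             "cluster")$auc)
  class(out) <- "benchmark_summary"
  out
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat("Benchmark vs reference\n")
  cat(sprintf("  Pearson (raw CTSS tpm)      %.4f\n", x$pearson_raw))
  cat(sprintf("  shared CTSS fraction        %.3f\n", x$shared_ctss_fraction))
  cat(sprintf("  shared cluster fraction     %.3f\n",
              x$shared_cluster_fraction))
  cat(sprintf("  dominant TSS identical      %.3f\n",
              x$dominant_same_fraction))
  cat(sprintf("  dominant TSS within 10 bp   %.3f\n",
              x$dominant_within_10bp_fraction))
  cat(sprintf("  AUC (CTSS / cluster)        %.3f / %.3f\n",
              x$auc_ctss, x$auc_cluster))
  invisible(x)
}
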