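# Cross-sample expression profiling over consensus clusters: expression
# matrix construction, self-organizing-map (SOM) class assignment,
# per-class genomic-location breakdown, and TSS-switch detection.

#' Build a cross-sample expression matrix over consensus clusters
#'
#' Rows are consensus clusters with at least one sample reaching `min_tpm`;
#' values are `log10(tpm + 1)` of the per-sample totals, optionally
#' row-standardized (z-score) afterwards.
#'
#' @param consensus a [merge_consensus()] result.
#' @param min_tpm minimum expression (in any sample) for a row to be kept
#'   (default 1).
#' @param standardize z-score each row after the log transform
#'   (default FALSE; [som_cluster()] standardizes internally by default).
#' @return Numeric matrix with one column per sample (named after the
#'   samples) and `rownames` = consensus ids; attributes `transform` and
#'   `standardized` record the processing.
#' @export
build_matrix <- function(consensus, min_tpm = 1, standardize = FALSE) {
  tpm_cols <- grep("^tpm_", names(consensus), value = TRUE)
  if (length(tpm_cols) < 2L) stop("need at least 2 samples")
  samples <- sub("^tpm_", "", tpm_cols)
  if (anyDuplicated(samples)) stop("duplicate sample names")
  m <- as.matrix(as.data.frame(consensus)[, tpm_cols])
  colnames(m) <- samples
  rownames(m) <- consensus$consensus_id
  keep <- apply(m, 1, max) >= min_tpm
  m <- log10(m[keep, , drop = FALSE] + 1)
  if (standardize) m <- row_zscore(m)
  attr(m, "transform") <- "log10(tpm+1)"
  attr(m, "standardized") <- standardize
  m
}

row_zscore <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  sd[sd == 0] <- 1  # flat rows stay at 0 rather than NaN
  sweep(sweep(m, 1, mu, "-"), 1, sd, "/")
}

#' SOM clustering of expression profiles
#'
#' Assigns every row of the expression matrix to a node of a self-
#' organizing map (batch SOM, via the `class` package), labelling nodes
#' `"x_y"` over an `xdim` x `ydim` grid. Rows are z-scored by default so
#' the map clusters profile shapes rather than absolute levels. Training
#' is deterministic for a fixed seed.
#'
#' @param matrix a [build_matrix()] result (or any numeric matrix).
#' @param grid length-2 integer, SOM grid dimensions (default `c(4, 2)`,
#'   i.e. 8 classes labelled `0_0` .. `3_1`).
#' @param epochs training length passed to the batch SOM (default 100).
#' @param standardize z-score rows before training (default TRUE).
#' @param seed RNG seed.
#' @return List with `labels` (character per row, `"x_y"`), `class_means`
#'   (mean profile per class over the *input* values), `codes` (trained
#'   codebook vectors), `grid`.
#' @export
som_cluster <- function(matrix, grid = c(4, 2), epochs = 100,
                        standardize = TRUE, seed = 1L) {
  stopifnot(is.matrix(matrix), length(grid) == 2L, all(grid >= 1))
  n_nodes <- prod(grid)
  if (n_nodes > nrow(matrix)) stop("more grid nodes than rows")
  train <- if (standardize) row_zscore(matrix) else matrix
  gr <- class::somgrid(xdim = grid[1], ydim = grid[2], topo = "rectangular")
  codes <- with_seed(seed, {
    if (n_nodes == 1L) {
      matrix(colMeans(train), 1L, ncol(train))
    } else {
      class::batchSOM(train, gr, radii = seq(2, 0,
                                             length.out = epochs))$codes
    }
  })
  # nearest codebook vector per row
  d <- as.matrix(stats::dist(rbind(codes, train)))
  d <- d[-seq_len(n_nodes), seq_len(n_nodes), drop = FALSE]
  node <- apply(d, 1, which.min)
  labels <- paste0((node - 1L) %% grid[1], "_", (node - 1L) %/% grid[1])
  class_means <- do.call(rbind, lapply(sort(unique(labels)), function(l) {
    colMeans(matrix[labels == l, , drop = FALSE])
  }))
  rownames(class_means) <- sort(unique(labels))
  list(labels = labels, class_means = class_means, codes = codes,
       grid = grid)
}

#' Genomic-location breakdown per SOM class
#'
#' For each SOM class, the proportions of its clusters over the genomic
#' location categories (promoter, 5'UTR, exon, intron, intergenic,
#' antisense), each row summing to 1. Clusters without a label are
#' excluded and counted.
#'
#' @param labels character vector of SOM class labels.
#' @param locations character vector of [annotate_location()] categories,
#'   parallel to `labels` (`NA` = unlabeled).
#' @return List with `proportions` (class x category matrix) and
#'   `n_excluded`.
#' @export
class_location_breakdown <- function(labels, locations) {
  stopifnot(length(labels) == length(locations))
  ok <- !is.na(labels) & !is.na(locations)
  cats <- c("promoter", "5'UTR", "exon", "intron", "intergenic", "antisense")
  tab <- table(factor(labels[ok]), factor(locations[ok], levels = cats))
  prop <- sweep(unclass(tab), 1, rowSums(tab), "/")
  list(proportions = prop, n_excluded = sum(!ok))
}

#' Detect TSS switching between two conditions
#'
#' A switching event is a consensus promoter region expressed at or above
#' `min_tpm` in both samples whose dominant CTSS positions differ by at
#' least `min_distance` bp, i.e. the same promoter region initiates at a
#' different position in the two conditions.
#'
#' @param consensus a [merge_consensus()] result over exactly 2 samples.
#' @param min_tpm minimum per-sample expression in the shared region
#'   (default 5).
#' @param min_distance minimum dominant-CTSS distance in bp (default 10).
#' @return List with `events` (`data.frame`: `consensus_id`, `chrom`,
#'   `strand`, `start`, `end`, per-sample dominants and tpm, `distance`)
#'   and `median_distance` (`NA` when no events).
#' @export
detect_switching <- function(consensus, min_tpm = 5, min_distance = 10) {
  tpm_cols <- grep("^tpm_", names(consensus), value = TRUE)
  dom_cols <- grep("^dom_", names(consensus), value = TRUE)
  if (length(tpm_cols) != 2L) stop("need exactly 2 samples")
  df <- as.data.frame(consensus)
  expressed <- df[[tpm_cols[1]]] >= min_tpm & df[[tpm_cols[2]]] >= min_tpm
  dist <- abs(df[[dom_cols[1]]] - df[[dom_cols[2]]])
  sel <- expressed & !is.na(dist) & dist >= min_distance
  events <- df[sel, c("consensus_id", "chrom", "strand", "start", "end",
                      dom_cols, tpm_cols), drop = FALSE]
  events$distance <- dist[sel]
  rownames(events) <- NULL
  list(events = events,
       median_distance = if (nrow(events)) stats::median(events$distance)
       else NA_real_)
}
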