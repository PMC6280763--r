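# Tag clustering: single-linkage grouping of CTSSs, interquantile-width
# promoter-shape summaries, cross-sample consensus clusters, genomic
# location annotation, and library subsampling.

#' Cluster CTSSs into tag clusters
#'
#' CTSSs in close vicinity reflect functionally equivalent transcripts and
#' are analyzed as a single transcriptional unit (a tag cluster). This runs
#' single-linkage along each (chrom, strand): consecutive retained CTSSs
#' whose positional gap is at most `max_gap` join one cluster. CTSSs whose
#' expression falls below `min_tpm` are excluded before linking; strands are
#' never merged.
#'
#' @param table a normalized [ctss_table()] (when no `tpm` column is
#'   present, raw counts are used as the expression value).
#' @param max_gap maximum allowed gap (bp) between consecutive cluster
#'   members (default 20).
#' @param min_tpm minimum per-CTSS expression for inclusion (default 1).
#' @return A `data.frame` of class `tag_clusters`, one row per cluster with
#'   columns `cluster_id`, `chrom`, `strand`, `start`, `end`, `n_ctss`,
#'   `total_tpm`, `q_low_pos`, `q_high_pos`, `iq_width`, `dominant_pos`,
#'   `dominant_tpm`, `shape_class`. The member-level assignment is attached
#'   as attribute `"members"` (columns `cluster_id`, `chrom`, `pos`,
#'   `strand`, `tpm`).
#' @export
cluster_ctss <- function(table, max_gap = 20, min_tpm = 1) {
  assert_ctss(table)
  if (max_gap < 0) stop("max_gap must be >= 0")
  tpm <- expr_col(table)
  keep <- tpm >= min_tpm
  tab <- table[keep, , drop = FALSE]
  tpm <- tpm[keep]
  if (nrow(tab) == 0L) return(empty_tag_clusters())
  o <- order(tab$chrom, tab$strand, tab$pos)
  tab <- tab[o, , drop = FALSE]
  tpm <- tpm[o]
  grp <- paste(tab$chrom, tab$strand)
  new_group <- c(TRUE, grp[-1] != grp[-length(grp)])
  gap_break <- c(TRUE, diff(tab$pos) > max_gap)
  cid <- cumsum(new_group | gap_break)
  members <- data.frame(cluster_id = cid, chrom = tab$chrom, pos = tab$pos,
                        strand = tab$strand, tpm = tpm,
                        stringsAsFactors = FALSE)
  summaries <- do.call(rbind, lapply(split(members, members$cluster_id),
                                     summarize_cluster))
  summaries$cluster_id <- as.integer(unique(members$cluster_id))
  summaries <- summaries[, c("cluster_id", setdiff(names(summaries),
                                                   "cluster_id"))]
  rownames(summaries) <- NULL
  attr(summaries, "members") <- members
  class(summaries) <- c("tag_clusters", "data.frame")
  summaries
}

empty_tag_clusters <- function() {
  out <- data.frame(cluster_id = integer(), chrom = character(),
                    strand = character(), start = integer(), end = integer(),
                    n_ctss = integer(), total_tpm = numeric(),
                    q_low_pos = integer(), q_high_pos = integer(),
                    iq_width = integer(), dominant_pos = integer(),
                    dominant_tpm = numeric(), shape_class = character(),
                    stringsAsFactors = FALSE)
  attr(out, "members") <- data.frame(cluster_id = integer(),
                                     chrom = character(), pos = integer(),
                                     strand = character(), tpm = numeric())
  class(out) <- c("tag_clusters", "data.frame")
  out
}

#' Summarize one tag cluster
#'
#' Computes the interquantile summary of a cluster: with members ordered
#' 5'-to-3' on the strand, `q_low_pos` is the first position at which the
#' cumulative expression reaches 10% of the cluster total and `q_high_pos`
#' the first at which it reaches 90% (no interpolation; the two are then
#' reported in genomic orientation so `q_low_pos <= q_high_pos`). The
#' interquantile width `iq_width = q_high_pos - q_low_pos + 1` excludes
#' extreme outlier CTSSs from the width estimate. The dominant CTSS is the
#' member with the highest expression (ties broken toward the 5' end); a
#' cluster is classified `sharp` when `iq_width <= 3` and `broad` otherwise.
#'
#' @param cluster `data.frame` with columns `chrom`, `pos`, `strand`, `tpm`
#'   (one strand, one chromosome).
#' @param sharp_max_iq_width widest IQ-width still called sharp (default 3).
#' @return One-row `data.frame` with the summary columns of
#'   [cluster_ctss()].
#' @export
summarize_cluster <- function(cluster, sharp_max_iq_width = 3) {
  stopifnot(is.data.frame(cluster), nrow(cluster) >= 1L,
            all(c("chrom", "pos", "strand", "tpm") %in% names(cluster)))
  strand <- cluster$strand[1]
  # 5'->3' order: ascending positions on +, descending on -
  o <- if (strand == "+") order(cluster$pos) else order(-cluster$pos)
  pos <- cluster$pos[o]
  tpm <- cluster$tpm[o]
  total <- sum(tpm)
  cum <- cumsum(tpm)
  q_lo <- pos[which(cum >= 0.1 * total)[1]]
  q_hi <- pos[which(cum >= 0.9 * total)[1]]
  dom_i <- which(tpm == max(tpm))[1]  # first in 5'->3' order on ties
  data.frame(chrom = cluster$chrom[1], strand = strand,
             start = min(pos), end = max(pos),
             n_ctss = length(pos), total_tpm = total,
             q_low_pos = min(q_lo, q_hi), q_high_pos = max(q_lo, q_hi),
             iq_width = abs(q_hi - q_lo) + 1L,
             dominant_pos = pos[dom_i], dominant_tpm = tpm[dom_i],
             shape_class = if (abs(q_hi - q_lo) + 1L <= sharp_max_iq_width)
               "sharp" else "broad",
             stringsAsFactors = FALSE)
}

clusters_granges <- function(clusters) {
  GenomicRanges::GRanges(clusters$chrom,
                         IRanges::IRanges(clusters$start, clusters$end),
                         strand = clusters$strand)
}

#' Merge tag clusters across samples into consensus clusters
#'
#' Same-strand tag clusters from different samples that overlap (or lie
#' within `max_gap` bp) are merged into one consensus promoter region. Each
#' consensus region records per-sample total expression (0 for samples with
#' no contributing cluster) and the per-sample dominant CTSS position (that
#' of the contributing cluster with the highest dominant expression; `NA`
#' for absent samples).
#'
#' @param cluster_sets named list of [cluster_ctss()] results, one per
#'   sample.
#' @param max_gap merge clusters separated by at most this many bp
#'   (default 0: overlapping or book-ended).
#' @return A `data.frame` of class `consensus_clusters` with columns
#'   `consensus_id`, `chrom`, `strand`, `start`, `end`, then one
#'   `tpm_<sample>` and one `dom_<sample>` column per sample.
#' @export
merge_consensus <- function(cluster_sets, max_gap = 0) {
  stopifnot(is.list(cluster_sets), length(cluster_sets) >= 1L)
  if (is.null(names(cluster_sets)) || anyDuplicated(names(cluster_sets))) {
    stop("cluster_sets must be a uniquely named list (one name per sample)")
  }
  samples <- names(cluster_sets)
  all_cl <- do.call(rbind, lapply(samples, function(s) {
    cl <- as.data.frame(cluster_sets[[s]])
    if (nrow(cl)) cl$sample <- s
    cl
  }))
  if (is.null(all_cl) || nrow(all_cl) == 0L) {
    out <- data.frame(consensus_id = integer(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
    class(out) <- c("consensus_clusters", "data.frame")
    return(out)
  }
  gr <- clusters_granges(all_cl)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L)
  hit <- GenomicRanges::findOverlaps(gr, merged)
  cons_of <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  out <- data.frame(consensus_id = seq_along(merged),
                    chrom = as.character(GenomicRanges::seqnames(merged)),
                    strand = as.character(GenomicRanges::strand(merged)),
                    start = GenomicRanges::start(merged),
                    end = GenomicRanges::end(merged),
                    stringsAsFactors = FALSE)
  for (s in samples) {
    tpm <- numeric(nrow(out))
    dom <- rep(NA_integer_, nrow(out))
    sel <- all_cl$sample == s
    if (any(sel)) {
      idx <- cons_of[sel]
      tpm_s <- all_cl$total_tpm[sel]
      agg <- tapply(tpm_s, idx, sum)
      tpm[as.integer(names(agg))] <- as.numeric(agg)
      # dominant of the contributing cluster with highest dominant expression
      dtpm <- all_cl$dominant_tpm[sel]
      dpos <- all_cl$dominant_pos[sel]
      for (k in unique(idx)) {
        in_k <- idx == k
        dom[k] <- dpos[in_k][which.max(dtpm[in_k])]
      }
    }
    out[[paste0("tpm_", s)]] <- tpm
    out[[paste0("dom_", s)]] <- dom
  }
  class(out) <- c("consensus_clusters", "data.frame")
  out
}

#' Annotate tag clusters with genomic location categories
#'
#' Assigns each cluster exactly one of `promoter`, `5'UTR`, `exon`,
#' `intron`, `antisense`, `intergenic`, using the precedence
#' promoter > 5'UTR > exon > intron > antisense > intergenic. The promoter
#' category is a strand-aware window around each annotated transcript start
#' (default -500..+100 bp).
#'
#' @param clusters a [cluster_ctss()] result (or compatible `data.frame`).
#' @param annotation list with element `transcripts` (`data.frame` with
#'   `chrom`, `start`, `end`, `strand`) and optional elements `exons` and
#'   `utr5` (same columns).
#' @param promoter_window length-2 integer window around the transcript
#'   start, in TSS-relative coordinates (default `c(-500, 100)`).
#' @return Character vector of categories, one per cluster.
#' @export
annotate_location <- function(clusters, annotation,
                              promoter_window = c(-500, 100)) {
  stopifnot(is.list(annotation), !is.null(annotation$transcripts))
  tx <- annotation$transcripts
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(tx)))
  if (nrow(clusters) == 0L) return(character(0))
  unknown <- setdiff(unique(clusters$chrom), unique(tx$chrom))
  if (length(unknown)) {
    stop("chromosome(s) absent from annotation: ",
         paste(unknown, collapse = ", "))
  }
  cl_gr <- clusters_granges(clusters)
  tx_gr <- GenomicRanges::GRanges(tx$chrom, IRanges::IRanges(tx$start, tx$end),
                                  strand = tx$strand)
  tss <- ifelse(tx$strand == "+", tx$start, tx$end)
  prom_start <- ifelse(tx$strand == "+", tss + promoter_window[1],
                       tss - promoter_window[2])
  prom_end <- ifelse(tx$strand == "+", tss + promoter_window[2],
                     tss - promoter_window[1])
  prom_gr <- GenomicRanges::GRanges(tx$chrom,
                                    IRanges::IRanges(pmax(prom_start, 1L),
                                                     prom_end),
                                    strand = tx$strand)
  overlaps_any <- function(query, subject, ignore_strand = FALSE) {
    if (length(subject) == 0L) return(logical(length(query)))
    IRanges::overlapsAny(query, subject, ignore.strand = ignore_strand)
  }
  df_gr <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                           strand = df$strand)
  }
  in_prom <- overlaps_any(cl_gr, prom_gr)
  in_utr5 <- overlaps_any(cl_gr, df_gr(annotation$utr5))
  in_exon <- overlaps_any(cl_gr, df_gr(annotation$exons))
  in_tx <- overlaps_any(cl_gr, tx_gr)
  anti_gr <- tx_gr
  GenomicRanges::strand(anti_gr) <- ifelse(tx$strand == "+", "-", "+")
  in_anti <- overlaps_any(cl_gr, anti_gr)
  out <- rep("intergenic", nrow(clusters))
  out[in_anti] <- "antisense"
  out[in_tx] <- "intron"
  out[in_exon] <- "exon"
  out[in_utr5] <- "5'UTR"
  out[in_prom] <- "promoter"
  out
}

#' Subsample a CTSS library without replacement
#'
#' Draws tags without replacement across CTSSs (multivariate
#' hypergeometric), emulating the loss of library complexity at lower
#' sequencing depth or input amount. Records whose subsampled count reaches
#' zero are dropped.
#'
#' @param table a [ctss_table()].
#' @param n_tags number of tags to retain (mutually exclusive with
#'   `fraction`).
#' @param fraction fraction of tags to retain, in (0, 1].
#' @param seed RNG seed.
#' @return A [ctss_table()] whose counts total `n_tags`.
#' @export
subsample_library <- function(table, n_tags = NULL, fraction = NULL,
                              seed = 1L) {
  assert_ctss(table)
  total <- sum(table$count)
  if (is.null(n_tags)) {
    if (is.null(fraction)) stop("give n_tags or fraction")
    if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
    n_tags <- round(fraction * total)
  }
  if (n_tags > total) stop("n_tags exceeds library total")
  if (n_tags == total) return(ctss_table(table$chrom, table$pos,
                                         table$strand, table$count))
  new_counts <- with_seed(seed, draw_without_replacement(table$count, n_tags))
  keep <- new_counts > 0
  ctss_table(table$chrom[keep], table$pos[keep], table$strand[keep],
             new_counts[keep])
}

# multivariate hypergeometric draw: n tags from categories with counts k
draw_without_replacement <- function(k, n) {
  idx <- rep.int(seq_along(k), k)
  taken <- sample(idx, n, replace = FALSE)
  tabulate(taken, nbins = length(k))
}

#' Export tag clusters as BED12
#'
#' `thickStart`/`thickEnd` carry the interquantile region, the name column
#' the dominant CTSS position, and the score the cluster expression scaled
#' to 0-1000.
#'
#' @param clusters a [cluster_ctss()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clusters_bed <- function(clusters, path) {
  if (nrow(clusters)) {
    score <- round(1000 * clusters$total_tpm / max(clusters$total_tpm))
  } else score <- integer()
  bed <- data.frame(chrom = clusters$chrom, start = clusters$start - 1L,
                    end = clusters$end,
                    name = paste0("dom:", clusters$dominant_pos),
                    score = score, strand = clusters$strand,
                    thickStart = clusters$q_low_pos - 1L,
                    thickEnd = clusters$q_high_pos,
                    itemRgb = 0, blockCount = 1,
                    blockSizes = clusters$end - clusters$start + 1L,
                    blockStarts = 0)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
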