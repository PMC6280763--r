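# Promoter-architecture sequence analysis: initiator composition at CTSSs,
# positional dinucleotide density matrices, PWM scanning (TATA-box), WW
# dinucleotide periodicity downstream of the dominant TSS, and overlap /
# coverage overlays of external interval tracks.

# genome accessor: accept a named DNAStringSet or named character vector
genome_strings <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else {
    stopifnot(is.character(genome), !is.null(names(genome)))
    genome
  }
}

revcomp <- function(s) {
  vapply(s, function(x) {
    if (is.na(x)) return(NA_character_)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# strand-oriented sequence for offsets from..to around a center position:
# offset o maps to genomic center+o on '+' and center-o on '-'; the result
# reads 5'->3' on the given strand. Out-of-bounds windows return NA.
oriented_window <- function(seqs, chrom, center, strand, from, to) {
  s <- seqs[[chrom]]
  if (is.null(s)) return(NA_character_)
  L <- nchar(s)
  if (strand == "+") {
    a <- center + from; b <- center + to
    if (a < 1 || b > L) return(NA_character_)
    substr(s, a, b)
  } else {
    a <- center - to; b <- center - from
    if (a < 1 || b > L) return(NA_character_)
    revcomp(substr(s, a, b))
  }
}

# expand a 2-letter IUPAC pattern into its dinucleotide set
iupac_dinucs <- function(pattern) {
  stopifnot(nchar(pattern) == 2L)
  tab <- list(A = "A", C = "C", G = "G", T = "T", W = c("A", "T"),
              S = c("C", "G"), R = c("A", "G"), Y = c("C", "T"),
              K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  parts <- strsplit(toupper(pattern), "")[[1]]
  if (!all(parts %in% names(tab))) stop("unknown IUPAC code in: ", pattern)
  as.vector(outer(tab[[parts[1]]], tab[[parts[2]]], paste0))
}

#' Base and initiator-dinucleotide composition at CTSSs
#'
#' Reports the nucleotide frequencies at the +1 position (the CTSS itself)
#' and the dinucleotide frequencies over [-1, +1], where +1 is the
#' identified CTSS. Minus-strand sequences are reverse-complemented before
#' counting, so a minus-strand CTSS over plus-strand genome "TG" counts as
#' initiator "CA". CTSSs at chromosome edges are excluded and counted.
#'
#' @param x a [ctss_table()] (all CTSSs) or a [cluster_ctss()] result
#'   (dominant CTSSs only).
#' @param genome named `DNAStringSet` or named character vector of
#'   chromosome sequences.
#' @return List with `base_freq` (named, sums to 1), `dinuc_freq` (named,
#'   sums to 1), `n_used`, `n_excluded`.
#' @export
ctss_composition <- function(x, genome) {
  seqs <- genome_strings(genome)
  if (inherits(x, "tag_clusters")) {
    chrom <- x$chrom; pos <- x$dominant_pos; strand <- x$strand
  } else {
    assert_ctss(x)
    chrom <- x$chrom; pos <- x$pos; strand <- x$strand
  }
  dinucs <- vapply(seq_along(pos), function(i) {
    oriented_window(seqs, chrom[i], pos[i], strand[i], -1L, 0L)
  }, character(1))
  excluded <- is.na(dinucs)
  if (any(excluded)) {
    warning(sum(excluded), " CTSS(s) at chromosome edge excluded")
  }
  dinucs <- toupper(dinucs[!excluded])
  base1 <- substr(dinucs, 2, 2)
  norm_table <- function(v, levels) {
    t <- table(factor(v, levels = levels))
    stats::setNames(as.numeric(t) / length(v), levels)
  }
  list(base_freq = norm_table(base1, c("A", "C", "G", "T")),
       dinuc_freq = norm_table(dinucs,
                               as.vector(outer(c("A", "C", "G", "T"),
                                               c("A", "C", "G", "T"),
                                               paste0))),
       n_used = length(dinucs), n_excluded = sum(excluded))
}

#' Positional dinucleotide density matrix around dominant CTSSs
#'
#' One row per tag cluster (ordered by IQ-width, sharpest on top), one
#' column per offset from the dominant CTSS (-flank..+flank, oriented
#' 5'-to-3' on the strand). A cell is 1 when the dinucleotide starting at
#' that offset matches `pattern` (a 2-letter IUPAC code: `"TA"`, `"GC"`,
#' `"WW"` = AA/AT/TA/TT, `"SS"`, ...), optionally smoothed by a positional
#' moving average. Rows whose window runs off the chromosome are dropped
#' and counted in attribute `"n_dropped"`.
#'
#' @param clusters a [cluster_ctss()] result.
#' @param genome named sequences.
#' @param pattern 2-letter IUPAC dinucleotide pattern.
#' @param flank half-width in bp (default 1000).
#' @param smooth width of the positional moving average in bp; 0 or 1
#'   disables smoothing (default 0, i.e. raw 0/1 indicators).
#' @return Numeric matrix (#clusters x 2*flank+1), columns named by offset,
#'   with attributes `iq_width` (per row) and `n_dropped`.
#' @export
dinuc_density_matrix <- function(clusters, genome, pattern = "TA",
                                 flank = 1000, smooth = 0) {
  seqs <- genome_strings(genome)
  targets <- iupac_dinucs(pattern)
  cl <- as.data.frame(clusters)
  cl <- cl[order(cl$iq_width), , drop = FALSE]
  offs <- -flank:flank
  rows <- lapply(seq_len(nrow(cl)), function(i) {
    # need flank+1 downstream bases so the dinucleotide at +flank is complete
    w <- oriented_window(seqs, cl$chrom[i], cl$dominant_pos[i], cl$strand[i],
                         -flank, flank + 1L)
    if (is.na(w)) return(NULL)
    di <- substring(toupper(w), seq_len(2L * flank + 1L),
                    seq_len(2L * flank + 1L) + 1L)
    as.numeric(di %in% targets)
  })
  keep <- !vapply(rows, is.null, logical(1))
  m <- do.call(rbind, rows[keep])
  if (is.null(m)) m <- matrix(numeric(0), 0, length(offs))
  colnames(m) <- offs
  if (smooth > 1 && nrow(m)) {
    k <- rep(1 / smooth, smooth)
    m <- t(apply(m, 1, function(r) stats::filter(r, k, sides = 2)))
    colnames(m) <- offs
  }
  attr(m, "iq_width") <- cl$iq_width[keep]
  attr(m, "n_dropped") <- sum(!keep)
  m
}

#' Build a log-odds position weight matrix
#'
#' Converts a 4 x L count (or frequency) matrix over A/C/G/T into log2-odds
#' scores against a background, with a pseudocount. The analytically
#' minimal and maximal achievable window scores are stored so that scanning
#' thresholds can be expressed as a fraction of the score range.
#'
#' @param counts 4 x L numeric matrix with rownames A, C, G, T.
#' @param background background base frequencies (default uniform).
#' @param pseudocount added to every count (default 0.5).
#' @return Object of class `pwm`: list with `matrix` (log2 odds),
#'   `background`, `min_score`, `max_score`, `length`.
#' @export
make_pwm <- function(counts, background = rep(0.25, 4), pseudocount = 0.5) {
  stopifnot(is.matrix(counts), nrow(counts) == 4L, ncol(counts) >= 2L)
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  background <- background / sum(background)
  freq <- sweep(counts + pseudocount, 2,
                colSums(counts + pseudocount), "/")
  lo <- log2(sweep(freq, 1, background, "/"))
  out <- list(matrix = lo, background = background,
              min_score = sum(apply(lo, 2, min)),
              max_score = sum(apply(lo, 2, max)),
              length = ncol(lo))
  class(out) <- "pwm"
  out
}

#' Bundled TATA-box position weight matrix
#'
#' An 8-position TATA-box matrix built from a synthetic consensus-derived
#' count matrix encoding TATAWAWR (the canonical TATA-box consensus), with
#' uniform background. It is a stand-in constructed for this package, not a
#' database matrix.
#'
#' @return A [make_pwm()] object.
#' @export
tata_pwm <- function() {
  counts <- matrix(c(
    # A   C   G   T     (one column per motif position, consensus TATAWAWR)
      5,  5,  5, 85,
     85,  5,  5,  5,
      5,  5,  5, 85,
     85,  5,  5,  5,
     45,  5,  5, 45,
     80,  5,  5, 10,
     45,  5,  5, 45,
     45,  5, 45,  5), nrow = 4,
    dimnames = list(c("A", "C", "G", "T"), NULL))
  make_pwm(counts)
}

score_pwm_window <- function(pwm, window) {
  b <- strsplit(toupper(window), "")[[1]]
  idx <- match(b, c("A", "C", "G", "T"))
  if (anyNA(idx)) return(NA_real_)  # ambiguous base: window skipped
  sum(pwm$matrix[cbind(idx, seq_along(idx))])
}

#' Scan promoter regions with a PWM
#'
#' For each tag cluster, scores every window whose start offset (relative
#' to the dominant CTSS, strand-oriented) lies in `search_window`, and
#' calls a hit when the best score reaches the threshold. With
#' `threshold_mode = "range"` (default) the threshold is
#' `min_score + threshold_fraction * (max_score - min_score)`; with
#' `"empirical"` it is the `threshold_fraction` quantile of all observed
#' window scores across clusters. Windows containing an ambiguous base are
#' skipped.
#'
#' @param clusters a [cluster_ctss()] result.
#' @param genome named sequences.
#' @param pwm a [make_pwm()] object (default [tata_pwm()]).
#' @param search_window start-offset range scanned, TSS-relative (default
#'   `c(-35, -25)`, the TATA-box location).
#' @param threshold_fraction fraction defining the hit threshold
#'   (default 0.8).
#' @param threshold_mode `"range"` or `"empirical"`.
#' @return List with `hit` (logical per cluster), `percent_hit`,
#'   `best_score`, `best_offset`, `threshold`.
#' @export
scan_pwm <- function(clusters, genome, pwm = tata_pwm(),
                     search_window = c(-35, -25), threshold_fraction = 0.8,
                     threshold_mode = c("range", "empirical")) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(inherits(pwm, "pwm"), threshold_fraction > 0,
            threshold_fraction <= 1)
  seqs <- genome_strings(genome)
  cl <- as.data.frame(clusters)
  L <- pwm$length
  starts <- search_window[1]:search_window[2]
  best_score <- rep(NA_real_, nrow(cl))
  best_offset <- rep(NA_integer_, nrow(cl))
  for (i in seq_len(nrow(cl))) {
    w <- oriented_window(seqs, cl$chrom[i], cl$dominant_pos[i], cl$strand[i],
                         search_window[1], search_window[2] + L - 1L)
    if (is.na(w)) next
    sc <- vapply(seq_along(starts), function(j) {
      score_pwm_window(pwm, substr(w, j, j + L - 1L))
    }, numeric(1))
    if (all(is.na(sc))) next
    best_score[i] <- max(sc, na.rm = TRUE)
    best_offset[i] <- starts[which.max(sc)]
  }
  threshold <- if (threshold_mode == "range") {
    pwm$min_score + threshold_fraction * (pwm$max_score - pwm$min_score)
  } else {
    stats::quantile(best_score, threshold_fraction, na.rm = TRUE,
                    names = FALSE)
  }
  hit <- !is.na(best_score) & best_score >= threshold
  list(hit = hit, percent_hit = 100 * mean(hit),
       best_score = best_score, best_offset = best_offset,
       threshold = threshold)
}

#' WW dinucleotide periodicity downstream of the dominant TSS
#'
#' Averages the WW (AA/AT/TA/TT) dinucleotide indicator over a downstream
#' region across (typically broad) tag clusters, removes a linear trend,
#' and estimates the dominant period from the power spectrum evaluated on a
#' fine period grid. A ~10.5-bp period reflects the rotational positioning
#' of the +1 nucleosome. The control mode aligns each cluster on a randomly
#' chosen member CTSS instead of the dominant one, which attenuates the
#' phased signal.
#'
#' @param clusters a [cluster_ctss()] result (pass broad clusters for the
#'   nucleosome-phasing use case).
#' @param genome named sequences.
#' @param region downstream offset range analyzed (default `c(1, 150)`).
#' @param period_range period search range in bp (default `c(5, 20)`).
#' @param align `"dominant"` (default) or `"random"` (control).
#' @param seed RNG seed for the random-alignment control.
#' @return Object of class `period_estimate`: `period` (bp), `amplitude`
#'   (spectral power at the dominant period), `peak_to_median` (ratio of
#'   peak power to median grid power), `profile`, `periods`, `power`,
#'   `n_clusters`.
#' @export
ww_periodicity <- function(clusters, genome, region = c(1, 150),
                           period_range = c(5, 20),
                           align = c("dominant", "random"), seed = 1L) {
  align <- match.arg(align)
  n_off <- region[2] - region[1] + 1L
  if (n_off < 2 * period_range[2]) {
    stop("region shorter than two periods of interest")
  }
  seqs <- genome_strings(genome)
  cl <- as.data.frame(clusters)
  centers <- cl$dominant_pos
  if (align == "random") {
    members <- attr(clusters, "members")
    if (is.null(members)) stop("random alignment needs cluster members")
    centers <- with_seed(seed, vapply(cl$cluster_id, function(id) {
      p <- members$pos[members$cluster_id == id]
      p[sample.int(length(p), 1L)]
    }, numeric(1)))
  }
  ww <- c("AA", "AT", "TA", "TT")
  rows <- lapply(seq_len(nrow(cl)), function(i) {
    w <- oriented_window(seqs, cl$chrom[i], centers[i], cl$strand[i],
                         region[1], region[2] + 1L)
    if (is.na(w)) return(NULL)
    di <- substring(toupper(w), seq_len(n_off), seq_len(n_off) + 1L)
    as.numeric(di %in% ww)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no usable clusters")
  profile <- colMeans(do.call(rbind, rows))
  t_off <- seq_len(n_off)
  detr <- stats::residuals(stats::lm(profile ~ t_off))
  # power on a uniform frequency grid over the period band, smoothed to the
  # Rayleigh resolution (1/n) so that peak_to_median is a stable
  # significance measure rather than the max of an oversampled raw
  # periodogram
  freqs <- seq(1 / period_range[2], 1 / period_range[1], length.out = 600)
  power <- vapply(freqs, function(f) {
    Mod(sum(detr * exp(-2i * pi * f * t_off)))^2 / n_off
  }, numeric(1))
  i_max <- which.max(power)
  periods <- 1 / freqs
  # significance of the peak: compare against a spectrum smoothed over ~5
  # Rayleigh widths (5/n in frequency), which tames the maximum of the
  # oversampled raw periodogram under white noise while leaving a genuine
  # phased peak far above the spectral median
  k <- max(3L, round((5 / n_off) / (freqs[2] - freqs[1])))
  smoothed <- as.numeric(stats::filter(power, rep(1 / k, k), sides = 2,
                                       circular = TRUE))
  out <- list(period = periods[i_max], amplitude = power[i_max],
              peak_to_median = smoothed[i_max] / stats::median(smoothed),
              profile = stats::setNames(profile, region[1]:region[2]),
              periods = periods, power = power, n_clusters = length(rows))
  class(out) <- "period_estimate"
  out
}

#' @export
print.period_estimate <- function(x, ...) {
  cat(sprintf(
    "WW periodicity: %.2f bp (power %.3g, %.1fx median) over %d clusters\n",
    x$period, x$amplitude, x$peak_to_median, x$n_clusters))
  invisible(x)
}

#' Overlay external intervals or coverage on promoter windows
#'
#' For each tag cluster, tests whether the window [-flank, +flank] around
#' its dominant CTSS intersects any supplied interval (e.g. CpG islands),
#' and averages a per-base coverage track over strand-oriented offsets.
#' Results are reported separately for sharp and broad clusters.
#'
#' @param clusters a [cluster_ctss()] result.
#' @param intervals `data.frame` with `chrom`, `start`, `end` (1-based
#'   inclusive; strand ignored) or a `GRanges`. May be `NULL`.
#' @param coverage optional bedGraph-like `data.frame` with `chrom`,
#'   `start`, `end`, `value` (sorted internally if needed, with a warning).
#' @param flank window half-width in bp (default 500).
#' @return List with elements `overall`, `sharp`, `broad`, each holding
#'   `overlap_fraction`, `n`, and (when coverage is given) `profile`
#'   (average coverage by offset).
#' @export
interval_overlay <- function(clusters, intervals = NULL, coverage = NULL,
                             flank = 500) {
  cl <- as.data.frame(clusters)
  win <- GenomicRanges::GRanges(
    cl$chrom, IRanges::IRanges(pmax(cl$dominant_pos - flank, 1L),
                               cl$dominant_pos + flank))
  flag <- logical(nrow(cl))
  if (!is.null(intervals)) {
    iv <- if (inherits(intervals, "GRanges")) intervals else {
      GenomicRanges::GRanges(intervals$chrom,
                             IRanges::IRanges(intervals$start, intervals$end))
    }
    if (length(iv)) {
      flag <- IRanges::overlapsAny(win, iv, ignore.strand = TRUE)
    }
  }
  profiles <- NULL
  if (!is.null(coverage)) {
    stopifnot(all(c("chrom", "start", "end", "value") %in% names(coverage)))
    o <- order(coverage$chrom, coverage$start)
    if (!identical(o, seq_len(nrow(coverage)))) {
      warning("coverage was unsorted; sorted internally")
      coverage <- coverage[o, , drop = FALSE]
    }
    cov_gr <- GenomicRanges::GRanges(
      coverage$chrom, IRanges::IRanges(coverage$start, coverage$end))
    offs <- -flank:flank
    profiles <- matrix(0, nrow(cl), length(offs), dimnames = list(NULL, offs))
    for (i in seq_len(nrow(cl))) {
      sgn <- if (cl$strand[i] == "+") 1L else -1L
      gpos <- cl$dominant_pos[i] + sgn * offs
      ok <- gpos >= 1L
      pos_gr <- GenomicRanges::GRanges(cl$chrom[i],
                                       IRanges::IRanges(gpos[ok], gpos[ok]))
      hit <- GenomicRanges::findOverlaps(pos_gr, cov_gr)
      v <- numeric(sum(ok))
      qh <- S4Vectors::queryHits(hit)
      v[qh] <- coverage$value[S4Vectors::subjectHits(hit)]
      profiles[i, ok] <- v
    }
  }
  summarize_set <- function(sel) {
    out <- list(overlap_fraction = if (any(sel)) mean(flag[sel]) else 0,
                n = sum(sel))
    if (!is.null(profiles)) {
      out$profile <- if (any(sel)) {
        colMeans(profiles[sel, , drop = FALSE])
      } else stats::setNames(numeric(2 * flank + 1), -flank:flank)
    }
    out
  }
  list(overall = summarize_set(rep(TRUE, nrow(cl))),
       sharp = summarize_set(cl$shape_class == "sharp"),
       broad = summarize_set(cl$shape_class == "broad"))
}
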