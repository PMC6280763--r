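# Synthetic-data generator: genomes with sharp and broad promoters,
# power-law-expressed CTSS libraries, library degradation (subsampling,
# PCR duplication, optional 5'-G capture bias), carrier contamination, and
# two-condition experiments with implanted TSS switching - all with full
# ground truth, so every pipeline stage is testable offline.

random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

# genomic indices and bases for writing string s at strand-oriented
# offsets off..off+nchar(s)-1 around dom (minus strand: complemented, laid
# out right-to-left). Returned as (idx, base) pairs so a caller can batch
# many implants into one vector assignment (later pairs override earlier).
implant_edit <- function(dom, strand, off, s) {
  b <- strsplit(s, "")[[1]]
  if (strand == "+") {
    list(idx = dom + off + seq_along(b) - 1L, base = b)
  } else {
    list(idx = dom - off - seq_along(b) + 1L,
         base = chartr("ACGT", "TGCA", b))
  }
}

#' Generate a synthetic genome with sharp and broad promoters
#'
#' Builds one chromosome of i.i.d. background sequence at the configured GC
#' content and implants `n_promoters` promoters of two architectural
#' classes. Sharp promoters carry a TATAAA element at -30 and a CA
#' initiator step at [-1, +1] with a small positional spread (<= 3 bp).
#' Broad promoters carry a GC-elevated island around the TSS, a CA
#' initiator, a wider spread (Gaussian sigma drawn from
#' `broad_sigma_range`), and WW dinucleotides phased every ~10.5 bp over
#' +1..+150 downstream of the dominant position (the rotational signature
#' of a positioned +1 nucleosome).
#'
#' @param n_promoters number of promoters (default 500).
#' @param sharp_fraction fraction of sharp promoters (default 0.5).
#' @param chrom_length chromosome length; computed from the promoter count
#'   when `NULL`. Too small a value for the promoters to fit without
#'   overlap is an error.
#' @param gc_background background GC content (default 0.40).
#' @param gc_island broad-promoter island GC content (default 0.60).
#' @param island_window island extent in TSS-relative offsets (default
#'   `c(-100, 250)`).
#' @param ww_period WW phasing period in bp (default 10.5).
#' @param ww_prob probability that a phased offset receives a WW
#'   dinucleotide (default 0.9).
#' @param broad_sigma_range range of broad-promoter spread sigmas in bp
#'   (default `c(5, 30)`).
#' @param spacing distance between consecutive promoter anchors in bp
#'   (default 2500).
#' @param seed RNG seed.
#' @return Object of class `synthetic_truth`: list with `genome` (named
#'   character vector of chromosome sequences), `truth` (`data.frame` with
#'   `promoter_id`, `chrom`, `strand`, `dominant_pos`, `class`, `spread`,
#'   `initiator`, `tata`, `island_start`, `island_end`), and `params`.
#' @export
generate_genome <- function(n_promoters = 500, sharp_fraction = 0.5,
                            chrom_length = NULL, gc_background = 0.40,
                            gc_island = 0.60, island_window = c(-100, 250),
                            ww_period = 10.5, ww_prob = 0.9,
                            broad_sigma_range = c(5, 30), spacing = 2500,
                            seed = 1L) {
  stopifnot(n_promoters >= 1, sharp_fraction >= 0, sharp_fraction <= 1)
  margin <- 2000L
  need <- margin + n_promoters * spacing + margin
  if (is.null(chrom_length)) chrom_length <- need
  if (chrom_length < need) {
    stop("chromosome too short for ", n_promoters,
         " promoters at spacing ", spacing, " (need ", need, " bp)")
  }
  with_seed(seed, {
    chars <- random_dna(chrom_length, gc_background)
    n_sharp <- round(sharp_fraction * n_promoters)
    cls <- sample(c(rep("sharp", n_sharp),
                    rep("broad", n_promoters - n_sharp)))
    strand <- sample(c("+", "-"), n_promoters, replace = TRUE)
    dom <- margin + (seq_len(n_promoters) - 1L) * spacing +
      sample(0:200, n_promoters, replace = TRUE)
    spread <- ifelse(cls == "sharp",
                     sample(1:3, n_promoters, replace = TRUE),
                     round(stats::runif(n_promoters, broad_sigma_range[1],
                                        broad_sigma_range[2])))
    island_start <- island_end <- rep(NA_integer_, n_promoters)
    phase_offsets <- unique(round(ww_period * seq_len(
      floor(150 / ww_period))))
    edits <- vector("list", n_promoters)
    for (i in seq_len(n_promoters)) {
      e <- list()
      if (cls[i] == "broad") {
        # GC-elevated island (replaces background over the island window)
        iw <- island_window[1]:island_window[2]
        isl <- random_dna(length(iw), gc_island)
        e[[length(e) + 1L]] <- implant_edit(dom[i], strand[i],
                                            island_window[1],
                                            paste(isl, collapse = ""))
        g1 <- if (strand[i] == "+") dom[i] + island_window[1] else
          dom[i] - island_window[2]
        g2 <- if (strand[i] == "+") dom[i] + island_window[2] else
          dom[i] - island_window[1]
        island_start[i] <- g1; island_end[i] <- g2
        # 10.5-bp WW phasing downstream of the dominant position
        for (off in phase_offsets) {
          if (stats::runif(1) < ww_prob) {
            e[[length(e) + 1L]] <- implant_edit(
              dom[i], strand[i], off, sample(c("AA", "AT", "TA", "TT"), 1L))
          }
        }
      } else {
        e[[length(e) + 1L]] <- implant_edit(dom[i], strand[i], -30L,
                                            "TATAAA")
      }
      e[[length(e) + 1L]] <- implant_edit(dom[i], strand[i], -1L, "CA")
      edits[[i]] <- list(idx = unlist(lapply(e, `[[`, "idx")),
                         base = unlist(lapply(e, `[[`, "base")))
    }
    all_idx <- unlist(lapply(edits, `[[`, "idx"))
    all_base <- unlist(lapply(edits, `[[`, "base"))
    chars[all_idx] <- all_base  # duplicated indices: the last write wins
    truth <- data.frame(promoter_id = seq_len(n_promoters), chrom = "chrS",
                        strand = strand, dominant_pos = dom, class = cls,
                        spread = spread, initiator = "CA",
                        tata = cls == "sharp",
                        island_start = island_start,
                        island_end = island_end,
                        stringsAsFactors = FALSE)
    out <- list(genome = c(chrS = paste(chars, collapse = "")),
                truth = truth,
                params = list(n_promoters = n_promoters,
                              sharp_fraction = sharp_fraction,
                              gc_background = gc_background,
                              gc_island = gc_island,
                              island_window = island_window,
                              ww_period = ww_period, ww_prob = ww_prob,
                              broad_sigma_range = broad_sigma_range,
                              spacing = spacing, seed = seed))
    class(out) <- "synthetic_truth"
    out
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic truth: %d promoters (%d sharp, %d broad) on %d chrom(s)\n",
    nrow(x$truth), sum(x$truth$class == "sharp"),
    sum(x$truth$class == "broad"), length(x$genome)))
  invisible(x)
}

# per-promoter distribution over TSS-relative offsets: a point mass at the
# dominant position plus a discretized Gaussian of the promoter's spread.
# Sharp promoters put >= 90% of their mass on the dominant CTSS; broad
# promoters keep a distinguishable dominant position (real broad promoters
# have one) on top of the wide envelope.
promoter_offset_probs <- function(class, spread, sharp_dominant_share = 0.90,
                                  broad_dominant_share = 0.25) {
  if (class == "sharp") {
    offs <- -spread:spread
    p <- rep((1 - sharp_dominant_share) / (length(offs) - 1L), length(offs))
    p[offs == 0L] <- sharp_dominant_share
  } else {
    K <- ceiling(3 * spread)
    offs <- -K:K
    g <- stats::dnorm(offs, 0, spread)
    g <- g / sum(g)
    p <- (1 - broad_dominant_share) * g
    p[offs == 0L] <- p[offs == 0L] + broad_dominant_share
  }
  list(offsets = offs, probs = p)
}

#' Simulate a CTSS library from a synthetic truth
#'
#' Draws per-promoter expression weights from a power law with the
#' configured reverse-cumulative slope, distributes `depth_tags` tags over
#' promoters (multinomial), and scatters each promoter's tags over
#' positions around its dominant CTSS: sharp promoters concentrate >= 90%
#' of their mass on the dominant position, broad promoters follow a wide
#' discretized-Gaussian envelope on top of a distinguishable dominant
#' share.
#'
#' @param truth a [generate_genome()] result (or its `truth` data.frame).
#' @param depth_tags total tag count (default 1e6).
#' @param slope power-law slope of the promoter expression weights
#'   (default 1.25).
#' @param weights optional per-promoter weights overriding the power-law
#'   draw.
#' @param dominant_override optional integer vector of per-promoter
#'   dominant positions replacing `truth$dominant_pos` (used for implanted
#'   TSS switching).
#' @param seed RNG seed.
#' @return A [ctss_table()] totalling exactly `depth_tags` tags, with the
#'   drawn weights attached as attribute `"weights"`.
#' @export
simulate_library <- function(truth, depth_tags = 1e6, slope = 1.25,
                             weights = NULL, dominant_override = NULL,
                             seed = 1L) {
  tr <- if (inherits(truth, "synthetic_truth")) truth$truth else truth
  n <- nrow(tr)
  if (depth_tags < n) stop("depth must be at least the number of promoters")
  dom <- if (is.null(dominant_override)) tr$dominant_pos else {
    stopifnot(length(dominant_override) == n)
    dominant_override
  }
  with_seed(seed, {
    if (is.null(weights)) {
      # Pareto draw: P(W >= w) = w^-slope
      weights <- (1 - stats::runif(n))^(-1 / slope)
    }
    n_per <- as.vector(stats::rmultinom(1, depth_tags,
                                        weights / sum(weights)))
    chrom <- pos <- strand <- cnt <- vector("list", n)
    for (i in seq_len(n)) {
      if (n_per[i] == 0L) next
      d <- promoter_offset_probs(tr$class[i], tr$spread[i])
      k <- as.vector(stats::rmultinom(1, n_per[i], d$probs))
      nz <- k > 0L
      sgn <- if (tr$strand[i] == "+") 1L else -1L
      pos[[i]] <- dom[i] + sgn * d$offsets[nz]
      cnt[[i]] <- k[nz]
      chrom[[i]] <- rep(tr$chrom[i], sum(nz))
      strand[[i]] <- rep(tr$strand[i], sum(nz))
    }
    df <- data.frame(chrom = unlist(chrom), pos = unlist(pos),
                     strand = unlist(strand), count = unlist(cnt),
                     stringsAsFactors = FALSE)
    agg <- stats::aggregate(count ~ chrom + pos + strand, df, sum)
    out <- ctss_table(agg$chrom, agg$pos, agg$strand, agg$count)
    attr(out, "weights") <- weights
    out
  })
}

#' Simulate library degradation
#'
#' Emulates a low-input, low-complexity library: molecules are subsampled
#' without replacement (optionally with a 5'-G capture bias), each survivor
#' is amplified through `pcr_cycles` PCR cycles (per-cycle duplication
#' probability `pcr_efficiency`), and the amplified pool is resampled to
#' the original depth. Incomplete CTSS detection in the result produces
#' artificially sharp tag clusters, the signature of degraded libraries.
#'
#' @param table a [ctss_table()].
#' @param subsample_fraction fraction of molecules surviving, in (0, 1].
#' @param pcr_cycles number of PCR cycles (default 0).
#' @param pcr_efficiency per-cycle duplication probability (default 0.8).
#' @param g_bias in [0, 1): capture probability of non-G-initiating tags is
#'   multiplied by `1 - g_bias` (requires `genome`).
#' @param genome named sequences (only needed when `g_bias > 0`).
#' @param seed RNG seed.
#' @return A [ctss_table()] at the original total depth (when
#'   `pcr_cycles > 0`) or at the subsampled depth.
#' @export
simulate_degradation <- function(table, subsample_fraction, pcr_cycles = 0,
                                 pcr_efficiency = 0.8, g_bias = 0,
                                 genome = NULL, seed = 1L) {
  assert_ctss(table)
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    stop("subsample_fraction must be in (0, 1]")
  }
  if (pcr_efficiency < 0 || pcr_efficiency > 1) {
    stop("pcr_efficiency must be in [0, 1]")
  }
  if (g_bias < 0 || g_bias >= 1) stop("g_bias must be in [0, 1)")
  if (g_bias > 0 && is.null(genome)) stop("g_bias needs the genome")
  total <- sum(table$count)
  n_keep <- max(1L, round(subsample_fraction * total))
  if (subsample_fraction == 1 && pcr_cycles == 0 && g_bias == 0) {
    return(ctss_table(table$chrom, table$pos, table$strand, table$count))
  }
  with_seed(seed, {
    idx <- rep.int(seq_len(nrow(table)), table$count)
    if (g_bias > 0) {
      seqs <- genome_strings(genome)
      plus1 <- vapply(seq_len(nrow(table)), function(i) {
        oriented_window(seqs, table$chrom[i], table$pos[i],
                        table$strand[i], 0L, 0L)
      }, character(1))
      w_rec <- ifelse(plus1 %in% "G", 1, 1 - g_bias)
      # weighted sampling without replacement (exponential-key trick)
      key <- stats::rexp(length(idx)) / w_rec[idx]
      surv <- idx[order(key)[seq_len(n_keep)]]
    } else {
      surv <- sample(idx, n_keep, replace = FALSE)
    }
    if (pcr_cycles > 0) {
      copies <- rep(1L, length(surv))
      for (cyc in seq_len(pcr_cycles)) {
        copies <- copies + stats::rbinom(length(copies), copies,
                                         pcr_efficiency)
      }
      resampled <- as.vector(stats::rmultinom(1, total,
                                              copies / sum(copies)))
      counts <- tapply(resampled, surv, sum)
    } else {
      counts <- table(surv)
    }
    rec <- as.integer(names(counts))
    ctss_table(table$chrom[rec], table$pos[rec], table$strand[rec],
               as.integer(counts))
  })
}

#' Spike carrier-derived tags into a library
#'
#' Appends tags originating from the carrier molecule (uniform positions
#' along the carrier sequence, on a dedicated `carrier` chromosome) so that
#' the carrier share of the combined library equals `leftover_fraction` up
#' to sampling error. Origin flags partition the table exactly.
#'
#' @param table a [ctss_table()].
#' @param design a [design_carrier()] result.
#' @param leftover_fraction carrier share of the combined total, in [0, 1).
#' @param seed RNG seed.
#' @return List with `table` (combined [ctss_table()]) and `carrier_origin`
#'   (logical, per combined row).
#' @export
spike_carrier <- function(table, design, leftover_fraction, seed = 1L) {
  assert_ctss(table)
  stopifnot(inherits(design, "carrier_design"))
  if (leftover_fraction < 0 || leftover_fraction >= 1) {
    stop("leftover_fraction must be in [0, 1)")
  }
  if (leftover_fraction == 0) {
    tab <- ctss_table(table$chrom, table$pos, table$strand, table$count)
    return(list(table = tab, carrier_origin = rep(FALSE, nrow(tab))))
  }
  total <- sum(table$count)
  n_c <- round(leftover_fraction / (1 - leftover_fraction) * total)
  L <- nchar(design$sequence)
  cpos <- with_seed(seed, sample.int(L, n_c, replace = TRUE))
  ctab <- table(cpos)
  comb <- rbind(
    data.frame(chrom = table$chrom, pos = table$pos, strand = table$strand,
               count = table$count, stringsAsFactors = FALSE),
    data.frame(chrom = "carrier", pos = as.integer(names(ctab)),
               strand = "+", count = as.integer(ctab),
               stringsAsFactors = FALSE))
  out <- ctss_table(comb$chrom, comb$pos, comb$strand, comb$count)
  list(table = out, carrier_origin = out$chrom == "carrier")
}

#' Generate a two-condition experiment with implanted TSS switching
#'
#' Splits the truth promoters into condition-A-specific, condition-B-
#' specific, switching, and ubiquitous sets. Specific promoters are
#' expressed `fold`-fold higher in their own condition. Switching promoters
#' initiate from two positions `switch_distance` bp apart within the same
#' promoter region, with the major/minor balance flipped between
#' conditions (share `1 - minor_share` at the condition's dominant
#' position), so the region's dominant CTSS moves by `switch_distance`
#' while signal remains at both positions - the signature of TSS switching
#' within a shared promoter. Ubiquitous promoters share weights across
#' conditions.
#'
#' For switch detection, build the cross-sample consensus at
#' promoter-region scale (e.g. `merge_consensus(..., max_gap = 150)`), so
#' both initiation sites of a switching promoter fall into one region.
#'
#' @param truth a [generate_genome()] result.
#' @param n_specific_a,n_specific_b,n_switch promoter counts per role.
#' @param switch_distance implanted dominant-CTSS shift in bp (>= 1).
#' @param depth_tags per-condition library depth (default 1e6).
#' @param fold expression fold-change of condition-specific promoters
#'   (default 10).
#' @param minor_share expression share of a switching promoter's
#'   non-dominant position (default 0.2).
#' @param slope power-law slope of the shared base weights (default 1.25).
#' @param seed RNG seed.
#' @return List with `table_a`, `table_b` ([ctss_table()]s), and `truth`
#'   (the input truth `data.frame` augmented with `role`, `dominant_a`,
#'   `dominant_b`).
#' @export
generate_two_conditions <- function(truth, n_specific_a = 50,
                                    n_specific_b = 50, n_switch = 20,
                                    switch_distance = 100, depth_tags = 1e6,
                                    fold = 10, minor_share = 0.2,
                                    slope = 1.25, seed = 1L) {
  if (switch_distance < 1) stop("switch_distance must be >= 1")
  stopifnot(minor_share >= 0, minor_share < 0.5)
  tr <- if (inherits(truth, "synthetic_truth")) truth$truth else truth
  n <- nrow(tr)
  if (n_specific_a + n_specific_b + n_switch > n) {
    stop("role counts exceed the number of promoters")
  }
  with_seed(seed, {
    roles <- rep("ubiquitous", n)
    pick <- sample.int(n, n_specific_a + n_specific_b + n_switch)
    roles[pick[seq_len(n_specific_a)]] <- "specific_a"
    roles[pick[n_specific_a + seq_len(n_specific_b)]] <- "specific_b"
    sw <- pick[n_specific_a + n_specific_b + seq_len(n_switch)]
    roles[sw] <- "switch"
    base_w <- (1 - stats::runif(n))^(-1 / slope)
    w_a <- base_w * ifelse(roles == "specific_a", fold, 1)
    w_b <- base_w * ifelse(roles == "specific_b", fold, 1)
    sgn <- ifelse(tr$strand == "+", 1L, -1L)
    dom_b <- ifelse(roles == "switch",
                    tr$dominant_pos + sgn * switch_distance,
                    tr$dominant_pos)
    # switching promoters get a second initiation site: one extra truth row
    # per switch promoter, holding the downstream position; weights carry
    # the major/minor split per condition
    ext <- tr[sw, , drop = FALSE]
    ext$dominant_pos <- as.integer(dom_b[sw])
    tr_ext <- rbind(tr, ext)
    w_a_ext <- c(replace(w_a, sw, w_a[sw] * (1 - minor_share)),
                 w_a[sw] * minor_share)
    w_b_ext <- c(replace(w_b, sw, w_b[sw] * minor_share),
                 w_b[sw] * (1 - minor_share))
    seeds <- sample.int(.Machine$integer.max, 2L)
    tab_a <- simulate_library(tr_ext, depth_tags, weights = w_a_ext,
                              seed = seeds[1])
    tab_b <- simulate_library(tr_ext, depth_tags, weights = w_b_ext,
                              seed = seeds[2])
    tr$role <- roles
    tr$dominant_a <- tr$dominant_pos
    tr$dominant_b <- as.integer(dom_b)
    list(table_a = tab_a, table_b = tab_b, truth = tr)
  })
}

#' Write a synthetic genome to FASTA and its truth record to JSON/BED
#'
#' @param truth a [generate_genome()] result.
#' @param fasta_path,json_path,bed_path output paths (any may be `NULL`).
#' @return Invisibly, the list of written paths.
#' @export
write_synthetic_truth <- function(truth, fasta_path = NULL, json_path = NULL,
                                  bed_path = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.null(fasta_path)) {
    x <- Biostrings::DNAStringSet(truth$genome)
    Biostrings::writeXStringSet(x, fasta_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(truth = truth$truth, params = truth$params),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bed_path)) {
    tr <- truth$truth
    bed <- data.frame(chrom = tr$chrom, start = tr$dominant_pos - 1L,
                      end = tr$dominant_pos,
                      name = paste0(tr$class, "_", tr$promoter_id),
                      score = 0, strand = tr$strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(list(fasta = fasta_path, json = json_path, bed = bed_path))
}
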