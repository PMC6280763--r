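# CTSS container, 5'-end extraction from alignments, mismatched-G
# correction, PCR read-pair deduplication, and TSV/BED serialization.

#' Construct a CTSS table
#'
#' A CTSS (CAGE tag-supported TSS) table records, for every unique
#' (chromosome, position, strand) 5'-end location, the number of CAGE tags
#' whose 5' end maps there. Positions are 1-based genomic coordinates.
#' Counts are raw tag counts; the `tpm` column holds normalized expression
#' (tags per million) and is absent until [normalize_power_law()] or
#' [normalize_tpm()] is applied.
#'
#' Rows with `count == 0` are dropped, duplicate keys are an error, and the
#' table is returned sorted by (chrom, pos, strand).
#'
#' @param chrom character chromosome names.
#' @param pos integer 1-based positions of tag 5' ends.
#' @param strand character, each `"+"` or `"-"`.
#' @param count non-negative integer tag counts.
#' @param tpm optional non-negative normalized expression values.
#' @return A `data.frame` of class `ctss_tbl` sorted by (chrom, pos, strand).
#' @examples
#' ctss_table(c("chr1", "chr1"), c(100L, 105L), c("+", "+"), c(3L, 1L))
#' @export
ctss_table <- function(chrom = character(), pos = integer(),
                       strand = character(), count = integer(), tpm = NULL) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(strand) == n, length(count) == n)
  if (!is.null(tpm)) stopifnot(length(tpm) == n)
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    stop("invalid strand value(s) at record(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  if (any(count < 0)) stop("negative counts are not allowed")
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = as.character(strand), count = as.numeric(count),
                   stringsAsFactors = FALSE)
  if (!is.null(tpm)) df$tpm <- as.numeric(tpm)
  df <- df[df$count > 0, , drop = FALSE]
  key <- paste(df$chrom, df$pos, df$strand)
  if (anyDuplicated(key)) stop("duplicate (chrom, pos, strand) keys")
  df <- df[order(df$chrom, df$pos, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ctss_tbl", "data.frame")
  df
}

#' @export
print.ctss_tbl <- function(x, ...) {
  cat(sprintf("CTSS table: %d positions, %s tags%s\n",
              nrow(x), format(sum(x$count), big.mark = ","),
              if ("tpm" %in% names(x)) ", normalized" else ""))
  NextMethod()
}

is_ctss_tbl <- function(x) {
  is.data.frame(x) && all(c("chrom", "pos", "strand", "count") %in% names(x))
}

assert_ctss <- function(x, normalized = FALSE) {
  if (!is_ctss_tbl(x)) stop("expected a CTSS table (chrom, pos, strand, count)")
  if (normalized && !"tpm" %in% names(x)) {
    stop("CTSS table must be normalized first (no 'tpm' column)")
  }
  invisible(x)
}

# expression column used by downstream analyses: tpm when present, else count
expr_col <- function(table) {
  if ("tpm" %in% names(table)) table$tpm else table$count
}

#' Extract CTSSs from aligned reads
#'
#' Collapses uniquely-mapped alignments to their 5' ends: for `+`-strand
#' reads the leftmost aligned base, for `-`-strand reads the rightmost. Each
#' unique (chrom, 5'-end, strand) becomes one CTSS whose count is the number
#' of contributing reads.
#'
#' @param alignments either a `data.frame` with columns `chrom`, `start`,
#'   `end` (1-based inclusive), `strand`, and optionally `mapq`, or a path to
#'   a BAM file (read via Rsamtools).
#' @param min_mapq alignments with mapping quality below this are treated as
#'   non-unique and excluded (default 20). Rows with `NA` mapq are kept.
#' @return A [ctss_table()].
#' @export
extract_ctss <- function(alignments, min_mapq = 20) {
  if (is.character(alignments) && length(alignments) == 1L) {
    alignments <- read_alignments_bam(alignments)
  }
  stopifnot(is.data.frame(alignments))
  req <- c("chrom", "start", "end", "strand")
  if (!all(req %in% names(alignments))) {
    stop("alignments need columns: ", paste(req, collapse = ", "))
  }
  if (nrow(alignments) == 0L) return(ctss_table())
  bad <- !alignments$strand %in% c("+", "-")
  if (any(bad)) {
    stop("unknown strand value at record(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  if ("mapq" %in% names(alignments)) {
    keep <- is.na(alignments$mapq) | alignments$mapq >= min_mapq
    alignments <- alignments[keep, , drop = FALSE]
  }
  if (nrow(alignments) == 0L) return(ctss_table())
  p5 <- ifelse(alignments$strand == "+", alignments$start, alignments$end)
  tab <- stats::aggregate(
    list(count = rep(1L, nrow(alignments))),
    by = list(chrom = alignments$chrom, pos = p5, strand = alignments$strand),
    FUN = sum)
  ctss_table(tab$chrom, tab$pos, tab$strand, tab$count)
}

read_alignments_bam <- function(path) {
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "mapq", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  if (length(b$pos) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(), mapq = integer()))
  }
  width <- GenomicAlignments_width(b$cigar)
  data.frame(chrom = as.character(b$rname), start = b$pos,
             end = b$pos + width - 1L, strand = as.character(b$strand),
             mapq = b$mapq, stringsAsFactors = FALSE)
}

# reference-consumed width from CIGAR (M/D/N/=/X advance the reference)
GenomicAlignments_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Correct template-free leading G nucleotides
#'
#' CAGE reverse transcription can add an extra G at the 5' end of the read,
#' complementary to the cap. Reads whose first base is a G that mismatches
#' the genome have their 5' end shifted one base toward 3'. Reads whose
#' first base is a G that *matches* the genome are shifted with probability
#' equal to the locally observed mismatched-G fraction at that (chrom, pos,
#' strand) site, because a genuine genomic G and a cap-derived G are
#' indistinguishable there.
#'
#' @param reads `data.frame` with columns `chrom`, `pos` (5'-end, 1-based),
#'   `strand`, `first_base` (read's first base), `g_mismatch` (logical; TRUE
#'   when the first base is a G that does not match the genome).
#' @param genome optional named `DNAStringSet` (or named character vector of
#'   sequences); when supplied, positions outside chromosome bounds raise an
#'   error naming the offending read.
#' @param seed integer seed for the probabilistic removal of matching Gs.
#' @return `reads` with corrected `pos` (and a logical `g_removed` column).
#' @export
correct_leading_g <- function(reads, genome = NULL, seed = 1L) {
  stopifnot(is.data.frame(reads))
  req <- c("chrom", "pos", "strand", "first_base", "g_mismatch")
  if (!all(req %in% names(reads))) {
    stop("reads need columns: ", paste(req, collapse = ", "))
  }
  if (nrow(reads) == 0L) {
    reads$g_removed <- logical(0)
    return(reads)
  }
  if (!is.null(genome)) {
    lens <- if (inherits(genome, "DNAStringSet")) {
      stats::setNames(Biostrings::width(genome), names(genome))
    } else {
      vapply(genome, nchar, integer(1))
    }
    bad <- reads$pos < 1L | reads$pos > lens[reads$chrom]
    bad[is.na(bad)] <- TRUE
    if (any(bad)) {
      stop("read(s) outside genome bounds: ",
           paste(utils::head(which(bad), 5L), collapse = ", "))
    }
  }
  is_g <- reads$first_base %in% c("G", "g")
  mism <- is_g & reads$g_mismatch
  match_g <- is_g & !reads$g_mismatch
  removed <- mism
  if (any(match_g)) {
    # per-site mismatched-G fraction among all G-first reads
    site <- paste(reads$chrom, reads$pos, reads$strand)
    g_sites <- site[is_g]
    frac <- tapply(mism[is_g], g_sites, mean)
    p <- as.numeric(frac[site[match_g]])
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    removed[match_g] <- stats::runif(sum(match_g)) < p
  }
  shift <- ifelse(reads$strand == "+", 1L, -1L)
  reads$pos <- reads$pos + ifelse(removed, shift, 0L)
  reads$g_removed <- removed
  reads
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# run expr with a seeded, isolated RNG stream
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  expr
}

#' Collapse PCR duplicates of paired-end reads
#'
#' Because reverse transcription primes with a random-hexamer primer, the
#' mate's 3' coordinate is effectively random per cDNA molecule: read pairs
#' identical in (chrom, 5'-end, strand, mate-end) are PCR duplicates and are
#' collapsed to one surviving pair. Pairs sharing a 5' end but differing in
#' mate end are independent molecules and are all kept.
#'
#' @param pairs `data.frame` with columns `chrom`, `five_prime_pos`,
#'   `strand`, `mate_end_pos`.
#' @return list with `pairs` (deduplicated `data.frame`) and `kept_fraction`
#'   (`NA` for empty input).
#' @export
collapse_read_pair_duplicates <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  req <- c("chrom", "five_prime_pos", "strand", "mate_end_pos")
  if (!all(req %in% names(pairs))) {
    stop("pairs need columns: ", paste(req, collapse = ", "))
  }
  if (anyNA(pairs$mate_end_pos) || anyNA(pairs$five_prime_pos)) {
    stop("unpaired record: missing coordinate")
  }
  if (nrow(pairs) == 0L) {
    return(list(pairs = pairs, kept_fraction = NA_real_))
  }
  key <- paste(pairs$chrom, pairs$five_prime_pos, pairs$strand,
               pairs$mate_end_pos)
  out <- pairs[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  list(pairs = out, kept_fraction = nrow(out) / nrow(pairs))
}

#' Read a CTSS table from TSV
#'
#' Expects the four-column dialect `chrom<TAB>pos<TAB>strand<TAB>count`
#' (an optional fifth `tpm` column is honoured). A header line is detected
#' and skipped. Malformed lines raise an error naming the line.
#'
#' @param path file path.
#' @return A [ctss_table()].
#' @export
read_ctss <- function(path) {
  lines <- readLines(path)
  if (length(lines) && grepl("^chrom\t", lines[1])) lines <- lines[-1]
  if (!length(lines)) return(ctss_table())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 4L | nf > 5L)
  if (length(bad)) stop("malformed CTSS line ", bad[1], ": ", lines[bad[1]])
  chrom <- vapply(parts, `[[`, "", 1L)
  pos <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  strand <- vapply(parts, `[[`, "", 3L)
  count <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4L)))
  if (anyNA(pos) || anyNA(count)) {
    stop("malformed CTSS line ", which(is.na(pos) | is.na(count))[1])
  }
  if (any(count < 0)) stop("negative count at line ", which(count < 0)[1])
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) stop("invalid strand at line ", bad[1], ": ", strand[bad[1]])
  tpm <- if (any(nf == 5L)) {
    suppressWarnings(as.numeric(vapply(parts, function(p)
      if (length(p) >= 5L) p[[5L]] else NA_character_, "")))
  } else NULL
  ctss_table(chrom, pos, strand, count, tpm)
}

#' Write a CTSS table to TSV
#'
#' @param table a [ctss_table()].
#' @param path output file path.
#' @param header write a header line (default FALSE, so the file round-trips
#'   through [read_ctss()] unambiguously).
#' @return `path`, invisibly.
#' @export
write_ctss <- function(table, path, header = FALSE) {
  assert_ctss(table)
  cols <- c("chrom", "pos", "strand", "count",
            if ("tpm" %in% names(table)) "tpm")
  utils::write.table(table[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = header)
  invisible(path)
}

#' Export CTSSs as BED6
#'
#' 1-based CTSS positions become 0-based half-open single-base intervals
#' (`start = pos - 1`, `end = pos`). The score column carries the raw count
#' (capped at 1000 per the BED convention).
#'
#' @param table a [ctss_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ctss_bed <- function(table, path) {
  assert_ctss(table)
  bed <- data.frame(chrom = table$chrom, start = table$pos - 1L,
                    end = table$pos,
                    name = paste0("ctss_", seq_len(nrow(table))),
                    score = pmin(round(table$count), 1000),
                    strand = table$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
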