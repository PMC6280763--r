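# Design of selectively degradable carrier RNA: a housekeeping-gene-like
# backbone embedded with alternating I-CeuI / I-SceI homing-endonuclease
# recognition sites, a T7 primer/template ladder for in vitro
# transcription, an independent-cut digestion model over multiple rounds,
# spike-in mass planning, and a qPCR model for leftover-carrier estimation.

#' Homing-endonuclease recognition motifs
#'
#' Canonical recognition sequences from standard enzyme catalogs:
#' I-SceI (18 nt) and I-CeuI (27 nt). Their lengths make chance occurrence
#' in a transcriptome highly improbable, which is what makes the carrier
#' selectively degradable.
#'
#' @return Named character vector with elements `"I-SceI"` and `"I-CeuI"`.
#' @export
endonuclease_motifs <- function() {
  c("I-SceI" = "TAGGGATAACAGGGTAAT",
    "I-CeuI" = "TAACTATAACGGTCCTAAGGTAGCGAA")
}

#' Generate a synthetic housekeeping-gene-like backbone
#'
#' Produces a codon-structured random sequence at a target GC content,
#' emulating the composition of a mesophilic bacterial housekeeping gene
#' (no strong repeats or extreme-GC stretches). This is a synthetic
#' stand-in sequence generated by this package, not a natural gene.
#'
#' @param length sequence length in nt (default 1100).
#' @param gc target GC fraction (default 0.5).
#' @param seed RNG seed.
#' @return A character scalar.
#' @export
synthetic_backbone <- function(length = 1100, gc = 0.5, seed = 7L) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, paste(sample(names(p), length, replace = TRUE, prob = p),
                        collapse = ""))
}

#' Design a selectively degradable carrier sequence
#'
#' Embeds `n_sites` homing-endonuclease recognition sites in the backbone,
#' alternating between I-CeuI and I-SceI: alternation increases degradation
#' efficiency and reduces sequence repetitiveness. Sites are substituted in
#' place (the backbone length is preserved) every `spacing` bases starting
#' at `offset`.
#'
#' @param backbone carrier backbone sequence (default
#'   [synthetic_backbone()]).
#' @param n_sites number of recognition sites (default 6).
#' @param spacing distance in bp between consecutive site start positions
#'   (default 150); must exceed the longest motif.
#' @param offset start position of the first site (default 50).
#' @return Object of class `carrier_design`: list with `sequence`, `sites`
#'   (`data.frame` with `position`, `enzyme`, `motif`), `backbone_gc`,
#'   `gc`.
#' @export
design_carrier <- function(backbone = synthetic_backbone(), n_sites = 6,
                           spacing = 150, offset = 50) {
  motifs <- endonuclease_motifs()
  if (spacing < max(nchar(motifs))) {
    stop("spacing shorter than the longest recognition motif (",
         max(nchar(motifs)), " nt)")
  }
  stopifnot(n_sites >= 1, offset >= 1)
  starts <- offset + (seq_len(n_sites) - 1L) * spacing
  enzymes <- rep(c("I-CeuI", "I-SceI"), length.out = n_sites)
  need <- starts[n_sites] + nchar(motifs[enzymes[n_sites]]) - 1L
  if (need > nchar(backbone)) {
    stop("backbone too short: need ", need, " nt for ", n_sites,
         " sites at spacing ", spacing)
  }
  seq <- backbone
  for (i in seq_len(n_sites)) {
    m <- motifs[[enzymes[i]]]
    substr(seq, starts[i], starts[i] + nchar(m) - 1L) <- m
  }
  gc_of <- function(s) {
    b <- strsplit(toupper(s), "")[[1]]
    mean(b %in% c("G", "C"))
  }
  out <- list(sequence = seq,
              sites = data.frame(position = starts, enzyme = enzymes,
                                 motif = unname(motifs[enzymes]),
                                 stringsAsFactors = FALSE),
              backbone_gc = gc_of(backbone), gc = gc_of(seq))
  class(out) <- "carrier_design"
  out
}

#' @export
print.carrier_design <- function(x, ...) {
  cat(sprintf("Carrier design: %d nt, %d sites (%s), GC %.3f\n",
              nchar(x$sequence), nrow(x$sites),
              paste(x$sites$enzyme, collapse = ", "), x$gc))
  invisible(x)
}

#' Find endonuclease recognition sites in a sequence
#'
#' Exact-match scan for every catalogued motif; used to verify that a
#' design record matches its emitted sequence.
#'
#' @param sequence character scalar.
#' @return `data.frame` with `position`, `enzyme`, `motif`, sorted by
#'   position.
#' @export
scan_motifs <- function(sequence) {
  motifs <- endonuclease_motifs()
  hits <- do.call(rbind, lapply(names(motifs), function(e) {
    m <- Biostrings::matchPattern(motifs[[e]],
                                  Biostrings::DNAString(sequence))
    if (length(m) == 0L) return(NULL)
    data.frame(position = Biostrings::start(m), enzyme = e,
               motif = motifs[[e]], stringsAsFactors = FALSE)
  }))
  if (is.null(hits)) {
    return(data.frame(position = integer(), enzyme = character(),
                      motif = character(), stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$position), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Canonical T7 promoter sequence
#' @return Character scalar (18 nt).
#' @export
t7_promoter <- function() "TAATACGACTCACTATAG"

#' Build the primer set and template ladder for carrier transcription
#'
#' The forward primer tail is the T7 promoter followed by five random
#' nucleotides; each reverse primer determines one template length and
#' appends six random nucleotides at the 3' end. One template is produced
#' per requested length.
#'
#' @param design a [design_carrier()] result.
#' @param lengths requested template lengths in bp (default the 10-step
#'   ladder from 386 to 1034 bp).
#' @param seed RNG seed for the random primer bases.
#' @return List with `forward_tail`, `templates` (`data.frame` with
#'   `length`, `sequence`), `primers` (`data.frame` with `name`,
#'   `sequence`).
#' @export
build_template_ladder <- function(design,
                                  lengths = round(seq(386, 1034, length.out = 10)),
                                  seed = 1L) {
  stopifnot(inherits(design, "carrier_design"))
  tail_len <- nchar(t7_promoter()) + 5L
  min_len <- tail_len + 6L + 1L
  if (any(lengths < min_len)) {
    stop("template length below the minimal amplicon (", min_len, " bp)")
  }
  if (any(lengths > nchar(design$sequence) + tail_len + 6L)) {
    stop("requested length exceeds the design sequence")
  }
  with_seed(seed, {
    fwd_tail <- paste0(t7_promoter(),
                       paste(sample(c("A", "C", "G", "T"), 5, TRUE),
                             collapse = ""))
    templates <- do.call(rbind, lapply(lengths, function(L) {
      core_len <- L - tail_len - 6L
      core <- substr(design$sequence, 1L, core_len)
      tail3 <- paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = "")
      data.frame(length = L, sequence = paste0(fwd_tail, core, tail3),
                 stringsAsFactors = FALSE)
    }))
  })
  primers <- data.frame(
    name = c("PCR_GN5_f1", paste0("PCR_N6_r", seq_along(lengths))),
    sequence = c(fwd_tail,
                 vapply(templates$sequence, function(s) {
                   revcomp(substr(s, nchar(s) - 23L, nchar(s)))
                 }, character(1), USE.NAMES = FALSE)),
    stringsAsFactors = FALSE)
  list(forward_tail = fwd_tail, templates = templates, primers = primers)
}

#' In-silico digestion of a carrier sequence
#'
#' Models selective degradation: each recognition site is cut independently
#' with probability `1 - (1 - e)^r` after `r` rounds at per-site, per-round
#' efficiency `e`. Fragments are the maximal uncut intervals; the intact
#' fraction (no cut at any site) is estimated over `n_molecules` molecules
#' and reported alongside the closed form `(1 - e)^(r * s)` for `s` sites.
#'
#' @param sequence carrier sequence (or a [design_carrier()] object).
#' @param efficiency per-site single-round cut probability, in [0, 1].
#' @param rounds number of digestion rounds (default 2, as in the
#'   degradation protocol the model describes).
#' @param n_molecules Monte-Carlo sample size (default 1e4).
#' @param seed RNG seed.
#' @return List with `fragment_lengths` (integer vector over all
#'   molecules), `intact_fraction`, `expected_intact` (closed form),
#'   `n_sites`, `cut_prob` (per-site probability after all rounds).
#' @export
in_silico_digest <- function(sequence, efficiency, rounds = 2,
                             n_molecules = 1e4, seed = 1L) {
  if (inherits(sequence, "carrier_design")) sequence <- sequence$sequence
  stopifnot(efficiency >= 0, efficiency <= 1, rounds >= 1, n_molecules >= 1)
  sites <- scan_motifs(sequence)
  L <- nchar(sequence)
  s <- nrow(sites)
  if (s == 0L) {
    warning("sequence has no recognition sites; nothing to digest")
    return(list(fragment_lengths = rep(L, n_molecules), intact_fraction = 1,
                expected_intact = 1, n_sites = 0L, cut_prob = 0))
  }
  p_cut <- 1 - (1 - efficiency)^rounds
  # cut coordinate: the site start (fragment boundary within the motif is
  # enzyme-specific in vitro; the fragment-length model only needs a fixed
  # per-site coordinate)
  cut_at <- sites$position
  res <- with_seed(seed, {
    cuts <- matrix(stats::runif(n_molecules * s) < p_cut, n_molecules, s)
    frag <- unlist(lapply(seq_len(n_molecules), function(i) {
      b <- cut_at[cuts[i, ]]
      diff(c(0L, b, L))
    }))
    list(frag = frag, intact = mean(rowSums(cuts) == 0L))
  })
  frag <- res$frag
  intact <- res$intact
  list(fragment_lengths = frag[frag > 0], intact_fraction = intact,
       expected_intact = (1 - efficiency)^(rounds * s),
       n_sites = s, cut_prob = p_cut)
}

#' Plan the carrier spike-in mass
#'
#' The carrier is mixed with the RNA of interest up to a standard total
#' mass (5 ug by default) so that cap-trapper chemistry runs at its usual
#' scale: e.g. 10 ng of sample RNA is mixed with 4990 ng of carrier.
#'
#' @param sample_ng sample RNA mass in ng.
#' @param total_ng total reaction mass in ng (default 5000).
#' @return Carrier mass in ng.
#' @export
plan_spike_in <- function(sample_ng, total_ng = 5000) {
  stopifnot(sample_ng > 0)
  if (sample_ng > total_ng) {
    stop("sample mass exceeds the total reaction mass")
  }
  total_ng - sample_ng
}

#' Input-reduction ratio relative to the reference protocol
#'
#' How much less material the carrier-based protocol needs than the
#' reference protocol: reference mass divided by sample mass (e.g.
#' 5000 ng / 5 ng = 1000-fold).
#'
#' @param sample_ng sample RNA mass in ng.
#' @param reference_ng reference-protocol input mass in ng (default 5000).
#' @return The fold reduction.
#' @export
input_reduction_ratio <- function(sample_ng, reference_ng = 5000) {
  stopifnot(sample_ng > 0, reference_ng > 0)
  reference_ng / sample_ng
}

#' Compose a carrier molecule mix
#'
#' Draws a set of carrier molecules with lengths uniform over the template
#' ladder and a capped flag per molecule, Bernoulli(`capped_fraction`).
#' The optimal mix is 10% capped / 90% uncapped molecules of varying
#' length, mimicking the composition of cellular total RNA.
#'
#' @param design a [design_carrier()] result (used for its default ladder
#'   when `lengths` is NULL).
#' @param capped_fraction fraction of capped molecules (default 0.10).
#' @param n_molecules number of molecules to draw.
#' @param lengths template ladder lengths (default 386..1034 in 10 steps).
#' @param seed RNG seed.
#' @return `data.frame` with `length` and `capped` per molecule.
#' @export
compose_carrier_mix <- function(design = design_carrier(),
                                capped_fraction = 0.10, n_molecules = 1e5,
                                lengths = NULL, seed = 1L) {
  stopifnot(capped_fraction >= 0, capped_fraction <= 1)
  if (n_molecules <= 0) stop("n_molecules must be positive")
  if (is.null(lengths)) lengths <- round(seq(386, 1034, length.out = 10))
  with_seed(seed, data.frame(
    length = sample(lengths, n_molecules, replace = TRUE),
    capped = stats::runif(n_molecules) < capped_fraction))
}

#' Estimate leftover carrier fraction from qPCR Ct values
#'
#' Under ideal amplification with per-cycle base `E` (2 = perfect
#' doubling), a template present at fraction `f` of the library reaches
#' threshold `log_E(1/f)` cycles later, so
#' `f = E^-(ct_carrier - ct_library)`. In the protocol this model
#' describes, whole-library Ct is typically 12-13 and carrier-specific Ct
#' 23-30, giving leftover fractions around `2^-11`.
#'
#' @param ct_library Ct with whole-library primers.
#' @param ct_carrier Ct with carrier-specific primers.
#' @param amplification_base per-cycle amplification factor `E` (> 1,
#'   default 2).
#' @return List with `fraction` and `flagged` (TRUE when the fraction
#'   exceeds 1, i.e. `ct_carrier < ct_library`).
#' @export
estimate_carrier_fraction_qpcr <- function(ct_library, ct_carrier,
                                           amplification_base = 2) {
  stopifnot(ct_library >= 0, ct_carrier >= 0)
  if (amplification_base <= 1) stop("amplification base must exceed 1")
  f <- amplification_base^(-(ct_carrier - ct_library))
  list(fraction = f, flagged = f > 1)
}

#' Write a carrier design record to JSON and FASTA
#'
#' @param design a [design_carrier()] result.
#' @param json_path,fasta_path output paths (either may be `NULL`).
#' @return Invisibly, a list of written paths.
#' @export
write_carrier_design <- function(design, json_path = NULL, fasta_path = NULL) {
  stopifnot(inherits(design, "carrier_design"))
  if (!is.null(json_path)) {
    jsonlite::write_json(list(sequence = design$sequence,
                              sites = design$sites, gc = design$gc),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(fasta_path)) {
    x <- Biostrings::DNAStringSet(design$sequence)
    names(x) <- "carrier"
    Biostrings::writeXStringSet(x, fasta_path)
  }
  invisible(list(json = json_path, fasta = fasta_path))
}
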