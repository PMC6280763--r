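---
title: "Methods and design notes for cageforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for cageforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cageforge)
```

# Scope

`cageforge` implements the computational battery used to analyse cap
analysis of gene expression (CAGE) libraries, with particular attention to
the quality control of low-input, carrier-assisted protocols: CTSS-level
TSS mapping, power-law normalization, tag clustering with
interquantile-width (IQ-width) shape metrics, benchmarking of a query
library against a reference, promoter-architecture sequence analysis,
SOM-based expression profiling with TSS-switch detection, and the in-silico
side of degradable carrier RNA design. A synthetic-data generator with full
ground truth makes every stage testable without downloading any data.

# From aligned tags to CTSSs

A CAGE tag's 5' end marks a transcription start site. `extract_ctss()`
counts, for every unique (chromosome, position, strand), the number of
uniquely-mapped reads whose 5' end falls there — the leftmost aligned base
on the plus strand, the rightmost on the minus strand. "Uniquely mapped" is
operationalized as a mapping-quality cutoff (default MAPQ >= 20,
configurable) because aligners encode uniqueness differently; rows without
a MAPQ are kept.

Reverse transcriptase often adds one template-free G complementary to the
cap. `correct_leading_g()` removes it: a leading G flagged as a genomic
mismatch always shifts the 5' end one base 3'-ward; a leading G that
*matches* the genome is shifted with probability equal to the locally
observed mismatched-G fraction at that site, since cap-derived and genomic
Gs are indistinguishable there. The per-site empirical fraction is the
natural estimator of that probability; draws are seeded for
reproducibility.

Because reverse transcription primes with a random hexamer, two read pairs
identical in 5' end *and* mate 3' end almost surely come from PCR
amplification of one cDNA; `collapse_read_pair_duplicates()` keeps one pair
per such key and reports the kept fraction.

# Power-law normalization

CTSS count distributions are heavy-tailed: the reverse cumulative
N(>= x) — the number of CTSSs supported by at least x tags — is
approximately linear in log-log space. `fit_power_law()` estimates the
slope by ordinary least squares on the distinct count values inside a fit
range (default counts in [10, 1000]); fitting distinct values rather than
per-CTSS replicated points avoids letting the enormous singleton mass
dominate. `normalize_power_law()` then maps counts onto a referent power
law of slope `alpha_ref = 1.25` totalling `10^6` tags:

$$\mathrm{tpm}_i = s \cdot c_i^{\,\alpha/\alpha_\mathrm{ref}}, \qquad
  \sum_i \mathrm{tpm}_i = 10^6 .$$

The map is strictly increasing, so ranks are preserved exactly, and after
the transform the reverse-cumulative slope over the (correspondingly
mapped) fit range equals the referent slope. The referent slope 1.25, the
fit range and the total are declared defaults of this package — they are
the values conventional in the CAGE normalization literature — and all
three are arguments. When the count distribution is degenerate (all counts
equal), the fit refuses and `normalize_tpm()` provides the depth-only
fallback.

# Tag clusters, IQ-widths and promoter shape

`cluster_ctss()` groups CTSSs by single linkage along each strand:
consecutive CTSSs at gap <= `max_gap` (default 20 bp, the convention of the
established CAGE clustering frameworks) join one cluster, after discarding
CTSSs below `min_tpm` (default 1). `summarize_cluster()` computes the
positions holding the 10th and 90th percentile of the cluster's cumulative
signal, walking 5'-to-3' with no interpolation (integer positions are
testable and unambiguous); their distance plus one is the IQ-width, which
is robust to extreme outlier CTSSs. The dominant CTSS is the member of
highest expression, ties broken toward the 5' end (deterministic and
strand-symmetric). Clusters with IQ-width <= 3 bp are classified sharp,
wider ones broad — the empirical boundary used throughout the promoter
literature. Degraded, low-complexity libraries detect CTSSs incompletely
and therefore produce artificially sharp clusters; the IQ-width
distribution is the standard visual indicator of that failure mode, and
`subsample_library()` (multivariate hypergeometric, without replacement)
reproduces it on demand.

`merge_consensus()` builds cross-sample promoter regions as the union of
overlapping same-strand tag clusters. The merge rule is a declared design
choice (the union is deterministic and order-independent); for TSS-switch
analyses the consensus should be built at promoter-region scale
(`max_gap` of roughly 150 bp), so that both initiation sites of a
switching promoter fall into one region. `annotate_location()` assigns one
category per cluster with precedence promoter > 5'UTR > exon > intron >
antisense > intergenic; the promoter window is -500..+100 around annotated
starts (unreported in the source protocols; configurable).

# Benchmarking against a reference

`correlate_ctss()` computes Pearson correlation of raw (non-log)
normalized expression over the union of CTSS keys, imputing 0 where a
library lacks a position — union semantics are the only choice that
penalizes missed TSSs. `roc_vs_reference()` ranks query entities by
descending expression against a truth set defined by the reference (CTSSs
with tpm >= 1 by default, or reference cluster regions); the ROC steps over
the rank threshold and AUC is the trapezoid area, with the degenerate
no-false-positive query assigned AUC 1. `dominant_distance_stats()` pairs
clusters by reciprocal overlap — mutual best partners by expression — so a
promoter fragmented into several query clusters contributes a single pair
through its strongest fragment, and reports the fractions of dominant
CTSSs identical and within 10 bp. `ratio_heatmap()` assembles the
per-CTSS log2 query/reference ratios (and reference-only expression) on a
strand-oriented offset grid around each reference dominant CTSS, rows
grouped into four reference-expression quartiles.

`permutation_similarity()` tests whether two positional matrices share
column structure. The statistic is the Pearson correlation of the two
column-mean profiles. For the null we permute the column order
independently within each row of the second matrix: this preserves every
row's value distribution while destroying positional structure. (A null
that permutes whole rows would leave column means — and hence the
statistic — unchanged, so it cannot calibrate this statistic; the
within-row permutation is the package's design choice.) The p-value is the
usual add-one permutation estimator, bounded below by 1/(n_perm + 1).

# Promoter architecture

Sequence analyses orient everything 5'-to-3' on the cluster strand,
reverse-complementing minus-strand windows. `ctss_composition()` reports
+1 base and [-1,+1] initiator dinucleotide frequencies (the canonical
initiator is the pyrimidine-purine step, e.g. CA).
`dinuc_density_matrix()` builds cluster-by-offset indicator matrices for
any two-letter IUPAC pattern (TA, GC, WW = AA/AT/TA/TT, SS, ...), rows
ordered sharpest-to-broadest, with an optional 5-bp positional moving
average for display.

`scan_pwm()` scores log2-odds PWM windows whose start offset lies in a
search window (default [-35, -25], motivated by the TATA-box position at
-30). A window is a hit when its score reaches
`min + 0.8 * (max - min)` of the analytically achievable score range —
the "80th-percentile match" convention of motif scanning. Because that
phrase can also be read as an empirical score quantile, both modes are
selectable (`threshold_mode`). The bundled `tata_pwm()` is a synthetic
consensus-derived (TATAWAWR) count matrix, not a database matrix.

`ww_periodicity()` averages the WW indicator over +1..+150 downstream of
the dominant CTSS across (broad) clusters, removes a linear trend, and
reads the dominant period off a finely sampled power spectrum restricted
to 5-20 bp. The ~10.5-bp WW periodicity reflects the rotational
positioning of the +1 nucleosome, and it is only visible when dominant
CTSSs are accurately placed — which is why the random-member alignment
control (`align = "random"`) attenuates it. Peak significance is reported
as the ratio of the peak to the spectral median after smoothing the
spectrum over about five Rayleigh widths (5/n in frequency); the raw
oversampled periodogram maximum would exceed 3x the median even for white
noise, whereas the smoothed ratio stays below 3 on featureless sequence
and far above it on phased input.

# Expression profiling and TSS switching

`build_matrix()` takes consensus clusters with at least one sample at
`min_tpm`, log-transforms (`log10(tpm + 1)`) and optionally z-scores rows.
`som_cluster()` trains a batch self-organizing map (via the `class`
package) on row-standardized profiles — standardization makes the map
cluster profile shapes rather than absolute levels — over a 4 x 2 grid by
default (eight classes labelled `0_0`..`3_1`); training is deterministic
given the seed. `detect_switching()` flags consensus regions expressed at
`min_tpm >= 5` in both of two samples whose dominant CTSSs lie at least
`min_distance = 10` bp apart. These thresholds are declared
operationalizations: switching reports in the literature give events and
distances but not the decision rule.

# Carrier design and digestion

The degradable carrier is a housekeeping-gene-like backbone embedded with
alternating I-CeuI (27-nt site) and I-SceI (18-nt site) recognition
sites — alternation improves degradation efficiency and reduces
repetitiveness, and sites of this length essentially never occur by chance
in a transcriptome. `design_carrier()` substitutes catalogued motifs into
the backbone at fixed spacing and verifies the design by exact motif scan;
the default backbone is a synthetic codon-structured sequence generated by
this package (`synthetic_backbone()`), not a natural gene.
`build_template_ladder()` produces the in-vitro-transcription templates:
a forward tail of the canonical T7 promoter plus five random nucleotides,
and one reverse primer per requested length (default ladder 386-1034 bp)
appending six random 3' nucleotides.

`in_silico_digest()` models degradation as independent cuts: after `r`
rounds at per-site efficiency `e`, each site is cut with probability
`1 - (1-e)^r`, fragments are maximal uncut intervals, and the intact
fraction has the closed form `(1-e)^(rs)` for `s` sites, which the
Monte-Carlo estimate converges to. Independence across sites and rounds is
the simplest model consistent with a two-round digestion protocol.
`plan_spike_in()` fills a sample up to the standard 5 ug reaction mass
(10 ng of sample + 4990 ng of carrier); `compose_carrier_mix()` draws the
optimal mix of 10% capped / 90% uncapped molecules with lengths uniform
over the ladder; `estimate_carrier_fraction_qpcr()` converts a Ct
difference into a leftover-carrier fraction under ideal doubling
(`f = E^-(Ct_carrier - Ct_library)`, `E = 2` by default; real amplicon
efficiencies differ, so `E` is an argument).

# The synthetic-data generator

`generate_genome()` writes i.i.d. background sequence at GC 0.40 and
implants promoters 2.5 kb apart: sharp promoters (spread <= 3 bp) carry
TATAAA at -30 and a CA initiator; broad promoters carry a GC-0.60 island
over -100..+250, a CA initiator, a Gaussian spread with sigma drawn from
5-30 bp, and WW dinucleotides placed with probability 0.9 at offsets
`round(10.5 k)` downstream of the dominant position. These constants are
the package's realistic-by-construction defaults where the modelled
protocols constrain the features only qualitatively, and all are
arguments.

`simulate_library()` draws promoter weights from a Pareto law with
reverse-cumulative slope 1.25 and scatters tags multinomially. Sharp
promoters put 90% of their mass on the dominant CTSS. Broad promoters use
a Gaussian envelope *plus* a 25% point mass on the dominant position: a
pure Gaussian has no distinguishable mode at realistic depths, whereas
real broad promoters do have a reproducible dominant CTSS; the point mass
is what makes "dominant recovery" a well-posed target while keeping
IQ-widths of order 2 sigma. `simulate_degradation()` subsamples molecules
without replacement (optionally biased against non-G-initiating tags by
`1 - g_bias`, the template-switching capture artefact), amplifies
survivors through a branching PCR process and resamples to the original
depth. `generate_two_conditions()` implants condition-specific (10-fold),
switching (major/minor initiation sites flipped between conditions,
minor share 0.2) and ubiquitous promoters.

What the generator does *not* emulate: mappability structure, sequencing
error, transcript-level RNA-seq signal, chromatin heterogeneity between
promoters of one class, or inter-promoter interference. Passing tests
therefore demonstrate correctness of the algorithms under the stated
generative model, not performance on any particular real library.

# Numerical choices and problem sizes

Quantile positions are the first position reaching the quantile (no
interpolation); dominant ties break 5'-ward; PWM windows containing N are
skipped rather than scored; the spectral peak is localized on a 600-point
frequency grid over 5-20 bp. Seeds isolate their RNG stream and restore
the caller's, so seeded operations compose without disturbing each other.

The shipped test suite and acceptance script run the full pipeline at 500
promoters and 10^6 tags for degradation benchmarking, 600 broad promoters
at 6x10^5 tags for periodicity estimation, and 300 promoters at 5x10^5
tags per condition for switch/SOM recovery — sizes at which the
stochastic targets are stable over seeds while the whole suite stays
fast on one CPU.

# Known limitations

The G-correction needs per-read first-base and mismatch flags (it does not
re-align); cluster-level ROC treats any overlap as a hit; the SOM is a
batch implementation without torus topology; carrier digestion ignores
partial-site degeneracy of the homing endonucleases; and the qPCR model
assumes equal amplification efficiency for both primer pairs.
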