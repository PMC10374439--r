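---
title: "Methods: screen quantification, activity models and unwinding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screen quantification, activity models and unwinding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sniperkit)
```

# Scope

`sniperkit` implements the quantitative machinery used to characterize
high-fidelity SpCas9 variants from paired sgRNA-target library screens:
background-corrected indel frequency estimation, PAM-compatibility and
mismatch-tolerance analytics, convolutional sequence-to-activity regression
networks, and single-molecule FRET (smFRET) two-state analysis of
RNP-induced DNA unwinding.  Everything runs end to end on synthetic data
generated by the package itself, with known ground truth, so each estimator
can be validated as an estimator.  Wet-lab stages of such screens (directed
evolution, viral delivery, selections) are out of scope; the package starts
where reads, counts or traces exist.

# Coordinates and annotation conventions

A library pair couples a 20-nt spacer with a 30-nt integrated target
context laid out as `[4 nt upstream][20 nt protospacer][3 nt PAM][3 nt
downstream]`.  Protospacer positions are reported PAM-anchored: position 1
is adjacent to the PAM, position 20 is the PAM-distal 5' end.  This
convention reproduces the conventional "position 13" reading for the
classic EMX1.6 spacer/off-target pair, whose single rU:dG wobble mismatch
sits 13 bases from the PAM; the literature also uses 5'-anchored numbering
in some contexts, so `pamToFivePrime()` converts (it is an involution) and
`annotateMismatches(numbering = "five_prime")` reports directly in the
other convention.

Mismatch classes follow the base-pairing chemistry of the sgRNA against
the target strand: *wobble* (spacer G over protospacer A, or spacer U over
protospacer C, i.e. rG:dT or rU:dG pairs), *non-wobble transition* (the
remaining purine-purine / pyrimidine-pyrimidine substitutions) and
*transversion*.  Every wobble is a transition at the protospacer level; at
any given position exactly one transition class is chemically realizable,
which the library generator respects.

U6-driven `gN19` guides carry an obligatory 5' G that often mismatches
position 20 of the target.  The annotator flags that difference
(`five_prime_g`) instead of counting it as a designed mismatch, which also
means a `gN19` library cannot carry a *designed* position-20 mismatch
distinguishable from the artifact -- fixtures that need the full 1-20
position range use `tRNA_N20` guides, mirroring why perfect-match
tRNA-processed libraries exist in practice.

# Indel quantification

Reads are assigned to pairs via an 8-nt pair barcode placed 3' of the
target context in the amplicon, read at a fixed offset from the 3' end so
that indels upstream cannot shift it; exact hash lookup first, then a
fallback tolerating up to 2 barcode mismatches, with ties left unassigned.
Barcoded assignment is a design choice of this package: window-independent
subsequence keys are not unique across pairs of the same guide once
PAM-proximal single mismatches are in play.

Indel calling aligns each non-identical read to its reference amplicon
(end-free pairwise alignment, match +2 / mismatch -2 / gap -5, implemented
in C++ for throughput) and calls `indel` iff an insertion/deletion op
overlaps the window of half-width 4 bp around the blunt cut site 3 bp 5'
of the PAM.  Substitutions never count; reads scoring below half the
perfect-match score are excluded from totals.  The window half-width and
score floor are configurable (`quantConfig()`); the original screens
delegate these details to prior pipelines, so the defaults here are
documented package choices rather than reconstructions.

Background correction removes the no-nuclease error rate `b` (fraction):

$$\hat p = \frac{x/N - b}{1 - b}$$

reported in percent, where `x` is the indel read count and `N` the total.
This is the exact inverse of the observation model
`p_obs = p + (1 - p) b` used by the simulators, which makes estimator
recovery well-posed.  Corrected values below zero are clipped to zero
(with the unclipped value retained) so downstream specificity statistics
stay in range.  Replicates are pooled by summing counts -- never by
averaging per-replicate ratios -- and the screen's exclusion rules are
applied strictly as stated: fewer than 100 total reads or background above
8% excludes a record; records exactly at either boundary are retained.
Days 4 and 7 are kept as separate conditions throughout.

# Specificity statistics

Specificity is `1 - off/on` over background-corrected frequencies, with
`off/on` (relative activity) its exact complement; records whose on-target
frequency is zero are dropped with a count.  Position profiles average
single-mismatch specificities per PAM-anchored position (per-record by
default; a per-guide option averages within guide first, since published
panels do not state which convention they use).  The activity-specificity
trade-off point of a variant uses medians (matching the box-plot-centric
presentation of variant comparisons), and "comparable" guides across
variants are selected by an explicit range criterion -- across-variant
max-min of on-target frequency at most a stated tolerance at day 4 or day
7 -- because no formula for "comparable" is standard.

# The synthetic study generator

The generator's defaults emulate the screen's published geometry: a
mismatch panel of 30 guides x 98 mismatched targets (one to three planted
mismatches; composition spread uniformly over positions, counts and
feasible classes, as the real composition is not published) plus matched
targets, and optional 256-PAM scans per guide.  Ground truth activity is a
deterministic landscape: a logistic function of a fixed 4 x 30
position-weight sum over the context (weights shipped in
`inst/extdata/landscape_weights.tsv`), a PAM factor (NGG 1.0, NGH 0.08,
non-NG 0.01, echoing the strong NGG preference of PAM scans), and one
multiplicative penalty per designed mismatch
`position_tolerance[p] * class_tolerance[class]`.  Default position
tolerances rise from the PAM-proximal seed toward the distal end with
local intolerance dips at positions 5 and 15, the regions where
high-fidelity variants are most discriminating; class tolerances order
wobble (0.8) > non-wobble transition (0.5) > transversion (0.1).

Counts are drawn with negative-binomial totals (variance 1.5 x mean;
amplicon libraries are overdispersed) and binomial indel reads at
`p + (1-p) b`; day 7 applies a saturation multiplier (1.25) to the true
frequency.  Reads are amplicons `[primer][context][barcode][primer]` with
indels planted centered on the cut site (geometric lengths truncated at 10
bp, deletions:insertions 2:1 -- unspecified by the screens, chosen to keep
desk-scale calls unambiguous) and independent substitution errors
(default 10^-3 per base).  Background rates are gamma-distributed around
1% by default.

What the generator does **not** emulate: PCR chimeras and jackpots,
position-dependent sequencing error, lentiviral integration effects, UMI
structure, or any sequence-dependent repair-outcome spectrum.  Passing
recovery tests therefore demonstrates that the estimators invert the
stated observation model at realistic depths -- not that they are robust
to every artifact of real amplicon data.

# Activity-prediction networks

No deep-learning framework is part of the package's dependency set; the
networks are implemented directly on BLAS matrix products (convolution as
im2col), with hand-derived backpropagation, inverted dropout and a fused
C++ Adam step.  This keeps the architecture fully inspectable and the
dependency footprint to base numerical linear algebra.

The **on-target** network takes the one-hot 30-nt context: one
convolution layer (256 filters, 5 nt wide, length-preserving zero
padding), average pooling (width 2 / stride 2; no standard pooling
geometry exists for this architecture, so it is configurable), fully connected
layers 1500-1500-100 with rectified linear activations and dropout 0.3,
and a learned 100-dimensional embedding of the binary expression-system
flag ((G/g)N19 vs tRNA-N20) multiplied elementwise with the final
100-unit layer -- elementwise is the only dimensionally consistent way to
combine a 100-vector embedding with a 100-unit layer output.  The
embedding initializes at all-ones so the product starts as the identity.
A linear map produces the score.

The **off-target** network stacks the one-hot spacer and target as 8
channels x 20 positions (convolution: 128 filters, width 3 for the
Sniper1 profile or 5 for the Sniper2L profile), concatenates a per-position
mismatch feature vector (integer code 0 for match, 1-12 indexing the
ordered substitution) after flattening, and continues through
1500-1500-1500-100 with a linear output (the final score is a linear map
of the last 100-unit layer); it receives no expression-system input.

Training minimizes mean absolute error with Adam at learning rate 10^-4.
Activity labels are z-standardized internally and predictions returned on
the percent scale: with MAE loss the gradient is a sign, so Adam moves each
parameter by at most the learning rate per step, and raw percent-scale
targets (offset ~50) would be unreachable in few epochs; standardization is
an optimization-health choice that leaves the loss and optimizer as
specified.  Batch size 64, early stopping on validation MAE (patience
configurable).  Five-fold cross-validation uses seed-reproducible disjoint
folds.  On the deterministic synthetic landscape, 5,000 training examples
reach held-out Pearson r about 0.95 within 8 epochs (the test suite and
acceptance script train exactly this configuration); correlations of the
kind reported for models trained on real screen measurements require
those screens' datasets, which the package accepts as an optional input
path (activity tables as TSV) but does not bundle.

# smFRET unwinding analysis

Per-frame FRET efficiency is `E = IA/(ID + IA)`; frames with non-positive
total intensity are invalid.  Histograms take the first five valid frames
of each molecule; molecules without acceptor signal can be excluded by an
acceptor-intensity threshold, mirroring acceptor-channel spot selection.
Three populations are classified -- donor-only (E < 0.2), low-FRET/unwound
(0.2 to the boundary) and high-FRET/rewound -- with the low/high boundary
at 0.6 by default and switchable to 0.65/0.70 as experiments vary it.  The
donor-only cutoff at 0.2 is a package default (published histograms show
the peak at E = 0 without printing a cutoff).  Molecules are assigned their
modal class over the five samples (a per-sample mode is available), since
"fraction of molecules" implies per-molecule assignment.

The unwound fraction is `f_unwound = low/(low + high)` (donor-only
excluded), unwinding specificity is `1 - f_mismatch/f_matched`, and the
n_PD threshold statistic is the smallest number of consecutive PAM-distal
mismatches whose unwound fraction falls below half the matched value.
Transition detection thresholds the 3-frame median-filtered E trace at the
low/high boundary and absorbs dwells shorter than 2 frames; this discards
single-frame dwells, biasing the detected transition fraction below the
closed-form `1 - (1 - p)^(F-1)` by roughly `2p + F p^2` per molecule --
negligible in the sub-10%-transitions regime these assays operate in,
and bounded explicitly in the test suite at larger flip rates.

# Numerical choices and degenerate inputs

* Filters use strict inequalities exactly as stated; boundary records pass.
* `total_reads = 0` or `background >= 100%` make corrected frequencies
  undefined (`NA`), never infinite.
* Specificity is undefined at zero on-target frequency; such records are
  dropped and counted rather than propagated.
* Alignment tie-breaks prefer the diagonal (substitutions over gaps);
  reads below the score floor are excluded from totals rather than called.
* Population-classification ties go to the lower-E class, deterministically.
* All generators accept a seed and restore the caller's RNG state; the
  pipeline manifest records seeds and content hashes and contains no
  timestamps, so identical configurations yield identical manifests.

# Problem sizes

Fixture sizes are chosen so the full suite runs comfortably on a laptop
core: depth 1,000-4,000 for count simulations, 600 x 1,000 reads for the
end-to-end recovery, 2,000 molecules per FRET condition, and 5,000/1,000
train/test examples (8 epochs) for the network learnability run.
Estimator variance at these sizes is what the stated tolerances reflect.

# Known limitations

* The synthetic landscape is smooth and deterministic; it demonstrates
  learnability of the architecture, not real-data performance.
* The indel caller handles a single contiguous indel per read well (the
  simulator's regime); complex multi-indel outcomes are called as "indel"
  but not decomposed.
* Background pooling without control counts falls back to a read-weighted
  mean of per-replicate background rates, which is exact only when control
  depth is proportional to sample depth.
* The off-target network's output stage admits more than one reading in
  circulating descriptions of this architecture family; the linear map of
  the final 100-unit layer is the one adopted here.
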