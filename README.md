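# sniperkit

Quantitative analysis of high-fidelity SpCas9 variant screens in R:
paired sgRNA–target library indel quantification with background
correction and filtering, PAM-compatibility and mismatch-tolerance
analytics, convolutional sequence-to-activity regression (on- and
off-target networks), and single-molecule FRET two-state analysis of
RNP-induced DNA unwinding. It is written for people who analyze
high-throughput genome-editing screens — or who develop methods for them
and need a fully synthetic, ground-truth-known testbed.

## The statistics at the core

For a pair with indel read count *x*, total read count *N* and
no-nuclease background indel frequency *b*, the background-corrected
indel frequency is

&nbsp;&nbsp;&nbsp;&nbsp;p̂ = (x/N − b) / (1 − b) × 100%

with records excluded when *N* < 100 or *b* > 8% (boundaries retained),
and replicates pooled by summing counts. Specificity of a mismatched
target is 1 − (off-target / on-target corrected frequency); its
complement is the relative activity. In the smFRET assay, per-frame FRET
efficiency is E = I_A/(I_D + I_A); molecules classify into donor-only
(E < 0.2), low-FRET/unwound (0.2 < E < 0.6) and high-FRET/rewound
(E > 0.6) populations, the unwound fraction is
f_unwound = low/(low + high), and unwinding specificity is
1 − f_unwound(mismatched)/f_unwound(matched). The DeepSniper-style
networks regress activity on one-hot sequence encodings (on-target:
conv 256×5 nt → average pooling → 1500-1500-100 with an
expression-system embedding; off-target: 8-channel spacer/target stack,
conv 128×3/5 nt, mismatch feature vector), trained with mean absolute
error and Adam at learning rate 10⁻⁴. The methods vignette
(`vignettes/sniperkit-methods.Rmd`) derives every convention and default.

## Worked example

Simulate a mismatch-tolerance screen (30 guides × 98 mismatched targets,
the panel geometry of a variant screen), quantify it at depth 1,000 with
two days × two replicates, and stratify mismatch tolerance:

```r
library(sniperkit)
lib    <- buildLibrary(libraryDesign(n_guides = 30,
                                     mismatch_targets_per_guide = 98),
                       seed = 1)
truth  <- makeGroundTruth(lib, seed = 2)
counts <- simulateCounts(truth, depth = 1000, seed = 3)
freq   <- applyFilters(mergeReplicates(counts))
recs   <- specificityRecords(freq[freq$day == 4, ], lib)
stratifyByMismatch(recs)$by_class
#>                 mclass   n median   mean
#> 1               wobble 117 0.2574 0.3251
#> 2 nonwobble_transition 377 0.1266 0.1647
#> 3         transversion 485 0.0308 0.0375
```

The median relative activity (off/on) per single-mismatch class recovers
the designed tolerance ordering: wobble mismatches are tolerated most
(0.26), transversions least (0.03). The annotator reproduces the classic
EMX1.6 spacer/off-target pair — a single wobble mismatch at PAM-anchored
position 13:

```r
annotateMismatches("gcgccacUgguugaugugau", "gcgccacCggttgatgtgat")
#>   position_pam spacer_base protospacer_base mclass five_prime_g
#> 1           13           U                C wobble        FALSE
```

And an smFRET experiment pairing a matched target (true unwound fraction
0.60) with a single-mismatch target (0.102) recovers the unwinding
specificity:

```r
f    <- fUnwoundFromTraces(simulateTraces(fretSpec(f_unwound_true = 0.6),
                                          2000, seed = 4))
f_mm <- fUnwoundFromTraces(simulateTraces(fretSpec(f_unwound_true = 0.102),
                                          2000, seed = 5))
unwindingSpecificity(f_mm, f)
#> [1] 0.84  (true value 1 - 0.102/0.6 = 0.83)
```

`runPipeline(pipelineConfig(...), outdir)` chains the stages
(simulate → quantify → stats → model → fret) and writes a manifest with
seeds and content hashes; reruns with an identical configuration are
bit-identical.

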