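---
title: "Models and methods behind optenrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optenrich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optenrich)
```

`optenrich` simulates and scores optical-enrichment pooled CRISPR screens:
cells are selected by an imaged phenotype, marked by timed photoactivation
of PA-mCherry, recovered by FACS, and scored from sgRNA sequencing counts.
This vignette documents the models, the tunable parameters and their
defaults, what the synthetic data do and do not emulate, and the numerical
conventions that make results reproducible.

## The library and population model

A screening library has genes clustered by transcription start site. The
default composition — 481 single-TSS genes, 63 two-TSS genes, 10 sgRNAs per
TSS, 22 nontargeting controls — totals 544 genes and 6,092 sgRNAs. A library
of 10 sgRNAs/gene cannot reach that sgRNA total with single-TSS genes alone;
allowing 63 genes a second TSS is the smallest departure consistent with
per-TSS clustering, and which genes get the second TSS is arbitrary (any
assignment with the same counts is equivalent for every statistic computed
here). Within each TSS, half the sgRNAs are labelled `top5` and half
`supp5`, emulating libraries split by predicted knockdown activity; per-sgRNA
efficacies are drawn from Beta(18, 2) (mean 0.9) and Beta(5, 5) (mean 0.5)
respectively, so subsetting to either class re-runs the analysis on a
realistic half-library.

Infection follows the low-MOI contract: each infected cell carries exactly
one sgRNA, drawn uniformly. Infection is reported by BFP, with
`ln(mean BFP)` at Normal(8.6, 0.5) for infected and Normal(6.6, 0.5) for
uninfected cells, so the 7.6 infection gate separates the populations with
about 2% loss on either side. Screens operate on puromycin-selected
populations, so the pipeline default is `infected_fraction = 1`; the
10–15% post-transduction regime is available through the same parameter.

Baseline nuclear area is log-normal with `sdlog = 0.62`, calibrated so the
99.5th percentile of control areas is exactly 1,000 µm² (median ≈ 202 µm²,
a plausible interphase RPE-1 nucleus). This ties the package's own
top-0.5%-of-controls screening gate to the 1,000 µm² threshold by
construction. A planted hit gene multiplies the area of phenotype-expressing
cells by `effect_size`; a cell expresses the phenotype with probability
`penetrance × efficacy(sgRNA)`.

**Choice of planted-effect defaults.** The pipeline runs at desk scale —
50,000 cells per imaging run instead of ~1.5 million — so per-sgRNA coverage
is ~8 cells rather than ~250. The limiting statistic is the expected number
of *sorted positive* cells per hit sgRNA per run: with the top-0.5% gate,
selection probability is `penetrance × efficacy × P(area > 1,000 | shifted)`
plus a 0.5% background. For the recovery experiments to be informative this
expectation must stay near or above one sorted cell per run, otherwise the
Poisson zero fraction dominates the Mann–Whitney ranks. The defaults
`effect_size = 4` (a 2 log2 area shift, within the range produced by
cytokinesis-failure and senescence phenotypes) and `penetrance = 0.6` give
`P(area > 1,000 | phenotype) ≈ 0.37` and ≈ 0.9 sorted cells per Top5 hit
sgRNA per run. Sort-only (FSC / H2B-GFP) screens have no imaging bottleneck
and default to 400,000 cells so the top-10% aliquot keeps ~5 recovered cells
per sgRNA; below that, sgRNAs at the zero-count pseudocount floor distort
the simulated-negative tail.

## Imaging and segmentation

Fields are rendered as uniform-intensity ellipses (1 px Gaussian edge blur)
over a camera offset, with optional Gaussian read noise and Poisson shot
noise, at 0.325 µm/px (a 20× objective on a 6.5 µm-pixel sCMOS; the value is
configurable and carried through all area computations). The ground-truth
label mask is always the exact raster, which is what the segmentation tests
score against. The generator does not model a PSF, autofocus, stage drift,
uneven illumination, or textured chromatin — so passing tests demonstrate
correctness of the measurement chain, not robustness to those artifacts.

Segmentation is deliberately classical and fast: Gaussian smoothing
(σ = 2 px), global Otsu threshold, hole filling, distance-transform
watershed (tolerance 2 px) to split touching nuclei, and removal of objects
under 40 µm². A global threshold on blurred edges biases area with cell
brightness — bright nuclei annex edge pixels, dim ones lose them, ±15% over
a two-fold intensity range — so each object is then re-thresholded at
background plus half its own interior median signal. The half-maximum
contour of a symmetrically blurred edge sits on the true boundary
independent of brightness; with this refinement, measured areas agree with
the analytic ellipse area to ~1%. Border-touching nuclei are excluded from
both the positive and the negative class: they are unanalyzed, exactly like
cells outside the imaged region.

## Photoactivation and sorting

The activation response is saturating first-order kinetics,
`I(t) = bg + (i_max − bg)(1 − e^{−t/τ})` with τ = 800 ms, plus
multiplicative log-normal noise (`noise_cv = 0.15`). Only the ordinal
structure matters to the method — distinct exposure times must map to
FACS-separable intensity populations — and with these defaults the
0/100/200/2,000 ms classes separate pairwise below 1% overlap except for the
adjacent 100 vs 200 ms pair. That pair cannot do better under any
parameterization of this model: `(1 − e^{−200/τ})/(1 − e^{−100/τ}) < 2` for
every τ, so the log-intensity gap between the two classes is bounded by
ln 2 and at cv 0.15 the two-class Bayes error is at least ≈1.6% (it is
≈2.1% at the defaults). Dual
activation therefore uses well-separated times (2,000 ms positives vs
100–200 ms negatives), where crossover is negligible.

Activation masks are the per-nucleus footprints eroded by 1 px: restricting
illumination to nuclei prevents photoactivating neighbors, and a one-pixel
guard is the most conservative margin that leaves small nuclei activatable. FACS gates are self-calibrated: class boundaries are placed
midway between the log-median intensities of reference populations activated
for known durations, with the lowest boundary at the 99.9th percentile of
the unactivated population. Sorted cells are recovered with probability 0.8
(FACS losses are real but unquantified; the value is configurable), and
sequencing draws reads multinomially over the sorted population's sgRNA
composition at depth 10⁶.

## Scoring, simulated negatives, and eFDR

Per-sgRNA scores use pseudocount 1, depth normalization, log2 ratio, and
centering on the nontargeting median (so the nontargeting null is exactly
zero by construction). Scores average arithmetically across runs; TSS groups
are tested two-sided against the 22 nontargeting scores by Mann–Whitney U
with midranks. The p-value is exact (from the null U distribution) whenever
`n1·n2 ≤ 10⁵` and the combined sample is tie-free; with ties it switches to
the tie-corrected normal approximation with continuity correction. An input
whose values are all identical is degenerate and returns p = 1. η is
`|ε| · (−ln p)` with the sign of ε retained separately; multi-TSS genes take
the TSS with maximal η.

Simulated negatives regroup *all* sgRNAs (targeting and nontargeting) into
groups of 10 and score them exactly like genes. The package draws 100
independent regroupings by default. The choice is driven by resolution: an
eFDR target of 0.1% cannot be estimated from a single draw of 609 null
scores — under a fully null screen the top pooled score is then a real gene
with probability ≈ 544/1153, so the top-cutoff rule would emit a false hit
in roughly half of null screens. With ~61,000 null scores that probability
drops below 1%. To keep the counting formula on the scale of one library,
the simulated-negative exceedance count is divided by the number of draws,
which reduces to the raw formula at one draw.

The eFDR is evaluated at every observed score, monotonized by a running
maximum from the highest cutoff downward (so it is non-increasing in the
cutoff, and the monotone value never understates the raw one), and the hit
cutoff is the smallest observed score whose monotone eFDR is at or below the
0.1% target. Exceedances are strict: scores tied with the cutoff are not
hits. One consequence worth knowing: when planted effects are strong, the
regrouped null inherits a contamination tail (random groups catching several
hit sgRNAs), which pushes the cutoff above the real-gene null — the
procedure is conservative in exactly the situations where hits are easy.

Replicates are analyzed independently and their hit lists intersected.
Sorted true negatives are the default reference; using the unanalyzed bulk
instead is supported and demonstrably yields a smaller separation between
hit and null groups whenever the positive fraction is non-negligible,
because the bulk contains the positives.

## Reproducibility and numerical conventions

Every stage derives its own sub-seed deterministically from the master seed,
so a configuration plus seed reproduces byte-identical output files; each
output TSV carries the seed and a hash of the configuration in a header
comment. Quantiles are type-7 (linear interpolation between order
statistics) everywhere, pinned so the top-0.5% gate is reproducible.
Top-fraction flow gates take exactly `round(f·n)` events. Image data
round-trip bit-exactly through 16-bit TIFFs.

Problem sizes are chosen once and stated here: null-calibration suites run
100 screens of the full 6,092-sgRNA library at depth 10⁶; recovery suites
run the full 4 × 2 × 50,000-cell design over 10 seeds; mock screens run
100,000 cells against the 860 + 6,100 barcode libraries. These sizes keep
the complete test suite in the minutes range on one CPU while preserving
the coverage ratios that the statistics depend on.

## Known limitations

The simulation treats detection as a per-cell Bernoulli process in the
cell-record pipeline rather than re-running segmentation on rendered images
for every screen (segmentation is validated separately against ground
truth); it does not model cell-cycle structure, fitness effects of
knockdowns, spectral spillover, doublets, or sequencing PCR bias. The
Mann–Whitney exact path assumes exchangeability under the null, which the
multinomial count model satisfies but real per-run batch effects may not —
run averaging is the only batch control implemented, matching the design it
emulates.
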