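---
title: "Extracting cell-cycle expression profiles from snapshot cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting cell-cycle expression profiles from snapshot cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytocycle)
```

## The measurement model

A snapshot of an asynchronous, exponentially growing culture contains
cells at every stage of the cycle. For a marker whose expression is a
programmed, single-valued function of cell-cycle position, the population
therefore samples the whole expression curve at once. Two facts turn this
into a measurement principle:

1. **Frequency is residence time.** The fraction of cells found inside any
   region of marker space is proportional to the time a cell spends
   traversing that region — up to the age-distribution correction below.
   Plotting a region's median expression at the center of its cumulative
   frequency interval, `x_i = Σ_{j<i} f_j + f_i/2`, lays the regions out on
   a 0–1 axis equal to one cell-cycle time.
2. **Unidirectionality.** The regions must discretize a trajectory that a
   cell traverses in one direction exactly once. A marker that rises and
   falls (PHH3 in mitosis) is ambiguous against DNA content alone, because
   rising and falling cells occupy the same place; adding a mitotic cyclin
   resolves the ambiguity: while PHH3 rises, the cyclin is high; while the
   cyclin falls, PHH3 is constant; PHH3 falls only after the cyclin is
   gone. Assignment is therefore done with ordered polygon regions across
   one or more bivariate views, each with a boolean gate context, and the
   global order is validated on synthetic data by checking that the median
   true position is strictly increasing across regions.

**Age distribution.** Binary division makes newborn cells twice as
frequent as dividing ones: the density of normalized age is
`2 ln2 · 2^(-a)`, with CDF `F(t) = 2(1 − 2^(−t))`. `frequency_to_time()`
inverts this (`t = −log2(1 − x/2)`); profiles default to the raw frequency
axis because that is the conventional plotting scale, and the package
deliberately does not correct for the one-mitotic-to-two-G1 wrap at
division — the frequency axis simply ends where the cycle does.

## Region construction rules

* Dividing sides between consecutive regions are perpendicular to the
  local slope of the data backbone (the modal ridge of the bivariate
  density), so that each region approximates a slice of the local 2-D
  error distribution. `build_orthogonal_regions()` computes each dividing
  side's two vertices once and reuses them for both neighbors: shared
  edges coincide exactly, so bands have zero overlap and zero gap by
  construction (verified in the tests by an independent polygon-clipping
  oracle).
* Terminal clusters whose internal spread is measurement error only (the
  G1 cluster, the late-mitotic cluster) are enclosed by single regions.
  Subdividing them would convert noise into spurious expression changes.
  In practice these regions are set from the data density, as the
  reference scheme does from the model's landmarks.
* Point-in-polygon uses the even-odd rule with boundary points counted as
  inside; regions are tested in global order and the first containing
  polygon wins, so shared-edge ties resolve deterministically toward the
  earlier region.
* Geometry operates in display coordinates: each view carries per-axis
  transforms (`linear`, `log10`, `asinh`) and events are transformed
  before containment tests.

## The synthetic generator

`phase_model()` defines the study conditions; they are fixed defaults, not
tuning knobs.

* **Phase time fractions** `(G1, S, G2, M) = (0.30, 0.40, 0.244, 0.056)`.
  After age weighting these place cyclin B1's accumulation onset at
  cumulative frequency ≈ 0.32 and cyclin A2's at ≈ 0.38 (the breakpoints
  used by the piecewise fits), and give a mitotic fraction of ≈ 4% — the
  scale of a typical lymphoblastoid culture.
* **DNA**: constant 2C (= 200) in G1, linear to 4C across S, constant 4C
  in G2+M; CV 3% (typical DAPI stoichiometry).
* **Cyclin A2**: zero through G1; second-order polynomial rise through
  early/mid S; exponential rise through late S/G2 to a peak of 100 at
  mitotic entry; a brief entry dip to 70 and a prophase plateau; steep
  exponential decay to its floor at u = 0.982.
* **Cyclin B1**: low but nonzero in G1 (5); slow exponential from late G1
  (u = 0.25), faster exponential after S/G2; entry dip and plateau; decay
  to its floor at u = 0.990 — after A2, before PHH3.
* **PHH3**: baseline 2; ramp beginning in late G2 (u = 0.925, when
  H3S10 phosphorylation initiates), saturating at 100 early in M; decay
  only after B1's floor, completing at u = 0.998. The ordering
  `u_A2 < u_B1 < u_PHH3` is asserted on the curve definitions.
* **Noise**: multiplicative log-normal (mean 1) per channel — CV 0.10 for
  the immunofluorescence channels, 0.03 for DNA, 0.15 for side scatter —
  reflecting that immunofluorescence distributions are approximately
  log-normal. `sample_replicates()` additionally draws one log-normal
  staining scale factor per channel per replicate (CV 0.05 for antibody
  channels, 0.01 for DNA), because separately stained samples carry
  staining error on top of sampling error.
* **Scope**: the generator emulates marker programs, age structure,
  measurement and staining noise, and an optional uniform contaminant
  cloud. It does not emulate lineage structure, growth-rate variability,
  spectral spillover between dyes, or doublet formation; passing tests
  therefore demonstrate correctness of the extraction machinery under a
  faithful single-cycle model, not robustness to every instrument
  artifact.

## Numerical and design choices

* **Center statistics**: median within regions; mean of medians across
  replicates, with SEM and t-based 95% CI.
* **Boundary points**: profiles are completed by flagged synthetic points
  at x = 0 and x = 1 and at declared expression-regime transitions, by
  linear extrapolation from the two nearest points of the adjoining
  stretch (constant extension, with a warning, when a stretch has a single
  point). These points anchor the steep transitions that interval-center
  points would otherwise cut across; panel merging interpolates over the
  completed profiles.
* **Recovery metric**: `profile_rmse()` defaults to frequency-weighted
  RMSE — the L2 error over the cumulative-frequency axis — because each
  point represents an interval of cells equal to its event fraction.
* **1-D segmentation boundaries**: terminal boundaries default to the
  equal-density crossing between each bounding component and its nearest
  S component, which balances misclassification in both directions; a
  mean ± k·sd rule is also provided. With six evenly spaced S components
  the crossing rule is the one that leaves the bounding clusters' recovered
  fractions unbiased at the G2+M end.
* **Contour gates**: kernel density on a 128×128 grid with Silverman
  bandwidths; the gate level is the percent of the probability mass of the
  contiguous population around the main mode (connected component above a
  0.2%-of-peak density floor). Defining the level over all events instead
  would force any 99% gate to retain most of a diffuse contaminant cloud.
* **Background subtraction**: a single Theil–Sen slope of cyclin on side
  scatter within a cyclin-negative reference population, subtracted from
  all events — the linear, spillover-style correction; the corrected
  reference median should sit within 1% of the channel's 90th percentile
  of zero. For n > 3000 the estimator uses the deterministic offset
  pairing of x-sorted points, keeping it reproducible and O(n).
* **Mitotic gate**: threshold at the density minimum between the
  interphase mode and the strongest mode at least ~4.5-fold above it on
  the asinh scale, computed within its gating context; a manual override
  is supported because real gates are often placed visually. With a
  continuous PHH3 ramp (no empty valley) the automatic threshold falls
  just above baseline — the override is the right tool there.
* **EM mixture fitting**: bounding components initialized at the
  histogram's two modes (the second sought near twice the first), S means
  evenly spaced and clamped strictly inside the bounding means after every
  M-step; convergence at relative log-likelihood change < 1e-8, sd floor
  of a quarter bin width with pruning.
* **Exponential trend fits**: nonlinear least squares initialized from the
  log-linear fit; rate comparisons use the average relative growth rate
  over each segment's domain, which equals the fitted `k` for exponential
  segments and remains defined for polynomial ones.

## Problem sizes

The packaged experiments use 50,000 events per sample (the desk-scale
proof-of-principle and the replicate comparisons) and 10^6 events per
panel for the independent-panel merge, the latter because the merge
deviation metric is alignment-limited at steep features and a full-scale
acquisition is the realistic setting for that question. Three replicates
are used wherever replicate dispersion is reported.

## Known limitations

* At near-vertical profile features (the terminal PHH3 dephosphorylation
  step spans ~0.4% of the frequency axis) any fixed-x comparison of two
  independently measured profiles is conditioning-limited: the deviation
  equals the local slope times the binomial noise of the cumulative
  frequency estimate, several percent of range even for perfect
  extraction. Ordering statements (which marker falls first) are robust;
  pointwise max-deviation statements at such features are not.
* The mitotic-exit wrap is not corrected: cells past the last resolvable
  mitotic state are genuinely indistinguishable from G1 in cyclin/PHH3
  space, and rejoin the cycle start unless DNA content separates them (the
  reference scheme's terminal 4C region does exactly that).
* Indirect (third-channel) profiles assume the channel does not oscillate
  within any single region; regions set on two channels are blind to
  structure orthogonal to their plane.
* Automatic backbone ridge tracing is a convenience for well-behaved
  density ridges; the supported workflow for complex data is manual
  anchors, mirroring how such schemes are set in practice.
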