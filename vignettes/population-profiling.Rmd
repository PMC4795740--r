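---
title: "Population profiling and cell-cycle gating: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population profiling and cell-cycle gating: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wellpop)
```

## Scope and data model

`wellpop` starts where image analysis ends: a CSV table with one row per
segmented cell, carrying at least a well label, a treatment label and one
numeric measurement. Nothing upstream (segmentation, feature extraction)
is attempted, and one measurement is processed at a time. Each input file
is one independent experiment — files are never merged, even when they
share well labels.

The reduction chain is

*cells → wells → histogram vectors → gated class fractions*,

with the per-well cell count kept alongside as a statistical-relevance
flag (a very low count usually means cell death, and population statistics
from a handful of cells mean little). All cells from the designated
negative-control wells are additionally pooled into one
`POOLED_CONTROL` record, which anchors binning, reference peaks and gates.

## The DNA-content model

Integrated DNA-stain intensity is proportional (ideally) to DNA amount,
so G1 cells cluster at one intensity, G2/M cells at twice that, and
S-phase cells span the gap. We work throughout in `log2` intensity, where
that doubling is a unit shift and the two clusters are symmetric, similar
spreads.

**Binning.** Histograms use plate-wide equal-width bins in log2 space:
64 bins spanning `[p1 − 3·IQR, p99 + 3·IQR]` of the pooled control (`p1`,
`p99` percentiles and interquartile range of the pooled control's log2
intensities). Shared edges are what make the saved histogram vectors
comparable across wells — per-well ranges would make bin *i* mean
different things in different wells. The generous padding keeps strongly
shifted treated wells (polyploidy, debris) inside the histogram range;
values that still fall outside are excluded from the vector but tallied,
and classification never depends on the histogram range because cells are
always classified from their raw values.

**Smoothing.** Counts are convolved with a discrete Gaussian kernel,
σ = 1.5 **bins**, truncated at 4σ, with reflect-padded boundaries. σ is
deliberately a bin-unit quantity: it belongs to the histogram filter, not
to the measurement axis, so its effect is independent of the plate's
intensity scale. Reflect padding keeps a constant signal exactly constant
and conserves total mass exactly for a symmetric kernel (the tests bound
the drift at 0.5% defensively, and check the convolution against a dense
direct-summation oracle at 1e−9). Smoothing exists **only** for peak and
valley detection and for display; per-cell classification always compares
raw values against gate boundaries.

**Peak detection.** A peak is a bin strictly greater than both neighbors;
an equal-valued plateau flanked by lower bins counts once, at its leftmost
bin; the first and last bins qualify against their single neighbor; ties
in height rank by lower bin index. These conventions make detection
deterministic on discrete count data, where exact ties are common.

**Reference peaks.** On the smoothed pooled control, the 2N center is the
highest local maximum. The 4N center is the highest maximum strictly to
its *right*, not simply the second-highest maximum overall: apoptotic
sub-G1 debris can form a peak taller than G2/M, but it lies left of 2N
and can never be tetraploid. Fewer than two maxima, or none to the right,
aborts with an instruction to gate manually.

**Normalization.** Both stated anchors — 2N peak at 1 *and* 4N peak at 2 —
cannot in general be satisfied by one linear scaling when staining is
sub-proportional (`p4N ≠ 2·p2N`, routinely observed as ratios around
1.8–1.9). We therefore use the affine map in log2 space,

$$u(x) = \frac{\log_2 x - \log_2 p_{2N}}{\log_2 p_{4N} - \log_2 p_{2N}},
\qquad \tilde{x} = 2^{u(x)},$$

which is strictly increasing, hits both anchors exactly, and reduces to
`x / p2N` in the proportional case. Since the pipeline's measurement is
defined in log2 units to begin with, affine-in-log2 is also the natural
family to normalize within.

## Gating

Default gates on the normalized axis:
`<2N = [0, 0.75)`, `2N = [0.75, 1.25)`, `S = [1.25, 1.75)`,
`4N = [1.75, 2.5)`, `>4N = [2.5, ∞)`. All intervals everywhere in the
package are half-open `[lower, upper)` — a value exactly at a threshold
joins the upper class. That convention is arbitrary but deterministic and
applied uniformly, including in manual gating.

**Adaptive adjustment.** Treatments can translate or reshape a well's
histogram (cell size, stain uptake) without changing class identity, so in
adaptive mode the interior boundaries follow each treated well's own
shape. The rule is the standard univariate valley-seeking heuristic:

1. Within each of the five default class intervals, find the highest
   smoothed local maximum of the well's normalized histogram (its
   "region peak"); a region may have none.
2. A boundary flanked by region peaks on *both* sides moves to the
   minimum of the smoothed histogram between the two peak bins (leftmost
   bin center on ties); a boundary with a missing flank keeps its default.
3. Every adjusted boundary is clamped to ±`adapt_clamp` (default 0.15) of
   its default value.

The clamp is the implementation's concrete reading of "within limits
defined by the control's 2N and 4N peaks": defaults live on the axis
anchored by those peaks, and 0.15 is under half the smallest default
class width, which guarantees the adapted gates stay ordered and
non-overlapping. With no peaks at all the control gates are returned
unchanged. Control wells themselves are never adapted — adjustment is a
treated-well analysis — so on a plate of controls, adaptive and fixed
gating coincide exactly; this is also the behavior fixed mode offers for
every well.

On a typical control-shaped well the S-phase population is a shoulder,
not a separate smoothed maximum, at the default bin width, so the 2N/S
and S/4N boundaries stay at their defaults; a well with a genuine
S-region mode (e.g. an early-S arrest) triggers valley placement, which
approximates the minimum-density (near-Bayes) boundary between adjacent
mixture components.

**Manual gating** accepts any number of named, non-overlapping intervals
on any measurement column (protein-translocation or EdU-incorporation
style analyses). Gaps are legitimate there, and gapped values are
reported in an explicit `ungated` tally rather than silently dropped —
silent dropping would corrupt the reported fractions.

## Comparison of profiles

Sub-population profiles are compared by Pearson's correlation of their
class-fraction vectors (fractions, not counts, so wells with different
cell numbers are comparable). A constant vector has no defined
correlation and raises an error; in a correlation matrix such pairs are
recorded as `NA` rather than silently imputed.

## The synthetic-data generator

`well_spec()`/`generate_plate()` draw each cell from a five-component
log-normal mixture on the intensity axis. With 2N center `I` and 4N/2N
stain ratio `r` (default 2), component centers sit at
`I·{0.5, 1, √r, r, 2r}` for `<2N, 2N, S, 4N, >4N`; each component gets
multiplicative log-normal noise with coefficient of variation `cv`
(default 0.05), median-centered so the component mode stays at its
center. Class weights are per-well. The ground-truth table records the
*realized* component draws, which is the exact oracle for recovery tests.
Generation is deterministic under the plate seed and leaves the caller's
RNG stream untouched.

Defaults emulate a clean adherent cancer-line screen: 2000–5000 analyzed
cells per well, a control well around 60% G1 / 13% S / 22% G2/M with 2%
debris and 3% polyploid, and treatment presets that are *illustrative
archetypes* (S-arrest, G2/M-arrest, osmotic stress, crosslinker), not
measured values. The generator deliberately omits much of what real
plates contain: debris is a tight bump at `0.5·I` rather than a broad
smear, there are no segmentation errors (doublets appearing at 4N), no
illumination or edge-of-plate gradients, no staining drift across the
plate, and S-phase is a single log-normal rather than a flat ramp.
Passing recovery tests on these plates therefore demonstrates the
*pipeline's* correctness on known mixtures — not robustness to every
artifact of real screens, where the manual-gating escape hatch and the
cell-count column earn their keep.

## Numerical conventions and degenerate inputs

* Histogram bins: `[e_i, e_{i+1})`, last bin closed; out-of-range values
  excluded but counted.
* Non-finite measurements and empty well labels are dropped at import,
  tallied per file, and reported.
* Non-positive intensities cannot be log-transformed: up to 1% of cells
  they are excluded with a warning and a count; beyond that the input is
  treated as corrupt and the run errors.
* A well with conflicting treatment labels is an error (well → treatment
  must be a function), not a warning.
* Zero-cell wells classify to all-zero counts, fractions reported as 0
  with a `zero_cells` flag.
* Fractions are written with 6 decimals; counts exactly. A written
  profile table re-read gives counts identical and fractions to ≤1e−6.

## Problem sizes in the test suite

The suite runs synthetic plates of 1–22 wells at 500–5000 cells per well
(50 000 for the convergence check), 100 randomized smoothing fixtures
against the dense-convolution oracle, exhaustive peak-finder enumeration
over all ~10 000 count patterns of length ≤ 8, and 1000 randomized
conservation cases — sizes chosen so the whole suite completes in about
two minutes on one core while keeping every statistical tolerance
(±2 percentage points class-fraction recovery, ±0.03 mixture-weight
recovery) several standard errors wide at the simulated n.

## Known limitations

* No parametric cell-cycle model fitting (Watson, Dean–Jett–Fox): the
  package gates, it does not fit — S-phase tails under the 2N/4N peaks
  are attributed to the peak classes.
* No aneuploidy or multi-clone deconvolution; a mixed-ploidy well will
  anchor on the dominant clone's peaks.
* One-dimensional gating only; no polygon gates on measurement pairs.
* Reference detection assumes the pooled control is at least bimodal
  after smoothing; heavily perturbed "controls" require manual gates.
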