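---
title: "Calibrating and integrating coverage tracks with the complement of the minimum Bayes' factor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating and integrating coverage tracks with the complement of the minimum Bayes' factor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmbftrack)
```

## The problem

ChIP-seq, ATAC-seq and related assays produce genome-wide read-depth
tracks in which the features of interest — transcription-factor binding
sites, open chromatin, histone marks — appear as localised enrichments on
top of pervasive background noise. Replicates are commonly peak-called one
at a time and then intersected, which discards most of the quantitative
agreement between tracks. `cmbftrack` instead calibrates every track onto
a common probability scale and combines tracks multiplicatively, producing
one integrated track that downstream peak callers or browsers can consume.

## Model and procedure

A track is a vector of read depths $r_i$ over fixed-width bins. The
pipeline has two stages.

**Calculator.** The local background noise at bin $i$ is estimated as a
scaled sliding-window median,
$$ n_i = m \cdot \mathrm{median}\{ r_j : |j - i| \le h \}, $$
computed per chromosome, and coverage is transformed through the
complement of the minimum Bayes' factor,
$$ p_i = 1 - \exp\!\left(-z_i^2 / 2\right), \qquad z_i = r_i / n_i. $$
$\exp(-z^2/2)$ is the minimum Bayes factor: the strongest evidence
against the null ("no signal, $r_i$ is background") attainable from a
z-statistic. Its complement is used here purely as a calibration — a
monotone map from depth onto $[0, 1)$ with $p_i = 0$ exactly where
$r_i = 0$ — not as a hypothesis test; no testing machinery is attached.

The median is a valid background estimator only under a sparsity
assumption: true-signal regions must occupy well under half of any window,
so the windowed median sits at the background level rather than inside
peaks. This is the method's central premise and holds for typical
punctate-signal assays; it degrades for very broad domains (see
Limitations).

**Integrator.** Given calibrated tracks $p_{k,i}$, $k = 1 \dots K$, the
integrated value is the per-bin joint probability
$$ P_i = \prod_{k=1}^{K} p_{k,i}, $$
evaluated as sequential pairwise products; commutativity and
associativity of multiplication make the result independent of input
order. Since background values are well below 1 in every track while
shared signal is near 1, the product shrinks unreplicated background much
faster than shared peaks, which is the source of the method's
signal-to-background sharpening. Both stages cost $O(kw)$ time for $k$
bins and window size $w$, and linear memory.

## Tunable parameters

| parameter | unit | default | role |
|---|---|---|---|
| `window_bp` | bp | 10000 | sliding-window size for the background median; wide enough to dwarf typical punctate peaks, narrow enough to track local coverage trends |
| `median_multiplier` | — | 2 | scale $m$ on the windowed median; the margin above the typical background level that coverage must clear before $z$ grows |
| `zero_replacement` | depth units | 0.1 | substituted when $m \cdot \mathrm{median} = 0$, keeping $n_i$ a valid divisor in fully unmapped or empty regions |
| `precision` | decimals | 6 | output formatting; probabilities below $10^{-6}$ are indistinguishable from 0 downstream |
| `missing_policy` | — | `"error"` | handling of bins present in only some tracks: abort, treat as 0, or intersect |

The window is given in bp and converted to a per-side half-width of
$h = \lfloor \texttt{window\_bp} / (2 \cdot \texttt{bin\_size}) \rfloor$
bins, symmetric about each position. With the defaults on 10 bp bins the
window spans 1001 bins.

## Numerical and boundary choices

* **Window truncation.** Windows truncate at chromosome ends and never
  span chromosome boundaries; no padding, mirroring or wraparound is
  invented. Truncated windows near boundaries can have an even count, in
  which case the median is the conventional mean of the two central order
  statistics. Interior windows are always odd ($2h + 1$) and are computed
  with `stats::runmed`'s running-median algorithm; only the boundary
  positions are evaluated directly.
* **Zero replacement target.** The replacement applies to the *scaled*
  median $m \cdot \mathrm{median}$, not to raw coverage: the only
  degenerate case in the pipeline is a zero divisor in $z_i = r_i / n_i$,
  and replacing raw zeros would bias medians in sparse regions.
* **Range handling.** $1 - \exp(-x)$ lies in $[0, 1)$ for $x \ge 0$, so
  probabilities need no clamping. Integration inputs outside $[0, 1]$ are
  a hard error rather than being clamped — they indicate raw coverage was
  passed where a probability track was expected.
* **Order invariance.** A single pairwise product is exactly commutative
  in floating point; chained products across three or more tracks can
  differ in the last ulp between orderings, so associativity is asserted
  to within one ulp in the tests, never exactly.
* **Degenerate inputs.** Empty tracks flow through every stage as empty
  results. A window smaller than one bin is rejected. Bins that overlap
  between two integration inputs without sharing boundaries indicate
  different grids and always abort with advice to `rebin()`; `rebin()`
  aggregates by the arithmetic mean so the width-weighted mean over any
  whole region is preserved.
* **Coordinates.** 0-based half-open throughout (the BED convention of
  the coverage tools that produce the inputs). Chromosome order is the
  order of first appearance in the input; no genome build or karyotype
  order is assumed.

## The synthetic-track generator

Testing needs tracks with known truth, so the package generates
single-chromosome tracks with a flat background (mean depth 5 by default,
the regime of a moderately sequenced input) and rectangular (boxcar)
peaks. Two noise models are provided: `"constant"`, where every bin takes
exactly its mean — used for exact-value contracts such as "background is
exactly $m \times$ rate everywhere" — and `"poisson"`, where each bin is
an independent Poisson draw, matching the counting nature of read depth.
A bin inside a peak draws from Poisson(background + height): a peak adds
mean depth and values stay integer counts. Replicates share peak
coordinates and heights but use one RNG seed per replicate, emulating
independent sequencing of the same biology. The generator enforces the
estimator's sparsity premise (total peak width below 50% of the
chromosome) so a fixture cannot silently violate the model it is meant to
exercise.

What the generator does *not* emulate: mappability gaps, GC and
copy-number biases, fragment-length autocorrelation between adjacent bins,
chromatin-state-dependent background, or asymmetric peak shapes. Passing
tests therefore demonstrate the algebraic and statistical contracts of the
method — calibration, background estimation, multiplicative sharpening —
not robustness to every artefact of real libraries; on real data those
artefacts enter through the background estimate and are mitigated, not
removed, by the windowed median.

Default verification sizes are deliberately desk-scale: chromosomes of
20–200 kb at 10 bp bins (2,000–20,000 bins), four replicates, and runtime
trend checks up to 800,000 bins. The method itself is linear in genome
size, so these sizes exercise every code path that a genome-scale run
would.

## Design choices where the design was open

* **Bin versus nucleotide granularity.** The transform is defined per
  position but inputs arrive pre-binned (commonly 10 bp); the package
  works at whatever resolution the input provides and never resamples
  implicitly.
* **Configurable multiplier.** The $2\times$ median background convention
  is exposed as `median_multiplier` rather than hard-coded; 2 is the
  default everywhere.
* **Missing bins.** Genome-wide tracks on a common grid are the expected
  input, so the default policy for bins present in only one track is an
  error; `treat-as-zero` (union grid, absent means no evidence) and
  `intersect` (drop) are offered for ragged real-world inputs.
* **Output precision** is a parameter (default 6 decimals) since the
  rounding behaviour of emitted probabilities is otherwise unspecified.

## Limitations

* Broad-domain signals (large H3K27me3 or lamina domains) can occupy a
  large fraction of a window, inflating the median and deflating $p_i$;
  the sparsity premise is essential.
* The joint probability treats tracks as independent evidence; technical
  correlation between replicates (shared input DNA, shared mapping
  artefacts) makes the integrated background optimistically low.
* A track whose coverage is zero almost everywhere gets $n_i =$
  `zero_replacement`, so isolated single reads can score high
  probabilities; inspect very sparse libraries before integrating them.
* BigWig I/O is out of scope; bedGraph output converts externally
  (`bedGraphToBigWig`).
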