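---
title: "Scoring spheroid z-stack quality: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring spheroid z-stack quality: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sqm)
```

`sqm` quantifies how sharply the interior of a 3-D spheroid is resolved in
a fluorescence z-stack, slice by slice, so that optical clearing protocols
can be ranked objectively. This vignette explains the models behind each
stage, the conventions and defaults we chose where several were defensible,
what the synthetic phantom does and does not emulate, and the limitations
we know about.

## Why slice-wise, no-reference metrics

There is no ground-truth "sharp" image of a cleared spheroid to compare
against, so all seven focus measures are no-reference statistics of a
single optical section. Light scattering degrades sections progressively
with depth, so the unit of analysis is the per-slice metric plot $g(j)$,
$j = 1..n$ from the top of the stack: the *shape* of that curve (how fast
sharpness decays into the sample) carries the clearing information, not any
single value.

All statistics use the population convention (denominator $MN$, never
$MN-1$), matching the defining variance formula of the intensity metric;
the same convention is applied to the gradient-magnitude and Laplacian
variances.

## Masking and normalization

Three conditions precede any pixel-statistics metric:

1. **Foreground restriction.** Background pixels carry no information about
   the sample, so metrics are restricted to the per-slice Otsu foreground.
   Otsu runs per slice, not per stack, because attenuation shifts the
   foreground/background separation with depth. The histogram uses 256 bins
   on $[0,1]$ (the 8-bit convention; the source is silent on binning), the
   threshold is the upper edge of the winning cut, ties take the lowest
   maximizing cut, and membership is strictly above the threshold. A
   constant slice has no separable classes: its mask is flagged degenerate
   and every downstream statistic of that slice is `NA` — never silently 0,
   which would bias stack scores.
2. **Stack-max normalization.** Intensities depend on staining and exposure;
   dividing every pixel by the *stack-wide* maximum maps each stack to
   $[0,1]$ while preserving the depth profile of brightness within the
   stack. Normalization happens before Otsu and before every metric.
3. **Internal circle.** Clearing agents that fail to penetrate leave a
   sharp rim around a blurred core; whole-foreground metrics then
   overestimate quality. The internal-circle mask keeps pixels strictly
   inside a circle of radius $r$ centered on the intensity-weighted
   centroid ($M_{10}/M_{00}$, $M_{01}/M_{00}$, computed over the Otsu
   foreground so background noise cannot drag the center). The centroid is
   recomputed on every slice, following the slice-by-slice design of the
   rest of the pipeline. Coordinates are 0-based with $x$ = column,
   $y$ = row.

The default radius is 200 px, appropriate for full-resolution light-sheet
frames; for the 256-px phantoms below we use $r = 60$, which keeps the
circle inside the spheroid's mid-stack cross-section (radius 100 px) in the
same proportion.

## Metric conventions worth knowing

* **Derivatives.** Gradients use central differences in the interior and
  one-sided differences on the borders — the minimal discretization of the
  continuous $\partial I/\partial x$. The Laplacian is the 4-neighbor
  stencil with replicate padding. Derivatives are always computed on the
  full slice and only then restricted to the mask, so mask boundaries do
  not manufacture edges.
* **Histogram threshold.** $T$ is the mean masked intensity and the metric
  sums $x_i f(x_i)$ over bins *strictly above the bin containing* $T$.
  Discretizing $T$ to the histogram domain is what makes the analytic
  anchors exact: a constant slice scores 0 (its only bin is never strictly
  above itself), as does an all-zero slice. $f$ counts raw pixels, and bin
  centers stand in for $x_i$.
* **Histogram entropy.** Implemented exactly as the $H_{max}$-normalized
  form $-\sum (f/H_{max})\log_2(f/H_{max})$, with empty bins contributing
  0. Note a quirk inherited from this definition: a single-bin histogram
  scores 0, but so would a perfectly uniform histogram in the limit of one
  bin per value class dominating — the form is *not* the sum-normalized
  Shannon entropy. A sum-normalized alternative is available via
  `normalization = "sum"` and is clearly marked as a departure.
* **Frequency threshold.** The forward DFT is the plain (unnormalized)
  sum; frequency indices are centered integers. The metric sums $|F|$
  strictly outside the circle $u^2+v^2 \le r_{freq}^2$. The high-pass
  radius was never fixed by the original analysis, so it is exposed;
  the default is $\min(M,N)/4$. A radius of 0 excludes nothing (the
  radius-0 disk is empty), so the sum then includes the DC term. The
  periodogram satisfies $\sum|F|^2 = MN\sum I^2$ under this convention,
  which the test suite asserts.
* **Kurtosis.** The periodogram $A=|F\bar F|=|F|^2$ is normalized to a
  probability distribution $h$ over centered frequencies and summarized by
  the bivariate kurtosis $\beta_{2,2}$ built from standardized moments
  $\gamma_{k,l}$ and the frequency correlation $\rho_{12}$. Degenerate
  cases return `NA`: a constant slice ($h$ a delta at DC, zero marginal
  variance) and $|\rho_{12}|=1$ (zero denominator). Kurtosis is the one
  metric where *lower* is sharper.

### How kurtosis actually behaves under blur

Blur drains the other four intensity/derivative/frequency metrics
monotonically, and the test suite asserts strict decrease across Gaussian
blurs of $\sigma \in \{0,1,2,4,8\}$ px on phantom slices. Kurtosis is more
subtle, and worth understanding before trusting it on smooth data. Strong
blur concentrates $h$ near DC over a residual floor, which drives
$\beta_{2,2}$ up — heavy and light defocus separate reliably. But near the
sharp end two effects run the other way: (i) sensor noise has a flat
spectrum whose heavy tail *inflates* the kurtosis of an unblurred slice, so
the first unit of blur can lower it; and (ii) on content whose spectrum
is already near-Gaussian — such as the Gaussian-blob nuclei of our
phantoms — $\beta_{2,2}$ is nearly scale-invariant, so small blurs change
it little and not always upward. Both effects are properties of the
statistic (the implementation agrees with a direct nested-loop evaluation
to 1e-8), and both are visible in the test suite: strict monotonicity from
$\sigma = 0$ holds on flat-spectrum noise images, while on phantom slices
only the ordering of heavier blurs is stable. On real nuclei images, which
carry sharp chromatin texture, the sharp end sits further from the
Gaussian regime; still, we recommend the variance-family metrics for
routine protocol ranking and treat kurtosis as corroborative.

## The single-value score

Plots assessed jointly form an assessment set; with $\alpha$ and $\beta$
the maximum and minimum over *all* plots in the set,

$$\mathrm{score}_i = \frac{1}{(\alpha-\beta)n}\sum_{j=1}^n (g_i(j)-\beta).$$

We compute it as $(\bar g_i - \beta)/(\alpha - \beta)$ — the same algebra,
but exact in floating point at the extremes, so a plot pinned at the set
maximum scores exactly 1 and at the minimum exactly 0. The score is
invariant under jointly applied affine maps $g \mapsto ag+b$ ($a>0$),
which the suite checks to 1e-12 on random sets.

Design choices around the score:

* **The pool is explicit.** Scores are only comparable within the set that
  provided $\alpha,\beta$. Pooling across protocols answers "which protocol
  cleared this cell line best"; pooling across cell lines answers a
  different question. `score_regions()` therefore takes `pool =
  "by_region"` (each stack third normalized against the same third of the
  other stacks — the default) or `"global"`, and never decides silently.
* **NA slices** (degenerate masks) are excluded from the $\alpha/\beta$
  pool and from the plot's own mean and $n$. Real stacks rarely produce
  them; phantoms and edge cases do.
* **Regions.** The slice axis splits into thirds at
  $\mathrm{round}(n/3)$ and $\mathrm{round}(2n/3)$ (a 10-slice stack
  splits 3/4/3). If the set's values are all equal the set is flagged
  degenerate and scores are 0.
* **1–5 rescale.** The min–max map onto $[1,5]$ exists to share a scale
  with expert scoring; it is monotone, so Pearson correlations are
  unchanged by it — the rescale is presentational and applied after
  scoring, before export. An all-equal set maps to the midpoint 3 with a
  warning.

## Statistics

Agreement with expert tables is summarized by Pearson's $r$ and an OLS fit
(expert on metric), overall and per region; unmatched (stack, region) pairs
are reported, never dropped silently. Group comparisons use the
Kolmogorov–Smirnov check against a fitted normal per group (motivating the
non-parametric route), the Kruskal–Wallis rank test, and Dunn's $z$-test on
pooled mean ranks with tie correction for the pairwise comparisons. The
multiplicity adjustment was unspecified in the source analysis; we default
to Holm — conservative, assumption-free — and expose the method. An
optional reference group restricts the Dunn family to control comparisons
and re-adjusts over the smaller family.

## The phantom: what it emulates, what it does not

`generate_phantom()` builds a sphere of Gaussian-blob nuclei (σ = radius/2)
placed uniformly at random, sampled into $n$ slices, then degraded with a
depth-linear model:

$$\sigma(j) = \sigma_0 + s_{ax}(j-1)(1-q),\qquad
  a(j) = e^{-\mu_{ax}(j-1)(1-q)},$$

plus optional lateral blur growing with distance from the illuminated left
edge at $s_{lat}(1-q)$ per pixel, Gaussian read noise, and clipping to
$[0,1]$. The clearing-quality dial $q \in [0,1]$ moves all degradation
rates at once: $q=1$ leaves only the baseline blur $\sigma_0$.

Defaults: 256×256×60 stack, spheroid radius 100 px, 300 nuclei of radius
2–4 px and peak intensity 0.5–1, $\sigma_0 = 0.6$, $s_{ax} = 0.05$ σ/slice,
$\mu_{ax} = 0.02$/slice, $s_{lat} = 0.002$ σ/px, noise sd 0.01, all at
$q = 0$ rates. These were fixed once to reproduce the qualitative curve
shapes seen in poorly vs well cleared samples — steep sharpness loss
concentrated in the first outer third at low $q$, near-flat curves at high
$q$ — at a size where a full stack evaluates in seconds. Blur is separable
Gaussian convolution with replicate borders (consistent with the Laplacian
border convention, and free of the wrap-around of FFT convolution).

The phantom is a test harness, not a physics model. It does not simulate a
light-sheet PSF, refractive-index mismatch, nuclear texture, or realistic
packing density (300 nuclei is far sparser than a real spheroid). One
consequence matters for interpretation: because the nuclei are sparse, a
degraded phantom's *global* intensity maximum can sit mid-stack and drop
with degradation, so stack-max normalization slightly inflates the
normalized top-slice values of poorly cleared phantoms. Pipeline tests
therefore compare phantoms of *fixed geometry* (same placement seed) across
$q$, the analogue of clearing sister spheroids with different protocols;
under that pairing the internal-circle intensity-variance score recovers
the rank of $q \in \{0.1,..,0.9\}$ essentially perfectly, and the
end-to-end protocol ranking test demands the correct $q$ order in at least
18 of 20 seeds. Passing these tests shows the pipeline is wired correctly
and sensitive to graded degradation; it does not by itself validate any
metric on real microscope data.

Simulated expert tables (`generate_expert_scores()`) map each phantom
region's ground-truth quality (brightness retained and blur incurred)
linearly onto $[1,5]$, add truncated Gaussian rater noise, round to the
integer anchors, and average over raters — emulating imperfect
self-consistent human scoring without modelling any particular rater.

## Problem sizes used by the test suite

Unit tests run metrics on 9–32 px slices against naive-loop oracles (direct
DFT evaluation included) at tolerances 1e-12 (pixel domain) and 1e-8
(frequency domain); property suites use 96–128 px phantoms; the
parameter-recovery and ranking suites use the default 256×256×60 phantom,
with 3 seeds × 9 qualities and 20 seeds × 3 qualities respectively. These
sizes are the package's own choice of desk-scale verification; nothing in
the method depends on them.

## Known limitations

* Slice spacing is assumed uniform: the score weights all slices equally.
* Slice order is taken as TIFF page order, top first; `reverse = TRUE` is
  the only orientation control, and nothing in the file format verifies it.
* No morphological cleanup of the Otsu mask (hole filling, largest
  component): degraded slices with bright debris keep it in the foreground.
* The $H_{max}$ entropy form and the kurtosis small-blur behavior make
  those two metrics unsuitable as sole ranking criteria; the
  variance-family metrics are the robust default, with intensity variance
  the cheapest and best-behaved.
* Expert-correlation results on phantoms quantify pipeline sensitivity,
  not human-agreement performance on real data: the simulated raters are
  drawn from the same quality model the phantom is built on.
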