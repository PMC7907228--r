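# sqm — slice-wise sharpness metrics and quality scoring for spheroid z-stacks

Optical clearing protocols make 3-D multicellular spheroids transparent
enough for light-sheet fluorescence microscopy to resolve single nuclei deep
inside the sample — but there is no agreed way to decide *which* protocol
cleared best. `sqm` implements a quantitative pipeline for exactly that
question: it evaluates no-reference sharpness metrics slice by slice over a
fluorescence z-stack, reduces each stack (or stack region) to a single
0–1 quality score, rescales scores to the 1–5 scale used by human raters,
and runs the correlation and group-comparison statistics needed to rank
clearing protocols. It is aimed at microscopists and image analysts
comparing clearing or staining conditions on 3-D cultures.

## The method

Every stack is first normalized by its global intensity maximum. Seven
focus measures are then applied independently to each optical section *j*,
giving a metric plot *g(j)*:

| metric | statistic | sharp slice |
|---|---|---|
| `intensity_variance` | population variance of intensities | high |
| `gradient_variance` | variance of the gradient magnitude \|∇I\| | high |
| `laplacian_variance` | variance of the 4-neighbor Laplacian | high |
| `histogram_threshold` | Σ xᵢ·f(xᵢ) over bins above the mean intensity | high |
| `histogram_entropy` | −Σ (f/Hmax)·log₂(f/Hmax) over the histogram | high |
| `frequency_threshold` | Σ \|F(u,v)\| outside a centered circle of radius r | high |
| `kurtosis` | bivariate kurtosis β₂,₂ of the normalized periodogram \|F\|² | **low** |

Pixel-statistics metrics are restricted to the spheroid: either the
per-slice Otsu foreground, or an *internal circle* of fixed radius around
the slice's intensity-weighted centroid (moments M₁₀/M₀₀, M₀₁/M₀₀), which
scores only the spheroid core and so cancels the sharp-rim artifact of
partially penetrating clearing agents. Frequency-domain metrics always see
the whole slice.

Metric plots assessed jointly form an assessment set with extremes
α = max g, β = min g over all plots; each plot's single-value score is

    score_i = 1/((α−β)·n) · Σ_j (g_i(j) − β)   ∈ [0, 1]

so a plot pinned at the set maximum scores exactly 1 and one at the set
minimum exactly 0. Stacks are split into top/middle/bottom thirds to
localize where clearing helps, scores are min–max rescaled to [1, 5] for
comparison with expert scoring (Pearson r, least squares), and protocols
are compared with Kruskal–Wallis plus Dunn's post-hoc test (Holm-adjusted).

A synthetic phantom generator (`generate_phantom()`) produces nuclei-filled
spherical stacks whose blur and brightness degrade with depth and with
lateral distance from the illuminated edge, at a rate set by one
`clearing_quality` parameter q ∈ [0, 1] — so the whole pipeline is testable
without microscope data.

## Worked example

Three simulated "protocols" (q = 0.2, 0.5, 0.8), five spheroids each,
scored with the internal-circle intensity variance and compared against
simulated expert ratings:

```r
library(sqm)
library(dplyr)

qs <- c(poorly_cleared = 0.2, moderately_cleared = 0.5, well_cleared = 0.8)
phantoms <- purrr::list_flatten(purrr::map(qs, \(q)
  purrr::map(1:5, \(s) generate_phantom(phantom_spec(clearing_quality = q, seed = s)))))

plots  <- sqm_assess(purrr::map(phantoms, "stack"),
                     metric = "intensity_variance",
                     masking = "internal_circle", r = 60)
scores <- score_regions(plots, pool = "by_region")

experts <- generate_expert_scores(purrr::map(phantoms, "truth"),
                                  noise_sd = 0.3, seed = 42, raters = 10)
tidy(correlate_with_experts(scores, experts))
#> # A tibble: 4 × 6
#>   stratum     n     r slope intercept     p_value
#>   <chr>   <int> <dbl> <dbl>     <dbl>       <dbl>
#> 1 overall    45 0.683 0.653     1.32  0.000000239
#> 2 top        15 0.288 0.124     3.94  0.298
#> 3 middle     15 0.877 0.584     1.32  0.0000181
#> 4 bottom     15 0.941 0.708     0.405 0.000000176

scores |>
  mutate(protocol = rep(names(qs), each = 15)) |>
  compare_groups(protocol, score01) |>
  tidy()
#> # A tibble: 3 × 6
#>   group1             group2              z p_unadjusted p_adjusted stars
#>   <chr>              <chr>           <dbl>        <dbl>      <dbl> <chr>
#> 1 moderately_cleared poorly_cleared  0.987     0.324       0.324   ns
#> 2 moderately_cleared well_cleared   -2.53      0.0114      0.0228  *
#> 3 poorly_cleared     well_cleared   -3.52      0.000437    0.00131 **
```

The metric score correlates with the simulated raters overall (r ≈ 0.68),
most strongly in the bottom region — where degradation separates the
protocols most — and the rank tests single out the well-cleared group.
`plot_metric_values(plots)` draws the per-slice sharpness curves;
`autoplot()` methods exist for score sets, correlations and group
comparisons. Real stacks enter through `read_stack("spheroid.tif")`, and
`inst/cli/sqm.R` wraps the same pipeline for shell use (TIFF in, per-slice
and per-region CSV out).

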