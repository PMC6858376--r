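# staphycurve

Quantifies the steepness of the foveal curvature inside a posterior
staphyloma from OCT B-scan tracings of the retinal pigment epithelium
(RPE), and runs the group-comparison analysis that asks whether that
steepness separates the major myopic macular complications — myopic
traction maculopathy (MTM) versus myopic choroidal neovascularization
(mCNV) — in highly myopic eyes. It is written for retina researchers who
have per-eye RPE depth profiles (traced, for example, in ImageJ) plus
clinical metadata, and for methodologists who want a fully seeded
synthetic test bed for this class of morphometric pipeline.

## What it computes

For each eye, from horizontal and vertical fovea-centred profiles
`z(x)` (µm, elevation anterior-positive, fovea at `x = 0`):

- **Magnification correction** — on-image lateral lengths become actual
  dimensions via `t = 3.382 × 0.01306 × (AL − 1.82) × s` (AL = axial
  length, mm); applied to `x` only.
- **Staphyloma heights** — `H = z(±3000) − z(0)` at 3 mm nasal, temporal,
  superior, inferior; negative when the peripheral RPE lies posterior to
  the subfoveal RPE; horizontal/vertical/total sums.
- **Coefficient *a*** — ordinary least squares fit of `a·x² + b·x + c` to
  the profile resampled at 300 µm intervals over the central 6 mm
  (21 points); *a* is the steepness of the best parabola.
- **Curvature index** — arc length of the RPE polyline between the two
  points 3 mm either side of the fovea, divided by the Euclidean chord
  between them; ≥ 1, with 1 meaning perfectly straight. For a parabola the
  closed form is `[u√(1+u²) + asinh(u)]/(2u)`, `u = 2aX`.

Around these sit the study's eligibility filters (high myopia: AL ≥ 26.5 mm
or SE ≤ −6 D; strict > 50 µm dome-shaped-macula exclusion via a
convex-hull tangent; one eye per patient with right-eye preference), two
seeded synthetic cohort generators (metric-level, matching published group
summary statistics at n = 72/58/69; geometry-level, producing actual
profiles for end-to-end recovery tests), and the statistical layer
(one-way ANOVA, Bonferroni-corrected pairwise t-tests, Pearson chi-square,
correlation analyses) assembled into a tidy `comparison_report`.

## Worked example

```r
library(staphycurve)

# a steep parabolic staphyloma (a = 7e-5 / µm), both scan orientations
x <- seq(-3100, 3100, by = 10)
h <- rpe_profile(x, 7e-5 * x^2, "horizontal", 29.8, scaled = TRUE)
v <- rpe_profile(x, 7e-5 * x^2, "vertical",   29.8, scaled = TRUE)
compute_metrics(h, v)[, c("h_total_um", "coef_a_avg", "ci_avg")]
#>   h_total_um coef_a_avg   ci_avg
#> 1       2520      7e-05 1.028667
```

Each side rises `a·3000² = 630` µm above the fovea, so the total height is
2520 µm; the fit returns the generating coefficient exactly; and the
polyline arc exceeds the 6 mm chord by 2.9%, a curvature index of 1.029.

```r
coh <- sample_cohort_metrics(seed = 1)   # synthetic MTM/mCNV/control cohort
rep <- build_report(coh)
rep
#> <comparison_report>
#> Groups: MTM (n=72), control (n=69), mCNV (n=58)
#> Curvature ANOVA p-values:
#>   ...
#>   h_total_um         p = <0.001
#>   ci_avg             p = <0.001

dplyr::filter(tidy(rep, "posthoc"), variable == "ci_avg")
#>   variable  group1 group2 t_statistic  df        p_raw   p_adjusted
#> 1   ci_avg control   mCNV   0.3249221 125 7.457832e-01 1.000000e+00
#> 2   ci_avg control    MTM  -4.5960297 139 9.573194e-06 2.871958e-05
#> 3   ci_avg    mCNV    MTM  -4.1648746 128 5.685806e-05 1.705742e-04
```

The synthetic cohort reproduces the qualitative clinical finding it was
configured from: the MTM group's curvature index is sharply higher than
both the mCNV and control groups (Bonferroni-adjusted p < 0.001), while
mCNV and control eyes are indistinguishable (adjusted p = 1.000) despite
comparable axial lengths.

An end-to-end run (`simulate → screen → metrics → report`, with a
manifest) is one call:

```r
run_pipeline(run_config("out/", mode = "geometry", seed = 1))
```

and a thin CLI wraps the same functions
(`inst/cli/staphycurve run --out out --seed 1`).

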