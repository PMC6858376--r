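---
title: "Quantifying foveal curvature within posterior staphyloma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying foveal curvature within posterior staphyloma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(staphycurve)
library(dplyr)
```

## The measurement problem

In highly myopic eyes the posterior wall of the globe can bulge outward as a
posterior staphyloma. The retina, retinal pigment epithelium (RPE) and
choroid draped over that bulge are stretched, and the *steepness* of the
bulge at the fovea — not merely the axial length — appears to discriminate
between the mechanical complications that develop there: traction
maculopathy in steep bowls, neovascularization in shallow ones.

`staphycurve` turns fovea-centred OCT B-scan tracings of the RPE/Bruch
hyperreflective line into three per-eye steepness parameters:

* **Staphyloma heights** `H_N, H_T, H_S, H_I`: the elevation of the RPE at
  3 mm nasal, temporal, superior and inferior of the fovea above the
  subfoveal RPE level, `H = z(±3000) − z(0)` µm. A side whose peripheral
  RPE sits *posterior* to the subfoveal RPE is negative. Horizontal,
  vertical and total sums follow.
* **Coefficient $a$**: the RPE line is resampled at 300 µm intervals across
  the central 6 mm (21 points) and fitted with $z = ax^2 + bx + c$ by
  ordinary least squares; $a$ (units 1/µm internally) is the steepness of
  the best-fitting parabola.
* **Curvature index**: the arc length of the traced RPE polyline between
  the two points 3 mm either side of the fovea, divided by the straight
  (Euclidean) chord between them. Flat or purely tilted lines give exactly
  1; posterior bowing pushes the index above 1. For a pure parabola the
  closed form is $[u\sqrt{1+u^2} + \operatorname{asinh} u]/(2u)$ with
  $u = 2aX$, $X = 3000$ µm.

Horizontal and vertical scans are measured separately and averaged
arithmetically, mirroring the clinical reading protocol.

## Conventions and assumptions

*Elevation* `z` increases anteriorly (toward the vitreous) and is zeroed at
the sample nearest the fovea, so a staphyloma is an upward-opening curve
with positive coefficient $a$ and (typically) positive heights. *Lateral*
`x` is negative nasally on horizontal scans and inferiorly on vertical
scans; left eyes can be normalised with `flip_lateral()`. Profiles are a
single polyline — whether a grader traced the inner or outer RPE boundary
is a data-producer decision the package does not second-guess.

**Magnification correction.** On-image lateral lengths are converted to
actual dimensions with `t = 3.382 × 0.01306 × (AL − 1.82) × s` (AL = axial
length in mm), a single factor linear in axial length that equals 1 near
AL = 24.46 mm. The correction is applied to the lateral coordinate only:
after 1:1 µm conversion the OCT's axial sampling is optically independent
of ocular magnification. All "3 mm from the fovea" landmarks are located in
actual, post-correction micrometres; this interpretation (rather than
on-image landmarks) is a documented package choice. The chord of the
curvature index includes the elevation difference of its endpoints — which
is why a 6 mm lateral window can have a chord longer than 6000 µm.

**Arc vs fit grids.** The 300 µm grid is used *only* for the polynomial
fit; the curvature index uses the full-resolution polyline (with the
window endpoints interpolated exactly, never extrapolated). The two
procedures are deliberately distinct: the fit summarises shape, the arc
measures the traced line itself. For parabolas up to $a = 2\times10^{-4}$
/µm even a 300 µm polyline underestimates the true arc by under 0.1%, so
tracing density is not a practical accuracy limit.

**Units of coefficient $a$.** Published values of $a$ are conventionally
displayed ×10⁴. With `x` in µm, geometrically self-consistent staphyloma
shapes (heights near 1000–1300 µm) imply $a \approx 0.7 \times 10^{-4}$
/µm, whereas clinical reports display magnitudes of 3–4.5 — plot-export
units differ between software pipelines. The package therefore keeps
everything internally in µm and 1/µm, reports both `coef_a_*` (1/µm) and
`coef_a_*_1e4` display columns, and exposes `x_unit_scale` in
`fit_coefficient_a()` so users can reproduce any export convention (the
fit is exactly equivariant: scaling `x` by `k` divides `a` by `k²`).
Metric-level synthetic cohorts are parameterised directly on the published
×10⁴ display scale; geometry-level cohorts are parameterised in 1/µm. The
two modes are not forced onto a common parabola, precisely because the
published display scale and the published heights are not mutually
consistent in µm units.

## Eligibility rules

`screen_eyes()` encodes the study filters as testable predicates:

* **High myopia**: axial length ≥ 26.5 mm, or spherical equivalent ≤ −6.0 D.
  Pseudophakic eyes qualify only through axial length. (The inclusive ≤ −6 D
  reading — *at least* six dioptres of myopia — is the only physiologically
  sensible one and is used throughout.)
* **Dome-shaped macula** (exclusion): an anterior bulge of the macular RPE
  of strictly more than 50 µm above a presumed line tangent to the RPE at
  the bottom of the staphyloma. The "presumed tangent" is operationalised
  as the lower-convex-hull segment of the profile whose endpoints bracket
  the fovea: for a convex bowl every sample supports the hull and the bulge
  is zero; a central bump lifts the profile off the bridging segment and
  the maximal lift is the bulge. When several hull segments exist, the one
  bracketing `x = 0` is used. The rule is strict at the threshold — a bulge
  of exactly 50 µm does not qualify. Note that the bulge is measured
  against the bridging tangent, not the bump's own amplitude: a broad bump
  on a steep bowl can be largely absorbed by the hull.
* Metadata flags carry the exclusions that cannot be computed from a
  profile (prior treatment, buckle surgery, coexisting exudative disease,
  a staphyloma not involving the fovea, poor image quality, simultaneous
  traction maculopathy and neovascularization).
* **One eye per patient**: among a patient's eligible eyes the right eye is
  kept (`one_eye_per_patient()`).

## Severity measures

Foveoschisis height is the ILM-to-inner-RPE elevation difference at the
foveal centre; with a full-thickness macular hole the ILM is replaced by
the straight bridge between the hole edges (`foveoschisis_height()`).
Subfoveal choroidal thickness is the mean of the horizontal and vertical
scan measurements (`average_sct()`). CNV size (in disc areas) is carried
as an input field — no angiographic measurement algorithm is implied.

## Synthetic cohorts

No patient-level dataset is publicly deposited, so the package generates
its own cohorts at two levels. The generators' defaults *are* the study
conditions; they are not tuning knobs.

**Metric level** (`sample_cohort_metrics()`): per-eye clinical variables and
curvature metrics are drawn directly from per-group distributions whose
default means/SDs, category frequencies and sizes (72/58/69) equal the
published group summaries. Design choices worth knowing:

* The three curvature metrics share a pairwise correlation (default 0.65)
  through a Gaussian copula — the study reports strong positive pairwise
  correlations (r ≈ 0.63–0.70) but no covariance matrix, so this is a
  documented stand-in, not an estimate.
* The curvature-index margin is lower-truncated at 1 with the underlying
  normal's parameters solved numerically so the *realized* truncated mean
  and SD equal the configured values. Naive truncation of N(1.066, 0.048)
  at 1 would inflate the mean by ~0.008 — an order of magnitude more than
  the sampler's own convergence tolerance — so moment matching is the only
  construction consistent with treating the published moments as targets.
  The same device is used for the non-negative thickness and severity
  variables.
* The four per-side heights are generated as random shares of the drawn
  total (share means taken from the published side means, share SD 0.08),
  so the height identities hold exactly per eye and side means match the
  configuration; only marginal side SDs are approximate. Publishing
  marginal side SDs *and* sums overdetermines the joint distribution, so
  something must give; the identities were kept.
* Orientation-specific values are the drawn average ± a symmetric offset
  targeting the published horizontal/vertical mean gap, so averages remain
  exact identities.
* Foveoschisis height (MTM, 300 ± 150 µm) and CNV size (mCNV, 1.0 ± 0.8
  disc areas) are not tabulated in the source; the defaults are realistic
  clinical magnitudes, uncorrelated with curvature — matching the study's
  null finding for these pairs.

**Geometry level** (`generate_group_geometry()`, `synthesize_profile()`):
each eye gets horizontal and vertical profiles
$z(x) = ax^2 + \text{tilt}\,x + \text{bump}\,e^{-x^2/2\sigma^2} +
\varepsilon$, with one steepness draw per eye (default range
$[5, 13]\times10^{-5}$ /µm, spanning curvature indices ~1.015–1.10),
tilt ±0.05, tracing noise $\varepsilon \sim N(0, \sigma_n^2)$ (0 by
default; 5 µm is a realistic manual-tracing jitter), 10 µm sampling over
±3100 µm. Profiles are centred *after* noise so the type invariant
`z(fovea) = 0` always holds — a constant shift with no statistical
consequence. This mode feeds the full measurement pipeline and is what the
recovery tests exercise (noiseless shapes are recovered to machine
precision; at 5 µm noise the fitted coefficient is unbiased to <1% over
500 replicates).

What the generators do **not** emulate: real tracing error is not i.i.d.
(graders err smoothly), real staphylomas are not parabolas plus Gaussian
bumps, axial length and curvature are sampled independently within groups,
and categorical variables are independent of the continuous ones. Passing
tests therefore demonstrate correctness of the *measurement and inference
machinery* under the published summary statistics — not properties of any
real cohort.

## Statistical layer

`build_report()` reproduces the analysis tables: one-way ANOVA
(equal-variance) for continuous baseline and curvature rows, Pearson
chi-square without continuity correction for categorical rows (small
expected counts are reported, not "fixed" — no Yates correction or exact
test, matching the reproduced printed p-values), Student's equal-variance
pairwise t-tests with Bonferroni ×3 correction capped at 1 (a Welch switch
is provided), and Pearson correlations (a Spearman switch is provided;
Pearson is the documented default, inferred from the
regression-line-with-r presentation style of such studies, not asserted
about the source). Pseudophakic eyes are excluded from every
refractive-error row; foveoschisis correlations are restricted to the MTM
group and CNV-size correlations to the mCNV group.

Degenerate inputs (zero-variance variables, empty groups) are flagged in
the report rather than raised, so a pathological cohort still yields a
complete, inspectable object.

## Numerical choices

* Interpolation is linear, exact at samples, and never extrapolates;
  profiles that do not span ±3000 µm after scaling are refused with an
  error naming the short side.
* The curvature index is clamped to 1 only within 10⁻¹² of it, absorbing
  the floating-point round-off of summing collinear segment lengths.
* The quadratic fit uses `lm()`'s QR decomposition; exact quadratics are
  recovered to 10⁻¹² relative.
* The truncated-normal moment matching solves a two-parameter least-squares
  problem with Nelder–Mead to a 10⁻¹⁰ objective; degenerate SD = 0 cases
  short-circuit.
* All randomness flows from explicit seeds (`withr::with_seed`), and the
  pipeline derives per-stage seeds from one root seed; equal seeds give
  byte-identical output files.

## Problem sizes

The bundled tests run the metric-level sampler at the study sizes
(n = 199) and at n = 10,000 for moment-convergence checks, 200–1,000
replicate simulations for calibration checks (type-I error, null
correlations, ANOVA power), and 500 replicates for the noise-bias bound;
geometry-level cohorts in the end-to-end tests use 6–18 eyes with ~620
samples per profile. These sizes give Monte-Carlo error comfortably below
every asserted tolerance.

## Known limitations

* The 6 mm window quantifies *foveal* curvature only; staphyloma walls
  beyond 3 mm (where additional discriminative signal likely lives) are
  out of scope, as is whole-posterior-pole curvature mapping.
* B-scan geometry itself distorts the globe (sector scans displayed as
  rectangles); the package measures the displayed geometry, as the
  clinical protocol does.
* The dome-tangent construction is one reasonable operationalisation of a
  verbally defined clinical rule; other constructions (e.g. a tangent at a
  single deepest point) would differ near threshold.
* Metric-level and geometry-level cohorts are intentionally not unified
  under one shape model (see the units discussion above).

## A worked example

```{r example}
# a steep parabolic staphyloma, both orientations
x <- seq(-3100, 3100, by = 10)
h <- rpe_profile(x, 7e-5 * x^2, "horizontal", 29.8, scaled = TRUE)
v <- rpe_profile(x, 7e-5 * x^2, "vertical", 29.8, scaled = TRUE)
compute_metrics(h, v)

# a seeded synthetic three-group cohort and its comparison report
coh <- sample_cohort_metrics(seed = 1)
rep <- build_report(coh)
tidy(rep, "curvature") |> filter(variable %in% c("h_total_um", "ci_avg"))
```
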