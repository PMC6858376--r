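#' Truncated-normal helpers with matched moments
#'
#' `match_truncnorm()` finds the location/scale of an underlying normal
#' such that its lower-truncated version has exactly the requested mean and
#' SD; `q_truncnorm()` is the quantile function of that truncated normal.
#' Matching the realized (post-truncation) moments keeps synthetic cohorts
#' faithful to configured summary statistics even for variables with a hard
#' floor (curvature index >= 1, thicknesses >= 0), where naive truncation
#' would bias the mean upward.
#'
#' @param mean,sd Target mean and SD of the truncated distribution.
#' @param lower Truncation point.
#' @param p Probabilities.
#' @param mu,sigma Parameters of the underlying (untruncated) normal.
#' @return `match_truncnorm()` a list with `mu`, `sigma`; `q_truncnorm()` a
#'   numeric vector.
#' @keywords internal
#' @export
match_truncnorm <- function(mean, sd, lower) {
  if (sd < 0) abort_validation("`sd` must be >= 0.")
  if (sd == 0) {
    if (mean < lower) {
      abort_validation("Degenerate distribution below the truncation point.")
    }
    return(list(mu = mean, sigma = 0))
  }
  if (mean <= lower) {
    abort_validation("Target mean must exceed the truncation point.")
  }
  moments <- function(mu, sigma) {
    a <- (lower - mu) / sigma
    lam <- dnorm(a) / (1 - pnorm(a))
    m <- mu + sigma * lam
    v <- sigma^2 * (1 + a * lam - lam^2)
    c(m, if (is.finite(v) && v > 0) sqrt(v) else NaN)
  }
  obj <- function(p) {
    mm <- moments(p[1], exp(p[2]))
    if (!all(is.finite(mm))) return(1e10)
    (mm[1] - mean)^2 + (mm[2] - sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  if (fit$value > 1e-10 * (sd^2 + 1e-12)) {
    abort_domain(sprintf(
      "Could not match truncated-normal moments (mean %g, sd %g, lower %g).",
      mean, sd, lower
    ))
  }
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' @rdname match_truncnorm
#' @export
q_truncnorm <- function(p, mu, sigma, lower) {
  if (sigma == 0) return(rep(mu, length(p)))
  p_lo <- pnorm(lower, mu, sigma)
  qnorm(p_lo + p * (1 - p_lo), mu, sigma)
}

#' Per-group generative distribution for metric-level cohorts
#'
#' Bundles the sample size, the means/SDs of the clinical and curvature
#' variables, categorical frequencies, and the inter-metric correlation
#' used by [sample_cohort_metrics()]. Defaults (see
#' [default_group_distributions()]) reproduce the published group summary
#' statistics of a three-group high-myopia staphyloma study.
#'
#' @param n Group size.
#' @param age,bcva,axial_length,refractive_error,sct,h_total,coef_a_avg,ci_avg
#'   Length-2 numeric `c(mean, sd)`. `coef_a_avg` is on the conventional
#'   x 10^4 display scale; `ci_avg` is lower-truncated at 1 with matched
#'   moments.
#' @param coef_a_h,coef_a_v,ci_h,ci_v Length-2 `c(mean, sd)` of the
#'   orientation-specific values; orientation splits are generated
#'   symmetrically around the drawn average so averages stay exact.
#' @param side_means Named numeric of the four per-side staphyloma height
#'   means `c(nasal, temporal, superior, inferior)` (um); only their
#'   proportions of the total are used.
#' @param share_sd SD of the random per-side share perturbation.
#' @param sex_freq,staphyloma_freq,metapm_freq Categorical frequencies
#'   (normalised internally): `c(M, F)`, `c(wide_macular, narrow_macular,
#'   other)`, four META-PM categories.
#' @param pseudophakic_rate Probability an eye is pseudophakic.
#' @param fsh,cnv_size Length-2 `c(mean, sd)` of the group-conditional
#'   severity measure (foveoschisis height, um; CNV size, disc areas), both
#'   lower-truncated at 0, or `NULL`.
#' @param curvature_cor Pairwise correlation among the three curvature
#'   metrics (Gaussian copula), in `[0, 1)`.
#' @return A list of class `group_distribution`.
#' @export
group_distribution <- function(n,
                               age = c(55, 10), bcva = c(0.6, 0.4),
                               axial_length = c(29.5, 1.5),
                               refractive_error = c(-12, 3),
                               sct = c(38, 18),
                               h_total = c(2000, 800),
                               coef_a_avg = c(3.2, 1.5),
                               ci_avg = c(1.045, 0.025),
                               coef_a_h = coef_a_avg, coef_a_v = coef_a_avg,
                               ci_h = ci_avg, ci_v = ci_avg,
                               side_means = c(nasal = 400, temporal = 650,
                                              superior = 600, inferior = 420),
                               share_sd = 0.08,
                               sex_freq = c(M = 0.25, F = 0.75),
                               staphyloma_freq = c(wide_macular = 0.45,
                                                   narrow_macular = 0.5,
                                                   other = 0.05),
                               metapm_freq = c(0.12, 0.47, 0.39, 0.02),
                               pseudophakic_rate = 0.1,
                               fsh = NULL, cnv_size = NULL,
                               curvature_cor = 0.65) {
  stopifnot(length(n) == 1, n >= 0)
  pairs <- list(age = age, bcva = bcva, axial_length = axial_length,
                refractive_error = refractive_error, sct = sct,
                h_total = h_total, coef_a_avg = coef_a_avg, ci_avg = ci_avg,
                coef_a_h = coef_a_h, coef_a_v = coef_a_v,
                ci_h = ci_h, ci_v = ci_v)
  for (nm in names(pairs)) {
    v <- pairs[[nm]]
    if (length(v) != 2 || !all(is.finite(v)) || v[2] < 0) {
      abort_validation(sprintf("`%s` must be c(mean, sd) with sd >= 0.", nm))
    }
  }
  if (!is.null(fsh) && (length(fsh) != 2 || fsh[2] < 0)) {
    abort_validation("`fsh` must be c(mean, sd) with sd >= 0.")
  }
  if (!is.null(cnv_size) && (length(cnv_size) != 2 || cnv_size[2] < 0)) {
    abort_validation("`cnv_size` must be c(mean, sd) with sd >= 0.")
  }
  if (curvature_cor < 0 || curvature_cor >= 1) {
    abort_validation("`curvature_cor` must be in [0, 1).")
  }
  norm1 <- function(p) p / sum(p)
  out <- c(pairs, list(
    n = as.integer(n),
    side_means = side_means, share_sd = share_sd,
    sex_freq = norm1(sex_freq), staphyloma_freq = norm1(staphyloma_freq),
    metapm_freq = norm1(metapm_freq),
    pseudophakic_rate = pseudophakic_rate,
    fsh = fsh, cnv_size = cnv_size,
    curvature_cor = curvature_cor
  ))
  structure(out, class = "group_distribution")
}

#' Default group distributions
#'
#' Group sizes 72/58/69 and per-group means/SDs and category frequencies of
#' the published MTM / mCNV / control comparison (demographics, myopia
#' severity, staphyloma type, META-PM category, choroidal thickness, and
#' the three curvature parameters). Severity measures not tabulated in the
#' source (foveoschisis height, CNV size) carry realistic clinical defaults
#' and are uncorrelated with curvature.
#'
#' @return Named list of [group_distribution()]s: `MTM`, `mCNV`, `control`.
#' @export
default_group_distributions <- function() {
  list(
    MTM = group_distribution(
      n = 72,
      age = c(60.7, 9.1), bcva = c(0.73, 0.54),
      axial_length = c(29.8, 1.7), refractive_error = c(-12.6, 3.7),
      sct = c(39.1, 19.7),
      h_total = c(2614.0, 944.3),
      coef_a_avg = c(4.33, 2.35),
      coef_a_h = c(4.47, 2.54), coef_a_v = c(4.21, 2.37),
      ci_avg = c(1.066, 0.048),
      ci_h = c(1.064, 0.053), ci_v = c(1.069, 0.050),
      side_means = c(nasal = 599.3, temporal = 727.0,
                     superior = 852.8, inferior = 434.8),
      sex_freq = c(M = 17, F = 55),
      staphyloma_freq = c(wide_macular = 31, narrow_macular = 36, other = 5),
      metapm_freq = c(8, 34, 29, 1),
      pseudophakic_rate = 10 / 72,
      fsh = c(300, 150)
    ),
    mCNV = group_distribution(
      n = 58,
      age = c(60.0, 10.6), bcva = c(0.80, 0.39),
      axial_length = c(30.0, 1.4), refractive_error = c(-12.4, 2.7),
      sct = c(34.0, 17.8),
      h_total = c(2030.7, 879.6),
      coef_a_avg = c(3.11, 1.39),
      coef_a_h = c(2.96, 1.46), coef_a_v = c(3.25, 1.48),
      ci_avg = c(1.044, 0.027),
      ci_h = c(1.044, 0.029), ci_v = c(1.043, 0.031),
      side_means = c(nasal = 257.2, temporal = 736.7,
                     superior = 658.9, inferior = 377.9),
      sex_freq = c(M = 11, F = 47),
      staphyloma_freq = c(wide_macular = 29, narrow_macular = 27, other = 2),
      metapm_freq = c(5, 27, 26, 0),
      pseudophakic_rate = 6 / 58,
      cnv_size = c(1.0, 0.8)
    ),
    control = group_distribution(
      n = 69,
      age = c(52.3, 9.1), bcva = c(0.54, 0.41),
      axial_length = c(29.5, 1.5), refractive_error = c(-11.9, 2.8),
      sct = c(37.9, 18.5),
      h_total = c(2042.2, 771.1),
      coef_a_avg = c(3.14, 1.56),
      coef_a_h = c(3.21, 1.62), coef_a_v = c(3.07, 1.61),
      ci_avg = c(1.042, 0.021),
      ci_h = c(1.043, 0.024), ci_v = c(1.041, 0.022),
      side_means = c(nasal = 382.8, temporal = 627.4,
                     superior = 597.2, inferior = 434.9),
      sex_freq = c(M = 20, F = 49),
      staphyloma_freq = c(wide_macular = 28, narrow_macular = 39, other = 2),
      metapm_freq = c(12, 33, 24, 0),
      pseudophakic_rate = 5 / 69
    )
  )
}

# symmetric orientation split around a drawn average: H = avg + e,
# V = avg - e, so the average identity holds exactly; e targets the
# tabulated H/V mean gap, with variance chosen so Var(H) ~ mean of the
# tabulated orientation variances; e is clipped so values stay above `floor`
orientation_split <- function(avg, mean_h, mean_v, sd_h, sd_v, sd_avg,
                              floor = -Inf) {
  n <- length(avg)
  e_mean <- (mean_h - mean_v) / 2
  e_sd <- sqrt(max(0, (sd_h^2 + sd_v^2) / 2 - sd_avg^2))
  e <- rnorm(n, e_mean, e_sd)
  if (is.finite(floor)) {
    lim <- pmax(0, avg - floor)
    e <- pmin(pmax(e, -lim), lim)
  }
  list(h = avg + e, v = avg - e)
}

sample_one_group <- function(d, group, id_prefix) {
  n <- d$n
  if (n == 0) {
    return(tibble(patient_id = character(), eye = character(),
                  group = character()))
  }
  # correlated uniforms for the three curvature metrics (Gaussian copula)
  rho <- d$curvature_cor
  R <- matrix(rho, 3, 3)
  diag(R) <- 1
  ch <- tryCatch(chol(R), error = function(e) {
    abort_validation("Curvature correlation matrix is not positive definite.")
  })
  z <- matrix(rnorm(3 * n), n, 3) %*% ch
  u <- pnorm(z)

  h_total <- qnorm(u[, 1], d$h_total[1], d$h_total[2])
  coef_avg <- qnorm(u[, 2], d$coef_a_avg[1], d$coef_a_avg[2])
  ci_par <- match_truncnorm(d$ci_avg[1], d$ci_avg[2], lower = 1)
  ci_avg <- q_truncnorm(u[, 3], ci_par$mu, ci_par$sigma, lower = 1)

  coef_hv <- orientation_split(coef_avg, d$coef_a_h[1], d$coef_a_v[1],
                               d$coef_a_h[2], d$coef_a_v[2], d$coef_a_avg[2])
  ci_hv <- orientation_split(ci_avg, d$ci_h[1], d$ci_v[1],
                             d$ci_h[2], d$ci_v[2], d$ci_avg[2], floor = 1)

  # per-side heights as random shares of the drawn total; identities exact
  f <- d$side_means / sum(d$side_means)
  shares <- matrix(rnorm(4 * n, rep(f, each = n), d$share_sd), n, 4)
  shares <- shares / rowSums(shares)
  sides <- shares * h_total

  sct_par <- match_truncnorm(d$sct[1], d$sct[2], lower = 0)
  fsh <- if (!is.null(d$fsh)) {
    p <- match_truncnorm(d$fsh[1], d$fsh[2], lower = 0)
    q_truncnorm(runif(n), p$mu, p$sigma, lower = 0)
  } else rep(NA_real_, n)
  cnv <- if (!is.null(d$cnv_size)) {
    p <- match_truncnorm(d$cnv_size[1], d$cnv_size[2], lower = 0)
    q_truncnorm(runif(n), p$mu, p$sigma, lower = 0)
  } else rep(NA_real_, n)

  sample_cat <- function(levels, freq) {
    if (length(levels) == 1) return(rep(levels, n))
    levels[sample.int(length(levels), n, replace = TRUE, prob = freq)]
  }

  tibble(
    patient_id = sprintf("%s%03d", id_prefix, seq_len(n)),
    eye = sample_cat(c("OD", "OS"), c(0.5, 0.5)),
    group = group,
    age_years = rnorm(n, d$age[1], d$age[2]),
    sex = sample_cat(c("M", "F"), d$sex_freq),
    bcva_logmar = rnorm(n, d$bcva[1], d$bcva[2]),
    axial_length_mm = rnorm(n, d$axial_length[1], d$axial_length[2]),
    refractive_error_d = rnorm(n, d$refractive_error[1], d$refractive_error[2]),
    pseudophakic = runif(n) < d$pseudophakic_rate,
    staphyloma_type = sample_cat(c("wide_macular", "narrow_macular", "other"),
                                 d$staphyloma_freq),
    metapm_category = as.integer(sample_cat(as.character(1:4), d$metapm_freq)),
    sct_um = q_truncnorm(runif(n), sct_par$mu, sct_par$sigma, lower = 0),
    fsh_um = fsh,
    cnv_size_da = cnv,
    h_nasal_um = sides[, 1], h_temporal_um = sides[, 2],
    h_superior_um = sides[, 3], h_inferior_um = sides[, 4],
    h_horizontal_um = sides[, 1] + sides[, 2],
    h_vertical_um = sides[, 3] + sides[, 4],
    h_total_um = h_total,
    coef_a_h_1e4 = coef_hv$h, coef_a_v_1e4 = coef_hv$v,
    coef_a_avg_1e4 = coef_avg,
    ci_h = ci_hv$h, ci_v = ci_hv$v, ci_avg = ci_avg
  )
}

#' Sample a metric-level synthetic cohort
#'
#' Draws per-eye clinical metadata and curvature metrics directly from the
#' configured group distributions (no profile geometry involved). The three
#' curvature metrics (total height, average coefficient a, average
#' curvature index) are drawn with a common pairwise correlation through a
#' Gaussian copula; the curvature index margin is lower-truncated at 1 with
#' matched moments. Given a seed the cohort is exactly reproducible.
#'
#' @param config Named list of [group_distribution()]s keyed by group
#'   label; defaults to [default_group_distributions()].
#' @param seed Optional integer seed.
#' @return A `staphy_cohort` tibble (provenance `"synthetic_metrics"`), one
#'   row per eye, with metric columns and no profiles.
#' @examples
#' coh <- sample_cohort_metrics(seed = 1)
#' dplyr::count(coh, group)
#' @export
sample_cohort_metrics <- function(config = default_group_distributions(),
                                  seed = NULL) {
  stopifnot(is.list(config), length(config) > 0)
  if (is.null(names(config)) || any(!nzchar(names(config)))) {
    abort_validation("`config` must be a named list of group distributions.")
  }
  draw <- function() {
    prefixes <- toupper(substr(names(config), 1, 1))
    if (anyDuplicated(prefixes)) {
      prefixes <- sprintf("G%d_", seq_along(config))
    }
    tabs <- map(seq_along(config), function(i) {
      sample_one_group(config[[i]], names(config)[i], prefixes[i])
    })
    list_rbind(tabs)
  }
  tab <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  as_cohort(tab, provenance = "synthetic_metrics", seed = seed)
}

#' Geometry parameters for a synthetic eye
#'
#' Shape parameters of a simulated RPE profile: a parabola-dominated
#' staphyloma (`a`, 1/um), a linear tilt, an optional Gaussian dome
#' perturbation at the fovea, and i.i.d. measurement noise on the traced
#' elevations.
#'
#' @param a_h,a_v Quadratic steepness per orientation (1/um).
#' @param tilt_h,tilt_v Linear slope per orientation (dimensionless).
#' @param bump_amplitude_um,bump_sigma_um Gaussian dome bump at the fovea.
#' @param noise_sd_um SD of the elevation tracing noise (um).
#' @param sample_spacing_um Lateral sample spacing (um).
#' @param span_um Half-span of the profile (um; must be >= 3000 for the
#'   metric operations).
#' @return A list of class `geometry_params`.
#' @export
geometry_params <- function(a_h = 7e-5, a_v = 7e-5, tilt_h = 0, tilt_v = 0,
                            bump_amplitude_um = 0, bump_sigma_um = 800,
                            noise_sd_um = 0, sample_spacing_um = 10,
                            span_um = 3100) {
  if (sample_spacing_um <= 0) abort_validation("`sample_spacing_um` must be > 0.")
  if (noise_sd_um < 0) abort_validation("`noise_sd_um` must be >= 0.")
  structure(
    list(a_h = a_h, a_v = a_v, tilt_h = tilt_h, tilt_v = tilt_v,
         bump_amplitude_um = bump_amplitude_um, bump_sigma_um = bump_sigma_um,
         noise_sd_um = noise_sd_um, sample_spacing_um = sample_spacing_um,
         span_um = span_um),
    class = "geometry_params"
  )
}

#' Synthesize one RPE profile
#'
#' Generates `z(x) = a x^2 + tilt x + bump exp(-x^2 / (2 sigma^2)) + noise`
#' on a regular lateral grid, centred so the subfoveal elevation is zero,
#' and marked as already magnification-corrected.
#'
#' @param params A [geometry_params()].
#' @param orientation `"horizontal"` or `"vertical"` (selects `a_h`/`a_v`
#'   and `tilt_h`/`tilt_v`).
#' @param axial_length_mm Axial length recorded on the profile.
#' @param seed Optional seed for the tracing noise.
#' @return An [rpe_profile()] with `scaled = TRUE`.
#' @export
synthesize_profile <- function(params, orientation = c("horizontal", "vertical"),
                               axial_length_mm = 29.8, seed = NULL) {
  stopifnot(inherits(params, "geometry_params"))
  orientation <- arg_match(orientation)
  a <- if (orientation == "horizontal") params$a_h else params$a_v
  tilt <- if (orientation == "horizontal") params$tilt_h else params$tilt_v
  x <- seq(-params$span_um, params$span_um, by = params$sample_spacing_um)
  build <- function() {
    z <- a * x^2 + tilt * x +
      params$bump_amplitude_um * exp(-x^2 / (2 * params$bump_sigma_um^2))
    if (params$noise_sd_um > 0) {
      z <- z + rnorm(length(x), 0, params$noise_sd_um)
    }
    z
  }
  z <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  rpe_profile(x, z, orientation = orientation,
              axial_length_mm = axial_length_mm, scaled = TRUE)
}

#' Generate a geometry-level synthetic cohort
#'
#' Samples per-eye shape parameters uniformly from the supplied ranges,
#' synthesizes horizontal and vertical RPE profiles for each eye, and
#' attaches clinical metadata drawn from a [group_distribution()]. The
#' resulting cohort feeds the full measurement pipeline
#' ([cohort_metrics()], [screen_eyes()], ...).
#'
#' @param n Number of eyes.
#' @param ranges Named list of length-2 ranges: `a` (1/um), `tilt`,
#'   `bump_amplitude`, `noise_sd`; a missing entry uses a degenerate range
#'   at the [geometry_params()] default. Each eye gets one `a` draw used
#'   for both orientations.
#' @param seed Optional integer seed.
#' @param group Group label stamped on every record.
#' @param dist A [group_distribution()] supplying metadata distributions.
#' @return A `staphy_cohort` (provenance `"synthetic_geometry"`) with
#'   profile list-columns.
#' @export
generate_group_geometry <- function(n,
                                    ranges = list(a = c(5e-5, 1.3e-4),
                                                  tilt = c(-0.05, 0.05)),
                                    seed = NULL, group = "control",
                                    dist = default_group_distributions()$control) {
  stopifnot(n >= 0)
  rng <- function(name, default) {
    r <- ranges[[name]] %||% c(default, default)
    if (length(r) == 1) r <- c(r, r)
    if (r[2] < r[1]) abort_validation(sprintf("Range `%s` must be ordered.", name))
    r
  }
  a_r <- rng("a", 7e-5)
  tilt_r <- rng("tilt", 0)
  bump_r <- rng("bump_amplitude", 0)
  noise_r <- rng("noise_sd", 0)
  build <- function() {
    if (n == 0) {
      return(tibble(patient_id = character(), eye = character(),
                    group = character()))
    }
    recs <- map(seq_len(n), function(i) {
      a <- runif(1, a_r[1], a_r[2])
      par <- geometry_params(
        a_h = a, a_v = a,
        tilt_h = runif(1, tilt_r[1], tilt_r[2]),
        tilt_v = runif(1, tilt_r[1], tilt_r[2]),
        bump_amplitude_um = runif(1, bump_r[1], bump_r[2]),
        noise_sd_um = runif(1, noise_r[1], noise_r[2])
      )
      al <- rnorm(1, dist$axial_length[1], dist$axial_length[2])
      tibble(
        patient_id = sprintf("%s_GEO%03d", group, i),
        eye = "OD",
        group = group,
        age_years = rnorm(1, dist$age[1], dist$age[2]),
        sex = sample(c("M", "F"), 1, prob = dist$sex_freq),
        bcva_logmar = rnorm(1, dist$bcva[1], dist$bcva[2]),
        axial_length_mm = al,
        refractive_error_d = rnorm(1, dist$refractive_error[1],
                                   dist$refractive_error[2]),
        pseudophakic = runif(1) < dist$pseudophakic_rate,
        staphyloma_type = sample(c("wide_macular", "narrow_macular", "other"),
                                 1, prob = dist$staphyloma_freq),
        metapm_category = sample(1:4, 1, prob = dist$metapm_freq),
        sct_um = max(0, rnorm(1, dist$sct[1], dist$sct[2])),
        profile_h = list(synthesize_profile(par, "horizontal",
                                            axial_length_mm = al)),
        profile_v = list(synthesize_profile(par, "vertical",
                                            axial_length_mm = al))
      )
    })
    list_rbind(recs)
  }
  tab <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  as_cohort(tab, provenance = "synthetic_geometry", seed = seed)
}
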