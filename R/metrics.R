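#' Interpolated RPE elevation
#'
#' Linear interpolation of the profile polyline; exact at sample points,
#' never extrapolating.
#'
#' @param profile A magnification-corrected [rpe_profile()].
#' @param x Lateral position(s) in micrometres, inside the profile span.
#' @return Elevation(s) in micrometres.
#' @export
elevation_at <- function(profile, x) {
  check_profile(profile)
  if (any(x < min(profile$x_um) | x > max(profile$x_um))) {
    abort_range(sprintf(
      "Requested x outside the profile span [%g, %g].",
      min(profile$x_um), max(profile$x_um)
    ))
  }
  approx(profile$x_um, profile$z_um, xout = x, method = "linear",
         ties = "ordered")$y
}

#' Staphyloma heights at 3 mm from the fovea
#'
#' The height on each side is the vertical (elevation) distance from the RPE
#' at 3 mm nasal, temporal, superior and inferior of the fovea down to the
#' subfoveal RPE level: `H = z(+/-3000) - z(0)`. A side whose peripheral RPE
#' lies posterior to the subfoveal RPE gets a negative height. Sums follow
#' the usual bookkeeping: horizontal = nasal + temporal, vertical =
#' superior + inferior, total = all four.
#'
#' @param horizontal,vertical Magnification-corrected [rpe_profile()]s
#'   covering at least +/-3000 um. By convention negative `x` is nasal on
#'   the horizontal scan and inferior on the vertical scan.
#' @param at_um Distance of the peripheral landmarks from the fovea
#'   (default 3000 um).
#' @return A one-row tibble with columns `h_nasal_um`, `h_temporal_um`,
#'   `h_superior_um`, `h_inferior_um`, `h_horizontal_um`, `h_vertical_um`,
#'   `h_total_um`.
#' @examples
#' x <- seq(-3100, 3100, by = 10)
#' h <- rpe_profile(x, 7e-5 * x^2, "horizontal", 29.8, scaled = TRUE)
#' v <- rpe_profile(x, 7e-5 * x^2, "vertical", 29.8, scaled = TRUE)
#' staphyloma_heights(h, v) # each side 630 um, total 2520 um
#' @export
staphyloma_heights <- function(horizontal, vertical, at_um = 3000) {
  check_span(horizontal, at_um)
  check_span(vertical, at_um)
  if (profile_orientation(horizontal) != "horizontal") {
    abort_validation("`horizontal` must be a horizontal-scan profile.")
  }
  if (profile_orientation(vertical) != "vertical") {
    abort_validation("`vertical` must be a vertical-scan profile.")
  }
  z0_h <- elevation_at(horizontal, 0)
  z0_v <- elevation_at(vertical, 0)
  h_n <- elevation_at(horizontal, -at_um) - z0_h
  h_t <- elevation_at(horizontal, at_um) - z0_h
  h_i <- elevation_at(vertical, -at_um) - z0_v
  h_s <- elevation_at(vertical, at_um) - z0_v
  tibble(
    h_nasal_um = h_n, h_temporal_um = h_t,
    h_superior_um = h_s, h_inferior_um = h_i,
    h_horizontal_um = h_n + h_t,
    h_vertical_um = h_s + h_i,
    h_total_um = h_n + h_t + h_s + h_i
  )
}

#' Quadratic steepness coefficient of the RPE line
#'
#' Resamples the profile on the fixed 21-point grid -3000, -2700, ..., +3000
#' um (300-um intervals across the central 6 mm) and fits
#' `z = a x^2 + b x + c` by ordinary least squares. The leading coefficient
#' `a` summarises the steepness of the staphyloma: larger `a`, steeper bowl.
#' Internally `x` is in micrometres, so `a` has units 1/um; use
#' `x_unit_scale` to reproduce fits done with the lateral axis in other
#' units (the fit is equivariant: scaling x by `k` divides `a` by `k^2`).
#'
#' @param profile A magnification-corrected [rpe_profile()] covering
#'   +/-3000 um.
#' @param x_unit_scale Multiplier applied to the lateral grid before
#'   fitting (default 1: micrometres).
#' @return An object of class `quad_fit` with fields `a`, `b`, `c`, `rss`
#'   (residual sum of squares, um^2), `n_points`.
#' @examples
#' x <- seq(-3100, 3100, by = 10)
#' p <- rpe_profile(x, 4.45e-4 * x^2, "horizontal", 29.8, scaled = TRUE)
#' fit_coefficient_a(p)$a # recovers 4.45e-4
#' @export
fit_coefficient_a <- function(profile, x_unit_scale = 1) {
  check_span(profile, 3000)
  grid <- seq(-3000, 3000, by = 300)
  z <- elevation_at(profile, grid)
  xs <- grid * x_unit_scale
  fit <- lm(z ~ xs + I(xs^2))
  cf <- coef(fit)
  structure(
    list(
      a = unname(cf[["I(xs^2)"]]),
      b = unname(cf[["xs"]]),
      c = unname(cf[["(Intercept)"]]),
      rss = sum(fit$residuals^2),
      n_points = length(grid),
      orientation = profile_orientation(profile)
    ),
    class = "quad_fit"
  )
}

#' @export
print.quad_fit <- function(x, ...) {
  cat(sprintf(
    "<quad_fit> z = %.4g x^2 + %.4g x + %.4g  (n = %d, rss = %.4g um^2)\n",
    x$a, x$b, x$c, x$n_points, x$rss
  ))
  invisible(x)
}

#' @export
tidy.quad_fit <- function(x, ...) {
  tibble(term = c("a", "b", "c"), estimate = c(x$a, x$b, x$c))
}

#' @export
glance.quad_fit <- function(x, ...) {
  tibble(rss = x$rss, n_points = x$n_points, df_residual = x$n_points - 3L)
}

# polyline clipped to [-half_span, half_span] with exactly interpolated
# endpoints; used by the curvature index and the dome rule
clip_polyline <- function(profile, half_span = 3000) {
  x <- profile$x_um
  z <- profile$z_um
  keep <- x > -half_span & x < half_span
  xi <- c(-half_span, x[keep], half_span)
  zi <- c(elevation_at(profile, -half_span), z[keep],
          elevation_at(profile, half_span))
  # guard against a sample landing exactly on an endpoint
  dup <- duplicated(xi)
  list(x = xi[!dup], z = zi[!dup])
}

#' Curvature index of the RPE line
#'
#' The length of the RPE polyline between the two points 3 mm either side
#' of the fovea (6 mm apart laterally), divided by the straight-line
#' (Euclidean, lateral and elevation components) distance between those two
#' points. A perfectly flat or tilted RPE gives exactly 1; posterior bowing
#' elongates the traced line and pushes the index above 1.
#'
#' @inheritParams fit_coefficient_a
#' @param half_span Half-width of the evaluation window (default 3000 um).
#' @return A dimensionless number `>= 1`.
#' @examples
#' x <- seq(-3100, 3100, by = 5)
#' p <- rpe_profile(x, 7.07e-5 * x^2, "horizontal", 29.8, scaled = TRUE)
#' curvature_index(p) # ~1.029
#' @export
curvature_index <- function(profile, half_span = 3000) {
  check_span(profile, half_span)
  pl <- clip_polyline(profile, half_span)
  dx <- diff(pl$x)
  dz <- diff(pl$z)
  arc <- sum(sqrt(dx^2 + dz^2))
  chord <- sqrt((pl$x[length(pl$x)] - pl$x[1])^2 +
                  (pl$z[length(pl$z)] - pl$z[1])^2)
  idx <- arc / chord
  # the polyline arc can round a hair under the chord for collinear samples
  if (idx < 1 && idx > 1 - 1e-12) idx <- 1
  idx
}

#' All curvature metrics for one eye
#'
#' Composes [staphyloma_heights()], [fit_coefficient_a()] and
#' [curvature_index()] over the horizontal and vertical B-scan profiles of
#' one eye. Orientation averages are arithmetic means. Coefficient-a columns
#' are reported both in 1/um (`coef_a_*`) and on the conventional x 10^4
#' display scale (`coef_a_*_1e4`).
#'
#' @inheritParams staphyloma_heights
#' @return A one-row tibble with all height, coefficient-a and
#'   curvature-index columns.
#' @export
compute_metrics <- function(horizontal, vertical) {
  heights <- staphyloma_heights(horizontal, vertical)
  fa_h <- fit_coefficient_a(horizontal)$a
  fa_v <- fit_coefficient_a(vertical)$a
  ci_h <- curvature_index(horizontal)
  ci_v <- curvature_index(vertical)
  bind_cols(
    heights,
    tibble(
      coef_a_h = fa_h, coef_a_v = fa_v, coef_a_avg = (fa_h + fa_v) / 2,
      coef_a_h_1e4 = fa_h * 1e4, coef_a_v_1e4 = fa_v * 1e4,
      coef_a_avg_1e4 = (fa_h + fa_v) / 2 * 1e4,
      ci_h = ci_h, ci_v = ci_v, ci_avg = (ci_h + ci_v) / 2
    )
  )
}

#' Per-eye metrics for a whole cohort
#'
#' Runs [compute_metrics()] on every record of a geometry-level cohort
#' (cohorts that carry profiles); metric-level cohorts already hold their
#' metric columns and are returned with just the identifying columns
#' selected.
#'
#' @param cohort A `staphy_cohort` (see [as_cohort()]).
#' @return A tibble, one row per eye: `patient_id`, `eye`, `group`, then
#'   the metric columns.
#' @export
cohort_metrics <- function(cohort) {
  stopifnot(inherits(cohort, "staphy_cohort"))
  id_cols <- c("patient_id", "eye", "group")
  if (nrow(cohort) == 0) {
    return(tibble(patient_id = character(), eye = character(),
                  group = character()))
  }
  has_profiles <- !map_lgl(cohort$profile_h, is.null) &
    !map_lgl(cohort$profile_v, is.null)
  if (all(has_profiles)) {
    mets <- map(seq_len(nrow(cohort)), function(i) {
      compute_metrics(cohort$profile_h[[i]], cohort$profile_v[[i]])
    })
    bind_cols(as_tibble(cohort)[, id_cols], list_rbind(mets))
  } else if (all(cohort_metric_cols %in% names(cohort))) {
    as_tibble(cohort)[, c(id_cols, cohort_metric_cols)]
  } else {
    abort_validation(
      "Cohort has neither complete profiles nor precomputed metric columns."
    )
  }
}

#' Foveoschisis height
#'
#' The perpendicular (elevation) distance between the internal limiting
#' membrane (ILM) and the inner RPE at the foveal centre. In eyes with a
#' full-thickness macular hole the ILM is interrupted; the measurement then
#' uses the straight line bridging the ILM at the two hole edges.
#'
#' @param ilm The ILM polyline: an [rpe_profile()] or a data frame with
#'   columns `x_um`, `z_um`.
#' @param rpe The RPE profile of the same scan.
#' @param hole Optional numeric length-2 interval `c(lo, hi)` straddling 0:
#'   the lateral extent of a full-thickness macular hole.
#' @return The foveoschisis height in micrometres (>= 0).
#' @export
foveoschisis_height <- function(ilm, rpe, hole = NULL) {
  ilm_fun <- function(x) {
    if (is_rpe_profile(ilm)) {
      elevation_at(ilm, x)
    } else {
      approx(ilm$x_um, ilm$z_um, xout = x, ties = "ordered")$y
    }
  }
  if (is.null(hole)) {
    ilm0 <- ilm_fun(0)
  } else {
    if (length(hole) != 2 || hole[1] >= 0 || hole[2] <= 0) {
      abort_validation("`hole` must be an interval c(lo, hi) straddling x = 0.")
    }
    z_lo <- ilm_fun(hole[1])
    z_hi <- ilm_fun(hole[2])
    # linear ILM bridge across the hole, evaluated at the foveal centre
    ilm0 <- z_lo + (0 - hole[1]) / (hole[2] - hole[1]) * (z_hi - z_lo)
  }
  rpe0 <- elevation_at(rpe, 0)
  fsh <- ilm0 - rpe0
  if (fsh < 0) {
    abort_validation(sprintf(
      "Negative foveoschisis height (%.1f um): ILM lies posterior to the RPE.", fsh
    ))
  }
  fsh
}

#' Average subfoveal choroidal thickness
#'
#' Arithmetic mean of the subfoveal choroidal thickness measured on the
#' horizontal and vertical fovea-centred B-scans.
#'
#' @param sct_horizontal,sct_vertical Thickness in micrometres, >= 0.
#' @return Mean thickness in micrometres (vectorised).
#' @export
average_sct <- function(sct_horizontal, sct_vertical) {
  if (any(sct_horizontal < 0, na.rm = TRUE) ||
      any(sct_vertical < 0, na.rm = TRUE)) {
    abort_validation("Choroidal thickness cannot be negative.")
  }
  (sct_horizontal + sct_vertical) / 2
}
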