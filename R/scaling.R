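#' Ocular magnification correction factor
#'
#' Lateral lengths measured on an OCT B-scan of a long eye underestimate the
#' true anatomical dimensions. The correction used here converts an on-image
#' measurement *s* to the actual dimension *t* by
#' `t = 3.382 x 0.01306 x (axial length - 1.82) x s`, i.e. a single
#' multiplicative factor linear in axial length. The factor equals 1 at an
#' axial length of about 24.46 mm and grows by 3.382 x 0.01306 ~= 0.0442 per
#' additional millimetre.
#'
#' @param axial_length_mm Axial length(s) in millimetres; must exceed
#'   1.82 mm, below which the formula is degenerate.
#' @return A tibble with columns `axial_length_mm` and `factor`.
#' @examples
#' scale_factor(c(26.5, 29.8))
#' @export
scale_factor <- function(axial_length_mm) {
  if (!is.numeric(axial_length_mm) || !all(is.finite(axial_length_mm))) {
    abort_validation("`axial_length_mm` must be finite numeric.")
  }
  if (any(axial_length_mm <= 1.82)) {
    abort_domain(
      "Axial length must exceed 1.82 mm; the magnification formula is degenerate at or below it."
    )
  }
  tibble(
    axial_length_mm = as.double(axial_length_mm),
    factor = 3.382 * 0.01306 * (axial_length_mm - 1.82)
  )
}

#' Apply magnification correction to a profile
#'
#' Multiplies the lateral coordinate of an on-image profile by the
#' axial-length correction factor of [scale_factor()]. Elevations are left
#' untouched: after 1:1 micrometre conversion the axial (depth) sampling of
#' the OCT is taken as true, independent of ocular magnification. All
#' downstream "3 mm from the fovea" landmarks refer to actual,
#' post-correction micrometres. Applying the correction twice is an error.
#'
#' @param profile An unscaled [rpe_profile()].
#' @return The profile with corrected `x_um` and `scaled = TRUE`.
#' @export
rescale_profile <- function(profile) {
  check_profile(profile)
  if (profile_is_scaled(profile)) {
    abort_state("Profile is already magnification-corrected; refusing to rescale twice.")
  }
  f <- scale_factor(profile_axial_length(profile))$factor
  rpe_profile(
    profile$x_um * f, profile$z_um,
    orientation = profile_orientation(profile),
    axial_length_mm = profile_axial_length(profile),
    scaled = TRUE
  )
}
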