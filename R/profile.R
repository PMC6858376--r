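#' Construct an RPE depth profile
#'
#' An `rpe_profile` is the traced hyperreflective RPE/Bruch line of one
#' fovea-centred OCT B-scan, stored as a tibble of sample points with scan
#' metadata in attributes. Lateral position `x_um` is measured from the fovea
#' (negative = nasal for horizontal scans, inferior for vertical scans);
#' elevation `z_um` increases anteriorly (toward the vitreous), so a posterior
#' staphyloma is an upward-opening curve with its minimum near the fovea.
#' Profiles are centred at construction so that elevation at the sample
#' nearest the fovea is exactly zero.
#'
#' @param x_um Numeric vector of lateral positions in micrometres, strictly
#'   increasing.
#' @param z_um Numeric vector of RPE elevations in micrometres, same length
#'   as `x_um`.
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param axial_length_mm Axial length of the eye in millimetres.
#' @param scaled Logical; `TRUE` once the lateral coordinate has been
#'   corrected for ocular magnification (see [rescale_profile()]).
#'
#' @return A tibble of class `rpe_profile` with columns `x_um`, `z_um` and
#'   attributes `orientation`, `axial_length_mm`, `scaled`.
#' @examples
#' x <- seq(-3000, 3000, by = 300)
#' p <- rpe_profile(x, 7e-5 * x^2, "horizontal", 29.8, scaled = TRUE)
#' p
#' @export
rpe_profile <- function(x_um, z_um, orientation = c("horizontal", "vertical"),
                        axial_length_mm, scaled = FALSE) {
  orientation <- arg_match(orientation)
  x_um <- as.double(x_um)
  z_um <- as.double(z_um)
  if (length(x_um) != length(z_um)) {
    abort_validation("`x_um` and `z_um` must have the same length.")
  }
  if (length(x_um) < 2) {
    abort_validation("An RPE profile needs at least 2 sample points.")
  }
  if (!all(is.finite(x_um)) || !all(is.finite(z_um))) {
    abort_validation("Profile coordinates must all be finite.")
  }
  if (any(diff(x_um) <= 0)) {
    bad <- which(diff(x_um) <= 0)[1]
    abort_validation(sprintf(
      "`x_um` must be strictly increasing; violation between samples %d and %d (x = %g, %g).",
      bad, bad + 1, x_um[bad], x_um[bad + 1]
    ))
  }
  if (!is.numeric(axial_length_mm) || length(axial_length_mm) != 1 ||
      !is.finite(axial_length_mm) || axial_length_mm <= 0) {
    abort_validation("`axial_length_mm` must be a single positive number.")
  }
  # centre: elevation at the sample nearest the fovea defines the zero level
  z_um <- z_um - z_um[which.min(abs(x_um))]
  out <- tibble(x_um = x_um, z_um = z_um)
  attr(out, "orientation") <- orientation
  attr(out, "axial_length_mm") <- as.double(axial_length_mm)
  attr(out, "scaled") <- isTRUE(scaled)
  class(out) <- c("rpe_profile", class(out))
  out
}

is_rpe_profile <- function(x) inherits(x, "rpe_profile")

#' Profile metadata accessors
#'
#' @param profile An [rpe_profile()].
#' @return `profile_orientation()` returns `"horizontal"` or `"vertical"`;
#'   `profile_axial_length()` the axial length in mm; `profile_is_scaled()`
#'   a logical.
#' @export
profile_orientation <- function(profile) attr(profile, "orientation")

#' @rdname profile_orientation
#' @export
profile_axial_length <- function(profile) attr(profile, "axial_length_mm")

#' @rdname profile_orientation
#' @export
profile_is_scaled <- function(profile) isTRUE(attr(profile, "scaled"))

check_profile <- function(profile, arg = caller_arg(profile)) {
  if (!is_rpe_profile(profile)) {
    abort_validation(sprintf("`%s` must be an <rpe_profile>.", arg))
  }
  invisible(profile)
}

# refuse metric operations on profiles that do not cover the +/- half_span
# window (in actual, post-scaling micrometres)
check_span <- function(profile, half_span = 3000, arg = caller_arg(profile)) {
  check_profile(profile, arg)
  if (!profile_is_scaled(profile)) {
    abort_state(sprintf(
      "`%s` has not been magnification-corrected; call rescale_profile() first.", arg
    ))
  }
  x <- profile$x_um
  if (min(x) > -half_span) {
    abort_range(sprintf(
      "`%s` does not reach %g um on the nasal/inferior side (min x = %g).",
      arg, -half_span, min(x)
    ))
  }
  if (max(x) < half_span) {
    abort_range(sprintf(
      "`%s` does not reach %g um on the temporal/superior side (max x = %g).",
      arg, half_span, max(x)
    ))
  }
  invisible(profile)
}

#' Reflect a profile laterally
#'
#' Maps `x` to `-x` (nasal/temporal or superior/inferior swap), used to
#' normalise left eyes to the nasal-negative convention.
#'
#' @param profile An [rpe_profile()].
#' @return The reflected profile.
#' @export
flip_lateral <- function(profile) {
  check_profile(profile)
  rpe_profile(
    rev(-profile$x_um), rev(profile$z_um),
    orientation = profile_orientation(profile),
    axial_length_mm = profile_axial_length(profile),
    scaled = profile_is_scaled(profile)
  )
}

#' @export
print.rpe_profile <- function(x, ...) {
  cat(sprintf(
    "<rpe_profile> %s, %d samples, x in [%g, %g] um, AL %.2f mm, %s\n",
    profile_orientation(x), nrow(x), min(x$x_um), max(x$x_um),
    profile_axial_length(x),
    if (profile_is_scaled(x)) "magnification-corrected" else "on-image units"
  ))
  NextMethod()
}

#' Plot an RPE profile
#'
#' @param object An [rpe_profile()].
#' @param ... Unused.
#' @return A ggplot of elevation against lateral position, y-flipped so the
#'   staphyloma appears as the posterior bowing seen on a B-scan.
#' @export
autoplot.rpe_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$x_um, y = -.data$z_um)) +
    geom_line(colour = "grey30") +
    geom_hline(yintercept = 0, linetype = "dotted") +
    labs(
      x = "Lateral position from fovea (µm)",
      y = "Posterior displacement of RPE (µm)",
      title = sprintf("RPE profile (%s scan)", profile_orientation(object))
    ) +
    theme_minimal()
}
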