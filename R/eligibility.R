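#' High-myopia criterion
#'
#' An eye qualifies as highly myopic when its axial length is at least
#' 26.5 mm, or its spherical-equivalent refractive error is -6.0 dioptres
#' or more myopic. Pseudophakic eyes never qualify through refraction (the
#' intraocular lens decouples refraction from globe elongation), only
#' through axial length.
#'
#' @param axial_length_mm Axial length(s), mm.
#' @param refractive_error_d Spherical equivalent(s), dioptres (myopia
#'   negative).
#' @param pseudophakic Logical(s); `TRUE` for pseudophakic eyes.
#' @return Logical vector.
#' @examples
#' is_high_myopia(26.5, -2.0, FALSE) # TRUE: axial length at the boundary
#' is_high_myopia(25.0, -7.0, FALSE) # TRUE: refraction criterion
#' @export
is_high_myopia <- function(axial_length_mm, refractive_error_d,
                           pseudophakic = FALSE) {
  if (!all(is.finite(axial_length_mm))) {
    abort_validation("`axial_length_mm` must be finite.")
  }
  refraction_ok <- !is.na(refractive_error_d) & refractive_error_d <= -6.0
  axial_length_mm >= 26.5 | (!pseudophakic & refraction_ok)
}

# lower convex hull (Andrew monotone chain) of the profile samples;
# returns indices into x, which must be strictly increasing
lower_hull_idx <- function(x, z) {
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]
      b <- hull[length(hull)]
      # drop b if it lies on or above the segment a--i (cross product <= 0)
      cross <- (x[b] - x[a]) * (z[i] - z[a]) - (z[b] - z[a]) * (x[i] - x[a])
      if (cross <= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  hull
}

# anterior bulge of the RPE above the supporting tangent line bridging the
# fovea; the tangent is the lower-convex-hull segment whose endpoints
# bracket x = 0
rpe_bulge <- function(profile, half_span = 3000) {
  pl <- clip_polyline(profile, half_span)
  hull <- lower_hull_idx(pl$x, pl$z)
  xh <- pl$x[hull]
  seg <- which(xh[-length(xh)] < 0 & xh[-1] > 0)
  if (length(seg) == 0) {
    return(0) # the fovea sample itself supports the hull: no bridged bulge
  }
  a <- hull[seg]
  b <- hull[seg + 1]
  inside <- which(pl$x > pl$x[a] & pl$x < pl$x[b])
  if (length(inside) == 0) return(0)
  tangent <- pl$z[a] + (pl$x[inside] - pl$x[a]) / (pl$x[b] - pl$x[a]) *
    (pl$z[b] - pl$z[a])
  max(pl$z[inside] - tangent)
}

#' Dome-shaped macula rule
#'
#' Detects an inward (anterior) bulge of the macular RPE above a presumed
#' line tangent to the RPE at the bottom of the posterior staphyloma. The
#' tangent is operationalised as the lower-convex-hull segment of the
#' profile bridging the fovea; the eye is flagged when the maximal bulge
#' above that segment strictly exceeds `threshold_um` in either scan
#' orientation. A purely convex (bowl-shaped) profile has zero bulge.
#'
#' @inheritParams staphyloma_heights
#' @param threshold_um Bulge threshold in micrometres (default 50; the rule
#'   is strict, a bulge of exactly 50 um does not qualify).
#' @return Logical scalar.
#' @export
dome_shaped_macula <- function(horizontal, vertical, threshold_um = 50) {
  check_span(horizontal)
  check_span(vertical)
  rpe_bulge(horizontal) > threshold_um || rpe_bulge(vertical) > threshold_um
}

screening_reasons <- c(
  "not_high_myopia", "dome_shaped_macula", "staphyloma_not_foveal",
  "both_mtm_and_mcnv", "prior_treatment", "prior_buckle",
  "other_exudative_disease", "poor_image_quality", "duplicate_eye"
)

#' Screen a cohort against the study eligibility rules
#'
#' Evaluates, per eye, the high-myopia criterion, the dome-shaped-macula
#' rule (from the profiles when present, otherwise from the `dome_shaped`
#' flag column) and the metadata exclusion flags, and records every reason
#' for exclusion. An eye is eligible iff no reason applies.
#'
#' @param cohort A `staphy_cohort`, possibly with both eyes of some
#'   patients (`allow_duplicates = TRUE` on construction).
#' @param dome_threshold_um Threshold for [dome_shaped_macula()].
#' @return The cohort with logical column `eligible` and list-column
#'   `reasons` appended.
#' @export
screen_eyes <- function(cohort, dome_threshold_um = 50) {
  stopifnot(inherits(cohort, "staphy_cohort"))
  n <- nrow(cohort)
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    r <- character(0)
    if (!is_high_myopia(cohort$axial_length_mm[i],
                        cohort$refractive_error_d[i],
                        isTRUE(cohort$pseudophakic[i]))) {
      r <- c(r, "not_high_myopia")
    }
    dome <- if (!is.null(cohort$profile_h[[i]]) &&
                !is.null(cohort$profile_v[[i]])) {
      dome_shaped_macula(cohort$profile_h[[i]], cohort$profile_v[[i]],
                         dome_threshold_um)
    } else {
      isTRUE(cohort$dome_shaped[i])
    }
    if (dome) r <- c(r, "dome_shaped_macula")
    if (isTRUE(cohort$staphyloma_not_foveal[i])) r <- c(r, "staphyloma_not_foveal")
    if (isTRUE(cohort$mtm_and_mcnv[i])) r <- c(r, "both_mtm_and_mcnv")
    if (isTRUE(cohort$prior_treatment[i])) r <- c(r, "prior_treatment")
    if (isTRUE(cohort$prior_buckle[i])) r <- c(r, "prior_buckle")
    if (isTRUE(cohort$other_exudative[i])) r <- c(r, "other_exudative_disease")
    if (isTRUE(cohort$poor_image_quality[i])) r <- c(r, "poor_image_quality")
    reasons[[i]] <- r
  }
  out <- cohort
  out$eligible <- lengths(reasons) == 0
  out$reasons <- reasons
  out
}

#' One eye per patient
#'
#' Keeps one record per patient from a screened cohort: ineligible eyes are
#' dropped, and when both eyes of a patient remain eligible the right eye
#' (OD) is kept.
#'
#' @param cohort A screened `staphy_cohort` (output of [screen_eyes()]; if
#'   no `eligible` column is present all eyes are treated as eligible).
#' @return The cohort restricted to one eligible eye per patient.
#' @export
one_eye_per_patient <- function(cohort) {
  stopifnot(inherits(cohort, "staphy_cohort"))
  if (nrow(cohort) == 0) return(cohort)
  elig <- if ("eligible" %in% names(cohort)) cohort$eligible else rep(TRUE, nrow(cohort))
  out <- cohort[elig, , drop = FALSE]
  dup_patients <- unique(out$patient_id[duplicated(out$patient_id)])
  keep <- rep(TRUE, nrow(out))
  for (pid in dup_patients) {
    idx <- which(out$patient_id == pid)
    od <- idx[out$eye[idx] == "OD"]
    if (length(od) == 0) {
      abort_validation(sprintf(
        "Patient %s has multiple eligible records but no unique OD eye.", pid
      ))
    }
    keep[setdiff(idx, od[1])] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  attr(out, "provenance") <- cohort_provenance(cohort)
  attr(out, "seed") <- cohort_seed(cohort)
  out
}
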