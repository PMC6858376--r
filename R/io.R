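#' Read and write RPE profile files
#'
#' Two plain-text dialects carry the same payload: a CSV with columns
#' `x_um`, `z_um` plus a JSON sidecar (`<path>.json`) holding the scan
#' metadata, or a single JSON file with fields `orientation`,
#' `axial_length_mm`, `scaled`, `x_um`, `z_um`. Profiles are re-centred on
#' read so elevation at the sample nearest the fovea is zero; a profile
#' written by [write_rpe_profile()] therefore round-trips exactly.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; guessed from the file extension by
#'   default.
#' @return [read_rpe_profile()] returns an [rpe_profile()];
#'   [write_rpe_profile()] returns `path`, invisibly.
#' @export
read_rpe_profile <- function(path, format = c("auto", "csv", "json")) {
  format <- arg_match(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    abort_parse(sprintf("Profile file does not exist: '%s'.", path))
  }
  if (format == "csv") {
    dat <- withCallingHandlers(
      readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
      warning = function(w) invokeRestart("muffleWarning")
    )
    probs <- readr::problems(dat)
    if (nrow(probs) > 0) {
      abort_parse(sprintf(
        "Malformed profile CSV '%s': %s at line %d.",
        path, probs$expected[1], probs$row[1]
      ))
    }
    if (!all(c("x_um", "z_um") %in% names(dat))) {
      abort_parse(sprintf(
        "Profile CSV '%s' must have columns x_um and z_um (found: %s).",
        path, paste(names(dat), collapse = ", ")
      ))
    }
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      abort_parse(sprintf(
        "Metadata sidecar '%s' is missing; it must carry orientation, axial_length_mm and scaled.",
        sidecar
      ))
    }
    meta <- jsonlite::fromJSON(sidecar)
    rpe_profile(
      dat$x_um, dat$z_um,
      orientation = meta$orientation,
      axial_length_mm = meta$axial_length_mm,
      scaled = isTRUE(meta$scaled)
    )
  } else {
    payload <- tryCatch(
      jsonlite::fromJSON(path),
      error = function(e) abort_parse(sprintf(
        "Malformed profile JSON '%s': %s", path, conditionMessage(e)
      ))
    )
    need <- c("orientation", "axial_length_mm", "x_um", "z_um")
    missing <- setdiff(need, names(payload))
    if (length(missing) > 0) {
      abort_parse(sprintf(
        "Profile JSON '%s' is missing field(s): %s.",
        path, paste(missing, collapse = ", ")
      ))
    }
    rpe_profile(
      payload$x_um, payload$z_um,
      orientation = payload$orientation,
      axial_length_mm = payload$axial_length_mm,
      scaled = isTRUE(payload$scaled)
    )
  }
}

#' @rdname read_rpe_profile
#' @param profile An [rpe_profile()] to write.
#' @export
write_rpe_profile <- function(profile, path, format = c("auto", "csv", "json")) {
  check_profile(profile)
  format <- arg_match(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  meta <- list(
    orientation = profile_orientation(profile),
    axial_length_mm = profile_axial_length(profile),
    scaled = profile_is_scaled(profile)
  )
  if (format == "csv") {
    readr::write_csv(tibble(x_um = profile$x_um, z_um = profile$z_um), path,
                     progress = FALSE)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    payload <- c(meta, list(x_um = profile$x_um, z_um = profile$z_um))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}

# cohort ---------------------------------------------------------------------

cohort_flag_cols <- c(
  "other_exudative", "prior_buckle", "mtm_and_mcnv", "staphyloma_not_foveal",
  "prior_treatment", "poor_image_quality", "dome_shaped"
)

cohort_metric_cols <- c(
  "h_nasal_um", "h_temporal_um", "h_superior_um", "h_inferior_um",
  "h_horizontal_um", "h_vertical_um", "h_total_um",
  "coef_a_h_1e4", "coef_a_v_1e4", "coef_a_avg_1e4",
  "ci_h", "ci_v", "ci_avg"
)

cohort_meta_cols <- c(
  "patient_id", "eye", "group", "age_years", "sex", "bcva_logmar",
  "axial_length_mm", "refractive_error_d", "pseudophakic",
  "staphyloma_type", "metapm_category", "sct_um", "fsh_um", "cnv_size_da"
)

#' Assemble an eye-level cohort
#'
#' A cohort is a tibble with one row per eye: clinical metadata, optional
#' exclusion flags, optional per-eye curvature metrics, and optional
#' horizontal/vertical [rpe_profile()]s in list-columns `profile_h`,
#' `profile_v`. `as_cohort()` validates enum fields, fills missing optional
#' columns, and enforces the one-record-per-patient invariant unless
#' `allow_duplicates = TRUE` (needed upstream of [one_eye_per_patient()]).
#'
#' @param x A data frame with at least `patient_id`, `eye`, `group`.
#' @param provenance `"measured"`, `"synthetic_metrics"` or
#'   `"synthetic_geometry"`.
#' @param seed Optional integer recorded alongside synthetic cohorts.
#' @param allow_duplicates Allow several eyes of one patient.
#' @return A tibble of class `staphy_cohort`.
#' @export
as_cohort <- function(x, provenance = c("measured", "synthetic_metrics",
                                        "synthetic_geometry"),
                      seed = NULL, allow_duplicates = FALSE) {
  provenance <- arg_match(provenance)
  x <- as_tibble(x)
  need <- c("patient_id", "eye", "group")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort_validation(sprintf("Cohort is missing column(s): %s.",
                             paste(missing, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (!all(x$eye %in% c("OD", "OS"))) {
      abort_validation("`eye` must be 'OD' or 'OS'.")
    }
    if (!all(x$group %in% c("MTM", "mCNV", "control"))) {
      abort_validation("`group` must be one of 'MTM', 'mCNV', 'control'.")
    }
    if ("metapm_category" %in% names(x) &&
        !all(is.na(x$metapm_category) | x$metapm_category %in% 1:4)) {
      abort_validation("`metapm_category` must be in 1..4.")
    }
    if ("staphyloma_type" %in% names(x) &&
        !all(is.na(x$staphyloma_type) |
               x$staphyloma_type %in% c("wide_macular", "narrow_macular", "other"))) {
      abort_validation(
        "`staphyloma_type` must be 'wide_macular', 'narrow_macular' or 'other'.")
    }
    dup <- duplicated(x$patient_id)
    if (!allow_duplicates && any(dup)) {
      abort_validation(sprintf(
        "One eye per patient: patient(s) %s appear more than once; screen with one_eye_per_patient() or set allow_duplicates = TRUE.",
        paste(unique(x$patient_id[dup]), collapse = ", ")
      ))
    }
  }
  for (col in cohort_flag_cols) {
    if (!col %in% names(x)) x[[col]] <- rep(FALSE, nrow(x))
  }
  for (col in setdiff(cohort_meta_cols, names(x))) {
    x[[col]] <- rep(NA_real_, nrow(x))
  }
  if (!"profile_h" %in% names(x)) x$profile_h <- rep(list(NULL), nrow(x))
  if (!"profile_v" %in% names(x)) x$profile_v <- rep(list(NULL), nrow(x))
  attr(x, "provenance") <- provenance
  attr(x, "seed") <- seed
  class(x) <- unique(c("staphy_cohort", class(x)))
  x
}

#' @rdname as_cohort
#' @export
cohort_provenance <- function(x) attr(x, "provenance")

#' @rdname as_cohort
#' @export
cohort_seed <- function(x) attr(x, "seed")

profile_rel_path <- function(dir_rel, patient_id, eye, which) {
  file.path(dir_rel, sprintf("%s_%s_%s.json", patient_id, eye, which))
}

#' Read and write cohort files
#'
#' A cohort is stored as one CSV (one row per eye, columns as in
#' [as_cohort()]) with per-eye profile JSON files referenced by relative
#' path in columns `profile_h_path` / `profile_v_path`.
#'
#' @param path Path of the cohort CSV. Profiles are written to / read from a
#'   sibling directory `<name>_profiles/`.
#' @param cohort A `staphy_cohort` tibble.
#' @param allow_duplicates Passed to [as_cohort()]; set `TRUE` for
#'   pre-screening cohorts with both eyes of some patients.
#' @return [read_cohort()] returns a `staphy_cohort`; [write_cohort()] the
#'   `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "staphy_cohort"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  pdir_rel <- paste0(tools::file_path_sans_ext(basename(path)), "_profiles")
  pdir <- file.path(dirname(path), pdir_rel)
  tab <- as_tibble(cohort)
  tab$profile_h_path <- NA_character_
  tab$profile_v_path <- NA_character_
  has_profiles <- nrow(tab) > 0 &&
    (any(!map_lgl(tab$profile_h, is.null)) || any(!map_lgl(tab$profile_v, is.null)))
  if (has_profiles) dir.create(pdir, showWarnings = FALSE)
  for (i in seq_len(nrow(tab))) {
    for (w in c("h", "v")) {
      p <- tab[[paste0("profile_", w)]][[i]]
      if (!is.null(p)) {
        rel <- profile_rel_path(pdir_rel, tab$patient_id[i], tab$eye[i], w)
        write_rpe_profile(p, file.path(dirname(path), rel), format = "json")
        tab[[paste0("profile_", w, "_path")]][i] <- rel
      }
    }
  }
  tab$profile_h <- NULL
  tab$profile_v <- NULL
  tab$provenance <- rep(cohort_provenance(cohort) %||% "measured", nrow(tab))
  seed <- cohort_seed(cohort)
  tab$seed <- rep(if (is.null(seed)) NA_integer_ else as.integer(seed), nrow(tab))
  readr::write_csv(tab, path, progress = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, allow_duplicates = FALSE) {
  if (!file.exists(path)) {
    abort_parse(sprintf("Cohort file does not exist: '%s'.", path))
  }
  tab <- withCallingHandlers(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    na = c("", "NA")),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (nrow(tab) == 0) {
    return(as_cohort(tibble(patient_id = character(), eye = character(),
                            group = character()),
                     provenance = "measured"))
  }
  provenance <- if ("provenance" %in% names(tab)) tab$provenance[1] else "measured"
  seed <- if ("seed" %in% names(tab) && !is.na(tab$seed[1])) tab$seed[1] else NULL
  tab$provenance <- NULL
  tab$seed <- NULL
  for (col in cohort_flag_cols) {
    if (col %in% names(tab)) tab[[col]] <- as.logical(tab[[col]])
  }
  if ("pseudophakic" %in% names(tab)) {
    tab$pseudophakic <- as.logical(tab$pseudophakic)
  }
  profs <- list(h = rep(list(NULL), nrow(tab)), v = rep(list(NULL), nrow(tab)))
  for (w in c("h", "v")) {
    col <- paste0("profile_", w, "_path")
    if (!col %in% names(tab)) next
    for (i in seq_len(nrow(tab))) {
      rel <- tab[[col]][i]
      if (is.na(rel) || !nzchar(rel)) next
      fp <- file.path(dirname(path), rel)
      if (!file.exists(fp)) {
        abort_parse(sprintf(
          "Profile file '%s' referenced by eye %s/%s is missing.",
          rel, tab$patient_id[i], tab$eye[i]
        ))
      }
      profs[[w]][[i]] <- read_rpe_profile(fp, format = "json")
    }
    tab[[col]] <- NULL
  }
  tab$profile_h <- profs$h
  tab$profile_v <- profs$v
  as_cohort(tab, provenance = provenance, seed = seed,
            allow_duplicates = allow_duplicates)
}
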