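#' One-way analysis of variance
#'
#' Classical (equal-variance) one-way ANOVA of a continuous variable across
#' group labels, as used for the between-group rows of the baseline and
#' curvature tables.
#'
#' @param data A data frame.
#' @param value,group Column names (strings or bare names) of the response
#'   and the grouping factor.
#' @return A one-row tibble: `f_statistic`, `df_between`, `df_within`,
#'   `p_value`, `n`.
#' @export
one_way_anova <- function(data, value, group) {
  value <- as_name(enquo(value))
  group <- as_name(enquo(group))
  y <- data[[value]]
  g <- factor(data[[group]])
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]
  g <- droplevels(g[ok])
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    abort_domain("ANOVA needs >= 2 groups with >= 2 observations each.")
  }
  res <- oneway.test(y ~ g, var.equal = TRUE)
  tibble(
    f_statistic = unname(res$statistic),
    df_between = as.integer(res$parameter[["num df"]]),
    df_within = as.integer(res$parameter[["denom df"]]),
    p_value = res$p.value,
    n = length(y)
  )
}

#' Bonferroni-corrected pairwise t-tests
#'
#' Post-hoc two-sample t-tests for every pair of groups, with the raw
#' p-values multiplied by the number of pairs and capped at 1. The default
#' is Student's equal-variance t; set `var_equal = FALSE` for Welch.
#'
#' @inheritParams one_way_anova
#' @param var_equal Assume equal variances (Student's t, the default).
#' @return A tibble with one row per pair: `group1`, `group2`,
#'   `t_statistic`, `df`, `p_raw`, `p_adjusted`.
#' @export
bonferroni_pairwise_t <- function(data, value, group, var_equal = TRUE) {
  value <- as_name(enquo(value))
  group <- as_name(enquo(group))
  y <- data[[value]]
  g <- factor(data[[group]])
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]
  g <- droplevels(g[ok])
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    abort_domain("Pairwise t-tests need >= 2 groups with >= 2 observations each.")
  }
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  m <- length(pairs)
  rows <- map(pairs, function(pr) {
    tt <- t.test(y[g == pr[1]], y[g == pr[2]], var.equal = var_equal)
    tibble(
      group1 = pr[1], group2 = pr[2],
      t_statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_raw = tt$p.value,
      p_adjusted = min(1, tt$p.value * m)
    )
  })
  list_rbind(rows)
}

#' Pearson chi-square test of a contingency table
#'
#' Pearson's chi-square without continuity correction, as used for the
#' categorical baseline rows (sex, staphyloma type, META-PM category).
#' Warnings about small expected counts are collected into an attribute
#' rather than raised.
#'
#' @param counts A matrix (or table) of nonnegative integer counts, at
#'   least 2 x 2.
#' @return A one-row tibble: `statistic`, `df`, `p_value`,
#'   `min_expected`.
#' @examples
#' sex <- rbind(MTM = c(17, 55), mCNV = c(11, 47), control = c(20, 49))
#' chi_square_test(sex) # p = 0.418
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    abort_validation("Contingency table must be at least 2 x 2.")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_validation("Counts must be nonnegative integers.")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort_validation("Contingency table has an all-zero row or column.")
  }
  res <- suppressWarnings(chisq.test(counts, correct = FALSE))
  tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value,
    min_expected = min(res$expected)
  )
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors (pairs with missing values are dropped;
#'   at least 3 complete pairs and nonzero variance required).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A one-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- arg_match(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) {
    abort_domain("Correlation needs at least 3 complete pairs.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort_domain("Correlation is undefined for a zero-variance variable.")
  }
  res <- suppressWarnings(cor.test(x, y, method = method))
  tibble(r = unname(res$estimate), p_value = res$p.value, n = length(x))
}

report_continuous_vars <- c(
  age_years = "Age (years)",
  bcva_logmar = "BCVA (logMAR)",
  axial_length_mm = "Axial length (mm)",
  refractive_error_d = "Refractive error (D)",
  sct_um = "Subfoveal choroidal thickness (um)"
)

report_curvature_vars <- c(
  h_nasal_um = "Staphyloma height, nasal (um)",
  h_temporal_um = "Staphyloma height, temporal (um)",
  h_superior_um = "Staphyloma height, superior (um)",
  h_inferior_um = "Staphyloma height, inferior (um)",
  h_horizontal_um = "Staphyloma height, horizontal (um)",
  h_vertical_um = "Staphyloma height, vertical (um)",
  h_total_um = "Staphyloma height, total (um)",
  coef_a_h_1e4 = "Coefficient a x 10^4, horizontal",
  coef_a_v_1e4 = "Coefficient a x 10^4, vertical",
  coef_a_avg_1e4 = "Coefficient a x 10^4, average",
  ci_h = "Curvature index, horizontal",
  ci_v = "Curvature index, vertical",
  ci_avg = "Curvature index, average"
)

group_summary_row <- function(dat, var, group) {
  dat |>
    group_by(.data[[group]]) |>
    summarise(mean = mean(.data[[var]], na.rm = TRUE),
              sd = sd(.data[[var]], na.rm = TRUE),
              n = sum(is.finite(.data[[var]])), .groups = "drop") |>
    mutate(variable = var, .before = 1)
}

safe_anova <- function(dat, var, group) {
  tryCatch(
    one_way_anova(dat, !!sym(var), !!sym(group)) |>
      mutate(variable = var, degenerate = FALSE, .before = 1),
    error = function(e) tibble(
      variable = var, f_statistic = NA_real_, df_between = NA_integer_,
      df_within = NA_integer_, p_value = NA_real_, n = NA_integer_,
      degenerate = TRUE
    )
  )
}

#' Build the full group-comparison report
#'
#' Assembles the three analysis layers of the study on any cohort with
#' per-eye metrics: (1) a baseline table of demographics and clinical
#' characteristics (means +/- SD with one-way ANOVA for continuous rows,
#' counts with Pearson chi-square for categorical rows), (2) a curvature
#' table comparing every height, coefficient-a and curvature-index variable
#' across groups with Bonferroni post-hoc pairwise t-tests, and (3)
#' per-group correlations of the three headline curvature parameters with
#' myopia severity and with the group-conditional severity measure
#' (foveoschisis height in MTM, CNV size in mCNV). Pseudophakic eyes are
#' excluded from all refractive-error rows.
#'
#' @param cohort A `staphy_cohort` carrying the clinical metadata.
#' @param metrics Per-eye metrics as returned by [cohort_metrics()];
#'   computed from `cohort` when `NULL`.
#' @param cor_method Correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @param var_equal Equal-variance t for the post-hoc tests.
#' @return An object of class `comparison_report`; see
#'   [tidy.comparison_report()].
#' @export
build_report <- function(cohort, metrics = NULL,
                         cor_method = c("pearson", "spearman"),
                         var_equal = TRUE) {
  stopifnot(inherits(cohort, "staphy_cohort"))
  cor_method <- arg_match(cor_method)
  if (is.null(metrics)) metrics <- cohort_metrics(cohort)
  need <- c("patient_id", "group")
  missing <- setdiff(need, names(metrics))
  if (length(missing) > 0) {
    abort_validation(sprintf("`metrics` is missing column(s): %s.",
                             paste(missing, collapse = ", ")))
  }
  keys <- intersect(c("patient_id", "eye"), names(metrics))
  meta_cols <- setdiff(
    intersect(c(cohort_meta_cols, "eligible"), names(cohort)),
    setdiff(names(metrics), keys)
  )
  meta <- as_tibble(cohort)[, unique(c(keys, meta_cols))]
  dat <- left_join(metrics, meta, by = keys)

  # --- baseline (continuous) ------------------------------------------------
  base_rows <- map(names(report_continuous_vars), function(v) {
    if (!v %in% names(dat)) return(NULL)
    d <- dat
    if (v == "refractive_error_d") d <- d[!isTRUE_vec(d$pseudophakic), ]
    anova <- safe_anova(d, v, "group")
    list(summary = group_summary_row(d, v, "group"), test = anova)
  })
  base_rows <- base_rows[!map_lgl(base_rows, is.null)]
  baseline_summary <- list_rbind(map(base_rows, "summary"))
  baseline_tests <- list_rbind(map(base_rows, "test"))

  # --- baseline (categorical) ----------------------------------------------
  cat_vars <- c("sex", "staphyloma_type", "metapm_category")
  cat_rows <- map(cat_vars, function(v) {
    if (!v %in% names(dat) || all(is.na(dat[[v]]))) return(NULL)
    tab <- table(dat$group, dat[[v]])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    res <- tryCatch(chi_square_test(tab),
                    error = function(e) tibble(statistic = NA_real_,
                                               df = NA_real_,
                                               p_value = NA_real_,
                                               min_expected = NA_real_))
    mutate(res, variable = v, .before = 1)
  })
  categorical_tests <- list_rbind(cat_rows[!map_lgl(cat_rows, is.null)])

  # --- curvature table ------------------------------------------------------
  curv_vars <- intersect(names(report_curvature_vars), names(dat))
  curv_summary <- list_rbind(map(curv_vars, function(v) {
    group_summary_row(dat, v, "group")
  }))
  curv_tests <- list_rbind(map(curv_vars, function(v) safe_anova(dat, v, "group")))
  posthoc <- list_rbind(map(curv_vars, function(v) {
    res <- tryCatch(
      bonferroni_pairwise_t(dat, !!sym(v), group, var_equal = var_equal),
      error = function(e) NULL
    )
    if (is.null(res)) return(NULL)
    mutate(res, variable = v, .before = 1)
  }))

  # --- correlations ---------------------------------------------------------
  curve_params <- intersect(c("h_total_um", "coef_a_avg_1e4", "ci_avg"),
                            names(dat))
  severity_for_group <- function(g) {
    s <- c("axial_length_mm", "refractive_error_d")
    if (g == "MTM" && "fsh_um" %in% names(dat)) s <- c(s, "fsh_um")
    if (g == "mCNV" && "cnv_size_da" %in% names(dat)) s <- c(s, "cnv_size_da")
    s
  }
  groups <- unique(dat$group)
  correlations <- list_rbind(map(groups, function(g) {
    dg <- dat[dat$group == g, ]
    list_rbind(map(curve_params, function(cp) {
      list_rbind(map(severity_for_group(g), function(sv) {
        dd <- dg
        if (sv == "refractive_error_d") dd <- dd[!isTRUE_vec(dd$pseudophakic), ]
        res <- tryCatch(
          pearson_correlation(dd[[cp]], dd[[sv]], method = cor_method),
          error = function(e) tibble(r = NA_real_, p_value = NA_real_,
                                     n = sum(is.finite(dd[[cp]]) &
                                               is.finite(dd[[sv]])))
        )
        mutate(res, group = g, parameter = cp, against = sv, .before = 1)
      }))
    }))
  }))

  structure(
    list(
      n_by_group = dplyr::count(dat, .data$group, name = "n"),
      baseline_summary = baseline_summary,
      baseline_tests = baseline_tests,
      categorical_tests = categorical_tests,
      curvature_summary = curv_summary,
      curvature_tests = curv_tests,
      posthoc = posthoc,
      correlations = correlations,
      cor_method = cor_method
    ),
    class = "comparison_report"
  )
}

isTRUE_vec <- function(x) !is.na(x) & x == TRUE

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat("Groups:", paste(sprintf("%s (n=%d)", x$n_by_group$group,
                               x$n_by_group$n), collapse = ", "), "\n")
  cat("Curvature ANOVA p-values:\n")
  ct <- x$curvature_tests
  for (i in seq_len(nrow(ct))) {
    cat(sprintf("  %-18s p = %s\n", ct$variable[i],
                format.pval(ct$p_value[i], digits = 3, eps = 1e-3)))
  }
  invisible(x)
}

#' Tidy a comparison report
#'
#' @param x A `comparison_report` from [build_report()].
#' @param table Which layer to return: `"curvature"` (ANOVA rows, default),
#'   `"curvature_summary"`, `"baseline"`, `"baseline_summary"`,
#'   `"categorical"`, `"posthoc"` or `"correlations"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.comparison_report <- function(x, table = c("curvature",
                                                "curvature_summary",
                                                "baseline", "baseline_summary",
                                                "categorical", "posthoc",
                                                "correlations"), ...) {
  table <- arg_match(table)
  switch(table,
    curvature = x$curvature_tests,
    curvature_summary = x$curvature_summary,
    baseline = x$baseline_tests,
    baseline_summary = x$baseline_summary,
    categorical = x$categorical_tests,
    posthoc = x$posthoc,
    correlations = x$correlations
  )
}

#' @export
glance.comparison_report <- function(x, ...) {
  tibble(
    n_total = sum(x$n_by_group$n),
    n_groups = nrow(x$n_by_group),
    n_curvature_vars = nrow(x$curvature_tests),
    n_correlations = nrow(x$correlations),
    cor_method = x$cor_method
  )
}

#' Plot a comparison report
#'
#' Group means with +/- 1 SD error bars for the three headline curvature
#' parameters.
#'
#' @param object A `comparison_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.comparison_report <- function(object, ...) {
  keep <- c("h_total_um", "coef_a_avg_1e4", "ci_avg")
  df <- object$curvature_summary |>
    filter(.data$variable %in% keep) |>
    mutate(variable = factor(.data$variable, levels = keep))
  ggplot(df, aes(x = .data$group, y = .data$mean)) +
    geom_col(fill = "grey70") +
    geom_errorbar(aes(ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd), width = 0.2) +
    facet_wrap(~variable, scales = "free_y") +
    labs(x = NULL, y = "Group mean ± SD") +
    theme_minimal()
}

#' Scatterplots of inter-metric correlations
#'
#' The triptych of pairwise scatterplots among the three curvature
#' parameters, coloured by group.
#'
#' @param metrics A per-eye metrics tibble ([cohort_metrics()] output or a
#'   metric-level cohort).
#' @return A ggplot.
#' @export
plot_curvature_correlations <- function(metrics) {
  need <- c("h_total_um", "coef_a_avg_1e4", "ci_avg")
  missing <- setdiff(need, names(metrics))
  if (length(missing) > 0) {
    abort_validation(sprintf("`metrics` is missing column(s): %s.",
                             paste(missing, collapse = ", ")))
  }
  prs <- list(c("h_total_um", "coef_a_avg_1e4"),
              c("coef_a_avg_1e4", "ci_avg"),
              c("ci_avg", "h_total_um"))
  df <- list_rbind(map(prs, function(pr) {
    tibble(panel = paste(pr[1], "vs", pr[2]),
           x = metrics[[pr[1]]], y = metrics[[pr[2]]],
           group = metrics$group)
  }))
  ggplot(df, aes(x = .data$x, y = .data$y, colour = .data$group)) +
    geom_point(alpha = 0.7, size = 1.5) +
    facet_wrap(~panel, scales = "free") +
    labs(x = NULL, y = NULL, colour = NULL) +
    theme_minimal()
}
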