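test_that("one-way ANOVA agrees with the explicit sum-of-squares oracle", {
  set.seed(11)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    n <- sample(5:20, k, replace = TRUE)
    dat <- tibble::tibble(
      y = rnorm(sum(n), mean = rep(rnorm(k, sd = 2), n)),
      g = rep(letters[1:k], n)
    )
    got <- one_way_anova(dat, y, g)
    oracle <- brute_anova(dat$y, dat$g)
    expect_equal(got$f_statistic, oracle$f, tolerance = 1e-10)
    expect_equal(got$p_value, oracle$p, tolerance = 1e-10)
    expect_equal(got$df_between, k - 1L)
    expect_equal(got$df_within, sum(n) - k)
  }
})

test_that("ANOVA handles zero within-group variance and degenerate input", {
  dat <- tibble::tibble(y = rep(c(1, 2), each = 3), g = rep(c("a", "b"), each = 3))
  res <- one_way_anova(dat, y, g)
  expect_true(is.infinite(res$f_statistic) || res$f_statistic > 1e10)
  expect_lt(res$p_value, 1e-15)
  expect_error(one_way_anova(tibble::tibble(y = 1:3, g = "a"), y, g),
               class = "staphycurve_domain_error")
  expect_error(one_way_anova(tibble::tibble(y = 1:3, g = c("a", "a", "b")),
                             y, g),
               class = "staphycurve_domain_error")
})

test_that("ANOVA type-I error is close to the nominal 5% under the null", {
  set.seed(13)
  rejections <- replicate(1000, {
    dat <- tibble::tibble(y = rnorm(30), g = rep(c("a", "b", "c"), each = 10))
    one_way_anova(dat, y, g)$p_value < 0.05
  })
  # binomial SE at p=0.05, n=1000 is ~0.0069
  expect_equal(mean(rejections), 0.05, tolerance = 0.022 / 0.05)
})

test_that("Bonferroni post-hoc: x3 scaling, cap at 1, monotone in raw p", {
  set.seed(17)
  dat <- tibble::tibble(
    y = c(rnorm(20, 0), rnorm(20, 1.2, 3), rnorm(20, 0.1)),
    g = rep(c("a", "b", "c"), each = 20)
  )
  res <- bonferroni_pairwise_t(dat, y, g)
  expect_equal(nrow(res), 3)
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 3))
  expect_true(all(res$p_adjusted <= 1))
  expect_true(all(diff(res$p_adjusted[order(res$p_raw)]) >= 0))
  # agreement with a direct Student t
  tt <- t.test(dat$y[dat$g == "a"], dat$y[dat$g == "b"], var.equal = TRUE)
  expect_equal(res$p_raw[res$group1 == "a" & res$group2 == "b"], tt$p.value,
               tolerance = 1e-12)
  # Welch switch changes the df
  welch <- bonferroni_pairwise_t(dat, y, g, var_equal = FALSE)
  expect_false(isTRUE(all.equal(welch$df, res$df)))
})

test_that("chi-square matches the expected-count oracle and published tables", {
  set.seed(19)
  for (i in 1:10) {
    tab <- matrix(rpois(12, lambda = 20) + 1, 3, 4)
    got <- chi_square_test(tab)
    oracle <- brute_chisq(tab)
    expect_equal(got$statistic, oracle$stat, tolerance = 1e-10)
    expect_equal(got$df, oracle$df)
    expect_equal(got$p_value, oracle$p, tolerance = 1e-10)
  }
  # perfectly proportional table: statistic 0, p 1
  prop <- outer(c(10, 20, 30), c(1, 2)) / 1
  res0 <- chi_square_test(prop)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)
  expect_error(chi_square_test(matrix(c(0, 0, 1, 2), 2, 2)),
               class = "staphycurve_validation_error")
  expect_error(chi_square_test(matrix(1:3, 1, 3)),
               class = "staphycurve_validation_error")
})

test_that("Pearson correlation: exact cases, brute-force oracle, errors", {
  x <- 1:20
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -2 * x + 3)$r, -1)
  set.seed(23)
  a <- rnorm(40)
  b <- 0.6 * a + rnorm(40)
  got <- pearson_correlation(a, b)
  oracle <- brute_pearson(a, b)
  expect_equal(got$r, oracle$r, tolerance = 1e-12)
  expect_equal(got$p_value, oracle$p, tolerance = 1e-10)
  expect_error(pearson_correlation(rep(1, 10), rnorm(10)),
               class = "staphycurve_domain_error")
  expect_error(pearson_correlation(1:2, 2:3),
               class = "staphycurve_domain_error")
})

test_that("null correlations centre at zero; rho = 0.7 is recovered at n = 199", {
  set.seed(29)
  null_rs <- replicate(300, pearson_correlation(rnorm(30), rnorm(30))$r)
  expect_lt(abs(mean(null_rs)), 3 / sqrt(30 * 300) * 2)
  rho_hat <- replicate(200, {
    z <- rnorm(199)
    w <- 0.7 * z + sqrt(1 - 0.49) * rnorm(199)
    pearson_correlation(z, w)$r
  })
  # E[r] ~ rho with O(1/n) bias; MC tolerance generous
  expect_equal(mean(rho_hat), 0.7, tolerance = 0.02 / 0.7)
})

test_that("build_report reproduces the qualitative MTM > {mCNV, control} pattern", {
  coh <- sample_cohort_metrics(seed = 31)
  rep <- build_report(coh)
  ct <- tidy(rep, "curvature")
  for (v in c("h_total_um", "coef_a_avg_1e4", "ci_avg")) {
    expect_lt(ct$p_value[ct$variable == v], 0.05)
  }
  ph <- tidy(rep, "posthoc")
  ph_ci <- ph[ph$variable == "ci_avg", ]
  mtm_ctrl <- ph_ci[(ph_ci$group1 == "MTM" & ph_ci$group2 == "control") |
                      (ph_ci$group1 == "control" & ph_ci$group2 == "MTM"), ]
  mcnv_ctrl <- ph_ci[(ph_ci$group1 == "mCNV" & ph_ci$group2 == "control") |
                       (ph_ci$group1 == "control" & ph_ci$group2 == "mCNV"), ]
  expect_lt(mtm_ctrl$p_adjusted, 0.05)
  expect_gt(mcnv_ctrl$p_adjusted, 0.05)
  # group means ordered as published
  cs <- tidy(rep, "curvature_summary")
  ci_means <- setNames(cs$mean[cs$variable == "ci_avg"],
                       cs$group[cs$variable == "ci_avg"])
  expect_gt(ci_means["MTM"], ci_means["mCNV"])
  expect_gt(ci_means["MTM"], ci_means["control"])
})

test_that("build_report excludes pseudophakic eyes from refraction rows only", {
  coh <- sample_cohort_metrics(seed = 37)
  rep <- build_report(coh)
  bs <- tidy(rep, "baseline_summary")
  n_total <- sum(bs$n[bs$variable == "age_years"])
  n_refr <- sum(bs$n[bs$variable == "refractive_error_d"])
  expect_equal(n_total - n_refr, sum(coh$pseudophakic))
  # group-conditional correlations are restricted to their group
  corr <- tidy(rep, "correlations")
  expect_true(all(corr$group[corr$against == "fsh_um"] == "MTM"))
  expect_true(all(corr$group[corr$against == "cnv_size_da"] == "mCNV"))
  expect_true(all(corr$r >= -1 & corr$r <= 1, na.rm = TRUE))
})

test_that("build_report flags degenerate inputs instead of crashing", {
  tab <- make_test_cohort(9, ids = sprintf("P%02d", 1:9))
  tab$group <- rep(c("MTM", "mCNV", "control"), each = 3)
  for (v in c("h_nasal_um", "h_temporal_um", "h_superior_um", "h_inferior_um",
              "h_horizontal_um", "h_vertical_um", "h_total_um",
              "coef_a_h_1e4", "coef_a_v_1e4", "coef_a_avg_1e4",
              "ci_h", "ci_v", "ci_avg")) {
    tab[[v]] <- 1
  }
  coh <- as_cohort(tab, provenance = "synthetic_metrics")
  rep <- build_report(coh)
  ct <- tidy(rep, "curvature")
  expect_true(all(is.na(ct$p_value) | is.nan(ct$f_statistic) |
                    ct$degenerate | !is.finite(ct$f_statistic) |
                    is.na(ct$f_statistic)))
  expect_s3_class(rep, "comparison_report")
})

test_that("report generation is a pure function of its inputs", {
  coh <- sample_cohort_metrics(seed = 41)
  r1 <- build_report(coh)
  r2 <- build_report(coh)
  expect_identical(tidy(r1, "curvature"), tidy(r2, "curvature"))
  expect_identical(tidy(r1, "correlations"), tidy(r2, "correlations"))
  expect_error(build_report(coh, metrics = tibble::tibble(x = 1)),
               class = "staphycurve_validation_error")
})
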