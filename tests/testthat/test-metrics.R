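test_that("elevation_at interpolates linearly and refuses extrapolation", {
  p <- rpe_profile(c(-3000, 0, 3000), c(600, 0, 700), "horizontal", 29.8,
                   scaled = TRUE)
  expect_identical(elevation_at(p, 0), 0)
  expect_identical(elevation_at(p, 3000), 700)
  expect_equal(elevation_at(p, 1500), 350)
  expect_error(elevation_at(p, 3001), class = "staphycurve_range_error")

  # dense parabola: interpolation error bounded by a h^2 / 4
  a <- 7e-5
  dense <- parabola_profile(a, spacing = 10)
  xq <- runif(50, -3000, 3000)
  expect_equal(elevation_at(dense, xq), a * xq^2, tolerance = a * 10^2 / 4)
})

test_that("staphyloma heights recover the parabola and the sign rule", {
  h <- parabola_profile(7e-5)
  v <- parabola_profile(7e-5, orientation = "vertical")
  hh <- staphyloma_heights(h, v)
  expect_equal(hh$h_nasal_um, 7e-5 * 3000^2, tolerance = 1e-9)  # 630 um
  expect_equal(hh$h_total_um, 4 * 630, tolerance = 1e-9)
  expect_equal(hh$h_horizontal_um, hh$h_nasal_um + hh$h_temporal_um)
  expect_equal(hh$h_vertical_um, hh$h_superior_um + hh$h_inferior_um)

  flat <- staphyloma_heights(parabola_profile(0),
                             parabola_profile(0, orientation = "vertical"))
  expect_equal(unlist(flat), setNames(rep(0, 7), names(unlist(flat))))

  # pure tilt: the downhill side is negative, sums cancel
  tilted <- parabola_profile(0, tilt = 0.1)
  tv <- parabola_profile(0, orientation = "vertical")
  ht <- staphyloma_heights(tilted, tv)
  expect_equal(ht$h_nasal_um, -300, tolerance = 1e-9)
  expect_equal(ht$h_temporal_um, 300, tolerance = 1e-9)
  expect_equal(ht$h_horizontal_um, 0, tolerance = 1e-9)
})

test_that("heights are invariant under z-translation; reflection swaps sides", {
  a <- 9e-5
  tilt <- 0.03
  h <- parabola_profile(a, tilt = tilt)
  v <- parabola_profile(a, orientation = "vertical")
  ref <- staphyloma_heights(h, v)
  flipped <- staphyloma_heights(flip_lateral(h), v)
  expect_equal(flipped$h_nasal_um, ref$h_temporal_um, tolerance = 1e-9)
  expect_equal(flipped$h_temporal_um, ref$h_nasal_um, tolerance = 1e-9)
  expect_equal(flipped$h_total_um, ref$h_total_um, tolerance = 1e-9)
})

test_that("profiles not spanning 3 mm are refused, naming the short side", {
  short <- rpe_profile(seq(-2000, 3000, 100), rnorm(51), "horizontal", 29.8,
                       scaled = TRUE)
  v <- parabola_profile(7e-5, orientation = "vertical")
  expect_error(staphyloma_heights(short, v), "nasal",
               class = "staphycurve_range_error")
  unscaled <- parabola_profile(7e-5, scaled = FALSE)
  expect_error(curvature_index(unscaled), class = "staphycurve_state_error")
})

test_that("the 300-um-grid fit recovers exact quadratics to machine precision", {
  a_true <- 4.45e-4
  fit <- fit_coefficient_a(parabola_profile(a_true, spacing = 10))
  expect_equal(fit$a, a_true, tolerance = 1e-12)
  expect_equal(fit$n_points, 21L)

  # full (a, b, c) recovery on a general quadratic
  x <- seq(-3100, 3100, 10)
  p <- rpe_profile(x, 2e-4 * x^2 - 0.05 * x + 40, "horizontal", 29.8,
                   scaled = TRUE)
  f2 <- fit_coefficient_a(p)
  expect_equal(f2$a, 2e-4, tolerance = 1e-12)
  expect_equal(f2$b, -0.05, tolerance = 1e-12)
  expect_lt(f2$rss, 1e-12)

  line <- parabola_profile(0, tilt = 0.02)
  f3 <- fit_coefficient_a(line)
  expect_equal(f3$a, 0, tolerance = 1e-15)
  expect_lt(f3$rss, 1e-15)

  # x_unit_scale equivariance: scaling x by k divides a by k^2
  f_mm <- fit_coefficient_a(parabola_profile(a_true, spacing = 10),
                            x_unit_scale = 1e-3)
  expect_equal(f_mm$a, a_true * 1e6, tolerance = 1e-6)
})

test_that("least-squares fits are unbiased under noise with matching rss", {
  a_true <- 7e-5
  sigma <- 5
  set.seed(101)
  fits <- replicate(300, {
    x <- seq(-3000, 3000, 300)
    p <- rpe_profile(x, a_true * x^2 + rnorm(21, 0, sigma), "horizontal",
                     29.8, scaled = TRUE)
    f <- fit_coefficient_a(p)
    c(f$a, f$rss)
  })
  # mean(a) -> truth; MC error of the mean ~ se(a)/sqrt(300)
  expect_equal(mean(fits[1, ]), a_true, tolerance = 0.002)
  # rss / (n - p) -> sigma^2 (centering at construction absorbs ~1 df of
  # noise into the level, so compare loosely)
  expect_equal(mean(fits[2, ]) / 18, sigma^2, tolerance = 0.1)
})

test_that("curvature index matches the closed-form parabola arc length", {
  expect_equal(curvature_index(parabola_profile(0, tilt = 0.05)), 1)
  # straight segment -> exactly 1
  expect_identical(curvature_index(parabola_profile(0)), 1)

  idx <- curvature_index(parabola_profile(7.07e-5, spacing = 5))
  oracle <- parabola_index_closed_form(7.07e-5)
  expect_equal(idx, oracle, tolerance = 1e-4)
  expect_equal(oracle, parabola_index_quadrature(7.07e-5), tolerance = 1e-10)
  expect_equal(round(idx, 2), 1.03)

  # discretization: 21-point polyline underestimates the true arc by < 0.1%
  # for a <= 2e-4 / um
  for (a in c(5e-5, 1e-4, 2e-4)) {
    coarse <- curvature_index(parabola_profile(a, spacing = 300, span = 3000))
    truth <- parabola_index_closed_form(a)
    expect_lte(coarse, truth)
    expect_lt((truth - coarse) / truth, 0.001)
  }
})

test_that("curvature index >= 1 always, = 1 iff collinear (property)", {
  set.seed(202)
  for (i in 1:30) {
    a <- runif(1, 0, 2e-4)
    tilt <- runif(1, -0.2, 0.2)
    noise <- runif(1, 0, 10)
    x <- seq(-3100, 3100, 20)
    z <- a * x^2 + tilt * x + rnorm(length(x), 0, noise)
    p <- rpe_profile(x, z, "horizontal", 29.8, scaled = TRUE)
    ci <- curvature_index(p)
    expect_gte(ci, 1)
    if (a == 0 && noise == 0) expect_equal(ci, 1) else expect_gt(ci, 1)
  }
  # collinear but tilted: exactly 1
  expect_equal(curvature_index(parabola_profile(0, tilt = 0.12)), 1,
               tolerance = 1e-12)
})

test_that("index and coefficient are translation-invariant; chord includes elevation", {
  a <- 1.2e-4
  x <- seq(-3100, 3100, 10)
  p0 <- rpe_profile(x, a * x^2, "horizontal", 29.8, scaled = TRUE)
  p1 <- rpe_profile(x, a * x^2 + 500, "horizontal", 29.8, scaled = TRUE)
  expect_equal(curvature_index(p0), curvature_index(p1), tolerance = 1e-12)
  expect_equal(fit_coefficient_a(p0)$a, fit_coefficient_a(p1)$a,
               tolerance = 1e-15)
  # tilt lengthens the chord (elevation difference between endpoints)
  tilted <- parabola_profile(7e-5, tilt = 0.0775, spacing = 5)
  q_oracle <- parabola_index_quadrature(7e-5, tilt = 0.0775)
  expect_equal(curvature_index(tilted), q_oracle, tolerance = 1e-4)
})

test_that("metrics are strictly co-monotone in parabola steepness", {
  as <- seq(4e-5, 1.6e-4, length.out = 8)
  out <- t(vapply(as, function(a) {
    h <- parabola_profile(a)
    v <- parabola_profile(a, orientation = "vertical")
    m <- compute_metrics(h, v)
    c(m$h_total_um, m$coef_a_avg, m$ci_avg)
  }, numeric(3)))
  expect_true(all(diff(out[, 1]) > 0))
  expect_true(all(diff(out[, 2]) > 0))
  expect_true(all(diff(out[, 3]) > 0))
  # H-sum / coefficient identity for pure parabolas: H_h = 2 a X^2
  expect_equal(out[, 1] / 2, 2 * as * 3000^2, tolerance = 1e-9)
})

test_that("compute_metrics composes the three measures with exact averages", {
  h <- parabola_profile(7e-5)
  v <- parabola_profile(7e-5, orientation = "vertical")
  m <- compute_metrics(h, v)
  expect_equal(m$h_total_um, 2520, tolerance = 1e-9)
  expect_equal(m$ci_avg, parabola_index_closed_form(7e-5), tolerance = 1e-4)
  expect_equal(m$coef_a_avg, 7e-5, tolerance = 1e-12)
  expect_equal(m$coef_a_avg_1e4, 0.7, tolerance = 1e-9)
  expect_identical(m$ci_avg, (m$ci_h + m$ci_v) / 2)

  # H steeper than V: averages strictly between the orientations
  v2 <- parabola_profile(5e-5, orientation = "vertical")
  m2 <- compute_metrics(h, v2)
  expect_true(m2$coef_a_v < m2$coef_a_avg && m2$coef_a_avg < m2$coef_a_h)
  expect_true(m2$ci_v < m2$ci_avg && m2$ci_avg < m2$ci_h)
})

test_that("foveoschisis height handles direct, bridged and crossed layers", {
  x <- seq(-3100, 3100, 50)
  rpe <- rpe_profile(x, 7e-5 * x^2, "horizontal", 29.8, scaled = TRUE)
  ilm_flat <- tibble::tibble(x_um = x, z_um = 7e-5 * x^2 + 300)
  expect_equal(foveoschisis_height(ilm_flat, rpe), 300, tolerance = 1e-9)

  # full-thickness hole: ILM bridged between the hole edges
  ilm_hole <- tibble::tibble(x_um = c(-3000, -500, 500, 3000),
                             z_um = c(100, 250, 350, 450))
  expect_equal(foveoschisis_height(ilm_hole, rpe, hole = c(-500, 500)), 300,
               tolerance = 1e-9)

  # coincident layers -> zero height
  ilm_same <- tibble::tibble(x_um = x, z_um = 7e-5 * x^2)
  expect_equal(foveoschisis_height(ilm_same, rpe), 0, tolerance = 1e-9)

  ilm_below <- tibble::tibble(x_um = x, z_um = 7e-5 * x^2 - 50)
  expect_error(foveoschisis_height(ilm_below, rpe),
               class = "staphycurve_validation_error")
  expect_error(foveoschisis_height(ilm_flat, rpe, hole = c(100, 500)),
               class = "staphycurve_validation_error")
})

test_that("subfoveal choroidal thickness averages the two scans", {
  expect_equal(average_sct(30, 50), 40)
  expect_equal(average_sct(77, 77), 77)
  set.seed(5)
  a <- runif(1000, 0, 300)
  b <- runif(1000, 0, 300)
  expect_equal(average_sct(a, b), (a + b) / 2)
  expect_error(average_sct(-1, 10), class = "staphycurve_validation_error")
})

test_that("quad_fit has tidy and glance methods", {
  f <- fit_coefficient_a(parabola_profile(7e-5))
  td <- generics::tidy(f)
  expect_equal(td$term, c("a", "b", "c"))
  expect_equal(td$estimate[1], 7e-5, tolerance = 1e-12)
  gl <- generics::glance(f)
  expect_equal(gl$n_points, 21L)
  expect_equal(gl$df_residual, 18L)
})
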