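# geometry fixtures and independent oracles shared across test files

parabola_profile <- function(a, tilt = 0, spacing = 10, span = 3100,
                             orientation = "horizontal", al = 29.8,
                             scaled = TRUE, bump = 0, bump_sigma = 800) {
  x <- seq(-span, span, by = spacing)
  z <- a * x^2 + tilt * x + bump * exp(-x^2 / (2 * bump_sigma^2))
  rpe_profile(x, z, orientation = orientation, axial_length_mm = al,
              scaled = scaled)
}

# closed-form arc-length/chord index of z = a x^2 over [-X, X]:
# arc = X sqrt(1+u^2) + asinh(u)/(2a), chord = 2X, with u = 2 a X
parabola_index_closed_form <- function(a, X = 3000) {
  if (a == 0) return(1)
  u <- 2 * a * X
  (u * sqrt(1 + u^2) + asinh(u)) / (2 * u)
}

# same quantity by adaptive quadrature, as an independent cross-check
parabola_index_quadrature <- function(a, tilt = 0, X = 3000) {
  arc <- integrate(function(x) sqrt(1 + (2 * a * x + tilt)^2), -X, X,
                   rel.tol = 1e-12)$value
  chord <- sqrt((2 * X)^2 + (tilt * 2 * X)^2)
  arc / chord
}

# brute-force one-way ANOVA by explicit sum-of-squares decomposition
brute_anova <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g)
  N <- length(y)
  gm <- tapply(y, g, mean)
  ssb <- sum(tabulate(g) * (gm - mean(y))^2)
  ssw <- sum((y - gm[as.integer(g)])^2)
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(f = f, p = pf(f, k - 1, N - k, lower.tail = FALSE))
}

# brute-force Pearson chi-square from the expected-count formula
brute_chisq <- function(tab) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

# brute-force Pearson r and its t-based two-sided p
brute_pearson <- function(x, y) {
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  n <- length(x)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# minimal valid metric-level cohort tibble for IO / screening tests
make_test_cohort <- function(n = 3, eyes = rep("OD", n),
                             ids = sprintf("P%02d", seq_len(n))) {
  tibble::tibble(
    patient_id = ids,
    eye = eyes,
    group = rep(c("MTM", "mCNV", "control"), length.out = n),
    age_years = 55 + seq_len(n),
    sex = rep(c("F", "M"), length.out = n),
    bcva_logmar = 0.5,
    axial_length_mm = 29 + seq_len(n) / 10,
    refractive_error_d = -11,
    pseudophakic = FALSE,
    staphyloma_type = "wide_macular",
    metapm_category = 2L,
    sct_um = 40,
    fsh_um = NA_real_,
    cnv_size_da = NA_real_
  )
}
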