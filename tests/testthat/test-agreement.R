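test_that("MAPE covers its exact cases and the half-normal analytic limit", {
  r <- c(10, 11, 12, 13)
  expect_equal(mape(r, r), 0)
  expect_equal(mape(1.1 * r, r), 10)
  expect_error(mape(r, c(10, 11, 12, 0)), class = "bisffm_error_input")

  # d ~ N(0, 0.39), reference 11.4: MAPE -> 100 * 0.39 * sqrt(2/pi) / 11.4
  set.seed(31)
  ref <- rep(11.4, 2e5)
  pred <- ref + rnorm(2e5, 0, 0.39)
  expect_equal(mape(pred, ref), 2.7296, tolerance = 0.02)
})

test_that("CCC equals its frozen oracle and is bounded by Pearson r", {
  x <- c(10.2, 11.5, 12.3, 9.8, 11.0, 12.9)
  y <- c(10.0, 11.9, 12.0, 10.1, 10.6, 13.2)
  out <- ccc(x, y)
  # frozen independent direct-formula evaluation
  expect_equal(out$ccc, 0.958634274458306, tolerance = 1e-12)
  expect_equal(out$ccc_lo, 0.7494842689607027, tolerance = 1e-9)
  expect_equal(out$ccc_hi, 0.9937894662149426, tolerance = 1e-9)

  expect_equal(ccc(x, x)$ccc, 1)

  # a pure location shift with equal variances is penalized below r = 1
  shift <- ccc(x, x + 0.8)
  expect_lt(shift$ccc, 1)
  expect_equal(shift$ccc, stats::var(x) * (5 / 6) * 2 /
                 (2 * stats::var(x) * (5 / 6) + 0.8^2), tolerance = 1e-12)

  # |ccc| <= |r| on random data
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(30)
    b <- 0.5 * a + rnorm(30)
    expect_lte(abs(ccc(a, b)$ccc), abs(cor(a, b)) + 1e-12)
  }
  expect_error(ccc(rep(1, 5), 1:5), class = "bisffm_error_input")
})

test_that("Bland-Altman reports bias, SD and exact limits of agreement", {
  r <- c(10, 11, 12, 13, 14)
  same <- bland_altman(r, r)
  expect_equal(same$bias, 0)
  expect_equal(same$sd_diff, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))

  shifted <- bland_altman(r + 0.5, r)
  expect_equal(shifted$bias, 0.5)
  expect_equal(shifted$sd_diff, 0)

  # printed-row arithmetic: bias -0.43, SD 0.63 gives LOA (-1.66, 0.80)
  set.seed(17)
  ref <- rnorm(65, 11.4, 1.2)
  d <- with_exact_moments(rnorm(65), -0.43, 0.63)
  ba <- bland_altman(ref + d, ref)
  expect_equal(ba$bias, -0.43, tolerance = 1e-12)
  expect_equal(ba$sd_diff, 0.63, tolerance = 1e-12)
  expect_equal(round(ba$loa_low, 2), -1.66)
  expect_equal(round(ba$loa_high, 2), 0.80)

  # LOA identity holds for arbitrary data
  set.seed(18)
  for (i in 1:10) {
    p <- rnorm(20, 11, 1)
    q <- rnorm(20, 11, 1)
    b <- bland_altman(p, q)
    expect_equal(b$loa_low, b$bias - 1.96 * b$sd_diff)
    expect_equal(b$loa_high, b$bias + 1.96 * b$sd_diff)
  }
  expect_error(bland_altman(1:2, 1:2), class = "bisffm_error_input")
})

test_that("a deliberate proportional bias is detected, a constant one is not", {
  set.seed(19)
  ref <- rnorm(60, 11.4, 1.2)
  prop <- ref + 0.5 * (ref - 11.4) + rnorm(60, 0, 0.1)
  expect_lt(bland_altman(prop, ref)$proportional_bias_p, 0.01)
  flat <- ref + 0.5 + rnorm(60, 0, 0.1)
  expect_gt(bland_altman(flat, ref)$proportional_bias_p, 0.05)
})

test_that("Passing-Bablok matches exact lines and the enumeration oracle", {
  x <- c(8.8, 9.5, 10.1, 10.6, 10.9, 11.2, 11.6, 12.0, 12.4, 12.9, 13.3, 14.0)
  expect_equal(passing_bablok(x, x)$slope, 1)
  expect_equal(passing_bablok(x, x)$intercept, 0)
  lin <- passing_bablok(2 * x + 1, x)
  expect_equal(lin$slope, 2)
  expect_equal(lin$intercept, 1)

  # 12-point fixture frozen from an independent enumeration
  y <- c(9.1, 9.3, 10.5, 10.3, 11.4, 11.1, 11.9, 12.6, 12.2, 13.4, 13.1, 14.5)
  pb <- passing_bablok(y, x)
  expect_equal(pb$slope, 1.0384615384615388, tolerance = 1e-12)
  expect_equal(pb$intercept, -0.09230769230769642, tolerance = 1e-12)
  expect_equal(pb$slope_lo, 0.9090909090909094, tolerance = 1e-12)
  expect_equal(pb$slope_hi, 1.2352941176470584, tolerance = 1e-12)
  # and against the brute-force helper on fresh random data
  set.seed(23)
  for (i in 1:5) {
    a <- rnorm(15, 11, 1.5)
    b <- 1.2 * a + rnorm(15, 0, 0.4)
    expect_equal(passing_bablok(b, a)$slope, pb_slope_bruteforce(a, b))
  }
})

test_that("Passing-Bablok is axis-swap consistent and scale-equivariant", {
  # a design with all pairwise slopes positive, so the -1 offset rule is
  # inactive and the symmetry of the estimator is exact
  set.seed(24)
  a <- seq(8, 17, by = 0.5)[1:19]
  b <- 0.9 * a + 1 + rnorm(19, 0, 0.05)
  fwd <- passing_bablok(b, a)
  rev <- passing_bablok(a, b)
  expect_equal(fwd$slope, 1 / rev$slope, tolerance = 1e-12)
  scaled <- passing_bablok(3 * b, a)
  expect_equal(scaled$slope, 3 * fwd$slope, tolerance = 1e-12)
  expect_error(passing_bablok(b, rep(11, 19)), class = "bisffm_error_input")
})

test_that("TOST reproduces the equivalence decisions and frozen p-value", {
  set.seed(27)
  ref <- rnorm(20, 11.4, 1)
  # mean difference -0.04, SD 0.4397116: 90% CI (-0.210, 0.130), p = 0.023
  d <- with_exact_moments(rnorm(20), -0.04, 0.4397116)
  out <- tost(ref + d, ref, bound = 0.25)
  expect_equal(out$p, 0.02296279703544366, tolerance = 1e-9)
  expect_equal(out$ci90_lo, -0.21001266571884233, tolerance = 1e-7)
  expect_equal(out$ci90_hi, 0.13001266571884232, tolerance = 1e-7)
  expect_true(out$equivalent)

  # point estimate outside the bound can never be equivalent
  d2 <- with_exact_moments(rnorm(20), 0.26, 0.3)
  out2 <- tost(ref + d2, ref, bound = 0.25)
  expect_false(out2$equivalent)
  expect_gt(out2$p, 0.5)

  # exact zero differences
  out3 <- tost(ref, ref, bound = 0.1)
  expect_true(out3$equivalent)
  expect_equal(out3$p, 0)
})

test_that("the TOST decision equals the 90% CI inclusion rule", {
  set.seed(28)
  for (i in 1:25) {
    ref <- rnorm(15, 11, 1)
    pred <- ref + rnorm(15, runif(1, -0.4, 0.4), runif(1, 0.05, 0.6))
    out <- tost(pred, ref, bound = 0.25)
    ci_rule <- out$ci90_lo > -0.25 && out$ci90_hi < 0.25
    expect_identical(out$equivalent, ci_rule)
  }
})

test_that("percent_of_mean reproduces the printed percentage conversions", {
  expect_equal(round(percent_of_mean(-0.43, 11.4), 1), -3.8)
  expect_equal(round(percent_of_mean(-2.05, 11.4), 1), -18.0)
  expect_equal(round(percent_of_mean(0.74, 11.4), 1), 6.5)
  expect_equal(percent_of_mean(0, 11.4), 0)
  expect_error(percent_of_mean(1, 0), class = "bisffm_error_input")
})

test_that("agreement() assembles the full battery consistently", {
  set.seed(29)
  df <- tibble::tibble(ref = rnorm(30, 11.4, 1.1))
  df$pred <- df$ref + rnorm(30, 0.1, 0.4)
  rep <- agreement(df, pred, ref, tost_bound = 0.25, method_label = "demo")
  expect_s3_class(rep, "bis_agreement")
  expect_equal(rep$n, 30)
  expect_equal(rep$loa_low_kg, rep$bias_kg - 1.96 * rep$sd_diff_kg)
  expect_lte(abs(rep$ccc), abs(rep$pearson_r) + 1e-12)
  expect_equal(rep$bias_pct, 100 * rep$bias_kg / mean(df$ref))
  expect_true(all(c("mape_pct", "ccc_lo", "pb_slope", "tost_p",
                    "proportional_bias_p") %in% names(rep)))
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
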