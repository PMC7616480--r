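hydra <- mixture_config("xitron_hydra")

test_that("Hanai ECW matches the frozen arithmetic oracle and its scalings", {
  # cohort male covariate means through the De Lorenzo constants
  ecw <- ecw_hanai(100.3, 15.7, 786, hydra)
  expect_equal(ecw, 4.20376713261519, tolerance = 1e-12)

  # power-law scaling in r0
  expect_equal(ecw_hanai(100.3, 15.7, 2 * 786, hydra),
               ecw * 2^(-2 / 3), tolerance = 1e-12)

  # body-geometry factor enters as kb^(2/3)
  cfg4 <- mixture_config("xitron_hydra", kb = 4 * 4.3)
  expect_equal(ecw_hanai(100.3, 15.7, 786, cfg4), ecw * 4^(2 / 3),
               tolerance = 1e-12)

  # monotone in height and weight, decreasing in r0
  expect_gt(ecw_hanai(105, 15.7, 786, hydra), ecw)
  expect_gt(ecw_hanai(100.3, 17, 786, hydra), ecw)
  expect_lt(ecw_hanai(100.3, 15.7, 800, hydra), ecw)
  expect_error(ecw_hanai(100.3, 15.7, -1, hydra), class = "bisffm_error_input")
})

test_that("implicit ICW root matches the bisection oracle and its residual", {
  ecw <- ecw_hanai(100.3, 15.7, 786, hydra)
  icw <- icw_hanai(ecw, 786, 597, hydra)
  # frozen 40-digit bisection oracle
  expect_equal(icw, 2.78314886223874, tolerance = 1e-9)

  # defining residual to 10 significant digits, across random inputs
  set.seed(5)
  k_rho <- hydra$rho_tbw / hydra$rho_ecw
  for (i in 1:20) {
    r0 <- runif(1, 500, 1000)
    rinf <- r0 * runif(1, 0.6, 0.95)
    e <- runif(1, 2, 6)
    ic <- icw_hanai(e, r0, rinf, hydra)
    ri <- r0 * rinf / (r0 - rinf)
    lhs <- (1 + ic / e)^2.5
    rhs <- (r0 + ri) / ri * (1 + k_rho * ic / e)
    expect_lt(abs(lhs - rhs) / rhs, 1e-10)
  }

  # a stronger intracellular path (lower rinf) yields more ICW, and the
  # near-degenerate limit sits far below any physiological volume
  expect_gt(icw_hanai(ecw, 786, 500, hydra), icw_hanai(ecw, 786, 650, hydra))
  expect_gt(icw_hanai(ecw, 786, 650, hydra), icw_hanai(ecw, 786, 780, hydra))
  expect_lt(icw_hanai(ecw, 786, 786 * (1 - 1e-9), hydra), 0.05 * ecw)
  expect_error(icw_hanai(ecw, 700, 700, hydra), class = "bisffm_error_input")
})

test_that("Moissl BMI-adjusted volumes match the oracle and its monotonicities", {
  cfg <- mixture_config("moissl")
  v <- ecw_icw_moissl(100.3, 15.7, 786, 597, cfg)
  expect_equal(v$ecw_l, 4.11505180096388, tolerance = 1e-12)
  expect_equal(v$icw_l, 5.06529708552601, tolerance = 1e-12)

  # k_ecw = a/BMI + b exactly
  bmi <- 15.5
  h <- 100
  w <- bmi * (h / 100)^2
  k <- ecw_icw_moissl(h, w, 786, 597, cfg)$ecw_l /
    (h^2 * sqrt(w) / 786)^(2 / 3)
  expect_equal(k, cfg$moissl_a / 15.5 + cfg$moissl_b, tolerance = 1e-12)

  # higher BMI shrinks the ECW coefficient
  lean <- ecw_icw_moissl(100, 14, 786, 597, cfg)$ecw_l / (100^2 * sqrt(14) / 786)^(2 / 3)
  heavy <- ecw_icw_moissl(100, 20, 786, 597, cfg)$ecw_l / (100^2 * sqrt(20) / 786)^(2 / 3)
  expect_gt(lean, heavy)
})

test_that("hydration conversion is exact division with table lookup", {
  cfg <- mixture_config("xitron_hydra",
                        hydration_table = tibble::tibble(
                          sex = c("M", "F"), hydration = c(0.75, 0.765)))
  expect_equal(ffm_from_tbw(9.0, "M", cfg), 12.0)
  expect_equal(ffm_from_tbw(8.74, "F", cfg), 11.42, tolerance = 5e-3)

  # missing table entry
  cfg_m <- mixture_config("xitron_hydra",
                          hydration_table = tibble::tibble(
                            sex = "M", hydration = 0.75))
  expect_error(ffm_from_tbw(9, "F", cfg_m), class = "bisffm_error_config")

  # age-banded tables are honoured
  cfg_band <- mixture_config("xitron_hydra",
                             hydration_table = tibble::tibble(
                               sex = c("M", "M"),
                               age_min_days = c(0, 1300),
                               age_max_days = c(1300, 2000),
                               hydration = c(0.78, 0.76)))
  expect_equal(ffm_from_tbw(9, "M", cfg_band, age_days = 1200), 9 / 0.78)
  expect_equal(ffm_from_tbw(9, "M", cfg_band, age_days = 1400), 9 / 0.76)
})

test_that("predict_mixture composes the chain and conserves water", {
  d <- cohort_table(seed = 21)

  # composition equals the hand-chained oracle for the SFB7 default scheme
  cfg <- mixture_config("sfb7_default")
  out <- predict_mixture(d, method = "sfb7_default")
  i <- 4
  e_i <- ecw_hanai(d$height_cm[i], d$weight_scale_kg[i], d$r0_ohm[i], cfg)
  i_i <- icw_hanai(e_i, d$r0_ohm[i], d$rinf_ohm[i], cfg)
  f_i <- ffm_from_tbw(e_i + i_i, d$sex[i], cfg)
  expect_equal(out$ecw_l[i], e_i)
  expect_equal(out$icw_l[i], i_i)
  expect_equal(out$ffm_kg[i], f_i)

  # tbw = ecw + icw exactly, for every scheme
  for (m in mixture_methods()$method) {
    bc <- predict_mixture(d, method = m)
    expect_equal(bc$tbw_l, bc$ecw_l + bc$icw_l, tolerance = 1e-12)
    expect_true(all(bc$ecw_l > 0 & bc$icw_l > 0 & bc$ffm_kg > 0))
  }

  # personalised kb equal to the default reproduces the default scheme
  d_kb <- dplyr::mutate(d, kb_personal = 4.3)
  expect_equal(predict_mixture(d_kb, method = "sfb7_personal_kb")$ffm_kg,
               predict_mixture(d, method = "sfb7_default")$ffm_kg)
})

test_that("mixture FFM strictly decreases when both resistances scale up", {
  # less body water means proportionally higher resistance at all frequencies
  base <- tibble::tibble(child_id = "a", sex = "F", weight_scale_kg = 15.3,
                         height_cm = 98.6)
  for (m in mixture_methods()$method) {
    ffms <- vapply(c(1, 1.1, 1.2, 1.3), function(sc) {
      predict_mixture(dplyr::mutate(base, r0_ohm = sc * 757 * 1.090,
                                    rinf_ohm = sc * 757 * 0.828),
                      method = m)$ffm_kg
    }, numeric(1))
    expect_true(all(diff(ffms) < 0), info = m)
  }
})

test_that("scheme bias ordering on synthetic cohorts is seed-stable", {
  schemes <- setdiff(mixture_methods()$method, "sfb7_personal_kb")
  rank_for_seed <- function(seed) {
    d <- cohort_table(seed = seed)
    bias <- vapply(schemes, function(m) {
      mean(predict_mixture(d, method = m)$ffm_kg - d$ffm_dxa_kg)
    }, numeric(1))
    order(abs(bias))
  }
  expect_identical(rank_for_seed(301), rank_for_seed(302))
})

test_that("the registry validates methods and overrides", {
  expect_error(mixture_config("nope"), class = "bisffm_error_config")
  expect_error(mixture_config("moissl", not_a_constant = 1),
               class = "bisffm_error_config")
  expect_error(mixture_config("moissl",
                              hydration_table = tibble::tibble(
                                sex = "M", hydration = 0.95)),
               class = "bisffm_error_config")
})
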