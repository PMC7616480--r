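#' Configuration of the synthetic-cohort generator
#'
#' Defaults encode the study conditions the analysis assumes: the 3.5-year
#' cohort's sex and ethnicity mix (25 M / 40 F; 14 of 65 Asian), sex-specific
#' height and weight distributions, sex-specific DXA fat-free mass means, the
#' ratios of the Cole resistances to the 50 kHz resistance, the
#' between-replicate measurement CV (0.17%), and the DXA measurement noise
#' implied by the final model's residual error (0.39 kg). The free calibration
#' choices (`wh_correlation`, `ffm_weight_slope`, `ffm_resid_sd`) are
#' discussed in the methods vignette.
#'
#' @param n_children Number of children.
#' @param p_male,p_asian Bernoulli probabilities for sex and ethnicity.
#' @param height_mean,height_sd,weight_mean,weight_sd Named numeric vectors
#'   `c(M = , F = )` (cm, kg).
#' @param ffm_mean Named vector of sex-specific true FFM means (kg).
#' @param wh_correlation Within-sex weight-height correlation.
#' @param ffm_weight_slope Conditional FFM~weight slope (kg/kg) of the latent
#'   FFM model.
#' @param ffm_eth_effect Additive Asian-ethnicity effect on latent FFM (kg).
#' @param ffm_resid_sd SD of the latent physiological FFM residual (kg).
#' @param dxa_noise_sd SD of DXA FFM measurement noise (kg).
#' @param dxa_weight_sd SD of DXA weight about the adjusted-weight line (kg).
#' @param replicate_cv Between-replicate multiplicative gain CV of the
#'   impedance measurement (fraction; 0.0017 = 0.17%).
#' @param point_noise_cv Per-frequency multiplicative noise CV within a
#'   replicate (fraction).
#' @param r0_ratio,rinf_ratio Ratios r0/r50 and rinf/r50 (must bracket 1).
#' @param alpha Cole dispersion exponent.
#' @param n_freq,freq_min,freq_max Logarithmic frequency grid (kHz).
#' @param n_replicates Spectra per child.
#' @param age_mean,age_sd Age at visit (days).
#' @param r50_bounds Plausibility bounds on the derived r50 (ohm); children
#'   falling outside are resampled (counted, capped).
#' @param max_resample Cap on per-child resampling attempts.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_children = 65,
                         p_male = 25 / 65,
                         p_asian = 14 / 65,
                         height_mean = c(M = 100.3, F = 98.6),
                         height_sd = c(M = 3.4, F = 3.5),
                         weight_mean = c(M = 15.7, F = 15.3),
                         weight_sd = c(M = 2.0, F = 1.7),
                         ffm_mean = c(M = 12.0, F = 11.1),
                         wh_correlation = 0.6,
                         ffm_weight_slope = 0.15,
                         ffm_eth_effect = 0.28,
                         ffm_resid_sd = 1.06,
                         dxa_noise_sd = 0.39,
                         dxa_weight_sd = 0.05,
                         replicate_cv = 0.0017,
                         point_noise_cv = 0.0017,
                         r0_ratio = 1.090,
                         rinf_ratio = 0.828,
                         alpha = 0.10,
                         n_freq = 256,
                         freq_min = 3,
                         freq_max = 1000,
                         n_replicates = 3,
                         age_mean = 1232,
                         age_sd = 60,
                         r50_bounds = c(300, 1500),
                         max_resample = 100) {
  cfg <- as.list(environment())
  if (p_male < 0 || p_male > 1 || p_asian < 0 || p_asian > 1) {
    abort_bisffm("Probabilities must lie in [0, 1].",
                 class = "bisffm_error_config")
  }
  for (nm in c("height_sd", "weight_sd", "ffm_resid_sd", "dxa_noise_sd",
               "dxa_weight_sd", "replicate_cv", "point_noise_cv")) {
    if (any(cfg[[nm]] < 0)) {
      abort_bisffm(sprintf("`%s` must be >= 0.", nm),
                   class = "bisffm_error_config")
    }
  }
  if (!(rinf_ratio < 1 && 1 < r0_ratio)) {
    abort_bisffm("Need rinf_ratio < 1 < r0_ratio.",
                 class = "bisffm_error_config")
  }
  structure(cfg, class = "synth_config")
}

# characteristic frequency that places the Cole real part at r50 for 50 kHz,
# given r0 = r0_ratio * r50 and rinf = rinf_ratio * r50. Closed form: with
# u = (50/fc)^(1-alpha), c = cos((1-alpha) pi/2) and
# t = (1 - rinf_ratio)/(r0_ratio - rinf_ratio), the real part condition is the
# quadratic t u^2 + c (2t - 1) u + (t - 1) = 0.
solve_fc <- function(r0_ratio, rinf_ratio, alpha) {
  t <- (1 - rinf_ratio) / (r0_ratio - rinf_ratio)
  cth <- cos((1 - alpha) * pi / 2)
  disc <- cth^2 * (2 * t - 1)^2 - 4 * t * (t - 1)
  u <- (-cth * (2 * t - 1) + sqrt(disc)) / (2 * t)
  50 / u^(1 / (1 - alpha))
}

#' Generate a synthetic cohort
#'
#' Simulates children through the generative chain the analysis assumes:
#' sex and ethnicity are Bernoulli draws; height is normal within sex; weight
#' is an affine function of height plus noise reproducing the configured
#' within-sex weight distribution and weight-height correlation; latent true
#' FFM is an affine function of weight, sex and ethnicity (calibrated so
#' sex-specific FFM means match the configured targets) plus a physiological
#' residual; the impedance index is obtained by inverting the final impedance
#' prediction equation at the latent FFM, giving `r50 = height^2 / index`;
#' the Cole resistances follow from the configured ratios with the
#' characteristic frequency solved so the modelled 50 kHz resistance equals
#' r50; triplicate spectra add replicate-level gain noise and per-frequency
#' noise; and the DXA reference adds measurement noise to the latent FFM,
#' with DXA weight placed on the adjusted-weight line.
#'
#' One RNG stream is derived per child from (`seed`, child index), so a
#' child's draw is reproducible independent of the others; children whose
#' derived r50 falls outside `r50_bounds` are resampled within their own
#' stream (the count is recorded in `attr(, "n_resampled")`).
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @param spectra Generate the per-replicate impedance spectra (set `FALSE`
#'   to skip the heaviest part when only the tabular cohort is needed).
#' @return A list of class `bis_cohort` with tibbles `records` (covariates and
#'   generating Cole parameters), `references` (DXA measures) and `spectra`
#'   (long-format replicate spectra, or `NULL`).
#' @export
generate_cohort <- function(config = synth_config(), seed, spectra = TRUE) {
  if (missing(seed)) {
    abort_bisffm("`seed` is required.", class = "bisffm_error_input")
  }
  n <- config$n_children
  set.seed(seed)
  child_seeds <- if (n > 0) sample.int(2147483646L, n) else integer(0)

  eq <- ffm_equations()
  eq <- eq[eq$equation == "nipper_final", ]
  # calibrate the latent-FFM affine model to the configured sex-specific means
  a0 <- config$ffm_mean[["F"]] -
    config$ffm_weight_slope * config$weight_mean[["F"]] -
    config$ffm_eth_effect * config$p_asian
  sex_effect <- (config$ffm_mean[["M"]] - config$ffm_mean[["F"]]) -
    config$ffm_weight_slope *
      (config$weight_mean[["M"]] - config$weight_mean[["F"]])
  fc <- solve_fc(config$r0_ratio, config$rinf_ratio, config$alpha)
  fgrid <- exp(seq(log(config$freq_min), log(config$freq_max),
                   length.out = config$n_freq))

  # each child's draw is a plain numeric vector; tibbles are built once at
  # the end so large cohorts stay fast
  one_child <- function(i) {
    set.seed(child_seeds[i])
    attempts <- 0
    repeat {
      attempts <- attempts + 1
      if (attempts > config$max_resample) {
        abort_bisffm("Resampling cap exceeded: derived r50 keeps leaving its bounds.",
                     class = "bisffm_error_generator")
      }
      sex <- if (stats::runif(1) < config$p_male) "M" else "F"
      eth <- as.numeric(stats::runif(1) < config$p_asian)
      h <- stats::rnorm(1, config$height_mean[[sex]], config$height_sd[[sex]])
      b_wh <- config$wh_correlation * config$weight_sd[[sex]] /
        config$height_sd[[sex]]
      w <- config$weight_mean[[sex]] +
        b_wh * (h - config$height_mean[[sex]]) +
        stats::rnorm(1, 0, config$weight_sd[[sex]] *
                       sqrt(1 - config$wh_correlation^2))
      s_num <- as.numeric(sex == "M")
      ffm_true <- a0 + config$ffm_weight_slope * w + sex_effect * s_num +
        config$ffm_eth_effect * eth + stats::rnorm(1, 0, config$ffm_resid_sd)
      idx <- (ffm_true - eq$b0 - eq$b_w * w - eq$b_s * s_num - eq$b_e * eth) /
        eq$b_idx
      if (idx <= 0 || w <= 0 || h <= 0) next
      r50 <- h^2 / idx
      if (r50 >= config$r50_bounds[1] && r50 <= config$r50_bounds[2]) break
    }
    age <- stats::rnorm(1, config$age_mean, config$age_sd)
    ffm_dxa <- ffm_true + stats::rnorm(1, 0, config$dxa_noise_sd)
    w_dxa <- adjusted_weight(w) + stats::rnorm(1, 0, config$dxa_weight_sd)
    c(sex = s_num, eth = eth, age = age, w = w, h = h, r50 = r50,
      ffm_true = ffm_true, ffm_dxa = ffm_dxa, w_dxa = w_dxa,
      resampled = attempts - 1)
  }

  draws <- vapply(seq_len(n), one_child, numeric(10))
  draws <- if (n > 0) t(draws) else
    matrix(numeric(0), 0, 10,
           dimnames = list(NULL, c("sex", "eth", "age", "w", "h", "r50",
                                   "ffm_true", "ffm_dxa", "w_dxa",
                                   "resampled")))
  ids <- sprintf("C%04d", seq_len(n))
  records <- tibble(
    child_id = ids,
    sex = ifelse(draws[, "sex"] == 1, "M", "F"),
    ethnicity_asian = draws[, "eth"],
    age_days = draws[, "age"],
    weight_scale_kg = draws[, "w"],
    height_cm = draws[, "h"],
    r50_ohm = draws[, "r50"],
    r0_ohm = config$r0_ratio * draws[, "r50"],
    rinf_ohm = config$rinf_ratio * draws[, "r50"],
    fc_khz = rep_len(fc, n),
    alpha = rep_len(config$alpha, n),
    ffm_true_kg = draws[, "ffm_true"]
  )
  references <- tibble(
    child_id = ids,
    ffm_dxa_kg = draws[, "ffm_dxa"],
    weight_dxa_kg = draws[, "w_dxa"],
    fm_dxa_kg = draws[, "w_dxa"] - draws[, "ffm_dxa"],
    fm_pct = 100 * (draws[, "w_dxa"] - draws[, "ffm_dxa"]) / draws[, "w_dxa"]
  )

  spec_tbl <- NULL
  if (spectra) {
    spec_tbl <- purrr::map(seq_len(n), function(i) {
      set.seed(child_seeds[i] %% 2147483646L + 1L)
      rec <- records[i, ]
      z <- cole_z(fgrid, rec$r0_ohm, rec$rinf_ohm, rec$fc_khz, rec$alpha)
      purrr::map(seq_len(config$n_replicates), function(rep_i) {
        gain <- 1 + stats::rnorm(1, 0, config$replicate_cv)
        tibble(
          child_id = rec$child_id,
          replicate = rep_i,
          frequency_khz = fgrid,
          resistance_ohm = Re(z) * gain *
            (1 + stats::rnorm(config$n_freq, 0, config$point_noise_cv)),
          reactance_ohm = -Im(z) * gain *
            (1 + stats::rnorm(config$n_freq, 0, config$point_noise_cv))
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    if (n == 0) {
      spec_tbl <- tibble(
        child_id = character(), replicate = integer(),
        frequency_khz = numeric(), resistance_ohm = numeric(),
        reactance_ohm = numeric()
      )
    }
  }

  structure(
    list(records = records, references = references, spectra = spec_tbl,
         seed = seed, config = config),
    n_resampled = sum(draws[, "resampled"]),
    class = "bis_cohort"
  )
}

#' @export
print.bis_cohort <- function(x, ...) {
  cat(sprintf("Synthetic BIS cohort: %d children (seed %s)\n",
              nrow(x$records), format(x$seed)))
  cat(sprintf("  males: %d, Asian: %d, spectra: %s\n",
              sum(x$records$sex == "M"), sum(x$records$ethnicity_asian == 1),
              if (is.null(x$spectra)) "none" else
                sprintf("%d rows", nrow(x$spectra))))
  invisible(x)
}

#' Cohort overview plot
#'
#' Impedance index against DXA fat-free mass by sex, the relationship the
#' prediction equations exploit.
#'
#' @param object A `bis_cohort`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bis_cohort <- function(object, ...) {
  df <- dplyr::left_join(object$records, object$references, by = "child_id") |>
    dplyr::mutate(idx = impedance_index(.data$height_cm, .data$r50_ohm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$ffm_dxa_kg,
                                   colour = .data$sex)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(L^2 / R[50] ~ (cm^2 / Omega)),
                  y = "DXA fat-free mass (kg)", colour = "Sex")
}

#' Write a cohort to plain-text CSV files
#'
#' Writes `cohort.csv`, `reference.csv`, `spectra.csv` (when present) and a
#' `cohort_meta.json` carrying the seed, in the formats the other modules
#' read; [read_cohort()] round-trips them.
#'
#' @param cohort A `bis_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$records, file.path(dir, "cohort.csv"))
  readr::write_csv(cohort$references, file.path(dir, "reference.csv"))
  if (!is.null(cohort$spectra)) {
    readr::write_csv(cohort$spectra, file.path(dir, "spectra.csv"))
  }
  jsonlite::write_json(list(seed = cohort$seed),
                       file.path(dir, "cohort_meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the CSV files.
#' @return A `bis_cohort` (config is not round-tripped; the tables are).
#' @export
read_cohort <- function(dir) {
  records <- readr::read_csv(
    file.path(dir, "cohort.csv"),
    col_types = readr::cols(child_id = readr::col_character(),
                            sex = readr::col_character(),
                            .default = readr::col_double())
  )
  references <- readr::read_csv(
    file.path(dir, "reference.csv"),
    col_types = readr::cols(child_id = readr::col_character(),
                            .default = readr::col_double())
  )
  spectra <- NULL
  if (file.exists(file.path(dir, "spectra.csv"))) {
    spectra <- read_spectra(file.path(dir, "spectra.csv"))
  }
  meta <- jsonlite::read_json(file.path(dir, "cohort_meta.json"))
  structure(
    list(records = records, references = references, spectra = spectra,
         seed = meta$seed, config = NULL),
    class = "bis_cohort"
  )
}
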