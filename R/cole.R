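#' Cole model impedance
#'
#' Evaluates the four-parameter Cole model of complex bioimpedance,
#' \deqn{Z(f) = R_\infty + \frac{R_0 - R_\infty}{1 + (j f/f_c)^{1-\alpha}},}
#' the semicircular resistance-reactance locus that bioimpedance spectroscopy
#' devices fit to multi-frequency measurements. \eqn{R_0} and \eqn{R_\infty}
#' are the resistances at zero and infinite frequency (current confined to
#' extracellular water vs. passing through all body water), \eqn{f_c} the
#' characteristic frequency at which the capacitive reactance peaks, and
#' \eqn{\alpha} the dispersion broadening exponent.
#'
#' @param freq_khz Frequencies in kHz (vector, `>= 0`).
#' @param r0,rinf Resistance at zero / infinite frequency (ohm), `0 < rinf < r0`.
#' @param fc_khz Characteristic frequency (kHz, `> 0`).
#' @param alpha Dispersion exponent, `0 <= alpha < 1`.
#' @param td_us Optional cable/time-delay correction (microseconds). The default
#'   0 is the plain Cole model; a non-zero value multiplies the impedance by
#'   \eqn{\exp(-j 2\pi f T_d)}.
#'
#' @return A tibble with columns `freq_khz`, `resistance_ohm` and
#'   `reactance_ohm`. Reactance is reported as the positive magnitude of the
#'   capacitive reactance (\eqn{-\mathrm{Im}\,Z}).
#' @examples
#' cole_impedance(c(0, 50, 1e6), r0 = 786, rinf = 597, fc_khz = 40, alpha = 0.1)
#' @export
cole_impedance <- function(freq_khz, r0, rinf, fc_khz, alpha = 0.1, td_us = 0) {
  check_cole_parameters(r0, rinf, fc_khz, alpha)
  if (any(freq_khz < 0)) {
    abort_bisffm("`freq_khz` must be >= 0.", class = "bisffm_error_input")
  }
  z <- cole_z(freq_khz, r0, rinf, fc_khz, alpha, td_us)
  tibble(
    freq_khz = as.numeric(freq_khz),
    resistance_ohm = Re(z),
    reactance_ohm = -Im(z)
  )
}

# complex-valued Cole model; freq in kHz, td in microseconds
cole_z <- function(freq_khz, r0, rinf, fc_khz, alpha, td_us = 0) {
  z <- rinf + (r0 - rinf) / (1 + (1i * freq_khz / fc_khz)^(1 - alpha))
  if (td_us != 0) {
    z <- z * exp(-2i * pi * freq_khz * 1e3 * td_us * 1e-6)
  }
  z
}

check_cole_parameters <- function(r0, rinf, fc_khz, alpha) {
  check_positive(r0, "r0")
  check_positive(rinf, "rinf")
  check_positive(fc_khz, "fc_khz")
  if (any(rinf >= r0)) {
    abort_bisffm("Cole parameters require 0 < rinf < r0.",
                 class = "bisffm_error_input")
  }
  if (any(alpha < 0) || any(alpha >= 1)) {
    abort_bisffm("`alpha` must satisfy 0 <= alpha < 1.",
                 class = "bisffm_error_input")
  }
  invisible(NULL)
}

validate_spectrum <- function(spectrum) {
  spectrum <- as_tibble(spectrum)
  needed <- c("frequency_khz", "resistance_ohm", "reactance_ohm")
  if (!all(needed %in% names(spectrum))) {
    abort_bisffm(
      paste0("Spectrum needs columns ", paste(needed, collapse = ", "), "."),
      class = "bisffm_error_input"
    )
  }
  if (nrow(spectrum) < 8) {
    abort_bisffm("A spectrum needs at least 8 frequencies.",
                 class = "bisffm_error_input")
  }
  f <- spectrum$frequency_khz
  if (any(f <= 0) || is.unsorted(f, strictly = TRUE)) {
    abort_bisffm("Frequencies must be strictly ascending and > 0.",
                 class = "bisffm_error_input")
  }
  if (any(spectrum$resistance_ohm <= 0)) {
    abort_bisffm("Resistances must be > 0.", class = "bisffm_error_input")
  }
  spectrum
}

#' Fit the Cole model to one impedance spectrum
#'
#' Nonlinear least squares over the joint real and imaginary parts of the
#' measured impedance (equal weights), i.e. the orthogonal misfit on the Cole
#' plot. Starting values are taken from the data: `r0` from the largest
#' measured resistance, `rinf` from the smallest, `fc_khz` from the frequency
#' of maximal reactance magnitude.
#'
#' @param spectrum A data frame with columns `frequency_khz`,
#'   `resistance_ohm` and `reactance_ohm` (capacitive reactance magnitude),
#'   one row per frequency, at least 8 frequencies.
#' @param rmse_threshold Fits with root-mean-square misfit exceeding
#'   `rmse_threshold * r0` are flagged as poor (`quality_flag = TRUE`); such
#'   Cole plots would be remeasured in practice. Default 1% of `r0`.
#'
#' @return A one-row tibble of class `cole_fit`: `r0`, `rinf`, `fc_khz`,
#'   `alpha`, `fit_rmse` (ohm, RMS modulus of the complex residual) and
#'   `quality_flag`.
#' @examples
#' sp <- cole_impedance(exp(seq(log(3), log(1000), length.out = 64)),
#'                      r0 = 786, rinf = 597, fc_khz = 40, alpha = 0.1)
#' names(sp)[1] <- "frequency_khz"
#' fit_cole(sp)
#' @export
fit_cole <- function(spectrum, rmse_threshold = 0.01) {
  spectrum <- validate_spectrum(spectrum)
  f <- spectrum$frequency_khz
  r <- spectrum$resistance_ohm
  x <- spectrum$reactance_ohm

  if (max(abs(x)) < 1e-9 * stats::median(r) || stats::sd(r) < 1e-12 * stats::median(r)) {
    abort_bisffm(
      "Spectrum is degenerate (flat resistance or zero reactance): the Cole model is not identifiable.",
      class = "bisffm_error_nonidentifiable"
    )
  }

  start <- c(
    r0 = max(r) * 1.05,
    rinf = min(r) * 0.95,
    fc_khz = f[which.max(abs(x))],
    alpha = 0.1
  )
  resid_fun <- function(p) {
    z <- cole_z(f, p[["r0"]], p[["rinf"]], p[["fc_khz"]], p[["alpha"]])
    c(Re(z) - r, -Im(z) - x)
  }
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fun,
    lower = c(1e-6, 1e-6, 1e-6, 0),
    upper = c(Inf, Inf, Inf, 0.999),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (!fit$info %in% 1:4) {
    abort_bisffm(
      paste0("Cole fit did not converge (", fit$message, ")."),
      class = "bisffm_error_fit",
      diagnostics = fit
    )
  }
  p <- fit$par
  if (p[["rinf"]] >= p[["r0"]]) {
    abort_bisffm("Cole fit converged to rinf >= r0; spectrum is inconsistent with the model.",
                 class = "bisffm_error_fit", diagnostics = fit)
  }
  res <- resid_fun(p)
  n <- length(f)
  fit_rmse <- sqrt(mean(res[seq_len(n)]^2 + res[n + seq_len(n)]^2))
  out <- tibble(
    r0 = p[["r0"]], rinf = p[["rinf"]], fc_khz = p[["fc_khz"]],
    alpha = p[["alpha"]], fit_rmse = fit_rmse,
    quality_flag = fit_rmse > rmse_threshold * p[["r0"]]
  )
  class(out) <- c("cole_fit", class(out))
  attr(out, "spectrum") <- spectrum
  out
}

#' Quantities derived from Cole parameters
#'
#' Adds the two single-frequency summaries used by prediction equations:
#' `r50_ohm`, the modelled resistance at 50 kHz, and `zc_ohm`, the impedance
#' modulus at the characteristic frequency.
#'
#' @param params A data frame with columns `r0`, `rinf`, `fc_khz`, `alpha`
#'   (one row per fit), e.g. from [fit_cole()].
#' @return `params` with `r50_ohm` and `zc_ohm` columns added.
#' @export
cole_quantities <- function(params) {
  params <- as_tibble(params)
  check_cole_parameters(params$r0, params$rinf, params$fc_khz, params$alpha)
  z50 <- cole_z(50, params$r0, params$rinf, params$fc_khz, params$alpha)
  zfc <- cole_z(params$fc_khz, params$r0, params$rinf, params$fc_khz, params$alpha)
  dplyr::mutate(params, r50_ohm = Re(z50), zc_ohm = Mod(zfc))
}

#' Fit the Cole model to replicate spectra
#'
#' BIS measurements are made in triplicate; replicate fits are combined by the
#' parameter-wise median, and the between-replicate coefficient of variation of
#' the fitted 50 kHz resistance is reported as a precision summary.
#'
#' @param spectra A data frame of long-format spectra with columns
#'   `frequency_khz`, `resistance_ohm`, `reactance_ohm`, a `replicate` column,
#'   and optionally `child_id` (fits are aggregated within each child).
#' @inheritParams fit_cole
#' @return A tibble with one row per child (or a single row when `child_id`
#'   is absent): median `r0`, `rinf`, `fc_khz`, `alpha`, median `fit_rmse`,
#'   `quality_flag` (any replicate flagged), `n_replicates`, `r50_cv_pct`
#'   (percent CV of per-replicate r50), and derived `r50_ohm`, `zc_ohm`.
#' @export
fit_cole_replicates <- function(spectra, rmse_threshold = 0.01) {
  spectra <- as_tibble(spectra)
  if (nrow(spectra) == 0) {
    abort_bisffm("No spectra supplied.", class = "bisffm_error_input")
  }
  if (!"replicate" %in% names(spectra)) spectra$replicate <- 1L
  if (!"child_id" %in% names(spectra)) spectra$child_id <- NA_character_

  one_child <- function(df) {
    fits <- df |>
      dplyr::group_by(.data$replicate) |>
      dplyr::group_map(~ fit_cole(.x, rmse_threshold = rmse_threshold)) |>
      dplyr::bind_rows()
    fits <- cole_quantities(fits)
    agg <- tibble(
      r0 = stats::median(fits$r0),
      rinf = stats::median(fits$rinf),
      fc_khz = stats::median(fits$fc_khz),
      alpha = stats::median(fits$alpha),
      fit_rmse = stats::median(fits$fit_rmse),
      quality_flag = any(fits$quality_flag),
      n_replicates = nrow(fits),
      r50_cv_pct = if (nrow(fits) > 1) {
        100 * stats::sd(fits$r50_ohm) / mean(fits$r50_ohm)
      } else {
        NA_real_
      }
    )
    cole_quantities(agg)
  }

  out <- spectra |>
    dplyr::group_by(.data$child_id) |>
    dplyr::group_modify(~ one_child(.x)) |>
    dplyr::ungroup()
  if (all(is.na(out$child_id))) out$child_id <- NULL
  out
}

#' Read an impedance-spectra CSV
#'
#' Long format, one row per (child, replicate, frequency):
#' `child_id, replicate, frequency_khz, resistance_ohm, reactance_ohm`.
#'
#' @param path File path.
#' @return A tibble of spectra.
#' @export
read_spectra <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      child_id = readr::col_character(),
      replicate = readr::col_integer(),
      frequency_khz = readr::col_double(),
      resistance_ohm = readr::col_double(),
      reactance_ohm = readr::col_double()
    )
  )
}

#' Cole plot of a fitted spectrum
#'
#' Resistance-reactance locus of the measured points with the fitted Cole
#' semicircle overlaid; the visual check used to decide whether a measurement
#' should be repeated.
#'
#' @param object A `cole_fit` from [fit_cole()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cole_fit <- function(object, ...) {
  sp <- attr(object, "spectrum")
  fgrid <- exp(seq(log(min(sp$frequency_khz)), log(max(sp$frequency_khz)),
                   length.out = 200))
  curve <- cole_impedance(fgrid, object$r0, object$rinf, object$fc_khz,
                          object$alpha)
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$resistance_ohm,
                                   y = .data$reactance_ohm)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_path(data = curve, colour = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Resistance (Ω)",
                  y = "Reactance (Ω)",
                  title = sprintf("Cole plot (RMSE %.2f Ω)", object$fit_rmse))
}
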