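#' Mean absolute percentage error
#'
#' `100/n * sum(|predicted - reference| / reference)`.
#'
#' @param predicted,reference Paired measurements; all `reference > 0`.
#' @return MAPE in percent.
#' @export
mape <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    abort_bisffm("`predicted` and `reference` must have equal length.",
                 class = "bisffm_error_input")
  }
  check_positive(reference, "reference")
  100 * mean(abs(predicted - reference) / reference)
}

#' Lin's concordance correlation coefficient
#'
#' \deqn{\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},}
#' which penalizes both imprecision (scatter about the best-fit line) and
#' location/scale shift away from the identity line, so `|CCC| <= |r|` always.
#' The confidence interval uses the Fisher z-transform with Lin's asymptotic
#' variance.
#'
#' @param predicted,reference Paired measurements, `n >= 3`, both with
#'   non-zero variance.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A one-row tibble: `ccc`, `ccc_lo`, `ccc_hi`.
#' @export
ccc <- function(predicted, reference, conf_level = 0.95) {
  x <- predicted
  y <- reference
  n <- length(x)
  if (n < 3 || length(y) != n) {
    abort_bisffm("Need paired data with n >= 3.", class = "bisffm_error_input")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_bisffm("Zero variance in one of the arrays.",
                 class = "bisffm_error_input")
  }
  # Lin's moment estimators (1/n denominators)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  p <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  u <- (mx - my) / (sx2 * sy2)^(1 / 4)
  z <- atanh(p)
  sz2 <- ((1 - r^2) * p^2 / ((1 - p^2) * r^2) +
            2 * p^3 * (1 - p) * u^2 / (r * (1 - p^2)^2) -
            p^4 * u^4 / (2 * r^2 * (1 - p^2)^2)) / (n - 2)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble(
    ccc = p,
    ccc_lo = tanh(z - q * sqrt(sz2)),
    ccc_hi = tanh(z + q * sqrt(sz2))
  )
}

#' Bland-Altman analysis
#'
#' Differences are taken as `predicted - reference`, so a positive bias means
#' the method overestimates the reference. Limits of agreement are
#' `bias +/- 1.96 * SD` of the differences (SD with n-1 denominator).
#' Proportional bias is assessed by the t-test of the slope in the OLS
#' regression of the differences on the pairwise means.
#'
#' @param predicted,reference Paired measurements, `n >= 3`.
#' @return A one-row tibble: `n`, `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `proportional_bias_p`.
#' @export
bland_altman <- function(predicted, reference) {
  n <- length(predicted)
  if (n < 3 || length(reference) != n) {
    abort_bisffm("Need paired data with n >= 3.", class = "bisffm_error_input")
  }
  d <- predicted - reference
  m <- (predicted + reference) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  p <- if (s == 0 || stats::sd(m) == 0) {
    NA_real_
  } else {
    summary(stats::lm(d ~ m))$coefficients[2, 4]
  }
  tibble(
    n = n, bias = bias, sd_diff = s,
    loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    proportional_bias_p = p
  )
}

# all pairwise slopes, excluding undefined (x ties) and exactly -1 slopes
pb_slopes <- function(x, y) {
  n <- length(x)
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  s <- dy[dx != 0] / dx[dx != 0]
  s[s != -1]
}

#' Passing-Bablok regression
#'
#' Nonparametric method-comparison regression: the slope is the shifted
#' median of all pairwise slopes (slopes of -1 and pairs with tied x are
#' excluded, and the median is offset by the number of slopes below -1 so the
#' estimator is unbiased under swapped axes), the intercept is
#' `median(y - slope * x)`. Confidence intervals are the rank-based intervals
#' of the original method.
#'
#' @param reference Method on the x axis.
#' @param predicted Method on the y axis.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `slope`, `slope_lo`, `slope_hi`, `intercept`,
#'   `intercept_lo`, `intercept_hi`, `n`.
#' @export
passing_bablok <- function(predicted, reference, conf_level = 0.95) {
  y <- predicted
  x <- reference
  n <- length(x)
  if (n < 3 || length(y) != n) {
    abort_bisffm("Need paired data with n >= 3.", class = "bisffm_error_input")
  }
  if (stats::sd(x) == 0) {
    abort_bisffm("All x values identical; slope undefined.",
                 class = "bisffm_error_input")
  }
  s <- sort(pb_slopes(x, y))
  nvalid <- length(s)
  if (nvalid == 0) {
    abort_bisffm("No valid pairwise slopes.", class = "bisffm_error_input")
  }
  k <- sum(s < -1)
  # shifted median (arithmetic mean of the two middle order stats when even)
  mid <- (nvalid + 1) / 2
  b <- if (nvalid %% 2 == 1) {
    s[mid + k]
  } else {
    mean(s[nvalid / 2 + k + c(0, 1)])
  }
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  cq <- q * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- round((nvalid - cq) / 2)
  m2 <- nvalid - m1 + 1
  b_lo <- if (m1 + k >= 1) s[m1 + k] else NA_real_
  b_hi <- if (m2 + k <= nvalid) s[m2 + k] else NA_real_
  a <- stats::median(y - b * x)
  tibble(
    slope = b, slope_lo = b_lo, slope_hi = b_hi,
    intercept = a,
    intercept_lo = if (is.na(b_hi)) NA_real_ else stats::median(y - b_hi * x),
    intercept_hi = if (is.na(b_lo)) NA_real_ else stats::median(y - b_lo * x),
    n = n
  )
}

#' Two one-sided tests of equivalence (TOST)
#'
#' Paired differences (`predicted - reference`) are tested against the
#' equivalence bounds `(-bound, +bound)` with two one-sided t-tests; the TOST
#' p-value is the larger of the two one-sided p-values, and equivalence at
#' level 0.05 is identical to the 90% confidence interval of the mean
#' difference lying inside the bounds. Zero-variance differences are handled
#' exactly: equivalent iff `|mean difference| < bound`.
#'
#' @param predicted,reference Paired measurements, `n >= 3`.
#' @param bound Symmetric equivalence bound (same units as the data, `> 0`).
#' @return A one-row tibble: `mean_diff`, `ci90_lo`, `ci90_hi`, `p`,
#'   `equivalent`.
#' @export
tost <- function(predicted, reference, bound) {
  n <- length(predicted)
  if (n < 3 || length(reference) != n) {
    abort_bisffm("Need paired data with n >= 3.", class = "bisffm_error_input")
  }
  check_positive(bound, "bound")
  d <- predicted - reference
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    eq <- abs(m) < bound
    return(tibble(mean_diff = m, ci90_lo = m, ci90_hi = m,
                  p = as.numeric(!eq), equivalent = eq))
  }
  se <- s / sqrt(n)
  df <- n - 1
  p_lower <- stats::pt((m + bound) / se, df, lower.tail = FALSE)
  p_upper <- stats::pt((m - bound) / se, df, lower.tail = TRUE)
  p <- max(p_lower, p_upper)
  halfwidth <- stats::qt(0.95, df) * se
  tibble(
    mean_diff = m, ci90_lo = m - halfwidth, ci90_hi = m + halfwidth,
    p = p, equivalent = p < 0.05
  )
}

#' Express an absolute quantity as a percentage of a reference mean
#'
#' @param value Absolute quantity (e.g. a bias in kg).
#' @param mean_reference Reference mean (same units, `> 0`).
#' @return `100 * value / mean_reference`.
#' @examples
#' percent_of_mean(-0.43, 11.4)
#' @export
percent_of_mean <- function(value, mean_reference) {
  check_positive(mean_reference, "mean_reference")
  100 * value / mean_reference
}

#' Full method-agreement battery
#'
#' Runs every validation statistic used to compare a predicted body
#' composition against the reference: MAPE, Pearson r, Lin's CCC with CI,
#' Bland-Altman bias/SD/limits of agreement with the proportional-bias test,
#' Passing-Bablok regression, and the TOST equivalence decision.
#'
#' @param data A data frame holding the paired measurements.
#' @param predicted,reference Column names (tidyselect, unquoted) of the
#'   predicted and reference measurements (kg).
#' @param tost_bound Equivalence bound in kg (0.25 for FFM, 0.10 for FM in
#'   the study design).
#' @param mean_reference Mean used to express bias and LOA as percentages;
#'   defaults to the mean of the reference column.
#' @param method_label Free-text label stored with the report.
#' @param conf_level Confidence level for CCC and Passing-Bablok intervals.
#' @return A one-row tibble of class `bis_agreement` with the full battery;
#'   [autoplot()] draws the Bland-Altman plot.
#' @export
agreement <- function(data, predicted, reference, tost_bound = 0.25,
                      mean_reference = NULL, method_label = NULL,
                      conf_level = 0.95) {
  data <- as_tibble(data)
  pred <- dplyr::pull(data, {{ predicted }})
  ref <- dplyr::pull(data, {{ reference }})
  if (is.null(mean_reference)) mean_reference <- mean(ref)
  ba <- bland_altman(pred, ref)
  cc <- ccc(pred, ref, conf_level = conf_level)
  pb <- passing_bablok(pred, ref, conf_level = conf_level)
  tt <- tost(pred, ref, bound = tost_bound)
  out <- dplyr::bind_cols(
    tibble(
      method = method_label %||% "predicted",
      n = length(pred),
      mape_pct = mape(pred, ref),
      pearson_r = stats::cor(pred, ref)
    ),
    cc,
    tibble(
      bias_kg = ba$bias,
      bias_pct = percent_of_mean(ba$bias, mean_reference),
      sd_diff_kg = ba$sd_diff,
      loa_low_kg = ba$loa_low,
      loa_high_kg = ba$loa_high,
      proportional_bias_p = ba$proportional_bias_p
    ),
    tibble(
      pb_slope = pb$slope, pb_slope_lo = pb$slope_lo, pb_slope_hi = pb$slope_hi,
      pb_intercept = pb$intercept,
      pb_intercept_lo = pb$intercept_lo, pb_intercept_hi = pb$intercept_hi
    ),
    tibble(
      tost_bound_kg = tost_bound, tost_mean_diff = tt$mean_diff,
      tost_ci90_lo = tt$ci90_lo, tost_ci90_hi = tt$ci90_hi,
      tost_p = tt$p, equivalent = tt$equivalent
    )
  )
  class(out) <- c("bis_agreement", class(out))
  attr(out, "pairs") <- tibble(predicted = pred, reference = ref)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bland-Altman plot of an agreement report
#'
#' @param object A `bis_agreement` from [agreement()].
#' @param ... Unused.
#' @return A ggplot object: differences against pairwise means with the bias
#'   and 95% limits of agreement.
#' @export
autoplot.bis_agreement <- function(object, ...) {
  pairs <- attr(object, "pairs")
  df <- tibble(
    m = (pairs$predicted + pairs$reference) / 2,
    d = pairs$predicted - pairs$reference
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$d)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias_kg, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = c(object$loa_low_kg, object$loa_high_kg),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "Mean of predicted and reference (kg)",
      y = "Predicted - reference (kg)",
      title = sprintf("%s: bias %.2f kg (%.1f%%), LOA [%.2f, %.2f]",
                      object$method, object$bias_kg, object$bias_pct,
                      object$loa_low_kg, object$loa_high_kg)
    )
}
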