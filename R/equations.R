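#' Impedance index
#'
#' The standard bioimpedance predictor of conductive volume,
#' height squared over resistance at 50 kHz (cm^2/ohm).
#'
#' @param height_cm Standing height (cm, `>= 0`).
#' @param r50_ohm Resistance at 50 kHz (ohm, `> 0`).
#' @return `height_cm^2 / r50_ohm`, vectorized.
#' @examples
#' impedance_index(98.6, 757)
#' @export
impedance_index <- function(height_cm, r50_ohm) {
  check_positive(r50_ohm, "r50_ohm")
  if (any(height_cm < 0)) {
    abort_bisffm("`height_cm` must be >= 0.", class = "bisffm_error_input")
  }
  height_cm^2 / r50_ohm
}

#' Catalogue of fat-free mass prediction equations
#'
#' All printed equations addressable by id: the seven-model ladder developed
#' on the 3.5-year derivation cohort (weight W alone through the final
#' W + L^2/R50 + S + E model), and the two previously published preschool
#' equations (Ejlerskov, gram scale; Rush, kg scale). Coefficients are the
#' printed values; `b_*` columns are the terms (intercept, weight kg, height
#' cm, impedance index cm^2/ohm, male indicator, Asian indicator) and
#' `scale_g` marks equations printed in grams. `fm_weight` records which
#' weight convention each equation's fat-mass derivation uses.
#'
#' @return A tibble with one row per equation.
#' @export
ffm_equations <- function() {
  tibble(
    equation = c("w", "w_l", "w_l_s", "w_idx", "w_idx_s",
                 "nipper_anthro", "nipper_final", "ejlerskov", "rush"),
    b0  = c(2.88, -9.19, -7.41, 1.49, 1.55, -7.16, 1.39, -2784.4, -2.490),
    b_w = c(0.55, 0.32, 0.36, 0.26, 0.30, 0.37, 0.30, 223.8, 0.188),
    b_l = c(0, 0.16, 0.13, 0, 0, 0.13, 0, 76.8, 0.077),
    b_idx = c(0, 0, 0, 0.44, 0.39, 0, 0.39, 327.2, 0.367),
    b_s = c(0, 0, 0.47, 0, 0.30, 0.48, 0.30, 417.6, 0.273),
    b_e = c(0, 0, 0, 0, 0, 0.18, 0.28, 0, 0),
    scale_g = c(rep(FALSE, 7), TRUE, FALSE),
    fm_weight = c(rep("adjusted", 8), "scale"),
    adj_r2 = c(0.726, 0.788, 0.822, 0.864, 0.875, 0.822, 0.882, NA, NA),
    rmse_kg = c(0.609, 0.529, 0.479, 0.423, 0.402, 0.474, 0.386, NA, NA)
  )
}

covariate_range_warnings <- function(weight, height) {
  if (any(!is.na(weight) & (weight <= 5 | weight >= 40))) {
    warn("Some weights fall outside the 5-40 kg range the equations were developed for.",
         class = "bisffm_warning_range")
  }
  if (any(!is.na(height) & (height <= 70 | height >= 130))) {
    warn("Some heights fall outside the 70-130 cm range the equations were developed for.",
         class = "bisffm_warning_range")
  }
}

#' Predict fat-free mass with a catalogued equation
#'
#' Evaluates one of the [ffm_equations()] rows for every child. Equations are
#' exactly affine in their covariates; values outside the development cohort's
#' anthropometric range produce a warning, not an error.
#'
#' @param data A data frame with one row per child. Required columns depend
#'   on the equation: `weight_scale_kg` always; `height_cm` for equations with
#'   a height or impedance-index term; `r50_ohm` for impedance equations;
#'   `sex` ("M"/"F" or 0/1) for equations with a sex term; `ethnicity_asian`
#'   (0/1) for equations with an ethnicity term.
#' @param equation Equation id (see [ffm_equations()]); default the final
#'   impedance model `"nipper_final"`.
#' @return `data` with columns `ffm_pred_kg` and `equation` appended.
#' @examples
#' child <- tibble::tibble(weight_scale_kg = 15.3, height_cm = 98.6,
#'                         r50_ohm = 757, sex = "F", ethnicity_asian = 0)
#' predict_ffm(child, "nipper_final")$ffm_pred_kg
#' @export
predict_ffm <- function(data, equation = "nipper_final") {
  data <- as_tibble(data)
  eq <- ffm_equations()
  eq <- eq[eq$equation == equation, ]
  if (nrow(eq) == 0) {
    abort_bisffm(paste0("Unknown equation id '", equation, "'."),
                 class = "bisffm_error_config")
  }
  w <- data[["weight_scale_kg"]]
  if (is.null(w)) {
    abort_bisffm("`weight_scale_kg` is required.", class = "bisffm_error_input")
  }
  h <- data[["height_cm"]]
  if ((eq$b_l != 0 || eq$b_idx != 0) && is.null(h)) {
    abort_bisffm("`height_cm` is required for this equation.",
                 class = "bisffm_error_input")
  }
  covariate_range_warnings(w, h)
  ffm <- eq$b0 + eq$b_w * w
  if (eq$b_l != 0) ffm <- ffm + eq$b_l * h
  if (eq$b_idx != 0) {
    r50 <- data[["r50_ohm"]]
    if (is.null(r50) || any(is.na(r50))) {
      abort_bisffm("`r50_ohm` is required for impedance-based equations.",
                   class = "bisffm_error_input")
    }
    ffm <- ffm + eq$b_idx * impedance_index(h, r50)
  }
  if (eq$b_s != 0) ffm <- ffm + eq$b_s * sex_indicator(data[["sex"]])
  if (eq$b_e != 0) {
    e <- data[["ethnicity_asian"]]
    if (is.null(e)) {
      abort_bisffm("`ethnicity_asian` is required for this equation.",
                   class = "bisffm_error_input")
    }
    check_binary(e, "ethnicity_asian")
    ffm <- ffm + eq$b_e * e
  }
  if (eq$scale_g) ffm <- ffm / 1000
  dplyr::mutate(data, ffm_pred_kg = ffm, equation = equation)
}

#' Adjusted weight
#'
#' Scale weight mapped onto the reference (DXA-consistent) weight scale by the
#' printed simple-regression adjustment `0.41 + 0.99 * weight`, used when
#' deriving fat mass from predicted fat-free mass.
#'
#' @param weight_scale_kg Scale weight (kg, `> 0`).
#' @return Adjusted weight (kg), vectorized.
#' @export
adjusted_weight <- function(weight_scale_kg) {
  if (any(weight_scale_kg < 0)) {
    abort_bisffm("`weight_scale_kg` must be >= 0.",
                 class = "bisffm_error_input")
  }
  0.41 + 0.99 * weight_scale_kg
}

#' Fat mass from predicted fat-free mass
#'
#' `FM = weight - FFM`, where the weight is either the adjusted scale weight
#' (the convention used for the cohort's own equations and Ejlerskov) or the
#' raw scale weight (the Rush convention). Negative fat mass is returned but
#' flagged with a warning.
#'
#' @param weight_scale_kg Scale weight (kg).
#' @param ffm_pred_kg Predicted fat-free mass (kg, `>= 0`).
#' @param weight_convention `"adjusted"` (default) or `"scale"`.
#' @return Fat mass (kg), vectorized.
#' @export
fat_mass <- function(weight_scale_kg, ffm_pred_kg,
                     weight_convention = c("adjusted", "scale")) {
  weight_convention <- match.arg(weight_convention)
  if (any(ffm_pred_kg < 0)) {
    abort_bisffm("`ffm_pred_kg` must be >= 0.", class = "bisffm_error_input")
  }
  w <- switch(weight_convention,
              adjusted = adjusted_weight(weight_scale_kg),
              scale = weight_scale_kg)
  fm <- w - ffm_pred_kg
  if (any(fm < 0)) {
    warn("Predicted FFM exceeds body weight for some children; negative fat mass returned.",
         class = "bisffm_warning_negative_fm")
  }
  fm
}

#' Predict fat-free and fat mass together
#'
#' Convenience wrapper chaining [predict_ffm()] and [fat_mass()] with the
#' equation's own weight convention.
#'
#' @inheritParams predict_ffm
#' @return `data` with `ffm_pred_kg`, `fm_pred_kg` and `equation` appended.
#' @export
predict_composition <- function(data, equation = "nipper_final") {
  eq <- ffm_equations()
  out <- predict_ffm(data, equation)
  conv <- eq$fm_weight[eq$equation == equation]
  dplyr::mutate(out, fm_pred_kg = fat_mass(.data$weight_scale_kg,
                                           .data$ffm_pred_kg,
                                           weight_convention = conv))
}
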