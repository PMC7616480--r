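#' Add derived model terms to a cohort table
#'
#' Computes the columns the prediction models are built from: `impedance_idx`
#' (height^2 / r50, when `r50_ohm` is present) and the numeric `sex_male`
#' indicator.
#'
#' @param data A cohort data frame with `height_cm`, `sex` and optionally
#'   `r50_ohm`.
#' @return `data` with `sex_male` (and `impedance_idx`) appended.
#' @export
add_model_terms <- function(data) {
  data <- as_tibble(data)
  data$sex_male <- sex_indicator(data$sex)
  if (!is.null(data[["r50_ohm"]])) {
    data$impedance_idx <- impedance_index(data$height_cm, data$r50_ohm)
  }
  data
}

#' Stratified derivation/validation split
#'
#' Randomly assigns children to a derivation (~70%) and validation (~30%)
#' cohort, stratifying by sex so both splits keep the cohort's sex mix. Within
#' each stratum the derivation count is `round(fraction * stratum size)`. The
#' split is deterministic given `seed`.
#'
#' @param data Cohort data frame with a `sex` column.
#' @param derivation_fraction Fraction assigned to the derivation cohort.
#' @param seed Integer seed (required; the split is part of the analysis
#'   record).
#' @return `data` with a `cohort` column (`"derivation"`/`"validation"`).
#' @export
split_cohort <- function(data, derivation_fraction = 0.7, seed) {
  data <- as_tibble(data)
  if (missing(seed)) {
    abort_bisffm("`seed` is required for a reproducible split.",
                 class = "bisffm_error_input")
  }
  if (derivation_fraction <= 0 || derivation_fraction > 1) {
    abort_bisffm("`derivation_fraction` must be in (0, 1].",
                 class = "bisffm_error_input")
  }
  s <- sex_indicator(data$sex)
  if (length(unique(s)) < 2) {
    abort_bisffm("Both sexes must be present to stratify the split.",
                 class = "bisffm_error_input")
  }
  if (derivation_fraction == 1) {
    warn("derivation_fraction = 1: the validation cohort is empty.",
         class = "bisffm_warning_split")
  }
  cohort <- character(nrow(data))
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    for (lev in sort(unique(s))) {
      idx <- which(s == lev)
      n_der <- round(derivation_fraction * length(idx))
      der <- sample(idx, n_der)
      cohort[der] <- "derivation"
      cohort[setdiff(idx, der)] <- "validation"
    }
  })
  dplyr::mutate(data, cohort = cohort)
}

#' Fit a fat-free mass regression model
#'
#' Ordinary least squares of a response (reference DXA fat-free mass, kg) on
#' a set of covariate columns, reporting the quantities used to compare the
#' candidate models: adjusted R^2, the residual standard error (`rmse_kg`,
#' denominator n - p - 1) and standardized coefficients
#' (\eqn{b_j\,SD(x_j)/SD(y)}).
#'
#' @param data A data frame containing `response` and every term column
#'   (see [add_model_terms()]).
#' @param terms Character vector of covariate column names.
#' @param response Response column name; default `"ffm_dxa_kg"`.
#' @return An object of class `ffm_model` with [tidy()]/[glance()] methods.
#' @export
fit_ffm_model <- function(data, terms, response = "ffm_dxa_kg") {
  data <- as_tibble(data)
  missing_cols <- setdiff(c(response, terms), names(data))
  if (length(missing_cols) > 0) {
    abort_bisffm(paste0("Missing column(s): ",
                        paste(missing_cols, collapse = ", "), "."),
                 class = "bisffm_error_input")
  }
  n <- nrow(data)
  if (n <= length(terms) + 1) {
    abort_bisffm("Need more observations than terms + 1.",
                 class = "bisffm_error_input")
  }
  sds <- vapply(data[terms], stats::sd, numeric(1))
  if (any(sds == 0)) {
    abort_bisffm(paste0("Zero-variance term(s): ",
                        paste(terms[sds == 0], collapse = ", "), "."),
                 class = "bisffm_error_input")
  }
  fml <- stats::reformulate(terms, response = response)
  fit <- stats::lm(fml, data = data)
  if (any(is.na(stats::coef(fit)))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    abort_bisffm(paste0("Rank-deficient design; collinear term(s): ",
                        paste(dropped, collapse = ", "), "."),
                 class = "bisffm_error_collinear")
  }
  sy <- stats::sd(data[[response]])
  coefs <- stats::coef(fit)[terms]
  structure(
    list(
      fit = fit,
      response = response,
      term_names = terms,
      intercept = unname(stats::coef(fit)[1]),
      coefficients = coefs,
      standardized_coefficients = coefs * sds / sy,
      adjusted_r2 = summary(fit)$adj.r.squared,
      rmse_kg = summary(fit)$sigma,
      n_fit = n
    ),
    class = "ffm_model"
  )
}

#' @export
print.ffm_model <- function(x, ...) {
  cat("FFM regression model:", deparse(stats::formula(x$fit)), "\n")
  cat(sprintf("  n = %d, adjusted R^2 = %.3f, RMSE = %.3f kg\n",
              x$n_fit, x$adjusted_r2, x$rmse_kg))
  print(round(stats::coef(x$fit), 4))
  invisible(x)
}

#' Tidy an `ffm_model`
#'
#' @param x An [fit_ffm_model()] object.
#' @param ... Unused.
#' @return One row per model term (intercept included): estimate, standard
#'   error, t statistic, p value, standardized coefficient.
#' @method tidy ffm_model
#' @export
tidy.ffm_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  std <- c(NA_real_, x$standardized_coefficients)
  tibble(
    term = rownames(sm),
    estimate = sm[, 1],
    std_error = sm[, 2],
    statistic = sm[, 3],
    p_value = sm[, 4],
    std_coef = unname(std)
  )
}

#' Model-level summary of an `ffm_model`
#'
#' @param x An [fit_ffm_model()] object.
#' @param ... Unused.
#' @return A one-row tibble: `adj_r2`, `rmse_kg`, `r2`, `n`, `df_residual`,
#'   `aic`.
#' @method glance ffm_model
#' @export
glance.ffm_model <- function(x, ...) {
  tibble(
    adj_r2 = x$adjusted_r2,
    rmse_kg = x$rmse_kg,
    r2 = summary(x$fit)$r.squared,
    n = x$n_fit,
    df_residual = x$fit$df.residual,
    aic = stats::AIC(x$fit)
  )
}

#' Predict from an `ffm_model`
#'
#' @param object An [fit_ffm_model()] object.
#' @param newdata Data frame with the model's term columns.
#' @param ... Unused.
#' @return Numeric vector of predicted FFM (kg).
#' @export
predict.ffm_model <- function(object, newdata, ...) {
  unname(stats::predict(object$fit, newdata = as_tibble(newdata)))
}

#' Bidirectional stepwise model selection
#'
#' Starting from the base model, adds or drops one candidate term per step to
#' minimize AIC until no move improves it (the conventional reading of
#' "bi-directional stepwise" selection). Deterministic given the data.
#'
#' @param data Data frame containing response, base and candidate columns.
#' @param base_terms Terms always kept in the model.
#' @param candidate_terms Terms the search may add or drop.
#' @param response Response column name.
#' @return The selected model as an `ffm_model`.
#' @export
stepwise_ffm <- function(data, base_terms, candidate_terms,
                         response = "ffm_dxa_kg") {
  data <- as_tibble(data)
  missing_cols <- setdiff(c(response, base_terms, candidate_terms), names(data))
  if (length(missing_cols) > 0) {
    abort_bisffm(paste0("Missing column(s): ",
                        paste(missing_cols, collapse = ", "), "."),
                 class = "bisffm_error_input")
  }
  lower <- if (length(base_terms) > 0) {
    stats::reformulate(base_terms, response = response)
  } else {
    stats::reformulate("1", response = response)
  }
  upper <- stats::reformulate(c(base_terms, candidate_terms),
                              response = response)
  start <- stats::lm(lower, data = data)
  sel <- stats::step(start, scope = list(lower = lower, upper = upper),
                     direction = "both", trace = 0)
  kept <- attr(stats::terms(sel), "term.labels")
  if (length(kept) == 0) {
    # intercept-only outcome: report it through the same interface
    return(structure(
      list(fit = sel, response = response, term_names = character(0),
           intercept = unname(stats::coef(sel)[1]),
           coefficients = numeric(0),
           standardized_coefficients = numeric(0),
           adjusted_r2 = summary(sel)$adj.r.squared,
           rmse_kg = summary(sel)$sigma, n_fit = nrow(data)),
      class = "ffm_model"
    ))
  }
  fit_ffm_model(data, kept, response = response)
}

#' Develop the scale-to-reference weight adjustment
#'
#' Simple linear regression of the reference (DXA) weight on scale weight,
#' the adjustment used before deriving fat mass.
#'
#' @param weight_scale_kg,weight_dxa_kg Paired weights (kg), `n >= 3`.
#' @return A one-row tibble: `intercept`, `slope`, `n`.
#' @export
develop_weight_adjustment <- function(weight_scale_kg, weight_dxa_kg) {
  if (length(weight_scale_kg) < 3 ||
      length(weight_scale_kg) != length(weight_dxa_kg)) {
    abort_bisffm("Need paired weights with n >= 3.",
                 class = "bisffm_error_input")
  }
  if (stats::sd(weight_scale_kg) == 0) {
    abort_bisffm("Scale weight has zero variance.",
                 class = "bisffm_error_input")
  }
  fit <- stats::lm(weight_dxa_kg ~ weight_scale_kg)
  tibble(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    n = length(weight_scale_kg)
  )
}

ladder_term_sets <- function() {
  list(
    w = "weight_scale_kg",
    w_l = c("weight_scale_kg", "height_cm"),
    w_l_s = c("weight_scale_kg", "height_cm", "sex_male"),
    w_idx = c("weight_scale_kg", "impedance_idx"),
    w_idx_s = c("weight_scale_kg", "impedance_idx", "sex_male"),
    nipper_anthro = c("weight_scale_kg", "height_cm", "sex_male",
                      "ethnicity_asian"),
    nipper_final = c("weight_scale_kg", "impedance_idx", "sex_male",
                     "ethnicity_asian")
  )
}

#' Fit the model ladder on a derivation cohort
#'
#' Refits the seven candidate models (weight alone up to the final
#' weight + impedance-index + sex + ethnicity model) and tabulates adjusted
#' R^2, RMSE and coefficients, mirroring the published model-comparison
#' layout.
#'
#' @param data Derivation cohort with the columns produced by
#'   [add_model_terms()] plus the response.
#' @param response Response column; default `"ffm_dxa_kg"`.
#' @return A tibble with one row per model and a `model` list-column of the
#'   fitted `ffm_model` objects.
#' @export
model_ladder <- function(data, response = "ffm_dxa_kg") {
  data <- add_model_terms(data)
  sets <- ladder_term_sets()
  purrr::imap(sets, function(terms, id) {
    m <- fit_ffm_model(data, terms, response = response)
    dplyr::bind_cols(
      tibble(equation = id, terms = paste(terms, collapse = " + ")),
      glance(m)[, c("adj_r2", "rmse_kg", "n")],
      tibble(model = list(m))
    )
  }) |>
    dplyr::bind_rows()
}
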