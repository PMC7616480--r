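#' Run the full analysis pipeline on a synthetic cohort
#'
#' End-to-end reproduction of the study flow: simulate a cohort, (optionally)
#' refit the Cole model to the simulated spectra, split into derivation and
#' validation cohorts stratified by sex, fit the model ladder on the
#' derivation cohort, validate the two final equations on the validation
#' cohort (FFM and derived FM, with TOST bounds of 0.25 and 0.10 kg), and
#' validate the published equations and every mixture-theory scheme on the
#' whole cohort.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param config A [synth_config()].
#' @param derivation_fraction Derivation share of the stratified split.
#' @param equations Published equations to validate on the whole cohort.
#' @param mixture_schemes Mixture methods to validate (see
#'   [mixture_methods()]).
#' @param tost_bound_ffm,tost_bound_fm Equivalence bounds (kg).
#' @param refit_cole If `TRUE`, generate spectra and obtain r50/r0/rinf by
#'   Cole-fitting the replicates instead of using the generator's values
#'   (slower; exercises the full measurement chain).
#' @param out_dir Optional directory: writes `model_ladder.csv`, `models.json`,
#'   `validation_ffm.json` and `method_comparison.csv`.
#' @return A list of class `bis_run`: the cohort, the split assignment, the
#'   ladder tibble, the validation agreement reports, and the `comparison`
#'   tibble (one row per method, in the layout of a method-comparison table).
#' @export
run_pipeline <- function(seed,
                         config = synth_config(),
                         derivation_fraction = 0.7,
                         equations = c("ejlerskov", "rush"),
                         mixture_schemes = mixture_methods()$method,
                         tost_bound_ffm = 0.25,
                         tost_bound_fm = 0.10,
                         refit_cole = FALSE,
                         out_dir = NULL) {
  bad_eq <- setdiff(equations, ffm_equations()$equation)
  if (length(bad_eq) > 0) {
    abort_bisffm(paste0("Unknown equation id(s): ",
                        paste(bad_eq, collapse = ", "), "."),
                 class = "bisffm_error_config")
  }
  bad_mix <- setdiff(mixture_schemes, mixture_methods()$method)
  if (length(bad_mix) > 0) {
    abort_bisffm(paste0("Unknown mixture scheme(s): ",
                        paste(bad_mix, collapse = ", "), "."),
                 class = "bisffm_error_config")
  }
  if (tost_bound_ffm <= 0 || tost_bound_fm <= 0) {
    abort_bisffm("TOST bounds must be > 0.", class = "bisffm_error_config")
  }

  cohort <- generate_cohort(config, seed = seed, spectra = refit_cole)
  data <- dplyr::left_join(cohort$records, cohort$references, by = "child_id")
  if (refit_cole) {
    fits <- fit_cole_replicates(cohort$spectra)
    data <- data |>
      dplyr::select(-"r50_ohm", -"r0_ohm", -"rinf_ohm") |>
      dplyr::left_join(
        dplyr::select(fits, "child_id", r50_ohm = "r50_ohm",
                      r0_ohm = "r0", rinf_ohm = "rinf"),
        by = "child_id"
      )
  }
  data <- add_model_terms(data)
  data <- split_cohort(data, derivation_fraction, seed = seed)
  deriv <- dplyr::filter(data, .data$cohort == "derivation")
  valid <- dplyr::filter(data, .data$cohort == "validation")

  ladder <- model_ladder(deriv)

  final_terms <- ladder_term_sets()[["nipper_final"]]
  anthro_terms <- ladder_term_sets()[["nipper_anthro"]]
  fit_final <- fit_ffm_model(deriv, final_terms)
  fit_anthro <- fit_ffm_model(deriv, anthro_terms)

  validate_fit <- function(fit, label) {
    v <- dplyr::mutate(valid,
                       ffm_pred_kg = predict(fit, valid),
                       fm_pred_kg = fat_mass(.data$weight_scale_kg,
                                             pmax(.data$ffm_pred_kg, 0)))
    list(
      ffm = agreement(v, "ffm_pred_kg", "ffm_dxa_kg",
                      tost_bound = tost_bound_ffm,
                      method_label = paste0(label, " (FFM)")),
      fm = agreement(v, "fm_pred_kg", "fm_dxa_kg",
                     tost_bound = tost_bound_fm,
                     method_label = paste0(label, " (FM)"))
    )
  }
  validation <- list(
    impedance = validate_fit(fit_final, "impedance equation"),
    anthropometry = validate_fit(fit_anthro, "anthropometry equation")
  )

  published <- purrr::map(equations, function(eq_id) {
    pred <- predict_composition(data, eq_id)
    agreement(pred, "ffm_pred_kg", "ffm_dxa_kg",
              tost_bound = tost_bound_ffm, method_label = eq_id)
  })

  mixture <- purrr::map(mixture_schemes, function(m) {
    bc <- predict_mixture(data, method = m)
    joined <- dplyr::left_join(bc, cohort$references, by = "child_id")
    agreement(joined, "ffm_kg", "ffm_dxa_kg",
              tost_bound = tost_bound_ffm, method_label = m)
  })

  strip_report <- function(a) {
    attr(a, "pairs") <- NULL
    class(a) <- c("tbl_df", "tbl", "data.frame")
    a
  }
  comparison <- c(
    unlist(purrr::map(validation, ~ list(.x$ffm, .x$fm)), recursive = FALSE),
    published, mixture
  ) |>
    purrr::map(strip_report) |>
    dplyr::bind_rows()

  run <- structure(
    list(cohort = cohort, data = data, ladder = ladder,
         models = list(impedance = fit_final, anthropometry = fit_anthro),
         validation = validation, comparison = comparison,
         seed = seed, config_hash = rlang::hash(config)),
    class = "bis_run"
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(dplyr::select(ladder, -"model"),
                     file.path(out_dir, "model_ladder.csv"))
    jsonlite::write_json(
      list(seed = seed, config_hash = run$config_hash,
           impedance = c(list(intercept = fit_final$intercept),
                         as.list(fit_final$coefficients),
                         list(adj_r2 = fit_final$adjusted_r2,
                              rmse_kg = fit_final$rmse_kg)),
           anthropometry = c(list(intercept = fit_anthro$intercept),
                             as.list(fit_anthro$coefficients),
                             list(adj_r2 = fit_anthro$adjusted_r2,
                                  rmse_kg = fit_anthro$rmse_kg))),
      file.path(out_dir, "models.json"), auto_unbox = TRUE, digits = NA
    )
    jsonlite::write_json(
      lapply(validation, function(v) {
        lapply(v, function(a) as.list(dplyr::select(
          as_tibble(a), -dplyr::any_of("method"))))
      }),
      file.path(out_dir, "validation_ffm.json"), auto_unbox = TRUE, digits = NA
    )
    readr::write_csv(comparison, file.path(out_dir, "method_comparison.csv"))
  }
  run
}

#' @export
print.bis_run <- function(x, ...) {
  cat(sprintf("BIS analysis run (seed %s, config %s)\n",
              format(x$seed), x$config_hash))
  cat(sprintf("  cohort: %d children; derivation %d / validation %d\n",
              nrow(x$data), sum(x$data$cohort == "derivation"),
              sum(x$data$cohort == "validation")))
  g <- glance(x$models$impedance)
  cat(sprintf("  final impedance model: adj R^2 %.3f, RMSE %.3f kg\n",
              g$adj_r2, g$rmse_kg))
  cat(sprintf("  methods compared: %d\n", nrow(x$comparison)))
  invisible(x)
}
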