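#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

abort_bisffm <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "bisffm_error"), ...)
}

# checks a numeric vector is finite and strictly positive
check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort_bisffm(
      sprintf("`%s` must be finite and > 0.", name),
      class = "bisffm_error_input"
    )
  }
  invisible(x)
}

check_binary <- function(x, name) {
  if (!all(x %in% c(0, 1))) {
    abort_bisffm(
      sprintf("`%s` must be coded 0/1.", name),
      class = "bisffm_error_input"
    )
  }
  invisible(x)
}

# sex can arrive as "M"/"F" or as the 0/1 male indicator used in the equations
sex_indicator <- function(sex) {
  if (is.numeric(sex)) {
    check_binary(sex, "sex")
    return(as.numeric(sex))
  }
  s <- toupper(as.character(sex))
  if (!all(s %in% c("M", "F"))) {
    abort_bisffm('`sex` must be "M"/"F" or a 0/1 male indicator.',
                 class = "bisffm_error_input")
  }
  as.numeric(s == "M")
}

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
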