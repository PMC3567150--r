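#' Extract estimated breeding values from a fit
#'
#' Returns the BLUP solutions for the additive genetic effects at the
#' converged variance components, with prediction-error variances and
#' reliabilities `1 - PEV / ((1 + F_i) V_POLY)`.
#'
#' @param fit A `grey_fit`.
#' @param animals Optional subset of animal ids; default all pedigree
#'   animals (`recorded_only = TRUE` restricts to animals with records).
#' @param recorded_only Keep only animals with their own records.
#' @return A tibble `trait, animal, ebv, pev, reliability, n_records`.
#' @export
predict_ebv <- function(fit, animals = NULL, recorded_only = FALSE) {
  stopifnot(inherits(fit, "grey_fit"))
  out <- fit$ebv
  if (recorded_only) out <- out[out$n_records > 0, ]
  if (!is.null(animals)) out <- out[out$animal %in% animals, ]
  out
}

#' Standardize breeding values
#'
#' Centres and scales a numeric vector to mean zero and standard deviation
#' one, as used for plotting breeding values of different traits on a
#' common scale. A constant vector has no scale and raises an error.
#'
#' @param x Numeric vector.
#' @return The standardized vector.
#' @export
standardize_ebv <- function(x) {
  x <- as.numeric(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("cannot standardize a constant vector (zero standard deviation)",
          class = "greyherit_error_standardize")
  }
  (x - mean(x)) / s
}
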