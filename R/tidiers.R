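# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibrated fate model
#'
#' Returns the audit table of the calibration: one row per dose with the
#' measured inhibition, the clamped target viable ratio, the raw calibrated
#' `p` and the monotone (isotonic-adjusted) `p` actually used, alongside the
#' model's `lambda` and exposure `k`.
#'
#' @param x A `fate_model`.
#' @param ... Unused.
#' @return A tibble with one row per calibrated dose.
#' @export
tidy.fate_model <- function(x, ...) {
  dplyr::mutate(x$table,
    drug = x$drug, lambda = x$lambda, k = x$k,
    .before = 1L
  )
}

#' One-row summary of a fate model
#'
#' @param x A `fate_model`.
#' @param ... Unused.
#' @return A one-row tibble with the drug label, mechanism parameters and
#'   the calibrated probability range.
#' @export
glance.fate_model <- function(x, ...) {
  tibble::tibble(
    drug = x$drug,
    lambda = x$lambda,
    k = x$k,
    sustained_death = x$sustained_death,
    n_doses = nrow(x$table),
    p_min = min(x$table$p),
    p_max = max(x$table$p),
    isotonic_adjusted = any(x$table$p != x$table$p_raw)
  )
}

#' Tidy a combination-grid experiment
#'
#' @param x A `combo_experiment`.
#' @param ... Unused.
#' @return The per-pair inhibition-ratio time series (dose_a, dose_b, day,
#'   ratio, sd).
#' @export
tidy.combo_experiment <- function(x, ...) x$series

#' Per-pair summary of a combination-grid experiment
#'
#' @param x A `combo_experiment`.
#' @param ... Unused.
#' @return One row per dose pair with the trajectory nadir, relapse
#'   classification and final inhibition.
#' @export
glance.combo_experiment <- function(x, ...) x$summary
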