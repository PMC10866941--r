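# Synthetic data generators: Hill-shaped dose-response curves and reference
# growth trajectories, standing in for unreleased assay data so the whole
# pipeline is exercisable offline. Both are pure functions of their
# parameters and the RNG state.

#' Generate a synthetic Hill-shaped dose-response curve
#'
#' `inhibition(c) = 100 * c^s / (ic50^s + c^s) + Normal(0, noise_sd)`.
#' Values may leave \[0, 100\]; downstream calibration clamps, the metrics do
#' not.
#'
#' @param doses_uM Positive dose vector (micromolar).
#' @param ic50_uM True half-inhibition concentration.
#' @param hill_slope Hill coefficient `s`.
#' @param noise_sd SD of additive Gaussian noise on the percent scale.
#' @return A tibble with columns `concentration_uM`, `inhibition_percent`.
#' @export
#' @examples
#' generate_dose_response(10^seq(-2, 1), ic50_uM = 0.5)
generate_dose_response <- function(doses_uM, ic50_uM, hill_slope = 1,
                                   noise_sd = 0) {
  if (ic50_uM <= 0) abort("`ic50_uM` must be > 0.")
  if (any(doses_uM <= 0)) abort("doses must be > 0.")
  inhib <- 100 * doses_uM^hill_slope /
    (ic50_uM^hill_slope + doses_uM^hill_slope)
  if (noise_sd > 0) inhib <- inhib + rnorm(length(doses_uM), 0, noise_sd)
  tibble::tibble(
    concentration_uM = doses_uM,
    inhibition_percent = inhib
  )
}

#' Generate a synthetic reference growth record
#'
#' Parametric spheroid-area trajectories at the experimental cadence (one
#' observation every two days over three weeks by default), with
#' multiplicative lognormal replicate noise:
#' `untreated_exponential` (area doubles every `area_doubling_days`),
#' `arrested` (plateau at the initial area), `regressing` (exponential decay
#' at `decay_rate` per day) and `relapse` (decay until `relapse_day`, then
#' regrowth at `regrow_rate` per day).
#'
#' @param scenario One of `"untreated_exponential"`, `"arrested"`,
#'   `"regressing"`, `"relapse"`.
#' @param days Observation days.
#' @param n_replicates Replicates to draw.
#' @param area0_um2 Initial spheroid area (um^2; default a 180 um radius
#'   disc).
#' @param area_doubling_days Area doubling time of the untreated scenario.
#' @param decay_rate,regrow_rate Exponential rates per day.
#' @param relapse_day Day the relapse scenario turns from decay to regrowth.
#' @param noise_sdlog SD of the lognormal replicate noise.
#' @param condition Condition label (defaults to the scenario name).
#' @return A tibble with columns `condition`, `replicate`, `day`, `area_um2`.
#' @export
#' @examples
#' generate_reference_growth("regressing", n_replicates = 2, noise_sdlog = 0)
generate_reference_growth <- function(scenario = c(
                                        "untreated_exponential", "arrested",
                                        "regressing", "relapse"
                                      ),
                                      days = seq(0, 20, by = 2),
                                      n_replicates = 6,
                                      area0_um2 = pi * 180^2,
                                      area_doubling_days = 4,
                                      decay_rate = 0.2,
                                      regrow_rate = 0.3,
                                      relapse_day = 8,
                                      noise_sdlog = 0.05,
                                      condition = NULL) {
  scenario <- match.arg(scenario)
  mean_area <- switch(scenario,
    untreated_exponential = area0_um2 * 2^(days / area_doubling_days),
    arrested = rep(area0_um2, length(days)),
    regressing = area0_um2 * exp(-decay_rate * days),
    relapse = {
      nadir <- area0_um2 * exp(-decay_rate * relapse_day)
      ifelse(days <= relapse_day,
        area0_um2 * exp(-decay_rate * days),
        nadir * exp(regrow_rate * (days - relapse_day))
      )
    }
  )
  condition <- condition %||% scenario
  tidyr::expand_grid(replicate = seq_len(n_replicates), day = days) |>
    dplyr::mutate(
      condition = condition,
      area_um2 = mean_area[match(.data$day, days)] *
        exp(rnorm(dplyr::n(), 0, noise_sdlog)),
      .before = 1L
    ) |>
    dplyr::select("condition", "replicate", "day", "area_um2")
}
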