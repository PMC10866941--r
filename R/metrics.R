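# Evaluation formulas: % growth inhibition, IC50, RMSE between
# treated/untreated area-ratio time series, replicate aggregation.

#' Percent growth inhibition
#'
#' `((positive_control - test_value) * 100) / positive_control`. Negative
#' values (growth stimulation) are passed through; clamping is the caller's
#' choice (the fate-model calibration clamps, the metrics do not).
#'
#' @param positive_control Untreated reference value(s), must be positive.
#' @param test_value Treated value(s).
#' @return Numeric vector of inhibition percentages.
#' @export
#' @examples
#' growth_inhibition(2, 0.5) # 75
growth_inhibition <- function(positive_control, test_value) {
  if (any(!is.finite(positive_control)) || any(positive_control <= 0)) {
    abort("`positive_control` must be positive.")
  }
  (positive_control - test_value) * 100 / positive_control
}

#' Half-maximal inhibitory concentration
#'
#' The drug concentration at which half the population is inhibited, located
#' by linear interpolation of inhibition against log10 concentration at the
#' first upward crossing of 50%.
#'
#' @param dose_response Data frame with columns `concentration_uM`
#'   (positive, increasing) and `inhibition_percent`.
#' @return IC50 in micromolar.
#' @export
#' @examples
#' ic50(data.frame(concentration_uM = c(1, 10), inhibition_percent = c(0, 100)))
ic50 <- function(dose_response) {
  dose_response <- as.data.frame(dose_response)
  conc <- dose_response$concentration_uM
  inhib <- dose_response$inhibition_percent
  if (is.null(conc) || is.null(inhib)) {
    abort("`dose_response` needs columns concentration_uM and inhibition_percent.")
  }
  if (any(conc <= 0)) abort("concentrations must be positive.")
  for (i in seq_along(conc)) {
    if (inhib[i] == 50) {
      return(conc[i])
    }
    if (i > 1L && inhib[i - 1] < 50 && inhib[i] > 50) {
      lx <- log10(conc)
      x50 <- lx[i - 1] + (50 - inhib[i - 1]) *
        (lx[i] - lx[i - 1]) / (inhib[i] - inhib[i - 1])
      return(10^x50)
    }
  }
  abort("IC50 not bracketed: no upward crossing of 50% inhibition in the table.")
}

#' RMSE between two treated/untreated area-ratio time series
#'
#' `sqrt( sum_t (ratio_a(t) - ratio_b(t))^2 / N_t )` over the shared
#' timepoints of two inhibition-ratio series (e.g. an in vitro reference and
#' a simulated record).
#'
#' @param reference,simulated Data frames with columns `day` and `ratio`.
#' @return The RMSE (dimensionless, on the ratio scale).
#' @export
#' @examples
#' a <- tibble::tibble(day = c(2, 4), ratio = c(0.8, 0.6))
#' b <- tibble::tibble(day = c(2, 4), ratio = c(0.6, 0.8))
#' rmse_inhibition(a, b) # 0.2
rmse_inhibition <- function(reference, simulated) {
  for (x in list(reference, simulated)) {
    if (!all(c("day", "ratio") %in% names(x))) {
      abort("inhibition series need columns `day` and `ratio`.")
    }
  }
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(reference), "day", ref = "ratio"),
    dplyr::select(tibble::as_tibble(simulated), "day", sim = "ratio"),
    by = "day"
  )
  if (nrow(joined) == 0L) abort("the two series share no timepoints.")
  sqrt(sum((joined$ref - joined$sim)^2) / nrow(joined))
}

#' Treated/untreated area-ratio series with replicate aggregation
#'
#' Per timepoint the ratio is the mean treated area divided by the mean
#' control area; its SD is propagated to first order from the replicate SDs,
#' `ratio * sqrt((sd_t/mean_t)^2 + (sd_c/mean_c)^2)`.
#'
#' @param treated,control `growth_record`-style data frames with columns
#'   `replicate`, `day` and `area_um2` (or `area`).
#' @return A tibble with columns `day`, `ratio`, `sd`, `n_treated`,
#'   `n_control`.
#' @export
assemble_inhibition_series <- function(treated, control) {
  pick_area <- function(x) {
    x <- tibble::as_tibble(x)
    if (!"area_um2" %in% names(x) && "area" %in% names(x)) {
      x <- dplyr::rename(x, area_um2 = "area")
    }
    if (!all(c("replicate", "day", "area_um2") %in% names(x))) {
      abort("records need columns `replicate`, `day` and `area_um2` (or `area`).")
    }
    dplyr::summarise(
      dplyr::group_by(x, .data$day),
      mean = mean(.data$area_um2), sd = sd(.data$area_um2),
      n = dplyr::n(), .groups = "drop"
    )
  }
  tr <- pick_area(treated)
  ct <- pick_area(control)
  if (nrow(tr) == 0L || nrow(ct) == 0L) abort("need at least one replicate each.")
  joined <- dplyr::inner_join(tr, ct, by = "day", suffix = c("_t", "_c"))
  if (nrow(joined) == 0L) abort("treated and control share no timepoints.")
  if (any(joined$mean_c <= 0)) {
    abort("control area is zero at one or more shared timepoints.")
  }
  rel <- function(s, m, n) ifelse(n > 1 & m > 0, (s / m)^2, 0)
  dplyr::transmute(joined,
    day = .data$day,
    ratio = .data$mean_t / .data$mean_c,
    sd = .data$ratio * sqrt(
      rel(.data$sd_t, .data$mean_t, .data$n_t) +
        rel(.data$sd_c, .data$mean_c, .data$n_c)
    ),
    n_treated = .data$n_t,
    n_control = .data$n_c
  )
}

#' Classify relapse in an inhibition-ratio series
#'
#' A treated spheroid is classed as relapsing when, after the minimum of its
#' treated/untreated area-ratio trajectory, the ratio regrows above
#' `threshold` times the nadir and stays there for at least `sustain_days`
#' consecutive observation days.
#'
#' @param series Data frame with columns `day` and `ratio`.
#' @param threshold Regrowth factor over the nadir (default 1.10, i.e.
#'   regrowth to >110% of the nadir).
#' @param sustain_days Minimum time span (days) the regrowth must persist.
#' @return A one-row tibble with `relapsed`, `nadir_day`, `nadir_ratio`,
#'   `relapse_day` (NA when none).
#' @export
classify_relapse <- function(series, threshold = 1.10, sustain_days = 2) {
  if (!all(c("day", "ratio") %in% names(series))) {
    abort("`series` needs columns `day` and `ratio`.")
  }
  series <- dplyr::arrange(tibble::as_tibble(series), .data$day)
  i_min <- which.min(series$ratio)
  nadir <- series$ratio[i_min]
  after <- series[series$day >= series$day[i_min], , drop = FALSE]
  above <- after$ratio > threshold * nadir
  relapse_day <- NA_real_
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      span <- after$day[ends[j]] - after$day[starts[j]]
      sustained <- span >= sustain_days ||
        (ends[j] == nrow(after) && after$day[nrow(after)] - after$day[starts[j]] >= 0 &&
           r$lengths[j] >= 2L)
      if (sustained) {
        relapse_day <- after$day[starts[j]]
        break
      }
    }
  }
  tibble::tibble(
    relapsed = !is.na(relapse_day),
    nadir_day = series$day[i_min],
    nadir_ratio = nadir,
    relapse_day = relapse_day
  )
}
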