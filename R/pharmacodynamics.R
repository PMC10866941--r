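#' Treated-to-untreated viable population ratio after k cycles
#'
#' Closed form of the branching process implied by the per-cycle fate rules:
#' at each mitosis a cycling cell divides unaffected with probability `p`
#' (two cycling daughters), enters irreversible G0 arrest with probability
#' `lambda * (1 - p)` (one permanently viable, non-cycling cell) or dies with
#' probability `(1 - lambda) * (1 - p)`. The untreated control doubles every
#' cycle, so after `k` cycles the expected cycling population per founder is
#' `(2p)^k`, the accumulated G0 population is
#' `lambda (1-p) ((2p)^k - 1) / (2p - 1)` (or `k lambda (1-p)` when 2p = 1),
#' and the viable ratio is their sum divided by `2^k`. Fractional `k` (e.g.
#' a 72 h assay at a 22 h doubling time, k = 72/22) uses the real-power
#' extension of the same expressions.
#'
#' @param p Per-cycle probability of remaining unaffected, in \[0, 1\].
#' @param lambda Cytostatic fraction: probability that an affected cell
#'   arrests (G0) rather than dies, in \[0, 1\].
#' @param k Number of cell cycles of drug exposure (>= 0, fractional allowed).
#'
#' @return Numeric vector of viable ratios (treated / untreated), recycled
#'   over the inputs.
#' @seealso [calibrate_p()] for the inverse mapping.
#' @export
#' @examples
#' viable_ratio(1, 0.5, 3) # no effect -> 1
#' viable_ratio(0.5^(1 / 3), lambda = 0, k = 3) # pure cytotoxic -> 0.5
viable_ratio <- function(p, lambda, k) {
  n <- max(length(p), length(lambda), length(k))
  p <- rep_len(p, n)
  lambda <- rep_len(lambda, n)
  k <- rep_len(k, n)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("`p` must lie in [0, 1].")
  }
  if (any(!is.finite(lambda)) || any(lambda < 0 | lambda > 1)) {
    abort("`lambda` must lie in [0, 1].")
  }
  if (any(!is.finite(k)) || any(k < 0)) abort("`k` must be >= 0.")
  m <- 2 * p
  pk <- m^k
  gk <- ifelse(
    abs(m - 1) < 1e-12,
    k * lambda * (1 - p),
    lambda * (1 - p) * (pk - 1) / (m - 1)
  )
  (pk + gk) / 2^k
}

#' Calibrate the unaffected probability from a target viable ratio
#'
#' Inverts [viable_ratio()] in `p` by bisection. The ratio is strictly
#' increasing in `p` for fixed `(lambda, k)`, so the solution is unique. The
#' attainable range is `[viable_ratio(0, lambda, k), 1]`; a fully arrested
#' population (`lambda = 1`) leaves a floor of `1 / 2^k` viable G0 cells per
#' founder, so smaller targets are not reachable and raise an error.
#'
#' @inheritParams viable_ratio
#' @param target_ratio Treated/untreated viable ratio to match, in (0, 1].
#' @param tol Bisection tolerance on the ratio scale.
#'
#' @return Numeric vector of probabilities `p`.
#' @export
#' @examples
#' calibrate_p(0.5, lambda = 0, k = 3) # = 0.5^(1/3)
calibrate_p <- function(target_ratio, lambda, k, tol = 1e-9) {
  n <- max(length(target_ratio), length(lambda), length(k))
  target_ratio <- rep_len(target_ratio, n)
  lambda <- rep_len(lambda, n)
  k <- rep_len(k, n)
  vapply(seq_len(n), function(i) {
    r <- target_ratio[i]
    lam <- lambda[i]
    kk <- k[i]
    if (!is.finite(r) || r <= 0 || r > 1) {
      abort("`target_ratio` must lie in (0, 1].")
    }
    floor_r <- viable_ratio(0, lam, kk)
    if (r < floor_r - 1e-12) {
      abort(sprintf(
        "target ratio %.4g is below the attainable range [%.4g, 1] for lambda = %g, k = %g.",
        r, floor_r, lam, kk
      ))
    }
    if (r >= 1) return(1)
    if (r <= floor_r) return(0)
    lo <- 0
    hi <- 1
    repeat {
      mid <- (lo + hi) / 2
      fr <- viable_ratio(mid, lam, kk)
      if ((abs(fr - r) < tol && (hi - lo) < 1e-9) || (hi - lo) < 1e-13) break
      if (fr < r) lo <- mid else hi <- mid
    }
    mid
  }, numeric(1))
}

#' Convert a dose-response table into a per-cell fate model
#'
#' Maps each measured inhibition value to a target viable ratio
#' `1 - inhibition / 100` (clamped into `(epsilon, 1]`; growth stimulation,
#' i.e. negative inhibition, is clamped to a ratio of 1 with a warning) and
#' calibrates the per-cycle unaffected probability `p` at every dose with
#' [calibrate_p()]. Intermediate doses are resolved by linear interpolation
#' of `p` against log10 concentration with constant extrapolation beyond the
#' measured range; a concentration of exactly zero always maps to `p = 1`.
#' If the raw `p` sequence is not non-increasing in dose it is replaced by
#' its isotonic (pool-adjacent-violators) projection and a warning reports
#' the adjustment.
#'
#' @param dose_response Data frame with columns `concentration_uM` (positive,
#'   strictly increasing) and `inhibition_percent`.
#' @inheritParams viable_ratio
#' @param k Exposure duration in cell cycles; defaults to 72/22 (a 72 h assay
#'   at a 22 h mean doubling time).
#' @param sustained_death Logical flag recording that the drug's death hazard
#'   persists after the extracellular field decays (e.g. doxorubicin retained
#'   intracellularly and re-released). Fate lookups always key on the maximum
#'   concentration a cell has experienced, which implements this persistence;
#'   the flag is carried as metadata on the model.
#' @param drug Drug label.
#' @param epsilon Lower clamp for target ratios, keeping calibration
#'   well-posed at 100% inhibition.
#'
#' @return A `fate_model` object; see [tidy.fate_model()] for its table form
#'   and [fate_probability()] for dose lookups.
#' @export
#' @examples
#' dr <- generate_dose_response(10^seq(-3, 1), ic50_uM = 0.05)
#' fm <- build_fate_model(dr, lambda = 0, drug = "DOX")
#' fate_probability(fm, c(0, 0.05, 5))
build_fate_model <- function(dose_response, lambda, k = 72 / 22,
                             sustained_death = FALSE, drug = "drug",
                             epsilon = 1e-6) {
  dose_response <- as.data.frame(dose_response)
  req <- c("concentration_uM", "inhibition_percent")
  if (!all(req %in% names(dose_response))) {
    abort("`dose_response` needs columns concentration_uM and inhibition_percent.")
  }
  conc <- dose_response$concentration_uM
  inhib <- dose_response$inhibition_percent
  if (length(conc) < 2L) abort("at least two dose points are required.")
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    abort("concentrations must be positive and finite.")
  }
  if (is.unsorted(conc, strictly = TRUE)) {
    abort("concentrations must be strictly increasing.")
  }
  if (any(!is.finite(inhib))) abort("inhibition values must be finite.")
  if (any(inhib > 100)) abort("inhibition cannot exceed 100%.")

  ratio <- 1 - inhib / 100
  n_stim <- sum(ratio > 1)
  if (n_stim > 0) {
    warn(sprintf(
      "%d dose(s) with negative inhibition (growth stimulation) clamped to ratio 1.",
      n_stim
    ))
  }
  ratio <- pmin(pmax(ratio, epsilon), 1)
  p_raw <- calibrate_p(ratio, lambda, k)
  p <- p_raw
  if (is.unsorted(rev(p), strictly = FALSE)) {
    # non-increasing isotonic projection (PAVA on the negated sequence)
    p <- -isoreg(seq_along(p), -p_raw)$yf
    warn(sprintf(
      "non-monotone p sequence adjusted by isotonic projection (max change %.3g).",
      max(abs(p - p_raw))
    ))
  }
  structure(
    list(
      drug = drug,
      lambda = lambda,
      k = k,
      sustained_death = isTRUE(sustained_death),
      table = tibble::tibble(
        concentration_uM = conc,
        inhibition_percent = inhib,
        target_ratio = ratio,
        p_raw = p_raw,
        p = p
      )
    ),
    class = "fate_model"
  )
}

#' Fate model with a dose-independent unaffected probability
#'
#' Convenience constructor used for validation experiments in which the
#' per-cycle probability is imposed directly rather than calibrated from a
#' dose-response curve: every positive concentration maps to the same `p`.
#'
#' @inheritParams build_fate_model
#' @param p Per-cycle probability of remaining unaffected at any positive
#'   dose.
#' @return A `fate_model`.
#' @export
#' @examples
#' fm <- constant_fate_model(0.6, lambda = 0.5)
#' fate_probability(fm, c(0, 1, 100))
constant_fate_model <- function(p, lambda, k = 72 / 22,
                                sustained_death = FALSE, drug = "drug") {
  if (!is.finite(p) || p < 0 || p > 1) abort("`p` must lie in [0, 1].")
  structure(
    list(
      drug = drug, lambda = lambda, k = k,
      sustained_death = isTRUE(sustained_death),
      table = tibble::tibble(
        concentration_uM = c(1e-6, 1e6),
        inhibition_percent = rep(100 * (1 - viable_ratio(p, lambda, k)), 2),
        target_ratio = rep(viable_ratio(p, lambda, k), 2),
        p_raw = c(p, p),
        p = c(p, p)
      )
    ),
    class = "fate_model"
  )
}

#' Look up the unaffected probability at given concentrations
#'
#' @param model A `fate_model`.
#' @param concentration_uM Concentrations in micromolar (>= 0).
#' @return Numeric vector of probabilities; exactly zero concentration maps
#'   to 1 (no exposure).
#' @export
fate_probability <- function(model, concentration_uM) {
  stopifnot(inherits(model, "fate_model"))
  if (any(concentration_uM < 0, na.rm = TRUE)) {
    abort("concentrations must be >= 0.")
  }
  out <- rep(1, length(concentration_uM))
  pos <- which(concentration_uM > 0)
  if (length(pos)) {
    out[pos] <- approx(
      x = log10(model$table$concentration_uM),
      y = model$table$p,
      xout = log10(concentration_uM[pos]),
      method = "linear", rule = 2, ties = "ordered"
    )$y
  }
  out
}

# fast lookup closure used inside the simulation loop (input in molar)
.fate_lookup_fun <- function(model) {
  lx <- log10(model$table$concentration_uM)
  py <- model$table$p
  function(conc_M) {
    if (conc_M <= 0) return(1)
    approx(lx, py, xout = log10(conc_M * 1e6), method = "linear",
           rule = 2, ties = "ordered")$y
  }
}

#' @export
print.fate_model <- function(x, ...) {
  cat(sprintf(
    "<fate_model> %s: lambda = %g, k = %.3f cycles, sustained death %s, %d dose points\n",
    x$drug, x$lambda, x$k, if (x$sustained_death) "on" else "off",
    nrow(x$table)
  ))
  print(x$table, ...)
  invisible(x)
}

#' Sample per-cell fates under monotherapy
#'
#' Draws the mitosis fate decision for `n` cells at the same effective
#' exposure: unaffected (proliferate) with probability `p`, G0 arrest with
#' probability `lambda * (1 - p)`, death with probability
#' `(1 - lambda) * (1 - p)`.
#'
#' @inheritParams viable_ratio
#' @param n Number of independent draws.
#' @return A factor with levels `proliferate`, `g0_arrest`, `die`.
#' @export
#' @examples
#' set.seed(1)
#' table(sample_fates(1000, p = 0.6, lambda = 0.5))
sample_fates <- function(n, p, lambda) {
  if (!is.finite(p) || p < 0 || p > 1) abort("`p` must lie in [0, 1].")
  if (!is.finite(lambda) || lambda < 0 || lambda > 1) {
    abort("`lambda` must lie in [0, 1].")
  }
  affected <- runif(n) >= p
  arrest <- runif(n) < lambda
  out <- rep("proliferate", n)
  out[affected & arrest] <- "g0_arrest"
  out[affected & !arrest] <- "die"
  factor(out, levels = c("proliferate", "g0_arrest", "die"))
}
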