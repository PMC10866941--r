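# Combination-therapy fate algebra: probabilistic-independence null model,
# intersection-fate policies, Bliss-style expectation, dose-grid runner.

#' Probability of being affected by either of two independent drugs
#'
#' Under probabilistic independence the chance of being affected by both
#' drugs is the product of the marginals, so the union probability is
#' `P_A + P_B - P_A * P_B`. The full decomposition over the four joint
#' outcomes is returned alongside.
#'
#' @param p_affected_a,p_affected_b Per-cell probabilities of being affected
#'   by each drug, in \[0, 1\].
#' @return A tibble with columns `p_either`, `only_a`, `only_b`, `both`,
#'   `neither` (rows recycled over the inputs; decomposition sums to 1).
#' @export
#' @examples
#' combined_affected_probability(0.5, 0.5)
combined_affected_probability <- function(p_affected_a, p_affected_b) {
  n <- max(length(p_affected_a), length(p_affected_b))
  pa <- rep_len(p_affected_a, n)
  pb <- rep_len(p_affected_b, n)
  if (any(!is.finite(pa) | pa < 0 | pa > 1) ||
      any(!is.finite(pb) | pb < 0 | pb > 1)) {
    abort("affected probabilities must lie in [0, 1].")
  }
  tibble::tibble(
    p_either = pa + pb - pa * pb,
    only_a = pa * (1 - pb),
    only_b = pb * (1 - pa),
    both = pa * pb,
    neither = (1 - pa) * (1 - pb)
  )
}

#' Expected combined inhibition under Bliss independence
#'
#' Population-level analogue of the independence null model:
#' `E_A + E_B - E_A * E_B` on fractional effects. The excess of an observed
#' combined effect over this expectation is the supra-additivity score.
#'
#' @param e_a,e_b Fractional inhibitions of the monotherapies, in \[0, 1\].
#' @return Expected combined fractional inhibition.
#' @export
#' @examples
#' bliss_expected_inhibition(0.5, 0.5) # 0.75
bliss_expected_inhibition <- function(e_a, e_b) {
  if (any(!is.finite(e_a) | e_a < 0 | e_a > 1) ||
      any(!is.finite(e_b) | e_b < 0 | e_b > 1)) {
    abort("fractional effects must lie in [0, 1].")
  }
  e_a + e_b - e_a * e_b
}

#' Bliss excess (supra-additivity score)
#'
#' @inheritParams bliss_expected_inhibition
#' @param observed Observed combined fractional inhibition.
#' @return A tibble with `expected`, `observed`, `excess` and
#'   `supra_additive` (excess > 0).
#' @export
#' @examples
#' bliss_excess(0.9, 0.5, 0.5) # excess +0.15
bliss_excess <- function(observed, e_a, e_b) {
  expected <- bliss_expected_inhibition(e_a, e_b)
  tibble::tibble(
    expected = expected,
    observed = observed,
    excess = observed - expected,
    supra_additive = observed - expected > 0
  )
}

#' Sample per-cell fates under a two-drug combination
#'
#' Draws independent affected indicators for the two drugs and resolves the
#' fate: a cell affected by one drug only follows that drug's
#' cytostatic/cytotoxic split; a cell affected by both follows the
#' intersection policy (`"toxic_dominates"`: death wins if either realised
#' fate is death; `"static_dominates"`: arrest wins; `"coin_flip"`: one
#' drug's realised fate is chosen at random); a cell affected by neither
#' proliferates.
#'
#' @param n Number of draws.
#' @param p_a,p_b Per-cycle probabilities of remaining unaffected by each
#'   drug.
#' @param lambda_a,lambda_b Cytostatic fractions of the two drugs.
#' @param policy Intersection policy.
#' @return A factor with levels `proliferate`, `g0_arrest`, `die`.
#' @export
#' @examples
#' set.seed(1)
#' table(sample_fates_combination(1e4, 0.5, 0.5, 0, 1)) / 1e4
sample_fates_combination <- function(n, p_a, p_b, lambda_a, lambda_b,
                                     policy = c(
                                       "toxic_dominates", "static_dominates",
                                       "coin_flip"
                                     )) {
  policy <- match.arg(policy)
  for (x in c(p_a, p_b, lambda_a, lambda_b)) {
    if (!is.finite(x) || x < 0 || x > 1) {
      abort("probabilities must lie in [0, 1].")
    }
  }
  aff_a <- runif(n) >= p_a
  die_a <- runif(n) >= lambda_a
  aff_b <- runif(n) >= p_b
  die_b <- runif(n) >= lambda_b
  out <- rep("proliferate", n)
  only_a <- aff_a & !aff_b
  only_b <- aff_b & !aff_a
  both <- aff_a & aff_b
  out[only_a & die_a] <- "die"
  out[only_a & !die_a] <- "g0_arrest"
  out[only_b & die_b] <- "die"
  out[only_b & !die_b] <- "g0_arrest"
  if (any(both)) {
    die_both <- switch(policy,
      toxic_dominates = die_a | die_b,
      static_dominates = die_a & die_b,
      coin_flip = ifelse(runif(n) < 0.5, die_a, die_b)
    )
    out[both & die_both] <- "die"
    out[both & !die_both] <- "g0_arrest"
  }
  factor(out, levels = c("proliferate", "g0_arrest", "die"))
}

#' Simulate a grid of drug combinations
#'
#' Runs replicate spheroid-slice simulations for every pair of doses of two
#' drugs under either the probabilistic-independence null model (both drugs
#' with their monotherapy transport) or the alternative-fit hypothesis
#' (drug B switched to spatially uniform, no-diffusion/no-uptake transport
#' with its own dilution schedule; the fate algebra is unchanged). Replicate
#' seeds depend only on `(seed, replicate)`, so a `(c, 0)` pair reproduces
#' monotherapy at `c` exactly.
#'
#' @param config A [sim_config()] (spheroid-slice initial configuration).
#' @param drug_a,drug_b Template [drug_treatment()] objects; their `dose_uM`
#'   is overridden by the grid values.
#' @param doses_a,doses_b Dose vectors in micromolar (non-empty).
#' @param hypothesis `"null_independence"` or `"alternative_fit"`.
#' @param policy Intersection-fate policy, see [sample_fates_combination()].
#' @param n_replicates Replicates per dose pair.
#' @param seed Base seed for the shared replicate-seed protocol.
#' @param record_days Optional observation days.
#' @return A `combo_experiment` list with elements `series` (per-pair
#'   inhibition-ratio time series), `summary` (per-pair nadir, relapse
#'   classification and final inhibition), `records` (raw growth records,
#'   control included) and the run settings.
#' @export
run_combination_experiment <- function(config, drug_a, drug_b,
                                       doses_a, doses_b,
                                       hypothesis = c(
                                         "null_independence", "alternative_fit"
                                       ),
                                       policy = "toxic_dominates",
                                       n_replicates = config$n_replicates,
                                       seed = 1L,
                                       record_days = NULL) {
  hypothesis <- match.arg(hypothesis)
  if (length(doses_a) == 0L || length(doses_b) == 0L) {
    abort("dose lists must be non-empty.")
  }
  control <- simulate_replicates(config,
    drugs = list(), n = n_replicates,
    seed = seed, record_days = record_days, condition = "control"
  )
  grid <- tidyr::expand_grid(dose_a = doses_a, dose_b = doses_b)
  runs <- purrr::pmap(grid, function(dose_a, dose_b) {
    da <- drug_a
    da$dose_uM <- dose_a
    db <- drug_b
    db$dose_uM <- dose_b
    if (hypothesis == "alternative_fit") {
      db$transport_mode <- "no_diffusion_alternative_fit"
      db$uptake_M_cell_s <- 0
    }
    rec <- simulate_replicates(config,
      drugs = list(da, db), n = n_replicates, seed = seed,
      policy = policy, record_days = record_days
    )
    series <- assemble_inhibition_series(rec, control)
    relapse <- classify_relapse(series)
    list(
      record = rec,
      series = tibble::add_column(series,
        dose_a = dose_a, dose_b = dose_b, .before = 1L
      ),
      summary = tibble::add_column(relapse,
        dose_a = dose_a, dose_b = dose_b,
        final_inhibition_pct = 100 * (1 - series$ratio[nrow(series)]),
        .before = 1L
      )
    )
  })
  structure(
    list(
      series = dplyr::bind_rows(purrr::map(runs, "series")),
      summary = dplyr::bind_rows(purrr::map(runs, "summary")),
      records = c(list(control = control), purrr::map(runs, "record")),
      hypothesis = hypothesis,
      policy = policy,
      n_replicates = n_replicates,
      seed = seed
    ),
    class = "combo_experiment"
  )
}

#' @export
print.combo_experiment <- function(x, ...) {
  cat(sprintf(
    "<combo_experiment> %s (%s policy), %d dose pairs x %d replicates\n",
    x$hypothesis, x$policy, nrow(x$summary), x$n_replicates
  ))
  print(x$summary, ...)
  invisible(x)
}
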