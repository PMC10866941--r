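#' Simulation configuration
#'
#' Bundles the lattice geometry, cell-kinetic parameters and numerical step
#' sizes of a simulation run. Defaults reproduce the reference experimental
#' conditions: 15 um lattice spacing (one cell per site), doubling times drawn
#' from Normal(22 h, 1 h), spontaneous death once per cycle with probability
#' 0.05 (reported intrinsic death in gliomas spans 5-11%), a 48 h lysis
#' period, Moore-neighbourhood space search up to ring 3, a 1 h agent step
#' and a 60 s diffusion step, 10 replicates, and a 300 x 300 lattice so a
#' three-week spheroid run never touches the boundary.
#'
#' @param n_rows,n_cols Lattice dimensions (sites).
#' @param spacing_um Lattice spacing in micrometres; one site holds one cell.
#' @param mean_doubling_time_h,doubling_time_sd_h Doubling-time distribution
#'   (hours); each cell draws its own doubling time at birth from this normal
#'   distribution truncated at +/- 4 SD.
#' @param spontaneous_death_prob Per-cycle probability of spontaneous death,
#'   evaluated once per completed cycle at the division attempt.
#' @param lysis_period_h Hours a dying cell occupies its site before the site
#'   becomes reusable debris.
#' @param g0_death_prob Optional per-cycle probability that a drug-arrested
#'   (G0) cell dies through necrosis; 0 disables the pathway.
#' @param max_search_ring Largest Moore ring searched for empty space (1-3).
#' @param dt_agent_h Agent (cell) time step in hours.
#' @param dt_pde_s Diffusion-solver time step in seconds.
#' @param days Total simulated days (time 0 = treatment application).
#' @param initial_config `"spheroid_slice"` or `"monolayer"`.
#' @param initial_radius_sites Initial spheroid-slice radius in sites.
#' @param initial_n_cells Number of cells seeded in the monolayer configuration.
#' @param n_replicates Default replicate count for replicate runs.
#' @param record_interval_days Observation cadence in days.
#'
#' @return A `sim_config` object (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_rows = 100, n_cols = 100, days = 7)
#' cfg$mean_doubling_time_h
sim_config <- function(n_rows = 300L,
                       n_cols = 300L,
                       spacing_um = 15,
                       mean_doubling_time_h = 22,
                       doubling_time_sd_h = 1,
                       spontaneous_death_prob = 0.05,
                       lysis_period_h = 48,
                       g0_death_prob = 0,
                       max_search_ring = 3L,
                       dt_agent_h = 1,
                       dt_pde_s = 60,
                       days = 21,
                       initial_config = c("spheroid_slice", "monolayer"),
                       initial_radius_sites = 12L,
                       initial_n_cells = 10000L,
                       n_replicates = 10L,
                       record_interval_days = 2) {
  initial_config <- match.arg(initial_config)
  cfg <- list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    spacing_um = spacing_um,
    mean_doubling_time_h = mean_doubling_time_h,
    doubling_time_sd_h = doubling_time_sd_h,
    spontaneous_death_prob = spontaneous_death_prob,
    lysis_period_h = lysis_period_h,
    g0_death_prob = g0_death_prob,
    max_search_ring = as.integer(max_search_ring),
    dt_agent_h = dt_agent_h,
    dt_pde_s = dt_pde_s,
    days = days,
    initial_config = initial_config,
    initial_radius_sites = as.integer(initial_radius_sites),
    initial_n_cells = as.integer(initial_n_cells),
    n_replicates = as.integer(n_replicates),
    record_interval_days = record_interval_days
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  pos <- c(
    "n_rows", "n_cols", "spacing_um", "mean_doubling_time_h",
    "doubling_time_sd_h", "lysis_period_h", "dt_agent_h", "dt_pde_s",
    "days", "n_replicates", "record_interval_days"
  )
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || !is.finite(cfg[[f]]) ||
        cfg[[f]] <= 0) {
      abort(sprintf("`%s` must be a single positive number.", f))
    }
  }
  for (f in c("spontaneous_death_prob", "g0_death_prob")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(sprintf("`%s` must be a probability in [0, 1].", f))
    }
  }
  if (!cfg$max_search_ring %in% 1:3) {
    abort("`max_search_ring` must be 1, 2 or 3.")
  }
  if (!cfg$initial_config %in% c("spheroid_slice", "monolayer")) {
    abort("`initial_config` must be \"spheroid_slice\" or \"monolayer\".")
  }
  if (cfg$initial_radius_sites < 0) abort("`initial_radius_sites` must be >= 0.")
  if (cfg$initial_n_cells < 0) abort("`initial_n_cells` must be >= 0.")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d x %d lattice (%g um), %s start, %g days, dt = %g h / %g s\n",
    x$n_rows, x$n_cols, x$spacing_um, x$initial_config, x$days,
    x$dt_agent_h, x$dt_pde_s
  ))
  invisible(x)
}

#' Dosing and medium-exchange schedule
#'
#' Describes the bath-dose events of an experiment. Time 0 is the moment of
#' treatment; spheroids are treated on day 4 post-seeding
#' (`treatment_start_day`, metadata only). From day 3 post-treatment on, half
#' of the medium is replaced with drug-free medium every two days, which
#' multiplies the bath dose by `1 - exchange_fraction`. The alternative-fit
#' transport mode instead dilutes a spatially uniform drug every
#' `alt_period_h` hours after `alt_start_h`, retaining `alt_retained_fraction`
#' of the concentration at each event.
#'
#' @param treatment_start_day Day post-seeding at which treatment starts
#'   (informational; simulations start at treatment).
#' @param exchange_start_day First medium exchange, days post-treatment.
#' @param exchange_period_days Days between medium exchanges.
#' @param exchange_fraction Fraction of the bath replaced with drug-free
#'   medium at each exchange.
#' @param alt_start_h Hours post-treatment of the first alternative-fit
#'   dilution event.
#' @param alt_period_h Hours between alternative-fit dilution events.
#' @param alt_retained_fraction Fraction of the concentration retained per
#'   alternative-fit dilution ("diluted by 2/3" read as retaining 1/3; set to
#'   2/3 for the minimal-dilution reading).
#'
#' @return A `dosing_schedule` object.
#' @export
#' @examples
#' dosing_schedule(exchange_fraction = 0.5)
dosing_schedule <- function(treatment_start_day = 4,
                            exchange_start_day = 3,
                            exchange_period_days = 2,
                            exchange_fraction = 0.5,
                            alt_start_h = 72,
                            alt_period_h = 48,
                            alt_retained_fraction = 1 / 3) {
  if (exchange_fraction < 0 || exchange_fraction > 1) {
    abort("`exchange_fraction` must be in [0, 1].")
  }
  if (alt_retained_fraction < 0 || alt_retained_fraction > 1) {
    abort("`alt_retained_fraction` must be in [0, 1].")
  }
  if (exchange_start_day < 0 || treatment_start_day < 0) {
    abort("schedule start days must be >= 0.")
  }
  if (exchange_period_days <= 0 || alt_period_h <= 0) {
    abort("schedule periods must be > 0.")
  }
  structure(
    list(
      treatment_start_day = treatment_start_day,
      exchange_start_day = exchange_start_day,
      exchange_period_days = exchange_period_days,
      exchange_fraction = exchange_fraction,
      alt_start_h = alt_start_h,
      alt_period_h = alt_period_h,
      alt_retained_fraction = alt_retained_fraction
    ),
    class = "dosing_schedule"
  )
}

#' Physical transport parameters for the reference drugs
#'
#' Returns the diffusion coefficient, uptake rate, cytostatic fraction and
#' sustained-death convention used for temozolomide (TMZ, predominantly
#' cytostatic, lambda = 1) and doxorubicin (DOX, predominantly cytotoxic,
#' lambda = 0, with long-term death probability via the peak-exposure memory).
#'
#' @param drug `"TMZ"` or `"DOX"`.
#' @return A list with elements `diffusion_cm2_s`, `uptake_M_cell_s`,
#'   `lambda` and `sustained_death`.
#' @export
#' @examples
#' default_drug_params("DOX")
default_drug_params <- function(drug = c("TMZ", "DOX")) {
  drug <- match.arg(drug)
  switch(drug,
    TMZ = list(
      diffusion_cm2_s = 8.68e-7, uptake_M_cell_s = 1.4e-10,
      lambda = 1, sustained_death = FALSE
    ),
    DOX = list(
      diffusion_cm2_s = 8.68e-8, uptake_M_cell_s = 1.4e-13,
      lambda = 0, sustained_death = TRUE
    )
  )
}

#' Describe one drug arm of a simulation
#'
#' Couples a calibrated [fate model][build_fate_model] to the physical
#' transport of the drug: its bath dose, diffusion coefficient, cellular
#' uptake rate, transport mode and dosing schedule.
#'
#' @param name Drug label (used to key exposure memory and random streams).
#' @param dose_uM Bath dose applied at treatment, in micromolar.
#' @param fate_model A `fate_model` from [build_fate_model()] or
#'   [constant_fate_model()].
#' @param diffusion_cm2_s Diffusion coefficient (cm^2/s).
#' @param uptake_M_cell_s Cellular uptake rate (molar per cell per second).
#' @param transport_mode `"reaction_diffusion"` (Dirichlet bath at the domain
#'   edge, uptake sink at live-cell sites), `"homogeneous"` (well-mixed; all
#'   sites always equal the scheduled bath dose, the monolayer assay
#'   condition) or `"no_diffusion_alternative_fit"` (spatially uniform, no
#'   uptake, diluted per the alternative-fit schedule).
#' @param schedule A [dosing_schedule()].
#'
#' @return A `drug_treatment` object.
#' @export
#' @examples
#' dr <- generate_dose_response(c(0.01, 0.05, 0.2, 1), ic50_uM = 0.05)
#' fm <- build_fate_model(dr, lambda = 0, drug = "DOX")
#' drug_treatment("DOX", dose_uM = 0.9, fate_model = fm)
drug_treatment <- function(name,
                           dose_uM,
                           fate_model,
                           diffusion_cm2_s = NULL,
                           uptake_M_cell_s = NULL,
                           transport_mode = c(
                             "reaction_diffusion", "homogeneous",
                             "no_diffusion_alternative_fit"
                           ),
                           schedule = dosing_schedule()) {
  transport_mode <- match.arg(transport_mode)
  if (!inherits(fate_model, "fate_model")) {
    abort("`fate_model` must be a fate_model object.")
  }
  defaults <- if (toupper(name) %in% c("TMZ", "DOX")) {
    default_drug_params(toupper(name))
  } else {
    list(diffusion_cm2_s = 1e-7, uptake_M_cell_s = 0)
  }
  diffusion_cm2_s <- diffusion_cm2_s %||% defaults$diffusion_cm2_s
  uptake_M_cell_s <- uptake_M_cell_s %||% defaults$uptake_M_cell_s
  if (dose_uM < 0) abort("`dose_uM` must be >= 0.")
  if (diffusion_cm2_s < 0) abort("`diffusion_cm2_s` must be >= 0.")
  if (uptake_M_cell_s < 0) abort("`uptake_M_cell_s` must be >= 0.")
  structure(
    list(
      name = name,
      dose_uM = dose_uM,
      fate_model = fate_model,
      diffusion_cm2_s = diffusion_cm2_s,
      uptake_M_cell_s = uptake_M_cell_s,
      transport_mode = transport_mode,
      schedule = schedule
    ),
    class = "drug_treatment"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
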