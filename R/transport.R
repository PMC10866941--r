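# Continuous drug concentration fields (molar, one value per lattice site).

#' Create the concentration field of a drug arm
#'
#' In `"reaction_diffusion"` mode the interior starts drug-free and the
#' outermost lattice ring is a Dirichlet bath held at the scheduled dose, so
#' drug diffuses inwards while live cells consume it. The `"homogeneous"` and
#' `"no_diffusion_alternative_fit"` modes are spatially uniform at the bath
#' concentration.
#'
#' @param treatment A [drug_treatment()].
#' @param config A [sim_config()].
#' @return A `drug_field` object.
#' @export
drug_field <- function(treatment, config) {
  bath <- treatment$dose_uM * 1e-6
  conc <- matrix(0, config$n_rows, config$n_cols)
  if (treatment$transport_mode == "reaction_diffusion") {
    conc[1, ] <- bath
    conc[config$n_rows, ] <- bath
    conc[, 1] <- bath
    conc[, config$n_cols] <- bath
  } else {
    conc[] <- bath
  }
  structure(
    list(
      name = treatment$name,
      conc = conc,
      bath = bath,
      initial_bath = bath,
      mode = treatment$transport_mode,
      D = treatment$diffusion_cm2_s,
      gamma = treatment$uptake_M_cell_s,
      schedule = treatment$schedule,
      fate_model = treatment$fate_model,
      spacing_um = config$spacing_um
    ),
    class = "drug_field"
  )
}

#' @export
print.drug_field <- function(x, ...) {
  cat(sprintf(
    "<drug_field> %s (%s): bath %.4g uM, D = %g cm2/s, gamma = %g M/(cell s)\n",
    x$name, x$mode, x$bath * 1e6, x$D, x$gamma
  ))
  invisible(x)
}

#' Advance a drug field by one agent time step
#'
#' Integrates `dC/dt = D lap(C) - gamma * rho(x)` over `dt_h` hours, where
#' `rho` indicates live-cell sites, with the boundary ring clamped to the
#' current bath dose (Dirichlet). The default solver is a dimensionally split
#' backward-Euler scheme (unconditionally stable, second order in space,
#' monotone, so the discrete maximum principle holds); an explicit FTCS
#' solver is retained for cross-validation and errors if `dt_pde_s` violates
#' its stability bound `h^2 / (4 D)`. Negative excursions are clipped at 0; a
#' warning is raised if the clipped magnitude exceeds 1e-12 M. The uniform
#' modes simply hold every site at the bath dose.
#'
#' @param field A [drug_field()].
#' @param lattice The current `hdc_lattice` (provides live-cell sites).
#' @param dt_h Agent step in hours.
#' @param dt_pde_s Diffusion substep in seconds.
#' @param solver `"implicit"` or `"explicit"`.
#' @return The updated `drug_field`.
#' @export
step_field <- function(field, lattice, dt_h, dt_pde_s = 60,
                       solver = c("implicit", "explicit")) {
  solver <- match.arg(solver)
  if (field$mode != "reaction_diffusion") {
    field$conc[] <- field$bath
    return(field)
  }
  h_cm <- field$spacing_um * 1e-4
  total_s <- dt_h * 3600
  nsteps <- max(1L, ceiling(total_s / dt_pde_s))
  dt_s <- total_s / nsteps
  r <- field$D * dt_s / h_cm^2
  live <- lattice$state == .STATE_PROLIFERATIVE |
    lattice$state == .STATE_QUIESCENT |
    lattice$state == .STATE_G0
  uptake <- field$gamma * dt_s
  if (solver == "implicit") {
    res <- diffuse_implicit(field$conc, live, r, uptake, field$bath, nsteps)
    field$conc <- res$conc
    if (res$max_clip > 1e-12) {
      warn(
        sprintf(
          "uptake clipped negative concentrations of magnitude %.3g M in field %s.",
          res$max_clip, field$name
        ),
        .frequency = "once",
        .frequency_id = paste0("spherosim_clip_", field$name)
      )
    }
  } else {
    if (r > 0.25) {
      abort(sprintf(
        "explicit solver unstable: dt = %g s exceeds the stability bound h^2/(4D) = %g s.",
        dt_s, h_cm^2 / (4 * field$D)
      ))
    }
    field$conc <- .diffuse_explicit(field$conc, live, r, uptake, field$bath, nsteps)
  }
  field
}

# explicit FTCS reference solver (vectorised; cross-validation only)
.diffuse_explicit <- function(C, live, r, uptake, bath, nsteps) {
  nr <- nrow(C)
  nc <- ncol(C)
  ii <- 2:(nr - 1)
  jj <- 2:(nc - 1)
  live_int <- live[ii, jj]
  for (s in seq_len(nsteps)) {
    C[1, ] <- bath; C[nr, ] <- bath; C[, 1] <- bath; C[, nc] <- bath
    Ci <- C[ii, jj]
    Cn <- Ci + r * (C[ii - 1, jj] + C[ii + 1, jj] +
      C[ii, jj - 1] + C[ii, jj + 1] - 4 * Ci)
    if (uptake > 0) Cn[live_int] <- Cn[live_int] - uptake
    Cn[Cn < 0] <- 0
    C[ii, jj] <- Cn
  }
  C[1, ] <- bath; C[nr, ] <- bath; C[, 1] <- bath; C[, nc] <- bath
  C
}

#' Replace part of the medium with drug-free medium
#'
#' Scales the bath (boundary) dose by `1 - fraction`; in the spatial
#' reaction-diffusion mode the interior is left unchanged and relaxes toward
#' the new bath through the PDE, mirroring an experimental half-medium
#' exchange that alters the surrounding medium but not the intra-spheroid
#' drug. Uniform transport modes are set to the new bath everywhere.
#'
#' @param field A [drug_field()].
#' @param fraction Fraction of the bath replaced, in \[0, 1\].
#' @return The updated `drug_field`.
#' @export
apply_medium_exchange <- function(field, fraction) {
  if (fraction < 0 || fraction > 1) abort("`fraction` must be in [0, 1].")
  field$bath <- field$bath * (1 - fraction)
  if (field$mode != "reaction_diffusion") {
    field$conc[] <- field$bath
  }
  field
}

#' Advance an alternative-fit field and apply its dilution events
#'
#' Under the alternative-fit hypothesis the drug is spatially uniform with no
#' diffusion or uptake; at every `alt_period_h` mark after `alt_start_h`
#' post-treatment the concentration is multiplied by the schedule's retained
#' fraction. Events falling in the half-open window `(t_h, t_h + dt_h]` are
#' applied.
#'
#' @param field A `drug_field` with mode `"no_diffusion_alternative_fit"`.
#' @param t_h Hours post-treatment at the start of the step.
#' @param dt_h Step length in hours.
#' @return The updated `drug_field`.
#' @export
alternative_fit_step <- function(field, t_h, dt_h) {
  if (field$mode != "no_diffusion_alternative_fit") {
    abort("`alternative_fit_step()` requires transport mode no_diffusion_alternative_fit.")
  }
  sch <- field$schedule
  n_events <- .events_in_window(t_h, dt_h, sch$alt_start_h, sch$alt_period_h)
  if (n_events > 0) {
    field$bath <- field$bath * sch$alt_retained_fraction^n_events
  }
  field$conc[] <- field$bath
  field
}

# number of scheduled event times (start + j*period, j >= 0) in (t, t + dt]
.events_in_window <- function(t_h, dt_h, start_h, period_h) {
  upper <- floor((t_h + dt_h - start_h) / period_h)
  lower <- ceiling((t_h - start_h) / period_h)
  if (t_h >= start_h && (t_h - start_h) %% period_h == 0) lower <- lower + 1L
  lower <- max(lower, 0)
  n <- upper - lower + 1L
  if (upper < 0 || n <= 0) 0L else as.integer(n)
}

# apply all scheduled bath events of a field in (t, t+dt]
.apply_schedule <- function(field, t_h, dt_h) {
  sch <- field$schedule
  if (field$mode == "no_diffusion_alternative_fit") {
    return(alternative_fit_step(field, t_h, dt_h))
  }
  n <- .events_in_window(
    t_h, dt_h, sch$exchange_start_day * 24, sch$exchange_period_days * 24
  )
  for (i in seq_len(n)) {
    field <- apply_medium_exchange(field, sch$exchange_fraction)
  }
  field
}

#' Update each cell's maximum experienced concentration
#'
#' Per-cell fate probabilities key on the peak extracellular concentration a
#' cell has been exposed to; this records the running maximum for every drug
#' field. Newborn cells start from the concentration at their birth site
#' (exposure memory is not inherited).
#'
#' @param lattice An `hdc_lattice`.
#' @param fields List of `drug_field` objects.
#' @return The updated lattice.
#' @export
record_max_concentration <- function(lattice, fields) {
  for (f in fields) {
    lattice$maxc[[f$name]] <- pmax(lattice$maxc[[f$name]], f$conc)
  }
  lattice
}
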