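# Configuration files, delimited-text I/O and run manifests.
#
# The configuration file is YAML: the top level holds the flat sim_config
# keys, plus an optional `drugs:` section (a list of per-drug blocks with
# dose, transport and fate-calibration parameters). Unknown keys are
# rejected so typos never pass silently.

.drug_keys <- c(
  "name", "dose_uM", "lambda", "k", "sustained_death", "transport_mode",
  "diffusion_cm2_s", "uptake_M_cell_s", "dose_response_csv", "constant_p",
  "ic50_uM", "hill_slope",
  "treatment_start_day", "exchange_start_day", "exchange_period_days",
  "exchange_fraction", "alt_start_h", "alt_period_h", "alt_retained_fraction"
)

#' Read / write a simulation configuration file
#'
#' `read_sim_config()` parses a YAML file whose top level contains
#' [sim_config()] fields (missing fields take their defaults) and optionally
#' a `drugs:` list; unknown keys raise an error naming the offenders.
#' Each drug block needs a `name`, a `dose_uM` and a fate specification:
#' either `dose_response_csv` (a dose-response table calibrated with the
#' block's `lambda`/`k`), `ic50_uM` (+ optional `hill_slope`, calibrated from
#' a noise-free Hill curve) or `constant_p`.
#'
#' @param path File path.
#' @return `read_sim_config()` returns a list with elements `config` (a
#'   [sim_config()]) and `drugs` (list of [drug_treatment()]).
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) abort("configuration file must be a YAML mapping.")
  drug_blocks <- raw$drugs
  raw$drugs <- NULL
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0(
      "unknown configuration key(s): ", paste(unknown, collapse = ", ")
    ))
  }
  config <- do.call(sim_config, raw)
  drugs <- lapply(drug_blocks, .parse_drug_block, dir = dirname(path))
  list(config = config, drugs = drugs)
}

.parse_drug_block <- function(block, dir = ".") {
  unknown <- setdiff(names(block), .drug_keys)
  if (length(unknown)) {
    abort(paste0(
      "unknown drug configuration key(s): ", paste(unknown, collapse = ", ")
    ))
  }
  if (is.null(block$name) || is.null(block$dose_uM)) {
    abort("each drug block needs `name` and `dose_uM`.")
  }
  lambda <- block$lambda %||%
    (if (toupper(block$name) %in% c("TMZ", "DOX")) {
      default_drug_params(toupper(block$name))$lambda
    } else {
      abort(sprintf("drug %s needs an explicit `lambda`.", block$name))
    })
  k <- block$k %||% (72 / 22)
  sustained <- block$sustained_death %||%
    (toupper(block$name) == "DOX")
  fm <- if (!is.null(block$constant_p)) {
    constant_fate_model(block$constant_p, lambda, k, sustained, block$name)
  } else if (!is.null(block$dose_response_csv)) {
    p <- block$dose_response_csv
    if (!file.exists(p)) p <- file.path(dir, block$dose_response_csv)
    build_fate_model(
      utils::read.csv(p), lambda, k, sustained, block$name
    )
  } else if (!is.null(block$ic50_uM)) {
    doses <- block$ic50_uM * 10^seq(-2, 2, length.out = 9)
    build_fate_model(
      generate_dose_response(doses, block$ic50_uM, block$hill_slope %||% 1),
      lambda, k, sustained, block$name
    )
  } else {
    abort(sprintf(
      "drug %s needs one of `dose_response_csv`, `ic50_uM` or `constant_p`.",
      block$name
    ))
  }
  sched_keys <- intersect(names(block), names(formals(dosing_schedule)))
  schedule <- do.call(dosing_schedule, block[sched_keys])
  drug_treatment(
    name = block$name,
    dose_uM = block$dose_uM,
    fate_model = fm,
    diffusion_cm2_s = block$diffusion_cm2_s,
    uptake_M_cell_s = block$uptake_M_cell_s,
    transport_mode = block$transport_mode %||% "reaction_diffusion",
    schedule = schedule
  )
}

#' @rdname read_sim_config
#' @param config A [sim_config()] to serialise.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the resolved configuration,
#' the seed, the command and the package version.
#'
#' @param path Output file (JSON).
#' @param config A [sim_config()].
#' @param seed Integer seed used.
#' @param command Character label of the command executed.
#' @param extra Optional named list of additional settings.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, seed, command = "simulate",
                               extra = list()) {
  manifest <- c(
    list(
      command = command,
      package = "spherosim",
      version = as.character(utils::packageVersion("spherosim")),
      seed = seed,
      config = unclass(config)
    ),
    extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read / write growth records as tidy CSV
#'
#' Growth records travel as comma-delimited text with a header row and
#' columns `condition`, `replicate`, `day`, `area_um2` (additional columns
#' are preserved).
#'
#' @param record A growth-record data frame.
#' @param path File path.
#' @return The tibble (readers) or `path` invisibly (writers).
#' @export
write_growth_record <- function(record, path) {
  utils::write.csv(tibble::as_tibble(record), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_growth_record
#' @export
read_growth_record <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  class(out) <- c("growth_record", class(out))
  out
}
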