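# Agent update loop and simulation runners.
#
# Per agent hour: (1) scheduled bath events and field transport, (2) exposure
# memory update, (3) lysis progression, (4) aging, (5) division / fate phase.
# Within the fate phase agents are visited in a freshly shuffled order; drug
# fate is decided first at mitosis, then the intrinsic (spontaneous) death
# check, and only surviving-unaffected cells search for space. Space-blocked
# quiescent cells re-check space every step but reach mitosis (and hence the
# fate draws) only once space is available.
#
# Per-drug fate decisions consume dedicated random streams keyed by the drug
# name, and the per-candidate uniforms are drawn regardless of which branch
# uses them, so adding a zero-dose second drug leaves every draw of the first
# drug - and therefore the whole trajectory - bitwise unchanged.

.derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(salt) * 104729) %% 2147483629) + 1L
}

.drug_salt <- function(name) sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))

.stream_init <- function(seed) {
  old <- get0(".Random.seed", envir = .GlobalEnv)
  set.seed(seed)
  s <- get(".Random.seed", envir = .GlobalEnv)
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  s
}

.stream_runif <- function(stream, n) {
  old <- get(".Random.seed", envir = .GlobalEnv)
  assign(".Random.seed", stream, envir = .GlobalEnv)
  u <- runif(n)
  s <- get(".Random.seed", envir = .GlobalEnv)
  assign(".Random.seed", old, envir = .GlobalEnv)
  list(u = u, stream = s)
}

.new_counters <- function() {
  c(
    divisions = 0, drug_deaths = 0, spontaneous_deaths = 0, g0_deaths = 0,
    drug_arrests = 0, quiescent_entries = 0, lysed = 0
  )
}

#' Advance the coupled lattice / drug-field system by one agent step
#'
#' Applies scheduled bath events and transport for every drug field, records
#' peak exposure, progresses lysis and aging, and runs the mitosis phase
#' (drug fate, spontaneous death, space search, division) for all cells whose
#' age has reached their doubling time. This is the unit step used by
#' [run_growth_simulation()]; it is exported so that single steps can be
#' inspected and tested.
#'
#' @param lattice An `hdc_lattice`.
#' @param config A [sim_config()].
#' @param fields Named list of [drug_field()] objects (may be empty).
#' @param streams Named list of per-drug random streams (as created by the
#'   runner); created on the fly from the current RNG when `NULL`.
#' @param counters Named numeric vector of cumulative event counts.
#' @param t_h Hours post-treatment at the start of the step.
#' @param policy Intersection policy when two drugs affect the same cell:
#'   `"toxic_dominates"`, `"static_dominates"` or `"coin_flip"`.
#' @param solver Diffusion solver passed to [step_field()].
#' @return A list with updated `lattice`, `fields`, `streams`, `counters`.
#' @export
step_lattice <- function(lattice, config, fields = list(), streams = NULL,
                         counters = NULL, t_h = 0,
                         policy = c("toxic_dominates", "static_dominates", "coin_flip"),
                         solver = "implicit") {
  policy <- match.arg(policy)
  dt <- config$dt_agent_h
  if (dt <= 0) abort("`dt_agent_h` must be > 0.")
  if (is.null(counters)) counters <- .new_counters()
  nd <- length(fields)
  if (nd > 0 && is.null(names(fields))) {
    names(fields) <- vapply(fields, function(f) f$name, character(1))
  }
  if (is.null(streams) && nd > 0) {
    streams <- lapply(fields, function(f) .stream_init(sample.int(2^31 - 2, 1)))
  }

  # (1) scheduled bath events, then transport
  for (d in seq_len(nd)) {
    fields[[d]] <- .apply_schedule(fields[[d]], t_h, dt)
    fields[[d]] <- step_field(fields[[d]], lattice, dt,
      dt_pde_s = config$dt_pde_s, solver = solver
    )
  }

  # (2) exposure memory
  if (nd > 0) lattice <- record_max_concentration(lattice, fields)

  st <- lattice$state
  age <- lattice$age
  tdv <- lattice$tdiv
  lys <- lattice$lysis

  # (3) lysis progression
  dying <- which(st == .STATE_DYING)
  if (length(dying)) {
    lys[dying] <- lys[dying] - dt
    done <- dying[lys[dying] <= 0]
    if (length(done)) {
      st[done] <- .STATE_DEBRIS
      counters["lysed"] <- counters["lysed"] + length(done)
    }
  }

  # (4) aging of cycling / quiescent cells
  grows <- st == .STATE_PROLIFERATIVE | st == .STATE_QUIESCENT
  age[grows] <- age[grows] + dt

  # (4b) optional G0 necrosis (per-cycle probability mapped to this step)
  if (config$g0_death_prob > 0) {
    g0 <- which(st == .STATE_G0)
    if (length(g0)) {
      p_step <- 1 - (1 - config$g0_death_prob)^(dt / config$mean_doubling_time_h)
      hit <- g0[runif(length(g0)) < p_step]
      if (length(hit)) {
        st[hit] <- .STATE_DYING
        lys[hit] <- config$lysis_period_h
        counters["g0_deaths"] <- counters["g0_deaths"] + length(hit)
      }
    }
  }

  # (5) mitosis phase
  nr <- nrow(st)
  nc <- ncol(st)
  ready_p <- which(st == .STATE_PROLIFERATIVE & age >= tdv)
  idx_q <- integer(0)
  ready_q <- which(st == .STATE_QUIESCENT & age >= tdv)
  if (length(ready_q)) {
    empty <- st == .STATE_EMPTY | st == .STATE_DEBRIS
    avail <- .dilate_chebyshev(empty, config$max_search_ring)
    idx_q <- ready_q[avail[ready_q]]
  }
  cand <- c(ready_p, idx_q)
  if (length(cand)) {
    is_q <- c(
      rep(FALSE, length(ready_p)),
      rep(TRUE, length(idx_q))
    )
    ord <- sample.int(length(cand))
    cand <- cand[ord]
    is_q <- is_q[ord]
    ncand <- length(cand)

    # pre-drawn uniforms: 2 per candidate per drug from the drug's stream
    U <- vector("list", nd)
    for (d in seq_len(nd)) {
      res <- .stream_runif(streams[[d]], 2L * ncand)
      streams[[d]] <- res$stream
      U[[d]] <- matrix(res$u, ncol = 2L)
    }
    u_spont <- runif(ncand)
    lambdas <- vapply(fields, function(f) f$fate_model$lambda, numeric(1))
    pfuns <- lapply(fields, function(f) .fate_lookup_fun(f$fate_model))
    maxc <- lattice$maxc
    sdp <- config$spontaneous_death_prob
    lysp <- config$lysis_period_h
    ring <- config$max_search_ring

    for (i in seq_len(ncand)) {
      s <- cand[i]
      target <- NULL
      if (is_q[i]) {
        target <- .find_empty_site_idx(st, s, nr, nc, ring)
        if (is.null(target)) next # still space-blocked: remains quiescent
      }
      # drug fate first
      if (nd > 0) {
        affected <- logical(nd)
        dies <- logical(nd)
        for (d in seq_len(nd)) {
          pd <- pfuns[[d]](maxc[[d]][s])
          affected[d] <- U[[d]][i, 1L] >= pd
          dies[d] <- U[[d]][i, 2L] >= lambdas[d]
        }
        if (any(affected)) {
          aff <- which(affected)
          fate_die <- if (length(aff) == 1L) {
            dies[aff]
          } else {
            switch(policy,
              toxic_dominates = any(dies[aff]),
              static_dominates = all(dies[aff]),
              coin_flip = dies[aff][sample.int(length(aff), 1L)]
            )
          }
          if (fate_die) {
            st[s] <- .STATE_DYING
            lys[s] <- lysp
            counters["drug_deaths"] <- counters["drug_deaths"] + 1
          } else {
            st[s] <- .STATE_G0
            counters["drug_arrests"] <- counters["drug_arrests"] + 1
          }
          next
        }
      }
      # intrinsic spontaneous death, once per cycle at the boundary crossing
      # (space-blocked cells re-attempting from quiescence had their check
      # when this cycle's boundary was first reached)
      if (!is_q[i] && sdp > 0 && u_spont[i] < sdp) {
        st[s] <- .STATE_DYING
        lys[s] <- lysp
        counters["spontaneous_deaths"] <- counters["spontaneous_deaths"] + 1
        next
      }
      # space search and division
      if (!is_q[i]) target <- .find_empty_site_idx(st, s, nr, nc, ring)
      if (is.null(target)) {
        if (st[s] != .STATE_QUIESCENT) {
          counters["quiescent_entries"] <- counters["quiescent_entries"] + 1
        }
        st[s] <- .STATE_QUIESCENT
        age[s] <- tdv[s] # held at threshold; re-attempts next step
      } else {
        st[s] <- .STATE_PROLIFERATIVE
        st[target] <- .STATE_PROLIFERATIVE
        newt <- draw_doubling_times(2L, config)
        tdv[s] <- newt[1L]
        tdv[target] <- newt[2L]
        age[s] <- 0
        age[target] <- 0
        for (d in seq_len(nd)) {
          maxc[[d]][target] <- fields[[d]]$conc[target]
        }
        counters["divisions"] <- counters["divisions"] + 1
      }
    }
    if (nd > 0) lattice$maxc <- maxc
  }

  lattice$state <- st
  lattice$age <- age
  lattice$tdiv <- tdv
  lattice$lysis <- lys
  list(lattice = lattice, fields = fields, streams = streams, counters = counters)
}

.condition_label <- function(drugs) {
  if (length(drugs) == 0) {
    return("untreated")
  }
  paste(
    vapply(drugs, function(d) sprintf("%s %g uM", d$name, d$dose_uM), character(1)),
    collapse = " + "
  )
}

#' Run a growth simulation
#'
#' Simulates `config$days` days of growth (time 0 = treatment application)
#' for an untreated, monotherapy or combination condition and returns the
#' census time series at the observation timepoints, together with the
#' viable-area proxy (viable-state sites x spacing^2) and cumulative event
#' counts.
#'
#' @inheritParams step_lattice
#' @param config A [sim_config()].
#' @param drugs A list of [drug_treatment()] objects (possibly empty).
#' @param seed Integer seed; identical config + seed give bitwise-identical
#'   output.
#' @param record_days Numeric days at which to record (defaults to every
#'   `config$record_interval_days` plus the final day; fractions allowed for
#'   sub-day assay horizons).
#' @param snapshot_days,snapshot_dir Optionally write integer-coded lattice
#'   snapshots at these days into `snapshot_dir`.
#' @param condition Condition label stored with the record (defaults to a
#'   label built from the drug doses).
#' @return A `growth_record` tibble with columns `day`, the [census()]
#'   counts, `area_um2`, per-drug bath concentrations (uM) and cumulative
#'   event counters.
#' @export
#' @examples
#' cfg <- sim_config(
#'   n_rows = 40, n_cols = 40, days = 2,
#'   initial_config = "spheroid_slice", initial_radius_sites = 5
#' )
#' rec <- run_growth_simulation(cfg, seed = 1)
#' rec
run_growth_simulation <- function(config, drugs = list(), seed = NULL,
                                  policy = "toxic_dominates",
                                  record_days = NULL,
                                  solver = "implicit",
                                  snapshot_days = NULL, snapshot_dir = NULL,
                                  condition = NULL) {
  if (inherits(drugs, "drug_treatment")) drugs <- list(drugs)
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1)
  set.seed(seed)
  condition <- condition %||% .condition_label(drugs)
  names(drugs) <- vapply(drugs, function(d) d$name, character(1))

  lat <- switch(config$initial_config,
    monolayer = init_monolayer(config, drugs = names(drugs)),
    spheroid_slice = init_spheroid_slice(config, drugs = names(drugs))
  )
  fields <- lapply(drugs, drug_field, config = config)
  streams <- lapply(drugs, function(d) {
    .stream_init(.derive_seed(seed, .drug_salt(d$name)))
  })
  counters <- .new_counters()

  record_days <- record_days %||%
    unique(c(seq(0, config$days, by = config$record_interval_days), config$days))
  record_h <- sort(unique(round(record_days * 24)))
  total_h <- round(config$days * 24)
  record_h <- record_h[record_h <= total_h]

  snap_h <- if (length(snapshot_days)) round(snapshot_days * 24) else integer(0)
  take_snapshot <- function(h) {
    if (h %in% snap_h && !is.null(snapshot_dir)) {
      write_lattice_snapshot(
        lat, file.path(snapshot_dir, sprintf("snapshot_day%05.1f.txt", h / 24))
      )
    }
  }

  rows <- vector("list", length(record_h))
  ri <- 1L
  rec_row <- function(h) {
    cs <- census(lat)
    baths <- if (length(fields)) {
      setNames(
        lapply(fields, function(f) f$bath * 1e6),
        paste0("bath_", names(fields), "_uM")
      )
    } else {
      NULL
    }
    dplyr::bind_cols(
      tibble::tibble(day = h / 24),
      cs,
      tibble::tibble(area_um2 = cs$n_viable * config$spacing_um^2),
      tibble::as_tibble(as.list(counters)),
      if (length(baths)) tibble::as_tibble(baths) else NULL
    )
  }
  if (0 %in% record_h) {
    rows[[ri]] <- rec_row(0)
    ri <- ri + 1L
  }
  take_snapshot(0L)

  # a growing spheroid slice should never reach the Dirichlet bath ring;
  # the monolayer configuration legitimately occupies the whole lattice
  boundary_warned <- config$initial_config != "spheroid_slice"
  nh <- total_h
  for (t in seq_len(nh) - 1L) {
    stepres <- step_lattice(lat, config, fields, streams, counters,
      t_h = t * config$dt_agent_h, policy = policy, solver = solver
    )
    lat <- stepres$lattice
    fields <- stepres$fields
    streams <- stepres$streams
    counters <- stepres$counters
    h <- t + 1L
    if (!boundary_warned) {
      edge <- c(lat$state[1, ], lat$state[nrow(lat$state), ],
                lat$state[, 1], lat$state[, ncol(lat$state)])
      if (any(edge != .STATE_EMPTY)) {
        warn("cell population reached the lattice boundary ring; growth is now confined.")
        boundary_warned <- TRUE
      }
    }
    if (h %in% record_h) {
      rows[[ri]] <- rec_row(h)
      ri <- ri + 1L
    }
    take_snapshot(h)
  }

  out <- dplyr::bind_rows(rows)
  out <- tibble::add_column(out, condition = condition, .before = 1L)
  class(out) <- c("growth_record", class(out))
  attr(out, "seed") <- seed
  attr(out, "config") <- config
  out
}

#' Run replicate simulations of one condition
#'
#' Runs `n` independent replicates of [run_growth_simulation()] with
#' replicate seeds derived deterministically from `seed`, and binds the
#' records with a `replicate` column. The replicate-seed protocol is shared
#' across conditions, so a combination arm at dose `(c, 0)` reproduces the
#' monotherapy trajectories at dose `c` exactly.
#'
#' @inheritParams run_growth_simulation
#' @param n Number of replicates (defaults to `config$n_replicates`).
#' @return A `growth_record` tibble with a `replicate` column.
#' @export
simulate_replicates <- function(config, drugs = list(), n = config$n_replicates,
                                seed = 1L, policy = "toxic_dominates",
                                record_days = NULL, solver = "implicit",
                                condition = NULL) {
  recs <- purrr::map(seq_len(n), function(i) {
    r <- run_growth_simulation(
      config, drugs,
      seed = .derive_seed(seed, i),
      policy = policy, record_days = record_days, solver = solver,
      condition = condition
    )
    tibble::add_column(r, replicate = i, .after = "condition")
  })
  out <- dplyr::bind_rows(recs)
  class(out) <- c("growth_record", class(out))
  attr(out, "seed") <- seed
  attr(out, "config") <- config
  out
}
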