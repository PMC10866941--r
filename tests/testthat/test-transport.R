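make_field <- function(n = 40, dose_uM = 1, D = 8.68e-8, gamma = 0,
                       mode = "reaction_diffusion", dt_pde = 60,
                       schedule = dosing_schedule()) {
  cfg <- sim_config(n_rows = n, n_cols = n, dt_pde_s = dt_pde)
  fm <- constant_fate_model(1, 0, drug = "X")
  tr <- drug_treatment("X", dose_uM, fm,
    diffusion_cm2_s = D,
    uptake_M_cell_s = gamma, transport_mode = mode, schedule = schedule
  )
  list(field = drug_field(tr, cfg), config = cfg)
}

empty_lattice <- function(n) {
  init_monolayer(sim_config(n_rows = n, n_cols = n), n_cells = 0)
}

test_that("a bath-equilibrated field without uptake is a steady state", {
  mk <- make_field(n = 30, dose_uM = 5, gamma = 0)
  f <- mk$field
  f$conc[] <- f$bath
  lat <- empty_lattice(30)
  f2 <- step_field(f, lat, dt_h = 1, dt_pde_s = 60)
  expect_equal(f2$conc, f$conc, tolerance = 1e-12)
})

test_that("Dirichlet relaxation is monotone, bounded and matches the slab series", {
  n <- 50
  mk <- make_field(n = n, dose_uM = 1, D = 8.68e-8)
  f <- mk$field
  lat <- empty_lattice(n)
  prev_gap <- 1
  for (hh in 1:8) {
    f <- step_field(f, lat, dt_h = 1, dt_pde_s = 60)
    gap <- max(abs(f$conc - f$bath)) / f$bath
    expect_lte(gap, prev_gap + 1e-12) # monotone approach to the bath
    expect_true(all(f$conc >= -1e-15 & f$conc <= f$bath * (1 + 1e-12)))
    prev_gap <- gap
    if (hh %in% c(1, 2, 4, 8)) {
      exact <- analytic_square_relaxation(n, 15, 8.68e-8, hh * 3600, f$bath)
      expect_lt(max(abs(f$conc - exact)) / f$bath, 0.01)
    }
  }
})

test_that("implicit and explicit solvers agree; explicit enforces stability", {
  n <- 40
  mki <- make_field(n = n, D = 8.68e-8, gamma = 1.4e-13)
  mke <- make_field(n = n, D = 8.68e-8, gamma = 1.4e-13)
  cfg <- mki$config
  lat <- withr::with_seed(1, init_spheroid_slice(cfg, 8))
  fi <- mki$field
  fe <- mke$field
  for (hh in 1:2) {
    fi <- step_field(fi, lat, 1, dt_pde_s = 60, solver = "implicit")
    fe <- step_field(fe, lat, 1, dt_pde_s = 5, solver = "explicit")
  }
  expect_lt(max(abs(fi$conc - fe$conc)) / fi$bath, 0.005)

  # stability bound for the explicit scheme: dt <= h^2 / (4 D)
  mk_fast <- make_field(n = 20, D = 8.68e-7)
  expect_error(
    step_field(mk_fast$field, empty_lattice(20), 1,
      dt_pde_s = 60, solver = "explicit"
    ),
    "stability bound"
  )
})

test_that("uptake creates an inward gradient obeying the maximum principle", {
  n <- 50
  mk <- make_field(n = n, dose_uM = 0.9, D = 8.68e-8, gamma = 1.4e-13)
  cfg <- mk$config
  lat <- withr::with_seed(2, init_spheroid_slice(cfg, 12))
  f <- mk$field
  centre <- c(n %/% 2 + 1, n %/% 2 + 1)
  for (hh in 1:12) {
    f <- suppressWarnings(step_field(f, lat, 1, dt_pde_s = 60))
    expect_true(all(f$conc >= 0 & f$conc <= f$initial_bath + 1e-15))
    rim <- f$conc[centre[1], 2]
    expect_lt(f$conc[centre[1], centre[2]], rim + 1e-15)
  }
  expect_gt(max(abs(f$conc - f$bath)), 0) # gradient actually present
})

test_that("medium exchange dilutes the bath only; interior relaxes via the PDE", {
  mk <- make_field(n = 30, dose_uM = 500, D = 8.68e-7)
  f <- mk$field
  f$conc[] <- f$bath # equilibrated
  expect_equal(apply_medium_exchange(f, 0)$bath, f$bath)
  expect_equal(apply_medium_exchange(f, 1)$bath, 0)
  f2 <- apply_medium_exchange(apply_medium_exchange(f, 0.5), 0.5)
  expect_equal(f2$bath * 1e6, 125)
  # interior untouched at the moment of the exchange
  expect_equal(max(f2$conc), 500e-6)
  expect_error(apply_medium_exchange(f, 1.2), "0, 1")
})

test_that("alternative-fit dilution fires exactly at 72 + 48k hours", {
  mk <- make_field(
    n = 20, dose_uM = 0.9, mode = "no_diffusion_alternative_fit"
  )
  f <- mk$field
  bath_trace <- numeric(0)
  for (t in 0:143) {
    f <- alternative_fit_step(f, t, 1)
    bath_trace <- c(bath_trace, f$bath * 1e6)
    expect_true(all(f$conc == f$bath)) # spatially uniform, always
  }
  h <- 1:144
  expect_true(all(abs(bath_trace[h <= 71] - 0.9) < 1e-12))
  expect_equal(bath_trace[72], 0.3) # first event in (71, 72]
  expect_true(all(abs(bath_trace[h > 72 & h <= 119] - 0.3) < 1e-12))
  expect_equal(bath_trace[120], 0.1) # 0.9 * (1/3)^2 after two events
  expect_true(all(abs(bath_trace[h > 120 & h <= 144] - 0.1) < 1e-12))

  expect_error(
    alternative_fit_step(make_field(n = 20)$field, 0, 1),
    "no_diffusion_alternative_fit"
  )
})

test_that("homogeneous mode always equals the scheduled bath dose", {
  mk <- make_field(n = 25, dose_uM = 100, mode = "homogeneous", gamma = 1e-10)
  cfg <- mk$config
  lat <- withr::with_seed(1, init_spheroid_slice(cfg, 8))
  f <- mk$field
  f <- step_field(f, lat, 1)
  expect_true(all(f$conc == f$bath))
  f <- apply_medium_exchange(f, 0.5)
  expect_true(all(f$conc == f$bath))
  expect_equal(f$bath, 50e-6, tolerance = 1e-12)
})

test_that("exposure memory keeps the historical peak; newborns start fresh", {
  cfg <- sim_config(
    n_rows = 20, n_cols = 20, spontaneous_death_prob = 0,
    initial_n_cells = 30, initial_config = "monolayer"
  )
  fm <- constant_fate_model(1, 0, drug = "X") # p = 1: no drug effect on fate
  tr <- drug_treatment("X", 100, fm,
    transport_mode = "homogeneous",
    uptake_M_cell_s = 0
  )
  lat <- withr::with_seed(3, init_monolayer(cfg, drugs = "X"))
  f <- drug_field(tr, cfg)
  bath0 <- f$bath
  lat <- record_max_concentration(lat, list(X = f))
  occ0 <- which(lat$state == 1L)
  expect_true(all(lat$maxc$X[occ0] == bath0))

  # the bath decays but the memory holds the peak
  f <- apply_medium_exchange(f, 0.9)
  lat <- record_max_concentration(lat, list(X = f))
  expect_true(all(lat$maxc$X[occ0] == bath0))

  # newborn daughters start from the current local concentration
  streams <- list(X = spherosim:::.stream_init(99))
  lat$age[occ0] <- lat$tdiv[occ0] # everyone divides now
  res <- withr::with_seed(4, step_lattice(
    lat, cfg,
    fields = list(X = f), streams = streams
  ))
  born <- setdiff(which(res$lattice$state == 1L), occ0)
  expect_gt(length(born), 0)
  expect_true(all(res$lattice$maxc$X[born] == f$bath))
  expect_equal(max(res$lattice$maxc$X[born]), 10e-6, tolerance = 1e-12)
  expect_true(all(res$lattice$maxc$X[occ0] == bath0))
})
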