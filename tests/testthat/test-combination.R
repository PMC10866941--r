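test_that("independence algebra matches exhaustive enumeration of two Bernoullis", {
  expect_equal(combined_affected_probability(0, 0.4)$p_either, 0.4)
  dec <- combined_affected_probability(0.5, 0.5)
  expect_equal(dec$p_either, 0.75)
  expect_equal(unlist(dec[, c("only_a", "only_b", "both", "neither")]),
    c(only_a = 0.25, only_b = 0.25, both = 0.25, neither = 0.25)
  )

  grid <- expand.grid(pa = seq(0, 1, 0.25), pb = seq(0, 1, 0.25))
  for (i in seq_len(nrow(grid))) {
    pa <- grid$pa[i]
    pb <- grid$pb[i]
    d <- combined_affected_probability(pa, pb)
    # enumerate the four joint outcomes of independent draws
    outcomes <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE))
    probs <- ifelse(outcomes$a, pa, 1 - pa) * ifelse(outcomes$b, pb, 1 - pb)
    expect_equal(d$both, sum(probs[outcomes$a & outcomes$b]))
    expect_equal(d$only_a, sum(probs[outcomes$a & !outcomes$b]))
    expect_equal(d$only_b, sum(probs[!outcomes$a & outcomes$b]))
    expect_equal(d$neither, sum(probs[!outcomes$a & !outcomes$b]))
    expect_equal(d$p_either, sum(probs[outcomes$a | outcomes$b]))
    expect_equal(d$only_a + d$only_b + d$both + d$neither, 1)
  }
  expect_error(combined_affected_probability(-0.1, 0.5), "0, 1")
})

test_that("Bliss expectation and supra-additivity score", {
  expect_equal(bliss_expected_inhibition(0.5, 0), 0.5)
  expect_equal(bliss_expected_inhibition(0.5, 0.5), 0.75)
  ex <- bliss_excess(0.9, 0.5, 0.5)
  expect_equal(ex$excess, 0.15)
  expect_true(ex$supra_additive)
  expect_error(bliss_expected_inhibition(1.2, 0), "0, 1")
})

test_that("combination fate sampling respects the intersection policy", {
  # A cytotoxic and always affected, B never affected: death, any policy
  for (pol in c("toxic_dominates", "static_dominates", "coin_flip")) {
    f <- withr::with_seed(1, sample_fates_combination(
      200, p_a = 0, p_b = 1, lambda_a = 0, lambda_b = 1, policy = pol
    ))
    expect_true(all(f == "die"))
  }
  # both unaffected: proliferate
  f <- sample_fates_combination(200, 1, 1, 0, 1)
  expect_true(all(f == "proliferate"))

  withr::local_seed(77)
  n <- 1e5
  quadrant_check <- function(policy, expected) {
    f <- sample_fates_combination(n, 0.5, 0.5, 0, 1, policy = policy)
    props <- as.numeric(table(f)) / n
    se <- sqrt(expected * (1 - expected) / n)
    expect_true(all(abs(props - expected) < 3 * se),
      label = paste("quadrant frequencies under", policy)
    )
    props
  }
  # neither 0.25 -> proliferate; only-A 0.25 -> die; only-B 0.25 -> G0;
  # both 0.25 -> policy-resolved
  p_tox <- quadrant_check("toxic_dominates", c(0.25, 0.25, 0.50))
  p_sta <- quadrant_check("static_dominates", c(0.25, 0.50, 0.25))
  quadrant_check("coin_flip", c(0.25, 0.375, 0.375))

  # policies can differ at most by the both-affected probability mass
  both_mass <- combined_affected_probability(0.5, 0.5)$both
  expect_lt(abs(p_tox[3] - p_sta[3]), both_mass + 3 * sqrt(0.25 / n))
})

test_that("a zero-dose partner leaves the monotherapy trajectory bitwise unchanged", {
  cfg <- sim_config(
    n_rows = 50, n_cols = 50, days = 4, initial_radius_sites = 8
  )
  fm_a <- build_fate_model(
    generate_dose_response(c(50, 150, 500, 1500), ic50_uM = 550, hill_slope = 1.5),
    lambda = 1, drug = "TMZ"
  )
  fm_b <- build_fate_model(
    generate_dose_response(c(0.005, 0.05, 0.5, 5), ic50_uM = 0.05),
    lambda = 0, sustained_death = TRUE, drug = "DOX"
  )
  tmz <- drug_treatment("TMZ", 300, fm_a)
  dox0 <- drug_treatment("DOX", 0, fm_b)

  mono <- suppressWarnings(
    run_growth_simulation(cfg, list(tmz), seed = 404, condition = "x")
  )
  combo <- suppressWarnings(
    run_growth_simulation(cfg, list(tmz, dox0), seed = 404, condition = "x")
  )
  drop_bath <- function(x) {
    as.data.frame(x[, !grepl("^bath_", names(x))])
  }
  expect_identical(drop_bath(mono), drop_bath(combo))
})

test_that("combination grids reproduce controls at (0, 0) and classify relapse", {
  cfg <- sim_config(
    n_rows = 40, n_cols = 40, days = 4, initial_radius_sites = 6,
    n_replicates = 2
  )
  fm <- constant_fate_model(0.5, lambda = 0, drug = "A")
  fmb <- constant_fate_model(0.5, lambda = 1, drug = "B")
  a <- drug_treatment("A", 1, fm, transport_mode = "homogeneous")
  b <- drug_treatment("B", 1, fmb, transport_mode = "homogeneous")

  expect_error(
    run_combination_experiment(cfg, a, b, numeric(0), 1, seed = 1),
    "non-empty"
  )

  exp0 <- run_combination_experiment(cfg, a, b,
    doses_a = 0, doses_b = 0,
    n_replicates = 2, seed = 9
  )
  # the zero-dose pair shares the control's replicate seeds: ratio exactly 1
  expect_true(all(exp0$series$ratio == 1))

  expect_s3_class(tidy(exp0), "tbl_df")
  expect_true(all(c("dose_a", "dose_b", "relapsed") %in% names(glance(exp0))))
})

test_that("relapse classification flags regrowth but not arrest", {
  withr::local_seed(5)
  ctrl <- generate_reference_growth("untreated_exponential",
    n_replicates = 4, noise_sdlog = 0.02
  )
  rel <- generate_reference_growth("relapse",
    n_replicates = 4, noise_sdlog = 0.02
  )
  arr <- generate_reference_growth("arrested",
    n_replicates = 4, noise_sdlog = 0.02
  )
  s_rel <- assemble_inhibition_series(rel, ctrl)
  s_arr <- assemble_inhibition_series(arr, ctrl)
  expect_true(classify_relapse(s_rel)$relapsed)
  expect_false(classify_relapse(s_arr)$relapsed)
})
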