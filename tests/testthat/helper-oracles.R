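# Independent oracles used to cross-check the package implementation.

# Brute-force Monte Carlo branching process: per cycle a cycling cell
# divides unaffected (prob p, two cycling daughters), arrests permanently
# (prob lambda * (1 - p)) or dies. Returns the per-founder viable ratio
# sample mean and its standard error.
branching_mc_ratio <- function(p, lambda, k, n_founders = 1e5) {
  cyc <- rep(1L, n_founders)
  g0 <- numeric(n_founders)
  for (j in seq_len(k)) {
    div <- rbinom(n_founders, cyc, p)
    aff <- cyc - div
    arr <- rbinom(n_founders, aff, lambda)
    g0 <- g0 + arr
    cyc <- 2L * div
  }
  v <- (cyc + g0) / 2^k
  list(mean = mean(v), se = sd(v) / sqrt(n_founders))
}

# Textbook pool-adjacent-violators projection onto non-increasing sequences.
pava_nonincreasing <- function(y) {
  vals <- as.list(y)
  wts <- as.list(rep(1, length(y)))
  i <- 1L
  while (i < length(vals)) {
    if (vals[[i]] < vals[[i + 1]] - 1e-15) {
      pooled <- (vals[[i]] * wts[[i]] + vals[[i + 1]] * wts[[i + 1]]) /
        (wts[[i]] + wts[[i + 1]])
      wts[[i]] <- wts[[i]] + wts[[i + 1]]
      vals[[i]] <- pooled
      vals[[i + 1]] <- NULL
      wts[[i + 1]] <- NULL
      if (i > 1L) i <- i - 1L
    } else {
      i <- i + 1L
    }
  }
  unlist(mapply(function(v, w) rep(v, w), vals, wts, SIMPLIFY = FALSE))
}

# Analytic relaxation of a slab held at 0 inside and clamped to 1 at both
# faces: 1 - sum over odd modes. The 2D square solution is the product form
# bath * (1 - v(x) v(y)).
slab_profile <- function(x, L, D, t, n_terms = 399) {
  v <- 0
  for (n in seq(1, n_terms, by = 2)) {
    v <- v + 4 / (n * pi) * sin(n * pi * x / L) * exp(-D * n^2 * pi^2 * t / L^2)
  }
  v
}

analytic_square_relaxation <- function(n_sites, spacing_um, D, t_s, bath) {
  h <- spacing_um * 1e-4
  L <- (n_sites - 1) * h
  x <- (seq_len(n_sites) - 1) * h
  v <- slab_profile(x, L, D, t_s)
  bath * (1 - outer(v, v))
}

# small helpers -------------------------------------------------------------

tiny_config <- function(...) {
  sim_config(
    n_rows = 40, n_cols = 40, days = 2, initial_radius_sites = 5,
    initial_n_cells = 50, n_replicates = 2, ...
  )
}

# a lattice with prescribed states at given linear indices
lattice_with_states <- function(config, states, tdiv = 22, age = 0, lysis = 0) {
  lat <- init_monolayer(config, n_cells = 0)
  idx <- as.integer(names(states))
  lat$state[idx] <- as.integer(states)
  lat$tdiv[idx] <- tdiv
  lat$age[idx] <- age
  lat$lysis[idx] <- lysis
  lat
}
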