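# Matrix-backed agent lattice. Each site is empty (0) or carries one cell /
# debris; parallel matrices hold per-cell age, doubling time, lysis clock and
# per-drug maximum experienced concentration (molar).

new_lattice <- function(n_rows, n_cols, spacing_um, drugs = character()) {
  z <- matrix(0, n_rows, n_cols)
  structure(
    list(
      state = matrix(.STATE_EMPTY, n_rows, n_cols),
      age = z,
      tdiv = z,
      lysis = z,
      maxc = setNames(lapply(drugs, function(d) z), drugs),
      spacing_um = spacing_um
    ),
    class = "hdc_lattice"
  )
}

#' @export
print.hdc_lattice <- function(x, ...) {
  cs <- census(x)
  cat(sprintf(
    "<hdc_lattice> %d x %d sites (%g um spacing): %d viable (%d proliferative, %d quiescent, %d G0), %d dying, %d debris\n",
    nrow(x$state), ncol(x$state), x$spacing_um,
    cs$n_viable, cs$n_proliferative, cs$n_quiescent, cs$n_g0,
    cs$n_dying, cs$n_debris
  ))
  invisible(x)
}

# doubling times: Normal(mean, sd) truncated at +/- 4 SD (positivity)
draw_doubling_times <- function(n, config) {
  m <- config$mean_doubling_time_h
  s <- config$doubling_time_sd_h
  out <- rnorm(n, m, s)
  bad <- which(abs(out - m) > 4 * s)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), m, s)
    bad <- bad[abs(out[bad] - m) > 4 * s]
  }
  out
}

.seed_cells <- function(lat, idx, config) {
  lat$state[idx] <- .STATE_PROLIFERATIVE
  lat$tdiv[idx] <- draw_doubling_times(length(idx), config)
  lat$age[idx] <- runif(length(idx)) * lat$tdiv[idx]
  lat
}

#' Initialise the monolayer configuration
#'
#' Places `n_cells` proliferative cells uniformly at random (no collisions)
#' on the lattice, emulating the low-cellularity monolayer assay in which the
#' drug is spatially homogeneous. Each cell draws its doubling time from the
#' configured truncated normal and a uniform age in `[0, doubling_time)` so
#' divisions are asynchronous.
#'
#' @param config A [sim_config()].
#' @param n_cells Number of cells to place (defaults to
#'   `config$initial_n_cells`).
#' @param drugs Character vector of drug names for which exposure memory is
#'   tracked.
#' @return An `hdc_lattice`.
#' @export
#' @examples
#' lat <- init_monolayer(sim_config(n_rows = 50, n_cols = 50), n_cells = 100)
#' census(lat)
init_monolayer <- function(config, n_cells = config$initial_n_cells,
                           drugs = character()) {
  total <- config$n_rows * config$n_cols
  if (n_cells > total) {
    abort(sprintf(
      "cannot place %d cells on a lattice with capacity %d sites.",
      n_cells, total
    ))
  }
  lat <- new_lattice(config$n_rows, config$n_cols, config$spacing_um, drugs)
  if (n_cells > 0) {
    idx <- sample.int(total, n_cells)
    lat <- .seed_cells(lat, idx, config)
  }
  lat
}

#' Initialise the planar central slice of a spheroid
#'
#' Occupies every site within Euclidean distance `initial_radius_sites` of
#' the lattice centre with proliferative cells carrying randomised ages and
#' doubling times. The occupied footprint is a deterministic function of the
#' radius; only ages and doubling times depend on the random seed.
#'
#' @inheritParams init_monolayer
#' @param initial_radius_sites Disc radius in lattice sites; the disc must
#'   fit in the lattice with a margin of at least two rings.
#' @return An `hdc_lattice`.
#' @export
#' @examples
#' lat <- init_spheroid_slice(sim_config(n_rows = 60, n_cols = 60), 10)
#' census(lat)$n_viable # 317 sites within Euclidean radius 10
init_spheroid_slice <- function(config,
                                initial_radius_sites = config$initial_radius_sites,
                                drugs = character()) {
  r <- initial_radius_sites
  nr <- config$n_rows
  nc <- config$n_cols
  cr <- nr %/% 2 + 1L
  cc <- nc %/% 2 + 1L
  if (cr - r < 3L || cc - r < 3L || cr + r > nr - 2L || cc + r > nc - 2L) {
    abort(sprintf(
      "a disc of radius %d does not fit a %d x %d lattice with a 2-ring margin.",
      r, nr, nc
    ))
  }
  lat <- new_lattice(nr, nc, config$spacing_um, drugs)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  idx <- which((rows - cr)^2 + (cols - cc)^2 <= r^2)
  .seed_cells(lat, idx, config)
}

# Chebyshev ring offsets, precomputed for rings 1..3
.ring_offsets <- local({
  mk <- function(r) {
    g <- expand.grid(dr = -r:r, dc = -r:r)
    g <- g[pmax(abs(g$dr), abs(g$dc)) == r, ]
    m <- as.matrix(g)
    dimnames(m) <- NULL
    m
  }
  lapply(1:3, mk)
})

#' Find empty space around a position
#'
#' Searches the Moore rings of a site nearest-first: ring 1 (the 8 adjacent
#' sites) is inspected, and only if it holds no empty or post-lysis debris
#' site does the search expand to the next ring, up to `max_ring`. Among the
#' free sites of the first non-full ring one is chosen uniformly at random.
#'
#' @param lattice An `hdc_lattice`.
#' @param position Integer `c(row, col)` of an occupied site.
#' @param max_ring Largest ring searched (1-3).
#' @return Integer `c(row, col)` of the chosen site, or `NULL` if all rings
#'   are full.
#' @export
find_empty_site <- function(lattice, position, max_ring = 3L) {
  idx <- .find_empty_site_idx(
    lattice$state,
    (position[2] - 1L) * nrow(lattice$state) + position[1],
    nrow(lattice$state), ncol(lattice$state), max_ring
  )
  if (is.null(idx)) return(NULL)
  c(((idx - 1L) %% nrow(lattice$state)) + 1L, ((idx - 1L) %/% nrow(lattice$state)) + 1L)
}

# linear-index version used in the simulation loop
.find_empty_site_idx <- function(st, s, nr, nc, max_ring) {
  r0 <- ((s - 1L) %% nr) + 1L
  c0 <- ((s - 1L) %/% nr) + 1L
  for (ring in seq_len(max_ring)) {
    off <- .ring_offsets[[ring]]
    rr <- r0 + off[, 1L]
    cc <- c0 + off[, 2L]
    keep <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    if (!any(keep)) next
    lin <- (cc[keep] - 1L) * nr + rr[keep]
    stv <- st[lin]
    free <- lin[stv == .STATE_EMPTY | stv == .STATE_DEBRIS]
    if (length(free)) {
      if (length(free) == 1L) return(free)
      return(free[sample.int(length(free), 1L)])
    }
  }
  NULL
}

# Chebyshev dilation of a logical mask by radius r (zero fill at edges):
# TRUE wherever some TRUE site lies within ring <= r.
.dilate_chebyshev <- function(mask, r) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- mask
  for (dr in -r:r) {
    for (dc in -r:r) {
      if (dr == 0L && dc == 0L) next
      src_r <- max(1L, 1L - dr):min(nr, nr - dr)
      src_c <- max(1L, 1L - dc):min(nc, nc - dc)
      out[src_r + dr, src_c + dc] <- out[src_r + dr, src_c + dc] |
        mask[src_r, src_c]
    }
  }
  out
}

#' Count cells by state
#'
#' @param lattice An `hdc_lattice`.
#' @return A one-row tibble with per-state counts, `n_viable` (proliferative
#'   + quiescent + G0-arrested), `n_occupied` (any cell or debris) and
#'   `n_empty`; the counts partition the lattice.
#' @export
census <- function(lattice) {
  st <- lattice$state
  tab <- tabulate(st + 1L, nbins = 6L)
  tibble::tibble(
    n_proliferative = tab[2L],
    n_quiescent = tab[3L],
    n_g0 = tab[4L],
    n_dying = tab[5L],
    n_debris = tab[6L],
    n_empty = tab[1L],
    n_viable = tab[2L] + tab[3L] + tab[4L],
    n_occupied = sum(tab[2:6])
  )
}

# viable-area proxy in um^2: viable-state sites x spacing^2 (debris excluded)
.viable_area_um2 <- function(lattice) {
  cs <- census(lattice)
  cs$n_viable * lattice$spacing_um^2
}

#' Write / read an integer-coded lattice snapshot
#'
#' Snapshots are space-delimited integer grids using the codes of
#' [cell_states()] (0 = empty), one row of the file per lattice row.
#'
#' @param lattice An `hdc_lattice`.
#' @param path File to write.
#' @return `write_lattice_snapshot()` returns `path` invisibly;
#'   `read_lattice_snapshot()` returns an integer matrix.
#' @export
write_lattice_snapshot <- function(lattice, path) {
  write.table(lattice$state, path,
    row.names = FALSE, col.names = FALSE, sep = " "
  )
  invisible(path)
}

#' @rdname write_lattice_snapshot
#' @export
read_lattice_snapshot <- function(path) {
  as.matrix(read.table(path, header = FALSE))
}
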