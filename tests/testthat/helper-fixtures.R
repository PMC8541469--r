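# Shared simulation fixtures, generated once per test run and memoized.
# All randomness is seeded locally so the suite is reproducible.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

test_geometry <- function(...) scanner_geometry(...)

# small labeled acquisition of a water cylinder + line source
sim_cylinder <- function(radius, min_accepted = 1e4, seed = 1234) {
  cached(sprintf("cyl_%s_%s_%s", radius, min_accepted, seed), {
    fx <- fixture_cylinder(radius)
    simulate_acquisition(fx$phantom, fx$source, test_geometry(),
                         min_accepted = min_accepted, seed = seed)
  })
}

# hand-built list-mode events on valid blocks/coordinates (no physics)
make_events <- function(n, geom = test_geometry(), truth = TRUE, seed = 1) {
  set.seed(seed)
  pairs <- allowed_pairs(geom)
  pick <- pairs[sample(nrow(pairs), n, replace = TRUE), , drop = FALSE]
  swap <- runif(n) < 0.5
  ev <- data.table::data.table(
    block1 = as.integer(ifelse(swap, pick[, 2], pick[, 1])),
    u1 = runif(n, -24.9, 24.9), v1 = runif(n, -24.9, 24.9),
    doi1 = runif(n, 0, 20), e1 = runif(n, 350, 650),
    block2 = as.integer(ifelse(swap, pick[, 1], pick[, 2])),
    u2 = runif(n, -24.9, 24.9), v2 = runif(n, -24.9, 24.9),
    doi2 = runif(n, 0, 20), e2 = runif(n, 350, 650),
    t = as.numeric(seq_len(n)))
  if (truth) {
    ev$nscat1 <- stats::rpois(n, 0.4)
    ev$nscat2 <- stats::rpois(n, 0.4)
    ev$scatter1 <- ev$nscat1 > 0
    ev$scatter2 <- ev$nscat2 > 0
    ev$e_true1 <- ifelse(ev$scatter1, runif(n, 200, 511), 511)
    ev$e_true2 <- ifelse(ev$scatter2, runif(n, 200, 511), 511)
    ev$origin_z <- runif(n, -30, 30)
    ev$origin_in_fov <- abs(ev$origin_z) <= geom$axial_fov / 2
    ev$source_id <- 1L
  }
  listmode_set(ev, geom)
}

# events with prescribed window labels and truth flags, for calibration tests:
# each row of spec is (window, scattered, count); energies are representative
# of the window (400/500/600 keV pairs)
make_labeled_counts <- function(spec, geom = test_geometry()) {
  rows <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    w <- spec$window[i]
    e <- switch(w, lew = c(400, 500), photopeak = c(500, 500),
                uew = c(500, 600))
    n <- spec$count[i]
    if (n == 0) return(NULL)
    data.frame(e1 = rep(e[1], n), e2 = e[2], scattered = spec$scattered[i])
  }))
  n <- nrow(rows)
  ev <- data.table::data.table(
    block1 = 0L, u1 = 0, v1 = 0, doi1 = 0, e1 = rows$e1,
    block2 = 10L, u2 = 0, v2 = 0, doi2 = 0, e2 = rows$e2,
    t = as.numeric(seq_len(n)),
    scatter1 = rows$scattered, scatter2 = FALSE,
    nscat1 = as.integer(rows$scattered), nscat2 = 0L)
  listmode_set(ev, geom)
}

# independent Klein-Nishina oracle: unnormalized pdf of cos(theta)
kn_pdf <- function(cost, E) {
  a <- E / 511
  r <- 1 / (1 + a * (1 - cost))
  r^2 * (r + 1 / r - 1 + cost^2)
}

# geometry small enough that the full LOR lattice can be smoothed densely
small_grid <- function() {
  geom <- scanner_geometry(n_blocks = 6, min_block_sep = 2, apothem = 80,
                           transaxial_fov = 120)
  virtual_pixel_grid(geom, 12.5)  # 4 x 4 pixels per face, 9 pairs, 2304 bins
}

small_events <- function(n, grid, seed = 21) {
  set.seed(seed)
  geom <- grid$geometry
  pairs <- grid$pairs
  pick <- pairs[sample(nrow(pairs), n, replace = TRUE), , drop = FALSE]
  ev <- data.table::data.table(
    block1 = pick[, 1], u1 = runif(n, -25, 25), v1 = runif(n, -25, 25),
    doi1 = 0, e1 = runif(n, 350, 650),
    block2 = pick[, 2], u2 = runif(n, -25, 25), v2 = runif(n, -25, 25),
    doi2 = 0, e2 = runif(n, 430, 545), t = as.numeric(seq_len(n)))
  listmode_set(ev, geom)
}
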