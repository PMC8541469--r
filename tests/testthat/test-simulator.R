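
test_that("Compton kinematics match the closed form", {
  expect_equal(compton_energy(511, 0), 511)
  expect_equal(compton_energy(511, pi / 2), 255.5)
  expect_equal(compton_energy(511, pi), 511 / 3)
  # arbitrary angles against a hand-written evaluation
  th <- seq(0.1, 3, by = 0.3)
  expect_equal(compton_energy(340, th), 340 / (1 + (340 / 511) * (1 - cos(th))))
})

test_that("attenuation tables are decreasing and match quadrature of the cross-section", {
  pt <- physics_tables(seq(50, 700, by = 10))
  expect_true(all(diff(pt$mu_total) < 0))
  expect_true(all(diff(pt$mu_compton) < 0))
  # mu_compton = n_e * integral of the differential KN cross-section
  re2 <- 2.8179403262e-12^2
  for (E in c(100, 511, 650)) {
    sigma <- 2 * pi * (re2 / 2) * integrate(kn_pdf, -1, 1, E = E,
                                            rel.tol = 1e-10)$value
    expect_equal(physics_tables(E)$mu_compton, 3.3428e20 * sigma,
                 tolerance = 1e-6)
  }
})

test_that("Klein-Nishina samples follow the differential cross-section", {
  E <- 511
  set.seed(5)
  th <- sample_klein_nishina(E, 2e5)
  cost <- cos(th)
  # quadrature CDF oracle on a cos(theta) grid
  Z <- integrate(kn_pdf, -1, 1, E = E, rel.tol = 1e-10)$value
  grid <- seq(-1, 1, length.out = 201)
  cdf <- vapply(grid, function(g)
    integrate(kn_pdf, -1, g, E = E, rel.tol = 1e-9)$value / Z, 1)
  emp <- ecdf(cost)(grid)
  expect_lt(max(abs(emp - cdf)), 0.006)
  mean_cost <- integrate(function(c) c * kn_pdf(c, E), -1, 1,
                         rel.tol = 1e-10)$value / Z
  expect_equal(mean(cost), mean_cost, tolerance = 0.01)
  # determinism under a fixed seed
  set.seed(99)
  a <- sample_klein_nishina(400, 50)
  set.seed(99)
  expect_identical(a, sample_klein_nishina(400, 50))
})

test_that("transport through air leaves photons untouched", {
  ph <- phantom(cylinder(c(0, 0, 0), 100, 100, "air"))
  out <- transport_photon(ph, c(0, 0, 0), c(1, 0, 0), 511, n = 50)
  expect_true(all(out$alive))
  expect_true(all(out$energy == 511))
  expect_true(all(out$nscat == 0))
  expect_true(all(out$dx == 1 & out$dy == 0))
})

test_that("unscattered survival through 10 cm of water obeys Beer-Lambert", {
  ph <- phantom(cylinder(c(0, 0, 0), 50, 60, "water"))
  set.seed(7)
  n <- 1e5
  # pencil beam entering at the upstream rim: 100 mm of water to traverse;
  # crossing without any interaction happens with probability exp(-mu * 100)
  out <- transport_photon(ph, c(-50, 0, 0), c(1, 0, 0), 511, n = n)
  surv <- mean(out$nscat == 0 & out$alive)
  p <- exp(-physics_tables(511)$mu_total * 100)
  expect_lt(abs(surv - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("scatter multiplicity grows with phantom size", {
  set.seed(8)
  ns <- function(r) {
    ph <- phantom(cylinder(c(0, 0, 0), r, 30, "water"))
    out <- transport_photon(ph, c(0, 0, 0), c(1, 0, 0), 511, n = 2e4)
    out$nscat
  }
  n40 <- ns(40); n160 <- ns(160)
  expect_gt(mean(n160), mean(n40))
  # first-order stochastic dominance on the low orders
  for (k in 0:3)
    expect_lte(mean(n160 <= k), mean(n40 <= k) + 0.01)
})

test_that("an air-phantom point source yields pure unscattered coincidences at 10% FWHM", {
  geom <- test_geometry()
  ph <- phantom(cylinder(c(0, 0, 0), 50, 30, "air"))
  src <- source_component("cylinder", c(0, 0, 0), 0.5, 0.5, activity = 1)
  s <- simulate_acquisition(ph, src, geom, min_accepted = 8000, seed = 31)
  expect_true(all(!truth_scattered(s)))
  e <- c(s$events$e1, s$events$e2)
  expect_equal(2.3548 * sd(e) / mean(e), 0.10, tolerance = 0.005)
  expect_equal(mean(e), 511, tolerance = 1)
})

test_that("pre-blur energy is 511 keV iff the photon never scattered", {
  s <- sim_cylinder(120, 5e3)
  ev <- s$events
  expect_true(all((ev$e_true1 == 511) == (ev$nscat1 == 0)))
  expect_true(all(ev$e_true2[ev$nscat2 > 0] < 511))
})

test_that("simulated scatter fraction increases with cylinder radius", {
  sf <- vapply(c(40, 120, 160), function(r)
    truth_scatter_fraction(sim_cylinder(r, 5e3)), 1)
  expect_true(all(diff(sf) > 0))
})

test_that("acquisitions are reproducible under a fixed seed and respect sources", {
  geom <- test_geometry()
  fx <- fixture_cylinder(60)
  a <- simulate_acquisition(fx$phantom, fx$source, geom, n_decays = 5e4,
                            seed = 77)
  b <- simulate_acquisition(fx$phantom, fx$source, geom, n_decays = 5e4,
                            seed = 77)
  expect_identical(a$events, b$events)
  # all decays in the 60 mm tall line source originate inside the axial FOV
  expect_true(all(a$events$origin_in_fov))
  # zero-activity source: valid empty acquisition
  src0 <- source_component("line", c(0, 0, 0), 1, 10, activity = 0)
  s0 <- simulate_acquisition(fx$phantom, src0, geom, n_decays = 100)
  expect_equal(n_events(s0), 0)
})

test_that("the Utah fixture carves the cold rod and keeps the 10:1 hot ratio", {
  fx <- fixture_utah()
  geom <- test_geometry()
  s <- simulate_acquisition(fx$phantom, fx$source, geom, n_decays = 4e5,
                            seed = 13)
  prov <- s$provenance
  bg_vol <- pi * 100^2 * 50 - 2 * pi * 25^2 * 50
  hot_vol <- pi * 25^2 * 50
  dens <- prov$component_decays / c(bg_vol, hot_vol)
  expect_equal(dens[2] / dens[1], 10, tolerance = 0.3)
  # no decays inside the cold rod (background component excludes it)
  ev <- s$events
  expect_true(all(ev$source_id %in% c(1L, 2L)))
})
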