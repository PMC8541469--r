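test_that("the Silverman factor matches direct evaluation of the rule", {
  set.seed(2)
  x <- matrix(rnorm(10000 * 4, sd = 10), ncol = 4)
  H <- silverman_bandwidth(x)
  expect_true(all(H[row(H) != col(H)] == 0))
  expect_equal(diag(H), (2 / 30000)^0.25 * apply(x, 2, var),
               tolerance = 1e-12)
  expect_equal(diag(H)[1], 9.036, tolerance = 0.15)  # sigma ~ 10 mm
  # homogeneity: scaling coordinates by c scales H by c^2
  expect_equal(diag(silverman_bandwidth(3 * x)), 9 * diag(H),
               tolerance = 1e-12)
  # n-dependence: doubling n shrinks the factor by 2^(-1/4)
  x2 <- rbind(x, x)
  expect_equal(diag(silverman_bandwidth(x2)),
               (2 / (3 * 20000))^0.25 * apply(x2, 2, var), tolerance = 1e-12)
  expect_equal(diag(silverman_bandwidth(x2)) / diag(H), rep(2^(-1 / 4), 4),
               tolerance = 1e-3)
  # degenerate inputs fall back
  expect_message(Hf <- silverman_bandwidth(x[1, , drop = FALSE], fallback = 4),
                 "fallback")
  expect_equal(diag(Hf), rep(4, 4))
})

test_that("kernel weights are radial, maximal at zero and cut at the 95% contour", {
  H <- diag(c(4, 4, 4, 4))
  expect_equal(kernel_weight(c(0, 0, 0, 0), H), 1)
  chi2 <- kernel_truncation()
  expect_equal(chi2, qchisq(0.95, 4))
  inside <- c(sqrt(9.48 * 4), 0, 0, 0)   # Mahalanobis^2 = 9.48
  outside <- c(sqrt(9.50 * 4), 0, 0, 0)  # 9.50 > chi2_4(0.95) = 9.4877
  expect_gt(kernel_weight(inside, H), 0)
  expect_identical(unname(kernel_weight(outside, H)), 0)
  # isotropic H: weight depends only on |dx|
  a <- kernel_weight(c(2, 0, 0, 0), H)
  b <- kernel_weight(c(0, 0, sqrt(2), sqrt(2)), H)
  expect_equal(a, b)
})

test_that("fast truncated smoothing equals the dense brute-force convolution", {
  grid <- small_grid()
  s <- small_events(300, grid)
  cfg <- energy_windows("TEW")
  H <- diag(rep(60, 4))  # wide kernel spanning several pixels
  bw <- list(lew = H, photopeak = H, uew = H)
  sm <- smooth_window_counts(s, cfg, grid, bandwidths = bw, output = "full")
  full <- attr(sm, "full")

  # oracle: dense per-event loop over every bin of the event's block pair
  bins <- bin_events(s, grid)
  w <- as.character(classify_events(s, cfg))
  P <- grid$n_pixels
  centers_u <- grid$u_centers
  centers_v <- grid$v_centers
  lat <- expand.grid(iu_a = 0:(grid$n_u - 1), iv_a = 0:(grid$n_v - 1),
                     iu_b = 0:(grid$n_u - 1), iv_b = 0:(grid$n_v - 1))
  lat_x <- cbind(centers_u[lat$iu_a + 1], centers_v[lat$iv_a + 1],
                 centers_u[lat$iu_b + 1], centers_v[lat$iv_b + 1])
  lat_pa <- lat$iu_a * grid$n_v + lat$iv_a
  lat_pb <- lat$iu_b * grid$n_v + lat$iv_b
  for (win in c("lew", "photopeak", "uew")) {
    dense <- new.env()
    sel <- which(w == win & !is.na(bins$pair))
    for (i in sel) {
      x <- as.numeric(bins[i, c("ua", "va", "ub", "vb"), with = FALSE])
      wts <- kernel_weight(sweep(lat_x, 2, x, "-") * -1, H)
      if (sum(wts) == 0) next
      wts <- wts / sum(wts)
      nz <- which(wts > 0)
      for (j in nz) {
        key <- sprintf("%d_%d_%d", bins$pair[i], lat_pa[j], lat_pb[j])
        dense[[key]] <- (dense[[key]] %||% 0) + wts[j]
      }
    }
    got <- full[full$window == win]
    expect_equal(nrow(got), length(ls(dense)))
    for (r in seq_len(nrow(got))) {
      key <- sprintf("%d_%d_%d", got$pair[r], got$pa[r], got$pb[r])
      expect_lt(abs(got$value[r] - dense[[key]]), 1e-9)
    }
  }
})

test_that("each window's smoothed mass equals its event count", {
  grid <- small_grid()
  s <- small_events(400, grid, seed = 5)
  cfg <- energy_windows("TEW")
  sm <- smooth_window_counts(s, cfg, grid, output = "full")
  w <- table(classify_events(s, cfg))
  full <- attr(sm, "full")
  for (win in names(w)) {
    got <- sum(full$value[full$window == win])
    expect_lt(abs(got - w[[win]]) / max(1, w[[win]]), 1e-6)
  }
  # a single event distributes exactly unit mass over its neighborhood
  s1 <- small_events(1, grid, seed = 8)
  sm1 <- smooth_window_counts(s1, energy_windows("TEW"), grid,
                              bandwidths = list(lew = diag(rep(60, 4)),
                                                photopeak = diag(rep(60, 4)),
                                                uew = diag(rep(60, 4))),
                              output = "full")
  f1 <- attr(sm1, "full")
  expect_gt(nrow(f1), 1)
  expect_equal(sum(f1$value), 1, tolerance = 1e-9)
})

test_that("a bandwidth far below the pitch reduces to raw binned counts", {
  grid <- small_grid()
  s <- small_events(200, grid, seed = 12)
  cfg <- energy_windows("TEW")
  tiny <- diag(rep(1e-6, 4))
  sm <- smooth_window_counts(s, cfg, grid,
                             bandwidths = list(lew = tiny, photopeak = tiny,
                                               uew = tiny))
  ct <- count_windows(s, cfg, grid)
  m <- merge(sm, ct, by = "bin")
  expect_equal(m$lew.x, as.numeric(m$lew.y))
  expect_equal(m$photopeak.x, as.numeric(m$photopeak.y))
  expect_equal(m$uew.x, as.numeric(m$uew.y))
})

test_that("smoothing reduces the variance of homogeneous Poisson counts", {
  grid <- small_grid()
  s <- small_events(3000, grid, seed = 30)
  cfg <- energy_windows("TEW")
  sm <- smooth_window_counts(s, cfg, grid, output = "full",
                             bandwidths = list(lew = diag(rep(40, 4)),
                                               photopeak = diag(rep(40, 4)),
                                               uew = diag(rep(40, 4))))
  full <- attr(sm, "full")
  ct <- count_windows(s, cfg, grid)
  # photopeak window: compare per-bin variance over the full lattice
  n_bins <- n_lor_bins(grid)
  raw <- c(ct$photopeak, rep(0, n_bins - nrow(ct)))
  smv <- full$value[full$window == "photopeak"]
  smv <- c(smv, rep(0, n_bins - length(smv)))
  expect_lt(var(smv), var(as.numeric(raw)))
})
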