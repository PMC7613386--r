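test_that("hypercube samples occupy every stratum exactly once", {
  space <- param_space(sza = 30)
  s4 <- sample_param_space(space, 4, seed = 3)
  u <- (s4$LAI - 0) / 7
  expect_equal(sort(findInterval(u, c(0, 0.25, 0.5, 0.75, 1), rightmost.closed = TRUE)),
    1:4)
  n <- 1000
  s <- sample_param_space(space, n, seed = 4)
  # uniform marginals: one sample per equal-probability stratum
  for (check in list(
    list(v = s$N, lo = 1.2, hi = 1.8),
    list(v = s$LAI, lo = 0, hi = 7),
    list(v = s$hot, lo = 0.01, hi = 0.5)
  )) {
    u <- (check$v - check$lo) / (check$hi - check$lo)
    strata <- findInterval(u, seq(0, 1, length.out = n + 1), rightmost.closed = TRUE)
    expect_equal(sort(strata), 1:n)
  }
  # gaussian marginal: strata of the truncated normal CDF
  plo <- pnorm(0, 45, 10)
  phi <- pnorm(70, 45, 10)
  ug <- (pnorm(s$Cab, 45, 10) - plo) / (phi - plo)
  expect_equal(sort(findInterval(ug, seq(0, 1, length.out = n + 1),
    rightmost.closed = TRUE
  )), 1:n)
})

test_that("sampled marginals respect bounds, grids and fixed values", {
  space <- param_space(sza = 30, browning = TRUE)
  s <- sample_param_space(space, 500, seed = 9)
  expect_true(all(s$Cab >= 0 & s$Cab <= 70))
  expect_true(all(s$ALIA %in% 20:70))
  expect_true(all(s$Cbp >= 0 & s$Cbp <= 0.5))
  expect_equal(unique(s$Ccx), 8)
  expect_equal(unique(s$Cw), 0.015)
  expect_true(all(s$soil %in% c("dry", "wet")))
  # large-n gaussian location check
  sg <- sample_param_space(param_space(sza = 30, cab_mean = 45, cab_sd = 6), 10000,
    seed = 10
  )
  expect_lt(abs(mean(sg$Cab) / 45 - 1), 0.02)
  expect_error(
    param_space(sza = 30, lai_bounds = c(2, 2)),
    "zero-width"
  )
})

test_that("a LUT pairs each sampled row with its forward simulation", {
  space <- param_space(sza = 30)
  lut <- build_lut(space, n = 30, seed = 42)
  expect_equal(nrow(lut$params), 30)
  expect_equal(dim(lut$reflectance), c(30, 10))
  expect_false(lut$noise_applied)
  # loop oracle: recompute every row with the public forward interface
  for (i in seq_len(30)) {
    p <- lut$params[i, ]
    spec <- prosail(
      leaf_params(N = p$N, Cab = p$Cab, Ccx = p$Ccx, Cbp = p$Cbp,
        Cw = p$Cw, Cm = p$Cm),
      canopy_params(LAI = p$LAI, ALIA = p$ALIA, hot = p$hot, SZA = 30,
        soil = soil_spectrum(p$soil))
    )
    expect_equal(unname(lut$reflectance[i, ]),
      resample_to_bands(spec, lut$bands)$value,
      tolerance = 1e-12
    )
  }
  # zero-LAI entries reproduce the resampled soil spectrum
  space0 <- param_space(sza = 30, lai_bounds = c(0, 1e-9))
  lut0 <- build_lut(space0, n = 5, seed = 1)
  for (i in 1:5) {
    soil <- soil_spectrum(lut0$params$soil[i])
    expect_equal(unname(lut0$reflectance[i, ]),
      resample_to_bands(soil, lut0$bands)$value,
      tolerance = 1e-6
    )
  }
  # deterministic rebuild
  lut2 <- build_lut(space, n = 30, seed = 42)
  expect_identical(lut$reflectance, lut2$reflectance)
  expect_identical(lut$params, lut2$params)
})

test_that("LUT noise is 2 % relative, single-shot and seeded", {
  lut <- small_lut()
  noisy <- add_noise(lut, 0.02, seed = 5)
  expect_true(noisy$noise_applied)
  expect_error(add_noise(noisy, 0.02, seed = 5), "already")
  again <- add_noise(lut, 0.02, seed = 5)
  expect_identical(noisy$reflectance, again$reflectance)
  silent <- add_noise(lut, 0, seed = 5)
  expect_identical(silent$reflectance, lut$reflectance)
  rel <- noisy$reflectance / lut$reflectance - 1
  expect_lt(abs(sd(rel) - 0.02), 0.002)
  # additive mode perturbs in absolute units (away from the zero clip)
  addn <- add_noise(lut, 0.01, seed = 6, mode = "additive")
  unclipped <- lut$reflectance > 0.05
  expect_lt(abs(sd((addn$reflectance - lut$reflectance)[unclipped]) - 0.01), 0.001)
})

test_that("self-inversion returns the generating row exactly", {
  lut <- small_lut()
  set.seed(77)
  for (i in sample.int(lut$n, 25)) {
    est <- invert_spectrum(lut$reflectance[i, ], lut, top_fraction = 1 / lut$n)
    expect_equal(est$estimate[est$variable == "LAI"], lut$params$LAI[i])
    expect_equal(est$estimate[est$variable == "Cab"], lut$params$Cab[i])
    expect_equal(
      est$estimate[est$variable == "CCC"],
      lut$params$Cab[i] * lut$params$LAI[i]
    )
  }
})

test_that("the retained solution count is the ceiling of the fraction", {
  lut <- small_lut() # 400 entries
  est <- invert_spectrum(lut$reflectance[1, ], lut, top_fraction = 0.05)
  expect_equal(unique(est$n_solutions), 20)
  est2 <- invert_spectrum(lut$reflectance[1, ], lut, top_fraction = 0.012)
  expect_equal(unique(est2$n_solutions), ceiling(0.012 * 400))
})

test_that("measurement noise cannot improve the generating row's cost", {
  lut <- small_lut()
  m <- lut$reflectance[17, ]
  base_cost <- lut_cost_functions$rmse(lut$reflectance, m)[17]
  expect_equal(base_cost, 0)
  set.seed(123)
  costs <- replicate(1000, {
    noisy <- m * (1 + rnorm(length(m), 0, 0.02))
    lut_cost_functions$rmse(lut$reflectance, noisy)[17]
  })
  expect_gt(mean(costs), base_cost)
})

test_that("alternative cost functions rank a perfect match first", {
  lut <- small_lut()
  m <- lut$reflectance[9, ]
  for (cost in c("rmse", "sse", "sam")) {
    est <- invert_spectrum(m, lut, top_fraction = 1 / lut$n, cost = cost)
    expect_equal(est$estimate[est$variable == "LAI"], lut$params$LAI[9])
  }
  expect_error(invert_spectrum(m, lut, cost = "nope"), "unknown cost")
  expect_error(invert_spectrum(unname(c(m[-1], NA)), lut), "non-finite")
})
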