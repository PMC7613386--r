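make_frame <- function(nx = 8, ny = 6, dn = NULL, bit_depth = 12) {
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  if (is.null(dn)) {
    set.seed(5)
    dn <- sample.int(2^bit_depth, nrow(g)) - 1L
  }
  tibble::tibble(x = g$x, y = g$y, dn = dn)
}

test_that("black-level pixels convert to zero radiance", {
  cal <- radiometric_cal(a1 = 1.7, g = 2, te = 1.2, p_bl = 205 / 2^12)
  frame <- make_frame(dn = rep(205L, 48))
  out <- raw_to_radiance(frame, cal, bit_depth = 12)
  expect_equal(out$radiance, rep(0, 48), tolerance = 1e-12)
})

test_that("the conversion formula substitutes directly", {
  # V = 1, g = 1, a2 = a3 = 0, te = 1, a1 = 2, p - p_bl = 0.5 -> L = 1
  cal <- radiometric_cal(a1 = 2, te = 1, p_bl = 0.25)
  frame <- tibble::tibble(x = 1L, y = 1L, dn = as.integer(0.75 * 2^16))
  out <- raw_to_radiance(frame, cal, bit_depth = 16)
  expect_equal(out$radiance, 1.0)
})

test_that("row-dependent correction matches a scalar-loop evaluation", {
  cal <- radiometric_cal(
    a1 = 1.3, a2 = 0.004, a3 = 0.0012, g = 2, te = 0.8, p_bl = 0.02,
    vignette = function(x, y) 1 + 0.001 * ((x - 4)^2 + (y - 3)^2)
  )
  frame <- make_frame()
  out <- raw_to_radiance(frame, cal, bit_depth = 12)
  for (i in seq_len(nrow(frame))) {
    p <- frame$dn[i] / 2^12
    v <- 1 + 0.001 * ((frame$x[i] - 4)^2 + (frame$y[i] - 3)^2)
    expected <- v * (1.3 / 2) * (p - 0.02) /
      (0.8 + 0.004 * frame$y[i] - 0.0012 * 0.8 * frame$y[i])
    expect_equal(out$radiance[i], expected)
  }
})

test_that("radiance is positively homogeneous in a1 and guards the denominator", {
  frame <- make_frame()
  l1 <- raw_to_radiance(frame, radiometric_cal(a1 = 1.1, te = 1), bit_depth = 12)
  l2 <- raw_to_radiance(frame, radiometric_cal(a1 = 2.2, te = 1), bit_depth = 12)
  expect_equal(2 * l1$radiance, l2$radiance)
  bad <- radiometric_cal(a1 = 1, a2 = -0.5, te = 1)
  expect_error(raw_to_radiance(frame, bad, bit_depth = 12), "denominator")
  expect_error(
    raw_to_radiance(make_frame(dn = rep(4096L, 48)), radiometric_cal(a1 = 1),
      bit_depth = 12
    ),
    "2\\^12"
  )
})

panel_set <- function(slope = 0.002, intercept = 0.01, noise_sd = 0,
                      reflectances = c(0.02, 0.05, 0.09, 0.14, 0.22, 0.30,
                        0.39, 0.50, 0.63)) {
  bands <- micasense_dual_bands()
  out <- expand.grid(
    panel_id = sprintf("panel%02d", seq_along(reflectances)),
    band = bands$band, stringsAsFactors = FALSE
  )
  out$nominal_reflectance <- reflectances[match(out$panel_id,
    sprintf("panel%02d", seq_along(reflectances)))]
  out$observed_radiance <- (out$nominal_reflectance - intercept) / slope
  if (noise_sd > 0) {
    out$observed_radiance <- out$observed_radiance *
      (1 + stats::rnorm(nrow(out), 0, noise_sd))
  }
  tibble::as_tibble(out)
}

test_that("exact linear panels recover slope and intercept per band", {
  model <- fit_elm(panel_set(slope = 0.002, intercept = 0.01))
  expect_equal(model$slope, rep(0.002, 10), tolerance = 1e-12)
  expect_equal(model$intercept, rep(0.01, 10), tolerance = 1e-12)
})

test_that("bright panels are excluded from visible bands only", {
  model <- fit_elm(panel_set())
  bands <- micasense_dual_bands()
  visible <- bands$center_nm < 700
  # default policy: panels above 22 % are saturated in the visible
  expect_equal(model$n_panels[visible], rep(5L, sum(visible)))
  expect_equal(model$n_panels[!visible], rep(9L, sum(!visible)))
  expect_equal(model$n_panels[model$band == "RE705"], 9L)
})

test_that("lowering the saturation threshold never adds panels", {
  thresholds <- c(0.65, 0.4, 0.22, 0.10)
  counts <- sapply(thresholds, function(th) {
    fit_elm(panel_set(), saturation_threshold = th)$n_panels
  })
  for (i in seq_len(nrow(counts))) {
    expect_true(all(diff(counts[i, ]) <= 0))
  }
  expect_error(
    fit_elm(panel_set(), saturation_threshold = 0.03),
    "fewer than 2 usable panels"
  )
})

test_that("noisy panels still recover the slope within 5 %", {
  set.seed(99)
  ok <- replicate(200, {
    m <- fit_elm(panel_set(noise_sd = 0.01))
    all(abs(m$slope / 0.002 - 1) < 0.05)
  })
  expect_true(all(ok))
})

test_that("the ELM round trip is exact and clipping is counted", {
  model <- fit_elm(panel_set(slope = 0.0015, intercept = 0.02))
  bands <- micasense_dual_bands()$band
  set.seed(2)
  refl <- matrix(runif(50 * 10, 0.01, 0.6), 50, 10, dimnames = list(NULL, bands))
  rad <- (refl - 0.02) / 0.0015
  pixels <- dplyr::bind_cols(
    tibble::tibble(x = rep(1:10, 5), y = rep(1:5, each = 10)),
    tibble::as_tibble(rad)
  )
  out <- apply_elm(pixels, model)
  expect_equal(as.matrix(out[, bands]), refl, tolerance = 1e-10)
  expect_equal(sum(attr(out, "clipped")), 0)

  ident <- model
  ident$slope <- rep(1, 10)
  ident$intercept <- rep(0, 10)
  pix2 <- pixels
  for (b in bands) pix2[[b]] <- refl[, b] # already in [0, 1]
  pix2[[bands[1]]] <- c(1.2, refl[-1, bands[1]])
  out2 <- apply_elm(pix2, ident)
  expect_equal(out2[[bands[1]]][1], 1.0)
  expect_equal(unname(attr(out2, "clipped")[bands[1]]), 1L)
  expect_equal(out2[[bands[2]]], pix2[[bands[2]]])
})

test_that("panel radiance extraction averages the eroded interior", {
  bands <- "NIR840"
  px <- expand.grid(x = 1:20, y = 1:20)
  val <- ifelse(px$x >= 6 & px$x <= 15 & px$y >= 6 & px$y <= 15, 100, 5)
  # contaminate the panel edge; erosion must ignore it
  val[px$x == 6 & px$y >= 6 & px$y <= 15] <- 50
  pixels <- tibble::tibble(x = px$x, y = px$y, NIR840 = val)
  rect <- tibble::tibble(
    panel_id = "p1", xmin = 6, xmax = 15, ymin = 6, ymax = 15,
    nominal_reflectance = 0.5
  )
  out <- extract_panel_radiance(pixels, rect, bands, erosion = 0.25)
  expect_equal(out$observed_radiance, 100)
  out0 <- extract_panel_radiance(pixels, rect, bands, erosion = 0)
  expect_lt(out0$observed_radiance, 100)
})
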