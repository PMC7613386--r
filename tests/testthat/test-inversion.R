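homog_pixels <- function(spec, nx = 6, ny = 6, bands = micasense_dual_bands()) {
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  vals <- matrix(spec, nrow(g), length(spec), byrow = TRUE,
    dimnames = list(NULL, bands$band))
  dplyr::bind_cols(tibble::tibble(x = g$x, y = g$y), tibble::as_tibble(vals))
}

test_that("a homogeneous plot inverts like its single pixel", {
  lut <- small_lut()
  spec <- lut$reflectance[42, ]
  pixels <- homog_pixels(spec)
  plots <- tibble::tibble(plot_id = "A", xmin = 1, xmax = 6, ymin = 1, ymax = 6)
  plot_est <- invert_plot_mean(pixels, plots, lut)
  pix_est <- invert_spectrum(spec, lut)
  expect_equal(plot_est$estimate, pix_est$estimate)
  expect_equal(plot_est$dispersion, pix_est$dispersion)
  expect_equal(unique(plot_est$n_pixels), 36L)
})

test_that("two equal pixel populations invert at their midpoint spectrum", {
  lut <- small_lut()
  s1 <- lut$reflectance[3, ]
  s2 <- lut$reflectance[301, ]
  pixels <- homog_pixels(s1, nx = 6, ny = 6)
  half <- pixels$y > 3
  for (b in lut$bands$band) pixels[[b]][half] <- s2[b]
  plots <- tibble::tibble(plot_id = "A", xmin = 1, xmax = 6, ymin = 1, ymax = 6)
  plot_est <- invert_plot_mean(pixels, plots, lut)
  mid_est <- invert_spectrum((s1 + s2) / 2, lut)
  expect_equal(plot_est$estimate, mid_est$estimate)
})

test_that("plots with distinct truths come back in the right order", {
  lut <- small_lut()
  truths <- c(1, 3.2, 5.8)
  specs <- lapply(truths, function(lai) {
    resample_to_bands(
      prosail(leaf_params(Cab = 42), canopy_params(LAI = lai, ALIA = 45, SZA = 30)),
      lut$bands
    )$value
  })
  pixels <- dplyr::bind_rows(lapply(seq_along(truths), function(i) {
    p <- homog_pixels(stats::setNames(specs[[i]], lut$bands$band), nx = 4, ny = 4)
    p$x <- p$x + (i - 1) * 4
    p
  }))
  plots <- tibble::tibble(
    plot_id = c("lo", "mid", "hi"),
    xmin = c(1, 5, 9), xmax = c(4, 8, 12), ymin = 1, ymax = 4
  )
  res <- invert_plot_mean(pixels, plots, lut)
  lai <- res$estimate[res$variable == "LAI"]
  expect_true(all(diff(lai) > 0))
})

test_that("empty plots are reported as missing, not as errors", {
  lut <- small_lut()
  pixels <- homog_pixels(lut$reflectance[5, ], nx = 4, ny = 4)
  plots <- tibble::tibble(
    plot_id = c("in", "out"),
    xmin = c(1, 50), xmax = c(4, 60), ymin = c(1, 50), ymax = c(4, 60)
  )
  res <- invert_plot_mean(pixels, plots, lut)
  expect_true(all(is.na(res$estimate[res$plot_id == "out"])))
  expect_true(all(res$n_pixels[res$plot_id == "out"] == 0))
  expect_true(all(is.finite(res$estimate[res$plot_id == "in"])))
})

test_that("block resampling averages full blocks before inversion", {
  lut <- small_lut()
  set.seed(15)
  # 6 x 6 native pixels with per-pixel jitter, one 0.09 m block from 0.015 m
  base <- lut$reflectance[20, ]
  pixels <- homog_pixels(base)
  for (b in lut$bands$band) {
    pixels[[b]] <- pixels[[b]] * (1 + runif(36, -0.05, 0.05))
  }
  out <- invert_pixelwise(pixels, lut, gsd = 0.015, target_gsd = 0.09)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_pixels, 36)
  mean_spec <- colMeans(as.matrix(pixels[, lut$bands$band]))
  direct <- invert_spectrum(mean_spec, lut)
  expect_equal(out$LAI, direct$estimate[direct$variable == "LAI"])
  expect_equal(out$Cab, direct$estimate[direct$variable == "Cab"])
  expect_error(invert_pixelwise(pixels, lut, gsd = 0.09, target_gsd = 0.015),
    "smaller")
  expect_error(invert_pixelwise(pixels, lut, gsd = 0.04, target_gsd = 0.09),
    "integer multiple")
})

test_that("a constant raster maps to constant parameter fields", {
  lut <- small_lut()
  spec <- lut$reflectance[88, ]
  pixels <- homog_pixels(spec, nx = 4, ny = 2)
  out <- invert_pixelwise(pixels, lut, gsd = 0.015)
  direct <- invert_spectrum(spec, lut)
  expect_equal(nrow(out), 8)
  expect_equal(unique(out$LAI), direct$estimate[direct$variable == "LAI"])
  expect_equal(unique(out$CCC), direct$estimate[direct$variable == "CCC"])
  expect_equal(unique(out$Cab_sd), direct$dispersion[direct$variable == "Cab"])
})

test_that("a chlorophyll gradient is retrieved monotonically", {
  lut <- small_lut()
  cabs <- seq(25, 60, length.out = 6)
  specs <- vapply(cabs, function(cab) {
    resample_to_bands(
      prosail(leaf_params(Cab = cab), canopy_params(LAI = 3, ALIA = 45, SZA = 30)),
      lut$bands
    )$value
  }, numeric(10))
  pixels <- dplyr::bind_cols(
    tibble::tibble(x = 1:6, y = 1L),
    tibble::as_tibble(t(specs), .name_repair = ~ lut$bands$band)
  )
  out <- invert_pixelwise(pixels, lut, gsd = 0.015)
  expect_true(all(diff(out$Cab[order(out$x)]) > 0))
})

test_that("plot aggregation of parameter maps matches a pixel loop", {
  lut <- small_lut()
  set.seed(44)
  g <- expand.grid(x = 1:8, y = 1:4)
  maps <- tibble::tibble(
    x = g$x, y = g$y,
    LAI = runif(32, 0, 6), Cab = runif(32, 20, 60)
  )
  maps$CCC <- maps$LAI * maps$Cab
  maps$LAI[3] <- NA # a failed pixel
  plots <- tibble::tibble(
    plot_id = c("L", "R"),
    xmin = c(1, 5), xmax = c(4, 8), ymin = 1, ymax = 4
  )
  res <- aggregate_plots(maps, plots)
  for (pid in plots$plot_id) {
    sel <- maps$x >= plots$xmin[plots$plot_id == pid] &
      maps$x <= plots$xmax[plots$plot_id == pid]
    for (v in c("LAI", "Cab", "CCC")) {
      manual <- mean(maps[[v]][sel], na.rm = TRUE)
      expect_equal(res$estimate[res$plot_id == pid & res$variable == v], manual)
    }
  }
  expect_equal(res$n_pixels[res$plot_id == "L" & res$variable == "LAI"], 15L)
  # half-masked plot: mean over the valid half only
  mask <- tibble::tibble(x = g$x, y = g$y, retained = g$y <= 2)
  res2 <- aggregate_plots(maps, plots, mask = mask)
  sel <- maps$x <= 4 & maps$y <= 2
  expect_equal(
    res2$estimate[res2$plot_id == "L" & res2$variable == "Cab"],
    mean(maps$Cab[sel])
  )
})
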