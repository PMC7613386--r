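test_that("the default configuration reproduces the trial layout", {
  cfg <- scene_config()
  expect_equal(cfg$plots_nx * cfg$plots_ny, 84)
  expect_equal(cfg$plot_size, 3)
  expect_equal(cfg$gsd, 0.015)
  expect_equal(cfg$plot_px, 200) # 3 m / 0.015 m
  expect_equal(length(cfg$panel_reflectances), 9)
  expect_equal(range(cfg$panel_reflectances), c(0.02, 0.63))
  expect_error(scene_config(plot_size = 0.9, gsd = 0.3, plots_nx = 2), NA)
  expect_error(scene_config(plot_size = 1, gsd = 0.15), "integer")
  expect_error(
    scene_config(canopy_fraction = c(sweet = 0.9, silage = 0.9),
      shadow_fraction = c(sweet = 0.2, silage = 0.2)),
    "sum <= 1"
  )
})

test_that("noiseless homogeneous plots render their truth spectra exactly", {
  cfg <- tiny_scene_config(
    canopy_fraction = c(sweet = 1, silage = 1),
    shadow_fraction = c(sweet = 0, silage = 0)
  )
  scene <- generate_scene(cfg)
  for (i in sample(nrow(scene$truth), 3)) {
    tr <- scene$truth[i, ]
    expected <- resample_to_bands(
      prosail(
        leaf_params(N = tr$N, Cab = tr$Cab, Cm = tr$Cm),
        canopy_params(LAI = tr$LAI, ALIA = tr$ALIA, hot = tr$hot,
          SZA = cfg$sza, soil = soil_spectrum(tr$soil))
      ),
      cfg$bands
    )$value
    px <- scene$pixels[scene$pixels$plot_id == tr$plot_id, ]
    expect_true(all(px$label == "vegetation"))
    for (j in seq_along(cfg$bands$band)) {
      expect_equal(unique(px[[cfg$bands$band[j]]]), expected[j])
    }
  }
})

test_that("pixel labels partition every plot", {
  scene <- generate_scene(tiny_scene_config())
  plot_px <- scene$pixels[scene$pixels$label != "panel", ]
  counts <- table(plot_px$plot_id)
  expect_true(all(counts == scene$config$plot_px^2))
  expect_true(all(plot_px$label %in% c("vegetation", "soil", "shadow")))
  # silage rows carry more shadow than sweet rows by construction
  sh <- tapply(plot_px$label == "shadow", scene$pixels$plot_id[scene$pixels$label != "panel"], mean)
  types <- scene$truth$maize_type[match(names(sh), scene$truth$plot_id)]
  expect_gt(mean(sh[types == "silage"]), mean(sh[types == "sweet"]))
})

test_that("the same configuration regenerates the scene bit-identically", {
  cfg <- tiny_scene_config(noise_sd = 0.005)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$pixels, s2$pixels)
  expect_identical(s1$truth, s2$truth)
  g1 <- generate_ground_truth(s1, 2, 0.3, seed = 7)
  g2 <- generate_ground_truth(s2, 2, 0.3, seed = 7)
  expect_identical(g1, g2)
})

test_that("ground truth round-trips the SPAD calibration without noise", {
  scene <- generate_scene(tiny_scene_config())
  gt <- generate_ground_truth(scene, 0, 0, seed = 1)
  expect_equal(spad_to_lcc(gt$spad_mean), scene$truth$Cab, tolerance = 1e-9)
  expect_equal(gt$LAI, scene$truth$LAI)
  expect_equal(gt$CCC, gt$LCC * gt$LAI)
})

test_that("ground-truth noise has the configured spread", {
  cfg <- scene_config(
    plots_nx = 20, plots_ny = 20, plot_size = 0.2, gsd = 0.1,
    silage_rows = 11:20, noise_sd = 0, seed = 2
  )
  scene <- generate_scene(cfg)
  gt <- generate_ground_truth(scene, spad_noise_sd = 2, lai_noise_sd = 0.3, seed = 8)
  spad_err <- gt$spad_mean - lcc_to_spad(scene$truth$Cab)
  expect_lt(abs(sd(spad_err) / 2 - 1), 0.1)
  lai_err <- gt$lai_mean - scene$truth$LAI
  expect_lt(abs(sd(lai_err) / 0.3 - 1), 0.1)
})

test_that("panels render flat at their nominal reflectance", {
  scene <- generate_scene(tiny_scene_config())
  bands <- scene$bands$band
  panel_px <- scene$pixels[scene$pixels$label == "panel", ]
  for (i in seq_len(nrow(scene$panels))) {
    p <- scene$panels[i, ]
    px <- panel_px[panel_px$plot_id == p$panel_id, ]
    for (b in bands) expect_equal(unique(px[[b]]), p$nominal_reflectance)
  }
  # panel extraction + ELM on the rendered panels reproduces an affine map
  radiance <- scene$pixels
  for (b in bands) radiance[[b]] <- (radiance[[b]] - 0.01) / 0.002
  panels <- extract_panel_radiance(
    radiance, scene$panels, bands,
    erosion = 0.25
  )
  model <- fit_elm(panels, scene$bands)
  expect_equal(model$slope, rep(0.002, 10), tolerance = 1e-9)
  expect_equal(model$intercept, rep(0.01, 10), tolerance = 1e-9)
})

test_that("both aggregation strategies coincide on a homogeneous scene", {
  cfg <- scene_config(
    plots_nx = 2, plots_ny = 2, plot_size = 0.9, gsd = 0.09,
    silage_rows = 2, noise_sd = 0,
    canopy_fraction = c(sweet = 1, silage = 1),
    shadow_fraction = c(sweet = 0, silage = 0), seed = 31
  )
  e2e <- run_end_to_end(cfg,
    lut_n = 400, lut_noise_sd = 0,
    pixel_target_gsd = 0.09, seed = 13
  )
  res <- e2e$results
  wide <- tidyr::pivot_wider(
    res[, c("plot_id", "variable", "approach", "estimate")],
    names_from = "approach", values_from = "estimate"
  )
  expect_equal(wide$mean, wide$pixel)
  expect_s3_class(tidy(e2e), "tbl_df")
  expect_true(all(c("rmse", "rrmse", "r2") %in% names(tidy(e2e))))
  expect_equal(glance(e2e)$lut_entries, 400)
  expect_s3_class(autoplot(e2e), "ggplot")
  expect_s3_class(plot_scene(e2e$scene), "ggplot")
  expect_s3_class(plot_spectrum(prospect5(leaf_params())), "ggplot")
})
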