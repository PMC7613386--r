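#' Configuration of a synthetic maize trial scene
#'
#' Describes a fully synthetic emulation of the field study layout: a grid
#' of square plots (default 12 x 7 = 84 plots of 3 x 3 m at 0.015 m ground
#' sampling distance), two maize types with contrasting leaf angles and row
#' shading (sweet: denser, more planophile; silage: more erect, more
#' within-row shadow), soil background in alternating crop-row stripes,
#' shadow as a multiplicative darkening of the soil spectrum, a strip of
#' nine calibration panels from 2 % to 63 % reflectance, and additive
#' Gaussian sensor noise per band.
#'
#' Per-plot truth values (LAI, leaf chlorophyll, leaf angle) are drawn
#' uniformly from ranges typical of the field campaign (LAI 0.5--5.5,
#' chlorophyll 30--55 ug/cm^2) and lie inside the default retrieval prior.
#'
#' @param plots_nx,plots_ny Plot grid dimensions (default 12 x 7).
#' @param plot_size Plot side length, metres (default 3).
#' @param gsd Ground sampling distance, metres (default 0.015);
#'   `plot_size / gsd` must be an integer.
#' @param silage_rows Which plot-grid rows carry silage maize (default the
#'   last three).
#' @param lai_range,cab_range Truth ranges for LAI and leaf chlorophyll.
#' @param alia_range_sweet,alia_range_silage Leaf-angle truth ranges per
#'   maize type, degrees.
#' @param canopy_fraction,shadow_fraction Named numeric vectors (`sweet`,
#'   `silage`): fraction of plot pixels that are sunlit vegetation /
#'   shadow; the remainder is sunlit soil. Canopy + shadow must not exceed
#'   1.
#' @param row_period_m Crop row repeat distance, metres (default 0.75).
#' @param shadow_darkening Multiplicative factor applied to the underlying
#'   spectrum in shadow (default 0.25).
#' @param noise_sd Additive Gaussian sensor noise per band in reflectance
#'   units (default 0.005).
#' @param panel_reflectances Nominal reflectances of the calibration
#'   panels (default nine values from 0.02 to 0.63).
#' @param panel_size_px Panel side length in pixels.
#' @param sza Sun zenith angle of the emulated acquisition, degrees.
#' @param leaf_n,leaf_cm,leaf_hot Truth values for leaf structure, dry
#'   matter and hot spot (inside the default prior).
#' @param bands Band-set tibble.
#' @param seed Integer seed; the scene is bit-reproducible given the
#'   config.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(plots_nx = 12, plots_ny = 7, plot_size = 3,
                         gsd = 0.015,
                         silage_rows = (plots_ny - 2):plots_ny,
                         lai_range = c(0.5, 5.5), cab_range = c(30, 55),
                         alia_range_sweet = c(30, 50),
                         alia_range_silage = c(45, 65),
                         canopy_fraction = c(sweet = 0.65, silage = 0.55),
                         shadow_fraction = c(sweet = 0.08, silage = 0.20),
                         row_period_m = 0.75,
                         shadow_darkening = 0.25,
                         noise_sd = 0.005,
                         panel_reflectances = c(
                           0.02, 0.05, 0.09, 0.14, 0.22,
                           0.30, 0.39, 0.50, 0.63
                         ),
                         panel_size_px = 20,
                         sza = 30,
                         leaf_n = 1.5, leaf_cm = 0.0055, leaf_hot = 0.1,
                         bands = micasense_dual_bands(),
                         seed = 1) {
  pps <- plot_size / gsd
  if (abs(pps - round(pps)) > 1e-9) {
    rlang::abort("plot_size / gsd must be an integer number of pixels")
  }
  for (ty in c("sweet", "silage")) {
    cf <- canopy_fraction[[ty]]
    sf <- shadow_fraction[[ty]]
    if (cf < 0 || sf < 0 || cf + sf > 1) {
      rlang::abort("canopy and shadow fractions must be in [0,1] with sum <= 1")
    }
  }
  structure(
    list(
      plots_nx = plots_nx, plots_ny = plots_ny, plot_size = plot_size,
      gsd = gsd, plot_px = as.integer(round(pps)),
      silage_rows = silage_rows,
      lai_range = lai_range, cab_range = cab_range,
      alia_range_sweet = alia_range_sweet,
      alia_range_silage = alia_range_silage,
      canopy_fraction = canopy_fraction, shadow_fraction = shadow_fraction,
      row_period_m = row_period_m,
      shadow_darkening = shadow_darkening, noise_sd = noise_sd,
      panel_reflectances = panel_reflectances,
      panel_size_px = panel_size_px,
      sza = sza, leaf_n = leaf_n, leaf_cm = leaf_cm, leaf_hot = leaf_hot,
      bands = bands, seed = seed
    ),
    class = "scene_config"
  )
}

#' Generate a synthetic study scene
#'
#' Renders the configured trial as a pixel table: every vegetation pixel of
#' a plot carries the band reflectance simulated from that plot's truth
#' parameters (forward leaf-canopy model, resampled to the sensor bands),
#' soil pixels carry the plot's soil spectrum, shadow pixels the soil
#' spectrum scaled by the darkening factor, and calibration panels are
#' homogeneous squares of their nominal reflectance. Additive Gaussian
#' sensor noise is applied to all pixels. Deterministic under the config's
#' seed.
#'
#' @param cfg A [scene_config()].
#' @return A list of class `synthetic_scene` with elements `pixels`
#'   (tibble: `x`, `y`, `plot_id`, `label`, band columns), `truth` (per-plot
#'   parameters), `plots` and `panels` (rectangles), `bands` and `config`.
#' @export
generate_scene <- function(cfg = scene_config()) {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(cfg$seed)
  pps <- cfg$plot_px
  n_plots <- cfg$plots_nx * cfg$plots_ny

  # per-plot truth -----------------------------------------------------
  grid <- expand.grid(col = seq_len(cfg$plots_nx), row = seq_len(cfg$plots_ny))
  maize_type <- ifelse(grid$row %in% cfg$silage_rows, "silage", "sweet")
  alia <- numeric(n_plots)
  for (i in seq_len(n_plots)) {
    rng <- if (maize_type[i] == "silage") cfg$alia_range_silage else cfg$alia_range_sweet
    alia[i] <- stats::runif(1, rng[1], rng[2])
  }
  truth <- tibble::tibble(
    plot_id = sprintf("P%03d", seq_len(n_plots)),
    row = grid$row, col = grid$col,
    maize_type = maize_type,
    LAI = stats::runif(n_plots, cfg$lai_range[1], cfg$lai_range[2]),
    Cab = stats::runif(n_plots, cfg$cab_range[1], cfg$cab_range[2]),
    ALIA = alia,
    soil = sample(c("dry", "wet"), n_plots, replace = TRUE),
    N = cfg$leaf_n, Cm = cfg$leaf_cm, hot = cfg$leaf_hot
  )
  truth$LCC <- truth$Cab
  truth$CCC <- truth$Cab * truth$LAI

  plots <- tibble::tibble(
    plot_id = truth$plot_id,
    maize_type = truth$maize_type,
    xmin = (truth$col - 1) * pps + 1, xmax = truth$col * pps,
    ymin = (truth$row - 1) * pps + 1, ymax = truth$row * pps
  )

  # band spectra per plot ----------------------------------------------
  band_names <- cfg$bands$band
  soil_bands <- lapply(
    list(dry = soil_spectrum("dry"), wet = soil_spectrum("wet")),
    function(s) resample_to_bands(s, cfg$bands)$value
  )
  veg_bands <- matrix(NA_real_, n_plots, length(band_names))
  for (i in seq_len(n_plots)) {
    leaf <- leaf_params(
      N = truth$N[i], Cab = truth$Cab[i], Cbp = 0,
      Cm = truth$Cm[i]
    )
    canopy <- canopy_params(
      LAI = truth$LAI[i], ALIA = truth$ALIA[i], hot = truth$hot[i],
      SZA = cfg$sza, soil = soil_spectrum(truth$soil[i])
    )
    veg_bands[i, ] <- resample_to_bands(prosail(leaf, canopy), cfg$bands)$value
  }

  # pixel labels: crop-row stripes of vegetation | shadow | soil --------
  period <- max(2L, as.integer(round(cfg$row_period_m / cfg$gsd)))
  pixel_list <- vector("list", n_plots + 1L)
  for (i in seq_len(n_plots)) {
    ty <- truth$maize_type[i]
    w_veg <- round(cfg$canopy_fraction[[ty]] * period)
    w_shadow <- round(cfg$shadow_fraction[[ty]] * period)
    px <- expand.grid(
      x = plots$xmin[i]:plots$xmax[i],
      y = plots$ymin[i]:plots$ymax[i]
    )
    phase <- (px$y - plots$ymin[i]) %% period
    label <- ifelse(phase < w_veg, "vegetation",
      ifelse(phase < w_veg + w_shadow, "shadow", "soil")
    )
    soil_vec <- soil_bands[[truth$soil[i]]]
    base <- matrix(NA_real_, nrow(px), length(band_names))
    fill <- function(base, sel, vals) {
      if (any(sel)) {
        base[sel, ] <- matrix(vals, sum(sel), length(vals), byrow = TRUE)
      }
      base
    }
    base <- fill(base, label == "vegetation", veg_bands[i, ])
    base <- fill(base, label == "soil", soil_vec)
    base <- fill(base, label == "shadow", soil_vec * cfg$shadow_darkening)
    colnames(base) <- band_names
    pixel_list[[i]] <- dplyr::bind_cols(
      tibble::tibble(
        x = px$x, y = px$y, plot_id = truth$plot_id[i], label = label
      ),
      tibble::as_tibble(base)
    )
  }

  # calibration panel strip below the plot grid ------------------------
  ps <- cfg$panel_size_px
  gap <- ps
  y0 <- cfg$plots_ny * pps + gap
  panels <- tibble::tibble(
    panel_id = sprintf("panel%02d", seq_along(cfg$panel_reflectances)),
    nominal_reflectance = cfg$panel_reflectances,
    xmin = (seq_along(cfg$panel_reflectances) - 1) * 2 * ps + 1,
    xmax = (seq_along(cfg$panel_reflectances) - 1) * 2 * ps + ps,
    ymin = y0 + 1, ymax = y0 + ps
  )
  panel_px <- lapply(seq_len(nrow(panels)), function(i) {
    px <- expand.grid(x = panels$xmin[i]:panels$xmax[i], y = panels$ymin[i]:panels$ymax[i])
    base <- matrix(panels$nominal_reflectance[i], nrow(px), length(band_names))
    colnames(base) <- band_names
    dplyr::bind_cols(
      tibble::tibble(
        x = px$x, y = px$y, plot_id = panels$panel_id[i], label = "panel"
      ),
      tibble::as_tibble(base)
    )
  })
  pixel_list[[n_plots + 1L]] <- dplyr::bind_rows(panel_px)
  pixels <- dplyr::bind_rows(pixel_list)

  # sensor noise --------------------------------------------------------
  if (cfg$noise_sd > 0) {
    for (b in band_names) {
      pixels[[b]] <- pmin(pmax(
        pixels[[b]] + stats::rnorm(nrow(pixels), 0, cfg$noise_sd), 0
      ), 1)
    }
  }

  structure(
    list(
      pixels = pixels, truth = truth, plots = plots, panels = panels,
      bands = cfg$bands, config = cfg
    ),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d plots (%d px each), %d panels, %d pixels, seed %d\n",
    nrow(x$truth), x$config$plot_px^2, nrow(x$panels), nrow(x$pixels),
    x$config$seed
  ))
  invisible(x)
}

#' Simulated plot-level ground truth measurements
#'
#' Emulates the field sampling: per plot, a mean SPAD reading obtained by
#' inverting the SPAD-to-chlorophyll calibration at the plot's truth
#' chlorophyll (plus Gaussian measurement noise in SPAD units), and a mean
#' LAI reading (truth plus Gaussian noise). Derived columns `LCC`
#' (calibration applied to the noisy SPAD), `LAI` and `CCC` are included,
#' ready for [evaluate()].
#'
#' @param scene A [generate_scene()] result.
#' @param spad_noise_sd Noise sd in SPAD units (default 0).
#' @param lai_noise_sd Noise sd in LAI units (default 0).
#' @param seed Integer seed.
#' @param date Date label attached to every row.
#' @return A tibble `plot_id`, `date`, `maize_type`, `spad_mean`,
#'   `lai_mean`, `LCC`, `LAI`, `CCC`.
#' @export
generate_ground_truth <- function(scene, spad_noise_sd = 0, lai_noise_sd = 0,
                                  seed = 1, date = "synthetic") {
  stopifnot(inherits(scene, "synthetic_scene"))
  set.seed(seed)
  tr <- scene$truth
  spad <- lcc_to_spad(tr$Cab) + stats::rnorm(nrow(tr), 0, spad_noise_sd)
  spad <- pmax(spad, 0)
  lai <- pmax(tr$LAI + stats::rnorm(nrow(tr), 0, lai_noise_sd), 0)
  lcc <- spad_to_lcc(spad)
  tibble::tibble(
    plot_id = tr$plot_id, date = date, maize_type = tr$maize_type,
    spad_mean = spad, lai_mean = lai,
    LCC = lcc, LAI = lai, CCC = lcc * lai
  )
}

#' Run the full synthetic retrieval study end to end
#'
#' Chains the whole pipeline on a synthetic scene: vegetation masking, LUT
#' construction from a chlorophyll prior tied to the (simulated) field
#' statistics, inversion under both aggregation strategies, and evaluation
#' against the generated ground truth.
#'
#' The mean-reflectance approach inverts one spectrum per plot: for leaf
#' chlorophyll the plot mean is computed over hue-masked (sunlit green)
#' pixels; for LAI and canopy chlorophyll over all plot pixels. The
#' pixel-based approach inverts block-averaged pixels at `pixel_target_gsd`
#' for LAI/CCC and hue-masked native pixels for LCC, then averages the
#' retrieved maps per plot.
#'
#' @param cfg A [scene_config()].
#' @param space Optional [param_space()]; by default one is derived from
#'   the simulated ground truth (chlorophyll prior mean/sd from the plot
#'   LCC values, sd floored at 5 ug/cm^2) with the scene's sun angle.
#' @param lut_n LUT size (default 10000).
#' @param lut_noise_sd Relative noise applied to the LUT (default 0.02; 0
#'   for a noiseless experiment).
#' @param pixel_target_gsd Coarser grid for the pixel-based LAI/CCC maps
#'   (default 0.09 m).
#' @param spad_noise_sd,lai_noise_sd Ground-truth measurement noise.
#' @param approaches Which aggregation strategies to run.
#' @param top_fraction Fraction of best LUT solutions averaged.
#' @param seed Seed for LUT sampling and noise (the scene uses the config
#'   seed).
#' @return A list of class `canopy_e2e` with `scene`, `ground_truth`,
#'   `lut`, `results` (per-plot estimates with an `approach` column) and
#'   `metrics` (evaluation table per approach, pooled and per maize type).
#' @export
run_end_to_end <- function(cfg = scene_config(), space = NULL,
                           lut_n = 10000, lut_noise_sd = 0.02,
                           pixel_target_gsd = 0.09,
                           spad_noise_sd = 0, lai_noise_sd = 0,
                           approaches = c("mean", "pixel"),
                           top_fraction = 0.05, seed = 1) {
  approaches <- match.arg(approaches, several.ok = TRUE)
  scene <- generate_scene(cfg)
  gt <- generate_ground_truth(scene, spad_noise_sd, lai_noise_sd, seed = seed + 1)
  if (is.null(space)) {
    space <- param_space(
      date = "synthetic", sza = cfg$sza,
      cab_mean = mean(gt$LCC), cab_sd = max(stats::sd(gt$LCC), 5)
    )
  }
  lut <- build_lut(space, cfg$bands, n = lut_n, seed = seed)
  lut <- add_noise(lut, relative_sd = lut_noise_sd, seed = seed + 2)
  mask <- hue_mask(scene$pixels)

  results <- list()
  if ("mean" %in% approaches) {
    unmasked <- invert_plot_mean(scene$pixels, scene$plots, lut,
      top_fraction = top_fraction
    )
    masked <- invert_plot_mean(scene$pixels, scene$plots, lut,
      mask = mask, top_fraction = top_fraction
    )
    res <- dplyr::bind_rows(
      unmasked[unmasked$variable %in% c("LAI", "CCC"), ],
      masked[masked$variable == "Cab", ]
    )
    res$approach <- "mean"
    results$mean <- res
  }
  if ("pixel" %in% approaches) {
    coarse <- invert_pixelwise(scene$pixels, lut,
      gsd = cfg$gsd, target_gsd = pixel_target_gsd,
      top_fraction = top_fraction
    )
    agg_coarse <- aggregate_plots(coarse, scene$plots,
      variables = c("LAI", "CCC")
    )
    native <- invert_pixelwise(apply_mask(scene$pixels, mask, cfg$bands$band),
      lut,
      gsd = cfg$gsd, top_fraction = top_fraction
    )
    agg_native <- aggregate_plots(native, scene$plots, variables = "Cab")
    res <- dplyr::bind_rows(agg_coarse, agg_native)
    res$dispersion <- NA_real_
    res$approach <- "pixel"
    results$pixel <- res
  }
  results <- dplyr::bind_rows(results)

  metrics <- dplyr::bind_rows(lapply(split(results, results$approach), function(r) {
    pooled <- evaluate(r, gt)
    pooled$maize_type <- "both"
    by_type <- evaluate(r, gt, group_by = "maize_type")
    out <- dplyr::bind_rows(pooled, by_type)
    out$approach <- r$approach[1]
    out
  }))

  structure(
    list(
      scene = scene, ground_truth = gt, lut = lut,
      results = results, metrics = metrics
    ),
    class = "canopy_e2e"
  )
}
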