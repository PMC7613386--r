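# Shared fixtures, built lazily so cheap test files stay cheap.

# A small LUT over the default parameter space, reused across files.
small_lut <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_lut(
        param_space(sza = 30, cab_mean = 42, cab_sd = 8),
        n = 400, seed = 101
      )
    }
    cache
  }
})

# A compact synthetic scene: 3 x 2 plots of 1.5 m at 0.05 m GSD (30 x 30 px
# per plot), one silage row, no sensor noise unless asked.
tiny_scene_config <- function(noise_sd = 0, seed = 11, ...) {
  scene_config(
    plots_nx = 3, plots_ny = 2, plot_size = 1.5, gsd = 0.05,
    silage_rows = 2, noise_sd = noise_sd, seed = seed, ...
  )
}

# Run the reference Python transcription of the radiative transfer model on
# a data frame of parameter sets; returns the long oracle table.
run_rtm_oracle <- function(params, soil = soil_spectrum("dry")) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  stopifnot(nzchar(py))
  script <- system.file("oracle", "prosail_reference.py", package = "canopylut")
  dir <- tempfile("oracle")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  const_path <- file.path(dir, "const.csv")
  params_path <- file.path(dir, "params.csv")
  soil_path <- file.path(dir, "soil.csv")
  out_path <- file.path(dir, "out.csv")
  utils::write.csv(leaf_optical_constants(), const_path, row.names = FALSE)
  utils::write.csv(params, params_path, row.names = FALSE)
  utils::write.csv(
    data.frame(wavelength = soil$wavelength, value = soil$value),
    soil_path,
    row.names = FALSE
  )
  status <- system2(py, c(script, const_path, params_path, soil_path, out_path))
  stopifnot(status == 0)
  utils::read.csv(out_path)
}

# Random valid parameter sets for oracle comparisons.
random_rtm_params <- function(n, seed) {
  set.seed(seed)
  data.frame(
    N = runif(n, 1.2, 1.8), Cab = runif(n, 0, 70), Ccx = runif(n, 0, 15),
    Cbp = runif(n, 0, 0.5), Cw = runif(n, 0.005, 0.03),
    Cm = runif(n, 0.004, 0.0075),
    LAI = runif(n, 0.1, 7), ALIA = sample(20:70, n, replace = TRUE),
    hot = runif(n, 0.01, 0.5),
    SZA = runif(n, 20, 50), OZA = 0, rAA = 0
  )
}
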