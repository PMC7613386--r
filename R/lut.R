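#' Define the model parameter space for one acquisition date
#'
#' Collects, for every state variable of the coupled leaf-canopy model, the
#' sampling distribution used to build that date's look-up table:
#'
#' * `N` -- uniform on `n_bounds` (default 1.2--1.8, maize literature range);
#' * `Cab` -- Gaussian with `cab_mean`/`cab_sd`, truncated to `cab_bounds`
#'   (default 0--70 ug/cm^2); location and scale should reflect the field
#'   statistics of the date being emulated;
#' * `Ccx`, `Cw` -- fixed constants (defaults 8 ug/cm^2 and 0.015 g/cm^2);
#' * `Cbp` -- fixed at 0 early season, uniform 0--0.5 when `browning = TRUE`
#'   (senescent dates);
#' * `Cm` -- uniform on `cm_bounds` (default 0.004--0.0075 g/cm^2);
#' * `LAI` -- uniform on `lai_bounds` (default 0--7);
#' * `ALIA` -- integer grid from `alia_bounds[1]` to `alia_bounds[2]` in
#'   steps of `alia_step` (default 20--70, step 1);
#' * `hot` -- uniform on `hot_bounds` (default 0.01--0.5; the narrower
#'   literature range 0--0.2 can be selected by passing it here).
#'
#' Acquisition geometry is fixed per date (`sza`, nadir view `oza = 0`,
#' `raa = 0`) and each table entry draws its soil background uniformly from
#' the `soil` list (default: the synthetic dry and wet curves).
#'
#' @param date Label for the acquisition date.
#' @param sza Sun zenith angle of the date, degrees.
#' @param cab_mean,cab_sd Location/scale of the Gaussian chlorophyll prior.
#' @param cab_bounds,n_bounds,cm_bounds,lai_bounds,alia_bounds,hot_bounds
#'   Numeric length-2 ranges.
#' @param browning If `TRUE`, brown pigment is uniform on `cbp_bounds`
#'   instead of fixed at 0.
#' @param cbp_bounds Brown-pigment range used when `browning = TRUE`.
#' @param ccx,cw Fixed carotenoid content and water thickness.
#' @param alia_step Step of the leaf-angle grid, degrees.
#' @param oza,raa Observer zenith / relative azimuth angles, degrees.
#' @param soil Named list of soil spectra (tibbles `wavelength`, `value`).
#' @return A list of class `param_space` with elements `variables` (one row
#'   per model variable), `soil`, `date` and `geometry`.
#' @export
#' @examples
#' sp <- param_space(date = "2021-06-23", sza = 27.8, cab_mean = 45, cab_sd = 6)
#' sp$variables
param_space <- function(date = "synthetic", sza = 30,
                        cab_mean = 45, cab_sd = 10, cab_bounds = c(0, 70),
                        n_bounds = c(1.2, 1.8),
                        browning = FALSE, cbp_bounds = c(0, 0.5),
                        cm_bounds = c(0.004, 0.0075),
                        ccx = 8, cw = 0.015,
                        lai_bounds = c(0, 7),
                        alia_bounds = c(20, 70), alia_step = 1,
                        hot_bounds = c(0.01, 0.5),
                        oza = 0, raa = 0,
                        soil = list(
                          dry = soil_spectrum("dry"),
                          wet = soil_spectrum("wet")
                        )) {
  row <- function(variable, dist, min = NA, max = NA, mean = NA, sd = NA,
                  step = NA, value = NA) {
    tibble::tibble(
      variable = variable, dist = dist, min = min, max = max,
      mean = mean, sd = sd, step = step, value = value
    )
  }
  variables <- dplyr::bind_rows(
    row("N", "uniform", min = n_bounds[1], max = n_bounds[2]),
    row("Cab", "gaussian",
      min = cab_bounds[1], max = cab_bounds[2],
      mean = cab_mean, sd = cab_sd
    ),
    row("Ccx", "fixed", value = ccx),
    if (browning) {
      row("Cbp", "uniform", min = cbp_bounds[1], max = cbp_bounds[2])
    } else {
      row("Cbp", "fixed", value = 0)
    },
    row("Cw", "fixed", value = cw),
    row("Cm", "uniform", min = cm_bounds[1], max = cm_bounds[2]),
    row("LAI", "uniform", min = lai_bounds[1], max = lai_bounds[2]),
    row("ALIA", "integer",
      min = alia_bounds[1], max = alia_bounds[2],
      step = alia_step
    ),
    row("hot", "uniform", min = hot_bounds[1], max = hot_bounds[2])
  )
  space <- structure(
    list(
      variables = variables, soil = soil, date = date,
      geometry = list(SZA = sza, OZA = oza, rAA = raa)
    ),
    class = "param_space"
  )
  validate_param_space(space)
  space
}

#' @rdname param_space
#' @param space A `param_space` object.
#' @export
validate_param_space <- function(space) {
  v <- space$variables
  required <- c("N", "Cab", "Ccx", "Cbp", "Cw", "Cm", "LAI", "ALIA", "hot")
  if (!identical(sort(v$variable), sort(required)) || anyDuplicated(v$variable)) {
    rlang::abort("parameter space must contain each model variable exactly once")
  }
  for (i in seq_len(nrow(v))) {
    if (v$dist[i] %in% c("uniform", "gaussian", "integer")) {
      if (!(v$min[i] < v$max[i])) {
        rlang::abort(sprintf(
          "variable `%s`: zero-width or inverted bounds for a %s distribution",
          v$variable[i], v$dist[i]
        ))
      }
    }
    if (v$dist[i] == "gaussian" && (!is.finite(v$sd[i]) || v$sd[i] <= 0)) {
      rlang::abort(sprintf("variable `%s`: gaussian sd must be > 0", v$variable[i]))
    }
  }
  if (length(space$soil) < 1) rlang::abort("at least one soil spectrum is required")
  invisible(space)
}

#' Latin hypercube sample of a parameter space
#'
#' Draws `n` stratified samples: each non-fixed variable's `n` values occupy
#' the `n` equal-probability strata of its marginal distribution exactly
#' once (the Latin hypercube property). Uniform variables are mapped
#' linearly, Gaussian variables through the inverse CDF of the truncated
#' normal, and integer-grid variables (leaf angle) onto their grid with
#' equal mass per grid value. The soil background is an additional
#' stratified categorical draw over the configured soil list.
#'
#' @param space A [param_space()].
#' @param n Number of samples.
#' @param seed Integer seed; the sample is reproducible given
#'   (`space`, `n`, `seed`).
#' @return A tibble with `n` rows, one column per model variable plus
#'   `soil` (name of the soil spectrum).
#' @export
sample_param_space <- function(space, n, seed = 1) {
  validate_param_space(space)
  stopifnot(n >= 1)
  v <- space$variables
  free <- which(v$dist != "fixed")
  set.seed(seed)
  u <- lhs::randomLHS(n, length(free) + 1L)
  out <- vector("list", nrow(v))
  names(out) <- v$variable
  ui <- 0L
  for (i in seq_len(nrow(v))) {
    if (v$dist[i] == "fixed") {
      out[[i]] <- rep(v$value[i], n)
      next
    }
    ui <- ui + 1L
    p <- u[, ui]
    out[[i]] <- switch(v$dist[i],
      uniform = v$min[i] + p * (v$max[i] - v$min[i]),
      gaussian = {
        plo <- stats::pnorm(v$min[i], v$mean[i], v$sd[i])
        phi <- stats::pnorm(v$max[i], v$mean[i], v$sd[i])
        stats::qnorm(plo + p * (phi - plo), v$mean[i], v$sd[i])
      },
      integer = {
        grid <- seq(v$min[i], v$max[i], by = v$step[i])
        grid[pmin(floor(p * length(grid)) + 1L, length(grid))]
      }
    )
  }
  soil_names <- names(space$soil)
  soil_idx <- pmin(floor(u[, length(free) + 1L] * length(soil_names)) + 1L,
    length(soil_names))
  out$soil <- soil_names[soil_idx]
  tibble::as_tibble(out)
}

#' Build a look-up table of simulated band reflectances
#'
#' Runs the coupled leaf-canopy model forward for every Latin hypercube
#' sample of the parameter space and convolves each simulated spectrum to
#' the sensor bands. The result pairs the parameter table with an
#' `n x n_bands` reflectance matrix, row-aligned.
#'
#' @param space A [param_space()].
#' @param bands Band-set tibble (default [micasense_dual_bands()]).
#' @param n Number of entries (default 10000).
#' @param seed Integer seed for the hypercube draw.
#' @param srf Spectral response shape passed to [resample_to_bands()].
#' @return An object of class `prosail_lut`: list with `params` (tibble),
#'   `reflectance` (matrix), `bands`, `space`, `seed`, `srf`,
#'   `noise_applied`.
#' @export
build_lut <- function(space, bands = micasense_dual_bands(), n = 10000,
                      seed = 1, srf = "gaussian") {
  params <- sample_param_space(space, n, seed)
  w <- .srf_weights(bands, srf)
  const <- leaf_optical_constants()
  geo <- space$geometry
  soil_values <- lapply(space$soil, .spectrum_values)

  # the leaf-angle grid is small, so angular coefficients are cached per
  # distinct ALIA value
  geom_cache <- new.env(parent = emptyenv())
  refl <- matrix(NA_real_, nrow = n, ncol = nrow(bands),
    dimnames = list(NULL, bands$band)
  )
  for (i in seq_len(n)) {
    p <- params[i, ]
    rt <- .prospect5_rt(p$N, p$Cab, p$Ccx, p$Cbp, p$Cw, p$Cm, const)
    key <- format(p$ALIA, digits = 12)
    geom <- get0(key, envir = geom_cache)
    if (is.null(geom)) {
      geom <- .sail_geom(p$ALIA, geo$SZA, geo$OZA, geo$rAA)
      assign(key, geom, envir = geom_cache)
    }
    brf <- .foursail_brf(
      rt$reflectance, rt$transmittance, p$LAI, p$ALIA, p$hot,
      geo$SZA, geo$OZA, geo$rAA, soil_values[[p$soil]],
      geom = geom
    )
    refl[i, ] <- as.numeric(brf %*% w)
  }
  structure(
    list(
      params = params, reflectance = refl, bands = bands, space = space,
      n = n, seed = seed, srf = srf, noise_applied = FALSE
    ),
    class = "prosail_lut"
  )
}

#' Degenerate constant-reflectance LUT
#'
#' A table whose every entry has the same reflectance in every band, with
#' parameter values fixed at the space's midpoints. Useful for diagnosing
#' the noise model ([add_noise()]): on a constant table the relative
#' perturbations can be read off directly.
#'
#' @param value Constant reflectance (default 0.3).
#' @param n Number of entries.
#' @param bands Band-set tibble.
#' @return A `prosail_lut`.
#' @export
constant_lut <- function(value = 0.3, n = 10000,
                         bands = micasense_dual_bands()) {
  stopifnot(value >= 0, value <= 1, n >= 1)
  space <- param_space()
  v <- space$variables
  mid <- ifelse(v$dist == "fixed", v$value, (v$min + v$max) / 2)
  params <- tibble::as_tibble(as.list(stats::setNames(mid, v$variable)))
  params <- params[rep(1, n), ]
  params$soil <- "dry"
  structure(
    list(
      params = params,
      reflectance = matrix(value, n, nrow(bands),
        dimnames = list(NULL, bands$band)
      ),
      bands = bands, space = space, n = as.integer(n), seed = NA_integer_,
      srf = "gaussian", noise_applied = FALSE
    ),
    class = "prosail_lut"
  )
}

#' @export
print.prosail_lut <- function(x, ...) {
  cat(sprintf(
    "<prosail_lut> %d entries x %d bands (date %s, seed %d, noise %s)\n",
    x$n, ncol(x$reflectance), x$space$date, x$seed,
    if (x$noise_applied) "applied" else "none"
  ))
  invisible(x)
}

#' Perturb LUT reflectances with Gaussian noise
#'
#' Models measurement uncertainty by perturbing every simulated band
#' reflectance once: `r * (1 + e)` with `e ~ N(0, relative_sd)` (default 2 %
#' relative noise), or `r + e` with `e ~ N(0, absolute_sd)` in additive
#' mode. Negative results are clipped to zero. A table can only be
#' perturbed once.
#'
#' @param lut A `prosail_lut`.
#' @param relative_sd Relative standard deviation (default 0.02).
#' @param seed Integer seed.
#' @param mode `"relative"` (default) or `"additive"`.
#' @return The perturbed `prosail_lut` with `noise_applied = TRUE`.
#' @export
add_noise <- function(lut, relative_sd = 0.02, seed = 1,
                      mode = c("relative", "additive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(lut, "prosail_lut"), relative_sd >= 0)
  if (lut$noise_applied) rlang::abort("noise has already been applied to this LUT")
  set.seed(seed)
  if (relative_sd > 0) {
    eps <- matrix(stats::rnorm(length(lut$reflectance), 0, relative_sd),
      nrow = nrow(lut$reflectance)
    )
    lut$reflectance <- if (mode == "relative") {
      lut$reflectance * (1 + eps)
    } else {
      lut$reflectance + eps
    }
    lut$reflectance[lut$reflectance < 0] <- 0
  }
  lut$noise_applied <- TRUE
  lut$noise_sd <- relative_sd
  lut$noise_mode <- mode
  lut
}

#' Cost function registry for LUT inversion
#'
#' Named list of spectral cost functions, each mapping an `n x b` LUT
#' reflectance matrix and a length-`b` measurement to `n` costs: `rmse`
#' (root-mean-square difference across bands, the default), `sse` (summed
#' squared error) and `sam` (spectral angle). User-supplied functions with
#' the same signature can be passed directly to [invert_spectrum()].
#'
#' @format A named list of functions `(R, m) -> costs`.
#' @export
lut_cost_functions <- list(
  rmse = function(R, m) sqrt(rowMeans((R - rep(m, each = nrow(R)))^2)),
  sse = function(R, m) rowSums((R - rep(m, each = nrow(R)))^2),
  sam = function(R, m) {
    num <- as.numeric(R %*% m)
    den <- sqrt(rowSums(R^2)) * sqrt(sum(m^2))
    acos(pmin(pmax(num / den, -1), 1))
  }
)

# Shared core: ranks LUT entries against one measurement and summarises the
# retained best solutions. Returns list(est, sd, k).
.invert_one <- function(m, lut, top_fraction, cost_fn, derived) {
  costs <- cost_fn(lut$reflectance, m)
  k <- ceiling(top_fraction * lut$n)
  best <- order(costs)[seq_len(k)] # stable: ties broken by entry index
  sol <- lut$params[best, ]
  vals <- lapply(derived, function(f) f(sol))
  list(
    est = vapply(vals, mean, numeric(1)),
    sd = vapply(vals, stats::sd, numeric(1)),
    k = k
  )
}

.default_inversion_variables <- function() {
  list(
    LAI = function(sol) sol$LAI,
    Cab = function(sol) sol$Cab,
    CCC = function(sol) sol$Cab * sol$LAI,
    ALIA = function(sol) sol$ALIA,
    N = function(sol) sol$N
  )
}

#' Invert one measured band-reflectance spectrum against a LUT
#'
#' Ranks all LUT entries by a spectral cost (default: root-mean-square
#' difference across bands) against the measurement, retains the best
#' `ceiling(top_fraction * n)` entries (default 5 %, i.e. 500 of 10000) and
#' reports, per variable, the mean of the retained solutions as the point
#' estimate and their standard deviation as the dispersion. Canopy
#' chlorophyll content `CCC` is derived per retained solution as
#' `Cab * LAI` before averaging.
#'
#' @param measured Named numeric vector of band reflectances (names matching
#'   the LUT bands, in order), or a tibble with `band` and `value`.
#' @param lut A `prosail_lut`.
#' @param top_fraction Fraction of entries retained (default 0.05).
#' @param cost Name of a cost function in `lut_cost_functions` ("rmse",
#'   "sse", "sam") or a function `(R, m) -> costs`.
#' @return A tibble with columns `variable`, `estimate`, `dispersion`,
#'   `n_solutions`.
#' @export
invert_spectrum <- function(measured, lut, top_fraction = 0.05, cost = "rmse") {
  stopifnot(inherits(lut, "prosail_lut"))
  if (is.data.frame(measured)) {
    stopifnot(all(c("band", "value") %in% names(measured)))
    measured <- stats::setNames(measured$value, measured$band)
  }
  if (!is.null(names(measured))) {
    missing <- setdiff(lut$bands$band, names(measured))
    if (length(missing) > 0) {
      rlang::abort(paste0("measurement lacks bands: ", paste(missing, collapse = ", ")))
    }
    measured <- measured[lut$bands$band]
  }
  if (length(measured) != ncol(lut$reflectance)) {
    rlang::abort("measurement length does not match the LUT band count")
  }
  if (any(!is.finite(measured))) rlang::abort("measurement contains non-finite values")
  cost_fn <- if (is.function(cost)) cost else lut_cost_functions[[cost]]
  if (is.null(cost_fn)) rlang::abort(sprintf("unknown cost function `%s`", cost))
  vars <- .default_inversion_variables()
  res <- .invert_one(as.numeric(measured), lut, top_fraction, cost_fn, vars)
  tibble::tibble(
    variable = names(vars),
    estimate = unname(res$est),
    dispersion = unname(res$sd),
    n_solutions = res$k
  )
}
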