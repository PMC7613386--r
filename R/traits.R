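#' Convert SPAD meter readings to leaf chlorophyll content
#'
#' Exponential calibration `LCC = scale * exp(rate * SPAD)` relating the
#' unitless transmittance-based SPAD reading to chlorophyll a+b per leaf
#' area. The default coefficients (`scale = 9.1411` ug/cm^2,
#' `rate = 0.0318` per SPAD unit) are the maize calibration used by the
#' retrieval study this package emulates; `SPAD = 0` maps to exactly
#' `scale`.
#'
#' @param spad Non-negative SPAD readings.
#' @param scale,rate Calibration coefficients, both > 0.
#' @return LCC in ug/cm^2, strictly increasing in `spad`.
#' @export
#' @examples
#' spad_to_lcc(c(0, 30, 50))
spad_to_lcc <- function(spad, scale = 9.1411, rate = 0.0318) {
  stopifnot(scale > 0, rate > 0)
  if (any(!is.finite(spad)) || any(spad < 0)) {
    rlang::abort("SPAD readings must be finite and non-negative")
  }
  scale * exp(rate * spad)
}

#' @rdname spad_to_lcc
#' @param lcc Leaf chlorophyll content in ug/cm^2, >= `scale`.
#' @export
lcc_to_spad <- function(lcc, scale = 9.1411, rate = 0.0318) {
  stopifnot(scale > 0, rate > 0)
  if (any(!is.finite(lcc)) || any(lcc < scale)) {
    rlang::abort(sprintf("LCC below the calibration floor of %.4f ug/cm^2", scale))
  }
  log(lcc / scale) / rate
}

#' Canopy chlorophyll content
#'
#' `CCC = LCC * LAI`: chlorophyll per unit ground area, the product of leaf
#' chlorophyll per leaf area and leaf area per ground area. Reported on the
#' ug/cm^2 ground-area basis (LAI is dimensionless).
#'
#' @param lcc Leaf chlorophyll content (ug/cm^2), >= 0.
#' @param lai Leaf area index (m^2/m^2), >= 0.
#' @return CCC (ug/cm^2 of ground).
#' @export
ccc <- function(lcc, lai) {
  stopifnot(all(lcc >= 0), all(lai >= 0))
  lcc * lai
}

#' Retrieval accuracy metrics
#'
#' `rmse()` is the root of the mean squared difference between observations
#' `d` and estimates `f`; `rrmse()` expresses it as a percentage of the
#' observation mean, `100 * RMSE / mean(d)`; `r_squared()` is the squared
#' Pearson correlation between observations and estimates (the scatter-plot
#' convention, invariant to affine rescaling of either argument).
#'
#' @param d Observed values.
#' @param f Estimated values, same length.
#' @return A scalar metric.
#' @export
#' @examples
#' rmse(c(0, 2), c(2, 0)) # 2
#' rrmse(c(4, 6), c(4.5, 5.5)) # 100 * 0.5 / 5
rmse <- function(d, f) {
  stopifnot(length(d) == length(f), length(d) >= 1)
  if (any(!is.finite(d)) || any(!is.finite(f))) {
    rlang::abort("metrics require finite paired values")
  }
  sqrt(mean((d - f)^2))
}

#' @rdname rmse
#' @export
rrmse <- function(d, f) {
  m <- mean(d)
  if (m == 0) rlang::abort("relative RMSE is undefined for zero observation mean")
  100 * rmse(d, f) / m
}

#' @rdname rmse
#' @export
r_squared <- function(d, f) {
  stopifnot(length(d) == length(f), length(d) >= 2)
  if (stats::var(d) == 0 || stats::var(f) == 0) {
    rlang::abort("coefficient of determination is undefined for degenerate variance")
  }
  stats::cor(d, f)^2
}

#' Evaluate retrievals against ground truth
#'
#' Joins per-plot estimates to the ground-truth table on `plot_id` (and
#' `date` when both carry it) and computes RMSE, relative RMSE and r^2 per
#' variable within each requested grouping -- mirroring the reporting
#' structure of per-maize-type rows with per-date panels.
#'
#' @param results Tibble of estimates: `plot_id`, `variable`, `estimate`
#'   (e.g. from [invert_plot_mean()] or [aggregate_plots()]).
#' @param truth Tibble with `plot_id` and one column per variable of
#'   observed values (e.g. `LAI`, `LCC`, `CCC`), plus any grouping columns
#'   such as `date` or `maize_type`.
#' @param group_by Character vector of grouping columns found in `truth`
#'   (default none: pooled).
#' @param variables Variables to evaluate; defaults to those present in
#'   both tables. Estimated `Cab` is compared to observed `LCC` (both are
#'   chlorophyll per leaf area).
#' @return A tibble of class `canopy_eval`: one row per variable x group
#'   with `n`, `rmse`, `rrmse`, `r2`.
#' @export
evaluate <- function(results, truth, group_by = character(), variables = NULL) {
  stopifnot(all(c("plot_id", "variable", "estimate") %in% names(results)))
  res <- results
  # the retrieval names leaf chlorophyll "Cab"; ground truth tables carry "LCC"
  if ("LCC" %in% names(truth) && !"Cab" %in% names(truth)) {
    res$variable[res$variable == "Cab"] <- "LCC"
  }
  keys <- intersect(c("plot_id", "date"), intersect(names(res), names(truth)))
  truth_vars <- setdiff(
    names(truth)[vapply(truth, is.numeric, logical(1))],
    c(keys, group_by)
  )
  if (is.null(variables)) variables <- intersect(unique(res$variable), truth_vars)
  if (length(variables) == 0) rlang::abort("no common variables between results and truth")
  long_truth <- tidyr::pivot_longer(
    truth[, c(keys, group_by, variables)],
    cols = dplyr::all_of(variables),
    names_to = "variable", values_to = "observed"
  )
  joined <- dplyr::inner_join(
    res[res$variable %in% variables, c(keys, "variable", "estimate")],
    long_truth,
    by = c(keys, "variable")
  )
  joined <- joined[is.finite(joined$observed) & is.finite(joined$estimate), ]
  if (nrow(joined) == 0) rlang::abort("join of results and truth produced zero rows")
  out <- joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_by, "variable")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      rmse = rmse(.data$observed, .data$estimate),
      rrmse = rrmse(.data$observed, .data$estimate),
      r2 = if (dplyr::n() >= 2 && stats::var(.data$observed) > 0 &&
        stats::var(.data$estimate) > 0) {
        r_squared(.data$observed, .data$estimate)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  attr(out, "pairs") <- joined
  class(out) <- c("canopy_eval", class(out))
  out
}
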