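# One-factor-at-a-time sensitivity of the homogeneous curve.

#' Baseline parameters for the sensitivity scan
#'
#' The reference point v0 = J0 = kv = kJ = 1e-3 about which each parameter is
#' perturbed multiplicatively.
#'
#' @return A [kinetic_params()] object.
#' @export
ofat_baseline <- function() kinetic_params(1e-3, 1e-3, 1e-3, 1e-3)

#' One-factor-at-a-time sensitivity scan
#'
#' Perturbs each target parameter in turn by the multiplicative factors while
#' holding the others at baseline, and evaluates the transformed-percentage
#' trajectory for every combination. The factor-1 rows reproduce the baseline
#' trajectory for every parameter.
#'
#' @param baseline A [kinetic_params()] object; defaults to [ofat_baseline()].
#' @param factors Positive multiplicative factors; default
#'   `c(0.5, 0.8, 1, 1.2, 1.5)`.
#' @param targets Parameters to perturb, a subset of
#'   `c("v0", "J0", "kv", "kJ")`.
#' @param times Output time grid in days; default 0 to 365 in steps of 5.
#' @param alpha Saturation bound in AT%-units.
#' @return A long tibble with columns `parameter`, `factor`, `time_days`,
#'   `ye`, `x`.
#' @examples
#' scan <- ofat_scan(times = c(0, 100, 200, 300))
#' dplyr::filter(scan, factor == 1, parameter == "v0")
#' @export
ofat_scan <- function(baseline = ofat_baseline(),
                      factors = c(0.5, 0.8, 1, 1.2, 1.5),
                      targets = c("v0", "J0", "kv", "kJ"),
                      times = seq(0, 365, by = 5),
                      alpha = 0.35) {
  check_finite(factors, "factors")
  if (any(factors <= 0)) stop_tau("`factors` must be strictly positive.", "invalid")
  targets <- match.arg(targets, c("v0", "J0", "kv", "kJ"), several.ok = TRUE)
  check_time_grid(times)
  grid <- tidyr::expand_grid(parameter = targets, factor = factors)
  purrr::pmap_dfr(grid, function(parameter, factor) {
    p <- baseline
    p[[parameter]] <- p[[parameter]] * factor
    p <- kinetic_params(p$v0, p$J0, p$kv, p$kJ)
    dplyr::mutate(
      kjma_trajectory(times, p, alpha),
      parameter = parameter, factor = factor, .before = 1
    )
  })
}
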