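# Projection of the calibrated homogeneous curve onto a nodal mechanical
# field. Each node carries a normalized stimulus w in [0,1]; the local
# extended variable is Y_i = A^4 w_i^4 Ye(t) and the local burden
# tau_i = 1 - exp(-S(t) Y_i), with S(t) solved at every time so that the
# unweighted node mean of tau equals the homogeneous X(t) exactly.

#' Validate a nodal mechanical field
#'
#' A mechanical field is a tibble with one row per mesh node: integer
#' `node_id` (unique), optional coordinates `x`, `y`, `z` in mm, and the raw
#' scalar stimulus `w0` (e.g. logarithmic maximum principal strain) in
#' arbitrary units.
#'
#' @param field A data frame with at least `node_id` and `w0`.
#' @return The field as a validated tibble.
#' @export
mechanical_field <- function(field) {
  field <- as_tibble(field)
  if (!all(c("node_id", "w0") %in% names(field))) {
    stop_tau("A mechanical field needs columns `node_id` and `w0`.", "format")
  }
  if (nrow(field) < 1L) stop_tau("A mechanical field needs at least one node.", "invalid")
  if (anyDuplicated(field$node_id)) {
    dup <- unique(field$node_id[duplicated(field$node_id)])
    stop_tau(
      sprintf("Duplicate node ids: %s", paste(utils::head(dup, 5), collapse = ", ")),
      "format"
    )
  }
  bad <- which(!is.finite(field$w0))
  if (length(bad)) {
    stop_tau(
      sprintf(
        "Non-finite `w0` at node ids: %s",
        paste(utils::head(field$node_id[bad], 5), collapse = ", ")
      ),
      "invalid"
    )
  }
  field
}

#' Min-max normalize a mechanical field
#'
#' Rescales the raw nodal scalar to w = (w0 - min) / (max - min) in \[0, 1\],
#' so w = 0 marks minimal and w = 1 maximal mechanical stimulus. A constant
#' raw field (the formula's 0/0 case) maps to w = 1 everywhere, so the
#' heterogeneous model degrades gracefully to the homogeneous curve.
#'
#' @inheritParams mechanical_field
#' @return The field tibble with a `w` column added; attributes `w0_min` and
#'   `w0_max` record the normalization provenance.
#' @examples
#' normalize_field(tibble::tibble(node_id = 1:3, w0 = c(2, 4, 6)))$w
#' @export
normalize_field <- function(field) {
  field <- mechanical_field(field)
  lo <- min(field$w0); hi <- max(field$w0)
  field$w <- if (hi > lo) (field$w0 - lo) / (hi - lo) else rep(1, nrow(field))
  attr(field, "w0_min") <- lo
  attr(field, "w0_max") <- hi
  field
}

#' Impact-amplitude factor
#'
#' Global scaling A = (Q / Q_ref) (n_impacts / n_ref) encoding impact
#' magnitude and count relative to reference values. With single-impact
#' calibration on a normalized field, A = 1.
#'
#' @param Q Impact magnitude; `Q_ref` its reference value.
#' @param Q_ref,n_ref Reference magnitude and impact count.
#' @param n_impacts Number of impacts or loading cycles.
#' @return A scalar amplitude factor A > 0.
#' @export
amplitude_factor <- function(Q = 1, Q_ref = 1, n_impacts = 1, n_ref = 1) {
  check_finite(c(Q, Q_ref, n_impacts, n_ref), "amplitude inputs")
  if (any(c(Q, Q_ref, n_impacts, n_ref) <= 0)) {
    stop_tau("Amplitude inputs must be strictly positive.", "invalid")
  }
  (Q / Q_ref) * (n_impacts / n_ref)
}

#' Local extended variable
#'
#' Per-node extended variable Y_i = A^p w_i^p Ye, with the weighting exponent
#' p defaulting to 4. The fourth power sharpens spatial contrast: the ratio
#' of local extended variables of two nodes is (w_i / w_j)^p exactly.
#'
#' @param w Normalized nodal values in \[0, 1\].
#' @param ye Homogeneous extended volume (scalar, >= 0).
#' @param A Amplitude factor, see [amplitude_factor()].
#' @param exponent Weighting power; default 4.
#' @return Per-node extended variables (0 where w = 0).
#' @export
local_extended <- function(w, ye, A = 1, exponent = 4) {
  check_finite(w, "w"); check_finite(ye, "ye")
  if (ye < 0) stop_tau("`ye` must be non-negative.", "invalid")
  (A * w)^exponent * ye
}

#' Solve the mean-enforcing correction factor S
#'
#' Finds S >= 0 such that the unweighted node mean of
#' 1 - exp(-S A^p w_i^p Ye) equals the homogeneous target
#' X = alpha (1 - exp(-Ye)). The left side is continuous and strictly
#' increasing in S (when Ye > 0 and some w_i > 0), so the root is unique;
#' it is bracketed by doubling and then bisected to the requested tolerance
#' on the mean. When Ye = 0 the equation is vacuous and S = 1 is returned by
#' convention.
#'
#' As S grows the mean approaches the fraction of nodes with positive
#' weight; if the target X meets or exceeds that fraction the equation has
#' no finite solution and a typed infeasibility error is raised.
#'
#' @inheritParams local_extended
#' @param alpha Saturation bound in AT%-units.
#' @param tol Absolute tolerance on the enforced mean; default 1e-12.
#' @return The scalar correction factor S.
#' @examples
#' # single node class: closed form -log(1 - X)/ye
#' solve_correction(rep(1, 10), ye = 1)
#' @export
solve_correction <- function(w, ye, A = 1, exponent = 4, alpha = 0.35,
                             tol = 1e-12) {
  check_finite(w, "w"); check_finite(ye, "ye"); check_alpha(alpha)
  if (ye < 0) stop_tau("`ye` must be non-negative.", "invalid")
  if (ye == 0) return(1)
  a <- (A * w)^exponent * ye
  target <- alpha * -expm1(-ye)
  pos_frac <- mean(a > 0)
  if (target >= pos_frac) {
    stop_tau(
      sprintf(
        "Mean enforcement infeasible: target X = %.6g but only %.4g of nodes have positive weight.",
        target, pos_frac
      ),
      "infeasible", target = target, positive_fraction = pos_frac
    )
  }
  f <- function(s) mean(-expm1(-s * a)) - target
  hi <- 1
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e300) stop_tau("Correction-factor bracket exceeded 1e300.", "numeric")
  }
  lo <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tol) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Spatiotemporal tau map over a mechanical field
#'
#' For each time on the grid, evaluates the homogeneous extended volume,
#' solves the mean-enforcing correction factor S(t), and computes the
#' per-node burden tau_i(t) = 1 - exp(-S(t) A^p w_i^p Ye(t)). The node mean
#' of every column equals the homogeneous curve X(t) to the solver
#' tolerance, and tau inherits both monotonicities: non-decreasing in time
#' at every node, and ordered by w across nodes at every time.
#'
#' @param field A normalized field from [normalize_field()] (a `w` column is
#'   required).
#' @param params A [kinetic_params()] object (typically calibrated).
#' @param times Output time grid in days.
#' @param alpha Saturation bound in AT%-units.
#' @param A Amplitude factor, see [amplitude_factor()].
#' @param exponent Weighting power; default 4.
#' @param tol Absolute tolerance on the enforced mean.
#' @return An object of class `tau_field`: a list with `field` (the input
#'   tibble), `times`, `tau` (nodes x times matrix, AT%-units), and
#'   `s_factors` (tibble with `time_days`, `ye`, `x`, `s`). Supports
#'   [tidy()] (long node/time/tau tibble) and [ggplot2::autoplot()].
#' @export
tau_map <- function(field, params, times = default_time_grid(),
                    alpha = 0.35, A = 1, exponent = 4, tol = 1e-12) {
  if (!is.data.frame(field) || is.null(field$w)) {
    stop_tau("`field` must carry a `w` column; call normalize_field() first.", "invalid")
  }
  check_time_grid(times)
  ye <- extended_volume(times, params)
  x <- alpha * -expm1(-ye)
  a_base <- (A * field$w)^exponent
  tau <- matrix(0, nrow = nrow(field), ncol = length(times),
                dimnames = list(NULL, paste0("t", times)))
  s <- numeric(length(times))
  # Solve in the composite variable lambda = S * Ye. The true lambda(t) is
  # non-decreasing because the target mean X(t) is and the mean is strictly
  # increasing in lambda; flooring each solve at the previous lambda keeps
  # per-node tau exactly monotone in time while changing the enforced mean
  # by at most the solver tolerance.
  lambda_prev <- 0
  for (k in seq_along(times)) {
    if (ye[k] == 0) {
      s[k] <- 1
      next
    }
    target <- x[k]
    pos_frac <- mean(a_base > 0)
    if (target >= pos_frac) {
      stop_tau(
        sprintf(
          "At t = %g days: mean enforcement infeasible (target X = %.6g, positive-weight fraction %.4g).",
          times[k], target, pos_frac
        ),
        "infeasible", time = times[k], target = target,
        positive_fraction = pos_frac
      )
    }
    f <- function(lam) mean(-expm1(-lam * a_base)) - target
    lo <- lambda_prev
    hi <- max(1, lambda_prev * 2)
    while (f(hi) < 0) {
      hi <- hi * 2
      if (hi > 1e300) stop_tau("Correction-factor bracket exceeded 1e300.", "numeric")
    }
    lambda <- if (f(lo) >= 0) lo else {
      for (i in 1:200) {
        mid <- (lo + hi) / 2
        fm <- f(mid)
        if (abs(fm) <= tol) break
        if (fm < 0) lo <- mid else hi <- mid
      }
      if (abs(fm) <= tol) mid else (lo + hi) / 2
    }
    s[k] <- lambda / ye[k]
    tau[, k] <- -expm1(-lambda * a_base)
    lambda_prev <- lambda
  }
  structure(
    list(
      field = field, times = times, tau = tau,
      s_factors = tibble(time_days = times, ye = ye, x = x, s = s),
      alpha = alpha, A = A, exponent = exponent
    ),
    class = "tau_field"
  )
}

#' Default output time grid
#'
#' Eight snapshots spanning the first post-injury year:
#' 1, 50, 100, 150, 200, 250, 300, 350 days.
#'
#' @return A numeric vector of days.
#' @export
default_time_grid <- function() c(1, 50, 100, 150, 200, 250, 300, 350)

#' @export
print.tau_field <- function(x, ...) {
  cat("<tau_field>\n")
  cat(sprintf(
    "  %d nodes x %d times (%g..%g days), exponent %g, A = %g, alpha = %g\n",
    nrow(x$tau), length(x$times), min(x$times), max(x$times),
    x$exponent, x$A, x$alpha
  ))
  cat(sprintf(
    "  final mean tau = %.6g (homogeneous X = %.6g)\n",
    mean(x$tau[, ncol(x$tau)]), x$s_factors$x[nrow(x$s_factors)]
  ))
  invisible(x)
}

#' @rdname tau_map
#' @param x A `tau_field` object.
#' @param ... Unused.
#' @method tidy tau_field
#' @export
tidy.tau_field <- function(x, ...) {
  out <- tidyr::expand_grid(
    node_id = x$field$node_id,
    time_days = x$times
  )
  out$tau <- as.vector(t(x$tau))
  out
}

#' @rdname tau_map
#' @method glance tau_field
#' @export
glance.tau_field <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$tau), n_times = length(x$times),
    max_tau = max(x$tau),
    max_mean_defect = max(abs(colMeans(x$tau) - x$s_factors$x)),
    exponent = x$exponent, A = x$A, alpha = x$alpha
  )
}
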