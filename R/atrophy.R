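# Atrophy surrogate: elements whose tau burden reaches a threshold are
# removed from the mesh, and the remaining tissue volume is tracked over
# time. Because tau is non-decreasing in time at every node, removal is
# automatically monotone: once an element is gone it stays gone.

#' Validate element connectivity
#'
#' Element connectivity is a tibble with one row per mesh element:
#' `element_id`, a `nodes` list-column of node-id vectors, optionally a
#' `type` column (`"hexahedron"`, `"triangle"`, ...) and a per-element
#' `volume` in mm^3.
#'
#' @param elements A data frame as described.
#' @param node_ids Optional vector of valid node ids to check references
#'   against.
#' @return The validated tibble.
#' @export
element_connectivity <- function(elements, node_ids = NULL) {
  elements <- as_tibble(elements)
  if (!all(c("element_id", "nodes") %in% names(elements))) {
    stop_tau("Connectivity needs columns `element_id` and `nodes`.", "format")
  }
  if (anyDuplicated(elements$element_id)) {
    stop_tau("Duplicate element ids.", "format")
  }
  if (!is.null(node_ids)) {
    referenced <- unique(unlist(elements$nodes))
    missing <- setdiff(referenced, node_ids)
    if (length(missing)) {
      stop_tau(
        sprintf("Elements reference unknown node ids: %s",
                paste(utils::head(missing, 5), collapse = ", ")),
        "invalid"
      )
    }
  }
  if (!is.null(elements[["volume"]]) && any(elements[["volume"]] <= 0, na.rm = TRUE)) {
    stop_tau("Element volumes must be positive.", "invalid")
  }
  elements
}

#' Reduce nodal tau to element tau
#'
#' Maps the per-node burden of a [tau_map()] result onto elements through a
#' reduction over each element's nodes: the arithmetic mean (default),
#' maximum, or minimum.
#'
#' @param tau_field A `tau_field` object from [tau_map()].
#' @param elements An [element_connectivity()] tibble.
#' @param rule Reduction rule: `"mean"`, `"max"` or `"min"`.
#' @return A long tibble with columns `element_id`, `time_days`, `tau`.
#' @export
element_tau <- function(tau_field, elements, rule = c("mean", "max", "min")) {
  stopifnot(inherits(tau_field, "tau_field"))
  if (is.character(rule) && length(rule) >= 1 &&
      !all(rule %in% c("mean", "max", "min"))) {
    stop_tau(
      sprintf("Unknown reduction rule '%s'; use mean, max or min.", rule[1]),
      "invalid"
    )
  }
  rule <- match.arg(rule)
  elements <- element_connectivity(elements, tau_field$field$node_id)
  reduce_fun <- switch(rule, mean = colMeans,
                       max = function(m) apply(m, 2, max),
                       min = function(m) apply(m, 2, min))
  idx <- setNames(seq_len(nrow(tau_field$field)), tau_field$field$node_id)
  per_elem <- purrr::map(elements$nodes, function(nn) {
    m <- tau_field$tau[idx[as.character(nn)], , drop = FALSE]
    reduce_fun(m)
  })
  out <- tidyr::expand_grid(
    element_id = elements$element_id,
    time_days = tau_field$times
  )
  out$tau <- unlist(per_elem, use.names = FALSE)
  attr(out, "rule") <- rule
  out
}

#' Threshold element tau into an atrophy mask
#'
#' Marks an element removed at every time at which its reduced tau meets or
#' exceeds the threshold (default 0.7 AT%-units, i.e. well above the
#' homogeneous saturation bound but reachable locally at high-strain nodes).
#' Removal is monotone in time because tau is.
#'
#' @param etau An `element_tau` long tibble.
#' @param threshold Removal threshold in AT%-units, in (0, 1).
#' @return An `atrophy_mask` long tibble with columns `element_id`,
#'   `time_days`, `removed`; the threshold and reduction rule are carried as
#'   attributes.
#' @export
apply_threshold <- function(etau, threshold = 0.7) {
  check_finite(threshold, "threshold")
  if (threshold <= 0 || threshold >= 1) {
    stop_tau("`threshold` must lie in (0, 1).", "invalid")
  }
  out <- dplyr::mutate(etau, removed = .data$tau >= threshold)
  out <- out[, c("element_id", "time_days", "removed")]
  attr(out, "threshold") <- threshold
  attr(out, "rule") <- attr(etau, "rule")
  class(out) <- c("atrophy_mask", class(out))
  out
}

#' Remaining tissue volume under an atrophy mask
#'
#' Sums the volume of the elements not yet removed at each time; the series
#' is non-increasing because removal is monotone.
#'
#' @param mask An [apply_threshold()] mask.
#' @param elements An [element_connectivity()] tibble with a `volume` column
#'   (mm^3).
#' @return A tibble with columns `time_days`, `volume_mm3`.
#' @export
remaining_volume <- function(mask, elements) {
  elements <- element_connectivity(elements)
  if (is.null(elements[["volume"]]) || anyNA(elements[["volume"]])) {
    stop_tau("`elements` must carry positive volumes for every element.", "invalid")
  }
  joined <- dplyr::left_join(
    as_tibble(mask), elements[, c("element_id", "volume")],
    by = "element_id"
  )
  dplyr::summarise(
    dplyr::group_by(joined, .data$time_days),
    volume_mm3 = sum(.data$volume[!.data$removed]),
    .groups = "drop"
  )
}
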