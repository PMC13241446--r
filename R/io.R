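# CSV and VTK XML (unstructured grid, ascii) input/output.
#
# CSV dialect: comma-separated, mandatory header, UTF-8, '.' decimal, full
# round-trip precision for doubles. VTK: XML UnstructuredGrid with point
# data for nodal scalars (tau, w) and cell data for atrophy masks.

.vtk_type_codes <- c(triangle = 5L, quad = 9L, tetrahedron = 10L, hexahedron = 12L)

.fmt_num <- function(x) sprintf("%.17g", x)

# Minimal ascii .vtu writer: coords is an N x 3 matrix, cells a list of
# 1-based node-index vectors, types a character vector of cell kinds.
.write_vtu <- function(path, coords, cells, types,
                       point_data = list(), cell_data = list()) {
  type_codes <- .vtk_type_codes[types]
  if (anyNA(type_codes)) {
    stop_tau(
      sprintf("Unsupported cell type(s): %s",
              paste(unique(types[is.na(type_codes)]), collapse = ", ")),
      "format"
    )
  }
  arr <- function(name, values, type, ncomp = NULL) {
    sprintf(
      '    <DataArray type="%s" Name="%s"%s format="ascii">\n%s\n    </DataArray>',
      type, name,
      if (is.null(ncomp)) "" else sprintf(' NumberOfComponents="%d"', ncomp),
      paste(values, collapse = " ")
    )
  }
  pd <- paste(
    purrr::imap_chr(point_data, function(v, nm) {
      arr(nm, if (is.double(v)) .fmt_num(v) else as.integer(v),
          if (is.double(v)) "Float64" else "Int64")
    }),
    collapse = "\n"
  )
  cd <- paste(
    purrr::imap_chr(cell_data, function(v, nm) {
      arr(nm, if (is.double(v)) .fmt_num(v) else as.integer(v),
          if (is.double(v)) "Float64" else "Int64")
    }),
    collapse = "\n"
  )
  connectivity <- unlist(lapply(cells, function(x) as.integer(x) - 1L))
  offsets <- cumsum(lengths(cells))
  lines <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    " <UnstructuredGrid>",
    sprintf('  <Piece NumberOfPoints="%d" NumberOfCells="%d">',
            nrow(coords), length(cells)),
    if (nzchar(pd)) c(
      sprintf('   <PointData Scalars="%s">', names(point_data)[1]), pd,
      "   </PointData>"
    ),
    if (nzchar(cd)) c("   <CellData>", cd, "   </CellData>"),
    "   <Points>",
    arr("Points", .fmt_num(as.vector(t(coords))), "Float64", ncomp = 3L),
    "   </Points>",
    "   <Cells>",
    arr("connectivity", connectivity, "Int64"),
    arr("offsets", offsets, "Int64"),
    arr("types", unname(type_codes), "UInt8"),
    "   </Cells>",
    "  </Piece>",
    " </UnstructuredGrid>",
    "</VTKFile>"
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

.read_vtu_array <- function(node) {
  txt <- xml2::xml_text(node)
  vals <- scan(text = txt, what = double(), quiet = TRUE)
  if (xml2::xml_attr(node, "type") %in% c("Int64", "Int32", "UInt8")) {
    vals <- as.integer(vals)
  }
  vals
}

.read_vtu <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop_tau(sprintf("Cannot parse VTK file '%s': %s", path, conditionMessage(e)), "format")
  })
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (inherits(piece, "xml_missing")) {
    stop_tau(sprintf("'%s' has no UnstructuredGrid Piece.", path), "format")
  }
  get_arrays <- function(xpath) {
    nodes <- xml2::xml_find_all(piece, xpath)
    setNames(lapply(nodes, .read_vtu_array), xml2::xml_attr(nodes, "Name"))
  }
  pts <- xml2::xml_find_first(piece, "./Points/DataArray")
  coords <- matrix(.read_vtu_array(pts), ncol = 3, byrow = TRUE)
  conn <- .read_vtu_array(xml2::xml_find_first(piece, './Cells/DataArray[@Name="connectivity"]'))
  offs <- .read_vtu_array(xml2::xml_find_first(piece, './Cells/DataArray[@Name="offsets"]'))
  codes <- .read_vtu_array(xml2::xml_find_first(piece, './Cells/DataArray[@Name="types"]'))
  starts <- c(0L, offs[-length(offs)]) + 1L
  cells <- purrr::map2(starts, offs, function(s, e) conn[s:e] + 1L)
  types <- names(.vtk_type_codes)[match(codes, .vtk_type_codes)]
  list(
    coords = coords, cells = cells, types = types,
    point_data = get_arrays("./PointData/DataArray"),
    cell_data = get_arrays("./CellData/DataArray")
  )
}

# Geometric cell measures from coordinates: volume for solids (hexahedra
# split into 5 tetrahedra, tetrahedra directly), area for triangles,
# NA otherwise.
.cell_measures <- function(coords, cells, types) {
  tet_vol <- function(p) abs(det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ]))) / 6
  tri_area <- function(p) {
    v1 <- p[2, ] - p[1, ]; v2 <- p[3, ] - p[1, ]
    cr <- c(
      v1[2] * v2[3] - v1[3] * v2[2],
      v1[3] * v2[1] - v1[1] * v2[3],
      v1[1] * v2[2] - v1[2] * v2[1]
    )
    0.5 * sqrt(sum(cr^2))
  }
  hex_tets <- list(c(1, 2, 4, 5), c(2, 3, 4, 7), c(2, 4, 5, 7), c(4, 5, 7, 8), c(2, 5, 6, 7))
  purrr::map2_dbl(cells, types, function(ix, ty) {
    p <- coords[ix, , drop = FALSE]
    switch(ty,
      hexahedron = sum(vapply(hex_tets, function(tt) tet_vol(p[tt, , drop = FALSE]), numeric(1))),
      tetrahedron = tet_vol(p),
      triangle = tri_area(p),
      NA_real_
    )
  })
}

#' Read and write nodal mechanical fields
#'
#' CSV fields carry columns `node_id`, `w0` and optionally `x`, `y`, `z`
#' (mm); the header is mandatory. VTK fields are XML unstructured grids with
#' the raw scalar stored as a named point-data array (default `"MPS"`);
#' node ids are preserved through a `node_id` point-data array when present.
#' Both round-trip values at full double precision.
#'
#' @param path File path.
#' @param field A nodal field tibble (see [mechanical_field()]).
#' @param elements An [element_connectivity()] tibble (VTK only).
#' @param scalar_name Name of the VTK point-data array holding the raw
#'   scalar; default `"MPS"`.
#' @return `read_field_csv()` returns a field tibble; `read_field_vtk()`
#'   returns `list(field, elements)`; writers return the path invisibly.
#' @name field_io
NULL

#' @rdname field_io
#' @export
read_field_csv <- function(path) {
  if (!file.exists(path)) stop_tau(sprintf("No such file: '%s'", path), "format")
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!all(c("node_id", "w0") %in% trimws(header))) {
    stop_tau(
      sprintf("'%s' must have a header with columns node_id and w0.", path),
      "format"
    )
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  mechanical_field(df)
}

#' @rdname field_io
#' @export
write_field_csv <- function(field, path) {
  field <- mechanical_field(field)
  readr::write_csv(field, path, progress = FALSE)
  invisible(path)
}

#' @rdname field_io
#' @export
write_field_vtk <- function(field, elements, path, scalar_name = "MPS") {
  field <- mechanical_field(field)
  elements <- element_connectivity(elements, field$node_id)
  if (!all(c("x", "y", "z") %in% names(field))) {
    stop_tau("VTK output needs node coordinates x, y, z.", "format")
  }
  idx <- setNames(seq_len(nrow(field)), field$node_id)
  cells <- lapply(elements$nodes, function(nn) unname(idx[as.character(nn)]))
  pd <- setNames(
    list(as.double(field$w0), as.integer(field$node_id)),
    c(scalar_name, "node_id")
  )
  .write_vtu(
    path, as.matrix(field[, c("x", "y", "z")]), cells,
    elements[["type"]] %||% rep("hexahedron", nrow(elements)), point_data = pd
  )
}

#' @rdname field_io
#' @export
read_field_vtk <- function(path, scalar_name = "MPS") {
  v <- .read_vtu(path)
  if (!scalar_name %in% names(v$point_data)) {
    stop_tau(
      sprintf("'%s' has no point-data array named '%s' (found: %s).",
              path, scalar_name, paste(names(v$point_data), collapse = ", ")),
      "format"
    )
  }
  node_id <- v$point_data$node_id %||% seq_len(nrow(v$coords))
  field <- mechanical_field(tibble(
    node_id = node_id,
    x = v$coords[, 1], y = v$coords[, 2], z = v$coords[, 3],
    w0 = v$point_data[[scalar_name]]
  ))
  elements <- tibble(
    element_id = seq_along(v$cells),
    nodes = lapply(v$cells, function(ix) node_id[ix]),
    type = v$types,
    volume = .cell_measures(v$coords, v$cells, v$types)
  )
  list(field = field, elements = elements)
}

#' Write a tau field as per-time VTK files and long CSV
#'
#' `write_tau_vtk()` emits one `.vtu` per output time with point-data array
#' `"tau"` (plus `w` and `node_id`); `write_tau_csv()` writes the long table
#' `node_id, time_days, tau`; `write_s_table()` writes the correction-factor
#' table `time_days, ye, x, s`.
#'
#' @param tau_field A `tau_field` from [tau_map()].
#' @param elements Connectivity for the VTK mesh.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix for the per-time VTK files.
#' @param path Output CSV path.
#' @return Paths of the files written, invisibly.
#' @name tau_io
NULL

#' @rdname tau_io
#' @export
write_tau_vtk <- function(tau_field, elements, dir, prefix = "tau") {
  stopifnot(inherits(tau_field, "tau_field"))
  field <- tau_field$field
  if (!all(c("x", "y", "z") %in% names(field))) {
    stop_tau("VTK output needs node coordinates x, y, z.", "format")
  }
  elements <- element_connectivity(elements, field$node_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- setNames(seq_len(nrow(field)), field$node_id)
  cells <- lapply(elements$nodes, function(nn) unname(idx[as.character(nn)]))
  paths <- character(0)
  for (k in seq_along(tau_field$times)) {
    p <- file.path(dir, sprintf("%s_t%03d.vtu", prefix, k))
    .write_vtu(
      p, as.matrix(field[, c("x", "y", "z")]), cells,
      elements[["type"]] %||% rep("hexahedron", nrow(elements)),
      point_data = list(
        tau = as.double(tau_field$tau[, k]),
        w = as.double(field$w),
        node_id = as.integer(field$node_id)
      )
    )
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname tau_io
#' @export
write_tau_csv <- function(tau_field, path) {
  readr::write_csv(tidy(tau_field), path, progress = FALSE)
  invisible(path)
}

#' @rdname tau_io
#' @export
write_s_table <- function(tau_field, path) {
  readr::write_csv(tau_field$s_factors, path, progress = FALSE)
  invisible(path)
}

#' Write an atrophy mask as per-time VTK files and CSV
#'
#' VTK output stores the removal state as a per-cell integer array
#' `"removed"`; the CSV is the long table `element_id, time_days, removed`.
#'
#' @param mask An [apply_threshold()] mask.
#' @param field The nodal field (for coordinates).
#' @param elements Connectivity.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @param path Output CSV path.
#' @return Paths written, invisibly.
#' @name mask_io
NULL

#' @rdname mask_io
#' @export
write_mask_vtk <- function(mask, field, elements, dir, prefix = "atrophy") {
  field <- mechanical_field(field)
  elements <- element_connectivity(elements, field$node_id)
  if (!all(c("x", "y", "z") %in% names(field))) {
    stop_tau("VTK output needs node coordinates x, y, z.", "format")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- setNames(seq_len(nrow(field)), field$node_id)
  cells <- lapply(elements$nodes, function(nn) unname(idx[as.character(nn)]))
  times <- sort(unique(mask$time_days))
  wide <- tidyr::pivot_wider(
    as_tibble(mask), names_from = "time_days", values_from = "removed"
  )
  wide <- wide[match(elements$element_id, wide$element_id), ]
  paths <- character(0)
  for (k in seq_along(times)) {
    p <- file.path(dir, sprintf("%s_t%03d.vtu", prefix, k))
    .write_vtu(
      p, as.matrix(field[, c("x", "y", "z")]), cells,
      elements[["type"]] %||% rep("hexahedron", nrow(elements)),
      cell_data = list(removed = as.integer(wide[[as.character(times[k])]]))
    )
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname mask_io
#' @export
write_mask_csv <- function(mask, path) {
  readr::write_csv(as_tibble(mask), path, progress = FALSE)
  invisible(path)
}

#' Read an observation series CSV
#'
#' Expects columns `time_days`, `tau_at_percent` with a mandatory header.
#'
#' @param path File path.
#' @param alpha Saturation bound the observations must respect.
#' @return An [observation_series()] tibble.
#' @export
read_observations_csv <- function(path, alpha = 0.35) {
  if (!file.exists(path)) stop_tau(sprintf("No such file: '%s'", path), "format")
  header <- trimws(strsplit(readLines(path, n = 1L), ",")[[1]])
  if (!all(c("time_days", "tau_at_percent") %in% header)) {
    stop_tau(
      sprintf("'%s' must have header columns time_days and tau_at_percent.", path),
      "format"
    )
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  observation_series(df$time_days, df$tau_at_percent, alpha)
}

#' Write a calibration report
#'
#' Serializes a [calibrate()] result to a structured YAML report: the four
#' parameters, the predicted table, rmse, r2, the seed and a config echo.
#'
#' @param fit A `tau_calibration` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_calibration_report <- function(fit, path) {
  stopifnot(inherits(fit, "tau_calibration"))
  report <- list(
    parameters = fit$params[c("v0", "J0", "kv", "kJ")],
    predicted = lapply(
      seq_len(nrow(fit$predicted)),
      function(i) as.list(fit$predicted[i, ])
    ),
    rmse = fit$rmse, r2 = fit$r2, objective = fit$objective,
    converged = fit$converged, alpha = fit$alpha,
    config = list(
      seed = fit$config$seed, n_samples = fit$config$n_samples,
      n_restarts = fit$config$n_restarts, bounds = fit$config$bounds,
      simplex_tol = fit$config$simplex_tol, max_iter = fit$config$max_iter,
      v0_ref = fit$config$v0_ref
    )
  )
  yaml::write_yaml(report, path, precision = 15)
  invisible(path)
}

#' Write a kinetic trajectory CSV
#'
#' Columns `time_days`, `ye`, `x`.
#'
#' @param traj A [kjma_trajectory()] tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  readr::write_csv(traj, path, progress = FALSE)
  invisible(path)
}
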