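# Synthetic mechanical fields standing in for finite-element output.
#
# The generator emulates the qualitative structure of an FE-derived
# (logarithmic) maximum principal strain field after a frontal impact: a
# smooth non-negative background with a focal Gaussian high-strain blob,
# plus optional seeded measurement-like noise. Defaults approximate a
# moderate-severe single impact: diffuse strain ~0.05, focal peak ~0.4, on
# a 20 mm cube meshed at 1 mm -- the same order as MPS values reported for
# injurious head impacts.

#' Generate a synthetic mechanical field and mesh
#'
#' Builds either a structured hexahedral grid (`"grid3d"`) or a triangulated
#' spherical shell (`"sphere_shell"`) and assigns each node the scalar
#' `background + blob_amplitude * exp(-|x - c|^2 / (2 sigma^2)) + noise`,
#' clipped at zero. Deterministic given the seed.
#'
#' @param mesh_kind `"grid3d"` or `"sphere_shell"`.
#' @param dims Integer node counts per axis for `grid3d`; default
#'   `c(20, 20, 20)`.
#' @param spacing Grid spacing in mm; default 1.
#' @param radius Shell radius in mm (sphere_shell only); default 10.
#' @param resolution Shell discretization (latitude bands; sphere_shell
#'   only); default 16.
#' @param blob_center Center of the focal high-strain region in mm; defaults
#'   to a frontal, superficial location of the mesh.
#' @param blob_sigma Focal-region spread in mm; default 3.
#' @param blob_amplitude Peak raw-field elevation above background; default
#'   0.35.
#' @param background Diffuse raw-field level; default 0.05.
#' @param noise_sd Standard deviation of additive Gaussian noise; default 0.
#' @param seed Integer RNG seed (required).
#' @return A list with `field` (nodal tibble: `node_id`, `x`, `y`, `z`,
#'   `w0`) and `elements` (an [element_connectivity()] tibble with `type`
#'   and `volume`; for shells the "volume" is the triangle area times a unit
#'   thickness).
#' @examples
#' mesh <- generate_synthetic_field(dims = c(5, 5, 5), seed = 1)
#' nrow(mesh$field)
#' @export
generate_synthetic_field <- function(mesh_kind = c("grid3d", "sphere_shell"),
                                     dims = c(20, 20, 20), spacing = 1,
                                     radius = 10, resolution = 16,
                                     blob_center = NULL, blob_sigma = 3,
                                     blob_amplitude = 0.35,
                                     background = 0.05, noise_sd = 0,
                                     seed) {
  mesh_kind <- match.arg(mesh_kind)
  if (missing(seed)) stop_tau("A `seed` is required.", "invalid")
  check_finite(c(blob_sigma, blob_amplitude, background, noise_sd), "field settings")
  if (noise_sd < 0 || blob_sigma <= 0) {
    stop_tau("`noise_sd` must be >= 0 and `blob_sigma` > 0.", "invalid")
  }
  mesh <- switch(mesh_kind,
    grid3d = .grid3d_mesh(dims, spacing),
    sphere_shell = .sphere_shell_mesh(radius, resolution)
  )
  nodes <- mesh$nodes
  if (is.null(blob_center)) {
    blob_center <- switch(mesh_kind,
      # front-of-mesh, superficial: emulates a frontal-impact strain focus
      grid3d = c(
        mean(range(nodes$x)), max(nodes$y) * 0.9 + min(nodes$y) * 0.1,
        max(nodes$z) * 0.85 + min(nodes$z) * 0.15
      ),
      sphere_shell = c(0, radius, 0)
    )
  }
  d2 <- (nodes$x - blob_center[1])^2 + (nodes$y - blob_center[2])^2 +
    (nodes$z - blob_center[3])^2
  w0 <- background + blob_amplitude * exp(-d2 / (2 * blob_sigma^2))
  if (noise_sd > 0) {
    w0 <- w0 + withr::with_seed(as.integer(seed), stats::rnorm(nrow(nodes), 0, noise_sd))
  }
  nodes$w0 <- pmax(w0, 0)
  list(field = mechanical_field(nodes), elements = mesh$elements)
}

# Structured grid of dims nodes per axis, hexahedral cells of spacing^3.
.grid3d_mesh <- function(dims, spacing) {
  if (length(dims) != 3L || any(dims < 2) || any(dims != round(dims))) {
    stop_tau("`dims` must be three integers >= 2.", "invalid")
  }
  if (spacing <= 0) stop_tau("`spacing` must be positive.", "invalid")
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  nodes <- tidyr::expand_grid(
    k = seq_len(nz) - 1L, j = seq_len(ny) - 1L, i = seq_len(nx) - 1L
  )
  nodes <- tibble(
    node_id = seq_len(nrow(nodes)),
    x = nodes$i * spacing, y = nodes$j * spacing, z = nodes$k * spacing
  )
  nid <- function(i, j, k) i + nx * (j + ny * k) + 1L # 0-based lattice -> id
  cells <- tidyr::expand_grid(
    k = 0:(nz - 2L), j = 0:(ny - 2L), i = 0:(nx - 2L)
  )
  conn <- purrr::pmap(cells, function(i, j, k) {
    c(
      nid(i, j, k), nid(i + 1L, j, k), nid(i + 1L, j + 1L, k), nid(i, j + 1L, k),
      nid(i, j, k + 1L), nid(i + 1L, j, k + 1L), nid(i + 1L, j + 1L, k + 1L),
      nid(i, j + 1L, k + 1L)
    )
  })
  elements <- tibble(
    element_id = seq_along(conn), nodes = conn,
    type = "hexahedron", volume = spacing^3
  )
  list(nodes = nodes, elements = elements)
}

# Latitude-longitude triangulated sphere shell.
.sphere_shell_mesh <- function(radius, resolution) {
  if (radius <= 0 || resolution < 3) {
    stop_tau("`radius` must be > 0 and `resolution` >= 3.", "invalid")
  }
  n_lat <- as.integer(resolution)
  n_lon <- 2L * n_lat
  theta <- seq(0, pi, length.out = n_lat + 1L) # poles included
  phi <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  # interior rings x longitudes, plus the two poles
  rings <- theta[-c(1L, n_lat + 1L)]
  grid <- tidyr::expand_grid(theta = rings, phi = phi)
  coords <- rbind(
    c(0, 0, radius),
    cbind(
      radius * sin(grid$theta) * cos(grid$phi),
      radius * sin(grid$theta) * sin(grid$phi),
      radius * cos(grid$theta)
    ),
    c(0, 0, -radius)
  )
  nodes <- tibble(
    node_id = seq_len(nrow(coords)),
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
  ring_id <- function(r, l) 1L + (r - 1L) * n_lon + ((l - 1L) %% n_lon) + 1L
  north <- 1L
  south <- nrow(coords)
  tris <- list()
  for (l in seq_len(n_lon)) { # polar caps
    tris[[length(tris) + 1L]] <- c(north, ring_id(1L, l), ring_id(1L, l + 1L))
    tris[[length(tris) + 1L]] <- c(south, ring_id(n_lat - 1L, l + 1L), ring_id(n_lat - 1L, l))
  }
  if (n_lat > 2L) {
    for (r in seq_len(n_lat - 2L)) {
      for (l in seq_len(n_lon)) {
        a <- ring_id(r, l); b <- ring_id(r, l + 1L)
        cc <- ring_id(r + 1L, l); d <- ring_id(r + 1L, l + 1L)
        tris[[length(tris) + 1L]] <- c(a, b, cc)
        tris[[length(tris) + 1L]] <- c(b, d, cc)
      }
    }
  }
  area <- vapply(tris, function(tr) {
    p <- coords[tr, , drop = FALSE]
    v1 <- p[2, ] - p[1, ]; v2 <- p[3, ] - p[1, ]
    cr <- c(
      v1[2] * v2[3] - v1[3] * v2[2],
      v1[3] * v2[1] - v1[1] * v2[3],
      v1[1] * v2[2] - v1[2] * v2[1]
    )
    0.5 * sqrt(sum(cr^2))
  }, numeric(1))
  elements <- tibble(
    element_id = seq_along(tris), nodes = tris,
    type = "triangle", volume = area # area x unit thickness
  )
  list(nodes = nodes, elements = elements)
}
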