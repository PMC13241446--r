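test_that("synthetic fields are deterministic and shaped by the blob", {
  a <- generate_synthetic_field(dims = c(6, 6, 6), seed = 4, noise_sd = 0.02)
  b <- generate_synthetic_field(dims = c(6, 6, 6), seed = 4, noise_sd = 0.02)
  expect_identical(a$field, b$field)
  other <- generate_synthetic_field(dims = c(6, 6, 6), seed = 5, noise_sd = 0.02)
  expect_false(identical(a$field$w0, other$field$w0))
  # amplitude 0, noise 0: constant background
  flat <- generate_synthetic_field(dims = c(4, 4, 4), seed = 1,
                                   blob_amplitude = 0, noise_sd = 0)
  expect_true(all(flat$field$w0 == 0.05))
  # noise-free field peaks at the node nearest the blob center
  centre <- c(2, 2, 2)
  peaked <- generate_synthetic_field(dims = c(5, 5, 5), seed = 1,
                                     blob_center = centre, noise_sd = 0)
  f <- peaked$field
  d2 <- (f$x - centre[1])^2 + (f$y - centre[2])^2 + (f$z - centre[3])^2
  expect_equal(which.max(f$w0), which.min(d2))
  # field is non-negative even with heavy noise
  noisy <- generate_synthetic_field(dims = c(4, 4, 4), seed = 2, noise_sd = 0.5)
  expect_true(all(noisy$field$w0 >= 0))
  expect_error(generate_synthetic_field(dims = c(1, 4, 4), seed = 1),
               class = "tauavrami_error_invalid")
  expect_error(generate_synthetic_field(dims = c(4, 4, 4)),
               class = "tauavrami_error_invalid")
})

test_that("grid meshes have consistent connectivity and volumes", {
  mesh <- generate_synthetic_field(dims = c(3, 4, 5), spacing = 2, seed = 1)
  expect_equal(nrow(mesh$field), 3 * 4 * 5)
  expect_equal(nrow(mesh$elements), 2 * 3 * 4)
  expect_true(all(lengths(mesh$elements$nodes) == 8))
  expect_true(all(unlist(mesh$elements$nodes) %in% mesh$field$node_id))
  expect_true(all(mesh$elements$volume == 8)) # spacing^3
})

test_that("sphere shells are closed triangulations on the radius", {
  mesh <- generate_synthetic_field("sphere_shell", radius = 5, resolution = 8, seed = 1)
  f <- mesh$field
  r <- sqrt(f$x^2 + f$y^2 + f$z^2)
  expect_equal(r, rep(5, nrow(f)), tolerance = 1e-12)
  expect_true(all(lengths(mesh$elements$nodes) == 3))
  expect_true(all(mesh$elements$volume > 0))
  # Euler characteristic of a closed sphere triangulation: V - E + F = 2
  edges <- unique(do.call(rbind, lapply(mesh$elements$nodes, function(tr) {
    rbind(sort(tr[1:2]), sort(tr[2:3]), sort(tr[c(1, 3)]))
  })))
  expect_equal(nrow(f) - nrow(edges) + nrow(mesh$elements), 2)
})

test_that("CSV fields round-trip at full precision and reject bad headers", {
  mesh <- focal_mesh(dims = c(4, 4, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(mesh$field, path)
  back <- read_field_csv(path)
  expect_equal(back$w0, mesh$field$w0)
  expect_equal(back$node_id, mesh$field$node_id)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,0.5", "2,0.7"), bad)
  expect_error(read_field_csv(bad), class = "tauavrami_error_format")
  expect_error(read_field_csv("no/such/file.csv"), class = "tauavrami_error_format")
})

test_that("VTK unstructured grids round-trip nodes, cells and scalars", {
  mesh <- focal_mesh(dims = c(4, 4, 4))
  path <- withr::local_tempfile(fileext = ".vtu")
  write_field_vtk(mesh$field, mesh$elements, path)
  back <- read_field_vtk(path)
  expect_equal(back$field$w0, mesh$field$w0)
  expect_equal(back$field$x, mesh$field$x)
  expect_equal(back$elements$nodes, mesh$elements$nodes)
  expect_true(all(back$elements$type == "hexahedron"))
  # a second write of the re-read field is byte-identical
  path2 <- withr::local_tempfile(fileext = ".vtu")
  write_field_vtk(back$field, back$elements, path2)
  expect_identical(readLines(path), readLines(path2))
  # custom scalar array names are honored, and missing ones are typed errors
  path3 <- withr::local_tempfile(fileext = ".vtu")
  write_field_vtk(mesh$field, mesh$elements, path3, scalar_name = "strain")
  expect_equal(read_field_vtk(path3, scalar_name = "strain")$field$w0, mesh$field$w0)
  expect_error(read_field_vtk(path3, scalar_name = "MPS"),
               class = "tauavrami_error_format")
})

test_that("tau and atrophy artifacts serialize to VTK and CSV", {
  mesh <- focal_mesh(dims = c(4, 4, 4))
  nf <- normalize_field(mesh$field)
  tf <- tau_map(nf, recovery_truth(), times = c(100, 300))
  dir <- withr::local_tempdir()
  vtks <- write_tau_vtk(tf, mesh$elements, dir)
  expect_length(vtks, 2)
  expect_true(all(file.exists(vtks)))
  round <- read_field_vtk(vtks[2], scalar_name = "tau")
  expect_equal(round$field$w0, unname(tf$tau[, 2]))
  csv <- file.path(dir, "tau.csv")
  write_tau_csv(tf, csv)
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)), 64 * 2)
  st <- file.path(dir, "s.csv")
  write_s_table(tf, st)
  expect_named(readr::read_csv(st, show_col_types = FALSE),
               c("time_days", "ye", "x", "s"))
  mask <- apply_threshold(element_tau(tf, mesh$elements), 0.7)
  mask_files <- write_mask_vtk(mask, nf, mesh$elements, dir)
  expect_length(mask_files, 2)
  raw <- tauavrami:::.read_vtu(mask_files[2])
  expect_length(raw$cells, nrow(mesh$elements))
  expect_equal(sum(raw$cell_data$removed), sum(mask$removed[mask$time_days == 300]))
})

test_that("observation CSVs round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(murine_tbi_observations(), path)
  obs <- read_observations_csv(path)
  expect_equal(obs, murine_tbi_observations())
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(read_observations_csv(bad), class = "tauavrami_error_format")
})
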