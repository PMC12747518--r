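test_that("OFF surfaces round-trip exactly", {
  sph <- fix_icosphere3()
  path <- withr::local_tempfile(fileext = ".off")
  write_mesh(sph, path)
  back <- read_mesh(path, "surface")
  expect_equal(back$vertices, sph$vertices)
  expect_identical(back$faces, sph$faces)
})

test_that("PLY carries per-vertex scalar properties", {
  hemi <- fix_hemisphere()
  vals <- sin(hemi$vertices[, 1] * 3)
  path <- withr::local_tempfile(fileext = ".ply")
  attr(hemi, "vertex_fields") <- list(quality = scalar_field(vals))
  write_mesh(hemi, path)
  surf <- read_mesh(path, "surface")
  expect_equal(surf$vertices, hemi$vertices)
  fld <- read_mesh(path, "field")
  expect_s3_class(fld, "scalar_field")
  expect_length(fld$values, nrow(hemi$vertices))
  expect_equal(fld$values, vals)
})

test_that("STL round-trips vertex positions after dedup", {
  sph <- make_icosphere(2L, 1.3)
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(sph, path)
  back <- read_mesh(path, "surface")
  expect_equal(nrow(back$vertices), nrow(sph$vertices))
  # match by nearest: every original vertex present within 1e-7
  d <- gyralkit:::cross_dist(sph$vertices, back$vertices)
  expect_lt(max(apply(d, 1, min)), 1e-7)
  expect_equal(nrow(back$faces), nrow(sph$faces))
})

test_that("VTK and node/ele tet volumes round-trip", {
  vol <- make_slab_volume(2L, 2L, 2L, 1, 1, 1)
  path <- withr::local_tempfile(fileext = ".vtk")
  write_mesh(vol, path)
  back <- read_mesh(path, "tet")
  expect_equal(back$vertices, vol$vertices)
  expect_identical(back$tets, vol$tets)

  node <- withr::local_tempfile(fileext = ".node")
  gyralkit:::write_node_ele(vol, node)
  back2 <- read_mesh(node, "tet")
  expect_equal(back2$vertices, vol$vertices)
  expect_identical(back2$tets, vol$tets)
})

test_that("CSV fields and JSON landmarks round-trip with validation", {
  f <- scalar_field(c(0.25, -1, 0.5, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_mesh(f, path)
  expect_equal(readLines(path, n = 1L), "vertex_index,value")
  back <- read_mesh(path, "field")
  expect_equal(back$values, f$values)

  lms <- list(landmark_curve(c(1L, 5L, 9L), "a"),
              landmark_curve(c(2L, 3L), "b"))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_mesh(lms, jpath)
  back <- read_mesh(jpath, "landmarks", n_vertices = 10L)
  expect_equal(back[[1]]$vertex_path, c(1L, 5L, 9L))
  expect_equal(back[[2]]$name, "b")
  # out-of-range landmark index is an error
  expect_error(read_mesh(jpath, "landmarks", n_vertices = 5L),
               "out of range")
})

test_that("unsupported kind/format pairings and malformed files error", {
  sph <- fix_icosphere3()
  expect_error(write_mesh(sph, withr::local_tempfile(fileext = ".vtk")),
               "does not support")
  expect_error(write_mesh(scalar_field(1:3),
                          withr::local_tempfile(fileext = ".off")),
               "does not support")
  bad <- withr::local_tempfile(fileext = ".off")
  writeLines(c("OFF", "1 1 0", "0 0 0", "3 0 1 2"), bad)
  expect_error(read_mesh(bad, "surface"))
  expect_error(read_mesh("no/such/file.off", "surface"), "not found")
  # kind mismatch is reported
  off <- withr::local_tempfile(fileext = ".off")
  write_mesh(sph, off)
  expect_error(read_mesh(off, "tet"), "not the requested")
})
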