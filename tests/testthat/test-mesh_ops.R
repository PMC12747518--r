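test_that("validate_surface reports topology by explicit counting", {
  sph <- fix_icosphere3()
  rep_ <- validate_surface(sph)
  expect_equal(rep_$euler_characteristic, 2L)
  expect_equal(rep_$boundary_loop_count, 0L)
  expect_true(rep_$is_edge_manifold)
  expect_true(rep_$is_oriented)
  expect_equal(rep_$genus_if_closed, 0L)
  expect_false(rep_$disk_mappable)

  hemi <- fix_hemisphere()
  rep_h <- validate_surface(hemi)
  expect_equal(rep_h$euler_characteristic, 1L)
  expect_equal(rep_h$boundary_loop_count, 1L)
  expect_true(rep_h$disk_mappable)

  # two triangles glued at a single vertex: chi = 5 - 6 + 2 = 1, but
  # not a disk (the shared vertex is non-manifold; both triangles are
  # their own boundary loop)
  pinch <- tri_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                             c(-1, 0, 0), c(0, -1, 0)),
                       rbind(c(1, 2, 3), c(1, 4, 5)))
  rep_p <- validate_surface(pinch)
  expect_equal(rep_p$boundary_loop_count, 2L)
  expect_false(rep_p$disk_mappable)

  # a genuinely non-manifold edge (three faces on one edge)
  fan <- tri_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                           c(0, -1, 0), c(0, 0, 1)),
                     rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)))
  expect_false(validate_surface(fan)$is_edge_manifold)
})

test_that("Euler characteristic agrees with an independent recount", {
  for (surf in list(fix_icosphere3(), fix_hemisphere(),
                    make_quadric_patch(1, -0.5, 0.5, 12L))) {
    expect_equal(gyralkit:::euler_characteristic(surf),
                 euler_recount(surf))
  }
})

test_that("cut_hemisphere splits exactly at the plane and conserves area", {
  sph <- fix_icosphere3()
  hemi <- cut_hemisphere(sph, c(0, 0, 0), c(1, 0, 0))
  rep_ <- validate_surface(hemi)
  expect_equal(rep_$euler_characteristic, 1L)
  expect_equal(rep_$boundary_loop_count, 1L)
  expect_gte(min(hemi$vertices[, 1]), -1e-12)

  other <- cut_hemisphere(sph, c(0, 0, 0), c(-1, 0, 0))
  a1 <- gyralkit:::surface_area(hemi)
  a2 <- gyralkit:::surface_area(other)
  a0 <- gyralkit:::surface_area(sph)
  expect_lt(abs(a1 + a2 - a0) / a0, 1e-9)

  # an offset, oblique plane still yields a disk
  ob <- cut_hemisphere(sph, c(0.2, 0.1, 0), c(1, 1, 0.5))
  expect_true(validate_surface(ob)$disk_mappable)
  expect_error(cut_hemisphere(sph, c(5, 0, 0), c(1, 0, 0)),
               "does not intersect")
})

test_that("normalize_halflength fixes the x-extent to 2 and is idempotent", {
  ell <- make_icosphere(2L, 1)
  ell$vertices <- sweep(ell$vertices, 2L, c(2, 1, 1), "*")
  nrm <- normalize_halflength(ell)
  expect_equal(max(abs(nrm$vertices[, 1])), 1)
  expect_equal(max(abs(nrm$vertices[, 2])), 0.5, tolerance = 1e-12)
  expect_equal(diff(range(nrm$vertices[, 1])), 2)
  twice <- normalize_halflength(nrm)
  expect_identical(twice$vertices, nrm$vertices)

  # translation only shifts the output, extents unchanged
  sh <- ell
  sh$vertices <- sh$vertices + matrix(rep(c(3, -1, 2), each =
                                            nrow(sh$vertices)), ncol = 3)
  nsh <- normalize_halflength(sh)
  expect_equal(apply(nsh$vertices, 2, function(x) diff(range(x))),
               apply(nrm$vertices, 2, function(x) diff(range(x))))
  empty <- tri_surface(matrix(numeric(0), 0, 3),
                       matrix(integer(0), 0, 3))
  expect_error(normalize_halflength(empty), "empty")
  flatx <- tri_surface(rbind(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                       rbind(c(1, 2, 3)))
  expect_error(normalize_halflength(flatx), "zero")
})
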