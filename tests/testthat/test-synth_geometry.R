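test_that("icosphere has the exact subdivision combinatorics and radius", {
  ico0 <- make_icosphere(0L, 1)
  expect_equal(nrow(ico0$vertices), 12L)
  expect_equal(nrow(ico0$faces), 20L)
  for (s in 0:3) {
    sph <- make_icosphere(s, 2.5)
    expect_equal(nrow(sph$faces), 20L * 4L^s)
    expect_lt(max(abs(sqrt(rowSums(sph$vertices^2)) - 2.5)), 1e-12)
    rep_ <- expect_surface_valid(sph)
    expect_equal(rep_$euler_characteristic, 2L)
    expect_equal(rep_$boundary_loop_count, 0L)
    expect_equal(rep_$genus_if_closed, 0L)
  }
  # outward orientation: positive enclosed volume
  expect_gt(gyralkit:::enclosed_volume(make_icosphere(2L)), 0)
})

test_that("quadric patches realize their analytic principal curvatures", {
  flat <- make_quadric_patch(0, 0, 0.5, 16L)
  expect_true(all(flat$vertices[, 3] == 0))
  rep_ <- expect_surface_valid(flat)
  expect_equal(rep_$euler_characteristic, 1L)
  expect_equal(rep_$boundary_loop_count, 1L)

  # symmetric saddle: analytic mean curvature 0 at the center
  sad <- make_quadric_patch(1, -1, 0.5, 33L)
  cf <- vertex_curvatures(sad)
  ctr <- which.min(rowSums(sad$vertices[, 1:2]^2))
  expect_lt(abs(cf$H[ctr]), 0.02)
  expect_lt(cf$K_gauss[ctr], -0.8)

  # cylindrical ridge: principal curvatures (1, 0) at the center
  rid <- make_quadric_patch(1, 0, 0.5, 33L)
  cfr <- vertex_curvatures(rid)
  ctr <- which.min(rowSums(rid$vertices[, 1:2]^2))
  expect_equal(cfr$H[ctr], 0.5, tolerance = 0.03)
  expect_lt(abs(cfr$K_gauss[ctr]), 0.05)
})

test_that("brain-like solids satisfy the volume invariants and are seeded", {
  vol <- make_brainlike_solid(seed = 1, semi_axes = c(1, 0.8, 0.7),
                              amplitude = 0.05, target_edge = 0.35)
  # brute-force loop over tets: every signed volume positive
  v <- vol$vertices
  for (i in seq_len(nrow(vol$tets))) {
    t_ <- vol$tets[i, ]
    m <- rbind(v[t_[2], ] - v[t_[1], ], v[t_[3], ] - v[t_[1], ],
               v[t_[4], ] - v[t_[1], ])
    expect_gt(det(m), 0)
  }
  bs <- boundary_surface(vol)
  rep_ <- expect_surface_valid(bs$surface)
  expect_equal(rep_$euler_characteristic, 2L)
  expect_equal(rep_$genus_if_closed, 0L)

  # determinism per seed, sensitivity across seeds
  vol_again <- make_brainlike_solid(seed = 1, semi_axes = c(1, 0.8, 0.7),
                                    amplitude = 0.05, target_edge = 0.35)
  expect_identical(vol$vertices, vol_again$vertices)
  expect_identical(vol$tets, vol_again$tets)
  vol2 <- make_brainlike_solid(seed = 2, semi_axes = c(1, 0.8, 0.7),
                               amplitude = 0.05, target_edge = 0.35)
  expect_false(isTRUE(all.equal(vol$vertices, vol2$vertices)))

  # amplitude 0: boundary vertices exactly on the ellipsoid
  vol0 <- make_brainlike_solid(seed = 1, semi_axes = c(1, 0.8, 0.7),
                               amplitude = 0, target_edge = 0.35)
  bs0 <- boundary_surface(vol0)
  r <- sqrt(rowSums(sweep(bs0$surface$vertices, 2,
                          c(1, 0.8, 0.7), "/")^2))
  expect_lt(max(abs(r - 1)), 1e-12)
})

test_that("landmark curves are disjoint seeded edge paths", {
  hemi <- fix_hemisphere()
  lms <- make_landmark_curves(hemi, n_curves = 3L, seed = 7L,
                              min_separation = 0.25)
  expect_length(lms, 3L)
  et <- gyralkit:::edge_table(hemi$faces)
  ekeys <- paste(et$edges[, 1], et$edges[, 2])
  all_verts <- unlist(lapply(lms, function(l) l$vertex_path))
  expect_false(anyDuplicated(all_verts) > 0)  # vertex-disjoint
  for (lc in lms) {
    p <- lc$vertex_path
    expect_false(anyDuplicated(p) > 0)  # simple
    # consecutive vertices share a mesh edge
    steps <- paste(pmin(p[-length(p)], p[-1]), pmax(p[-length(p)], p[-1]))
    expect_true(all(steps %in% ekeys))
  }
  # pairwise separation
  for (a in 1:2) for (b in (a + 1):3) {
    d <- gyralkit:::cross_dist(hemi$vertices[lms[[a]]$vertex_path, ],
                               hemi$vertices[lms[[b]]$vertex_path, ])
    expect_gte(min(d), 0.25)
  }
  # determinism
  lms2 <- make_landmark_curves(hemi, n_curves = 3L, seed = 7L,
                               min_separation = 0.25)
  expect_identical(lapply(lms, `[[`, "vertex_path"),
                   lapply(lms2, `[[`, "vertex_path"))
  # unsatisfiable separation errors out
  expect_error(make_landmark_curves(hemi, n_curves = 10L, seed = 1L,
                                    min_separation = 2, max_retries = 5L),
               "separation")
})

test_that("generated tet meshes are conforming (interior faces shared twice)", {
  for (vol in list(make_slab_volume(3L, 2L, 2L, 1.5, 1, 1),
                   gyralkit:::ball_tet_mesh(2L, c(1, 0.7, 0.45)))) {
    tri <- rbind(vol$tets[, c(1, 3, 2)], vol$tets[, c(1, 2, 4)],
                 vol$tets[, c(2, 3, 4)], vol$tets[, c(1, 4, 3)])
    key <- apply(tri, 1L, function(r) paste(sort.int(r), collapse = " "))
    counts <- table(table(key))
    expect_true(all(names(counts) %in% c("1", "2")))
    expect_gt(min(gyralkit:::tet_signed_volumes(vol)), 0)
  }
})
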