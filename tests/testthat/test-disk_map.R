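test_that("disk parameterization of a hemisphere meets its contracts", {
  hemi <- fix_hemisphere()
  D <- disk_conformal(hemi)
  # boundary on the unit circle
  br <- sqrt(rowSums(D$uv[D$boundary_indices, ]^2))
  expect_lt(max(abs(br - 1)), 1e-6)
  # interior strictly inside
  int <- setdiff(seq_len(nrow(D$uv)), D$boundary_indices)
  expect_lt(max(sqrt(rowSums(D$uv[int, ]^2))), 1)
  # no flipped parameter triangles (brute-force signed areas)
  sa <- gyralkit:::uv_signed_areas(D$uv, hemi$faces)
  expect_gt(min(sa), 0)
  # a smooth hemisphere is nearly conformally flattened
  expect_lt(D$mean_abs_mu, 0.1)
})

test_that("planar disk meshes are reproduced up to rotation", {
  # build a planar triangulated disk from the hemisphere's own uv
  hemi <- fix_hemisphere()
  D <- disk_conformal(hemi)
  flat <- tri_surface(cbind(D$uv, 0), hemi$faces)
  D2 <- disk_conformal(flat)
  br <- sqrt(rowSums(D2$uv[D2$boundary_indices, ]^2))
  expect_lt(max(abs(br - 1)), 1e-6)
  # conformal distortion of re-flattening a flat disk is tiny
  expect_lt(D2$mean_abs_mu, 0.02)
  expect_error(disk_conformal(fix_icosphere3()), "disk-mappable")
})

test_that("Beltrami coefficients of analytic planar maps are exact", {
  hemi <- fix_hemisphere()
  D <- disk_conformal(hemi)
  uv <- D$uv
  f <- hemi$faces
  mu_id <- beltrami_coefficient(uv, uv, f)
  expect_lt(max(Mod(mu_id)), 1e-12)
  # f(z) = 2 z: still conformal
  mu_scale <- beltrami_coefficient(uv, 2 * uv, f)
  expect_lt(max(Mod(mu_scale)), 1e-12)
  # f(z) = z + 0.5 zbar: mu = 0.5 everywhere
  z <- complex(real = uv[, 1], imaginary = uv[, 2])
  w <- z + 0.5 * Conj(z)
  mu_half <- beltrami_coefficient(uv, cbind(Re(w), Im(w)), f)
  expect_lt(max(Mod(mu_half - 0.5)), 1e-10)
  # |mu| < 1 iff orientation preserved: reflection gives |mu| > 1
  mu_refl <- beltrami_coefficient(uv, cbind(uv[, 1], -uv[, 2]), f)
  expect_gt(min(Mod(mu_refl)), 1)
})

test_that("linear Beltrami solver reconstructs prescribed maps", {
  hemi <- fix_hemisphere()
  D <- disk_conformal(hemi)
  uv <- D$uv
  f <- hemi$faces
  nf <- nrow(f)
  b <- D$boundary_indices
  # mu = 0 with full boundary pinned to the identity -> identity
  con <- data.frame(i = b, u = uv[b, 1], v = uv[b, 2], weight = Inf)
  sol <- linear_beltrami_solve(uv, f, rep(complex(real = 0), nf), con)
  expect_lt(max(abs(sol$uv - uv)), 1e-8)

  # recover an affine map from its Beltrami coefficient and two pins
  A <- matrix(c(1.3, 0.2, -0.25, 0.8), 2)
  img <- uv %*% t(A) + matrix(c(0.05, -0.1), nrow(uv), 2, byrow = TRUE)
  mu_aff <- beltrami_coefficient(uv, img, f)
  expect_lt(diff(range(Mod(mu_aff))), 1e-10)  # constant over faces
  pins <- c(b[1], b[round(length(b) / 2)])
  con2 <- data.frame(i = pins, u = img[pins, 1], v = img[pins, 2],
                     weight = Inf)
  sol2 <- linear_beltrami_solve(uv, f, mu_aff, con2)
  expect_lt(max(abs(sol2$uv - img)), 1e-7)

  # smooth random |mu| <= 0.9 fields keep orientation (seeded trials)
  set.seed(31)
  z <- complex(real = uv[, 1], imaginary = uv[, 2])
  zc <- (z[f[, 1]] + z[f[, 2]] + z[f[, 3]]) / 3
  for (trial in 1:20) {
    coef <- complex(real = rnorm(3, sd = 0.3), imaginary =
                      rnorm(3, sd = 0.3))
    mu <- coef[1] + coef[2] * zc + coef[3] * zc^2
    scl <- max(Mod(mu))
    if (scl > 0.9) mu <- mu * (0.9 / scl)
    sol <- linear_beltrami_solve(uv, f, mu, con)
    expect_gt(min(gyralkit:::uv_signed_areas(sol$uv, f)), 0)
  }
  expect_error(linear_beltrami_solve(uv, f,
                                     rep(complex(real = 1.2), nf), con),
               "mu")
})

test_that("landmark-matched maps align curves within tolerance", {
  hemi <- fix_hemisphere()
  D <- disk_conformal(hemi)
  lms <- make_landmark_curves(hemi, n_curves = 2L, seed = 3L,
                              min_separation = 0.3)
  # identity case: same disk, same landmarks
  qm <- landmark_qc_map(D, D, lms, lms, tol = 1e-3, faces1 = hemi$faces)
  expect_true(qm$feasible)
  expect_lt(qm$residual, 1e-3)
  expect_lt(max(abs(qm$image - D$uv)), 1e-4)
  expect_lt(max(Mod(qm$mu)), 1)

  # translated landmark target inside the disk
  D2 <- D
  shift <- c(0.05, -0.03)
  D2$uv <- D$uv
  lm_shift <- lms
  # target curves: synthetic disk positions moved by `shift`; realized
  # by moving the target disk's vertices on those curves
  ids <- unique(unlist(lapply(lms, `[[`, "vertex_path")))
  D2$uv[ids, ] <- D2$uv[ids, ] + matrix(shift, length(ids), 2,
                                        byrow = TRUE)
  qm2 <- landmark_qc_map(D, D2, lms, lm_shift, tol = 5e-3,
                         faces1 = hemi$faces)
  expect_true(qm2$feasible)
  expect_lt(qm2$residual, 5e-3)
  expect_lt(max(Mod(qm2$mu)), 1)
  expect_gt(min(gyralkit:::uv_signed_areas(qm2$image, hemi$faces)), 0)

  # composing with the reverse map returns points near the start
  qm_back <- landmark_qc_map(D2, D, lm_shift, lms, tol = 5e-3,
                             faces1 = hemi$faces)
  loc <- gyralkit:::locate_in_triangulation(qm2$image, D2$uv, hemi$faces,
                                            D2$boundary_indices)
  fb <- qm_back$image
  comp <- loc$bary[, 1] * fb[hemi$faces[loc$face, 1], ] +
    loc$bary[, 2] * fb[hemi$faces[loc$face, 2], ] +
    loc$bary[, 3] * fb[hemi$faces[loc$face, 3], ]
  rt <- sqrt(rowSums((comp - D$uv)^2))
  expect_lt(stats::median(rt), 5e-2)
})

test_that("landmark correspondence is monotone along resampled curves", {
  hemi <- fix_hemisphere()
  D <- disk_conformal(hemi)
  lms <- make_landmark_curves(hemi, n_curves = 1L, seed = 12L,
                              min_separation = 0.3)
  rs <- gyralkit:::resample_polyline(D$uv, lms[[1]]$vertex_path, 20L)
  # samples advance monotonically along the curve's arclength
  seg_pos <- rs$frame$i + rs$frame$t
  cum <- cumsum(c(0, sqrt(rowSums(diff(rs$points)^2))))
  expect_true(all(diff(cum) >= 0))
  expect_equal(rs$points[1, ], D$uv[lms[[1]]$vertex_path[1], ])
  expect_equal(rs$points[20, ],
               D$uv[lms[[1]]$vertex_path[
                 length(lms[[1]]$vertex_path)], ])
})

test_that("pullback reproduces identity, constant and linear fields", {
  hemi <- fix_hemisphere()
  D <- disk_conformal(hemi)
  lms <- make_landmark_curves(hemi, n_curves = 2L, seed = 3L,
                              min_separation = 0.3)
  qm <- landmark_qc_map(D, D, lms, lms, tol = 1e-3, faces1 = hemi$faces)
  vals <- sin(2 * hemi$vertices[, 1]) + hemi$vertices[, 3]
  back <- pullback_field(scalar_field(vals), qm, hemi$faces)
  expect_equal(back$values, vals, tolerance = 1e-3)
  const <- pullback_field(scalar_field(rep(0.7, nrow(hemi$vertices))),
                          qm, hemi$faces)
  expect_equal(const$values, rep(0.7, nrow(hemi$vertices)))
  # a field linear in uv is reproduced exactly under barycentric
  # interpolation, for any qc map image
  lin <- 0.3 * D$uv[, 1] - 1.1 * D$uv[, 2] + 0.2
  qm3 <- qm
  set.seed(4)
  lin_at <- function(p) 0.3 * p[, 1] - 1.1 * p[, 2] + 0.2
  back_lin <- pullback_field(scalar_field(lin), qm3, hemi$faces)
  expect_equal(back_lin$values, lin_at(qm3$image), tolerance = 1e-10)
})
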