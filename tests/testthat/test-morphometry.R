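test_that("discrete curvatures reproduce the analytic sphere", {
  sph <- make_icosphere(4L, 2)
  cf <- vertex_curvatures(sph)
  expect_lt(abs(median(cf$H) - 0.5) / 0.5, 0.02)
  expect_lt(abs(median(cf$K_gauss) - 0.25) / 0.25, 0.02)
  expect_false(any(cf$boundary_mask))
})

test_that("angle defects satisfy Gauss-Bonnet on closed genus-0 meshes", {
  for (surf in list(fix_icosphere3(),
                    boundary_surface(make_brainlike_solid(
                      seed = 3, target_edge = 0.4))$surface)) {
    expect_lt(abs(sum(vertex_curvatures(surf)$angle_defect) - 4 * pi),
              1e-9)
  }
})

test_that("flat patch interiors have vanishing curvature", {
  flat <- make_quadric_patch(0, 0, 0.5, 24L)
  cf <- vertex_curvatures(flat)
  int <- !cf$boundary_mask
  expect_lt(max(abs(cf$H[int])), 1e-9)
  expect_lt(max(abs(cf$K_gauss[int])), 1e-9)
})

test_that("shape_index handles regular, umbilic and planar inputs", {
  expect_equal(as.numeric(shape_index(0.5, 0)), 0.5)     # ridge
  expect_equal(as.numeric(shape_index(1, 1)), 1)         # umbilic cap
  expect_equal(as.numeric(shape_index(-1, 1)), -1)       # umbilic cup
  expect_equal(as.numeric(shape_index(0, -1)), 0)        # saddle
  expect_equal(as.numeric(shape_index(0, 0)), 0)         # plane
  # impossible pair H^2 < K beyond tolerance: clamped to umbilic, flagged
  si <- shape_index(c(0.5, 0.2), c(0.5, 0.01))
  expect_equal(as.numeric(si), c(1, 0.2 * 0 + (2 / pi) *
                                   atan(0.2 / sqrt(0.04 - 0.01))))
  expect_equal(attr(si, "clamped"), 1L)
  # vectorized bounds
  H <- seq(-2, 2, length.out = 41)
  si <- shape_index(H, H^2 - abs(H) - 0.1)
  expect_true(all(abs(si) <= 1))
})

test_that("shape index is scale-invariant and flips with orientation", {
  wavy <- fix_wavy_hemisphere()
  cf <- vertex_curvatures(wavy)
  int <- !cf$boundary_mask
  si <- as.numeric(shape_index(cf$H, cf$K_gauss))
  scaled <- tri_surface(wavy$vertices * 3.7, wavy$faces)
  cfs <- vertex_curvatures(scaled)
  sis <- as.numeric(shape_index(cfs$H, cfs$K_gauss))
  expect_lt(stats::median(abs(si[int] - sis[int])), 1e-6)

  flipped <- tri_surface(wavy$vertices, wavy$faces[, c(1, 3, 2)])
  cff <- vertex_curvatures(flipped)
  expect_equal(cff$H, -cf$H, tolerance = 1e-12)
  sif <- as.numeric(shape_index(cff$H, cff$K_gauss))
  expect_equal(sif[int], -si[int], tolerance = 1e-9)
})

test_that("quadric-family shape indices match the closed form", {
  # brute-force oracle: SI from principal curvatures (a, b) directly
  si_closed <- function(a, b) {
    H <- (a + b) / 2; K <- a * b
    if (abs(a - b) < 1e-12) return(sign(H))
    (2 / pi) * atan(H / sqrt(H^2 - K))
  }
  cases <- list(c(1, 1), c(1, 0.5), c(1, 0), c(1, -0.5), c(1, -1),
                c(0.5, -1), c(0, -1), c(-0.5, -1), c(-1, -1))
  for (ab in cases) {
    p <- make_quadric_patch(ab[1], ab[2], 0.4, 41L)
    cf <- vertex_curvatures(p)
    ctr <- which.min(rowSums(p$vertices[, 1:2]^2))
    si_ctr <- as.numeric(shape_index(cf$H, cf$K_gauss))[ctr]
    expect_equal(si_ctr, si_closed(ab[1], ab[2]), tolerance = 0.05,
                 label = sprintf("SI at center for (a=%g, b=%g)",
                                 ab[1], ab[2]))
  }
})

test_that("rescale_mean_curvature is the exact affine map onto [-1, 1]", {
  expect_equal(rescale_mean_curvature(c(0, 1, 2)), c(-1, 0, 1))
  set.seed(1)
  x <- rnorm(50)
  y <- rescale_mean_curvature(x)
  expect_equal(y[which.min(x)], -1)
  expect_equal(y[which.max(x)], 1)
  expect_error(rescale_mean_curvature(rep(2, 5)), "constant")
  f <- scalar_field(c(3, 5))
  expect_equal(rescale_mean_curvature(f)$values, c(-1, 1))
})

test_that("classify_shape applies the five classes and tie-breaks", {
  si <- c(-0.75, -0.25, 0, 0.25, 0.75, -0.5, 0.5, -1, 1)
  counts <- classify_shape(si)
  expect_equal(sum(counts), length(si))
  expect_equal(unname(counts["sulcal_pit"]), 2L)     # -0.75, -1
  expect_equal(unname(counts["sulcal_saddle"]), 2L)  # -0.25, -0.5
  expect_equal(unname(counts["saddle"]), 1L)         # 0
  expect_equal(unname(counts["gyral_saddle"]), 2L)   # 0.25, +0.5
  expect_equal(unname(counts["gyral_node"]), 2L)     # 0.75, +1
  expect_error(classify_shape(1.5), "outside")
})

test_that("histogram_modes finds constructed modes and sums to one", {
  set.seed(11)
  x <- c(-0.5 + 0.03 * rnorm(600), 0.5 + 0.03 * rnorm(900))
  x <- pmin(pmax(x, -1), 1)
  hm <- histogram_modes(x, n_bins = 64L)
  expect_lt(abs(sum(hm$probabilities) - 1), 1e-12)
  expect_gte(length(hm$modes), 2L)
  top2 <- sort(hm$modes[1:2])
  bw <- 2 / 64
  expect_lt(abs(top2[1] - (-0.5)), bw)
  expect_lt(abs(top2[2] - 0.5), bw)
  expect_gt(hm$mode_heights[1], hm$mode_heights[2] - 1e-12)

  one <- histogram_modes(rep(0.25, 100), n_bins = 32L)
  expect_length(one$modes, 1L)
  expect_error(histogram_modes(numeric(0)), "empty")
})
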