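# Shared fixtures, computed lazily once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

fix_icosphere3 <- function() fixture("ico3", make_icosphere(3L, 1))
fix_icosphere4 <- function() fixture("ico4", make_icosphere(4L, 1))

fix_hemisphere <- function()
  fixture("hemi", cut_hemisphere(make_icosphere(3L, 1), c(0, 0, 0),
                                 c(0, 0, 1)))

# A wavy open surface with non-trivial curvature (perturbed hemisphere),
# for mapping and similarity tests.
fix_wavy_hemisphere <- function() fixture("wavy_hemi", {
  h <- fix_hemisphere()
  v <- h$vertices
  r <- 1 + 0.08 * sin(3 * atan2(v[, 2], v[, 1])) * v[, 3]^2
  tri_surface(v * r, h$faces)
})

# Small tet mesh with seeded vertex jitter for force/energy oracles.
fix_random_tet_mesh <- function() fixture("rand_tets", {
  vol <- make_slab_volume(2L, 2L, 1L, 1, 1, 0.5)  # 24 tets
  set.seed(7)
  v <- vol$vertices + matrix(rnorm(length(vol$vertices), sd = 0.015),
                             ncol = 3)
  tet_volume(v, vol$tets)
})

expect_surface_valid <- function(surface) {
  rep_ <- validate_surface(surface)
  expect_true(rep_$is_edge_manifold)
  expect_true(rep_$is_oriented)
  invisible(rep_)
}

# Independent Euler characteristic recount: naive unique-edge counting
# with a different mechanism (sorted pair strings via apply).
euler_recount <- function(surface) {
  f <- surface$faces
  pairs <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  keys <- unique(apply(t(apply(pairs, 1L, sort)), 1L, paste,
                       collapse = "-"))
  nrow(surface$vertices) - length(keys) + nrow(f)
}
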