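test_that("boundary distance field is exact on the ball", {
  ball <- gyralkit:::ball_tet_mesh(3L, c(1, 0.8, 0.6, 0.4))
  df <- boundary_distance_field(ball)
  bs <- boundary_surface(ball)
  expect_lt(max(abs(df$d[bs$vertex_map])), 1e-12)  # boundary -> 0
  expect_true(all(df$d >= 0))
  expect_true(all(df$d <= 1 + 1e-12))
  ctr <- which(rowSums(ball$vertices^2) == 0)
  edge <- gyralkit:::edge_table(bs$surface$faces)$edges
  mean_edge <- mean(sqrt(rowSums(
    (bs$surface$vertices[edge[, 1], ] -
       bs$surface$vertices[edge[, 2], ])^2)))
  expect_lt(abs(df$d[ctr] - 1), 2 * mean_edge)
  expect_lt(max(abs(sqrt(rowSums(df$n^2)) - 1)), 1e-9)  # unit directions
  # interior directions point inward (towards the center for a ball)
  int <- df$d > 0.05 & rowSums(ball$vertices^2) > 1e-12
  align <- rowSums(df$n[int, ] * (-ball$vertices[int, ] /
                                    sqrt(rowSums(ball$vertices[int, ]^2))))
  # up to faceting error of the discrete sphere
  expect_gt(min(align), 0.75)
  expect_gt(stats::median(align), 0.95)
})

test_that("sigmoid profile matches its closed form", {
  expect_equal(sigmoid_profile(1, 1, 3, 1), 2)  # d = h -> midpoint
  expect_equal(sigmoid_profile(0, 0.5, 2, 5), 5 + (2 - 5) / (1 + exp(-10)))
  d <- seq(0, 1, by = 0.01)
  v <- sigmoid_profile(d, 0.25, 2, 1)
  expect_true(all(diff(v) < 0))  # monotone decreasing for surface > deep
  expect_error(sigmoid_profile(0.1, -1, 2, 1))
})

test_that("growth tensor has the prescribed spectrum and axis", {
  n <- c(1, 2, -0.5); n <- n / sqrt(sum(n^2))
  G <- growth_tensor(1.8, n)
  expect_equal(det(G), 1.8, tolerance = 1e-12)
  expect_lt(max(abs(G %*% n - n)), 1e-15)
  ev <- sort(eigen(G, symmetric = TRUE)$values)
  expect_equal(ev, sort(c(1, sqrt(1.8), sqrt(1.8))), tolerance = 1e-12)
  expect_equal(growth_tensor(1, c(0, 0, 1)), diag(3))
  expect_error(growth_tensor(1.5, c(1, 1, 0)), "unit")
})

test_that("neo-Hookean energy is zero at F = G and non-negative", {
  n <- c(0, 0, 1)
  G <- growth_tensor(1.8, n)
  expect_equal(neo_hookean_energy(G, G, 1, 5), 0)
  lam <- 1.7
  A <- diag(c(lam, 1 / lam, 1))
  expect_equal(neo_hookean_energy(A, diag(3), 1, 5),
               (lam^2 + lam^-2 + 1 - 3) / 2)
  # W >= 0 for random A with det A > 0 (AM-GM: J^{-2/3} tr(A'A) >= 3)
  set.seed(5)
  worst <- Inf
  for (i in 1:10000) {
    A <- matrix(rnorm(9), 3)
    if (det(A) <= 0) A[1, ] <- -A[1, ]
    worst <- min(worst, neo_hookean_energy(A, diag(3), 1, 5))
  }
  expect_gte(worst, 0)
  expect_error(neo_hookean_energy(diag(c(-1, 1, 1)), diag(3), 1, 5),
               "det F")
})

test_that("forces are the exact negative gradient of the total energy", {
  vol <- fix_random_tet_mesh()
  cfg <- growth_config(g_g = 1.4, h0 = 0.3, h_slope = 0,
                       contact_stiffness = 0)
  st <- gyralkit:::init_sim_state(vol, cfg)
  st$profiles <- gyralkit:::profile_fields(st, cfg, 1.3, 1.05, 0.3)
  set.seed(9)
  st$current_vertices <- st$current_vertices +
    matrix(rnorm(length(st$current_vertices), sd = 0.01), ncol = 3)
  ef <- total_energy_and_forces(st, cfg)
  expect_gt(ef$W_total, 0)
  eps <- 1e-6
  set.seed(10)
  picks <- cbind(sample(nrow(vol$vertices), 20L, replace = TRUE),
                 sample(3L, 20L, replace = TRUE))
  for (r in seq_len(nrow(picks))) {
    i <- picks[r, 1]; k <- picks[r, 2]
    stp <- st; stp$current_vertices[i, k] <- st$current_vertices[i, k] + eps
    stm <- st; stm$current_vertices[i, k] <- st$current_vertices[i, k] - eps
    fd <- -(total_energy_and_forces(stp, cfg)$W_total -
              total_energy_and_forces(stm, cfg)$W_total) / (2 * eps)
    expect_lt(abs(fd - ef$forces[i, k]) / max(abs(fd), 1e-8), 1e-5)
  }
})

test_that("energy and forces are translation invariant; contact off when apart", {
  vol <- fix_random_tet_mesh()
  cfg <- growth_config(contact_stiffness = NULL)
  st <- gyralkit:::init_sim_state(vol, cfg)
  ef <- total_energy_and_forces(st, cfg)
  expect_equal(ef$W_contact, 0)  # undeformed slab: no close pairs
  st2 <- st
  st2$current_vertices <- st$current_vertices +
    matrix(rep(c(0.4, -1.2, 2), each = nrow(st$current_vertices)),
           ncol = 3)
  ef2 <- total_energy_and_forces(st2, cfg)
  expect_equal(ef2$W_total, ef$W_total, tolerance = 1e-12)
  expect_lt(max(abs(ef2$forces - ef$forces)), 1e-10)
  # rigid translation of a stress-free state: exactly zero forces
  expect_lt(max(abs(ef$forces)), 1e-10)
})

test_that("inverted elements are reported with their tet index", {
  vol <- fix_random_tet_mesh()
  cfg <- growth_config(contact_stiffness = 0)
  st <- gyralkit:::init_sim_state(vol, cfg)
  # collapse one vertex far through the mesh to invert elements
  st$current_vertices[1, ] <- c(2, 2, 2)
  expect_error(total_energy_and_forces(st, cfg), "inverted element")
})

test_that("relax is a fixed point at g = 1 and decreases energy", {
  vol <- make_brainlike_solid(seed = 4, target_edge = 0.35,
                              amplitude = 0.04)
  cfg <- growth_config()
  st <- gyralkit:::init_sim_state(vol, cfg)
  st2 <- relax(st, cfg)
  expect_lt(max(abs(st2$current_vertices - st$current_vertices)), 1e-6)

  # perturbed slab relaxes with a window-monotone energy trace
  slab <- make_slab_volume(6L, 3L, 2L, 3, 1.5, 1)
  cfgs <- growth_config(contact_stiffness = 0, max_iters = 2000L)
  sts <- gyralkit:::init_sim_state(slab, cfgs)
  set.seed(21)
  sts$current_vertices <- sts$current_vertices +
    matrix(rnorm(length(sts$current_vertices), sd = 0.03), ncol = 3)
  sts2 <- relax(sts, cfgs)
  tr <- sts2$energy_trace
  expect_gt(length(tr), 1)
  expect_lt(tr[length(tr)], tr[1])
  if (length(tr) > 100) {
    w <- length(tr) - 100
    viol <- tr[101:length(tr)] - tr[1:w] * (1 + 1e-6) - 1e-12
    expect_lt(max(viol), 0)
  }
  # no inverted tets at termination
  expect_gt(min(gyralkit:::tet_signed_volumes(
    tet_volume(sts2$current_vertices, slab$tets, validate = FALSE))), 0)
})

test_that("run_growth with no growth and equal moduli returns the input", {
  vol <- make_brainlike_solid(seed = 5, target_edge = 0.4)
  cfg <- growth_config(g_g = 1, g_w = 1, mu_g = 1, mu_w = 1)
  snaps <- run_growth(vol, cfg)
  fin <- snaps[[length(snaps)]]
  expect_lt(max(abs(fin$current_vertices - vol$vertices)), 1e-6)
})

test_that("step-wise protocol resets stored energy at stage boundaries", {
  vol <- make_brainlike_solid(seed = 6, target_edge = 0.4)
  cfg <- growth_config(g_g = 1.2, protocol = "step-wise",
                       stage_times = 0.5, max_g_increment = 0.05,
                       snapshot_times = c(0.5, 1),
                       max_iters = 800L)
  snaps <- run_growth(vol, cfg)
  # a fresh state rebased at t = 0.5 has W = 0 before further growth
  mid <- snaps[[which.min(abs(vapply(snaps, function(s) s$t, 0) - 0.5))]]
  rebased <- gyralkit:::init_sim_state(
    tet_volume(mid$current_vertices, vol$tets), cfg)
  ef <- total_energy_and_forces(rebased, cfg)
  expect_equal(ef$W_total, 0)
  # growth continued afterwards
  fin <- snaps[[length(snaps)]]
  expect_gt(fin$t, 0.99)
})

test_that("boundary surface extraction is outward and area-consistent", {
  vol <- make_brainlike_solid(seed = 2, target_edge = 0.4)
  cfg <- growth_config()
  st <- gyralkit:::init_sim_state(vol, cfg)
  surf <- extract_boundary_surface(st)
  rep_ <- validate_surface(surf)
  expect_equal(rep_$euler_characteristic, 2L)
  expect_equal(rep_$genus_if_closed, 0L)
  expect_gt(gyralkit:::enclosed_volume(surf), 0)  # outward orientation
  # independent area recount
  v <- surf$vertices; f <- surf$faces
  areas <- vapply(seq_len(nrow(f)), function(i) {
    e1 <- v[f[i, 2], ] - v[f[i, 1], ]
    e2 <- v[f[i, 3], ] - v[f[i, 1], ]
    sqrt(sum(pracma::cross(e1, e2)^2)) / 2
  }, 0)
  expect_equal(sum(areas), gyralkit:::surface_area(surf),
               tolerance = 1e-12)
})
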