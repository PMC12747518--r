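# Differential-growth simulator: multiplicative decomposition F = A G,
# compressible neo-Hookean energy on the elastic part, sigmoid
# gray/white profiles in the reference distance to the cortical surface,
# explicit quasi-static relaxation with self-contact, continuous and
# step-wise growth protocols.

#' Growth simulation configuration
#'
#' Collects the material, growth-schedule and solver parameters of the
#' differential-growth model. The tangential growth ratio and the shear
#' modulus both follow a sigmoid profile in the reference distance `d`
#' to the cortical surface, `val_deep + (val_surface - val_deep) /
#' (1 + exp(10 (d/h - 1)))`, with cortical thickness schedule
#' `h(t) = h0 - h_slope * t` on normalized time `t` in `[0, t_end]`.
#' The bulk modulus is `bulk_ratio` times the local shear modulus
#' (modestly compressible tissue).
#'
#' @param g_g areal tangential growth ratio reached at the cortical
#'   surface at `t_end` (the `g` of the growth tensor, `det G = g`;
#'   dimensionless, >= 1). A quoted "growth ratio" of 1.8 in the linear
#'   tangential-expansion convention corresponds to `g_g = 1.8^2`, the
#'   default: at the printed areal value the elastic surface strain
#'   (~0.25) stays below the creasing threshold of an equal-stiffness
#'   bilayer and no folds can form.
#' @param g_w growth ratio reached at the innermost white matter.
#' @param mu_g,mu_w shear moduli of gray and white matter (arbitrary
#'   stress units; their ratio is the stiffness ratio).
#' @param bulk_ratio bulk-to-shear modulus ratio K/mu.
#' @param h0,h_slope normalized cortical thickness schedule
#'   `h(t) = h0 - h_slope * t`; for the step-wise protocol these may be
#'   vectors with one entry per stage.
#' @param protocol `"continuous"` or `"step-wise"`.
#' @param stage_times for the step-wise protocol, interior times at
#'   which the current geometry is adopted as the new stress-free
#'   reference.
#' @param t_end final normalized time.
#' @param snapshot_times times at which states are recorded (always
#'   includes `t_end`).
#' @param max_g_increment largest increase of the surface growth ratio
#'   applied between relaxations (quasi-static stepping).
#' @param damping velocity damping per explicit step, in (0, 1).
#' @param dt explicit step size; `NULL` for an automatic CFL-style
#'   estimate from element size and wave speed.
#' @param contact_stiffness,contact_range self-contact penalty stiffness
#'   and activation distance; `NULL` for mesh-scaled defaults (a penalty
#'   range of 0.6 of the mean boundary edge).
#' @param max_iters relaxation iteration cap per growth increment.
#' @param force_tol residual force threshold; `NULL` for a mesh-scaled
#'   default.
#' @param energy_rtol relative energy-plateau threshold per 100
#'   iterations; reaching it also counts as converged.
#' @param perturb seeded symmetry-breaking noise added to the free
#'   vertices before each relaxation, as a fraction of the mean
#'   boundary edge (scaled down automatically if it would invert an
#'   element); the crease instability is subcritical and a smooth
#'   compressed state is a (meta)stable equilibrium, so folds need a
#'   finite seed to nucleate.
#' @param growth_mask optional per-vertex factor in `[0, 1]` damping the
#'   local growth (1 = full growth, 0 = non-growing region).
#' @param fixed_vertices optional vertex indices clamped in place.
#' @param seed integer seed recorded in manifests.
#' @return an object of class `growth_config`.
#' @export
growth_config <- function(g_g = 1.8^2, g_w = 1, mu_g = 1, mu_w = 1,
                          bulk_ratio = 5, h0 = 0.1, h_slope = 0.005,
                          protocol = c("continuous", "step-wise"),
                          stage_times = numeric(0), t_end = 1,
                          snapshot_times = NULL, max_g_increment = 0.05,
                          damping = 0.05, dt = NULL,
                          contact_stiffness = NULL, contact_range = NULL,
                          max_iters = 4000L, force_tol = NULL,
                          energy_rtol = 1e-8, perturb = 0.15,
                          growth_mask = NULL, fixed_vertices = integer(0),
                          seed = 1L) {
  protocol <- match.arg(protocol)
  stopifnot(g_g >= 1, g_w > 0, g_g >= g_w, mu_g > 0, mu_w > 0,
            bulk_ratio > 0, t_end > 0, max_g_increment > 0,
            damping > 0, damping < 1)
  n_stages <- if (protocol == "step-wise") length(stage_times) + 1L else 1L
  h0 <- rep_len(h0, n_stages)
  h_slope <- rep_len(h_slope, n_stages)
  tt <- seq(0, t_end, length.out = 101)
  stage_of <- pmax(1L, findInterval(tt, c(0, stage_times),
                                    rightmost.closed = TRUE))
  hmin <- min(h0[stage_of] - h_slope[stage_of] * tt)
  if (hmin <= 0) stop("cortical thickness h(t) <= 0 within the schedule")
  if (length(stage_times) &&
        (any(diff(c(0, stage_times, t_end)) <= 0)))
    stop("stage_times must be increasing and inside (0, t_end)")
  structure(list(g_g = g_g, g_w = g_w, mu_g = mu_g, mu_w = mu_w,
                 bulk_ratio = bulk_ratio, h0 = h0, h_slope = h_slope,
                 protocol = protocol, stage_times = stage_times,
                 t_end = t_end, snapshot_times = snapshot_times,
                 max_g_increment = max_g_increment, damping = damping,
                 dt = dt, contact_stiffness = contact_stiffness,
                 contact_range = contact_range,
                 max_iters = as.integer(max_iters), force_tol = force_tol,
                 energy_rtol = energy_rtol, perturb = perturb,
                 growth_mask = growth_mask,
                 fixed_vertices = as.integer(fixed_vertices),
                 seed = as.integer(seed)),
            class = "growth_config")
}

#' Sigmoid gray/white profile
#'
#' `val_deep + (val_surface - val_deep) / (1 + exp(10 (d/h - 1)))`: a
#' smoothed step centered one cortical thickness below the surface, with
#' the surface value attained (to within `1/(1+e^10)`) at `d = 0` and
#' the deep value in the white-matter interior.
#'
#' @param d distance to the cortical surface (vectorized).
#' @param h cortical thickness, positive.
#' @param val_surface,val_deep values at surface and depth.
#' @return numeric vector.
#' @export
sigmoid_profile <- function(d, h, val_surface, val_deep) {
  stopifnot(h > 0, all(d >= -1e-12))
  val_deep + (val_surface - val_deep) / (1 + exp(10 * (d / h - 1)))
}

#' Tangential growth tensor
#'
#' `G = sqrt(g) I + (1 - sqrt(g)) n %o% n`: isotropic area growth by
#' factor `g` in the plane perpendicular to `n`, no growth along `n`.
#' Eigenvalues are `(sqrt(g), sqrt(g), 1)`, `G n = n`, `det G = g`.
#'
#' @param g growth ratio, positive.
#' @param n unit vector (the growth-normal direction).
#' @return a 3x3 matrix.
#' @export
growth_tensor <- function(g, n) {
  stopifnot(g > 0)
  if (abs(sum(n^2) - 1) > 1e-8) stop("n must be a unit vector")
  sqrt(g) * diag(3) + (1 - sqrt(g)) * tcrossprod(n)
}

#' Neo-Hookean strain energy density with growth
#'
#' `W = mu/2 (J_A^{-2/3} tr(A'A) - 3) + K/2 (J_A - 1)^2` with
#' `A = F G^{-1}` the elastic part of the deformation gradient and
#' `J_A = det A`; zero exactly when `F = G` and non-negative otherwise.
#'
#' @param F,G 3x3 deformation gradient and growth tensor.
#' @param mu shear modulus.
#' @param K_bulk bulk modulus.
#' @return energy density (scalar).
#' @export
neo_hookean_energy <- function(F, G, mu, K_bulk) {
  if (det(F) <= 0) stop("det F <= 0")
  if (det(G) <= 0) stop("det G <= 0")
  A <- F %*% solve(G)
  J <- det(A)
  if (J <= 0) stop("det A <= 0")
  mu / 2 * (J^(-2 / 3) * sum(A * A) - 3) + K_bulk / 2 * (J - 1)^2
}

#' Distance and growth-normal direction field
#'
#' For every vertex of a tet volume, the exact Euclidean distance to the
#' boundary surface in the reference configuration and the unit inward
#' direction of its gradient (the direction to the nearest boundary
#' point). Boundary vertices get `d = 0` and the inward surface normal.
#'
#' @param volume a [tet_volume()].
#' @return list with `d` (per-vertex distance) and `n` (per-vertex unit
#'   direction matrix).
#' @export
boundary_distance_field <- function(volume) {
  bs <- boundary_surface(volume)
  res <- surface_distance_cpp(volume$vertices, bs$surface$vertices,
                              bs$surface$faces)
  d <- res$distance
  n <- volume$vertices - res$closest
  len <- sqrt(rowSums(n^2))
  small <- len < 1e-9
  n[!small, ] <- n[!small, , drop = FALSE] / len[!small]
  if (any(small)) {
    # on (or numerically at) the boundary: use the inward surface normal
    vn <- vertex_normals(bs$surface)
    near_local <- max.col(-cross_dist(volume$vertices[small, ,
                                                      drop = FALSE],
                                      bs$surface$vertices))
    n[small, ] <- -vn[near_local, , drop = FALSE]
  }
  d[d < 0] <- 0
  list(d = d, n = n)
}

# --- Simulation state -----------------------------------------------------

# Build the stress-free state for a (possibly rebased) reference
# configuration: element shape matrices, lumped masses, per-tet distance
# and growth-normal direction at the tet centroid, contact tables and
# solver scales.
init_sim_state <- function(volume, config, current = NULL) {
  shp <- tet_shape_cpp(volume$vertices, volume$tets)
  nt <- nrow(volume$tets)
  nv <- nrow(volume$vertices)
  centroids <- (volume$vertices[volume$tets[, 1], , drop = FALSE] +
                  volume$vertices[volume$tets[, 2], , drop = FALSE] +
                  volume$vertices[volume$tets[, 3], , drop = FALSE] +
                  volume$vertices[volume$tets[, 4], , drop = FALSE]) / 4
  bs <- boundary_surface(volume)
  res <- surface_distance_cpp(centroids, bs$surface$vertices,
                              bs$surface$faces)
  d_tet <- pmax(res$distance, 0)
  n_tet <- centroids - res$closest
  len <- sqrt(rowSums(n_tet^2))
  bad <- len < 1e-9
  n_tet[!bad, ] <- n_tet[!bad, , drop = FALSE] / len[!bad]
  if (any(bad)) n_tet[bad, ] <- matrix(rep(c(0, 0, 1), sum(bad)),
                                       ncol = 3, byrow = TRUE)
  # Dynamic-relaxation mass scaling: masses are arbitrary in a
  # quasi-static solve, so use stiffness-proportional lumped masses that
  # equalize nodal frequencies (k_e ~ (K + 4/3 mu) V_e / h_e^2 with h_e
  # the smallest element altitude), giving a mesh-independent stable
  # step near dt = 1.
  fa <- tet_face_areas_max(volume)
  alt <- 3 * shp$vol / fa
  mu_ref <- max(config$mu_g, config$mu_w)
  k_tet <- (config$bulk_ratio + 4 / 3) * mu_ref * shp$vol / alt^2
  mass <- rowsum_vec(rep(k_tet / 4, 4), as.vector(volume$tets), nv)
  # growth mask averaged onto tets
  mask_tet <- if (is.null(config$growth_mask)) rep(1, nt) else
    rowMeans(matrix(config$growth_mask[volume$tets], nt, 4))
  # mesh scales for solver defaults
  be <- edge_table(bs$surface$faces)$edges
  bedge <- mean(sqrt(rowSums((bs$surface$vertices[be[, 1], , drop = FALSE] -
                                bs$surface$vertices[be[, 2],
                                                    , drop = FALSE])^2)))
  barea <- mean(face_areas(bs$surface))
  mu_max <- max(config$mu_g, config$mu_w)
  contact_range <- config$contact_range %||% (0.6 * bedge)
  contact_stiffness <- config$contact_stiffness %||% (2 * mu_max * bedge)
  force_tol <- config$force_tol %||% (1e-3 * mu_max * barea)
  # with mass scaling the stable step is O(1) in mesh units
  dt <- config$dt %||% 0.3
  # contact exclusion: 1-ring on the boundary surface (volume indices)
  adj <- boundary_one_ring(bs)
  fixed <- logical(nv)
  fixed[config$fixed_vertices] <- TRUE
  state <- list(
    mean_boundary_edge = bedge,
    reference_vertices = volume$vertices,
    current_vertices = current %||% volume$vertices,
    volume = volume, DmInv = shp$DmInv, vol_ref = shp$vol,
    d_tet = d_tet, n_tet = n_tet, mass = mass, mask_tet = mask_tet,
    boundary = bs, contact = list(
      bverts = adj$bverts, btris = bs$vertex_map[bs$surface$faces],
      excl_ptr = adj$ptr, excl_idx = adj$idx,
      range = contact_range, stiffness = contact_stiffness),
    dt = dt, force_tol = force_tol, fixed = fixed,
    g_tet = rep(1, nt), mu_tet = rep(max(config$mu_w), nt),
    t = 0, W_total = 0, energy_trace = numeric(0))
  dim(state$contact$btris) <- dim(bs$surface$faces)
  class(state) <- "sim_state"
  state
}

# CSR adjacency: for each boundary vertex, itself plus its boundary
# 1-ring, in volume vertex indices (used to exclude self-contact with
# incident and neighboring triangles).
boundary_one_ring <- function(bs) {
  f <- bs$surface$faces
  he <- halfedges(f)
  nb <- nrow(bs$surface$vertices)
  nbrs <- split(bs$vertex_map[he[, 2]], he[, 1])
  ptr <- integer(nb + 1L)
  idx <- vector("list", nb)
  for (i in seq_len(nb)) {
    key <- as.character(i)
    ring <- unique(c(bs$vertex_map[i], nbrs[[key]]))
    idx[[i]] <- ring
    ptr[i + 1L] <- ptr[i] + length(ring)
  }
  list(bverts = bs$vertex_map, ptr = ptr, idx = unlist(idx))
}

# max face area per tet (vectorized)
tet_face_areas_max <- function(volume) {
  v <- volume$vertices; t_ <- volume$tets
  tri_area <- function(a, b, c) {
    e1 <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    e2 <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
    n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    0.5 * sqrt(rowSums(n^2))
  }
  pmax(tri_area(t_[, 1], t_[, 2], t_[, 3]),
       tri_area(t_[, 1], t_[, 2], t_[, 4]),
       tri_area(t_[, 1], t_[, 3], t_[, 4]),
       tri_area(t_[, 2], t_[, 3], t_[, 4]))
}

# Per-tet inverse growth tensors (nt x 9, row-major) and det G, from
# per-tet growth ratios g and directions n: G^{-1} = g^{-1/2} I +
# (1 - g^{-1/2}) n n'.
growth_tensor_inverse_rows <- function(g, n) {
  s <- 1 / sqrt(g)
  nt <- length(g)
  Ginv <- matrix(0, nt, 9)
  for (i in 1:3) for (j in 1:3) {
    Ginv[, 3 * (i - 1) + j] <- (1 - s) * n[, i] * n[, j] +
      if (i == j) s else 0
  }
  list(Ginv = Ginv, detG = g)
}

# Growth and modulus profiles of a state at scheduled values.
profile_fields <- function(state, config, g_surf, g_deep, h) {
  g <- sigmoid_profile(state$d_tet, h, g_surf, g_deep)
  g <- 1 + (g - 1) * state$mask_tet
  mu <- sigmoid_profile(state$d_tet, h, config$mu_g, config$mu_w)
  list(g = g, mu = mu)
}

#' Total energy and nodal forces of a simulation state
#'
#' Sums the per-element neo-Hookean energy (reference volume times
#' growth Jacobian as the integration weight) and the self-contact
#' penalty, and returns the exact negative gradient with respect to the
#' current vertex positions. Rigid translations leave both unchanged.
#'
#' @param state a `sim_state` (see [run_growth()]).
#' @param config the [growth_config()] in force.
#' @return list with `W_total`, `W_elastic`, `W_contact`, `forces`
#'   (n x 3), and `min_detF`.
#' @export
total_energy_and_forces <- function(state, config) {
  pf <- state$profiles %||% profile_fields(state, config, 1, 1,
                                           config$h0[1])
  gt <- growth_tensor_inverse_rows(pf$g, state$n_tet)
  weight <- state$vol_ref * gt$detG
  res <- energy_forces_cpp(state$current_vertices, state$volume$tets,
                           state$DmInv, weight, pf$mu,
                           config$bulk_ratio * pf$mu, gt$Ginv,
                           state$contact)
  if (!is.finite(res$W_elastic))
    stop("inverted element encountered at tet ", res$bad_tet)
  res
}

#' Relax a simulation state to quasi-static equilibrium
#'
#' Damped explicit iteration (velocity-scaled dissipation) until the
#' maximal nodal force drops below `force_tol` or `max_iters` is
#' reached. A window safeguard rejects steps that would raise the energy
#' above its value 100 iterations earlier (beyond 1e-6 relative),
#' halving the step size instead, so the recorded energy trace is
#' non-increasing across any 100-iteration window and no element
#' inverts. Persistent divergence is reported with the last stable state
#' retained.
#'
#' @param state a `sim_state`.
#' @param config the [growth_config()] in force.
#' @return the updated `sim_state` (with `energy_trace`, `W_total`,
#'   `converged` fields refreshed).
#' @export
relax <- function(state, config) {
  pf <- state$profiles %||% profile_fields(state, config, 1, 1,
                                           config$h0[1])
  gt <- growth_tensor_inverse_rows(pf$g, state$n_tet)
  weight <- state$vol_ref * gt$detG
  res <- relax_cpp(state$current_vertices, state$volume$tets, state$DmInv,
                   weight, pf$mu, config$bulk_ratio * pf$mu, gt$Ginv,
                   state$mass, state$fixed, state$contact,
                   state$dt, config$damping, state$force_tol,
                   config$max_iters, 10L, 100L, 1e-6,
                   config$energy_rtol %||% 1e-8)
  if (res$diverged)
    warning("relaxation diverged; returning last stable state")
  state$current_vertices <- res$x_best
  state$W_total <- res$W_final
  state$energy_trace <- res$energy_trace
  state$converged <- res$converged
  state$profiles <- pf
  state
}

#' Run the growth protocol
#'
#' Ramps the tangential growth from 1 to its configured targets over
#' normalized time, relaxing to quasi-static equilibrium after each
#' increment of at most `max_g_increment` in the surface growth ratio.
#' Under the continuous protocol the reference configuration is the
#' initial geometry throughout. Under the step-wise protocol, at each
#' `stage_time` the current geometry is adopted as the new stress-free
#' reference: element shape matrices, the distance field and the growth
#' direction are recomputed on the deformed mesh, accumulated growth is
#' reset (so the stored elastic energy is exactly zero), and growth
#' resumes with the next stage's thickness schedule; each of `k` stages
#' applies a `g^(dt_stage/t_end)` multiplicative share of the total
#' growth.
#'
#' @param volume a [tet_volume()], the initial (stress-free) geometry.
#' @param config a [growth_config()].
#' @param verbose print per-increment progress.
#' @return list of `sim_state` snapshots (at `snapshot_times` and stage
#'   boundaries; always including the final state), each carrying its
#'   time `t`, energy and energy trace.
#' @export
run_growth <- function(volume, config, verbose = FALSE) {
  stopifnot(inherits(volume, "tet_volume"), inherits(config,
                                                     "growth_config"))
  stage_bounds <- c(0, config$stage_times, config$t_end)
  snap_times <- sort(unique(c(config$snapshot_times, config$t_end)))
  snapshots <- list()
  state <- init_sim_state(volume, config)
  n_stages <- length(stage_bounds) - 1L
  for (stage in seq_len(n_stages)) {
    t0 <- stage_bounds[stage]
    t1 <- stage_bounds[stage + 1L]
    if (stage > 1L) {
      # rebase: deformed geometry becomes the new stress-free reference
      newvol <- tet_volume(state$current_vertices, volume$tets)
      state <- init_sim_state(newvol, config)
      state$t <- t0
    }
    # stage growth: multiplicative share of the total ratio
    frac <- (t1 - t0) / config$t_end
    g_g_stage <- config$g_g^frac
    g_w_stage <- config$g_w^frac
    n_inc <- max(1L, ceiling((g_g_stage - 1) / config$max_g_increment))
    for (inc in seq_len(n_inc)) {
      a <- inc / n_inc
      t_now <- t0 + a * (t1 - t0)
      h <- config$h0[stage] - config$h_slope[stage] * t_now
      g_surf <- 1 + a * (g_g_stage - 1)
      g_deep <- 1 + a * (g_w_stage - 1)
      state$profiles <- profile_fields(state, config, g_surf, g_deep, h)
      pert <- config$perturb %||% 0
      # the noise exists to break symmetry under growth; a no-growth
      # relaxation must return the input geometry untouched
      if (max(abs(state$profiles$g - 1)) < 1e-12) pert <- 0
      if (pert > 0) {
        amp <- pert * state$mean_boundary_edge
        noise <- with_seed(config$seed * 10000L + stage * 100L + inc,
                           matrix(stats::runif(3L * nrow(
                             state$current_vertices), -amp, amp),
                             ncol = 3))
        noise[state$fixed, ] <- 0
        # never let the symmetry-breaking noise invert an element
        for (halve in 1:12) {
          cand <- state$current_vertices + noise
          sv <- tet_signed_volumes(tet_volume(cand, state$volume$tets,
                                              validate = FALSE))
          if (min(sv) > 0) {
            state$current_vertices <- cand
            break
          }
          noise <- noise / 2
        }
      }
      state <- relax(state, config)
      state$t <- t_now
      if (verbose)
        message(sprintf(
          "stage %d inc %d/%d t=%.3f g_surf=%.3f W=%.5g iters=%d",
          stage, inc, n_inc, t_now, g_surf, state$W_total,
          length(state$energy_trace)))
      hit <- snap_times[snap_times > t0 + (a - 1 / n_inc) * (t1 - t0) +
                          1e-12 & snap_times <= t_now + 1e-12]
      if (length(hit) || inc == n_inc) {
        snapshots[[length(snapshots) + 1L]] <- state
      }
    }
  }
  snapshots
}

#' Extract the boundary surface of a simulation state
#'
#' Boundary triangles of the tet mesh at the current (deformed) vertex
#' positions, outward-oriented.
#'
#' @param state a `sim_state`.
#' @return a [tri_surface()].
#' @export
extract_boundary_surface <- function(state) {
  boundary_surface(state$volume, state$current_vertices)$surface
}

#' @export
print.sim_state <- function(x, ...) {
  cat("sim_state: t =", format(x$t, digits = 4), "| vertices =",
      nrow(x$current_vertices), "| tets =", nrow(x$volume$tets),
      "| W =", format(x$W_total, digits = 6), "\n")
  invisible(x)
}
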