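# Seeded generators for all input geometry: brain-like solids, analytic
# curvature test patches, landmark curves. Every downstream stage of the
# package is testable from these without external data.

# Run code with a local, seeded RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Icosphere: subdivided icosahedron projected to a sphere
#'
#' The workhorse closed genus-0 fixture. Subdivision `s` gives
#' `20 * 4^s` faces; all vertices lie exactly at distance `radius` from
#' the origin and faces are counterclockwise seen from outside.
#'
#' @param subdivisions non-negative integer, at most 7.
#' @param radius sphere radius.
#' @return a [tri_surface()].
#' @export
make_icosphere <- function(subdivisions = 3L, radius = 1) {
  stopifnot(subdivisions >= 0L, subdivisions <= 7L, radius > 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    sub <- subdivide_midpoint(v, f)
    v <- sub$vertices / sqrt(rowSums(sub$vertices^2))
    f <- sub$faces
  }
  tri_surface(v * radius, f)
}

# One 1-to-4 midpoint subdivision; midpoints shared across faces.
subdivide_midpoint <- function(v, f) {
  he <- cbind(as.vector(f[, c(1, 2, 3)]), as.vector(f[, c(2, 3, 1)]))
  lo <- pmin(he[, 1], he[, 2]); hi <- pmax(he[, 1], he[, 2])
  key <- paste(lo, hi)
  first <- !duplicated(key)
  mid_id <- match(key, key[first]) + nrow(v)
  mids <- (v[lo[first], , drop = FALSE] + v[hi[first], , drop = FALSE]) / 2
  nf <- nrow(f)
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m31 <- mid_id[2L * nf + seq_len(nf)]
  faces <- rbind(cbind(f[, 1], m12, m31),
                 cbind(f[, 2], m23, m12),
                 cbind(f[, 3], m31, m23),
                 cbind(m12, m23, m31))
  list(vertices = rbind(v, mids), faces = faces)
}

#' Analytic quadric test patch
#'
#' Generates the graph `z = (a*x^2 + b*y^2)/2` over a square, an open
#' surface whose principal curvatures at the center are exactly `(a, b)`
#' with respect to the upward (+z, outward) normal. Choosing the signs of
#' `(a, b)` realizes each shape-index class (cap, ridge, saddle, rut,
#' cup, plane) analytically.
#'
#' @param a,b principal curvatures at the center (1/length).
#' @param halfwidth half the side length of the sampled square.
#' @param resolution vertices per side, at least 8.
#' @return an open [tri_surface()] with Euler characteristic 1.
#' @export
make_quadric_patch <- function(a, b, halfwidth = 0.5, resolution = 32L) {
  stopifnot(resolution >= 8L, halfwidth > 0)
  s <- seq(-halfwidth, halfwidth, length.out = resolution)
  g <- expand.grid(x = s, y = s)
  z <- (a * g$x^2 + b * g$y^2) / 2
  v <- cbind(g$x, g$y, z)
  idx <- function(i, j) (j - 1L) * resolution + i
  i <- rep(seq_len(resolution - 1L), resolution - 1L)
  j <- rep(seq_len(resolution - 1L), each = resolution - 1L)
  # Outward normal is -z: the graph z = (a x^2 + b y^2)/2 is convex
  # toward -z, so with this orientation the center's principal
  # curvatures w.r.t. the outward normal are exactly (a, b).
  f <- rbind(cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i + 1L, j)),
             cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j + 1L)))
  tri_surface(v, f)
}

# --- Layered ball tetrahedralization -------------------------------------

# The 6 symmetries of a triangular prism (V1V2V3 bottom, V4V5V6 top) that
# preserve the quad faces; used to rotate the global minimum to slot 1.
prism_perms <- rbind(
  c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4), c(3, 1, 2, 6, 4, 5),
  c(4, 6, 5, 1, 3, 2), c(5, 4, 6, 2, 1, 3), c(6, 5, 4, 3, 2, 1))

# Split prisms (rows of a 6-column global-index matrix) into 3 tets each,
# with quad diagonals through the smallest global index so that adjacent
# prisms conform.
split_prisms <- function(P) {
  n <- nrow(P)
  tets <- matrix(0L, 3L * n, 4L)
  for (i in seq_len(n)) {
    p <- P[i, ]
    rot <- prism_perms[which.max(apply(prism_perms, 1L,
                                       function(pr) p[pr[1]] == min(p))), ]
    q <- p[rot]
    if (min(q[2], q[6]) < min(q[3], q[5])) {
      t3 <- rbind(q[c(1, 2, 3, 6)], q[c(1, 2, 6, 5)], q[c(1, 5, 6, 4)])
    } else {
      t3 <- rbind(q[c(1, 2, 3, 5)], q[c(1, 5, 3, 6)], q[c(1, 5, 6, 4)])
    }
    tets[(3L * i - 2L):(3L * i), ] <- t3
  }
  tets
}

# Tet mesh of the unit ball: concentric icosphere shells at the given
# radii (decreasing, first must be 1) joined by prisms, innermost shell
# coned to a center vertex. Tets are reoriented to positive volume.
ball_tet_mesh <- function(subdivisions, radii) {
  stopifnot(abs(radii[1] - 1) < 1e-12, all(diff(radii) < 0),
            all(radii > 0))
  sph <- make_icosphere(subdivisions, 1)
  nv <- nrow(sph$vertices)
  nshell <- length(radii)
  verts <- do.call(rbind, lapply(radii, function(r) sph$vertices * r))
  verts <- rbind(verts, c(0, 0, 0))
  center <- nrow(verts)
  tets <- vector("list", nshell)
  for (k in seq_len(nshell - 1L)) {
    off_out <- (k - 1L) * nv
    off_in <- k * nv
    prisms <- cbind(sph$faces + off_out, sph$faces + off_in)
    tets[[k]] <- split_prisms(prisms)
  }
  inner <- sph$faces + (nshell - 1L) * nv
  tets[[nshell]] <- cbind(center, inner)
  tets <- do.call(rbind, tets)
  vol <- tet_volume(verts, tets, validate = FALSE)
  sv <- tet_signed_volumes(vol)
  flip <- sv < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  tet_volume(verts, tets)
}

# Real spherical harmonics Y_lm evaluated at unit directions (rows of U),
# for l = 1..lmax, all m; returns a matrix with one column per (l, m).
real_sph_harm <- function(U, lmax) {
  ct <- pmin(pmax(U[, 3], -1), 1)
  phi <- atan2(U[, 2], U[, 1])
  cols <- list()
  for (l in seq_len(lmax)) {
    P <- pracma::legendre(l, ct)  # (l+1) x n, rows m = 0..l
    for (m in 0:l) {
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      base <- nrm * P[m + 1L, ]
      if (m == 0) {
        cols[[length(cols) + 1L]] <- base
      } else {
        cols[[length(cols) + 1L]] <- sqrt(2) * base * cos(m * phi)
        cols[[length(cols) + 1L]] <- sqrt(2) * base * sin(m * phi)
      }
    }
  }
  do.call(cbind, cols)
}

#' Brain-like synthetic solid
#'
#' A tetrahedralized smooth genus-0 solid emulating a smooth fetal brain:
#' an ellipsoid whose boundary is perturbed by a seeded band-limited
#' radial field (a mixture of real spherical harmonics up to degree
#' `n_modes`, scaled so the maximal radial displacement equals
#' `amplitude * min(semi_axes)`). The perturbation decays quadratically
#' toward the center so interior tets stay positively oriented. The mesh
#' is a layered icosphere ball (concentric shells joined by prisms split
#' into conforming tets, innermost shell coned to the center). Purely
#' deterministic per seed.
#'
#' @param seed integer RNG seed for the perturbation coefficients.
#' @param semi_axes three positive semi-axes, longitudinal (x) first.
#' @param n_modes highest spherical-harmonic degree of the perturbation.
#' @param amplitude perturbation amplitude as a fraction of the smallest
#'   semi-axis; must be below 0.2.
#' @param target_edge requested boundary edge length (same units as
#'   `semi_axes`); controls the icosphere subdivision level and the
#'   radial shell spacing.
#' @param subdivisions optional explicit icosphere subdivision level,
#'   overriding the one derived from `target_edge`.
#' @param radii optional explicit radial shell sequence (decreasing,
#'   starting at 1), overriding the `target_edge`-derived layering.
#' @return a [tet_volume()] with genus-0 boundary and positive tets.
#' @export
make_brainlike_solid <- function(seed, semi_axes = c(1, 0.75, 0.65),
                                 n_modes = 4L, amplitude = 0.05,
                                 target_edge = 0.2, subdivisions = NULL,
                                 radii = NULL) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0),
            amplitude >= 0, amplitude < 0.2, target_edge > 0)
  subdiv <- subdivisions %||%
    max(1L, min(6L, ceiling(log2(1.0515 * max(semi_axes) / target_edge))))
  if (is.null(radii)) {
    # Radial shells: near-surface spacing ~ target_edge, coarsening
    # inward; the remaining core is coned to the center.
    delta <- target_edge / mean(semi_axes)
    radii <- 1
    r <- 1; step <- delta
    while (r - step > 0.3) {
      r <- r - step
      radii <- c(radii, r)
      step <- step * 1.4
    }
  }
  ball <- ball_tet_mesh(subdiv, radii)
  u <- ball$vertices
  ru <- sqrt(rowSums(u^2))
  dir <- u / ifelse(ru > 0, ru, 1)
  x <- sweep(u, 2L, semi_axes, "*")
  if (amplitude > 0 && n_modes >= 1L) {
    coef <- with_seed(seed, stats::rnorm((n_modes + 1L)^2 - 1L))
    Y <- real_sph_harm(dir, n_modes)
    gfun <- as.vector(Y %*% coef)
    gfun <- gfun / max(abs(gfun))
    bump <- amplitude * min(semi_axes) * gfun * ru^2
    x <- x + dir * bump
  }
  vol <- tet_volume(x, ball$tets)
  sv <- tet_signed_volumes(vol)
  if (any(sv <= 0))
    stop("tetrahedralization failure: ", sum(sv <= 0),
         " non-positive tets after perturbation (min signed volume ",
         format(min(sv)), "); reduce amplitude or n_modes")
  vol
}

#' Synthetic sulcal landmark curves
#'
#' Draws `n_curves` vertex-disjoint approximate-shortest paths between
#' seeded endpoint pairs on a surface, standing in for hand-traced major
#' sulci. Endpoints are drawn uniformly from the surface vertices with
#' rejection until all pairwise vertex distances between accepted curves
#' are at least `min_separation`. Paths are graph shortest paths on edge
#' lengths, so consecutive vertices always share a mesh edge.
#'
#' @param surface a [tri_surface()], open or closed.
#' @param n_curves number of curves, at least 1.
#' @param seed integer RNG seed.
#' @param min_separation minimal Euclidean distance between any two
#'   vertices of different curves (and between the endpoints of one
#'   curve).
#' @param max_retries bounded rejection attempts per curve.
#' @return a list of [landmark_curve()] objects.
#' @export
make_landmark_curves <- function(surface, n_curves = 3L, seed = 1L,
                                 min_separation = 0.2, max_retries = 200L) {
  stopifnot(n_curves >= 1L)
  et <- edge_table(surface$faces)
  v <- surface$vertices
  w <- sqrt(rowSums((v[et$edges[, 1], , drop = FALSE] -
                       v[et$edges[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(et$edges, directed = FALSE)
  igraph::E(g)$weight <- w
  nv <- nrow(v)
  with_seed(seed, {
    curves <- list()
    used <- integer(0)
    for (ci in seq_len(n_curves)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        ends <- sample.int(nv, 2L)
        if (sqrt(sum((v[ends[1], ] - v[ends[2], ])^2)) < min_separation)
          next
        if (length(used) &&
              min(cross_dist(v[ends, , drop = FALSE],
                             v[used, , drop = FALSE])) < min_separation)
          next
        gsub <- if (length(used)) igraph::delete_vertices(g, used) else g
        keep <- setdiff(seq_len(nv), used)
        from <- match(ends[1], keep); to <- match(ends[2], keep)
        sp <- suppressWarnings(
          igraph::shortest_paths(gsub, from, to, output = "vpath"))
        path <- keep[as.integer(sp$vpath[[1]])]
        if (length(path) < 2L) next
        if (length(used) &&
              min(cross_dist(v[path, , drop = FALSE],
                             v[used, , drop = FALSE])) < min_separation)
          next
        curves[[ci]] <- landmark_curve(path, name = paste0("curve", ci))
        used <- c(used, path)
        ok <- TRUE
        break
      }
      if (!ok)
        stop("could not place landmark curve ", ci, " with separation ",
             min_separation, " after ", max_retries, " retries")
    }
    curves
  })
}

# Min distance matrix helper: all pairwise distances between rows of A, B.
cross_dist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Rectangular slab tetrahedral mesh
#'
#' A regular grid slab split into conforming tets (Kuhn subdivision of
#' each hexahedral cell). Useful as a bilayer buckling fixture: the top
#' surface (`z = lz`) plays the cortical surface.
#'
#' @param nx,ny,nz number of cells along each axis.
#' @param lx,ly,lz slab extents.
#' @return a [tet_volume()].
#' @export
make_slab_volume <- function(nx = 20L, ny = 4L, nz = 4L,
                             lx = 5, ly = 1, lz = 1) {
  xs <- seq(0, lx, length.out = nx + 1L)
  ys <- seq(0, ly, length.out = ny + 1L)
  zs <- seq(0, lz, length.out = nz + 1L)
  g <- expand.grid(x = xs, y = ys, z = zs)
  v <- as.matrix(g)
  idx <- function(i, j, k)
    ((k - 1L) * (ny + 1L) + (j - 1L)) * (nx + 1L) + i
  # Kuhn: 6 tets per cube along the main diagonal; identical in every
  # cell, hence globally conforming.
  kuhn <- rbind(c(1, 2, 4, 8), c(1, 2, 8, 6), c(1, 6, 8, 5),
                c(1, 4, 3, 8), c(1, 3, 7, 8), c(1, 7, 5, 8))
  cells <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  corners <- cbind(idx(cells$i, cells$j, cells$k),
                   idx(cells$i + 1L, cells$j, cells$k),
                   idx(cells$i, cells$j + 1L, cells$k),
                   idx(cells$i + 1L, cells$j + 1L, cells$k),
                   idx(cells$i, cells$j, cells$k + 1L),
                   idx(cells$i + 1L, cells$j, cells$k + 1L),
                   idx(cells$i, cells$j + 1L, cells$k + 1L),
                   idx(cells$i + 1L, cells$j + 1L, cells$k + 1L))
  tets <- do.call(rbind, lapply(seq_len(6L), function(t_)
    corners[, kuhn[t_, ], drop = FALSE]))
  vol <- tet_volume(v, tets, validate = FALSE)
  sv <- tet_signed_volumes(vol)
  flip <- sv < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  tet_volume(v, tets)
}
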