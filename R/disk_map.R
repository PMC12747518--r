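# Disk conformal parameterization of simply connected open surfaces and
# landmark-matched quasi-conformal maps between parameterized disks.

#' Disk parameterization container
#'
#' @param uv one 2D point per vertex, inside the closed unit disk.
#' @param boundary_indices ordered boundary loop (vertex indices).
#' @param surface_id optional identifier.
#' @param mean_abs_mu mean per-face Beltrami magnitude of the
#'   parameterization, as reported by [disk_conformal()].
#' @return an object of class `disk_param`.
#' @export
disk_param <- function(uv, boundary_indices, surface_id = NULL,
                       mean_abs_mu = NA_real_) {
  uv <- as_point_matrix(uv, 2L, "uv")
  structure(list(uv = uv, boundary_indices = as.integer(boundary_indices),
                 surface_id = surface_id, mean_abs_mu = mean_abs_mu),
            class = "disk_param")
}

#' @export
print.disk_param <- function(x, ...) {
  cat("disk_param:", nrow(x$uv), "vertices,",
      length(x$boundary_indices), "boundary vertices, mean |mu| =",
      format(x$mean_abs_mu, digits = 4), "\n")
  invisible(x)
}

# Signed areas of parameter triangles (positive = counterclockwise).
uv_signed_areas <- function(uv, faces) {
  p1 <- uv[faces[, 1], , drop = FALSE]
  p2 <- uv[faces[, 2], , drop = FALSE]
  p3 <- uv[faces[, 3], , drop = FALSE]
  ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
     (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])) / 2
}

# Per-face isometric 2D coordinates of a 3D surface: each triangle laid
# flat with corner 1 at the origin and corner 2 on the +x axis. Returns
# an F x 6 matrix (x1 y1 x2 y2 x3 y3).
face_local_coords <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  l1 <- sqrt(rowSums(e1^2))
  dot12 <- rowSums(e1 * e2)
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  h <- sqrt(rowSums(cr^2)) / l1
  cbind(0, 0, l1, 0, dot12 / l1, h)
}

# Cotangent weights per undirected edge, negative values clamped to a
# small positive floor so the harmonic system stays a Tutte embedding
# (positive weights + convex boundary => no flipped triangles).
cot_edge_weights <- function(surface, clamp_floor = 1e-6) {
  v <- surface$vertices
  f <- surface$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  area <- face_areas(surface)
  l23 <- rowSums((p2 - p3)^2)
  l13 <- rowSums((p1 - p3)^2)
  l12 <- rowSums((p1 - p2)^2)
  cot1 <- (l12 + l13 - l23) / (4 * area)
  cot2 <- (l12 + l23 - l13) / (4 * area)
  cot3 <- (l13 + l23 - l12) / (4 * area)
  et <- edge_table(f)
  w <- numeric(nrow(et$edges))
  he_cot <- c(cot3, cot1, cot2)  # halfedges (1,2),(2,3),(3,1) per face
  # halfedges() lists (1,2),(2,3),(3,1) interleaved per face; rebuild in
  # the same order:
  nf <- nrow(f)
  ord_cot <- as.vector(rbind(cot3, cot1, cot2))
  acc <- rowsum(ord_cot, et$edge_of_he)
  w[as.integer(rownames(acc))] <- acc[, 1]
  mw <- mean(abs(w))
  w[w < clamp_floor * mw] <- clamp_floor * mw
  list(edges = et$edges, w = w)
}

#' Disk conformal parameterization
#'
#' Maps a simply connected open surface onto the closed unit disk:
#' the boundary loop goes to the unit circle (initially with
#' arclength-proportional spacing), the interior follows by discrete
#' harmonic extension with cotangent weights, and a few correction
#' passes re-space the boundary according to the measured boundary
#' conformal factor and re-solve, keeping the iterate with the smallest
#' mean per-face Beltrami magnitude. Negative cotangent weights are
#' clamped to a small positive floor, so the parameter triangles are
#' never flipped (Tutte embedding with convex boundary).
#'
#' @param surface a [tri_surface()] that [validate_surface()] reports
#'   disk-mappable.
#' @param n_correction number of boundary-respacing correction passes.
#' @return a [disk_param()] with `mean_abs_mu` reported.
#' @export
disk_conformal <- function(surface, n_correction = 5L) {
  rep_ <- validate_surface(surface)
  if (!rep_$disk_mappable)
    stop("surface is not disk-mappable (chi = ", rep_$euler_characteristic,
         ", boundary loops = ", rep_$boundary_loop_count, ")")
  loop <- boundary_loops(surface$faces)[[1]]
  v <- surface$vertices
  nb <- length(loop)
  seg <- sqrt(rowSums((v[loop, , drop = FALSE] -
                         v[loop[c(2:nb, 1)], , drop = FALSE])^2))
  cw <- cot_edge_weights(surface)
  L <- Matrix::sparseMatrix(
    i = c(cw$edges[, 1], cw$edges[, 2]),
    j = c(cw$edges[, 2], cw$edges[, 1]),
    x = c(-cw$w, -cw$w), dims = c(nrow(v), nrow(v)))
  L <- L + Matrix::Diagonal(nrow(v), -Matrix::rowSums(L))
  interior <- setdiff(seq_len(nrow(v)), loop)
  LII <- L[interior, interior, drop = FALSE]
  LIB <- L[interior, loop, drop = FALSE]
  solve_with_lengths <- function(lens) {
    theta <- 2 * pi * cumsum(c(0, lens[-nb])) / sum(lens)
    uvb <- cbind(cos(theta), sin(theta))
    uv <- matrix(0, nrow(v), 2)
    uv[loop, ] <- uvb
    if (length(interior))
      uv[interior, ] <- as.matrix(Matrix::solve(LII, -LIB %*% uvb))
    # boundary loop direction depends on the surface orientation; make
    # the parameter triangles counterclockwise
    if (sum(uv_signed_areas(uv, surface$faces)) < 0) uv[, 2] <- -uv[, 2]
    uv
  }
  fl <- face_local_coords(surface)
  src_uv_faces <- fl
  best <- NULL
  lens <- seg
  for (pass in 0:n_correction) {
    uv <- solve_with_lengths(lens)
    mu <- beltrami_from_local(src_uv_faces, uv, surface$faces)
    mam <- mean(abs(mu))
    if (is.null(best) || mam < best$mean_abs_mu)
      best <- list(uv = uv, mean_abs_mu = mam)
    if (pass == n_correction) break
    # measured boundary conformal factor: image/source length of each
    # boundary segment; re-space proportionally to source length times
    # the geometric mean of the two incident factors
    img_seg <- sqrt(rowSums((uv[loop, , drop = FALSE] -
                               uv[loop[c(2:nb, 1)], , drop = FALSE])^2))
    fac <- img_seg / seg
    lens <- seg * sqrt(fac * fac[c(nb, 1:(nb - 1))])
  }
  disk_param(best$uv, loop, mean_abs_mu = best$mean_abs_mu)
}

#' Per-face Beltrami coefficient of a piecewise-linear planar map
#'
#' For the map taking each source triangle to its target triangle,
#' `mu = (df/dzbar) / (df/dz)`; `|mu| < 1` iff the face orientation is
#' preserved.
#'
#' @param source_uv,target_uv vertex coordinate matrices (n x 2).
#' @param faces triangle index matrix.
#' @return complex vector, one coefficient per face.
#' @export
beltrami_coefficient <- function(source_uv, target_uv, faces) {
  fl <- local_from_uv(source_uv, faces)
  beltrami_from_local(fl, target_uv, faces)
}

# Source faces given directly as F x 6 local coordinates.
local_from_uv <- function(uv, faces) {
  cbind(uv[faces[, 1], 1], uv[faces[, 1], 2],
        uv[faces[, 2], 1], uv[faces[, 2], 2],
        uv[faces[, 3], 1], uv[faces[, 3], 2])
}

# Beltrami coefficient per face from local source coords (F x 6) and
# target uv positions.
beltrami_from_local <- function(fl, target_uv, faces) {
  dz <- dz_operators(fl)
  w <- complex(real = target_uv[, 1], imaginary = target_uv[, 2])
  w1 <- w[faces[, 1]]; w2 <- w[faces[, 2]]; w3 <- w[faces[, 3]]
  fz <- dz$cz1 * w1 + dz$cz2 * w2 + dz$cz3 * w3
  fzb <- dz$cb1 * w1 + dz$cb2 * w2 + dz$cb3 * w3
  fzb / fz
}

# P1 differentiation operators per face: complex coefficients such that
# f_z = sum cz_i w_i and f_zbar = sum cb_i w_i, from the source local
# coordinates (F x 6). Hat-function gradients: grad phi_i =
# perp(opposite edge) / (2A).
dz_operators <- function(fl) {
  x1 <- fl[, 1]; y1 <- fl[, 2]; x2 <- fl[, 3]; y2 <- fl[, 4]
  x3 <- fl[, 5]; y3 <- fl[, 6]
  A2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)  # 2*area
  gx1 <- (y2 - y3) / A2; gy1 <- (x3 - x2) / A2
  gx2 <- (y3 - y1) / A2; gy2 <- (x1 - x3) / A2
  gx3 <- (y1 - y2) / A2; gy3 <- (x2 - x1) / A2
  list(cz1 = complex(real = gx1, imaginary = -gy1) / 2,
       cz2 = complex(real = gx2, imaginary = -gy2) / 2,
       cz3 = complex(real = gx3, imaginary = -gy3) / 2,
       cb1 = complex(real = gx1, imaginary = gy1) / 2,
       cb2 = complex(real = gx2, imaginary = gy2) / 2,
       cb3 = complex(real = gx3, imaginary = gy3) / 2,
       area = abs(A2) / 2)
}

#' Least-squares quasi-conformal reconstruction
#'
#' Finds the piecewise-linear planar map whose per-face Beltrami
#' coefficient matches `target_mu` in (area-weighted) least squares,
#' subject to point constraints: minimize
#' `sum_f A_f |df/dzbar - mu_f df/dz|^2` plus quadratic penalties
#' `weight * |f(constraint) - position|^2`. Hard constraints
#' (`weight = Inf`) are eliminated. Constraint points may sit on a mesh
#' edge (two indices and a segment parameter).
#'
#' @param source_uv source vertex coordinates (n x 2).
#' @param faces triangle index matrix.
#' @param target_mu per-face complex Beltrami coefficients, `|mu| < 1`.
#' @param constraints a data frame (or list) with columns `i` (vertex
#'   index), optional `j`/`t` for an edge point `(1-t) v_i + t v_j`,
#'   `u`, `v` (target position), `weight` (`Inf` = hard, only for pure
#'   vertex constraints).
#' @return list with `uv` (n x 2 map image) and `mu` (achieved per-face
#'   Beltrami coefficients).
#' @export
linear_beltrami_solve <- function(source_uv, faces, target_mu,
                                  constraints) {
  if (any(Mod(target_mu) >= 1))
    stop("target Beltrami coefficients must satisfy |mu| < 1")
  con <- as.data.frame(constraints)
  if (is.null(con$j)) { con$j <- con$i; con$t <- 0 }
  if (is.null(con$t)) con$t <- 0
  if (is.null(con$weight)) con$weight <- Inf
  nv <- nrow(source_uv)
  fl <- local_from_uv(source_uv, faces)
  dz <- dz_operators(fl)
  # residual row per face: sum_i (cb_i - mu cz_i) w_i, weighted sqrt(A)
  co1 <- (dz$cb1 - target_mu * dz$cz1) * sqrt(dz$area)
  co2 <- (dz$cb2 - target_mu * dz$cz2) * sqrt(dz$area)
  co3 <- (dz$cb3 - target_mu * dz$cz3) * sqrt(dz$area)
  nf <- nrow(faces)
  rows <- rep(seq_len(nf), 3L)
  cols <- c(faces[, 1], faces[, 2], faces[, 3])
  vals <- c(co1, co2, co3)
  # complex LS ||B w||, w = u + i v: real block system on (u, v)
  Br <- Matrix::sparseMatrix(i = rows, j = cols, x = Re(vals),
                             dims = c(nf, nv))
  Bi <- Matrix::sparseMatrix(i = rows, j = cols, x = Im(vals),
                             dims = c(nf, nv))
  Areal <- rbind(cbind(Br, -Bi), cbind(Bi, Br))
  rhs <- numeric(2L * nf)
  # soft constraints as extra rows
  soft <- con[is.finite(con$weight), , drop = FALSE]
  if (nrow(soft)) {
    sw <- sqrt(soft$weight)
    ns <- nrow(soft)
    Cs <- Matrix::sparseMatrix(
      i = c(seq_len(ns), seq_len(ns)),
      j = c(soft$i, soft$j),
      x = c(sw * (1 - soft$t), sw * soft$t), dims = c(ns, nv))
    Z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(ns, nv))
    Areal <- rbind(Areal, cbind(Cs, Z), cbind(Z, Cs))
    rhs <- c(rhs, sw * soft$u, sw * soft$v)
  }
  hard <- con[!is.finite(con$weight), , drop = FALSE]
  x <- numeric(2L * nv)
  free <- rep(TRUE, 2L * nv)
  if (nrow(hard)) {
    if (any(hard$t != 0)) stop("hard constraints must be mesh vertices")
    x[hard$i] <- hard$u
    x[nv + hard$i] <- hard$v
    free[c(hard$i, nv + hard$i)] <- FALSE
  }
  Af <- Areal[, free, drop = FALSE]
  b <- rhs - as.vector(Areal[, !free, drop = FALSE] %*% x[!free])
  AtA <- Matrix::crossprod(Af)
  Atb <- Matrix::crossprod(Af, b)
  sol <- tryCatch(as.vector(Matrix::solve(AtA, Atb)),
                  error = function(e)
                    stop("singular quasi-conformal system: add ",
                         "constraints (", conditionMessage(e), ")"))
  x[free] <- sol
  uv <- cbind(x[seq_len(nv)], x[nv + seq_len(nv)])
  list(uv = uv, mu = beltrami_coefficient(source_uv, uv, faces))
}

#' Landmark-matching quasi-conformal map between two disks
#'
#' Computes `f12 : D1 -> D2` aligning landmark curves: each source
#' curve, resampled by normalized arclength, is pulled toward its
#' corresponding target curve by soft point constraints whose weight is
#' increased until the worst landmark mismatch falls below `tol` or
#' further progress would require `|mu| >= 1` (the coefficient is
#' clamped at 0.95 and the weight ramp stops). The unit-circle boundary
#' maps to the unit circle (hard identity constraints on D1's boundary
#' vertices). D1 is the reference: constraints pull D2's landmarks
#' toward positions aligned with D1's.
#'
#' @param D1,D2 [disk_param()] objects.
#' @param lm1,lm2 corresponding lists of [landmark_curve()] on the two
#'   surfaces (equal counts, corresponding order and direction).
#' @param tol landmark mismatch tolerance (in disk units).
#' @param n_samples arclength samples per curve.
#' @param faces1 triangle matrix of D1's surface (required to evaluate
#'   Beltrami coefficients).
#' @return an object of class `qc_map` with fields `image` (the mapped
#'   position of every D1 vertex), `mu` (per-face Beltrami), `residual`
#'   (achieved worst landmark mismatch) and `feasible`.
#' @export
landmark_qc_map <- function(D1, D2, lm1, lm2, tol = 1e-3,
                            n_samples = 20L, faces1) {
  stopifnot(length(lm1) == length(lm2), length(lm1) >= 1L)
  # arclength-resampled correspondences: source points on D1 edges,
  # target points on D2 polylines
  src <- list(); tgt <- list()
  for (k in seq_along(lm1)) {
    sp <- resample_polyline(D1$uv, lm1[[k]]$vertex_path, n_samples)
    tp <- resample_polyline(D2$uv, lm2[[k]]$vertex_path, n_samples)
    src[[k]] <- sp
    tgt[[k]] <- tp$points
  }
  bidx <- D1$boundary_indices
  hard <- data.frame(i = bidx, j = bidx, t = 0,
                     u = D1$uv[bidx, 1], v = D1$uv[bidx, 2],
                     weight = Inf)
  srcdf <- do.call(rbind, lapply(src, function(s) s$frame))
  tgtm <- do.call(rbind, tgt)
  lambda <- 10
  best <- NULL
  mu_t <- rep(complex(real = 0), nrow(faces1))
  for (it in seq_len(15L)) {
    soft <- data.frame(i = srcdf$i, j = srcdf$j, t = srcdf$t,
                       u = tgtm[, 1], v = tgtm[, 2], weight = lambda)
    sol <- linear_beltrami_solve(D1$uv, faces1, mu_t, rbind(hard, soft))
    mu <- sol$mu
    maxmu <- max(Mod(mu))
    img_pts <- (1 - srcdf$t) * sol$uv[srcdf$i, , drop = FALSE] +
      srcdf$t * sol$uv[srcdf$j, , drop = FALSE]
    resid <- max(sqrt(rowSums((img_pts - tgtm)^2)))
    ok <- maxmu < 1
    if (ok && (is.null(best) || resid < best$residual))
      best <- list(uv = sol$uv, mu = mu, residual = resid,
                   lambda = lambda)
    if (ok && resid <= tol) break
    if (!ok) {
      lambda <- lambda / 4
      if (lambda < 1e-3) break
      next
    }
    # chop the achieved coefficient and feed it back as the target
    mu_c <- mu
    big <- Mod(mu_c) > 0.95
    mu_c[big] <- mu_c[big] / Mod(mu_c[big]) * 0.95
    mu_t <- mu_c
    lambda <- lambda * 4
  }
  if (is.null(best))
    stop("landmark constraints infeasible: no orientation-preserving ",
         "map found")
  feas <- best$residual <= tol
  if (!feas)
    warning("landmark tolerance ", tol, " unreachable with |mu| < 1; ",
            "achieved mismatch ", format(best$residual, digits = 4))
  structure(list(source = D1, target = D2, image = best$uv,
                 mu = best$mu, residual = best$residual,
                 feasible = feas, faces = faces1),
            class = "qc_map")
}

#' @export
print.qc_map <- function(x, ...) {
  cat("qc_map:", nrow(x$image), "vertices | max |mu| =",
      format(max(Mod(x$mu)), digits = 4), "| landmark residual =",
      format(x$residual, digits = 4), "\n")
  invisible(x)
}

# Resample a polyline (uv positions along a vertex path) at n points of
# equal normalized arclength. Returns the points and, for source use, a
# frame (i, j, t) expressing each sample as (1-t) v_i + t v_j on a path
# edge.
resample_polyline <- function(uv, path, n) {
  P <- uv[path, , drop = FALSE]
  seg <- sqrt(rowSums((P[-1, , drop = FALSE] -
                         P[-nrow(P), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  targets <- seq(0, cum[length(cum)], length.out = n)
  idx <- pmin(findInterval(targets, cum, rightmost.closed = TRUE),
              length(seg))
  t_ <- (targets - cum[idx]) / pmax(seg[idx], 1e-30)
  t_ <- pmin(pmax(t_, 0), 1)
  pts <- (1 - t_) * P[idx, , drop = FALSE] + t_ * P[idx + 1L, , drop = FALSE]
  list(points = pts,
       frame = data.frame(i = path[idx], j = path[idx + 1L], t = t_))
}

#' Pull back a scalar field through a quasi-conformal map chain
#'
#' Evaluates a field given on the target surface's vertices at the image
#' of every source vertex under `f12 . g1` (the `qc_map` image), by
#' barycentric interpolation over the target disk's parameter triangles
#' (the `g2^{-1}` step). Image points that spill outside the target
#' disk numerically are projected to the nearest boundary point first.
#'
#' @param field_on_S2 [scalar_field()] (or numeric) on the target
#'   surface's vertices.
#' @param qcmap a `qc_map` from [landmark_qc_map()].
#' @param faces2 triangle matrix of the target surface.
#' @return a [scalar_field()] on the source surface's vertices.
#' @export
pullback_field <- function(field_on_S2, qcmap, faces2) {
  vals <- field_values(field_on_S2)
  D2 <- qcmap$target
  loc <- locate_in_triangulation(qcmap$image, D2$uv, faces2,
                                 boundary = D2$boundary_indices)
  f <- faces2[loc$face, , drop = FALSE]
  out <- loc$bary[, 1] * vals[f[, 1]] + loc$bary[, 2] * vals[f[, 2]] +
    loc$bary[, 3] * vals[f[, 3]]
  scalar_field(out)
}

# Point location in a 2D triangulation with a uniform grid over face
# bounding boxes; points that fall in no triangle are projected to the
# nearest point on the boundary polygon and relocated (tolerantly).
locate_in_triangulation <- function(pts, uv, faces, boundary = NULL,
                                    tol = 1e-9) {
  nf <- nrow(faces)
  p1 <- uv[faces[, 1], , drop = FALSE]
  p2 <- uv[faces[, 2], , drop = FALSE]
  p3 <- uv[faces[, 3], , drop = FALSE]
  ng <- max(4L, floor(sqrt(nf)))
  rngx <- range(uv[, 1]); rngy <- range(uv[, 2])
  hx <- (rngx[2] - rngx[1]) / ng; hy <- (rngy[2] - rngy[1]) / ng
  cell_of <- function(x, y) {
    ix <- pmin(pmax(floor((x - rngx[1]) / hx), 0), ng - 1L)
    iy <- pmin(pmax(floor((y - rngy[1]) / hy), 0), ng - 1L)
    ix * ng + iy + 1L
  }
  buckets <- vector("list", ng * ng)
  for (f_ in seq_len(nf)) {
    xs <- c(p1[f_, 1], p2[f_, 1], p3[f_, 1])
    ys <- c(p1[f_, 2], p2[f_, 2], p3[f_, 2])
    ix <- pmin(pmax(floor((range(xs) - rngx[1]) / hx), 0), ng - 1L)
    iy <- pmin(pmax(floor((range(ys) - rngy[1]) / hy), 0), ng - 1L)
    for (a in ix[1]:ix[2]) for (b in iy[1]:iy[2]) {
      cid <- a * ng + b + 1L
      buckets[[cid]] <- c(buckets[[cid]], f_)
    }
  }
  bary_in <- function(pt, cand) {
    A <- p1[cand, , drop = FALSE]
    B <- p2[cand, , drop = FALSE]
    C <- p3[cand, , drop = FALSE]
    d <- (B[, 1] - A[, 1]) * (C[, 2] - A[, 2]) -
      (C[, 1] - A[, 1]) * (B[, 2] - A[, 2])
    w1 <- ((B[, 1] - pt[1]) * (C[, 2] - pt[2]) -
             (C[, 1] - pt[1]) * (B[, 2] - pt[2])) / d
    w2 <- ((C[, 1] - pt[1]) * (A[, 2] - pt[2]) -
             (A[, 1] - pt[1]) * (C[, 2] - pt[2])) / d
    w3 <- 1 - w1 - w2
    cbind(w1, w2, w3)
  }
  n <- nrow(pts)
  face_id <- integer(n)
  bary <- matrix(0, n, 3)
  for (q in seq_len(n)) {
    pt <- pts[q, ]
    for (attempt in 1:2) {
      cand <- buckets[[cell_of(pt[1], pt[2])]]
      hit <- 0L
      if (length(cand)) {
        W <- bary_in(pt, cand)
        inside <- which(W[, 1] >= -tol & W[, 2] >= -tol & W[, 3] >= -tol)
        if (length(inside)) hit <- cand[inside[1]]
      }
      if (!hit) {
        # global fallback: face with the least-negative worst barycentric
        W <- bary_in(pt, seq_len(nf))
        worst <- pmin(W[, 1], W[, 2], W[, 3])
        bestf <- which.max(worst)
        if (worst[bestf] >= -1e-6) {
          hit <- bestf
          W <- W[bestf, , drop = FALSE]
          inside <- 1L
          cand <- bestf
        } else if (attempt == 1L && !is.null(boundary)) {
          pt <- project_to_polygon(pt, uv[boundary, , drop = FALSE])
          next
        } else {
          stop("point (", pt[1], ", ", pt[2],
               ") not locatable in the target disk")
        }
      }
      k <- which(cand == hit)[1]
      face_id[q] <- hit
      W_hit <- bary_in(pt, hit)
      bary[q, ] <- pmin(pmax(W_hit, 0), 1)
      bary[q, ] <- bary[q, ] / sum(bary[q, ])
      break
    }
  }
  list(face = face_id, bary = bary)
}

# Nearest point on a closed polygon (rows of P) to pt.
project_to_polygon <- function(pt, P) {
  n <- nrow(P)
  A <- P
  B <- P[c(2:n, 1), , drop = FALSE]
  AB <- B - A
  len2 <- rowSums(AB^2)
  t_ <- pmin(pmax(((pt[1] - A[, 1]) * AB[, 1] +
                     (pt[2] - A[, 2]) * AB[, 2]) / pmax(len2, 1e-30),
                  0), 1)
  proj <- A + AB * t_
  d2 <- (proj[, 1] - pt[1])^2 + (proj[, 2] - pt[2])^2
  proj[which.min(d2), ]
}
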