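# Discrete curvature and shape-index morphometry of folded surfaces.

#' Discrete per-vertex curvatures
#'
#' Gaussian curvature by angle defect over the mixed Voronoi area
#' (Meyer's scheme) and mean curvature as half the cotangent-Laplacian
#' mean-curvature normal projected on the outward vertex normal, so that
#' H > 0 on outward-convex (gyral) regions. Boundary vertices are
#' flagged as unreliable in `boundary_mask` and excluded from downstream
#' histograms and similarity fields.
#'
#' @param surface an oriented manifold [tri_surface()].
#' @return an object of class `curvature_field` with per-vertex `H`,
#'   `K_gauss`, `boundary_mask`, `voronoi_area` and `angle_defect` (the
#'   raw defect, before division by area).
#' @export
vertex_curvatures <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  nv <- nrow(v)
  if (any(face_areas(surface) <= 0))
    stop("degenerate (zero-area) triangle at face ",
         which(face_areas(surface) <= 0)[1])
  # Corner geometry, one row per face.
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  l23 <- rowSums((p2 - p3)^2)   # squared edge opposite corner 1
  l13 <- rowSums((p1 - p3)^2)
  l12 <- rowSums((p1 - p2)^2)
  area <- face_areas(surface)
  # cot of the angle at each corner from squared edge lengths:
  # cot = dot / |cross| = ((b^2 + c^2 - a^2)/2) / (2 * area)
  cot1 <- (l12 + l13 - l23) / (4 * area)
  cot2 <- (l12 + l23 - l13) / (4 * area)
  cot3 <- (l13 + l23 - l12) / (4 * area)
  ang1 <- atan2(1, cot1); ang2 <- atan2(1, cot2); ang3 <- atan2(1, cot3)
  # Mixed Voronoi area per corner (Meyer et al.).
  obtuse <- cot1 < 0 | cot2 < 0 | cot3 < 0
  vor1 <- (l12 * cot3 + l13 * cot2) / 8
  vor2 <- (l12 * cot3 + l23 * cot1) / 8
  vor3 <- (l13 * cot2 + l23 * cot1) / 8
  a1 <- ifelse(obtuse, ifelse(cot1 < 0, area / 2, area / 4), vor1)
  a2 <- ifelse(obtuse, ifelse(cot2 < 0, area / 2, area / 4), vor2)
  a3 <- ifelse(obtuse, ifelse(cot3 < 0, area / 2, area / 4), vor3)
  A <- rowsum_vec(a1, f[, 1], nv) + rowsum_vec(a2, f[, 2], nv) +
    rowsum_vec(a3, f[, 3], nv)
  angle_sum <- rowsum_vec(ang1, f[, 1], nv) +
    rowsum_vec(ang2, f[, 2], nv) + rowsum_vec(ang3, f[, 3], nv)
  bnd <- boundary_vertex_mask(surface)
  defect <- ifelse(bnd, pi, 2 * pi) - angle_sum
  K <- defect / A
  # Cotangent mean-curvature normal: (1/4A) sum (cot a + cot b)(x_i-x_j).
  Hvec <- matrix(0, nv, 3)
  add_edge <- function(Hvec, i, j, w) {
    d <- (v[i, , drop = FALSE] - v[j, , drop = FALSE]) * w
    Hvec[, 1] <- Hvec[, 1] + rowsum_vec(d[, 1], i, nv) -
      rowsum_vec(d[, 1], j, nv)
    Hvec[, 2] <- Hvec[, 2] + rowsum_vec(d[, 2], i, nv) -
      rowsum_vec(d[, 2], j, nv)
    Hvec[, 3] <- Hvec[, 3] + rowsum_vec(d[, 3], i, nv) -
      rowsum_vec(d[, 3], j, nv)
    Hvec
  }
  # Edge (2,3) is opposite corner 1 with cotangent cot1, etc.; each
  # directed contribution (x_i - x_j) * cot(opposite) / 2 appears once
  # per incident face, building the full (cot a + cot b) weight.
  Hvec <- add_edge(Hvec, f[, 2], f[, 3], cot1 / 2)
  Hvec <- add_edge(Hvec, f[, 1], f[, 3], cot2 / 2)
  Hvec <- add_edge(Hvec, f[, 1], f[, 2], cot3 / 2)
  n_out <- vertex_normals(surface)
  H <- rowSums(Hvec * n_out) / (2 * A)
  structure(list(H = H, K_gauss = K, boundary_mask = bnd,
                 voronoi_area = A, angle_defect = defect,
                 surface_id = NULL),
            class = "curvature_field")
}

#' @export
print.curvature_field <- function(x, ...) {
  int <- !x$boundary_mask
  cat("curvature_field over", length(x$H), "vertices (",
      sum(x$boundary_mask), "boundary-masked )\n")
  cat("  H  interior range:", format(range(x$H[int]), digits = 4), "\n")
  cat("  K  interior range:", format(range(x$K_gauss[int]),
                                     digits = 4), "\n")
  invisible(x)
}

#' Shape index
#'
#' `SI = (2/pi) * atan(H / sqrt(H^2 - K))`, a dimensionless,
#' scale-independent descriptor in `[-1, 1]` running from concave (cup,
#' -1) through saddle (0) to convex (cap, +1). At umbilic points the two
#' principal curvatures coincide, `H^2 - K` vanishes and the index
#' degenerates to `sign(H)`; near-planar points (both `H^2` and
#' `H^2 - K` below tolerance) get `SI = 0`. Values with `H^2 < K` beyond
#' tolerance (impossible for a true curvature pair) are clamped to the
#' umbilic limit and counted in the `"clamped"` attribute.
#'
#' @param H mean curvature (vector).
#' @param K_gauss Gaussian curvature (vector).
#' @param umbilic_tol tolerance on `H^2 - K` (units 1/length^2);
#'   default `1e-12` at unit mesh scale.
#' @return numeric vector of shape indices in `[-1, 1]`.
#' @export
shape_index <- function(H, K_gauss, umbilic_tol = 1e-12) {
  disc <- H^2 - K_gauss
  clamped <- disc < -umbilic_tol
  disc[disc < 0] <- 0
  si <- numeric(length(H))
  regular <- disc > umbilic_tol
  si[regular] <- (2 / pi) * atan(H[regular] / sqrt(disc[regular]))
  umb <- !regular & (H^2 > umbilic_tol)
  si[umb] <- sign(H[umb])
  # remaining: planar (both H and the discriminant below tolerance) -> 0
  structure(si, clamped = which(clamped))
}

#' Rescaled mean curvature
#'
#' Affine rescaling of a mean-curvature field onto `[-1, 1]`:
#' `2 * (H - min(H)) / (max(H) - min(H)) - 1`, exact at the extremes.
#'
#' @param H_field a [scalar_field()] or numeric vector.
#' @return object of the same kind with values in `[-1, 1]`.
#' @export
rescale_mean_curvature <- function(H_field) {
  vals <- field_values(H_field)
  rng <- range(vals)
  if (rng[2] <= rng[1]) stop("constant field: zero range")
  out <- 2 * (vals - rng[1]) / (rng[2] - rng[1]) - 1
  if (inherits(H_field, "scalar_field")) {
    H_field$values <- out
    H_field
  } else out
}

#' Five-class shape classification
#'
#' Counts vertices per shape class: sulcal pits (`-1 <= SI < -0.5`),
#' sulcal saddles (`-0.5 <= SI < 0`), saddles (`SI == 0`), gyral saddles
#' (`0 < SI <= 0.5`) and gyral nodes (`0.5 < SI <= 1`). The printed
#' intervals are open; exact boundary values are tie-broken
#' deterministically: `+-0.5` joins the saddle-side class, exactly `0`
#' the "saddle" class, `+-1` the pit/node class.
#'
#' @param SI_field a [scalar_field()] or numeric vector in `[-1, 1]`.
#' @return named integer vector of class counts summing to the number of
#'   values.
#' @export
classify_shape <- function(SI_field) {
  si <- field_values(SI_field)
  if (any(si < -1 - 1e-9 | si > 1 + 1e-9))
    stop("shape index outside [-1, 1]")
  si <- pmin(pmax(si, -1), 1)
  cls <- ifelse(si < -0.5, "sulcal_pit",
         ifelse(si < 0, "sulcal_saddle",
         ifelse(si == 0, "saddle",
         ifelse(si <= 0.5, "gyral_saddle", "gyral_node"))))
  counts <- table(factor(cls, levels = c("sulcal_pit", "sulcal_saddle",
                                         "saddle", "gyral_saddle",
                                         "gyral_node")))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Histogram and mode detection on [-1, 1]
#'
#' Bin probabilities over equal-width bins on `[-1, 1]` and the modes of
#' the kernel-smoothed histogram (Gaussian kernel, 1.5 bins standard
#' deviation). A local maximum counts as a mode when its topographic
#' prominence is at least `prominence` times the global maximum of the
#' smoothed histogram.
#'
#' @param field a [scalar_field()] or numeric vector in `[-1, 1]`.
#' @param n_bins number of bins, at least 8.
#' @param prominence fraction of the global maximum.
#' @param smooth_sd kernel standard deviation in bins.
#' @return a list with `breaks`, `centers`, `probabilities` (summing to
#'   1), `smoothed`, `modes` (bin centers, ordered by decreasing height)
#'   and `mode_heights`.
#' @export
histogram_modes <- function(field, n_bins = 64L, prominence = 0.1,
                            smooth_sd = 1.5) {
  vals <- field_values(field)
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("empty field")
  stopifnot(n_bins >= 8L)
  breaks <- seq(-1, 1, length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(vals, breaks, rightmost.closed = TRUE),
                   1L), n_bins)
  prob <- tabulate(idx, n_bins) / length(vals)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  # Gaussian smoothing, truncated kernel, renormalized at the edges.
  half <- max(1L, ceiling(4 * smooth_sd))
  kern <- stats::dnorm(seq(-half, half), sd = smooth_sd)
  sm <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    lo <- max(1L, b - half); hi <- min(n_bins, b + half)
    kk <- kern[(lo - b + half + 1L):(hi - b + half + 1L)]
    sm[b] <- sum(prob[lo:hi] * kk) / sum(kk)
  }
  peaks <- which(diff(sign(diff(c(-Inf, sm, -Inf)))) == -2)
  prom <- vapply(peaks, function(p) {
    h <- sm[p]
    left <- sm[seq_len(p - 1L)]
    right <- if (p < n_bins) sm[(p + 1L):n_bins] else numeric(0)
    valley <- function(side) {
      higher <- which(side >= h)
      if (length(higher) == 0L) return(min(c(side, h)))
      # nearest higher bin: valley is the minimum in between
      min(side)
    }
    vl <- if (length(left)) {
      hi <- which(left > h)
      if (length(hi)) min(left[(max(hi) + 1L):length(left)]) else -Inf
    } else -Inf
    vr <- if (length(right)) {
      hi <- which(right > h)
      if (length(hi)) min(right[seq_len(min(hi) - 1L)]) else Inf
    } else Inf
    base <- max(c(vl, if (is.finite(vr)) vr else -Inf))
    if (!is.finite(base)) base <- 0
    h - base
  }, numeric(1))
  keep <- prom >= prominence * max(sm)
  ord <- order(sm[peaks[keep]], decreasing = TRUE)
  list(breaks = breaks, centers = centers, probabilities = prob,
       smoothed = sm, modes = centers[peaks[keep]][ord],
       mode_heights = sm[peaks[keep]][ord])
}
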