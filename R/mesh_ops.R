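# Topological validation, hemisphere dissection and the half-longitudinal
# length normalization applied to every surface before morphometry.

#' Validate surface topology
#'
#' Computes the Euler characteristic, boundary loop count, edge-manifold
#' and orientation flags by explicit counting. A surface is suitable for
#' disk parameterization ("disk-mappable") iff it is an oriented
#' edge-manifold with Euler characteristic 1 and exactly one boundary
#' loop (a simply connected open surface). Problems are reported in the
#' returned object, never raised.
#'
#' @param surface a [tri_surface()].
#' @return an object of class `validation_report` with fields
#'   `euler_characteristic`, `boundary_loop_count`, `is_edge_manifold`,
#'   `is_oriented`, `genus_if_closed` (NA when open or non-manifold) and
#'   `disk_mappable`.
#' @export
validate_surface <- function(surface) {
  et <- edge_table(surface$faces)
  V <- nrow(surface$vertices)
  E <- nrow(et$edges)
  F_ <- nrow(surface$faces)
  chi <- V - E + F_
  manifold <- all(et$count <= 2L)
  # Oriented: every directed halfedge occurs at most once, so the two
  # faces of an interior edge traverse it in opposite directions.
  he <- halfedges(surface$faces)
  oriented <- !anyDuplicated(paste(he[, 1], he[, 2]))
  loops <- boundary_loops(surface$faces)
  closed <- length(loops) == 0L && all(et$count == 2L)
  genus <- if (closed && manifold) as.integer((2L - chi) / 2L) else
    NA_integer_
  structure(list(euler_characteristic = chi,
                 boundary_loop_count = length(loops),
                 is_edge_manifold = manifold,
                 is_oriented = oriented,
                 genus_if_closed = genus,
                 disk_mappable = manifold && oriented && chi == 1L &&
                   length(loops) == 1L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report: chi =", x$euler_characteristic,
      "| boundary loops =", x$boundary_loop_count,
      "| manifold =", x$is_edge_manifold,
      "| oriented =", x$is_oriented,
      "| genus =", x$genus_if_closed,
      "| disk-mappable =", x$disk_mappable, "\n")
  invisible(x)
}

#' Cut a closed surface by a plane, keeping one side
#'
#' Dissects a closed surface into a hemisphere: triangles crossing the
#' plane are split exactly at the edge/plane intersections and the part
#' on the positive side of `plane_normal` is kept. Vertices exactly on
#' the plane are assigned to the kept side (deterministic tie-break).
#'
#' @param surface a closed [tri_surface()].
#' @param plane_point a point on the cutting plane.
#' @param plane_normal plane normal; the kept side is the one it points
#'   to.
#' @param tol on-plane tolerance relative to the mesh scale.
#' @return an open [tri_surface()] whose cut edges form the boundary.
#' @export
cut_hemisphere <- function(surface, plane_point = c(0, 0, 0),
                           plane_normal = c(1, 0, 0), tol = 1e-12) {
  n <- plane_normal / sqrt(sum(plane_normal^2))
  v <- surface$vertices
  s <- as.vector((v - matrix(plane_point, nrow(v), 3,
                             byrow = TRUE)) %*% n)
  scale <- max(abs(s), 1)
  eps <- tol * scale
  state <- ifelse(s > eps, 1L, ifelse(s < -eps, -1L, 0L))
  if (all(state >= 0L) || all(state <= 0L))
    stop("plane does not intersect the surface")
  newv <- list()            # intersection points appended after v
  edge_cut <- new.env(hash = TRUE)  # undirected edge -> new vertex id
  nv0 <- nrow(v)
  cut_point <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    if (exists(key, envir = edge_cut, inherits = FALSE))
      return(get(key, envir = edge_cut))
    t_ <- s[a] / (s[a] - s[b])
    p <- v[a, ] + t_ * (v[b, ] - v[a, ])
    newv[[length(newv) + 1L]] <<- p
    id <- nv0 + length(newv)
    assign(key, id, envir = edge_cut)
    id
  }
  out_faces <- list()
  f <- surface$faces
  for (i in seq_len(nrow(f))) {
    tri <- f[i, ]
    st <- state[tri]
    if (all(st >= 0L)) { out_faces[[length(out_faces) + 1L]] <- tri; next }
    if (!any(st > 0L)) next  # entirely on or below the plane: discarded
    # Sutherland-Hodgman clip of the triangle against s >= 0; on-plane
    # vertices (st == 0) are inside.
    poly <- integer(0)
    for (k in 1:3) {
      a <- tri[k]; b <- tri[if (k == 3L) 1L else k + 1L]
      ain <- state[a] >= 0L; bin <- state[b] >= 0L
      if (ain) poly <- c(poly, a)
      if (ain != bin && state[a] != 0L && state[b] != 0L)
        poly <- c(poly, cut_point(a, b))
    }
    if (length(poly) == 3L) {
      out_faces[[length(out_faces) + 1L]] <- poly
    } else if (length(poly) == 4L) {
      out_faces[[length(out_faces) + 1L]] <- poly[c(1, 2, 3)]
      out_faces[[length(out_faces) + 1L]] <- poly[c(1, 3, 4)]
    } else if (length(poly) > 0L && length(poly) < 3L) {
      next  # degenerate sliver collapsed to an edge or point
    }
  }
  allv <- if (length(newv)) rbind(v, do.call(rbind, newv)) else v
  faces <- do.call(rbind, out_faces)
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(allv)); remap[used] <- seq_along(used)
  out <- tri_surface(allv[used, , drop = FALSE],
                     matrix(remap[faces], ncol = 3))
  nloops <- length(boundary_loops(out$faces))
  if (nloops != 1L)
    warning("cut produced ", nloops, " boundary loops (expected 1)")
  out
}

#' Normalize by the half longitudinal length
#'
#' Divides all coordinates by half the x-extent, the characteristic
#' length L = Lx/2 used to put surfaces of different species on a common
#' scale. The longitudinal axis is the x axis by package convention;
#' callers must pre-align their meshes. Idempotent.
#'
#' @param x a [tri_surface()] or [tet_volume()].
#' @return the same kind of object with x-extent exactly 2.
#' @export
normalize_halflength <- function(x) {
  stopifnot(inherits(x, c("tri_surface", "tet_volume")))
  if (nrow(x$vertices) == 0L) stop("empty mesh")
  rng <- range(x$vertices[, 1])
  L <- (rng[2] - rng[1]) / 2
  if (L <= 0) stop("zero longitudinal extent")
  x$vertices <- x$vertices / L
  x
}
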