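#' Triangle surface mesh
#'
#' Constructs an oriented triangle mesh, the universal surface
#' representation used throughout the package. Faces are stored
#' counterclockwise with respect to the outward normal. Vertex indices are
#' 1-based in memory (the R convention); all on-disk formats use 0-based
#' indices and are converted by the readers/writers.
#'
#' @param vertices numeric matrix with one 3D point per row.
#' @param faces integer matrix with one triangle per row (1-based vertex
#'   indices, counterclockwise seen from outside).
#' @param validate if `TRUE`, check index ranges and finiteness.
#' @return an object of class `tri_surface` with components `vertices` and
#'   `faces`.
#' @export
tri_surface <- function(vertices, faces, validate = TRUE) {
  vertices <- as_point_matrix(vertices, 3L, "vertices")
  faces <- as_index_matrix(faces, 3L, "faces")
  if (validate) {
    if (!all(is.finite(vertices))) stop("non-finite vertex coordinate")
    if (nrow(faces) > 0L) {
      rng <- range(faces)
      if (rng[1] < 1L || rng[2] > nrow(vertices))
        stop("face index out of range [1, ", nrow(vertices), "]")
      if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
                faces[, 1] == faces[, 3]))
        stop("degenerate face with repeated vertex index")
    }
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_surface")
}

#' Tetrahedral volume mesh
#'
#' The simulation domain for the growth model. Tets are stored with
#' positive signed volume (vertex 4 on the positive side of the oriented
#' face 1-2-3).
#'
#' @param vertices numeric matrix of 3D points.
#' @param tets integer matrix with one tetrahedron per row (1-based).
#' @param validate if `TRUE`, check index ranges.
#' @return an object of class `tet_volume`.
#' @export
tet_volume <- function(vertices, tets, validate = TRUE) {
  vertices <- as_point_matrix(vertices, 3L, "vertices")
  tets <- as_index_matrix(tets, 4L, "tets")
  if (validate) {
    if (!all(is.finite(vertices))) stop("non-finite vertex coordinate")
    if (nrow(tets) > 0L) {
      rng <- range(tets)
      if (rng[1] < 1L || rng[2] > nrow(vertices))
        stop("tet index out of range [1, ", nrow(vertices), "]")
    }
  }
  structure(list(vertices = vertices, tets = tets), class = "tet_volume")
}

#' Landmark curve on a surface
#'
#' An ordered simple path of vertex indices whose consecutive vertices
#' share a mesh edge, standing in for a hand-traced major sulcus.
#'
#' @param vertex_path integer vector of 1-based vertex indices.
#' @param name optional curve name.
#' @return an object of class `landmark_curve`.
#' @export
landmark_curve <- function(vertex_path, name = NULL) {
  vertex_path <- as.integer(vertex_path)
  if (length(vertex_path) < 2L) stop("a landmark curve needs >= 2 vertices")
  if (anyDuplicated(vertex_path)) stop("landmark curve repeats a vertex")
  structure(list(vertex_path = vertex_path, name = name),
            class = "landmark_curve")
}

#' Per-vertex scalar field
#'
#' @param values numeric vector, one value per vertex of the surface it
#'   refers to.
#' @param surface_id optional identifier of the parent surface.
#' @return an object of class `scalar_field`.
#' @export
scalar_field <- function(values, surface_id = NULL) {
  values <- as.numeric(values)
  structure(list(values = values, surface_id = surface_id),
            class = "scalar_field")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat("tri_surface:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces\n")
  invisible(x)
}

#' @export
print.tet_volume <- function(x, ...) {
  cat("tet_volume:", nrow(x$vertices), "vertices,", nrow(x$tets), "tets\n")
  invisible(x)
}

#' @export
print.landmark_curve <- function(x, ...) {
  cat("landmark_curve", if (!is.null(x$name)) paste0("'", x$name, "'"),
      "with", length(x$vertex_path), "vertices\n")
  invisible(x)
}

#' @export
print.scalar_field <- function(x, ...) {
  cat("scalar_field of length", length(x$values), "\n")
  invisible(x)
}

# Coerce scalar_field or bare numeric to a numeric vector.
field_values <- function(x) {
  if (inherits(x, "scalar_field")) x$values else as.numeric(x)
}

as_point_matrix <- function(x, ncol, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (length(x) == 0L) x <- matrix(numeric(0), 0L, ncol)
  if (ncol(x) != ncol) stop(what, " must have ", ncol, " columns")
  dimnames(x) <- NULL
  x
}

as_index_matrix <- function(x, ncol, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (length(x) == 0L) x <- matrix(integer(0), 0L, ncol)
  if (ncol(x) != ncol) stop(what, " must have ", ncol, " columns")
  dimnames(x) <- NULL
  x
}

# --- Mesh combinatorics helpers ------------------------------------------

# Directed halfedges of each face: rows (from, to), 3 per face in face order.
halfedges <- function(faces) {
  cbind(from = as.vector(t(faces[, c(1, 2, 3), drop = FALSE])),
        to   = as.vector(t(faces[, c(2, 3, 1), drop = FALSE])))
}

# Undirected edge table with counts of incident faces. Returns a list with
# `edges` (E x 2, sorted rows), `count` (faces per edge), and `edge_of_he`
# mapping each halfedge row to its undirected edge id.
edge_table <- function(faces) {
  he <- halfedges(faces)
  lo <- pmin(he[, 1], he[, 2])
  hi <- pmax(he[, 1], he[, 2])
  key <- paste(lo, hi)
  first <- !duplicated(key)
  ids <- match(key, key[first])
  list(edges = cbind(lo[first], hi[first]),
       count = tabulate(ids, sum(first)),
       edge_of_he = ids)
}

euler_characteristic <- function(surface) {
  et <- edge_table(surface$faces)
  nrow(surface$vertices) - nrow(et$edges) + nrow(surface$faces)
}

# Boundary edges: undirected edges with exactly one incident face,
# returned as directed (from, to) in boundary orientation.
boundary_halfedges <- function(faces) {
  he <- halfedges(faces)
  lo <- pmin(he[, 1], he[, 2])
  hi <- pmax(he[, 1], he[, 2])
  key <- paste(lo, hi)
  cnt <- table(key)
  he[cnt[key] == 1L, , drop = FALSE]
}

# Ordered boundary loops (list of vertex index cycles).
boundary_loops <- function(faces) {
  bhe <- boundary_halfedges(faces)
  if (nrow(bhe) == 0L) return(list())
  nxt <- new.env(hash = TRUE)
  for (i in seq_len(nrow(bhe)))
    assign(as.character(bhe[i, 1]), bhe[i, 2], envir = nxt)
  unvisited <- new.env(hash = TRUE)
  for (i in seq_len(nrow(bhe)))
    assign(as.character(bhe[i, 1]), TRUE, envir = unvisited)
  loops <- list()
  for (i in seq_len(nrow(bhe))) {
    s <- as.character(bhe[i, 1])
    if (!exists(s, envir = unvisited, inherits = FALSE)) next
    loop <- integer(0)
    cur <- s
    repeat {
      if (!exists(cur, envir = unvisited, inherits = FALSE)) break
      rm(list = cur, envir = unvisited)
      loop <- c(loop, as.integer(cur))
      if (!exists(cur, envir = nxt, inherits = FALSE)) break
      cur <- as.character(get(cur, envir = nxt))
      if (cur == s) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

# Logical mask of boundary vertices.
boundary_vertex_mask <- function(surface) {
  mask <- logical(nrow(surface$vertices))
  bhe <- boundary_halfedges(surface$faces)
  mask[unique(as.vector(bhe))] <- TRUE
  mask
}

face_normals <- function(surface, normalize = TRUE) {
  v <- surface$vertices
  f <- surface$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  if (normalize) {
    len <- sqrt(rowSums(n^2))
    len[len == 0] <- 1
    n <- n / len
  }
  n
}

face_areas <- function(surface) {
  n <- face_normals(surface, normalize = FALSE)
  0.5 * sqrt(rowSums(n^2))
}

surface_area <- function(surface) sum(face_areas(surface))

# Area-weighted outward vertex normals.
vertex_normals <- function(surface) {
  fn <- face_normals(surface, normalize = FALSE)  # 2*area-weighted
  n <- matrix(0, nrow(surface$vertices), 3)
  for (k in 1:3) {
    idx <- surface$faces[, k]
    n[, 1] <- n[, 1] + unname(rowsum_vec(fn[, 1], idx, nrow(n)))
    n[, 2] <- n[, 2] + unname(rowsum_vec(fn[, 2], idx, nrow(n)))
    n[, 3] <- n[, 3] + unname(rowsum_vec(fn[, 3], idx, nrow(n)))
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# Sum `vals` into bins `idx` over n bins, returning a dense vector.
rowsum_vec <- function(vals, idx, n) {
  out <- numeric(n)
  acc <- rowsum(vals, idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

# Signed volume enclosed by a closed oriented surface (divergence theorem).
enclosed_volume <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
        a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
        a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# Signed volumes of all tets.
tet_signed_volumes <- function(volume) {
  v <- volume$vertices
  t_ <- volume$tets
  a <- v[t_[, 1], , drop = FALSE]
  b <- v[t_[, 2], , drop = FALSE] - a
  c_ <- v[t_[, 3], , drop = FALSE] - a
  d <- v[t_[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) +
     b[, 2] * (c_[, 3] * d[, 1] - c_[, 1] * d[, 3]) +
     b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

# Boundary triangles of a tet mesh, oriented outward. Returns an index
# matrix into the volume's vertices.
tet_boundary_faces <- function(tets) {
  # Local faces chosen so each is outward-oriented for a positive tet.
  tri <- rbind(tets[, c(1, 3, 2), drop = FALSE],
               tets[, c(1, 2, 4), drop = FALSE],
               tets[, c(2, 3, 4), drop = FALSE],
               tets[, c(1, 4, 3), drop = FALSE])
  a <- pmin(tri[, 1], tri[, 2], tri[, 3])
  c_ <- pmax(tri[, 1], tri[, 2], tri[, 3])
  b <- as.double(tri[, 1]) + tri[, 2] + tri[, 3] - a - c_
  key <- paste(a, b, c_)
  first <- !duplicated(key)
  ids <- match(key, key[first])
  tri[tabulate(ids, sum(first))[ids] == 1L, , drop = FALSE]
}

#' Extract the boundary surface of a tetrahedral mesh
#'
#' Collects the triangles incident to exactly one tetrahedron, oriented
#' outward, and reindexes them over the boundary vertices.
#'
#' @param volume a [tet_volume()].
#' @param vertices optional replacement coordinates (e.g. the deformed
#'   configuration of a simulation state); defaults to the volume's own.
#' @return a list with `surface` (a [tri_surface()]) and `vertex_map`
#'   (index into the volume's vertices for each surface vertex).
#' @export
boundary_surface <- function(volume, vertices = NULL) {
  if (is.null(vertices)) vertices <- volume$vertices
  tri <- tet_boundary_faces(volume$tets)
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(vertices))
  remap[used] <- seq_along(used)
  surf <- tri_surface(vertices[used, , drop = FALSE],
                      matrix(remap[tri], ncol = 3))
  list(surface = surf, vertex_map = used)
}
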