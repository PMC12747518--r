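# ASCII mesh readers/writers. All on-disk vertex indices are 0-based
# (the convention of OFF/PLY/VTK and of the JSON landmark format);
# in-memory indices are 1-based.

#' Read a mesh, field or landmark file
#'
#' Supported dialects: OFF, ASCII PLY and ASCII STL for triangle
#' surfaces; legacy ASCII VTK unstructured grids and TetGen-style
#' `.node`/`.ele` pairs for tetrahedral volumes; CSV
#' (`vertex_index,value`) for per-vertex scalar fields; JSON (a list of
#' objects `{name, vertex_path}`) for landmark curves. The dialect is
#' chosen from the file extension. Every returned object is validated
#' against its type invariants.
#'
#' @param path file to read (for `.node`, the matching `.ele` must sit
#'   beside it).
#' @param kind one of `"surface"`, `"tet"`, `"field"`, `"landmarks"`;
#'   checked against the dialect.
#' @param n_vertices for `kind = "field"` or `"landmarks"`, optional
#'   vertex count of the parent surface used for range checking.
#' @return a [tri_surface()], [tet_volume()], [scalar_field()] or list
#'   of [landmark_curve()].
#' @export
read_mesh <- function(path, kind = c("surface", "tet", "field",
                                     "landmarks"),
                      n_vertices = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  obj <- switch(ext,
    off = read_off(path),
    ply = read_ply(path),
    stl = read_stl(path),
    vtk = read_vtk_tet(path),
    node = read_node_ele(path),
    csv = read_field_csv(path),
    json = read_landmarks_json(path),
    stop("unsupported file extension: .", ext))
  if (kind == "field" && inherits(obj, "tri_surface")) {
    # PLY with an extra per-vertex scalar property carries a field.
    flds <- attr(obj, "vertex_fields")
    if (is.null(flds))
      stop("file ", path, " has no per-vertex scalar property")
    obj <- flds[[1]]
  }
  want <- switch(kind, surface = "tri_surface", tet = "tet_volume",
                 field = "scalar_field", landmarks = "list")
  got <- if (is.list(obj) && !inherits(obj, c("tri_surface", "tet_volume",
                                              "scalar_field")))
    "list" else class(obj)[1]
  if (got != want)
    stop("file ", path, " holds a ", got, ", not the requested ", kind)
  if (!is.null(n_vertices)) {
    if (kind == "field" && length(obj$values) != n_vertices)
      stop("field length ", length(obj$values), " != vertex count ",
           n_vertices)
    if (kind == "landmarks") {
      for (lc in obj)
        if (any(lc$vertex_path < 1L | lc$vertex_path > n_vertices))
          stop("landmark vertex index out of range [1, ", n_vertices, "]")
    }
  }
  obj
}

#' Write a mesh, field or landmark set
#'
#' Inverse of [read_mesh()]. Coordinates are written with 17 significant
#' digits, so connectivity and geometry round-trip losslessly (STL, which
#' stores triangle soup, round-trips geometry to the vertex-merge
#' tolerance).
#'
#' @param object a [tri_surface()], [tet_volume()], [scalar_field()] or
#'   list of [landmark_curve()].
#' @param path output file.
#' @param format one of `"OFF"`, `"PLY"`, `"STL"`, `"VTK"`, `"CSV"`,
#'   `"JSON"`; defaults to the file extension.
#' @return `invisible(path)`.
#' @export
write_mesh <- function(object, path, format = NULL) {
  if (is.null(format)) format <- toupper(tools::file_ext(path))
  format <- toupper(format)
  ok <- switch(format,
    OFF = , PLY = , STL = inherits(object, "tri_surface"),
    VTK = inherits(object, "tet_volume"),
    CSV = inherits(object, "scalar_field"),
    JSON = is.list(object) && all(vapply(object, inherits, TRUE,
                                         "landmark_curve")),
    FALSE)
  if (!isTRUE(ok))
    stop("format ", format, " does not support objects of class ",
         class(object)[1])
  switch(format,
    OFF = write_off(object, path),
    PLY = write_ply(object, path),
    STL = write_stl(object, path),
    VTK = write_vtk_tet(object, path),
    CSV = write_field_csv(object, path),
    JSON = write_landmarks_json(object, path))
  invisible(path)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

# --- OFF ------------------------------------------------------------------

read_off <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE,
               comment.char = "#")
  if (toupper(toks[1]) != "OFF") stop("not an OFF file: ", path)
  nv <- as.integer(toks[2]); nf <- as.integer(toks[3])
  pos <- 5L
  v <- matrix(as.numeric(toks[pos:(pos + 3L * nv - 1L)]), nv, 3,
              byrow = TRUE)
  if (!all(is.finite(v))) stop("non-finite coordinate in ", path)
  pos <- pos + 3L * nv
  f <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    k <- as.integer(toks[pos])
    if (k != 3L) stop("non-triangular face in ", path)
    f[i, ] <- as.integer(toks[(pos + 1L):(pos + 3L)])
    pos <- pos + k + 1L
  }
  if (nf > 0L && (min(f) < 0L || max(f) >= nv))
    stop("face index out of range in ", path)
  tri_surface(v, f + 1L)
}

write_off <- function(surface, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nrow(surface$vertices), nrow(surface$faces), 0), con)
  writeLines(apply(surface$vertices, 1L,
                   function(r) paste(fmt_num(r), collapse = " ")), con)
  if (nrow(surface$faces) > 0L)
    writeLines(paste(3L, surface$faces[, 1] - 1L, surface$faces[, 2] - 1L,
                     surface$faces[, 3] - 1L), con)
}

# --- PLY (ascii) ----------------------------------------------------------

read_ply <- function(path) {
  lines <- readLines(path)
  if (tolower(trimws(lines[1])) != "ply") stop("not a PLY file: ", path)
  hdr_end <- match("end_header", trimws(tolower(lines)))
  if (is.na(hdr_end)) stop("PLY header unterminated in ", path)
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format\\s+ascii", trimws(hdr))))
    stop("only ascii PLY is supported: ", path)
  elems <- list(); cur <- NULL
  for (ln in hdr) {
    t_ <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(t_) == 0) next
    if (t_[1] == "element") {
      cur <- t_[2]
      elems[[cur]] <- list(n = as.integer(t_[3]), props = character(0))
    } else if (t_[1] == "property" && !is.null(cur)) {
      if (t_[2] == "list") {
        elems[[cur]]$props <- c(elems[[cur]]$props, paste0("list:", t_[5]))
      } else {
        elems[[cur]]$props <- c(elems[[cur]]$props, t_[3])
      }
    }
  }
  if (is.null(elems$vertex)) stop("PLY without vertex element: ", path)
  body <- lines[(hdr_end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  nv <- elems$vertex$n
  vprops <- elems$vertex$props
  vdat <- utils::read.table(text = body[seq_len(nv)],
                            col.names = vprops,
                            colClasses = "numeric")
  v <- as.matrix(vdat[, c("x", "y", "z")])
  nf <- if (!is.null(elems$face)) elems$face$n else 0L
  f <- matrix(integer(0), 0L, 3L)
  if (nf > 0L) {
    flines <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    f <- t(vapply(flines, function(t_) {
      if (as.integer(t_[1]) != 3L) stop("non-triangular PLY face")
      as.integer(t_[2:4])
    }, integer(3)))
    if (min(f) < 0L || max(f) >= nv)
      stop("face index out of range in ", path)
  }
  extra <- setdiff(vprops, c("x", "y", "z"))
  surf <- tri_surface(v, f + 1L)
  if (length(extra)) {
    attr(surf, "vertex_fields") <-
      lapply(stats::setNames(extra, extra),
             function(p) scalar_field(vdat[[p]]))
  }
  surf
}

write_ply <- function(surface, path, fields = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  nv <- nrow(surface$vertices); nf <- nrow(surface$faces)
  fields <- fields %||% attr(surface, "vertex_fields")
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nv),
               "property double x", "property double y",
               "property double z"), con)
  if (!is.null(fields))
    for (nm in names(fields))
      writeLines(paste("property double", nm), con)
  writeLines(c(paste("element face", nf),
               "property list uchar int vertex_indices",
               "end_header"), con)
  vdat <- surface$vertices
  if (!is.null(fields))
    for (nm in names(fields))
      vdat <- cbind(vdat, field_values(fields[[nm]]))
  writeLines(apply(vdat, 1L, function(r) paste(fmt_num(r),
                                               collapse = " ")), con)
  if (nf > 0L)
    writeLines(paste(3L, surface$faces[, 1] - 1L, surface$faces[, 2] - 1L,
                     surface$faces[, 3] - 1L), con)
}

# --- STL (ascii) ----------------------------------------------------------

read_stl <- function(path, merge_tol = 1e-7) {
  toks <- scan(path, what = character(), quiet = TRUE)
  vi <- which(toks == "vertex")
  if (length(vi) == 0L || length(vi) %% 3L != 0L)
    stop("malformed ascii STL: ", path)
  coords <- matrix(as.numeric(toks[rep(vi, each = 3L) + 1:3]),
                   ncol = 3, byrow = TRUE)
  if (!all(is.finite(coords))) stop("non-finite coordinate in ", path)
  # Merge duplicate corner vertices within tolerance (grid snap).
  scale <- max(1, max(abs(coords)))
  key <- apply(round(coords / (merge_tol * scale)), 1L, paste,
               collapse = " ")
  first <- !duplicated(key)
  ids <- match(key, key[first])
  v <- coords[first, , drop = FALSE]
  f <- matrix(ids, ncol = 3, byrow = TRUE)
  tri_surface(v, f)
}

write_stl <- function(surface, path) {
  con <- file(path, "w"); on.exit(close(con))
  n <- face_normals(surface)
  v <- surface$vertices; f <- surface$faces
  writeLines("solid surface", con)
  for (i in seq_len(nrow(f))) {
    writeLines(c(paste("facet normal", paste(fmt_num(n[i, ]),
                                             collapse = " ")),
                 "  outer loop",
                 paste("    vertex", paste(fmt_num(v[f[i, 1], ]),
                                           collapse = " ")),
                 paste("    vertex", paste(fmt_num(v[f[i, 2], ]),
                                           collapse = " ")),
                 paste("    vertex", paste(fmt_num(v[f[i, 3], ]),
                                           collapse = " ")),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid surface", con)
}

# --- VTK legacy ascii unstructured grid (tets) ----------------------------

read_vtk_tet <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, skip = 2L)
  ip <- which(toupper(toks) == "POINTS")[1]
  if (is.na(ip)) stop("VTK POINTS section missing in ", path)
  np <- as.integer(toks[ip + 1L])
  v <- matrix(as.numeric(toks[(ip + 3L):(ip + 2L + 3L * np)]), np, 3,
              byrow = TRUE)
  ic <- which(toupper(toks) == "CELLS")[1]
  if (is.na(ic)) stop("VTK CELLS section missing in ", path)
  nc <- as.integer(toks[ic + 1L]); sz <- as.integer(toks[ic + 2L])
  cells <- as.integer(toks[(ic + 3L):(ic + 2L + sz)])
  it <- which(toupper(toks) == "CELL_TYPES")[1]
  types <- as.integer(toks[(it + 2L):(it + 1L + nc)])
  if (any(types != 10L)) stop("VTK file contains non-tet cells: ", path)
  tets <- matrix(0L, nc, 4)
  pos <- 1L
  for (i in seq_len(nc)) {
    k <- cells[pos]
    if (k != 4L) stop("non-tet cell size in ", path)
    tets[i, ] <- cells[(pos + 1L):(pos + 4L)]
    pos <- pos + 5L
  }
  if (min(tets) < 0L || max(tets) >= np)
    stop("tet index out of range in ", path)
  tet_volume(v, tets + 1L)
}

write_vtk_tet <- function(volume, path) {
  con <- file(path, "w"); on.exit(close(con))
  nv <- nrow(volume$vertices); nt <- nrow(volume$tets)
  writeLines(c("# vtk DataFile Version 3.0", "tet volume", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nv, "double")), con)
  writeLines(apply(volume$vertices, 1L,
                   function(r) paste(fmt_num(r), collapse = " ")), con)
  writeLines(paste("CELLS", nt, 5L * nt), con)
  writeLines(paste(4L, volume$tets[, 1] - 1L, volume$tets[, 2] - 1L,
                   volume$tets[, 3] - 1L, volume$tets[, 4] - 1L), con)
  writeLines(paste("CELL_TYPES", nt), con)
  writeLines(as.character(rep(10L, nt)), con)
}

# --- TetGen-style .node/.ele ----------------------------------------------

read_node_ele <- function(node_path) {
  ele_path <- sub("\\.node$", ".ele", node_path)
  if (!file.exists(ele_path)) stop("missing .ele companion for ",
                                   node_path)
  nd <- scan(node_path, quiet = TRUE, comment.char = "#")
  nv <- as.integer(nd[1]); dim <- as.integer(nd[2])
  nattr <- as.integer(nd[3]); nbm <- as.integer(nd[4])
  stride <- 1L + dim + nattr + nbm
  body <- nd[-(1:4)]
  rows <- matrix(body[seq_len(nv * stride)], nv, stride, byrow = TRUE)
  first_index <- as.integer(rows[1, 1])
  v <- rows[, 2:(1 + dim), drop = FALSE]
  el <- scan(ele_path, quiet = TRUE, comment.char = "#")
  nt <- as.integer(el[1]); npt <- as.integer(el[2])
  nattr_e <- as.integer(el[3])
  if (npt != 4L) stop("only 4-node tets supported in ", ele_path)
  stride_e <- 1L + npt + nattr_e
  erows <- matrix(el[-(1:3)][seq_len(nt * stride_e)], nt, stride_e,
                  byrow = TRUE)
  tets <- matrix(as.integer(erows[, 2:5]), nt, 4) - first_index + 1L
  if (min(tets) < 1L || max(tets) > nv)
    stop("tet index out of range in ", ele_path)
  tet_volume(v, tets)
}

write_node_ele <- function(volume, node_path) {
  ele_path <- sub("\\.node$", ".ele", node_path)
  nv <- nrow(volume$vertices); nt <- nrow(volume$tets)
  con <- file(node_path, "w")
  writeLines(paste(nv, 3, 0, 0), con)
  writeLines(paste(seq_len(nv) - 1L,
                   apply(volume$vertices, 1L,
                         function(r) paste(fmt_num(r), collapse = " "))),
             con)
  close(con)
  con <- file(ele_path, "w")
  writeLines(paste(nt, 4, 0), con)
  writeLines(paste(seq_len(nt) - 1L, volume$tets[, 1] - 1L,
                   volume$tets[, 2] - 1L, volume$tets[, 3] - 1L,
                   volume$tets[, 4] - 1L), con)
  close(con)
}

# --- CSV scalar field -----------------------------------------------------

read_field_csv <- function(path) {
  dat <- utils::read.csv(path)
  if (!all(c("vertex_index", "value") %in% names(dat)))
    stop("field CSV must have header vertex_index,value: ", path)
  ord <- order(dat$vertex_index)
  dat <- dat[ord, ]
  if (!identical(as.integer(dat$vertex_index),
                 seq_len(nrow(dat)) - 1L))
    stop("field CSV vertex_index must cover 0..n-1: ", path)
  if (!all(is.finite(dat$value))) stop("non-finite field value in ", path)
  scalar_field(dat$value)
}

write_field_csv <- function(field, path) {
  utils::write.csv(
    data.frame(vertex_index = seq_along(field$values) - 1L,
               value = field$values),
    path, row.names = FALSE, quote = FALSE)
}

# --- JSON landmarks -------------------------------------------------------

read_landmarks_json <- function(path) {
  dat <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!is.list(dat)) stop("landmark JSON must be a list of objects")
  lapply(dat, function(o) {
    vp <- as.integer(o$vertex_path)
    if (any(vp < 0L)) stop("negative landmark vertex index in ", path)
    landmark_curve(vp + 1L, name = o$name)
  })
}

write_landmarks_json <- function(curves, path) {
  out <- lapply(curves, function(lc)
    list(name = lc$name %||% "", vertex_path = lc$vertex_path - 1L))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
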