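#' Triangle mesh in the patient coordinate frame
#'
#' Constructs a validated triangle surface mesh. Vertices are 3D points in
#' millimetres (+x patient-left, +y cranial, +z anterior); faces are triples
#' of 0-based vertex indices; an optional per-vertex RGB colour matrix (0-1)
#' may be attached.
#'
#' @param vertices numeric matrix, n x 3, vertex positions in mm.
#' @param faces integer matrix, m x 3, 0-based vertex indices.
#' @param colors optional numeric matrix, n x 3, per-vertex RGB in [0, 1].
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, colors = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (nrow(faces) > 0L && ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    if (nrow(colors) != nrow(vertices) || ncol(colors) != 3L)
      stop("colors must be an n x 3 matrix matching vertices")
  }
  mesh <- structure(list(vertices = vertices, faces = faces, colors = colors),
                    class = "tri_mesh")
  validate_mesh(mesh)
  mesh
}

#' Validate triangle mesh invariants
#'
#' Checks that all face indices are in range, that no face repeats a vertex
#' and that no face is degenerate (area below `area_tol`).
#'
#' @param mesh a [tri_mesh()].
#' @param area_tol minimum face area in mm^2 (default 1e-9).
#' @return The mesh, invisibly; errors describe the first violated invariant.
#' @export
validate_mesh <- function(mesh, area_tol = 1e-9) {
  stopifnot(inherits(mesh, "tri_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) > 0L) {
    if (min(f) < 0L || max(f) >= nrow(v))
      stop("face index out of range: indices must be 0-based and < vertex count")
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
      stop("face with a repeated vertex")
    a <- v[f[, 1] + 1L, , drop = FALSE]
    b <- v[f[, 2] + 1L, , drop = FALSE]
    cc <- v[f[, 3] + 1L, , drop = FALSE]
    n <- vec_cross(b - a, cc - a)
    area2 <- sqrt(rowSums(n^2))
    if (any(area2 / 2 <= area_tol))
      stop(sprintf("degenerate face with area <= %g mm^2 (first at face %d)",
                   area_tol, which(area2 / 2 <= area_tol)[1]))
  }
  invisible(mesh)
}

vec_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' @export
print.tri_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("tri_mesh: %d vertices, %d faces%s\n", nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$colors)) ", per-vertex colors" else ""))
  cat(sprintf("  bbox mm: x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

guess_format <- function(path, format = "auto") {
  format <- match.arg(format, c("auto", "obj", "ply", "stl"))
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("obj", "ply", "stl"))
    stop(sprintf("unsupported format token '%s' (use obj, ply or stl)", ext))
  ext
}

#' Read a triangle mesh from OBJ, PLY or STL
#'
#' OBJ and PLY are parsed as ASCII; STL as the standard binary layout (with a
#' fallback to ASCII STL). OBJ 1-based indices are converted to the package's
#' 0-based convention; PLY per-vertex uchar RGB is preserved. STL triangle
#' soup is welded into an indexed mesh by exact coordinate match.
#'
#' @param path file path.
#' @param format `"obj"`, `"ply"`, `"stl"`, or `"auto"` (from the extension).
#' @return A [tri_mesh()].
#' @export
read_mesh <- function(path, format = "auto") {
  if (!file.exists(path)) stop(sprintf("mesh file not found: %s", path))
  format <- guess_format(path, format)
  switch(format,
         obj = read_obj(path),
         ply = read_ply(path),
         stl = read_stl(path))
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines)
  flines <- grep("^f\\s", lines)
  v <- matrix(0, length(vlines), 3)
  for (i in seq_along(vlines)) {
    parts <- strsplit(trimws(lines[vlines[i]]), "\\s+")[[1]]
    xyz <- suppressWarnings(as.numeric(parts[2:4]))
    if (length(parts) < 4 || anyNA(xyz))
      stop(sprintf("malformed OBJ vertex record at line %d", vlines[i]))
    v[i, ] <- xyz
  }
  f <- matrix(0L, length(flines), 3)
  for (i in seq_along(flines)) {
    parts <- strsplit(trimws(lines[flines[i]]), "\\s+")[[1]][-1]
    if (length(parts) != 3)
      stop(sprintf("malformed OBJ face record at line %d (triangles only)", flines[i]))
    idx <- suppressWarnings(as.integer(vapply(strsplit(parts, "/"), `[`, "", 1)))
    if (anyNA(idx)) stop(sprintf("malformed OBJ face record at line %d", flines[i]))
    f[i, ] <- idx - 1L # OBJ is 1-based
  }
  tri_mesh(v, f)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || lines[1] != "ply") stop("malformed PLY: missing magic at line 1")
  endh <- match("end_header", lines)
  if (is.na(endh)) stop("malformed PLY: no end_header")
  header <- lines[seq_len(endh)]
  nv <- as.integer(sub(".*vertex\\s+", "", grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "", grep("^element face", header, value = TRUE)[1]))
  vprop_lines <- header[seq(grep("^element vertex", header)[1] + 1, length(header))]
  stopv <- grep("^element|^end_header", vprop_lines)[1]
  vprops <- sub("^property\\s+\\S+\\s+", "", vprop_lines[seq_len(stopv - 1)])
  has_rgb <- all(c("red", "green", "blue") %in% vprops)
  vdat <- strsplit(trimws(lines[endh + seq_len(nv)]), "\\s+")
  vmat <- t(vapply(vdat, function(p) as.numeric(p), numeric(length(vprops))))
  ix <- match(c("x", "y", "z"), vprops)
  if (anyNA(ix)) stop("malformed PLY: vertex element lacks x/y/z properties")
  v <- vmat[, ix, drop = FALSE]
  colors <- if (has_rgb) vmat[, match(c("red", "green", "blue"), vprops), drop = FALSE] / 255 else NULL
  f <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    ln <- endh + nv + i
    parts <- suppressWarnings(as.integer(strsplit(trimws(lines[ln]), "\\s+")[[1]]))
    if (length(parts) < 4 || parts[1] != 3L || anyNA(parts))
      stop(sprintf("malformed PLY face record at line %d (triangles only)", ln))
    f[i, ] <- parts[2:4]
  }
  tri_mesh(v, f, colors)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  if (length(header) < 80) stop("malformed STL: truncated header")
  if (grepl("^solid", rawToChar(header[1:5]))) {
    close(con)
    on.exit()
    return(read_stl_ascii(path))
  }
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  tris <- matrix(0, nf * 3, 3)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    if (length(rec) < 12) stop(sprintf("malformed STL: truncated facet %d", i))
    readBin(con, "raw", 2) # attribute byte count
    tris[3 * i - 2, ] <- rec[4:6]
    tris[3 * i - 1, ] <- rec[7:9]
    tris[3 * i, ] <- rec[10:12]
  }
  weld_triangles(tris)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  tris <- t(vapply(strsplit(trimws(lines[vl]), "\\s+"),
                   function(p) as.numeric(p[2:4]), numeric(3)))
  if (nrow(tris) %% 3 != 0) stop("malformed ASCII STL: vertex count not a multiple of 3")
  weld_triangles(tris)
}

# Weld a triangle soup into an indexed mesh; duplicates matched on exact
# printed coordinates so the dedup is deterministic.
weld_triangles <- function(tris) {
  key <- paste(sprintf("%.9g", tris[, 1]), sprintf("%.9g", tris[, 2]),
               sprintf("%.9g", tris[, 3]))
  uk <- !duplicated(key)
  ids <- match(key, key[uk]) - 1L
  v <- tris[uk, , drop = FALSE]
  f <- matrix(ids, ncol = 3, byrow = TRUE)
  tri_mesh(v, f)
}

#' Write a triangle mesh to OBJ, PLY or STL
#'
#' @param mesh a [tri_mesh()].
#' @param path output file path.
#' @param format `"obj"`, `"ply"`, `"stl"`, or `"auto"` (from the extension).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = "auto") {
  validate_mesh(mesh)
  if (nrow(mesh$vertices) == 0L) stop("refusing to write a mesh with no vertices")
  format <- guess_format(path, format)
  v <- mesh$vertices
  f <- mesh$faces
  if (format == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1] + 1L, f[, 2] + 1L, f[, 3] + 1L), con)
  } else if (format == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    rgb <- !is.null(mesh$colors)
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 if (rgb) c("property uchar red", "property uchar green", "property uchar blue"),
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    if (rgb) {
      cc <- round(mesh$colors * 255)
      writeLines(sprintf("%.6f %.6f %.6f %d %d %d", v[, 1], v[, 2], v[, 3],
                         cc[, 1], cc[, 2], cc[, 3]), con)
    } else {
      writeLines(sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
    }
    writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else { # binary stl
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    a <- v[f[, 1] + 1L, , drop = FALSE]
    b <- v[f[, 2] + 1L, , drop = FALSE]
    cc <- v[f[, 3] + 1L, , drop = FALSE]
    n <- vec_cross(b - a, cc - a)
    n <- n / pmax(sqrt(rowSums(n^2)), 1e-30)
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(n[i, ], a[i, ], b[i, ], cc[i, ])), con, size = 4,
               endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  }
  invisible(path)
}

#' Unsigned distance from points to a mesh surface
#'
#' Minimum point-to-triangle distance for one or more query points; 0 for
#' points on the surface.
#'
#' @param points numeric vector of length 3 or n x 3 matrix, in mm.
#' @param mesh a [tri_mesh()].
#' @return Numeric vector of distances in mm.
#' @export
point_surface_distance <- function(points, mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (nrow(mesh$faces) == 0L) stop("empty mesh: no faces to measure against")
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  cpp_closest_points(points, mesh$vertices, mesh$faces)$distance
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal (R'R != I within 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation determinant is not +1 within 1e-9")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.3f deg, translation (%.2f, %.2f, %.2f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_rigid(T2, T1)` is the transform that applies `T1` first, then
#' `T2`.
#'
#' @param t2,t1 [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_rigid <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) + t2$translation)
}

#' Invert a rigid transform
#' @param t a [rigid_transform()].
#' @return A [rigid_transform()].
#' @export
invert_rigid <- function(t) {
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation))
}

#' Rotation about a coordinate axis
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param degrees rotation angle.
#' @return A 3 x 3 rotation matrix.
#' @export
rotation_about <- function(axis = c("x", "y", "z"), degrees) {
  axis <- match.arg(axis)
  a <- degrees * pi / 180
  cs <- cos(a)
  sn <- sin(a)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, cs, -sn, 0, sn, cs), 3, byrow = TRUE),
         y = matrix(c(cs, 0, sn, 0, 1, 0, -sn, 0, cs), 3, byrow = TRUE),
         z = matrix(c(cs, -sn, 0, sn, cs, 0, 0, 0, 1), 3, byrow = TRUE))
}

#' Apply a rigid transform to a mesh
#'
#' Every vertex is mapped to `R v + t`; faces (and colors) are unchanged.
#'
#' @param mesh a [tri_mesh()].
#' @param transform a [rigid_transform()].
#' @return The transformed [tri_mesh()].
#' @export
apply_rigid <- function(mesh, transform) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(transform, "rigid_transform"))
  v <- mesh$vertices %*% t(transform$rotation)
  v <- sweep(v, 2, transform$translation, "+")
  out <- mesh
  out$vertices <- v
  out
}

#' Distances measured on the digital patient model
#'
#' Euclidean mode returns the straight-line distance between the two points;
#' on-surface mode snaps both points to their nearest mesh vertices and
#' returns the shortest along-edge path length (a graph approximation of the
#' geodesic).
#'
#' @param mesh a [tri_mesh()].
#' @param a,b length-3 points in mm, on or near the surface.
#' @param mode `"euclidean"` or `"on_surface"`.
#' @return Length in mm.
#' @export
measure_on_mesh <- function(mesh, a, b, mode = c("euclidean", "on_surface")) {
  mode <- match.arg(mode)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (mode == "euclidean") return(sqrt(sum((a - b)^2)))
  v <- mesh$vertices
  ia <- which.min(colSums((t(v) - a)^2))
  ib <- which.min(colSums((t(v) - b)^2))
  if (ia == ib) return(0)
  f <- mesh$faces + 1L
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  w <- sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  d <- igraph::distances(g, v = ia, to = ib, weights = w)[1, 1]
  if (!is.finite(d))
    stop("on_surface measurement failed: points lie on disconnected surface components")
  d
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem; requires consistently oriented
#' outward normals (as produced by the package's surface extraction).
#'
#' @param mesh a [tri_mesh()].
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1] + 1L, , drop = FALSE]
  b <- v[f[, 2] + 1L, , drop = FALSE]
  cc <- v[f[, 3] + 1L, , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Total surface area of a mesh
#' @param mesh a [tri_mesh()].
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1] + 1L, , drop = FALSE]
  b <- v[f[, 2] + 1L, , drop = FALSE]
  cc <- v[f[, 3] + 1L, , drop = FALSE]
  sum(sqrt(rowSums(vec_cross(b - a, cc - a)^2))) / 2
}
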