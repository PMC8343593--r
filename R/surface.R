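## Triangulated surface container, mesh utilities and plain-text I/O
## (PLY / OFF / legacy VTK polydata).

#' Triangulated surface mesh
#'
#' Container for the cortical (or fixture) surfaces consumed by the hinge
#' detection pipeline: vertex coordinates in mm and 1-based triangle
#' connectivity.  Construction validates manifoldness (every edge shared by
#' at most two triangles) and rejects degenerate triangles.
#'
#' @param vertices Numeric matrix, V x 3 (mm).
#' @param faces Integer matrix, F x 3, 1-based vertex indices.
#' @param validate Check manifoldness and degeneracy (disable only for
#'   meshes produced by trusted internal code).
#' @return An object of class \code{surface_mesh}.
#' @export
surface_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L || !all(is.finite(vertices)))
    stop("'vertices' must be a finite V x 3 matrix", call. = FALSE)
  if (ncol(faces) != 3L || any(faces < 1L) || any(faces > nrow(vertices)))
    stop("'faces' must be a 1-based F x 3 index matrix", call. = FALSE)
  if (validate) {
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
      stop("degenerate triangles (repeated vertex) in surface", call. = FALSE)
    ek <- .edge_keys(faces)
    cnt <- table(ek)
    if (any(cnt > 2L))
      stop("non-manifold surface: an edge is shared by > 2 triangles",
           call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

# canonical "lo_hi" keys of all face edges (3F keys)
.edge_keys <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "_")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("Surface mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# unique undirected edges as a 2-column matrix
.surface_edges <- function(surface) {
  f <- surface$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# sparse vertex adjacency (V x V, pattern) from the triangle edges
.surface_adjacency <- function(surface) {
  e <- .surface_edges(surface)
  V <- nrow(surface$vertices)
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(V, V))
}

#' Area-weighted outward vertex normals
#'
#' Face normals (right-hand rule on the triangle orientation) accumulated at
#' vertices with face-area weights and normalized.
#'
#' @param surface A \code{\link{surface_mesh}}.
#' @return V x 3 matrix of unit normals.
#' @export
vertex_normals <- function(surface) {
  V <- surface$vertices; f <- surface$faces
  a <- V[f[, 2], , drop = FALSE] - V[f[, 1], , drop = FALSE]
  b <- V[f[, 3], , drop = FALSE] - V[f[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])   # 2x area * unit normal
  ## accumulate with rowsum (fast, handles isolated vertices)
  idx <- as.vector(f)
  acc <- rowsum(rbind(fn, fn, fn), group = idx, reorder = TRUE)
  n <- matrix(0, nrow(V), 3)
  n[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' One level of midpoint subdivision
#'
#' Splits every triangle into four by inserting edge midpoints; the surface
#' geometry is unchanged (no smoothing), only the resolution increases.
#'
#' @param surface A \code{\link{surface_mesh}}.
#' @return The subdivided \code{surface_mesh}.
#' @export
subdivide_surface <- function(surface) {
  V <- surface$vertices; f <- surface$faces
  e <- .surface_edges(surface)
  key <- paste(e[, 1], e[, 2], sep = "_")
  mid_id <- stats::setNames(nrow(V) + seq_len(nrow(e)), key)
  mids <- (V[e[, 1], , drop = FALSE] + V[e[, 2], , drop = FALSE]) / 2
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "_")
  m12 <- mid_id[ekey(f[, 1], f[, 2])]
  m23 <- mid_id[ekey(f[, 2], f[, 3])]
  m31 <- mid_id[ekey(f[, 3], f[, 1])]
  faces <- rbind(cbind(f[, 1], m12, m31),
                 cbind(f[, 2], m23, m12),
                 cbind(f[, 3], m31, m23),
                 cbind(m12, m23, m31))
  surface_mesh(rbind(V, mids), faces, validate = FALSE)
}

#' Apply a rigid motion (or uniform scaling) to a surface
#'
#' @param surface A \code{\link{surface_mesh}}.
#' @param R 3 x 3 rotation matrix.
#' @param t Length-3 translation vector (mm).
#' @param scale Uniform scale factor.
#' @return The transformed \code{surface_mesh}.
#' @export
transform_surface <- function(surface, R = diag(3), t = c(0, 0, 0),
                              scale = 1) {
  V <- scale * surface$vertices %*% t(R)
  V <- sweep(V, 2, -as.numeric(t))
  surface_mesh(V, surface$faces, validate = FALSE)
}

## ---------------------------------------------------------------- file I/O

#' Read a triangulated surface from PLY, OFF or legacy VTK polydata
#'
#' Only ASCII variants are supported; faces with more than three vertices
#' are fan-triangulated.
#'
#' @param path File path; the format is chosen by extension
#'   (\code{.ply}, \code{.off}, \code{.vtk}).
#' @return A \code{\link{surface_mesh}}.
#' @export
read_surface <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = .read_ply(path),
         off = .read_off(path),
         vtk = .read_vtk_poly(path),
         stop("unsupported surface format: .", ext, call. = FALSE))
}

#' Write a triangulated surface to PLY, OFF or legacy VTK polydata
#'
#' @param surface A \code{\link{surface_mesh}}.
#' @param path Output path; format chosen by extension.
#' @param scalars Optional named list of per-vertex numeric vectors written
#'   as scalar fields (VTK only).
#' @return The path, invisibly.
#' @export
write_surface <- function(surface, path, scalars = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = .write_ply(surface, path),
         off = .write_off(surface, path),
         vtk = .write_vtk_poly(surface, path, scalars),
         stop("unsupported surface format: .", ext, call. = FALSE))
  invisible(path)
}

.read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1], "ply")) stop("not a PLY file", call. = FALSE)
  hend <- which(trimws(lines) == "end_header")[1]
  header <- lines[seq_len(hend)]
  if (any(grepl("format\\s+binary", header)))
    stop("binary PLY is not supported", call. = FALSE)
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", header, value = TRUE)[1]))
  body <- lines[(hend + 1L):length(lines)]
  vl <- body[seq_len(nv)]
  vparts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                  function(x) as.numeric(x[1:3])))
  fl <- body[nv + seq_len(nf)]
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    n <- as.integer(x[1])
    idx <- as.integer(x[2:(n + 1)]) + 1L
    if (n == 3L) matrix(idx, 1) else
      cbind(idx[1], idx[2:(n - 1)], idx[3:n])
  }))
  surface_mesh(vparts, faces)
}

.write_ply <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(surface$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(surface$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(surface$vertices, 1, function(v)
    sprintf("%.9g %.9g %.9g", v[1], v[2], v[3])), con)
  writeLines(apply(surface$faces - 1L, 1, function(f)
    sprintf("3 %d %d %d", f[1], f[2], f[3])), con)
}

.read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (trimws(lines[1]) != "OFF") stop("not an OFF file", call. = FALSE)
  cnt <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- cnt[1]; nf <- cnt[2]
  vparts <- do.call(rbind, lapply(strsplit(trimws(lines[2 + seq_len(nv)]),
                                           "\\s+"),
                                  function(x) as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(lines[2 + nv + seq_len(nf)]),
                                          "\\s+"), function(x) {
    n <- as.integer(x[1])
    idx <- as.integer(x[2:(n + 1)]) + 1L
    if (n == 3L) matrix(idx, 1) else cbind(idx[1], idx[2:(n - 1)], idx[3:n])
  }))
  surface_mesh(vparts, faces)
}

.write_off <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(surface$vertices), nrow(surface$faces)),
             con)
  writeLines(apply(surface$vertices, 1, function(v)
    sprintf("%.9g %.9g %.9g", v[1], v[2], v[3])), con)
  writeLines(apply(surface$faces - 1L, 1, function(f)
    sprintf("3 %d %d %d", f[1], f[2], f[3])), con)
}

.read_vtk_poly <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", lines)[1]
  ipoly <- grep("^POLYGONS", lines)[1]
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  nums <- as.numeric(unlist(strsplit(trimws(
    lines[(ip + 1L):(ipoly - 1L)]), "\\s+")))
  V <- matrix(nums[seq_len(3L * np)], ncol = 3, byrow = TRUE)
  hdr <- as.integer(strsplit(lines[ipoly], "\\s+")[[1]][2:3])
  iend <- grep("^(POINT_DATA|CELL_DATA)", lines)
  iend <- if (length(iend)) min(iend[iend > ipoly]) - 1L else length(lines)
  vals <- as.integer(unlist(strsplit(trimws(
    lines[(ipoly + 1L):iend]), "\\s+")))
  vals <- vals[seq_len(hdr[2])]
  faces <- list(); k <- 1L
  while (k <= length(vals)) {
    n <- vals[k]
    idx <- vals[(k + 1L):(k + n)] + 1L
    faces[[length(faces) + 1L]] <- if (n == 3L) matrix(idx, 1) else
      cbind(idx[1], idx[2:(n - 1)], idx[3:n])
    k <- k + n + 1L
  }
  surface_mesh(V, do.call(rbind, faces))
}

.write_vtk_poly <- function(surface, path, scalars = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(surface$vertices))), con)
  writeLines(apply(surface$vertices, 1, function(v)
    sprintf("%.9g %.9g %.9g", v[1], v[2], v[3])), con)
  nf <- nrow(surface$faces)
  writeLines(sprintf("POLYGONS %d %d", nf, 4L * nf), con)
  writeLines(apply(surface$faces - 1L, 1, function(f)
    sprintf("3 %d %d %d", f[1], f[2], f[3])), con)
  if (!is.null(scalars) && length(scalars)) {
    writeLines(sprintf("POINT_DATA %d", nrow(surface$vertices)), con)
    for (nm in names(scalars)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", scalars[[nm]]), con)
    }
  }
}

#' Export a volume mesh as legacy VTK unstructured grid
#'
#' Writes the (optionally deformed) hexahedral mesh with region labels and
#' growth state as cell fields, for inspection in ParaView.
#'
#' @param mesh A \code{\link{build_slab}} mesh.
#' @param path Output \code{.vtk} path.
#' @param state Optional \code{solve_state} whose displacements and growth
#'   ratios are written.
#' @return The path, invisibly.
#' @export
write_volume_vtk <- function(mesh, path, state = NULL) {
  coords <- mesh$coords
  if (!is.null(state)) coords <- coords + state$u
  g <- if (is.null(state)) mesh$g else state$g
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "bilayer slab", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", nrow(coords))), con)
  writeLines(apply(coords, 1, function(v)
    sprintf("%.9g %.9g %.9g", v[1], v[2], v[3])), con)
  M <- nrow(mesh$conn)
  writeLines(sprintf("CELLS %d %d", M, 9L * M), con)
  writeLines(apply(mesh$conn - 1L, 1, function(c8)
    paste(c(8L, c8), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", M), con)
  writeLines(rep("12", M), con)
  writeLines(sprintf("CELL_DATA %d", M), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", match(mesh$region, c("core", "cortex", "fiber"))),
             con)
  writeLines(c("SCALARS growth_ratio float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", g), con)
  writeLines(c("SCALARS growth_rate_scale float 1", "LOOKUP_TABLE default"),
             con)
  writeLines(sprintf("%.9g", mesh$rate_scale), con)
  invisible(path)
}
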