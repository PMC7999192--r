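#' Triangulated surface mesh
#'
#' The measurable artifact extracted from a 1-bit model: vertices in world mm
#' and positively oriented triangular faces, with provenance (segmentation
#' threshold, source, voxel width) carried along for audit.
#'
#' @param vertices numeric n x 3 matrix of vertex positions (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param provenance named list; typically `threshold_used`, `source`,
#'   `voxel` (output voxel width in mm, used as the default measurement slab
#'   thickness).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, provenance = list()) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop_condylometry("vertices and faces must have 3 columns")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop_condylometry("face indices out of range")
  structure(list(vertices = vertices, faces = faces, provenance = provenance),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  if (!is.null(x$provenance$threshold_used))
    cat(sprintf("  threshold_used %.4g\n", x$provenance$threshold_used))
  invisible(x)
}

#' Mesh surface area, enclosed volume and topology
#'
#' `mesh_area` sums triangle areas; `mesh_volume` applies the divergence
#' theorem (positive for outward-oriented closed surfaces);
#' `mesh_is_closed` checks that every edge is shared by exactly two faces
#' with opposite orientation (a closed, consistently oriented 2-manifold);
#' `mesh_euler` returns V - E + F (2 for a closed genus-0 surface).
#'
#' @param mesh a [surface_mesh()].
#' @return A scalar.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' @rdname mesh_area
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' @rdname mesh_area
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  # directed edges; closed + consistently oriented <=> every directed edge
  # appears exactly once and its reverse exactly once
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(e[, 1], e[, 2])
  rkey <- paste(e[, 2], e[, 1])
  !anyDuplicated(key) && all(key %in% rkey)
}

#' @rdname mesh_area
#' @export
mesh_euler <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  length(unique(as.vector(f))) - nrow(e) + nrow(f)
}

#' Apply a rigid motion to a mesh
#'
#' @param mesh a [surface_mesh()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation (mm).
#' @return The transformed [surface_mesh()].
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  surface_mesh(v, mesh$faces, mesh$provenance)
}

#' Read and write surface meshes (ASCII STL and PLY)
#'
#' @param mesh a [surface_mesh()].
#' @param file output path (`.stl` or `.ply`).
#' @return `write_mesh` invisibly returns `file`; `read_mesh` returns a
#'   [surface_mesh()].
#' @export
write_mesh <- function(mesh, file) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (grepl("\\.ply$", file, ignore.case = TRUE)) .write_ply(mesh, file)
  else .write_stl(mesh, file)
  invisible(file)
}

.write_stl <- function(mesh, file) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("solid condylometry threshold=%s",
                     format(mesh$provenance$threshold_used %||% NA)), con)
  p1 <- v[f[, 1], , drop = FALSE]; p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  a <- p2 - p1; b <- p3 - p1
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  txt <- sprintf(
    "facet normal %.8g %.8g %.8g\n outer loop\n  vertex %.8g %.8g %.8g\n  vertex %.8g %.8g %.8g\n  vertex %.8g %.8g %.8g\n endloop\nendfacet",
    n[, 1], n[, 2], n[, 3],
    p1[, 1], p1[, 2], p1[, 3], p2[, 1], p2[, 2], p2[, 3],
    p3[, 1], p3[, 2], p3[, 3])
  writeLines(txt, con)
  writeLines("endsolid condylometry", con)
}

.write_ply <- function(mesh, file) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment threshold_used %s",
                       format(mesh$provenance$threshold_used %||% NA)),
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.8g %.8g %.8g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(file) {
  if (grepl("\\.ply$", file, ignore.case = TRUE)) return(.read_ply(file))
  .read_stl(file)
}

.read_stl <- function(file) {
  lines <- readLines(file)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  if (nrow(nums) %% 3 != 0) stop_condylometry("malformed STL")
  key <- apply(nums, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- nums[uk, , drop = FALSE]
  faces <- matrix(match(key, key[uk]), ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces, provenance = list(source = file))
}

.read_ply <- function(file) {
  lines <- readLines(file)
  hend <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vt <- do.call(rbind, lapply(strsplit(lines[hend + seq_len(nv)], "\\s+"),
                              function(x) as.numeric(x[1:3])))
  ft <- do.call(rbind, lapply(strsplit(lines[hend + nv + seq_len(nf)], "\\s+"),
                              function(x) as.integer(x[2:4]) + 1L))
  surface_mesh(vt, ft, provenance = list(source = file))
}
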