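#' Triangle mesh container
#'
#' Construct a triangle mesh from a vertex matrix and a face index matrix.
#' Meshes are stored in millimetres with the +z axis pointing toward the
#' camera ring. Faces use counter-clockwise winding as seen from outside the
#' surface, so the winding-derived normal is the outward normal.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per face, three vertex indices
#'   (1-based, counter-clockwise seen from outside).
#' @param normals optional numeric matrix of per-face unit outward normals.
#'   When omitted (or when a stored normal is degenerate) normals are derived
#'   from the vertex winding. Stored normals must agree with the
#'   winding-derived direction.
#' @param tags optional character vector of per-face region labels (e.g.
#'   `"top_surface"`, `"wall"`, `"anatomy"`).
#' @return an object of class `triangle_mesh`: a list with elements
#'   `vertices`, `faces`, `normals` and `tags`.
#' @examples
#' m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                    matrix(c(1L, 2L, 3L), 1))
#' mesh_area(m)
#' @export
triangle_mesh <- function(vertices, faces, normals = NULL, tags = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0L) {
    if (ncol(faces) != 3L) stop("faces must have 3 columns")
    if (any(faces < 1L) || any(faces > nrow(vertices)))
      stop("face index out of range")
    if (any(faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
            faces[, 1L] == faces[, 3L]))
      stop("face with repeated vertex index")
  }
  derived <- face_normals(vertices, faces)
  if (is.null(normals)) {
    normals <- derived
  } else {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    if (!all(dim(normals) == dim(faces))) stop("normals dimension mismatch")
    len <- sqrt(rowSums(normals^2))
    bad <- !is.finite(len) | len < 1e-12
    normals[bad, ] <- derived[bad, , drop = FALSE]
    len[bad] <- 1
    normals <- normals / len
    agree <- rowSums(normals * derived)
    if (any(agree < 0.999 & rowSums(derived^2) > 0.5))
      stop("stored normals disagree with vertex winding")
  }
  if (!is.null(tags)) {
    tags <- as.character(tags)
    if (length(tags) != nrow(faces)) stop("tags length mismatch")
  }
  structure(list(vertices = vertices, faces = faces,
                 normals = normals, tags = tags),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces, total area",
      format(mesh_area(x), digits = 6), "mm^2\n")
  if (!is.null(x$tags)) {
    tb <- table(x$tags)
    cat("  tags:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# Unit normals from vertex winding; zero rows for degenerate faces.
face_normals <- function(vertices, faces) {
  if (nrow(faces) == 0L) return(matrix(0, 0, 3))
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c3 <- vertices[faces[, 3L], , drop = FALSE]
  e1 <- b - a
  e2 <- c3 - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  nz <- len > 1e-14
  n[nz, ] <- n[nz, , drop = FALSE] / len[nz]
  n[!nz, ] <- 0
  n
}

#' Per-face and total surface areas
#'
#' @param mesh a [triangle_mesh()].
#' @return `face_areas` returns a numeric vector of face areas (mm^2);
#'   `mesh_area` their sum.
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) return(numeric(0))
  a <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - a
  e2 <- v[f[, 3L], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(n^2))
}

#' @rdname face_areas
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Validate mesh topology and geometry
#'
#' Report-only structural check: counts degenerate (zero-area) faces,
#' boundary edges (used by exactly one face), non-manifold edges (used by
#' more than two faces), and edges whose two incident faces traverse them in
#' the same direction (inconsistent winding). A mesh is watertight when every
#' edge is shared by exactly two faces.
#'
#' @param mesh a [triangle_mesh()].
#' @param area_eps faces with area below this are counted degenerate (mm^2).
#' @return a list of class `mesh_validation` with elements `n_vertices`,
#'   `n_faces`, `degenerate_faces`, `boundary_edges`, `non_manifold_edges`,
#'   `inconsistent_edges`, `watertight` and `total_area`.
#' @export
validate_mesh <- function(mesh, area_eps = .tol$area_mm2) {
  f <- mesh$faces
  areas <- face_areas(mesh)
  degen <- sum(areas <= area_eps)
  if (nrow(f) == 0L) {
    return(structure(list(n_vertices = nrow(mesh$vertices), n_faces = 0L,
                          degenerate_faces = 0L, boundary_edges = 0L,
                          non_manifold_edges = 0L, inconsistent_edges = 0L,
                          watertight = FALSE, total_area = 0),
                     class = "mesh_validation"))
  }
  # directed half-edges
  he_from <- c(f[, 1L], f[, 2L], f[, 3L])
  he_to   <- c(f[, 2L], f[, 3L], f[, 1L])
  lo <- pmin(he_from, he_to)
  hi <- pmax(he_from, he_to)
  key <- paste(lo, hi)
  cnt <- table(key)
  boundary <- sum(cnt == 1L)
  nonmanifold <- sum(cnt > 2L)
  # winding: for an edge shared by two faces, the directed half-edges must be
  # antiparallel, i.e. among the half-edges with the same undirected key the
  # (from < to) and (from > to) orientations each appear once
  dirflag <- he_from < he_to
  same_dir <- tapply(dirflag, key, function(z)
    length(z) == 2L && z[1L] == z[2L])
  inconsistent <- sum(unlist(same_dir), na.rm = TRUE)
  structure(list(n_vertices = nrow(mesh$vertices), n_faces = nrow(f),
                 degenerate_faces = degen, boundary_edges = boundary,
                 non_manifold_edges = nonmanifold,
                 inconsistent_edges = inconsistent,
                 watertight = boundary == 0L && nonmanifold == 0L,
                 total_area = sum(areas)),
            class = "mesh_validation")
}

#' @export
print.mesh_validation <- function(x, ...) {
  cat("mesh validation:", x$n_faces, "faces,", x$n_vertices, "vertices\n")
  cat("  watertight:", x$watertight,
      "| boundary edges:", x$boundary_edges,
      "| non-manifold edges:", x$non_manifold_edges, "\n")
  cat("  degenerate faces:", x$degenerate_faces,
      "| inconsistent winding edges:", x$inconsistent_edges, "\n")
  cat("  total area:", format(x$total_area, digits = 8), "mm^2\n")
  invisible(x)
}

#' Select faces lying on the top surface
#'
#' Returns the indices of faces whose three vertices all lie at the top plane
#' `z_top` (within `tol`) and whose normal points upward. Used to exclude the
#' draped block surface around the corridor opening from area summaries.
#'
#' @param mesh a [triangle_mesh()].
#' @param z_top top plane height (mm). Defaults to the maximum vertex z among
#'   faces with an upward normal component.
#' @param tol absolute tolerance on vertex z (mm).
#' @return integer vector of face indices (possibly empty).
#' @export
tag_top_surface <- function(mesh, z_top = NULL, tol = 1e-6) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(integer(0))
  up <- mesh$normals[, 3L] > 0
  if (is.null(z_top)) {
    if (!any(up)) return(integer(0))
    zf <- cbind(mesh$vertices[f[, 1L], 3L], mesh$vertices[f[, 2L], 3L],
                mesh$vertices[f[, 3L], 3L])
    z_top <- max(zf[up, ])
  }
  z1 <- abs(mesh$vertices[f[, 1L], 3L] - z_top) <= tol
  z2 <- abs(mesh$vertices[f[, 2L], 3L] - z_top) <= tol
  z3 <- abs(mesh$vertices[f[, 3L], 3L] - z_top) <= tol
  unname(which(up & z1 & z2 & z3))
}
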