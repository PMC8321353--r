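#' Read an STL file
#'
#' Reads a triangle mesh from binary STL (80-byte header, little-endian
#' uint32 triangle count, 50-byte records). ASCII STL is auto-detected (file
#' starts with `solid` and is not consistent with the binary layout) and
#' parsed as well, since small fixtures are often hand-written. Vertices that
#' coincide exactly are merged so that topology checks (watertightness) work
#' on the result. Stored facet normals are kept when they agree with the
#' winding; zero or degenerate stored normals are replaced by winding-derived
#' ones.
#'
#' @param path file path.
#' @return a [triangle_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  size <- file.info(path)$size
  raw <- readBin(path, "raw", n = size)
  is_binary <- FALSE
  if (size >= 84) {
    ntri <- readBin(raw[81:84], "integer", size = 4, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && size == 84 + 50 * as.numeric(ntri))
      is_binary <- TRUE
  }
  if (is_binary) {
    .read_stl_binary(raw)
  } else {
    head <- rawToChar(raw[seq_len(min(80, size))])
    if (grepl("^\\s*solid", head)) {
      .read_stl_ascii(path)
    } else {
      stop("malformed STL: declared triangle count inconsistent with file size")
    }
  }
}

.read_stl_binary <- function(raw) {
  ntri <- readBin(raw[81:84], "integer", size = 4, endian = "little")
  if (ntri == 0L) {
    return(triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  }
  base <- 84 + 50 * (seq_len(ntri) - 1)           # record offsets
  idx <- as.vector(outer(1:48, base, `+`))        # the 12 float32 per record
  vals <- readBin(raw[idx], "double", size = 4, n = 12L * ntri,
                  endian = "little")
  rec <- matrix(vals, nrow = 12L)                  # cols = triangles
  normals <- t(rec[1:3, , drop = FALSE])
  verts <- rbind(t(rec[4:6, , drop = FALSE]),
                 t(rec[7:9, , drop = FALSE]),
                 t(rec[10:12, , drop = FALSE]))
  ord <- as.vector(t(matrix(seq_len(3L * ntri), ncol = 3L)))  # v1,v2,v3 per tri
  verts <- verts[ord, , drop = FALSE]
  .mesh_from_soup(verts, normals)
}

.read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vtx <- grep("^\\s*vertex\\b", lines, value = TRUE)
  nl <- grep("^\\s*facet\\s+normal\\b", lines, value = TRUE)
  if (length(vtx) %% 3L != 0L)
    stop("malformed ASCII STL: vertex count not a multiple of 3")
  parse_nums <- function(x, skip) {
    m <- matrix(NA_real_, length(x), 3L)
    for (i in seq_along(x)) {
      tok <- strsplit(trimws(x[i]), "\\s+")[[1L]]
      m[i, ] <- as.numeric(tok[(skip + 1L):(skip + 3L)])
    }
    m
  }
  verts <- parse_nums(vtx, 1L)
  normals <- if (length(nl) == length(vtx) / 3L) parse_nums(nl, 2L) else NULL
  .mesh_from_soup(verts, normals)
}

# triangle soup (3 rows per face) -> deduplicated triangle_mesh
.mesh_from_soup <- function(verts, normals = NULL) {
  key <- paste(verts[, 1L], verts[, 2L], verts[, 3L])
  uid <- match(key, key[!duplicated(key)])
  uv <- verts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3L, byrow = TRUE)
  degen <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
    faces[, 1L] == faces[, 3L]
  if (any(degen)) {
    faces <- faces[!degen, , drop = FALSE]
    if (!is.null(normals)) normals <- normals[!degen, , drop = FALSE]
    warning(sum(degen), " degenerate STL facet(s) dropped")
  }
  derived <- face_normals(uv, faces)
  if (!is.null(normals)) {
    len <- sqrt(rowSums(normals^2))
    bad <- !is.finite(len) | len < 1e-6
    # float32 rounding can tilt stored normals; renormalize and fall back to
    # winding where disagreement is large
    normals[!bad, ] <- normals[!bad, , drop = FALSE] / len[!bad]
    agree <- rowSums(normals * derived)
    bad <- bad | (agree < 0.999 & rowSums(derived^2) > 0.5)
    normals[bad, ] <- derived[bad, , drop = FALSE]
  } else {
    normals <- derived
  }
  triangle_mesh(uv, faces, normals)
}

#' Write a mesh as binary STL
#'
#' Little-endian binary STL: 80-byte header, uint32 triangle count, one
#' 50-byte record per face (normal, three vertices as float32, zero attribute
#' count). Round-trips through [read_stl()] to float32 precision.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param header optional header text (at most 79 bytes, must not start with
#'   `solid` to keep binary auto-detection unambiguous).
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, header = "reconsim binary STL") {
  if (grepl("^\\s*solid", header)) stop("binary STL header must not start with 'solid'")
  hdr <- charToRaw(header)
  if (length(hdr) > 80L) stop("header too long")
  hdr <- c(hdr, raw(80L - length(hdr)))
  ntri <- nrow(mesh$faces)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(as.integer(ntri), con, size = 4, endian = "little")
  if (ntri > 0L) {
    v <- mesh$vertices
    f <- mesh$faces
    dat <- cbind(mesh$normals,
                 v[f[, 1L], , drop = FALSE],
                 v[f[, 2L], , drop = FALSE],
                 v[f[, 3L], , drop = FALSE])   # ntri x 12
    fb <- writeBin(as.vector(t(dat)), raw(), size = 4, endian = "little")
    fb <- matrix(fb, nrow = 48L)
    recs <- rbind(fb, matrix(as.raw(0L), 2L, ntri))
    writeBin(as.vector(recs), con)
  }
  invisible(path)
}
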