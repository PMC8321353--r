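#' Ray-cast visibility of a surface point
#'
#' Independent brute-force visibility check used to verify the exact
#' clipping pipeline: a point on a mesh face is visible to a camera when its
#' source face is front-facing, the point projects inside the FOV rectangle,
#' and the segment from the point (offset slightly along the face normal) to
#' the aperture intersects no other mesh triangle.
#'
#' @param point 3D point on a mesh face.
#' @param face_id index of the source face (excluded from intersection).
#' @param camera a [make_camera()] camera.
#' @param mesh the mesh.
#' @param eps normal offset in mm to avoid self-intersection.
#' @return logical flag.
#' @export
ray_visible <- function(point, face_id, camera, mesh, eps = 1e-6) {
  if (as.vector(mesh$normals[face_id, ] %*% camera$frame$l) <= 0) return(FALSE)
  pr <- project_points(camera, point)
  hw <- camera$fov_half[1]; hh <- camera$fov_half[2]
  if (abs(pr$xy[1L, 1L]) > hw || abs(pr$xy[1L, 2L]) > hh) return(FALSE)
  o <- matrix(point + eps * mesh$normals[face_id, ], 1L)
  a <- matrix(camera$frame$aperture, 1L)
  as.logical(segments_blocked(o, a, as.integer(face_id),
                              mesh$vertices, mesh$faces, 1e-9)) == FALSE
}

#' Monte-Carlo estimate of the reconstructable area fraction
#'
#' Samples points area-uniformly on the mesh (per-face allocation by
#' cumulative area inversion, uniform barycentric sampling within faces) and
#' counts the fraction visible to at least `T` cameras by ray casting. The
#' estimate converges to the exact pipeline's `Ar / total_area`; the
#' binomial standard error quantifies the Monte-Carlo uncertainty.
#'
#' @param mesh a [triangle_mesh()].
#' @param setup a [make_ring_setup()].
#' @param T reconstructability threshold.
#' @param n_samples number of sample points.
#' @param seed mandatory integer seed; the global RNG state is left
#'   untouched.
#' @param eps normal offset passed to the ray test (mm).
#' @return a list of class `oracle_estimate`: `fraction`, `se`
#'   (`sqrt(p(1-p)/n)`), `n_samples`, `hits`, `seed`.
#' @export
mc_reconstructable_fraction <- function(mesh, setup, T = 2L, n_samples = 20000L,
                                        seed, eps = 1e-6) {
  if (missing(seed)) stop("seed is required")
  if (n_samples < 1L) stop("n_samples must be positive")
  rng <- .local_rng(seed)
  areas <- face_areas(mesh)
  cum <- cumsum(areas) / sum(areas)
  u <- rng$runif(n_samples)
  fid <- findInterval(u, cum) + 1L
  fid[fid > length(areas)] <- length(areas)
  r1 <- rng$runif(n_samples)
  r2 <- rng$runif(n_samples)
  flip <- r1 + r2 > 1
  r1[flip] <- 1 - r1[flip]
  r2[flip] <- 1 - r2[flip]
  f <- mesh$faces[fid, , drop = FALSE]
  A <- mesh$vertices[f[, 1L], , drop = FALSE]
  B <- mesh$vertices[f[, 2L], , drop = FALSE]
  C <- mesh$vertices[f[, 3L], , drop = FALSE]
  pts <- A + r1 * (B - A) + r2 * (C - A)
  nrm <- mesh$normals[fid, , drop = FALSE]
  orig <- pts + eps * nrm
  counts <- integer(n_samples)
  for (cam in setup$cameras) {
    facing <- as.vector(nrm %*% cam$frame$l) > 0
    live <- which(facing)
    if (length(live) == 0L) next
    pr <- project_points(cam, pts[live, , drop = FALSE])
    hw <- cam$fov_half[1]; hh <- cam$fov_half[2]
    infov <- abs(pr$xy[, 1L]) <= hw & abs(pr$xy[, 2L]) <= hh
    live <- live[infov]
    if (length(live) == 0L) next
    ap <- matrix(cam$frame$aperture, length(live), 3L, byrow = TRUE)
    blocked <- segments_blocked(orig[live, , drop = FALSE], ap,
                                as.integer(fid[live]),
                                mesh$vertices, mesh$faces, 1e-9)
    counts[live[!blocked]] <- counts[live[!blocked]] + 1L
  }
  hits <- sum(counts >= T)
  p <- hits / n_samples
  structure(list(fraction = p, se = sqrt(p * (1 - p) / n_samples),
                 n_samples = n_samples, hits = hits, seed = seed),
            class = "oracle_estimate")
}

#' @export
print.oracle_estimate <- function(x, ...) {
  cat("Monte-Carlo visibility estimate:", format(x$fraction, digits = 5),
      "+/-", format(x$se, digits = 3), "(se, n =", x$n_samples, ")\n")
  invisible(x)
}
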