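.norm3 <- function(v) sqrt(sum(v^2))
.unit3 <- function(v) v / .norm3(v)
.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Look-at camera frame
#'
#' Derives the orthonormal camera axes from the look-at parametrization:
#' the look-at axis `l = (a - F)/|a - F|` points from the reference point to
#' the aperture, the right axis is `r = up_hint x l` normalized, and the up
#' axis is `u = l x r`. The viewing direction toward the scene is `-l`.
#'
#' @param aperture 3D aperture position `a` (mm).
#' @param ref central reference point `F` that the camera looks at (mm).
#' @param up_hint approximate up direction; must not be parallel to `a - F`.
#' @return a list of class `camera_frame` with unit axes `l`, `r`, `up`,
#'   plus `aperture` and `ref`.
#' @export
look_at_axes <- function(aperture, ref = c(0, 0, 0), up_hint = c(0, 1, 0)) {
  aperture <- as.numeric(aperture); ref <- as.numeric(ref)
  d <- aperture - ref
  if (.norm3(d) < 1e-12) stop("aperture coincides with the reference point")
  l <- .unit3(d)
  rx <- .cross3(as.numeric(up_hint), l)
  if (.norm3(rx) < 1e-9)
    stop("degenerate frame: up_hint parallel to the viewing axis")
  r <- .unit3(rx)
  u <- .cross3(l, r)
  structure(list(aperture = aperture, ref = ref, l = l, r = r, up = u),
            class = "camera_frame")
}

#' Extrinsic camera matrix
#'
#' The 3x4 extrinsic matrix `[R | t]` with rotation rows `(r; u; -l)` and
#' translation `t = -R a`. World points map to camera coordinates with the
#' scene at positive third coordinate.
#'
#' @param frame a [look_at_axes()] frame.
#' @return 3x4 numeric matrix.
#' @export
extrinsic_matrix <- function(frame) {
  R <- rbind(frame$r, frame$up, -frame$l)
  dimnames(R) <- NULL
  t <- -R %*% frame$aperture
  cbind(R, t)
}

#' Intrinsic camera matrix
#'
#' Upper-triangular 3x3 intrinsic matrix with negative focal diagonal,
#' zero skew and zero principal-point offset:
#' `diag(-f/sx, -f/sy, 1)`.
#'
#' @param f image distance (pinhole to sensor, mm).
#' @param sx,sy pixel size in x and y (mm per pixel).
#' @return 3x3 numeric matrix.
#' @export
intrinsic_matrix <- function(f = 1, sx = 1, sy = 1) {
  if (f <= 0 || sx <= 0 || sy <= 0) stop("f, sx, sy must be positive")
  diag(c(-f / sx, -f / sy, 1))
}

#' Pinhole camera
#'
#' Bundles a camera frame with its extrinsic, intrinsic and projection
#' matrices and the image-space half-extents of the field-of-view rectangle.
#' The FOV is specified as a width x height rectangle in the focal plane
#' (the plane through the reference point normal to the viewing axis); its
#' image-space half-extents follow from similar triangles at the
#' aperture-to-reference distance.
#'
#' @param frame a [look_at_axes()] frame.
#' @param fov length-2 vector: FOV width and height in the focal plane (mm).
#' @param f,sx,sy intrinsic parameters, see [intrinsic_matrix()].
#' @return a list of class `camera` with `frame`, `Mext`, `Mint`, `P`,
#'   `f`, `sx`, `sy`, `dist` (aperture-to-reference distance) and
#'   `fov_half` (image-space half-extents).
#' @export
make_camera <- function(frame, fov = c(36, 24), f = 1, sx = 1, sy = 1) {
  if (any(fov <= 0)) stop("fov extents must be positive")
  Mext <- extrinsic_matrix(frame)
  Mint <- intrinsic_matrix(f, sx, sy)
  dist <- .norm3(frame$aperture - frame$ref)
  fov_half <- c((f / sx) * fov[1] / 2 / dist, (f / sy) * fov[2] / 2 / dist)
  structure(list(frame = frame, Mext = Mext, Mint = Mint,
                 P = Mint %*% Mext, f = f, sx = sx, sy = sy,
                 dist = dist, fov = fov, fov_half = fov_half),
            class = "camera")
}

#' Project world points into a camera's image space
#'
#' Applies the homogeneous projection `P (x, y, z, 1)'` and dehomogenizes.
#' All points must lie strictly in front of the camera (positive depth along
#' the viewing axis).
#'
#' @param camera a [make_camera()] camera.
#' @param points numeric matrix, one world point per row (or a length-3
#'   vector for a single point).
#' @return a list with `xy` (n x 2 image coordinates), `w` (axial depth,
#'   the homogeneous divisor) and `dist` (Euclidean aperture-to-point
#'   distances, the depth used for occlusion ordering).
#' @export
project_points <- function(camera, points) {
  if (is.null(dim(points))) points <- matrix(points, 1L)
  h <- camera$P %*% rbind(t(points), 1)
  w <- h[3L, ]
  if (any(w <= 0))
    stop("point at or behind the aperture plane cannot be projected")
  d <- sqrt(colSums((t(points) - camera$frame$aperture)^2))
  list(xy = cbind(h[1L, ] / w, h[2L, ] / w), w = w, dist = d)
}

#' Image-space field-of-view rectangle
#'
#' @param camera a [make_camera()] camera.
#' @return list with `half` (half-extents) and `ring` (closed rectangle as a
#'   polygon ring usable in 2D boolean operations).
#' @export
fov_rectangle <- function(camera) {
  hw <- camera$fov_half[1]; hh <- camera$fov_half[2]
  list(half = c(hw, hh),
       ring = list(x = c(-hw, hw, hw, -hw), y = c(-hh, -hh, hh, hh)))
}

#' Confocal camera ring
#'
#' Places `M` identical pinhole cameras equidistantly on a ring of diameter
#' `d` at height `h` above the common reference point, all looking at the
#' reference point. This models a common-main-objective microscope whose
#' usable stereo baseline equals the main objective diameter: every aperture
#' sits at the same distance `sqrt(h^2 + (d/2)^2)` from the reference point
#' (the simulated main-lens focal length), making the ring confocal.
#'
#' @param M number of cameras (>= 1).
#' @param d ring diameter in mm (the maximum usable baseline).
#' @param h working distance in mm (axial distance ring plane to reference).
#' @param ref common reference point (world origin by default).
#' @param fov FOV width and height in the focal plane (mm).
#' @param start_angle angular position of the first camera (radians).
#' @param f,sx,sy intrinsics, see [intrinsic_matrix()].
#' @param up_hint up hint for the look-at frames; cameras whose viewing axis
#'   is parallel to it fall back to `c(1, 0, 0)`.
#' @return a list of class `ring_setup` with `cameras` (list of cameras),
#'   `M`, `d`, `h`, `ref`, `fov`, `start_angle`, `radius` (aperture-to-ref
#'   distance).
#' @export
make_ring_setup <- function(M, d = 30, h = 400, ref = c(0, 0, 0),
                            fov = c(36, 24), start_angle = 0,
                            f = 1, sx = 1, sy = 1, up_hint = c(0, 1, 0)) {
  if (M < 1L) stop("M must be at least 1")
  if (d <= 0 || h <= 0) stop("d and h must be positive")
  ang <- start_angle + 2 * pi * (seq_len(M) - 1L) / M
  cams <- vector("list", M)
  for (k in seq_len(M)) {
    a <- ref + c(d / 2 * cos(ang[k]), d / 2 * sin(ang[k]), h)
    hint <- up_hint
    if (.norm3(.cross3(hint, .unit3(a - ref))) < 1e-9) hint <- c(1, 0, 0)
    cams[[k]] <- make_camera(look_at_axes(a, ref, hint), fov = fov,
                             f = f, sx = sx, sy = sy)
  }
  structure(list(cameras = cams, M = as.integer(M), d = d, h = h,
                 ref = ref, fov = fov, start_angle = start_angle,
                 radius = sqrt(h^2 + (d / 2)^2)),
            class = "ring_setup")
}

#' @export
print.ring_setup <- function(x, ...) {
  cat("ring_setup:", x$M, "cameras, d =", x$d, "mm, h =", x$h,
      "mm, aperture-to-focus", format(x$radius, digits = 6), "mm\n")
  cat("  FOV", x$fov[1], "x", x$fov[2], "mm in the focal plane\n")
  invisible(x)
}
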