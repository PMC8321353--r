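#' Local planar frame of a triangular face
#'
#' Builds the in-plane 2D coordinate system used for the 2.5D boolean
#' operations: origin at the first vertex, x axis along the first edge, the
#' plane normal from the winding, and the y axis completing the frame so
#' that the third vertex has positive local y.
#'
#' @param v1,v2,v3 the face vertices (3D, mm).
#' @return a list of class `local_frame` with `origin`, `x`, `y`, `n`.
#' @export
local_frame <- function(v1, v2, v3) {
  o <- as.numeric(v1)
  e1 <- as.numeric(v2) - o
  if (.norm3(e1) < 1e-12) stop("degenerate face: coincident vertices")
  x <- .unit3(e1)
  n0 <- .cross3(x, as.numeric(v3) - o)
  if (.norm3(n0) < 1e-12) stop("degenerate face: collinear vertices")
  n <- .unit3(n0)
  y <- .unit3(.cross3(n, x))
  structure(list(origin = o, x = x, y = y, n = n), class = "local_frame")
}

#' Transform points between 3D and a local planar frame
#'
#' `to_local` maps in-plane 3D points to 2D coordinates
#' `((p - o) . x, (p - o) . y)`; `from_local` is its inverse
#' `o + p1 x + p2 y`. The pair is an isometry on the frame's plane, so
#' polygon areas are preserved.
#'
#' @param frame a [local_frame()].
#' @param points for `to_local` an n x 3 matrix (or length-3 vector) of 3D
#'   points; for `from_local` an n x 2 matrix (or length-2 vector).
#' @param tol maximum allowed out-of-plane distance (mm) in `to_local`.
#' @return n x 2 (respectively n x 3) coordinate matrix.
#' @export
to_local <- function(frame, points, tol = 1e-6) {
  if (is.null(dim(points))) points <- matrix(points, 1L)
  d <- sweep(points, 2L, frame$origin)
  off <- abs(d %*% frame$n)
  if (any(off > tol))
    stop("point lies off the frame's plane by ", format(max(off)), " mm")
  cbind(d %*% frame$x, d %*% frame$y)
}

#' @rdname to_local
#' @export
from_local <- function(frame, points) {
  if (is.null(dim(points))) points <- matrix(points, 1L)
  t(frame$origin + outer(frame$x, points[, 1L]) + outer(frame$y, points[, 2L]))
}

## ---- planar polygon sets -------------------------------------------------
## A polygon set is a list of rings, each ring list(x =, y =). Exterior rings
## are counter-clockwise (positive signed area), holes clockwise; nonzero
## fill rule throughout, matching the clipping kernel.

ring_area <- function(ring) {
  x <- ring$x; y <- ring$y
  0.5 * sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)
}

ps_triangle <- function(p) {
  # 3x2 matrix -> one CCW ring
  r <- list(x = p[, 1L], y = p[, 2L])
  if (ring_area(r) < 0) r <- list(x = rev(r$x), y = rev(r$y))
  list(r)
}

ps_clean <- function(ps, area_eps) {
  if (length(ps) == 0L) return(list())
  keep <- vapply(ps, function(r)
    length(r$x) >= 3L && abs(ring_area(r)) > area_eps, logical(1L))
  ps[keep]
}

# Collapse consecutive near-coincident vertices (including the wrap-around
# pair). Clipping outputs occasionally carry zero-length spur edges at the
# snapping scale; left in place they corrupt later boolean operations.
ring_dedup <- function(r, tol) {
  n <- length(r$x)
  if (n < 3L) return(r)
  nx <- c(r$x[-1L], r$x[1L])
  ny <- c(r$y[-1L], r$y[1L])
  keep <- (abs(r$x - nx) > tol) | (abs(r$y - ny) > tol)
  if (all(keep)) return(r)
  list(x = r$x[keep], y = r$y[keep])
}

#' Area of a planar polygon set
#'
#' Sum of signed ring areas: exterior rings counter-clockwise positive,
#' holes clockwise negative, so hole areas are subtracted.
#'
#' @param ps a polygon set (list of rings, each `list(x =, y =)`).
#' @return nonnegative area.
#' @export
polygon_area <- function(ps) {
  if (length(ps) == 0L) return(0)
  a <- sum(vapply(ps, ring_area, numeric(1L)))
  max(a, 0)
}

#' 2D boolean operations on polygon sets
#'
#' Intersection, difference and union of planar polygon sets via the Vatti
#' clipping kernel (nonzero fill rule, holes supported). Results are cleaned:
#' rings whose absolute area is below `area_eps` (slivers from clipping) are
#' discarded. Polygons that touch only along a boundary of zero area count
#' as not overlapping.
#'
#' @param op `"intersect"`, `"subtract"` or `"union"`.
#' @param A,B polygon sets in the same 2D space.
#' @param area_eps sliver threshold for cleaning the result.
#' @param snap absolute lattice spacing of the clipping kernel. All
#'   operations in one coordinate space must share one lattice (origin 0),
#'   so that coincident edges coincide exactly and results of one operation
#'   enter the next without re-snapping drift. The default (1e-8) suits
#'   local face frames in mm; image-space callers use 1e-12.
#' @return a polygon set (possibly empty list).
#' @export
boolean_2d <- function(op = c("intersect", "subtract", "union"), A, B,
                       area_eps = .tol$area_mm2, snap = .tol$snap_mm) {
  op <- match.arg(op)
  if (length(A) == 0L)
    return(if (op == "union") ps_clean(B, area_eps) else list())
  if (length(B) == 0L)
    return(if (op == "intersect") list() else ps_clean(A, area_eps))
  cop <- switch(op, intersect = "intersection", subtract = "minus",
                union = "union")
  # The lattice must be coarse enough to swallow the ~1e-9 mm float noise of
  # back-projected vertices: on a finer grid, nearly-collinear overlapping
  # edges from different cameras cross at micro-scale and the kernel can
  # mis-resolve the topology. 1e-8 mm is still orders of magnitude below any
  # geometric feature.
  out <- polyclip::polyclip(A, B, op = cop,
                            fillA = "nonzero", fillB = "nonzero",
                            x0 = 0, y0 = 0, eps = snap)
  out <- lapply(out, ring_dedup, tol = snap)
  ps_clean(out, area_eps)
}

ps_union_all <- function(pss, area_eps, snap = .tol$snap_mm) {
  # union of a list of polygon sets in one kernel call: with the nonzero
  # fill rule, the rings of all sets together already describe the union
  if (length(pss) == 0L) return(list())
  if (length(pss) == 1L) return(ps_clean(pss[[1L]], area_eps))
  boolean_2d("union", do.call(c, pss[-1L]), pss[[1L]],
             area_eps = area_eps, snap = snap)
}

#' Back-project an image-space polygon onto a 3D plane
#'
#' Each 2D vertex defines a ray from the camera aperture; the 3D vertex is
#' the intersection of that ray with the given plane. Projecting the result
#' forward reproduces the 2D polygon. Used to lift FOV- and occlusion-
#' clipped fragments back onto their parent face's plane.
#'
#' @param camera a [make_camera()] camera.
#' @param ps polygon set in the camera's image space.
#' @param plane_point,plane_normal a point on the target plane and its
#'   normal (3D).
#' @return list of 3D rings (matrices, one vertex per row), in ring order
#'   of `ps`.
#' @export
back_project <- function(camera, ps, plane_point, plane_normal) {
  a <- camera$frame$aperture
  fr <- camera$frame
  sxf <- camera$sx / camera$f
  syf <- camera$sy / camera$f
  n <- as.numeric(plane_normal)
  rhs <- sum(n * (as.numeric(plane_point) - a))
  lapply(ps, function(ring) {
    # camera-space direction for image point (ix, iy) is
    # (-ix sx/f, -iy sy/f, 1) in the (r, u, -l) basis
    dirs <- outer(-ring$x * sxf, fr$r) + outer(-ring$y * syf, fr$up) -
      matrix(fr$l, length(ring$x), 3L, byrow = TRUE)
    denom <- dirs %*% n
    if (any(abs(denom) < 1e-14))
      stop("vertex ray parallel to the target plane")
    tt <- rhs / denom
    sweep(dirs * as.vector(tt), 2L, -a)
  })
}

## ---- triangulation (export only) ----------------------------------------

# Ear-clip a simple CCW ring given as list(x, y); returns list of index
# triples into the ring. Assumes no self-intersections (clipping output).
.ear_clip <- function(x, y) {
  n <- length(x)
  idx <- seq_len(n)
  tris <- list()
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  guard <- 0L
  while (length(idx) > 3L && guard < 10000L) {
    guard <- guard + 1L
    m <- length(idx)
    clipped <- FALSE
    for (k in seq_len(m)) {
      i0 <- idx[if (k == 1L) m else k - 1L]
      i1 <- idx[k]
      i2 <- idx[if (k == m) 1L else k + 1L]
      cr <- cross2(x[i0], y[i0], x[i1], y[i1], x[i2], y[i2])
      if (cr <= 0) next              # reflex or degenerate corner
      # no other active vertex inside the candidate ear
      others <- setdiff(idx, c(i0, i1, i2))
      inside <- FALSE
      for (j in others) {
        d1 <- cross2(x[i0], y[i0], x[i1], y[i1], x[j], y[j])
        d2 <- cross2(x[i1], y[i1], x[i2], y[i2], x[j], y[j])
        d3 <- cross2(x[i2], y[i2], x[i0], y[i0], x[j], y[j])
        if (d1 >= 0 && d2 >= 0 && d3 >= 0) { inside <- TRUE; break }
      }
      if (inside) next
      tris[[length(tris) + 1L]] <- c(i0, i1, i2)
      idx <- idx[idx != i1]
      clipped <- TRUE
      break
    }
    if (!clipped) break              # numerically stuck; fan the rest
  }
  if (length(idx) == 3L) {
    tris[[length(tris) + 1L]] <- idx
  } else if (length(idx) > 3L) {
    for (k in 2L:(length(idx) - 1L))
      tris[[length(tris) + 1L]] <- c(idx[1L], idx[k], idx[k + 1L])
  }
  tris
}

# Bridge holes into their enclosing exterior ring (rightmost-vertex bridge),
# then ear-clip. ps: polygon set. Returns list of 2D triangles (3x2).
triangulate_polyset <- function(ps) {
  if (length(ps) == 0L) return(list())
  areas <- vapply(ps, ring_area, numeric(1L))
  ext <- which(areas > 0)
  holes <- which(areas < 0)
  used_holes <- logical(length(ps))
  out <- list()
  point_in_ring <- function(px, py, r) {
    x <- r$x; y <- r$y; n <- length(x); j <- n; inside <- FALSE
    for (i in seq_len(n)) {
      if ((y[i] > py) != (y[j] > py) &&
          px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
        inside <- !inside
      j <- i
    }
    inside
  }
  for (ei in ext) {
    r <- ps[[ei]]
    x <- r$x; y <- r$y
    for (hi in holes) {
      if (used_holes[hi]) next
      h <- ps[[hi]]
      if (!point_in_ring(h$x[1L], h$y[1L], r)) next
      used_holes[hi] <- TRUE
      # connect the hole's rightmost vertex to the nearest exterior vertex
      # to its right (simple bridge; clipping output is well-behaved)
      hk <- which.max(h$x)
      hx <- h$x[hk]; hy <- h$y[hk]
      cand <- which(x >= hx)
      if (length(cand) == 0L) cand <- seq_along(x)
      bk <- cand[which.min((x[cand] - hx)^2 + (y[cand] - hy)^2)]
      # splice: ext[1..bk], hole[hk..], hole[..hk], ext[bk..]
      hord <- c(hk:length(h$x), if (hk > 1L) 1:(hk - 1L)) # hole is CW already
      x <- c(x[1:bk], h$x[hord], h$x[hk], x[bk:length(x)])
      y <- c(y[1:bk], h$y[hord], h$y[hk], y[bk:length(y)])
    }
    tris <- .ear_clip(x, y)
    for (tr in tris)
      out[[length(out) + 1L]] <- cbind(x[tr], y[tr])
  }
  out
}
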