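#' Cull faces invisible to a camera
#'
#' First stage of the per-camera pipeline. A face survives only if (a) its
#' outward normal points toward the camera side, i.e. the dot product with
#' the axis from the reference point to the aperture is strictly positive
#' (backfaces and faces exactly on the contour are removed), and (b) its
#' image-space triangle is not entirely outside the FOV rectangle. Faces
#' whose image crosses the FOV border are flagged for clipping.
#'
#' @param mesh a [triangle_mesh()]; every vertex must be strictly in front
#'   of the camera.
#' @param camera a [make_camera()] camera.
#' @return a list of class `candidate_faces`: `idx` (face indices),
#'   `tri_img` (n x 6 image triangles, x1,y1,x2,y2,x3,y3), `min_depth`
#'   (smallest Euclidean aperture-to-vertex distance per face, mm),
#'   `fov_status` (`"inside"` or `"straddling"`) and `circ` (n x 3
#'   enclosing-circle centre and radius in image space).
#' @export
cull_faces <- function(mesh, camera) {
  pr <- project_points(camera, mesh$vertices)
  f <- mesh$faces
  keep <- as.vector(mesh$normals %*% camera$frame$l) > 0
  idx <- which(keep)
  if (length(idx) == 0L)
    return(structure(list(idx = integer(0),
                          tri_img = matrix(0, 0, 6), min_depth = numeric(0),
                          fov_status = character(0), circ = matrix(0, 0, 3)),
                     class = "candidate_faces"))
  fi <- f[idx, , drop = FALSE]
  x1 <- pr$xy[fi[, 1L], 1L]; y1 <- pr$xy[fi[, 1L], 2L]
  x2 <- pr$xy[fi[, 2L], 1L]; y2 <- pr$xy[fi[, 2L], 2L]
  x3 <- pr$xy[fi[, 3L], 1L]; y3 <- pr$xy[fi[, 3L], 2L]
  hw <- camera$fov_half[1]; hh <- camera$fov_half[2]
  xmin <- pmin(x1, x2, x3); xmax <- pmax(x1, x2, x3)
  ymin <- pmin(y1, y2, y3); ymax <- pmax(y1, y2, y3)
  inside <- xmin >= -hw & xmax <= hw & ymin >= -hh & ymax <= hh
  outside <- xmax < -hw | xmin > hw | ymax < -hh | ymin > hh
  sel <- !outside
  idx <- idx[sel]
  tri_img <- cbind(x1, y1, x2, y2, x3, y3)[sel, , drop = FALSE]
  fov_status <- ifelse(inside[sel], "inside", "straddling")
  fi <- fi[sel, , drop = FALSE]
  min_depth <- pmin(pr$dist[fi[, 1L]], pr$dist[fi[, 2L]], pr$dist[fi[, 3L]])
  structure(list(idx = idx, tri_img = tri_img, min_depth = min_depth,
                 fov_status = fov_status, circ = .circumcircles(tri_img)),
            class = "candidate_faces")
}

# circumcircle per image triangle; near-degenerate triangles fall back to an
# enclosing circle around the longest edge (still containing all vertices)
.circumcircles <- function(tri) {
  ax <- tri[, 1L]; ay <- tri[, 2L]
  bx <- tri[, 3L]; by <- tri[, 4L]
  cx <- tri[, 5L]; cy <- tri[, 6L]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  scale2 <- pmax(a2, b2, c2, 1e-300)
  ok <- abs(d) > 1e-12 * scale2
  ux <- uy <- numeric(length(ax))
  ux[ok] <- (a2[ok] * (by[ok] - cy[ok]) + b2[ok] * (cy[ok] - ay[ok]) +
               c2[ok] * (ay[ok] - by[ok])) / d[ok]
  uy[ok] <- (a2[ok] * (cx[ok] - bx[ok]) + b2[ok] * (ax[ok] - cx[ok]) +
               c2[ok] * (bx[ok] - ax[ok])) / d[ok]
  if (any(!ok)) {
    # midpoint of the two farthest-apart vertices
    dab <- (ax - bx)^2 + (ay - by)^2
    dac <- (ax - cx)^2 + (ay - cy)^2
    dbc <- (bx - cx)^2 + (by - cy)^2
    w <- !ok
    pick <- pmax.int(dab[w], dac[w], dbc[w])
    mx <- ifelse(pick == dab[w], (ax[w] + bx[w]) / 2,
                 ifelse(pick == dac[w], (ax[w] + cx[w]) / 2, (bx[w] + cx[w]) / 2))
    my <- ifelse(pick == dab[w], (ay[w] + by[w]) / 2,
                 ifelse(pick == dac[w], (ay[w] + cy[w]) / 2, (by[w] + cy[w]) / 2))
    ux[w] <- mx; uy[w] <- my
  }
  r <- sqrt(pmax((ax - ux)^2 + (ay - uy)^2,
                 (bx - ux)^2 + (by - uy)^2,
                 (cx - ux)^2 + (cy - uy)^2)) * (1 + 1e-12)
  cbind(ux, uy, r)
}

#' Detect mutual occlusions among surviving faces
#'
#' Broad phase: only face pairs whose image-space enclosing circles overlap
#' are considered. Narrow phase: occlusion is confirmed when the two image
#' triangles overlap with positive area (boundary contact does not count).
#' For a confirmed pair the face with the greater minimal depth (smallest
#' aperture-to-vertex distance) is the occludee; the shallower face is
#' appended to its occluder list. Pairs at an exact depth tie are skipped.
#'
#' @param candidates a [cull_faces()] result.
#' @param camera the camera (unused in the computation; kept for interface
#'   symmetry).
#' @return the candidate list with an `occluders` element added: for each
#'   candidate, integer positions (into the candidate list) of its occluders.
#' @export
find_occluders <- function(candidates, camera = NULL) {
  n <- length(candidates$idx)
  occ <- rep(list(integer(0)), n)
  if (n >= 2L) {
    cx <- candidates$circ[, 1L]; cy <- candidates$circ[, 2L]
    cr <- candidates$circ[, 3L]
    pi_ <- integer(0); pj_ <- integer(0)
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      hit <- (cx[j] - cx[i])^2 + (cy[j] - cy[i])^2 < (cr[j] + cr[i])^2
      if (any(hit)) {
        jj <- j[hit]
        pi_ <- c(pi_, rep.int(i, length(jj)))
        pj_ <- c(pj_, jj)
      }
    }
    if (length(pi_)) {
      ov <- tri_overlap_pairs(candidates$tri_img, cbind(pi_, pj_), 1e-12)
      pi_ <- pi_[ov]; pj_ <- pj_[ov]
      if (length(pi_)) {
        di <- candidates$min_depth[pi_]; dj <- candidates$min_depth[pj_]
        tie <- abs(di - dj) <= .tol$depth_tie_mm
        deeper <- ifelse(di > dj, pi_, pj_)
        shallower <- ifelse(di > dj, pj_, pi_)
        deeper <- deeper[!tie]; shallower <- shallower[!tie]
        if (length(deeper)) {
          sp <- split(shallower, deeper)
          for (key in names(sp)) occ[[as.integer(key)]] <- sp[[key]]
        }
      }
    }
  }
  candidates$occluders <- occ
  candidates
}

#' Clip a face image to the FOV rectangle
#'
#' @param ps image-space polygon set of the subject face.
#' @param camera a [make_camera()] camera.
#' @return the portion of `ps` inside the FOV rectangle (possibly empty).
#' @export
clip_to_fov <- function(ps, camera) {
  boolean_2d("intersect", ps, list(fov_rectangle(camera)$ring),
             area_eps = .tol$area_image, snap = .tol$snap_image)
}

#' Clip a face image against its merged occluders
#'
#' The images of all known occluders are merged into as few polygons as
#' possible (holes preserved) and subtracted from the subject region.
#'
#' @param ps image-space polygon set of the subject region.
#' @param occluder_tris list of image-space occluder triangles (3 x 2
#'   matrices) or polygon sets.
#' @return the visible remainder (possibly empty).
#' @export
clip_against_occluders <- function(ps, occluder_tris) {
  if (length(occluder_tris) == 0L) return(ps)
  occ <- ps_union_all(lapply(occluder_tris, function(o) {
    if (is.matrix(o)) ps_triangle(o) else o
  }), area_eps = .tol$area_image, snap = .tol$snap_image)
  boolean_2d("subtract", ps, occ, area_eps = .tol$area_image, snap = .tol$snap_image)
}

# Per-face local frames and canonical local triangles, reused across cameras.
precompute_frames <- function(mesh) {
  f <- mesh$faces
  n <- nrow(f)
  frames <- vector("list", n)
  local_tri <- vector("list", n)
  for (i in seq_len(n)) {
    v1 <- mesh$vertices[f[i, 1L], ]
    v2 <- mesh$vertices[f[i, 2L], ]
    v3 <- mesh$vertices[f[i, 3L], ]
    fr <- local_frame(v1, v2, v3)
    frames[[i]] <- fr
    l3 <- to_local(fr, rbind(v1, v2, v3), tol = 1e-6)
    local_tri[[i]] <- ps_triangle(l3)
  }
  list(frames = frames, local_tri = local_tri, areas = face_areas(mesh))
}

#' Visible subset of a mesh for one camera
#'
#' Runs the full per-camera pipeline in order: invisibility culling,
#' occluder detection, FOV clipping where flagged, and clipping against the
#' merged occluder images. Visible fragments are back-projected onto their
#' parent face's plane and returned in the face's local 2D frame, where
#' areas equal true 3D areas (the in-plane map is an isometry).
#'
#' @param mesh a [triangle_mesh()].
#' @param camera a [make_camera()] camera.
#' @param pre optional precomputed `precompute_frames(mesh)` result, reused
#'   across cameras of a setup.
#' @return a list of class `visibility_map`: `face_idx` (faces with
#'   nonempty visible subset), `frags` (per face, polygon set in the face's
#'   local frame), `areas` (visible area per listed face, mm^2).
#' @export
visible_subset <- function(mesh, camera, pre = NULL) {
  if (is.null(pre)) pre <- precompute_frames(mesh)
  cand <- find_occluders(cull_faces(mesh, camera), camera)
  n <- length(cand$idx)
  face_idx <- integer(0)
  frags <- list()
  areas <- numeric(0)
  if (n > 0L) {
    rect <- list(fov_rectangle(camera)$ring)
    for (k in seq_len(n)) {
      i <- cand$idx[k]
      tri2 <- matrix(cand$tri_img[k, ], 3L, 2L, byrow = TRUE)
      clipped <- FALSE
      ps <- ps_triangle(tri2)
      if (cand$fov_status[k] == "straddling") {
        ps <- boolean_2d("intersect", ps, rect, area_eps = .tol$area_image, snap = .tol$snap_image)
        clipped <- TRUE
        if (length(ps) == 0L) next
      }
      occ <- cand$occluders[[k]]
      if (length(occ) > 0L) {
        occ_tris <- lapply(occ, function(q)
          matrix(cand$tri_img[q, ], 3L, 2L, byrow = TRUE))
        ps <- clip_against_occluders(ps, occ_tris)
        clipped <- TRUE
        if (length(ps) == 0L) next
      }
      fr <- pre$frames[[i]]
      if (!clipped) {
        frag <- pre$local_tri[[i]]
        area <- pre$areas[i]
      } else {
        rings3 <- back_project(camera, ps, fr$origin, fr$n)
        frag <- lapply(rings3, function(r3) {
          l2 <- to_local(fr, r3, tol = 1e-5)
          list(x = l2[, 1L], y = l2[, 2L])
        })
        tot <- sum(vapply(frag, ring_area, numeric(1L)))
        if (tot < 0)   # the image->plane map may flip orientation globally
          frag <- lapply(frag, function(r) list(x = rev(r$x), y = rev(r$y)))
        frag <- ps_clean(frag, .tol$area_mm2)
        if (length(frag) == 0L) next
        area <- polygon_area(frag)
      }
      face_idx <- c(face_idx, i)
      frags[[length(frags) + 1L]] <- frag
      areas <- c(areas, area)
    }
  }
  structure(list(face_idx = face_idx, frags = frags, areas = areas),
            class = "visibility_map")
}
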