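#' Specification of a synthetic operative-corridor mesh
#'
#' Parametric description of a deep-channel surgical-site model: a
#' rectangular block pierced by a blind channel of circular or deformed
#' elliptical cross-section, with the channel bottom at the focal plane
#' (z = 0) and the block's top surface at z = `depth`, facing the camera
#' ring. Optional simple anatomy can be placed in the channel.
#'
#' The deformed elliptical profile is an ellipse with semi-axes
#' `axes/2` whose minor direction is modulated by an egg-like factor
#' `(1 + 0.18 cos(theta))`, giving the asymmetric "deformed" outline of a
#' widened approach corridor.
#'
#' @param cross_section `"circular"` or `"elliptical"`.
#' @param diameter channel diameter in mm (circular).
#' @param axes length-2 vector: channel length and width in mm (elliptical).
#' @param depth channel depth in mm (top surface sits at z = depth).
#' @param block_extent length-2 lateral size of the block (mm); must exceed
#'   the channel cross-section.
#' @param anatomy one of `"none"`, `"flat_relief"`, `"spanning_artery"`,
#'   `"overhang"`.
#' @param artery_height height of the spanning artery's centreline above the
#'   channel bottom (mm).
#' @param artery_diameter artery diameter (mm).
#' @param relief_amplitude amplitude of the bottom height-field relief (mm).
#' @param segments number of boundary segments used to discretize the
#'   channel cross-section.
#' @param wall_bands number of vertical subdivisions of the channel wall.
#' @param bottom_rings number of radial subdivisions of the channel bottom.
#' @param base_thickness thickness of solid block material below the channel
#'   bottom (mm); the block bottom face sits at z = -base_thickness.
#' @param z_offset axial shift applied to the whole mesh (mm); 0 places the
#'   channel bottom (the anatomy level) in the focal plane.
#' @param seed integer seed for the deterministic relief height field.
#' @return a list of class `channel_spec`.
#' @seealso [make_channel_site()]
#' @export
channel_spec <- function(cross_section = c("circular", "elliptical"),
                         diameter = 25, axes = c(42.5, 22.5), depth = 50,
                         block_extent = c(60, 60),
                         anatomy = c("none", "flat_relief",
                                     "spanning_artery", "overhang"),
                         artery_height = 30, artery_diameter = 8,
                         relief_amplitude = 1.5,
                         segments = 128, wall_bands = 8, bottom_rings = NULL,
                         base_thickness = 5, z_offset = 0, seed = 1L) {
  cross_section <- match.arg(cross_section)
  anatomy <- match.arg(anatomy)
  if (depth <= 0) stop("depth must be positive")
  if (cross_section == "circular") {
    if (diameter <= 0) stop("diameter must be positive")
    half <- c(diameter, diameter) / 2
  } else {
    if (any(axes <= 0)) stop("axes must be positive")
    half <- axes / 2
  }
  if (any(block_extent / 2 <= half * 1.2))
    stop("block_extent must be strictly larger than the channel cross-section")
  if (anatomy == "spanning_artery") {
    if (artery_diameter <= 0) stop("artery_diameter must be positive")
    if (artery_height >= depth) stop("artery_height must be below depth")
    if (artery_height - artery_diameter / 2 <= 0 ||
        artery_height + artery_diameter / 2 >= depth)
      stop("artery does not fit inside the channel")
  }
  if (is.null(bottom_rings))
    bottom_rings <- max(3L, ceiling(min(half) / 4))
  if (segments < 8L) stop("segments must be at least 8")
  structure(list(cross_section = cross_section, diameter = diameter,
                 axes = axes, depth = depth, block_extent = block_extent,
                 anatomy = anatomy, artery_height = artery_height,
                 artery_diameter = artery_diameter,
                 relief_amplitude = relief_amplitude,
                 segments = as.integer(segments),
                 wall_bands = as.integer(wall_bands),
                 bottom_rings = as.integer(bottom_rings),
                 base_thickness = base_thickness, z_offset = z_offset,
                 seed = as.integer(seed)),
            class = "channel_spec")
}

# cross-section boundary point at angle theta (counter-clockwise, z = 0)
.channel_boundary <- function(spec, theta) {
  if (spec$cross_section == "circular") {
    r <- spec$diameter / 2
    cbind(r * cos(theta), r * sin(theta))
  } else {
    a <- spec$axes[1] / 2
    b <- spec$axes[2] / 2
    cbind(a * cos(theta), b * sin(theta) * (1 + 0.18 * cos(theta)))
  }
}

# triangle-soup builder shared by the generator primitives
.soup_new <- function() {
  e <- new.env(parent = emptyenv())
  e$tris <- list()
  e$tags <- character(0)
  e
}
.soup_tri <- function(e, p1, p2, p3, tag) {
  e$tris[[length(e$tris) + 1L]] <- rbind(p1, p2, p3)
  e$tags[length(e$tags) + 1L] <- tag
}
# quad split into two triangles, vertices in boundary order
.soup_quad <- function(e, p1, p2, p3, p4, tag) {
  .soup_tri(e, p1, p2, p3, tag)
  .soup_tri(e, p1, p3, p4, tag)
}
.soup_mesh <- function(e) {
  verts <- do.call(rbind, e$tris)
  tags <- e$tags
  key <- paste(verts[, 1L], verts[, 2L], verts[, 3L])
  uid <- match(key, key[!duplicated(key)])
  uv <- verts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3L, byrow = TRUE)
  keep <- !(faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
              faces[, 1L] == faces[, 3L])
  triangle_mesh(uv, faces[keep, , drop = FALSE], tags = tags[keep])
}

# deterministic low-frequency height field used for the "flat_relief" bottom
.relief_fun <- function(spec) {
  rng <- .local_rng(spec$seed)
  phase <- rng$runif(3, 0, 2 * pi)
  lambda <- rng$runif(3, 8, 16)
  amp <- spec$relief_amplitude
  function(x, y) {
    amp * (0.7 * sin(2 * pi * x / lambda[1] + phase[1]) *
             cos(2 * pi * y / lambda[2] + phase[2]) +
             0.3 * sin(2 * pi * (x + y) / lambda[3] + phase[3]))
  }
}

# seeded RNG that does not disturb the global .Random.seed
.local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
  list(runif = function(...) draw(runif, ...),
       rnorm = function(...) draw(rnorm, ...))
}

#' Generate a synthetic operative-corridor mesh
#'
#' Builds a watertight triangle mesh of a deep surgical corridor: a solid
#' rectangular block with a blind channel. Faces are tagged by region:
#' `"top_surface"` (block top around the opening), `"wall"` (channel wall),
#' `"anatomy"` (channel bottom and any anatomy primitive), and `"block"`
#' (block sides and underside, never visible to the ring). The channel
#' bottom lies at z = 0 (+ `z_offset`), the focal plane of the camera setup,
#' and the top surface at z = `depth`.
#'
#' Anatomy options: `"flat_relief"` replaces the flat bottom by a seeded
#' low-amplitude smooth height field; `"spanning_artery"` adds a capped
#' horizontal cylinder spanning the channel at `artery_height` above the
#' bottom; `"overhang"` adds a flattened ellipsoidal bulge protruding from
#' the channel wall. Anatomy solids are closed surfaces that interpenetrate
#' the block, so every edge of the output remains shared by exactly two
#' faces.
#'
#' @param spec a [channel_spec()].
#' @return a [triangle_mesh()] with per-face tags.
#' @examples
#' site <- make_channel_site(channel_spec(segments = 32, wall_bands = 3))
#' validate_mesh(site)$watertight
#' @export
make_channel_site <- function(spec) {
  if (!inherits(spec, "channel_spec")) stop("spec must be a channel_spec")
  K0 <- spec$segments
  hx <- spec$block_extent[1] / 2
  hy <- spec$block_extent[2] / 2
  # angle set: uniform + the four block corners so the top outline is exact
  th <- 2 * pi * (0:(K0 - 1)) / K0
  corners <- atan2(c(hy, hy, -hy, -hy), c(hx, -hx, -hx, hx)) %% (2 * pi)
  th <- sort(unique(c(th, corners)))
  drop <- c(diff(th), 2 * pi - (th[length(th)] - th[1])) < 1e-9
  th <- th[!drop]
  K <- length(th)

  inner <- .channel_boundary(spec, th)            # channel outline (xy)
  # outer outline: ray from the axis through each angle to the block edge
  tmax <- pmin(hx / pmax(abs(cos(th)), 1e-300), hy / pmax(abs(sin(th)), 1e-300))
  outer <- cbind(tmax * cos(th), tmax * sin(th))

  z0 <- spec$z_offset                              # channel bottom
  zt <- z0 + spec$depth                            # top surface
  zb <- z0 - spec$base_thickness                   # block underside

  relief <- if (spec$anatomy == "flat_relief") .relief_fun(spec) else function(x, y) 0 * x

  e <- .soup_new()
  nxt <- function(i) if (i == K) 1L else i + 1L

  for (i in seq_len(K)) {
    j <- nxt(i)
    # top surface ring (normal +z)
    .soup_quad(e, c(outer[i, ], zt), c(outer[j, ], zt),
               c(inner[j, ], zt), c(inner[i, ], zt), "top_surface")
    # block sides (outward normal)
    .soup_quad(e, c(outer[i, ], zt), c(outer[i, ], zb),
               c(outer[j, ], zb), c(outer[j, ], zt), "block")
    # block underside fan (normal -z)
    .soup_tri(e, c(0, 0, zb), c(outer[j, ], zb), c(outer[i, ], zb), "block")
  }

  # channel wall: vertical bands from the top surface down to the bottom
  zrows <- seq(zt, z0, length.out = spec$wall_bands + 1L)
  for (w in seq_len(spec$wall_bands)) {
    z1 <- zrows[w]; z2 <- zrows[w + 1L]
    for (i in seq_len(K)) {
      j <- nxt(i)
      .soup_quad(e, c(inner[i, ], z1), c(inner[j, ], z1),
                 c(inner[j, ], z2), c(inner[i, ], z2), "wall")
    }
  }

  # channel bottom: radial grid, relief tapered to zero at the wall
  nr <- spec$bottom_rings
  ringpt <- function(jring, i) {
    s <- jring / nr
    xy <- inner[i, ] * s
    z <- z0 + relief(xy[1], xy[2]) * (1 - s^2)
    c(xy, z)
  }
  ctr <- c(0, 0, z0 + relief(0, 0))
  for (i in seq_len(K)) {
    j <- nxt(i)
    .soup_tri(e, ctr, ringpt(1L, i), ringpt(1L, j), "anatomy")
    if (nr > 1L) {
      for (q in seq_len(nr - 1L)) {
        .soup_quad(e, ringpt(q, i), ringpt(q + 1L, i),
                   ringpt(q + 1L, j), ringpt(q, j), "anatomy")
      }
    }
  }

  if (spec$anatomy == "spanning_artery") .add_artery(e, spec, z0)
  if (spec$anatomy == "overhang") .add_overhang(e, spec, z0)

  .soup_mesh(e)
}

# capped horizontal cylinder spanning the channel along the x axis
.add_artery <- function(e, spec, z0) {
  ra <- spec$artery_diameter / 2
  zc <- z0 + spec$artery_height
  chord <- if (spec$cross_section == "circular") spec$diameter else spec$axes[1]
  L <- min(chord + 8, spec$block_extent[1] - 2)
  nc <- 24L; na <- 8L
  xs <- seq(-L / 2, L / 2, length.out = na + 1L)
  ph <- 2 * pi * (0:(nc - 1)) / nc
  ring <- function(x) cbind(x, ra * cos(ph), zc + ra * sin(ph))
  nxt <- function(i) if (i == nc) 1L else i + 1L
  for (a in seq_len(na)) {
    r1 <- ring(xs[a]); r2 <- ring(xs[a + 1L])
    for (i in seq_len(nc)) {
      j <- nxt(i)
      # outward normal: increasing phi is counter-clockwise seen from +x
      .soup_quad(e, r1[i, ], r1[j, ], r2[j, ], r2[i, ], "anatomy")
    }
  }
  r1 <- ring(xs[1]); r2 <- ring(xs[na + 1L])
  c1 <- c(xs[1], 0, zc); c2 <- c(xs[na + 1L], 0, zc)
  for (i in seq_len(nc)) {
    j <- nxt(i)
    .soup_tri(e, c1, r1[j, ], r1[i, ], "anatomy")   # cap facing -x
    .soup_tri(e, c2, r2[i, ], r2[j, ], "anatomy")   # cap facing +x
  }
}

# flattened ellipsoid bulging out of the channel wall
.add_overhang <- function(e, spec, z0) {
  half <- if (spec$cross_section == "circular") spec$diameter / 2 else spec$axes[1] / 2
  rad <- 0.55 * half                       # lateral semi-axes
  rz <- 0.35 * half                        # vertical semi-axis
  cx <- half * 0.95                        # centre buried in the wall
  zc <- z0 + 0.6 * spec$depth
  nu <- 20L; nv <- 10L
  pt <- function(u, v) {                   # u: azimuth, v: polar from +z
    sv <- sin(v)
    if (abs(sv) < 1e-12) sv <- 0           # snap poles so vertices merge
    c(cx + rad * sv * cos(u), rad * sv * sin(u), zc + rz * cos(v))
  }
  us <- 2 * pi * (0:(nu - 1)) / nu
  vs <- pi * (0:nv) / nv
  nxtu <- function(i) if (i == nu) 1L else i + 1L
  for (b in seq_len(nv)) {
    v1 <- vs[b]; v2 <- vs[b + 1L]
    for (i in seq_len(nu)) {
      j <- nxtu(i)
      if (b == 1L) {
        .soup_tri(e, pt(us[i], v1), pt(us[i], v2), pt(us[j], v2), "anatomy")
      } else if (b == nv) {
        .soup_tri(e, pt(us[i], v1), pt(us[i], v2), pt(us[j], v1), "anatomy")
      } else {
        .soup_quad(e, pt(us[i], v1), pt(us[i], v2),
                   pt(us[j], v2), pt(us[j], v1), "anatomy")
      }
    }
  }
}

#' Generate a flat rectangular plate mesh
#'
#' An open (not watertight) plate in a horizontal plane with upward normals,
#' subdivided into a regular triangle grid. Used as the simplest test scene:
#' fully visible to any camera above it.
#'
#' @param width,height plate extent in mm.
#' @param z plate height (mm).
#' @param nx,ny number of grid cells per side.
#' @param center xy centre of the plate.
#' @param tag face tag.
#' @return a [triangle_mesh()].
#' @export
make_plate <- function(width = 20, height = 20, z = 0, nx = 2L, ny = 2L,
                       center = c(0, 0), tag = "plate") {
  xs <- seq(-width / 2, width / 2, length.out = nx + 1L) + center[1]
  ys <- seq(-height / 2, height / 2, length.out = ny + 1L) + center[2]
  e <- .soup_new()
  for (ix in seq_len(nx)) {
    for (iy in seq_len(ny)) {
      p1 <- c(xs[ix], ys[iy], z); p2 <- c(xs[ix + 1L], ys[iy], z)
      p3 <- c(xs[ix + 1L], ys[iy + 1L], z); p4 <- c(xs[ix], ys[iy + 1L], z)
      .soup_quad(e, p1, p2, p3, p4, tag)
    }
  }
  .soup_mesh(e)
}
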