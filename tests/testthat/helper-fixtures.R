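# Shared fixtures, built in code and cached for the duration of the run.
# Meshes are kept small enough that every pipeline call stays fast while the
# geometry still exercises curved walls, occluders and FOV clipping.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_cache)) assign(name, build(), .fixture_cache)
  get(name, .fixture_cache)
}

# study-condition channel meshes; centered axially like the reference setup
fix_channel <- function(anatomy = "none", cross = "circular",
                        segments = 36L, wall_bands = 5L) {
  fixture(paste("channel", anatomy, cross, segments, wall_bands, sep = "_"),
          function() {
            spec <- channel_spec(cross_section = cross, anatomy = anatomy,
                                 segments = segments, wall_bands = wall_bands,
                                 bottom_rings = 3L,
                                 z_offset = -channel_spec()$depth / 2)
            make_channel_site(spec)
          })
}

fix_plate <- function() fixture("plate", function() make_plate(20, 14, nx = 3L, ny = 3L))

# two stacked plates: the small upper one shadows part of the lower one
fix_stacked <- function() {
  fixture("stacked", function() {
    lower <- make_plate(24, 16, z = 0, nx = 3L, ny = 3L, tag = "lower")
    upper <- make_plate(10, 8, z = 12, nx = 2L, ny = 2L,
                        center = c(2, 1), tag = "upper")
    triangle_mesh(rbind(lower$vertices, upper$vertices),
                  rbind(lower$faces, upper$faces + nrow(lower$vertices)),
                  tags = c(lower$tags, upper$tags))
  })
}

# open cylindrical tube (channel wall only), inward normals, used against
# the semi-analytic cylinder-visibility oracle
fix_tube <- function(radius = 9, depth = 40, K = 128L, bands = 8L) {
  fixture(paste("tube", radius, depth, K, bands, sep = "_"), function() {
    th <- 2 * pi * (0:(K - 1)) / K
    zs <- seq(depth, 0, length.out = bands + 1L)
    verts <- NULL
    for (z in zs) verts <- rbind(verts, cbind(radius * cos(th), radius * sin(th), z))
    faces <- NULL
    nxt <- function(i) if (i == K) 1L else i + 1L
    for (b in seq_len(bands)) {
      o1 <- (b - 1L) * K; o2 <- b * K
      for (i in seq_len(K)) {
        j <- nxt(i)
        faces <- rbind(faces,
                       c(o1 + i, o1 + j, o2 + j),
                       c(o1 + i, o2 + j, o2 + i))
      }
    }
    triangle_mesh(verts, faces, tags = rep("wall", nrow(faces)))
  })
}

# Semi-analytic visible-area fraction of the smooth open tube for one or
# more cameras: a wall point is visible when its inward normal faces the
# camera and the sight line exits the cylinder above the rim. Independent of
# the polygon pipeline (direct numerical quadrature of the closed-form
# condition).
tube_visible_fraction <- function(radius, depth, apertures, T = 1L,
                                  n_phi = 1200L, n_z = 300L) {
  phi <- 2 * pi * (seq_len(n_phi) - 0.5) / n_phi
  zz <- depth * (seq_len(n_z) - 0.5) / n_z
  visible_cam <- function(a) {
    px <- radius * cos(phi); py <- radius * sin(phi)
    vis <- matrix(FALSE, n_phi, n_z)
    facing <- -(cos(phi) * a[1] + sin(phi) * a[2]) > 0
    for (iz in seq_len(n_z)) {
      z <- zz[iz]
      dx <- a[1] - px; dy <- a[2] - py; dz <- a[3] - z
      # |p_xy + t d_xy| = radius  ->  t1 = -2 (p.d) / |d|^2
      pd <- px * dx + py * dy
      dd <- dx^2 + dy^2
      t1 <- -2 * pd / dd
      zexit <- z + t1 * dz
      vis[, iz] <- facing & (t1 <= 0 | zexit >= depth)
    }
    vis
  }
  counts <- Reduce(`+`, lapply(apertures, visible_cam))
  mean(counts >= T)
}

# nonzero-rule point membership in a polygon set (test-side oracle)
point_in_polyset <- function(px, py, ps) {
  wind <- 0L
  for (r in ps) {
    x <- r$x; y <- r$y; n <- length(x); j <- n
    for (i in seq_len(n)) {
      if (y[j] <= py) {
        if (y[i] > py && (x[i] - x[j]) * (py - y[j]) - (px - x[j]) * (y[i] - y[j]) > 0)
          wind <- wind + 1L
      } else if (y[i] <= py &&
                 (x[i] - x[j]) * (py - y[j]) - (px - x[j]) * (y[i] - y[j]) < 0) {
        wind <- wind - 1L
      }
      j <- i
    }
  }
  wind != 0L
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%g vs %g (tol %g)", object, expected, tol))
}
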