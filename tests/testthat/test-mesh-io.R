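test_that("binary STL round trip preserves geometry to float32 precision", {
  plate <- make_plate(1, 1, nx = 1L, ny = 1L)   # 2-triangle unit square
  tf <- withr::local_tempfile(fileext = ".stl")
  write_stl(plate, tf)
  m <- read_stl(tf)
  expect_equal(nrow(m$faces), 2L)
  expect_equal(mesh_area(m), 1.0, tolerance = 1e-7)

  site <- make_channel_site(channel_spec(segments = 24L, wall_bands = 3L))
  tf2 <- withr::local_tempfile(fileext = ".stl")
  write_stl(site, tf2)
  m2 <- read_stl(tf2)
  expect_equal(nrow(m2$faces), nrow(site$faces))
  expect_equal(mesh_area(m2), mesh_area(site), tolerance = 1e-4)
  # same vertex multiset up to float32 rounding: every re-read vertex has an
  # original within float32 resolution
  expect_equal(nrow(m2$vertices), nrow(site$vertices))
  dmin <- apply(m2$vertices, 1L, function(p)
    min(colSums((t(site$vertices) - p)^2)))
  expect_lt(max(sqrt(dmin)), 1e-4)
})

test_that("STL reader rejects inconsistent byte counts and accepts ASCII", {
  plate <- make_plate(1, 1, nx = 1L, ny = 1L)
  tf <- withr::local_tempfile(fileext = ".stl")
  write_stl(plate, tf)
  raw <- readBin(tf, "raw", file.info(tf)$size)
  tf_bad <- withr::local_tempfile(fileext = ".stl")
  writeBin(raw[seq_len(length(raw) - 10L)], tf_bad)   # truncated record
  expect_error(read_stl(tf_bad), "malformed")

  tf_ascii <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid unit",
               " facet normal 0 0 1", "  outer loop",
               "   vertex 0 0 0", "   vertex 1 0 0", "   vertex 1 1 0",
               "  endloop", " endfacet",
               " facet normal 0 0 1", "  outer loop",
               "   vertex 0 0 0", "   vertex 1 1 0", "   vertex 0 1 0",
               "  endloop", " endfacet",
               "endsolid unit"), tf_ascii)
  ma <- read_stl(tf_ascii)
  expect_equal(nrow(ma$faces), 2L)
  expect_equal(mesh_area(ma), 1.0)
})

test_that("empty and zero-face STL files are handled", {
  empty <- triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3))
  tf <- withr::local_tempfile(fileext = ".stl")
  write_stl(empty, tf)
  m <- read_stl(tf)
  expect_equal(nrow(m$faces), 0L)
})

test_that("mesh validator distinguishes watertight, boundary and non-manifold", {
  site <- make_channel_site(channel_spec(segments = 24L, wall_bands = 3L))
  v <- validate_mesh(site)
  expect_true(v$watertight)
  expect_equal(v$degenerate_faces, 0L)
  expect_equal(v$inconsistent_edges, 0L)

  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       matrix(c(1L, 2L, 3L), 1))
  vt <- validate_mesh(tri)
  expect_false(vt$watertight)
  expect_equal(vt$boundary_edges, 3L)

  dup <- triangle_mesh(site$vertices, rbind(site$faces, site$faces[1L, ]))
  expect_gt(validate_mesh(dup)$non_manifold_edges, 0L)
})

test_that("triangle_mesh constructor enforces its invariants", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(triangle_mesh(v, matrix(c(1L, 2L, 4L), 1)), "out of range")
  expect_error(triangle_mesh(v, matrix(c(1L, 1L, 3L), 1)), "repeated")
  expect_error(triangle_mesh(v, matrix(c(1L, 2L, 3L), 1),
                             normals = matrix(c(0, 0, -1), 1)),
               "disagree")
  # agreeing stored normal accepted after renormalization
  m <- triangle_mesh(v, matrix(c(1L, 2L, 3L), 1),
                     normals = matrix(c(0, 0, 2), 1))
  expect_equal(m$normals[1L, ], c(0, 0, 1))
})

test_that("channel generator meets its analytic and invariant checks", {
  for (an in c("none", "flat_relief", "spanning_artery", "overhang")) {
    m <- make_channel_site(channel_spec(anatomy = an, segments = 32L,
                                        wall_bands = 3L))
    v <- validate_mesh(m)
    expect_true(v$watertight, label = paste("watertight", an))
    expect_equal(v$degenerate_faces, 0L)
    expect_equal(v$inconsistent_edges, 0L)
  }
  m <- make_channel_site(channel_spec("elliptical", segments = 32L,
                                      wall_bands = 3L))
  expect_true(validate_mesh(m)$watertight)

  # lateral wall area ~ pi * d * depth at fine discretization
  m <- make_channel_site(channel_spec(segments = 128L, wall_bands = 2L))
  wall <- sum(face_areas(m)[m$tags == "wall"])
  expect_equal(wall, pi * 25 * 50, tolerance = 1e-3)

  # spanning artery sits ~30 mm above the bottom anatomy
  ma <- make_channel_site(channel_spec(anatomy = "spanning_artery",
                                       segments = 32L, wall_bands = 3L))
  tube <- ma$vertices[unique(as.vector(ma$faces[ma$tags == "anatomy", ])), ]
  tube <- tube[tube[, 3] > 5, ]        # artery vertices (above bottom relief)
  expect_equal(mean(range(tube[, 3])), 30, tolerance = 0.5)

  expect_error(channel_spec(depth = 0), "depth")
  expect_error(channel_spec(anatomy = "spanning_artery", artery_height = 60),
               "artery")
  expect_error(channel_spec(block_extent = c(26, 26)), "block_extent")
})

test_that("top-surface tagging matches the generator ground truth", {
  m <- make_channel_site(channel_spec(segments = 32L, wall_bands = 3L))
  tagged <- tag_top_surface(m)
  expect_setequal(tagged, which(m$tags == "top_surface"))
  # exact coordinates: zero tolerance selects the same set
  expect_setequal(tag_top_surface(m, z_top = 50, tol = 0), tagged)
  # a plane with no faces at z_top gives the empty set
  expect_length(tag_top_surface(m, z_top = 123.4), 0L)
})
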