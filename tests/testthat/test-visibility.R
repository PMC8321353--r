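test_that("culling removes backfaces, contour faces and out-of-FOV faces", {
  cm <- make_camera(look_at_axes(c(0, 0, 400), c(0, 0, 0)), fov = c(36, 24))
  plate <- make_plate(10, 10, nx = 1L, ny = 1L)
  cand <- cull_faces(plate, cm)
  expect_length(cand$idx, 2L)
  expect_true(all(cand$fov_status == "inside"))

  flipped <- triangle_mesh(plate$vertices, plate$faces[, c(1L, 3L, 2L)])
  expect_length(cull_faces(flipped, cm)$idx, 0L)

  # face exactly parallel to the viewing axis (contour, dot = 0) is culled
  vert <- triangle_mesh(rbind(c(0, 0, 0), c(0, 5, 0), c(0, 0, 5)),
                        matrix(c(1L, 2L, 3L), 1))
  expect_length(cull_faces(vert, cm)$idx, 0L)

  # far outside the FOV rectangle
  off <- make_plate(4, 4, nx = 1L, ny = 1L, center = c(200, 0))
  expect_length(cull_faces(off, cm)$idx, 0L)

  # straddling faces are flagged for clipping
  edge <- make_plate(8, 8, nx = 1L, ny = 1L, center = c(17, 0))
  st <- cull_faces(edge, cm)
  expect_true(any(st$fov_status == "straddling"))
})

test_that("occluder detection matches a brute-force all-pairs oracle", {
  cm <- make_camera(look_at_axes(c(0, 0, 400), c(0, 0, 0)), fov = c(36, 24))
  # stacked parallel plates: lower occluded by upper
  st <- fix_stacked()
  cand <- find_occluders(cull_faces(st, cm), cm)
  lower <- which(st$tags[cand$idx] == "lower")
  upper <- which(st$tags[cand$idx] == "upper")
  expect_true(all(lengths(cand$occluders[upper]) == 0L))
  expect_true(any(lengths(cand$occluders[lower]) > 0L))
  occ_of_lower <- unique(unlist(cand$occluders[lower]))
  expect_true(all(st$tags[cand$idx[occ_of_lower]] == "upper"))

  # laterally separated plates with disjoint circumcircles: no occlusion
  two <- triangle_mesh(
    rbind(make_plate(4, 4, center = c(-8, 0))$vertices,
          make_plate(4, 4, z = 5, center = c(8, 0))$vertices),
    rbind(make_plate(4, 4, center = c(-8, 0))$faces,
          make_plate(4, 4, z = 5, center = c(8, 0))$faces + 9L))
  cand2 <- find_occluders(cull_faces(two, cm), cm)
  expect_true(all(lengths(cand2$occluders) == 0L))

  # randomized scenes: occluder lists equal the brute-force overlap test
  set.seed(19)
  for (rep in 1:3) {
    nv <- 60L
    v <- cbind(runif(nv, -12, 12), runif(nv, -8, 8), runif(nv, 0, 30))
    f <- matrix(sample(nv, 150, replace = TRUE), ncol = 3L)
    f <- f[f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3], , drop = FALSE]
    m <- triangle_mesh(v, f)
    cand <- find_occluders(cull_faces(m, cm), cm)
    n <- length(cand$idx)
    brute <- rep(list(integer(0)), n)
    for (i in seq_len(max(n - 1L, 0L))) {
      ti <- matrix(cand$tri_img[i, ], 3, 2, byrow = TRUE)
      for (j in (i + 1L):n) {
        tj <- matrix(cand$tri_img[j, ], 3, 2, byrow = TRUE)
        ov <- polygon_area(boolean_2d("intersect", reconsim:::ps_triangle(ti),
                                      reconsim:::ps_triangle(tj), area_eps = 0))
        if (ov > 1e-15) {
          di <- cand$min_depth[i]; dj <- cand$min_depth[j]
          if (abs(di - dj) > 1e-9) {
            if (di > dj) brute[[i]] <- c(brute[[i]], j)
            else brute[[j]] <- c(brute[[j]], i)
          }
        }
      }
    }
    for (k in seq_len(n))
      expect_setequal(cand$occluders[[k]], brute[[k]])
  }
})

test_that("occlusion clipping yields the unoccluded remainder", {
  cm <- make_camera(look_at_axes(c(0, 0, 400), c(0, 0, 0)), fov = c(36, 24))
  # identical plate fully covering a lower one: lower face invisible
  pl <- make_plate(10, 10, nx = 1L, ny = 1L)
  nv <- nrow(pl$vertices)
  both <- triangle_mesh(rbind(pl$vertices,
                              sweep(pl$vertices, 2, c(0, 0, -5), `+`)),
                        rbind(pl$faces, pl$faces + nv),
                        tags = c(rep("up", nrow(pl$faces)),
                                 rep("down", nrow(pl$faces))))
  vm <- visible_subset(both, cm)
  expect_setequal(both$tags[vm$face_idx], "up")
  expect_equal(sum(vm$areas), 100, tolerance = 1e-9)

  # a symmetric half-occluder leaves exactly half the face visible
  sq <- list(list(x = c(-1, 1, 1, -1) * 0.01, y = c(-1, -1, 1, 1) * 0.01))
  half <- list(list(x = c(-0.02, 0, 0, -0.02), y = c(-0.02, -0.02, 0.02, 0.02)))
  res <- clip_against_occluders(sq, list(half))
  expect_equal(polygon_area(res), polygon_area(sq) / 2, tolerance = 1e-7)
})

test_that("per-camera visible areas agree with the cylinder oracle and
           conserve face areas", {
  tube <- fix_tube(radius = 9, depth = 40, K = 128L, bands = 8L)
  s <- make_ring_setup(2, d = 30, h = 400)
  pre_total <- mesh_area(tube)
  vm <- visible_subset(tube, s$cameras[[1]])
  # conservation: per-face visible area never exceeds the face area
  fa <- face_areas(tube)
  expect_true(all(vm$areas <= fa[vm$face_idx] + 1e-8))
  # semi-analytic smooth-cylinder oracle (discretization-limited agreement)
  frac <- tube_visible_fraction(9, 40, list(s$cameras[[1]]$frame$aperture),
                                T = 1L)
  expect_equal(sum(vm$areas) / pre_total, frac, tolerance = 0.03)

  # flat plate: a single camera sees the whole plate
  plate <- fix_plate()
  cm <- s$cameras[[1]]
  vmp <- visible_subset(plate, cm)
  expect_equal(sum(vmp$areas), mesh_area(plate), tolerance = 1e-9)
})

test_that("visible areas are insensitive to the face ordering of the mesh", {
  m <- fix_channel("flat_relief", segments = 24L, wall_bands = 3L)
  cm <- make_ring_setup(4)$cameras[[2]]
  vm1 <- visible_subset(m, cm)
  set.seed(5)
  perm <- sample(nrow(m$faces))
  m2 <- triangle_mesh(m$vertices, m$faces[perm, , drop = FALSE],
                      tags = m$tags[perm])
  vm2 <- visible_subset(m2, cm)
  a1 <- numeric(nrow(m$faces)); a1[vm1$face_idx] <- vm1$areas
  a2 <- numeric(nrow(m$faces)); a2[perm[vm2$face_idx]] <- vm2$areas
  expect_equal(a1, a2, tolerance = 1e-7)
})

test_that("visible fragments forward-project inside the FOV for straddling
           faces", {
  cm <- make_camera(look_at_axes(c(15, 0, 400), c(0, 0, 0)), fov = c(36, 24))
  set.seed(23)
  hw <- cm$fov_half[1]; hh <- cm$fov_half[2]
  checked <- 0L
  for (rep in 1:100) {
    ctr <- c(runif(1, 14, 22) * sample(c(-1, 1), 1),
             runif(1, 8, 16) * sample(c(-1, 1), 1), runif(1, -5, 5))
    v <- rbind(ctr + c(-4, -3, 0), ctr + c(5, -1, 0), ctr + c(0, 4, 0))
    m <- triangle_mesh(v, matrix(1:3, 1))
    cand <- cull_faces(m, cm)
    if (length(cand$idx) == 0L || cand$fov_status[1] != "straddling") next
    vm <- visible_subset(m, cm)
    if (length(vm$face_idx) == 0L) next
    fr <- local_frame(v[1, ], v[2, ], v[3, ])
    for (ring in vm$frags[[1]]) {
      p3 <- from_local(fr, cbind(ring$x, ring$y))
      pr <- project_points(cm, p3)
      expect_true(all(abs(pr$xy[, 1]) <= hw + 1e-7))
      expect_true(all(abs(pr$xy[, 2]) <= hh + 1e-7))
    }
    checked <- checked + 1L
  }
  expect_gt(checked, 20L)
})
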