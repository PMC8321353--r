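#' Per-face camera lists
#'
#' For each mesh face, the list of cameras that see at least a partial area
#' of it (nonempty visible fragment set).
#'
#' @param vmaps list of [visible_subset()] results, one per camera of the
#'   same setup.
#' @param n_faces number of faces of the mesh.
#' @return list of integer vectors: camera indices per face.
#' @export
camera_lists <- function(vmaps, n_faces) {
  li <- rep(list(integer(0)), n_faces)
  for (j in seq_along(vmaps)) {
    for (i in vmaps[[j]]$face_idx) li[[i]] <- c(li[[i]], j)
  }
  li
}

#' Number of T-subsets of the cameras seeing a face
#'
#' Binomial coefficient `choose(n_visible, T)`; zero when fewer cameras see
#' the face than the reconstructability threshold requires.
#'
#' @param n_visible number of cameras with a nonempty visible fragment set.
#' @param T reconstructability threshold.
#' @return integer count of camera combinations.
#' @export
combo_count <- function(n_visible, T) {
  if (any(n_visible < 0) || any(T < 0)) stop("negative input")
  ifelse(n_visible < T, 0, choose(n_visible, T))
}

#' Reconstructable subset of a single face
#'
#' Combines the per-camera visible fragment sets of one face (all in the
#' face's local 2D frame) into the region visible to at least `T` cameras.
#' Two equivalent strategies are provided: `"enumerate"` forms the union
#' over all T-subsets of cameras of the intersection of their fragment sets
#' (the literal set expression), `"coverage_count"` incrementally tracks the
#' region covered by at least k cameras for k = 1..T (linear in the number
#' of cameras). Both compute the same region; `coverage_count` is the
#' default.
#'
#' @param frag_sets list of polygon sets, one per camera that sees the face.
#' @param T reconstructability threshold.
#' @param strategy `"coverage_count"` or `"enumerate"`.
#' @param enumerate_cap refuse to enumerate more than this many T-subsets.
#' @param area_eps sliver threshold (mm^2).
#' @param full_region optional polygon set of the whole parent face; when the
#'   combined region covers the face up to clipping-kernel noise the exact
#'   face polygon is returned instead of the snapped result, so both
#'   strategies canonicalize saturated faces identically.
#' @return polygon set of the reconstructable region (possibly empty).
#' @export
reconstructable_face <- function(frag_sets, T,
                                 strategy = c("coverage_count", "enumerate"),
                                 enumerate_cap = 1e6,
                                 area_eps = .tol$area_mm2,
                                 full_region = NULL) {
  strategy <- match.arg(strategy)
  k <- length(frag_sets)
  if (k < T) return(list())
  if (T < 1L) stop("T must be at least 1")
  finish <- function(out) {
    if (!is.null(full_region) && length(out) > 0L) {
      fa <- polygon_area(full_region)
      if (polygon_area(out) >= fa - max(area_eps, 1e-7 * fa))
        return(full_region)
    }
    out
  }
  if (strategy == "enumerate") {
    ncmb <- combo_count(k, T)
    if (ncmb > enumerate_cap)
      stop("combination count ", ncmb, " exceeds the enumeration cap; ",
           "use strategy = 'coverage_count'")
    combos <- combn(k, T)
    out <- list()
    for (c0 in seq_len(ncol(combos))) {
      inter <- frag_sets[[combos[1L, c0]]]
      for (t in seq_len(T)[-1L]) {
        inter <- boolean_2d("intersect", inter, frag_sets[[combos[t, c0]]],
                            area_eps = area_eps)
        if (length(inter) == 0L) break
      }
      if (length(inter) > 0L)
        out <- boolean_2d("union", out, inter, area_eps = area_eps)
    }
    finish(out)
  } else {
    cov <- rep(list(list()), T)   # cov[[k]]: region covered by >= k cameras
    for (f in frag_sets) {
      if (T >= 2L) {
        for (q in seq.int(T, 2L)) {
          if (length(cov[[q - 1L]]) > 0L) {
            add <- boolean_2d("intersect", cov[[q - 1L]], f, area_eps = area_eps)
            if (length(add) > 0L)
              cov[[q]] <- boolean_2d("union", cov[[q]], add, area_eps = area_eps)
          }
        }
      }
      cov[[1L]] <- boolean_2d("union", cov[[1L]], f, area_eps = area_eps)
    }
    finish(cov[[T]])
  }
}

#' Reconstructable subset of a mesh for a camera setup
#'
#' Runs the per-camera visibility pipeline for every camera of the ring and
#' combines, per face, the visible fragments into the region visible to at
#' least `T` cameras. Areas are exact polygon areas (no rasterization).
#'
#' @param mesh a [triangle_mesh()].
#' @param setup a [make_ring_setup()].
#' @param T reconstructability threshold (>= 1); the default 2 corresponds
#'   to stereo triangulation.
#' @param strategy see [reconstructable_face()].
#' @param enumerate_cap see [reconstructable_face()].
#' @return a list of class `reconstruction`: `face_idx` (faces with a
#'   nonempty reconstructable region), `frags` (per listed face, polygon set
#'   in the face's local frame), `areas` (mm^2), `tags` (parent-face tags,
#'   inherited by fragments), `cam_lists` (cameras seeing each listed face),
#'   `area_total`, `area_by_tag`, `M`, `T`, and the setup parameters.
#' @export
reconstructable_subset <- function(mesh, setup, T = 2L,
                                   strategy = c("coverage_count", "enumerate"),
                                   enumerate_cap = 1e6) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(setup, "ring_setup"))
  if (T < 1L) stop("T must be at least 1")
  pre <- precompute_frames(mesh)
  nf <- nrow(mesh$faces)
  M <- setup$M
  if (strategy == "enumerate") {
    vmaps <- lapply(setup$cameras, function(cm) visible_subset(mesh, cm, pre))
    li <- camera_lists(vmaps, nf)
    frag_of <- function(i, j) {
      vm <- vmaps[[j]]
      vm$frags[[match(i, vm$face_idx)]]
    }
    face_idx <- integer(0); frags <- list(); areas <- numeric(0)
    keep_li <- list()
    for (i in seq_len(nf)) {
      if (length(li[[i]]) < T) next
      fs <- lapply(li[[i]], function(j) frag_of(i, j))
      ri <- reconstructable_face(fs, T, "enumerate", enumerate_cap,
                                 full_region = pre$local_tri[[i]])
      if (length(ri) == 0L) next
      face_idx <- c(face_idx, i)
      frags[[length(frags) + 1L]] <- ri
      areas <- c(areas, polygon_area(ri))
      keep_li[[length(keep_li) + 1L]] <- li[[i]]
    }
  } else {
    # streaming coverage: per face keep only the >=k coverage regions
    cov <- vector("list", nf)       # each: list of T polygon sets
    li <- rep(list(integer(0)), nf)
    done <- logical(nf)             # face already fully reconstructable
    eps <- .tol$area_mm2
    for (j in seq_len(M)) {
      vm <- visible_subset(mesh, setup$cameras[[j]], pre)
      for (q in seq_along(vm$face_idx)) {
        i <- vm$face_idx[q]
        li[[i]] <- c(li[[i]], j)
        if (done[i]) next
        f <- vm$frags[[q]]
        st <- cov[[i]]
        if (is.null(st)) st <- rep(list(list()), T)
        if (T >= 2L) {
          for (k in seq.int(T, 2L)) {
            if (length(st[[k - 1L]]) > 0L) {
              add <- boolean_2d("intersect", st[[k - 1L]], f, area_eps = eps)
              if (length(add) > 0L)
                st[[k]] <- boolean_2d("union", st[[k]], add, area_eps = eps)
            }
          }
        }
        st[[1L]] <- boolean_2d("union", st[[1L]], f, area_eps = eps)
        cov[[i]] <- st
        if (polygon_area(st[[T]]) >=
            pre$areas[i] - max(eps, 1e-7 * pre$areas[i])) {
          # saturated: the whole face is reconstructable, skip further work
          cov[[i]][[T]] <- pre$local_tri[[i]]
          done[i] <- TRUE
        }
      }
    }
    face_idx <- integer(0); frags <- list(); areas <- numeric(0)
    keep_li <- list()
    for (i in seq_len(nf)) {
      if (is.null(cov[[i]]) || length(li[[i]]) < T) next
      ri <- cov[[i]][[T]]
      if (length(ri) == 0L) next
      face_idx <- c(face_idx, i)
      frags[[length(frags) + 1L]] <- ri
      areas <- c(areas, polygon_area(ri))
      keep_li[[length(keep_li) + 1L]] <- li[[i]]
    }
  }
  tags <- if (is.null(mesh$tags)) rep(NA_character_, length(face_idx)) else mesh$tags[face_idx]
  area_by_tag <- if (length(areas)) tapply(areas, tags, sum) else numeric(0)
  structure(list(face_idx = face_idx, frags = frags, areas = areas,
                 tags = tags, cam_lists = keep_li,
                 area_total = sum(areas),
                 area_by_tag = area_by_tag,
                 M = M, T = as.integer(T), d = setup$d, h = setup$h,
                 fov = setup$fov, start_angle = setup$start_angle,
                 pre = pre),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat("reconstruction: M =", x$M, ", T =", x$T, "\n")
  cat("  reconstructable faces:", length(x$face_idx),
      "| area:", format(x$area_total, digits = 8), "mm^2\n")
  if (length(x$area_by_tag)) {
    cat("  by tag:", paste(names(x$area_by_tag),
                           format(unclass(x$area_by_tag), digits = 6),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reconstructable area, optionally excluding the top surface
#'
#' @param recon a [reconstructable_subset()] result.
#' @param exclude_top drop fragments inherited from `"top_surface"`-tagged
#'   faces.
#' @return area in mm^2.
#' @export
recon_area <- function(recon, exclude_top = FALSE) {
  if (!exclude_top) return(recon$area_total)
  sum(recon$areas[is.na(recon$tags) | recon$tags != "top_surface"])
}

#' Normalized area summary across camera counts
#'
#' Normalizes each reconstructable area to the benchmark camera count
#' (the dense-ring reference) and appends increment columns. With
#' `exclude_top`, areas of top-surface fragments are removed from numerator
#' and denominator before normalizing.
#'
#' @param results_by_M list of [reconstructable_subset()] results; names or
#'   `M` fields give the camera counts.
#' @param benchmark_M camera count used as the normalization benchmark.
#' @param exclude_top exclude `"top_surface"` fragments.
#' @return a data.frame with columns `n`, `area_mm2`, `norm`, `delta`,
#'   `delta_pct`.
#' @export
area_summary <- function(results_by_M, benchmark_M = 360L,
                         exclude_top = FALSE) {
  ms <- vapply(results_by_M, function(r) r$M, numeric(1L))
  ord <- order(ms)
  results_by_M <- results_by_M[ord]
  ms <- ms[ord]
  areas <- vapply(results_by_M, recon_area, numeric(1L),
                  exclude_top = exclude_top)
  bi <- match(benchmark_M, ms)
  if (is.na(bi)) stop("benchmark camera count not present in results")
  if (areas[bi] <= 0) stop("benchmark reconstructable area is zero")
  norm <- areas / areas[bi]
  dd <- delta_areas(norm)
  data.frame(n = ms, area_mm2 = areas, norm = norm,
             delta = dd$delta, delta_pct = dd$delta_pct)
}

#' Convert a reconstruction result into a fragment mesh
#'
#' Ear-clips every reconstructable fragment polygon into triangles and lifts
#' them back to 3D. The output is a fragment soup (adjacent faces are not
#' stitched); areas are computed on the polygons, not on this export.
#'
#' @param recon a [reconstructable_subset()] result.
#' @return a [triangle_mesh()] with inherited tags.
#' @export
recon_to_mesh <- function(recon) {
  e <- .soup_new()
  for (q in seq_along(recon$face_idx)) {
    i <- recon$face_idx[q]
    fr <- recon$pre$frames[[i]]
    tris2 <- triangulate_polyset(recon$frags[[q]])
    for (t2 in tris2) {
      p3 <- from_local(fr, t2)
      .soup_tri(e, p3[1L, ], p3[2L, ], p3[3L, ],
                if (is.na(recon$tags[q])) "fragment" else recon$tags[q])
    }
  }
  .soup_mesh(e)
}
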