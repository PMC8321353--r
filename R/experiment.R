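#' Camera-count sweep
#'
#' Evaluates the reconstructable subset of a mesh for a series of
#' equidistant ring placements and tabulates absolute and normalized areas,
#' with and without the top surface. The benchmark count (the largest by
#' default, conventionally 360) normalizes each column to its maximum
#' reconstructable area.
#'
#' @param mesh a [triangle_mesh()].
#' @param counts camera counts, ascending; must include `benchmark_M`.
#' @param d,h,fov,start_angle ring parameters, see [make_ring_setup()].
#' @param T reconstructability threshold.
#' @param benchmark_M normalization benchmark count.
#' @param verbose print progress per count.
#' @return a list of class `sweep_table`: `table` (data.frame with columns
#'   `n`, `area_mm2`, `norm`, `delta`, `delta_pct`, and the same four with
#'   suffix `_excl_top` for the top-surface-excluded variant) and the run
#'   parameters.
#' @export
run_camera_sweep <- function(mesh, counts = c(2, 4, 6, 8, 16, 32, 64, 128, 256, 360),
                             d = 30, h = 400, T = 2L, fov = c(36, 24),
                             start_angle = 0, benchmark_M = max(counts),
                             verbose = FALSE) {
  counts <- sort(unique(as.integer(counts)))
  if (!benchmark_M %in% counts) stop("benchmark_M must be one of counts")
  recons <- vector("list", length(counts))
  for (q in seq_along(counts)) {
    if (verbose) message("cameras: ", counts[q])
    setup <- make_ring_setup(counts[q], d = d, h = h, fov = fov,
                             start_angle = start_angle)
    recons[[q]] <- reconstructable_subset(mesh, setup, T = T)
  }
  inc <- area_summary(recons, benchmark_M = benchmark_M, exclude_top = FALSE)
  exc <- area_summary(recons, benchmark_M = benchmark_M, exclude_top = TRUE)
  tab <- cbind(inc,
               setNames(exc[, c("area_mm2", "norm", "delta", "delta_pct")],
                        paste0(c("area_mm2", "norm", "delta", "delta_pct"),
                               "_excl_top")))
  structure(list(table = tab, counts = counts, d = d, h = h, T = T,
                 fov = fov, start_angle = start_angle,
                 benchmark_M = benchmark_M),
            class = "sweep_table")
}

#' @export
print.sweep_table <- function(x, ...) {
  cat("camera sweep: d =", x$d, "mm, h =", x$h, "mm, T =", x$T,
      ", FOV", x$fov[1], "x", x$fov[2], "mm\n")
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Consecutive increments of normalized areas
#'
#' Differences of consecutive normalized areas with the relative-percentage
#' convention: each increment is also expressed as a percentage of the
#' previous value. The first row has increment 0. Decreases yield negative
#' increments.
#'
#' @param norm numeric vector of (normalized) areas in sweep order, or a
#'   data.frame with a `norm` column.
#' @return a data.frame with columns `norm`, `delta`, `delta_pct`.
#' @export
delta_areas <- function(norm) {
  if (is.data.frame(norm)) norm <- norm$norm
  if (length(norm) < 1L) stop("need at least one value")
  delta <- c(0, diff(norm))
  prev <- c(NA_real_, norm[-length(norm)])
  delta_pct <- ifelse(is.na(prev), 0, 100 * delta / prev)
  data.frame(norm = norm, delta = delta, delta_pct = delta_pct)
}

#' Fit an n-phase exponential saturation curve
#'
#' Least-squares fit of the approach-to-plateau model
#' `A(n) = c0 - sum_i a_i exp(-b_i n)` with positive amplitudes `a_i` and
#' rates `b_i`, the multi-phase negative-exponential family that describes
#' how the reconstructable area saturates with the number of cameras.
#' Levenberg-Marquardt with a deterministic multi-start; for three phases
#' the best two-phase fit seeds one start, so the three-phase residual never
#' exceeds the two-phase one.
#'
#' @param n camera counts (abscissae).
#' @param y (normalized) areas.
#' @param n_phases 2 or 3.
#' @param seed integer seed for the multi-start perturbations.
#' @param n_starts number of random starts.
#' @return a list of class `decay_fit`: `c0`, `a`, `b` (phases sorted by
#'   decreasing rate), `residual_norm`, `fitted` (function of n),
#'   `n_phases`, `data`.
#' @export
fit_decay <- function(n, y, n_phases = 2L, seed = 1L, n_starts = 24L) {
  stopifnot(length(n) == length(y), n_phases %in% c(2L, 3L))
  if (length(n) < 2L * n_phases + 1L)
    stop("need at least ", 2L * n_phases + 1L, " data points")
  if (diff(range(y)) < 1e-12) {
    const <- mean(y)
    fitted_fun <- function(nn) rep(const, length(nn))
    return(structure(list(c0 = const, a = rep(0, n_phases),
                          b = rep(1, n_phases), residual_norm = 0,
                          fitted = fitted_fun, n_phases = n_phases,
                          data = data.frame(n = n, y = y)),
                     class = "decay_fit"))
  }
  rng <- .local_rng(seed)
  dat <- data.frame(n = n, y = y)
  span <- diff(range(y))
  nmax <- max(n)
  model_formula <- function(p) {
    terms <- paste0("a", seq_len(p), " * exp(-b", seq_len(p), " * n)")
    stats::as.formula(paste("y ~ c0 -", paste(terms, collapse = " - ")))
  }
  run_fit <- function(p, start) {
    lower <- c(-Inf, rep(1e-8, 2L * p))
    names(lower) <- names(start)
    tryCatch(
      minpack.lm::nlsLM(model_formula(p), data = dat, start = start,
                        lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  starts_for <- function(p) {
    base_b <- 10^seq(-0.3, -2, length.out = p)   # rates spread over decades
    out <- list()
    for (s in seq_len(n_starts)) {
      jit_b <- base_b * 10^rng$runif(p, -0.5, 0.5)
      jit_a <- (span / p) * 10^rng$runif(p, -0.5, 0.5)
      st <- c(max(y), jit_a, jit_b)
      names(st) <- c("c0", paste0("a", seq_len(p)), paste0("b", seq_len(p)))
      out[[s]] <- st
    }
    out
  }
  best <- NULL
  best_rss <- Inf
  pick <- function(fit) {
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (rss < best_rss) {
        best <<- fit
        best_rss <<- rss
      }
    }
  }
  if (n_phases == 3L) {
    two <- tryCatch(fit_decay(n, y, 2L, seed = seed, n_starts = n_starts),
                    error = function(e) NULL)
    if (!is.null(two)) {
      st <- c(two$c0, two$a, span * 1e-3, two$b, 10^-1.5)
      names(st) <- c("c0", "a1", "a2", "a3", "b1", "b2", "b3")
      pick(run_fit(3L, st))
    }
  }
  for (st in starts_for(n_phases)) pick(run_fit(n_phases, st))
  if (is.null(best))
    stop("decay fit did not converge from any start")
  cf <- coef(best)
  a <- cf[paste0("a", seq_len(n_phases))]
  b <- cf[paste0("b", seq_len(n_phases))]
  ord <- order(b, decreasing = TRUE)
  a <- unname(a[ord]); b <- unname(b[ord])
  c0 <- unname(cf["c0"])
  fitted_fun <- function(nn)
    c0 - rowSums(vapply(seq_len(n_phases),
                        function(i) a[i] * exp(-b[i] * nn),
                        numeric(length(nn))))
  structure(list(c0 = c0, a = a, b = b,
                 residual_norm = sqrt(best_rss),
                 fitted = fitted_fun, n_phases = n_phases,
                 data = dat),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(x$n_phases, "-phase exponential saturation fit\n", sep = "")
  cat("  plateau c0 =", format(x$c0, digits = 6), "\n")
  for (i in seq_len(x$n_phases))
    cat("  phase", i, ": amplitude", format(x$a[i], digits = 5),
        ", rate", format(x$b[i], digits = 5), "\n")
  cat("  residual norm:", format(x$residual_norm, digits = 4), "\n")
  invisible(x)
}

#' Write sweep tables, fits and a summary figure to disk
#'
#' Renders each sweep as CSV, writes a plain-text run log of parameters, and
#' draws normalized area versus camera count with the fitted saturation
#' curves. Output is deterministic for fixed inputs.
#'
#' @param sweeps named list of [run_camera_sweep()] results.
#' @param fits optional named list of [fit_decay()] results (names matched
#'   to `sweeps`).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
report_sweep <- function(sweeps, fits = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  log_lines <- c("reconsim sweep report",
                 paste0("package version: ",
                        as.character(utils::packageVersion("reconsim"))))
  for (nm in names(sweeps)) {
    sw <- sweeps[[nm]]
    csv <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(format(sw$table, digits = 10), csv, row.names = FALSE)
    paths <- c(paths, csv)
    log_lines <- c(log_lines,
                   sprintf("sweep %s: counts=%s d=%g h=%g T=%d fov=%gx%g benchmark=%d",
                           nm, paste(sw$counts, collapse = ","), sw$d, sw$h,
                           sw$T, sw$fov[1], sw$fov[2], sw$benchmark_M))
  }
  plot_path <- file.path(out_dir, "sweep.svg")
  dev_ok <- TRUE
  tryCatch(grDevices::svg(plot_path, width = 7, height = 5),
           error = function(e) dev_ok <<- FALSE)
  if (dev_ok) {
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(NA, xlim = range(unlist(lapply(sweeps, function(s) s$counts))),
         ylim = c(0, 1.05), log = "x",
         xlab = "number of cameras", ylab = "normalized reconstructable area")
    cols <- seq_along(sweeps)
    for (q in seq_along(sweeps)) {
      sw <- sweeps[[q]]
      graphics::points(sw$table$n, sw$table$norm, col = cols[q], pch = 16)
      nm <- names(sweeps)[q]
      if (!is.null(fits) && nm %in% names(fits)) {
        nn <- exp(seq(log(min(sw$table$n)), log(max(sw$table$n)),
                      length.out = 200))
        graphics::lines(nn, fits[[nm]]$fitted(nn), col = cols[q])
      }
    }
    graphics::legend("bottomright", legend = names(sweeps), col = cols,
                     pch = 16, bty = "n")
    paths <- c(paths, plot_path)
  }
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  paths <- c(paths, log_path)
  invisible(paths)
}
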