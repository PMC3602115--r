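#' Initialize a cell pair
#'
#' Two cells on the x-axis at center separation `d0` (default: touching,
#' `2R`), each with fresh uniformly distributed C-C and C-M site sets drawn
#' from the current random stream.
#'
#' @param params A [cell_params()].
#' @param d0 Initial center-to-center distance; must exceed the
#'   core-exclusion distance `2R(1 - alpha)`.
#' @return A [cell_system()] of two cells at time 0.
#' @export
init_pair <- function(params, d0 = 2 * params$R) {
  d_core <- 2 * params$R * (1 - params$alpha)
  if (d0 <= d_core)
    stop("'d0' (", d0, ") must exceed the core-exclusion distance ",
         "2R(1-alpha) = ", d_core, call. = FALSE)
  centers <- rbind(c(0, 0, 0), c(d0, 0, 0))
  cc <- list(sample_sphere_sites(params$n_cc), sample_sphere_sites(params$n_cc))
  cm <- list(sample_sphere_sites(params$n_cm), sample_sphere_sites(params$n_cm))
  cell_system(centers, params$R, cc, cm)
}

#' Initialize a random cluster of cells
#'
#' Places `n` cells uniformly in a ball sized for the requested packing
#' fraction, by rejection sampling under the constraint that no two cells'
#' impenetrable cores intersect (every pairwise center distance exceeds
#' `2R(1 - alpha)`). Each cell receives fresh uniform site sets.
#'
#' @param params A [cell_params()].
#' @param n Number of cells.
#' @param packing Nominal cell volume fraction of the placement ball.
#' @param max_attempts Placement attempts per cell before giving up.
#' @return A [cell_system()] of `n` cells at time 0.
#' @export
init_cluster <- function(params, n = 50L, packing = 0.3,
                         max_attempts = 10000L) {
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  R <- params$R
  d_min <- 2 * R * (1 - params$alpha)
  r_ball <- R * (n / packing)^(1 / 3)
  centers <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    if (i == 1L) next  # first cell at the origin
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      u <- stats::rnorm(3L)
      u <- u / sqrt(sum(u^2))
      cand <- u * r_ball * stats::runif(1L)^(1 / 3)
      prev <- centers[seq_len(i - 1L), , drop = FALSE]
      if (min(sqrt(rowSums(sweep(prev, 2L, cand)^2))) > d_min) {
        centers[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place cell ", i, " after ", max_attempts,
           " attempts; enlarge the region or lower 'packing'", call. = FALSE)
  }
  cc <- lapply(seq_len(n), function(i) sample_sphere_sites(params$n_cc))
  cm <- lapply(seq_len(n), function(i) sample_sphere_sites(params$n_cm))
  cell_system(centers, R, cc, cm)
}

#' Run a batch of independent pair simulations
#'
#' Each run draws a fresh random distribution of surface sites (seeded
#' `base_seed + k - 1` for run `k`), simulates the pair to `t_total`, and
#' is summarized by its time of first break-up and companion time.
#'
#' @param params A [cell_params()].
#' @param n_runs Number of independent runs.
#' @param base_seed Seed of the first run.
#' @param d0 Initial separation (default touching).
#' @param thin Trajectory thinning passed to [run_simulation()].
#' @return A list with `summaries` (list of [pair_summary()] results) and
#'   `batch` (their [batch_summary()]).
#' @export
run_pair_batch <- function(params, n_runs = 10L, base_seed = params$seed,
                           d0 = 2 * params$R, thin = 1L) {
  summaries <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    set.seed(base_seed + k - 1L)
    state <- init_pair(params, d0)
    traj <- run_simulation(state, params, seed = NULL, thin = thin)
    summaries[[k]] <- pair_summary(traj)
  }
  list(summaries = summaries, batch = batch_summary(summaries, params$t_total))
}

# Canonical ordering of a sweep grid: points sorted by their serialized
# overrides, so seeds attach to points, not to the order of supply.
canonical_grid <- function(grid) {
  key <- vapply(grid, function(g) {
    g <- g[order(names(g))]
    paste(names(g), vapply(g, format, character(1L)), sep = "=",
          collapse = ";")
  }, character(1L))
  grid[order(key)]
}

#' Pair-stability sweep over a parameter grid
#'
#' For every grid point, runs a batch of independent pair simulations and
#' aggregates break-up statistics; when the grid varies the traction
#' `f_lr`, a Gompertz curve is fitted to the break-up fractions along the
#' `f_lr` axis. Seeds are keyed to the canonically ordered grid, so the
#' order in which points are supplied does not affect any result.
#'
#' @param spec An [experiment_spec()].
#' @return A list of class `sweep_result`: `points` (a data.frame with one
#'   row per grid point: overrides plus `mean_tfb`, `sem2_tfb`, `mean_ct`,
#'   `sem2_ct`, `frac_broke`, `n_runs`), `gompertz` (fit over the `f_lr`
#'   axis, or `NULL`), and `spec`.
#' @export
run_pair_sweep <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  grid <- canonical_grid(spec$grid)
  base <- apply_case(spec$params, spec$case)
  rows <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    p <- base
    for (nm in names(grid[[g]])) p[[nm]] <- grid[[g]][[nm]]
    validate_params(p)
    res <- run_pair_batch(p, n_runs = spec$n_runs,
                          base_seed = spec$base_seed +
                            (g - 1L) * spec$seed_stride,
                          d0 = spec$d0)
    rows[[g]] <- c(grid[[g]], res$batch)
  }
  points <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  gomp <- NULL
  if ("f_lr" %in% names(points) && nrow(points) >= 3L &&
      length(unique(points$f_lr)) == nrow(points)) {
    gomp <- tryCatch(fit_gompertz(points$f_lr, points$frac_broke),
                     error = function(e) NULL)
  }
  structure(list(points = points, gompertz = gomp, spec = spec),
            class = "sweep_result")
}

#' Pair sweep under adhesion depletion
#'
#' As [run_pair_sweep()], but crossing the grid with a set of power-law
#' decay exponents for the adhesion schedule (`"none"` reproduces the
#' constant-adhesion sweep bit-for-bit at equal seeds). Reports companion
#' times and break-up fractions per (exponent, grid point).
#'
#' @param spec An [experiment_spec()].
#' @param exponents Vector of decay exponents (numbers and/or `"none"`).
#' @return A list of class `sweep_result` whose `points` data.frame gains a
#'   `decay_exponent` column.
#' @export
run_depletion_sweep <- function(spec, exponents = c("none", 2, 1, 0.5)) {
  stopifnot(inherits(spec, "experiment_spec"))
  out <- vector("list", length(exponents))
  for (e in seq_along(exponents)) {
    p <- exponents[[e]]
    spec_e <- spec
    spec_e$params$decay_exponent <- if (identical(p, "none")) "none"
                                    else as.numeric(p)
    res <- run_pair_sweep(spec_e)
    res$points$decay_exponent <- if (identical(p, "none")) NA_real_
                                 else as.numeric(p)
    out[[e]] <- res$points
  }
  structure(list(points = do.call(rbind, out), gompertz = NULL, spec = spec),
            class = "sweep_result")
}

#' Cluster dissociation demonstration
#'
#' Simulates one cluster under several traction strengths, reusing the same
#' initial configuration and site distributions for every traction value
#' (sites are held static: case I), and records the evolution of the
#' radius of gyration and of the mean overlapping-neighbor count.
#'
#' @param params A [cell_params()] (site modes are forced to static).
#' @param n Number of cells.
#' @param f_lr_values Traction per site values to compare.
#' @param seed Seed for the shared initial configuration.
#' @param n_steps Number of timesteps to integrate (defaults to the full
#'   `t_total / dt`).
#' @param thin Frame thinning for the recorded series.
#' @return A list of class `cluster_demo`: `series` (data.frame with
#'   columns `f_lr`, `t`, `r_gyr`, `mean_neighbors`), `trajectories`
#'   (one `cell_trajectory` per traction value), `initial` (shared state).
#' @export
run_cluster_demo <- function(params, n = 50L, f_lr_values = c(0, 0.01),
                             seed = params$seed, n_steps = NULL, thin = 5L) {
  if (n < 2L) stop("'n' must be >= 2", call. = FALSE)
  params <- apply_case(params, "I")
  if (!is.null(n_steps)) params$t_total <- n_steps * params$dt
  set.seed(seed)
  initial <- init_cluster(params, n)
  trajs <- vector("list", length(f_lr_values))
  series <- vector("list", length(f_lr_values))
  for (v in seq_along(f_lr_values)) {
    p <- params
    p$f_lr <- f_lr_values[v]
    traj <- run_simulation(initial, p, seed = seed + 1L, thin = thin)
    trajs[[v]] <- traj
    ts <- sort(unique(traj$t))
    rg <- vapply(ts, function(tt) {
      fr <- traj[traj$t == tt, ]
      radius_of_gyration(cbind(fr$x, fr$y, fr$z))
    }, numeric(1L))
    nb <- vapply(ts, function(tt) {
      fr <- traj[traj$t == tt, ]
      mean_overlapping_neighbors(cbind(fr$x, fr$y, fr$z), params$R)
    }, numeric(1L))
    series[[v]] <- data.frame(f_lr = f_lr_values[v], t = ts, r_gyr = rg,
                              mean_neighbors = nb)
  }
  structure(list(series = do.call(rbind, series), trajectories = trajs,
                 initial = initial),
            class = "cluster_demo")
}

#' Default traction grid for pair sweeps
#'
#' The traction values spanning, at the canonical parameter values, the
#' regime from rarely breaking to always breaking within the default total
#' time: `f_lr` in `{0.002, 0.004, 0.006, 0.009, 0.012}`.
#'
#' @return A list of grid points suitable for [experiment_spec()].
#' @export
default_traction_grid <- function() {
  lapply(c(0.002, 0.004, 0.006, 0.009, 0.012), function(v) list(f_lr = v))
}

#' Write a sweep summary to CSV
#'
#' @param result A `sweep_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(result, path) {
  utils::write.csv(result$points, path, row.names = FALSE)
  invisible(path)
}
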