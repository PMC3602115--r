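#' Adhesion depletion schedule
#'
#' Models weakening intercellular bonds (as in epithelial-to-mesenchymal
#' transitions): the active adhesion energy scale decays from `sigma0` to 0
#' over the run as `sigma(t) = sigma0 * (1 - (t / t_total)^p)`, clamped at
#' zero. Smaller exponents deplete faster; `p = "none"` keeps adhesion
#' constant.
#'
#' @param t Current time, `0 <= t <= t_total`.
#' @param sigma0 Initial adhesion energy scale.
#' @param t_total Total simulation time.
#' @param p Positive decay exponent, or `"none"`.
#' @return The active adhesion scale at time `t`.
#' @export
sigma_schedule <- function(t, sigma0, t_total, p = "none") {
  if (identical(p, "none") || is.null(p)) return(sigma0)
  if (!is.numeric(p) || length(p) != 1L || p <= 0)
    stop("decay exponent 'p' must be a positive number or \"none\"",
         call. = FALSE)
  max(sigma0 * (1 - (t / t_total)^p), 0)
}

#' Draw the randomness frozen within one integration step
#'
#' One timestep is one movement cycle; its stochastic choices are drawn once
#' and held fixed for all four Runge-Kutta stages: the visiting order of
#' each cell's C-C sites for the one-to-one negotiation (a fresh random
#' permutation per step, unless `negotiation = "fixed"`), and, for systems
#' of three or more cells, a uniform draw per C-C site deciding which
#' overlap neighbor a multiply-trapped site is counted against.
#'
#' @param state A [cell_system()].
#' @param params A [cell_params()].
#' @return A list with `perms` and `assign` (per-cell lists), or `NULL` in
#'   the fixed-order diagnostic mode.
#' @export
draw_step_randomness <- function(state, params) {
  if (params$negotiation == "fixed") return(NULL)
  n <- nrow(state$centers)
  perms <- lapply(seq_len(n), function(i) sample.int(params$n_cc))
  assign <- if (n > 2L)
    lapply(seq_len(n), function(i) stats::runif(params$n_cc))
  else
    lapply(seq_len(n), function(i) numeric(params$n_cc))
  list(perms = perms, assign = assign)
}

#' One classical fourth-order Runge-Kutta step
#'
#' Advances all cell centers simultaneously over one timestep `dt`. Site
#' directions, the negotiation order and the multi-overlap assignments are
#' frozen for the four stages, so the stage velocity field is a
#' deterministic function of positions; geometric predicates (overlap,
#' exposure, pairings) are re-evaluated at each stage from the stage
#' positions. The active adhesion scale is evaluated from the depletion
#' schedule at the step's start time.
#'
#' @param state A [cell_system()].
#' @param params A [cell_params()].
#' @param step_rand Frozen per-step randomness; drawn via
#'   [draw_step_randomness()] when `NULL` and `negotiation = "per_step"`.
#' @return The advanced `cell_system` (time increased by `dt`).
#' @export
rk4_step <- function(state, params, step_rand = NULL) {
  if (is.null(step_rand) && params$negotiation == "per_step")
    step_rand <- draw_step_randomness(state, params)
  dt <- params$dt
  sig <- sigma_schedule(state$time, params$sigma0, params$t_total,
                        params$decay_exponent)
  drag <- 6 * pi * params$eta * state$radius
  vel <- function(centers) {
    f <- compute_system_forces(centers, state$radius, state$cc, state$cm,
                               params, sig, step_rand)
    (f$adhesion + f$traction + f$repulsion) / drag
  }
  y <- state$centers
  k1 <- vel(y)
  k2 <- vel(y + dt / 2 * k1)
  k3 <- vel(y + dt / 2 * k2)
  k4 <- vel(y + dt * k3)
  ynew <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(!is.finite(ynew)))
    stop("non-finite cell positions after RK4 step (wall_force_cap too ",
         "small or dt too large)", call. = FALSE)
  state$centers <- ynew
  state$time <- state$time + dt
  state
}

#' Reallocate surface sites between timesteps
#'
#' Applies the site-dynamics regime: site sets in `"dynamic"` mode are
#' resampled uniformly on the sphere after each completed step (C-C sites
#' draw first, then C-M, cell by cell); `"static"` sets are left untouched.
#'
#' @param state A [cell_system()].
#' @param params A [cell_params()].
#' @return The updated `cell_system`.
#' @export
update_sites <- function(state, params) {
  n <- nrow(state$centers)
  for (i in seq_len(n)) {
    if (params$cc_mode == "dynamic")
      state$cc[[i]] <- sample_sphere_sites(params$n_cc)
    if (params$cm_mode == "dynamic")
      state$cm[[i]] <- sample_sphere_sites(params$n_cm)
  }
  state
}

#' Run a full simulation
#'
#' Integrates the system from its current time to `t_total` with repeated
#' [rk4_step()] + [update_sites()] cycles, recording cell centers. The full
#' trajectory is a pure function of (initial state, parameters, seed).
#'
#' @param initial A [cell_system()] initial state (e.g. from [init_pair()]
#'   or [init_cluster()]).
#' @param params A [cell_params()].
#' @param seed Integer seed applied before the loop; `NULL` continues the
#'   current random stream (used inside batch drivers that seed per run).
#' @param thin Record every `thin`-th frame (the initial and final frames
#'   are always kept).
#' @return A `cell_trajectory`: a data.frame with columns `t`, `cell`, `x`,
#'   `y`, `z` and attributes `radius` and `params`.
#' @export
run_simulation <- function(initial, params, seed = params$seed, thin = 1L) {
  if (!is.null(seed)) set.seed(seed)
  n_steps <- floor(params$t_total / params$dt + 1e-9)
  n <- nrow(initial$centers)
  keep <- unique(c(0L, seq_len(n_steps)[seq_len(n_steps) %% thin == 0L],
                   n_steps))
  frames <- vector("list", length(keep))
  fi <- 1L
  state <- initial
  record <- function(state) {
    data.frame(t = state$time, cell = seq_len(n),
               x = state$centers[, 1L], y = state$centers[, 2L],
               z = state$centers[, 3L])
  }
  frames[[fi]] <- record(state)
  for (s in seq_len(n_steps)) {
    state <- rk4_step(state, params)
    state <- update_sites(state, params)
    if (s %in% keep) {
      fi <- fi + 1L
      frames[[fi]] <- record(state)
    }
  }
  traj <- do.call(rbind, frames[seq_len(fi)])
  rownames(traj) <- NULL
  structure(traj, radius = initial$radius, params = params,
            final_state = state,
            class = c("cell_trajectory", "data.frame"))
}

#' Write a trajectory to CSV
#'
#' One row per cell per sampled time, columns `run`, `t`, `cell`, `x`, `y`,
#' `z`.
#'
#' @param traj A `cell_trajectory`.
#' @param path Output file path.
#' @param run_id Run identifier stored in the `run` column.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, run_id = 1L) {
  df <- cbind(run = run_id, as.data.frame(traj))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
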