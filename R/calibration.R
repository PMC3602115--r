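#' Freeze the current engagement pattern of a system
#'
#' Negotiates C-C pairings (index order) and evaluates C-M exposure at the
#' system's current positions, returning the complete engagement pattern:
#' per-pair site matches, trapped-pair counts and per-cell exposure masks.
#' Holding this pattern fixed makes the force field a smooth function of
#' the cell centers.
#'
#' @param state A [cell_system()].
#' @param params A [cell_params()].
#' @return A list of class `engagement_pattern` with `pairs` (per
#'   interacting pair: `i`, `j`, `matches`, `m_min`) and `exposure`
#'   (per-cell logical masks over C-M sites).
#' @export
freeze_engagement <- function(state, params) {
  n <- nrow(state$centers)
  R <- state$radius
  pairs <- list()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- sqrt(sum((state$centers[i, ] - state$centers[j, ])^2))
        if (d >= 2 * R + params$r_cut) next
        pr <- negotiate_pairings(system_cell(state, i), system_cell(state, j),
                                 params$r_cut, order = seq_len(params$n_cc))
        pairs[[length(pairs) + 1L]] <-
          list(i = i, j = j, matches = pr$matches,
               m_min = min(pr$m_i, pr$m_j))
      }
    }
  }
  exposure <- lapply(seq_len(n), function(i) {
    Q <- sweep(state$cm[[i]] * R, 2L, state$centers[i, ], "+")
    is_exposed(Q, state$centers[-i, , drop = FALSE], R)
  })
  structure(list(pairs = pairs, exposure = exposure),
            class = "engagement_pattern")
}

# Forces with a frozen engagement pattern: smooth in the centers (bond and
# repulsion magnitudes still vanish continuously at their cutoffs).
frozen_pattern_forces <- function(centers, state, params, sigma, pattern) {
  n <- nrow(centers)
  R <- state$radius
  Ftot <- matrix(0, n, 3L)
  two_R <- 2 * R
  d_core <- two_R * (1 - params$alpha)
  eps_eff <- params$eps * max(params$n_cc, 1L)
  for (pp in pattern$pairs) {
    i <- pp$i; j <- pp$j
    dvec <- centers[j, ] - centers[i, ]
    d <- sqrt(sum(dvec^2))
    nv <- dvec / d
    f <- c(0, 0, 0)
    if (pp$m_min > 0)
      f <- f + (sigma / params$r_cut) * pp$m_min * nv
    if (nrow(pp$matches)) {
      Pi <- sweep(state$cc[[i]][pp$matches[, 1L], , drop = FALSE] * R,
                  2L, centers[i, ], "+")
      Pj <- sweep(state$cc[[j]][pp$matches[, 2L], , drop = FALSE] * R,
                  2L, centers[j, ], "+")
      dm <- Pj - Pi
      s <- sqrt(rowSums(dm^2))
      ok <- s > 0 & s < params$r_cut
      if (any(ok)) {
        w <- (sigma / params$r_cut^2) * (params$r_cut - s[ok]) / s[ok]
        f <- f + colSums(dm[ok, , drop = FALSE] * w)
      }
    }
    Ftot[i, ] <- Ftot[i, ] + f
    Ftot[j, ] <- Ftot[j, ] - f
    if (d < two_R) {
      mag <- if (d <= d_core) params$wall_force_cap
             else eps_eff * (two_R - d) / two_R^2
      Ftot[i, ] <- Ftot[i, ] - mag * nv
      Ftot[j, ] <- Ftot[j, ] + mag * nv
    }
  }
  kf <- params$K * params$f_lr
  if (kf != 0) {
    for (i in seq_len(n)) {
      ex <- pattern$exposure[[i]]
      if (any(ex))
        Ftot[i, ] <- Ftot[i, ] + kf * colSums(state$cm[[i]][ex, , drop = FALSE])
    }
  }
  Ftot
}

#' Relax a system to a force-balance equilibrium
#'
#' Computes the equilibrium configuration of the force balance by freezing
#' the engagement pattern at the current positions ([freeze_engagement()])
#' and integrating the resulting smooth, overdamped field with RK4 until
#' the largest per-cell speed falls below `tol`. This is the calibration
#' operation behind the choice of the adhesion and repulsion scales: with
#' no traction, a touching pair must admit a bound equilibrium.
#'
#' Under the running model the negotiation order is re-randomized every
#' timestep, which dithers the net force by a fraction of the per-bond
#' scale; the pair is then stationary in distribution around this
#' equilibrium rather than pointwise at rest.
#'
#' @param state A [cell_system()], typically pre-relaxed by a short run.
#' @param params A [cell_params()].
#' @param tol Convergence threshold on the maximum per-cell speed.
#' @param max_steps Step budget.
#' @return A list with `state` (at equilibrium), `speed` (final maximum
#'   per-cell speed), `steps` used, and `converged`.
#' @export
relax_to_equilibrium <- function(state, params, tol = 1e-10,
                                 max_steps = 20000L) {
  pattern <- freeze_engagement(state, params)
  sigma <- sigma_schedule(state$time, params$sigma0, params$t_total,
                          params$decay_exponent)
  drag <- 6 * pi * params$eta * state$radius
  dt <- params$dt
  vel <- function(centers)
    frozen_pattern_forces(centers, state, params, sigma, pattern) / drag
  y <- state$centers
  speed <- Inf
  steps <- 0L
  while (steps < max_steps) {
    k1 <- vel(y)
    speed <- sqrt(max(rowSums(k1^2)))
    if (speed < tol) break
    k2 <- vel(y + dt / 2 * k1)
    k3 <- vel(y + dt / 2 * k2)
    k4 <- vel(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    steps <- steps + 1L
  }
  state$centers <- y
  list(state = state, speed = speed, steps = steps, converged = speed < tol)
}
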