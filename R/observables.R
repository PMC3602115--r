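#' Center-to-center distance trace of a cell pair
#'
#' @param traj A `cell_trajectory` of exactly two cells.
#' @return A data.frame with columns `t` and `d`.
#' @export
pair_distance_trace <- function(traj) {
  cells <- unique(traj$cell)
  if (length(cells) != 2L)
    stop("pair_distance_trace() needs a trajectory of exactly 2 cells, got ",
         length(cells), call. = FALSE)
  a <- traj[traj$cell == cells[1L], ]
  b <- traj[traj$cell == cells[2L], ]
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  data.frame(t = a$t, d = d)
}

#' Bound/detached classification of a pair separation
#'
#' A pair is bound while its center distance is at most twice the cell
#' radius (the boundary is included on the bound side) and detached beyond.
#'
#' @param d Center-to-center distance(s).
#' @param R Cell radius.
#' @return `"bound"` or `"detached"` per element.
#' @export
classify_bound <- function(d, R) {
  ifelse(d <= 2 * R, "bound", "detached")
}

#' Time of first break-up
#'
#' The first sampled time at which the pair distance exceeds `2R` -- the
#' pair's first unbound state -- or `NA` if the pair never detaches.
#'
#' @param d Distance series.
#' @param times Matching time series.
#' @param R Cell radius.
#' @return A time, or `NA_real_`.
#' @export
time_of_first_breakup <- function(d, times, R) {
  if (length(d) != length(times))
    stop("'d' and 'times' must have equal length", call. = FALSE)
  i <- which(d > 2 * R)
  if (!length(i)) return(NA_real_)
  times[i[1L]]
}

#' Companion time
#'
#' The total time the pair spends in the bound state during a run, using
#' left-endpoint interval accounting at the sampling resolution: each
#' interval `[t_k, t_{k+1})` counts as bound time iff the pair is bound at
#' `t_k`. No sub-step crossing interpolation is performed.
#'
#' @inheritParams time_of_first_breakup
#' @return Total bound time.
#' @export
companion_time <- function(d, times, R) {
  if (length(d) != length(times))
    stop("'d' and 'times' must have equal length", call. = FALSE)
  if (length(d) < 2L) return(0)
  k <- seq_len(length(d) - 1L)
  sum(diff(times)[d[k] <= 2 * R])
}

#' Summarize one pair run
#'
#' @param traj A two-cell `cell_trajectory`.
#' @param R Cell radius (defaults to the trajectory's).
#' @return A list with `tfb` (time of first break-up, `NA` if none), `ct`
#'   (companion time) and `broke` (logical).
#' @export
pair_summary <- function(traj, R = attr(traj, "radius")) {
  tr <- pair_distance_trace(traj)
  tfb <- time_of_first_breakup(tr$d, tr$t, R)
  list(tfb = tfb, ct = companion_time(tr$d, tr$t, R), broke = !is.na(tfb))
}

#' Aggregate pair summaries over a batch of independent runs
#'
#' Means and twice-standard-error error bars for the time of first break-up
#' and the companion time, plus the fraction of runs with a break-up. Runs
#' that never break contribute `tfb = t_total` to the mean (right-censoring
#' by truncation, matching break-up curves that saturate at the maximum
#' simulated time).
#'
#' @param summaries List of [pair_summary()] results.
#' @param t_total Total simulated time, used for censored runs.
#' @return A list with `mean_tfb`, `sem2_tfb`, `mean_ct`, `sem2_ct`,
#'   `frac_broke`, `n_runs`.
#' @export
batch_summary <- function(summaries, t_total) {
  n <- length(summaries)
  if (!n) stop("empty batch", call. = FALSE)
  tfb <- vapply(summaries, function(s) if (is.na(s$tfb)) t_total else s$tfb,
                numeric(1L))
  ct <- vapply(summaries, function(s) s$ct, numeric(1L))
  broke <- vapply(summaries, function(s) isTRUE(s$broke), logical(1L))
  sem2 <- function(x) if (n > 1L) 2 * stats::sd(x) / sqrt(n) else 0
  list(mean_tfb = mean(tfb), sem2_tfb = sem2(tfb),
       mean_ct = mean(ct), sem2_ct = sem2(ct),
       frac_broke = mean(broke), n_runs = n)
}

#' Fit a Gompertz curve to break-up fractions
#'
#' Least-squares fit of `y = exp(-exp(-c * (x - b)))` to fractions in
#' `[0, 1]` versus an abscissa (typically the traction per site). `b` is the
#' displacement of the curve along the abscissa and `c` the rate of growth
#' toward the upper asymptote at 1; the curve tends to 0 for `x << b`.
#' The fit is deterministic: it starts from `b` at the abscissa of the point
#' whose fraction is nearest `exp(-1)` (the curve's value at `x = b`; first
#' such point on ties) and `c = 1`, refined by Levenberg-Marquardt.
#'
#' @param x Abscissa values (at least 3).
#' @param y Fractions in `[0, 1]`.
#' @return A list with `b`, `c`, `rss` and the `fitted` values.
#' @export
fit_gompertz <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (any(y < 0 | y > 1)) stop("'y' must lie in [0, 1]", call. = FALSE)
  b0 <- x[which.min(abs(y - exp(-1)))]
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ exp(-exp(-cc * (x - b))),
                      start = list(b = b0, cc = 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Gompertz fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  list(b = unname(cf["b"]), c = unname(cf["cc"]),
       rss = sum(stats::resid(fit)^2),
       fitted = unname(stats::fitted(fit)))
}

#' Radius of gyration of a group of cells
#'
#' Root-mean-square distance of all cell centers from their centroid,
#' over every cell regardless of whether it is still attached to a common
#' structure.
#'
#' @param positions `n x 3` matrix of cell centers.
#' @return The radius of gyration.
#' @export
radius_of_gyration <- function(positions) {
  if (!is.matrix(positions)) positions <- matrix(positions, ncol = 3L)
  if (!nrow(positions)) stop("empty input", call. = FALSE)
  centroid <- colMeans(positions)
  sqrt(mean(rowSums(sweep(positions, 2L, centroid)^2)))
}

#' Mean number of overlapping neighbors per cell
#'
#' Average over cells of the count of other cells whose center lies closer
#' than `2R`.
#'
#' @param centers `n x 3` matrix of cell centers.
#' @param R Common cell radius.
#' @return The mean overlapping-neighbor count (possibly fractional).
#' @export
mean_overlapping_neighbors <- function(centers, R) {
  if (!is.matrix(centers)) centers <- matrix(centers, ncol = 3L)
  n <- nrow(centers)
  if (!n) stop("empty input", call. = FALSE)
  if (n == 1L) return(0)
  d <- as.matrix(stats::dist(centers))
  mean(colSums(d < 2 * R) - 1L)
}
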