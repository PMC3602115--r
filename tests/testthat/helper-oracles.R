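# Independent brute-force oracles and small fixture builders.

# Reference greedy matcher: explicit nested loops over site lists, kept
# deliberately naive and separate from the package's vectorized matcher.
oracle_greedy_match <- function(Pi, Pj, free_i, free_j, order, r_cut) {
  taken <- rep(FALSE, nrow(Pj))
  matches <- NULL
  for (idx in order) {
    if (!(idx %in% free_i)) next
    best <- NA_integer_
    best_d <- Inf
    for (jj in free_j) {
      if (taken[jj]) next
      dd <- sqrt(sum((Pi[idx, ] - Pj[jj, ])^2))
      if (dd < best_d) { best_d <- dd; best <- jj }
    }
    if (!is.na(best) && best_d <= r_cut) {
      taken[best] <- TRUE
      matches <- rbind(matches, c(idx, best))
    }
  }
  if (is.null(matches)) matrix(integer(0), 0L, 2L) else matches
}

# Reference exposure check: plain double loop.
oracle_exposed <- function(site_pos, centers, radius) {
  out <- rep(TRUE, nrow(site_pos))
  for (s in seq_len(nrow(site_pos))) {
    for (k in seq_len(nrow(centers))) {
      if (sqrt(sum((site_pos[s, ] - centers[k, ])^2)) < radius) {
        out[s] <- FALSE
        break
      }
    }
  }
  out
}

# Reference neighbor count: plain double loop over ordered pairs.
oracle_mean_neighbors <- function(centers, R) {
  n <- nrow(centers)
  cnt <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && sqrt(sum((centers[i, ] - centers[j, ])^2)) < 2 * R)
      cnt <- cnt + 1L
  }
  cnt / n
}

# A two-cell system with prescribed site directions (unit rows).
make_pair_system <- function(d, cc1, cc2, cm1 = cc1, cm2 = cc2, R = 1) {
  cell_system(rbind(c(0, 0, 0), c(d, 0, 0)), R,
              cc = list(cc1, cc2), cm = list(cm1, cm2))
}

unit <- function(v) v / sqrt(sum(v^2))

# Small parameter set for fast plumbing tests (fewer sites, short runs).
fast_params <- function(...) {
  args <- list(n_cc = 12, n_cm = 12, t_total = 0.5)
  over <- list(...)
  args[names(over)] <- over
  do.call(cell_params, args)
}
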