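#' One-to-one negotiation of C-C adhesion bonds between two cells
#'
#' C-C sites engage strictly one-to-one. Sites of either cell that are
#' trapped in the mutual overlap region are first removed from the pool and
#' counted (`m_i`, `m_j`); the remaining free sites of cell i are then
#' visited in the order given by `order` (a random permutation in the
#' running model, redrawn every timestep so that negotiation restarts anew),
#' and each greedily claims the nearest unclaimed free site of cell j within
#' site-site distance `r_cut`. Matches are mutually exclusive: no site index
#' is ever reused.
#'
#' @param cell_i,cell_j Two [cell_state()] objects.
#' @param r_cut Largest site-site distance at which a bond acts.
#' @param order Visiting order over cell i's C-C site indices (a permutation
#'   of `1:n_cc`); `NULL` draws one from the current random stream.
#' @return A list with `matches` (two-column matrix of engaged site indices,
#'   cell i's in column 1), `m_i` and `m_j` (overlap-trapped counts), and
#'   the logical vectors `trapped_i`, `trapped_j`.
#' @export
negotiate_pairings <- function(cell_i, cell_j, r_cut, order = NULL) {
  Pi <- site_positions(cell_i, "cc")
  Pj <- site_positions(cell_j, "cc")
  trapped_i <- in_overlap_region(Pi, cell_j$center, cell_j$radius)
  trapped_j <- in_overlap_region(Pj, cell_i$center, cell_i$radius)
  free_i <- which(!trapped_i)
  free_j <- which(!trapped_j)
  if (is.null(order)) order <- sample.int(nrow(Pi))
  matches <- greedy_match(Pi, Pj, free_i, free_j, order, r_cut)
  list(matches = matches, m_i = sum(trapped_i), m_j = sum(trapped_j),
       trapped_i = trapped_i, trapped_j = trapped_j)
}

# Greedy nearest-available matching. free_i/free_j are candidate site
# indices; `order` is a permutation of all of cell i's site indices, and
# only its free entries are visited. Returns a 2-column index matrix.
greedy_match <- function(Pi, Pj, free_i, free_j, order, r_cut) {
  if (!length(free_i) || !length(free_j))
    return(matrix(integer(0), 0L, 2L))
  A <- Pi[free_i, , drop = FALSE]
  B <- Pj[free_j, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  r2 <- r_cut^2
  claimed <- rep(FALSE, length(free_j))
  out_i <- integer(min(length(free_i), length(free_j)))
  out_j <- integer(length(out_i))
  nm <- 0L
  pos_in_free <- match(order, free_i)       # visiting order within free set
  pos_in_free <- pos_in_free[!is.na(pos_in_free)]
  for (a in pos_in_free) {
    row <- d2[a, ]
    row[claimed] <- Inf
    b <- which.min(row)
    if (row[b] <= r2) {
      claimed[b] <- TRUE
      nm <- nm + 1L
      out_i[nm] <- free_i[a]
      out_j[nm] <- free_j[b]
      if (all(claimed)) break
    }
  }
  cbind(i = out_i[seq_len(nm)], j = out_j[seq_len(nm)])
}

#' Adhesion force between one engaged pair of C-C sites
#'
#' The bond force is linear in the site-site separation `s`: magnitude
#' `sigma * (r_cut - s) / r_cut^2`, zero at the cutoff and maximal
#' (`sigma / r_cut`) at contact, directed from site k toward site l
#' (attractive) along the line of the two sites. Beyond the cutoff, or for
#' coincident sites (undefined direction), the zero vector is returned.
#'
#' @param pos_k,pos_l World positions of the engaged sites; the force acts
#'   on site k's cell.
#' @param sigma Active adhesion energy scale.
#' @param r_cut Cutoff distance.
#' @return Length-3 force vector on site k's cell.
#' @export
site_pair_adhesion_force <- function(pos_k, pos_l, sigma, r_cut) {
  dvec <- pos_l - pos_k
  s <- sqrt(sum(dvec^2))
  if (s > r_cut || s == 0) return(c(0, 0, 0))
  (sigma / r_cut^2) * (r_cut - s) * dvec / s
}

#' Adhesion force from sites trapped in the overlap region
#'
#' Trapped sites interact by count, not by position: only the minimum of
#' the two trapped counts participates (sites must pair to pull), each
#' contributing the contact-strength bond force `sigma / r_cut`, along the
#' line of centers.
#'
#' @param m_i,m_j Trapped C-C site counts for the two cells.
#' @param sigma Active adhesion energy scale.
#' @param r_cut Cutoff distance.
#' @param n_ij Unit vector from cell i toward cell j.
#' @return Length-3 force vector on cell i (attractive, along `+n_ij`).
#' @export
overlap_adhesion_force <- function(m_i, m_j, sigma, r_cut, n_ij) {
  (sigma / r_cut) * min(m_i, m_j) * n_ij
}

#' Total adhesion force on a cell
#'
#' Sums, over all neighbors, the engaged site-pair forces outside the
#' overlap region and the count-based force of the trapped sites. The
#' resultant is applied at the cell center (cells do not rotate).
#'
#' @param cell_i A [cell_state()].
#' @param neighbors List of neighboring `cell_state` objects.
#' @param pairings List of [negotiate_pairings()] results, one per neighbor.
#' @param sigma Active adhesion energy scale.
#' @param r_cut Cutoff distance.
#' @return Length-3 force vector on `cell_i`.
#' @export
total_adhesion <- function(cell_i, neighbors, pairings, sigma, r_cut) {
  f <- c(0, 0, 0)
  if (!length(neighbors)) return(f)
  Pi <- site_positions(cell_i, "cc")
  for (k in seq_along(neighbors)) {
    nb <- neighbors[[k]]
    pr <- pairings[[k]]
    Pj <- site_positions(nb, "cc")
    if (nrow(pr$matches)) {
      for (r in seq_len(nrow(pr$matches))) {
        f <- f + site_pair_adhesion_force(Pi[pr$matches[r, 1L], ],
                                          Pj[pr$matches[r, 2L], ],
                                          sigma, r_cut)
      }
    }
    dvec <- nb$center - cell_i$center
    d <- sqrt(sum(dvec^2))
    if (d > 0 && min(pr$m_i, pr$m_j) > 0)
      f <- f + overlap_adhesion_force(pr$m_i, pr$m_j, sigma, r_cut, dvec / d)
  }
  f
}

#' Traction force from matrix-exposed C-M sites
#'
#' Every C-M site whose world position is exposed to the matrix (trapped in
#' no other cell's sphere) contributes `K * f_lr` along the outward surface
#' normal at the site. Sites trapped in an overlap region are inactive.
#' The resultant depends only on the exposure pattern; for a fully,
#' antipodally covered isolated sphere it vanishes.
#'
#' @param cell_i A [cell_state()].
#' @param others List of other `cell_state` objects (or an `m x 3` matrix of
#'   their centers).
#' @param K Adhesivity function value.
#' @param f_lr Force per ligand-receptor complex.
#' @return Length-3 force vector on `cell_i`.
#' @export
traction_force <- function(cell_i, others, K, f_lr) {
  dirs <- cell_i$cm_sites
  if (!nrow(dirs)) return(c(0, 0, 0))
  Q <- site_positions(cell_i, "cm")
  centers <- if (is.matrix(others)) others
             else do.call(rbind, lapply(others, function(c.) c.$center))
  exposed <- is_exposed(Q, centers, cell_i$radius)
  if (!any(exposed)) return(c(0, 0, 0))
  K * f_lr * colSums(dirs[exposed, , drop = FALSE])
}

#' Soft-sphere repulsion with an incompressible core
#'
#' When two cells overlap, a repulsive force linear in the center distance
#' pushes them apart: magnitude `eps * (2R - d) / (2R)^2` for
#' `d_core < d < 2R`, where `d_core = 2R(1 - alpha)` is the incompressible
#' core diameter. At or below the core the infinite wall is realized as the
#' finite magnitude `wall_force_cap`, so the equations of motion stay
#' integrable (core rebounds are a known non-biological artifact and are
#' ignored in analysis). Non-overlapping and tangent cells feel nothing.
#'
#' In the assembled per-cell force balance the per-contact scale `eps` is
#' multiplied by the number of C-C contacts per cell (see
#' [compute_system_forces()]); this function is the bare per-contact law.
#'
#' @param cell_i,cell_j [cell_state()] objects, or length-3 centers when
#'   `R` is supplied.
#' @param eps Repulsive energy scale per contact.
#' @param R Cell radius.
#' @param alpha Compressibility in (0,1).
#' @param wall_force_cap Finite magnitude used at or inside the core.
#' @return Length-3 force vector on cell i (pointing away from cell j).
#' @export
repulsion_force <- function(cell_i, cell_j, eps, R = NULL, alpha,
                            wall_force_cap = 1000) {
  if (inherits(cell_i, "cell_state")) {
    ci <- cell_i$center; cj <- cell_j$center
    if (is.null(R)) R <- cell_i$radius
  } else {
    ci <- as.numeric(cell_i); cj <- as.numeric(cell_j)
  }
  dvec <- ci - cj
  d <- sqrt(sum(dvec^2))
  if (d == 0) stop("coincident cell centers: repulsion direction undefined",
                   call. = FALSE)
  if (d >= 2 * R) return(c(0, 0, 0))
  d_core <- 2 * R * (1 - alpha)
  mag <- if (d <= d_core) wall_force_cap
         else eps * (2 * R - d) / (2 * R)^2
  mag * dvec / d
}

#' Overdamped velocity from the force balance
#'
#' Inertia is neglected: the total active force on a cell is balanced by
#' Stokes drag in the viscous matrix, giving
#' `v = (F_adh + F_trac + F_rep) / (6 * pi * eta * R)`.
#'
#' @param breakdown List (or matrix rows) with components `adhesion`,
#'   `traction`, `repulsion`, each a length-3 force vector.
#' @param eta ECM viscosity.
#' @param R Cell radius.
#' @return Length-3 velocity vector.
#' @export
net_velocity <- function(breakdown, eta, R) {
  f <- breakdown$adhesion + breakdown$traction + breakdown$repulsion
  f / (6 * pi * eta * R)
}

# ---------------------------------------------------------------------------
# System-level force engine (hot path).
#
# Computes adhesion, traction and repulsion for every cell of a system at
# the given centers, with the site directions and the per-step randomness
# (negotiation orders, multi-overlap assignment draws) frozen. Pairs are
# processed in ascending (i, j) order; one-to-one exclusivity of C-C sites
# is enforced globally across neighbors. A C-C site trapped in the overlap
# region of more than one neighbor is counted against a single neighbor,
# chosen by the frozen per-step uniform draw.

#' Per-cell force breakdown for a whole system
#'
#' Evaluates the three active force contributions for every cell at the
#' supplied centers, holding site directions and the per-step random choices
#' fixed (as within one integration step).
#'
#' @param centers `n x 3` matrix of cell centers.
#' @param radius Common cell radius.
#' @param cc,cm Lists of site-direction matrices, one per cell.
#' @param params A [cell_params()] object.
#' @param sigma Active adhesion energy scale (after any depletion schedule).
#' @param step_rand Per-step randomness from [draw_step_randomness()], or
#'   `NULL` for the deterministic fixed-order negotiation.
#' @return List of three `n x 3` matrices: `adhesion`, `traction`,
#'   `repulsion`.
#' @export
compute_system_forces <- function(centers, radius, cc, cm, params, sigma,
                                  step_rand = NULL) {
  n <- nrow(centers)
  Fa <- matrix(0, n, 3L)
  Ft <- matrix(0, n, 3L)
  Fr <- matrix(0, n, 3L)
  R <- radius
  r_cut <- params$r_cut
  two_R <- 2 * R
  d_core <- two_R * (1 - params$alpha)
  eps_eff <- params$eps * max(params$n_cc, 1L)   # per-contact scale x contacts
  reach <- two_R + r_cut

  # world positions of sites
  P <- vector("list", n)  # cc
  Q <- vector("list", n)  # cm
  for (i in seq_len(n)) {
    P[[i]] <- sweep(cc[[i]] * R, 2L, centers[i, ], "+")
    Q[[i]] <- sweep(cm[[i]] * R, 2L, centers[i, ], "+")
  }

  # neighbor pairs within interaction reach
  pairs <- NULL
  if (n > 1L) {
    idx <- utils::combn(n, 2L)
    dvecs <- centers[idx[2L, ], , drop = FALSE] - centers[idx[1L, ], , drop = FALSE]
    dists <- sqrt(rowSums(dvecs^2))
    keep <- dists < reach
    pairs <- list(i = idx[1L, keep], j = idx[2L, keep],
                  d = dists[keep], nv = dvecs[keep, , drop = FALSE])
  }

  # trapped status / neighbor assignment for C-C sites, exposure for C-M
  trapped_owner <- lapply(seq_len(n), function(i)
    integer(nrow(P[[i]])))                 # 0 = free, else neighbor index
  cm_exposed <- lapply(seq_len(n), function(i) rep(TRUE, nrow(Q[[i]])))
  if (!is.null(pairs) && length(pairs$i)) {
    overl <- which(pairs$d < two_R)
    # eligible overlap neighbors per cc site
    elig <- lapply(seq_len(n), function(i)
      vector("list", nrow(P[[i]])))
    for (k in overl) {
      i <- pairs$i[k]; j <- pairs$j[k]
      ti <- in_overlap_region(P[[i]], centers[j, ], R)
      tj <- in_overlap_region(P[[j]], centers[i, ], R)
      for (s in which(ti)) elig[[i]][[s]] <- c(elig[[i]][[s]], j)
      for (s in which(tj)) elig[[j]][[s]] <- c(elig[[j]][[s]], i)
      cm_exposed[[i]] <- cm_exposed[[i]] & !in_overlap_region(Q[[i]], centers[j, ], R)
      cm_exposed[[j]] <- cm_exposed[[j]] & !in_overlap_region(Q[[j]], centers[i, ], R)
    }
    for (i in seq_len(n)) {
      for (s in seq_along(elig[[i]])) {
        e <- elig[[i]][[s]]
        if (is.null(e)) next
        if (length(e) == 1L) {
          trapped_owner[[i]][s] <- e
        } else {
          u <- if (is.null(step_rand)) 0 else step_rand$assign[[i]][s]
          trapped_owner[[i]][s] <- e[1L + floor(u * length(e)) %% length(e)]
        }
      }
    }
  }

  # pair interactions in ascending (i, j) order with global exclusivity
  if (!is.null(pairs) && length(pairs$i)) {
    engaged <- lapply(seq_len(n), function(i) rep(FALSE, nrow(P[[i]])))
    ord <- order(pairs$i, pairs$j)
    for (k in ord) {
      i <- pairs$i[k]; j <- pairs$j[k]
      d <- pairs$d[k]; nv <- pairs$nv[k, ] / d
      m_ij <- sum(trapped_owner[[i]] == j)
      m_ji <- sum(trapped_owner[[j]] == i)
      fpair <- c(0, 0, 0)
      m_min <- min(m_ij, m_ji)
      if (m_min > 0) fpair <- fpair + (sigma / r_cut) * m_min * nv
      free_i <- which(trapped_owner[[i]] == 0L & !engaged[[i]])
      free_j <- which(trapped_owner[[j]] == 0L & !engaged[[j]])
      if (length(free_i) && length(free_j)) {
        ord_i <- if (is.null(step_rand)) seq_len(nrow(P[[i]]))
                 else step_rand$perms[[i]]
        mt <- greedy_match(P[[i]], P[[j]], free_i, free_j, ord_i, r_cut)
        if (nrow(mt)) {
          engaged[[i]][mt[, 1L]] <- TRUE
          engaged[[j]][mt[, 2L]] <- TRUE
          dm <- P[[j]][mt[, 2L], , drop = FALSE] - P[[i]][mt[, 1L], , drop = FALSE]
          s <- sqrt(rowSums(dm^2))
          ok <- s > 0
          if (any(ok)) {
            w <- (sigma / r_cut^2) * (r_cut - s[ok]) / s[ok]
            fpair <- fpair + colSums(dm[ok, , drop = FALSE] * w)
          }
        }
      }
      Fa[i, ] <- Fa[i, ] + fpair
      Fa[j, ] <- Fa[j, ] - fpair
      if (d < two_R) {
        mag <- if (d <= d_core) params$wall_force_cap
               else eps_eff * (two_R - d) / (two_R)^2
        Fr[i, ] <- Fr[i, ] - mag * nv
        Fr[j, ] <- Fr[j, ] + mag * nv
      }
    }
  }

  # traction from exposed C-M sites
  kf <- params$K * params$f_lr
  if (kf != 0) {
    for (i in seq_len(n)) {
      ex <- cm_exposed[[i]]
      if (any(ex))
        Ft[i, ] <- kf * colSums(cm[[i]][ex, , drop = FALSE])
    }
  }

  list(adhesion = Fa, traction = Ft, repulsion = Fr)
}
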