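#' Sample site directions uniformly on the unit sphere
#'
#' Draws `n` independent directions uniform on the unit sphere by
#' normalizing standard trivariate normal deviates (the zero vector, a
#' measure-zero event, is rejected). Surface receptor sites are stored as
#' these body-frame unit vectors; since cells cannot rotate about their
#' centers, a site's world position is always `center + R * direction`.
#'
#' @param n Number of sites (may be 0).
#' @return An `n x 3` matrix of unit row vectors.
#' @export
sample_sphere_sites <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 0)
    stop("'n' must be a single non-negative count", call. = FALSE)
  n <- as.integer(n)
  if (n == 0L) return(matrix(numeric(0), 0L, 3L))
  m <- matrix(stats::rnorm(3L * n), n, 3L)
  nrm <- sqrt(rowSums(m^2))
  while (any(bad <- nrm == 0)) {
    m[bad, ] <- stats::rnorm(3L * sum(bad))
    nrm <- sqrt(rowSums(m^2))
  }
  m / nrm
}

#' Construct a single cell state
#'
#' A cell is a sphere of fixed radius with two ordered sets of surface
#' sites, each stored as body-frame unit direction vectors: C-C adhesion
#' sites and C-M traction sites.
#'
#' @param center Numeric length-3 position of the cell center.
#' @param radius Cell radius (> 0).
#' @param cc_sites,cm_sites Matrices of unit direction row vectors (or
#'   counts, in which case fresh uniform sites are drawn).
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(center, radius, cc_sites = 0L, cm_sites = 0L) {
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("'center' must be a finite length-3 vector", call. = FALSE)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("'radius' must be a single positive number", call. = FALSE)
  as_sites <- function(x, what) {
    if (is.matrix(x)) {
      if (ncol(x) != 3L) stop(what, " must have 3 columns", call. = FALSE)
      nrm <- sqrt(rowSums(x^2))
      if (nrow(x) && any(abs(nrm - 1) > 1e-12))
        stop(what, " directions must be unit vectors", call. = FALSE)
      x
    } else {
      sample_sphere_sites(x)
    }
  }
  structure(list(center = center, radius = radius,
                 cc_sites = as_sites(cc_sites, "cc_sites"),
                 cm_sites = as_sites(cm_sites, "cm_sites")),
            class = "cell_state")
}

#' World coordinates of surface sites
#'
#' @param cell A [cell_state()].
#' @param which `"cc"` or `"cm"`, or a matrix of directions to place on this
#'   cell's surface.
#' @return Matrix of site positions, `center + radius * direction` per row.
#' @export
site_positions <- function(cell, which = "cc") {
  dirs <- if (is.matrix(which)) which
          else if (which == "cc") cell$cc_sites
          else if (which == "cm") cell$cm_sites
          else stop("'which' must be \"cc\", \"cm\" or a direction matrix",
                    call. = FALSE)
  sweep(dirs * cell$radius, 2L, cell$center, "+")
}

#' Overlap-region membership of site positions
#'
#' A site is trapped in the overlap region with another cell when it lies
#' strictly inside that cell's sphere. The boundary is excluded: a site
#' exactly on the neighbor's surface counts as outside (tangency is a
#' measure-zero configuration, and this keeps tangent cells force-free).
#'
#' @param site_pos Matrix of site positions (rows) or a length-3 vector.
#' @param center Length-3 center of the other cell.
#' @param radius Radius of the other cell.
#' @return Logical vector, one entry per site.
#' @export
in_overlap_region <- function(site_pos, center, radius) {
  if (!is.matrix(site_pos)) site_pos <- matrix(site_pos, 1L, 3L)
  d2 <- (site_pos[, 1L] - center[1L])^2 + (site_pos[, 2L] - center[2L])^2 +
        (site_pos[, 3L] - center[3L])^2
  d2 < radius^2
}

#' Matrix exposure of site positions
#'
#' A site is exposed to the extracellular matrix when it is trapped in no
#' other cell's sphere; only exposed C-M sites generate traction.
#'
#' @param site_pos Matrix of site positions (rows) or a length-3 vector.
#' @param centers `m x 3` matrix of the *other* cells' centers (the owner
#'   cell must not be included).
#' @param radius Common cell radius.
#' @return Logical vector, one entry per site.
#' @export
is_exposed <- function(site_pos, centers, radius) {
  if (!is.matrix(site_pos)) site_pos <- matrix(site_pos, 1L, 3L)
  exposed <- rep(TRUE, nrow(site_pos))
  if (is.null(centers) || NROW(centers) == 0L) return(exposed)
  if (!is.matrix(centers)) centers <- matrix(centers, 1L, 3L)
  for (k in seq_len(nrow(centers))) {
    exposed <- exposed & !in_overlap_region(site_pos, centers[k, ], radius)
  }
  exposed
}

#' Do two cells overlap?
#'
#' Cells overlap when their center distance is strictly less than the sum of
#' their radii; tangent cells (distance exactly `2R`) do not overlap and all
#' their sites are exposed.
#'
#' @param a,b [cell_state()] objects, or length-3 centers when `radius` is
#'   supplied.
#' @param radius Optional common radius when `a`, `b` are bare centers.
#' @return `TRUE` or `FALSE`.
#' @export
cells_overlap <- function(a, b, radius = NULL) {
  if (inherits(a, "cell_state")) {
    d <- sqrt(sum((a$center - b$center)^2))
    return(d < a$radius + b$radius)
  }
  d <- sqrt(sum((as.numeric(a) - as.numeric(b))^2))
  d < 2 * radius
}

#' Construct a multi-cell system state
#'
#' @param centers `n x 3` matrix of cell centers.
#' @param radius Common cell radius.
#' @param cc,cm Lists (length n) of site-direction matrices.
#' @param time Current simulation time.
#' @return An object of class `cell_system`.
#' @export
cell_system <- function(centers, radius, cc, cm, time = 0) {
  if (!is.matrix(centers) || ncol(centers) != 3L)
    stop("'centers' must be an n x 3 matrix", call. = FALSE)
  n <- nrow(centers)
  if (length(cc) != n || length(cm) != n)
    stop("'cc' and 'cm' must hold one site set per cell", call. = FALSE)
  structure(list(time = time, centers = centers, radius = radius,
                 cc = cc, cm = cm),
            class = "cell_system")
}

#' @export
print.cell_system <- function(x, ...) {
  cat(sprintf("<cell_system> %d cell(s), R = %g, t = %g\n",
              nrow(x$centers), x$radius, x$time))
  invisible(x)
}

# Extract one cell of a system as a cell_state.
#' @rdname cell_system
#' @param state A `cell_system`.
#' @param i Cell index.
#' @export
system_cell <- function(state, i) {
  cell_state(state$centers[i, ], state$radius, state$cc[[i]], state$cm[[i]])
}
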