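#' Model parameters for the cell-migration simulation
#'
#' Constructs and validates the full nondimensional parameter set of the
#' model. The defaults are the canonical parameter values of the framework:
#' cell radius 1, timestep 0.01, 100 cell-cell (C-C) and 100 cell-matrix
#' (C-M) receptor sites per cell, ECM viscosity 0.0016, C-C cutoff 1,
#' adhesion energy scale 0.004, repulsive energy scale 0.025,
#' compressibility 0.5, adhesivity K = 1 and traction 0.01 per
#' ligand-receptor complex.
#'
#' All quantities are nondimensional; the dimensional scales they correspond
#' to (a movement cycle of roughly 10 minutes, cell radius of order 10 um,
#' forces of order 1-100 pN) are commentary only and never enter any
#' computation.
#'
#' @param R Cell radius (length units). All cells share one radius.
#' @param dt Integration timestep; one timestep is one complete movement
#'   cycle (protrusion, attachment, traction, detachment), and all cells are
#'   synchronous.
#' @param n_cc Number of C-C adhesion sites per cell.
#' @param n_cm Number of C-M traction sites per cell.
#' @param eta ECM viscosity entering the Stokes drag 6*pi*eta*R.
#' @param r_cut Largest site-site distance at which a C-C adhesion bond acts.
#' @param sigma0 Adhesion energy scale per engaged site pair.
#' @param eps Repulsive energy scale per cell-cell contact complex.
#' @param alpha Compressibility in (0,1): centers cannot approach closer
#'   than the core diameter 2*R*(1-alpha).
#' @param K Adhesivity function value for C-M sites (taken equal for all
#'   sites and cells).
#' @param f_lr Traction force per ligand-receptor complex.
#' @param cc_mode,cm_mode `"static"` (sites keep their initial positions) or
#'   `"dynamic"` (sites are randomly reallocated after every timestep).
#' @param decay_exponent Power-law exponent p > 0 of the adhesion depletion
#'   schedule sigma(t) = sigma0 * (1 - (t/t_total)^p), or `"none"` for
#'   constant adhesion.
#' @param t_total Total simulated time.
#' @param wall_force_cap Finite force magnitude standing in for the infinite
#'   wall at the incompressible core.
#' @param seed Integer seed for the run's random stream.
#' @param negotiation `"per_step"` (the one-to-one site negotiation visits
#'   free sites in a fresh random order every timestep, the model's default)
#'   or `"fixed"` (index order; a deterministic diagnostic mode used for
#'   equilibrium calibration).
#'
#' @return An object of class `cell_params`: a validated named list.
#' @seealso [case_to_modes()], [load_params()], [save_params()]
#' @examples
#' p <- cell_params()            # canonical defaults
#' p2 <- cell_params(f_lr = 0)   # no traction
#' @export
cell_params <- function(R = 1, dt = 0.01, n_cc = 100, n_cm = 100,
                        eta = 0.0016, r_cut = 1, sigma0 = 0.004,
                        eps = 0.025, alpha = 0.5, K = 1, f_lr = 0.01,
                        cc_mode = "static", cm_mode = "static",
                        decay_exponent = "none", t_total = 8,
                        wall_force_cap = 1000, seed = 1L,
                        negotiation = "per_step") {
  p <- list(R = R, dt = dt, n_cc = n_cc, n_cm = n_cm, eta = eta,
            r_cut = r_cut, sigma0 = sigma0, eps = eps, alpha = alpha,
            K = K, f_lr = f_lr, cc_mode = cc_mode, cm_mode = cm_mode,
            decay_exponent = decay_exponent, t_total = t_total,
            wall_force_cap = wall_force_cap, seed = as.integer(seed),
            negotiation = negotiation)
  validate_params(p)
  structure(p, class = "cell_params")
}

# Validation is total: every violated invariant stops with the field name
# and the offending value; nothing is silently clamped.
validate_params <- function(p) {
  num1 <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", field, "' must be a single finite number, got: ",
           deparse(v), call. = FALSE)
    v
  }
  pos <- function(field) {
    v <- num1(field)
    if (v <= 0) stop("parameter '", field, "' must be > 0, got: ", v,
                     call. = FALSE)
    v
  }
  nonneg <- function(field) {
    v <- num1(field)
    if (v < 0) stop("parameter '", field, "' must be >= 0, got: ", v,
                    call. = FALSE)
    v
  }
  pos("R"); pos("dt"); pos("eta"); pos("r_cut")
  nonneg("sigma0"); nonneg("eps"); nonneg("K"); nonneg("f_lr")
  nonneg("wall_force_cap")
  for (field in c("n_cc", "n_cm")) {
    v <- num1(field)
    if (v < 0 || v != round(v))
      stop("parameter '", field, "' must be a non-negative integer, got: ",
           v, call. = FALSE)
  }
  a <- num1("alpha")
  if (a <= 0 || a >= 1)
    stop("parameter 'alpha' must lie strictly in (0, 1), got: ", a,
         call. = FALSE)
  if (num1("t_total") < p$dt)
    stop("parameter 't_total' must be >= dt, got: ", p$t_total, call. = FALSE)
  for (field in c("cc_mode", "cm_mode")) {
    v <- p[[field]]
    if (!is.character(v) || length(v) != 1L ||
        !v %in% c("static", "dynamic"))
      stop("parameter '", field, "' must be \"static\" or \"dynamic\", got: ",
           deparse(v), call. = FALSE)
  }
  de <- p$decay_exponent
  if (!(identical(de, "none") ||
        (is.numeric(de) && length(de) == 1L && is.finite(de) && de > 0)))
    stop("parameter 'decay_exponent' must be a positive number or \"none\", ",
         "got: ", deparse(de), call. = FALSE)
  if (!is.numeric(p$seed) || length(p$seed) != 1L || is.na(p$seed))
    stop("parameter 'seed' must be a single integer, got: ",
         deparse(p$seed), call. = FALSE)
  if (!p$negotiation %in% c("per_step", "fixed"))
    stop("parameter 'negotiation' must be \"per_step\" or \"fixed\", got: ",
         deparse(p$negotiation), call. = FALSE)
  invisible(p)
}

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params>\n")
  for (nm in names(x)) cat(sprintf("  %-15s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Map a site-dynamics case label to the site modes
#'
#' The four regimes of receptor dynamics: case I ("persistence") keeps both
#' site types fixed, case II reallocates only C-M sites each timestep,
#' case III only C-C sites, and case IV both.
#'
#' @param case_label One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @return A list with elements `cc_mode` and `cm_mode`.
#' @examples
#' case_to_modes("II")  # list(cc_mode = "static", cm_mode = "dynamic")
#' @export
case_to_modes <- function(case_label) {
  modes <- switch(as.character(case_label),
    I   = list(cc_mode = "static",  cm_mode = "static"),
    II  = list(cc_mode = "static",  cm_mode = "dynamic"),
    III = list(cc_mode = "dynamic", cm_mode = "static"),
    IV  = list(cc_mode = "dynamic", cm_mode = "dynamic"),
    stop("unknown case label: ", deparse(case_label),
         " (expected \"I\", \"II\", \"III\" or \"IV\")", call. = FALSE)
  )
  modes
}

#' Apply a case label to a parameter set
#'
#' @param params A [cell_params()] object.
#' @param case_label One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @return The parameter set with `cc_mode`/`cm_mode` set accordingly.
#' @export
apply_case <- function(params, case_label) {
  m <- case_to_modes(case_label)
  params$cc_mode <- m$cc_mode
  params$cm_mode <- m$cm_mode
  params
}

#' Load model parameters from a YAML configuration file
#'
#' The configuration dialect is YAML with up to three top-level sections:
#' `model` (fields of [cell_params()]), `experiment` and `output` (both kept
#' verbatim as attributes for callers such as the command-line driver).
#' Missing `model` keys take the canonical defaults; unknown keys are
#' rejected by name.
#'
#' @param path Path to a YAML file, or a YAML string.
#' @return A validated `cell_params` object; any `experiment`/`output`
#'   sections are attached as attributes of the same names.
#' @seealso [save_params()]
#' @export
load_params <- function(path) {
  doc <- if (is.character(path) && length(path) == 1L && !file.exists(path) &&
             grepl("[:\n]", path)) {
    yaml::yaml.load(path)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stop("configuration must be a YAML mapping", call. = FALSE)
  unknown_sections <- setdiff(names(doc), c("model", "experiment", "output"))
  if (length(unknown_sections))
    stop("unknown configuration section(s): ",
         paste(unknown_sections, collapse = ", "), call. = FALSE)
  model <- doc$model
  if (is.null(model)) model <- list()
  known <- names(formals(cell_params))
  unknown <- setdiff(names(model), known)
  if (length(unknown))
    stop("unknown model parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p <- do.call(cell_params, model)
  attr(p, "experiment") <- doc$experiment
  attr(p, "output") <- doc$output
  p
}

#' Serialize model parameters to YAML
#'
#' Writes the `model` section in a fixed key order, so equal parameter sets
#' serialize to byte-identical files. `load_params(save_params(p))`
#' reconstructs an equal object.
#'
#' @param params A `cell_params` object.
#' @param path File path to write; if `NULL`, the YAML text is returned.
#' @return `path` invisibly, or the YAML string when `path` is `NULL`.
#' @export
save_params <- function(params, path = NULL) {
  stopifnot(inherits(params, "cell_params"))
  fields <- params[names(formals(cell_params))]
  txt <- yaml::as.yaml(list(model = fields))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Experiment specification for batch sweeps
#'
#' Describes a batch experiment: a grid of parameter points (each point is a
#' named list of `cell_params` overrides, e.g. `list(f_lr = 0.004)`), the
#' number of independent runs per point, the site-dynamics case, the initial
#' configuration, and the seed ladder. Run `k` (1-based) at grid point `g`
#' uses seed `base_seed + (g - 1) * seed_stride + (k - 1)`, where `g` indexes
#' the canonically ordered grid, so results do not depend on the order in
#' which points are supplied.
#'
#' @param grid A list of named lists of parameter overrides (one per point).
#' @param n_runs Independent runs per grid point (each run draws a fresh
#'   random distribution of surface sites).
#' @param case Site-dynamics case label, `"I"`..`"IV"`.
#' @param init `"pair"` or `"cluster"`.
#' @param d0 Initial center-to-center distance for pair initialization
#'   (default: touching, `2 * R`).
#' @param n_cells Number of cells for cluster initialization.
#' @param base_seed Base of the seed ladder.
#' @param seed_stride Seed spacing between grid points; must exceed `n_runs`.
#' @param params Baseline [cell_params()] that every point modifies.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(grid, n_runs = 100, case = "I", init = "pair",
                            d0 = NULL, n_cells = 50, base_seed = 1L,
                            seed_stride = 10000L, params = cell_params()) {
  stopifnot(inherits(params, "cell_params"))
  if (!is.list(grid) || !length(grid))
    stop("'grid' must be a non-empty list of parameter-override lists",
         call. = FALSE)
  if (!all(vapply(grid, is.list, TRUE)))
    stop("each grid point must be a named list of overrides", call. = FALSE)
  if (n_runs < 1) stop("'n_runs' must be >= 1", call. = FALSE)
  if (seed_stride <= n_runs)
    stop("'seed_stride' must exceed 'n_runs'", call. = FALSE)
  case_to_modes(case)  # validates the label
  if (!init %in% c("pair", "cluster"))
    stop("'init' must be \"pair\" or \"cluster\"", call. = FALSE)
  if (is.null(d0)) d0 <- 2 * params$R
  if (init == "pair" && d0 <= 2 * params$R * (1 - params$alpha))
    stop("'d0' must exceed the core-exclusion distance 2R(1-alpha) = ",
         2 * params$R * (1 - params$alpha), call. = FALSE)
  structure(list(grid = grid, n_runs = as.integer(n_runs), case = case,
                 init = init, d0 = d0, n_cells = as.integer(n_cells),
                 base_seed = as.integer(base_seed),
                 seed_stride = as.integer(seed_stride), params = params),
            class = "experiment_spec")
}
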