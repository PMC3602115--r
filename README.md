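# cellmotion

An off-lattice, three-dimensional agent-based model of collective cell
migration through extracellular matrix (ECM), built for computational cell
biophysicists studying how receptor-mediated forces shape the stability and
motility of small cellular assemblies — cell pairs above all, as the
elementary unit of collective motion, and clusters of tens of cells.

## The model

Cells are spheres of fixed radius `R` that may partially overlap. Each cell
carries two kinds of coarse-grained surface receptor sites, placed uniformly
at random on its surface:

* **C-C (cell-cell) sites** mediate adhesion. Outside the overlap region of
  two cells, sites engage strictly one-to-one: each free site claims the
  nearest unclaimed partner site on the neighbor within a cutoff `r_cut`,
  with the visiting order randomly permuted at every timestep so the
  negotiation restarts anew. An engaged pair at site separation `s` pulls
  with force `sigma (r_cut - s) / r_cut^2` along the line of the two sites.
  Sites trapped in the overlap region interact by count instead: the
  minimum of the two trapped counts, `M = min(m_i, m_j)`, contributes
  `sigma M / r_cut` along the line of centers.
* **C-M (cell-matrix) sites** generate traction. Every site exposed to the
  matrix (trapped in no neighbor's sphere) contributes `K f_lr` radially
  outward along its surface normal; trapped sites are silent. With ~100
  random sites, the resultant is a nonzero, site-distribution-dependent
  propulsive force.

Overlapping cells also repel: a force linear in the center distance `d`,
with an incompressible core of diameter `2R(1 - alpha)` realized as a
capped wall force. Motion is overdamped — the forces, all applied at the
cell center, balance a Stokes drag `6 pi eta R v` — giving a coupled,
stochastic first-order system for the cell centers,

```
v_i = (F_adh,i + F_trac,i + F_rep,i) / (6 pi eta R),
```

integrated by a fixed-step classical Runge-Kutta scheme with the random
site configuration frozen within each step. Sites can be *static* for a
whole run or *dynamic* (resampled every timestep), independently for the
two site types: cases I (static/static, "persistence") through IV
(dynamic/dynamic).

The package implements the model plus its standard experiments and
statistics: time of first break-up (TFB, first excursion of the pair
distance beyond `2R`), companion time (CT, total bound time), break-up
fractions across traction with Gompertz fits
`y = exp(-exp(-c (x - b)))`, adhesion-depletion schedules
`sigma(t) = sigma0 (1 - (t/T)^p)`, and cluster observables (radius of
gyration over all cells, mean overlapping-neighbor count).

All quantities are nondimensional; the canonical parameter set
(`cell_params()` defaults) is `R = 1`, `dt = 0.01`, 100 sites of each
type, `eta = 0.0016`, `r_cut = 1`, `sigma = 0.004`, `eps = 0.025`,
`alpha = 0.5`, `K = 1`, `f_lr = 0.01`.

## Worked example

Calibration first: with no traction, a touching pair must relax to a bound
equilibrium of the adhesion-repulsion balance.

```r
library(cellmotion)
p <- cell_params(f_lr = 0)          # canonical parameters, traction off
set.seed(1)
pair <- init_pair(p)                # two touching cells, random sites
short <- p; short$t_total <- 2
traj <- run_simulation(pair, short, seed = NULL)
eq <- relax_to_equilibrium(attr(traj, "final_state"), p)
sqrt(sum((eq$state$centers[1, ] - eq$state$centers[2, ])^2))
#> [1] 1.961687                      # bound: d* < 2R, outside the core
eq$speed
#> [1] 9.99487e-11                   # a genuine fixed point
```

The pair is bound (`d* = 1.96 < 2R = 2`) and at rest. Now switch traction
on at an intermediate strength with dynamic C-M sites (case II) and gather
break-up statistics over independent site draws:

```r
p2 <- apply_case(cell_params(), "II")
p2$f_lr <- 0.006
b <- run_pair_batch(p2, n_runs = 5, base_seed = 1)
unlist(b$batch)
#>   mean_tfb   sem2_tfb    mean_ct    sem2_ct frac_broke     n_runs
#>  1.4300000  2.6870579  7.7540000  0.2106751  1.0000000  5.0000000
```

Every run broke up (`frac_broke = 1`), and quickly (`mean TFB = 1.43` of 8
time units) — but the mean companion time is 7.75: with traction direction
re-randomized each movement cycle, detached cells keep finding their way
back and spend almost the whole run bound. Under persistence (case I) the
same traction gives CT almost equal to TFB: break-ups are irreversible.
That contrast is the model's central result for pair dynamics.

The command-line driver in `inst/cli/cellmotion.R` exposes `run`,
`sweep-pairs`, `sweep-depletion` and `cluster` subcommands over YAML
configuration files.

## Further reading

The methods vignette (`vignettes/cellmotion-methods.Rmd`) documents the
force laws and their normalizations, the stage-freezing of the stochastic
integrator, the calibration of the bound state, what the statistics mean,
and known limitations.
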