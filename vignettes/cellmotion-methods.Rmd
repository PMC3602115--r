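---
title: "Receptor-mediated cell migration in 3D: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor-mediated cell migration in 3D: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmotion)
```

## The model

`cellmotion` simulates groups of cells migrating through extracellular
matrix (ECM) as an off-lattice, cell-center model. Each cell is a sphere of
fixed radius $R$ that can partially overlap its neighbors (a stand-in for
deformability), carrying two sets of coarse-grained receptor sites placed
uniformly at random on its surface: C-C adhesion sites and C-M traction
sites. Inertia is negligible at cellular scales, so the forces on each cell
balance a Stokes drag at every instant:

$$\mathbf v_i \;=\; \frac{\mathbf F^{\mathrm{adh}}_i + \mathbf F^{\mathrm{trac}}_i
+ \mathbf F^{\mathrm{rep}}_i}{6\pi\eta R},$$

a coupled, autonomous, first-order system for the cell centers. All forces
are applied at the center — cells translate but cannot rotate, so a site's
world position is always $\mathbf c_i + R\,\hat{\mathbf u}$ for its
body-frame direction $\hat{\mathbf u}$.

One timestep $\Delta t$ represents one complete movement cycle (protrusion,
attachment, traction, detachment), assumed synchronous and of equal
duration across cells. The per-step forces are cycle averages, not
instantaneous values.

### Adhesion

Outside the overlap region of two cells, C-C sites engage strictly
one-to-one. At each timestep the free sites of the lower-indexed cell are
visited in a freshly drawn random order; each claims the nearest unclaimed
free site of the neighbor within the cutoff $r_{\mathrm{cut}}$. An engaged
pair at site separation $s$ attracts with magnitude

$$F^{(4)}(s) = \frac{\sigma}{r_{\mathrm{cut}}^2}\,(r_{\mathrm{cut}} - s),
\qquad 0 \le s \le r_{\mathrm{cut}},$$

along the line of the two sites: zero at the cutoff, maximal
($\sigma/r_{\mathrm{cut}}$) at contact. Sites trapped inside the partner
sphere interact by count instead: with $m_i$, $m_j$ trapped sites on the
two cells, the minimum $M = \min(m_i, m_j)$ (sites must pair to pull)
contributes

$$F^{(5)} = \frac{\sigma}{r_{\mathrm{cut}}}\,M$$

along the line of centers. In assemblies, a site trapped in more than one
neighbor's overlap region is counted against a single neighbor drawn
uniformly per timestep, and one-to-one exclusivity is enforced globally:
no site appears in two bonds, with pairs processed in ascending index
order.

### Traction

Each C-M site exposed to the matrix contributes $K f^{LR}$ radially
outward along its surface normal; sites trapped in an overlap region are
silent. Matrix ligands are treated as unlimited and every exposed site as
active. A perfectly uniform, antipodally balanced covering would produce
zero resultant; with a finite number of random sites the resultant is a
nonzero propulsive force whose direction is fixed for static sites
(*persistent* motion, e.g. under a chemotactic gradient) and re-randomized
every cycle for dynamic sites (receptors rearranging while probing the
matrix).

### Repulsion and the incompressible core

Overlapping cells repel along the line of centers with a force linear in
the center distance $d$, vanishing at contact ($d = 2R$) and cut off by a
wall at the incompressible core $d_{\mathrm{core}} = 2R(1-\alpha)$, where
$\alpha$ is the compressibility. The wall is realized as a finite capped
magnitude (`wall_force_cap`, default $10^3$) so the system remains
integrable; core rebounds are a known non-biological artifact that the
analysis ignores.

**Normalization of the repulsive scale.** The per-bond adhesion and
per-complex traction scales make the per-cell resultants grow with the
site count $N_{CC}$: at the canonical values the net adhesion on a bound
pair is of order $\sigma N_{CC}/40 \approx 0.01$–$0.1$. A repulsion slope
of order $\varepsilon/(2R)^2$ alone could never balance it — a pair would
collapse onto the core wall, and no bound state would exist anywhere in
$(d_{\mathrm{core}}, 2R)$. Since the deformation cost of overlap is borne
by the same population of surface contacts, the package scales the
per-contact $\varepsilon$ by the contact count:

$$F^{\mathrm{rep}}(d) = \frac{\varepsilon\,N_{CC}}{(2R)^2}(2R - d),
\qquad d_{\mathrm{core}} < d < 2R.$$

With the canonical values this places a stable bound equilibrium at
$d^\ast \approx 1.94$–$1.98$ (verified by the test suite over ten site
draws), satisfying the calibration requirement that a touching pair with
no traction relaxes into a bound state. `repulsion_force()` itself keeps
the bare per-contact law; the $N_{CC}$ factor is applied where per-cell
forces are assembled, so alternative normalizations can be swapped in one
place.

## Parameters

`cell_params()` carries the full nondimensional set; all defaults below
are the model's canonical values.

| name | default | meaning |
|------|---------|---------|
| `R` | 1 | cell radius (the length unit is ~a cell radius, ~10 um) |
| `dt` | 0.01 | timestep = one movement cycle (~10 min) |
| `n_cc`, `n_cm` | 100 | sites per cell; a compromise between realism and cost — enough that coverage is never degenerate, and pair dynamics is insensitive to further increase |
| `eta` | 0.0016 | ECM viscosity in the Stokes drag |
| `r_cut` | 1 | C-C bond cutoff; equal to `R` so cells engage in proximity — much larger is not biological, much smaller prevents stable bound states |
| `sigma0` | 0.004 | adhesion energy scale per bond |
| `eps` | 0.025 | repulsive energy scale per contact |
| `alpha` | 0.5 | compressibility; cores touch at `d = 1` |
| `K`, `f_lr` | 1, 0.01 | adhesivity and traction per ligand-receptor complex |
| `t_total` | 8 | run length (~800 cycles, several days of cell time); an experiment knob, not a model constant |
| `wall_force_cap` | 1000 | finite stand-in for the infinite core wall |

The site-dynamics regime is a pair of modes (`cc_mode`, `cm_mode`), with
the four named cases I (static/static), II (static/dynamic), III
(dynamic/static), IV (dynamic/dynamic) mapped by `case_to_modes()`.
Validation is total — every violated invariant names its field; nothing is
clamped. Configuration files use YAML with `model`, `experiment` and
`output` sections; `save_params()` writes keys in a fixed order so equal
parameter sets serialize identically.

## The integrator and its frozen randomness

Each step advances all centers simultaneously with classical fourth-order
Runge-Kutta. Within a step, the stochastic configuration is frozen: site
directions, the negotiation visiting order, and the multi-overlap
assignment draws are fixed for all four stages, so the stage velocity
field is a deterministic function of positions. Geometric predicates
(overlap membership, exposure, pairings under the frozen order) are
re-evaluated at each stage from the stage positions; the depletion
schedule is evaluated at the step's start time. Site resampling for
dynamic modes happens between steps, never inside one. On a smooth
segment the observed convergence order is 4 (checked against a
100-fold-finer reference).

Numerical edge conventions, chosen once:

* *Boundaries are strict.* "Inside the overlap region" means strictly
  inside; tangent cells ($d = 2R$ exactly) are non-overlapping, their
  sites exposed, and the pair classified bound but force-free. This makes
  the bound/detached threshold ($d \le 2R$ bound) consistent with a
  force-free tangency.
* *Coincident engaged sites* ($s = 0$, direction undefined) contribute
  zero force — a measure-zero event.
* *Negotiation sidedness.* The greedy claim is one-sided: for a pair
  $(i, j)$ the lower-indexed cell's sites do the claiming, in its frozen
  permutation order. The model prescribes the random order and
  nearest-available choice; sidedness is a convention kept fixed for
  reproducibility.
* *Wall events* inside a stage simply use the capped force; there is no
  event detection or step rejection.

### The bound equilibrium and the dither floor

The greedy matching is order-dependent whenever two sites contest the same
partner, so the per-step random permutation dithers the net force on a
bound pair by a fraction of the single-bond scale. A relaxing pair
therefore becomes stationary *in distribution* — its separation settles to
four decimals — but not pointwise at rest. The calibration operation
`relax_to_equilibrium()` computes the underlying fixed point exactly: it
freezes the entire engagement pattern (matches, trapped counts, exposure)
at the current positions, which makes the force field smooth, and
integrates until the residual speed falls below tolerance (default
`1e-10`). The equilibrium calibration reported by the test suite and the
acceptance script is this fixed point; the never-breaking of the full
stochastic dynamics at zero traction is checked separately over ten
independent site draws.

## Initial conditions and what the generator emulates

`init_pair()` places two cells on the x-axis at separation $d_0$ (default
$2R$: touching) with fresh uniform site draws — the configuration of all
pair experiments. `init_cluster()` packs $n$ cells uniformly into a ball
sized for a nominal 30% volume fraction by rejection sampling under the
core-exclusion constraint (all pairwise distances $> 2R(1-\alpha)$), the
standard initial condition for cluster dissociation runs. Uniform sphere
sampling normalizes trivariate normal deviates — exactly uniform and
reproducible.

These generators emulate the model's own idealizations, not real tissue:
monodisperse spheres, homogeneous ECM with constant viscosity, unlimited
matrix ligands, fixed site counts. Passing tests therefore demonstrate the
internal correctness and calibration of the model, not agreement with any
particular experimental system.

## Observables and statistics

For a pair run of total time $T$:

* **TFB** — time of first break-up: the first *sampled* time with
  $d > 2R$; runs that never break contribute $T$ to batch means
  (right-censoring by truncation, matching curves that saturate at the
  maximum time).
* **CT** — companion time: total bound time, accumulated by the
  left-endpoint rule at the sampling resolution; no sub-step crossing
  interpolation. CT $\ge$ TFB whenever a break-up exists, with equality
  when the pair never rejoins — the signature separating persistent from
  dynamic-traction regimes.
* **Batch aggregates** report means with error bars of twice the standard
  error of the mean, and the fraction of runs with at least one break-up.
* **Gompertz fits** of break-up fractions against traction use
  $y = \exp(-\exp(-c\,(x - b)))$: asymptotes 0 and 1, $b$ the abscissa
  displacement, $c$ the growth rate toward the upper asymptote. The fit is
  deterministic: Levenberg-Marquardt from $b_0$ at the point nearest
  $y = e^{-1}$ (the curve's value at $x = b$; first on ties) and
  $c_0 = 1$. Non-convergence is reported, never swallowed; near-step data
  on coarse grids can legitimately fail or return a very large $c$.
* **Cluster observables**: the radius of gyration is computed over *all*
  cells regardless of connectivity (so free cells make it grow linearly),
  and the mean overlapping-neighbor count uses center distance $< 2R$.

Batch experiments use a seed ladder — run $k$ at canonical grid position
$g$ uses `base_seed + (g-1) * seed_stride + (k-1)` — so every run is
independently reproducible and grid iteration order is irrelevant.

## Experiment scale and default grids

The traction values at which pairs cross from never-breaking to
always-breaking are not a universal constant of the model; they were
located once at the canonical parameter set by a coarse bisection pre-pass
and frozen as the default grid `f_lr` in {0.002, 0.004, 0.006, 0.009,
0.012} (`default_traction_grid()`). Production sweeps default to 100 runs
per point; the test suite and the acceptance script use 10 runs per point
on 4–6 point grids and runs of 800 steps, and the cluster demonstration
uses 50 cells over 100 steps — sizes chosen so the whole suite completes
in minutes while leaving the break-up signatures unambiguous.

## Known limitations

* Movement cycles are synchronous; the asynchronous extension (a per-cell
  probability of zero traction per cycle) is deliberately not adopted.
* No receptor shuttling or membrane diffusion: site dynamics are either
  frozen or fully resampled.
* Cells cannot rotate, deform (beyond overlap), divide or die; the ECM is
  homogeneous, non-depleting and purely viscous.
* The greedy one-to-one negotiation is order-dependent in contested
  configurations; this is intrinsic to the model's stochastic
  re-negotiation, and is why pointwise equilibria are computed with the
  engagement pattern frozen.
* Core-wall rebounds under very strong adhesion (or very soft cells) are
  integrable but non-biological; results in that regime should be
  discarded.
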