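---
title: "Modeling cell aggregation on soft substrates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cell aggregation on soft substrates: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellagg)
```

## The biological problem

Weakly adherent cells (glioma lines such as F98 and U87) deposited on a soft
hydrogel do not spread; they stay round, perform a random walk on the
surface, stick to each other on contact, and over a few hours coalesce into
compact multicellular aggregates.  Time-lapse microscopy records a fixed
field of view (1280 x 1080 px, 0.658 um/px) at one frame per minute, and
the experimental observables are two curves: the number of aggregates over
time, normalized by the initial cell count, and the mean projected
aggregate area.  `cellagg` provides two complementary models of this
process plus the measurement and calibration machinery to connect them to
such curves.

## The spaceless model: Smoluchowski coagulation

The size spectrum $N_k(t)$ (number of aggregates of $k$ cells) follows the
coagulation equations

$$\frac{dN_k}{dt} = \tfrac12 \sum_{i+j=k} K_{ij} N_i N_j - N_k \sum_i K_{ik} N_i.$$

Two kernel scenarios are implemented:

* **Constant kernel.**  Every pair of clusters merges at the same rate.  We
  parameterize it by the classical *coagulation constant* $K$ defined
  through the total-number equation $dN/dt = -K N^2$, whose solution is
  $N(t) = N_0/(1 + K N_0 t)$.  Note this corresponds to kernel entries
  $K_{ij} = 2K$ in the size-resolved equation above (the standard
  $\tfrac12$ in the gain term halves the pairwise rate in the total); the
  package keeps this bookkeeping internal so that the fitted rate is the
  one appearing in the closed form.  The equivalence of the integrated
  spectrum and the closed form is tested to $10^{-6}$ relative.
* **Monomer-only kernel.**  Only individual cells move and react
  ($K_{1j}=K_{j1}=K_1$, $K_{ij}=0$ for $i,j>1$), giving
  $dN_1/dt = -K_1 N_1 N$, $dN_2/dt = K_1(\tfrac12 N_1^2 - N_1 N_2)$ and
  $dN_k/dt = K_1 N_1 (N_{k-1}-N_k)$ for $k \ge 3$.  The sign of the dimer
  source term is fixed by requiring that the $k$-resolved derivatives
  telescope exactly to the total-number equation
  $dN/dt = K_1 N_1(\tfrac12 N_1 - N)$ (verified numerically to
  $10^{-10}$), and independently by agreement with an exact Gillespie
  stochastic simulation.

The spectrum is truncated at `kmax` (default 256).  Coagulation past the
truncation edge loses mass; the integrator monitors
$\sum_k k N_k$ and doubles `kmax` automatically when more than 1% of the
mass is lost over the requested horizon.  Integration uses
`deSolve::lsoda` with relative tolerance $10^{-8}$.

Kernel rates live in "count space" (per pair per minute, for counts in one
field of view).  `convert_rate_units()` maps to area units via the
observed field area $842.24 \times 710.64\ \mu m^2$; this normalization
convention is configurable because published rates in $m^2 s^{-1}$ do not
state it.

**Fitting.** `smol_fit()` minimizes the (optionally weighted) sum of
squared count residuals over the single rate parameter, by a log-spaced
bracket over the dimensionless decay depth $K N_0 t_{max}$ followed by
golden-section refinement (`stats::optimize`).  `kernel = "auto"` fits both
scenarios and selects the lower SSE; ties are reported and resolved toward
the constant kernel.  A flat series returns rate 0 with a warning.

## The spatial model: off-lattice agents

Cells are disks of fixed diameter $d$ (13.2 um for F98, 21.1 um for U87)
with real-valued center coordinates in a square periodic box.  The box side
(842.24 um by default) matches the experimental field width; periodic
boundaries avoid wall artifacts.  One iteration is one minute.  The rules,
per iteration:

1. **Aggregate motion.**  Aggregates (connected components of the contact
   graph; two cells are in contact when their center distance is at most
   $d$, with a $10^{-6}$ um tolerance) perform one rigid random step of
   length $a_0/N$ for an $N$-cell aggregate, mirroring the $1/r$ scaling
   of Stokes drag.  The move is truncated at first contact with any
   non-member.
2. **Individual motion.**  Every cell, visited in a fresh random
   permutation, draws a direction and moves by $a_0/(1+n^2)$ where $n$ is
   its current neighbor count.  Moves are truncated exactly at the
   hard-core distance (ray-circle intersection under the minimal-image
   convention); a cancel-instead-of-truncate variant is available as
   `cancel_on_contact`.
3. **Adhesion (no detachment).**  A move is kept only if the cell ends
   with at least as many neighbors as it started with.
4. **Superimposition.**  Centers may approach down to
   $d(1-\alpha_{max})$; the coefficient $\alpha_{max} \in [0,1)$ is the 2D
   stand-in for 3D stacking and deformability (0.7 for F98, 0.2 for U87,
   set from images of superimposed cell pairs, never fitted).
5. **Compaction.**  Members of an $N$-cell aggregate draw their direction
   in a sector of half-width $90(1+e^{-N/40})$ degrees centered on the
   direction to the aggregate's center of mass; isolated cells draw
   uniformly.  The sector shrinks from the full circle (small aggregates)
   to $\pm 90^\circ$ (massive ones).
6. **Flux.**  On non-adhesive gels a hydrodynamic bias restricts
   directions to the half-plane around the flux direction.  Scope options:
   individuals only, individuals and all aggregates (default), or
   individuals and aggregates below a size threshold (default 10 cells;
   the threshold is a package choice, "small" being unquantified in the
   source experiments).
7. **Proliferation.**  After moving, each cell divides with probability
   $\kappa$ per iteration; a single daughter position is drawn at distance
   $d$ and uniform angle and the division is aborted (no retries) if it
   would violate the superimposition rule.  Daughters are immediate
   obstacles but are not updated in their birth iteration (this shifts the
   effective $\kappa$ negligibly).

Design choices where the rules left room:

* The composition of collective and individual motion is ordered
  rigid-then-individual, with cluster membership frozen per iteration;
  this keeps the hard-core constraint satisfiable and runs reproducible.
  Neighbor counts for step lengths and the no-detachment rule are
  recomputed on the fly, since cells move sequentially.
* When compaction and flux could both apply to an aggregate member, the
  compaction sector wins; flux still drives the aggregate's collective
  move and individual cells.
* The periodic center of mass is the per-axis circular mean (map
  coordinates to angles, average unit vectors, map back), which is
  translation-equivariant and equals the minimal-image arithmetic mean for
  clusters smaller than half the box — always the case here.
* Initialization rejection-samples uniform positions under the hard-core
  constraint (budget $10^6$ draws, then an error reporting the achievable
  density).
* All randomness flows through R's RNG in a documented draw order
  (aggregate directions in order of smallest member index, a Fisher-Yates
  permutation, then per cell: direction, division Bernoulli, placement
  angle), so a configuration plus seed reproduces a trajectory
  bit-exactly.  The engine core is C++ (Rcpp) for replicate throughput.

Numerical tolerances: contact tolerance $10^{-6}$ um on the neighbor
relation; hard-core slack $10^{-9}$ um on constraint checks.  The
invariant `min pairwise distance >= d(1 - alpha_max) - 1e-9` is asserted
across rule combinations in the test suite.

## Measurement: mirroring the image analysis

Simulated configurations are rasterized into the experimental viewport
(disk radius $d/2$, pixel centers tested under the minimal image
convention).  For the calibrated box the viewport is 1280 x 1080 px —
the full box width but only 1080 of 1280 rows, reproducing the
experimental crop; for smaller boxes the viewport spans the whole box.
Connected components of the binary mask are labeled with 8-connectivity
(the Fiji particle-analysis convention; 4-connectivity is a switch).  On
an axis where the viewport spans the full periodic box, label
connectivity wraps across the seam so a disk straddling it remains one
component; a cropped axis is never wrapped.  No minimum-size filter is
applied by default (normalized counts start at 1 when all cells are
separated, consistent with the experimental curves), but a `min_area`
filter is available.

Per frame we report the component count, the count normalized by $N_0$,
and the mean component area (px² and µm²).  `frame_circularity()`
additionally reports $4\pi A/P^2$ per aggregate of at least `min_cells`
cells, with the perimeter estimated from exposed 4-neighbor pixel edges —
a biased but consistent estimator, used only for the on/off compaction
contrast where the bias cancels.

Mean squared displacement uses unwrapped tracks (cumulative minimal-image
displacements) with time-origin averaging; the diffusion coefficient is
the through-origin slope over the first half of the available lags,
divided by 4.  For the model's uniform random walk the closed form is
$MSD(t) = a_0^2 t$, so $D = a_0^2/4$ per minute — recovered within 5% in
the tests.

## Calibration workflow

Experiments are matched by (i) fixing $d$ and $\alpha_{max}$ per cell
line, (ii) reading $N_0$ off the first frame, and (iii) grid-searching
$a_0$ (which controls the count decay), $\kappa$ (which controls late-time
area growth) and the flux setting.  The package formalizes the original
visual matching as a weighted SSE
$w_n \sum \Delta n_{norm}^2 + w_a \sum (\Delta A / A_{ref}(0))^2$
with simulated curves interpolated onto the reference grid; each grid
point is scored with $R$ replicate runs sharing seeds across grid points
(common random numbers).  Ties break toward smaller $a_0$, then smaller
$\kappa$, then flux off.

`make_synthetic_reference()` generates reference curves from known
parameters (replicate means, optional multiplicative noise), enabling
parameter-recovery studies without the original experimental tables,
which were published only as figures.  The recovery suites use scales
chosen from signal-to-noise probes: step-length recovery at $N_0 = 100$
in a 300 um box over 240 min; $\kappa$ recovery at $N_0 = 150$ over the
full 720 min (late-time area carries the signal) with a grid spaced by
factors of 4, so recovery to within a factor of 2 is a discriminating
check; the
compaction contrast at the density of ~2000 cells per calibrated field,
transplanted into a 300 um box for throughput.  Replicate counts default
to 20 (the plotting convention of the original study) but are reduced in
the recovery tests.

## What the synthetic data does and does not emulate

The generator reproduces the *model's* study conditions: random uniform
seeding, the five interaction rules, the experimental viewport and
measurement chain, and triplicate-style replicate averaging.  It does not
emulate segmentation noise of real micrographs, uneven illumination,
cell-size dispersion, polarization or shape change, aggregate
fragmentation, or genuine 3D mechanics ($\alpha_{max}$ is an effective 2D
proxy).  Passing recovery tests therefore demonstrates that the inference
workflow is self-consistent at realistic densities and horizons — not
that the model is identifiable against arbitrary experimental data.

## Known limitations

* The rasterized aggregate count can transiently increase by one when a
  marginal contact (center distance near $d$) contributes no shared
  foreground pixel; the graph-based cluster count is exactly
  non-increasing without proliferation and is the quantity used for that
  invariant.
* Constant-kernel and monomer-only rates use slightly different
  conventions (total-equation vs spectrum-equation), inherited from the
  closed form used for fitting; `coagulation_rhs` documents the factor.
* The engine's collective move truncates against non-members as a whole;
  simultaneous multi-aggregate collisions within one iteration resolve in
  aggregate order (smallest member index first), which is reproducible
  but arbitrary.
* At very high density (hard-core area fraction beyond ~0.6) the
  rejection-sampling initializer fails before jamming is reached.

## A worked example

```{r example, eval = FALSE}
cfg <- abm_preset("F98-nonadhesive")   # a0 = 6 px, N0 = 784, flux on
traj <- run_abm(cfg, seed = 1, stride = 60)
ts <- aggregate_timeseries(traj)
plot(ts, which = "count")

fit <- smol_fit(data.frame(time = ts$time_min, count = ts$n_aggregates),
                kernel = "auto")
summary(fit)
```
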