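---
title: "Models and methods: accuracy-persistence constraints in single-cell chemotaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: accuracy-persistence constraints in single-cell chemotaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemocrescent)
```

# The scientific problem

A cell migrating up a chemoattractant gradient can be scored along three
largely independent axes: **accuracy** (does it move in the gradient
direction?), **persistence** (does it move in a straight line, in any
direction?) and **speed**. `chemocrescent` implements the quantitative
machinery for asking whether these performance measures constrain one
another: trajectory metrics for time-lapse tracking data, a cellular Potts
model (CPM) of a single chemotaxing cell, a biased persistent random walk
(BPRW) theory whose attainable accuracy-persistence region is a bounded
"crescent", a model of the chemical environment, and a synthetic-cohort
generator with known ground truth.

# Trajectory metrics

A trajectory is an ordered series of 2-D centroid positions at a uniform
recording interval $\Delta t$ (default 15 min over 9 h, i.e. $M = 36$
steps). The metrics are:

* **Chemotactic index**: $\mathrm{CI} = \cos\theta$, where $\theta$ is
  the angle between the net displacement and the gradient axis. One value
  per cell; bounded in $[-1, 1]$; cohort accuracy is the average (or
  median) over cells. A per-step variant (`method = "step"`) is provided
  but non-default, matching the one-point-per-cell distributions used in
  box plots.
* **Directional persistence**: $\mathrm{DP} =$ net displacement / path
  length, in $(0, 1]$; gradient-independent.
* **Mean speed**: per-interval distance over $\Delta t$, averaged,
  reported in µm/h.
* **Directional autocorrelation time**:
  $\tau_{AC} = \int_0^{\infty} \langle\cos(\theta_{t+t'} - \theta_t)\rangle\,dt'$
  over step directions. Finite tracks force truncation: we integrate by
  the trapezoidal rule up to `max_lag` (default half the step count).
  The lag-0 value is 1 by definition; zero-length steps carry no
  direction and are skipped in all angle-based quantities.

**Stationary-cell filter.** Cells that never move farther than one cell
diameter from their start are excluded from cohort statistics. The
default diameter, 20 µm, is the side of a square with the relaxed cell
area $A_0 = 400\ \mu m^2$; both the threshold and its interpretation
(maximum displacement from the starting point) are configurable and
documented because tracking studies vary on this point.

**Cohort statistics.** Group comparisons use the two-sided Mann-Whitney
U test (metric distributions are not normal; the CI is a cosine), exact
for small tie-free samples and normal-approximated with tie correction
otherwise. Replicated conditions are summarised as the mean of
per-replicate medians ± SEM over replicates.

# The cellular Potts model

The cell is a simply connected set of sites on a square lattice
(spacing $\ell = 2\ \mu m$), evolving by Metropolis-style label-copy
attempts against the energy

$$u = \alpha L + \lambda (A - A_0)^2,$$

with $L$ the cell-medium boundary length (4-adjacency edge count times
$\ell$) and $A$ the area. An attempt changing the energy by $\Delta u$
and the centre of mass by $\Delta\vec{x}$ is accepted with probability
$e^{-(\Delta u - w)}$ if $\Delta u - w > 0$ and 1 otherwise, where
$w = \Delta\vec{x}\cdot\vec{p}$ biases motion along the polarization
vector $\vec{p}$. One update step lasts $\tau$ and comprises $S$
attempts ($S$ = domain site count). After each step the polarization is
updated:

$$\vec p \leftarrow \vec p + r\tau\,(-\vec p + \eta\,\hat{\Delta x}_\tau + \epsilon\,\vec q),$$

an exponential decay at rate $r$ plus alignment with the last interval's
displacement direction (strength $\eta$; skipped if the displacement is
zero) and with the sensing vector $\vec q$ (strength $\epsilon$).
$r\tau \le 1$ is required; the default $r\tau = 1$ resets the memory
fully each step.

**Stochastic sensing with receptor saturation.** Each site detects
$n_i = \min(\mathrm{receptors}_i, \mathrm{ligand}_i)$ molecules, both
Poisson: receptors with mean $N$/site-count, ligand with mean
$(c + g x_i)\ell^3$ converted at 1 nM = 0.602 molecules/µm³, $x_i$
measured from the domain centre where the background $c$ applies
(negative concentrations are clamped to zero). The sensing vector
$\vec q = \langle (n_i - \bar n)\,\hat r_i\rangle$ averages
count-weighted unit vectors from the centre of mass; the subtraction of
$\bar n$ makes the readout adaptive, and the $\min$ destroys positional
information wherever ligand outnumbers receptors — the mechanism that
saturates accuracy at strong gradients.

**Default parameters.** 9 h runs recorded every 15 min; $c = 2.5$ nM,
$g = 5$ nM/mm; $A_0 = 400\ \mu m^2$, $\ell = 2\ \mu m$ (100 sites/cell);
$\alpha = 2\ \mu m^{-1}$ (of order $\ell^{-1}$, the crossover between a
fragmenting and an immobile cell); $\lambda = 0.01\ \mu m^{-4}$ (area
fluctuations $\lambda^{-1/2}/A_0 = 2.5\%$); $\tau = 100$ s (far above
the ~0.4 s site-diffusion time at $D \sim 10\ \mu m^2/s$, below
$\Delta t$); $N = 10{,}000$ receptors; $\epsilon = 56$, $\eta = 107$;
$r = 0.01\ s^{-1}$.

## Design choices in the CPM

* **Connectivity.** Copy attempts and perimeter counting use the
  4-neighbourhood (an 8-neighbourhood attempt kernel is available behind
  the `neighborhood` flag). Simple connectivity is enforced by accepting
  only flips of digitally *simple* points under the standard (4, 8)
  connectivity pair (cell 4-connected, medium 8-connected), decided by a
  precomputed 256-entry neighbourhood table. This is the exact local
  criterion for preserving the topology of both phases under single-site
  flips, so no global flood-fill is needed at run time; the tests verify
  connectivity and hole-freeness independently by flood fill.
* **Domain and boundaries.** The lattice default is 100×100 sites with
  the cell at the centre and a hard error if the cell comes within 5
  sites of an edge — boundary effects are refused rather than
  approximated. Realistic 9-h trajectories cover up to ~350 µm of path,
  so dose-response runs in this package use 400×400-site domains
  (±400 µm); with the event engine (below) the domain size has no
  bearing on run time.
* **Execution engines.** Only attempts that pick a cell-medium boundary
  edge can change the state, and between two such attempts the crossing
  probability $2E/(n_{\mathrm{neigh}} W H)$ is constant. The default
  `"event"` engine therefore draws the geometric number of intervening
  no-ops and jumps straight to the next effective attempt, maintaining
  the boundary-edge list incrementally; the `"exhaustive"` engine runs
  the literal attempt loop. The two sample the same process exactly (a
  statistical-equivalence test is included); the event engine's cost
  scales with the cell boundary rather than the domain.
* **Sensing schedule.** $\vec q$ is resampled once per $\tau$ with fresh
  independent Poisson draws; $\tau \gg \ell^2/D$ justifies treating
  successive draws as independent.
* **Units.** $u$, $w$ and $\vec p$ are treated as dimensionless, with
  $\alpha$ in µm⁻¹ and $\Delta \vec x$ in µm; $\epsilon$ and $\eta$ are
  pure calibration numbers scaling the dimensionless $\vec q$ and
  $\hat{\Delta x}$ into $\vec p$'s units.
* **Seeds.** Trial $i$ of a run with master seed $s$ reseeds R's RNG
  with $(s + 9973 i) \bmod (2^{31}-1)$, so any trial is independently
  reproducible.

## The gradient dose-response and the coupled background

In the source-sink microfluidic device the attractant enters at one side
and is absorbed at the other, so the concentration at the channel middle
is tied to the gradient: $c = gL/2$ for a channel of width $L = 1$ mm.
The reference condition $g = 5$ nM/mm, $c = 2.5$ nM obeys this relation.
`cpm_gradient_series()` therefore sweeps $g$ with the coupled background
(the $g = 0$ control has essentially no attractant anywhere, as in the
assay). The coupling matters physically: at $g = 50$ nM/mm it puts the
cell at $c = 25$ nM ≈ 120 ligand molecules per site against ~100
receptors per site, so receptor saturation is active and the accuracy
plateaus between $g = 5$ and 50 — and collapses at ten times the largest
gradient. Sweeping $g$ at fixed $c = 2.5$ nM would keep the ligand far
below receptor numbers everywhere the cell can reach in 9 h and the
accuracy would keep rising instead.

## Known deviations at the defaults

* The stationary mean area sits a few sites *below* $A_0$ (measured
  ≈ 388 µm² vs 400): the perimeter term penalises larger cells while
  lattice-shape entropy pushes the other way. The area is pinned within
  the fluctuation scale $\lambda^{-1/2}$, which is what the tests
  assert; the acceptance rule itself is tested exactly against Boltzmann
  statistics on a pure-area caricature.
* With the memory time lengthened to $r^{-1} = 10\tau$, baseline
  persistence at $g = 0$ rises to DP ≈ 0.85 (the polarization vector
  averages its alignment noise over ~10 steps). The expected
  *increase* of DP with gradient strength under long memory is then not
  resolved at these parameters: the bias-induced persistence adds only
  ~0.01 at $g = 5$, and at $g = 50$ the receptor-saturated sensing noise
  lowers DP (≈ 0.77). The corresponding acceptance assertion is left
  failing rather than recalibrated; reducing $\eta$ does produce the
  increasing-DP regime but at speeds below the observed 10–100 µm/h.

# The biased persistent random walk

The BPRW reduces the cell to a point taking $M$ steps with exponential
(mean 1) lengths. The step-angle density relative to the gradient is

$$P(\theta\,|\,\theta') = b\cos\theta + \frac{e^{p\cos(\theta-\theta')}}{2\pi I_0(p)},$$

a gradient-aligned bias (strength $b$; integrates to zero, so it only
reshapes the distribution) plus a von Mises persistence term (strength
$p$) centred on the previous angle. Non-negativity over all angles
requires $b \le e^{-p} / (2\pi I_0(p))$ (`max_bias()`); at $p = 0$ this
is $(2\pi)^{-1} \approx 0.16$, and the bound is sharp — 1% above it the
density dips negative. The first step of a trajectory has no previous
angle; its persistence term is replaced by the uniform density, making
$b$ the only directional input initially.

Sampling is by rejection against a constant envelope equal to the
density supremum $b + e^p/(2\pi I_0(p))$; all Bessel evaluations use
exponential scaling so large $p$ cannot overflow.

## Closed-form moments and the two stopping rules

The mean squared displacement $\langle r^2\rangle$ and the mean drift
$\langle x\rangle$ are known in closed form in terms of
$\psi = I_1(p)/I_0(p)$, $\chi = \pi b$, $z = \chi/(1-\psi)$ and
$\tilde M = M(1-\psi)$, and `analytic_moments()` evaluates them exactly
as printed. These formulas describe the *velocity-jump* reading of the
walk: unit speed, exponential runs, uniform (bias-free) initial
direction, observed at fixed elapsed time $t = M$ — one can check, for
example, that at $p = 0$ they give $\langle x\rangle = z(M - 1 + e^{-M})$
where the fixed-step walk gives exactly $zM$. The difference is $O(1/M)$
but resolvable at $10^4$ trajectories. `bprw_ensemble()` therefore
offers both stopping rules: `stop = "steps"` (the trajectory contract
used for cohorts and the crescent scan) and `stop = "time"` (the process
the moments describe, used for moment validation).

The accuracy and persistence are approximated from the moments as
$\mathrm{CI} \approx \langle x\rangle/\sqrt{\langle r^2\rangle}$ and
$\mathrm{DP} \approx \sqrt{\langle r^2\rangle}/M$. Because
$\langle r\rangle \le \sqrt{\langle r^2\rangle}$, these slightly
underestimate CI and overestimate DP; the tests assert the inequality on
simulated ensembles.

## The crescent and its bounding curves

Feasible $(b, p)$ pairs map to a restricted crescent-shaped region of
the CI-DP plane, bounded by three analytic curves:

* **bottom**: $\mathrm{CI} = 0$ at $b = 0$;
* **left** (minimal DP at given CI): eliminating $b$ from the $p = 0$
  moments for $M \gg 1$ gives
  $\mathrm{DP} = [1 + M(1 - \mathrm{CI}^2)/2]^{-1/2}$ — at CI = 0 this
  is the simple-random-walk scaling $(M/2)^{-1/2}$;
* **right** (maximal persistence): traced parametrically by setting
  $b = $ `max_bias(p)` and evaluating the moment approximations along
  increasing $p$.

`crescent_scan()` samples pairs ($p$ log-uniform on $[10^{-3}, 20]$, $b$
uniform on $[0, b_{max}(p)]$ — the sampling distribution for the scan is
a documented choice, since only containment and the corner structure are
meaningful), simulates 300 fixed-step trajectories per pair and records
the ensemble CI (mean cosine of net-displacement angles) and mean DP.
Three "forbidden" regions — DP below the finite-$M$ floor, high CI with
near-zero DP, and high DP at intermediate CI — stay empty.

# The chemical environment

`gradient_field()`/`concentration_at()` evaluate the linear profile with
clamping at zero. `ligand_budget()` does the detection-limit
bookkeeping: for $c = 2.5$ nM, $g = 5$ nM/mm and a 10-µm cell it
reports a 0.05 nM difference across the body (2% relative), ~1500
molecules in half the body and a ~30-molecule difference between the
halves — numbers kept as exact floats internally and rounded only when
printed. `diffusion_profile_1d()` solves
$\partial_t c = D\,\partial_x^2 c$ with Dirichlet source/sink boundaries
by explicit finite differences at 40% of the stability bound
$dx^2/(2D)$, reporting profiles and the first time the deviation from
the linear steady state falls below 5% of the range. The default
$D = 90\ \mu m^2/s$ is a Stokes-Einstein estimate for a 2.3-nm tracer at
37 °C; with it a 1-mm channel relaxes in under 3 h, consistent with the
assay's equilibration window — a consistency check, not a fitted value,
since $D$ is configurable.

# Synthetic cohorts and parameter recovery

`generate_cohort()` emulates an assay cohort: by default 40 cells, 36
steps at 15 min, mean step 7.5 µm (≈ 30 µm/h — "tens of µm/h"), 25%
stationary cells and 0.5 µm additive centroid noise (sub-pixel error
scale). Motile cells are BPRW tracks scaled *after* angle generation, so
speed is decoupled from $(b, p)$; stationary cells are jitter inside a
4-µm disc — deliberately not zero motion, so the stationary filter's
threshold behaviour is exercised. Fixed seeds give bit-identical CSVs;
ground truth travels with the cohort as an attribute.

`condition_series()` maps a gradient series $g \in \{0, 1, 5, 50\}$
nM/mm to bias values through the saturating curve
$b(g) = b_\infty(1 - e^{-g/g_{1/2}})$ with $b_\infty = 0.03$,
$g_{1/2} = 1.2$ nM/mm and constant $p = 0.3$ — chosen once so that the
median CI rises and saturates between the two largest gradients at
roughly the observed magnitudes (CI ~ 0.2–0.4) while DP stays flat
(sensing decoupled from persistence by construction), and feasible with
margin at all gradients.

`recover_parameters()` inverts the moment approximations: the observed
ensemble (CI, DP) is matched to `ci_dp_approx()` by squared-distance
minimisation over the feasible region (25×25 grid on the transformed
coordinates, then Nelder-Mead). Cohorts far outside the crescent
(residual distance > 0.2) are flagged rather than silently projected.

What the generator does *not* emulate: division events, drift or stage
jitter in the imaging, non-exponential step lengths (the empirical
step-length law of these cells is not published; the BPRW's exponential
assumption is used), and 3-D to 2-D projection. Passing tests on
synthetic cohorts therefore validate the pipeline's internal
consistency, not those aspects of real data.

# Problem sizes and tolerances used in the checks

Monte-Carlo checks compare means within 3 standard errors under fixed
seeds. The moment grid uses 25 feasible $(b, p)$ pairs × $10^4$
trajectories; the crescent scan 500 pairs × 300 trajectories; CPM
dose-response runs 100 trials per condition on 400×400-site domains;
symmetry controls 1000 trials; the diffusion solver is checked against a
200-term Fourier series within 2% and for grid convergence within 1%.
The full test suite runs in about a minute on one CPU; the scale of each
check was chosen to keep Monte-Carlo error well below the effect sizes
being asserted.
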