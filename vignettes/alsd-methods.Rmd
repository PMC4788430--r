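---
title: "Expanded-ensemble lambda dynamics for a tethered polyelectrolyte tail: models, estimators, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alsdyn)
```

## The scientific problem

Histone tails are intrinsically disordered, strongly cationic peptides that
spend most of their time electrostatically adsorbed on nucleosomal DNA.
Plain molecular dynamics cannot sample their conformational ensemble: the
tail–DNA attraction traps any single trajectory in one adsorbed
arrangement.  Expanded-ensemble lambda dynamics solves this by making the
strength of the tail's interactions itself a dynamical variable.  The
potential energy is split into three terms,

$$E = E_\text{tail} + E_\text{tail-rest} + E_\text{rest},$$

and the sampler evolves an extended Hamiltonian

$$H = \lambda^2 E_\text{tail} + \lambda E_\text{tail-rest} + E_\text{rest}
 + K + \tfrac{1}{2} m_\lambda \dot\lambda^2 + RT \ln P(\lambda, T),$$

where $\lambda \in [0.6, 1.03]$ scales the tail's internal energy
quadratically and its coupling to the environment linearly.  When the
umbrella term $RT\ln P(\lambda,T)$ equals the (a priori unknown) canonical
log-probability of $\lambda$, the $\lambda$-marginal of the extended
ensemble is flat and the system random-walks between strong coupling
($\lambda = 1$, physical) and weak coupling ($\lambda = 0.6$, tail
loosened and partially released).  Canonical expectations at $\lambda = 1$
are recovered afterwards by importance reweighting.

This package implements that machinery at desk scale — a coarse-grained
tail-on-scaffold model built in-package — together with the full analysis
suite (SASA/CSA, radius of gyration, contacts, exposure, density grids,
dihedral-based helix content, distance distributions) that applies equally
to the toy ensembles and to all-atom PDB structures.

## The synthetic system: what it emulates and what it does not

`build_tail_scaffold_system()` creates a 40-bead flexible chain — one bead
per residue of an H3 N-terminal tail — carrying +1 charges at the
lysine/arginine-like positions (2, 4, 8, 9, 14, 17, 18, 23, 26, 27, 36,
37, 40; 13 charges in all), tethered by its last bead to a rigid scaffold
of two parallel strands of −1 "phosphate" beads laid along an arc with a
3.4 Å axial rise (60 beads, i.e. −2 per base-pair-like position, arc
radius 41.5 Å as in the nucleosomal superhelix).  Interactions are
harmonic bonds (k = 10 kcal/mol/Å², rest length 3.8 Å), WCA excluded
volume (ε = 0.2 kcal/mol, contact distance the sum of radii: 2.0 Å tail,
2.5 Å scaffold), and Debye–Hückel screened Coulomb electrostatics with
ε_r = 80 and ionic strength 0.153 M (the physiological salt condition;
κ⁻¹ ≈ 7.9 Å), cut at four Debye lengths with an energy shift.  Units
throughout: Å, kcal/mol, K, elementary charges.

The model reproduces the *mechanism* under study — a polycationic tethered
chain electrostatically trapped on a polyanionic scaffold, with a
charge-neutralizing "acetylation" perturbation
(`apply_acetylation()`) — and the *machinery* (every estimator sees the
same data structures an all-atom pipeline would produce).  It does not
reproduce atomistic nucleosome physics: no explicit water or ions, no
base-pair geometry, no secondary-structure propensity, no
microsecond-scale convergence.  Absolute observable values from the toy
(CSA of a few hundred Å², Rg of ~15 Å) are therefore *not* comparable to
all-atom reference values, and no test asserts that they are.  What a
green run establishes is: the sampler is correct against closed forms,
the reweighting is consistent with direct canonical simulation, and the
charge-neutralization effect has the expected *direction* (lower tail–DNA
contact area, more compact tail).

The mobile-bead mass and the time unit are reduced (mass 1); only
equilibrium ensembles are targeted, so this is a choice of parametrization,
not an approximation.

## Sampler numerics

**Integrator.** BAOAB splitting — deterministic half-kicks and drifts
around an exact Ornstein–Uhlenbeck friction/noise update — applied jointly
to the mobile beads and to $\lambda$.  All randomness comes from R's
seeded RNG stream, so every run is bit-reproducible.  The default
timestep is 0.01 reduced time units (0.02 suffices for the stiffest test
systems).  `m_lambda` defaults to 1, giving $\lambda$ a thermal speed
$\sqrt{RT/m_\lambda} \approx 0.77$ per time unit — it would sweep the
0.43-wide range ballistically in roughly 50–60 timesteps, comfortably
slower than the bead vibrations and much faster than the conformational
modes it must average over.

**Friction.** Default 0.1 (weak coupling).  The sampled ensemble is
friction-independent, but the slowest mode of the toy — global chain
rearrangement — relaxes on a timescale proportional to the friction, and
$\lambda$ round-trip mixing is rate-limited by that mode.  Weak coupling
buys roughly an order of magnitude in effective samples per step over
$\gamma = 1$.

**$\lambda$ walls.** Half-harmonic restraints (k = 1000 kcal/mol per unit
$\lambda^2$) outside $[0.6, 1.03]$ rather than reflective boundaries: a
smooth restraint is differentiable, testable by finite differences, and
leaves the in-range density exactly canonical.  For the same reason the
$\lambda$ histogram only counts in-range samples — clamping wall
excursions into the edge bins would systematically inflate them.

**Bias representation.** $\ln P(\lambda)$ is tabulated on 30 knots at the
histogram bin centers and interpolated with a monotone cubic
(Fritsch–Carlson) spline — value and first derivative continuous, with
O(h²) three-point endpoint slopes (the one-sided secant endpoint was
measurably too crude: the profile's slope reaches ≈ 40 kT per unit
$\lambda$, and the resulting edge error showed up directly as edge-bin
occupancy excess).  Outside the knot range the spline continues linearly,
so the bias force is defined throughout the wall region.

**Bias adaptation.** Each iteration runs the sampler under the current
bias, bins $\lambda$, and accumulates the binned free-energy derivative
$\langle 2\lambda E_\text{tail} + E_\text{tail-rest} \mid \lambda\rangle$
— conditional thermodynamic integration.  Because the umbrella bias
depends on $\lambda$ alone, the coordinate distribution *conditional on
$\lambda$* is canonical at that $\lambda$ under any bias, so these binned
means estimate $F'(\lambda)$ without bias-dependent corrections;
trapezoid integration and division by $-RT$ give $\ln P(\lambda)$ up to
its irrelevant constant, which becomes the next iteration's bias.  Three
implementation lessons, each visible as a reproducible failure mode
before its fix, shaped this estimator:

1. *Incremental log-histogram updates oscillate.*  The textbook rule
   (add the smoothed log-histogram each iteration) assumes each
   iteration's histogram is a fair draw of the biased marginal; on the
   toy the chain's configurational state lags $\lambda$, single-iteration
   histograms are systematically tilted, and a full-gain update amplifies
   the tilt.  The derivative estimator pools every sample ever collected
   instead, and carries far less variance per sample than bin occupancy.
2. *Walker independence matters more than trajectory length.*  A single
   trajectory's slow conformational mode (correlation ~50k steps and
   beyond) produces common-mode errors in the pooled derivative that
   decay only as the square root of the number of *independent* slow-mode
   draws.  `adapt_bias(n_walkers = 8)` advances several independent
   walkers (distinct self-avoiding starts, persistent states) under the
   shared bias each iteration — the same trivial-parallelization design
   the production stage uses.
3. *Un-equilibrated starts tilt all walkers the same way.*  Self-avoiding
   regrowths are extended relative to the adsorbed equilibrium, and their
   shared transient enters every walker's early samples with the same
   sign.  A per-walker burn-in at $\lambda = 1$ (`n_equil`) before any
   sample is pooled removes the common-mode transient.

A schedule of short exploration iterations followed by long refinement
iterations is exposed via `steps_per_iteration`.

**Flatness.** The diagnostic is min/max over the 30 bins of an iteration's
own histogram; adaptation stops early when it exceeds the threshold
(default 0.7).  Note that at desk-scale iteration lengths this statistic
is noise-dominated well before the bias error is: a perfect bias with ~40
$\lambda$ round trips per iteration still yields flatness ≈ 0.5.  The
acceptance criterion applies the 0.7 bar to a long *production* histogram,
where the noise floor is low enough for the bar to measure bias quality.

## Closed-form anchors

The one-bead harmonic system (`harmonic_test_system()`) has
$E_\text{tail} = \frac{1}{2} k x^2$ in one dimension, giving three exact
results used throughout the tests:

* canonical $\lambda$-marginal $\propto 1/\lambda$, hence converged bias
  $\ln P(\lambda) = -\ln\lambda + \text{const}$;
* equipartition $\langle x^2 \rangle = RT/k$ at fixed $\lambda = 1$;
* reweighted $\langle x^2 \rangle = RT/k$ from the full expanded ensemble.

With `lambda_min == lambda_max == 1` the $\lambda$ dynamics is disabled
entirely and the sampler must reproduce plain canonical Langevin MD; the
test suite checks this against an independently coded pure-R BAOAB
integrator.

## Reweighting

Per frame, $\ln w = -\beta[(1-\lambda^2)E_\text{tail} +
(1-\lambda)E_\text{tail-rest}] + \ln P(\lambda)$, normalized within each
run by log-sum-exp; the Kish effective sample size is reported.  Weights
are normalized per run and runs are only ever combined through run-level
means with the standard error across runs (the TTP contract) — frames are
never pooled for an estimate, only for purely descriptive histograms.  All
frames contribute regardless of $\lambda$ (an optional `lambda_window`
exists for sensitivity analysis); the binding correctness contract is the
canonical-MD oracle, not a particular window choice.  Reweighting refuses
to run if the bias content hash does not match the trajectory metadata —
silent misweighting with a retuned bias is the classic failure mode of
this scheme.

## Analysis conventions

* **SASA** is Shrake–Rupley with a deterministic golden-spiral point set
  (default 960 points; 3840 in validation), probe 1.4 Å, and the radii
  C 1.70 / N 1.625 / O 1.48 / P 1.87 Å; hydrogens are excluded before the
  computation so they neither receive nor occlude area.  S 1.8 Å is
  included so that arbitrary protein structures do not error; it is a
  package choice, not a reference value.
* **CSA** is the SASA of the DNA selection computed without the tail
  minus with the tail present, everything else held fixed.  For deposited
  structures both context conventions are available (`context = "all"`:
  the histone core occludes in both evaluations; `context = "pair"`: only
  the two selections exist), because printed reference values rarely state
  the convention; validation code reports both.
* **Helix content** uses a dihedral-window stand-in for hydrogen-bond
  based assignment: a residue is helical when $(\phi, \psi) \in
  [-100°, -30°] \times [-80°, -5°]$ *and* it sits in a run of ≥ 4
  consecutive in-window residues.  The window and run rule are validated
  on ideal constructed geometries (`build_backbone()`); the stand-in
  reports a single helical class and will not reproduce a DSSP
  assignment residue-for-residue on real structures.
* **Contact definitions.** Terminal-atom DNA contact: buried-against-DNA
  area > 0.1 Å² (the discretization noise floor at 960 points).
  Per-position contact: center distance ≤ sum of radii + 2.8 Å (one water
  diameter).  Both thresholds are config values recorded in every output
  header.
* **Density grids** default to 2.0 Å voxels for the coarse-grained system
  (1.0 Å is appropriate at all-atom resolution); difference grids
  normalize each input to unit total first, so the difference sums to
  zero by construction.

## Initial conformations and TTP

Published enhanced-sampling studies of histone tails launch their
independent runs from distinct initial conformations without a canonical
generation recipe; here they are
self-avoiding random regrowths of the tail from its anchor (minimum
separation 0.95 of contact distance, bounded retries), which is simple,
seedable, and guarantees bonded geometry within tolerance.  Run seeds
derive deterministically from `(base_seed, run_index)` and are recorded in
the trajectory metadata together with the config and bias hashes.

## Known limitations

* The charge-neutralization effects in the toy are small relative to its
  conformational noise (a few percent of CSA, ~2% of Rg), and the slow
  adsorption mode decorrelates over tens of thousands of steps, so
  detecting both effects at multi-sigma significance requires hours of
  sampling.  The packaged directional test asserts the full significance
  bar and is expected to stay red at desk-scale budgets; the directions
  themselves reproduce.

* The adaptive bias needs several million steps on the 100-bead toy to
  reach production-histogram flatness ≥ 0.7; the acceptance test budgets
  exactly that.  Harder electrostatics (lower salt, lower dielectric)
  would need correspondingly more.
* The toy's absolute observables have no quantitative correspondence to
  all-atom values; only directions and machinery are transferable.
* The PDB reader handles ATOM/HETATM/MODEL/TER records only (no mmCIF,
  no altloc resolution beyond keeping all locations).
* `helix_content` requires complete N/CA/C backbones; missing atoms yield
  per-residue missing flags, not interpolation.
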