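---
title: "Free energies from steered pulling ensembles: model and methods"
author: "steeredFE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free energies from steered pulling ensembles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steeredFE)
```

## The scientific question

When a purine riboswitch binds its ligand, the ligand stacks directly on
the innermost base pair of the terminal P1 helix (A9-U63 in the adenine
aptamer) and is thought to stabilize it, tipping the balance toward helix
formation and hence toward one of two mutually exclusive folds of the
downstream expression platform.  The quantity of interest is the
free-energy difference between the *paired* (bound) and *open* (unbound)
states of that single base pair, measured once without the ligand (apo)
and once with it (holo).  Their difference,

$$\Delta\Delta F \;=\; \Delta F^{\mathrm{apo}}_{\mathrm{breaking}} -
\Delta F^{\mathrm{holo}}_{\mathrm{breaking}},$$

is the ligand-induced stabilization: a negative value means the ligand
favors the paired state.

In the simulation experiment this package re-implements analytically, the
pair is ruptured by *steered* dynamics: a stiff harmonic restraint on a
separation-like collective variable (CV) is dragged at constant velocity,
and the mechanical work of many independent repetitions is turned into
equilibrium free energies.  `steeredFE` provides every analysis stage of
that workflow, plus a one-dimensional Langevin simulator with an exactly
solvable ground truth so the whole pipeline can be validated end to end,
and a nearest-neighbor duplex module for the secondary-structure
counterpart of the same comparison.

## Work, the Jarzynski equality, and reweighting

Each replica evolves under the time-dependent potential
$U(x) + V(x, \lambda_t)$ with $V(x,\lambda) = \tfrac{k}{2}(x-\lambda)^2$
and $\lambda_t = \lambda_0 + v t$.  Work is accumulated by the
potential-difference convention

$$W_{t+1} = W_t + V(x_t, \lambda_{t+1}) - V(x_t, \lambda_t),$$

which is the discrete-time convention under which the Jarzynski identity
$\langle e^{-\beta W_t}\rangle = e^{-\beta \Delta F_t}$ holds exactly for
a Boltzmann-preserving propagator (the force-times-displacement
convention does not share this property, and is not used).
`jarzynskiProfile()` evaluates the per-slice exponential average with a
log-sum-exp scheme, so $|\beta W|$ up to $10^4$ cannot overflow, and by
Jensen's inequality the profile never exceeds the mean-work profile — a
property the test suite asserts on every simulated ensemble.

The profile along the schedule is not yet the quantity of interest: the
bound/unbound partition is defined by an *a-posteriori* CV (the discrete
hydrogen-bond count), not by the steered CV.  `frameWeights()` therefore
assigns every recorded frame an unbiased statistical weight by combining
the per-slice Jarzynski free energies $f_{t}$ with weighted-histogram
(umbrella-sampling) pooling over all restraint positions:

$$w_{t,i} \;\propto\;
\frac{e^{-\beta (W_{t,i} - f_t)}}
     {\sum_{t'} N\, e^{-\beta\left(V(q_{t,i},\lambda_{t'}) - f_{t'}\right)}}.$$

The numerator factor $e^{+\beta f_t}$ deserves a note.  The per-slice
identity behind the scheme is
$\langle\delta(x-x_t)\,e^{-\beta W_t}\rangle = e^{-\beta(U(x)+V_t(x))}/Z_0$:
each slice's work-weighted histogram must be normalized by
$\langle e^{-\beta W_t}\rangle = e^{-\beta f_t}$ *before* the slices are
pooled, otherwise the pooled density is biased by an $x$-dependent factor
$\sum_t e^{-\beta V_t(x)} / \sum_t e^{-\beta(V_t(x)-f_t)}$ (on the
packaged landscapes the omission roughly doubles the estimated
$\Delta F$).  With one time slice and zero works the weights reduce
exactly to standard umbrella unbiasing $w_i \propto e^{+\beta V(q_i)}$,
which the tests check to $10^{-10}$.

The slice free energies are taken from the Jarzynski estimates directly;
no self-consistent iteration is performed (that is the structure of the
combined Jarzynski + WHAM scheme, and iterating would reintroduce the
very coupling the identity avoids).  A `stride` argument can decimate the
denominator slices for speed; all tests and packaged analyses run at
stride 1.

Summing weights over frame partitions gives populations:
`projectFreeEnergy()` bins frames by any per-frame CV (empty bins are
reported as `NA`, never interpolated), and `stateDeltaF()` computes

$$\Delta F_{\mathrm{breaking}} = -k_BT\,
\ln\frac{\sum_{\mathrm{unbound}} w}{\sum_{\mathrm{bound}} w},$$

with `formation` defined as its exact negative.  `deltaDeltaF()` forms
apo − holo and combines standard errors in quadrature,
$\sqrt{se_a^2 + se_h^2}$ (the combination rule for the published
difference error is not otherwise specified; quadrature is this package's
documented choice for independent systems).

## Uncertainty and diagnostics

Frames within a trajectory are strongly correlated, so the exchangeable
unit is the whole trajectory: `bootstrapDeltaF()` draws B (default 200)
resamples of the N trajectories with replacement, reruns the entire
weights-and-partition pipeline per resample, and reports the standard
deviation of the resample distribution.  The point estimate is always the
full-sample value.  Resamples that leave a state empty are dropped and
counted; more than 20% failures aborts the estimate.  Frame-level or
block bootstrap variants are deliberately not offered.

Exponential work averages fail in a characteristic way: a few low-work
realizations capture most of the weight.  `weightConcentration()`
aggregates the normalized weights per trajectory and reports the Kish
effective sample size $(\sum_i w_i)^2/\sum_i w_i^2$ and the largest
single-trajectory share, warning above 0.5.  `convergenceReport()` flags
an estimate converged when the bootstrap error is at or below the thermal
energy $k_BT$, the trajectory ESS is at least 10, and no trajectory
carries more than half the weight.  The thresholds are heuristics chosen
here; the $k_BT$ criterion mirrors the convergence language customary for
work-based estimates.

## The toy system and its calibration

The simulator replaces the all-atom system with an overdamped Langevin
particle on a bounded 1-D coordinate (nm), with reflecting walls,
integrated by Euler–Maruyama:

$$x \leftarrow x - \beta D\, \partial_x (U + V)\, \mathrm{d}t +
\sqrt{2 D\, \mathrm{d}t}\;\eta.$$

The landscape is a sum of smoothed-rectangular (or Gaussian) wells: a
bound basin around the paired geometry and an unbound basin past the
rupture point, with two thresholds (defaults 0.12 and 0.25 nm) mapping
position to a hydrogen-bond count of 2, 1 or 0, so that the pulled range
ends fully unbound at 0.35 nm.  The protocol defaults are dimensionally
faithful to the reference steered-MD experiment: spring constant
$3.9\times10^4$ (kJ/mol)/nm², pull from 0 to 0.35 nm at 0.175 nm/ns,
300 K, 512 replicas started from independent draws of the
$\lambda_0$-restrained Boltzmann density (rejection sampling; independent
draws replace equidistant extraction from an equilibrium run and keep the
bootstrap's independence assumption exact).

Numerical parameters that matter:

* **Time step** dt = 0.01 ps.  **Diffusion coefficient** D = $10^{-3}$
  nm²/ps.  The stability of the explicit update for the stiffly
  restrained coordinate requires $\beta k D\,\mathrm{d}t < 2$; the
  defaults give $\approx 0.16$, comfortably stable with a small
  discretization bias.  Raising D at this dt makes the update unstable
  outright; lowering it increases friction $\gamma = k_BT/D$ and hence
  dissipated work ($\bar W_{\mathrm{diss}} \approx \gamma v^2 T$), which
  we observed degrades the finite-N estimates far more than the smaller
  step bias helps.
* **Force evaluation** inside the integrator uses a 32768-node linear
  interpolation table (interpolation error ~$10^{-5}$ of the well depth);
  the quadrature oracle always evaluates the analytic potential.
* **Recording stride.** Work is accumulated at every step; frames are
  recorded every `recordEvery` steps (~200 frames per replica by
  default).  The recorded slice spacing (~0.0017 nm) is much finer than
  the restraint width $\sqrt{k_BT/k} \approx 0.008$ nm, so the pooled
  frames tile the pulled range densely.
* **RNG.**  Each trajectory runs its own counter-based generator
  (xoshiro256++ seeded from the replica seed), so a (landscape, protocol,
  seed) triple yields a bitwise-identical trajectory regardless of R's
  RNG state; replica $i$ of an ensemble uses `baseSeed + i`.

The ground truth is exact: `quadratureDeltaF()` integrates
$e^{-\beta U}$ over the bound ($n \ge 1$) and unbound ($n = 0$) regions
by adaptive quadrature, and `calibrateDepth()` root-finds the bound-well
depth until that oracle hits a requested $\Delta F$ to within
$10^{-3}$ kJ/mol.  The packaged experiment calibrates the apo-like system
to $-2.5$ kJ/mol and the holo-like system to $+1.9$ kJ/mol — the
published per-system values of the reference analysis — so the pipeline's
task is to *recover known numbers*, which is the only honest test
available at desk scale (the published numbers themselves required about
a microsecond of all-atom MD per system).  The default well depths
(unbound 12 kJ/mol; calibrated bound depths ≈ 9.8 and 14.7 kJ/mol) are
chosen deep enough that the thermally relevant region is covered by the
pulled range; edge softness 0.015 nm keeps the combined potential
monostable under the stiff restraint (well-edge curvature below $k$), so
pulling stays near quasi-static at the packaged speed.

The packaged protocol pulls at 1/8 of the reference speed (16 ns per
replica, $1.6\times10^6$ steps).  At that speed the friction dissipation
is ~0.02 kJ/mol and the two-system experiment (2 × 512 replicas plus two
200-resample bootstraps) completes in a few minutes on one CPU; this is
the problem size used by the acceptance analysis and the heavyweight
test.  Unit tests use faster protocols and smaller ensembles.

What the toy emulates — and what it does not.  It reproduces the
*statistical* structure of the experiment: stiff-spring constant-velocity
pulling, work fluctuation and dissipation, a discrete a-posteriori state
variable imperfectly aligned with the steered CV, outlier-dominated
exponential averages, and trajectory-level resampling.  It does not
emulate the molecular sources of those statistics: there is no geometric
hydrogen-bond criterion (the count is a step function of one coordinate),
no alternative pairing pathways, no orthogonal slow degrees of freedom.
Passing tests therefore validate the estimators, not the force field or
the CV choice of any particular MD study.

## The nearest-neighbor comparison

An independent check on a pulling-derived $\Delta\Delta F$ comes from
duplex thermodynamics: if the bound ligand behaves like one extra AU pair
stacked on the 9-bp P1 stem, the stabilization should match the
nearest-neighbor cost of extending the printed duplex by that pair,

$$\Delta\Delta G^\circ_{37} = \Delta G^\circ_{37}(\text{10-bp}) -
\Delta G^\circ_{37}(\text{9-bp}),$$

in which initiation cancels exactly and, for this sequence, the terminal
AU penalties cancel too, leaving the single added 5'AA3'/3'UU5' stack.
Two Turner-rule parameter tables ship as plain TSVs: `turner1999`
(0.1 kcal/mol precision, as distributed with the Vienna RNA package;
gives $-3.77$ kJ/mol) and `turner2004` (two-decimal Watson-Crick stacks;
gives $-3.89$ kJ/mol).  The default is `turner1999`, the set closest to
the published melting-experiment figure of $-3.7$ kJ/mol; which exact
parameter revision produced that printed value is not recorded, so the
residual 0.1–0.2 kJ/mol spread across candidate sets is documented rather
than resolved, and every result carries its parameter-set name.  Dangling
ends and terminal mismatches are excluded: the comparison is a pure
helix-extension difference.  The duplex model handles only fully paired
duplexes (Watson-Crick + G·U wobble); loops, bulges and partition
functions are out of scope.

## Design choices on open points

* **State pooling.**  Frames with one *or* two hydrogen bonds are pooled
  as "bound" at every time slice; no alternative pooling is implemented.
* **$\Delta\Delta F$ error bar** is the quadrature sum of the two
  independent bootstrap errors.
* **External data.**  COLVAR-dialect files are ingested by header-name
  mapping; ensembles with mismatched time grids are rejected rather than
  aligned, and a missing work column is recomputed at the recorded
  resolution (which differs from step-resolution accumulation only
  through the recording stride).
* **Empty bins / empty states** are reported as undefined (`NA`, or an
  error naming the empty state) — never silently interpolated.

## Limitations

The estimator suite is forward-pulling only (no Crooks/Bennett
bidirectional estimators, matching the reference protocol), free-energy
surfaces are one-dimensional, and the bootstrap assumes independent
replicas — true by construction here, an approximation whenever starting
points are extracted from one correlated equilibrium run.  Calibrated
recovery on the toy landscape bounds estimator error, not model error:
agreement of the packaged experiment with its targets says nothing about
force fields, sampling of orthogonal coordinates, or the realism of any
particular CV.
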