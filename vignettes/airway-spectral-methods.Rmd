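---
title: "Spectral analysis of resistive airway trees: models, parameters, and numerical choices"
author: "AirwaySpectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral analysis of resistive airway trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AirwaySpectra)
```

## The model

Gas flow in the conducting airways is modelled as laminar flow on a rooted
tree network: nodes are airway junctions, branches are airways, and each
branch $e_j$ carries a resistance $r_j$ so that the branch flux obeys the
linear resistance relation $q = \mathrm{diag}(r)^{-1} N^T P$, where $N$ is
the signed node–branch incidence matrix and $P$ the node pressures. Flow
enters at the root (the trachea) and leaves through the terminal nodes,
each of which feeds an acinus. Applying $N$ gives the conductance
Laplacian $L = N\,\mathrm{diag}(r)^{-1} N^T$; fixing the pressure drops
$\Delta P_{term}$ (relative to the root) reduces the problem to the
internal block $L_{int}\,\Delta P_{int} = B\,\Gamma_{term}\Delta P_{term}$,
which is sparse, symmetric positive definite, and solved by Cholesky
factorization.

The package's central object is the **Maury operator**
$R = T\,\mathrm{diag}(r)\,T^T$, where $T$ maps each branch to the terminal
nodes beneath it. $R$ is a dense symmetric positive-definite
$|T|\times|T|$ matrix acting only on the terminal nodes: entry $(i,i')$ is
the resistance of the shared root path of terminals $i$ and $i'$
(root-to-lowest-common-ancestor resistance), and
$R\,Q_{term} = -\Delta P_{term}$. Its eigenvectors are the resistive
relaxation modes of the tree; each mode behaves as an independent resistor
of resistance $\mu_k$ in parallel. Because every pair of terminals shares
at least the root branch, $R$ is strictly positive, so its top eigenvalue
is simple with a sign-constant (Perron) eigenvector — the lowest-resistance
global flow pattern. Three independent constructions (sparse factors,
explicit shared-path sums, and the inverse of the Laplacian's terminal
response) are implemented and cross-checked in the tests at $10^{-10}$
relative tolerance.

### Ventilation

Each terminal unit is an elastic compartment of elastance $\kappa$ driven
by a shared sinusoidal pleural pressure
$P_{pl}(t) = P_{pl0} + P_s \sin(2\pi t/\tau)$, giving
$R\dot V + \kappa V = -P_{pl}(t)\,e$. In the Maury eigenbasis this
decouples into scalar RC equations with time constants $\mu_k/\kappa$,
yielding a closed-form periodic tidal volume per unit,
$\Delta V_i$, and the ventilation heterogeneity index $\sigma_V$, the
coefficient of variation of $\Delta V$ (population normalization by
default; sample normalization is selectable). Modes with
$\mu_k \ll \kappa\tau$ are compliance-dominated and contribute only the
uniform elastic term, so truncating to the largest-eigenvalue modes —
typically $\le 1\%$ of the spectrum — reproduces $\sigma_V$ from full
simulation; the count of "large" modes ($\mu_k > 0.1\,\kappa\tau$) is
itself a compact heterogeneity marker.

## Parameters and defaults

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| viscosity | 1.93e-5 | Pa s | dynamic viscosity of air |
| Poiseuille prefactor | 8/$\pi$ | — | $r = c\,\mu l/a^4$ |
| $\kappa/|T|$ | 5 | cmH2O/l | total lung elastance |
| $\tau$ | 4 | s | breath period |
| $P_s$ | 1 | cmH2O | pleural pressure amplitude |
| trachea radius | 9 | mm | Weibel generator |
| length-to-diameter | 3 | — | $l = 6a$ for every airway |
| reduction range | [0.50, 0.95] | — | constriction severity |
| distal taper ratio | 1.15 | — | per-order diameter ratio |

Geometry is in mm, pressure in cmH2O, volume in l, time in s; resistances
are converted from SI to cmH2O s/l inside `poiseuilleResistances()`.
$\sigma_V$ is invariant to $P_s$ (linearity) and to $P_{pl0}$ (a volume
offset), so neither needs to match any particular physiological value;
this invariance is asserted in the tests.

Two conventions deserve explicit note:

* **Poiseuille constant.** The physical Poiseuille law
  $r = 8\mu l/(\pi a^4)$ is used (prefactor $8/\pi$, configurable, and
  recorded in the tree metadata). A global constant rescales all
  resistances uniformly and therefore changes no eigenvector, no mode
  ranking, no mode count at fixed $\mu/(\kappa\tau)$ scaling, and no
  $\sigma_V$ trend.
* **Constriction semantics.** "Reducing the radius by a factor between
  50% and 95%" is implemented as $a \to a(1-u)$, $u \sim U[0.50, 0.95]$,
  i.e. constricted radii are 5–50% of the original (the multiplicative
  alternative is selectable via `mode = "multiply-by"`). Selection uses a
  seeded random permutation, with per-branch severities drawn in
  permutation order, so the constricted sets are *nested* as the fraction
  $f$ grows at a fixed seed. Since $R$ is linear in $r$ with
  positive-semidefinite per-branch increments, nesting makes every
  eigenvalue — and hence the large-mode count — provably nondecreasing
  in $f$.

## Generators: what the synthetic trees emulate

`weibelTree(N, A)` builds the asymmetric dyadic tree in which major and
minor daughters scale radius and length by $((1+A)/2)^{1/3}$ and
$((1-A)/2)^{1/3}$. The cube root keeps each daughter pair's parallel
resistance equal to its parent's resistance and conserves the total airway
volume per generation, independent of $A$ — both are tested, the former
through the exact closed form $R_{eq} = r_{trachea}(N+1)$ for the
root-to-terminal equivalent resistance under equal terminal pressures.
At $A = 0.98$ nearly the whole cross-section goes to one daughter, so one
low-resistance path dominates the flow.

`horsfieldTree()` expands a user-supplied per-order morphometry table
(child orders strictly below the parent; orders at or below the
termination order become terminal) with independent Gaussian noise on
radius and length (sd = 10% or 20% of the mean emulates healthy
variability); draws at or below 5% of the mean are resampled rather than
truncated — resampling keeps the distribution smooth near the floor and
cannot produce nonphysical near-zero airways. The shipped demonstration table (orders 1–10, child
orders $(g-1, g-2)$, 89 terminals from root order 10) is a *synthetic*
fixture: its dimensions follow the classical symmetric taper (9 mm
trachea radius, radius factor $2^{-1/3}$ per order, $l = 6a$) so that the
unconstricted tree is "healthy" — every Maury eigenvalue sits well below
$0.1\,\kappa\tau$ at adult elastance. It is *not* published human
morphometry: the published adult tables (tens of thousands of terminals,
10–25 bifurcations to a terminal) are not redistributable here, so
terminal-count checks run against the recursion's exact combinatorial
oracle ($T(g) = T(g{-}1) + T(g{-}2)$) instead of the published count.

What passing tests on these trees do **not** show: real airway trees have
image-derived branching angles and lobar geometry, gravitationally graded
compliance, nonlinear and inertial resistance, and airway wall compliance.
The generators emulate none of these, so agreement between direct and
reduced-order $\sigma_V$ here demonstrates the internal consistency of
the linear model and the fidelity of its spectral reduction — not
patient-level prediction.

## Numerical choices

* **Sparse paths.** All flow solves factor $L_{int}$ (sparse Cholesky);
  the dense $R$ is only formed below a size cap (4096 terminals).
  Partial Maury spectra apply $v \mapsto T(r \odot T^T v)$ matrix-free
  inside an implicitly restarted Lanczos iteration, so the largest
  (high-resistance) modes never require the dense operator. Eigenpair
  residuals are checked against $10^{-8}$ and solve residuals against
  $10^{-10}$ (relative).
* **Full spectra.** The truncation metrics $\delta_L$, $\delta_R$ need
  every eigenvalue; both are defined as the normalized Frobenius
  distance between the operator's inverse and its truncated spectral
  reconstruction, which by orthonormality reduces to the closed form
  $\sqrt{\sum_{excl}\lambda^{-2}/\sum\lambda^{-2}}$. The tests verify
  the closed form against explicit dense Frobenius evaluations.
* **Degeneracy.** Symmetric trees have degenerate eigenvalues and
  solver-dependent eigenvector bases; every assertion on degenerate
  subspaces uses rotation-invariant quantities (projections, coefficient
  sums), never individual vectors. Mode rankings break ties by
  eigenvalue-descending order under a stable sort, so mode counts are
  deterministic even at exact symmetry.
* **Direct simulation transients.** The periodic regime requires
  $t \gg \mu_1/\kappa$. `simulateDirect()` estimates $\mu_1$ by power
  iteration and integrates $\max(5, \lceil \ln(10^6)\,\mu_1/(\kappa\tau)
  \rceil + 1)$ cycles, reads $\Delta V$ off the final cycle at 200
  samples per cycle, and checks the final cycle against the preceding one
  at $10^{-4}$ relative tolerance.
* **Problem sizes.** The test and reproduction workloads use 9–10
  division Weibel trees (512–1024 terminals), 50 randomized trees of up
  to 64 terminals for the construction-equivalence surface, and the
  89-terminal demonstration tree for constriction sweeps — sizes at which
  every full decomposition is exact and cheap while still exercising the
  matrix-free and sparse code paths used at scale.

## Reconstruction accuracy: a genuinely open definition

The mode-count experiment ("how many Maury modes reach 75% accuracy of
the terminal flux on a 9-division Weibel tree?") depends on what
"accuracy" means, and several readings are defensible.
`minModesForAccuracy()` therefore exposes the metric explicitly:

* `energy` (default): the top-$M$ modes capture a fraction $a$ of the
  squared solution norm, i.e. relative L2 error $\le \sqrt{1-a}$. With
  modes ranked by $|q_k|$ the increments are orthogonal, so this is
  exactly the cumulative share of $\sum_k q_k^2$ — the standard captured-
  energy criterion of model-order reduction.
* `l2`: accuracy read as one minus the relative L2 error
  ($\epsilon \le 1-a$); roughly three times as many modes at mid
  asymmetry.
* `norm`: the reconstruction recovers a fraction $a$ of the solution
  norm ($\epsilon \le \sqrt{1-a^2}$); about half as many.

Under the default, the maximum count over the asymmetry grid
$A \in \{0, 0.1, \ldots, 0.9, 0.95, 0.98\}$ is 11, attained near
$A = 0.3$, with single-mode reconstructions at both extremes — the
characteristic mid-asymmetry peak. The demand peaks in the middle because
at $A = 0$ the uniform boundary condition drives only the Perron mode,
while at extreme $A$ the flow concentrates on a handful of low-resistance
paths; in between, the flux spreads over many comparably weighted modes.

## Known limitations

* Linear, rigid-airway resistance only: no inertial corrections, no
  airway compliance, no dynamic bronchoconstriction. Where airway
  compliance dominates, a fixed resistance operator is the wrong
  description.
* Uniform unit elastance: heterogeneous $\kappa_i$ breaks the modal
  decoupling and is rejected rather than approximated.
* Pressure boundary conditions only (root plus terminals); prescribed
  flow at the mouth is out of scope.
* Sinusoidal driving has a closed form; other profiles go through
  `simulateModalQuadrature()`, which converges to the closed form for
  sinusoidal input after the transient (tested) but needs a quadrature
  resolution appropriate to the profile's bandwidth.
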