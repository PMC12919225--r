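---
title: "Fluctuation-response analysis and design of Markov jump networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluctuation-response analysis and design of Markov jump networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caliberflow)
library(ggplot2)
```

## The model

caliberflow analyzes ergodic continuous-time Markov jump processes on finite
networks: states $n = 1,\dots,V$ connected by reversible transitions with
strictly positive rates $k_{ij}$ (every edge present in both directions, no
self-loops, connected support).  Biophysically these are the kinetic diagrams
of molecular motors, enzymes, pumps and signalling cycles; the package's
question is the *design* question — how every long-time statistic of the flow
(occupancies, traffics, cycle currents, and their fluctuations) responds to
every local rate constant, computed exactly rather than by resimulation.

All rates are dimensionless multiples of a unit-rate reference process, so
"per unit time" always means per unit of that reference timescale.

### The observable basis

Raw trajectory counts — transitions $N_{ij}$ and dwell times $T_i$ — are
asymptotically redundant: dwell times add up to the duration and Kirchhoff's
current law couples the counts.  The package therefore works in a complete,
asymptotically orthogonal basis fixed by a *frame*: a reference state $m$, a
spanning tree, and the fundamental cycles closed by the chords.  The basis
rate observables are

* **edge traffic** $\phi_{ij} = (N_{ij} + N_{ji})/t$, one per undirected
  edge;
* **dwell fraction** $f_n = T_n/t$, one per state except the reference;
* **cycle net flux** $\psi_c$, the net completion rate of each fundamental
  cycle, counted on its chord.

With $E$ undirected edges the basis has dimension $2E$, matching the number
of directed transitions.  Stationary means are written
$\langle x\rangle = (\tau_{ij}, \pi_n, J_c)$.

Conjugate to these observables are the *forces*: the edge force
$\tfrac12\log(k_{ij}k_{ji})$ (the symmetric combination, conjugate to
traffic), the node force $\varepsilon_m - \varepsilon_n$ with
$\varepsilon_i = \sum_j (k_{ij} - 1)$ the excess escape rate, and the cycle
affinity $\tfrac12\log$ of the ratio of forward to reverse rate products
around the cycle.  The scalar $c = \varepsilon_m$ (the *caliber rate*) plays
the role of a log dynamical partition function per unit time: the path
entropy of a long trajectory against the unit-rate reference is
$F\cdot x - c$ up to an $O(1/t)$ boundary term, which
`path_entropy_rate()` exposes and the tests verify on simulated paths.

On the symmetric-vs-ratio ambiguity for the edge force: conjugacy with
traffic requires the *product* form (substituting
$N_{ij} = (\Phi_{ij} + \text{net})/2$ into the path entropy), and the
antisymmetric log-ratio appears only inside cycle affinities.  The choice is
validated numerically against the closed-form two-state response.  The node
force sign (reference minus node) is likewise fixed by the identity
$c = \varepsilon_m$ and validated by the node symmetry audit.  Note that
$\varepsilon_i$ sums $k_{ij} - 1$ per present edge: this is forced by the
requirement that the path entropy vanish identically when all rates equal 1
(the reference process itself), as a unit-rate cycle demonstrates.

### The Jacobian and the response-inverse-matrix relation

The central object is the sparse $2E \times 2E$ Jacobian
$A_{(ij),\beta} = \partial F_\beta / \partial \log k_{ij}$: rows are directed
edges, columns are forces.  Edge columns hold constants $\pm\tfrac12$, cycle
columns hold $\pm\tfrac12$ on the edges the cycle traverses, and only the
node columns carry rates.  Its inverse delivers every steady-state response
exactly:

$$\frac{\partial \langle x_\alpha\rangle}{\partial \log k_{ij}}
  = \pi_i k_{ij}\,[A^{-1}]_{\alpha,(ij)}.$$

Each transition also carries an independent noise source
$\lambda_{ij} = (N_{ij} - k_{ij}T_i)/t$ with asymptotically diagonal
covariance $\pi_i k_{ij}/t$.  Projecting observables onto these orthogonal
axes gives the scaled asymptotic covariances

$$D = A^{-1}\,\mathrm{diag}(\pi_i k_{ij})\,A^{-\mathsf T},
  \qquad D_{\alpha\beta} = \lim_{t\to\infty} t\,\mathrm{Cov}(x_\alpha, x_\beta),$$

which equals the force-susceptibility matrix
$\partial\langle x_\alpha\rangle/\partial F_\beta$ — fluctuation equals
response, with symmetry (reciprocity) and a positive diagonal (monotonic
own-force response).  Both routes are implemented separately
(`covariance_matrix()`, `force_susceptibility()`) and their agreement is a
standing audit.

### Randomness parameter and its decomposition

For a net flux $\psi$ (e.g. the mechanical stepping current of a motor), the
randomness parameter $r = \lim_t t\,\mathrm{Var}(\psi)/\langle\psi\rangle$
is the flux Fano factor: 1 for Poisson stepping, $1/N$ for a cycle of $N$
near-deterministic sequential transitions.  The projection identity gives an
exact per-transition decomposition

$$r = \frac{1}{\langle\psi\rangle}\sum_{i,j}
      \frac{k_{ij}}{\pi_i}
      \left(\frac{\partial\langle\psi\rangle}{\partial k_{ij}}\right)^{\!2},$$

each term non-negative: a transition contributes noise in proportion to the
*square* of its flux sensitivity.  `randomness_decomposition()` returns the
per-edge table (with optional functional-group sums from edge metadata) and
the terms sum to $r$ to machine precision by construction.

### Analytic gradients and design

Because $\partial A^{-1} = -A^{-1}(\partial A)A^{-1}$ and $\partial A$ has a
single nonzero row (the node-force columns of the perturbed edge), the full
gradient of any variance — and hence of $r$ — over all $2E$ rates comes from
a *single* factorization of $A$ (`covariance_gradient()`,
`randomness_gradient()`).  The brute-force alternative, central finite
differences of tilted-generator eigenvalues, recomputes an eigenproblem per
parameter; `benchmark_gradient_scaling()` measures the growing cost ratio on
Theta-shaped substep networks.  `design_step()` is a deliberately minimal
fixed-step projected-gradient primitive (maximize a mean flux or minimize
$r$); line search and full optimization campaigns are out of scope.

### Universal audits

Three identities follow from $A^{-1}A = I$ and hold for every basis
observable on every ergodic network: the node escaping symmetry (weighted
escape-sensitivity difference equals 1 exactly for the node's own occupancy,
else 0), edge reciprocity ($\frac1{\pi_i}\partial_{k_{ij}}\langle x\rangle +
\frac1{\pi_j}\partial_{k_{ji}}\langle x\rangle = 2$ for the edge's own
traffic, else 0), and the cycle symmetry (oriented sensitivity sum equals 2
for the cycle's own flux, else 0).  `symmetry_residuals()` evaluates all of
them; since the left-hand sides reduce to signed sums of $A^{-1}$ entries,
nonzero residuals diagnose implementation bugs rather than physics.

The one-way flux responses obey the kinetic hierarchy
$\pi_i \ge \partial p_{ij}/\partial k_{ij} \ge \partial p_{ji}/\partial
k_{ij} \ge 0$ (population depletion, causality, Le Chatelier-like
compensation), checked pointwise by `bound_hierarchy_check()` and over
ensembles by `ensemble_bound_scatter()`.  One subtlety surfaced by direct
computation: the middle bound saturates only where the net flux is
*insensitive* to the forward rate (topological bridges), not on every
zero-flux edge — perturbing a single rate of a detailed-balanced cycle
creates first-order net flux.  The package flags saturation accordingly.

## A worked example

```{r kinesin}
kin <- kinesin6()
glance(kin)
fr <- build_frame(kin)
mech <- edge_flux_observable(fr, "2", "5")
dec <- randomness_decomposition(kin, fr, mech)
glance(dec)
attr(dec, "group_summary")
```

The six-state kinesin-like fixture (chemical ring + mechanical chord) ships
with illustrative rates only — plausible orders of magnitude, clearly
flagged, replaceable via `kinesin6(rates = ...)` for quantitative work with
fitted rate tables.  Group labels on the edges drive the stacked
decomposition; which transitions belong to which functional group is fixture
metadata, not a claim.

```{r design}
rg <- randomness_gradient(kin, fr, mech)
head(dplyr::arrange(rg, d_r_dlnk), 3)
better <- design_step(kin, fr, "min_randomness", mech, step = 0.05)
attr(better, "objective_delta")
```

## Verification strategy

Every analytic pipeline has at least one independent oracle:

* **spectral** — `tilted_cumulants()` differentiates the dominant eigenvalue
  of the tilted generator ($k_{ij}e^{sw_{ij}}$ off-diagonal) by
  Richardson-extrapolated central differences; its first/second derivatives
  at $s=0$ must match the mean and $D$-predicted variance of any
  jump-representable observable (dwell coordinates have no jump
  representation and are cross-checked by sampling instead);
* **sampling** — a compiled Gillespie kernel (`gillespie_simulate()`,
  `ensemble_statistics()`) with exact dwell accounting; ensemble covariances
  must bracket $D$ within standard errors, and the empirical
  $\lambda$-covariances must be diagonal with weights $\pi_i k_{ij}$;
* **finite differences** — `finite_difference_response()` recomputes any
  mean under $k \to k(1\pm h)$.

`run_full_audit()` composes the whole chain into one pass/fail report.

## Numerical choices

* Stationary distributions come from an LU solve of the balance system with
  one row replaced by normalization (no eigen-iteration); the global-balance
  residual must stay below $10^{-12}$ relative or the network is rejected as
  degenerate.
* $A$ is stored sparse.  Up to dimension 400 the dense inverse is formed
  once (the regime of all audits here); above that, LU factors are kept and
  rows of $A^{-1}$ are pulled by transposed solves.
* The tilt step for spectral cumulants defaults to $5\times10^{-3}$ with
  Richardson extrapolation: the dominant-eigenvalue accuracy (~$10^{-13}$)
  divided by $h^2$ makes much smaller steps roundoff-limited, while
  truncation at this step is $O(h^4) \approx 10^{-9}$.
* `rates_from_forces()` inverts the force map by damped Newton in $\log k$
  (step capped at 2 in log-rate units) starting from the unit-rate
  reference; edge and cycle forces are linear in $\log k$, node forces
  linear in $k$, so the capped iteration converges in practice and the
  round-trip is tested to $10^{-8}$ on random networks.
* Spanning trees are grown breadth-first from the reference with neighbours
  visited in state-list order — a declared deterministic tie-break, since
  any tree gives the same physics (frame-invariance of physical responses is
  tested to $10^{-10}$).  A labelled mechanical edge is kept out of the tree
  when possible so the mechanical flux is itself a cycle coordinate.
* Zero rates are invalid (forces diverge); `regularize()` repairs a raw edge
  table with an explicit $\varepsilon$ and a warning, never silently.

## What the generators emulate — and what they do not

`random_ergodic_network()` draws connected reversible graphs with
log-uniform rates on $[0.1, 10]$ — a generic, moderately stiff ensemble used
for all property tests and the bound-hierarchy scatter.
`theta_motor_network()` replaces the single mechanical hop with an $N$-step
biased lattice walk whose per-hop log rate ratio preserves the original
edge's total affinity, emulating a diffusive mechanical swing for the
scaling benchmark.  None of these claim to reproduce measured kinesin
kinetics: load and [ATP] dependence, fitted rate constants, and velocity
curves require externally fitted rate tables that users must supply.
Passing tests demonstrate the exactness and internal consistency of the
response/fluctuation machinery on such networks — not the biological
accuracy of any default parameter set.

Problem sizes used throughout the test suite (networks of 2–8 states for
property tests, 500-network ensembles at 4 states, Theta networks to
$N = 64$, Gillespie ensembles of 400 trajectories at $t = 2\times10^3$) were
chosen so each check isolates one claim at well-understood precision.

## Known limitations

* Time-homogeneous rates only; no absorbing states, no continuous state
  spaces.
* Asymptotic (long-time) statistics only: no finite-time Fano factors,
  transient responses, or first-passage quantities.
* Cumulants up to order two; no full large-deviation rate functions.
* The benchmark's absolute timings are hardware-dependent; only the
  analytic-vs-brute-force cost *ratio* trend is meaningful.
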