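---
title: "Ensemble alchemical free-energy estimation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble alchemical free-energy estimation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alchemr)
```

## The problem

Relative binding free energies (RBFE) between two ligands are computed by
alchemically morphing ligand A into ligand B along a coupling parameter
$\lambda \in [0, 1]$, in two environments ("legs"): the ligand in solvent and
the ligand bound to the solvated protein. Each leg yields an alchemical
$\Delta G$, and the thermodynamic cycle gives

$$\Delta\Delta G \;=\; \Delta G^{\mathrm{alch}}_{\mathrm{complex}}
  - \Delta G^{\mathrm{alch}}_{\mathrm{solvent}},$$

the difference in binding free energy between the ligands (negative values
favor the transformed ligand with our sign convention). Because molecular
dynamics trajectories are chaotic, a single simulation per $\lambda$ window is
not reproducible: this package is built around *ensembles* of independent
replicas per window, with all uncertainty quantification derived from the
spread across replicas.

`alchemr` implements the analysis layer of this workflow — estimators,
uncertainty machinery, diagnostics and comparison statistics — and replaces
the MD engine with synthetic samplers whose free energies are known exactly,
so every stage can be validated end to end against closed forms.

## Estimators

**Thermodynamic integration (TI).** Each window's samples give a time average
of the reduced gradient $\langle \partial u/\partial\lambda \rangle_{\lambda_i}$;
the leg free energy is the trapezoid-rule integral of these means over the
$\lambda$ grid. The ensemble protocol (TIES) first time-averages the
gradient per replica, then bootstraps the replica means within each window to
obtain the window mean and its standard error $\sigma(\lambda_i)$, integrates
the window means, and propagates the window errors through the trapezoid
weights:

$$\sigma^2_{\mathrm{leg}} \;=\; \sum_i w_i^2\, \sigma^2(\lambda_i), \qquad
  w_i = \tfrac{1}{2}(\Delta\lambda_{i-1} + \Delta\lambda_i),$$

with one-sided half-weights at the path ends. The propagation formula is our
interpretation of "propagating $\sigma^2(\lambda)$ with the $\Delta\lambda$
between adjacent windows": it is exactly the standard deviation of the
trapezoid estimator under independent window errors, and the suite verifies
it against brute-force Monte-Carlo propagation on arbitrary grids to better
than 2%.

**MBAR.** The multistate Bennett acceptance ratio estimates all $K$
dimensionless state free energies jointly from the $N \times K$
cross-evaluated reduced-potential matrix:

$$f_i = -\ln \sum_{n=1}^{N}
  \frac{\exp(-u_i(x_n))}{\sum_k N_k \exp(f_k - u_k(x_n))}.$$

We solve the self-consistent equations with log-sum-exp throughout (no
overflow for $|u| \le 700$), switching to damped Newton steps on the
maximum-likelihood gradient once the residual drops below $10^{-2}$
(falling back to self-consistent iteration if a Newton step increases the
residual). Defaults: tolerance $10^{-10}$ on $\max|\Delta f|$, at most
$10^4$ iterations, gauge $f_1 = 0$. With $K = 2$ the same equations are
Bennett's acceptance ratio; `bar_estimate()` solves that case independently
by bracketed scalar root finding, which gives the suite a genuine two-route
consistency check (agreement to $10^{-8}$). One-sided exponential averaging
(`zwanzig_estimate()`) is provided with its effective-sample-size
diagnostic; its bias is documented, not guarded.

**Ensemble FEP.** Mirroring the TI protocol, MBAR is solved per replica on
that replica's pooled samples, and the five per-replica $\Delta G$ values are
bootstrapped for the mean and SEM. A pooled mode (one MBAR solve over all
replicas, SEM from the asymptotic covariance) exists for single-trajectory
comparisons.

## Uncertainty: ensemble versus analytic errors

The asymptotic ("analytic") MBAR covariance is computed from the converged
weight matrix with the pseudo-inverse estimator
$\Theta = V S (I - S V^{\top} N V S)^{+} S V^{\top}$ (thin SVD $W = USV^\top$,
$N = \mathrm{diag}(N_k)$); small negative variances from roundoff are clipped
to zero with a warning. Validation is by repeated independent regeneration:
the analytic SEM matches the observed spread of estimates within sampling
error, and halves when the sample count quadruples.

`error_comparison()` contrasts this single-trajectory error estimate with
the ensemble route. The per-replica analytic SEMs are averaged and divided
by $\sqrt{R}$ so that both quantities estimate the error of the same
object — the $R$-replica mean. For well-mixed sampling the ratio
ensemble/analytic is close to 1 (calibrated band 0.7–1.4 over 50 seeds).
When sampling is governed by rare events, single-trajectory estimates miss
the between-mode variance entirely and the ratio grows far beyond 2; the
slow-switch generator below reproduces this regime on demand. De-correlating
each series by its statistical inefficiency first (initial-positive-sequence
truncation, $g = 1 + 2\sum_t \rho_t$, stride $\lceil g \rceil$) does not
change that verdict, which the suite asserts explicitly.

## Synthetic systems: what they emulate, and what they do not

**Gaussian chain** (`gaussian_chain_system()`): $K$ harmonic states with
reduced potential $u_k(x) = \tfrac12 K_k (x - \mu_k)^2 + c_k$; force
constants interpolate log-linearly in $\lambda$ (positivity and a constant
expected gradient), centers and offsets linearly. Free energies are known in
closed form, $f_k = -\tfrac12 \ln(2\pi/K_k) + c_k$, which the suite
cross-checks against numerical quadrature to $10^{-8}$. The default study
geometry is 13 windows × 5 replicas × 1000 samples per window — the standard
ensemble protocol's sampling geometry at sample-count parity (five replicas
per state, samples every 4 ps over 4 ns of production). The default
endpoints ($K: 1 \to 4$, $\mu: 0 \to 1$) give gentle adjacent-state overlap
(first off-diagonals ≈ 0.08–0.12, comfortably above the 0.03 criterion) —
deliberately a *well-behaved* transformation.

**Slow mode-switching mixture** (`sample_slow_switch_mixture()`): each
window is a two-mode Gaussian mixture (modes 6 standard deviations apart by
default, the second offset in reduced energy by $g\lambda$ with $g = 2$),
and each replica carries a two-state Markov chain over the modes with a
per-step switch probability. At switch probability $10^{-4}$ and $10^3$
samples a replica almost never switches: it is trapped in the mode drawn
from the stationary distribution at initialisation — exactly "varying only
in the random initial conditions". Mixture free energies remain available in
closed form.

**Toy Lennard-Jones particle** (`toy_lj_system()`,
`metropolis_toy_lj()`): one mobile particle in a periodic cubic box
(edge $4\sigma$) interacting with a fixed neighbor through the soft-core
pair potential

$$U(r, \lambda) = 4\varepsilon \lambda^a \left[
  \big(\alpha (1-\lambda)^b + (r/\sigma)^c\big)^{-12/c} -
  \big(\alpha (1-\lambda)^b + (r/\sigma)^c\big)^{-6/c} \right],$$

the parameterised form whose defaults are $\alpha = 0.5, a = b = 1$ with
$c = 6$ (OpenMMTools convention) or $c = 2$ (NAMD convention). Metropolis
sampling tunes its step size toward 40% acceptance during the discard phase
and freezes it before production (determinism requires freezing; in a
near-empty box the realised acceptance rate stays higher because most of the
volume is flat). This is the minimal system that shows the end-state
gradient pathology: with $c = 2$ and $\alpha = 0.5$ the mean
$\partial u/\partial\lambda$ profile of a disappearing particle bends
sharply at the final windows, and a 13-window trapezoid integral
acquires a visible bias against a 129-window dense reference
(computed deterministically by `toy_lj_exact_gradient()`, a 3-D Boltzmann
quadrature). Softening to $\alpha = 0.7$ removes both the curvature and the
bias — the mechanism by which soft-core parameter choice resolves TI–FEP
discrepancies.

None of these generators have force fields, solvent, barostats or
constraint algorithms; annihilate/decouple semantics are carried as metadata
and, in the toy system, amount to including or excluding the intra-region
term. Passing tests therefore validate the *estimators and statistics*, not
any claim about real protein–ligand systems: real MD data add force-field
error, equilibration artifacts and far richer slow modes than the two-mode
caricature here.

## Schedules and interaction classes

`build_lambda_schedule()` maps a uniform global $\lambda$ grid (13 windows
by default; the grid is user-overridable since only the window count, not
the spacing, is conventionally fixed) to four interaction-class factors.
The two-step (annihilation-style) convention removes outgoing
electrostatics entirely over the first half of the path while growing
incoming vdW, then removes outgoing vdW while growing incoming
electrostatics, with the boundary at $\lambda = 0.5$ and linear sub-ramps —
the ordering is conventional, the rates are our choice. The one-step
(decoupling-style) convention scales all classes across the whole path with
electrostatics at a configurable faster pace (`elec_pace = 0.5` by default,
matching the common engine default of completing electrostatic decoupling
halfway). Electrostatics always scale linearly without a soft-core; the toy
systems have no charges, so this enters only through the schedule factors.
End states are exact by construction ($0$ and $1$, never approximately so).

## Numerical and statistical choices

* Units: kcal/mol externally, dimensionless reduced energies internally;
  $k_B = 0.0019872041$ kcal/(mol·K); the synthetic chains use $\beta = 1$.
* Bootstrap: resampling with replacement, percentile intervals, 5000
  resamples by default (95% and 90% intervals alike); a single replica
  yields `NA` SEM/CI rather than an error. The calibration studies in the
  test suite use 2000 resamples to keep the 100-seed loops inside a couple
  of minutes; SEM noise from the bootstrap count is negligible next to the
  5-replica sampling noise.
* "MSE" in the comparison report is the mean *squared* error, so
  RMSD $= \sqrt{\mathrm{MSE}}$ holds identically on the point estimates —
  the convention consistent with reported table values elsewhere.
* Kendall correlation is tau-b (tie-corrected), verified against exhaustive
  pair enumeration; skewness is $m_3/m_2^{3/2}$ and excess kurtosis
  $m_4/m_2^2 - 3$ (moment definitions, Gaussian baseline 0), with 90%
  percentile-bootstrap intervals whose coverage on $n = 48$ Gaussian
  ensembles is verified at 80–98% across 100 seeds (percentile intervals
  for kurtosis are known to undercover slightly at this $n$).
* Two estimates are called different when $|\Delta| > z\sigma_{\mathrm{quad}}$
  with $\sigma_{\mathrm{quad}}$ the quadrature-combined SEM and $z = 1$ by
  default (configurable); this reproduces the reference classifications
  0.40(0.34) → different, −0.01(0.33) and −0.03(0.30) → not.
* Overlap matrices $O_{ik} = N_k \sum_n W_{ni} W_{nk}$ are row-stochastic at
  convergence (asserted to $10^{-10}$); the tridiagonality criterion gates
  only the first off-diagonals (> 0.03), farther entries are reported but
  never fail a run. Replica averaging of overlap matrices is entrywise.
* Degenerate inputs fail loudly and early: non-positive distances or force
  constants, pressure without volume, mismatched lengths, zero-variance
  inputs to correlations/shape statistics, non-finite window means (named
  by window), unconverged MBAR (with residual).

## Problem sizes

The shipped analyses and checks run on one CPU core in a few minutes total:
100-seed calibration loops at 13 × 5 × 1000, toy-LJ Metropolis runs at
13 × 5 × 4000 with a 129-window deterministic reference, 4 × 10^4-draw
Monte-Carlo error-propagation oracles, and 100 × 2000-resample coverage
studies. These sizes were chosen so that every statistical band in the test
suite is comfortably resolved by the corresponding oracle.

## Known limitations

* The synthetic legs share no configuration space with real MD output;
  reading engine-native formats (e.g. NAMD fepout) is out of scope, though
  the tabular format's columns follow the usual dHdλ / u_nk conventions so
  adapters are straightforward.
* The two-mode Markov generator models one rare-event timescale; real
  complex legs mix many.
* Percentile bootstrap intervals (not BCa) throughout; at ensemble sizes of
  5 the SEM itself is noisy, and the 3-SEM coverage of the ensemble-MBAR
  estimate sits near its nominal boundary by construction (a 5-value
  bootstrap SEM underestimates the population SEM by ≈ $\sqrt{4/5}$).
* The one-sided Zwanzig estimator's forward/reverse pair does not reliably
  bracket the truth on mildly perturbed states (bias ≪ noise there); the
  effective sample size is the more informative asymmetry diagnostic.
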