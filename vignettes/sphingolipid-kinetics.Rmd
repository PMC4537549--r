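---
title: "Compartmental kinetics of sphingolipid metabolism: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental kinetics of sphingolipid metabolism: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameterization of the built-in sphingolipid network, the
numerical choices behind each analysis stage, and what the synthetic
fixtures do and do not establish about real data.

## The model

The state of the system is a vector of species concentrations `S(t)` in
nine subcellular compartments; its dynamics are `dS/dt = M v(S)` where `M`
is the species-by-reaction stoichiometry matrix and `v` stacks the reaction
fluxes. Two rate-law families are used:

* **Mass action** for molecular transport between compartments and for the
  exogenous inflows: `v = k * prod([S]^nu)`. Transport of membrane-bound
  lipids (CER, SM, GSL) represents carrier-protein and vesicular routes;
  the hydrophilic species (Sph, S1P, C1P) desorb to the cytosol directly.
* **Michaelis–Menten** for enzymatic conversions:
  `v = Vmax [S] / (Km + [S])`, with the catalyzing enzyme recorded as an
  annotation (modifier) whose concentration is absorbed into `Vmax`.

Inhibition — the regulatory action of S1P and C1P on ceramide-generating
enzymes — is non-competitive and multiplicative: each inhibitor `I` with
constant `Ki` scales the flux by `1/(1 + [I]/Ki)`. We allow the inhibitor
list on any law form, not only on Michaelis–Menten: the de novo ceramide
inflow into the ER (a serine-palmitoyltransferase surrogate) is a
zero-order mass-action inflow that is nevertheless feedback-inhibited, and
forcing it into a substrate-based form would have required a fictitious
precursor species.

All compartment volumes are 1, so concentrations and copy numbers share one
scale and the stochastic propensities equal the macroscopic fluxes. This
convention matters: the magnitudes of the Linear Noise Approximation
variances depend on it, so only the *pattern* of variance components (which
reactions dominate which species), not their absolute scale, should be
interpreted.

### The built-in sphingolipid network

`build_homeostasis_model()` assembles 39 species (CER, SM, Sph, S1P, C1P
and a single GSL pool, resolved per compartment), 69 reactions (29
mass-action transport/inflow, 40 enzymatic) catalyzed by 37 enzymes (the
endocytic machinery is shared by three endocytosis reactions and the SK2
isoform acts in both cytoplasm and nucleus), and 129 parameters (29 rate
constants, 40 pairs `Vmax`/`Km`, 20 inhibition constants). De novo
ceramide synthesis enters as a constant inflow into the ER; exogenous C1P,
CER, Sph, S1P and SM enter at the outer membrane; S1P leaves the lipid pool
only through irreversible S1P lyase cleavage in the ER. The inner-leaflet
GSL pool is a passive flip equilibrium whose initial value is derived from
the outer-leaflet pool rather than tabulated, which is why the model
carries 38 explicit initial concentrations for 39 species.

### Placeholder parameter calibration

Published kinetic constants for this pathway are scattered and
incomplete, so the default parameterization is calibrated rather than
measured, with two principles:

1. **Stationarity by construction.** A strictly positive flux distribution
   with `M v = 0` is built as a weighted sum of source-to-sink routes
   (every route runs from an inflow to the S1P lyase sink) plus internal
   futile cycles; rate constants are then backed out so each reaction
   carries its assigned flux at the tabulated concentrations. The model is
   therefore stationary at its initial state to machine precision, which is
   the operating point of every analysis.
2. **Operating saturation per enzyme class.** Each Michaelis–Menten
   reaction is assigned the fraction of `Vmax` at which it runs in
   homeostasis: degradative sphingomyelinases and the endocytic machinery
   near capacity (70 %), ceramidases with modest reserve (60 %), kinases
   and phosphatases at 40–50 %, synthases with reserve (25–60 %).
   `Km` follows from the saturation level and the stationary substrate
   concentration. These reserves are what make the network fragile in the
   disease scenario: perturbations that push a degradative flux demand
   beyond its saturable capacity produce unbounded accumulation, exactly
   the failure mode the Alzheimer simulation probes. Inhibition constants
   equal the inhibitor's homeostatic level, so each inhibited reaction runs
   at half its disinhibited rate per inhibitor — a strong, responsive
   feedback.

Concentrations are in arbitrary molar-equivalent units with the outer
membrane SM pool dominant (40) and the signaling species (S1P, C1P) two
orders of magnitude smaller, reflecting the rheostat asymmetry.

### The Alzheimer scenario

`ad_scenario()` encodes the disease fingerprint as multiplicative parameter
edits. The core changes: ceramidase activity down (×0.8), sphingosine- and
ceramide-kinase activity down (×0.7), CERT-mediated ER-to-Golgi ceramide
transport down (×0.2), de novo ceramide synthesis up (×3). Applied alone,
these overload the saturable sphingomyelin-degradation capacity: SM grows
without bound in the outer membrane, inner membrane, ER and lysosome, and
the Golgi ceramide pool escapes too. The corrected scenario adds reduced
CERT-independent vesicular transport (×0.3), increased sphingomyelinase
activity (×1.6–2.5 by compartment) and minor SM-transport adjustments,
after which every pool is bounded and the simulation shows ceramide
accumulation (strongest in ER and lysosome), an immediate sphingosine dip
followed by accumulation, and reduced S1P in the kinase-driven pools.

All magnitudes are documented placeholders chosen so the corrected system
is bounded while the uncorrected one is not; they were fixed once during
development and are overridable per entry. Two S1P pools cannot decline in
this reconstruction regardless of magnitudes: the outer-membrane pool is
pinned by its fixed exogenous inflow (its only source), and the ER pool is
the substrate of the single irreversible lyase sink, so it must rise
whenever total throughput rises. Interpreting "S1P decreases" therefore
means the kinase-driven pools (inner membrane, cytoplasm, nucleus,
mitochondrion) and the median over all pools. Similarly, C1P rises rather
than falls: the reduced ceramide-kinase rate is outweighed by the
accumulating ceramide substrate.

## Analysis stages and numerical choices

**Simulation and stabilization.** `deSolve::lsoda` with `rtol = 1e-8`,
`atol = 1e-12`; the stationarity residual feeds the noise and
identifiability analyses and must be clean. The plateau criterion is
`max|dx/dt| < 1e-9 (1 + max|x|)` sustained over the last 10 % of the
horizon, with the horizon quadrupling until it holds, then Newton polishing
on `M v(x) = 0` with the analytic flux Jacobian. Divergence detection
reports first crossings of a concentration threshold (default one million
times the largest initial value; the disease analyses use 25 times, a
level no bounded pool approaches).

**Stochastic simulation.** Gillespie's direct method in compiled code,
driven by R's RNG so a single `set.seed()` governs reproducibility. It is
the oracle for the LNA: on first-order networks the stationary covariance
is exactly Poisson/product-Poisson, and the test-suite compares simulated
ensembles (10⁴ paths) against both the analytic law and the Lyapunov
solution.

**Sensitivities.** Three routes, cross-validated against each other and
against central finite differences (relative step 1e-6, agreement to 1e-4
relative): an augmented variational ODE for small systems; an exact
linear-time-invariant expression through the eigendecomposition of the
drift matrix when the initial state is stationary; and piecewise-frozen
matrix-exponential propagation (`expstep`, via the augmented-exponential
construction that avoids matrix inversion) for large systems off
equilibrium. Indices integrate `|dS_n/d theta_i|` by trapezoid over the
result grid; the raw index is the formula-faithful default and the
log-parameter normalization (`theta_i` times the derivative) is what makes
ranks comparable across parameters with different units, so rankings use
it.

**Noise decomposition.** The stationary covariance solves
`A Sigma + Sigma A' + D = 0`; the Kronecker system is factorized once and
reused for all 69 rank-one diffusion pieces, so additivity of the
per-reaction components holds to solver precision by linearity. Components
are flagged per species when they exceed 110 % of that species' mean
component. The "mean" is taken over all reactions of one species, matching
the per-species reference line of the reference analysis.

**Identifiability and clustering.** The Fisher information uses a
perturb-and-relax design: the stabilized state is displaced by four
multiplicative patterns (global ×1.3, global ×0.7, two alternating
patterns) and each relaxation is observed at 50 log-spaced times for all
species under unit noise, on the log-parameter scale, with max-diagonal
normalization. The design choice is forced by a structural fact: observed
at an exact fixed point, every sensitivity trajectory factors through one
N-dimensional linear map, the information matrix has rank at most N = 39,
and all 129 parameters are mutually confounded — excitation is what
creates identifiability. Functional redundancy uses natural logarithms
(nats), making it equal to the Gaussian mutual information between
parameter blocks, which the test-suite verifies against the closed form on
random SPD matrices. Block pseudo-inverses truncate eigendirections below
`zeta` times the largest diagonal: information below the identifiability
floor is treated as absent, keeping the two uses of `zeta` consistent.
The defaults `(delta, zeta) = (1e-6, 1e-3)` come from a documented sweep;
at these values the homeostasis model has exactly 37 non-identifiable
parameters, and within the same sweep the Alzheimer model reaches its
reference count of 36 at `zeta = 1.1e-4`. The agglomerative loop merges
the pair of sets with the largest redundancy, re-applies the filter on the
shrinking universe each iteration (an up-front-only mode is available),
and stops at one set or all-zero redundancies; infinite-redundancy merges
(a canonical correlation of 1) order above every finite height. The
automatic cluster count cuts at the largest relative drop between
consecutive finite merge heights; `cut_redundancy_tree()` cuts at any
requested k for composition questions. On the placeholder parameterization
the automatic cut yields two clusters in both scenarios — the placeholder
redundancy profile is flatter than a literature-calibrated one, and cluster
counts should be read as threshold- and parameter-sensitive.

## What the synthetic fixtures establish

The birth–death, linear-chain, redundant-pair and random-network
generators exercise every pipeline stage against analytic oracles:
closed-form trajectories and stationary states, Poisson/product-Poisson
stationary laws, finite-difference sensitivities, closed-form Gaussian
mutual information, and structural non-identifiability of a product-
confounded parameter pair. They emulate continuous-time reaction networks
with intrinsic copy-number noise and a stationary state — the statistical
structure the analyses assume — but they are small, first-order-dominated
and noise-idealized. Passing them shows the machinery is correct; it does
not show that the placeholder sphingolipid parameterization matches any
particular tissue, which would require the fitted constants the model is
designed to accept (`params_source`, SBML import, scenario overrides).

## Problem sizes

The shipped analyses use: stabilization and design horizon 400 for
homeostasis (the Alzheimer stationary search extends its own horizon
automatically), 50-point log-spaced design grids, 4 relaxation
experiments, disease simulations to t = 5000, and 10⁴ stochastic paths
for the oracle comparisons. These sizes keep the full validation suite
comfortably reproducible on a single CPU while leaving all quantities well
inside their asymptotic regimes (doubling any of them changes reported
numbers by less than the stated tolerances).

## Known limitations

* Parameter values are calibrated placeholders; absolute concentrations,
  variances and sensitivity magnitudes are not tissue predictions.
* The single irreversible S1P lyase sink couples ER S1P to total
  throughput (see the Alzheimer discussion above).
* The de novo ceramide pathway is a lumped inflow; upstream intermediates
  are out of scope.
* LNA variances are Gaussian approximations; no finite-volume corrections
  or higher-order closures are attempted.
* SBML support covers core constructs (compartments, species, reactions,
  local/global parameters, kinetic-law math); events, rules and
  constraints are reported as unsupported rather than interpreted.
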