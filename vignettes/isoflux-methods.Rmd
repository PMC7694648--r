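---
title: "Methods: labeling simulation and flux estimation in isoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: labeling simulation and flux estimation in isoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoflux)
```

# The model and its assumptions

`isoflux` works on atom-transition network models: each reaction step lists
its substrates and products with letter strings mapping every traced product
atom to a unique substrate atom. Two assumptions underlie everything the
package computes:

1. **No kinetic isotope effect.** Fluxes act linearly and identically on all
   labeled forms of a substrate. For ¹³C this is a good approximation; for
   ²H tracers it can fail badly, and `isoflux` makes no attempt to model it.
2. **Well-mixed pools.** Each metabolite is one homogeneous pool with a
   single MID — no substrate channeling, no unresolved compartments.
   Compartmentalized metabolites should be modeled as distinct metabolite
   names.

Reversible reactions are represented as two irreversible steps with separate
flux ids (aldolase is `f2`/`f3` in the shipped glycolysis model). This keeps
every labeling-balance coefficient an actual one-way flux; no net/exchange
reparameterization is offered, because all balance equations and the EMU
decomposition operate directly on the one-way steps.

At metabolic steady state the balance `sum(production) = sum(consumption)`
holds per balanced metabolite. Source metabolites have their labeling fixed
by the tracer and carry no balance equation; sinks absorb material and may
drop atoms (a sink reaction need not carry all substrate atoms to its
product side).

## Free-flux parameterization

The balance constraints plus any fixed fluxes leave `n - rank` free fluxes;
all fluxes are affine in the free ones (`complete_fluxes()`). The free set
is chosen greedily, *preferring later flux ids*. For networks written in the
conventional forward/reverse order this selects the reverse (exchange)
fluxes as free — on the glycolysis model with f1 fixed it yields `{f3, f5}`,
matching how the example is usually parameterized. A lexicographically-first
rule would instead select `{f2, f4}`, which is mathematically equivalent but
makes the worked equations (`f2 = 100 + f3`, `f4 = 100 + f5`, `f6 = 200`)
less recognizable. Users can override the choice with the `free` argument.
Inconsistent fixed-flux sets (e.g. fixing both f1 = 100 and f6 = 100 here,
when balance forces f6 = 200) are detected by a least-squares residual check
on the affine map and rejected.

# EMU decomposition

Only the EMUs backward-reachable from the measured targets are enumerated.
Condensation steps produce convolution source terms; `⊕` is commutative, so
convolution sources are stored sorted and duplicate edges are merged by
summing their multiplicity.

**Molecular symmetry** (e.g. succinate, declared `symmetry=4321`) is
implemented by *orientation averaging*: producing edges into a symmetric
metabolite are split 50/50 between the two atom orderings, and EMUs related
by the involution collapse onto one representative. This is the exact
infinite-rate limit of the "flipping flux" device and avoids choosing an
arbitrary large flux magnitude. A self-symmetric EMU (such as `[2,3]` of a
4-carbon symmetric molecule) keeps a single orientation with weight 1.
Prochiral metabolites (citrate) must *not* be declared symmetric — their
mirror-related groups are not interconvertible — and are left untouched.
Predictions are symmetrized; measurements are taken as given.

Cumomer-style positional enrichments are not a separate network: a weight-1
cumomer equals the M+1 fraction of the corresponding size-1 EMU, which is
what `positional_enrichment()` solves.

# Steady-state solver numerics

Sizes are processed in ascending order; within one size all unknown MIDs are
assembled into a single dense linear system and solved simultaneously with
`solve()`, which handles interconversion cycles (DHAP/GAP) without
iteration. Systems are small by construction — the glycolysis example has a
4-unknown size-3 block and a 1-unknown size-6 block.

Numerical choices:

- An EMU with zero total inflow makes the system singular; this is reported
  with the EMU name and its inflow fluxes. EMUs not forward-reachable from
  any tracer source are rejected at decomposition time.
- Round-off can produce tiny negative fractions; values down to −10⁻¹² are
  clipped to zero and the MID renormalized. Anything more negative is an
  error, since the solves involved cannot legitimately produce it.
- Tracer mixtures are expanded exactly: each mixture component contributes
  its mole fraction at mass shift `|EMU atoms ∩ labeled positions|`.
  Isotopic purity is assumed 100%; natural isotope abundance is out of
  scope, so measured MIDs should be abundance-corrected upstream.

## The brute-force oracle

`isotopomer_steady()` tracks full isotopomer distributions (2ⁿ states per
metabolite, capped at 2¹⁰) and integrates the master equations with unit
pools until the largest derivative falls below 10⁻⁹, doubling the horizon
(from 50 slowest-turnover times) as needed. It shares no code path with the
EMU solver beyond the model parser — production terms are computed from
joint isotopomer patterns, not MID convolutions — which is what makes the
`solve == oracle` tests meaningful. It exists for testing and for
exhaustive positional queries on tiny networks, not for production use.

# Fitting

`mfa_fit()` exposes the *residual vector* `(predicted − measured)/SD` to a
bounded Levenberg–Marquardt optimizer (`minpack.lm::nls.lm`, finite-
difference Jacobian) rather than the scalar SSR; least-squares structure
speeds convergence considerably. The measurement covariance is diagonal —
correlated MID errors are not supported.

- Default free-flux bounds are `[0, 10⁴]` in model units, wide enough to be
  uninformative for nmol/h-scale problems while keeping the search bounded.
- Multi-start: `n_starts = 10` initial points drawn log-uniformly over the
  box (floored at 10⁻⁴ of the upper bound so the log is defined when the
  lower bound is 0), from a caller-supplied seed; results are
  bit-reproducible given `(seed, n_starts)`. The RNG state of the session
  is saved and restored around every draw.
- Convergence tolerances `ftol = ptol = 10⁻¹⁰`; a start that fails to
  converge is recorded (`starts$converged = FALSE`) but not fatal while at
  least one start succeeds.
- Endpoints whose SSR ties the minimum within 10⁻⁹ are resolved toward the
  smallest parameter norm, making the reported optimum deterministic even on
  flat ridges (relevant for unidentifiable tracers, where the whole ridge is
  optimal). All endpoints are retained in the fit object.

For time-stamped measurements the same machinery runs with the EMU ODE as
the forward model; pools named in `free_pools` join the parameter vector
with bounds `pool_bounds` (default `[1, 10⁶]` nmol).

# Uncertainty

The SSR acceptance rule is `SSR ≤ SSR_min + qchisq(level, df)`. **df = 1 is
the default for both the per-flux profiles and the 2-D region raster**,
following the per-flux convention in which the worked sub-optimal point
(f3 = 48, f5 = 210; χ² ≈ 1.33 < 3.84) is accepted; the jointly-calibrated
df = 2 threshold is available through the `df` argument of `ssr_region()`
and `confint()`. χ² quantiles are always computed from `qchisq()`, never
hardcoded.

Profile intervals step the target flux from its optimum (initial step 1% of
the estimate, or 1.0 if zero), re-optimize the remaining parameters with a
warm start from the previous profile point, double the step until the cutoff
is crossed, then bisect to three significant figures. Profiles that reach an
optimization bound first return the bound with a flag instead of failing —
that is the expected outcome for unidentifiable fluxes.

The region raster evaluates the SSR on a rectangular grid (re-optimizing any
remaining free parameters per cell, warm-started along the sweep). Profile
endpoints and region extremes agree to within one grid cell on the fixtures;
region bounds are reported at grid resolution by construction.

Two Monte-Carlo samplers are provided, because "sample the flux
distribution" admits both readings: a random-walk Metropolis sampler in free-
flux space with log-density −SSR/2 (proposal scale adapted toward ~30%
acceptance during burn-in, with a warning when the final acceptance rate
leaves [0.05, 0.8]), and a measurement-perturbation sampler that refits
after adding Gaussian noise (the measurement SDs) to the data. Neither is
presented as canonical; on the glycolysis fixture their 95% spans agree with
the profile intervals to well within 15%.

# Non-stationary simulation

Concentration `c` and cell volume `V` are never tracked separately: every
equation is written in the pool *amount* `c·V` (nmol) and absolute fluxes,
which leaves the labeling ODE unchanged and avoids an unobservable split.
The integrator is `deSolve::lsoda` (stiff-capable), `rtol = 10⁻⁸`,
`atol = 10⁻¹⁰`, sampled at the requested times; MIDs are renormalized
against integrator drift (guard tolerance 10⁻⁷). The pre-switch state is
fully unlabeled by default; a pre-labeled initial state can be supplied.

With evolving pools, `d(cV)/dt = f_NetPro` is co-integrated (net production
from the stoichiometry; fluxes need not balance) and a root function stops
integration with an error if any pool hits zero. `simulate_to_steady()`
integrates in chunks of ten slowest-turnover times until
`max |dm̄/dt| < 10⁻⁹` or 50 turnovers, whichever comes first.

The non-stationary fixture (`inst_glycolysis_fixture()`) makes Glc6P an
explicit intermediate (Fruc6P lumped into it) with FBP/DHAP/GAP pools of
1000 nmol and Glc6P at 400 or 3000 nmol for the small/large comparison. The
published comparison does not print its absolute flux values, so the fixture
reuses the steady-state reference fluxes (f1 = 100, f3 = 50, f5 = 150);
consequently only ordering properties of the two pool scenarios (the larger
Glc6P pool delays FBP labeling at every finite time; the steady state is
identical) are asserted, not absolute curves, and the time axis is
conventional (hours at these flux units).

# The synthetic measurement generator

`simulate_measurements()` adds independent Gaussian noise per MID fraction
at the requested SD, clips negatives at zero and renormalizes each MID; the
`sd` column records the nominal noise level (not the post-clip dispersion),
matching the "1% error on all labeled fractions" convention used for the χ²
thresholds. Structural zeros — fractions to which no atom path can deliver
label — are dropped before noise is added, as a mass spectrometrist would
not report them; this also keeps the generator unbiased at the measured
fractions (clipped noise on a true zero has positive mean). `sd = 0`
returns exact predictions; output is byte-reproducible given the seed.

What the generator deliberately does **not** emulate: natural isotope
abundance, correlated errors across fractions of one MID (real
renormalized MS data are correlated), intensity-dependent variance, and
instrument drift over a time course. Tests passing on generated data
therefore demonstrate correctness of the estimator under its own error
model, not robustness to real-instrument artifacts.

# Problem sizes and runtime

The test-suite and acceptance computations use the glycolysis fixtures
(8-EMU steady-state network; 10-EMU non-stationary variant), 10 random
starts for headline fits and 3–6 elsewhere, a 61×87 region raster, 1500
Metropolis draws, 60 perturbation refits, and 6-time-point time courses for
the non-stationary round trip. These sizes were chosen so every property is
exercised with comfortable margins while the whole suite stays fast; all
scale linearly (or, for the raster, quadratically) if enlarged.

# Known limitations

- No natural-abundance correction and no isotopic-impurity model.
- Diagonal measurement covariance only.
- No net/exchange flux transform, no SBML import, no NMR fine structure.
- The brute-force oracle is exponential in atom count (capped at 2¹⁰
  states per metabolite) by design.
- Multi-start local search is not a global optimizer; pathological
  landscapes may need more starts or custom bounds.
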