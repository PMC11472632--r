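---
title: "Half-life kinetics and normalized slope conductance of photoswitch-gated whole-cell currents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Half-life kinetics and normalized slope conductance of photoswitch-gated whole-cell currents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoclamp)
```

## The measurement problem

Azobenzene-based photoswitchable channel activators (the DAG analogues
OptoDArG and PhoDAG, and the GSK derivative OptoBI-1 acting on TRPC6) let an
experimenter switch a ligand between its active *cis* form (UV light,
~365 nm) and its inactive *trans* form (blue light, ~445 nm) on a
millisecond clock.  A whole-cell recording during such photoswitching shows
three kinetic phases: **activation** when UV turns the ligand on,
**inactivation** (a biphasic decline) while UV stays on, and
**deactivation** when blue light turns it off.  `optoclamp` quantifies
these phases as half-life time constants, and separately compares the
*shape* of current-density–voltage relations between stimuli through the
normalized slope conductance (NSC).

All currents are handled in the standard electrophysiological sign
convention (inward current negative) and summarised as current densities
(pA/pF) so that cell size drops out.  Time is kept in seconds throughout
the code; milliseconds and minutes appear only at reporting boundaries.

## The half-life fit routine

Segments cut from a constant-holding trace (conventionally −60 mV, 2 kHz)
are normalized to a dimensionless signal `y(t)` with `t` shifted to zero,
then fitted by minimising the summed squared residuals (SSE) of a base-2
exponential model:

* rising (activation): `f(t) = a · 2^(+t/τ_H) + c`
* decaying (deactivation): `f(t) = a · 2^(−t/τ_H) + c`
* biphasic (inactivation): `f(t) = a₁ · 2^(−t/τ_H1) + a₂ · 2^(−t/τ_H2) + c`

so that `τ_H` is directly a half-life (decay) or doubling time (rise).

The normalization conventions are phase-specific:

* **activation** — the median current over a pre-UV window (default 1 s)
  maps to 0 and 30% of the maximal activated deflection maps to +1; the fit
  window ends where the signal reaches +1.  Fitting only the first 30% of
  the rise excludes the inactivation that is already emerging near the
  peak.  The 30% constant is configurable (`frac`, sanity-bounded to
  0.2–0.5).
* **deactivation** — the median deflection before the blue-light onset maps
  to +1, the settled tail median to 0.
* **inactivation** — the peak deflection maps to +1, the median of the last
  10% of the UV period (the steady state) to 0, and `t = 0` at the peak.

Minimisation uses an fminsearch-style Nelder–Mead simplex
(`fminsearch_nm()`): standard Lagarias coefficients, a 5% initial-simplex
perturbation, and the joint termination rule (both the parameter spread and
the objective spread of the simplex must fall below their tolerances).
The optimizer caps and tolerances are `max_fun_evals = 5000`,
`max_iter = 10000`, `tol_x = 1e−10`, `tol_fun = 1e−6`; the start points are
`a = 0.01, τ = 1, c = 0.01` (activation), `a = 0.7, τ = 7, c = 0.1`
(deactivation) and `a₁ = 1, τ₁ = 0.02, a₂ = 1, τ₂ = 3.8, c = 0.1`
(inactivation).  The search is unconstrained; a sign-flipped τ is reflected
to its absolute value and flagged rather than hidden.

### Units of the start-value time constants

The start values carry no explicit unit, and the choice matters.  We read
them **on the scale of the kinetics they seed**: milliseconds for
activation and deactivation (observed half-lives are 5–200 ms) and seconds
for inactivation (observed 0.3–190 s).  The alternative — seconds
everywhere — starts the activation search three orders of magnitude from
any millisecond-scale optimum, and the unconstrained simplex then reliably
collapses into a degenerate valley (`τ → ∞` with huge cancelling `a` and
`c`, i.e. a straight-line fit).  With the scale-matched reading, every
observed half-life class is recovered from noiseless segments to ~10⁻¹⁰
relative error.  The interpretation is exposed as the `fit_options()` field
`tau_init_unit` and can be overridden per call.  Thermal-relaxation fits
(`fit_thermal_relaxation()`) read the start values in raw axis units
(minutes), since those half-lives are hundreds of minutes.

### Robustness in the cohort pipeline

On noisy cohort traces a single-start simplex occasionally still lands in
the degenerate valley.  The cohort pipeline (`run_kinetics_study()`)
therefore screens each result: a fit that hit its caps or returned a
half-life more than ten times the segment span (or below a tenth of a
sample interval) is deterministically refit from a data-derived start
obtained by conditional least squares — for a grid of candidate τ the
amplitudes and offset are linear and solved exactly, and the best grid
point seeds a second simplex run (`profile_start()`).  The better SSE wins
and the refit is flagged `profile-restart`.  Direct calls to `fit_mono()` /
`fit_bi()` never restart: they honour exactly one simplex run from the
canonical start.

Degenerate bi-exponential outcomes are reported, not suppressed: half-life
ratios under 3 raise `components-indistinct`, and a fast half-life below
one sample interval (a component that only ever touches the first sample)
raises `fast-component-unresolved`.

## The synthetic recording generator

No raw recordings are distributed with the study conditions, so the
generator is the package's only data source and is itself first-class,
tested code.  It composes a dimensionless open-fraction `g(t) ∈ [0, 1]`
from the same functional forms the fit assumes:

* UV onset: an accelerating rise `g = a·(2^(Δt/τ_act) − 1)` capped at 1,
  with `a` chosen so the cap is reached after `10/3 · τ_act` — the level at
  30% of the span of this curve is what the activation fit window sees, so
  the generating τ is recoverable exactly.  A saturating-rise mode
  (`1 − 2^(−Δt/τ_act)`) exists for realism studies; it is deliberately not
  the default because fitting a positive-exponent model to a saturating
  rise is biased by construction.
* sustained UV: biphasic decay
  `g = (1−c)(f·2^(−Δt/τ_fast) + (1−f)·2^(−Δt/τ_slow)) + c` from the cap.
* blue onset: decay to zero with half-life `τ_deact` from the running
  level.

A holding trace is then
`I(t) = C·(baseline_cd + g(t)·cd_at_holding) + ε`, with `ε` Gaussian and
`cd_at_holding` taken from an I–V template (near-symmetric or outwardly
rectifying, monotone-cubic through anchors at −100, 0 and +100 mV) scaled
so the current density at the reference potential equals `peak_cd_pApF`.
Ramp sessions evaluate the same template along the command voltage of a
2 Hz (50/400/50 ms) or 50 Hz (7/10/3 ms) ramp protocol at 5 kHz.

Cohorts draw per-cell parameters from log-normal distributions (median ×
geometric SD) with per-cell seeds derived arithmetically from one master
seed, and return a manifest of every true parameter.  Defaults emulate the
study conditions: 2 kHz holding traces at −60 mV, capacitance median 15 pF
(geometric SD 1.2), current noise SD 2 pA, and arm medians set to the
reported half-life constants (e.g. `optodarg_light_source_config()` uses
activation 5.8 vs 130.0 ms, deactivation 8.4 vs 94.4 ms, fast inactivation
0.3 vs 4.0 s, slow inactivation 13.1 vs 57.3 s for LED vs xenon arms).
Light-source intensity does not rescale kinetics automatically — no rate
law links lamp power to τ — so slower sources are emulated by supplying
larger τ medians.

What the generator does **not** emulate: series-resistance and capacitive
artefacts, rundown/drift, line noise, seal instability, or any
photochemical model of isomer fractions.  Passing tests therefore
demonstrate correctness of the analysis pipeline under the stated
statistical structure, not robustness to every artefact of real recordings.

## Normalized slope conductance

For each cell the I–V relation of a selected ramp sweep (by convention the
2 Hz protocol, at the maximal cis-induced current) is binned to a 1 mV
grid, fitted with a cubic smoothing spline (`smooth_iv()`; generalized
cross-validation by default, a fixed shared `lambda` when comparing
groups), and normalized per branch: the inward branch is scaled so the
smoothed density at −100 mV is −100%, the outward branch so +100 mV is
+100%.  The two branches are anchored independently — rectification ratios
are deliberately discarded, leaving pure curve shape.  The NSC is the
analytic spline derivative of the normalized density, rescaled per branch
to branch-mean 1, so an ohmic relation gives NSC ≡ 1 and deviations
localise where the I–V shape bends.  The derivative at 0 mV is excluded
(the anchors make it degenerate) and branch endpoints are flagged as
one-sided.  Every constant used (scales, branch means, smoothing parameter)
is recorded on the output object.

Group comparison is pointwise per grid voltage: Mann–Whitney U for two
groups, Kruskal–Wallis for three or more, with no across-voltage
multiplicity adjustment by default (a Holm option exists), matching the
pointwise presentation convention for NSC figures.

## Statistics battery

`mann_whitney_u()` is authored in-package: exact permutation enumeration of
the U distribution for `min(n, m) ≤ 8` — mid-ranks throughout, so ties are
handled exactly, and identical samples give p = 1 — and the tie-corrected
normal approximation with continuity correction otherwise.  The
signed-rank, Kruskal–Wallis and Friedman tests wrap the corresponding
`stats` routines behind the module surface.  Dunn's post hoc test (z on
mean ranks with tie correction) is authored, with Bonferroni adjustment by
default (Holm and none available) — the adjustment convention is recorded
in the output.  Cohort summaries report median, quartiles, SD and n
(boxplot statistics plus median ± SD).

## Numerical choices and degenerate inputs

* Voltage bins are left-closed (`[v, v + 1 mV)`), values are bin means, and
  voltages within floating-point error of a bin edge are snapped upward so
  command voltages computed from sample times bin predictably.
* Plateau current densities at ±100 mV are medians over the hold segments,
  excluding the first 20% of each hold (capacitive-transient margin;
  configurable) — point reads at an arrow time would be noisier.
* Peak detection uses an 11-sample moving median before the argmax so a
  single noise spike cannot define the peak or its time.
* Acquisition chains sampling at exactly twice the anti-alias cutoff
  (5 kHz after 2.5 kHz filtering) validate: the Nyquist check is `≥`, not
  strict.
* Flat traces, absent light events, holds shorter than the settle margin,
  all-zero branches and constant-τ correlation inputs all raise typed
  errors naming the problem rather than returning silent nonsense.

## Containers

Recordings round-trip through two dialects of one hierarchical schema
(`meta` / `schedule` / `traces`): a single-file JSON archive written at 17
significant digits (bit-exact for doubles) and a directory of per-trace
CSVs with a JSON sidecar for interchange.  Both dialects are tested to
produce identical downstream analyses.

## Problem sizes used in the test suite

The suite regenerates everything at run time.  Mono-exponential recovery
runs on 2 kHz segments of up to 50 s; bi-exponential recovery uses 60 s for
the (0.3, 13.1) s pair and 120 s for the (0.935, 86) s pair, covering at
least one slow half-life; the noisy-fit and null-calibration suites use 200
seeded replicates each; cohort pipeline checks run 2 arms × 3–5 cells at
20 s per trace.  These sizes were chosen so each property is measured well
clear of its tolerance while the whole suite stays desk-scale.

## Known limitations

* The NSC normalization constant of the original slope-conductance method
  is not restated in our sources; the branch-anchored percent scaling plus
  branch-mean-1 rescaling used here is declared, configurable, and
  recorded, but not asserted to be numerically identical to that method.
* Cohort-level numbers from the original recordings are not reproducible
  (no deposited raw data); recovery is demonstrated against synthetic
  ground truth generated at the reported parameter values.
* The activation fit-window reading ("30% of peak" as the window end, not
  merely a rescaling) is the only interpretation that actually excludes
  the emerging inactivation; we implement that reading.
* ABF (instrument-format) ingestion is out of scope; the containers above
  are the supported interfaces.
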