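---
title: "Mechanics and kinetics of multi-domain dimers under force: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics and kinetics of multi-domain dimers under force: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtdimer)
```

This vignette is the package's own account of the models it implements,
the choices made where the design was genuinely open, and what the tests
do and do not establish.

## Mechanical models

Every element on the force path is one of three segment types, all sharing
a `polymer_env()` of physical constants (thermal energy `kBT`, persistence
length `A`, contour length per residue `l0`; units are pN, nm, s and pN·nm
throughout, with no conversions inside any operation):

* **Rigid body** (`rigid_segment(b)`): a folded domain or dimer interface
  of span `b` between its force-attachment points. Its force–extension
  curve is the orientational average of a single freely-jointed segment,
  `x(f) = b·[coth(fb/kBT) − kBT/(fb)]`. Extension runs from 0 at zero
  force to `b` at infinite force.
* **Flexible chain** (`flexible_chain(N)`): an unfolded run of `N`
  residues with contour length `N·l0`, following the Marko–Siggia
  worm-like-chain interpolation
  `fA/kBT = 1/[4(1−x/L)²] − 1/4 + x/L`. The fractional extension
  approaches 1 only as `1 − sqrt(kBT/(4Af))` — about 95% at 500 pN — which
  is the asymptote the tests assert.
* **Constant segment** (`const_segment(x)`): a geometrically imposed,
  force-independent span (used for the looped linker inside an intact
  dimer).

Defaults: `kBT = 4.075` pN·nm, the thermal energy at 22 °C, the stated
experimental temperature; `A = 0.8` nm and `l0 = 0.38` nm/residue, the
values appropriate for unstructured polypeptide. All are overridable per
call.

Numerical choices: the Langevin function `coth(a) − 1/a` switches to its
series `a/3 − a³/45` below `a = 1e-4` to avoid catastrophic cancellation;
the worm-like-chain inversion brackets the root on `[0, L(1−1e-9)]`
(`uniroot`) and Newton-polishes to an absolute force residual of 1e-9 pN.
Both are deterministic.

## Constructs, states and step sizes

A `construct_spec()` describes a looped dimer construct: two identical
rods of domains (defaults: ~110-residue repeats folding to ~5 nm; a
four-repeat rod of ~480 residues, helical linkers included, folding to
~24 nm), a flexible loop linker (~170 residues in shear geometry, ~218 in
unzip), and the rigid spans of the dimer before and after rupture (24 nm
both in shear; ~2 nm before and 2 × 24 nm in series after in unzip).
Presets for the experimentally studied constructs ship as an editable YAML
file (`inst/extdata/constructs.yaml`); spans of partial rods are
proportional estimates, since only the full-rod and single-repeat spans
are reported.

A `tether_state()` says which elements bear force: while dimerized, each
domain is `"shielded"` (inside the dimer), `"folded"` (stretched rigid
body) or `"unfolded"` (flexible chain); after rupture nothing is shielded
and the released loop joins the force path. `state_to_series()` turns a
state into a mechanical series; the step size of a transition at force `f`
is the extension difference of the two series at `f`.

**Loop bookkeeping.** Two conventions coexist in the literature-style step
estimates, and the package keeps both deliberately:

* For a *pure rupture* (loop release with no concurrent change in
  unfolded-domain count), the step is the extension difference of the
  looped linker before and after release, i.e. its WLC extension minus its
  geometrically imposed in-dimer end-to-end distance (24/18/12 nm for the
  full/three-repeat/two-repeat shear constructs, ~2 nm for unzip).
  `predicted_step_table()` applies this correction, and the synthetic
  trace generator uses the equivalent state-function height (in-dimer
  states carry the loop span as a constant offset), so simulated pure
  rupture steps match this prediction exactly.
* For *rupture concurrent with domain unfolding*, the published estimates
  are reproduced by the plain series difference of the composite states
  (before: dimer span plus already-unfolded chains; after: the tethered
  rod's total residues as one chain plus the released loop chain), with no
  end-to-end subtraction. The exact residue accounting behind the printed
  composite values is not stated in the source material; this convention
  reproduces them to within ~5%, and the tolerance on those comparisons is
  set accordingly (10%).

The naive WLC evaluation for the unzip-geometry linker (218 residues at
~2 nm end-to-end) gives ~0.19 pN where "less than 0.1 pN" is quoted, and
~1.6 pN where "less than 1.5 pN" is quoted for the two-repeat construct;
both quoted values are upper bounds resting on unstated linker-length
assumptions, so the package reports its computed values and does not force
agreement.

## Multivalent rupture kinetics

All rates are Bell rates `k(f) = k0·exp(Δf/kBT)`; Δ > 0 accelerates with
force (un-pairing, unfolding), Δ ≤ 0 is enforced for re-pairing and
refolding. Exponents are capped at 700 and rates at 1e12 s⁻¹ — numerical
guards far outside the physical regime.

The `multivalent_dimer_model()` couples `n` domain pairs in a row:

* only *boundary* pairs of the remaining intact block may un-pair
  (dissociation initiates from the force-bearing ends; both ends by
  default, one end optionally);
* an un-paired domain is on the force path and may unfold/refold;
* only the un-paired *folded* domain adjacent to the block may re-pair —
  unfolding gates re-pairing;
* rupture (all pairs un-paired) is absorbing.

Because un-pairing only peels from the ends, the intact set stays
contiguous and the reachable state space is small (49 transient states for
n = 4). `mean_lifetime_exact()` solves the first-passage linear system of
the continuous-time Markov chain directly (base `solve()`); no detailed
balance is assumed, only reachability of the absorbing state, which is
checked. The Gillespie simulator (`simulate_constant_force()`) draws exact
trajectories over the same transition generator, so simulator and solver
can only agree if both are right — the suite holds them to 3 standard
errors at 1000 runs for every n ≤ 4.

Ramps are simulated with piecewise-constant force, the increment capped at
0.01 pN per step; for a single Bell bond the runs are vectorised and
converge to the inhomogeneous-Poisson closed form, with the Evans–Ritchie
modal force `(kBT/Δ)·ln(rΔ/(k0·kBT))` as the analytic cross-check (2%
tolerance at 1000 runs). `ramp_modal_force()` estimates the modal force by
maximum likelihood of the single-Bell rupture-force distribution rather
than a kernel-density mode, which is unstable at these sample sizes.

Per-pair kinetic parameters for demonstrations and tests are free choices
of this package (chosen so that lifetimes at the test forces are seconds,
keeping simulations fast); no fitted panel values are baked in anywhere.

## Trace analysis

Traces are uniform (time, force, height) series at 200 Hz by default. The
"n-point FFT smoothing" convention is under-specified in figure captions;
it is implemented as a brick-wall low-pass retaining frequencies below
`f_sample/(2·window)`, with a centred moving average as the alternative —
both reduce white-noise standard deviation by about `sqrt(window)`.

Step detection defaults to greedy binary segmentation of a
piecewise-constant fit: the split with the largest residual-reduction is
accepted while it exceeds a BIC-style penalty `2σ²log n`, with σ estimated
robustly from successive differences; adjacent levels closer than
`min_step` are merged afterwards. The default `min_step` of 10 nm suits
rupture/unfolding steps; ~2 nm suits hopping traces, for which a
self-contained Gaussian-emission HMM (quantile-initialised Baum–Welch plus
Viterbi; deterministic) is the alternative backend, as two-state hopping
is the one setting where an explicit state model beats change-points. Step
time is the midpoint of the fitted transition; the force at a step is read
from the force channel at that sample. Detection is invariant to constant
height offsets.

Dwell extraction from jump cycles keeps holds without a qualifying step as
*right-censored* records at the hold duration — discarding them would bias
lifetimes upward at low force. Events within a configurable blank interval
(0.3 s default) after a jump are ignored, mirroring the bead
re-orientation transient of real force jumps; the synthetic generator can
inject exactly such an artifact so the hazard is testable.

## Lifetime inference

The per-force point estimate is the censored-exponential maximum
likelihood `τ = (Σ all dwells)/(# ruptures)`; fully censored samples yield
a flagged unbounded estimate, not an error. The bootstrap draws M
resamples (default M = 20) of size N with replacement, estimates the rate
on each (closed-form MLE by default; the figure-style least-squares fit of
the empirical cumulative rupture probability `P(t) = 1 − exp(−kt)` is
selectable), and reports mean, standard deviation and standard error
(sd/√M) over the pool of M values for both `k` and `τ = 1/k` — the
sd-over-resamples is the standard error of the estimate itself and is what
the recovery criteria use. All-censored resamples are redrawn and counted.

`fit_bell()` is weighted least squares of `log k` on force (slope `Δ/kBT`,
intercept `log k0`), weights from the delta-method errors of `log k`.
`bell_from_dwells()` propagates bootstrap uncertainty by refitting the
line to each resample's per-force rates. Gaussian force-histogram peaks
use the closed-form MLE (one component) or deterministic model-based
mixture fitting (two components); the re-dimerization logistic
`P(F) = 1/(exp((F−Fc)Δx/kBT)+1)` is fitted by Levenberg–Marquardt least
squares, and `P(Fc) = 0.5` holds exactly by construction. A two-component
exponential-mixture EM is provided for clustered dwell populations but is
flagged as exploratory — the standard treatment fits each user-assigned
cluster separately.

## What the synthetic data does and does not emulate

The generators reproduce the statistical structure the analysis assumes:
exponential force-dependent dwells with Bell rates; block-correlated
sub-state sequences for clustered lifetimes; step-wise height traces at
200 Hz with 2–5 nm Gaussian noise under constant-force, ramp and
jump-cycle protocols; hold-window metadata; an optional decaying
force-jump artifact; and exact ground truth for every transition. Noise is
white and Gaussian — real traces have correlated bead fluctuations, drift,
and tracking artifacts; force calibration error (~10%) is metadata only.
Passing round-trip tests therefore demonstrates that the analysis chain is
self-consistent and unbiased under its own model assumptions, not that it
is robust to every instrumental pathology.

Heights are emitted relative to the initial state's extension; absolute
tether geometry and bead rotation are not modelled. Sub-rupture
transitions (un-pairing, re-pairing) move the bead by only a few nm and
are below the default detection threshold, as in the experiments.

## Problem sizes and determinism

The test suite and the acceptance checks use: 1000 Gillespie runs per
model/force for simulator-versus-solver agreement; 1000 ramp runs for the
modal-force comparison; 20 replicates of a 5-force × 50-dwell recovery
experiment; and jump-cycle round trips of 25 cycles at three forces with
σ = 3 nm at 200 Hz. These sizes give the stochastic criteria comfortable
statistical headroom while keeping the whole suite under a minute of
simulation time. Every stochastic routine takes an explicit seed, a single
seeded generator drives each simulation run, and seeds are recorded in all
result files; fixed seed means bit-identical output.

## Known limitations

* The worm-like chain is inextensible; enthalpic stretching, twist and
  torque are out of scope.
* The composite-rupture step convention approximates unstated residue
  bookkeeping (see above); its predictions carry ~5% systematic
  uncertainty.
* The multivalent model treats pairs as a linear row with end peeling;
  domain-pair re-orientation cooperativity (a plausible cause of clustered
  stability groups) is not modelled.
* Automatic clustering of dwell populations is exploratory; the supported
  analysis fits user-assigned clusters.
* The HMM backend assumes Gaussian emissions with state-specific variance
  and is intended for few-state hopping, not for arbitrary multi-level
  staircases.
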