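# mtdimer

Analysis toolkit for single-molecule magnetic-tweezers experiments on
multi-domain protein dimers — the kind of construct exemplified by
α-actinin rod dimers, where two four-spectrin-repeat rods associate
anti-parallel and are pulled in shear or unzip geometry. The package covers
the full computational chain of such an experiment:

* **Polymer mechanics** — force–extension models for the mechanical
  elements on the force path and the transition step sizes built from them.
* **Construct modelling** — declarative descriptions of looped dimer
  constructs and the mapping from a conformational state (dimerized,
  stretched, unfolded, ruptured) to a mechanical series, yielding predicted
  step-size tables over force.
* **Rupture kinetics** — Bell slip-bond rates, an exact (linear-algebra)
  mean-lifetime solver for a multivalent dimer model with boundary
  un-pairing, re-pairing and unfolding-gated re-pairing, and Gillespie
  simulators for constant force and linear force ramps.
* **Trace analysis** — FFT/moving-average smoothing, change-point and
  Gaussian-HMM step detection, dwell-time extraction from force-jump
  cycles (with honest right-censoring), rupture events from ramps.
* **Dwell inference** — censored-exponential lifetime estimation, an
  M-resample bootstrap of rupture rates, weighted Bell-model fitting with
  bootstrap-propagated uncertainties, Gaussian rupture-force peaks, and the
  re-dimerization logistic.
* **Synthetic data** — generators for dwell tables, clustered
  (slowly interconverting) lifetime sub-states and full bead-height traces
  with ground-truth annotations, so every stage is testable end to end.

## The models

A folded domain or dimer interface of span *b* behaves as a single-segment
freely-jointed chain,

x(f) = b [coth(fb/k_BT) − k_BT/(fb)],

and an unfolded stretch of N residues as a Marko–Siggia worm-like chain
with persistence length A ≈ 0.8 nm and contour length N·l₀ (l₀ = 0.38
nm/residue),

fA/k_BT = 1/[4(1 − x/L)²] − 1/4 + x/L.

The bead-height step of a conformational transition at force f is the
extension difference of the mechanical series before and after,
Δx(f) = x_after(f) − x_before(f). Force-dependent rates follow the Bell
model k(f) = k₀·exp(Δf/k_BT), and the most probable rupture force under a
force ramp of rate r is F* = (k_BT/Δ)·ln(rΔ/(k₀k_BT)). The multivalent
dimer model couples n domain pairs: only boundary pairs of the intact block
can un-pair, un-paired folded domains can rapidly re-pair, and domain
unfolding blocks re-pairing — the interplay that amplifies dimer lifetimes.

## Worked example

```r
library(mtdimer)

## predicted step sizes of the full-rod shear dimer
construct <- construct_presets("actn1_shear_full")
steps <- predicted_step_table(construct,
  standard_transitions(construct, c("unfold_one", "rupture_unfold_rest")),
  forces = c(45, 56))
print(steps, digits = 4)
#>            transition force_pN step_nm
#> 1          unfold_one       45   29.62
#> 2          unfold_one       56   30.39
#> 3 rupture_unfold_rest       45  145.59
#> 4 rupture_unfold_rest       56  149.46
```

Unfolding of one ~110-residue repeat from its 5 nm folded body produces a
~30 nm step at 45 pN; rupture concurrent with unfolding of the remaining
repeats releases the 170-residue loop linker and unravels the 480-residue
rod for a ~146 nm step.

```r
## force-clamp dwell times -> bootstrap -> Bell fit
dwells <- do.call(rbind, lapply(1:5, function(i)
  generate_dwells(bell_params(1e-3, 0.5), force = c(20, 30, 40, 50, 60)[i],
                  n = 50, rng_seed = 100 + i)))
fit <- bell_from_dwells(dwells, bootstrap_config(20, rng_seed = 1))
print(fit)
#> <bell_fit> k0 = 0.001223 /s (se 0.000236), delta = 0.4865 nm (se 0.0187)
print(fit$estimates[["40"]])
#> <lifetime_estimate> force 40 pN: tau = 5.87 s (se 0.147), k = 0.1703 /s, n = 50 (0 censored)
```

The generating parameters (k₀ = 10⁻³ s⁻¹, Δ = 0.5 nm) are recovered within
the bootstrap uncertainties.

```r
## multivalency: exact mean lifetime vs number of domain pairs
lifetime_vs_pairs(pair_kinetics(bell_params(0.5, 0.3), bell_params(2, -0.3)),
                  n_pairs = 1:4, forces = 10)
#>   n_pairs force_pN mean_lifetime_s
#> 1       1       10           0.958
#> 2       2       10           1.876
#> 3       3       10           3.035
#> 4       4       10           4.421
```

A command-line wrapper over the pipeline functions
(`predict-steps`, `generate`, `simulate`, `analyze`, `fit`) is installed at
`inst/cli/mtdimer.R`; each subcommand is driven by a YAML/JSON
configuration whose hash and seeds are echoed into every output file.

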