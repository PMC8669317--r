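# mpva — meta-population viability analysis for island-breeding seabirds

Most threatened seabirds breed on islands, where invasive predators
(rats, cats, pigs) depress chick production and adult survival, and
where management can actually act: eradicate the invasives, reduce
at-sea mortality, or move birds to safer islands. `mpva` is a toolkit
for asking, consistently across species, *how much does each action
reduce extinction risk?* It is aimed at quantitative conservation
ecologists who need comparable 100-year projections for many species,
including data-poor ones — not a replacement for a carefully tailored
single-species model.

## The model

The demographic core is a three-stage female projection matrix
(sub-adult, breeding adult, non-breeding adult) under a pre-breeding
census:

```
A = | s1 (1-g)   (e/2) h f s0    0        |
    | s1 g       s2 b            s3 b     |
    | 0          s2 (1-b)        s3 (1-b) |
```

with the growth transition `g = ((s1/λ)^T − (s1/λ)^(T−1)) / ((s1/λ)^T − 1)`
solved jointly with the dominant eigenvalue λ by fixed-point iteration
(`T = AFR − 1` sub-adult years). Colonies are linked into a
metapopulation matrix `M = (IP ⊗ D) C + C`, where `C` is the block
diagonal of colony matrices, `D` the diagonal of stage emigration
probabilities, and `IP` an exponential-kernel connectivity matrix whose
columns are destination distributions (diagonal fixed at −1, so
dispersal conserves individuals).

Invasive impacts enter as cumulative log hazard ratios,

```
γ_f = [Σ_x log Δ_x] (1/X)^φ (1/Area)^ψ ,   f' = f^exp(γ_f)
```

with the adult analogue using
`log Ω_x = ζ_x β1 log(Δ_x)/(1/AdSz + 1)^β2`. φ interpolates between
additive (0) and compensatory (1) mortality from multiple invasives; ψ
shrinks per-capita impacts on larger islands. The hazard parameters are
fitted with a Bayesian state-space model (deterministic latent
stage-structured abundance, Poisson survey counts) to time series from
islands where invasives were present or removed. Vital-rate priors are
maximum-likelihood fits to literature records weighted 20×/5×/1× by
same-species / same-genus / same-family relatedness, and categorical
IUCN-style trend labels (Increasing / Stable / Decreasing / Unknown)
update the posteriors through 100 pseudo-observed growth rates. Forward
projections run two nested loops (parameter draws × stochastic
replicates) with density-dependent fledging `f/(1+(N/K)^θ)`,
spatiotemporally correlated environmental noise (lag-1 r = 0.67;
between-colony r = 0.9 at 100 km, 0.5 at 1000 km), beta-sampled
demographic noise below 100 individuals, and report quasi-extinction
probability (QEP) and projected abundance under management scenarios.

Everything is testable offline: `make_world()` /
`make_removal_experiment()` generate every input format with known
ground truth.

## Worked example

Compare quasi-extinction risk with and without rat eradication on the
two invaded islands of a three-island metapopulation:

```r
library(mpva)
conf <- species_config(
  islands = list(
    list(id = "a", area = 1.5, K = 3000,
         assemblage = invasive_assemblage("rat", area = 1.5)),
    list(id = "b", area = 0.8, K = 2000,
         assemblage = invasive_assemblage("rat", area = 0.8)),
    list(id = "c", area = 3, K = 2500)),
  AFR = 4,
  geometry = colony_geometry(distances = matrix(c(0, 120, 300, 120, 0,
                                                  200, 300, 200, 0), 3)),
  dispersal = dispersal_spec(),
  hazards = hazard_parameters(delta_x = c(rat = 1.4), phi = 0.5,
                              psi = 0.1, beta1 = 0.5, beta2 = 1))
v <- vital_rates(0.55, 0.78, 0.91, 0.89, 0.85, 1.5, 0.72, 0.68, 4)
init <- initialize_population(stable_stage_distribution(build_matrix(v)),
                              totals = c(600, 400, 300))
samples <- cbind(s0 = rep(v$s0, 40), s1 = v$s1, s2 = v$s2, s3 = v$s3,
                 b = v$b, e = v$e, h = v$h, f = v$f)
run_full(samples, conf, init, scenario_default(), NS1 = 10, NS2 = 25,
         seed = 7)
run_full(samples, conf, init, scenario_invasive_removal(c(1, 2)),
         NS1 = 10, NS2 = 25, seed = 7)
```

```
mPVA projection (default scenario, QE = 50 females)
       median     se iqr_lo iqr_hi
N_proj    0.0 6.2435   0.00   0.00
QEP       0.6 0.0196   0.56   0.64

mPVA projection (invasive_removal scenario, QE = 50 females)
        median      se  iqr_lo   iqr_hi
N_proj 85.6246 27.1252 52.9087 157.3788
QEP     0.4800  0.0259  0.4500   0.4800
```

Read: under current threats the median projected abundance after 100
years is below the 50-female quasi-extinction threshold and 60% of
trajectories cross it; eradicating rats on both invaded islands leaves
a median of ~86 females and drops the century-scale quasi-extinction
probability to 48%. (Tiny replicate counts here for a fast example —
use the `NS1 = NS2 = 100` defaults for real comparisons.)

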