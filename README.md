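# pmkinetics

Model-based analysis of Biolog Phenotype MicroArray (PM) kinetic data.

PM plates read the respiration of an organism on 96 substrates at once:
each well's tetrazolium-dye signal is recorded every 15 minutes for
about 48 hours, giving one *metabolic profile* per substrate. Studies
typically compare such plates across a two-factor design (for example
strain × temperature) with replicate plates per condition. `pmkinetics`
implements a three-stage pipeline for these data:

1. **Grouping** — classify each well as *active* or *non-active* with a
   hard-assignment EM algorithm over a two-model mixture: active
   profiles follow a logistic curve
   `F(t) = Asym / (1 + exp((xmid − t)/scale))`, non-active profiles a
   line `b0 + b1·t`. An optional activity threshold pre-filters wells
   and lets a plate with no activity at all bypass the EM.
2. **Normalization** — remove multiplicative array effects by fitting
   per-plate, per-group *base curves*, choosing the replicate closest
   to the others (in summed Euclidean base-curve distance) as the
   reference, and scaling every other array by the normalization factor
   `NF = Σ base(reference) / Σ base(array)` — separately for the active
   and non-active groups, optionally after stabilizing labels across
   replicates.
3. **Effect identification** — a Bayesian hierarchical two-factor
   variance analysis with interaction on denoised fitted values at
   thinned time points: `y ~ N(μ, σ²)` with
   `μ = ζ_t + α_{a,t} + β_{b,t} + γ_{ab,t}` relative to a control
   condition, sampled by an internal Gibbs sampler (all full
   conditionals are conjugate). Effects are significant when their 95%
   credible interval excludes zero; `σ²` is the user's sensitivity
   knob.

A seeded synthetic-data generator (`simulate_experiment()`) produces
complete factorial PM experiments with known ground truth, so every
stage is testable end to end without any real data.

## Worked example

Simulate a 12-plate experiment (2 × 2 conditions × 3 replicates, known
array effects 1.1 / 1.0 / 0.9) in which well A01 carries condition
effects on its logistic asymptote (α = −50, β = −150, γ = −120), then
run the three stages:

```r
library(pmkinetics)

sim <- simulate_experiment(
  n_wells = 12, times = seq(0, 47.5, by = 0.5), active_fraction = 1,
  asym_range = c(335, 360), noise_sd = 5,
  array_factors = setNames(rep(c(1.1, 1.0, 0.9), 4), as.character(1:12)),
  effects = list(wells = "A01", alpha = -50, beta = -150, gamma = -120),
  seed = 42
)

groupings <- lapply(sim$experiment$plates, group_plate, threshold = 100)
sapply(groupings, count_active)
#>  1  2  3  4  5  6  7  8  9 10 11 12
#> 12 12 12 11 11 11 12 12 12 11 11 11
```

All wells are active except A01 on the plates where the injected shifts
push its asymptote below the threshold. Normalization recovers the
array effects (the array scaled by 1.1 gets factor ≈ 1/1.1 relative to
the reference):

```r
norm <- normalize_experiment(sim$experiment, groupings)
subset(norm$factors, group == "active" & setup == 1)
#>   setup factor_a factor_b  group array_id reference        nf
#> 1     1       28    53/03 active        1     FALSE 0.9092161
#> 2     1       28    53/03 active        2      TRUE 1.0000000
#> 3     1       28    53/03 active        3     FALSE 1.1113762
```

Effect identification on A01 flags all three injected effects with the
right signs (time-averaged estimates are attenuated relative to the
asymptote shifts because all curves coincide near t = 0; the
time-point-wise rows of the same summary show the full late-time
magnitudes):

```r
eff <- run_effects(
  norm, tstar = thin_timepoints(sim$experiment$times, stride = 16),
  wells = "A01", sigma2 = 100, n_iter = 2000, burn_in = 500,
  n_chains = 2, seed = 1
)
subset(eff, time == "averaged")
#>  substrate effect_type level_a level_b     time   mean   lower  upper significant
#>        A01     control      28   53/03 averaged 235.39  231.43 239.43          NA
#>        A01           A      37   53/03 averaged -33.99  -40.26 -28.03        TRUE
#>        A01           B      28   8081c averaged -94.37 -100.34 -88.27        TRUE
#>        A01 interaction      37   8081c averaged -81.03  -89.96 -72.24        TRUE
```

`run_pipeline()` wires the stages together from a metadata CSV or YAML
config and writes labels, factors, normalized plates and the effects
table as CSVs. The same operations are available from a shell via the
installed script:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "pmkinetics.R", package = "pmkinetics"))')" \
    simulate --out sim_dir --seed 1
```

with subcommands `simulate`, `group`, `normalize`, `effects` and `run`.

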