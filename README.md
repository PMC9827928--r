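# c4leak

Continuous estimation of bundle-sheath CO₂ leakiness (ϕ) in C4 leaves
through photosynthetic induction, from a gas-exchange system coupled to a
tunable diode laser absorption spectroscope (TDL).

## The problem

C4 plants such as maize and sorghum concentrate CO₂ into their
bundle-sheath cells at a cost of 2 extra ATP per PEP carboxylation. The
bundle sheath is not gas-tight: a fraction ϕ of the CO₂ released there
diffuses back to the mesophyll and must be pumped again, so the ATP cost
of a net CO₂ rises as `3 + 2/(1 − ϕ)`. At steady state in high light
ϕ ≈ 0.2 in NADP-ME species, but leaves in crop canopies are rarely at
steady state. This package implements a measurement pipeline that tracks
ϕ every 10 s through a dark-to-high-light induction, where transient
decoupling of the C4 (PEPC) and C3 (Rubisco) cycles elevates ϕ — and with
it the energy cost of assimilation.

ϕ is estimated by comparing observed online ¹³C photosynthetic
discrimination with the Farquhar-type C4 discrimination model. The TDL
measures ¹²CO₂ and ¹³CO₂ of the air entering and leaving the leaf
chamber; observed discrimination is

    Δ¹³C_obs = 1000 ξ (δ_s − δ_r) / (1000 + δ_s − ξ (δ_s − δ_r)),
    ξ = C_ref / (C_ref − C_samp)

Bundle-sheath CO₂ (C_bs) and the component fluxes (V_p, V_c, V_o) come
from the von Caemmerer light-limited C4 model, with the total electron
transport rate J_t obtained as the admissible root of a quadratic in the
measured net assimilation. Leakiness (infinite mesophyll conductance,
C_m = C_i) is then

    ϕ = (C_bs − C_i)/C_i ·
        [(1 − t) Δ¹³C_obs C_a − a′(C_a − C_i) − (1 + t) C_i b₄] /
        [(1 + t)(b₃ C_bs − s(C_bs − C_i)) + a′(C_a − C_i) − (1 − t) Δ¹³C_obs C_a]

with the ternary factor t, combined diffusional fractionation a′ and the
effective carboxylation fractionations b₃, b₄ (respiration and
photorespiration folded in). Because ξ amplifies instrument noise, every
point carries the error model `error = 2 ξ X` (X = laser precision of a
10 s average) and points whose relative error exceeds 50% are flagged.

The pipeline covers the full instrument chain: concentration-series
calibration of the TDL with drift correction across 740 s measurement
cycles, 10 s block averaging, chamber washout / transport-delay
correction, the biochemical inversion, and kinetic characterisation of
the induction (piecewise fits, decline time constant, IT50/IT90, window
means, ATP costs). A forward simulator generates both instrument streams
from a prescribed ϕ(t), so the entire inversion is verifiable by
parameter recovery.

## Worked example

Simulate a sorghum-like induction experiment (reference CO₂
800 µmol mol⁻¹, flow 300 µmol s⁻¹, leaf at 27 °C, ϕ rising to 0.35 at
290 s then decaying with a 500 s time constant to 0.18, laser precision
0.24‰) and run the analysis:

```r
library(c4leak)

sc  <- synthetic_scenario(seed = 42)
sim <- simulate_run(sc, tempfile())

cfg <- config_from_scenario(sc)
cfg$paths$gasex <- sim$paths$gasex
cfg$paths$tdl   <- sim$paths$tdl
run <- run_analysis(cfg)
print(run)
#> c4leak analysis run: 177 sample blocks, 64 usable leakiness points
#>   phi mean_600 = 0.313, mean_1500 = 0.286, steady = 0.236
```

A single noisy run is dominated by the high-ξ early blocks; the bench
protocol measures eight replicate plants and averages, which
`run_simulate_then_analyze()` reproduces:

```r
rec <- run_simulate_then_analyze(sc)
print(rec)
#> Recovery over 131 points (8 replicates):
#>   phi RMSE = 0.0129 (max |err| = 0.0510)
#>   t_peak: true 290 s, recovered 365 s (err +75 s)
#>   tau_phi: true 500 s, recovered 431 s (err -13.8%)
```

The replicate-mean ϕ̂(t) tracks the hidden truth to about 0.013 RMSE;
the piecewise fit of the mean curve returns the time of peak leakiness
and the exponential decline constant. Induction kinetics of assimilation
come from the same run:

```r
m <- run$metrics
c(IT50 = m$induction_times$IT50, IT90 = m$induction_times$IT90,
  tau_A = m$rubisco$tau_A)
#>  IT50  IT90 tau_A
#>   263   728   297
atp_cost(0.2)    # ATP per net CO2 at steady-state leakiness
#> [1] 5.5
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/c4leak.R simulate --out sim/ --seed 4
Rscript inst/cli/c4leak.R analyze  --config run.yaml --out results/
Rscript inst/cli/c4leak.R recover  --seed 4
```

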