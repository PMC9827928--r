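---
title: "Estimating bundle-sheath leakiness through photosynthetic induction: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating bundle-sheath leakiness through photosynthetic induction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c4leak)
```

## The measurement and its model

Bundle-sheath leakiness ϕ is the fraction of CO₂ released by C4-acid
decarboxylation in the bundle sheath that diffuses back to the mesophyll
instead of being refixed by Rubisco. It cannot be measured directly; it
is inferred by comparing *observed* online ¹³C photosynthetic
discrimination with the discrimination a biochemical model predicts for
the same leaf state.

The instrument chain couples an open gas-exchange system to a tunable
diode laser spectroscope (TDL) that measures the ¹²CO₂ and ¹³CO₂ mole
fractions of the air entering (`ref`) and leaving (`samp`) the leaf
chamber. Observed discrimination at each 10 s block is

$$\Delta^{13}C_{obs} = \frac{1000\,\xi\,(\delta_s-\delta_r)}
  {1000 + \delta_s - \xi(\delta_s-\delta_r)},
  \qquad \xi = \frac{C_{ref}}{C_{ref}-C_{samp}},$$

where ξ is computed from ¹²CO₂ mole fractions. ξ is also the noise
amplifier of the method: the uncertainty of a block is modelled as
$2\xi X$ with $X$ the laser precision of a 10 s average (0.24‰ for the
configuration emulated here), and blocks whose relative error exceeds
50% are flagged as uninformative.

The biochemical side is the von Caemmerer light-limited C4 model. From
net assimilation $A$, day respiration $R_d$ (mesophyll share
$R_m = 0.5R_d$) and mesophyll CO₂ $C_m = C_i$, the total electron
transport rate $J_t$ is the root of a quadratic derived from the
mesophyll mass balance $g_{bs}(C_{bs}-C_m) = xJ_t/2 - A - R_m$ combined
with the bundle-sheath relations; the admissible root must satisfy
$(1-x)J_t/3 > A+R_d$ (positive bundle-sheath CO₂). The state then
follows: $V_p = xJ_t/2$, $O_s = \alpha A/(0.047 g_{bs}) + O_m$,
$C_{bs} = \gamma^* O_s\,(7(A+R_d)/3 + (1-x)J_t/3)\,/\,((1-x)J_t/3 -
(A+R_d))$, $V_c = (A+R_d)/(1-\gamma^*O_s/C_{bs})$ and
$V_o = 2(V_c - A - R_d)$, so $A = V_c - V_o/2 - R_d$ holds identically.

Leakiness (assuming infinite mesophyll conductance) follows from the
full C4 discrimination model,

$$\phi = \frac{C_{bs}-C_i}{C_i}\;
  \frac{(1-t)\Delta^{13}C_{obs}C_a - a'(C_a-C_i) - (1+t)C_i b_4}
       {(1+t)\bigl(b_3 C_{bs} - s(C_{bs}-C_i)\bigr) + a'(C_a-C_i)
        - (1-t)\Delta^{13}C_{obs}C_a},$$

a ratio of terms affine in $\Delta^{13}C_{obs}$, which makes the forward
map (Δ for a prescribed ϕ) closed-form — the property the synthetic-data
generator relies on. The effective fractionations fold respiratory and
photorespiratory isotope effects into the carboxylation terms:
$b_3 = b_3' - e'R_d/V_c - fV_o/V_c$, $b_4 = b_4'(T) - e'R_m/V_p$ with
$b_4'(T) = -9483/(273+T) + 26.09$ and
$e' = e + \delta^{13}C_{ref} - \delta^{13}C_{gatm}$.

### Constants

| symbol | default | units | meaning |
|---|---|---|---|
| a, a_b | 4.4, 2.9 | ‰ | stomatal / boundary-layer fractionation |
| b₃′ | 30 | ‰ | Rubisco carboxylation fractionation |
| b₄′(27 °C) | −5.52 | ‰ | CO₂ dissolution + hydration + PEPC |
| s | 1.8 | ‰ | fractionation during bundle-sheath leakage |
| f | 11.6 | ‰ | photorespiratory fractionation |
| e | 0 | ‰ | decarboxylation fractionation |
| g_bs | 0.00113 | mol m⁻² s⁻¹ | bundle-sheath CO₂ conductance |
| x | 0.4 | — | ATP share of the C4 cycle |
| α | 0 | — | PSII share in the bundle sheath |
| γ* | 0.000193 | — | half reciprocal Rubisco specificity |
| O_m | 210000 | µmol mol⁻¹ | mesophyll O₂ |
| δ¹³C_gatm | −8 | ‰ | growth-air CO₂ signature |
| R (VPDB) | 0.0111797 | — | ¹³C/¹²C of the delta scale |

All are overridable through `c4_constants()` or the `constants:` block of
a configuration file, and the effective values are echoed into every
run's metadata. Two published values deserve comment. The
photorespiratory fractionation is sometimes tabulated as 1.6‰; the
primary sources give 11.6‰ and that is the default here, with the
alternative available as an override. The VPDB ratio never enters the
physics (both isotopologues are measured); it only anchors the delta
notation, so its exact value cancels from Δ¹³C_obs.

All CO₂ and O₂ quantities are mole fractions in µmol mol⁻¹ of dry air.
Helper conversions from partial pressures are deliberately not built
into the model core: mixing the two unit systems is the most common
error in this calculation.

## Instrument processing

**Cycle segmentation.** The TDL cycles through eight gas streams —
CO₂-free air, three dilutions of one CO₂ source (identical isotopic
composition), a certified tank, the reference line, 600 s of chamber
air, and the reference again — 740 s per cycle. The first 10 s of every
phase is discarded while the line flushes; the rest is averaged in 10 s
blocks (59 chamber blocks per cycle), with block timestamps at block
centres.

**Calibration.** Each isotopologue is calibrated with a straight line
`measured = gain·true + offset` against the known dilution series; the
tank provides an independent QC residual. Because the laser drifts, the
gain is allowed to move linearly in time. Two estimators are provided:
per-cycle fits interpolated between neighbouring cycles
(`calibration_drift: "per_cycle"`), and the default single regression
`measured = (g₀+g₁t)·true + offset` pooled over all cycles
(`"global"`). The two are identical in expectation for linear drift, but
the per-cycle estimator leaves independent parameter noise in each
cycle's corrected ¹³CO₂, which shifts whole 600 s segments of ϕ(t)
coherently and corrupts the decline time constant; pooling removes that
term. For the per-cycle estimator the fit is anchored at the
leverage-weighted mean time of its calibration blocks, which makes
linear-drift interpolation exact rather than approximately centred.

**Reference air.** The per-cycle convention averages the reference
blocks bracketing each sample phase. The pipeline default
(`reference_pooling: "pooled"`) averages all reference blocks of the
run: the reference is one tank, stationary after drift correction, and
its per-cycle reading error (≈ X/√2 ≈ 0.17‰) is otherwise the largest
cycle-correlated error source in ϕ(t). The bracketed convention remains
available and is what `pair_reference()` implements.

**Delay correction.** The chamber (volume V, flow f) mixes as a
first-order system with τ = V/(f·V_m); the chamber-to-laser plumbing
adds a transport lag. The default correction is a pure time shift of the
TDL block timestamps by the transport lag, with first-order
deconvolution (adds τ·dC/dt) available but off by default — the shift
captures the first-order behaviour and deconvolution amplifies block
noise. The delay simulator integrates
`dC/dt = S_leaf (A_app(C) − A′(t)) V_m / V` on a fixed 0.1 s grid using
the exact exponential step for linear-in-step forcing rather than an
explicit Runge–Kutta rule: the explicit rule is unstable once the step
exceeds ~2.8τ, which forecloses the vanishing-volume limit, while the
exponential step is unconditionally stable, collapses exactly to the
instantaneous response as V → 0, and is second order in the forcing
curvature at negligible cost.

## Kinetic characterisation

The ϕ(t) time course is summarised by a piecewise fit (grid search over
observed timestamps; flat / linear / exponential segments;
`y = y₀ + A₁·exp(−(t−t_b)/t₁)` for the decline), the time of peak
leakiness (end of the rising segment), the decline constant t₁, window
means of ϕ over (0, 600] s, (0, 1500] s and beyond 1500 s, the induction
times IT50/IT90 of assimilation, and the Rubisco-activation constant
τ_A from the semilog slope of ln(A_f − A) over 300–900 s.

Two fitting variants exist. Independent per-segment least squares is the
default and is how per-segment R² values are conventionally reported.
For noisy data the independent fit's SSE landscape is nearly flat in the
breakpoint, so the replicate-recovery analysis uses the
continuity-constrained variant (`continuity = TRUE`): segments share the
breakpoint value, leaving four free parameters plus the breakpoint. On
replicate-mean curves this halves the breakpoint scatter. Points can be
inverse-variance weighted; the recovery weights by the across-replicate
standard error so the high-ξ early blocks cannot dominate the search.

The error rule interacts with the kinetics in a subtlety worth stating.
At steady state Δ¹³C_obs ≈ 2‰ while the error is ≈ 1.2‰, so a literal
per-point "> 50%" exclusion, applied to noisy single blocks, randomly
deletes about half of the steady-state points — and the survivors are
selected for high Δ, biasing ϕ̂ upward. Operationally the rule marks
when the measurement *becomes* informative: the replicate-level recovery
therefore applies it to the replicate-mean discrimination as an initial
exclusion onset (everything before the first crossing below 50% is
discarded; later marginal re-crossings of a declining signal do not
re-exclude), while single-run outputs carry the literal per-point flags.
Window means use only included points in both cases.

## The synthetic-data generator

`synthetic_scenario()` forward-simulates the complete experiment so the
whole inversion is testable by parameter recovery. The defaults describe
a sorghum-like run: A_f = 40 µmol m⁻² s⁻¹ approached with τ_A = 300 s
(net assimilation starts at −R_d in darkness), stomata opening
sigmoidally 0.04 → 0.57 mol m⁻² s⁻¹ (half-time 300 s, slope 100 s),
reference CO₂ 800 µmol mol⁻¹ at 300 µmol s⁻¹, leaf area 24 cm² (giving
the observed steady drawdown to ≈ 480 µmol mol⁻¹ and ξ ≈ 2.5), leaf at
27 °C, R_d = 1.5, chamber volume 0.3 L, transport lag 20 s, and a true
leakiness that rises linearly from 0.23 to 0.35 at 290 s before decaying
with τ_ϕ = 500 s toward 0.18. The TDL stream is emitted at 10 Hz with
the full cycle structure; noise is Gaussian per raw sample, apportioned
between the isotopologues so a 10 s block δ has precision X = 0.24‰, and
a linear gain drift (10⁻⁶ s⁻¹) tests the calibration chain. Gas-exchange
records carry independent noise on A (σ 0.2 µmol m⁻² s⁻¹) and g_s
(σ 0.005 mol m⁻² s⁻¹), with the CO₂ cascade re-derived from the noisy
values as a real instrument would.

Two deliberate simplifications keep the generator honest about what it
tests. First, the "true" leaf state is defined at the level the
instruments see: logged assimilation is the apparent (chamber-mixed)
rate, and Δ_true is constructed from ϕ_true through the forward model at
that state, so a noise-free run must invert to ϕ_true exactly (observed:
max |ϕ̂ − ϕ_true| < 10⁻¹¹) — the generator validates the inversion, not
the chamber physics. Second, the raw TDL samples within one 10 s block
carry the block-centre truth value (the induction signal has no
sub-block structure), which makes block averaging exactly invertible;
noise still enters per raw sample.

What passing recovery tests therefore *do* show: the calibration, drift
correction, alignment, discrimination arithmetic and biochemical
inversion are mutually consistent and recover a known ϕ(t) under
realistic noise (RMSE ≈ 0.012 over eight replicates, the study's sample
size). What they do *not* show: that the biochemical model itself is
correct for a real leaf (its assumptions — C_m = C_i, infinite mesophyll
conductance, constant g_bs and γ*, R_m = 0.5R_d — are inherited, not
tested), nor that chamber mixing is exactly first-order, nor anything
about mesophyll-conductance dynamics during induction.

Under the default noise the recovered peak time scatters by roughly
±30–50 s across random seeds and the decline constant by ±10–15%; RMSE
of the replicate-mean curve is stable near 0.012. The exclusion onset
lands between 180 and 250 s, bracketing the ≈ 150 s at which the
signal-to-error ratio of this configuration crosses 50%.

## Problem sizes

The test suite and the acceptance analysis run the generator at the
study scale: 30 min runs logged at 10 s (178 records), three 740 s TDL
cycles at 10 Hz (~22 000 raw samples), eight replicates for the noisy
recovery, and 1000 random leaf states for the inversion oracle. The full
suite completes in under a minute on one core.

## Known limitations

* The finite-mesophyll-conductance variant of the inversion is out of
  scope; only the C_m = C_i form is implemented.
* Temperature dependence of γ* and g_bs is not modelled (both constant).
* The calibration model is strictly linear per isotopologue; curvature
  in the laser response would alias into concentration-dependent δ bias.
* `estimate_lag()` assumes a single dominant transient; periodic signals
  alias.
* The exclusion-onset rule assumes the error ratio declines through
  induction (true whenever drawdown grows monotonically); a pathological
  non-monotone run would need the per-point rule.
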