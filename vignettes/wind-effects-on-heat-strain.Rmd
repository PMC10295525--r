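---
title: "Methods: temperature-humidity-dependent wind effects on heat strain and the UTCI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wind effects on heat strain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models implemented in `heatwind`, the choices
behind the synthetic data generator, and the numerical decisions a user
should know before trusting or changing defaults. It states no empirical
result beyond what the package's tests and the acceptance script themselves
compute.

## 1. The scientific setting

Increased air movement can either relieve or aggravate physiological heat
strain. Below air temperatures of about 35 °C (typical skin temperature),
stronger wind always increases convective heat loss. Above it, convection
turns into a heat gain, but wind still accelerates sweat evaporation — so in
humid heat the net effect remains cooling, while in hot-dry conditions,
where evaporation is already maximally efficient, added wind heats the body.
The package quantifies this transition in two independent ways and compares
them:

1. an **environment-side index**: the Universal Thermal Climate Index
   (UTCI), an equivalent temperature derived from a dynamic thermoregulation
   model for a walking reference person (4 km/h, 2.3 MET), evaluated via its
   published operational-procedure polynomial; and
2. a **physiology-side estimate**: penalized spline regression surfaces
   fitted to trial-level heat-strain responses measured under a reference
   and an elevated wind speed.

## 2. UTCI engine

The operational procedure approximates the full model by
`UTCI = T_a + offset(T_a, v_a10m, ΔT_mrt, p_a)` with the offset a complete
polynomial of total degree 6 in its four arguments — all
`choose(10, 4) = 210` monomials. The coefficients are embedded as named
constants in the reference-source ordering; a structural test asserts the
term set is exactly the complete degree-6 basis. Inputs and units:

| input | unit | validity |
|---|---|---|
| air temperature `t_air` | °C | −50 … 50 |
| vapor pressure `p_vap` | kPa | 0 … 5, and ≤ saturation (rH ≤ 100 %) |
| mean radiant temperature `t_mrt` | °C | `t_mrt − t_air` in −30 … 70 K |
| wind speed at 10 m `v10` | m/s | 0.5 … 17 |

Out-of-validity conditions raise errors with the offending row and values;
nothing is clamped, because the analysis grids are explicitly restricted to
the validity window. Humidity is kPa everywhere in the public interface; the
saturation pressure uses Hardy's ITS-90 formulation (evaluated in Pa
internally, returned in kPa), which reproduces standard psychrometric tables
(3.17 kPa at 25 °C, 0.611 kPa at 0 °C).

Two wind conversions accompany the polynomial. The logarithmic profile with
0.01 m roughness length gives person level speed `v1 = v10/1.5`. The
angle-averaged relative air velocity of a walker with speed `v_w = 1.1` m/s
is the mean over all wind-to-walking angles of the vector difference
magnitude; it is evaluated by 3600-point trapezoidal quadrature over the
angle. The closed form `(2/π) √(A+B) E(k)` with the complete elliptic
integral of the second kind serves as the independent oracle in the tests
(agreement required to 1e−6 m/s). A known artifact worth stating: being a
degree-6 fit, the polynomial wiggles slightly at the corners of its domain —
e.g. UTCI is not strictly increasing in humidity in the very dry range at
45–50 °C. Tests assert monotonicity away from that corner.

## 3. Wind-effect mapping

The wind effect is `Δ_v UTCI = UTCI(v10_hi) − UTCI(v10_ref)` cellwise over a
psychrometric grid, all other inputs fixed; `v10_ref = 0.5` m/s is the UTCI
reference (person-level 0.3 m/s). Defaults follow the study conditions:
T_a 25–50 °C × p_a 0.1–5 kPa, `T_mrt = T_a`, with the elevated wind 3 m/s
(person level 2 m/s). Grid steps (0.5 °C × 0.1 kPa) are a resolution choice,
not part of the science; threshold claims in the tests are also checked at
2× refinement, and the zero-crossing utilities work on the continuous
function (bisection), so they cannot depend on the grid.

Cells with `p_vap` above saturation or above 5 kPa are masked out, not
clamped. Percentile summaries (P0/P25/P50/P75/P100) are computed over the
masked grid; whether a rectangular or rH-masked grid is used changes the
percentiles slightly since the excluded supersaturated cells would carry
strong cooling values — the masked grid is the documented choice, as only it
lies inside the index's validity.

The zero-effect contour is extracted by marching squares with linear
interpolation and each vertex is refined by 1-D bisection of the continuous
UTCI difference to |Δ| < 0.01 K. Where the field is locally flat along both
axes within one grid step, the marching-squares vertex is kept unrefined.

The radiant sensitivity statistic is defined as the unmasked-cell mean of
`UTCI(ΔT_mrt = 10 K) − UTCI(ΔT_mrt = 0)` at reference wind; the sweep
utility evaluates the 3 × 4 combinations of wind (3/4/6 m/s) and radiant
load (0–30 K).

## 4. Synthetic trial generator

The experimental database is not public, so the generator reproduces its
*statistical structure*, not its measurements. Fixed by the study design:
5 subjects, 10 series (one per subject × wind condition) of 16–25 trials,
97 reference-wind and 101 high-wind trials, conditions quasi-uniform over
T_a 25–55 °C × p_a 0.5–5.3 kPa under rH ≤ 100 % (rejection sampling),
premature abort when rectal temperature exceeds 38.5 °C, and six local skin
temperatures whose 0.05/0.20/0.15/0.20/0.25/0.15 weighted mean (head, chest,
back, arm, thigh, leg) equals the generated mean skin temperature exactly.

Each noise-free response is

    truth(T_a, p_a, wind) = mean + amplitude * (logistic((h − h0)/hw) − c0)
                            + 1{HiWind} * M * tanh(d(T_a, p_a))

with heat-load score `h = T_a + 3 p_a` (3 °C/kPa trades humidity against
temperature at roughly the rate the strain responses do), ramp center
`h0 = 48`, width `hw = 6`, and `c0` the ramp's mean over the design region so
that the population mean of each response equals its configured intercept
(102.5 bpm, 37.6 °C, 35.5 °C, 744.4 g/h). The wind-effect surface uses the
signed score `d = min((T_a − 35)/5, (p_thr − p_a)/1)`, positive exactly in
the hot-dry region `T_a > 35 °C, p_a < p_thr`, zero exactly on its boundary
— the configurable threshold curve (defaults 2 kPa for HR/T_re, 3 kPa for
T_sk/SR). `min` of two smooth ramps is continuous but has a crease along the
diagonal where both arguments are equal; the spline stage is not expected to
reproduce the crease, only the smooth field around it.

Calibration choices, in units, with reasons:

* noise SDs 7.6 bpm, 0.2 °C, 0.4 °C, 120.1 g/h — the reported residual
  scales of the study's models;
* response amplitudes 45 bpm, 1.4 °C, 4 °C, 700 g/h over the heat-load
  range — spans typical third-hour steady-state responses from comfortable
  to near-tolerance conditions, and makes aborts (T_re > 38.5 °C) possible
  but rare, as in the data;
* wind-effect magnitudes 12 bpm and 0.25 °C for HR/T_re — chosen so that
  pronounced effects (>10 bpm, >0.15 °C) appear only toward 4 kPa, as
  reported; 1.5 °C and 250 g/h for T_sk/SR — larger relative to their noise
  because wind acts directly on skin convection and evaporation, which is
  also why the index agrees best with these two responses;
* subject-intercept SDs 2 bpm, 0.15 °C, 0.3 °C, 80 g/h — plausible
  inter-individual spread for five acclimated young males; the study reports
  no values, and these are not claimed to match it (HR's small value encodes
  the observation that individual influences on HR were not significant);
* independent dropout probability 0.02 per response (HR, T_sk, SR) on top of
  the abort rule, emulating the handful of missing values per response
  without targeting exact counts. T_re stays observed in aborted trials
  (the probe records up to the abort).

What the generator does **not** emulate: minute-resolution time courses,
hidromeiosis (sweat suppression under prolonged skin wetness), acclimation
dynamics, fluid-intake correction (SR is generated as the corrected
quantity), clothing, and any population beyond young fit males. Passing
tests therefore demonstrate that the pipeline recovers known smooth surfaces
under realistic noise, sample size and censoring — not that it would handle
the dynamics or demographics the generator omits.

## 5. Strain surface GAMs

Per response, with trial `j` of subject `i`:

    E[Y_ij] = µ + s(ID_i) + te(T_a, p_a) + te_Δv(T_a, p_a) + ε_ij,  ε Gaussian

* `te(T_a, p_a)`: tensor product of two cubic regression spline bases of
  rank 9 (total rank 81), sum-to-zero constrained (80 columns);
* `te_Δv(T_a, p_a)`: the same tensor basis multiplied by the HiWind
  indicator — zero on all reference rows, so its evaluation *is* the
  HiWind-minus-RefWind difference surface. It is deliberately uncentered
  (81 columns): centering would force the wind effect to average zero and
  absorb the level shift into other terms, breaking the difference
  interpretation;
* `s(ID)`: random subject intercept, i.e. ridge-penalized indicator
  coefficients (rank 5 for five subjects);
* smoothing parameters by maximum likelihood (`method = "ML"`, as in the
  original analysis; REML is available as an option since the two are easy
  to confuse and give slightly different shrinkage);
* complete-case rows per response.

Fitting is delegated to `mgcv::gam`; the package's contribution is the
coding, the difference-surface evaluation and the downstream analysis. A
test verifies that at fixed smoothing parameters the fit equals a direct
ridge-augmented normal-equations solve to 1e−8.

The difference surface is evaluated as the difference of the two linear
predictor rows (HiWind minus RefWind), with pointwise SE from the Bayesian
coefficient covariance and two-sided Wald p-values for Δ_v = 0. Testing is
deliberately **pointwise** at α = 0.05 with no multiplicity correction —
the maps answer "where is the effect distinguishable from zero cell by
cell", matching how such difference maps are read; a familywise-corrected
map would be markedly more conservative. Under a generator with no wind
effect, the fraction of supported cells flagged significant averages close
to the nominal 5 % (the test suite checks 5 % ± 4 % over 50 replicates).

Cells outside the data support are flagged rather than dropped: the support
region is the convex hull of the observed (T_a, p_a) points dilated by one
grid step. The dilation acknowledges that a spline prediction half a step
beyond the outermost design point is still informed by data; anything
further is extrapolation.

Smooth-term summaries report effective degrees of freedom, reference df and
Wald F/p-values from the penalized-coefficient covariance. Several published
variants of this test exist; the package uses the one implemented by
`summary.gam`, and the package's own calibration claims rest on the
synthetic-null simulations rather than on reproducing any specific reported
p-value. Adjusted R² is reported as mgcv computes it, i.e. including the
variance explained by the subject intercepts.

Problem sizes used in the shipped tests were chosen to mirror the study
scale (198 trials) where the claim is about study-scale behavior, with a
5-fold larger design for noiseless-recovery checks and 50 replicates for the
calibration property.

## 6. UTCI-physiology comparison

At the experimental (T_a, p_a) conditions, both the UTCI wind-effect field
and the fitted physiological difference surface are interpolated bilinearly;
conditions outside either support (e.g. trials above 50 °C, beyond the UTCI
grid) are dropped with a warning. The comparison is deliberately based on
the *fitted* surfaces, not raw paired trials: the design has no exactly
paired conditions across wind levels, and the surface pools information
across neighbors exactly as the original analysis does.

Agreement is summarized by the Spearman rank correlation (mid-ranks for
ties, two-sided p from the t approximation) and by the binary classification
of heating events: truth `Δ_v physio > 0`, prediction `Δ_v UTCI > 0`, both
strict, so exact zeros count as non-heating; sensitivity is reported as NA
when no positive truth case exists. Both statistics depend only on ranks and
signs, hence are invariant to monotone transforms of either effect scale. By
default all supported conditions enter; a `significant_only` switch
restricts to cells with pointwise-significant physiological effects, since
it is unknowable from the published analysis which choice was made there.

## 7. Known limitations

* The UTCI is used only through its polynomial approximation; the dynamic
  thermoregulation model behind it is out of scope, so conclusions inherit
  the polynomial's approximation error (up to a few tenths of a kelvin, and
  the corner wiggles noted above).
* The generator's truth surfaces are parametric conveniences (logistic ramp,
  tanh threshold), not heat-balance physics; parameter-recovery results
  certify the estimator, not the physiology.
* The zero-contour position recovered from 198 noisy trials carries sampling
  uncertainty of the order of 1–2 °C / 0.3–0.5 kPa; the tests assert median
  tracking of the truth curve within 2 °C / 0.5 kPa, not pointwise accuracy.
* Cold-side wind-chill assessment and UTCI categories below "no thermal
  stress" are not implemented.
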