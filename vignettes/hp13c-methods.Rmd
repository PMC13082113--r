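---
title: "Models and methods behind hp13c"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hp13c}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hp13c)
```

This vignette is the package's own account of its science: the forward
and inverse kinetic models, the map and ROI conventions, what the
synthetic generator does and does not emulate, and the numerical and
design choices made where more than one reasonable option existed.

## The three-pool exchange model

After an intravenous bolus of hyperpolarized [1-¹³C]pyruvate, the
longitudinal magnetizations of pyruvate (P), lactate (L) and
bicarbonate (B) in a voxel evolve as a unidirectional two-site exchange
from pyruvate into each product pool:

$$\frac{dP}{dt} = -\Big(\tfrac{1}{T_{1P}} + k_{PL} + k_{PB}\Big)P + g(t),
\qquad
\frac{dL}{dt} = k_{PL}P - \tfrac{L}{T_{1L}},
\qquad
\frac{dB}{dt} = k_{PB}P - \tfrac{B}{T_{1B}}.$$

$g(t)$ is the pyruvate inflow; back-conversion ($k_{LP}$) is neglected,
standard for the short (60 s) acquisition window. Each metabolite is
excited every $\Delta t$ with its own constant flip angle $\alpha_m$:
the measured signal is $M_z\sin\alpha_m$ and the magnetization is
reduced by $\cos\alpha_m$ — hyperpolarized magnetization is a
non-renewable resource, and this RF sampling loss is part of the model,
not a nuisance correction.

### Forward simulation

`simulate_voxel_dynamics()` advances the linear system with exact
matrix-exponential steps (the system is triangular, so the exponential
is closed-form) on a sub-grid of each sampling interval, holding $g(t)$
at its midpoint value per sub-step. The default of 60 sub-steps (50 ms
at $\Delta t = 3$ s) leaves the piecewise-constant treatment of the
bolus as the only discretization error, about $10^{-5}$ relative — an
order of magnitude below the $10^{-4}$ agreement the test suite demands
against an independent fine-step Euler integrator. The equal-eigenvalue
degeneracy ($\lambda_P = \lambda_L$) takes the analytic limit
$t\,e^{\lambda t}$ rather than dividing by a vanishing gap.

### Acquisition parameters

| parameter | default | units | rationale |
|---|---|---|---|
| flips (pyr/lac/bic) | 20/30/30 | degrees | lower pyruvate angle preserves the substrate pool across 20 excitations |
| `n_timepoints` | 20 | — | 60 s dynamic window |
| `dt` | 3 | s | temporal resolution of the frequency-selective EPI readout |
| `t1_pyr` | 30 | s | apparent in-vivo T₁ of [1-¹³C]pyruvate at 3 T |
| `t1_lac`, `t1_bic` | 25 | s | apparent product-pool T₁ |

The T₁ values are assumed constants, not fitted; they are standard
field values for brain at 3 T and are surfaced in `acq_params()`
precisely because any site may prefer its own calibration. Rates are
*apparent* rate constants: they absorb perfusion, transport and
compartment effects, which is why treatment comparisons are made
within-patient and against NAWM rather than in absolute units.

## The inputless fit

`fit_voxel_inputless()` avoids an arterial input function by using the
measured pyruvate signal itself as the drive: $P_z[m] =
s_{pyr}[m]/\sin\alpha_{pyr}$. Between excitations the product pool obeys

$$L[m+1] = L[m]\cos\alpha_{lac}\,e^{-\Delta t/T_{1L}} + k_{PL}\,U_m,$$

where $U_m = \int_0^{\Delta t} e^{-(\Delta t-s)/T_{1L}}\,P(s)\,ds$ is
the T₁-weighted drive integral over the interval. Only the interval's
endpoints of $P$ are observed (post-flip at $m$, pre-flip at $m+1$), so
$P(s)$ is linearly interpolated between them and the integral is
evaluated *exactly* for that interpolant:

$$U_m = a\,T_1(1-E) + \frac{b-a}{\Delta t}\Big(T_1\Delta t - T_1^2(1-E)\Big),
\quad a = P_z[m]\cos\alpha_{pyr},\; b = P_z[m+1],\; E = e^{-\Delta t/T_{1L}}.$$

A two-point trapezoid of the same integrand leaves a ~0.5% quadrature
residual at $\Delta t = 3$ s purely from the curvature of the
exponential kernel; the closed form removes it, and the discrete
propagation then matches fine-step integration of the same
interpolated-drive model to ~$2\times10^{-5}$. What remains against the
*continuous* three-pool model (~0.5%) is intrinsic: two samples 3 s
apart cannot resolve the in-interval shape of a bolus with a 4-s time
scale, and no two-point rule can remove it. Noiseless end-to-end rate
recovery lands below 0.5% relative error across
$k_{PL} \in \{0.005, 0.02, 0.05\}$ s⁻¹.

Given the drive, the response is linear in two quantities: the rate
$k$ and the initial product magnetization $M_0$ (propagated as
$d^m$, $d = \cos\alpha\,e^{-\Delta t/T_1}$). Both are estimated by
closed-form least squares; $M_0$ is a nuisance parameter. Fitting
$M_0$ rather than pinning it to the (noisy) first measured lactate
point keeps first-frame noise from propagating through the whole
trajectory and handles acquisitions that catch nonzero lactate at the
first frame. The rate is clamped to $[0, 1]$ s⁻¹ — values outside are
unphysical for brain — and $M_0$ is re-optimized at the clamped rate.

**Modeling error.** The per-voxel fit uncertainty is the relative
standard error of the rate from the two-parameter linearized residual
covariance: standard, computable per voxel, and monotone in noise.
Error masks keep voxels with relative error ≤ 30% (kPL) and ≤ 50%
(kPB); the looser bicarbonate bound reflects its intrinsically lower
SNR. Channels are decoupled (lactate and bicarbonate fitted
independently given the drive), matching the one-parameter-per-channel
inputless convention; T₁ values are fixed, not fitted.

Properties the suite verifies: scaling invariance (rates unchanged when
all curves are multiplied by $c > 0$), forward–inverse consistency,
lesion/background ordering preserved across noise realizations
(≥ 95% of seeds), and median |kPL error| under 10% at 200 Monte-Carlo
voxels whose curves carry aSNR-20 noise per metabolite.

## Maps

- **AUC**: voxel-wise temporal sum. With i.i.d. per-timepoint noise of
  sd $\sigma$, the AUC noise sd is $\sigma\sqrt{T}$, hence
  $\mathrm{aSNR} = \mathrm{AUC}/(\sigma\sqrt{T})$. That denominator is a
  declared convention — noise propagation through upstream denoising is
  not modeled here (denoised inputs are accepted as-is).
- **Noise**: pooled sd of all non-brain voxel samples across
  timepoints; at least 100 background voxels required. Estimation is
  within 5% of truth on the default phantom geometry.
- **SNR masks**: aSNR strictly below 5 is filtered; the boundary value
  5 is kept. Masks are monotone in the threshold.
- **Ratios**: Lac/Pyr, Bic/Pyr, Bic/Lac from AUC maps, defined only
  where *both* constituents pass their own SNR masks. Invalid voxels
  are `NA`, never zero — a zero would silently drag ROI medians.
- **Percentiles**: brain voxels are ranked with average-rank tie
  handling and scaled by $100/N_{brain}$ (no SNR filtering). The result
  is invariant under any strictly increasing transform of the values,
  which is what makes Pyr%/Lac%/Bic% comparable across patients and
  polarization levels. Non-brain voxels are `NA` (declared choice; the
  alternative of zero would alias with genuine low ranks). Rank-sum
  conservation — mean percentile $= 100(N+1)/2N$ — is asserted for
  arbitrary inputs.

## ROI geometry

NEL = T2L ∖ CEL and NAWM = WM ∖ T2L at ¹H resolution. Mapping to the
¹³C grid uses exact block refinement (the ¹H grid is an integer
refinement of the ¹³C grid, default factor 8 ≈ 15 mm / 1.875 mm), so
overlap fractions are exact counts. A ¹³C voxel is labeled T2L when
≥ 30% *of its own volume* is ¹H T2L; of the remaining voxels, NAWM at
≥ 50% overlap. Both thresholds are inclusive, and T2L takes precedence,
so labels are mutually exclusive by construction.

The 30% criterion is read as fraction-of-voxel, not
fraction-of-total-lesion: the alternative would make a voxel's label
depend on how large the rest of the lesion is, contradicting per-voxel
labeling. Real-data affine/oblique resampling is out of scope — the
supported geometry is the exact refinement the generator guarantees.
Enhancing-lesion analysis at ¹³C resolution is deliberately excluded:
post-surgical CEL volumes are small relative to a 3.4 cm³ ¹³C voxel.

## Longitudinal summaries

Per scan and ROI the *median* over valid voxels summarizes each
parameter (medians are robust to the heavy tails of ratio maps).
Validity flows through the maps as missingness: percentiles are valid
on all brain voxels; ratios require their SNR masks; rates require the
pyruvate SNR mask and their modeling-error masks. Lesion values are
then normalized by the same patient's median NAWM value — the
patient-internal reference that absorbs polarization-level and delivery
differences — making the normalized value unitless and scale-invariant.
A zero or missing NAWM median yields a missing normalized value.

Grouping: regimens containing bevacizumab are BEV+; otherwise
everolimus → EVER+; otherwise multi-agent alkylating combinations →
ALKYL+; single-agent TMZ or CCNU → control; anything unrecognized is
left explicitly unclassified. The priority order is declared (a
hypothetical bevacizumab + everolimus regimen is BEV+). Progressor
class: PFS < 6 months is early.

Trajectories: scans are binned to integer months (baseline = 0); when a
patient has two scans in one bin the first is kept (declared rule);
group mean, SD and SE = SD/√N are reported with N, SD/SE only when
N > 1. Percent change is always $100(x_{follow} - x_{base})/x_{base}$;
a zero baseline yields a missing value, never an infinity. Paired
voxel-wise comparison restricts to voxels in the ROI and valid at
*both* timepoints, excluding zeros in either scan so the voxel set is
symmetric in scan order.

## The synthetic phantom

The generator emulates the acquisition end of a dynamic HP-¹³C brain
exam: a 16×16×8 ¹³C grid at 15 mm isotropic, 20 timepoints at 3 s, a
gamma-variate bolus $g(t) = A((t-d)/\beta)^\alpha e^{-(t-d)/\beta}$
(α = 2.5, β = 4 s, delay 5 s — peak ~15 s post-injection, a typical
brain arrival), an ellipsoidal brain with inner white matter, a
spherical T2 lesion straddling the white-matter boundary with a small
enhancing core, lesion kPL = 0.02 vs background 0.01 s⁻¹ (Warburg
elevation ×2), lesion kPB = 0.002 vs 0.005 s⁻¹ (reduced oxidative
flux), and additive i.i.d. Gaussian noise, default σ = 0.03. That noise
level puts background-brain lactate at aSNR ≈ 23 and bicarbonate at
≈ 12 while pushing *lesion* bicarbonate near the aSNR-5 floor — so SNR
filtering is genuinely exercised, as it is in patients. ¹H masks are
the same continuous shapes evaluated on the refined grid, so
partial-volume borders are real and the 30%/50% overlap rules bite.

What it does **not** emulate — and hence what passing tests do not show
about patient data: k-space sampling, coil combination and denoising;
B₀/B₁ inhomogeneity and EPI artifacts; a vascular compartment
(pyruvate in vessels contributes signal without conversion); spatially
varying T₁; irregular lesion shapes; registration error between serial
scans; and oblique ¹H-to-¹³C geometry. Parameter recovery here bounds
the *algorithmic* error of the pipeline, not the physiological accuracy
of kPL in vivo.

The synthetic response cohort (`simulate_response_cohort()`) adds
per-patient biological variability as a log-normal scale (CV 10%) on
all rate constants, applied identically at both timepoints, and
programs a treatment effect by multiplying lesion kPL by 1.2 at
follow-up in one group. The programmed Lac/Pyr truth compared against
is the noiseless ratio change implied by the generator's own forward
model (20.6%), not the nominal 20% — so the recovery check is exact
rather than first-order. Under the default conditions the treated-group
recovery lands within 2 SE of that truth and the untreated group stays
within a 1-percentage-point equivalence bound of zero.

## Problem sizes and runtime

The shipped validation suite runs at desk scale by design: single-voxel
oracle comparisons; 200-voxel Monte-Carlo recovery; 50-volume oracle
sweeps for percentile ranking and ROI downsampling; 100 random mask
sets for the algebra invariants; and a 40-scan response cohort (2
groups × 10 patients × 2 timepoints on the full 16×16×8×20 grid). The
complete test suite runs in about half a minute; the acceptance script
in about a quarter of a minute.

## Known limitations

- Unidirectional exchange only; no $k_{LP}$, no T₁ fitting, no spatial
  regularization across voxels.
- The aSNR noise model assumes i.i.d. per-timepoint noise; temporally
  correlated noise (e.g. after temporal denoising) would bias the
  aSNR scale, though not the ranking-based percentile maps.
- ROI mapping supports exact block refinement only; oblique or
  non-integer geometries need upstream resampling.
- Group trajectories are descriptive (mean ± SD/SE); no between-group
  hypothesis testing or survival modeling is provided.
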