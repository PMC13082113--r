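# hp13c — hyperpolarized [1-¹³C]pyruvate MRI treatment-response analysis

Hyperpolarized (HP) [1-¹³C]pyruvate MRI watches, in real time, how
injected pyruvate is converted to lactate and bicarbonate in the living
brain. In high-grade glioma, tumor tissue preferentially converts
pyruvate to lactate even in the presence of oxygen (the Warburg effect),
so the apparent conversion rate constants and metabolite ratios are
candidate early markers of treatment response — changing weeks before
anything is visible on anatomical MRI.

`hp13c` implements a complete, tested voxel-wise analysis pipeline for
serial dynamic HP-¹³C brain exams, aimed at imaging scientists analyzing
longitudinal patient cohorts:

- **Inputless kinetic modeling.** Apparent rates kPL (pyruvate→lactate)
  and kPB (pyruvate→bicarbonate) are fitted per voxel with the measured
  pyruvate signal itself as the driving input — no arterial input
  function. Between excitations the product magnetization evolves as

  dL/dt = kPL·P(t) − L/T₁L (and likewise for bicarbonate),

  with RF sampling losses cos(α) applied at each excitation and the
  measured signal being Mz·sin(α). Given the pyruvate drive the model is
  linear in the rate, so the nonnegative least-squares estimate and its
  relative standard error ("modeling error") are computed in closed form.
- **Parametric maps.** AUC (temporal-sum) maps per metabolite, background
  noise estimation, apparent-SNR maps with aSNR ≥ 5 masking, SNR-masked
  Lac/Pyr, Bic/Pyr, Bic/Lac ratio maps, and tied-rank percentile maps
  (Pyr%, Lac%, Bic%) over the brain — rank-based normalization that makes
  signals comparable across patients and polarization levels.
- **ROI geometry.** NEL = T2L − CEL and NAWM = WM − T2L mask arithmetic
  at ¹H resolution, and mutually exclusive downsampling onto the coarse
  ¹³C grid: a ¹³C voxel is T2-lesion if ≥ 30% of its volume overlaps the
  ¹H T2L; remaining voxels are NAWM at ≥ 50% overlap.
- **Longitudinal summaries.** Per-scan ROI medians, patient-internal
  normalization of lesion values by the median NAWM value, treatment
  (BEV+/EVER+/ALKYL+/control) and progressor (PFS < 6 months) grouping,
  group mean ± SD/SE trajectories, and paired voxel-wise serial
  comparison on template-aligned scans.
- **Synthetic phantom generator.** Desk-scale dynamic studies with known
  kPL/kPB ground truth: gamma-variate bolus inflow, exact three-pool
  forward model with RF losses, additive Gaussian noise, and nested
  anatomical masks at ¹H resolution with genuine partial-volume borders.

## Worked example

Simulate a study (16×16×8 ¹³C grid, 20 timepoints at 3 s, flips
20/30/30°, lesion kPL = 0.02 s⁻¹ over background 0.01 s⁻¹) and run the
full analysis:

```r
library(hp13c)

study <- generate_phantom(phantom_config(seed = 7), acq_params())
an <- analyze_study(study)
an$voxel_counts
#> brain_13c   snr_pyr   snr_lac   snr_bic    fitted  kpl_pass  kpb_pass   t2l_13c  nawm_13c
#>       624       624       624       584       624       624       624        52       176

an$summary[, c("parameter", "t2l_median", "nawm_median", "t2l_norm")]
#>   parameter t2l_median nawm_median t2l_norm
#> 1   pyr_pct    4.24679    51.76282   0.0820
#> 2   lac_pct   95.91346    43.42949   2.2085
#> 3   lac_pyr    0.29811     0.14788   2.0159
#> 4       kpl    0.01991     0.01005   1.9809
#> 5       kpb    0.00202     0.00502   0.4028
#> ...
```

Reading the output: 624 of the 2048 ¹³C voxels are brain; all brain
voxels pass the pyruvate aSNR ≥ 5 mask but 40 lose bicarbonate to SNR
filtering (reduced oxidative flux in the lesion). The lesion's median
fitted kPL (0.0199 s⁻¹) recovers the programmed 0.02 s⁻¹, and after
patient-internal NAWM normalization the lesion reads 1.98 — the
programmed 2× Warburg-type elevation. The lesion ranks at the top of the
brain's lactate distribution (Lac% median 95.9) and bottom of pyruvate
(Pyr% 4.2), the signature of avid conversion.

A single voxel can be fitted directly:

```r
p <- acq_params()
g <- function(t) gamma_variate(t, 1, 2.5, 4, delay = 5)
s <- simulate_voxel_dynamics(0.02, 0.005, g, p)
fit_voxel_inputless(s$pyruvate, s$lactate, s$bicarbonate, p)
#> kPL = 0.02007 1/s (rel. err 0.1%), kPB = 0.005016 1/s (rel. err 0.1%)
```

The clinical side: `parse_clinical_table()` reads a cohort CSV
(see `inst/extdata/glioma_cohort.csv`, a 20-patient recurrent grade-4
glioma cohort), `assign_groups()` classifies regimens, and
`group_trajectories()` produces the per-group longitudinal mean ± SE
tables. `run_pipeline()` ties everything together and writes NIfTI maps,
CSV summaries and a hashed artifact manifest for reproducibility.

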