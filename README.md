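# gadcsf

Quantifying gadolinium entry into cerebrospinal fluid from dynamic MRI.

After an intravenous injection, gadolinium-based contrast agent (GBCA) can
cross the blood–CSF barrier at the choroid plexus and enter the ventricular
CSF even in healthy subjects. `gadcsf` implements the quantitative machinery
for measuring that process with two pulse sequences:

- **cDSC MRI** — a single-shot long-echo-train spin-echo acquisition with
  TE = 1347 ms. At that echo time every compartment with T2 under ~150 ms
  (blood, parenchyma) retains less than 0.1 % of its equilibrium signal, so
  the image is effectively pure CSF; gadolinium *reduces* the CSF signal.
- **FLAIR** — inversion recovery tuned to null CSF; gadolinium *increases*
  the CSF signal.

The package is aimed at researchers analyzing dynamic contrast studies of
the blood–CSF barrier, and at anyone who needs a fully synthetic, seeded
test bed for such pipelines.

## The model

Gadolinium shortens relaxation times linearly in concentration
(relaxivities r1, r2 in L·mmol⁻¹·s⁻¹, medium-dependent):

    1/T1_Gd = 1/T1_0 + r1·[Gd]        1/T2_Gd = 1/T2_0 + r2·[Gd]

The cDSC steady-state signal, as a fraction of equilibrium magnetization,
uses a saturation-recovery model with the recovery time equal to TR minus
the echo-train duration (echo spacing × echo-train length), and
mono-exponential decay at the nominal TE:

    S = (1 − exp(−(TR − ES·ETL)/T1)) · exp(−TE/T2)

The measured quantity per ROI is the relative signal change
ΔS/S = 100·(S̄_post − S̄_pre)/S̄_pre. For CSF parameters this is a
decreasing function of [Gd] over the working range, so a measured negative
ΔS/S inverts to a unique concentration by bracketed root finding. The ROI
pipeline adds reference-region (corpus callosum) normalization across
sessions, onset-time and time-to-plateau detection, windowed summaries
(50–250 s post-injection by default), and group statistics (paired t,
partial correlation by the residual method).

## Worked example

Invert a measured 4 h ventricular signal change of −7.58 % to a
concentration, convert units, and probe parameter sensitivity:

```r
library(gadcsf)

seq <- cdsc_params()              # TR/TE/ES = 10000/1347/3.2 ms, ETL 1024
csf <- tissue_defaults("csf")     # T1/T2 = 4310/1400 ms, r1/r2 = 2.8/3.4

t1_with_gd(csf$T1_0, csf$r1, 0.2)        # 1262.597  (ms at 0.2 mmol/L)
t2_with_gd(csf$T2_0, csf$r2, 0.2)        # 717.2131

est <- estimate_concentration(-7.58, seq, csf)
est
#> <concentration_estimate> [Gd] = 0.0501 mmol/L (from delta-S/S = -7.58%)
mmol_per_l_to_ng_per_ml(est$c)           # 27970.23 ng/mL (Gadoteridol stock)

sensitivity_analysis(-7.58,
  list(baseline = c(), pessimistic = c(T1_0 = 0.8, r1 = 0.8, r2 = 1.2)),
  seq, csf)
#>      scenario T1_0 T2_0  r1  r2          c
#> 1    baseline  1.0    1 1.0 1.0 0.05007201
#> 2 pessimistic  0.8    1 0.8 1.2 0.02296032
```

So a 20 % shorter baseline T1, 20 % lower r1 and 20 % higher r2 roughly
halve the estimate to ~0.02 mmol/L — the dominant systematic uncertainty of
the method.

Run the whole pipeline on the seeded synthetic phantom (a ventricle with a
choroid plexus blob, its two-voxel transition shell, perivascular cortex
and a corpus callosum reference, with Rician noise at SNR 50):

```r
ph  <- render_dynamic_series(phantom_spec(seed = 42))
analyze_series(ph$series, ph$rois)
#>          roi      delta_s baseline_sd          gd t_onset ttp n_voxels
#> 1         cp -2.290843485   0.3400814 0.027155448      20  30       56
#> 2 transition -0.334251036   0.1538911 0.012957631     100 100      200
#> 3 rest_of_lv  0.045500878   0.1428557          NA      NA  NA      264
#> 4        cgm -0.005791452   0.2043399          NA      NA  NA      976
```

The choroid plexus shows a −2.29 % change in the 50–250 s window, inverting
to 0.0272 mmol/L against a programmed truth of 0.027; onset is detected at
20 s and the plateau at 30 s, matching the programmed kinetics. The rest of
the ventricle shows no significant early change (its accumulation is slow),
so no concentration or timing is reported for it — exactly the behavior
expected in vivo. `run_pipeline(out_dir, seed = 7)` performs the same
analysis end to end (phantom → NIfTI round trip → ROI analysis → 4 h
cross-session comparison → cohort statistics) and writes CSV tables plus a
provenance JSON that suffices to reproduce the run bit-identically.

## Limitations

The signal models are closed-form steady-state expressions: no echo-train
relaxation during readout, flip-angle modulation, flow, or B0/B1 effects.
The phantom emulates the statistical structure of a real study (geometry,
kinetics, Rician noise, session gains), not anatomy or physiology; see the
methods vignette (`vignettes/gadolinium-csf-quantification.Rmd`) for the
full account of assumptions, parameter choices and numerical behavior.
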