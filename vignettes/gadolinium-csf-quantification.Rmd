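---
title: "Quantifying gadolinium in CSF: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gadolinium in CSF: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gadcsf)
```

This vignette is the package's own account of the science it implements:
the signal models and their assumptions, the parameters that matter, what
the synthetic phantom does and does not emulate, and the design choices
made where the design was genuinely open.

## The measurement problem

Intravenously injected gadolinium-based contrast agent (GBCA) is largely
confined to blood in the healthy brain, but the choroid plexus epithelium
— the blood–CSF barrier — is leakier than the blood–brain barrier, and a
small fraction of the agent enters ventricular CSF. Concentrations there
are tiny (tens of micromolar, one to two orders below blood), so the
measurement strategy is to make the CSF itself the only visible
compartment and track its signal over time.

The package models two complementary acquisitions:

* a **long-echo-time CSF-selective sequence** ("cDSC"): a single-shot
  spin-echo train with TR = 10000 ms, nominal TE = 1347 ms, echo spacing
  3.2 ms and train length 1024. Only spins with very long T2 (CSF,
  ~1400 ms) survive the echo time; gadolinium shortens T2 and *darkens*
  CSF.
* **FLAIR** (TR/TI/TE = 6000/2000/180 ms): CSF is nulled by the inversion
  time, and gadolinium's T1 shortening pulls CSF off the null, so CSF
  *brightens*.

Only the CSF-selective sequence is quantified: its voxels are effectively
pure CSF, whereas a FLAIR voxel can mix blood, CSF and parenchyma
contributions with opposite concentration dependencies, which is modeled
here (`voxel_signal()`) but deliberately not inverted.

## Signal models

Relaxation with agent follows the linear relaxivity model,
$1/T_{i,\mathrm{Gd}} = 1/T_{i,0} + r_i\,[\mathrm{Gd}]$, $i = 1, 2$. Times
are carried in ms and relaxivities in the conventional
L·mmol⁻¹·s⁻¹; the implementation forms rates in s⁻¹ and converts back,
so the unit bridge appears in exactly one place (`t1_with_gd()`,
`t2_with_gd()`).

The CSF-selective sequence is modeled as saturation recovery with an
effective recovery time of TR minus the echo-train duration, times
mono-exponential decay at the nominal TE:

$$S = \left(1 - e^{-(TR - ES\cdot ETL)/T_1}\right) e^{-TE/T_2}.$$

This is the simplest model consistent with a single-shot long-train
acquisition: during the ~3.3 s train the longitudinal magnetization is
consumed, and recovery happens in the remaining ~6.7 s. FLAIR uses the
classic inversion-recovery steady state
$(1 - 2e^{-TI/T_1} + e^{-TR/T_1})\,e^{-TE/T_2}$. Neither model includes
echo-train relaxation during readout, flip-angle modulation,
magnetization transfer, flow, or field inhomogeneity; signals are signed,
and comparisons with (magnitude-reconstructed) images use absolute
values.

Default tissue parameters (3 T literature values, shipped in
`inst/extdata/tissue_params.yaml`): CSF T1/T2 = 4310/1400 ms with
r1/r2 = 2.8/3.4; fully oxygenated blood 1878/157 ms with r1/r2 = 4.4/5.5
(hematocrit 0.43 recorded as metadata); cortical gray matter 1607/63 ms
and white matter 838/77 ms with zero relaxivity — healthy parenchyma
behind an intact blood–brain barrier sees no agent unless explicitly
overridden. The parameter file also records published post-contrast blood
values that are *not* jointly consistent with the relaxivity equations at
any single concentration (the T1 entry implies ≈ 1.0 mmol/L, the T2 entry
≈ 1.4 mmol/L); the package always computes post-contrast relaxation from
the equations and keeps the printed pair as a documented reference only.

## Concentration inversion and its one subtlety

The measured quantity is the relative change
$\Delta S/S = 100\,(S(c) - S(0))/S(0)$ (percent). For CSF parameters this
is *almost* strictly decreasing in $c$: in a narrow initial band the
T1-recovery term outpaces T2 decay, producing a shallow positive lobe —
at the defaults, a maximum of +0.08 % at ≈ 0.004 mmol/L with a zero
crossing near 0.008 mmol/L:

```{r lobe}
g <- seq(0, 0.02, length.out = 201)
f <- forward_delta_s(g, cdsc_params(), tissue_defaults("csf"))
round(c(peak_pct = max(f), at_mmol_per_l = g[which.max(f)]), 4)
```

`estimate_concentration()` therefore profiles the forward curve on a
1000-point grid over the bracket (default 0–5 mmol/L) and requires
(a) any rising lobe to be confined to the first 1 % of the bracket and
(b) the remainder to be non-increasing with a strict overall decrease —
the tolerance for "non-increasing" is 1e-10 percentage points, which
absorbs floating-point saturation where the signal has fully decayed.
Root finding (Brent via `uniroot`, tolerance 1e-8 mmol/L) then runs on
the decreasing branch, where any negative $\Delta S/S$ has a unique
preimage. Positive measured changes are rejected rather than clipped to
zero: under this sequence a positive CSF change signals contamination
(partial volume, motion), and silently reporting 0 mmol/L would hide it.
The lobe is physically irrelevant for the measurement — real measured
changes are well below −0.1 % — but it is why the package never claims
strict monotonicity *from zero*.

Group-level use: the package inverts whatever $\Delta S/S$ it is given
(per voxel, per ROI mean, per subject) and lets the caller average.
Because the map is nonlinear, inverting a group-mean change is not the
same as averaging per-subject inversions; no ordering is imposed.

Sensitivity analysis re-inverts the same measurement under
multiplicative parameter perturbations. The canonical pessimistic
scenario (T1 −20 %, r1 −20 %, r2 +20 %) roughly halves the estimate,
which is the method's dominant systematic uncertainty; directions of all
four parameter sensitivities are verified against finite differences in
the test suite.

## ROI pipeline

* **Transition shell.** The region between choroid plexus and open CSF
  is built by dilating the CP mask one voxel at a time, twice, clipping
  each step to the ventricle, then removing the CP. One dilation step
  uses face (6-) connectivity by default — "two layers of voxels" read
  as two one-voxel morphological shells — with 18/26-connectivity
  available. The result equals a brute-force L1-ball construction on
  convex ventricles (tested).
* **Frame timing.** Frame $i$ covers $[(i-1)\Delta t, i\Delta t)$; a
  frame belongs to a window iff its midpoint does; injection falls on a
  frame boundary. All timings are reported as frame start times relative
  to injection.
* **Reference normalization.** Every frame is divided by the
  session-wide mean corpus callosum signal; the CC shows no
  contrast-induced change over the experiment, so this cancels
  inter-session scanner gain exactly (a multiplicative-gain invariance
  test pins this down). Within a session it is a constant and cannot
  affect $\Delta S/S$.
* **$\Delta S/S$ and windowed summary.** ROI means are taken over the
  whole ROI with no voxel selection; the baseline is the mean over all
  pre-injection frames; the summary window is 50–250 s post-injection,
  which by construction excludes the transient bolus-phase dip sometimes
  seen at 20–30 s (the phantom can inject such a dip; the pipeline only
  ever excludes it).
* **Onset and plateau.** Onset is the first frame starting a run of ≥ 3
  consecutive frames beyond 2 baseline-SDs in the expected (negative)
  direction; undefined when no run qualifies, mirroring the convention
  of not reporting timings for non-significant changes. The plateau
  level is the *median* $\Delta S/S$ over the summary window (robust to
  the dip), and time-to-plateau is the first post-onset frame reaching
  90 % of it. Both thresholds are exposed as arguments; the defaults
  make a 20 s onset detectable at the phantom's noise level. These
  detection rules are a reasonable reconstruction of common practice,
  not a transcription of any particular published estimator.

## The synthetic phantom

No real scans ship with the package, so the generator produces the
statistical structure the analysis assumes, with known truth:

* **Geometry** (default 24×24×16 grid, 0.8 mm isotropic): a ventricle
  ellipsoid containing a central CP blob, the two-layer transition shell
  built by the package's own rule, rest-of-ventricle, a perivascular
  cortical shell, a corpus callosum block (512 voxels) and generic
  parenchyma. Labels are disjoint by construction.
* **Kinetics.** A gamma-variate arterial input function (shape 1, scale
  2.4 s, delay 20 s, peak 1 mmol/L — the typical post-bolus blood
  concentration) drives one-compartment uptake into the CP region,
  $dC/dt = k_{in} C_{aif} - k_{out} C$. With the default $k_{out} = 0$
  the CP curve is the scaled running integral of the bolus (closed form
  via the incomplete gamma function) and plateaus exactly at its
  set-point once the bolus has passed; the shape/scale/delay were chosen
  once so the clean curve first becomes non-zero at 20 s and reaches
  90 % of plateau at ~30 s on the 10 s frame grid. The rest of the
  ventricle and the perivascular cortex follow a delayed saturating
  exponential (delay 300 s, time constant 5000 s) that is essentially
  zero during the first five minutes and normalized to hit the 4 h
  set-point exactly; the transition shell is the mean of the CP and
  ventricle curves. Set-points default to 0.027 mmol/L (CP plateau) and
  0.050 mmol/L (ventricle at 4 h), the magnitudes the method is designed
  to resolve. $k_{out} > 0$ switches to explicit Euler stepping on the
  acquisition grid, refusing unstable steps ($k\,\Delta t > 1$); the
  solution is cross-checked against an adaptive ODE solver in the tests.
* **Acquisition.** 28 pre- and 32 post-injection frames at 10 s, plus a
  separate 23-frame stationary series at 4 h (matching a ~4 min delayed
  scan); per-session scanner gains are deliberately unequal (1000 vs
  1300) so reference normalization is actually exercised.
* **Noise.** Magnitude images get Rician noise: the clean signal is the
  real channel mean and both channels receive Gaussian noise with
  $\sigma$ = clean ventricular CSF signal / SNR (default SNR 50). At
  that level the Rician mean bias is below 0.1 % and, being common to
  both sessions, cancels in the cross-session ratio. Partial-volume
  regions (perivascular cortex 30 % CSF, corpus callosum 10 % CSF) mix
  compartment signals by volume fraction; parenchyma contributes
  essentially nothing at TE = 1347 ms, which is precisely why ROI
  $\Delta S/S$ is unaffected by a static CSF fraction.
* **Determinism.** A fixed seed yields byte-identical output; the
  generator saves and restores the caller's RNG state.

What the phantom does **not** emulate: anatomy (shapes are ellipsoids and
boxes), CSF flow and pulsation, motion, coil profiles, k-space artifacts,
or between-subject physiology. Passing the recovery tests therefore shows
that the *estimation chain* is unbiased at realistic noise levels — not
that real data meet the models' assumptions (registration, no motion,
literature relaxation values).

The cohort simulator (`simulate_cohort()`) is the group-level analog:
ages 48.9 ± 19.5 years, dose = 0.1 mmol/kg of body weight, ventricular
volume drifting with age, and per-subject $\Delta S/S$ drawn around the
session/ROI set-points with between-subject spreads consistent with the
group standard errors the study design anticipates (early session SDs
0.75–1.5 %, 4 h SDs 8.6–12.7 %); each subject's concentration is obtained
by inverting their own signal change, so undefined values arise naturally
for positive changes, and summary cells with more than half the subjects
undefined are reported as missing.

## Problem sizes and runtime

Default sizes were chosen so that the complete test suite runs in a few
seconds on one core: a 24×24×16 phantom (9216 voxels, 83 frames,
~1.5 million noise draws), 1000-point inversion profiles, and cohorts of
25–50 subjects. All results quoted in the README were produced by these
defaults with the seeds shown.

## Known limitations

* The steady-state signal models ignore echo-train relaxation during the
  readout; if the true acquisition deviates strongly, the forward model —
  and hence every inverted concentration — shifts systematically. The
  sensitivity machinery is the honest way to express that uncertainty.
* Concentration inversion assumes a dilute aqueous solution; protein
  binding or compartmentalization in vivo would violate the linear
  relaxivity model.
* The onset/plateau estimators are threshold rules on noisy series;
  near-threshold regions (e.g. the transition shell at its detection
  limit) can report late or missing onsets, which is the intended
  behavior rather than a defect.
* FLAIR is modeled for simulation and partial-volume reasoning only; no
  concentration is ever estimated from it.
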