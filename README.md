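# gaitrel

Wearable-sensor gait assessment with a reliability layer, aimed at
neurorehabilitation research — in particular severe traumatic brain injury
(sTBI) survivors walking short 10 m bouts, where clinicians need to know
whether a change in an instrumented gait index reflects the patient or the
measurement.

`gaitrel` takes raw tri-axial accelerations and angular velocities from five
body-worn IMUs (head, sternum, pelvis, both shanks; 128 Hz) and computes, per
trial, fifteen gait indices in three families:

* **Stability — normalized RMS.** Per stride,
  `nRMS = RMS(x) / RMS(y)` with `x` the AP or ML acceleration and `y` the CC
  acceleration of the same sensor (pelvis, trunk, head). Higher values mean
  larger horizontal accelerations relative to vertical, i.e. reduced
  stability.
* **Symmetry — improved harmonic ratio (pelvis).** With `P_I,i` and `P_E,i`
  the powers of the first `K = 20` intrinsic and extrinsic stride-frequency
  harmonics (even harmonics intrinsic for AP/CC, odd for ML),
  `iHR = 100 · Σ P_I / (Σ P_I + Σ P_E)` — 100% is perfect bilateral symmetry,
  0% complete asymmetry.
* **Smoothness — log dimensionless jerk (pelvis).** Per axis and stride,
  `LDLJ = −ln( (t2−t1)³ / max s² · ∫ (ds/dt)² dt )`, from accelerations
  (LDLJa) and angular velocities (LDLJw).

Upstream, the package implements the full preprocessing chain (gyroscope
static-bias removal, gravity alignment to anatomical axes, gravity removal
from CC, zero-phase Butterworth filtering at 10/6 Hz) and stride segmentation
from the shank angular velocity. Downstream, `reliability_table()` turns
paired test/retest index tables into the reliability surface: Shapiro–Wilk
gated paired tests with Cohen's d, single-measure ICC (absolute agreement by
default, consistency ICC(3,1) optional) with F-based 95% CIs,
`SEM = SD·√(1−ICC)` and `MDC` under both the ×1.96×2 and ×1.96×√2
conventions.

Because no public recordings exist for this population, the package ships a
synthetic cohort generator (`cohort_spec()`, `generate_cohort()`) whose
harmonic signal model makes every index analytically checkable and whose
test-retest variance structure realizes an exact, user-chosen true ICC.

## Worked example

```r
library(gaitrel)

spec   <- cohort_spec(n_subjects = 8, seed = 42)   # 8 subjects, 2 sessions
cohort <- generate_cohort(spec)
run    <- run_pipeline(cohort$trials)

run$index_table[1:4, c("subject_id", "session", "nRMS_AP_pelvis",
                       "iHR_AP", "LDLJa_AP", "n_strides_used")]
#>   subject_id session nRMS_AP_pelvis iHR_AP LDLJa_AP n_strides_used
#> 1 S001       test             0.884   65.7    -4.30              6
#> 2 S001       retest           0.878   75.4    -4.33              6
#> 3 S002       test             1.13    53.5    -3.92              6
#> 4 S002       retest           1.12    54.3    -3.91              6
```

Each row is one trial: subject S001's test walk had, averaged over its 6
steady-state strides, AP pelvis accelerations 0.88× the vertical ones
(stable), 65.7% of AP harmonic power in the symmetric harmonics, and an AP
smoothness of −4.30.

```r
dplyr::filter(run$reliability,
              index %in% c("nRMS_AP_pelvis", "iHR_CC", "LDLJa_AP")) |>
  dplyr::select(index, icc, icc_lo, icc_hi, sem, mdc, p, d)
#>   index            icc icc_lo icc_hi    sem    mdc     p      d
#> 1 nRMS_AP_pelvis 0.933  0.710  0.986 0.0418  0.164 0.661 -0.162
#> 2 iHR_CC         0.797  0.330  0.955 5.25   20.6   0.285 -0.410
#> 3 LDLJa_AP       0.979  0.902  0.996 0.0603  0.236 0.194 -0.508
```

Read: across this small simulated cohort the AP pelvis nRMS shows excellent
test-retest reliability (ICC 0.93); a real change must exceed its MDC of
0.16 to outgrow measurement error. No index shows a significant session shift
(all p > 0.05). `autoplot(run$reliability)` draws the ICC forest plot and
`plot_test_retest_differences(run$index_table)` the per-index difference
distributions.

Real data enter through `read_trial_csv()` (one CSV per trial, six channels
per sensor plus a time column, units declared in the header) and
`read_manifest()`; `run_pipeline(manifest, out_dir = ...)` then writes the
index table, reliability table, QC log and run metadata.

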