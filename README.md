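# synergyflow

Motor-module (muscle-synergy) analysis of fast changes of direction while
running, with and without a support-surface perturbation at initial contact.

During a 90° side-step cutting manoeuvre, the envelopes of `M = 16`
lower-limb and trunk muscle EMGs over a movement cycle, collected in a
nonnegative matrix `X` (muscles × 200 cycle points), are modelled as

```
X ≈ S P
```

where the columns of `S` (M × N) are **motor modules** — fixed muscle
weightings recruited as a unit — and the rows of `P` (N × K) are
**activation signals**, the time-varying drive to each module. The package
provides, as a single tested pipeline:

* EMG envelope construction: 20–500 Hz band-pass, rectification, 10 Hz
  low-pass (all zero-phase), 200-point cycle normalization, and the two
  amplitude normalizations the analysis needs (whole-cycle peak for
  factorization, stance-period peak for epoch analysis);
* non-negative matrix factorization by multiplicative updates
  (`synergy_nmf()`, a classed model object with `print`/`summary`/`coef`/
  `predict`/`residuals`/`plot`/`simulate` methods), with
  variance-accounted-for (VAF = 1 − SSE/SST) dimensionality selection on an
  80% floor plus slope-flattening rule;
* cross-condition machinery: normalized-scalar-product module similarity
  with optimal matching (r > 0.80 = "similar"), and fixed-factor
  cross-reconstruction (reconstruct perturbed trials from fixed unperturbed
  weightings or activations, 1000 multiplicative updates, random-matrix
  baselines);
* knee co-contraction ratio and index (`CCR = ((BF+ST)/2)/((VM+VL+RF)/3)`,
  `CCI = mean(5 knee muscles) × CCR`) over three stance epochs (10 ms
  pre-contact; initial contact to the negative CoM-power peak; 50 ms around
  the positive CoM-power peak);
* kinetics: stance detection (Fz > 20 N with debounce), CoM power
  (`F·v/m`, W/kg) with load-acceptance/propulsion phase works (J/kg),
  approach speed, first-half-of-stance horizontal force peaks, and generic
  phase-wise peak extraction for joint-angle/moment series;
* a synthetic-data generator with planted ground truth (`simulate_subject()`)
  that emulates the study layout — 10 unperturbed trials plus one trial
  perturbed at initial contact (10 cm / 150 ms platform translation) — for
  parameter-recovery validation.

## Worked example

Simulate one subject with known ground truth and run the full per-subject
analysis:

```r
library(synergyflow)

subj <- simulate_subject(n_upt = 6, n_ptb = 1, noise_level = 0.05, seed = 42)
rep  <- run_subject(subj, n_range = 1:6, n_restarts = 3, seed = 7)
print(rep)
#> Subject report: 5 motor modules (UPT VAF 99.7%)
#>   UPT vs PTB similarity: weightings 0.999, activations 0.999 (median)
#>   cross-reconstruction VAF (%): fixed_weightings 99.7, fixed_activations 99.6, random_weightings 56.5, random_activations 40.5
#>   CCR (UPT): pre 6.05, la 12.88, prp 0.28
#>   kinetics: stance_ms 327.15, com_speed 2.67, w_lac -2.66, w_prp 1.18, hf_ap 9.93, hf_ml 6.97
```

Reading the report: the VAF curve selects 5 modules (the planted number);
matched module similarities between conditions are near 1 for the
weightings; reconstructing the perturbed trial from *fixed unperturbed
weightings* works better than from *fixed unperturbed activations* — and
both beat their random-matrix baselines by a wide margin — the signature
that a perturbation alters *when* modules are recruited more than *which
muscles* form them. The epoch CCRs reflect the planted activation timing
(hamstring-dominated load acceptance), and the kinetic summary returns the
generator's planted conditions (330 ms stance, 2.67 m/s approach,
~10 N/kg anterior-posterior force peak).

The factorization itself is an ordinary R model object:

```r
X <- concatenate_trials(normalize_amplitude(
       subj$trials$trials[subj$trials$conditions == "UPT"]))
fit <- synergy_nmf(X, 5, seed = 1, n_restarts = 5)
print(fit)
#> Motor module set: 5 modules, 16 muscles x 1200 time points
#>   VAF 99.7% (SSE 6.163 / SST 2356), 976 iterations, restart 4
#>   activation peak times (% cycle): 17.9, 39.5, 47.1, 49.2, 60.6
coef(fit)              # muscle weightings S (unit-norm columns)
peak_timing(cycle_average_activations(coef(fit, "activations"), 200))
plot(fit)              # weighting barplots + activation curves
```

## Data formats

Plain-text only: an EMG CSV dialect (one row per muscle, first column the
muscle label), a TSV for force/CoM traces (`time_s, Fx, Fy, Fz, CoM_vx,
CoM_vy, CoM_vz`), a JSON sidecar for planted ground truth, and a YAML study
config (`load_study_config()` / `write_subject()` round-trip a whole
subject).
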