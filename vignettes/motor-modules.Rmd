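---
title: "Motor-module analysis of perturbed cutting manoeuvres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-module analysis of perturbed cutting manoeuvres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergyflow)
```

## The problem and the model

During rapid 90-degree side-step changes of direction (cutting manoeuvres),
the central nervous system coordinates many lower-limb and trunk muscles at
once. A compact description of that coordination is the motor-module (muscle
synergy) model: the envelope of the surface EMG of $M$ muscles over a
movement cycle, collected in a nonnegative matrix $X \in
\mathbb{R}_{\ge 0}^{M \times K}$ ($K$ cycle samples), is approximated as

$$ X \approx S\,P, $$

where the columns of $S \in \mathbb{R}_{\ge 0}^{M \times N}$ are motor
modules — fixed muscle weightings recruited as a unit — and the rows of
$P \in \mathbb{R}_{\ge 0}^{N \times K}$ are activation signals, the
time-varying drive to each module. With $N \ll M$ this is a dimensionality
reduction whose parts are directly interpretable: *which* muscles act
together ($S$) and *when* they are recruited ($P$).

The package implements the full analysis chain for comparing unperturbed
(UPT) cutting trials against trials perturbed at initial contact by a
support-surface translation (PTB; 10 cm over 150 ms, i.e. 66.7 cm/s —
`platform_perturbation()`): envelope preprocessing, factorization,
dimensionality selection, cross-condition comparison, knee co-contraction
over stance epochs, and CoM-power-based stance segmentation. Because no
real recordings ship with the package, a synthetic-data module generates
envelope and kinetic data with planted ground truth, which is how every
claim in the test suite is validated.

## Preprocessing

Raw EMG (16 channels, 2048 Hz; `emg_recording()`) is processed in a fixed
order:

1. `bandpass()` — zero-phase 2nd-order Butterworth, 20–500 Hz;
2. segmentation to the cycle (contralateral initial contact to ipsilateral
   toe-off);
3. `envelope()` — full-wave rectification, zero-phase 2nd-order 10 Hz
   low-pass, residual undershoot clipped at 0;
4. `time_normalize()` — linear interpolation onto 200 cycle points;
5. amplitude normalization.

Rectification and band-pass do not commute, so the order is asserted in the
tests. All filters are applied forward–backward with odd reflective padding
(at least three filter lengths), so symmetric peaks do not shift. The filter
order for the envelope low-pass is not dictated by any convention we know
of; second-order zero-phase is used for both filters and recorded in the
fit provenance. Linear interpolation was chosen for the 200-point cycle
normalization because it is monotone and standard for gait-cycle
normalization.

Two amplitude normalizations coexist deliberately:

* `normalize_amplitude()` divides each muscle by its peak over **all** pooled
  trials (UPT and PTB) of a subject — used before factorization, so envelopes
  lie in $[0,1]$;
* `epoch_normalize_amplitude()` divides by the **stance-period** peak —
  used for the epoch-window and co-contraction analysis, where amplitudes
  are expressed as a fraction of the stance maximum.

Note one consequence of the first normalization: it rescales the rows of the
generative weighting matrix. When recovered weightings are compared against
planted truth, the truth must be mapped into the same coordinates with
`normalized_truth_weightings()`; comparing against the raw truth instead
produces an apparent recovery ceiling (~0.96) that is pure row-rescaling,
not estimation error.

## Factorization

`synergy_nmf()` is the modelling core: multiplicative-update NMF for the
Frobenius objective (implemented in compiled code; an independently written
R version of the update rules serves as an oracle in the tests). Design
points:

* **Initialization** — uniform $(0,1]$ entries scaled so the initial product
  matches the data mean; `n_restarts` independent seeded restarts (default
  20), best final error wins. All seeds are explicit arguments; every fit is
  bit-reproducible.
* **Convergence** — stop when the relative error change falls below `tol`
  (default $10^{-6}$) or after `max_iter` updates. A negative `tol` disables
  the test, which is how the fixed-factor procedure runs an exact number of
  updates.
* **Numerics** — denominators carry an additive guard of $10^{-12}$; updates
  can never produce negative entries, and the error trace is returned so
  monotonicity is assertable per iteration.
* **Canonicalization** — weighting columns are rescaled to unit Euclidean
  norm (scale absorbed into activations; the product is unchanged to
  $10^{-12}$) and modules are ordered by activation peak time, which makes
  fits comparable across runs.

Reconstruction quality is the variance accounted for,
$\mathrm{VAF} = 1 - \mathrm{SSE}/\mathrm{SST}$ with **uncentered**
$\mathrm{SST} = \sum X^2$ — the dominant convention in this literature; it
makes the zero reconstruction score exactly 0. Centered SST is available via
`vaf(..., centered = TRUE)`.

`vaf_curve()` fits each candidate $N$; monotone non-decreasing VAF is
guaranteed structurally, because the fit at $N+1$ also tries a warm start
built from the $N$-module solution plus one random module.
`select_dimensionality()` implements the selection rule: the smallest $N$
whose VAF reaches the 80% floor **and** after which the curve has flattened
— the gain from the next module is below `gain_eps` percentage points
(default 3, placing a reported ~4-point sixth-module gain just past the
boundary). If the floor is reached but the curve never flattens, the
smallest above-floor $N$ is returned flagged.

## Comparing module sets

Similarity between modules is the normalized scalar product
$u \cdot v / (\lVert u\rVert\,\lVert v\rVert)$, with $r > 0.80$ counted as
"similar" — for both weightings and activation signals.
`match_modules()` pairs two sets by **optimal assignment** (exhaustive over
permutations, exact for the $N \le 8$ used here) rather than greedily,
because greedy matching can pair near-duplicate modules wrongly; greedy is
available as an option. `group_similarity()` pools matched pairwise
similarities across many sets and reports medians and quartiles, the
descriptive summaries used for inter-subject comparisons.

`fixed_factor_fit()` is the cross-reconstruction procedure: reconstruct PTB
envelopes while holding one factor from the UPT fit fixed, updating only the
free factor for exactly 1000 multiplicative updates from a seeded random
initialization. Two details are open in the source material and were
decided here:

* The random "free-to-vary" baselines fix a seeded uniform matrix of the
  same shape in place of the UPT factor (the description of which factors
  combine with random matrices is internally inconsistent in the source;
  both wirings are reachable since the function accepts any fixed matrix).
* Fixing "UPT activations" requires an $N \times 200$ matrix while the UPT
  factors come from a concatenated fit; `cycle_average_activations()` folds
  the concatenated activations back onto one cycle by averaging. No time
  warping is applied anywhere — the shared 200-point normalization is the
  alignment.

## Co-contraction and kinetics

Stance is segmented from the vertical GRF with a 20 N threshold and a 5 ms
debounce (`detect_stance()`). CoM power is $F \cdot v / m$ in W/kg
(`com_power()`; per-body-*weight* normalization is a flag, but W/kg is what
the reported units imply). The load-acceptance (LA) phase is the contiguous
negative-power span, propulsion (PRP) the positive span; with noisy traces
that change sign more than once, the longest negative span before the
longest positive span is used and a message is emitted. Phase works
`w_lac`/`w_prp` are trapezoidal integrals with the crossing trapezoid split
between phases, so the two works partition the whole-trace integral.

Three epochs drive the co-contraction analysis (`cycle_epochs()`): PRE, the
10 ms before initial contact; LA, from initial contact to the negative
CoM-power peak; PRP, a 50 ms window centred on the positive peak ("around
the peak" is not further specified; centring is our reading). On
stance-normalized envelopes, `epoch_mean_amplitude()` averages each muscle
per epoch, and

$$ \mathrm{CCR} = \frac{(\mathrm{BF}+\mathrm{ST})/2}
                       {(\mathrm{VM}+\mathrm{VL}+\mathrm{RF})/3}, \qquad
   \mathrm{CCI} = \overline{m}_5 \times \mathrm{CCR}, $$

where $\overline{m}_5$ is the grand mean of the five knee muscles' epoch
means. The CCI sentence in the source is grammatically ambiguous (pool all
five muscles, or average the two group means first); the grand-mean reading
is the default and a sum-based variant sits behind `method = "sum"`. CCR is
invariant to a common rescaling of the five muscles; CCI is homogeneous of
degree 1 — both properties are tested.

`com_speed()` reads the approach speed from the CoM trajectory 200–100 ms
before contact (central differences after a 10 Hz low-pass);
`horizontal_force_peaks()` takes max $|F_y|/m$ and $|F_x|/m$ over the first
half of stance (absolute values — whether signed peaks were intended is
unstated); `series_peaks()` extracts phase-wise extrema and timings for any
stance-aligned joint series, which are treated strictly as inputs (no
inverse dynamics here).

## The synthetic generator

`simulate_subject()` emulates one subject of the emulated protocol: 10
unperturbed trials and 1 perturbed trial (the perturbation arrives
unannounced on the last trial), each a 16-muscle by 200-point envelope, plus
per-trial force-plate/CoM traces (1024 Hz forces, 256 Hz kinematics, 330 ms
stance, 71 kg, 2.67 m/s approach, ~1500 N peak vertical force, ~10 and
~7 N/kg horizontal force peaks). Initial contact sits at 30% of the
normalized cycle.

Ground truth (`cutting_truth_preset()`) plants five modules: pre-contact
dorsiflexors/quadriceps, hamstrings/hip extensors at initial contact, knee
extensors in load acceptance, plantar flexors in propulsion, and a
trunk/late-cycle module, with activation peaks at 8, 37.2, 64.1, 82.9 and
96% of the cycle — the three middle timings at values reported for cutting,
the outer two placed in the uninstrumented parts of the cycle. Choices a
user should know about, with their reasons:

* **Noise model** — additive Gaussian on the envelope, clipped at zero, with
  sd equal to `noise_level` times the clean-mixture RMS (default 0.05).
  Envelopes are nonnegative and no noise model is documented for such data;
  truncated Gaussian is the simplest compatible choice. Clipping biases the
  realized noise sd downwards; the bias stays below 10% up to
  `noise_level = 0.2` given the next item.
* **Tonic baseline 0.04** — each activation signal is a Gaussian bump
  (width 6% of cycle) on a 4% tonic floor. Real envelopes never rest at
  exactly zero, and without the floor the clipping bias explodes on
  zero-activity samples (a clipped half-normal has sd $0.58\sigma$). The
  level is deliberately small: a large floor makes all activation signals
  share a common direction, blurring the planted dimensionality. 0.04
  satisfies both constraints with margin; this trade-off is the single most
  consequential generator constant.
* **Distinct planted modules** — random weighting columns (40% sparsity) are
  redrawn until pairwise cosines stay below 0.6, comfortably under the
  $r > 0.80$ "same module" criterion. Unconstrained uniform draws in 16
  dimensions are often cosine-0.75+ similar, which would mean the "five
  planted modules" are not actually five distinguishable modules.
* **Condition effect** — the perturbation multiplies the hamstring module's
  activation by 0.85 inside 30–60% of the cycle (initial contact through
  load acceptance). The gain was set so the downstream LA-epoch CCR
  reduction (~15%) is of the order reported for perturbed cutting (~11%),
  rather than a caricature.
* **Inter-trial variability** — by default trials differ only by noise;
  peak-time jitter exists (`jitter_pct`) but is off, because the source
  material does not characterize inter-trial variability and a zero default
  keeps the zero-noise identity $X = SP$ exact.
* **Kinetic traces** — a half-sine vertical GRF, braking/medial force bumps
  peaking in the first half of stance, and a vertical CoM velocity shaped so
  the power is strictly negative then strictly positive with one sign change
  at mid-stance. These traces are synthetic stand-ins with the right *shape
  constraints*, not biomechanical simulations: work magnitudes, for
  instance, are smaller than in real maximal cutting.

What passing tests on these data do and do not show: they validate the
*machinery* — that the pipeline recovers a known low-dimensional structure,
orders reconstructions correctly, and computes the defined quantities — on
data with exactly the statistical structure the model assumes (cycle-locked
unimodal activations, stationary weightings, homoscedastic envelope noise).
Real EMG has trial-to-trial timing variability, non-stationary baselines,
crosstalk and artifacts that the generator does not emulate, so test results
here do not certify performance on real recordings.

## Problem sizes and determinism

The test suite and the acceptance script run the recovery study at 16
muscles, 5 modules, 10 trials and 5% noise across 50 (suite) or 20 (script)
seeds, with 3 restarts, `tol = 1e-5` and 500 iterations per curve fit —
settings chosen as the package's standard study configuration; the slower
defaults give the same selections. Every stochastic step takes an explicit
seed, and reports carry full provenance (seeds, restarts, iterations), so
`run_subject()` output is reproducible to the bit.

## Known limitations

* Optimal module matching is exhaustive over permutations and falls back to
  greedy above $N = 8$.
* The envelope pipeline low-passes before segmentation boundaries are
  applied, so extreme windows near recording edges rely on the reflective
  padding.
* `select_dimensionality()` needs a contiguous curve starting at $N = 1$.
* The fixed-activation cross-fit depends on the cycle-averaging convention
  for concatenated activations; alternatives (e.g. per-trial fits) are easy
  to express but not built in.
* C3D reading is out of scope; data enter as the package's CSV/TSV dialects.
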