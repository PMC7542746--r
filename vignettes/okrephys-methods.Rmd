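---
title: "Quantifying Purkinje-cell intrinsic excitability and OKR gain: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Purkinje-cell intrinsic excitability and OKR gain: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(okrephys)
```

## The scientific problem

Cerebellum-dependent oculomotor learning — here, adaptation of the
optokinetic response (OKR), the reflexive eye movement that follows motion of
the visual surround — leaves cellular traces in floccular Purkinje cells.
One candidate trace is a change in *intrinsic excitability*: how readily a
cell fires in response to direct somatic current, independent of synaptic
input. Testing that idea requires two measurement pipelines and a
statistical layer joining them:

1. **Oculography**: from screen (stimulus) and eye position traces, compute
   the OKR gain — the ratio of the fitted eye oscillation amplitude to the
   fitted screen amplitude at the stimulus frequency — before and after
   training, and compare per animal (paired t).
2. **Current-clamp feature extraction**: from step-protocol sweeps, extract
   the F–I curve (mean firing rate vs injected current), the rheobase, the
   single-AP waveform features (threshold, amplitude, afterhyperpolarization)
   and the input resistance, keeping only regular-spiking cells.
3. **Group statistics**: Welch t comparisons per single-cell feature, and a
   linear mixed model over the F–I curve (firing rate ~ group × step with a
   random intercept per cell) with a likelihood-ratio test for the
   group-involving terms and per-step contrasts.

The recordings behind the original study are not deposited, so the package
ships a *ground-truthed synthetic generator* for both data arms. Every
analysis stage is validated against quantities the generator knows exactly:
its spike registry, its closed-form rheobase, its quick-phase log, and the
per-cell parameters it drew.

## The neuron model and why it was chosen

Cells are simulated with the adaptive exponential integrate-and-fire (AdEx)
model,

$$C \frac{dV}{dt} = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T} - w + I(t),
\qquad
\tau_w \frac{dw}{dt} = a (V - E_L) - w,$$

with a spike registered when $V$ reaches the cutoff, followed by reset to
$V_r$ and $w \mathrel{+}= b$. AdEx is not a biophysical Purkinje-cell model
(no ionic conductances — deliberately out of scope); it was chosen because

* in the non-adapting limit ($a = 0$) its rheobase has a closed form,
  $I_{rh} = g_L (V_T - E_L - \Delta_T)$ (the current at which the
  subthreshold fixed points vanish in a saddle-node), giving an exact oracle
  for the pipeline's rheobase measurement;
* parameter changes produce both tonic firing and bursting/stuttering
  phenotypes, so the regular-spiking inclusion filter has realistic work to
  do.

Default parameters describe a Purkinje-like cell: $C = 150$ pF,
$g_L = 10$ nS (100 MΩ input resistance, 15 ms membrane time constant),
$E_L = -65$ mV, $V_T = -50$ mV, $\Delta_T = 2$ mV, reset $-58$ mV, cutoff
$+20$ mV, 2 ms refractory, mild spike-triggered adaptation
($a = 2$ nS, $b = 60$ pA, $\tau_w = 120$ ms). This puts rheobase near
150–200 pA and top rates near 100–150 Hz over the +100…+1200 pA series —
the regime the standard protocol is designed for. The non-regular phenotype
(20% of cells by default, matching a regular-spiking majority above 79%)
overrides the reset to $V_T + 5$ mV with strong slow adaptation
($b = 300$ pA, $\tau_w = 300$ ms, $a = 6$ nS), which yields spike doublets
and bursts separated by long adaptation-governed silences — high ISI
coefficient of variation and large gaps, exactly what the inclusion rule
screens out.

Membrane noise is parameterized by its *stationary standard deviation* in
mV (default 0.8 mV for generated cohorts): the per-step Gaussian increment
is scaled by $\sigma \sqrt{2\,dt/\tau_m}$ so the free membrane fluctuates
with SD $\sigma$ regardless of $dt$.

### Numerical scheme

Integration is fixed-step Heun (explicit trapezoidal, second order) at
$dt = 0.01$ ms (simulations reject $dt > 0.05$ ms). Spikes are handled as
continuous-time events: once the trajectory crosses a registration trigger
($\min(\text{cutoff}, V_T + 8\Delta_T)$, beyond which the exponential
blow-up to the recorded peak takes microseconds), the crossing time is
located by interpolation within the step, the refractory period ends at
`spike + t_ref` in continuous time, and integration resumes with a partial
step. Sample-quantized resets would otherwise accumulate one-sample timing
biases per interspike interval; with event handling, halving $dt$ moves
spike times by under ~0.1 ms across 500 ms trains (the suite asserts
< 0.5 ms). The exponential term is clamped at $e^{30}$ against overflow
and dropped below $e^{-9}$, where it contributes under $10^{-3}$ pA.

## Feature extraction: definitions and defaults

All knobs live in `feature_config()`; internal units are fixed at mV, pA,
ms, MΩ, Hz, with conversion only at the I/O boundary.

* **Spike detection** — upward crossings of a fixed level (default
  $-20$ mV) with a 1 ms lockout. Simple and auditable; Purkinje somatic
  spikes are large, so the level is uncritical over tens of mV.
* **Mean firing rate** — spikes with onset ≤ t < offset divided by the step
  duration; rebound spikes after the step do not count.
* **Rheobase** — amplitude of the first sweep of the ascending
  fine-increment series (50 ms steps, 10 pA apart) containing a spike
  inside the step window; absent (not an error) if no sweep spikes. Short
  steps overshoot the sustained (500 ms / closed-form) rheobase by up to a
  few tens of pA — charging time and spike latency near the saddle-node —
  which the oracle tests bound at 60 pA.
* **AP threshold** — searching backward from the spike peak, the voltage
  where the centred-difference $dV/dt$ last rises through 20 mV/ms. The
  criterion is a config knob (`dvdt_criterion`); an optional moving-average
  half-width (`smooth`) can precede differentiation, off by default. With
  Purkinje-scale capacitance this operational threshold sits several mV
  above the AdEx $V_T$; the tests bound it against fine-$dt$ reference
  integrations rather than against $V_T$ itself.
* **AP amplitude** — peak minus threshold (not peak minus baseline).
  Flat-topped spikes (possible amplifier clipping) use the maximum sample
  and log a warning.
* **AHP amplitude** — threshold minus the post-peak minimum within a 10 ms
  window, floored at 0. The window is additionally capped at the command
  step offset: the AHP is defined under sustained drive, and letting the
  window run into post-stimulus repolarization would bias late-latency,
  near-rheobase spikes (the repolarization depth depends on the reset–rest
  distance, which can differ systematically between groups).
* **Input resistance** — (steady-state − baseline voltage) / step
  amplitude on a hyperpolarizing sweep; steady state is the final 20% of
  the step, baseline the 50 ms before onset. With subthreshold adaptation
  the steady-state slope conductance is $g_L + a$, and the generator's
  manifest records $1/(g_L + a)$ as the recoverable truth.
* **Regular-spiking rule** — evaluated at the first sweep with ≥ 5 spikes:
  regular iff the ISI coefficient of variation is ≤ 0.5, no gap exceeds
  3 × the median ISI, and firing persists into the final 20% of the step
  (no depolarization block). Fewer than 3 suprathreshold sweeps, or no
  sweep with 5 spikes, labels the cell non-regular with a warning. These
  thresholds operationalize a criterion the source literature leaves
  qualitative; they recover generated phenotypes with ~97% agreement.

## Oculography: desaccading and gain

The synthetic stimulus is $A\sin(2\pi f t)$ with $f = 0.5$ Hz and $A = 5°$
peak amplitude by default. Protocol descriptions of the form "±5°
peak-to-peak" are ambiguous between peak and peak-to-peak conventions (the
two differ by 2×); the simulator takes *peak* amplitude and exposes it as
`stimulus_amplitude`. Since gain is a ratio, downstream results are
insensitive to the convention. The eye trace follows with a gain below one,
plus slow drift (0.05 °/s), measurement noise (0.3° SD), and Poisson-timed
quick phases: 300 °/s resetting ramps that recentre the non-stimulus
component and land ~`saccade_amplitude` to a random side, each logged for
validation.

* **Desaccading** masks samples whose velocity exceeds 50 °/s, padded by
  50 ms per side. Velocity is the centred difference of a 25 ms
  moving-average-smoothed position: at video-oculography sampling rates,
  raw sample-to-sample noise masquerades as tens of °/s and would saturate
  the mask, while the stimulus' slow-phase peak velocity (~16 °/s) stays
  far below threshold either way. Records with > 60% masked samples are
  rejected as unanalyzable.
* **Sinusoid fitting** is linear least squares of
  $a\sin(2\pi f t) + b\cos(2\pi f t)$ plus baseline terms on unmasked
  samples; amplitude $\sqrt{a^2+b^2}$, phase $\mathrm{atan2}(b, a)$
  (positive = eye leads screen). Masked samples are excluded, never
  interpolated. Because each quick phase displaces the eye, the slow-phase
  trace is a sinusoid on a piecewise-constant baseline; the per-record
  analysis therefore fits one offset per contiguous unmasked segment
  (`segment_offsets = TRUE`), which reduces to the classic 3-parameter fit
  when nothing is masked. This removes the offset-step leakage that
  otherwise biases the amplitude by several percent on saccade-rich
  records; with it, recovered gains sit within ~1.5% of truth at default
  noise.
* **Gain** is the eye/screen fitted-amplitude ratio from position fits
  (matching how such traces are conventionally fitted); a velocity-domain
  gain is not implemented. Pre/post learning comparison is a paired t over
  per-animal gains (`pre − post`, so learning yields a negative statistic).

## Statistics

* `paired_t()` and `welch_t()` wrap the classical tests (two-sided; Welch–
  Satterthwaite df by default, pooled variant behind a flag — the
  unequal-variance form is the package default because reported
  non-integer dfs in this literature indicate it). All-zero paired
  differences report t = 0, p = 1; zero variance around a non-zero
  difference is rejected as degenerate.
* `lmm_fi_comparison()` fits `rate ~ group * step + (1 | cell)` by maximum
  likelihood and reports the likelihood-ratio χ² of *all group-involving
  terms* (group main effect + group:step interaction) against the
  group-free null. The df is the parameter-count difference of the two
  fitted models — 12 for the standard 12-step protocol — not a hard-coded
  constant, since which single term a published χ² with df = 11 tested is
  generally not recoverable. Per-step group contrasts use a single-step
  multivariate-t ("mvt") adjustment over the 12-contrast family, in the
  Tukey spirit; if that adjustment fails numerically the output falls back
  to Holm and says so. A singular random-intercept fit falls back to the
  fixed-effects model, labelled in the output. The grouping unit is the
  cell (repeated measures across steps); per-animal nesting is not modelled
  because the animal of each cell is not tracked by the generator.
* `summarize_groups()` excludes non-regular cells first (with a full
  exclusion table), then applies Welch comparisons to rheobase, AP
  threshold, AP amplitude, AHP amplitude and input resistance, and the
  mixed model to the F–I table. A feature absent for an entire group is
  skipped with a warning, never silently.

## What the generator emulates — and what it does not

The synthetic cohorts reproduce the *structure* of the real experiment:
group sizes (89/67 recorded cells by default), the exact protocols (500 ms
steps from +100 to +1200 pA in 100 pA increments; 50 ms steps in 10 pA
increments spanning each cell's expected rheobase, as an experimenter would
range them; one hyperpolarizing step), a regular-spiking majority with a
bursting minority, between-cell parameter jitter, membrane noise, and for
the eye: gain below one, drift, noise and quick phases. They do **not**
emulate dendritic or climbing-fibre events, ionic conductance diversity,
electrode/access artefacts, true Purkinje AP waveforms (AdEx spikes are
stylized), session-level drifts in oculography, or video tracking error
structure. Green tests therefore certify the *pipeline* — detection,
measurement definitions, masking, fitting, model code — on data whose
ground truth is known; they do not certify that the AdEx waveform is a
faithful Purkinje cell.

Monte-Carlo problem sizes in the test-suite were chosen to estimate each
property with useful precision: 100-cell parameter sweeps for the rheobase
oracle, 50 cells for noisy input-resistance recovery, 200 seeds for gain
recovery, 1000 null replicates for the t-test calibrations and 1000
fresh-draw null cohorts for the mixed-model likelihood-ratio calibration,
and 100 end-to-end cohort replicates at n = 30/30.

## Known limitations and open choices

* **Power of the joint LRT at small n.** With the default between-cell
  variability (10% SD on $g_L$ and $C$, 20% on the adaptation increment,
  ~1 mV on voltages — if anything conservative relative to real Purkinje
  heterogeneity), a +4 mV soft-threshold shift moves F–I rates by only
  ~7 Hz against between-cell SDs of ~20% of rate. At 30 cells per group the
  df = 12 joint likelihood-ratio test then reaches significance in roughly
  85% of cohorts, although the *direction* of both effects (higher
  rheobase, lower rates in the learned group) is recovered essentially
  always. Detecting such effects reliably needs either the full study-sized
  cohort or a more concentrated test; the package reports the joint test
  by design and does not pretend otherwise.
* **Operational AP threshold ≠ model $V_T$.** The 20 mV/ms criterion lands
  several mV above the AdEx soft threshold, by an amount depending on
  capacitance and $\Delta_T$. Comparisons between groups are unaffected
  (the offset is common), but absolute thresholds should be read as
  criterion-dependent.
* **Single-frequency fit.** The sinusoid fit models the fundamental only;
  harmonic distortion of real slow phases ends up in the residual. A
  harmonic extension would be straightforward but is not implemented.
* **Axon Binary Format** ingestion is not included; recordings must be
  exported to the documented delimited sweep dialect.
* The t = 0 / p = 1 convention for exactly identical paired samples is a
  pragmatic choice for degenerate synthetic input, not a statistical
  recommendation.

## Reproducibility

Every generator takes an integer seed and restores the caller's RNG state;
`run_pipeline()` writes its resolved configuration, an MD5 fingerprint and
a manifest, and a rerun with the same configuration and seed reproduces the
report bundle byte for byte.
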