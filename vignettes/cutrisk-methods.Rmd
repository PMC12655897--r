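---
title: "Methods: cutting-biomechanics risk screening in cutrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cutting-biomechanics risk screening in cutrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cutrisk)
```

## The screening problem

Non-contact ACL injuries in football cluster around cutting maneuvers, and
athletes returning to sport after reconstruction frequently retain the
kinematic signatures that load the ligament: a stiff, knee-extended landing
with compensatory hip flexion, frontal-plane knee collapse, and poor
trunk–pelvis control. `cutrisk` screens for these signatures from
wearable-sensor joint kinematics recorded on the pitch during two task
classes: a pre-planned ~90° cut inside an agility T-drill (AGTT) and an
unplanned football-specific deceiving action (FS). Everything is referenced
to matched healthy-control data, so the output is always "how far from
normal," never an absolute verdict.

## Event detection

Foot contacts are local minima of the pelvis vertical velocity after a
zero-lag 4th-order Butterworth low-pass at 10 Hz (`lowpass_hz`). Minima must
have prominence ≥ 0.1 m/s (`min_prominence`) and be ≥ 0.2 s apart
(`min_separation_s`) — standard settings for 100 Hz running data; the
vertical pelvis excursion at running cadence produces ~0.8 m/s
peak-to-trough oscillations, an order of magnitude above sensor noise. The
filter is applied forward and backward (with odd-reflection edge padding) so
that smoothing never shifts event timing.

The stance window of the final pre-cut foot strike (FC window) runs from
that contact to the next detected contact, capped at 0.5 s (`max_stance_s`)
so a missed contact cannot inflate the window. Its two evaluation frames
are **IC**, defined as the window-opening foot strike itself (the natural
reading; no alternative definition is given in the source material), and
**pKF**, the within-window maximum of the stance limb's knee flexion.

## The multistep cut-angle algorithm

At each interior contact the candidate angle is the angle between the
normalized horizontal pelvis displacements to the 5th preceding and 5th
following contact (`candidate_k = 5`). Using displacements over five steps
averages out step-to-step lateral sway; using fewer makes candidates noisy,
more smears the cut across neighbors. Three filters follow:

1. **Plausibility**: only 10–110° can be cut angles for these tasks;
   boundaries are kept inclusive because the stated rule discards angles
   *below* 10° and *above* 110°.
2. **Velocity interval**: a cut is a deceleration into the plant followed by
   re-acceleration, so eligible candidates must lie between a local maximum
   of the resultant horizontal speed and the subsequent local minimum.
   Extrema need prominence ≥ 0.3 m/s (`speed_prominence`): the
   peak-to-dip excursion of a genuine cut is of order m/s while filtered
   noise ripple is an order of magnitude smaller, and ripple-level "minima"
   on the deceleration slope would otherwise truncate the interval early.
   The interval's minimum end is padded by 0.05 s
   (`velocity_interval_margin_s`) because the detected contact and the
   filtered speed minimum are estimated from different signals and need not
   coincide to the sample. Extrema within 0.15 s of the trial edges are
   ignored (zero-phase filter edge transients).
3. **Derivative window**: the mediolateral velocity changes sharply at the
   plant. Within a 1 s search window (`derivative_search_s`; no length is
   stated in the source, 1 s comfortably covers stance) after the global
   speed peak, the first local maximum of the *magnitude* of the
   (filtered) mediolateral-velocity derivative is located — magnitude,
   because the transient's sign depends on cut direction. The maximum must
   have prominence ≥ 0.5 × the window's peak (`deriv_prominence_frac`);
   a genuine direction-change transient dominates this window, so the
   threshold rejects ringing without ever rejecting the transient itself.
   Candidates within ±250 ms survive (`derivative_window_s = 0.5`, read as
   centered since only "around this maximum" is stated).

The highest surviving angle is the trial's cut angle (ties break to the
earliest sample, for determinism). An empty set at any stage is reported as
no-cut-detected with the stage name; such trials are excluded from the
report sections but listed with their failure stage.

## Performance, dials

Speed is the horizontal magnitude of the pelvis velocity — the pelvis
sensor trajectory proxies the center of mass, which is not available
without the vendor's full-body model. Acceleration is its
central-difference derivative. The entry window is the 2 s before the FC
window; the exit window mirrors it at 2 s (`exit_window_s`; unstated in the
source) after the window, clipped to the trial end with the clip flagged.
Each metric's z-score against control norms drives a seven-level dial,
`sign(z) * min(3, floor(|z|))`: 0 (green) within ±1σ, ±1 (yellow), ±2
(orange), ±3 (red) beyond ±3σ. By construction ~68% of healthy-control
draws land on dial 0.

## Asymmetry

Per joint, each limb is summarized by its peak sagittal angle within the FC
window — the sample of largest magnitude, which preserves sign for
plantarflexion-dominant ankle traces — averaged over that limb's trials.
The asymmetry percentage is the symmetric mean-normalized difference

$$\mathrm{pct} = 100\,\frac{|a_\text{inj} - a_\text{non}|}{\tfrac12(|a_\text{inj}| + |a_\text{non}|)}$$

No formula is stated in the source material; this one is symmetric under
limb swap, scale-invariant, and can exceed 100% (as reported clinically for
ankle flexion), all properties the published examples require. A max-based
denominator is available via `asym_denominator = "max"`. Scores bin as
<20% → 0, 20–50% → 1, 50–70% → 2, ≥70% → 3, with shared edges going to the
higher score (the stated "<20%" bound forces 20 upward; 50 is resolved
upward for conservatism). An asterisk-style `extreme` flag fires when the
percentage sits more than 3σ above the control asymmetry distribution.

## Risk factors and thresholds

Nine factors, three categories: SKL = {HK, HF, KF, AF}, KVC = {KV, HA, HI},
TPI = {TIB, TCR}. All are instantaneous stance-limb values at the frame
sample except HK, the ratio of the median knee-flexion angle to the first
quartile of the hip-flexion angle, computed over a 100 ms sub-window
(`hk_window_s`) centered on the frame and clipped to the FC window: the
ratio is defined through window statistics but thresholds are
frame-specific, and a frame-centered sub-window reconciles the two.

Classification is directional: "above" factors (HK, HF, KV, HI, TIB, TCR)
are at risk when exceeding the threshold, "below" factors (KF, AF) when
falling under it, and HA — a single factor with two bounds — when outside
its [adduction, abduction] band. The deviation percentage against the
violated bound is `100·|value − thr|/|thr|`, with >100% marked extreme
("double or half the threshold"). When the violated threshold is exactly 0
(the FS/IC HK strata) the percentage is undefined; the deviation is
reported in absolute units and excluded from the extreme rule.

A trial is at **overall risk** at ≥ 4 simultaneous factors. A category is
at risk in a trial only when *all* of its factors are (4/4, 3/3, 2/2); the
dashboard light turns red when that happens in at least one trial, with the
percentage of such trials also reported. Player-level per-factor
percentages of trials at risk bin as <20 green, 20–50 yellow, >50–70
orange, >70 red (shared edges to the lower bin, since the stated wording is
"between").

Thresholds are bundled (the published 8-strata × 10-value table, carried
byte-for-byte in `inst/extdata/table1_thresholds.csv`; the one "> −0.0"
entry is carried as 0.0) or derived from control cohorts as μ ± 1.05σ. The
stated "additional ±5% conservative tolerance" is applied as a 5% inflation
of σ rather than of the threshold: several published thresholds sit at or
near zero, where percent-of-threshold degenerates, while σ-inflation is
well-defined everywhere and strictly conservative. `tolerance_pct` and the
alternative interpretation remain config-exposed.

## The synthetic world

`generate_cut_trial()` emulates exactly the features the pipeline keys on,
and nothing more:

- pelvis horizontal path: straight approach, single-sample heading change
  of the requested angle at the cut contact, straight exit;
- horizontal speed: rises to the approach speed 0.4 s before the cut, dips
  to 55% of the slower of approach/exit speed at the plant, recovers to the
  exit speed — the minimal profile with the peak→dip structure the velocity
  filter requires;
- vertical velocity: a 0.4 m/s-amplitude cosine at step frequency whose
  minima are the ground-truth contacts, tapered to zero at quarter-period
  zero crossings outside the contact span;
- joint angles: per-stance raised-cosine bumps whose IC value and
  mid-stance peak are independently controllable, so factor values can be
  planted exactly at both evaluation frames (`factor_targets`); pKF falls
  at mid-stance by construction. HK cannot be planted directly (it is a
  derived ratio); its ground truth is computed from the clean bump curves.
- noise: additive white Gaussian, one `noise_sd` knob covering angles
  (degrees) and velocities (m/s). The default 0.05 reflects that
  vendor-fused inertial kinematics are smooth — the moderate level used in
  the event-detection robustness criterion — and is deliberately a single
  stated value, not tuned per test.

What a green test therefore establishes: the algorithm recovers events,
angles and planted factor values from signals containing the stated
features under the stated noise. What it does not establish: performance on
real sensor artifacts (soft-tissue wobble, autocorrelated drift, dropped
samples), multi-cut trials, or the side-shuffle sub-phases of the agility
drill — none of which the generator models.

Control cohorts (`generate_control_cohort()`) draw per-player factor values
from stated normal distributions and embed them in trials, which is what
the threshold-derivation and norms machinery consume in tests.

## Numerical choices and degenerate inputs

- Candidate angles use `acos` of a dot product clamped to [−1, 1].
- Derivatives are central differences; one-sided at the ends.
- Time steps must be uniform to 1e-6 s; NaN anywhere fails validation — no
  silent interpolation, since 100 Hz vendor exports are gap-free and gaps
  indicate sensor faults.
- Trial files serialize numbers at 15 significant digits; write→read round
  trips are bit-faithful to well below 1e-9 relative error.
- Reports serialize to JSON with fixed 10-digit precision, making repeated
  runs byte-identical; rendering (HTML with inline SVG dials, bars, pies,
  dashboard) only formats numbers already present in the JSON.
- Ties anywhere (max angle, pKF sample) break to the earliest sample.

## Known limitations

- IC is the detected foot strike; without force plates, true initial
  contact may differ by a few samples.
- The stance end is the next contact (capped at 0.5 s), not toe-off;
  toe-off is not observable from pelvis velocity alone.
- The asymmetry scalar (FC-window peak) and the asymmetry formula are
  package choices where the source is silent; both are config-exposed.
- Normative statistics computed from small control cohorts are noisy;
  `derive_thresholds()` insists on ≥ 2 observations per stratum but
  meaningful thresholds need far more.
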