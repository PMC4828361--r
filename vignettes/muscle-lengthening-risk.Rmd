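---
title: "From marker trajectories to muscle over-lengthening risk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From marker trajectories to muscle over-lengthening risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinerisk)
```

## The problem

Repetitive stress injuries (RSIs) of muscle develop through accumulated
micro-trauma rather than a single impact. Animal work locates a practical
danger zone: repeated lengthening beyond roughly 120 % of a muscle's rest
length. Complex motor skills — a maximal instep kick, a dancer's fan kick, a
martial-arts axe kick, a baseball pitch — drive joints through large ranges
of motion (ROM) and can push specific muscles past that limit on every
repetition. `kinerisk` implements the full chain needed to quantify this
from optical motion capture: labelled 3D marker trajectories in, a
per-muscle risk report out.

## Pipeline

1. **Input.** A `marker_series`: positions (mm) of labelled reflective
   markers at a fixed frame rate (default 200 Hz, matching common capture
   protocols), with an explicit missing flag per sample. Readers exist for
   TRC (primary, text), C3D (binary, Intel/float dialect) and a long CSV.
2. **Gap filling** (`fill_gaps`). Interior occlusion gaps up to `max_gap`
   frames (default 10, i.e. 50 ms at 200 Hz) are linearly interpolated per
   coordinate; edge gaps are held at the nearest observed value; longer
   gaps stay missing and are reported.
3. **Smoothing** (`smooth_five_point`). The classic five-point filter with
   weights (1, 3, 4, 3, 1)/12, applied to each marker coordinate before any
   model fitting. The first and last two samples use the truncated kernel
   renormalised to unit sum: this keeps the output length equal to the
   input length without extrapolating beyond observed data. On white noise
   the interior gain is `sqrt(36/144) = 1/2` in SD.
4. **Segment poses** (`fit_segment_pose`, `fit_poses`). The body is 15
   rigid segments (head, upper and lower trunk, paired upper arms,
   forearms, hands, thighs, shanks, feet). Each segment's pose per frame is
   the least-squares rigid transform (Kabsch/SVD with a determinant guard
   against reflections, no scaling) aligning its marker template to the
   observed markers. Frames with fewer than three usable markers are
   invalid for that segment; collinear templates are rejected outright.
5. **Joint angles** (`compute_joint_angles`). The relative rotation
   `t(R_parent) %*% R_child` is decomposed in a configurable Cardan
   sequence, default `YXZ`: flexion/extension about the medio-lateral axis
   first, then abduction/adduction, then axial rotation — the clinical
   ordering. Angles are unwrapped over time (adjacent-frame jumps above
   180° corrected by 360°) and frames whose middle angle comes within 1° of
   ±90° carry a gimbal warning flag. ROM is simply max − min
   (`compute_rom`); `angular_velocity` uses central differences with
   one-sided edges and reports the peak speed and the steepest post-peak
   deceleration interval.
6. **Muscle lengths** (`muscle_series`). Muscles are straight polylines
   through attachment points fixed in segment frames (origin, optional via
   points, insertion). The length at a frame is the sum of consecutive
   Euclidean distances after transforming each point through its segment's
   pose. Rest length is the same evaluation at the neutral standing
   posture, and normalised length is `100 * length / rest_length`.
   Lengthening speed is the central-difference derivative in m/s; work
   pattern is classified from its sign with a ±0.005 m/s dead band
   (`lengthening` / `shortening` / `isometric`).
7. **Risk** (`assess_risk`, `rank_muscles`). A muscle is flagged when its
   maximal normalised length *strictly* exceeds the threshold (default
   120 %, following the ">120 %" formulation of the criterion).
   `detect_impact_like` looks for the signature of impact-like eccentric
   loading: lengthening speed rising from at-or-below a reference level to
   at least `rise_factor` (3) times that level within `rise_window`
   (100 ms) while the muscle lengthens. For pitching trials,
   `segment_pitch_phases` locates the seven standard events (initial
   position, balance point, foot contact, maximum external rotation, ball
   release, maximum internal rotation, fielding position) and the six
   phases between them.
8. **Statistics** (`describe`, `t_test_raw`, `t_test_from_summary`,
   `run_comparison`). Group results are mean ± SD with n; skills are
   compared with independent two-sample t-tests, pooled variance by
   default (Welch by flag), two-sided p, α = 0.05. Because published
   movement studies often report only summaries, the summary-driven test
   is a first-class interface and is algebraically identical to the raw
   test applied to samples with those moments. No multiple-testing
   correction is applied (none is conventional in this literature) — treat
   families of comparisons accordingly.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `frame_rate` | 200 | Hz | standard optical-capture rate for fast skills |
| `max_gap` | 10 | frames | 50 ms: about the longest occlusion a linear bridge survives |
| smoothing weights | (1,3,4,3,1)/12 | — | the five-point smoothing function used on raw coordinates |
| Cardan `sequence` | YXZ | — | flexion first, the clinical convention; configurable per joint |
| `threshold` | 120 | % rest | the RSI over-lengthening criterion; strict `>` |
| `rise_window`, `rise_factor` | 100 ms, 3 | — | encode "speedy increase … in under 100 ms"; the detection rule itself is this package's construction |
| `dead_band` | 0.005 | m/s | keeps 200 Hz numerical ripple out of the isometric class |
| `alpha` | 0.05 | — | significance level of the skill comparisons |

## The synthetic generator

No capture recordings accompany the published group results, so the
`synthetic_data` module is the package's test bed. `preset_script` encodes
one curated trial per skill; `generate_motion` runs forward kinematics down
the joint tree, emits the 42 markers from their owning segments, then
applies seeded isotropic Gaussian noise and scripted occlusions. The
ground truth (prescribed angles, true poses, muscle lengths computed from
the true poses, pitch events) never touches the marker-fitting code, which
makes it a genuine oracle for the pipeline.

Choices worth knowing:

* **Excursions are the published group means**: hip flexion/extension
  129° for the instep kick; 146.3° (fan) vs 162.2° (axe); knee 108.9° vs
  65.3°; and so on. Curve *shapes* are plausible splines — amplitude is
  calibrated (the sampled curve is rescaled so its realised range equals
  the excursion exactly), timing and waveform are inventions.
* **Durations**: instep kick 1.2 s, fan kick 2.0 s, axe kick 1.0 s (about
  half the fan kick, as reported), pitch 2.0 s, all at 200 Hz.
* **Gimbal safety**: abduction/adduction (the middle Cardan angle) uses
  near-zero-mean shapes so the scaled curve stays clear of ±90°.
* **Pitch timing**: the shoulder-rotation extrema sit in symmetric
  parabolic caps wider than the smoothing kernel, so the five-point filter
  does not move the event frames; the lead-leg lift is a raised-cosine
  bump. Event ground truth is computed from the prescribed series by the
  same definitional rules the detector uses (peak foot height, return
  threshold, rotation extrema, hand-speed peak) — what the round trip
  tests is the marker-fitting chain, not the event definitions.
* **Body geometry** is a 1.70 m reference body; marker and attachment
  coordinates are plausible fixtures, not anatomical ground truth. The
  published prose marker list sums to 42 but leaves each thigh with too
  few rigid markers for pose fitting, so the default set substitutes the
  two scapula markers with second thigh markers and places joint-adjacent
  markers (acromion, lateral epicondyle, radial styloid, lateral tibial
  condyle, lateral malleolus) exactly at joint centres, letting adjacent
  segments share them rigidly.

What the generator does *not* emulate: soft-tissue artifact (markers ride
rigidly on segments), anthropometric variation beyond linear scaling,
ball/environment objects, and muscle wrapping. Passing round-trip tests
therefore demonstrates internal consistency of the pipeline, not validity
on real skin-marker data.

## Numerical choices and edge cases

* Missing samples are an explicit flag; zero is a valid coordinate.
* Pose fitting marks frames invalid rather than guessing when fewer than
  three markers survive occlusion; downstream series carry `NA` there.
* The zero-noise round-trip checks run with smoothing off: with nothing to
  smooth, the filter only attenuates signal, and on the fastest preset
  (axe kick) that attenuation alone moves muscle lengths by up to ~0.7 %
  near the edge frames — a property of the filter, not of the fit. ROM
  recovery stays within 1° either way; lengths are machine-precision
  accurate (< 1e-12) in the unsmoothed round trip.
* With 2 mm marker noise the ROM error budget differs by angle component,
  because ROM is an extreme-value statistic and each component has a
  different marker lever arm: flexion/extension stays within 2°, hip
  abduction/adduction within ~3°, knee abduction/adduction within ~5°, and
  axial rotation — observed from skin markers lying near the segment's
  long axis — can inflate by several degrees more. That hierarchy is a
  physical observability limit of marker-based capture, worth remembering
  when comparing small rotation ROMs between skills.
* `detect_impact_like` uses the series median as its reference level; when
  a mixed lengthening/shortening trial makes that median non-positive, the
  median of the lengthening part is used instead, and series whose
  reference level is below 0.01 m/s are treated as not lengthening at all
  (no events from numerical ripple).
* t statistics with zero variance in both groups and equal means are
  refused as undefined rather than returned as 0/0.

## Worked-example discrepancies

Re-running the risk rule on the published per-muscle means flags
adductor magnus, gracilis and semimembranosus for the instep kick and four
muscles (those plus biceps femoris) for the axe kick, exactly as published.
Two fine points surface when recomputing:

* For the fan kick the published table puts 127.9 ± 4.0 % in the gluteus
  medius row while the accompanying prose attributes the same number to
  rectus femoris (whose tabulated fan-kick value, 104.2 %, is below
  threshold). This package follows the table: five fan-kick muscles exceed
  120 %, with gluteus medius and not rectus femoris among them.
* The prose reports no significant fan-vs-axe difference for knee
  abduction/adduction and knee rotation; recomputing a pooled t from the
  printed knee-rotation summaries (28.2 ± 4.1, n = 7 vs 21.5 ± 4.3,
  n = 13) actually gives p ≈ 0.003. Subject-level data could resolve this;
  from summaries alone it cannot, so the package's tests assert the three
  positively printed bounds (hip flexion/extension p < 0.05, hip
  abduction/adduction p < 0.01, knee flexion/extension p < 0.01) and the
  two comparisons that recompute as non-significant.

## Problem sizes

The bundled checks use the four presets at their native lengths (201–401
frames, 42 markers, 15 segments, 9 muscles), 1 000 random rigid transforms
and rotations for the numerical oracles, and 10 000 replicates for the
null calibration of the t-test (rejection rate 0.05 ± 0.01 at n = 7 vs
13). These sizes make the whole suite run in well under a minute per
module on a single CPU while leaving the Monte-Carlo assertions
comfortably powered.

## Known limitations

* Straight-line muscle paths with fixed via points: no wrapping surfaces,
  so lengths of muscles that bend around bone (e.g. gluteals at deep hip
  flexion) are approximations.
* "Lengthening" is a kinematic proxy for eccentric work — without EMG or
  force data, a lengthening muscle is only presumed active.
* Rest length is defined operationally as the path length in the neutral
  standing posture; other definitions (e.g. optimal fibre length) would
  shift all normalised values.
* Per-segment independent fits: no whole-chain inverse kinematics, no
  joint-centre regression, no kinetics or inertial parameters.
* Default attachment coordinates are fixtures; quantitative risk
  assessments on real data require subject-specific or literature-based
  attachment geometry via `load_model_config`.
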