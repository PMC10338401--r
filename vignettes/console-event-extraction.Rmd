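---
title: "Console event extraction, hand-path metrics and annotation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Console event extraction, hand-path metrics and annotation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgevents)
```

## The problem

A da Vinci surgical console reports its own activity visually: screen-edge
lines appear when the surgeon's foot hovers over a pedal and change color
when it is pressed; bottom-panel icons switch when the clutch is engaged,
the third arm is swapped in, or the camera is being driven. No open data
port exposes these events, but the ocular video feed does — so discrete
console events can be recovered from video alone, on any console
generation, with nothing but a capture card. `surgevents` implements that
recovery plus the surrounding preparation steps (stereo cropping, stream
synchronization, hand-path kinematics, temporal annotation handling, and
cohort summaries) needed to turn raw recordings into features and labels
for machine-learning work on surgical skill.

## Detection model

### Profiles as calibration artifacts

Indicator positions differ between console generations (and with recording
resolution), and the vendor publishes no coordinates, so geometry is never
hard-coded. A `system_profile` is a calibration artifact: for each event
channel, a region of interest (ROI), an *active* template image, an
optional *hover* template, and a match threshold. Profiles serialize as
YAML plus PNG templates (`save_profile()` / `load_profile()` round-trip).
Conventions, stated once and used everywhere: pixel coordinates are
0-based with origin top-left; an ROI `(x, y, w, h)` covers the half-open
extent `[x, x+w) × [y, y+h)`; frame ranges and label intervals are also
half-open.

Generation semantics are part of the type: an Si profile may expose only
the conjoined `CLUTCH` channel, an Xi profile only `CLUTCH_L`/`CLUTCH_R`.
`pool_clutch_counts()` maps between the conventions when comparing across
generations. Whether a camera indicator has a hover appearance is not
fixed by the model; `hover_template` is therefore optional per indicator.

### Matching

For frame $f$ and indicator $i$, the score is the normalized correlation
coefficient (Pearson correlation over all ROI pixels, color channels
pooled):

$$ r_i(f) \;=\; \frac{\operatorname{cov}(f_{\mathrm{ROI}_i},\, T_i)}
  {\sigma(f_{\mathrm{ROI}_i})\,\sigma(T_i)} \in [-1, 1], $$

with $T_i$ the active template. The frame's state is `active` when
$r_i(f) \ge \theta_i$, else `hover` when a hover template exists and
matches at the same threshold, else `inactive`. The correlation
coefficient is used (rather than squared-difference scores) because it
makes a pixel-exact self-match score exactly 1, putting thresholds on an
absolute, interpretable scale. Degenerate zero-variance inputs (flat crop
or flat template) score 1 if pixel-identical and 0 otherwise, so a blank
background can never spuriously correlate with a structured template.

Template matching only works at the calibrated resolution; against a
differently sized recording the matcher silently never fires.
`validate_templates()` therefore reports a per-indicator `OK`/`MISMATCH`
verdict against the video's geometry, and `scan_video()` refuses to run
with any mismatch — a loud error instead of a silent all-zero event log.
Recordings at other resolutions need their own profile (and in practice
low-resolution material may also need per-file threshold overrides, which
`indicator_spec(threshold = …)` supports; no low-resolution preset is
bundled).

### From states to events

An *event* is one discrete activation — a pedal press, a clutch engage —
so it is counted as a rising edge: one maximal run of `active` frames per
event, regardless of hold duration. `hover` is audit information and never
counts. `events_from_states()` optionally debounces: runs separated by
fewer than `min_gap_frames` non-active frames are merged first, then
merged runs shorter than `min_duration_frames` are dropped. The defaults
(both 1) perform no debouncing, since clean indicator renders need none;
the parameters exist for flickery real material. Raising either parameter
can only reduce the raw-run count (the suite checks this monotonicity; the
merge-then-filter order means a gap increase can, by design, rescue a
too-short run from the duration filter when both parameters are raised
together).

### Default thresholds

| Channels | Default θ |
| --- | --- |
| `COAG_L/R`, `CLUTCH*`, `CUT_L/R` | 0.95 |
| `CAMERA`, `THIRD_ARM_SWAP` | 0.90 |

0.95 and 0.90 are the operating points established for pedal/clutch and
camera/arm-swap indicators respectively. The cut pedals inherit the
coagulation value: they are indicators of the same family (same screen
furniture, different color), and cut events are rare enough in practice
that no separate operating point exists.

## Hand-path kinematics

A pluggable detector contract (`detector(frame, frame_index)` returning
`(hand, landmark, x, y, confidence)` rows) feeds per-hand tracks; CSV
streams are equivalent first-class input, so the module needs no bundled
pose model. An observation is valid when it lies in-frame and its
confidence reaches 0.5 (configurable; detectors vary and no canonical
value exists). Path length is the cumulative Euclidean distance over valid
points, in pixels only — no pixel-to-metric conversion is attempted for a
2D stream, since none is defined without depth calibration.

Tracking dropouts (hand briefly out of view) create gaps. Two policies are
reported: `bridge` (default) spans each gap with a straight segment —
matching what naive trackers and their overlays actually do, visible as
straight-line artifacts — and `split` breaks the path at gaps, the robust
alternative. By the triangle inequality `split ≤ bridge` for every track;
the suite verifies this, along with translation invariance, linear
scaling, additivity under concatenation, and agreement with a brute-force
segment-sum oracle to 1e-9. Overlay rendering draws per observation pair
(no resampling), cumulative, blue left / green right.

## Annotation handling

The TSV dialect of behavioral-observation exporters is parsed with a
required header (Time / Behavior / Status, case-insensitive, extra
columns tolerated — exporters add many), decimal-second times, and
START/STOP statuses. Pairing uses a per-behavior LIFO stack: each STOP
closes the most recent open START of its behavior, so same-behavior
nesting is permitted (the permissive choice; a `strict` flag rejects it,
since ordinary annotation files never nest a behavior inside itself).
Unbalanced files fail loudly, naming the behavior.

The bundled default schema has three categories — suturing (4
subcategories), dissection (3), other (8) — and aggregation counts paired
intervals per subcategory (one label = one START/STOP pair; counting
instances of the raw rows would double every figure). Category totals are
derived, never stored, so the invariant "category total = sum of
subcategory counts" holds by construction and is still asserted in tests.

Clip extraction maps `[start_s, stop_s)` to frames
`[round(start_s · fps), round(stop_s · fps))`. All time-to-frame rounding
in the package is *half-up* (`floor(x + 0.5)`), not banker's rounding, so
clip and segment frame counts are bit-reproducible and match hand
arithmetic (e.g. `[0.5, 1.5)` s at 15 fps is exactly 15 frames).

## Summaries

Experience follows the RAS learning-curve convention: fewer than 100 prior
procedures is *novice*. The convention leaves exactly 100 unassigned; the
package assigns 100 to *experienced* (the stated boundary is "under 100"
for novices) and documents it here. Group cells report the arithmetic mean
and the sample (n−1) standard deviation, with SD = NA for singleton cells;
durations are kept in seconds internally and rendered as `mm.ss` strings
for report parity. Whether such tables should summarize raw counts or
per-minute rates is genuinely ambiguous — session durations differ wildly —
so `build_event_table()` emits either (`per_minute = TRUE`), and both are
recommended side by side.

## The simulator: what it emulates, and what it does not

`generate_console_video()` renders a scripted `event_timeline` onto a flat
background: each active span pastes the channel's active template into its
ROI for frames `[round(start·fps), round(end·fps))`, hover spans paste the
hover template, and optional Gaussian pixel noise is added last (clamped
to [0, 1]). The paired ground-truth `event_log` is exact by construction.
Two deliberate choices:

- **Templates are crops of the renderer's own active state.** Real
  console overlays are proprietary imagery; the detection method only
  requires geometric and photometric consistency between profile and
  video, which self-rendered templates guarantee. Each (channel, state)
  pattern is a distinct Fourier mode of the ROI grid, so distinct patterns
  are near-orthogonal under correlation: active scores ~1 on itself and
  ~0 on background, hover, and other channels.
- **Timelines are frame-aligned and same-channel spans must be separated
  by at least one frame**, otherwise two scripted presses would fuse into
  one rendered run and no detector could tell them apart; the timeline
  constructor rejects such scripts instead of silently producing
  unrecoverable truth.

The bundled toy profiles (320×180 at 15 fps, one 30×20 ROI per channel)
keep the full render-and-detect loop fast: the suite runs 20 seeded random
timelines of 6 s on both generations (plus noise-robustness and
determinism checks) in well under a minute.

Noise robustness: with template pixel SD ≈ 0.2, additive Gaussian noise of
SD $\sigma$ attenuates the expected correlation to roughly
$1/\sqrt{1 + (\sigma/0.2)^2}$ — about 0.97 at $\sigma = 0.05$, still above
the 0.95 threshold. The suite pins exact count recovery at
`noise_sd = 0.05`; beyond roughly 0.08 the margin to the pedal threshold
vanishes and recovery is no longer guaranteed.

What the simulator does **not** emulate — and hence what passing tests do
not show about real recordings: compression artifacts and codec blur,
interlacing, camera-feed motion underneath the overlays,
partially-transparent overlay compositing, brightness drift, and
resolution mismatch between calibration and recording (the latter is
caught by validation rather than modeled). Real deployments must calibrate
profiles from their own reference frames; the simulator demonstrates the
machinery, not the vendor's pixels.

## Video representation and synchronization

Videos are lossless PNG frame-sequence directories (plus in-memory frame
lists behind the same `frame_video` class). Frame sequences make every
pixel-level invariant exact — stereo crop reconstruction
(`left ⊕ right = source`, checked pixel-exact), overlay untouched-pixel
identity, byte-identical deterministic renders — and are the
codec-independent interchange form; conversion to and from container
formats is a transcoding step outside the package's scope. PNG stores
8-bit samples, so arbitrary float frames survive a write/read round trip
to within 1/255 per pixel (exactly, if quantized to that grid); templates
pass through the same quantization on both the profile and the render
side, so detection is unaffected.

Two independently started streams (console feed and overhead motion
camera) are aligned by a marker event visible in both — a clap. Marker
*frames* are supplied explicitly (automatic clap detection is out of
scope); `find_offset()` turns them into a signed offset
(`offset(A,B) = −offset(B,A)`), and `apply_offset()` shifts event or label
timestamps onto the shared clock, clamping (and flagging) times that
would go negative.

## Numerical and degenerate-input choices

- NCC zero-variance guard: score 0 unless pixel-identical (then 1).
- Time→frame rounding: half-up, everywhere.
- Tracks with 0 or 1 valid point have path length 0; empty videos are
  rejected at construction; an empty keep-list for segment cutting is an
  error (refusing to emit an empty video) rather than an empty file.
- Pairing ties at identical timestamps keep file order (stable sort).
- `group_stats()` on a singleton returns SD = NA, on a constant vector 0.

## Known limitations

- No codec I/O: MP4/AVI material must be unpacked to frame sequences by an
  external transcoder before analysis.
- Frame-sequence scanning is pure R and processes roughly a few hundred
  small frames per second; full-length 1280×720 recordings are batch
  workloads.
- 3D (depth-camera) path length is out of scope; metrics are 2D pixels.
- No automatic marker detection for synchronization, and no spatial
  (bounding-box) annotation support.
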