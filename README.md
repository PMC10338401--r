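# surgevents

Turning raw recordings of a surgical-robot console into
machine-learning-ready data.

Robot-assisted surgery (RAS) skill assessment increasingly relies on
automated analysis, but the commercial da Vinci consoles expose no open
telemetry. What *is* accessible is the ocular video feed — and everything a
skills researcher needs is painted on it: screen-edge readiness lines and
bottom-panel indicators that light up on every cut or coagulation pedal
press, clutch engage, third-arm swap and camera movement. `surgevents`
provides the full desk-side pipeline around that observation, for surgical
data scientists and education researchers preparing RAS video for
machine-learning work:

- **Event detection.** Each indicator is described by a calibration
  *profile* (per-channel region of interest, template image, threshold).
  Every frame is scanned; the ROI crop is scored against the template with
  the normalized correlation coefficient
  `r = cov(crop, template) / (sd(crop) · sd(template)) ∈ [−1, 1]`,
  and the frame is *active* when `r ≥ θ` (defaults `θ = 0.95` for the
  pedal/clutch indicators, `0.90` for camera and third-arm swap). One
  **event** is a maximal run of active frames — a press is counted once,
  however long it is held. Foot-hover states (readiness lines) are recorded
  but never counted. Generation semantics are modeled: the Si console
  clutches both hands jointly (`CLUTCH`), the Xi per hand
  (`CLUTCH_L`/`CLUTCH_R`).
- **Hand kinematics.** From a landmark stream (any hand-tracking detector,
  or a CSV), per-wrist path length in pixels
  `L = Σᵢ ‖pᵢ₊₁ − pᵢ‖₂` — the classic economy-of-motion metric — under a
  `bridge` (span tracking dropouts) or `split` (break at dropouts) policy,
  plus the familiar blue-left/green-right trail overlay.
- **Annotation.** Behavioral-observation TSV labels (time / behavior /
  START-STOP) parsed, paired into intervals, extracted as clips, and
  aggregated into category count tables over a suturing / dissection /
  other schema.
- **Summaries.** Event totals and per-minute rates, grouped by procedure
  and experience (novice < 100 prior RAS cases ≤ experienced), reported as
  mean (sample SD).
- **Simulation.** A synthetic console-video generator renders scripted
  event timelines with exact frame-level ground truth, so the whole
  pipeline is testable end to end without proprietary robot imagery.

Videos are handled as lossless PNG frame-sequence directories
(`frame_000001.png`, …, `meta.yaml`); see `?frame_video`.

## Worked example

Script a 3-second timeline, render it with the bundled toy Xi profile, and
detect the events back:

```r
library(surgevents)

profile  <- toy_profile("XI")
timeline <- event_timeline(data.frame(
  channel = c("COAG_R", "COAG_R", "CLUTCH_L", "CAMERA"),
  start_s = c(0.2, 1.2, 0.5, 2.0),
  end_s   = c(0.6, 1.8, 1.0, 2.6)), fps = 15, duration_s = 3)

sim <- generate_console_video(timeline, profile)
log <- detect_events(sim$video, profile)
log
#> <event_log 'synthetic'> 45 frames @ 15 fps, 4 event(s)
#>   counts: CUT_L=0, CUT_R=0, COAG_L=0, COAG_R=2, THIRD_ARM_SWAP=0,
#>           CAMERA=1, CLUTCH_L=1, CLUTCH_R=0
```

The two scripted right-coagulation presses, one left-clutch engage and one
camera movement come back exactly. As a usage rate:

```r
per_minute(log$counts[["COAG_R"]], video_meta(sim$video)$duration_s)
#> [1] 40
```

(2 presses in 3 s is 40/min.) Hand-path metrics from a generated wrist
stream:

```r
gen   <- generate_landmark_stream(n_steps = 300, seed = 7)
track <- build_tracks(gen$landmarks, fps = 15)$left
path_length(track)
#> <path_metrics> 1131.89 px over 301 valid points (0 gap(s), bridge), 20.07 s
```

And a minimal annotation round trip:

```r
ev <- data.frame(time_s = c(10, 25), behavior = "Dissection, ordinary",
                 status = c("START", "STOP"))
category_totals(aggregate_label_counts(ev))
#> dissection      other   suturing
#>          1          0          0
```

A thin command-line front end over the same functions ships in
`inst/cli/surgevents` (`detect-events`, `simulate`, `track-hands`,
`labels-summarize`, `summarize`, `crop`, `cut`, `sync`).

## Package layout

| Area | Functions |
| --- | --- |
| Profiles | `load_profile`, `save_profile`, `validate_templates`, `toy_profile` |
| Detection | `detect_events`, `scan_video`, `match_roi`, `events_from_states`, `write_event_csv` |
| Kinematics | `track_hands`, `build_tracks`, `path_length`, `render_path_overlay` |
| Annotation | `parse_labels`, `build_intervals`, `extract_clips`, `aggregate_label_counts` |
| Summaries | `build_event_table`, `classify_experience`, `per_minute`, `group_stats` |
| Simulation | `generate_console_video`, `random_timeline`, `generate_landmark_stream`, `generate_label_file` |
| Video I/O | `read_video`, `write_video`, `crop_stereo`, `cut_segments`, `find_offset`, `apply_offset` |

The methods vignette (`vignettes/console-event-extraction.Rmd`) documents
the detection model, its parameters and the simulator's scope in detail.
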