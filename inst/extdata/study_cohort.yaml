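# Printed cohort figures of the motivating porcine study, used as inputs
# to the roll-up arithmetic (participant totals, recording totals).
participants:
  novice: 11
  experienced: 4
# Per-group recording subtotals as printed; each robot recording has one
# paired movement video, so streams_per_recording = 2.
recordings:
  novice: 74
  experienced: 20
streams_per_recording: 2
# Per-procedure recording counts (novice / experienced). Note: the novice
# column of the source table is internally inconsistent with its printed
# subtotal (the column entries sum to 65, the subtotal row prints 74); the
# subtotal rows above are what the total of 94 recordings derives from.
procedures:
  - {name: Salpingectomy, novice: 12, experienced: 2}
  - {name: Bladder puncture, novice: 16, experienced: 3}
  - {name: Lymph node dissection, novice: 20, experienced: 8}
  - {name: Partial nephrectomy, novice: 4, experienced: 2}
  - {name: Nephrectomy, novice: 2, experienced: 1}
  - {name: Ureter dissection, novice: 1, experienced: 1}
  - {name: Ureter implantation, novice: 5, experienced: 0}
  - {name: Ureter anastomosis, novice: 2, experienced: 0}
  - {name: Cystectomy, novice: 1, experienced: 0}
  - {name: Bowel puncture, novice: 2, experienced: 3}
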