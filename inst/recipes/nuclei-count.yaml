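name: nuclei-count
description: >
  Nuclear-stain fields with planted counts 25, 26, 25, 26 (mean 25.5, the
  control cell number of the measured tube region); counting must be exact
  per field.
mirrors: tracheal cell number in the measured tube region
type: nuclei_count
seed: 20170711
params:
  planted_counts: [25, 26, 25, 26]
  group_label: control
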