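# cobci on-disk formats

All interchange files are plain text (TSV + JSON). Times are seconds,
amplitudes microvolts, sample indices 1-based unless noted.

## Recording container (`write_recording`)

A directory per subject:

- `samples.tsv` — no header; one row per channel: channel label, then one
  column per sample (microvolts).
- `events.tsv` — header row; columns `onset`, `duration`, `video_id`,
  `class` (`target`/`nontarget`), `target_onset` (seconds; `NA` for
  nontarget videos). Event onsets are strictly increasing; every target
  video has exactly one `target_onset`.
- `meta.json` — `subject_id`, `fs` (Hz), `channels` (ordered montage).

## Trial-set container (`write_trial_set`)

- `trials.tsv` — no header; one row per (trial, channel): trial number,
  channel label, then one column per sample.
- `trials_meta.tsv` — header; per-trial `trial`, `label` (1 target /
  0 nontarget), `validity` (TRUE/FALSE), `trial_index` (stimulus-stream
  position shared across a synchronized group), and `offset` (0-based
  alignment offset) for aligned sets.
- `meta.json` — `subject_id`, `fs`, `channels`, `n_trials`, `n_samples`,
  `aligned` flag.

## ERP template (`write_template`)

- `template.tsv` — header; `sample` (1..100), `value` (the 1-D template).
- `filter.json` — `weights` (unit-norm 16-vector of the CSP filter),
  `eigenvalue`, `crop_start` (0-based offset of the 100-sample window in
  the 150-sample epoch).

## P3 maps (`write_p3_maps`)

Single TSV, one row per subject: `subject_id`, `peak_latency_ms`, then 16
columns named by channel with the topography at the P3 peak.

## Experiment report (`run_experiment`)

`report.tsv` — header; one row per framework: `framework`, `accuracy`,
`hit_rate`, `false_alarm_rate`, `f1`, then `net_f1_<k>` per group member
(for `sbci`, the per-subject single-mind F1 scores).
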