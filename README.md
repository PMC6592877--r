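# eegbids

Organize, read, write and validate EEG datasets in the Brain Imaging Data
Structure (BIDS).

Electroencephalography labs accumulate raw recordings in vendor formats plus
undocumented conventions for everything else — task names, reference
schemes, bad channels, electrode positions. BIDS replaces those conventions
with a fixed directory layout, a filename grammar of entity key–value pairs
(`sub-01_task-rest_eeg.vhdr`), and sidecar metadata in TSV and JSON files.
eegbids is a complete toolkit for the EEG flavour of that standard, aimed at
anyone who needs to produce, check or consume EEG-BIDS trees from R:

* **Filename grammar and indexing** — `parse_bids_path()` /
  `build_bids_path()` are exact inverses over the entity grammar
  (`sub < ses < task < acq < run`); `index_bids_dataset()` walks a tree
  deterministically, keeping unparseable files flagged for the validator.
* **The two official data formats** — `read_edf()` / `write_edf()` for the
  European Data Format (fixed-width ASCII headers, 16-bit integer records
  with per-signal affine calibration `p = p_min + (d − d_min)·(p_max −
  p_min)/(d_max − d_min)`), and `read_brainvision()` /
  `write_brainvision()` for the BrainVision Core Data Format triplet
  (INI header, INI markers, multiplexed binary payload, IEEE float32 by
  default). EDF round-trips within one quantization step per channel;
  float32 BrainVision round-trips bit-exactly at single precision.
* **Sidecars and the Inheritance Principle** — schema-checked TSV/JSON IO
  (`read_bids_tsv()`, `write_bids_json()`, ...) and
  `resolve_bids_metadata()`, which merges the applicable JSON sidecars
  root-first so deeper documents override shallower ones key by key.
* **A rule-based validator** — `validate_bids()` applies a catalog of 14
  rules (missing files, disallowed formats, header/sidecar contradictions,
  malformed events, grammar violations, ...) and returns machine-readable
  issues; `report_to_json()` serializes them.
* **A converter** — `convert_recording()` turns a recording plus study
  metadata into a validator-clean subtree (data file, channels.tsv,
  eeg.json, events.tsv, dataset scaffolding), atomically.
* **A synthetic generator** — `make_recording()`, `make_dataset()` and
  `inject_violation()` build deterministic fixtures (sinusoids + noise,
  event markers, 10–20-style electrode labels) so everything above is
  testable offline.
* **A CLI** — `exec/eegbids` with `validate`, `convert` and `fixture`
  subcommands (exit 0 = ok, 1 = validation errors, 2 = usage, 3 = I/O or
  format failure).

## Worked example

```r
library(eegbids)

rec <- make_recording(n_channels = 4, sfreq = 250, duration_s = 4, seed = 1)
rec
#> <eeg_recording> 4 channel(s) x 1000 sample(s) @ 250 Hz (4.000 s), 3 event(s)

root <- file.path(tempdir(), "study")
convert_recording(rec, entity_set(sub = "01", task = "rest"),
                  eeg_metadata(TaskName = "rest", EEGReference = "Cz",
                               PowerLineFrequency = 50),
                  root)
#> [1] "sub-01/eeg/sub-01_task-rest_eeg.vhdr"
#> [2] "sub-01/eeg/sub-01_task-rest_eeg.vmrk"
#> [3] "sub-01/eeg/sub-01_task-rest_eeg.eeg"
#> [4] "sub-01/eeg/sub-01_task-rest_channels.tsv"
#> [5] "sub-01/eeg/sub-01_task-rest_eeg.json"
#> [6] "sub-01/eeg/sub-01_task-rest_events.tsv"
#> [7] "dataset_description.json"
#> [8] "participants.tsv"

validate_bids(root)
#> BIDS validation of /tmp/.../study: OK (0 error(s), 0 warning(s))
```

The conversion wrote the BrainVision triplet plus its sidecar family: the
channels table (name/type/units/status per channel), the eeg.json metadata
(task, reference, mains frequency, and the measured sampling frequency,
channel counts and duration), and the events table (onsets in seconds from
recording start). Deleting a required file is caught immediately:

```r
inject_violation(root, "R2")
#> [1] "deleted sub-01/eeg/sub-01_task-rest_channels.tsv"
validate_bids(root)
#> BIDS validation of /tmp/.../study: FAILED (1 error(s), 0 warning(s))
#>   [error] R2 sub-01/eeg/sub-01_task-rest_eeg.vhdr: no matching channels.tsv for this EEG recording
```

The vignette (`vignettes/eeg-bids-toolkit.Rmd`) documents the model in
detail: the grammar, both codecs and their precision guarantees, the
inheritance semantics, the full rule catalog, and what the synthetic
substrate does and does not emulate.

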