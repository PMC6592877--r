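---
title: "Organizing EEG recordings as BIDS datasets with eegbids"
author: "eegbids authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organizing EEG recordings as BIDS datasets with eegbids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegbids)
```

## The problem

Raw EEG leaves the amplifier as a vendor-specific binary file plus a head
full of tacit knowledge: which task the participant performed, what the
reference electrode was, which channels went bad halfway through, where the
electrodes sat. The Brain Imaging Data Structure (BIDS) turns that tacit
knowledge into files with fixed names and formats, so that a stranger — or a
pipeline — can consume the study without emailing the experimenter. eegbids
implements the EEG flavour of that standard as a working toolkit: the
filename grammar, the two official on-disk data formats, the sidecar
metadata model with its inheritance rule, a validator, a converter, and a
synthetic-data generator that makes the whole stack testable without
downloading anything.

## The dataset model

A BIDS file name is a chain of entity key–value pairs followed by a suffix
and extension, for example `sub-01_ses-02_task-rest_eeg.vhdr`, stored under
`sub-01/ses-02/eeg/`. eegbids fixes the entity order as
`sub < ses < task < acq < run` and restricts labels to `[A-Za-z0-9]+`; names
are treated case-sensitively for portability across file systems.
`parse_bids_path()` is total: every string either yields a `bids_path`
object or a grammar error — out-of-order entities are never silently
accepted — and `build_bids_path()` is its exact inverse on valid paths.

```{r grammar}
p <- parse_bids_path("sub-01/eeg/sub-01_task-rest_channels.tsv")
p
unclass(p$entities)
```

The datatype directories are limited to `eeg` and `anat`; anything else
under a subject directory indexes as unparseable and surfaces as a validator
issue rather than an exception. The free-form `sourcedata/`, `stimuli/` and
`code/` directories are indexed by name, but their contents are deliberately
never parsed as BIDS files.

One typographic note: the naming pattern is sometimes rendered in print with
a space before the extension; the canonical serialized form used here has
none.

## The two official data formats

**European Data Format (EDF).** Fixed-width ASCII headers (256 bytes plus
256 per signal) followed by data records of 16-bit little-endian integers.
Each signal carries an affine calibration mapping the digital range
`[digital_min, digital_max]` onto a physical range
`[physical_min, physical_max]`:

$$p = p_{\min} + (d - d_{\min}) \cdot \frac{p_{\max} - p_{\min}}{d_{\max} - d_{\min}}$$

`write_edf()` chooses the physical range per channel as a symmetric
`[-m, m]` with `m = 1.01·max|x|` (1 µV for an all-zero channel), so the
calibration is never zero-width and the quantization step is `2m/65535`.
The ASCII rendering of `m` is parsed back before quantizing, so the
calibration used for the samples is exactly what the header stores, and the
write→read round-trip error is bounded by one quantization step per channel.
Records default to 1 s; for non-integral sampling frequencies the smallest
record length up to 10 s giving a whole number of samples per record is
used. A final partial record is padded with the last sample value. Only
continuous EDF is produced — no EDF+ annotation channel is written, because
in a BIDS tree events belong in `events.tsv`; an annotations signal
encountered on read is skipped with a warning.

**BrainVision Core Data Format.** A triplet: an INI-style text header
(`.vhdr`), an INI-style marker file (`.vmrk`), and a raw binary payload
(`.eeg`) in multiplexed sample order. The default binary encoding is
`IEEE_FLOAT_32` — physical values stored verbatim at single precision, which
is the format's higher-precision mode — with `INT_16` available on request
(per-channel resolution `max|x|/32767`). `SamplingInterval` is microseconds,
so `SamplingInterval × sfreq = 10⁶`. Markers are positioned in 1-based
samples while BIDS events are 0-based seconds; the fixed conversion is
`position = round(onset·sfreq) + 1`, which is an exact inverse for onsets on
the sample grid. Files are written with LF line endings in UTF-8; reads
accept CRLF and fall back to Latin-1. `VECTORIZED` and `ASCII` payloads are
rejected with a clear error rather than half-supported.

The unofficial formats (EEGLAB `.set`/`.fdt`, Biosemi `.bdf`) are recognized
by extension and pairing only; their contents are never opened.

## Sidecar metadata and the Inheritance Principle

Metadata lives next to the data in TSV tables (`channels.tsv`,
`electrodes.tsv`, `events.tsv`, `participants.tsv`) and JSON documents
(`eeg.json`, `coordsystem.json`, `dataset_description.json`). The TSV
dialect is fixed: tab-delimited, header row, `n/a` as the only
missing-value token, leading columns in a prescribed order (`onset`,
`duration` first for events; `name`, `type`, `units` for channels). Numeric
cells are written with 15 significant digits, so doubles survive a round
trip to within 1 ulp.

A JSON sidecar *applies* to a data file when its entity set is a subset of
the target's entities and its suffix matches the suffix being resolved;
applicable sidecars are merged shallowly from the dataset root downwards, so
a deeper document overrides a shallower one key by key. The merge is
deliberately shallow rather than recursive: overriding whole top-level keys
(for instance the entire `SoftwareFilters` object) keeps the semantics
predictable, whereas a recursive merge has no agreed-upon behaviour for
nested objects. Two distinct sidecars applying at the same directory level
is ambiguous and raises an error rather than picking one arbitrarily.

The resolved `eeg.json` for a recording must contain `TaskName`,
`SamplingFrequency`, `EEGReference`, `PowerLineFrequency` and
`SoftwareFilters`. The standard asks the sidecar to specify the task and
recording system exhaustively without enumerating keys; this minimal set is
what the validator enforces, and anything else (`Manufacturer`, channel
counts, duration) is carried along but optional.

## The validator

`validate_bids()` applies 14 rules and returns machine-readable issues
(code, severity, path, message). Severities mirror the standard's modal
verbs: "must" violations are errors (missing `dataset_description.json`,
missing `channels.tsv`, an unpaired `electrodes.tsv`/`coordsystem.json`,
disallowed data formats, header/sidecar contradictions, malformed events,
grammar violations, bad `status` values), "should"/"can" violations are
warnings (missing `events.tsv`, unofficial formats, channel-name mismatches,
electrodes missing for EEG channels, dangling `stim_file` references). The
issue codes are this package's own stable vocabulary — the standard names no
codes — and `report$ok` depends only on error-severity issues.

Three numerical/behavioural choices worth knowing:

* `SamplingFrequency` in the sidecar is compared to the data header with a
  relative tolerance of 10⁻⁶, since headers store it through floating point
  or as a derived quantity (microsecond sampling intervals).
* Header-level checks (channel counts, names, sampling frequency, recording
  duration) open only EDF and BrainVision files; `.set`/`.bdf` contents are
  never parsed, so those recordings get structural checks only.
* Unsorted event onsets are not flagged — the standard does not require
  ordering. Reference and ground electrodes appearing in `electrodes.tsv`
  without a corresponding channel are likewise never flagged: they are
  electrodes, not channels.

Malformed content inside the tree (truncated binaries, invalid JSON, broken
TSV) always becomes an issue on the offending path, never an exception, and
validation is read-only.

## The converter

`convert_recording()` takes an in-memory recording (or a readable `.edf` /
`.vhdr` file) plus user metadata and produces a validator-clean subtree:
the re-encoded data file, `channels.tsv` (with a `status` column initialized
to `good`), `eeg.json` (user keys plus measured `SamplingFrequency`, channel
counts, duration), `events.tsv`, a root `dataset_description.json` if
absent, and a `participants.tsv` row if the subject is new. The default
output format is BrainVision/IEEE_FLOAT_32, the higher-precision official
encoding; EDF is available on request, and `copy_through = TRUE` copies an
already-compliant source byte for byte. `trial_type` is written only when
at least one event carries a description — an all-`n/a` column says nothing.
All files are staged in a temporary directory and moved in only after every
writer has succeeded, so a failed conversion leaves no partial state;
existing targets are refused unless `overwrite = TRUE`. Acquisition
date/time is not propagated into the sidecars; the EDF start fields hold a
fixed epoch (1 January 2000) unless the caller supplies real ones, which
also keeps outputs byte-reproducible.

## The synthetic generator

`make_recording()` produces channels of summed sinusoids with
channel-specific phases plus Gaussian noise, with events placed uniformly on
the sample grid. The phase of each component is quantized to a whole number
of sample periods so that the sampled extrema reach the nominal amplitude
whenever the grid covers the sinusoid's peak — that makes amplitude
contracts exactly testable. Defaults (4 channels, 250 Hz, 4 s, 10 Hz at
50 µV plus 22 Hz at 10 µV, 5 µV noise, 3 events) are a plausible small
resting-state acquisition. `make_dataset()` converts one such recording per
subject × task and adds README, dataset description, participants table and
per-subject electrode files; `inject_violation()` applies the minimal
mutation that triggers a given validator code, which gives the validator a
soundness oracle over its whole catalog.

Electrode positions use 10–20-style labels (Fz, Cz, Pz, ...) but the
*coordinates* are a deterministic spiral on the upper unit hemisphere in
meters — synthetic stand-ins, clearly labelled as such in
`coordsystem.json`, not measured positions. All randomness flows through
one seeded generator and no output contains wall-clock time, so a fixed
seed reproduces a dataset byte for byte.

What passing tests on this substrate do **not** show: the signals have no
1/f spectrum, no artifacts, no evoked responses, and the electrode geometry
is not anatomical. The generator exercises structure — formats, names,
metadata, calibration — not biology, and conclusions from the test suite
should be read accordingly.

## Problem sizes used in the checks

The shipped tests and the acceptance script work at small scale, chosen to
exercise every code path while keeping fixtures trivial to regenerate:
recordings of 2–16 channels, 100–1000 Hz, 0.5–10 s; 50 seeded recordings
for the codec-fidelity bounds; 25 randomized conversions for the
convert-then-validate property; one single-subject dataset per validator
code for the soundness cross-product; 200 generated paths for the grammar
inverse. These sizes are the package's own choice of a convincing yet quick
demonstration; nothing in the implementation depends on them.

## Known limitations

* No segmented/epoched BrainVision files, no per-signal sampling rates in
  EDF, no EDF+ discontinuous recordings.
* HED event annotations, anatomical MRI content, and BIDS derivatives are
  out of scope; `anat/` placement is accepted but not inspected.
* The CLI (`validate` / `convert` / `fixture`, installed under
  `exec/eegbids`) treats exit codes as its only machine contract; warnings
  never affect them.
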