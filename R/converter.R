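# Raw recording -> validator-clean EEG-BIDS subtree.
#
# All destination files are staged in a temporary directory and moved into
# the dataset root only after every writer has succeeded, so a failed
# conversion leaves no partial files behind.

#' Metadata document for an EEG recording
#'
#' Convenience constructor for the user-supplied study metadata consumed by
#' [convert_recording()]. `TaskName`, `EEGReference`, `PowerLineFrequency`
#' and `SoftwareFilters` describe the experiment and acquisition chain and
#' cannot be derived from the signal; `SamplingFrequency` and the channel
#' counts are filled in from the data at conversion time.
#'
#' @param TaskName Task label (should match the `task` entity).
#' @param EEGReference Description of the reference scheme (e.g. `"Cz"`,
#'   `"average"`).
#' @param PowerLineFrequency Mains frequency in Hz (50 or 60), or `"n/a"`.
#' @param SoftwareFilters Named list of applied software filters, or `"n/a"`.
#' @param ... Further keys written verbatim into eeg.json (e.g.
#'   `Manufacturer`).
#' @return Named list suitable for the `meta` argument of
#'   [convert_recording()].
#' @export
eeg_metadata <- function(TaskName, EEGReference = "n/a",
                         PowerLineFrequency = "n/a",
                         SoftwareFilters = "n/a", ...) {
  c(list(TaskName = TaskName, EEGReference = EEGReference,
         PowerLineFrequency = PowerLineFrequency,
         SoftwareFilters = SoftwareFilters), list(...))
}

read_raw_file <- function(path) {
  ext <- tolower(paste0(".", tools::file_ext(path)))
  switch(ext,
         ".edf" = read_edf(path),
         ".vhdr" = read_brainvision(path),
         format_error(sprintf(
           "cannot read '%s': content-level parsing supports .edf and .vhdr", path)))
}

#' Convert a recording into an EEG-BIDS subtree
#'
#' Writes the data file (re-encoded into the chosen official format, or
#' byte-copied when `copy_through = TRUE` and the source file is already in
#' an allowed format), a `channels.tsv` derived from the channel
#' names/types/units, an `eeg.json` built from `meta` with
#' `SamplingFrequency`, channel counts and duration filled from the data, an
#' `events.tsv` from the recording's events, a root
#' `dataset_description.json` if absent, and a `participants.tsv` row if the
#' subject is new. The keystone contract is that `validate_bids(root)$ok` is
#' `TRUE` afterwards.
#'
#' @param source An `eeg_recording`, or a path to a readable raw file
#'   (`.edf` or `.vhdr`).
#' @param entities [entity_set()] for the output; must contain `sub` and
#'   `task`.
#' @param meta Named list of eeg.json metadata (see [eeg_metadata()]).
#' @param root Dataset root (created if needed).
#' @param format Output data format, `"brainvision"` (default; stored as
#'   IEEE_FLOAT_32) or `"edf"`.
#' @param copy_through Copy the source file verbatim instead of re-encoding
#'   (requires `source` to be a path to an allowed format).
#' @param overwrite Allow replacing existing target files; without it a
#'   collision raises an error.
#' @return Character vector of written paths relative to `root`.
#' @export
convert_recording <- function(source, entities, meta, root,
                              format = c("brainvision", "edf"),
                              copy_through = FALSE, overwrite = FALSE) {
  format <- match.arg(format)
  entities <- validate_entities(unclass(entities))
  if (!all(c("sub", "task") %in% names(entities))) {
    invariant_error("entities must contain sub and task")
  }
  source_path <- NULL
  if (is.character(source)) {
    source_path <- source
    if (!file.exists(source_path)) io_error(sprintf("no such file: %s", source_path))
    rec <- read_raw_file(source_path)
  } else {
    stopifnot(inherits(source, "eeg_recording"))
    rec <- source
  }
  if (copy_through) {
    if (is.null(source_path)) {
      invariant_error("copy_through requires a file path source")
    }
    src_ext <- tolower(paste0(".", tools::file_ext(source_path)))
    if (!src_ext %in% EEG_PRIMARY_EXTENSIONS) {
      invariant_error(sprintf("copy_through source extension '%s' is not an allowed format", src_ext))
    }
  }

  stage <- tempfile("bids_stage_")
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  datadir_rel <- dirname(build_bids_path(bids_path(entities, "eeg", ".edf")))
  dir.create(file.path(stage, datadir_rel), recursive = TRUE)

  relpaths <- character(0)
  data_relpaths <- if (copy_through) {
    ext <- tolower(paste0(".", tools::file_ext(source_path)))
    target <- build_bids_path(bids_path(entities, "eeg", ext))
    # a BrainVision source drags its siblings along, rewritten to BIDS names
    if (ext == ".vhdr") {
      copy_bv_triplet(source_path, file.path(stage, target))
      paste0(sub("\\.vhdr$", "", target), c(".vhdr", ".vmrk", ".eeg"))
    } else {
      file.copy(source_path, file.path(stage, target))
      target
    }
  } else if (format == "brainvision") {
    base_rel <- sub("\\.edf$", "",
                    build_bids_path(bids_path(entities, "eeg", ".edf")))
    paths <- write_brainvision(rec, file.path(stage, base_rel))
    paste0(base_rel, c(".vhdr", ".vmrk", ".eeg"))
  } else {
    target <- build_bids_path(bids_path(entities, "eeg", ".edf"))
    write_edf(rec, file.path(stage, target))
    target
  }
  relpaths <- c(relpaths, data_relpaths)

  # channels.tsv (status column included so curation state is explicit)
  channels <- data.frame(name = rec$channel_names, type = rec$channel_types,
                         units = rec$channel_units,
                         status = rep("good", n_channels(rec)),
                         stringsAsFactors = FALSE)
  channels_rel <- build_bids_path(bids_path(entities, "channels", ".tsv"))
  write_bids_tsv(channels, file.path(stage, channels_rel), schema = "channels")
  relpaths <- c(relpaths, channels_rel)

  # eeg.json: user metadata + quantities measured from the data
  doc <- meta
  doc$SamplingFrequency <- rec$sfreq
  doc$EEGChannelCount <- sum(rec$channel_types == "EEG")
  doc$EOGChannelCount <- sum(rec$channel_types == "EOG")
  doc$TriggerChannelCount <- sum(rec$channel_types == "TRIG")
  doc$RecordingDuration <- n_samples(rec) / rec$sfreq
  missing_req <- setdiff(REQUIRED_EEG_JSON_KEYS, names(doc))
  if (length(missing_req) > 0) {
    schema_error(sprintf("meta is missing required key(s): %s",
                         paste(missing_req, collapse = ", ")))
  }
  json_rel <- build_bids_path(bids_path(entities, "eeg", ".json"))
  write_bids_json(doc, file.path(stage, json_rel))
  relpaths <- c(relpaths, json_rel)

  # events.tsv; trial_type only when at least one event carries a description
  ev <- rec$events
  events <- data.frame(onset = ev$onset, duration = ev$duration,
                       stringsAsFactors = FALSE)
  if (nrow(ev) > 0 && any(!is.na(ev$description) & nzchar(ev$description))) {
    events$trial_type <- ifelse(nzchar(ev$description), ev$description, NA_character_)
  }
  events_rel <- build_bids_path(bids_path(entities, "events", ".tsv"))
  write_bids_tsv(events, file.path(stage, events_rel), schema = "events")
  relpaths <- c(relpaths, events_rel)

  # collision check before touching the root
  if (!dir.exists(root)) dir.create(root, recursive = TRUE)
  existing <- relpaths[file.exists(file.path(root, relpaths))]
  if (length(existing) > 0 && !overwrite) {
    collision_error(sprintf("target file(s) already exist (use overwrite = TRUE): %s",
                            paste(existing, collapse = ", ")))
  }

  for (rp in relpaths) {
    dest <- file.path(root, rp)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    file.copy(file.path(stage, rp), dest, overwrite = TRUE)
  }

  written <- relpaths
  if (!file.exists(file.path(root, "dataset_description.json"))) {
    write_bids_json(list(Name = "EEG dataset", BIDSVersion = "1.2.0"),
                    file.path(root, "dataset_description.json"))
    written <- c(written, "dataset_description.json")
  }
  if (append_participant(root, entities[["sub"]])) {
    written <- c(written, "participants.tsv")
  }
  written
}

# copy a BrainVision triplet, renaming siblings and rewriting the
# cross-references to the BIDS basename
copy_bv_triplet <- function(src_vhdr, dest_vhdr) {
  src_base <- sub("\\.vhdr$", "", src_vhdr)
  dest_base <- sub("\\.vhdr$", "", dest_vhdr)
  hdr <- read_ini_file(src_vhdr)
  df <- hdr[["Common Infos"]][["DataFile"]]
  mf <- hdr[["Common Infos"]][["MarkerFile"]]
  out <- basename(dest_base)
  rewrite <- function(path_in, path_out) {
    txt <- readLines(path_in, warn = FALSE, encoding = "UTF-8")
    txt <- sub("^DataFile=.*$", paste0("DataFile=", out, ".eeg"), txt)
    txt <- sub("^MarkerFile=.*$", paste0("MarkerFile=", out, ".vmrk"), txt)
    write_lines_lf(txt, path_out)
  }
  rewrite(src_vhdr, dest_vhdr)
  dirn <- dirname(src_vhdr)
  if (is.null(df) || !file.exists(file.path(dirn, df))) {
    format_error(sprintf("%s: referenced data file '%s' not found", src_vhdr, df))
  }
  file.copy(file.path(dirn, df), paste0(dest_base, ".eeg"))
  if (is.null(mf) || !file.exists(file.path(dirn, mf))) {
    format_error(sprintf("%s: referenced marker file '%s' not found", src_vhdr, mf))
  }
  rewrite(file.path(dirn, mf), paste0(dest_base, ".vmrk"))
  invisible(NULL)
}

#' Add a participant to participants.tsv
#'
#' Creates or updates the root `participants.tsv`. One row per subject;
#' calling again with an existing `participant_id` is a no-op. The column
#' set grows monotonically: new fields are added for everyone with `n/a`
#' backfill for earlier rows.
#'
#' @param root Dataset root.
#' @param sub_label Subject label (without the `sub-` prefix).
#' @param fields Named list of extra column values (e.g. `list(age = 23)`).
#' @return `TRUE` if the file was created or changed, `FALSE` for a no-op,
#'   invisibly.
#' @export
append_participant <- function(root, sub_label, fields = list()) {
  path <- file.path(root, "participants.tsv")
  pid <- paste0("sub-", sub_label)
  tab <- if (file.exists(path)) {
    read_bids_tsv(path, schema = "participants")
  } else {
    data.frame(participant_id = character(0), stringsAsFactors = FALSE)
  }
  if (pid %in% tab$participant_id) return(invisible(FALSE))
  row <- c(list(participant_id = pid), lapply(fields, as.character))
  for (col in setdiff(names(row), names(tab))) tab[[col]] <- rep(NA_character_, nrow(tab))
  for (col in setdiff(names(tab), names(row))) row[[col]] <- NA_character_
  tab <- rbind(tab, as.data.frame(row, stringsAsFactors = FALSE)[names(tab)])
  tab <- tab[order(tab$participant_id, method = "radix"), , drop = FALSE]
  write_bids_tsv(tab, path, schema = "participants")
  invisible(TRUE)
}
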