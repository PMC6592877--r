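# Entity filename grammar and dataset layout.
#
# A BIDS filename is a chain of entity key-value pairs followed by a suffix
# and an extension, e.g. sub-01_ses-02_task-rest_eeg.vhdr. Entities appear in
# a fixed canonical order and the directory tree mirrors the sub/ses entities.

ENTITY_KEYS <- c("sub", "ses", "task", "acq", "run")

SUFFIXES <- c("eeg", "channels", "electrodes", "coordsystem", "events",
              "participants", "dataset_description", "README")

DATATYPES <- c("eeg", "anat")

# data-carrying extensions for suffix "eeg": the two official formats
# (EDF; BrainVision triplet) plus the two tolerated unofficial ones
# (EEGLAB .set/.fdt, Biosemi .bdf)
EEG_DATA_EXTENSIONS <- c(".edf", ".vhdr", ".vmrk", ".eeg", ".set", ".fdt", ".bdf")

# extensions of the file a reader opens first ("primary" data files; .vmrk,
# .eeg and .fdt are satellites of .vhdr / .set)
EEG_PRIMARY_EXTENSIONS <- c(".edf", ".vhdr", ".set", ".bdf")

# extensions accepted per suffix (suffix "eeg" is special-cased: the parser
# accepts anything so the validator can flag disallowed formats)
SUFFIX_EXTENSIONS <- list(
  channels            = c(".tsv", ".json"),
  electrodes          = c(".tsv", ".json"),
  events              = c(".tsv", ".json"),
  coordsystem         = ".json",
  participants        = c(".tsv", ".json"),
  dataset_description = ".json",
  README              = ""
)

#' Construct an entity set
#'
#' An entity set is the parsed identity of a BIDS filename: an ordered set of
#' key-value pairs such as `sub-01`, `task-rest`. Keys are restricted to
#' `sub`, `ses`, `task`, `acq`, `run` and are stored in that canonical order
#' regardless of input order; labels must be non-empty alphanumeric strings.
#'
#' @param ... Entity labels named by key, e.g. `entity_set(sub = "01", task = "rest")`.
#' @return A named character vector of class `bids_entities` in canonical order.
#' @examples
#' entity_set(task = "rest", sub = "01")  # reordered to sub, task
#' @export
entity_set <- function(...) {
  x <- c(...)
  if (is.null(x)) x <- character(0)
  x <- as.character(stats::setNames(x, names(c(...))))
  names(x) <- names(c(...))
  validate_entities(x)
}

validate_entities <- function(x) {
  if (length(x) == 0) {
    return(structure(stats::setNames(character(0), character(0)),
                     class = "bids_entities"))
  }
  keys <- names(x)
  if (is.null(keys) || any(keys == "")) {
    grammar_error("entities must be named by key")
  }
  bad <- setdiff(keys, ENTITY_KEYS)
  if (length(bad) > 0) {
    grammar_error(sprintf("unknown entity key(s): %s", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(keys)) {
    grammar_error("duplicate entity keys")
  }
  if (any(!grepl("^[A-Za-z0-9]+$", x))) {
    grammar_error("entity labels must be non-empty alphanumeric")
  }
  x <- x[intersect(ENTITY_KEYS, keys)]
  structure(x, class = "bids_entities")
}

#' Construct a BIDS path object
#'
#' A `bids_path` carries the parsed identity of one file in a BIDS dataset:
#' its entities, datatype directory (`eeg`, `anat`, or none for root-level
#' files), suffix, and extension (with leading dot; `""` for README).
#'
#' @param entities A [entity_set()] or named character vector.
#' @param suffix One of eeg, channels, electrodes, coordsystem, events,
#'   participants, dataset_description, README.
#' @param extension Extension string including the leading dot.
#' @param datatype `"eeg"`, `"anat"`, or `NULL` for root-level files.
#' @return An object of class `bids_path`.
#' @export
bids_path <- function(entities = entity_set(), suffix, extension, datatype = NULL) {
  entities <- validate_entities(unclass(entities))
  if (!suffix %in% SUFFIXES) {
    grammar_error(sprintf("unknown suffix '%s'", suffix))
  }
  if (!is.null(datatype) && !datatype %in% DATATYPES) {
    grammar_error(sprintf("unknown datatype '%s'", datatype))
  }
  if (suffix %in% c("eeg", "channels", "events") && !"task" %in% names(entities)) {
    grammar_error(sprintf("suffix '%s' requires a task entity", suffix))
  }
  if (!is.null(datatype) && !"sub" %in% names(entities)) {
    grammar_error("subject-level files require a sub entity")
  }
  structure(list(entities = entities, datatype = datatype,
                 suffix = suffix, extension = extension),
            class = "bids_path")
}

#' @export
print.bids_path <- function(x, ...) {
  cat("<bids_path> ", build_bids_path(x, check = FALSE), "\n", sep = "")
  invisible(x)
}

#' @export
format.bids_path <- function(x, ...) build_bids_path(x, check = FALSE)

# TRUE iff suffix and extension are compatible. Suffix "eeg" accepts the
# data extensions and .json sidecars.
extension_compatible <- function(suffix, extension) {
  if (suffix == "eeg") {
    return(extension %in% c(EEG_DATA_EXTENSIONS, ".json"))
  }
  extension %in% SUFFIX_EXTENSIONS[[suffix]]
}

split_extension <- function(filename) {
  m <- regexpr("\\.[A-Za-z0-9]+$", filename)
  if (m == -1) {
    list(base = filename, extension = "")
  } else {
    list(base = substr(filename, 1, m - 1),
         extension = substr(filename, m, nchar(filename)))
  }
}

parse_entity_chain <- function(tokens, context) {
  if (length(tokens) == 0) {
    return(validate_entities(character(0)))
  }
  parts <- regmatches(tokens, regexec("^([a-z]+)-([A-Za-z0-9]+)$", tokens))
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) {
    grammar_error(sprintf("malformed entity token '%s' in %s",
                          tokens[bad][1], context))
  }
  keys <- vapply(parts, `[[`, "", 2)
  labels <- vapply(parts, `[[`, "", 3)
  unknown <- setdiff(keys, ENTITY_KEYS)
  if (length(unknown) > 0) {
    grammar_error(sprintf("unknown entity key '%s' in %s", unknown[1], context))
  }
  if (anyDuplicated(keys)) {
    grammar_error(sprintf("duplicate entity key in %s", context))
  }
  ord <- match(keys, ENTITY_KEYS)
  if (is.unsorted(ord, strictly = TRUE)) {
    grammar_error(sprintf(
      "entities out of canonical order (%s) in %s",
      paste(ENTITY_KEYS, collapse = " < "), context))
  }
  validate_entities(stats::setNames(labels, keys))
}

#' Parse a relative path under the BIDS filename grammar
#'
#' Accepts a forward-slash path relative to the dataset root, either a
#' root-level file (`dataset_description.json`, `participants.tsv`, `README`,
#' root-level sidecars such as `task-rest_events.json`) or a subject-level
#' file `sub-<label>[/ses-<label>]/<datatype>/<filename>`. Entities embedded
#' in directory names must agree with the filename entities.
#'
#' Any string either parses to a [bids_path()] or raises a grammar error;
#' out-of-order entities are never silently accepted. For suffix `eeg` the
#' extension is not restricted at parse time (the validator reports
#' disallowed data formats); all other suffixes must carry a compatible
#' extension.
#'
#' @param relative_path Path string with `/` separators, relative to the root.
#' @return A `bids_path` object.
#' @examples
#' parse_bids_path("sub-01/eeg/sub-01_task-rest_channels.tsv")
#' parse_bids_path("dataset_description.json")
#' @export
parse_bids_path <- function(relative_path) {
  if (!is.character(relative_path) || length(relative_path) != 1 || is.na(relative_path)) {
    grammar_error("relative_path must be a single string")
  }
  parts <- strsplit(relative_path, "/", fixed = TRUE)[[1]]
  if (length(parts) == 0 || any(parts == "")) {
    grammar_error(sprintf("empty path component in '%s'", relative_path))
  }
  filename <- parts[length(parts)]
  dirs <- parts[-length(parts)]

  dir_sub <- NULL
  dir_ses <- NULL
  datatype <- NULL
  if (length(dirs) > 0) {
    if (!grepl("^sub-[A-Za-z0-9]+$", dirs[1])) {
      grammar_error(sprintf("'%s': first directory must be sub-<label>", relative_path))
    }
    dir_sub <- sub("^sub-", "", dirs[1])
    rest <- dirs[-1]
    if (length(rest) > 0 && grepl("^ses-[A-Za-z0-9]+$", rest[1])) {
      dir_ses <- sub("^ses-", "", rest[1])
      rest <- rest[-1]
    }
    if (length(rest) != 1 || !rest %in% DATATYPES) {
      grammar_error(sprintf(
        "'%s': expected sub-<label>[/ses-<label>]/<datatype>/ with datatype in {%s}",
        relative_path, paste(DATATYPES, collapse = ", ")))
    }
    datatype <- rest
  }

  if (filename == "README") {
    if (length(dirs) > 0) grammar_error("README must live at the dataset root")
    return(bids_path(entity_set(), "README", ""))
  }

  se <- split_extension(filename)
  if (se$extension == "") {
    grammar_error(sprintf("'%s': missing extension", filename))
  }
  # the suffix may itself contain underscores (dataset_description), so
  # match against the known suffixes, longest first, before splitting the
  # remaining prefix into entity tokens
  suffix <- NULL
  for (sfx in SUFFIXES[order(-nchar(SUFFIXES))]) {
    if (se$base == sfx || endsWith(se$base, paste0("_", sfx))) {
      suffix <- sfx
      break
    }
  }
  if (is.null(suffix)) {
    grammar_error(sprintf("'%s': unknown or missing suffix", filename))
  }
  prefix <- substr(se$base, 1, nchar(se$base) - nchar(suffix))
  prefix <- sub("_$", "", prefix)
  tokens <- if (nzchar(prefix)) strsplit(prefix, "_", fixed = TRUE)[[1]] else character(0)
  entities <- parse_entity_chain(tokens, sprintf("'%s'", filename))

  if (suffix != "eeg" && !extension_compatible(suffix, se$extension)) {
    grammar_error(sprintf("'%s': extension '%s' not allowed for suffix '%s'",
                          filename, se$extension, suffix))
  }

  if (!is.null(dir_sub)) {
    if (!identical(unname(entities["sub"]), dir_sub) || is.na(entities["sub"])) {
      grammar_error(sprintf(
        "'%s': directory subject 'sub-%s' does not match filename entities",
        relative_path, dir_sub))
    }
    if (is.null(dir_ses) && "ses" %in% names(entities)) {
      grammar_error(sprintf("'%s': ses entity present but no ses directory", relative_path))
    }
    if (!is.null(dir_ses) &&
        (!"ses" %in% names(entities) || !identical(unname(entities["ses"]), dir_ses))) {
      grammar_error(sprintf(
        "'%s': directory session 'ses-%s' does not match filename entities",
        relative_path, dir_ses))
    }
  } else if ("sub" %in% names(entities)) {
    grammar_error(sprintf("'%s': subject file outside a sub-* directory", relative_path))
  }

  bids_path(entities, suffix, se$extension, datatype)
}

#' Serialize a BIDS path object to its canonical relative path
#'
#' Left inverse of [parse_bids_path()]: for any grammar-valid `bids_path` `p`,
#' `parse_bids_path(build_bids_path(p))` reproduces `p`.
#'
#' @param p A `bids_path`.
#' @param check Verify suffix/extension compatibility (raises an invariant
#'   error when violated). Default `TRUE`.
#' @return The relative path string, POSIX-style separators.
#' @export
build_bids_path <- function(p, check = TRUE) {
  stopifnot(inherits(p, "bids_path"))
  if (check && !extension_compatible(p$suffix, p$extension)) {
    invariant_error(sprintf("extension '%s' incompatible with suffix '%s'",
                            p$extension, p$suffix))
  }
  ent <- p$entities
  chain <- if (length(ent) > 0) {
    paste0(paste0(names(ent), "-", unname(ent)), collapse = "_")
  } else ""
  filename <- if (p$suffix == "README" && p$extension == "") {
    "README"
  } else if (chain == "") {
    paste0(p$suffix, p$extension)
  } else {
    paste0(chain, "_", p$suffix, p$extension)
  }
  if ("sub" %in% names(ent)) {
    dirs <- paste0("sub-", ent[["sub"]])
    if ("ses" %in% names(ent)) dirs <- c(dirs, paste0("ses-", ent[["ses"]]))
    dt <- if (is.null(p$datatype)) "eeg" else p$datatype
    paste(c(dirs, dt, filename), collapse = "/")
  } else {
    filename
  }
}

# ---------------------------------------------------------------------------
# Recording: in-memory continuous multichannel signal

CHANNEL_TYPES <- c("EEG", "EOG", "ECG", "EMG", "TRIG", "MISC")

#' Construct an in-memory EEG recording
#'
#' The shared container passed between codecs, the converter and the
#' synthetic generator: a channels-by-samples matrix of physical values (in
#' the units of `channel_units`, microvolts by default), one sampling
#' frequency for all channels, and a table of event markers.
#'
#' @param data Numeric matrix, channels x samples.
#' @param sfreq Sampling frequency in Hz (> 0), shared by all channels.
#' @param channel_names Unique channel names; default Ch1..ChN.
#' @param channel_types Per-channel type label (EEG, EOG, ECG, EMG, TRIG,
#'   MISC); recycled if length 1.
#' @param channel_units Per-channel physical unit; default `"µV"`.
#' @param events Data frame with columns onset (s, >= 0), duration (s, >= 0),
#'   description (character). Onsets must lie within the recorded interval.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, sfreq,
                          channel_names = NULL,
                          channel_types = "EEG",
                          channel_units = "µV",
                          events = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    invariant_error("data must be a numeric channels x samples matrix")
  }
  n_ch <- nrow(data)
  n_samp <- ncol(data)
  if (!is.numeric(sfreq) || length(sfreq) != 1 || sfreq <= 0) {
    invariant_error("sfreq must be a single positive number")
  }
  if (is.null(channel_names)) channel_names <- paste0("Ch", seq_len(n_ch))
  if (length(channel_names) != n_ch || anyDuplicated(channel_names)) {
    invariant_error("channel_names must be unique, one per row of data")
  }
  if (length(channel_types) == 1) channel_types <- rep(channel_types, n_ch)
  if (length(channel_types) != n_ch || any(!channel_types %in% CHANNEL_TYPES)) {
    invariant_error(sprintf("channel_types must be one of {%s} per channel",
                            paste(CHANNEL_TYPES, collapse = ", ")))
  }
  if (length(channel_units) == 1) channel_units <- rep(channel_units, n_ch)
  if (length(channel_units) != n_ch) {
    invariant_error("channel_units must have one entry per channel")
  }
  if (is.null(events)) {
    events <- data.frame(onset = numeric(0), duration = numeric(0),
                         description = character(0), stringsAsFactors = FALSE)
  }
  if (!is.data.frame(events) ||
      !all(c("onset", "duration", "description") %in% names(events))) {
    invariant_error("events must have columns onset, duration, description")
  }
  t_end <- n_samp / sfreq
  if (nrow(events) > 0 &&
      (any(events$onset < 0) || any(events$onset > t_end) ||
       any(events$duration < 0))) {
    invariant_error(sprintf(
      "event onsets must lie in [0, %g] s and durations be non-negative", t_end))
  }
  rownames(data) <- channel_names
  structure(list(data = data, sfreq = sfreq,
                 channel_names = as.character(channel_names),
                 channel_types = as.character(channel_types),
                 channel_units = as.character(channel_units),
                 events = events[, c("onset", "duration", "description")]),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d sample(s) @ %g Hz (%.3f s), %d event(s)\n",
              nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq,
              nrow(x$events)))
  invisible(x)
}

n_samples <- function(r) ncol(r$data)
n_channels <- function(r) nrow(r$data)

# ---------------------------------------------------------------------------
# Dataset index

# free-form containers: indexed by name, contents never parsed as BIDS files
FREEFORM_DIRS <- c("sourcedata", "stimuli", "code")

#' Index a BIDS dataset tree
#'
#' Walks the tree under `root` and classifies every file: root-level files,
#' subject-level files keyed by subject label, and files that do not parse
#' under the grammar (retained with an `unparseable` flag for the validator
#' rather than dropped). The contents of the free-form `sourcedata/`,
#' `stimuli/` and `code/` directories are never parsed. The index is
#' deterministic: entries are sorted lexicographically by relative path, so
#' indexing an unchanged tree twice yields identical results.
#'
#' @param root Dataset root directory.
#' @return An object of class `bids_index` with elements `root`, `entries`
#'   (list of `relpath` / `path` (a `bids_path` or NULL) / `unparseable` /
#'   `reason`), `root_files`, `subject_files` (entry lists keyed by subject
#'   label), and `freeform_dirs`.
#' @export
index_bids_dataset <- function(root) {
  if (!dir.exists(root)) {
    io_error(sprintf("dataset root '%s' does not exist", root))
  }
  files <- list.files(root, recursive = TRUE, all.files = FALSE, no.. = TRUE)
  files <- sort(files, method = "radix")
  top <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  freeform <- sort(intersect(top, FREEFORM_DIRS))
  keep <- !vapply(files, function(f) {
    strsplit(f, "/", fixed = TRUE)[[1]][1] %in% FREEFORM_DIRS
  }, logical(1))
  files <- files[keep]

  entries <- lapply(files, function(f) {
    p <- tryCatch(parse_bids_path(f), eegbids_grammar_error = function(e) e)
    if (inherits(p, "bids_path")) {
      list(relpath = f, path = p, unparseable = FALSE, reason = NA_character_)
    } else {
      list(relpath = f, path = NULL, unparseable = TRUE,
           reason = conditionMessage(p))
    }
  })
  names(entries) <- files

  is_root <- !grepl("/", files, fixed = TRUE)
  sub_of <- ifelse(grepl("^sub-[A-Za-z0-9]+/", files),
                   sub("^sub-([A-Za-z0-9]+)/.*$", "\\1", files), NA_character_)
  subject_files <- split(entries[!is.na(sub_of)], sub_of[!is.na(sub_of)])

  structure(list(root = root,
                 entries = entries,
                 root_files = entries[is_root],
                 subject_files = subject_files,
                 freeform_dirs = freeform),
            class = "bids_index")
}

#' @export
print.bids_index <- function(x, ...) {
  cat(sprintf("<bids_index> %s: %d file(s), %d subject(s), %d unparseable\n",
              x$root, length(x$entries), length(x$subject_files),
              sum(vapply(x$entries, `[[`, TRUE, "unparseable"))))
  invisible(x)
}

# entries (parsed only) matching a predicate on the bids_path
index_select <- function(index, pred) {
  Filter(function(e) !e$unparseable && isTRUE(pred(e$path)), index$entries)
}

# primary EEG data files (the file a reader opens first)
index_data_files <- function(index) {
  index_select(index, function(p) {
    p$suffix == "eeg" && p$extension %in% EEG_PRIMARY_EXTENSIONS
  })
}
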