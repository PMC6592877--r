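# Deterministic synthetic fixtures: recordings, whole valid datasets, and
# seeded violation mutants. This is the test substrate for the entire stack;
# it emulates the *structure* of multichannel EEG (sinusoids + Gaussian
# noise, event markers, 10-20-style electrode labels), not its physiology.

TEN_TWENTY <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz",
                "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2")

# evaluate expr under a fixed RNG state without disturbing the caller's
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a deterministic synthetic recording
#'
#' Each channel is a sum of sinusoids with channel-specific phases plus
#' Gaussian noise; events are placed uniformly at random on the sample grid
#' (so their onsets are exact multiples of `1/sfreq`). The same seed always
#' yields the same samples and events.
#'
#' @param n_channels Number of channels (>= 1); named after the 10-20 system
#'   while labels last, `ChN` beyond.
#' @param sfreq Sampling frequency in Hz.
#' @param duration_s Recording length in seconds.
#' @param components List of `c(freq_hz, amplitude_uv)` sinusoid components.
#' @param noise_sd_uv Standard deviation of the additive Gaussian noise, µV.
#' @param n_events Number of event markers.
#' @param seed RNG seed.
#' @return An `eeg_recording` with all channels typed `EEG` in µV.
#' @export
make_recording <- function(n_channels = 4, sfreq = 250, duration_s = 4,
                           components = list(c(10, 50), c(22, 10)),
                           noise_sd_uv = 5, n_events = 3, seed = 1) {
  stopifnot(n_channels >= 1, sfreq > 0, duration_s > 0)
  with_seed(seed, {
    nsamp <- as.integer(round(duration_s * sfreq))
    t <- (seq_len(nsamp) - 1) / sfreq
    data <- matrix(0, n_channels, nsamp)
    for (i in seq_len(n_channels)) {
      x <- numeric(nsamp)
      for (comp in components) {
        # channel-specific phase, quantized to a whole number of sample
        # periods so that sampled extrema reach the nominal amplitude
        # whenever the sampling grid covers the sinusoid's peak
        shift <- (sample.int(nsamp, 1) - 1) / sfreq
        x <- x + comp[2] * sin(2 * pi * comp[1] * (t + shift))
      }
      if (noise_sd_uv > 0) x <- x + stats::rnorm(nsamp, sd = noise_sd_uv)
      data[i, ] <- x
    }
    names <- if (n_channels <= length(TEN_TWENTY)) {
      TEN_TWENTY[seq_len(n_channels)]
    } else {
      c(TEN_TWENTY, paste0("Ch", seq(length(TEN_TWENTY) + 1, n_channels)))
    }
    events <- if (n_events > 0) {
      idx <- sort(sample.int(nsamp, n_events)) - 1L
      data.frame(onset = idx / sfreq,
                 duration = rep(0, n_events),
                 description = sample(c("target", "standard"), n_events,
                                      replace = TRUE),
                 stringsAsFactors = FALSE)
    } else NULL
    new_recording(data, sfreq = sfreq, channel_names = names,
                  channel_types = "EEG", channel_units = "µV",
                  events = events)
  })
}

# deterministic electrode positions: upper-hemisphere spiral on a unit
# sphere (meters); purely synthetic stand-ins for measured 10-20 positions
synthetic_electrode_positions <- function(names) {
  n <- length(names)
  i <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  z <- 0.15 + 0.85 * (i - 0.5) / n       # upper hemisphere
  rad <- sqrt(pmax(0, 1 - z^2))
  data.frame(name = names,
             x = round(rad * cos(golden * i), 6),
             y = round(rad * sin(golden * i), 6),
             z = round(z, 6),
             stringsAsFactors = FALSE)
}

#' Generate a complete valid synthetic dataset
#'
#' Builds one converted recording per subject x task via
#' [convert_recording()], plus `dataset_description.json`,
#' `participants.tsv`, `README`, and per-subject `electrodes.tsv` +
#' `coordsystem.json` with synthetic 10-20-style coordinates. The output
#' tree validates clean ([validate_bids()] reports zero issues) and is
#' byte-reproducible for a fixed seed (no wall-clock anywhere).
#'
#' @param root Destination root (must be empty or absent).
#' @param n_subjects Number of subjects (`sub-01`, `sub-02`, ...).
#' @param tasks Character vector of task labels.
#' @param format `"brainvision"` (default) or `"edf"`.
#' @param seed Base RNG seed; per-recording seeds are derived from it.
#' @param ... Passed to [make_recording()] (channel count, sfreq, ...).
#' @return The [index_bids_dataset()] of the finished tree.
#' @export
make_dataset <- function(root, n_subjects = 2, tasks = "rest",
                         format = "brainvision", seed = 1, ...) {
  if (dir.exists(root) && length(list.files(root, all.files = TRUE, no.. = TRUE)) > 0) {
    collision_error(sprintf("root '%s' is not empty", root))
  }
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("Synthetic EEG-BIDS dataset",
               "Generated for testing; signals are sinusoids plus noise."),
             file.path(root, "README"))
  write_bids_json(list(Name = "Synthetic EEG dataset",
                       BIDSVersion = "1.2.0",
                       Authors = list("eegbids synthetic generator"),
                       License = "CC0"),
                  file.path(root, "dataset_description.json"))
  subs <- sprintf("%02d", seq_len(n_subjects))
  for (si in seq_along(subs)) {
    first_rec <- NULL
    for (ti in seq_along(tasks)) {
      subseed <- (as.numeric(seed) * 1000 + si * 10 + ti) %% 2147483647
      rec <- make_recording(seed = subseed, ...)
      if (is.null(first_rec)) first_rec <- rec
      convert_recording(rec, entity_set(sub = subs[si], task = tasks[ti]),
                        eeg_metadata(TaskName = tasks[ti],
                                     EEGReference = "Cz",
                                     PowerLineFrequency = 50,
                                     SoftwareFilters = "n/a",
                                     Manufacturer = "synthetic"),
                        root, format = format)
    }
    # electrodes for the subject's EEG channels plus reference and ground
    eeg_names <- first_rec$channel_names[first_rec$channel_types == "EEG"]
    electrodes <- synthetic_electrode_positions(c(eeg_names, "REF", "GND"))
    el_rel <- build_bids_path(bids_path(entity_set(sub = subs[si]),
                                        "electrodes", ".tsv"))
    write_bids_tsv(electrodes, file.path(root, el_rel), schema = "electrodes")
    cs_rel <- build_bids_path(bids_path(entity_set(sub = subs[si]),
                                        "coordsystem", ".json"))
    write_bids_json(list(
      EEGCoordinateSystem = "Other",
      EEGCoordinateUnits = "m",
      EEGCoordinateSystemDescription = paste(
        "Synthetic CapTrak-like frame: electrodes on the upper unit",
        "hemisphere, origin at the head center; generated positions,",
        "not measurements."),
      FiducialsDescription = "No physical fiducials; positions are synthetic."),
      file.path(root, cs_rel))
  }
  index_bids_dataset(root)
}

#' Inject a single validator violation into a pristine dataset
#'
#' Applies the minimal mutation that makes [validate_bids()] report the
#' given catalog code (see [validator_codes()]): deleting a file for
#' R1/R2/R3/R4, renaming or planting a file for R5/R6/R12, editing one cell
#' or row for the tabular and metadata rules.
#'
#' @param root A pristine [make_dataset()] output tree.
#' @param code Validator issue code, `"R1"` ... `"R14"`.
#' @return A one-line description of the mutation performed.
#' @export
inject_violation <- function(root, code) {
  index <- index_bids_dataset(root)
  first_rel <- function(pred) {
    hits <- index_select(index, pred)
    if (length(hits) == 0) {
      io_error(sprintf("no target file in '%s' for code %s", root, code))
    }
    hits[[1]]$relpath
  }
  data_entry <- function() {
    hits <- index_data_files(index)
    if (length(hits) == 0) io_error("no data file in the tree")
    hits[[1]]$path
  }
  rel_of <- function(suffix, ext) first_rel(function(p) {
    p$suffix == suffix && p$extension == ext
  })

  switch(code,
    R1 = {
      file.remove(file.path(root, "dataset_description.json"))
      "deleted dataset_description.json"
    },
    R2 = {
      rel <- rel_of("channels", ".tsv")
      file.remove(file.path(root, rel))
      paste("deleted", rel)
    },
    R3 = {
      rel <- rel_of("coordsystem", ".json")
      file.remove(file.path(root, rel))
      paste("deleted", rel)
    },
    R4 = {
      rel <- rel_of("events", ".tsv")
      file.remove(file.path(root, rel))
      paste("deleted", rel)
    },
    R5 = {
      p <- data_entry()
      ents <- c(unclass(p$entities), acq = "zz")
      rel <- build_bids_path(bids_path(validate_entities(ents), "eeg", ".dat"),
                             check = FALSE)
      writeLines("not an allowed EEG data format", file.path(root, rel))
      paste("planted", rel)
    },
    R6 = {
      p <- data_entry()
      ents <- c(unclass(p$entities), acq = "zz")
      rel <- build_bids_path(bids_path(validate_entities(ents), "eeg", ".bdf"))
      writeLines("placeholder Biosemi payload (recognition only)", file.path(root, rel))
      paste("planted", rel)
    },
    R7 = {
      rel <- rel_of("channels", ".tsv")
      tab <- read_bids_tsv(file.path(root, rel))
      write_bids_tsv(tab[-nrow(tab), , drop = FALSE], file.path(root, rel))
      paste("dropped the last row of", rel)
    },
    R8 = {
      rel <- rel_of("channels", ".tsv")
      tab <- read_bids_tsv(file.path(root, rel))
      tab$name[1:2] <- tab$name[2:1]
      write_bids_tsv(tab, file.path(root, rel))
      paste("swapped the first two channel names in", rel)
    },
    R9 = {
      rel <- rel_of("electrodes", ".tsv")
      ch_rel <- rel_of("channels", ".tsv")
      ch <- read_bids_tsv(file.path(root, ch_rel))
      el <- read_bids_tsv(file.path(root, rel))
      victim <- intersect(el$name, ch$name[ch$type == "EEG"])[1]
      write_bids_tsv(el[el$name != victim, , drop = FALSE], file.path(root, rel))
      sprintf("removed electrode '%s' from %s", victim, rel)
    },
    R10 = {
      rel <- rel_of("eeg", ".json")
      doc <- read_bids_json(file.path(root, rel))
      doc$EEGReference <- NULL
      write_bids_json(doc, file.path(root, rel))
      paste("removed EEGReference from", rel)
    },
    R11 = {
      rel <- rel_of("events", ".tsv")
      tab <- read_bids_tsv(file.path(root, rel))
      if (nrow(tab) > 0) {
        tab$onset[1] <- "-1.0"
        write_bids_tsv(tab, file.path(root, rel))
        paste("negated the first event onset in", rel)
      } else {
        tab <- tab[, c(2, 1, seq_len(ncol(tab))[-(1:2)]), drop = FALSE]
        write_bids_tsv(tab, file.path(root, rel))
        paste("swapped the onset/duration columns of", rel)
      }
    },
    R12 = {
      p <- data_entry()
      rel <- file.path(paste0("sub-", p$entities[["sub"]]), "eeg", "notbids.txt")
      writeLines("stray file", file.path(root, rel))
      paste("planted", rel)
    },
    R13 = {
      rel <- rel_of("channels", ".tsv")
      tab <- read_bids_tsv(file.path(root, rel))
      tab$status[1] <- "meh"
      write_bids_tsv(tab, file.path(root, rel))
      paste("set a status cell to 'meh' in", rel)
    },
    R14 = {
      rel <- rel_of("events", ".tsv")
      tab <- read_bids_tsv(file.path(root, rel))
      if (nrow(tab) == 0) {
        tab <- data.frame(onset = "0.5", duration = "0.0", stringsAsFactors = FALSE)
      }
      tab$stim_file <- c("ghost.png", rep(NA_character_, nrow(tab) - 1))
      write_bids_tsv(tab, file.path(root, rel))
      paste("pointed stim_file at a missing stimulus in", rel)
    },
    unknown_code_error(sprintf("unknown validator code '%s'", code))
  )
}
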