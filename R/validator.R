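# Rule-based dataset validator: checks an EEG-BIDS tree for missing data and
# underspecified metadata, emitting machine-readable issues. Malformed
# content inside the tree yields issues, never exceptions; validation is
# read-only and deterministic (issues ordered by path, then code).

#' Validator rule catalog
#'
#' A data frame of the stable issue codes, one row per rule, with the fixed
#' severity of each. Severities follow the standard's modal verbs: "must"
#' violations are errors, "should"/"can" violations are warnings.
#'
#' @return Data frame with columns `code`, `severity`, `description`.
#' @export
validator_codes <- function() {
  data.frame(
    code = c("R1", "R2", "R3", "R4", "R5", "R6", "R7", "R8", "R9", "R10",
             "R11", "R12", "R13", "R14"),
    severity = c("error", "error", "error", "warning", "error", "warning",
                 "error", "warning", "warning", "error", "error", "error",
                 "error", "warning"),
    name = c("DATASET_DESCRIPTION_MISSING", "CHANNELS_TSV_MISSING",
             "ELECTRODES_COORDSYSTEM_UNPAIRED", "EVENTS_TSV_ABSENT",
             "UNALLOWED_DATA_FORMAT", "UNOFFICIAL_FORMAT",
             "CHANNEL_COUNT_MISMATCH", "CHANNEL_NAME_MISMATCH",
             "ELECTRODE_NOT_FOUND", "EEG_JSON_UNDERSPECIFIED",
             "EVENTS_MALFORMED", "FILENAME_GRAMMAR", "BAD_STATUS_VALUE",
             "STIM_FILE_MISSING"),
    description = c(
      "no dataset_description.json at the dataset root",
      "an EEG data file has no matching channels.tsv",
      "electrodes.tsv without coordsystem.json or vice versa",
      "task recording with no events.tsv",
      "eeg suffix with an extension outside the allowed data formats",
      "unofficial data format (.set/.fdt or .bdf)",
      "channels.tsv row count differs from the data header channel count",
      "channel names or order differ between channels.tsv and the data header",
      "an EEG-type channel has no row in electrodes.tsv",
      "resolved eeg.json metadata misses a required key or contradicts the data header",
      "malformed events.tsv (column order, negative onset, onset past the end)",
      "unparseable filename inside a subject directory",
      "channels.tsv status outside {good, bad}",
      "events stim_file not found under stimuli/"),
    stringsAsFactors = FALSE)
}

issue <- function(code, path, message) {
  cat_ <- validator_codes()
  data.frame(code = code,
             severity = cat_$severity[match(code, cat_$code)],
             path = path, message = message, stringsAsFactors = FALSE)
}

no_issues <- function() issue(character(0), character(0), character(0))

# read the channel names / count / sampling frequency from a data file
# header; EDF and BrainVision only, NULL when unreadable or unsupported
read_data_header <- function(abspath, extension) {
  tryCatch({
    if (extension == ".edf") {
      h <- read_edf_header(abspath)
      keep <- h$label != "EDF Annotations"
      list(n_channels = sum(keep), channel_names = h$label[keep],
           sfreq = h$sfreq,
           duration_s = h$n_samples / h$sfreq)
    } else if (extension == ".vhdr") {
      hdr <- read_ini_file(abspath)
      ns <- suppressWarnings(as.integer(hdr[["Common Infos"]][["NumberOfChannels"]]))
      si <- suppressWarnings(as.numeric(hdr[["Common Infos"]][["SamplingInterval"]]))
      ch <- hdr[["Channel Infos"]]
      ch <- ch[grepl("^Ch[0-9]+$", names(ch))]
      ch <- ch[order(as.integer(sub("^Ch", "", names(ch))))]
      nm <- bv_unescape(vapply(strsplit(unname(ch), ",", fixed = TRUE),
                               function(p) p[1], ""))
      sfreq <- if (!is.na(si) && si > 0) 1e6 / si else NA_real_
      dur <- NA_real_
      df <- hdr[["Common Infos"]][["DataFile"]]
      bf <- hdr[["Binary Infos"]][["BinaryFormat"]]
      if (!is.null(df) && !is.null(bf) && !is.na(ns) && ns > 0) {
        dpath <- file.path(dirname(abspath), df)
        if (file.exists(dpath)) {
          bytes <- if (bf == "IEEE_FLOAT_32") 4 else if (bf == "INT_16") 2 else NA
          if (!is.na(bytes) && !is.na(sfreq)) {
            dur <- file.size(dpath) / (bytes * ns) / sfreq
          }
        }
      }
      list(n_channels = ns, channel_names = nm, sfreq = sfreq, duration_s = dur)
    } else NULL
  }, error = function(e) NULL, warning = function(w) NULL)
}

# applicable .tsv companion of a data file (channels/events/electrodes):
# same subset-of-entities rule as JSON sidecars, deepest match wins
find_companion_tsv <- function(index, target, suffix) {
  cands <- index_select(index, function(p) {
    p$suffix == suffix && p$extension == ".tsv" &&
      entities_subset(p$entities, target$entities)
  })
  if (length(cands) == 0) return(NULL)
  depth <- vapply(cands, function(e) path_depth(e$relpath), 0L)
  cands[[which.max(depth)]]
}

#' Validate an EEG-BIDS dataset tree
#'
#' Applies the full rule catalog (see [validator_codes()]) to the tree under
#' `root` and returns a machine-readable report. The dataset is never
#' modified; issues are ordered by path, then code, so repeated validation
#' of an unchanged tree is reproducible.
#'
#' @param root Dataset root directory.
#' @param ignore_warnings Drop warning-severity issues from the report.
#' @return An object of class `bids_report`: list with `issues` (data frame
#'   code/severity/path/message), `counts` (issues by severity), and `ok`
#'   (`TRUE` iff there are zero error-severity issues).
#' @export
validate_bids <- function(root, ignore_warnings = FALSE) {
  if (!dir.exists(root)) io_error(sprintf("dataset root '%s' does not exist", root))
  index <- index_bids_dataset(root)
  iss <- list()
  add <- function(x) iss[[length(iss) + 1]] <<- x

  rel_exists <- function(rel) !is.null(index$entries[[rel]])

  # R1: dataset_description.json at root
  if (!rel_exists("dataset_description.json")) {
    add(issue("R1", "<root>", "dataset_description.json is missing at the dataset root"))
  }

  # R12: unparseable filenames inside sub-*/
  for (e in index$entries) {
    if (e$unparseable && grepl("^sub-", e$relpath)) {
      add(issue("R12", e$relpath, paste0("filename does not follow the grammar: ", e$reason)))
    }
  }

  # per data-file rules; "data file" = eeg suffix with a primary extension
  data_files <- index_data_files(index)
  for (e in data_files) {
    p <- e$path
    abspath <- file.path(root, e$relpath)

    # R6: tolerated unofficial formats
    if (p$extension %in% c(".set", ".bdf")) {
      add(issue("R6", e$relpath, sprintf(
        "data format '%s' is unofficial (tolerated but not encouraged); prefer EDF or BrainVision",
        p$extension)))
    }

    hdr <- read_data_header(abspath, p$extension)

    # R2: matching channels.tsv
    channels_entry <- find_companion_tsv(index, p, "channels")
    if (is.null(channels_entry)) {
      add(issue("R2", e$relpath, "no matching channels.tsv for this EEG recording"))
    } else {
      ch_tab <- tryCatch(read_bids_tsv(file.path(root, channels_entry$relpath),
                                       schema = NULL),
                         error = function(err) NULL)
      if (!is.null(ch_tab)) {
        # R13: status vocabulary
        if ("status" %in% names(ch_tab)) {
          bad <- !is.na(ch_tab$status) & !ch_tab$status %in% c("good", "bad")
          if (any(bad)) {
            add(issue("R13", channels_entry$relpath, sprintf(
              "status value '%s' outside {good, bad}", ch_tab$status[bad][1])))
          }
        }
        if (!is.null(hdr) && !is.na(hdr$n_channels)) {
          # R7: row count vs header channel count
          if (nrow(ch_tab) != hdr$n_channels) {
            add(issue("R7", channels_entry$relpath, sprintf(
              "channels.tsv lists %d channel(s) but the data header has %d",
              nrow(ch_tab), hdr$n_channels)))
          } else if ("name" %in% names(ch_tab) &&
                     !identical(ch_tab$name, hdr$channel_names)) {
            # R8: names/order
            add(issue("R8", channels_entry$relpath,
                      "channel names or order differ between channels.tsv and the data header"))
          }
        }
        # R9: every EEG-type channel has an electrode row (extra electrodes
        # such as reference/ground are fine and never flagged)
        electrodes_entry <- find_companion_tsv(index, p, "electrodes")
        if (!is.null(electrodes_entry) &&
            all(c("name", "type") %in% names(ch_tab))) {
          el_tab <- tryCatch(read_bids_tsv(file.path(root, electrodes_entry$relpath),
                                           schema = NULL),
                             error = function(err) NULL)
          if (!is.null(el_tab) && "name" %in% names(el_tab)) {
            eeg_ch <- ch_tab$name[!is.na(ch_tab$type) & ch_tab$type == "EEG"]
            missing_el <- setdiff(eeg_ch, el_tab$name)
            for (nm in missing_el) {
              add(issue("R9", electrodes_entry$relpath, sprintf(
                "EEG channel '%s' has no row in electrodes.tsv", nm)))
            }
          }
        }
      }
    }

    # R4 / R11 / R14: events
    events_entry <- find_companion_tsv(index, p, "events")
    if (is.null(events_entry)) {
      add(issue("R4", e$relpath, "no events.tsv for this task recording"))
    } else {
      ev_path <- file.path(root, events_entry$relpath)
      ev_raw <- tryCatch(read_bids_tsv(ev_path, schema = NULL),
                         error = function(err) NULL)
      if (is.null(ev_raw)) {
        add(issue("R11", events_entry$relpath, "events.tsv could not be parsed"))
      } else if (length(names(ev_raw)) < 2 ||
                 !identical(names(ev_raw)[1:2], c("onset", "duration"))) {
        add(issue("R11", events_entry$relpath, sprintf(
          "first columns must be (onset, duration), found (%s)",
          paste(utils::head(names(ev_raw), 2), collapse = ", "))))
      } else {
        onset <- suppressWarnings(as.numeric(ev_raw$onset))
        if (any(!is.na(onset) & onset < 0)) {
          add(issue("R11", events_entry$relpath, "negative event onset"))
        } else if (!is.null(hdr) && !is.na(hdr$duration_s) &&
                   any(!is.na(onset) & onset > hdr$duration_s + 1e-9)) {
          add(issue("R11", events_entry$relpath, sprintf(
            "event onset beyond the recording end (%.3f s)", hdr$duration_s)))
        }
        # R14: stim_file must exist under stimuli/
        if ("stim_file" %in% names(ev_raw)) {
          sf <- ev_raw$stim_file[!is.na(ev_raw$stim_file)]
          for (f in unique(sf)) {
            if (!file.exists(file.path(root, "stimuli", f))) {
              add(issue("R14", events_entry$relpath, sprintf(
                "stim_file '%s' not found under stimuli/", f)))
            }
          }
        }
      }
    }

    # R10: resolved eeg.json metadata
    meta <- tryCatch(resolve_bids_metadata(index, p, suffix = "eeg"),
                     error = function(err) NULL)
    if (is.null(meta)) {
      add(issue("R10", e$relpath, "eeg.json sidecar chain could not be resolved"))
    } else {
      missing_keys <- setdiff(REQUIRED_EEG_JSON_KEYS, names(meta))
      if (length(missing_keys) > 0) {
        add(issue("R10", e$relpath, sprintf(
          "resolved eeg.json metadata misses required key(s): %s",
          paste(missing_keys, collapse = ", "))))
      } else if (!is.null(hdr) && !is.na(hdr$sfreq)) {
        sf_meta <- suppressWarnings(as.numeric(meta$SamplingFrequency))
        if (!is.na(sf_meta) &&
            abs(sf_meta - hdr$sfreq) > 1e-6 * max(abs(hdr$sfreq), 1)) {
          add(issue("R10", e$relpath, sprintf(
            "eeg.json SamplingFrequency %g disagrees with the data header (%g Hz)",
            sf_meta, hdr$sfreq)))
        }
      }
    }
  }

  # R5: eeg suffix with a disallowed extension (.json sidecars are fine)
  for (e in index_select(index, function(p) {
    p$suffix == "eeg" && !p$extension %in% c(EEG_DATA_EXTENSIONS, ".json")
  })) {
    add(issue("R5", e$relpath, sprintf(
      "extension '%s' is not an allowed EEG data format (%s)",
      e$path$extension, paste(EEG_DATA_EXTENSIONS, collapse = ", "))))
  }

  # R3: electrodes.tsv <-> coordsystem.json pairing (by entity set)
  electrodes <- index_select(index, function(p) {
    p$suffix == "electrodes" && p$extension == ".tsv"
  })
  coordsys <- index_select(index, function(p) p$suffix == "coordsystem")
  ent_key <- function(e) paste(names(e$path$entities), unclass(e$path$entities),
                               sep = "-", collapse = "_")
  el_keys <- vapply(electrodes, ent_key, "")
  cs_keys <- vapply(coordsys, ent_key, "")
  for (i in seq_along(electrodes)) {
    if (!el_keys[i] %in% cs_keys) {
      add(issue("R3", electrodes[[i]]$relpath,
                "electrodes.tsv without an accompanying coordsystem.json"))
    }
  }
  for (i in seq_along(coordsys)) {
    if (!cs_keys[i] %in% el_keys) {
      add(issue("R3", coordsys[[i]]$relpath,
                "coordsystem.json without an accompanying electrodes.tsv"))
    }
  }

  issues <- if (length(iss) == 0) no_issues() else do.call(rbind, iss)
  if (ignore_warnings) issues <- issues[issues$severity != "warning", , drop = FALSE]
  issues <- issues[order(issues$path, issues$code, method = "radix"), , drop = FALSE]
  rownames(issues) <- NULL
  structure(list(
    issues = issues,
    counts = c(error = sum(issues$severity == "error"),
               warning = sum(issues$severity == "warning")),
    ok = !any(issues$severity == "error"),
    root = root), class = "bids_report")
}

#' @export
print.bids_report <- function(x, ...) {
  cat(sprintf("BIDS validation of %s: %s (%d error(s), %d warning(s))\n",
              x$root, if (x$ok) "OK" else "FAILED",
              x$counts[["error"]], x$counts[["warning"]]))
  if (nrow(x$issues) > 0) {
    apply(x$issues, 1, function(r) {
      cat(sprintf("  [%s] %s %s: %s\n", r[["severity"]], r[["code"]],
                  r[["path"]], r[["message"]]))
    })
  }
  invisible(x)
}

#' Serialize a validation report as JSON
#'
#' @param report A `bids_report` from [validate_bids()].
#' @return A JSON string (issue list plus summary counts and the ok flag).
#' @export
report_to_json <- function(report) {
  stopifnot(inherits(report, "bids_report"))
  jsonlite::toJSON(list(ok = report$ok,
                        counts = as.list(report$counts),
                        issues = report$issues),
                   auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
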