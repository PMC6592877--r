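# Sidecar metadata: TSV tables, JSON documents, and the Inheritance
# Principle (JSON sidecars at higher directory levels apply to lower levels
# unless a deeper file overrides their keys, key by key).

# required keys of the resolved eeg.json metadata; what validator rule
# EEG_JSON_UNDERSPECIFIED enforces
REQUIRED_EEG_JSON_KEYS <- c("TaskName", "SamplingFrequency", "EEGReference",
                            "PowerLineFrequency", "SoftwareFilters")

NA_TOKEN <- "n/a"

# Column schemas. `order`: leading columns that must appear first and in this
# order; `numeric`: columns converted to numeric on read; `unique`: column
# whose values must be unique; `allowed`: restricted vocabularies (NA always
# permitted, it means "missing").
TABLE_SCHEMAS <- list(
  channels = list(
    order = c("name", "type", "units"),
    unique = "name",
    numeric = character(0),
    allowed = list(status = c("good", "bad"))
  ),
  electrodes = list(
    order = c("name", "x", "y", "z"),
    unique = "name",
    numeric = c("x", "y", "z"),
    allowed = list()
  ),
  events = list(
    order = c("onset", "duration"),
    unique = NULL,
    numeric = c("onset", "duration", "response_time"),
    allowed = list()
  ),
  participants = list(
    order = "participant_id",
    unique = "participant_id",
    numeric = character(0),
    allowed = list()
  )
)

#' Read a BIDS tab-separated table
#'
#' Reads a UTF-8, tab-delimited file with a header row. The token `n/a`
#' denotes a missing value and is mapped to `NA`; when a schema is given,
#' leading-column order, uniqueness and restricted vocabularies are checked
#' and numeric columns are converted.
#'
#' @param path File to read.
#' @param schema One of `"channels"`, `"electrodes"`, `"events"`,
#'   `"participants"`, a schema list of the same shape, or `NULL` for no
#'   checking (all columns kept as character).
#' @return A data frame; `attr(, "schema")` records the schema used.
#' @seealso [write_bids_tsv()] for the inverse; the pair round-trips cell
#'   values and column order, numeric cells to within 1 ulp.
#' @export
read_bids_tsv <- function(path, schema = NULL) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          check.names = FALSE, quote = "", na.strings = NULL,
                          fileEncoding = "UTF-8")
  df[] <- lapply(df, function(col) ifelse(col == NA_TOKEN, NA_character_, col))
  check_bids_table(df, schema, context = path)
}

# schema checks + numeric conversion, shared by reader and writer
check_bids_table <- function(df, schema = NULL, context = "table") {
  sch <- if (is.character(schema)) TABLE_SCHEMAS[[schema]] else schema
  if (is.character(schema) && is.null(sch)) {
    schema_error(sprintf("unknown table schema '%s'", schema))
  }
  if (!is.null(sch)) {
    lead <- sch$order
    if (length(names(df)) < length(lead) ||
        !identical(names(df)[seq_along(lead)], lead)) {
      schema_error(sprintf(
        "%s: leading columns must be (%s), found (%s)",
        context, paste(lead, collapse = ", "),
        paste(utils::head(names(df), length(lead)), collapse = ", ")))
    }
    for (col in intersect(sch$numeric, names(df))) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- !is.na(df[[col]]) & is.na(v)
      if (any(bad)) {
        schema_error(sprintf("%s: column '%s' has non-numeric value '%s'",
                             context, col, df[[col]][bad][1]))
      }
      df[[col]] <- v
    }
    if (!is.null(sch$unique) && sch$unique %in% names(df)) {
      if (anyDuplicated(df[[sch$unique]][!is.na(df[[sch$unique]])])) {
        schema_error(sprintf("%s: duplicate values in column '%s'",
                             context, sch$unique))
      }
    }
    for (col in names(sch$allowed)) {
      if (col %in% names(df)) {
        v <- df[[col]]
        bad <- !is.na(v) & !v %in% sch$allowed[[col]]
        if (any(bad)) {
          schema_error(sprintf(
            "%s: column '%s' value '%s' outside {%s}",
            context, col, v[bad][1], paste(sch$allowed[[col]], collapse = ", ")))
        }
      }
    }
  }
  attr(df, "schema") <- schema
  df
}

# format one column for TSV output; numerics keep full double precision and
# always carry a decimal point so they read back as numbers
fmt_tsv_column <- function(col) {
  if (is.numeric(col)) {
    out <- vapply(col, function(x) {
      if (is.na(x)) return(NA_character_)
      s <- sprintf("%.15g", x)
      if (!grepl("[.eE]", s)) s <- paste0(s, ".0")
      s
    }, "")
  } else {
    out <- as.character(col)
  }
  ifelse(is.na(out), NA_TOKEN, out)
}

#' Write a BIDS tab-separated table
#'
#' Inverse of [read_bids_tsv()]: tab-delimited UTF-8 with a header row,
#' missing cells serialized as `n/a`, no quoting, LF line endings.
#'
#' @param df Data frame to write.
#' @param path Destination file.
#' @param schema Optional schema (as in [read_bids_tsv()]) checked before
#'   writing.
#' @return `path`, invisibly.
#' @export
write_bids_tsv <- function(df, path, schema = attr(df, "schema")) {
  check_bids_table(df, schema, context = path)
  out <- as.data.frame(lapply(df, fmt_tsv_column),
                       check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- names(df)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(out), collapse = "\t"),
               if (nrow(out) > 0) do.call(paste, c(unname(out), sep = "\t"))),
             con, sep = "\n", useBytes = FALSE)
  invisible(path)
}

#' Read a JSON sidecar document
#'
#' @param path File to read.
#' @return A named list (top-level JSON object).
#' @export
read_bids_json <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE,
                                     simplifyDataFrame = FALSE,
                                     simplifyMatrix = FALSE),
                  error = function(e) {
                    format_error(sprintf("%s: invalid JSON (%s)", path,
                                         conditionMessage(e)))
                  })
  if (!is.list(doc)) format_error(sprintf("%s: top level must be a JSON object", path))
  doc
}

#' Write a JSON sidecar document
#'
#' UTF-8, pretty-printed, numbers written without locale formatting or digit
#' rounding.
#'
#' @param doc Named list (top-level JSON object).
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_bids_json <- function(doc, path) {
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

# directory depth of a relative path (0 = dataset root)
path_depth <- function(relpath) lengths(gregexpr("/", relpath, fixed = TRUE)) *
  grepl("/", relpath, fixed = TRUE)

# is `sub` (sidecar entity set) a subset of `sup` (target entity set),
# with equal labels on shared keys?
entities_subset <- function(sub, sup) {
  k <- names(sub)
  all(k %in% names(sup)) && all(unname(sub) == unname(unclass(sup)[k]))
}

#' Find the JSON sidecars applicable to a data file
#'
#' Implements the selection half of the Inheritance Principle: a JSON sidecar
#' applies to a target file iff the sidecar's entity set is a subset of the
#' target's entities (with equal labels) and its suffix matches the queried
#' suffix. The result is ordered shallowest first (dataset root, then
#' subject, then session level), which is the merge order used by
#' [resolve_bids_metadata()].
#'
#' @param index A [index_bids_dataset()] result.
#' @param target The `bids_path` of the data file.
#' @param suffix Sidecar suffix to resolve; defaults to the target's own
#'   suffix (so for an `_eeg.vhdr` file the `eeg.json` chain is returned;
#'   pass `"events"` to resolve the events sidecars of the same recording).
#' @return List of applicable index entries, root-first. Raises an ambiguity
#'   error if two distinct sidecars at the same directory level both apply.
#' @export
applicable_sidecars <- function(index, target, suffix = target$suffix) {
  stopifnot(inherits(index, "bids_index"), inherits(target, "bids_path"))
  cands <- index_select(index, function(p) {
    p$suffix == suffix && p$extension == ".json" &&
      entities_subset(p$entities, target$entities)
  })
  if (length(cands) == 0) return(list())
  depth <- vapply(cands, function(e) path_depth(e$relpath), 0L)
  if (anyDuplicated(depth)) {
    d <- depth[duplicated(depth)][1]
    clash <- vapply(cands[depth == d], `[[`, "", "relpath")
    ambiguity_error(sprintf(
      "sidecars '%s' at the same level both apply to '%s'",
      paste(clash, collapse = "' and '"), build_bids_path(target, check = FALSE)))
  }
  cands[order(depth)]
}

#' Resolve inherited metadata for a data file
#'
#' Implements the merge half of the Inheritance Principle: the applicable
#' sidecars are merged shallowly (top-level keys) in root-to-leaf order, so a
#' deeper document overrides a shallower one key by key; keys absent from
#' every applicable sidecar are absent from the result. The outcome is
#' deterministic and independent of filesystem enumeration order.
#'
#' @inheritParams applicable_sidecars
#' @return Named list: the merged metadata document (empty list if no sidecar
#'   applies).
#' @export
resolve_bids_metadata <- function(index, target, suffix = target$suffix) {
  chain <- applicable_sidecars(index, target, suffix)
  merged <- list()
  for (e in chain) {
    doc <- read_bids_json(file.path(index$root, e$relpath))
    merged[names(doc)] <- doc
  }
  merged
}
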