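# Shared fixture builders. Everything is generated in code under tempdir();
# no fixture files ship with the package.

tmp_root <- function(prefix = "eegbids_test_", envir = parent.frame()) {
  root <- tempfile(prefix)
  withr::defer(unlink(root, recursive = TRUE), envir = envir)
  root
}

# a small pristine dataset; deleted when the calling test finishes
pristine_dataset <- function(seed = 1, n_subjects = 1, tasks = "rest", ...,
                             envir = parent.frame()) {
  root <- tmp_root("ds_", envir = envir)
  make_dataset(root, n_subjects = n_subjects, tasks = tasks, seed = seed, ...)
  root
}

# seeded generator of grammar-valid bids_path objects for property tests
random_bids_path <- function() {
  label <- function() paste0(sample(c(letters, 0:9), sample(1:4, 1), replace = TRUE),
                             collapse = "")
  if (stats::runif(1) < 0.15) {
    # root-level file
    choice <- sample(c("dataset_description", "participants", "README", "events"), 1)
    return(switch(choice,
      dataset_description = bids_path(entity_set(), "dataset_description", ".json"),
      participants = bids_path(entity_set(), "participants",
                               sample(c(".tsv", ".json"), 1)),
      README = bids_path(entity_set(), "README", ""),
      events = bids_path(entity_set(task = label()), "events", ".json")))
  }
  ents <- c(sub = label())
  if (stats::runif(1) < 0.4) ents <- c(ents, ses = label())
  suffix <- sample(c("eeg", "channels", "events", "electrodes", "coordsystem"), 1)
  if (suffix %in% c("eeg", "channels", "events")) {
    ents <- c(ents, task = label())
  } else if (stats::runif(1) < 0.5) {
    ents <- c(ents, task = label())
  }
  if (stats::runif(1) < 0.3) ents <- c(ents, acq = label())
  if (stats::runif(1) < 0.3) ents <- c(ents, run = label())
  extension <- switch(suffix,
                      eeg = sample(c(".edf", ".vhdr", ".vmrk", ".eeg", ".set",
                                     ".fdt", ".bdf", ".json"), 1),
                      coordsystem = ".json",
                      sample(c(".tsv", ".json"), 1))
  bids_path(do.call(entity_set, as.list(ents)), suffix, extension, datatype = "eeg")
}

# file-level checksum map of a tree, for read-only / determinism assertions
tree_checksums <- function(root) {
  files <- sort(list.files(root, recursive = TRUE))
  vapply(files, function(f) {
    paste(tools::md5sum(file.path(root, f)), collapse = "")
  }, "")
}
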