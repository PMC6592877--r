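test_that("TSV round trip preserves values, column order and n/a cells", {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  tab <- data.frame(name = c("Fz", "Cz", "Pz", "Oz"),
                    type = c("EEG", "EEG", "EOG", "EEG"),
                    units = rep("µV", 4),
                    status = c("good", "bad", NA, "good"),
                    stringsAsFactors = FALSE)
  write_bids_tsv(tab, path, schema = "channels")
  back <- read_bids_tsv(path, schema = "channels")
  expect_equal(names(back), names(tab))
  expect_equal(back$status, tab$status)
  expect_equal(nrow(back), 4)
  # the n/a token is literally in the file
  expect_true(any(grepl("\tn/a", readLines(path))))

  # numeric cells survive within 1 ulp
  ev <- data.frame(onset = c(0.1 + 0.2, 1/3, 2.5), duration = c(0, 1e-9, pi))
  evp <- tempfile(fileext = ".tsv")
  on.exit(unlink(evp), add = TRUE)
  write_bids_tsv(ev, evp, schema = "events")
  evb <- read_bids_tsv(evp, schema = "events")
  expect_equal(evb$onset, ev$onset, tolerance = 1e-15)
  expect_equal(evb$duration, ev$duration, tolerance = 1e-15)
})

test_that("table schemas reject wrong leading columns and duplicates", {
  p <- tempfile(fileext = ".tsv")
  on.exit(unlink(p))
  writeLines(c("duration\tonset", "0.0\t1.0"), p)
  expect_error(read_bids_tsv(p, schema = "events"), class = "eegbids_schema_error")

  writeLines(c("name\ttype\tunits", "Cz\tEEG\tµV", "Cz\tEEG\tµV"), p)
  expect_error(read_bids_tsv(p, schema = "channels"), class = "eegbids_schema_error")

  writeLines(c("name\ttype\tunits\tstatus", "Cz\tEEG\tµV\tmeh"), p)
  expect_error(read_bids_tsv(p, schema = "channels"), class = "eegbids_schema_error")

  writeLines(c("onset\tduration", "abc\t0.0"), p)
  expect_error(read_bids_tsv(p, schema = "events"), class = "eegbids_schema_error")
})

# minimal tree with sidecars at two levels for inheritance tests
inheritance_fixture <- function(root_doc, subject_doc = NULL,
                                root_name = "task-rest_eeg.json",
                                envir = parent.frame()) {
  root <- tmp_root("inh_", envir = envir)
  dir.create(file.path(root, "sub-01", "eeg"), recursive = TRUE)
  data_rel <- "sub-01/eeg/sub-01_task-rest_eeg.vhdr"
  writeLines("stub", file.path(root, data_rel))
  write_bids_json(root_doc, file.path(root, root_name))
  if (!is.null(subject_doc)) {
    write_bids_json(subject_doc,
                    file.path(root, "sub-01", "eeg", "sub-01_task-rest_eeg.json"))
  }
  list(root = root, index = index_bids_dataset(root),
       target = parse_bids_path(data_rel))
}

test_that("sidecar applicability follows the entity-subset rule", {
  fx <- inheritance_fixture(list(TaskName = "rest"),
                            subject_doc = list(SamplingFrequency = 512),
                            root_name = "task-rest_eeg.json")
  chain <- applicable_sidecars(fx$index, fx$target)
  expect_length(chain, 2)
  expect_equal(chain[[1]]$relpath, "task-rest_eeg.json")  # root first

  # a root events.json applies to the recording when resolving events metadata
  write_bids_json(list(StimulusPresentation = "screen"),
                  file.path(fx$root, "task-rest_events.json"))
  idx <- index_bids_dataset(fx$root)
  ev_chain <- applicable_sidecars(idx, fx$target, suffix = "events")
  expect_length(ev_chain, 1)
  expect_equal(ev_chain[[1]]$relpath, "task-rest_events.json")

  # mismatching task entity does not apply
  fx2 <- inheritance_fixture(list(TaskName = "other"),
                             root_name = "task-other_eeg.json")
  expect_length(applicable_sidecars(fx2$index, fx2$target), 0)
})

test_that("inheritance merge is root-first with key-by-key override", {
  # single source: merged document is identical
  fx <- inheritance_fixture(list(SamplingFrequency = 1000, TaskName = "YY"))
  expect_equal(resolve_bids_metadata(fx$index, fx$target),
               list(SamplingFrequency = 1000, TaskName = "YY"))

  # deeper document overrides key by key
  fx <- inheritance_fixture(list(SamplingFrequency = 1000, TaskName = "YY"),
                            subject_doc = list(SamplingFrequency = 512))
  merged <- resolve_bids_metadata(fx$index, fx$target)
  expect_equal(merged$SamplingFrequency, 512)
  expect_equal(merged$TaskName, "YY")

  # disjoint key sets merge to the union
  fx <- inheritance_fixture(list(TaskName = "YY"),
                            subject_doc = list(EEGReference = "Cz"))
  expect_mapequal(resolve_bids_metadata(fx$index, fx$target),
                  list(TaskName = "YY", EEGReference = "Cz"))
})

test_that("two applicable sidecars at one level raise an ambiguity error", {
  fx <- inheritance_fixture(list(TaskName = "rest"))
  # second root-level sidecar that also applies (bare eeg.json has no task
  # entity requirement at the root only via task-entity form; use acq to vary)
  write_bids_json(list(TaskName = "rest2"),
                  file.path(fx$root, "task-rest_acq-x_eeg.json"))
  # give the target an acq entity so both root sidecars apply
  dir.create(file.path(fx$root, "sub-02", "eeg"), recursive = TRUE)
  rel <- "sub-02/eeg/sub-02_task-rest_acq-x_eeg.vhdr"
  writeLines("stub", file.path(fx$root, rel))
  idx <- index_bids_dataset(fx$root)
  expect_error(applicable_sidecars(idx, parse_bids_path(rel)),
               class = "eegbids_ambiguity_error")
})

test_that("JSON documents round trip through read/write", {
  p <- tempfile(fileext = ".json")
  on.exit(unlink(p))
  doc <- list(TaskName = "rest", SamplingFrequency = 250,
              SoftwareFilters = list(HighPass = list(CutoffHz = 0.1)))
  write_bids_json(doc, p)
  back <- read_bids_json(p)
  expect_equal(back$TaskName, "rest")
  expect_equal(back$SamplingFrequency, 250)
  expect_equal(back$SoftwareFilters$HighPass$CutoffHz, 0.1)
  writeLines("[1, 2]", p)
  expect_error(read_bids_json(p), class = "eegbids_format_error")
})
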