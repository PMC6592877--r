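test_that("parse_bids_path handles subject-level and root-level names", {
  p <- parse_bids_path("sub-XX/eeg/sub-XX_task-YY_channels.tsv")
  expect_equal(unclass(p$entities), c(sub = "XX", task = "YY"))
  expect_equal(p$datatype, "eeg")
  expect_equal(p$suffix, "channels")
  expect_equal(p$extension, ".tsv")

  d <- parse_bids_path("dataset_description.json")
  expect_length(d$entities, 0)
  expect_equal(d$suffix, "dataset_description")
  expect_equal(d$extension, ".json")
  expect_null(d$datatype)

  r <- parse_bids_path("README")
  expect_equal(r$suffix, "README")
  expect_equal(r$extension, "")

  s <- parse_bids_path("task-rest_events.json")
  expect_equal(unclass(s$entities), c(task = "rest"))
})

test_that("grammar violations are rejected, never silently accepted", {
  # run before task violates canonical order
  expect_error(parse_bids_path("sub-01/eeg/sub-01_run-1_task-rest_eeg.edf"),
               class = "eegbids_grammar_error")
  # directory/filename entity mismatch
  expect_error(parse_bids_path("sub-01/eeg/sub-02_task-rest_eeg.edf"),
               class = "eegbids_grammar_error")
  expect_error(parse_bids_path("sub-01/ses-a/eeg/sub-01_ses-b_task-rest_eeg.edf"),
               class = "eegbids_grammar_error")
  # unknown entity key, duplicate key, missing suffix, bad datatype
  expect_error(parse_bids_path("sub-01/eeg/sub-01_foo-1_task-rest_eeg.edf"),
               class = "eegbids_grammar_error")
  expect_error(parse_bids_path("sub-01/eeg/sub-01_sub-01_task-rest_eeg.edf"),
               class = "eegbids_grammar_error")
  expect_error(parse_bids_path("sub-01/eeg/sub-01_task-rest.edf"),
               class = "eegbids_grammar_error")
  expect_error(parse_bids_path("sub-01/meg/sub-01_task-rest_eeg.edf"),
               class = "eegbids_grammar_error")
  # suffix eeg without task
  expect_error(parse_bids_path("sub-01/eeg/sub-01_eeg.edf"),
               class = "eegbids_grammar_error")
})

test_that("build_bids_path serializes canonically and checks compatibility", {
  expect_equal(
    build_bids_path(bids_path(entity_set(sub = "XX", task = "YY"), "eeg", ".edf")),
    "sub-XX/eeg/sub-XX_task-YY_eeg.edf")
  expect_equal(
    build_bids_path(bids_path(entity_set(sub = "01", ses = "02", task = "med"),
                              "eeg", ".vhdr")),
    "sub-01/ses-02/eeg/sub-01_ses-02_task-med_eeg.vhdr")
  expect_error(
    build_bids_path(bids_path(entity_set(sub = "01", task = "a"), "eeg", ".xyz")),
    class = "eegbids_invariant_error")
  expect_error(
    build_bids_path(bids_path(entity_set(sub = "01", task = "a"), "channels", ".edf",
                              datatype = "eeg")),
    class = "eegbids_invariant_error")
  # suffixes eeg/channels/events demand a task entity at construction
  expect_error(bids_path(entity_set(sub = "01"), "channels", ".tsv"),
               class = "eegbids_grammar_error")
})

test_that("parse is the left inverse of build over 200 random valid paths", {
  set.seed(20260922)
  for (i in 1:200) {
    p <- random_bids_path()
    rel <- build_bids_path(p, check = FALSE)
    expect_identical(parse_bids_path(rel), p, label = rel)
  }
})

test_that("entity sets are canonically ordered and validated", {
  e <- entity_set(task = "rest", sub = "01")
  expect_equal(names(e), c("sub", "task"))
  expect_error(entity_set(sub = "01", bogus = "x"), class = "eegbids_grammar_error")
  expect_error(entity_set(sub = "a b"), class = "eegbids_grammar_error")
  expect_error(entity_set(sub = ""), class = "eegbids_grammar_error")
})

test_that("index_bids_dataset is deterministic and keeps unparseable entries", {
  root <- tmp_root()
  dir.create(file.path(root, "sub-01", "eeg"), recursive = TRUE)
  writeLines("x", file.path(root, "sub-01", "eeg", "notbids.txt"))
  writeLines("x", file.path(root, "sub-01", "eeg", "sub-01_task-a_channels.tsv"))
  writeLines("{}", file.path(root, "dataset_description.json"))
  dir.create(file.path(root, "sourcedata"))
  writeLines("raw", file.path(root, "sourcedata", "anything goes.xyz"))

  idx <- index_bids_dataset(root)
  expect_equal(length(idx$entries), 3)  # sourcedata contents never parsed
  bad <- Filter(function(e) e$unparseable, idx$entries)
  expect_equal(vapply(bad, `[[`, "", "relpath"), "sub-01/eeg/notbids.txt",
               ignore_attr = TRUE)
  expect_equal(names(idx$subject_files), "01")
  expect_equal(idx$freeform_dirs, "sourcedata")

  idx2 <- index_bids_dataset(root)
  expect_identical(idx, idx2)

  empty <- tmp_root()
  dir.create(empty)
  e <- index_bids_dataset(empty)
  expect_length(e$root_files, 0)
  expect_length(e$subject_files, 0)

  expect_error(index_bids_dataset(tempfile("missing_")), class = "eegbids_io_error")
})

test_that("recordings enforce their invariants", {
  d <- matrix(0, 2, 100)
  expect_s3_class(new_recording(d, 100), "eeg_recording")
  expect_error(new_recording(d, 0), class = "eegbids_invariant_error")
  expect_error(new_recording(d, 100, channel_names = c("a", "a")),
               class = "eegbids_invariant_error")
  expect_error(new_recording(d, 100, channel_types = "XXX"),
               class = "eegbids_invariant_error")
  ev <- data.frame(onset = 2, duration = 0, description = "late")
  expect_error(new_recording(d, 100, events = ev),  # 100 samples @100 Hz = 1 s
               class = "eegbids_invariant_error")
})
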