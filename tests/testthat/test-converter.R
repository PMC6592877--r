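test_that("conversion writes the full sidecar family and validates clean", {
  rec <- make_recording(n_channels = 4, sfreq = 250, duration_s = 2,
                        n_events = 2, seed = 10)
  root <- tmp_root("conv_")
  written <- convert_recording(rec, entity_set(sub = "01", task = "rest"),
                               eeg_metadata("rest", "Cz", 50), root)
  # triplet + channels + eeg.json + events under sub-01/eeg/
  in_subtree <- grep("^sub-01/eeg/", written, value = TRUE)
  expect_length(in_subtree, 6)
  expect_setequal(tools::file_ext(basename(in_subtree)),
                  c("vhdr", "vmrk", "eeg", "tsv", "json"))
  expect_true("dataset_description.json" %in% written)
  expect_true("participants.tsv" %in% written)
  expect_true(validate_bids(root)$ok)

  # eeg.json carries measured quantities
  meta <- read_bids_json(file.path(root, "sub-01/eeg/sub-01_task-rest_eeg.json"))
  expect_equal(meta$SamplingFrequency, 250)
  expect_equal(meta$EEGChannelCount, 4)
  expect_equal(meta$RecordingDuration, 2)
})

test_that("events.tsv rows carry onsets in seconds", {
  rec <- new_recording(matrix(0, 1, 1000), 100,
                       events = data.frame(onset = c(1.0, 2.5),
                                           duration = c(0, 0),
                                           description = c("a", "b")))
  root <- tmp_root("convev_")
  convert_recording(rec, entity_set(sub = "01", task = "x"),
                    eeg_metadata("x"), root)
  lines <- readLines(file.path(root, "sub-01/eeg/sub-01_task-x_events.tsv"))
  expect_equal(lines[1], "onset\tduration\ttrial_type")
  expect_equal(lines[2], "1.0\t0.0\ta")
  expect_equal(lines[3], "2.5\t0.0\tb")
})

test_that("trial_type is omitted when no event has a description", {
  rec <- new_recording(matrix(0, 1, 1000), 100,
                       events = data.frame(onset = 1, duration = 0,
                                           description = ""))
  root <- tmp_root("convtt_")
  convert_recording(rec, entity_set(sub = "01", task = "x"),
                    eeg_metadata("x"), root)
  lines <- readLines(file.path(root, "sub-01/eeg/sub-01_task-x_events.tsv"))
  expect_equal(lines[1], "onset\tduration")
})

test_that("EDF output round trips within the codec bound", {
  rec <- make_recording(n_channels = 3, sfreq = 500, duration_s = 2, seed = 44)
  root <- tmp_root("convedf_")
  convert_recording(rec, entity_set(sub = "02", task = "rest"),
                    eeg_metadata("rest"), root, format = "edf")
  f <- file.path(root, "sub-02/eeg/sub-02_task-rest_eeg.edf")
  expect_true(file.exists(f))
  back <- read_edf(f)
  m <- 1.01 * apply(abs(rec$data), 1, max)
  expect_true(all(abs(rec$data - back$data) <= 2 * max(m) / 65535))
  expect_true(validate_bids(root)$ok)
})

test_that("copy_through preserves the source bytes", {
  rec <- make_recording(n_channels = 2, seed = 45)
  src <- tempfile(fileext = ".edf")
  on.exit(unlink(src))
  write_edf(rec, src)
  root <- tmp_root("convct_")
  convert_recording(src, entity_set(sub = "03", task = "rest"),
                    eeg_metadata("rest"), root, copy_through = TRUE)
  out <- file.path(root, "sub-03/eeg/sub-03_task-rest_eeg.edf")
  expect_identical(readBin(out, "raw", file.size(out)),
                   readBin(src, "raw", file.size(src)))
  expect_true(validate_bids(root)$ok)
})

test_that("collisions are refused without overwrite and leave no partial state", {
  rec <- make_recording(seed = 46)
  root <- tmp_root("convcol_")
  ents <- entity_set(sub = "01", task = "rest")
  convert_recording(rec, ents, eeg_metadata("rest"), root)
  before <- tree_checksums(root)
  expect_error(convert_recording(rec, ents, eeg_metadata("rest"), root),
               class = "eegbids_collision_error")
  expect_identical(tree_checksums(root), before)  # atomic: nothing changed
  # with overwrite it succeeds
  expect_no_error(convert_recording(rec, ents, eeg_metadata("rest"), root,
                                    overwrite = TRUE))
})

test_that("a failing conversion leaves no partial files", {
  rec <- make_recording(seed = 47)
  root <- tmp_root("convfail_")
  expect_error(convert_recording(rec, entity_set(sub = "01", task = "rest"),
                                 list(TaskName = "rest"),  # missing required keys
                                 root),
               class = "eegbids_schema_error")
  expect_true(!dir.exists(root) ||
                length(list.files(root, recursive = TRUE)) == 0)
})

test_that("participants.tsv grows idempotently with n/a backfill", {
  root <- tmp_root("part_")
  dir.create(root)
  expect_true(append_participant(root, "01"))
  lines <- readLines(file.path(root, "participants.tsv"))
  expect_equal(lines, c("participant_id", "sub-01"))
  # second call with the same subject is a no-op
  expect_false(append_participant(root, "01"))
  expect_equal(readLines(file.path(root, "participants.tsv")), lines)
  # a new column backfills earlier rows with n/a
  append_participant(root, "02", fields = list(age = 23))
  tab <- read_bids_tsv(file.path(root, "participants.tsv"), schema = "participants")
  expect_equal(tab$participant_id, c("sub-01", "sub-02"))
  expect_equal(tab$age, c(NA, "23"))
})

test_that("entities must include sub and task", {
  rec <- make_recording(seed = 48)
  expect_error(convert_recording(rec, entity_set(sub = "01"),
                                 eeg_metadata("x"), tmp_root()),
               class = "eegbids_invariant_error")
})
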