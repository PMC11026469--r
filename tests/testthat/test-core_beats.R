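test_that("beats-csv reader parses, validates and round-trips", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_r_ms,label,morph_id,p_on_ms,qrs_on_ms,qrs_off_ms,t_end_ms,fqrs",
               "0,N,,,,,,", "500,N,,,,,,", "1000,N,,,,,,"), tf)
  bs <- read_beats(tf)
  expect_s3_class(bs, "beat_series")
  expect_equal(n_beats(bs), 3)
  expect_equal(nrow(bs$beats) - 1, 2)          # 2 raw intervals
  expect_equal(bs$beats$t_r, c(0, 500, 1000))

  # writer/reader round trip preserves all fields bit-for-bit
  sp <- synthetic_spec(duration_min = 2, base_rr_ms = 600, seed = 4)
  gen <- gen_beats(sp)
  tf2 <- withr::local_tempfile(fileext = ".csv")
  write_beats(gen, tf2)
  back <- read_beats(tf2)
  expect_identical(back$beats$t_r, gen$beats$t_r)
  expect_identical(back$beats$t_end, gen$beats$t_end)
  expect_identical(back$beats$label, gen$beats$label)
})

test_that("unknown labels fall back to artifact with a warning", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_r_ms,label", "0,N", "500,Q", "1000,N"), tf)
  expect_warning(bs <- read_beats(tf), "unknown label")
  expect_equal(bs$beats$label, c("N", "A", "N"))
})

test_that("unsorted times and empty files are hard errors", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_r_ms,label", "1000,N", "500,N"), tf)
  expect_error(read_beats(tf), "non-monotonic beat time at row 2")
  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("t_r_ms,label", tf2)
  expect_error(read_beats(tf2), "empty")
  expect_error(read_beats(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("wfdb-ann dialect maps mnemonics and converts samples", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("  0:00.000      0     N    0    0    0",
               "  0:00.500    250     V    0    0    0",
               "  0:01.000    500     A    0    0    0",
               "  0:01.500    750     F    0    0    0"), tf)
  bs <- read_beats(tf, dialect = "wfdb-ann", meta = list(fs_hz = 500))
  expect_equal(bs$beats$t_r, c(0, 500, 1000, 1500))
  expect_equal(bs$beats$label, c("N", "V", "S", "A"))
})

test_that("clean_to_nn keeps only intervals between normal complexes", {
  # one V: both flanking intervals excluded
  nn <- clean_to_nn(bs_labels(c("N", "N", "V", "N", "N")))
  expect_equal(length(nn$rr_ms), 2)
  expect_equal(nn$n_excluded, 2)
  # all N
  for (k in c(2, 5, 11)) {
    nn <- clean_to_nn(bs_labels(rep("N", k)))
    expect_equal(length(nn$rr_ms), k - 1)
    expect_equal(nn$n_excluded, 0)
  }
  # alternation: every interval touches a V
  nn <- clean_to_nn(bs_labels(c("N", "V", "N", "V", "N")))
  expect_equal(length(nn$rr_ms), 0)
  expect_equal(nn$n_excluded, 4)
  expect_error(clean_to_nn(bs_labels("N")), "no intervals")
})

test_that("kept + excluded always partitions the raw intervals", {
  set.seed(42)
  for (rep in 1:50) {
    labs <- sample(c("N", "V", "S", "A"), sample(2:40, 1), replace = TRUE,
                   prob = c(0.8, 0.1, 0.05, 0.05))
    s <- bs_labels(labs, spacing = 800)
    nn <- clean_to_nn(s)
    expect_equal(length(nn$rr_ms) + nn$n_excluded + nn$n_guard_excluded,
                 length(labs) - 1)
    # idempotence in effect: every kept interval is a consecutive N-N pair
    # of the series with non-N beats deleted
    nset <- s$beats$t_r[s$beats$label == "N"]
    if (length(nn$rr_ms)) {
      expect_true(all(nn$start_ms %in% nset))
      expect_true(all((nn$start_ms + nn$rr_ms) %in% nset))
    }
  }
})

test_that("physiologic guard drops implausible NN with its own count", {
  s <- bs_labels(rep("N", 5), spacing = 1000)
  s$beats$t_r[4:5] <- s$beats$t_r[4:5] + 5000   # one 6-s dropout interval
  s$meta$duration_ms <- max(s$beats$t_r)
  nn <- clean_to_nn(s)
  expect_equal(nn$n_guard_excluded, 1)
  expect_equal(length(nn$rr_ms) + nn$n_excluded + nn$n_guard_excluded, 4)
  nn2 <- clean_to_nn(s, nn_max = 10000)
  expect_equal(nn2$n_guard_excluded, 0)
})

test_that("write_summary emits stable decimal text that round-trips", {
  rows <- list(
    list(recording_id = "a", hr_bpm = 123.456789012345, lown = "2"),
    list(recording_id = "b", hr_bpm = 60.1, lown = "0")
  )
  tf <- withr::local_tempfile(fileext = ".csv")
  write_summary(rows, tf)
  back <- read_summary(tf)
  expect_equal(nrow(back), 2)
  expect_identical(back$hr_bpm, c(123.456789012345, 60.1))
  expect_identical(back$recording_id, c("a", "b"))
  expect_error(write_summary(list(), tf), "no summary rows")
})
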