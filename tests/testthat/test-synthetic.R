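test_that("unmodulated IPFM emits beats at exactly the base period", {
  sp <- synthetic_spec(duration_min = 10, base_rr_ms = 1000,
                       modulators = NULL, rsa_amp_ms = 0, seed = 1)
  bs <- gen_beats(sp)
  expect_lte(abs(n_beats(bs) - 600), 1)
  rr <- diff(bs$beats$t_r)
  expect_lt(max(abs(rr - 1000)), 1e-6)
  # beat count bound for a few base periods
  for (b in c(400, 700, 1300)) {
    spb <- synthetic_spec(duration_min = 5, base_rr_ms = b,
                          modulators = NULL, rsa_amp_ms = 0, seed = 1)
    expect_lte(abs(n_beats(gen_beats(spb)) - floor(5 * 60000 / b)), 1)
  }
})

test_that("generation is deterministic given the spec", {
  sp <- synthetic_spec(duration_min = 5, seed = 42)
  b1 <- gen_beats(sp)
  b2 <- gen_beats(sp)
  expect_identical(b1$beats, b2$beats)
  b3 <- gen_beats(synthetic_spec(duration_min = 5, seed = 43))
  expect_false(identical(b1$beats$t_end, b3$beats$t_end))
})

test_that("tachogram variance matches the planted modulator power", {
  sp <- synthetic_spec(duration_min = 30, base_rr_ms = 500,
                       modulators = data.frame(freq_hz = c(0.05, 0.12),
                                               amp_ms = c(30, 25),
                                               phase = c(0, 2)),
                       rsa_amp_ms = 20, rsa_freq_hz = 0.25, seed = 8)
  bs <- gen_beats(sp)
  rr <- diff(bs$beats$t_r)
  planted <- (30^2 + 25^2 + 20^2) / 2
  expect_equal(mean((rr - mean(rr))^2), planted, tolerance = 0.05)
})

test_that("deep modulation and degenerate specs are rejected", {
  expect_error(synthetic_spec(base_rr_ms = 100), "outside")
  expect_error(
    synthetic_spec(base_rr_ms = 600,
                   modulators = data.frame(freq_hz = 0.1, amp_ms = 300,
                                           phase = 0)),
    "too deep")
})

test_that("generator output passes its own reader validation", {
  sp <- synthetic_spec(duration_min = 3, base_rr_ms = 750, seed = 5,
                       ectopy = ectopy_spec(rate_per_hr = 40))
  bs <- gen_beats(sp)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_beats(bs, tf)
  back <- read_beats(tf)
  expect_equal(n_beats(back), n_beats(bs))
  expect_equal(sum(back$beats$label == "V"), sum(bs$beats$label == "V"))
})

test_that("injected ectopy realises the requested grammar", {
  base <- function(seed = 2, dur = 60)
    gen_beats(synthetic_spec(duration_min = dur, base_rr_ms = 1000,
                             modulators = NULL, rsa_amp_ms = 30, seed = seed))
  # 45/hr isolated monomorphic over 1 h -> Lown 2
  s45 <- inject_ectopy(base(), ectopy_spec(rate_per_hr = 45), seed = 3)
  a45 <- arrhythmia_summary(s45)
  expect_equal(a45$n_pvb, 45)
  expect_equal(as.character(a45$lown), "2")
  truth <- attr(s45, "ectopy_truth")
  expect_equal(nrow(truth), 45)
  expect_true(all(truth$type == "isolated"))
  # one run of 5 -> VT -> 4b
  s5 <- inject_ectopy(base(), ectopy_spec(rate_per_hr = 1,
                                          run_len_probs = c(0, 0, 0, 0, 1)),
                      seed = 4)
  a5 <- arrhythmia_summary(s5)
  expect_equal(a5$max_run_len, 5)
  expect_equal(as.character(a5$lown), "4b")
  # R-on-T toggle -> detected via fiducials
  srt <- inject_ectopy(base(), ectopy_spec(rate_per_hr = 5, r_on_t = TRUE),
                       seed = 5)
  expect_true(as.logical(detect_r_on_t(srt)))
  expect_equal(as.character(arrhythmia_summary(srt)$lown), "5")
  # bigeminy toggle
  sbg <- inject_ectopy(base(), ectopy_spec(rate_per_hr = 2, bigeminy = TRUE),
                       seed = 6)
  expect_true(detect_bigeminy(sbg))
  # polymorphic morphology ids
  spm <- inject_ectopy(base(), ectopy_spec(rate_per_hr = 40, morph_ids = 1:3),
                       seed = 7)
  expect_true(arrhythmia_summary(spm)$polymorphic)
  # impossible density
  expect_error(inject_ectopy(base(dur = 5), ectopy_spec(rate_per_hr = 5000)),
               "too high")
})

test_that("gen_cohort is reproducible and writes a complete on-disk dataset", {
  cs <- cohort_spec(n_per_group = c(GRMD = 2, healthy = 2),
                    timepoints = c(4, 24), duration_min = 2, seed = 12)
  c1 <- gen_cohort(cs)
  c2 <- gen_cohort(cs)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$series[[1]]$beats, c2$series[[1]]$beats)
  expect_equal(nrow(c1$manifest), 8)
  expect_true(all(c("vlf_power_ms2", "hr_bpm", "lvfs_24m") %in% names(c1$truth)))
  # GRMD runs faster by the planted offset, on average
  hr <- tapply(c1$truth$hr_bpm, c1$truth$group, mean)
  expect_gt(hr[["GRMD"]], hr[["healthy"]])

  dir <- withr::local_tempdir()
  gen_cohort(cs, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_true(all(file.exists(file.path(dir, man$recording_path))))
  # dogfood: every written recording passes the reader
  for (p in man$recording_path) expect_s3_class(read_beats(file.path(dir, p)),
                                                "beat_series")
})
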