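test_that("epochize windows the recording and applies the coverage rule", {
  # 12 h fully covered at NN 1000 -> 48 epochs, all used
  nn <- nn_direct(rep(1000, 12 * 3600), duration_ms = 12 * 3600 * 1000)
  ep <- epochize(nn)
  expect_equal(sum(ep$reason != "partial"), 48)
  expect_true(all(ep$used[ep$reason != "partial"]))
  # 20-min recording: one full epoch used, trailing partial rejected
  nn2 <- nn_direct(rep(1000, 20 * 60), duration_ms = 20 * 60 * 1000)
  ep2 <- epochize(nn2)
  expect_equal(sum(ep2$used), 1)
  expect_equal(ep2$reason[2], "partial")
  # 50 % coverage -> rejected at the 0.8 default
  nn3 <- nn_direct(rep(1000, 450), duration_ms = 15 * 60 * 1000)
  ep3 <- epochize(nn3)
  expect_false(ep3$used[1])
  expect_equal(ep3$reason[1], "low_coverage")
  expect_equal(ep3$coverage_frac[1], 0.5)
})

test_that("one-sided periodogram conserves variance exactly (Parseval)", {
  set.seed(17)
  for (n in c(64, 512)) {
    x <- stats::rnorm(n)
    p <- holterhrv:::segment_periodogram(x)
    expect_equal(sum(p), mean((x - mean(x))^2), tolerance = 1e-10)
  }
})

test_that("band powers recover planted sinusoid variance a^2/2", {
  mk <- function(f, a) nn_tachogram(15 * 60, function(t) 500 + a * sin(2 * pi * f * t))
  bp_lf <- band_power(mk(0.10, 50), 0, 15 * 60 * 1000)
  expect_equal(bp_lf$lf_ms2, 50^2 / 2, tolerance = 0.1)
  expect_lt(bp_lf$vlf_ms2 + bp_lf$hf_ms2, 0.05 * bp_lf$lf_ms2)
  bp_hf <- band_power(mk(0.25, 30), 0, 15 * 60 * 1000)
  expect_equal(bp_hf$hf_ms2, 30^2 / 2, tolerance = 0.1)
  expect_lt(bp_hf$lf_hf, 0.05)
  bp_vlf <- band_power(mk(0.02, 40), 0, 15 * 60 * 1000)
  expect_equal(bp_vlf$vlf_ms2, 40^2 / 2, tolerance = 0.1)
  # constant tachogram: all powers essentially zero
  bp0 <- band_power(nn_tachogram(15 * 60, function(t) 500), 0, 15 * 60 * 1000)
  expect_lt(bp0$total_ms2, 1e-6)
})

test_that("white-noise tachogram power integrates to its variance within 2%", {
  set.seed(23)
  # white modulation on the evenly resampled series: compare integrated
  # (0, Nyquist] power of the Welch estimate against the resampled series
  # variance (rectangular window conserves power)
  nn <- nn_tachogram(30 * 60, function(t) 500 + stats::rnorm(1, 0, 30))
  rs <- holterhrv:::resample_tachogram(nn, 0, 30 * 60 * 1000)
  x <- rs$x[rs$valid]
  nfft <- 512
  starts <- seq(1, length(x) - nfft + 1, by = nfft / 2)
  pw <- rowMeans(vapply(starts, function(s)
    holterhrv:::segment_periodogram(x[s:(s + nfft - 1)]),
    numeric(nfft / 2)))
  segvar <- mean(vapply(starts, function(s) {
    xs <- x[s:(s + nfft - 1)]; mean((xs - mean(xs))^2)
  }, 0))
  expect_equal(sum(pw), segvar, tolerance = 0.02)
})

test_that("band power scales quadratically with modulation amplitude", {
  mk <- function(c) nn_tachogram(15 * 60, function(t)
    600 + c * (30 * sin(2 * pi * 0.1 * t) + 20 * sin(2 * pi * 0.25 * t)))
  b1 <- band_power(mk(1), 0, 15 * 60 * 1000)
  b2 <- band_power(mk(2), 0, 15 * 60 * 1000)
  expect_equal(b2$lf_ms2 / b1$lf_ms2, 4, tolerance = 0.02)
  expect_equal(b2$hf_ms2 / b1$hf_ms2, 4, tolerance = 0.02)
})

test_that("band additivity total = vlf + lf + hf is exact", {
  set.seed(3)
  nn <- nn_tachogram(16 * 60, function(t)
    700 + 40 * sin(2 * pi * 0.02 * t) + 30 * sin(2 * pi * 0.1 * t) +
      25 * sin(2 * pi * 0.3 * t))
  bp <- band_power(nn, 0, 15 * 60 * 1000)
  expect_identical(bp$total_ms2, bp$vlf_ms2 + bp$lf_ms2 + bp$hf_ms2)
})

test_that("long gaps break segments instead of fabricating power", {
  rr <- rep(800, 15 * 60 * 1000 / 800)
  nn_gap <- nn_direct(rr, gap_after = floor(length(rr) / 2), gap_ms = 60000,
                      duration_ms = 16.5 * 60 * 1000)
  bp <- band_power(nn_gap, 0, 15 * 60 * 1000)
  full <- band_power(nn_direct(rr, duration_ms = 15 * 60 * 1000), 0,
                     15 * 60 * 1000)
  if (!is.null(bp)) expect_lt(bp$n_segments, full$n_segments)
})

test_that("spectral_summary averages per-epoch results", {
  nn <- nn_tachogram(31 * 60, function(t) 600 + 35 * sin(2 * pi * 0.12 * t))
  ss <- spectral_summary(nn)
  expect_equal(ss$n_epochs_used, 2)
  used <- ss$epochs[ss$epochs$used, ]
  expect_equal(ss$lf_ms2, mean(used$lf_ms2))
  expect_equal(ss$hf_nu_pct, mean(used$hf_nu_pct))
  expect_true(ss$vlf_estimability_warning)   # 900 s < 3 cycles of 0.003 Hz
  # equal LF and HF content -> HF n.u. 50 % (bin-centered tones)
  f_lf <- 26 * 2 / 512; f_hf <- 64 * 2 / 512
  nn2 <- nn_tachogram(16 * 60, function(t)
    600 + 30 * sin(2 * pi * f_lf * t) + 30 * sin(2 * pi * f_hf * t))
  ss2 <- spectral_summary(nn2)
  expect_equal(ss2$hf_nu_pct, 50, tolerance = 0.02)
  expect_equal(ss2$lf_hf, 1, tolerance = 0.05)
  # no usable epoch: absent with a reason
  short <- nn_direct(rep(1000, 60), duration_ms = 61000)
  ss3 <- spectral_summary(short)
  expect_true(is.na(ss3$vlf_ms2))
  expect_equal(ss3$reason, "no usable epoch")
})
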