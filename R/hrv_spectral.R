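#' Default HRV frequency bands (Hz)
#'
#' Very-low, low and high frequency bands of RR-interval power:
#' 0.003-0.04, 0.04-0.15 and 0.15-0.4 Hz. Band intervals are half-open
#' `[low, high)` and spectral bins are assigned by bin-center frequency.
#'
#' @return named list of `c(low, high)` pairs.
#' @export
hrv_bands <- function() {
  list(vlf = c(0.003, 0.04), lf = c(0.04, 0.15), hf = c(0.15, 0.4))
}

#' Split an NN series into fixed-length spectral epochs
#'
#' Contiguous non-overlapping windows of `epoch_min` minutes from recording
#' start (time 0). Only windows fully inside the recording are formed; a
#' trailing partial window is counted as rejected. A window is usable when
#' the fraction of its span covered by kept NN time is at least
#' `min_coverage`.
#'
#' @param nn an `nn_series`.
#' @param duration_ms recording duration; default from `nn$meta`.
#' @param epoch_min epoch length in minutes (default 15).
#' @param min_coverage minimum NN-time coverage fraction (default 0.8).
#' @return data.frame with one row per window: `epoch`, `start_ms`,
#'   `end_ms`, `coverage_frac`, `used`, `reason` (`""`, `"low_coverage"` or
#'   `"partial"`).
#' @export
epochize <- function(nn, duration_ms = NULL, epoch_min = 15, min_coverage = 0.8) {
  if (is.null(duration_ms)) duration_ms <- nn$meta$duration_ms
  L <- epoch_min * 60000
  n_full <- floor(duration_ms / L)
  starts <- (seq_len(n_full) - 1) * L
  cov <- vapply(starts, function(s) {
    lo <- pmax(nn$start_ms, s)
    hi <- pmin(nn$start_ms + nn$rr_ms, s + L)
    sum(pmax(hi - lo, 0)) / L
  }, 0)
  out <- data.frame(
    epoch = seq_len(n_full), start_ms = starts, end_ms = starts + L,
    coverage_frac = cov,
    used = cov >= min_coverage,
    reason = ifelse(cov >= min_coverage, "", "low_coverage"),
    stringsAsFactors = FALSE
  )
  if (duration_ms - n_full * L > 0) {
    out <- rbind(out, data.frame(
      epoch = n_full + 1L, start_ms = n_full * L, end_ms = duration_ms,
      coverage_frac = NA_real_, used = FALSE, reason = "partial"))
  }
  out
}

# Evenly resampled tachogram over [t0, t1): value = RR at each interval's end
# time, cubic-spline interpolation between end times (linear interpolation
# acts as a sinc^2 low-pass at the beat rate and measurably attenuates the
# HF band; the spline passband is flat well past 0.4 Hz at canine rates),
# constant extension at the edges. Samples bridging a cleaning gap longer
# than max_gap_ms (or lying further than max_gap_ms outside the knot span)
# are flagged invalid so that no low-frequency power is fabricated across
# dropouts.
resample_tachogram <- function(nn, t0, t1, fs_hz = 2, max_gap_ms = 5000) {
  grid <- seq(t0, t1 - 1000 / fs_hz, by = 1000 / fs_hz)
  tk <- nn$start_ms + nn$rr_ms
  sel <- tk >= t0 - max_gap_ms & tk <= t1 + max_gap_ms
  tk <- tk[sel]; vk <- nn$rr_ms[sel]
  if (length(tk) < 4) {
    return(list(t = grid, x = rep(NA_real_, length(grid)),
                valid = rep(FALSE, length(grid))))
  }
  x <- stats::spline(tk, vk, xout = grid, method = "natural",
                     ties = "ordered")$y
  x <- pmin(pmax(x, min(vk)), max(vk))   # clamp spline overshoot at edges/gaps
  pos <- findInterval(grid, tk)
  gap_ok <- rep(FALSE, length(grid))
  inner <- pos >= 1 & pos < length(tk)
  gap_ok[inner] <- (tk[pmin(pos + 1, length(tk))] - tk[pmax(pos, 1)])[inner] <= max_gap_ms
  gap_ok[pos == 0] <- (tk[1] - grid[pos == 0]) <= max_gap_ms
  gap_ok[pos == length(tk)] <- (grid[pos == length(tk)] - tk[length(tk)]) <= max_gap_ms
  list(t = grid, x = x, valid = gap_ok)
}

# One-sided periodogram of a mean-removed segment, rectangular window,
# scaled so that the sum over (0, Nyquist] bins equals the segment's
# population variance (Parseval).
segment_periodogram <- function(xs) {
  n <- length(xs)
  p <- Mod(stats::fft(xs - mean(xs)))^2 / n^2
  half <- n %/% 2
  one <- c(2 * p[2:half], p[half + 1])   # bins 1..n/2 (Nyquist unfolded once)
  one
}

#' Spectral band powers of one epoch
#'
#' The NN tachogram inside the epoch is resampled to an evenly spaced series
#' (default 2 Hz, cubic-spline interpolation across gaps up to 5 s — longer
#' gaps invalidate the affected samples), split into `nfft`-sample segments with
#' 50\% overlap, rectangular-windowed (i.e. unwindowed) with per-segment mean
#' removal, and periodograms scaled so that the integrated power over
#' (0, Nyquist] equals the series variance in ms^2 are averaged across the
#' valid segments (Welch). Band powers are the sums over bins whose center
#' frequency lies in each half-open band; `total = vlf + lf + hf` by
#' construction.
#'
#' @param nn an `nn_series`.
#' @param t0_ms,t1_ms epoch bounds (ms).
#' @param fs_hz resampling rate (default 2).
#' @param nfft segment length in samples (default 512).
#' @param overlap fractional segment overlap (default 0.5).
#' @param max_gap_ms longest gap bridged by interpolation (default 5000).
#' @param bands band definition as from [hrv_bands()].
#' @return list `vlf_ms2`, `lf_ms2`, `hf_ms2`, `total_ms2`, `lf_hf`,
#'   `hf_nu_pct`, `n_segments`; `NULL` if no fully valid segment fits the
#'   epoch (too short or gap-broken).
#' @export
band_power <- function(nn, t0_ms, t1_ms, fs_hz = 2, nfft = 512, overlap = 0.5,
                       max_gap_ms = 5000, bands = hrv_bands()) {
  stopifnot(all(c("vlf", "lf", "hf") %in% names(bands)))
  rs <- resample_tachogram(nn, t0_ms, t1_ms, fs_hz, max_gap_ms)
  n <- length(rs$x)
  if (n < nfft) return(NULL)
  step <- max(1, round(nfft * (1 - overlap)))
  starts <- seq(1, n - nfft + 1, by = step)
  ok_segments <- 0L
  acc <- NULL
  for (s in starts) {
    idx <- s:(s + nfft - 1)
    if (!all(rs$valid[idx])) next
    p <- segment_periodogram(rs$x[idx])
    acc <- if (is.null(acc)) p else acc + p
    ok_segments <- ok_segments + 1L
  }
  if (ok_segments == 0L) return(NULL)
  p <- acc / ok_segments
  freqs <- (1:(nfft %/% 2)) * fs_hz / nfft
  bp <- vapply(bands, function(b) sum(p[freqs >= b[1] & freqs < b[2]]), 0)
  total <- bp[["vlf"]] + bp[["lf"]] + bp[["hf"]]
  lf_hf <- if (bp[["hf"]] > 0) bp[["lf"]] / bp[["hf"]] else NA_real_
  hf_nu <- if (bp[["lf"]] + bp[["hf"]] > 0)
    100 * bp[["hf"]] / (bp[["lf"]] + bp[["hf"]]) else NA_real_
  list(vlf_ms2 = bp[["vlf"]], lf_ms2 = bp[["lf"]], hf_ms2 = bp[["hf"]],
       total_ms2 = total, lf_hf = lf_hf, hf_nu_pct = hf_nu,
       n_segments = ok_segments)
}

#' Frequency-domain HRV summary of one recording
#'
#' Epochises the NN series ([epochize()]), computes band powers per usable
#' epoch ([band_power()]), and reports the arithmetic means over used
#' epochs: mean VLF/LF/HF/total (ms^2), mean LF/HF ratio across epochs and
#' mean HF in normalized units (100 * HF/(LF+HF), computed per epoch and
#' then averaged). A VLF estimability warning is raised when fewer than 3
#' cycles of the lowest VLF frequency fit in one epoch.
#'
#' @inheritParams band_power
#' @inheritParams epochize
#' @return list of class `spectral_summary`: `epochs` (per-epoch data.frame
#'   with powers and rejection reasons), `vlf_ms2`, `lf_ms2`, `hf_ms2`,
#'   `total_ms2`, `lf_hf`, `hf_nu_pct` (trace means), `n_epochs_used`,
#'   `n_epochs_rejected`, `vlf_estimability_warning`. All means `NA` with a
#'   reason when no epoch is usable.
#' @export
spectral_summary <- function(nn, duration_ms = NULL, epoch_min = 15,
                             min_coverage = 0.8, fs_hz = 2, nfft = 512,
                             overlap = 0.5, max_gap_ms = 5000,
                             bands = hrv_bands()) {
  ep <- epochize(nn, duration_ms, epoch_min, min_coverage)
  cols <- c("vlf_ms2", "lf_ms2", "hf_ms2", "total_ms2", "lf_hf",
            "hf_nu_pct", "n_segments")
  for (cl in cols) ep[[cl]] <- NA_real_
  for (k in which(ep$used)) {
    bp <- band_power(nn, ep$start_ms[k], ep$end_ms[k], fs_hz, nfft,
                     overlap, max_gap_ms, bands)
    if (is.null(bp)) {
      ep$used[k] <- FALSE
      ep$reason[k] <- "no_valid_segment"
    } else {
      for (cl in cols) ep[[cl]][k] <- bp[[cl]]
    }
  }
  used <- ep[ep$used, , drop = FALSE]
  m <- function(cl) if (nrow(used)) mean(used[[cl]], na.rm = TRUE) else NA_real_
  structure(
    list(epochs = ep,
         vlf_ms2 = m("vlf_ms2"), lf_ms2 = m("lf_ms2"), hf_ms2 = m("hf_ms2"),
         total_ms2 = m("total_ms2"), lf_hf = m("lf_hf"),
         hf_nu_pct = m("hf_nu_pct"),
         n_epochs_used = nrow(used),
         n_epochs_rejected = sum(!ep$used),
         vlf_estimability_warning = epoch_min * 60 < 3 / bands$vlf[1],
         reason = if (nrow(used)) "" else "no usable epoch"),
    class = "spectral_summary"
  )
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary> %d/%d epochs used\n",
              x$n_epochs_used, x$n_epochs_used + x$n_epochs_rejected))
  cat(sprintf("  VLF %.1f  LF %.1f  HF %.1f  total %.1f ms^2 | LF/HF %.3f  HF n.u. %.1f%%\n",
              x$vlf_ms2, x$lf_ms2, x$hf_ms2, x$total_ms2, x$lf_hf, x$hf_nu_pct))
  invisible(x)
}
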