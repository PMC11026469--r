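# Population (divide-by-n) SD throughout the time-domain indices: keeps the
# STV = RMSSD/sqrt(2) identity exact and is negligible vs n-1 on long traces.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' HRV triangular index
#'
#' Geometric index: total number of NN intervals divided by the count in the
#' highest bin of the NN density histogram at the bin width implied by a
#' 128 Hz discretisation of the interval axis (1000/128 = 7.8125 ms), bins
#' anchored at 0 (bin k covers `[k*7.8125, (k+1)*7.8125)`).
#'
#' @param nn an `nn_series` with at least 1 interval.
#' @return triangular index, in `[1, n_nn]`; 1 when all intervals share a bin.
#' @export
triangular_index <- function(nn) {
  rr <- nn$rr_ms
  if (!length(rr)) stop("empty NN series")
  bw <- 1000 / 128
  counts <- table(floor(rr / bw))
  length(rr) / max(counts)
}

#' Time-domain HRV indices
#'
#' Classical statistical indices of one recording's cleaned NN series:
#' SDNN (population SD of all NN, ms), CV(RR) = SDNN/meanNN, RMSSD (root
#' mean square of successive differences, ms), the HRV triangular index,
#' pNN50 (percentage of successive differences exceeding 50 ms), and
#' pNN10\%(meanRR) (same with threshold 10\% of the trace's mean NN, a
#' rate-adaptive variant). Successive-difference indices use only pairs of
#' NN intervals contiguous in time — differences spanning a cleaning gap are
#' artifacts of exclusion, not physiology, and are skipped.
#'
#' @param nn an `nn_series` with at least 2 intervals.
#' @return list of class `time_domain_hrv`: `mean_nn_ms`, `sdnn_ms`, `cv_rr`,
#'   `rmssd_ms`, `hrv_ti`, `pnn50_pct`, `pnn10pct_meanrr_pct`, `n_nn`,
#'   `n_pairs` (contiguous successive pairs used). When no contiguous pair
#'   exists the difference-based indices are `NA` and `diff_indices_absent`
#'   is TRUE.
#' @export
time_domain <- function(nn) {
  rr <- nn$rr_ms
  if (length(rr) < 2) stop("need at least 2 NN intervals")
  mean_nn <- mean(rr)
  i <- nn_contiguous_pairs(nn)
  d <- nn$rr_ms[i + 1] - nn$rr_ms[i]
  have_pairs <- length(d) > 0
  structure(
    list(mean_nn_ms = mean_nn,
         sdnn_ms = pop_sd(rr),
         cv_rr = pop_sd(rr) / mean_nn,
         rmssd_ms = if (have_pairs) sqrt(mean(d^2)) else NA_real_,
         hrv_ti = triangular_index(nn),
         pnn50_pct = if (have_pairs) 100 * mean(abs(d) > 50) else NA_real_,
         pnn10pct_meanrr_pct =
           if (have_pairs) 100 * mean(abs(d) > 0.1 * mean_nn) else NA_real_,
         n_nn = length(rr),
         n_pairs = length(d),
         diff_indices_absent = !have_pairs),
    class = "time_domain_hrv"
  )
}

#' @export
print.time_domain_hrv <- function(x, ...) {
  cat(sprintf(
    "<time_domain_hrv> n=%d meanNN=%.1f SDNN=%.1f CV=%.3f RMSSD=%.1f TI=%.1f pNN50=%.1f%% pNN10%%=%.1f%%\n",
    x$n_nn, x$mean_nn_ms, x$sdnn_ms, x$cv_rr, x$rmssd_ms, x$hrv_ti,
    x$pnn50_pct, x$pnn10pct_meanrr_pct))
  invisible(x)
}

#' Poincare plot quantification (SD1/SD2)
#'
#' Each NN interval is plotted against the previous one; only contiguous
#' pairs enter. Short-term variability STV (SD1) is the dispersion of the
#' points perpendicular to the line of identity RR\[n+1\] = RR\[n\] — the RMS
#' of `(x - y)/sqrt(2)` about the line itself — and long-term variability
#' LTV (SD2) is the population SD of the points along the identity line,
#' `(x + y)/sqrt(2)`, about the mean point. With this convention
#' `STV = RMSSD/sqrt(2)` exactly on the same pair set.
#'
#' @param nn an `nn_series` with at least 2 contiguous pairs.
#' @return list of class `poincare_hrv`: `stv_ms`, `ltv_ms`, `stv_ltv_ratio`
#'   (`NA` when `ltv == 0`), `n_pairs`, and `points` (data.frame `rr_n`,
#'   `rr_next` for plotting).
#' @export
poincare <- function(nn) {
  i <- nn_contiguous_pairs(nn)
  if (length(i) < 2) stop("need at least 2 contiguous NN pairs")
  x <- nn$rr_ms[i]
  y <- nn$rr_ms[i + 1]
  stv <- sqrt(mean(((x - y) / sqrt(2))^2))
  ltv <- pop_sd((x + y) / sqrt(2))
  structure(
    list(stv_ms = stv, ltv_ms = ltv,
         stv_ltv_ratio = if (ltv > 0) stv / ltv else NA_real_,
         n_pairs = length(i),
         points = data.frame(rr_n = x, rr_next = y)),
    class = "poincare_hrv"
  )
}

#' @export
print.poincare_hrv <- function(x, ...) {
  cat(sprintf("<poincare_hrv> STV=%.2f ms, LTV=%.2f ms, STV/LTV=%s (n=%d pairs)\n",
              x$stv_ms, x$ltv_ms,
              if (is.na(x$stv_ltv_ratio)) "NA" else sprintf("%.3f", x$stv_ltv_ratio),
              x$n_pairs))
  invisible(x)
}
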