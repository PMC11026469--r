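#' Heart-rate correction of the QT interval
#'
#' The four corrections in common use for canine Holter work. With `rr_s`
#' the preceding RR interval in seconds and `rr_ms` in milliseconds:
#' \describe{
#'   \item{B (Bazett)}{`QT / sqrt(rr_s)`}
#'   \item{F (Fridericia)}{`QT / rr_s^(1/3)`}
#'   \item{V (Van de Water)}{`QT - 87 * (rr_s - 1)`}
#'   \item{M (Matsunaga)}{`QT * log(600) / log(rr_ms)`, natural log}
#' }
#' B, F and V return `qt_ms` unchanged at RR = 1 s; the Matsunaga form is
#' normalised to a canine reference interval of RR = 600 ms (HR 100 bpm)
#' and is the identity there instead.
#'
#' @param qt_ms QT interval(s), ms, > 0.
#' @param rr_ms preceding RR interval(s), ms, > 0. Recycled against `qt_ms`.
#' @param formula one of `"B"`, `"F"`, `"V"`, `"M"`.
#' @return corrected QT in ms, vectorised.
#' @examples
#' qtc(250, 1000, "B")   # 250: identity at RR = 1 s
#' qtc(220, 500, "V")    # 220 - 87 * (0.5 - 1) = 263.5
#' @export
qtc <- function(qt_ms, rr_ms, formula = c("B", "F", "V", "M")) {
  formula <- match.arg(formula)
  if (any(qt_ms <= 0) || any(rr_ms <= 0)) stop("qt_ms and rr_ms must be > 0")
  rr_s <- rr_ms / 1000
  switch(formula,
    B = qt_ms / sqrt(rr_s),
    F = qt_ms / rr_s^(1 / 3),
    V = qt_ms - 87 * (rr_s - 1),
    M = qt_ms * log(600) / log(rr_ms)
  )
}

qtc_formulas <- c("B", "F", "V", "M")

#' Trace-level interval summary
#'
#' Averages over the whole trace, the convention of long ambulatory
#' recordings: heart rate is `60000 / mean(NN)` (NN from [clean_to_nn()]);
#' PR is the mean of `qrs_on - p_on` and QT the mean of `t_end - qrs_on`
#' over normal beats carrying the needed fiducials (beats lacking them are
#' skipped and counted). Corrected QT is computed per beat from that beat's
#' own preceding RR and then averaged (`qtc_mode = "per-beat"`, the default,
#' standard Holter practice and what makes a per-trace QTc-vs-HR correlation
#' meaningful), or by correcting the trace-mean QT with the trace-mean NN
#' (`"trace-mean"`). For per-beat correction the RR used is the interval
#' ending at the beat, and beats following a non-normal beat are skipped
#' (post-extrasystolic RR bias).
#'
#' @param series a `beat_series` with at least 2 normal beats.
#' @param qtc_mode `"per-beat"` or `"trace-mean"`.
#' @param nn_min,nn_max physiologic guard passed to [clean_to_nn()].
#' @return list of class `interval_summary`: `hr_bpm`, `mean_nn_ms`, `pr_ms`,
#'   `qt_ms`, `qtc_ms` (named list B/F/V/M; all `NA` when QT not computable),
#'   `n_beats_used` (per measure), `qtc_mode`.
#' @export
summarize_intervals <- function(series, qtc_mode = c("per-beat", "trace-mean"),
                                nn_min = 200, nn_max = 3000) {
  qtc_mode <- match.arg(qtc_mode)
  b <- series$beats
  if (sum(b$label == "N") < 2) stop("need at least 2 normal beats")
  nn <- clean_to_nn(series, nn_min = nn_min, nn_max = nn_max)
  mean_nn <- mean(nn$rr_ms)
  hr <- 60000 / mean_nn

  is_n <- b$label == "N"
  has_pr <- is_n & !is.na(b$p_on) & !is.na(b$qrs_on)
  has_qt <- is_n & !is.na(b$qrs_on) & !is.na(b$t_end)
  pr <- if (any(has_pr)) mean(b$qrs_on[has_pr] - b$p_on[has_pr]) else NA_real_
  qt <- if (any(has_qt)) mean(b$t_end[has_qt] - b$qrs_on[has_qt]) else NA_real_

  qtc_means <- stats::setNames(rep(NA_real_, 4), qtc_formulas)
  n_qtc <- 0L
  if (any(has_qt)) {
    if (qtc_mode == "per-beat") {
      pb <- qtc_beat_pairs(series)
      if (nrow(pb)) {
        for (f in qtc_formulas) qtc_means[[f]] <- mean(qtc(pb$qt, pb$rr, f))
        n_qtc <- nrow(pb)
      }
    } else {
      for (f in qtc_formulas) qtc_means[[f]] <- qtc(qt, mean_nn, f)
      n_qtc <- sum(has_qt)
    }
  }
  structure(
    list(hr_bpm = hr, mean_nn_ms = mean_nn, pr_ms = pr, qt_ms = qt,
         qtc_ms = as.list(qtc_means), qtc_mode = qtc_mode,
         n_beats_used = list(
           nn = length(nn$rr_ms), pr = sum(has_pr), qt = sum(has_qt),
           qtc = n_qtc, skipped_no_fiducial = sum(is_n) - sum(has_qt))),
    class = "interval_summary"
  )
}

# Per-beat (hr, qt, rr) triples usable for rate correction: normal beats with
# QT fiducials whose preceding beat is also normal (RR ending at the beat).
qtc_beat_pairs <- function(series) {
  b <- series$beats
  n <- nrow(b)
  if (n < 2) return(data.frame(hr = numeric(0), qt = numeric(0), rr = numeric(0)))
  i <- 2:n
  ok <- b$label[i] == "N" & b$label[i - 1] == "N" &
    !is.na(b$qrs_on[i]) & !is.na(b$t_end[i])
  i <- i[ok]
  rr <- b$t_r[i] - b$t_r[i - 1]
  pos <- rr > 0
  i <- i[pos]; rr <- rr[pos]
  data.frame(hr = 60000 / rr, qt = b$t_end[i] - b$qrs_on[i], rr = rr)
}

#' Select the QT-correction formula that best decorrelates QTc from heart rate
#'
#' For each of the four formulas, the QTc values of the supplied
#' (HR, QT, RR) observations are computed, then Pearson's r of QTc against HR
#' and the ordinary least-squares slope of QTc on HR. A Shapiro-Wilk
#' normality screen is run on each formula's QTc set. The selected formula
#' minimises `|r|`; ties on `|r|` break on smaller `|slope|`.
#'
#' @param hr_bpm,qt_ms,rr_ms aligned numeric vectors (>= 3 observations):
#'   heart rate, raw QT and the RR used for correction. Typically pooled
#'   per-beat values from healthy subjects, or per-subject trace means —
#'   both usages are supported (the caller decides the pooling level).
#' @return list of class `qtc_selection`: `per_formula` data.frame
#'   (formula, pearson_r, slope, normality_p, n), `selected`, and the raw
#'   QT-vs-HR `raw_r` and `raw_slope` for reference.
#' @export
select_qtc <- function(hr_bpm, qt_ms, rr_ms) {
  n <- length(hr_bpm)
  stopifnot(length(qt_ms) == n, length(rr_ms) == n)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(hr_bpm) == 0) stop("zero HR variance: correlation undefined")
  res <- lapply(qtc_formulas, function(f) {
    q <- qtc(qt_ms, rr_ms, f)
    r <- if (stats::sd(q) == 0) 0 else stats::cor(hr_bpm, q)
    slope <- if (stats::sd(q) == 0) 0 else
      stats::cov(hr_bpm, q) / stats::var(hr_bpm)
    sw <- tryCatch(
      stats::shapiro.test(if (n > 5000) sample(q, 5000) else q)$p.value,
      error = function(e) NA_real_)
    data.frame(formula = f, pearson_r = r, slope = slope,
               normality_p = sw, n = n, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  ord <- order(abs(tab$pearson_r), abs(tab$slope))
  raw_r <- stats::cor(hr_bpm, qt_ms)
  raw_slope <- stats::cov(hr_bpm, qt_ms) / stats::var(hr_bpm)
  structure(
    list(per_formula = tab, selected = tab$formula[ord[1]],
         raw_r = raw_r, raw_slope = raw_slope),
    class = "qtc_selection"
  )
}

#' @export
print.qtc_selection <- function(x, ...) {
  cat(sprintf("<qtc_selection> raw QT~HR: r = %.3f, slope = %.3f\n",
              x$raw_r, x$raw_slope))
  print(x$per_formula, row.names = FALSE)
  cat("selected:", x$selected, "\n")
  invisible(x)
}
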