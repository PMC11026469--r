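#' Annotated beat series
#'
#' The universal input of the package: one Holter recording reduced to its
#' annotated beat stream. Each beat carries its R-peak time (ms from recording
#' start), a label (`N` normal sinus, `V` ventricular ectopic, `S`
#' supraventricular ectopic, `A` artifact), an optional small-integer
#' morphology class for `V` beats (0 = unassigned), optional wave fiducials
#' (P onset, QRS onset/offset, T end; ms) and an optional fragmented-QRS flag
#' (a visual call made upstream, carried through as data).
#'
#' @param beats data.frame with columns `t_r`, `label`, and optionally
#'   `morph_id`, `p_on`, `qrs_on`, `qrs_off`, `t_end`, `fqrs`. Missing
#'   optional columns are added as `NA`.
#' @param meta list of recording metadata: `recording_id`, `subject_id`,
#'   `group` (`"GRMD"` or `"healthy"`), `age_months`, `duration_ms`
#'   (defaults to the last beat time), `fs_hz` (sampling rate of the source
#'   waveform, default 500).
#' @return An object of class `beat_series`: a list with elements `beats`
#'   (validated data.frame) and `meta`.
#' @examples
#' bs <- beat_series(data.frame(t_r = c(0, 500, 1000), label = "N"))
#' n_beats(bs)
#' @export
beat_series <- function(beats, meta = list()) {
  stopifnot(is.data.frame(beats))
  if (!all(c("t_r", "label") %in% names(beats))) {
    stop("beats needs at least columns 't_r' and 'label'")
  }
  opt_num <- c("morph_id", "p_on", "qrs_on", "qrs_off", "t_end")
  for (col in opt_num) if (is.null(beats[[col]])) beats[[col]] <- NA_real_
  if (is.null(beats$fqrs)) beats$fqrs <- NA
  beats <- beats[, c("t_r", "label", opt_num, "fqrs")]
  beats$t_r <- as.numeric(beats$t_r)
  beats$label <- as.character(beats$label)
  beats$morph_id[is.na(beats$morph_id)] <- 0
  beats$fqrs <- as.logical(beats$fqrs)

  meta <- utils::modifyList(
    list(recording_id = NA_character_, subject_id = NA_character_,
         group = NA_character_, age_months = NA_real_,
         duration_ms = NA_real_, fs_hz = 500),
    meta
  )
  if (is.na(meta$duration_ms)) {
    meta$duration_ms <- if (nrow(beats)) max(beats$t_r) else 0
  }
  x <- structure(list(beats = beats, meta = meta), class = "beat_series")
  validate_beat_series(x)
}

#' Validate a beat series
#'
#' Enforces the structural invariants: non-negative, strictly increasing
#' R-peak times; known labels (unknown labels are remapped to artifact `A`
#' with a warning); fiducial ordering `p_on < qrs_on < qrs_off < t_end` and
#' `qrs_on <= t_r <= qrs_off` wherever fiducials are present; recording
#' duration at least the last beat time.
#'
#' @param x a `beat_series`.
#' @return `x`, possibly with remapped labels.
#' @export
validate_beat_series <- function(x) {
  b <- x$beats
  if (nrow(b) == 0) stop("empty beat series")
  if (any(b$t_r < 0)) stop("negative beat time")
  d <- diff(b$t_r)
  if (length(d) && any(d <= 0)) {
    stop(sprintf("non-monotonic beat time at row %d", which(d <= 0)[1] + 1L))
  }
  bad <- !(b$label %in% c("N", "V", "S", "A"))
  if (any(bad)) {
    warning(sprintf("%d beat(s) with unknown label (%s) mapped to artifact 'A'",
                    sum(bad), paste(unique(b$label[bad]), collapse = ",")))
    b$label[bad] <- "A"
    x$beats <- b
  }
  has_fid <- !is.na(b$p_on) & !is.na(b$qrs_on) & !is.na(b$qrs_off) & !is.na(b$t_end)
  if (any(has_fid)) {
    f <- b[has_fid, ]
    ok <- f$p_on < f$qrs_on & f$qrs_on < f$qrs_off & f$qrs_off < f$t_end &
      f$qrs_on <= f$t_r & f$t_r <= f$qrs_off
    if (!all(ok)) stop("fiducial ordering violated for at least one beat")
  }
  if (x$meta$duration_ms < max(b$t_r)) stop("duration_ms earlier than last beat")
  x
}

#' @export
print.beat_series <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<beat_series> %d beats over %.1f min (subject %s, group %s, %s months)\n",
              nrow(x$beats), m$duration_ms / 60000,
              m$subject_id, m$group, format(m$age_months)))
  tab <- table(factor(x$beats$label, levels = c("N", "V", "S", "A")))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Number of beats
#' @param x a `beat_series`.
#' @return integer count.
#' @export
n_beats <- function(x) nrow(x$beats)

#' Read an annotated beat stream from disk
#'
#' Two dialects are supported. `beats-csv` is the canonical plain-text format:
#' header `t_r_ms,label,morph_id,p_on_ms,qrs_on_ms,qrs_off_ms,t_end_ms,fqrs`,
#' empty cells meaning absent. `wfdb-ann` reads the portable text form of a
#' WFDB annotation file (as printed by `rdann -v`: whitespace-separated table
#' whose columns include the sample index and the beat mnemonic); sample
#' indices are converted to ms via `fs_hz`, and mnemonics are mapped
#' N->N, V->V, S/A(atrial premature)->S, everything else -> artifact.
#'
#' @param path file path.
#' @param dialect `"beats-csv"` (default) or `"wfdb-ann"`.
#' @param meta optional metadata list merged into the result (see
#'   [beat_series()]); `fs_hz` is used for `wfdb-ann` sample conversion.
#' @return a validated `beat_series`. Unknown labels become `A` with a warning;
#'   unsorted times are a hard error naming the first offending row.
#' @export
read_beats <- function(path, dialect = c("beats-csv", "wfdb-ann"), meta = list()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "beats-csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0) stop("empty beat file: ", path)
    ren <- c(t_r_ms = "t_r", p_on_ms = "p_on", qrs_on_ms = "qrs_on",
             qrs_off_ms = "qrs_off", t_end_ms = "t_end")
    for (nm in names(ren)) {
      if (nm %in% names(df)) names(df)[names(df) == nm] <- ren[[nm]]
    }
    if (is.null(meta$recording_id)) meta$recording_id <- basename(path)
    beat_series(df, meta)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !grepl("^(#|Time)", lines)]
    if (!length(lines)) stop("empty beat file: ", path)
    parts <- strsplit(lines, "[[:space:]]+")
    # rdann -v layout: elapsed-time, sample, type, sub, chan, num
    samp <- vapply(parts, function(p) suppressWarnings(as.numeric(p[2])), 0)
    code <- vapply(parts, function(p) as.character(p[3]), "")
    if (anyNA(samp)) stop("unparsable annotation line: ", lines[which(is.na(samp))[1]])
    fs <- if (!is.null(meta$fs_hz)) meta$fs_hz else 500
    label <- ifelse(code == "N", "N",
             ifelse(code == "V", "V",
             ifelse(code %in% c("S", "A", "a", "J"), "S", "A")))
    if (is.null(meta$recording_id)) meta$recording_id <- basename(path)
    beat_series(data.frame(t_r = samp / fs * 1000, label = label), meta)
  }
}

#' Write a beat series in the canonical beats-csv dialect
#'
#' @param x a `beat_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_beats <- function(x, path) {
  b <- x$beats
  fmt <- function(v) ifelse(is.na(v), "",
    vapply(v, format, "", digits = 17, scientific = FALSE, trim = TRUE))
  out <- data.frame(
    t_r_ms = fmt(b$t_r), label = b$label, morph_id = b$morph_id,
    p_on_ms = fmt(b$p_on), qrs_on_ms = fmt(b$qrs_on),
    qrs_off_ms = fmt(b$qrs_off), t_end_ms = fmt(b$t_end), fqrs = b$fqrs
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Extract cleaned normal-to-normal (NN) intervals
#'
#' Applies the arrhythmia-adjacent exclusion rule: of the `n - 1` raw
#' consecutive-beat intervals, an interval is kept if and only if both of its
#' flanking beats are labelled `N`. This removes the RR intervals preceding
#' and following every ectopic or artifact beat, keeping only intervals
#' between normal complexes. A physiologic guard additionally drops kept
#' intervals outside `[nn_min, nn_max]` ms (telemetry dropouts otherwise
#' masquerade as giant RR); guarded intervals are counted separately.
#'
#' @param series a `beat_series` with at least 2 beats.
#' @param nn_min,nn_max physiologic NN bounds in ms (defaults 200 and 3000).
#' @return An object of class `nn_series`: list with `start_ms` and `rr_ms`
#'   (aligned numeric vectors; `start_ms` is the time of the interval's first
#'   beat), `n_excluded` (intervals dropped by the label rule),
#'   `n_guard_excluded` (dropped by the physiologic guard) and `meta`.
#'   `n_excluded + n_guard_excluded + length(rr_ms) == n_beats - 1`.
#' @export
clean_to_nn <- function(series, nn_min = 200, nn_max = 3000) {
  b <- series$beats
  if (nrow(b) < 2) stop("no intervals: fewer than 2 beats")
  n <- nrow(b)
  keep <- b$label[-n] == "N" & b$label[-1] == "N"
  rr <- diff(b$t_r)
  start <- b$t_r[-n]
  n_excluded <- sum(!keep)
  rr_k <- rr[keep]
  start_k <- start[keep]
  guard <- rr_k < nn_min | rr_k > nn_max
  structure(
    list(start_ms = start_k[!guard], rr_ms = rr_k[!guard],
         n_excluded = n_excluded, n_guard_excluded = sum(guard),
         meta = series$meta),
    class = "nn_series"
  )
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("<nn_series> %d NN intervals (mean %.1f ms), %d excluded by label, %d by guard\n",
              length(x$rr_ms), mean(x$rr_ms), x$n_excluded, x$n_guard_excluded))
  invisible(x)
}

#' Indices of contiguous successive NN pairs
#'
#' Successive-difference statistics (RMSSD, pNN50, Poincare) must only use
#' pairs of NN intervals that are adjacent in time — no excluded interval
#' between them. Pair `i` is contiguous iff the second interval starts where
#' the first one ends.
#'
#' @param nn an `nn_series`.
#' @param tol time tolerance in ms.
#' @return integer vector of indices `i` such that intervals `i` and `i + 1`
#'   form a contiguous pair.
#' @export
nn_contiguous_pairs <- function(nn, tol = 1e-6) {
  k <- length(nn$rr_ms)
  if (k < 2) return(integer(0))
  i <- seq_len(k - 1)
  i[abs(nn$start_ms[i] + nn$rr_ms[i] - nn$start_ms[i + 1]) <= tol]
}

#' Write per-recording summary rows to CSV
#'
#' One row per recording, stable column order (union of fields, first-seen
#' order), full float precision (decimal text round-trips bit-for-bit).
#'
#' @param rows a non-empty list of `trace_summary` rows (named lists or
#'   one-row data.frames), or a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(rows, path) {
  if (is.data.frame(rows)) rows <- split(rows, seq_len(nrow(rows)))
  if (length(rows) == 0) stop("no summary rows to write")
  rows <- lapply(rows, function(r) {
    r <- as.list(r)
    r[vapply(r, is.null, TRUE)] <- NA
    r
  })
  cols <- unique(unlist(lapply(rows, names)))
  mat <- lapply(rows, function(r) {
    vals <- lapply(cols, function(cl) if (is.null(r[[cl]])) NA else r[[cl]])
    names(vals) <- cols
    as.data.frame(vals, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, mat)
  num <- vapply(df, is.numeric, TRUE)
  for (cl in names(df)[num]) {
    df[[cl]] <- vapply(df[[cl]], function(v) {
      if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE, trim = TRUE)
    }, "")
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a summary CSV written by [write_summary()]
#' @param path file path.
#' @return data.frame with numeric columns restored.
#' @export
read_summary <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
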