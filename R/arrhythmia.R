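#' Maximal runs of consecutive ventricular beats
#'
#' A doublet is a run of 2, a triplet a run of 3, and a salvo of ventricular
#' tachycardia a run of 4 or more (> 3 consecutive premature ventricular
#' beats).
#'
#' @param series a `beat_series`.
#' @return data.frame with one row per maximal run of consecutive `V` labels:
#'   `start_idx` (beat index), `start_ms`, `length`. Zero rows when no `V`
#'   beats are present.
#' @export
find_runs <- function(series) {
  lab <- series$beats$label
  r <- rle(lab == "V")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(
    start_idx = starts[keep],
    start_ms = series$beats$t_r[starts[keep]],
    length = r$lengths[keep]
  )
}

#' Detect ventricular bigeminy
#'
#' True when the trace contains a sustained stretch of at least
#' `min_alternations` consecutive normal-ventricular pairs
#' (`N V N V ...`).
#'
#' @param series a `beat_series`.
#' @param min_alternations minimum number of consecutive `N,V` pairs
#'   (default 4, i.e. `N V N V N V N V`).
#' @return logical scalar.
#' @export
detect_bigeminy <- function(series, min_alternations = 4) {
  lab <- series$beats$label
  n <- length(lab)
  if (n < 2 * min_alternations) return(FALSE)
  # pair i = (beat 2i-1, beat 2i) pattern at each possible phase
  is_pair <- lab[-n] == "N" & lab[-1] == "V"      # pair starting at index i
  for (phase in 1:2) {
    idx <- seq(phase, n - 1, by = 2)
    if (!length(idx)) next
    r <- rle(is_pair[idx])
    if (any(r$values & r$lengths >= min_alternations)) return(TRUE)
  }
  FALSE
}

#' Detect the R-on-T phenomenon
#'
#' A premature ventricular beat whose R wave falls on the previous beat's T
#' wave. With fiducials the rule is direct: some `V` beat's `t_r` precedes
#' the `t_end` of the preceding beat. When the preceding beat's `t_end` is
#' absent, a heuristic fallback is used: coupling interval shorter than
#' `0.5 * mean(NN)`; the result then carries `attr(, "heuristic") = TRUE`.
#'
#' @param series a `beat_series`.
#' @return logical scalar with attribute `heuristic` (TRUE when any V beat
#'   was judged by the fallback rule).
#' @export
detect_r_on_t <- function(series) {
  b <- series$beats
  v <- which(b$label == "V")
  v <- v[v > 1]
  if (!length(v)) return(structure(FALSE, heuristic = FALSE))
  prev_tend <- b$t_end[v - 1]
  direct <- !is.na(prev_tend)
  hit <- any(b$t_r[v[direct]] < prev_tend[direct])
  heuristic <- FALSE
  if (!hit && any(!direct)) {
    nn <- tryCatch(clean_to_nn(series), error = function(e) NULL)
    if (!is.null(nn) && length(nn$rr_ms)) {
      coupling <- b$t_r[v[!direct]] - b$t_r[v[!direct] - 1]
      if (any(coupling < 0.5 * mean(nn$rr_ms))) {
        hit <- TRUE
        heuristic <- TRUE
      }
    }
  }
  structure(hit, heuristic = heuristic)
}

lown_levels <- c("0", "1", "2", "3a", "3b", "4a", "4b", "5")

#' Lown grade of ventricular ectopy severity
#'
#' Highest applicable class in the order `5 > 4b > 4a > 3b > 3a > 2 > 1 > 0`:
#' 0 no PVB; 1 rare isolated PVBs, < 30/hr; 2 frequent isolated PVBs,
#' >= 30/hr (the published boundary leaves exactly 30/hr open; it is classed
#' as 2 here); 3a isolated polymorphic PVBs; 3b bigeminy; 4a doublets or
#' triplets; 4b ventricular tachycardia (run of more than 3 consecutive
#' PVBs); 5 R-on-T.
#'
#' @param n_isolated number of isolated PVBs (runs of length 1).
#' @param duration_hr recording duration in hours, > 0.
#' @param polymorphic logical: >= 2 distinct morphologies among PVBs.
#' @param bigeminy logical.
#' @param n_doublets,n_triplets counts of runs of length 2 and 3.
#' @param max_run_len longest consecutive-PVB run (0 if none).
#' @param r_on_t logical.
#' @return a factor of the Lown grade, ordered, levels
#'   `0 < 1 < 2 < 3a < 3b < 4a < 4b < 5`.
#' @export
grade_lown <- function(n_isolated, duration_hr, polymorphic = FALSE,
                       bigeminy = FALSE, n_doublets = 0, n_triplets = 0,
                       max_run_len = 0, r_on_t = FALSE) {
  if (duration_hr <= 0) stop("duration_hr must be > 0")
  rate <- n_isolated / duration_hr
  any_pvb <- n_isolated > 0 || max_run_len > 0
  g <-
    if (r_on_t && any_pvb) "5"
    else if (max_run_len >= 4) "4b"
    else if (n_doublets > 0 || n_triplets > 0) "4a"
    else if (bigeminy) "3b"
    else if (polymorphic && n_isolated > 0) "3a"
    else if (rate >= 30) "2"
    else if (n_isolated > 0) "1"
    else "0"
  factor(g, levels = lown_levels, ordered = TRUE)
}

#' Full ventricular-arrhythmia summary of one recording
#'
#' Counts PVBs, normalises them both per hour and as a percentage of total
#' beats (both conventions are in use for reporting ectopy burden),
#' enumerates doublets/triplets/salvos, detects bigeminy and R-on-T, judges
#' polymorphism from the `morph_id` labels (>= 2 distinct nonzero
#' morphologies; all-zero morphologies are assumed monomorphic with a
#' caveat flag) and assigns the Lown grade.
#'
#' @param series a `beat_series`.
#' @param duration_hr recording duration in hours; default from metadata.
#' @param min_alternations passed to [detect_bigeminy()].
#' @return list of class `arrhythmia_summary` with fields `n_pvb`,
#'   `pvb_per_hr`, `pvb_pct`, `n_isolated`, `n_doublets`, `n_triplets`,
#'   `n_salvos`, `max_run_len`, `bigeminy`, `polymorphic`,
#'   `morph_unassigned` (caveat flag), `r_on_t`, `r_on_t_heuristic`, `lown`.
#' @export
arrhythmia_summary <- function(series, duration_hr = NULL, min_alternations = 4) {
  if (is.null(duration_hr)) duration_hr <- series$meta$duration_ms / 3600000
  if (duration_hr <= 0) stop("duration_hr must be > 0")
  b <- series$beats
  runs <- find_runs(series)
  n_pvb <- sum(b$label == "V")
  n_isolated <- sum(runs$length == 1)
  morphs <- unique(b$morph_id[b$label == "V"])
  morph_unassigned <- n_pvb > 0 && all(morphs == 0)
  polymorphic <- length(setdiff(morphs, 0)) >= 2
  bigem <- detect_bigeminy(series, min_alternations)
  rot <- detect_r_on_t(series)
  lown <- grade_lown(
    n_isolated = n_isolated, duration_hr = duration_hr,
    polymorphic = polymorphic, bigeminy = bigem,
    n_doublets = sum(runs$length == 2), n_triplets = sum(runs$length == 3),
    max_run_len = if (nrow(runs)) max(runs$length) else 0,
    r_on_t = as.logical(rot)
  )
  structure(
    list(n_pvb = n_pvb,
         pvb_per_hr = n_pvb / duration_hr,
         pvb_pct = 100 * n_pvb / nrow(b),
         n_isolated = n_isolated,
         n_doublets = sum(runs$length == 2),
         n_triplets = sum(runs$length == 3),
         n_salvos = sum(runs$length >= 4),
         max_run_len = if (nrow(runs)) max(runs$length) else 0L,
         bigeminy = bigem,
         polymorphic = polymorphic,
         morph_unassigned = morph_unassigned,
         r_on_t = as.logical(rot),
         r_on_t_heuristic = attr(rot, "heuristic"),
         duration_hr = duration_hr,
         lown = lown),
    class = "arrhythmia_summary"
  )
}

#' @export
print.arrhythmia_summary <- function(x, ...) {
  cat(sprintf("<arrhythmia_summary> %d PVB (%.2f/hr, %.3f%% of beats), Lown %s\n",
              x$n_pvb, x$pvb_per_hr, x$pvb_pct, as.character(x$lown)))
  cat(sprintf("  doublets %d, triplets %d, salvos %d (max run %d); bigeminy %s; R-on-T %s%s\n",
              x$n_doublets, x$n_triplets, x$n_salvos, x$max_run_len,
              x$bigeminy, x$r_on_t, if (x$r_on_t_heuristic) " (heuristic)" else ""))
  invisible(x)
}
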