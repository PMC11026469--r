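# Run code under a local, seeded RNG stream without disturbing the caller's.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic beat stream
#'
#' States the generative world of one recording: a base heart period,
#' sinusoidal RR modulators given in real-time frequency (Hz), respiratory
#' sinus arrhythmia as one prominent high-frequency modulator, an optional
#' ectopy grammar, and linear rate laws for the wave fiducials
#' (`pr = pr0 + pr_slope * rr`, `qt = qt0 + 87 * (rr_s - 1)`, small
#' Gaussian noise on each). Defaults emulate an overnight canine Holter:
#' 12 h, adult resting RR around 880 ms (about 68 bpm), band-structured
#' oscillations in the VLF/LF ranges, and pronounced respiratory sinus
#' arrhythmia at 0.25 Hz.
#'
#' @param duration_min recording length, minutes (default 720 = 12 h).
#' @param base_rr_ms base heart period, ms, in `[200, 3000]` (default 880).
#' @param modulators data.frame `freq_hz, amp_ms, phase` of sinusoidal RR
#'   modulators. Default: 0.01 Hz / 60 ms (VLF), 0.08 Hz / 55 ms (LF).
#' @param rsa_amp_ms,rsa_freq_hz respiratory sinus arrhythmia amplitude and
#'   breathing frequency (defaults 90 ms at 0.25 Hz).
#' @param ectopy `NULL` or a list from [ectopy_spec()].
#' @param pr0,pr_slope,pr_noise_sd PR law: `pr = pr0 + pr_slope * rr` + noise
#'   (defaults 55 ms, 0.05, 1.5 ms — PR about 100 ms at RR 880 ms).
#' @param qt0,qt_slope_ms_per_s,qt_noise_sd QT law:
#'   `qt = qt0 + qt_slope_ms_per_s * (rr / 1000 - 1)` + noise (defaults
#'   230 ms, 87, 1.5 ms — the Van de Water inverse law, so QTcV recovers
#'   `qt0` exactly up to noise).
#' @param qrs_half_width_ms half-width of the QRS complex (default 25 ms).
#' @param fiducials emit wave fiducials? (default TRUE)
#' @param seed integer RNG seed (default 1).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(duration_min = 720, base_rr_ms = 880,
                           modulators = data.frame(
                             freq_hz = c(0.01, 0.08),
                             amp_ms = c(60, 55),
                             phase = c(0, 1)),
                           rsa_amp_ms = 90, rsa_freq_hz = 0.25,
                           ectopy = NULL,
                           pr0 = 55, pr_slope = 0.05, pr_noise_sd = 1.5,
                           qt0 = 230, qt_slope_ms_per_s = 87, qt_noise_sd = 1.5,
                           qrs_half_width_ms = 25,
                           fiducials = TRUE, seed = 1) {
  if (base_rr_ms < 200 || base_rr_ms > 3000) stop("base_rr_ms outside [200, 3000]")
  mods <- modulators
  if (is.null(mods)) mods <- data.frame(freq_hz = numeric(0), amp_ms = numeric(0),
                                        phase = numeric(0))
  if (rsa_amp_ms > 0) {
    mods <- rbind(mods, data.frame(freq_hz = rsa_freq_hz, amp_ms = rsa_amp_ms,
                                   phase = 0))
  }
  if (any(mods$amp_ms < 0)) stop("modulator amplitudes must be >= 0")
  if (sum(mods$amp_ms^2 / 2) >= (base_rr_ms / 3)^2) {
    stop("modulation too deep: total modulator power >= (base_rr/3)^2")
  }
  structure(
    list(duration_min = duration_min, base_rr_ms = base_rr_ms,
         modulators = mods, ectopy = ectopy,
         pr0 = pr0, pr_slope = pr_slope, pr_noise_sd = pr_noise_sd,
         qt0 = qt0, qt_slope_ms_per_s = qt_slope_ms_per_s,
         qt_noise_sd = qt_noise_sd,
         qrs_half_width_ms = qrs_half_width_ms,
         fiducials = fiducials, seed = seed),
    class = "synthetic_spec"
  )
}

#' Ectopy grammar for the synthetic generator
#'
#' @param rate_per_hr ectopic events per hour (an event is a run).
#' @param coupling_frac coupling interval as a fraction of the local NN
#'   (default 0.6; full compensation leaves the sinus schedule intact).
#' @param comp_pause_factor prematurity compensation: the sinus beat resumes
#'   at `comp_pause_factor * NN` after the last pre-ectopic sinus beat
#'   (default 2.0 = fully compensatory for a single PVB).
#' @param run_len_probs probability vector over run lengths 1, 2, 3, ...
#'   (default `c(1)`: isolated PVBs only).
#' @param bigeminy emit one sustained bigeminal stretch? (default FALSE)
#' @param bigeminy_n_pairs pairs in that stretch (default 6).
#' @param r_on_t force at least one event to land on the preceding T wave?
#' @param morph_ids pool of morphology ids assigned to V beats (default 1:
#'   monomorphic; give >= 2 ids for polymorphic ectopy).
#' @return list of class `ectopy_spec`.
#' @export
ectopy_spec <- function(rate_per_hr = 10, coupling_frac = 0.6,
                        comp_pause_factor = 2.0, run_len_probs = c(1),
                        bigeminy = FALSE, bigeminy_n_pairs = 6,
                        r_on_t = FALSE, morph_ids = 1L) {
  stopifnot(rate_per_hr >= 0, coupling_frac > 0, coupling_frac < 1,
            comp_pause_factor > 1, all(run_len_probs >= 0),
            sum(run_len_probs) > 0)
  structure(
    list(rate_per_hr = rate_per_hr, coupling_frac = coupling_frac,
         comp_pause_factor = comp_pause_factor,
         run_len_probs = run_len_probs / sum(run_len_probs),
         bigeminy = bigeminy, bigeminy_n_pairs = bigeminy_n_pairs,
         r_on_t = r_on_t, morph_ids = as.integer(morph_ids)),
    class = "ectopy_spec"
  )
}

# Instantaneous heart-period signal m(t), ms, t in seconds.
heart_period_signal <- function(spec, t_s) {
  m <- rep(spec$base_rr_ms, length(t_s))
  mods <- spec$modulators
  for (i in seq_len(nrow(mods))) {
    m <- m + mods$amp_ms[i] * sin(2 * pi * mods$freq_hz[i] * t_s + mods$phase[i])
  }
  m
}

#' Generate a synthetic beat stream by integral pulse frequency modulation
#'
#' The instantaneous heart-period signal
#' `m(t) = base_rr + sum of modulators(t)` (ms) drives an IPFM emitter: a
#' beat fires each time the integral of `dt / m(t)` accrues one unit, so
#' modulator frequencies are defined in real time (Hz) exactly as the band
#' analysis assumes. Fiducials follow the spec's PR/QT rate laws using each
#' beat's own preceding RR; all labels are `N` (use [inject_ectopy()] to add
#' ventricular events). Output is deterministic given the spec (seed
#' included).
#'
#' @param spec a [synthetic_spec()].
#' @param meta extra metadata merged into the result's `meta`.
#' @return a validated `beat_series` (ectopy applied when `spec$ectopy` is
#'   set; the ground-truth event log is then in `attr(, "ectopy_truth")`).
#' @export
gen_beats <- function(spec, meta = list()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  T_s <- spec$duration_min * 60
  dt <- 0.05                       # integration step, s
  tg <- seq(0, T_s, by = dt)
  m <- heart_period_signal(spec, tg)
  if (any(m <= 0)) stop("modulation too deep: m(t) <= 0")
  # cumulative trapezoid of dt/m(t), in beats (m is in ms, dt in s)
  rate <- 1000 / m                 # beats per second
  acc <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * dt))
  n_beats_total <- floor(acc[length(acc)])
  if (n_beats_total < 2) stop("recording too short for its base RR")
  ks <- seq_len(n_beats_total)
  j <- pmin(findInterval(ks, acc), length(acc) - 1L)
  # linear interpolation of the crossing time inside grid cell j
  frac <- (ks - acc[j]) / (acc[j + 1] - acc[j])
  t_beat_s <- tg[j] + frac * dt
  t_r <- t_beat_s * 1000

  series <- with_local_seed(spec$seed, {
    n <- length(t_r)
    rr <- c(spec$base_rr_ms, diff(t_r))
    df <- data.frame(t_r = t_r, label = "N", morph_id = 0,
                     p_on = NA_real_, qrs_on = NA_real_, qrs_off = NA_real_,
                     t_end = NA_real_, fqrs = NA)
    if (spec$fiducials) {
      pr <- spec$pr0 + spec$pr_slope * rr + stats::rnorm(n, 0, spec$pr_noise_sd)
      qt <- spec$qt0 + spec$qt_slope_ms_per_s * (rr / 1000 - 1) +
        stats::rnorm(n, 0, spec$qt_noise_sd)
      w <- spec$qrs_half_width_ms
      df$qrs_on <- t_r - w
      df$qrs_off <- t_r + w
      df$p_on <- df$qrs_on - pr
      df$t_end <- df$qrs_on + qt
    }
    meta_full <- utils::modifyList(
      list(duration_ms = T_s * 1000, fs_hz = 500,
           synthetic_seed = spec$seed), meta)
    bs <- beat_series(df, meta_full)
    if (!is.null(spec$ectopy)) bs <- inject_ectopy(bs, spec$ectopy,
                                                   seed = spec$seed + 1L)
    bs
  })
  series
}

#' Inject premature ventricular beats into an all-normal series
#'
#' Selected sinus beats are replaced by premature ventricular events: the
#' first beat of an event fires at `coupling_frac` of the local NN after the
#' preceding sinus beat, run beats follow at the same coupling spacing, and
#' the sinus rhythm resumes after a compensatory pause
#' (`comp_pause_factor * NN` after the last pre-ectopic sinus beat for an
#' isolated PVB — 2.0 means full compensation, i.e. the underlying sinus
#' clock is untouched). Event sites are placed uniformly at random but
#' non-overlapping. With `r_on_t`, the first event's coupling is shortened
#' so its R wave falls before the preceding beat's T end. With `bigeminy`,
#' one sustained stretch of alternating N/V pairs is written at the first
#' event site.
#'
#' @param series an all-normal `beat_series`.
#' @param espec an [ectopy_spec()].
#' @param seed RNG seed for site/run-length draws.
#' @return the modified `beat_series`; `attr(, "ectopy_truth")` holds a
#'   data.frame of planted events (`time_ms`, `run_len`, `type`).
#' @export
inject_ectopy <- function(series, espec, seed = 1) {
  stopifnot(inherits(espec, "ectopy_spec"))
  b <- series$beats
  if (any(b$label != "N")) stop("inject_ectopy expects an all-normal series")
  n <- nrow(b)
  dur_hr <- series$meta$duration_ms / 3600000
  n_events <- round(espec$rate_per_hr * dur_hr)
  with_local_seed(seed, {
    run_lens <- if (n_events > 0)
      sample.int(length(espec$run_len_probs), n_events, replace = TRUE,
                 prob = espec$run_len_probs) else integer(0)
    # candidate anchor = index of the sinus beat the event replaces; keep a
    # margin of max run length + 2 beats between events and from the edges
    margin <- max(c(run_lens, 1)) + 2L
    need <- n_events * margin + if (espec$bigeminy) 2L * espec$bigeminy_n_pairs + 4L else 0L
    if (need >= n - 4L) stop("ectopy rate too high to place without overlap")
    # stratified placement: one anchor per chosen slot of width `margin`
    # guarantees non-overlap without rejection sampling
    slot_starts <- seq(3L, n - margin, by = margin)
    if (n_events > length(slot_starts)) {
      stop("ectopy rate too high to place without overlap")
    }
    anchors <- sort(sample(slot_starts, n_events))
    events <- data.frame(time_ms = numeric(0), run_len = integer(0),
                         type = character(0), stringsAsFactors = FALSE)
    drop_idx <- integer(0)
    new_rows <- list()
    for (k in seq_along(anchors)) {
      i <- anchors[k]
      L <- run_lens[k]
      prev <- i - 1L
      local_nn <- b$t_r[i] - b$t_r[prev]
      coupling <- espec$coupling_frac * local_nn
      if (espec$r_on_t && k == 1L) {
        ref_tend <- b$t_end[prev]
        target <- if (!is.na(ref_tend)) 0.9 * (ref_tend - b$t_r[prev])
                  else 0.3 * local_nn
        coupling <- min(coupling, target)
      }
      v_times <- b$t_r[prev] + coupling * seq_len(L)
      resume <- b$t_r[prev] + espec$comp_pause_factor * local_nn +
        (L - 1L) * coupling
      # drop sinus beats from the anchor up to the resume time
      j <- i
      while (j <= n && b$t_r[j] < resume - 1e-9) {
        drop_idx <- c(drop_idx, j)
        j <- j + 1L
      }
      if (max(v_times) >= resume || (j <= n && max(v_times) >= b$t_r[j])) {
        stop("ectopy rate too high to place without overlap")
      }
      morph <- sample(espec$morph_ids, 1)
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        t_r = v_times, label = "V", morph_id = morph,
        p_on = NA_real_, qrs_on = NA_real_, qrs_off = NA_real_,
        t_end = NA_real_, fqrs = NA)
      events <- rbind(events, data.frame(
        time_ms = v_times[1], run_len = L,
        type = if (espec$r_on_t && k == 1L) "r_on_t" else
          c("isolated", "doublet", "triplet")[min(L, 3)],
        stringsAsFactors = FALSE))
      events$type[nrow(events)] <- if (espec$r_on_t && k == 1L) "r_on_t"
        else if (L >= 4) "salvo" else c("isolated", "doublet", "triplet")[L]
    }
    if (espec$bigeminy) {
      # convert every second sinus beat of a clear stretch into a coupled PVB
      free <- setdiff(seq(3L, n - 2L), c(drop_idx, anchors))
      start <- free[which(diff(free, lag = 2L * espec$bigeminy_n_pairs) ==
                            2L * espec$bigeminy_n_pairs)[1]]
      if (is.na(start)) stop("no room for bigeminal stretch")
      for (q in seq_len(espec$bigeminy_n_pairs)) {
        i <- start + 2L * (q - 1L) + 1L
        local_nn <- b$t_r[i] - b$t_r[i - 1L]
        new_rows[[length(new_rows) + 1L]] <- data.frame(
          t_r = b$t_r[i - 1L] + espec$coupling_frac * local_nn, label = "V",
          morph_id = espec$morph_ids[1],
          p_on = NA_real_, qrs_on = NA_real_, qrs_off = NA_real_,
          t_end = NA_real_, fqrs = NA)
        drop_idx <- c(drop_idx, i)
      }
      events <- rbind(events, data.frame(
        time_ms = b$t_r[start], run_len = 1L, type = "bigeminy"))
    }
    keep <- b[setdiff(seq_len(n), drop_idx), ]
    allb <- rbind(keep, do.call(rbind, new_rows))
    allb <- allb[order(allb$t_r), ]
    out <- beat_series(allb, series$meta)
    attr(out, "ectopy_truth") <- events
    out
  })
}

#' Specification of a synthetic longitudinal cohort
#'
#' States the cohort-level world: group sizes, timepoints, an age law for
#' the base heart period (linear interpolation through resting heart rates
#' typical of growing dogs: about 133 bpm at 2 months falling to 68 bpm at
#' 24 months), group effects (a heart-rate offset, a multiplicative VLF
#' suppression, a QTc drift and ectopy escalation with age in the affected
#' group), per-subject random effects, and the outcome law
#' `lvfs_24m = alpha + beta * VLF_true(4 months) + noise`.
#'
#' @param n_per_group named vector `c(GRMD = , healthy = )` (default 8/8).
#' @param timepoints ages in months (default `c(2, 4, 6, 12, 24)`).
#' @param duration_min recording length per timepoint (default 720; tests
#'   and quick studies scale this down).
#' @param hr_age_bpm reference heart rate by age: data.frame `age_months,
#'   hr_bpm` interpolated linearly (constant beyond the range).
#' @param delta_hr_bpm additive GRMD heart-rate excess (default 20).
#' @param vlf_scale_grmd multiplicative VLF-amplitude factor for GRMD
#'   (default 0.6, i.e. VLF power scaled by 0.36).
#' @param qtc_drift_ms_per_mo GRMD QTc (qt0) drift per month (default 0.7).
#' @param ectopy_base_per_hr,ectopy_slope_per_mo GRMD ectopy rate
#'   `max(0, base + slope * (age - 4))` per hour (defaults 0 and 1.5;
#'   healthy dogs stay ectopy-free).
#' @param vlf_amp_range_ms per-subject VLF modulator amplitude, drawn
#'   uniformly in this range (default `c(20, 80)` — a wide between-subject
#'   spread comparable to the several-fold VLF differences seen between
#'   young dogs).
#' @param subj_hr_sd_bpm per-subject random heart-rate offset SD (default 3).
#' @param lvfs_alpha,lvfs_beta,lvfs_noise_sd outcome law (defaults 20,
#'   0.02 %/ms^2, 0.5 % — the planted deterministic span dominates the noise).
#' @param rsa_amp_ms,lf_amp_ms fixed modulator amplitudes (defaults 90, 55).
#' @param vlf_freq_hz,lf_freq_hz,rsa_freq_hz modulator frequencies
#'   (defaults 0.02, 0.08, 0.25 Hz).
#' @param seed integer seed (default 1).
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(GRMD = 8, healthy = 8),
                        timepoints = c(2, 4, 6, 12, 24),
                        duration_min = 720,
                        hr_age_bpm = data.frame(
                          age_months = c(2, 6, 12, 24),
                          hr_bpm = c(133, 106, 79, 68)),
                        delta_hr_bpm = 20,
                        vlf_scale_grmd = 0.6,
                        qtc_drift_ms_per_mo = 0.7,
                        ectopy_base_per_hr = 0,
                        ectopy_slope_per_mo = 1.5,
                        vlf_amp_range_ms = c(20, 80),
                        subj_hr_sd_bpm = 3,
                        lvfs_alpha = 20, lvfs_beta = 0.02, lvfs_noise_sd = 0.5,
                        rsa_amp_ms = 90, lf_amp_ms = 55,
                        vlf_freq_hz = 0.02, lf_freq_hz = 0.08,
                        rsa_freq_hz = 0.25,
                        seed = 1) {
  stopifnot(all(n_per_group >= 0), all(c("GRMD", "healthy") %in% names(n_per_group)),
            subj_hr_sd_bpm >= 0, lvfs_noise_sd >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws per-subject random effects, builds one [synthetic_spec()] per
#' subject x timepoint from the cohort's age and group laws, generates the
#' beat streams, and assembles the manifest and a ground-truth table
#' recording every planted parameter (true VLF power, base RR, ectopy rate,
#' outcome). With `out_dir` the beat streams, `manifest.csv` and `truth.csv`
#' are written in the package's CSV dialects; otherwise everything is
#' returned in memory.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory, or `NULL` for in-memory results.
#' @return list of class `synthetic_cohort`: `manifest` (data.frame
#'   `subject, group, age_months, recording_path, lvfs_24m, ctni, ntprobnp`),
#'   `truth` (per subject x age planted parameters), `series` (named list of
#'   `beat_series`, `NULL`-free only when `out_dir` is `NULL`).
#' @export
gen_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_local_seed(spec$seed, {
    subjects <- data.frame(
      subject = character(0), group = character(0), stringsAsFactors = FALSE)
    for (g in names(spec$n_per_group)) {
      ng <- spec$n_per_group[[g]]
      if (ng > 0) {
        subjects <- rbind(subjects, data.frame(
          subject = sprintf("%s%02d", toupper(substr(g, 1, 1)), seq_len(ng)),
          group = g, stringsAsFactors = FALSE))
      }
    }
    ns <- nrow(subjects)
    subjects$hr_re <- stats::rnorm(ns, 0, spec$subj_hr_sd_bpm)
    subjects$vlf_amp <- stats::runif(ns, spec$vlf_amp_range_ms[1],
                                     spec$vlf_amp_range_ms[2])
    subjects$seed <- spec$seed + seq_len(ns) * 1000L

    truth <- list()
    series <- list()
    manifest <- list()
    for (si in seq_len(ns)) {
      s <- subjects[si, ]
      grmd <- s$group == "GRMD"
      for (a in spec$timepoints) {
        hr_ref <- stats::approx(spec$hr_age_bpm$age_months,
                                spec$hr_age_bpm$hr_bpm, xout = a,
                                rule = 2)$y
        hr <- hr_ref + s$hr_re + if (grmd) spec$delta_hr_bpm else 0
        base_rr <- 60000 / hr
        # scale oscillation amplitudes with the base period so young
        # fast-heart traces carry proportionally less absolute variability
        amp_scale <- base_rr / 880
        vlf_amp <- s$vlf_amp * amp_scale * if (grmd) spec$vlf_scale_grmd else 1
        qt0 <- 230 + if (grmd) spec$qtc_drift_ms_per_mo * a else 0
        erate <- if (grmd) max(0, spec$ectopy_base_per_hr +
                                 spec$ectopy_slope_per_mo * (a - 4)) else 0
        sp <- synthetic_spec(
          duration_min = spec$duration_min, base_rr_ms = base_rr,
          modulators = data.frame(
            freq_hz = c(spec$vlf_freq_hz, spec$lf_freq_hz),
            amp_ms = c(vlf_amp, spec$lf_amp_ms * amp_scale),
            phase = stats::runif(2, 0, 2 * pi)),
          rsa_amp_ms = spec$rsa_amp_ms * amp_scale,
          rsa_freq_hz = spec$rsa_freq_hz,
          ectopy = if (erate > 0) ectopy_spec(rate_per_hr = erate) else NULL,
          qt0 = qt0,
          seed = s$seed + match(a, spec$timepoints))
        rec_id <- sprintf("%s_m%02d", s$subject, a)
        bs <- gen_beats(sp, meta = list(
          recording_id = rec_id, subject_id = s$subject, group = s$group,
          age_months = a))
        series[[paste0(rec_id, ".csv")]] <- bs
        truth[[rec_id]] <- data.frame(
          subject = s$subject, group = s$group, age_months = a,
          base_rr_ms = base_rr, hr_bpm = hr,
          vlf_amp_ms = vlf_amp, vlf_power_ms2 = vlf_amp^2 / 2,
          qt0_ms = qt0, ectopy_per_hr = erate, seed = sp$seed,
          stringsAsFactors = FALSE)
        manifest[[rec_id]] <- data.frame(
          subject = s$subject, group = s$group, age_months = a,
          recording_path = paste0(rec_id, ".csv"), stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth)
    manifest <- do.call(rbind, manifest)
    rownames(truth) <- rownames(manifest) <- NULL

    # outcome law: lvfs_24m from the subject's planted VLF power at 4 months
    ref_age <- if (4 %in% spec$timepoints) 4 else spec$timepoints[1]
    lvfs <- stats::setNames(rep(NA_real_, ns), subjects$subject)
    for (si in seq_len(ns)) {
      tv <- truth$vlf_power_ms2[truth$subject == subjects$subject[si] &
                                  truth$age_months == ref_age]
      lvfs[si] <- spec$lvfs_alpha + spec$lvfs_beta * tv +
        stats::rnorm(1, 0, spec$lvfs_noise_sd)
    }
    manifest$lvfs_24m <- lvfs[manifest$subject]
    manifest$ctni <- NA_real_
    manifest$ntprobnp <- NA_real_
    truth$lvfs_24m <- lvfs[truth$subject]

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (fn in names(series)) {
        write_beats(series[[fn]], file.path(out_dir, fn))
      }
      utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                       row.names = FALSE)
      utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    }
    structure(list(manifest = manifest, truth = truth, series = series,
                   spec = spec),
              class = "synthetic_cohort")
  })
}
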