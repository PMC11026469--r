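# In-code fixtures shared across the suite. No files: everything is built
# programmatically.

# Beat series with equal spacing and given labels.
bs_labels <- function(labels, spacing = 1000, t0 = 0, morph_id = 0, ...) {
  n <- length(labels)
  beat_series(
    data.frame(t_r = t0 + spacing * (seq_len(n) - 1), label = labels,
               morph_id = morph_id),
    meta = list(...)
  )
}

# NN series built directly from interval values; contiguous by construction
# unless extra time gaps are inserted after the 1-based indices in gap_after.
nn_direct <- function(rr, gap_after = integer(0), gap_ms = 10000,
                      duration_ms = NULL) {
  start <- cumsum(c(0, rr[-length(rr)]))
  if (length(gap_after)) {
    for (g in sort(gap_after)) {
      idx <- (g + 1):length(rr)
      start[idx] <- start[idx] + gap_ms
    }
  }
  if (is.null(duration_ms)) duration_ms <- start[length(start)] + rr[length(rr)]
  structure(
    list(start_ms = start, rr_ms = as.numeric(rr), n_excluded = 0L,
         n_guard_excluded = 0L, meta = list(duration_ms = duration_ms)),
    class = "nn_series"
  )
}

# Tachogram-as-NN fixture: interval values follow rr_fun(t) evaluated at each
# interval's start time, intervals laid end to end (so the NN series samples
# the target tachogram at roughly the beat rate, like a real recording).
nn_tachogram <- function(duration_s, rr_fun, rr0 = NULL) {
  t <- 0
  start <- numeric(0)
  rr <- numeric(0)
  while (t < duration_s * 1000) {
    v <- rr_fun(t / 1000)
    start <- c(start, t)
    rr <- c(rr, v)
    t <- t + v
  }
  structure(
    list(start_ms = start, rr_ms = rr, n_excluded = 0L,
         n_guard_excluded = 0L, meta = list(duration_ms = duration_s * 1000)),
    class = "nn_series"
  )
}

# ---- independent brute-force oracles -------------------------------------

bf_pnn <- function(rr, thr) {
  cnt <- 0; tot <- 0
  for (i in seq_len(length(rr) - 1)) {
    tot <- tot + 1
    if (abs(rr[i + 1] - rr[i]) > thr) cnt <- cnt + 1
  }
  100 * cnt / tot
}

bf_runs <- function(labels) {
  lens <- integer(0)
  cur <- 0L
  for (l in c(labels, "N")) {
    if (l == "V") cur <- cur + 1L
    else {
      if (cur > 0L) lens <- c(lens, cur)
      cur <- 0L
    }
  }
  lens
}

bf_bigeminy <- function(labels, k = 4) {
  n <- length(labels)
  for (s in seq_len(max(0, n - 2 * k + 1))) {
    seg <- labels[s:(s + 2 * k - 1)]
    if (all(seg == rep(c("N", "V"), k))) return(TRUE)
  }
  FALSE
}

bf_triangular <- function(rr) {
  bw <- 1000 / 128
  bins <- floor(rr / bw)
  length(rr) / max(table(bins))
}

# tie-averaged ranks by explicit counting
bf_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

bf_spearman <- function(x, y) {
  rx <- bf_ranks(x); ry <- bf_ranks(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
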