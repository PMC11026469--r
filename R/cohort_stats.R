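#' Assemble a long-format cohort table
#'
#' One row per subject x age x variable. Wide per-recording summary rows
#' (as from [run_trace()] / [write_summary()]) are melted; outcome/covariate
#' columns from the manifest (e.g. `lvfs_24m`, `ctni`, `ntprobnp`) can be
#' appended as variables with the age they were measured at.
#'
#' @param summaries data.frame of per-recording rows containing at least
#'   `subject`, `group`, `age_months` plus numeric result columns.
#' @param covariates optional data.frame `subject, variable, age_months,
#'   value` (or a manifest-like data.frame with `subject`, `group` and
#'   covariate columns, taken as measured at `covariate_age`).
#' @param covariate_age age assigned to manifest covariate columns
#'   (default 24).
#' @return data.frame of class `cohort_table`: `subject`, `group`,
#'   `age_months`, `variable`, `value`.
#' @export
cohort_table <- function(summaries, covariates = NULL, covariate_age = 24) {
  stopifnot(all(c("subject", "group", "age_months") %in% names(summaries)))
  id_cols <- c("subject", "group", "age_months")
  val_cols <- setdiff(names(summaries)[vapply(summaries, is.numeric, TRUE)],
                      id_cols)
  long <- do.call(rbind, lapply(val_cols, function(v) {
    data.frame(subject = summaries$subject, group = summaries$group,
               age_months = summaries$age_months, variable = v,
               value = summaries[[v]], stringsAsFactors = FALSE)
  }))
  if (!is.null(covariates)) {
    if (all(c("variable", "value") %in% names(covariates))) {
      cv <- covariates
      if (is.null(cv$group)) cv$group <- NA_character_
      if (is.null(cv$age_months)) cv$age_months <- covariate_age
      long <- rbind(long, cv[, c("subject", "group", "age_months",
                                 "variable", "value")])
    } else {
      cov_cols <- setdiff(names(covariates)[vapply(covariates, is.numeric, TRUE)],
                          c("age_months"))
      for (v in cov_cols) {
        long <- rbind(long, data.frame(
          subject = covariates$subject,
          group = if (is.null(covariates$group)) NA_character_ else covariates$group,
          age_months = covariate_age, variable = v,
          value = covariates[[v]], stringsAsFactors = FALSE))
      }
    }
  }
  long <- long[!is.na(long$value), ]
  key <- paste(long$subject, long$age_months, long$variable)
  if (anyDuplicated(key)) stop("duplicate subject x age x variable value")
  class(long) <- c("cohort_table", "data.frame")
  long
}

#' Per-timepoint group contrast with a pooled-variance LSD test
#'
#' Fisher-LSD-style contrast of the two groups at each shared age for one
#' variable: the error mean square is pooled over all group x age cells of
#' that variable (cells with n < 2 contribute no variance), and at each age
#' `t = (m1 - m2) / sqrt(MSE * (1/n1 + 1/n2))` with the pooled error
#' degrees of freedom. This is the classical LSD construction; the full
#' mixed-model omnibus machinery is deliberately not reproduced. A
#' within-group age-effect p (one-way ANOVA across ages) is reported per
#' group for orientation.
#'
#' @param table a `cohort_table`.
#' @param variable variable name to contrast.
#' @return list of class `group_comparison`: `variable`, `per_age`
#'   data.frame (`age_months`, per-group mean/sd/n, `t`, `p`), `mse`,
#'   `df_error`, `age_effect` data.frame (`group`, `p`).
#' @export
lsd_compare <- function(table, variable) {
  d <- table[table$variable == variable, ]
  if (!nrow(d)) stop("variable not present: ", variable)
  groups <- sort(unique(d$group))
  if (length(groups) < 2) stop("no contrast possible: variable present in one group only")
  # pooled within-cell error across all group x age cells
  cell <- interaction(d$group, d$age_months, drop = TRUE)
  ss <- tapply(d$value, cell, function(v) sum((v - mean(v))^2))
  df <- tapply(d$value, cell, function(v) length(v) - 1L)
  df_error <- sum(unlist(df))
  if (df_error == 0) stop("pooled error degrees of freedom is zero")
  mse <- sum(unlist(ss)) / df_error
  ages <- sort(unique(d$age_months))
  rows <- lapply(ages, function(a) {
    v1 <- d$value[d$group == groups[1] & d$age_months == a]
    v2 <- d$value[d$group == groups[2] & d$age_months == a]
    if (!length(v1) || !length(v2)) return(NULL)
    se <- sqrt(mse * (1 / length(v1) + 1 / length(v2)))
    tt <- if (se > 0) (mean(v1) - mean(v2)) / se else 0
    data.frame(age_months = a,
               mean_1 = mean(v1), sd_1 = stats::sd(v1), n_1 = length(v1),
               mean_2 = mean(v2), sd_2 = stats::sd(v2), n_2 = length(v2),
               t = tt, p = 2 * stats::pt(-abs(tt), df_error))
  })
  per_age <- do.call(rbind, rows)
  if (is.null(per_age)) stop("no contrast possible: no shared timepoint")
  age_eff <- do.call(rbind, lapply(groups, function(g) {
    dg <- d[d$group == g, ]
    p <- if (length(unique(dg$age_months)) > 1 && nrow(dg) > length(unique(dg$age_months))) {
      stats::anova(stats::lm(value ~ factor(age_months), data = dg))$`Pr(>F)`[1]
    } else NA_real_
    data.frame(group = g, p = p, stringsAsFactors = FALSE)
  }))
  structure(
    list(variable = variable, groups = groups, per_age = per_age,
         mse = mse, df_error = df_error, age_effect = age_eff),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s vs %s (pooled MSE %.4g, df %d)\n",
              x$variable, x$groups[1], x$groups[2], x$mse, x$df_error))
  print(x$per_age, row.names = FALSE, digits = 4)
  invisible(x)
}

# tie-averaged ranks without relying on rank()'s default being audited
avg_ranks <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation with exact small-sample p
#'
#' rho is the Pearson correlation of tie-averaged ranks. For n <= 9 the
#' two-sided p-value is computed by exact enumeration of all permutations of
#' one margin (valid under ties); for larger n the usual t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` is used.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list `rho`, `p`, `n`, `method` (`"exact"` or `"t-approx"`).
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  rx <- avg_ranks(x); ry <- avg_ranks(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) stop("zero rank variance")
  rho <- stats::cov(rx, ry) / (pop_sd_n(rx) * pop_sd_n(ry))
  if (n <= 9) {
    perms <- permutations_of(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- (n - 1) * pop_sd_n(rx) * pop_sd_n(ry)
    rhos <- as.vector(matrix(ryc[perms], nrow(perms)) %*% rxc) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), n - 2)
    }
    method <- "t-approx"
  }
  list(rho = rho, p = p, n = n, method = method)
}

# sample-convention SD helper used for rank correlation (cov is n-1; keep
# the same convention in the denominator so rho is scale-consistent)
pop_sd_n <- function(x) stats::sd(x)

permutations_of <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Screen early indices against a late outcome
#'
#' For each requested predictor (variable at a given age), the Spearman
#' correlation with the outcome variable (one value per subject, e.g.
#' left-ventricular fractional shortening at 24 months) is computed over the
#' subjects having both values. No multiple-testing correction is applied to
#' the reported p (matching the unadjusted screening procedure this mirrors)
#' but a Benjamini-Hochberg adjusted column is emitted alongside.
#'
#' @param table a `cohort_table`.
#' @param predictors data.frame with columns `variable` and `age_months`.
#' @param outcome outcome variable name (default `"lvfs_24m"`).
#' @param outcome_age age at which the outcome is stored (default 24).
#' @param group restrict to one group (default `"GRMD"`; `NULL` = all).
#' @return data.frame of class `correlation_screen`, sorted by decreasing
#'   `|rho|`: `variable`, `age_months`, `outcome`, `rho`, `n`, `p`, `p_bh`,
#'   `skipped_reason` (rows with n < 3 are kept with NA rho and a reason).
#' @export
early_late_screen <- function(table, predictors, outcome = "lvfs_24m",
                              outcome_age = 24, group = "GRMD") {
  if (!is.null(group)) {
    keep_subj <- unique(table$subject[table$group %in% c(group, NA)])
    table <- table[table$subject %in% keep_subj, ]
  }
  out <- table[table$variable == outcome & table$age_months == outcome_age, ]
  if (!nrow(out)) stop("outcome not present: ", outcome)
  out_val <- stats::setNames(out$value, out$subject)
  rows <- lapply(seq_len(nrow(predictors)), function(i) {
    v <- predictors$variable[i]; a <- predictors$age_months[i]
    pr <- table[table$variable == v & table$age_months == a, ]
    subj <- intersect(pr$subject, names(out_val))
    base <- data.frame(variable = v, age_months = a, outcome = outcome,
                       rho = NA_real_, n = length(subj), p = NA_real_,
                       skipped_reason = "", stringsAsFactors = FALSE)
    if (length(subj) < 3) {
      base$skipped_reason <- "fewer than 3 complete pairs"
      return(base)
    }
    x <- stats::setNames(pr$value, pr$subject)[subj]
    sc <- tryCatch(spearman_cor(x, out_val[subj]), error = function(e) NULL)
    if (is.null(sc)) {
      base$skipped_reason <- "zero rank variance"
      return(base)
    }
    base$rho <- sc$rho; base$p <- sc$p; base$n <- sc$n
    base
  })
  res <- do.call(rbind, rows)
  res$p_bh <- NA_real_
  ok <- !is.na(res$p)
  res$p_bh[ok] <- stats::p.adjust(res$p[ok], method = "BH")
  res <- res[order(-abs(res$rho), na.last = TRUE), ]
  rownames(res) <- NULL
  class(res) <- c("correlation_screen", "data.frame")
  res
}
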