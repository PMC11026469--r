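mk_table <- function(df) {
  class(df) <- c("cohort_table", "data.frame")
  df
}

test_that("lsd_compare reduces to the pooled two-sample t at one timepoint", {
  set.seed(11)
  v1 <- rnorm(8, 10, 2); v2 <- rnorm(8, 12, 2)
  tab <- mk_table(data.frame(
    subject = sprintf("s%02d", 1:16),
    group = rep(c("GRMD", "healthy"), each = 8),
    age_months = 6, variable = "x", value = c(v1, v2)))
  cmp <- lsd_compare(tab, "x")
  tt <- stats::t.test(v1, v2, var.equal = TRUE)
  expect_equal(cmp$per_age$p, tt$p.value, tolerance = 1e-12)
  expect_equal(abs(cmp$per_age$t), abs(unname(tt$statistic)), tolerance = 1e-12)
})

test_that("lsd_compare handles identical groups and degenerate layouts", {
  tab <- mk_table(data.frame(
    subject = sprintf("s%d", 1:8), group = rep(c("GRMD", "healthy"), each = 4),
    age_months = 2, variable = "x", value = rep(5, 8)))
  cmp <- lsd_compare(tab, "x")
  expect_equal(cmp$per_age$t, 0)
  expect_equal(cmp$per_age$p, 1)
  one <- mk_table(data.frame(subject = c("a", "b"), group = "GRMD",
                             age_months = 2, variable = "x", value = c(1, 2)))
  expect_error(lsd_compare(one, "x"), "one group")
  expect_error(lsd_compare(tab, "nope"), "not present")
})

test_that("lsd_compare pools variance across group x age cells", {
  set.seed(2)
  d <- expand.grid(subject = 1:6, group = c("GRMD", "healthy"),
                   age_months = c(2, 6, 12))
  d$subject <- paste0(d$group, d$subject)
  d$variable <- "x"
  d$value <- rnorm(nrow(d), ifelse(d$group == "GRMD", 20, 10), 3)
  cmp <- lsd_compare(mk_table(d), "x")
  # pooled df = sum over 6 cells of (6 - 1)
  expect_equal(cmp$df_error, 30)
  expect_equal(nrow(cmp$per_age), 3)
  expect_true(all(cmp$per_age$p < 0.01))
  expect_true(all(!is.na(cmp$age_effect$p)))
})

test_that("planted 3-SD group shift is detected at p < 0.01", {
  set.seed(99)
  hits <- 0
  for (i in 1:20) {
    d <- data.frame(
      subject = sprintf("s%02d", 1:16),
      group = rep(c("GRMD", "healthy"), each = 8),
      age_months = 6, variable = "x",
      value = c(rnorm(8, 13, 1), rnorm(8, 10, 1)))   # 3-SD shift
    p <- lsd_compare(mk_table(d), "x")$per_age$p
    if (p < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("spearman_cor matches brute-force rank formulas", {
  # monotone and antisymmetric
  expect_equal(spearman_cor(1:6, c(2, 4, 9, 11, 30, 31))$rho, 1)
  expect_equal(spearman_cor(1:6, -c(2, 4, 9, 11, 30, 31))$rho, -1)
  # swapped neighbour pair, n = 8: classical 1 - 6*sum(d^2)/(n(n^2-1))
  x <- 1:8; y <- c(1, 2, 4, 3, 5, 6, 7, 8)
  sc <- spearman_cor(x, y)
  expect_equal(sc$rho, 1 - 6 * sum((x - y)^2) / (8 * (64 - 1)), tolerance = 1e-12)
  expect_equal(sc$method, "exact")
  set.seed(41)
  for (i in 1:40) {
    n <- sample(3:15, 1)
    xx <- sample(1:6, n, replace = TRUE)   # ties likely
    yy <- sample(1:6, n, replace = TRUE)
    if (length(unique(xx)) < 2 || length(unique(yy)) < 2) next
    expect_equal(spearman_cor(xx, yy)$rho, bf_spearman(xx, yy), tolerance = 1e-12)
    expect_equal(spearman_cor(xx, yy)$rho,
                 suppressWarnings(stats::cor(xx, yy, method = "spearman")),
                 tolerance = 1e-12)
  }
  expect_error(spearman_cor(c(1, 1, 1), c(1, 2, 3)), "zero rank variance")
  expect_error(spearman_cor(1:2, 2:3), "at least 3")
})

test_that("exact permutation p agrees with cor.test on tie-free data", {
  set.seed(43)
  for (i in 1:5) {
    x <- sample(1:8); y <- sample(1:8)
    sc <- spearman_cor(x, y)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(sc$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(sc$p, ct$p.value, tolerance = 1e-9)
  }
})

test_that("early_late_screen recovers planted relations and is order invariant", {
  set.seed(55)
  subj <- sprintf("g%02d", 1:8)
  vlf <- runif(8, 200, 3000)
  lvfs <- 20 + 0.004 * vlf + rnorm(8, 0, 0.3)
  tab <- mk_table(rbind(
    data.frame(subject = subj, group = "GRMD", age_months = 4,
               variable = "vlf_ms2", value = vlf),
    data.frame(subject = subj, group = "GRMD", age_months = 4,
               variable = "hr_bpm", value = 150 - 0.01 * vlf + rnorm(8, 0, 1)),
    data.frame(subject = subj, group = "GRMD", age_months = 24,
               variable = "lvfs_24m", value = lvfs)))
  preds <- data.frame(variable = c("vlf_ms2", "hr_bpm"), age_months = 4)
  sc <- early_late_screen(tab, preds)
  expect_gt(sc$rho[sc$variable == "vlf_ms2"], 0.8)
  expect_lt(sc$rho[sc$variable == "hr_bpm"], 0)
  expect_true(all(c("p", "p_bh") %in% names(sc)))
  expect_true(all(diff(abs(sc$rho)) <= 0))     # sorted by |rho|
  # permutation invariance to subject ordering
  perm <- sample(nrow(tab))
  sc2 <- early_late_screen(tab[perm, ], preds)
  expect_equal(sc2$rho, sc$rho)
  expect_equal(sc2$p, sc$p)
  # shuffled outcome: small average |rho|
  rhos <- replicate(20, {
    t2 <- tab
    i <- t2$variable == "lvfs_24m"
    t2$value[i] <- sample(t2$value[i])
    early_late_screen(t2, preds[1, , drop = FALSE])$rho
  })
  expect_lt(mean(abs(rhos)), 0.5)
  # n < 3 rows are kept with a reason
  small <- tab[c(1:2, 17:18), ]
  sc3 <- early_late_screen(mk_table(small), preds[1, , drop = FALSE])
  expect_true(is.na(sc3$rho[1]))
  expect_match(sc3$skipped_reason[1], "fewer than 3")
})

test_that("cohort_table enforces one value per subject x age x variable", {
  s <- data.frame(subject = c("a", "a"), group = "GRMD", age_months = c(2, 2),
                  hr_bpm = c(100, 110))
  expect_error(cohort_table(s), "duplicate")
  s2 <- data.frame(subject = c("a", "b"), group = "GRMD", age_months = 2,
                   hr_bpm = c(100, 110), sdnn_ms = c(50, NA))
  tab <- cohort_table(s2)
  expect_equal(nrow(tab), 3)   # NA dropped, absent not zero-filled
})
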