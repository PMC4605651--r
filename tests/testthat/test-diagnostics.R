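# Cohort diagnostics: rejection classification, correlation CIs, rank
# tests, ROC, Wilson intervals, exponential trends.

test_that("rejection classification returns the full label set", {
  expect_equal(classify_rejection("0", 0.3), "none")
  expect_setequal(classify_rejection("2R", 2.5),
                  c("mod_severe_ACR", "elevated_cfdDNA"))
  expect_equal(classify_rejection(NA, 1.5), "elevated_cfdDNA")
  expect_equal(classify_rejection("1R", NA), "mild_ACR")
  expect_equal(classify_rejection("3R", 0.2), "mod_severe_ACR")
  expect_error(classify_rejection(NA, NA), "Unclassifiable")
  expect_error(classify_rejection("4X", 0.5), "invalid")
})

test_that("Fisher r-to-z interval matches the closed form and cor.test", {
  set.seed(42)
  n <- 100
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n, sd = sqrt(1 - 0.25))
  res <- pearson_with_fisher_ci(x, y)
  r <- cor(x, y)
  expect_equal(res$r, r, tolerance = 1e-12)
  expect_equal(res$lo, tanh(atanh(r) - qnorm(0.975) / sqrt(n - 3)),
               tolerance = 1e-12)
  expect_equal(res$hi, tanh(atanh(r) + qnorm(0.975) / sqrt(n - 3)),
               tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(unname(res$lo), unname(ct$conf.int[1]), tolerance = 1e-10)
  expect_equal(unname(res$hi), unname(ct$conf.int[2]), tolerance = 1e-10)
  expect_equal(res$p, ct$p.value, tolerance = 1e-10)
  # perfectly linear data: degenerate interval at r = 1
  res1 <- pearson_with_fisher_ci(1:10, 2 * (1:10) + 3)
  expect_equal(res1$r, 1)
  expect_equal(res1$lo, 1)
  expect_error(pearson_with_fisher_ci(rep(1, 5), 1:5), "variance")
  expect_error(pearson_with_fisher_ci(1:3, 3:1), "at least 4")
})

test_that("Fisher interval coverage is nominal under the null", {
  set.seed(7)
  n <- 10
  hits <- 0
  n_sim <- 1000
  for (i in seq_len(n_sim)) {
    res <- pearson_with_fisher_ci(rnorm(n), rnorm(n))
    if (res$lo <= 0 && res$hi >= 0) hits <- hits + 1
  }
  cover <- hits / n_sim
  se <- sqrt(0.95 * 0.05 / n_sim)
  expect_lt(abs(cover - 0.95), 3 * se)
})

test_that("Mann-Whitney exact branch equals permutation enumeration", {
  mw <- mann_whitney_one_sided(c(5, 6, 7), c(1, 2, 3))
  expect_equal(mw$U, 9)
  expect_equal(mw$p, 1 / choose(6, 3))
  expect_equal(mw$method, "exact")
  # identical multisets: p >= 0.5
  same <- mann_whitney_one_sided(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p, 0.5)
  # property: exact branch = full enumeration, with and without ties
  set.seed(5)
  for (i in 1:12) {
    na <- sample(2:8, 1)
    nb <- sample(2:8, 1)
    a <- sample(1:6, na, replace = TRUE) + i %% 2 * 0.5  # ties likely
    b <- sample(1:6, nb, replace = TRUE)
    got <- mann_whitney_one_sided(a, b)
    expect_equal(got$method, "exact")
    expect_equal(got$p, mw_enumeration_p(a, b), tolerance = 1e-12)
  }
  # tie-free case agrees with wilcox.test's exact one-sided p
  set.seed(8)
  a <- rnorm(7); b <- rnorm(6)
  got <- mann_whitney_one_sided(a, b)
  wt <- wilcox.test(a, b, alternative = "greater", exact = TRUE)
  expect_equal(got$p, wt$p.value, tolerance = 1e-12)
  expect_equal(got$U, unname(wt$statistic))
})

test_that("exact and approximate Mann-Whitney branches agree at n=15 vs 15", {
  set.seed(11)
  for (i in 1:5) {
    a <- rnorm(15, mean = 0.3)
    b <- rnorm(15)
    ex <- mann_whitney_one_sided(a, b, exact_limit = 400)
    ap <- mann_whitney_one_sided(a, b, exact_limit = 1)
    expect_equal(ex$method, "exact")
    expect_equal(ap$method, "normal_approx")
    expect_lt(abs(ex$p - ap$p), 0.01)
  }
})

test_that("c-statistic equals brute-force pairwise concordance", {
  # perfectly separated scores
  r <- roc_c_statistic(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1), n_boot = 50)
  expect_equal(r$auc, 1)
  # 12-point toy set with ties
  sc <- c(0.1, 0.2, 0.2, 0.3, 0.35, 0.4, 0.4, 0.5, 0.6, 0.6, 0.7, 0.9)
  lb <- c(0, 0, 1, 0, 0, 1, 0, 1, 0, 1, 1, 1)
  r2 <- roc_c_statistic(sc, lb, n_boot = 50)
  expect_equal(r2$auc, auc_bruteforce(sc, lb))
  # property: random instances up to 50 samples
  set.seed(13)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    lab <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)
    expect_equal(roc_c_statistic(s, lab, n_boot = 2)$auc,
                 auc_bruteforce(s, lab))
  }
  # null data: auc near 1/2
  set.seed(17)
  s <- runif(2000)
  lab <- rep(0:1, 1000)
  expect_lt(abs(roc_c_statistic(s, lab, n_boot = 2)$auc - 0.5), 0.04)
  expect_error(roc_c_statistic(1:4, c(1, 1, 1, 1), n_boot = 2), "classes")
})

test_that("c-statistic matches pROC and bootstrap CI brackets the estimate", {
  set.seed(19)
  s <- c(rnorm(30, 1), rnorm(40))
  lab <- rep(c(1, 0), c(30, 40))
  r <- roc_c_statistic(s, lab, n_boot = 400, seed = 3)
  ref <- suppressMessages(pROC::auc(pROC::roc(lab, s, direction = "<",
                                              quiet = TRUE)))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
  expect_lte(r$lo, r$auc)
  expect_gte(r$hi, r$auc)
  # ROC points: monotone from (0,0) to (1,1)
  pts <- r$roc_points
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_true(all(diff(pts$tpr) >= 0))
  expect_true(all(diff(pts$fpr) >= 0))
})

test_that("Wilson continuity-corrected interval matches its root oracle", {
  for (case in list(c(17, 20), c(1, 12), c(10, 130), c(5, 7), c(50, 61))) {
    got <- wilson_cc_interval(case[1], case[2])
    want <- wilson_cc_oracle(case[1], case[2])
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
  }
  expect_equal(unname(wilson_cc_interval(0, 10)[1]), 0)
  expect_equal(unname(wilson_cc_interval(10, 10)[2]), 1)
  # bounds contain k/n, lie in [0,1], and narrow with n at fixed k/n
  widths <- vapply(c(1, 2, 4, 8, 16), function(m) {
    ci <- wilson_cc_interval(3 * m, 10 * m)
    expect_true(ci[1] >= 0 && ci[2] <= 1)
    expect_true(ci[1] <= 0.3 && 0.3 <= ci[2])
    unname(diff(ci))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(wilson_cc_interval(5, 4), "not TRUE")
})

test_that("threshold metrics come from the 2x2 table with Wilson CIs", {
  # 5 of 7 positives called, 41 of 50 negatives correctly excluded
  scores <- c(runif(5, 0.5, 1), runif(2, 0, 0.4),   # positives
              runif(9, 0.5, 1), runif(41, 0, 0.4))  # negatives
  labels <- rep(c(1, 0), c(7, 50))
  m <- binary_metrics_at_threshold(scores, labels, threshold = 0.45)
  expect_equal(m$sensitivity$estimate, 5 / 7)
  expect_equal(round(100 * m$sensitivity$lo, 1), 30.3)
  expect_equal(round(100 * m$sensitivity$hi, 1), 94.9)
  expect_equal(m$specificity$estimate, 41 / 50)
  expect_equal(m$ppv$estimate, 5 / 14)
  expect_equal(m$npv$estimate, 41 / 43)
  # extreme thresholds
  lo <- binary_metrics_at_threshold(scores, labels, threshold = -1)
  expect_equal(lo$sensitivity$estimate, 1)
  expect_equal(lo$specificity$estimate, 0)
  expect_true(is.na(lo$npv$estimate))  # empty negative-call margin
  hi <- binary_metrics_at_threshold(scores, labels, threshold = 2)
  expect_equal(hi$sensitivity$estimate, 0)
  expect_equal(hi$specificity$estimate, 1)
})

test_that("exponential trend fits recover known dynamics", {
  t <- seq(0, 300, 30)
  y <- 0.03 * exp(0.005 * t)
  f <- fit_exponential_trend(t, y)
  expect_equal(f$a, 0.03, tolerance = 1e-8)
  expect_equal(f$b, 0.005, tolerance = 1e-8)
  # constant series
  f0 <- fit_exponential_trend(t, rep(0.02, length(t)))
  expect_equal(f0$a, 0.02, tolerance = 1e-10)
  expect_equal(f0$b, 0, tolerance = 1e-10)
  # noisy data: least-squares fit at least as good as a grid-search oracle
  set.seed(29)
  yn <- y * exp(rnorm(length(t), sd = 0.1))
  fn <- fit_exponential_trend(t, yn)
  grid_a <- seq(0.02, 0.05, length.out = 60)
  grid_b <- seq(0.002, 0.008, length.out = 60)
  rss <- outer(grid_a, grid_b, Vectorize(function(a, b)
    sum((yn - a * exp(b * t))^2)))
  best <- arrayInd(which.min(rss), dim(rss))
  expect_lte(fn$rss, min(rss) + 1e-12)
  expect_lt(abs(fn$a - grid_a[best[1]]), diff(grid_a[1:2]) * 1.5)
  expect_lt(abs(fn$b - grid_b[best[2]]), diff(grid_b[1:2]) * 1.5)
  expect_error(fit_exponential_trend(t, y - 0.03), "positive")
  expect_error(fit_exponential_trend(1:2, c(1, 2)), "3 points")
})
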