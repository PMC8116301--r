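test_that("IQR outlier rule matches the worked quartile examples", {
  expect_equal(flag_outliers_iqr(c(1, 2, 3, 4, 5)), rep(FALSE, 5))
  expect_equal(flag_outliers_iqr(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(flag_outliers_iqr(rep(3, 6)), rep(FALSE, 6))
  expect_warning(small <- flag_outliers_iqr(c(1, 100, 1000)), "fewer than 4")
  expect_equal(small, rep(FALSE, 3))
})

test_that("IQR flags agree with the brute-force quartile oracle", {
  set.seed(111)
  for (i in 1:120) {
    n <- sample(4:300, 1)
    x <- switch(sample(3, 1),
                rnorm(n),
                rexp(n),
                sample(1:10, n, replace = TRUE))
    expect_identical(flag_outliers_iqr(x), iqr_flags_oracle(x))
  }
})

test_that("exact Mann-Whitney equals the full labeling scan up to 6+6", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$p.value, 1 / 3)
  set.seed(121)
  for (n1 in 1:6) {
    for (n2 in n1:6) {
      x <- runif(n1 + n2)  # tie-free almost surely
      a <- x[seq_len(n1)]
      b <- x[-seq_len(n1)]
      got <- mann_whitney(a, b, mode = "exact")
      expect_equal(got$p.value, mw_scan_oracle(a, b), tolerance = 1e-12)
      expect_equal(got$statistic, u_pairwise(a, b))
    }
  }
})

test_that("identical groups give the central U and a p-value near 1", {
  a <- c(1, 2, 3, 4, 5)
  got <- mann_whitney(a, a)
  expect_equal(got$statistic, length(a)^2 / 2)
  expect_gte(got$p.value, 0.99)
})

test_that("normal approximation tracks the exact test and wilcox.test", {
  set.seed(131)
  x <- rnorm(8)
  y <- rnorm(8) + 0.5
  p_exact <- mann_whitney(x, y, mode = "exact")$p.value
  p_norm <- mann_whitney(x, y, mode = "normal")$p.value
  expect_lt(abs(p_exact - p_norm), 0.02)
  # independent reference implementation, with ties present
  xt <- sample(1:6, 30, replace = TRUE)
  yt <- sample(2:8, 40, replace = TRUE)
  ref <- suppressWarnings(stats::wilcox.test(xt, yt, correct = TRUE,
                                             exact = FALSE))
  got <- mann_whitney(xt, yt)
  expect_equal(got$method, "normal")
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Bonferroni adjusts, clamps, and is identity at m = 1", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.5, m = 10), 1)
  expect_equal(bonferroni(c(0.2, 0.7), m = 1), c(0.2, 0.7))
  expect_equal(bonferroni(c(0.01, 0.02)), p.adjust(c(0.01, 0.02),
                                                   "bonferroni"))
  expect_error(bonferroni(1.2), "\\[0, 1\\]")
})

test_that("ROC handles separation, degeneracy and the pairwise oracle", {
  sep <- roc_curve(c(1, 2, 3, 10, 11, 12),
                   c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
                   direction = "higher_indicates_case")
  expect_equal(sep$auc, 1)
  cp <- optimal_cutpoint(sep)
  expect_equal(cp$sensitivity, 1)
  expect_equal(cp$specificity, 1)
  expect_equal(cp$cutoff, 6.5)
  ident <- roc_curve(rep(1, 10), rep(c(TRUE, FALSE), 5),
                     direction = "higher_indicates_case")
  expect_equal(ident$auc, 0.5)
  mixed <- roc_curve(c(2, 3, 1, 2), c(TRUE, TRUE, FALSE, FALSE),
                     direction = "higher_indicates_case")
  expect_equal(mixed$auc, 0.875)
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("ROC point sequence is monotone from (0,0) to (1,1)", {
  set.seed(141)
  for (i in 1:20) {
    s <- sample(1:8, 30, replace = TRUE)
    l <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.3, 0.7))
    if (!any(l) || all(l)) next
    r <- roc_curve(s, l)
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[1], 0)
    expect_equal(tail(r$points$fpr, 1), 1)
    expect_equal(tail(r$points$tpr, 1), 1)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
  }
})

test_that("trapezoid AUC equals the tie-corrected U identity and pROC", {
  set.seed(151)
  for (i in 1:50) {
    n1 <- sample(2:20, 1)
    n2 <- sample(2:20, 1)
    case <- sample(1:6, n1, replace = TRUE)
    ctrl <- sample(1:6, n2, replace = TRUE)
    r <- roc_curve(c(case, ctrl), rep(c(TRUE, FALSE), c(n1, n2)),
                   direction = "higher_indicates_case")
    expect_equal(r$auc, u_pairwise(case, ctrl) / (n1 * n2),
                 tolerance = 1e-12)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(152)
    s <- rnorm(60)
    l <- rep(c(TRUE, FALSE), c(25, 35))
    s[l] <- s[l] + 1
    mine <- roc_curve(s, l, direction = "higher_indicates_case")
    ref <- pROC::roc(l, s, direction = "<", quiet = TRUE)
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  }
})

test_that("direction auto-detection is safe under score inversion", {
  set.seed(161)
  s <- rnorm(60)
  l <- rep(c(TRUE, FALSE), c(20, 40))
  s[l] <- s[l] - 1  # cases lower
  r1 <- roc_curve(s, l)
  r2 <- roc_curve(-s, l)
  expect_equal(r1$direction, "lower_indicates_case")
  expect_equal(r2$direction, "higher_indicates_case")
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
  c1 <- optimal_cutpoint(r1)
  c2 <- optimal_cutpoint(r2)
  expect_equal(c1$sensitivity, c2$sensitivity)
  expect_equal(c1$specificity, c2$specificity)
  expect_equal(c1$cutoff, -c2$cutoff, tolerance = 1e-12)
})

test_that("Youden cutpoint equals a brute-force threshold scan", {
  set.seed(171)
  for (i in 1:20) {
    s <- round(rnorm(40), 1)
    l <- rep(c(TRUE, FALSE), each = 20)
    s[l] <- s[l] + sample(c(0, 0.5, 1), 1)
    r <- roc_curve(s, l, direction = "higher_indicates_case")
    cp <- optimal_cutpoint(r)
    js <- vapply(sort(unique(s)), function(t) {
      sum(s >= t & l) / sum(l) + sum(s < t & !l) / sum(!l) - 1
    }, numeric(1))
    expect_equal(cp$youden, max(js), tolerance = 1e-12)
  }
})

test_that("cutpoint ties resolve toward higher specificity", {
  # two thresholds reach J = 0.5; the higher-specificity one must win
  s <- c(1, 2, 3, 4)
  l <- c(FALSE, TRUE, FALSE, TRUE)
  r <- roc_curve(s, l, direction = "higher_indicates_case")
  cp <- optimal_cutpoint(r)
  expect_equal(cp$youden, 0.5)
  expect_equal(cp$specificity, 1)
  expect_equal(cp$cutoff, 3.5)
})

test_that("Spearman correlation follows the rank-Pearson definition", {
  x <- c(1, 2, 3, 4)
  expect_equal(spearman_cor(x, exp(x)), 1)
  expect_equal(spearman_cor(x, -x), -1)
  expect_equal(spearman_cor(x, c(1, 3, 2, 4)), 0.8)
  expect_error(spearman_cor(1:3, 1:4), "equal length")
  expect_error(spearman_cor(c(1, NA, 3), c(1, 2, NA)), "3 complete")
})

test_that("triplicate CVs are recovered and RI-filtered in the summary", {
  trip <- tibble::tibble(plate = c(1, 1, 1),
                         pA = c(9, 10, 11), pB = c(0.05, 0.05, 0.05))
  qc <- qc_cv(trip)
  expect_equal(qc$per_peak$intra_cv[qc$per_peak$peak == "pA"], 10)
  # all replicates identical: zero CVs
  same <- tibble::tibble(plate = rep(1:2, each = 3), pA = 5, pB = 5)
  qc0 <- qc_cv(same)
  expect_equal(qc0$per_peak$intra_cv, c(0, 0))
  expect_equal(qc0$per_peak$inter_cv, c(0, 0))
  # a peak averaging 0.5% relative intensity is excluded from the summary
  low <- tibble::tibble(plate = rep(1:2, each = 3),
                        pA = c(99, 100, 101, 98, 100, 102),
                        pB = 100 * 0.005)
  qc1 <- qc_cv(low, ri_min = 1)
  kept <- qc1$per_peak$peak[qc1$per_peak$mean_ri > 1]
  expect_equal(kept, "pA")
  expect_equal(qc1$summary$n_peaks_ri, 1)
  expect_equal(qc1$summary$mean_intra_cv,
               qc1$per_peak$intra_cv[qc1$per_peak$peak == "pA"])
})
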