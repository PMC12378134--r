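test_that("agreement reproduces textbook Pearson and Bland-Altman formulas", {
  set.seed(13)
  x <- rnorm(40, 20, 6)
  y <- x + rnorm(40, 2, 3)
  a <- agreement(x, y)
  d <- x - y
  expect_equal(a$r, sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  expect_equal(a$mean_diff, mean(d))
  expect_equal(a$loa_lower, mean(d) - 1.96 * sd(d))
  expect_equal(a$loa_upper, mean(d) + 1.96 * sd(d))
  expect_equal(a$n, 40L)

  # constant offset: perfect correlation, degenerate limits
  b <- agreement(x + 2, x)
  expect_equal(b$r, 1)
  expect_equal(c(b$mean_diff, b$loa_lower, b$loa_upper), c(2, 2, 2))

  expect_warning(cc <- agreement(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.na(cc$r))
  expect_error(agreement(1:4, 1:5), "paired")
})

test_that("AUC equals the exhaustive case-control pair count", {
  set.seed(14)
  for (k in 1:20) {
    m <- sample(2:10, 1); n <- sample(2:10, 1)
    v <- round(c(rnorm(m, 1), rnorm(n)), 1)   # rounding induces ties
    lab <- rep(c(TRUE, FALSE), c(m, n))
    expect_equal(roc(v, lab)$auc, auc_pairs_oracle(v, lab))
  }
  # perfect separation and label-independent marker
  expect_equal(roc(c(5, 6, 7, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))$auc, 1)
  set.seed(15)
  null_auc <- roc(rnorm(2000), rep(c(TRUE, FALSE), 1000))$auc
  expect_equal(null_auc, 0.5, tolerance = 0.05)
  expect_error(roc(1:5, rep(TRUE, 5)), "degenerate")
})

test_that("direction handling and the Youden operating point are correct", {
  v <- c(10, 9, 8, 7, 3, 2, 1)                # low values = disease
  lab <- c(rep(FALSE, 4), rep(TRUE, 3))
  r <- roc(v, lab, direction = "<")
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_true(r$cutoff >= 3 && r$cutoff < 7)  # positive call: value <= cutoff
  # a known mixed fixture: best cutoff trades one miss for full specificity
  v2 <- c(1, 2, 3, 4, 5, 6, 2.5)
  lab2 <- c(rep(FALSE, 3), rep(TRUE, 4))
  r2 <- roc(v2, lab2, direction = ">")
  expect_equal(r2$sensitivity, 0.75)
  expect_equal(r2$specificity, 1)
  expect_equal(r2$accuracy, 6 / 7)
})

test_that("AUC and DeLong inference agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(16)
  v <- c(rnorm(25, 1.2), rnorm(30))
  lab <- rep(c(1, 0), c(25, 30))
  mine <- roc(v, lab)
  ref <- pROC::roc(lab, v, direction = "<", quiet = TRUE)
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)))
  expect_equal(mine$var, pROC::var(ref))
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(mine$ci, pmin(pmax(c(ci[1], ci[3]), 0), 1), tolerance = 1e-3)

  # paired AUC comparison against pROC's DeLong test
  w <- v + rnorm(55, 0, 1.5)
  cmp <- compare_rocs(v, w, lab)
  ref2 <- pROC::roc.test(pROC::roc(lab, v, direction = "<", quiet = TRUE),
                         pROC::roc(lab, w, direction = "<", quiet = TRUE),
                         method = "delong", paired = TRUE)
  expect_equal(cmp$p, ref2$p.value)
})

test_that("paired DeLong test is symmetric, permutation-invariant and sane", {
  set.seed(17)
  lab <- rep(c(TRUE, FALSE), c(20, 25))
  a <- rnorm(45) + 2 * lab    # strong marker
  b <- rnorm(45)              # uninformative marker
  cmp <- compare_rocs(a, b, lab)
  expect_lt(cmp$p, 0.05)
  expect_equal(compare_rocs(b, a, lab)$p, cmp$p)
  # identical markers: no difference
  expect_equal(compare_rocs(a, a, lab)$p, 1)
  # jointly permuting subjects changes nothing
  perm <- sample(45)
  expect_equal(compare_rocs(a[perm], b[perm], lab[perm])$p, cmp$p)
})

test_that("Kruskal-Wallis wrapper matches hand ranking and rank-sum checks", {
  vals <- c(2.1, 3.5, 3.5, 1.2, 5.0, 4.4, 0.7, 2.1, 6.3)
  grp <- rep(c("a", "b", "c"), each = 3)
  k <- kruskal_wallis(vals, grp)
  expect_equal(k$H, kw_hand_oracle(vals, grp))
  expect_equal(k$p, pchisq(k$H, 2, lower.tail = FALSE))
  expect_equal(k$H, unname(kruskal.test(vals, factor(grp))$statistic))

  # all values equal: H = 0 (tie-corrected form is 0/0 -> NaN in the raw
  # formula; the implementation must report a non-significant zero)
  flat <- kruskal_wallis(rep(3, 9), grp)
  expect_false(isTRUE(flat$significant))

  # two groups: p consistent with the normal-approximation rank-sum test
  set.seed(18)
  v2 <- c(rnorm(12, 1), rnorm(15))
  g2 <- rep(c("x", "y"), c(12, 15))
  k2 <- kruskal_wallis(v2, g2)
  w2 <- wilcox.test(v2 ~ factor(g2), exact = FALSE, correct = FALSE)
  expect_equal(k2$p, w2$p.value, tolerance = 1e-10)
  expect_error(kruskal_wallis(v2, rep("x", 27)), "grouping")
})

test_that("combined logistic model recovers nulls and nests deviances", {
  set.seed(19)
  n <- 3000
  hmr <- rnorm(n, 2.2, 0.3)
  score <- rpois(n, 6)
  y <- rbinom(n, 1, 0.4)          # labels independent of both predictors
  fit <- fit_combined(hmr, score, y)
  expect_equal(unname(fit$coefficients["hmr"]), 0, tolerance = 0.25)
  expect_equal(unname(fit$coefficients["score"]), 0, tolerance = 0.05)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
  expect_lte(fit$deviance, fit$deviance_hmr)
  expect_lte(fit$deviance, fit$deviance_score)
  # combined in-sample AUC at least matches the weaker single predictor
  r_comb <- roc(fit$fitted, y == 1)
  r_hmr <- roc(hmr, y == 1)
  r_score <- roc(score, y == 1)
  expect_gte(r_comb$auc, min(r_hmr$auc, r_score$auc) - 1e-12)
  expect_error(fit_combined(rep(1, 10), 1:10, rep(c(TRUE, FALSE), 5)),
               "non-constant")
})

test_that("perfect separation is flagged but still reported", {
  hmr <- c(1.2, 1.3, 1.4, 2.5, 2.6, 2.7)
  score <- c(30, 28, 25, 2, 1, 0)
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_warning(fit <- fit_combined(hmr, score, y), "separation")
  expect_true(fit$separation)
  expect_length(fit$coefficients, 3)
})
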