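# O(n^2) pairwise AUC oracle.
auc_oracle <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

test_that("roc_auc handles separation, ties, and matches the pairwise oracle", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(roc_auc(c(1, 0), c(0.4, 0.4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both label categories")
  withr::local_seed(23)
  for (i in 1:110) {
    n <- 50
    y <- c(rep(1, sample(5:45, 1)))
    y <- c(y, rep(0, n - length(y)))
    s <- round(runif(n), sample(c(1, 3), 1))
    expect_equal(roc_auc(y, s), auc_oracle(y, s))
  }
})

test_that("roc_auc agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(31)
  y <- rbinom(80, 1, 0.4)
  y[1:2] <- c(0, 1)
  s <- runif(80)
  expect_equal(roc_auc(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("AUC is invariant under monotone transforms and antisymmetric", {
  withr::local_seed(9)
  y <- rep(c(0, 1), 25)
  s <- rnorm(50)
  a <- roc_auc(y, s)
  expect_equal(roc_auc(y, exp(s)), a)
  expect_equal(roc_auc(y, 3 * s - 7), a)
  expect_equal(roc_auc(y, s) + roc_auc(y, -s), 1)  # tie-free scores
})

test_that("log loss matches closed forms and hand arithmetic", {
  expect_equal(log_loss(c(0, 1, 0, 1), rep(0.5, 4)), log(2))
  expect_lt(log_loss(c(0, 1), c(1e-16, 1 - 1e-16)), 1e-10)
  expect_equal(log_loss(c(1, 0), c(0.9, 0.2)), -0.5 * (log(0.9) + log(0.8)))
  expect_error(log_loss(c(1, 0), 0.5), "length mismatch")
})

test_that("threshold metrics follow the confusion matrix with prob >= t positive", {
  # TP=3 FN=1 TN=4 FP=2
  y <- c(rep(1, 4), rep(0, 6))
  p <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.55, 0.1, 0.2, 0.3, 0.4)
  m <- threshold_metrics(y, p, 0.5)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 4 / 6)
  expect_equal(m$accuracy, 0.7)
  # boundary: prob exactly at the threshold counts positive
  b <- threshold_metrics(c(1, 0), c(0.5, 0.1), 0.5)
  expect_equal(b$sensitivity, 1.0)
  # degenerate direction: everything called positive
  a <- threshold_metrics(c(1, 0), c(0.8, 0.9), 0.5)
  expect_equal(a$sensitivity, 1.0)
  expect_equal(a$specificity, 0.0)
})

test_that("bootstrap CIs are deterministic, zero-width for constants, and bracket the point", {
  y <- rep(c(0, 1), 20)
  p <- rep(0.5, 40)
  ci <- bootstrap_ci(log_loss, y, p, eval_config(seed = 4))
  expect_equal(ci$ci_low, ci$ci_high)
  expect_equal(ci$ci_low, log(2))

  withr::local_seed(12)
  s <- rnorm(40, mean = y)
  c1 <- bootstrap_ci(roc_auc, y, s, eval_config(seed = 7))
  c2 <- bootstrap_ci(roc_auc, y, s, eval_config(seed = 7))
  expect_identical(c1$ci_low, c2$ci_low)
  expect_identical(c1$ci_high, c2$ci_high)
  a <- roc_auc(y, s)
  expect_lte(c1$ci_low, a + 1e-9)
  expect_gte(c1$ci_high, a - 1e-9)
})

test_that("evaluation reports round-trip through JSON losslessly", {
  withr::local_seed(2)
  pred <- data.frame(slide_id = sprintf("s%02d", 1:30),
                     label = rep(c("positive", "negative"), 15),
                     probability = runif(30))
  rep1 <- evaluate_predictions(pred, eval_config(n_bootstrap = 50, seed = 3))
  path <- file.path(withr::local_tempdir(), "r.json")
  write_eval_report(rep1, path)
  rep2 <- read_eval_report(path)
  for (m in c("auc", "log_loss", "accuracy", "sensitivity", "specificity")) {
    expect_equal(rep1[[m]]$point, rep2[[m]]$point, tolerance = 1e-12)
    expect_equal(rep1[[m]]$ci_low, rep2[[m]]$ci_low, tolerance = 1e-12)
    expect_equal(rep1[[m]]$ci_high, rep2[[m]]$ci_high, tolerance = 1e-12)
  }
  expect_equal(rep2$n_positive, 15)
  expect_equal(rep2$bootstrap_variant, "percentile")
})

test_that("roc_points trace the empirical ROC curve", {
  y <- c(0, 0, 1, 1)
  s <- c(0.1, 0.6, 0.4, 0.9)
  pts <- roc_points(y, s)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_true(all(diff(pts$tpr) >= 0) && all(diff(pts$fpr) >= 0))
})
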