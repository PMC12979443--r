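test_that("confusion metrics follow the closed formulas and flag degeneracy", {
  # TP 3, FP 1, FN 1, TN 5
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  s <- c(.9, .8, .7, .2, .6, .1, .3, .4, .35, .15)
  m <- confusion_metrics(y, s)
  expect_equal(unname(m$counts), c(3L, 1L, 1L, 5L))
  expect_equal(m$SEN, 0.75)
  expect_equal(m$PRE, 0.75)
  expect_equal(m$SPE, 5 / 6)
  expect_equal(m$ACC, 0.8)
  expect_equal(m$F1, 0.75)
  expect_false(m$degenerate)

  perfect <- confusion_metrics(y, y)
  expect_true(all(unlist(perfect[c("PRE", "SEN", "SPE", "ACC", "F1")]) == 1))

  none <- confusion_metrics(c(1, 0), c(0.1, 0.2))
  expect_equal(none$PRE, 0)
  expect_true(none$degenerate)

  expect_error(confusion_metrics(c(1, 2), c(.5, .5)), "binary")
})

test_that("ROC-AUC equals exhaustive pairwise concordance with ties at half", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(.9, .8, .2, .1)), 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(.1, .2, .8, .9)), 0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(.5, 4)), 0.5)
  set.seed(21)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 1)  # rounded: forces ties
    expect_equal(roc_auc(y, s), auc_pairwise(y, s), tolerance = 1e-12)
  }
  expect_error(roc_auc(rep(1, 5), runif(5)), "both")
})

test_that("ROC-AUC is invariant under strictly monotone score transforms", {
  set.seed(4)
  y <- rbinom(40, 1, 0.5); s <- runif(40)
  a <- roc_auc(y, s)
  expect_equal(roc_auc(y, qlogis(s)), a)
  expect_equal(roc_auc(y, s^3 + 2 * s), a)
})

test_that("PR-AUC matches brute-force step integration and tie closed forms", {
  expect_equal(pr_auc(c(1, 1, 0, 0), c(.9, .8, .2, .1)), 1)
  # all scores tied: average precision equals prevalence
  y <- c(1, 1, 0, 0, 0)
  expect_equal(pr_auc(y, rep(0.3, 5)), 0.4)
  set.seed(31)
  for (i in 1:20) {
    y <- rbinom(20, 1, 0.4)
    if (sum(y) == 0) next
    s <- round(runif(20), 1)
    expect_equal(pr_auc(y, s), prauc_bruteforce(y, s), tolerance = 1e-12)
  }
  expect_error(pr_auc(rep(0, 4), runif(4)), "positive")
})

test_that("rank-based AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- rbinom(60, 1, 0.5); s <- runif(60)
  expect_equal(roc_auc(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("decision-curve net benefit obeys its reference lines and bound", {
  set.seed(13)
  y <- rbinom(120, 1, 0.4)
  s <- plogis(rnorm(120) + 2 * y)
  dc <- decision_curve(y, s)
  prev <- mean(y)
  expect_true(all(dc$nb_none == 0))
  expect_equal(dc$nb_all,
               prev - (1 - prev) * dc$thresholds / (1 - dc$thresholds))
  # cannot beat treating exactly the positives with no false positives
  expect_true(all(dc$nb_model <= prev + 1e-12))
  # perfect predictor attains prevalence below the smallest positive score
  yp <- c(rep(1, 4), rep(0, 6)); sp <- c(.9, .95, .9, .85, rep(.05, 6))
  dcp <- decision_curve(yp, sp, thresholds = c(0.1, 0.5, 0.8))
  expect_equal(dcp$nb_model, rep(0.4, 3))
  expect_error(decision_curve(y, s, thresholds = c(0.5, 1)), "inside")
})

test_that("calibration bins partition the sample and Brier is the MSE", {
  set.seed(17)
  y <- rbinom(200, 1, 0.5); s <- runif(200)
  cal <- calibration(y, s)
  expect_equal(sum(cal$bin_n), 200)
  expect_equal(cal$brier, mean((s - y)^2))
  expect_equal(calibration(y, as.numeric(y))$brier, 0)
  expect_equal(calibration(y, rep(0.5, 200))$brier, 0.25)
  # constant prediction at prevalence: Brier = p(1-p)
  p <- mean(y)
  expect_equal(calibration(y, rep(p, 200))$brier, p * (1 - p))
})
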