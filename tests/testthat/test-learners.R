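test_that("hyperparameter space registry matches the tuning table", {
  xgb <- learner_space("xgb")
  expect_length(xgb, 7)
  expect_equal(xgb$learning_rate$range, c(0.01, 0.3))
  expect_equal(xgb$max_depth$kind, "integer")
  expect_equal(xgb$reg_lambda$range, c(0, 2))

  svm <- learner_space("svm")
  expect_equal(svm$degree$active_when, list(param = "kernel", value = "poly"))
  expect_equal(svm$C$kind, "log_uniform")

  lr <- learner_space("lr")
  expect_equal(unlist(lr$penalty$categories), c("l1", "l2"))
  expect_equal(lr$C$range, c(0.001, 100))

  bp <- learner_space("bp")
  expect_true(any(vapply(bp$hidden_layer_sizes$categories,
                         function(c) identical(c, c(50L, 50L)), logical(1))))
  expect_error(learner_space("rf"))
})

test_that("out-of-range hyperparameters are rejected before training", {
  d <- separable_data()
  hp <- mid_hyperparams("xgb")
  hp$max_depth <- 20
  expect_error(train_learner("xgb", hp, d[1:3], d$caf), "outside its range")
  hp2 <- mid_hyperparams("lr"); hp2$penalty <- "elasticnet"
  expect_error(train_learner("lr", hp2, d[1:3], d$caf), "category set")
  hp3 <- mid_hyperparams("svm"); hp3$degree <- 2.5
  expect_error(train_learner("svm", hp3, d[1:3], d$caf), "integer")
})

test_that("all four learners emit probabilities in [0,1], deterministically", {
  d <- separable_data(n = 80)
  X <- d[c("x1", "x2", "noise")]
  for (ln in c("lr", "svm", "xgb", "bp")) {
    hp <- mid_hyperparams(ln)
    fit <- train_learner(ln, hp, X, d$caf, seed = 11, bp_epochs = 60L)
    p <- predict(fit, X)
    expect_true(all(p >= 0 & p <= 1), info = ln)
    fit2 <- train_learner(ln, hp, X, d$caf, seed = 11, bp_epochs = 60L)
    expect_identical(predict(fit2, X), p, info = ln)
  }
})

test_that("logistic regression separates a linearly separable toy exactly", {
  d <- separable_data(n = 100)
  hp <- list(penalty = "l2", C = 100, max_iter = 500)
  fit <- train_learner("lr", hp, d[c("x1", "x2")], d$caf, seed = 1)
  acc <- mean((predict(fit, d[c("x1", "x2")]) >= 0.5) == d$caf)
  expect_equal(acc, 1)
})

test_that("standardization statistics come only from the training rows", {
  d <- separable_data(n = 60)
  X <- d[c("x1", "x2")]
  fit <- train_learner("lr", mid_hyperparams("lr"), X, d$caf, seed = 2)
  probe <- data.frame(x1 = c(0, 5), x2 = c(0, -5))
  base <- predict(fit, probe)
  # scoring wildly shifted held-out rows must not change the fitted
  # transform: refitting on the same training rows reproduces it
  fit2 <- train_learner("lr", mid_hyperparams("lr"), X, d$caf, seed = 2)
  shifted <- data.frame(x1 = probe$x1 + 100, x2 = probe$x2 - 100)
  invisible(predict(fit2, shifted))
  expect_identical(predict(fit2, probe), base)
  # the stored centering comes from training data alone
  pp <- fit$preproc
  centers <- vapply(pp$columns, function(ci)
    if (ci$type == "continuous") ci$center else NA_real_, numeric(1))
  expect_equal(centers[1], mean(X$x1))
})

test_that("degenerate outcomes and malformed features are rejected", {
  d <- separable_data(n = 30)
  expect_error(train_learner("lr", mid_hyperparams("lr"), d[1:2],
                             rep(1, 30)), "both classes")
  bad <- d[1:2]; bad$x1[3] <- Inf
  expect_error(train_learner("lr", mid_hyperparams("lr"), bad, d$caf),
               "non-finite")
})

test_that("categorical features are one-hot encoded against training levels", {
  set.seed(3)
  d <- data.frame(g = factor(sample(c("a", "b", "c"), 90, replace = TRUE)),
                  x = rnorm(90))
  y <- as.integer(d$g == "a" | d$x > 1)
  fit <- train_learner("lr", mid_hyperparams("lr"), d, y, seed = 4)
  p <- predict(fit, d)
  expect_true(all(p >= 0 & p <= 1))
  unseen <- data.frame(g = factor("z"), x = 0)
  expect_error(predict(fit, unseen), "unseen category")
})
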