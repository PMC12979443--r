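test_that("exact attributions recover additive models against a zero background", {
  f <- function(X) X$x1 + 2 * X$x2
  a <- shapley_values(f, data.frame(x1 = 2, x2 = 3),
                      data.frame(x1 = 0, x2 = 0))
  expect_equal(unname(a$contributions), c(2, 6), tolerance = 1e-12)
  expect_equal(a$base_value, 0)
  expect_equal(a$base_value + sum(a$contributions), a$prediction,
               tolerance = 1e-9)
})

test_that("constant predictors attribute nothing; dummies get zero", {
  bg <- data.frame(x1 = rnorm(20), x2 = rnorm(20))
  a <- shapley_values(function(X) rep(0.7, nrow(X)),
                      data.frame(x1 = 1, x2 = -1), bg)
  expect_equal(unname(a$contributions), c(0, 0))
  expect_equal(a$base_value, 0.7)
  # x2 provably ignored -> phi exactly 0 in exact mode
  a2 <- shapley_values(function(X) sin(X$x1), data.frame(x1 = 1, x2 = 5), bg)
  expect_equal(unname(a2$contributions[2]), 0, tolerance = 1e-12)
})

test_that("symmetric features at equal values get equal attributions", {
  set.seed(2)
  v <- rnorm(15)
  bg <- data.frame(x1 = v, x2 = v)  # exchangeable background
  a <- shapley_values(function(X) X$x1 * X$x2, data.frame(x1 = 2, x2 = 2), bg)
  expect_equal(a$contributions[["x1"]], a$contributions[["x2"]],
               tolerance = 1e-12)
})

test_that("exact efficiency holds on random nonlinear models up to 8 features", {
  set.seed(14)
  for (d in c(3, 5, 8)) {
    bg <- as.data.frame(matrix(rnorm(10 * d), 10))
    names(bg) <- paste0("x", 1:d)
    w <- rnorm(d)
    f <- function(X) plogis(as.numeric(as.matrix(X) %*% w) + X[[1]] * X[[2]])
    row <- bg[1, , drop = FALSE] + 1
    a <- shapley_values(f, row, bg)
    expect_equal(a$base_value + sum(a$contributions), a$prediction,
                 tolerance = 1e-9, info = paste("d =", d))
  }
})

test_that("sampled mode agrees with exact within 3 MC standard errors and converges as 1/sqrt(n)", {
  set.seed(15)
  d <- 5
  bg <- as.data.frame(matrix(rnorm(12 * d), 12)); names(bg) <- paste0("x", 1:d)
  w <- rnorm(d)
  f <- function(X) as.numeric(as.matrix(X) %*% w) + 0.5 * X[[1]] * X[[3]]
  row <- data.frame(matrix(rnorm(d), 1)); names(row) <- names(bg)
  ex <- shapley_values(f, row, bg, mode = "exact")
  sa <- shapley_values(f, row, bg, mode = "sampled", n_perm = 256, seed = 1)
  expect_true(all(abs(sa$contributions - ex$contributions) <=
                    3 * sa$mc_se + 1e-10))
  expect_lte(abs(sa$base_value + sum(sa$contributions) - sa$prediction),
             3 * sum(sa$mc_se) + 1e-10)
  # mc_se shrinks roughly as 1/sqrt(n_perm)
  ses <- vapply(c(64, 256, 1024), function(np)
    sum(shapley_values(f, row, bg, mode = "sampled", n_perm = np,
                       seed = 2)$mc_se), numeric(1))
  expect_true(all(diff(ses) < 0))
  expect_equal(ses[1] / ses[3], sqrt(1024 / 64), tolerance = 0.6)
})

test_that("attribution works on fitted learners and enforces preconditions", {
  d <- separable_data(n = 60)
  fit <- train_learner("lr", mid_hyperparams("lr"), d[c("x1", "x2")],
                       d$caf, seed = 1)
  a <- shapley_values(fit, d[1, c("x1", "x2")], d[1:20, c("x1", "x2")])
  expect_equal(a$base_value + sum(a$contributions), a$prediction,
               tolerance = 1e-9)
  expect_error(shapley_values(fit, d[1, c("x1", "x2")],
                              d[0, c("x1", "x2")]), "non-empty")
  wide <- as.data.frame(matrix(rnorm(26), 2)); names(wide) <- paste0("x", 1:13)
  expect_error(shapley_values(function(X) X[[1]], wide[1, ], wide),
               "sampled")
})

test_that("global importance is the ranked mean |phi| with linear scaling", {
  mk <- function(phi) structure(list(contributions = phi), class = "attribution")
  atts <- list(mk(c(a = 1, b = -2, c = 0)), mk(c(a = -3, b = 2, c = 0)))
  gi <- global_importance(atts)
  expect_equal(unname(gi$importance), c(2, 2, 0))
  expect_equal(gi$ranking, c("a", "b", "c"))  # tie broken by feature order
  expect_equal(gi$ranking[3], "c")            # all-zero feature ranks last
  atts2 <- list(mk(c(a = 2, b = -2, c = 0)), mk(c(a = -6, b = 2, c = 0)))
  expect_equal(global_importance(atts2)$importance[["a"]],
               2 * gi$importance[["a"]])
  expect_error(global_importance(list(mk(c(a = 1)), mk(c(z = 1)))),
               "inconsistent")
})

test_that("explanation views telescope from base value to prediction", {
  f <- function(X) X$x1 - X$x2 + 3 * X$x3
  bg <- data.frame(x1 = 0, x2 = 0, x3 = 0)
  a <- shapley_values(f, data.frame(x1 = 1, x2 = 2, x3 = 0.5), bg)
  v <- explanation_views(a)
  expect_equal(v$waterfall$cumulative[nrow(v$waterfall)], a$prediction,
               tolerance = 1e-9)
  expect_equal(v$waterfall$feature[1],
               names(sort(abs(a$contributions), decreasing = TRUE))[1])
  expect_equal(sum(v$force$increasing) + sum(v$force$decreasing),
               a$prediction - a$base_value, tolerance = 1e-9)
  expect_equal(v$decision$cumulative, v$waterfall$cumulative)
  # single feature: one-step waterfall
  a1 <- shapley_values(function(X) 2 * X$x1, data.frame(x1 = 1),
                       data.frame(x1 = 0))
  expect_equal(nrow(explanation_views(a1)$waterfall), 1)
})

test_that("dependence data pairs feature values with their attributions", {
  f <- function(X) X$x1 * (X$x2 > 0)
  set.seed(6)
  bg <- data.frame(x1 = rnorm(15), x2 = rnorm(15))
  rows <- data.frame(x1 = c(1, 2, 3), x2 = c(-1, 1, 1))
  atts <- lapply(1:3, function(i) shapley_values(f, rows[i, ], bg))
  dd <- dependence_data(atts, "x1", "x2")
  expect_equal(nrow(dd), 3)
  expect_equal(dd$value, rows$x1)
  expect_equal(dd$color, rows$x2)
  same <- dependence_data(atts, "x1", "x1")
  expect_equal(same$color, same$value)
  expect_error(dependence_data(atts, "zz"), "unknown feature")
  # the interaction shows: phi(x1) larger when the gate x2 is open
  expect_gt(mean(dd$phi[dd$color > 0]), mean(dd$phi[dd$color < 0]))
})
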