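test_that("position decoding follows the threshold, repair and range rules", {
  schema <- encoding_schema(c("a", "b", "c"), learner_space("lr"))
  # mask (0.7, 0.2, 0.5) at threshold 0.5 -> features a and c
  pos <- c(0.7, 0.2, 0.5, 0.2, 0.5, 0.5)
  cand <- decode_position(pos, schema)
  expect_equal(cand$features, c("a", "c"))
  # u = 0.5 on log-uniform [0.001, 100] -> 10^(-3 + 0.5*5)
  expect_equal(cand$hyperparams$C, 10^(-0.5), tolerance = 1e-12)
  # integer decode: round(50 + 0.5 * 450)
  expect_equal(cand$hyperparams$max_iter, 275)
  # categorical decode by index: u = 0.2 of 2 categories -> first
  expect_equal(cand$hyperparams$penalty, "l1")
  # repair rule: no coordinate passes -> argmax only
  cand2 <- decode_position(c(0.1, 0.45, 0.3, 1, 1, 1), schema)
  expect_equal(cand2$features, "b")
  expect_equal(cand2$hyperparams$C, 100)      # u = 1 upper end
  expect_equal(cand2$hyperparams$penalty, "l2")  # index capped at K
  # out-of-box coordinates are clipped before decoding (idempotent)
  cand3 <- decode_position(c(1.4, -0.2, 0.3, 2, 2, 2), schema)
  expect_equal(cand3$features, "a")
  expect_equal(cand3$hyperparams$C, 100)
  expect_error(decode_position(c(0.5, 0.5), schema), "length")
})

test_that("conditional hyperparameters are decoded but flagged inactive", {
  schema <- encoding_schema("f1", learner_space("svm"))
  # kernel coordinate 0.1 -> linear; degree decoded yet inactive
  cand <- decode_position(c(0.9, 0.5, 0.1, 0.5, 0.5), schema)
  expect_equal(cand$hyperparams$kernel, "linear")
  expect_true("degree" %in% names(cand$hyperparams))
  expect_equal(cand$inactive, "degree")
  # kernel coordinate 0.9 -> poly; degree active
  cand2 <- decode_position(c(0.9, 0.5, 0.9, 0.5, 0.5), schema)
  expect_equal(cand2$hyperparams$kernel, "poly")
  expect_length(cand2$inactive, 0)
})

test_that("stratified split reproduces the published 433/108 partition", {
  co <- generate_cohort(seed = 2)  # 360 / 181
  sp <- split_stratified(co, "caf", 0.2, seed = 9)
  expect_equal(nrow(sp$train), 433)
  expect_equal(nrow(sp$test), 108)
  expect_equal(sum(sp$train$caf), 288)
  expect_equal(sum(sp$test$caf), 72)
  # disjoint and exhaustive
  expect_equal(nrow(merge(sp$train, sp$test)), 0)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(co))
  # class proportions preserved to within one row per class
  expect_lt(abs(mean(sp$train$caf) - mean(co$caf)), 1 / nrow(sp$train) * 2)
  sp2 <- split_stratified(co, "caf", 0.2, seed = 9)
  expect_identical(sp$train, sp2$train)
  expect_error(split_stratified(data.frame(caf = rep(1, 5)), "caf", 0.2, 1),
               "zero rows|binary")
})

test_that("cross-validated fitness is deterministic and ranks signal above noise", {
  d <- separable_data(n = 80)
  schema <- encoding_schema(c("x1", "x2", "noise"), learner_space("lr"))
  signal <- decode_position(c(0.9, 0.9, 0.1, 0.6, 0.8, 0.5), schema)
  noise <- decode_position(c(0.1, 0.2, 0.9, 0.6, 0.8, 0.5), schema)
  fr <- cv_fitness(signal, d, "lr", cv_seed = 5)
  expect_equal(fr$mean_f1, 1)               # separable: every fold perfect
  expect_length(fr$per_fold, 5)
  expect_equal(fr$mean_f1,
               mean(vapply(fr$per_fold, `[[`, numeric(1), "F1")))
  fr2 <- cv_fitness(signal, d, "lr", cv_seed = 5)
  expect_equal(fr, fr2)
  fn <- cv_fitness(noise, d, "lr", cv_seed = 5)
  expect_lt(fn$mean_fitness, fr$mean_fitness)
  expect_error(cv_fitness(signal, d[1:6, ], "lr", k = 5), "at least k")
})

test_that("an unselected pure-noise column never changes the fitness", {
  d <- separable_data(n = 80)
  schema <- encoding_schema(c("x1", "x2"), learner_space("lr"))
  cand <- decode_position(c(0.9, 0.9, 0.6, 0.8, 0.5), schema)
  f_base <- cv_fitness(cand, d[c("x1", "x2", "caf")], "lr", cv_seed = 3)
  d2 <- d[c("x1", "x2", "caf")]
  d2$junk <- rnorm(nrow(d2))
  f_junk <- cv_fitness(cand, d2, "lr", cv_seed = 3)
  expect_equal(f_base$mean_f1, f_junk$mean_f1)
  expect_equal(f_base$per_fold, f_junk$per_fold)
})

test_that("sync_fit selects the signal, retrains, predicts, and reproduces", {
  d <- planted_signal_dataset(n = 150, n_informative = 2, n_noise = 2,
                              effect_size = 2, seed = 13)
  fit <- sync_fit(caf ~ ., d, learner = "lr", population = 8,
                  iterations = 8, seed = 13)
  expect_s3_class(fit, "sync_fit")
  expect_gte(length(fit$candidate$features), 1)
  expect_true(all(c("inf1", "inf2") %in% fit$candidate$features))
  expect_length(fit$convergence, 8)
  expect_true(all(diff(fit$convergence) >= -1e-12))  # maximization view
  p <- predict(fit, d)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(roc_auc(d$caf, p), 0.9)
  fit2 <- sync_fit(caf ~ ., d, learner = "lr", population = 8,
                   iterations = 8, seed = 13)
  expect_identical(fit2$candidate, fit$candidate)
  expect_identical(predict(fit2, d), p)
  expect_output(print(fit), "selected")
  expect_output(summary(fit), "per-fold F1")
})
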