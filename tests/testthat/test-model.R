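test_that("cohort splitting is exhaustive, stratified and seeded", {
  coh <- make_separable_cohort(50)        # 100 rows, 50/50
  sp <- split_cohort(coh, seed = 3)
  expect_equal(nrow(sp$train), 70)
  expect_equal(nrow(sp$test), 30)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(coh))

  # stratification on an 80/20 imbalance preserves class ratios
  imb <- make_separable_cohort(50)
  imb$label <- c(rep("hypertensive", 80), rep("control", 20))
  spi <- split_cohort(imb, seed = 4)
  expect_equal(sum(spi$train$label == "hypertensive"), 56)
  expect_equal(sum(spi$train$label == "control"), 14)

  expect_identical(split_cohort(coh, seed = 9), split_cohort(coh, seed = 9))
  expect_false(identical(split_cohort(coh, seed = 9),
                         split_cohort(coh, seed = 10)))

  solo <- coh[coh$label == "control", ]
  expect_error(split_cohort(solo), "both classes")
})

test_that("random forest separates a separable cohort and is seeded", {
  coh <- make_separable_cohort(40, shift = 5, seed = 2)
  rf <- train_rf(coh, n_trees = 100, seed = 1)
  pr <- predict_proba(rf, coh)
  acc <- mean((pr >= 0.5) == (coh$label == "hypertensive"))
  expect_equal(acc, 1)
  # pure-class training rows sit near probability 1 for their class
  expect_gt(min(pr[coh$label == "hypertensive"]), 0.8)
  expect_lt(max(pr[coh$label == "control"]), 0.2)

  rf2 <- train_rf(coh, n_trees = 100, seed = 1)
  expect_identical(predict_proba(rf2, coh), pr)

  expect_error(train_rf(coh[coh$label == "control", ]), "single class")
})

test_that("both split criteria produce valid forests", {
  coh <- make_separable_cohort(30, shift = 3, seed = 5)
  for (crit in c("gini", "entropy")) {
    rf <- train_rf(coh, n_trees = 60, criterion = crit, seed = 2)
    pr <- predict_proba(rf, coh)
    expect_true(all(pr >= 0 & pr <= 1))
    imp <- feature_importance(rf)
    expect_true(all(imp >= 0))
    expect_equal(sum(imp), 1, tolerance = 1e-12)
    expect_gt(mean((pr >= 0.5) == (coh$label == "hypertensive")), 0.95)
  }
})

test_that("permuted labels drop test accuracy to chance", {
  coh <- make_separable_cohort(60, shift = 4, seed = 6)
  set.seed(7)
  coh$label <- sample(coh$label)
  sp <- split_cohort(coh, seed = 8)
  rf <- train_rf(sp$train, n_trees = 150, seed = 8)
  rep <- evaluate_model(rf, sp$test)
  expect_gt(rep$metrics$accuracy, 30)
  expect_lt(rep$metrics$accuracy, 70)
})

test_that("forest accuracy is comparable to an established implementation", {
  coh <- make_separable_cohort(50, shift = 2, seed = 11)
  sp <- split_cohort(coh, seed = 11)
  rf <- train_rf(sp$train, n_trees = 200, seed = 11)
  mine <- evaluate_model(rf, sp$test)$metrics$accuracy

  set.seed(11)
  ref_fit <- randomForest::randomForest(
    x = sp$train[, c("f_sig", "f_noise1", "f_noise2")],
    y = factor(sp$train$label), ntree = 200)
  ref_pred <- predict(ref_fit, sp$test[, c("f_sig", "f_noise1", "f_noise2")])
  ref_acc <- 100 * mean(as.character(ref_pred) == sp$test$label)
  expect_lt(abs(mine - ref_acc), 15)
})

test_that("MLP learns a separable cohort, clips out-of-range inputs,
           and trains reproducibly", {
  coh <- make_separable_cohort(40, shift = 4, seed = 3)
  mlp <- train_mlp(coh, seed = 2)
  pr <- predict_proba(mlp, coh)
  expect_gte(mean((pr >= 0.5) == (coh$label == "hypertensive")), 0.95)

  far <- data.frame(f_sig = 1e4, f_noise1 = -1e4, f_noise2 = 0)
  pf <- predict_proba(mlp, far)
  expect_true(pf >= 0 && pf <= 1)

  mlp2 <- train_mlp(coh, seed = 2)
  expect_identical(mlp$fit$wts, mlp2$fit$wts)
})

test_that("prediction refuses or imputes missing features explicitly", {
  coh <- make_separable_cohort(30, seed = 4)
  rf <- train_rf(coh, n_trees = 50, seed = 4)
  expect_error(predict_proba(rf, coh[, c("f_sig", "f_noise1")]),
               "f_noise2")
  holed <- coh
  holed$f_noise2[3] <- NA
  expect_error(predict_proba(rf, holed), "f_noise2")
  pr <- predict_proba(rf, holed, impute = TRUE)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("evaluation metrics satisfy their defining identities", {
  m <- confusion_metrics(tp = 8, fp = 2, tn = 6, fn = 4)
  expect_equal(m$accuracy, 70)
  expect_equal(m$sensitivity, 100 * 8 / 12, tolerance = 1e-12)
  expect_equal(m$specificity, 75)
  expect_equal(m$positive_prediction, 80)
  expect_equal(m$negative_prediction, 60)

  # perfect classifier on a separable cohort
  coh <- make_separable_cohort(40, shift = 6, seed = 9)
  sp <- split_cohort(coh, seed = 9)
  rf <- train_rf(sp$train, n_trees = 100, seed = 9)
  rep <- evaluate_model(rf, sp$test)
  expect_equal(rep$metrics$accuracy, 100)
  expect_equal(rep$auc, 1)
})

test_that("AUC equals the Wilcoxon statistic and is monotone-invariant", {
  set.seed(21)
  for (i in 1:5) {
    pr <- runif(150)
    truth <- runif(150) < 0.4
    roc <- crowdhrv:::roc_points(pr, truth)
    auc <- crowdhrv:::trapezoid_auc(roc)
    wilc <- mean(outer(pr[truth], pr[!truth], ">") +
                 0.5 * outer(pr[truth], pr[!truth], "=="))
    expect_equal(auc, wilc, tolerance = 1e-12)
    # strictly monotone transform leaves the ROC sweep unchanged
    auc2 <- crowdhrv:::trapezoid_auc(
      crowdhrv:::roc_points(plogis(4 * pr - 2), truth))
    expect_equal(auc2, auc, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(22)
  pr <- runif(300)
  truth <- c(rep(TRUE, 120), rep(FALSE, 180))
  pr[truth] <- pr[truth] + 0.3
  mine <- crowdhrv:::trapezoid_auc(crowdhrv:::roc_points(pr, truth))
  ref <- as.numeric(pROC::auc(pROC::roc(truth, pr, quiet = TRUE,
                                        direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-9)
})

test_that("mean-decrease-impurity importance finds the informative feature", {
  coh <- make_separable_cohort(60, shift = 3, seed = 13)
  rf <- train_rf(coh, n_trees = 150, seed = 13)
  imp <- feature_importance(rf)
  expect_identical(names(imp)[1], "f_sig")
  expect_equal(sum(imp), 1, tolerance = 1e-12)
  expect_true(all(imp >= 0))
  # pure-noise features share the small remainder roughly evenly
  expect_lt(max(imp[c("f_noise1", "f_noise2")]), 0.3)

  mlp <- train_mlp(coh, seed = 13)
  expect_error(feature_importance(mlp), "random-forest")
})

test_that("probability feedback maps to the warning band", {
  expect_identical(classify_feedback(c(0.1, 0.353, 0.6)),
                   c("negative", "negative (high risk)", "positive"))
  expect_identical(classify_feedback(0.5), "positive")
  expect_identical(classify_feedback(0.29), "negative")
})
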