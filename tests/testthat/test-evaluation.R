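test_that("mean squared error matches its closed form", {
  expect_equal(mse_metric(0, 2), 4.0)
  expect_equal(mse_metric(c(18, 20), c(18, 20)), 0.0)
  expect_equal(mse_metric(c(18, 20), c(19, 18)), 2.5)
})

test_that("mean absolute error, spread and confidence interval", {
  m <- mae_metric(c(18, 20), c(19, 18))
  expect_equal(m$mae, 1.5)
  expect_equal(m$sd, stats::sd(c(1, 2)))

  m0 <- mae_metric(c(17, 19), c(17, 19))
  expect_equal(m0$mae, 0)
  expect_equal(m0$sd, 0)

  # residuals all equal -> degenerate interval at |c|
  mc <- mae_metric(c(15, 16, 17), c(14, 15, 16))
  expect_equal(mc$mae, 1)
  expect_equal(mc$sd, 0)
  expect_equal(mc$ci95, c(1, 1))
  expect_lte(mc$ci95[1], mc$mae)
  expect_gte(mc$ci95[2], mc$mae)
})

test_that("classification metrics match hand-computed ratios", {
  cm <- classification_metrics(list(tp = 2, tn = 1, fp = 1, fn = 0))
  expect_equal(cm$accuracy, 0.75)
  expect_equal(cm$sensitivity, 1.0)
  expect_equal(cm$specificity, 0.5)

  perfect <- classification_metrics(list(tp = 3, tn = 4, fp = 0, fn = 0))
  expect_equal(perfect$accuracy, 1.0)

  expect_warning(
    und <- classification_metrics(list(tp = 2, tn = 0, fp = 0, fn = 1)),
    "specificity")
  expect_true(is.na(und$specificity))
  expect_error(classification_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)))
})

test_that("confusion counts use minors as positives", {
  cc <- confusion_counts(pred_minor = c(TRUE, TRUE, FALSE, FALSE),
                         true_minor = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(cc, list(tp = 1L, tn = 1L, fp = 1L, fn = 1L))
})

test_that("AUC equals the rank statistic and hand examples", {
  expect_equal(auc_score(c(0.9, 0.8, 0.4, 0.1), c(TRUE, TRUE, FALSE, FALSE)),
               1.0)
  # swap the adjacent minor/adult scores (0.8 and 0.4): three of the four
  # minor-adult pairs remain correctly ordered (value from the pair-counting
  # oracle)
  swapped <- c(0.9, 0.4, 0.8, 0.1)
  expect_equal(auc_oracle(swapped, c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(auc_score(swapped, c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(auc_score(c(0.5, 0.5, 0.5), c(TRUE, FALSE, TRUE)), 0.5)
  expect_error(auc_score(c(0.2, 0.4), c(TRUE, TRUE)))
})

test_that("AUC matches the exhaustive pair-counting oracle for n <= 8", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    minor <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(runif(n), 1)   # coarse grid provokes ties
    expect_equal(auc_score(scores, minor), auc_oracle(scores, minor))
  }
})

test_that("AUC from ROC-curve integration agrees with the rank form", {
  roc_integral <- function(scores, minor) {
    th <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
    tpr <- sapply(th, function(t) mean(scores[minor] >= t))
    fpr <- sapply(th, function(t) mean(scores[!minor] >= t))
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  set.seed(7)
  for (rep in 1:10) {
    n <- 30
    minor <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(minor)) < 2) next
    scores <- runif(n)
    expect_equal(auc_score(scores, minor), roc_integral(scores, minor),
                 tolerance = 1e-9)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  minor <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  scores <- runif(40) + 0.5 * minor
  ref <- as.numeric(pROC::auc(pROC::roc(response = minor, predictor = scores,
                                        quiet = TRUE, direction = "<")))
  expect_equal(auc_score(scores, minor), ref, tolerance = 1e-12)
})

test_that("stratified fold plans are unique, exhaustive and balanced", {
  set.seed(3)
  ages <- runif(50, 13, 21.8)
  plan <- make_repeated_stratified_folds(ages, k = 5, repeats = 10, seed = 9)
  expect_equal(plan$k, 5L)
  expect_equal(plan$repeats, 10L)
  # partition: every subject in exactly one test fold, folds of size 10
  expect_equal(sort(unlist(lapply(1:5, function(f) which(plan$fold == f)))),
               1:50)
  expect_equal(as.numeric(table(plan$fold)), rep(10, 5))
  # age stratification: per-bin fold counts proportional within 1
  for (b in unique(plan$bins)) {
    cnt <- table(factor(plan$fold[plan$bins == b], levels = 1:5))
    expect_lte(max(cnt) - min(cnt), 1)
  }
  # repeats leave the partition fixed and only vary derived seeds
  plan2 <- make_repeated_stratified_folds(ages, k = 5, repeats = 10, seed = 9)
  expect_identical(plan$fold, plan2$fold)
  expect_equal(length(unique(plan$repeat_seeds)), 10)
  expect_error(make_repeated_stratified_folds(runif(3), k = 5))
})

test_that("uniform ages over bins give proportional fold bin counts", {
  ages <- rep(seq(13.5, 17.5, by = 1), each = 10)   # 5 bins x 10 subjects
  plan <- make_repeated_stratified_folds(ages, k = 5, repeats = 1, seed = 2)
  for (b in unique(plan$bins)) {
    cnt <- table(factor(plan$fold[plan$bins == b], levels = 1:5))
    expect_equal(as.numeric(cnt), rep(2, 5))
  }
})

test_that("cross-validation plumbing: oracle and naive predictors", {
  set.seed(5)
  ages <- c(runif(30, 13, 17.9), runif(20, 18.1, 21.8))
  plan <- make_repeated_stratified_folds(ages, k = 5, repeats = 2, seed = 1)

  rep_oracle <- run_cv(ages, plan, "oracle")
  expect_equal(rep_oracle$pooled$mae, 0)
  expect_equal(rep_oracle$pooled$accuracy, 1)

  rep_naive <- run_cv(ages, plan, "naive")
  expect_equal(rep_naive$pooled$sensitivity, 1.0)
  expect_equal(rep_naive$pooled$specificity, 0.0)
  expect_equal(rep_naive$pooled$auc, 0.5)
  # the naive regressor is the training-mean constant predictor;
  # baselines on identical folds agree with it
  expect_equal(rep_naive$pooled$mae,
               mean(abs(unlist(lapply(1:5, function(f) {
                 ages[plan$fold == f] - mean(ages[plan$fold != f])
               })))))

  # identical seeds -> identical reports
  plan_b <- make_repeated_stratified_folds(ages, k = 5, repeats = 2, seed = 1)
  expect_identical(run_cv(ages, plan_b, "naive"), rep_naive)
})
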