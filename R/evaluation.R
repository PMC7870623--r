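# Evaluation metrics and the repeated stratified 5-fold cross-validation
# protocol.  Minors (age strictly under 18) are the positive class.

#' Mean squared error
#' @param y true ages (years).
#' @param y_hat predicted ages.
#' @return mean of squared residuals.
#' @export
mse_metric <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 1)
  mean((y - y_hat)^2)
}

#' Mean absolute error with spread and confidence interval
#'
#' Returns the mean absolute residual, the standard deviation of the
#' absolute residuals, and the normal-approximation 95% confidence interval
#' of the mean (`mae +- 1.96 * sd / sqrt(n)`).
#'
#' @param y true ages (years).
#' @param y_hat predicted ages.
#' @return list with `mae`, `sd`, `ci95` (length-2), `n`.
#' @export
mae_metric <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 1)
  ae <- abs(y - y_hat)
  mae <- mean(ae)
  s <- if (length(ae) > 1) stats::sd(ae) else 0
  half <- 1.96 * s / sqrt(length(ae))
  list(mae = mae, sd = s, ci95 = c(mae - half, mae + half), n = length(ae))
}

#' Confusion counts with minors as positives
#'
#' @param pred_minor predicted minor labels (logical).
#' @param true_minor true minor labels (logical; age < 18).
#' @return list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred_minor, true_minor) {
  stopifnot(length(pred_minor) == length(true_minor))
  pred_minor <- as.logical(pred_minor); true_minor <- as.logical(true_minor)
  list(tp = sum(pred_minor & true_minor),
       tn = sum(!pred_minor & !true_minor),
       fp = sum(pred_minor & !true_minor),
       fn = sum(!pred_minor & true_minor))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Ratios with a zero denominator are reported as `NA` with a warning.
#'
#' @param counts output of [confusion_counts()] (or a list with tp/tn/fp/fn).
#' @return list with `accuracy`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(counts) {
  n <- counts$tp + counts$tn + counts$fp + counts$fn
  if (n == 0) stop("empty confusion counts")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NA_real_)
    }
    num / den
  }
  list(accuracy = (counts$tp + counts$tn) / n,
       sensitivity = ratio(counts$tp, counts$tp + counts$fn, "sensitivity"),
       specificity = ratio(counts$tn, counts$tn + counts$fp, "specificity"))
}

#' Area under the ROC curve
#'
#' Rank-statistic form: the probability that a randomly chosen minor scores
#' above a randomly chosen adult, with ties counted one half.
#'
#' @param scores classifier scores (higher = more likely minor).
#' @param minor true minor labels (logical).
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, minor) {
  minor <- as.logical(minor)
  stopifnot(length(scores) == length(minor))
  np <- sum(minor); nn <- sum(!minor)
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[minor]) - np * (np + 1) / 2) / (np * nn)
}

#' Build a repeated stratified k-fold plan
#'
#' Subjects are binned by age (1-year bins by default, adjacent bins merged
#' until every bin holds at least `k` subjects) and each bin's subjects are
#' spread over the `k` folds round-robin after a seeded shuffle, so every
#' fold's age distribution mirrors the cohort's.  Test folds are pairwise
#' disjoint and jointly exhaustive.  The fold partition is fixed across
#' repeats; each repeat only changes the training seed.
#'
#' @param ages subject ages (years).
#' @param k number of folds (default 5).
#' @param repeats number of repeats (default 10).
#' @param seed seed for the fold assignment; repeat seeds are derived as
#'   `seed + repeat`.
#' @param bin_width stratification bin width in years.
#' @return a `fold_plan`: list with `fold` (per-subject fold id), `k`,
#'   `repeats`, `repeat_seeds`, `bins`.
#' @export
make_repeated_stratified_folds <- function(ages, k = 5L, repeats = 10L,
                                           seed = 1L, bin_width = 1) {
  n <- length(ages)
  if (k > n) stop("more folds than subjects")
  set.seed(seed)
  bins <- floor(ages / bin_width)
  # merge sparse bins upward until every bin holds >= k subjects
  ub <- sort(unique(bins))
  repeat {
    cnt <- table(factor(bins, levels = ub))
    small <- which(cnt < k)
    if (length(small) == 0 || length(ub) == 1) break
    i <- small[1]
    j <- if (i == length(ub)) i - 1 else i + 1
    bins[bins == ub[i]] <- ub[j]
    ub <- sort(unique(bins))
  }
  fold <- integer(n)
  off <- 0L
  for (b in sort(unique(bins))) {
    ib <- which(bins == b)
    ib <- ib[sample.int(length(ib))]
    fold[ib] <- ((seq_along(ib) - 1 + off) %% k) + 1
    off <- off + length(ib)   # stagger so remainders spread over folds
  }
  structure(list(fold = fold, k = as.integer(k),
                 repeats = as.integer(repeats),
                 repeat_seeds = as.integer(seed) + seq_len(repeats),
                 bins = bins),
            class = "fold_plan")
}

#' Run the cross-validated evaluation
#'
#' Executes a subject-level predictor over every fold and repeat of a
#' [make_repeated_stratified_folds()] plan, and reports regression and
#' classification metrics per fold/repeat, pooled over the repeated CV
#' ("rep."), for the best fold ("best": lowest mean MAE for regression,
#' highest mean accuracy for classification), and for the best-available-
#' guess baselines evaluated on the identical folds.
#'
#' @param ages subject ages (years).
#' @param plan a `fold_plan`.
#' @param predictor function `(train_idx, test_idx, seed)` returning a list
#'   with `age` (test-set age predictions) and optionally `score`
#'   (minor-probability scores) and `minor` (hard labels).  Built-in
#'   shortcuts: `"oracle"` (predicts the true age) and `"naive"`
#'   (best-guess mean age + all-minors classifier).
#' @return a `metrics_report`: list with `per_fold` data frame, `pooled`,
#'   `best`, and `baseline` summaries.
#' @export
run_cv <- function(ages, plan, predictor) {
  stopifnot(inherits(plan, "fold_plan"), length(ages) == length(plan$fold))
  if (is.character(predictor)) {
    kind <- match.arg(predictor, c("oracle", "naive"))
    predictor <- if (kind == "oracle") {
      function(train_idx, test_idx, seed) {
        list(age = ages[test_idx],
             score = as.numeric(ages[test_idx] < MINOR_AGE_LIMIT),
             minor = ages[test_idx] < MINOR_AGE_LIMIT)
      }
    } else {
      function(train_idx, test_idx, seed) {
        bg <- best_guess_regressor(ages[train_idx])
        nc <- naive_classifier()
        pm <- predict_minor(nc, matrix(0, length(test_idx), 1))
        list(age = predict_age(bg, matrix(0, length(test_idx), 1)),
             score = pm$score, minor = pm$minor)
      }
    }
  }
  rows <- list()
  abs_err_pool <- numeric()
  for (f in seq_len(plan$k)) {
    test_idx <- which(plan$fold == f)
    train_idx <- which(plan$fold != f)
    true_minor <- ages[test_idx] < MINOR_AGE_LIMIT
    for (r in seq_len(plan$repeats)) {
      pred <- predictor(train_idx, test_idx, plan$repeat_seeds[r])
      mm <- mae_metric(ages[test_idx], pred$age)
      row <- data.frame(fold = f, rep = r, n_test = length(test_idx),
                        mae = mm$mae, sd_abs_err = mm$sd,
                        ci95_lo = mm$ci95[1], ci95_hi = mm$ci95[2],
                        accuracy = NA_real_, sensitivity = NA_real_,
                        specificity = NA_real_, auc = NA_real_)
      if (!is.null(pred$minor) && length(unique(true_minor)) == 2) {
        cm <- classification_metrics(confusion_counts(pred$minor, true_minor))
        row$accuracy <- cm$accuracy
        row$sensitivity <- cm$sensitivity
        row$specificity <- cm$specificity
        row$auc <- auc_score(pred$score, true_minor)
      }
      rows[[length(rows) + 1]] <- row
      abs_err_pool <- c(abs_err_pool, abs(ages[test_idx] - pred$age))
    }
  }
  per_fold <- do.call(rbind, rows)
  pooled_mae <- mean(abs_err_pool)
  half <- 1.96 * stats::sd(abs_err_pool) / sqrt(length(abs_err_pool))
  pooled <- list(mae = pooled_mae, sd_abs_err = stats::sd(abs_err_pool),
                 ci95 = c(pooled_mae - half, pooled_mae + half),
                 accuracy = mean(per_fold$accuracy),
                 sensitivity = mean(per_fold$sensitivity),
                 specificity = mean(per_fold$specificity),
                 auc = mean(per_fold$auc))
  fold_mae <- tapply(per_fold$mae, per_fold$fold, mean)
  fold_acc <- tapply(per_fold$accuracy, per_fold$fold, mean)
  best_reg <- as.integer(names(fold_mae)[which.min(fold_mae)])
  best_cls <- if (all(is.na(fold_acc))) NA_integer_ else
    as.integer(names(fold_acc)[which.max(fold_acc)])
  best <- list(
    regression_fold = best_reg,
    mae = unname(fold_mae[as.character(best_reg)]),
    classification_fold = best_cls,
    accuracy = if (is.na(best_cls)) NA_real_ else
      unname(fold_acc[as.character(best_cls)]))
  # baselines on the identical folds
  base_rows <- list()
  for (f in seq_len(plan$k)) {
    test_idx <- which(plan$fold == f)
    train_idx <- which(plan$fold != f)
    bg <- best_guess_regressor(ages[train_idx])
    yhat <- rep(bg$mean_age, length(test_idx))
    mm <- mae_metric(ages[test_idx], yhat)
    true_minor <- ages[test_idx] < MINOR_AGE_LIMIT
    cls <- if (length(unique(true_minor)) == 2) {
      cm <- classification_metrics(confusion_counts(rep(TRUE, length(test_idx)),
                                                    true_minor))
      c(cm$accuracy, cm$sensitivity, cm$specificity,
        auc_score(rep(1, length(test_idx)), true_minor))
    } else rep(NA_real_, 4)
    base_rows[[f]] <- data.frame(fold = f, mae = mm$mae, sd_abs_err = mm$sd,
                                 accuracy = cls[1], sensitivity = cls[2],
                                 specificity = cls[3], auc = cls[4])
  }
  baseline <- do.call(rbind, base_rows)
  structure(list(per_fold = per_fold, pooled = pooled, best = best,
                 baseline = baseline),
            class = "metrics_report")
}

#' Write a metrics report as CSV and JSON
#'
#' @param report a `metrics_report`.
#' @param prefix output path prefix; writes `<prefix>_per_fold.csv`,
#'   `<prefix>_baseline.csv` and `<prefix>_summary.json`.
#' @return `prefix`, invisibly.
#' @export
write_metrics_report <- function(report, prefix) {
  utils::write.csv(report$per_fold, paste0(prefix, "_per_fold.csv"),
                   row.names = FALSE)
  utils::write.csv(report$baseline, paste0(prefix, "_baseline.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(pooled = report$pooled, best = report$best),
                       paste0(prefix, "_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
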