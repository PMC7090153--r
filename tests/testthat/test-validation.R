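test_that("AUC handles separation, noise and the worked pair count", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1), n_boot = 0)$auc, 1)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), n_boot = 0)$auc,
               0.75)
  set.seed(2)
  res <- roc_auc(runif(300), rbinom(300, 1, 0.3), n_boot = 500, seed = 9L)
  expect_equal(res$auc, 0.5, tolerance = 0.2)
  expect_true(res$ci[1] < res$auc && res$auc < res$ci[2])
  expect_error(roc_auc(1:4, rep(1, 4), n_boot = 0), "classes")
})

test_that("rank AUC equals brute-force pairwise concordance, ties included", {
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(6:50, 1)
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    pred <- sample(round(runif(n, 0, 1), 1))  # coarse grid forces ties
    expect_equal(roc_auc(pred, y, n_boot = 0)$auc, auc_bruteforce(pred, y),
                 tolerance = 1e-12)
  }
})

test_that("the Youden cutoff separates separable groups and matches brute force", {
  yc <- youden_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_gt(yc$cutoff, 0.2); expect_lt(yc$cutoff, 0.8)
  expect_equal(yc$J, 1)
  expect_warning(deg <- youden_cutoff(rep(0.4, 6), c(0, 0, 0, 1, 1, 1)),
                 "degenerate")
  expect_equal(deg$J, 0)
  set.seed(21)
  for (rep in 1:15) {
    y <- rbinom(20, 1, 0.4)
    if (length(unique(y)) < 2) next
    v <- round(runif(20), 2)
    expect_equal(youden_cutoff(v, y)$J, youden_bruteforce(v, y),
                 tolerance = 1e-9)
  }
})

test_that("Youden ties break toward higher specificity", {
  # thresholds 1.5 and 3.5 reach the same J; the larger one must win
  v <- c(1, 2, 3, 4)
  y <- c(0, 1, 0, 1)
  yc <- youden_cutoff(v, y)
  expect_equal(yc$cutoff, 3.5)
  expect_equal(yc$spec, 1)
})

test_that("accuracy and balanced accuracy follow the confusion arithmetic", {
  perfect <- accuracies(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), 0.5)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$balanced_accuracy, 1)
  # TP=10, TN=80, FP=5, FN=5
  pred <- c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 80))
  y <- c(rep(1, 15), rep(0, 85))
  acc <- accuracies(pred, y, 0.5)
  expect_equal(acc$accuracy, 0.90)
  expect_equal(acc$balanced_accuracy, (10 / 15 + 80 / 85) / 2)
  # all-negative prediction at 9% prevalence: high accuracy, chance balance
  n1 <- 15; n0 <- 151
  acc2 <- accuracies(rep(0, n0 + n1), c(rep(1, n1), rep(0, n0)), 0.5)
  expect_equal(acc2$accuracy, n0 / (n0 + n1))
  expect_equal(acc2$balanced_accuracy, 0.5)
  expect_error(accuracies(pred, y, Inf), "finite")
})

test_that("calibration recovers the identity line and flags miscalibration", {
  set.seed(33)
  p <- runif(4000, 0.02, 0.6)
  y <- rbinom(4000, 1, p)
  cal <- calibration(p, y, n_bins = 8)
  expect_equal(cal$slope, 1, tolerance = 2.5 * cal$slope_se / 1)
  expect_lt(abs(cal$intercept), 2.5 * cal$intercept_se + 0.02)
  expect_error(calibration(rep(0.3, 100), rbinom(100, 1, 0.3)), "bins")
  # squared predictions are visibly miscalibrated
  cal2 <- calibration(p^2, y, n_bins = 8)
  expect_gt(abs(cal2$slope - 1), 2 * cal2$slope_se)
})

test_that("leave-one-out reruns the pipeline per fold and is reproducible", {
  set.seed(44)
  n <- 30
  x <- rnorm(n)
  y <- rbinom(n, 1, stats::plogis(-1 + 2 * x))
  if (length(unique(y)) < 2) y[1:3] <- c(0L, 1L, 1L)
  fit_fun <- function(train) stats::glm(y[train] ~ x[train],
                                        family = stats::binomial())
  pred_fun <- function(fit, i) {
    stats::plogis(sum(stats::coef(fit) * c(1, x[i])))
  }
  p1 <- loo_predict(fit_fun, pred_fun, n, y)
  p2 <- loo_predict(fit_fun, pred_fun, n, y)
  expect_identical(p1, p2)                 # bit-for-bit reproducible
  expect_length(p1, n)
  # a constant-model pipeline gives LOO predictions equal to refitted means
  const_pred <- loo_predict(function(train) mean(y[train]),
                            function(fit, i) fit, n, y)
  expect_equal(const_pred[1], mean(y[-1]))
  expect_error(loo_predict(function(t) 1, function(f, i) 1, 2, c(0, 1)),
               ">= 3")
})

test_that("leave-one-out recomputes variable selection inside each fold", {
  set.seed(46)
  n <- 40
  vars <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, 0.35)
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  seen <- character(0)
  p <- loo_predict(function(train) {
    sc <- suppressWarnings(univariable_screen(vars[train, ], y[train],
                                              p_enter = 0.7))
    kp <- collinearity_filter(sc, vars[train, ])
    seen <<- c(seen, paste(kp, collapse = "+"))
    fit_logistic_ntcp(vars[train, ], y[train], candidates = kp,
                      p_enter = 0.7)
  }, function(fit, i) predict(fit, vars[i, , drop = FALSE]), n, y)
  # on a null cohort the per-fold screen must not be frozen: fold-to-fold
  # variation in the screened set is evidence it is recomputed
  expect_gt(length(unique(seen)), 1)
})

test_that("fold failures from vanished events are excluded with a warning", {
  n <- 10
  y <- c(1L, rep(0L, n - 1))
  expect_warning(
    p <- loo_predict(function(train) mean(y[train]),
                     function(fit, i) fit, n, y),
    "failed")
  expect_true(is.na(p[1]))
  expect_identical(attr(p, "failed"), 1L)
})

test_that("the validation report bundles discrimination and calibration", {
  set.seed(50)
  p <- runif(400, 0, 0.5)
  y <- rbinom(400, 1, p)
  rep <- validation_report(p, y, n_boot = 300)
  expect_gt(rep$auc, 0.5)
  expect_length(rep$auc_ci, 2)
  expect_true(rep$balanced_accuracy >= 0 && rep$balanced_accuracy <= 1)
  expect_false(is.null(rep$calibration))
})
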