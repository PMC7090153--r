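#' ROC area under the curve with bootstrap CI
#'
#' AUC by the rank (Mann-Whitney) formulation with midranks for ties; the
#' 95% CI is obtained from stratified bootstrap percentiles (resampling
#' events and non-events separately).
#'
#' @param pred predicted scores or probabilities
#' @param y 0/1 outcomes, both classes present
#' @param n_boot bootstrap replicates (0 skips the CI)
#' @param seed bootstrap seed
#' @return list with `auc` and `ci` (length 2, or NULL)
#' @export
roc_auc <- function(pred, y, n_boot = 2000L, seed = 1L) {
  y <- as.integer(y)
  if (all(y == 0L) || all(y == 1L)) stop("both outcome classes required")
  auc <- auc_rank(pred, y)
  ci <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    i1 <- which(y == 1L); i0 <- which(y == 0L)
    reps <- vapply(seq_len(n_boot), function(b) {
      s <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
      auc_rank(pred[s], y[s])
    }, numeric(1))
    ci <- unname(stats::quantile(reps, c(0.025, 0.975)))
  }
  list(auc = auc, ci = ci)
}

auc_rank <- function(pred, y) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  r <- rank(pred)  # midranks for ties
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-J optimal cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 over midpoints of adjacent
#' distinct observed values (classification rule: value > cutoff is
#' positive). Ties in J are broken toward higher specificity, i.e. the
#' larger cutoff. If all values coincide the cutoff is degenerate and a
#' warning is raised.
#'
#' @param values metric or probability values
#' @param y 0/1 outcomes, both classes present
#' @return list with `cutoff`, `J`, `sens`, `spec`
#' @export
youden_cutoff <- function(values, y) {
  y <- as.integer(y)
  if (all(y == 0L) || all(y == 1L)) stop("both outcome classes required")
  v <- sort(unique(values))
  if (length(v) == 1L) {
    warning("all values identical: degenerate cutoff")
    return(list(cutoff = v, J = 0, sens = 1, spec = 0))
  }
  cand <- (utils::head(v, -1) + utils::tail(v, -1)) / 2
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  stats <- vapply(cand, function(ct) {
    sens <- sum(values > ct & y == 1L) / n1
    spec <- sum(values <= ct & y == 0L) / n0
    c(sens + spec - 1, sens, spec)
  }, numeric(3))
  best <- max(stats[1, ])
  idx <- which(stats[1, ] >= best - 1e-12)
  pick <- idx[length(idx)]  # larger cutoff = higher specificity
  list(cutoff = cand[pick], J = stats[1, pick],
       sens = stats[2, pick], spec = stats[3, pick])
}

#' Accuracy and balanced accuracy at a cutoff
#'
#' @param pred predicted values
#' @param y 0/1 outcomes
#' @param cutoff classification threshold (`pred > cutoff` is positive)
#' @return list with `accuracy`, `balanced_accuracy`, `sens`, `spec`
#' @export
accuracies <- function(pred, y, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  y <- as.integer(y)
  pos <- pred > cutoff
  tp <- sum(pos & y == 1L); tn <- sum(!pos & y == 0L)
  sens <- if (any(y == 1L)) tp / sum(y == 1L) else NA_real_
  spec <- if (any(y == 0L)) tn / sum(y == 0L) else NA_real_
  list(accuracy = (tp + tn) / length(y),
       balanced_accuracy = (sens + spec) / 2,
       sens = sens, spec = spec)
}

#' Calibration summary of predicted probabilities
#'
#' Groups patients into equal-count bins by predicted probability and
#' regresses the observed event fraction on the mean prediction by weighted
#' least squares (weights = bin counts), giving the calibration slope and
#' intercept with standard errors; per-bin 68% Wilson intervals are
#' returned for plotting.
#'
#' @param pred predicted probabilities
#' @param y 0/1 outcomes
#' @param n_bins number of equal-count bins (default 5)
#' @return list with `slope`, `slope_se`, `intercept`, `intercept_se`,
#'   `bins` (per-bin table)
#' @export
calibration <- function(pred, y, n_bins = 5L) {
  y <- as.integer(y)
  ord <- order(pred)
  grp <- ceiling(seq_along(pred) / (length(pred) / n_bins))
  grp <- grp[rank(pred, ties.method = "first")]
  tab <- data.frame(
    n = as.integer(table(grp)),
    mean_pred = as.numeric(tapply(pred, grp, mean)),
    obs_frac = as.numeric(tapply(y, grp, mean)))
  tab <- tab[tab$n > 0, , drop = FALSE]
  if (length(unique(tab$mean_pred)) < 2L)
    stop("fewer than 2 distinct non-empty calibration bins")
  wil <- t(vapply(seq_len(nrow(tab)), function(i) {
    wilson_interval(round(tab$obs_frac[i] * tab$n[i]), tab$n[i], 0.68)
  }, numeric(2)))
  tab$lo68 <- wil[, 1]; tab$hi68 <- wil[, 2]
  fit <- stats::lm(obs_frac ~ mean_pred, data = tab, weights = tab$n)
  cf <- summary(fit)$coefficients
  list(slope = cf[2, 1], slope_se = cf[2, 2],
       intercept = cf[1, 1], intercept_se = cf[1, 2],
       bins = tab)
}

wilson_interval <- function(k, n, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Leave-one-out predictions of a full modeling pipeline
#'
#' For each patient the entire pipeline — screening, selection, fitting,
#' whatever `fit_fun` encapsulates — is re-run on the cohort without that
#' patient, and the held-out patient is predicted. Folds whose training set
#' loses its last event are recorded as failures and excluded with a
#' warning.
#'
#' @param fit_fun function(train_idx) returning a fitted object
#' @param predict_fun function(fit, test_idx) returning the held-out
#'   prediction
#' @param n cohort size (>= 3)
#' @param y 0/1 outcomes (used to detect degenerate folds)
#' @return numeric predictions, NA for failed folds; attribute `failed`
#'   lists failed fold indices
#' @export
loo_predict <- function(fit_fun, predict_fun, n, y) {
  if (n < 3L) stop("leave-one-out needs >= 3 patients")
  y <- as.integer(y)
  pred <- rep(NA_real_, n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    if (length(unique(y[train])) < 2L) {
      failed <- c(failed, i)
      next
    }
    fit <- try(fit_fun(train), silent = TRUE)
    if (inherits(fit, "try-error")) {
      failed <- c(failed, i)
      next
    }
    pred[i] <- predict_fun(fit, i)
  }
  if (length(failed))
    warning(sprintf("%d leave-one-out folds failed and were excluded",
                    length(failed)))
  attr(pred, "failed") <- failed
  pred
}

#' Validation report for a set of predictions
#'
#' Bundles the discrimination and calibration summaries reported for an
#' NTCP model: AUC with bootstrap CI, accuracy and balanced accuracy at the
#' Youden cutoff derived from the same predictions, and the calibration
#' slope/intercept.
#'
#' @param pred predicted probabilities
#' @param y 0/1 outcomes
#' @param n_bins calibration bins
#' @param n_boot AUC bootstrap replicates
#' @param seed bootstrap seed
#' @return a `validation_report` list
#' @export
validation_report <- function(pred, y, n_bins = 5L, n_boot = 2000L,
                              seed = 1L) {
  keep <- !is.na(pred)
  pred <- pred[keep]; y <- as.integer(y)[keep]
  roc <- roc_auc(pred, y, n_boot = n_boot, seed = seed)
  yc <- youden_cutoff(pred, y)
  acc <- accuracies(pred, y, yc$cutoff)
  cal <- try(calibration(pred, y, n_bins), silent = TRUE)
  if (inherits(cal, "try-error")) cal <- NULL
  structure(list(auc = roc$auc, auc_ci = roc$ci,
                 cutoff = yc$cutoff, youden_j = yc$J,
                 accuracy = acc$accuracy,
                 balanced_accuracy = acc$balanced_accuracy,
                 calibration = cal, n = length(y), events = sum(y)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> n = %d (%d events)\n", x$n, x$events))
  cat(sprintf("  AUC = %.3f%s\n", x$auc,
              if (!is.null(x$auc_ci))
                sprintf(" [%.3f, %.3f]", x$auc_ci[1], x$auc_ci[2]) else ""))
  cat(sprintf("  cutoff (Youden) = %.4g, accuracy = %.3f, balanced = %.3f\n",
              x$cutoff, x$accuracy, x$balanced_accuracy))
  if (!is.null(x$calibration))
    cat(sprintf("  calibration slope = %.3f +/- %.3f, intercept = %.4f +/- %.4f\n",
                x$calibration$slope, x$calibration$slope_se,
                x$calibration$intercept, x$calibration$intercept_se))
  invisible(x)
}
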