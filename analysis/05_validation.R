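#!/usr/bin/env Rscript

# Internal validation of both NTCP models: training-set performance and
# leave-one-out cross-validation of the full pipeline (screening +
# selection + fitting per fold), with ROC AUC, Youden cutoffs, accuracy,
# balanced accuracy and calibration. Reads results/ from the earlier
# steps; writes results/validation.json and a text performance table.

suppressPackageStartupMessages(library(skinNTCP))
stopifnot(file.exists("results/cohort.csv"))

cov <- read.csv("results/cohort.csv")
curves <- read_dsh_tsv("results/dsh_curves.tsv")
y <- cov$g3_rd
n <- length(y)

vars <- cov[, c("age_yr", "gtv_cm3", "weight_kg", "height_cm", "bsa_m2",
                paste0("S_", c(5, 10, 15, 20, 25, 30, 35, 40, 45)),
                "gender", "side", "lobe", "modality", "smoking")]

## training fits
lkb <- fit_lkb(curves, y)
screen <- suppressWarnings(univariable_screen(vars, y))
kept <- collinearity_filter(screen, vars)
logistic <- fit_logistic_ntcp(vars, y, candidates = kept)

train_lkb <- validation_report(predict(lkb, curves), y, seed = 5L)
train_log <- validation_report(predict(logistic, vars), y, seed = 5L)

## leave-one-out over the whole pipelines
loo_lkb <- loo_predict(
  fit_fun = function(tr) fit_lkb(curves[tr], y[tr], n_starts = 3L),
  predict_fun = function(fit, i) predict(fit, curves[[i]]),
  n = n, y = y)
loo_log <- loo_predict(
  fit_fun = function(tr) {
    sc <- suppressWarnings(univariable_screen(vars[tr, ], y[tr]))
    kp <- collinearity_filter(sc, vars[tr, ])
    fit_logistic_ntcp(vars[tr, ], y[tr], candidates = kp)
  },
  predict_fun = function(fit, i) predict(fit, vars[i, , drop = FALSE]),
  n = n, y = y)

cv_lkb <- validation_report(loo_lkb, y, seed = 6L)
cv_log <- validation_report(loo_log, y, seed = 6L)

# metric-scale Youden cutoff for the selected surface metric
s20_cut <- youden_cutoff(cov$S_20, y)

fmt <- function(r) {
  sprintf("AUC %.2f [%.2f, %.2f]  acc %.2f  bal-acc %.2f  cal slope %s",
          r$auc, r$auc_ci[1], r$auc_ci[2], r$accuracy, r$balanced_accuracy,
          if (is.null(r$calibration)) "-" else
            sprintf("%.2f +/- %.2f", r$calibration$slope,
                    r$calibration$slope_se))
}
lines <- c(
  sprintf("n = %d, events = %d", n, sum(y)),
  paste("LKB      train:", fmt(train_lkb)),
  paste("LKB      LOO:  ", fmt(cv_lkb)),
  paste("logistic train:", fmt(train_log)),
  paste("logistic LOO:  ", fmt(cv_log)),
  sprintf("Youden S_20Gy cutoff: %.2f%% of BSA (J = %.2f)",
          s20_cut$cutoff, s20_cut$J))
writeLines(lines)
writeLines(lines, "results/performance_table.txt")

report <- list(
  training = list(lkb = unclass(train_lkb), logistic = unclass(train_log)),
  loo = list(lkb = unclass(cv_lkb), logistic = unclass(cv_log)),
  s20_cutoff_pct_bsa = s20_cut$cutoff)
jsonlite::write_json(report, "results/validation.json", auto_unbox = TRUE,
                     digits = NA, force = TRUE)
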