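#!/usr/bin/env Rscript

# NTCP model fitting on the simulated cohort: the DSH-recast LKB model by
# Nelder-Mead maximum likelihood with profile-likelihood 95% CIs, and the
# multivariable stepwise logistic model on the screened, collinearity-
# filtered candidates. Reads results/ from analysis/01 and /03; writes
# results/lkb_fit.json and results/logistic_fit.json.

suppressPackageStartupMessages(library(skinNTCP))
stopifnot(file.exists("results/cohort.csv"))

cov <- read.csv("results/cohort.csv")
curves <- read_dsh_tsv("results/dsh_curves.tsv")
y <- cov$g3_rd

lkb <- fit_lkb(curves, y)
cis <- lapply(c(td50 = "td50", m = "m", n = "n"), function(p) {
  as.numeric(suppressWarnings(profile_ci(lkb, p)))
})
cat(sprintf("LKB: TD50 = %.2f Gy [%.2f, %.2f], m = %.3f [%.3f, %.3f], n = %.3f [%.3f, %.3f]\n",
            lkb$td50, cis$td50[1], cis$td50[2],
            lkb$m, cis$m[1], cis$m[2], lkb$n, cis$n[1], cis$n[2]))
jsonlite::write_json(list(td50 = lkb$td50, m = lkb$m, n = lkb$n,
                          loglik = lkb$loglik, ci95 = cis),
                     "results/lkb_fit.json", auto_unbox = TRUE, digits = NA)

vars <- cov[, c("age_yr", "gtv_cm3", "weight_kg", "height_cm", "bsa_m2",
                paste0("S_", c(5, 10, 15, 20, 25, 30, 35, 40, 45)),
                "gender", "side", "lobe", "modality", "smoking")]
screen <- suppressWarnings(univariable_screen(vars, y))
kept <- collinearity_filter(screen, vars)
logistic <- fit_logistic_ntcp(vars, y, candidates = kept)
print(logistic)
jsonlite::write_json(list(selected = logistic$selected,
                          intercept = logistic$intercept,
                          intercept_se = logistic$intercept_se,
                          or = logistic$or, loglik = logistic$loglik,
                          trace = logistic$trace),
                     "results/logistic_fit.json", auto_unbox = TRUE,
                     digits = NA)
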