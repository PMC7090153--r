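test_that("Mann-Whitney handles identical, separated and degenerate input", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3)), 1, tolerance = 1e-9)
  expect_equal(mann_whitney(c(1, 2, 3), c(10, 11, 12)), 0.1, tolerance = 1e-9)
  set.seed(1)
  expect_lt(mann_whitney(rnorm(200), rnorm(200) + 2), 1e-3)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("the exact Mann-Whitney branch matches full enumeration", {
  set.seed(42)
  for (rep in 1:20) {
    n0 <- sample(2:5, 1); n1 <- sample(2:5, 1)
    x0 <- round(runif(n0, 0, 100), 3)
    x1 <- round(runif(n1, 0, 100) + runif(1, -20, 20), 3)
    expect_equal(mann_whitney(x0, x1), mw_bruteforce(x0, x1),
                 tolerance = 1e-9)
  }
})

test_that("categorical tests pick Fisher under Cochran's rule", {
  flat <- matrix(c(10, 10, 10, 10), 2)
  res <- categorical_test(flat)
  expect_equal(res$p, 1)
  # smoking-style table: a small expected cell triggers Fisher, p near 1
  smoking <- matrix(c(12, 139, 1, 14), 2, byrow = TRUE)
  res2 <- categorical_test(t(smoking))
  expect_identical(res2$test, "fisher")
  expect_gt(res2$p, 0.95)
  expect_error(categorical_test(matrix(c(0, 0, 3, 5), 2)), "margin")
})

test_that("Fisher branch equals hypergeometric enumeration for small tables", {
  set.seed(7)
  checked <- 0
  while (checked < 25) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || sum(tab) > 40) next
    res <- categorical_test(tab)
    if (res$test != "fisher") next
    expect_equal(res$p, fisher_bruteforce(tab), tolerance = 1e-9)
    checked <- checked + 1
  }
})

test_that("pointwise DSH comparison flags separation and nothing else", {
  set.seed(3)
  a <- matrix(rnorm(20 * 30), 20)
  res <- pointwise_dsh_test(a, a)
  expect_true(all(res$p == 1))
  b <- a[1:10, ] + 5
  res2 <- pointwise_dsh_test(a, b)
  expect_true(all(res2$p < 1e-6))
  expect_error(pointwise_dsh_test(a[1, , drop = FALSE], a), ">= 2")
  expect_error(pointwise_dsh_test(a, a[, 1:5]), "differ")
})

test_that("pointwise test holds its size under the null", {
  set.seed(8)
  hits <- replicate(400, {
    a <- matrix(rnorm(15 * 10), 15)
    b <- matrix(rnorm(15 * 10), 15)
    mean(pointwise_dsh_test(a, b)$p < 0.05)
  })
  expect_equal(mean(hits), 0.05, tolerance = 0.35)
})

test_that("Holm-Sidak thresholds follow the step-down formula", {
  expect_identical(holm_sidak(0.049), TRUE)
  expect_identical(holm_sidak(0.051), FALSE)
  p <- c(0.001, 0.02, 0.04)
  # thresholds 1-(1-a)^(1/3), 1-(1-a)^(1/2), a: 0.01695, 0.02532, 0.05
  expect_identical(holm_sidak(p), c(TRUE, TRUE, TRUE))
  expect_identical(holm_sidak(c(0.001, 0.03, 0.04)),
                   c(TRUE, FALSE, FALSE))  # 0.03 > 0.02532 stops the walk
  expect_identical(holm_sidak(rep(0.9, 5)), rep(FALSE, 5))
  expect_error(holm_sidak(c(0.2, 1.2)), "\\[0, 1\\]")
})

test_that("Holm-Sidak controls the family-wise error under a global null", {
  set.seed(12)
  m <- 60
  n_rep <- 2000
  fwer_hits <- replicate(n_rep, {
    a <- matrix(rnorm(12 * m), 12)
    b <- matrix(rnorm(12 * m), 12)
    any(holm_sidak(pointwise_dsh_test(a, b)$p))
  })
  fwer <- mean(fwer_hits)
  mc_se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(fwer, 0.05 + 2 * mc_se)
})

test_that("univariable screening finds the dosimetric family and drops constants", {
  set.seed(2)
  curves <- sample_dsh_curves(166, seed = 55L)
  mets <- lapply(curves, extract_metrics)
  vars <- data.frame(S_10 = vapply(mets, s_metric, numeric(1), 10),
                     S_20 = vapply(mets, s_metric, numeric(1), 20),
                     age = rnorm(166, 65, 9),
                     gender = sample(c("M", "F"), 166, replace = TRUE),
                     fixed = rep(1, 166))
  y <- simulate_outcomes(stats::plogis(-6.34 + log(31.4) * vars$S_20),
                         seed = 56L)
  expect_warning(res <- univariable_screen(vars, y), "constant")
  expect_true(all(c("S_20", "S_10") %in% res$variable[res$pass]))
  expect_false("fixed" %in% res$variable)
  expect_error(univariable_screen(vars[, 1:2], rep(0L, 166)), "single class")
})

test_that("screening passes about alpha of unrelated variables under the null", {
  set.seed(77)
  m <- 12
  pass_counts <- replicate(60, {
    vars <- as.data.frame(matrix(rnorm(80 * m), 80))
    y <- rbinom(80, 1, 0.3)
    if (length(unique(y)) < 2 || min(table(y)) < 2) return(NA)
    sum(univariable_screen(vars, y)$pass)
  })
  expect_equal(mean(pass_counts, na.rm = TRUE), 0.1 * m, tolerance = 0.45)
})

test_that("the collinearity filter keeps one representative per family", {
  set.seed(4)
  base <- rnorm(120)
  vars <- data.frame(S_15 = base + rnorm(120, 0, 0.1),
                     S_20 = base + rnorm(120, 0, 0.05),
                     S_25 = base + rnorm(120, 0, 0.1),
                     indep = rnorm(120))
  y <- rbinom(120, 1, stats::plogis(-2 + 1.5 * vars$S_20))
  screen <- data.frame(variable = c("S_20", "S_15", "S_25", "indep"),
                       test = "mann-whitney",
                       p = c(0.001, 0.004, 0.007, 0.02),
                       pass = TRUE)
  kept <- collinearity_filter(screen, vars)
  expect_identical(kept, c("S_20", "indep"))
  # invariant to the input row order
  kept2 <- collinearity_filter(screen[c(3, 1, 4, 2), ], vars)
  expect_identical(kept2, kept)
  empty <- screen[screen$p > 1, ]
  expect_identical(collinearity_filter(empty, vars), character(0))
})
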