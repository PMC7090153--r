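test_that("gEUD obeys the uniform-dose identity and closed-form cases", {
  edges <- seq(0, 30, 1e-3)
  uni <- dsh(edges, ifelse(edges < 25, 3.2, 0), "relative")
  for (n in c(0.1, 0.62, 1, 1.8)) {
    expect_equal(geud(uni, n), 25, tolerance = 1e-3)
  }
  # two-level surface: s = (0.5, 0.5), d = (10, 20), n = 0.5 -> sqrt(250)
  e2 <- seq(0, 25, 1e-3)
  two <- dsh(e2, ifelse(e2 < 10, 2, ifelse(e2 < 20, 1, 0)), "relative")
  expect_equal(geud(two, 0.5), sqrt(250), tolerance = 1e-3)
  expect_equal(geud(two, 1), 15, tolerance = 1e-3)  # n = 1: mean dose
  expect_error(geud(two, 0), "positive")
})

test_that("gEUD interpolates between max dose and mean as n grows", {
  cv <- sample_dsh_curves(1, seed = 5L)[[1]]
  ns <- c(0.05, 0.1, 0.3, 0.62, 1, 1.5, 2)
  gs <- vapply(ns, function(n) geud(cv, n), numeric(1))
  expect_true(all(diff(gs) <= 1e-9))  # non-increasing in n
  expect_lte(gs[1], max(cv$edges[cv$area > 0]))
  expect_equal(gs[ns == 1], extract_metrics(cv)$Dmean, tolerance = 0.01)
})

test_that("histogram gEUD matches the direct surface power-sum oracle", {
  ph <- sphere_phantom(R_mm = 30, spacing = 2)
  d <- dim(ph$truth$data)
  g <- skinNTCP:::grid_coords(d, ph$truth$spacing)
  dz <- array(rep(30 * g$z / max(g$z), each = d[1] * d[2]), d)
  dose <- image_volume(dz, ph$truth$spacing, units = "Gy")
  h <- normalize_dsh(compute_dsh(dose, ph$truth), compute_bsa(80, 176))
  for (n in c(0.3, 0.62, 1)) {
    expect_equal(geud(h, n), geud_faces(dose, ph$truth, n), tolerance = 0.01)
  }
})

test_that("the LKB probit hits its anchor points", {
  expect_equal(lkb_ntcp(9.5, 9.5, 0.24), 0.5)
  expect_equal(lkb_ntcp(11.78, 9.5, 0.24), pnorm(1), tolerance = 1e-3)
  expect_equal(lkb_ntcp(0, 9.5, 0.24), pnorm(-1 / 0.24))
  expect_error(lkb_ntcp(5, -1, 0.24), "positive")
  expect_error(lkb_ntcp(5, 9.5, 0), "positive")
})

test_that("the Bernoulli log-likelihood matches direct arithmetic", {
  expect_equal(ntcp_loglik(c(1, 0, 1), c(1, 0, 1)), 0, tolerance = 1e-9)
  expect_equal(ntcp_loglik(rep(0.5, 10), rep(c(0, 1), 5)), 10 * log(0.5))
  p <- c(0.2, 0.7, 0.05)
  y <- c(0, 1, 1)
  expect_equal(ntcp_loglik(p, y),
               log(0.8) + log(0.7) + log(0.05), tolerance = 1e-12)
  expect_error(ntcp_loglik(c(0.5, 0.5), 1), "lengths")
})

test_that("LKB fits are invariant to duplication and permutation", {
  curves <- sample_dsh_curves(60, seed = 14L)
  g <- vapply(curves, geud, numeric(1), 0.62)
  y <- simulate_outcomes(lkb_ntcp(g, 9.5, 0.24), seed = 15L)
  if (all(y == 0)) y[which.max(g)] <- 1L
  f1 <- fit_lkb(curves, y, n_starts = 3L)
  f2 <- fit_lkb(c(curves, curves), c(y, y), n_starts = 3L)
  expect_equal(f2$td50, f1$td50, tolerance = 0.01)
  expect_equal(f2$n, f1$n, tolerance = 0.05)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 0.01)
  perm <- sample(seq_along(y))
  f3 <- fit_lkb(curves[perm], y[perm], n_starts = 3L)
  expect_equal(f3$loglik, f1$loglik, tolerance = 1e-6)
  expect_error(fit_lkb(curves, rep(0L, 60)), "degenerate")
})

test_that("multi-start optima agree on the best log-likelihood", {
  curves <- sample_dsh_curves(120, seed = 18L)
  g <- vapply(curves, geud, numeric(1), 0.62)
  y <- simulate_outcomes(lkb_ntcp(g, 9.5, 0.24), seed = 19L)
  f <- fit_lkb(curves, y)
  top <- sort(f$starts$loglik, decreasing = TRUE)
  # several independent starts reach the same optimum
  expect_gte(sum(top > f$loglik - 1e-4), 3)
  expect_equal(max(top), f$loglik, tolerance = 1e-9)
})

test_that("profile CIs collapse at level 0 and match the Gaussian limit", {
  curves <- sample_dsh_curves(800, seed = 23L)
  g <- vapply(curves, geud, numeric(1), 0.62)
  y <- simulate_outcomes(lkb_ntcp(g, 9.5, 0.24), seed = 24L)
  f <- fit_lkb(curves, y, n_starts = 3L)
  expect_equal(profile_ci(f, "td50", level = 0), rep(f$td50, 2))
  ci <- profile_ci(f, "td50")
  expect_lt(ci[1], f$td50); expect_gt(ci[2], f$td50)
  # large-sample Gaussian limit: profile CI ~ MLE +/- 1.96 SE (numerical
  # Hessian of the log-likelihood in the original parameter scale)
  nll <- function(p) -lkb_loglik(list(td50 = p[1], m = p[2], n = p[3]),
                                 curves, y)
  hess <- stats::optimHess(c(f$td50, f$m, f$n), nll)
  se <- sqrt(diag(solve(hess)))[1]
  expect_equal(ci[1], f$td50 - 1.96 * se, tolerance = 0.15)
  expect_equal(ci[2], f$td50 + 1.96 * se, tolerance = 0.15)
})

test_that("an uninformative parameter direction yields an open profile bound", {
  # all curves identical: n is unidentified, its profile is flat
  cv <- sample_dsh_curves(1, seed = 30L)[[1]]
  curves <- rep(list(cv), 40)
  y <- c(rep(1L, 8), rep(0L, 32))
  f <- fit_lkb(curves, y, n_starts = 2L)
  ci <- suppressWarnings(profile_ci(f, "n"))
  expect_true(any(attr(ci, "open")))
  expect_equal(as.numeric(ci), f$box$n, tolerance = 1e-6)
})

test_that("LKB predictions respect the TD50 anchor and monotonicity", {
  f <- structure(list(td50 = 9.5, m = 0.24, n = 0.62), class = "lkb_fit")
  edges <- seq(0, 30, 1e-3)
  uni <- dsh(edges, ifelse(edges < f$td50, 3, 0), "relative")
  expect_equal(predict(f, uni), 0.5, tolerance = 1e-3)
  curves <- sample_dsh_curves(30, seed = 40L)
  p <- predict(f, curves)
  gg <- vapply(curves, geud, numeric(1), f$n)
  expect_true(all(diff(p[order(gg)]) >= -1e-12))
})
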