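#' Generalized equivalent uniform dose of a DSH
#'
#' Surface-weighted power mean of the dose: `gEUD = (sum_i s_i d_i^(1/n))^n`
#' with differential surface fractions `s_i` normalized to sum to one over
#' the in-scan skin surface and `d_i` the dose bin centers. `n = 1` gives
#' the surface mean dose; small `n` approaches the maximum dose. The
#' normalization over the segmented surface (not BSA) preserves the
#' uniform-dose identity `gEUD(uniform D) = D` that the TD50 definition of
#' the LKB model assumes; set `weights = "bsa"` for the alternative reading.
#'
#' @param x a `dsh` (any flavor)
#' @param n surface-effect exponent (> 0)
#' @param weights `"surface"` (default) or `"bsa"` (relative flavor only)
#' @return gEUD in Gy
#' @export
geud <- function(x, n, weights = c("surface", "bsa")) {
  weights <- match.arg(weights)
  stopifnot(inherits(x, "dsh"))
  if (n <= 0) stop("gEUD exponent n must be positive")
  if (length(x$edges) < 2L) stop("DSH is empty")
  sd <- dsh_differential(x)
  denom <- if (weights == "surface") sum(sd$s) else {
    if (x$flavor != "relative") stop("BSA weights require a relative DSH")
    100
  }
  if (denom <= 0) return(0)
  w <- sd$s / denom
  (sum(w * sd$d^(1 / n)))^n
}

# Differential representation of a cumulative DSH: mass per bin at the bin
# center, plus any residual area at the last edge.
dsh_differential <- function(x) {
  s <- -diff(x$area)
  d <- (utils::head(x$edges, -1) + utils::tail(x$edges, -1)) / 2
  last <- x$area[length(x$area)]
  if (last > 0) {
    s <- c(s, last)
    d <- c(d, x$edges[length(x$edges)])
  }
  keep <- s > 0
  list(s = s[keep], d = d[keep])
}

#' LKB probit dose-response
#'
#' `NTCP = pnorm((gEUD - TD50) / (m * TD50))`: TD50 is the uniform dose to
#' the whole surface giving 50% complication probability, m is inversely
#' proportional to the slope at TD50.
#'
#' @param geud_gy gEUD values, Gy
#' @param td50 Gy (> 0)
#' @param m slope parameter (> 0)
#' @return complication probabilities
#' @export
lkb_ntcp <- function(geud_gy, td50, m) {
  if (td50 <= 0 || m <= 0) stop("TD50 and m must be positive")
  stats::pnorm((geud_gy - td50) / (m * td50))
}

#' Bernoulli log-likelihood of an NTCP model
#'
#' @param p predicted probabilities
#' @param y observed 0/1 outcomes
#' @param clip probability clipping bound for numerical stability
#' @return sum of per-patient log-likelihood contributions
#' @export
ntcp_loglik <- function(p, y, clip = 1e-12) {
  if (length(p) != length(y)) stop("probability and outcome lengths differ")
  p <- pmin(pmax(p, clip), 1 - clip)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' LKB log-likelihood over a cohort of DSHs
#'
#' @param params list or vector with `td50`, `m`, `n`
#' @param curves list of `dsh` objects
#' @param y 0/1 outcomes
#' @return log-likelihood value
#' @export
lkb_loglik <- function(params, curves, y) {
  params <- as.list(params)
  g <- vapply(curves, function(cv) geud(cv, params$n), numeric(1))
  ntcp_loglik(lkb_ntcp(g, params$td50, params$m), y)
}

# Precompute the differential surface matrix of a cohort on a common dose
# support so the likelihood is a matrix-vector product per evaluation.
cohort_dsh_matrix <- function(curves) {
  reps <- lapply(curves, dsh_differential)
  d_all <- sort(unique(unlist(lapply(reps, `[[`, "d"))))
  S <- matrix(0, length(curves), length(d_all))
  for (i in seq_along(reps)) {
    idx <- match(reps[[i]]$d, d_all)
    tot <- sum(reps[[i]]$s)
    if (tot > 0) S[i, idx] <- reps[[i]]$s / tot
  }
  list(S = S, d = d_all)
}

#' Maximum-likelihood fit of the DSH-recast LKB model
#'
#' Maximizes the Bernoulli log-likelihood over (TD50, m, n) by Nelder-Mead
#' in log-parameter space from a log-spaced multi-start grid, within the box
#' TD50 in \[0.5, 200\] Gy, m in \[0.01, 2\], n in \[0.01, 2\].
#'
#' @param curves list of `dsh` objects (one per patient)
#' @param y 0/1 outcomes
#' @param n_starts starts per axis of the multi-start grid (default 4)
#' @param box parameter box, list of length-2 ranges
#' @param reltol Nelder-Mead relative convergence tolerance
#' @param maxit Nelder-Mead iteration cap per start
#' @return an `lkb_fit`: `td50`, `m`, `n`, `loglik`, `convergence`,
#'   `starts` (per-start results)
#' @export
fit_lkb <- function(curves, y, n_starts = 4L,
                    box = list(td50 = c(0.5, 200), m = c(0.01, 2),
                               n = c(0.01, 2)),
                    reltol = 1e-9, maxit = 500L) {
  y <- as.integer(y)
  if (length(curves) != length(y)) stop("curve and outcome lengths differ")
  if (all(y == 0L) || all(y == 1L)) stop("degenerate outcome vector")
  mat <- cohort_dsh_matrix(curves)
  nll <- lkb_nll_factory(mat, y, box)
  grid <- expand.grid(
    td50 = exp(seq(log(2), log(60), length.out = n_starts)),
    m = exp(seq(log(0.06), log(0.9), length.out = max(n_starts - 1L, 2L))),
    n = exp(seq(log(0.08), log(1.4), length.out = max(n_starts - 1L, 2L))))
  fits <- lapply(seq_len(nrow(grid)), function(i) {
    stats::optim(log(as.numeric(grid[i, ])), nll, method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = maxit))
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  par <- exp(best$par)
  structure(list(td50 = par[1], m = par[2], n = par[3],
                 loglik = -best$value, convergence = best$convergence,
                 starts = data.frame(td50 = exp(vapply(fits, function(f) f$par[1], 1)),
                                     m = exp(vapply(fits, function(f) f$par[2], 1)),
                                     n = exp(vapply(fits, function(f) f$par[3], 1)),
                                     loglik = -vals),
                 mat = mat, y = y, box = box),
            class = "lkb_fit")
}

# Negative log-likelihood in log-parameter space with box walls.
lkb_nll_factory <- function(mat, y, box) {
  lb <- log(c(box$td50[1], box$m[1], box$n[1]))
  ub <- log(c(box$td50[2], box$m[2], box$n[2]))
  function(theta) {
    if (any(!is.finite(theta)) || any(theta < lb) || any(theta > ub))
      return(1e10)
    td50 <- exp(theta[1]); m <- exp(theta[2]); n <- exp(theta[3])
    g <- as.numeric(mat$S %*% mat$d^(1 / n))^n
    -ntcp_loglik(stats::pnorm((g - td50) / (m * td50)), y)
  }
}

#' @export
print.lkb_fit <- function(x, ...) {
  cat(sprintf("<lkb_fit> TD50 = %.3g Gy, m = %.3g, n = %.3g, LLH = %.4f\n",
              x$td50, x$m, x$n, x$loglik))
  invisible(x)
}

#' Profile-likelihood confidence interval for an LKB parameter
#'
#' Bounds where the profile log-likelihood (re-optimizing the other two
#' parameters by Nelder-Mead from the MLE) drops by `qchisq(level, 1) / 2`
#' from its maximum; located by bisection to `tol` on the parameter scale.
#' A bound not bracketed inside the parameter box is reported one-sided at
#' the box edge with a warning.
#'
#' @param fit an `lkb_fit`
#' @param parameter `"td50"`, `"m"` or `"n"`
#' @param level confidence level (default 0.95)
#' @param tol bisection tolerance on the parameter scale
#' @return numeric length-2 CI; attribute `open` flags unbounded sides
#' @export
profile_ci <- function(fit, parameter = c("td50", "m", "n"), level = 0.95,
                       tol = 1e-3) {
  parameter <- match.arg(parameter)
  if (level < 0 || level >= 1) stop("level must be in [0, 1)")
  mle <- c(td50 = fit$td50, m = fit$m, n = fit$n)
  if (level == 0) return(rep(unname(mle[parameter]), 2))
  k <- match(parameter, c("td50", "m", "n"))
  drop <- stats::qchisq(level, 1) / 2
  target <- fit$loglik - drop
  nll <- lkb_nll_factory(fit$mat, fit$y, fit$box)
  prof <- function(value) {
    theta_fix <- log(value)
    free0 <- log(mle[-k])
    obj <- function(th2) {
      theta <- numeric(3); theta[k] <- theta_fix; theta[-k] <- th2
      nll(theta)
    }
    o <- stats::optim(free0, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-9, maxit = 400))
    -o$value
  }
  box <- fit$box[[parameter]]
  open <- c(FALSE, FALSE)
  bound <- function(dir) {
    lim <- if (dir < 0) box[1] else box[2]
    lo <- unname(mle[parameter])
    hi <- lo
    repeat {
      hi <- if (dir < 0) max(hi / 1.6, lim) else min(hi * 1.6, lim)
      if (prof(hi) < target) break
      if (hi == lim) {
        warning(sprintf("profile CI for %s not bracketed; one-sided at box edge",
                        parameter))
        open[if (dir < 0) 1 else 2] <<- TRUE
        return(lim)
      }
    }
    stats::uniroot(function(v) prof(v) - target, sort(c(lo, hi)),
                   tol = tol)$root
  }
  ci <- c(bound(-1), bound(1))
  attr(ci, "open") <- open
  ci
}

#' Predict NTCP from a fitted LKB model
#'
#' @param object an `lkb_fit`
#' @param newdata list of `dsh` objects
#' @param ... unused
#' @return complication probabilities
#' @export
predict.lkb_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "dsh")) newdata <- list(newdata)
  g <- vapply(newdata, function(cv) geud(cv, object$n), numeric(1))
  lkb_ntcp(g, object$td50, object$m)
}
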