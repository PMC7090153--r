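#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two groups: exact enumeration (no ties)
#' when the pooled size is at most `exact_limit`, otherwise the normal
#' approximation with tie correction and no continuity correction.
#'
#' @param x0,x1 numeric samples, both non-empty
#' @param exact_limit pooled-size cap for the exact branch
#' @return two-sided p-value
#' @export
mann_whitney <- function(x0, x1, exact_limit = 12L) {
  if (length(x0) == 0L || length(x1) == 0L) stop("both groups must be non-empty")
  use_exact <- (length(x0) + length(x1)) <= exact_limit &&
    !any(duplicated(c(x0, x1)))
  suppressWarnings(
    stats::wilcox.test(x0, x1, exact = use_exact, correct = FALSE)$p.value)
}

#' Association test for a 2 x k contingency table
#'
#' Pearson's chi-squared test without continuity correction by default;
#' Fisher's exact test on 2 x 2 tables when any expected count is below 5
#' (Cochran's rule).
#'
#' @param tab matrix of non-negative integer counts with positive margins
#' @param yates apply Yates continuity correction to the chi-squared branch
#' @return list with `p` and `test` ("chisq" or "fisher")
#' @export
categorical_test <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has a zero margin")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(dim(tab) == c(2L, 2L)) && any(expected < 5)) {
    list(p = stats::fisher.test(tab)$p.value, test = "fisher")
  } else {
    p <- suppressWarnings(stats::chisq.test(tab, correct = yates)$p.value)
    list(p = p, test = "chisq")
  }
}

#' Pointwise comparison of two groups of DSH curves
#'
#' Welch two-sample two-tailed t-test of the cumulative area at every dose
#' edge, plus the group means and standard errors for plotting.
#'
#' @param a,b matrices of relative DSH values, one row per patient, columns
#'   on a common dose grid
#' @param edges common dose edges, Gy (optional, for the output table)
#' @return data.frame with per-edge means, SEMs and p-values
#' @export
pointwise_dsh_test <- function(a, b, edges = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("curve grids differ")
  if (nrow(a) < 2L || nrow(b) < 2L) stop("need >= 2 curves per group")
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0] <- 1   # identical, degenerate columns
  data.frame(edge = if (is.null(edges)) seq_along(ma) - 1L else edges,
             mean_a = ma, sem_a = sqrt(va / na),
             mean_b = mb, sem_b = sqrt(vb / nb),
             p = p)
}

#' Holm-Sidak step-down multiple-comparison procedure
#'
#' Sorts the m p-values ascending and rejects the i-th smallest while
#' `p_(i) <= 1 - (1 - alpha)^(1 / (m - i + 1))`, stopping at the first
#' failure. Controls the family-wise error rate at `alpha`.
#'
#' @param pvals p-values in \[0, 1\]
#' @param alpha family-wise significance level
#' @return logical rejection flags, in the input order
#' @export
holm_sidak <- function(pvals, alpha = 0.05) {
  if (any(pvals < 0 | pvals > 1 | !is.finite(pvals)))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  ord <- order(pvals)
  thresh <- 1 - (1 - alpha)^(1 / (m - seq_len(m) + 1))
  ok <- pvals[ord] <= thresh
  fail <- which(!ok)
  if (length(fail)) ok[fail[1]:m] <- FALSE
  reject <- logical(m)
  reject[ord] <- ok
  reject
}

#' Univariable screening against a binary endpoint
#'
#' Tests every candidate variable with the appropriate univariable test —
#' Mann-Whitney for continuous variables, chi-squared/Fisher for
#' categorical ones — and returns those with p below the screening
#' threshold. Constant (degenerate) variables are excluded with a warning.
#'
#' @param data data.frame of candidate variables
#' @param y 0/1 endpoint vector
#' @param p_enter screening threshold (default 0.1)
#' @return data.frame with `variable`, `test`, `p`, `pass`, ordered by p
#' @export
univariable_screen <- function(data, y, p_enter = 0.1) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("endpoint has a single class")
  if (min(table(y)) < 2L) stop("need >= 2 patients per endpoint class")
  rows <- lapply(names(data), function(v) {
    x <- data[[v]]
    if (is.numeric(x)) {
      if (stats::var(x) == 0) {
        warning(sprintf("constant variable '%s' excluded", v))
        return(NULL)
      }
      p <- mann_whitney(x[y == 0], x[y == 1])
      data.frame(variable = v, test = "mann-whitney", p = p)
    } else {
      x <- as.factor(x)
      if (nlevels(droplevels(x)) < 2L) {
        warning(sprintf("constant variable '%s' excluded", v))
        return(NULL)
      }
      tab <- table(y, droplevels(x))
      ct <- categorical_test(tab)
      data.frame(variable = v, test = ct$test, p = ct$p)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p), , drop = FALSE]
  out$pass <- out$p < p_enter
  rownames(out) <- NULL
  out
}

#' Greedy collinearity filter
#'
#' Walks the screened candidates by ascending univariable p-value and drops
#' any whose Spearman rank correlation with an already-kept variable reaches
#' `|Rs| >= threshold`, so each retained variable is the most
#' endpoint-correlated representative of its collinear family. The result
#' does not depend on the input order (candidates are re-sorted by p).
#'
#' @param screen result of [univariable_screen()] (rows with `pass = TRUE`
#'   are considered)
#' @param data data.frame holding the candidate variables
#' @param threshold absolute Spearman correlation cut (default 0.75)
#' @return character vector of retained variable names, ascending p
#' @export
collinearity_filter <- function(screen, data, threshold = 0.75) {
  cand <- screen[screen$pass, , drop = FALSE]
  cand <- cand[order(cand$p), , drop = FALSE]
  kept <- character(0)
  for (v in cand$variable) {
    x <- rank_of(data[[v]])
    collinear <- any(vapply(kept, function(k) {
      abs(stats::cor(x, rank_of(data[[k]]), method = "spearman")) >= threshold
    }, logical(1)))
    if (!collinear) kept <- c(kept, v)
  }
  kept
}

rank_of <- function(x) {
  if (is.numeric(x)) x else as.numeric(as.factor(x))
}
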