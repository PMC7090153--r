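#' Multivariable stepwise logistic NTCP model
#'
#' Forward stepwise selection over the screened, collinearity-filtered
#' candidates: at each step the variable with the smallest likelihood-ratio
#' p-value enters if below `p_enter`; after each entry, variables whose Wald
#' p-value exceeds `p_remove` are dropped; iterated to stability. The final
#' model is fitted by maximum likelihood (IRLS via `glm`), reporting odds
#' ratios `exp(coef)` with Wald 95% CIs. With no admissible candidate the
#' intercept-only model (intercept = logit of the event rate) is returned.
#'
#' @param data data.frame of candidate covariates (numeric or factor)
#' @param y 0/1 endpoint
#' @param candidates candidate variable names (default: all columns)
#' @param p_enter likelihood-ratio entry threshold
#' @param p_remove Wald removal threshold
#' @return a `logistic_fit`: `model` (glm), `selected`, `coef`, `or` table,
#'   `loglik`, `trace`
#' @export
fit_logistic_ntcp <- function(data, y, candidates = names(data),
                              p_enter = 0.05, p_remove = 0.10) {
  y <- as.integer(y)
  if (all(y == 0L) || all(y == 1L)) stop("degenerate outcome vector")
  df <- data.frame(.y = y, data, check.names = FALSE)
  selected <- character(0)
  trace <- character(0)
  visited <- character(0)  # guard against enter/remove cycling
  repeat {
    state <- paste(sort(selected), collapse = "|")
    if (state %in% visited) break
    visited <- c(visited, state)
    changed <- FALSE
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      base_fml <- stats::reformulate(if (length(selected)) selected else "1",
                                     response = ".y")
      base <- stats::glm(base_fml, family = stats::binomial(), data = df)
      lr_p <- vapply(pool, function(v) {
        fml <- stats::reformulate(c(selected, v), response = ".y")
        fit <- fit_glm_checked(fml, df)
        stats::pchisq(base$deviance - fit$deviance,
                      df = fit$df.null - fit$df.residual -
                        (base$df.null - base$df.residual),
                      lower.tail = FALSE)
      }, numeric(1))
      if (min(lr_p) < p_enter) {
        v <- pool[which.min(lr_p)]
        selected <- c(selected, v)
        trace <- c(trace, sprintf("enter %s (LR p = %.3g)", v, min(lr_p)))
        changed <- TRUE
      }
    }
    if (length(selected)) {
      fml <- stats::reformulate(selected, response = ".y")
      fit <- fit_glm_checked(fml, df)
      wald <- summary(fit)$coefficients
      wp <- wald[-1, 4]
      # map coefficient rows back to variables (factors expand to dummies)
      var_of <- variable_of_terms(fit, selected)
      worst <- vapply(selected, function(v) min(wp[var_of == v]), numeric(1))
      if (max(worst) > p_remove) {
        v <- selected[which.max(worst)]
        selected <- setdiff(selected, v)
        trace <- c(trace, sprintf("remove %s (Wald p = %.3g)", v, max(worst)))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fml <- stats::reformulate(if (length(selected)) selected else "1",
                            response = ".y")
  fit <- fit_glm_checked(fml, df)
  cf <- summary(fit)$coefficients
  or <- data.frame(term = rownames(cf)[-1],
                   coef = cf[-1, 1], se = cf[-1, 2],
                   or = exp(cf[-1, 1]),
                   lo95 = exp(cf[-1, 1] - 1.96 * cf[-1, 2]),
                   hi95 = exp(cf[-1, 1] + 1.96 * cf[-1, 2]))
  rownames(or) <- NULL
  structure(list(model = fit, selected = selected,
                 coef = stats::coef(fit), intercept = unname(stats::coef(fit)[1]),
                 intercept_se = cf[1, 2], or = or,
                 loglik = as.numeric(stats::logLik(fit)), trace = trace),
            class = "logistic_fit")
}

fit_glm_checked <- function(fml, df) {
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(), data = df))
  p <- stats::fitted(fit)
  if (any(p < 1e-10 | p > 1 - 1e-10) && !fit$converged)
    stop("perfect separation: logistic likelihood unbounded for ",
         deparse(fml))
  fit
}

variable_of_terms <- function(fit, selected) {
  labs <- names(stats::coef(fit))[-1]
  assign <- attr(stats::model.matrix(fit), "assign")[-1]
  terms <- attr(stats::terms(fit), "term.labels")
  terms[assign]
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> %s; intercept = %.3f, LLH = %.4f\n",
              if (length(x$selected)) paste(x$selected, collapse = " + ")
              else "(intercept only)",
              x$intercept, x$loglik))
  if (nrow(x$or)) {
    for (i in seq_len(nrow(x$or)))
      cat(sprintf("  %s: OR = %.3g [%.3g, %.3g]\n", x$or$term[i],
                  x$or$or[i], x$or$lo95[i], x$or$hi95[i]))
  }
  invisible(x)
}

#' Predict NTCP from a fitted stepwise logistic model
#'
#' @param object a `logistic_fit`
#' @param newdata data.frame holding the selected covariates
#' @param ... unused
#' @return complication probabilities in \[0, 1\]
#' @export
predict.logistic_fit <- function(object, newdata, ...) {
  missing <- setdiff(object$selected, names(newdata))
  if (length(missing))
    stop("missing covariates: ", paste(missing, collapse = ", "))
  as.numeric(stats::predict(object$model, newdata = newdata,
                            type = "response"))
}
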