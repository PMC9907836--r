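#' Univariate logistic screening of mortality risk factors
#'
#' Fits one single-predictor logistic regression of 28-day death per
#' candidate and flags candidates with p < `p_screen` as eligible for the
#' multivariate model. Constant predictors and predictors causing
#' (quasi-)complete separation are flagged and excluded from eligibility.
#'
#' @param data Data.frame containing the outcome and candidates.
#' @param candidates Character vector of predictor column names.
#' @param outcome Binary 0/1 outcome column (default `"death_28d"`).
#' @param p_screen Screening gate on the Wald p-value (default 0.20).
#' @return A data.frame with one row per candidate: `variable`, `or`,
#'   `ci_low`, `ci_high`, `p_value`, `eligible`, `flag` (`"ok"`,
#'   `"constant"`, `"separation"`).
#' @export
univariate_screen <- function(data, candidates, outcome = "death_28d",
                              p_screen = 0.20) {
  y <- data[[outcome]]
  if (is.null(y) || !all(y %in% c(0, 1)))
    stop("outcome '", outcome, "' must be a 0/1 column")
  rows <- lapply(candidates, function(v) {
    x <- data[[v]]
    if (is.null(x)) stop("candidate column not found: ", v)
    cc <- !is.na(x) & !is.na(y)
    x <- x[cc]; yy <- y[cc]
    if (length(unique(x)) == 1L)
      return(data.frame(variable = v, or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        eligible = FALSE, flag = "constant"))
    fit <- suppressWarnings(stats::glm(yy ~ x, family = stats::binomial()))
    co <- summary(fit)$coefficients
    sep <- !fit$converged || abs(co["x", "Estimate"]) > 15 ||
      co["x", "Std. Error"] > 100
    if (sep)
      return(data.frame(variable = v, or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        eligible = FALSE, flag = "separation"))
    b <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
    p <- co["x", "Pr(>|z|)"]
    data.frame(variable = v, or = exp(b),
               ci_low = exp(b - 1.959964 * se),
               ci_high = exp(b + 1.959964 * se),
               p_value = p, eligible = p < p_screen, flag = "ok")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  bad <- out$flag == "separation"
  if (any(bad))
    warning("separation detected for: ",
            paste(out$variable[bad], collapse = ", "),
            " (excluded from eligibility)")
  out
}

#' Forward stepwise multivariate logistic regression
#'
#' Builds the multivariate mortality model by forward selection: starting
#' from the intercept-only model, at each step the eligible variable with
#' the smallest likelihood-ratio p-value is added if that p-value is below
#' `p_enter`; selection stops when no remaining variable qualifies. A
#' variable adding no information beyond the current model (e.g. a
#' duplicate of an entered predictor) yields a likelihood-ratio p near 1
#' and never enters. Final-model odds ratios carry Wald 95% confidence
#' intervals.
#'
#' @param data Data.frame with outcome and candidate columns
#'   (complete-case on the candidates; dropped rows are counted).
#' @param candidates Character vector of eligible predictor names
#'   (typically `univariate_screen()` output with `eligible == TRUE`).
#' @param outcome Binary 0/1 outcome column (default `"death_28d"`).
#' @param p_enter Likelihood-ratio entry threshold (default 0.05).
#' @return A list of class `forward_logistic`: `terms` (data.frame
#'   `variable`, `or`, `ci_low`, `ci_high`, `p_value` for the final
#'   model), `entered` (in entry order), `steps` (data.frame of the
#'   selection path), `converged`, `n_used`, `n_dropped`, `model` (the
#'   final `glm`, or `NULL` if empty).
#' @export
forward_logistic <- function(data, candidates, outcome = "death_28d",
                             p_enter = 0.05) {
  if (length(candidates) == 0L)
    return(structure(list(terms = empty_terms(), entered = character(),
                          steps = NULL, converged = TRUE,
                          n_used = 0L, n_dropped = 0L, model = NULL,
                          flag = "no_candidates"),
                     class = "forward_logistic"))
  cols <- c(outcome, candidates)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("column(s) not found: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[cols])
  d <- data[cc, cols, drop = FALSE]
  if (nrow(d) <= 10 * length(candidates))
    warning("n = ", nrow(d), " is small for ", length(candidates),
            " candidate predictors; estimates may be unstable")
  entered <- character()
  remaining <- candidates
  current <- stats::glm(stats::reformulate("1", response = outcome),
                        data = d, family = stats::binomial())
  steps <- list()
  repeat {
    if (length(remaining) == 0L) break
    ps <- vapply(remaining, function(v) {
      f <- stats::reformulate(c(entered, v), response = outcome)
      cand <- suppressWarnings(stats::glm(f, data = d,
                                          family = stats::binomial()))
      lr <- current$deviance - cand$deviance
      stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
    }, 0)
    best <- which.min(ps)
    if (ps[best] >= p_enter) break
    entered <- c(entered, remaining[best])
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(entered), variable = remaining[best],
      lr_p = unname(ps[best]))
    remaining <- remaining[-best]
    current <- suppressWarnings(stats::glm(
      stats::reformulate(entered, response = outcome),
      data = d, family = stats::binomial()))
  }
  if (length(entered) == 0L)
    return(structure(list(terms = empty_terms(), entered = character(),
                          steps = NULL, converged = TRUE,
                          n_used = nrow(d), n_dropped = sum(!cc),
                          model = NULL, flag = "no_entry"),
                     class = "forward_logistic"))
  co <- summary(current)$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  terms <- data.frame(
    variable = rownames(co),
    or = exp(co[, "Estimate"]),
    ci_low = exp(co[, "Estimate"] - 1.959964 * co[, "Std. Error"]),
    ci_high = exp(co[, "Estimate"] + 1.959964 * co[, "Std. Error"]),
    p_value = co[, "Pr(>|z|)"])
  rownames(terms) <- NULL
  structure(list(terms = terms, entered = entered,
                 steps = do.call(rbind, steps),
                 converged = current$converged,
                 n_used = nrow(d), n_dropped = sum(!cc),
                 model = current, flag = "ok"),
            class = "forward_logistic")
}

empty_terms <- function() {
  data.frame(variable = character(), or = numeric(), ci_low = numeric(),
             ci_high = numeric(), p_value = numeric())
}

#' @export
print.forward_logistic <- function(x, ...) {
  cat("<forward_logistic> entered:",
      if (length(x$entered)) paste(x$entered, collapse = " -> ")
      else "(none)", "\n")
  if (nrow(x$terms)) print(x$terms, digits = 4)
  invisible(x)
}

#' Multivariable logistic fit with Wald intervals
#'
#' Plain (non-stepwise) logistic fit of a binary outcome on a fixed set of
#' predictors; the workhorse behind the stepwise wrapper, exported for
#' parameter-recovery checks where the model is known.
#'
#' @inheritParams forward_logistic
#' @param variables Predictor column names (all entered).
#' @return A data.frame `variable`, `estimate` (log-odds), `se`, `or`,
#'   `ci_low`, `ci_high`, `p_value`, with attribute `converged`.
#' @export
fit_logistic <- function(data, variables, outcome = "death_28d") {
  f <- stats::reformulate(variables, response = outcome)
  fit <- suppressWarnings(stats::glm(f, data = data,
                                     family = stats::binomial()))
  co <- summary(fit)$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  out <- data.frame(
    variable = rownames(co),
    estimate = co[, "Estimate"], se = co[, "Std. Error"],
    or = exp(co[, "Estimate"]),
    ci_low = exp(co[, "Estimate"] - 1.959964 * co[, "Std. Error"]),
    ci_high = exp(co[, "Estimate"] + 1.959964 * co[, "Std. Error"]),
    p_value = co[, "Pr(>|z|)"])
  rownames(out) <- NULL
  attr(out, "converged") <- fit$converged
  out
}
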