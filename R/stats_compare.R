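#' Normality assessment for a continuous sample
#'
#' Kolmogorov-Smirnov-type test of composite normality with the
#' estimated-parameter (Lilliefors) correction; the plain KS test against a
#' normal with the sample's own mean and SD is anticonservative, so the
#' corrected null distribution is used. The verdict is "normal" iff
#' p >= 0.05.
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @param min_n Below this sample size the test is unreliable; the verdict
#'   defaults to non-normal with a small-sample flag (default 8).
#' @return A list: `normal` (logical), `p_value`, `n`, `flag`
#'   (`"ok"`, `"small_sample"` or `"degenerate_sd"`).
#' @export
assess_normality <- function(x, min_n = 8) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < min_n)
    return(list(normal = FALSE, p_value = NA_real_, n = n,
                flag = "small_sample"))
  if (stats::sd(x) == 0)
    return(list(normal = FALSE, p_value = NA_real_, n = n,
                flag = "degenerate_sd"))
  p <- nortest::lillie.test(x)$p.value
  list(normal = p >= 0.05, p_value = p, n = n, flag = "ok")
}

#' Two-group comparison with automatic test choice
#'
#' Implements the conventional descriptive battery: a continuous variable
#' that passes the normality check in both groups is compared with
#' Student's t-test and summarized as mean (SD); a non-normal continuous
#' variable with the Wilcoxon rank-sum test and median \[IQR\]; a
#' categorical variable with the Pearson chi-square test (no continuity
#' correction) and counts (%).
#'
#' @param data Data frame holding the variable and the grouping column.
#' @param group Name of a two-level grouping column.
#' @param variable Name of the column to compare.
#' @param type `"auto"` (binary 0/1 columns are treated as categorical),
#'   `"continuous"` or `"categorical"`.
#' @return A list of class `comparison_result`: `variable`, `test`
#'   (`"t"`, `"wilcoxon"` or `"chisq"`), `summaries` (named character,
#'   one per group), `estimates` (numeric group summaries), `statistic`,
#'   `p_value`, `flag`.
#' @export
compare_groups <- function(data, group, variable, type = "auto") {
  type <- match.arg(type, c("auto", "continuous", "categorical"))
  g <- data[[group]]
  x <- data[[variable]]
  if (is.null(g) || is.null(x))
    stop("column not found: ", if (is.null(g)) group else variable)
  keep <- !is.na(g) & !is.na(x)   # complete-case per variable
  g <- factor(g[keep])
  x <- x[keep]
  lev <- levels(g)
  if (length(lev) != 2L) stop("grouping column must have exactly 2 levels")
  if (any(table(g) == 0L)) stop("a comparison group is empty")
  if (type == "auto")
    type <- if (all(x %in% c(0, 1))) "categorical" else "continuous"

  if (type == "categorical") {
    tab <- table(g, factor(x))
    if (ncol(tab) < 2L) {  # constant: no association testable
      return(comparison_result(variable, "chisq",
                               summaries_cat(tab, lev), tab,
                               NA_real_, NA_real_, "constant"))
    }
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(comparison_result(variable, "chisq", summaries_cat(tab, lev), tab,
                             unname(ht$statistic), ht$p.value, "ok"))
  }

  sds <- tapply(x, g, stats::sd)
  normal <- all(sds > 0) &&
    all(vapply(lev, function(l) assess_normality(x[g == l])$normal, TRUE))
  if (normal) {
    ht <- stats::t.test(x ~ g, var.equal = TRUE)
    s <- tapply(x, g, function(v)
      sprintf("%.1f ± %.1f", mean(v), stats::sd(v)))
    est <- tapply(x, g, mean)
    comparison_result(variable, "t", s, est, unname(ht$statistic),
                      ht$p.value, "ok")
  } else {
    flag <- if (any(sds == 0)) "zero_variance_wilcoxon_fallback" else "ok"
    ht <- suppressWarnings(stats::wilcox.test(x ~ g))
    s <- tapply(x, g, function(v) {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75))
      sprintf("%.1f [%.1f, %.1f]", q[2], q[1], q[3])
    })
    est <- tapply(x, g, stats::median)
    comparison_result(variable, "wilcoxon", s, est, unname(ht$statistic),
                      ht$p.value, flag)
  }
}

comparison_result <- function(variable, test, summaries, estimates,
                              statistic, p_value, flag) {
  structure(list(variable = variable, test = test,
                 summaries = summaries, estimates = estimates,
                 statistic = statistic, p_value = p_value, flag = flag),
            class = "comparison_result")
}

summaries_cat <- function(tab, lev) {
  # count (%) of the highest category (for 0/1 flags: the 1s)
  vapply(lev, function(l) {
    r <- tab[l, ]
    k <- r[length(r)]
    sprintf("%d (%.1f)", k, 100 * k / sum(r))
  }, "")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> %s [%s]: %s vs %s, p = %.4g (%s)\n",
              x$variable, x$test, x$summaries[1], x$summaries[2],
              x$p_value, x$flag))
  invisible(x)
}

#' Build a grouped descriptive table
#'
#' Runs [compare_groups()] over a set of variables and assembles a
#' baseline-characteristics table (one row per variable: per-group
#' summary, test used, p-value).
#'
#' @param data Data frame.
#' @param group Two-level grouping column name.
#' @param variables Character vector of column names.
#' @param types Optional character vector (recycled) of types per
#'   variable, as in [compare_groups()].
#' @return A data.frame with columns `variable`, `test`, one summary
#'   column per group level, `statistic`, `p_value`, `flag`.
#' @export
baseline_table <- function(data, group, variables, types = "auto") {
  types <- rep_len(types, length(variables))
  rows <- Map(function(v, ty) {
    r <- compare_groups(data, group, v, ty)
    out <- data.frame(variable = v, test = r$test,
                      s1 = r$summaries[1], s2 = r$summaries[2],
                      statistic = r$statistic, p_value = r$p_value,
                      flag = r$flag)
    names(out)[3:4] <- paste0("group_", levels(factor(data[[group]])))
    out
  }, variables, types)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
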