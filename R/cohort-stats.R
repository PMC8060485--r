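# Cohort-level statistics: 2x2 odds ratios with Woolf confidence intervals
# (Haldane-Anscombe corrected for zero cells), 2x2 association tests,
# two-sample comparisons, and logistic models with Wald intervals. The
# generic tests are delegated to the standard implementations in 'stats'
# behind the module surface; the Woolf/Haldane odds-ratio arithmetic and the
# table formatting are authored here because they are the quantities the
# published tables print.

# Coerce a 2x2 table given as a matrix or four counts a, b, c, d with
# a = exposed-case, b = unexposed-case, c = exposed-control,
# d = unexposed-control (matrix layout: rows case/control, cols
# exposed/unexposed).
as_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a) || is.table(a)) {
    if (!all(dim(a) == c(2L, 2L))) stop("contingency table must be 2x2")
    cells <- c(a = a[1, 1], b = a[1, 2], c = a[2, 1], d = a[2, 2])
  } else {
    if (is.null(b) || is.null(c) || is.null(d)) {
      stop("supply a 2x2 matrix or four counts a, b, c, d")
    }
    cells <- c(a = a, b = b, c = c, d = d)
  }
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) stop("the contingency table is empty (total count 0)")
  cells
}

cells_to_matrix <- function(cells) {
  matrix(cells, nrow = 2, byrow = TRUE,
         dimnames = list(c("case", "control"), c("exposed", "unexposed")))
}

#' Odds ratio with Woolf (log-normal) confidence interval
#'
#' Computes the cross-product odds ratio `(a*d)/(b*c)` of a 2x2 table with the
#' Woolf interval `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When any
#' cell is zero, 0.5 is first added to every cell (Haldane-Anscombe
#' correction) and the method is flagged `"woolf_haldane"`.
#'
#' @param a A 2x2 matrix/table (rows: case/control, columns:
#'   exposed/unexposed), or the exposed-case count.
#' @param b,c,d Unexposed-case, exposed-control and unexposed-control counts
#'   when `a` is a scalar.
#' @param conf_level Confidence level (default 0.95, z = 1.959964).
#' @return An object of class `"odds_ratio_result"` with elements
#'   `odds_ratio`, `ci_low`, `ci_high`, `method` (`"woolf"` or
#'   `"woolf_haldane"`), `z`, `conf_level` and `counts`.
#' @export
#' @examples
#' # velocity x collateral: 11 fast-poor, 3 slow-poor, 8 fast-good, 14 slow-good
#' odds_ratio_woolf(11, 3, 8, 14)  # OR 6.42, 95% CI 1.37-30.05
odds_ratio_woolf <- function(a, b = NULL, c = NULL, d = NULL,
                             conf_level = 0.95) {
  cells <- as_2x2(a, b, c, d)
  method <- "woolf"
  work <- cells
  if (any(cells == 0)) {
    work <- cells + 0.5
    method <- "woolf_haldane"
  }
  or <- (work["a"] * work["d"]) / (work["b"] * work["c"])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / work))
  ci <- exp(log(or) + c(-1, 1) * z * se)
  structure(
    list(odds_ratio = unname(or), ci_low = ci[1], ci_high = ci[2],
         method = method, z = z, conf_level = conf_level, counts = cells),
    class = "odds_ratio_result"
  )
}

#' @export
print.odds_ratio_result <- function(x, digits = 2, ...) {
  cat(sprintf("OR %.*f (%.0f%% CI %.*f-%.*f), %s\n",
              digits, x$odds_ratio, 100 * x$conf_level,
              digits, x$ci_low, digits, x$ci_high, x$method))
  invisible(x)
}

#' Association test for a 2x2 table
#'
#' Pearson's chi-square (no continuity correction), the Yates-corrected
#' chi-square, or Fisher's exact test. Mode `"auto"` applies Fisher's exact
#' test when any expected cell count is below 5 and Pearson's chi-square
#' otherwise. A table with a zero margin is degenerate: the statistic is 0,
#' the p-value 1, and the result is flagged.
#'
#' @inheritParams odds_ratio_woolf
#' @param mode One of `"auto"`, `"pearson"`, `"yates"`, `"fisher"`.
#' @return An object of class `"cvf_test"`: list with `statistic`, `p_value`,
#'   `method` and `degenerate`.
#' @export
association_test_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                                 mode = c("auto", "pearson", "yates",
                                          "fisher")) {
  mode <- match.arg(mode)
  cells <- as_2x2(a, b, c, d)
  tab <- cells_to_matrix(cells)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(structure(
      list(statistic = 0, p_value = 1, method = mode, degenerate = TRUE),
      class = "cvf_test"
    ))
  }
  if (mode == "auto") {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    mode <- if (any(expected < 5)) "fisher" else "pearson"
  }
  res <- switch(
    mode,
    pearson = {
      ht <- stats::chisq.test(tab, correct = FALSE)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    yates = {
      ht <- stats::chisq.test(tab, correct = TRUE)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    fisher = {
      ht <- stats::fisher.test(tab)
      list(statistic = NA_real_, p_value = ht$p.value)
    }
  )
  structure(
    list(statistic = res$statistic, p_value = res$p_value, method = mode,
         degenerate = FALSE),
    class = "cvf_test"
  )
}

#' Compare a continuous variable between two groups
#'
#' `mode = "t"` runs the two-sided pooled-variance Student t-test;
#' `mode = "mann_whitney"` runs the Mann-Whitney U test, exact by complete
#' enumeration when the combined sample size is at most 10 and tie-free, and
#' via the normal approximation with tie correction otherwise.
#'
#' @param x,y Numeric samples (`NA`s dropped).
#' @param mode `"mann_whitney"` (default) or `"t"`.
#' @return An object of class `"cvf_test"` with `statistic` (U for
#'   Mann-Whitney, t otherwise), `p_value` and `method`.
#' @export
group_compare_continuous <- function(x, y, mode = c("mann_whitney", "t")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  if (mode == "t") {
    if (length(x) < 2 || length(y) < 2) {
      stop("the t-test needs at least 2 observations per group")
    }
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      cvf_stop("cvf_degenerate_test",
               "both samples have zero variance; the t statistic is undefined")
    }
    ht <- stats::t.test(x, y, var.equal = TRUE)
    method <- "t"
  } else {
    exact <- (length(x) + length(y) <= 10) && !anyDuplicated(c(x, y))
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = FALSE)
    )
    method <- if (exact) "mann_whitney_exact" else "mann_whitney_normal"
  }
  structure(
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = method, degenerate = FALSE),
    class = "cvf_test"
  )
}

#' @export
print.cvf_test <- function(x, ...) {
  cat(sprintf("<cvf_test> %s: statistic %s, p = %.4g%s\n", x$method,
              if (is.na(x$statistic)) "-" else format(x$statistic, digits = 4),
              x$p_value, if (x$degenerate) " (degenerate table)" else ""))
  invisible(x)
}

#' Logistic regression with Wald odds-ratio intervals
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares,
#' convergence tolerance 1e-8, at most 100 iterations) returning coefficients
#' on the log-odds scale with Wald 95% intervals exponentiated to odds
#' ratios. Separation is reported as an error rather than silently returning
#' divergent estimates.
#'
#' @param outcome Binary vector (0/1, logical, or 2-level factor); both
#'   classes must occur.
#' @param predictors Optional vector, matrix, or data frame of predictors
#'   (`NULL` fits an intercept-only model).
#' @param adjustment Optional additional covariates (vector/matrix/data
#'   frame) for an adjusted model.
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @param tol IRLS convergence tolerance (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param divergence_bound Absolute log-odds value beyond which a coefficient
#'   is considered separated (default 15).
#' @return An object of class `"logistic_fit"`: `coefficients`, `se`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `converged`, `n_iter`,
#'   and the underlying `fit`.
#' @section Errors: non-convergence or separation signals a condition of
#'   class `"cvf_separation"` carrying the iteration count.
#' @export
logistic_regression <- function(outcome, predictors = NULL, adjustment = NULL,
                                conf_level = 0.95, tol = 1e-8, max_iter = 100,
                                divergence_bound = 15) {
  y <- if (is.factor(outcome)) as.integer(outcome) - 1L else as.integer(outcome)
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop("'outcome' must be binary (0/1, logical, or a 2-level factor)")
  }
  if (length(unique(y)) < 2L) stop("'outcome' must contain both classes")
  as_df <- function(v, prefix) {
    if (is.null(v)) return(NULL)
    df <- as.data.frame(v)
    if (is.null(colnames(v)) && ncol(df) == 1L && identical(names(df), "v")) {
      names(df) <- prefix
    }
    df
  }
  df <- data.frame(.y = y)
  px <- as_df(predictors, "x")
  ax <- as_df(adjustment, "adj")
  if (!is.null(px)) df <- cbind(df, px)
  if (!is.null(ax)) df <- cbind(df, ax)
  if (nrow(df) <= ncol(df)) {
    stop("more parameters than observations; the model is not identifiable")
  }
  fit <- suppressWarnings(stats::glm(
    .y ~ ., data = df, family = stats::binomial(),
    control = stats::glm.control(epsilon = tol, maxit = max_iter)
  ))
  if (!fit$converged || any(abs(stats::coef(fit)) > divergence_bound)) {
    cvf_stop("cvf_separation",
             sprintf(paste0("logistic fit did not reach a finite optimum ",
                            "(separation or non-convergence) after %d ",
                            "iterations"), fit$iter),
             iterations = fit$iter, coefficients = stats::coef(fit))
  }
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  structure(
    list(coefficients = est, se = se, odds_ratio = exp(est),
         ci_low = exp(est - z * se), ci_high = exp(est + z * se),
         p_value = sm[, "Pr(>|z|)"], converged = fit$converged,
         n_iter = fit$iter, conf_level = conf_level, fit = fit),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<logistic_fit> converged in %d iterations\n", x$n_iter))
  tab <- data.frame(
    coef = round(x$coefficients, digits),
    se = round(x$se, digits),
    OR = round(x$odds_ratio, digits),
    ci_low = round(x$ci_low, digits),
    ci_high = round(x$ci_high, digits),
    p = signif(x$p_value, digits)
  )
  print(tab)
  invisible(x)
}

#' Format a count with its percentage
#'
#' Renders `k` of `n` as `"k (p%)"` with the percentage rounded half away
#' from zero to an integer, the convention of the published tables
#' (8 of 22 prints as `"8 (36%)"`).
#'
#' @param k Count (vectorized).
#' @param n Denominator.
#' @return Character vector.
#' @export
#' @examples
#' fmt_count_pct(c(8, 11), c(22, 14))  # "8 (36%)", "11 (79%)"
fmt_count_pct <- function(k, n) {
  pct <- ifelse(n > 0, round_half_away(100 * k / n), 0)
  sprintf("%d (%d%%)", k, pct)
}

#' Format a median with its interquartile range
#'
#' @param x Numeric sample (`NA`s dropped).
#' @param digits Decimal places (default 1).
#' @return `"median (q1-q3)"` as a character scalar, `"-"` if empty.
#' @export
fmt_median_iqr <- function(x, digits = 1) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return("-")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  sprintf("%.*f (%.*f-%.*f)", digits, q[2], digits, q[1], digits, q[3])
}

fmt_mean_sd <- function(x, digits = 1) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return("-")
  sprintf("%.*f ± %.*f", digits, mean(x), digits, stats::sd(x))
}

fmt_p <- function(p) {
  if (is.na(p)) return("-")
  if (p < 0.001) "<0.001" else sprintf("%.2g", p)
}
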