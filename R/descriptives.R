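# Univariate/bivariate description and model screening: cross-tabulations
# in the percent-of-grand-total convention, Pearson chi-square tests, VIF
# multicollinearity checks and the p < 0.05 selection rule.

#' Cross-tabulate a categorical variable against the modern/traditional outcome
#'
#' Percentages are percent of the grand total (so the traditional and
#' modern columns of one category sum to the category's share of the
#' table), matching the published table convention; row percentages are
#' available with \code{percent = "row"}.
#'
#' @param records coded data.frame with an \code{outcome_modern} column.
#' @param variable name of a categorical column.
#' @param percent \code{"total"} (default) or \code{"row"}.
#' @param yates apply the continuity correction for 2x2 tables.
#' @return object of class \code{mcp_crosstab}: per-category counts and
#'   percentages plus the chi-square test.
#' @export
crosstab <- function(records, variable, percent = c("total", "row"),
                     yates = FALSE) {
  percent <- match.arg(percent)
  if (!variable %in% names(records)) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  keep <- !is.na(records[[variable]]) & !is.na(records$outcome_modern)
  v <- records[[variable]][keep]
  if (!is.factor(v)) v <- factor(v)
  y <- records$outcome_modern[keep]
  n <- length(y)
  counts <- table(v)
  O <- table(v, factor(y, levels = c(0, 1),
                       labels = c("traditional", "modern")))
  denom <- if (percent == "total") n else as.numeric(counts)
  tab <- data.frame(
    category = names(counts),
    n = as.integer(counts),
    pct = 100 * as.integer(counts) / n,
    traditional_pct = 100 * O[, "traditional"] / denom,
    modern_pct = 100 * O[, "modern"] / denom,
    row.names = NULL, stringsAsFactors = FALSE
  )
  test <- if (nrow(O) >= 2 && all(rowSums(O) > 0) && all(colSums(O) > 0)) {
    chi_square_test(unclass(O)[, , drop = FALSE], yates = yates)
  } else list(statistic = NA_real_, df = NA_integer_, p = NA_real_)
  structure(list(variable = variable, table = tab, n = n,
                 observed = O, chi_square = test$statistic,
                 df = test$df, p_value = test$p, percent = percent),
            class = "mcp_crosstab")
}

#' @export
print.mcp_crosstab <- function(x, ...) {
  cat(sprintf("%s (n = %d, %% of %s)\n", x$variable, x$n,
              if (x$percent == "total") "grand total" else "row"))
  print(transform(x$table, pct = round(pct, 1),
                  traditional_pct = round(traditional_pct, 1),
                  modern_pct = round(modern_pct, 1)))
  if (!is.na(x$chi_square)) {
    cat(sprintf("Pearson chi-square = %.3f, df = %d, p = %.4g\n",
                x$chi_square, x$df, x$p_value))
  }
  invisible(x)
}

#' Pearson chi-square test of independence on an observed table
#'
#' @param observed matrix of observed counts (r x c).
#' @param yates continuity correction (2x2 only).
#' @return list with \code{statistic}, \code{df}, \code{p},
#'   \code{expected}.
#' @export
chi_square_test <- function(observed, yates = FALSE) {
  O <- as.matrix(observed)
  if (any(O < 0)) stop("counts must be non-negative", call. = FALSE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  if (any(E <= 0)) {
    stop("degenerate table: some expected cell counts are zero", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(O, correct = yates))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value), expected = ct$expected)
}

#' Variance inflation factors of a dummy-coded design matrix
#'
#' VIF_k = 1 / (1 - R^2_k) where R^2_k is from regressing predictor k on
#' all other predictors (plus an intercept). Exact collinearity is
#' reported as an infinite, flagged VIF rather than an error.
#'
#' @param X numeric design matrix, reference categories dropped, no
#'   intercept column.
#' @param vif_max flag threshold (default 10).
#' @return data.frame (predictor, vif, flagged) with attribute
#'   \code{summary} = c(mean, min, max) over finite VIFs.
#' @export
vif_screen <- function(X, vif_max = 10) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 1) stop("empty design matrix", call. = FALSE)
  if (any(apply(X, 2, var) == 0)) {
    stop("constant column among predictors", call. = FALSE)
  }
  vifs <- vapply(seq_len(p), function(k) {
    yk <- X[, k]
    Z <- cbind(1, X[, -k, drop = FALSE])
    fit <- stats::lm.fit(Z, yk)
    rss <- sum(fit$residuals^2)
    tss <- sum((yk - mean(yk))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  out <- data.frame(predictor = colnames(X) %||% paste0("x", seq_len(p)),
                    vif = vifs, flagged = vifs > vif_max,
                    stringsAsFactors = FALSE)
  fin <- vifs[is.finite(vifs)]
  attr(out, "summary") <- c(mean = mean(fin), min = min(fin), max = max(fin))
  out
}

#' Bivariate screening followed by the VIF filter
#'
#' Keeps variables whose bivariate chi-square p-value is below
#' \code{alpha}, then drops any kept variable whose dummies reach a VIF
#' above \code{vif_max} (a variable's VIF is the maximum over its dummy
#' columns). Order follows the input crosstab order.
#'
#' @param crosstabs list of \code{\link{crosstab}} objects.
#' @param data coded data.frame (needed to build the joint dummy design
#'   for the VIF step); if NULL, the VIF step is skipped.
#' @param alpha significance threshold (default 0.05).
#' @param vif_max VIF threshold (default 10).
#' @return character vector of selected variables, with attributes
#'   \code{dropped_p} and \code{dropped_vif} naming the exclusions.
#' @export
select_variables <- function(crosstabs, data = NULL, alpha = 0.05,
                             vif_max = 10) {
  vars <- vapply(crosstabs, function(x) x$variable, character(1))
  ps <- vapply(crosstabs, function(x) x$p_value, numeric(1))
  keep <- vars[!is.na(ps) & ps < alpha]
  dropped_p <- setdiff(vars, keep)
  dropped_vif <- character(0)
  if (!is.null(data) && length(keep) >= 2) {
    f <- stats::as.formula(paste("~", paste(keep, collapse = " + ")))
    X <- model.matrix(f, data = data)[, -1, drop = FALSE]
    v <- vif_screen(X, vif_max = vif_max)
    assign_var <- vapply(v$predictor, function(pn) {
      hits <- keep[startsWith(pn, keep)]
      hits[which.max(nchar(hits))]
    }, character(1))
    by_var <- tapply(v$vif, assign_var, max)
    dropped_vif <- names(by_var)[by_var > vif_max]
    keep <- setdiff(keep, dropped_vif)
  }
  structure(keep, dropped_p = dropped_p, dropped_vif = dropped_vif)
}
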