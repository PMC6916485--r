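# Univariate distribution tests and bivariate association screens with
# Benjamini-Hochberg multiplicity control.

.new_test_result <- function(test_name, y_var, x_var, statistic, p,
                             n_used, q = p, flagged = NA,
                             group_summaries = NULL, posthoc = NULL,
                             degenerate = FALSE, extra = list()) {
  out <- tibble::tibble(
    test_name = test_name, y_var = y_var, x_var = x_var,
    statistic = statistic, p = p, q = q, n_used = n_used,
    flagged = flagged, degenerate = degenerate,
    group_summaries = list(group_summaries), posthoc = list(posthoc)
  )
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

.group_summary <- function(y, g) {
  levs <- unique(as.character(g))
  do.call(rbind, lapply(levs, function(l) {
    v <- y[g == l]
    se <- stats::sd(v) / sqrt(length(v))
    half <- if (length(v) > 1) stats::qt(0.975, length(v) - 1) * se else NA_real_
    tibble::tibble(level = l, n = length(v), mean = mean(v),
                   median = stats::median(v),
                   ci_lo = mean(v) - half, ci_hi = mean(v) + half)
  }))
}

#' Test the distribution of a single variable
#'
#' Continuous variables are tested for normality with the Shapiro-Wilk W test;
#' categorical variables against an equal-frequency null with the
#' likelihood-ratio chi-square test (df = levels - 1). Small p-values reject
#' normality / evenness of the distribution.
#'
#' @param values the observations (missing values dropped).
#' @param var_type `"auto"` (numeric means continuous), `"continuous"` or
#'   `"categorical"`.
#' @param name variable name carried into the result.
#' @return one-row tibble (test result).
#' @export
test_distribution <- function(values, var_type = c("auto", "continuous",
                                                   "categorical"),
                              name = deparse1(substitute(values))) {
  var_type <- match.arg(var_type)
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("need at least 3 non-missing values")
  if (var_type == "auto") {
    var_type <- if (is.numeric(values)) "continuous" else "categorical"
  }
  if (var_type == "continuous") {
    if (stats::sd(values) == 0) stop("degenerate distribution: all values identical")
    sw <- stats::shapiro.test(values)
    .new_test_result("shapiro_wilk", name, NA_character_,
                     unname(sw$statistic), sw$p.value, length(values))
  } else {
    counts <- table(as.character(values))
    k <- length(counts)
    if (k < 2) stop("degenerate distribution: all values identical")
    expected <- length(values) / k
    lr <- 2 * sum(counts * log(as.numeric(counts) / expected))
    p <- stats::pchisq(lr, df = k - 1, lower.tail = FALSE)
    .new_test_result("lr_chisq", name, NA_character_, lr, p, length(values),
                     group_summaries = tibble::tibble(
                       level = names(counts), n = as.integer(counts),
                       mean = NA_real_, median = NA_real_,
                       ci_lo = NA_real_, ci_hi = NA_real_))
  }
}

#' Fisher's exact test for a 2 x k contingency table
#'
#' Two-tailed exact test summing, over all tables with the observed margins,
#' the probabilities of tables no more probable than the observed one (the
#' point-probability definition; for 2 x 3 tables the network enumeration of
#' the conditional distribution is used). A table with a zero row or column
#' margin carries no information about association: it returns p = 1 flagged
#' as degenerate rather than an error.
#'
#' @param tab matrix (or table) of nonnegative integer counts with 2 rows and
#'   2 or 3 columns (transposed input is accepted).
#' @param y_var,x_var optional variable names for the report.
#' @return one-row tibble; `statistic` is the conditional odds-ratio estimate
#'   for 2 x 2 tables, `NA` otherwise.
#' @export
fisher_exact <- function(tab, y_var = NA_character_, x_var = NA_character_) {
  tab <- as.matrix(tab)
  if (nrow(tab) > 2 && ncol(tab) == 2) tab <- t(tab)
  if (nrow(tab) != 2 || !ncol(tab) %in% c(2, 3)) {
    stop("contingency table must be 2 x 2 or 2 x 3")
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers")
  }
  n <- sum(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(.new_test_result("fisher_exact", y_var, x_var, NA_real_, 1, n,
                            degenerate = TRUE))
  }
  ft <- stats::fisher.test(tab)
  or <- if (all(dim(tab) == 2)) unname(ft$estimate) else NA_real_
  .new_test_result("fisher_exact", y_var, x_var, or, ft$p.value, n)
}

#' Two-group t test
#'
#' Two-sided pooled-variance t test by default ("t test" without a Welch
#' qualification); Welch's unequal-variance form is available via
#' `welch = TRUE`. Reports per-group means with 95% CIs and the difference CI.
#'
#' @param y continuous response.
#' @param group two-level grouping variable.
#' @param welch use the Welch correction instead of pooled variance.
#' @param y_var,x_var optional variable names for the report.
#' @return one-row tibble; `estimate` is the mean difference
#'   (first level minus second).
#' @export
two_group_t <- function(y, group, welch = FALSE,
                        y_var = NA_character_, x_var = NA_character_) {
  keep <- !is.na(y) & !is.na(group)
  y <- y[keep]; group <- as.character(group)[keep]
  levs <- sort(unique(group))
  if (length(levs) != 2) stop("grouping variable must have exactly 2 levels")
  if (any(table(group) < 2)) stop("both groups need at least 2 values")
  tt <- stats::t.test(y[group == levs[1]], y[group == levs[2]],
                      var.equal = !welch)
  .new_test_result(if (welch) "welch_t" else "pooled_t", y_var, x_var,
                   unname(tt$statistic), tt$p.value, length(y),
                   group_summaries = .group_summary(y, group),
                   extra = list(estimate = unname(diff(rev(tt$estimate))),
                                ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2]))
}

#' One-way ANOVA with Tukey-Kramer post hoc comparisons
#'
#' Singleton levels (one observation) cannot contribute a within-group
#' variance and are excluded, with the excluded levels reported. The post hoc
#' table uses the Tukey-Kramer adjustment, valid for unbalanced groups.
#'
#' @param y continuous response.
#' @param group grouping variable with >= 2 usable levels.
#' @param y_var,x_var optional variable names for the report.
#' @return one-row tibble; `posthoc` holds the pairwise comparisons and
#'   `excluded` any singleton levels.
#' @export
anova_tukey <- function(y, group, y_var = NA_character_, x_var = NA_character_) {
  keep <- !is.na(y) & !is.na(group)
  y <- y[keep]; group <- as.character(group)[keep]
  counts <- table(group)
  excluded <- names(counts)[counts < 2]
  keep2 <- !group %in% excluded
  y <- y[keep2]; group <- factor(group[keep2])
  if (nlevels(group) < 2) stop("need at least 2 groups with at least 2 values")
  fit <- stats::aov(y ~ group)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  posthoc <- tibble::tibble(comparison = rownames(tk),
                            diff = tk[, "diff"], lwr = tk[, "lwr"],
                            upr = tk[, "upr"], p_adj = tk[, "p adj"])
  .new_test_result("anova", y_var, x_var, an$`F value`[1], an$`Pr(>F)`[1],
                   length(y), group_summaries = .group_summary(y, group),
                   posthoc = posthoc,
                   extra = list(excluded = paste(excluded, collapse = ",")))
}

#' Simple linear regression of one continuous variable on another
#'
#' Ordinary least squares fit reporting the slope, R-squared and the F-test
#' p-value, plus the pieces needed to draw a 95% confidence band
#' (intercept, residual SD, mean and SS of x).
#'
#' @param y,x continuous variables.
#' @param y_var,x_var optional variable names for the report.
#' @return one-row tibble; `statistic` is the F statistic and `estimate` the
#'   slope.
#' @export
simple_regression <- function(y, x, y_var = NA_character_,
                              x_var = NA_character_) {
  keep <- !is.na(y) & !is.na(x)
  y <- y[keep]; x <- x[keep]
  if (length(y) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0) stop("x is constant")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- unname(sm$fstatistic)
  p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  .new_test_result("regression", y_var, x_var, fstat[1], p, length(y),
                   extra = list(estimate = unname(stats::coef(fit)[2]),
                                intercept = unname(stats::coef(fit)[1]),
                                r_squared = sm$r.squared,
                                sigma = sm$sigma, x_mean = mean(x),
                                x_ss = sum((x - mean(x))^2)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts the raw p-values ascending, takes `q_i = min_{j >= i} p_j * m / j`
#' capped at 1, and restores the original order. Q-values are adjusted within
#' one family at a time -- one family per screen, mirroring the per-analysis
#' grouping of the multiplicity control.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @param family_label unused label, retained for report bookkeeping.
#' @return adjusted q-values in the original order (empty in, empty out).
#' @export
bh_adjust <- function(pvalues, family_label = NULL) {
  if (!length(pvalues)) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

.var_type <- function(x) if (is.numeric(x)) "continuous" else "categorical"

#' Screen one response against a set of explanatory variables
#'
#' Dispatches per variable-type pair: continuous x continuous goes to
#' [simple_regression()]; continuous x categorical to [two_group_t()] (two
#' levels) or [anova_tukey()] (more); categorical x categorical to
#' [fisher_exact()] on the contingency table. Rows incomplete for a given
#' pair are dropped for that test only (complete-case analysis). Raw p-values
#' are BH-adjusted as one family and results with `q < fdr` flagged.
#'
#' @param data cohort (or per-allele) tibble.
#' @param y_var response column name.
#' @param x_vars explanatory column names.
#' @param fdr false-discovery-rate threshold for flagging (default 0.10).
#' @param welch passed to [two_group_t()].
#' @return tibble with one row per test, q-values and `flagged`.
#' @export
screen <- function(data, y_var, x_vars, fdr = 0.10, welch = FALSE) {
  stopifnot(y_var %in% names(data), all(x_vars %in% names(data)))
  rows <- lapply(x_vars, function(xv) {
    y <- data[[y_var]]; x <- data[[xv]]
    keep <- !is.na(y) & !is.na(x)
    y <- y[keep]; x <- x[keep]
    ty <- .var_type(y); tx <- .var_type(x)
    res <- if (ty == "continuous" && tx == "continuous") {
      simple_regression(y, x, y_var, xv)
    } else if (ty == "continuous" && tx == "categorical") {
      if (length(unique(x)) == 2) two_group_t(y, x, welch, y_var, xv)
      else anova_tukey(y, x, y_var, xv)
    } else if (ty == "categorical" && tx == "continuous") {
      if (length(unique(y)) == 2) two_group_t(x, y, welch, y_var, xv)
      else anova_tukey(x, y, y_var, xv)
    } else {
      fisher_exact(table(y, x), y_var, xv)
    }
    res
  })
  all_names <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(all_names, names(r))) r[[nm]] <- NA
    r[all_names]
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p, family_label = y_var)
  out$flagged <- out$q < fdr
  out
}

#' Export a screen as a tidy delimited table
#'
#' Writes one row per test with the scalar columns
#' (`test_name, y_var, x_var, n_used, statistic, p, q, flagged`).
#'
#' @param results tibble from [screen()] or the single-test functions.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_screen <- function(results, path) {
  cols <- intersect(c("test_name", "y_var", "x_var", "n_used", "statistic",
                      "estimate", "p", "q", "flagged", "degenerate"),
                    names(results))
  utils::write.csv(results[cols], path, row.names = FALSE, na = "")
  invisible(path)
}
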