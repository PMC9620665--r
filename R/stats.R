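#' Per-SD logistic odds ratio for cognitive impairment
#'
#' Maximum-likelihood logistic regression of a binary outcome (cognitive
#' impairment) on one burden measure, optionally with covariates. With
#' `standardize = TRUE` (the default) the predictor and every continuous
#' covariate are z-scored first, so the reported odds ratio is per standard
#' deviation of the measure — the only scale on which measures with wildly
#' different native units (counts/mm^2, pixel fractions, ordinal stages,
#' graph coefficients) are comparable. Confidence interval and p-value are
#' Wald-based, matching the OR-with-95%-CI reporting convention.
#'
#' @param outcome binary vector: 0/1, logical, or a factor/character with
#'   levels NCI/CI (CI = event).
#' @param predictor numeric burden measure.
#' @param covariates optional numeric matrix or data.frame of covariates;
#'   continuous columns (more than two distinct values) are z-scored when
#'   `standardize` is on.
#' @param standardize z-score predictor and continuous covariates
#'   (default TRUE).
#' @param measure_name label carried into reports.
#' @param adjusted_for_age bookkeeping flag carried into reports.
#' @param min_per_class minimum observations required in each outcome class
#'   after listwise deletion (default 10).
#' @return object of class `or_fit` with fields `measure_name`,
#'   `odds_ratio`, `ci95_low`, `ci95_high`, `p_raw`, `p_fdr` (NA until a
#'   battery applies FDR), `adjusted_for_age`, `covariates`, `n`, `n_dropped`
#'   and the underlying `glm` fit.
#' @export
fit_logistic_or <- function(outcome, predictor, covariates = NULL,
                            standardize = TRUE, measure_name = "measure",
                            adjusted_for_age = FALSE, min_per_class = 10L) {
  y <- as_binary_outcome(outcome)
  x <- as.numeric(predictor)
  cv <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (!is.null(cv) && is.null(colnames(cv)))
    colnames(cv) <- paste0("cov", seq_len(ncol(cv)))
  ok <- !is.na(y) & !is.na(x)
  if (!is.null(cv)) ok <- ok & stats::complete.cases(cv)
  n_dropped <- sum(!ok)
  y <- y[ok]; x <- x[ok]; cv <- cv[ok, , drop = FALSE]
  if (min(sum(y == 1L), sum(y == 0L)) < min_per_class)
    stop("fewer than ", min_per_class, " observations in an outcome class ",
         "for predictor '", measure_name, "'")
  if (stats::sd(x) == 0)
    stop("constant predictor '", measure_name, "'")
  zscore <- function(v) (v - mean(v)) / stats::sd(v)
  if (standardize) {
    x <- zscore(x)
    if (!is.null(cv) && ncol(cv))
      for (j in seq_len(ncol(cv)))
        if (length(unique(cv[, j])) > 2L) cv[, j] <- zscore(cv[, j])
  }
  dat <- data.frame(.y = y, .x = x)
  if (!is.null(cv) && ncol(cv)) dat <- cbind(dat, as.data.frame(cv))
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  b <- sm[".x", "Estimate"]; se <- sm[".x", "Std. Error"]
  if (!fit$converged || abs(b) > 15 || se > 100)
    stop("perfect or quasi-perfect separation on predictor '",
         measure_name, "'")
  zq <- stats::qnorm(0.975)
  structure(list(
    measure_name = measure_name,
    odds_ratio = exp(b),
    ci95_low = exp(b - zq * se),
    ci95_high = exp(b + zq * se),
    p_raw = sm[".x", "Pr(>|z|)"],
    p_fdr = NA_real_,
    adjusted_for_age = adjusted_for_age,
    covariates = if (is.null(cv)) character(0) else colnames(cv),
    n = length(y), n_dropped = n_dropped,
    standardized = standardize, fit = fit),
    class = "or_fit")
}

as_binary_outcome <- function(outcome) {
  if (is.logical(outcome)) return(as.integer(outcome))
  if (is.factor(outcome)) outcome <- as.character(outcome)
  if (is.character(outcome)) {
    out <- ifelse(outcome == "CI", 1L, ifelse(outcome == "NCI", 0L, NA))
    if (any(is.na(out) & !is.na(outcome)))
      stop("character outcome must use labels 'CI' / 'NCI'")
    return(out)
  }
  if (!all(outcome %in% c(0, 1, NA)))
    stop("numeric outcome must be 0/1")
  as.integer(outcome)
}

#' @export
print.or_fit <- function(x, ...) {
  cat(sprintf("<or_fit> %s%s: OR %.3f (95%% CI %.3f-%.3f), p = %.4g, n = %d\n",
              x$measure_name,
              if (x$adjusted_for_age) " [age-adjusted]" else "",
              x$odds_ratio, x$ci95_low, x$ci95_high, x$p_raw, x$n))
  invisible(x)
}

#' @export
summary.or_fit <- function(object, ...) {
  print(object)
  if (length(object$covariates))
    cat("  covariates:", paste(object$covariates, collapse = ", "), "\n")
  if (object$n_dropped)
    cat("  listwise-deleted observations:", object$n_dropped, "\n")
  invisible(summary(object$fit))
}

#' @export
coef.or_fit <- function(object, ...) stats::coef(object$fit)

#' @export
confint.or_fit <- function(object, parm, level = 0.95, ...) {
  c(ci95_low = object$ci95_low, ci95_high = object$ci95_high)
}

#' @export
predict.or_fit <- function(object, newdata = NULL, type = "response", ...) {
  if (is.null(newdata)) stats::predict(object$fit, type = type, ...)
  else stats::predict(object$fit, newdata = newdata, type = type, ...)
}

contingency_result <- function(statistic, df, p_value, correction, dims) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), correction = correction,
                 table_dims = dims),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> %dx%d chi-square%s: X2 = %.4f, df = %d, p = %.4g\n",
              x$table_dims[1L], x$table_dims[2L],
              if (x$correction == "yates") " (Yates)" else "",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

check_contingency <- function(tab) {
  tab <- as.matrix(tab)
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab)))
    stop("contingency table must hold non-negative integer counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has a zero margin")
  tab
}

#' 2x2 chi-square test with optional Yates correction
#'
#' Pearson chi-square on a 2x2 count table, by default with the Yates
#' continuity correction (the convention used for the cohort's 2x2 group
#' comparisons).
#'
#' @param tab 2x2 matrix of non-negative integer counts, positive margins.
#' @param correction `"yates"` (default) or `"none"`.
#' @return a `contingency_result` (statistic, df = 1, two-sided p).
#' @export
chi_square_2x2 <- function(tab, correction = c("yates", "none")) {
  correction <- match.arg(correction)
  tab <- check_contingency(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  ct <- suppressWarnings(
    stats::chisq.test(tab, correct = correction == "yates"))
  contingency_result(ct$statistic, ct$parameter, ct$p.value, correction,
                     dim(tab))
}

#' r x c Pearson chi-square test
#'
#' Uncorrected Pearson chi-square on an r x c count table (used e.g. for the
#' Braak-stage distribution across cognitive-status groups).
#'
#' @param tab matrix of non-negative integer counts, positive margins.
#' @return a `contingency_result` with df = (r-1)(c-1).
#' @export
chi_square_rxc <- function(tab) {
  tab <- check_contingency(tab)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  contingency_result(ct$statistic, ct$parameter, ct$p.value, "none", dim(tab))
}

#' Cochran-Mantel-Haenszel stratified odds ratio
#'
#' Pools 2x2 tables over strata (here: two age strata, for age adjustment of
#' a categorical association). The pooled odds ratio is the Mantel-Haenszel
#' estimator `sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`; the p-value is the
#' CMH chi-square, by default without continuity correction (set
#' `correct = TRUE` for the corrected statistic).
#'
#' @param strata list of 2x2 count matrices, or a 2x2xK array.
#' @param correct apply the continuity correction to the CMH chi-square
#'   statistic (default FALSE).
#' @return object of class `cmh_result`: `pooled_or`, `statistic`, `df`,
#'   `p_value`, `n_strata`.
#' @export
cmh_pooled_or <- function(strata, correct = FALSE) {
  if (is.array(strata) && length(dim(strata)) == 3L)
    strata <- lapply(seq_len(dim(strata)[3L]), function(k) strata[, , k])
  if (!length(strata)) stop("at least one stratum is required")
  strata <- lapply(strata, function(s) {
    s <- as.matrix(s)
    if (!all(dim(s) == c(2L, 2L))) stop("every stratum must be 2x2")
    if (anyNA(s) || any(s < 0)) stop("strata must hold non-negative counts")
    if (sum(s) == 0) stop("empty stratum")
    s
  })
  num <- sum(vapply(strata, function(s) s[1, 1] * s[2, 2] / sum(s),
                    numeric(1L)))
  den <- sum(vapply(strata, function(s) s[1, 2] * s[2, 1] / sum(s),
                    numeric(1L)))
  if (num == 0 && den == 0)
    stop("all strata degenerate: no discordant cell products")
  # CMH chi-square: squared pooled deviation of the (1,1) cell from its
  # hypergeometric expectation over the summed hypergeometric variances
  dev <- 0; vsum <- 0
  for (s in strata) {
    n <- sum(s)
    if (n < 2) next
    r1 <- sum(s[1L, ]); r2 <- sum(s[2L, ])
    c1 <- sum(s[, 1L]); c2 <- sum(s[, 2L])
    dev <- dev + s[1L, 1L] - r1 * c1 / n
    vsum <- vsum + r1 * r2 * c1 * c2 / (n^2 * (n - 1))
  }
  if (vsum <= 0) stop("all strata degenerate: zero pooled variance")
  stat <- (max(abs(dev) - if (correct) 0.5 else 0, 0))^2 / vsum
  structure(list(pooled_or = num / den,
                 statistic = stat,
                 df = 1L,
                 p_value = stats::pchisq(stat, 1L, lower.tail = FALSE),
                 n_strata = length(strata), correct = correct),
            class = "cmh_result")
}

#' @export
print.cmh_result <- function(x, ...) {
  cat(sprintf("<cmh_result> %d strata: pooled OR %.3f, CMH X2 = %.4f, p = %.4g\n",
              x$n_strata, x$pooled_or, x$statistic, x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1, in input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (`NA` passed
#'   through).
#' @return adjusted vector, same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Two-sample t-test for group differences
#'
#' Welch (unequal-variance) two-sample t by default; set
#' `var_equal = TRUE` for the pooled-variance Student test. Two degenerate
#' zero-variance groups with equal means return t = 0, p = 1 by convention;
#' zero variance with unequal means is an error.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param var_equal pooled-variance Student test instead of Welch.
#' @return list with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
group_t_test <- function(values_a, values_b, var_equal = FALSE) {
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2L, p_value = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    stop("both groups have zero variance with unequal means")
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; p from the t
#' approximation. A constant input leaves the coefficient undefined: the
#' result carries `NA` with a warning rather than an arbitrary value.
#'
#' @param x,y numeric vectors, length >= 3, pairwise complete.
#' @return list with `rho` and `p_value`.
#' @export
spearman_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Pearson product-moment correlation
#'
#' @inheritParams spearman_corr
#' @return list with `r` and `p_value`.
#' @export
pearson_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Pearson correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Sequential (Type-I) sums of squares on a two-factor design with
#' interaction — unambiguous on the balanced designs it is meant for
#' (region x cognitive status with equal cell sizes); a warning flags
#' unbalanced input.
#'
#' @param values numeric response.
#' @param factor_a,factor_b factors (or coercible), >= 2 levels each, every
#'   cell of the cross non-empty.
#' @return data.frame with one row per effect (`factor_a`, `factor_b`,
#'   `interaction`, `residuals`): `df`, `sum_sq`, `mean_sq`, `F`, `p_value`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (nlevels(fa) < 2L || nlevels(fb) < 2L)
    stop("each factor needs at least 2 levels")
  cells <- table(fa, fb)
  if (any(cells == 0)) stop("empty design cell")
  if (length(unique(as.vector(cells))) > 1L)
    warning("unbalanced design: sequential sums of squares are order-dependent")
  fit <- stats::aov(values ~ fa * fb)
  sm <- summary(fit)[[1L]]
  data.frame(
    effect = c("factor_a", "factor_b", "interaction", "residuals"),
    df = sm[["Df"]], sum_sq = sm[["Sum Sq"]], mean_sq = sm[["Mean Sq"]],
    F = sm[["F value"]], p_value = sm[["Pr(>F)"]],
    stringsAsFactors = FALSE)
}
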