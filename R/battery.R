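#' Odds-ratio battery over burden measures
#'
#' Fits, for every supplied burden measure, the per-SD logistic odds ratio
#' of cognitive impairment — unadjusted and age-adjusted — and applies
#' Benjamini-Hochberg FDR within each adjustment condition (the battery of
#' measures is the multiplicity family; the radius grid of an OR curve is a
#' separate family handled by [or_curve_over_r()]). A clustering-coefficient
#' measure may be flagged so that the total NFT count enters its fits as a
#' nuisance covariate in both conditions.
#'
#' @param data data.frame with one row per subject.
#' @param measure_cols character vector of measure column names (e.g. the
#'   nine region x metric burden columns, plus optionally Braak stage and
#'   the mean clustering coefficient).
#' @param outcome_col name of the binary outcome column (default
#'   `"cognitive_status"`, CI/NCI).
#' @param age_col name of the age column (default `"age_at_death"`).
#' @param clustering_cols subset of `measure_cols` that need the NFT-count
#'   nuisance covariate.
#' @param n_nfts_col column holding the total NFT count (required when
#'   `clustering_cols` is non-empty).
#' @param standardize per-SD scaling (default TRUE).
#' @return object of class `or_battery`: data.frame with columns `measure`,
#'   `condition` (`unadjusted` / `age_adjusted`), `odds_ratio`, `ci95_low`,
#'   `ci95_high`, `p_raw`, `p_fdr`, `n`.
#' @export
or_battery <- function(data, measure_cols,
                       outcome_col = "cognitive_status",
                       age_col = "age_at_death",
                       clustering_cols = character(0),
                       n_nfts_col = NULL, standardize = TRUE) {
  stopifnot(all(measure_cols %in% names(data)),
            outcome_col %in% names(data), age_col %in% names(data))
  if (length(clustering_cols)) {
    if (is.null(n_nfts_col))
      stop("n_nfts_col is required when clustering measures are included")
    if (!n_nfts_col %in% names(data))
      stop("n_nfts_col '", n_nfts_col, "' not found in data")
  }
  one <- function(measure, adjusted) {
    cov <- NULL
    if (measure %in% clustering_cols)
      cov <- cbind(n_nfts = data[[n_nfts_col]])
    if (adjusted) cov <- cbind(cov, age = data[[age_col]])
    fit <- fit_logistic_or(
      data[[outcome_col]], data[[measure]], covariates = cov,
      standardize = standardize, measure_name = measure,
      adjusted_for_age = adjusted)
    data.frame(measure = measure,
               condition = if (adjusted) "age_adjusted" else "unadjusted",
               odds_ratio = fit$odds_ratio, ci95_low = fit$ci95_low,
               ci95_high = fit$ci95_high, p_raw = fit$p_raw, n = fit$n,
               stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, c(
    lapply(measure_cols, one, adjusted = FALSE),
    lapply(measure_cols, one, adjusted = TRUE)))
  d$p_fdr <- NA_real_
  for (cond in unique(d$condition)) {
    i <- d$condition == cond
    d$p_fdr[i] <- bh_fdr(d$p_raw[i])
  }
  d <- d[c("measure", "condition", "odds_ratio", "ci95_low", "ci95_high",
           "p_raw", "p_fdr", "n")]
  structure(d, class = c("or_battery", "data.frame"))
}

#' @export
print.or_battery <- function(x, digits = 3, ...) {
  cat("<or_battery> odds of cognitive impairment per SD of each measure\n")
  for (cond in unique(x$condition)) {
    cat(sprintf("-- %s --\n", cond))
    sub <- x[x$condition == cond, ]
    for (i in seq_len(nrow(sub)))
      cat(sprintf("  %-28s OR %5.2f (%.2f-%.2f)  p %.4g  p_fdr %.4g%s\n",
                  sub$measure[i], sub$odds_ratio[i], sub$ci95_low[i],
                  sub$ci95_high[i], sub$p_raw[i], sub$p_fdr[i],
                  if (!is.na(sub$p_fdr[i]) && sub$p_fdr[i] < 0.05) " *" else ""))
  }
  invisible(x)
}

#' Age-adjusted group residuals
#'
#' Residualizes a burden measure on age with an ordinary linear fit, for
#' age-corrected group displays and t-tests: the residual carries the part
#' of the measure not linearly explained by age.
#'
#' @param values numeric measure.
#' @param age numeric age vector.
#' @return residual vector (same length; `NA` where either input is `NA`).
#' @export
age_adjusted_residuals <- function(values, age) {
  ok <- !is.na(values) & !is.na(age)
  out <- rep(NA_real_, length(values))
  fit <- stats::lm(values[ok] ~ age[ok])
  out[ok] <- stats::resid(fit)
  out
}
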