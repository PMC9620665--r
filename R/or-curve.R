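#' Odds-ratio curve over the radius sweep
#'
#' For every radius of the clustering sweep, fits the per-SD logistic odds
#' ratio of cognitive impairment on the mean clustering coefficient at that
#' radius. The total NFT count enters every fit as a nuisance covariate
#' (the coefficient of a radius graph confounds arrangement with density);
#' age is added when supplied. P-values are FDR-adjusted across the radius
#' grid, which is the multiplicity family here.
#'
#' Subjects whose sweep is undefined (fewer than 3 NFTs) are dropped
#' listwise; a radius at which the fit is impossible (too few subjects per
#' class, constant or separating predictor) is reported as a missing row,
#' never silently skipped.
#'
#' @param sweeps list of [clustering_sweep()] objects, one per subject, all
#'   on the same radius grid.
#' @param outcome binary outcome vector aligned with `sweeps` (see
#'   [fit_logistic_or()] for accepted encodings).
#' @param age optional numeric age vector aligned with `sweeps`; when given,
#'   fits are age-adjusted.
#' @param include_n_nfts include the total NFT count nuisance covariate
#'   (default TRUE).
#' @param standardize per-SD scaling as in [fit_logistic_or()].
#' @param min_per_class minimum subjects per outcome class at each radius
#'   (default 2).
#' @return object of class `or_curve`: data.frame with columns `r_px`,
#'   `odds_ratio`, `ci95_low`, `ci95_high`, `p_raw`, `p_fdr`, `n_used`.
#' @export
or_curve_over_r <- function(sweeps, outcome, age = NULL,
                            include_n_nfts = TRUE, standardize = TRUE,
                            min_per_class = 2L) {
  if (inherits(sweeps, "clustering_sweep")) sweeps <- list(sweeps)
  n_sub <- length(sweeps)
  if (n_sub < 2L) stop("need sweeps for at least 2 subjects")
  r <- sweeps[[1L]]$r_px
  for (s in sweeps)
    if (!identical(s$r_px, r)) stop("all sweeps must share one radius grid")
  cc <- vapply(sweeps, function(s) s$mean_cc, numeric(length(r)))
  cc <- matrix(cc, nrow = length(r))          # radii x subjects
  n_nfts <- vapply(sweeps, function(s) s$n_nfts[1L], numeric(1L))
  y <- as_binary_outcome(outcome)
  if (length(y) != n_sub) stop("outcome length must match number of sweeps")
  if (!is.null(age) && length(age) != n_sub)
    stop("age length must match number of sweeps")
  rows <- lapply(seq_along(r), function(i) {
    xi <- cc[i, ]
    cov <- NULL
    if (include_n_nfts) cov <- cbind(n_nfts = n_nfts)
    if (!is.null(age)) cov <- cbind(cov, age = age)
    fit <- tryCatch(
      fit_logistic_or(y, xi, covariates = cov, standardize = standardize,
                      measure_name = sprintf("mean_cc@r=%g", r[i]),
                      adjusted_for_age = !is.null(age),
                      min_per_class = min_per_class),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(r_px = r[i], odds_ratio = NA_real_,
                        ci95_low = NA_real_, ci95_high = NA_real_,
                        p_raw = NA_real_, n_used = sum(!is.na(xi) & !is.na(y))))
    data.frame(r_px = r[i], odds_ratio = fit$odds_ratio,
               ci95_low = fit$ci95_low, ci95_high = fit$ci95_high,
               p_raw = fit$p_raw, n_used = fit$n)
  })
  d <- do.call(rbind, rows)
  d$p_fdr <- bh_fdr(d$p_raw)
  d <- d[c("r_px", "odds_ratio", "ci95_low", "ci95_high",
           "p_raw", "p_fdr", "n_used")]
  structure(d, class = c("or_curve", "data.frame"),
            adjusted_for_age = !is.null(age),
            include_n_nfts = include_n_nfts)
}

#' @export
print.or_curve <- function(x, ...) {
  ok <- !is.na(x$p_fdr)
  cat(sprintf("<or_curve> %d radii (%g..%g px)%s\n", nrow(x),
              min(x$r_px), max(x$r_px),
              if (isTRUE(attr(x, "adjusted_for_age"))) ", age-adjusted" else ""))
  if (any(ok)) {
    imax <- which.max(ifelse(ok, x$odds_ratio, -Inf))
    cat(sprintf("  max OR %.3f at r = %g px (p_fdr = %.4g)\n",
                x$odds_ratio[imax], x$r_px[imax], x$p_fdr[imax]))
    sig <- ok & x$p_fdr < 0.05
    if (any(sig))
      cat(sprintf("  FDR-significant radii: %g..%g px (%d of %d)\n",
                  min(x$r_px[sig]), max(x$r_px[sig]), sum(sig), sum(ok)))
    else cat("  no FDR-significant radius\n")
  }
  invisible(x)
}

#' @export
plot.or_curve <- function(x, ...) {
  ok <- !is.na(x$odds_ratio)
  graphics::plot(x$r_px[ok], x$odds_ratio[ok], type = "l",
                 ylim = range(c(x$ci95_low[ok], x$ci95_high[ok], 1)),
                 xlab = "radius threshold r (px)",
                 ylab = "odds ratio of cognitive impairment (per SD)", ...)
  graphics::polygon(c(x$r_px[ok], rev(x$r_px[ok])),
                    c(x$ci95_low[ok], rev(x$ci95_high[ok])),
                    col = grDevices::adjustcolor("red", 0.15), border = "red")
  graphics::lines(x$r_px[ok], x$odds_ratio[ok])
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
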