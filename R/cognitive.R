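#' Label a subject's cognitive status from clinical scores
#'
#' Dichotomizes antemortem cognition into cognitively impaired (`CI`) versus
#' no cognitive impairment (`NCI`). When both a Clinical Dementia Rating and
#' a Mini-Mental State Examination score are on record, the more recently
#' assessed one decides; on a shared (or unresolvable) assessment date the
#' CDR decides. CDR >= 0.5 or MMSE < 26 reads as impaired; CDR 0 or
#' MMSE >= 26 as normal. With neither score available, a chart-review
#' impairment flag decides.
#'
#' @param cdr CDR global score in \{0, 0.5, 1, 2, 3\}, or `NA`.
#' @param cdr_date,mmse_date assessment dates (`Date` or parseable string),
#'   `NA` if unknown. Dates are compared at day resolution.
#' @param mmse MMSE total 0-30, or `NA`.
#' @param clinical_flag logical chart-review impairment flag, or `NA`.
#' @return `"CI"` or `"NCI"`.
#' @export
label_cognitive_status <- function(cdr = NA, cdr_date = NA,
                                   mmse = NA, mmse_date = NA,
                                   clinical_flag = NA) {
  has_cdr <- !is.na(cdr); has_mmse <- !is.na(mmse)
  if (!has_cdr && !has_mmse && is.na(clinical_flag))
    stop("cannot label cognitive status: no CDR, MMSE or chart-review flag")
  if (has_cdr && !cdr %in% c(0, 0.5, 1, 2, 3))
    stop("CDR must be one of 0, 0.5, 1, 2, 3")
  if (has_mmse && (mmse < 0 || mmse > 30))
    stop("MMSE must be in 0..30")
  from_cdr <- function() if (cdr >= 0.5) "CI" else "NCI"
  from_mmse <- function() if (mmse < 26) "CI" else "NCI"
  if (has_cdr && has_mmse) {
    d1 <- suppressWarnings(as.Date(cdr_date))
    d2 <- suppressWarnings(as.Date(mmse_date))
    if (is.na(d1) || is.na(d2)) {
      warning("missing assessment date with both scores present; using CDR")
      return(from_cdr())
    }
    if (d2 > d1) return(from_mmse())
    return(from_cdr())          # more recent CDR, or same-date tie
  }
  if (has_cdr) return(from_cdr())
  if (has_mmse) return(from_mmse())
  if (isTRUE(as.logical(clinical_flag))) "CI" else "NCI"
}

#' Label cognitive status for every subject of a cohort table
#'
#' Vectorized wrapper over [label_cognitive_status()]; subjects with no
#' usable input get `NA` and are counted in the attached exclusion log.
#'
#' @param cohort data.frame as returned by [read_cohort_table()].
#' @return the cohort with a `cognitive_status` column added; attribute
#'   `n_unlabelable` counts subjects that could not be labeled.
#' @export
label_cohort <- function(cohort) {
  get <- function(nm) if (nm %in% names(cohort)) cohort[[nm]]
                      else rep(NA, nrow(cohort))
  cdr <- get("cdr"); mmse <- get("mmse"); flag <- get("clinical_impairment")
  cdr_d <- get("cdr_date"); mmse_d <- get("mmse_date")
  status <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    status[i] <- if (is.na(cdr[i]) && is.na(mmse[i]) && is.na(flag[i]))
      NA_character_
    else
      label_cognitive_status(cdr[i], cdr_d[i], mmse[i], mmse_d[i], flag[i])
  }
  cohort$cognitive_status <- status
  attr(cohort, "n_unlabelable") <- sum(is.na(status))
  cohort
}
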