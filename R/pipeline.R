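#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis: input/output paths,
#' pixel pitch, instance-extraction parameters, the radius sweep grid, and
#' the statistical options (per-SD standardization, t-test variant, the
#' CMH age cut, the low-degree clustering convention, the radius reported
#' in the odds-ratio battery).
#'
#' @param cohort_path cohort covariate table (CSV).
#' @param slide_dir directory of per-subject NFT tables
#'   (`<subject_id>.csv`).
#' @param regions_path region annotation GeoJSON shared by all slides.
#' @param out_dir output directory.
#' @param pixel_size_um microns per pixel.
#' @param threshold,min_size_px,connectivity instance-extraction defaults
#'   (used when inputs are probability maps).
#' @param r_start_px,r_stop_px,r_step_px clustering sweep grid.
#' @param r_report_px radius whose mean clustering coefficient enters the
#'   OR battery (default 800).
#' @param standardize per-SD odds ratios (default TRUE).
#' @param t_var_equal pooled-variance Student t instead of Welch.
#' @param cmh_cut age cut for the two CMH strata: `"median"` or a number.
#' @param low_degree clustering convention for degree-<2 nodes
#'   (`"zero"`/`"exclude"`).
#' @param seed integer seed recorded in the run manifest.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_path, slide_dir, regions_path, out_dir,
                            pixel_size_um = 0.5066, threshold = 0.5,
                            min_size_px = 20L, connectivity = 8L,
                            r_start_px = 100, r_stop_px = 5000,
                            r_step_px = 100, r_report_px = 800,
                            standardize = TRUE, t_var_equal = FALSE,
                            cmh_cut = "median",
                            low_degree = c("zero", "exclude"), seed = 1L) {
  structure(list(cohort_path = cohort_path, slide_dir = slide_dir,
                 regions_path = regions_path, out_dir = out_dir,
                 pixel_size_um = pixel_size_um, threshold = threshold,
                 min_size_px = min_size_px, connectivity = connectivity,
                 r_start_px = r_start_px, r_stop_px = r_stop_px,
                 r_step_px = r_step_px, r_report_px = r_report_px,
                 standardize = standardize, t_var_equal = t_var_equal,
                 cmh_cut = cmh_cut,
                 low_degree = match.arg(low_degree), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Validate a pipeline configuration
#'
#' Collects every problem rather than failing on the first, so a config can
#' be fixed in one pass.
#'
#' @param config a [pipeline_config()].
#' @return character vector of error messages; empty when valid.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  if (!file.exists(config$cohort_path))
    add(paste0("cohort_path does not exist: ", config$cohort_path))
  if (!dir.exists(config$slide_dir))
    add(paste0("slide_dir does not exist: ", config$slide_dir))
  if (!file.exists(config$regions_path))
    add(paste0("regions_path does not exist: ", config$regions_path))
  if (!is.numeric(config$pixel_size_um) || config$pixel_size_um <= 0)
    add("pixel_size_um must be positive")
  if (config$threshold <= 0 || config$threshold >= 1)
    add("threshold must be in (0, 1)")
  if (config$min_size_px < 1) add("min_size_px must be >= 1")
  if (!config$connectivity %in% c(4L, 8L))
    add("connectivity must be 4 or 8")
  if (config$r_start_px <= 0) add("r_start_px must be positive")
  if (config$r_stop_px < config$r_start_px)
    add("r_stop_px must be >= r_start_px")
  if (config$r_step_px <= 0) add("r_step_px must be positive")
  if (!(identical(config$cmh_cut, "median") || is.numeric(config$cmh_cut)))
    add("cmh_cut must be \"median\" or a number")
  errs
}

# two-level age stratification of a 2x2 association
cmh_age_strata <- function(exposure, outcome, age, cut = "median") {
  cutv <- if (identical(cut, "median")) stats::median(age, na.rm = TRUE)
          else cut
  ok <- !is.na(exposure) & !is.na(outcome) & !is.na(age)
  lapply(split(seq_along(age)[ok], age[ok] > cutv), function(i) {
    table(factor(exposure[i], levels = c(TRUE, FALSE)),
          factor(outcome[i], levels = c("CI", "NCI")))
  })
}

#' Group descriptives with tests
#'
#' The cohort-summary table: sex and ARTAG 2x2 Yates chi-squares (plus the
#' CMH age-stratified pooled OR for ARTAG), the Braak-stage r x c
#' chi-square, and the Welch t-test on age at death, each comparing
#' cognitively impaired against unimpaired subjects.
#'
#' @param subjects labeled cohort table (with `cognitive_status`).
#' @param t_var_equal pooled-variance t instead of Welch.
#' @param cmh_cut age cut for the ARTAG CMH strata.
#' @return data.frame with columns `variable`, `test`, `statistic`,
#'   `p_value`, `note`.
#' @export
cohort_descriptives <- function(subjects, t_var_equal = FALSE,
                                cmh_cut = "median") {
  st <- subjects$cognitive_status
  rows <- list()
  push <- function(variable, test, statistic, p_value, note = "")
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, test = test, statistic = statistic,
      p_value = p_value, note = note, stringsAsFactors = FALSE)
  if ("sex" %in% names(subjects)) {
    tab <- table(subjects$sex, st)
    r <- chi_square_2x2(tab)
    push("sex", "chi2_yates", r$statistic, r$p_value)
  }
  if ("artag" %in% names(subjects)) {
    tab <- table(subjects$artag, st)
    r <- chi_square_2x2(tab)
    push("artag", "chi2_yates", r$statistic, r$p_value)
    if ("age_at_death" %in% names(subjects)) {
      strata <- cmh_age_strata(subjects$artag, st, subjects$age_at_death,
                               cmh_cut)
      cm <- cmh_pooled_or(strata)
      push("artag", "cmh_age_adjusted", cm$statistic, cm$p_value,
           sprintf("pooled OR %.3f over %d age strata", cm$pooled_or,
                   cm$n_strata))
    }
  }
  if ("braak_stage" %in% names(subjects)) {
    tab <- table(subjects$braak_stage, st)
    r <- chi_square_rxc(tab)
    push("braak_stage", "chi2_rxc", r$statistic, r$p_value,
         sprintf("df %d", r$df))
  }
  if ("age_at_death" %in% names(subjects)) {
    tt <- group_t_test(subjects$age_at_death[st == "CI"],
                       subjects$age_at_death[st == "NCI"],
                       var_equal = t_var_equal)
    push("age_at_death", if (t_var_equal) "student_t" else "welch_t",
         tt$t, tt$p_value,
         sprintf("CI mean %.2f vs NCI mean %.2f", tt$mean_a, tt$mean_b))
  }
  do.call(rbind, rows)
}

#' Per-subject wide measure table
#'
#' Computes burden metrics for every slide and spreads them into one row
#' per subject with `<metric>_<region>` columns, joining positive-pixel
#' counts from the cohort table (`positive_px_<region>` /
#' `total_px_<region>` columns) when present, plus the total NFT count and,
#' when sweeps are supplied, the mean clustering coefficient at the
#' reporting radius.
#'
#' @param slides list of [slide_record()] objects.
#' @param subjects cohort table.
#' @param sweeps optional list of [clustering_sweep()] objects aligned with
#'   `slides`.
#' @param r_report_px radius reported as `mean_cc` (default 800).
#' @return data.frame keyed by `subject_id`.
#' @export
cohort_measure_table <- function(slides, subjects, sweeps = NULL,
                                 r_report_px = 800) {
  wide <- lapply(slides, function(s) {
    pos <- NULL; tot <- NULL
    row <- subjects[match(s$subject_id, subjects$subject_id), , drop = FALSE]
    reg_names <- c(vapply(s$regions, function(r) r$label, character(1L)),
                   "combined")
    pos_cols <- paste0("positive_px_", reg_names)
    if (nrow(row) == 1L && all(pos_cols %in% names(subjects))) {
      pos <- stats::setNames(as.numeric(row[1L, pos_cols]), reg_names)
      areas <- vapply(s$regions, function(r) r$area_px, numeric(1L))
      tot <- stats::setNames(c(areas, sum(areas)), reg_names)
    }
    m <- burden_metrics(s, positive_px = pos, total_px = tot)
    out <- data.frame(subject_id = s$subject_id, n_nfts = nrow(s$nfts),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(m))) {
      rg <- m$region[i]
      out[[paste0("nft_count_density_", rg)]] <- m$nft_count_density[i]
      out[[paste0("nft_pixel_density_", rg)]] <- m$nft_pixel_density[i]
      out[[paste0("positive_pixel_burden_", rg)]] <-
        m$positive_pixel_burden[i]
    }
    out
  })
  d <- do.call(rbind, wide)
  # the freshly computed NFT count is authoritative over any same-named
  # column already in the cohort table
  subjects <- subjects[setdiff(names(subjects), c("n_nfts", "mean_cc"))]
  if (!is.null(sweeps)) {
    cc <- vapply(sweeps, function(s) {
      i <- which(s$r_px == r_report_px)
      if (length(i)) s$mean_cc[i] else NA_real_
    }, numeric(1L))
    d$mean_cc <- cc[match(d$subject_id,
                          vapply(sweeps, function(s) s$subject_id[1L],
                                 character(1L)))]
  }
  merge(subjects, d, by = "subject_id", sort = TRUE)
}

#' Run the full analysis pipeline
#'
#' Ingestion, regional burden metrics, the clustering sweep, and the
#' statistical battery, in one deterministic pass: (a) group
#' descriptives, (b) the per-SD odds-ratio battery
#' (unadjusted and age-adjusted, FDR within each condition), (c) the
#' odds-ratio-versus-radius curve with the NFT-count nuisance covariate,
#' (d) the per-subject metrics table. Every exclusion (unlabelable
#' subjects, slides with fewer than 3 NFTs, missing slide files) is
#' messaged, never silent. All outputs are written under
#' `config$out_dir` and returned invisibly.
#'
#' @param config a [pipeline_config()] (or path to its YAML form).
#' @return object of class `nft_report`: list with `descriptives`,
#'   `battery`, `or_curve`, `measures`, `sweeps`, `exclusions`, `config`.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  errs <- validate_config(config)
  if (length(errs))
    stop("invalid pipeline config:\n  ", paste(errs, collapse = "\n  "))
  subjects <- read_cohort_table(config$cohort_path)
  subjects <- subjects[order(subjects$subject_id), , drop = FALSE]
  subjects <- label_cohort(subjects)
  excl <- list(unlabelable = attr(subjects, "n_unlabelable"))
  if (excl$unlabelable)
    message(excl$unlabelable, " subject(s) lack CDR/MMSE/chart data and ",
            "stay unlabeled")
  regions <- read_region_geojson(config$regions_path)
  paths <- file.path(config$slide_dir, paste0(subjects$subject_id, ".csv"))
  have <- file.exists(paths)
  excl$missing_slides <- sum(!have)
  if (excl$missing_slides)
    message(excl$missing_slides, " subject(s) have no NFT table and are ",
            "dropped")
  subjects <- subjects[have, , drop = FALSE]
  slides <- lapply(seq_len(nrow(subjects)), function(i) {
    nfts <- assign_regions(
      read_nft_table(file.path(config$slide_dir,
                               paste0(subjects$subject_id[i], ".csv"))),
      regions)
    slide_record(subjects$subject_id[i], nfts, regions,
                 pixel_size_um = config$pixel_size_um, check = FALSE)
  })
  sweeps <- lapply(slides, function(s)
    clustering_sweep(s$nfts[, c("x", "y")], config$r_start_px,
                     config$r_stop_px, config$r_step_px,
                     pixel_size_um = config$pixel_size_um,
                     low_degree = config$low_degree,
                     subject_id = s$subject_id))
  excl$sweep_undefined <- sum(vapply(sweeps, function(s)
    all(is.na(s$mean_cc)), logical(1L)))
  if (excl$sweep_undefined)
    message(excl$sweep_undefined, " slide(s) have < 3 NFTs; their sweep ",
            "values are missing and excluded from clustering regressions")
  measures <- cohort_measure_table(slides, subjects, sweeps,
                                   config$r_report_px)
  descriptives <- cohort_descriptives(measures,
                                      t_var_equal = config$t_var_equal,
                                      cmh_cut = config$cmh_cut)
  burden_cols <- grep("^(nft_count_density|nft_pixel_density|positive_pixel_burden)_",
                      names(measures), value = TRUE)
  burden_cols <- burden_cols[vapply(burden_cols, function(cl)
    sum(!is.na(measures[[cl]])) > 0 &&
      stats::sd(measures[[cl]], na.rm = TRUE) > 0, logical(1L))]
  measure_cols <- burden_cols
  clustering_cols <- character(0)
  if ("braak_stage" %in% names(measures)) measure_cols <-
    c("braak_stage", measure_cols)
  if ("mean_cc" %in% names(measures) &&
      sum(!is.na(measures$mean_cc)) > 0) {
    measure_cols <- c(measure_cols, "mean_cc")
    clustering_cols <- "mean_cc"
  }
  battery <- or_battery(measures, measure_cols,
                        clustering_cols = clustering_cols,
                        n_nfts_col = "n_nfts",
                        standardize = config$standardize)
  curve <- or_curve_over_r(sweeps, measures$cognitive_status,
                           standardize = config$standardize)
  report <- structure(list(descriptives = descriptives, battery = battery,
                           or_curve = curve, measures = measures,
                           sweeps = sweeps, exclusions = excl,
                           config = config),
                      class = "nft_report")
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  utils::write.csv(descriptives, file.path(out, "descriptives.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(battery), file.path(out, "or_report.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(as.data.frame(battery),
                       file.path(out, "or_report.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(as.data.frame(curve), file.path(out, "or_curve.csv"),
                   row.names = FALSE, na = "")
  drop_dates <- setdiff(names(measures), c("cdr_date", "mmse_date"))
  utils::write.csv(measures[drop_dates], file.path(out, "measures.csv"),
                   row.names = FALSE, na = "")
  write_sweep_table(sweeps, file.path(out, "sweeps.csv"))
  invisible(report)
}

#' @export
print.nft_report <- function(x, ...) {
  cat("<nft_report>\n== descriptives ==\n")
  print(x$descriptives, row.names = FALSE)
  cat("== odds-ratio battery ==\n")
  print(x$battery)
  cat("== OR curve ==\n")
  print(x$or_curve)
  invisible(x)
}
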