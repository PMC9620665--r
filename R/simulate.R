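#' Built-in region annotation template
#'
#' The two fixed, non-overlapping region polygons used by the synthetic
#' cohort: a half-annulus "hippocampus" (about 32 mm^2 at the default pixel
#' pitch) and a rectangular "entorhinal" band (about 50 mm^2) below it.
#' They stand in for the manually traced anatomy of a real slide; a GeoJSON
#' copy ships in `inst/extdata/region_template.geojson`.
#'
#' @param n_arc vertices per arc of the half-annulus (default 40).
#' @return list of two [region_annotation()] objects.
#' @export
region_template <- function(n_arc = 40L) {
  cx <- 16000; cy <- 13000
  ro <- 12000; ri <- 8000
  th <- seq(0, pi, length.out = n_arc)
  outer_arc <- cbind(cx + ro * cos(th), cy - ro * sin(th))
  inner_arc <- cbind(cx + ri * cos(rev(th)), cy - ri * sin(rev(th)))
  hip <- region_annotation("hippocampus", rbind(outer_arc, inner_arc))
  ent <- region_annotation("entorhinal",
                           cbind(c(2000, 30000, 30000, 2000),
                                 c(14000, 14000, 20960, 20960)))
  list(hip, ent)
}

#' Simulate complete spatial randomness in a region
#'
#' Homogeneous Poisson process: the point count is Poisson with mean
#' `intensity x area`, and locations are uniform in the polygon by
#' rejection from its bounding box. This is the null spatial model against
#' which clustered tangle patterns are judged.
#'
#' @param intensity expected points per mm^2 (> 0).
#' @param region a [region_annotation()].
#' @param pixel_size_um microns per pixel.
#' @param seed optional integer seed.
#' @param n_points optional fixed point count (overrides the Poisson draw;
#'   used for matched-n comparisons).
#' @return two-column matrix of point coordinates (level-0 pixels).
#' @export
simulate_csr <- function(intensity, region, pixel_size_um = 0.5066,
                         seed = NULL, n_points = NULL) {
  if (is.null(n_points) && intensity <= 0) stop("intensity must be positive")
  if (!is.null(seed)) set.seed(seed)
  area <- region_area_mm2(region, pixel_size_um)
  n <- if (is.null(n_points)) stats::rpois(1L, intensity * area)
       else as.integer(n_points)
  v <- region$vertices
  xr <- range(v[, 1L]); yr <- range(v[, 2L])
  accept <- region$area_px / (diff(xr) * diff(yr))
  if (accept < 1e-4)
    stop("degenerate sliver polygon: rejection acceptance below 1e-4")
  pts <- matrix(numeric(0), 0L, 2L)
  while (nrow(pts) < n) {
    m <- ceiling((n - nrow(pts)) / accept * 1.2) + 16L
    cand <- cbind(stats::runif(m, xr[1L], xr[2L]),
                  stats::runif(m, yr[1L], yr[2L]))
    keep <- point_in_polygon(cand[, 1L], cand[, 2L], v)
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts[seq_len(n), , drop = FALSE]
}

#' Simulate a Thomas cluster process in a region
#'
#' Neyman-Scott clustered alternative: Poisson parents at intensity `kappa`
#' over the region's bounding box dilated by four dispersion lengths,
#' Poisson(`mu`) offspring per parent displaced by an isotropic Gaussian of
#' standard deviation `sigma_px`, offspring outside the polygon discarded.
#' The retained count has mean approximately `kappa * mu * area`.
#'
#' @param kappa parent intensity, parents per mm^2 (> 0).
#' @param mu mean offspring per parent (> 0).
#' @param sigma_px Gaussian dispersion of offspring around their parent, in
#'   pixels (> 0).
#' @inheritParams simulate_csr
#' @return two-column matrix of retained point coordinates.
#' @export
simulate_thomas <- function(kappa, mu, sigma_px, region,
                            pixel_size_um = 0.5066, seed = NULL) {
  if (kappa <= 0 || mu <= 0 || sigma_px <= 0)
    stop("kappa, mu and sigma_px must be positive")
  if (!is.null(seed)) set.seed(seed)
  v <- region$vertices
  pad <- 4 * sigma_px
  xr <- range(v[, 1L]) + c(-pad, pad)
  yr <- range(v[, 2L]) + c(-pad, pad)
  mm_per_px <- pixel_size_um / 1000
  win_mm2 <- diff(xr) * diff(yr) * mm_per_px^2
  n_par <- stats::rpois(1L, kappa * win_mm2)
  if (n_par == 0L) return(matrix(numeric(0), 0L, 2L))
  parx <- stats::runif(n_par, xr[1L], xr[2L])
  pary <- stats::runif(n_par, yr[1L], yr[2L])
  n_off <- stats::rpois(n_par, mu)
  if (sum(n_off) == 0L) return(matrix(numeric(0), 0L, 2L))
  ox <- rep(parx, n_off) + stats::rnorm(sum(n_off), 0, sigma_px)
  oy <- rep(pary, n_off) + stats::rnorm(sum(n_off), 0, sigma_px)
  keep <- point_in_polygon(ox, oy, v)
  cbind(ox[keep], oy[keep])
}

#' Parameters of the synthetic autopsy cohort
#'
#' Encodes the statistical structure the analysis assumes: ~700 elderly
#' subjects (truncated-normal age, mean 85, SD 10, range 55-110); per-slide
#' NFT counts log-linear in standardized age with the slope solved so the
#' count-age correlation is about 0.3; spatial patterns a mixture of Thomas
#' (clustered) and homogeneous Poisson points at matched expected count; and
#' a logistic outcome model
#' `logit P(CI) = beta0 + beta_burden * z(count) + beta_age * z(age)` with a
#' per-SD burden odds ratio of 1.40 and the age coefficient moment-matched
#' to a ~4.5-year CI/NCI age gap. Clinical instruments (CDR, MMSE,
#' chart-review flag) encode the outcome with a symmetric label-noise
#' probability (default 0.1) emulating the noise of retrospective clinical
#' classification.
#'
#' @param n_subjects cohort size (default 706).
#' @param age_mean,age_sd,age_bounds truncated-normal age model (years).
#' @param mean_nft_count expected whole-slide NFT count at mean age.
#' @param count_age_corr target Pearson correlation between NFT count and
#'   age (default 0.3); the log-intensity slope is solved from it by moment
#'   matching.
#' @param clustered_weight probability a subject's pattern is Thomas rather
#'   than CSR (default 0.5).
#' @param thomas_mu,thomas_sigma_px Thomas offspring mean and dispersion.
#' @param beta_burden per-SD log-odds of the burden effect
#'   (default `log(1.40)`).
#' @param beta_age per-SD-age log-odds; `NULL` (default) moment-matches an
#'   `age_gap_years` CI/NCI gap.
#' @param age_gap_years target CI-minus-NCI mean age gap (default 4.5).
#' @param beta0 outcome intercept (default `log(344/362)`, a ~49% impaired
#'   fraction).
#' @param label_noise symmetric label-flip probability for the clinical
#'   instruments (default 0.1).
#' @param mean_nft_area_px,sdlog_nft_area lognormal NFT pixel-area model.
#' @param pixel_size_um microns per pixel.
#' @param seed master seed (default 1).
#' @return object of class `cohort_sim_params`; derived fields
#'   `count_age_slope` (log-intensity slope) and `count_sd` (theoretical SD
#'   of the whole-slide count, used to standardize the burden in the
#'   outcome model).
#' @export
cohort_sim_params <- function(n_subjects = 706L,
                              age_mean = 85, age_sd = 10,
                              age_bounds = c(55, 110),
                              mean_nft_count = 120,
                              count_age_corr = 0.3,
                              clustered_weight = 0.5,
                              thomas_mu = 10, thomas_sigma_px = 400,
                              beta_burden = log(1.40),
                              beta_age = NULL, age_gap_years = 4.5,
                              beta0 = log(344 / 362),
                              label_noise = 0.1,
                              mean_nft_area_px = 600, sdlog_nft_area = 0.5,
                              pixel_size_um = 0.5066, seed = 1L) {
  stopifnot(n_subjects >= 1L, age_sd > 0, age_bounds[1L] < age_bounds[2L],
            mean_nft_count > 0, count_age_corr >= 0, count_age_corr < 1,
            clustered_weight >= 0, clustered_weight <= 1,
            thomas_mu > 0, thomas_sigma_px > 0,
            label_noise >= 0, label_noise <= 1, pixel_size_um > 0)
  m <- mean_nft_count
  # over-dispersion of the count, Poisson for CSR, ~ (1 + mu) for Thomas:
  # Var(N | lambda) ~= lambda * (1 + w * mu)
  od <- 1 + clustered_weight * thomas_mu
  # count-age moment match: N | z ~ mixed Poisson with lambda =
  # m * exp(b z - b^2/2), z ~ N(0,1); Cov(N, z) = m b and
  # Var(N) = m * od + m^2 (exp(b^2) - 1)
  b <- if (count_age_corr == 0) 0 else {
    f <- function(b) m * b / sqrt(m * od + m^2 * (exp(b^2) - 1)) -
      count_age_corr
    # the correlation rises then falls in b; solve on the rising branch
    if (f(1) <= 0)
      stop("count_age_corr unattainable at these count/cluster parameters")
    stats::uniroot(f, c(1e-8, 1), tol = 1e-10)$root
  }
  count_sd <- sqrt(m * od + m^2 * (exp(b^2) - 1))
  if (is.null(beta_age)) {
    # Solve beta_age so the marginal CI-NCI age gap matches age_gap_years.
    # Under a bivariate-normal approximation of (z_age, z_count) — with the
    # age z carrying its truncated-normal variance — the group gap of any
    # covariate is its covariance with the linear predictor times the
    # logistic selection gap of that predictor, which is computed by
    # numerical integration rather than a linear (discriminant) shortcut.
    a1 <- (age_bounds[1L] - age_mean) / age_sd
    a2 <- (age_bounds[2L] - age_mean) / age_sd
    zc <- stats::pnorm(a2) - stats::pnorm(a1)
    mz <- (stats::dnorm(a1) - stats::dnorm(a2)) / zc
    vz <- 1 + (a1 * stats::dnorm(a1) - a2 * stats::dnorm(a2)) / zc - mz^2
    rho <- count_age_corr
    gap_u <- function(sigma) {
      if (sigma < 1e-8) return(0)
      pbar <- stats::integrate(function(u)
        stats::plogis(u) * stats::dnorm(u, 0, sigma), -Inf, Inf)$value
      m1 <- stats::integrate(function(u)
        u * stats::plogis(u) * stats::dnorm(u, 0, sigma), -Inf, Inf)$value
      m1 / (pbar * (1 - pbar))
    }
    g <- function(ba) {
      su2 <- ba^2 * vz + beta_burden^2 + 2 * ba * beta_burden * rho * sqrt(vz)
      cov_au <- ba * vz + beta_burden * rho * sqrt(vz)
      age_sd * cov_au / su2 * gap_u(sqrt(su2)) - age_gap_years
    }
    beta_age <- if (age_gap_years <= 0 || g(0) >= 0) 0
                else stats::uniroot(g, c(0, 3), tol = 1e-10)$root
  }
  structure(list(
    n_subjects = as.integer(n_subjects), age_mean = age_mean,
    age_sd = age_sd, age_bounds = age_bounds,
    mean_nft_count = mean_nft_count, count_age_corr = count_age_corr,
    count_age_slope = b, count_sd = count_sd,
    clustered_weight = clustered_weight, thomas_mu = thomas_mu,
    thomas_sigma_px = thomas_sigma_px,
    beta_burden = beta_burden, beta_age = beta_age,
    age_gap_years = age_gap_years, beta0 = beta0,
    label_noise = label_noise,
    mean_nft_area_px = mean_nft_area_px, sdlog_nft_area = sdlog_nft_area,
    pixel_size_um = pixel_size_um, seed = as.integer(seed)),
    class = "cohort_sim_params")
}

#' @export
print.cohort_sim_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<cohort_sim_params> n = %d, age ~ truncN(%g, %g) in [%g, %g]\n",
    "  mean NFT count %g (age slope %.4f -> target r %.2f), clustered %g\n",
    "  outcome: beta0 %.3f, beta_burden %.3f (OR %.2f/SD), beta_age %.3f\n",
    "  label noise %g, seed %d\n"),
    x$n_subjects, x$age_mean, x$age_sd, x$age_bounds[1L], x$age_bounds[2L],
    x$mean_nft_count, x$count_age_slope, x$count_age_corr,
    x$clustered_weight, x$beta0, x$beta_burden, exp(x$beta_burden),
    x$beta_age, x$label_noise, x$seed))
  invisible(x)
}

# truncated-normal draw by rejection (bounds are a few SDs wide, so the
# acceptance rate is high)
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    v <- stats::rnorm(2L * (n - length(out)) + 8L, mean, sd)
    out <- c(out, v[v >= lo & v <= hi])
  }
  out[seq_len(n)]
}

#' Simulate one subject: slide and clinical record
#'
#' Draws age; sets the expected NFT count from age through the log-linear
#' intensity model; draws a Thomas or CSR point pattern at that expected
#' count over the region template; draws latent cognitive status from the
#' logistic outcome model (standardizing the realized count with the
#' parameter object's theoretical moments); then emits clinical instruments
#' (CDR and/or MMSE with dates, chart-review flag) encoding the, possibly
#' label-flipped, status together with Braak stage, CERAD, sex and ARTAG
#' covariates.
#'
#' @param params a [cohort_sim_params()].
#' @param regions region polygons (default [region_template()]).
#' @param seed integer seed for this subject.
#' @param subject_id identifier.
#' @return list with elements `slide` (a [slide_record()]) and `subject`
#'   (one-row data.frame of the cohort-table fields plus the latent
#'   `true_status` and `clustered` generator fields).
#' @export
simulate_subject <- function(params, regions = region_template(),
                             seed = 1L, subject_id = "s1") {
  stopifnot(inherits(params, "cohort_sim_params"))
  set.seed(seed)
  p <- params
  age <- rtruncnorm1(1L, p$age_mean, p$age_sd, p$age_bounds[1L],
                     p$age_bounds[2L])
  z_age <- (age - p$age_mean) / p$age_sd
  b <- p$count_age_slope
  lambda <- p$mean_nft_count * exp(b * z_age - b^2 / 2)
  areas_mm2 <- vapply(regions, region_area_mm2,
                      pixel_size_um = p$pixel_size_um, numeric(1L))
  a_tot <- sum(areas_mm2)
  clustered <- stats::runif(1L) < p$clustered_weight
  pts_list <- lapply(regions, function(r) {
    if (clustered)
      simulate_thomas(lambda / (a_tot * p$thomas_mu), p$thomas_mu,
                      p$thomas_sigma_px, r, p$pixel_size_um)
    else
      simulate_csr(lambda / a_tot, r, p$pixel_size_um)
  })
  pts <- do.call(rbind, pts_list)
  n <- nrow(pts)
  reg_lab <- rep(vapply(regions, function(r) r$label, character(1L)),
                 vapply(pts_list, nrow, integer(1L)))
  nfts <- nft_table(
    id = if (n) paste0(subject_id, "_", seq_len(n)) else character(0),
    x = pts[, 1L], y = pts[, 2L],
    area_px = if (n) round(stats::rlnorm(
      n, log(p$mean_nft_area_px) - p$sdlog_nft_area^2 / 2,
      p$sdlog_nft_area)) + 1 else numeric(0),
    region = reg_lab)
  slide <- slide_record(subject_id, nfts, regions,
                        pixel_size_um = p$pixel_size_um, check = FALSE)
  z_burden <- (n - p$mean_nft_count) / p$count_sd
  eta <- p$beta0 + p$beta_burden * z_burden + p$beta_age * z_age
  true_status <- if (stats::runif(1L) < stats::plogis(eta)) "CI" else "NCI"
  obs <- if (stats::runif(1L) < p$label_noise)
    setdiff(c("CI", "NCI"), true_status) else true_status
  # clinical instruments encoding the observed label
  has_cdr <- stats::runif(1L) < 0.75
  has_mmse <- stats::runif(1L) < 0.6
  has_flag <- if (!has_cdr && !has_mmse) TRUE else stats::runif(1L) < 0.2
  cdr <- NA_real_; mmse <- NA_integer_
  cdr_date <- as.Date(NA); mmse_date <- as.Date(NA)
  base_date <- as.Date("2010-01-01")
  if (has_cdr) {
    cdr <- if (obs == "CI")
      sample(c(0.5, 1, 2, 3), 1L, prob = c(0.5, 0.3, 0.15, 0.05)) else 0
    cdr_date <- base_date + sample.int(3000L, 1L)
  }
  if (has_mmse) {
    mmse <- if (obs == "CI") sample(5:25, 1L) else sample(26:30, 1L)
    mmse_date <- base_date + sample.int(3000L, 1L)
  }
  flag <- if (has_flag) obs == "CI" else NA
  # neuropathology covariates: Braak tracks burden; ARTAG tracks age
  braak_latent <- 0.6 * z_burden + stats::rnorm(1L)
  braak_cuts <- stats::qnorm(c(.0908, .2482, .5163, .7801, .9589),
                             sd = sqrt(1 + 0.36))
  braak <- findInterval(braak_latent, braak_cuts)
  artag <- stats::runif(1L) <
    stats::plogis(stats::qlogis(0.269) + 0.4 * z_age)
  # standard positive-pixel counts: NFT pixels plus thread/background
  # immunoreactivity, both with multiplicative noise
  pos <- vapply(regions, function(r) {
    nft_px <- sum(nfts$area_px[nfts$region == r$label])
    bg <- r$area_px * 3e-4 * exp(stats::rnorm(1L, 0, 0.4))
    min(round(nft_px * 2 * exp(stats::rnorm(1L, 0, 0.25)) + bg), r$area_px)
  }, numeric(1L))
  subject <- data.frame(
    subject_id = subject_id, age_at_death = age,
    sex = sample(c("M", "F"), 1L, prob = c(329, 377)),
    cdr = cdr, cdr_date = cdr_date, mmse = mmse, mmse_date = mmse_date,
    clinical_impairment = flag, braak_stage = braak,
    cerad = sample(c("C0", "C1"), 1L, prob = c(0.84, 0.16)),
    artag = artag, true_status = true_status, clustered = clustered,
    n_nfts = n,
    positive_px_hippocampus = pos[1L], positive_px_entorhinal = pos[2L],
    positive_px_combined = sum(pos), stringsAsFactors = FALSE)
  list(slide = slide, subject = subject)
}

#' Simulate a full synthetic cohort
#'
#' Draws `params$n_subjects` independent subjects, each from a seed derived
#' deterministically from the master seed, labels cognitive status from the
#' generated clinical instruments, and (optionally) writes the cohort in
#' the package's standard on-disk formats: per-subject NFT tables, the
#' region GeoJSON, the cohort covariate table and a manifest recording
#' parameters and seed.
#'
#' @param params a [cohort_sim_params()].
#' @param dir optional output directory; created if missing. `NULL` keeps
#'   the cohort in memory only.
#' @param regions region polygons (default [region_template()]).
#' @return object of class `nft_cohort`: list with `params`, `subjects`
#'   (cohort table incl. derived `cognitive_status`), `slides` (list of
#'   [slide_record()]), `regions`, and `dir` if written.
#' @export
simulate_cohort <- function(params = cohort_sim_params(), dir = NULL,
                            regions = region_template()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  n <- params$n_subjects
  ids <- sprintf("s%04d", seq_len(n))
  subs <- vector("list", n)
  slides <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- as.integer((as.numeric(params$seed) * 48271 +
                            i * 1000003) %% 2147483647)
    r <- simulate_subject(params, regions, seed = seed_i,
                          subject_id = ids[i])
    subs[[i]] <- r$subject
    slides[[i]] <- r$slide
  }
  subjects <- do.call(rbind, subs)
  subjects <- label_cohort(subjects)
  cohort <- structure(list(params = params, subjects = subjects,
                           slides = slides, regions = regions, dir = dir),
                      class = "nft_cohort")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    nft_dir <- file.path(dir, "nft_tables")
    if (!dir.exists(nft_dir)) dir.create(nft_dir)
    for (s in slides)
      write_nft_table(s$nfts, file.path(nft_dir,
                                        paste0(s$subject_id, ".csv")))
    write_region_geojson(regions, file.path(dir, "regions.geojson"))
    utils::write.csv(subjects, file.path(dir, "cohort.csv"),
                     row.names = FALSE, na = "")
    jsonlite::write_json(
      list(params = unclass(params), generator = "nftburden"),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  cohort
}

#' @export
print.nft_cohort <- function(x, ...) {
  s <- x$subjects
  cat(sprintf("<nft_cohort> %d subjects (seed %d)\n",
              nrow(s), x$params$seed))
  cat(sprintf("  age %.1f +/- %.1f; status: %d CI / %d NCI; median NFTs %g\n",
              mean(s$age_at_death), stats::sd(s$age_at_death),
              sum(s$cognitive_status == "CI", na.rm = TRUE),
              sum(s$cognitive_status == "NCI", na.rm = TRUE),
              stats::median(s$n_nfts)))
  invisible(x)
}
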