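test_that("point processes respect their first moments and the window", {
  reg <- region_template()[[2L]]           # 50 mm^2 rectangle
  area <- region_area_mm2(reg)
  set.seed(81)
  counts <- replicate(300, nrow(simulate_csr(2, reg)))
  expect_lt(abs(mean(counts) - 2 * area), 3 * sqrt(2 * area / 300))
  pts <- simulate_csr(2, reg, seed = 5)
  expect_true(all(point_in_polygon(pts[, 1L], pts[, 2L], reg$vertices)))
  # tiny intensity with a fixed seed: usually empty
  expect_equal(nrow(simulate_csr(1e-6, reg, seed = 1)), 0L)

  kappa <- 0.2; mu <- 8
  counts_t <- replicate(300, nrow(simulate_thomas(kappa, mu, 300, reg)))
  expected <- kappa * mu * area
  # Neyman-Scott count variance ~ kappa A mu (1 + mu)
  se <- sqrt(kappa * area * mu * (1 + mu) / 300)
  expect_lt(abs(mean(counts_t) - expected), 3 * se)
  ptst <- simulate_thomas(kappa, mu, 300, reg, seed = 6)
  expect_true(all(point_in_polygon(ptst[, 1L], ptst[, 2L], reg$vertices)))
})

test_that("vanishing dispersion collapses offspring onto parents", {
  reg <- region_template()[[2L]]
  pts <- simulate_thomas(0.3, 10, 1e-8, reg, seed = 7)
  d <- dist(pts)
  # distances are either ~0 (same parent) or macroscopic (different parents)
  expect_true(all(d < 1e-5 | d > 1))
})

test_that("cohorts are reproducible and internally consistent", {
  p <- cohort_sim_params(n_subjects = 12, seed = 9)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$subjects, b$subjects)
  for (i in seq_len(12))
    expect_identical(a$slides[[i]]$nfts, b$slides[[i]]$nfts)
  expect_s3_class(a$subjects$cdr_date, "Date")
  # generated slides satisfy the data-model invariants without special cases
  for (sl in a$slides) {
    expect_true(all(sl$nfts$area_px > 0))
    expect_true(all(is.finite(sl$nfts$x)), all(is.finite(sl$nfts$y)))
    relabeled <- assign_regions(sl$nfts, sl$regions)
    expect_identical(relabeled$region, sl$nfts$region)
  }
})

test_that("noise-free labels reproduce the generating status exactly", {
  p <- cohort_sim_params(n_subjects = 60, seed = 10, label_noise = 0)
  co <- simulate_cohort(p)
  expect_identical(co$subjects$cognitive_status, co$subjects$true_status)
  # with full label noise every label flips
  pf <- cohort_sim_params(n_subjects = 30, seed = 10, label_noise = 1)
  cf <- simulate_cohort(pf)
  expect_true(all(cf$subjects$cognitive_status != cf$subjects$true_status))
})

test_that("the count-age correlation calibration holds empirically", {
  rs <- vapply(1:8, function(k) {
    s <- simulate_cohort(cohort_sim_params(n_subjects = 700,
                                           seed = 100 + k))$subjects
    cor(s$n_nfts, s$age_at_death)
  }, numeric(1L))
  expect_lt(abs(mean(rs) - 0.3), 0.08)
})

test_that("an on-disk cohort round-trips through the readers", {
  d <- tempfile()
  co <- simulate_cohort(cohort_sim_params(n_subjects = 10, seed = 11),
                        dir = d)
  expect_true(file.exists(file.path(d, "cohort.csv")))
  expect_true(file.exists(file.path(d, "regions.geojson")))
  expect_true(file.exists(file.path(d, "manifest.json")))
  subs <- read_cohort_table(file.path(d, "cohort.csv"))
  expect_equal(nrow(subs), 10L)
  regs <- read_region_geojson(file.path(d, "regions.geojson"))
  expect_length(regs, 2L)
  for (sid in subs$subject_id) {
    nfts <- read_nft_table(file.path(d, "nft_tables", paste0(sid, ".csv")))
    orig <- co$slides[[match(sid, subs$subject_id)]]$nfts
    expect_identical(nfts$x, orig$x)
    expect_identical(nfts$area_px, orig$area_px)
    expect_identical(nfts$region, orig$region)
  }
  mani <- jsonlite::fromJSON(file.path(d, "manifest.json"))
  expect_equal(mani$params$seed, 11L)
  expect_equal(mani$params$n_subjects, 10L)
})

test_that("parameter guards reject impossible configurations", {
  expect_error(cohort_sim_params(n_subjects = 0), "n_subjects")
  expect_error(cohort_sim_params(clustered_weight = 1.5), "clustered_weight")
  expect_error(cohort_sim_params(count_age_corr = 0.9,
                                 mean_nft_count = 5), "unattainable")
  expect_error(simulate_thomas(-1, 5, 100, region_template()[[1L]]),
               "positive")
  expect_error(simulate_csr(0, region_template()[[1L]]), "positive")
})
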