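make_square_region <- function(side_px, label = "hippocampus") {
  region_annotation(label, cbind(c(0, side_px, side_px, 0),
                                 c(0, 0, side_px, side_px)))
}

test_that("count and pixel densities match their defining ratios", {
  reg <- make_square_region(5000)          # 25 mm^2 at 1 um/px
  n <- 50L
  set.seed(41)
  nfts <- nft_table(seq_len(n), runif(n, 1, 4999), runif(n, 1, 4999),
                    rep(200, n), region = rep("hippocampus", n))
  expect_equal(nft_count_density(nfts, reg, 1), 2.0)
  empty <- nft_table(character(0), numeric(0), numeric(0), numeric(0))
  expect_equal(nft_count_density(empty, reg, 1), 0)
  expect_equal(nft_pixel_density(empty, reg), 0)
  expect_equal(nft_pixel_density(nfts, reg), 50 * 200 / 25e6)

  # saturation bound: one NFT tiling the region exactly
  one <- nft_table("a", 2500, 2500, 25e6, region = "hippocampus")
  expect_equal(nft_pixel_density(one, reg), 1.0)

  # 1e4 px^2 of NFT in a 1e6 px^2 region
  reg2 <- make_square_region(1000)
  nf2 <- nft_table(c("a", "b"), c(10, 20), c(10, 20), c(6000, 4000),
                   region = rep("hippocampus", 2))
  expect_equal(nft_pixel_density(nf2, reg2), 0.01)
})

test_that("positive-pixel burden is a guarded fraction with a method tag", {
  expect_equal(as.numeric(positive_pixel_burden(0, 1e6)), 0)
  expect_equal(as.numeric(positive_pixel_burden(1e6, 1e6)), 1)
  expect_equal(as.numeric(positive_pixel_burden(250, 1000)), 0.25)
  expect_equal(attr(positive_pixel_burden(1, 2, "threshold"), "method"),
               "threshold")
  expect_error(positive_pixel_burden(2, 1), "\\[0, total_px\\]")
  expect_error(positive_pixel_burden(1, 0), "positive")
})

test_that("pixel-pitch scaling behaves as dimensional analysis requires", {
  reg <- make_square_region(3000)
  set.seed(42)
  nfts <- nft_table(1:30, runif(30, 1, 2999), runif(30, 1, 2999),
                    rexp(30, 1 / 500) + 1, region = rep("hippocampus", 30))
  a1 <- region_area_mm2(reg, 0.5); a2 <- region_area_mm2(reg, 1.0)
  expect_equal(a2 / a1, 4)                         # doubling px size quarters.. x4 area
  d1 <- nft_count_density(nfts, reg, 0.5)
  d2 <- nft_count_density(nfts, reg, 1.0)
  expect_equal(d1 / d2, 4)                          # density scales inversely
  expect_equal(nft_pixel_density(nfts, reg),
               nft_pixel_density(nfts, reg))        # pitch-free
})

test_that("combined region pools objects and areas additively", {
  regs <- region_template()
  set.seed(43)
  co <- simulate_cohort(cohort_sim_params(n_subjects = 3, seed = 43))
  for (sl in co$slides) {
    m <- burden_metrics(sl)
    h <- m[m$region == "hippocampus", ]; e <- m[m$region == "entorhinal", ]
    cb <- m[m$region == "combined", ]
    expect_equal(cb$nft_count, h$nft_count + e$nft_count)
    expect_equal(cb$region_area_mm2, h$region_area_mm2 + e$region_area_mm2)
    expect_equal(cb$nft_count_density,
                 cb$nft_count / cb$region_area_mm2)
    # combined pixel density is the area-weighted pooling, not the average
    hp <- vapply(sl$regions, function(r) r$area_px, numeric(1L))
    expect_equal(cb$nft_pixel_density,
                 (h$nft_pixel_density * hp[1L] + e$nft_pixel_density * hp[2L])
                 / sum(hp))
    expect_true(all(m$nft_pixel_density >= 0 & m$nft_pixel_density <= 1))
    expect_true(all(m$nft_count_density >= 0))
  }
})

test_that("estimated density of a homogeneous pattern matches its intensity", {
  reg <- make_square_region(2000)   # 4 mm^2 at 1 um/px
  lambda <- 10
  set.seed(44)
  dens <- replicate(100, {
    pts <- simulate_csr(lambda, reg, pixel_size_um = 1)
    nfts <- nft_table(seq_len(nrow(pts)), pts[, 1L], pts[, 2L],
                      rep(1, nrow(pts)),
                      region = rep("hippocampus", nrow(pts)))
    nft_count_density(nfts, reg, 1)
  })
  # mean count 40 per replicate; SE of the mean density over 100 reps
  se <- sqrt(lambda / 4) / sqrt(100)
  expect_lt(abs(mean(dens) - lambda), 3 * se)
})

test_that("metrics tables write with deterministic columns and empties", {
  co <- simulate_cohort(cohort_sim_params(n_subjects = 2, seed = 7))
  m <- do.call(rbind, lapply(co$slides, burden_metrics))
  f <- tempfile(fileext = ".csv")
  write_metrics_table(m, f)
  hdr <- readLines(f, n = 1L)
  expect_equal(hdr, paste("subject_id,region,nft_count,region_area_mm2",
                          "nft_count_density,nft_pixel_density",
                          "positive_pixel_burden", sep = ","))
  back <- read.csv(f)
  expect_equal(nrow(back), 6L)
  expect_true(all(is.na(back$positive_pixel_burden)))
})
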