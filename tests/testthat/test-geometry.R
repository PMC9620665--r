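test_that("shoelace areas and unit conversions match closed forms", {
  expect_equal(polygon_area(cbind(c(0, 2, 2, 0), c(0, 0, 3, 3))), 6)
  expect_equal(polygon_area(cbind(c(0, 2000, 0), c(0, 0, 2000))), 2e6)
  # vertex order (orientation) does not affect the magnitude
  expect_equal(polygon_area(cbind(c(0, 0, 2, 2), c(0, 3, 3, 0))), 6)

  expect_equal(px_to_micron(0), 0)
  expect_equal(px_to_micron(800), 405.28)
  expect_equal(px_to_micron(1200), 607.92)
  expect_equal(px_to_micron(5000), 2533)
  expect_error(px_to_micron(-1), "non-negative")

  sq1000 <- region_annotation("hippocampus",
                              cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000)))
  expect_equal(region_area_mm2(sq1000, 1), 1)
  sq1974 <- region_annotation("hippocampus",
                              cbind(c(0, 1974, 1974, 0), c(0, 0, 1974, 1974)))
  expect_equal(region_area_mm2(sq1974, 0.5066), (1974 * 0.5066 / 1000)^2)
  tri <- region_annotation("entorhinal",
                           cbind(c(0, 2000, 0), c(0, 0, 2000)))
  expect_equal(region_area_mm2(tri, 1), 2)
})

test_that("simplicity check separates simple from self-intersecting rings", {
  expect_true(polygon_is_simple(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))))
  expect_false(polygon_is_simple(cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))))
  expect_true(polygon_is_simple(region_template()[[1L]]$vertices))
  expect_error(region_annotation("hippocampus",
                                 cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))),
               "self-intersecting")
})

test_that("containment agrees with ray-casting and mgcv oracles on random points", {
  set.seed(11)
  polys <- list(
    cbind(c(0, 10, 12, 6, 0), c(0, -2, 8, 12, 7)),   # convex-ish pentagon
    region_template()[[1L]]$vertices)                 # concave half-annulus
  for (v in polys) {
    n <- 1000L
    x <- runif(n, min(v[, 1L]) - 2, max(v[, 1L]) + 2)
    y <- runif(n, min(v[, 2L]) - 2, max(v[, 2L]) + 2)
    got <- point_in_polygon(x, y, v)
    expect_identical(got, ray_cast_oracle(x, y, v))
    expect_identical(got,
                     as.logical(mgcv::in.out(rbind(v, v[1L, ]), cbind(x, y))))
  }
})

test_that("boundary points count as inside", {
  v <- cbind(c(0, 4, 4, 0), c(0, 0, 4, 4))
  expect_true(point_in_polygon(2, 0, v))   # edge midpoint
  expect_true(point_in_polygon(0, 0, v))   # vertex
  expect_true(point_in_polygon(4, 2, v))   # right edge
  expect_false(point_in_polygon(4 + 1e-6, 2, v))
})

test_that("region assignment labels by containment and preserves order", {
  regs <- region_template()
  # hippocampus interior, entorhinal interior, outside both
  nfts <- nft_table(c("a", "b", "c"),
                    x = c(16000 + 10000, 16000, 0),
                    y = c(13000 - 1, 17000, 0),
                    area_px = c(5, 5, 5))
  got <- assign_regions(nfts, regs)
  expect_equal(got$region, c("hippocampus", "entorhinal", "unassigned"))
  expect_equal(got$id, nfts$id)

  # 1000 random points against the ray-casting oracle, both polygons
  set.seed(21)
  x <- runif(1000, 0, 32000); y <- runif(1000, 0, 22000)
  rnd <- assign_regions(nft_table(seq_len(1000), x, y, rep(1, 1000)), regs)
  for (r in regs) {
    expected <- ray_cast_oracle(x, y, r$vertices)
    expect_identical(rnd$region == r$label, expected)
  }
})
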