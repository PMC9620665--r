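test_that("edge rule is strict and matches the pairwise-distance oracle", {
  # 3-4-5 right triangle: distance exactly 5 is a non-edge
  g <- build_geometric_graph(rbind(c(0, 0), c(3, 4)), r_px = 5)
  expect_equal(sum(g$adjacency), 0)
  g2 <- build_geometric_graph(rbind(c(0, 0), c(3, 4)), r_px = 5 + 1e-9)
  expect_equal(sum(g2$adjacency) / 2, 1)
  # vanishing radius: no edges
  set.seed(51)
  pts <- matrix(runif(40), ncol = 2)
  expect_equal(sum(build_geometric_graph(pts, 1e-12)$adjacency), 0)

  # 200 seeded uniform points: edge set identical to the O(n^2) oracle
  pts <- matrix(runif(400, 0, 1000), ncol = 2)
  r <- 120
  g <- build_geometric_graph(pts, r)
  d <- as.matrix(dist(pts))
  oracle <- (d * d) < r * r; diag(oracle) <- FALSE
  expect_identical(unname(g$adjacency), unname(oracle))
  expect_true(isSymmetric(g$adjacency))
  expect_error(build_geometric_graph(rbind(c(NA, 1)), 5), "finite")
})

test_that("local clustering matches closed forms and per-node enumeration", {
  tri <- build_geometric_graph(rbind(c(0, 0), c(1, 0), c(0.5, 0.9)), 1.5)
  expect_equal(local_clustering(tri), c(1, 1, 1))
  path <- build_geometric_graph(rbind(c(0, 0), c(1, 0), c(2, 0)), 1.5)
  expect_equal(local_clustering(path, 2L), 0)     # open triad
  expect_equal(local_clustering(path, 1L), 0)     # degree-1 convention
  expect_error(local_clustering(path, 9L), "invalid node")

  # random geometric graph vs neighbor-pair enumeration through igraph
  set.seed(52)
  pts <- matrix(runif(160, 0, 100), ncol = 2)
  g <- build_geometric_graph(pts, 18)
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  expected <- igraph::transitivity(ig, type = "local", isolates = "zero")
  expected[is.na(expected)] <- 0
  expect_equal(local_clustering(g), expected, tolerance = 1e-12)
})

test_that("mean clustering coefficient hits its degenerate and limit cases", {
  eq_tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(mean_clustering_coefficient(eq_tri, 1.1), 1.0)
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(mean_clustering_coefficient(square, 1.2), 0.0)  # 4-cycle
  expect_equal(mean_clustering_coefficient(square, 0.5), 0.0)  # all isolated
  expect_equal(mean_clustering_coefficient(square, 2.0), 1.0)  # complete
  expect_true(is.na(mean_clustering_coefficient(rbind(c(0, 0), c(1, 1)),
                                                1)))
  expect_true(is.na(suppressWarnings(
    clustering_sweep(rbind(c(0, 0), c(1, 1)))$mean_cc[1])))
})

test_that("sweep equals standalone calls, keeps the default 50-radius grid", {
  set.seed(53)
  pts <- matrix(runif(300, 0, 8000), ncol = 2)
  sw <- clustering_sweep(pts, subject_id = "t")
  expect_equal(nrow(sw), 50L)
  expect_equal(sw$r_px, seq(100, 5000, 100))
  expect_equal(sw$r_um, seq(100, 5000, 100) * 0.5066)
  expect_equal(sw$n_nfts, rep(150L, 50L), ignore_attr = TRUE)
  for (r in c(100, 800, 2500, 5000))
    expect_identical(sw$mean_cc[sw$r_px == r],
                     mean_clustering_coefficient(pts, r))
  # all points mutually within r_start: coefficient 1 everywhere
  tight <- matrix(runif(20, 0, 30), ncol = 2)
  swt <- clustering_sweep(tight)
  expect_true(all(swt$mean_cc == 1))
  expect_error(clustering_sweep(pts, r_start_px = 500, r_stop_px = 100),
               "invalid radius grid")
})

test_that("sweep values are invariant to rigid motions", {
  set.seed(54)
  for (rep in 1:3) {
    pts <- matrix(runif(120, 0, 3000), ncol = 2)
    theta <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    moved <- sweep(pts %*% R, 2, c(1234.5, -987.6), "+")
    a <- clustering_sweep(pts)$mean_cc
    b <- clustering_sweep(moved)$mean_cc
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("the degree-<2 convention switch matches its definition", {
  set.seed(55)
  pts <- matrix(runif(80, 0, 1000), ncol = 2)
  r <- 100
  expect_equal(mean_clustering_coefficient(pts, r, low_degree = "zero"),
               brute_mean_cc(pts, r, exclude_low_degree = FALSE),
               tolerance = 1e-12)
  expect_equal(mean_clustering_coefficient(pts, r, low_degree = "exclude"),
               brute_mean_cc(pts, r, exclude_low_degree = TRUE),
               tolerance = 1e-12)
})
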