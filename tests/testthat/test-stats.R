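test_that("chi-square tests match formula oracles and degenerate cases", {
  prop <- matrix(c(10, 20, 30, 60), 2, byrow = TRUE)
  r0 <- chi_square_2x2(prop, correction = "none")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$df, 1L)

  # identical column distributions: statistic 0 in r x c
  same <- matrix(c(5, 10, 15, 10, 20, 30), ncol = 2)
  expect_equal(chi_square_rxc(same)$statistic, 0)

  # random 3x3 against direct sum((O-E)^2/E)
  set.seed(61)
  tab <- matrix(rpois(9, 20) + 1, 3, 3)
  got <- chi_square_rxc(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(got$df, 4L)
  expect_equal(got$p_value, pchisq(got$statistic, 4, lower.tail = FALSE))

  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "zero margin")
  expect_error(chi_square_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
  expect_error(chi_square_2x2(matrix(1:6, 3)), "2x2")
})

test_that("per-SD logistic OR is affine-invariant and flags degeneracies", {
  set.seed(62)
  n <- 400L
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.4 * x))
  f1 <- fit_logistic_or(y, x)
  f2 <- fit_logistic_or(y, 1000 * x - 77)       # affine rescaling
  expect_equal(f1$odds_ratio, f2$odds_ratio, tolerance = 1e-9)
  expect_equal(f1$p_raw, f2$p_raw, tolerance = 1e-9)
  # agrees with a direct glm on the z-scored predictor
  z <- (x - mean(x)) / sd(x)
  ref <- glm(y ~ z, family = binomial())
  expect_equal(unname(log(f1$odds_ratio)), unname(coef(ref)["z"]),
               tolerance = 1e-10)
  expect_true(f1$ci95_low <= f1$odds_ratio && f1$odds_ratio <= f1$ci95_high)

  expect_error(fit_logistic_or(y, rep(1, n)), "constant predictor")
  expect_error(fit_logistic_or(y, as.numeric(y)), "separation")
  expect_error(fit_logistic_or(c(rep(0, 30), rep(1, 5)), rnorm(35)),
               "fewer than")
})

test_that("logistic CI covers the null for an independent predictor", {
  set.seed(63)
  cover <- replicate(60, {
    y <- rbinom(300, 1, 0.5)
    x <- rnorm(300)
    f <- fit_logistic_or(y, x)
    f$ci95_low <= 1 && 1 <= f$ci95_high
  })
  expect_gte(mean(cover), 0.88)   # ~95% nominal, Monte-Carlo slack
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  set.seed(64)
  for (rep in 1:5) {
    p <- runif(37)
    got <- bh_fdr(p)
    expect_equal(got, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(got >= p))                    # never anti-conservative
    expect_true(all(diff(got[order(p)]) >= -1e-15))  # monotone in rank order
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Mantel-Haenszel pooling matches the closed form and collapses", {
  s <- matrix(c(12, 5, 7, 19), 2, byrow = TRUE)
  single <- cmh_pooled_or(list(s))
  expect_equal(single$pooled_or, (12 * 19) / (5 * 7), tolerance = 1e-12)

  twin <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  expect_equal(cmh_pooled_or(list(twin, twin))$pooled_or, 0.25,
               tolerance = 1e-12)
  # K copies of one stratum give the single-stratum OR for any K
  for (k in c(3L, 7L))
    expect_equal(cmh_pooled_or(rep(list(s), k))$pooled_or,
                 single$pooled_or, tolerance = 1e-12)
  set.seed(65)
  strata <- lapply(1:4, function(i) matrix(rpois(4, 15) + 1, 2))
  got <- cmh_pooled_or(strata)
  expect_equal(got$pooled_or, mh_or_oracle(strata), tolerance = 1e-12)
  # statistic and p agree with the reference implementation
  arr <- array(unlist(strata), dim = c(2, 2, 4))
  ref <- mantelhaen.test(arr, correct = FALSE, exact = FALSE)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  refc <- mantelhaen.test(arr, correct = TRUE, exact = FALSE)
  gotc <- cmh_pooled_or(strata, correct = TRUE)
  expect_equal(gotc$statistic, unname(refc$statistic), tolerance = 1e-10)
  expect_error(cmh_pooled_or(list()), "at least one")
  expect_error(cmh_pooled_or(list(matrix(c(5, 0, 7, 0), 2, byrow = TRUE))),
               "degenerate")
})

test_that("stratified pooling removes confounding by a common cause", {
  # stratum variable drives both exposure and outcome; conditional OR is 1
  set.seed(66)
  recovered <- replicate(20, {
    z <- rbinom(800, 1, 0.5)
    e <- rbinom(800, 1, 0.2 + 0.5 * z)
    y <- rbinom(800, 1, 0.2 + 0.5 * z)
    tabs <- lapply(split(seq_along(z), z), function(i)
      table(factor(e[i], c(1, 0)), factor(y[i], c(1, 0))))
    crude <- table(factor(e, c(1, 0)), factor(y, c(1, 0)))
    crude_or <- (crude[1, 1] * crude[2, 2]) / (crude[1, 2] * crude[2, 1])
    c(pooled = cmh_pooled_or(tabs)$pooled_or, crude = crude_or)
  })
  expect_lt(abs(mean(log(recovered["pooled", ]))),
            abs(mean(log(recovered["crude", ]))))
  expect_lt(abs(mean(log(recovered["pooled", ]))), 0.15)
})

test_that("Welch t-test matches the textbook formula and conventions", {
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2)
  got <- group_t_test(a, b)
  ref <- welch_oracle(a, b)
  expect_equal(got$t, ref$t, tolerance = 1e-10)
  expect_equal(got$df, ref$df, tolerance = 1e-10)
  expect_equal(got$p_value, ref$p, tolerance = 1e-10)

  expect_equal(group_t_test(c(5, 5, 5), c(5, 5))$p_value, 1)
  expect_error(group_t_test(c(5, 5, 5), c(6, 6)), "zero variance")
  expect_error(group_t_test(1, c(2, 3)), "at least 2")

  set.seed(67)
  x <- rnorm(100); y <- rnorm(100, mean = 1)
  expect_lt(group_t_test(x, y)$p_value, 1e-3)
  # pooled-variance switch reproduces the Student test
  st <- t.test(x, y, var.equal = TRUE)
  got2 <- group_t_test(x, y, var_equal = TRUE)
  expect_equal(got2$t, unname(st$statistic))
  expect_equal(got2$df, unname(st$parameter))
})

test_that("correlations separate rank and linear association", {
  x <- seq(1, 5, length.out = 30)
  y <- exp(x)                      # monotone but nonlinear
  expect_equal(spearman_corr(x, y)$rho, 1)
  expect_lt(pearson_corr(x, y)$r, 1)
  expect_equal(spearman_corr(x, -x)$rho, -1)
  expect_equal(pearson_corr(x, -x)$r, -1)
  expect_warning(out <- pearson_corr(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(out$r))
  set.seed(68)
  z1 <- rnorm(700); z2 <- 0.3 * z1 + sqrt(1 - 0.09) * rnorm(700)
  expect_lt(abs(pearson_corr(z1, z2)$r - 0.3), 0.08)
})

test_that("two-way ANOVA reproduces hand-computed sums of squares", {
  set.seed(69)
  reg <- gl(3, 40, labels = c("ent", "hip", "comb"))
  st <- gl(2, 20, length = 120, labels = c("NCI", "CI"))
  y <- rnorm(120) + 0.8 * (st == "CI")
  got <- two_way_anova(y, reg, st)
  ref <- anova_oracle(y, reg, st)
  expect_equal(got$F[got$effect == "factor_a"], ref$F_a, tolerance = 1e-9)
  expect_equal(got$F[got$effect == "factor_b"], ref$F_b, tolerance = 1e-9)
  expect_equal(got$F[got$effect == "interaction"], ref$F_ab,
               tolerance = 1e-9)

  # pure status effect: region sum of squares vanishes, status dominates
  y2 <- 2 * (st == "CI") + rnorm(120, sd = 1e-6)
  got2 <- two_way_anova(y2, reg, st)
  expect_lt(got2$sum_sq[got2$effect == "factor_a"], 1e-9)
  expect_gt(got2$F[got2$effect == "factor_b"], 1e6)

  expect_error(two_way_anova(rnorm(4), factor(c("a", "a", "b", "b")),
                             factor(c("x", "x", "x", "y"))), "empty")
})

test_that("permuted labels give F statistics at their reference quantile", {
  set.seed(70)
  y <- rnorm(80)
  reg <- gl(2, 40); st <- gl(2, 20, length = 80)
  fs <- replicate(400, {
    two_way_anova(y[sample.int(80)], reg, st)$F[2L]
  })
  q95 <- quantile(fs, 0.95)
  ref <- qf(0.95, 1, 76)
  expect_lt(abs(q95 - ref) / ref, 0.35)   # Monte-Carlo slack on a tail quantile
})
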