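# Independent oracle implementations used to cross-check the package.
# Each is written as a direct transcription of the defining formula or a
# naive algorithm, deliberately sharing no code with the implementation.

# crossing-number point-in-polygon, one point at a time
ray_cast_oracle <- function(x, y, vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  vapply(seq_along(x), function(k) {
    crossings <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      x1 <- v[i, 1L]; y1 <- v[i, 2L]; x2 <- v[j, 1L]; y2 <- v[j, 2L]
      if ((y1 > y[k]) != (y2 > y[k])) {
        xi <- x1 + (y[k] - y1) * (x2 - x1) / (y2 - y1)
        if (xi > x[k]) crossings <- crossings + 1L
      }
    }
    crossings %% 2L == 1L
  }, logical(1L))
}

# queue-based flood fill component labeling; returns list of component sizes
# and centroids, sorted by centroid for canonical comparison
flood_fill_oracle <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  if (connectivity == 8L)
    nbr <- expand.grid(dr = -1:1, dc = -1:1)[-5L, ]
  else
    nbr <- data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  comps <- list()
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!mask[rr, cc] || seen[rr, cc]) next
    queue <- list(c(rr, cc)); seen[rr, cc] <- TRUE
    members <- matrix(numeric(0), 0L, 2L)
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      members <- rbind(members, p)
      for (q in seq_len(nrow(nbr))) {
        r2 <- p[1L] + nbr$dr[q]; c2 <- p[2L] + nbr$dc[q]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc &&
            mask[r2, c2] && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          queue <- c(queue, list(c(r2, c2)))
        }
      }
    }
    comps[[length(comps) + 1L]] <-
      list(size = nrow(members),
           cx = mean(members[, 2L]), cy = mean(members[, 1L]))
  }
  comps
}

# mean clustering coefficient by adjacency-matrix algebra
brute_mean_cc <- function(pts, r, exclude_low_degree = FALSE) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  A <- (d * d) < r * r
  diag(A) <- FALSE
  cc <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ]); k <- length(nb)
    if (k < 2L) return(NA_real_)
    sum(A[nb, nb]) / (k * (k - 1))
  }, numeric(1L))
  if (exclude_low_degree) {
    if (all(is.na(cc))) NA_real_ else mean(cc, na.rm = TRUE)
  } else {
    cc[is.na(cc)] <- 0
    mean(cc)
  }
}

# mean clustering coefficient via dense matrix algebra: triangles through i
# are rowSums((A %*% A) * A) / 2 -- a second independent brute-force route
# that stays fast enough for n = 300 over a 50-radius grid
brute_mean_cc_matrix <- function(pts, r_values) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  vapply(r_values, function(r) {
    A <- (d * d) < r * r
    diag(A) <- FALSE
    A <- A * 1
    k <- rowSums(A)
    paired <- rowSums((A %*% A) * A)   # 2 * triangles through each node
    cc <- ifelse(k >= 2, paired / (k * (k - 1)), 0)
    mean(cc)
  }, numeric(1L))
}

# Benjamini-Hochberg by its step-up definition: sort, scale, cumulative
# minimum from the largest, unsort
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Mantel-Haenszel pooled odds ratio straight from the formula
mh_or_oracle <- function(strata) {
  num <- sum(vapply(strata, function(s) s[1, 1] * s[2, 2] / sum(s),
                    numeric(1L)))
  den <- sum(vapply(strata, function(s) s[1, 2] * s[2, 1] / sum(s),
                    numeric(1L)))
  num / den
}

# Welch statistic from the textbook formula
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# balanced two-way ANOVA sums of squares by hand
anova_oracle <- function(y, fa, fb) {
  fa <- factor(fa); fb <- factor(fb)
  gm <- mean(y)
  n_cell <- table(fa, fb)[1L, 1L]
  a_means <- tapply(y, fa, mean); b_means <- tapply(y, fb, mean)
  cell_means <- tapply(y, interaction(fa, fb), mean)
  ss_a <- sum(table(fa) * (a_means - gm)^2)
  ss_b <- sum(table(fb) * (b_means - gm)^2)
  ss_cells <- n_cell * sum((cell_means - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((y - gm)^2)
  ss_res <- ss_tot - ss_cells
  df_a <- nlevels(fa) - 1L; df_b <- nlevels(fb) - 1L
  df_ab <- df_a * df_b
  df_res <- length(y) - nlevels(fa) * nlevels(fb)
  ms_res <- ss_res / df_res
  list(F_a = (ss_a / df_a) / ms_res,
       F_b = (ss_b / df_b) / ms_res,
       F_ab = (ss_ab / df_ab) / ms_res)
}

# small helper: temp CSV fixture
write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
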