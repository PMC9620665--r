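#' Geometric graph over NFT centroids
#'
#' Builds the radius-threshold (random geometric) graph in which every NFT
#' centroid is a node and an undirected edge joins two nodes iff their
#' Euclidean distance is strictly less than `r_px`. Distances are compared on
#' squared values, so a pair at distance exactly `r_px` is a non-edge — the
#' deterministic boundary rule used throughout the package (ties are
#' measure-zero for continuous centroids).
#'
#' @param points two-column matrix (or data.frame) of centroid coordinates in
#'   level-0 pixels; at least one point, all coordinates finite.
#' @param r_px radius threshold in pixels (> 0).
#' @return object of class `geometric_graph`: fields `n_nodes`, `adjacency`
#'   (symmetric logical matrix, no self-edges), `r_px`, `points`.
#' @export
build_geometric_graph <- function(points, r_px) {
  pts <- as_point_matrix(points)
  if (length(r_px) != 1L || !is.finite(r_px) || r_px <= 0)
    stop("r_px must be a single positive number")
  n <- nrow(pts)
  if (n < 1L) stop("at least one point is required")
  dx <- outer(pts[, 1L], pts[, 1L], "-")
  dy <- outer(pts[, 2L], pts[, 2L], "-")
  adj <- (dx * dx + dy * dy) < r_px^2
  diag(adj) <- FALSE
  structure(list(n_nodes = n, adjacency = adj, r_px = r_px, points = pts),
            class = "geometric_graph")
}

as_point_matrix <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("points must be a two-column (x, y) matrix")
  storage.mode(pts) <- "double"
  if (nrow(pts) && (anyNA(pts) || any(!is.finite(pts))))
    stop("point coordinates must be finite")
  dimnames(pts) <- NULL
  pts
}

#' @export
print.geometric_graph <- function(x, ...) {
  cat(sprintf("<geometric_graph> %d nodes, %d edges, r = %g px\n",
              x$n_nodes, sum(x$adjacency) / 2L, x$r_px))
  invisible(x)
}

#' Local clustering coefficient
#'
#' For a node of degree k >= 2, the fraction of its k(k-1)/2 neighbor pairs
#' that are themselves connected (`2 T / (k (k - 1))` with `T` the triangle
#' count through the node). Nodes of degree 0 or 1 have no neighbor pair and
#' return 0 by convention.
#'
#' @param graph a [build_geometric_graph()] result.
#' @param node node index (1-based) or vector of indices; default all nodes.
#' @return numeric vector of local coefficients in \[0, 1\].
#' @export
local_clustering <- function(graph, node = seq_len(graph$n_nodes)) {
  stopifnot(inherits(graph, "geometric_graph"))
  if (any(node < 1L) || any(node > graph$n_nodes) || anyNA(node))
    stop("invalid node index")
  A <- graph$adjacency
  vapply(as.integer(node), function(i) {
    nb <- which(A[i, ])
    k <- length(nb)
    if (k < 2L) return(0)
    sum(A[nb, nb]) / (k * (k - 1))
  }, numeric(1L))
}

#' Mean clustering coefficient of the NFT radius graph
#'
#' The slide-level spatial summary: the arithmetic mean of the local
#' clustering coefficient over all nodes of the radius-`r_px` geometric
#' graph on the NFT centroids. Clustered tangle patterns yield neighbor sets
#' that are mutually close, hence high means; dispersed patterns yield low
#' means. Fewer than 3 points leave the statistic undefined and return `NA`
#' (never 0, which is a legitimate value for dispersed patterns).
#'
#' @inheritParams build_geometric_graph
#' @param low_degree how nodes of degree < 2 enter the mean: `"zero"`
#'   (default; they contribute 0) or `"exclude"` (averaged over degree >= 2
#'   nodes only).
#' @return scalar in \[0, 1\], or `NA` if undefined.
#' @export
mean_clustering_coefficient <- function(points, r_px,
                                        low_degree = c("zero", "exclude")) {
  low_degree <- match.arg(low_degree)
  pts <- as_point_matrix(points)
  if (length(r_px) != 1L || !is.finite(r_px) || r_px <= 0)
    stop("r_px must be a single positive number")
  if (nrow(pts) < 3L) return(NA_real_)
  cc_sweep_cpp(pts, as.numeric(r_px), low_degree == "exclude")[1L]
}

#' Clustering-coefficient sweep over radius thresholds
#'
#' There is no canonical inter-NFT distance, so the mean clustering
#' coefficient is evaluated over a grid of radii — by default 100 to 5000 px
#' in 100 px steps (50.66 to 2533 um at the default pixel pitch), 50 values.
#' The slide's total NFT count rides along as `n_nfts`: it is the nuisance
#' covariate that all downstream statistics on this metric must include,
#' because the coefficient of a radius graph depends on point density as
#' well as on spatial arrangement.
#'
#' Slides with fewer than 3 NFTs yield `NA` at every radius (undefined, not
#' zero) and are excluded from clustering-based regressions downstream.
#'
#' @inheritParams mean_clustering_coefficient
#' @param r_start_px,r_stop_px,r_step_px sweep grid in pixels;
#'   `0 < r_start_px <= r_stop_px`, `r_step_px > 0`, both endpoints included
#'   when the step lands on them.
#' @param pixel_size_um microns per pixel, used only to report `r_um`.
#' @param subject_id identifier carried into the output table.
#' @return object of class `clustering_sweep`: data.frame columns
#'   `subject_id, r_px, r_um, mean_cc, n_nfts`.
#' @export
clustering_sweep <- function(points, r_start_px = 100, r_stop_px = 5000,
                             r_step_px = 100, pixel_size_um = 0.5066,
                             low_degree = c("zero", "exclude"),
                             subject_id = NA_character_) {
  low_degree <- match.arg(low_degree)
  if (r_start_px <= 0 || r_stop_px < r_start_px || r_step_px <= 0)
    stop("invalid radius grid: need 0 < r_start_px <= r_stop_px, r_step_px > 0")
  pts <- as_point_matrix(points)
  r <- seq(r_start_px, r_stop_px, by = r_step_px)
  cc <- if (nrow(pts) < 3L) rep(NA_real_, length(r))
        else cc_sweep_cpp(pts, r, low_degree == "exclude")
  structure(
    data.frame(subject_id = subject_id, r_px = r,
               r_um = px_to_micron(r, pixel_size_um),
               mean_cc = cc, n_nfts = nrow(pts),
               stringsAsFactors = FALSE),
    class = c("clustering_sweep", "data.frame"))
}

#' @export
print.clustering_sweep <- function(x, ...) {
  n <- x$n_nfts[1L]
  cat(sprintf("<clustering_sweep> subject %s: %d NFTs, %d radii (%g..%g px)\n",
              x$subject_id[1L], n, nrow(x), min(x$r_px), max(x$r_px)))
  if (all(is.na(x$mean_cc))) {
    cat("  mean_cc undefined (< 3 NFTs)\n")
  } else {
    cat(sprintf("  mean_cc range %.4f .. %.4f\n",
                min(x$mean_cc, na.rm = TRUE), max(x$mean_cc, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
plot.clustering_sweep <- function(x, ...) {
  graphics::plot(x$r_px, x$mean_cc, type = "l", ylim = c(0, 1),
                 xlab = "radius threshold r (px)",
                 ylab = "mean clustering coefficient", ...)
  invisible(x)
}
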