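#' Read a single-channel NFT probability map
#'
#' Accepts 8-bit grayscale PNG (values rescaled by 1/255) or float TIFF with
#' values already in \[0, 1\]. Multi-channel rasters are reduced to their
#' first channel.
#'
#' @param path raster file path (`.png`, `.tif`/`.tiff`).
#' @return numeric matrix with values in \[0, 1\]; rows index y (top-down),
#'   columns index x.
#' @export
read_prob_map <- function(path) {
  if (!file.exists(path)) stop("probability map not found: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext))
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  if (any(m < 0 | m > 1)) stop("probability map values outside [0, 1]")
  m
}

# Connected-component labeling on a logical matrix by iterative stack-based
# flood fill; connectivity 8 (default) or 4.
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 0L, 0L, 1L); dc <- c(0L, -1L, 1L, 0L)
  }
  cur <- 0L
  seeds <- which(mask)
  for (s in seeds) {
    if (labels[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    labels[s] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      r0 <- ((p - 1L) %% nr) + 1L
      c0 <- ((p - 1L) %/% nr) + 1L
      rr <- r0 + dr; cc <- c0 + dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      q <- (cc[ok] - 1L) * nr + rr[ok]
      q <- q[mask[q] & labels[q] == 0L]
      if (length(q)) { labels[q] <- cur; stack <- c(stack, q) }
    }
  }
  labels
}

#' Extract NFT instances from a probability map
#'
#' Binarizes the per-pixel NFT probability raster at `threshold`
#' (inclusive), labels connected components, discards components smaller
#' than `min_size_px`, and reduces each survivor to an NFT object: its area
#' is the component pixel count, its centroid the unweighted mean of member
#' pixel centers. Pixel centers sit at integer coordinates with the raster's
#' top-left pixel center at (1, 1): x is the column index, y the row index.
#'
#' The segmentation model emits probabilities, not instances; the reduction
#' to discrete tangles is this function's job and its `threshold = 0.5`,
#' `min_size_px = 20`, 8-connectivity defaults are explicit, configurable
#' stand-ins — no canonical post-processing rule exists for these maps.
#'
#' @param prob_map numeric matrix with values in \[0, 1\] (rows = y).
#' @param threshold binarization cut in (0, 1); pixels with probability
#'   `>= threshold` are foreground.
#' @param min_size_px minimum component pixel count kept (>= 1).
#' @param connectivity 8 (default) or 4.
#' @param id_prefix prefix for generated object ids.
#' @return an [nft_table()], components ordered by first (column-major)
#'   foreground pixel.
#' @export
extract_instances <- function(prob_map, threshold = 0.5, min_size_px = 20L,
                              connectivity = 8L, id_prefix = "nft") {
  if (!is.matrix(prob_map)) prob_map <- as.matrix(prob_map)
  if (any(prob_map < 0 | prob_map > 1, na.rm = FALSE))
    stop("probability map values outside [0, 1]")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (min_size_px < 1L) stop("min_size_px must be >= 1")
  labels <- label_components(prob_map >= threshold, connectivity)
  k <- max(labels)
  if (k == 0L)
    return(nft_table(character(0), numeric(0), numeric(0), numeric(0)))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- ((idx - 1L) %% nrow(prob_map)) + 1L
  cols <- ((idx - 1L) %/% nrow(prob_map)) + 1L
  size <- tabulate(lab, nbins = k)
  cx <- tapply(cols, lab, mean)
  cy <- tapply(rows, lab, mean)
  keep <- which(size >= min_size_px)
  nft_table(id = paste0(id_prefix, "_", seq_along(keep)),
            x = as.numeric(cx[keep]), y = as.numeric(cy[keep]),
            area_px = as.numeric(size[keep]))
}

#' Assign NFTs to anatomical regions
#'
#' Labels each NFT with the region whose polygon contains its centroid
#' (boundary inclusive); centroids in neither polygon are labeled
#' `unassigned`. If both polygons claim a centroid (possible only within the
#' overlap tolerance of the slide invariant), the first region in `regions`
#' wins. Input order is preserved.
#'
#' @param nfts an [nft_table()].
#' @param regions list of [region_annotation()] objects.
#' @return the input table with its `region` column filled in.
#' @export
assign_regions <- function(nfts, regions) {
  stopifnot(inherits(nfts, "nft_table"))
  if (!nrow(nfts)) return(nfts)
  lab <- rep("unassigned", nrow(nfts))
  for (r in rev(regions)) {
    inside <- point_in_polygon(nfts$x, nfts$y, r$vertices)
    lab[inside] <- r$label
  }
  nfts$region <- lab
  nfts
}
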