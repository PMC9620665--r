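#' NFT count density of a region
#'
#' Number of NFTs assigned to the region divided by the region area in mm^2.
#'
#' @param nfts a region-assigned [nft_table()].
#' @param region a [region_annotation()].
#' @param pixel_size_um microns per pixel.
#' @return NFTs per mm^2.
#' @export
nft_count_density <- function(nfts, region, pixel_size_um = 0.5066) {
  stopifnot(inherits(nfts, "nft_table"))
  sum(nfts$region == region$label) / region_area_mm2(region, pixel_size_um)
}

#' NFT positive-pixel density of a region
#'
#' Sum of the pixel areas of all NFTs assigned to the region divided by the
#' region's pixel area: a dimensionless fraction, invariant to the scan's
#' pixel pitch.
#'
#' @inheritParams nft_count_density
#' @return fraction in \[0, 1\].
#' @export
nft_pixel_density <- function(nfts, region) {
  stopifnot(inherits(nfts, "nft_table"))
  if (region$area_px <= 0) stop("degenerate region: zero area")
  sum(nfts$area_px[nfts$region == region$label]) / region$area_px
}

#' Normalized positive-pixel burden
#'
#' Fraction of immunoreactive (positive) pixels over total region pixels —
#' the 0-1 p-tau burden scale. Counts are consumed as given; they may come
#' from an external positive-pixel algorithm (`method = "external"`) or from
#' a simple intensity threshold on a supplied raster
#' (`method = "threshold"`); the method tag rides along as an attribute.
#'
#' @param positive_px positive pixel count (0 <= positive_px <= total_px).
#' @param total_px total region pixel count (> 0).
#' @param method provenance tag, `"external"` or `"threshold"`.
#' @return fraction in \[0, 1\] with attribute `method`.
#' @export
positive_pixel_burden <- function(positive_px, total_px,
                                  method = c("external", "threshold")) {
  method <- match.arg(method)
  if (any(total_px <= 0)) stop("total_px must be positive")
  if (any(positive_px < 0) || any(positive_px > total_px))
    stop("positive_px must lie in [0, total_px]")
  structure(positive_px / total_px, method = method)
}

#' Regional burden metrics for one slide
#'
#' Computes, for the hippocampus proper, the entorhinal cortex and the two
#' pooled (`combined`), the three scalar burden measures: NFT count density
#' (counts / mm^2), NFT positive-pixel density (summed NFT pixel area /
#' region pixel area) and, when positive/total pixel counts are supplied,
#' the normalized positive-pixel burden. The combined region pools objects
#' and sums areas — it is not an average of the two per-region densities.
#'
#' @param slide a [slide_record()]; its NFTs must be region-assigned.
#' @param positive_px,total_px optional named vectors (names =
#'   region labels incl. `combined`) of externally computed positive-pixel
#'   counts and region totals.
#' @return data.frame, one row per region, columns `subject_id, region,
#'   nft_count, region_area_mm2, nft_count_density, nft_pixel_density,
#'   positive_pixel_burden`.
#' @export
burden_metrics <- function(slide, positive_px = NULL, total_px = NULL) {
  stopifnot(inherits(slide, "slide_record"))
  px <- slide$pixel_size_um
  per <- lapply(slide$regions, function(r) {
    data.frame(
      subject_id = slide$subject_id, region = r$label,
      nft_count = sum(slide$nfts$region == r$label),
      region_area_mm2 = region_area_mm2(r, px),
      nft_count_density = nft_count_density(slide$nfts, r, px),
      nft_pixel_density = nft_pixel_density(slide$nfts, r),
      stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, per)
  labs <- d$region
  comb <- data.frame(
    subject_id = slide$subject_id, region = "combined",
    nft_count = sum(d$nft_count),
    region_area_mm2 = sum(d$region_area_mm2),
    nft_count_density = sum(d$nft_count) / sum(d$region_area_mm2),
    nft_pixel_density =
      sum(slide$nfts$area_px[slide$nfts$region %in% labs]) /
      sum(vapply(slide$regions, function(r) r$area_px, numeric(1L))),
    stringsAsFactors = FALSE)
  d <- rbind(d, comb)
  d$positive_pixel_burden <- NA_real_
  if (!is.null(positive_px)) {
    if (is.null(total_px)) stop("total_px required with positive_px")
    for (i in seq_len(nrow(d))) {
      rg <- d$region[i]
      if (!is.na(positive_px[rg]) && !is.na(total_px[rg]))
        d$positive_pixel_burden[i] <-
          as.numeric(positive_pixel_burden(positive_px[[rg]], total_px[[rg]]))
    }
  }
  d
}
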