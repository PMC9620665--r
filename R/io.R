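#' Construct an NFT object table
#'
#' The atomic spatial datum is one segmented neurofibrillary tangle: a
#' centroid in continuous level-0 pixel coordinates (origin top-left, x
#' rightward, y downward) and a pixel area. The table form keeps one row per
#' tangle; `region` is `"unassigned"` until [assign_regions()] is run.
#'
#' @param id identifier vector (coerced to character).
#' @param x,y centroid coordinates, level-0 pixels (finite).
#' @param area_px object area in pixels squared (> 0).
#' @param region optional region label vector.
#' @return data.frame of class `nft_table` with columns
#'   `id, x, y, area_px, region`.
#' @export
nft_table <- function(id, x, y, area_px,
                      region = rep("unassigned", length(x))) {
  x <- as.numeric(x); y <- as.numeric(y); area_px <- as.numeric(area_px)
  if (length(x) && (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))))
    stop("NFT centroid coordinates must be finite")
  if (length(area_px) && (anyNA(area_px) || any(area_px <= 0)))
    stop("NFT area_px must be positive")
  bad <- setdiff(unique(region), c("hippocampus", "entorhinal", "unassigned"))
  if (length(bad))
    stop("unknown region label(s): ", paste(bad, collapse = ", "))
  structure(
    data.frame(id = as.character(id), x = x, y = y, area_px = area_px,
               region = as.character(region), stringsAsFactors = FALSE),
    class = c("nft_table", "data.frame"))
}

#' Read a per-slide NFT object table
#'
#' Comma-delimited text with a header declaring `id,x,y,area_px` columns
#' (extra columns are ignored; a `region` column, if present, is kept). Row
#' order is preserved.
#'
#' @param path file path.
#' @return an [nft_table()].
#' @export
read_nft_table <- function(path) {
  if (!file.exists(path)) stop("NFT table not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("id", "x", "y", "area_px")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("NFT table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  parse_num <- function(col) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !(d[[col]] %in% c("", "NA")))
    if (length(bad))
      stop("non-numeric value in column '", col, "' of ", path,
           " at data line ", bad[1L])
    v
  }
  reg <- if ("region" %in% names(d) && nrow(d)) d$region
         else rep("unassigned", nrow(d))
  nft_table(id = d$id, x = parse_num("x"), y = parse_num("y"),
            area_px = parse_num("area_px"), region = reg)
}

#' Write an NFT object table
#'
#' @param nfts an [nft_table()].
#' @param path output file path.
#' @param keep_region write the region column too (default TRUE).
#' @return `path`, invisibly.
#' @export
write_nft_table <- function(nfts, path, keep_region = TRUE) {
  d <- as.data.frame(nfts)
  if (!keep_region) d$region <- NULL
  utils::write.csv(format(d, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read region annotations from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features, each carrying a `label`
#' property equal to `hippocampus` or `entorhinal`, with coordinates in
#' level-0 pixels. Polygons are validated simple; unknown labels are rejected.
#'
#' @param path GeoJSON file path.
#' @return list of [region_annotation()] objects.
#' @export
read_region_geojson <- function(path) {
  if (!file.exists(path)) stop("region file not found: ", path)
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(g$type, "FeatureCollection")) g$features
           else if (identical(g$type, "Feature")) list(g)
           else stop("not a GeoJSON Feature/FeatureCollection: ", path)
  lapply(feats, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("region geometry must be a Polygon (got ",
           f$geometry$type %||% "nothing", ")")
    label <- f$properties$label
    if (is.null(label))
      stop("region feature lacks a 'label' property in ", path)
    if (!label %in% c("hippocampus", "entorhinal"))
      stop("unknown region label '", label, "' in ", path)
    ring <- f$geometry$coordinates[[1L]]  # exterior ring; holes unsupported
    v <- do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
    region_annotation(label, v)
  })
}

#' Write region annotations to GeoJSON
#'
#' @param regions list of [region_annotation()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_geojson <- function(regions, path) {
  feats <- lapply(regions, function(r) {
    v <- rbind(r$vertices, r$vertices[1L, ])  # close the ring
    ring <- lapply(seq_len(nrow(v)), function(i) c(v[i, 1L], v[i, 2L]))
    list(type = "Feature",
         properties = list(label = r$label),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a slide record
#'
#' One subject's hippocampal section: its NFT objects, its region
#' annotations and the scan's pixel pitch. Region polygons of one slide must
#' not overlap (intersection under 0.1% of the smaller region); any NFT
#' already carrying a region label must actually sit inside that region.
#'
#' @param subject_id subject identifier.
#' @param nfts an [nft_table()].
#' @param regions list of [region_annotation()] objects.
#' @param pixel_size_um microns per pixel (default 0.5066).
#' @param check run the containment/overlap invariants (default TRUE).
#' @return object of class `slide_record`.
#' @export
slide_record <- function(subject_id, nfts, regions,
                         pixel_size_um = 0.5066, check = TRUE) {
  stopifnot(inherits(nfts, "nft_table"))
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  labs <- vapply(regions, function(r) r$label, character(1L))
  if (anyDuplicated(labs)) stop("duplicate region labels on one slide")
  if (check && length(regions) == 2L) {
    ov <- polygon_overlap_area(regions[[1L]], regions[[2L]])
    if (ov >= 0.001 * min(regions[[1L]]$area_px, regions[[2L]]$area_px))
      stop("hippocampus and entorhinal annotations overlap")
  }
  if (check && nrow(nfts)) {
    for (r in regions) {
      in_r <- nfts$region == r$label
      if (any(in_r) &&
          !all(point_in_polygon(nfts$x[in_r], nfts$y[in_r], r$vertices)))
        stop("NFT labeled '", r$label, "' lies outside that region polygon")
    }
  }
  structure(list(subject_id = as.character(subject_id),
                 pixel_size_um = pixel_size_um,
                 nfts = nfts, regions = regions),
            class = "slide_record")
}

#' @export
print.slide_record <- function(x, ...) {
  cat(sprintf("<slide_record> subject %s: %d NFTs, %d region(s), %.4f um/px\n",
              x$subject_id, nrow(x$nfts), length(x$regions), x$pixel_size_um))
  if (nrow(x$nfts))
    print(table(region = x$nfts$region))
  invisible(x)
}

#' Read a cohort covariate table
#'
#' Delimited text with a declared header; missing values are empty fields.
#' Recognized columns: `subject_id`, `age_at_death`, `sex`, `cdr`,
#' `cdr_date`, `mmse`, `mmse_date`, `clinical_impairment`, `braak_stage`,
#' `cerad`, `artag`. Extra columns pass through untouched (e.g. genotype
#' categories used only as covariates).
#'
#' @param path file path.
#' @return data.frame, one row per subject.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("cohort table not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!"subject_id" %in% names(d))
    stop("cohort table must declare a subject_id column")
  if ("age_at_death" %in% names(d)) {
    bad <- !is.na(d$age_at_death) &
      (d$age_at_death < 0 | d$age_at_death > 130)
    if (any(bad)) stop("age_at_death outside [0, 130] for subject(s): ",
                       paste(d$subject_id[bad], collapse = ", "))
  }
  for (dc in intersect(c("cdr_date", "mmse_date"), names(d)))
    d[[dc]] <- as.Date(d[[dc]])
  d
}

#' Write the per-subject burden metrics table
#'
#' One row per subject and region, deterministic column order; optional
#' metrics left missing are written as empty fields.
#'
#' @param metrics data.frame as returned by [burden_metrics()] (possibly
#'   row-bound over subjects).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(metrics, path) {
  cols <- c("subject_id", "region", "nft_count", "region_area_mm2",
            "nft_count_density", "nft_pixel_density", "positive_pixel_burden")
  for (cl in setdiff(cols, names(metrics))) metrics[[cl]] <- NA_real_
  utils::write.csv(metrics[cols], path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Write a clustering sweep table
#'
#' Columns `subject_id, r_px, r_um, mean_cc, n_nfts`; undefined sweep values
#' (slides with fewer than 3 NFTs) are written as empty fields, never as 0.
#'
#' @param sweeps a `clustering_sweep` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(sweeps, path) {
  if (inherits(sweeps, "clustering_sweep")) sweeps <- list(sweeps)
  d <- do.call(rbind, lapply(sweeps, as.data.frame))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
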