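#' Image-quantification chain configuration
#'
#' Defaults mirror the published MetaXpress custom-module settings: top hat
#' of size 12 with a circular structuring element, adaptive threshold on the
#' top-hat image with minimum width 10 px, maximum width 800 px and
#' intensity above local background 500 counts, and a minimum-area filter
#' of 500 px. The MetaXpress "size" is taken as the disc *radius*
#' (`tophat_size_as = "radius"`, kernel diameter 25): with a diameter-12
#' disc, uniformly lit objects wider than 12 px would be morphologically
#' open and vanish from the top hat, emptying the assay's own 10-800 px
#' width window. The radius reading keeps objects up to ~2x the size
#' parameter detectable; both conventions are available.
#'
#' @param tophat_size_px structuring-element size (px).
#' @param tophat_shape structuring-element shape (only `"circle"`).
#' @param tophat_size_as `"radius"` (default) or `"diameter"`.
#' @param min_width_px,max_width_px admissible object width (inclusive),
#'   measured as 2 x the maximum inscribed-disc radius (distance-transform
#'   maximum) of each connected component.
#' @param intensity_above_background detection threshold on the top-hat
#'   (local-background-subtracted) value, counts.
#' @param min_area_px minimum connected-component area (inclusive), px.
#' @param connectivity pixel connectivity for components (8 or 4).
#' @param site_aggregate how per-site totals combine into the per-well
#'   value: `"mean"`, `"sum"` or `"median"`.
#' @param intensity_source image whose pixels are summed under the final
#'   mask: `"original"` (default; cell fluorescence including local
#'   background) or `"tophat"` (background-subtracted). Both totals are
#'   always recorded.
#' @param saturation_level,max_saturated_fraction artifact rule: flag a
#'   site when more than this fraction of pixels is at/above the
#'   saturation level.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(tophat_size_px = 12, tophat_shape = "circle",
                            tophat_size_as = c("radius", "diameter"),
                            min_width_px = 10, max_width_px = 800,
                            intensity_above_background = 500,
                            min_area_px = 500, connectivity = 8,
                            site_aggregate = c("mean", "sum", "median"),
                            intensity_source = c("original", "tophat"),
                            saturation_level = 65535,
                            max_saturated_fraction = 0.001) {
  tophat_size_as <- match.arg(tophat_size_as)
  site_aggregate <- match.arg(site_aggregate)
  intensity_source <- match.arg(intensity_source)
  stopifnot(tophat_size_px >= 1, min_width_px > 0,
            max_width_px > min_width_px, intensity_above_background >= 0,
            min_area_px >= 0, connectivity %in% c(4, 8))
  if (tophat_shape != "circle") stop("only the circle structuring element is supported")
  structure(as.list(environment()), class = "pipeline_config")
}

se_radius <- function(config) {
  if (config$tophat_size_as == "radius") as.integer(config$tophat_size_px)
  else as.integer(floor(config$tophat_size_px / 2))
}

#' White top-hat transform
#'
#' Image minus its grayscale morphological opening by a flat disc:
#' suppresses slowly varying background and any structure the disc fits
#' inside, retaining objects narrower than the structuring element at their
#' intensity above local background. Output is non-negative and bounded by
#' the input; `top_hat(x + c) = top_hat(x)` for constant `c`.
#'
#' @param image numeric matrix of counts.
#' @param size_px structuring-element size; see [pipeline_config()].
#' @param shape only `"circle"`.
#' @param size_as `"radius"` or `"diameter"`.
#' @return numeric matrix, same shape as `image`.
#' @export
top_hat <- function(image, size_px = 12, shape = "circle",
                    size_as = c("radius", "diameter")) {
  size_as <- match.arg(size_as)
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a 2-D numeric matrix")
  if (size_px < 1) stop("size_px must be >= 1")
  if (shape != "circle") stop("only the circle structuring element is supported")
  r <- if (size_as == "radius") as.integer(size_px)
       else as.integer(floor(size_px / 2))
  opened <- gray_dilate_disc(gray_erode_disc(image, r), r)
  image - opened
}

label_components <- function(mask, connectivity = 8) {
  storage.mode(mask) <- "integer"
  label_components_cpp(mask, as.integer(connectivity))
}

# width of each labeled component: 2 x maximum inscribed-disc radius,
# via the Euclidean distance transform of the foreground mask.
component_widths <- function(labels) {
  n <- max(labels)
  if (n == 0) return(numeric(0))
  dm <- EBImage::distmap(labels > 0)
  dm <- matrix(as.numeric(dm), nrow(labels), ncol(labels))
  2 * vapply(seq_len(n), function(k) max(dm[labels == k]), numeric(1))
}

#' Adaptive threshold with width constraints
#'
#' Pixels whose top-hat (local-background-subtracted) value meets
#' `intensity_above_background` form candidate regions; connected regions
#' whose width falls outside `[min_width_px, max_width_px]` are removed.
#' Width is 2 x the component's maximum inscribed-disc radius
#' (distance-transform maximum), robust for elongated objects.
#'
#' @param source the top-hat image (numeric matrix).
#' @param min_width_px,max_width_px,intensity_above_background,connectivity
#'   see [pipeline_config()].
#' @return logical mask.
#' @export
adaptive_threshold <- function(source, min_width_px = 10, max_width_px = 800,
                               intensity_above_background = 500,
                               connectivity = 8) {
  cand <- source >= intensity_above_background
  if (!any(cand)) return(cand)
  labels <- label_components(cand, connectivity)
  widths <- component_widths(labels)
  keep <- which(widths >= min_width_px & widths <= max_width_px)
  matrix(labels %in% keep, nrow(source), ncol(source))
}

#' Minimum-area filter on a mask
#'
#' Retains connected components with area >= `min_area_px` (inclusive) and
#' relabels survivors contiguously from 1.
#'
#' @param mask logical or labeled integer matrix.
#' @param min_area_px minimum area (px).
#' @param connectivity component connectivity (used when `mask` is binary).
#' @return integer label matrix (0 = background).
#' @export
filter_mask <- function(mask, min_area_px = 500, connectivity = 8) {
  labels <- if (is.logical(mask)) label_components(mask, connectivity)
            else { storage.mode(mask) <- "integer"; mask }
  if (max(labels) == 0) return(labels)
  areas <- tabulate(labels[labels > 0], nbins = max(labels))
  keep <- which(areas >= min_area_px)
  map <- integer(max(labels))
  map[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0] <- map[labels[labels > 0]]
  out
}

# per-object metrics table for a labeled mask
measure_objects <- function(labels, image, tophat_image) {
  n <- max(labels)
  if (n == 0)
    return(data.frame(label = integer(0), area_px = integer(0),
                      width_px = numeric(0), integrated_intensity = numeric(0),
                      mean_intensity = numeric(0),
                      integrated_tophat = numeric(0)))
  idx <- labels > 0
  lab <- labels[idx]
  areas <- tabulate(lab, nbins = n)
  tot <- as.numeric(tapply(image[idx], lab, sum))
  tot_th <- as.numeric(tapply(tophat_image[idx], lab, sum))
  data.frame(label = seq_len(n), area_px = areas,
             width_px = component_widths(labels),
             integrated_intensity = tot, mean_intensity = tot / areas,
             integrated_tophat = tot_th)
}

#' Quantify fluorescence under a segmentation mask
#'
#' Sums the pixels of `image` under the final mask and reports the masked
#' area, object count and mean masked intensity. An empty mask gives total
#' intensity 0.
#'
#' @param image numeric matrix (the intensity source).
#' @param mask logical or labeled matrix, same shape as `image`.
#' @return list `total_intensity, masked_area_px, mean_intensity,
#'   object_count`.
#' @export
quantify <- function(image, mask) {
  if (!all(dim(image) == dim(mask))) stop("image and mask shapes differ")
  labels <- if (is.logical(mask)) label_components(mask, 8)
            else { storage.mode(mask) <- "integer"; mask }
  idx <- labels > 0
  area <- sum(idx)
  total <- if (area > 0) sum(image[idx]) else 0
  list(total_intensity = total, masked_area_px = area,
       mean_intensity = if (area > 0) total / area else NA_real_,
       object_count = max(labels))
}

# run the full chain on one site image
analyze_site <- function(image, config = pipeline_config()) {
  th <- top_hat(image, config$tophat_size_px, config$tophat_shape,
                config$tophat_size_as)
  cand <- adaptive_threshold(th, config$min_width_px, config$max_width_px,
                             config$intensity_above_background,
                             config$connectivity)
  labels <- filter_mask(cand, config$min_area_px, config$connectivity)
  objects <- measure_objects(labels, image, th)
  src <- if (config$intensity_source == "original") image else th
  q <- quantify(src, labels)
  bg_median <- median(image[labels == 0])
  list(tophat = th, labels = labels, objects = objects,
       measurement = q, background_median = bg_median,
       total_intensity_original = quantify(image, labels)$total_intensity,
       total_intensity_tophat = quantify(th, labels)$total_intensity)
}

#' Flag artifact images (debris / auto-fluorescence)
#'
#' A site is flagged when (a) the saturated-pixel fraction exceeds
#' `max_saturated_fraction` (`"debris"`), (b) any object's mean intensity
#' exceeds 5x the plate's median object mean intensity
#' (`"bright_object"`), or (c) the background median exceeds 3x the plate
#' median background (`"autofluorescence"`). Rules (b) and (c) need plate
#' context and are skipped when `plate_stats` is `NULL`.
#'
#' @param image site image (numeric matrix).
#' @param labels final label matrix for the site.
#' @param objects per-object table from the site.
#' @param plate_stats optional list
#'   `median_object_mean_intensity, median_background`.
#' @param config a [pipeline_config()].
#' @return list `flag` (logical), `reason` (character vector, possibly
#'   empty).
#' @export
flag_artifacts <- function(image, labels, objects, plate_stats = NULL,
                           config = pipeline_config()) {
  reasons <- character(0)
  sat <- mean(image >= config$saturation_level)
  if (sat > config$max_saturated_fraction) reasons <- c(reasons, "debris")
  if (!is.null(plate_stats)) {
    mo <- plate_stats$median_object_mean_intensity
    if (is.finite(mo) && nrow(objects) > 0 &&
        any(objects$mean_intensity > 5 * mo))
      reasons <- c(reasons, "bright_object")
    mb <- plate_stats$median_background
    bg <- median(image[labels == 0])
    if (is.finite(mb) && is.finite(bg) && bg > 3 * mb)
      reasons <- c(reasons, "autofluorescence")
  }
  list(flag = length(reasons) > 0, reason = reasons)
}

#' Analyze one well from its site images
#'
#' Runs the full chain per site (two sites per well in the assay),
#' aggregates per-site total intensities (mean by default) over sites not
#' flagged as artifacts, and sets the well's artifact flag if any site is
#' flagged. If every site is flagged, the aggregate uses all sites and the
#' flag is set.
#'
#' @param images list of site images (numeric matrices); >= 1.
#' @param config a [pipeline_config()].
#' @param plate_stats optional plate context for [flag_artifacts()].
#' @param well well coordinate to attach.
#' @return a one-row data.frame: `well, total_intensity, masked_area_px,
#'   object_count, n_sites, artifact_flag, artifact_reason`.
#' @export
analyze_well <- function(images, config = pipeline_config(),
                         plate_stats = NULL, well = NA_character_) {
  if (length(images) == 0) stop("analyze_well needs >= 1 site image")
  sites <- lapply(images, analyze_site, config = config)
  flags <- lapply(seq_along(sites), function(i)
    flag_artifacts(images[[i]], sites[[i]]$labels, sites[[i]]$objects,
                   plate_stats, config))
  flagged <- vapply(flags, `[[`, logical(1), "flag")
  use <- if (all(flagged)) seq_along(sites) else which(!flagged)
  agg <- function(x) switch(config$site_aggregate,
                            mean = mean(x), sum = sum(x), median = median(x))
  totals <- vapply(sites, function(s) s$measurement$total_intensity,
                   numeric(1))
  data.frame(
    well = well,
    total_intensity = agg(totals[use]),
    total_intensity_original = agg(vapply(sites, `[[`, numeric(1),
                                          "total_intensity_original")[use]),
    total_intensity_tophat = agg(vapply(sites, `[[`, numeric(1),
                                        "total_intensity_tophat")[use]),
    masked_area_px = agg(vapply(sites, function(s)
      as.numeric(s$measurement$masked_area_px), numeric(1))[use]),
    object_count = agg(vapply(sites, function(s)
      as.numeric(s$measurement$object_count), numeric(1))[use]),
    n_sites = length(images),
    artifact_flag = any(flagged),
    artifact_reason = paste(unique(unlist(lapply(flags, `[[`, "reason"))),
                            collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Analyze a plate of well images
#'
#' Two-pass analysis: the first pass segments every site and accumulates
#' the plate-level medians (object mean intensity, background) that the
#' artifact rules need; the second pass applies [flag_artifacts()] with
#' that context and aggregates sites per well.
#'
#' @param well_images named list (well -> list of site images).
#' @param config a [pipeline_config()].
#' @return data.frame of per-well measurements (one row per well).
#' @export
analyze_plate_images <- function(well_images, config = pipeline_config()) {
  if (length(well_images) == 0) stop("no wells supplied")
  all_sites <- lapply(well_images, function(imgs)
    lapply(imgs, analyze_site, config = config))
  obj_means <- unlist(lapply(all_sites, function(ss)
    unlist(lapply(ss, function(s) s$objects$mean_intensity))))
  bgs <- unlist(lapply(all_sites, function(ss)
    vapply(ss, `[[`, numeric(1), "background_median")))
  plate_stats <- list(
    median_object_mean_intensity = if (length(obj_means)) median(obj_means)
                                   else NA_real_,
    median_background = median(bgs))
  out <- lapply(names(well_images), function(wname) {
    analyze_well(well_images[[wname]], config, plate_stats, well = wname)
  })
  do.call(rbind, out)
}

#' Read / write 16-bit grayscale TIFF well images
#'
#' Images are stored as 16-bit grayscale TIFF with integer counts in
#' `[0, 65535]`; site files follow the `<plate>_<well>_s<site>.tif` naming
#' convention.
#'
#' @param path TIFF path.
#' @param image numeric matrix of counts.
#' @return `read_well_image` returns an integer-valued numeric matrix.
#' @export
read_well_image <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.numeric(img), nrow(img), ncol(img))
}

#' @rdname read_well_image
#' @export
write_well_image <- function(image, path) {
  img <- pmin(pmax(round(image), 0), 65535) / 65535
  tiff::writeTIFF(img, path, bits.per.sample = 16)
  invisible(path)
}
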