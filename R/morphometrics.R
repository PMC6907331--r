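#' Count nuclei in a binary mask
#'
#' Labels connected components (8-connectivity, so touching nuclei merge —
#' a documented limitation of mask-based counting), discards components
#' smaller than `min_nucleus_area_px`, and returns centroids.
#'
#' @param nuclei_mask logical (or 0/1) matrix.
#' @param min_nucleus_area_px minimum component area (px), default 20.
#' @param connectivity 8 (default) or 4.
#' @return matrix with columns `cx, cy` (row/column pixel coordinates),
#'   zero rows for an empty mask.
#' @export
count_nuclei <- function(nuclei_mask, min_nucleus_area_px = 20,
                         connectivity = 8) {
  labels <- label_components(nuclei_mask != 0, connectivity)
  n <- max(labels)
  if (n == 0) return(matrix(numeric(0), 0, 2,
                            dimnames = list(NULL, c("cx", "cy"))))
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  areas <- tabulate(lab, nbins = n)
  cx <- tapply(idx[, 1], lab, mean)
  cy <- tapply(idx[, 2], lab, mean)
  keep <- areas >= min_nucleus_area_px
  cbind(cx = as.numeric(cx)[keep], cy = as.numeric(cy)[keep])
}

#' Fusion index from nuclei and MHC masks
#'
#' Fraction of nuclei whose centroid lies on a true pixel of the
#' myosin-heavy-chain (MHC) positive mask, pooled over fields by summed
#' counts (unbiased when fields carry unequal nucleus numbers); the
#' mean-of-field-indices alternative is available via `aggregate`.
#'
#' @param fields list of fields, each a list with `nuclei` (centroid
#'   matrix/data.frame with columns `cx, cy`, or a binary mask run through
#'   [count_nuclei()]) and `mhc_mask` (binary matrix).
#' @param aggregate `"pooled"` (default) or `"mean_of_fields"`.
#' @param min_nucleus_area_px passed to [count_nuclei()] for mask inputs.
#' @return list `fusion_index`, `per_field` (data.frame
#'   `field, n_nuclei, n_fused, index`).
#' @export
fusion_index <- function(fields, aggregate = c("pooled", "mean_of_fields"),
                         min_nucleus_area_px = 20) {
  aggregate <- match.arg(aggregate)
  if (length(fields) == 0) stop("fusion_index needs >= 1 field")
  per <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    cen <- f$nuclei
    is_mask <- is.matrix(cen) && (is.logical(cen) || ncol(cen) > 2)
    if (is_mask) cen <- count_nuclei(cen, min_nucleus_area_px)
    cen <- as.matrix(as.data.frame(cen)[, c("cx", "cy")])
    mhc <- f$mhc_mask != 0
    fused <- if (nrow(cen) == 0) logical(0) else {
      ri <- pmin(pmax(round(cen[, 1]), 1), nrow(mhc))
      ci <- pmin(pmax(round(cen[, 2]), 1), ncol(mhc))
      mhc[cbind(ri, ci)]
    }
    data.frame(field = i, n_nuclei = nrow(cen), n_fused = sum(fused),
               index = if (nrow(cen) > 0) mean(fused) else NA_real_)
  })
  per <- do.call(rbind, per)
  if (sum(per$n_nuclei) == 0) stop("undefined fusion index: zero nuclei")
  fi <- if (aggregate == "pooled") sum(per$n_fused) / sum(per$n_nuclei)
        else mean(per$index[per$n_nuclei > 0])
  list(fusion_index = fi, per_field = per)
}

#' Densitometry normalization against a loading control
#'
#' `ratio = target_band / loading_band` per lane, rescaled so the
#' calibrator lane (vehicle-treated in the assay) has relative level 1.
#'
#' @param records data.frame `sample_id, target_band, loading_band`.
#' @param calibrator_sample calibrator lane's `sample_id`.
#' @return `records` with `ratio` and `relative_level` columns.
#' @export
densitometry_normalize <- function(records, calibrator_sample) {
  need <- c("sample_id", "target_band", "loading_band")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ","))
  if (any(records$loading_band <= 0)) stop("loading bands must be > 0")
  if (!calibrator_sample %in% records$sample_id)
    stop("calibrator sample absent from records")
  records$ratio <- records$target_band / records$loading_band
  cal <- records$ratio[records$sample_id == calibrator_sample][1]
  records$relative_level <- records$ratio / cal
  records
}
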