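#' ddCT relative expression from a replicate Ct table
#'
#' Technical replicates are combined by arithmetic mean of Ct per
#' (sample, gene); "undetermined" Cts (NA) are excluded from the mean and
#' it is an error for all replicates of a (sample, gene) to be
#' undetermined. Then `dCt = Ct_gene - Ct_ref` per sample,
#' `ddCt = dCt_sample - dCt_calibrator`, and `fold = 2^(-ddCt)`; the
#' calibrator sample (vehicle-treated in the assay) has fold 1 by
#' construction for every gene, as does the reference gene for every
#' sample. The reference gene is a required argument: the assay normalized
#' to beta-actin or GAPDH depending on the experiment.
#'
#' @param table data.frame `sample_id, gene, replicate, ct` (NA ct =
#'   undetermined).
#' @param reference_gene reference (housekeeping) gene name.
#' @param calibrator_sample calibrator sample name.
#' @param efficiency_corrected if `TRUE`, folds use the per-gene
#'   amplification efficiencies in `efficiencies` (gene -> AE fraction)
#'   via `(1 + AE)^(-ddCt-ish)` Pfaffl-style single-gene correction;
#'   off by default (pure `2^(-ddCt)`).
#' @param efficiencies named vector of amplification-efficiency fractions,
#'   only used when `efficiency_corrected = TRUE`; genes missing from it
#'   fall back to perfect doubling (AE 1).
#' @return data.frame `sample_id, gene, mean_ct, delta_ct, delta_delta_ct,
#'   fold`.
#' @export
ddct_fold_change <- function(table, reference_gene, calibrator_sample,
                             efficiency_corrected = FALSE,
                             efficiencies = NULL) {
  need <- c("sample_id", "gene", "ct")
  if (!all(need %in% names(table)))
    stop("Ct table must have columns sample_id, gene, ct")
  if (!reference_gene %in% table$gene)
    stop("reference gene ", reference_gene, " absent from the table")
  if (!calibrator_sample %in% table$sample_id)
    stop("calibrator sample ", calibrator_sample, " absent from the table")

  agg <- unique(data.frame(sample_id = table$sample_id, gene = table$gene,
                           stringsAsFactors = FALSE))
  agg$mean_ct <- vapply(seq_len(nrow(agg)), function(i) {
    x <- table$ct[table$sample_id == agg$sample_id[i] &
                    table$gene == agg$gene[i]]
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  }, numeric(1))
  if (any(is.na(agg$mean_ct)))
    stop("all replicates undetermined for ",
         paste(agg$sample_id[is.na(agg$mean_ct)],
               agg$gene[is.na(agg$mean_ct)], sep = "/", collapse = ", "))

  ref_ct <- setNames(agg$mean_ct[agg$gene == reference_gene],
                     agg$sample_id[agg$gene == reference_gene])
  if (!all(unique(agg$sample_id) %in% names(ref_ct)))
    stop("reference gene missing for some samples")
  agg$delta_ct <- agg$mean_ct - ref_ct[agg$sample_id]
  cal <- agg[agg$sample_id == calibrator_sample, ]
  cal_dct <- setNames(cal$delta_ct, cal$gene)
  if (!all(unique(agg$gene) %in% names(cal_dct)))
    stop("calibrator sample missing for some genes")
  agg$delta_delta_ct <- agg$delta_ct - cal_dct[agg$gene]
  if (efficiency_corrected) {
    ae <- rep(1, nrow(agg))
    if (!is.null(efficiencies)) {
      m <- match(agg$gene, names(efficiencies))
      ae[!is.na(m)] <- efficiencies[m[!is.na(m)]]
    }
    agg$fold <- (1 + ae)^(-agg$delta_delta_ct)
  } else {
    agg$fold <- 2^(-agg$delta_delta_ct)
  }
  rownames(agg) <- NULL
  agg
}

#' Amplification efficiency from a standard curve
#'
#' Least-squares slope of mean Ct against log10 template input, converted
#' with `AE = 10^(-1/slope) - 1`; a slope of -3.3219 (= -1/log10(2)) is
#' perfect doubling, AE = 1.
#'
#' @param log10_input,mean_ct standard-curve points (>= 2), or
#' @param slope an explicit slope (cycles per log10 unit) instead of
#'   points.
#' @return list `slope, amplification_efficiency`.
#' @export
amplification_efficiency <- function(log10_input = NULL, mean_ct = NULL,
                                     slope = NULL) {
  if (is.null(slope)) {
    if (length(log10_input) < 2 || length(log10_input) != length(mean_ct))
      stop("need >= 2 standard-curve points or an explicit slope")
    slope <- unname(coef(lm(mean_ct ~ log10_input))[2])
  }
  if (!is.finite(slope) || slope >= 0)
    stop("invalid standard curve: slope must be negative")
  list(slope = slope, amplification_efficiency = 10^(-1 / slope) - 1)
}
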