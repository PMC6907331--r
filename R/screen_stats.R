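#' Unscaled median absolute deviation
#'
#' Median of absolute deviations from the median, with no consistency
#' constant: the 1.4826 factor that rescales the MAD to a normal standard
#' deviation is applied inside [ssmd_star()], exactly where the screen's
#' statistic places it.
#'
#' @param values numeric vector, length >= 1.
#' @return non-negative scalar.
#' @export
mad_unscaled <- function(values) {
  if (length(values) < 1) stop("mad_unscaled needs >= 1 value")
  median(abs(values - median(values)))
}

#' Robust strictly standardized mean difference (SSMD*)
#'
#' `(median(pos) - median(neg)) / (1.4826 * sqrt(MAD(pos)^2 + MAD(neg)^2))`
#' with unscaled MADs. Used both for plate quality control (threshold 1,
#' inclusive, for a good moderate positive control) and hit strength
#' (strictly above 0.25).
#' When both MADs are zero the statistic is degenerate: equal medians give
#' 0, unequal medians give signed infinity; either way the result carries a
#' `degenerate` attribute.
#'
#' @param pos_values,neg_values positive-control and negative-control
#'   (vehicle) values; both non-empty.
#' @return scalar, with attribute `degenerate` (logical).
#' @export
ssmd_star <- function(pos_values, neg_values) {
  if (length(pos_values) < 1 || length(neg_values) < 1)
    stop("ssmd_star needs non-empty groups")
  dmed <- median(pos_values) - median(neg_values)
  s <- sqrt(mad_unscaled(pos_values)^2 + mad_unscaled(neg_values)^2)
  if (s == 0) {
    out <- if (dmed == 0) 0 else sign(dmed) * Inf
    return(structure(out, degenerate = TRUE))
  }
  structure(dmed / (1.4826 * s), degenerate = FALSE)
}

#' Single-replicate SSMD* for primary hit selection
#'
#' A primary screen tests each compound in one well, so the compound-side
#' MAD is undefined; the standard no-replicate construction sets it equal
#' to the vehicle MAD, giving
#' `(x - median(neg)) / (1.4826 * sqrt(2) * MAD(neg))`.
#'
#' @param x single compound value (vectorized over wells).
#' @param neg_values vehicle values, length >= 2.
#' @return numeric vector, with attribute `degenerate` (logical).
#' @export
ssmd_star_single <- function(x, neg_values) {
  if (length(neg_values) < 2) stop("ssmd_star_single needs >= 2 negatives")
  s <- mad_unscaled(neg_values)
  d <- x - median(neg_values)
  if (s == 0) {
    out <- ifelse(d == 0, 0, sign(d) * Inf)
    return(structure(out, degenerate = TRUE))
  }
  structure(d / (1.4826 * sqrt(2) * s), degenerate = FALSE)
}

plate_invalid_error <- function(msg) {
  structure(class = c("plate_invalid_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

# vehicle reference values of a measurement table (non-artifact)
usable_vehicle <- function(measurements) {
  v <- measurements$value[measurements$role == "vehicle" &
                            !measurements$artifact_flag]
  if (length(v) < 2)
    stop(plate_invalid_error("plate has < 2 usable (non-artifact) vehicle wells"))
  v
}

#' Normalize a plate to its vehicle median
#'
#' Adds `fold_change = value / median(vehicle values)` per well, where the
#' reference median is taken over the plate's non-artifact vehicle wells.
#'
#' @param measurements per-well data.frame with columns
#'   `well, role, value, artifact_flag` (and optionally `compound_id`,
#'   `plate_id`).
#' @return `measurements` with a `fold_change` column.
#' @export
normalize_plate <- function(measurements) {
  ref <- median(usable_vehicle(measurements))
  measurements$fold_change <- measurements$value / ref
  measurements
}

#' Plate quality control via SSMD*
#'
#' SSMD* between the plate's non-artifact positive-control and vehicle
#' wells; the plate passes when `ssmd_star >= qc_cutoff` (inclusive, per
#' the assay's ">= 1" rule).
#'
#' @param measurements per-well data.frame (see [normalize_plate()]).
#' @param qc_cutoff plate-quality threshold (default 1).
#' @return list `ssmd_star, qc_pass, n_pos, n_veh`.
#' @export
plate_qc <- function(measurements, qc_cutoff = 1) {
  veh <- usable_vehicle(measurements)
  pos <- measurements$value[measurements$role == "positive_control" &
                              !measurements$artifact_flag]
  if (length(pos) < 2)
    stop(plate_invalid_error("plate has < 2 usable positive-control wells"))
  s <- ssmd_star(pos, veh)
  list(ssmd_star = as.numeric(s), qc_pass = as.numeric(s) >= qc_cutoff,
       n_pos = length(pos), n_veh = length(veh))
}

#' Primary hit calling
#'
#' A compound well is a primary hit when its vehicle-normalized fold change
#' attains `fold_cutoff` (inclusive), its single-replicate SSMD* strictly
#' exceeds `ssmd_cutoff`, and the well is not artifact-flagged.
#'
#' @param measurements normalized per-well data.frame
#'   (from [normalize_plate()]); compound rows must carry `compound_id`.
#' @param fold_cutoff fold-change threshold (default 1.4, inclusive).
#' @param ssmd_cutoff SSMD* threshold (default 0.25, strict).
#' @return data.frame `compound_id, well, fold_change, ssmd_star,
#'   artifact_flag, hit`.
#' @export
call_hits_primary <- function(measurements, fold_cutoff = 1.4,
                              ssmd_cutoff = 0.25) {
  if (is.null(measurements$fold_change))
    measurements <- normalize_plate(measurements)
  veh <- usable_vehicle(measurements)
  cmp <- measurements[measurements$role == "compound", , drop = FALSE]
  ssmd <- as.numeric(ssmd_star_single(cmp$value, veh))
  data.frame(
    compound_id = cmp$compound_id,
    well = cmp$well,
    fold_change = cmp$fold_change,
    ssmd_star = ssmd,
    artifact_flag = cmp$artifact_flag,
    hit = cmp$fold_change >= fold_cutoff & ssmd > ssmd_cutoff &
      !cmp$artifact_flag,
    stringsAsFactors = FALSE
  )
}

#' Validation-stage hit confirmation
#'
#' Rescreen replicates (n = 24 per compound on each of 2 plates in the
#' assay) are scored per plate as `ssmd_star(compound replicates, vehicle
#' replicates)`; the per-compound aggregate is the median of the per-plate
#' SSMD* values and a compound validates when it strictly exceeds
#' `ssmd_cutoff`.
#'
#' @param replicates data.frame `plate_id, compound_id, role, value`;
#'   vehicle rows have `role == "vehicle"`. Every compound must appear on
#'   every plate.
#' @param ssmd_cutoff validation threshold (default 0.25, strict).
#' @return data.frame `compound_id, fold_change, ssmd_star, validated` with
#'   one row per compound (`fold_change` is the median across plates of the
#'   per-plate vehicle-normalized median).
#' @export
validate_hits <- function(replicates, ssmd_cutoff = 0.25) {
  plates <- unique(replicates$plate_id)
  if (length(plates) < 1) stop("no validation plates supplied")
  cmp_ids <- unique(replicates$compound_id[replicates$role == "compound"])
  per_plate <- lapply(plates, function(p) {
    d <- replicates[replicates$plate_id == p, , drop = FALSE]
    veh <- d$value[d$role == "vehicle"]
    if (length(veh) < 2)
      stop(plate_invalid_error(paste0("validation plate ", p,
                                      " lacks vehicle controls")))
    sapply(cmp_ids, function(id) {
      x <- d$value[d$role == "compound" & d$compound_id == id]
      if (length(x) == 0)
        stop("compound ", id, " missing from validation plate ", p)
      c(ssmd = as.numeric(ssmd_star(x, veh)),
        fold = median(x) / median(veh))
    })
  })
  ssmd_mat <- do.call(rbind, lapply(per_plate, function(m) m["ssmd", ]))
  fold_mat <- do.call(rbind, lapply(per_plate, function(m) m["fold", ]))
  ssmd <- apply(ssmd_mat, 2, median)
  data.frame(
    compound_id = cmp_ids,
    fold_change = apply(fold_mat, 2, median),
    ssmd_star = ssmd,
    validated = ssmd > ssmd_cutoff,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Viability as percent of vehicle
#'
#' `100 * treated / median(vehicle luminescence)`, the normalization used
#' for ATP-based (CellTiter-Glo) viability readouts.
#'
#' @param treated_luminescence treated-well luminescence (vectorized).
#' @param vehicle_luminescences vehicle-well luminescence values.
#' @return percent viability.
#' @export
viability_percent <- function(treated_luminescence, vehicle_luminescences) {
  ref <- median(vehicle_luminescences)
  if (!is.finite(ref) || ref <= 0) stop("vehicle median must be > 0")
  100 * treated_luminescence / ref
}

#' Summarize a dose-response titration
#'
#' Per-dose median fold change and unscaled MAD, doses sorted ascending;
#' duplicate dose rows are pooled.
#'
#' @param doses_uM dose of each observation (uM).
#' @param fold_changes vehicle-normalized fold change of each observation.
#' @param compound_id optional identifier attached to the result.
#' @return data.frame `compound_id, dose_uM, fold_change, dispersion, n`
#'   with strictly increasing doses.
#' @export
dose_response_summary <- function(doses_uM, fold_changes,
                                  compound_id = NA_character_) {
  stopifnot(length(doses_uM) == length(fold_changes))
  if (length(unique(doses_uM)) < 2)
    stop("dose_response_summary needs >= 2 distinct doses")
  sp <- split(fold_changes, doses_uM)
  d <- as.numeric(names(sp))
  o <- order(d)
  data.frame(
    compound_id = compound_id,
    dose_uM = d[o],
    fold_change = vapply(sp, median, numeric(1))[o],
    dispersion = vapply(sp, mad_unscaled, numeric(1))[o],
    n = vapply(sp, length, integer(1))[o],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
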