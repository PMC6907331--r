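#' Configuration for a simulated reporter screen
#'
#' Defaults encode the screen's study conditions: 384-well plates with 32
#' vehicle and 32 positive-control wells, 320 compound wells, a 1.4-fold
#' positive-control median effect, 10% well-to-well coefficient of
#' variation, and a small planted-enhancer fraction at 1.5-fold.
#'
#' @param seed integer seed; all randomness in [simulate_screen()] flows
#'   from it.
#' @param n_plates number of plates.
#' @param n_vehicle,n_positive,n_compounds wells per role on each plate.
#' @param baseline_intensity vehicle median intensity (arbitrary units).
#' @param well_cv well-to-well coefficient of variation (fraction);
#'   intensities are lognormal with median = baseline x fold and
#'   `sdlog = sqrt(log(1 + cv^2))`.
#' @param positive_effect positive-control median fold effect.
#' @param enhancer_fraction fraction of compounds with a true effect.
#' @param enhancer_effect_range `c(fold_low, fold_high)`; planted enhancer
#'   folds are drawn uniformly from this range.
#' @param artifact_rate fraction of wells whose images would be discarded as
#'   debris/auto-fluorescence artifacts; simulated wells get a spuriously
#'   inflated value and a truth artifact flag.
#' @return a `screen_sim_config` list.
#' @export
screen_sim_config <- function(seed = 1, n_plates = 1,
                              n_vehicle = 32, n_positive = 32,
                              n_compounds = 320,
                              baseline_intensity = 1e5, well_cv = 0.10,
                              positive_effect = 1.4,
                              enhancer_fraction = 0.02,
                              enhancer_effect_range = c(1.5, 1.5),
                              artifact_rate = 0.01) {
  stopifnot(well_cv >= 0, positive_effect > 0,
            enhancer_fraction >= 0, enhancer_fraction <= 1,
            artifact_rate >= 0, artifact_rate <= 1,
            length(enhancer_effect_range) == 2,
            all(enhancer_effect_range > 0),
            baseline_intensity > 0)
  structure(as.list(environment()), class = "screen_sim_config")
}

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

rlnorm_median <- function(n, med, cv) {
  if (cv == 0) return(rep(med, length.out = n))
  med * exp(rnorm(n, 0, cv_to_sdlog(cv)))
}

#' Simulate a multi-plate reporter screen with known ground truth
#'
#' Vehicle wells are lognormal with median `baseline_intensity`; positive
#' controls have median `baseline x positive_effect`; compound wells have
#' median `baseline x planted fold` (1 for non-enhancers). A fraction of
#' wells is marked as imaging artifacts and given inflated values, mimicking
#' debris / auto-fluorescent compounds. Output is bit-reproducible for a
#' fixed config.
#'
#' @param config a [screen_sim_config()].
#' @return list with `plates` (one per-well measurement data.frame per
#'   plate: `plate_id, well, role, compound_id, value, artifact_flag`),
#'   `layouts`, and `truth` (list with per-compound `compounds` table:
#'   `compound_id, true_fold, enhancer`, and per-well `wells` table with
#'   true folds and artifact flags).
#' @export
simulate_screen <- function(config = screen_sim_config()) {
  stopifnot(inherits(config, "screen_sim_config"))
  with_seed(config$seed, {
    plates <- vector("list", config$n_plates)
    layouts <- vector("list", config$n_plates)
    cmp_truth <- vector("list", config$n_plates)
    well_truth <- vector("list", config$n_plates)
    for (p in seq_len(config$n_plates)) {
      pid <- sprintf("plate%02d", p)
      ids <- sprintf("%s_C%03d", pid, seq_len(config$n_compounds))
      layout <- standard_screen_layout(config$n_vehicle, config$n_positive,
                                       ids, plate_id = pid)
      enh <- runif(config$n_compounds) < config$enhancer_fraction
      folds <- ifelse(enh,
                      runif(config$n_compounds,
                            config$enhancer_effect_range[1],
                            config$enhancer_effect_range[2]),
                      1)
      true_fold <- setNames(rep(1, nrow(layout)), layout$well)
      true_fold[layout$well[layout$role == "positive_control"]] <-
        config$positive_effect
      cmp_rows <- layout$role == "compound"
      true_fold[layout$well[cmp_rows]] <- folds[match(
        layout$compound_id[cmp_rows], ids)]
      used <- layout$role != "empty"
      n_used <- sum(used)
      value <- rlnorm_median(n_used,
                             config$baseline_intensity * true_fold[layout$well[used]],
                             config$well_cv)
      artifact <- runif(n_used) < config$artifact_rate
      value[artifact] <- value[artifact] * runif(sum(artifact), 3, 10)
      meas <- data.frame(
        plate_id = pid,
        well = layout$well[used],
        role = layout$role[used],
        compound_id = layout$compound_id[used],
        value = value,
        artifact_flag = artifact,
        stringsAsFactors = FALSE
      )
      plates[[p]] <- meas
      layouts[[p]] <- layout
      cmp_truth[[p]] <- data.frame(compound_id = ids, true_fold = folds,
                                   enhancer = enh, stringsAsFactors = FALSE)
      well_truth[[p]] <- data.frame(plate_id = pid, well = layout$well[used],
                                    true_fold = unname(true_fold[layout$well[used]]),
                                    artifact = artifact,
                                    stringsAsFactors = FALSE)
    }
    list(plates = plates, layouts = layouts,
         truth = list(compounds = do.call(rbind, cmp_truth),
                      wells = do.call(rbind, well_truth)))
  })
}

#' Simulate confirmatory rescreen plates for selected compounds
#'
#' Emulates the validation stage: each compound is re-tested with
#' `n_replicates` wells on each of `n_plates` plates that also carry
#' vehicle-control wells, at the same noise model as the primary screen.
#'
#' @param compounds data.frame with `compound_id` and `true_fold`.
#' @param n_replicates compound replicate wells per plate (24 in the assay).
#' @param n_plates number of rescreen plates (2 in the assay).
#' @param n_vehicle vehicle wells per plate.
#' @param baseline_intensity,well_cv as in [screen_sim_config()].
#' @param seed integer seed.
#' @return data.frame `plate_id, compound_id, role, value` where vehicle
#'   rows have `compound_id = NA`.
#' @export
simulate_validation_plates <- function(compounds, n_replicates = 24,
                                       n_plates = 2, n_vehicle = 32,
                                       baseline_intensity = 1e5,
                                       well_cv = 0.10, seed = 1) {
  stopifnot(all(c("compound_id", "true_fold") %in% names(compounds)))
  with_seed(seed, {
    out <- vector("list", n_plates)
    for (p in seq_len(n_plates)) {
      pid <- sprintf("vplate%02d", p)
      veh <- data.frame(plate_id = pid, compound_id = NA_character_,
                        role = "vehicle",
                        value = rlnorm_median(n_vehicle, baseline_intensity,
                                              well_cv),
                        stringsAsFactors = FALSE)
      cmp <- do.call(rbind, lapply(seq_len(nrow(compounds)), function(i) {
        data.frame(plate_id = pid,
                   compound_id = compounds$compound_id[i],
                   role = "compound",
                   value = rlnorm_median(
                     n_replicates,
                     baseline_intensity * compounds$true_fold[i], well_cv),
                   stringsAsFactors = FALSE)
      }))
      out[[p]] <- rbind(veh, cmp)
    }
    do.call(rbind, out)
  })
}

#' Configuration for synthetic well images
#'
#' Renders elongated capsule-shaped myotube-like objects of specified
#' width, length and intensity over a textured background, with optional
#' ultra-bright debris disks, additive Gaussian noise and 16-bit clipping.
#' Default object widths (12-22 px) sit inside the detection band of the
#' default image pipeline, whose top-hat structuring element bounds the
#' detectable object width from above.
#'
#' @param shape `c(height, width)` in pixels.
#' @param bit_depth image bit depth (clipping at `2^bit_depth - 1`).
#' @param background_level,background_texture_sd background counts and the
#'   standard deviation of its smooth texture.
#' @param n_objects objects per image.
#' @param object_width_px,object_length_px ranges (2-vectors, px).
#' @param object_intensity_above_bg range of object intensity above local
#'   background (counts).
#' @param noise_sd additive Gaussian noise sd (counts).
#' @param debris optional `list(n =, size_px =, intensity =)` of saturating
#'   debris disks (`size_px` is a diameter).
#' @param autofluorescence_offset additive whole-image offset (counts),
#'   emulating an auto-fluorescent compound; 0 for none.
#' @return an `image_sim_config` list.
#' @export
image_sim_config <- function(shape = c(1080, 1080), bit_depth = 16,
                             background_level = 800,
                             background_texture_sd = 0,
                             n_objects = 8,
                             object_width_px = c(12, 22),
                             object_length_px = c(60, 220),
                             object_intensity_above_bg = c(800, 1500),
                             noise_sd = 30,
                             debris = NULL,
                             autofluorescence_offset = 0) {
  stopifnot(length(shape) == 2, all(shape >= 32), noise_sd >= 0,
            background_level >= 0, n_objects >= 0)
  structure(as.list(environment()), class = "image_sim_config")
}

# Render one capsule (segment dilated by a disc) into img; returns a list
# with the updated image and the exact mask.
render_capsule <- function(img, cx, cy, theta, length_px, width_px,
                           intensity) {
  r <- width_px / 2
  hx <- cos(theta) * (length_px / 2 - r)
  hy <- sin(theta) * (length_px / 2 - r)
  pad <- ceiling(r) + 2L
  rmin <- floor(min(cx - hx, cx + hx)) - pad
  rmax <- ceiling(max(cx - hx, cx + hx)) + pad
  cmin <- floor(min(cy - hy, cy + hy)) - pad
  cmax <- ceiling(max(cy - hy, cy + hy)) + pad
  d2 <- segment_dist2(nrow(img), ncol(img), cx - hx, cy - hy, cx + hx, cy + hy,
                      rmin, rmax, cmin, cmax)
  mask <- d2 <= r^2
  img[mask] <- img[mask] + intensity
  list(img = img, mask = mask)
}

#' Simulate one well image with per-object ground truth
#'
#' Objects are placed uniformly at random orientation, fully inside the
#' frame and mutually separated so that ground-truth masks are exact before
#' noise. The truth table classifies every object against `criteria`
#' (default pipeline thresholds), flagging sub-threshold plants.
#'
#' @param config an [image_sim_config()].
#' @param seed integer seed.
#' @param criteria a [pipeline_config()] used to label each planted object
#'   as meeting / violating the detection criteria.
#' @return list with `image` (numeric matrix, counts), `truth` (list:
#'   `objects` data.frame with `id, cx, cy, width_px, length_px, area_px,
#'   intensity_above_bg, integrated_intensity, meets_criteria,
#'   sub_threshold_reason`, `labels` ground-truth label matrix,
#'   `background_level`, `debris_px`).
#' @export
simulate_well_image <- function(config = image_sim_config(), seed = 1,
                                criteria = pipeline_config()) {
  stopifnot(inherits(config, "image_sim_config"))
  with_seed(seed, {
    h <- config$shape[1]; w <- config$shape[2]
    img <- matrix(config$background_level, h, w)
    if (config$background_texture_sd > 0) {
      # smooth texture: coarse Gaussian grid, bilinearly interpolated
      gh <- max(2, ceiling(h / 128)); gw <- max(2, ceiling(w / 128))
      g <- matrix(rnorm(gh * gw, 0, config$background_texture_sd), gh, gw)
      xi <- seq(1, gh, length.out = h); yi <- seq(1, gw, length.out = w)
      x0 <- pmin(floor(xi), gh - 1); y0 <- pmin(floor(yi), gw - 1)
      fx <- xi - x0; fy <- yi - y0
      tex <- (g[cbind(rep(x0, w), rep(y0, each = h))] * (1 - fx) * rep(1 - fy, each = h) +
              g[cbind(rep(x0 + 1, w), rep(y0, each = h))] * fx * rep(1 - fy, each = h) +
              g[cbind(rep(x0, w), rep(y0 + 1, each = h))] * (1 - fx) * rep(fy, each = h) +
              g[cbind(rep(x0 + 1, w), rep(y0 + 1, each = h))] * fx * rep(fy, each = h))
      img <- img + matrix(tex, h, w)
    }
    labels <- matrix(0L, h, w)
    objs <- NULL
    occupied <- matrix(FALSE, h, w)
    min_sep <- 2 * se_radius(criteria) + 6
    n_placed <- 0
    tries <- 0
    while (n_placed < config$n_objects && tries < 200 * config$n_objects) {
      tries <- tries + 1
      wid <- runif(1, config$object_width_px[1], config$object_width_px[2])
      len <- runif(1, max(config$object_length_px[1], wid + 2),
                   config$object_length_px[2])
      theta <- runif(1, 0, pi)
      margin <- len / 2 + min_sep
      if (2 * margin >= min(h, w)) next
      cx <- runif(1, margin, h - margin)
      cy <- runif(1, margin, w - margin)
      inten <- runif(1, config$object_intensity_above_bg[1],
                     config$object_intensity_above_bg[2])
      # separation check on a dilated bounding box
      r <- len / 2 + min_sep / 2
      rr <- max(1, floor(cx - r)):min(h, ceiling(cx + r))
      cc <- max(1, floor(cy - r)):min(w, ceiling(cy + r))
      if (any(occupied[rr, cc])) next
      res <- render_capsule(img, cx, cy, theta, len, wid, inten)
      img <- res$img
      n_placed <- n_placed + 1
      labels[res$mask] <- n_placed
      occupied[rr, cc] <- TRUE
      area <- sum(res$mask)
      meets <- wid >= criteria$min_width_px && wid <= criteria$max_width_px &&
        inten >= criteria$intensity_above_background &&
        area >= criteria$min_area_px
      reason <- if (meets) NA_character_ else paste(
        c(if (wid < criteria$min_width_px) "width_below_min",
          if (wid > criteria$max_width_px) "width_above_max",
          if (inten < criteria$intensity_above_background) "intensity_below_min",
          if (area < criteria$min_area_px) "area_below_min"),
        collapse = ";")
      objs <- rbind(objs, data.frame(
        id = n_placed, cx = cx, cy = cy, width_px = wid, length_px = len,
        area_px = area, intensity_above_bg = inten,
        integrated_intensity = inten * area,
        meets_criteria = meets, sub_threshold_reason = reason,
        stringsAsFactors = FALSE))
    }
    debris_px <- 0L
    if (!is.null(config$debris) && config$debris$n > 0) {
      for (k in seq_len(config$debris$n)) {
        dcx <- runif(1, 10, h - 10); dcy <- runif(1, 10, w - 10)
        res <- render_capsule(img, dcx, dcy, 0, config$debris$size_px,
                              config$debris$size_px, 0)
        img <- res$img
        img[res$mask] <- config$debris$intensity
        debris_px <- debris_px + sum(res$mask)
      }
    }
    img <- img + config$autofluorescence_offset
    if (config$noise_sd > 0) img <- img + rnorm(h * w, 0, config$noise_sd)
    img <- pmin(pmax(round(img), 0), 2^config$bit_depth - 1)
    list(image = img,
         truth = list(objects = objs, labels = labels,
                      background_level = config$background_level,
                      debris_px = debris_px))
  })
}

#' Simulate a replicate Ct table with planted fold changes
#'
#' Ct values are drawn so that the ddCT estimator `2^(-ddCt)` recovers the
#' planted folds in expectation: each target gene's Ct in the treated sample
#' sits `log2(fold)` cycles below its calibrator Ct, the reference gene is
#' constant across samples, and iid Gaussian noise of sd `ct_sd` is added to
#' every replicate.
#'
#' @param true_folds named numeric vector, gene -> fold (relative to the
#'   calibrator sample); must be positive.
#' @param reference_gene reference (housekeeping) gene name; fold fixed at 1.
#' @param n_replicates technical replicates per (sample, gene).
#' @param ct_sd replicate noise sd (cycles).
#' @param seed integer seed.
#' @param sample_id,calibrator_id sample names for the treated and
#'   calibrator (vehicle) samples.
#' @param base_ct,ref_ct calibrator-sample target Ct and reference-gene Ct.
#' @return a `ct_table` data.frame: `sample_id, gene, replicate, ct`.
#' @export
simulate_ct_table <- function(true_folds, reference_gene = "ACTB",
                              n_replicates = 3, ct_sd = 0.1, seed = 1,
                              sample_id = "treated",
                              calibrator_id = "vehicle",
                              base_ct = 25, ref_ct = 18) {
  stopifnot(all(true_folds > 0), is.numeric(ct_sd), ct_sd >= 0)
  genes <- names(true_folds)
  if (is.null(genes)) stop("true_folds must be a named vector (gene -> fold)")
  with_seed(seed, {
    rows <- list()
    add <- function(s, g, mu) {
      data.frame(sample_id = s, gene = g, replicate = seq_len(n_replicates),
                 ct = mu + rnorm(n_replicates, 0, ct_sd),
                 stringsAsFactors = FALSE)
    }
    for (g in genes) {
      rows[[length(rows) + 1]] <- add(calibrator_id, g, base_ct)
      rows[[length(rows) + 1]] <- add(sample_id, g, base_ct - log2(true_folds[[g]]))
    }
    rows[[length(rows) + 1]] <- add(calibrator_id, reference_gene, ref_ct)
    rows[[length(rows) + 1]] <- add(sample_id, reference_gene, ref_ct)
    structure(do.call(rbind, rows), class = c("ct_table", "data.frame"))
  })
}

#' Simulate two-channel fusion-index mask images with known ground truth
#'
#' Builds a myosin-heavy-chain (MHC) positive region covering roughly the
#' left part of the field and places non-overlapping nucleus disks so that
#' exactly `round(n_nuclei * fused_fraction)` nucleus centroids fall inside
#' the MHC mask; the rest are placed clear of it.
#'
#' @param n_nuclei total nuclei.
#' @param fused_fraction fraction of nuclei inside the MHC-positive region.
#' @param seed integer seed.
#' @param shape image `c(height, width)` (px).
#' @param nucleus_radius_px nucleus disk radius (px).
#' @return list `nuclei_mask`, `mhc_mask` (logical matrices), `truth`
#'   (data.frame `cx, cy, fused`).
#' @export
simulate_fusion_images <- function(n_nuclei = 200, fused_fraction = 0.3,
                                   seed = 1, shape = c(512, 512),
                                   nucleus_radius_px = 4) {
  stopifnot(fused_fraction >= 0, fused_fraction <= 1, n_nuclei >= 1)
  with_seed(seed, {
    h <- shape[1]; w <- shape[2]
    split_col <- floor(w / 2)
    mhc <- matrix(FALSE, h, w)
    mhc[, seq_len(split_col)] <- TRUE
    n_fused <- round(n_nuclei * fused_fraction)
    r <- nucleus_radius_px
    nuc <- matrix(FALSE, h, w)
    centers <- matrix(NA_real_, 0, 2)
    place <- function(inside) {
      repeat {
        cx <- runif(1, r + 2, h - r - 2)
        cy <- if (inside) runif(1, r + 2, split_col - r - 2)
              else runif(1, split_col + r + 3, w - r - 2)
        if (nrow(centers) == 0 ||
            all((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 >
                (2 * r + 3)^2))
          return(c(cx, cy))
      }
    }
    for (i in seq_len(n_nuclei)) {
      ctr <- place(i <= n_fused)
      centers <- rbind(centers, ctr)
      d2 <- segment_dist2(h, w, ctr[1], ctr[2], ctr[1], ctr[2],
                          floor(ctr[1]) - r - 2, ceiling(ctr[1]) + r + 2,
                          floor(ctr[2]) - r - 2, ceiling(ctr[2]) + r + 2)
      nuc[d2 <= r^2] <- TRUE
    }
    truth <- data.frame(cx = centers[, 1], cy = centers[, 2],
                        fused = seq_len(n_nuclei) <= n_fused)
    list(nuclei_mask = nuc, mhc_mask = mhc, truth = truth)
  })
}
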