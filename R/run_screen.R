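#' End-to-end screen run configuration
#'
#' Bundles the simulation (or input) settings and the decision thresholds
#' of the assay: fold cutoff 1.4 (inclusive), hit SSMD* cutoff 0.25
#' (strict), plate-QC SSMD* cutoff 1 (inclusive).
#'
#' @param sim a [screen_sim_config()] (simulation mode), or `NULL` when
#'   supplying measurement tables directly to [run_screen()].
#' @param fold_cutoff,ssmd_hit_cutoff,ssmd_qc_cutoff decision thresholds.
#' @param validation_replicates,validation_plates,validation_vehicle
#'   rescreen geometry (24 replicates x 2 plates in the assay).
#' @param out_dir optional directory for result CSVs.
#' @param seed top-level seed; all randomness derives from it.
#' @return a `run_config` list.
#' @export
run_config <- function(sim = screen_sim_config(), fold_cutoff = 1.4,
                       ssmd_hit_cutoff = 0.25, ssmd_qc_cutoff = 1,
                       validation_replicates = 24, validation_plates = 2,
                       validation_vehicle = 32,
                       out_dir = NULL, seed = 1) {
  stopifnot(fold_cutoff > 0, ssmd_hit_cutoff > 0, ssmd_qc_cutoff > 0)
  structure(as.list(environment()), class = "run_config")
}

#' Run a screen end to end
#'
#' Simulation mode: generates the plates from `config$sim` (re-seeded from
#' the top-level seed), then per plate normalizes to the vehicle median and
#' computes QC; compounds on QC-passing plates are scored with the primary
#' hit rule; primary hits are rescreened on simulated validation plates
#' (using the compounds' true planted folds) and confirmed with the
#' replicate SSMD* rule. Plates with fewer than 2 usable vehicle or
#' positive wells are excluded with a warning, not an error. Measurement
#' tables can also be supplied directly via `plates`, skipping simulation
#' (no validation stage is simulated for user data unless
#' `validation_replicates_table` is given).
#'
#' @param config a [run_config()].
#' @param plates optional list of per-well measurement data.frames
#'   (`plate_id, well, role, compound_id, value, artifact_flag`), replacing
#'   simulation.
#' @param validation_replicates_table optional replicate table for
#'   [validate_hits()] when `plates` is supplied.
#' @return a `screen_result` list: `per_well` (normalized measurements),
#'   `plate_qc`, `hits_primary`, `hits_validated`, `excluded_plates`,
#'   `truth` (simulation mode only), `thresholds`, `summary`.
#' @export
run_screen <- function(config = run_config(), plates = NULL,
                       validation_replicates_table = NULL) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (is.null(plates)) {
    sim <- config$sim
    sim$seed <- derive_seed(config$seed, 1)
    gen <- simulate_screen(sim)
    plates <- gen$plates
    truth <- gen$truth
  }
  qc_rows <- list(); norm <- list(); excluded <- character(0)
  for (p in seq_along(plates)) {
    meas <- plates[[p]]
    pid <- meas$plate_id[1]
    res <- tryCatch({
      m <- normalize_plate(meas)
      qc <- plate_qc(m, config$ssmd_qc_cutoff)
      list(m = m, qc = qc)
    }, plate_invalid_error = function(e) e)
    if (inherits(res, "plate_invalid_error")) {
      warning("plate ", pid, " excluded: ", conditionMessage(res),
              call. = FALSE)
      excluded <- c(excluded, pid)
      next
    }
    norm[[length(norm) + 1]] <- res$m
    qc_rows[[length(qc_rows) + 1]] <- data.frame(
      plate_id = pid, ssmd_star = res$qc$ssmd_star,
      qc_pass = res$qc$qc_pass, stringsAsFactors = FALSE)
  }
  if (length(norm) == 0) stop("no analyzable plates")
  qc_tab <- do.call(rbind, qc_rows)
  per_well <- do.call(rbind, norm)

  hits <- do.call(rbind, lapply(norm, function(m) {
    if (!qc_tab$qc_pass[qc_tab$plate_id == m$plate_id[1]]) return(NULL)
    call_hits_primary(m, config$fold_cutoff, config$ssmd_hit_cutoff)
  }))
  primary_ids <- if (is.null(hits)) character(0) else hits$compound_id[hits$hit]

  validated <- NULL
  if (length(primary_ids) > 0) {
    if (!is.null(validation_replicates_table)) {
      validated <- validate_hits(validation_replicates_table,
                                 config$ssmd_hit_cutoff)
    } else if (!is.null(truth)) {
      cmp <- truth$compounds[truth$compounds$compound_id %in% primary_ids, ]
      reps <- simulate_validation_plates(
        cmp, n_replicates = config$validation_replicates,
        n_plates = config$validation_plates,
        n_vehicle = config$validation_vehicle,
        baseline_intensity = config$sim$baseline_intensity,
        well_cv = config$sim$well_cv,
        seed = derive_seed(config$seed, 2))
      validated <- validate_hits(reps, config$ssmd_hit_cutoff)
    }
  }

  thresholds <- data.frame(fold_cutoff = config$fold_cutoff,
                           ssmd_hit_cutoff = config$ssmd_hit_cutoff,
                           ssmd_qc_cutoff = config$ssmd_qc_cutoff)
  n_cmp <- if (is.null(hits)) 0L else nrow(hits)
  summary <- list(
    n_plates = length(plates), n_plates_analyzed = nrow(qc_tab),
    n_plates_qc_pass = sum(qc_tab$qc_pass),
    n_compounds_scored = n_cmp,
    n_primary_hits = length(primary_ids),
    primary_hit_rate = if (n_cmp > 0) length(primary_ids) / n_cmp else NA_real_,
    n_validated = if (is.null(validated)) 0L else sum(validated$validated))

  out <- list(per_well = per_well, plate_qc = qc_tab, hits_primary = hits,
              hits_validated = validated, excluded_plates = excluded,
              truth = truth, thresholds = thresholds, summary = summary)
  class(out) <- "screen_result"
  if (!is.null(config$out_dir)) write_screen_result(out, config$out_dir)
  out
}

#' Write screen result CSVs
#'
#' Emits `plate_qc.csv`, `hits_primary.csv` and `hits_validated.csv`
#' (fold values are relative units, R.U., normalized to vehicle); each
#' file carries the threshold values used, so the tables are
#' self-describing.
#'
#' @param result a `screen_result`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_screen_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  add_thr <- function(df) {
    if (is.null(df)) df <- data.frame()
    if (nrow(df) == 0) return(df)
    cbind(df, result$thresholds[rep(1, nrow(df)), , drop = FALSE])
  }
  write.csv(add_thr(result$plate_qc), file.path(out_dir, "plate_qc.csv"),
            row.names = FALSE)
  write.csv(add_thr(result$hits_primary),
            file.path(out_dir, "hits_primary.csv"), row.names = FALSE)
  write.csv(add_thr(result$hits_validated),
            file.path(out_dir, "hits_validated.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.screen_result <- function(x, ...) {
  s <- x$summary
  cat("High-content screen result\n")
  cat(sprintf("  plates: %d analyzed (%d passed QC) of %d\n",
              s$n_plates_analyzed, s$n_plates_qc_pass, s$n_plates))
  cat(sprintf("  compounds scored: %d\n", s$n_compounds_scored))
  cat(sprintf("  primary hits: %d (rate %.3f%%)\n", s$n_primary_hits,
              100 * (s$primary_hit_rate %||% NA_real_)))
  cat(sprintf("  validated hits: %d\n", s$n_validated))
  invisible(x)
}

#' Compare screen calls against simulation ground truth
#'
#' Sensitivity is the fraction of planted enhancer compounds (on analyzed,
#' QC-passing plates) that pass both the primary and the validation stage;
#' the null end-to-end rate is the corresponding fraction among
#' non-enhancer compounds.
#'
#' @param result a `screen_result` from a simulated [run_screen()].
#' @return list `sensitivity, null_end_to_end_rate, primary_hit_rate,
#'   n_enhancers, n_null`.
#' @export
screen_performance <- function(result) {
  if (is.null(result$truth)) stop("result has no simulation ground truth")
  scored <- result$hits_primary
  tr <- result$truth$compounds
  tr <- tr[tr$compound_id %in% scored$compound_id, ]
  val_ids <- if (is.null(result$hits_validated)) character(0)
             else result$hits_validated$compound_id[result$hits_validated$validated]
  confirmed <- tr$compound_id %in% val_ids
  list(
    sensitivity = if (any(tr$enhancer)) mean(confirmed[tr$enhancer]) else NA_real_,
    null_end_to_end_rate = if (any(!tr$enhancer)) mean(confirmed[!tr$enhancer])
                           else NA_real_,
    primary_hit_rate = result$summary$primary_hit_rate,
    n_enhancers = sum(tr$enhancer), n_null = sum(!tr$enhancer))
}
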