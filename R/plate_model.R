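#' Well coordinate names for a microplate
#'
#' @param n_rows,n_cols plate dimensions (16 x 24 for 384-well).
#' @return character vector of coordinates `"A01"..."P24"` in row-major order.
#' @export
well_names <- function(n_rows = 16, n_cols = 24) {
  as.vector(t(outer(LETTERS[seq_len(n_rows)],
                    sprintf("%02d", seq_len(n_cols)), paste0)))
}

#' A single liquid-handling step
#'
#' Steps model the screen's dispense/aspirate protocol. `seed` and `add`
#' dispense `volume_ul` of liquid, optionally carrying solutes;
#' `aspirate_to_residual` removes liquid down to a residual volume of
#' `volume_ul`, removing solutes in proportion to the volume removed
#' (perfect-mixing assumption).
#'
#' @param action one of `"seed"`, `"add"`, `"aspirate_to_residual"`.
#' @param volume_ul dispensed volume, or residual volume for aspiration (ul).
#' @param solute optional character vector of solute names carried by the
#'   added liquid (e.g. a compound id, `"DMSO"`).
#' @param solute_conc concentrations parallel to `solute`, in the solute's
#'   native unit (uM for compounds, percent v/v for DMSO).
#' @return a `pipetting_step` object.
#' @export
pipetting_step <- function(action = c("seed", "add", "aspirate_to_residual"),
                           volume_ul, solute = NULL, solute_conc = NULL) {
  action <- match.arg(action)
  stopifnot(is.numeric(volume_ul), length(volume_ul) == 1, volume_ul >= 0)
  if (length(solute) != length(solute_conc))
    stop("solute and solute_conc must have equal length")
  if (any(solute_conc < 0)) stop("solute concentrations must be >= 0")
  structure(list(action = action, volume_ul = volume_ul,
                 solute = as.character(solute),
                 solute_conc = as.numeric(solute_conc)),
            class = "pipetting_step")
}

#' Apply an ordered sequence of pipetting steps to one well
#'
#' Tracks the well volume and absolute solute amounts (concentration x
#' volume, in each solute's native unit times ul). Aspiration removes each
#' solute proportionally to the volume removed, i.e. the well is assumed
#' perfectly mixed. Final concentrations are amount / final volume, so the
#' screen protocol (seed 50, aspirate to 10, add 30, add 0.5 ul of 1000 uM
#' compound in 100% DMSO, add 50) yields 5.5 uM compound in 0.55% DMSO.
#'
#' @param steps list of [pipetting_step()] objects; must start with a
#'   `seed`/`add` establishing positive volume.
#' @return a `well_state` list with `volume_ul`, `amounts` (named numeric)
#'   and `concentrations` (named numeric, native units).
#' @export
apply_pipetting <- function(steps) {
  if (length(steps) == 0) stop("no steps supplied")
  if (inherits(steps, "pipetting_step")) steps <- list(steps)
  volume <- 0
  amounts <- numeric(0)
  first <- TRUE
  for (s in steps) {
    if (!inherits(s, "pipetting_step")) stop("steps must be pipetting_step objects")
    if (first) {
      if (!s$action %in% c("seed", "add") || s$volume_ul <= 0)
        stop("invalid protocol: steps must begin with a seed/add of positive volume")
      first <- FALSE
    }
    if (s$action %in% c("seed", "add")) {
      volume <- volume + s$volume_ul
      for (i in seq_along(s$solute)) {
        nm <- s$solute[i]
        amounts[nm] <- (if (nm %in% names(amounts)) amounts[[nm]] else 0) +
          s$solute_conc[i] * s$volume_ul
      }
    } else {  # aspirate_to_residual
      if (s$volume_ul > volume)
        stop("invalid protocol: residual volume exceeds current well volume")
      frac <- if (volume > 0) s$volume_ul / volume else 0
      amounts <- amounts * frac
      volume <- s$volume_ul
    }
  }
  conc <- if (volume > 0) amounts / volume else amounts * NA_real_
  structure(list(volume_ul = volume, amounts = amounts,
                 concentrations = conc),
            class = "well_state")
}

#' The screen's treatment protocol as a pipetting sequence
#'
#' Convenience constructor for the per-well treatment used in the screen:
#' seed 50 ul, aspirate to a 10 ul residual, add 30 ul media, add
#' `compound_volume_ul` of compound stock in DMSO, then add 50 ul media.
#'
#' @param stock_conc_uM compound stock concentration (uM).
#' @param compound_volume_ul stock volume dispensed (ul).
#' @param dmso_pct DMSO content of the stock (percent v/v).
#' @return list of [pipetting_step()]s suitable for [apply_pipetting()].
#' @export
screen_treatment_steps <- function(stock_conc_uM = 1000,
                                   compound_volume_ul = 0.5,
                                   dmso_pct = 100) {
  list(
    pipetting_step("seed", 50),
    pipetting_step("aspirate_to_residual", 10),
    pipetting_step("add", 30),
    pipetting_step("add", compound_volume_ul,
                   solute = c("compound", "DMSO"),
                   solute_conc = c(stock_conc_uM, dmso_pct)),
    pipetting_step("add", 50)
  )
}

#' Deterministic 384-well screening layout
#'
#' Controls occupy fixed columns adjacent to (but not on) the plate edge:
#' vehicle wells fill columns 2, 3, ... top-to-bottom and positive controls
#' fill columns 23, 22, ... top-to-bottom; compound wells fill the remaining
#' wells row-major. The published screen does not state its plate map, so
#' this layout is a reproducible default.
#'
#' @param n_vehicle,n_positive numbers of vehicle / positive-control wells
#'   (each >= 2 for an analyzable plate).
#' @param compounds character vector of compound ids (one well each).
#' @param dose_uM dose assigned to every compound well (uM).
#' @param plate_id plate identifier.
#' @param n_rows,n_cols plate dimensions.
#' @return a `plate_layout` data.frame with columns
#'   `well`, `role`, `compound_id`, `dose_uM` and attributes
#'   `plate_id`, `n_rows`, `n_cols`.
#' @export
standard_screen_layout <- function(n_vehicle = 32, n_positive = 32,
                                   compounds = character(), dose_uM = 5.5,
                                   plate_id = "plate1",
                                   n_rows = 16, n_cols = 24) {
  stopifnot(n_vehicle >= 2, n_positive >= 2)
  n_total <- n_rows * n_cols
  n_cmp <- length(compounds)
  if (n_vehicle + n_positive + n_cmp > n_total)
    stop("capacity error: layout requires more than ", n_total, " wells")
  wells <- well_names(n_rows, n_cols)
  col_of <- rep(seq_len(n_cols), times = n_rows)
  row_of <- rep(seq_len(n_rows), each = n_cols)

  pick_cols <- function(n, cols) {
    out <- character(0)
    for (cc in cols) {
      if (length(out) >= n) break
      cand <- wells[col_of == cc][order(row_of[col_of == cc])]
      out <- c(out, cand[seq_len(min(n_rows, n - length(out)))])
    }
    if (length(out) < n) stop("capacity error: not enough control columns")
    out
  }
  veh <- pick_cols(n_vehicle, seq(2, n_cols - 1))
  pos <- pick_cols(n_positive, seq(n_cols - 1, 2))
  if (any(pos %in% veh)) stop("capacity error: control columns overlap")

  role <- rep("empty", n_total)
  names(role) <- wells
  role[veh] <- "vehicle"
  role[pos] <- "positive_control"
  free <- wells[role[wells] == "empty"]
  cmp_wells <- free[seq_len(n_cmp)]
  role[cmp_wells] <- "compound"

  layout <- data.frame(
    well = wells,
    role = unname(role[wells]),
    compound_id = NA_character_,
    dose_uM = NA_real_,
    stringsAsFactors = FALSE
  )
  layout$compound_id[match(cmp_wells, layout$well)] <- compounds
  layout$dose_uM[match(cmp_wells, layout$well)] <- dose_uM
  structure(layout, plate_id = plate_id, n_rows = n_rows, n_cols = n_cols,
            class = c("plate_layout", "data.frame"))
}

#' Validate a plate layout
#'
#' Checks the layout invariants: unique in-grid coordinates, at least two
#' vehicle and two positive-control wells, and compound wells carrying both
#' a compound id and a dose.
#'
#' @param layout a `plate_layout` (or compatible data.frame).
#' @return the layout, invisibly; errors on violation.
#' @export
validate_plate_layout <- function(layout) {
  n_rows <- attr(layout, "n_rows") %||% 16
  n_cols <- attr(layout, "n_cols") %||% 24
  valid <- well_names(n_rows, n_cols)
  if (anyDuplicated(layout$well)) stop("duplicate well coordinates")
  if (!all(layout$well %in% valid)) stop("well coordinates outside the grid")
  if (sum(layout$role == "vehicle") < 2 ||
      sum(layout$role == "positive_control") < 2)
    stop("analyzable plates need >= 2 vehicle and >= 2 positive-control wells")
  cmp <- layout$role == "compound"
  if (any(cmp & (is.na(layout$compound_id) | is.na(layout$dose_uM))))
    stop("compound wells must carry a compound_id and dose")
  invisible(layout)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write plate maps as CSV
#'
#' Plate maps use columns `well,role,compound_id,dose_uM` with well
#' coordinates in letter + zero-padded-number form (`"A01"`..`"P24"`).
#'
#' @param path CSV file path.
#' @param layout a `plate_layout`.
#' @param plate_id plate identifier to attach on read.
#' @return `read_plate_map` returns a validated `plate_layout`.
#' @export
read_plate_map <- function(path, plate_id = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "role", "compound_id", "dose_uM")
  if (!all(need %in% names(df)))
    stop("plate map must have columns ", paste(need, collapse = ","))
  df$compound_id <- as.character(df$compound_id)
  df$compound_id[df$compound_id %in% c("", "NA")] <- NA_character_
  df$dose_uM <- as.numeric(df$dose_uM)
  out <- structure(df[need], plate_id = plate_id %||% "plate1",
                   n_rows = 16, n_cols = 24,
                   class = c("plate_layout", "data.frame"))
  validate_plate_layout(out)
  out
}

#' @rdname read_plate_map
#' @export
write_plate_map <- function(layout, path) {
  write.csv(as.data.frame(layout)[c("well", "role", "compound_id", "dose_uM")],
            path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
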