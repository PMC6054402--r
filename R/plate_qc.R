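# Plate-level normalization and quality control: control-well CV,
# signal-over-noise, and the directionality-of-response filter.

#' Quality-control thresholds for screening plates and curves
#'
#' All three comparisons are strict: a plate passes with control CV
#' strictly below `max_control_cv` and signal-over-noise strictly above
#' `min_signal_over_noise`; a curve is rejected when its low-dose /
#' high-dose viability ratio is strictly below
#' `min_directionality_ratio`.
#'
#' @param max_control_cv Maximum control-well coefficient of variation
#'   (default 0.20, i.e. 20%).
#' @param min_signal_over_noise Minimum ratio of mean control signal to
#'   mean blank signal (default 5).
#' @param min_directionality_ratio Minimum ratio of mean viability at
#'   the two lowest doses to mean viability at the two highest doses
#'   (default 1.2).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_control_cv = 0.20, min_signal_over_noise = 5,
                          min_directionality_ratio = 1.2) {
  stopifnot(max_control_cv > 0, min_signal_over_noise > 0,
            min_directionality_ratio > 0)
  structure(list(max_control_cv = max_control_cv,
                 min_signal_over_noise = min_signal_over_noise,
                 min_directionality_ratio = min_directionality_ratio),
            class = "qc_thresholds")
}

#' Normalize raw fluorescence to viability on one plate
#'
#' Viability is blank-subtracted and control-anchored:
#' `(raw - mean(blank)) / (mean(control) - mean(blank))`, so the mean of
#' the untreated control wells maps to exactly 1 and the mean blank to 0.
#' No clamping: negative values are preserved.
#'
#' @param wells Well table for a single plate with columns `role`,
#'   `raw_signal` (and the usual identifiers).
#' @return The treated rows with an added `viability` column.
#' @export
normalize_plate <- function(wells) {
  ctrl <- wells$raw_signal[wells$role == "control"]
  blk <- wells$raw_signal[wells$role == "blank"]
  if (length(ctrl) < 2 || length(blk) < 2) {
    stop("plate needs >= 2 control and >= 2 blank wells", call. = FALSE)
  }
  cm <- mean(ctrl)
  bm <- mean(blk)
  if (cm <= bm) {
    stop(sprintf("plate %s rejected: degenerate dynamic range (control mean %.3g <= blank mean %.3g)",
                 wells$plate_id[1], cm, bm), call. = FALSE)
  }
  out <- wells[wells$role == "treated", , drop = FALSE]
  out$viability <- (out$raw_signal - bm) / (cm - bm)
  rownames(out) <- NULL
  out
}

#' Compute the plate-level QC report
#'
#' Control CV uses the sample (n-1) standard deviation; signal over
#' noise is mean(control) / mean(blank). Pass flags use strict
#' inequalities against the thresholds.
#'
#' @param wells Well table for a single plate.
#' @param thresholds A [qc_thresholds()].
#' @return One-row data.frame: `plate_id`, `control_cv`,
#'   `signal_over_noise`, `pass_cv`, `pass_sn`, `pass`.
#' @export
qc_plate <- function(wells, thresholds = qc_thresholds()) {
  ctrl <- wells$raw_signal[wells$role == "control"]
  blk <- wells$raw_signal[wells$role == "blank"]
  if (length(ctrl) < 2 || length(blk) < 1) {
    stop("plate needs >= 2 control and >= 1 blank wells", call. = FALSE)
  }
  cm <- mean(ctrl)
  if (cm == 0) stop("control mean signal is zero", call. = FALSE)
  cv <- stats::sd(ctrl) / cm
  sn <- cm / mean(blk)
  pass_cv <- cv < thresholds$max_control_cv
  pass_sn <- sn > thresholds$min_signal_over_noise
  data.frame(plate_id = wells$plate_id[1], control_cv = cv,
             signal_over_noise = sn, pass_cv = pass_cv, pass_sn = pass_sn,
             pass = pass_cv && pass_sn, stringsAsFactors = FALSE)
}

#' Directionality-of-response check for one viability curve
#'
#' Compares the mean viability at the two lowest doses against the mean
#' at the two highest doses and fails the curve when the ratio is
#' strictly below the threshold (wrong, or absent, direction of
#' response). Replicate wells at the same dose are averaged first.
#'
#' @param doses Dose vector (may contain replicate doses).
#' @param viabilities Matching viability values.
#' @param thresholds A [qc_thresholds()].
#' @return A list with `ratio`, `pass`, and `degenerate` (TRUE when the
#'   high-dose mean is <= 0, in which case the curve fails).
#' @export
directionality_check <- function(doses, viabilities,
                                 thresholds = qc_thresholds()) {
  stopifnot(length(doses) == length(viabilities))
  m <- tapply(viabilities, doses, mean)
  d <- as.numeric(names(m))
  if (length(d) < 4) stop("need >= 4 distinct doses", call. = FALSE)
  o <- order(d)
  m <- as.numeric(m)[o]
  low <- mean(m[1:2])
  high <- mean(m[(length(m) - 1):length(m)])
  if (high <= 0) {
    return(list(ratio = NA_real_, pass = FALSE, degenerate = TRUE))
  }
  ratio <- low / high
  list(ratio = ratio, pass = ratio >= thresholds$min_directionality_ratio,
       degenerate = FALSE)
}

#' Normalize a whole screen and assign per-curve QC status
#'
#' Runs [qc_plate()] and [normalize_plate()] on every plate, averages
#' replicate wells per (cell line, dose), and applies
#' [directionality_check()] to each curve. Curves that fail any filter
#' are retained with a `qc_status` of `fail_cv`, `fail_sn` or
#' `fail_directionality` (in that precedence) so rejection counts stay
#' auditable; passing curves get `pass`.
#'
#' @param wells Full well table (all plates).
#' @param thresholds A [qc_thresholds()].
#' @return A list with `curves` (cell_line_id, plate_id, dose_um,
#'   viability, qc_status; ascending dose within line) and `plate_qc`
#'   (one row per plate).
#' @export
normalize_screen <- function(wells, thresholds = qc_thresholds()) {
  by_plate <- split(wells, wells$plate_id)
  reports <- do.call(rbind, lapply(by_plate, qc_plate, thresholds = thresholds))
  rownames(reports) <- NULL
  norm <- do.call(rbind, lapply(by_plate, normalize_plate))

  agg <- stats::aggregate(viability ~ cell_line_id + plate_id + dose_um,
                          data = norm, FUN = mean)
  agg <- agg[order(agg$cell_line_id, agg$dose_um), , drop = FALSE]

  plate_status <- stats::setNames(
    ifelse(!reports$pass_cv, "fail_cv",
           ifelse(!reports$pass_sn, "fail_sn", "pass")),
    reports$plate_id
  )
  status <- vapply(split(agg, agg$cell_line_id), function(cur) {
    ps <- plate_status[[cur$plate_id[1]]]
    if (ps != "pass") return(ps)
    dc <- directionality_check(cur$dose_um, cur$viability, thresholds)
    if (!dc$pass) "fail_directionality" else "pass"
  }, character(1))
  agg$qc_status <- status[agg$cell_line_id]
  rownames(agg) <- NULL
  list(curves = agg[, c("cell_line_id", "plate_id", "dose_um", "viability",
                        "qc_status")],
       plate_qc = reports)
}
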