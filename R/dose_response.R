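# Bounded four-parameter logistic dose-response fitting and the derived
# response metrics IC50 (absolute), AUC (over log-dose) and Emax.

dose_means <- function(doses, viabilities) {
  m <- tapply(viabilities, doses, mean)
  d <- as.numeric(names(m))
  o <- order(d)
  list(dose = d[o], viability = as.numeric(m)[o])
}

#' Area under the dose-response curve
#'
#' Trapezoidal mean of the observed viabilities over log2(dose),
#' normalized by the log-dose span, so a flat no-effect curve scores
#' exactly 1 and lower values mean more sensitivity. The metric uses
#' observed points, not the fitted curve, and is invariant to the dose
#' unit. Replicate wells at the same dose are averaged first.
#'
#' @param doses Dose vector (> 0; may contain replicates).
#' @param viabilities Matching viability values.
#' @return AUC as a unitless fraction.
#' @export
compute_auc <- function(doses, viabilities) {
  dm <- dose_means(doses, viabilities)
  if (length(dm$dose) < 2) {
    stop("AUC needs at least 2 distinct doses", call. = FALSE)
  }
  x <- log2(dm$dose)
  v <- dm$viability
  area <- sum(diff(x) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  area / (max(x) - min(x))
}

#' Maximum observed effect (Emax)
#'
#' The minimum of the replicate-mean viabilities at the two highest
#' tested doses.
#'
#' @inheritParams compute_auc
#' @return Emax as a viability fraction (lower = stronger effect).
#' @export
compute_emax <- function(doses, viabilities) {
  dm <- dose_means(doses, viabilities)
  k <- length(dm$dose)
  if (k < 2) stop("Emax needs at least 2 distinct doses", call. = FALSE)
  min(dm$viability[(k - 1):k])
}

fourpl_rss <- function(par, d, v) {
  # par = (bottom, span, hill, log10 ic50_fit); top = bottom + span
  pred <- par[1] + par[2] / (1 + (d / 10^par[4])^par[3])
  sum((v - pred)^2) + 1e3 * max(0, par[1] + par[2] - 1.2)^2
}

#' Fit a bounded four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `v(d) = bottom + (top - bottom) / (1 + (d / ic50_fit)^hill)` with
#' bounds `0 <= bottom <= top <= 1.2` and `hill` in \[0.1, 10\], using
#' L-BFGS-B from three starts (`hill` in 0.5/1/2, midpoint at the
#' geometric median dose); ties are broken by lowest residual sum of
#' squares, then lowest Hill slope. The reported `ic50_um` is the
#' absolute IC50: the dose at which the fitted curve crosses viability
#' 0.5, searched on `[d_min/10, 10 * d_max]`. Curves that never reach
#' 0.5 in that window are censored at `10 * d_max` (resistant) or at
#' `d_min / 10` (already below 0.5 at the lowest searched dose), with
#' `ic50_censored = TRUE`. AUC and Emax are always computed from the raw
#' points, so they survive fit failures.
#'
#' @inheritParams compute_auc
#' @return A list of class `dose_response_fit`: `top`, `bottom`, `hill`,
#'   `ic50_fit`, `ic50_um`, `ic50_censored`, `auc`, `emax`, `converged`,
#'   `rss`, `n_doses`.
#' @export
fit_curve <- function(doses, viabilities) {
  dm <- dose_means(doses, viabilities)
  d <- dm$dose
  v <- dm$viability
  if (length(d) < 4) {
    stop("curve fitting needs >= 4 distinct doses", call. = FALSE)
  }
  auc <- compute_auc(doses, viabilities)
  emax <- compute_emax(doses, viabilities)

  lo_x <- log10(min(d) / 10)
  hi_x <- log10(max(d) * 10)
  lower <- c(0, 0, 0.1, lo_x)
  upper <- c(1.2, 1.2, 10, hi_x)
  b0 <- min(max(min(v), 0), 1.2)
  s0 <- min(max(max(v) - b0, 1e-3), 1.2)
  x0 <- stats::median(log10(d))

  best <- NULL
  converged <- FALSE
  for (h0 in c(0.5, 1, 2)) {
    fit <- tryCatch(
      stats::optim(c(b0, s0, h0, x0), fourpl_rss, d = d, v = v,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (fit$convergence == 0) converged <- TRUE
    better <- is.null(best) ||
      fit$value < best$value - 1e-12 ||
      (abs(fit$value - best$value) <= 1e-12 && fit$par[3] < best$par[3])
    if (better) best <- fit
  }

  if (is.null(best)) {
    return(structure(
      list(top = NA_real_, bottom = NA_real_, hill = NA_real_,
           ic50_fit = NA_real_, ic50_um = max(d) * 10, ic50_censored = TRUE,
           auc = auc, emax = emax, converged = FALSE, rss = NA_real_,
           n_doses = length(d)),
      class = "dose_response_fit"
    ))
  }

  bottom <- best$par[1]
  top <- min(bottom + best$par[2], 1.2)
  hill <- best$par[3]
  ic50_fit <- 10^best$par[4]

  fitted_v <- function(x) viability_4pl(10^x, ic50_fit, hill, top, bottom)
  v_lo <- fitted_v(lo_x)
  v_hi <- fitted_v(hi_x)
  if (v_lo < 0.5) {
    # below half-viability everywhere in the search window
    ic50 <- min(d) / 10
    censored <- TRUE
  } else if (v_hi > 0.5) {
    ic50 <- max(d) * 10
    censored <- TRUE
  } else {
    root <- stats::uniroot(function(x) fitted_v(x) - 0.5, c(lo_x, hi_x),
                           tol = 1e-9)
    ic50 <- 10^root$root
    censored <- FALSE
  }

  structure(
    list(top = top, bottom = bottom, hill = hill, ic50_fit = ic50_fit,
         ic50_um = ic50, ic50_censored = censored, auc = auc, emax = emax,
         converged = converged, rss = best$value, n_doses = length(d)),
    class = "dose_response_fit"
  )
}

#' Fit dose-response metrics for every curve in a screen
#'
#' Curves with `qc_status == "pass"` are fitted with [fit_curve()];
#' curves that failed QC are retained in the output with their status,
#' raw-point AUC and Emax, and `NA` IC50 (excluded from fitting).
#'
#' @param curves Long-format curve table from [normalize_screen()].
#' @return A data.frame with one row per cell line: `cell_line_id`,
#'   `qc_status`, `top`, `bottom`, `hill`, `ic50_um`, `ic50_censored`,
#'   `auc`, `emax`, `converged`, `rss`.
#' @export
fit_screen <- function(curves) {
  rows <- lapply(split(curves, curves$cell_line_id), function(cur) {
    st <- cur$qc_status[1]
    if (st == "pass") {
      f <- fit_curve(cur$dose_um, cur$viability)
      data.frame(cell_line_id = cur$cell_line_id[1], qc_status = st,
                 top = f$top, bottom = f$bottom, hill = f$hill,
                 ic50_um = f$ic50_um, ic50_censored = f$ic50_censored,
                 auc = f$auc, emax = f$emax, converged = f$converged,
                 rss = f$rss, stringsAsFactors = FALSE)
    } else {
      data.frame(cell_line_id = cur$cell_line_id[1], qc_status = st,
                 top = NA_real_, bottom = NA_real_, hill = NA_real_,
                 ic50_um = NA_real_, ic50_censored = NA,
                 auc = compute_auc(cur$dose_um, cur$viability),
                 emax = compute_emax(cur$dose_um, cur$viability),
                 converged = NA, rss = NA_real_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-tissue response summary (waterfall ordering)
#'
#' Joins fitted response metrics with tissue labels and orders cell
#' lines within each tissue by ascending AUC (most sensitive first), the
#' ordering used for waterfall-style displays of IC50 / AUC / Emax
#' across tissues of origin.
#'
#' @param fits Output of [fit_screen()].
#' @param tissues data.frame with `cell_line_id` and `tissue`.
#' @return A data.frame with one row per cell line: `cell_line_id`,
#'   `tissue`, `ic50_um`, `ic50_censored`, `auc`, `emax`, `qc_status`.
#' @export
summarize_screen <- function(fits, tissues) {
  missing <- setdiff(fits$cell_line_id, tissues$cell_line_id)
  if (length(missing) > 0) {
    stop("missing tissue label for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- merge(fits, tissues[, c("cell_line_id", "tissue")],
               by = "cell_line_id")
  out <- out[order(out$tissue, out$auc, out$cell_line_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("cell_line_id", "tissue", "ic50_um", "ic50_censored", "auc",
          "emax", "qc_status")]
}
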