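# Synthetic screen generator: cohort, multi-omic genomics with planted
# effects, and plate-level well tables with control/blank wells.

#' Default tissue panel for synthetic cohorts
#'
#' The 22 tissues of origin represented in a large pan-cancer cell-line
#' collection, used as the default tissue panel by [cohort_spec()].
#'
#' @return Character vector of 22 tissue labels.
#' @export
default_tissues <- function() {
  c("Biliary Tract", "Bone", "Brain", "Breast", "Esophagus", "Head & Neck",
    "Intestine", "Kidney", "Leukemia", "Liver", "Lung", "Lymphoma",
    "Muscle", "Nervous System", "Ovary", "Pancreas", "Pleura", "Skin",
    "Stomach", "Thyroid", "Urinary Tract", "Uterus")
}

#' Two-fold dilution dose series
#'
#' Generates the dose series by successive halving from the top dose.
#' The default reproduces a 7-point series from 10.64 uM down to
#' 0.166 uM (0.16 at the printed precision).
#'
#' @param top_dose Highest concentration (uM).
#' @param n_doses Number of doses in the series.
#' @param dilution Fold-dilution between consecutive doses.
#' @return Numeric vector of doses in ascending order (uM).
#' @examples
#' dose_series() # 0.166 ... 10.64
#' @export
dose_series <- function(top_dose = 10.64, n_doses = 7, dilution = 2) {
  stopifnot(top_dose > 0, n_doses >= 1, dilution > 1)
  sort(top_dose / dilution^(seq_len(n_doses) - 1L))
}

#' Specify a synthetic cell-line cohort
#'
#' @param n_lines Number of cell lines (default 624).
#' @param tissues Character vector of tissue labels.
#' @param proportions Tissue membership probabilities; must sum to 1.
#'   Defaults to equal proportions across `tissues`.
#' @param seed Optional integer seed carried by the spec; may be
#'   overridden at generation time.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_lines = 624, tissues = default_tissues(),
                        proportions = NULL, seed = NULL) {
  if (length(tissues) == 0) {
    stop("at least one tissue label is required", call. = FALSE)
  }
  if (n_lines < 1) stop("n_lines must be >= 1", call. = FALSE)
  if (is.null(proportions)) {
    proportions <- rep(1 / length(tissues), length(tissues))
  }
  if (length(proportions) != length(tissues)) {
    stop("tissues and proportions must have equal length", call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("tissue proportions must sum to 1", call. = FALSE)
  }
  structure(
    list(n_lines = as.integer(n_lines), tissues = as.character(tissues),
         proportions = as.numeric(proportions), seed = seed),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort of cell lines
#'
#' Draws each cell line's tissue of origin from the multinomial defined
#' by the spec proportions. Deterministic given `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to the seed stored in `spec`.
#' @return A data.frame with columns `cell_line_id` and `tissue`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  tissue <- sample(spec$tissues, spec$n_lines, replace = TRUE,
                   prob = spec$proportions)
  data.frame(
    cell_line_id = sprintf("CL%04d", seq_len(spec$n_lines)),
    tissue = tissue,
    stringsAsFactors = FALSE
  )
}

#' Declare planted genomic effects
#'
#' A planted effect ties a genomic feature to the latent log10(IC50)
#' score: `beta` is the shift in log10(IC50 uM) per standard deviation of
#' the feature. Negative `beta` marks a sensitivity feature (higher
#' feature value, lower IC50); positive `beta` marks resistance.
#'
#' @param feature Typed feature names, e.g. `"MUT_MG0001"`,
#'   `"EXP_EG0005"`, `"CN_CG0003"`.
#' @param beta Signed effect sizes; must be non-zero.
#' @return A data.frame with columns `feature`, `beta`, `direction`.
#' @export
planted_effect <- function(feature, beta) {
  if (length(feature) != length(beta)) {
    stop("feature and beta must have equal length", call. = FALSE)
  }
  if (any(beta == 0)) stop("planted effects must have beta != 0", call. = FALSE)
  data.frame(
    feature = as.character(feature),
    beta = as.numeric(beta),
    direction = ifelse(beta < 0, "sensitivity", "resistance"),
    stringsAsFactors = FALSE
  )
}

#' Specify synthetic genomic feature tables
#'
#' Expression and copy-number features are standard normal; mutation
#' features are sparse Bernoulli indicators (default rate 0.05, typical
#' of filtered exome calls). The latent log10(IC50 uM) score of each
#' cell line is `baseline + sum(beta * standardized feature) + noise`.
#'
#' @param n_exp,n_cn,n_mut Feature counts per data type.
#' @param planted Optional [planted_effect()] table.
#' @param mutation_rate Per-gene mutation probability.
#' @param baseline Baseline log10(IC50 uM); default log10(1.33), the
#'   geometric centre of the default dose series.
#' @param residual_sd SD of the Gaussian residual on the latent score.
#' @return An object of class `genomics_spec`.
#' @export
genomics_spec <- function(n_exp = 500, n_cn = 300, n_mut = 100,
                          planted = NULL, mutation_rate = 0.05,
                          baseline = log10(1.33), residual_sd = 0.3) {
  stopifnot(n_exp >= 0, n_cn >= 0, n_mut >= 0,
            mutation_rate >= 0, mutation_rate <= 1, residual_sd >= 0)
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted), all(c("feature", "beta") %in% names(planted)))
    if (any(planted$beta == 0)) stop("planted beta must be non-zero", call. = FALSE)
  }
  structure(
    list(n_exp = as.integer(n_exp), n_cn = as.integer(n_cn),
         n_mut = as.integer(n_mut), planted = planted,
         mutation_rate = mutation_rate, baseline = baseline,
         residual_sd = residual_sd),
    class = "genomics_spec"
  )
}

#' Generate synthetic genomic feature tables and latent response scores
#'
#' @param cohort Cohort data.frame from [generate_cohort()].
#' @param spec A [genomics_spec()].
#' @param seed Optional integer seed.
#' @return A list of class `genomics_tables` with elements `expression`,
#'   `cn` (real matrices), `mutations` (binary matrix), all keyed by
#'   cell line in rownames; `latent`, a named vector of latent
#'   log10(IC50 uM) scores; and `truth`, the planted-effect table.
#' @export
generate_genomics <- function(cohort, spec = genomics_spec(), seed = NULL) {
  stopifnot(inherits(spec, "genomics_spec"))
  if (nrow(cohort) == 0) stop("cohort must be non-empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  ids <- cohort$cell_line_id

  gene_names <- function(prefix, k) sprintf("%s%04d", prefix, seq_len(k))
  expression <- matrix(stats::rnorm(n * spec$n_exp), n, spec$n_exp,
                       dimnames = list(ids, gene_names("EG", spec$n_exp)))
  cn <- matrix(stats::rnorm(n * spec$n_cn), n, spec$n_cn,
               dimnames = list(ids, gene_names("CG", spec$n_cn)))
  mutations <- matrix(stats::rbinom(n * spec$n_mut, 1L, spec$mutation_rate),
                      n, spec$n_mut,
                      dimnames = list(ids, gene_names("MG", spec$n_mut)))

  latent <- rep(spec$baseline, n)
  planted <- spec$planted
  if (!is.null(planted) && nrow(planted) > 0) {
    tables <- list(EXP = expression, CN = cn, MUT = mutations)
    for (i in seq_len(nrow(planted))) {
      feat <- planted$feature[i]
      type <- sub("_.*$", "", feat)
      gene <- sub("^[A-Z]+_", "", feat)
      if (!type %in% names(tables) || !gene %in% colnames(tables[[type]])) {
        stop(sprintf("planted feature '%s' not found in any feature table", feat),
             call. = FALSE)
      }
      col <- tables[[type]][, gene]
      s <- stats::sd(col)
      if (s == 0) {
        stop(sprintf("planted feature '%s' has zero variance in this cohort", feat),
             call. = FALSE)
      }
      latent <- latent + planted$beta[i] * (col - mean(col)) / s
    }
  }
  if (spec$residual_sd > 0) {
    latent <- latent + stats::rnorm(n, 0, spec$residual_sd)
  }

  structure(
    list(expression = expression, cn = cn, mutations = mutations,
         latent = stats::setNames(latent, ids),
         truth = if (is.null(planted)) planted_effect(character(), numeric()) else planted),
    class = "genomics_tables"
  )
}

#' Specify the plate layout and response model of a synthetic screen
#'
#' Cell lines are mostly dichotomous: a fraction `responder_fraction`
#' follow a true four-parameter logistic viability curve, the rest stay
#' flat at viability ~ 1 at every dose. Raw fluorescence for a well is
#' `blank_level + viability * (control_level - blank_level)` plus
#' Gaussian noise whose SD is `noise_sd` times the dynamic range.
#'
#' @param doses Ascending dose series (uM), all > 0.
#' @param responder_fraction Probability that a line is a responder.
#' @param responder_ic50_log10_mean,responder_ic50_log10_sd Log-normal
#'   parameters (log10 uM scale) used for responder IC50s when no latent
#'   scores are supplied; default centred at the geometric middle of the
#'   dose range.
#' @param hill,top,bottom True curve shape for responders.
#' @param noise_sd Noise SD as a fraction of the dynamic range.
#' @param control_level,blank_level Mean raw fluorescence of untreated
#'   control wells and cell-free blank wells.
#' @param n_control,n_blank Control and blank wells per plate (>= 8 so
#'   CV and signal-over-noise are estimable).
#' @param replicates Treated wells per (line, dose).
#' @param plate_size Total wells per plate (default 384).
#' @return An object of class `screen_spec`.
#' @export
screen_spec <- function(doses = dose_series(), responder_fraction = 0.3,
                        responder_ic50_log10_mean = log10(1.33),
                        responder_ic50_log10_sd = 0.5,
                        hill = 1, top = 1, bottom = 0,
                        noise_sd = 0.05,
                        control_level = 50000, blank_level = 2500,
                        n_control = 16, n_blank = 16,
                        replicates = 1, plate_size = 384) {
  if (any(doses <= 0)) stop("all doses must be > 0", call. = FALSE)
  if (is.unsorted(doses, strictly = TRUE)) {
    stop("doses must be strictly increasing", call. = FALSE)
  }
  if (responder_fraction < 0 || responder_fraction > 1) {
    stop("responder_fraction must be in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  stopifnot(control_level > blank_level, blank_level >= 0,
            n_control >= 2, n_blank >= 2, replicates >= 1, plate_size >= 1)
  structure(
    list(doses = doses, responder_fraction = responder_fraction,
         responder_ic50_log10_mean = responder_ic50_log10_mean,
         responder_ic50_log10_sd = responder_ic50_log10_sd,
         hill = hill, top = top, bottom = bottom, noise_sd = noise_sd,
         control_level = control_level, blank_level = blank_level,
         n_control = as.integer(n_control), n_blank = as.integer(n_blank),
         replicates = as.integer(replicates),
         plate_size = as.integer(plate_size)),
    class = "screen_spec"
  )
}

#' Four-parameter logistic viability curve
#'
#' `v(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)`; with
#' `hill > 0` viability decreases from `top` (dose 0) to `bottom`.
#'
#' @param dose Dose(s), same units as `ic50`.
#' @param ic50 Curve midpoint (inflection dose).
#' @param hill Hill slope.
#' @param top,bottom Upper and lower asymptotes.
#' @return Viability fraction(s).
#' @export
viability_4pl <- function(dose, ic50, hill = 1, top = 1, bottom = 0) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

well_position_ids <- function(k, plate_size) {
  if (plate_size == 384) {
    # 16 x 24 layout, row-major
    sprintf("%s%02d", LETTERS[(seq_len(k) - 1L) %/% 24L + 1L],
            (seq_len(k) - 1L) %% 24L + 1L)
  } else {
    sprintf("W%03d", seq_len(k))
  }
}

#' Generate plate-level well records for a synthetic screen
#'
#' Lines are packed onto plates (treated wells first, then control and
#' blank wells). Responders follow a true 4PL curve with IC50 equal to
#' `10^latent` when latent scores are supplied, otherwise drawn from the
#' spec's log-normal; non-responders are flat at viability 1.
#'
#' @param cohort Cohort data.frame from [generate_cohort()].
#' @param spec A [screen_spec()].
#' @param latent Optional named vector of latent log10(IC50 uM) scores
#'   (from [generate_genomics()]); must cover every cell line.
#' @param seed Optional integer seed.
#' @return A list of class `synthetic_screen` with `wells` (plate_id,
#'   well_id, cell_line_id, role, dose_um, raw_signal) and `truth`
#'   (cell_line_id, responder, true_ic50_um).
#' @export
generate_screen <- function(cohort, spec = screen_spec(), latent = NULL,
                            seed = NULL) {
  stopifnot(inherits(spec, "screen_spec"))
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  ids <- cohort$cell_line_id

  responder <- stats::rbinom(n, 1L, spec$responder_fraction) == 1L
  if (is.null(latent)) {
    ic50 <- 10^stats::rnorm(n, spec$responder_ic50_log10_mean,
                            spec$responder_ic50_log10_sd)
  } else {
    if (!all(ids %in% names(latent))) {
      stop("every cell line must have a latent score", call. = FALSE)
    }
    ic50 <- 10^unname(latent[ids])
  }

  doses <- spec$doses
  wells_per_line <- length(doses) * spec$replicates
  lines_per_plate <- (spec$plate_size - spec$n_control - spec$n_blank) %/%
    wells_per_line
  if (lines_per_plate < 1) {
    stop("plate too small for dose series plus control/blank wells",
         call. = FALSE)
  }
  plate_of_line <- ceiling(seq_len(n) / lines_per_plate)
  n_plates <- max(plate_of_line)

  # treated wells
  treated <- data.frame(
    plate_id = rep(sprintf("P%03d", plate_of_line), each = wells_per_line),
    cell_line_id = rep(ids, each = wells_per_line),
    role = "treated",
    dose_um = rep(rep(doses, spec$replicates), times = n),
    stringsAsFactors = FALSE
  )
  v <- ifelse(rep(responder, each = wells_per_line),
              viability_4pl(treated$dose_um,
                            rep(ic50, each = wells_per_line),
                            spec$hill, spec$top, spec$bottom),
              1)
  treated$raw_signal <- spec$blank_level +
    v * (spec$control_level - spec$blank_level)

  ctrl <- data.frame(
    plate_id = rep(sprintf("P%03d", seq_len(n_plates)), each = spec$n_control),
    cell_line_id = NA_character_, role = "control", dose_um = NA_real_,
    raw_signal = spec$control_level, stringsAsFactors = FALSE
  )
  blank <- data.frame(
    plate_id = rep(sprintf("P%03d", seq_len(n_plates)), each = spec$n_blank),
    cell_line_id = NA_character_, role = "blank", dose_um = NA_real_,
    raw_signal = spec$blank_level, stringsAsFactors = FALSE
  )

  wells <- rbind(treated, ctrl, blank)
  wells <- wells[order(wells$plate_id), , drop = FALSE]
  wells$well_id <- stats::ave(seq_len(nrow(wells)), wells$plate_id,
                              FUN = function(i) seq_along(i))
  wells$well_id <- unlist(lapply(split(wells$well_id, wells$plate_id),
                                 function(k) well_position_ids(length(k), spec$plate_size)),
                          use.names = FALSE)
  if (spec$noise_sd > 0) {
    wells$raw_signal <- wells$raw_signal +
      stats::rnorm(nrow(wells), 0,
                   spec$noise_sd * (spec$control_level - spec$blank_level))
  }
  wells$raw_signal <- pmax(wells$raw_signal, 0)
  wells <- wells[, c("plate_id", "well_id", "cell_line_id", "role",
                     "dose_um", "raw_signal")]
  rownames(wells) <- NULL

  truth <- data.frame(
    cell_line_id = ids,
    responder = responder,
    true_ic50_um = ifelse(responder, ic50, NA_real_),
    stringsAsFactors = FALSE
  )
  structure(list(wells = wells, truth = truth, spec = spec),
            class = "synthetic_screen")
}
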