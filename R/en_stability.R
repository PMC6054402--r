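# Repeated leave-10%-out elastic-net stability selection and the
# Freq / weight / effect aggregation over runs.

#' Configuration for elastic-net stability selection
#'
#' @param n_runs Number of resampling runs (default 100).
#' @param holdout_fraction Fraction of cell lines left out per run
#'   (default 0.10).
#' @param l1_ratio Elastic-net mixing parameter alpha (1 = lasso,
#'   default 0.5).
#' @param cv_folds Folds of the internal cross-validation used to pick
#'   the penalty on each training split (default 5; minimum-CV-error
#'   lambda, no one-standard-error rule).
#' @param seed Optional integer seed; fixes the holdout draws and the
#'   internal CV folds, making the whole procedure reproducible.
#' @param lambda Optional fixed penalty; when supplied the internal CV
#'   is skipped (mainly for limit checks in tests).
#' @param weight_all_runs If TRUE, per-feature weight averages the
#'   coefficient over all runs (zeros included) instead of only over the
#'   runs in which the feature was selected.
#' @param exclude_censored If TRUE, lines whose response is censored are
#'   excluded before resampling.
#' @return An object of class `en_config`.
#' @export
en_config <- function(n_runs = 100, holdout_fraction = 0.10, l1_ratio = 0.5,
                      cv_folds = 5, seed = NULL, lambda = NULL,
                      weight_all_runs = FALSE, exclude_censored = FALSE) {
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("holdout_fraction must be in (0, 1)", call. = FALSE)
  }
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  if (l1_ratio <= 0 || l1_ratio > 1) {
    stop("l1_ratio must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(n_runs = as.integer(n_runs), holdout_fraction = holdout_fraction,
         l1_ratio = l1_ratio, cv_folds = as.integer(cv_folds), seed = seed,
         lambda = lambda, weight_all_runs = weight_all_runs,
         exclude_censored = exclude_censored),
    class = "en_config"
  )
}

#' Run repeated leave-p%-out elastic-net stability selection
#'
#' For each run, a random `holdout_fraction` of the cell lines is left
#' out, columns are standardized on the training split (zero-variance
#' columns get coefficient 0), and an elastic net is fitted with the
#' penalty chosen by internal k-fold cross-validation on the training
#' split. Per feature, `freq` is the fraction of runs with a nonzero
#' coefficient, `weight` the mean coefficient over the runs in which it
#' was selected (per-SD scale), and `effect` the weight normalized by
#' the square root of the number of features of the same data type.
#' Negative weight marks sensitivity (higher feature value in lines with
#' lower IC50), positive weight resistance.
#'
#' @param fm A [feature_matrix()].
#' @param cfg An [en_config()].
#' @return An object of class `en_summary`: list with `features`
#'   (feature, type, freq, weight, effect, direction), `runs` (run,
#'   n_holdout, heldout_r2, lambda, n_selected), `coefficients` (features x runs
#'   matrix of per-run coefficients) and `config`.
#' @export
run_stability_selection <- function(fm, cfg = en_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(cfg, "en_config"))
  x <- fm$x
  y <- fm$y
  if (cfg$exclude_censored) {
    keep <- !fm$censored
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
  }
  n <- nrow(x)
  p <- ncol(x)
  if (n < 20) stop("stability selection needs >= 20 cell lines", call. = FALSE)
  if (!all(is.finite(y))) stop("response must be finite", call. = FALSE)
  h <- ceiling(cfg$holdout_fraction * n)
  if (h > n - 10) stop("holdout leaves fewer than 10 training lines", call. = FALSE)

  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  coefs <- matrix(0, p, cfg$n_runs, dimnames = list(colnames(x), NULL))
  r2 <- lambda_sel <- rep(NA_real_, cfg$n_runs)

  constant_y <- stats::sd(y) == 0
  if (constant_y) {
    warning("response is constant across cell lines; no selectable signal")
  } else {
    for (r in seq_len(cfg$n_runs)) {
      hold <- sample.int(n, h)
      xtr <- x[-hold, , drop = FALSE]
      ytr <- y[-hold]
      mu <- colMeans(xtr)
      sdev <- apply(xtr, 2, stats::sd)
      keep <- sdev > 0
      xs <- scale(xtr[, keep, drop = FALSE], mu[keep], sdev[keep])
      if (is.null(cfg$lambda)) {
        cvfit <- glmnet::cv.glmnet(xs, ytr, alpha = cfg$l1_ratio,
                                   nfolds = cfg$cv_folds, standardize = FALSE)
        lam <- cvfit$lambda.min
        b <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
      } else {
        lam <- cfg$lambda
        path <- sort(unique(lam * c(100, 10, 1)), decreasing = TRUE)
        fit <- glmnet::glmnet(xs, ytr, alpha = cfg$l1_ratio,
                              lambda = path, standardize = FALSE)
        b <- as.numeric(stats::coef(fit, s = lam))
      }
      beta <- b[-1]
      coefs[keep, r] <- beta
      xh <- scale(x[hold, keep, drop = FALSE], mu[keep], sdev[keep])
      pred <- b[1] + as.numeric(xh %*% beta)
      yh <- y[hold]
      sst <- sum((yh - mean(yh))^2)
      r2[r] <- if (sst > 0) 1 - sum((yh - pred)^2) / sst else NA_real_
      lambda_sel[r] <- lam
    }
  }

  freq <- rowMeans(coefs != 0)
  weight <- apply(coefs, 1, function(z) {
    if (cfg$weight_all_runs) mean(z)
    else if (any(z != 0)) mean(z[z != 0]) else 0
  })
  type <- sub("_.*$", "", colnames(x))
  tcount <- fm$type_counts[type]
  effect <- ifelse(tcount > 0, weight / sqrt(tcount), 0)
  features <- data.frame(
    feature = colnames(x), type = type, freq = freq, weight = weight,
    effect = as.numeric(effect),
    direction = ifelse(weight < 0, "sensitivity",
                       ifelse(weight > 0, "resistance", NA_character_)),
    stringsAsFactors = FALSE
  )
  rownames(features) <- NULL
  runs <- data.frame(run = seq_len(cfg$n_runs), n_holdout = h,
                     heldout_r2 = r2, lambda = lambda_sel,
                     n_selected = colSums(coefs != 0))
  structure(list(features = features, runs = runs, coefficients = coefs,
                 config = cfg),
            class = "en_summary")
}

#' Report sensitivity and resistance features above a frequency threshold
#'
#' Partitions the features with selection frequency strictly above
#' `freq_threshold` by the sign of their weight: negative weight is the
#' sensitivity list, positive weight the resistance list. Each list is
#' ranked by decreasing absolute normalized effect, then feature name.
#'
#' @param summary An `en_summary` from [run_stability_selection()].
#' @param freq_threshold Strict selection-frequency cutoff
#'   (default 0.7).
#' @return A list with data.frames `sensitivity` and `resistance`.
#' @export
summarize_features <- function(summary, freq_threshold = 0.7) {
  stopifnot(inherits(summary, "en_summary"))
  f <- summary$features
  sel <- f[f$freq > freq_threshold, , drop = FALSE]
  rank_block <- function(b) {
    b <- b[order(-abs(b$effect), b$feature), , drop = FALSE]
    rownames(b) <- NULL
    b
  }
  list(sensitivity = rank_block(sel[sel$weight < 0, , drop = FALSE]),
       resistance = rank_block(sel[sel$weight > 0, , drop = FALSE]))
}
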