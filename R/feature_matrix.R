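# Assembly of the multi-omic design matrix (tissue one-hot, capped copy
# number, expression, mutation) and the log10(IC50) response vector.

FEATURE_TYPES <- c("TIS", "CN", "EXP", "MUT")

#' One-hot encode tissue labels
#'
#' @param labels Character vector of tissue labels (one per line).
#' @param ids Optional cell-line ids for rownames.
#' @return Binary matrix with one `TIS_`-prefixed column per distinct
#'   tissue; each row sums to exactly 1.
#' @export
encode_tissue <- function(labels, ids = names(labels)) {
  labels <- as.character(labels)
  if (any(is.na(labels) | labels == "")) {
    stop("every cell line needs a non-empty tissue label", call. = FALSE)
  }
  lev <- sort(unique(labels))
  m <- vapply(lev, function(l) as.numeric(labels == l), numeric(length(labels)))
  m <- matrix(m, nrow = length(labels),
              dimnames = list(ids, paste0("TIS_", lev)))
  m
}

#' Low-level feature-matrix constructor
#'
#' Builds a `feature_matrix` from an already-assembled design matrix
#' whose column names carry a type prefix (`TIS_`, `CN_`, `EXP_` or
#' `MUT_`) and a response vector. Most users should call
#' [assemble_features()] instead.
#'
#' @param x Numeric matrix, cell lines in rows, typed features in
#'   columns.
#' @param y Response: log10(IC50 uM) per cell line.
#' @param censored Optional logical mask of censored responses.
#' @return An object of class `feature_matrix`: list with `x`, `y`,
#'   `censored`, `type_counts`, `cell_lines`.
#' @export
feature_matrix <- function(x, y, censored = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (anyNA(x) || !all(is.finite(y))) {
    stop("feature matrix and response must be complete and finite",
         call. = FALSE)
  }
  type <- sub("_.*$", "", colnames(x))
  bad <- !type %in% FEATURE_TYPES
  if (any(bad)) {
    stop("feature names must carry a TIS_/CN_/EXP_/MUT_ prefix; offending: ",
         paste(utils::head(colnames(x)[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(censored)) censored <- rep(FALSE, length(y))
  tc <- table(factor(type, levels = FEATURE_TYPES))
  structure(
    list(x = x, y = as.numeric(y), censored = as.logical(censored),
         type_counts = stats::setNames(as.integer(tc), names(tc)),
         cell_lines = rownames(x)),
    class = "feature_matrix"
  )
}

cn_expression_rank <- function(cn, expression) {
  # |Pearson correlation| between a gene's CN and its own expression;
  # genes without an expression counterpart rank last (correlation 0)
  shared <- intersect(rownames(cn), rownames(expression))
  r <- vapply(colnames(cn), function(g) {
    if (!g %in% colnames(expression)) return(0)
    val <- suppressWarnings(stats::cor(cn[shared, g], expression[shared, g]))
    if (is.na(val)) 0 else abs(val)
  }, numeric(1))
  order(-r, colnames(cn))
}

#' Assemble the multi-omic design matrix and response
#'
#' Restricts to the cell lines shared by every input (dropped lines are
#' reported), truncates the copy-number block to the `cn_cap` genes most
#' strongly coupled to their own expression (largest absolute
#' CN-expression Pearson correlation, ties broken lexicographically),
#' one-hot encodes tissue, and sets the response to `log10(ic50_um)`.
#' Censored IC50s are kept at their censoring bound with the mask set,
#' so resistant lines remain in the regression. Features are not
#' standardized here; standardization happens inside each elastic-net
#' training split to avoid leakage.
#'
#' @param expression,cn Numeric matrices, cell lines x genes.
#' @param mutations Binary matrix, cell lines x genes.
#' @param tissues data.frame with `cell_line_id`, `tissue`.
#' @param fits data.frame with `cell_line_id`, `ic50_um`,
#'   `ic50_censored` (e.g. from [fit_screen()]); lines with `NA` IC50
#'   (QC failures) are dropped and reported.
#' @param cn_cap Maximum number of copy-number features retained
#'   (default 1700).
#' @return A [feature_matrix()] with an extra `dropped` element listing
#'   excluded cell lines.
#' @export
assemble_features <- function(expression, cn, mutations, tissues, fits,
                              cn_cap = 1700) {
  fits <- fits[!is.na(fits$ic50_um), , drop = FALSE]
  keys <- list(rownames(expression), rownames(cn), rownames(mutations),
               tissues$cell_line_id, fits$cell_line_id)
  common <- sort(Reduce(intersect, keys))
  if (length(common) < 2) {
    stop("fewer than 2 cell lines shared across all inputs", call. = FALSE)
  }
  dropped <- sort(setdiff(Reduce(union, keys), common))

  expression <- expression[common, , drop = FALSE]
  cn <- cn[common, , drop = FALSE]
  mutations <- mutations[common, , drop = FALSE]
  if (!all(mutations %in% c(0, 1))) {
    stop("mutation matrix must be binary", call. = FALSE)
  }

  if (cn_cap > ncol(cn)) {
    warning(sprintf("cn_cap (%d) exceeds available CN genes (%d); keeping all",
                    cn_cap, ncol(cn)))
  } else if (ncol(cn) > cn_cap) {
    keep <- cn_expression_rank(cn, expression)[seq_len(cn_cap)]
    cn <- cn[, sort(keep), drop = FALSE]
  }

  tis_lab <- stats::setNames(tissues$tissue, tissues$cell_line_id)[common]
  tis <- encode_tissue(tis_lab, ids = common)

  prefix_cols <- function(m, p) {
    if (ncol(m) > 0) colnames(m) <- paste0(p, colnames(m))
    m
  }
  x <- cbind(tis,
             prefix_cols(cn, "CN_"),
             prefix_cols(expression, "EXP_"),
             prefix_cols(mutations, "MUT_"))
  rownames(x) <- common

  f <- fits[match(common, fits$cell_line_id), , drop = FALSE]
  fm <- feature_matrix(x, y = log10(f$ic50_um),
                       censored = isTRUE_vec(f$ic50_censored))
  fm$dropped <- dropped
  fm
}

isTRUE_vec <- function(z) !is.na(z) & z
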