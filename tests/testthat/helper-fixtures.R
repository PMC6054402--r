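# Programmatic fixtures shared across test files.

# A single-plate well table from explicit signal vectors.
make_plate <- function(controls, blanks, treated_signal = numeric(),
                       treated_dose = numeric(), plate_id = "P001",
                       cell_line_id = "CL0001") {
  stopifnot(length(treated_signal) == length(treated_dose))
  n <- length(controls) + length(blanks) + length(treated_signal)
  data.frame(
    plate_id = plate_id,
    well_id = sprintf("W%03d", seq_len(n)),
    cell_line_id = c(rep(cell_line_id, length(treated_signal)),
                     rep(NA_character_, length(controls) + length(blanks))),
    role = c(rep("treated", length(treated_signal)),
             rep("control", length(controls)),
             rep("blank", length(blanks))),
    dose_um = c(treated_dose, rep(NA_real_, length(controls) + length(blanks))),
    raw_signal = c(treated_signal, controls, blanks),
    stringsAsFactors = FALSE
  )
}

# Erdos-Renyi G(n, p) edge table (all unordered pairs, kept w.p. p).
make_er_edges <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  data.frame(a = sprintf("G%03d", pairs[keep, 1]),
             b = sprintf("G%03d", pairs[keep, 2]),
             stringsAsFactors = FALSE)
}

# Brute-force count of edges with both ends in the set.
brute_force_edges <- function(gene_set, network) {
  cnt <- 0L
  for (i in seq_along(network$from)) {
    if (network$from[i] %in% gene_set && network$to[i] %in% gene_set) {
      cnt <- cnt + 1L
    }
  }
  cnt
}

# Random feature matrix with noise-only response.
make_null_fm <- function(n, p, seed, prefix = "EXP_G") {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(sprintf("CL%03d", seq_len(n)),
                              paste0(prefix, sprintf("%03d", seq_len(p)))))
  feature_matrix(x, y = stats::rnorm(n))
}
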