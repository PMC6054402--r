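# Plain-text readers and writers for the pipeline's tabular interfaces
# (well tables, feature matrices, edge lists, gene sets, GMT term sets).

#' Read a plate-level well table
#'
#' Expects tab-separated columns `plate_id`, `well_id`, `cell_line_id`,
#' `role`, `dose_um`, `raw_signal`.
#'
#' @param path File path.
#' @return data.frame of well records.
#' @export
read_wells <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(plate_id = "character",
                                   well_id = "character",
                                   cell_line_id = "character",
                                   role = "character"))
}

#' Read a cell-lines-by-genes matrix from TSV
#'
#' First column holds cell-line ids; the header row holds gene ids.
#'
#' @param path File path.
#' @return Numeric matrix with cell lines in rownames.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Read a gene-gene edge list (TSV) into an interaction network
#'
#' Two columns of gene ids; an optional third column is treated as a
#' confidence score and filtered at `score_cutoff`.
#'
#' @param path File path.
#' @param score_cutoff Minimum confidence score kept (default 0.4).
#' @return An [interaction_network()].
#' @export
read_edge_list <- function(path, score_cutoff = 0.4) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  interaction_network(df, score_cutoff = score_cutoff)
}

#' Read a gene set (one identifier per line)
#'
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Read annotation term sets in GMT format
#'
#' Each line: term, description, then member genes, tab-separated.
#'
#' @param path File path.
#' @return Named list of term -> character vector of gene ids;
#'   descriptions are kept in the `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- vapply(parts, `[[`, character(1), 1)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- terms
  attr(sets, "description") <- stats::setNames(
    vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "", character(1)),
    terms)
  sets
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the full set of synthetic-screen tables to a directory
#'
#' Emits `wells.tsv`, `expression.tsv`, `cn.tsv`, `mutations.tsv`,
#' `tissues.tsv` and `truth.tsv` (per-line responder flag and true IC50
#' plus the planted-feature effects).
#'
#' @param screen A `synthetic_screen` from [generate_screen()].
#' @param genomics A `genomics_tables` from [generate_genomics()].
#' @param cohort Cohort data.frame.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_screen_tables <- function(screen, genomics, cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mat_df <- function(m) data.frame(cell_line_id = rownames(m), m,
                                   check.names = FALSE,
                                   stringsAsFactors = FALSE)
  paths <- c(
    wells = file.path(dir, "wells.tsv"),
    expression = file.path(dir, "expression.tsv"),
    cn = file.path(dir, "cn.tsv"),
    mutations = file.path(dir, "mutations.tsv"),
    tissues = file.path(dir, "tissues.tsv"),
    truth = file.path(dir, "truth.tsv"),
    truth_features = file.path(dir, "truth_features.tsv")
  )
  write_tsv(screen$wells, paths["wells"])
  write_tsv(mat_df(genomics$expression), paths["expression"])
  write_tsv(mat_df(genomics$cn), paths["cn"])
  write_tsv(mat_df(genomics$mutations), paths["mutations"])
  write_tsv(cohort, paths["tissues"])
  write_tsv(screen$truth, paths["truth"])
  write_tsv(genomics$truth, paths["truth_features"])
  invisible(paths)
}
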