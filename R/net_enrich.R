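# Connectivity of a gene set in an interaction network (permutation
# null) and annotation-term enrichment (hypergeometric + BH).

#' Build an undirected interaction network from an edge table
#'
#' Self-loops are dropped and duplicate (unordered) edges collapsed. If
#' the table has a third column it is treated as an interaction
#' confidence score and edges below `score_cutoff` (default 0.4, a
#' common medium-confidence setting) are removed before
#' deduplication.
#'
#' @param edges data.frame or matrix whose first two columns are gene
#'   identifiers (optional third column: confidence score).
#' @param score_cutoff Minimum confidence score kept.
#' @param nodes Optional additional node identifiers (e.g. genes with no
#'   interactions) to include in the node universe.
#' @return An object of class `interaction_network`: list with `nodes`,
#'   `from`, `to`.
#' @export
interaction_network <- function(edges, score_cutoff = 0.4, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop("edge table needs at least two columns", call. = FALSE)
  if (ncol(edges) >= 3) {
    edges <- edges[as.numeric(edges[[3]]) >= score_cutoff, , drop = FALSE]
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  keep <- a != b
  a <- a[keep]
  b <- b[keep]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  d <- !duplicated(paste(lo, hi, sep = "\r"))
  structure(
    list(nodes = sort(unique(c(lo, hi, as.character(nodes)))),
         from = lo[d], to = hi[d]),
    class = "interaction_network"
  )
}

#' Permutation test of gene-set connectivity
#'
#' Counts the network edges with both endpoints inside the gene set and
#' compares the count with a null of uniformly sampled node sets of the
#' same size. The expected edge count is the null mean and the p-value
#' the add-one upper-tail estimate `(1 + #{null >= observed}) /
#' (1 + n_perm)`, which can never be exactly zero. Genes absent from the
#' network are dropped with a warning.
#'
#' @param gene_set Character vector of gene identifiers.
#' @param network An [interaction_network()].
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return An object of class `connectivity_result`: list with
#'   `set_size`, `observed`, `expected`, `null_sd`, `p_value`, `n_perm`.
#' @export
connectivity_test <- function(gene_set, network, n_perm = 10000,
                              seed = NULL) {
  stopifnot(inherits(network, "interaction_network"))
  gs <- unique(as.character(gene_set))
  absent <- setdiff(gs, network$nodes)
  if (length(absent) > 0) {
    warning("dropping ", length(absent), " gene(s) not in the network: ",
            paste(utils::head(absent, 5), collapse = ", "))
    gs <- setdiff(gs, absent)
  }
  k <- length(gs)
  if (k < 2) {
    stop("need at least 2 set genes present in the network", call. = FALSE)
  }
  nn <- length(network$nodes)
  fi <- match(network$from, network$nodes)
  ti <- match(network$to, network$nodes)

  count_edges <- function(idx) {
    memb <- logical(nn)
    memb[idx] <- TRUE
    sum(memb[fi] & memb[ti])
  }
  observed <- count_edges(match(gs, network$nodes))

  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm),
                 function(i) count_edges(sample.int(nn, k)),
                 numeric(1))
  structure(
    list(set_size = k, observed = observed, expected = mean(null),
         null_sd = stats::sd(null),
         p_value = (1 + sum(null >= observed)) / (1 + n_perm),
         n_perm = n_perm),
    class = "connectivity_result"
  )
}

#' Hypergeometric term enrichment with BH adjustment
#'
#' For each annotation term, computes the hypergeometric upper-tail
#' probability of observing at least the overlap between the gene set
#' and the term within the universe, then adjusts across all tested
#' terms with Benjamini-Hochberg. Term memberships are restricted to the
#' universe before testing.
#'
#' @param gene_set Character vector of genes; must be contained in
#'   `universe`.
#' @param annotations Named list of term -> gene identifier vectors
#'   (e.g. from [read_gmt()]).
#' @param universe Character vector of all assayable genes.
#' @return data.frame sorted by `fdr`, then `p`, then term: `term`,
#'   `overlap`, `set_size`, `term_size`, `universe_size`, `p`, `fdr`.
#' @export
term_enrichment <- function(gene_set, annotations, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  gs <- unique(as.character(gene_set))
  outside <- setdiff(gs, universe)
  if (length(outside) > 0) {
    stop("gene set contains genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n <- length(gs)
  res <- lapply(names(annotations), function(term) {
    members <- intersect(unique(as.character(annotations[[term]])), universe)
    K <- length(members)
    k <- length(intersect(members, gs))
    data.frame(term = term, overlap = k, set_size = n, term_size = K,
               universe_size = N,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(term = character(), overlap = integer(),
                      set_size = integer(), term_size = integer(),
                      universe_size = integer(), p = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE))
  }
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$fdr, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
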