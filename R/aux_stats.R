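#' Gene-set over-representation analysis
#'
#' Plain hypergeometric upper-tail test of a query gene list against each term
#' of a gene-set collection, with Benjamini-Hochberg adjustment across the
#' reported terms. This is a generic stand-in for annotation-service GO
#' analyses: it reproduces the plotted quantities (−log10 p and term ranks),
#' not any service's modified statistic.
#'
#' @param query_genes character vector, a subset of `universe`.
#' @param term_map named list term id -> character vector of member genes
#'   (each a subset of `universe`).
#' @param universe character vector of all eligible genes.
#' @return data frame sorted by ascending p with columns `term_id`, `K` (term
#'   size in universe), `k` (overlap with query), `p` (P(X >= k)), `q` (BH),
#'   `neg_log10_p`.
#' @export
ora <- function(query_genes, term_map, universe) {
  universe <- unique(universe)
  query_genes <- unique(query_genes)
  if (!length(universe)) abort("empty universe")
  if (!length(query_genes)) abort("empty query")
  if (!all(query_genes %in% universe))
    abort("query genes outside the universe")
  N <- length(universe)
  n <- length(query_genes)
  K <- vapply(term_map, function(g) sum(unique(g) %in% universe), 0L)
  k <- vapply(term_map, function(g) sum(unique(g) %in% query_genes), 0L)
  if (any(k > pmin(K, n))) abort("term genes outside the universe")
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = names(term_map), K = K, k = k, p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    neg_log10_p = -log10(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p, out$term_id), , drop = FALSE]
}

#' Rank percentile of a term across per-sample ORA tables
#'
#' The term list of each sample is normalized to 100: the percentile is
#' 100 x rank(term, by ascending p, ties to the smallest rank) / number of
#' terms in that sample's table. Smaller is more enriched.
#'
#' @param term_tables named list sample id -> ORA table ([ora()] output).
#' @param term_id term to locate.
#' @return named numeric vector sample -> percentile, `NA` where the term is
#'   absent from a sample's table.
#' @export
term_rank_percentile <- function(term_tables, term_id) {
  vapply(term_tables, function(tab) {
    i <- match(term_id, tab$term_id)
    if (is.na(i)) return(NA_real_)
    r <- rank(tab$p, ties.method = "min")[i]
    100 * r / nrow(tab)
  }, 0)
}

#' ChIP-qPCR fold enrichment over an IgG control
#'
#' Standard delta-Ct conversion: one cycle of difference doubles the amount of
#' immunoprecipitated DNA, so fold = 2^(Ct_IgG − Ct_ChIP). Equal Cts give 1.
#'
#' @param ct_chip,ct_igg finite positive cycle-threshold values (vectorized).
#' @return numeric fold enrichment.
#' @export
qpcr_fold <- function(ct_chip, ct_igg) {
  if (any(!is.finite(ct_chip)) || any(!is.finite(ct_igg)) ||
      any(ct_chip <= 0) || any(ct_igg <= 0))
    abort("Ct values must be finite and positive")
  2^(ct_igg - ct_chip)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (term, description, tab-separated genes).
#' @return named list term id -> character vector of genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) abort("malformed GMT line ", bad[1L], " in ", path)
  stats::setNames(lapply(parts, function(x) unique(x[-(1:2)])),
                  vapply(parts, `[`, "", 1L))
}
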