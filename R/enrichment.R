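#' Hypergeometric over-representation analysis with rich factors
#'
#' For each term with at least one background gene, tests whether the gene set
#' is over-represented among the term's genes: with `N` universe genes, `K` of
#' them in the term, `n` genes in the query set and `k` of those in the term,
#' the one-sided p-value is the exact upper tail
#' `P(X >= k) = sum_{i=k}^{min(K, n)} dhyper(i, K, N - K, n)`.
#' BH adjustment runs across all tested terms. The rich factor is `k / K`
#' (query genes in the term over all background genes in the term).
#'
#' @param gene_set character vector of query gene ids (must lie inside the
#'   universe).
#' @param term_map data.frame with columns `gene_id`, `term_id` (one row per
#'   annotation).
#' @param universe background gene ids; defaults to all genes in `term_map`.
#' @return data.frame with one row per tested term: `term_id`, `k`, `K`, `n`,
#'   `N`, `p_value`, `q_value`, `rich_factor`, sorted by p ascending with ties
#'   broken by term id.
#' @export
enrich <- function(gene_set, term_map, universe = NULL) {
  if (!all(c("gene_id", "term_id") %in% names(term_map)))
    stop("term_map needs columns gene_id and term_id")
  if (is.null(universe)) universe <- unique(term_map$gene_id)
  gene_set <- unique(gene_set)
  outside <- setdiff(gene_set, universe)
  if (length(outside) > 0)
    stop("gene(s) outside the universe: ", paste(outside, collapse = ", "))
  term_map <- unique(term_map[term_map$gene_id %in% universe,
                              c("gene_id", "term_id")])
  N <- length(universe)
  n <- length(gene_set)
  terms <- unique(term_map$term_id)
  K <- as.integer(table(factor(term_map$term_id, levels = terms)))
  in_set <- term_map$gene_id %in% gene_set
  k <- as.integer(table(factor(term_map$term_id[in_set], levels = terms)))
  keep <- K > 0
  terms <- terms[keep]; K <- K[keep]; k <- k[keep]
  p <- vapply(seq_along(terms), function(i)
    hyper_tail_p(k[i], K[i], n, N), numeric(1))
  out <- data.frame(term_id = terms, k = k, K = K, n = n, N = N,
                    p_value = p,
                    q_value = p.adjust(p, method = "BH"),
                    rich_factor = k / K,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact hypergeometric upper-tail probability
#'
#' `P(X >= k)` for X ~ hypergeometric(N, K, n), assembled by explicit
#' summation of the pmf over `k .. min(K, n)`.
#'
#' @param k observed overlap.
#' @param K term size in the background.
#' @param n query-set size.
#' @param N universe size.
#' @return the tail probability.
#' @export
hyper_tail_p <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || K > N || n > N || k > min(K, n))
    stop("invalid hypergeometric configuration")
  sum(dhyper(seq.int(k, min(K, n)), K, N - K, n))
}
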