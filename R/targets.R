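#' Predict cis targets of lncRNAs by genomic proximity
#'
#' A coding gene is a cis target of a lncRNA when the span-to-span gap between
#' the gene locus and the lncRNA locus is at most `window` bp (50 kb upstream
#' and downstream by default); overlapping loci have distance 0. Strand is
#' ignored. Gene loci are the per-`gene_id` union of coding transcript spans.
#'
#' @param lnc_exons exon-level table of the lncRNAs of interest.
#' @param coding_exons exon-level table providing the coding annotation.
#' @param window distance window in bp (default 50000).
#' @return data.frame of pairs: `lnc_id`, `gene_id`, `mode` ("cis"),
#'   `distance` (bp gap, 0 if overlapping).
#' @export
cis_targets <- function(lnc_exons, coding_exons, window = 50000L) {
  lnc <- transcript_summary(lnc_exons)
  genes <- gene_spans(coding_exons)
  out <- list()
  for (i in seq_len(nrow(lnc))) {
    g <- genes[genes$chrom == lnc$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    gap <- pmax(0L, pmax(g$start - lnc$span_end[i],
                         lnc$span_start[i] - g$end))
    hit <- gap <= window
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(
        lnc_id = lnc$transcript_id[i], gene_id = g$gene_id[hit],
        mode = "cis", distance = as.integer(gap[hit]),
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(lnc_id = character(), gene_id = character(),
                      mode = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-gene loci (union of coding transcript spans)
#' @param coding_exons exon-level table; only `coding` rows are used.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`.
#' @export
gene_spans <- function(coding_exons) {
  cod <- coding_exons[coding_exons$biotype == "coding", , drop = FALSE]
  if (nrow(cod) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  ids <- unique(cod$gene_id)
  f <- factor(cod$gene_id, levels = ids)
  data.frame(gene_id = ids,
             chrom = cod$chrom[match(ids, cod$gene_id)],
             start = as.integer(tapply(cod$start, f, min)),
             end = as.integer(tapply(cod$end, f, max)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Predict trans targets by expression correlation
#'
#' For every (lncRNA, mRNA) pair computes the Pearson correlation of
#' `log2(value + 1)` profiles across the shared samples, a two-sided p-value
#' from the exact t transform `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2
#' degrees of freedom, and a BH q-value over all tested pairs as one global
#' family. Pairs with `|r| > r_threshold` and `q < fdr_threshold` are
#' reported. Zero-variance features are skipped with a warning (r undefined).
#'
#' @param lnc_mat lncRNA expression matrix (features x samples).
#' @param mrna_mat mRNA expression matrix over the same samples, same order.
#' @param r_threshold absolute-correlation threshold (default 0.95).
#' @param fdr_threshold BH q-value threshold (default 0.05).
#' @param log_transform correlate `log2(x + 1)` (default) or raw values.
#' @param keep_all return all tested pairs with a `selected` flag instead of
#'   only the retained ones.
#' @return data.frame of pairs: `lnc_id`, `gene_id`, `mode` ("trans"),
#'   `correlation`, `p_value`, `q_value` (and `selected` if `keep_all`).
#' @export
trans_targets <- function(lnc_mat, mrna_mat, r_threshold = 0.95,
                          fdr_threshold = 0.05, log_transform = TRUE,
                          keep_all = FALSE) {
  if (ncol(lnc_mat) != ncol(mrna_mat) ||
      !identical(colnames(lnc_mat), colnames(mrna_mat)))
    stop("matrices must share the same samples in the same order")
  n <- ncol(lnc_mat)
  if (n < 3) stop("need at least 3 samples for a correlation p-value")
  x <- if (log_transform) log2(lnc_mat + 1) else lnc_mat
  y <- if (log_transform) log2(mrna_mat + 1) else mrna_mat
  const_x <- apply(x, 1, function(v) var(v) == 0)
  const_y <- apply(y, 1, function(v) var(v) == 0)
  if (any(const_x) || any(const_y))
    warning("skipping zero-variance features: ",
            paste(c(rownames(x)[const_x], rownames(y)[const_y]),
                  collapse = ", "))
  x <- x[!const_x, , drop = FALSE]
  y <- y[!const_y, , drop = FALSE]
  empty <- data.frame(lnc_id = character(), gene_id = character(),
                      mode = character(), correlation = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(x) == 0 || nrow(y) == 0) return(empty)

  r <- cor(t(x), t(y))
  r_clamped <- pmin(pmax(r, -1), 1)
  p <- matrix(0, nrow(r), ncol(r))
  finite <- abs(r_clamped) < 1
  tstat <- r_clamped[finite] * sqrt((n - 2) / (1 - r_clamped[finite]^2))
  p[finite] <- 2 * pt(-abs(tstat), n - 2)
  q <- matrix(p.adjust(as.vector(p), method = "BH"), nrow(r), ncol(r))

  pairs <- data.frame(
    lnc_id = rep(rownames(x), times = ncol(r)),
    gene_id = rep(rownames(y), each = nrow(r)),
    mode = "trans",
    correlation = as.vector(r_clamped),
    p_value = as.vector(p),
    q_value = as.vector(q),
    stringsAsFactors = FALSE)
  pairs$selected <- abs(pairs$correlation) > r_threshold &
    pairs$q_value < fdr_threshold
  if (keep_all) return(pairs)
  out <- pairs[pairs$selected, setdiff(names(pairs), "selected"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the lncRNA-mRNA co-expression network
#'
#' Restricts trans-target pairs to differentially expressed lncRNAs and a
#' supplied pathway-annotated DE mRNA list, then builds the bipartite
#' undirected network whose edges carry the correlation weights. Nodes appear
#' only as endpoints of surviving edges (isolated nodes are dropped).
#'
#' @param pairs data.frame from [trans_targets()].
#' @param de_lncs character vector of DE lncRNA ids.
#' @param annotated_mrnas character vector of pathway-annotated DE mRNA ids.
#' @return igraph object with vertex attribute `type` ("lncRNA" or "mRNA")
#'   and edge attribute `correlation`.
#' @export
build_coexpression_network <- function(pairs, de_lncs, annotated_mrnas) {
  keep <- pairs$lnc_id %in% de_lncs & pairs$gene_id %in% annotated_mrnas
  pairs <- pairs[keep, , drop = FALSE]
  g <- igraph::make_empty_graph(directed = FALSE)
  if (nrow(pairs) == 0) return(g)
  nodes <- data.frame(name = c(unique(pairs$lnc_id), unique(pairs$gene_id)),
                      type = c(rep("lncRNA", length(unique(pairs$lnc_id))),
                               rep("mRNA", length(unique(pairs$gene_id)))),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = pairs$lnc_id, to = pairs$gene_id,
                      correlation = pairs$correlation,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Node and edge tables of a typed network
#'
#' @param g igraph object with a `type` vertex attribute.
#' @return list of two data.frames: `nodes` (`id`, `type`, `degree`) and
#'   `edges` (`source`, `target`, plus any edge attributes).
#' @export
network_tables <- function(g) {
  nodes <- data.frame(id = igraph::V(g)$name,
                      type = igraph::V(g)$type,
                      degree = igraph::degree(g),
                      row.names = NULL, stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(source = el[, 1], target = el[, 2],
                      stringsAsFactors = FALSE)
  for (a in igraph::edge_attr_names(g)) edges[[a]] <- igraph::edge_attr(g, a)
  list(nodes = nodes, edges = edges)
}
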