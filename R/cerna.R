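#' Select lncRNAs eligible for the ceRNA network
#'
#' The ceRNA screen keeps the DE lncRNAs that are line-specific (expressed in
#' only one group) AND localized to the cytoplasm, since only cytoplasmic
#' transcripts can titrate miRNAs.
#'
#' @param de_records data.frame from [screen_de()] (needs `feature_id` and
#'   `specificity`).
#' @param localization named vector, feature id -> "cytoplasm"/"nucleus"
#'   (see [read_localization()]); must cover every DE lncRNA.
#' @return character vector of selected lncRNA ids, in input order.
#' @export
select_cerna_lncrnas <- function(de_records, localization) {
  missing <- setdiff(de_records$feature_id, names(localization))
  if (length(missing) > 0)
    stop("localization missing for: ", paste(missing, collapse = ", "))
  specific <- de_records$specificity %in% c("fat_only", "lean_only")
  cyto <- localization[de_records$feature_id] == "cytoplasm"
  de_records$feature_id[specific & cyto]
}

#' Build the lncRNA-miRNA-mRNA ceRNA network
#'
#' Both pair tables are first filtered to prediction scores >=
#' `score_threshold` (the conventional reading of a miRDB "threshold score of
#' 70"). Only miRNAs present in BOTH filtered tables (the shared, "common"
#' miRNAs) are kept; edges are all filtered pairs whose miRNA survives, and
#' nodes are the endpoints of surviving edges. The result is a tripartite
#' graph: lncRNA-miRNA and miRNA-mRNA edges only.
#'
#' @param lnc_mirna pair table with `source_id` = lncRNA id and `mirna_id` =
#'   miRNA id - see [read_pair_table()].
#' @param mirna_mrna pair table with `source_id` = mRNA id and `mirna_id` =
#'   miRNA id.
#' @param score_threshold minimum prediction score (default 70).
#' @return igraph object, vertex attribute `type` in
#'   {"lncRNA", "miRNA", "mRNA"}, edge attributes `edge_type` and `score`.
#' @export
build_cerna <- function(lnc_mirna, mirna_mrna, score_threshold = 70) {
  validate_pairs(lnc_mirna)
  validate_pairs(mirna_mrna)
  lt <- lnc_mirna[lnc_mirna$score >= score_threshold, , drop = FALSE]
  mt <- mirna_mrna[mirna_mrna$score >= score_threshold, , drop = FALSE]
  shared <- intersect(unique(lt$mirna_id), unique(mt$mirna_id))
  lt <- lt[lt$mirna_id %in% shared, , drop = FALSE]
  mt <- mt[mt$mirna_id %in% shared, , drop = FALSE]
  if (nrow(lt) == 0 || nrow(mt) == 0)
    return(igraph::make_empty_graph(directed = FALSE))
  nodes <- data.frame(
    name = c(unique(lt$source_id), shared, unique(mt$source_id)),
    type = c(rep("lncRNA", length(unique(lt$source_id))),
             rep("miRNA", length(shared)),
             rep("mRNA", length(unique(mt$source_id)))),
    stringsAsFactors = FALSE)
  edges <- rbind(
    data.frame(from = lt$source_id, to = lt$mirna_id,
               edge_type = "lncRNA-miRNA", score = lt$score,
               stringsAsFactors = FALSE),
    data.frame(from = mt$mirna_id, to = mt$source_id,
               edge_type = "miRNA-mRNA", score = mt$score,
               stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  assert_tripartite(g)
  g
}

#' Assert the ceRNA tripartite structure
#'
#' Hard-fails unless every edge connects a lncRNA to a miRNA or a miRNA to an
#' mRNA (no within-type or lncRNA-mRNA edges).
#'
#' @param g igraph object with a `type` vertex attribute.
#' @return `g`, invisibly.
#' @export
assert_tripartite <- function(g) {
  if (igraph::ecount(g) == 0) return(invisible(g))
  el <- igraph::as_edgelist(g)
  t1 <- igraph::V(g)$type[match(el[, 1], igraph::V(g)$name)]
  t2 <- igraph::V(g)$type[match(el[, 2], igraph::V(g)$name)]
  ok <- (t1 == "miRNA") != (t2 == "miRNA")
  if (!all(ok))
    stop("network violates tripartite structure (",
         sum(!ok), " invalid edge(s))")
  invisible(g)
}

#' Rank hub nodes by degree
#'
#' @param g typed igraph network.
#' @param node_type which node class to rank (e.g. "lncRNA").
#' @return data.frame `node`, `degree`, sorted by degree descending with
#'   lexicographic tie-break on the node id.
#' @export
hub_rank <- function(g, node_type = "lncRNA") {
  if (igraph::vcount(g) == 0)
    return(data.frame(node = character(), degree = integer(),
                      stringsAsFactors = FALSE))
  keep <- igraph::V(g)$type == node_type
  out <- data.frame(node = igraph::V(g)$name[keep],
                    degree = unname(igraph::degree(g)[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the ego sub-network of a hub lncRNA
#'
#' The sub-network contains the hub, its incident miRNAs, and those miRNAs'
#' mRNA partners within the global network; edges of both types among these
#' nodes are retained.
#'
#' @param g ceRNA network from [build_cerna()].
#' @param hub lncRNA node id.
#' @return igraph sub-network.
#' @export
cerna_subnetwork <- function(g, hub) {
  if (!hub %in% igraph::V(g)$name) stop("hub not in network: ", hub)
  nb <- igraph::neighbors(g, hub)
  mirnas <- nb$name[nb$type == "miRNA"]
  mrnas <- unique(unlist(lapply(mirnas, function(m) {
    nb <- igraph::neighbors(g, m)
    nb$name[nb$type == "mRNA"]
  })))
  igraph::induced_subgraph(g, c(hub, mirnas, mrnas))
}

#' Summary counts of a ceRNA network
#'
#' @param g ceRNA network.
#' @return list with `n_lncrna`, `n_mirna`, `n_mrna`, `n_edges`.
#' @export
cerna_summary <- function(g) {
  types <- if (igraph::vcount(g) > 0) igraph::V(g)$type else character()
  list(n_lncrna = sum(types == "lncRNA"),
       n_mirna = sum(types == "miRNA"),
       n_mrna = sum(types == "mRNA"),
       n_edges = igraph::ecount(g))
}

#' circRNA-miRNA sponge table
#'
#' Filters circRNA-miRNA predicted pairs to the supplied expressed/DE circRNA
#' set and prediction scores >= `score_threshold`, and reports summary counts.
#'
#' @param circ_mirna pair table (`source_id` = circRNA).
#' @param expressed_circs circRNA ids to keep.
#' @param score_threshold minimum score (default 70).
#' @return list with `pairs` (filtered table) and `summary`
#'   (`n_circ`, `n_mirna`, `n_pairs`).
#' @export
sponge_table <- function(circ_mirna, expressed_circs, score_threshold = 70) {
  validate_pairs(circ_mirna)
  keep <- circ_mirna$source_id %in% expressed_circs &
    circ_mirna$score >= score_threshold
  pairs <- circ_mirna[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       summary = list(n_circ = length(unique(pairs$source_id)),
                      n_mirna = length(unique(pairs$mirna_id)),
                      n_pairs = nrow(pairs)))
}
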