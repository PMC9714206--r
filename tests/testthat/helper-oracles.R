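# Brute-force reference implementations, deliberately independent of the
# package's indexed/vectorized code paths: plain loops and arithmetic only.

ov <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1  # half-open overlap

# Precompute per-transcript structures of a coding annotation for the
# all-pairs scans.
oracle_coding_list <- function(coding_exons) {
  cod <- coding_exons[coding_exons$biotype == "coding", , drop = FALSE]
  lapply(split(cod, cod$transcript_id), function(ce) {
    ce <- ce[order(ce$start), , drop = FALSE]
    list(chrom = ce$chrom[1], strand = ce$strand[1],
         ex_s = ce$start, ex_e = ce$end,
         in_s = if (nrow(ce) > 1) ce$end[-nrow(ce)] else numeric(),
         in_e = if (nrow(ce) > 1) ce$start[-1] else numeric(),
         span_s = min(ce$start), span_e = max(ce$end))
  })
}

# Per-pair class codes follow the classifier's priority order; the oracle
# takes the minimum code over all coding transcripts.
oracle_lnc_class <- function(lnc_exons, coding, window = 1000) {
  classes <- c("exon_sense_overlapping", "intron_sense_overlapping",
               "natural_antisense", "intronic_antisense", "bidirectional",
               "intergenic")
  ls <- min(lnc_exons$start); le <- max(lnc_exons$end)
  lchrom <- lnc_exons$chrom[1]; lstrand <- lnc_exons$strand[1]
  best <- 6L
  for (tx in coding) {
    if (tx$chrom != lchrom) next
    same <- tx$strand == lstrand
    exon_exon <- FALSE
    for (i in seq_along(lnc_exons$start))
      if (any(ov(lnc_exons$start[i], lnc_exons$end[i], tx$ex_s, tx$ex_e)))
        exon_exon <- TRUE
    span_exon <- any(ov(ls, le, tx$ex_s, tx$ex_e))
    span_intron <- length(tx$in_s) > 0 && any(ov(ls, le, tx$in_s, tx$in_e))
    cls <- 6L
    if (same && exon_exon) cls <- 1L
    else if (same && span_intron) cls <- 2L
    else if (!same && span_exon) cls <- 3L
    else if (!same && span_intron) cls <- 4L
    else if (!same) {
      if (lstrand == "-") { m_end <- le; p_start <- tx$span_s }
      else { m_end <- tx$span_e; p_start <- ls }
      if (m_end <= p_start && (p_start - (m_end - 1)) <= window) cls <- 5L
    }
    best <- min(best, cls)
  }
  classes[best]
}

oracle_circ_class <- function(start, end, chrom, strand, coding) {
  classes <- c("exonic", "intronic", "sense_overlapping", "antisense",
               "intergenic")
  b1 <- start; b2 <- end - 1
  best <- 5L
  for (tx in coding) {
    if (tx$chrom != chrom) next
    same <- tx$strand == strand
    span_ov <- ov(start, end, tx$span_s, tx$span_e)
    cls <- 5L
    if (same &&
        any(tx$ex_s <= b1 & b1 < tx$ex_e) &&
        any(tx$ex_s <= b2 & b2 < tx$ex_e)) cls <- 1L
    else if (same && length(tx$in_s) > 0 &&
             any(tx$in_s <= start & end <= tx$in_e)) cls <- 2L
    else if (same && span_ov) cls <- 3L
    else if (!same && span_ov) cls <- 4L
    best <- min(best, cls)
  }
  classes[best]
}

# classify every lncRNA/circRNA in a landscape with the all-pairs oracle
oracle_classify_landscape <- function(exons, junctions = NULL, window = 1000) {
  coding <- oracle_coding_list(exons)
  lnc <- exons[exons$biotype == "lncRNA_candidate", , drop = FALSE]
  ids <- unique(lnc$transcript_id)
  lnc_cls <- vapply(ids, function(id)
    oracle_lnc_class(lnc[lnc$transcript_id == id, , drop = FALSE], coding,
                     window), character(1))
  out <- list(lnc = data.frame(transcript_id = ids, class = unname(lnc_cls),
                               stringsAsFactors = FALSE))
  if (!is.null(junctions)) {
    circ_cls <- vapply(seq_len(nrow(junctions)), function(i)
      oracle_circ_class(junctions$start[i], junctions$end[i],
                        junctions$chrom[i], junctions$strand[i], coding),
      character(1))
    out$circ <- data.frame(circ_id = junctions$circ_id, class = circ_cls,
                           stringsAsFactors = FALSE)
  }
  out
}

# naive sort-based Benjamini-Hochberg
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# hypergeometric upper tail by combinatorial enumeration (counts of draws)
oracle_hyper_tail <- function(k, K, n, N) {
  ks <- seq.int(k, min(K, n))
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# per-pair Pearson r and t-transform p on log2(x + 1)
oracle_pearson <- function(x, y) {
  x <- log2(x + 1); y <- log2(y + 1)
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  r <- min(max(r, -1), 1)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t), n - 2)
  }
  list(r = r, p = p)
}

# brute-force shared-miRNA ceRNA construction
oracle_cerna <- function(lnc, mrna, thr = 70) {
  l <- lnc[lnc$score >= thr, , drop = FALSE]
  m <- mrna[mrna$score >= thr, , drop = FALSE]
  shared <- intersect(unique(l$mirna_id), unique(m$mirna_id))
  l <- l[l$mirna_id %in% shared, , drop = FALSE]
  m <- m[m$mirna_id %in% shared, , drop = FALSE]
  edges <- sort(c(paste(pmin(l$source_id, l$mirna_id),
                        pmax(l$source_id, l$mirna_id)),
                  paste(pmin(m$mirna_id, m$source_id),
                        pmax(m$mirna_id, m$source_id))))
  list(n_lncrna = length(unique(l$source_id)),
       n_mirna = length(shared),
       n_mrna = length(unique(m$source_id)),
       n_edges = nrow(l) + nrow(m),
       edges = edges)
}

# sorted multiset of undirected edge keys of an igraph
graph_edge_keys <- function(g) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) return(character())
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
}
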