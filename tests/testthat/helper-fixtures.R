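# small builders used across tests

# one transcript as an exon table; starts/ends are 0-based half-open
tx <- function(id, starts, ends, strand = "+", biotype = "lncRNA_candidate",
               chrom = "chr1", gene = paste0("G_", id)) {
  data.frame(transcript_id = id, gene_id = gene, biotype = biotype,
             chrom = chrom, start = as.integer(starts), end = as.integer(ends),
             strand = strand, stringsAsFactors = FALSE)
}

# a three-exon coding transcript: exons [o,o+600), [o+1500,o+2100),
# [o+3000,o+3600)
coding_tx <- function(id = "CT1", o = 10000L, strand = "+", chrom = "chr1") {
  tx(id, o + c(0L, 1500L, 3000L), o + c(600L, 2100L, 3600L),
     strand = strand, biotype = "coding", chrom = chrom)
}

circ_row <- function(id, start, end, strand = "+", chrom = "chr1", ...) {
  counts <- list(...)
  base <- data.frame(circ_id = id, chrom = chrom, start = as.integer(start),
                     end = as.integer(end), strand = strand,
                     stringsAsFactors = FALSE)
  if (length(counts) > 0) base <- cbind(base, as.data.frame(counts))
  base
}

random_pair_table <- function(n, sources, mirnas) {
  data.frame(source_id = sample(sources, n, replace = TRUE),
             mirna_id = sample(mirnas, n, replace = TRUE),
             score = round(runif(n, 0, 100), 2),
             stringsAsFactors = FALSE)
}

# matrix + design shortcut: 3 fat and 3 lean columns
expr_mat <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- names(default_design())
  m
}
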