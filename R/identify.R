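#' Filter lncRNA candidate transcripts
#'
#' Applies the standard candidate screen: transcripts annotated as known mRNAs
#' (`coding`) or other non-coding RNA classes (`other_ncRNA`, e.g. pseudogene,
#' pre-miRNA, tRNA) are removed; of the remaining candidates, those with fewer
#' than `min_exons` exons or a spliced length (summed exon lengths) strictly
#' shorter than `min_length` bp are dropped. A candidate of exactly
#' `min_length` bp is kept. Input order is preserved.
#'
#' @param exons exon-level transcript table.
#' @param min_exons minimum exon count (default 2).
#' @param min_length minimum spliced length in bp (default 200).
#' @return character vector of retained transcript ids, in input order.
#' @export
filter_candidates <- function(exons, min_exons = 2L, min_length = 200L) {
  if (nrow(exons) == 0) return(character())
  validate_transcripts(exons)
  tx <- transcript_summary(exons)
  keep <- tx$biotype == "lncRNA_candidate" &
    tx$n_exons >= min_exons &
    tx$tx_length >= min_length
  tx$transcript_id[keep]
}

#' Coding-potential consensus over four assessors
#'
#' A candidate is accepted as a lncRNA only if all four coding-potential
#' assessors (CNCI, CPC, PFAM, CPAT) call it noncoding, i.e. the result is the
#' intersection of the four per-tool noncoding sets.
#'
#' @param candidates character vector of candidate feature ids.
#' @param verdicts verdict table (see [read_verdicts()]).
#' @return character vector of retained ids, in `candidates` order.
#' @export
coding_consensus <- function(candidates, verdicts) {
  validate_verdicts(verdicts)
  missing <- setdiff(candidates, verdicts$feature_id)
  if (length(missing) > 0)
    stop("candidates lack coding-potential verdicts: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ..." else "")
  idx <- match(candidates, verdicts$feature_id)
  all_nc <- Reduce(`&`, lapply(VERDICT_TOOLS, function(tool)
    verdicts[[tool]][idx] == "noncoding"))
  candidates[all_nc]
}
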