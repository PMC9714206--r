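#' @importFrom methods as
#' @importFrom stats pt setNames cor p.adjust dhyper rnorm runif var rlnorm
#' @importFrom utils read.delim write.table head
NULL

VALID_BIOTYPES <- c("coding", "lncRNA_candidate", "other_ncRNA")
LNC_CLASSES <- c("exon_sense_overlapping", "intron_sense_overlapping",
                 "intronic_antisense", "natural_antisense",
                 "bidirectional", "intergenic")
CIRC_CLASSES <- c("exonic", "intronic", "intergenic",
                  "sense_overlapping", "antisense")

#' Validate an exon-level transcript table
#'
#' Transcript sets are plain data.frames with one row per exon and columns
#' `transcript_id`, `gene_id`, `biotype`, `chrom`, `start`, `end`, `strand`
#' (plus an optional `extra` column of opaque GTF attribute text). Coordinates
#' are 0-based half-open throughout the package; conversion to/from the GTF
#' 1-based inclusive convention happens exactly once, in [read_gtf()] and
#' [write_gtf()].
#'
#' @param exons data.frame of exons.
#' @return The input, invisibly, after validation.
#' @export
validate_transcripts <- function(exons) {
  required <- c("transcript_id", "gene_id", "biotype", "chrom",
                "start", "end", "strand")
  missing <- setdiff(required, names(exons))
  if (length(missing) > 0)
    stop("transcript table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(exons) == 0) return(invisible(exons))
  if (any(exons$start < 0) || any(exons$end <= exons$start))
    stop("invalid exon coordinates: require 0 <= start < end")
  if (!all(exons$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(exons$biotype %in% VALID_BIOTYPES))
    stop("unknown biotype values: ",
         paste(setdiff(unique(exons$biotype), VALID_BIOTYPES), collapse = ", "))
  per_tx <- split(exons, exons$transcript_id)
  for (tx in per_tx) {
    if (length(unique(tx$chrom)) != 1 || length(unique(tx$strand)) != 1)
      stop("transcript ", tx$transcript_id[1],
           " mixes chromosomes or strands across exons")
    o <- order(tx$start)
    s <- tx$start[o]; e <- tx$end[o]
    if (length(s) > 1 && any(s[-1] < e[-length(e)]))
      stop("transcript ", tx$transcript_id[1], " has overlapping exons")
  }
  invisible(exons)
}

#' Summarise transcripts to one row per transcript
#'
#' @param exons exon-level transcript table (see [validate_transcripts()]).
#' @return data.frame with one row per transcript: `transcript_id`, `gene_id`,
#'   `biotype`, `chrom`, `strand`, `span_start`, `span_end` (transcript span,
#'   half-open), `n_exons` and `tx_length` (sum of exon lengths, the spliced
#'   transcript length used by the 200-bp candidate filter).
#' @export
transcript_summary <- function(exons) {
  if (nrow(exons) == 0) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      biotype = character(), chrom = character(),
                      strand = character(), span_start = integer(),
                      span_end = integer(), n_exons = integer(),
                      tx_length = integer(), stringsAsFactors = FALSE))
  }
  ids <- unique(exons$transcript_id)
  idx <- match(ids, exons$transcript_id)
  f <- factor(exons$transcript_id, levels = ids)
  data.frame(
    transcript_id = ids,
    gene_id  = exons$gene_id[idx],
    biotype  = exons$biotype[idx],
    chrom    = exons$chrom[idx],
    strand   = exons$strand[idx],
    span_start = as.integer(tapply(exons$start, f, min)),
    span_end   = as.integer(tapply(exons$end, f, max)),
    n_exons    = as.integer(tapply(exons$start, f, length)),
    tx_length  = as.integer(tapply(exons$end - exons$start, f, sum)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Canonical ordering of an exon table
#'
#' Sorts by transcript id, then exon start, so two representations of the same
#' transcript set compare equal. Used by the GTF round-trip identity.
#'
#' @param exons exon-level transcript table.
#' @return The reordered data.frame (row names dropped).
#' @export
canonical_exons <- function(exons) {
  cols <- c("transcript_id", "gene_id", "biotype", "chrom",
            "start", "end", "strand")
  out <- exons[order(exons$transcript_id, exons$start), cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transcription start site (0-based position of the first transcribed base)
#'
#' @param span_start,span_end transcript span (half-open).
#' @param strand "+" or "-".
#' @return Integer position: `span_start` on "+", `span_end - 1` on "-".
#' @keywords internal
tss_position <- function(span_start, span_end, strand) {
  ifelse(strand == "+", span_start, span_end - 1L)
}

#' Validate a back-splice junction table
#'
#' @param junctions data.frame with columns `circ_id`, `chrom`, `start`, `end`
#'   (0-based half-open back-splice span), `strand`, plus one integer count
#'   column per sample.
#' @param samples character vector of expected sample names; when given, each
#'   must be a column.
#' @return The input, invisibly.
#' @export
validate_junctions <- function(junctions, samples = NULL) {
  required <- c("circ_id", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(junctions))
  if (length(missing) > 0)
    stop("junction table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(junctions$circ_id))
    stop("duplicate circ_id in junction table")
  if (nrow(junctions) > 0) {
    if (any(junctions$start < 0) || any(junctions$end <= junctions$start))
      stop("invalid junction coordinates: require 0 <= start < end")
    if (!all(junctions$strand %in% c("+", "-")))
      stop("junction strand must be '+' or '-' (unknown strands are rejected)")
  }
  if (!is.null(samples)) {
    absent <- setdiff(samples, names(junctions))
    if (length(absent) > 0)
      stop("junction table lacks count columns for samples: ",
           paste(absent, collapse = ", "))
    cnt <- as.matrix(junctions[, samples, drop = FALSE])
    if (nrow(junctions) > 0 && (any(is.na(cnt)) || any(cnt < 0)))
      stop("junction counts must be non-negative")
  }
  invisible(junctions)
}

#' Validate a two-group design
#'
#' @param design named character vector mapping sample name to group
#'   ("fat" or "lean").
#' @param mat optional matrix whose columns must equal the design samples.
#' @return The design, invisibly.
#' @export
validate_design <- function(design, mat = NULL) {
  if (is.null(names(design)) || any(names(design) == ""))
    stop("design must be a named vector (sample -> group)")
  if (!all(design %in% c("fat", "lean")))
    stop("design groups must be 'fat' or 'lean'")
  if (!any(design == "fat") || !any(design == "lean"))
    stop("both groups must be non-empty")
  if (!is.null(mat)) {
    if (!all(names(design) %in% colnames(mat)))
      stop("design samples missing from matrix columns: ",
           paste(setdiff(names(design), colnames(mat)), collapse = ", "))
  }
  invisible(design)
}
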