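#' @importFrom GenomicRanges GRanges findOverlaps invertStrand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# GRanges from 0-based half-open coordinates.
to_granges <- function(chrom, start, end, strand) {
  GRanges(seqnames = chrom, ranges = IRanges(start + 1L, end), strand = strand)
}

#' Build an interval-queryable index of a coding annotation
#'
#' Collects the coding transcripts of an annotation into exon, intron and
#' transcript-span interval sets used by the positional classifiers.
#'
#' @param exons exon-level transcript table; only rows with
#'   `biotype == "coding"` are used.
#' @return list with elements `tx` (per-transcript summary), `exons`,
#'   `introns`, `spans` (GRanges, each carrying a `tx` metadata column holding
#'   the row index into `tx`).
#' @export
build_coding_index <- function(exons) {
  validate_transcripts(exons)
  cod <- exons[exons$biotype == "coding", , drop = FALSE]
  tx <- transcript_summary(cod)
  exon_gr <- to_granges(cod$chrom, cod$start, cod$end, cod$strand)
  exon_gr$tx <- match(cod$transcript_id, tx$transcript_id)

  # introns: gaps between consecutive exons of each transcript
  intr <- list()
  if (nrow(cod) > 0) {
    for (i in seq_len(nrow(tx))) {
      e <- cod[cod$transcript_id == tx$transcript_id[i], , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) > 1) {
        intr[[length(intr) + 1L]] <- data.frame(
          chrom = tx$chrom[i],
          start = e$end[-nrow(e)], end = e$start[-1],
          strand = tx$strand[i], tx = i, stringsAsFactors = FALSE)
      }
    }
  }
  intr <- if (length(intr) > 0) do.call(rbind, intr) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), tx = integer())
  intron_gr <- to_granges(intr$chrom, intr$start, intr$end, intr$strand)
  intron_gr$tx <- intr$tx

  span_gr <- to_granges(tx$chrom, tx$span_start, tx$span_end, tx$strand)
  span_gr$tx <- seq_len(nrow(tx))

  list(tx = tx, exons = exon_gr, introns = intron_gr, spans = span_gr)
}

#' Classify lncRNAs by genomic position relative to coding transcripts
#'
#' Assigns each lncRNA exactly one of six positional classes, evaluated in a
#' fixed priority order so that exon-level evidence outranks intron-level and
#' sense outranks antisense:
#' \enumerate{
#'   \item `exon_sense_overlapping` - a lncRNA exon overlaps a coding exon on
#'     the same strand;
#'   \item `intron_sense_overlapping` - the lncRNA span overlaps a coding
#'     intron on the same strand;
#'   \item `natural_antisense` - the lncRNA span overlaps a coding exon on the
#'     opposite strand;
#'   \item `intronic_antisense` - the lncRNA span overlaps a coding intron on
#'     the opposite strand;
#'   \item `bidirectional` - no overlap, opposite strands, divergent
#'     (head-to-head) orientation, TSS-to-TSS distance at most
#'     `bidirectional_window` bp;
#'   \item `intergenic` - none of the above.
#' }
#' Overlap means at least one shared base under half-open semantics.
#'
#' @param lnc_exons exon-level table of the lncRNAs to classify (biotype must
#'   not be `coding`).
#' @param index coding index from [build_coding_index()].
#' @param bidirectional_window TSS-to-TSS window in bp (default 1000).
#' @return data.frame with columns `transcript_id` and `class`.
#' @export
classify_lncrnas <- function(lnc_exons, index, bidirectional_window = 1000L) {
  validate_transcripts(lnc_exons)
  if (any(lnc_exons$biotype == "coding"))
    stop("cannot classify coding transcripts as lncRNAs")
  lnc <- transcript_summary(lnc_exons)
  n <- nrow(lnc)
  if (n == 0)
    return(data.frame(transcript_id = character(), class = character(),
                      stringsAsFactors = FALSE))

  exon_gr <- to_granges(lnc_exons$chrom, lnc_exons$start, lnc_exons$end,
                        lnc_exons$strand)
  exon_of <- match(lnc_exons$transcript_id, lnc$transcript_id)
  span_gr <- to_granges(lnc$chrom, lnc$span_start, lnc$span_end, lnc$strand)

  hit_ids <- function(q, subject, of = seq_len(n)) {
    h <- findOverlaps(q, subject)
    unique(of[queryHits(h)])
  }

  cls <- rep(NA_character_, n)
  assign_class <- function(ids, label) {
    ids <- ids[is.na(cls[ids])]
    cls[ids] <<- label
    invisible(NULL)
  }
  assign_class(hit_ids(exon_gr, index$exons, exon_of), "exon_sense_overlapping")
  assign_class(hit_ids(span_gr, index$introns), "intron_sense_overlapping")
  assign_class(hit_ids(invertStrand(span_gr), index$exons), "natural_antisense")
  assign_class(hit_ids(invertStrand(span_gr), index$introns), "intronic_antisense")

  # bidirectional: search opposite-strand coding spans within the window
  rest <- which(is.na(cls))
  if (length(rest) > 0 && length(index$spans) > 0) {
    q <- span_gr[rest]
    qwide <- to_granges(lnc$chrom[rest],
                        pmax(0L, lnc$span_start[rest] - bidirectional_window),
                        lnc$span_end[rest] + bidirectional_window,
                        lnc$strand[rest])
    h <- findOverlaps(invertStrand(qwide), index$spans)
    if (length(h) > 0) {
      qi <- rest[queryHits(h)]
      ci <- index$spans$tx[subjectHits(h)]
      ok <- is_divergent_pair(
        lnc$span_start[qi], lnc$span_end[qi], lnc$strand[qi],
        index$tx$span_start[ci], index$tx$span_end[ci], index$tx$strand[ci],
        bidirectional_window)
      assign_class(unique(qi[ok]), "bidirectional")
    }
  }
  cls[is.na(cls)] <- "intergenic"
  data.frame(transcript_id = lnc$transcript_id, class = cls,
             stringsAsFactors = FALSE)
}

# Divergent (head-to-head) test for opposite-strand, same-chromosome pairs:
# spans disjoint, the minus-strand partner entirely upstream (left) of the
# plus-strand partner, TSS-to-TSS distance <= window.
is_divergent_pair <- function(a_start, a_end, a_strand,
                              b_start, b_end, b_strand, window) {
  opposite <- a_strand != b_strand
  m_end   <- ifelse(a_strand == "-", a_end, b_end)
  p_start <- ifelse(a_strand == "+", a_start, b_start)
  disjoint_divergent <- m_end <= p_start
  tss_dist <- p_start - (m_end - 1L)
  opposite & disjoint_divergent & tss_dist <= window
}

#' Classify circRNAs by genomic position relative to coding transcripts
#'
#' Assigns each back-splice junction exactly one of five classes, in priority
#' order:
#' \enumerate{
#'   \item `exonic` - both back-splice boundaries fall within exons of one
#'     coding transcript on the same strand;
#'   \item `intronic` - the span lies entirely within a single intron of a
#'     same-strand coding transcript;
#'   \item `sense_overlapping` - the span overlaps a same-strand coding
#'     transcript but is neither exonic nor intronic;
#'   \item `antisense` - the span overlaps a coding transcript on the opposite
#'     strand only;
#'   \item `intergenic` - no coding-transcript overlap.
#' }
#'
#' @param junctions back-splice junction table (see [validate_junctions()]).
#' @param index coding index from [build_coding_index()].
#' @return data.frame with columns `circ_id` and `class`.
#' @export
classify_circrnas <- function(junctions, index) {
  validate_junctions(junctions)
  n <- nrow(junctions)
  if (n == 0)
    return(data.frame(circ_id = character(), class = character(),
                      stringsAsFactors = FALSE))
  span_gr <- to_granges(junctions$chrom, junctions$start, junctions$end,
                        junctions$strand)

  # exonic: boundary bases each inside an exon of the same transcript
  b1 <- to_granges(junctions$chrom, junctions$start, junctions$start + 1L,
                   junctions$strand)
  b2 <- to_granges(junctions$chrom, junctions$end - 1L, junctions$end,
                   junctions$strand)
  key <- function(point_gr) {
    h <- findOverlaps(point_gr, index$exons)
    paste(queryHits(h), index$exons$tx[subjectHits(h)])
  }
  exonic_idx <- as.integer(sub(" .*", "", intersect(key(b1), key(b2))))

  h_within <- findOverlaps(span_gr, index$introns, type = "within")
  h_sense <- findOverlaps(span_gr, index$spans)
  h_anti <- findOverlaps(invertStrand(span_gr), index$spans)

  cls <- rep(NA_character_, n)
  assign_class <- function(ids, label) {
    ids <- ids[is.na(cls[ids])]
    cls[ids] <- label
    cls
  }
  cls <- assign_class(unique(exonic_idx), "exonic")
  cls <- assign_class(unique(queryHits(h_within)), "intronic")
  cls <- assign_class(unique(queryHits(h_sense)), "sense_overlapping")
  cls <- assign_class(unique(queryHits(h_anti)), "antisense")
  cls[is.na(cls)] <- "intergenic"
  data.frame(circ_id = junctions$circ_id, class = cls, stringsAsFactors = FALSE)
}

#' Tabulate class counts and proportions
#'
#' @param classes data.frame from [classify_lncrnas()] or
#'   [classify_circrnas()].
#' @param levels the full class vocabulary (zero counts are kept).
#' @return data.frame with `class`, `n`, `proportion`.
#' @export
class_summary <- function(classes,
                          levels = if ("circ_id" %in% names(classes))
                            CIRC_CLASSES else LNC_CLASSES) {
  counts <- table(factor(classes$class, levels = levels))
  data.frame(class = names(counts), n = as.integer(counts),
             proportion = if (nrow(classes) > 0)
               as.numeric(counts) / nrow(classes) else rep(0, length(counts)),
             stringsAsFactors = FALSE)
}
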