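#' Read transcript models from a GTF file
#'
#' Parses `exon` features from a GTF (1-based inclusive coordinates) into the
#' package's exon-level transcript table (0-based half-open). Attribute keys
#' are matched permissively: `transcript_id`/`transcript` and `gene_id`/`gene`
#' are both accepted (synonym use is reported via [message()]). The biotype is
#' taken from the first of `biotype`, `transcript_biotype`, `gene_biotype`
#' present, defaulting to `coding` when absent; common annotation vocabularies
#' are mapped onto the package's three biotypes (`protein_coding`/`mRNA` to
#' `coding`, `lncRNA`/`lincRNA`/`antisense` to `lncRNA_candidate`, any other
#' non-coding label to `other_ncRNA`). All remaining attributes are kept as
#' opaque text in the `extra` column so [write_gtf()] can reproduce them.
#'
#' @param path path to a GTF file.
#' @return exon-level transcript data.frame (see [validate_transcripts()]),
#'   exons sorted by start within each transcript.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(empty_exons())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9))
    stop("malformed GTF line ", lineno[which(nf < 9)[1]],
         ": expected 9 tab-separated fields, got ", nf[which(nf < 9)[1]])
  m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9, byrow = TRUE)

  is_exon <- m[, 3] == "exon"
  if (!any(is_exon)) return(empty_exons())
  m <- m[is_exon, , drop = FALSE]
  lineno <- lineno[is_exon]

  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad) > 0)
    stop("malformed GTF line ", lineno[bad[1]], ": non-numeric coordinates")
  bad <- which(end1 < start1)
  if (length(bad) > 0)
    stop("invalid GTF line ", lineno[bad[1]], ": end (", end1[bad[1]],
         ") < start (", start1[bad[1]], ")")
  strand <- m[, 7]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0)
    stop("invalid GTF line ", lineno[bad[1]], ": strand must be '+' or '-'")

  att <- lapply(m[, 9], parse_gtf_attributes)
  pick <- function(a, keys) {
    for (k in keys) if (!is.null(a$kv[[k]])) return(a$kv[[k]])
    NA_character_
  }
  tx <- vapply(att, pick, character(1), keys = c("transcript_id", "transcript"))
  gn <- vapply(att, pick, character(1), keys = c("gene_id", "gene"))
  bt_raw <- vapply(att, pick, character(1),
                   keys = c("biotype", "transcript_biotype", "gene_biotype"))
  bad <- which(is.na(tx))
  if (length(bad) > 0)
    stop("GTF line ", lineno[bad[1]], ": no transcript_id attribute")
  bad <- which(is.na(gn))
  if (length(bad) > 0)
    stop("GTF line ", lineno[bad[1]], ": no gene_id attribute")
  syn <- vapply(att, function(a)
    (is.null(a$kv[["transcript_id"]]) && !is.null(a$kv[["transcript"]])) ||
    (is.null(a$kv[["gene_id"]]) && !is.null(a$kv[["gene"]])), logical(1))
  if (any(syn))
    message("read_gtf: accepted attribute-key synonyms (transcript/gene) on ",
            sum(syn), " line(s)")

  extra <- vapply(att, function(a) {
    drop <- c("transcript_id", "transcript", "gene_id", "gene",
              "biotype", "transcript_biotype", "gene_biotype")
    left <- a$pairs[!a$keys %in% drop]
    if (length(left) == 0) NA_character_ else paste(left, collapse = " ")
  }, character(1))

  exons <- data.frame(
    transcript_id = tx, gene_id = gn,
    biotype = normalize_biotype(bt_raw),
    chrom = m[, 1],
    start = start1 - 1L, end = end1,
    strand = strand, extra = extra,
    stringsAsFactors = FALSE
  )
  exons <- exons[order(match(exons$transcript_id, unique(exons$transcript_id)),
                       exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  validate_transcripts(exons)
  exons
}

empty_exons <- function() {
  data.frame(transcript_id = character(), gene_id = character(),
             biotype = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             extra = character(), stringsAsFactors = FALSE)
}

# Split one GTF attribute field into key/value pairs; values may be quoted.
parse_gtf_attributes <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  keys <- sub("^(\\S+)\\s.*$", "\\1", parts)
  vals <- sub("^\\S+\\s+", "", parts)
  vals <- gsub("^\"|\"$", "", vals)
  kv <- as.list(vals)
  names(kv) <- keys
  list(kv = kv, keys = keys, pairs = paste0(parts, ";"))
}

normalize_biotype <- function(x) {
  out <- rep("coding", length(x))
  known <- x %in% VALID_BIOTYPES
  out[known] <- x[known]
  lnc <- !known & x %in% c("lncRNA", "lincRNA", "antisense", "lnc_RNA")
  out[lnc] <- "lncRNA_candidate"
  other <- !known & !lnc & !is.na(x) &
    !x %in% c("protein_coding", "mRNA", "coding")
  out[other] <- "other_ncRNA"
  out
}

#' Write transcript models to a GTF file
#'
#' Emits one `exon` line per exon row, converting the internal 0-based
#' half-open coordinates back to GTF's 1-based inclusive convention. Output is
#' byte-stable for a fixed input ordering; `read_gtf(write_gtf(x))` restores
#' the transcript set exactly. Opaque attribute text in the `extra` column is
#' appended verbatim after the package-managed attributes.
#'
#' @param exons exon-level transcript table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path) {
  validate_transcripts(exons)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write GTF to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines("#gtf-version 2.2", con)
  if (nrow(exons) == 0) return(invisible(path))
  extra <- if ("extra" %in% names(exons)) exons$extra else
    rep(NA_character_, nrow(exons))
  attr_txt <- paste0(
    "gene_id \"", exons$gene_id, "\"; ",
    "transcript_id \"", exons$transcript_id, "\"; ",
    "biotype \"", exons$biotype, "\";",
    ifelse(is.na(extra) | !nzchar(extra), "", paste0(" ", extra))
  )
  writeLines(paste(exons$chrom, "lncirc", "exon",
                   exons$start + 1L, exons$end, ".", exons$strand, ".",
                   attr_txt, sep = "\t"), con)
  invisible(path)
}
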