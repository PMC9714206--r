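#' Read an expression matrix from TSV
#'
#' Expects a header row whose first column names the feature id and remaining
#' columns name samples; values must be numeric and non-negative. Duplicate
#' feature ids are rejected.
#'
#' @param path TSV path.
#' @param unit declared abundance unit, attached as the `"unit"` attribute
#'   ("FPKM" for lncRNA/mRNA, "CPM" for circRNA).
#' @return numeric matrix, features in rows, samples in columns.
#' @export
read_expression_matrix <- function(path, unit = c("FPKM", "CPM")) {
  unit <- match.arg(unit)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression matrix needs a feature column and >=1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature id in expression matrix: ",
         ids[duplicated(ids)][1])
  vals <- df[, -1, drop = FALSE]
  nonnum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonnum))
    stop("non-numeric cell(s) in expression matrix column(s): ",
         paste(names(vals)[nonnum], collapse = ", "))
  mat <- as.matrix(vals)
  if (any(is.na(mat))) stop("missing values in expression matrix")
  if (any(mat < 0)) stop("negative values in expression matrix")
  rownames(mat) <- ids
  attr(mat, "unit") <- unit
  mat
}

#' Write an expression matrix to TSV
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @param id_column header name of the feature-id column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, id_column = "feature_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write_tsv(df, path)
}

#' Read a miRNA pair table
#'
#' Three tab-separated columns: source id (lncRNA, circRNA or mRNA), miRNA id,
#' and a prediction score on the 0-100 scale used by miRDB-style predictors.
#'
#' @param path TSV path (with header).
#' @return data.frame with columns `source_id`, `mirna_id`, `score`.
#' @export
read_pair_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 3) stop("pair table must have exactly 3 columns, got ", ncol(df))
  names(df) <- c("source_id", "mirna_id", "score")
  if (!is.numeric(df$score)) stop("non-numeric score column in pair table")
  validate_pairs(df)
  df
}

#' Validate a miRNA pair table
#' @param pairs data.frame with `source_id`, `mirna_id`, `score`.
#' @return The input, invisibly.
#' @export
validate_pairs <- function(pairs) {
  required <- c("source_id", "mirna_id", "score")
  missing <- setdiff(required, names(pairs))
  if (length(missing) > 0)
    stop("pair table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(pairs) > 0 && (any(is.na(pairs$score)) ||
                          any(pairs$score < 0) || any(pairs$score > 100)))
    stop("pair scores must lie in [0, 100]")
  invisible(pairs)
}

#' Read a subcellular localization table
#'
#' @param path two-column TSV (feature_id, localization) with header;
#'   localization must be `cytoplasm` or `nucleus`.
#' @return named character vector, feature id -> localization.
#' @export
read_localization <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 2) stop("localization table must have 2 columns")
  loc <- as.character(df[[2]])
  if (!all(loc %in% c("cytoplasm", "nucleus")))
    stop("localization must be 'cytoplasm' or 'nucleus'")
  if (anyDuplicated(df[[1]])) stop("duplicate feature id in localization table")
  setNames(loc, as.character(df[[1]]))
}

#' Read a coding-potential verdict table
#'
#' One row per candidate feature and one column per assessor (CNCI, CPC, PFAM,
#' CPAT), each cell `coding` or `noncoding`.
#'
#' @param path TSV path with header `feature_id`, `CNCI`, `CPC`, `PFAM`, `CPAT`.
#' @return data.frame with those columns.
#' @export
read_verdicts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "feature_id"
  validate_verdicts(df)
  df
}

VERDICT_TOOLS <- c("CNCI", "CPC", "PFAM", "CPAT")

#' Validate a verdict table
#' @param verdicts data.frame with `feature_id` and the four tool columns.
#' @return The input, invisibly.
#' @export
validate_verdicts <- function(verdicts) {
  missing <- setdiff(c("feature_id", VERDICT_TOOLS), names(verdicts))
  if (length(missing) > 0)
    stop("verdict table lacks columns: ", paste(missing, collapse = ", "))
  for (tool in VERDICT_TOOLS) {
    v <- verdicts[[tool]]
    if (!all(v %in% c("coding", "noncoding")))
      stop("verdicts for ", tool, " must be 'coding' or 'noncoding'")
  }
  if (anyDuplicated(verdicts$feature_id))
    stop("duplicate feature id in verdict table")
  invisible(verdicts)
}

#' Read back-splice junction records
#'
#' BED-like TSV (0-based half-open span) with header columns `circ_id`,
#' `chrom`, `start`, `end`, `strand` followed by one junction-read count
#' column per sample.
#'
#' @param path TSV path.
#' @param samples expected sample names (checked if given).
#' @return data.frame of junctions (see [validate_junctions()]).
#' @export
read_junctions <- function(path, samples = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_junctions(df, samples)
  df
}

#' Write a data.frame as TSV (atomic: write to temp file then rename)
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!file.rename(tmp, path)) stop("cannot move temporary file onto ", path)
  invisible(path)
}
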