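#' Presence filter for expression matrices
#'
#' A feature is retained when it has a positive value in at least
#' `min_positive_samples` samples of the fat group OR of the lean group. The
#' default of 3 is the "> 0 in more than 2 samples in either group" rule for a
#' 3 vs 3 design; the count is exposed because that wording is ambiguous for
#' other group sizes.
#'
#' @param mat expression matrix (features x samples).
#' @param design named group vector (see [validate_design()]).
#' @param min_positive_samples required positive-sample count within a group.
#' @return character vector of retained feature ids, in matrix order.
#' @export
presence_filter <- function(mat, design, min_positive_samples = 3L) {
  validate_design(design, mat)
  sizes <- table(design)
  if (min_positive_samples > max(sizes))
    stop("min_positive_samples (", min_positive_samples,
         ") exceeds the largest group size (", max(sizes), ")")
  fat <- names(design)[design == "fat"]
  lean <- names(design)[design == "lean"]
  n_fat <- rowSums(mat[, fat, drop = FALSE] > 0)
  n_lean <- rowSums(mat[, lean, drop = FALSE] > 0)
  rownames(mat)[n_fat >= min_positive_samples | n_lean >= min_positive_samples]
}

#' Expressed-circRNA filter on junction reads
#'
#' A circRNA counts as expressed when its junction-read count reaches
#' `min_reads` in at least one sample. The default of 2 is the strict reading
#' of "junction reads over than one" (a single read is not over one).
#'
#' @param junctions junction table (see [validate_junctions()]).
#' @param samples sample names (count columns).
#' @param min_reads per-sample junction-read threshold (default 2).
#' @return character vector of expressed circ ids, in input order.
#' @export
circ_expressed <- function(junctions, samples, min_reads = 2L) {
  validate_junctions(junctions, samples)
  if (nrow(junctions) == 0) return(character())
  cnt <- as.matrix(junctions[, samples, drop = FALSE])
  junctions$circ_id[apply(cnt, 1, max) >= min_reads]
}

#' Log2 fold change with a pseudocount
#'
#' `log2((mean_fat + eps) / (mean_lean + eps))`. The pseudocount keeps
#' line-specific features (one group all zero) at a large finite fold change.
#' Antisymmetric under group swap.
#'
#' @param mean_fat,mean_lean non-negative group means.
#' @param pseudocount eps >= 0 (default 0.01; 0 is allowed only when both
#'   means are positive).
#' @return log2 fold change (fat vs lean).
#' @export
log2_fold_change <- function(mean_fat, mean_lean, pseudocount = 0.01) {
  if (any(mean_fat < 0) || any(mean_lean < 0))
    stop("group means must be non-negative")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(mean_fat == 0 | mean_lean == 0))
    stop("pseudocount 0 requires strictly positive means")
  log2((mean_fat + pseudocount) / (mean_lean + pseudocount))
}

#' Two-sample test on log2(x + 1) values
#'
#' The screening statistic used in place of a count-model engine: per feature,
#' a two-sample t statistic on `log2(value + 1)` with a two-sided p-value.
#' Group variances are pooled by default (`var_equal = TRUE`): abundances are
#' modeled as homoscedastic on the log scale, and with three replicates per
#' group the pooled test is calibrated at its nominal level where the
#' Welch-Satterthwaite correction is markedly conservative. Set
#' `var_equal = FALSE` for the Welch form. When both groups have zero variance
#' the statistic is undefined; by convention p = 1 if the group means are
#' equal (no signal) and p = 0 otherwise (infinite separation).
#'
#' @param values numeric vector (one feature) or matrix (features x samples).
#' @param design named group vector over the value columns.
#' @param var_equal pool the group variances (default) or use Welch's
#'   approximation.
#' @return numeric vector of p-values (length = number of features).
#' @export
de_test <- function(values, design, var_equal = TRUE) {
  if (is.null(dim(values)))
    values <- matrix(values, nrow = 1,
                     dimnames = list(NULL, names(values)))
  validate_design(design, values)
  fat <- names(design)[design == "fat"]
  lean <- names(design)[design == "lean"]
  if (length(fat) < 2 || length(lean) < 2)
    stop("each group needs at least 2 samples")
  y <- log2(values + 1)
  y1 <- y[, fat, drop = FALSE]; y2 <- y[, lean, drop = FALSE]
  n1 <- length(fat); n2 <- length(lean)
  m1 <- rowMeans(y1); m2 <- rowMeans(y2)
  v1 <- rowSums((y1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((y2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
  } else {
    se2 <- v1 / n1 + v2 / n2
  }
  p <- numeric(nrow(y))
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  if (any(!degenerate)) {
    i <- !degenerate
    tstat <- (m1[i] - m2[i]) / sqrt(se2[i])
    df <- if (var_equal) rep(n1 + n2 - 2, sum(i)) else
      se2[i]^2 / (ifelse(v1[i] > 0, (v1[i] / n1)^2 / (n1 - 1), 0) +
                  ifelse(v2[i] > 0, (v2[i] / n2)^2 / (n2 - 1), 0))
    p[i] <- 2 * pt(-abs(tstat), df)
  }
  unname(p)
}

#' Differential-expression screen with line-specificity flags
#'
#' For every feature computes the pseudocounted log2 fold change (fat vs
#' lean), the Welch p-value from [de_test()], a regulation status (`up` when
#' `log2fc >= lfc_threshold` and `p < alpha`; `down` when
#' `log2fc <= -lfc_threshold` and `p < alpha`; otherwise `ns`) and a
#' line-specificity flag: `fat_only` when every lean value is zero and at
#' least one fat value is positive, `lean_only` symmetrically, `absent` when
#' all values are zero, `shared` otherwise. Raw p-values are screened, as is
#' conventional for this design; a BH-adjusted column is added when
#' `adjust = TRUE`.
#'
#' @param mat expression matrix (already presence-filtered).
#' @param design named group vector.
#' @param lfc_threshold absolute log2 fold-change threshold (default 1).
#' @param alpha p-value threshold (default 0.05).
#' @param pseudocount fold-change pseudocount (default 0.01).
#' @param adjust also compute BH-adjusted q-values (off by default; the screen
#'   thresholds raw p either way).
#' @return data.frame with columns `feature_id`, `mean_fat`, `mean_lean`,
#'   `log2fc`, `p_value`, (`q_value`,) `status`, `specificity`.
#' @export
screen_de <- function(mat, design, lfc_threshold = 1, alpha = 0.05,
                      pseudocount = 0.01, adjust = FALSE) {
  validate_design(design, mat)
  fat <- names(design)[design == "fat"]
  lean <- names(design)[design == "lean"]
  mf <- rowMeans(mat[, fat, drop = FALSE])
  ml <- rowMeans(mat[, lean, drop = FALSE])
  lfc <- log2_fold_change(mf, ml, pseudocount)
  p <- de_test(mat, design)
  status <- rep("ns", nrow(mat))
  status[lfc >= lfc_threshold & p < alpha] <- "up"
  status[lfc <= -lfc_threshold & p < alpha] <- "down"
  any_fat <- rowSums(mat[, fat, drop = FALSE] > 0) > 0
  any_lean <- rowSums(mat[, lean, drop = FALSE] > 0) > 0
  specificity <- rep("shared", nrow(mat))
  specificity[any_fat & !any_lean] <- "fat_only"
  specificity[!any_fat & any_lean] <- "lean_only"
  specificity[!any_fat & !any_lean] <- "absent"
  out <- data.frame(feature_id = rownames(mat), mean_fat = unname(mf),
                    mean_lean = unname(ml), log2fc = unname(lfc),
                    p_value = p, status = status, specificity = specificity,
                    stringsAsFactors = FALSE)
  if (adjust) out$q_value <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Junction counts to a counts-per-million matrix
#'
#' @param junctions junction table.
#' @param samples sample names.
#' @return CPM matrix (circ features x samples); columns with zero total reads
#'   yield zero CPM.
#' @export
junctions_to_cpm <- function(junctions, samples) {
  validate_junctions(junctions, samples)
  cnt <- as.matrix(junctions[, samples, drop = FALSE])
  rownames(cnt) <- junctions$circ_id
  totals <- colSums(cnt)
  cpm <- sweep(cnt, 2, ifelse(totals > 0, totals, 1), "/") * 1e6
  cpm[, totals == 0] <- 0
  attr(cpm, "unit") <- "CPM"
  cpm
}
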