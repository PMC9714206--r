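#' Evaluate code under a temporary RNG seed
#'
#' All generators are pure functions of (seed, parameters): they seed the RNG
#' locally and restore the caller's RNG state on exit, so repeated calls are
#' byte-identical and do not disturb surrounding code.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# A three-exon coding "anchor" transcript at a given offset:
# exons [o, o+600), [o+1500, o+2100), [o+3000, o+3600).
anchor_exons <- function(offset, strand, tx_id, gene_id, chrom) {
  data.frame(transcript_id = tx_id, gene_id = gene_id, biotype = "coding",
             chrom = chrom,
             start = offset + c(0L, 1500L, 3000L),
             end = offset + c(600L, 2100L, 3600L),
             strand = strand, stringsAsFactors = FALSE)
}

flip <- function(strand) ifelse(strand == "+", "-", "+")

# Exons of a planted lncRNA constructed to satisfy exactly one positional
# class relative to its private anchor (anchor at `o`, strand `s`).
planted_lnc_exons <- function(class, o, s, tx_id, gene_id, chrom) {
  geom <- switch(class,
    exon_sense_overlapping = list(starts = c(300L, 950L),
                                  ends = c(900L, 1250L), strand = s),
    intron_sense_overlapping = list(starts = c(650L, 900L),
                                    ends = c(800L, 1100L), strand = s),
    natural_antisense = list(starts = c(1600L, 1850L),
                             ends = c(1800L, 2050L), strand = flip(s)),
    intronic_antisense = list(starts = c(2150L, 2400L),
                              ends = c(2300L, 2600L), strand = flip(s)),
    bidirectional =
      if (s == "+") list(starts = c(-999L, -799L), ends = c(-849L, -599L),
                         strand = "-")
      else list(starts = c(4199L, 4399L), ends = c(4349L, 4599L),
                strand = "+"),
    intergenic = list(starts = c(0L, 300L), ends = c(200L, 500L), strand = s),
    stop("unknown lncRNA class: ", class))
  data.frame(transcript_id = tx_id, gene_id = gene_id,
             biotype = "lncRNA_candidate", chrom = chrom,
             start = o + geom$starts, end = o + geom$ends,
             strand = geom$strand, stringsAsFactors = FALSE)
}

# Back-splice span of a planted circRNA relative to its anchor.
planted_circ_span <- function(class, o, s) {
  switch(class,
    exonic = list(start = o, end = o + 2100L, strand = s),
    intronic = list(start = o + 700L, end = o + 1400L, strand = s),
    sense_overlapping = list(start = o + 300L, end = o + 1200L, strand = s),
    antisense = list(start = o + 1600L, end = o + 2000L, strand = flip(s)),
    intergenic = list(start = o, end = o + 800L, strand = s),
    stop("unknown circRNA class: ", class))
}

#' Generate a synthetic annotation with planted positional classes
#'
#' Places features in disjoint, widely spaced genomic slots so every planted
#' lncRNA/circRNA satisfies exactly its intended class under the classifier's
#' priority rules. Classes needing a coding partner get a private three-exon
#' "anchor" transcript in their slot; the remaining coding transcripts are
#' placed as background in their own slots. Optional decoy candidates exercise
#' the identification filters: mono-exonic and short (< 200 bp) candidates,
#' and `other_ncRNA` transcripts.
#'
#' @param seed integer seed.
#' @param n_coding total number of coding transcripts (anchors plus
#'   background); must be at least the number of anchors required.
#' @param n_lnc_per_class planted lncRNAs per positional class (6 classes).
#' @param n_circ_per_class planted circRNAs per positional class (5 classes).
#' @param n_decoy_monoexonic,n_decoy_short,n_other_ncrna decoy counts.
#' @param chrom chromosome name.
#' @param slot_bp slot width in bp (features in different slots are separated
#'   by more than any classification or cis window when `slot_bp` is large).
#' @param chrom_length optional chromosome length; an error is raised when the
#'   slots do not fit.
#' @return list with `exons` (full annotation), `junctions` (planted circRNA
#'   spans, no counts), and `truth` (data.frames `lnc_classes`,
#'   `circ_classes`, plus `decoys`).
#' @export
make_annotation <- function(seed, n_coding = 60L, n_lnc_per_class = 10L,
                            n_circ_per_class = 6L,
                            n_decoy_monoexonic = 0L, n_decoy_short = 0L,
                            n_other_ncrna = 0L,
                            chrom = "chr1", slot_bp = 20000L,
                            chrom_length = NULL) {
  n_lnc <- 6L * n_lnc_per_class
  n_circ <- 5L * n_circ_per_class
  anchors_needed <- 5L * n_lnc_per_class + 4L * n_circ_per_class
  if (n_coding < anchors_needed)
    stop("n_coding (", n_coding, ") smaller than the ", anchors_needed,
         " anchors required by the planted classes")
  n_background <- n_coding - anchors_needed
  n_slots <- n_lnc + n_circ + n_background +
    n_decoy_monoexonic + n_decoy_short + n_other_ncrna
  needed_len <- (n_slots + 1L) * slot_bp
  if (!is.null(chrom_length) && chrom_length < needed_len)
    stop("infeasible packing: ", n_slots, " slots of ", slot_bp,
         " bp need a chrom_length of at least ", needed_len)

  with_seed(seed, {
    slot <- 0L
    next_offset <- function() {
      slot <<- slot + 1L
      (slot - 1L) * slot_bp + 5000L
    }
    exon_list <- list()
    junc_list <- list()
    anchor_i <- 0L
    add_anchor <- function(o) {
      anchor_i <<- anchor_i + 1L
      s <- sample(c("+", "-"), 1)
      exon_list[[length(exon_list) + 1L]] <<- anchor_exons(
        o, s, sprintf("TXA_%04d", anchor_i), sprintf("GENA_%04d", anchor_i),
        chrom)
      s
    }

    lnc_truth <- data.frame(transcript_id = character(), class = character(),
                            stringsAsFactors = FALSE)
    for (cls in LNC_CLASSES) {
      for (i in seq_len(n_lnc_per_class)) {
        o <- next_offset()
        s <- if (cls == "intergenic") sample(c("+", "-"), 1) else add_anchor(o)
        id <- sprintf("LNC_%s_%03d", cls, i)
        exon_list[[length(exon_list) + 1L]] <-
          planted_lnc_exons(cls, o, s, id, paste0("G", id), chrom)
        lnc_truth <- rbind(lnc_truth,
                           data.frame(transcript_id = id, class = cls,
                                      stringsAsFactors = FALSE))
      }
    }

    circ_truth <- data.frame(circ_id = character(), class = character(),
                             stringsAsFactors = FALSE)
    for (cls in CIRC_CLASSES) {
      for (i in seq_len(n_circ_per_class)) {
        o <- next_offset()
        s <- if (cls == "intergenic") sample(c("+", "-"), 1) else add_anchor(o)
        id <- sprintf("CIRC_%s_%03d", cls, i)
        span <- planted_circ_span(cls, o, s)
        junc_list[[length(junc_list) + 1L]] <- data.frame(
          circ_id = id, chrom = chrom, start = span$start, end = span$end,
          strand = span$strand, stringsAsFactors = FALSE)
        circ_truth <- rbind(circ_truth,
                            data.frame(circ_id = id, class = cls,
                                       stringsAsFactors = FALSE))
      }
    }

    decoys <- data.frame(transcript_id = character(), kind = character(),
                         stringsAsFactors = FALSE)
    for (i in seq_len(n_decoy_monoexonic)) {
      o <- next_offset()
      id <- sprintf("DECOY_MONO_%03d", i)
      exon_list[[length(exon_list) + 1L]] <- data.frame(
        transcript_id = id, gene_id = paste0("G", id),
        biotype = "lncRNA_candidate", chrom = chrom,
        start = o, end = o + 5000L, strand = sample(c("+", "-"), 1),
        stringsAsFactors = FALSE)
      decoys <- rbind(decoys, data.frame(transcript_id = id,
                                         kind = "monoexonic",
                                         stringsAsFactors = FALSE))
    }
    for (i in seq_len(n_decoy_short)) {
      o <- next_offset()
      id <- sprintf("DECOY_SHORT_%03d", i)
      exon_list[[length(exon_list) + 1L]] <- data.frame(
        transcript_id = id, gene_id = paste0("G", id),
        biotype = "lncRNA_candidate", chrom = chrom,
        start = o + c(0L, 150L), end = o + c(100L, 249L),
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      decoys <- rbind(decoys, data.frame(transcript_id = id, kind = "short",
                                         stringsAsFactors = FALSE))
    }
    for (i in seq_len(n_other_ncrna)) {
      o <- next_offset()
      id <- sprintf("OTHERNC_%03d", i)
      exon_list[[length(exon_list) + 1L]] <- data.frame(
        transcript_id = id, gene_id = paste0("G", id),
        biotype = "other_ncRNA", chrom = chrom,
        start = o + c(0L, 400L), end = o + c(300L, 700L),
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      decoys <- rbind(decoys, data.frame(transcript_id = id,
                                         kind = "other_ncRNA",
                                         stringsAsFactors = FALSE))
    }

    for (i in seq_len(n_background)) {
      o <- next_offset()
      n_ex <- sample(2:4, 1)
      widths <- sample(200:800, n_ex, replace = TRUE)
      gaps <- sample(200:1500, n_ex - 1, replace = TRUE)
      starts <- o + cumsum(c(0L, widths[-n_ex] + gaps))
      exon_list[[length(exon_list) + 1L]] <- data.frame(
        transcript_id = sprintf("TXB_%04d", i),
        gene_id = sprintf("GENB_%04d", i), biotype = "coding",
        chrom = chrom, start = as.integer(starts),
        end = as.integer(starts + widths),
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
    }

    exons <- do.call(rbind, exon_list)
    rownames(exons) <- NULL
    validate_transcripts(exons)
    junctions <- if (length(junc_list) > 0) do.call(rbind, junc_list) else
      data.frame(circ_id = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character(),
                 stringsAsFactors = FALSE)
    list(exons = exons, junctions = junctions,
         truth = list(lnc_classes = lnc_truth, circ_classes = circ_truth,
                      decoys = decoys))
  })
}

#' Generate a randomly placed annotation landscape
#'
#' Unlike [make_annotation()], features are scattered without reserved slots,
#' producing arbitrary overlap configurations. This is the stress fixture used
#' to compare the indexed classifiers against brute-force all-pairs scans.
#'
#' @param seed integer seed.
#' @param n_coding,n_lnc,n_circ feature counts.
#' @param chrom_length chromosome length in bp.
#' @param chrom chromosome name.
#' @return list with `exons` (coding + lncRNA candidates) and `junctions`.
#' @export
make_random_landscape <- function(seed, n_coding = 200L, n_lnc = 1000L,
                                  n_circ = 500L, chrom_length = 2000000L,
                                  chrom = "chr1") {
  with_seed(seed, {
    rand_tx <- function(id, gene, biotype, max_exons) {
      n_ex <- sample(seq_len(max_exons), 1)
      widths <- sample(80:800, n_ex, replace = TRUE)
      gaps <- if (n_ex > 1) sample(50:2000, n_ex - 1, replace = TRUE) else
        integer()
      starts <- cumsum(c(0L, widths[-n_ex] + gaps))
      span <- sum(widths) + sum(gaps)
      o <- sample.int(max(1L, chrom_length - span), 1)
      data.frame(transcript_id = id, gene_id = gene, biotype = biotype,
                 chrom = chrom, start = as.integer(o + starts),
                 end = as.integer(o + starts + widths),
                 strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
    }
    empty <- empty_exons()[, setdiff(names(empty_exons()), "extra")]
    coding <- if (n_coding > 0)
      do.call(rbind, lapply(seq_len(n_coding), function(i)
        rand_tx(sprintf("RTX_%04d", i), sprintf("RGEN_%04d", i), "coding",
                4L))) else empty
    lncs <- if (n_lnc > 0)
      do.call(rbind, lapply(seq_len(n_lnc), function(i)
        rand_tx(sprintf("RLNC_%04d", i), sprintf("GRLNC_%04d", i),
                "lncRNA_candidate", 3L))) else empty
    if (n_circ > 0) {
      width <- sample(150:4000, n_circ, replace = TRUE)
      start <- vapply(width, function(w)
        sample.int(chrom_length - w, 1), integer(1))
      junctions <- data.frame(
        circ_id = sprintf("RCIRC_%04d", seq_len(n_circ)), chrom = chrom,
        start = start, end = start + width,
        strand = sample(c("+", "-"), n_circ, replace = TRUE),
        stringsAsFactors = FALSE)
    } else {
      junctions <- data.frame(circ_id = character(), chrom = character(),
                              start = integer(), end = integer(),
                              strand = character(), stringsAsFactors = FALSE)
    }
    list(exons = rbind(coding, lncs), junctions = junctions)
  })
}

#' Generate an expression matrix with planted differential expression
#'
#' Null features are i.i.d. log-normal across samples (`meanlog = base_mu`,
#' `sdlog = sigma`). Planted `up`/`down` features multiply the fat/lean group
#' mean by `fold`; planted line-specific features are exactly zero in the
#' other group; planted `sparse` features have positive values in fewer
#' samples than the presence filter requires. Roles are assigned to shuffled
#' feature positions. The truth table records each feature's role and the
#' status/specificity the screen is expected to recover (a line-specific
#' feature is expected `up`/`down` through the pseudocount fold change).
#'
#' @param seed integer seed.
#' @param design named group vector (default 3 fat + 3 lean samples).
#' @param n_features total features.
#' @param n_up,n_down,n_fat_only,n_lean_only,n_sparse planted counts.
#' @param base_mu log-normal meanlog of the baseline abundance.
#' @param sigma log-normal sdlog (biological noise between replicates).
#' @param fold multiplicative group effect for up/down features (>= 2
#'   recommended for recovery with 3 replicates).
#' @param ids optional feature ids (default F00001...).
#' @return list with `mat` (matrix, unit attribute "FPKM") and `truth`
#'   (data.frame `feature_id`, `role`, `true_fold`, `expected_status`,
#'   `expected_specificity`).
#' @export
make_expression <- function(seed, design = default_design(),
                            n_features = 1000L, n_up = 19L, n_down = 11L,
                            n_fat_only = 0L, n_lean_only = 0L, n_sparse = 0L,
                            base_mu = 3, sigma = 0.15, fold = 4, ids = NULL) {
  validate_design(design)
  n_planted <- n_up + n_down + n_fat_only + n_lean_only + n_sparse
  if (n_planted > n_features)
    stop("planted feature counts exceed n_features")
  samples <- names(design)
  fat <- samples[design == "fat"]; lean <- samples[design == "lean"]
  if (is.null(ids)) ids <- sprintf("F%05d", seq_len(n_features))
  if (length(ids) != n_features) stop("ids length must equal n_features")

  with_seed(seed, {
    mat <- matrix(stats::rlnorm(n_features * length(samples),
                                meanlog = base_mu, sdlog = sigma),
                  nrow = n_features, dimnames = list(ids, samples))
    pos <- sample.int(n_features, n_planted)
    role <- rep("null", n_features)
    take <- function(k) {
      if (k == 0) return(integer(0))
      out <- pos[seq_len(k)]
      pos <<- pos[-seq_len(k)]
      out
    }
    i_up <- take(n_up); i_down <- take(n_down)
    i_fat <- take(n_fat_only); i_lean <- take(n_lean_only)
    i_sparse <- take(n_sparse)
    role[i_up] <- "up"; role[i_down] <- "down"
    role[i_fat] <- "fat_only"; role[i_lean] <- "lean_only"
    role[i_sparse] <- "sparse"
    mat[i_up, fat] <- mat[i_up, fat, drop = FALSE] * fold
    mat[i_down, lean] <- mat[i_down, lean, drop = FALSE] * fold
    mat[i_fat, lean] <- 0
    mat[i_lean, fat] <- 0
    if (n_sparse > 0) {
      # positive in only (presence - 1) = 2 samples of one group
      mat[i_sparse, ] <- 0
      mat[i_sparse, fat[seq_len(min(2, length(fat)))]] <-
        stats::rlnorm(n_sparse * min(2, length(fat)), base_mu, sigma)
    }
    truth <- data.frame(
      feature_id = ids, role = role,
      true_fold = ifelse(role == "up", fold,
                  ifelse(role == "down", 1 / fold, 1)),
      expected_status = ifelse(role %in% c("up", "fat_only"), "up",
                        ifelse(role %in% c("down", "lean_only"), "down",
                               "ns")),
      expected_specificity = ifelse(role == "fat_only", "fat_only",
                             ifelse(role == "lean_only", "lean_only",
                             ifelse(role == "sparse", "fat_only", "shared"))),
      stringsAsFactors = FALSE)
    attr(mat, "unit") <- "FPKM"
    list(mat = mat, truth = truth)
  })
}

#' Default 3 fat vs 3 lean design
#' @return named character vector F1..F3 -> fat, L1..L3 -> lean.
#' @export
default_design <- function() {
  setNames(c("fat", "fat", "fat", "lean", "lean", "lean"),
           c("F1", "F2", "F3", "L1", "L2", "L3"))
}

#' Generate ceRNA pair tables with a planted shared-miRNA structure
#'
#' Builds lncRNA-miRNA and mRNA-miRNA prediction tables in which exactly
#' `n_edges` qualifying pairs (score >= 70) survive the shared-miRNA
#' intersection: every shared miRNA appears in both tables, every lncRNA and
#' mRNA carries at least one edge, and the qualifying edge count is planted
#' exactly. Decoy miRNAs appear in only one table (score >= 70) and
#' sub-threshold pairs carry scores below 70; neither can enter the network.
#'
#' @param seed integer seed.
#' @param lnc_ids lncRNA node ids (default 7 ids).
#' @param mrna_ids mRNA node ids (default 11 ids).
#' @param n_shared_mirna number of shared miRNAs (default 28).
#' @param n_edges total qualifying edges (default 75; must be at least
#'   `2 * n_shared_mirna` and at most the number of distinct possible pairs).
#' @param n_decoy_mirna decoy miRNAs per table.
#' @param n_subthreshold sub-threshold (score < 70) pairs per table.
#' @param score_range range for qualifying scores (must start at >= 70).
#' @return list with `lnc_mirna`, `mirna_mrna` (pair tables) and `truth`
#'   (expected node/edge counts and the planted qualifying edges).
#' @export
make_pair_tables <- function(seed, lnc_ids = sprintf("CELNC_%02d", 1:7),
                             mrna_ids = sprintf("CEMRNA_%02d", 1:11),
                             n_shared_mirna = 28L, n_edges = 75L,
                             n_decoy_mirna = 6L, n_subthreshold = 8L,
                             score_range = c(70, 100)) {
  if (score_range[1] < 70) stop("qualifying scores must be >= 70")
  n_lnc <- length(lnc_ids); n_mrna <- length(mrna_ids)
  mirna_ids <- sprintf("MIR_%03d", seq_len(n_shared_mirna))
  if (n_edges < 2L * n_shared_mirna)
    stop("n_edges must be at least 2 * n_shared_mirna so every shared miRNA ",
         "touches both sides")
  max_edges <- n_shared_mirna * (n_lnc + n_mrna)
  if (n_edges > max_edges) stop("n_edges exceeds the distinct pair capacity")

  with_seed(seed, {
    # one lncRNA edge and one mRNA edge per shared miRNA, round-robin so all
    # lncRNAs/mRNAs are covered
    lnc_edges <- data.frame(
      source_id = lnc_ids[(seq_len(n_shared_mirna) - 1L) %% n_lnc + 1L],
      mirna_id = mirna_ids, stringsAsFactors = FALSE)
    mrna_edges <- data.frame(
      source_id = mrna_ids[(seq_len(n_shared_mirna) - 1L) %% n_mrna + 1L],
      mirna_id = mirna_ids, stringsAsFactors = FALSE)
    n_extra <- n_edges - 2L * n_shared_mirna
    if (n_extra > 0) {
      all_lnc <- expand.grid(source_id = lnc_ids, mirna_id = mirna_ids,
                             stringsAsFactors = FALSE)
      all_mrna <- expand.grid(source_id = mrna_ids, mirna_id = mirna_ids,
                              stringsAsFactors = FALSE)
      all_lnc$side <- "lnc"
      all_mrna$side <- "mrna"
      pool <- rbind(
        all_lnc[!paste(all_lnc$source_id, all_lnc$mirna_id) %in%
                  paste(lnc_edges$source_id, lnc_edges$mirna_id), ],
        all_mrna[!paste(all_mrna$source_id, all_mrna$mirna_id) %in%
                   paste(mrna_edges$source_id, mrna_edges$mirna_id), ])
      extra <- pool[sample.int(nrow(pool), n_extra), , drop = FALSE]
      lnc_edges <- rbind(lnc_edges, extra[extra$side == "lnc",
                                          c("source_id", "mirna_id")])
      mrna_edges <- rbind(mrna_edges, extra[extra$side == "mrna",
                                            c("source_id", "mirna_id")])
    }
    qscore <- function(k) runif(k, score_range[1], score_range[2])
    lnc_tab <- data.frame(lnc_edges, score = qscore(nrow(lnc_edges)),
                          stringsAsFactors = FALSE)
    mrna_tab <- data.frame(mrna_edges, score = qscore(nrow(mrna_edges)),
                           stringsAsFactors = FALSE)

    # decoys: qualifying score but present in one table only
    if (n_decoy_mirna > 0) {
      d1 <- sprintf("MIRDECOY_L%02d", seq_len(n_decoy_mirna))
      d2 <- sprintf("MIRDECOY_M%02d", seq_len(n_decoy_mirna))
      lnc_tab <- rbind(lnc_tab, data.frame(
        source_id = sample(lnc_ids, n_decoy_mirna, replace = TRUE),
        mirna_id = d1, score = qscore(n_decoy_mirna),
        stringsAsFactors = FALSE))
      mrna_tab <- rbind(mrna_tab, data.frame(
        source_id = sample(mrna_ids, n_decoy_mirna, replace = TRUE),
        mirna_id = d2, score = qscore(n_decoy_mirna),
        stringsAsFactors = FALSE))
    }
    # sub-threshold pairs: shared miRNAs but score < 70, on fresh source ids
    if (n_subthreshold > 0 && n_shared_mirna > 0) {
      lnc_tab <- rbind(lnc_tab, data.frame(
        source_id = sprintf("SUBLNC_%02d", seq_len(n_subthreshold)),
        mirna_id = sample(mirna_ids, n_subthreshold, replace = TRUE),
        score = runif(n_subthreshold, 40, 69.5), stringsAsFactors = FALSE))
      mrna_tab <- rbind(mrna_tab, data.frame(
        source_id = sprintf("SUBMRNA_%02d", seq_len(n_subthreshold)),
        mirna_id = sample(mirna_ids, n_subthreshold, replace = TRUE),
        score = runif(n_subthreshold, 40, 69.5), stringsAsFactors = FALSE))
    }
    rownames(lnc_tab) <- rownames(mrna_tab) <- NULL
    list(lnc_mirna = lnc_tab, mirna_mrna = mrna_tab,
         truth = list(n_lncrna = n_lnc, n_mirna = n_shared_mirna,
                      n_mrna = n_mrna, n_edges = n_edges,
                      lnc_edges = lnc_edges, mrna_edges = mrna_edges))
  })
}

#' Generate a circRNA-miRNA sponge prediction table
#'
#' Plants exactly `n_pairs` qualifying binding relations between `circ_ids`
#' and `n_mirna` distinct miRNAs (every circRNA and every miRNA covered),
#' plus optional sub-threshold decoy rows.
#'
#' @param seed integer seed.
#' @param circ_ids circRNA ids.
#' @param n_mirna distinct miRNAs (default 314).
#' @param n_pairs qualifying pairs (default 364; at least
#'   `max(n_mirna, length(circ_ids))`).
#' @param n_subthreshold sub-threshold rows.
#' @return list with `circ_mirna` (pair table) and `truth` (counts).
#' @export
make_sponge_pairs <- function(seed, circ_ids, n_mirna = 314L,
                              n_pairs = 364L, n_subthreshold = 10L) {
  n_circ <- length(circ_ids)
  if (n_pairs < max(n_mirna, n_circ) || n_pairs > n_mirna * n_circ)
    stop("n_pairs incompatible with the requested node counts")
  with_seed(seed, {
    mirna_ids <- sprintf("SPONGEMIR_%03d", seq_len(n_mirna))
    # cover every miRNA once (round-robin over circRNAs covers every circRNA)
    base <- data.frame(
      source_id = circ_ids[(seq_len(n_mirna) - 1L) %% n_circ + 1L],
      mirna_id = mirna_ids, stringsAsFactors = FALSE)
    pool <- expand.grid(source_id = circ_ids, mirna_id = mirna_ids,
                        stringsAsFactors = FALSE)
    pool <- pool[!paste(pool$source_id, pool$mirna_id) %in%
                   paste(base$source_id, base$mirna_id), , drop = FALSE]
    extra <- pool[sample.int(nrow(pool), n_pairs - n_mirna), , drop = FALSE]
    tab <- rbind(base, extra)
    tab$score <- runif(nrow(tab), 70, 100)
    if (n_subthreshold > 0)
      tab <- rbind(tab, data.frame(
        source_id = sample(circ_ids, n_subthreshold, replace = TRUE),
        mirna_id = sprintf("SPONGESUB_%02d", seq_len(n_subthreshold)),
        score = runif(n_subthreshold, 40, 69.5), stringsAsFactors = FALSE))
    rownames(tab) <- NULL
    list(circ_mirna = tab,
         truth = list(n_circ = n_circ, n_mirna = n_mirna, n_pairs = n_pairs))
  })
}

#' Generate a gene-to-term map with one planted enriched term
#'
#' @param seed integer seed.
#' @param universe background gene ids.
#' @param planted_genes gene set the planted term should be enriched in.
#' @param n_terms total terms (the planted one included when
#'   `planted_overlap > 0`).
#' @param planted_term_size genes in the planted term.
#' @param planted_overlap how many of them come from `planted_genes`.
#' @param term_size_range size range of the random terms.
#' @return list with `term_map` (data.frame `gene_id`, `term_id`) and `truth`
#'   (`planted_term`, `planted_overlap`).
#' @export
make_term_map <- function(seed, universe, planted_genes = character(),
                          n_terms = 30L, planted_term_size = 15L,
                          planted_overlap = 10L,
                          term_size_range = c(5L, 30L)) {
  if (planted_overlap > min(planted_term_size, length(planted_genes)))
    stop("planted_overlap exceeds the planted term or gene-set size")
  with_seed(seed, {
    rows <- list()
    planted_term <- NA_character_
    n_random <- n_terms
    if (planted_overlap > 0) {
      planted_term <- "TERM_PLANTED"
      inside <- sample(planted_genes, planted_overlap)
      outside <- sample(setdiff(universe, planted_genes),
                        planted_term_size - planted_overlap)
      rows[[1]] <- data.frame(gene_id = c(inside, outside),
                              term_id = planted_term, stringsAsFactors = FALSE)
      n_random <- n_terms - 1L
    }
    for (i in seq_len(n_random)) {
      size <- sample(seq(term_size_range[1], term_size_range[2]), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sample(universe, size), term_id = sprintf("TERM_%03d", i),
        stringsAsFactors = FALSE)
    }
    term_map <- do.call(rbind, rows)
    rownames(term_map) <- NULL
    list(term_map = term_map,
         truth = list(planted_term = planted_term,
                      planted_overlap = planted_overlap))
  })
}
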