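#' Default pipeline configuration
#'
#' All thresholds of the workflow in one record: candidate filters
#' (`min_exons` 2, `min_length` 200 bp), presence screen (3 positive samples
#' in either group for lncRNA FPKM; any positive sample for circRNA CPM),
#' expressed-circRNA junction reads (2), DE thresholds (|log2FC| >= 1,
#' p < 0.05), trans-target correlation (|r| > 0.95, FDR < 0.05), cis window
#' (50 kb), miRNA prediction score (70), and bidirectional TSS window
#' (1000 bp).
#'
#' @param ... overrides for any listed field.
#' @return named list of thresholds.
#' @export
pipeline_config <- function(...) {
  cfg <- list(min_exons = 2L, min_length = 200L,
              presence = 3L, circ_presence = 1L, min_junction_reads = 2L,
              lfc = 1, alpha = 0.05, pseudocount = 0.01,
              r = 0.95, fdr = 0.05, cis_window = 50000L,
              mirna_score = 70, bidirectional_window = 1000L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  num <- vapply(cfg, function(x) is.numeric(x) && length(x) == 1 && x > 0,
                logical(1))
  if (!all(num)) stop("all thresholds must be positive scalars")
  cfg
}

#' Simulate a complete synthetic study with planted ground truth
#'
#' Produces a coherent input bundle emulating a two-line abdominal-fat
#' profiling study: a planted-class annotation with decoy candidates,
#' coding-potential verdicts (identified lncRNAs are unanimous noncoding;
#' consensus decoys draw at least one coding verdict), lncRNA FPKM and circRNA
#' CPM matrices with planted differential expression and line specificity,
#' back-splice junction counts, an mRNA matrix with planted trans-target
#' (proportional) pairs, localization labels, ceRNA and sponge pair tables
#' with planted network structure, and a term map with one planted enriched
#' term. When `dir` is given the bundle is also written as the GTF/TSV files
#' the pipeline reads (see [write_study()]).
#'
#' @param seed integer seed; every downstream random draw derives from it.
#' @param dir optional output directory.
#' @param n_lnc_per_class planted lncRNAs per class (default 100, i.e. 600
#'   identified lncRNAs).
#' @param n_circ_per_class planted circRNAs per class (default 9, i.e. 45
#'   circRNAs, 5 of which are left below the junction-read threshold).
#' @param sigma log-normal replicate noise (sdlog).
#' @param fold planted fold change.
#' @return the bundle (list); see the pipeline stage functions for consumers.
#' @export
simulate_study <- function(seed, dir = NULL, n_lnc_per_class = 100L,
                           n_circ_per_class = 9L, sigma = 0.15, fold = 4) {
  if (6L * n_lnc_per_class < 59L)
    stop("n_lnc_per_class must be at least 10 to host the planted DE and ",
         "sparse lncRNA features")
  if (5L * n_circ_per_class < 22L)
    stop("n_circ_per_class must be at least 5 to host the planted DE ",
         "circRNAs and the unexpressed decoys")
  design <- default_design()
  samples <- names(design)
  sub <- with_seed(seed, sample.int(1e8, 12))

  ann <- make_annotation(sub[1], n_coding = 5L * n_lnc_per_class +
                           4L * n_circ_per_class + 50L,
                         n_lnc_per_class = n_lnc_per_class,
                         n_circ_per_class = n_circ_per_class,
                         n_decoy_monoexonic = 20L, n_decoy_short = 20L,
                         n_other_ncrna = 20L)
  identified <- ann$truth$lnc_classes$transcript_id

  # consensus decoys: well-formed candidates on a second chromosome that at
  # least one coding-potential tool calls coding
  n_cdecoy <- 20L
  cdecoy_ids <- sprintf("DECOY_CODING_%03d", seq_len(n_cdecoy))
  o <- (seq_len(n_cdecoy) - 1L) * 20000L + 5000L
  cdecoy <- data.frame(
    transcript_id = rep(cdecoy_ids, each = 2L),
    gene_id = rep(paste0("G", cdecoy_ids), each = 2L),
    biotype = "lncRNA_candidate", chrom = "chr2",
    start = as.vector(rbind(o, o + 400L)),
    end = as.vector(rbind(o + 300L, o + 700L)),
    strand = "+", stringsAsFactors = FALSE)
  exons <- rbind(ann$exons, cdecoy)

  candidates <- unique(exons$transcript_id[
    exons$biotype == "lncRNA_candidate"])
  verdicts <- with_seed(sub[2], {
    v <- data.frame(feature_id = candidates, CNCI = "noncoding",
                    CPC = "noncoding", PFAM = "noncoding", CPAT = "noncoding",
                    stringsAsFactors = FALSE)
    for (id in cdecoy_ids) {
      tools <- sample(VERDICT_TOOLS, sample(1:4, 1))
      v[v$feature_id == id, tools] <- "coding"
    }
    v
  })

  lnc_expr <- make_expression(sub[3], design, n_features = length(identified),
                              n_up = 5L, n_down = 6L, n_fat_only = 14L,
                              n_lean_only = 5L, n_sparse = 10L,
                              sigma = sigma, fold = fold, ids = identified)

  # mRNA matrix: 60 genes, the first 30 pathway-annotated; 20 planted
  # proportional (trans-target) pairs onto planted-DE lncRNAs
  mrna_ids <- sprintf("MRNA_%02d", 1:60)
  annotated_mrnas <- mrna_ids[1:30]
  mrna_expr <- make_expression(sub[4], design, n_features = 60L,
                               n_up = 0L, n_down = 0L, sigma = sigma,
                               ids = mrna_ids)
  de_lnc_ids <- lnc_expr$truth$feature_id[
    lnc_expr$truth$expected_status != "ns"]
  trans_truth <- with_seed(sub[5], {
    lncs <- sample(de_lnc_ids, 20L)
    mrnas <- sample(annotated_mrnas, 20L)
    scale <- runif(20L, 0.5, 2)
    data.frame(lnc_id = lncs, gene_id = mrnas, scale = scale,
               stringsAsFactors = FALSE)
  })
  mrna_mat <- mrna_expr$mat
  mrna_mat[trans_truth$gene_id, ] <-
    lnc_expr$mat[trans_truth$lnc_id, ] * trans_truth$scale

  # circRNAs: CPM with planted DE; 5 null circRNAs kept below the
  # junction-read threshold
  circ_ids <- ann$truth$circ_classes$circ_id
  circ_expr <- make_expression(sub[6], design, n_features = length(circ_ids),
                               n_up = 5L, n_down = 0L, n_fat_only = 9L,
                               n_lean_only = 3L, sigma = sigma, fold = fold,
                               ids = circ_ids)
  circ_cpm <- circ_expr$mat
  attr(circ_cpm, "unit") <- "CPM"
  unexpressed <- with_seed(sub[7], sample(
    circ_expr$truth$feature_id[circ_expr$truth$role == "null"], 5L))
  counts <- round(circ_cpm)
  counts[unexpressed, ] <- 0
  counts[unexpressed, samples[1]] <- 1
  circ_cpm[unexpressed, ] <- counts[unexpressed, ]
  junctions <- cbind(ann$junctions,
                     as.data.frame(counts)[match(ann$junctions$circ_id,
                                                 rownames(counts)), ,
                                           drop = FALSE])
  rownames(junctions) <- NULL
  circ_truth <- circ_expr$truth
  circ_truth$expected_status[circ_truth$feature_id %in% unexpressed] <- "ns"

  # localization: 16 of the 19 line-specific lncRNAs in the cytoplasm
  specific <- lnc_expr$truth$feature_id[
    lnc_expr$truth$role %in% c("fat_only", "lean_only")]
  localization <- with_seed(sub[8], {
    loc <- setNames(sample(c("cytoplasm", "nucleus"), length(identified),
                           replace = TRUE), identified)
    loc[specific] <- "cytoplasm"
    loc[sample(specific, 3L)] <- "nucleus"
    loc
  })
  selected_cerna <- specific[localization[specific] == "cytoplasm"]

  cerna_lncs <- with_seed(sub[9], sample(selected_cerna, 7L))
  cerna_mrnas <- with_seed(sub[10], sample(annotated_mrnas, 11L))
  pair_tabs <- make_pair_tables(sub[11], lnc_ids = sort(cerna_lncs),
                                mrna_ids = sort(cerna_mrnas))

  de_circ_ids <- circ_truth$feature_id[circ_truth$expected_status != "ns"]
  sponge <- make_sponge_pairs(sub[12], circ_ids = sort(de_circ_ids))

  universe <- unique(c(exons$gene_id, mrna_ids))
  terms <- make_term_map(sub[2] + 1L, universe = universe,
                         planted_genes = trans_truth$gene_id)

  bundle <- list(
    seed = seed, design = design,
    exons = exons, junctions = junctions, verdicts = verdicts,
    lnc_fpkm = lnc_expr$mat, mrna_fpkm = mrna_mat, circ_cpm = circ_cpm,
    localization = localization,
    annotated_mrnas = annotated_mrnas,
    lnc_mirna = pair_tabs$lnc_mirna, mirna_mrna = pair_tabs$mirna_mrna,
    circ_mirna = sponge$circ_mirna, term_map = terms$term_map,
    truth = list(
      lnc_classes = ann$truth$lnc_classes,
      circ_classes = ann$truth$circ_classes,
      filter_decoys = ann$truth$decoys,
      consensus_decoys = cdecoy_ids,
      identified = identified,
      lnc_de = lnc_expr$truth,
      circ_de = circ_truth,
      unexpressed_circs = unexpressed,
      trans_pairs = trans_truth,
      selected_cerna = selected_cerna,
      cerna = pair_tabs$truth[c("n_lncrna", "n_mirna", "n_mrna", "n_edges")],
      sponge = sponge$truth,
      enrichment = terms$truth))
  if (!is.null(dir)) write_study(bundle, dir)
  bundle
}

#' Write a simulated study bundle to disk
#'
#' Emits the exact formats the pipeline reads: `annotation.gtf`,
#' `junctions.tsv`, `verdicts.tsv`, `lnc_fpkm.tsv`, `mrna_fpkm.tsv`,
#' `circ_cpm.tsv`, `localization.tsv`, `annotated_mrnas.txt`, `design.tsv`,
#' pair tables, `term_map.tsv`, plus the truth tables under `truth/` and the
#' generating parameters in `params.json`.
#'
#' @param bundle list from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_gtf(bundle$exons, p("annotation.gtf"))
  write_tsv(bundle$junctions, p("junctions.tsv"))
  write_tsv(bundle$verdicts, p("verdicts.tsv"))
  write_expression_matrix(bundle$lnc_fpkm, p("lnc_fpkm.tsv"))
  write_expression_matrix(bundle$mrna_fpkm, p("mrna_fpkm.tsv"))
  write_expression_matrix(bundle$circ_cpm, p("circ_cpm.tsv"))
  write_tsv(data.frame(feature_id = names(bundle$localization),
                       localization = unname(bundle$localization)),
            p("localization.tsv"))
  writeLines(bundle$annotated_mrnas, p("annotated_mrnas.txt"))
  write_tsv(data.frame(sample = names(bundle$design),
                       group = unname(bundle$design)), p("design.tsv"))
  write_tsv(bundle$lnc_mirna, p("lnc_mirna.tsv"))
  write_tsv(bundle$mirna_mrna, p("mirna_mrna.tsv"))
  write_tsv(bundle$circ_mirna, p("circ_mirna.tsv"))
  write_tsv(bundle$term_map, p("term_map.tsv"))
  dir.create(p("truth"), showWarnings = FALSE)
  for (nm in names(bundle$truth)) {
    x <- bundle$truth[[nm]]
    if (is.data.frame(x)) write_tsv(x, p("truth", paste0(nm, ".tsv")))
    else jsonlite::write_json(x, p("truth", paste0(nm, ".json")),
                              auto_unbox = TRUE)
  }
  jsonlite::write_json(list(seed = bundle$seed), p("params.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a study input directory
#'
#' @param dir directory written by [write_study()] (or assembled by hand in
#'   the same formats).
#' @return list of parsed inputs.
#' @export
read_study <- function(dir) {
  p <- function(...) {
    f <- file.path(dir, ...)
    if (!file.exists(f)) stop("missing input: ", f)
    f
  }
  design_df <- read.delim(p("design.tsv"), stringsAsFactors = FALSE)
  design <- setNames(design_df$group, design_df$sample)
  validate_design(design)
  list(
    design = design,
    exons = read_gtf(p("annotation.gtf")),
    junctions = read_junctions(p("junctions.tsv"), names(design)),
    verdicts = read_verdicts(p("verdicts.tsv")),
    lnc_fpkm = read_expression_matrix(p("lnc_fpkm.tsv"), "FPKM"),
    mrna_fpkm = read_expression_matrix(p("mrna_fpkm.tsv"), "FPKM"),
    circ_cpm = read_expression_matrix(p("circ_cpm.tsv"), "CPM"),
    localization = read_localization(p("localization.tsv")),
    annotated_mrnas = readLines(p("annotated_mrnas.txt")),
    lnc_mirna = read_pair_table(p("lnc_mirna.tsv")),
    mirna_mrna = read_pair_table(p("mirna_mrna.tsv")),
    circ_mirna = read_pair_table(p("circ_mirna.tsv")))
}

stage_log <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the analysis workflow on a study directory
#'
#' Executes the stages in dependency order - identify, classify, de, targets,
#' cerna, enrich - writing each stage's TSV outputs into `out_dir` and a run
#' manifest (`manifest.json`) with the per-stage counts. Identical inputs and
#' configuration yield an identical manifest.
#'
#' @param input_dir study directory (see [read_study()]).
#' @param out_dir output directory.
#' @param config from [pipeline_config()].
#' @param stages subset of
#'   `c("identify", "classify", "de", "targets", "cerna", "enrich")` or
#'   `"all"`; earlier stages are always computed (they are cheap), only the
#'   requested stages' files are written.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(input_dir, out_dir, config = pipeline_config(),
                         stages = "all") {
  all_stages <- c("identify", "classify", "de", "targets", "cerna", "enrich")
  if (identical(stages, "all")) stages <- all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown) > 0)
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  inp <- read_study(input_dir)
  manifest <- list(config = config)
  want <- function(s) s %in% stages

  ## identify
  candidates <- unique(inp$exons$transcript_id[
    inp$exons$biotype == "lncRNA_candidate"])
  filter_pass <- filter_candidates(inp$exons, config$min_exons,
                                   config$min_length)
  identified <- coding_consensus(filter_pass, inp$verdicts)
  stage_log("identify", length(candidates), " candidates -> ",
            length(filter_pass), " after structure filter -> ",
            length(identified), " identified lncRNAs")
  manifest$identify <- list(n_candidates = length(candidates),
                            n_filter_pass = length(filter_pass),
                            n_identified = length(identified))
  if (want("identify"))
    write_tsv(data.frame(transcript_id = identified), p("identified_lncrnas.tsv"))

  ## classify
  index <- build_coding_index(inp$exons)
  lnc_exons <- inp$exons[inp$exons$transcript_id %in% identified, ,
                         drop = FALSE]
  lnc_classes <- classify_lncrnas(lnc_exons, index,
                                  config$bidirectional_window)
  circ_classes <- classify_circrnas(inp$junctions, index)
  manifest$classify <- list(
    lnc = as.list(setNames(class_summary(lnc_classes)$n, LNC_CLASSES)),
    circ = as.list(setNames(class_summary(circ_classes)$n, CIRC_CLASSES)))
  stage_log("classify", nrow(lnc_classes), " lncRNAs / ",
            nrow(circ_classes), " circRNAs classified")
  if (want("classify")) {
    write_tsv(lnc_classes, p("lnc_classes.tsv"))
    write_tsv(circ_classes, p("circ_classes.tsv"))
    write_tsv(class_summary(lnc_classes), p("lnc_class_summary.tsv"))
    write_tsv(class_summary(circ_classes), p("circ_class_summary.tsv"))
  }

  ## de
  lnc_mat <- inp$lnc_fpkm[rownames(inp$lnc_fpkm) %in% identified, ,
                          drop = FALSE]
  present <- presence_filter(lnc_mat, inp$design, config$presence)
  de_lnc <- screen_de(lnc_mat[present, , drop = FALSE], inp$design,
                      config$lfc, config$alpha, config$pseudocount)
  expressed <- circ_expressed(inp$junctions, names(inp$design),
                              config$min_junction_reads)
  circ_mat <- inp$circ_cpm[rownames(inp$circ_cpm) %in% expressed, ,
                           drop = FALSE]
  circ_present <- presence_filter(circ_mat, inp$design, config$circ_presence)
  de_circ <- screen_de(circ_mat[circ_present, , drop = FALSE], inp$design,
                       config$lfc, config$alpha, config$pseudocount)
  de_counts <- function(de) {
    sig <- de[de$status != "ns", , drop = FALSE]
    list(n_screened = nrow(de), n_de = nrow(sig),
         n_up = sum(de$status == "up"), n_down = sum(de$status == "down"),
         n_fat_only = sum(sig$specificity == "fat_only"),
         n_lean_only = sum(sig$specificity == "lean_only"))
  }
  manifest$de <- list(lnc = de_counts(de_lnc),
                      circ = c(list(n_expressed = length(expressed)),
                               de_counts(de_circ)))
  stage_log("de", "lncRNA: ", manifest$de$lnc$n_up, " up / ",
            manifest$de$lnc$n_down, " down; circRNA: ",
            manifest$de$circ$n_up, " up / ", manifest$de$circ$n_down, " down")
  if (want("de")) {
    write_tsv(de_lnc, p("de_lncrna.tsv"))
    write_tsv(de_circ, p("de_circrna.tsv"))
  }

  ## targets
  de_lnc_ids <- de_lnc$feature_id[de_lnc$status != "ns"]
  de_lnc_exons <- inp$exons[inp$exons$transcript_id %in% de_lnc_ids, ,
                            drop = FALSE]
  cis <- cis_targets(de_lnc_exons, inp$exons, config$cis_window)
  trans <- trans_targets(inp$lnc_fpkm[de_lnc_ids, , drop = FALSE],
                         inp$mrna_fpkm[inp$annotated_mrnas, , drop = FALSE],
                         config$r, config$fdr)
  coexp <- build_coexpression_network(trans, de_lnc_ids, inp$annotated_mrnas)
  ct <- network_tables(coexp)
  manifest$targets <- list(
    n_cis_pairs = nrow(cis), n_cis_genes = length(unique(cis$gene_id)),
    n_trans_pairs = nrow(trans),
    coexp_n_lnc = sum(ct$nodes$type == "lncRNA"),
    coexp_n_mrna = sum(ct$nodes$type == "mRNA"),
    coexp_n_edges = nrow(ct$edges))
  stage_log("targets", nrow(cis), " cis pairs; ", nrow(trans),
            " trans pairs; co-expression network ",
            nrow(ct$nodes), " nodes / ", nrow(ct$edges), " edges")
  if (want("targets")) {
    write_tsv(cis, p("cis_targets.tsv"))
    write_tsv(trans, p("trans_targets.tsv"))
    write_tsv(ct$nodes, p("coexpression_nodes.tsv"))
    write_tsv(ct$edges, p("coexpression_edges.tsv"))
  }

  ## cerna
  de_rows <- de_lnc[de_lnc$status != "ns", , drop = FALSE]
  selected <- select_cerna_lncrnas(de_rows, inp$localization)
  cerna <- build_cerna(inp$lnc_mirna, inp$mirna_mrna, config$mirna_score)
  hubs <- hub_rank(cerna, "lncRNA")
  sponge <- sponge_table(inp$circ_mirna,
                         de_circ$feature_id[de_circ$status != "ns"],
                         config$mirna_score)
  manifest$cerna <- c(list(n_selected_lncrnas = length(selected)),
                      cerna_summary(cerna),
                      list(top_hub = if (nrow(hubs) > 0) hubs$node[1] else NA,
                           sponge = sponge$summary))
  stage_log("cerna", length(selected), " selected lncRNAs; network ",
            manifest$cerna$n_lncrna, " lncRNA / ", manifest$cerna$n_mirna,
            " miRNA / ", manifest$cerna$n_mrna, " mRNA nodes, ",
            manifest$cerna$n_edges, " edges")
  if (want("cerna")) {
    nt <- network_tables(cerna)
    write_tsv(nt$nodes, p("cerna_nodes.tsv"))
    write_tsv(nt$edges, p("cerna_edges.tsv"))
    write_tsv(hubs, p("cerna_hubs.tsv"))
    write_tsv(sponge$pairs, p("sponge_pairs.tsv"))
  }

  ## enrich
  term_map <- read.delim(file.path(input_dir, "term_map.tsv"),
                         stringsAsFactors = FALSE)
  universe <- unique(c(inp$exons$gene_id, rownames(inp$mrna_fpkm)))
  gene_set <- intersect(unique(c(cis$gene_id, trans$gene_id)), universe)
  enr <- enrich(gene_set, term_map, universe)
  manifest$enrich <- list(
    n_terms = nrow(enr), n_significant = sum(enr$p_value < 0.05),
    top_term = if (nrow(enr) > 0) enr$term_id[1] else NA)
  stage_log("enrich", nrow(enr), " terms tested, ",
            manifest$enrich$n_significant, " significant (raw p < 0.05)")
  if (want("enrich")) write_tsv(enr, p("enrichment.tsv"))

  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
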