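# coding anchor used by the definition-forced cases: single-exon transcript
one_exon_coding <- function(start, end, strand = "+")
  tx("C1", start, end, strand = strand, biotype = "coding")

test_that("definition-forced lncRNA cases classify as expected", {
  idx <- build_coding_index(one_exon_coding(1000, 2000, "+"))
  expect_equal(
    classify_lncrnas(tx("L1", 1500, 2500, strand = "+"), idx)$class,
    "exon_sense_overlapping")
  expect_equal(
    classify_lncrnas(tx("L2", 1500, 2500, strand = "-"), idx)$class,
    "natural_antisense")
})

test_that("intron overlap classes require the intron, not the exons", {
  idx <- build_coding_index(coding_tx(o = 10000L, strand = "+"))
  # inside intron 1 ([10600,11500)), same strand
  expect_equal(
    classify_lncrnas(tx("L1", c(10650, 10900), c(10800, 11100), "+"),
                     idx)$class,
    "intron_sense_overlapping")
  expect_equal(
    classify_lncrnas(tx("L2", c(10650, 10900), c(10800, 11100), "-"),
                     idx)$class,
    "intronic_antisense")
})

test_that("bidirectional requires head-to-head TSSs within the window", {
  idx <- build_coding_index(one_exon_coding(50000, 55000, "+"))
  # '-' lncRNA whose TSS (end - 1) sits `d` bp upstream of the coding TSS
  lnc_at <- function(d) {
    end <- 50000 - d + 1
    tx("L", end - 400, end, strand = "-")
  }
  expect_equal(classify_lncrnas(lnc_at(600), idx)$class, "bidirectional")
  expect_equal(classify_lncrnas(lnc_at(1000), idx)$class, "bidirectional")
  expect_equal(classify_lncrnas(lnc_at(1001), idx)$class, "intergenic")
  # same strand at 600 bp: not head-to-head
  conv <- tx("L", 49001, 49401, strand = "+")
  expect_equal(classify_lncrnas(conv, idx)$class, "intergenic")
  # convergent (tail-to-tail) '-' lncRNA downstream: not bidirectional
  down <- tx("L", 55600, 56000, strand = "-")
  expect_equal(classify_lncrnas(down, idx)$class, "intergenic")
})

test_that("definition-forced circRNA cases classify as expected", {
  cod <- coding_tx(o = 10000L, strand = "+")
  idx <- build_coding_index(cod)
  cases <- rbind(
    circ_row("exonic", 11500, 13600),          # exon2 start .. exon3 end
    circ_row("intronic", 10700, 11400),        # inside intron 1
    circ_row("senseov", 10300, 11200),         # exon1 into intron 1
    circ_row("anti", 11600, 12000, strand = "-"),
    circ_row("inter", 200000, 200800))
  got <- classify_circrnas(cases, idx)
  expect_equal(got$class, c("exonic", "intronic", "sense_overlapping",
                            "antisense", "intergenic"))
})

test_that("planted annotation classes are recovered exactly", {
  ann <- make_annotation(101, n_coding = 70L, n_lnc_per_class = 3L,
                         n_circ_per_class = 3L)
  idx <- build_coding_index(ann$exons)
  lnc_exons <- ann$exons[ann$exons$biotype == "lncRNA_candidate", ]
  got <- classify_lncrnas(lnc_exons, idx)
  expect_equal(got[order(got$transcript_id), ]$class,
               ann$truth$lnc_classes[
                 order(ann$truth$lnc_classes$transcript_id), ]$class)
  gotc <- classify_circrnas(ann$junctions, idx)
  expect_equal(gotc$class, ann$truth$circ_classes$class)
})

test_that("indexed classifiers equal the brute-force all-pairs oracle", {
  land <- make_random_landscape(77, n_coding = 60L, n_lnc = 250L,
                                n_circ = 120L, chrom_length = 400000L)
  idx <- build_coding_index(land$exons)
  lnc_exons <- land$exons[land$exons$biotype == "lncRNA_candidate", ]
  got <- classify_lncrnas(lnc_exons, idx)
  gotc <- classify_circrnas(land$junctions, idx)
  want <- oracle_classify_landscape(land$exons, land$junctions)
  expect_equal(got[order(got$transcript_id), "class"],
               want$lnc[order(want$lnc$transcript_id), "class"])
  expect_equal(gotc$class, want$circ$class)
})

test_that("classification is total: one class from the vocabulary each", {
  land <- make_random_landscape(78, n_coding = 30L, n_lnc = 100L,
                                n_circ = 50L, chrom_length = 200000L)
  idx <- build_coding_index(land$exons)
  lnc_exons <- land$exons[land$exons$biotype == "lncRNA_candidate", ]
  got <- classify_lncrnas(lnc_exons, idx)
  expect_equal(nrow(got), 100L)
  expect_true(all(got$class %in% c("exon_sense_overlapping",
                                   "intron_sense_overlapping",
                                   "intronic_antisense", "natural_antisense",
                                   "bidirectional", "intergenic")))
  gotc <- classify_circrnas(land$junctions, idx)
  expect_equal(nrow(gotc), 50L)
  expect_false(any(is.na(gotc$class)))
  s <- class_summary(got)
  expect_equal(sum(s$n), 100L)
  expect_equal(sum(s$proportion), 1)
})

test_that("coding transcripts are refused as classification input", {
  idx <- build_coding_index(coding_tx())
  expect_error(classify_lncrnas(coding_tx(id = "X", o = 0L), idx), "coding")
})
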