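design <- default_design()

test_that("cis window boundaries behave per the 50-kb rule", {
  lnc <- tx("L1", 200000, 201000)
  gene_gap <- function(gap) tx("G", 200000 - gap - 500, 200000 - gap,
                               biotype = "coding", gene = "G")
  hit <- function(gap) nrow(cis_targets(lnc, gene_gap(gap)))
  expect_equal(hit(49999), 1L)
  expect_equal(hit(50000), 1L)   # at the boundary: within 50 kb
  expect_equal(hit(50001), 0L)
  ov <- cis_targets(lnc, tx("G", 200500, 202000, biotype = "coding"))
  expect_equal(ov$distance, 0L)
  # downstream side is symmetric
  down <- tx("G", 201000 + 49999, 201000 + 50500, biotype = "coding")
  expect_equal(cis_targets(lnc, down)$distance, 49999L)
})

test_that("cis targets equal a naive distance-scan oracle", {
  land <- make_random_landscape(55, n_coding = 300L, n_lnc = 40L, n_circ = 0L,
                                chrom_length = 3000000L)
  lnc_exons <- land$exons[land$exons$biotype == "lncRNA_candidate", ]
  got <- cis_targets(lnc_exons, land$exons)
  genes <- gene_spans(land$exons)
  lncs <- transcript_summary(lnc_exons)
  want <- list()
  for (i in seq_len(nrow(lncs))) for (j in seq_len(nrow(genes))) {
    if (lncs$chrom[i] != genes$chrom[j]) next
    gap <- max(0, genes$start[j] - lncs$span_end[i],
               lncs$span_start[i] - genes$end[j])
    if (gap <= 50000)
      want[[length(want) + 1L]] <- paste(lncs$transcript_id[i],
                                         genes$gene_id[j], gap)
  }
  expect_setequal(paste(got$lnc_id, got$gene_id, got$distance),
                  unlist(want))
})

test_that("exact proportional profiles are retained with |r| = 1", {
  base <- make_expression(61, n_features = 30L, n_up = 0L, n_down = 0L)$mat
  lnc <- base[1:10, ]
  mrna <- rbind(pos_copy = 2 ^ (log2(lnc[1, ] + 1) + 1) - 1,  # affine in log
                neg_copy = 2 ^ (-log2(lnc[2, ] + 1) + 20) - 1,
                base[11:20, ])
  got <- trans_targets(lnc, mrna)
  pos <- got[got$lnc_id == rownames(lnc)[1] & got$gene_id == "pos_copy", ]
  neg <- got[got$lnc_id == rownames(lnc)[2] & got$gene_id == "neg_copy", ]
  expect_equal(pos$correlation, 1)
  expect_equal(neg$correlation, -1)   # absolute-value rule keeps it
  expect_equal(pos$q_value, 0)
})

test_that("trans targets match the per-pair oracle to 1e-12", {
  lnc <- make_expression(62, n_features = 8L, n_up = 0L, n_down = 0L,
                         sigma = 0.5)$mat
  mrna <- make_expression(63, n_features = 9L, n_up = 0L, n_down = 0L,
                          sigma = 0.5)$mat
  mrna[1, ] <- lnc[1, ] * 1.7
  got <- trans_targets(lnc, mrna, keep_all = TRUE)
  ps <- numeric(nrow(got)); rs <- numeric(nrow(got))
  for (i in seq_len(nrow(got))) {
    o <- oracle_pearson(lnc[got$lnc_id[i], ], mrna[got$gene_id[i], ])
    rs[i] <- o$r; ps[i] <- o$p
  }
  expect_equal(got$correlation, rs, tolerance = 1e-12)
  expect_equal(got$p_value, ps, tolerance = 1e-12)
  expect_equal(got$q_value, oracle_bh(ps), tolerance = 1e-12)
  # BH sanity: q >= p, and q monotone non-decreasing in p
  expect_true(all(got$q_value >= got$p_value - 1e-15))
  o <- order(got$p_value)
  expect_true(all(diff(got$q_value[o]) >= -1e-15))
})

test_that("trans targets are invariant to a shared sample permutation", {
  lnc <- make_expression(64, n_features = 6L, n_up = 0L, n_down = 0L)$mat
  mrna <- make_expression(65, n_features = 6L, n_up = 0L, n_down = 0L)$mat
  perm <- c(3, 1, 6, 2, 4, 5)
  a <- trans_targets(lnc, mrna, keep_all = TRUE)
  b <- trans_targets(lnc[, perm], mrna[, perm], keep_all = TRUE)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("zero-variance features are skipped with a warning", {
  lnc <- make_expression(66, n_features = 3L, n_up = 0L, n_down = 0L)$mat
  lnc[1, ] <- 5
  mrna <- make_expression(67, n_features = 3L, n_up = 0L, n_down = 0L)$mat
  expect_warning(got <- trans_targets(lnc, mrna, keep_all = TRUE),
                 "zero-variance")
  expect_false(rownames(lnc)[1] %in% got$lnc_id)
  expect_equal(length(unique(got$lnc_id)), 2L)
})

test_that("co-expression network obeys the handshake lemma", {
  pairs <- data.frame(lnc_id = c("l1", "l1", "l2"),
                      gene_id = c("m1", "m2", "m1"),
                      mode = "trans", correlation = c(0.99, 0.97, -0.98),
                      p_value = 1e-6, q_value = 1e-5,
                      stringsAsFactors = FALSE)
  g <- build_coexpression_network(pairs, c("l1", "l2"), c("m1", "m2"))
  t <- network_tables(g)
  expect_equal(nrow(t$nodes), 4L)
  expect_equal(nrow(t$edges), 3L)
  expect_equal(sum(t$nodes$degree), 6L)
  # restriction to DE/annotated sets drops other pairs
  g2 <- build_coexpression_network(pairs, "l1", c("m1", "m2"))
  expect_equal(igraph::ecount(g2), 2)
  empty <- build_coexpression_network(pairs[0, ], "l1", "m1")
  expect_equal(igraph::vcount(empty), 0)
})

test_that("network node/edge counts equal a set-cardinality oracle", {
  with_seed(68, {
    for (rep in 1:5) {
      n <- sample(5:40, 1)
      pairs <- unique(data.frame(
        lnc_id = sample(sprintf("l%d", 1:8), n, TRUE),
        gene_id = sample(sprintf("m%d", 1:8), n, TRUE),
        stringsAsFactors = FALSE))
      pairs$mode <- "trans"; pairs$correlation <- 0.99
      pairs$p_value <- 1e-8; pairs$q_value <- 1e-6
      g <- build_coexpression_network(pairs, sprintf("l%d", 1:8),
                                      sprintf("m%d", 1:8))
      expect_equal(igraph::vcount(g),
                   length(unique(pairs$lnc_id)) +
                     length(unique(pairs$gene_id)))
      expect_equal(igraph::ecount(g), nrow(pairs))
    }
  })
})
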