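pair <- function(s, m, score) data.frame(source_id = s, mirna_id = m,
                                         score = score,
                                         stringsAsFactors = FALSE)

test_that("ceRNA lncRNA selection is the specific-AND-cytoplasm conjunction", {
  de <- data.frame(feature_id = c("a", "b", "c", "d"),
                   specificity = c("fat_only", "fat_only", "lean_only",
                                   "shared"),
                   stringsAsFactors = FALSE)
  loc <- c(a = "cytoplasm", b = "nucleus", c = "cytoplasm", d = "cytoplasm")
  expect_equal(select_cerna_lncrnas(de, loc), c("a", "c"))
  expect_error(select_cerna_lncrnas(de, loc[-2]), "b")
  # random flag table equals the two-predicate oracle
  rnd <- with_seed(71, data.frame(
    feature_id = sprintf("f%02d", 1:50),
    specificity = sample(c("fat_only", "lean_only", "shared"), 50, TRUE),
    stringsAsFactors = FALSE))
  rloc <- with_seed(72, setNames(
    sample(c("cytoplasm", "nucleus"), 50, TRUE), rnd$feature_id))
  got <- select_cerna_lncrnas(rnd, rloc)
  want <- rnd$feature_id[rnd$specificity %in% c("fat_only", "lean_only") &
                           rloc[rnd$feature_id] == "cytoplasm"]
  expect_equal(got, want)
})

test_that("ceRNA construction keeps only shared, score-qualified miRNAs", {
  g <- build_cerna(pair("L1", "m1", 85), pair("G1", "m1", 90))
  s <- cerna_summary(g)
  expect_equal(s, list(n_lncrna = 1L, n_mirna = 1L, n_mrna = 1L,
                       n_edges = 2))
  # miRNA absent from the mRNA side drops out
  g <- build_cerna(rbind(pair("L1", "m1", 85), pair("L1", "m2", 85)),
                   pair("G1", "m1", 90))
  expect_false("m2" %in% igraph::V(g)$name)
  # sub-threshold score drops before the intersection
  g <- build_cerna(pair("L1", "m1", 69), pair("G1", "m1", 90))
  expect_equal(igraph::vcount(g), 0)
  g <- build_cerna(pair("L1", "m1", 70), pair("G1", "m1", 90))
  expect_equal(igraph::ecount(g), 2)
})

test_that("ceRNA network equals the brute-force intersection on random tables", {
  with_seed(73, {
    lnc <- random_pair_table(1000, sprintf("L%d", 1:15),
                             sprintf("mir%d", 1:40))
    mrna <- random_pair_table(1000, sprintf("G%d", 1:20),
                              sprintf("mir%d", 1:40))
  })
  g <- build_cerna(lnc, mrna)
  want <- oracle_cerna(lnc, mrna)
  expect_equal(cerna_summary(g),
               want[c("n_lncrna", "n_mirna", "n_mrna", "n_edges")])
  expect_equal(graph_edge_keys(g), want$edges)
  expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
})

test_that("raising the score threshold only shrinks the network", {
  with_seed(74, {
    lnc <- random_pair_table(400, sprintf("L%d", 1:10), sprintf("mir%d", 1:25))
    mrna <- random_pair_table(400, sprintf("G%d", 1:12), sprintf("mir%d", 1:25))
  })
  prev <- build_cerna(lnc, mrna, score_threshold = 50)
  for (thr in c(60, 70, 80, 95)) {
    cur <- build_cerna(lnc, mrna, score_threshold = thr)
    expect_true(all(igraph::V(cur)$name %in% igraph::V(prev)$name))
    expect_true(all(graph_edge_keys(cur) %in% graph_edge_keys(prev)))
    prev <- cur
  }
})

test_that("tripartite structure is enforced as a hard failure", {
  bad <- igraph::graph_from_data_frame(
    data.frame(from = "L1", to = "G1"), directed = FALSE,
    vertices = data.frame(name = c("L1", "G1"),
                          type = c("lncRNA", "mRNA")))
  expect_error(assert_tripartite(bad), "tripartite")
  ok <- build_cerna(pair("L1", "m1", 80), pair("G1", "m1", 80))
  expect_silent(assert_tripartite(ok))
})

test_that("hub ranking is by degree with lexicographic tie-break", {
  lnc <- rbind(pair("Lstar", sprintf("m%02d", 1:14), 80),
               pair("Lb", c("m01", "m02", "m03"), 80),
               pair("La", c("m04", "m05", "m06"), 80))
  mrna <- pair("G1", sprintf("m%02d", 1:14), 80)
  g <- build_cerna(lnc, mrna)
  h <- hub_rank(g, "lncRNA")
  expect_equal(h$node[1], "Lstar")
  expect_equal(h$degree[1], 14L)
  expect_equal(h$node[2:3], c("La", "Lb"))  # tie at 3, alphabetical
  # degrees equal an adjacency-count oracle
  el <- igraph::as_edgelist(g)
  for (i in seq_len(nrow(h)))
    expect_equal(h$degree[i], sum(el == h$node[i]))
  expect_equal(hub_rank(igraph::make_empty_graph(directed = FALSE))$node,
               character())
})

test_that("planted pair tables reproduce the target network exactly", {
  pt <- make_pair_tables(81)
  g <- build_cerna(pt$lnc_mirna, pt$mirna_mrna)
  expect_equal(cerna_summary(g),
               list(n_lncrna = 7L, n_mirna = 28L, n_mrna = 11L, n_edges = 75))
  expect_equal(cerna_summary(g)[c("n_lncrna", "n_mirna", "n_mrna", "n_edges")],
               pt$truth[c("n_lncrna", "n_mirna", "n_mrna", "n_edges")],
               ignore_attr = TRUE)
  # decoys and sub-threshold rows never enter
  expect_false(any(grepl("DECOY|SUB", igraph::V(g)$name)))
  # no shared miRNAs -> empty network
  pt0 <- make_pair_tables(82, n_shared_mirna = 0L, n_edges = 0L)
  expect_equal(igraph::vcount(build_cerna(pt0$lnc_mirna, pt0$mirna_mrna)), 0)
})

test_that("hub sub-networks contain the hub, its miRNAs and their mRNAs", {
  pt <- make_pair_tables(83)
  g <- build_cerna(pt$lnc_mirna, pt$mirna_mrna)
  hub <- hub_rank(g, "lncRNA")$node[1]
  sub <- cerna_subnetwork(g, hub)
  expect_true(hub %in% igraph::V(sub)$name)
  nb <- igraph::neighbors(g, hub)$name
  expect_true(all(nb %in% igraph::V(sub)$name))
  expect_true(igraph::ecount(sub) >= length(nb))
  types <- igraph::V(sub)$type
  expect_equal(sum(types == "lncRNA"), 1L)
})

test_that("sponge table filters by circRNA set and score with exact counts", {
  tab <- rbind(pair("c1", c("m1", "m2", "m3"), c(75, 80, 95)),
               pair("c1", "m4", 69),
               pair("c2", "m1", 90))
  st <- sponge_table(tab, "c1")
  expect_equal(st$summary, list(n_circ = 1L, n_mirna = 3L, n_pairs = 3L))
  expect_equal(sponge_table(tab, character())$summary$n_pairs, 0L)
  # random tables vs a group-by oracle
  rnd <- with_seed(84, random_pair_table(500, sprintf("c%d", 1:20),
                                         sprintf("m%d", 1:100)))
  keep_ids <- sprintf("c%d", 1:10)
  st <- sponge_table(rnd, keep_ids)
  ok <- rnd[rnd$source_id %in% keep_ids & rnd$score >= 70, ]
  expect_equal(st$summary$n_pairs, nrow(ok))
  expect_equal(st$summary$n_circ, length(unique(ok$source_id)))
  expect_equal(st$summary$n_mirna, length(unique(ok$mirna_id)))
  # planted sponge structure
  sp <- make_sponge_pairs(85, circ_ids = sprintf("c%02d", 1:17))
  got <- sponge_table(sp$circ_mirna, sprintf("c%02d", 1:17))
  expect_equal(got$summary, list(n_circ = 17L, n_mirna = 314L,
                                 n_pairs = 364L))
})
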