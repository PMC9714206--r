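design <- default_design()

test_that("presence filter keeps features positive in either group", {
  m <- expr_mat(list(A = c(1.2, 0.5, 3.0, 0, 0, 0),
                     B = c(1.2, 0, 0, 0, 0.3, 0),
                     C = c(0, 0, 0, 0.1, 0.2, 0.3)))
  expect_equal(presence_filter(m, design), c("A", "C"))
  expect_equal(presence_filter(m, design, min_positive_samples = 1L),
               c("A", "B", "C"))
  expect_error(presence_filter(m, design, min_positive_samples = 4L),
               "group size")
})

test_that("presence filter equals a per-row count oracle and is monotone", {
  m <- with_seed(31, matrix(rbinom(500 * 6, 1, 0.5) * runif(500 * 6),
                            nrow = 500,
                            dimnames = list(sprintf("f%03d", 1:500),
                                            names(design))))
  got <- presence_filter(m, design, 2L)
  want <- character()
  for (i in seq_len(nrow(m))) {
    nf <- sum(m[i, 1:3] > 0); nl <- sum(m[i, 4:6] > 0)
    if (nf >= 2 || nl >= 2) want <- c(want, rownames(m)[i])
  }
  expect_equal(got, want)
  for (k in 1:3)
    expect_true(all(presence_filter(m, design, k) %in%
                      presence_filter(m, design, max(1L, k - 1L))))
})

test_that("circRNA expression needs junction reads over one", {
  j <- rbind(circ_row("c1", 0, 100, F1 = 0L, F2 = 0L, F3 = 1L,
                      L1 = 0L, L2 = 0L, L3 = 0L),
             circ_row("c2", 0, 100, F1 = 0L, F2 = 0L, F3 = 2L,
                      L1 = 0L, L2 = 0L, L3 = 0L))
  expect_equal(circ_expressed(j, names(design)), "c2")
  # oracle comparison on random counts + threshold monotonicity
  jr <- with_seed(32, {
    cnt <- matrix(rpois(200 * 6, 1.2), nrow = 200)
    colnames(cnt) <- names(design)
    cbind(circ_row(sprintf("r%03d", 1:200), seq(0, by = 200, length.out = 200),
                   seq(100, by = 200, length.out = 200)),
          as.data.frame(cnt))
  })
  got <- circ_expressed(jr, names(design), 2L)
  want <- jr$circ_id[apply(as.matrix(jr[, names(design)]), 1, max) >= 2]
  expect_equal(got, want)
  expect_true(all(circ_expressed(jr, names(design), 3L) %in% got))
})

test_that("log2 fold change follows the pseudocount formula", {
  expect_equal(log2_fold_change(4, 1, 0), 2)
  expect_equal(log2_fold_change(7.3, 7.3), 0)
  expect_equal(log2_fold_change(5, 0, 0.01), log2(5.01 / 0.01))
  expect_equal(log2_fold_change(5, 0, 0.01), 8.969, tolerance = 1e-4)
  # antisymmetric under group swap
  expect_equal(log2_fold_change(3, 11), -log2_fold_change(11, 3))
  expect_error(log2_fold_change(-1, 2), "non-negative")
  expect_error(log2_fold_change(5, 0, 0), "positive")
})

test_that("the screening test matches t.test and handles degeneracy", {
  expect_equal(de_test(c(F1 = 2, F2 = 5, F3 = 3, L1 = 2, L2 = 5, L3 = 3),
                       design), 1)
  x <- c(F1 = 8, F2 = 8.01, F3 = 7.99, L1 = 2, L2 = 2.01, L3 = 1.99)
  expect_lt(de_test(x, design), 0.05)
  # cross-check the vectorized arithmetic against stats::t.test
  m <- with_seed(33, matrix(rlnorm(50 * 6, 3, 0.5), nrow = 50,
                            dimnames = list(NULL, names(design))))
  got <- de_test(m, design)
  want <- apply(log2(m + 1), 1, function(y)
    t.test(y[1:3], y[4:6], var.equal = TRUE)$p.value)
  expect_equal(got, unname(want), tolerance = 1e-12)
  gotw <- de_test(m, design, var_equal = FALSE)
  wantw <- apply(log2(m + 1), 1, function(y)
    t.test(y[1:3], y[4:6])$p.value)
  expect_equal(gotw, unname(wantw), tolerance = 1e-12)
  # both groups constant but different: infinite separation convention
  expect_equal(de_test(c(F1 = 4, F2 = 4, F3 = 4, L1 = 1, L2 = 1, L3 = 1),
                       design), 0)
})

test_that("screen_de recovers planted truth under low noise", {
  e <- make_expression(41, n_features = 300L, n_up = 10L, n_down = 8L,
                       n_fat_only = 6L, n_lean_only = 4L, sigma = 0.05)
  de <- screen_de(e$mat, design)
  merged <- merge(de, e$truth, by = "feature_id")
  expect_equal(merged$status, merged$expected_status)
  expect_equal(merged$specificity, merged$expected_specificity)
  # tallies equal planted counts exactly
  expect_equal(sum(de$status == "up"), 16L)      # 10 up + 6 fat-only
  expect_equal(sum(de$status == "down"), 12L)    # 8 down + 4 lean-only
  sig <- de[de$status != "ns", ]
  expect_equal(sum(sig$specificity == "fat_only"), 6L)
  expect_equal(sum(sig$specificity == "lean_only"), 4L)
})

test_that("swapping group labels negates fold changes and swaps statuses", {
  e <- make_expression(42, n_features = 120L, n_up = 8L, n_down = 5L,
                       n_fat_only = 4L, n_lean_only = 3L)
  swapped <- setNames(ifelse(design == "fat", "lean", "fat"), names(design))
  a <- screen_de(e$mat, design)
  b <- screen_de(e$mat, swapped)
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  map_status <- c(up = "down", down = "up", ns = "ns")
  expect_equal(unname(map_status[a$status]), b$status)
  map_spec <- c(fat_only = "lean_only", lean_only = "fat_only",
                shared = "shared", absent = "absent")
  expect_equal(unname(map_spec[a$specificity]), b$specificity)
})

test_that("line-specific features are flagged from the zero pattern alone", {
  m <- expr_mat(list(fatonly = c(3, 2, 4, 0, 0, 0),
                     leanonly = c(0, 0, 0, 5, 4, 6),
                     absent = c(0, 0, 0, 0, 0, 0),
                     shared = c(1, 2, 3, 1, 2, 3)))
  de <- screen_de(m, design)
  expect_equal(de$specificity, c("fat_only", "lean_only", "absent", "shared"))
  expect_equal(de$status[3], "ns")
})

test_that("CPM conversion scales columns to a million", {
  j <- rbind(circ_row("c1", 0, 100, F1 = 10L, F2 = 0L),
             circ_row("c2", 200, 400, F1 = 30L, F2 = 0L))
  cpm <- junctions_to_cpm(j, c("F1", "F2"))
  expect_equal(cpm[, "F1"], c(c1 = 250000, c2 = 750000))
  expect_equal(unname(cpm[, "F2"]), c(0, 0))
})
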