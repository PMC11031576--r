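test_that("Welch statistic matches the closed form and stats::t.test", {
  es <- expression_set(rbind(p1 = c(1, 2, 3, 4, 5, 6)),
                       data.frame(sample_id = paste0("s", 1:6),
                                  group = rep(c("a", "b"), each = 3)))
  deg <- differential_test(es)
  expect_equal(deg$t, -3 / sqrt(2 / 3), tolerance = 1e-12)  # = -3.674
  expect_equal(deg$p, 2 * pt(-3 / sqrt(2 / 3), df = 4), tolerance = 1e-12)
  expect_lt(abs(deg$p - 0.021), 1e-3)
  ref <- t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(deg$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(deg$p, ref$p.value, tolerance = 1e-10)

  # cross-check the vectorized path against t.test on random matrices
  es <- two_group_expression(30, 5, 4, effect = 1.5, seed = 9)
  deg <- differential_test(es)
  for (i in c(1, 7, 30)) {
    ref <- t.test(es$values[i, 1:4], es$values[i, 5:8])
    expect_equal(deg$t[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(deg$p[i], ref$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate probes follow the stated conventions", {
  es <- expression_set(rbind(same = c(2, 2, 2, 2, 2, 2),
                             shift = c(1, 1, 1, 2, 2, 2)),
                       data.frame(group = rep(c("a", "b"), each = 3)))
  deg <- differential_test(es)
  expect_equal(deg$p[1], 1)
  expect_equal(deg$t[1], 0)
  expect_equal(deg$p[2], 0)
  expect_error(differential_test(es, rep(c("a", "b"), c(1, 5))),
               "at least 2")
})

test_that("statistics are invariant to joint column/label permutation", {
  es <- two_group_expression(20, 3, 3, effect = 2, seed = 4)
  perm <- sample(6)
  es2 <- expression_set(es$values[, perm], es$samples[perm, ])
  expect_equal(differential_test(es)$t, differential_test(es2)$t)
})

test_that("BH adjustment matches hand computations and a brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")

  grid <- seq(0.01, 0.99, by = 0.14)
  for (a in grid) for (b in grid) for (c in grid) {
    p <- c(a, b, c)
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  # adjusted >= raw, in [0,1], monotone in rank order
  set.seed(1)
  p <- runif(200)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p & adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("signal selection is inclusive at the threshold and ordered", {
  tab <- data.frame(probe_id = c("p3", "p1", "p2"),
                    p_adj = c(0.03, 0.01, 0.02))
  expect_equal(select_signal(tab, alpha = 0.02), c("p1", "p2"))
  expect_equal(select_signal(tab, alpha = 1), c("p1", "p2", "p3"))
  expect_error(select_signal(tab, alpha = 0), "alpha")
})

test_that("probe collapsing averages duplicates and preserves order", {
  es <- expression_set(rbind(p1 = c(2, 10), p2 = c(4, 20), p3 = c(7, 7)),
                       data.frame(sample_id = c("s1", "s2")))
  map <- c(p1 = "G", p2 = "G", p3 = "H")
  out <- collapse_probes(es, map)
  expect_equal(rownames(out$values), c("G", "H"))
  expect_equal(unname(out$values["G", ]), c(3, 15))
  expect_equal(unname(out$values["H", ]), c(7, 7))

  # 31 probes, 12 of them pairwise mapping to 6 genes -> 25 output rows
  probes <- sprintf("p%02d", 1:31)
  genes <- c(rep(sprintf("dup%d", 1:6), each = 2), sprintf("uni%d", 1:19))
  es <- expression_set(matrix(rnorm(31 * 4), 31, 4,
                              dimnames = list(probes, NULL)))
  out <- collapse_probes(es, setNames(genes, probes))
  expect_equal(nrow(out$values), 25L)

  # collapsing commutes with sample permutation
  perm <- c(3, 1, 4, 2)
  es2 <- expression_set(es$values[, perm], es$samples[perm, ])
  out2 <- collapse_probes(es2, setNames(genes, probes))
  expect_equal(out2$values, out$values[, perm])

  # unannotated probes: drop with warning by default, error on request
  partial <- setNames(genes, probes)[-1]
  expect_warning(collapse_probes(es, partial), "unannotated")
  expect_error(collapse_probes(es, partial, unannotated = "error"),
               "unannotated")
})
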