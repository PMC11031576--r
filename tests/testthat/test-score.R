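test_that("count tables tally exact joint counts", {
  d <- dd(c(0, 0), c(0, 1), c(1, 2), cardinality = 3L)
  ct <- count_table(d, "A")
  expect_equal(ct$q, 1L)
  expect_equal(as.vector(ct$n_jk), c(2L, 1L, 0L))
  ct <- count_table(d, "B", "A")
  expect_equal(ct$q, 3L)
  expect_equal(ct$n_jk[1L, ], c(1L, 1L, 0L))  # A=0 rows: B = 0, 1
  expect_equal(ct$n_jk[2L, ], c(0L, 0L, 1L))  # A=1 row:  B = 2
  # two ternary parents -> 9 configurations; empty data -> all zero
  d3 <- dd(c(0, 0, 0), cardinality = 3L)[0, , drop = FALSE]
  d3 <- discrete_data(d3, cardinality = 3L)
  ct <- count_table(d3, "C", c("A", "B"))
  expect_equal(ct$q, 9L)
  expect_true(all(ct$n_jk == 0L))
  expect_error(count_table(d, "Z"), "unknown")
  expect_error(count_table(d, "A", "A"), "parents")
})

test_that("local BDeu score reproduces analytic small cases", {
  empty <- discrete_data(matrix(integer(0), 0, 1,
                                dimnames = list(NULL, "A")),
                         cardinality = 2L)
  expect_identical(local_bde(count_table(empty, "A"), ess = 1), 0)
  one <- discrete_data(matrix(0L, 1, 1, dimnames = list(NULL, "A")),
                       cardinality = 2L)
  expect_equal(local_bde(count_table(one, "A"), ess = 1), log(0.5),
               tolerance = 1e-12)
  two <- discrete_data(matrix(c(0L, 0L), 2, 1, dimnames = list(NULL, "A")),
                       cardinality = 2L)
  expect_equal(local_bde(count_table(two, "A"), ess = 1), log(0.375),
               tolerance = 1e-12)
  expect_error(local_bde(count_table(one, "A"), ess = 0), "ess")
})

test_that("network score decomposes and caches by family", {
  d <- random_discrete(4, 100, seed = 3)
  g <- dag(colnames(d), rbind(c("V01", "V02"), c("V03", "V02")))
  manual <- local_bde(count_table(d, "V01"), 1) +
    local_bde(count_table(d, "V02", c("V01", "V03")), 1) +
    local_bde(count_table(d, "V03"), 1) +
    local_bde(count_table(d, "V04"), 1)
  expect_equal(network_score(d, g), manual, tolerance = 1e-12)
  # decomposability: a move changes only the touched family's contribution
  cache <- score_cache()
  s0 <- network_score(d, g, cache = cache)
  g2 <- apply_move(g, "add", "V01", "V04")
  s1 <- network_score(d, g2, cache = cache)
  delta <- local_bde(count_table(d, "V04", "V01"), 1) -
    local_bde(count_table(d, "V04"), 1)
  expect_equal(s1 - s0, delta, tolerance = 1e-10)
  # parent order within a family does not matter
  g3 <- dag(colnames(d), rbind(c("V03", "V02"), c("V01", "V02")))
  expect_equal(network_score(d, g3), network_score(d, g), tolerance = 1e-12)
})

test_that("Markov-equivalent DAGs score identically (covered reversals)", {
  # two variables: A -> B vs B -> A
  d <- random_discrete(2, 80, seed = 5)
  gAB <- dag(colnames(d), rbind(c("V01", "V02")))
  gBA <- dag(colnames(d), rbind(c("V02", "V01")))
  expect_equal(network_score(d, gAB), network_score(d, gBA),
               tolerance = 1e-9)
  # covered-arc reversals on random graphs: pa(y) = pa(x) + {x}
  for (seed in 1:15) {
    d <- random_discrete(5, 60, seed = 100 + seed)
    g <- random_dag(5, 3, seed = seed, arc_prob = 0.5)
    g <- dag(colnames(d), arcs(g))
    a <- arcs(g)
    s0 <- network_score(d, g)
    for (i in seq_len(nrow(a))) {
      x <- a[i, 1L]; y <- a[i, 2L]
      covered <- setequal(g$parents[[y]], c(g$parents[[x]], x))
      if (!covered) next
      rev <- apply_move(g, "reverse", x, y)
      expect_true(is_acyclic(rev))
      expect_equal(network_score(d, rev), s0, tolerance = 1e-9)
    }
  }
})

test_that("score is invariant to row permutation and state relabeling", {
  d <- random_discrete(4, 120, seed = 8)
  g <- random_dag(4, 2, seed = 9, arc_prob = 0.6)
  s0 <- network_score(d, g)
  set.seed(1)
  perm <- sample(nrow(d))
  dp <- discrete_data(unclass(d)[perm, ], cardinality = 3L)
  expect_equal(network_score(dp, g), s0, tolerance = 1e-12)
  # consistent relabeling of one variable's states
  m <- unclass(d)
  m[, 2] <- c(2L, 0L, 1L)[m[, 2] + 1L]
  dr <- discrete_data(m, cardinality = 3L)
  expect_equal(network_score(dr, g), s0, tolerance = 1e-12)
})

test_that("closed-form BDeu equals the prequential oracle", {
  expect_identical(prequential_oracle(
    discrete_data(matrix(integer(0), 0, 1, dimnames = list(NULL, "A")),
                  cardinality = 2L), dag("A")), 0)
  one <- discrete_data(matrix(0L, 1, 1, dimnames = list(NULL, "A")),
                       cardinality = 2L)
  expect_equal(prequential_oracle(one, dag("A")), log(0.5),
               tolerance = 1e-12)
  # randomized instances, several ess values
  for (seed in 1:20) {
    d <- random_discrete(5, 200, seed = 300 + seed)
    g <- random_dag(5, 3, seed = seed, arc_prob = 0.5)
    for (ess in c(0.5, 1, 4)) {
      expect_equal(network_score(d, g, ess = ess),
                   prequential_oracle(d, g, ess = ess),
                   tolerance = 1e-8)
    }
  }
})
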