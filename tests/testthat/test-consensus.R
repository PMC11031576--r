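# Hand-built top_networks over a fixed variable set.
make_tops <- function(arc_sets, scores = NULL,
                      vars = c("A", "B", "C")) {
  if (is.null(scores)) scores <- -seq_along(arc_sets)
  entries <- Map(function(a, s) list(dag = dag(vars, a), log_score = s),
                 arc_sets, scores)
  structure(entries, class = "top_networks", variables = vars,
            n_evaluations = length(arc_sets), best_score = max(scores))
}

test_that("consensus arc probabilities and the inclusive threshold", {
  ab <- rbind(c("A", "B"))
  bc <- rbind(c("B", "C"))
  # arc in every network -> probability 1; single network -> its arc set
  tops <- make_tops(list(ab, ab, ab, ab))
  cn <- consensus_network(tops)
  expect_equal(cn$prob, 1)
  single <- consensus_network(make_tops(list(rbind(ab, bc))))
  expect_equal(nrow(single), 2L)
  # 49/100 excluded, 50/100 retained (inclusive "at least 50%")
  sets100 <- c(replicate(50, ab, simplify = FALSE),
               replicate(50, NULL, simplify = FALSE))
  cn <- consensus_network(make_tops(sets100))
  expect_equal(nrow(cn), 1L)
  expect_equal(cn$prob, 0.5)
  sets100 <- c(replicate(49, ab, simplify = FALSE),
               replicate(51, NULL, simplify = FALSE))
  expect_equal(nrow(consensus_network(make_tops(sets100))), 0L)
  empty_tops <- structure(list(), class = "top_networks",
                          variables = c("A", "B", "C"))
  expect_error(consensus_network(empty_tops), "empty")
})

test_that("score weighting favours arcs of high-scoring networks", {
  ab <- rbind(c("A", "B"))
  bc <- rbind(c("B", "C"))
  tops <- make_tops(list(ab, bc), scores = c(0, -50))
  cn <- consensus_network(tops, weighting = "score")
  expect_equal(nrow(cn), 1L)
  expect_equal(cn$from, "A")
  # uniform weighting keeps both at exactly 0.5 (inclusive)
  cu <- consensus_network(tops, weighting = "uniform")
  expect_equal(nrow(cu), 2L)
  # opposite directions cannot both exceed half under uniform weighting
  tops <- make_tops(list(rbind(c("A", "B")), rbind(c("B", "A")),
                         rbind(c("B", "A")), NULL))
  cn <- consensus_network(tops, threshold = 0.2)
  pab <- cn$prob[cn$from == "A" & cn$to == "B"]
  pba <- cn$prob[cn$from == "B" & cn$to == "A"]
  expect_lte(pab + pba, 1 + 1e-12)
})

test_that("weighted overlay counts match the brute-force oracle", {
  set.seed(5)
  vars <- c("A", "B", "C", "D")
  all_arcs <- expand.grid(from = vars, to = vars,
                          stringsAsFactors = FALSE)
  all_arcs <- all_arcs[all_arcs$from != all_arcs$to, ]
  nets <- lapply(1:8, function(i) {
    take <- all_arcs[sample(nrow(all_arcs), sample(0:5, 1)), ]
    take$prob <- runif(nrow(take), 0.5, 1)
    structure(take, class = c("consensus_net", "data.frame"),
              variables = vars, threshold = 0.5, weighting = "uniform",
              n_networks = 100)
  })
  w <- weighted_network(nets)
  expect_equal(attr(w, "runs"), 8L)
  oracle <- weight_oracle(nets)
  expect_equal(nrow(w), nrow(oracle))
  for (i in seq_len(nrow(w))) {
    expect_equal(
      w$weight[i],
      oracle$weight[oracle$from == w$from[i] & oracle$to == w$to[i]])
  }
  expect_true(all(w$weight >= 1 & w$weight <= 8))
  # single consensus network -> all weights 1, same arc set
  w1 <- weighted_network(nets[1])
  expect_true(all(w1$weight == 1L))
  expect_setequal(paste(w1$from, w1$to), paste(nets[[1]]$from, nets[[1]]$to))
})

test_that("the majority filter uses an inclusive ceiling cutoff", {
  vars <- c("A", "B")
  w <- structure(
    data.frame(from = c("A", "B"), to = c("B", "A"),
               weight = c(25L, 24L), stringsAsFactors = FALSE),
    class = c("weighted_net", "data.frame"), runs = 50L, variables = vars)
  f <- final_network(w, min_fraction = 0.5)
  expect_equal(nrow(f), 1L)
  expect_equal(f$weight, 25L)
  expect_equal(attr(f, "cutoff"), 25)
  # min_fraction = 1 keeps only unanimous arcs
  expect_equal(nrow(final_network(w, 1)), 0L)
  # monotone in min_fraction: raising the threshold never adds arcs
  fracs <- seq(0.1, 1, by = 0.1)
  ns <- vapply(fracs, function(mf) nrow(final_network(w, mf)), integer(1))
  expect_true(all(diff(ns) <= 0L))
  # empty weighted network -> empty final network
  w0 <- structure(
    data.frame(from = character(0), to = character(0), weight = integer(0)),
    class = c("weighted_net", "data.frame"), runs = 50L, variables = vars)
  expect_equal(nrow(final_network(w0)), 0L)
})

test_that("consensus_bn is reproducible and its pieces are consistent", {
  d <- random_discrete(4, 150, seed = 71, concentration = 0.3)
  sch <- anneal_schedule(max_evaluations = 3000)
  fit <- consensus_bn(d, n_runs = 6, schedule = sch, seed = 11)
  fit2 <- consensus_bn(d, n_runs = 6, schedule = sch, seed = 11)
  expect_identical(fit$final, fit2$final)
  expect_identical(fit$weighted, fit2$weighted)
  # final is the filtered weighted network
  expect_true(all(fit$final$weight >= attr(fit$final, "cutoff")))
  expect_true(all(paste(fit$final$from, fit$final$to) %in%
                    paste(fit$weighted$from, fit$weighted$to)))
  # coef exposes arc weights
  co <- coef(fit)
  expect_equal(length(co), nrow(fit$weighted))
  s <- summary(fit)
  expect_equal(s$n_final_arcs, nrow(fit$final))
})

test_that("stability check reports determinism and agreement", {
  d <- random_discrete(4, 200, seed = 81, concentration = 0.2)
  sch <- anneal_schedule(max_evaluations = 3000)
  # identical seeds -> identical final networks, Jaccard 1
  rep_same <- stability_check(d, seeds = c(5, 5), n_runs = 4,
                              schedule = sch)
  expect_true(rep_same$all_identical)
  expect_equal(min(rep_same$jaccard), 1)
  # pure-noise data: the report is produced without error
  set.seed(99)
  noise <- discrete_data(matrix(sample(0:2, 300, TRUE), 100, 3,
                                dimnames = list(NULL, paste0("N", 1:3))))
  rep_noise <- stability_check(noise, seeds = c(1, 2), n_runs = 3,
                               schedule = sch)
  expect_true(is.matrix(rep_noise$jaccard))
})
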