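# Small in-code fixtures shared across test files.

# Discrete dataset from an integer matrix given as rows of states.
dd <- function(..., cardinality = 3L, vars = NULL) {
  m <- rbind(...)
  if (is.null(vars)) vars <- LETTERS[seq_len(ncol(m))]
  colnames(m) <- vars
  discrete_data(m, cardinality = cardinality)
}

# Chain DAG A -> B -> C -> ... over the first n letters.
chain_dag <- function(n) {
  vars <- LETTERS[seq_len(n)]
  dag(vars, cbind(vars[-n], vars[-1L]))
}

# Random discrete dataset sampled from a random ground-truth network.
random_discrete <- function(n_vars, n_obs, seed, max_parents = 2L,
                            concentration = 1) {
  g <- random_dag(n_vars, min(max_parents, n_vars - 1L), seed = seed)
  pd <- sample_cpts(g, concentration = concentration, seed = seed + 1L)
  sample_discrete(pd, n_obs, seed = seed + 2L)
}

# Brute-force Benjamini-Hochberg step-up (independent oracle).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force arc presence/absence summation across consensus networks.
weight_oracle <- function(consensus_list) {
  arcs <- unique(do.call(rbind, lapply(consensus_list, function(x) {
    as.data.frame(x)[, c("from", "to")]
  })))
  if (is.null(arcs) || nrow(arcs) == 0L) return(arcs)
  arcs$weight <- vapply(seq_len(nrow(arcs)), function(i) {
    sum(vapply(consensus_list, function(x) {
      any(x$from == arcs$from[i] & x$to == arcs$to[i])
    }, logical(1)))
  }, numeric(1))
  arcs
}
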