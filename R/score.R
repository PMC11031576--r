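#' Sufficient statistics for one family (child + parent set)
#'
#' Tallies, for every joint parent configuration j and child state k, the
#' number of observations N_jk. Parent configurations are indexed in mixed
#' radix over the parents in listed order (first parent varying fastest),
#' so the indexing is deterministic.
#'
#' @param data A \code{\link{discrete_data}}.
#' @param child Child variable name.
#' @param parents Character vector of parent variable names (may be empty).
#' @return A list of class \code{count_table}: \code{child},
#'   \code{parents}, \code{r} (child cardinality), \code{q} (number of
#'   parent configurations), \code{n_jk} (q x r count matrix), \code{n_j}
#'   (row sums).
#' @export
count_table <- function(data, child, parents = character(0)) {
  stopifnot(inherits(data, "discrete_data"))
  vars <- dd_vars(data)
  unknown <- setdiff(c(child, parents), vars)
  if (length(unknown)) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (child %in% parents) {
    stop("'child' must not appear among 'parents'", call. = FALSE)
  }
  card <- dd_card(data)
  r <- card[[child]]
  pc <- card[parents]
  q <- if (length(parents)) prod(pc) else 1L
  n_jk <- matrix(0L, nrow = q, ncol = r)
  if (nrow(data) > 0L) {
    j <- rep(0L, nrow(data))
    mult <- 1L
    for (i in seq_along(parents)) {
      j <- j + unclass(data)[, parents[i]] * mult
      mult <- mult * pc[[i]]
    }
    tab <- table(factor(j, levels = 0:(q - 1L)),
                 factor(unclass(data)[, child], levels = 0:(r - 1L)))
    n_jk <- matrix(as.integer(tab), nrow = q, ncol = r)
  }
  structure(list(child = child, parents = parents, r = r, q = q,
                 n_jk = n_jk, n_j = rowSums(n_jk)),
            class = "count_table")
}

#' Local BDeu score of one family
#'
#' Log marginal likelihood of a child's data given its parents under a
#' uniform Dirichlet prior scaled by the equivalent sample size (BDeu):
#' \deqn{\sum_j [\ln\Gamma(\alpha_j) - \ln\Gamma(\alpha_j + N_j) +
#'   \sum_k (\ln\Gamma(\alpha_{jk} + N_{jk}) - \ln\Gamma(\alpha_{jk}))]}
#' with \eqn{\alpha_{jk} = ess / (q r)} and \eqn{\alpha_j = ess / q}.
#' Empty data score exactly 0.
#'
#' @param counts A \code{\link{count_table}}.
#' @param ess Equivalent sample size (> 0), default 1.
#' @return The local log score (natural log), a finite number.
#' @export
local_bde <- function(counts, ess = 1) {
  stopifnot(inherits(counts, "count_table"))
  if (!is.numeric(ess) || ess <= 0) {
    stop("'ess' must be > 0", call. = FALSE)
  }
  a_jk <- ess / (counts$q * counts$r)
  a_j <- ess / counts$q
  sum(lgamma(a_j) - lgamma(a_j + counts$n_j)) +
    sum(lgamma(a_jk + counts$n_jk) - lgamma(a_jk))
}

#' Create a cache for family scores
#'
#' Memoizes local BDeu scores by (child, sorted parent set) so that a
#' structure search only rescores the families a move touched.
#'
#' @return An environment usable as the \code{cache} argument of
#'   \code{\link{network_score}}.
#' @export
score_cache <- function() new.env(parent = emptyenv())

# Cached local score of one family.
family_score <- function(data, child, parents, ess, cache = NULL) {
  if (is.null(cache)) {
    return(local_bde(count_table(data, child, parents), ess))
  }
  key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
  val <- cache[[key]]
  if (is.null(val)) {
    val <- local_bde(count_table(data, child, parents), ess)
    cache[[key]] <- val
  }
  val
}

#' BDeu network score of a DAG given complete discrete data
#'
#' The network score decomposes into the sum of local family scores
#' (\code{\link{local_bde}}) over all variables with their parent sets.
#' A uniform structure prior is assumed, so the score is the log marginal
#' likelihood alone. Markov-equivalent DAGs receive identical scores
#' (likelihood equivalence of BDeu).
#'
#' @param data A \code{\link{discrete_data}} whose variables include those
#'   of \code{dag}.
#' @param dag A \code{bn_dag}.
#' @param ess Equivalent sample size (> 0), default 1.
#' @param cache Optional \code{\link{score_cache}}; families already scored
#'   are not recomputed.
#' @return Log network score (natural log).
#' @export
network_score <- function(data, dag, ess = 1, cache = NULL) {
  stopifnot(inherits(data, "discrete_data"), inherits(dag, "bn_dag"))
  unknown <- setdiff(dag$variables, dd_vars(data))
  if (length(unknown)) {
    stop("DAG variables absent from data: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sum(vapply(dag$variables, function(v) {
    family_score(data, v, dag$parents[[v]], ess, cache)
  }, numeric(1)))
}

#' Prequential (sequential-predictive) oracle for the BDeu score
#'
#' Independent brute-force computation of the log marginal likelihood:
#' observations are processed one at a time and each variable's value
#' contributes the log posterior-predictive probability given the counts
#' accumulated so far, \eqn{(\alpha_{jk} + N_{jk}) / (\alpha_j + N_j)}.
#' By the chain rule of the Dirichlet-multinomial this equals the
#' closed-form BDeu score exactly; it is intended as a test oracle on small
#' inputs, not for production scoring.
#'
#' @param data A \code{\link{discrete_data}} (intended for <= 1000 rows and
#'   <= 8 variables).
#' @param dag A \code{bn_dag}.
#' @param ess Equivalent sample size (> 0), default 1.
#' @return Log marginal likelihood.
#' @export
prequential_oracle <- function(data, dag, ess = 1) {
  stopifnot(inherits(data, "discrete_data"), inherits(dag, "bn_dag"))
  if (ess <= 0) stop("'ess' must be > 0", call. = FALSE)
  card <- dd_card(data)
  vars <- dag$variables
  counts <- lapply(vars, function(v) {
    pas <- dag$parents[[v]]
    q <- if (length(pas)) prod(card[pas]) else 1L
    matrix(0, nrow = q, ncol = card[[v]])
  })
  names(counts) <- vars
  logml <- 0
  m <- unclass(data)
  for (row in seq_len(nrow(m))) {
    for (v in vars) {
      pas <- dag$parents[[v]]
      r <- card[[v]]
      q <- nrow(counts[[v]])
      j <- 1L
      if (length(pas)) {
        j <- 1L + config_index(m[row, pas], unname(card[pas]))
      }
      k <- m[row, v] + 1L
      a_jk <- ess / (q * r)
      a_j <- ess / q
      n_j <- sum(counts[[v]][j, ])
      logml <- logml + log((a_jk + counts[[v]][j, k]) / (a_j + n_j))
      counts[[v]][j, k] <- counts[[v]][j, k] + 1
    }
  }
  logml
}
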