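#' Fit a consensus Bayesian network by repeated annealed searches
#'
#' The central estimator of the package. From one discrete dataset it runs
#' \code{n_runs} independent simulated-annealing structure searches, builds
#' a consensus network from the \code{top_n} highest-scoring unique
#' networks of each search (arcs present in at least half of them), overlays
#' the \code{n_runs} consensus networks into a weighted network whose arc
#' weights count supporting runs, and filters the weighted network at
#' majority support (\code{min_fraction}, default: arcs in at least half of
#' the runs) to obtain the final network.
#'
#' All randomness derives from \code{seed} via \code{\link{derive_seeds}},
#' so a fit is exactly reproducible.
#'
#' @param data A \code{\link{discrete_data}} (observations x variables).
#' @param n_runs Number of independent search/consensus runs (default 50).
#' @param top_n Top-scoring unique networks kept per search (default 100).
#' @param consensus_threshold Arc-presence probability threshold within one
#'   consensus network (default 0.5, inclusive).
#' @param min_fraction Majority-support fraction for the final filter
#'   (default 0.5, i.e. 25 of 50 runs).
#' @param schedule An \code{\link{anneal_schedule}}.
#' @param ess Equivalent sample size of the BDeu score (default 1).
#' @param weighting Consensus weighting, \code{"uniform"} or
#'   \code{"score"}.
#' @param seed Integer master seed.
#' @param keep_runs Keep the per-run \code{top_networks} objects (memory
#'   heavy; default \code{FALSE}).
#' @return An object of class \code{consensus_bn} with components
#'   \code{weighted} (the weighted network), \code{final} (the filtered arc
#'   data frame), \code{consensus} (per-run consensus networks),
#'   \code{best_scores} (best log score per run), and the call/settings.
#' @seealso \code{\link{stability_check}} for repeat-to-repeat agreement,
#'   \code{\link{run_pipeline}} for the full expression-to-network
#'   pipeline.
#' @examples
#' truth <- random_dag(6, max_parents = 2, seed = 1)
#' sim <- sample_discrete(noisy_copy_cpts(truth), n_obs = 150, seed = 2)
#' fit <- consensus_bn(sim, n_runs = 5,
#'                     schedule = anneal_schedule(max_evaluations = 2000),
#'                     seed = 3)
#' fit
#' @export
consensus_bn <- function(data, n_runs = 50L, top_n = 100L,
                         consensus_threshold = 0.5, min_fraction = 0.5,
                         schedule = anneal_schedule(), ess = 1,
                         weighting = c("uniform", "score"),
                         seed = NULL, keep_runs = FALSE) {
  stopifnot(inherits(data, "discrete_data"))
  if (n_runs < 1L) stop("'n_runs' must be >= 1", call. = FALSE)
  weighting <- match.arg(weighting)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  run_seeds <- derive_seeds(seed, n_runs)
  consensus <- vector("list", n_runs)
  runs <- if (keep_runs) vector("list", n_runs) else NULL
  best_scores <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    tops <- simulated_annealing(data, schedule = schedule, top_n = top_n,
                                seed = run_seeds[i], ess = ess)
    best_scores[i] <- attr(tops, "best_score")
    consensus[[i]] <- consensus_network(tops, threshold = consensus_threshold,
                                        weighting = weighting)
    if (keep_runs) runs[[i]] <- tops
  }
  weighted <- weighted_network(consensus)
  final <- final_network(weighted, min_fraction = min_fraction)
  structure(list(call = match.call(),
                 variables = dd_vars(data),
                 n_obs = nrow(data),
                 n_runs = n_runs, top_n = top_n,
                 consensus_threshold = consensus_threshold,
                 min_fraction = min_fraction,
                 schedule = schedule, ess = ess, weighting = weighting,
                 seed = seed, run_seeds = run_seeds,
                 best_scores = best_scores,
                 consensus = consensus, weighted = weighted,
                 final = final, runs = runs),
            class = "consensus_bn")
}

#' @export
print.consensus_bn <- function(x, ...) {
  cat("Consensus Bayesian network\n")
  cat("  ", length(x$variables), " variables, ", x$n_obs,
      " observations\n", sep = "")
  cat("  ", x$n_runs, " search runs, top ", x$top_n,
      " networks each; majority filter >= ",
      attr(x$final, "cutoff"), "/", x$n_runs, " runs\n", sep = "")
  cat("  Final network: ", nrow(x$final), " arcs\n", sep = "")
  if (nrow(x$final) > 0L) {
    cat(paste0("    ", x$final$from, " -> ", x$final$to,
               "  (", x$final$weight, "/", x$n_runs, ")"), sep = "\n")
  }
  invisible(x)
}

#' @export
summary.consensus_bn <- function(object, ...) {
  sk <- skeleton(object$final)
  out <- list(n_variables = length(object$variables),
              n_obs = object$n_obs,
              n_runs = object$n_runs,
              best_score_range = range(object$best_scores),
              n_weighted_arcs = nrow(object$weighted),
              n_final_arcs = nrow(object$final),
              n_skeleton_edges = nrow(sk),
              cutoff = attr(object$final, "cutoff"),
              final = object$final)
  class(out) <- "summary.consensus_bn"
  out
}

#' @export
print.summary.consensus_bn <- function(x, ...) {
  cat("Consensus Bayesian network fit\n")
  cat("  Variables:          ", x$n_variables, "\n")
  cat("  Observations:       ", x$n_obs, "\n")
  cat("  Search runs:        ", x$n_runs, "\n")
  cat("  Best score range:   ",
      paste(format(x$best_score_range), collapse = " .. "), "\n")
  cat("  Weighted arcs:      ", x$n_weighted_arcs, "\n")
  cat("  Final arcs (>= ", x$cutoff, "): ", x$n_final_arcs,
      " (", x$n_skeleton_edges, " skeleton edges)\n", sep = "")
  if (x$n_final_arcs > 0L) print(x$final)
  invisible(x)
}

#' Arc support weights of a fitted consensus network
#'
#' @param object A \code{consensus_bn} fit.
#' @param ... Unused.
#' @return Named numeric vector: for every arc in the weighted network, the
#'   number of consensus runs supporting it, named \code{"from->to"}.
#' @export
coef.consensus_bn <- function(object, ...) {
  w <- object$weighted
  if (nrow(w) == 0L) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(as.numeric(w$weight), paste0(w$from, "->", w$to))
}

#' Plot a fitted consensus network
#'
#' Draws the final network with edge widths proportional to arc support.
#' Requires the \pkg{igraph} package.
#'
#' @param x A \code{consensus_bn} fit.
#' @param which \code{"final"} (default) or \code{"weighted"}.
#' @param ... Passed to \code{plot.igraph}.
#' @export
plot.consensus_bn <- function(x, which = c("final", "weighted"), ...) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("plotting requires the 'igraph' package", call. = FALSE)
  }
  which <- match.arg(which)
  edges <- if (which == "final") x$final else x$weighted
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = x$variables))
  ew <- if (nrow(edges) > 0L) 1 + 3 * edges$weight / x$n_runs else numeric(0)
  igraph::plot.igraph(g, edge.width = ew, ...)
  invisible(g)
}
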