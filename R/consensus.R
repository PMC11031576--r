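#' Consensus network from the top networks of one search
#'
#' Each arc's presence probability is estimated across the retained
#' top-scoring networks — uniformly (each network counts once, the
#' default) or score-weighted (networks weighted by their normalized
#' exponentiated log scores) — and arcs at or above the threshold are kept.
#' The threshold is inclusive: probability exactly 0.5 is retained under
#' the default.
#'
#' @param tops A nonempty \code{top_networks} collection.
#' @param threshold Minimum presence probability in (0, 1]; default 0.5.
#' @param weighting \code{"uniform"} (default) or \code{"score"}.
#' @return An object of class \code{consensus_net}: a data frame with
#'   columns \code{from}, \code{to}, \code{prob}, sorted by descending
#'   probability then lexicographic arc, with a \code{variables} attribute.
#' @export
consensus_network <- function(tops, threshold = 0.5,
                              weighting = c("uniform", "score")) {
  stopifnot(inherits(tops, "top_networks"))
  if (length(tops) == 0L) stop("'tops' is empty", call. = FALSE)
  if (!(threshold > 0 && threshold <= 1)) {
    stop("'threshold' must lie in (0, 1]", call. = FALSE)
  }
  weighting <- match.arg(weighting)
  w <- if (weighting == "uniform") {
    rep(1 / length(tops), length(tops))
  } else {
    ls <- vapply(tops, `[[`, numeric(1), "log_score")
    ew <- exp(ls - max(ls))
    ew / sum(ew)
  }
  probs <- new.env(parent = emptyenv())
  for (i in seq_along(tops)) {
    a <- arcs(tops[[i]]$dag)
    if (nrow(a) == 0L) next
    keys <- paste(a[, 1L], a[, 2L], sep = "\r")
    for (key in keys) {
      probs[[key]] <- (if (is.null(probs[[key]])) 0 else probs[[key]]) + w[i]
    }
  }
  keys <- ls(probs)
  if (length(keys) == 0L) {
    out <- data.frame(from = character(0), to = character(0),
                      prob = numeric(0), stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    out <- data.frame(from = vapply(parts, `[`, character(1), 1L),
                      to = vapply(parts, `[`, character(1), 2L),
                      prob = vapply(keys, function(k) probs[[k]], numeric(1)),
                      row.names = NULL, stringsAsFactors = FALSE)
    # tolerance absorbs accumulation error in the probability sums
    out <- out[out$prob >= threshold - 1e-12, , drop = FALSE]
    out <- out[order(-out$prob, out$from, out$to), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("consensus_net", "data.frame"),
            variables = attr(tops, "variables"), threshold = threshold,
            weighting = weighting, n_networks = length(tops))
}

#' Overlay consensus networks into a weighted network
#'
#' Converts each consensus network to a presence/absence indicator per arc
#' and sums the indicators across the R runs, so each retained arc carries
#' an integer weight in 1..R: the number of consensus networks that contain
#' it.
#'
#' @param consensus_list Nonempty list of \code{consensus_net} objects over
#'   the same variable set.
#' @return An object of class \code{weighted_net}: data frame with columns
#'   \code{from}, \code{to}, \code{weight}, sorted by descending weight then
#'   lexicographic arc, with attributes \code{runs} (R) and
#'   \code{variables}.
#' @export
weighted_network <- function(consensus_list) {
  if (inherits(consensus_list, "consensus_net")) {
    consensus_list <- list(consensus_list)
  }
  stopifnot(is.list(consensus_list), length(consensus_list) >= 1L)
  lapply(consensus_list, function(x) stopifnot(inherits(x, "consensus_net")))
  ref <- attr(consensus_list[[1L]], "variables")
  for (i in seq_along(consensus_list)[-1L]) {
    vi <- attr(consensus_list[[i]], "variables")
    if (!setequal(ref, vi)) {
      stop("consensus networks 1 and ", i, " span different variable sets",
           call. = FALSE)
    }
  }
  all_arcs <- do.call(rbind, lapply(consensus_list, function(x) {
    unique(as.data.frame(x)[, c("from", "to"), drop = FALSE])
  }))
  if (nrow(all_arcs) == 0L) {
    out <- data.frame(from = character(0), to = character(0),
                      weight = integer(0), stringsAsFactors = FALSE)
  } else {
    key <- paste(all_arcs$from, all_arcs$to, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    out <- data.frame(from = vapply(parts, `[`, character(1), 1L),
                      to = vapply(parts, `[`, character(1), 2L),
                      weight = as.integer(tab),
                      row.names = NULL, stringsAsFactors = FALSE)
    out <- out[order(-out$weight, out$from, out$to), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("weighted_net", "data.frame"),
            runs = length(consensus_list), variables = ref)
}

#' Majority-support filter on a weighted network
#'
#' Retains the arcs supported by at least \code{ceiling(min_fraction * R)}
#' of the R consensus runs (with R = 50 and the default fraction this is
#' the 25-or-more rule). The result is a directed graph that need not be
#' acyclic, since its arcs come from different runs.
#'
#' @param weighted A \code{weighted_net}.
#' @param min_fraction Minimum support fraction in (0, 1]; default 0.5.
#' @return A data frame (\code{from}, \code{to}, \code{weight}) sorted by
#'   descending weight then lexicographic arc, with attributes \code{runs}
#'   and \code{cutoff}.
#' @export
final_network <- function(weighted, min_fraction = 0.5) {
  stopifnot(inherits(weighted, "weighted_net"))
  if (!(min_fraction > 0 && min_fraction <= 1)) {
    stop("'min_fraction' must lie in (0, 1]", call. = FALSE)
  }
  runs <- attr(weighted, "runs")
  cutoff <- ceiling(min_fraction * runs)
  out <- as.data.frame(weighted)[weighted$weight >= cutoff, , drop = FALSE]
  out <- out[order(-out$weight, out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("final_net", "data.frame"), runs = runs,
            cutoff = cutoff, variables = attr(weighted, "variables"))
}

#' @export
print.consensus_net <- function(x, ...) {
  cat("Consensus network: ", nrow(x), " arcs at threshold >= ",
      attr(x, "threshold"), " over ", attr(x, "n_networks"),
      " top networks (", attr(x, "weighting"), " weighting)\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
print.weighted_net <- function(x, ...) {
  cat("Weighted network over ", attr(x, "runs"), " consensus runs: ",
      nrow(x), " arcs (weights ",
      if (nrow(x)) paste(range(x$weight), collapse = "..") else "-",
      ")\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
print.final_net <- function(x, ...) {
  cat("Final network: ", nrow(x), " arcs supported by >= ",
      attr(x, "cutoff"), " of ", attr(x, "runs"),
      " consensus runs\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' Stability of the full aggregation across repeated runs
#'
#' Repeats the whole search-to-final-network chain with independent seeds
#' and reports whether the repeats agree: pairwise arc-set equality and the
#' Jaccard index between final arc sets. A robust signal should yield
#' identical final networks across repeats.
#'
#' @param data A \code{\link{discrete_data}}.
#' @param seeds Integer vector of length >= 2, one seed per repeat.
#' @param ... Arguments passed to \code{\link{consensus_bn}} (schedule,
#'   \code{n_runs}, \code{top_n}, \code{min_fraction}, \code{ess}, ...).
#' @return A list of class \code{stability_report}: \code{finals} (the
#'   final arc data frames), \code{equal} and \code{jaccard} (pairwise
#'   matrices), and \code{all_identical}.
#' @export
stability_check <- function(data, seeds, ...) {
  stopifnot(length(seeds) >= 2L)
  fits <- lapply(seeds, function(s) consensus_bn(data, seed = s, ...))
  finals <- lapply(fits, `[[`, "final")
  keys <- lapply(finals, function(f) {
    if (nrow(f) == 0L) character(0) else paste(f$from, f$to, sep = ">")
  })
  n <- length(seeds)
  eq <- matrix(TRUE, n, n)
  jac <- matrix(1, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      eq[i, j] <- setequal(keys[[i]], keys[[j]])
      u <- length(union(keys[[i]], keys[[j]]))
      jac[i, j] <- if (u == 0L) 1 else
        length(intersect(keys[[i]], keys[[j]])) / u
    }
  }
  structure(list(seeds = seeds, finals = finals, equal = eq, jaccard = jac,
                 all_identical = all(eq)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability over ", length(x$seeds), " repeats: ",
      if (x$all_identical) "all final networks identical"
      else paste0("min pairwise Jaccard = ",
                  format(min(x$jaccard), digits = 3)),
      "\n", sep = "")
  invisible(x)
}
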