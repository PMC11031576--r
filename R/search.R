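#' Annealing schedule for the structure search
#'
#' @param initial_temperature Starting temperature (> 0), or \code{NULL}
#'   (default) to calibrate it from the data: the temperature is set so a
#'   move of size equal to the median absolute score change of 100 random
#'   single-arc additions from the empty graph is accepted with probability
#'   about 0.8.
#' @param cooling_factor Geometric cooling multiplier in (0, 1), applied
#'   every \code{moves_per_temperature} evaluations. Default 0.999.
#' @param moves_per_temperature Evaluations between cooling steps (>= 1).
#'   Default 10, so the default schedule anneals through roughly three
#'   orders of magnitude of temperature over a 1e5-evaluation run.
#' @param max_evaluations Total number of network score evaluations
#'   (proposals, including the initial empty graph). Default 1e5.
#' @param max_parents Maximum in-degree during the search. Default 5.
#' @return An object of class \code{anneal_schedule}.
#' @export
anneal_schedule <- function(initial_temperature = NULL,
                            cooling_factor = 0.999,
                            moves_per_temperature = 10L,
                            max_evaluations = 1e5,
                            max_parents = 5L) {
  if (!is.null(initial_temperature) && initial_temperature <= 0) {
    stop("'initial_temperature' must be > 0", call. = FALSE)
  }
  if (cooling_factor <= 0 || cooling_factor >= 1) {
    stop("'cooling_factor' must lie in (0, 1)", call. = FALSE)
  }
  if (moves_per_temperature < 1) {
    stop("'moves_per_temperature' must be >= 1", call. = FALSE)
  }
  if (max_evaluations < 1) {
    stop("'max_evaluations' must be >= 1", call. = FALSE)
  }
  if (max_parents < 0) stop("'max_parents' must be >= 0", call. = FALSE)
  structure(list(initial_temperature = initial_temperature,
                 cooling_factor = cooling_factor,
                 moves_per_temperature = as.integer(moves_per_temperature),
                 max_evaluations = max_evaluations,
                 max_parents = as.integer(max_parents)),
            class = "anneal_schedule")
}

#' Metropolis acceptance rule
#'
#' An improving move (\code{delta > 0}) is always accepted; a worsening move
#' is accepted with probability \code{exp(delta / temperature)}.
#'
#' @param delta Score change of the proposed move (new minus old).
#' @param temperature Current temperature (> 0).
#' @return \code{TRUE} to accept, \code{FALSE} to retain the current state.
#' @export
metropolis_accept <- function(delta, temperature) {
  if (temperature <= 0) stop("'temperature' must be > 0", call. = FALSE)
  if (delta > 0) return(TRUE)
  stats::runif(1) < exp(delta / temperature)
}

#' One proposal step of the annealing search
#'
#' Draws one move uniformly at random from the legal moves of the current
#' structure, rescores only the families the move touches, and applies the
#' Metropolis rule. This is the reference R implementation of the step the
#' compiled search loop iterates; it is exported so the move/acceptance
#' mechanics can be exercised and instrumented directly.
#'
#' @param current List with elements \code{dag} (a \code{bn_dag}) and
#'   \code{log_score} (its score).
#' @param temperature Current temperature (> 0).
#' @param data A \code{\link{discrete_data}}.
#' @param ess Equivalent sample size.
#' @param cache A \code{\link{score_cache}} (strongly recommended).
#' @param max_parents Maximum in-degree.
#' @return A list \code{(dag, log_score, proposed_score, accepted)}; when
#'   no legal move exists the current state is returned with
#'   \code{accepted = FALSE}.
#' @export
propose_and_decide <- function(current, temperature, data, ess = 1,
                               cache = NULL, max_parents = 5L) {
  stopifnot(inherits(current$dag, "bn_dag"))
  if (temperature <= 0) stop("'temperature' must be > 0", call. = FALSE)
  mv <- legal_moves(current$dag, max_parents)
  if (nrow(mv) == 0L) {
    return(list(dag = current$dag, log_score = current$log_score,
                proposed_score = NA_real_, accepted = FALSE))
  }
  pick <- mv[sample.int(nrow(mv), 1L), ]
  cand <- apply_move(current$dag, pick$kind, pick$from, pick$to)
  touched <- if (pick$kind == "reverse") c(pick$from, pick$to) else pick$to
  delta <- 0
  for (v in touched) {
    delta <- delta +
      family_score(data, v, cand$parents[[v]], ess, cache) -
      family_score(data, v, current$dag$parents[[v]], ess, cache)
  }
  accepted <- metropolis_accept(delta, temperature)
  if (accepted) {
    list(dag = cand, log_score = current$log_score + delta,
         proposed_score = current$log_score + delta, accepted = TRUE)
  } else {
    list(dag = current$dag, log_score = current$log_score,
         proposed_score = current$log_score + delta, accepted = FALSE)
  }
}

# Calibrate the initial temperature: median |delta| of single-arc additions
# from the empty graph, scaled so that move is accepted with prob ~0.8.
calibrate_temperature <- function(data, ess, n_probe = 100L) {
  vars <- dd_vars(data)
  p <- length(vars)
  if (p < 2L) return(1)
  cache <- score_cache()
  deltas <- numeric(n_probe)
  for (i in seq_len(n_probe)) {
    pair <- sample.int(p, 2L)
    deltas[i] <-
      family_score(data, vars[pair[2L]], vars[pair[1L]], ess, cache) -
      family_score(data, vars[pair[2L]], character(0), ess, cache)
  }
  med <- stats::median(abs(deltas))
  if (med == 0) med <- 1
  med / log(1 / 0.8)
}

#' Simulated-annealing search over DAG structures
#'
#' Starts from the empty graph and iterates single-arc moves (add, delete,
#' reverse) drawn uniformly from the legal move set, accepting by the
#' Metropolis rule under geometric cooling, until \code{max_evaluations}
#' networks have been scored. Every evaluated structure — accepted or not —
#' is offered to a bounded collection of the \code{top_n} highest-scoring
#' unique networks. The same seed reproduces the search exactly.
#'
#' The inner loop runs in compiled code with family-score memoization;
#' budgets of millions of evaluations are practical.
#'
#' @param data A nonempty \code{\link{discrete_data}}.
#' @param schedule An \code{\link{anneal_schedule}}.
#' @param top_n Number of top-scoring unique networks to retain
#'   (default 100).
#' @param seed Optional integer seed.
#' @param ess Equivalent sample size for the BDeu score (default 1).
#' @return An object of class \code{top_networks}: a list of entries, each
#'   \code{(dag, log_score)}, sorted by descending score (ties broken by
#'   the lexicographic arc set), plus attributes \code{n_evaluations},
#'   \code{best_score}, \code{accepted}.
#' @export
simulated_annealing <- function(data, schedule = anneal_schedule(),
                                top_n = 100L, seed = NULL, ess = 1) {
  stopifnot(inherits(data, "discrete_data"))
  if (nrow(data) < 1L) stop("'data' must be nonempty", call. = FALSE)
  if (top_n < 1L) stop("'top_n' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t0 <- schedule$initial_temperature
  if (is.null(t0)) t0 <- calibrate_temperature(data, ess)
  vars <- dd_vars(data)
  res <- sa_search_cpp(unclass(data)[, , drop = FALSE],
                       as.integer(dd_card(data)), ess,
                       schedule$max_parents, t0,
                       schedule$cooling_factor,
                       schedule$moves_per_temperature,
                       as.numeric(schedule$max_evaluations),
                       as.integer(top_n))
  entries <- lapply(res$top, function(e) {
    am <- e$arcs
    arcs <- if (nrow(am) > 0L) {
      cbind(vars[am[, 1L]], vars[am[, 2L]])
    } else NULL
    list(dag = dag(vars, arcs, check = FALSE), log_score = e$log_score)
  })
  structure(entries, class = "top_networks",
            variables = vars,
            n_evaluations = res$n_evaluations,
            best_score = res$best_score,
            accepted = res$accepted,
            final_temperature = res$final_temperature,
            initial_temperature = t0, ess = ess)
}

#' @export
print.top_networks <- function(x, ...) {
  cat("Top ", length(x), " unique networks from ",
      format(attr(x, "n_evaluations"), big.mark = ","),
      " evaluations\n", sep = "")
  cat("Best log score: ", format(attr(x, "best_score")), "\n", sep = "")
  invisible(x)
}

#' Exhaustive structure search by DAG enumeration
#'
#' Enumerates every labeled DAG over the data's variables (at most 5 — the
#' count grows super-exponentially), scores each with the BDeu score, and
#' returns a maximum-scoring structure, breaking score ties by the
#' lexicographically smallest arc set. Used as the ground-truth oracle for
#' the stochastic search on small instances.
#'
#' @param data A \code{\link{discrete_data}} with at most 5 variables.
#' @param ess Equivalent sample size (default 1).
#' @return A list \code{(dag, log_score, n_dags)} where \code{n_dags} is
#'   the number of labeled DAGs enumerated (3 for 2 variables, 25 for 3,
#'   543 for 4, 29281 for 5).
#' @export
exhaustive_search <- function(data, ess = 1) {
  stopifnot(inherits(data, "discrete_data"))
  vars <- dd_vars(data)
  if (length(vars) > 5L) {
    stop("exhaustive enumeration is limited to 5 variables (got ",
         length(vars), ")", call. = FALSE)
  }
  res <- exhaustive_cpp(unclass(data)[, , drop = FALSE],
                        as.integer(dd_card(data)), ess)
  am <- res$arcs
  arcs <- if (nrow(am) > 0L) cbind(vars[am[, 1L]], vars[am[, 2L]]) else NULL
  list(dag = dag(vars, arcs), log_score = res$log_score,
       n_dags = res$n_dags)
}
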