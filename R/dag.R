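#' Construct a directed acyclic graph over named variables
#'
#' A DAG is stored as a parent-set list: for every variable, the character
#' vector of its parents. Arcs are ordered pairs \code{parent -> child};
#' direction encodes statistical dependence, not causation.
#'
#' @param variables Character vector of unique variable names.
#' @param arcs Optional two-column matrix or data frame of arcs
#'   (column 1 = parent, column 2 = child). Defaults to the empty graph.
#' @param check If \code{TRUE} (default), verify acyclicity.
#' @return An object of class \code{bn_dag}.
#' @examples
#' g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' is_acyclic(g)
#' @export
dag <- function(variables, arcs = NULL, check = TRUE) {
  variables <- as.character(variables)
  if (length(variables) < 1L) {
    stop("a DAG needs at least one variable", call. = FALSE)
  }
  if (anyDuplicated(variables)) {
    stop("variable names must be unique", call. = FALSE)
  }
  parents <- stats::setNames(
    replicate(length(variables), character(0), simplify = FALSE), variables)
  if (!is.null(arcs) && NROW(arcs) > 0L) {
    arcs <- as.matrix(arcs)
    if (ncol(arcs) != 2L) stop("'arcs' must have two columns", call. = FALSE)
    storage.mode(arcs) <- "character"
    bad <- !(arcs %in% variables)
    if (any(bad)) {
      stop("unknown variables in arcs: ",
           paste(unique(arcs[bad]), collapse = ", "), call. = FALSE)
    }
    if (any(arcs[, 1L] == arcs[, 2L])) {
      stop("self-loops are not allowed", call. = FALSE)
    }
    for (i in seq_len(nrow(arcs))) {
      ch <- arcs[i, 2L]
      if (arcs[i, 1L] %in% parents[[ch]]) next  # at most one arc per pair
      parents[[ch]] <- c(parents[[ch]], arcs[i, 1L])
    }
  }
  g <- structure(list(variables = variables, parents = parents),
                 class = "bn_dag")
  if (check && !is_acyclic(g)) {
    stop("arcs define a cyclic graph", call. = FALSE)
  }
  g
}

#' @export
print.bn_dag <- function(x, ...) {
  a <- arcs(x)
  cat("Directed acyclic graph: ", length(x$variables), " variables, ",
      nrow(a), " arcs\n", sep = "")
  if (nrow(a) > 0L) {
    cat(paste0("  ", a[, 1L], " -> ", a[, 2L]), sep = "\n")
  }
  invisible(x)
}

#' Arc set of a DAG
#'
#' @param dag A \code{bn_dag} object.
#' @return A two-column character matrix (\code{from}, \code{to}), sorted
#'   lexicographically so equal graphs yield identical matrices.
#' @export
arcs <- function(dag) {
  stopifnot(inherits(dag, "bn_dag"))
  from <- unlist(dag$parents, use.names = FALSE)
  to <- rep(names(dag$parents), lengths(dag$parents))
  m <- cbind(from = from, to = to)
  if (nrow(m) > 1L) m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  m
}

#' Test whether a directed graph admits a topological order
#'
#' Kahn's algorithm: repeatedly remove parentless variables; the graph is
#' acyclic iff all variables can be removed.
#'
#' @param dag A \code{bn_dag} object.
#' @return \code{TRUE} iff the graph is acyclic.
#' @export
is_acyclic <- function(dag) {
  !is.null(topo_sort(dag))
}

# Topological order of a bn_dag, or NULL if the graph is cyclic.
topo_sort <- function(dag) {
  indeg <- lengths(dag$parents)
  children <- child_map(dag)
  queue <- names(indeg)[indeg == 0L]
  order <- character(0)
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) == length(dag$variables)) order else NULL
}

# variable -> character vector of children
child_map <- function(dag) {
  children <- stats::setNames(
    replicate(length(dag$variables), character(0), simplify = FALSE),
    dag$variables)
  for (ch in dag$variables) {
    for (pa in dag$parents[[ch]]) children[[pa]] <- c(children[[pa]], ch)
  }
  children
}

# TRUE iff a directed path from 'from' to 'to' exists (DFS).
has_path <- function(dag, from, to, children = child_map(dag)) {
  if (from == to) return(TRUE)
  seen <- character(0)
  stack <- from
  while (length(stack) > 0L) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v %in% seen) next
    if (v == to) return(TRUE)
    seen <- c(seen, v)
    stack <- c(stack, children[[v]])
  }
  FALSE
}

#' Generate a random DAG
#'
#' Draws a uniformly random permutation of the variables as a topological
#' order, then includes each order-respecting arc independently with
#' probability \code{arc_prob}, truncating each parent set at
#' \code{max_parents} (keeping the parents earliest in the order). Acyclicity
#' holds by construction.
#'
#' @param n_vars Number of variables (>= 1). Variables are named
#'   \code{V01, V02, ...}.
#' @param max_parents Maximum in-degree, \code{0 <= max_parents < n_vars}.
#' @param seed Optional integer seed for reproducibility.
#' @param arc_prob Inclusion probability per order-respecting pair.
#' @return A \code{bn_dag}.
#' @examples
#' random_dag(5, max_parents = 2, seed = 1)
#' @export
random_dag <- function(n_vars, max_parents, seed = NULL, arc_prob = 0.3) {
  if (!is.numeric(n_vars) || length(n_vars) != 1L || n_vars < 1) {
    stop("'n_vars' must be a positive integer", call. = FALSE)
  }
  n_vars <- as.integer(n_vars)
  if (max_parents < 0 || max_parents >= n_vars) {
    stop("'max_parents' must satisfy 0 <= max_parents < n_vars",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  vars <- sprintf("V%02d", seq_len(n_vars))
  ord <- sample(vars)
  parents <- stats::setNames(
    replicate(n_vars, character(0), simplify = FALSE), vars)
  if (n_vars > 1L && max_parents > 0L) {
    for (i in 2:n_vars) {
      earlier <- ord[seq_len(i - 1L)]
      keep <- earlier[stats::runif(length(earlier)) < arc_prob]
      if (length(keep) > max_parents) keep <- keep[seq_len(max_parents)]
      parents[[ord[i]]] <- keep
    }
  }
  structure(list(variables = vars, parents = parents), class = "bn_dag")
}

#' Enumerate the legal single-arc moves from a DAG
#'
#' The move set is arc addition, arc deletion, and arc reversal. A move is
#' legal iff its application yields a distinct acyclic graph in which no
#' variable exceeds \code{max_parents} parents.
#'
#' @param dag A \code{bn_dag}.
#' @param max_parents Maximum in-degree constraint.
#' @return A data frame with columns \code{kind} (\code{"add"},
#'   \code{"delete"}, \code{"reverse"}), \code{from}, \code{to}.
#' @export
legal_moves <- function(dag, max_parents = Inf) {
  stopifnot(inherits(dag, "bn_dag"))
  vars <- dag$variables
  children <- child_map(dag)
  kind <- from <- to <- character(0)
  for (x in vars) {
    for (y in vars) {
      if (x == y) next
      if (x %in% dag$parents[[y]]) {
        kind <- c(kind, "delete"); from <- c(from, x); to <- c(to, y)
        # reverse x->y: drop the arc, then y->x must not close a cycle and
        # x must have spare parent capacity
        if (length(dag$parents[[x]]) + 1L <= max_parents) {
          tmp <- dag
          tmp$parents[[y]] <- setdiff(tmp$parents[[y]], x)
          if (!has_path(tmp, x, y)) {
            kind <- c(kind, "reverse"); from <- c(from, x); to <- c(to, y)
          }
        }
      } else if (!(y %in% dag$parents[[x]])) {
        if (length(dag$parents[[y]]) + 1L <= max_parents &&
            !has_path(dag, y, x, children)) {
          kind <- c(kind, "add"); from <- c(from, x); to <- c(to, y)
        }
      }
    }
  }
  data.frame(kind = kind, from = from, to = to, stringsAsFactors = FALSE)
}

#' Apply a single-arc move to a DAG
#'
#' @param dag A \code{bn_dag}.
#' @param kind One of \code{"add"}, \code{"delete"}, \code{"reverse"}.
#' @param from,to The arc's parent and child variable.
#' @return The modified \code{bn_dag}.
#' @export
apply_move <- function(dag, kind, from, to) {
  stopifnot(inherits(dag, "bn_dag"))
  kind <- match.arg(kind, c("add", "delete", "reverse"))
  present <- from %in% dag$parents[[to]]
  if (kind == "add") {
    if (present) stop("arc already present", call. = FALSE)
    dag$parents[[to]] <- c(dag$parents[[to]], from)
  } else if (kind == "delete") {
    if (!present) stop("arc not present", call. = FALSE)
    dag$parents[[to]] <- setdiff(dag$parents[[to]], from)
  } else {
    if (!present) stop("arc not present", call. = FALSE)
    dag$parents[[to]] <- setdiff(dag$parents[[to]], from)
    dag$parents[[from]] <- c(dag$parents[[from]], to)
  }
  dag
}

# Canonical single-string key for a DAG structure (used for deduplication).
dag_key <- function(dag) {
  a <- arcs(dag)
  paste(paste(a[, 1L], a[, 2L], sep = ">"), collapse = ";")
}

#' Undirected skeleton of a directed graph
#'
#' @param x A \code{bn_dag} or a two-column arc matrix / data frame.
#' @return A two-column character matrix of undirected edges, each written
#'   with its endpoints in lexicographic order, deduplicated and sorted.
#' @export
skeleton <- function(x) {
  a <- if (inherits(x, "bn_dag")) arcs(x) else as.matrix(x)[, 1:2, drop = FALSE]
  storage.mode(a) <- "character"
  if (nrow(a) == 0L) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("a", "b"))))
  }
  e <- t(apply(a, 1L, sort))
  e <- unique(e)
  colnames(e) <- c("a", "b")
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}
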