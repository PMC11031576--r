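#' Per-probe Welch two-sample test between two groups
#'
#' Computes, for every probe (row) of an expression set, the Welch
#' unequal-variance t statistic, its two-sided p-value under the
#' Welch-Satterthwaite degrees of freedom, and Benjamini-Hochberg adjusted
#' p-values. Probes are returned in input order.
#'
#' When both groups have zero within-group variance the statistic is
#' undefined; by convention such probes get \code{t = 0, p = 1} when the
#' group means are equal, and \code{p = 0} with an infinite statistic when
#' they differ.
#'
#' @param expr An \code{\link{expression_set}}.
#' @param groups Two-level factor/character vector aligned with the columns
#'   of \code{expr}; defaults to the \code{group} column of the sample
#'   metadata.
#' @return A data frame of class \code{deg_table} with columns
#'   \code{probe_id}, \code{gene_id} (NA unless annotated later),
#'   \code{mean_1}, \code{mean_2}, \code{t}, \code{p}, \code{p_adj}.
#' @examples
#' es <- two_group_expression(50, 5, 3, effect = 3, seed = 1)
#' head(differential_test(es))
#' @export
differential_test <- function(expr, groups = expr$samples$group) {
  stopifnot(inherits(expr, "expr_set"))
  groups <- as.character(groups)
  if (length(groups) != ncol(expr$values)) {
    stop("'groups' must align with the expression columns", call. = FALSE)
  }
  lev <- sort(unique(groups[!is.na(groups)]))
  if (length(lev) != 2L) {
    stop("'groups' must have exactly two levels", call. = FALSE)
  }
  i1 <- which(groups == lev[1L]); i2 <- which(groups == lev[2L])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  x1 <- expr$values[, i1, drop = FALSE]
  x2 <- expr$values[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    same <- degenerate & (m1 == m2)
    tstat[same] <- 0; p[same] <- 1
    diffm <- degenerate & (m1 != m2)
    tstat[diffm] <- sign(m1[diffm] - m2[diffm]) * Inf
    p[diffm] <- 0
  }
  out <- data.frame(probe_id = rownames(expr$values),
                    gene_id = NA_character_,
                    mean_1 = unname(m1), mean_2 = unname(m2),
                    t = unname(tstat), p = unname(p),
                    p_adj = bh_adjust(unname(p)),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order and
#' clipped at 1 (delegates to \code{\link[stats]{p.adjust}} after input
#' validation).
#'
#' @param pvalues Numeric vector with all entries in \code{[0, 1]}.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Select the differential-expression signal at an FDR threshold
#'
#' Keeps probes whose adjusted p-value is less than or equal to
#' \code{alpha} (the threshold is inclusive), ordered by ascending adjusted
#' p-value with ties broken by probe id.
#'
#' @param table A \code{deg_table} from \code{\link{differential_test}}.
#' @param alpha Adjusted-p threshold in \code{(0, 1]}; default 0.02.
#' @return Character vector of selected probe ids.
#' @export
select_signal <- function(table, alpha = 0.02) {
  stopifnot(is.data.frame(table), all(c("probe_id", "p_adj") %in% names(table)))
  if (!(alpha > 0 && alpha <= 1)) {
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  }
  keep <- table[table$p_adj <= alpha, , drop = FALSE]
  keep <- keep[order(keep$p_adj, keep$probe_id), , drop = FALSE]
  keep$probe_id
}

#' Collapse duplicate probes to one row per gene
#'
#' Probes annotated to the same gene are averaged into a single expression
#' row (arithmetic mean per sample). Output genes appear in order of first
#' appearance among the input probes.
#'
#' @param expr An \code{\link{expression_set}} with probe ids as row names.
#' @param probe_to_gene Data frame with columns \code{probe_id},
#'   \code{gene_id}, or a named character vector (names = probe ids).
#' @param unannotated What to do with probes lacking a gene id:
#'   \code{"drop"} them with a warning (default) or \code{"error"}.
#' @return An \code{\link{expression_set}} with one row per gene.
#' @export
collapse_probes <- function(expr, probe_to_gene,
                            unannotated = c("drop", "error")) {
  stopifnot(inherits(expr, "expr_set"))
  unannotated <- match.arg(unannotated)
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(as.character(probe_to_gene$gene_id),
                           as.character(probe_to_gene$probe_id))
  } else {
    map <- probe_to_gene
  }
  probes <- rownames(expr$values)
  genes <- unname(map[probes])
  missing <- is.na(genes) | genes == ""
  if (any(missing)) {
    if (unannotated == "error") {
      stop("unannotated probes: ",
           paste(probes[missing], collapse = ", "), call. = FALSE)
    }
    warning("dropping ", sum(missing), " unannotated probe(s): ",
            paste(utils::head(probes[missing], 5L), collapse = ", "),
            if (sum(missing) > 5L) ", ..." else "", call. = FALSE)
  }
  keep <- !missing
  vals <- expr$values[keep, , drop = FALSE]
  genes <- genes[keep]
  ug <- unique(genes)  # first-appearance order
  out <- matrix(0, nrow = length(ug), ncol = ncol(vals),
                dimnames = list(ug, colnames(vals)))
  for (g in ug) {
    out[g, ] <- colMeans(vals[genes == g, , drop = FALSE])
  }
  expression_set(out, expr$samples)
}
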