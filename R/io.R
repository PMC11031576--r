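#' Write / read an expression set as TSV
#'
#' The expression matrix is written with gene ids in the first column
#' (\code{gene_id}) and one column per sample; the sample metadata
#' (\code{sample_id}, \code{dataset_id}, \code{group}) goes to a companion
#' TSV.
#'
#' @param expr An \code{\link{expression_set}}.
#' @param path Output TSV path for the matrix.
#' @param meta_path Output TSV path for the metadata; default
#'   \code{<path>.meta.tsv}.
#' @return \code{path}, invisibly.
#' @export
write_expression_tsv <- function(expr, path,
                                 meta_path = paste0(path, ".meta.tsv")) {
  stopifnot(inherits(expr, "expr_set"))
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param path,meta_path Paths written by \code{write_expression_tsv}.
#' @export
read_expression_tsv <- function(path, meta_path = paste0(path, ".meta.tsv")) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  samples <- if (file.exists(meta_path)) {
    utils::read.delim(meta_path, stringsAsFactors = FALSE)
  } else NULL
  expression_set(m, samples)
}

#' Write / read a discrete dataset as TSV
#'
#' Integer states with a header row of variable names and a leading
#' \code{dataset_id} provenance column.
#'
#' @param data A \code{\link{discrete_data}}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_discrete_tsv <- function(data, path) {
  stopifnot(inherits(data, "discrete_data"))
  ids <- attr(data, "dataset_id")
  if (is.null(ids)) ids <- rep("d1", nrow(data))
  df <- data.frame(dataset_id = ids, unclass(data), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_discrete_tsv
#' @param cardinality States per variable of the stored data (default 3).
#' @export
read_discrete_tsv <- function(path, cardinality = 3L) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- df$dataset_id
  m <- as.matrix(df[, setdiff(names(df), "dataset_id"), drop = FALSE])
  discrete_data(m, cardinality = cardinality, dataset_id = ids)
}

#' Export a network's arcs as edge-list TSV, SIF, or DOT
#'
#' @param net A \code{consensus_net}, \code{weighted_net},
#'   \code{final_net}, or plain arc data frame with a third value column.
#' @param path Output file path.
#' @param format \code{"tsv"} (parent, child, value), \code{"sif"}
#'   (\code{parent arc child}), or \code{"dot"} (Graphviz digraph with the
#'   value as edge label).
#' @return \code{path}, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif", "dot")) {
  format <- match.arg(format)
  df <- as.data.frame(net)
  valcol <- setdiff(names(df), c("from", "to"))[1L]
  if (format == "tsv") {
    out <- df[, c("from", "to", valcol)]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "sif") {
    lines <- if (nrow(df)) paste(df$from, "arc", df$to) else character(0)
    writeLines(lines, path)
  } else {
    vars <- attr(net, "variables")
    body <- c(
      if (!is.null(vars)) paste0("  \"", vars, "\";") else character(0),
      if (nrow(df)) {
        paste0("  \"", df$from, "\" -> \"", df$to, "\" [label=\"",
               df[[valcol]], "\"];")
      } else character(0))
    writeLines(c("digraph consensus {", body, "}"), path)
  }
  invisible(path)
}

#' Serialize / deserialize a top-networks collection as JSON
#'
#' @param tops A \code{top_networks} object.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_top_networks <- function(tops, path) {
  stopifnot(inherits(tops, "top_networks"))
  entries <- lapply(tops, function(e) {
    a <- arcs(e$dag)
    list(arcs = if (nrow(a)) unname(apply(a, 1L, as.list)) else list(),
         log_score = e$log_score)
  })
  obj <- list(variables = attr(tops, "variables"),
              n_evaluations = attr(tops, "n_evaluations"),
              networks = entries)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_top_networks
#' @export
read_top_networks <- function(path) {
  obj <- jsonlite::read_json(path)
  vars <- unlist(obj$variables)
  entries <- lapply(obj$networks, function(e) {
    arcs <- if (length(e$arcs)) {
      do.call(rbind, lapply(e$arcs, function(a) unlist(a)))
    } else NULL
    list(dag = dag(vars, arcs), log_score = e$log_score)
  })
  structure(entries, class = "top_networks", variables = vars,
            n_evaluations = obj$n_evaluations,
            best_score = if (length(entries)) entries[[1L]]$log_score
                         else NA_real_)
}
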