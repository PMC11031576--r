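#' Discrete observation matrix over ordered states
#'
#' Observations x variables matrix of integer states \code{0..k-1}
#' (0 = low, k-1 = high), with per-variable cardinality and per-row dataset
#' provenance. All downstream scoring and search operates on this container.
#'
#' @param x Integer matrix, observations in rows, variables in columns
#'   (column names required).
#' @param cardinality Integer (or integer vector, one per variable) giving
#'   the number of states per variable; default 3.
#' @param dataset_id Optional character vector, one per row, recording which
#'   dataset each observation came from.
#' @return An object of class \code{discrete_data} (an integer matrix with
#'   \code{cardinality} and \code{dataset_id} attributes).
#' @export
discrete_data <- function(x, cardinality = 3L, dataset_id = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (is.null(colnames(x))) {
    stop("'x' must have column (variable) names", call. = FALSE)
  }
  cardinality <- as.integer(cardinality)
  if (any(cardinality < 2L)) {
    stop("'cardinality' must be >= 2", call. = FALSE)
  }
  cardinality <- rep_len(cardinality, ncol(x))
  names(cardinality) <- colnames(x)
  if (nrow(x) > 0L) {
    bad <- x < 0L | sweep(x, 2L, cardinality, ">=")
    if (any(bad, na.rm = TRUE)) {
      stop("states must lie in 0..cardinality-1 for every variable",
           call. = FALSE)
    }
  }
  if (!is.null(dataset_id)) {
    dataset_id <- as.character(dataset_id)
    if (length(dataset_id) != nrow(x)) {
      stop("'dataset_id' must have one entry per row", call. = FALSE)
    }
  }
  structure(x, cardinality = cardinality, dataset_id = dataset_id,
            class = c("discrete_data", class(x)))
}

#' @export
print.discrete_data <- function(x, ...) {
  cat("Discrete dataset: ", nrow(x), " observations x ", ncol(x),
      " variables (states per variable: ",
      paste(unique(attr(x, "cardinality")), collapse = "/"), ")\n", sep = "")
  ids <- attr(x, "dataset_id")
  if (!is.null(ids)) {
    tab <- table(ids)
    cat("Datasets: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Variables of a discrete_data object.
dd_vars <- function(data) colnames(data)

# Cardinality lookup, named by variable.
dd_card <- function(data) attr(data, "cardinality")

#' Continuous expression matrix with sample metadata
#'
#' A genes x samples numeric matrix plus a sample table recording, for each
#' column, its dataset of origin and experimental group.
#'
#' @param values Numeric matrix, genes in rows (row names = gene/probe ids),
#'   samples in columns.
#' @param samples Data frame with columns \code{sample_id},
#'   \code{dataset_id}, \code{group}; one row per matrix column. Missing
#'   columns are filled with placeholders.
#' @return An object of class \code{expr_set}.
#' @export
expression_set <- function(values, samples = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(values),
                          dataset_id = "d1", group = NA_character_,
                          stringsAsFactors = FALSE)
  }
  samples <- as.data.frame(samples)
  if (!"sample_id" %in% names(samples)) samples$sample_id <- colnames(values)
  if (!"dataset_id" %in% names(samples)) samples$dataset_id <- "d1"
  if (!"group" %in% names(samples)) samples$group <- NA_character_
  if (nrow(samples) != ncol(values)) {
    stop("'samples' must have one row per expression column", call. = FALSE)
  }
  structure(list(values = values, samples = samples), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("Expression set: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  tab <- table(x$samples$dataset_id)
  cat("Datasets: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  if (!all(is.na(x$samples$group))) {
    tab <- table(x$samples$group, useNA = "no")
    cat("Groups:   ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)
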