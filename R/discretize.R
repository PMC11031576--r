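#' Equal-frequency (quantile) discretization of one variable
#'
#' Partitions the values into \code{k} ordered bins by rank so that bin
#' occupancies are as equal as the data allow. Target bin sizes differ by at
#' most one, with any surplus assigned to the lower-indexed bins. Identical
#' values always share a bin: each group of tied values is assigned the bin
#' of its (lower) median rank position, so bin boundaries fall between
#' distinct value groups.
#'
#' @param values Numeric vector, length >= \code{k}.
#' @param k Number of bins (>= 2), default 3 (low / medium / high).
#' @return Integer vector of bin labels \code{0..k-1}, in input order.
#' @examples
#' quantile_discretize(c(5, 1, 9, 3), k = 3)  # 1 0 2 0
#' @export
quantile_discretize <- function(values, k = 3L) {
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be >= 2", call. = FALSE)
  n <- length(values)
  if (n < k) {
    stop("need at least k = ", k, " values, got ", n, call. = FALSE)
  }
  if (anyNA(values)) stop("missing values are not supported", call. = FALSE)
  if (length(unique(values)) == 1L) {
    warning("all values identical; assigning every observation to bin 0",
            call. = FALSE)
    return(integer(n))
  }
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  cum <- cumsum(sizes)
  ord <- order(values)
  sorted <- values[ord]
  grp <- cumsum(c(TRUE, sorted[-1L] != sorted[-n]))  # tie groups, sorted order
  bins_sorted <- integer(n)
  for (g in seq_len(grp[n])) {
    pos <- which(grp == g)
    med <- pos[1L] + (pos[length(pos)] - pos[1L]) %/% 2L  # lower median rank
    bins_sorted[pos] <- sum(med > cum)
  }
  out <- integer(n)
  out[ord] <- bins_sorted
  out
}

#' Discretize one expression dataset into ordered states
#'
#' Applies \code{\link{quantile_discretize}} independently to every gene,
#' using only this dataset's samples — discretization must happen per
#' dataset, before any cross-dataset merging, so that each experiment's own
#' location and scale define its low/medium/high states. The result is
#' transposed to the observations x variables orientation used by the
#' scoring and search stages.
#'
#' @param expr An \code{\link{expression_set}} holding a single dataset.
#' @param k Number of states per gene (>= 2), default 3.
#' @return A \code{\link{discrete_data}} (samples x genes).
#' @export
discretize_dataset <- function(expr, k = 3L) {
  stopifnot(inherits(expr, "expr_set"))
  ids <- unique(expr$samples$dataset_id)
  if (length(ids) > 1L) {
    warning("expression set spans ", length(ids),
            " datasets; discretizing them jointly defeats per-dataset ",
            "normalization", call. = FALSE)
  }
  disc <- t(apply(expr$values, 1L, quantile_discretize, k = k))
  discrete_data(t(disc), cardinality = k,
                dataset_id = expr$samples$dataset_id)
}

#' Merge discretized datasets into one observation matrix
#'
#' Row-concatenates per-dataset discrete matrices after aligning their
#' variables by name (column order may differ between parts). Provenance is
#' preserved in the \code{dataset_id} attribute. Parts whose variable sets
#' differ raise an error naming the offending genes — no silent
#' intersection.
#'
#' @param parts List of \code{\link{discrete_data}} objects over the same
#'   variable set.
#' @return A single \code{\link{discrete_data}} with
#'   \code{sum(nrow(parts))} rows.
#' @export
merge_datasets <- function(parts) {
  if (inherits(parts, "discrete_data")) return(parts)
  stopifnot(is.list(parts), length(parts) >= 1L)
  lapply(parts, function(p) stopifnot(inherits(p, "discrete_data")))
  if (length(parts) == 1L) return(parts[[1L]])
  ref <- colnames(parts[[1L]])
  for (i in seq_along(parts)[-1L]) {
    vars <- colnames(parts[[i]])
    missing <- setdiff(ref, vars)
    extra <- setdiff(vars, ref)
    if (length(missing) || length(extra)) {
      stop("variable sets differ between parts 1 and ", i,
           if (length(missing)) paste0("; missing: ",
                                       paste(missing, collapse = ", ")),
           if (length(extra)) paste0("; extra: ",
                                     paste(extra, collapse = ", ")),
           call. = FALSE)
    }
  }
  card <- dd_card(parts[[1L]])
  mats <- lapply(parts, function(p) unclass(p)[, ref, drop = FALSE])
  ids <- unlist(lapply(seq_along(parts), function(i) {
    id <- attr(parts[[i]], "dataset_id")
    if (is.null(id)) rep(paste0("part", i), nrow(parts[[i]])) else id
  }))
  discrete_data(do.call(rbind, mats), cardinality = card, dataset_id = ids)
}
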