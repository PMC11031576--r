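#' Derive per-stage seeds from one master seed
#'
#' All pipeline randomness flows from a single master seed: the master seed
#' initializes R's RNG, and \code{n} stage seeds are drawn as uniform
#' integers below 2^31. The same master seed therefore reproduces every
#' stage of a run.
#'
#' @param master_seed Integer master seed.
#' @param n Number of stage seeds to derive.
#' @return Integer vector of length \code{n}.
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 0)
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max, n)
}

#' Draw random conditional probability tables for a DAG
#'
#' Each variable receives a CPT with one row per joint parent configuration
#' (mixed-radix indexing over the listed parents, first parent varying
#' fastest) and one column per state. Rows are independent draws from a
#' symmetric Dirichlet; small \code{concentration} gives near-deterministic
#' rows, large gives near-uniform rows.
#'
#' @param dag A \code{bn_dag}.
#' @param cardinality States per variable (>= 2), default 3.
#' @param concentration Dirichlet concentration parameter (> 0).
#' @param seed Optional integer seed.
#' @return An object of class \code{param_dag}: list with elements
#'   \code{dag}, \code{cardinality}, and \code{cpts} (named list of
#'   q x r probability matrices).
#' @export
sample_cpts <- function(dag, cardinality = 3L, concentration = 1,
                        seed = NULL) {
  stopifnot(inherits(dag, "bn_dag"))
  cardinality <- as.integer(cardinality)
  if (cardinality < 2L) stop("'cardinality' must be >= 2", call. = FALSE)
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("'concentration' must be > 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  r <- cardinality
  cpts <- lapply(dag$variables, function(v) {
    q <- r ^ length(dag$parents[[v]])
    g <- matrix(stats::rgamma(q * r, shape = concentration), nrow = q)
    p <- g / rowSums(g)
    colnames(p) <- paste0("s", seq_len(r) - 1L)
    p
  })
  names(cpts) <- dag$variables
  structure(list(dag = dag, cardinality = r, cpts = cpts),
            class = "param_dag")
}

#' Build noisy-copy conditional probability tables
#'
#' A deterministic alternative to \code{\link{sample_cpts}} that guarantees
#' balanced marginals and strong, identifiable dependencies: root variables
#' are uniform over their states; a child copies the state of one of its
#' parents — parent i is copied with probability proportional to
#' \code{2^-(i-1)}, scaled so the copy probabilities total \code{fidelity} —
#' and otherwise draws a state uniformly at random. Because each row is a
#' mixture of point masses on parent states and a uniform floor, every
#' child-parent pair is marginally dependent and the marginal distribution
#' of every variable stays uniform.
#'
#' @param dag A \code{bn_dag}.
#' @param cardinality States per variable (>= 2), default 3.
#' @param fidelity Total copy probability in (0, 1); the remaining
#'   \code{1 - fidelity} is spread uniformly. Default 0.9
#'   (near-deterministic).
#' @return A \code{param_dag}.
#' @export
noisy_copy_cpts <- function(dag, cardinality = 3L, fidelity = 0.9) {
  stopifnot(inherits(dag, "bn_dag"))
  cardinality <- as.integer(cardinality)
  if (cardinality < 2L) stop("'cardinality' must be >= 2", call. = FALSE)
  if (fidelity <= 0 || fidelity >= 1) {
    stop("'fidelity' must lie strictly between 0 and 1", call. = FALSE)
  }
  r <- cardinality
  cpts <- lapply(dag$variables, function(v) {
    pas <- dag$parents[[v]]
    np <- length(pas)
    q <- r ^ np
    p <- matrix(0, nrow = q, ncol = r,
                dimnames = list(NULL, paste0("s", seq_len(r) - 1L)))
    if (np == 0L) {
      p[] <- 1 / r
      return(p)
    }
    w <- 2 ^ -(seq_len(np) - 1L)
    w <- w / sum(w) * fidelity
    for (j in seq_len(q)) {
      states <- config_states(j - 1L, rep(r, np))
      row <- rep((1 - fidelity) / r, r)
      for (i in seq_len(np)) row[states[i] + 1L] <- row[states[i] + 1L] + w[i]
      p[j, ] <- row
    }
    p
  })
  names(cpts) <- dag$variables
  structure(list(dag = dag, cardinality = r, cpts = cpts),
            class = "param_dag")
}

#' @export
print.param_dag <- function(x, ...) {
  cat("Parameterized Bayesian network: ", length(x$dag$variables),
      " variables, cardinality ", x$cardinality, "\n", sep = "")
  print(x$dag)
  invisible(x)
}

# Decode a mixed-radix configuration index (0-based) into parent states;
# the first parent varies fastest.
config_states <- function(idx, cards) {
  states <- integer(length(cards))
  for (i in seq_along(cards)) {
    states[i] <- idx %% cards[i]
    idx <- idx %/% cards[i]
  }
  states
}

# Encode parent states (0-based) into a configuration index, first parent
# varying fastest.
config_index <- function(states, cards) {
  idx <- 0L
  mult <- 1L
  for (i in seq_along(cards)) {
    idx <- idx + states[i] * mult
    mult <- mult * cards[i]
  }
  idx
}

#' Forward-sample discrete observations from a parameterized network
#'
#' Ancestral sampling: variables are visited in a topological order of the
#' DAG and each value is drawn from the variable's CPT row selected by its
#' parents' already-sampled states.
#'
#' @param pdag A \code{param_dag} from \code{\link{sample_cpts}} or
#'   \code{\link{noisy_copy_cpts}}.
#' @param n_obs Number of observations (>= 0).
#' @param seed Optional integer seed.
#' @param dataset_id Dataset label stored with the rows (default
#'   \code{"sim"}).
#' @return A \code{\link{discrete_data}} with \code{n_obs} rows.
#' @export
sample_discrete <- function(pdag, n_obs, seed = NULL, dataset_id = "sim") {
  stopifnot(inherits(pdag, "param_dag"))
  if (!is.numeric(n_obs) || n_obs < 0) {
    stop("'n_obs' must be >= 0", call. = FALSE)
  }
  n_obs <- as.integer(n_obs)
  if (!is.null(seed)) set.seed(seed)
  g <- pdag$dag
  r <- pdag$cardinality
  ord <- topo_sort(g)
  x <- matrix(NA_integer_, nrow = n_obs, ncol = length(g$variables),
              dimnames = list(NULL, g$variables))
  for (v in ord) {
    pas <- g$parents[[v]]
    cpt <- pdag$cpts[[v]]
    if (n_obs == 0L) { x[, v] <- integer(0); next }
    if (length(pas) == 0L) {
      x[, v] <- sample.int(r, n_obs, replace = TRUE, prob = cpt[1L, ]) - 1L
    } else {
      idx <- rep(0L, n_obs)
      mult <- 1L
      for (pa in pas) {
        idx <- idx + x[, pa] * mult
        mult <- mult * r
      }
      u <- stats::runif(n_obs)
      cum <- t(apply(cpt, 1L, cumsum))
      # per-row inverse-CDF draw using the configuration-specific CPT row
      x[, v] <- rowSums(u > cum[idx + 1L, , drop = FALSE])
    }
  }
  discrete_data(x, cardinality = r,
                dataset_id = rep(dataset_id, n_obs))
}

#' Specify one synthetic expression batch
#'
#' Describes how one batch (one experiment) turns discrete states into
#' continuous expression: value = \code{scale * state_means[state + 1] +
#' location_shift + N(0, noise_sd)}. Distinct batches get distinct affine
#' maps and noise levels, emulating heterogeneous experiments that share an
#' underlying dependency structure.
#'
#' @param n_samples Number of samples drawn from this batch (>= 1).
#' @param location_shift Additive offset of the batch.
#' @param scale Multiplicative scale (> 0).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param state_means Strictly increasing vector of mean levels, one per
#'   discrete state.
#' @return An object of class \code{batch_spec}.
#' @export
batch_spec <- function(n_samples, location_shift = 0, scale = 1,
                       noise_sd = 0.25, state_means = c(0, 1, 2)) {
  if (!is.numeric(n_samples) || n_samples < 1) {
    stop("'n_samples' must be >= 1", call. = FALSE)
  }
  if (scale <= 0) stop("'scale' must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (any(diff(state_means) <= 0)) {
    stop("'state_means' must be strictly increasing", call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples),
                 location_shift = location_shift, scale = scale,
                 noise_sd = noise_sd, state_means = state_means),
            class = "batch_spec")
}

#' Emit continuous multi-batch expression from discrete ground truth
#'
#' Splits the rows of a discrete dataset into consecutive batches and maps
#' each batch's states to continuous values under that batch's affine model
#' plus Gaussian noise (see \code{\link{batch_spec}}). The output matrices
#' are genes x samples, matching microarray convention.
#'
#' @param dataset A \code{\link{discrete_data}}; rows are assigned to
#'   batches in order.
#' @param batch_specs List of \code{\link{batch_spec}} objects whose
#'   \code{n_samples} sum to \code{nrow(dataset)}.
#' @param seed Optional integer seed.
#' @return List of \code{\link{expression_set}} objects, one per batch,
#'   each tagged with batch id \code{b1, b2, ...}.
#' @export
emit_batches <- function(dataset, batch_specs, seed = NULL) {
  stopifnot(inherits(dataset, "discrete_data"))
  if (inherits(batch_specs, "batch_spec")) batch_specs <- list(batch_specs)
  ns <- vapply(batch_specs, function(b) b$n_samples, integer(1))
  if (sum(ns) != nrow(dataset)) {
    stop("batch sample counts (", sum(ns),
         ") must sum to the dataset row count (", nrow(dataset), ")",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ends <- cumsum(ns)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- vector("list", length(batch_specs))
  for (b in seq_along(batch_specs)) {
    sp <- batch_specs[[b]]
    rows <- starts[b]:ends[b]
    states <- unclass(dataset)[rows, , drop = FALSE]
    if (max(states) + 1L > length(sp$state_means)) {
      stop("batch ", b, ": 'state_means' shorter than the state range",
           call. = FALSE)
    }
    vals <- sp$scale * matrix(sp$state_means[states + 1L], nrow = nrow(states)) +
      sp$location_shift
    if (sp$noise_sd > 0) {
      vals <- vals + stats::rnorm(length(vals), sd = sp$noise_sd)
    }
    # genes x samples orientation
    m <- t(vals)
    rownames(m) <- colnames(dataset)
    colnames(m) <- sprintf("b%d_s%03d", b, seq_len(ncol(m)))
    out[[b]] <- expression_set(
      m, data.frame(sample_id = colnames(m),
                    dataset_id = sprintf("b%d", b),
                    group = NA_character_, stringsAsFactors = FALSE))
  }
  out
}

#' Simulate a two-group differential-expression experiment
#'
#' Emulates a small two-condition (control vs. stress) microarray study:
#' all genes are standard Gaussian in the control group; the first
#' \code{n_true} genes have their mean shifted by \code{effect} in the
#' stress group; the rest are null.
#'
#' @param n_genes Total number of genes.
#' @param n_true Number of truly differential genes (\code{0 <= n_true <=
#'   n_genes}).
#' @param n_per_group Samples per group (>= 2; a two-sample test is
#'   undefined below that).
#' @param effect Mean shift of true genes in the stress group.
#' @param seed Optional integer seed.
#' @return An \code{\link{expression_set}} with \code{2 * n_per_group}
#'   samples and group labels \code{"control"} / \code{"stress"}.
#' @export
two_group_expression <- function(n_genes, n_true, n_per_group, effect,
                                 seed = NULL) {
  if (n_true < 0 || n_true > n_genes) {
    stop("'n_true' must lie in 0..n_genes", call. = FALSE)
  }
  if (n_per_group < 2) {
    stop("'n_per_group' must be >= 2", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_genes <- as.integer(n_genes); n_per_group <- as.integer(n_per_group)
  m <- matrix(stats::rnorm(n_genes * 2L * n_per_group), nrow = n_genes)
  if (n_true > 0L) {
    m[seq_len(n_true), n_per_group + seq_len(n_per_group)] <-
      m[seq_len(n_true), n_per_group + seq_len(n_per_group)] + effect
  }
  rownames(m) <- sprintf("probe%04d", seq_len(n_genes))
  colnames(m) <- c(sprintf("ctrl%d", seq_len(n_per_group)),
                   sprintf("stress%d", seq_len(n_per_group)))
  expression_set(
    m, data.frame(sample_id = colnames(m), dataset_id = "twogroup",
                  group = rep(c("control", "stress"), each = n_per_group),
                  stringsAsFactors = FALSE))
}
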