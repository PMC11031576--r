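#' Assemble a pipeline configuration
#'
#' Collects every tunable of the expression-to-network pipeline in one
#' JSON-serializable object. The defaults mirror the published settings:
#' adjusted-p threshold 0.02, three discretization states, top 100 networks
#' per search, 50 consensus runs, majority (50\%) arc support, and 4
#' stability repeats.
#'
#' Exactly one input source must be given: \code{expression_paths} (TSV
#' files as written by \code{\link{write_expression_tsv}}, the first one
#' carrying the two-group design used for signal selection) or
#' \code{synthetic} (a ground-truth generation block, see Details).
#'
#' @details The \code{synthetic} block is a list with fields
#'   \code{n_vars}, \code{max_parents}, \code{arc_prob}, \code{fidelity}
#'   (noisy-copy CPT fidelity), \code{n_obs} (total observations), and
#'   \code{batches}: a list of per-batch lists with fields
#'   \code{n_samples}, \code{location_shift}, \code{scale},
#'   \code{noise_sd}, \code{state_means}. In synthetic mode the gene list
#'   is fixed by construction, so the differential-expression stage is
#'   skipped.
#'
#' @param expression_paths Character vector of expression TSV paths (each
#'   with a \code{<path>.meta.tsv} companion), or \code{NULL}.
#' @param annotation_path Optional probe-to-gene TSV (columns
#'   \code{probe_id}, \code{gene_id}) used to collapse duplicate probes.
#' @param signal Optional pre-selected character vector of gene ids; skips
#'   the differential-expression stage.
#' @param synthetic Optional synthetic-generation block (see Details).
#' @param alpha Adjusted-p selection threshold, inclusive (default 0.02).
#' @param k Discretization states per gene (default 3).
#' @param ess BDeu equivalent sample size (default 1).
#' @param schedule An \code{\link{anneal_schedule}} or a plain list of its
#'   fields.
#' @param top_n Top networks per search (default 100).
#' @param n_consensus_runs Consensus runs per repeat (default 50).
#' @param min_fraction Majority-support fraction (default 0.5).
#' @param n_repeats Stability repeats (default 4).
#' @param master_seed Master seed (default 1).
#' @param out_dir Output directory for artifacts.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(expression_paths = NULL, annotation_path = NULL,
                            signal = NULL, synthetic = NULL,
                            alpha = 0.02, k = 3L, ess = 1,
                            schedule = anneal_schedule(),
                            top_n = 100L, n_consensus_runs = 50L,
                            min_fraction = 0.5, n_repeats = 4L,
                            master_seed = 1L, out_dir = tempfile("run")) {
  if (inherits(schedule, "anneal_schedule")) schedule <- unclass(schedule)
  structure(list(expression_paths = expression_paths,
                 annotation_path = annotation_path,
                 signal = signal, synthetic = synthetic,
                 alpha = alpha, k = as.integer(k), ess = ess,
                 schedule = schedule, top_n = as.integer(top_n),
                 n_consensus_runs = as.integer(n_consensus_runs),
                 min_fraction = min_fraction,
                 n_repeats = as.integer(n_repeats),
                 master_seed = as.integer(master_seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config A \code{pipeline_config}.
#' @return Character vector of violations, each naming the field and the
#'   rule it breaks; empty iff the configuration is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (is.null(config$expression_paths) && is.null(config$synthetic)) {
    add("input: either 'expression_paths' or a 'synthetic' block is required")
  }
  if (!is.null(config$expression_paths) && !is.null(config$synthetic)) {
    add("input: 'expression_paths' and 'synthetic' are mutually exclusive")
  }
  if (!(config$alpha > 0 && config$alpha <= 1)) {
    add("alpha: must lie in (0, 1]")
  }
  if (is.na(config$k) || config$k < 2) add("k: must be >= 2")
  if (config$ess <= 0) add("ess: must be > 0")
  if (config$top_n < 1) add("top_n: must be >= 1")
  if (config$n_consensus_runs < 1) add("n_consensus_runs: must be >= 1")
  if (!(config$min_fraction > 0 && config$min_fraction <= 1)) {
    add("min_fraction: must lie in (0, 1]")
  }
  if (config$n_repeats < 1) add("n_repeats: must be >= 1")
  s <- config$schedule
  if (!is.null(s$initial_temperature) && s$initial_temperature <= 0) {
    add("schedule$initial_temperature: must be > 0 (or NULL for automatic)")
  }
  if (s$cooling_factor <= 0 || s$cooling_factor >= 1) {
    add("schedule$cooling_factor: must lie in (0, 1)")
  }
  if (s$moves_per_temperature < 1) {
    add("schedule$moves_per_temperature: must be >= 1")
  }
  if (s$max_evaluations < 1) add("schedule$max_evaluations: must be >= 1")
  if (s$max_parents < 0) add("schedule$max_parents: must be >= 0")
  if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    for (f in c("n_vars", "n_obs", "batches")) {
      if (is.null(sy[[f]])) add(paste0("synthetic$", f, ": required"))
    }
    if (!is.null(sy$n_obs) && !is.null(sy$batches)) {
      ns <- vapply(sy$batches, function(b) as.integer(b$n_samples),
                   integer(1))
      if (sum(ns) != sy$n_obs) {
        add("synthetic$batches: n_samples must sum to synthetic$n_obs")
      }
    }
  }
  v
}

# Pairwise agreement metrics between final arc data frames.
compare_finals <- function(finals) {
  keys <- lapply(finals, function(f) {
    if (nrow(f) == 0L) character(0) else paste(f$from, f$to, sep = ">")
  })
  n <- length(finals)
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
  list(equal = eq, jaccard = jac, all_identical = all(eq))
}

#' Run the full expression-to-network pipeline
#'
#' Orchestrates every stage: load (or synthesize) per-dataset expression,
#' optionally select the differential-expression signal on the two-group
#' dataset and collapse duplicate probes, discretize each dataset into
#' \code{k} equal-frequency states, merge the discrete datasets, then for
#' each of \code{n_repeats} independent repeats fit a
#' \code{\link{consensus_bn}} (annealed searches, top-\code{top_n}
#' consensus, weighted overlay, majority filter) and finally compare the
#' repeats' final networks. Every intermediate artifact is written under
#' \code{config$out_dir} together with a manifest that reproduces the run.
#'
#' @param config A valid \code{\link{pipeline_config}}.
#' @param quiet Suppress progress messages (default \code{FALSE}).
#' @return Invisibly, a list with the merged discrete data, per-repeat
#'   \code{consensus_bn} fits, the stability report, and the paths of all
#'   written artifacts.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  violations <- validate_config(config)
  if (length(violations)) {
    stop("invalid configuration:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  say <- function(...) if (!quiet) message("[pipeline] ", ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$master_seed, 2L + config$n_repeats)
  paths <- list()

  # --- stage 1: inputs -----------------------------------------------------
  if (!is.null(config$synthetic)) {
    say("generating synthetic multi-batch data")
    sy <- config$synthetic
    truth <- random_dag(sy$n_vars, sy$max_parents %||% 2L,
                        seed = seeds[1L],
                        arc_prob = sy$arc_prob %||% 0.3)
    pdag <- noisy_copy_cpts(truth, cardinality = config$k,
                            fidelity = sy$fidelity %||% 0.9)
    disc_truth <- sample_discrete(pdag, sy$n_obs, seed = seeds[2L])
    specs <- lapply(sy$batches, function(b) {
      batch_spec(b$n_samples, b$location_shift %||% 0, b$scale %||% 1,
                 b$noise_sd %||% 0.25,
                 unlist(b$state_means %||% list(0, 1, 2)))
    })
    datasets <- emit_batches(disc_truth, specs, seed = seeds[2L])
    paths$truth <- file.path(config$out_dir, "truth_network.tsv")
    a <- arcs(truth)
    utils::write.table(
      data.frame(from = a[, 1L], to = a[, 2L]), paths$truth,
      sep = "\t", quote = FALSE, row.names = FALSE)
    signal <- NULL  # gene set fixed by construction
  } else {
    say("reading ", length(config$expression_paths), " expression dataset(s)")
    datasets <- lapply(config$expression_paths, read_expression_tsv)
    signal <- config$signal
  }

  # --- stage 2: differential-expression signal -----------------------------
  annotation <- if (!is.null(config$annotation_path)) {
    utils::read.delim(config$annotation_path, stringsAsFactors = FALSE)
  } else NULL
  if (is.null(config$synthetic) && is.null(signal)) {
    first <- datasets[[1L]]
    groups <- first$samples$group
    if (length(unique(stats::na.omit(groups))) != 2L) {
      stop("stage deg_signal: the first dataset must carry a two-level ",
           "'group' column (or supply 'signal')", call. = FALSE)
    }
    say("selecting differential-expression signal at alpha = ", config$alpha)
    deg <- differential_test(first, groups)
    probes <- select_signal(deg, config$alpha)
    paths$deg <- file.path(config$out_dir, "deg_table.tsv")
    deg$selected <- as.integer(deg$probe_id %in% probes)
    if (!is.null(annotation)) {
      map <- stats::setNames(annotation$gene_id, annotation$probe_id)
      deg$gene_id <- unname(map[deg$probe_id])
    }
    utils::write.table(deg, paths$deg, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (length(probes) == 0L) {
      stop("stage deg_signal: no probes pass alpha = ", config$alpha,
           call. = FALSE)
    }
    keep_probe <- function(es) {
      expression_set(es$values[rownames(es$values) %in% probes, ,
                               drop = FALSE], es$samples)
    }
    datasets <- lapply(datasets, keep_probe)
    if (!is.null(annotation)) {
      say("collapsing duplicate probes to genes")
      datasets <- lapply(datasets, collapse_probes, annotation)
    }
  }

  # --- stage 3: per-dataset discretization, then merge ---------------------
  say("discretizing each dataset into ", config$k, " states, then merging")
  disc <- lapply(datasets, discretize_dataset, k = config$k)
  merged <- merge_datasets(disc)
  paths$merged <- file.path(config$out_dir, "merged_discrete.tsv")
  write_discrete_tsv(merged, paths$merged)

  # --- stage 4: repeated consensus fits ------------------------------------
  fits <- vector("list", config$n_repeats)
  sched <- do.call(anneal_schedule, config$schedule)
  for (r in seq_len(config$n_repeats)) {
    say("repeat ", r, "/", config$n_repeats, ": ",
        config$n_consensus_runs, " searches x ",
        format(sched$max_evaluations, big.mark = ","), " evaluations")
    fits[[r]] <- consensus_bn(
      merged, n_runs = config$n_consensus_runs, top_n = config$top_n,
      min_fraction = config$min_fraction, schedule = sched,
      ess = config$ess, seed = seeds[2L + r])
    base <- file.path(config$out_dir, sprintf("repeat%d", r))
    write_network(fits[[r]]$weighted, paste0(base, "_weighted.tsv"))
    write_network(fits[[r]]$final, paste0(base, "_final.tsv"))
    write_network(fits[[r]]$final, paste0(base, "_final.sif"),
                  format = "sif")
    write_network(fits[[r]]$final, paste0(base, "_final.dot"),
                  format = "dot")
    paths[[sprintf("final_%d", r)]] <- paste0(base, "_final.tsv")
  }

  # --- stage 5: stability report and manifest ------------------------------
  stability <- compare_finals(lapply(fits, `[[`, "final"))
  stability$seeds <- seeds[2L + seq_len(config$n_repeats)]
  paths$stability <- file.path(config$out_dir, "stability.json")
  jsonlite::write_json(
    list(all_identical = stability$all_identical,
         jaccard = stability$jaccard, seeds = stability$seeds),
    paths$stability, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(
    list(config = unclass(config), derived_seeds = seeds,
         package_version = as.character(utils::packageVersion("consensusbn")),
         r_version = R.version.string),
    paths$manifest, auto_unbox = TRUE, digits = NA, null = "null")
  say("done; final network(s) ",
      if (stability$all_identical) "identical across repeats"
      else "differ between repeats")
  invisible(list(merged = merged, fits = fits, stability = stability,
                 paths = paths, config = config))
}

#' Re-run a pipeline from its saved manifest
#'
#' Reads the manifest written by \code{\link{run_pipeline}} and re-executes
#' the run it describes. With the same inputs this reproduces every output
#' byte for byte.
#'
#' @param manifest_path Path to a \code{manifest.json}.
#' @param out_dir Optional new output directory (defaults to the one in the
#'   manifest).
#' @param quiet Passed to \code{\link{run_pipeline}}.
#' @return See \code{\link{run_pipeline}}.
#' @export
run_from_manifest <- function(manifest_path, out_dir = NULL, quiet = FALSE) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  cfg <- man$config
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(cfg$schedule$initial_temperature) &&
      length(cfg$schedule$initial_temperature) == 0L) {
    cfg$schedule$initial_temperature <- NULL
  }
  config <- pipeline_config(
    expression_paths = cfg$expression_paths,
    annotation_path = cfg$annotation_path,
    signal = cfg$signal, synthetic = cfg$synthetic,
    alpha = cfg$alpha, k = cfg$k, ess = cfg$ess,
    schedule = do.call(anneal_schedule, cfg$schedule),
    top_n = cfg$top_n, n_consensus_runs = cfg$n_consensus_runs,
    min_fraction = cfg$min_fraction, n_repeats = cfg$n_repeats,
    master_seed = cfg$master_seed, out_dir = cfg$out_dir)
  run_pipeline(config, quiet = quiet)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
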