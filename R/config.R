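# Run configuration ---------------------------------------------------------
#
# A small YAML-backed configuration layer for scripted runs. All defaults
# live in one table; unknown keys are rejected so that typos fail loudly
# instead of silently falling back to defaults.

run_config_defaults <- function() {
  list(
    simulate = list(n_pos = 100, degree = 5, window_length = 141,
                    dimer_start = 61, signal = 0.6),
    variant = list(variant = "CTEOD", N = NULL, alpha = 1, tau_low = 0.7,
                   target_iterations = 50, k_per_class = 2),
    cv = list(k = 10, labeled_fraction = 0.01),
    grid = list(degrees = c(5, 10), variants = c("CTEOD", "CTEPD", "STEPD"),
                replicates = 1),
    seed = 1
  )
}

#' Assemble a run configuration
#'
#' Starts from the package defaults, overlays an optional YAML file, then
#' applies in-memory overrides. Keys absent from the defaults table are
#' rejected.
#'
#' @param path optional path to a YAML configuration file with any of the
#'   sections `simulate`, `variant`, `cv`, `grid` and the scalar `seed`.
#' @param overrides named list in the same shape, applied last.
#' @return a `run_config` list.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read configuration files")
    }
    cfg <- merge_config(cfg, yaml::read_yaml(path), "")
  }
  cfg <- merge_config(cfg, overrides, "")
  structure(cfg, class = "run_config")
}

merge_config <- function(base, new, prefix) {
  if (is.null(new)) return(base)
  if (!is.list(new)) return(new)
  for (key in names(new)) {
    full <- paste0(prefix, key)
    if (!key %in% names(base)) {
      stop("unknown configuration key: ", full)
    }
    base[[key]] <- if (is.list(base[[key]]) && is.list(new[[key]])) {
      merge_config(base[[key]], new[[key]], paste0(full, "."))
    } else {
      new[[key]]
    }
  }
  base
}

#' Simulate a dataset and write it to disk
#'
#' Writes a labeled FASTA file plus a JSON sidecar recording the full
#' generating configuration.
#'
#' @param config a `run_config` (see [run_config()]).
#' @param out_dir output directory, created if missing.
#' @return invisibly, the paths written.
#' @export
cmd_simulate <- function(config, out_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$simulate
  rec <- simulate_splice_data(n_pos = sim$n_pos, degree = sim$degree,
                              window_length = sim$window_length,
                              dimer_start = sim$dimer_start,
                              signal = sim$signal, seed = config$seed)
  fasta <- file.path(out_dir, "dataset.fasta")
  sidecar <- file.path(out_dir, "dataset.json")
  write_splice_fasta(rec, fasta)
  jsonlite::write_json(c(attr(rec, "sim_config"), list(seed = config$seed)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fasta, sidecar = sidecar))
}

#' Run an experiment grid and write its results
#'
#' Drives [run_experiment()] from a configuration: simulates the base
#' datasets, runs the requested degrees and variants, and writes the
#' results TSV plus a JSON manifest of all seeds and per-fold values.
#'
#' @param config a `run_config`.
#' @param out_dir output directory, created if missing.
#' @param data optional `splice_records` base dataset; by default bases are
#'   simulated from the `simulate` section.
#' @return the `ssl_results` object, invisibly.
#' @export
cmd_experiment <- function(config, out_dir = ".", data = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- config$grid
  if (is.null(data)) {
    sim <- config$simulate
    data <- list(n_pos = sim$n_pos, window_length = sim$window_length,
                 dimer_start = sim$dimer_start, signal = sim$signal)
  }
  res <- run_experiment(data, degrees = grid$degrees,
                        variants = grid$variants,
                        k = config$cv$k,
                        labeled_fraction = config$cv$labeled_fraction,
                        replicates = grid$replicates,
                        N = config$variant$N,
                        alpha = config$variant$alpha,
                        tau_low = config$variant$tau_low,
                        target_iterations = config$variant$target_iterations,
                        k_per_class = config$variant$k_per_class,
                        seed = config$seed)
  write_results_tsv(res, file.path(out_dir, "results.tsv"))
  results_manifest(res, file.path(out_dir, "manifest.json"))
  invisible(res)
}
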