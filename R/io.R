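# Flat key:value configuration files, TSV trace writers, and the run launcher
# behind the command-line wrapper. All tables are written with '.' decimals and
# 17 significant digits so a written trace replays a run exactly.

config_keys <- function(mode) {
  common <- c("mode", "problem", "master_seed", "output_dir", "log_level",
              "window_size", "t_initial", "gain", "max_log10_step", "t_min",
              "t_max", "frozen_boost_log10")
  sa <- c("ar_initial", "ar_final", "n_iterations_per_cycle", "n_cycles",
          "n_parallel_runs")
  re <- c("ar_values", "exchange_period_windows", "n_iterations_total")
  switch(mode, SA = c(common, sa), RE = c(common, re), c(common, sa, re))
}

#' Parse and validate an engine configuration file
#'
#' Configuration files are flat `key: value` YAML (no nesting). Required keys:
#' `mode` (`SA` or `RE`), `problem` (a problem reference, see below) and
#' `master_seed`. All other keys default to the package defaults
#' ([annealing_config()], [exchange_config()], [controller_params()]). Unknown
#' keys, keys belonging to the other mode, missing required keys, and
#' out-of-range values are all reported together in a single error.
#'
#' Problem references are either `builtin:<name>` (see [example_problem()]) or
#' the path to an R file that defines `problem`, `k0` and optionally `data`.
#'
#' @param path Path to the configuration file.
#' @return An `engine_config` list: `mode`, `problem` (the reference string),
#'   `output_dir`, `log_level`, and `settings` (an [annealing_config()] or
#'   [exchange_config()]).
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be flat key: value pairs", call. = FALSE)
  errs <- character()
  mode <- raw$mode
  if (is.null(mode) || !is.character(mode) || !(mode %in% c("SA", "RE"))) {
    errs <- c(errs, "mode: required, must be 'SA' or 'RE'")
    mode <- NA_character_
  }
  known <- config_keys(if (is.na(mode)) "ANY" else mode)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    errs <- c(errs, paste0(unknown, ": unknown key",
                           if (!is.na(mode)) paste0(" for mode ", mode) else ""))
  }
  if (is.null(raw$problem) || !is.character(raw$problem)) {
    errs <- c(errs, "problem: required, must be 'builtin:<name>' or an R file path")
  }
  if (is.null(raw$master_seed) || !is.numeric(raw$master_seed)) {
    errs <- c(errs, "master_seed: required, must be an integer")
  }
  num_in <- function(key, lo, hi, lo_open = FALSE, hi_open = FALSE) {
    v <- raw[[key]]
    if (is.null(v)) return(TRUE)
    ok <- is.numeric(v) && length(v) == 1L && !is.na(v) &&
      (if (lo_open) v > lo else v >= lo) && (if (hi_open) v < hi else v <= hi)
    if (!ok) errs <<- c(errs, sprintf("%s: must be a number in %s%g, %g%s", key,
                                      if (lo_open) "(" else "[", lo, hi,
                                      if (hi_open) ")" else "]"))
    ok
  }
  num_in("ar_initial", 0, 1, lo_open = TRUE)
  num_in("ar_final", 0, 1, hi_open = TRUE)
  num_in("t_initial", 0, Inf, lo_open = TRUE)
  num_in("gain", 0, Inf, lo_open = TRUE)
  num_in("window_size", 1, Inf)
  num_in("n_iterations_per_cycle", 1, Inf)
  num_in("n_cycles", 1, Inf)
  num_in("n_parallel_runs", 1, Inf)
  num_in("exchange_period_windows", 1, Inf)
  num_in("n_iterations_total", 1, Inf)
  if (!is.null(raw$ar_values)) {
    av <- raw$ar_values
    if (is.character(av)) av <- as.numeric(strsplit(av, ",")[[1]])
    if (anyNA(av) || length(av) < 2) {
      errs <- c(errs, "ar_values: must be >= 2 comma-separated numbers in (0, 1]")
    }
    raw$ar_values <- av
  }
  if (!is.null(raw$log_level) && !(raw$log_level %in% c("quiet", "info", "debug"))) {
    errs <- c(errs, "log_level: must be one of quiet, info, debug")
  }
  if (length(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  ctrl_args <- raw[intersect(names(raw), c("gain", "max_log10_step", "t_min",
                                           "t_max", "frozen_boost_log10"))]
  controller <- do.call(controller_params, ctrl_args)
  pick <- function(keys) {
    a <- raw[intersect(names(raw), keys)]
    a$controller <- controller
    a$master_seed <- raw$master_seed
    a
  }
  settings <- tryCatch(
    if (mode == "SA") {
      do.call(annealing_config,
              pick(c("ar_initial", "ar_final", "n_iterations_per_cycle",
                     "n_cycles", "window_size", "t_initial",
                     "n_parallel_runs")))
    } else {
      do.call(exchange_config,
              pick(c("ar_values", "exchange_period_windows",
                     "n_iterations_total", "window_size", "t_initial")))
    },
    error = function(e) stop("invalid configuration:\n  ",
                             conditionMessage(e), call. = FALSE))
  structure(list(mode = mode,
                 problem = raw$problem,
                 output_dir = if (is.null(raw$output_dir)) "aropt_output"
                              else raw$output_dir,
                 log_level = if (is.null(raw$log_level)) "info"
                             else raw$log_level,
                 settings = settings),
            class = "engine_config")
}

# Flatten an engine_config back to the flat key set; the written effective
# config must re-parse to an identical object (round-trip contract).
as_flat_config <- function(cfg) {
  s <- cfg$settings
  out <- list(mode = cfg$mode, problem = cfg$problem,
              output_dir = cfg$output_dir, log_level = cfg$log_level,
              master_seed = s$master_seed, window_size = s$window_size,
              t_initial = s$t_initial)
  if (cfg$mode == "SA") {
    out <- c(out, list(ar_initial = s$ar_initial, ar_final = s$ar_final,
                       n_iterations_per_cycle = s$n_iterations_per_cycle,
                       n_cycles = s$n_cycles,
                       n_parallel_runs = s$n_parallel_runs))
  } else {
    out <- c(out, list(ar_values = paste(s$ar_values, collapse = ","),
                       exchange_period_windows = s$exchange_period_windows,
                       n_iterations_total = s$n_iterations_total))
  }
  c(out, unclass(s$controller))
}

#' Write the effective (defaults-filled) configuration for provenance
#'
#' @param cfg An `engine_config` from [parse_config()].
#' @param path Destination file; defaults to `config_effective.yaml` in the
#'   configured output directory.
#' @return The path, invisibly.
#' @export
write_effective_config <- function(cfg, path = file.path(cfg$output_dir,
                                                         "config_effective.yaml")) {
  stopifnot(inherits(cfg, "engine_config"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  txt <- yaml::as.yaml(as_flat_config(cfg), precision = 15)
  tmp <- tempfile("cfg", tmpdir = dirname(path))
  writeLines(txt, tmp)
  file.rename(tmp, path)
  invisible(path)
}

# Atomic TSV writer: doubles at 17 significant digits, write-to-temp + rename
# so no output file is ever left partially written.
write_tsv_atomic <- function(df, path) {
  fmt <- function(col) {
    if (is.double(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- "NA"
      out
    } else col
  }
  out <- as.data.frame(lapply(df, fmt), stringsAsFactors = FALSE,
                       check.names = FALSE)
  tmp <- tempfile("tsv", tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp))
  utils::write.table(out, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write result tables for a finished run
#'
#' Writes, per run (SA) or per replica (RE), the step trace and window summary
#' tables, plus a cross-run summary (`summary.tsv`), a one-line best-result
#' record (`best.tsv`), a human-readable summary (`best_summary.txt`), and for
#' replica exchange the exchange log (`exchanges.tsv`). All writes are atomic
#' (temp file + rename) and deterministic given the run.
#'
#' @param result An `aropt_result` from [run_sa()] or [run_re()].
#' @param config An `engine_config`, or simply an output directory path.
#' @return Character vector of the paths written.
#' @export
write_results <- function(result, config) {
  stopifnot(inherits(result, "aropt_result"))
  outdir <- if (is.character(config)) config else config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  label <- if (result$mode == "SA") "run" else "replica"
  paths <- character()
  for (i in seq_along(result$traces)) {
    p <- file.path(outdir, sprintf("trace_%s%d.tsv", label, i))
    write_tsv_atomic(result$traces[[i]], p)
    p2 <- file.path(outdir, sprintf("windows_%s%d.tsv", label, i))
    write_tsv_atomic(result$windows[[i]], p2)
    paths <- c(paths, p, p2)
  }
  if (result$mode == "RE") {
    p <- file.path(outdir, "exchanges.tsv")
    write_tsv_atomic(result$exchange_log, p)
    paths <- c(paths, p)
  }
  p <- file.path(outdir, "summary.tsv")
  write_tsv_atomic(result$per_run_bests, p)
  paths <- c(paths, p)
  p <- file.path(outdir, "best.tsv")
  write_tsv_atomic(data.frame(mode = result$mode,
                              best_energy = result$best_energy,
                              best_quality = result$best_quality,
                              n_steps_total = result$n_steps_total), p)
  paths <- c(paths, p)
  p <- file.path(outdir, "best_summary.txt")
  tmp <- tempfile("txt", tmpdir = outdir)
  writeLines(utils::capture.output(print(result)), tmp)
  file.rename(tmp, p)
  paths <- c(paths, p)
  paths
}

#' Resolve a problem reference string
#'
#' `builtin:<name>` resolves through [example_problem()] (seeded with the run's
#' master seed); anything else must be the path to an R file that defines
#' `problem` (an [new_problem()]), `k0` and optionally `data` when sourced into
#' a fresh environment.
#'
#' @param ref Reference string.
#' @param seed Seed forwarded to builtin generators.
#' @return A list with `problem`, `k0`, `data`.
#' @export
resolve_problem_ref <- function(ref, seed = 1L) {
  stopifnot(is.character(ref), length(ref) == 1L)
  if (startsWith(ref, "builtin:")) {
    return(example_problem(sub("^builtin:", "", ref), seed = seed))
  }
  if (!file.exists(ref)) {
    stop("problem reference is neither builtin:<name> nor an existing file: ",
         ref, call. = FALSE)
  }
  env <- new.env(parent = globalenv())
  sys.source(ref, envir = env)
  if (!exists("problem", env, inherits = FALSE) ||
      !exists("k0", env, inherits = FALSE)) {
    stop("problem file must define `problem` and `k0`: ", ref, call. = FALSE)
  }
  list(problem = get("problem", env), k0 = get("k0", env),
       data = if (exists("data", env, inherits = FALSE)) get("data", env)
              else NULL)
}

#' Run the engine from a configuration file or object
#'
#' Parses (if given a path), resolves the problem reference, checks the output
#' directory is writable before any computation starts, runs the configured
#' mode, writes the result tables and the effective configuration, and returns
#' the result.
#'
#' @param config Path to a configuration file or an `engine_config`.
#' @param seed Optional master-seed override.
#' @param outdir Optional output-directory override.
#' @param mode Optional mode override (`"SA"` or `"RE"`); must match the keys
#'   present in the configuration.
#' @param write If `FALSE`, skip writing tables (library use).
#' @return The `aropt_result`, invisibly.
#' @export
run_from_config <- function(config, seed = NULL, outdir = NULL, mode = NULL,
                            write = TRUE) {
  cfg <- if (is.character(config)) parse_config(config) else config
  stopifnot(inherits(cfg, "engine_config"))
  if (!is.null(mode) && !identical(mode, cfg$mode)) {
    stop("mode override ", mode, " conflicts with configured mode ", cfg$mode,
         call. = FALSE)
  }
  if (!is.null(outdir)) cfg$output_dir <- outdir
  if (!is.null(seed)) cfg$settings$master_seed <- as.integer(seed)
  if (write) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    if (file.access(cfg$output_dir, 2L) != 0L) {
      stop("output_dir is not writable: ", cfg$output_dir, call. = FALSE)
    }
  }
  prob <- resolve_problem_ref(cfg$problem, seed = cfg$settings$master_seed)
  result <- if (cfg$mode == "SA") {
    run_sa(prob$problem, prob$k0, prob$data, cfg$settings)
  } else {
    run_re(prob$problem, prob$k0, prob$data, cfg$settings)
  }
  if (write) {
    write_effective_config(cfg)
    write_results(result, cfg)
  }
  invisible(result)
}
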