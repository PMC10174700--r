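#' Configuration for acceptance-ratio simulated annealing
#'
#' In acceptance-ratio simulated annealing the annealed quantity is the target
#' acceptance ratio, not the temperature: each cycle sweeps a linear target-AR
#' regimen from `ar_initial` down to `ar_final`, and the thermoregulator adapts
#' the pseudo-temperature so the observed per-window acceptance ratio follows
#' it. The temperature is *not* reset between cycles; the restart of the
#' high-AR target forces the controller to reheat, which is what re-opens the
#' search at each cycle boundary.
#'
#' @param ar_initial Target acceptance ratio at the first step of a cycle,
#'   in `(0, 1]`.
#' @param ar_final Target at the last step of a cycle, in `[0, 1)`; must be
#'   below `ar_initial`.
#' @param n_iterations_per_cycle Steps per annealing cycle; must be a multiple
#'   of `window_size`.
#' @param n_cycles Number of annealing cycles per run.
#' @param window_size Steps per statistics window (the AR measurement
#'   resolution is `1 / window_size`).
#' @param t_initial Pseudo-temperature entering the first window.
#' @param controller A [controller_params()] object.
#' @param master_seed Single integer seed; per-run seeds are fanned out from it.
#' @param n_parallel_runs Number of independent annealing runs.
#' @return An `annealing_config` list.
#' @export
annealing_config <- function(ar_initial = 0.9, ar_final = 0.01,
                             n_iterations_per_cycle = 10000L, n_cycles = 3L,
                             window_size = 20L, t_initial = 1,
                             controller = controller_params(),
                             master_seed = 1L, n_parallel_runs = 1L) {
  stopifnot(ar_initial > 0, ar_initial <= 1, ar_final >= 0, ar_final < 1,
            n_iterations_per_cycle >= 1, n_cycles >= 1, window_size >= 1,
            t_initial > 0, n_parallel_runs >= 1,
            inherits(controller, "controller_params"))
  if (ar_initial <= ar_final) {
    stop("ar_initial must exceed ar_final (annealing lowers acceptance)",
         call. = FALSE)
  }
  if (n_iterations_per_cycle %% window_size != 0) {
    stop("window_size must divide n_iterations_per_cycle", call. = FALSE)
  }
  structure(list(ar_initial = as.numeric(ar_initial),
                 ar_final = as.numeric(ar_final),
                 n_iterations_per_cycle = as.integer(n_iterations_per_cycle),
                 n_cycles = as.integer(n_cycles),
                 window_size = as.integer(window_size),
                 t_initial = as.numeric(t_initial),
                 controller = controller,
                 master_seed = as.integer(master_seed),
                 n_parallel_runs = as.integer(n_parallel_runs)),
            class = "annealing_config")
}

#' Linear target acceptance-ratio regimen
#'
#' Target AR at a (0-based) step of a cycle of `n_iterations_per_cycle` steps:
#' linear interpolation from `ar_initial` at step 0 to `ar_final` at the last
#' step. A one-step cycle returns `ar_initial`.
#'
#' @param step 0-based step index, `0 <= step < n_iterations_per_cycle`.
#' @param n_iterations_per_cycle Cycle length in steps.
#' @param ar_initial,ar_final Regimen endpoints.
#' @return The target acceptance ratio at that step.
#' @examples
#' target_ar_at_step(0, 101, 0.9, 0.1)    # 0.9
#' target_ar_at_step(50, 101, 0.9, 0.1)   # 0.5
#' target_ar_at_step(100, 101, 0.9, 0.1)  # 0.1
#' @export
target_ar_at_step <- function(step, n_iterations_per_cycle, ar_initial,
                              ar_final) {
  if (any(step < 0) || any(step >= n_iterations_per_cycle)) {
    stop("step must lie in [0, n_iterations_per_cycle - 1]", call. = FALSE)
  }
  if (n_iterations_per_cycle == 1) return(rep(ar_initial, length(step)))
  # convex form keeps both endpoints exact in floating point
  f <- step / (n_iterations_per_cycle - 1)
  ar_initial * (1 - f) + ar_final * f
}

#' Run one annealing cycle
#'
#' Executes `n_iterations_per_cycle / window_size` thermoregulated windows.
#' The continuous linear regimen is sampled at each window's final step index
#' to give that window's target (AR is only measurable per window). The
#' temperature entering the cycle is `t_in`; the returned `t_out` feeds the
#' next cycle unchanged.
#'
#' @param state A `chain_state` from [chain_init()].
#' @param config An [annealing_config()].
#' @param t_in Temperature entering the cycle.
#' @param problem,data,rng As in [run_window()].
#' @param cycle_index 1-based cycle number stamped into the trace.
#' @return `list(state =, t_out =, windows =, records =)` with one window
#'   summary row per window and the full per-step trace.
#' @export
run_annealing_cycle <- function(state, config, t_in, problem, data = NULL,
                                rng = NULL, cycle_index = 1L) {
  stopifnot(inherits(config, "annealing_config"))
  ws <- config$window_size
  n_win <- config$n_iterations_per_cycle %/% ws
  t_cur <- t_in
  recs <- vector("list", n_win)
  wins <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    target <- target_ar_at_step(w * ws - 1L, config$n_iterations_per_cycle,
                                config$ar_initial, config$ar_final)
    reg <- regulate_window(state, t_cur, target, ws, problem, data,
                           config$controller, rng)
    state <- reg$state
    r <- reg$records
    r$cycle <- cycle_index
    r$window <- w
    recs[[w]] <- r
    st <- reg$stats
    wins[[w]] <- data.frame(cycle = cycle_index, window = w,
                            temperature_used = st$temperature_used,
                            target_ar = st$target_ar,
                            observed_ar = st$observed_ar,
                            n_accepted = st$n_accepted, n_steps = st$n_steps,
                            boosted = st$boosted)
    t_cur <- reg$temperature
  }
  list(state = state, t_out = t_cur,
       windows = do.call(rbind, wins), records = do.call(rbind, recs))
}

#' Fan out per-run seeds from a master seed
#'
#' Deterministically derives `n_runs` pairwise-distinct seeds from one master
#' seed, so a whole ensemble of parallel annealing runs is reproduced by a
#' single integer.
#'
#' @param master_seed Master seed.
#' @param n_runs Number of seeds required.
#' @return An integer vector of length `n_runs`, pairwise distinct.
#' @export
fan_out_seeds <- function(master_seed, n_runs) {
  stopifnot(n_runs >= 1)
  with_stream(rng_stream(master_seed),
              sample.int(.Machine$integer.max, as.integer(n_runs)))
}

#' Acceptance-ratio simulated annealing
#'
#' Runs `n_parallel_runs` independent annealing runs (each `n_cycles` cycles of
#' `n_iterations_per_cycle` steps) from seeds fanned out of `master_seed`, and
#' returns the overall best configuration by lowest pseudo-energy. Each run
#' owns an independent random stream, so the result is identical whether the
#' runs execute sequentially or concurrently.
#'
#' @param problem An [new_problem()] definition.
#' @param k0 Initial configuration (shared by all runs).
#' @param data Optional opaque payload.
#' @param config An [annealing_config()].
#' @param parallel If `TRUE`, runs execute via [parallel::mclapply()] on
#'   `cores` workers; the result is identical to sequential execution.
#' @param cores Worker count when `parallel = TRUE`.
#' @param validate Run [validate_problem()] first (recommended).
#' @return An `aropt_result` list: `mode`, `best_k`, `best_energy`,
#'   `best_quality`, `n_steps_total`, `per_run_bests` (one row per run:
#'   `run`, `seed`, `best_energy`, `best_quality`), `traces` and `windows`
#'   (one data frame per run), `final_states`, `config`.
#' @examples
#' ex <- benchmark_problem("quadratic")
#' cfg <- annealing_config(n_iterations_per_cycle = 200, n_cycles = 1,
#'                         master_seed = 7)
#' res <- run_sa(ex$problem, ex$k0, config = cfg)
#' res$best_energy
#' @export
run_sa <- function(problem, k0, data = NULL, config = annealing_config(),
                   parallel = FALSE, cores = 2L, validate = TRUE) {
  stopifnot(inherits(config, "annealing_config"))
  if (validate) validate_problem(problem, k0, data, seed = config$master_seed)
  seeds <- fan_out_seeds(config$master_seed, config$n_parallel_runs)
  run_one <- function(run_idx) {
    seed <- seeds[run_idx]
    rng <- rng_stream(seed)
    state <- chain_init(problem, k0, data)
    t_cur <- config$t_initial
    recs <- vector("list", config$n_cycles)
    wins <- vector("list", config$n_cycles)
    for (cy in seq_len(config$n_cycles)) {
      cyc <- run_annealing_cycle(state, config, t_cur, problem, data, rng, cy)
      state <- cyc$state
      t_cur <- cyc$t_out
      recs[[cy]] <- cyc$records
      wins[[cy]] <- cyc$windows
    }
    trace <- do.call(rbind, recs)
    trace$replica <- run_idx
    trace <- trace[, c("step", "cycle", "window", "replica", "temperature",
                       "target_ar", "proposal_energy", "accepted",
                       "current_energy", "best_energy", "best_quality")]
    windows <- do.call(rbind, wins)
    list(run = run_idx, seed = seed, state = state, trace = trace,
         windows = windows)
  }
  runs <- if (parallel) {
    parallel::mclapply(seq_along(seeds), run_one, mc.cores = as.integer(cores),
                       mc.set.seed = FALSE)
  } else {
    lapply(seq_along(seeds), run_one)
  }
  bad <- vapply(runs, function(r) inherits(r, "try-error") || is.null(r$state),
                logical(1))
  if (any(bad)) {
    stop("annealing run failed for seed(s) ",
         paste(seeds[bad], collapse = ", "), call. = FALSE)
  }
  per_run <- data.frame(
    run = vapply(runs, `[[`, 0L, "run"),
    seed = vapply(runs, `[[`, 0L, "seed"),
    best_energy = vapply(runs, function(r) r$state$best_energy, 0),
    best_quality = vapply(runs, function(r) r$state$best_quality, 0))
  ib <- which.min(per_run$best_energy)
  structure(list(mode = "SA",
                 best_k = runs[[ib]]$state$best_k,
                 best_energy = per_run$best_energy[ib],
                 best_quality = per_run$best_quality[ib],
                 n_steps_total = config$n_parallel_runs * config$n_cycles *
                   config$n_iterations_per_cycle,
                 per_run_bests = per_run,
                 traces = lapply(runs, `[[`, "trace"),
                 windows = lapply(runs, `[[`, "windows"),
                 final_states = lapply(runs, `[[`, "state"),
                 exchange_log = NULL,
                 config = config),
            class = "aropt_result")
}

#' @export
print.aropt_result <- function(x, ...) {
  cat("Acceptance-ratio optimization result (mode ", x$mode, ")\n", sep = "")
  cat("  total steps:  ", x$n_steps_total, "\n", sep = "")
  cat("  best energy:  ", format(x$best_energy, digits = 8), "\n", sep = "")
  cat("  best quality: ", format(x$best_quality, digits = 8), "\n", sep = "")
  cat("  best configuration:\n")
  print(x$best_k)
  invisible(x)
}
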