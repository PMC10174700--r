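#' Configuration for acceptance-ratio replica exchange
#'
#' Replica exchange here departs from physical parallel tempering in two ways:
#' each replica holds a *fixed target acceptance ratio* (its temperature adapts
#' under thermoregulation rather than being fixed), and selected replica pairs
#' swap configurations *unconditionally* — no Metropolis swap test. This is an
#' optimization device, not equilibrium sampling: the point is to hand good
#' configurations found by exploratory (high-AR, hot) replicas to greedy
#' (low-AR, cold) replicas for refinement.
#'
#' @param ar_values Per-replica target acceptance ratios in `(0, 1]`, strictly
#'   decreasing (replica 0 is the most exploratory), length >= 2. The default
#'   eight-replica ladder spans exploratory to greedy.
#' @param exchange_period_windows Number of thermoregulated windows each
#'   replica runs between consecutive exchange events. A period longer than
#'   the whole run degenerates to independent fixed-AR runs.
#' @param n_iterations_total Steps per replica; must be a multiple of
#'   `window_size`.
#' @param window_size,t_initial,controller,master_seed As in
#'   [annealing_config()].
#' @return An `exchange_config` list.
#' @export
exchange_config <- function(ar_values = c(0.9, 0.6, 0.4, 0.25, 0.15, 0.08,
                                          0.04, 0.01),
                            exchange_period_windows = 5L,
                            n_iterations_total = 10000L, window_size = 20L,
                            t_initial = 1, controller = controller_params(),
                            master_seed = 1L) {
  stopifnot(is.numeric(ar_values), exchange_period_windows >= 1,
            n_iterations_total >= 1, window_size >= 1, t_initial > 0,
            inherits(controller, "controller_params"))
  if (length(ar_values) < 2L) {
    stop("replica exchange needs at least 2 ar_values", call. = FALSE)
  }
  if (anyDuplicated(ar_values)) {
    stop("ar_values must be pairwise distinct", call. = FALSE)
  }
  if (any(ar_values <= 0) || any(ar_values > 1)) {
    stop("ar_values must lie in (0, 1]", call. = FALSE)
  }
  if (is.unsorted(rev(ar_values), strictly = TRUE)) {
    stop("ar_values must be strictly decreasing (replica 0 most exploratory)",
         call. = FALSE)
  }
  if (n_iterations_total %% window_size != 0) {
    stop("window_size must divide n_iterations_total", call. = FALSE)
  }
  structure(list(ar_values = as.numeric(ar_values),
                 exchange_period_windows = as.integer(exchange_period_windows),
                 n_iterations_total = as.integer(n_iterations_total),
                 window_size = as.integer(window_size),
                 t_initial = as.numeric(t_initial),
                 controller = controller,
                 master_seed = as.integer(master_seed)),
            class = "exchange_config")
}

#' Initialise replicas from a shared starting configuration
#'
#' One replica per target AR, all starting from an independently copied `k0`
#' (evaluated once), each with its own random stream fanned out of the master
#' seed (replica `i` gets the `i+1`-th fanned seed; the extra last seed drives
#' the exchange scheduler in [run_re()]).
#'
#' @param config An [exchange_config()].
#' @param k0 Initial configuration.
#' @param problem,data As in [run_sa()].
#' @return A list of `replica_state` lists: `replica_id` (0-based, in AR
#'   order), `target_ar`, `chain`, `temperature`, `seed`, `rng`.
#' @export
init_replicas <- function(config, k0, problem, data = NULL) {
  stopifnot(inherits(config, "exchange_config"))
  n <- length(config$ar_values)
  seeds <- fan_out_seeds(config$master_seed, n + 1L)
  state0 <- chain_init(problem, k0, data)
  lapply(seq_len(n), function(i) {
    structure(list(replica_id = i - 1L,
                   target_ar = config$ar_values[i],
                   chain = state0,
                   temperature = config$t_initial,
                   seed = seeds[i],
                   rng = rng_stream(seeds[i])),
              class = "replica_state")
  })
}

#' Select a pair of replicas for exchange
#'
#' Uniformly random *adjacent* pair in the acceptance-ratio ordering:
#' adjacency limits the configuration shock between very different acceptance
#' regimes. The selection rule is deliberately simple and replaceable.
#'
#' @param n_replicas Number of replicas, >= 2.
#' @param rng Optional [rng_stream()] supplying the draw.
#' @return Integer vector `c(i, i + 1)` of 1-based replica positions,
#'   `1 <= i <= n_replicas - 1`.
#' @export
select_exchange_pair <- function(n_replicas, rng = NULL) {
  if (!is.numeric(n_replicas) || n_replicas < 2) {
    stop("n_replicas must be >= 2", call. = FALSE)
  }
  i <- if (is.null(rng)) {
    sample.int(n_replicas - 1L, 1L)
  } else {
    with_stream(rng, sample.int(n_replicas - 1L, 1L))
  }
  c(i, i + 1L)
}

#' Unconditionally exchange configurations between two replicas
#'
#' Swaps the current configurations, energies and qualities of `a` and `b`.
#' Replica identities, target ARs, temperatures, random streams and
#' best-so-far records stay with their replicas; no acceptance test is
#' applied, and energies travel with their configurations (evaluation is
#' deterministic, so re-evaluation would be redundant).
#'
#' @param a,b Two `replica_state` objects from [init_replicas()].
#' @return `list(a =, b =)` with the swap applied.
#' @export
perform_exchange <- function(a, b) {
  stopifnot(inherits(a, "replica_state"), inherits(b, "replica_state"))
  if (identical(a$replica_id, b$replica_id)) {
    stop("cannot exchange a replica with itself", call. = FALSE)
  }
  swap <- c("current_k", "current_energy", "current_quality")
  tmp <- a$chain[swap]
  a$chain[swap] <- b$chain[swap]
  b$chain[swap] <- tmp
  list(a = a, b = b)
}

#' Acceptance-ratio replica exchange
#'
#' Runs `length(ar_values)` replicas, each a thermoregulated chain at its own
#' fixed target acceptance ratio. After every `exchange_period_windows`
#' windows (per replica) one adjacent pair is selected and its configurations
#' are exchanged unconditionally; no exchange is scheduled after the final
#' window. Replica chains draw from independent streams and the exchange
#' scheduler from its own, so the run is reproducible and independent of
#' physical execution order. The overall best is the lowest pseudo-energy seen
#' by any replica at any step.
#'
#' @inheritParams run_sa
#' @param config An [exchange_config()].
#' @return An `aropt_result` as in [run_sa()], with `mode = "RE"`,
#'   `per_run_bests` keyed by replica (columns `replica`, `target_ar`, `seed`,
#'   `best_energy`, `best_quality`) and an `exchange_log` data frame
#'   (`event_index`, `step`, `replica_i`, `replica_j`).
#' @examples
#' ex <- benchmark_problem("double_well")
#' cfg <- exchange_config(ar_values = c(0.5, 0.1), n_iterations_total = 200,
#'                        master_seed = 3)
#' run_re(ex$problem, ex$k0, config = cfg)$best_energy
#' @export
run_re <- function(problem, k0, data = NULL, config = exchange_config(),
                   validate = TRUE) {
  stopifnot(inherits(config, "exchange_config"))
  if (validate) validate_problem(problem, k0, data, seed = config$master_seed)
  n <- length(config$ar_values)
  reps <- init_replicas(config, k0, problem, data)
  ex_rng <- rng_stream(fan_out_seeds(config$master_seed, n + 1L)[n + 1L])
  ws <- config$window_size
  n_win <- config$n_iterations_total %/% ws
  rep_recs <- lapply(seq_len(n), function(i) vector("list", n_win))
  rep_wins <- lapply(seq_len(n), function(i) vector("list", n_win))
  exch <- list()
  w_done <- 0L
  ev <- 0L
  while (w_done < n_win) {
    w_run <- min(config$exchange_period_windows, n_win - w_done)
    for (r in seq_len(n)) {
      rs <- reps[[r]]
      for (w in seq_len(w_run)) {
        reg <- regulate_window(rs$chain, rs$temperature, rs$target_ar, ws,
                               problem, data, config$controller, rs$rng)
        rs$chain <- reg$state
        rs$temperature <- reg$temperature
        widx <- w_done + w
        rec <- reg$records
        rec$cycle <- 1L
        rec$window <- widx
        rec$replica <- rs$replica_id
        rep_recs[[r]][[widx]] <-
          rec[, c("step", "cycle", "window", "replica", "temperature",
                  "target_ar", "proposal_energy", "accepted", "current_energy",
                  "best_energy", "best_quality")]
        st <- reg$stats
        rep_wins[[r]][[widx]] <- data.frame(
          replica = rs$replica_id, window = widx,
          temperature_used = st$temperature_used, target_ar = st$target_ar,
          observed_ar = st$observed_ar, n_accepted = st$n_accepted,
          n_steps = st$n_steps, boosted = st$boosted)
      }
      reps[[r]] <- rs
    }
    w_done <- w_done + w_run
    if (w_done < n_win) {
      pr <- select_exchange_pair(n, ex_rng)
      sw <- perform_exchange(reps[[pr[1]]], reps[[pr[2]]])
      reps[[pr[1]]] <- sw$a
      reps[[pr[2]]] <- sw$b
      ev <- ev + 1L
      exch[[ev]] <- data.frame(event_index = ev, step = w_done * ws,
                               replica_i = sw$a$replica_id,
                               replica_j = sw$b$replica_id)
    }
  }
  per_rep <- data.frame(
    replica = vapply(reps, `[[`, 0L, "replica_id"),
    target_ar = vapply(reps, `[[`, 0, "target_ar"),
    seed = vapply(reps, `[[`, 0L, "seed"),
    best_energy = vapply(reps, function(x) x$chain$best_energy, 0),
    best_quality = vapply(reps, function(x) x$chain$best_quality, 0))
  ib <- which.min(per_rep$best_energy)
  exchange_log <- if (ev > 0) do.call(rbind, exch) else
    data.frame(event_index = integer(), step = integer(),
               replica_i = integer(), replica_j = integer())
  structure(list(mode = "RE",
                 best_k = reps[[ib]]$chain$best_k,
                 best_energy = per_rep$best_energy[ib],
                 best_quality = per_rep$best_quality[ib],
                 n_steps_total = n * config$n_iterations_total,
                 per_run_bests = per_rep,
                 traces = lapply(rep_recs, function(x) do.call(rbind, x)),
                 windows = lapply(rep_wins, function(x) do.call(rbind, x)),
                 final_states = reps,
                 exchange_log = exchange_log,
                 config = config),
            class = "aropt_result")
}
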