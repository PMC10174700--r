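#' Metropolis acceptance rule
#'
#' Classical Metropolis criterion: a proposal with energy change
#' `delta_energy` at pseudo-temperature `temperature` is accepted iff
#' `delta_energy <= 0` or `uniform_draw < exp(-delta_energy / temperature)`.
#' Ties (`delta_energy == 0`) are always accepted. A `+Inf` energy change
#' (forbidden proposal from a feasible state) is always rejected.
#'
#' @param delta_energy Proposal energy minus current energy.
#' @param temperature Pseudo-temperature, strictly positive.
#' @param uniform_draw A number in `[0, 1)`, typically `runif(1)`.
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @examples
#' metropolis_accept(-2.5, 1, 0.99)          # downhill: TRUE
#' metropolis_accept(1, 1, 0.5)              # 0.5 >= exp(-1): FALSE
#' metropolis_accept(1, 1, 0.3)              # 0.3 <  exp(-1): TRUE
#' @export
metropolis_accept <- function(delta_energy, temperature, uniform_draw) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      is.na(temperature) || temperature <= 0) {
    stop("temperature must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(uniform_draw) || length(uniform_draw) != 1L ||
      is.na(uniform_draw) || uniform_draw < 0 || uniform_draw >= 1) {
    stop("uniform_draw must lie in [0, 1)", call. = FALSE)
  }
  if (is.nan(delta_energy)) stop("delta_energy is NaN", call. = FALSE)
  delta_energy <= 0 || uniform_draw < exp(-delta_energy / temperature)
}

#' Initialise a Markov-chain state from a configuration
#'
#' Evaluates `k0` once (this evaluation happens before step 0 and is not
#' counted in any statistics window) and seeds both the current and the
#' best-so-far records with it.
#'
#' @inheritParams validate_problem
#' @return A `chain_state` list: `current_k`, `current_energy`,
#'   `current_quality`, `best_k`, `best_energy`, `best_quality`, `step_index`.
#' @export
chain_init <- function(problem, k0, data = NULL) {
  eq <- eval_config(problem, k0, data)
  structure(list(current_k = k0,
                 current_energy = eq$energy,
                 current_quality = eq$quality,
                 best_k = k0,
                 best_energy = eq$energy,
                 best_quality = eq$quality,
                 step_index = 0L),
            class = "chain_state")
}

#' Advance a chain by one Metropolis step
#'
#' Proposes via the move rule, evaluates via model + evaluate, applies
#' [metropolis_accept()] at the given temperature, and updates the current and
#' best-so-far records. When both the current and the proposed configuration
#' are forbidden (`+Inf` energy) the move is treated as a tie, letting a chain
#' started in an infeasible region wander until it finds feasibility.
#'
#' @param state A `chain_state` from [chain_init()].
#' @param problem An [new_problem()] definition.
#' @param data Optional opaque payload.
#' @param temperature Positive pseudo-temperature for this step.
#' @param rng Optional [rng_stream()]; if `NULL`, the ambient RNG state is used
#'   (callers that manage streams activate them around whole windows).
#' @return `list(state =, record =)` where `record` holds `step_index`,
#'   `proposal_energy`, `accepted`, `temperature`.
#' @export
chain_step <- function(state, problem, data = NULL, temperature, rng = NULL) {
  if (!is.null(rng)) {
    return(with_stream(rng, chain_step(state, problem, data, temperature)))
  }
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  step <- state$step_index + 1L
  kp <- tryCatch(problem$move(state$current_k),
                 error = function(e) stop("move_rule failed at step ", step, ": ",
                                          conditionMessage(e), call. = FALSE))
  eq <- tryCatch(eval_config(problem, kp, data),
                 error = function(e) stop("at step ", step, ": ",
                                          conditionMessage(e), call. = FALSE))
  de <- eq$energy - state$current_energy
  if (is.nan(de)) de <- 0  # both forbidden (+Inf - +Inf): treat as tie
  u <- stats::runif(1L)
  accepted <- de <= 0 || u < exp(-de / temperature)
  state$step_index <- step
  if (accepted) {
    state$current_k <- kp
    state$current_energy <- eq$energy
    state$current_quality <- eq$quality
    if (eq$energy < state$best_energy) {
      state$best_k <- kp
      state$best_energy <- eq$energy
      state$best_quality <- eq$quality
    }
  }
  list(state = state,
       record = list(step_index = step, proposal_energy = eq$energy,
                     accepted = accepted, temperature = temperature))
}

#' Run a fixed-temperature window of Metropolis steps
#'
#' Executes exactly `n_steps` chain steps at one temperature and aggregates the
#' acceptance decisions into window statistics. This is the unit over which the
#' observed acceptance ratio is measured.
#'
#' @inheritParams chain_step
#' @param n_steps Number of steps (>= 1).
#' @param target_ar Target acceptance ratio recorded alongside the trace
#'   (purely informational here; the thermoregulator consumes it).
#' @return `list(state =, stats =, records =)`: the advanced state, a list with
#'   `n_steps`, `n_accepted`, `observed_ar`, `temperature_used`, `target_ar`,
#'   and a data frame of per-step records.
#' @export
run_window <- function(state, n_steps, temperature, problem, data = NULL,
                       rng = NULL, target_ar = NA_real_) {
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1) {
    stop("n_steps must be a positive integer", call. = FALSE)
  }
  if (!is.null(rng)) {
    return(with_stream(rng, run_window(state, n_steps, temperature, problem,
                                       data, rng = NULL, target_ar = target_ar)))
  }
  n_steps <- as.integer(n_steps)
  steps <- integer(n_steps)
  prop_e <- numeric(n_steps)
  acc <- logical(n_steps)
  cur_e <- numeric(n_steps)
  best_e <- numeric(n_steps)
  best_q <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    res <- chain_step(state, problem, data, temperature)
    state <- res$state
    steps[i] <- res$record$step_index
    prop_e[i] <- res$record$proposal_energy
    acc[i] <- res$record$accepted
    cur_e[i] <- state$current_energy
    best_e[i] <- state$best_energy
    best_q[i] <- state$best_quality
  }
  n_acc <- sum(acc)
  stats <- list(n_steps = n_steps, n_accepted = n_acc,
                observed_ar = n_acc / n_steps,
                temperature_used = temperature, target_ar = target_ar)
  records <- data.frame(step = steps, temperature = temperature,
                        target_ar = target_ar, proposal_energy = prop_e,
                        accepted = acc, current_energy = cur_e,
                        best_energy = best_e, best_quality = best_q)
  list(state = state, stats = stats, records = records)
}
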