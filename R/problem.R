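#' Define an optimization problem from three callbacks
#'
#' The engine is fully generic: it never inspects the parameter state `K` it
#' optimizes. A problem is expressed through three user functions:
#'
#' * `move`: `function(k)` — propose a new configuration from the current one.
#'   May (and usually should) use R's random generators; the engine supplies
#'   and manages the random stream so seeded runs are reproducible.
#' * `model`: `function(k, data)` — map a configuration (plus the optional,
#'   engine-opaque `data` payload) to a model output of any shape.
#' * `evaluate`: `function(model_output, data)` — return
#'   `list(energy = E, quality = Q)`. `E` is the pseudo-energy the engine
#'   minimizes; `Q` is a human-meaningful quality carried through for
#'   reporting. `evaluate` must be deterministic.
#'
#' Energies must be finite or `+Inf`; `+Inf` marks a forbidden configuration
#' (hard constraint violation) and is always rejected from a feasible state.
#' `NaN`, `NA` and `-Inf` energies are errors.
#'
#' @param move,model,evaluate The three callbacks described above.
#' @return An object of class `aropt_problem`.
#' @seealso [validate_problem()], [run_sa()], [run_re()]
#' @export
new_problem <- function(move, model, evaluate) {
  if (!is.function(move) || !is.function(model) || !is.function(evaluate)) {
    stop("move, model and evaluate must all be functions", call. = FALSE)
  }
  structure(list(move = move, model = model, evaluate = evaluate),
            class = "aropt_problem")
}

#' Construct a pseudo-energy / quality pair
#'
#' @param energy Pseudo-energy: finite number or `+Inf` (forbidden state).
#' @param quality Reporting metric; defaults to the energy.
#' @return `list(energy =, quality =)` of class `energy_quality`.
#' @export
energy_quality <- function(energy, quality = energy) {
  structure(check_energy_quality(list(energy = energy, quality = quality)),
            class = "energy_quality")
}

# Validates an evaluate() return value; shared by energy_quality() and the
# chain engine. +Inf energy is legal (forbidden state), NaN/-Inf/NA are not.
check_energy_quality <- function(eq) {
  if (!is.list(eq) || is.null(eq$energy) || is.null(eq$quality)) {
    stop("evaluate must return list(energy =, quality =)", call. = FALSE)
  }
  e <- eq$energy
  if (!is.numeric(e) || length(e) != 1L || is.nan(e) || is.na(e) ||
      (is.infinite(e) && e < 0)) {
    stop("invalid energy: must be a finite number or +Inf", call. = FALSE)
  }
  q <- eq$quality
  if (!is.numeric(q) || length(q) != 1L) {
    stop("invalid quality: must be a single number", call. = FALSE)
  }
  list(energy = as.numeric(e), quality = as.numeric(q))
}

# Run model + evaluate on one configuration, with callback-naming errors.
eval_config <- function(problem, k, data) {
  out <- tryCatch(problem$model(k, data),
                  error = function(e) stop("model callback failed: ",
                                           conditionMessage(e), call. = FALSE))
  eq <- tryCatch(problem$evaluate(out, data),
                 error = function(e) stop("evaluate callback failed: ",
                                          conditionMessage(e), call. = FALSE))
  check_energy_quality(eq)
}

#' Validate a problem definition before running the engine
#'
#' Exercises the full callback contract once: proposes a move from `k0`,
#' evaluates both the initial and the proposed configuration, and checks that
#'
#' * the move rule does not alias or mutate the retained current state
#'   (deep-equality via serialization before/after),
#' * `evaluate` is deterministic (two calls on the same model output agree),
#' * energies are legal (finite or `+Inf`; `NaN` is an "invalid energy" error).
#'
#' Errors raised inside a callback are re-raised naming the offending callback.
#'
#' @param problem An [new_problem()] definition.
#' @param k0 Initial configuration.
#' @param data Optional opaque data payload passed untouched to callbacks.
#' @param seed Seed for the engine-supplied random stream used by the move.
#' @return A list of class `aropt_validation` with elements `ok`, `initial` and
#'   `proposal` (the two energy/quality pairs). Failure is an error, not a
#'   return value.
#' @examples
#' p <- new_problem(
#'   move = function(k) k + rnorm(1),
#'   model = function(k, data) k,
#'   evaluate = function(k, data) list(energy = k^2, quality = k^2)
#' )
#' validate_problem(p, k0 = 3, seed = 1)
#' @export
validate_problem <- function(problem, k0, data = NULL, seed = 1L) {
  if (!inherits(problem, "aropt_problem")) {
    stop("problem must be created with new_problem()", call. = FALSE)
  }
  snap <- serialize(k0, NULL)
  rng <- rng_stream(seed)
  k1 <- with_stream(rng, tryCatch(problem$move(k0),
    error = function(e) stop("move_rule callback failed: ",
                             conditionMessage(e), call. = FALSE)))
  if (!identical(serialize(k0, NULL), snap)) {
    stop("move_rule mutated its input in place (aliasing); ",
         "it must return a fresh configuration", call. = FALSE)
  }
  out0 <- tryCatch(problem$model(k0, data),
                   error = function(e) stop("model callback failed: ",
                                            conditionMessage(e), call. = FALSE))
  eq0 <- tryCatch(problem$evaluate(out0, data),
                  error = function(e) stop("evaluate callback failed: ",
                                           conditionMessage(e), call. = FALSE))
  eq0b <- tryCatch(problem$evaluate(out0, data), error = function(e) NULL)
  if (!identical(eq0, eq0b)) {
    stop("evaluate is not deterministic: two calls on the same model output ",
         "disagreed", call. = FALSE)
  }
  eq0 <- check_energy_quality(eq0)
  eq1 <- eval_config(problem, k1, data)
  if (!identical(serialize(k0, NULL), snap)) {
    stop("a callback mutated the initial configuration in place", call. = FALSE)
  }
  structure(list(ok = TRUE, initial = eq0, proposal = eq1, seed = as.integer(seed)),
            class = "aropt_validation")
}
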