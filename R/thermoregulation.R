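#' Observed acceptance ratio of a statistics window
#'
#' The exact fraction of accepted moves among all trials of the current window.
#'
#' @param n_accepted Number of accepted moves, `0 <= n_accepted <= n_steps`.
#' @param n_steps Window length in steps, `>= 1`.
#' @return `n_accepted / n_steps`.
#' @export
observed_acceptance_ratio <- function(n_accepted, n_steps) {
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1) {
    stop("n_steps must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(n_accepted) || length(n_accepted) != 1L ||
      n_accepted < 0 || n_accepted > n_steps) {
    stop("n_accepted must lie in [0, n_steps]", call. = FALSE)
  }
  n_accepted / n_steps
}

#' Thermoregulation controller parameters
#'
#' The pseudo-temperature controller is proportional in log10-temperature:
#' after each statistics window the temperature is multiplied by
#' `10^(gain * (target - observed))`, with the exponent clamped to
#' `[-max_log10_step, +max_log10_step]` per update and the temperature itself
#' clamped to `[t_min, t_max]`. When a window records zero acceptances while
#' the target is positive (a frozen chain in a deep trap), an additional
#' `frozen_boost_log10` is added to the exponent *after* the per-step clamp —
#' the heat-shock escape that produces the abrupt temperature jumps
#' characteristic of acceptance-ratio annealing.
#'
#' @param gain Log10-temperature response per unit of acceptance-ratio error.
#' @param max_log10_step Cap on one update's proportional |log10 T| change.
#' @param t_min,t_max Hard temperature bounds, `0 < t_min < t_max`. The wide
#'   defaults realise an effectively unconstrained adaptive temperature.
#' @param frozen_boost_log10 Extra log10 jump applied on a zero-acceptance
#'   window (not subject to `max_log10_step`).
#' @return A `controller_params` list.
#' @export
controller_params <- function(gain = 5, max_log10_step = 1,
                              t_min = 1e-12, t_max = 1e12,
                              frozen_boost_log10 = 1) {
  stopifnot(gain > 0, max_log10_step > 0, t_min > 0, t_max > 0,
            t_min < t_max, frozen_boost_log10 > 0)
  structure(list(gain = as.numeric(gain),
                 max_log10_step = as.numeric(max_log10_step),
                 t_min = as.numeric(t_min), t_max = as.numeric(t_max),
                 frozen_boost_log10 = as.numeric(frozen_boost_log10)),
            class = "controller_params")
}

#' Adaptive thermoregulation update
#'
#' Computes the pseudo-temperature for the next statistics window from the
#' acceptance-ratio error of the last one. Direction contract: the temperature
#' rises when too few moves were accepted, falls when too many were, and is
#' unchanged at the target (within the hard bounds).
#'
#' @param t_current Current positive pseudo-temperature.
#' @param observed Observed acceptance ratio in `[0, 1]`.
#' @param target Target acceptance ratio in `[0, 1]`.
#' @param params A [controller_params()] object.
#' @return The new temperature, inside `[t_min, t_max]`.
#' @examples
#' p <- controller_params(gain = 1, max_log10_step = 1, frozen_boost_log10 = 1)
#' update_temperature(1, observed = 0.2, target = 0.5, p)  # 10^0.3
#' update_temperature(1, observed = 0,   target = 0.5, p)  # 10^1.5 heat shock
#' @export
update_temperature <- function(t_current, observed, target,
                               params = controller_params()) {
  stopifnot(inherits(params, "controller_params"),
            t_current > 0, observed >= 0, observed <= 1,
            target >= 0, target <= 1)
  s <- params$gain * (target - observed)
  s <- max(-params$max_log10_step, min(params$max_log10_step, s))
  if (observed == 0 && target > 0) s <- s + params$frozen_boost_log10
  min(params$t_max, max(params$t_min, t_current * 10^s))
}

#' Run one thermoregulated statistics window
#'
#' Runs a fixed-temperature window, measures the observed acceptance ratio,
#' and returns the temperature the controller prescribes for the next window.
#'
#' @inheritParams run_window
#' @param t_state Temperature at which this window runs.
#' @param target Target acceptance ratio for this window.
#' @param window_size Number of steps in the window.
#' @param params A [controller_params()] object.
#' @return `list(state =, temperature =, stats =, records =)`; `temperature`
#'   is the *next* window's temperature, `stats` gains a `boosted` flag marking
#'   frozen-state heat shocks.
#' @export
regulate_window <- function(state, t_state, target, window_size, problem,
                            data = NULL, params = controller_params(),
                            rng = NULL) {
  res <- run_window(state, window_size, t_state, problem, data, rng,
                    target_ar = target)
  obs <- res$stats$observed_ar
  res$stats$boosted <- obs == 0 && target > 0
  list(state = res$state,
       temperature = update_temperature(t_state, obs, target, params),
       stats = res$stats,
       records = res$records)
}
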