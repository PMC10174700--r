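#' Synthetic polynomial-coefficient fitting problem
#'
#' Generates noisy observations `y = a0 + a1*x + a2*x^2 + N(0, noise_sd)` on an
#' equally spaced grid and wraps them as an engine problem: the configuration
#' is the coefficient triple, the pseudo-energy is the residual sum of squares,
#' the quality is the root-mean-square residual, and the move rule perturbs one
#' uniformly chosen coefficient by `N(0, move_sd)`.
#'
#' @param seed Seed for the synthetic data.
#' @param n_points Number of observations (>= 10).
#' @param true_coeffs The generating `(a0, a1, a2)`.
#' @param noise_sd Observation noise standard deviation.
#' @param x_range Range of the x grid.
#' @param move_sd Proposal standard deviation per coefficient.
#' @return A list with `problem` ([new_problem()]), `k0` (all-zero start),
#'   `data` (`x`, `y`), `true_coeffs`, `x_values`, `y_values`, `noise_sd`,
#'   `move_sd`.
#' @export
generate_polyfit <- function(seed, n_points = 50L, true_coeffs = c(2, -1, 0.5),
                             noise_sd = 0.05, x_range = c(-3, 3),
                             move_sd = 0.1) {
  stopifnot(n_points >= 10, length(true_coeffs) == 3, noise_sd >= 0,
            move_sd > 0, length(x_range) == 2, x_range[1] < x_range[2])
  x <- seq(x_range[1], x_range[2], length.out = n_points)
  y <- with_stream(rng_stream(seed),
                   true_coeffs[1] + true_coeffs[2] * x + true_coeffs[3] * x^2 +
                     stats::rnorm(n_points, 0, noise_sd))
  move <- function(k) {
    i <- sample.int(3L, 1L)
    k[i] <- k[i] + stats::rnorm(1L, 0, move_sd)
    k
  }
  model <- function(k, data) k[1] + k[2] * data$x + k[3] * data$x^2
  evaluate <- function(yhat, data) {
    r <- data$y - yhat
    list(energy = sum(r * r), quality = sqrt(mean(r * r)))
  }
  structure(list(problem = new_problem(move, model, evaluate),
                 k0 = c(0, 0, 0), data = list(x = x, y = y),
                 true_coeffs = true_coeffs, x_values = x, y_values = y,
                 noise_sd = noise_sd, move_sd = move_sd),
            class = c("polyfit_problem", "aropt_example"))
}

#' Two-compartment first-order kinetics, fixed-step Runge-Kutta
#'
#' Integrates `dA/dt = -k1 A`, `dB/dt = k1 A - k2 B` with `A(0) = a0`,
#' `B(0) = 0` by classical fourth-order Runge-Kutta on a fixed grid of width
#' `integrator_step` (refined with the requested sample times), and returns the
#' trajectories at `times`. For `k1 != k2` the closed form is
#' `A(t) = a0 exp(-k1 t)`,
#' `B(t) = a0 k1 / (k2 - k1) * (exp(-k1 t) - exp(-k2 t))`, which the
#' integrator reproduces to ~1e-6 relative error at `integrator_step = 0.001`.
#'
#' @param k1,k2 Positive rate constants (1/time).
#' @param a0 Initial amount of species A.
#' @param times Strictly increasing sample times starting at 0.
#' @param integrator_step Fixed step width; must not exceed the smallest
#'   spacing of `times`.
#' @return `list(A =, B =)` vectors aligned with `times`.
#' @export
simulate_two_step_kinetics <- function(k1, k2, a0, times,
                                       integrator_step = 0.001) {
  stopifnot(k1 > 0, k2 > 0, a0 > 0, length(times) >= 2)
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing and start at 0", call. = FALSE)
  }
  if (integrator_step > min(diff(times))) {
    stop("integrator_step must not exceed the smallest spacing of times",
         call. = FALSE)
  }
  grid <- sort(unique(c(seq(0, max(times), by = integrator_step), times)))
  deriv <- function(t, y, parms) {
    list(c(-k1 * y[1], k1 * y[1] - k2 * y[2]))
  }
  sol <- deSolve::rk4(c(A = a0, B = 0), grid, deriv, parms = NULL)
  idx <- match(times, grid)
  list(A = unname(sol[idx, "A"]), B = unname(sol[idx, "B"]))
}

#' Synthetic kinetic ODE parameter-estimation problem
#'
#' Simulates the two-compartment scheme of [simulate_two_step_kinetics()] at
#' the true rates, adds Gaussian noise to both species, and wraps rate-constant
#' recovery as an engine problem: the configuration is `(k1, k2)`, the
#' pseudo-energy is the summed squared residual over A and B, the quality is
#' the root-mean-square residual, and the move rule applies a multiplicative
#' log-normal perturbation to one rate. Non-positive rates are forbidden
#' states (`+Inf` energy), exercising the hard-constraint mechanism.
#'
#' @param seed Seed for the synthetic observations.
#' @param true_k1,true_k2 Generating rate constants.
#' @param a0 Initial amount of A.
#' @param times Sample times (strictly increasing, starting at 0).
#' @param noise_sd Observation noise standard deviation (same units as A).
#' @param integrator_step Step width used by the in-loop integrator. The
#'   default 0.1 keeps each energy evaluation cheap while staying far below
#'   the noise floor in accuracy.
#' @param move_sdlog Standard deviation of the log-normal rate perturbation.
#' @return A list with `problem`, `k0` (`c(0.5, 0.5)`), `data`, `true_k1`,
#'   `true_k2`, `times`, `observed_A`, `observed_B`, `noise_sd`.
#' @export
generate_odefit <- function(seed, true_k1 = 1, true_k2 = 0.3, a0 = 1,
                            times = seq(0, 10, length.out = 12),
                            noise_sd = 0.01, integrator_step = 0.1,
                            move_sdlog = 0.15) {
  stopifnot(true_k1 > 0, true_k2 > 0, noise_sd >= 0, move_sdlog > 0)
  truth <- simulate_two_step_kinetics(true_k1, true_k2, a0, times,
                                      integrator_step = min(0.01, integrator_step))
  obs <- with_stream(rng_stream(seed), {
    nA <- stats::rnorm(length(times), 0, noise_sd)
    nB <- stats::rnorm(length(times), 0, noise_sd)
    list(A = truth$A + nA, B = truth$B + nB)
  })
  data <- list(times = times, observed_A = obs$A, observed_B = obs$B,
               a0 = a0, integrator_step = integrator_step)
  move <- function(k) {
    i <- sample.int(2L, 1L)
    k[i] <- k[i] * exp(stats::rnorm(1L, 0, move_sdlog))
    k
  }
  model <- function(k, data) {
    if (any(!is.finite(k)) || any(k <= 0)) return(NULL)  # forbidden state
    simulate_two_step_kinetics(k[1], k[2], data$a0, data$times,
                               data$integrator_step)
  }
  evaluate <- function(sim, data) {
    if (is.null(sim)) return(list(energy = Inf, quality = Inf))
    rA <- data$observed_A - sim$A
    rB <- data$observed_B - sim$B
    ss <- sum(rA * rA) + sum(rB * rB)
    list(energy = ss, quality = sqrt(ss / (2 * length(data$times))))
  }
  structure(list(problem = new_problem(move, model, evaluate),
                 k0 = c(0.5, 0.5), data = data,
                 true_k1 = true_k1, true_k2 = true_k2, times = times,
                 observed_A = obs$A, observed_B = obs$B, noise_sd = noise_sd),
            class = c("odefit_problem", "aropt_example"))
}

#' Synthetic lock-constrained shuffling problem
#'
#' A discrete, constrained, non-smooth benchmark: a random integer sequence in
#' which a random subset of positions is locked (immutable). The pseudo-energy
#' is the total adjacent dissimilarity `sum(|v_i - v_{i+1}|)`, so the optimum
#' is a sorted-as-possible arrangement of the free values around the locked
#' ones; the quality is its negation. The move rule swaps two uniformly chosen
#' unlocked positions, so locked positions are invariant by construction.
#'
#' @param seed Seed for the synthetic instance.
#' @param n Sequence length (>= 8).
#' @param n_locked Number of locked positions, `0 <= n_locked <= n/2`.
#' @param value_range Inclusive integer range the values are drawn from.
#' @return A list with `problem`, `k0` (the generated sequence), `data`
#'   (`NULL`), `sequence`, `locked_mask`.
#' @export
generate_shuffle <- function(seed, n = 8L, n_locked = 2L,
                             value_range = c(1L, 20L)) {
  stopifnot(n >= 8, n_locked >= 0, n_locked <= n / 2, length(value_range) == 2)
  gen <- with_stream(rng_stream(seed), {
    list(sequence = sample(seq(value_range[1], value_range[2]), n,
                           replace = TRUE),
         locked_at = sample.int(n, n_locked))
  })
  locked <- rep(FALSE, n)
  locked[gen$locked_at] <- TRUE
  free <- which(!locked)
  move <- function(k) {
    ij <- free[sample.int(length(free), 2L)]
    tmp <- k[ij[1]]
    k[ij[1]] <- k[ij[2]]
    k[ij[2]] <- tmp
    k
  }
  model <- function(k, data) k
  evaluate <- function(k, data) {
    e <- sum(abs(diff(k)))
    list(energy = e, quality = -e)
  }
  structure(list(problem = new_problem(move, model, evaluate),
                 k0 = gen$sequence, data = NULL,
                 sequence = gen$sequence, locked_mask = locked),
            class = c("shuffle_problem", "aropt_example"))
}

#' Exact optimum of a small shuffling instance by exhaustive enumeration
#'
#' Enumerates every arrangement of the free values over the free positions
#' (locked positions stay put) and returns the minimum adjacent-dissimilarity
#' energy. Intended as an independent oracle for instances with at most 8 free
#' positions (8! = 40320 arrangements).
#'
#' @param sp A [generate_shuffle()] instance.
#' @return `list(energy =, sequence =)` — the exact optimum.
#' @export
brute_force_shuffle_optimum <- function(sp) {
  stopifnot(inherits(sp, "shuffle_problem"))
  free <- which(!sp$locked_mask)
  if (length(free) > 8) {
    stop("brute force limited to <= 8 free positions", call. = FALSE)
  }
  if (!requireNamespace("e1071", quietly = TRUE)) {
    stop("the e1071 package is required for the brute-force oracle",
         call. = FALSE)
  }
  perms <- e1071::permutations(length(free))
  vals <- sp$sequence[free]
  best_e <- Inf
  best_s <- sp$sequence
  for (r in seq_len(nrow(perms))) {
    s <- sp$sequence
    s[free] <- vals[perms[r, ]]
    e <- sum(abs(diff(s)))
    if (e < best_e) {
      best_e <- e
      best_s <- s
    }
  }
  list(energy = best_e, sequence = best_s)
}

#' Analytic one-dimensional benchmark landscapes
#'
#' Two standard continuous test problems used throughout the package's own
#' diagnostics:
#'
#' * `"quadratic"`: `E(k) = k^2`, started at `k0 = 5`, Gaussian moves
#'   (default sd 0.5). A smooth bowl on which any target acceptance ratio is
#'   attainable — the reference landscape for acceptance-ratio tracking.
#' * `"double_well"`: `E(k) = (k^2 - 1)^2 + 0.3 k`, started in the shallower
#'   right-hand well at `k0 = 1`, narrow Gaussian moves (default sd 0.15).
#'   A rugged landscape with a barrier at `k = 0` separating the start from
#'   the global minimum near `k = -1.04`.
#'
#' @param name `"quadratic"` or `"double_well"`.
#' @param move_sd Override the default proposal standard deviation.
#' @return A list with `problem`, `k0`, `data` (`NULL`).
#' @export
benchmark_problem <- function(name = c("quadratic", "double_well"),
                              move_sd = NULL) {
  name <- match.arg(name)
  if (name == "quadratic") {
    sd <- if (is.null(move_sd)) 0.5 else move_sd
    energy <- function(k) k * k
    k0 <- 5
  } else {
    sd <- if (is.null(move_sd)) 0.15 else move_sd
    energy <- function(k) (k * k - 1)^2 + 0.3 * k
    k0 <- 1
  }
  stopifnot(sd > 0)
  move <- function(k) k + stats::rnorm(1L, 0, sd)
  model <- function(k, data) k
  evaluate <- function(k, data) {
    e <- energy(k)
    list(energy = e, quality = e)
  }
  list(problem = new_problem(move, model, evaluate), k0 = k0, data = NULL)
}

#' Look up a bundled example problem by name
#'
#' @param name One of `"polyfit"`, `"odefit"`, `"shuffle"`, `"quadratic"`,
#'   `"double_well"`.
#' @param seed Seed for the synthetic data (ignored by the analytic
#'   benchmarks).
#' @param ... Passed to the underlying generator.
#' @return A list with at least `problem`, `k0`, `data`.
#' @export
example_problem <- function(name = c("polyfit", "odefit", "shuffle",
                                     "quadratic", "double_well"),
                            seed = 1L, ...) {
  name <- match.arg(name)
  switch(name,
         polyfit = generate_polyfit(seed, ...),
         odefit = generate_odefit(seed, ...),
         shuffle = generate_shuffle(seed, ...),
         quadratic = benchmark_problem("quadratic", ...),
         double_well = benchmark_problem("double_well", ...))
}
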