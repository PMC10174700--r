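test_that("polynomial fit energy is exact on noiseless data", {
  pf <- generate_polyfit(seed = 1, noise_sd = 0)
  at <- function(k) pf$problem$evaluate(pf$problem$model(k, pf$data), pf$data)
  expect_equal(at(pf$true_coeffs)$energy, 0)
  # constant unit offset: RSS = n_points * 1^2
  expect_equal(at(pf$true_coeffs + c(1, 0, 0))$energy, length(pf$x_values))
  expect_equal(at(pf$true_coeffs)$quality, 0)
})

test_that("polynomial problems are reproducible from their seed", {
  expect_identical(generate_polyfit(3)$y_values, generate_polyfit(3)$y_values)
  expect_false(identical(generate_polyfit(3)$y_values,
                         generate_polyfit(4)$y_values))
})

test_that("the kinetic integrator matches the closed-form solution", {
  times <- c(0, 0.25, 0.5, 1, 2)
  s <- simulate_two_step_kinetics(1, 0.5, 1, times)
  expect_equal(s$A[1], 1)                        # initial condition A(0) = a0
  expect_equal(s$B[1], 0)
  expect_equal(s$A, exp(-times), tolerance = 1e-6)
  s2 <- simulate_two_step_kinetics(2, 1, 1, c(0, 1))
  expect_equal(s2$B[2], 2 * (exp(-1) - exp(-2)), tolerance = 1e-6)
  closed_B <- function(k1, k2, a0, t) a0 * k1 / (k2 - k1) *
    (exp(-k1 * t) - exp(-k2 * t))
  expect_equal(s$B, closed_B(1, 0.5, 1, times), tolerance = 1e-6)
  expect_error(simulate_two_step_kinetics(1, 1, 1, c(0, 0.1, 0.2),
                                          integrator_step = 0.5), "spacing")
  expect_error(simulate_two_step_kinetics(1, 1, 1, c(1, 2)), "start at 0")
})

test_that("kinetic fitting energy is zero at the truth and +Inf off the domain", {
  ode <- generate_odefit(seed = 2, noise_sd = 0)
  at <- function(k) ode$problem$evaluate(ode$problem$model(k, ode$data),
                                         ode$data)
  # truth simulated finer than the in-loop integrator: tiny but nonzero RSS
  expect_lt(at(c(ode$true_k1, ode$true_k2))$energy, 1e-8)
  expect_identical(at(c(-1, 0.3))$energy, Inf)
  expect_identical(at(c(1, 0))$energy, Inf)
  expect_identical(generate_odefit(9)$observed_A, generate_odefit(9)$observed_A)
})

test_that("log-normal rate moves never propose non-positive rates", {
  ode <- generate_odefit(seed = 2)
  ks <- with_stream(rng_stream(1),
                    replicate(100, ode$problem$move(c(0.01, 5))))
  expect_true(all(ks > 0))
})

test_that("shuffle energy is the adjacent dissimilarity and locks are immutable", {
  sp <- generate_shuffle(seed = 5, n = 8, n_locked = 2)
  ev <- function(k) sp$problem$evaluate(k, NULL)
  expect_equal(ev(c(1, 2, 3, 4, 5, 6, 7, 8))$energy, 7)
  expect_equal(ev(sp$k0)$quality, -ev(sp$k0)$energy)
  locked_vals <- sp$sequence[sp$locked_mask]
  moved <- with_stream(rng_stream(3),
                       replicate(200, sp$problem$move(sp$sequence)))
  expect_true(all(apply(moved, 2, function(k)
    identical(k[sp$locked_mask], locked_vals))))
  # every move is a transposition: the value multiset is conserved
  expect_true(all(apply(moved, 2, function(k)
    identical(sort(k), sort(sp$sequence)))))
})

test_that("annealing reaches the brute-force optimum of a small shuffle", {
  sp <- generate_shuffle(seed = 42, n = 8, n_locked = 2)
  opt <- brute_force_shuffle_optimum(sp)
  expect_lte(opt$energy, sp$problem$evaluate(sp$k0, NULL)$energy)
  cfg <- annealing_config(n_iterations_per_cycle = 2500, n_cycles = 2,
                          master_seed = 1)
  res <- run_sa(sp$problem, sp$k0, config = cfg)
  expect_equal(res$best_energy, opt$energy)
  # locked positions are invariant in the optimized configuration too
  expect_identical(res$best_k[sp$locked_mask], sp$sequence[sp$locked_mask])
})

test_that("example_problem dispatches to every bundled generator", {
  for (nm in c("polyfit", "odefit", "shuffle", "quadratic", "double_well")) {
    ex <- example_problem(nm, seed = 1)
    expect_s3_class(ex$problem, "aropt_problem")
    expect_true(validate_problem(ex$problem, ex$k0, ex$data, seed = 1)$ok)
  }
})
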