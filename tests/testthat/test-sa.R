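test_that("the linear target-AR regimen hits its endpoints and midpoint exactly", {
  expect_identical(target_ar_at_step(0, 101, 0.9, 0.1), 0.9)
  expect_identical(target_ar_at_step(100, 101, 0.9, 0.1), 0.1)
  expect_identical(target_ar_at_step(50, 101, 0.9, 0.1), 0.5)
  expect_identical(target_ar_at_step(0, 1, 0.9, 0.1), 0.9)  # one-step cycle
  expect_error(target_ar_at_step(101, 101, 0.9, 0.1), "step")
  expect_error(target_ar_at_step(-1, 101, 0.9, 0.1), "step")
})

test_that("annealing configs are validated", {
  expect_error(annealing_config(ar_initial = 0.1, ar_final = 0.9), "exceed")
  expect_error(annealing_config(n_iterations_per_cycle = 101, window_size = 20),
               "divide")
  expect_s3_class(annealing_config(), "annealing_config")
})

test_that("a single-window cycle targets ar_final and identity moves accept everything", {
  cfg <- annealing_config(n_iterations_per_cycle = 20, n_cycles = 1,
                          window_size = 20, master_seed = 1)
  st <- chain_init(identity_problem(), 1)
  cyc <- run_annealing_cycle(st, cfg, 1, identity_problem(),
                             rng = rng_stream(1))
  expect_equal(nrow(cyc$windows), 1L)
  expect_equal(cyc$windows$target_ar, cfg$ar_final)
  expect_equal(cyc$windows$observed_ar, 1)
})

test_that("seed fan-out is deterministic and pairwise distinct", {
  s1 <- fan_out_seeds(7, 8)
  s2 <- fan_out_seeds(7, 8)
  expect_identical(s1, s2)
  expect_length(s1, 8)
  expect_false(anyDuplicated(s1) > 0)
  expect_length(fan_out_seeds(7, 1), 1)
  expect_false(identical(fan_out_seeds(8, 8), s1))
})

test_that("run_sa with one run returns that run's best", {
  ex <- benchmark_problem("quadratic")
  cfg <- annealing_config(n_iterations_per_cycle = 200, n_cycles = 1,
                          master_seed = 5)
  res <- run_sa(ex$problem, ex$k0, config = cfg)
  expect_equal(res$best_energy, res$per_run_bests$best_energy[1])
  expect_equal(res$best_energy, min(res$traces[[1]]$best_energy))
  expect_equal(res$best_energy, res$best_k^2)
})

test_that("the overall best is the minimum across parallel runs", {
  ex <- benchmark_problem("quadratic")
  cfg <- annealing_config(n_iterations_per_cycle = 200, n_cycles = 1,
                          master_seed = 5, n_parallel_runs = 3)
  res <- run_sa(ex$problem, ex$k0, config = cfg)
  expect_equal(nrow(res$per_run_bests), 3L)
  expect_equal(res$best_energy, min(res$per_run_bests$best_energy))
})

test_that("identical seeds replay identical runs", {
  ex <- benchmark_problem("quadratic")
  cfg <- annealing_config(n_iterations_per_cycle = 200, n_cycles = 2,
                          master_seed = 17, n_parallel_runs = 2)
  r1 <- run_sa(ex$problem, ex$k0, config = cfg)
  r2 <- run_sa(ex$problem, ex$k0, config = cfg)
  expect_identical(r1$traces, r2$traces)
  expect_identical(r1$per_run_bests, r2$per_run_bests)
})

test_that("concurrent and sequential execution give identical results", {
  ex <- benchmark_problem("quadratic")
  cfg <- annealing_config(n_iterations_per_cycle = 200, n_cycles = 1,
                          master_seed = 23, n_parallel_runs = 3)
  seq_res <- run_sa(ex$problem, ex$k0, config = cfg, parallel = FALSE)
  par_res <- run_sa(ex$problem, ex$k0, config = cfg, parallel = TRUE, cores = 2)
  expect_identical(seq_res$traces, par_res$traces)
  expect_identical(seq_res$best_k, par_res$best_k)
})

test_that("cycle restarts re-impose a high target AR and force reheating", {
  ex <- benchmark_problem("quadratic")
  hits <- 0L
  for (seed in 1:5) {
    cfg <- annealing_config(n_iterations_per_cycle = 400, n_cycles = 2,
                            window_size = 20, master_seed = seed)
    res <- run_sa(ex$problem, ex$k0, config = cfg)
    w <- res$windows[[1]]
    t_end_c1 <- w$temperature_used[w$cycle == 1][sum(w$cycle == 1)]
    t_c2 <- w$temperature_used[w$cycle == 2][1:5]
    if (any(t_c2 > t_end_c1)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("the SA trace table carries the canonical column layout", {
  ex <- benchmark_problem("quadratic")
  cfg <- annealing_config(n_iterations_per_cycle = 40, n_cycles = 1,
                          master_seed = 2)
  res <- run_sa(ex$problem, ex$k0, config = cfg)
  expect_identical(names(res$traces[[1]]),
                   c("step", "cycle", "window", "replica", "temperature",
                     "target_ar", "proposal_energy", "accepted",
                     "current_energy", "best_energy", "best_quality"))
  expect_identical(res$traces[[1]]$step, 1:40)
})
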