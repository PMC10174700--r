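test_that("exchange configs are validated", {
  expect_error(exchange_config(ar_values = 0.5), "at least 2")
  expect_error(exchange_config(ar_values = c(0.5, 0.5)), "distinct")
  expect_error(exchange_config(ar_values = c(0.1, 0.5)), "decreasing")
  expect_error(exchange_config(ar_values = c(0.5, 0.1),
                               n_iterations_total = 101, window_size = 20),
               "divide")
  expect_s3_class(exchange_config(), "exchange_config")
})

test_that("replicas are initialised per AR value with independent streams", {
  ex <- benchmark_problem("quadratic")
  cfg <- exchange_config(ar_values = c(0.5, 0.1), n_iterations_total = 100,
                         window_size = 20, master_seed = 9)
  reps <- init_replicas(cfg, ex$k0, ex$problem)
  expect_length(reps, 2)
  expect_identical(vapply(reps, `[[`, 0L, "replica_id"), c(0L, 1L))
  expect_identical(vapply(reps, `[[`, 0, "target_ar"), c(0.5, 0.1))
  expect_false(identical(reps[[1]]$seed, reps[[2]]$seed))
  # same master seed twice -> identical initial streams
  reps2 <- init_replicas(cfg, ex$k0, ex$problem)
  expect_identical(with_stream(reps[[1]]$rng, runif(3)),
                   with_stream(reps2[[1]]$rng, runif(3)))
})

test_that("exchange pairs are uniform over adjacent pairs only", {
  expect_identical(select_exchange_pair(2, rng_stream(1)), c(1L, 2L))
  r <- rng_stream(4)
  draws <- replicate(300, select_exchange_pair(3, r)[1])
  expect_true(all(draws %in% c(1L, 2L)))           # never the (1, 3) pair
  r <- rng_stream(11)
  n <- 10000
  first <- replicate(n, select_exchange_pair(5, r)[1])
  freq <- tabulate(first, 4) / n
  se3 <- 3 * sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(freq - 0.25) < se3))
  expect_error(select_exchange_pair(1), ">= 2")
})

test_that("exchange swaps configurations, is an involution, and conserves the multiset", {
  ex <- benchmark_problem("quadratic")
  cfg <- exchange_config(ar_values = c(0.5, 0.1), n_iterations_total = 100,
                         window_size = 20, master_seed = 2)
  reps <- init_replicas(cfg, ex$k0, ex$problem)
  # diverge the chains first
  for (i in 1:2) {
    reg <- regulate_window(reps[[i]]$chain, 1, reps[[i]]$target_ar, 20,
                           ex$problem, rng = reps[[i]]$rng)
    reps[[i]]$chain <- reg$state
  }
  before <- lapply(reps, function(r)
    list(r$chain$current_k, r$chain$current_energy, r$chain$current_quality,
         r$chain$best_energy, r$replica_id, r$target_ar))
  sw <- perform_exchange(reps[[1]], reps[[2]])
  expect_identical(sw$a$chain$current_k, before[[2]][[1]])
  expect_identical(sw$b$chain$current_k, before[[1]][[1]])
  expect_identical(sw$a$chain$current_energy, before[[2]][[2]])
  # identity, target AR and best records stay with their replicas
  expect_identical(sw$a$replica_id, before[[1]][[5]])
  expect_identical(sw$a$target_ar, before[[1]][[6]])
  expect_identical(sw$a$chain$best_energy, before[[1]][[4]])
  # multiset of (configuration, energy) pairs conserved
  after <- list(list(sw$a$chain$current_k, sw$a$chain$current_energy),
                list(sw$b$chain$current_k, sw$b$chain$current_energy))
  before_pairs <- lapply(before[1:2], function(x) x[1:2])
  expect_true(all(vapply(after, function(p)
    any(vapply(before_pairs, identical, logical(1), p)), logical(1))))
  # involution
  sw2 <- perform_exchange(sw$a, sw$b)
  expect_identical(sw2$a$chain$current_k, before[[1]][[1]])
  expect_identical(sw2$b$chain$current_k, before[[2]][[1]])
  expect_error(perform_exchange(sw$a, sw$a), "itself")
})

test_that("a period longer than the run degenerates to independent fixed-AR chains", {
  ex <- benchmark_problem("quadratic")
  cfg <- exchange_config(ar_values = c(0.5, 0.1), n_iterations_total = 200,
                         window_size = 20, exchange_period_windows = 1000,
                         master_seed = 31)
  res <- run_re(ex$problem, ex$k0, config = cfg)
  expect_equal(nrow(res$exchange_log), 0L)
  # replica 0's trajectory equals a manual fixed-AR thermoregulated chain
  # driven by the same stream
  reps <- init_replicas(cfg, ex$k0, ex$problem)
  st <- reps[[1]]$chain
  t_cur <- reps[[1]]$temperature
  for (w in 1:10) {
    reg <- regulate_window(st, t_cur, 0.5, 20, ex$problem,
                           rng = reps[[1]]$rng)
    st <- reg$state
    t_cur <- reg$temperature
  }
  expect_identical(res$final_states[[1]]$chain, st)
  expect_equal(res$best_energy, min(res$per_run_bests$best_energy))
})

test_that("identity-move replicas exchange equal states and keep the initial energy", {
  cfg <- exchange_config(ar_values = c(0.5, 0.1), n_iterations_total = 200,
                         window_size = 20, exchange_period_windows = 2,
                         master_seed = 6)
  res <- run_re(identity_problem(), 3, config = cfg)
  expect_gt(nrow(res$exchange_log), 0L)
  expect_equal(res$best_energy, 3)
  expect_true(all(res$traces[[1]]$accepted))
})

test_that("replica exchange replays byte-identically under a fixed master seed", {
  ex <- benchmark_problem("double_well")
  cfg <- exchange_config(ar_values = c(0.6, 0.3, 0.1), n_iterations_total = 400,
                         window_size = 20, exchange_period_windows = 3,
                         master_seed = 12)
  r1 <- run_re(ex$problem, ex$k0, config = cfg)
  r2 <- run_re(ex$problem, ex$k0, config = cfg)
  expect_identical(r1$traces, r2$traces)
  expect_identical(r1$exchange_log, r2$exchange_log)
})

test_that("hotter (higher-target-AR) replicas hold higher time-averaged temperatures", {
  ex <- benchmark_problem("quadratic")
  hits <- 0L
  for (seed in 1:5) {
    cfg <- exchange_config(ar_values = c(0.5, 0.1), n_iterations_total = 1000,
                           window_size = 20, exchange_period_windows = 5,
                           master_seed = seed)
    res <- run_re(ex$problem, ex$k0, config = cfg)
    t0 <- mean(log10(res$windows[[1]]$temperature_used))
    t1 <- mean(log10(res$windows[[2]]$temperature_used))
    if (t0 > t1) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
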