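test_that("replication allocation sums exactly and follows the shape", {
  expect_equal(allocate_replications(2000, 10, "equal"), rep(200L, 10))
  inc <- allocate_replications(2000, 10, "increasing")
  expect_equal(sum(inc), 2000L)
  expect_true(all(diff(inc) >= 0))
  expect_equal(allocate_replications(10, 2, "u_shaped"), c(5L, 5L))
  u <- allocate_replications(1000, 9, "u_shaped")
  expect_equal(sum(u), 1000L)
  # symmetric around the middle step, apart from the remainder on the last
  expect_equal(u[2:4], rev(u[6:8]))
  expect_lt(u[5], u[1])
  expect_error(allocate_replications(5, 10), "at least")
})

test_that("size draws stay in bounds and are symmetric in expectation", {
  expect_equal(draw_sizes(100, 100, 5), rep(100L, 5))
  s <- draw_sizes(50, 150, 1e4, seed = 3)
  expect_true(all(s >= 50 & s <= 150))
  se <- sqrt((150 - 50 + 1)^2 / 12 / 1e4)
  expect_lt(abs(mean(s) - 100), 3 * se)
  expect_error(draw_sizes(10, 5, 3), "n_min")
})

test_that("artificial backend matches its generating curve", {
  be <- make_artificial_backend(-1.64, 0.2)
  ev <- be$eval(rep(616L, 2e4), seeds = 42L)
  p_hat <- mean(ev$records$poi)
  p_true <- pnorm(-1.64 + 0.2 * sqrt(616))
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 2e4))
  # zero slope: constant probability
  be0 <- make_artificial_backend(0, 0)
  ev0 <- be0$eval(rep(100L, 2e4), seeds = 1L)
  expect_lt(abs(mean(ev0$records$poi) - 0.5), 0.02)
})

test_that("brute force reproduces a systematic grid and inverts the curve", {
  be <- make_artificial_backend(-1.64, 0.2)
  cfg <- search_config(R = 2000, n_min = 140, n_max = 1139,
                       draw = "systematic", reps_per_size = 2L, seed = 5)
  res <- run_brute_force(be, cfg)
  expect_s3_class(res, "mspe_result")
  ns <- res$records$n
  expect_equal(length(ns), 2000L)
  expect_true(all(table(ns) == 2L))      # 1000 grid points, 2 each
  expect_equal(min(ns), 140)
  expect_equal(max(ns), 1139)
  expect_equal(unique(diff(sort(unique(ns)))), 1)
  # the inversion lands near the generating target of 154
  expect_lt(abs(res$N_alpha_overall - 154), 25)
  expect_gte(res$N_lb_overall, res$N_alpha_overall)
  expect_error(run_brute_force(be, search_config(R = 100, n_min = 300,
                                                 n_max = 100, seed = 1)),
               "n_min")
})

test_that("adaptive search respects bounds, budget and accumulation", {
  be <- make_artificial_backend(-1.64, 0.2)
  cfg <- search_config(R = 3000, n_lb = 50, n_start = 150, seed = 17)
  res <- run_adaptive(be, cfg)
  h <- res$step_history
  expect_equal(nrow(h), 10L)
  expect_equal(sum(h$R_j), 3000L)
  expect_equal(nrow(res$records), 3000L)
  expect_true(all(res$records$n >= 50))
  # with constrained change, endpoints move at most a factor of 2 per step
  expect_true(all(h$n_min[-1] >= h$n_min[-10] / 2 - 1e-9))
  expect_true(all(h$n_max[-1] <= h$n_max[-10] * 2 + 1e-9))
  # narrow steps concentrate near the target sample size
  expect_lt(h$n_max[10] - h$n_min[10], h$n_max[1] - h$n_min[1])
  expect_lt(abs(res$N_alpha_overall - 154), 20)
})

test_that("search results are bit-identical across repeated runs", {
  be <- make_artificial_backend(-1.64, 0.1)
  cfg <- search_config(R = 1000, seed = 23)
  r1 <- run_adaptive(be, cfg)
  r2 <- run_adaptive(be, cfg)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$N_lb_overall, r2$N_lb_overall)
  expect_identical(r1$step_history, r2$step_history)
})

test_that("early separation falls back to interval widening", {
  # a huge starting size makes step-1 decisions all significant; the driver
  # must widen and still finish once lower sizes appear
  be <- make_artificial_backend(-1.64, 0.2)
  cfg <- search_config(R = 2000, n_start = 5000, n_lb = 10, seed = 31)
  res <- run_adaptive(be, cfg)
  expect_s3_class(res, "mspe_result")
  expect_lt(res$N_alpha_overall, 400)
})
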