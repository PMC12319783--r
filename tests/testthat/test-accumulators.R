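test_that("stochastic accumulator: zero-input and noise-free limits", {
  grid <- time_grid(duration = 5)

  # no drift, no noise: the state never leaves zero
  run0 <- simulate_stochastic(stochastic_params(I = 0, c = 0), grid, seed = 1)
  expect_true(all(run0$trace == 0))
  expect_true(is.na(run0$crossing_time))

  # noise off at the study drift/leak: trace follows the closed form of the
  # discrete recursion, converges monotonically toward I/k = 0.22, and never
  # reaches the 0.298 threshold
  p <- stochastic_params(c = 0)
  run <- simulate_stochastic(p, time_grid(duration = 20), seed = 1)
  cf <- leaky_closed_form(p$I, p$k, 0.001, 20000)
  expect_lt(max(abs(run$trace - cf) / cf), 1e-8)
  expect_true(all(diff(run$trace) > 0))
  expect_lt(max(run$trace), p$I / p$k)
  expect_true(is.na(run$crossing_time))
})

test_that("stochastic accumulator is reproducible and rejects bad input", {
  grid <- time_grid(duration = 2)
  a <- simulate_stochastic(stochastic_params(), grid, seed = 7)
  b <- simulate_stochastic(stochastic_params(), grid, seed = 7)
  expect_identical(a$trace, b$trace)
  expect_identical(a$crossing_time, b$crossing_time)
  c <- simulate_stochastic(stochastic_params(), grid, seed = 8)
  expect_false(identical(a$trace, c$trace))
  expect_error(stochastic_params(I = NaN), "finite")
  expect_error(stochastic_params(threshold = 0), ">")
})

test_that("classic model: noise-free ramp crosses at onset + threshold/input", {
  grid <- time_grid(duration = 20)
  p <- classic_params(step_noise_sd = 0, input_low = 1, input_high = 1)
  run <- simulate_classic(p, grid, seed = 42)
  expect_false(is.na(run$onset_time))
  # linear rise at unit input: crossing = t_on + threshold (within grid step)
  expect_equal(run$crossing_time, run$onset_time + p$threshold,
               tolerance = 2 * grid$dt / run$crossing_time)
  # state is flat zero before the onset
  pre <- run$trace[seq_len(floor(run$onset_time / grid$dt) - 1)]
  expect_true(all(pre == 0))

  # onset sampled beyond the grid: flat zero trace, run returned uncrossed
  p_late <- classic_params(step_noise_sd = 0, onset_scale = 1000)
  run_late <- simulate_classic(p_late, time_grid(duration = 2), seed = 1)
  expect_true(is.na(run_late$crossing_time))
  expect_true(all(run_late$trace == 0))
})

test_that("classic model crossings follow t_on + threshold/I run-for-run", {
  # with per-step noise silenced the simulated crossing must reproduce the
  # analytic map of the sampled onset and input strength, seed for seed
  grid <- time_grid(duration = 30)
  p <- classic_params(step_noise_sd = 0)
  seeds <- derive_seeds(123, 200, salt = 1L)
  for (s in seeds[1:25]) {
    run <- simulate_classic(p, grid, seed = s)
    set.seed(s)
    t_on <- rgamma(1, shape = 4, scale = 1)
    input <- runif(1, 0.25, 1.25)
    expect_equal(run$onset_time, t_on)
    expect_equal(run$crossing_time, t_on + p$threshold / input,
                 tolerance = 3 * grid$dt)
  }
})

test_that("LBA: boundary start, linear closed form, and waiting-time distribution", {
  grid <- time_grid(duration = 20)
  # starting point at the bound: crossing when accumulation begins
  p_at <- lba_params(start_low = 4000, start_high = 4000)
  run_at <- simulate_lba(p_at, grid, seed = 3)
  expect_equal(run_at$crossing_time, 2.5)

  # deterministic slope and start: crossing = delay + (b - x0)/slope
  p_det <- lba_params(slope_mean = 2, slope_sd = 0,
                      start_low = 1000, start_high = 1000)
  run_det <- simulate_lba(p_det, grid, seed = 4)
  expect_equal(run_det$crossing_time, 2.5 + (4000 - 1000) / 2 / 1000,
               tolerance = 2e-3)

  # defaults: crossing-time distribution matches direct sampling of
  # delay + (b - x0)/slope with a positive-truncated normal slope
  batch <- simulate_batch("lba", lba_params(), grid, 4000, seed = 9)
  sim <- batch$crossing_time[!is.na(batch$crossing_time)]
  set.seed(99)
  slope <- rnorm(40000, 2, 1)
  slope <- slope[slope > 0][1:20000]
  x0 <- runif(20000, 0, 4000)
  oracle <- 2.5 + (4000 - x0) / slope / 1000
  oracle <- oracle[oracle <= 20]
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  expect_equal(quantile(sim, qs), quantile(oracle, qs), tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("pink-noise model: noise-off limit, stored input, and determinism", {
  grid <- time_grid(duration = 5)
  p0 <- pink_params(accumulator = stochastic_params(c = 0))
  run0 <- simulate_pink(p0, grid, seed = 2, keep_state = TRUE)
  cf <- leaky_closed_form(0.11, 0.5, grid$dt, grid$n_steps)
  expect_lt(max(abs(run0$state - cf) / cf), 1e-8)

  a <- simulate_pink(pink_params(), grid, seed = 11)
  b <- simulate_pink(pink_params(), grid, seed = 11)
  expect_identical(a$trace, b$trace)
  expect_identical(a$crossing_time, b$crossing_time)
  # the stored trace is the 1/f input, not the accumulator state
  expect_gt(sd(a$trace), 0.5)
})

test_that("pink-noise input has the configured 1/f spectral slope", {
  grid <- time_grid(duration = 20)
  batch <- simulate_batch("pink", pink_params(), grid, 50, seed = 21)
  exps <- apply(batch$traces, 2, psd_fit)
  expect_lt(abs(mean(exps) - 1.5), 0.2)
})

test_that("first-crossing correctness holds on every simulated run", {
  grid <- time_grid(duration = 10)
  for (model in c("stochastic", "classic", "lba")) {
    params <- switch(model, stochastic = stochastic_params(),
                     classic = classic_params(), lba = lba_params())
    batch <- simulate_batch(model, params, grid, 40, seed = 31)
    thr <- if (model == "lba") params$threshold else params$threshold
    for (i in which(!is.na(batch$crossing_time))) {
      idx <- round(batch$crossing_time[i] / grid$dt)
      expect_gte(batch$traces[idx, i], thr)
      if (model != "lba") {
        expect_true(all(batch$traces[seq_len(idx - 1), i] < thr))
      }
    }
  }
})

test_that("batches are reproducible and consistent with single runs", {
  grid <- time_grid(duration = 3)
  b1 <- simulate_batch("stochastic", stochastic_params(), grid, 1, seed = 5)
  single <- simulate_stochastic(stochastic_params(), grid,
                                seed = derive_seeds(5, 1, salt = 1L))
  expect_identical(b1$traces[, 1], single$trace)
  expect_identical(b1$crossing_time[1], single$crossing_time)

  b2 <- simulate_batch("stochastic", stochastic_params(), grid, 50, seed = 5)
  b3 <- simulate_batch("stochastic", stochastic_params(), grid, 50, seed = 5)
  expect_identical(b2$traces, b3$traces)
  expect_identical(tidy(b2), tidy(b3))
})

test_that("increment autocorrelation separates white-noise and 1/f input", {
  grid <- time_grid(duration = 10)
  sto <- simulate_batch("stochastic", stochastic_params(), grid, 20, seed = 41)
  ac_sto <- mean(apply(diff(sto$traces), 2,
                       function(d) cor(d[-1], d[-length(d)])))
  pink <- simulate_batch("pink", pink_params(), grid, 20, seed = 41)
  ac_pink <- mean(apply(pink$traces, 2,
                        function(p) cor(p[-1], p[-length(p)])))
  expect_lt(abs(ac_sto), 0.05)   # near-white increments
  expect_gt(ac_pink, 0.5)        # strongly autocorrelated input
})
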