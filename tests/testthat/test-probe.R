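test_that("probe times respect the shifted-gamma schedule", {
  sch <- probe_schedule(shift = 2)
  draws <- draw_probe_time(sch, 20000, seed = 1)
  expect_true(all(draws > 2))
  # gamma(4, 0.75) mean = 3: sample mean within Monte-Carlo error of 5
  expect_equal(mean(draws), 5, tolerance = 0.02)
  expect_identical(draw_probe_time(sch, 5, seed = 9),
                   draw_probe_time(sch, 5, seed = 9))
})

test_that("outcome categorization follows the probe/crossing taxonomy", {
  expect_identical(categorize_outcome(4.0, 5.0), "Movement")
  expect_identical(categorize_outcome(5.1, 5.0, fti_window = 0.2), "FTI")
  expect_identical(categorize_outcome(NA_real_, 5.0), "ProbeTrial")
  expect_identical(categorize_outcome(5.4, 5.0, fti_window = 0.2), "ProbeTrial")
  # boundary: crossing exactly at the probe is a failure to inhibit
  expect_identical(categorize_outcome(5.0, 5.0), "FTI")
  expect_error(categorize_outcome(3, probe_time = 19.9, duration = 20),
               "FTI window")

  # partition is exhaustive/exclusive over random inputs, and enlarging the
  # FTI window never decreases the FTI count
  set.seed(5)
  crossing <- ifelse(runif(500) < 0.1, NA, runif(500, 0, 20))
  probe <- runif(500, 2, 8)
  prev <- 0
  for (w in c(0, 0.1, 0.2, 0.5)) {
    out <- categorize_outcome(crossing, probe, fti_window = w)
    expect_true(all(out %in% c("Movement", "FTI", "ProbeTrial")))
    expect_length(out, 500)
    expect_gte(sum(out == "FTI"), prev)
    prev <- sum(out == "FTI")
  }
})

test_that("percentile splits give exact, stable label counts", {
  cfg <- reporting_config("single_stage")
  trials <- tibble::tibble(run = 1:1000, amplitude_at_probe = sample(rnorm(1000)))
  lab <- single_stage_report(trials, cfg)
  expect_identical(as.integer(table(lab$report)[c("NoPrep", "Unsure", "Prep")]),
                   c(532L, 114L, 354L))

  # all-tied feature values: counts unchanged, assignment deterministic
  tied <- tibble::tibble(run = 1:1000, amplitude_at_probe = rep(1, 1000))
  lab_t1 <- single_stage_report(tied, cfg)
  lab_t2 <- single_stage_report(tied, cfg)
  expect_identical(lab_t1$report, lab_t2$report)
  expect_identical(as.integer(table(lab_t1$report)[c("NoPrep", "Unsure", "Prep")]),
                   c(532L, 114L, 354L))
  expect_identical(lab_t1$report[1:532], rep("NoPrep", 532))

  # 50/0/50 equals an independent median split
  cfg5 <- reporting_config("single_stage", splits = c(50, 0, 50))
  set.seed(2)
  vals <- rnorm(401)
  lab5 <- single_stage_report(
    tibble::tibble(run = seq_along(vals), amplitude_at_probe = vals), cfg5)
  med <- median(vals)
  expect_identical(lab5$report[vals < med][1:200], rep("NoPrep", 200))
  expect_true(all(lab5$report[vals > med] == "Prep"))

  expect_error(single_stage_report(trials[0, ], cfg), "No probe trials")
  expect_error(reporting_config(splits = c(50, 10, 50)), "sum to 100")
})

test_that("dual-stage slopes and labels match naive per-trial regression", {
  grid <- time_grid(duration = 10)
  rc <- reporting_config("dual_stage", fti_window = 0)
  tr <- run_experiment("stochastic", rc, grid = grid, n_runs = 300, seed = 14,
                       keep_batch = TRUE)
  batch <- attr(tr, "batch")
  probe <- which(tr$outcome == "ProbeTrial")
  idx <- probe[1:25]
  naive <- sapply(idx, function(i)
    slope_oracle_lm(batch$traces[, i], tr$probe_time[i], grid$dt))
  expect_equal(tr$post_probe_slope[idx], naive, tolerance = 1e-10)

  keep <- probe[!is.na(tr$post_probe_slope[probe])]
  expect_identical(tr$report[keep],
                   split_oracle(tr$post_probe_slope[keep]))
})

test_that("exact linear and flat traces give exact dual-stage slopes", {
  # one linear trace and one flat trace, probed mid-run
  dt <- 0.01
  n <- 500
  traces <- cbind(3 * (1:n) * dt, rep(2, n))
  slopes <- probeacc:::post_probe_slopes(traces, probe_time = c(2, 2),
                                         cols = 1:2, dt = dt, window = 0.5)
  expect_equal(slopes, c(3, 0), tolerance = 1e-10)
})

test_that("random reporting respects splits and the seed", {
  trials <- tibble::tibble(run = 1:200, amplitude_at_probe = rnorm(200))
  all_np <- random_report(trials, reporting_config("random",
                                                   splits = c(100, 0, 0)),
                          seed = 1)
  expect_true(all(all_np$report == "NoPrep"))
  r1 <- random_report(trials, reporting_config("random"), seed = 4)
  r2 <- random_report(trials, reporting_config("random"), seed = 4)
  expect_identical(r1$report, r2$report)
  expect_identical(sort(as.integer(table(r1$report))), sort(c(22L, 72L, 106L)))
})

test_that("classic-onset reporting keys on the input onset, ties to Prep", {
  trials <- tibble::tibble(run = 1:3, probe_time = c(3, 4.5, 4),
                           onset_time = c(4, 4, 4))
  lab <- classic_onset_report(trials)
  expect_identical(lab$report, c("NoPrep", "Prep", "Prep"))
  bad <- tibble::tibble(run = 1, probe_time = 3, onset_time = NA_real_)
  expect_error(classic_onset_report(bad), "onset_time")
  expect_error(run_experiment("stochastic", reporting_config("classic_onset"),
                              n_runs = 2, seed = 1), "classic model")
})

test_that("run_experiment categorizes, labels, and reproduces", {
  # deterministic LBA crossing at 4 s, probes always later: all Movement
  p <- lba_params(slope_mean = 2, slope_sd = 0, start_low = 1000,
                  start_high = 1000)
  tr <- run_experiment("lba", reporting_config("single_stage"), params = p,
                       schedule = probe_schedule(shift = 6),
                       grid = time_grid(duration = 20), n_runs = 10, seed = 2)
  expect_true(all(tr$outcome == "Movement"))
  expect_true(all(tr$report == "none"))

  # classic model: Prep fraction among labeled probe trials equals the
  # fraction recomputed directly from stored onset and probe times
  trc <- run_experiment("classic", reporting_config("classic_onset"),
                        grid = time_grid(duration = 20), n_runs = 800,
                        seed = 3)
  probe <- trc[trc$outcome == "ProbeTrial", ]
  expect_identical(probe$report,
                   ifelse(probe$probe_time < probe$onset_time,
                          "NoPrep", "Prep"))

  # outcome partition accounts for every run
  expect_identical(nrow(trc), 800L)
  expect_true(all(table(trc$outcome) >= 0))
  expect_identical((trc$report != "none"), (trc$outcome == "ProbeTrial"))

  # same master seed reproduces every label
  tr1 <- run_experiment("stochastic", reporting_config("dual_stage"),
                        grid = time_grid(duration = 8), n_runs = 150, seed = 4)
  tr2 <- run_experiment("stochastic", reporting_config("dual_stage"),
                        grid = time_grid(duration = 8), n_runs = 150, seed = 4)
  expect_identical(tr1, tr2)
})

test_that("alternative reporting models relabel the same runs", {
  tr <- run_experiment("stochastic", reporting_config("single_stage",
                                                      fti_window = 0),
                       grid = time_grid(duration = 8), n_runs = 200, seed = 6,
                       keep_batch = TRUE)
  dual <- apply_reporting(tr, reporting_config("dual_stage", fti_window = 0))
  expect_identical(dual$crossing_time, tr$crossing_time)
  probe <- which(tr$outcome == "ProbeTrial" & !is.na(tr$post_probe_slope))
  expect_identical(dual$report[probe],
                   split_oracle(tr$post_probe_slope[probe]))

  # single-stage behavioral direction: reported preparation is more likely
  # the later the probe (amplitude grows toward threshold on average)
  trs <- run_experiment("stochastic", reporting_config("single_stage",
                                                       fti_window = 0),
                        n_runs = 2500, seed = 8, keep_batch = TRUE)
  f <- probe_features(trs)
  expect_gt(mean(f$probe_time[f$report == "Prep"]),
            mean(f$probe_time[f$report == "NoPrep"]))
})
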