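test_that("degenerate hierarchy reproduces ordinary least squares", {
  tab <- balanced_table(c(A = 1, B = 3, C = -2), n_participants = 6,
                        reps = 8, noise_sd = 1, seed = 2)
  fit <- fit_linear_random_intercept(tab, "y")
  ols <- lm(y ~ condition, data = tab)
  expect_equal(unname(tidy(fit)$estimate), unname(coef(ols)),
               tolerance = 1e-6)
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("marginal means are estimable exactly on noise-free balanced data", {
  means <- c(A = 1.5, B = -0.25, C = 0, D = 4)
  tab <- balanced_table(means, n_participants = 5, reps = 4, noise_sd = 0)
  fit <- suppressMessages(fit_linear_random_intercept(tab, "y"))
  got <- setNames(fit$means$emmean, as.character(fit$means$condition))
  expect_equal(got[names(means)], means, tolerance = 1e-8)
  # every pairwise contrast equals the difference of marginal means
  ph <- posthoc_pairwise(fit, "tukey")
  for (i in seq_len(nrow(ph))) {
    parts <- strsplit(ph$contrast[i], " - ")[[1]]
    expect_equal(ph$estimate[i], got[[parts[1]]] - got[[parts[2]]],
                 tolerance = 1e-8)
  }
})

test_that("post hoc machinery: counts, 2-level identity, corrections", {
  tab4 <- balanced_table(c(A = 0, B = 1, C = 2, D = 3), reps = 6,
                         noise_sd = 0.8, seed = 5)
  fit4 <- fit_linear_random_intercept(tab4, "y")
  ph <- posthoc_pairwise(fit4, "tukey")
  expect_identical(nrow(ph), 6L)            # 4 choose 2
  expect_true(all(ph$p.corrected >= ph$p.raw - 1e-12))
  ph_fdr <- posthoc_pairwise(fit4, "fdr")
  expect_true(all(ph_fdr$p.corrected >= ph_fdr$p.raw - 1e-12))
  expect_error(posthoc_pairwise(fit4, "bonferroni"), "arg")

  tab2 <- balanced_table(c(A = 0, B = 0.5), reps = 10, noise_sd = 1, seed = 6)
  fit2 <- fit_linear_random_intercept(tab2, "y")
  ph2t <- posthoc_pairwise(fit2, "tukey")
  ph2f <- posthoc_pairwise(fit2, "fdr")
  expect_equal(ph2t$p.corrected, ph2t$p.raw, tolerance = 1e-10)
  expect_equal(ph2f$p.corrected, ph2f$p.raw, tolerance = 1e-12)

  # Benjamini-Hochberg step-up on a known p-vector, against hand computation:
  # sorted p * n / rank, cumulative minimum from the largest rank
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               c(0.04, 0.04, 0.04, 0.04))
  expect_error(fit_linear_random_intercept(tab2[tab2$condition == "A", ], "y"),
               "2 condition levels")
})

test_that("interaction model recovers per-condition slopes from exact lines", {
  tab <- expand.grid(participant = sprintf("P%d", 1:4),
                     condition = c("slow", "fast"),
                     stringsAsFactors = FALSE)
  tab <- tab[rep(seq_len(nrow(tab)), each = 11), ]
  tab$time <- rep(seq(-1, 0, by = 0.1), times = 8)
  tab$y <- ifelse(tab$condition == "slow", -0.5, -2) * tab$time + 1
  fit <- suppressMessages(
    fit_linear_with_interaction(tab, "y", time = "time"))
  sl <- setNames(fit$slopes$time.trend, as.character(fit$slopes$condition))
  expect_equal(sl[["slow"]], -0.5, tolerance = 1e-6)
  expect_equal(sl[["fast"]], -2, tolerance = 1e-6)
})

test_that("interaction model separates equal and different generated slopes", {
  make_lines <- function(d, seed) {
    set.seed(seed)
    grid <- expand.grid(participant = sprintf("P%d", 1:10),
                        condition = c("a", "b"), trial = 1:12,
                        stringsAsFactors = FALSE)
    out <- grid[rep(seq_len(nrow(grid)), each = 6), ]
    out$time <- rep(seq(-1, 0, by = 0.2), times = nrow(grid))
    base_slope <- -0.6
    out$y <- (base_slope + ifelse(out$condition == "b", d, 0)) * out$time +
      rnorm(nrow(out), 0, 0.3)
    out
  }
  null_fit <- fit_linear_with_interaction(make_lines(0, 1), "y", time = "time")
  ctr <- null_fit$contrasts
  expect_lt(abs(ctr$estimate[1]) / ctr$SE[1], 2.5)
  eff_fit <- fit_linear_with_interaction(make_lines(-1, 2), "y", time = "time")
  ctr2 <- eff_fit$contrasts
  expect_lt(abs(abs(ctr2$estimate[1]) - 1) / ctr2$SE[1], 3)
})

test_that("logistic random-slope model: null and recovery behaviour", {
  set.seed(9)
  n <- 1500
  tab <- data.frame(participant = sample(sprintf("P%d", 1:15), n, TRUE),
                    timeprobe = runif(n, 2, 8))
  tab$isprep <- rbinom(n, 1, 0.4)           # no time dependence
  null_fit <- suppressMessages(fit_logistic_random_slope(tab))
  sl <- tidy(null_fit)
  expect_lt(abs(sl$statistic[sl$term == "timeprobe"]), 2.5)

  beta <- 0.5
  tab$isprep <- rbinom(n, 1, plogis(-2 + beta * tab$timeprobe))
  rec <- suppressMessages(fit_logistic_random_slope(tab))
  row <- tidy(rec)[tidy(rec)$term == "timeprobe", ]
  expect_lt(abs(row$estimate - beta), 3 * row$std.error)
  expect_error(
    fit_logistic_random_slope(transform(tab, isprep = 1)), "both classes")
})

test_that("time-frequency condition maps recover injected modulation", {
  # build band-limited epochs whose 6 Hz amplitude is higher on Prep trials
  fs <- 100
  tt <- seq(-1, 2, by = 1 / fs)
  n_per <- 60
  set.seed(33)
  make <- function(cond, gain) {
    t(sapply(seq_len(n_per), function(i)
      gain * cos(2 * pi * 6 * tt + runif(1, 0, 2 * pi)) +
        rnorm(length(tt), 0, 0.8)))
  }
  data <- rbind(make("Prep", 1.6), make("NoPrep", 1.0))
  ep <- epoch_set(data, tt, labels = rep(c("Prep", "NoPrep"), each = n_per),
                  participants = rep(sprintf("P%d", 1:6), length.out = 2 * n_per))
  cfg <- spectral_config(freqs = c(6, 12), cycles = c(5, 6))
  tfp <- morlet_power(ep, cfg)
  map <- tf_condition_map(tfp, conditions = c("NoPrep", "Prep"),
                          times = c(0, 1))
  m6 <- map[map$freq == 6, ]
  expect_true(all(!m6$failed))
  # injected effect: Prep power above NoPrep at 6 Hz, detected at most times
  expect_gt(mean(m6$estimate > 0), 0.95)
  expect_gt(mean(m6$p < 0.05), 0.9)
  # no injected 12 Hz effect: mostly non-significant
  m12 <- map[map$freq == 12, ]
  expect_lt(mean(m12$p < 0.05), 0.2)

  ep_one <- epoch_set(data[1:n_per, ], tt, labels = rep("Prep", n_per),
                      participants = rep("P1", n_per))
  expect_error(tf_condition_map(morlet_power(ep_one, cfg)),
               "Both conditions")
})
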