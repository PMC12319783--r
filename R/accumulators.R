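#' Discrete simulation time grid
#'
#' @param dt step size in seconds (default 0.001 s)
#' @param duration total simulated time in seconds (default 20 s)
#' @return a `time_grid` object with fields `dt`, `duration`, `n_steps`
#' @export
#' @examples
#' time_grid(dt = 0.001, duration = 20)
time_grid <- function(dt = 0.001, duration = 20) {
  check_number(dt, "dt", lower = 0, strict = TRUE)
  check_number(duration, "duration", lower = 0, strict = TRUE)
  structure(
    list(dt = dt, duration = duration, n_steps = as.integer(round(duration / dt))),
    class = "time_grid"
  )
}

grid_times <- function(grid) grid$dt * seq_len(grid$n_steps)

#' @exportS3Method base::print
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> dt = %g s, duration = %g s, %d steps\n",
              x$dt, x$duration, x$n_steps))
  invisible(x)
}

#' Parameter sets for the four action-initiation models
#'
#' Constructors with the study defaults. `stochastic_params()` parameterizes
#' the leaky stochastic accumulator (drift `I`, leak `k`, noise scale `c`,
#' threshold, and the discretization of the noise term); `classic_params()`
#' the classic readiness-potential model (gamma-distributed onset of a strong
#' input, uniform input strength, per-step additive noise);
#' `lba_params()` the linear ballistic accumulator (normal slope, uniform
#' starting point, fixed onset delay, all in millisecond units);
#' `pink_params()` the pink-noise-input accumulator (1/f spectral exponent of
#' the input plus the stochastic-accumulator parameters it feeds).
#'
#' @param I drift rate (arbitrary units per second)
#' @param k leak rate (1/s)
#' @param c noise scaling
#' @param threshold crossing threshold (amplitude)
#' @param noise_scaling `"sqrt_dt"` (standard Euler-Maruyama, default) or
#'   `"dt"` (literal reading of the printed update rule)
#' @return a parameter object of class `stochastic_params`
#' @export
#' @examples
#' stochastic_params()
stochastic_params <- function(I = 0.11, k = 0.5, c = 0.1, threshold = 0.298,
                              noise_scaling = c("sqrt_dt", "dt")) {
  check_number(I, "I")
  check_number(k, "k", lower = 0)
  check_number(c, "c", lower = 0)
  check_number(threshold, "threshold", lower = 0, strict = TRUE)
  noise_scaling <- match.arg(noise_scaling)
  structure(list(I = I, k = k, c = c, threshold = threshold,
                 noise_scaling = noise_scaling),
            class = "stochastic_params")
}

#' @rdname stochastic_params
#' @param onset_shape,onset_scale gamma parameters of the input-onset time
#'   `t_on` (seconds)
#' @param input_low,input_high uniform bounds of the input strength
#' @param step_noise_sd standard deviation of the per-step additive noise
#' @export
classic_params <- function(onset_shape = 4, onset_scale = 1,
                           input_low = 0.25, input_high = 1.25,
                           step_noise_sd = 0.005, threshold = 4 / 3) {
  check_number(onset_shape, "onset_shape", lower = 0, strict = TRUE)
  check_number(onset_scale, "onset_scale", lower = 0, strict = TRUE)
  check_number(input_low, "input_low")
  check_number(input_high, "input_high", lower = input_low)
  check_number(step_noise_sd, "step_noise_sd", lower = 0)
  check_number(threshold, "threshold", lower = 0, strict = TRUE)
  structure(list(onset_shape = onset_shape, onset_scale = onset_scale,
                 input_low = input_low, input_high = input_high,
                 step_noise_sd = step_noise_sd, threshold = threshold),
            class = "classic_params")
}

#' @rdname stochastic_params
#' @param slope_mean,slope_sd normal distribution of the accumulation slope
#'   (amplitude per millisecond)
#' @param start_low,start_high uniform bounds of the starting point
#' @param onset_delay fixed delay before accumulation begins (milliseconds)
#' @param negative_slopes `"resample"` (truncated normal, default) or
#'   `"none"` (keep the draw; non-positive slopes never cross)
#' @export
lba_params <- function(slope_mean = 2, slope_sd = 1,
                       start_low = 0, start_high = 4000,
                       onset_delay = 2500, threshold = 4000,
                       negative_slopes = c("resample", "none")) {
  check_number(slope_mean, "slope_mean")
  check_number(slope_sd, "slope_sd", lower = 0)
  check_number(start_low, "start_low")
  check_number(start_high, "start_high", lower = start_low)
  check_number(onset_delay, "onset_delay", lower = 0)
  check_number(threshold, "threshold", lower = 0, strict = TRUE)
  structure(list(slope_mean = slope_mean, slope_sd = slope_sd,
                 start_low = start_low, start_high = start_high,
                 onset_delay = onset_delay, threshold = threshold,
                 negative_slopes = match.arg(negative_slopes)),
            class = "lba_params")
}

#' @rdname stochastic_params
#' @param spectral_exponent 1/f slope of the noise input (default 1.5)
#' @param accumulator `stochastic_params()` for the leaky accumulator the
#'   pink-noise input feeds
#' @export
pink_params <- function(spectral_exponent = 1.5,
                        accumulator = stochastic_params()) {
  check_number(spectral_exponent, "spectral_exponent", lower = 0)
  stopifnot(inherits(accumulator, "stochastic_params"))
  structure(list(spectral_exponent = spectral_exponent,
                 accumulator = accumulator),
            class = "pink_params")
}

new_model_run <- function(model, grid, trace, threshold, seed,
                          onset_time = NA_real_, crossing_state = NULL) {
  state <- if (is.null(crossing_state)) trace else crossing_state
  idx <- which(state >= threshold)[1]
  crossing_time <- if (is.na(idx)) NA_real_ else idx * grid$dt
  structure(
    list(model = model, grid = grid, trace = trace,
         crossing_time = crossing_time, onset_time = onset_time,
         threshold = threshold, seed = seed),
    class = "model_run"
  )
}

#' @exportS3Method base::print
print.model_run <- function(x, ...) {
  cat(sprintf("<model_run:%s> %d samples (dt = %g s), crossing at %s s%s\n",
              x$model, length(x$trace), x$grid$dt,
              if (is.na(x$crossing_time)) "--" else format(x$crossing_time),
              if (is.na(x$onset_time)) "" else
                sprintf(", input onset at %.3f s", x$onset_time)))
  invisible(x)
}

#' Simulate the leaky stochastic accumulator
#'
#' Euler integration of `x <- x + (I - k x) dt + c xi s`, with `xi ~ N(0, 1)`
#' independent per step and `s` either `sqrt(dt)` (default) or `dt`. Movement
#' is triggered when the state first reaches the threshold.
#'
#' @param params a `stochastic_params()` object
#' @param grid a `time_grid()` object
#' @param seed integer seed (one stream per run)
#' @return a `model_run` with the state trajectory and first-crossing time
#' @export
#' @examples
#' run <- simulate_stochastic(stochastic_params(), time_grid(duration = 5), seed = 1)
#' run$crossing_time
simulate_stochastic <- function(params, grid, seed) {
  stopifnot(inherits(params, "stochastic_params"), inherits(grid, "time_grid"))
  seed <- check_seed(seed)
  s <- if (params$noise_scaling == "sqrt_dt") sqrt(grid$dt) else grid$dt
  set.seed(seed)
  noise <- (params$c * s) * rnorm(grid$n_steps)
  trace <- euler_leaky(noise, params$I, params$k, grid$dt)
  new_model_run("stochastic", grid, trace, params$threshold, seed)
}

#' Simulate the classic readiness-potential model
#'
#' Noisy fluctuation (additive per-step noise) until a gamma-distributed onset
#' time `t_on`, after which a strong input of uniform strength drives the
#' accumulator linearly to the threshold. The sampled onset is recorded in
#' `onset_time`; a grid shorter than `t_on` yields a run with no crossing.
#'
#' @inheritParams simulate_stochastic
#' @param params a `classic_params()` object
#' @export
simulate_classic <- function(params, grid, seed) {
  stopifnot(inherits(params, "classic_params"), inherits(grid, "time_grid"))
  seed <- check_seed(seed)
  set.seed(seed)
  t_on <- rgamma(1, shape = params$onset_shape, scale = params$onset_scale)
  input <- runif(1, params$input_low, params$input_high)
  eps <- if (params$step_noise_sd > 0) {
    rnorm(grid$n_steps, 0, params$step_noise_sd)
  } else {
    numeric(grid$n_steps)
  }
  drive <- input * grid$dt * (grid_times(grid) > t_on)
  trace <- cumsum(drive + eps)
  new_model_run("classic", grid, trace, params$threshold, seed,
                onset_time = t_on)
}

#' Simulate the linear ballistic accumulator
#'
#' The state sits at its uniformly drawn starting point until the fixed onset
#' delay, then rises linearly with a normally distributed slope (resampled to
#' be positive by default). Dynamics are defined on a millisecond grid
#' (slope in amplitude/ms, delay and starting range in ms); `crossing_time`
#' is reported in seconds on the shared run contract. Crossings are only
#' possible once accumulation has begun, so a starting point at the threshold
#' crosses at the onset delay.
#'
#' @inheritParams simulate_stochastic
#' @param params an `lba_params()` object
#' @export
simulate_lba <- function(params, grid, seed) {
  stopifnot(inherits(params, "lba_params"), inherits(grid, "time_grid"))
  seed <- check_seed(seed)
  set.seed(seed)
  slope <- rnorm(1, params$slope_mean, params$slope_sd)
  if (params$negative_slopes == "resample") {
    while (slope <= 0) slope <- rnorm(1, params$slope_mean, params$slope_sd)
  }
  start <- runif(1, params$start_low, params$start_high)
  t_ms <- grid_times(grid) * 1000
  trace <- start + slope * pmax(0, t_ms - params$onset_delay)
  run <- new_model_run("lba", grid, trace, params$threshold, seed)
  # accumulation is inert before the onset delay; a starting point already at
  # the bound crosses when the ramp begins, not at the first sample
  if (!is.na(run$crossing_time)) {
    run$crossing_time <- max(run$crossing_time, params$onset_delay / 1000)
  }
  run
}

#' Simulate the pink-noise-input accumulator
#'
#' Generates a 1/f noise series `P` with the configured spectral exponent and
#' drives the leaky accumulator with `c * P * dt` as its per-step input (the
#' printed update rule read literally). The crossing is determined by the
#' accumulator state, but `trace` stores the input `P`, which is the series
#' carried forward into all trace analyses for this model.
#'
#' @inheritParams simulate_stochastic
#' @param params a `pink_params()` object
#' @param keep_state also return the accumulator state as `$state`
#' @export
simulate_pink <- function(params, grid, seed, keep_state = FALSE) {
  stopifnot(inherits(params, "pink_params"), inherits(grid, "time_grid"))
  seed <- check_seed(seed)
  acc <- params$accumulator
  set.seed(seed)
  p <- powerlaw_noise(grid$n_steps, params$spectral_exponent)
  state <- euler_leaky(p * (acc$c * grid$dt), acc$I, acc$k, grid$dt)
  run <- new_model_run("pink", grid, p, acc$threshold, seed,
                       crossing_state = state)
  if (keep_state) run$state <- state
  run
}

simulate_one <- function(model, params, grid, seed) {
  switch(model,
         stochastic = simulate_stochastic(params, grid, seed),
         classic = simulate_classic(params, grid, seed),
         lba = simulate_lba(params, grid, seed),
         pink = simulate_pink(params, grid, seed),
         stop(sprintf("Unknown model '%s'.", model), call. = FALSE))
}

#' Simulate a reproducible batch of accumulator runs
#'
#' Runs `n_runs` independent simulations with per-run seeds derived from the
#' master seed, so any single run can be regenerated in isolation and the
#' whole batch is reproducible.
#'
#' @param model one of `"stochastic"`, `"classic"`, `"lba"`, `"pink"`
#' @param params the matching parameter object
#' @param grid a `time_grid()`
#' @param n_runs number of runs (>= 1)
#' @param seed master seed
#' @param keep_traces keep the full trace matrix (steps x runs); turn off to
#'   retain only crossing/onset metadata for very large batches
#' @return an `accumulator_batch`: trace matrix plus per-run crossing times,
#'   onset times (classic model), and seeds
#' @export
#' @examples
#' b <- simulate_batch("stochastic", stochastic_params(), time_grid(duration = 5),
#'                     n_runs = 10, seed = 42)
#' tidy(b)
simulate_batch <- function(model, params, grid, n_runs, seed,
                           keep_traces = TRUE) {
  check_number(n_runs, "n_runs", lower = 1)
  n_runs <- as.integer(n_runs)
  seeds <- derive_seeds(seed, n_runs, salt = 1L)
  traces <- if (keep_traces) matrix(NA_real_, grid$n_steps, n_runs) else NULL
  crossing <- numeric(n_runs)
  onset <- rep(NA_real_, n_runs)
  for (i in seq_len(n_runs)) {
    run <- simulate_one(model, params, grid, seeds[i])
    if (keep_traces) traces[, i] <- run$trace
    crossing[i] <- run$crossing_time
    onset[i] <- run$onset_time
  }
  structure(
    list(model = model, params = params, grid = grid, n_runs = n_runs,
         traces = traces, crossing_time = crossing, onset_time = onset,
         seeds = seeds, master_seed = check_seed(seed)),
    class = "accumulator_batch"
  )
}

#' @exportS3Method base::print
print.accumulator_batch <- function(x, ...) {
  cat(sprintf(
    "<accumulator_batch:%s> %d runs x %d steps (dt = %g s); %.1f%% crossed\n",
    x$model, x$n_runs, x$grid$n_steps, x$grid$dt,
    100 * mean(!is.na(x$crossing_time))))
  invisible(x)
}

#' @describeIn simulate_batch per-run metadata as a tibble
#' @param x an `accumulator_batch`
#' @param ... unused
#' @export
tidy.accumulator_batch <- function(x, ...) {
  tibble::tibble(
    run = seq_len(x$n_runs),
    model = x$model,
    seed = x$seeds,
    crossing_time = x$crossing_time,
    onset_time = x$onset_time
  )
}
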