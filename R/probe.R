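#' Probe delivery schedule
#'
#' Probe times are drawn as `shift + Gamma(shape, scale)`. The study defaults
#' are shape 4, scale 0.75, with a shift of 2.5 s for the classic model and
#' 2 s for all other models.
#'
#' @param shape,scale gamma parameters
#' @param shift constant added to every draw, seconds
#' @export
probe_schedule <- function(shape = 4, scale = 0.75, shift = 2) {
  check_number(shape, "shape", lower = 0, strict = TRUE)
  check_number(scale, "scale", lower = 0, strict = TRUE)
  check_number(shift, "shift", lower = 0)
  structure(list(shape = shape, scale = scale, shift = shift),
            class = "probe_schedule")
}

default_schedule <- function(model) {
  probe_schedule(shift = if (identical(model, "classic")) 2.5 else 2)
}

#' Draw probe delivery times
#'
#' @param schedule a `probe_schedule()`
#' @param n number of draws
#' @param seed optional seed; when `NULL` the current RNG state is used
#' @return numeric vector of probe times (seconds), each `> shift`
#' @export
draw_probe_time <- function(schedule, n = 1, seed = NULL) {
  stopifnot(inherits(schedule, "probe_schedule"))
  if (!is.null(seed)) set.seed(check_seed(seed))
  schedule$shift + rgamma(n, shape = schedule$shape, scale = schedule$scale)
}

#' Reporting-model configuration
#'
#' @param mode `"single_stage"` (amplitude at probe), `"dual_stage"`
#'   (post-probe slope), `"classic_onset"` (probe before/after input onset;
#'   classic model only), or `"random"` (random labels, the control analysis)
#' @param slope_window dual-stage regression window after the probe, seconds
#' @param report_delay delay between probe and the start of the metacognitive
#'   read-out window, seconds (0 by default; the delayed-report variant)
#' @param splits percentages (NoPrep, Unsure, Prep) summing to 100; the study
#'   values mirror the empirical report proportions
#' @param fti_window window after the probe within which a threshold crossing
#'   counts as a failure to inhibit, seconds
#' @param amplitude_source `"trace"` reads the stored trace at the probe
#'   sample (for the pink-noise model this is the input P); `"state"` reads
#'   the accumulator state instead
#' @export
reporting_config <- function(mode = c("dual_stage", "single_stage",
                                      "classic_onset", "random"),
                             slope_window = 0.2, report_delay = 0,
                             splits = c(53.2, 11.4, 35.4),
                             fti_window = 0.2,
                             amplitude_source = c("trace", "state")) {
  mode <- match.arg(mode)
  check_number(slope_window, "slope_window", lower = 0, strict = TRUE)
  check_number(report_delay, "report_delay", lower = 0)
  check_number(fti_window, "fti_window", lower = 0)
  check_splits(splits)
  structure(list(mode = mode, slope_window = slope_window,
                 report_delay = report_delay, splits = splits,
                 fti_window = fti_window,
                 amplitude_source = match.arg(amplitude_source)),
            class = "reporting_config")
}

#' Categorize a trial outcome from crossing and probe times
#'
#' The outcome partition is exhaustive and exclusive: `Movement` when the
#' threshold crossing preceded the probe, `FTI` (failure to inhibit) when the
#' crossing fell within `fti_window` after the probe, and `ProbeTrial` when
#' there was no crossing or it came later than `probe + fti_window`.
#'
#' @param crossing_time crossing times in seconds (`NA` for no crossing); a
#'   `model_run` is also accepted
#' @param probe_time probe times in seconds
#' @param fti_window seconds (default 0.2)
#' @param duration optional grid duration; probes for which the FTI window is
#'   not fully observable are rejected
#' @return character vector of outcomes
#' @export
#' @examples
#' categorize_outcome(c(4, 5.1, NA), probe_time = 5, fti_window = 0.2)
categorize_outcome <- function(crossing_time, probe_time, fti_window = 0.2,
                               duration = NULL) {
  if (inherits(crossing_time, "model_run")) {
    duration <- duration %||% crossing_time$grid$duration
    crossing_time <- crossing_time$crossing_time
  }
  if (!is.null(duration) && any(probe_time + fti_window > duration)) {
    stop("Probe time(s) too close to the end of the run to evaluate the ",
         "FTI window.", call. = FALSE)
  }
  out <- rep("ProbeTrial", length(crossing_time))
  crossed <- !is.na(crossing_time)
  out[crossed & crossing_time < probe_time] <- "Movement"
  out[crossed & crossing_time >= probe_time &
        crossing_time <= probe_time + fti_window] <- "FTI"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reporting models for probe trials
#'
#' Each reporting model takes the probe-trial table and returns it with the
#' `report` column filled.
#'
#' `single_stage_report()` ranks trials by accumulator amplitude at the time
#' of the probe and assigns the lowest `splits[1]`% to NoPrep, the next
#' `splits[2]`% to Unsure (discarded from contrasts), and the highest to
#' Prep. `dual_stage_report()` applies the same percentile split to the
#' ordinary-least-squares slope of the trace in the `slope_window` after the
#' probe (the post-decision read-out). `random_report()` permutes labels with
#' the same marginal proportions, the control for reports unrelated to the
#' accumulator. `classic_onset_report()` labels a trial NoPrep if the probe
#' preceded the sampled input-onset time and Prep otherwise (ties go to
#' Prep); it requires runs with an `onset_time`.
#'
#' Ties in the ranked feature are broken by trial order, so label counts are
#' exact integers regardless of the feature values.
#'
#' @param trials tibble of probe trials with the feature column populated
#'   (`amplitude_at_probe` or `post_probe_slope`)
#' @param config a `reporting_config()`
#' @param seed seed for `random_report()`
#' @return `trials` with `report` filled
#' @export
single_stage_report <- function(trials, config = reporting_config("single_stage")) {
  if (nrow(trials) == 0) stop("No probe trials to label.", call. = FALSE)
  if (anyNA(trials$amplitude_at_probe)) {
    stop("`amplitude_at_probe` must be populated for every probe trial.",
         call. = FALSE)
  }
  trials$report <- assign_splits(trials$amplitude_at_probe, config$splits)
  trials
}

#' @rdname single_stage_report
#' @export
dual_stage_report <- function(trials, config = reporting_config("dual_stage")) {
  if (nrow(trials) == 0) stop("No probe trials to label.", call. = FALSE)
  if (anyNA(trials$post_probe_slope)) {
    stop("`post_probe_slope` must be populated for every probe trial.",
         call. = FALSE)
  }
  trials$report <- assign_splits(trials$post_probe_slope, config$splits)
  trials
}

#' @rdname single_stage_report
#' @export
random_report <- function(trials, config = reporting_config("random"), seed = NULL) {
  if (nrow(trials) == 0) stop("No probe trials to label.", call. = FALSE)
  if (!is.null(seed)) set.seed(check_seed(seed))
  n <- nrow(trials)
  n_noprep <- floor(config$splits[1] / 100 * n)
  n_unsure <- floor(config$splits[2] / 100 * n)
  labels <- c(rep("NoPrep", n_noprep), rep("Unsure", n_unsure),
              rep("Prep", n - n_noprep - n_unsure))
  trials$report <- sample(labels)
  trials
}

#' @rdname single_stage_report
#' @export
classic_onset_report <- function(trials,
                                 config = reporting_config("classic_onset")) {
  if (nrow(trials) == 0) stop("No probe trials to label.", call. = FALSE)
  if (anyNA(trials$onset_time)) {
    stop("classic_onset reporting needs runs with an `onset_time` ",
         "(classic model only).", call. = FALSE)
  }
  trials$report <- ifelse(trials$probe_time < trials$onset_time,
                          "NoPrep", "Prep")
  trials
}

# Trace read-outs at/after the probe -----------------------------------------

trace_at <- function(traces, idx, cols) {
  traces[cbind(idx, cols)]
}

# OLS slope of trace over the (start, start + window] sample range, per run.
post_probe_slopes <- function(traces, probe_time, cols, dt,
                              window, delay = 0) {
  n_steps <- nrow(traces)
  start <- probe_time + delay
  i0 <- floor(start / dt) + 1L     # first sample strictly after the window start
  i1 <- floor((start + window) / dt)
  out <- rep(NA_real_, length(cols))
  nw <- unique(i1 - i0)
  for (len in nw) {
    sel <- which((i1 - i0) == len)
    if (any(i1[sel] > n_steps) || len < 2L) next
    ok <- sel[i1[sel] <= n_steps]
    if (!length(ok)) next
    tt <- dt * seq(0, len)
    tc <- tt - mean(tt)
    denom <- sum(tc^2)
    for (j in ok) {
      y <- traces[i0[j]:i1[j], cols[j]]
      out[j] <- sum(tc * y) / denom
    }
  }
  out
}

#' Run a full simulated probe experiment
#'
#' Simulates a batch of accumulator runs, draws one probe time per run,
#' categorizes every trial as Movement / FTI / ProbeTrial, extracts the
#' reporting features (amplitude at the probe sample and post-probe slope)
#' for probe trials, and applies the configured reporting model. All
#' randomness derives from the master seed (separate streams for simulation,
#' probe schedule, and random reporting).
#'
#' @param model `"stochastic"`, `"classic"`, `"lba"`, or `"pink"`
#' @param reporting a `reporting_config()`; `classic_onset` mode is only
#'   valid with the classic model
#' @param params model parameters (defaults chosen by model)
#' @param grid a `time_grid()`
#' @param schedule a `probe_schedule()`; default shift 2.5 s for the classic
#'   model and 2 s otherwise
#' @param n_runs number of simulated runs
#' @param seed master seed
#' @param keep_batch attach the simulated `accumulator_batch` as the
#'   `"batch"` attribute (needed for subsequent epoching)
#' @return a tibble with one row per run: `run`, `model`, `seed`,
#'   `probe_time`, `crossing_time`, `onset_time`, `outcome`, `report`,
#'   `amplitude_at_probe`, `post_probe_slope`
#' @export
#' @examples
#' tr <- run_experiment("stochastic", reporting_config("dual_stage"),
#'                      grid = time_grid(duration = 10), n_runs = 50, seed = 7)
#' table(tr$outcome)
run_experiment <- function(model,
                           reporting = reporting_config(),
                           params = NULL,
                           grid = time_grid(),
                           schedule = NULL,
                           n_runs = 10000,
                           seed = 1,
                           keep_batch = FALSE) {
  if (identical(reporting$mode, "classic_onset") && !identical(model, "classic")) {
    stop("classic_onset reporting is only compatible with the classic model.",
         call. = FALSE)
  }
  params <- params %||% switch(model,
                               stochastic = stochastic_params(),
                               classic = classic_params(),
                               lba = lba_params(),
                               pink = pink_params(),
                               stop(sprintf("Unknown model '%s'.", model),
                                    call. = FALSE))
  schedule <- schedule %||% default_schedule(model)
  batch <- simulate_batch(model, params, grid, n_runs, seed)
  probe_time <- draw_probe_time(schedule, n_runs,
                                seed = derive_seeds(seed, 1, salt = 2L))

  dt <- grid$dt
  usable <- probe_time + reporting$fti_window <= grid$duration
  outcome <- rep(NA_character_, n_runs)
  outcome[usable] <- categorize_outcome(batch$crossing_time[usable],
                                        probe_time[usable],
                                        reporting$fti_window)
  if (any(!usable)) {
    message(sprintf("Dropped %d run(s) whose probe fell too late in the grid.",
                    sum(!usable)))
  }

  trials <- tibble::tibble(
    run = seq_len(n_runs), model = model, seed = batch$seeds,
    probe_time = probe_time, crossing_time = batch$crossing_time,
    onset_time = batch$onset_time, outcome = outcome,
    report = "none",
    amplitude_at_probe = NA_real_, post_probe_slope = NA_real_
  )

  is_probe <- !is.na(outcome) & outcome == "ProbeTrial"
  if (any(is_probe)) {
    cols <- which(is_probe)
    idx <- pmin(pmax(round(probe_time[cols] / dt), 1L), grid$n_steps)
    traces <- batch$traces
    if (identical(model, "pink") &&
        identical(reporting$amplitude_source, "state")) {
      acc <- params$accumulator
      traces <- apply(traces, 2, function(p)
        euler_leaky(p * (acc$c * dt), acc$I, acc$k, dt))
    }
    trials$amplitude_at_probe[cols] <- trace_at(traces, idx, cols)
    slopes <- post_probe_slopes(traces, probe_time[cols], cols, dt,
                                window = reporting$slope_window,
                                delay = reporting$report_delay)
    trials$post_probe_slope[cols] <- slopes

    probe_rows <- trials[cols, ]
    incomplete <- is.na(probe_rows$post_probe_slope) &
      reporting$mode == "dual_stage"
    if (any(incomplete)) {
      message(sprintf(
        "Excluded %d probe trial(s) with insufficient post-probe samples.",
        sum(incomplete)))
      probe_rows <- probe_rows[!incomplete, ]
    }
    labeled <- switch(reporting$mode,
      single_stage = single_stage_report(probe_rows, reporting),
      dual_stage = dual_stage_report(probe_rows, reporting),
      classic_onset = classic_onset_report(probe_rows, reporting),
      random = random_report(probe_rows, reporting,
                             seed = derive_seeds(seed, 1, salt = 3L)))
    trials$report[match(labeled$run, trials$run)] <- labeled$report
  }

  if (keep_batch) attr(trials, "batch") <- batch
  attr(trials, "reporting") <- reporting
  trials
}

#' Relabel a trial table under a different reporting model
#'
#' The reporting features (amplitude at probe, post-probe slope) are already
#' stored on the trial table, so alternative reporting models can be applied
#' to the *same* simulated runs without re-simulating -- exactly how the
#' reporting models are meant to be contrasted.
#'
#' @param trials a trial table from `run_experiment()`
#' @param reporting a `reporting_config()`; its `fti_window` must match the
#'   one used to categorize outcomes
#' @param seed seed for `random` mode
#' @return the trial table with `report` reassigned (batch attribute kept)
#' @export
apply_reporting <- function(trials, reporting, seed = NULL) {
  is_probe <- !is.na(trials$outcome) & trials$outcome == "ProbeTrial"
  probe_rows <- trials[is_probe, ]
  labeled <- switch(reporting$mode,
    single_stage = single_stage_report(probe_rows, reporting),
    dual_stage = dual_stage_report(probe_rows[!is.na(probe_rows$post_probe_slope), ],
                                   reporting),
    classic_onset = classic_onset_report(probe_rows, reporting),
    random = random_report(probe_rows, reporting, seed = seed))
  trials$report <- "none"
  trials$report[match(labeled$run, trials$run)] <- labeled$report
  attr(trials, "reporting") <- reporting
  trials
}
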