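#' Subject-level parameters for the synthetic EEG generator
#'
#' Defaults emulate preprocessed single-channel data from a self-initiated
#' movement probe study: 200 Hz sampling, epochs from 3.5 s before to 2 s
#' after the alignment event, a late-accelerating readiness-potential (RP)
#' negativity on the midline channel, 1/f background noise, a beta-band
#' oscillation with pre-movement desynchronization on the motor channel, a
#' biphasic probe-evoked deflection on probed trials, and participant-level
#' amplitude offsets. Waiting times are gamma distributed with a 2.5 s floor
#' (mean 4.0 s, sd 0.87 s), matching typical self-paced waiting behaviour.
#'
#' @param rp_amplitude RP peak (at the event) in microvolts; `<= 0` by the
#'   negativity convention
#' @param rp_tau exponential buildup time constant, seconds
#' @param wait_shape,wait_scale,wait_shift gamma parameters (+ shift) of the
#'   movement waiting time, seconds
#' @param noise_exponent 1/f spectral exponent of the background noise
#' @param noise_scale background-noise RMS amplitude, microvolts
#' @param beta_freq motor-channel oscillation frequency, Hz
#' @param beta_amp oscillation amplitude, microvolts (base band power tracks
#'   its square)
#' @param beta_desync_depth fractional power reduction before movement, in
#'   `[0, 1]`
#' @param prep_desync_frac fraction of `beta_desync_depth` applied on Prep
#'   trials (NoPrep trials stay at base power)
#' @param probe_evoked_amp amplitude of the probe-evoked deflection, microvolts
#' @param intercept_sd across-participant SD of the midline DC offset, microvolts
#' @export
subject_params <- function(rp_amplitude = -6, rp_tau = 0.4,
                           wait_shape = 3, wait_scale = 0.5, wait_shift = 2.5,
                           noise_exponent = 1, noise_scale = 8,
                           beta_freq = 16, beta_amp = 3,
                           beta_desync_depth = 0.5, prep_desync_frac = 0.5,
                           probe_evoked_amp = 5, intercept_sd = 2) {
  if (rp_amplitude > 0) {
    stop("`rp_amplitude` must be <= 0 (RP negativity convention).",
         call. = FALSE)
  }
  check_number(rp_tau, "rp_tau", lower = 0, strict = TRUE)
  check_number(beta_desync_depth, "beta_desync_depth", lower = 0)
  if (beta_desync_depth > 1) {
    stop("`beta_desync_depth` must be in [0, 1].", call. = FALSE)
  }
  check_number(noise_scale, "noise_scale", lower = 0)
  check_number(intercept_sd, "intercept_sd", lower = 0)
  structure(list(rp_amplitude = rp_amplitude, rp_tau = rp_tau,
                 wait_shape = wait_shape, wait_scale = wait_scale,
                 wait_shift = wait_shift,
                 noise_exponent = noise_exponent, noise_scale = noise_scale,
                 beta_freq = beta_freq, beta_amp = beta_amp,
                 beta_desync_depth = beta_desync_depth,
                 prep_desync_frac = prep_desync_frac,
                 probe_evoked_amp = probe_evoked_amp,
                 intercept_sd = intercept_sd),
            class = "subject_params")
}

#' Injected fixed effects for synthetic datasets
#'
#' The ground-truth condition effects the generator injects and records.
#' `amp_offsets` are per-condition DC shifts (microvolts) applied to the
#' midline channel from 0.5 s before the event onward, so the expected
#' pre-event (250 ms) amplitude contrast between two conditions equals the
#' difference of their offsets exactly. `rp_scale` scales the RP template per
#' condition (Movement and FTI carry a full RP by default; Prep and NoPrep
#' none, mirroring the empirical pattern). `beta_depth` overrides the
#' per-condition desynchronization depth (`NULL` = derive from the subject
#' parameters). `logit` gives the intercept and probe-time slope (log-odds
#' per second) generating Prep vs NoPrep reports on probed trials.
#'
#' @param amp_offsets named numeric, microvolts
#' @param rp_scale named numeric template scaling
#' @param beta_depth named numeric in `[0, 1]`, or `NULL`
#' @param logit `c(intercept, slope)` on the log-odds scale
#' @param logit_intercept_sd,logit_slope_sd participant random-effect SDs of
#'   the reporting model (independent effects)
#' @export
effect_config <- function(amp_offsets = c(Movement = 0, FTI = 0,
                                          Prep = 0, NoPrep = 0),
                          rp_scale = c(Movement = 1, FTI = 1,
                                       Prep = 0, NoPrep = 0),
                          beta_depth = NULL,
                          logit = c(intercept = -2, slope = 0.322),
                          logit_intercept_sd = 0.5,
                          logit_slope_sd = 0.1) {
  structure(list(amp_offsets = amp_offsets, rp_scale = rp_scale,
                 beta_depth = beta_depth, logit = logit,
                 logit_intercept_sd = logit_intercept_sd,
                 logit_slope_sd = logit_slope_sd),
            class = "effect_config")
}

resolve_beta_depth <- function(subject, effects) {
  effects$beta_depth %||% c(
    Movement = subject$beta_desync_depth,
    FTI = subject$beta_desync_depth,
    Prep = subject$prep_desync_frac * subject$beta_desync_depth,
    NoPrep = 0)
}

# Beta envelope: base amplitude until -1.5 s, linear amplitude ramp down to
# sqrt(1 - depth) at -0.75 s, then constant. The measurement window
# [-0.25, 0) is therefore stationary and the expected band-power factor is
# exactly (1 - depth).
beta_envelope <- function(t, depth) {
  lo <- sqrt(1 - depth)
  env <- rep(1, length(t))
  ramp <- t > -1.5 & t < -0.75
  env[ramp] <- 1 + (lo - 1) * (t[ramp] + 1.5) / 0.75
  env[t >= -0.75] <- lo
  env
}

rp_template <- function(t, amplitude, tau) {
  out <- numeric(length(t))
  pre <- t <= 0
  out[pre] <- amplitude * exp(t[pre] / tau)
  out[!pre] <- amplitude * exp(-t[!pre] / 0.1)
  out
}

probe_evoked <- function(t, amp) {
  -amp * exp(-0.5 * ((t - 0.15) / 0.05)^2) +
    1.1 * amp * exp(-0.5 * ((t - 0.45) / 0.12)^2)
}

synth_conditions <- c("Movement", "FTI", "Prep", "NoPrep")

#' Generate one synthetic trial (midline + motor channel)
#'
#' @param subject a `subject_params()`
#' @param condition one of Movement, FTI, Prep, NoPrep
#' @param seed integer seed for this trial
#' @param effects an `effect_config()`
#' @param fs sampling rate, Hz
#' @param t_range epoch extent `(start, end)` relative to the event, seconds
#' @return list with numeric `midline` and `motor` epochs and the `time` axis
#' @export
generate_trial <- function(subject, condition, seed,
                           effects = effect_config(),
                           fs = 200, t_range = c(-3.5, 2)) {
  if (!condition %in% synth_conditions) {
    stop(sprintf("Invalid condition '%s'.", condition), call. = FALSE)
  }
  set.seed(check_seed(seed))
  t <- seq(t_range[1], t_range[2], by = 1 / fs)
  n <- length(t)
  depth <- resolve_beta_depth(subject, effects)[[condition]]

  noise_mid <- if (subject$noise_scale > 0)
    subject$noise_scale * powerlaw_noise(n, subject$noise_exponent) else 0
  noise_mot <- if (subject$noise_scale > 0)
    subject$noise_scale * powerlaw_noise(n, subject$noise_exponent) else 0
  phase <- runif(1, 0, 2 * pi)

  midline <- noise_mid +
    effects$rp_scale[[condition]] *
      rp_template(t, subject$rp_amplitude, subject$rp_tau) +
    effects$amp_offsets[[condition]] * (t >= -0.5)
  if (condition %in% c("FTI", "Prep", "NoPrep") &&
      subject$probe_evoked_amp != 0) {
    midline <- midline + probe_evoked(t, subject$probe_evoked_amp)
  }
  motor <- noise_mot +
    subject$beta_amp * beta_envelope(t, depth) *
      cos(2 * pi * subject$beta_freq * t + phase)
  list(midline = midline, motor = motor, time = t, condition = condition)
}

#' Generate a multi-participant synthetic EEG dataset
#'
#' Draws per-participant intercepts, assigns conditions (Movement, FTI, and
#' probed report trials in the study's empirical proportions), generates
#' Prep/NoPrep reports from a logistic model in probe time with participant
#' random effects, synthesizes midline and motor epochs per trial, and
#' records every injected effect in a ground-truth ledger, so downstream
#' estimators can be checked against what was generated.
#'
#' @param n_participants number of participants (>= 2)
#' @param trials_per_participant trials per participant
#' @param subject a `subject_params()`
#' @param effects an `effect_config()`
#' @param seed master seed
#' @param channels subset of `c("midline", "motor")` to synthesize
#' @param fs sampling rate, Hz
#' @param t_range epoch extent, seconds
#' @param condition_probs probabilities for (Movement, FTI, report trial);
#'   defaults follow the empirical outcome frequencies (probes on 39.2% of
#'   trials; 24.1% FTI among probe trials, unsure discarded)
#' @return a `synthetic_dataset`: `epochs` (one `epoch_set` per channel),
#'   `trials` tibble, and `ground_truth`
#' @export
generate_dataset <- function(n_participants = 20, trials_per_participant = 180,
                             subject = subject_params(),
                             effects = effect_config(),
                             seed = 1,
                             channels = c("midline", "motor"),
                             fs = 200, t_range = c(-3.5, 2),
                             condition_probs = NULL) {
  if (n_participants < 2) stop("Need at least 2 participants.", call. = FALSE)
  channels <- match.arg(channels, several.ok = TRUE)
  # probe rate 0.392; among probes FTI 0.241, Prep 0.269, NoPrep 0.404,
  # unsure 0.087 discarded before analysis
  if (is.null(condition_probs)) {
    raw <- c(movement = 0.608, fti = 0.392 * 0.241,
             report = 0.392 * (0.269 + 0.404))
    condition_probs <- raw / sum(raw)
  }
  n_total <- n_participants * trials_per_participant
  participants <- rep(sprintf("P%02d", seq_len(n_participants)),
                      each = trials_per_participant)

  set.seed(derive_seeds(seed, 1, salt = 11L))
  intercepts <- rnorm(n_participants, 0, subject$intercept_sd)
  u0 <- rnorm(n_participants, 0, effects$logit_intercept_sd)
  u1 <- rnorm(n_participants, 0, effects$logit_slope_sd)
  kind <- sample(names(condition_probs), n_total, replace = TRUE,
                 prob = condition_probs)
  schedule <- probe_schedule(shift = 2)
  probe_t <- draw_probe_time(schedule, n_total)
  wait_t <- subject$wait_shift +
    rgamma(n_total, shape = subject$wait_shape, scale = subject$wait_scale)
  pidx <- rep(seq_len(n_participants), each = trials_per_participant)

  condition <- character(n_total)
  timeprobe <- rep(NA_real_, n_total)
  isprep <- rep(NA_integer_, n_total)
  event_time <- numeric(n_total)
  for (i in seq_len(n_total)) {
    if (kind[i] == "movement") {
      condition[i] <- "Movement"
      event_time[i] <- wait_t[i]
    } else {
      timeprobe[i] <- probe_t[i]
      event_time[i] <- probe_t[i]
      if (kind[i] == "fti") {
        condition[i] <- "FTI"
      } else {
        eta <- effects$logit[["intercept"]] + u0[pidx[i]] +
          (effects$logit[["slope"]] + u1[pidx[i]]) * probe_t[i]
        isprep[i] <- rbinom(1, 1, plogis(eta))
        condition[i] <- if (isprep[i] == 1) "Prep" else "NoPrep"
      }
    }
  }

  trial_seeds <- derive_seeds(seed, n_total, salt = 13L)
  t_axis <- seq(t_range[1], t_range[2], by = 1 / fs)
  n_samples <- length(t_axis)
  data <- lapply(channels, function(ch) matrix(NA_real_, n_total, n_samples))
  names(data) <- channels
  for (i in seq_len(n_total)) {
    tr <- generate_trial(subject, condition[i], trial_seeds[i],
                         effects = effects, fs = fs, t_range = t_range)
    if ("midline" %in% channels) {
      data$midline[i, ] <- tr$midline + intercepts[pidx[i]]
    }
    if ("motor" %in% channels) data$motor[i, ] <- tr$motor
  }
  epochs <- lapply(channels, function(ch) {
    epoch_set(data[[ch]], t_axis, labels = condition,
              participants = participants,
              alignment = "movement/probe")
  })
  names(epochs) <- channels

  depth <- resolve_beta_depth(subject, effects)
  ground_truth <- list(
    amp_offsets = as.list(effects$amp_offsets),
    rp_scale = as.list(effects$rp_scale),
    beta_depth = as.list(depth),
    beta_power_factor = as.list(1 - depth),   # window [-0.25, 0) is stationary
    beta_amp = subject$beta_amp,
    beta_freq = subject$beta_freq,
    logit = as.list(effects$logit),
    intercept_sd = subject$intercept_sd,
    intercepts = as.list(setNames(intercepts,
                                  sprintf("P%02d", seq_len(n_participants)))),
    condition_probs = as.list(condition_probs)
  )

  structure(
    list(epochs = epochs,
         trials = tibble::tibble(
           participant = participants, trial = seq_len(n_total),
           condition = condition, event_time = event_time,
           timeprobe = timeprobe, isprep = isprep),
         ground_truth = ground_truth,
         subject = subject, effects = effects, seed = check_seed(seed)),
    class = "synthetic_dataset"
  )
}

#' @exportS3Method base::print
print.synthetic_dataset <- function(x, ...) {
  tab <- table(x$trials$condition)
  cat(sprintf("<synthetic_dataset> %d participants, %d trials (%s); channels: %s\n",
              length(unique(x$trials$participant)), nrow(x$trials),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              paste(names(x$epochs), collapse = ", ")))
  invisible(x)
}

#' @describeIn generate_dataset trial metadata as a tibble
#' @param x a `synthetic_dataset`
#' @param ... unused
#' @export
tidy.synthetic_dataset <- function(x, ...) x$trials
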