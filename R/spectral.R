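#' Morlet wavelet decomposition settings
#'
#' The default analysis grid spans 0.5-40 Hz with the number of wavelet
#' cycles increasing linearly from 4 at the lowest frequency to 13 at the
#' highest, and the conventional band definitions (delta 0.5-4, theta 4-7,
#' alpha 7-12, low beta 12-20, high beta 20-30, gamma 30-40 Hz; half-open
#' `[lo, hi)` intervals on the frequency grid).
#'
#' @param freqs frequency grid in Hz
#' @param cycles length-2 `(start, end)` cycles spanned linearly over the
#'   grid, or one value per frequency (must be non-decreasing)
#' @param bands named list of `c(lo, hi)` frequency intervals
#' @export
spectral_config <- function(freqs = seq(0.5, 40, by = 0.5),
                            cycles = c(4, 13),
                            bands = list(
                              delta = c(0.5, 4), theta = c(4, 7),
                              alpha = c(7, 12), `low beta` = c(12, 20),
                              `high beta` = c(20, 30), gamma = c(30, 40))) {
  stopifnot(is.numeric(freqs), all(freqs > 0), !is.unsorted(freqs))
  if (length(cycles) == 2L && length(freqs) != 2L) {
    cycles <- if (length(freqs) == 1L) cycles[1] else
      cycles[1] + (freqs - min(freqs)) / diff(range(freqs)) * diff(cycles)
  }
  if (length(cycles) != length(freqs)) {
    stop("`cycles` must be length 2 or match `freqs`.", call. = FALSE)
  }
  if (is.unsorted(cycles)) {
    stop("`cycles` must be non-decreasing with frequency.", call. = FALSE)
  }
  structure(list(freqs = freqs, cycles = cycles, bands = bands),
            class = "spectral_config")
}

#' Analytic steady-state Morlet gain for a pure tone
#'
#' Amplitude gain of the wavelet filter centred at `f_center` (with the given
#' cycle count) applied to a stationary sinusoid at `f_tone`. With the
#' package's unit-peak-gain normalization a tone of amplitude A yields power
#' `(A * gain)^2`; this closed form is what the synthetic-data recovery
#' checks use as ground truth.
#'
#' @param f_tone tone frequency, Hz
#' @param f_center wavelet centre frequency, Hz
#' @param cycles wavelet cycles at `f_center`
#' @return amplitude gain in `[0, 1]`
#' @export
morlet_tone_gain <- function(f_tone, f_center, cycles) {
  sigma_f <- f_center / cycles
  exp(-0.5 * ((f_tone - f_center) / sigma_f)^2)
}

#' Morlet wavelet time-frequency power
#'
#' Convolves every trial with a complex Morlet wavelet per frequency
#' (frequency-domain implementation: a Gaussian of width `sigma_f = f/cycles`
#' applied to the analytic spectrum) and returns squared magnitudes. Wavelets
#' are normalized to unit peak spectral gain, so a stationary sinusoid of
#' amplitude A at a wavelet's centre frequency has power `A^2`. Samples
#' within six temporal standard deviations (`sigma_t = cycles / (2 pi f)`) of
#' either epoch edge are flagged as edge-contaminated and excluded from all
#' downstream statistics; frequencies whose wavelet does not fit in the epoch
#' at all are fully masked.
#'
#' @param epochs an `epoch_set`
#' @param config a `spectral_config()`
#' @return a `tf_power` object: `power` (trials x freqs x times, NA where
#'   masked), `freqs`, `time`, per-frequency `margin` (samples masked at each
#'   end) and `fully_masked` flags, and the band definitions
#' @export
morlet_power <- function(epochs, config = spectral_config()) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(config, "spectral_config"))
  fs <- sampling_rate(epochs)
  if (fs < 2 * max(config$freqs)) {
    stop(sprintf("Sampling rate %.1f Hz is below twice the maximum analysis frequency (%g Hz).",
                 fs, max(config$freqs)), call. = FALSE)
  }
  n <- ncol(epochs$data)
  n_trials <- nrow(epochs$data)
  n_freqs <- length(config$freqs)
  X <- stats::mvfft(t(epochs$data))           # samples x trials, complex
  fg <- (seq_len(n) - 1) * fs / n
  pos <- fg <= fs / 2
  power <- array(NA_real_, dim = c(n_trials, n_freqs, n))
  margin <- integer(n_freqs)
  fully_masked <- logical(n_freqs)
  for (i in seq_len(n_freqs)) {
    f <- config$freqs[i]
    cyc <- config$cycles[i]
    sigma_t <- cyc / (2 * pi * f)
    m <- as.integer(ceiling(6 * sigma_t * fs))
    margin[i] <- m
    if (2 * m >= n) {
      fully_masked[i] <- TRUE
      next
    }
    sigma_f <- f / cyc
    gain <- numeric(n)
    gain[pos] <- 2 * exp(-0.5 * ((fg[pos] - f) / sigma_f)^2)
    gain[1] <- gain[1] / 2                    # DC is its own conjugate
    if (n %% 2 == 0) gain[n / 2 + 1] <- gain[n / 2 + 1] / 2
    resp <- stats::mvfft(X * gain, inverse = TRUE) / n
    p <- t(Mod(resp)^2)                       # trials x times
    p[, c(seq_len(m), n - seq_len(m) + 1L)] <- NA_real_
    power[, i, ] <- p
  }
  structure(
    list(power = power, freqs = config$freqs, time = epochs$time,
         margin = margin, fully_masked = fully_masked,
         cycles = config$cycles, bands = config$bands, fs = fs,
         labels = epochs$labels, participants = epochs$participants),
    class = "tf_power"
  )
}

#' @exportS3Method base::print
print.tf_power <- function(x, ...) {
  cat(sprintf("<tf_power> %d trials x %d freqs (%g-%g Hz) x %d samples; %d freq(s) fully masked\n",
              dim(x$power)[1], length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$time), sum(x$fully_masked)))
  invisible(x)
}

band_freq_idx <- function(tfp, band_name) {
  band <- tfp$bands[[band_name]]
  if (is.null(band)) {
    stop(sprintf("Unknown band '%s'. Available: %s.", band_name,
                 paste(names(tfp$bands), collapse = ", ")), call. = FALSE)
  }
  idx <- which(tfp$freqs >= band[1] & tfp$freqs < band[2] & !tfp$fully_masked)
  if (!length(idx)) {
    stop(sprintf("Band '%s' [%g, %g) Hz has no usable frequencies on the grid.",
                 band_name, band[1], band[2]), call. = FALSE)
  }
  idx
}

#' Band-averaged power
#'
#' Unweighted mean over the frequencies falling in the named band; samples
#' within the widest in-band edge margin stay `NA`.
#'
#' @param tfp a `tf_power`
#' @param band_name one of the configured band names
#' @return trials x times matrix of band power
#' @export
band_average <- function(tfp, band_name) {
  stopifnot(inherits(tfp, "tf_power"))
  idx <- band_freq_idx(tfp, band_name)
  out <- apply(tfp$power[, idx, , drop = FALSE], c(1, 3), mean)
  attr(out, "margin") <- max(tfp$margin[idx])
  attr(out, "band") <- band_name
  out
}

#' Pre-event band power per trial
#'
#' Mean power over the in-band frequencies and the half-open `[-window, 0)`
#' pre-event window.
#'
#' @param tfp a `tf_power`
#' @param band_name configured band name
#' @param window seconds before the event (default 0.25)
#' @return numeric vector, one value per trial
#' @export
pre_event_band_power <- function(tfp, band_name, window = 0.25) {
  stopifnot(inherits(tfp, "tf_power"))
  idx <- band_freq_idx(tfp, band_name)
  sel <- which(tfp$time >= -window - 1e-12 & tfp$time < -1e-12)
  if (!length(sel)) stop("Pre-event window has no samples.", call. = FALSE)
  n <- length(tfp$time)
  usable <- idx[tfp$margin[idx] < min(sel) & tfp$margin[idx] < n - max(sel) + 1]
  if (!length(usable)) {
    stop(sprintf(
      "Pre-event window fully edge-masked for band '%s'; lowest offending frequency %g Hz needs %d-sample margins.",
      band_name, tfp$freqs[idx[1]], tfp$margin[idx[1]]), call. = FALSE)
  }
  if (length(usable) < length(idx)) {
    message(sprintf("Band '%s': %d low frequency(ies) edge-masked in the window were excluded.",
                    band_name, length(idx) - length(usable)))
  }
  apply(tfp$power[, usable, sel, drop = FALSE], 1, mean)
}

#' Per-(frequency, time) condition contrast map
#'
#' Fits `power ~ condition + (1 | participant)` at every unmasked
#' time-frequency pair (via fast refits of a single template model) and
#' returns the condition contrast and its Wald p-value, the machinery behind
#' exploratory time-frequency modulation maps. Pairs whose fit fails are
#' recorded, not fatal.
#'
#' @param tfp a `tf_power` carrying trial labels and participant ids
#' @param conditions the two condition levels to contrast
#'   (estimate = second minus first)
#' @param times optional time subset (seconds) to restrict the map
#' @return tibble with `freq`, `time`, `estimate`, `se`, `p`, `failed`
#' @export
tf_condition_map <- function(tfp, conditions = c("NoPrep", "Prep"),
                             times = NULL) {
  stopifnot(inherits(tfp, "tf_power"))
  if (length(conditions) != 2) {
    stop("`conditions` must name exactly two levels.", call. = FALSE)
  }
  rows <- which(tfp$labels %in% conditions)
  if (length(unique(tfp$labels[rows])) < 2) {
    stop("Both conditions must be present in the trial labels.", call. = FALSE)
  }
  if (is.null(tfp$participants)) {
    stop("Participant ids are required for the mixed-model map.", call. = FALSE)
  }
  cond <- factor(tfp$labels[rows], levels = conditions)
  part <- factor(tfp$participants[rows])
  t_idx <- seq_along(tfp$time)
  if (!is.null(times)) {
    t_idx <- t_idx[tfp$time >= min(times) & tfp$time <= max(times)]
  }
  template <- NULL
  out <- list()
  n <- length(tfp$time)
  for (fi in which(!tfp$fully_masked)) {
    m <- tfp$margin[fi]
    ok_t <- t_idx[t_idx > m & t_idx <= n - m]
    for (ti in ok_t) {
      y <- tfp$power[rows, fi, ti]
      res <- tryCatch({
        if (is.null(template)) {
          template <- lme4::lmer(y ~ cond + (1 | part),
                                 data = data.frame(y = y, cond = cond,
                                                   part = part),
                                 REML = FALSE,
                                 control = lme4::lmerControl(calc.derivs = FALSE))
          fit <- template
        } else {
          fit <- lme4::refit(template, newresp = y)
        }
        est <- lme4::fixef(fit)[[2]]
        se <- sqrt(diag(as.matrix(vcov(fit))))[[2]]
        c(est, se, 2 * pnorm(-abs(est / se)), 0)
      }, error = function(e) c(NA_real_, NA_real_, NA_real_, 1))
      out[[length(out) + 1L]] <- c(tfp$freqs[fi], tfp$time[ti], res)
    }
  }
  if (!length(out)) stop("No unmasked time-frequency pairs to fit.", call. = FALSE)
  mat <- do.call(rbind, out)
  tibble::tibble(freq = mat[, 1], time = mat[, 2], estimate = mat[, 3],
                 se = mat[, 4], p = mat[, 5], failed = mat[, 6] > 0)
}
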