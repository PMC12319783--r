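#' Event-aligned epoch container
#'
#' Trials x samples amplitude matrix sharing one uniformly spaced time axis
#' with t = 0 at the alignment event, plus per-trial condition labels and
#' (optionally) participant ids.
#'
#' @param data numeric matrix, trials x samples
#' @param time numeric time axis in seconds (strictly increasing, uniform)
#' @param labels per-trial condition labels (recycled `NA` when absent)
#' @param participants optional per-trial participant ids
#' @param alignment name of the alignment event (`"movement"`, `"probe"`,
#'   `"threshold_crossing"`, ...)
#' @return an `epoch_set`
#' @export
epoch_set <- function(data, time, labels = NULL, participants = NULL,
                      alignment = "event") {
  data <- as.matrix(data)
  if (ncol(data) != length(time)) {
    stop("`time` must have one entry per sample column.", call. = FALSE)
  }
  steps <- diff(time)
  if (length(steps) &&
      (any(steps <= 0) || diff(range(steps)) > 1e-9 * max(abs(steps)))) {
    stop("`time` must be strictly increasing with uniform spacing.",
         call. = FALSE)
  }
  labels <- labels %||% rep(NA_character_, nrow(data))
  if (length(labels) != nrow(data)) {
    stop("`labels` must have one entry per trial row.", call. = FALSE)
  }
  if (!is.null(participants) && length(participants) != nrow(data)) {
    stop("`participants` must have one entry per trial row.", call. = FALSE)
  }
  structure(list(data = data, time = time, labels = as.character(labels),
                 participants = participants, alignment = alignment),
            class = "epoch_set")
}

#' @exportS3Method base::print
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d samples, t in [%g, %g] s, aligned to %s\n",
              nrow(x$data), ncol(x$data), min(x$time), max(x$time), x$alignment))
  if (!all(is.na(x$labels))) {
    tab <- table(x$labels, useNA = "no")
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

sampling_rate <- function(epochs) 1 / mean(diff(epochs$time))

#' @describeIn epoch_set epochs in long (trial, time, amplitude) form
#' @param x an `epoch_set`
#' @param ... unused
#' @export
tidy.epoch_set <- function(x, ...) {
  tibble::tibble(
    trial = rep(seq_len(nrow(x$data)), each = ncol(x$data)),
    condition = rep(x$labels, each = ncol(x$data)),
    time = rep(x$time, nrow(x$data)),
    amplitude = as.vector(t(x$data))
  )
}

#' Extract event-aligned epochs from traces
#'
#' Cuts a `[-pre, +post]` window around each per-trial event time out of a
#' batch of simulated traces (or a plain trial x sample matrix). Sources that
#' do not fully cover the window are dropped with a logged count; t = 0 is
#' the alignment event.
#'
#' @param x an `accumulator_batch` or a numeric matrix (trials x samples,
#'   with `dt` giving the sampling step and samples starting at `t = dt`)
#' @param event_times per-trial event times in seconds (`NA` drops the trial)
#' @param pre,post window extent before/after the event, seconds (>= 0)
#' @param labels,participants optional per-trial metadata (same length as
#'   `event_times`), carried through for retained trials
#' @param alignment label recorded on the result
#' @param dt sampling step for the matrix method
#' @return an `epoch_set`; the number of dropped trials is in
#'   `attr(, "dropped")` and retained source rows in `attr(, "source_rows")`
#' @export
epoch_align <- function(x, event_times, pre, post, labels = NULL,
                        participants = NULL, alignment = "event", dt = NULL) {
  check_number(pre, "pre", lower = 0)
  check_number(post, "post", lower = 0)
  if (inherits(x, "accumulator_batch")) {
    if (is.null(x$traces)) {
      stop("Batch was simulated with `keep_traces = FALSE`.", call. = FALSE)
    }
    traces <- x$traces            # steps x runs
    dt <- x$grid$dt
  } else {
    traces <- t(as.matrix(x))
    if (is.null(dt)) stop("`dt` is required for matrix input.", call. = FALSE)
  }
  n_steps <- nrow(traces)
  n_trials <- ncol(traces)
  if (length(event_times) != n_trials) {
    stop("`event_times` must have one entry per trial.", call. = FALSE)
  }
  n_pre <- round(pre / dt)
  n_post <- round(post / dt)
  i0 <- round(event_times / dt)
  ok <- !is.na(event_times) & (i0 - n_pre >= 1) & (i0 + n_post <= n_steps)
  if (!any(ok)) {
    stop("No trial covers the requested epoch window.", call. = FALSE)
  }
  dropped <- sum(!ok & !is.na(event_times))
  if (dropped > 0) {
    message(sprintf("Dropped %d trial(s) not covering the epoch window.",
                    dropped))
  }
  keep <- which(ok)
  offsets <- seq(-n_pre, n_post)
  out <- matrix(NA_real_, length(keep), length(offsets))
  for (j in seq_along(keep)) {
    out[j, ] <- traces[i0[keep[j]] + offsets, keep[j]]
  }
  ep <- epoch_set(out, offsets * dt,
                  labels = if (!is.null(labels)) labels[keep],
                  participants = if (!is.null(participants)) participants[keep],
                  alignment = alignment)
  attr(ep, "dropped") <- dropped
  attr(ep, "source_rows") <- keep
  ep
}

#' Per-condition mean and standard-error traces
#'
#' @param epochs an `epoch_set` with condition labels
#' @param conditions optional subset/order of conditions
#' @return a tibble with `condition`, `time`, `mean`, `se`, `n`; `se` is 0
#'   (flagged via the `"se_undefined"` attribute) for single-trial conditions
#' @export
condition_mean <- function(epochs, conditions = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  labs <- epochs$labels
  conditions <- conditions %||% unique(labs[!is.na(labs)])
  if (!length(conditions)) stop("No condition labels present.", call. = FALSE)
  unknown <- setdiff(conditions, labs)
  if (length(unknown)) {
    stop("Unknown condition label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  se_undef <- FALSE
  out <- purrr::map_dfr(conditions, function(cond) {
    rows <- which(labs == cond)
    m <- colMeans(epochs$data[rows, , drop = FALSE])
    if (length(rows) > 1) {
      s <- apply(epochs$data[rows, , drop = FALSE], 2, sd) / sqrt(length(rows))
    } else {
      s <- rep(0, length(m))
      se_undef <<- TRUE
    }
    tibble::tibble(condition = cond, time = epochs$time, mean = m, se = s,
                   n = length(rows))
  })
  attr(out, "se_undefined") <- se_undef
  out
}

#' Baseline-correct epochs
#'
#' Subtracts each trial's mean amplitude over the baseline interval; the
#' operation is idempotent.
#'
#' @param epochs an `epoch_set`
#' @param interval `(start, end)` in seconds relative to the event (default
#'   `c(-2.5, -2)`, the pre-movement convention)
#' @return the baselined `epoch_set`
#' @export
baseline_correct <- function(epochs, interval = c(-2.5, -2)) {
  stopifnot(inherits(epochs, "epoch_set"), length(interval) == 2)
  sel <- epochs$time >= interval[1] & epochs$time <= interval[2]
  if (!any(sel)) {
    stop("Baseline interval contains no samples.", call. = FALSE)
  }
  epochs$data <- epochs$data -
    rowMeans(epochs$data[, sel, drop = FALSE])
  epochs
}

pre_event_columns <- function(epochs, window) {
  check_number(window, "window", lower = 0, strict = TRUE)
  if (min(epochs$time) > -window + 1e-12) {
    stop(sprintf("Epoch starts at %g s; cannot cover a %g s pre-event window.",
                 min(epochs$time), window), call. = FALSE)
  }
  # half-open [-window, 0): the event sample belongs to the post-event response
  which(epochs$time >= -window - 1e-12 & epochs$time < -1e-12)
}

#' Pre-event single-trial statistics
#'
#' `pre_event_mean()` averages each trial over the half-open window
#' `[-window, 0)` before the alignment event (the event sample is excluded);
#' `pre_event_slope()` fits an ordinary-least-squares slope of amplitude on
#' time over the same window (amplitude per second), which is invariant to
#' any additive baseline.
#'
#' @param epochs an `epoch_set`
#' @param window window length in seconds (default 0.25 for the mean, 1 for
#'   the slope)
#' @return numeric vector, one value per trial
#' @export
pre_event_mean <- function(epochs, window = 0.25) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- pre_event_columns(epochs, window)
  rowMeans(epochs$data[, sel, drop = FALSE])
}

#' @rdname pre_event_mean
#' @export
pre_event_slope <- function(epochs, window = 1) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- pre_event_columns(epochs, window)
  if (length(sel) < 3) {
    stop("Fewer than 3 samples in the slope window.", call. = FALSE)
  }
  tc <- epochs$time[sel] - mean(epochs$time[sel])
  as.vector(epochs$data[, sel, drop = FALSE] %*% tc) / sum(tc^2)
}
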