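# Independent oracle implementations used across the suite. These are kept
# deliberately naive (plain loops, lm(), direct convolution) and share no
# code with the package internals they check.

# Plain-R Euler loop for the leaky stochastic accumulator, consuming the
# same per-run seed stream as the package simulator.
euler_oracle_r <- function(params, grid, seed) {
  set.seed(seed)
  xi <- rnorm(grid$n_steps)
  s <- if (params$noise_scaling == "sqrt_dt") sqrt(grid$dt) else grid$dt
  cs <- params$c * s
  x <- 0
  trace <- numeric(grid$n_steps)
  for (i in seq_len(grid$n_steps)) {
    x <- x + (params$I - params$k * x) * grid$dt + cs * xi[i]
    trace[i] <- x
  }
  idx <- which(trace >= params$threshold)[1]
  list(trace = trace,
       crossing_time = if (is.na(idx)) NA_real_ else idx * grid$dt)
}

# Closed form of the discrete noise-free leaky recursion x_{n} with x_0 = 0.
leaky_closed_form <- function(I, k, dt, n_steps) {
  n <- seq_len(n_steps)
  if (k == 0) return(I * dt * n)
  (I / k) * (1 - (1 - k * dt)^n)
}

# lm()-based post-probe slope for one trace (window (start, start + w]).
slope_oracle_lm <- function(trace, probe_time, dt, window = 0.2) {
  i0 <- floor(probe_time / dt) + 1L
  i1 <- floor((probe_time + window) / dt)
  tt <- (i0:i1) * dt
  unname(coef(lm(trace[i0:i1] ~ tt))[2])
}

# Percentile labels by explicit sort (secondary key = index), mirroring the
# printed split rule but coded independently.
split_oracle <- function(values, splits = c(53.2, 11.4, 35.4)) {
  n <- length(values)
  ord <- order(values, seq_len(n))
  n1 <- floor(splits[1] / 100 * n)
  n2 <- floor(splits[2] / 100 * n)
  lab <- rep("Prep", n)
  lab[ord[seq_len(n1)]] <- "NoPrep"
  if (n2 > 0) lab[ord[n1 + seq_len(n2)]] <- "Unsure"
  lab
}

# Direct time-domain complex Morlet convolution (truncated at +-8 sigma_t,
# unit peak spectral gain via envelope-sum normalization). O(n * L) loop.
morlet_conv_oracle <- function(x, fs, f, cycles) {
  sigma_t <- cycles / (2 * pi * f)
  L <- ceiling(8 * sigma_t * fs)
  tt <- (-L:L) / fs
  env <- exp(-tt^2 / (2 * sigma_t^2))
  # factor 2: analytic-signal convention, so a real tone at the centre
  # frequency keeps its amplitude (power = A^2), as in the implementation
  w <- 2 * env * exp(2i * pi * f * tt) / sum(env)
  n <- length(x)
  out <- complex(length.out = n)
  for (t in seq_len(n)) {
    ls <- max(-L, t - n):min(L, t - 1)
    out[t] <- sum(x[t - ls] * w[ls + L + 1])
  }
  out
}

# Log-log periodogram slope (positive beta for 1/f^beta input).
psd_fit <- function(x) {
  n <- length(x)
  spec <- Mod(fft(x))^2 / n
  freq <- (seq_len(n) - 1) / n
  keep <- freq > 0 & freq <= 0.4
  -unname(lm.fit(cbind(1, log(freq[keep])), log(spec[keep]))$coefficients[2])
}

# Means of a series over consecutive fixed-width bins (used for monotonicity
# checks at a resolution where Monte-Carlo jitter averages out).
binned_means <- function(x, width) {
  nb <- floor(length(x) / width)
  sapply(seq_len(nb), function(b) mean(x[((b - 1) * width + 1):(b * width)]))
}

# Tiny balanced trial table with exact per-condition means and participant
# offsets; used by the estimability checks.
balanced_table <- function(cond_means, n_participants = 4, reps = 5,
                           intercepts = NULL, noise_sd = 0, seed = 1) {
  set.seed(seed)
  conds <- names(cond_means)
  tab <- expand.grid(participant = sprintf("P%d", seq_len(n_participants)),
                     condition = conds, rep = seq_len(reps),
                     stringsAsFactors = FALSE)
  u <- intercepts %||% rep(0, n_participants)
  tab$y <- cond_means[tab$condition] +
    u[match(tab$participant, sprintf("P%d", seq_len(n_participants)))] +
    rnorm(nrow(tab), 0, noise_sd)
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
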