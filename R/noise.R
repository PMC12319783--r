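#' Gaussian power-law (1/f) noise
#'
#' Frequency-domain synthesis of stationary Gaussian noise whose power
#' spectral density falls off as `1/f^exponent` (Timmer-Konig construction):
#' independent normal deviates are drawn for the real and imaginary part of
#' each positive-frequency Fourier coefficient with standard deviation
#' `f^(-exponent/2)`, the DC scale is clamped to that of the lowest nonzero
#' frequency, and the series is normalized analytically to unit variance per
#' sample. Uses the current RNG state, so it is seedable with `set.seed()`.
#'
#' @param n number of samples (>= 4)
#' @param exponent spectral exponent beta in `1/f^beta` (0 = white noise)
#' @return numeric vector of length `n` with (expected) unit variance
#' @export
#' @examples
#' set.seed(1)
#' p <- powerlaw_noise(4096, 1.5)
powerlaw_noise <- function(n, exponent = 1.5) {
  check_number(n, "n", lower = 4)
  check_number(exponent, "exponent", lower = 0)
  n <- as.integer(n)
  m <- n %/% 2L
  f <- (0:m) / n
  s <- c(f[2], f[-1])^(-exponent / 2)   # clamp DC to the first nonzero bin
  a <- rnorm(m + 1L) * s
  b <- rnorm(m + 1L) * s
  b[1L] <- 0
  even <- n %% 2L == 0L
  if (even) b[m + 1L] <- 0
  spec <- complex(real = a, imaginary = b)
  full <- if (even) {
    c(spec, Conj(spec[m:2]))
  } else {
    c(spec, Conj(spec[(m + 1L):2]))
  }
  y <- Re(fft(full, inverse = TRUE)) / n
  # exact per-sample variance of the synthesis above
  interior <- if (even) s[2:m] else s[2:(m + 1L)]
  sigma2 <- (s[1]^2 + (if (even) s[m + 1L]^2 else 0) +
               4 * sum(interior^2)) / n^2
  y / sqrt(sigma2)
}

# Least-squares log-log slope of the periodogram; used by tests and the
# synthetic-EEG generator checks. Returns the fitted exponent (positive beta).
psd_exponent <- function(x, fs = 1) {
  n <- length(x)
  spec <- Mod(fft(x))^2 / n
  freq <- (seq_len(n) - 1) * fs / n
  keep <- freq > 0 & freq <= fs * 0.4
  fit <- lm.fit(cbind(1, log(freq[keep])), log(spec[keep] + 1e-300))
  -unname(fit$coefficients[2])
}
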