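# Internal validation and seeding helpers.

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number, got %s.",
                 name, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    stop(sprintf("`%s` must be %s %s (got %g).",
                 name, if (strict) ">" else ">=", format(lower), x),
         call. = FALSE)
  }
  invisible(x)
}

check_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed)) {
    stop("`seed` must be a single finite integer.", call. = FALSE)
  }
  as.integer(seed)
}

#' Derive reproducible child seeds from a master seed
#'
#' A single master seed deterministically yields independent per-run or
#' per-stage seeds, so every stage of a pipeline is re-runnable in isolation.
#' The `salt` distinguishes streams (simulation, probe schedule, reporting,
#' ...) drawn from the same master seed.
#'
#' @param seed master seed (integer)
#' @param n number of child seeds
#' @param salt integer stream identifier
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`
#' @export
derive_seeds <- function(seed, n, salt = 0L) {
  seed <- check_seed(seed)
  check_number(n, "n", lower = 1)
  mixed <- (as.numeric(seed) + 104729 * as.numeric(salt)) %% 2147483646 + 1
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(mixed))
  sample.int(2147483645L, size = n, replace = FALSE)
}

# Stable percentile-split assignment shared by the reporting models.
# Values are ranked with the trial index as secondary key; the lowest
# floor(p_noprep * n) get "NoPrep", the next floor(p_unsure * n) "Unsure",
# and the remainder "Prep" (conservation-exact).
assign_splits <- function(values, splits) {
  n <- length(values)
  ord <- order(values, seq_len(n))
  n_noprep <- floor(splits[[1]] / 100 * n)
  n_unsure <- floor(splits[[2]] / 100 * n)
  lab <- rep("Prep", n)
  lab[ord[seq_len(n_noprep)]] <- "NoPrep"
  if (n_unsure > 0) {
    lab[ord[n_noprep + seq_len(n_unsure)]] <- "Unsure"
  }
  lab
}

check_splits <- function(splits) {
  if (length(splits) != 3L || !is.numeric(splits)) {
    stop("`splits` must be three percentages (NoPrep, Unsure, Prep).",
         call. = FALSE)
  }
  if (abs(sum(splits) - 100) > 1e-9) {
    stop("Split percentages must sum to 100.", call. = FALSE)
  }
  invisible(splits)
}
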