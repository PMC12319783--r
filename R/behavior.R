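#' Chance level for post-probe presses within a window
#'
#' Expected percentage of post-probe button presses falling within `window`
#' seconds of probe onset if press times were uniform over `span` seconds
#' after the probe — the chance benchmark against which the observed
#' concentration of early (ballistic) presses is judged. Closed form
#' `100 * window / span`; a Monte-Carlo estimate over `n_sim` uniform draws
#' is returned instead when `n_sim` is given.
#'
#' @param window seconds after probe onset (default 0.25)
#' @param span support of the uniform press distribution, seconds (default 1)
#' @param n_sim optional number of simulation draws
#' @param seed seed for the simulation path
#' @return percentage in `[0, 100]`
#' @export
#' @examples
#' chance_press_rate()                 # 25
#' chance_press_rate(n_sim = 1e5, seed = 1)
chance_press_rate <- function(window = 0.25, span = 1, n_sim = NULL,
                              seed = NULL) {
  check_number(window, "window", lower = 0)
  check_number(span, "span", lower = 0, strict = TRUE)
  if (window > span) stop("`window` cannot exceed `span`.", call. = FALSE)
  if (is.null(n_sim)) {
    return(100 * window / span)
  }
  if (!is.null(seed)) set.seed(check_seed(seed))
  100 * mean(runif(n_sim, 0, span) <= window)
}
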