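#' Per-trial pre-probe features for labeled probe trials
#'
#' Epochs the probe trials of a simulated experiment around their probe
#' times and extracts the single-trial pre-probe mean amplitude and slope
#' used by the model-comparison grid.
#'
#' @param trials a trial table from `run_experiment(..., keep_batch = TRUE)`
#' @param window pre-probe averaging window, seconds (default 0.25)
#' @param slope_window pre-probe slope window, seconds (default 1)
#' @param reports which report labels to keep (default Prep and NoPrep)
#' @return tibble with `run`, `report`, `probe_time`, `pre_mean`, `pre_slope`
#' @export
probe_features <- function(trials, window = 0.25, slope_window = 1,
                           reports = c("Prep", "NoPrep")) {
  batch <- attr(trials, "batch")
  if (is.null(batch)) {
    stop("Trial table carries no batch; rerun with `keep_batch = TRUE`.",
         call. = FALSE)
  }
  keep <- !is.na(trials$outcome) & trials$outcome == "ProbeTrial" &
    trials$report %in% reports
  if (!any(keep)) stop("No labeled probe trials.", call. = FALSE)
  pre <- max(window, slope_window)
  events <- ifelse(keep, trials$probe_time, NA_real_)
  ep <- epoch_align(batch, events, pre = pre, post = 0,
                    labels = trials$report, alignment = "probe")
  rows <- attr(ep, "source_rows")
  tibble::tibble(
    run = trials$run[rows],
    report = trials$report[rows],
    probe_time = trials$probe_time[rows],
    pre_mean = pre_event_mean(ep, window),
    pre_slope = pre_event_slope(ep, slope_window)
  )
}

#' Prep-vs-NoPrep pre-probe contrast summary
#'
#' Welch summary of the difference in mean pre-probe amplitude between Prep
#' and NoPrep probe trials, plus per-label mean pre-probe slopes (with
#' standard errors), the quantities compared across the model-by-reporting
#' grid.
#'
#' @param features output of `probe_features()`
#' @return one-row tibble: per-label means, the contrast (Prep - NoPrep),
#'   its standard error and t statistic, and per-label slope summaries
#' @export
contrast_summary <- function(features) {
  f_prep <- features[features$report == "Prep", ]
  f_nop <- features[features$report == "NoPrep", ]
  if (!nrow(f_prep) || !nrow(f_nop)) {
    stop("Both Prep and NoPrep labels are required.", call. = FALSE)
  }
  se2 <- function(x) var(x) / length(x)
  tibble::tibble(
    n_prep = nrow(f_prep), n_noprep = nrow(f_nop),
    mean_prep = mean(f_prep$pre_mean), mean_noprep = mean(f_nop$pre_mean),
    contrast = mean(f_prep$pre_mean) - mean(f_nop$pre_mean),
    contrast_se = sqrt(se2(f_prep$pre_mean) + se2(f_nop$pre_mean)),
    slope_prep = mean(f_prep$pre_slope),
    slope_prep_se = sqrt(se2(f_prep$pre_slope)),
    slope_noprep = mean(f_nop$pre_slope),
    slope_noprep_se = sqrt(se2(f_nop$pre_slope))
  ) |>
    dplyr::mutate(contrast_t = .data$contrast / .data$contrast_se)
}

#' End-to-end experiment configuration
#'
#' A serializable bundle of everything a grid or synthetic-EEG run needs:
#' which model-by-reporting cells to run, simulation sizes, analysis
#' windows, and the master seed. Round-trips losslessly through YAML, and
#' every run writes its exact config next to its outputs.
#'
#' @param models accumulator models to include
#' @param reporting_modes reporting models crossed with `models` (the
#'   classic model always runs with `classic_onset` reporting instead)
#' @param n_runs runs per cell
#' @param seed master seed
#' @param dt,duration simulation grid, seconds
#' @param contrast_window,slope_window pre-probe analysis windows, seconds
#' @param epoch_pre,epoch_post condition-mean epoch extent, seconds
#' @param baseline baseline interval for exported condition means, seconds
#' @param include_classic,include_random add the classic-model cell and the
#'   random-report control cells
#' @param fti_window failure-to-inhibit window for the single/dual/random
#'   reporting protocol, seconds; 0 by default, because under that protocol
#'   every trial whose probe precedes the crossing counts as a probe trial
#' @param fti_window_classic FTI window for the classic-model protocol
#'   (default 0.2 s)
#' @param synth named list of `generate_dataset()` arguments for the
#'   synthetic-EEG chain
#' @export
experiment_config <- function(models = c("stochastic", "lba", "pink"),
                              reporting_modes = c("single_stage", "dual_stage"),
                              n_runs = 10000, seed = 1,
                              dt = 0.001, duration = 20,
                              contrast_window = 0.25, slope_window = 1,
                              epoch_pre = 2, epoch_post = 0,
                              baseline = c(-2.5, -2),
                              include_classic = TRUE,
                              include_random = FALSE,
                              fti_window = 0, fti_window_classic = 0.2,
                              synth = list(n_participants = 20,
                                           trials_per_participant = 180)) {
  structure(list(models = models, reporting_modes = reporting_modes,
                 n_runs = n_runs, seed = seed, dt = dt, duration = duration,
                 contrast_window = contrast_window,
                 slope_window = slope_window,
                 epoch_pre = epoch_pre, epoch_post = epoch_post,
                 baseline = baseline,
                 include_classic = include_classic,
                 include_random = include_random,
                 fti_window = fti_window,
                 fti_window_classic = fti_window_classic,
                 synth = synth),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param config an `experiment_config`
#' @param path YAML file path
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_config <- function(path) {
  raw <- yaml::yaml.load_file(path)
  do.call(experiment_config, raw)
}

grid_cells <- function(config) {
  cells <- expand.grid(model = config$models,
                       reporting = config$reporting_modes,
                       stringsAsFactors = FALSE)
  if (config$include_classic) {
    cells <- rbind(cells, data.frame(model = "classic",
                                     reporting = "classic_onset"))
  }
  if (config$include_random) {
    cells <- rbind(cells, data.frame(model = config$models,
                                     reporting = "random"))
  }
  cells
}

#' Run the model-by-reporting simulation grid
#'
#' For every cell (accumulator model crossed with reporting model, plus the
#' classic-model cell and optional random-report controls): simulate, draw
#' probes, categorize outcomes, label reports, epoch the probe trials, and
#' summarize the Prep-vs-NoPrep pre-probe contrast. When `out_dir` is given,
#' per-cell condition means, trial tables, the contrast summary, and a copy
#' of the config are written as CSV/YAML. A failure in one cell is logged
#' and does not abort the others.
#'
#' @param config an `experiment_config()`
#' @param out_dir optional output directory
#' @return tibble with one row per cell: contrast and slope summaries
#' @export
run_model_grid <- function(config = experiment_config(), out_dir = NULL) {
  cells <- grid_cells(config)
  grid <- time_grid(config$dt, config$duration)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    model <- cells$model[i]
    mode <- cells$reporting[i]
    tag <- paste(model, mode, sep = "_")
    fti <- if (identical(mode, "classic_onset")) config$fti_window_classic
           else config$fti_window
    res[[i]] <- tryCatch({
      trials <- run_experiment(model, reporting_config(mode, fti_window = fti),
                               grid = grid, n_runs = config$n_runs,
                               seed = config$seed, keep_batch = TRUE)
      feats <- probe_features(trials, window = config$contrast_window,
                              slope_window = config$slope_window)
      summ <- contrast_summary(feats)
      if (!is.null(out_dir)) {
        utils::write.csv(trials,
                         file.path(out_dir, paste0(tag, "_trials.csv")),
                         row.names = FALSE)
        batch <- attr(trials, "batch")
        keep <- trials$outcome %in% "ProbeTrial" &
          trials$report %in% c("Prep", "NoPrep")
        ep <- epoch_align(batch, ifelse(keep, trials$probe_time, NA),
                          pre = config$epoch_pre, post = config$epoch_post,
                          labels = trials$report, alignment = "probe")
        cm <- condition_mean(ep)
        utils::write.csv(cm, file.path(out_dir, paste0(tag, "_condition_means.csv")),
                         row.names = FALSE)
      }
      dplyr::bind_cols(tibble::tibble(model = model, reporting = mode), summ)
    }, error = function(e) {
      message(sprintf("Cell %s failed: %s", tag, conditionMessage(e)))
      tibble::tibble(model = model, reporting = mode)
    })
  }
  out <- dplyr::bind_rows(res)
  if (!is.null(out_dir)) {
    utils::write.csv(out, file.path(out_dir, "grid_summary.csv"),
                     row.names = FALSE)
  }
  out
}

#' Crop an epoch set in time
#'
#' @param epochs an `epoch_set`
#' @param tmin,tmax retained time range, seconds
#' @export
crop_epochs <- function(epochs, tmin, tmax) {
  sel <- epochs$time >= tmin - 1e-12 & epochs$time <= tmax + 1e-12
  if (!any(sel)) stop("Empty crop window.", call. = FALSE)
  epochs$data <- epochs$data[, sel, drop = FALSE]
  epochs$time <- epochs$time[sel]
  epochs
}

#' Run the synthetic-EEG analysis chain
#'
#' Generates a synthetic dataset, runs the ERP analysis (single-trial
#' pre-event mean amplitude, random-intercept model, corrected post hocs),
#' the beta-band analysis (Morlet band power in the pre-event window,
#' random-intercept model), and compares the estimated Prep-vs-NoPrep and
#' Movement-vs-NoPrep contrasts with the generator's recorded ground truth.
#'
#' @param config an `experiment_config()` (its `synth` entry is passed to
#'   `generate_dataset()`)
#' @param out_dir optional output directory for tidy CSVs
#' @param effects an `effect_config()` forwarded to the generator
#' @param band band analyzed on the motor channel (default `"low beta"`)
#' @return list with the two fits, the per-trial feature table, and a
#'   recovery tibble (estimate, SE, ground truth per contrast)
#' @export
run_synthetic_analysis <- function(config = experiment_config(),
                                   effects = effect_config(),
                                   out_dir = NULL, band = "low beta") {
  args <- c(list(effects = effects, seed = config$seed), config$synth)
  ds <- do.call(generate_dataset, args)
  trials <- ds$trials

  amp <- pre_event_mean(ds$epochs$midline, window = 0.25)
  amp_tab <- dplyr::mutate(trials, amplitude = amp)
  amp_fit <- fit_linear_random_intercept(amp_tab, "amplitude")
  amp_ph <- posthoc_pairwise(amp_fit, "tukey")

  motor <- crop_epochs(ds$epochs$motor, -1.6, 0.6)
  cfg <- spectral_config(freqs = seq(12, 20, by = 1), cycles = c(6, 7.5))
  cfg$bands <- list(`low beta` = c(12, 20.5))
  tfp <- morlet_power(motor, cfg)
  pow <- pre_event_band_power(tfp, band, window = 0.25)
  pow_tab <- dplyr::mutate(trials, power = pow)
  pow_fit <- fit_linear_random_intercept(pow_tab, "power")
  pow_ph <- posthoc_pairwise(pow_fit, "tukey")

  gt <- ds$ground_truth
  gain2 <- mean(morlet_tone_gain(gt$beta_freq, cfg$freqs, cfg$cycles)^2)
  base_pow <- gain2 * gt$beta_amp^2
  contrast_gt <- function(tab, a, b, gt_amp, gt_pow) {
    nm <- paste(a, "-", b)
    tibble::tibble(
      contrast = nm,
      amp_estimate = tab$amp[tab$amp_contrast == nm],
      pow_estimate = tab$pow[tab$pow_contrast == nm],
      amp_truth = gt_amp, pow_truth = gt_pow)
  }
  pairs_tab <- tibble::tibble(
    amp_contrast = amp_ph$contrast, amp = amp_ph$estimate,
    pow_contrast = pow_ph$contrast, pow = pow_ph$estimate)
  conds <- sort(unique(trials$condition))
  recovery <- purrr::map_dfr(utils::combn(conds, 2, simplify = FALSE),
    function(pr) {
      a <- pr[1]; b <- pr[2]
      contrast_gt(pairs_tab, a, b,
                  gt$amp_offsets[[a]] - gt$amp_offsets[[b]] +
                    (gt$rp_scale[[a]] - gt$rp_scale[[b]]) *
                      pre_window_template_mean(ds$subject),
                  base_pow * (gt$beta_power_factor[[a]] -
                                gt$beta_power_factor[[b]]))
    })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(amp_ph, file.path(out_dir, "erp_posthoc.csv"),
                     row.names = FALSE)
    utils::write.csv(pow_ph, file.path(out_dir, "beta_posthoc.csv"),
                     row.names = FALSE)
    utils::write.csv(recovery, file.path(out_dir, "recovery.csv"),
                     row.names = FALSE)
  }
  list(dataset = ds, amp_fit = amp_fit, pow_fit = pow_fit,
       amp_posthoc = amp_ph, pow_posthoc = pow_ph, recovery = recovery)
}

# Expected mean of the RP template over the [-0.25, 0) pre-event window.
pre_window_template_mean <- function(subject, window = 0.25) {
  a <- subject$rp_amplitude
  tau <- subject$rp_tau
  a * tau * (1 - exp(-window / tau)) / window
}
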