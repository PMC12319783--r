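# Columnar export of epochs, trial tables, and ground truth. Tables go to
# CSV; the trial x sample matrix goes to a gzip-compressed CSV with a YAML
# sidecar recording the time axis, alignment, and provenance.

#' Write an epoch set to disk
#'
#' Writes `<prefix>_data.csv.gz` (trials x samples), `<prefix>_trials.csv`
#' (labels/participants), and `<prefix>_meta.yaml` (time axis + alignment).
#'
#' @param epochs an `epoch_set`
#' @param prefix file path prefix
#' @return the prefix, invisibly
#' @export
write_epochs <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "epoch_set"))
  con <- gzfile(paste0(prefix, "_data.csv.gz"), "w")
  utils::write.table(epochs$data, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  close(con)
  utils::write.csv(
    data.frame(trial = seq_len(nrow(epochs$data)),
               condition = epochs$labels,
               participant = epochs$participants %||%
                 rep(NA_character_, nrow(epochs$data))),
    paste0(prefix, "_trials.csv"), row.names = FALSE)
  yaml::write_yaml(list(time = epochs$time, alignment = epochs$alignment),
                   paste0(prefix, "_meta.yaml"))
  invisible(prefix)
}

#' @rdname write_epochs
#' @param prefix file path prefix used by `write_epochs()`
#' @export
read_epochs <- function(prefix) {
  data <- as.matrix(utils::read.csv(gzfile(paste0(prefix, "_data.csv.gz")),
                                    header = FALSE))
  meta <- yaml::yaml.load_file(paste0(prefix, "_meta.yaml"))
  tab <- utils::read.csv(paste0(prefix, "_trials.csv"))
  participants <- if (all(is.na(tab$participant))) NULL else tab$participant
  dimnames(data) <- NULL
  epoch_set(data, as.numeric(meta$time), labels = as.character(tab$condition),
            participants = participants, alignment = meta$alignment)
}

#' Serialize a synthetic dataset's ground truth
#'
#' The ground-truth ledger (every injected effect plus participant
#' intercepts) round-trips losslessly through YAML, so recovery analyses can
#' run against stored datasets.
#'
#' @param dataset a `synthetic_dataset`
#' @param path YAML file path
#' @export
write_ground_truth <- function(dataset, path) {
  yaml::write_yaml(dataset$ground_truth, path, precision = 15L)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  yaml::yaml.load_file(path)
}
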