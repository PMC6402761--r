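#' Write EEG epochs to a text container
#'
#' Serialises an `eeg_epochs` object as a single long-format CSV (columns
#' `epoch`, `channel`, `sample`, `value`) plus a JSON sidecar holding the
#' metadata (sampling rate, trial/agent ids, class labels, generative
#' patterns). Intended for small exports and interop, not bulk storage.
#'
#' @param x an `eeg_epochs` object.
#' @param data_file path of the CSV to write.
#' @param meta_file path of the JSON sidecar (default `<data_file>.json`).
#' @return invisibly, the two paths.
#' @export
write_epochs <- function(x, data_file,
                         meta_file = paste0(data_file, ".json")) {
  stopifnot(inherits(x, "eeg_epochs"))
  d <- dim(x$data)
  df <- data.frame(
    epoch = rep(seq_len(d[3]), each = d[1] * d[2]),
    channel = rep(rep(seq_len(d[1]), times = d[2]), times = d[3]),
    sample = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    value = as.vector(x$data)
  )
  utils::write.csv(df, data_file, row.names = FALSE)
  meta <- list(
    n_channels = d[1], n_samples = d[2], n_epochs = d[3], fs = x$fs,
    trial_id = x$trial_id, agent_id = x$agent_id,
    label = as.character(x$label),
    patterns = unclass(as.data.frame(x$patterns)), snr = x$snr
  )
  jsonlite::write_json(meta, meta_file, auto_unbox = TRUE, digits = NA)
  invisible(c(data = data_file, meta = meta_file))
}

#' Read EEG epochs from a text container
#'
#' Inverse of [write_epochs()].
#'
#' @param data_file CSV path.
#' @param meta_file JSON sidecar path (default `<data_file>.json`).
#' @return an `eeg_epochs` object.
#' @export
read_epochs <- function(data_file, meta_file = paste0(data_file, ".json")) {
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  df <- utils::read.csv(data_file)
  ord <- order(df$epoch, df$sample, df$channel)
  arr <- array(df$value[ord],
               dim = c(meta$n_channels, meta$n_samples, meta$n_epochs))
  patterns <- as.matrix(as.data.frame(meta$patterns))
  structure(
    list(data = arr, fs = meta$fs,
         trial_id = meta$trial_id, agent_id = meta$agent_id,
         label = factor(meta$label, levels = c("correct", "incorrect")),
         patterns = patterns, snr = meta$snr),
    class = "eeg_epochs"
  )
}
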