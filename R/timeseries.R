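#' Multichannel time-series container
#'
#' Bundles one recording's node-by-sample numeric matrix with the metadata the
#' downstream graph pipeline needs: sampling rate (Hz for EEG, 1/TR for fMRI),
#' modality, subject, group and ordered node labels.
#'
#' @param values numeric matrix, nodes in rows, samples in columns.
#' @param sampling_rate samples per second; for fMRI use `1 / TR_seconds`.
#' @param modality `"eeg"` or `"fmri"`.
#' @param subject_id subject identifier.
#' @param group one of `"HC"`, `"R1"`, `"R2"` (or `NA` outside a study).
#' @param node_labels character vector, one label per row; defaults to
#'   `node_1 ... node_N`.
#' @return an object of class `mm_timeseries`.
#' @export
time_series_matrix <- function(values, sampling_rate, modality,
                               subject_id = NA_character_,
                               group = NA_character_,
                               node_labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    stop("time series contains non-finite values")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  modality <- match.arg(modality, c("eeg", "fmri"))
  if (is.null(node_labels)) {
    node_labels <- sprintf("node_%d", seq_len(nrow(values)))
  }
  if (length(node_labels) != nrow(values)) {
    stop("node_labels length (", length(node_labels),
         ") must equal the number of rows (", nrow(values), ")")
  }
  if (!is.na(group)) group <- match.arg(group, c("HC", "R1", "R2"))
  rownames(values) <- node_labels
  structure(
    list(values = values, sampling_rate = sampling_rate, modality = modality,
         subject_id = subject_id, group = group,
         node_labels = as.character(node_labels)),
    class = "mm_timeseries")
}

#' @export
print.mm_timeseries <- function(x, ...) {
  cat(sprintf("<mm_timeseries> %s, %d nodes x %d samples @ %g Hz",
              x$modality, nrow(x$values), ncol(x$values), x$sampling_rate))
  if (!is.na(x$subject_id)) cat(sprintf(", subject %s", x$subject_id))
  if (!is.na(x$group)) cat(sprintf(" (%s)", x$group))
  cat("\n")
  invisible(x)
}

n_samples <- function(ts) ncol(ts$values)

#' Write / read a recording as TSV plus a JSON sidecar
#'
#' The matrix is stored as a nodes-by-samples TSV (node labels in the first
#' column); modality, sampling rate, subject, group and units go into
#' `<path>.json`.
#'
#' @param ts an `mm_timeseries`.
#' @param path output TSV path.
#' @param units signal units recorded in the sidecar (default `"uV"` for EEG,
#'   `"a.u."` for fMRI).
#' @return `path`, invisibly.
#' @export
write_timeseries_tsv <- function(ts, path, units = NULL) {
  stopifnot(inherits(ts, "mm_timeseries"))
  if (is.null(units)) units <- if (ts$modality == "eeg") "uV" else "a.u."
  df <- data.frame(node = ts$node_labels, ts$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  sidecar <- list(modality = ts$modality, sampling_rate = ts$sampling_rate,
                  subject_id = ts$subject_id, group = ts$group, units = units,
                  n_nodes = nrow(ts$values), n_samples = ncol(ts$values))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = c("character", rep("numeric", sidecar$n_samples)))
  values <- as.matrix(df[, -1, drop = FALSE])
  dimnames(values) <- NULL
  time_series_matrix(values, sidecar$sampling_rate, sidecar$modality,
                     subject_id = sidecar$subject_id, group = sidecar$group,
                     node_labels = df[[1]])
}
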