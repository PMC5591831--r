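# EEG band-limiting, band decomposition, epoching with amplitude rejection;
# fMRI nuisance regression, temporal filtering and sphere-ROI extraction.

#' Default EEG frequency bands
#'
#' theta 4-8, alpha 8-13, beta1 13-20 and beta2 20-30 Hz.
#'
#' @return named list of `c(low_hz, high_hz)` pairs.
#' @export
default_eeg_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta1 = c(13, 20), beta2 = c(20, 30))
}

#' Drop initial scanner dynamics
#'
#' Removes the leading `n_dynamics * tr_s` seconds from every channel —
#' the customary exclusion of start-transition volumes (e.g., the first five
#' dynamics at TR = 3 s, i.e., 15 s) applied to both modalities.
#'
#' @param ts an `mm_timeseries`.
#' @param n_dynamics number of fMRI dynamics (volumes) to drop.
#' @param tr_s repetition time in seconds; defaults to `1 / sampling_rate`
#'   for fMRI input so each dynamic is one sample.
#' @return the shortened `mm_timeseries`.
#' @export
drop_initial_dynamics <- function(ts, n_dynamics, tr_s = NULL) {
  stopifnot(inherits(ts, "mm_timeseries"))
  if (n_dynamics == 0) return(ts)
  if (is.null(tr_s)) {
    if (ts$modality != "fmri") {
      stop("tr_s must be given for EEG input")
    }
    tr_s <- 1 / ts$sampling_rate
  }
  n_drop <- round(n_dynamics * tr_s * ts$sampling_rate)
  if (n_drop >= n_samples(ts)) {
    stop("recording too short: dropping ", n_drop, " of ", n_samples(ts),
         " samples")
  }
  ts$values <- ts$values[, -seq_len(n_drop), drop = FALSE]
  ts
}

# 4th-order zero-phase Butterworth band-pass applied per channel.
apply_bandpass <- function(x, low_hz, high_hz, fs, order = 4) {
  nyq <- fs / 2
  filt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  t(apply(x, 1, function(ch) signal::filtfilt(filt, ch)))
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero group delay) 4th-order Butterworth band-pass, so
#' filtering preserves epoch alignment between EEG and fMRI dynamics.
#'
#' @param ts an `mm_timeseries`.
#' @param low_hz,high_hz band edges; must satisfy
#'   `0 < low < high < sampling_rate / 2`.
#' @param order filter order (default 4).
#' @return the filtered `mm_timeseries`.
#' @export
bandpass_filter <- function(ts, low_hz, high_hz, order = 4) {
  stopifnot(inherits(ts, "mm_timeseries"))
  nyq <- ts$sampling_rate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop(sprintf("invalid band edges: need 0 < %g < %g < Nyquist (%g Hz)",
                 low_hz, high_hz, nyq))
  }
  ts$values <- apply_bandpass(ts$values, low_hz, high_hz, ts$sampling_rate,
                              order)
  rownames(ts$values) <- ts$node_labels
  ts
}

#' Decompose a recording into frequency bands
#'
#' One zero-phase band-passed copy per band; the default is the four
#' canonical bands of [default_eeg_bands()].
#'
#' @param ts an `mm_timeseries`.
#' @param bands named list of `c(low_hz, high_hz)` pairs.
#' @return named list of filtered `mm_timeseries`, one per band.
#' @export
split_bands <- function(ts, bands = default_eeg_bands()) {
  out <- list()
  for (nm in names(bands)) {
    out[[nm]] <- bandpass_filter(ts, bands[[nm]][1], bands[[nm]][2])
  }
  out
}

#' Epoch a recording and reject high-amplitude epochs
#'
#' Splits the recording into fixed-length epochs (a trailing partial epoch is
#' dropped), rejects every epoch whose peak-to-peak range exceeds
#' `threshold_uv` on at least one channel, and concatenates the survivors in
#' time order.
#'
#' @param ts an `mm_timeseries` (EEG, microvolts).
#' @param epoch_length_s epoch length in seconds (default 3).
#' @param threshold_uv rejection threshold in microvolts (default 150).
#' @param statistic `"peak_to_peak"` (default) or `"absolute"` (max |x|).
#' @return list with `ts` (concatenated survivors) and `report`, a list with
#'   fields `epoch_length_s`, `threshold_uv`, `n_total`, `n_rejected`,
#'   `n_kept` and `rejected_indices`.
#' @export
epoch_and_reject <- function(ts, epoch_length_s = 3, threshold_uv = 150,
                             statistic = c("peak_to_peak", "absolute")) {
  stopifnot(inherits(ts, "mm_timeseries"))
  statistic <- match.arg(statistic)
  len <- epoch_length_s * ts$sampling_rate
  if (abs(len - round(len)) > 1e-9) {
    stop("epoch_length_s * sampling_rate must be a whole number of samples")
  }
  len <- as.integer(round(len))
  n_total <- n_samples(ts) %/% len
  if (n_total == 0) stop("recording shorter than one epoch")
  rejected <- integer(0)
  for (e in seq_len(n_total)) {
    seg <- ts$values[, ((e - 1) * len + 1):(e * len), drop = FALSE]
    stat <- if (statistic == "peak_to_peak") {
      apply(seg, 1, function(ch) diff(range(ch)))
    } else {
      apply(seg, 1, function(ch) max(abs(ch)))
    }
    if (any(stat > threshold_uv)) rejected <- c(rejected, e)
  }
  kept <- setdiff(seq_len(n_total), rejected)
  if (length(kept) == 0) {
    stop("all ", n_total, " epochs rejected at ", threshold_uv,
         " uV; downstream correlation undefined")
  }
  keep_cols <- unlist(lapply(kept, function(e) ((e - 1) * len + 1):(e * len)))
  ts$values <- ts$values[, keep_cols, drop = FALSE]
  report <- list(epoch_length_s = epoch_length_s, threshold_uv = threshold_uv,
                 n_total = n_total, n_rejected = length(rejected),
                 n_kept = length(kept), rejected_indices = rejected)
  list(ts = ts, report = report)
}

#' Regress nuisance signals out of every channel
#'
#' Each output channel is the least-squares residual of the input channel on
#' an intercept plus the confound columns (e.g., white-matter and CSF mean
#' signals). With no confounds this demeans each channel. Residuals are
#' orthogonal to every confound column; the operation is idempotent.
#'
#' @param ts an `mm_timeseries`.
#' @param confound_matrix numeric matrix, samples x confounds (may have zero
#'   columns).
#' @return the residual `mm_timeseries`.
#' @export
regress_nuisance <- function(ts, confound_matrix = NULL) {
  stopifnot(inherits(ts, "mm_timeseries"))
  ns <- n_samples(ts)
  if (is.null(confound_matrix)) {
    confound_matrix <- matrix(numeric(0), nrow = ns, ncol = 0)
  }
  confound_matrix <- as.matrix(confound_matrix)
  if (nrow(confound_matrix) != ns) {
    stop("confound rows (", nrow(confound_matrix),
         ") must match sample count (", ns, ")")
  }
  design <- cbind(intercept = rep(1, ns), confound_matrix)
  if (qr(scale(design, center = TRUE, scale = FALSE)[, -1, drop = FALSE])$rank <
      ncol(confound_matrix)) {
    stop("confound design is rank-deficient after demeaning")
  }
  fit <- lm.fit(design, t(ts$values))
  ts$values <- t(as.matrix(fit$residuals))
  rownames(ts$values) <- ts$node_labels
  ts
}

#' Extract sphere-ROI time series from voxel data
#'
#' The signal of an ROI is the unweighted mean over all voxels whose centre
#' lies within `radius_mm` (Euclidean, MNI millimetres) of the ROI centre.
#' ROIs capturing no voxel are flagged (and warned about), never silently
#' dropped; their series is `NA`.
#'
#' @param voxel_grid_ts an `mm_timeseries` whose rows are voxels.
#' @param voxel_coords_mm voxels x 3 matrix of MNI coordinates (mm).
#' @param roi_table data.frame with columns `label`, `x_mm`, `y_mm`, `z_mm`.
#' @param radius_mm sphere radius in millimetres (default 5).
#' @return an `mm_timeseries` of ROI means with attribute `empty_rois`
#'   (labels of ROIs capturing zero voxels).
#' @export
extract_roi_timeseries <- function(voxel_grid_ts, voxel_coords_mm, roi_table,
                                   radius_mm = 5) {
  stopifnot(inherits(voxel_grid_ts, "mm_timeseries"), radius_mm > 0)
  voxel_coords_mm <- as.matrix(voxel_coords_mm)
  if (nrow(voxel_coords_mm) != nrow(voxel_grid_ts$values)) {
    stop("voxel coordinate rows must match voxel time-series rows")
  }
  n_roi <- nrow(roi_table)
  out <- matrix(NA_real_, n_roi, n_samples(voxel_grid_ts))
  empty <- character(0)
  for (r in seq_len(n_roi)) {
    centre <- as.numeric(roi_table[r, c("x_mm", "y_mm", "z_mm")])
    d2 <- rowSums(sweep(voxel_coords_mm, 2, centre)^2)
    inside <- which(d2 <= radius_mm^2)
    if (length(inside) == 0) {
      empty <- c(empty, roi_table$label[r])
    } else {
      out[r, ] <- colMeans(voxel_grid_ts$values[inside, , drop = FALSE])
    }
  }
  if (length(empty) > 0) {
    warning("ROIs capturing zero voxels: ", paste(empty, collapse = ", "))
    # placeholder zeros keep the container finite; flag carries the truth
    out[is.na(out)] <- 0
  }
  res <- time_series_matrix(out, voxel_grid_ts$sampling_rate, "fmri",
                            subject_id = voxel_grid_ts$subject_id,
                            group = voxel_grid_ts$group,
                            node_labels = roi_table$label)
  attr(res, "empty_rois") <- empty
  res
}
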