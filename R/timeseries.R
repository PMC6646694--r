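#' ROI time-series container
#'
#' Bundles a frames x regions signal matrix with its sampling interval and a
#' subject label. All subjects of a study must share the same region labels
#' in the same order.
#'
#' @param data Numeric matrix, frames x regions. Column names are taken as
#'   region labels unless `region_labels` is given.
#' @param subject_id Character scalar identifying the subject.
#' @param sampling_interval Seconds per frame (repetition time); default 2.
#' @param region_labels Optional character vector of region names.
#' @return An object of class `roi_ts`.
#' @export
roi_timeseries <- function(data, subject_id = "subject",
                           sampling_interval = 2,
                           region_labels = colnames(data)) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(region_labels)) {
    region_labels <- sprintf("R%03d", seq_len(ncol(data)))
  }
  if (length(region_labels) != ncol(data)) {
    stop("region_labels length (", length(region_labels),
         ") does not match number of columns (", ncol(data), ")")
  }
  if (anyNA(data)) stop("time series contains missing values")
  if (!is.numeric(sampling_interval) || sampling_interval <= 0) {
    stop("sampling_interval must be a positive number of seconds")
  }
  colnames(data) <- region_labels
  structure(
    list(subject_id = as.character(subject_id), data = data,
         sampling_interval = as.numeric(sampling_interval)),
    class = "roi_ts"
  )
}

#' @export
print.roi_ts <- function(x, ...) {
  cat("<roi_ts> subject:", x$subject_id,
      "|", nrow(x$data), "frames x", ncol(x$data), "regions",
      "| TR =", x$sampling_interval, "s\n")
  invisible(x)
}

n_frames <- function(ts) nrow(ts$data)
n_regions <- function(ts) ncol(ts$data)

#' Drop initial frames
#'
#' Removes the first `n` frames of a series, e.g. to discard magnetisation
#' non-equilibrium volumes at the start of an acquisition (conventionally
#' the first 10 frames).
#'
#' @param ts A `roi_ts` object.
#' @param n Number of leading frames to drop (default 10).
#' @return A `roi_ts` with `n` fewer frames.
#' @export
discard_frames <- function(ts, n = 10) {
  stopifnot(inherits(ts, "roi_ts"))
  if (n < 0 || n >= n_frames(ts)) {
    stop("cannot discard ", n, " frames from a series of ", n_frames(ts))
  }
  if (n == 0) return(ts)
  roi_timeseries(ts$data[-seq_len(n), , drop = FALSE], ts$subject_id,
                 ts$sampling_interval)
}

# Head-motion inclusion thresholds used by the study design this pipeline
# mirrors; screening real scans against them happens upstream of this package.
MOTION_LIMITS <- c(translation_mm = 2, rotation_deg = 2)

#' Average labelled voxel series into region series
#'
#' Collapses a frames x voxels matrix into a frames x regions matrix by
#' taking, at each frame, the arithmetic mean of all voxels carrying the
#' same region label.
#'
#' @param voxel_series Numeric matrix, frames x voxels.
#' @param labels Vector of region labels, one per voxel column.
#' @param region_order Optional character vector fixing the output region
#'   order (every entry must have at least one voxel). Defaults to the order
#'   of first appearance in `labels`.
#' @param subject_id,sampling_interval Passed to [roi_timeseries()].
#' @return A `roi_ts` with one column per region.
#' @export
average_labeled_voxels <- function(voxel_series, labels,
                                   region_order = unique(as.character(labels)),
                                   subject_id = "subject",
                                   sampling_interval = 2) {
  voxel_series <- as.matrix(voxel_series)
  labels <- as.character(labels)
  if (length(labels) != ncol(voxel_series)) {
    stop("need one label per voxel column")
  }
  missing <- setdiff(region_order, labels)
  if (length(missing) > 0) {
    stop("region(s) with zero voxels: ", paste(missing, collapse = ", "))
  }
  out <- vapply(region_order, function(r) {
    rowMeans(voxel_series[, labels == r, drop = FALSE])
  }, numeric(nrow(voxel_series)))
  roi_timeseries(out, subject_id, sampling_interval, region_labels = region_order)
}

#' Build a nuisance-regressor set
#'
#' Assembles the conventional confound matrix: mean white-matter, mean CSF
#' and global (whole-brain) signals, six rigid-body motion parameters, and
#' the first-order temporal derivative of each of the nine. Derivatives are
#' first differences padded with a leading zero so that all columns keep the
#' original frame count.
#'
#' @param nuisance Numeric matrix, frames x k, of nuisance signals (any k;
#'   typically 9 = WM + CSF + global + 6 motion).
#' @param derivatives Add first-difference columns (default TRUE).
#' @return Numeric matrix, frames x (k or 2k), with named columns.
#' @export
confound_set <- function(nuisance, derivatives = TRUE) {
  nuisance <- as.matrix(nuisance)
  if (is.null(colnames(nuisance))) {
    colnames(nuisance) <- sprintf("nuis%02d", seq_len(ncol(nuisance)))
  }
  if (!derivatives) return(nuisance)
  d <- apply(nuisance, 2, function(x) c(0, diff(x)))
  colnames(d) <- paste0("d_", colnames(nuisance))
  cbind(nuisance, d)
}

#' Regress confounds out of ROI series
#'
#' Removes nuisance structure by ordinary least squares: each region series
#' is replaced by its residual after projection on the confound columns plus
#' an intercept. Collinear confound columns are pruned (with a warning)
#' before fitting, so the projection is always well defined.
#'
#' @param ts A `roi_ts` object.
#' @param confounds Numeric matrix, frames x k (e.g. from [confound_set()]).
#' @return A `roi_ts` of residual series, orthogonal to every retained
#'   confound column.
#' @export
regress_confounds <- function(ts, confounds) {
  stopifnot(inherits(ts, "roi_ts"))
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != n_frames(ts)) {
    stop("confound frame count (", nrow(confounds),
         ") does not match series frame count (", n_frames(ts), ")")
  }
  design <- cbind(`(Intercept)` = 1, confounds)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    keep <- qrd$pivot[seq_len(qrd$rank)]
    dropped <- colnames(design)[setdiff(seq_len(ncol(design)), keep)]
    warning("pruning collinear confound column(s): ",
            paste(dropped, collapse = ", "))
    design <- design[, sort(keep), drop = FALSE]
    qrd <- qr(design)
  }
  resid <- qr.resid(qrd, ts$data)
  roi_timeseries(resid, ts$subject_id, ts$sampling_interval)
}

#' Chebyshev band-pass filter
#'
#' Temporally filters every region series with a type-I Chebyshev band-pass
#' filter, applied forward and backward ([signal::filtfilt()]) so that the
#' net phase shift is zero and frames stay aligned across regions. The
#' default design (order 4, 0.5 dB pass-band ripple) retains at least 90%
#' of the amplitude of in-band sinusoids and attenuates out-of-band
#' sinusoids below 10%.
#'
#' @param ts A `roi_ts` object.
#' @param low_hz,high_hz Pass-band edges in Hz; defaults 0.01 and 0.08, the
#'   conventional resting-state band.
#' @param order Filter order (default 4).
#' @param ripple_db Pass-band ripple in dB (default 0.5).
#' @return A `roi_ts` with the same frame count.
#' @export
bandpass_chebyshev <- function(ts, low_hz = 0.01, high_hz = 0.08,
                               order = 4, ripple_db = 0.5) {
  stopifnot(inherits(ts, "roi_ts"))
  nyquist <- 1 / (2 * ts$sampling_interval)
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("need 0 < low_hz < high_hz")
  }
  if (high_hz >= nyquist) {
    stop("high_hz (", high_hz, " Hz) must be below the Nyquist frequency (",
         nyquist, " Hz)")
  }
  flt <- signal::cheby1(order, ripple_db, c(low_hz, high_hz) / nyquist,
                        type = "pass")
  filtered <- apply(ts$data, 2, function(x) signal::filtfilt(flt, x))
  roi_timeseries(filtered, ts$subject_id, ts$sampling_interval)
}

#' Standard preprocessing chain for ROI series
#'
#' Applies, in order: leading-frame discard, Chebyshev band-pass filtering,
#' and nuisance regression (filter first, then regress — the order used for
#' the connectome analysis this package implements; set
#' `filter_first = FALSE` to regress before filtering).
#'
#' @param ts A `roi_ts` object.
#' @param confounds Optional confound matrix covering the *retained* frames
#'   (after discard); NULL skips the regression step.
#' @param discard Leading frames to drop (default 0: caller already did it).
#' @param low_hz,high_hz Band edges, see [bandpass_chebyshev()].
#' @param filter_first Filter before regressing (default TRUE).
#' @return A preprocessed `roi_ts`.
#' @export
preprocess_timeseries <- function(ts, confounds = NULL, discard = 0,
                                  low_hz = 0.01, high_hz = 0.08,
                                  filter_first = TRUE) {
  if (discard > 0) ts <- discard_frames(ts, discard)
  if (filter_first) {
    ts <- bandpass_chebyshev(ts, low_hz, high_hz)
    if (!is.null(confounds)) ts <- regress_confounds(ts, confounds)
  } else {
    if (!is.null(confounds)) ts <- regress_confounds(ts, confounds)
    ts <- bandpass_chebyshev(ts, low_hz, high_hz)
  }
  ts
}
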