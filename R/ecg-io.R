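#' ECG signal container
#'
#' A uniformly sampled single-lead voltage series with its sampling rate
#' and subject metadata.
#'
#' @param samples Numeric voltage series (mV), length >= 2.
#' @param rate Sampling rate in Hz (> 0).
#' @param subject_id Subject identifier.
#' @param label Optional `"case"`/`"control"` label.
#' @return An object of class `ecg_signal`.
#' @export
ecg_signal <- function(samples, rate, subject_id = "", label = NA_character_) {
  if (!is.numeric(samples) || length(samples) < 2L)
    stop("ecg_signal: samples must be a numeric vector of length >= 2")
  if (!is.numeric(rate) || rate <= 0) stop("ecg_signal: rate must be > 0")
  structure(list(samples = as.numeric(samples), rate = rate,
                 subject_id = subject_id, label = label),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal %s: %d samples @ %g Hz (%.1f s)%s>\n",
              x$subject_id, length(x$samples), x$rate,
              length(x$samples) / x$rate,
              if (!is.na(x$label)) paste0(", ", x$label) else ""))
  invisible(x)
}

#' Read a Holter-style ECG CSV export
#'
#' Reads a plain-text comma-separated export with a time column and one
#' voltage column. The sampling rate is inferred from the median time step;
#' steps deviating more than 1% from the median are rejected as
#' non-uniform sampling.
#'
#' @param path Path to the CSV file.
#' @param time_col,voltage_col Column names (or integer positions) of the
#'   time and voltage columns.
#' @param time_unit `"s"` or `"ms"`.
#' @param scale Multiplicative factor applied to the voltage column to
#'   convert it to mV.
#' @param header Does the file carry a header row?
#' @param subject_id,label Metadata attached to the returned signal.
#' @return An [ecg_signal()].
#' @export
read_ecg_csv <- function(path, time_col = "time", voltage_col = "voltage",
                         time_unit = c("s", "ms"), scale = 1, header = TRUE,
                         subject_id = "", label = NA_character_) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("read_ecg_csv: no such file: ", path)
  df <- utils::read.csv(path, header = header)
  pick <- function(col, what) {
    if (is.numeric(col)) {
      if (col > ncol(df)) stop("read_ecg_csv: ", what, " column index out of range")
      df[[col]]
    } else {
      if (!col %in% names(df)) stop("read_ecg_csv: missing ", what, " column '", col, "'")
      df[[col]]
    }
  }
  tm <- as.numeric(pick(time_col, "time"))
  vv <- as.numeric(pick(voltage_col, "voltage")) * scale
  if (length(tm) < 2L) stop("read_ecg_csv: fewer than 2 rows")
  if (time_unit == "ms") tm <- tm / 1000
  dt <- diff(tm)
  if (any(dt <= 0)) stop("read_ecg_csv: time column is not strictly increasing")
  step <- stats::median(dt)
  if (max(abs(dt - step)) > 0.01 * step)
    stop("read_ecg_csv: non-uniform sampling (steps deviate > 1% from the median)")
  rate <- 1 / step
  message(sprintf("read_ecg_csv: %d samples, inferred rate %.6g Hz", length(vv), rate))
  ecg_signal(vv, rate, subject_id = subject_id, label = label)
}

#' Write an ECG signal as CSV
#'
#' Writes the dialect [read_ecg_csv()] consumes: a header row and two
#' columns, time (s) and voltage (mV).
#'
#' @param signal An [ecg_signal()].
#' @param path Output path.
#' @param digits Number of significant digits for the voltage column.
#' @return Invisibly, `path`.
#' @export
write_ecg_csv <- function(signal, path, digits = 7) {
  stopifnot(inherits(signal, "ecg_signal"))
  tm <- (seq_along(signal$samples) - 1) / signal$rate
  df <- data.frame(time = format(tm, trim = TRUE, digits = 12),
                   voltage = format(signal$samples, trim = TRUE, digits = digits))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Down-sample an ECG signal
#'
#' Anti-aliased down-sampling to the analysis rate: a zero-phase (forward-
#' backward) 6th-order Butterworth low-pass at 80% of the target Nyquist
#' frequency, followed by exact decimation for integer rate ratios or
#' spline interpolation onto the target grid otherwise. Zero-phase
#' filtering keeps fiducial sample positions aligned between rates.
#'
#' @param signal An [ecg_signal()].
#' @param target_rate Target rate in Hz (<= the signal's rate).
#' @return An [ecg_signal()] at `target_rate` with
#'   `round(n * target/source)` samples.
#' @export
resample_ecg <- function(signal, target_rate = 125) {
  stopifnot(inherits(signal, "ecg_signal"))
  src <- signal$rate
  if (target_rate > src)
    stop("resample_ecg: upsampling is not supported (target exceeds source rate)")
  if (isTRUE(all.equal(target_rate, src))) return(signal)
  bf <- signal::butter(6, 0.8 * target_rate / src)
  xf <- signal::filtfilt(bf, signal$samples)
  n_out <- round(length(signal$samples) * target_rate / src)
  ratio <- src / target_rate
  if (isTRUE(all.equal(ratio, round(ratio)))) {
    idx <- seq(1L, by = as.integer(round(ratio)), length.out = n_out)
    idx <- idx[idx <= length(xf)]
    y <- xf[idx]
  } else {
    t_src <- (seq_along(xf) - 1) / src
    t_out <- (seq_len(n_out) - 1) / target_rate
    y <- stats::spline(t_src, xf, xout = pmin(t_out, max(t_src)))$y
  }
  ecg_signal(y, target_rate, subject_id = signal$subject_id, label = signal$label)
}
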