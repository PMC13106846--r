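#' Detect R peaks
#'
#' Pan-Tompkins-style detector: 5-40 Hz zero-phase band-pass,
#' differentiation, squaring, 150 ms moving-window integration and an
#' adaptive threshold, followed by peak refinement on the raw signal and a
#' 0.3 s refractory interval (consistent with rates up to 200 bpm).
#'
#' @param signal An [ecg_signal()] of at least 2 s.
#' @param threshold_frac Fraction of the upper integrated-energy quantile
#'   used as detection threshold.
#' @return Ascending integer sample indices (possibly empty).
#' @export
detect_r_peaks <- function(signal, threshold_frac = 0.2) {
  stopifnot(inherits(signal, "ecg_signal"))
  fs <- signal$rate
  x <- signal$samples
  n <- length(x)
  if (n < 2 * fs) stop("detect_r_peaks: need at least 2 s of signal")
  hi <- min(40, 0.45 * fs)
  bf <- signal::butter(3, c(5, hi) / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, x)
  dsq <- c(0, diff(bp))^2
  w <- max(3L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(dsq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- threshold_frac * stats::quantile(integ, 0.995, names = FALSE)
  if (!is.finite(thr) || thr <= 1e-12) return(integer(0))
  above <- integ > thr
  # contiguous supra-threshold regions -> one candidate peak each
  starts <- which(above & !c(FALSE, above[-n]))
  ends <- which(above & !c(above[-1], FALSE))
  if (!length(starts)) return(integer(0))
  pol_ref <- which.max(abs(bp))
  pol <- sign(x[pol_ref] - stats::median(x))
  if (pol == 0) pol <- 1
  half <- round(0.04 * fs)
  peaks <- integer(0)
  strength <- numeric(0)
  for (g in seq_along(starts)) {
    reg <- starts[g]:ends[g]
    cand <- reg[which.max(abs(bp[reg]))]
    lo_i <- max(1L, cand - half); hi_i <- min(n, cand + half)
    wv <- x[lo_i:hi_i]
    pk <- lo_i - 1L + which.max(pol * (wv - stats::median(wv)))
    peaks <- c(peaks, pk)
    strength <- c(strength, max(abs(bp[reg])))
  }
  o <- order(peaks)
  peaks <- peaks[o]; strength <- strength[o]
  # refractory: drop the weaker of any pair closer than 0.3 s
  refr <- 0.3 * fs
  keep <- rep(TRUE, length(peaks))
  last <- 1L
  for (i in seq_along(peaks)[-1]) {
    if (peaks[i] - peaks[last] < refr) {
      if (strength[i] > strength[last]) { keep[last] <- FALSE; last <- i }
      else keep[i] <- FALSE
    } else last <- i
  }
  unique(peaks[keep])
}

#' 60-s strip container
#'
#' @param samples Strip samples (mV).
#' @param rate Sampling rate (Hz).
#' @param start 1-based start index into the source signal.
#' @param r_peaks Strip-local R-peak indices.
#' @param subject_id,label Metadata.
#' @return An object of class `ecg_strip`.
#' @export
ecg_strip <- function(samples, rate, start, r_peaks, subject_id = "",
                      label = NA_character_) {
  rr <- diff(r_peaks) / rate
  structure(list(samples = samples, rate = rate, start = start,
                 r_peaks = r_peaks, mean_hr = 60 / mean(rr),
                 subject_id = subject_id, label = label,
                 baseline_removed = FALSE),
            class = "ecg_strip")
}

#' @export
print.ecg_strip <- function(x, ...) {
  cat(sprintf("<ecg_strip %s: start %d, %d beats, mean HR %.1f bpm>\n",
              x$subject_id, x$start, length(x$r_peaks), x$mean_hr))
  invisible(x)
}

#' Extract artefact-free strips in a heart-rate band
#'
#' Greedy left-to-right scan over candidate windows anchored at R peaks.
#' A 60-s window is accepted iff every RR interval inside it deviates less
#' than `rr_dev` (default 30%) from the window's mean RR and the window's
#' mean heart rate lies in `[hr_lo, hr_hi]`. After an accepted window the
#' scan resumes at the first beat past its end (accepted strips never
#' overlap); after a rejection it advances one beat.
#'
#' @param signal An [ecg_signal()].
#' @param r_peaks Indices from [detect_r_peaks()].
#' @param hr_lo,hr_hi Heart-rate band (bpm), `hr_lo < hr_hi`.
#' @param rr_dev Maximum fractional RR deviation from the window mean.
#' @param duration_s Window length in seconds.
#' @return List of [ecg_strip()] objects.
#' @export
find_segments <- function(signal, r_peaks, hr_lo = 30, hr_hi = 120,
                          rr_dev = 0.30, duration_s = 60) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (hr_lo >= hr_hi) stop("find_segments: hr_lo must be < hr_hi")
  fs <- signal$rate
  L <- round(duration_s * fs)
  n <- length(signal$samples)
  strips <- list()
  i <- 1L
  while (i <= length(r_peaks)) {
    start <- r_peaks[i]
    if (start + L - 1L > n) break
    inside <- r_peaks[r_peaks >= start & r_peaks < start + L]
    ok <- FALSE
    if (length(inside) >= 2L) {
      rr <- diff(inside) / fs
      mrr <- mean(rr)
      hr <- 60 / mrr
      if (all(abs(rr - mrr) < rr_dev * mrr) && hr >= hr_lo && hr <= hr_hi)
        ok <- TRUE
    }
    if (ok) {
      strips[[length(strips) + 1L]] <-
        ecg_strip(signal$samples[start:(start + L - 1L)], fs, start,
                  inside - start + 1L, signal$subject_id, signal$label)
      nxt <- which(r_peaks >= start + L)
      if (!length(nxt)) break
      i <- nxt[1]
    } else i <- i + 1L
  }
  strips
}

#' Remove baseline wander from a strip
#'
#' Fits a natural cubic spline through knots placed at the middle of each
#' RR interval, with the knot value taken as the local median voltage in a
#' +/-40 ms window, and subtracts the fitted curve. With fewer than two
#' knots the strip median is subtracted instead (logged).
#'
#' @param strip An [ecg_strip()].
#' @return The strip with the baseline removed.
#' @export
remove_baseline <- function(strip) {
  stopifnot(inherits(strip, "ecg_strip"))
  fs <- strip$rate
  v <- strip$samples
  r <- strip$r_peaks
  half <- round(0.04 * fs)
  if (length(r) < 3L) {
    message("remove_baseline: fewer than 2 knots; subtracting the strip median")
    strip$samples <- v - stats::median(v)
    strip$baseline_removed <- TRUE
    return(strip)
  }
  knots <- floor((r[-length(r)] + r[-1]) / 2)
  vals <- vapply(knots, function(k) {
    stats::median(v[max(1, k - half):min(length(v), k + half)])
  }, numeric(1))
  if (length(knots) >= 3L) {
    f <- stats::splinefun(knots, vals, method = "natural")
    base <- f(seq_along(v))
  } else {
    base <- stats::approx(knots, vals, xout = seq_along(v), rule = 2)$y
  }
  strip$samples <- v - base
  strip$baseline_removed <- TRUE
  strip
}

#' Mean heart rate of a strip
#'
#' `60 / mean(RR)` over the strip's R peaks.
#'
#' @param strip An [ecg_strip()].
#' @return Heart rate in bpm.
#' @export
strip_heart_rate <- function(strip) {
  stopifnot(inherits(strip, "ecg_strip"))
  if (length(strip$r_peaks) < 2L)
    stop("strip_heart_rate: need at least 2 R peaks")
  60 / mean(diff(strip$r_peaks) / strip$rate)
}
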