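#' Locate the six fiducial markers in every beat of a strip
#'
#' For each detected R peak, searches windows scaled to the local RR
#' interval: Q peak is the extremum opposite to R within 0.12 RR before R;
#' Q onset the last sample before Q peak whose magnitude falls below 5% of
#' the beat's peak-to-peak range; QRS end the first such sample after the
#' S extremum; T peak the largest deflection between QRS end + 50 ms and
#' QRS end + 0.45 RR; T end the first sample after T peak decaying below
#' 5% of the T-peak amplitude. Beats in which any search fails (or the
#' marker ordering is violated) are flagged and excluded.
#'
#' @param strip A baseline-removed [ecg_strip()].
#' @return Data.frame `beat, q_onset, q_peak, r_peak, qrs_end, t_peak,
#'   t_end` (strip-local indices), only beats annotated successfully;
#'   attribute `n_flagged` counts excluded beats.
#' @export
annotate_beats <- function(strip) {
  stopifnot(inherits(strip, "ecg_strip"))
  fs <- strip$rate
  v <- strip$samples
  r <- strip$r_peaks
  n <- length(v)
  if (length(r) < 2L) stop("annotate_beats: strip has fewer than 2 R peaks")
  # search on a zero-phase low-passed copy: the 5% on/offset crossings lie
  # below the raw noise floor; 30 Hz keeps wave peak positions unbiased
  if (fs > 70) {
    bf <- signal::butter(4, min(30, 0.45 * fs) / (fs / 2))
    v <- signal::filtfilt(bf, v)
  }
  rr_all <- diff(r)
  pol <- if (abs(max(v)) >= abs(min(v))) 1 else -1
  rows <- list()
  flagged <- 0L
  for (j in seq_along(r)) {
    rj <- r[j]
    rr <- if (j == 1L) rr_all[1] else if (j == length(r)) rr_all[length(rr_all)]
          else mean(rr_all[c(j - 1L, j)])
    win <- function(lo, hi) {
      i <- max(1L, round(lo)):min(n, round(hi))
      i[i >= 1 & i <= n]
    }
    fail <- function() { flagged <<- flagged + 1L; NULL }
    res <- local({
      # per-beat local offset from the pre-Q isoelectric window, so the 5%
      # crossings are measured against the local baseline, not any residual
      # wander the spline left behind
      iso <- win(rj - 0.14 * fs, rj - 0.08 * fs)
      b0 <- if (length(iso)) stats::median(v[iso]) else 0
      vb <- v - b0
      bw <- win(rj - 0.15 * rr, rj + 0.6 * rr)
      ptp <- max(vb[bw]) - min(vb[bw])
      if (ptp <= 0) return(fail())
      thr <- .FID_AMP_FRAC * ptp
      qw <- win(rj - 0.12 * rr, rj - 1L)
      if (length(qw) < 2L) return(fail())
      q_pk <- qw[which.min(pol * vb[qw])]
      back <- win(rj - 0.3 * rr, q_pk - 1L)
      qon_c <- back[abs(vb[back]) < thr]
      if (!length(qon_c)) return(fail())
      q_on <- max(qon_c)
      sw <- win(rj + 1L, rj + 0.12 * rr)
      if (length(sw) < 2L) return(fail())
      s_pk <- sw[which.min(pol * vb[sw])]
      fwd <- win(s_pk + 1L, rj + 0.3 * rr)
      qe_c <- fwd[abs(vb[fwd]) < thr]
      if (!length(qe_c)) return(fail())
      qrs_end <- min(qe_c)
      t_hi <- min(qrs_end + 0.45 * rr, if (j < length(r)) r[j + 1L] - 0.15 * rr else n)
      tw <- win(qrs_end + 0.05 * fs, t_hi)
      if (length(tw) < 2L) return(fail())
      t_pk <- tw[which.max(abs(vb[tw]))]
      t_amp <- abs(vb[t_pk])
      if (t_amp <= 2 * thr) return(fail())          # missing/degenerate T wave
      te_lim <- if (j < length(r)) r[j + 1L] - 0.12 * rr else n
      dw <- win(t_pk + 1L, te_lim)
      te_c <- dw[abs(vb[dw]) < .FID_AMP_FRAC * t_amp]
      if (!length(te_c)) return(fail())
      t_end <- min(te_c)
      fid <- c(q_on, q_pk, rj, qrs_end, t_pk, t_end)
      if (any(diff(fid) <= 0)) return(fail())
      data.frame(beat = j, q_onset = q_on, q_peak = q_pk, r_peak = rj,
                 qrs_end = qrs_end, t_peak = t_pk, t_end = t_end)
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows))
    stop("annotate_beats: no annotatable beats in strip")
  ann <- do.call(rbind, rows)
  # enforce t_end < next beat's q_onset across consecutive annotated beats
  if (nrow(ann) > 1L) {
    bad <- which(ann$t_end[-nrow(ann)] >= ann$q_onset[-1])
    if (length(bad)) {
      flagged <- flagged + length(bad)
      ann <- ann[-bad, , drop = FALSE]
    }
  }
  if (flagged > 0L)
    message("annotate_beats: ", flagged, " beat(s) flagged and excluded")
  attr(ann, "n_flagged") <- flagged
  ann
}

#' Threshold-crossing (TC) coarse graining
#'
#' Binary symbolisation of a strip: samples at or above the strip's median
#' voltage become `'1'`, the rest `'0'`.
#'
#' @param strip An [ecg_strip()] or numeric vector.
#' @return A [symbol_string()] with scheme `"TC"`.
#' @export
tc_string <- function(strip) {
  v <- if (inherits(strip, "ecg_strip")) strip$samples else strip
  if (!length(v)) stop("tc_string: empty strip")
  med <- stats::median(v)
  symbol_string(paste(ifelse(v >= med, "1", "0"), collapse = ""),
                scheme = "TC", alphabet = c("0", "1"))
}

# XD symbol per fiducial marker, and mask bit order for FD codes
.XD_SYMBOLS <- c(q_onset = "6", q_peak = "7", r_peak = "A",
                 qrs_end = "G", t_peak = "J", t_end = "L")
.MASK_BITS <- c(q_onset = 1L, q_peak = 2L, r_peak = 4L,
                qrs_end = 8L, t_peak = 16L, t_end = 32L)

#' Features included in an FD mask code
#'
#' Mask codes 1-63 encode non-empty subsets of the six fiducial markers
#' with bit values Qon=1, Qpk=2, R=4, QRSend=8, Tpk=16, Tend=32.
#'
#' @param code Integer mask code in 1..63.
#' @return Character vector of included feature names.
#' @export
mask_features <- function(code) {
  code <- as.integer(code)
  if (code < 1L || code > 63L) stop("mask_features: code must be in 1..63")
  names(.MASK_BITS)[bitwAnd(code, .MASK_BITS) > 0L]
}

#' Extended feature-detection (XD) coarse graining
#'
#' Marks the six fiducial markers of every annotated beat with distinct
#' symbols -- `'6'` Q onset, `'7'` Q peak, `'A'` R peak, `'G'` QRS end,
#' `'J'` T peak, `'L'` T end -- and every other sample with `'0'`.
#'
#' @param annotations Data.frame from [annotate_beats()].
#' @param strip_length Strip length in samples.
#' @return A [symbol_string()] with scheme `"XD"`.
#' @export
xd_string <- function(annotations, strip_length) {
  chars <- rep("0", strip_length)
  idx_all <- integer(0)
  for (f in names(.XD_SYMBOLS)) {
    idx <- annotations[[f]]
    if (any(idx < 1 | idx > strip_length))
      stop("xd_string: fiducial index outside the strip")
    idx_all <- c(idx_all, idx)
    chars[idx] <- .XD_SYMBOLS[[f]]
  }
  if (anyDuplicated(idx_all))
    stop("xd_string: two fiducial markers map to the same sample (annotation collision)")
  symbol_string(paste(chars, collapse = ""), scheme = "XD",
                alphabet = c("0", "6", "7", "A", "G", "J", "L"))
}

#' Generate the 63 feature-detection (FD) strings
#'
#' Projects an XD string onto every non-empty subset of the six fiducial
#' markers: positions carrying an included marker become `'1'`, all other
#' positions `'0'`.
#'
#' @param xd A [symbol_string()] with scheme `"XD"`.
#' @param codes Mask codes to generate (default all 63).
#' @return Named list (by mask code) of binary [symbol_string()]s.
#' @export
fd_strings <- function(xd, codes = 1:63) {
  if (!inherits(xd, "symbol_string") || attr(xd, "scheme") != "XD")
    stop("fd_strings: input must be an XD symbol string")
  chars <- strsplit(unclass(xd), "")[[1]]
  pos <- lapply(.XD_SYMBOLS, function(sym) which(chars == sym))
  zero <- rep("0", length(chars))
  out <- lapply(codes, function(code) {
    feats <- mask_features(code)
    cc <- zero
    cc[unlist(pos[feats], use.names = FALSE)] <- "1"
    symbol_string(paste(cc, collapse = ""), scheme = "FD", alphabet = c("0", "1"))
  })
  names(out) <- as.character(codes)
  out
}
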