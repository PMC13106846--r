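#' Per-beat restitution intervals
#'
#' Converts consecutive annotated beats into restitution records: RR (R to
#' next R), QT (Q onset to T end), TQ (T end to next Q onset, the diastolic
#' interval) and QRS width (Q onset to QRS end), all in milliseconds. Only
#' pairs of consecutively annotated beats emit a record; the last beat
#' emits none. By construction `qt + tq` equals the Q-onset-to-next-Q-onset
#' interval exactly.
#'
#' @param annotations Data.frame from [annotate_beats()] (>= 2 beats).
#' @param rate Sampling rate (Hz) of the annotated strip.
#' @return Data.frame `rr, qt, tq, qrs_width` (ms).
#' @export
beat_intervals <- function(annotations, rate) {
  stopifnot(is.data.frame(annotations))
  if (nrow(annotations) < 2L)
    stop("beat_intervals: need at least 2 annotated beats")
  a <- annotations[order(annotations$beat), ]
  consec <- which(diff(a$beat) == 1L)
  if (!length(consec))
    stop("beat_intervals: no consecutive annotated beat pairs")
  ms <- function(d) 1000 * d / rate
  i <- consec; j <- consec + 1L
  out <- data.frame(
    rr = ms(a$r_peak[j] - a$r_peak[i]),
    qt = ms(a$t_end[i] - a$q_onset[i]),
    tq = ms(a$q_onset[j] - a$t_end[i]),
    qrs_width = ms(a$qrs_end[i] - a$q_onset[i]))
  if (any(out <= 0)) stop("beat_intervals: non-positive interval encountered")
  out
}

#' Restitution curve data
#'
#' Builds the four paired series of the restitution analysis -- QT vs RR,
#' TQ vs RR, QT vs TQ and QRS width vs RR -- with a Spearman rank
#' correlation per pair (reported as NA when a series is constant).
#'
#' @param beats Data.frame from [beat_intervals()] (>= 10 beats).
#' @return Named list of `list(data, spearman)` entries: `qt_rr`, `tq_rr`,
#'   `qt_tq`, `qrs_rr`.
#' @export
restitution_curves <- function(beats) {
  stopifnot(is.data.frame(beats))
  if (nrow(beats) < 10L)
    stop("restitution_curves: need at least 10 beat records")
  pairs <- list(qt_rr = c("rr", "qt"), tq_rr = c("rr", "tq"),
                qt_tq = c("tq", "qt"), qrs_rr = c("rr", "qrs_width"))
  lapply(pairs, function(p) {
    x <- beats[[p[1]]]; y <- beats[[p[2]]]
    rho <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
           else suppressWarnings(stats::cor(x, y, method = "spearman"))
    list(data = data.frame(x = x, y = y, row.names = NULL),
         xvar = p[1], yvar = p[2], spearman = rho)
  })
}

#' k-nearest-neighbour classification of interval triplets
#'
#' Classifies (TQ, QT, RR) triplets by majority vote among the k nearest
#' training triplets in z-score-standardised Euclidean space
#' (standardisation estimated on the training set). Vote ties fall back to
#' k - 2, k - 4, ... down to the single nearest neighbour.
#'
#' @param train Data.frame/matrix of training triplets (columns tq, qt, rr).
#' @param train_labels Labels of the training rows.
#' @param test Data.frame/matrix of query triplets, same columns.
#' @param k Number of neighbours, `1 <= k <= nrow(train)`.
#' @return Character vector of predicted labels.
#' @export
knn_classify <- function(train, train_labels, test, k = 5L) {
  train <- as.matrix(train); test <- as.matrix(test)
  if (!nrow(train)) stop("knn_classify: empty training set")
  if (k < 1L || k > nrow(train))
    stop("knn_classify: k must be between 1 and the training-set size")
  if (length(train_labels) != nrow(train))
    stop("knn_classify: labels do not match the training set")
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[sdv == 0] <- 1
  zt <- sweep(sweep(train, 2, mu), 2, sdv, "/")
  zq <- sweep(sweep(test, 2, mu), 2, sdv, "/")
  train_labels <- as.character(train_labels)
  apply(zq, 1, function(q) {
    d <- sqrt(colSums((t(zt) - q)^2))
    o <- order(d)
    kk <- k
    repeat {
      tab <- table(train_labels[o[seq_len(kk)]])
      top <- names(tab)[tab == max(tab)]
      if (length(top) == 1L || kk <= 1L) return(top[1])
      kk <- max(kk - 2L, 1L)
    }
  })
}
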