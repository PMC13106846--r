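#' Fit the heart-rate dependence of complexity values
#'
#' Bins per-strip complexity values into heart-rate bins (default 5 bpm),
#' takes the mean per bin, and fits least-squares polynomials of degree 2,
#' 3 and 4 to the binned means. The degree is selected by
#' `AIC = n * ln(RSS/n) + 2k` (k = number of coefficients); ties go to the
#' lower degree. Degrees that the number of bins cannot support are
#' skipped.
#'
#' @param points Data.frame with columns `mean_hr` (bpm) and `value`
#'   (normalised complexity); at least 6 rows spanning at least 3 distinct
#'   heart rates.
#' @param degrees Candidate polynomial degrees.
#' @param bin_width Heart-rate bin width (bpm).
#' @param aicc Use the small-sample corrected criterion instead.
#' @return An object of class `hr_polynomial`: degree, raw-polynomial
#'   `coefficients` (intercept first), per-degree `aic`, fitted `hr_range`.
#' @export
fit_hr_polynomial <- function(points, degrees = 2:4, bin_width = 5,
                              aicc = FALSE) {
  stopifnot(is.data.frame(points), all(c("mean_hr", "value") %in% names(points)))
  if (nrow(points) < 6L || length(unique(points$mean_hr)) < 3L)
    stop("fit_hr_polynomial: need >= 6 points spanning >= 3 distinct heart rates")
  bin <- floor(points$mean_hr / bin_width)
  agg <- stats::aggregate(list(hr = points$mean_hr, value = points$value),
                          list(bin = bin), mean)
  nb <- nrow(agg)
  # floor essentially-exact fits so the parameter penalty breaks the tie
  rss_floor <- 1e-16 * sum((agg$value - mean(agg$value))^2) + 1e-300
  fits <- list(); aics <- c()
  for (d in degrees) {
    if (nb < d + 1L) next
    fit <- stats::lm(value ~ poly(hr, d, raw = TRUE), data = agg)
    rss <- max(sum(stats::residuals(fit)^2), rss_floor)
    k <- d + 1
    aic <- nb * log(rss / nb) + 2 * k
    if (aicc) aic <- aic + 2 * k * (k + 1) / max(nb - k - 1, 1)
    fits[[as.character(d)]] <- fit
    aics[as.character(d)] <- aic
  }
  if (!length(fits)) stop("fit_hr_polynomial: too few heart-rate bins for any candidate degree")
  best <- names(aics)[which.min(aics)]     # which.min takes the first (lowest degree) on ties
  structure(list(degree = as.integer(best),
                 coefficients = unname(stats::coef(fits[[best]])),
                 aic = aics,
                 hr_range = range(points$mean_hr),
                 bin_width = bin_width),
            class = "hr_polynomial")
}

#' @export
print.hr_polynomial <- function(x, ...) {
  cat(sprintf("<hr_polynomial degree %d, fitted on HR %.1f-%.1f bpm>\n",
              x$degree, x$hr_range[1], x$hr_range[2]))
  invisible(x)
}

#' @param object An `hr_polynomial`.
#' @param newdata Numeric heart rates (bpm).
#' @param ... Unused.
#' @rdname fit_hr_polynomial
#' @export
predict.hr_polynomial <- function(object, newdata, ...) {
  hr <- as.numeric(newdata)
  co <- object$coefficients
  v <- rep(co[1], length(hr))
  for (p in seq_along(co)[-1]) v <- v + co[p] * hr^(p - 1)
  v
}

#' Subtract the fitted heart-rate trend
#'
#' Corrected complexity = value - polynomial(mean HR), keeping the
#' bit/sample units. Points outside the fitted heart-rate range are
#' extrapolated (logged).
#'
#' @param points Data.frame with `mean_hr` and `value` columns.
#' @param poly An `hr_polynomial` from [fit_hr_polynomial()].
#' @return `points` with an added `corrected` column.
#' @export
correct_hr <- function(points, poly) {
  stopifnot(inherits(poly, "hr_polynomial"))
  out <- sum(points$mean_hr < poly$hr_range[1] | points$mean_hr > poly$hr_range[2])
  if (out > 0)
    message("correct_hr: ", out, " point(s) outside the fitted HR range (extrapolating)")
  points$corrected <- points$value - predict(poly, points$mean_hr)
  points
}

#' Per-subject mean corrected complexity
#'
#' Averages heart-rate-corrected complexity over each subject's strips and
#' attaches the case/control label.
#'
#' @param points Data.frame with `subject_id` and `corrected` columns, and
#'   either a `label` column or a separate `labels` lookup.
#' @param labels Optional data.frame `subject_id, label`.
#' @return Data.frame `subject_id, label, score, n_strips`.
#' @export
subject_score <- function(points, labels = NULL) {
  stopifnot(is.data.frame(points),
            all(c("subject_id", "corrected") %in% names(points)))
  sc <- stats::aggregate(list(score = points$corrected),
                         list(subject_id = points$subject_id), mean)
  ns <- stats::aggregate(list(n_strips = points$corrected),
                         list(subject_id = points$subject_id), length)
  sc <- merge(sc, ns, by = "subject_id")
  if (is.null(labels)) {
    if (!"label" %in% names(points))
      stop("subject_score: no labels available")
    labels <- unique(points[, c("subject_id", "label")])
  }
  sc <- merge(sc, labels[, c("subject_id", "label")], by = "subject_id",
              all.x = TRUE)
  if (any(is.na(sc$label) | !sc$label %in% c("case", "control")))
    stop("subject_score: unknown label for subject(s): ",
         paste(sc$subject_id[is.na(sc$label) | !sc$label %in% c("case", "control")],
               collapse = ", "))
  sc[, c("subject_id", "label", "score", "n_strips")]
}
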