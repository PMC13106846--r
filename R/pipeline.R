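#' Complexity table for one recording
#'
#' Runs the strip-level pipeline on a single recording: down-sample to the
#' analysis rate, detect R peaks, extract artefact-free 60-s strips in the
#' heart-rate band, remove baseline wander, annotate fiducials, build the
#' TC string and the FD string set, and evaluate the requested estimators.
#' Strips whose annotation fails are skipped (logged).
#'
#' @param rec A recording: `list(signal, label, subject_id)` as produced by
#'   [generate_cohort()], or an [ecg_signal()].
#' @param hr_lo,hr_hi Extraction heart-rate band (bpm).
#' @param estimators Subset of LZ76, LZ78, Titchener, Shannon, ApEn, SampEn.
#' @param masks FD mask codes to evaluate (default all 63).
#' @param include_tc Also evaluate symbolic estimators on the TC string.
#' @param target_rate Analysis sampling rate (Hz).
#' @param rr_dev,duration_s Passed to [find_segments()].
#' @param entropy [entropy_params()] for ApEn/SampEn.
#' @param peaks Optional precomputed R peaks (at `target_rate`).
#' @param signal125 Optional precomputed down-sampled signal.
#' @param cache Optional environment memoising per-strip results across
#'   repeated calls (used by the heart-rate-band sweep).
#' @return Data.frame: subject_id, label, start, mean_hr, estimator,
#'   scheme, mask, raw, normalised, n.
#' @export
analyse_recording <- function(rec, hr_lo = 30, hr_hi = 120,
                              estimators = c("LZ76", "Titchener"),
                              masks = 1:63, include_tc = TRUE,
                              target_rate = 125, rr_dev = 0.30,
                              duration_s = 60, entropy = entropy_params(),
                              peaks = NULL, signal125 = NULL, cache = NULL) {
  sig <- if (inherits(rec, "ecg_signal")) rec else rec$signal
  if (is.null(signal125)) signal125 <- resample_ecg(sig, target_rate)
  if (is.null(peaks)) peaks <- detect_r_peaks(signal125)
  strips <- find_segments(signal125, peaks, hr_lo, hr_hi, rr_dev, duration_s)
  rows <- lapply(strips, function(strip) {
    key <- paste(strip$subject_id, strip$start, sep = "@")
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    res <- tryCatch(.strip_complexity(strip, estimators, masks, include_tc,
                                      entropy),
                    error = function(e) {
                      message("analyse_recording: skipping strip at ",
                              strip$start, ": ", conditionMessage(e))
                      NULL
                    })
    if (!is.null(cache) && !is.null(res)) cache[[key]] <- res
    res
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(subject_id = character(), label = character(),
                      start = integer(), mean_hr = numeric(),
                      estimator = character(), scheme = character(),
                      mask = integer(), raw = numeric(),
                      normalised = numeric(), n = integer()))
  }
  do.call(rbind, rows)
}

.strip_complexity <- function(strip, estimators, masks, include_tc, entropy) {
  strip <- remove_baseline(strip)
  ann <- suppressMessages(annotate_beats(strip))
  xd <- xd_string(ann, length(strip$samples))
  fds <- fd_strings(xd, masks)
  tc <- if (include_tc) tc_string(strip) else NULL
  symbolic <- intersect(estimators, c("LZ76", "LZ78", "Titchener", "Shannon"))
  raw_est <- intersect(estimators, c("ApEn", "SampEn"))
  out <- list()
  meta <- function(estimator, scheme, mask, val) {
    data.frame(subject_id = strip$subject_id, label = strip$label,
               start = strip$start, mean_hr = strip$mean_hr,
               estimator = val$estimator, scheme = scheme, mask = mask,
               raw = val$raw, normalised = val$normalised, n = val$n)
  }
  for (est in symbolic) {
    for (code in names(fds))
      out[[length(out) + 1L]] <-
        meta(est, "FD", as.integer(code), complexity_value(est, sym = fds[[code]]))
    if (!is.null(tc))
      out[[length(out) + 1L]] <- meta(est, "TC", NA_integer_,
                                      complexity_value(est, sym = tc))
  }
  for (est in raw_est)
    out[[length(out) + 1L]] <-
      meta(est, "RAW", NA_integer_,
           complexity_value(est, x = strip$samples, params = entropy))
  do.call(rbind, out)
}

#' Heart-rate correction and group comparison for every combination
#'
#' For each estimator x scheme x mask combination in a cohort complexity
#' table: fit the heart-rate polynomial on the full table (bin means, AIC
#' degree selection), subtract it, average per subject, and compare cases
#' to controls (Welch t-test + AUC).
#'
#' @param tbl Cohort complexity table ([analyse_recording()] rows bound
#'   together).
#' @param band Heart-rate band recorded in the comparison rows.
#' @param min_points Minimum strips per combination to attempt a fit.
#' @return List: `comparisons` (one row per combination), `scores` (named
#'   list of per-subject score tables), `polys` (fitted polynomials).
#' @export
evaluate_cohort <- function(tbl, band = c(NA_real_, NA_real_),
                            min_points = 6L) {
  stopifnot(is.data.frame(tbl), nrow(tbl) > 0)
  combos <- unique(tbl[, c("estimator", "scheme", "mask")])
  comparisons <- list(); scores <- list(); polys <- list()
  for (ci in seq_len(nrow(combos))) {
    sel <- tbl$estimator == combos$estimator[ci] &
      tbl$scheme == combos$scheme[ci] &
      (is.na(combos$mask[ci]) | (!is.na(tbl$mask) & tbl$mask == combos$mask[ci]))
    if (is.na(combos$mask[ci])) sel <- sel & is.na(tbl$mask)
    pts <- tbl[sel, ]
    pts$value <- pts$normalised
    key <- paste(combos$estimator[ci], combos$scheme[ci], combos$mask[ci], sep = ":")
    res <- tryCatch({
      poly <- tryCatch(fit_hr_polynomial(pts), error = function(e) {
        # narrow heart-rate spread (e.g. a tight sweep band): fall back to
        # mean-centring, i.e. a degree-0 trend
        structure(list(degree = 0L, coefficients = mean(pts$value),
                       aic = c(`0` = NA_real_),
                       hr_range = range(pts$mean_hr),
                       bin_width = NA_real_),
                  class = "hr_polynomial")
      })
      pts <- suppressMessages(correct_hr(pts, poly))
      sc <- subject_score(pts)
      cmp <- compare_groups(sc, estimator = combos$estimator[ci],
                            mask = combos$mask[ci], band = band)
      cmp$scheme <- combos$scheme[ci]
      list(cmp = cmp, sc = sc, poly = poly)
    }, error = function(e) NULL)
    if (is.null(res)) next
    comparisons[[key]] <- res$cmp
    scores[[key]] <- res$sc
    polys[[key]] <- res$poly
  }
  if (!length(comparisons))
    stop("evaluate_cohort: no combination could be evaluated")
  list(comparisons = do.call(rbind, c(comparisons, make.row.names = FALSE)),
       scores = scores, polys = polys)
}

#' Sweep the heart-rate band limits
#'
#' For every pair (lo, hi) with lo < hi from the supplied grids the cohort
#' strips are re-extracted in that band, complexity recomputed (memoised
#' per strip), heart-rate-corrected, scored per subject and compared
#' between groups; the sweep reports the median and minimum p-value and
#' the median and maximum AUC across the FD masks, per estimator.
#'
#' @param recordings Cohort list from [generate_cohort()].
#' @param lo_values,hi_values Band limit grids (bpm), non-empty.
#' @param estimators,masks,include_tc,target_rate,rr_dev,duration_s As in
#'   [analyse_recording()].
#' @return Data.frame of class `sweep_result`: estimator, hr_lo, hr_hi,
#'   n_strips, median_p, min_p, median_auc, max_auc (NA where a cell had
#'   an empty class or too few strips).
#' @export
hr_range_sweep <- function(recordings, lo_values, hi_values,
                           estimators = c("LZ76", "Titchener"),
                           masks = 1:63, include_tc = FALSE,
                           target_rate = 125, rr_dev = 0.30,
                           duration_s = 60) {
  if (!length(lo_values) || !length(hi_values))
    stop("hr_range_sweep: band grids must be non-empty")
  # down-sample and detect R peaks once per recording
  prep <- lapply(recordings, function(rec) {
    s <- resample_ecg(rec$signal, target_rate)
    list(rec = rec, signal125 = s, peaks = detect_r_peaks(s))
  })
  cache <- new.env(parent = emptyenv())
  cells <- list()
  for (lo in lo_values) for (hi in hi_values) {
    if (lo >= hi) next
    tbl <- do.call(rbind, lapply(prep, function(p)
      analyse_recording(p$rec, lo, hi, estimators, masks, include_tc,
                        target_rate, rr_dev, duration_s,
                        peaks = p$peaks, signal125 = p$signal125,
                        cache = cache)))
    for (est in estimators) {
      row <- data.frame(estimator = est, hr_lo = lo, hr_hi = hi,
                        n_strips = NA_integer_, median_p = NA_real_,
                        min_p = NA_real_, median_auc = NA_real_,
                        max_auc = NA_real_)
      sub <- tbl[tbl$estimator == est & tbl$scheme == "FD", ]
      if (nrow(sub)) {
        row$n_strips <- length(unique(paste(sub$subject_id, sub$start)))
        ev <- tryCatch(evaluate_cohort(sub, band = c(lo, hi)),
                       error = function(e) NULL)
        if (!is.null(ev)) {
          cmp <- ev$comparisons
          row$median_p <- stats::median(cmp$p)
          row$min_p <- min(cmp$p)
          row$median_auc <- stats::median(cmp$auc)
          row$max_auc <- max(cmp$auc)
        }
      }
      cells[[length(cells) + 1L]] <- row
    }
  }
  if (!length(cells)) stop("hr_range_sweep: no valid (lo, hi) cell in the grids")
  out <- do.call(rbind, cells)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Pipeline configuration
#'
#' Collects every knob of an end-to-end run in one list; [run_pipeline()]
#' consumes it. Simulation settings are used when no `recordings` are
#' supplied.
#'
#' @param n_cases,n_controls Simulated cohort sizes.
#' @param effect Case effect on the fiducial timing jitter sd (s).
#' @param hr_range Range subjects' constant heart rates are drawn from.
#' @param duration_s Recording duration (s).
#' @param band Analysis heart-rate band (bpm).
#' @param rr_dev RR deviation threshold for strip acceptance.
#' @param target_rate Analysis sampling rate (Hz).
#' @param estimators,masks,include_tc As in [analyse_recording()].
#' @param seed Integer seed for the whole run.
#' @param out_dir Optional output directory for run artefacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_cases = 10, n_controls = 30, effect = -0.015,
                            hr_range = c(60, 95), duration_s = 150,
                            band = c(30, 120), rr_dev = 0.30,
                            target_rate = 125,
                            estimators = c("LZ76", "Titchener"),
                            masks = 1:63, include_tc = TRUE, seed = 1L,
                            out_dir = NULL) {
  structure(list(n_cases = n_cases, n_controls = n_controls, effect = effect,
                 hr_range = hr_range, duration_s = duration_s, band = band,
                 rr_dev = rr_dev, target_rate = target_rate,
                 estimators = estimators, masks = masks,
                 include_tc = include_tc, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' simulate (unless recordings are given) -> extract -> annotate ->
#' complexity -> heart-rate correction -> per-subject scores -> group
#' evaluation and algorithm ranking. Every stage logs its in/out counts;
#' reruns with the same configuration and seed are deterministic. When
#' `config$out_dir` is set, the complexity table, comparison table,
#' ranking and subject scores of the top algorithm are written as CSV and
#' the run metadata as JSON.
#'
#' @param config A [pipeline_config()].
#' @param recordings Optional pre-existing cohort (list of
#'   `list(signal, label, subject_id)`), bypassing simulation.
#' @return List: `config`, `counts`, `table`, `comparisons`, `ranking`,
#'   `best`, `scores_best`.
#' @export
run_pipeline <- function(config = pipeline_config(), recordings = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(recordings)) {
    if (config$n_cases + config$n_controls == 0)
      stop("run_pipeline: empty input (no subjects configured)")
    message("run_pipeline: simulating ", config$n_cases, " cases + ",
            config$n_controls, " controls")
    base <- subject_sim_params(duration_s = config$duration_s)
    recordings <- generate_cohort(config$n_cases, config$n_controls,
                                  effect = config$effect, seed = config$seed,
                                  base = base, hr_range = config$hr_range)
  }
  if (!length(recordings)) stop("run_pipeline: empty input (no recordings)")
  message("run_pipeline: analysing ", length(recordings), " recordings")
  tbl <- do.call(rbind, lapply(recordings, function(rec)
    analyse_recording(rec, config$band[1], config$band[2],
                      config$estimators, config$masks, config$include_tc,
                      config$target_rate, config$rr_dev)))
  if (is.null(tbl) || !nrow(tbl))
    stop("run_pipeline: no strips extracted in the configured band")
  n_strips <- length(unique(paste(tbl$subject_id, tbl$start)))
  message("run_pipeline: ", n_strips, " strips, ", nrow(tbl),
          " complexity values")
  ev <- evaluate_cohort(tbl, band = config$band)
  ranking <- rank_algorithms(ev$comparisons)
  best_key <- paste(ranking$estimator[1], ranking$scheme[1], ranking$mask[1],
                    sep = ":")
  report <- list(config = config,
                 counts = list(recordings = length(recordings),
                               strips = n_strips, values = nrow(tbl),
                               combinations = nrow(ev$comparisons)),
                 table = tbl, comparisons = ev$comparisons,
                 ranking = ranking, best = best_key,
                 scores_best = ev$scores[[best_key]])
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tbl, file.path(config$out_dir, "complexity.csv"),
                     row.names = FALSE)
    utils::write.csv(ev$comparisons,
                     file.path(config$out_dir, "comparisons.csv"),
                     row.names = FALSE)
    utils::write.csv(ranking, file.path(config$out_dir, "ranking.csv"),
                     row.names = FALSE)
    utils::write.csv(report$scores_best,
                     file.path(config$out_dir, "subject_scores_best.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, band = config$band, best = best_key,
           counts = report$counts),
      file.path(config$out_dir, "run_report.json"), auto_unbox = TRUE)
  }
  report
}
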