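#' Beat template parameters
#'
#' Parameters of the stylised single-lead beat model: each of the P, Q, R,
#' S, T waves is a Gaussian bump with an amplitude (mV), a centre offset
#' from the R peak (s; R fixed at 0) and a width (s). The defaults imitate
#' a base-apex-style equine waveform with a dominant positive R deflection.
#'
#' @param p,q,r,s,t Numeric vectors `c(amplitude, centre, width)` per wave.
#' @return A list of class `beat_template_params`.
#' @export
beat_template_params <- function(p = c(0.20, -0.26, 0.035),
                                 q = c(-0.12, -0.040, 0.012),
                                 r = c(1.00, 0.000, 0.016),
                                 s = c(-0.25, 0.035, 0.014),
                                 t = c(0.35, 0.22, 0.050)) {
  waves <- list(P = p, Q = q, R = r, S = s, T = t)
  for (w in names(waves)) {
    if (length(waves[[w]]) != 3L || !is.numeric(waves[[w]]))
      stop("beat_template_params: wave ", w, " must be c(amplitude, centre, width)")
    if (waves[[w]][3] <= 0)
      stop("beat_template_params: wave ", w, " width must be > 0")
  }
  amps <- vapply(waves, `[`, numeric(1), 1L)
  if (any(abs(amps["R"]) < abs(amps[c("Q", "S")])))
    stop("beat_template_params: R amplitude must dominate Q and S in magnitude")
  if (waves$T[3] <= max(waves$Q[3], waves$R[3], waves$S[3]))
    stop("beat_template_params: T width must exceed the QRS wave widths")
  structure(waves, class = "beat_template_params")
}

# fiducial thresholds, shared by ground truth and annotation:
# on/offsets are crossings of 5% of the beat peak-to-peak range; T end is the
# 5%-of-T-amplitude decay point
.FID_AMP_FRAC <- 0.05

# Brute-force fiducial scan over a densely sampled clean beat waveform.
# v: samples; tt: times relative to R centre; returns NULL when no beat.
.scan_fiducials <- function(v, tt, rate) {
  ptp <- max(v) - min(v)
  if (ptp <= 0) return(NULL)                       # flat: no beat
  pol <- if (abs(max(v)) >= abs(min(v))) 1 else -1
  r_idx <- which.max(pol * v)
  thr <- .FID_AMP_FRAC * ptp
  win <- function(lo_s, hi_s) {
    i <- which(tt >= lo_s & tt <= hi_s)
    i[i > 0 & i <= length(v)]
  }
  qw <- win(-0.15, tt[r_idx] - 1 / rate)
  if (!length(qw)) return(NULL)
  q_pk <- qw[which.min(pol * v[qw])]
  below <- which(abs(v) < thr)
  qon_cand <- below[below < q_pk]
  if (!length(qon_cand)) return(NULL)
  q_on <- max(qon_cand)
  sw <- win(tt[r_idx] + 1 / rate, 0.15)
  if (!length(sw)) return(NULL)
  s_pk <- sw[which.min(pol * v[sw])]
  after <- which(abs(v) < thr)
  qe_cand <- after[after > s_pk]
  if (!length(qe_cand)) return(NULL)
  qrs_end <- min(qe_cand)
  tw <- which(seq_along(v) > qrs_end + round(0.05 * rate))
  if (!length(tw)) return(NULL)
  t_pk <- tw[which.max(abs(v[tw]))]
  t_amp <- abs(v[t_pk])
  if (t_amp <= 2 * thr) return(NULL)               # no usable T wave
  dec <- which(abs(v) < .FID_AMP_FRAC * t_amp)
  te_cand <- dec[dec > t_pk]
  if (!length(te_cand)) return(NULL)
  t_end <- min(te_cand)
  fid <- c(q_onset = q_on, q_peak = q_pk, r_peak = r_idx,
           qrs_end = qrs_end, t_peak = t_pk, t_end = t_end)
  if (any(diff(fid) <= 0)) return(NULL)
  fid
}

# Evaluate the sum-of-Gaussians template on a time grid (times relative to R)
.template_eval <- function(params, tt) {
  v <- numeric(length(tt))
  for (w in params) v <- v + w[1] * exp(-((tt - w[2])^2) / (2 * w[3]^2))
  v
}

#' Generate a single beat template
#'
#' Samples the five-bump beat model at a given rate and locates the six
#' fiducial markers (Q onset, Q peak, R peak, QRS end, T peak, T end) by a
#' direct scan of the dense waveform. Onsets/offsets are crossings of 5% of
#' the beat's peak-to-peak range; T end is where the T deflection decays
#' below 5% of the T-peak amplitude.
#'
#' @param params A [beat_template_params()] object.
#' @param rate Sampling rate in Hz (> 0).
#' @return List with `waveform`, `time` (s, R at 0), `fiducials` (named
#'   sample indices, or `NULL` with `has_beat = FALSE` for a flat template).
#' @export
generate_beat_template <- function(params = beat_template_params(), rate = 500) {
  if (!inherits(params, "beat_template_params"))
    stop("generate_beat_template: params must be beat_template_params()")
  if (rate <= 0) stop("generate_beat_template: rate must be > 0")
  centres <- vapply(params, `[`, numeric(1), 2L)
  widths <- vapply(params, `[`, numeric(1), 3L)
  lo <- min(centres - 4 * widths)
  hi <- max(centres + 4 * widths)
  tt <- seq(lo, hi, by = 1 / rate)
  v <- .template_eval(params, tt)
  fid <- .scan_fiducials(v, tt, rate)
  list(waveform = v, time = tt, fiducials = fid, has_beat = !is.null(fid))
}

#' Subject simulation parameters
#'
#' Parameters of one simulated recording. The heart-rate trajectory may be a
#' constant (bpm) or a `data.frame(time, bpm)` interpolated linearly; all
#' rates must stay within 25-200 bpm. The beat-to-beat fiducial timing
#' jitter (`fiducial_jitter_sd`, s) perturbs wave centres per beat and is
#' the knob that sets waveform complexity; when `effect_hr_threshold` is
#' set, `fiducial_jitter_sd_above` replaces it for beats whose nominal
#' instantaneous rate exceeds the threshold.
#'
#' @param subject_id Subject identifier.
#' @param label `"case"`, `"control"` or `NA`.
#' @param duration_s Recording duration (s).
#' @param hr Constant bpm or `data.frame(time, bpm)`.
#' @param rr_jitter_sd Beat-to-beat RR jitter sd, fraction of the nominal RR.
#' @param ectopic_rate Ectopic beats per minute.
#' @param ectopic_prematurity Prematurity of ectopics, fraction of the local
#'   RR (>= 0.35 so ectopics always violate the 30% RR exclusion rule).
#' @param fiducial_jitter_sd Per-beat timing jitter sd (s) of the P, Q, S, T
#'   wave centres.
#' @param fiducial_jitter_sd_above Jitter sd used above `effect_hr_threshold`.
#' @param effect_hr_threshold Optional bpm threshold gating the jitter switch.
#' @param amp_jitter_sd Per-beat multiplicative amplitude jitter sd (fraction).
#' @param qt_rr_slope Shift of the T-wave centre per second of RR deviation
#'   from `rr_ref` (dimensionless), imitating rate adaptation of the QT
#'   interval.
#' @param rr_ref Reference RR (s) for the T-centre adaptation.
#' @param wander_amp,wander_freq Baseline wander amplitude (mV) and
#'   frequency (Hz).
#' @param noise_sd Additive measurement noise sd (mV).
#' @param fs Native sampling rate (Hz, >= 250).
#' @param template A [beat_template_params()] object.
#' @param seed Integer random seed.
#' @return A list of class `subject_sim_params`.
#' @export
subject_sim_params <- function(subject_id = "S1", label = NA_character_,
                               duration_s = 150, hr = 75,
                               rr_jitter_sd = 0.04,
                               ectopic_rate = 0, ectopic_prematurity = 0.40,
                               fiducial_jitter_sd = 0.020,
                               fiducial_jitter_sd_above = NULL,
                               effect_hr_threshold = NULL,
                               amp_jitter_sd = 0.05,
                               qt_rr_slope = 0.25, rr_ref = 0.8,
                               wander_amp = 0.15, wander_freq = 0.25,
                               noise_sd = 0.02, fs = 500,
                               template = beat_template_params(),
                               seed = 1L) {
  num_ok <- function(x) is.numeric(x) && all(x >= 0)
  if (!num_ok(rr_jitter_sd) || !num_ok(ectopic_rate) ||
      !num_ok(fiducial_jitter_sd) || !num_ok(amp_jitter_sd) ||
      !num_ok(wander_amp) || !num_ok(noise_sd))
    stop("subject_sim_params: rates and standard deviations must be >= 0")
  if (fs < 250) stop("subject_sim_params: native sampling rate must be >= 250 Hz")
  hr_vals <- if (is.data.frame(hr)) hr$bpm else hr
  if (any(hr_vals < 25 | hr_vals > 200))
    stop("subject_sim_params: heart rate trajectory must stay within 25-200 bpm")
  if (ectopic_rate > 0 && ectopic_prematurity < 0.35)
    stop("subject_sim_params: ectopic prematurity must be >= 0.35")
  structure(list(subject_id = subject_id, label = label,
                 duration_s = duration_s, hr = hr,
                 rr_jitter_sd = rr_jitter_sd, ectopic_rate = ectopic_rate,
                 ectopic_prematurity = ectopic_prematurity,
                 fiducial_jitter_sd = fiducial_jitter_sd,
                 fiducial_jitter_sd_above = fiducial_jitter_sd_above,
                 effect_hr_threshold = effect_hr_threshold,
                 amp_jitter_sd = amp_jitter_sd,
                 qt_rr_slope = qt_rr_slope, rr_ref = rr_ref,
                 wander_amp = wander_amp, wander_freq = wander_freq,
                 noise_sd = noise_sd, fs = fs, template = template,
                 seed = as.integer(seed)),
            class = "subject_sim_params")
}

.hr_at <- function(hr, t) {
  if (is.data.frame(hr)) {
    stats::approx(hr$time, hr$bpm, xout = t, rule = 2)$y
  } else rep(hr, length(t))
}

# per-beat template with jittered wave centres/amplitudes and rate-adapted T
.jitter_template <- function(base, jit_sd, amp_sd, rr, qt_slope, rr_ref,
                             ectopic = FALSE) {
  tpl <- unclass(base)
  # timing jitter acts mainly on the slow waves (P, T); the tightly coupled
  # intra-QRS timings (Q, S) vary a quarter as much
  for (w in c("P", "Q", "S", "T")) {
    if (jit_sd > 0) {
      sdw <- if (w %in% c("Q", "S")) 0.25 * jit_sd else jit_sd
      tpl[[w]][2] <- tpl[[w]][2] + stats::rnorm(1, 0, sdw)
    }
  }
  if (amp_sd > 0) {
    for (w in names(tpl)) tpl[[w]][1] <- tpl[[w]][1] * (1 + stats::rnorm(1, 0, amp_sd))
  }
  # rate adaptation: the T centre follows RR (QT shortening at speed) and the
  # P wave keeps a roughly proportional PR interval, both clamped so waves
  # stay clear of their neighbours at the band edges
  tpl$T[2] <- min(tpl$T[2] + qt_slope * (rr - rr_ref), 0.6 * rr)
  tpl$P[2] <- tpl$P[2] * min(max(rr / rr_ref, 0.75), 1.3)
  if (ectopic) {
    tpl$P[1] <- 0                      # no sinus P wave
    tpl$Q[3] <- tpl$Q[3] * 1.4         # broadened, altered QRS-T morphology
    tpl$R[3] <- tpl$R[3] * 1.4
    tpl$S[3] <- tpl$S[3] * 1.4
    tpl$R[1] <- tpl$R[1] * 1.6         # large so the detector cannot miss it
    tpl$T[1] <- -0.8 * tpl$T[1]
  }
  class(tpl) <- "beat_template_params"
  tpl
}

#' Generate a synthetic single-lead ECG with ground truth
#'
#' Builds a beat schedule from the heart-rate trajectory with log-free
#' multiplicative RR jitter, inserts premature ectopic beats at the
#' configured rate, renders every beat from its own jittered template,
#' adds sinusoidal baseline wander and white measurement noise, and
#' returns the exact fiducial indices of each clean beat.
#'
#' @param sim A [subject_sim_params()] object.
#' @return List with `signal` (an [ecg_signal()]) and `ground_truth`
#'   (data.frame: beat, q_onset, q_peak, r_peak, qrs_end, t_peak, t_end,
#'   ectopic; 1-based indices at the native rate).
#' @export
generate_ecg <- function(sim) {
  if (!inherits(sim, "subject_sim_params"))
    stop("generate_ecg: sim must be subject_sim_params()")
  if (sim$duration_s < 60 / max(.hr_at(sim$hr, 0), 1))
    stop("generate_ecg: duration must cover at least one beat")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(sim$seed)

  fs <- sim$fs
  n <- round(sim$duration_s * fs)
  tgrid_end <- (n - 1) / fs

  # --- beat schedule -------------------------------------------------------
  beats <- list()                      # (time, rr_nominal, ectopic)
  t_beat <- 0.45                       # first R, clear of the record start
  while (t_beat < sim$duration_s - 0.65) {
    hr_now <- .hr_at(sim$hr, t_beat)
    rr_nom <- 60 / hr_now
    beats[[length(beats) + 1L]] <- list(time = t_beat, rr_nom = rr_nom,
                                        ectopic = FALSE)
    rr <- rr_nom * (1 + stats::rnorm(1, 0, sim$rr_jitter_sd))
    rr <- max(rr, 0.3 * rr_nom)
    # premature ectopic between this sinus beat and the next one
    if (sim$ectopic_rate > 0 &&
        stats::runif(1) < sim$ectopic_rate * rr_nom / 60) {
      t_ect <- t_beat + (1 - sim$ectopic_prematurity) * rr
      if (t_ect < sim$duration_s - 0.65)
        beats[[length(beats) + 1L]] <- list(time = t_ect, rr_nom = rr_nom,
                                            ectopic = TRUE)
    }
    t_beat <- t_beat + rr
  }
  if (!length(beats)) stop("generate_ecg: no beats fit into the duration")

  # --- render --------------------------------------------------------------
  v <- numeric(n)
  gt <- vector("list", length(beats))
  for (b in seq_along(beats)) {
    bt <- beats[[b]]
    hr_now <- .hr_at(sim$hr, bt$time)
    jit <- sim$fiducial_jitter_sd
    if (!is.null(sim$effect_hr_threshold) && hr_now > sim$effect_hr_threshold &&
        !is.null(sim$fiducial_jitter_sd_above))
      jit <- sim$fiducial_jitter_sd_above
    tpl <- .jitter_template(sim$template, jit, sim$amp_jitter_sd, bt$rr_nom,
                            sim$qt_rr_slope, sim$rr_ref, bt$ectopic)
    centres <- vapply(tpl, `[`, numeric(1), 2L)
    widths <- vapply(tpl, `[`, numeric(1), 3L)
    lo <- bt$time + min(centres - 4 * widths)
    hi <- bt$time + max(centres + 4 * widths)
    i0 <- max(1L, floor(lo * fs) + 1L)
    i1 <- min(n, ceiling(hi * fs) + 1L)
    if (i1 <= i0) next
    idx <- i0:i1
    tt <- (idx - 1) / fs - bt$time
    bw <- .template_eval(tpl, tt)
    v[idx] <- v[idx] + bw
    fid <- .scan_fiducials(bw, tt, fs)
    if (!is.null(fid)) {
      gt[[b]] <- data.frame(beat = b, t(fid + i0 - 1L), ectopic = bt$ectopic)
    }
  }
  gt <- do.call(rbind, gt[!vapply(gt, is.null, logical(1))])
  if (is.null(gt) || !nrow(gt)) stop("generate_ecg: no annotatable beats generated")
  gt$beat <- seq_len(nrow(gt))

  tg <- (seq_len(n) - 1) / fs
  if (sim$wander_amp > 0)
    v <- v + sim$wander_amp * sin(2 * pi * sim$wander_freq * tg)
  if (sim$noise_sd > 0)
    v <- v + stats::rnorm(n, 0, sim$noise_sd)

  list(signal = ecg_signal(v, fs, subject_id = sim$subject_id, label = sim$label),
       ground_truth = gt)
}

#' Generate a labelled case/control cohort
#'
#' Simulates `n_cases + n_controls` recordings. Controls use the baseline
#' simulation parameters; cases receive `effect` added to the fiducial
#' timing jitter sd (negative effects reduce beat-to-beat waveform
#' variability, i.e. lower complexity). When `effect_hr_threshold` is
#' given, the case effect applies only to beats above that rate.
#'
#' @param n_cases,n_controls Non-negative cohort sizes.
#' @param effect Additive change (s) to the case fiducial jitter sd.
#' @param seed Integer seed; each subject derives its own sub-seed.
#' @param base A [subject_sim_params()] template for all subjects.
#' @param effect_hr_threshold Optional bpm gate for the case effect.
#' @param hr_range Optional length-2 range: each subject's constant heart
#'   rate is drawn uniformly from it (deterministically from `seed`),
#'   giving the cohort a realistic spread of strip heart rates. Ignored
#'   when `NULL` (all subjects then share `base$hr`).
#' @return List of recordings, each `list(signal, ground_truth, label,
#'   subject_id)`.
#' @export
generate_cohort <- function(n_cases, n_controls, effect = -0.015,
                            seed = 1L, base = subject_sim_params(),
                            effect_hr_threshold = NULL, hr_range = NULL) {
  if (n_cases < 0 || n_controls < 0)
    stop("generate_cohort: cohort sizes must be >= 0")
  labels <- c(rep("case", n_cases), rep("control", n_controls))
  subject_hr <- NULL
  if (!is.null(hr_range)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    subject_hr <- stats::runif(length(labels), hr_range[1], hr_range[2])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    sim <- base
    sim$subject_id <- sprintf("%s%02d", ifelse(labels[i] == "case", "CA", "CO"), i)
    sim$label <- labels[i]
    if (!is.null(subject_hr)) sim$hr <- subject_hr[i]
    sim$seed <- as.integer((seed * 10007L + i * 131L) %% .Machine$integer.max)
    if (labels[i] == "case") {
      case_sd <- max(base$fiducial_jitter_sd + effect, 0)
      if (is.null(effect_hr_threshold)) {
        sim$fiducial_jitter_sd <- case_sd
      } else {
        sim$effect_hr_threshold <- effect_hr_threshold
        sim$fiducial_jitter_sd_above <- case_sd
      }
    }
    class(sim) <- "subject_sim_params"
    rec <- generate_ecg(sim)
    out[[i]] <- list(signal = rec$signal, ground_truth = rec$ground_truth,
                     label = labels[i], subject_id = sim$subject_id)
  }
  out
}

#' Rescale ground-truth indices to another sampling rate
#'
#' @param gt Ground-truth data.frame from [generate_ecg()].
#' @param from,to Source and target sampling rates (Hz).
#' @return The data.frame with index columns mapped to the target rate.
#' @export
rescale_ground_truth <- function(gt, from, to) {
  cols <- c("q_onset", "q_peak", "r_peak", "qrs_end", "t_peak", "t_end")
  for (cc in cols) gt[[cc]] <- round((gt[[cc]] - 1) * to / from) + 1
  gt
}
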