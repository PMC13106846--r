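test_that("R detection: flat signal yields no peaks, clean ECG hits ground truth", {
  expect_identical(detect_r_peaks(ecg_signal(rep(0, 1000), 125)), integer(0))
  expect_error(detect_r_peaks(ecg_signal(rnorm(100), 125)), "2 s")

  fx <- fixture_noiseless()
  pk <- fx$peaks
  gt <- fx$gt125
  expect_lt(abs(length(pk) - nrow(gt)), 2)
  d <- vapply(gt$r_peak, function(r) min(abs(pk - r)), numeric(1))
  expect_true(all(d <= 2))                       # within 16 ms at 125 Hz
})

test_that("R detection stays reliable at 10% noise", {
  sim <- subject_sim_params(duration_s = 60, hr = 65, seed = 21, noise_sd = 0.1)
  rec <- generate_ecg(sim)
  s125 <- resample_ecg(rec$signal, 125)
  pk <- detect_r_peaks(s125)
  gt <- rescale_ground_truth(rec$ground_truth, 500, 125)
  d <- vapply(gt$r_peak, function(r) min(abs(pk - r)), numeric(1))
  expect_gte(mean(d <= 3), 0.95)
})

test_that("segment scan accepts stable windows and respects the band and 30% rule", {
  # constant RR = 1 s: every 60-s window qualifies; expect 3 disjoint strips
  sim <- subject_sim_params(duration_s = 183, hr = 60, rr_jitter_sd = 0,
                            noise_sd = 0, wander_amp = 0,
                            fiducial_jitter_sd = 0, amp_jitter_sd = 0, seed = 2)
  rec <- generate_ecg(sim)
  s125 <- resample_ecg(rec$signal, 125)
  pk <- detect_r_peaks(s125)
  strips <- find_segments(s125, pk, 30, 120)
  expect_length(strips, 3)
  # pairwise disjoint
  iv <- vapply(strips, function(s) s$start, numeric(1))
  expect_true(all(diff(iv) >= 7500))
  # band exclusion: a 125 bpm recording yields nothing in 30-120
  sim2 <- subject_sim_params(duration_s = 70, hr = 125, seed = 3)
  rec2 <- generate_ecg(sim2)
  s2 <- resample_ecg(rec2$signal, 125)
  expect_length(find_segments(s2, detect_r_peaks(s2), 30, 120), 0)
  expect_error(find_segments(s2, integer(0), 120, 30), "hr_lo")
})

test_that("a single shortened RR poisons every window containing it", {
  # synthetic peak train: RR 1 s with one 0.5 s interval in the middle minute
  fs <- 125
  r <- cumsum(c(1, rep(1, 179))) * fs
  r <- as.integer(r)
  bad_at <- 90
  r[(bad_at + 1):length(r)] <- r[(bad_at + 1):length(r)] - as.integer(0.5 * fs)
  sig <- ecg_signal(rep(0.01 * sin(1:(186 * fs)), 1), fs)   # carrier, peaks given
  strips <- find_segments(sig, r, 30, 120)
  # no accepted strip may contain the short interval's flanking beats
  short_pos <- r[bad_at:(bad_at + 1)]
  for (st in strips) {
    inside <- short_pos >= st$start & short_pos < st$start + 7500
    expect_false(all(inside))
  }
  # direct rule evaluation: the window starting at the first beat and holding
  # the short RR violates the 30% criterion
  w <- r[r >= r[31] & r < r[31] + 7500]
  rr <- diff(w) / fs
  expect_true(any(abs(rr - mean(rr)) >= 0.3 * mean(rr)))
})

test_that("strip invariants hold on random synthetic recordings", {
  set.seed(77)
  for (i in 1:8) {
    hr <- sample(45:105, 1)
    sim <- subject_sim_params(duration_s = 80, hr = hr, seed = 1000 + i,
                              ectopic_rate = sample(c(0, 3), 1))
    rec <- generate_ecg(sim)
    s125 <- resample_ecg(rec$signal, 125)
    strips <- find_segments(s125, detect_r_peaks(s125), 30, 120)
    for (st in strips) {
      expect_length(st$samples, 7500)
      expect_gte(length(st$r_peaks), 2)
      rr <- diff(st$r_peaks) / 125
      expect_true(all(abs(rr - mean(rr)) < 0.3 * mean(rr)))
      expect_gte(st$mean_hr, 30)
      expect_lte(st$mean_hr, 120)
    }
  }
})

test_that("premature ectopics never survive inside accepted strips", {
  set.seed(42)
  found_ect <- 0L; n_strips <- 0L
  for (i in 1:6) {
    sim <- subject_sim_params(duration_s = 140, hr = sample(55:90, 1),
                              seed = 2000 + i, ectopic_rate = 1)
    rec <- generate_ecg(sim)
    ect <- rescale_ground_truth(rec$ground_truth, 500, 125)
    ect <- ect$r_peak[ect$ectopic]
    s125 <- resample_ecg(rec$signal, 125)
    strips <- find_segments(s125, detect_r_peaks(s125), 30, 120)
    n_strips <- n_strips + length(strips)
    for (st in strips)
      found_ect <- found_ect + sum(ect >= st$start & ect < st$start + 7500)
  }
  expect_identical(found_ect, 0L)
})

test_that("baseline removal eliminates most injected wander and is benign without it", {
  fx <- fixture_noiseless()
  strips <- find_segments(fx$s125, fx$peaks, 30, 120)
  st <- strips[[1]]
  # zero-baseline strip: knot values are ~0, output ~input
  clean <- remove_baseline(st)
  knots <- floor((st$r_peaks[-length(st$r_peaks)] + st$r_peaks[-1]) / 2)
  expect_lt(max(abs(clean$samples[knots] - st$samples[knots])), 0.02)

  # inject 0.5 mV, 0.15 Hz wander and check residual power
  tt <- (seq_along(st$samples) - 1) / 125
  wander <- 0.5 * sin(2 * pi * 0.15 * tt)
  st2 <- st; st2$samples <- st$samples + wander
  out <- remove_baseline(st2)
  resid <- out$samples - st$samples
  # compare power at the wander frequency band
  pw <- function(x) {
    sp <- stats::spec.pgram(stats::ts(x - mean(x), frequency = 125),
                            plot = FALSE, taper = 0, detrend = FALSE)
    sum(sp$spec[sp$freq < 0.5])
  }
  expect_lt(pw(resid) / pw(wander), 0.10)
})

test_that("baseline removal boundary cases: 3 beats run, fewer knots fall back", {
  fx <- fixture_noiseless()
  strips <- find_segments(fx$s125, fx$peaks, 30, 120)
  st <- strips[[1]]
  st3 <- st; st3$r_peaks <- st$r_peaks[1:3]       # exactly 2 knots
  expect_s3_class(remove_baseline(st3), "ecg_strip")
  st2 <- st; st2$r_peaks <- st$r_peaks[1:2]       # 1 knot -> median fallback
  expect_message(remove_baseline(st2), "median")
})

test_that("strip heart rate is 60 over the mean RR", {
  st <- ecg_strip(rep(0, 1000), 125, 1, c(1, 126, 251), "s")
  expect_equal(strip_heart_rate(st), 60)
  st2 <- ecg_strip(rep(0, 1000), 125, 1, as.integer(c(1, 1 + 125 * 0.8,
                                                      1 + 125 * 1.8, 1 + 125 * 3.0)), "s")
  expect_equal(strip_heart_rate(st2), 60 / 1.0)
  st3 <- st; st3$r_peaks <- 1L
  expect_error(strip_heart_rate(st3), "2 R peaks")
})
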