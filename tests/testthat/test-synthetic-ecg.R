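test_that("beat template: flat, single-bump and default fiducials", {
  flat <- beat_template_params(p = c(0, -0.26, 0.035), q = c(0, -0.04, 0.012),
                               r = c(0, 0, 0.016), s = c(0, 0.035, 0.014),
                               t = c(0, 0.22, 0.05))
  tpl <- generate_beat_template(flat, 500)
  expect_false(tpl$has_beat)
  expect_true(all(tpl$waveform == 0))

  solo <- beat_template_params(p = c(0, -0.26, 0.035), q = c(0, -0.04, 0.012),
                               r = c(1, 0, 0.02), s = c(0, 0.035, 0.014),
                               t = c(0, 0.22, 0.05))
  tpl <- generate_beat_template(solo, 500)
  expect_equal(which.max(tpl$waveform), which.min(abs(tpl$time)))

  expect_error(beat_template_params(r = c(1, 0, -0.01)), "width")
  expect_error(beat_template_params(q = c(-2, -0.04, 0.012)), "dominate")
})

test_that("default template fiducials equal a brute-force scan of the dense waveform", {
  tpl <- generate_beat_template(beat_template_params(), 500)
  expect_true(tpl$has_beat)
  v <- tpl$waveform; tt <- tpl$time
  # independent exhaustive scan with the documented 5% threshold rules
  ptp <- max(v) - min(v); thr <- 0.05 * ptp
  r_idx <- which.max(v)
  qw <- which(tt >= -0.15 & tt < tt[r_idx])
  q_pk <- qw[which.min(v[qw])]
  q_on <- max(which(abs(v) < thr & seq_along(v) < q_pk))
  sw <- which(tt > tt[r_idx] & tt <= 0.15)
  s_pk <- sw[which.min(v[sw])]
  qrs_end <- min(which(abs(v) < thr & seq_along(v) > s_pk))
  tw <- which(seq_along(v) > qrs_end + round(0.05 * 500))
  t_pk <- tw[which.max(abs(v[tw]))]
  t_end <- min(which(abs(v) < 0.05 * abs(v[t_pk]) & seq_along(v) > t_pk))
  expect_equal(unname(tpl$fiducials),
               c(q_on, q_pk, r_idx, qrs_end, t_pk, t_end))
})

test_that("generated beat schedule matches the requested rate and is deterministic", {
  sim <- subject_sim_params(duration_s = 62, hr = 60, rr_jitter_sd = 0,
                            noise_sd = 0, wander_amp = 0,
                            fiducial_jitter_sd = 0, amp_jitter_sd = 0, seed = 2)
  rec <- generate_ecg(sim)
  rr <- diff(rec$ground_truth$r_peak) / 500
  expect_equal(length(rec$ground_truth$r_peak), 61)
  expect_true(all(abs(rr - 1.0) < 1e-9))

  rec2 <- generate_ecg(sim)
  expect_identical(rec$signal$samples, rec2$signal$samples)
  expect_identical(rec$ground_truth, rec2$ground_truth)
})

test_that("RR jitter reproduces the requested coefficient of variation", {
  sim <- subject_sim_params(duration_s = 610, hr = 60, rr_jitter_sd = 0.05,
                            noise_sd = 0, wander_amp = 0,
                            fiducial_jitter_sd = 0, amp_jitter_sd = 0, seed = 9)
  rec <- generate_ecg(sim)
  rr <- diff(rec$ground_truth$r_peak) / 500
  expect_gt(length(rr), 550)
  expect_lt(abs(sd(rr / mean(rr)) - 0.05), 0.01)
})

test_that("generated RR mean maps to the requested heart rate within 1%", {
  for (hr in c(40, 75, 110)) {
    sim <- subject_sim_params(duration_s = 60 / hr * 320, hr = hr, seed = hr,
                              noise_sd = 0, wander_amp = 0)
    rec <- generate_ecg(sim)
    rr <- diff(rec$ground_truth$r_peak[!rec$ground_truth$ectopic]) / 500
    expect_lt(abs(60 / mean(rr) - hr) / hr, 0.01)
  }
})

test_that("ground-truth fiducial ordering holds for every generated beat", {
  set.seed(3)
  for (i in 1:5) {
    sim <- subject_sim_params(duration_s = 40, hr = sample(c(40, 70, 100), 1),
                              seed = i, ectopic_rate = 2)
    gt <- generate_ecg(sim)$ground_truth
    m <- as.matrix(gt[, fid_cols])
    expect_true(all(apply(m, 1, function(r) all(diff(r) > 0))))
  }
})

test_that("heart rates outside 25-200 bpm are rejected", {
  expect_error(subject_sim_params(hr = 20), "25-200")
  expect_error(subject_sim_params(hr = 220), "25-200")
  expect_error(subject_sim_params(hr = data.frame(time = c(0, 10),
                                                  bpm = c(60, 210))), "25-200")
  expect_error(subject_sim_params(fs = 125), "250")
  expect_error(subject_sim_params(noise_sd = -1), ">= 0")
})

test_that("cohort generation labels subjects and applies the case effect", {
  coh <- generate_cohort(2, 3, effect = -0.01, seed = 6,
                         base = subject_sim_params(duration_s = 30))
  expect_length(coh, 5)
  expect_equal(vapply(coh, `[[`, character(1), "label"),
               c("case", "case", "control", "control", "control"))
  expect_error(generate_cohort(-1, 2), ">= 0")
  # determinism
  coh2 <- generate_cohort(2, 3, effect = -0.01, seed = 6,
                          base = subject_sim_params(duration_s = 30))
  expect_identical(coh[[1]]$signal$samples, coh2[[1]]$signal$samples)
})
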