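test_that("noiseless strips annotate within 3 samples of ground truth", {
  fx <- fixture_noiseless()
  sf <- fixture_strip()
  errs <- match_truth(sf$ann, fx$gt125, sf$raw_strip$start)
  expect_true(all(errs <= 3))
  expect_gte(nrow(sf$ann), length(sf$raw_strip$r_peaks) - 3)
})

test_that("fiducial ordering is monotone within and across annotated beats", {
  set.seed(55)
  checked <- 0L
  for (i in 1:6) {
    sim <- subject_sim_params(duration_s = 75, hr = sample(50:95, 1),
                              seed = 3000 + i)
    rec <- generate_ecg(sim)
    s125 <- resample_ecg(rec$signal, 125)
    strips <- find_segments(s125, detect_r_peaks(s125), 30, 120)
    for (st in strips) {
      ann <- suppressMessages(annotate_beats(remove_baseline(st)))
      m <- as.matrix(ann[, fid_cols])
      expect_true(all(apply(m, 1, function(r) all(diff(r) > 0))))
      if (nrow(ann) > 1)
        expect_true(all(ann$t_end[-nrow(ann)] < ann$q_onset[-1]))
      checked <- checked + nrow(ann)
    }
  }
  expect_gt(checked, 100)
})

test_that("a missing T wave flags beats and fails the strip", {
  tpl <- beat_template_params(t = c(0, 0.22, 0.05))   # T amplitude zero
  sim <- subject_sim_params(duration_s = 70, hr = 70, seed = 4, template = tpl,
                            noise_sd = 0, wander_amp = 0)
  expect_error(generate_ecg(sim), "no annotatable beats")
  # and on the annotation side: erase the T waves of a good strip
  sf <- fixture_strip()
  st <- sf$strip
  for (i in seq_len(nrow(sf$ann))) {
    hi <- min(sf$ann$t_end[i] + 3, length(st$samples))
    st$samples[(sf$ann$qrs_end[i] + 8):hi] <- 0
  }
  expect_error(suppressMessages(annotate_beats(st)), "no annotatable beats")
})

test_that("TC string thresholds at the median with ties counted as '1'", {
  expect_equal(as.character(tc_string(c(1, 2, 3, 4))), "0011")
  expect_equal(as.character(tc_string(c(1, 2, 2, 3))), "0111")
  set.seed(6)
  s <- tc_string(rnorm(501))
  ch <- strsplit(unclass(s), "")[[1]]
  expect_gte(sum(ch == "1"), sum(ch == "0"))
  sf <- fixture_strip()
  expect_equal(nchar(unclass(tc_string(sf$strip))), 7500)
})

test_that("XD string places the six marker symbols and zeros elsewhere", {
  ann <- data.frame(beat = 1, q_onset = 10, q_peak = 12, r_peak = 15,
                    qrs_end = 18, t_peak = 25, t_end = 32)
  xd <- xd_string(ann, 40)
  ch <- strsplit(unclass(xd), "")[[1]]
  expect_equal(ch[c(10, 12, 15, 18, 25, 32)], c("6", "7", "A", "G", "J", "L"))
  expect_true(all(ch[-c(10, 12, 15, 18, 25, 32)] == "0"))

  expect_equal(as.character(xd_string(ann[0, ], 12)), strrep("0", 12))

  ann2 <- rbind(ann, data.frame(beat = 2, q_onset = 32, q_peak = 33,
                                r_peak = 34, qrs_end = 35, t_peak = 36,
                                t_end = 37))
  expect_error(xd_string(ann2, 40), "collision")

  # B annotated beats give exactly 6B non-zero symbols
  sf <- fixture_strip()
  xd2 <- xd_string(sf$ann, 7500)
  ch2 <- strsplit(unclass(xd2), "")[[1]]
  expect_equal(sum(ch2 != "0"), 6 * nrow(sf$ann))
})

test_that("FD projection: 63 strings, correct counts, union property", {
  sf <- fixture_strip()
  xd <- xd_string(sf$ann, 7500)
  fds <- fd_strings(xd)
  expect_length(fds, 63)
  expect_named(fds, as.character(1:63))
  nb <- nrow(sf$ann)
  ones <- function(s) sum(strsplit(unclass(s), "")[[1]] == "1")
  # mask {R} = code 4
  expect_equal(ones(fds[["4"]]), nb)
  # full mask has as many ones as the XD string has non-zero symbols
  expect_equal(ones(fds[["63"]]), 6 * nb)
  # union of masks = union of ones (codes 5 = 1|4)
  c1 <- strsplit(unclass(fds[["1"]]), "")[[1]] == "1"
  c4 <- strsplit(unclass(fds[["4"]]), "")[[1]] == "1"
  c5 <- strsplit(unclass(fds[["5"]]), "")[[1]] == "1"
  expect_identical(c5, c1 | c4)
  # every string is length-preserving
  expect_true(all(vapply(fds, function(s) nchar(unclass(s)), numeric(1)) == 7500))
})

test_that("mask codes decode to the documented bit order", {
  expect_equal(mask_features(1), "q_onset")
  expect_equal(mask_features(32), "t_end")
  expect_setequal(mask_features(44), c("r_peak", "qrs_end", "t_end"))
  expect_error(mask_features(64), "1..63")
  expect_error(mask_features(0), "1..63")
})

test_that("annotation is deterministic for a fixed strip", {
  sf <- fixture_strip()
  a1 <- suppressMessages(annotate_beats(sf$strip))
  a2 <- suppressMessages(annotate_beats(sf$strip))
  expect_identical(a1, a2)
})
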