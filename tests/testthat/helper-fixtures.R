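# Shared synthetic fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# a clean constant-rate recording with its down-sampled form and strips
clean_recording <- function(hr = 70, duration_s = 100, seed = 5,
                            noiseless = FALSE, fs = 500) {
  args <- list(duration_s = duration_s, hr = hr, seed = seed, fs = fs)
  if (noiseless) {
    args <- c(args, list(noise_sd = 0, wander_amp = 0, fiducial_jitter_sd = 0,
                         amp_jitter_sd = 0, rr_jitter_sd = 0))
  }
  sim <- do.call(subject_sim_params, args)
  rec <- generate_ecg(sim)
  s125 <- resample_ecg(rec$signal, 125)
  peaks <- detect_r_peaks(s125)
  list(rec = rec, s125 = s125, peaks = peaks,
       gt125 = rescale_ground_truth(rec$ground_truth, fs, 125))
}

fixture_noiseless <- function() fixture("noiseless70",
  function() clean_recording(hr = 70, duration_s = 100, seed = 5, noiseless = TRUE))

fixture_default <- function() fixture("default75",
  function() clean_recording(hr = 75, duration_s = 100, seed = 3))

# one annotated, baseline-removed strip from the noiseless recording
fixture_strip <- function() fixture("strip_noiseless", function() {
  fx <- fixture_noiseless()
  strips <- find_segments(fx$s125, fx$peaks, 30, 120)
  st <- remove_baseline(strips[[1]])
  ann <- suppressMessages(annotate_beats(st))
  list(strip = st, raw_strip = strips[[1]], ann = ann)
})

fid_cols <- c("q_onset", "q_peak", "r_peak", "qrs_end", "t_peak", "t_end")

# strip-local ground truth matched to annotations by nearest R peak
match_truth <- function(ann, gt125, strip_start) {
  gl <- gt125
  for (cc in fid_cols) gl[[cc]] <- gl[[cc]] - strip_start + 1
  t(vapply(seq_len(nrow(ann)), function(i) {
    j <- which.min(abs(gl$r_peak - ann$r_peak[i]))
    abs(unlist(ann[i, fid_cols]) - unlist(gl[j, fid_cols]))
  }, numeric(length(fid_cols))))
}
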