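test_that("identical configs give bit-identical recordings, seeds change noise", {
  cfg <- synth_config(duration = 50, seed = 7)
  r1 <- generate_session(cfg)
  r2 <- generate_session(cfg)
  expect_identical(r1$data, r2$data)
  cfg8 <- synth_config(duration = 50, seed = 8)
  expect_false(identical(generate_session(cfg8)$data, r1$data))
})

test_that("too-short sessions are rejected", {
  expect_error(generate_session(synth_config(duration = 35)), "40 s")
})

test_that("session indices map onto the 1-3 / 4-6 / 7-11 stage split", {
  expect_identical(stage_of_session(1:11),
                   c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 3L))
  stages <- unlist(make_stage_dataset(
    n_subjects = 1, sessions_per_stage = c(3, 3, 5), effect_size = 0.5,
    seed = 1, duration = 40, handler = function(r) r$meta$stage))
  expect_identical(stages, c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 3L))
})

test_that("a single oscillator concentrates spectral power where configured", {
  prof <- matrix(0, 14, 6,
                 dimnames = list(channels14, band_set()$band))
  prof["O1", "alpha"] <- 5
  cfg <- synth_config(duration = 50, band_profiles = prof, noise_sd = 0,
                      amp_jitter = 0, seed = 3)
  rec <- generate_session(cfg)
  seg <- slice_segments(filter_recording(rec))[[1]]
  psd <- welch_psd(seg)
  expect_equal(psd$freq[which.max(psd$psd["O1", ])], 10)
  in_alpha <- psd$freq >= 8 & psd$freq < 12
  expect_gt(sum(psd$psd["O1", in_alpha]) / sum(psd$psd["O1", ]), 0.95)
  others <- setdiff(channels14, "O1")
  expect_lt(max(rowSums(psd$psd[others, ])), 1e-12)
})

test_that("a full-strength coupled pair yields PLI 1 at the analytic lag", {
  prof <- matrix(0, 14, 6, dimnames = list(channels14, band_set()$band))
  prof[, "alpha"] <- 4
  cfg <- synth_config(duration = 50, band_profiles = prof, noise_sd = 0,
                      amp_jitter = 0, seed = 5,
                      coupling = list(list(a = "F3", b = "F4", band = "alpha",
                                           lag = pi / 2, strength = 1)))
  seg <- slice_segments(filter_recording(generate_session(cfg)))[[1]]
  P <- pli_matrix(seg, band = c(8, 12))
  expect_equal(P["F3", "F4"], 1, tolerance = 1e-12)
})

test_that("zero artifact rates leave the recording untouched", {
  cfg <- synth_config(duration = 45, seed = 2)
  rec <- generate_session(cfg)
  out <- inject_artifacts(rec, artifact_spec(), seed = 9)
  expect_identical(out$data, rec$data)
  expect_identical(nrow(attr(out, "artifacts")), 0L)
})

test_that("every injected event is recorded with a recoverable sample range", {
  spec <- artifact_spec(spike_rate = 0.2, drift_rate = 0.1,
                        excursion_rate = 0.2, half_lead_rate = 0.2)
  cfg <- synth_config(duration = 130, seed = 11, artifact_spec = spec)
  rec <- generate_session(cfg)
  led <- attr(rec, "artifacts")
  expect_gt(nrow(led), 0)
  expect_true(all(led$start >= 1 & led$end <= ncol(rec$data)))
  expect_true(all(led$start <= led$end))
  # events lie inside the analysis window of their declared segment
  seg_lo <- 30 * 128 + (led$segment - 1) * 10 * 128 + 1
  seg_hi <- 30 * 128 + led$segment * 10 * 128
  expect_true(all(led$start >= seg_lo & led$end <= seg_hi))
  # changed samples are confined to ledger ranges
  clean <- generate_session(synth_config(duration = 130, seed = 11))
  changed <- which(colSums(abs(rec$data - clean$data)) > 0)
  covered <- unlist(Map(seq, led$start, led$end))
  expect_true(all(changed %in% covered))
})

test_that("effect_size 0 collapses all stages to one generative law", {
  for (task in c("lecture", "lab", "quiz")) {
    p1 <- default_band_profiles(1, task, effect_size = 0)
    p2 <- default_band_profiles(2, task, effect_size = 0)
    p3 <- default_band_profiles(3, task, effect_size = 0)
    expect_identical(p1, p2)
    expect_identical(p1, p3)
  }
})

test_that("Emotiv-style CSV round-trips data, metadata and ledger", {
  spec <- artifact_spec(spike_rate = 0.5)
  cfg <- synth_config(duration = 45, seed = 4, artifact_spec = spec,
                      session = 5L, task = "quiz")
  rec <- generate_session(cfg)
  path <- file.path(withr::local_tempdir(), "rec.csv")
  write_emotiv_csv(rec, path)
  back <- read_emotiv_csv(path)
  expect_equal(back$data, rec$data, tolerance = 1e-6)
  expect_equal(back$meta$session, 5L)
  expect_equal(back$meta$stage, 2L)
  expect_equal(nrow(attr(back, "artifacts")), nrow(attr(rec, "artifacts")))
})
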