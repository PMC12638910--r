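test_that("Welch PSD locates tones, satisfies Parseval and is flat for white noise", {
  fs <- 128
  tt <- (0:1279) / fs
  p <- welch_psd(sin(2 * pi * 10 * tt), fs = fs)
  expect_equal(p$freq[which.max(p$psd[1, ])], 10)
  expect_lte(diff(p$freq)[1], 0.5)

  set.seed(4)
  x <- rnorm(1280)
  p2 <- welch_psd(x, fs = fs)
  expect_equal(sum(p2$psd) * diff(p2$freq)[1], var(x), tolerance = 0.05)

  # averaged over seeds, band means agree within Monte Carlo tolerance
  acc <- 0
  for (s in 1:25) {
    set.seed(s)
    acc <- acc + welch_psd(rnorm(1280), fs = fs)$psd[1, ]
  }
  acc <- acc / 25
  f <- p2$freq
  lo <- mean(acc[f >= 2 & f < 20])
  hi <- mean(acc[f >= 20 & f < 45])
  expect_equal(lo / hi, 1, tolerance = 0.15)
  expect_error(welch_psd(rnorm(100), fs = fs), "shorter")
})

test_that("relative band power normalizes, tiles to one and splits two tones", {
  fs <- 128
  tt <- (0:1279) / fs
  set.seed(1)
  tone <- rep14(sin(2 * pi * 10 * tt) + rnorm(1280, sd = 1e-3))
  rp <- relative_band_power(welch_psd(tone, fs = fs))
  expect_true(all(rp[, "alpha"] >= 0.95))
  expect_true(all(rp >= 0 & rp <= 1))
  expect_equal(unname(rowSums(rp)), rep(1, 14), tolerance = 1e-9)

  two <- sin(2 * pi * 6 * tt) + sin(2 * pi * 20 * tt) + rnorm(1280, sd = 1e-3)
  rp2 <- relative_band_power(welch_psd(two, fs = fs))
  expect_equal(unname(rp2[1, "theta"]), 0.5, tolerance = 0.01)
  expect_equal(unname(rp2[1, "high_beta"]), 0.5, tolerance = 0.01)

  expect_error(relative_band_power(welch_psd(rep(0, 1280), fs = fs)),
               "degenerate")
})

test_that("relative powers are scale-invariant and band-monotone", {
  set.seed(7)
  base <- matrix(rnorm(14 * 1280, sd = 5), 14)
  seg <- make_seg(base)
  seg2 <- make_seg(base * 3.7)
  expect_equal(feature_vector(seg), feature_vector(seg2), tolerance = 1e-12)

  tt <- (0:1279) / 128
  f_of_amp <- function(a) {
    s <- make_seg(base + rep14(a * sin(2 * pi * 10 * tt)))
    feature_vector(s)[["O1_alpha"]]
  }
  v <- vapply(c(1, 3, 6, 12), f_of_amp, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("average amplitude matches closed forms and is homogeneous", {
  expect_equal(unname(average_amplitude(matrix(0, 14, 1280))), rep(0, 14))
  tt <- (0:1279) / 128
  amp <- average_amplitude(rep14(sin(2 * pi * 10 * tt)))
  expect_equal(unname(amp), rep(2 / pi, 14), tolerance = 1e-3)
  x <- matrix(rnorm(14 * 1280), 14)
  expect_equal(average_amplitude(2 * x), 2 * average_amplitude(x))
})

test_that("feature vectors are 84-long, channel-major, deterministic and permute with channels", {
  set.seed(5)
  base <- matrix(rnorm(14 * 1280, sd = 5), 14)
  seg <- make_seg(base)
  v <- feature_vector(seg)
  expect_length(v, 14 * 6)
  expect_identical(names(v)[1:6], paste0("AF3_", band_set()$band))
  expect_identical(names(v)[79:84], paste0("AF4_", band_set()$band))
  expect_identical(v, feature_vector(make_seg(base)))

  perm <- sample(14)
  permuted <- base[perm, ]
  rownames(permuted) <- channels14[perm]
  seg_p <- eegstages:::new_segment(permuted, 128, 1L, 30,
                                   list(subject = "S01", session = 1L,
                                        task = "lab", stage = 1L))
  vp <- feature_vector(seg_p)
  for (k in seq_along(perm)) {
    blk <- paste0(channels14[perm[k]], "_", band_set()$band)
    expect_equal(vp[blk], v[blk])
  }
})

test_that("the tidy feature table carries labels, 84 features and amplitudes", {
  cfg <- synth_config(duration = 55, seed = 6, task = "quiz", session = 7L)
  pp <- preprocess_recording(generate_session(cfg))
  ft <- extract_features(pp$kept)
  expect_identical(nrow(ft), length(pp$kept))
  expect_identical(ft$stage[1], 3L)
  expect_identical(ft$task[1], "quiz")
  band_cols <- grep("_(delta|theta|alpha|low_beta|high_beta|gamma)$",
                    names(ft))
  expect_length(band_cols, 84)
  expect_length(grep("_amp$", names(ft)), 14)
})
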