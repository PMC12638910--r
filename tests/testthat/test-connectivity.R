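test_that("instantaneous phase tracks tones, offsets and sign flips", {
  fs <- 128
  tt <- (0:1279) / fs
  x <- rbind(sin(2 * pi * 10 * tt), sin(2 * pi * 10 * tt + pi / 2),
             -sin(2 * pi * 10 * tt))
  ph <- instantaneous_phase(x, band = c(8, 12), fs = fs)
  mid <- 200:1000
  slope <- mean(diff(unwrap_phase <- cumsum(
    c(ph[1, mid][1], atan2(sin(diff(ph[1, mid])), cos(diff(ph[1, mid]))))))) * fs
  expect_equal(slope, 2 * pi * 10, tolerance = 0.5)
  d12 <- atan2(sin(ph[2, mid] - ph[1, mid]), cos(ph[2, mid] - ph[1, mid]))
  expect_equal(mean(d12), pi / 2, tolerance = 0.05)
  d13 <- abs(atan2(sin(ph[3, mid] - ph[1, mid]), cos(ph[3, mid] - ph[1, mid])))
  expect_equal(mean(d13), pi, tolerance = 0.05)
})

test_that("PLI hits its analytic limits and invariances", {
  fs <- 128
  tt <- (0:1279) / fs
  s <- sin(2 * pi * 10 * tt)
  x <- rbind(s, sin(2 * pi * 10 * tt + pi / 2), s, 4 * s)
  P <- pli_matrix(x, band = c(8, 12), fs = fs)
  expect_equal(P[1, 2], 1, tolerance = 1e-12)        # constant pi/2 lag
  expect_equal(P[1, 3], 0, tolerance = 1e-12)        # identical channels
  expect_equal(P[1, 4], 0, tolerance = 1e-12)        # amplitude-scaled copy
  expect_true(isSymmetric(unclass(unname(P))))
  expect_true(all(diag(P) == 0))
  # independent noise: small PLI within a 3/sqrt(n) style bound
  set.seed(2)
  v <- vapply(1:30, function(s) {
    m <- matrix(rnorm(2 * 1280), 2)
    pli_matrix(m, band = c(1, 45), fs = fs)[1, 2]
  }, numeric(1))
  expect_lt(mean(v), 0.1)
})

test_that("top link extraction filters, ranks and tie-breaks deterministically", {
  ch <- channels14
  P <- matrix(0, 14, 14, dimnames = list(ch, ch))
  set.seed(1)
  # interhemispheric pairs are always long range under both rules
  P["AF3", "AF4"] <- P["AF4", "AF3"] <- 0.65
  P["F7", "F8"] <- P["F8", "F7"] <- 0.6
  P["O1", "O2"] <- P["O2", "O1"] <- 0.6        # tie with F7-F8
  P["T7", "T8"] <- P["T8", "T7"] <- 0.45       # below range
  P["P7", "P8"] <- P["P8", "P7"] <- 0.8        # above range
  out <- top_links(P, k = 10, rule = "interhemispheric")
  expect_identical(nrow(out), 3L)
  expect_identical(out$chan_a[1], "AF3")
  # tie: F7 (index 2) before O1 (index 7)
  expect_identical(out$chan_a[2:3], c("F7", "O1"))
  expect_identical(nrow(suppressMessages(
    top_links(P * 0.01, k = 10, rule = "interhemispheric"))), 0L)
  out2 <- top_links(P, k = 2, rule = "interhemispheric")
  expect_identical(nrow(out2), 2L)
})

test_that("weighted efficiencies match closed forms and the exhaustive oracle", {
  K <- matrix(1, 5, 5); diag(K) <- 0
  e <- efficiency(K)
  expect_equal(e$global_efficiency, 1)
  expect_equal(e$local_efficiency, 1)
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(efficiency(path3)$global_efficiency, 5 / 6)
  set.seed(3)
  for (r in 1:60) {
    W <- random_weight_graph(sample(3:7, 1))
    e <- efficiency(W)
    expect_equal(e$global_efficiency, fw_global_eff(W), tolerance = 1e-12)
    expect_equal(e$local_efficiency, fw_local_eff(W), tolerance = 1e-12)
  }
})

test_that("delay embedding lays out lagged copies row-wise", {
  expect_identical(delay_embed(c(1, 2, 3, 4), m = 2, tau = 1),
                   cbind(c(1, 2, 3), c(2, 3, 4)))
  x <- rnorm(10)
  expect_equal(delay_embed(x, m = 1, tau = 3), matrix(x, ncol = 1),
                   ignore_attr = TRUE)
  expect_identical(nrow(delay_embed(x, m = 3, tau = 2)), 6L)
  expect_error(delay_embed(rnorm(4), m = 3, tau = 4), "samples")
})

test_that("mutual information obeys its identities and bounds", {
  set.seed(4)
  x <- matrix(rnorm(3 * 1288), 3)
  x[3, ] <- 7                                   # constant channel
  M <- mi_matrix(x)
  expect_true(isSymmetric(unclass(unname(M))))
  expect_true(all(M >= 0))
  expect_equal(M[3, 3], 0)                      # H(constant) = 0
  expect_equal(M[1, 3], 0)
  expect_lte(M[1, 2], min(M[1, 1], M[2, 2]) + 1e-12)

  # deterministic 4-state copy: exactly 2 bits
  v <- rep(c(0, 1, 2, 3), length.out = 1288)
  M4 <- mi_matrix(rbind(v, v))
  expect_equal(M4[1, 2], 2, tolerance = 1e-12)
  expect_equal(M4[1, 1], 2, tolerance = 1e-12)

  # independent channels: bias-corrected MI is near zero on average
  vals <- vapply(1:30, function(s) {
    set.seed(400 + s)
    mi_matrix(matrix(rnorm(2 * 1288), 2), bias_correct = TRUE)[1, 2]
  }, numeric(1))
  expect_lt(mean(vals), 0.05)
})
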