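# Shared fixtures and independent oracles for the test suite.

channels14 <- emotiv_montage()$channel

# Build a recording directly from a channels x samples matrix.
make_rec <- function(data, fs = 128,
                     meta = list(subject = "S01", session = 1L,
                                 task = "lab", stage = 1L)) {
  eegstages:::new_recording(data, fs, meta)
}

# A detrended 10 s segment from a channels x samples matrix (bypasses QC).
make_seg <- function(data, fs = 128, index = 1L,
                     meta = list(subject = "S01", session = 1L,
                                 task = "lab", stage = 1L)) {
  rownames(data) <- channels14[seq_len(nrow(data))]
  eegstages:::new_segment(data, fs, index, 30, meta)
}

# Matrix with the same vector on every one of 14 channels.
rep14 <- function(v) matrix(rep(v, each = 14L), nrow = 14L,
                            dimnames = list(channels14, NULL))

# Independent shortest-path oracle: Floyd-Warshall over edge distances 1/w.
fw_distances <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

fw_global_eff <- function(W) {
  if (nrow(W) < 2L) return(0)
  D <- fw_distances(W)
  inv <- 1 / D
  diag(inv) <- NA
  mean(inv[upper.tri(inv)])
}

fw_local_eff <- function(W) {
  mean(sapply(seq_len(nrow(W)), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2L) 0 else fw_global_eff(W[nb, nb, drop = FALSE])
  }))
}

random_weight_graph <- function(n, p_zero = 0.3) {
  W <- matrix(0, n, n)
  up <- upper.tri(W)
  vals <- stats::runif(sum(up))
  vals[stats::runif(sum(up)) < p_zero] <- 0
  W[up] <- vals
  W + t(W)
}

# Exhaustive permutation oracle for the two-sided rank-sum p-value.
ranksum_enum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u0 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  Us <- apply(combs, 2L, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(Us <= u0), mean(Us >= u0)))
}

# Trials sharing one source pattern at a given total SNR (dB).
planted_trials <- function(n_trials = 20L, n_samples = 512L, snr_db = 0) {
  a <- stats::rnorm(14)
  a <- a / sqrt(sum(a^2))
  s <- as.numeric(stats::filter(stats::rnorm(n_samples), rep(1, 8) / 8,
                                circular = TRUE))
  s <- s / stats::sd(s)
  sigma <- sqrt(10^(-snr_db / 10) / 14)
  trials <- lapply(seq_len(n_trials), function(k)
    outer(a, s) + matrix(stats::rnorm(14 * n_samples, sd = sigma), 14L))
  list(pattern = a, trials = trials)
}

# Gaussian 84-feature dataset with one informative planted feature.
planted_feature_dataset <- function(n_per_class = 100L, planted = 25L,
                                    snr = 2) {
  y <- rep(1:3, each = n_per_class)
  X <- matrix(stats::rnorm(3 * n_per_class * 84L), ncol = 84L)
  X[, planted] <- X[, planted] / snr + y
  bands <- band_set()$band
  colnames(X) <- paste(rep(channels14, each = 6L), rep(bands, 14L), sep = "_")
  structure(list(X = X, y = factor(y),
                 groups = as.character(seq_along(y)), counts = table(y)),
            class = "eeg_dataset")
}

# Feature tibble of iid Gaussian band columns, optionally with a stage shift
# on one band (whole-brain), for the comparison harness.
gaussian_feature_table <- function(n_per_cell, stages = 1:3, task = "lab",
                                   shift_stage = NULL, shift_band = "alpha",
                                   shift = 0) {
  bands <- band_set()$band
  rows <- do.call(rbind, lapply(stages, function(st) {
    n <- n_per_cell
    m <- matrix(stats::rnorm(n * 14L * 6L), nrow = n)
    colnames(m) <- paste(rep(channels14, each = 6L), rep(bands, 14L),
                         sep = "_")
    if (!is.null(shift_stage) && st == shift_stage) {
      cols <- paste0(channels14, "_", shift_band)
      m[, cols] <- m[, cols] + shift
    }
    amp <- matrix(stats::rnorm(n * 14L), nrow = n,
                  dimnames = list(NULL, paste0(channels14, "_amp")))
    tibble::as_tibble(cbind(
      tibble::tibble(subject = "S01", session = st, task = task, stage = st,
                     segment = seq_len(n)),
      tibble::as_tibble(m), tibble::as_tibble(amp)))
  }))
  rows
}
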