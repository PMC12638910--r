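#' Frequency-band definitions
#'
#' Ordered, non-overlapping band edges `[low, high)` in Hz. The defaults
#' (delta 1-4, theta 4-8, alpha 8-12, low-beta 12-16, high-beta 16-25,
#' gamma 25-45) follow common consumer-EEG conventions; exact edges are an
#' assumption and fully configurable. The six default bands tile the 1-45 Hz
#' analysis range, so the six relative powers of a channel sum to 1.
#'
#' @param bands named list of `c(low, high)` pairs.
#' @param fs sampling rate used for validity checks.
#' @return tibble with columns `band`, `lo`, `hi`.
#' @export
band_set <- function(bands = list(delta = c(1, 4), theta = c(4, 8),
                                  alpha = c(8, 12), low_beta = c(12, 16),
                                  high_beta = c(16, 25), gamma = c(25, 45)),
                     fs = 128) {
  bs <- tibble::tibble(band = names(bands),
                       lo = vapply(bands, `[`, numeric(1), 1L),
                       hi = vapply(bands, `[`, numeric(1), 2L))
  stop_if_not(all(bs$hi > bs$lo), "band edges must satisfy low < high")
  stop_if_not(all(bs$lo > 0) && all(bs$hi < fs / 2),
              "bands must lie within (0, fs/2)")
  stop_if_not(all(diff(bs$lo) > 0) && all(bs$lo[-1] >= bs$hi[-nrow(bs)]),
              "bands must be non-overlapping and increasing")
  bs
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: 2 s Hamming windows with 50% overlap by
#' default (9 windows per 10 s segment at 128 Hz, 0.5 Hz frequency
#' resolution). One-sided density scaling, so the PSD integrates to the
#' signal variance (Parseval, up to windowing bias).
#'
#' @param x an `eeg_segment`, or a channels x samples matrix, or a vector.
#' @param fs sampling rate (taken from the segment if omitted).
#' @param nperseg window length in samples (default `2 * fs`).
#' @param overlap fractional window overlap (default 0.5).
#' @return list with `freq` (Hz) and `psd` (channels x frequencies, uV^2/Hz).
#' @export
welch_psd <- function(x, fs = NULL, nperseg = NULL, overlap = 0.5) {
  if (inherits(x, "eeg_segment")) {
    fs <- x$fs
    x <- x$data
  }
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  stop_if_not(!is.null(fs), "fs is required for matrix/vector input")
  nperseg <- nperseg %||% round(2 * fs)
  n <- ncol(x)
  stop_if_not(n >= nperseg, "segment shorter than one Welch window")
  hop <- max(1L, round(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(nperseg) - 1) / (nperseg - 1))
  scale <- 1 / (fs * sum(w^2))
  nf <- floor(nperseg / 2) + 1L
  freq <- (seq_len(nf) - 1) * fs / nperseg
  nch <- nrow(x)
  nwin <- length(starts)
  # window index matrix, shared across channels; all channels and windows go
  # through a single FFT call
  idx <- outer(seq_len(nperseg) - 1L, starts, `+`)
  seg_all <- matrix(0, nperseg, nwin * nch)
  for (ch in seq_len(nch)) {
    v <- x[ch, ]
    seg_all[, ((ch - 1L) * nwin + 1L):(ch * nwin)] <- v[idx] * w
  }
  seg_all <- sweep(seg_all, 2L, colMeans(seg_all))   # remove per-window DC
  P <- Mod(stats::mvfft(seg_all))^2 * scale
  P <- P[seq_len(nf), , drop = FALSE]
  if (nperseg %% 2L == 0L) P[2:(nf - 1L), ] <- 2 * P[2:(nf - 1L), ]
  else P[2:nf, ] <- 2 * P[2:nf, ]
  psd <- t(vapply(seq_len(nch), function(ch)
    rowMeans(P[, ((ch - 1L) * nwin + 1L):(ch * nwin), drop = FALSE]),
    numeric(nf)))
  rownames(psd) <- rownames(x)
  list(freq = freq, psd = psd)
}

#' Relative band power
#'
#' Band-integrated PSD divided by the total PSD over the analysed spectrum
#' (1-45 Hz by default; content outside it is filter artifact). Values lie
#' in \[0, 1\] and are invariant to amplitude scaling; with the default bands
#' the six values of a channel sum to 1.
#'
#' @param psd output of [welch_psd()].
#' @param bands a [band_set()].
#' @param total_range analysis range over which the total power is taken.
#' @return channels x bands matrix of relative powers.
#' @export
relative_band_power <- function(psd, bands = band_set(),
                                total_range = c(1, 45)) {
  f <- psd$freq
  tot_idx <- f >= total_range[1] & f < total_range[2]
  total <- rowSums(psd$psd[, tot_idx, drop = FALSE])
  if (any(total <= 0)) stop("degenerate segment: zero total power",
                            call. = FALSE)
  out <- sapply(seq_len(nrow(bands)), function(b) {
    idx <- f >= bands$lo[b] & f < bands$hi[b]
    rowSums(psd$psd[, idx, drop = FALSE]) / total
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  dimnames(out) <- list(rownames(psd$psd), bands$band)
  out
}

#' Per-channel average amplitude
#'
#' Mean absolute voltage per channel (after high-pass filtering the raw mean
#' is ~0, so a magnitude statistic is the meaningful per-channel amplitude
#' summary; RMS is available as an alternative).
#'
#' @param seg an `eeg_segment` (or channels x samples matrix).
#' @param type `"mean_abs"` (default) or `"rms"`.
#' @return named numeric vector, one value per channel (uV).
#' @export
average_amplitude <- function(seg, type = c("mean_abs", "rms")) {
  type <- match.arg(type)
  x <- if (inherits(seg, "eeg_segment")) seg$data else seg
  if (type == "mean_abs") rowMeans(abs(x)) else sqrt(rowMeans(x^2))
}

#' 84-dimensional relative-power feature vector
#'
#' Channel-major concatenation of the per-channel relative band powers
#' (14 channels x 6 bands = 84 features with the default montage and bands),
#' named `<channel>_<band>` (e.g. `O1_alpha`). Deterministic ordering:
#' montage order outer, band order inner.
#'
#' @param seg a kept `eeg_segment`.
#' @param bands a [band_set()].
#' @return named numeric vector of length `channels * bands`, with the
#'   segment labels attached as the `labels` attribute.
#' @export
feature_vector <- function(seg, bands = band_set()) {
  rp <- relative_band_power(welch_psd(seg), bands)
  v <- as.vector(t(rp))                       # channel-major
  names(v) <- paste(rep(rownames(rp), each = nrow(bands)),
                    rep(bands$band, times = nrow(rp)), sep = "_")
  attr(v, "labels") <- c(seg$meta[c("subject", "session", "task", "stage")],
                         segment = seg$index)
  v
}

#' Tidy feature table for a set of kept segments
#'
#' One row per segment: labels (subject, session, task, stage, segment),
#' the 84 relative-power features and the 14 per-channel average amplitudes
#' (`<channel>_amp`).
#'
#' @param segments list of kept `eeg_segment`s.
#' @param bands a [band_set()].
#' @return a tibble.
#' @export
extract_features <- function(segments, bands = band_set()) {
  stop_if_not(length(segments) > 0, "no segments supplied")
  one <- feature_vector(segments[[1L]], bands)
  amp1 <- average_amplitude(segments[[1L]])
  nv <- length(one)
  vals <- vapply(segments, function(seg)
    c(feature_vector(seg, bands), average_amplitude(seg)),
    numeric(nv + length(amp1)))
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = 1L)
  labs <- lapply(segments, function(seg)
    c(seg$meta[c("subject", "session", "task", "stage")],
      segment = seg$index))
  out <- tibble::tibble(
    subject = vapply(labs, function(l) as.character(l$subject), character(1)),
    session = vapply(labs, function(l) as.integer(l$session), integer(1)),
    task = vapply(labs, function(l) as.character(l$task), character(1)),
    stage = vapply(labs, function(l) as.integer(l$stage), integer(1)),
    segment = vapply(labs, function(l) as.integer(l[["segment"]]), integer(1)))
  m <- t(vals)
  colnames(m) <- c(names(one), paste0(names(amp1), "_amp"))
  tibble::as_tibble(cbind(out, tibble::as_tibble(m)))
}
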