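#' Band-limit a recording for analysis
#'
#' Zero-phase 4th-order Butterworth 1 Hz high-pass plus a 50 Hz notch
#' (biquad, Q = 30), both applied forward and backward with
#' [signal::filtfilt()] so topographies are not distorted by phase lags.
#' Removes DC/baseline drift and attenuates mains interference by well over
#' 20 dB.
#'
#' @param rec an `eeg_recording` with `fs > 100` (the notch must sit below
#'   Nyquist).
#' @param hp high-pass cutoff (Hz).
#' @param notch mains frequency (Hz).
#' @param q notch quality factor.
#' @return the filtered recording.
#' @export
filter_recording <- function(rec, hp = 1, notch = 50, q = 30) {
  stop_if_not(rec$fs > 100, "fs must exceed 100 Hz (notch below Nyquist)")
  bw <- signal::butter(4, hp / (rec$fs / 2), type = "high")
  w0 <- 2 * pi * notch / rec$fs
  alpha <- sin(w0) / (2 * q)
  bn <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  an <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  # cascade high-pass and notch into a single section (coefficient
  # polynomials multiplied); one zero-phase pass per channel
  b <- stats::convolve(bw$b, rev(bn), type = "open")
  a <- stats::convolve(bw$a, rev(an), type = "open")
  x <- rec$data
  for (ch in seq_len(nrow(x)))
    x[ch, ] <- zero_phase_filter(b, a, x[ch, ])
  rec$data <- x
  led <- attr(rec, "artifacts")
  if (!is.null(led)) attr(rec, "artifacts") <- led
  rec
}

#' @keywords internal
new_segment <- function(data, fs, index, t_start, meta) {
  structure(list(data = data, fs = fs, index = index, t_start = t_start,
                 meta = meta, qc = "pending",
                 corrections = list()),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> #%d [%g s) %d ch x %d samples, qc: %s\n",
              x$index, x$t_start, nrow(x$data), ncol(x$data), x$qc))
  invisible(x)
}

#' Slice a recording into 10 s analysis segments
#'
#' Discards the first `discard` seconds (electrode settling), cuts the
#' remainder into non-overlapping `seg_len`-second windows (trailing
#' remainder dropped) and removes a per-channel linear trend from each
#' window (de-baselining).
#'
#' @param rec an `eeg_recording` longer than `discard` seconds.
#' @param discard seconds dropped from the start (default 30).
#' @param seg_len segment length in seconds (default 10).
#' @param detrend remove per-channel linear trends (default TRUE).
#' @return list of `eeg_segment`s with `qc = "pending"`; zero segments (with
#'   a warning) when the recording is shorter than `discard + seg_len`.
#' @export
slice_segments <- function(rec, discard = 30, seg_len = 10, detrend = TRUE) {
  fs <- rec$fs
  duration <- ncol(rec$data) / fs
  stop_if_not(duration > discard, "recording shorter than the discard window")
  nseg <- floor((duration - discard) / seg_len)
  if (nseg < 1) {
    warning("recording too short for any full segment after the ",
            discard, " s discard; returning zero segments")
    return(list())
  }
  first <- round(discard * fs)
  width <- round(seg_len * fs)
  lapply(seq_len(nseg), function(k) {
    idx <- (first + (k - 1L) * width + 1L):(first + k * width)
    d <- rec$data[, idx, drop = FALSE]
    if (detrend) d <- detrend_linear(d)
    rownames(d) <- rownames(rec$data)
    new_segment(d, fs, k, discard + (k - 1) * seg_len, rec$meta)
  })
}

#' Count amplitude outliers in a channel
#'
#' Number of samples with `|y - center| > k * spread` (strict inequality, so
#' a constant signal has zero outliers). By default the reference statistics
#' are the mean and standard deviation of the supplied samples themselves;
#' segment-level QC passes segment-wide statistics instead.
#'
#' @param x numeric vector of samples.
#' @param k multiplier (default 3).
#' @param center,spread reference statistics (default mean/SD of `x`).
#' @return integer outlier count.
#' @export
count_outliers <- function(x, k = 3, center = mean(x), spread = stats::sd(x)) {
  stop_if_not(length(x) > 0, "channel data must be non-empty")
  stop_if_not(k > 0, "k must be positive")
  if (is.na(spread) || spread == 0) spread <- 0
  sum(abs(x - center) > k * spread)
}

#' @keywords internal
nearest_good_fill <- function(v, bad) {
  good <- which(!bad)
  if (!length(good) || !any(bad)) return(v)
  bi <- which(bad)
  pos <- findInterval(bi, good)
  left <- good[pmax(pos, 1L)]
  right <- good[pmin(pos + 1L, length(good))]
  dl <- abs(bi - left)
  dr <- abs(right - bi)
  pick <- ifelse(pos == 0L, right, ifelse(dl <= dr, left, right))  # ties: earlier
  v[bi] <- v[pick]
  v
}

#' Quality-control one segment
#'
#' Applies the segment QC rules in fixed order: (a) if any channel has more
#' outliers than half its samples the segment is discarded
#' (`discarded_outliers`); (b) otherwise outliers are replaced by the value
#' of the nearest non-outlier sample on the same channel (ties broken toward
#' the earlier sample); (c) if any remaining sample magnitude exceeds
#' `amp_limit` the segment is discarded (`discarded_amplitude`); (d)
#' otherwise it is `kept` (`kept_corrected` when any sample was replaced).
#'
#' Outliers are samples with `|y - mean| > k * sd`. With
#' `scope = "segment"` (the default) mean and sd are computed over all
#' channels of the segment jointly; this is what makes the half-lead rule
#' operative, since relative to a channel's *own* mean/SD at most 1/9 of
#' samples can ever exceed 3 SD (Chebyshev). `scope = "channel"` computes
#' the statistics per channel instead.
#'
#' Calling on an already-QCed segment returns it unchanged (idempotent).
#'
#' @param seg an `eeg_segment`.
#' @param k outlier multiplier (default 3).
#' @param amp_limit amplitude rejection threshold in uV (default 150).
#' @param scope `"segment"` or `"channel"` reference statistics.
#' @return the segment with terminal `qc` status and per-channel
#'   `corrections` (indices of replaced samples).
#' @export
qc_segment <- function(seg, k = 3, amp_limit = 150,
                       scope = c("segment", "channel")) {
  scope <- match.arg(scope)
  if (seg$qc != "pending") return(seg)
  x <- seg$data
  ns <- ncol(x)
  if (scope == "segment") {
    m <- mean(x)
    s <- stats::sd(as.vector(x))
    mask <- abs(x - m) > k * s
  } else {
    m <- rowMeans(x)
    s <- apply(x, 1L, stats::sd)
    s[is.na(s)] <- 0
    mask <- abs(x - m) > k * s
  }
  counts <- rowSums(mask)
  if (any(counts > ns / 2)) {
    seg$qc <- "discarded_outliers"
    return(seg)
  }
  corrections <- list()
  if (any(counts > 0)) {
    for (ch in which(counts > 0)) {
      bad <- mask[ch, ]
      if (all(bad)) next                      # no reference sample to copy
      x[ch, ] <- nearest_good_fill(x[ch, ], bad)
      corrections[[rownames(x)[ch]]] <- which(bad)
    }
    seg$data <- x
    seg$corrections <- corrections
  }
  if (any(abs(x) > amp_limit)) {
    seg$qc <- "discarded_amplitude"
  } else if (length(corrections)) {
    seg$qc <- "kept_corrected"
  } else {
    seg$qc <- "kept"
  }
  seg
}

#' Preprocess one recording end to end
#'
#' Filtering, slicing/detrending and segment QC in sequence, with a QC
#' report. The optional ICA step has no default implementation (component
#' selection criteria are montage- and study-specific); a hook can be
#' supplied to transform the filtered recording before slicing.
#'
#' @param rec an `eeg_recording`.
#' @param discard,seg_len slicing parameters (seconds).
#' @param k,amp_limit,scope QC parameters, see [qc_segment()].
#' @param ica_hook optional `function(rec) rec` applied after filtering;
#'   `NULL` (default) skips it.
#' @return list with `segments` (all, with terminal statuses), `kept` (the
#'   usable segments) and `report` (tibble of per-status counts; counts sum
#'   to the number of segments).
#' @export
preprocess_recording <- function(rec, discard = 30, seg_len = 10, k = 3,
                                 amp_limit = 150, scope = "segment",
                                 ica_hook = NULL) {
  f <- filter_recording(rec)
  if (!is.null(ica_hook)) f <- ica_hook(f)
  segs <- slice_segments(f, discard = discard, seg_len = seg_len)
  segs <- lapply(segs, qc_segment, k = k, amp_limit = amp_limit, scope = scope)
  status <- vapply(segs, function(s) s$qc, character(1))
  lv <- c("kept", "kept_corrected", "discarded_outliers", "discarded_amplitude")
  counts <- as.integer(table(factor(status, levels = lv)))
  report <- tibble::tibble(status = lv, n = counts)
  list(segments = segs,
       kept = segs[status %in% c("kept", "kept_corrected")],
       report = report)
}

#' Write a QC report as JSON
#'
#' @param report tibble from [preprocess_recording()] (`$report`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(as.list(stats::setNames(report$n, report$status)),
                       path, auto_unbox = TRUE)
  invisible(path)
}
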