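#' Band-pass filter a channels x samples matrix
#' @keywords internal
bandpass <- function(x, fs, band) {
  stop_if_not(band[1] > 0 && band[2] < fs / 2, "band must lie in (0, fs/2)")
  bw <- signal::butter(4, band / (fs / 2), type = "pass")
  t(apply(x, 1L, function(v) zero_phase_filter(bw$b, bw$a, v)))
}

#' Instantaneous phase per channel
#'
#' Band-pass filters each channel (zero-phase Butterworth) and takes the
#' phase of the analytic signal; values in (-pi, pi].
#'
#' @param seg an `eeg_segment` (or channels x samples matrix with `fs`).
#' @param band analysis band in Hz (default the full 1-45 Hz range).
#' @param fs sampling rate for matrix input.
#' @return channels x samples phase matrix (radians).
#' @export
instantaneous_phase <- function(seg, band = c(1, 45), fs = NULL) {
  if (inherits(seg, "eeg_segment")) {
    fs <- seg$fs
    x <- seg$data
  } else x <- seg
  xf <- bandpass(x, fs, band)
  ph <- t(apply(xf, 1L, function(v) Arg(analytic_signal(v))))
  rownames(ph) <- rownames(x)
  ph
}

#' Phase-lag index matrix
#'
#' For each channel pair, `|time-mean of sign(dphi)|` where `dphi` is the
#' wrapped instantaneous phase difference (computed as `sign(sin(dphi))`,
#' which handles phase wrapping and makes a zero lag contribute 0, neither
#' lead nor lag). A constant nonzero lag gives 1; inconsistent lags give
#' values near 0. The index is insensitive to channel amplitude scaling and,
#' by ignoring zero-lag differences, robust to volume conduction. The first
#' and last 5% of samples are trimmed to avoid filter transients.
#'
#' @param seg an `eeg_segment` (or channels x samples matrix with `fs`).
#' @param band analysis band (Hz).
#' @param trim fraction of samples trimmed at each end.
#' @param fs sampling rate for matrix input.
#' @return symmetric channels x channels matrix in \[0, 1\] with zero
#'   diagonal, of class `pli_matrix` with the band as an attribute.
#' @export
pli_matrix <- function(seg, band = c(1, 45), trim = 0.05, fs = NULL) {
  ph <- instantaneous_phase(seg, band, fs)
  n <- ncol(ph)
  keep <- (floor(n * trim) + 1L):(n - floor(n * trim))
  ph <- ph[, keep, drop = FALSE]
  nc <- nrow(ph)
  P <- matrix(0, nc, nc, dimnames = list(rownames(ph), rownames(ph)))
  for (i in seq_len(nc - 1L)) {
    for (j in (i + 1L):nc) {
      P[i, j] <- P[j, i] <- abs(mean(sign(sin(ph[i, ] - ph[j, ]))))
    }
  }
  structure(P, class = c("pli_matrix", "matrix"), band = band)
}

#' Strongest long-range links
#'
#' Among channel pairs satisfying the long-range rule and whose PLI lies
#' inside `value_range`, returns the `k` strongest links (deterministic
#' tie-break by channel index order). The long-range rule is either
#' `"distance"` (schematic electrode distance exceeding the median pairwise
#' distance) or `"interhemispheric"` (channels on opposite hemispheres).
#'
#' @param pli a `pli_matrix` (or plain symmetric matrix with channel names).
#' @param k number of links (default 10).
#' @param value_range inclusive PLI window (default `c(0.5, 0.7)`).
#' @param rule long-range rule.
#' @param montage montage tibble.
#' @return tibble `chan_a`, `chan_b`, `weight`, strongest first; fewer than
#'   `k` rows (with a message) when fewer links qualify.
#' @export
top_links <- function(pli, k = 10, value_range = c(0.5, 0.7),
                      rule = c("distance", "interhemispheric"),
                      montage = emotiv_montage()) {
  rule <- match.arg(rule)
  stop_if_not(k >= 1, "k must be >= 1")
  ch <- montage$channel
  P <- unclass(pli)[ch, ch]
  D <- montage_distances(montage)
  med <- stats::median(D[upper.tri(D)])
  rows <- list()
  for (i in seq_along(ch)[-length(ch)]) {
    for (j in (i + 1L):length(ch)) {
      long <- if (rule == "distance") D[i, j] > med
              else montage$hemisphere[i] != montage$hemisphere[j]
      if (!long) next
      w <- P[i, j]
      if (w < value_range[1] || w > value_range[2]) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chan_a = ch[i], chan_b = ch[j], weight = w, i = i, j = j)
    }
  }
  if (!length(rows)) {
    message("no links qualify")
    return(tibble::tibble(chan_a = character(), chan_b = character(),
                          weight = numeric()))
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$weight, tab$i, tab$j), ]
  if (nrow(tab) < k) message(nrow(tab), " qualifying links (< k = ", k, ")")
  utils::head(tab[, c("chan_a", "chan_b", "weight")], k)
}

#' @keywords internal
global_efficiency_matrix <- function(W) {
  nn <- nrow(W)
  if (nn < 2L) return(0)
  A <- ifelse(W > 0, 1 / W, 0)                 # edge distance = 1/weight
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, algorithm = "dijkstra")
  inv <- 1 / D
  diag(inv) <- NA
  mean(inv[upper.tri(inv)])                    # 1/Inf = 0 for disconnected
}

#' Weighted global and local efficiency
#'
#' Latora-Marchiori efficiencies of the weighted (unthresholded) graph with
#' edge distance `1 / weight`: global efficiency is the mean inverse
#' shortest-path distance over all node pairs (disconnected pairs contribute
#' 0); local efficiency is the mean over nodes of the global efficiency of
#' the subgraph induced by each node's neighbours (nodes with fewer than two
#' neighbours contribute 0). For weights in \[0, 1\] (such as PLI) both lie
#' in \[0, 1\].
#'
#' @param W symmetric nonnegative weight matrix (e.g. a `pli_matrix`).
#' @return list with `global_efficiency` and `local_efficiency`.
#' @export
efficiency <- function(W) {
  W <- unclass(W)
  stop_if_not(isSymmetric(unname(W)), "weight matrix must be symmetric")
  stop_if_not(all(W >= 0), "weights must be nonnegative")
  diag(W) <- 0
  glob <- global_efficiency_matrix(W)
  loc <- mean(vapply(seq_len(nrow(W)), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2L) return(0)
    global_efficiency_matrix(W[nb, nb, drop = FALSE])
  }, numeric(1)))
  list(global_efficiency = glob, local_efficiency = loc)
}

#' Time-delay (phase-space) embedding
#'
#' Row `i` of the result is `(x_i, x_{i+tau}, ..., x_{i+(m-1)tau})`; there
#' are `n = length(x) - (m-1) * tau` rows.
#'
#' @param x numeric vector.
#' @param m embedding dimension (>= 1).
#' @param tau delay in samples (>= 1).
#' @return an `n x m` matrix.
#' @export
delay_embed <- function(x, m = 3, tau = 4) {
  stop_if_not(m >= 1 && tau >= 1, "m and tau must be >= 1")
  n <- length(x) - (m - 1L) * tau
  stop_if_not(n >= 1, "not enough samples for one embedded vector")
  out <- vapply(seq_len(m), function(j) x[(1:n) + (j - 1L) * tau], numeric(n))
  if (n == 1L) out <- matrix(out, nrow = 1L)
  out
}

#' @keywords internal
discretize_equal_width <- function(v, bins) {
  rng <- range(v)
  if (rng[2] == rng[1]) return(rep(1L, length(v)))
  b <- floor((v - rng[1]) / (rng[2] - rng[1]) * bins) + 1L
  pmin(b, bins)
}

#' @keywords internal
entropy_bits <- function(counts, n, correct = FALSE) {
  p <- counts[counts > 0] / n
  h <- -sum(p * log2(p))
  if (correct) h <- h + (length(p) - 1) / (2 * n * log(2))  # Miller-Madow
  h
}

#' Histogram mutual-information transfer matrix
#'
#' Pairwise mutual information `MI(q, s) = H(q) + H(s) - H(q, s)` in bits
#' between channels, with state probabilities estimated by histogramming the
#' leading coordinate of each channel's time-delay embedding into `bins`
#' equal-width bins (the joint uses the `bins x bins` 2D histogram of the
#' paired coordinates). Symmetric by construction, nonnegative, with
#' `MI(i, i) = H(i)` on the diagonal, and `MI(q, s) <= min(H(q), H(s))`.
#' Optional Miller-Madow small-sample bias correction (clamped at 0).
#'
#' @param seg an `eeg_segment` (or channels x samples matrix).
#' @param m,tau embedding dimension and delay (defaults 3 and 4 samples,
#'   about 31 ms at 128 Hz).
#' @param bins histogram bins per dimension (default 16).
#' @param bias_correct apply Miller-Madow correction (default FALSE, i.e. the
#'   plug-in estimator).
#' @return symmetric channels x channels matrix (bits), class `mi_matrix`
#'   with estimator settings attached.
#' @export
mi_matrix <- function(seg, m = 3, tau = 4, bins = 16, bias_correct = FALSE) {
  x <- if (inherits(seg, "eeg_segment")) seg$data else seg
  nch <- nrow(x)
  nemb <- ncol(x) - (m - 1L) * tau
  stop_if_not(nemb >= 2, "not enough samples for the embedding")
  states <- matrix(0L, nch, nemb)
  H <- K <- numeric(nch)
  for (ch in seq_len(nch)) {
    lead <- delay_embed(x[ch, ], m, tau)[, 1L]
    states[ch, ] <- discretize_equal_width(lead, bins)
    cnt <- tabulate(states[ch, ], bins)
    H[ch] <- entropy_bits(cnt, nemb, bias_correct)
  }
  M <- matrix(0, nch, nch, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(nch)) {
    for (j in i:nch) {
      joint <- tabulate((states[i, ] - 1L) * bins + states[j, ], bins * bins)
      Hij <- entropy_bits(joint, nemb, bias_correct)
      mi <- H[i] + H[j] - Hij
      if (bias_correct) mi <- max(mi, 0)
      M[i, j] <- M[j, i] <- mi
    }
  }
  structure(M, class = c("mi_matrix", "matrix"),
            settings = list(m = m, tau = tau, bins = bins,
                            bias_correct = bias_correct))
}

#' Write a labelled matrix as TSV
#' @param m matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(unclass(m), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Export a network in BrainNet-style .node/.edge text format
#'
#' @param W weight matrix (channels x channels).
#' @param prefix output path prefix; writes `<prefix>.node` and
#'   `<prefix>.edge`.
#' @param montage montage tibble for node coordinates.
#' @return `prefix`, invisibly.
#' @export
write_brainnet <- function(W, prefix, montage = emotiv_montage()) {
  node <- data.frame(x = montage$x, y = montage$y, z = 0,
                     color = 1, size = 1, label = montage$channel)
  utils::write.table(node, paste0(prefix, ".node"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(unclass(W), paste0(prefix, ".edge"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
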