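#' Trial set for task-related component analysis
#'
#' Bundles channels x samples trial matrices (optionally grouped by
#' subject); trials of unequal length are truncated to the common minimum.
#'
#' @param trials list of channels x samples matrices with a consistent
#'   channel count/order.
#' @param subjects optional subject id per trial (defaults to one group).
#' @param condition optional metadata list (task, stage).
#' @return a `trial_set`.
#' @export
trial_set <- function(trials, subjects = NULL, condition = list()) {
  stop_if_not(length(trials) >= 2L, "need at least 2 trials")
  nch <- vapply(trials, nrow, integer(1))
  stop_if_not(length(unique(nch)) == 1L,
              "all trials must have the same channel count")
  tmin <- min(vapply(trials, ncol, integer(1)))
  trials <- lapply(trials, function(x) x[, seq_len(tmin), drop = FALSE])
  subjects <- subjects %||% rep("S01", length(trials))
  stop_if_not(length(subjects) == length(trials),
              "one subject id per trial required")
  structure(list(trials = trials, subjects = subjects, condition = condition),
            class = "trial_set")
}

#' @keywords internal
gtrca_covariances <- function(ts) {
  tmin <- ncol(ts$trials[[1L]])
  nch <- nrow(ts$trials[[1L]])
  Q <- matrix(0, nch, nch)
  S <- matrix(0, nch, nch)
  for (g in unique(ts$subjects)) {
    idx <- which(ts$subjects == g)
    Ysum <- matrix(0, nch, tmin)
    for (k in idx) {
      Xc <- ts$trials[[k]] - rowMeans(ts$trials[[k]])
      Q <- Q + Xc %*% t(Xc) / tmin
      Ysum <- Ysum + Xc
    }
    # sum of cross-trial covariances within the subject block:
    # sum_{j != k} X_j X_k' = (sum X)(sum X)' - sum X_k X_k'
    Sg <- Ysum %*% t(Ysum) / tmin
    for (k in idx) {
      Xc <- ts$trials[[k]] - rowMeans(ts$trials[[k]])
      Sg <- Sg - Xc %*% t(Xc) / tmin
    }
    S <- S + (Sg + t(Sg)) / 2
  }
  list(Q = Q, S = S)
}

#' Fit group task-related components
#'
#' Spatial filters maximizing trial-to-trial reproducibility: solves the
#' generalized eigenproblem `S w = lambda Q w` where `S` sums the
#' cross-trial covariances (within each subject block, pooled over
#' subjects) and `Q` is the pooled within-trial covariance. Eigenvalues
#' (the reproducibility objectives) are returned in descending order.
#' `Q` is always ridge-regularized by `ridge * trace(Q)/C` on the diagonal;
#' rank deficiency beyond that is reported via a message. Filters are unit
#' length and sign-fixed so the largest-magnitude pattern entry is positive.
#'
#' @param ts a [trial_set()] (at least 2 trials, samples >> channels).
#' @param n_components number of components (default 1; the leading
#'   topography is usually the one mapped).
#' @param ridge relative ridge strength (default 1e-6).
#' @return object of class `gtrca` with `filters` (channels x components),
#'   `patterns` (forward projections, normalized), `objectives` and the
#'   regularization actually applied.
#' @export
fit_gtrca <- function(ts, n_components = 1L, ridge = 1e-6) {
  stop_if_not(inherits(ts, "trial_set"), "ts must be a trial_set")
  nch <- nrow(ts$trials[[1L]])
  stop_if_not(ncol(ts$trials[[1L]]) > nch,
              "trials need more samples than channels")
  cv <- gtrca_covariances(ts)
  lambda <- ridge * sum(diag(cv$Q)) / nch
  Qr <- cv$Q + diag(lambda, nch)
  ev <- eigen(Qr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev))
    message("near-singular covariance; ridge ", signif(lambda, 3), " applied")
  R <- chol(Qr)
  Ri <- backsolve(R, diag(nch))
  M <- t(Ri) %*% cv$S %*% Ri
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  W <- Ri %*% e$vectors[, seq_len(n_components), drop = FALSE]
  W <- sweep(W, 2L, sqrt(colSums(W^2)), `/`)
  A <- Qr %*% W
  A <- sweep(A, 2L, sqrt(colSums(A^2)), `/`)
  sgn <- vapply(seq_len(ncol(A)), function(k) {
    s <- sign(A[which.max(abs(A[, k])), k])
    if (s == 0) 1 else s
  }, numeric(1))
  W <- sweep(W, 2L, sgn, `*`)
  A <- sweep(A, 2L, sgn, `*`)
  ch <- rownames(ts$trials[[1L]])
  if (!is.null(ch)) rownames(W) <- rownames(A) <- ch
  structure(list(filters = W, patterns = A,
                 objectives = e$values[seq_len(n_components)],
                 ridge = lambda, condition = ts$condition),
            class = "gtrca")
}

#' @export
print.gtrca <- function(x, ...) {
  cat(sprintf("<gtrca> %d component(s), leading objective %.4g\n",
              ncol(x$filters), x$objectives[1]))
  invisible(x)
}

#' Forward-model scalp pattern of a component
#'
#' Projects a fitted spatial filter back through the trial covariance
#' (`pattern = Q w`, normalized, sign-fixed), giving per-channel topography
#' values suitable for scalp-map rendering.
#'
#' @param comp a fitted `gtrca` object.
#' @param ts the [trial_set()] to project through (defaults to the fit's
#'   stored patterns when omitted).
#' @param component component index (default 1).
#' @return named per-channel numeric vector, unit length.
#' @export
project_pattern <- function(comp, ts = NULL, component = 1L) {
  stop_if_not(inherits(comp, "gtrca"), "comp must be a fitted gtrca")
  if (is.null(ts)) return(comp$patterns[, component])
  Q <- gtrca_covariances(ts)$Q
  a <- as.numeric(Q %*% comp$filters[, component])
  a <- a / sqrt(sum(a^2))
  s <- sign(a[which.max(abs(a))])
  if (s < 0) a <- -a
  names(a) <- rownames(comp$filters)
  a
}

#' Serialize fitted components to JSON
#'
#' @param comp a `gtrca` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtrca_json <- function(comp, path) {
  jsonlite::write_json(list(filters = unname(as.data.frame(comp$filters)),
                            patterns = unname(as.data.frame(comp$patterns)),
                            objectives = comp$objectives,
                            ridge = comp$ridge),
                       path, digits = NA)
  invisible(path)
}
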