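#' Assemble the stage classification dataset
#'
#' Turns a tidy feature table into a samples x 84 matrix with stage labels
#' and subject/session group ids, in a deterministic row order (subject,
#' session, segment). Duplicate segment identities and missing stage
#' classes are rejected.
#'
#' @param features tibble from [extract_features()].
#' @param feature_cols columns used as predictors (default: the 84
#'   `<channel>_<band>` relative-power columns).
#' @return an `eeg_dataset`: list with `X`, `y` (factor of stages), `groups`
#'   and per-stage `counts`.
#' @export
assemble_dataset <- function(features, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    bands <- band_set()$band
    feature_cols <- paste(rep(emotiv_montage()$channel, each = length(bands)),
                          rep(bands, times = 14L), sep = "_")
  }
  stop_if_not(all(feature_cols %in% names(features)),
              "feature table lacks expected feature columns")
  key <- paste(features$subject, features$session, features$task,
               features$segment)
  if (anyDuplicated(key)) stop("duplicate segment ids in feature table",
                               call. = FALSE)
  ord <- order(features$subject, features$session, features$segment)
  features <- features[ord, ]
  X <- as.matrix(features[, feature_cols])
  stop_if_not(!anyNA(X), "feature matrix contains missing values")
  y <- factor(features$stage, levels = sort(unique(features$stage)))
  if (nlevels(y) < 2L) stop("need at least two stage classes", call. = FALSE)
  counts <- table(y)
  message("per-stage sample counts: ",
          paste(names(counts), counts, sep = "=", collapse = ", "))
  structure(list(X = X, y = y,
                 groups = paste(features$subject, features$session, sep = "."),
                 counts = counts),
            class = "eeg_dataset")
}

#' @keywords internal
discretize_quantile <- function(v, bins = 4L) {
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1L),
                               names = FALSE))
  if (length(br) < 2L) return(rep(1L, length(v)))
  cut(v, br, include.lowest = TRUE, labels = FALSE)
}

#' @keywords internal
discrete_mi_bits <- function(a, b) {
  la <- max(a); lb <- max(b)
  n <- length(a)
  pj <- tabulate((a - 1L) * lb + b, la * lb) / n
  pa <- tabulate(a, la) / n
  pb <- tabulate(b, lb) / n
  pj <- pj[pj > 0]
  sum(pj * log2(pj)) - sum(pa[pa > 0] * log2(pa[pa > 0])) -
    sum(pb[pb > 0] * log2(pb[pb > 0]))
}

#' MRMR feature ranking
#'
#' Greedy max-relevance min-redundancy ranking with the MID (difference)
#' criterion: the first feature maximizes mutual information with the stage
#' label; each subsequent feature maximizes relevance minus the mean MI with
#' the already-selected set. Features are discretized into equal-frequency
#' 4-bin codes before MI estimation; ties break toward the lower feature
#' index, so the ranking is deterministic. A constant feature has zero
#' relevance and is never picked before an informative one.
#'
#' @param ds an `eeg_dataset` from [assemble_dataset()].
#' @param k how many features to rank (default: all).
#' @param bins discretization bins (default 4).
#' @return tibble `rank`, `feature` (column name), `index`, `score`,
#'   `relevance`, `redundancy`.
#' @export
mrmr_rank <- function(ds, k = ncol(ds$X), bins = 4L) {
  stop_if_not(k >= 1 && k <= ncol(ds$X), "k must be in 1..n_features")
  p <- ncol(ds$X)
  disc <- apply(ds$X, 2L, discretize_quantile, bins = bins)
  yi <- as.integer(ds$y)
  relevance <- vapply(seq_len(p), function(j) discrete_mi_bits(disc[, j], yi),
                      numeric(1))
  selected <- integer(0)
  red_sum <- numeric(p)
  scores <- numeric(k)
  reds <- numeric(k)
  for (step in seq_len(k)) {
    if (step == 1L) {
      score <- relevance
    } else {
      score <- relevance - red_sum / (step - 1L)
    }
    score[selected] <- -Inf
    best <- which.max(score)              # which.max breaks ties low-index
    selected[step] <- best
    scores[step] <- score[best]
    reds[step] <- if (step == 1L) 0 else red_sum[best] / (step - 1L)
    if (step < k) {
      upd <- setdiff(seq_len(p), selected)
      red_sum[upd] <- red_sum[upd] +
        vapply(upd, function(j) discrete_mi_bits(disc[, j], disc[, best]),
               numeric(1))
    }
  }
  tibble::tibble(rank = seq_len(k), feature = colnames(ds$X)[selected],
                 index = selected, score = scores,
                 relevance = relevance[selected], redundancy = reds)
}

#' @keywords internal
zscore_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(mu = mu, sd = sd)
}

#' @keywords internal
zscore_apply <- function(X, zs) sweep(sweep(X, 2L, zs$mu), 2L, zs$sd, `/`)

#' @keywords internal
fit_rqda <- function(X, y, lambda = 1e-4) {
  classes <- levels(y)
  p <- ncol(X)
  mods <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    mu <- colMeans(Xi)
    S <- stats::cov(Xi)
    S <- S + diag(lambda * mean(diag(S)) + 1e-12, p)
    R <- chol(S)
    list(mu = mu, R = R, logdet = 2 * sum(log(diag(R))),
         logprior = log(nrow(Xi) / nrow(X)))
  })
  structure(list(classes = classes, mods = mods), class = "rqda")
}

#' @keywords internal
predict_rqda <- function(fit, X) {
  scores <- vapply(fit$mods, function(m) {
    Z <- forwardsolve(t(m$R), t(X) - m$mu)
    -0.5 * colSums(Z^2) - 0.5 * m$logdet + m$logprior
  }, numeric(nrow(X)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  factor(fit$classes[max.col(scores, ties.method = "first")],
         levels = fit$classes)
}

#' @keywords internal
default_model_params <- function(model) {
  switch(model,
         svm = list(kernel = "radial"),
         knn = list(k = 10L),
         decision_tree = list(cp = 0, maxdepth = 20L),
         qda = list(lambda = 1e-4),
         neural_network = list(size = 30L, decay = 1e-3, maxit = 200L))
}

#' @keywords internal
fit_predict <- function(model, Xtr, ytr, Xte, params) {
  params <- utils::modifyList(default_model_params(model), params)
  if (model %in% c("svm", "knn", "neural_network")) {
    zs <- zscore_fit(Xtr)
    Xtr <- zscore_apply(Xtr, zs)
    Xte <- zscore_apply(Xte, zs)
  }
  switch(model,
    svm = {
      fit <- e1071::svm(Xtr, ytr, kernel = params$kernel, scale = FALSE)
      stats::predict(fit, Xte)
    },
    knn = class::knn(Xtr, Xte, ytr, k = params$k),
    decision_tree = {
      df <- data.frame(y = ytr, Xtr)
      fit <- rpart::rpart(y ~ ., df, method = "class",
                          control = rpart::rpart.control(
                            cp = params$cp, maxdepth = params$maxdepth,
                            xval = 0))
      stats::predict(fit, data.frame(Xte), type = "class")
    },
    qda = predict_rqda(fit_rqda(Xtr, ytr, params$lambda), Xte),
    neural_network = {
      fit <- nnet::nnet(Xtr, nnet::class.ind(ytr), size = params$size,
                        decay = params$decay, maxit = params$maxit,
                        MaxNWts = 20000L, softmax = TRUE, trace = FALSE)
      pr <- stats::predict(fit, Xte)
      factor(levels(ytr)[max.col(pr, ties.method = "first")],
             levels = levels(ytr))
    },
    stop("unknown model: ", model))
}

#' @keywords internal
stratified_split <- function(y, frac) {
  test <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    test <- c(test, sample(idx, max(1L, round(length(idx) * frac))))
  }
  sort(test)
}

#' @keywords internal
stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Train and evaluate one stage classifier
#'
#' Protocol: a stratified 80/20 train-pool/test split (seed controlled)
#' precedes a stratified 10-fold cross-validation on the pool (9:1
#' train/validation within the pool). Validation accuracy is the mean of
#' the 10 fold accuracies; the model is then refit on the whole pool and
#' scored once on the untouched test set. Test indices are programmatically
#' asserted disjoint from every fold. Identical inputs and seed give an
#' identical report.
#'
#' Splitting is segment-level by default, mirroring a pooled-segments
#' design; `grouped = TRUE` instead assigns whole subject-sessions to
#' splits/folds (the leakage-safe alternative when segments within a
#' session are correlated).
#'
#' @param ds an `eeg_dataset`.
#' @param model one of `"svm"`, `"knn"`, `"decision_tree"`, `"qda"`,
#'   `"neural_network"`.
#' @param split_seed RNG seed controlling the split, folds and any model
#'   randomness.
#' @param test_frac held-out test fraction (default 0.2).
#' @param folds CV folds (default 10).
#' @param grouped split by subject-session groups instead of segments.
#' @param params named list overriding model hyperparameters.
#' @return a `classifier_report`: model, validation/test accuracy, 3 x 3
#'   confusion matrices (rows = true, cols = predicted), fold assignment and
#'   index bookkeeping.
#' @export
train_eval <- function(ds, model = c("svm", "knn", "decision_tree", "qda",
                                     "neural_network"),
                       split_seed = 1L, test_frac = 0.2, folds = 10L,
                       grouped = FALSE, params = list()) {
  model <- match.arg(model)
  stop_if_not(inherits(ds, "eeg_dataset"), "ds must be an eeg_dataset")
  with_seed(split_seed, {
    if (grouped) {
      g <- factor(ds$groups)
      gy <- factor(vapply(split(as.integer(ds$y), g), function(v)
        levels(ds$y)[round(stats::median(v))], character(1)), levels = levels(ds$y))
      gtest <- stratified_split(gy, test_frac)
      test_idx <- which(g %in% levels(g)[gtest])
      pool_idx <- setdiff(seq_along(ds$y), test_idx)
      gfold <- stratified_folds(gy[-gtest], folds)
      pool_groups <- g[pool_idx]
      fold_id <- gfold[match(pool_groups, levels(g)[-gtest])]
    } else {
      test_idx <- stratified_split(ds$y, test_frac)
      pool_idx <- setdiff(seq_along(ds$y), test_idx)
      fold_id <- stratified_folds(ds$y[pool_idx], folds)
    }
    stopifnot(length(intersect(test_idx, pool_idx)) == 0L)   # no leakage
    ypool <- ds$y[pool_idx]
    Xpool <- ds$X[pool_idx, , drop = FALSE]
    fold_acc <- numeric(folds)
    val_pred <- factor(rep(NA, length(ypool)), levels = levels(ds$y))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (nlevels(droplevels(ypool[tr])) < nlevels(ds$y) ||
          !any(!tr))
        stop("stratification failed: a fold is missing a class", call. = FALSE)
      pred <- fit_predict(model, Xpool[tr, , drop = FALSE], ypool[tr],
                          Xpool[!tr, , drop = FALSE], params)
      val_pred[!tr] <- pred
      fold_acc[f] <- mean(pred == ypool[!tr])
    }
    test_pred <- fit_predict(model, Xpool, ypool,
                             ds$X[test_idx, , drop = FALSE], params)
    ytest <- ds$y[test_idx]
    structure(list(
      model = model,
      validation_accuracy = mean(fold_acc),
      test_accuracy = mean(test_pred == ytest),
      confusion_validation = table(true = ypool, predicted = val_pred),
      confusion_test = table(true = ytest, predicted = test_pred),
      fold_accuracy = fold_acc, fold_id = fold_id,
      test_idx = test_idx, pool_idx = pool_idx,
      split_seed = split_seed, n = length(ds$y)),
      class = "classifier_report")
  })
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s: validation %.1f%%, test %.1f%% (n = %d)\n",
              x$model, 100 * x$validation_accuracy, 100 * x$test_accuracy, x$n))
  invisible(x)
}

#' Confusion matrix of a report
#'
#' @param report a `classifier_report`.
#' @param which `"test"` (default) or `"validation"`.
#' @return class x class count matrix, rows = true stage, columns =
#'   predicted stage.
#' @export
confusion <- function(report, which = c("test", "validation")) {
  which <- match.arg(which)
  m <- if (which == "test") report$confusion_test
       else report$confusion_validation
  unclass(m)
}
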