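test_that("dataset assembly orders rows, logs counts and enforces integrity", {
  set.seed(21)
  ft <- gaussian_feature_table(c(3, 4, 5)[1], stages = 1:3)
  ft <- rbind(gaussian_feature_table(3, stages = 1),
              gaussian_feature_table(4, stages = 2),
              gaussian_feature_table(5, stages = 3))
  expect_message(ds <- assemble_dataset(ft), "1=3, 2=4, 3=5")
  expect_identical(dim(ds$X), c(12L, 84L))
  expect_identical(levels(ds$y), c("1", "2", "3"))

  dup <- rbind(ft, ft[1, ])
  expect_error(suppressMessages(assemble_dataset(dup)), "duplicate")
  expect_error(suppressMessages(
    assemble_dataset(gaussian_feature_table(5, stages = 1))), "two stage")
})

test_that("MRMR ranks a planted informative feature first", {
  firsts <- vapply(1:10, function(s) {
    set.seed(s)
    ds <- planted_feature_dataset(n_per_class = 100, planted = 25, snr = 2)
    mrmr_rank(ds, k = 5)$index[1]
  }, numeric(1))
  expect_true(all(firsts == 25))
})

test_that("MRMR penalizes redundant copies below weaker independent features", {
  set.seed(22)
  n <- 300
  y <- rep(1:3, each = n / 3)
  X <- matrix(rnorm(n * 6), ncol = 6)
  X[, 1] <- y + rnorm(n, sd = 0.3)       # strong informative
  X[, 2] <- X[, 1]                        # exact duplicate
  X[, 3] <- y + rnorm(n, sd = 1.2)       # weaker but independent
  colnames(X) <- paste0("f", 1:6)
  ds <- structure(list(X = X, y = factor(y), groups = as.character(1:n),
                       counts = table(y)), class = "eeg_dataset")
  rk <- mrmr_rank(ds, k = 6)
  expect_identical(rk$index[1], 1L)
  expect_lt(which(rk$index == 3), which(rk$index == 2))
})

test_that("constant features are never ranked before informative ones", {
  set.seed(23)
  n <- 150
  y <- rep(1:3, each = n / 3)
  X <- cbind(rep(1, n), y + rnorm(n, sd = 0.5), rnorm(n))
  colnames(X) <- c("const", "info", "noise")
  ds <- structure(list(X = X, y = factor(y), groups = as.character(1:n),
                       counts = table(y)), class = "eeg_dataset")
  rk <- mrmr_rank(ds, k = 3)
  expect_identical(rk$index[1], 2L)
  expect_equal(rk$relevance[rk$index == 1], 0, tolerance = 1e-12)
})

test_that("well-separated clusters are classified nearly perfectly", {
  set.seed(24)
  n <- 240
  y <- factor(rep(1:3, each = n / 3))
  mu <- matrix(rnorm(3 * 84, sd = 4), 3)
  X <- mu[as.integer(y), ] + matrix(rnorm(n * 84), n)
  colnames(X) <- paste0("f", 1:84)
  ds <- structure(list(X = X, y = y, groups = as.character(1:n),
                       counts = table(y)), class = "eeg_dataset")
  for (m in c("svm", "knn")) {
    rep <- train_eval(ds, m, split_seed = 1)
    expect_gte(rep$test_accuracy, 0.99)
    expect_gte(rep$validation_accuracy, 0.99)
  }
  # every model of the suite runs and reports sane accuracies
  for (m in c("decision_tree", "qda", "neural_network")) {
    rep <- train_eval(ds, m, split_seed = 1,
                      params = if (m == "neural_network")
                        list(size = 10, maxit = 80) else list())
    expect_gte(rep$test_accuracy, 0.5)
    expect_lte(rep$test_accuracy, 1)
  }
})

test_that("permuted labels drop accuracy to chance", {
  set.seed(25)
  n <- 300
  y <- factor(sample(rep(1:3, each = n / 3)))
  X <- matrix(rnorm(n * 20), n)
  colnames(X) <- paste0("f", 1:20)
  ds <- structure(list(X = X, y = y, groups = as.character(1:n),
                       counts = table(y)), class = "eeg_dataset")
  rep <- train_eval(ds, "svm", split_seed = 2)
  expect_gt(rep$test_accuracy, 0.15)
  expect_lt(rep$test_accuracy, 0.55)
})

test_that("the protocol never leaks test samples and is seed-reproducible", {
  set.seed(26)
  ds <- planted_feature_dataset(40)
  r1 <- train_eval(ds, "decision_tree", split_seed = 7)
  r2 <- train_eval(ds, "decision_tree", split_seed = 7)
  expect_identical(r1$test_accuracy, r2$test_accuracy)
  expect_identical(r1$confusion_test, r2$confusion_test)
  expect_length(intersect(r1$test_idx, r1$pool_idx), 0)
  r3 <- train_eval(ds, "decision_tree", split_seed = 8)
  expect_false(identical(r1$test_idx, r3$test_idx))
})

test_that("confusion matrices conserve counts and diagonalize for perfect fits", {
  set.seed(27)
  ds <- planted_feature_dataset(50, snr = 20)
  rep <- train_eval(ds, "knn", split_seed = 3)
  cm <- confusion(rep)
  expect_identical(sum(cm), length(rep$test_idx))
  expect_equal(unname(rowSums(cm)),
               as.numeric(table(ds$y[rep$test_idx])))
  if (rep$test_accuracy == 1) expect_identical(sum(diag(cm)), sum(cm))
})
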