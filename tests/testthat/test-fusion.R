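# Feature fusion, XGBoost classification, AUC, ablation harness.

fake_deep <- function(len, backbone) {
  v <- rnorm(len)
  attr(v, "backbone") <- backbone
  v
}

test_that("fusion concatenates blocks in the fixed [deep || MA EX HEM] order", {
  counts <- c(MA = 1, EX = 2, HEM = 0)
  expect_equal(as.numeric(fuse_features(counts = counts)), c(1, 2, 0))
  set.seed(50)
  deep <- fake_deep(10, "vgg16")
  f <- fuse_features(deep, counts)
  expect_length(f, 13)
  expect_equal(as.numeric(f[11:13]), c(1, 2, 0))
  expect_equal(attr(f, "blocks"), c("vgg16", "lesions"))
  expect_error(fuse_features(), "at least one")
  expect_error(fuse_features(counts = c(a = 1)), "named MA")
})

test_that("separable lesion counts are classified perfectly", {
  set.seed(51)
  n <- 40
  y <- rep(c("healthy", "DR"), each = n / 2)
  X <- t(vapply(y, function(l) {
    if (l == "DR") c(sample(0:3, 1), sample(0:2, 1), sample(1:2, 1))
    else c(0, 0, 0)
  }, numeric(3)))
  colnames(X) <- lesion_classes()
  clf <- train_dr_classifier(X[seq(1, n, 2), ], y[seq(1, n, 2)], seed = 1)
  rep <- evaluate_dr(clf, X[seq(2, n, 2), ], y[seq(2, n, 2)])
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$auc, 1)
})

test_that("training is deterministic under a fixed seed", {
  set.seed(52)
  X <- matrix(rnorm(60 * 8), 60)
  y <- rep(c(0, 1), 30)
  c1 <- train_dr_classifier(X, y, seed = 3)
  c2 <- train_dr_classifier(X, y, seed = 3)
  expect_equal(predict_dr(c1, X), predict_dr(c2, X))
})

test_that("single-class training is rejected; dimension is free", {
  X <- matrix(rnorm(20 * 3), 20)
  expect_error(train_dr_classifier(X, rep("DR", 20)), "both classes")
  set.seed(53)
  y <- rep(c("healthy", "DR"), 10)
  expect_s3_class(train_dr_classifier(matrix(rnorm(20 * 3), 20), y),
                  "dr_classifier")
  expect_s3_class(train_dr_classifier(matrix(rnorm(20 * 500), 20), y,
                                      nrounds = 5), "dr_classifier")
})

test_that("rank AUC equals the brute-force pairwise Mann-Whitney oracle", {
  brute_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(54)
  for (i in 1:25) {
    n <- sample(4:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    expect_equal(auc_rank(s, y), brute_auc(s, y),
                 label = sprintf("case %d", i))
  }
  expect_equal(auc_rank(rep(0.7, 10), rep(c(0, 1), 5)), 0.5)
  expect_true(is.na(auc_rank(runif(5), rep(1, 5))))
})

test_that("rank AUC matches an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  s <- rnorm(40)
  expect_equal(auc_rank(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("evaluation reports are internally consistent with their confusion", {
  set.seed(56)
  X <- matrix(rnorm(40 * 4), 40)
  y <- rep(c("healthy", "DR"), 20)
  clf <- train_dr_classifier(X[1:30, ], y[1:30], seed = 2)
  rep <- evaluate_dr(clf, X[31:40, ], y[31:40], subset = "test")
  m <- metrics_from_confusion(rep$confusion)
  expect_equal(rep$accuracy, m$accuracy)
  expect_equal(rep$precision, m$precision)
  expect_equal(rep$recall, m$recall)
  expect_equal(rep$f1, m$f1)
  expect_equal(rep$accuracy_pct, round(100 * m$accuracy, 2))
  expect_equal(sum(rep$confusion), 10)
})

test_that("one error in 162 images reads as 99.38% accuracy", {
  # pluggable-classifier seam: fixed scores emulate a near-perfect model
  y <- rep(c("DR", "healthy"), each = 81)
  scores <- c(rep(0.9, 80), 0.1, rep(0.05, 81))  # one DR image missed
  eng <- function(x, y01, seed) list(predict = function(newx) scores)
  clf <- train_dr_classifier(matrix(0, 162, 1), y, engine = eng)
  rep <- evaluate_dr(clf, matrix(0, 162, 1), y)
  expect_equal(rep$confusion[["TP"]], 80)
  expect_equal(rep$confusion[["FN"]], 1)
  expect_equal(rep$confusion[["TN"]], 81)
  expect_equal(rep$confusion[["FP"]], 0)
  expect_equal(rep$accuracy_pct, 99.38)
})

test_that("the ablation harness enumerates the full subset grid", {
  set.seed(57)
  n <- 30
  y <- rep(c("healthy", "healthy", "DR", "DR"), length.out = n)
  lesions <- t(vapply(y, function(l)
    if (l == "DR") c(sample(1:3, 1), sample(0:2, 1), sample(0:1, 1))
    else c(0, 0, 0), numeric(3)))
  colnames(lesions) <- lesion_classes()
  feats <- list(vgg16 = matrix(rnorm(n * 12), n),
                resnet50 = matrix(rnorm(n * 20), n),
                lesions = lesions)
  tr <- seq(1, n, 2); te <- seq(2, n, 2)
  sub <- function(f, idx) lapply(f, function(m) m[idx, , drop = FALSE])
  out <- ablation_suite(sub(feats, tr), y[tr], sub(feats, te), y[te],
                        seed = 4, nrounds = 10)
  expect_length(out$reports, 11)
  expect_setequal(
    names(out$reports),
    c("vgg16", "resnet50", "lesions", "vgg16+resnet50", "vgg16+lesions",
      "resnet50+lesions", "vgg16+resnet50+lesions", "MA", "EX", "HEM",
      "MA+EX+HEM"))
  expect_equal(names(out$table),
               c("Classifier", "Accuracy %", "Precision", "Recall",
                 "F1-score", "AUC"))
  # lesion blocks are informative by construction; noise blocks are not
  expect_gte(out$reports$lesions$accuracy,
             out$reports[["vgg16+resnet50"]]$accuracy)
})
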