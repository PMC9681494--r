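#' Fuse deep features and lesion counts into one flat vector
#'
#' Deterministic block order `[deep || MA || EX || HEM]`. With VGG-16
#' features plus the three lesion counts the fused length is
#' 25,088 + 3 = 25,091; with ResNet-50, 100,352 + 3 = 100,355. Either
#' block may be absent (but not both).
#'
#' @param deep Numeric deep-feature vector (see
#'   [extract_deep_features()]), or `NULL`.
#' @param counts Named lesion counts `c(MA=, EX=, HEM=)`, or `NULL`.
#' @return Numeric vector with `attr(, "blocks")` describing the present
#'   feature blocks.
#' @export
fuse_features <- function(deep = NULL, counts = NULL) {
  if (is.null(deep) && is.null(counts))
    stop("at least one feature block must be present")
  blocks <- character(0)
  out <- numeric(0)
  if (!is.null(deep)) {
    blocks <- c(blocks, attr(deep, "backbone") %||% "deep")
    out <- c(out, as.numeric(deep))
  }
  if (!is.null(counts)) {
    cn <- lesion_classes()
    if (!all(cn %in% names(counts)))
      stop("counts must be named MA, EX, HEM")
    blocks <- c(blocks, "lesions")
    out <- c(out, as.numeric(counts[cn]))
  }
  attr(out, "blocks") <- blocks
  out
}

.as_binary_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    if (!all(y %in% c("healthy", "DR")))
      stop("labels must be 'healthy'/'DR' (or 0/1)")
    return(as.integer(y == "DR"))
  }
  if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1")
  as.integer(y)
}

#' Train the gradient-boosted DR classifier
#'
#' XGBoost with library default settings (binary logistic objective), a
#' fixed seed and a single thread for bit-reproducibility. A pluggable
#' seam: pass a function `engine(x, y01, seed)` returning a list with a
#' `predict(newx)` element to substitute any other classifier behind the
#' same interface.
#'
#' @param x Numeric feature matrix (rows = images).
#' @param y Labels: `"healthy"`/`"DR"`, factor, or 0/1 (1 = DR).
#' @param nrounds Boosting rounds (default 100).
#' @param params Extra XGBoost parameters merged over the defaults.
#' @param seed Integer seed.
#' @param engine `"xgboost"` (default) or a classifier-factory function.
#' @return An object of class `dr_classifier`.
#' @export
train_dr_classifier <- function(x, y, nrounds = 100, params = list(),
                                seed = 1L, engine = "xgboost") {
  x <- as.matrix(x)
  y01 <- .as_binary_labels(y)
  if (length(unique(y01)) < 2)
    stop("training labels must contain both classes")
  if (is.function(engine)) {
    fit <- engine(x, y01, seed)
    return(structure(list(fit = fit, engine = "custom", seed = seed),
                     class = "dr_classifier"))
  }
  pars <- modifyList(list(objective = "binary:logistic", nthread = 1,
                          seed = as.integer(seed)), params)
  dtrain <- xgboost::xgb.DMatrix(x, label = y01)
  booster <- xgboost::xgb.train(params = pars, data = dtrain,
                                nrounds = nrounds, verbose = 0)
  structure(list(fit = booster, engine = "xgboost",
                 version = as.character(utils::packageVersion("xgboost")),
                 nrounds = nrounds, params = pars, seed = seed,
                 n_features = ncol(x)),
            class = "dr_classifier")
}

#' @export
print.dr_classifier <- function(x, ...) {
  cat(sprintf("dr_classifier (%s%s), %s features\n", x$engine,
              if (!is.null(x$version)) paste0(" ", x$version) else "",
              x$n_features %||% "?"))
  invisible(x)
}

#' Predict DR scores
#'
#' @param clf A [train_dr_classifier()] model.
#' @param x Feature matrix.
#' @return Numeric vector of DR probabilities/scores.
#' @export
predict_dr <- function(clf, x) {
  x <- as.matrix(x)
  if (clf$engine == "custom") return(clf$fit$predict(x))
  predict(clf$fit, xgboost::xgb.DMatrix(x))
}

#' Rank-based AUC (Mann–Whitney with midranks)
#'
#' Area under the ROC curve computed as the normalized Mann–Whitney U
#' statistic; tied scores use the midrank convention. Equivalent to the
#' trapezoidal integral of the empirical ROC curve.
#'
#' @param scores Numeric classifier scores (higher = more DR-like).
#' @param labels Binary labels (1/`"DR"` = positive).
#' @return AUC in \eqn{[0,1]}, or `NA` when only one class is present.
#' @export
auc_rank <- function(scores, labels) {
  y <- .as_binary_labels(labels)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Evaluate the DR classifier on a labeled set
#'
#' Image-level confusion counts from hard predictions at score 0.5 (TP =
#' correctly classified DR images, TN = correctly classified healthy
#' images), the derived accuracy/precision/recall/F1, and the ranking AUC.
#'
#' @param clf A `dr_classifier`.
#' @param x Feature matrix.
#' @param y Labels.
#' @param subset Optional description of the feature subset used.
#' @return An `eval_report` list: `accuracy_pct` (percent, 2 decimals),
#'   `accuracy`, `precision`, `recall`, `f1`, `auc`, `confusion`, `n`,
#'   `subset`.
#' @export
evaluate_dr <- function(clf, x, y, subset = NULL) {
  y01 <- .as_binary_labels(y)
  scores <- predict_dr(clf, x)
  hard <- as.integer(scores >= 0.5)
  cc <- confusion_counts(hard == 1L, y01 == 1L)
  met <- metrics_from_confusion(cc)
  structure(list(accuracy_pct = round(100 * met$accuracy, 2),
                 accuracy = met$accuracy, precision = met$precision,
                 recall = met$recall, f1 = met$f1,
                 auc = auc_rank(scores, y01),
                 confusion = cc, n = length(y01),
                 subset = subset %||% "all"),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report [%s]: accuracy %.2f%%, P %.3f, R %.3f, F1 %.3f, AUC %.3f (n=%d)\n",
    x$subset, x$accuracy_pct, x$precision, x$recall, x$f1, x$auc, x$n))
  invisible(x)
}

#' Render evaluation reports as a metrics table
#'
#' @param reports Named list of `eval_report`s.
#' @return data.frame with columns Classifier, `Accuracy %`, Precision,
#'   Recall, `F1-score`, AUC.
#' @export
eval_report_table <- function(reports) {
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(Classifier = nm, `Accuracy %` = r$accuracy_pct,
               Precision = round(r$precision, 2), Recall = round(r$recall, 2),
               `F1-score` = round(r$f1, 2), AUC = round(r$auc, 3),
               check.names = FALSE)
  }))
}

.subset_matrix <- function(features, blocks, lesion_cols = NULL) {
  mats <- list()
  for (b in blocks) {
    if (b %in% c("vgg16", "resnet50")) mats[[b]] <- features[[b]]
    else if (b == "lesions") mats[[b]] <- features$lesions
    else mats[[b]] <- features$lesions[, b, drop = FALSE]
  }
  do.call(cbind, mats)
}

#' Feature-ablation harness
#'
#' Trains and evaluates one classifier per feature subset: the seven
#' non-empty combinations of \{vgg16, resnet50, lesions\}, the three
#' per-lesion singletons \{MA, EX, HEM\}, and the combined lesion trio —
#' the grid used to study which feature family carries the signal.
#' Subsets whose feature block is absent from `features` are skipped.
#'
#' @param train_features,test_features Lists with (any of) elements
#'   `vgg16`, `resnet50` (deep feature matrices) and `lesions` (n x 3
#'   count matrix with columns MA, EX, HEM).
#' @param train_labels,test_labels Binary labels.
#' @param seed Seed passed to every classifier fit.
#' @param nrounds,params Passed to [train_dr_classifier()].
#' @return List with `reports` (named `eval_report`s) and `table`
#'   (rendered data.frame).
#' @export
ablation_suite <- function(train_features, train_labels, test_features,
                           test_labels, seed = 1L, nrounds = 100,
                           params = list()) {
  deep_blocks <- intersect(c("vgg16", "resnet50"), names(train_features))
  has_lesions <- "lesions" %in% names(train_features)
  combos <- list()
  pool <- c(deep_blocks, if (has_lesions) "lesions")
  for (k in seq_along(pool))
    combos <- c(combos, utils::combn(pool, k, simplify = FALSE))
  if (has_lesions)
    combos <- c(combos, as.list(lesion_classes()),
                list(lesion_classes()))
  reports <- list()
  for (blocks in combos) {
    nm <- paste(blocks, collapse = "+")
    xtr <- .subset_matrix(train_features, blocks)
    xte <- .subset_matrix(test_features, blocks)
    clf <- train_dr_classifier(xtr, train_labels, nrounds = nrounds,
                               params = params, seed = seed)
    reports[[nm]] <- evaluate_dr(clf, xte, test_labels, subset = nm)
  }
  list(reports = reports, table = eval_report_table(reports))
}
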