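#' Pipeline run configuration
#'
#' Single source of parameters for an end-to-end run: data (either existing
#' manifests or a synthetic-data recipe), preprocessing, one segmentation
#' configuration per lesion class, the backbone choice, classifier
#' settings, and one global seed from which every stochastic stage derives
#' its own. Fully serializable to YAML/JSON.
#'
#' @param out_dir Output directory for all artifacts.
#' @param train_manifest,test_manifest Optional paths to existing manifest
#'   CSVs; when `NULL`, synthetic datasets are generated per `synth`.
#' @param synth List: `n_train_healthy`, `n_train_dr`, `n_test_healthy`,
#'   `n_test_dr`, and optional [synth_spec()] arguments under `template`.
#' @param preprocess List: `clip_limit`, `gamma`.
#' @param seg Named list of per-class [seg_config()] argument lists
#'   (`MA`, `EX`, `HEM`); entries are merged over `seg$default`.
#' @param lesion_source `"unet"` (train segmentation models and count
#'   predicted masks) or `"truth"` (count the ground-truth masks — the
#'   oracle path isolating classification from segmentation error).
#' @param backbone `NULL`, `"vgg16"` or `"resnet50"` (random weights).
#' @param classifier List: `nrounds`, `params`.
#' @param seed Global integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       train_manifest = NULL, test_manifest = NULL,
                       synth = list(n_train_healthy = 20, n_train_dr = 20,
                                    n_test_healthy = 10, n_test_dr = 10,
                                    template = list()),
                       preprocess = list(clip_limit = 2, gamma = 0.8),
                       seg = list(default = list(base_filters = 8,
                                                 epochs = 3)),
                       lesion_source = c("unet", "truth"),
                       backbone = NULL,
                       classifier = list(nrounds = 100, params = list()),
                       seed = 1L) {
  lesion_source <- match.arg(lesion_source)
  if (!is.null(backbone) && !backbone %in% c("vgg16", "resnet50"))
    stop("backbone must be NULL, 'vgg16' or 'resnet50'")
  structure(list(out_dir = out_dir, train_manifest = train_manifest,
                 test_manifest = test_manifest, synth = synth,
                 preprocess = preprocess, seg = seg,
                 lesion_source = lesion_source, backbone = backbone,
                 classifier = classifier, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tf))
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

.stage_stop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(...)), call. = FALSE)
}

# per-class seg_config assembled from cfg$seg with derived seed
.seg_cfg_for <- function(cfg, class, offset) {
  args <- modifyList(cfg$seg$default %||% list(),
                     cfg$seg[[class]] %||% list())
  args$lesion_class <- class
  args$seed <- (cfg$seed + offset) %% .Machine$integer.max
  do.call(seg_config, args)
}

#' Assemble training patches for one lesion class from a manifest
#'
#' Enhances every image, tiles image and class mask into aligned
#' overlapping patches, and records the source image of each patch so
#' folds can be grouped by image.
#'
#' @param manifest Manifest data.frame (see [read_manifest()]).
#' @param class `"MA"`, `"EX"` or `"HEM"`.
#' @param scfg The class's [seg_config()].
#' @param preprocess List with `clip_limit`, `gamma`.
#' @return List `patches`, `masks`, `group`.
#' @export
build_training_patches <- function(manifest, class, scfg,
                                   preprocess = list(clip_limit = 2,
                                                     gamma = 0.8)) {
  dir <- attr(manifest, "dir")
  maskcol <- paste0(tolower(class), "_mask")
  patches <- list(); masks <- list(); group <- integer(0)
  for (i in seq_len(nrow(manifest))) {
    img <- read_image(file.path(dir, manifest$image[i]))
    enh <- enhance(img, clip_limit = preprocess$clip_limit,
                   gamma = preprocess$gamma)
    msk <- read_mask(file.path(dir, manifest[[maskcol]][i]))
    pi <- tile_patches(enh$data, scfg$n, scfg$patch_stride)
    pm <- tile_patches(msk, scfg$n, scfg$patch_stride)
    patches <- c(patches, pi$patches)
    masks <- c(masks, pm$patches)
    group <- c(group, rep(i, length(pi$patches)))
  }
  list(patches = patches, masks = masks, group = group)
}

.manifest_labels <- function(m) m$label

.manifest_truth_counts <- function(manifest, min_area = 0) {
  dir <- attr(manifest, "dir")
  t(vapply(seq_len(nrow(manifest)), function(i) {
    masks <- list(MA = read_mask(file.path(dir, manifest$ma_mask[i])),
                  EX = read_mask(file.path(dir, manifest$ex_mask[i])),
                  HEM = read_mask(file.path(dir, manifest$hem_mask[i])))
    count_lesion_masks(masks, min_area = min_area)
  }, integer(3)))
}

.manifest_unet_counts <- function(manifest, models, preprocess) {
  dir <- attr(manifest, "dir")
  t(vapply(seq_len(nrow(manifest)), function(i) {
    img <- read_image(file.path(dir, manifest$image[i]))
    extract_lesion_features(img, models)
  }, integer(3)))
}

.manifest_deep_features <- function(manifest, backbone) {
  dir <- attr(manifest, "dir")
  t(vapply(seq_len(nrow(manifest)), function(i) {
    as.numeric(extract_deep_features(
      read_image(file.path(dir, manifest$image[i])), backbone))
  }, numeric(deep_feature_length(backbone$spec))))
}

#' Run the full DR-detection pipeline
#'
#' Orchestrates data generation/ingestion, contrast enhancement,
#' cross-validated segmentation training (one U-Net per lesion class),
#' lesion counting, deep feature extraction, feature fusion, classifier
#' training, and evaluation. Every stage failure aborts with a
#' stage-tagged message; all artifacts are written under `cfg$out_dir`
#' together with a machine-readable run summary carrying the config hash.
#'
#' @param cfg A [run_config()].
#' @return List with `report` (the test-set [evaluate_dr()] report),
#'   `seg_metrics` (per-class cross-validation metrics, when segmentation
#'   was trained), `counts` (train/test lesion-count matrices), `paths`
#'   (artifact locations) and `config_hash`.
#' @export
run_full_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  hash <- config_hash(cfg)
  # ---- validation (fail fast, before any compute) ----
  if (is.null(cfg$train_manifest) != is.null(cfg$test_manifest))
    .stage_stop("validate",
                "train and test manifests must be given together")
  for (mf in c(cfg$train_manifest, cfg$test_manifest))
    if (!file.exists(mf))
      .stage_stop("validate", "manifest not found: %s", mf)
  if (!dir.exists(cfg$out_dir) &&
      !dir.create(cfg$out_dir, recursive = TRUE))
    .stage_stop("validate", "cannot create out_dir %s", cfg$out_dir)

  # ---- data ----
  if (is.null(cfg$train_manifest)) {
    .log_stage("synth", "generating synthetic datasets (seed %d)", cfg$seed)
    template <- do.call(synth_spec, cfg$synth$template %||% list())
    tr_dir <- file.path(cfg$out_dir, "train")
    te_dir <- file.path(cfg$out_dir, "test")
    generate_fundus_dataset(cfg$synth$n_train_healthy, cfg$synth$n_train_dr,
                            template, tr_dir, seed = cfg$seed + 101L)
    generate_fundus_dataset(cfg$synth$n_test_healthy, cfg$synth$n_test_dr,
                            template, te_dir, seed = cfg$seed + 202L)
    cfg$train_manifest <- file.path(tr_dir, "manifest.csv")
    cfg$test_manifest <- file.path(te_dir, "manifest.csv")
  }
  train_m <- tryCatch(read_manifest(cfg$train_manifest),
                      error = function(e) .stage_stop("ingest", "%s",
                                                      conditionMessage(e)))
  test_m <- tryCatch(read_manifest(cfg$test_manifest),
                     error = function(e) .stage_stop("ingest", "%s",
                                                     conditionMessage(e)))

  # ---- lesion features ----
  seg_met <- NULL
  if (cfg$lesion_source == "unet") {
    models <- list(); seg_met <- list()
    for (ci in seq_along(lesion_classes())) {
      cl <- lesion_classes()[ci]
      scfg <- .seg_cfg_for(cfg, cl, 10L * ci)
      .log_stage("train-seg", "class %s: n=%d, base_filters=%d", cl,
                 scfg$n, scfg$base_filters)
      tp <- build_training_patches(train_m, cl, scfg, cfg$preprocess)
      cv <- train_seg_cv(tp$patches, tp$masks, scfg)
      models[[cl]] <- cv$model
      seg_met[[cl]] <- cv$metrics
      .log_stage("train-seg", "class %s: best fold %d, val IoU %.3f", cl,
                 cv$best_fold, cv$metrics$iou[cv$best_fold])
    }
    .log_stage("count", "extracting lesion counts from U-Net predictions")
    counts_tr <- .manifest_unet_counts(train_m, models, cfg$preprocess)
    counts_te <- .manifest_unet_counts(test_m, models, cfg$preprocess)
  } else {
    .log_stage("count", "counting ground-truth masks (oracle path)")
    counts_tr <- .manifest_truth_counts(train_m)
    counts_te <- .manifest_truth_counts(test_m)
  }
  colnames(counts_tr) <- colnames(counts_te) <- lesion_classes()

  # ---- deep features ----
  deep_tr <- deep_te <- NULL
  if (!is.null(cfg$backbone)) {
    .log_stage("features", "extracting %s deep features (random weights)",
               cfg$backbone)
    bb <- build_backbone(backbone_spec(cfg$backbone, "random",
                                       seed = cfg$seed + 303L))
    deep_tr <- .manifest_deep_features(train_m, bb)
    deep_te <- .manifest_deep_features(test_m, bb)
  }

  # ---- fusion + classification ----
  xtr <- if (is.null(deep_tr)) counts_tr else cbind(deep_tr, counts_tr)
  xte <- if (is.null(deep_te)) counts_te else cbind(deep_te, counts_te)
  subset <- paste(c(cfg$backbone, "lesions"), collapse = "+")
  .log_stage("train-clf", "training XGBoost on %d x %d features",
             nrow(xtr), ncol(xtr))
  clf <- train_dr_classifier(xtr, .manifest_labels(train_m),
                             nrounds = cfg$classifier$nrounds %||% 100,
                             params = cfg$classifier$params %||% list(),
                             seed = cfg$seed + 404L)
  report <- evaluate_dr(clf, xte, .manifest_labels(test_m), subset = subset)
  .log_stage("evaluate", "test accuracy %.2f%%, AUC %.3f",
             report$accuracy_pct, report$auc)

  # ---- artifacts ----
  paths <- list(
    counts_train = file.path(cfg$out_dir, "counts_train.csv"),
    counts_test = file.path(cfg$out_dir, "counts_test.csv"),
    report = file.path(cfg$out_dir, "eval_report.json"),
    summary = file.path(cfg$out_dir, "run_summary.json"))
  aug <- function(m, counts) cbind(m, ma_count = counts[, "MA"],
                                   ex_count = counts[, "EX"],
                                   hem_count = counts[, "HEM"])
  write.csv(aug(as.data.frame(train_m), counts_tr), paths$counts_train,
            row.names = FALSE)
  write.csv(aug(as.data.frame(test_m), counts_te), paths$counts_test,
            row.names = FALSE)
  jsonlite::write_json(list(config_hash = hash,
                            report = unclass(report)[c(
                              "accuracy_pct", "precision", "recall", "f1",
                              "auc", "n", "subset")],
                            confusion = as.list(report$confusion)),
                       paths$report, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(config_hash = hash, config = unclass(cfg),
                            seg_metrics = seg_met),
                       paths$summary, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  list(report = report, seg_metrics = seg_met,
       counts = list(train = counts_tr, test = counts_te),
       paths = paths, config_hash = hash)
}
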