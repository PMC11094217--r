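# Confusion-matrix evaluation and end-to-end orchestration. The binary
# screening reduction groups the three normal cell types as negative and
# the four dysplastic/malignant types as positive; the full 7x7 confusion
# matrix and macro-averaged one-vs-rest table are always reported as well.

#' Binary confusion counts
#'
#' Reduces multi-class truth/prediction vectors to the screening binary:
#' positive = membership in `positive` (default the abnormal classes).
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive Labels counted as positive.
#' @return List with integer `TP`, `TN`, `FP`, `FN` (summing to `n`).
#' @export
confusion <- function(y_true, y_pred, positive = abnormal_classes()) {
  if (length(y_true) != length(y_pred))
    stop("label vectors differ in length", call. = FALSE)
  if (!length(y_true)) stop("empty label vectors", call. = FALSE)
  tp_true <- y_true %in% positive
  tp_pred <- y_pred %in% positive
  list(TP = sum(tp_true & tp_pred), TN = sum(!tp_true & !tp_pred),
       FP = sum(!tp_true & tp_pred), FN = sum(tp_true & !tp_pred))
}

metric_ratio <- function(num, den) {
  if (den == 0) NA_real_ else num / den
}

#' Confusion-matrix metrics
#'
#' `specificity = TN/(TN+FP)`, `sensitivity = TP/(TP+FN)`,
#' `accuracy = (TP+TN)/n`, `precision = TP/(TP+FP)`,
#' `npv = TN/(TN+FN)`. A metric whose denominator is zero is reported as
#' `NA` (serialized as null), never as 0.
#'
#' @param counts List with `TP`, `TN`, `FP`, `FN` (see [confusion()]).
#' @return Scalar in \[0, 1\] or `NA`.
#' @export
specificity <- function(counts) metric_ratio(counts$TN, counts$TN + counts$FP)

#' @rdname specificity
#' @export
sensitivity <- function(counts) metric_ratio(counts$TP, counts$TP + counts$FN)

#' @rdname specificity
#' @export
accuracy <- function(counts)
  metric_ratio(counts$TP + counts$TN,
               counts$TP + counts$TN + counts$FP + counts$FN)

#' @rdname specificity
#' @export
precision <- function(counts) metric_ratio(counts$TP, counts$TP + counts$FP)

#' @rdname specificity
#' @export
npv <- function(counts) metric_ratio(counts$TN, counts$TN + counts$FN)

binary_metrics <- function(counts) {
  list(counts = counts,
       specificity = specificity(counts), sensitivity = sensitivity(counts),
       accuracy = accuracy(counts), precision = precision(counts),
       npv = npv(counts))
}

#' Full classification report
#'
#' Binary (normal vs abnormal) metrics, the 7x7 confusion matrix, a
#' per-class one-vs-rest table and its macro averages.
#'
#' @param y_true,y_pred Label vectors.
#' @param class_names Ordered class vocabulary.
#' @return List with `binary`, `confusion_matrix`, `per_class`, `macro`.
#' @export
metrics_report <- function(y_true, y_pred, class_names = cyto_classes()) {
  cm <- table(factor(y_true, levels = class_names),
              factor(y_pred, levels = class_names))
  per <- lapply(class_names, function(cl) {
    c_ <- confusion(y_true, y_pred, positive = cl)
    data.frame(class = cl, TP = c_$TP, FP = c_$FP, FN = c_$FN, TN = c_$TN,
               sensitivity = sensitivity(c_), precision = precision(c_),
               specificity = specificity(c_), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  macro <- list(sensitivity = mean(per$sensitivity, na.rm = TRUE),
                precision = mean(per$precision, na.rm = TRUE),
                specificity = mean(per$specificity, na.rm = TRUE))
  list(binary = binary_metrics(confusion(y_true, y_pred)),
       confusion_matrix = cm, per_class = per, macro = macro)
}

#' Default pipeline configuration
#'
#' @param manifest Path to the dataset manifest CSV.
#' @param mask_dir Optional directory of ground-truth masks named like the
#'   images; enables Dice reporting.
#' @param seed Master seed for the whole run.
#' @param n_thresholds,objective Segmentation settings.
#' @param segment_population,segment_iterations Optimizer budget per image.
#' @param preprocess A [preprocess_config()].
#' @param glcm,gabor Feature configurations.
#' @param lbp_on_gabor Compute LBP on the Gabor response image.
#' @param train An [ssnf_train_config()] (its seed is derived from `seed`).
#' @param out_dir Optional run directory for artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(manifest, mask_dir = NULL, seed = 1L,
                            n_thresholds = 2,
                            objective = "otsu",
                            segment_population = 20,
                            segment_iterations = 40,
                            preprocess = preprocess_config(),
                            glcm = glcm_config(), gabor = gabor_config(),
                            lbp_on_gabor = FALSE,
                            train = ssnf_train_config(),
                            out_dir = NULL) {
  structure(list(manifest = manifest, mask_dir = mask_dir,
                 seed = as.integer(seed), n_thresholds = n_thresholds,
                 objective = objective,
                 segment_population = segment_population,
                 segment_iterations = segment_iterations,
                 preprocess = preprocess, glcm = glcm, gabor = gabor,
                 lbp_on_gabor = isTRUE(lbp_on_gabor), train = train,
                 out_dir = out_dir),
            class = "pipeline_config")
}

# read a pipeline config from YAML (blocks: data, preprocess, segment,
# features, ssnf, seed)
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pre <- do.call(preprocess_config, y$preprocess %||% list())
  tr_args <- y$ssnf %||% list()
  tr <- do.call(ssnf_train_config, tr_args)
  seg <- y$segment %||% list()
  feat <- y$features %||% list()
  pipeline_config(
    manifest = y$data$manifest,
    mask_dir = y$data$mask_dir,
    seed = y$seed %||% 1L,
    n_thresholds = seg$n_thresholds %||% 2,
    objective = seg$objective %||% "otsu",
    segment_population = seg$population_size %||% 20,
    segment_iterations = seg$max_iterations %||% 40,
    preprocess = pre,
    lbp_on_gabor = feat$lbp_on_gabor %||% FALSE,
    train = tr,
    out_dir = y$out_dir)
}

stage_error <- function(stage, path, e) {
  stop(sprintf("[%s] failed for %s: %s", stage, path, conditionMessage(e)),
       call. = FALSE)
}

#' Run the full pipeline on a manifest
#'
#' For every image: preprocess, optimizer-driven threshold segmentation,
#' ROI crop, texture feature extraction. The feature transform and the
#' classifier are fitted on the training split; the test split is
#' classified and scored. When `mask_dir` is given, nucleus/cytoplasm Dice
#' against ground truth is reported for the test images. Fully
#' deterministic given `cfg$seed` (per-image optimizer seeds and the
#' training seed are derived from it).
#'
#' @param cfg A [pipeline_config()], or a path to a YAML file.
#' @return List with `report` (see [metrics_report()]), `dice`
#'   (per-test-image nucleus and cytoplasm Dice, or `NULL`), `model`,
#'   `predictions` data frame, and `seed`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  manifest <- tryCatch(load_manifest(cfg$manifest),
                       error = function(e) stage_error("data", cfg$manifest, e))
  n <- nrow(manifest)
  feats <- matrix(NA_real_, n, 58)
  dice_nuc <- dice_cyto <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    path <- manifest$image_path[i]
    img <- tryCatch(read_image(path),
                    error = function(e) stage_error("imgio", path, e))
    pim <- tryCatch(preprocess_image(img, cfg$preprocess),
                    error = function(e) stage_error("preprocess", path, e))
    seg <- tryCatch(
      ho_threshold_search(pim, cfg$n_thresholds, cfg$objective,
                          cfg$segment_population, cfg$segment_iterations,
                          seed = cfg$seed + i),
      error = function(e) stage_error("segment", path, e))
    mask <- apply_thresholds(pim, seg$thresholds)
    if (!is.null(cfg$mask_dir)) {
      mpath <- file.path(cfg$mask_dir, basename(path))
      if (file.exists(mpath)) {
        om <- overlap_metrics(mask, read_mask(mpath))
        dice_nuc[i] <- om$dice[["label_2"]]
        dice_cyto[i] <- om$dice[["label_1"]]
      }
    }
    roi <- tryCatch(extract_roi(pim, mask),
                    error = function(e) stage_error("segment", path, e))
    feats[i, ] <- tryCatch(
      extract_features(roi, cfg$glcm, cfg$gabor, cfg$lbp_on_gabor),
      error = function(e) stage_error("features", path, e))
  }
  colnames(feats) <- feature_names(cfg$glcm, cfg$gabor)
  is_train <- manifest$split == "train"
  is_test <- manifest$split == "test"
  if (!any(is_train) || !any(is_test))
    stop("[data] manifest must contain both train and test records",
         call. = FALSE)
  std <- standardize_features(feats[is_train, , drop = FALSE])
  tr_cfg <- cfg$train
  tr_cfg$seed <- cfg$seed + 1000003L
  model <- tryCatch(
    ssnf_train(std$X, manifest$class_label[is_train],
               class_names = attr(manifest, "class_names"),
               cfg = tr_cfg, transform = std$transform),
    error = function(e) stage_error("ssnf", cfg$manifest, e))
  X_test <- apply_standardization(std$transform,
                                  feats[is_test, , drop = FALSE])
  y_pred <- ssnf_classify(model, X_test)
  y_true <- manifest$class_label[is_test]
  report <- metrics_report(y_true, y_pred,
                           class_names = attr(manifest, "class_names"))
  dice <- if (!is.null(cfg$mask_dir))
    list(nucleus = dice_nuc[is_test], cytoplasm = dice_cyto[is_test])
  else NULL
  preds <- data.frame(image_path = manifest$image_path[is_test],
                      true = y_true, predicted = y_pred,
                      stringsAsFactors = FALSE)
  out <- list(report = report, dice = dice, model = model,
              predictions = preds, seed = cfg$seed)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    save_model(model, file.path(cfg$out_dir, "model.json"))
    utils::write.csv(preds, file.path(cfg$out_dir, "predictions.csv"),
                     row.names = FALSE)
    rep_json <- list(
      seed = cfg$seed,
      binary = report$binary,
      macro = report$macro,
      confusion_matrix = as.data.frame.matrix(report$confusion_matrix),
      per_class = report$per_class,
      dice = if (!is.null(dice))
        list(nucleus_mean = mean(dice$nucleus, na.rm = TRUE),
             cytoplasm_mean = mean(dice$cytoplasm, na.rm = TRUE)))
    jsonlite::write_json(rep_json, file.path(cfg$out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE, na = "null")
  }
  out
}
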