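# Dataset readers/writers (challenge-style layout: images/NNN.png,
# masks/NNN_Annotation.png, annotations.csv), experiment configuration, and
# the cross-validated experiment runner tying both HC routes together.

#' Write a phantom dataset to disk
#'
#' Layout: `images/<filename>` (8-bit grayscale PNG),
#' `masks/<stem>_Annotation.png` (0/255 PNG of the filled head mask), and
#' `annotations.csv` with columns `filename`, `pixel_size_mm`, `hc_mm`.
#'
#' @param dataset A list with `records` and `annotations` as produced by
#'   [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  ann <- dataset$annotations
  for (i in seq_along(dataset$records)) {
    rec <- dataset$records[[i]]
    png::writePNG(rec$image, file.path(dir, "images", ann$filename[i]))
    stem <- sub("\\.png$", "", ann$filename[i])
    write_mask_png(rec$gt_mask,
                   file.path(dir, "masks", paste0(stem, "_Annotation.png")))
  }
  utils::write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a dataset from disk
#'
#' Reads the layout written by [write_dataset()] (or any dataset in the same
#' challenge-style format). The annotation table is validated strictly
#' (unique filenames, positive pixel sizes and HC values, images present);
#' missing masks are tolerated with a warning (prediction-only mode).
#'
#' @param dir Dataset directory.
#' @return A list with `records` (each with `id`, `image`, `gt_mask` or NULL,
#'   `spacing`, `hc_mm`) and `annotations`.
#' @export
read_dataset <- function(dir) {
  csv <- file.path(dir, "annotations.csv")
  if (!file.exists(csv))
    stop_invalid_input(sprintf("annotation file not found: %s", csv))
  ann <- utils::read.csv(csv, stringsAsFactors = FALSE)
  need <- c("filename", "pixel_size_mm", "hc_mm")
  if (!all(need %in% names(ann)))
    stop_invalid_input(sprintf("annotations.csv must have columns %s",
                               paste(need, collapse = ", ")))
  if (anyDuplicated(ann$filename))
    stop_invalid_input("duplicate filenames in annotations.csv")
  bad <- which(!is.finite(ann$pixel_size_mm) | ann$pixel_size_mm <= 0 |
                 !is.finite(ann$hc_mm) | ann$hc_mm <= 0)
  if (length(bad))
    stop_invalid_input(sprintf(
      "invalid pixel size or HC in annotations.csv row %d (%s)",
      bad[1], ann$filename[bad[1]]))
  any_missing_mask <- FALSE
  records <- lapply(seq_len(nrow(ann)), function(i) {
    ipath <- file.path(dir, "images", ann$filename[i])
    if (!file.exists(ipath))
      stop_invalid_input(sprintf("image not found: %s", ipath))
    img <- png::readPNG(ipath)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    stem <- sub("\\.png$", "", ann$filename[i])
    mpath <- file.path(dir, "masks", paste0(stem, "_Annotation.png"))
    mask <- NULL
    if (file.exists(mpath)) mask <- read_mask_png(mpath)
    else any_missing_mask <<- TRUE
    list(id = stem, image = img, gt_mask = mask,
         spacing = pixel_spacing(ann$pixel_size_mm[i]), hc_mm = ann$hc_mm[i])
  })
  if (any_missing_mask)
    warning("some masks are absent; dataset loaded in prediction-only mode")
  list(records = records, annotations = ann)
}

#' Default desk-scale experiment configuration
#'
#' A complete, validated configuration for [run_experiment()]. The defaults
#' run a small but end-to-end cross-validated comparison of the two routes on
#' synthetic phantoms in a few minutes on one CPU; each field can be
#' overridden. Fields:
#' `seed` (master seed for everything), `n_images`, `folds`, `routes`,
#' `phantom` (a [phantom_config()]), `input_size`, `epochs_seg`, `epochs_reg`,
#' `lr_seg`, `lr_reg`, `batch_size`, `depth_seg`, `depth_reg`, `base_filters`,
#' `dropout_keep`, `loss_reg` (one of MAE/MSE/Huber), `augment` (apply the
#' flip+rotation augmentation to each training fold), `threshold`.
#'
#' @param ... Overrides of the fields above.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(...) {
  cfg <- list(seed = 1L, n_images = 80L, folds = 2L,
              routes = c("segmentation", "regression"),
              phantom = phantom_config(size = c(64L, 64L)),
              input_size = c(64L, 64L), epochs_seg = 15L, epochs_reg = 30L,
              lr_seg = 1e-3, lr_reg = 2e-3, batch_size = 16L, depth_seg = 3L,
              depth_reg = 5L, base_filters = 8L, dropout_keep = 0.9,
              loss_reg = "MAE", augment = TRUE, threshold = 0.5)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop_config_error(sprintf("unknown experiment config keys: %s",
                              paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  if (!all(cfg$routes %in% c("segmentation", "regression")))
    stop_config_error("routes must be 'segmentation' and/or 'regression'")
  if (cfg$folds < 2L) stop_config_error("folds must be >= 2")
  if (cfg$n_images < 2L * cfg$folds)
    stop_config_error("n_images too small for the requested folds")
  if (!cfg$loss_reg %in% c("MAE", "MSE", "Huber"))
    stop_config_error("loss_reg must be MAE, MSE or Huber")
  structure(cfg, class = "experiment_config")
}

#' Read an experiment configuration from a YAML/JSON file
#'
#' Unknown keys are rejected before any computation.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file of overrides.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop_config_error(sprintf("config not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$phantom)) vals$phantom <- do.call(phantom_config, vals$phantom)
  do.call(experiment_config, vals)
}

# train both routes on one fold and predict its test set
run_fold <- function(records, fold, cfg, fold_id) {
  train_recs <- records[fold$train]
  test_recs <- records[fold$test]
  if (isTRUE(cfg$augment)) train_recs <- augment_training_set(train_recs)
  out <- list()

  if ("segmentation" %in% cfg$routes) {
    tc <- train_config(learning_rate = cfg$lr_seg,
                       batch_size = cfg$batch_size, epochs = cfg$epochs_seg,
                       seed = cfg$seed + fold_id, input_size = cfg$input_size,
                       depth = cfg$depth_seg, base_filters = cfg$base_filters)
    net <- build_tiny_segnet(tc)
    fit <- train_model(net, list(
      x = lapply(train_recs, `[[`, "image"),
      y = lapply(train_recs, `[[`, "gt_mask")), tc)
    preds <- lapply(test_recs, function(r)
      estimate_hc_segmentation(r$image, fit$model, r$spacing, id = r$id,
                               threshold = cfg$threshold))
    segm <- lapply(test_recs, function(r) {
      pm <- predict_prob_map(fit$model, r$image)
      pm_full <- resize_bilinear(pm, nrow(r$image), ncol(r$image))
      binarize(pmin(pmax(pm_full, 0), 1), cfg$threshold)
    })
    dice <- mapply(function(s, r) dice_index(s, r$gt_mask), segm, test_recs)
    hd <- assd <- rep(NA_real_, length(test_recs))
    for (i in seq_along(test_recs)) {
      ok <- tryCatch({
        cs <- boundary_points(segm[[i]])
        cg <- boundary_points(test_recs[[i]]$gt_mask)
        hd[i] <- hausdorff_mm(cs, cg, test_recs[[i]]$spacing)
        assd[i] <- assd_mm(cs, cg, test_recs[[i]]$spacing)
        TRUE
      }, fetalhc_error = function(e) FALSE)
    }
    out$segmentation <- list(preds = preds, trace = fit$trace, dice = dice,
                             hd = hd, assd = assd)
  }

  if ("regression" %in% cfg$routes) {
    hc_train <- vapply(train_recs, `[[`, numeric(1), "hc_mm")
    tc <- train_config(learning_rate = cfg$lr_reg,
                       batch_size = cfg$batch_size, epochs = cfg$epochs_reg,
                       seed = cfg$seed + 100L + fold_id,
                       input_size = cfg$input_size, depth = cfg$depth_reg,
                       base_filters = cfg$base_filters,
                       dropout_keep = cfg$dropout_keep,
                       hc_norm_constant = max(hc_train))
    net <- build_tiny_regnet(tc)
    fit <- train_model(net, list(
      x = lapply(train_recs, `[[`, "image"), y = hc_train), tc,
      loss = regression_loss_spec(cfg$loss_reg))
    preds <- lapply(test_recs, function(r)
      estimate_hc_regression(r$image, fit$model, tc, id = r$id))
    out$regression <- list(preds = preds, trace = fit$trace)
  }
  out
}

#' Run a cross-validated two-route experiment on synthetic phantoms
#'
#' Generates a phantom dataset, builds seeded k-fold cross-validation splits
#' shared by both routes, trains the miniature segmentation and/or regression
#' models on each training fold, predicts every test fold, and aggregates HC
#' errors, segmentation metrics and agreement statistics. Failed segmentation
#' fits are excluded from the error aggregates and their count is reported.
#'
#' @param config An `experiment_config` (or path to a YAML file of overrides).
#' @param out_dir Optional directory; when given, writes `summary.csv`,
#'   `predictions.csv`, per-route agreement JSON and plots.
#' @return A list with `summary` (one row per route: mean and sd of MAE and
#'   PMAE across folds, plus Dice/HD/ASSD for the segmentation route),
#'   `predictions` (per-image data frame), `agreement` (per-route
#'   [agreement_report()] on pooled predictions), `paired_p` (paired t-test
#'   p-value between the two routes' absolute errors on commonly predicted
#'   images, `NA` if a single route), `n_failed` (failed segmentations), and
#'   `config`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  ds <- generate_dataset(config$n_images, config$seed, config$phantom)
  folds <- kfold_indices(config$n_images, config$folds, config$seed)
  gt_by_id <- stats::setNames(
    vapply(ds$records, `[[`, numeric(1), "hc_mm"),
    vapply(ds$records, `[[`, character(1), "id"))

  preds <- data.frame()
  fold_rows <- data.frame()
  seg_metrics <- data.frame()
  for (f in seq_along(folds)) {
    res <- run_fold(ds$records, folds[[f]], config, f)
    for (route in names(res)) {
      pr <- res[[route]]$preds
      preds <- rbind(preds, data.frame(
        fold = f, route = route,
        id = vapply(pr, `[[`, character(1), "id"),
        hc_pred_mm = vapply(pr, `[[`, numeric(1), "hc_mm"),
        failed = vapply(pr, `[[`, logical(1), "failed"),
        stringsAsFactors = FALSE))
      if (route == "segmentation")
        seg_metrics <- rbind(seg_metrics, data.frame(
          fold = f, dice = res$segmentation$dice,
          hd_mm = res$segmentation$hd, assd_mm = res$segmentation$assd))
    }
  }
  preds$hc_gt_mm <- unname(gt_by_id[preds$id])

  summarize_route <- function(route) {
    p <- preds[preds$route == route & !preds$failed, ]
    by_fold <- lapply(split(p, p$fold), function(pf)
      hc_errors(pf$hc_pred_mm, pf$hc_gt_mm))
    mae <- vapply(by_fold, `[[`, numeric(1), "mae")
    pmae <- vapply(by_fold, `[[`, numeric(1), "pmae")
    row <- data.frame(route = route, mae_mm = mean(mae), mae_sd = stats::sd(mae),
                      pmae_pct = mean(pmae), pmae_sd = stats::sd(pmae),
                      dice = NA_real_, hd_mm = NA_real_, assd_mm = NA_real_)
    if (route == "segmentation" && nrow(seg_metrics)) {
      row$dice <- mean(seg_metrics$dice, na.rm = TRUE)
      row$hd_mm <- mean(seg_metrics$hd_mm, na.rm = TRUE)
      row$assd_mm <- mean(seg_metrics$assd_mm, na.rm = TRUE)
    }
    row
  }
  summary <- do.call(rbind, lapply(unique(preds$route), summarize_route))

  agreement <- list()
  for (route in unique(preds$route)) {
    p <- preds[preds$route == route & !preds$failed, ]
    if (nrow(p) >= 3L)
      agreement[[route]] <- agreement_report(p$hc_pred_mm, p$hc_gt_mm)
  }
  paired_p <- NA_real_
  if (all(c("segmentation", "regression") %in% unique(preds$route))) {
    ps <- preds[preds$route == "segmentation" & !preds$failed, ]
    pr <- preds[preds$route == "regression", ]
    common <- intersect(ps$id, pr$id)
    if (length(common) >= 3L) {
      ea <- abs(ps$hc_pred_mm - ps$hc_gt_mm)[match(common, ps$id)]
      eb <- abs(pr$hc_pred_mm - pr$hc_gt_mm)[match(common, pr$id)]
      paired_p <- paired_t(ea, eb)
    }
  }
  n_failed <- sum(preds$failed)
  if (n_failed > 0)
    message(sprintf("%d segmentation prediction(s) failed and were excluded",
                    n_failed))

  result <- list(summary = summary, predictions = preds,
                 agreement = agreement, paired_p = paired_p,
                 n_failed = n_failed, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- sprintf("# seed: %d", config$seed)
    write_csv_with_header <- function(df, path) {
      con <- file(path, "w"); on.exit(close(con))
      writeLines(hdr, con)
      utils::write.csv(df, con, row.names = FALSE)
    }
    write_csv_with_header(summary, file.path(out_dir, "summary.csv"))
    write_csv_with_header(preds, file.path(out_dir, "predictions.csv"))
    for (route in names(agreement)) {
      write_agreement_json(agreement[[route]],
                           file.path(out_dir, paste0("agreement_", route, ".json")))
      p <- preds[preds$route == route & !preds$failed, ]
      plot_agreement(p$hc_pred_mm, p$hc_gt_mm,
                     file.path(out_dir, paste0("agreement_", route, ".png")),
                     main = route)
    }
  }
  result
}
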