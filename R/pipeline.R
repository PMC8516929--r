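# Workflow entry points: cohort synthesis, training, prediction,
# evaluation, and the end-to-end synthetic benchmark. A thin command-line
# wrapper over these functions ships in inst/cli/wsimine.R.

#' Pipeline configuration
#'
#' All defaults follow the reference training recipe: k = 16, N = 256,
#' batch size 32, Adam (0.9, 0.999), initial learning rate 0.001 decayed by
#' 0.95 every 2 epochs, patience 2 (phase switch) / 10 (early stop),
#' decision threshold 0.5, 1000 bootstrap iterations. The four standard
#' model configurations (two-stage x10/224 and one-stage x10/224, x20/224,
#' x20/512) are all expressible.
#'
#' @param mode "one_stage" or "two_stage".
#' @param magnification nominal tile magnification (10 or 20 typically).
#' @param tile_size tile side in pixels (224 or 512 typically).
#' @param stride sliding-window stride for heatmap inference and hard-tile
#'   mining. Defaults to half the tile size: annotation sampling centres
#'   training tiles on lesions, so a non-overlapping inference grid can
#'   split every lesion across cell borders and dilute its tiles; a
#'   half-tile stride guarantees some window nearly re-centres each lesion.
#' @param min_tissue_fraction per-tile tissue criterion.
#' @param thumbnail_downsample tissue-detection downsample.
#' @param k,N hard-mining parameters.
#' @param batch_size,initial_lr,lr_decay,decay_every,beta1,beta2 optimiser.
#' @param switch_patience,stop_patience patience in epochs.
#' @param threshold,n_bootstrap evaluation settings.
#' @param seed master seed; all internal seeds derive from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("one_stage", "two_stage"),
                            magnification = 20, tile_size = 224L,
                            stride = max(1L, tile_size %/% 2L),
                            min_tissue_fraction = 0.25,
                            thumbnail_downsample = 32L,
                            k = 16L, N = 256L, batch_size = 32L,
                            initial_lr = 0.001, lr_decay = 0.95,
                            decay_every = 2L, beta1 = 0.9, beta2 = 0.999,
                            switch_patience = 2L, stop_patience = 10L,
                            threshold = 0.5, n_bootstrap = 1000L,
                            seed = 1L) {
  mode <- match.arg(mode)
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  stopifnot(cfg$magnification > 0, is_count(cfg$tile_size, 1),
            is_count(cfg$stride, 1))
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Synthesise a cohort on disk
#'
#' Generates `n_positive` + `n_negative` synthetic slides and writes them
#' with annotations and a manifest (see [write_cohort()]). `split_counts`
#' optionally assigns train/val/test splits: a named list of
#' `c(positive, negative)` counts that must sum to the cohort size.
#'
#' @param out_dir output directory.
#' @param n_positive,n_negative slide counts.
#' @param spec template `synthetic_slide_spec`.
#' @param seed cohort seed.
#' @param split_counts e.g. `list(train = c(40, 40), val = c(10, 10))`.
#' @param force overwrite a non-empty directory.
#' @return manifest path, invisibly.
#' @export
run_synth <- function(out_dir, n_positive, n_negative,
                      spec = synthetic_slide_spec(), seed = 1L,
                      split_counts = NULL, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stopf("output directory %s is not empty (use force = TRUE)", out_dir)
  split <- NULL
  if (!is.null(split_counts)) {
    pos <- vapply(split_counts, `[`, 0, 1)
    neg <- vapply(split_counts, `[`, 0, 2)
    if (sum(pos) != n_positive || sum(neg) != n_negative)
      stopf("split_counts must sum to the cohort size per label")
    split <- c(rep(names(split_counts), pos), rep(names(split_counts), neg))
  }
  dir.create(file.path(out_dir, "slides"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "annotations"), showWarnings = FALSE)
  # slides are generated and written one at a time: a cohort never needs to
  # fit in memory
  rows <- lapply(seq_len(n_positive + n_negative), function(i) {
    m <- cohort_member_spec(spec, i, n_positive, seed)
    r <- generate_slide(m$spec, slide_id = m$slide_id)
    sp <- file.path("slides", paste0(r$slide_id, ".tif"))
    write_slide(r$slide, file.path(out_dir, sp))
    ap <- ""
    if (length(r$annotations) > 0) {
      ap <- file.path("annotations", paste0(r$slide_id, ".geojson"))
      write_annotations(r$annotations, file.path(out_dir, ap))
    }
    data.frame(slide_id = r$slide_id, slide_path = sp, annotation_path = ap,
               label = r$label,
               split = if (is.null(split)) NA_character_ else split[i])
  })
  manifest <- do.call(rbind, rows)
  if (is.null(split)) manifest$split <- NULL
  path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Load a cohort manifest into labelled slide entries
#'
#' @param manifest_path path to a `manifest.csv` written by [run_synth()]
#'   (paths are resolved relative to the manifest's directory).
#' @return list of entries (`slide` path, `annotations`, `label`,
#'   `slide_id`, `split`).
#' @export
load_manifest <- function(manifest_path) {
  df <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(df)), function(i) {
    ann <- if (!is.na(df$annotation_path[i]) && nzchar(df$annotation_path[i]))
      read_annotations(file.path(base, df$annotation_path[i]))
    else annotation_set()
    list(slide = file.path(base, df$slide_path[i]), annotations = ann,
         label = df$label[i],
         slide_id = if ("slide_id" %in% names(df)) df$slide_id[i]
         else sprintf("slide_%03d", i),
         split = if ("split" %in% names(df)) df$split[i] else NA_character_)
  })
}

entry_split <- function(entries, split) {
  Filter(function(e) identical(e$split, split), entries)
}

#' Train from a cohort manifest
#'
#' Uses the manifest's `split` column: rows marked "train" fit the model,
#' rows marked "val" drive the validation loss. Writes the best checkpoint
#' (`checkpoint.rds`), a checkpoint manifest (`checkpoint.json`, including
#' the configuration hash), and the per-epoch training log.
#'
#' @param manifest_path cohort manifest.
#' @param config a [pipeline_config()].
#' @param out_dir output directory for checkpoint and logs.
#' @return the training result of [train_wsi_classifier()], invisibly.
#' @export
run_train <- function(manifest_path, config = pipeline_config(),
                      out_dir = dirname(manifest_path)) {
  entries <- load_manifest(manifest_path)
  train <- entry_split(entries, "train")
  val <- entry_split(entries, "val")
  if (length(train) == 0) stopf("manifest has no rows with split == 'train'")
  if (length(val) == 0) stopf("manifest has no rows with split == 'val'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "training_log.txt")
  fit <- train_wsi_classifier(train, val, config, log_file = log_file)
  ckpt <- file.path(out_dir, "checkpoint.rds")
  saveRDS(list(model = fit$model, config = config), ckpt)
  jsonlite::write_json(
    list(config = unclass(config), config_hash = rlang::hash(unclass(config)),
         best_val_loss = fit$best_val_loss,
         epochs = nrow(fit$history)),
    file.path(out_dir, "checkpoint.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(fit$history, file.path(out_dir, "training_history.csv"),
                   row.names = FALSE)
  invisible(fit)
}

#' Predict slide probabilities from a checkpoint
#'
#' Runs sliding-window inference with max aggregation on every manifest
#' slide. In two-stage mode a CSV of first-stage probabilities
#' (`slide_id`, `p1`) must be supplied and the product rule is applied.
#'
#' @param checkpoint_path `checkpoint.rds` from [run_train()].
#' @param manifest_path cohort manifest (all rows are scored).
#' @param out_csv output predictions CSV.
#' @param stage1_csv optional first-stage probabilities (required when the
#'   checkpoint's mode is "two_stage").
#' @param overlay_dir if set, writes one heatmap overlay PNG per slide.
#' @return the predictions data frame, invisibly.
#' @export
run_predict <- function(checkpoint_path, manifest_path, out_csv,
                        stage1_csv = NULL, overlay_dir = NULL) {
  ckpt <- readRDS(checkpoint_path)
  config <- ckpt$config
  entries <- load_manifest(manifest_path)
  stage1 <- NULL
  if (identical(config$mode, "two_stage")) {
    if (is.null(stage1_csv))
      stopf("two_stage mode needs a stage-1 probability CSV")
    stage1 <- utils::read.csv(stage1_csv, stringsAsFactors = FALSE)
  }
  if (!is.null(overlay_dir))
    dir.create(overlay_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(entries, function(e) {
    slide <- open_slide(e$slide)
    h <- predict_heatmap(slide, ckpt$model, config$magnification,
                         config$tile_size, config$stride,
                         config$min_tissue_fraction,
                         working_downsample = config$thumbnail_downsample,
                         slide_id = e$slide_id)
    p2 <- slide_probability(h)
    if (!is.null(overlay_dir))
      render_overlay(slide, h, file.path(overlay_dir,
                                         paste0(e$slide_id, ".png")))
    if (!is.null(stage1)) {
      m <- match(e$slide_id, stage1$slide_id)
      if (is.na(m)) stopf("no stage-1 probability for slide %s", e$slide_id)
      data.frame(slide_id = e$slide_id, label = e$label,
                 p1 = stage1$p1[m], p2 = p2,
                 probability = two_stage_probability(stage1$p1[m], p2))
    } else {
      data.frame(slide_id = e$slide_id, label = e$label, probability = p2)
    }
  })
  pred <- do.call(rbind, rows)
  utils::write.csv(pred, out_csv, row.names = FALSE)
  invisible(pred)
}

#' Evaluate a predictions CSV
#'
#' @param predictions_csv CSV with `slide_id`, `label`, `probability`
#'   columns (as written by [run_predict()]); labels may instead come from
#'   `labels_csv` (`slide_id`, `label`), matched by slide id.
#' @param out_json optional report destination.
#' @param cfg an [eval_config()].
#' @param labels_csv optional separate label file.
#' @return the `eval_report`, invisibly.
#' @export
run_evaluate <- function(predictions_csv, out_json = NULL,
                         cfg = eval_config(), labels_csv = NULL) {
  pred <- utils::read.csv(predictions_csv, stringsAsFactors = FALSE)
  if (!is.null(labels_csv)) {
    lab <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
    m <- match(pred$slide_id, lab$slide_id)
    if (anyNA(m))
      stopf("unmatched slide_id(s): %s",
            paste(pred$slide_id[is.na(m)], collapse = ", "))
    pred$label <- lab$label[m]
  }
  if (is.null(pred$label)) stopf("no labels available for evaluation")
  report <- evaluate_predictions(pred, cfg)
  if (!is.null(out_json)) write_eval_report(report, out_json)
  invisible(report)
}

#' End-to-end synthetic benchmark
#'
#' The package's scaled-down analogue of the headline experiment: generate
#' a seeded synthetic cohort (`n_train` training slides split 80/20 into
#' fit/validation, `n_test` held-out slides, half positive throughout),
#' train the toy scorer with the two-phase procedure at the reference
#' hyperparameters, score the held-out slides by max-tile aggregation, and
#' report the slide-level ROC AUC.
#'
#' @param n_train training cohort size (default 100).
#' @param n_test held-out cohort size (default 40).
#' @param seed master seed.
#' @param config a [pipeline_config()] (seed is overridden by `seed`).
#' @param spec slide generator template.
#' @param dir working directory (default: a fresh temporary directory;
#'   deleted afterwards unless `keep`).
#' @param keep keep the generated cohort on disk?
#' @return list: `auc`, `predictions`, `history`, `report`
#'   (an `eval_report` on the held-out slides), `n_test`.
#' @export
run_synthetic_benchmark <- function(n_train = 100L, n_test = 40L, seed = 1L,
                                    config = pipeline_config(),
                                    spec = synthetic_slide_spec(),
                                    dir = NULL, keep = FALSE) {
  config$seed <- as.integer(seed)
  own_dir <- is.null(dir)
  dir <- dir %||% file.path(tempfile("wsimine_bench_"))
  if (own_dir && !keep) on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  n_tr_pos <- n_train %/% 2L; n_tr_neg <- n_train - n_tr_pos
  n_te_pos <- n_test %/% 2L; n_te_neg <- n_test - n_te_pos
  fit_pos <- round(0.8 * n_tr_pos); fit_neg <- round(0.8 * n_tr_neg)
  manifest <- run_synth(
    dir, n_tr_pos + n_te_pos, n_tr_neg + n_te_neg, spec,
    seed = derive_seed(seed, 101),
    split_counts = list(train = c(fit_pos, fit_neg),
                        val = c(n_tr_pos - fit_pos, n_tr_neg - fit_neg),
                        test = c(n_te_pos, n_te_neg)),
    force = TRUE)
  run_train(manifest, config, out_dir = file.path(dir, "model"))
  pred_csv <- file.path(dir, "predictions_test.csv")
  # score only the held-out rows
  entries <- load_manifest(manifest)
  test_df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  test_manifest <- file.path(dir, "manifest_test.csv")
  utils::write.csv(test_df[test_df$split == "test", ], test_manifest,
                   row.names = FALSE)
  pred <- run_predict(file.path(dir, "model", "checkpoint.rds"),
                      test_manifest, pred_csv)
  auc <- roc_auc(pred$label, pred$probability)
  report <- evaluate_predictions(pred, eval_config(seed = derive_seed(seed, 202)))
  history <- utils::read.csv(file.path(dir, "model", "training_history.csv"),
                             stringsAsFactors = FALSE)
  list(auc = auc, predictions = pred, history = history, report = report,
       n_test = nrow(pred))
}
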