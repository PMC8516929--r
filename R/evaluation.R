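# Slide-level evaluation: ROC AUC, log loss, threshold metrics, and
# percentile bootstrap confidence intervals over slide resamples.

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(as.character(labels) == "positive")
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be binary (0/1)")
  labels
}

#' ROC AUC (Mann-Whitney statistic)
#'
#' Equals the mean over (positive, negative) score pairs of
#' `[s_pos > s_neg] + 0.5 * [s_pos == s_neg]`, computed via midranks.
#'
#' @param labels binary labels (0/1, logical, or "positive"/"negative").
#' @param scores numeric scores (higher = more positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  y <- as_binary_labels(labels)
  if (length(y) != length(scores)) stopf("labels/scores length mismatch")
  np <- sum(y == 1); nn <- sum(y == 0)
  if (np == 0 || nn == 0)
    stopf("ROC AUC needs both label categories")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Binary log loss
#'
#' `-mean(y log p + (1 - y) log(1 - p))` with probabilities clipped to
#' `[eps, 1 - eps]`, `eps = 1e-15`.
#'
#' @param labels binary labels.
#' @param probs predicted probabilities.
#' @param eps clipping constant.
#' @return log loss (natural log).
#' @export
log_loss <- function(labels, probs, eps = 1e-15) {
  y <- as_binary_labels(labels)
  if (length(y) != length(probs)) stopf("labels/probs length mismatch")
  p <- clamp(probs, eps, 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Accuracy, sensitivity and specificity at a probability threshold
#'
#' A slide is called positive iff its probability is greater than or equal
#' to the threshold (boundary inclusive).
#'
#' @param labels binary labels (both categories required).
#' @param probs predicted probabilities.
#' @param threshold decision threshold (default 0.5).
#' @return named list: `accuracy`, `sensitivity`, `specificity`.
#' @export
threshold_metrics <- function(labels, probs, threshold = 0.5) {
  y <- as_binary_labels(labels)
  if (sum(y == 1) == 0 || sum(y == 0) == 0)
    stopf("threshold metrics need both label categories")
  pred <- as.integer(probs >= threshold)
  list(accuracy = mean(pred == y),
       sensitivity = mean(pred[y == 1] == 1),
       specificity = mean(pred[y == 0] == 0))
}

#' Evaluation configuration
#'
#' @param threshold decision threshold in (0, 1).
#' @param n_bootstrap bootstrap iterations (paper default 1000).
#' @param ci_level confidence level.
#' @param seed bootstrap RNG seed.
#' @return object of class `eval_config`.
#' @export
eval_config <- function(threshold = 0.5, n_bootstrap = 1000L,
                        ci_level = 0.95, seed = 1L) {
  stopifnot(threshold > 0, threshold < 1, n_bootstrap >= 1,
            ci_level > 0, ci_level < 1)
  structure(list(threshold = threshold, n_bootstrap = as.integer(n_bootstrap),
                 ci_level = ci_level, seed = as.integer(seed)),
            class = "eval_config")
}

#' Percentile bootstrap confidence interval of a slide-level metric
#'
#' Resamples slides with replacement `n_bootstrap` times, recomputes the
#' metric on each resample, and returns the percentile interval at
#' `ci_level`. Degenerate resamples on which the metric is undefined
#' (a single label category) are redrawn, keeping exactly `n_bootstrap`
#' values. Deterministic for a fixed seed.
#'
#' @param metric function `(labels, scores) -> number`.
#' @param labels,scores slide-level labels and scores.
#' @param cfg an [eval_config()].
#' @return list: `ci_low`, `ci_high` (attribute `stats` holds the bootstrap
#'   replicates).
#' @export
bootstrap_ci <- function(metric, labels, scores, cfg = eval_config()) {
  y <- as_binary_labels(labels)
  n <- length(y)
  if (n < 2) stopf("bootstrap needs n >= 2 slides")
  stats_v <- with_seed(cfg$seed, {
    out <- numeric(cfg$n_bootstrap)
    for (b in seq_len(cfg$n_bootstrap)) {
      val <- NULL
      for (attempt in 1:1000) {
        idx <- sample.int(n, n, replace = TRUE)
        val <- tryCatch(metric(y[idx], scores[idx]), error = function(e) NULL)
        if (!is.null(val) && is.finite(val)) break
        val <- NULL
      }
      if (is.null(val)) stopf("metric undefined on all bootstrap resamples")
      out[b] <- val
    }
    out
  })
  a <- (1 - cfg$ci_level) / 2
  q <- unname(stats::quantile(stats_v, c(a, 1 - a), type = 7))
  out <- list(ci_low = q[1], ci_high = q[2])
  attr(out, "stats") <- stats_v
  out
}

#' Evaluate slide-level predictions
#'
#' Computes ROC AUC, log loss and threshold metrics with percentile
#' bootstrap confidence intervals, mirroring the headline result tables.
#'
#' @param predictions data frame with columns `label`
#'   ("positive"/"negative" or 0/1) and `probability`; an optional
#'   `slide_id` column is carried through.
#' @param cfg an [eval_config()].
#' @return object of class `eval_report`: per metric a list
#'   `(point, ci_low, ci_high)`, plus counts and metadata.
#' @export
evaluate_predictions <- function(predictions, cfg = eval_config()) {
  y <- as_binary_labels(predictions$label)
  p <- predictions$probability
  if (sum(y == 1) == 0 || sum(y == 0) == 0)
    stopf("evaluation needs both positive and negative slides")
  wrap <- function(point, metric, seed_off) {
    ci <- bootstrap_ci(metric, y, p,
                       eval_config(cfg$threshold, cfg$n_bootstrap,
                                   cfg$ci_level, derive_seed(cfg$seed, seed_off)))
    list(point = point, ci_low = ci$ci_low, ci_high = ci$ci_high)
  }
  tm <- threshold_metrics(y, p, cfg$threshold)
  report <- list(
    auc = wrap(roc_auc(y, p), roc_auc, 1L),
    log_loss = wrap(log_loss(y, p), log_loss, 2L),
    accuracy = wrap(tm$accuracy, function(l, s)
      threshold_metrics(l, s, cfg$threshold)$accuracy, 3L),
    sensitivity = wrap(tm$sensitivity, function(l, s)
      threshold_metrics(l, s, cfg$threshold)$sensitivity, 4L),
    specificity = wrap(tm$specificity, function(l, s)
      threshold_metrics(l, s, cfg$threshold)$specificity, 5L),
    n_positive = sum(y == 1), n_negative = sum(y == 0),
    threshold = cfg$threshold, n_bootstrap = cfg$n_bootstrap,
    ci_level = cfg$ci_level, bootstrap_variant = "percentile")
  structure(report, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d positive / %d negative slides\n",
              x$n_positive, x$n_negative))
  for (m in c("auc", "log_loss", "accuracy", "sensitivity", "specificity"))
    cat(sprintf("  %-12s %.4f [%.4f, %.4f]\n", m, x[[m]]$point,
                x[[m]]$ci_low, x[[m]]$ci_high))
  invisible(x)
}

#' Write / read an evaluation report as JSON
#'
#' The round trip is lossless for all metric values.
#'
#' @param report an `eval_report`.
#' @param path JSON path.
#' @return `path` (write) or the report (read).
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "eval_report")
}

#' ROC curve points
#'
#' @param labels,scores slide-level labels and scores.
#' @return data frame of (threshold, tpr, fpr) over all score cut points.
#' @export
roc_points <- function(labels, scores) {
  y <- as_binary_labels(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[y == 1] >= t), 0),
    fpr = vapply(thr, function(t) mean(scores[y == 0] >= t), 0))
}
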