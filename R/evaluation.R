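# Detection and classification metrics, and the grouped cross-validation
# protocol: IoU, greedy confidence-ordered matching, mAP/mAR over IoU
# sweeps, ROC and precision-recall AUC, and patient-level threefold CV with
# a 2:1 train:test split so no patient crosses between training and test.

abort_metric <- function(msg) rlang::abort(msg, class = "aplsmear_metric_error")

#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are `c(x_min, y_min, x_max, y_max)`, half-open. A degenerate
#' (zero-area) box yields 0 by convention (with a message).
#' @param a,b numeric length-4 boxes.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  area_a <- max(0, a[3] - a[1]) * max(0, a[4] - a[2])
  area_b <- max(0, b[3] - b[1]) * max(0, b[4] - b[2])
  if (area_a == 0 || area_b == 0) {
    rlang::inform("degenerate zero-area box; IoU taken as 0")
    return(0)
  }
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  inter <- max(0, iw) * max(0, ih)
  inter / (area_a + area_b - inter)
}

# IoU of every row-box in `p` (n x 4 matrix) against every row-box in `g`.
iou_matrix <- function(p, g) {
  n <- nrow(p); m <- nrow(g)
  if (n == 0 || m == 0) return(matrix(0, n, m))
  area_p <- pmax(0, p[, 3] - p[, 1]) * pmax(0, p[, 4] - p[, 2])
  area_g <- pmax(0, g[, 3] - g[, 1]) * pmax(0, g[, 4] - g[, 2])
  out <- matrix(0, n, m)
  for (j in seq_len(m)) {
    iw <- pmin(p[, 3], g[j, 3]) - pmax(p[, 1], g[j, 1])
    ih <- pmin(p[, 4], g[j, 4]) - pmax(p[, 2], g[j, 2])
    inter <- pmax(0, iw) * pmax(0, ih)
    denom <- area_p + area_g[j] - inter
    out[, j] <- ifelse(denom > 0, inter / denom, 0)
  }
  out
}

box_matrix <- function(df) {
  cbind(df$x_min, df$y_min, df$x_max, df$y_max)
}

#' Greedy matching of detections to ground truth
#'
#' Detections are processed in order of descending confidence (ties broken
#' by lower `region_id`); each is matched to the unmatched ground-truth box
#' of highest IoU provided that IoU reaches `iou_threshold`; each ground
#' truth matches at most once.
#'
#' @param predictions tibble with box columns, `confidence` and `region_id`.
#' @param ground_truth tibble with box columns.
#' @param iou_threshold matching threshold in `[0, 1]`.
#' @return List with `predictions` (input rows in processing order plus
#'   `is_tp` and `matched_gt`) and `gt_matched` (logical, original ground
#'   truth order).
#' @export
match_detections <- function(predictions, ground_truth, iou_threshold = 0.5) {
  ord <- order(-predictions$confidence, predictions$region_id)
  preds <- predictions[ord, , drop = FALSE]
  pm <- box_matrix(preds); gm <- box_matrix(ground_truth)
  ious <- iou_matrix(pm, gm)
  gt_matched <- rep(FALSE, nrow(ground_truth))
  is_tp <- rep(FALSE, nrow(preds))
  matched_gt <- rep(NA_integer_, nrow(preds))
  for (i in seq_len(nrow(preds))) {
    cand <- which(!gt_matched & ious[i, ] >= iou_threshold)
    if (length(cand)) {
      best <- cand[which.max(ious[i, cand])]
      gt_matched[best] <- TRUE
      is_tp[i] <- TRUE
      matched_gt[i] <- best
    }
  }
  preds$is_tp <- is_tp
  preds$matched_gt <- matched_gt
  list(predictions = preds, gt_matched = gt_matched)
}

# AP by all-point interpolation of the precision-recall curve of a
# confidence-ranked TP/FP sequence.
ap_from_ranked <- function(is_tp, n_gt) {
  if (!length(is_tp) || n_gt == 0) return(0)
  tp <- cumsum(is_tp)
  fp <- cumsum(!is_tp)
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  envelope <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * envelope)
}

#' Mean average precision and recall over an IoU threshold sweep
#'
#' AP at one threshold is the area under the all-point-interpolated
#' precision-recall curve of the confidence-ranked detections pooled across
#' images; AR is the maximal recall (matched ground truth / total ground
#' truth). Both are averaged over `iou_thresholds`.
#'
#' @param predictions tibble of detections (`image_id`, box columns,
#'   `confidence`, `region_id`).
#' @param ground_truth tibble of ground-truth boxes (`image_id`, box
#'   columns).
#' @param iou_thresholds numeric vector, e.g. `0.5` or [iou_sweep()].
#' @return List with `map`, `mar` and `per_threshold` (tibble of
#'   `iou_threshold`, `ap`, `ar`).
#' @export
mean_ap_ar <- function(predictions, ground_truth,
                       iou_thresholds = 0.5) {
  if (nrow(ground_truth) == 0) abort_metric("no ground-truth objects")
  if (!"image_id" %in% names(ground_truth)) ground_truth$image_id <- "img"
  if (nrow(predictions) && !"image_id" %in% names(predictions)) {
    predictions$image_id <- "img"
  }
  n_gt <- nrow(ground_truth)
  per <- purrr::map_dfr(iou_thresholds, function(thr) {
    conf <- numeric(0); tp <- logical(0)
    for (id in unique(ground_truth$image_id)) {
      gt <- ground_truth[ground_truth$image_id == id, ]
      pr <- predictions[predictions$image_id == id, , drop = FALSE]
      if (nrow(pr)) {
        m <- match_detections(pr, gt, thr)
        conf <- c(conf, m$predictions$confidence)
        tp <- c(tp, m$predictions$is_tp)
      }
    }
    # stray detections on images with no ground truth count as FP
    if (nrow(predictions)) {
      stray <- !predictions$image_id %in% ground_truth$image_id
      if (any(stray)) {
        conf <- c(conf, predictions$confidence[stray])
        tp <- c(tp, rep(FALSE, sum(stray)))
      }
    }
    ord <- order(-conf)
    tibble::tibble(
      iou_threshold = thr,
      ap = ap_from_ranked(tp[ord], n_gt),
      ar = sum(tp) / n_gt
    )
  })
  list(map = mean(per$ap), mar = mean(per$ar), per_threshold = per)
}

#' Standard IoU sweep 0.50 to 0.95 in steps of 0.05
#' @return Numeric vector of ten thresholds.
#' @export
iou_sweep <- function() seq(0.5, 0.95, by = 0.05)

#' Area under the ROC curve
#'
#' Rank statistic: the probability that a random positive outscores a random
#' negative, with ties counting one half.
#' @param scores numeric scores.
#' @param labels logical or 0/1 class labels.
#' @return AUROC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) abort_metric("both classes required for AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-curve (rectangular) area over all score thresholds:
#' `sum (R_i - R_{i-1}) * P_i` over the distinct score cutoffs in descending
#' order. With all scores tied this equals the prevalence.
#' @param scores numeric scores.
#' @param labels logical or 0/1 class labels.
#' @return AUPRC in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  if (n_pos == 0) abort_metric("at least one positive required for AUPRC")
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); n_pred <- seq_along(y)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  recall <- tp[last_of_tie] / n_pos
  precision <- tp[last_of_tie] / n_pred[last_of_tie]
  sum(diff(c(0, recall)) * precision)
}

#' ROC / precision-recall curve points
#'
#' One row per distinct score cutoff, suitable for plotting or CSV export.
#' @param scores numeric scores.
#' @param labels logical or 0/1 class labels.
#' @return Tibble with `threshold`, `tpr`/`fpr` (ROC) or
#'   `recall`/`precision` (PR).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_tie]; n <- seq_along(y)[last_of_tie]
  tibble::tibble(
    threshold = s[last_of_tie],
    tpr = tp / sum(labels),
    fpr = (n - tp) / sum(!labels)
  ) |>
    (\(d) dplyr::bind_rows(
      tibble::tibble(threshold = Inf, tpr = 0, fpr = 0), d
    ))()
}

#' @rdname roc_curve
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_tie]; n <- seq_along(y)[last_of_tie]
  tibble::tibble(
    threshold = s[last_of_tie],
    recall = tp / sum(labels),
    precision = tp / n
  )
}

#' Precision, recall and F1 at a decision threshold
#' @param scores numeric scores.
#' @param labels logical or 0/1 class labels.
#' @param threshold decision threshold (call positive when score >=
#'   threshold).
#' @return Tibble with `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  calls <- scores >= threshold
  tp <- sum(calls & labels)
  precision <- if (sum(calls) > 0) tp / sum(calls) else 0
  recall <- if (sum(labels) > 0) tp / sum(labels) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble::tibble(precision = precision, recall = recall, f1 = f1)
}

#' Patient-level stratified k-fold assignment
#'
#' Patients (never individual images) are assigned to folds, stratified by
#' diagnosis, so that each fold's test set holds about 1/k of the patients
#' of each class: with `k = 3` every fold trains on 2/3 and tests on 1/3 of
#' patients (the 2:1 split). Augmented records inherit their parent's
#' `patient_id` and therefore its fold.
#'
#' @param manifest tibble with `patient_id` and `diagnosis` columns (one or
#'   more rows per patient).
#' @param k number of folds.
#' @param seed integer seed for the within-class shuffle.
#' @return Tibble with `patient_id`, `diagnosis`, `fold` (1..k), one row per
#'   patient.
#' @export
patient_folds <- function(manifest, k = 3L, seed = 1L) {
  pats <- dplyr::distinct(manifest, .data$patient_id, .data$diagnosis)
  if (anyDuplicated(pats$patient_id)) {
    abort_data("a patient_id maps to more than one diagnosis")
  }
  counts <- table(pats$diagnosis)
  if (any(counts < k)) {
    abort_data(sprintf("every class needs >= %d patients", k))
  }
  set.seed(seed)
  purrr::map_dfr(split(pats, pats$diagnosis), function(cl) {
    cl <- cl[sample.int(nrow(cl)), ]
    cl$fold <- rep_len(seq_len(k), nrow(cl))
    cl
  })
}

#' Macro average of per-fold metric values
#' @param values numeric vector of per-fold metrics.
#' @return List with `mean` and `sd` (0 for a single fold).
#' @export
macro_average <- function(values) {
  if (!length(values)) abort_metric("no fold values")
  list(
    mean = mean(values),
    sd = if (length(values) > 1L) stats::sd(values) else 0
  )
}

#' Assemble an evaluation report
#'
#' @param fold_metrics tibble with one row per fold: `fold`, `roc_auc`,
#'   `pr_auc`, `precision`, `recall`, `f1` (plus optional columns).
#' @param detection list from [mean_ap_ar()] at IoU 0.5 (`at_50`) and over
#'   the sweep (`sweep`), or `NULL`.
#' @param folds the patient fold assignment used.
#' @param task task label.
#' @param curves optional list of per-fold ROC/PR curve tibbles.
#' @return Object of class `eval_report`.
#' @export
eval_report <- function(fold_metrics, detection = NULL, folds = NULL,
                        task = NA_character_, curves = NULL) {
  structure(
    list(
      task = task,
      fold_metrics = fold_metrics,
      macro_roc_auc = macro_average(fold_metrics$roc_auc),
      macro_pr_auc = macro_average(fold_metrics$pr_auc),
      map_at_50 = detection$at_50$map %||% NA_real_,
      mar_at_50 = detection$at_50$mar %||% NA_real_,
      map_50_95 = detection$sweep$map %||% NA_real_,
      mar_50_95 = detection$sweep$mar %||% NA_real_,
      folds = folds,
      curves = curves
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %s>\n", x$task))
  cat(sprintf(
    "  macro ROC AUC %.4f (sd %.4f), macro PR AUC %.4f (sd %.4f)\n",
    x$macro_roc_auc$mean, x$macro_roc_auc$sd,
    x$macro_pr_auc$mean, x$macro_pr_auc$sd
  ))
  if (!is.na(x$map_at_50)) {
    cat(sprintf(
      "  detection mAP@0.5 %.4f, mAR@0.5 %.4f, mAP@0.5:0.95 %.4f, mAR@0.5:0.95 %.4f\n",
      x$map_at_50, x$mar_at_50, x$map_50_95, x$mar_50_95
    ))
  }
  print(x$fold_metrics)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.eval_report <- function(x, ...) x$fold_metrics

#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    task = x$task,
    macro_roc_auc = x$macro_roc_auc$mean, roc_auc_sd = x$macro_roc_auc$sd,
    macro_pr_auc = x$macro_pr_auc$mean, pr_auc_sd = x$macro_pr_auc$sd,
    map_at_50 = x$map_at_50, mar_at_50 = x$mar_at_50,
    map_50_95 = x$map_50_95, mar_50_95 = x$mar_50_95,
    n_folds = nrow(x$fold_metrics)
  )
}

#' Serialize an evaluation report to JSON
#' @param report an `eval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(
    list(
      task = report$task,
      fold_metrics = report$fold_metrics,
      macro_roc_auc = report$macro_roc_auc,
      macro_pr_auc = report$macro_pr_auc,
      detection = list(
        map_at_50 = report$map_at_50, mar_at_50 = report$mar_at_50,
        map_50_95 = report$map_50_95, mar_50_95 = report$mar_50_95
      ),
      folds = report$folds
    ),
    path,
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
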