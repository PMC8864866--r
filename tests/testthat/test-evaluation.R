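# Independent oracles used here:
#  * AUROC — exhaustive pairwise comparison over all positive x negative
#    pairs (ties worth 1/2)
#  * AP — precision envelope integrated on a fine recall grid
#  * AUPRC — explicit sweep over every distinct score threshold

oracle_auroc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

oracle_ap <- function(is_tp, n_gt, grid = 20000L) {
  if (!length(is_tp)) return(0)
  tp <- cumsum(is_tp)
  fp <- cumsum(!is_tp)
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  rs <- seq(1 / grid, 1, length.out = grid)
  vals <- vapply(rs, function(r) {
    ok <- recall >= r
    if (!any(ok)) 0 else max(precision[ok])
  }, numeric(1))
  mean(vals) # area on [0, 1]; zero beyond the maximal recall
}

oracle_prauc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    calls <- scores >= t
    c(
      recall = sum(calls & labels) / sum(labels),
      precision = sum(calls & labels) / sum(calls)
    )
  }, numeric(2)))
  sum(diff(c(0, pts[, "recall"])) * pts[, "precision"])
}

test_that("IoU matches closed forms", {
  a <- c(0, 0, 10, 10)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, c(20, 20, 30, 30)), 0)
  expect_equal(iou(a, c(5, 0, 15, 10)), 50 / 150)
  expect_equal(iou(a, c(10, 0, 20, 10)), 0) # half-open boxes just touching
  expect_message(z <- iou(a, c(3, 3, 3, 9)), "degenerate")
  expect_equal(z, 0)
})

test_that("greedy matching follows confidence order with one-to-one GT use", {
  gt <- tibble::tibble(x_min = 0, y_min = 0, x_max = 10, y_max = 10)
  preds <- tibble::tibble(
    region_id = 1:2,
    x_min = c(0, 2), y_min = c(0, 0), x_max = c(9, 10), y_max = c(10, 10),
    confidence = c(0.7, 0.9)
  )
  m <- match_detections(preds, gt, 0.5)
  expect_equal(m$predictions$region_id, c(2L, 1L)) # processed by confidence
  expect_equal(m$predictions$is_tp, c(TRUE, FALSE))
  expect_true(all(m$gt_matched))

  none <- match_detections(preds[0, ], gt[c(1, 1, 1), ], 0.5)
  expect_equal(nrow(none$predictions), 0L)
  expect_equal(none$gt_matched, rep(FALSE, 3))

  # perfect one-to-one
  p2 <- tibble::tibble(
    region_id = 1:3,
    x_min = c(0, 20, 40), y_min = 0, x_max = c(10, 30, 50), y_max = 10,
    confidence = 1
  )
  g2 <- p2[, c("x_min", "y_min", "x_max", "y_max")]
  m2 <- match_detections(p2, g2, 0.5)
  expect_true(all(m2$predictions$is_tp))
  expect_true(all(m2$gt_matched))
})

test_that("AP agrees with the ranked closed form and the grid oracle", {
  # perfect detector
  gt <- tibble::tibble(
    image_id = "a",
    x_min = c(0, 20, 40), y_min = 0, x_max = c(10, 30, 50), y_max = 10
  )
  perfect <- dplyr::mutate(gt, region_id = 1:3, confidence = 1)
  res <- mean_ap_ar(perfect, gt, c(0.5, 0.75, 0.95))
  expect_equal(res$map, 1)
  expect_equal(res$mar, 1)

  expect_equal(mean_ap_ar(perfect[0, ], gt, 0.5)$map, 0)

  # ranked TP, FP, TP with 3 GT: AP = 1/3 * 1 + 1/3 * 2/3 = 5/9
  expect_equal(aplsmear:::ap_from_ranked(c(TRUE, FALSE, TRUE), 3), 5 / 9)
  expect_equal(oracle_ap(c(TRUE, FALSE, TRUE), 3), 5 / 9, tolerance = 1e-3)

  # random ranked sequences against the grid oracle
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(1:10, 1)
    n_gt <- sample(1:6, 1)
    flags <- stats::runif(n) < 0.5
    flags[cumsum(flags) > n_gt] <- FALSE # cannot exceed available GT
    expect_equal(
      aplsmear:::ap_from_ranked(flags, n_gt),
      oracle_ap(flags, n_gt),
      tolerance = 2e-3
    )
  }

  expect_error(mean_ap_ar(perfect, gt[0, ], 0.5),
    class = "aplsmear_metric_error"
  )
})

test_that("AUROC equals the exhaustive pairwise oracle (ties worth 1/2)", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    labels <- c(TRUE, FALSE, stats::runif(n - 2) < 0.5) # both classes present
    scores <- round(stats::runif(n), 1) # coarse grid forces ties
    expect_equal(roc_auc(scores, labels), oracle_auroc(scores, labels))
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), class = "aplsmear_metric_error")
})

test_that("AUROC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (rep in 1:5) {
    labels <- c(TRUE, FALSE, stats::runif(30) < 0.4)
    scores <- stats::rnorm(32)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores,
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
    )))
    expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-10)
  }
})

test_that("AUPRC equals the exhaustive threshold-sweep oracle", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # single positive ranked last among 10
  scores <- seq(1, 0.1, by = -0.1)
  labels <- c(rep(FALSE, 9), TRUE)
  expect_equal(pr_auc(scores, labels), oracle_prauc(scores, labels))
  expect_equal(pr_auc(scores, labels), 0.1)
  # total ties: precision = prevalence at full recall
  expect_equal(pr_auc(rep(0.5, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(3:12, 1)
    labels <- c(TRUE, stats::runif(n - 1) < 0.5)
    scores <- round(stats::runif(n), 1)
    expect_equal(pr_auc(scores, labels), oracle_prauc(scores, labels))
  }
  expect_error(pr_auc(1:3, c(0, 0, 0)), class = "aplsmear_metric_error")
})

test_that("patient folds give a 2:1 split, stratified, with no leakage", {
  manifest <- tidyr::expand_grid(
    diagnosis = c("APL", "HEALTHY"),
    pat = 1:9, img = 1:2
  ) |>
    dplyr::mutate(
      patient_id = paste0(.data$diagnosis, "_p", .data$pat),
      image_id = paste0(.data$patient_id, "_i", .data$img)
    )
  folds <- patient_folds(manifest, k = 3, seed = 5)
  expect_equal(nrow(folds), 18L)
  tab <- table(folds$diagnosis, folds$fold)
  expect_true(all(tab == 3)) # 3 test patients per class per fold; 6 train
  # each patient in exactly one fold; each image inherits exactly one fold
  expect_equal(anyDuplicated(folds$patient_id), 0L)
  joined <- dplyr::left_join(manifest, folds[, c("patient_id", "fold")],
    by = "patient_id"
  )
  expect_false(any(is.na(joined$fold)))
  for (f in 1:3) {
    test_pats <- folds$patient_id[folds$fold == f]
    train_pats <- folds$patient_id[folds$fold != f]
    expect_length(intersect(test_pats, train_pats), 0)
  }
  expect_error(patient_folds(manifest[manifest$pat <= 2, ], k = 3),
    class = "aplsmear_data_error"
  )
})

test_that("augmented records inherit their parent's fold", {
  set.seed(2)
  records <- tibble::tibble(
    record_id = 1:30,
    patient_id = rep(sprintf("p%02d", 1:10), each = 3),
    diagnosis = rep(c("APL", "HEALTHY"), each = 15),
    class = rep(c("APL", "HEALTHY"), each = 15)
  )
  # unbalance, then rebalance with augmented copies (keeping >= 3 patients
  # per class so folds remain constructible)
  records <- records[-(1:5), ]
  balanced <- balance_classes(records, seed = 3)
  folds <- patient_folds(
    dplyr::distinct(records, .data$patient_id, .data$diagnosis),
    k = 3, seed = 1
  )
  balanced <- dplyr::left_join(balanced, folds[, c("patient_id", "fold")],
    by = "patient_id"
  )
  aug <- balanced[!is.na(balanced$parent_id), ]
  parents <- balanced[match(aug$parent_id, balanced$record_id), ]
  expect_true(all(aug$patient_id == parents$patient_id))
  expect_true(all(aug$fold == parents$fold))
})

test_that("macro averaging is the fold mean with fold-value dispersion", {
  m <- macro_average(c(0.9, 0.9, 0.9))
  expect_equal(m$mean, 0.9)
  expect_equal(m$sd, 0)
  expect_equal(macro_average(c(0.8, 1.0))$mean, 0.9)
  s <- macro_average(0.73)
  expect_equal(s$mean, 0.73)
  expect_equal(s$sd, 0)
})

test_that("eval reports tidy, glance and serialize", {
  fm <- tibble::tibble(
    fold = 1:3, roc_auc = c(0.9, 1, 0.95), pr_auc = c(0.92, 1, 0.96),
    precision = 1, recall = 1, f1 = 1
  )
  rep <- eval_report(fm, task = "APL_vs_HEALTHY")
  expect_equal(nrow(tidy(rep)), 3L)
  g <- glance(rep)
  expect_equal(g$macro_roc_auc, mean(fm$roc_auc))
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$macro_roc_auc$mean, mean(fm$roc_auc))
})
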