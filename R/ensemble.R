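# Image-level classification. Per-cell probabilities are aggregated into
# per-smear ratio features (fraction of cells called myeloblast,
# promyelocyte, Auer-rod-bearing) and a single fully connected layer with
# no dropout — an affine map plus sigmoid over the ratios — classifies the
# smear for one binary task (APL vs healthy donor, or APL vs non-APL AML).

abort_no_cells <- function(msg) rlang::abort(msg, class = "aplsmear_no_cells")

TASKS <- c("APL_vs_HEALTHY", "APL_vs_AML")

#' Aggregate per-cell predictions into per-smear ratio features
#'
#' `ratio_X = count(p_X >= call_threshold) / n_cells` for each of the three
#' cell-level tasks. Invariant under any permutation of the cells.
#'
#' @param cell_predictions tibble from [predict_cells()] (>= 1 row).
#' @param call_threshold per-cell decision threshold.
#' @param include_morphometrics also emit the means of the morphometric
#'   columns (off by default).
#' @return One-row tibble with `ratio_myeloblast`, `ratio_promyelocyte`,
#'   `ratio_auer_rod`, `n_cells` (+ morphometric means when requested).
#' @export
smear_features <- function(cell_predictions, call_threshold = 0.5,
                           include_morphometrics = FALSE) {
  n <- nrow(cell_predictions)
  if (is.null(n) || n == 0) {
    abort_no_cells("no cells: image is unanalyzable")
  }
  out <- tibble::tibble(
    ratio_myeloblast = sum(cell_predictions$p_myeloblast >= call_threshold) / n,
    ratio_promyelocyte =
      sum(cell_predictions$p_promyelocyte >= call_threshold) / n,
    ratio_auer_rod = sum(cell_predictions$p_auer_rod >= call_threshold) / n,
    n_cells = n
  )
  if (include_morphometrics) {
    out$mean_size_px2 <- mean(cell_predictions$size_px2)
    out$mean_volume_proxy <- mean(cell_predictions$volume_proxy)
    out$mean_contrast <- mean(cell_predictions$contrast)
  }
  out
}

enn_feature_cols <- function(features, use_n_cells = FALSE) {
  base <- c("ratio_myeloblast", "ratio_promyelocyte", "ratio_auer_rod")
  extra <- intersect(
    c(
      if (use_n_cells) "n_cells",
      "mean_size_px2", "mean_volume_proxy", "mean_contrast"
    ),
    names(features)
  )
  c(base, extra)
}

#' Train the single-layer ensemble net for one binary task
#'
#' The model is exactly one fully connected layer without dropout: an
#' affine map over the smear features followed by a sigmoid (parameter
#' count = number of features + 1), trained full-batch with Adam. Optional
#' seeded random-search hyperparameter optimization (via [hpo()]) over the
#' learning rate and epoch budget uses an internal 2:1 patient split.
#'
#' @param features tibble of smear feature rows (see [smear_features()]);
#'   an optional `patient_id` column groups the internal HPO split.
#' @param labels logical / 0-1 vector (`TRUE` = APL), one per row.
#' @param task `"APL_vs_HEALTHY"` or `"APL_vs_AML"`.
#' @param seed integer seed.
#' @param epochs,lr training schedule (overridden when `hpo_trials > 0`).
#' @param hpo_trials number of random-search trials (0 = none).
#' @param use_n_cells include `n_cells` as a model input (off by default:
#'   the ratios are the canonical inputs).
#' @return Object of class `enn_model`.
#' @export
train_enn <- function(features, labels, task = "APL_vs_HEALTHY", seed = 1L,
                      epochs = 400L, lr = 0.2, hpo_trials = 0L,
                      use_n_cells = FALSE) {
  task <- match.arg(task, TASKS)
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) {
    abort_data("both classes must be present")
  }
  cols <- enn_feature_cols(features, use_n_cells)
  X <- as.matrix(features[, cols])
  if (!all(is.finite(X))) abort_data("non-finite features")
  fit_once <- function(X, y, epochs, lr, seed) {
    scaler <- fit_scaler(X)
    net <- mlp_init(c(ncol(X), 1L), seed = seed)
    fit <- mlp_train(net, apply_scaler(scaler, X), y,
      epochs = epochs, lr = lr, seed = seed
    )
    list(scaler = scaler, net = fit$net, loss = utils::tail(fit$loss_trace, 1),
      loss_history = fit$loss_trace)
  }
  y <- as.numeric(labels)
  trial_log <- NULL
  if (hpo_trials > 0L) {
    groups <- if ("patient_id" %in% names(features)) {
      features$patient_id
    } else {
      as.character(seq_len(nrow(X)))
    }
    set.seed(seed)
    pats <- unique(groups)
    val_pats <- sample(pats, max(1L, round(length(pats) / 3)))
    val <- groups %in% val_pats
    if (length(unique(labels[val])) < 2L || length(unique(labels[!val])) < 2L) {
      val <- rep(FALSE, length(labels)) # degenerate split: skip HPO
    }
    if (any(val)) {
      objective <- function(cfg) {
        f <- fit_once(X[!val, , drop = FALSE], y[!val], cfg$epochs, cfg$lr,
          seed
        )
        p <- mlp_predict(f$net, apply_scaler(f$scaler, X[val, , drop = FALSE]))
        roc_auc(p, labels[val])
      }
      res <- hpo(objective,
        space = list(lr = c(0.05, 0.1, 0.2, 0.5), epochs = c(200L, 400L, 600L)),
        n_trials = hpo_trials, seed = seed
      )
      lr <- res$best_config$lr
      epochs <- res$best_config$epochs
      trial_log <- res$trials
    }
  }
  f <- fit_once(X, y, epochs, lr, seed)
  structure(
    list(
      task = task, feature_names = cols, scaler = f$scaler, net = f$net,
      decision_threshold = 0.5, final_loss = f$loss,
      loss_history = f$loss_history,
      n_parameters = ncol(X) + 1L, hpo_trials = trial_log,
      epochs = epochs, lr = lr, seed = seed
    ),
    class = "enn_model"
  )
}

#' @export
print.enn_model <- function(x, ...) {
  cat(sprintf(
    "<enn_model task=%s, %d parameters, final loss %.4f>\n",
    x$task, x$n_parameters, x$final_loss
  ))
  invisible(x)
}

#' @export
tidy.enn_model <- function(x, ...) {
  w <- x$net$layers[[1]]$W[, 1] / x$scaler$sd
  b <- x$net$layers[[1]]$b - sum(x$net$layers[[1]]$W[, 1] *
    x$scaler$mu / x$scaler$sd)
  tibble::tibble(
    term = c("(Intercept)", x$feature_names),
    estimate = c(b, w)
  )
}

#' @export
glance.enn_model <- function(x, ...) {
  tibble::tibble(
    task = x$task, n_parameters = x$n_parameters,
    final_loss = x$final_loss, epochs = x$epochs, lr = x$lr
  )
}

#' Probability of APL for smear feature rows
#' @param model an `enn_model`.
#' @param features tibble of smear feature rows.
#' @return Numeric vector of `p_apl` in `[0, 1]`.
#' @export
predict_enn <- function(model, features) {
  X <- as.matrix(features[, model$feature_names])
  mlp_predict(model$net, apply_scaler(model$scaler, X))
}

#' Classify one smear image end to end
#'
#' Runs detect -> crop -> per-cell classification -> ratio features ->
#' ensemble net, and returns the image-level probability and call along
#' with per-stage wall-clock timings. An image with zero detections is
#' flagged unanalyzable (no call).
#'
#' @param enn trained `enn_model`.
#' @param detector trained `cell_detector`.
#' @param cell_models named list of the three `cell_cnn`s.
#' @param image `H x W x 3` array.
#' @param crop_size crop side length fed to the cell models (defaults to
#'   the cell models' input size).
#' @param call_threshold per-cell decision threshold.
#' @param decision_threshold image-level decision threshold.
#' @return One-row tibble: `task`, `p_apl`, `call` (`"APL"` / `"other"` /
#'   `NA`), `unanalyzable`, `n_cells`, the three ratios, and stage timings
#'   in seconds (`t_detect`, `t_cells`, `t_ensemble`).
#' @export
classify_smear <- function(enn, detector, cell_models, image,
                           crop_size = NULL, call_threshold = 0.5,
                           decision_threshold = enn$decision_threshold) {
  crop_size <- crop_size %||% cell_models$myeloblast$input_size
  t0 <- proc.time()[["elapsed"]]
  regions <- detect_cells(detector, image)
  t1 <- proc.time()[["elapsed"]]
  if (nrow(regions) == 0) {
    return(tibble::tibble(
      task = enn$task, p_apl = NA_real_, call = NA_character_,
      unanalyzable = TRUE, n_cells = 0L,
      ratio_myeloblast = NA_real_, ratio_promyelocyte = NA_real_,
      ratio_auer_rod = NA_real_,
      t_detect = t1 - t0, t_cells = 0, t_ensemble = 0
    ))
  }
  crops <- crop_cells(image, regions, crop_size)
  preds <- predict_cells(cell_models, crops)
  t2 <- proc.time()[["elapsed"]]
  feats <- smear_features(preds, call_threshold,
    include_morphometrics = "mean_size_px2" %in% enn$feature_names
  )
  p <- predict_enn(enn, feats)
  t3 <- proc.time()[["elapsed"]]
  tibble::tibble(
    task = enn$task, p_apl = p,
    call = if (p >= decision_threshold) "APL" else "other",
    unanalyzable = FALSE, n_cells = feats$n_cells,
    ratio_myeloblast = feats$ratio_myeloblast,
    ratio_promyelocyte = feats$ratio_promyelocyte,
    ratio_auer_rod = feats$ratio_auer_rod,
    t_detect = t1 - t0, t_cells = t2 - t1, t_ensemble = t3 - t2
  )
}
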