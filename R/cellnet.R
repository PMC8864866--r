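# Per-cell classification. Three independent binary classifiers — one each
# for myeloblast, promyelocyte and Auer rod — share a fixed convolutional /
# statistical feature extractor (grid colour pooling, local-contrast and
# high-pass texture energy, colour-opponency extrema that respond to the
# needle-shaped crimson Auer rods) topped by a trainable fully connected
# head of one to three layers with dropout. Each cell keeps its own
# multi-label encoding: a promyelocyte bearing one Auer rod is
# (myeloblast 0, promyelocyte 1, Auer rod 1).

#' Classifier head configuration
#'
#' @param n_fc_layers number of fully connected layers, 1 to 3.
#' @param widths hidden-layer widths (recycled; ignored for
#'   `n_fc_layers = 1`).
#' @param dropout dropout rate on hidden activations, in `[0, 1)`. The tuned
#'   values 0.32 and 0.46 used upstream of the two ensemble tasks are set by
#'   the pipeline configuration.
#' @param feature_dim optional expected feature dimension (informational;
#'   the native-scale extractor contract is 2048, the packaged desk-scale
#'   extractor emits its own fixed dimension).
#' @param epochs,lr training schedule.
#' @param seed integer seed.
#' @return Object of class `head_config`.
#' @export
head_config <- function(n_fc_layers = 2L, widths = 32L, dropout = 0,
                        feature_dim = NULL, epochs = 120L, lr = 0.01,
                        seed = 1L) {
  if (!n_fc_layers %in% 1:3) {
    abort_param("n_fc_layers must be between 1 and 3")
  }
  if (dropout < 0 || dropout >= 1) abort_param("dropout must be in [0, 1)")
  structure(
    list(
      n_fc_layers = as.integer(n_fc_layers), widths = as.integer(widths),
      dropout = dropout, feature_dim = feature_dim,
      epochs = as.integer(epochs), lr = lr, seed = as.integer(seed)
    ),
    class = "head_config"
  )
}

#' Multi-label encoding of an annotated cell
#'
#' Each cell receives three independent binary labels; e.g. a promyelocyte
#' with a single Auer rod encodes as myeloblast 0, promyelocyte 1,
#' Auer rod 1, and an "other" cell as (0, 0, 0).
#' @param annotations annotation tibble (rows with `is_myeloblast`,
#'   `is_promyelocyte`, `has_auer_rod`).
#' @return Tibble of integer columns `is_myeloblast`, `is_promyelocyte`,
#'   `has_auer_rod`.
#' @export
encode_label <- function(annotations) {
  tibble::tibble(
    is_myeloblast = as.integer(annotations$is_myeloblast),
    is_promyelocyte = as.integer(annotations$is_promyelocyte),
    has_auer_rod = as.integer(annotations$has_auer_rod)
  )
}

block_mean <- function(mat, nb) {
  h <- nrow(mat); w <- ncol(mat)
  h2 <- (h %/% nb) * nb; w2 <- (w %/% nb) * nb
  m <- mat[seq_len(h2), seq_len(w2), drop = FALSE]
  rg <- rep(seq_len(nb), each = h2 / nb)
  cg <- rep(seq_len(nb), each = w2 / nb)
  t(rowsum(t(rowsum(m, rg)), cg)) / ((h2 / nb) * (w2 / nb))
}

highpass3 <- function(mat) {
  h <- nrow(mat); w <- ncol(mat)
  if (h < 3 || w < 3) return(matrix(0, 1, 1))
  ctr <- mat[2:(h - 1), 2:(w - 1)]
  acc <- matrix(0, h - 2, w - 2)
  for (dr in -1:1) for (dc in -1:1) {
    acc <- acc + mat[(2 + dr):(h - 1 + dr), (2 + dc):(w - 1 + dc)]
  }
  ctr - acc / 9
}

#' Fixed feature extraction for a cell crop
#'
#' @param crop square `s x s x 3` array in `[0, 1]`.
#' @return Named numeric feature vector (constant length for a given crop
#'   size).
#' @export
featurize_crop <- function(crop) {
  assert_image(crop)
  r <- crop[, , 1]; g <- crop[, , 2]; b <- crop[, , 3]
  lum <- 0.2126 * r + 0.7152 * g + 0.0722 * b
  qs <- c(0.01, 0.1, 0.5, 0.9, 0.99)
  grid <- c(
    block_mean(r, 8), block_mean(g, 8), block_mean(b, 8),
    block_mean((lum - mean(lum))^2, 4)
  )
  opp <- function(m) stats::quantile(m, c(0.01, 0.5, 0.99, 1), names = FALSE)
  hp <- highpass3(lum)
  bg <- estimate_background(crop, frame = 2L)
  fg_frac <- mean(background_distance(crop, bg) > 0.08)
  feats <- c(
    grid,
    stats::quantile(r, qs, names = FALSE),
    stats::quantile(g, qs, names = FALSE),
    stats::quantile(b, qs, names = FALSE),
    opp(r - g), opp(r - b), opp(g - b),
    opp(-(r - b)), # nucleus-blue extreme
    mean(abs(hp)), stats::quantile(abs(hp), c(0.9, 0.99), names = FALSE),
    mean(lum < 0.3), mean(lum < 0.45), mean(lum < 0.6),
    fg_frac
  )
  as.numeric(feats)
}

featurize_crops <- function(crops) {
  t(vapply(crops, featurize_crop, featurize_crop(crops[[1]])))
}

#' Train one binary per-cell classifier
#'
#' Balances the two classes by augmented upsampling of the minority class
#' (see [balance_classes()]), extracts fixed features and trains the
#' configured fully connected head with Adam; bitwise reproducible for a
#' fixed seed.
#'
#' @param crops list of square crops (all the same size).
#' @param targets logical / 0-1 vector, one per crop.
#' @param config a [head_config()].
#' @param task label stored in the model (e.g. `"myeloblast"`).
#' @return Object of class `cell_cnn`.
#' @export
train_cell_cnn <- function(crops, targets, config = head_config(),
                           task = "cell") {
  targets <- as.logical(targets)
  if (length(crops) != length(targets)) abort_data("crops/targets mismatch")
  if (length(unique(targets)) < 2L) {
    abort_data("both classes must be present in targets")
  }
  records <- tibble::tibble(
    record_id = seq_along(crops), class = as.character(targets)
  )
  balanced <- balance_classes(records, seed = config$seed)
  crop_of <- function(row) {
    if (is.na(balanced$parent_id[row])) {
      crops[[balanced$record_id[row]]]
    } else {
      augment_image(crops[[balanced$parent_id[row]]],
        balanced$augmentation[[row]]
      )
    }
  }
  all_crops <- purrr::map(seq_len(nrow(balanced)), crop_of)
  X <- featurize_crops(all_crops)
  y <- as.numeric(balanced$class == "TRUE")
  scaler <- fit_scaler(X)
  widths <- rep_len(config$widths, max(config$n_fc_layers - 1L, 1L))
  dims <- c(ncol(X), widths[seq_len(config$n_fc_layers - 1L)], 1L)
  net <- mlp_init(dims, seed = config$seed)
  fit <- mlp_train(net, apply_scaler(scaler, X), y,
    epochs = config$epochs, lr = config$lr, dropout = config$dropout,
    weight_decay = 1e-4, seed = config$seed
  )
  structure(
    list(
      task = task, scaler = scaler, net = fit$net, config = config,
      input_size = dim(crops[[1]])[1], loss_history = fit$loss_trace
    ),
    class = "cell_cnn"
  )
}

#' @export
print.cell_cnn <- function(x, ...) {
  if (!is.null(x$constant)) {
    cat(sprintf(
      "<cell_cnn task=%s, constant rate %.4f>\n", x$task, x$constant
    ))
  } else {
    cat(sprintf(
      "<cell_cnn task=%s, %d-layer head, input %dx%d, final loss %.4f>\n",
      x$task, x$config$n_fc_layers, x$input_size, x$input_size,
      utils::tail(x$loss_history, 1)
    ))
  }
  invisible(x)
}

#' Score crops with one trained cell classifier
#' @param model a `cell_cnn`.
#' @param crops list of crops matching the model's input size.
#' @return Numeric probabilities in `[0, 1]`.
#' @export
predict_cell_probs <- function(model, crops) {
  if (!length(crops)) return(numeric(0))
  if (dim(crops[[1]])[1] != model$input_size) {
    rlang::abort(
      sprintf(
        "crop size %d does not match model input %d",
        dim(crops[[1]])[1], model$input_size
      ),
      class = "aplsmear_shape_error"
    )
  }
  score_features(model, featurize_crops(crops))
}

# Score a pre-computed feature matrix (lets the three classifiers share one
# feature extraction pass).
score_features <- function(model, X) {
  if (!is.null(model$constant)) return(rep(model$constant, nrow(X)))
  mlp_predict(model$net, apply_scaler(model$scaler, X))
}

#' Constant-rate fallback cell model
#'
#' Stands in for a binary cell classifier when a label class is entirely
#' absent from the training crops (e.g. no Auer-rod cells in a healthy-donor
#' training fold): it scores every crop with the observed positive rate.
#' @param rate constant probability emitted for every crop.
#' @param input_size expected crop side length.
#' @param task label stored in the model.
#' @return Object of class `cell_cnn` with a `constant` field.
#' @export
constant_cell_model <- function(rate, input_size = 64L, task = "cell") {
  structure(
    list(
      task = task, constant = min(max(rate, 1e-6), 1 - 1e-6),
      input_size = as.integer(input_size), config = NULL,
      loss_history = numeric(0)
    ),
    class = "cell_cnn"
  )
}

#' Per-cell predictions from the three binary classifiers
#'
#' @param models named list with elements `myeloblast`, `promyelocyte`,
#'   `auer_rod`, each a trained `cell_cnn`.
#' @param crops list of crops.
#' @return Tibble with one row per crop: `p_myeloblast`, `p_promyelocyte`,
#'   `p_auer_rod` plus morphometrics `size_px2`, `volume_proxy`, `contrast`.
#' @export
predict_cells <- function(models, crops) {
  if (!length(crops)) {
    return(tibble::tibble(
      p_myeloblast = numeric(), p_promyelocyte = numeric(),
      p_auer_rod = numeric(), size_px2 = numeric(),
      volume_proxy = numeric(), contrast = numeric()
    ))
  }
  morph <- purrr::map_dfr(crops, morphometrics)
  if (dim(crops[[1]])[1] != models$myeloblast$input_size) {
    rlang::abort("crop size does not match model input",
      class = "aplsmear_shape_error"
    )
  }
  X <- featurize_crops(crops)
  tibble::tibble(
    p_myeloblast = score_features(models$myeloblast, X),
    p_promyelocyte = score_features(models$promyelocyte, X),
    p_auer_rod = score_features(models$auer_rod, X)
  ) |>
    dplyr::bind_cols(morph)
}

#' Classical morphometrics of a cell crop
#'
#' Size is the foreground pixel count; the volume proxy is the
#' sphere-equivalent volume of a disc of that area,
#' `V = 4 / (3 sqrt(pi)) * size^(3/2)`; contrast is the RMS deviation of
#' foreground luminance.
#'
#' @param crop `s x s x 3` array.
#' @param mask optional logical foreground mask (e.g. from
#'   [refine_ellipse()]); by default the crop is thresholded against its
#'   border background colour, falling back to the whole crop if the
#'   threshold finds nothing.
#' @return Tibble with `size_px2`, `volume_proxy`, `contrast`.
#' @export
morphometrics <- function(crop, mask = NULL) {
  lum <- luminance(crop)
  if (is.null(mask)) {
    bg <- estimate_background(crop, frame = 2L)
    mask <- background_distance(crop, bg) > 0.08
  }
  if (!any(mask)) mask <- matrix(TRUE, nrow(lum), ncol(lum))
  size <- sum(mask)
  vals <- lum[mask]
  tibble::tibble(
    size_px2 = size,
    volume_proxy = 4 / (3 * sqrt(pi)) * size^1.5,
    contrast = sqrt(mean((vals - mean(vals))^2))
  )
}

#' Write a crop dataset to a directory
#'
#' PNG crops plus a CSV label table (`crop_path`, `image_id`, `patient_id`,
#' `is_myeloblast`, `is_promyelocyte`, `has_auer_rod`).
#' @param crops list of crops.
#' @param labels tibble with `image_id`, `patient_id` and the three label
#'   columns, one row per crop.
#' @param dir output directory.
#' @return The label table with `crop_path` filled in.
#' @export
write_crop_dataset <- function(crops, labels, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels$crop_path <- file.path(dir, sprintf("crop_%05d.png", seq_along(crops)))
  purrr::walk2(crops, labels$crop_path, write_image)
  enc <- encode_label(labels)
  out <- dplyr::bind_cols(
    labels[, c("crop_path", "image_id", "patient_id")], enc
  )
  utils::write.csv(out, file.path(dir, "labels.csv"), row.names = FALSE)
  out
}
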