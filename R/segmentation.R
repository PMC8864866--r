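# Two-stage cell detector. Stage one proposes candidate regions from a
# learned background colour model: pixels deviating from the background are
# segmented, split into touching components by a distance-transform
# watershed, and summarized as candidate boxes with moment-fitted ellipses.
# Stage two is a learned region scorer (logistic layer on region features,
# trained by gradient descent with per-epoch loss logging) that separates
# viable cells from background artifacts and smudges. Detections are
# confidence-ranked, non-maximum-suppressed on axis-aligned boxes, and can
# be polished by an intensity-based ellipse refinement.

abort_state <- function(msg) rlang::abort(msg, class = "aplsmear_state_error")

#' Detector configuration
#'
#' @param prop_threshold background-deviation threshold for stage-one
#'   proposals (pixel scale).
#' @param min_area minimum proposal area, px^2.
#' @param score_threshold default confidence cut for [detect_cells()].
#' @param nms_iou IoU threshold for non-maximum suppression.
#' @param watershed_tolerance tolerance of the distance-transform watershed
#'   that splits touching cells (px).
#' @param epochs,lr region-scorer training schedule.
#' @param crop_size side length of per-cell crops, px (native acquisition
#'   uses 299).
#' @param seed integer seed for scorer initialization and training.
#' @return Object of class `detector_config`.
#' @export
detector_config <- function(prop_threshold = 0.08, min_area = 60,
                            score_threshold = 0.5, nms_iou = 0.5,
                            watershed_tolerance = 3,
                            epochs = 40L, lr = 0.2, crop_size = 299L,
                            seed = 1L) {
  stopifnot(
    prop_threshold > 0, score_threshold >= 0, score_threshold <= 1,
    nms_iou >= 0, nms_iou <= 1, crop_size > 0, epochs >= 0
  )
  structure(
    list(
      prop_threshold = prop_threshold, min_area = min_area,
      score_threshold = score_threshold, nms_iou = nms_iou,
      watershed_tolerance = watershed_tolerance,
      epochs = as.integer(epochs), lr = lr,
      crop_size = as.integer(crop_size), seed = as.integer(seed)
    ),
    class = "detector_config"
  )
}

# Stage one: candidate regions with geometry and scorer features.
propose_regions <- function(image, bg, config) {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  dist <- background_distance(image, bg)
  mask <- dist > config$prop_threshold
  m <- EBImage::opening(ebi_gray(mask), EBImage::makeBrush(3, "diamond"))
  dm <- EBImage::distmap(m)
  labels <- EBImage::watershed(dm, tolerance = config$watershed_tolerance,
    ext = 1
  )
  lab <- t(EBImage::imageData(labels)) # back to row-major H x W
  n_lab <- max(lab)
  if (n_lab == 0) return(empty_regions())
  lum <- luminance(image)
  out <- vector("list", n_lab)
  idx <- which(lab > 0)
  rows_all <- (idx - 1L) %% h + 1L
  cols_all <- (idx - 1L) %/% h + 1L
  lab_val <- lab[idx]
  ord <- order(lab_val)
  idx <- idx[ord]; rows_all <- rows_all[ord]; cols_all <- cols_all[ord]
  bounds <- c(0L, cumsum(tabulate(lab_val, n_lab)))
  k <- 0L
  for (l in seq_len(n_lab)) {
    sel <- seq.int(bounds[l] + 1L, bounds[l + 1L])
    if (length(sel) < config$min_area) next
    rr <- rows_all[sel]; cc <- cols_all[sel]
    px <- cc - 0.5; py <- rr - 0.5
    ell <- moments_to_ellipse(px, py)
    pix <- idx[sel]
    mr <- mean(image[, , 1][pix]); mg <- mean(image[, , 2][pix])
    mb <- mean(image[, , 3][pix])
    sdl <- stats::sd(lum[pix]); if (!is.finite(sdl)) sdl <- 0
    mdist <- mean(dist[pix])
    area <- length(sel)
    bw <- max(cc) - min(cc) + 1L; bh <- max(rr) - min(rr) + 1L
    k <- k + 1L
    out[[k]] <- tibble::tibble(
      region_id = k,
      x_min = min(cc) - 1, y_min = min(rr) - 1,
      x_max = max(cc), y_max = max(rr),
      cx = ell$cx, cy = ell$cy, rx = ell$rx, ry = ell$ry, theta = ell$theta,
      confidence = NA_real_, source = "proposed",
      f_log_area = log(area), f_fill = area / (bw * bh),
      f_log_aspect = log(bw / bh),
      f_mean_r = mr, f_mean_g = mg, f_mean_b = mb,
      f_sd_lum = sdl, f_mean_dist = mdist,
      f_ecc = ell$ry / ell$rx
    )
  }
  if (k == 0) return(empty_regions())
  dplyr::bind_rows(out[seq_len(k)])
}

empty_regions <- function() {
  tibble::tibble(
    region_id = integer(),
    x_min = numeric(), y_min = numeric(), x_max = numeric(), y_max = numeric(),
    cx = numeric(), cy = numeric(), rx = numeric(), ry = numeric(),
    theta = numeric(), confidence = numeric(), source = character(),
    f_log_area = numeric(), f_fill = numeric(), f_log_aspect = numeric(),
    f_mean_r = numeric(), f_mean_g = numeric(), f_mean_b = numeric(),
    f_sd_lum = numeric(), f_mean_dist = numeric(), f_ecc = numeric()
  )
}

# Ellipse from second-order moments of a pixel cloud; exact for a filled
# ellipse (eigenvalues of the covariance are (rx/2)^2 and (ry/2)^2).
moments_to_ellipse <- function(px, py) {
  cx <- mean(px); cy <- mean(py)
  n <- length(px)
  if (n < 3) return(list(cx = cx, cy = cy, rx = 1, ry = 1, theta = 0))
  cxx <- mean((px - cx)^2); cyy <- mean((py - cy)^2)
  cxy <- mean((px - cx) * (py - cy))
  e <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  rx <- 2 * sqrt(max(e$values[1], 1e-6))
  ry <- 2 * sqrt(max(e$values[2], 1e-6))
  theta <- atan2(e$vectors[2, 1], e$vectors[1, 1])
  if (theta < 0) theta <- theta + pi
  list(cx = cx, cy = cy, rx = rx, ry = ry, theta = theta)
}

feature_cols <- function() {
  c(
    "f_log_area", "f_fill", "f_log_aspect", "f_mean_r", "f_mean_g",
    "f_mean_b", "f_sd_lum", "f_mean_dist", "f_ecc"
  )
}

#' Train the two-stage cell detector
#'
#' Fits the background colour model on the training images and trains the
#' stage-two region scorer on stage-one proposals, labelled positive when
#' they overlap an annotated cell at IoU >= 0.5. Training is full-batch and
#' single-threaded, hence bitwise reproducible for a fixed seed.
#'
#' @param images named list of `H x W x 3` arrays, keyed by `image_id`.
#' @param annotations tibble of ground-truth cell annotations covering the
#'   training images (`image_id` must match the list names).
#' @param config a [detector_config()].
#' @return Object of class `cell_detector` with the per-epoch training-loss
#'   trace in `$loss_history`. With `epochs = 0` the scorer is left
#'   untrained and the model is flagged `trained = FALSE`.
#' @export
train_detector <- function(images, annotations, config = detector_config()) {
  if (length(images) == 0) abort_data("empty training set")
  if (is.null(names(images))) {
    names(images) <- sprintf("img_%04d", seq_along(images))
  }
  bg <- rowMeans(vapply(images, estimate_background, numeric(3)))
  props <- purrr::imap_dfr(images, function(img, id) {
    p <- propose_regions(img, bg, config)
    p$image_id <- id
    gt <- annotations[annotations$image_id == id, , drop = FALSE]
    p$label <- if (nrow(gt) && nrow(p)) {
      apply(iou_matrix(box_matrix(p), box_matrix(gt)), 1, max) >= 0.5
    } else {
      rep(FALSE, nrow(p))
    }
    p
  })
  model <- structure(
    list(
      background = bg, config = config, trained = FALSE,
      scaler = NULL, net = NULL, loss_history = numeric(0),
      n_train_proposals = nrow(props)
    ),
    class = "cell_detector"
  )
  if (config$epochs == 0L || nrow(props) == 0) {
    return(model)
  }
  X <- as.matrix(props[, feature_cols()])
  y <- as.numeric(props$label)
  scaler <- fit_scaler(X)
  net <- mlp_init(c(ncol(X), 1L), seed = config$seed)
  fit <- mlp_train(net, apply_scaler(scaler, X), y,
    epochs = config$epochs, lr = config$lr, seed = config$seed
  )
  model$scaler <- scaler
  model$net <- fit$net
  model$loss_history <- fit$loss_trace
  model$trained <- TRUE
  model
}

#' @export
print.cell_detector <- function(x, ...) {
  cat(sprintf(
    "<cell_detector: %s, %d scorer epochs, %d training proposals>\n",
    if (x$trained) "trained" else "untrained",
    length(x$loss_history), x$n_train_proposals
  ))
  invisible(x)
}

#' Non-maximum suppression on axis-aligned boxes
#'
#' Greedy, confidence-descending (ties broken by lower `region_id`);
#' suppresses any box overlapping a kept box at IoU > `nms_iou`.
#' Idempotent: applying it twice equals once.
#' @param regions tibble of detections with box columns, `confidence`,
#'   `region_id`.
#' @param nms_iou suppression threshold.
#' @return The surviving rows, confidence-descending.
#' @export
nms_regions <- function(regions, nms_iou = 0.5) {
  if (nrow(regions) <= 1L) return(regions)
  ord <- order(-regions$confidence, regions$region_id)
  regions <- regions[ord, ]
  boxes <- box_matrix(regions)
  keep <- logical(nrow(regions))
  ious <- iou_matrix(boxes, boxes)
  for (i in seq_len(nrow(regions))) {
    kept <- which(keep)
    keep[i] <- !length(kept) || all(ious[i, kept] <= nms_iou)
  }
  regions[keep, ]
}

#' Detect cells on a smear image
#'
#' Runs stage-one proposals, scores them with the trained region scorer,
#' drops proposals below `score_threshold`, applies non-maximum suppression
#' and clips boxes to the image.
#'
#' @param model a trained [train_detector()] model.
#' @param image `H x W x 3` array.
#' @param score_threshold confidence cut; defaults to the config value.
#' @return Tibble of detected regions sorted by descending confidence
#'   (`region_id` renumbered in that order, `source = "proposed"`).
#' @export
detect_cells <- function(model, image, score_threshold = NULL) {
  if (!inherits(model, "cell_detector")) abort_state("not a cell_detector")
  if (!model$trained) abort_state("detector is untrained")
  score_threshold <- score_threshold %||% model$config$score_threshold
  stopifnot(score_threshold >= 0, score_threshold <= 1)
  props <- propose_regions(image, model$background, model$config)
  if (nrow(props) == 0) return(props[, detection_cols()])
  X <- apply_scaler(model$scaler, as.matrix(props[, feature_cols()]))
  props$confidence <- mlp_predict(model$net, X)
  props <- props[props$confidence >= score_threshold, , drop = FALSE]
  props <- nms_regions(props, model$config$nms_iou)
  d <- dim(image)
  props$x_min <- pmax(props$x_min, 0); props$y_min <- pmax(props$y_min, 0)
  props$x_max <- pmin(props$x_max, d[2]); props$y_max <- pmin(props$y_max, d[1])
  props <- props[order(-props$confidence, props$region_id), ]
  props$region_id <- seq_len(nrow(props))
  props[, detection_cols()]
}

detection_cols <- function() {
  c(
    "region_id", "x_min", "y_min", "x_max", "y_max",
    "cx", "cy", "rx", "ry", "theta", "confidence", "source"
  )
}

#' Refine a detected region's ellipse from image intensities
#'
#' Re-fits the ellipse by image moments of the foreground component inside
#' a 1.25x-expanded box around the detection. If no foreground pixels are
#' found (uniform background), the input region is returned unchanged; on
#' success `source` becomes `"refined"` and the box is the tight box of the
#' refined component, never exceeding the expanded input box.
#'
#' @param image `H x W x 3` array.
#' @param region one-row tibble of a detected region.
#' @return The (possibly) refined one-row region tibble.
#' @export
refine_ellipse <- function(image, region) {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  bcx <- (region$x_min + region$x_max) / 2
  bcy <- (region$y_min + region$y_max) / 2
  hw <- (region$x_max - region$x_min) / 2 * 1.25
  hh <- (region$y_max - region$y_min) / 2 * 1.25
  win <- clip_box(c(bcx - hw, bcy - hh, bcx + hw, bcy + hh), h, w)
  px <- box_pixels(win, h, w)
  sub <- image[px$rows, px$cols, , drop = FALSE]
  bg <- estimate_background(sub, frame = 2L)
  mask <- background_distance(sub, bg) > 0.08
  if (!any(mask)) return(region)
  lab <- t(EBImage::imageData(EBImage::bwlabel(ebi_gray(mask))))
  # component containing (or nearest to) the region centre
  ctr_r <- round(bcy - (px$rows[1] - 1)) ; ctr_c <- round(bcx - (px$cols[1] - 1))
  ctr_r <- min(max(ctr_r, 1L), nrow(lab)); ctr_c <- min(max(ctr_c, 1L), ncol(lab))
  comp <- lab[ctr_r, ctr_c]
  if (comp == 0) {
    sizes <- tabulate(lab[lab > 0])
    if (!length(sizes)) return(region)
    comp <- which.max(sizes)
  }
  sel <- which(lab == comp)
  rr <- (sel - 1L) %% nrow(lab) + 1L
  cc <- (sel - 1L) %/% nrow(lab) + 1L
  abs_x <- cc + (px$cols[1] - 1L) - 0.5
  abs_y <- rr + (px$rows[1] - 1L) - 0.5
  ell <- moments_to_ellipse(abs_x, abs_y)
  out <- region
  out$cx <- ell$cx; out$cy <- ell$cy
  out$rx <- ell$rx; out$ry <- ell$ry; out$theta <- ell$theta
  out$x_min <- max(min(abs_x) - 0.5, win[1])
  out$y_min <- max(min(abs_y) - 0.5, win[2])
  out$x_max <- min(max(abs_x) + 0.5, win[3])
  out$y_max <- min(max(abs_y) + 0.5, win[4])
  out$source <- "refined"
  out
}

#' Refine every region of a detection table
#' @param image `H x W x 3` array.
#' @param regions detection tibble.
#' @return Detection tibble with refined rows.
#' @export
refine_regions <- function(image, regions) {
  if (nrow(regions) == 0) return(regions)
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    refine_ellipse(image, regions[i, , drop = FALSE])
  })
}

#' One human-in-the-loop correction round
#'
#' Simulates the annotator correction step: current model proposals that
#' overlap a ground-truth cell at IoU >= `iou_accept` are kept; the
#' remaining proposals are discarded and every uncovered ground-truth cell
#' is added back as a corrected region. The detector is then retrained on
#' the corrected annotation set. With an untrained model (round zero) the
#' corrected set equals the ground truth; with `iou_accept = 0` all
#' proposals are kept verbatim.
#'
#' @param model a `cell_detector` (possibly untrained).
#' @param images named list of images.
#' @param ground_truth tibble of ground-truth annotations (the simulated
#'   hematologist).
#' @param config [detector_config()] for retraining.
#' @param iou_accept acceptance threshold in `[0, 1]`.
#' @return List with `annotations` (the corrected set, `source` column
#'   marking `"proposed"` vs `"corrected"`) and `model` (retrained).
#' @export
hitl_round <- function(model, images, ground_truth,
                       config = model$config, iou_accept = 0.5) {
  if (length(images) == 0) abort_data("empty image set")
  corrected <- purrr::imap_dfr(images, function(img, id) {
    gt <- ground_truth[ground_truth$image_id == id, , drop = FALSE]
    dets <- if (inherits(model, "cell_detector") && model$trained) {
      detect_cells(model, img)
    } else {
      empty_regions()[, detection_cols()]
    }
    if (nrow(dets) && nrow(gt)) {
      best_iou <- apply(iou_matrix(box_matrix(dets), box_matrix(gt)), 1, max)
      kept <- dets[best_iou >= iou_accept, , drop = FALSE]
      covered <- match_detections(dets, gt, max(iou_accept, 1e-9))$gt_matched
    } else {
      kept <- dets[0, , drop = FALSE]
      covered <- rep(FALSE, nrow(gt))
    }
    kept_ann <- if (nrow(kept)) {
      tibble::tibble(
        region_id = kept$region_id, image_id = id,
        patient_id = gt$patient_id[1] %||% NA_character_,
        cx = kept$cx, cy = kept$cy, rx = kept$rx, ry = kept$ry,
        theta = kept$theta,
        x_min = kept$x_min, y_min = kept$y_min,
        x_max = kept$x_max, y_max = kept$y_max,
        cell_type = "other", is_myeloblast = FALSE,
        is_promyelocyte = FALSE, has_auer_rod = FALSE, n_auer_rods = 0L,
        source = "proposed"
      )
    } else NULL
    add <- gt[!covered, , drop = FALSE]
    if (nrow(add)) add$source <- "corrected"
    dplyr::bind_rows(kept_ann, add)
  })
  list(
    annotations = corrected,
    model = train_detector(images, corrected, config)
  )
}

#' Crop fixed-size per-cell images
#'
#' Extracts each region's box, pads it to a square with the image background
#' colour (border regions are padded, never read out of bounds) and resizes
#' it, aspect preserved, to `crop_size` x `crop_size`.
#'
#' @param image `H x W x 3` array.
#' @param regions tibble with box columns (detections or annotations).
#' @param crop_size output side length in px (299 at native acquisition
#'   scale, 64 in the desk-scale configuration).
#' @return List of `crop_size x crop_size x 3` arrays, one per region row.
#' @export
crop_cells <- function(image, regions, crop_size = 299L) {
  stopifnot(crop_size > 0)
  if (nrow(regions) == 0) return(list())
  d <- dim(image)
  fill <- estimate_background(image)
  purrr::map(seq_len(nrow(regions)), function(i) {
    box <- clip_box(c(
      regions$x_min[i], regions$y_min[i],
      regions$x_max[i], regions$y_max[i]
    ), d[1], d[2])
    if (box[3] - box[1] < 1 || box[4] - box[2] < 1) {
      return(array(rep(fill, each = crop_size * crop_size),
        dim = c(crop_size, crop_size, 3)
      ))
    }
    px <- box_pixels(box, d[1], d[2])
    resize_pad(image[px$rows, px$cols, , drop = FALSE], crop_size, fill)
  })
}

#' Save / load a detector checkpoint
#' @param model a `cell_detector`.
#' @param path file path.
#' @return `save_detector()` returns `path` invisibly; `load_detector()` the
#'   model.
#' @export
save_detector <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) readRDS(path)

#' Export detections to the annotation JSON dialect
#' @param regions detection tibble for one image.
#' @param image_id image identifier.
#' @param path output JSON path.
#' @param canvas optional `c(width, height)`.
#' @return `path`, invisibly.
#' @export
write_detections <- function(regions, image_id, path, canvas = NULL) {
  ann <- tibble::tibble(
    region_id = regions$region_id, image_id = image_id,
    patient_id = NA_character_,
    cx = regions$cx, cy = regions$cy, rx = regions$rx, ry = regions$ry,
    theta = regions$theta,
    x_min = regions$x_min, y_min = regions$y_min,
    x_max = regions$x_max, y_max = regions$y_max,
    cell_type = "other", is_myeloblast = FALSE, is_promyelocyte = FALSE,
    has_auer_rod = FALSE, n_auer_rods = 0L,
    confidence = regions$confidence
  )
  write_annotations(ann, path, canvas = canvas)
}
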