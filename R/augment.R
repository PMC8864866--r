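# Augmentation operators and class balancing. The operators are
# annotation-geometry-safe (flips and right-angle rotations only, plus
# per-channel colour shift and brightness), used to enlarge and balance the
# minority class for binary training, mirroring how a small APL sample is
# countered in practice.

abort_param <- function(msg) rlang::abort(msg, class = "aplsmear_invalid_param")

#' Apply a deterministic augmentation to an image
#'
#' Operations are applied as: horizontal flip, vertical flip, rotation,
#' colour shift, brightness. Pixel values are clipped to `[0, 1]`; 90/270
#' degree rotations swap width and height.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param params list with any of `flip_h`, `flip_v` (logical), `rotation`
#'   (0, 90, 180 or 270 degrees counter-clockwise), `color_shift` (length-3
#'   per-channel delta) and `brightness` (scalar delta), all on the `[0, 1]`
#'   pixel scale.
#' @return Augmented image array.
#' @export
augment_image <- function(image, params = list()) {
  assert_image(image)
  rot <- params$rotation %||% 0
  if (!rot %in% c(0, 90, 180, 270)) {
    abort_param("rotation must be one of 0, 90, 180, 270")
  }
  img <- image
  if (isTRUE(params$flip_h)) img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  if (isTRUE(params$flip_v)) img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  if (rot == 90) { # counter-clockwise
    img <- aperm(img, c(2, 1, 3))[rev(seq_len(dim(img)[2])), , , drop = FALSE]
  } else if (rot == 180) {
    img <- img[rev(seq_len(dim(img)[1])), rev(seq_len(dim(img)[2])), , drop = FALSE]
  } else if (rot == 270) {
    img <- aperm(img, c(2, 1, 3))[, rev(seq_len(dim(img)[1])), , drop = FALSE]
  }
  shift <- params$color_shift %||% c(0, 0, 0)
  bright <- params$brightness %||% 0
  if (any(shift != 0) || bright != 0) {
    for (ch in 1:3) img[, , ch] <- img[, , ch] + shift[ch] + bright
    img <- clip01(img)
  }
  img
}

#' Draw random augmentation parameters
#' @param max_color_shift,max_brightness half-widths of the uniform deltas
#'   (pixel scale).
#' @return A `params` list for [augment_image()].
#' @export
sample_augment_params <- function(max_color_shift = 0.05,
                                  max_brightness = 0.08) {
  list(
    flip_h = stats::runif(1) < 0.5,
    flip_v = stats::runif(1) < 0.5,
    rotation = sample(c(0, 90, 180, 270), 1L),
    color_shift = stats::runif(3, -max_color_shift, max_color_shift),
    brightness = stats::runif(1, -max_brightness, max_brightness)
  )
}

#' Balance class counts by augmenting minority records
#'
#' Tops every minority class up to the majority class count with augmented
#' copies of randomly drawn parents. Originals are always retained; each
#' copy records its parent row and its own augmentation parameter draw, and
#' inherits the parent's `patient_id` so fold assignment follows the parent.
#'
#' @param records tibble with a `class` column (and typically `patient_id`).
#' @param seed integer seed.
#' @return Tibble: the originals (with `parent_id = NA`, `augmentation`
#'   empty) plus augmented rows (`parent_id` = parent's row id,
#'   `augmentation` = the parameter draw, list-column). A `record_id` column
#'   is added if absent.
#' @export
balance_classes <- function(records, seed = 1L) {
  if (!"class" %in% names(records)) abort_data("records need a `class` column")
  counts <- table(records$class)
  if (any(counts == 0) || nrow(records) == 0) {
    abort_data("every class must be non-empty")
  }
  if (!"record_id" %in% names(records)) {
    records$record_id <- seq_len(nrow(records))
  }
  records$parent_id <- NA_integer_
  records$augmentation <- replicate(nrow(records), list(), simplify = FALSE)
  target <- max(counts)
  set.seed(seed)
  extra <- list()
  next_id <- max(records$record_id) + 1L
  for (cl in names(counts)) {
    deficit <- target - counts[[cl]]
    if (deficit == 0) next
    parents <- records[records$class == cl & is.na(records$parent_id), ]
    pick <- parents[sample.int(nrow(parents), deficit, replace = TRUE), ]
    pick$parent_id <- pick$record_id
    pick$record_id <- seq.int(next_id, length.out = deficit)
    next_id <- next_id + deficit
    pick$augmentation <- replicate(deficit, sample_augment_params(),
      simplify = FALSE
    )
    extra[[cl]] <- pick
  }
  dplyr::bind_rows(records, dplyr::bind_rows(extra))
}
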