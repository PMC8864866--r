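# Occlusion sensitivity mapping: patches of the image are replaced by a
# fill colour one grid position at a time and the image-level score is
# recomputed; the importance of a patch is the score drop it causes. High
# importance concentrated on cells (rather than background or smudge) is
# the proof-of-concept check that the image-level classifier looks at
# cells.

#' Occlusion sensitivity map of an image-level scoring function
#'
#' @param score_fn function `image -> numeric scalar` (typically the
#'   end-to-end `p_apl` of [classify_smear()]).
#' @param image `H x W x 3` array.
#' @param patch_size occluder side length, px (must fit inside the image).
#' @param stride grid stride, px (>= 1).
#' @param fill length-3 occluder colour; defaults to the image's estimated
#'   background colour.
#' @return Object of class `occlusion_map`: `importance` (matrix with
#'   `floor((H - patch)/stride) + 1` rows and
#'   `floor((W - patch)/stride) + 1` columns, `baseline - occluded` score),
#'   `baseline`, `patch_size`, `stride`, `image_dim`. The input image is
#'   left unmodified.
#' @export
occlusion_map <- function(score_fn, image, patch_size = 32L, stride = 16L,
                          fill = NULL) {
  assert_image(image)
  d <- dim(image)
  if (patch_size > min(d[1], d[2])) {
    abort_param("patch_size must not exceed the image")
  }
  if (stride < 1) abort_param("stride must be >= 1")
  fill <- fill %||% estimate_background(image)
  baseline <- score_fn(image)
  n_rows <- floor((d[1] - patch_size) / stride) + 1L
  n_cols <- floor((d[2] - patch_size) / stride) + 1L
  imp <- matrix(NA_real_, n_rows, n_cols)
  for (gr in seq_len(n_rows)) {
    r0 <- (gr - 1L) * stride
    rows <- (r0 + 1L):(r0 + patch_size)
    for (gc in seq_len(n_cols)) {
      c0 <- (gc - 1L) * stride
      cols <- (c0 + 1L):(c0 + patch_size)
      occluded <- image
      for (ch in 1:3) occluded[rows, cols, ch] <- fill[ch]
      imp[gr, gc] <- baseline - score_fn(occluded)
    }
  }
  structure(
    list(
      importance = imp, baseline = baseline,
      patch_size = as.integer(patch_size), stride = as.integer(stride),
      image_dim = c(height = d[1], width = d[2]), fill = fill
    ),
    class = "occlusion_map"
  )
}

#' @export
print.occlusion_map <- function(x, ...) {
  cat(sprintf(
    "<occlusion_map %dx%d (patch %d, stride %d), baseline %.4f, max importance %.4f>\n",
    nrow(x$importance), ncol(x$importance), x$patch_size, x$stride,
    x$baseline, max(x$importance)
  ))
  invisible(x)
}

viridis_lut <- function(n = 256L) {
  t(grDevices::col2rgb(grDevices::hcl.colors(n, "viridis")) / 255)
}

#' Render an occlusion map as a colour overlay
#'
#' Importance is min-max normalized (an all-equal map renders uniformly at
#' mid-scale), mapped through a perceptually ordered colormap (viridis:
#' yellow/green = important, blue/purple = negligible) and alpha-blended
#' over the image; two maps that are positive scalar multiples of each
#' other render identically.
#'
#' @param map an `occlusion_map` computed on `image`.
#' @param image the same `H x W x 3` array.
#' @param alpha overlay opacity in `[0, 1]`.
#' @return `H x W x 3` overlay array.
#' @export
render_map <- function(map, image, alpha = 0.5) {
  assert_image(image)
  d <- dim(image)
  if (!identical(unname(map$image_dim), c(d[1], d[2]))) {
    abort_param("map does not match image dimensions")
  }
  imp <- map$importance
  rng <- range(imp)
  norm <- if (diff(rng) < 1e-12) {
    matrix(0.5, nrow(imp), ncol(imp))
  } else {
    (imp - rng[1]) / diff(rng)
  }
  up <- EBImage::resize(ebi_gray(norm), w = d[2], h = d[1])
  field <- clip01(t(EBImage::imageData(up)))
  lut <- viridis_lut()
  idx <- pmin(pmax(round(field * 255) + 1L, 1L), 256L)
  overlay <- image
  for (ch in 1:3) {
    colmat <- matrix(lut[idx, ch], d[1], d[2])
    overlay[, , ch] <- (1 - alpha) * image[, , ch] + alpha * colmat
  }
  clip01(overlay)
}

#' Export the raw importance grid as CSV
#' @param map an `occlusion_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occlusion_grid <- function(map, path) {
  utils::write.csv(map$importance, path, row.names = FALSE)
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.occlusion_map <- function(object, ...) {
  df <- tidyr::expand_grid(
    row = seq_len(nrow(object$importance)),
    col = seq_len(ncol(object$importance))
  )
  df$importance <- as.vector(t(object$importance))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
    fill = .data$importance
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "grid column", y = "grid row",
      title = "Occlusion sensitivity"
    )
}
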