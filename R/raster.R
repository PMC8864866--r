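# Raster conventions used throughout the package:
#   * an image is a numeric array dim c(H, W, 3), values in [0, 1], RGB
#   * origin top-left; x runs along columns, y along rows
#   * coordinates are 0-based and continuous: pixel (row i, col j) (1-based R
#     indices) covers x in [j-1, j), y in [i-1, i); its centre is (j-.5, i-.5)
#   * boxes are c(x_min, y_min, x_max, y_max), 0-based, half-open

#' Dimensions of a smear image
#' @param image numeric `H x W x 3` array.
#' @return Named integer vector with elements `height` and `width`.
#' @export
image_dim <- function(image) {
  d <- dim(image)
  c(height = as.integer(d[1]), width = as.integer(d[2]))
}

assert_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("expected an H x W x 3 numeric array", call. = FALSE)
  }
  invisible(image)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Read / write a smear image as 8-bit RGB PNG
#'
#' Thin wrappers around the png package keeping the package-wide
#' `H x W x 3`, `[0, 1]` array convention.
#' @param path file path.
#' @param image numeric `H x W x 3` array in `[0, 1]`.
#' @return `read_image()` returns the array; `write_image()` returns `path`
#'   invisibly.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  assert_image(image)
  png::writePNG(clip01(image), target = path)
  invisible(path)
}

# EBImage stores images x-major; transpose at this boundary only.
as_ebi <- function(image) {
  EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
}

ebi_gray <- function(mat) EBImage::Image(t(mat), colormode = "Grayscale")

#' Tight axis-aligned bounding box of a rotated ellipse
#'
#' @param cx,cy ellipse centre (0-based image coordinates, px).
#' @param rx,ry semi-axes (px).
#' @param theta rotation in radians, counter-clockwise.
#' @return Numeric vector `c(x_min, y_min, x_max, y_max)` (half-open).
#' @export
ellipse_bbox <- function(cx, cy, rx, ry, theta) {
  hw <- sqrt((rx * cos(theta))^2 + (ry * sin(theta))^2)
  hh <- sqrt((rx * sin(theta))^2 + (ry * cos(theta))^2)
  c(cx - hw, cy - hh, cx + hw, cy + hh)
}

# Logical mask (H x W) of pixels whose centres fall inside the ellipse.
ellipse_mask <- function(h, w, cx, cy, rx, ry, theta) {
  px <- matrix(seq_len(w) - 0.5, h, w, byrow = TRUE)
  py <- matrix(seq_len(h) - 0.5, h, w)
  u <- cos(theta) * (px - cx) + sin(theta) * (py - cy)
  v <- -sin(theta) * (px - cx) + cos(theta) * (py - cy)
  (u / rx)^2 + (v / ry)^2 <= 1
}

clip_box <- function(box, h, w) {
  c(
    max(box[1], 0), max(box[2], 0),
    min(box[3], w), min(box[4], h)
  )
}

# Integer pixel-index range (1-based rows/cols) covered by a 0-based box.
box_pixels <- function(box, h, w) {
  cols <- seq.int(max(1L, floor(box[1]) + 1L), min(w, ceiling(box[3])))
  rows <- seq.int(max(1L, floor(box[2]) + 1L), min(h, ceiling(box[4])))
  list(rows = rows, cols = cols)
}

# Aspect-preserving resize of an H x W x 3 array to size x size, padding with
# `fill` (length-3 colour).
resize_pad <- function(image, size, fill) {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  scale <- size / max(h, w)
  nh <- max(1L, round(h * scale)); nw <- max(1L, round(w * scale))
  res <- EBImage::resize(as_ebi(image), w = nw, h = nh)
  res <- aperm(EBImage::imageData(res), c(2, 1, 3))
  out <- array(rep(fill, each = size * size), dim = c(size, size, 3))
  r0 <- (size - nh) %/% 2L
  c0 <- (size - nw) %/% 2L
  out[r0 + seq_len(nh), c0 + seq_len(nw), ] <- clip01(res)
  out
}

luminance <- function(image) {
  0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
}

# Robust background colour estimate: per-channel median over a border frame.
estimate_background <- function(image, frame = 4L) {
  d <- dim(image)
  frame <- min(frame, floor(d[1] / 2), floor(d[2] / 2))
  idx_r <- c(seq_len(frame), d[1] - seq_len(frame) + 1L)
  idx_c <- c(seq_len(frame), d[2] - seq_len(frame) + 1L)
  vapply(1:3, function(ch) {
    stats::median(c(image[idx_r, , ch], image[, idx_c, ch]))
  }, numeric(1))
}

# Per-pixel max-channel absolute deviation from a background colour.
background_distance <- function(image, bg) {
  pmax(
    abs(image[, , 1] - bg[1]),
    abs(image[, , 2] - bg[2]),
    abs(image[, , 3] - bg[3])
  )
}
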