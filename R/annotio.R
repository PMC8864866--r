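# Annotation IO in a VGG-Image-Annotator-compatible JSON dialect.
#
# Layout: a top-level object keyed by filename; each record has `filename`,
# optional `width`/`height` (canvas size; used to clip derived boxes for
# border cells), and `regions`, a list of
#   { "shape_attributes":  {"name": "ellipse", "cx", "cy", "rx", "ry",
#                           "theta"},
#     "region_attributes": {"cell_type": "myeloblast|promyelocyte|other",
#                           "auer_rod": 0|1, ...} }
# Rotation is stored in radians, counter-clockwise, image coordinates.
# Region attributes beyond the ones this package writes are preserved
# verbatim on a read -> write round trip (list-column `region_extra`).

abort_format <- function(msg) rlang::abort(msg, class = "aplsmear_format_error")

KNOWN_REGION_ATTRS <- c(
  "cell_type", "auer_rod", "patient_id", "region_id", "n_auer_rods",
  "confidence"
)

#' Write cell annotations to a VIA-style JSON file
#'
#' @param annotations tibble of cell annotations (as produced by
#'   [generate_smear()] or [read_annotations()]); one or more `image_id`s.
#' @param path output path.
#' @param filename optional filename key to use when all annotations share
#'   one `image_id` (defaults to `<image_id>.png`).
#' @param canvas optional `c(width, height)` of the image canvas, stored in
#'   the file so boxes of border cells can be re-clipped on read.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, filename = NULL,
                              canvas = NULL) {
  ids <- unique(annotations$image_id)
  if (!is.null(filename) && length(ids) > 1L) {
    abort_format("explicit filename requires a single image_id")
  }
  records <- list()
  split_ids <- if (nrow(annotations)) ids else character(0)
  for (id in split_ids) {
    rows <- annotations[annotations$image_id == id, ]
    fn <- filename %||% paste0(id, ".png")
    has <- function(col) col %in% names(rows)
    regions <- purrr::map(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      ra <- list(
        cell_type = if (has("cell_type")) r$cell_type else "other",
        auer_rod = as.integer(has("has_auer_rod") && isTRUE(r$has_auer_rod)),
        patient_id = if (has("patient_id")) r$patient_id else NA_character_,
        region_id = as.integer(r$region_id)
      )
      if (has("n_auer_rods")) ra$n_auer_rods <- as.integer(r$n_auer_rods)
      if (has("confidence") && !is.na(r$confidence)) {
        ra$confidence <- r$confidence
      }
      if (has("region_extra")) {
        extra <- r$region_extra[[1]]
        if (length(extra)) ra[names(extra)] <- extra
      }
      list(
        shape_attributes = list(
          name = "ellipse", cx = r$cx, cy = r$cy, rx = r$rx, ry = r$ry,
          theta = r$theta
        ),
        region_attributes = ra
      )
    })
    rec <- list(filename = fn, regions = regions)
    if (!is.null(canvas)) {
      rec$width <- as.integer(canvas[1]); rec$height <- as.integer(canvas[2])
    }
    records[[fn]] <- rec
  }
  jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read cell annotations from a VIA-style JSON file
#'
#' Malformed regions (missing or non-numeric ellipse attributes, unknown
#' shape) are skipped with one summary warning; the skip count is attached
#' as attribute `n_skipped`. Boxes are derived as the tight box of each
#' ellipse, clipped to the stored canvas when the file records one.
#'
#' @param path path to an annotation JSON file.
#' @return Tibble of cell annotations (possibly 0 rows) with the same
#'   columns as [generate_smear()] output plus `confidence` and
#'   `region_extra` where present.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort_format(paste("no such file:", path))
  records <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) abort_format(paste("unparseable annotation file:",
      conditionMessage(e)))
  )
  out <- list()
  n_skipped <- 0L
  first_bad <- NULL
  for (rec in records) {
    fn <- rec$filename %||% "unknown"
    image_id <- sub("\\.[A-Za-z]+$", "", fn)
    canvas <- if (!is.null(rec$width)) c(rec$width, rec$height) else NULL
    for (ri in seq_along(rec$regions)) {
      reg <- rec$regions[[ri]]
      sa <- reg$shape_attributes
      ok <- !is.null(sa) && identical(sa$name, "ellipse") &&
        all(vapply(
          c("cx", "cy", "rx", "ry"),
          function(k) is.numeric(sa[[k]]) && length(sa[[k]]) == 1L, logical(1)
        ))
      if (!ok) {
        n_skipped <- n_skipped + 1L
        if (is.null(first_bad)) first_bad <- sprintf("%s region %d", fn, ri)
        next
      }
      theta <- if (is.numeric(sa$theta)) sa$theta else 0
      ra <- reg$region_attributes %||% list()
      cell_type <- as.character(ra$cell_type %||% "other")
      has_rod <- isTRUE(as.integer(ra$auer_rod %||% 0L) == 1L)
      bb <- ellipse_bbox(sa$cx, sa$cy, sa$rx, sa$ry, theta)
      if (!is.null(canvas)) bb <- clip_box(bb, canvas[2], canvas[1])
      extra <- ra[setdiff(names(ra), KNOWN_REGION_ATTRS)]
      out[[length(out) + 1L]] <- tibble::tibble(
        region_id = as.integer(ra$region_id %||% ri),
        image_id = image_id,
        patient_id = as.character(ra$patient_id %||% NA_character_),
        cx = sa$cx, cy = sa$cy, rx = sa$rx, ry = sa$ry, theta = theta,
        x_min = bb[1], y_min = bb[2], x_max = bb[3], y_max = bb[4],
        cell_type = cell_type,
        is_myeloblast = cell_type == "myeloblast",
        is_promyelocyte = cell_type == "promyelocyte",
        has_auer_rod = has_rod,
        n_auer_rods = as.integer(ra$n_auer_rods %||%
          if (has_rod) 1L else 0L),
        confidence = as.numeric(ra$confidence %||% NA_real_),
        region_extra = list(extra)
      )
    }
  }
  if (n_skipped > 0L) {
    warning(sprintf(
      "skipped %d malformed region(s); first: %s", n_skipped, first_bad
    ), call. = FALSE)
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    dplyr::mutate(empty_annotations(),
      confidence = numeric(0), region_extra = list()
    )
  attr(res, "n_skipped") <- n_skipped
  res
}
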