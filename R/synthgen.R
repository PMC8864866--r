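# Synthetic bone-marrow-smear generator. Renders Romanowsky-like elliptical
# cells (cytoplasm + eccentric nucleus + granules + optional Auer-rod line
# primitives) on a pale background with annotation-free smudge artifacts, and
# emits exact elliptical ground truth for every cell. Class-conditional
# composition mimics the three study cohorts: healthy marrow has almost no
# blasts, non-APL AML an excess of myeloblasts, APL an excess of abnormal
# promyelocytes of which a fraction carry Auer rods.

CELL_TYPES <- c("myeloblast", "promyelocyte", "auer_promyelocyte", "other")

abort_spec <- function(msg) rlang::abort(msg, class = "aplsmear_invalid_spec")
abort_data <- function(msg) rlang::abort(msg, class = "aplsmear_data_error")

#' Describe the rendered appearance of one cell type
#'
#' @param type_name one of `"myeloblast"`, `"promyelocyte"`,
#'   `"auer_promyelocyte"`, `"other"`.
#' @param radius_range length-2 min/max of the cell semi-axes in px.
#' @param granule_density granules per 100 px^2 of cell area (promyelocytes
#'   are heavily granulated, myeloblasts nearly agranular).
#' @param nucleus_fraction fraction of cell area occupied by the nucleus,
#'   in (0, 1).
#' @param auer_rod_count_range length-2 integer min/max of Auer-rod line
#'   primitives per cell; must be >= 1 exactly for `auer_promyelocyte`.
#' @param palette named list of RGB triples (`cytoplasm`, `nucleus`,
#'   `granule`, `rod`), each in `[0, 1]`.
#' @return An object of class `cell_type_spec`.
#' @export
cell_type_spec <- function(type_name, radius_range, granule_density,
                           nucleus_fraction, auer_rod_count_range = c(0L, 0L),
                           palette = NULL) {
  type_name <- match.arg(type_name, CELL_TYPES)
  if (length(radius_range) != 2L || radius_range[1] > radius_range[2] ||
      radius_range[1] <= 0) {
    abort_spec("radius_range must be positive with min <= max")
  }
  if (granule_density < 0) abort_spec("granule_density must be >= 0")
  if (nucleus_fraction <= 0 || nucleus_fraction >= 1) {
    abort_spec("nucleus_fraction must be in (0, 1)")
  }
  rods_required <- type_name == "auer_promyelocyte"
  if (rods_required && auer_rod_count_range[1] < 1) {
    abort_spec("auer_promyelocyte requires auer_rod_count_range min >= 1")
  }
  if (!rods_required && auer_rod_count_range[2] > 0) {
    abort_spec("only auer_promyelocyte may carry Auer rods")
  }
  structure(
    list(
      type_name = type_name, radius_range = as.numeric(radius_range),
      granule_density = granule_density, nucleus_fraction = nucleus_fraction,
      auer_rod_count_range = as.integer(auer_rod_count_range),
      palette = palette %||% default_palette(type_name)
    ),
    class = "cell_type_spec"
  )
}

default_palette <- function(type_name) {
  switch(type_name,
    myeloblast = list(
      cytoplasm = c(0.70, 0.75, 0.89), nucleus = c(0.34, 0.26, 0.56),
      granule = c(0.50, 0.30, 0.55), rod = c(0.55, 0.08, 0.18)
    ),
    promyelocyte = ,
    auer_promyelocyte = list(
      cytoplasm = c(0.87, 0.70, 0.78), nucleus = c(0.42, 0.30, 0.58),
      granule = c(0.55, 0.20, 0.50), rod = c(0.55, 0.08, 0.18)
    ),
    other = list(
      cytoplasm = c(0.91, 0.82, 0.84), nucleus = c(0.52, 0.44, 0.64),
      granule = c(0.60, 0.40, 0.55), rod = c(0.55, 0.08, 0.18)
    )
  )
}

#' Default renderable cell types
#'
#' Radii are tuned to the desk-scale 512 x 384 px canvas; the same specs scale
#' to the native 2560 x 1920 acquisition size by passing larger
#' `radius_range`s.
#' @return Named list of [cell_type_spec()] objects.
#' @export
default_cell_types <- function() {
  list(
    myeloblast = cell_type_spec("myeloblast", c(14, 21),
      granule_density = 0.15, nucleus_fraction = 0.72
    ),
    promyelocyte = cell_type_spec("promyelocyte", c(15, 23),
      granule_density = 6, nucleus_fraction = 0.42
    ),
    auer_promyelocyte = cell_type_spec("auer_promyelocyte", c(15, 23),
      granule_density = 6, nucleus_fraction = 0.42,
      auer_rod_count_range = c(1L, 3L)
    ),
    other = cell_type_spec("other", c(10, 16),
      granule_density = 0.5, nucleus_fraction = 0.35
    )
  )
}

#' Describe one diagnostic cohort for the generator
#'
#' `composition_dist` holds the mean cell-type fractions and a Dirichlet
#' concentration; each synthetic patient draws one composition from
#' `Dirichlet(concentration * mean)` and shares it across all of their
#' images, giving the patient-level correlation the grouped 2:1 split must
#' respect.
#'
#' @param diagnosis `"APL"`, `"AML"` or `"HEALTHY"`.
#' @param n_patients,images_per_patient cohort size.
#' @param cells_per_image_range length-2 integer min/max cells per image.
#' @param composition_dist list with `mean` (named fractions over the four
#'   cell types, summing to 1) and `concentration` (> 0; larger = less
#'   patient-to-patient variation).
#' @param overlap_prob probability that a placed cell skips the
#'   non-overlap check.
#' @param smudge_rate expected annotation-free smudge artifacts per image.
#' @param image_size `c(width, height)` px.
#' @param cell_types named list of [cell_type_spec()]s.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(diagnosis, n_patients, images_per_patient = 2L,
                        cells_per_image_range = c(20L, 30L),
                        composition_dist = NULL,
                        overlap_prob = 0.05, smudge_rate = 1,
                        image_size = c(512L, 384L),
                        cell_types = default_cell_types()) {
  diagnosis <- match.arg(diagnosis, c("APL", "AML", "HEALTHY"))
  if (any(image_size <= 0)) abort_spec("image_size must be positive")
  if (n_patients < 0) abort_spec("n_patients must be >= 0")
  if (length(cells_per_image_range) != 2L ||
      cells_per_image_range[1] > cells_per_image_range[2] ||
      cells_per_image_range[1] < 0) {
    abort_spec("cells_per_image_range must be 0 <= min <= max")
  }
  if (overlap_prob < 0 || overlap_prob > 1) {
    abort_spec("overlap_prob must be in [0, 1]")
  }
  composition_dist <- composition_dist %||% default_composition(diagnosis)
  m <- composition_dist$mean
  if (is.null(names(m)) || !setequal(names(m), CELL_TYPES)) {
    abort_spec("composition mean must be named over the four cell types")
  }
  if (abs(sum(m) - 1) > 1e-9) abort_spec("composition mean must sum to 1")
  if (composition_dist$concentration <= 0) {
    abort_spec("composition concentration must be > 0")
  }
  structure(
    list(
      diagnosis = diagnosis, n_patients = as.integer(n_patients),
      images_per_patient = as.integer(images_per_patient),
      cells_per_image_range = as.integer(cells_per_image_range),
      composition_dist = composition_dist,
      overlap_prob = overlap_prob, smudge_rate = smudge_rate,
      image_size = as.integer(image_size), cell_types = cell_types
    ),
    class = "cohort_spec"
  )
}

# Cohort compositions. The APL promyelocyte family (promyelocyte +
# auer_promyelocyte) is centred at 0.63 and the AML myeloblast fraction at
# 0.635, the two cohorts' median marrow blast percentages; healthy marrow
# keeps the blast family at 5%. Concentration 8 gives a patient-level
# fraction SD of ~0.16, matching the clinical interquartile spread.
default_composition <- function(diagnosis) {
  mean <- switch(diagnosis,
    APL = c(
      myeloblast = 0.07, promyelocyte = 0.48,
      auer_promyelocyte = 0.15, other = 0.30
    ),
    AML = c(
      myeloblast = 0.635, promyelocyte = 0.065,
      auer_promyelocyte = 0, other = 0.30
    ),
    HEALTHY = c(
      myeloblast = 0.02, promyelocyte = 0.03,
      auer_promyelocyte = 0, other = 0.95
    )
  )
  list(mean = mean, concentration = 8)
}

#' Default desk-scale cohort specifications
#' @param n_patients patients per cohort.
#' @param ... passed on to [cohort_spec()].
#' @return Named list of three [cohort_spec()]s (APL, AML, HEALTHY).
#' @export
default_cohort_specs <- function(n_patients = 17L, ...) {
  list(
    APL = cohort_spec("APL", n_patients, ...),
    AML = cohort_spec("AML", n_patients, ...),
    HEALTHY = cohort_spec("HEALTHY", n_patients, ...)
  )
}

# Dirichlet draw via normalized gammas; zero-mean components stay zero.
sample_composition <- function(dist) {
  a <- dist$concentration * dist$mean
  g <- ifelse(a > 0, stats::rgamma(length(a), shape = pmax(a, 1e-12)), 0)
  if (sum(g) == 0) g <- dist$mean
  stats::setNames(g / sum(g), names(dist$mean))
}

derive_seed <- function(seed, i, j = 0) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + i * 104729 + j * 7919) %%
    2147483647)
}

BACKGROUND_RGB <- c(0.94, 0.91, 0.93)

empty_annotations <- function() {
  tibble::tibble(
    region_id = integer(), image_id = character(), patient_id = character(),
    cx = numeric(), cy = numeric(), rx = numeric(), ry = numeric(),
    theta = numeric(), x_min = numeric(), y_min = numeric(),
    x_max = numeric(), y_max = numeric(), cell_type = character(),
    is_myeloblast = logical(), is_promyelocyte = logical(),
    has_auer_rod = logical(), n_auer_rods = integer()
  )
}

#' Render one synthetic bone-marrow-smear image with ground truth
#'
#' Identical `(spec, patient_id, seed, composition)` inputs yield
#' byte-identical images and annotations. Cells are placed so that at most
#' ~30% of a border cell's area is clipped by the canvas; ground-truth boxes
#' are the tight boxes of the ellipses, clipped to the canvas for border
#' cells (the visible extent an annotator would mark).
#'
#' @param spec a [cohort_spec()].
#' @param patient_id identifier stamped into the annotations.
#' @param seed integer seed for this image.
#' @param composition optional fixed cell-type fractions (named over the four
#'   types); by default one draw from `spec$composition_dist`.
#' @param image_id identifier stamped into the annotations.
#' @return List with `image` (H x W x 3 array) and `annotations` (tibble,
#'   one row per cell; columns include ellipse parameters, the tight
#'   bounding box, the three binary labels and `n_auer_rods`).
#' @export
generate_smear <- function(spec, patient_id = "P01", seed = 1L,
                           composition = NULL, image_id = "img_0001") {
  if (!inherits(spec, "cohort_spec")) abort_spec("spec must be a cohort_spec")
  w <- spec$image_size[1]; h <- spec$image_size[2]
  set.seed(seed)
  img <- array(rep(BACKGROUND_RGB, each = h * w), dim = c(h, w, 3))
  img <- clip01(img + stats::rnorm(h * w * 3, 0, 0.012))

  comp <- composition %||% sample_composition(spec$composition_dist)
  comp <- comp[CELL_TYPES]
  n_cells <- if (spec$cells_per_image_range[1] == spec$cells_per_image_range[2]) {
    spec$cells_per_image_range[1]
  } else {
    sample(seq(spec$cells_per_image_range[1], spec$cells_per_image_range[2]), 1L)
  }

  # smudges first so cells render on top
  n_smudge <- stats::rpois(1, spec$smudge_rate)
  for (s in seq_len(n_smudge)) img <- draw_smudge(img, h, w)

  ann <- empty_annotations()
  placed <- matrix(numeric(0), ncol = 3) # cx, cy, rmax
  for (i in seq_len(n_cells)) {
    type <- sample(CELL_TYPES, 1L, prob = comp)
    ts <- spec$cell_types[[type]]
    rx <- stats::runif(1, ts$radius_range[1], ts$radius_range[2])
    ry <- rx * stats::runif(1, 0.75, 1)
    theta <- stats::runif(1, 0, pi)
    bb0 <- ellipse_bbox(0, 0, rx, ry, theta)
    mx <- 0.42 * bb0[3]; my <- 0.42 * bb0[4] # >= 70% of area stays inside
    allow_overlap <- stats::runif(1) < spec$overlap_prob
    rmax <- max(rx, ry)
    for (attempt in 1:60) {
      cx <- stats::runif(1, mx, w - mx)
      cy <- stats::runif(1, my, h - my)
      ok <- allow_overlap || nrow(placed) == 0 ||
        all((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2 >
          (placed[, 3] + rmax)^2)
      if (ok || attempt == 60L) break
    }
    placed <- rbind(placed, c(cx, cy, rmax))
    drawn <- draw_cell(img, h, w, cx, cy, rx, ry, theta, ts)
    img <- drawn$image
    bb <- clip_box(ellipse_bbox(cx, cy, rx, ry, theta), h, w)
    ann <- dplyr::bind_rows(ann, tibble::tibble(
      region_id = i, image_id = image_id, patient_id = patient_id,
      cx = cx, cy = cy, rx = rx, ry = ry, theta = theta,
      x_min = bb[1], y_min = bb[2], x_max = bb[3], y_max = bb[4],
      cell_type = if (type == "auer_promyelocyte") "promyelocyte" else type,
      is_myeloblast = type == "myeloblast",
      is_promyelocyte = type %in% c("promyelocyte", "auer_promyelocyte"),
      has_auer_rod = drawn$n_rods >= 1L,
      n_auer_rods = drawn$n_rods
    ))
  }
  list(image = img, annotations = ann)
}

draw_cell <- function(img, h, w, cx, cy, rx, ry, theta, ts) {
  bb <- clip_box(ellipse_bbox(cx, cy, rx, ry, theta), h, w)
  px <- box_pixels(bb, h, w)
  rows <- px$rows; cols <- px$cols
  pxm <- matrix(cols - 0.5, length(rows), length(cols), byrow = TRUE)
  pym <- matrix(rows - 0.5, length(rows), length(cols))
  u <- cos(theta) * (pxm - cx) + sin(theta) * (pym - cy)
  v <- -sin(theta) * (pxm - cx) + cos(theta) * (pym - cy)
  rho2 <- (u / rx)^2 + (v / ry)^2
  inside <- rho2 <= 1

  # eccentric nucleus: same orientation, axes scaled by sqrt(area fraction)
  sc <- sqrt(ts$nucleus_fraction)
  off_ang <- stats::runif(1, 0, 2 * pi)
  off_len <- stats::runif(1, 0, 0.6 * (1 - sc))
  nu <- u - cos(off_ang) * off_len * rx
  nv <- v - sin(off_ang) * off_len * ry
  in_nuc <- (nu / (sc * rx))^2 + (nv / (sc * ry))^2 <= 1

  n_in <- sum(inside)
  if (n_in > 0) {
    for (ch in 1:3) {
      sl <- img[rows, cols, ch]
      base <- ifelse(in_nuc, ts$palette$nucleus[ch], ts$palette$cytoplasm[ch])
      sl[inside] <- clip01(base[inside] + stats::rnorm(n_in, 0, 0.02))
      img[rows, cols, ch] <- sl
    }
  }

  # granules, uniform over the cell disc
  area <- pi * rx * ry
  n_gran <- stats::rpois(1, ts$granule_density * area / 100)
  if (n_gran > 0) {
    r <- sqrt(stats::runif(n_gran)); ang <- stats::runif(n_gran, 0, 2 * pi)
    gu <- r * cos(ang) * rx * 0.92; gv <- r * sin(ang) * ry * 0.92
    gx <- cx + cos(theta) * gu - sin(theta) * gv
    gy <- cy + sin(theta) * gu + cos(theta) * gv
    img <- stamp_points(img, h, w, gx, gy, ts$palette$granule, radius = 1)
  }

  # Auer rods: thin dark-crimson needles through the cytoplasm
  n_rods <- 0L
  rr <- ts$auer_rod_count_range
  want <- if (rr[2] >= 1L) sample(seq(rr[1], rr[2]), 1L) else 0L
  for (k in seq_len(want)) {
    r <- 0.45 * sqrt(stats::runif(1)); ang <- stats::runif(1, 0, 2 * pi)
    mu <- r * cos(ang) * rx; mv <- r * sin(ang) * ry
    mxp <- cx + cos(theta) * mu - sin(theta) * mv
    myp <- cy + sin(theta) * mu + cos(theta) * mv
    phi <- stats::runif(1, 0, pi)
    half <- 0.45 * min(rx, ry)
    tt <- seq(-half, half, by = 0.35)
    lx <- mxp + cos(phi) * tt; ly <- myp + sin(phi) * tt
    keep <- in_ellipse(lx, ly, cx, cy, rx * 0.95, ry * 0.95, theta)
    if (sum(keep) >= 3) {
      img <- stamp_points(img, h, w, lx[keep], ly[keep], ts$palette$rod,
        radius = 0.8
      )
      n_rods <- n_rods + 1L
    }
  }
  list(image = img, n_rods = n_rods)
}

in_ellipse <- function(x, y, cx, cy, rx, ry, theta) {
  u <- cos(theta) * (x - cx) + sin(theta) * (y - cy)
  v <- -sin(theta) * (x - cx) + cos(theta) * (y - cy)
  (u / rx)^2 + (v / ry)^2 <= 1
}

# Paint small discs of `color` at continuous positions (x, y).
stamp_points <- function(img, h, w, x, y, color, radius = 1) {
  ir <- ceiling(radius)
  for (k in seq_along(x)) {
    cc <- floor(x[k]) + 1L; rr <- floor(y[k]) + 1L
    cols <- (cc - ir):(cc + ir); rows <- (rr - ir):(rr + ir)
    keep_c <- cols >= 1L & cols <= w; keep_r <- rows >= 1L & rows <= h
    cols <- cols[keep_c]; rows <- rows[keep_r]
    if (!length(cols) || !length(rows)) next
    dx <- matrix(cols - 0.5 - x[k], length(rows), length(cols), byrow = TRUE)
    dy <- matrix(rows - 0.5 - y[k], length(rows), length(cols))
    hit <- dx^2 + dy^2 <= radius^2
    for (ch in 1:3) {
      sl <- img[rows, cols, ch]
      sl[hit] <- color[ch]
      img[rows, cols, ch] <- sl
    }
  }
  img
}

draw_smudge <- function(img, h, w) {
  r <- stats::runif(1, 8, 18)
  cx <- stats::runif(1, r, w - r); cy <- stats::runif(1, r, h - r)
  p1 <- stats::runif(1, 0, 2 * pi); p2 <- stats::runif(1, 0, 2 * pi)
  bb <- clip_box(c(cx - 1.4 * r, cy - 1.4 * r, cx + 1.4 * r, cy + 1.4 * r), h, w)
  px <- box_pixels(bb, h, w)
  pxm <- matrix(px$cols - 0.5, length(px$rows), length(px$cols), byrow = TRUE)
  pym <- matrix(px$rows - 0.5, length(px$rows), length(px$cols))
  ang <- atan2(pym - cy, pxm - cx)
  rho <- sqrt((pxm - cx)^2 + (pym - cy)^2)
  lim <- r * (1 + 0.25 * sin(3 * ang + p1) + 0.15 * sin(7 * ang + p2))
  hit <- rho <= lim
  color <- c(0.72, 0.68, 0.74)
  n_hit <- sum(hit)
  if (n_hit > 0) {
    for (ch in 1:3) {
      sl <- img[px$rows, px$cols, ch]
      sl[hit] <- clip01(color[ch] + stats::rnorm(n_hit, 0, 0.015))
      img[px$rows, px$cols, ch] <- sl
    }
  }
  img
}

#' Generate a full multi-cohort synthetic dataset on disk
#'
#' Writes one PNG and one annotation JSON per image plus a dataset manifest
#' CSV (`image_path,annotation_path,patient_id,diagnosis`). Each patient's
#' cell-type composition is drawn once and shared across their images.
#'
#' @param specs list of [cohort_spec()]s with distinct diagnoses.
#' @param dir output directory (created if missing).
#' @param seed integer master seed; all per-patient and per-image seeds are
#'   derived from it.
#' @return The manifest as a tibble (also written to `dir/manifest.csv`),
#'   with columns `image_path`, `annotation_path`, `patient_id`, `diagnosis`,
#'   `image_id`.
#' @export
generate_cohort <- function(specs, dir, seed = 1L) {
  if (inherits(specs, "cohort_spec")) specs <- list(specs)
  diags <- vapply(specs, function(s) s$diagnosis, character(1))
  if (anyDuplicated(diags)) abort_spec("duplicate diagnosis across specs")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    for (p in seq_len(spec$n_patients)) {
      patient_id <- sprintf("%s_p%02d", spec$diagnosis, p)
      set.seed(derive_seed(seed, si * 1000L + p))
      comp <- sample_composition(spec$composition_dist)
      for (j in seq_len(spec$images_per_patient)) {
        image_id <- sprintf("%s_i%02d", patient_id, j)
        sm <- generate_smear(spec, patient_id,
          seed = derive_seed(seed, si * 1000L + p, j),
          composition = comp, image_id = image_id
        )
        image_path <- file.path(dir, paste0(image_id, ".png"))
        annotation_path <- file.path(dir, paste0(image_id, ".json"))
        write_image(sm$image, image_path)
        write_annotations(sm$annotations, annotation_path,
          filename = basename(image_path), canvas = spec$image_size
        )
        rows[[length(rows) + 1L]] <- tibble::tibble(
          image_path = image_path, annotation_path = annotation_path,
          patient_id = patient_id, diagnosis = spec$diagnosis,
          image_id = image_id
        )
      }
    }
  }
  manifest <- if (length(rows)) {
    dplyr::bind_rows(rows)
  } else {
    tibble::tibble(
      image_path = character(), annotation_path = character(),
      patient_id = character(), diagnosis = character(),
      image_id = character()
    )
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
    row.names = FALSE
  )
  manifest
}

#' Read a dataset manifest CSV
#' @param path path to a manifest written by [generate_cohort()].
#' @return Tibble with one row per image.
#' @export
read_manifest <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
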