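test_that("scorer training reduces the logged loss and is reproducible", {
  det <- fx_detector()
  expect_true(det$trained)
  expect_lt(tail(det$loss_history, 1), det$loss_history[1])
  # same data, same seed: identical final loss
  sm <- fx_smears()
  ids <- fx_train_ids()
  det2 <- train_detector(
    sm$images[ids], sm$annotations[sm$annotations$image_id %in% ids, ],
    detector_config(seed = 11L)
  )
  expect_equal(tail(det2$loss_history, 1), tail(det$loss_history, 1),
    tolerance = 1e-6
  )
  d1 <- detect_cells(det, sm$images[[fx_test_ids()[1]]])
  d2 <- detect_cells(det2, sm$images[[fx_test_ids()[1]]])
  expect_identical(d1$confidence, d2$confidence)
})

test_that("zero-epoch training returns an untrained, flagged model", {
  sm <- fx_smears()
  ids <- fx_train_ids()[1:2]
  det0 <- train_detector(
    sm$images[ids], sm$annotations[sm$annotations$image_id %in% ids, ],
    detector_config(epochs = 0L)
  )
  expect_false(det0$trained)
  expect_length(det0$loss_history, 0)
  expect_error(detect_cells(det0, sm$images[[1]]),
    class = "aplsmear_state_error"
  )
  expect_error(train_detector(list(), fx_smears()$annotations),
    class = "aplsmear_data_error"
  )
})

test_that("detections are thresholded, suppressed, clipped and sorted", {
  sm <- fx_smears()
  det <- fx_detector()
  img <- sm$images[[fx_test_ids()[1]]]
  expect_equal(nrow(detect_cells(det, img, score_threshold = 1)), 0L)
  d <- detect_cells(det, img)
  n_gt <- sum(sm$annotations$image_id == fx_test_ids()[1])
  expect_gte(nrow(d), ceiling(0.8 * n_gt))
  expect_lte(nrow(d), floor(1.2 * n_gt))
  expect_true(all(diff(d$confidence) <= 0))
  expect_true(all(d$x_min >= 0 & d$y_min >= 0))
  expect_true(all(d$x_max <= dim(img)[2] & d$y_max <= dim(img)[1]))
  expect_true(all(d$confidence >= 0 & d$confidence <= 1))
})

test_that("NMS keeps the higher-confidence duplicate and is idempotent", {
  dup <- tibble::tibble(
    region_id = 1:2,
    x_min = 0, y_min = 0, x_max = 10, y_max = 10,
    confidence = c(0.9, 0.8)
  )
  kept <- nms_regions(dup, 0.5)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$confidence, 0.9)

  set.seed(21)
  rand <- tibble::tibble(
    region_id = 1:30,
    x_min = runif(30, 0, 80), y_min = runif(30, 0, 80)
  )
  rand$x_max <- rand$x_min + runif(30, 5, 25)
  rand$y_max <- rand$y_min + runif(30, 5, 25)
  rand$confidence <- runif(30)
  once <- nms_regions(rand, 0.4)
  twice <- nms_regions(once, 0.4)
  expect_identical(once, twice)
})

test_that("ellipse refinement recovers the true cell ellipse", {
  # one clean synthetic cell with exact elliptical ground truth
  spec <- cohort_spec("AML", 1,
    cells_per_image_range = c(1L, 1L),
    smudge_rate = 0, image_size = c(128L, 96L)
  )
  sm <- generate_smear(spec, "P1", seed = 31)
  gt <- sm$annotations[1, ]
  # start from a deliberately sloppy box around the cell
  rough <- tibble::tibble(
    region_id = 1L,
    x_min = gt$x_min - 4, y_min = gt$y_min - 3,
    x_max = gt$x_max + 5, y_max = gt$y_max + 2,
    cx = gt$cx + 2, cy = gt$cy - 2, rx = gt$rx * 0.8, ry = gt$ry * 1.2,
    theta = 0, confidence = 0.9, source = "proposed"
  )
  ref <- refine_ellipse(sm$image, rough)
  expect_equal(ref$source, "refined")
  expect_gte(mask_iou(96, 128, as.list(gt), as.list(ref)), 0.9)
  # containment in the 1.25x expanded input box
  hw <- (rough$x_max - rough$x_min) / 2 * 1.25
  hh <- (rough$y_max - rough$y_min) / 2 * 1.25
  bcx <- (rough$x_min + rough$x_max) / 2
  bcy <- (rough$y_min + rough$y_max) / 2
  expect_gte(ref$x_min, bcx - hw - 1e-9)
  expect_lte(ref$x_max, bcx + hw + 1e-9)
  expect_gte(ref$y_min, bcy - hh - 1e-9)
  expect_lte(ref$y_max, bcy + hh + 1e-9)

  # a region over uniform background is returned unchanged
  flat <- array(rep(c(0.94, 0.91, 0.93), each = 96 * 128),
    dim = c(96, 128, 3)
  )
  out <- refine_ellipse(flat, rough)
  expect_equal(out$source, "proposed")
  expect_equal(out$cx, rough$cx)
})

test_that("crops are fixed-size, aspect-padded and count-preserving", {
  sm <- fx_smears()
  img <- sm$images[[1]]
  ann <- sm$annotations[sm$annotations$image_id == "img_01", ]
  crops <- crop_cells(img, ann) # native default
  expect_length(crops, nrow(ann))
  expect_true(all(vapply(crops, function(c) all(dim(c) == c(299, 299, 3)),
    logical(1)
  )))
  # a region hanging over the image corner still yields a full padded crop
  corner <- tibble::tibble(
    x_min = -10, y_min = -8, x_max = 30, y_max = 25
  )
  cc <- crop_cells(img, corner, 64L)
  expect_equal(dim(cc[[1]]), c(64, 64, 3))
  expect_true(all(is.finite(cc[[1]])))
  expect_length(crop_cells(img, ann[0, ], 64L), 0)
})

test_that("human-in-the-loop rounds correct annotations and hold mAP", {
  sm <- fx_smears()
  ids <- fx_train_ids()[1:4]
  imgs <- sm$images[ids]
  gt <- sm$annotations[sm$annotations$image_id %in% ids, ]
  val_ids <- fx_test_ids()
  cfg <- detector_config(seed = 17L, epochs = 25L)

  # round zero: untrained proposals -> corrected set is exactly ground truth
  untrained <- structure(list(trained = FALSE), class = "cell_detector")
  r1 <- hitl_round(untrained, imgs, gt, cfg)
  expect_equal(nrow(r1$annotations), nrow(gt))
  expect_true(all(r1$annotations$source == "corrected"))
  expect_equal(sort(r1$annotations$cx), sort(gt$cx))

  map_of <- function(model) {
    dets <- purrr::map_dfr(val_ids, function(id) {
      d <- detect_cells(model, sm$images[[id]])
      if (nrow(d)) d$image_id <- id
      d
    })
    mean_ap_ar(dets, sm$annotations[sm$annotations$image_id %in% val_ids, ],
      0.5
    )$map
  }
  maps <- numeric(3)
  maps[1] <- map_of(r1$model)
  r2 <- hitl_round(r1$model, imgs, gt, cfg)
  maps[2] <- map_of(r2$model)
  r3 <- hitl_round(r2$model, imgs, gt, cfg)
  maps[3] <- map_of(r3$model)
  expect_true(all(diff(maps) >= -0.02)) # monotone up to noise

  # degenerate acceptance threshold keeps proposals verbatim
  r0 <- hitl_round(r1$model, imgs, gt, cfg, iou_accept = 0)
  n_props <- sum(purrr::map_int(ids, function(id) {
    nrow(detect_cells(r1$model, sm$images[[id]]))
  }))
  expect_equal(sum(r0$annotations$source == "proposed"), n_props)

  expect_error(hitl_round(untrained, list(), gt, cfg),
    class = "aplsmear_data_error"
  )
})

test_that("detector checkpoints round-trip and detections export to JSON", {
  det <- fx_detector()
  sm <- fx_smears()
  path <- withr::local_tempfile(fileext = ".rds")
  save_detector(det, path)
  back <- load_detector(path)
  img <- sm$images[[fx_test_ids()[2]]]
  expect_identical(detect_cells(back, img), detect_cells(det, img))

  d <- detect_cells(det, img)
  jp <- withr::local_tempfile(fileext = ".json")
  write_detections(d, "img_08", jp, canvas = c(384L, 288L))
  ann <- read_annotations(jp)
  expect_equal(nrow(ann), nrow(d))
  expect_equal(sort(ann$confidence), sort(d$confidence), tolerance = 1e-9)
})
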