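test_that("the multi-label encoding follows the cell-type semantics", {
  ann <- tibble::tibble(
    is_myeloblast = c(FALSE, TRUE, FALSE),
    is_promyelocyte = c(TRUE, FALSE, FALSE),
    has_auer_rod = c(TRUE, FALSE, FALSE)
  )
  enc <- encode_label(ann)
  # a promyelocyte with a single Auer rod: myeloblast 0, promyelocyte 1,
  # Auer rod 1
  expect_equal(unlist(enc[1, ]), c(
    is_myeloblast = 0L, is_promyelocyte = 1L, has_auer_rod = 1L
  ))
  expect_equal(unlist(enc[2, ]), c(
    is_myeloblast = 1L, is_promyelocyte = 0L, has_auer_rod = 0L
  ))
  expect_equal(unlist(enc[3, ]), c(
    is_myeloblast = 0L, is_promyelocyte = 0L, has_auer_rod = 0L
  ))
})

test_that("head configuration bounds are enforced", {
  expect_error(head_config(n_fc_layers = 4), class = "aplsmear_invalid_param")
  expect_error(head_config(n_fc_layers = 0), class = "aplsmear_invalid_param")
  expect_error(head_config(dropout = 1), class = "aplsmear_invalid_param")
  expect_s3_class(head_config(n_fc_layers = 3, dropout = 0.46), "head_config")
})

test_that("morphometrics match geometric oracles", {
  # filled axis-aligned ellipse, semi-axes 10 and 8
  mask <- aplsmear:::ellipse_mask(40, 48, 24, 20, 10, 8, 0)
  crop <- array(0.5, dim = c(40, 48, 3))
  m <- morphometrics(crop, mask)
  expect_equal(m$size_px2, pi * 10 * 8, tolerance = 0.02)
  expect_equal(m$contrast, 0) # constant luminance

  # doubling both semi-axes multiplies the volume proxy by 8
  mask2 <- aplsmear:::ellipse_mask(120, 140, 70, 60, 20, 16, 0)
  m2 <- morphometrics(array(0.5, dim = c(120, 140, 3)), mask2)
  expect_equal(m2$volume_proxy / m$volume_proxy, 8, tolerance = 0.05)
})

test_that("classifiers separate synthetic cell types on held-out crops", {
  cr <- fx_crops()
  models <- fx_cell_models()
  for (task in c("is_myeloblast", "is_promyelocyte", "has_auer_rod")) {
    y <- cr$test$labels[[task]]
    if (length(unique(y)) < 2) next
    model <- switch(task,
      is_myeloblast = models$myeloblast,
      is_promyelocyte = models$promyelocyte,
      has_auer_rod = models$auer_rod
    )
    p <- predict_cell_probs(model, cr$test$crops)
    expect_gte(roc_auc(p, y), 0.95)
  }
  # separation check on the mean scores
  p_promy <- predict_cell_probs(models$promyelocyte, cr$test$crops)
  y <- cr$test$labels$is_promyelocyte == 1
  expect_gt(mean(p_promy[y]), mean(p_promy[!y]))
})

test_that("untrained heads score at chance level", {
  cr <- fx_crops()
  y <- cr$test$labels$is_promyelocyte
  aucs <- vapply(1:10, function(s) {
    m <- train_cell_cnn(
      cr$train$crops[1:40], cr$train$labels$is_promyelocyte[1:40],
      head_config(epochs = 0L, seed = s)
    )
    roc_auc(predict_cell_probs(m, cr$test$crops), y)
  }, numeric(1))
  expect_gte(mean(aucs), 0.3)
  expect_lte(mean(aucs), 0.7)
})

test_that("training inputs are validated", {
  cr <- fx_crops()
  expect_error(
    train_cell_cnn(cr$train$crops[1:5], rep(TRUE, 5)),
    class = "aplsmear_data_error"
  )
  models <- fx_cell_models()
  small <- list(array(0.5, dim = c(32, 32, 3)))
  expect_error(predict_cell_probs(models$myeloblast, small),
    class = "aplsmear_shape_error"
  )
})

test_that("predictions are bounded and classifiers are task-isolated", {
  cr <- fx_crops()
  models <- fx_cell_models()
  preds <- predict_cells(models, cr$test$crops)
  expect_equal(nrow(preds), length(cr$test$crops))
  for (col in c("p_myeloblast", "p_promyelocyte", "p_auer_rod")) {
    expect_true(all(preds[[col]] >= 0 & preds[[col]] <= 1))
  }
  expect_true(all(preds$size_px2 >= 0))
  expect_true(all(preds$contrast >= 0))
  expect_true(all(is.finite(preds$volume_proxy)))

  # retraining the Auer-rod model must not move myeloblast predictions
  alt <- models
  alt$auer_rod <- train_cell_cnn(
    cr$train$crops, cr$train$labels$has_auer_rod,
    head_config(epochs = 30L, seed = 123L), "auer_rod"
  )
  preds2 <- predict_cells(alt, cr$test$crops)
  expect_identical(preds$p_myeloblast, preds2$p_myeloblast)
  expect_identical(preds$p_promyelocyte, preds2$p_promyelocyte)

  expect_equal(nrow(predict_cells(models, list())), 0L)
})

test_that("crop datasets round-trip through the CSV store", {
  cr <- fx_crops()
  sm <- fx_smears()
  ann <- sm$annotations[sm$annotations$image_id == "img_01", ]
  crops <- crop_cells(sm$images[[1]], ann, 64L)
  dir <- withr::local_tempdir()
  table <- write_crop_dataset(crops, ann, dir)
  expect_true(all(file.exists(table$crop_path)))
  stored <- utils::read.csv(file.path(dir, "labels.csv"))
  expect_equal(nrow(stored), length(crops))
  expect_equal(stored$is_promyelocyte, as.integer(ann$is_promyelocyte))
  back <- read_image(table$crop_path[1])
  expect_equal(dim(back), c(64, 64, 3))
})
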