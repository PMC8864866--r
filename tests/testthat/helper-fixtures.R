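# Shared fixtures, built once per test run (lazily) and reused across
# files. All synthetic data are generated in code under fixed seeds.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

# Balanced-ish composition with all four cell types, fixed per patient
# (huge concentration), convenient for classifier training fixtures.
fx_mixed_spec <- function() {
  cohort_spec("APL",
    n_patients = 2L,
    cells_per_image_range = c(18L, 24L),
    composition_dist = list(
      mean = c(
        myeloblast = 0.25, promyelocyte = 0.30,
        auer_promyelocyte = 0.20, other = 0.25
      ),
      concentration = 1e6
    ),
    overlap_prob = 0, smudge_rate = 1,
    image_size = c(384L, 288L)
  )
}

# Eight clean smears with mixed composition; first six train, last two test.
fx_smears <- function() {
  fixture("smears", {
    spec <- fx_mixed_spec()
    sms <- lapply(1:8, function(i) {
      generate_smear(spec, sprintf("P%02d", i),
        seed = 4200L + i,
        image_id = sprintf("img_%02d", i)
      )
    })
    list(
      spec = spec,
      images = stats::setNames(
        lapply(sms, `[[`, "image"), sprintf("img_%02d", 1:8)
      ),
      annotations = do.call(rbind, lapply(sms, `[[`, "annotations"))
    )
  })
}

fx_train_ids <- function() sprintf("img_%02d", 1:6)
fx_test_ids <- function() sprintf("img_%02d", 7:8)

fx_detector <- function() {
  fixture("detector", {
    sm <- fx_smears()
    ids <- fx_train_ids()
    train_detector(
      sm$images[ids],
      sm$annotations[sm$annotations$image_id %in% ids, ],
      detector_config(seed = 11L)
    )
  })
}

# Ground-truth 64 px crops with multi-label encodings, split train/test.
fx_crops <- function() {
  fixture("crops", {
    sm <- fx_smears()
    per_set <- function(ids) {
      crops <- list()
      labels <- list()
      for (id in ids) {
        ann <- sm$annotations[sm$annotations$image_id == id, ]
        crops <- c(crops, crop_cells(sm$images[[id]], ann, 64L))
        labels[[id]] <- encode_label(ann)
      }
      list(crops = crops, labels = do.call(rbind, labels))
    }
    list(train = per_set(fx_train_ids()), test = per_set(fx_test_ids()))
  })
}

fx_cell_models <- function() {
  fixture("cell_models", {
    cr <- fx_crops()
    cfg <- head_config(epochs = 120L, seed = 3L)
    list(
      myeloblast = train_cell_cnn(
        cr$train$crops, cr$train$labels$is_myeloblast, cfg, "myeloblast"
      ),
      promyelocyte = train_cell_cnn(
        cr$train$crops, cr$train$labels$is_promyelocyte, cfg, "promyelocyte"
      ),
      auer_rod = train_cell_cnn(
        cr$train$crops, cr$train$labels$has_auer_rod, cfg, "auer_rod"
      )
    )
  })
}

# ENN trained on generator-like ratio features for the APL-vs-healthy task.
fx_enn <- function() {
  fixture("enn", {
    set.seed(99)
    n <- 40L
    apl <- tibble::tibble(
      ratio_myeloblast = stats::rbinom(n, 25, 0.07) / 25,
      ratio_promyelocyte = stats::rbinom(n, 25, 0.63) / 25,
      ratio_auer_rod = stats::rbinom(n, 25, 0.15) / 25,
      n_cells = 25L
    )
    healthy <- tibble::tibble(
      ratio_myeloblast = stats::rbinom(n, 25, 0.02) / 25,
      ratio_promyelocyte = stats::rbinom(n, 25, 0.03) / 25,
      ratio_auer_rod = 0,
      n_cells = 25L
    )
    train_enn(rbind(apl, healthy), rep(c(TRUE, FALSE), each = n),
      task = "APL_vs_HEALTHY", seed = 1L, epochs = 300L
    )
  })
}

# Pixel-mask IoU of two ellipses on a shared canvas (oracle for refinement).
mask_iou <- function(h, w, e1, e2) {
  m1 <- aplsmear:::ellipse_mask(h, w, e1$cx, e1$cy, e1$rx, e1$ry, e1$theta)
  m2 <- aplsmear:::ellipse_mask(h, w, e2$cx, e2$cy, e2$rx, e2$ry, e2$theta)
  sum(m1 & m2) / sum(m1 | m2)
}
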