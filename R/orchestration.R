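# Pipeline orchestration: configuration, seeded hyperparameter search and
# the end-to-end workflow (synthesize/load -> detector [-> HITL rounds] ->
# crops -> cell classifiers -> smear features -> ensemble net ->
# patient-level threefold cross-validated evaluation).

#' Seeded hyperparameter optimization
#'
#' Random search (default) over a named space; an exhaustive mode
#' enumerates finite grids. Every trial's configuration and score are
#' logged; the argmax over evaluated configurations is returned.
#'
#' @param objective function `config (named list) -> numeric score`
#'   (maximized).
#' @param space named list; each element is either a vector of choices or
#'   `list(min =, max =)` for a continuous parameter (random mode only).
#' @param n_trials number of evaluations in random mode (>= 1).
#' @param seed integer seed.
#' @param mode `"random"` or `"exhaustive"`.
#' @return List with `best_config`, `best_score` and `trials` (one row per
#'   evaluation, in order).
#' @export
hpo <- function(objective, space, n_trials = 10L, seed = 1L,
                mode = c("random", "exhaustive")) {
  mode <- match.arg(mode)
  if (length(space) == 0) abort_param("empty hyperparameter space")
  if (mode == "exhaustive") {
    if (any(vapply(space, is.list, logical(1)))) {
      abort_param("exhaustive mode requires finite choice sets")
    }
    grid <- expand.grid(space, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    configs <- purrr::map(
      seq_len(nrow(grid)),
      function(i) as.list(grid[i, , drop = FALSE])
    )
  } else {
    if (n_trials < 1) abort_param("n_trials must be >= 1")
    set.seed(seed)
    configs <- purrr::map(seq_len(n_trials), function(i) {
      purrr::map(space, function(par) {
        if (is.list(par)) {
          stats::runif(1, par$min, par$max)
        } else {
          par[[sample.int(length(par), 1L)]]
        }
      })
    })
  }
  scores <- vapply(configs, function(cfg) objective(cfg), numeric(1))
  trials <- dplyr::bind_cols(
    tibble::tibble(trial = seq_along(configs)),
    purrr::map_dfr(configs, tibble::as_tibble),
    tibble::tibble(score = scores)
  )
  best <- which.max(scores)
  list(
    best_config = configs[[best]], best_score = scores[best],
    trials = trials
  )
}

#' Pipeline configuration
#'
#' @param task `"APL_vs_HEALTHY"` or `"APL_vs_AML"`.
#' @param seed master seed; all stage seeds derive from it.
#' @param n_patients patients per cohort arm.
#' @param images_per_patient images per patient.
#' @param dir working directory for generated data (a temp dir by default).
#' @param detector a [detector_config()]; its `crop_size` is overridden by
#'   `crop_size` below.
#' @param crop_size per-cell crop side length (desk scale 64; native 299).
#' @param heads named list of three [head_config()]s (`myeloblast`,
#'   `promyelocyte`, `auer_rod`). The default applies the tuned pooling
#'   dropout of the APL-vs-healthy task (0.32); [pipeline_config()] swaps in
#'   0.46 for APL-vs-AML.
#' @param enn list of ensemble-net settings (`epochs`, `lr`, `hpo_trials`).
#' @param k cross-validation folds.
#' @param call_threshold per-cell decision threshold.
#' @param hitl_rounds human-in-the-loop refinement rounds for the detector
#'   (0 = plain training on the ground truth).
#' @param detection_metrics also compute detection mAP/mAR per fold.
#' @param include_morphometrics feed morphometric means to the ensemble net
#'   (off by default; ratios are the canonical inputs).
#' @param cohort_args extra arguments passed to [cohort_spec()].
#' @param log_file optional path for the line-oriented run log.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(task = "APL_vs_HEALTHY", seed = 7L,
                            n_patients = 17L, images_per_patient = 2L,
                            dir = NULL,
                            detector = detector_config(crop_size = 64L),
                            crop_size = 64L,
                            heads = NULL,
                            enn = list(epochs = 400L, lr = 0.2,
                              hpo_trials = 5L),
                            k = 3L, call_threshold = 0.5,
                            hitl_rounds = 0L, detection_metrics = FALSE,
                            include_morphometrics = FALSE,
                            cohort_args = list(), log_file = NULL) {
  task <- match.arg(task, TASKS)
  dropout <- if (task == "APL_vs_HEALTHY") 0.32 else 0.46
  heads <- heads %||% list(
    myeloblast = head_config(dropout = dropout),
    promyelocyte = head_config(dropout = dropout),
    auer_rod = head_config(dropout = dropout)
  )
  structure(
    list(
      task = task, seed = as.integer(seed),
      n_patients = as.integer(n_patients),
      images_per_patient = as.integer(images_per_patient),
      dir = dir, detector = detector, crop_size = as.integer(crop_size),
      heads = heads, enn = enn, k = as.integer(k),
      call_threshold = call_threshold,
      hitl_rounds = as.integer(hitl_rounds),
      detection_metrics = detection_metrics,
      include_morphometrics = include_morphometrics,
      cohort_args = cohort_args, log_file = log_file
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys mirror [pipeline_config()] arguments, with
#'   `detector` and `heads` sub-maps passed to their constructors.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$detector)) y$detector <- do.call(detector_config, y$detector)
  if (!is.null(y$heads)) {
    y$heads <- purrr::map(y$heads, function(h) do.call(head_config, h))
  }
  do.call(pipeline_config, y)
}

log_line <- function(msg, file = NULL) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), msg)
  message(line)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE)
  invisible(line)
}

with_stage <- function(stage, expr, log_file = NULL) {
  log_line(paste("stage:", stage), log_file)
  tryCatch(expr, error = function(e) {
    rlang::abort(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = "aplsmear_stage_error", parent = e
    )
  })
}

load_dataset <- function(manifest) {
  images <- purrr::map(manifest$image_path, read_image)
  names(images) <- manifest$image_id
  annotations <- purrr::map_dfr(manifest$annotation_path, read_annotations)
  annotations <- dplyr::left_join(
    annotations,
    manifest[, c("image_id", "diagnosis")],
    by = "image_id"
  )
  list(images = images, annotations = annotations)
}

#' Run the full workflow for one binary task
#'
#' Generates (or loads) the cohort, assigns patient-level folds, and per
#' fold trains the detector (optionally through human-in-the-loop rounds),
#' the three cell classifiers and the ensemble net on the training
#' patients, then scores every test-fold image end to end. Fold ROC/PR
#' AUCs are macro-averaged. Reruns with the same configuration and seed
#' reproduce the report (single-threaded, all stage seeds derived from the
#' master seed).
#'
#' @param config a [pipeline_config()].
#' @param manifest optional pre-built dataset manifest (as from
#'   [generate_cohort()]); by default a synthetic cohort for the task's two
#'   arms is generated under `config$dir`.
#' @return List with `report` (an [eval_report()]), `predictions`
#'   (per-test-image tibble), `folds`, `models` (last fold's models),
#'   `manifest`, `config_hash` and `seed`.
#' @export
run_pipeline <- function(config = pipeline_config(), manifest = NULL) {
  lf <- config$log_file
  seed <- config$seed
  dir <- config$dir %||% file.path(tempdir(), paste0("aplsmear_", config$task))
  if (is.null(manifest)) {
    manifest <- with_stage("synthesize", {
      arms <- if (config$task == "APL_vs_HEALTHY") {
        c("APL", "HEALTHY")
      } else {
        c("APL", "AML")
      }
      specs <- purrr::map(arms, function(d) {
        do.call(cohort_spec, c(
          list(
            diagnosis = d, n_patients = config$n_patients,
            images_per_patient = config$images_per_patient
          ),
          config$cohort_args
        ))
      })
      generate_cohort(specs, dir, seed = seed)
    }, lf)
  }
  data <- with_stage("load", load_dataset(manifest), lf)
  folds <- with_stage(
    "folds", patient_folds(manifest, k = config$k, seed = seed), lf
  )
  apl_label <- function(diag) diag == "APL"

  fold_rows <- list()
  predictions <- list()
  det_metrics <- list()
  models <- NULL
  for (f in sort(unique(folds$fold))) {
    fseed <- derive_seed(seed, f)
    train_pats <- folds$patient_id[folds$fold != f]
    test_pats <- folds$patient_id[folds$fold == f]
    train_man <- manifest[manifest$patient_id %in% train_pats, ]
    test_man <- manifest[manifest$patient_id %in% test_pats, ]
    train_imgs <- data$images[train_man$image_id]
    train_ann <- data$annotations[
      data$annotations$image_id %in% train_man$image_id,
    ]

    detector <- with_stage(sprintf("detector (fold %d)", f), {
      dcfg <- config$detector
      dcfg$seed <- fseed
      dcfg$crop_size <- config$crop_size
      if (config$hitl_rounds > 0L) {
        mdl <- structure(list(trained = FALSE), class = "cell_detector")
        for (r in seq_len(config$hitl_rounds)) {
          mdl <- hitl_round(mdl, train_imgs, train_ann, dcfg)$model
        }
        mdl
      } else {
        train_detector(train_imgs, train_ann, dcfg)
      }
    }, lf)

    cell_models <- with_stage(sprintf("cell classifiers (fold %d)", f), {
      crops <- list(); labels <- list()
      for (id in names(train_imgs)) {
        ann <- train_ann[train_ann$image_id == id, ]
        if (!nrow(ann)) next
        crops <- c(crops, crop_cells(train_imgs[[id]], ann, config$crop_size))
        labels[[id]] <- encode_label(ann)
      }
      labels <- dplyr::bind_rows(labels)
      train_task <- function(targets, cfg, task) {
        if (length(unique(targets)) < 2L) {
          # a label class entirely absent in this training fold
          return(constant_cell_model(mean(targets), config$crop_size, task))
        }
        cfg$seed <- derive_seed(fseed, match(task, c(
          "myeloblast", "promyelocyte", "auer_rod"
        )))
        train_cell_cnn(crops, targets, cfg, task = task)
      }
      list(
        myeloblast = train_task(
          labels$is_myeloblast, config$heads$myeloblast, "myeloblast"
        ),
        promyelocyte = train_task(
          labels$is_promyelocyte, config$heads$promyelocyte, "promyelocyte"
        ),
        auer_rod = train_task(
          labels$has_auer_rod, config$heads$auer_rod, "auer_rod"
        )
      )
    }, lf)

    smear_of <- function(image) {
      regions <- detect_cells(detector, image)
      if (nrow(regions) == 0) return(NULL)
      crops <- crop_cells(image, regions, config$crop_size)
      preds <- predict_cells(cell_models, crops)
      smear_features(preds, config$call_threshold,
        include_morphometrics = config$include_morphometrics
      )
    }

    enn <- with_stage(sprintf("ensemble net (fold %d)", f), {
      feats <- purrr::map(train_man$image_id, function(id) {
        sf <- smear_of(data$images[[id]])
        if (is.null(sf)) return(NULL)
        sf$patient_id <- train_man$patient_id[train_man$image_id == id]
        sf$diagnosis <- train_man$diagnosis[train_man$image_id == id]
        sf
      })
      feats <- dplyr::bind_rows(feats)
      train_enn(feats, apl_label(feats$diagnosis),
        task = config$task, seed = fseed,
        epochs = config$enn$epochs %||% 400L, lr = config$enn$lr %||% 0.2,
        hpo_trials = config$enn$hpo_trials %||% 0L
      )
    }, lf)

    fold_pred <- with_stage(sprintf("evaluate (fold %d)", f), {
      purrr::map_dfr(seq_len(nrow(test_man)), function(i) {
        row <- test_man[i, ]
        out <- classify_smear(enn, detector, cell_models,
          data$images[[row$image_id]],
          crop_size = config$crop_size,
          call_threshold = config$call_threshold
        )
        out$image_id <- row$image_id
        out$patient_id <- row$patient_id
        out$diagnosis <- row$diagnosis
        out$fold <- f
        out
      })
    }, lf)
    predictions[[f]] <- fold_pred

    ok <- !fold_pred$unanalyzable
    scores <- fold_pred$p_apl[ok]
    labels <- apl_label(fold_pred$diagnosis[ok])
    fold_rows[[f]] <- dplyr::bind_cols(
      tibble::tibble(
        fold = f,
        roc_auc = roc_auc(scores, labels),
        pr_auc = pr_auc(scores, labels)
      ),
      classification_metrics(scores, labels, 0.5)
    )

    if (config$detection_metrics) {
      det_metrics[[f]] <- with_stage(sprintf("detection metrics (fold %d)", f), {
        dets <- purrr::map_dfr(test_man$image_id, function(id) {
          d <- refine_regions(data$images[[id]], detect_cells(
            detector, data$images[[id]]
          ))
          if (nrow(d)) d$image_id <- id
          d
        })
        gt <- data$annotations[
          data$annotations$image_id %in% test_man$image_id,
        ]
        at50 <- mean_ap_ar(dets, gt, 0.5)
        sw <- mean_ap_ar(dets, gt, iou_sweep())
        tibble::tibble(
          fold = f, map_at_50 = at50$map, mar_at_50 = at50$mar,
          map_50_95 = sw$map, mar_50_95 = sw$mar
        )
      }, lf)
    }
    models <- list(detector = detector, cell_models = cell_models, enn = enn)
  }

  fold_metrics <- dplyr::bind_rows(fold_rows)
  detection <- if (length(det_metrics)) {
    dm <- dplyr::bind_rows(det_metrics)
    list(
      at_50 = list(map = mean(dm$map_at_50), mar = mean(dm$mar_at_50)),
      sweep = list(map = mean(dm$map_50_95), mar = mean(dm$mar_50_95))
    )
  } else NULL
  report <- eval_report(fold_metrics,
    detection = detection, folds = folds,
    task = config$task
  )
  log_line(sprintf(
    "done: macro ROC AUC %.4f, macro PR AUC %.4f",
    report$macro_roc_auc$mean, report$macro_pr_auc$mean
  ), lf)
  list(
    report = report,
    predictions = dplyr::bind_rows(predictions),
    folds = folds, models = models, manifest = manifest,
    # hash of the scientific configuration (paths excluded)
    config_hash = rlang::hash(
      config[setdiff(names(config), c("dir", "log_file"))]
    ),
    seed = seed
  )
}

#' Export pipeline predictions as CSV
#' @param predictions the `predictions` tibble of [run_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE)
  invisible(path)
}
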