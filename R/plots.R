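# ggplot2 displays for smears, detections and evaluation reports.

#' Plot a smear image with optional region overlays
#'
#' @param image `H x W x 3` array.
#' @param regions optional tibble of annotations or detections; ellipse
#'   outlines are drawn over the raster.
#' @param n_ellipse_points polyline resolution per ellipse.
#' @return A ggplot object.
#' @export
plot_smear <- function(image, regions = NULL, n_ellipse_points = 60L) {
  d <- dim(image)
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(
      grDevices::as.raster(clip01(image)),
      xmin = 0, xmax = d[2], ymin = -d[1], ymax = 0
    ) +
    ggplot2::coord_equal(xlim = c(0, d[2]), ylim = c(-d[1], 0),
      expand = FALSE
    ) +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::scale_y_continuous(labels = function(v) -v)
  if (!is.null(regions) && nrow(regions)) {
    tt <- seq(0, 2 * pi, length.out = n_ellipse_points)
    outlines <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
      r <- regions[i, ]
      tibble::tibble(
        id = i,
        x = r$cx + cos(r$theta) * r$rx * cos(tt) -
          sin(r$theta) * r$ry * sin(tt),
        y = -(r$cy + sin(r$theta) * r$rx * cos(tt) +
          cos(r$theta) * r$ry * sin(tt))
      )
    })
    p <- p + ggplot2::geom_path(
      data = outlines,
      ggplot2::aes(.data$x, .data$y, group = .data$id),
      colour = "yellow", linewidth = 0.4
    )
  }
  p
}

#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$fold_metrics,
    cols = c("roc_auc", "pr_auc"),
    names_to = "metric", values_to = "auc"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    factor(.data$fold), .data$auc,
    fill = .data$metric
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(
      yintercept = object$macro_roc_auc$mean, linetype = 2
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "fold", y = "AUC",
      title = sprintf("%s: macro ROC AUC %.3f, macro PR AUC %.3f",
        object$task, object$macro_roc_auc$mean, object$macro_pr_auc$mean
      )
    )
}

#' Plot ROC or PR curves for fold predictions
#' @param predictions tibble with `p_apl`, `diagnosis`, `fold`.
#' @param type `"roc"` or `"pr"`.
#' @return A ggplot object.
#' @export
plot_cv_curves <- function(predictions, type = c("roc", "pr")) {
  type <- match.arg(type)
  ok <- !predictions$unanalyzable
  df <- purrr::map_dfr(
    split(predictions[ok, ], predictions$fold[ok]),
    function(fp) {
      lab <- fp$diagnosis == "APL"
      cur <- if (type == "roc") {
        roc_curve(fp$p_apl, lab)
      } else {
        pr_curve(fp$p_apl, lab)
      }
      cur$fold <- factor(fp$fold[1])
      cur
    }
  )
  if (type == "roc") {
    ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr,
      colour = .data$fold
    )) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(linetype = 3) +
      ggplot2::labs(x = "FPR (1 - specificity)", y = "TPR (recall)")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$recall, .data$precision,
      colour = .data$fold
    )) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::labs(x = "recall", y = "precision")
  }
}
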