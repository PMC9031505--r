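#' Plot per-patient evaluation metrics
#'
#' One point per patient and metric (rates on the percent scale),
#' with degenerate (empty-label) patients marked.
#'
#' @param object a `metrics_report` from [evaluate_cohort()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.metrics_report <- function(object, ...) {
  pp <- object$per_patient
  metrics <- c("sensitivity", "specificity_as_printed", "f1", "jaccard", "vs")
  df <- do.call(rbind, lapply(metrics, function(m)
    data.frame(patient_id = pp$patient_id, metric = m,
               value_pct = 100 * pp[[m]], degenerate = pp$degenerate)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value_pct)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$degenerate), alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "metric (%)", shape = "empty label") +
    ggplot2::ylim(0, 100)
}

#' Display a slice with mask overlays
#'
#' Grey intensity image of one axial slice with the label and/or
#' predicted mask boundaries drawn as filled transparent overlays —
#' the usual visual check of a segmentation result.
#'
#' @param study a [dwi_study()].
#' @param slice slice index.
#' @param label,prediction optional [lesion_mask()] objects aligned to
#'   the study (native geometry).
#' @return A ggplot object.
#' @export
plot_slice_overlay <- function(study, slice = 1L, label = NULL, prediction = NULL) {
  img <- study$voxels[slice, , ]
  df <- data.frame(row = as.vector(row(img)), col = as.vector(col(img)),
                   intensity = as.vector(img))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  add_layer <- function(p, mask, colour) {
    m <- mask$voxels[slice, , ]
    if (!any(m == 1)) return(p)
    md <- data.frame(row = as.vector(row(m))[m == 1], col = as.vector(col(m))[m == 1])
    p + ggplot2::annotate("tile", x = md$col, y = md$row, fill = colour,
                          alpha = 0.35)
  }
  if (!is.null(label)) p <- add_layer(p, label, "yellow")
  if (!is.null(prediction)) p <- add_layer(p, prediction, "red")
  p
}
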