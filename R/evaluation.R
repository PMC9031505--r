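#' Pixelwise confusion counts between a prediction and a label
#'
#' @param pred,label aligned binary [lesion_mask()] objects (or bare
#'   binary arrays of equal shape).
#' @return A `confusion_counts` object: list with integer `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion <- function(pred, label) {
  p <- if (inherits(pred, "lesion_mask")) pred$voxels else pred
  y <- if (inherits(label, "lesion_mask")) label$voxels else label
  if (!identical(dim(p), dim(y)))
    stop("prediction and label shapes differ", call. = FALSE)
  if (!all(p %in% c(0, 1)) || !all(y %in% c(0, 1)))
    stop("masks must be binary", call. = FALSE)
  confusion_counts(tp = sum(p == 1 & y == 1), fp = sum(p == 1 & y == 0),
                   fn = sum(p == 0 & y == 1), tn = sum(p == 0 & y == 0))
}

#' @param tp,fp,fn,tn nonnegative pixel tallies.
#' @rdname confusion
#' @export
confusion_counts <- function(tp, fp, fn, tn = 0) {
  if (any(c(tp, fp, fn, tn) < 0)) stop("counts must be nonnegative", call. = FALSE)
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 fn = as.numeric(fn), tn = as.numeric(tn)),
            class = "confusion_counts")
}

rate <- function(num, den) if (den > 0) num / den else 0

#' Segmentation rate metrics from confusion counts
#'
#' `sensitivity` is TP/(TP+FN). `specificity_as_printed` is TP/(TP+FP):
#' some published stroke-segmentation results report this precision-style
#' quantity under the name "specificity", so it is implemented exactly as
#' printed there under an explicit name — no guess is made about intent —
#' and the conventional TN/(TN+FP) is available as `true_specificity`. `f1` is the harmonic
#' mean of precision and recall and `jaccard` is TP/(TP+FP+FN); the two
#' are linked by `jaccard = f1 / (2 - f1)`. A zero denominator yields 0
#' (degenerate case, e.g. an empty-label control patient).
#'
#' @param c a `confusion_counts` object.
#' @return A scalar in \[0, 1\].
#' @export
sensitivity <- function(c) rate(c$tp, c$tp + c$fn)

#' @rdname sensitivity
#' @export
specificity_as_printed <- function(c) rate(c$tp, c$tp + c$fp)

#' @rdname sensitivity
#' @export
true_specificity <- function(c) rate(c$tn, c$tn + c$fp)

#' @rdname sensitivity
#' @export
f1 <- function(c) {
  prec <- rate(c$tp, c$tp + c$fp); rec <- rate(c$tp, c$tp + c$fn)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

#' @rdname sensitivity
#' @export
jaccard <- function(c) rate(c$tp, c$tp + c$fp + c$fn)

#' Volume similarity of two masks
#'
#' `VS = 1 - |FN - FP| / (2 TP + FP + FN)`, equivalently
#' `1 - ||m| - |g|| / (|m| + |g|)` with `|m| = TP + FP` predicted and
#' `|g| = TP + FN` labelled pixels. VS compares the two volumes
#' irrespective of localization: it is 1 whenever the predicted and true
#' pixel counts agree, even with zero overlap. Two empty masks are defined
#' as VS = 1.
#'
#' @param c a `confusion_counts` object.
#' @return A scalar in \[0, 1\].
#' @export
volume_similarity <- function(c) {
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) return(1)
  1 - abs(c$fn - c$fp) / den
}

#' Mean absolute volume error
#'
#' The mean over patients of |estimated - true| volume, in cc.
#'
#' @param estimated_cc,true_cc numeric vectors of equal length (>= 1).
#' @return Scalar MAE in cc.
#' @export
mean_absolute_error <- function(estimated_cc, true_cc) {
  if (length(estimated_cc) == 0) stop("empty input", call. = FALSE)
  if (length(estimated_cc) != length(true_cc)) stop("length mismatch", call. = FALSE)
  mean(abs(estimated_cc - true_cc))
}

#' Evaluate predictions over a cohort
#'
#' Computes per-patient confusion counts, rate metrics, and estimated and
#' true volumes, then aggregates. Rate metrics are macro-averaged over
#' patients; patients with an empty label (controls) have degenerate rate
#' denominators and are excluded from the rate averages by default (they
#' still contribute to MAE, which is how control cohorts are assessed).
#' `pooled = TRUE` instead pools pixel counts over the cohort before
#' computing rates.
#'
#' @param predictions list of predicted [lesion_mask()] objects.
#' @param labels list of ground-truth [lesion_mask()] objects (same
#'   geometry as the matching prediction).
#' @param studies list of [dwi_study()] objects supplying geometry for
#'   volumetry. Volumes are estimated from the predictions and the truth
#'   from the labels via [estimate_volume()].
#' @param include_degenerate include empty-label patients (as rate 0) in
#'   the macro averages.
#' @param pooled pool pixels across patients instead of macro-averaging.
#' @return A `metrics_report`: list with `per_patient` (tibble) and
#'   `summary` (tibble of cohort metrics on the percent scale, plus
#'   `mae_cc` and `n_patients`).
#' @export
evaluate_cohort <- function(predictions, labels, studies,
                            include_degenerate = FALSE, pooled = FALSE) {
  n <- length(predictions)
  if (n == 0) stop("empty cohort", call. = FALSE)
  stopifnot(length(labels) == n, length(studies) == n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cc <- confusion(predictions[[i]], labels[[i]])
    est <- estimate_volume(predictions[[i]], studies[[i]])
    tru <- estimate_volume(labels[[i]], studies[[i]])
    rows[[i]] <- tibble::tibble(
      patient_id = studies[[i]]$patient_id,
      tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
      sensitivity = sensitivity(cc),
      specificity_as_printed = specificity_as_printed(cc),
      true_specificity = true_specificity(cc),
      f1 = f1(cc), jaccard = jaccard(cc),
      vs = volume_similarity(cc),
      degenerate = (cc$tp + cc$fn) == 0,
      estimated_cc = est$volume_cc, true_cc = tru$volume_cc)
  }
  per_patient <- do.call(rbind, rows)
  keep <- if (include_degenerate) rep(TRUE, n) else !per_patient$degenerate
  rate_cols <- c("sensitivity", "specificity_as_printed", "true_specificity",
                 "f1", "jaccard", "vs")
  if (pooled) {
    pc <- confusion_counts(sum(per_patient$tp), sum(per_patient$fp),
                           sum(per_patient$fn), sum(per_patient$tn))
    agg <- c(sensitivity = sensitivity(pc),
             specificity_as_printed = specificity_as_printed(pc),
             true_specificity = true_specificity(pc),
             f1 = f1(pc), jaccard = jaccard(pc), vs = volume_similarity(pc))
  } else if (any(keep)) {
    agg <- colMeans(per_patient[keep, rate_cols])
  } else {
    agg <- setNames(rep(NA_real_, length(rate_cols)), rate_cols)
  }
  summary <- tibble::tibble(
    sensitivity_pct = 100 * agg[["sensitivity"]],
    specificity_pct = 100 * agg[["specificity_as_printed"]],
    true_specificity_pct = 100 * agg[["true_specificity"]],
    f1_pct = 100 * agg[["f1"]],
    jaccard_pct = 100 * agg[["jaccard"]],
    vs_pct = 100 * agg[["vs"]],
    mae_cc = mean_absolute_error(per_patient$estimated_cc, per_patient$true_cc),
    n_patients = n)
  structure(list(per_patient = per_patient, summary = summary),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<metrics_report> %d patients\n", s$n_patients))
  cat(sprintf("  Sensitivity %.2f%%  Specificity %.2f%%  F1 %.2f%%  Jaccard %.2f%%\n",
              s$sensitivity_pct, s$specificity_pct, s$f1_pct, s$jaccard_pct))
  cat(sprintf("  VS %.2f%%  MAE %.3f cc\n", s$vs_pct, s$mae_cc))
  invisible(x)
}

#' @export
tidy.metrics_report <- function(x, ...) x$per_patient

#' @export
glance.metrics_report <- function(x, ...) x$summary
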