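# Object Keypoint Similarity (OKS) and the AP/AR metric family.
#
# OKS for one instance is a Gaussian of per-keypoint normalized distances
# averaged over labeled keypoints:
#   OKS = sum_i exp(-d_i^2 / (2 s^2 k_i^2)) [v_i > 0] / sum_i [v_i > 0],
# with s = sqrt(instance area) and k_i the per-keypoint falloff weight.
# AP at threshold T is the fraction of instances with OKS strictly greater
# than T; headline AP averages the grid T = 0.50, 0.55, ..., 0.95.

#' OKS threshold grid
#'
#' The ten thresholds 0.50, 0.55, ..., 0.95 over which AP and AR are
#' averaged.
#'
#' @return numeric vector of length 10.
#' @export
oks_thresholds <- function() seq(0.50, 0.95, by = 0.05)

#' Compute Object Keypoint Similarity for one instance
#'
#' @param pred M x 2 (or M x 3) matrix of predicted (x, y) px.
#' @param gt M x 3 matrix of ground-truth (x, y, v).
#' @param s target scale (sqrt of instance area), > 0.
#' @param k per-keypoint falloff weights (length M or scalar).
#' @return OKS in [0, 1].
#' @export
compute_oks <- function(pred, gt, s, k) {
  pred <- matrix(as.numeric(pred), nrow = nrow(gt))
  gt <- matrix(as.numeric(gt), ncol = 3L)
  M <- nrow(gt)
  if (length(k) == 1L) k <- rep(k, M)
  if (length(k) != M) stop("k must have one weight per keypoint")
  if (any(k <= 0)) stop("all k weights must be positive")
  if (s <= 0) stop("scale s must be positive")
  vis <- gt[, 3L] > 0
  if (!any(vis)) stop("OKS is undefined when no keypoint is labeled (all v = 0)")
  d2 <- (pred[, 1L] - gt[, 1L])^2 + (pred[, 2L] - gt[, 2L])^2
  mean(exp(-d2[vis] / (2 * s^2 * k[vis]^2)))
}

#' Average precision over an OKS threshold grid
#'
#' At each threshold T the score is the fraction of instances with
#' OKS strictly greater than T; AP is the mean over the grid.
#'
#' @param oks_list numeric vector of per-instance OKS values.
#' @param thresholds threshold grid (default [oks_thresholds()]).
#' @return list with `AP` (percent), `per_threshold` (named percents), and
#'   the single-threshold values `AP50` and `AP75` when 0.5/0.75 are in the
#'   grid.
#' @export
compute_ap <- function(oks_list, thresholds = oks_thresholds()) {
  if (length(oks_list) == 0L) stop("cannot compute AP from an empty OKS list")
  per <- vapply(thresholds, function(T) 100 * mean(oks_list > T), numeric(1L))
  names(per) <- sprintf("%.2f", thresholds)
  out <- list(AP = mean(per), per_threshold = per)
  if ("0.50" %in% names(per)) out$AP50 <- unname(per["0.50"])
  if ("0.75" %in% names(per)) out$AP75 <- unname(per["0.75"])
  out
}

#' Classify an instance by area
#'
#' Medium: 32^2 <= area <= 96^2; large: area > 96^2; anything smaller is
#' "small" and excluded from both APM and APL.
#'
#' @param area instance area in px^2.
#' @return "small", "medium" or "large".
#' @export
partition_by_scale <- function(area) {
  if (!is.finite(area) || area <= 0) stop("area must be positive")
  if (area > 96^2) return("large")
  if (area >= 32^2) return("medium")
  "small"
}

#' Evaluate predictions against ground truth
#'
#' Top-down evaluation: predictions are matched to ground-truth instances by
#' annotation id (at most one prediction per instance; duplicates are an
#' error). Instances with no prediction count as OKS 0. AP, AP50, AP75 and
#' AR are computed over all instances; APM and APL restrict to the medium /
#' large area partitions (NaN when a partition is empty).
#'
#' @param preds list of prediction records (fields `annotation_id`,
#'   `keypoints`), e.g. from [read_coco_results()] or [predict.promptpose()].
#' @param gts an [annotation_set()].
#' @param sigmas per-keypoint OKS weights (default: the schema's).
#' @param thresholds OKS threshold grid.
#' @return object of class `metrics_report`: list with AP, AP50, AP75, APM,
#'   APL, AR (percent), per-instance OKS values and partition counts.
#' @export
evaluate_dataset <- function(preds, gts, sigmas = NULL,
                             thresholds = oks_thresholds()) {
  stopifnot(inherits(gts, "annotation_set"))
  if (is.null(sigmas)) sigmas <- gts$schema$sigmas
  ids <- vapply(preds, function(p) as.integer(p$annotation_id), integer(1L))
  if (anyDuplicated(ids)) stop("duplicate predictions for one ground-truth instance")
  pred_by_id <- stats::setNames(preds, as.character(ids))
  oks <- numeric(0); cls <- character(0)
  for (a in gts$annotations) {
    if (!any(a$keypoints[, 3L] > 0)) next  # nothing labeled: no OKS defined
    p <- pred_by_id[[as.character(a$id)]]
    o <- if (is.null(p)) 0 else
      compute_oks(p$keypoints[, 1:2, drop = FALSE], a$keypoints,
                  sqrt(a$area), sigmas)
    oks <- c(oks, o)
    cls <- c(cls, partition_by_scale(a$area))
  }
  if (length(oks) == 0L) stop("no evaluable ground-truth instances")
  ap_all <- compute_ap(oks, thresholds)
  part_ap <- function(keep) {
    if (!any(keep)) return(NaN)
    compute_ap(oks[keep], thresholds)$AP
  }
  # AR: mean over thresholds of the fraction of ground-truth instances with
  # a prediction of OKS > T (missing predictions enter as OKS 0)
  ar <- mean(vapply(thresholds, function(T) 100 * mean(oks > T), numeric(1L)))
  structure(list(
    AP = ap_all$AP, AP50 = ap_all$AP50, AP75 = ap_all$AP75,
    APM = part_ap(cls == "medium"), APL = part_ap(cls == "large"),
    AR = ar, oks = oks, partition = cls,
    n_instances = c(all = length(oks), medium = sum(cls == "medium"),
                    large = sum(cls == "large"), small = sum(cls == "small"))),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("OKS metrics over %d instances (%d medium, %d large):\n",
              x$n_instances["all"], x$n_instances["medium"], x$n_instances["large"]))
  cat(sprintf("  AP %.1f | AP50 %.1f | AP75 %.1f | APM %s | APL %s | AR %.1f\n",
              x$AP, x$AP50, x$AP75,
              if (is.nan(x$APM)) "-" else sprintf("%.1f", x$APM),
              if (is.nan(x$APL)) "-" else sprintf("%.1f", x$APL), x$AR))
  invisible(x)
}
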