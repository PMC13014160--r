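#' Greedy one-to-one matching of detections to ground truths
#'
#' Detections are processed in descending score order (ties broken by
#' input index); each claims the unclaimed ground truth with which it has
#' the highest IoU, provided that IoU reaches `iou_thr`, otherwise it is a
#' false positive. Each ground truth is matched at most once — additional
#' detections on the same lesion count as false positives.
#'
#' @param dets Detections data frame (box columns + `score`).
#' @param gts Ground-truth boxes (m-by-6).
#' @param iou_thr Matching threshold in `(0, 1]`.
#' @return A list with `tp` (logical per detection, in input order),
#'   `matched_gt` (claimed ground-truth index or NA) and `gt_detected`
#'   (logical per ground truth).
#' @export
match_detections <- function(dets, gts, iou_thr = 0.1) {
  if (iou_thr <= 0 || iou_thr > 1) stop("iou_thr must lie in (0,1]")
  dets <- as_detections(dets)
  g <- as_box_matrix(gts)
  n <- nrow(dets)
  m <- nrow(g)
  tp <- logical(n)
  matched <- rep(NA_integer_, n)
  gt_done <- logical(m)
  if (n && m) {
    iou <- iou_matrix(as_box_matrix(dets), g)
    for (i in order(-dets$score, seq_len(n))) {
      free <- which(!gt_done)
      if (!length(free)) break
      j <- free[which.max(iou[i, free])]
      if (iou[i, j] >= iou_thr) {
        tp[i] <- TRUE
        matched[i] <- j
        gt_done[j] <- TRUE
      }
    }
  }
  list(tp = tp, matched_gt = matched, gt_detected = gt_done)
}

## Pool per-subject matches into a score-ordered TP/FP table.
## `dets` and `gts` are parallel lists over subjects.
pooled_matches <- function(dets, gts, iou_thr) {
  stopifnot(length(dets) == length(gts))
  npos <- sum(vapply(gts, function(g) nrow(as_box_matrix(g)), integer(1)))
  if (npos == 0L) stop("undefined metric: no ground-truth lesions")
  rows <- lapply(seq_along(dets), function(i) {
    d <- as_detections(dets[[i]])
    if (nrow(d) == 0L) return(NULL)
    mr <- match_detections(d, gts[[i]], iou_thr)
    data.frame(score = d$score, tp = mr$tp, subject = i,
               idx = seq_len(nrow(d)))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(score = numeric(0), tp = logical(0),
                      subject = integer(0), idx = integer(0))
  }
  tab <- tab[order(-tab$score, tab$subject, tab$idx), , drop = FALSE]
  list(tab = tab, npos = npos, n_subjects = length(dets))
}

#' Average precision at a fixed IoU threshold
#'
#' Detections are pooled across subjects and sorted by score; AP is the
#' area under the precision-recall curve using the all-points precision
#' envelope (precision at each recall level is the maximum precision at
#' any equal-or-higher recall).
#'
#' @param dets List of per-subject detection frames.
#' @param gts List of per-subject ground-truth box matrices.
#' @param iou_thr Matching threshold (the tracer-transfer experiments use
#'   0.1, 0.25 and 0.5).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(dets, gts, iou_thr = 0.1) {
  pm <- pooled_matches(dets, gts, iou_thr)
  tab <- pm$tab
  if (nrow(tab) == 0L) return(0)
  tp <- cumsum(tab$tp)
  fp <- cumsum(!tab$tp)
  recall <- tp / pm$npos
  precision <- tp / (tp + fp)
  ## precision envelope, right to left
  penv <- rev(cummax(rev(precision)))
  r_prev <- c(0, utils::head(recall, -1L))
  sum((recall - r_prev) * penv)
}

#' FROC curve
#'
#' Sweeps the confidence cutoff from high to low; at each distinct score
#' the operating point is (mean false positives per subject, pooled lesion
#' sensitivity). Matching uses IoU >= `iou_thr` (default 0.1).
#'
#' @inheritParams average_precision
#' @return An object of class `"froc_curve"`: a data frame with columns
#'   `threshold` (strictly decreasing), `fp_per_scan` and `sensitivity`.
#' @export
froc_curve <- function(dets, gts, iou_thr = 0.1) {
  pm <- pooled_matches(dets, gts, iou_thr)
  tab <- pm$tab
  if (nrow(tab) == 0L) {
    out <- data.frame(threshold = Inf, fp_per_scan = 0, sensitivity = 0)
  } else {
    tp <- cumsum(tab$tp)
    fp <- cumsum(!tab$tp)
    last <- !duplicated(tab$score, fromLast = TRUE)
    out <- data.frame(threshold = tab$score[last],
                      fp_per_scan = fp[last] / pm$n_subjects,
                      sensitivity = tp[last] / pm$npos)
  }
  class(out) <- c("froc_curve", "data.frame")
  out
}

#' Sensitivity at a false-positive budget
#'
#' The largest sensitivity among FROC operating points with at most
#' `fp_per_scan` mean false positives per subject; 0 when no operating
#' point fits the budget.
#'
#' @param curve A [froc_curve()].
#' @param fp_per_scan Non-negative budget.
#' @return Sensitivity in `[0, 1]`.
#' @export
sensitivity_at_fp <- function(curve, fp_per_scan) {
  if (fp_per_scan < 0) stop("fp_per_scan must be >= 0")
  ok <- curve$fp_per_scan <= fp_per_scan
  if (!any(ok)) return(0)
  max(curve$sensitivity[ok])
}

#' @export
plot.froc_curve <- function(x, ..., add = FALSE, col = 1) {
  if (!add) {
    graphics::plot(x$fp_per_scan, x$sensitivity, type = "s", col = col,
                   xlab = "mean false positives per scan",
                   ylab = "lesion sensitivity", ylim = c(0, 1), ...)
  } else {
    graphics::lines(x$fp_per_scan, x$sensitivity, type = "s", col = col, ...)
  }
  invisible(x)
}

#' Detection metrics summary
#'
#' Convenience wrapper computing AP at the standard thresholds and the
#' FROC curve in one pass.
#'
#' @inheritParams average_precision
#' @param ap_thresholds IoU thresholds for AP.
#' @param froc_iou Matching IoU for the FROC analysis.
#' @return A list with `ap` (named vector) and `froc` (a [froc_curve()]).
#' @export
evaluate_detections <- function(dets, gts,
                                ap_thresholds = c(0.1, 0.25, 0.5),
                                froc_iou = 0.1) {
  ap <- vapply(ap_thresholds, function(t) average_precision(dets, gts, t),
               numeric(1))
  names(ap) <- paste0("AP@", ap_thresholds)
  list(ap = ap, froc = froc_curve(dets, gts, froc_iou))
}
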