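#' Clean raw detections into a candidate set
#'
#' Confidence gating then NMS, in that order: detections with
#' `score < tau` are discarded and 3D non-maximum suppression removes
#' largely overlapping survivors.
#'
#' @param raw Detections data frame (box columns + `score`).
#' @param tau Confidence gate in `[0, 1]` (default 0.5).
#' @param nms_iou NMS threshold in `(0, 1)` (default 0.25).
#' @return Cleaned detections sorted by score descending; all scores are
#'   `>= tau` and retained pairs overlap below `nms_iou`.
#' @export
clean_candidates <- function(raw, tau = 0.5, nms_iou = 0.25) {
  if (tau < 0 || tau > 1) stop("tau must lie in [0,1]")
  raw <- as_detections(raw)
  gated <- raw[raw$score >= tau, , drop = FALSE]
  if (nrow(gated) == 0L) return(empty_detections())
  nms3d(gated, nms_iou)
}

#' Prior-guided pseudo-label selection
#'
#' Allocates the subject's budget `ceiling(lam * mu)` over volume bins
#' proportionally to the prior histogram `h` (largest-remainder method),
#' then keeps the top-scoring candidates within each bin up to its quota.
#' A bin with fewer candidates than quota keeps all of them; the unused
#' slots are not transferred to other bins, so the selected size
#' composition tracks `h` rather than the detector's confidence profile.
#'
#' Candidates whose volume falls below the first bin edge cannot be
#' assigned a bin and are dropped (they are sub-floor boxes that a label
#' set would not contain either).
#'
#' @param cands Cleaned candidate detections (see [clean_candidates()]).
#' @param prior A [size_prior()].
#' @param binning A [size_binning()].
#' @param sp A [spacing()].
#' @param lam Admission factor in `(0, 1]`.
#' @return A detections data frame of selected pseudo labels (at most the
#'   subject budget), sorted by score descending.
#' @export
select_prior_guided <- function(cands, prior, binning, sp, lam) {
  cands <- as_detections(cands)
  budget <- subject_budget(prior, lam)
  if (budget == 0L || nrow(cands) == 0L) return(empty_detections())
  v <- box_volume_cc(cands, sp)
  ok <- v >= binning$edges[1L]
  cands <- cands[ok, , drop = FALSE]
  if (nrow(cands) == 0L) return(empty_detections())
  quotas <- allocate_quotas(prior$h, budget)
  bins <- bin_of(cands, sp, binning)
  keep <- logical(nrow(cands))
  for (b in seq_len(binning$B)) {
    if (quotas[b] == 0L) next
    in_bin <- which(bins == b)
    if (length(in_bin) == 0L) next
    ord <- in_bin[order(-cands$score[in_bin], in_bin)]
    keep[utils::head(ord, quotas[b])] <- TRUE
  }
  out <- cands[keep, , drop = FALSE]
  out <- out[order(-out$score, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-fraction pseudo-label selection (baseline)
#'
#' The conventional self-training rule: keep the top `ceiling(p * n)`
#' candidates by confidence. The ceiling means a lone candidate survives
#' `p = 0.5`, so sparse subjects are not silenced.
#'
#' @param cands Cleaned candidate detections.
#' @param p Fraction in `(0, 1]` (the comparison arm uses 0.5).
#' @return Selected detections sorted by score descending.
#' @export
select_top_fraction <- function(cands, p = 0.5) {
  if (p <= 0 || p > 1) stop("p must lie in (0,1]")
  cands <- as_detections(cands)
  n <- nrow(cands)
  if (n == 0L) return(empty_detections())
  k <- as.integer(ceiling(p * n))
  ord <- order(-cands$score, seq_len(n))
  out <- cands[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Linear admission schedule for the selection factor
#'
#' `lambda` grows linearly from `lam_start` at round 0 to `lam_end` at
#' round `R - 1`, admitting pseudo labels more aggressively as the priors
#' and the detector stabilize. The reference schedule runs 0.1 to 0.8 over
#' 200 rounds.
#'
#' @param r 0-based round index, `0 <= r < R`.
#' @param R Total number of rounds (`>= 1`).
#' @param lam_start,lam_end Schedule endpoints.
#' @return The round's admission factor, clamped to
#'   `[lam_start, lam_end]`.
#' @export
lambda_schedule <- function(r, R, lam_start = 0.1, lam_end = 0.8) {
  if (R < 1) stop("R must be >= 1")
  if (r < 0 || r >= R) stop("round index out of range")
  if (R == 1L) return(lam_start)
  lam <- lam_start + (lam_end - lam_start) * r / (R - 1)
  min(max(lam, min(lam_start, lam_end)), max(lam_start, lam_end))
}
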