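mk_det <- function(boxes, scores) {
  d <- as.data.frame(box3d(boxes))
  d$score <- scores
  d
}

test_that("matching is one-to-one with extra detections as false positives", {
  gt <- box3d(c(0, 0, 0, 4, 4, 4))
  d1 <- mk_det(c(0, 0, 0, 4, 4, 4), 0.9)
  m1 <- match_detections(d1, gt, 0.5)
  expect_true(m1$tp)
  expect_equal(m1$matched_gt, 1L)
  ## second detection on the same lesion is a false positive
  d2 <- mk_det(rbind(c(0, 0, 0, 4, 4, 4), c(0.2, 0, 0, 4.2, 4, 4)),
               c(0.9, 0.8))
  m2 <- match_detections(d2, gt, 0.5)
  expect_equal(m2$tp, c(TRUE, FALSE))
  ## lower-scored detection processed later even if listed first
  d3 <- d2[2:1, ]
  m3 <- match_detections(d3, gt, 0.5)
  expect_equal(m3$tp, c(FALSE, TRUE))
})

test_that("matching agrees with the brute-force oracle on random cases", {
  for (s in 1:40) {
    set.seed(s)
    nd <- sample(1:8, 1)
    ng <- sample(1:5, 1)
    d <- rand_detections(nd, dim = c(12, 12, 12), seed = 100 + s)
    g <- rand_boxes(ng, dim = c(12, 12, 12), seed = 200 + s)
    thr <- sample(c(0.1, 0.25, 0.5), 1)
    got <- match_detections(d, g, thr)
    expect_equal(got$tp, match_oracle(d, g, thr), label = sprintf("case %d", s))
    ## one-to-one constraints
    expect_lte(max(table(stats::na.omit(got$matched_gt)), 0), 1)
    expect_equal(sum(got$tp), sum(got$gt_detected))
  }
})

test_that("average precision reproduces hand-computed values", {
  gt2 <- list(box3d(rbind(c(0, 0, 0, 4, 4, 4), c(10, 10, 10, 14, 14, 14))))
  ## all detected, no FP -> 1
  d_perfect <- list(mk_det(rbind(c(0, 0, 0, 4, 4, 4),
                                 c(10, 10, 10, 14, 14, 14)), c(0.9, 0.8)))
  expect_equal(average_precision(d_perfect, gt2, 0.5), 1)
  ## no detections -> 0
  expect_equal(average_precision(list(mk_det(c(0,0,0,1,1,1), 0.5)[0, ]), gt2,
                                 0.5), 0)
  ## 1 TP at 0.9, 1 FP at 0.8, 1 missed GT: envelope area = 0.5
  d_half <- list(mk_det(rbind(c(0, 0, 0, 4, 4, 4),
                              c(30, 30, 30, 31, 31, 31)), c(0.9, 0.8)))
  gt_far <- list(box3d(rbind(c(0, 0, 0, 4, 4, 4), c(10, 10, 10, 14, 14, 14))))
  expect_equal(average_precision(d_half, gt_far, 0.5), 0.5)
  expect_error(average_precision(d_perfect, list(empty_gt = box3d(
    matrix(numeric(0), 0, 6))), 0.5), "no ground-truth")
})

test_that("average precision matches an independent recomputation", {
  for (s in 1:25) {
    set.seed(s)
    ns <- sample(1:3, 1)
    dets <- lapply(1:ns, function(i) rand_detections(sample(0:8, 1),
                                                     seed = 300 + s * 10 + i))
    gts <- lapply(1:ns, function(i) rand_boxes(sample(1:5, 1),
                                               seed = 400 + s * 10 + i))
    for (thr in c(0.1, 0.5)) {
      expect_equal(average_precision(dets, gts, thr), ap_oracle(dets, gts, thr),
                   tolerance = 1e-12, label = sprintf("case %d thr %.1f", s, thr))
    }
  }
})

test_that("AP is invariant to subject order and monotone score transforms", {
  dets <- lapply(1:3, function(i) rand_detections(6, seed = 500 + i))
  gts <- lapply(1:3, function(i) rand_boxes(4, seed = 600 + i))
  a1 <- average_precision(dets, gts, 0.25)
  expect_equal(average_precision(rev(dets), rev(gts), 0.25), a1)
  dets2 <- lapply(dets, function(d) { d$score <- d$score^3; d })
  expect_equal(average_precision(dets2, gts, 0.25), a1)
  ## stricter threshold can only lower AP
  expect_lte(average_precision(dets, gts, 0.5), a1)
  expect_lte(a1, average_precision(dets, gts, 0.1))
})

test_that("FROC sweeps cutoffs with non-decreasing sensitivity", {
  gt <- list(box3d(c(0, 0, 0, 4, 4, 4)), box3d(c(2, 2, 2, 6, 6, 6)))
  dets <- list(mk_det(c(0, 0, 0, 4, 4, 4), 0.9),
               mk_det(rbind(c(2, 2, 2, 6, 6, 6), c(20, 20, 20, 24, 24, 24)),
                      c(0.8, 0.7)))
  cur <- froc_curve(dets, gt, 0.1)
  expect_true(all(diff(cur$threshold) < 0))
  expect_true(all(diff(cur$sensitivity) >= 0))
  ## exhaustive per-cutoff recount oracle
  for (i in seq_len(nrow(cur))) {
    t <- cur$threshold[i]
    tp <- 0; fp <- 0
    for (k in 1:2) {
      d <- dets[[k]][dets[[k]]$score >= t, , drop = FALSE]
      if (nrow(d) == 0) next
      tpf <- match_oracle(d, gt[[k]], 0.1)
      tp <- tp + sum(tpf); fp <- fp + sum(!tpf)
    }
    expect_equal(cur$sensitivity[i], tp / 2)
    expect_equal(cur$fp_per_scan[i], fp / 2)
  }
  ## perfect detector reaches sensitivity 1 at zero FPs
  perf <- froc_curve(list(mk_det(c(0, 0, 0, 4, 4, 4), 1)),
                     list(box3d(c(0, 0, 0, 4, 4, 4))), 0.1)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$fp_per_scan, 0)
  ## silent detector: single (0, 0) point
  silent <- froc_curve(list(mk_det(c(0, 0, 0, 1, 1, 1), 0.5)[0, ]),
                       list(box3d(c(0, 0, 0, 4, 4, 4))), 0.1)
  expect_equal(silent$sensitivity, 0)
  expect_equal(silent$fp_per_scan, 0)
})

test_that("sensitivity_at_fp is a step-function lookup", {
  cur <- structure(data.frame(threshold = c(0.9, 0.5, 0.2),
                              fp_per_scan = c(0, 1, 3),
                              sensitivity = c(0.4, 0.6, 0.9)),
                   class = c("froc_curve", "data.frame"))
  expect_equal(sensitivity_at_fp(cur, 10), 0.9)   # beyond the curve
  expect_equal(sensitivity_at_fp(cur, 2), 0.6)    # interior budget
  expect_equal(sensitivity_at_fp(cur, 0), 0.4)    # admits the x = 0 point
  cur2 <- cur; cur2$fp_per_scan <- c(0.5, 1, 3)
  expect_equal(sensitivity_at_fp(cur2, 0), 0)     # nothing fits the budget
})

test_that("evaluate_detections bundles AP and FROC", {
  dets <- lapply(1:2, function(i) rand_detections(5, seed = 700 + i))
  gts <- lapply(1:2, function(i) rand_boxes(3, seed = 800 + i))
  res <- evaluate_detections(dets, gts)
  expect_named(res$ap, c("AP@0.1", "AP@0.25", "AP@0.5"))
  expect_true(all(res$ap >= 0 & res$ap <= 1))
  expect_s3_class(res$froc, "froc_curve")
})
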