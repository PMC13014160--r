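anc3 <- anchor_set(rbind(c(4, 4, 3), c(8, 8, 6), c(16, 16, 12)))

test_that("anchor grid tiles K anchors per stride point, clipped", {
  g1 <- build_anchor_grid(c(8, 8, 8), 8L, anc3)
  expect_equal(nrow(g1$boxes), 3L)
  g2 <- build_anchor_grid(c(16, 16, 16), 8L, anc3)
  expect_equal(nrow(g2$boxes), 24L)
  expect_true(all(g2$boxes[, 1:3] >= 0))
  expect_true(all(g2$boxes[, 4:6] <= 16))
  ## single anchor the size of the volume covers it from the center
  a1 <- anchor_set(matrix(c(8, 8, 8), 1))
  g3 <- build_anchor_grid(c(8, 8, 8), 8L, a1)
  expect_equal(as.numeric(g3$boxes), c(0, 0, 0, 8, 8, 8))
})

test_that("encode/decode round-trips arbitrary box-anchor pairs", {
  set.seed(5)
  for (rep in 1:20) {
    b <- rand_boxes(4, seed = rep)
    centers <- matrix(runif(12, 2, 18), 4, 3)
    extents <- matrix(runif(12, 1, 10), 4, 3)
    t <- encode_boxes(b, centers, extents)
    back <- decode_boxes(t, centers, extents)
    expect_equal(unname(back), unname(b), tolerance = 1e-6)
  }
})

test_that("anchor assignment follows the threshold band with best-match forcing", {
  ## GT equal to the clipped mid anchor at grid point (4,4,4)
  gt <- box3d(c(0, 0, 1, 8, 8, 7))
  grid <- build_anchor_grid(c(16, 16, 16), 8L, anc3)
  asg <- assign_anchors(grid$boxes, gt)
  ident <- which(apply(grid$boxes, 1, function(r)
    isTRUE(all.equal(as.numeric(r), c(0, 0, 1, 8, 8, 7)))))
  expect_true(length(ident) == 1 && asg$cls[ident] == 1)
  ## no ground truths -> all negative
  asg0 <- assign_anchors(grid$boxes, empty_gt <- matrix(numeric(0), 0, 6))
  expect_true(all(asg0$cls == 0))
  ## every GT has at least one positive anchor even with poor IoU
  tiny <- box3d(c(0.2, 0.2, 0.2, 1, 1, 1))
  asg2 <- assign_anchors(grid$boxes, tiny)
  expect_gte(sum(asg2$cls %in% 1), 1L)
  ## in-between IoU is ignored unless best for some GT
  a <- box3d(c(0, 0, 0, 10, 10, 10))
  cand <- rbind(c(0, 0, 0, 10, 10, 10),  # IoU 1 -> positive
                c(0, 0, 3.8, 10, 10, 13.8), # IoU ~0.45 -> band
                c(50, 50, 50, 60, 60, 60))  # disjoint -> negative
  asg3 <- assign_anchors(cand, a)
  expect_equal(asg3$cls[1], 1)
  expect_true(is.na(asg3$cls[2]))
  expect_equal(asg3$cls[3], 0)
})

test_that("ignore boxes shield their neighbourhood from the negative class", {
  a <- rbind(c(0, 0, 0, 4, 4, 4), c(20, 20, 20, 24, 24, 24))
  gt <- matrix(numeric(0), 0, 6)
  asg <- assign_anchors(a, gt, ignore_boxes = box3d(c(1, 1, 1, 4, 4, 4)))
  expect_true(is.na(asg$cls[1]))
  expect_equal(asg$cls[2], 0)
})

test_that("focal loss matches hand values and reduces to cross-entropy", {
  expect_equal(focal_loss(0.5, 1, gamma = 2, alpha_bal = 0.25),
               0.25 * 0.25 * log(2), tolerance = 1e-12)
  expect_lt(focal_loss(0.999999, 1), 1e-10)
  p <- c(0.1, 0.4, 0.9)
  cls <- c(1, 0, 1)
  ce <- -ifelse(cls == 1, log(p), log(1 - p))
  expect_equal(focal_loss(p, cls, gamma = 0, alpha_bal = 1), ce)
  ## non-negative and monotone in p_t
  ps <- seq(0.01, 0.99, by = 0.01)
  fl <- focal_loss(ps, rep(1, length(ps)))
  expect_true(all(fl >= 0))
  expect_true(all(diff(fl) < 0))
})

test_that("smooth L1 is quadratic below delta and linear above", {
  t0 <- matrix(0, 1, 6)
  expect_equal(smooth_l1(t0, t0), 0)
  d5 <- t0; d5[1] <- 0.5
  expect_equal(smooth_l1(d5, t0), 0.125)
  d2 <- t0; d2[1] <- 2
  expect_equal(smooth_l1(d2, t0), 1.5)
  expect_error(smooth_l1(matrix(0, 1, 6), matrix(0, 2, 6)), "mismatch")
})

test_that("detection_loss composes focal and regression terms", {
  asg <- list(cls = c(1, 0), gt_index = c(1L, NA))
  p <- c(0.8, 0.3)
  tp <- rbind(c(0.1, 0, 0, 0, 0, 0), rep(0, 6))
  tt <- rbind(rep(0, 6), rep(0, 6))
  want <- (focal_loss(0.8, 1) + focal_loss(0.3, 0) +
             smooth_l1(tp[1, , drop = FALSE], tt[1, , drop = FALSE])) / 1
  expect_equal(detection_loss(p, tp, asg, tt), want)
  ## no positives: regression contributes nothing
  asg0 <- list(cls = c(0, 0), gt_index = c(NA, NA))
  expect_equal(detection_loss(p, tp, asg0, tt),
               sum(focal_loss(p, c(0, 0))))
  ## near-perfect predictions give near-zero loss
  expect_lt(detection_loss(c(0.9999, 1e-4), tt, asg, tt), 1e-3)
})

test_that("the mini detector overfits one subject and predicts deterministically", {
  s <- tiny_sample(seed = 31)
  expect_gt(nrow(s$boxes), 0)
  det <- mini_detector(K = 3, lr = 1e-2, seed = 2)
  s$features <- featurize_volume(s$pet, s$ct, det$stride)
  anc <- anchor_set(rbind(c(3, 3, 3), c(6, 6, 5), c(12, 12, 9)))
  losses <- numeric(120)
  for (i in 1:120) {
    det <- detector_train_step(det, list(s), anc)
    losses[i] <- det$last_loss
  }
  ## training reduces the loss substantially
  expect_lt(mean(tail(losses, 10)), 0.5 * mean(head(losses, 10)))
  p1 <- detector_predict(det, s, anc)
  p2 <- detector_predict(det, s, anc)
  expect_identical(p1, p2)
  expect_true(all(p1$score >= det$score_floor & p1$score <= 1))
  ## the top detections recover the ground truth at a loose threshold
  mr <- match_detections(utils::head(p1, 20), s$boxes, 0.25)
  expect_gte(sum(mr$tp), 1L)
})

test_that("untrained detector runs on noise without crashing", {
  set.seed(8)
  s <- list(pet = array(rnorm(32^3), c(32, 32, 32)),
            ct = array(rnorm(32^3), c(32, 32, 32)))
  det <- mini_detector(seed = 4)
  anc <- anchor_set(rbind(c(4, 4, 4), c(7, 7, 7), c(11, 11, 11)))
  p <- detector_predict(det, s, anc)
  expect_true(is.data.frame(p))
  expect_true(all(p$score < 0.5)) # bias init keeps raw scores low
})

test_that("sliding window equals direct prediction for window-sized volumes", {
  s <- tiny_sample(seed = 12)
  det <- mini_detector(seed = 3)
  anc <- anchor_set(rbind(c(4, 4, 4), c(8, 8, 6), c(14, 14, 10)))
  direct <- detector_predict(det, s, anc)
  slid <- sliding_window_predict(det, s, anc, window = dim(s$pet))
  expect_identical(direct, slid)
})

test_that("a lesion on a window seam is reported once after the merge", {
  ## two tiles with 50% overlap; a bright synthetic blob at the seam
  pet <- array(0, c(64, 32, 32))
  ct <- array(0, c(64, 32, 32))
  pet[30:36, 14:20, 14:20] <- 6
  s <- list(pet = pet, ct = ct,
            boxes = box3d(c(29, 13, 13, 36, 20, 20)))
  det <- mini_detector(seed = 6)
  anc <- anchor_set(rbind(c(6, 6, 6), c(10, 10, 10), c(16, 16, 16)))
  ## train on the sample itself so the blob scores high
  s32 <- list(pet = pet[17:48, , ], ct = ct[17:48, , ],
              boxes = box3d(c(13, 13, 13, 20, 20, 20)))
  s32$features <- featurize_volume(s32$pet, s32$ct, det$stride)
  for (i in 1:80) det <- detector_train_step(det, list(s32), anc)
  out <- sliding_window_predict(det, s, anc, window = c(32, 32, 32),
                                overlap = 0.5)
  hits <- clean_candidates(out, tau = 0.5, nms_iou = 0.25)
  expect_gte(nrow(hits), 1L)
  on_blob <- iou3d(box3d(as.matrix(hits[, 1:6])), s$boxes)
  expect_equal(sum(on_blob > 0.1), 1L)
})
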