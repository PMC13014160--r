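## ---- anchor grid, box coding, assignment, losses ----

#' Tile anchor boxes over a volume
#'
#' Places the `K` anchor shapes at every stride-spaced grid point of the
#' volume and clips the resulting boxes to the volume bounds. Rows are
#' ordered grid-point-fastest within each anchor shape, i.e. row
#' `(k - 1) * G + g` is shape `k` at grid point `g`.
#'
#' @param vol_dim Integer volume dimensions (voxels).
#' @param stride Grid stride in voxels.
#' @param anchors An [anchor_set()].
#' @return A list with `boxes` (clipped, `G * K` rows), `centers`
#'   (unclipped anchor centers, same rows), `extents` (unclipped anchor
#'   extents), `grid` (the `G` grid centers) and `K`.
#' @export
build_anchor_grid <- function(vol_dim, stride, anchors) {
  vol_dim <- as.integer(vol_dim)
  g_axis <- pmax(1L, vol_dim %/% stride)
  ax <- lapply(1:3, function(i) ((seq_len(g_axis[i]) - 0.5) * stride))
  grid <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  G <- nrow(grid)
  K <- anchors$K
  centers <- grid[rep(seq_len(G), times = K), , drop = FALSE]
  extents <- anchors$shapes[rep(seq_len(K), each = G), , drop = FALSE]
  lo <- centers - extents / 2
  hi <- centers + extents / 2
  boxes <- cbind(pmax(lo, 0),
                 sweep(pmin(hi, matrix(vol_dim, nrow(hi), 3, byrow = TRUE)),
                       2, c(0, 0, 0), `+`))
  colnames(boxes) <- BOX_COLS
  list(boxes = boxes, centers = centers, extents = extents,
       grid = grid, K = K, G = G, stride = stride)
}

#' Encode / decode boxes against anchors
#'
#' The usual anchor parameterization: three center offsets normalized by
#' the anchor extent and three log extent ratios. `decode_boxes()` inverts
#' `encode_boxes()` exactly.
#'
#' @param boxes An n-by-6 box matrix.
#' @param centers,extents n-by-3 anchor centers and extents.
#' @return `encode_boxes()`: an n-by-6 matrix of regression targets;
#'   `decode_boxes()`: an n-by-6 box matrix.
#' @export
encode_boxes <- function(boxes, centers, extents) {
  b <- as_box_matrix(boxes)
  bc <- (b[, 1:3, drop = FALSE] + b[, 4:6, drop = FALSE]) / 2
  be <- box_extents(b)
  t <- cbind((bc - centers) / extents, log(be / extents))
  colnames(t) <- c("tx", "ty", "tz", "tw", "th", "td")
  t
}

#' @rdname encode_boxes
#' @param t An n-by-6 matrix of regression parameters.
#' @export
decode_boxes <- function(t, centers, extents) {
  t <- matrix(as.numeric(t), ncol = 6L)
  bc <- centers + t[, 1:3, drop = FALSE] * extents
  be <- extents * exp(t[, 4:6, drop = FALSE])
  out <- cbind(bc - be / 2, bc + be / 2)
  colnames(out) <- BOX_COLS
  out
}

#' Assign anchors to ground-truth boxes
#'
#' RetinaNet-style assignment: an anchor is positive when its best IoU over
#' ground truths reaches `iou_pos`, negative below `iou_neg`, ignored in
#' between. Additionally every ground truth forces its own best-overlapping
#' anchor positive so no lesion goes unsupervised.
#'
#' @param anchor_boxes Anchor boxes (clipped), n-by-6.
#' @param gt_boxes Ground-truth boxes, m-by-6 (may have zero rows).
#' @param iou_pos,iou_neg Assignment thresholds, `iou_neg <= iou_pos`.
#' @param ignore_boxes Optional regions excluded from the negative class:
#'   a non-positive anchor overlapping one of these at
#'   `IoU >= ignore_iou` is marked ignore. Used when training on sparse
#'   pseudo labels, where unselected plausible-lesion regions must not
#'   act as hard negatives.
#' @param ignore_iou Overlap at which `ignore_boxes` shield an anchor;
#'   deliberately loose (0.1), since a small plausible lesion rarely
#'   reaches the `iou_neg` band with any anchor.
#' @return A list with `cls` (+1 positive, 0 negative, NA ignore) and
#'   `gt_index` (matched ground truth for positives, NA otherwise).
#' @export
assign_anchors <- function(anchor_boxes, gt_boxes, iou_pos = 0.5,
                           iou_neg = 0.4, ignore_boxes = NULL,
                           ignore_iou = 0.1) {
  if (iou_neg > iou_pos) stop("iou_neg must be <= iou_pos")
  a <- as_box_matrix(anchor_boxes)
  g <- as_box_matrix(gt_boxes)
  n <- nrow(a)
  cls <- rep(0, n)
  gt_index <- rep(NA_integer_, n)
  if (!is.null(ignore_boxes)) {
    ig <- as_box_matrix(ignore_boxes)
    if (nrow(ig)) {
      ig_iou <- iou_matrix(a, ig)
      cls[apply(ig_iou, 1L, max) >= ignore_iou] <- NA
    }
  }
  if (nrow(g) == 0L) return(list(cls = cls, gt_index = gt_index))
  iou <- iou_matrix(a, g)
  best <- max.col(iou, ties.method = "first")
  best_iou <- iou[cbind(seq_len(n), best)]
  cls[best_iou >= iou_pos] <- 1
  cls[best_iou >= iou_neg & best_iou < iou_pos] <- NA
  ## best-match forcing: each GT claims its top anchor
  for (j in seq_len(nrow(g))) {
    i <- which.max(iou[, j])
    cls[i] <- 1
    best[i] <- j
  }
  gt_index[cls %in% 1] <- best[cls %in% 1]
  list(cls = cls, gt_index = gt_index)
}

#' Focal loss
#'
#' `-alpha_t * (1 - p_t)^gamma * log(p_t)` with `p_t = p` for the positive
#' class and `1 - p` otherwise; `alpha_t` is `alpha_bal` for positives and
#' `1 - alpha_bal` for negatives. With `gamma = 0`, `alpha_bal = 1` this
#' reduces to cross-entropy. Probabilities are clamped away from 0/1.
#'
#' @param p Predicted probabilities.
#' @param cls Labels in `{0, 1}`.
#' @param gamma Focusing exponent (default 2).
#' @param alpha_bal Positive-class balance weight (default 0.25).
#' @return Elementwise non-negative losses.
#' @export
focal_loss <- function(p, cls, gamma = 2, alpha_bal = 0.25) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  pt <- ifelse(cls == 1, p, 1 - p)
  at <- ifelse(cls == 1, alpha_bal, 1 - alpha_bal)
  if (isTRUE(all.equal(alpha_bal, 1))) at <- rep(1, length(p))
  -at * (1 - pt)^gamma * log(pt)
}

## d(focal)/d(logit), elementwise; same clamping as focal_loss.
focal_grad_logit <- function(p, cls, gamma = 2, alpha_bal = 0.25) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  pt <- ifelse(cls == 1, p, 1 - p)
  at <- ifelse(cls == 1, alpha_bal, 1 - alpha_bal)
  if (isTRUE(all.equal(alpha_bal, 1))) at <- rep(1, length(p))
  dl_dpt <- at * (gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt)
  dpt_dz <- ifelse(cls == 1, 1, -1) * pt * (1 - pt)
  dl_dpt * dpt_dz
}

#' Smooth-L1 (Huber-style) regression loss
#'
#' Quadratic for residuals below `delta`, linear beyond, summed over the
#' six box parameters of each row.
#'
#' @param t,t_hat Matrices (or 6-vectors) of predicted and target box
#'   parameters.
#' @param delta Transition point (default 1).
#' @return Per-row non-negative losses.
#' @export
smooth_l1 <- function(t, t_hat, delta = 1) {
  t <- matrix(as.numeric(t), ncol = 6L)
  t_hat <- matrix(as.numeric(t_hat), ncol = 6L)
  if (!all(dim(t) == dim(t_hat))) stop("shape mismatch")
  d <- abs(t - t_hat)
  l <- ifelse(d < delta, 0.5 * d^2 / delta, d - 0.5 * delta)
  rowSums(l)
}

smooth_l1_grad <- function(t, t_hat, delta = 1) {
  d <- t - t_hat
  pmin(pmax(d / delta, -1), 1)
}

#' Combined detection loss
#'
#' Focal classification loss over all non-ignored anchors plus smooth-L1
#' regression loss over positive anchors, each normalized by the number of
#' positives (at least 1). Normalization keeps the scale comparable across
#' crops with different lesion counts.
#'
#' @param p Predicted probabilities, one per anchor.
#' @param t_pred n-by-6 predicted regression parameters.
#' @param assignment Output of [assign_anchors()].
#' @param t_target n-by-6 regression targets (rows for non-positives are
#'   ignored).
#' @param gamma,alpha_bal,delta Loss hyperparameters.
#' @return A scalar loss.
#' @export
detection_loss <- function(p, t_pred, assignment, t_target,
                           gamma = 2, alpha_bal = 0.25, delta = 1) {
  cls <- assignment$cls
  use <- !is.na(cls)
  npos <- max(1, sum(cls %in% 1))
  cl <- sum(focal_loss(p[use], cls[use], gamma, alpha_bal))
  pos <- which(cls %in% 1)
  rl <- if (length(pos)) {
    sum(smooth_l1(t_pred[pos, , drop = FALSE],
                  t_target[pos, , drop = FALSE], delta))
  } else 0
  (cl + rl) / npos
}

## ---- multi-scale box-filter features ----

## Zero-padded 3D integral image: I[i+1,j+1,k+1] = sum v[1:i,1:j,1:k].
integral3d <- function(v) {
  d <- dim(v)
  I <- array(0, d + 1L)
  I[-1L, -1L, -1L] <- v
  I <- apply(I, c(2L, 3L), cumsum)            # over dim 1 -> dims (1,2,3)
  I <- aperm(apply(I, c(1L, 3L), cumsum), c(2L, 1L, 3L))
  I <- aperm(apply(I, c(1L, 2L), cumsum), c(2L, 3L, 1L))
  I
}

## Separable running-max filter: per axis, max over offsets -rad..rad
## with edge clamping. Composing the three axes gives the cube max.
maxfilt3d <- function(v, rad) {
  d <- dim(v)
  for (ax in 1:3) {
    out <- v
    for (off in seq_len(rad)) {
      idx_lo <- pmax(seq_len(d[ax]) - off, 1L)
      idx_hi <- pmin(seq_len(d[ax]) + off, d[ax])
      if (ax == 1L) {
        out <- pmax(out, v[idx_lo, , , drop = FALSE],
                    v[idx_hi, , , drop = FALSE])
      } else if (ax == 2L) {
        out <- pmax(out, v[, idx_lo, , drop = FALSE],
                    v[, idx_hi, , drop = FALSE])
      } else {
        out <- pmax(out, v[, , idx_lo, drop = FALSE],
                    v[, , idx_hi, drop = FALSE])
      }
    }
    v <- out
  }
  v
}

## Mean of v over the clipped cube of half-width rad around integer voxel
## centers (1-based, n-by-3), vectorized over centers. `I` is integral3d(v).
box_mean_at <- function(I, d, centers, rad) {
  lo <- pmax(centers - rad, 1L)
  hi <- pmin(centers + rad, matrix(d, nrow(centers), 3L, byrow = TRUE))
  cnt <- (hi[, 1] - lo[, 1] + 1) * (hi[, 2] - lo[, 2] + 1) *
    (hi[, 3] - lo[, 3] + 1)
  at <- function(x, y, z) {
    I[cbind(x + 1L, y + 1L, z + 1L)]
  }
  s <- at(hi[, 1], hi[, 2], hi[, 3]) - at(lo[, 1] - 1L, hi[, 2], hi[, 3]) -
    at(hi[, 1], lo[, 2] - 1L, hi[, 3]) - at(hi[, 1], hi[, 2], lo[, 3] - 1L) +
    at(lo[, 1] - 1L, lo[, 2] - 1L, hi[, 3]) +
    at(lo[, 1] - 1L, hi[, 2], lo[, 3] - 1L) +
    at(hi[, 1], lo[, 2] - 1L, lo[, 3] - 1L) -
    at(lo[, 1] - 1L, lo[, 2] - 1L, lo[, 3] - 1L)
  s / cnt
}

#' Multi-scale features at grid points
#'
#' The fixed feature extractor of the compact reference detector: local
#' cube means of the two z-scored channels at several radii, two
#' center-surround contrasts on the PET-like channel, and six directional
#' asymmetry features (shifted-cube differences along each axis) that make
#' center-offset regression possible for a linear head. An intercept
#' column is appended.
#'
#' @param pet,ct 3D arrays of equal dimension.
#' @param stride Grid stride in voxels.
#' @return A list with `feat` (`G`-by-`F+1` matrix, last column 1) and
#'   `grid` (grid centers in continuous voxel coordinates).
#' @export
featurize_volume <- function(pet, ct, stride = 4L) {
  d <- dim(pet)
  if (!all(dim(ct) == d)) stop("channel shape mismatch")
  g_axis <- pmax(1L, d %/% stride)
  ax <- lapply(1:3, function(i) {
    pmin(pmax(as.integer(round((seq_len(g_axis[i]) - 0.5) * stride + 0.5)),
              1L), d[i])
  })
  ctr <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  Ip <- integral3d(pet)
  Ic <- integral3d(ct)
  m <- function(I, rad, off = c(0L, 0L, 0L)) {
    cs <- sweep(ctr, 2L, off, `+`)
    cs <- pmin(pmax(cs, 1L), matrix(d, nrow(cs), 3L, byrow = TRUE))
    box_mean_at(I, d, cs, rad)
  }
  p1 <- m(Ip, 1L); p2 <- m(Ip, 2L); p4 <- m(Ip, 4L); p8 <- m(Ip, 8L)
  px1 <- maxfilt3d(pet, 1L)[ctr]
  px2 <- maxfilt3d(pet, 2L)[ctr]
  feat <- cbind(
    pet0 = pet[ctr], pet1 = p1, pet2 = p2, pet4 = p4, pet8 = p8,
    pmax1 = px1, pmax2 = px2, pkcon = px2 - p8,
    ct0 = ct[ctr], ct2 = m(Ic, 2L), ct8 = m(Ic, 8L),
    con14 = p1 - p4, con28 = p2 - p8,
    dx3 = m(Ip, 2L, c(3L, 0L, 0L)) - m(Ip, 2L, c(-3L, 0L, 0L)),
    dy3 = m(Ip, 2L, c(0L, 3L, 0L)) - m(Ip, 2L, c(0L, -3L, 0L)),
    dz3 = m(Ip, 2L, c(0L, 0L, 3L)) - m(Ip, 2L, c(0L, 0L, -3L)),
    dx6 = m(Ip, 4L, c(6L, 0L, 0L)) - m(Ip, 4L, c(-6L, 0L, 0L)),
    dy6 = m(Ip, 4L, c(0L, 6L, 0L)) - m(Ip, 4L, c(0L, -6L, 0L)),
    dz6 = m(Ip, 4L, c(0L, 0L, 6L)) - m(Ip, 4L, c(0L, 0L, -6L)),
    bias = 1
  )
  grid <- as.matrix(expand.grid(
    x = (seq_len(g_axis[1]) - 0.5) * stride,
    y = (seq_len(g_axis[2]) - 0.5) * stride,
    z = (seq_len(g_axis[3]) - 0.5) * stride
  ))
  list(feat = feat, grid = grid, dim = d, stride = stride)
}

N_FEATURES <- 20L # 19 features + intercept

## ---- the compact MLP-head detector ----

#' Compact CPU-scale anchor-based detector
#'
#' A deliberately small reference implementation of the detector contract:
#' a one-hidden-layer ReLU network over the fixed multi-scale box-filter
#' features of [featurize_volume()], with per-anchor sigmoid
#' classification and 6-parameter box regression heads, at a single
#' stride-4 feature level. Together with the average-pooling feature
#' stage this is a tiny two-layer convolutional detector; the hidden
#' layer matters because distractor suppression is non-monotone in
#' brightness (a blob can be too bright to be a lesion), which no linear
#' head can express. Trained with the focal + smooth-L1 detection loss
#' by exact backpropagation and Adam. Any detector honouring the same
#' predict/train surface can be substituted.
#'
#' @param K Number of anchor shapes.
#' @param stride Feature grid stride in voxels.
#' @param hidden Hidden layer width.
#' @param lr Adam learning rate.
#' @param seed Seed for the weight initialization.
#' @return An object of class `c("mini_detector", "lesion_detector")`.
#' @export
mini_detector <- function(K = 3, stride = 4L, hidden = 48L, lr = 1e-2,
                          seed = 1) {
  Ff <- N_FEATURES
  H <- as.integer(hidden)
  init <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(Ff * H, sd = sqrt(2 / Ff)), Ff, H),
    Wc = matrix(stats::rnorm((H + 1L) * K, sd = 0.01), H + 1L, K),
    Wr = matrix(stats::rnorm((H + 1L) * 6 * K, sd = 0.01), H + 1L, 6 * K)
  ))
  ## classification bias starts low: almost everything is background
  init$Wc[H + 1L, ] <- -2
  zero <- function(m) m * 0
  structure(list(
    W1 = init$W1, Wc = init$Wc, Wr = init$Wr,
    K = as.integer(K), H = H, stride = as.integer(stride),
    lr = lr, gamma = 1, alpha_bal = 0.5, delta = 1,
    iou_pos = 0.5, iou_neg = 0.4, score_floor = 0.05,
    opt = list(t = 0L,
               m = lapply(init, zero), v = lapply(init, zero))
  ), class = c("mini_detector", "lesion_detector"))
}

## Forward pass on cached features. Returns hidden activations and the
## head outputs: probabilities (G x K), regression parameters (G x 6K).
detector_forward <- function(det, feat) {
  A <- feat %*% det$W1
  A[A < 0] <- 0
  Ab <- cbind(A, 1)
  z <- Ab %*% det$Wc
  list(A = A, Ab = Ab, z = z, p = 1 / (1 + exp(-z)), t = Ab %*% det$Wr)
}

#' One optimization step on a batch of samples
#'
#' Computes the normalized detection loss and its exact gradient through
#' the network on each sample (using cached features where present),
#' averages gradients over the batch and applies one Adam update.
#'
#' @param det A [mini_detector()].
#' @param batch A list of subject samples (see [generate_subject()]); each
#'   may carry a precomputed `features` entry.
#' @param anchors An [anchor_set()].
#' @return The updated detector, with the batch loss in `$last_loss`.
#' @export
detector_train_step <- function(det, batch, anchors) {
  UseMethod("detector_train_step")
}

#' @export
detector_train_step.mini_detector <- function(det, batch, anchors) {
  g <- list(W1 = det$W1 * 0, Wc = det$Wc * 0, Wr = det$Wr * 0)
  H <- det$H
  total <- 0
  for (s in batch) {
    fv <- s$features %||% featurize_volume(s$pet, s$ct, det$stride)
    grid <- build_anchor_grid(fv$dim, det$stride, anchors)
    fw <- detector_forward(det, fv$feat)
    G <- nrow(fv$feat)
    K <- det$K
    asg <- assign_anchors(grid$boxes, s$boxes, det$iou_pos, det$iou_neg,
                          ignore_boxes = s$ignore_boxes)
    cls <- matrix(asg$cls, G, K)      # rows grid, cols anchor shape
    p <- fw$p
    npos <- max(1, sum(cls %in% 1, na.rm = TRUE))
    use <- !is.na(cls)
    ## classification branch
    dZ <- matrix(0, G, K)
    dZ[use] <- focal_grad_logit(p[use], cls[use], det$gamma, det$alpha_bal)
    dZ <- dZ / npos
    loss_cl <- sum(focal_loss(p[use], cls[use], det$gamma, det$alpha_bal)) /
      npos
    ## regression branch on positives
    dT <- matrix(0, G, 6 * K)
    loss_rg <- 0
    pos <- which(!is.na(asg$cls) & asg$cls == 1)
    if (length(pos)) {
      gt <- as_box_matrix(s$boxes)[asg$gt_index[pos], , drop = FALSE]
      tt <- encode_boxes(gt, grid$centers[pos, , drop = FALSE],
                         grid$extents[pos, , drop = FALSE])
      gi <- ((pos - 1L) %% G) + 1L    # grid row
      ki <- ((pos - 1L) %/% G) + 1L   # anchor shape
      tp <- matrix(0, length(pos), 6L)
      for (c6 in 1:6) tp[, c6] <- fw$t[cbind(gi, (ki - 1L) * 6L + c6)]
      loss_rg <- sum(smooth_l1(tp, tt, det$delta)) / npos
      gr <- smooth_l1_grad(tp, tt, det$delta) / npos
      for (c6 in 1:6) {
        idx <- cbind(gi, (ki - 1L) * 6L + c6)
        dT[idx] <- dT[idx] + gr[, c6]
      }
    }
    ## backprop
    g$Wc <- g$Wc + crossprod(fw$Ab, dZ)
    g$Wr <- g$Wr + crossprod(fw$Ab, dT)
    dA <- tcrossprod(dZ, det$Wc[seq_len(H), , drop = FALSE]) +
      tcrossprod(dT, det$Wr[seq_len(H), , drop = FALSE])
    dA[fw$A <= 0] <- 0
    g$W1 <- g$W1 + crossprod(fv$feat, dA)
    total <- total + loss_cl + loss_rg
  }
  nb <- length(batch)
  det <- adam_step(det, lapply(g, function(x) x / nb))
  det$last_loss <- total / nb
  det
}

adam_step <- function(det, grads, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  o <- det$opt
  o$t <- o$t + 1L
  for (nm in names(grads)) {
    o$m[[nm]] <- b1 * o$m[[nm]] + (1 - b1) * grads[[nm]]
    o$v[[nm]] <- b2 * o$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mh <- o$m[[nm]] / (1 - b1^o$t)
    vh <- o$v[[nm]] / (1 - b2^o$t)
    det[[nm]] <- det[[nm]] - det$lr * mh / (sqrt(vh) + eps)
  }
  det$opt <- o
  det
}

#' Detector inference on one volume
#'
#' Deterministic forward pass: anchors are tiled over the volume, logits
#' are mapped through a sigmoid, regressions are decoded against the
#' anchors, boxes are clipped to the volume, and detections below the
#' score floor (0.05) are dropped. No NMS is applied here — cleaning is
#' the selection stage's job.
#'
#' @param det A detector object.
#' @param sample A subject sample (needs `pet` and `ct`; an attached
#'   `features` entry is reused).
#' @param anchors An [anchor_set()].
#' @param max_det Cap on returned detections (highest scores kept).
#' @return A detections data frame sorted by score descending.
#' @export
detector_predict <- function(det, sample, anchors, max_det = 200L) {
  UseMethod("detector_predict")
}

#' @export
detector_predict.mini_detector <- function(det, sample, anchors,
                                             max_det = 200L) {
  fv <- sample$features %||% featurize_volume(sample$pet, sample$ct,
                                              det$stride)
  grid <- build_anchor_grid(fv$dim, det$stride, anchors)
  fw <- detector_forward(det, fv$feat)
  G <- nrow(fv$feat)
  K <- det$K
  p <- as.numeric(fw$p)             # column-major: matches grid row order
  keep <- which(p >= det$score_floor)
  if (length(keep) == 0L) return(empty_detections())
  gi <- ((keep - 1L) %% G) + 1L
  ki <- ((keep - 1L) %/% G) + 1L
  t6 <- matrix(0, length(keep), 6L)
  for (c6 in 1:6) t6[, c6] <- fw$t[cbind(gi, (ki - 1L) * 6L + c6)]
  t6[, 4:6] <- pmin(pmax(t6[, 4:6], -2), 2)  # guard extreme size ratios
  boxes <- decode_boxes(t6, grid$centers[keep, , drop = FALSE],
                        grid$extents[keep, , drop = FALSE])
  ## clip to volume, drop degenerates
  d <- fv$dim
  boxes[, 1:3] <- pmax(boxes[, 1:3], 0)
  for (ax in 1:3) boxes[, ax + 3L] <- pmin(boxes[, ax + 3L], d[ax])
  ok <- boxes[, 4] > boxes[, 1] & boxes[, 5] > boxes[, 2] &
    boxes[, 6] > boxes[, 3]
  boxes <- boxes[ok, , drop = FALSE]
  sc <- p[keep][ok]
  out <- detections(boxes, sc)
  ord <- order(-out$score, seq_len(nrow(out)))
  out <- out[utils::head(ord, max_det), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sliding-window inference
#'
#' Volumes larger than the working window are tiled with the requested
#' overlap; per-window detections are shifted to global coordinates and
#' merged with NMS at IoU 0.25 so a lesion straddling a seam is reported
#' once. A volume that fits in a single window is passed through
#' [detector_predict()] unchanged.
#'
#' @param det A detector object.
#' @param sample A subject sample.
#' @param anchors An [anchor_set()].
#' @param window Window extents in voxels.
#' @param overlap Fractional overlap between neighbouring windows.
#' @param merge_iou NMS threshold for the seam merge.
#' @return A detections data frame.
#' @export
sliding_window_predict <- function(det, sample, anchors,
                                   window = c(96L, 96L, 96L),
                                   overlap = 0.5, merge_iou = 0.25) {
  d <- dim(sample$pet)
  window <- pmin(as.integer(window), d)
  starts <- lapply(1:3, function(ax) {
    if (d[ax] <= window[ax]) return(0L)
    step <- max(1L, as.integer(round(window[ax] * (1 - overlap))))
    unique(c(seq(0L, d[ax] - window[ax], by = step), d[ax] - window[ax]))
  })
  origins <- as.matrix(expand.grid(starts[[1]], starts[[2]], starts[[3]]))
  if (nrow(origins) == 1L) {
    return(detector_predict(det, sample, anchors))
  }
  pooled <- empty_detections()
  for (i in seq_len(nrow(origins))) {
    o <- origins[i, ]
    xs <- (o[1] + 1L):(o[1] + window[1])
    ys <- (o[2] + 1L):(o[2] + window[2])
    zs <- (o[3] + 1L):(o[3] + window[3])
    sub <- list(pet = sample$pet[xs, ys, zs, drop = FALSE],
                ct = sample$ct[xs, ys, zs, drop = FALSE])
    dets <- detector_predict(det, sub, anchors)
    if (nrow(dets)) {
      dets[, 1:3] <- sweep(as.matrix(dets[, 1:3]), 2L, o, `+`)
      dets[, 4:6] <- sweep(as.matrix(dets[, 4:6]), 2L, o, `+`)
      pooled <- rbind(pooled, dets)
    }
  }
  if (nrow(pooled) == 0L) return(pooled)
  nms3d(pooled, merge_iou)
}

## ---- oracle detector (for prior-recovery experiments) ----

#' Oracle detector
#'
#' A detector-contract stand-in that returns each subject's ground-truth
#' boxes at score 1 plus seeded low-score distractor boxes. Used to study
#' the prior-estimation machinery in isolation from detector quality: with
#' the default `fp_score_max` below the 0.5 confidence gate, the cleaned
#' candidate sets equal the true label sets.
#'
#' @param n_fp Mean number of false-positive boxes per subject (Poisson).
#' @param fp_score_max Upper bound on false-positive scores.
#' @param seed Seed for the distractor stream.
#' @return An object of class `c("oracle_detector", "lesion_detector")`.
#' @export
oracle_detector <- function(n_fp = 5, fp_score_max = 0.45, seed = 1) {
  structure(list(n_fp = n_fp, fp_score_max = fp_score_max, seed = seed,
                 calls = 0L),
            class = c("oracle_detector", "lesion_detector"))
}

#' @export
detector_predict.oracle_detector <- function(det, sample, anchors,
                                             max_det = 200L) {
  gt <- as_box_matrix(sample$boxes)
  out <- if (nrow(gt)) detections(gt, rep(1, nrow(gt))) else
    empty_detections()
  sd_sub <- derive_seed(det$seed, sample$id %||% 0L)
  d <- if (!is.null(sample$pet)) dim(sample$pet) else sample$dim
  fp <- with_seed(sd_sub, {
    n <- stats::rpois(1L, det$n_fp)
    if (n > 0L) {
      ext <- matrix(stats::runif(3 * n, 2, 8), n, 3)
      lo <- sapply(1:3, function(ax) stats::runif(n, 0, d[ax] - ext[, ax]))
      lo <- matrix(lo, n, 3)
      list(boxes = cbind(lo, lo + ext),
           score = stats::runif(n, 0.05, det$fp_score_max))
    } else NULL
  })
  if (!is.null(fp)) {
    b <- fp$boxes
    colnames(b) <- BOX_COLS
    out <- rbind(out, detections(b, fp$score))
  }
  out[order(-out$score, seq_len(nrow(out))), , drop = FALSE]
}

#' @export
detector_train_step.oracle_detector <- function(det, batch, anchors) {
  det$last_loss <- 0
  det
}
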