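## Shared fixtures: small deterministic boxes, detections and volumes.

rand_boxes <- function(n, dim = c(20, 20, 20), max_ext = 8, seed = 1) {
  if (n == 0) {
    m <- matrix(numeric(0), 0, 6)
    colnames(m) <- c("x0", "y0", "z0", "x1", "y1", "z1")
    return(m)
  }
  set.seed(seed)
  lo <- cbind(runif(n, 0, dim[1] - 1), runif(n, 0, dim[2] - 1),
              runif(n, 0, dim[3] - 1))
  ext <- matrix(runif(3 * n, 0.5, max_ext), n, 3)
  hi <- pmin(lo + ext, matrix(dim, n, 3, byrow = TRUE))
  b <- cbind(lo, hi)
  colnames(b) <- c("x0", "y0", "z0", "x1", "y1", "z1")
  b
}

rand_detections <- function(n, dim = c(20, 20, 20), seed = 1) {
  b <- rand_boxes(n, dim, seed = seed)
  set.seed(seed + 1)
  d <- as.data.frame(b)
  d$score <- round(runif(n), 3)
  d
}

## Brute-force greedy NMS oracle: O(n^2), no cleverness.
nms_oracle <- function(dets, thr) {
  ord <- order(-dets$score, seq_len(nrow(dets)))
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (iou3d(as.numeric(dets[i, 1:6]), as.numeric(dets[j, 1:6])) >= thr) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  dets[kept[order(-dets$score[kept], kept)], , drop = FALSE]
}

## Largest-remainder apportionment oracle, written independently.
quota_oracle <- function(h, n) {
  frac <- h * n
  base <- floor(frac)
  rem <- frac - base
  give <- n - sum(base)
  if (give > 0) {
    ord <- order(-rem, seq_along(h))
    for (i in ord[seq_len(give)]) base[i] <- base[i] + 1
  }
  as.integer(base)
}

## Greedy score-ordered matching oracle.
match_oracle <- function(dets, gts, thr) {
  taken <- rep(FALSE, nrow(gts))
  tp <- rep(FALSE, nrow(dets))
  for (i in order(-dets$score, seq_len(nrow(dets)))) {
    best <- 0; bj <- 0
    for (j in seq_len(nrow(gts))) {
      if (taken[j]) next
      v <- iou3d(as.numeric(dets[i, 1:6]), as.numeric(gts[j, ]))
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0 && best >= thr) { tp[i] <- TRUE; taken[bj] <- TRUE }
  }
  tp
}

## Independent AP recomputation: explicit PR curve + envelope integration.
ap_oracle <- function(dets, gts, thr) {
  rows <- NULL
  npos <- 0
  for (k in seq_along(dets)) {
    g <- gts[[k]]
    npos <- npos + nrow(g)
    d <- dets[[k]]
    if (nrow(d) == 0) next
    tp <- match_oracle(d, g, thr)
    rows <- rbind(rows, data.frame(score = d$score, tp = tp, subj = k,
                                   idx = seq_len(nrow(d))))
  }
  if (is.null(rows) || nrow(rows) == 0) return(0)
  rows <- rows[order(-rows$score, rows$subj, rows$idx), ]
  tp <- cumsum(rows$tp); fp <- cumsum(!rows$tp)
  rec <- tp / npos
  prec <- tp / (tp + fp)
  area <- 0
  prev_r <- 0
  for (i in seq_along(rec)) {
    env <- max(prec[i:length(prec)])
    area <- area + (rec[i] - prev_r) * env
    prev_r <- rec[i]
  }
  area
}

tiny_sample <- function(seed = 1, shape = c(32, 32, 32)) {
  specs <- default_domain_specs()
  normalize_channels(generate_subject(specs$fdg, shape, seed = seed))
}
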