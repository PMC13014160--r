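BOX_COLS <- c("x0", "y0", "z0", "x1", "y1", "z1")

#' Construct axis-aligned 3D boxes
#'
#' Boxes live in 0-based voxel coordinates with the half-open convention
#' `[x0, x1) x [y0, y1) x [z0, z1)`, so a one-voxel box at index `(i, j, k)`
#' is `c(i, j, k, i + 1, j + 1, k + 1)` and voxel extents are simple
#' coordinate differences.
#'
#' @param x A numeric vector of length 6 (`x0, y0, z0, x1, y1, z1`), an
#'   n-by-6 matrix, or a data frame with those columns.
#' @return A numeric matrix with one row per box and columns
#'   `x0, y0, z0, x1, y1, z1`.
#' @examples
#' box3d(c(0, 0, 0, 2, 2, 2))
#' @export
box3d <- function(x) {
  b <- as_box_matrix(x)
  validate_boxes(b)
  b
}

## Coerce without validating; internal fast path.
as_box_matrix <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(BOX_COLS %in% names(x)))
    b <- as.matrix(x[, BOX_COLS, drop = FALSE])
  } else if (is.matrix(x)) {
    b <- x
    if (ncol(b) != 6L) stop("boxes must have 6 columns")
  } else {
    if (length(x) %% 6L != 0L) stop("boxes must have 6 coordinates")
    b <- matrix(as.numeric(x), ncol = 6L, byrow = TRUE)
  }
  storage.mode(b) <- "double"
  colnames(b) <- BOX_COLS
  b
}

validate_boxes <- function(b) {
  if (nrow(b) == 0L) return(invisible(b))
  if (any(!is.finite(b))) stop("invalid box: non-finite coordinates")
  ext <- box_extents(b)
  if (any(ext <= 0)) stop("invalid box: zero or negative extent")
  invisible(b)
}

box_extents <- function(b) {
  b <- as_box_matrix(b)
  b[, 4:6, drop = FALSE] - b[, 1:3, drop = FALSE]
}

empty_boxes <- function() {
  m <- matrix(numeric(0), ncol = 6L)
  colnames(m) <- BOX_COLS
  m
}

#' Voxel spacing
#'
#' @param dx,dy,dz Voxel edge lengths in millimetres; all strictly positive.
#' @return A named numeric vector of class `"spacing"`.
#' @examples
#' spacing(4, 4, 5) # the working whole-body PET/CT spacing
#' @export
spacing <- function(dx, dy, dz = dy) {
  s <- c(dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz))
  if (any(!is.finite(s)) || any(s <= 0)) stop("spacing must be positive")
  class(s) <- "spacing"
  s
}

#' Intersection over union of 3D boxes
#'
#' Pairwise IoU of two boxes, or (with matrix inputs) the full IoU matrix
#' between two box sets. Symmetric; 0 for disjoint boxes, 1 only for
#' identical boxes.
#'
#' @param a,b Boxes as accepted by [box3d()].
#' @return A scalar for two single boxes, otherwise an
#'   `nrow(a)`-by-`nrow(b)` matrix.
#' @examples
#' iou3d(c(0, 0, 0, 2, 2, 2), c(1, 0, 0, 3, 2, 2)) # 1/3
#' @export
iou3d <- function(a, b) {
  a <- box3d(a)
  b <- box3d(b)
  m <- iou_matrix(a, b)
  if (nrow(a) == 1L && nrow(b) == 1L) m[1L, 1L] else m
}

## IoU matrix without revalidation (callers validate once).
iou_matrix <- function(a, b) {
  na <- nrow(a)
  nb <- nrow(b)
  if (na == 0L || nb == 0L) return(matrix(numeric(0), na, nb))
  inter <- matrix(1, na, nb)
  for (ax in 1:3) {
    lo <- outer(a[, ax], b[, ax], pmax)
    hi <- outer(a[, ax + 3L], b[, ax + 3L], pmin)
    inter <- inter * pmax(hi - lo, 0)
  }
  vola <- apply(box_extents(a), 1L, prod)
  volb <- apply(box_extents(b), 1L, prod)
  un <- outer(vola, volb, `+`) - inter
  pmin(pmax(inter / un, 0), 1) # clamp float jitter at the boundaries
}

#' Greedy 3D non-maximum suppression
#'
#' Detections are processed in descending score order; a detection is
#' suppressed when its IoU with an already-retained detection reaches
#' `iou_thr`. Ties in score are broken by input order (earlier wins), so the
#' result is deterministic.
#'
#' @param dets A data frame of detections with box columns and a `score`
#'   column in `[0, 1]`.
#' @param iou_thr Suppression threshold in `(0, 1)`; overlaps with
#'   `IoU >= iou_thr` are removed. Candidate cleaning uses 0.25.
#' @return The retained detections, sorted by score descending.
#' @export
nms3d <- function(dets, iou_thr = 0.25) {
  if (iou_thr <= 0 || iou_thr >= 1) stop("iou_thr must be in (0,1)")
  dets <- as_detections(dets)
  n <- nrow(dets)
  if (n <= 1L) return(dets)
  b <- box3d(dets)
  ord <- order(-dets$score, seq_len(n))
  iou <- iou_matrix(b, b)
  keep <- logical(n)
  alive <- rep(TRUE, n)
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[iou[i, ] >= iou_thr] <- FALSE
  }
  out <- dets[keep, , drop = FALSE]
  out <- out[order(-out$score, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Normalize a detections data frame: box columns + score.
as_detections <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L) ||
      (is.matrix(x) && nrow(x) == 0L)) {
    return(empty_detections())
  }
  if (!is.data.frame(x)) stop("detections must be a data.frame")
  if (!"score" %in% names(x)) stop("detections need a 'score' column")
  if (any(x$score < 0 | x$score > 1)) stop("scores must lie in [0,1]")
  out <- as.data.frame(as_box_matrix(x))
  out$score <- as.numeric(x$score)
  out
}

empty_detections <- function() {
  out <- as.data.frame(empty_boxes())
  out$score <- numeric(0)
  out
}

detections <- function(boxes, score) {
  boxes <- as_box_matrix(boxes)
  out <- as.data.frame(boxes)
  out$score <- as.numeric(score)
  as_detections(out)
}

#' Box volume in cubic centimetres
#'
#' @param boxes Boxes as accepted by [box3d()].
#' @param sp A [spacing()] in mm.
#' @return Numeric vector of volumes in cc. A one-voxel box at 4 x 4 x 5 mm
#'   spacing has volume 0.08 cc.
#' @export
box_volume_cc <- function(boxes, sp) {
  b <- box3d(boxes)
  sp <- as_spacing(sp)
  ext <- box_extents(b)
  vox <- ext[, 1L] * ext[, 2L] * ext[, 3L]
  unname(vox * prod(sp) / 1000)
}

as_spacing <- function(sp) {
  if (inherits(sp, "spacing")) return(sp)
  if (length(sp) == 1L) sp <- rep(sp, 3L)
  spacing(sp[[1L]], sp[[2L]], sp[[3L]])
}

#' Drop boxes below a minimum physical volume
#'
#' The discard rule is strict: boxes with volume `< min_cc` are removed, a
#' box at exactly `min_cc` is kept. With the default 0.08 cc threshold at
#' 4 x 4 x 5 mm spacing this removes sub-voxel labels.
#'
#' @inheritParams box_volume_cc
#' @param min_cc Minimum volume in cc (default 0.08).
#' @return The retained boxes, input order preserved.
#' @export
filter_small_boxes <- function(boxes, sp, min_cc = 0.08) {
  if (min_cc < 0) stop("min_cc must be >= 0")
  b <- box3d(boxes)
  if (nrow(b) == 0L) return(b)
  b[box_volume_cc(b, sp) >= min_cc, , drop = FALSE]
}

#' Convert a 3D label mask to tight bounding boxes
#'
#' Foreground voxels (value > 0) are grouped into connected components under
#' 26-connectivity (face, edge and corner neighbours), and each component is
#' wrapped in its tight half-open bounding box. Lesions are blob-like, so
#' the permissive 26-neighbourhood is used to avoid splitting a contiguous
#' region that touches only diagonally.
#'
#' @param mask A 3D array; 0 is background, any positive value foreground.
#' @return An n-by-6 box matrix in 0-based voxel coordinates (one row per
#'   component); zero rows for an empty mask.
#' @export
masks_to_boxes <- function(mask) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  if (any(mask < 0)) stop("mask values must be >= 0")
  lab <- label_components_26(mask > 0)
  k <- attr(lab, "n")
  if (k == 0L) return(empty_boxes())
  idx <- which(lab > 0L)
  comp <- lab[idx]
  co <- arrayInd(idx, dim(mask))
  out <- matrix(0, nrow = k, ncol = 6L, dimnames = list(NULL, BOX_COLS))
  for (ax in 1:3) {
    out[, ax] <- tapply(co[, ax], comp, min) - 1L
    out[, ax + 3L] <- tapply(co[, ax], comp, max) # half-open: max index
  }
  out
}

## 26-connected component labelling by BFS flood fill.
## Returns an integer array of labels (0 = background) with attr "n".
label_components_26 <- function(fg) {
  d <- dim(fg)
  lab <- array(0L, d)
  idx <- which(fg)
  if (length(idx) == 0L) {
    attr(lab, "n") <- 0L
    return(lab)
  }
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0L, , drop = FALSE]
  n_comp <- 0L
  for (seed in idx) {
    if (lab[seed] != 0L) next
    n_comp <- n_comp + 1L
    lab[seed] <- n_comp
    queue <- seed
    while (length(queue) > 0L) {
      co <- arrayInd(queue, d)
      cand <- do.call(rbind, lapply(seq_len(nrow(nb)), function(j) {
        sweep(co, 2L, nb[j, ], `+`)
      }))
      ok <- cand[, 1L] >= 1L & cand[, 1L] <= d[1L] &
        cand[, 2L] >= 1L & cand[, 2L] <= d[2L] &
        cand[, 3L] >= 1L & cand[, 3L] <= d[3L]
      cand <- cand[ok, , drop = FALSE]
      lin <- unique(cand[, 1L] + d[1L] * (cand[, 2L] - 1L) +
                      d[1L] * d[2L] * (cand[, 3L] - 1L))
      lin <- lin[fg[lin] & lab[lin] == 0L]
      lab[lin] <- n_comp
      queue <- lin
    }
  }
  attr(lab, "n") <- n_comp
  lab
}

#' Rasterize boxes into a binary mask
#'
#' Inverse-direction helper for mask/box round trips: marks every voxel
#' covered by any half-open box.
#'
#' @param boxes Boxes as accepted by [box3d()].
#' @param dim Integer volume dimensions.
#' @return A logical 3D array.
#' @export
boxes_to_mask <- function(boxes, dim) {
  b <- box3d(boxes)
  m <- array(FALSE, dim)
  for (i in seq_len(nrow(b))) {
    xs <- max(1L, floor(b[i, 1L]) + 1L):min(dim[1L], ceiling(b[i, 4L]))
    ys <- max(1L, floor(b[i, 2L]) + 1L):min(dim[2L], ceiling(b[i, 5L]))
    zs <- max(1L, floor(b[i, 3L]) + 1L):min(dim[3L], ceiling(b[i, 6L]))
    m[xs, ys, zs] <- TRUE
  }
  m
}
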