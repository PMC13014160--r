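#' Anchor shape set
#'
#' `K` prototype box extents `(w, h, d)` in voxels. Anchors are tiled over
#' feature-map positions; the detector regresses offsets from them, so
#' their fit to the lesion size distribution matters, and they are the
#' quantity adapted across self-training rounds.
#'
#' @param shapes A `K`-by-3 matrix (or coercible) of positive extents in
#'   voxels.
#' @param round Round index the set belongs to (bookkeeping only).
#' @return An object of class `"anchor_set"`; shapes are stored sorted by
#'   volume ascending.
#' @export
anchor_set <- function(shapes, round = 0L) {
  m <- matrix(as.numeric(shapes), ncol = 3L)
  colnames(m) <- c("w", "h", "d")
  if (nrow(m) < 1L) stop("need at least one anchor shape")
  if (any(!is.finite(m)) || any(m <= 0)) stop("anchor extents must be > 0")
  m <- m[order(m[, 1L] * m[, 2L] * m[, 3L]), , drop = FALSE]
  structure(list(shapes = m, K = nrow(m), round = as.integer(round)),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat("anchor_set (round ", x$round, "):\n", sep = "")
  print(round(x$shapes, 2))
  invisible(x)
}

#' k-means estimation of anchor shapes from boxes
#'
#' Clusters box extent triples `(w, h, d)` in voxel space with k-means
#' (k-means++ seeding, Lloyd iterations, Euclidean distance) and returns
#' the `K` centroids sorted by volume. Deterministic for a fixed seed and
#' input order.
#'
#' @param boxes Boxes as accepted by [box3d()]; at least `K` required.
#' @param K Number of shapes (default 3).
#' @param seed RNG seed for the k-means++ initialization.
#' @param init_centers Optional `K`-by-3 matrix of starting centroids
#'   (warm start). Round-wise re-estimation warm-starts from the current
#'   anchors so the EMA tracks one continuous solution path instead of
#'   hopping between local optima of a fresh seeding.
#' @return A `K`-by-3 matrix of extents.
#' @export
kmeans_shapes <- function(boxes, K = 3, seed = 1, init_centers = NULL) {
  b <- box3d(boxes)
  if (nrow(b) < K) stop("insufficient boxes for k-means: need at least K")
  ext <- box_extents(b)
  centers <- if (is.null(init_centers)) {
    with_seed(seed, kmeanspp_centers(ext, K))
  } else {
    matrix(as.numeric(init_centers), ncol = 3L)
  }
  if (K == 1L) {
    cent <- matrix(colMeans(ext), nrow = 1L)
  } else {
    fit <- suppressWarnings(
      stats::kmeans(ext, centers = centers, iter.max = 100L,
                    algorithm = "Lloyd")
    )
    cent <- fit$centers
    ## an emptied cluster (possible when inputs are degenerate) yields a
    ## NaN centroid; park it on the global mean shape
    bad <- !is.finite(cent[, 1L])
    if (any(bad)) cent[bad, ] <- rep(colMeans(ext), each = sum(bad))
  }
  cent <- cent[order(cent[, 1L] * cent[, 2L] * cent[, 3L]), , drop = FALSE]
  dimnames(cent) <- list(NULL, c("w", "h", "d"))
  cent
}

## k-means++ seeding: first center uniform, then proportional to squared
## distance to the nearest chosen center. Duplicate points are tolerated
## (zero-weight rows fall back to uniform choice among unchosen).
kmeanspp_centers <- function(x, K) {
  n <- nrow(x)
  chosen <- integer(K)
  chosen[1L] <- sample.int(n, 1L)
  if (K > 1L) {
    d2 <- rowSums(sweep(x, 2L, x[chosen[1L], ], `-`)^2)
    for (k in 2:K) {
      if (sum(d2) <= 0) {
        pool <- setdiff(seq_len(n), chosen[seq_len(k - 1L)])
        chosen[k] <- pool[sample.int(length(pool), 1L)]
      } else {
        chosen[k] <- sample.int(n, 1L, prob = d2 / sum(d2))
      }
      d2 <- pmin(d2, rowSums(sweep(x, 2L, x[chosen[k], ], `-`)^2))
    }
  }
  centers <- x[chosen, , drop = FALSE]
  ## Perturb exact duplicates so stats::kmeans accepts the centers.
  if (anyDuplicated(centers)) {
    dup <- duplicated(centers)
    centers[dup, ] <- centers[dup, , drop = FALSE] *
      (1 + 1e-6 * seq_len(sum(dup)))
  }
  centers
}

#' EMA update of an anchor set
#'
#' New centroids are paired with the previous shapes by the one-to-one
#' assignment minimizing total squared distance (exhaustive over
#' permutations for small `K`), then blended componentwise:
#' `s_k <- (1 - beta) * s_k_prev + beta * s_k_new`. The optimal pairing
#' avoids pairing drift when cluster volumes cross between rounds.
#'
#' @param prev An [anchor_set()].
#' @param new_shapes A `K`-by-3 matrix of freshly estimated extents.
#' @param beta EMA momentum in `(0, 1)` (default 0.9).
#' @return The updated [anchor_set()] (volume-sorted).
#' @export
ema_update_anchors <- function(prev, new_shapes, beta = 0.9) {
  if (beta <= 0 || beta >= 1) stop("beta must lie in (0,1)")
  new_shapes <- matrix(as.numeric(new_shapes), ncol = 3L)
  if (nrow(new_shapes) != prev$K) stop("anchor count mismatch")
  perm <- match_shapes(prev$shapes, new_shapes)
  blended <- (1 - beta) * prev$shapes + beta * new_shapes[perm, , drop = FALSE]
  anchor_set(blended, round = prev$round + 1L)
}

## One-to-one assignment of new shapes to previous shapes minimizing total
## squared distance. Exhaustive for K <= 7; greedy nearest-neighbour beyond.
match_shapes <- function(prev, new) {
  K <- nrow(prev)
  if (K == 1L) return(1L)
  d2 <- outer(seq_len(K), seq_len(K),
              Vectorize(function(i, j) sum((prev[i, ] - new[j, ])^2)))
  if (K <= 7L) {
    perms <- permutations_of(K)
    costs <- vapply(seq_len(nrow(perms)), function(p) {
      sum(d2[cbind(seq_len(K), perms[p, ])])
    }, numeric(1))
    perms[which.min(costs), ]
  } else {
    perm <- integer(K)
    free <- rep(TRUE, K)
    for (i in seq_len(K)) {
      j <- which(free)[which.min(d2[i, free])]
      perm[i] <- j
      free[j] <- FALSE
    }
    perm
  }
}

permutations_of <- function(K) {
  if (K == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(K - 1L)
  do.call(rbind, lapply(seq_len(K), function(v) {
    rest <- setdiff(seq_len(K), v)
    cbind(v, matrix(rest[sub], nrow(sub)))
  }))
}

#' Round-wise anchor adaptation from selected pseudo labels
#'
#' Pools all pseudo boxes selected in the round, re-estimates `K` shapes by
#' [kmeans_shapes()], and blends them into the previous anchors with
#' [ema_update_anchors()]. If the pool holds fewer than `K` boxes the
#' previous anchors are carried over unchanged.
#'
#' @param selected A list of pseudo-label detection frames (or box
#'   matrices), one per subject.
#' @param prev The previous [anchor_set()].
#' @param K Number of shapes.
#' @param beta EMA momentum.
#' @param seed k-means seed.
#' @return The [anchor_set()] for the next round.
#' @export
anchors_for_round <- function(selected, prev, K = prev$K, beta = 0.9,
                              seed = 1) {
  pool <- do.call(rbind, lapply(selected, function(s) {
    if (is.null(s) || nrow(s) == 0L) return(NULL)
    as_box_matrix(s)
  }))
  if (is.null(pool) || nrow(pool) < K) {
    prev$round <- prev$round + 1L
    return(prev)
  }
  cent <- kmeans_shapes(pool, K = K, seed = seed,
                        init_centers = if (K == prev$K) prev$shapes)
  ema_update_anchors(prev, cent, beta = beta)
}
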