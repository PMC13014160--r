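#' Lesion-volume binning
#'
#' A set of `B` half-open volume bins `[edge_i, edge_{i+1})` in cc. The
#' default covers the clinically relevant range with `B = 10`
#' logarithmically spaced bins from the 0.08 cc label floor up to 150 cc,
#' plus an open final bin for very large (>= 150 cc) lesions.
#'
#' @param edges Strictly increasing numeric vector of `B + 1` boundaries in
#'   cc; the last may be `Inf`.
#' @return An object of class `"size_binning"`.
#' @export
size_binning <- function(edges) {
  edges <- as.numeric(edges)
  if (length(edges) < 2L) stop("need at least 2 edges")
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  structure(list(edges = edges, B = length(edges) - 1L),
            class = "size_binning")
}

#' @rdname size_binning
#' @param B Number of bins.
#' @param min_cc,max_cc Closed lower edge and the boundary of the open top
#'   bin, in cc.
#' @export
default_binning <- function(B = 10, min_cc = 0.08, max_cc = 150) {
  inner <- exp(seq(log(min_cc), log(max_cc), length.out = B))
  size_binning(c(inner, Inf))
}

#' @export
print.size_binning <- function(x, ...) {
  cat("size_binning:", x$B, "bins, edges (cc):",
      paste(signif(x$edges, 3), collapse = " "), "\n")
  invisible(x)
}

#' Map boxes to volume bins
#'
#' @param boxes Boxes as accepted by [box3d()].
#' @param sp A [spacing()].
#' @param binning A [size_binning()].
#' @return Integer bin indices in `1..B`; a volume exactly on an interior
#'   edge goes to the higher bin (half-open convention).
#' @export
bin_of <- function(boxes, sp, binning) {
  v <- box_volume_cc(boxes, sp)
  bin_of_volume(v, binning)
}

bin_of_volume <- function(v, binning) {
  if (any(v < binning$edges[1L])) {
    stop("volume below the first bin edge")
  }
  idx <- findInterval(v, binning$edges, rightmost.closed = FALSE)
  idx[idx > binning$B] <- binning$B # open top bin absorbs the last edge
  as.integer(idx)
}

#' Normalized lesion-volume histogram
#'
#' @inheritParams bin_of
#' @return A length-`B` vector of bin fractions summing to 1.
#' @export
size_histogram <- function(boxes, sp, binning) {
  b <- box3d(boxes)
  if (nrow(b) == 0L) stop("cannot build a histogram from zero boxes")
  idx <- bin_of(b, sp, binning)
  h <- tabulate(idx, nbins = binning$B)
  h / sum(h)
}

#' Target-domain label priors
#'
#' Holds the running estimates of the target label distribution: the mean
#' number of lesions per subject `mu` and the normalized `B`-bin volume
#' histogram `h`, together with their EMA momenta. Both are initialized
#' from source-domain statistics and updated online from target-domain
#' predictions during self-training.
#'
#' @param mu Non-negative mean lesions per subject.
#' @param h Length-`B` non-negative vector summing to 1.
#' @param alpha_mu,alpha_h EMA momenta in `(0, 1)`; the default 0.9 weights
#'   the current round's estimate heavily to stabilize early rounds.
#' @return An object of class `"size_prior"`.
#' @export
size_prior <- function(mu, h, alpha_mu = 0.9, alpha_h = 0.9) {
  if (mu < 0) stop("mu must be >= 0")
  h <- as.numeric(h)
  if (any(h < 0)) stop("h must be non-negative")
  if (abs(sum(h) - 1) > 1e-9) stop("h must sum to 1")
  for (a in c(alpha_mu, alpha_h)) {
    if (a <= 0 || a >= 1) stop("momenta must lie in (0,1)")
  }
  structure(list(mu = mu, h = h, alpha_mu = alpha_mu, alpha_h = alpha_h),
            class = "size_prior")
}

#' @export
print.size_prior <- function(x, ...) {
  cat("size_prior: mu =", format(x$mu, digits = 4),
      "| h =", paste(sprintf("%.3f", x$h), collapse = " "), "\n")
  invisible(x)
}

#' EMA update of the lesions-per-subject mean
#'
#' `mu_new = (1 - alpha_mu) * mu_old + alpha_mu * mean(counts)`; the result
#' always lies between the old value and the new batch mean.
#'
#' @param prior A [size_prior()].
#' @param counts Non-negative per-subject lesion counts (one per target
#'   subject in the round).
#' @return The updated prior.
#' @export
update_mu <- function(prior, counts) {
  if (length(counts) == 0L) stop("need at least one subject count")
  if (any(counts < 0)) stop("counts must be non-negative")
  prior$mu <- (1 - prior$alpha_mu) * prior$mu +
    prior$alpha_mu * mean(counts)
  prior
}

#' EMA update of the size histogram
#'
#' Convex combination `(1 - alpha_h) * h_old + alpha_h * h_hat`, followed by
#' L1 renormalization (a no-op when both terms are normalized, but kept as a
#' guard against numeric drift).
#'
#' @param prior A [size_prior()].
#' @param h_hat Length-`B` non-negative vector summing to 1 (the round's
#'   observed histogram).
#' @return The updated prior.
#' @export
update_histogram <- function(prior, h_hat) {
  h_hat <- as.numeric(h_hat)
  if (length(h_hat) != length(prior$h)) stop("h_hat has the wrong length")
  if (any(h_hat < 0)) stop("h_hat must be non-negative")
  if (abs(sum(h_hat) - 1) > 1e-6) stop("h_hat must sum to 1")
  h <- (1 - prior$alpha_h) * prior$h + prior$alpha_h * h_hat
  prior$h <- h / sum(h)
  prior
}

#' Per-subject pseudo-label budget
#'
#' `ceiling(lambda * mu)`: the integer cap on how many pseudo labels one
#' subject may contribute in a round. The cap exists to stop
#' false-positive-rich scans from dominating; rounding up rather than
#' down matters in small-`mu` regimes, where flooring would return a
#' budget of zero for every subject and permanently stall the
#' self-training bootstrap (at `mu` of ten or more the two rules are
#' practically indistinguishable).
#'
#' @param prior A [size_prior()].
#' @param lam Admission factor in `(0, 1]`.
#' @return A non-negative integer.
#' @export
subject_budget <- function(prior, lam) {
  if (lam <= 0 || lam > 1) stop("lam must lie in (0,1]")
  as.integer(ceiling(lam * prior$mu))
}

#' Largest-remainder quota allocation
#'
#' Distributes an integer budget over bins proportionally to `h`:
#' fractional quotas `h_b * n_allow` are floored and the remaining slots go
#' to the bins with the largest fractional parts. Ties in fractional part
#' are broken toward lower bin index (smaller lesions first).
#'
#' @param h Length-`B` normalized histogram.
#' @param n_allow Non-negative integer budget.
#' @return An integer vector summing exactly to `n_allow`, with each entry
#'   within 1 of its fractional quota.
#' @export
allocate_quotas <- function(h, n_allow) {
  h <- as.numeric(h)
  if (n_allow < 0) stop("n_allow must be >= 0")
  n_allow <- as.integer(n_allow)
  if (n_allow == 0L) return(integer(length(h)))
  frac <- h * n_allow
  q <- as.integer(floor(frac))
  rem <- n_allow - sum(q)
  if (rem > 0L) {
    ord <- order(-(frac - q), seq_along(h))
    q[ord[seq_len(rem)]] <- q[ord[seq_len(rem)]] + 1L
  }
  q
}
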