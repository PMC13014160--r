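#' Domain specification for the dual-tracer simulator
#'
#' Describes one tracer's lesion statistics and appearance: the
#' lesions-per-subject Poisson rate, a log-normal distribution over lesion
#' volume (cc), the lesion-to-background uptake contrast, the rate and
#' intensity of unlabeled physiological distractor blobs (the analogue of
#' brain/myocardium or salivary-gland/kidney uptake, which a detector must
#' learn not to report), and the additive noise level.
#'
#' @param name Domain tag.
#' @param rate Mean lesions per subject (Poisson), `> 0`.
#' @param vol_meanlog,vol_sdlog Parameters of `Lognormal` lesion volume in
#'   cc.
#' @param contrast Lesion peak uptake above background, `> 0`.
#' @param n_distractor Mean number of distractor blobs per subject.
#' @param distractor_contrast Distractor peak uptake above background.
#' @param burst_prob Probability that a subject shows extensive
#'   physiological uptake (a "burst" scan with `burst_factor` times the
#'   distractor rate) — the handful of false-positive-rich scans that a
#'   per-subject pseudo-label budget is meant to keep from dominating.
#' @param burst_factor Distractor-rate multiplier for burst subjects.
#' @param noise_sd SD of additive Gaussian noise on the PET-like channel.
#' @return An object of class `"domain_spec"`.
#' @export
domain_spec <- function(name, rate, vol_meanlog, vol_sdlog, contrast,
                        n_distractor = 3, distractor_contrast = 6,
                        burst_prob = 0.1, burst_factor = 4,
                        noise_sd = 0.5) {
  if (rate <= 0) stop("rate must be > 0")
  if (contrast <= 0) stop("contrast must be > 0")
  structure(list(name = name, rate = rate, vol_meanlog = vol_meanlog,
                 vol_sdlog = vol_sdlog, contrast = contrast,
                 n_distractor = n_distractor,
                 distractor_contrast = distractor_contrast,
                 burst_prob = burst_prob, burst_factor = burst_factor,
                 noise_sd = noise_sd),
            class = "domain_spec")
}

#' Default FDG-like and PSMA-like domain specifications
#'
#' The pair encodes the cross-tracer shift the package targets. Label
#' shift: the PSMA-like domain has about twice the lesion rate (8 vs 4 per
#' subject) with a much smaller median volume (1.5 vs 3 cc), while the
#' FDG-like log-normal has a heavier upper tail, so a larger fraction of
#' its lesions lands in the open >= 150 cc bin. Covariate shift: the
#' PSMA-like domain has lower lesion contrast and more noise, plus one
#' extra distractor blob per subject.
#'
#' @return A list with elements `fdg` and `psma`, each a [domain_spec()].
#' @export
default_domain_specs <- function() {
  list(
    fdg = domain_spec("fdg", rate = 4, vol_meanlog = log(3),
                      vol_sdlog = 1.6, contrast = 4,
                      n_distractor = 3, distractor_contrast = 6,
                      noise_sd = 0.5),
    psma = domain_spec("psma", rate = 8, vol_meanlog = log(1.5),
                       vol_sdlog = 1.0, contrast = 3,
                       n_distractor = 4, distractor_contrast = 6,
                       noise_sd = 0.6)
  )
}

#' Simulate one dual-channel subject volume
#'
#' Generates a PET-like channel (background + soft ellipsoidal lesion
#' blobs + bright unlabeled distractor blobs + Gaussian noise) and a
#' CT-like channel (smooth anatomical background with soft "organ"
#' regions, independent of the lesions). Distractors are preferentially
#' placed near the CT organ regions, so the CT channel carries information
#' a detector can use to suppress them. The label mask contains lesions
#' only; ground-truth boxes are derived from the mask's 26-connected
#' components and filtered at the 0.08 cc floor, so overlapping lesions
#' merge into a single labeled region exactly as mask-derived annotations
#' would.
#'
#' @param spec A [domain_spec()].
#' @param shape Volume dimensions in voxels (each `>= 32`).
#' @param sp A [spacing()] (default the 4 x 4 x 5 mm working spacing).
#' @param seed Subject seed; the same seed reproduces the sample bitwise.
#' @return A subject sample: list with `pet`, `ct`, `mask`, `boxes`,
#'   `spacing`, `domain`, `id`, `lesion_cc` (true per-lesion volumes).
#' @export
generate_subject <- function(spec, shape = c(48L, 48L, 48L),
                             sp = spacing(4, 4, 5), seed = 1) {
  shape <- as.integer(shape)
  if (any(shape < 32L)) stop("shape must be >= 32 per axis")
  sp <- as_spacing(sp)
  with_seed(seed, {
    d <- shape
    ax_mm <- lapply(1:3, function(i) ((seq_len(d[i]) - 0.5) * sp[i]))
    ## CT: smooth gradient + 2 large soft organ blobs
    ct <- outer(outer(ax_mm[[1]] / max(ax_mm[[1]]),
                      ax_mm[[2]] / max(ax_mm[[2]]), `+`) / 2,
                ax_mm[[3]] / max(ax_mm[[3]]), `+`) / 2
    n_org <- 2L
    organ_ctr <- matrix(stats::runif(3 * n_org, 0.2, 0.8), n_org, 3) *
      matrix(d, n_org, 3, byrow = TRUE)
    organ_rad <- stats::runif(n_org, 5, 9) # voxels
    for (o in seq_len(n_org)) {
      ct <- ct + soft_blob(d, organ_ctr[o, ], rep(organ_rad[o], 3)) * 2
    }
    ct <- ct + array(stats::rnorm(prod(d), sd = 0.2), d)
    ## PET background
    pet <- array(1, d) + 0.3 * ct
    mask <- array(0L, d)
    ## lesions
    n_les <- stats::rpois(1L, spec$rate)
    lesion_cc <- numeric(0)
    if (n_les > 0L) {
      vol_cc <- stats::rlnorm(n_les, spec$vol_meanlog, spec$vol_sdlog)
      for (j in seq_len(n_les)) {
        r_mm <- (3 * vol_cc[j] * 1000 / (4 * pi))^(1 / 3)
        aniso <- exp(stats::rnorm(3, sd = 0.15))
        aniso <- aniso / prod(aniso)^(1 / 3)
        semi_vox <- pmax(r_mm * aniso / sp, 0.4)
        semi_vox <- pmin(semi_vox, d / 2 - 1)
        ctr <- sapply(1:3, function(ax) {
          stats::runif(1, 1 + semi_vox[ax], d[ax] - semi_vox[ax])
        })
        blob <- soft_blob(d, ctr, semi_vox)
        pet <- pet + spec$contrast * blob
        mask[blob > 0.25] <- j          # inside ~ the nominal ellipsoid
        lesion_cc <- c(lesion_cc, vol_cc[j])
      }
    }
    ## distractors: bright, unlabeled, organ-scale physiological uptake
    ## (brain / myocardium / kidney / salivary-gland analogues). Half sit
    ## on the CT organ regions (suppressible from the CT channel), half
    ## are placed anywhere with no CT conspicuity and form irreducible
    ## false-positive pressure. Their several-cm size puts the resulting
    ## false candidates into the large-volume bins, which is exactly the
    ## failure mode confidence-ranked pseudo-label selection inherits.
    dis_rate <- spec$n_distractor *
      (if (stats::runif(1) < (spec$burst_prob %||% 0)) spec$burst_factor
       else 1)
    n_dis <- stats::rpois(1L, dis_rate)
    if (n_dis > 0L) {
      for (j in seq_len(n_dis)) {
        if (stats::runif(1) < 0.5) {
          o <- sample.int(n_org, 1L)
          ctr <- organ_ctr[o, ] + stats::rnorm(3, sd = 2)
          rad <- organ_rad[o] * stats::runif(1, 0.5, 0.9)
        } else {
          ctr <- stats::runif(3, 0.1, 0.9) * d
          rad <- stats::runif(1, 2.5, 6)
        }
        ctr <- pmin(pmax(ctr, 3), d - 3)
        pet <- pet + spec$distractor_contrast * stats::runif(1, 0.6, 1) *
          soft_blob(d, ctr, rep(rad, 3) * exp(stats::rnorm(3, sd = 0.1)))
      }
    }
    pet <- pet + array(stats::rnorm(prod(d), sd = spec$noise_sd), d)
    boxes <- filter_small_boxes(masks_to_boxes(mask), sp, 0.08)
    list(pet = pet, ct = ct, mask = mask, boxes = boxes, spacing = sp,
         domain = spec$name, id = seed, lesion_cc = lesion_cc)
  })
}

## Soft ellipsoidal profile max(0, 1 - rho^2)^1 on the voxel grid,
## evaluated only on the blob's bounding sub-grid.
soft_blob <- function(d, ctr, semi) {
  v <- array(0, d)
  lo <- pmax(1L, floor(ctr - semi - 1))
  hi <- pmin(d, ceiling(ctr + semi + 1))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  rx <- ((xs - ctr[1]) / semi[1])^2
  ry <- ((ys - ctr[2]) / semi[2])^2
  rz <- ((zs - ctr[3]) / semi[3])^2
  rho2 <- outer(outer(rx, ry, `+`), rz, `+`)
  v[xs, ys, zs] <- pmax(0, 1 - rho2 / 1.8) # profile extends past the mask
  v
}

#' Generate a seeded dataset of subjects
#'
#' Per-subject seeds are derived from the master seed, so any subject can
#' be regenerated independently and the whole dataset is reproducible.
#'
#' @param n Number of subjects.
#' @param spec A [domain_spec()].
#' @inheritParams generate_subject
#' @param normalize Apply [normalize_channels()] to each sample.
#' @return A list of subject samples with ids `1..n`.
#' @export
generate_dataset <- function(n, spec, shape = c(48L, 48L, 48L),
                             sp = spacing(4, 4, 5), seed = 1,
                             normalize = TRUE) {
  lapply(seq_len(n), function(i) {
    s <- generate_subject(spec, shape, sp, seed = derive_seed(seed, i))
    s$id <- i
    if (normalize) s <- normalize_channels(s)
    s
  })
}

#' Z-score normalize the two channels
#'
#' Each channel is independently centred and scaled to unit SD over the
#' whole volume; a constant channel maps to all zeros.
#'
#' @param sample A subject sample.
#' @return The sample with normalized `pet` and `ct`.
#' @export
normalize_channels <- function(sample) {
  zs <- function(v) {
    mu <- mean(v)
    sd <- stats::sd(as.numeric(v))
    if (!is.finite(sd) || sd == 0) return(array(0, dim(v)))
    (v - mu) / sd
  }
  sample$pet <- zs(sample$pet)
  sample$ct <- zs(sample$ct)
  sample
}

#' Random crop with label bookkeeping
#'
#' Crops a cubic (or rectangular) window at a uniformly random corner.
#' Boxes are intersected with the window and translated to crop
#' coordinates; a box retaining less than half of its original volume is
#' dropped from the crop's labels.
#'
#' @param sample A subject sample.
#' @param size Crop extents in voxels (scalar or length 3).
#' @param seed Crop seed.
#' @return The cropped sample.
#' @export
random_crop <- function(sample, size, seed = 1) {
  d <- dim(sample$pet)
  size <- as.integer(rep(size, length.out = 3L))
  if (any(size > d)) stop("crop size exceeds volume extents")
  corner <- with_seed(seed, sapply(1:3, function(ax) {
    if (d[ax] == size[ax]) 0L else sample.int(d[ax] - size[ax] + 1L, 1L) - 1L
  }))
  xs <- (corner[1] + 1L):(corner[1] + size[1])
  ys <- (corner[2] + 1L):(corner[2] + size[2])
  zs <- (corner[3] + 1L):(corner[3] + size[3])
  out <- sample
  out$pet <- sample$pet[xs, ys, zs, drop = FALSE]
  out$ct <- sample$ct[xs, ys, zs, drop = FALSE]
  if (!is.null(sample$mask)) {
    out$mask <- sample$mask[xs, ys, zs, drop = FALSE]
  }
  out$features <- NULL
  b <- as_box_matrix(sample$boxes)
  if (nrow(b)) {
    lo <- sweep(b[, 1:3, drop = FALSE], 2L, corner, `-`)
    hi <- sweep(b[, 4:6, drop = FALSE], 2L, corner, `-`)
    clo <- pmax(lo, 0)
    chi <- pmin(hi, matrix(size, nrow(b), 3L, byrow = TRUE))
    kept <- apply(pmax(chi - clo, 0), 1L, prod)
    orig <- apply(hi - lo, 1L, prod)
    keep <- kept >= 0.5 * orig & kept > 0
    out$boxes <- cbind(clo, chi)[keep, , drop = FALSE]
    colnames(out$boxes) <- BOX_COLS
  } else {
    out$boxes <- empty_boxes()
  }
  out
}

#' Split subject indices into train/validation/test
#'
#' Split sizes are the round-to-nearest of `n * fraction` with any
#' remainder corrected on the largest split, so e.g. 369 subjects at
#' 70/10/20 yield 258/37/74. The assignment is a seeded shuffle.
#'
#' @param n Number of subjects.
#' @param fractions Length-3 fractions summing to 1 (train, val, test).
#' @param seed Shuffle seed.
#' @return A list of disjoint, exhaustive index vectors `train`, `val`,
#'   `test`.
#' @export
split_dataset <- function(n, fractions = c(0.7, 0.1, 0.2), seed = 1) {
  if (length(fractions) != 3L) stop("need three fractions")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (n < sum(fractions > 0)) stop("n smaller than the number of splits")
  sizes <- round(n * fractions)
  excess <- sum(sizes) - n
  if (excess != 0) {
    big <- which.max(sizes)
    sizes[big] <- sizes[big] - excess
  }
  perm <- with_seed(seed, sample.int(n))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- lapply(1:3, function(i) {
    if (sizes[i] == 0L) integer(0) else sort(perm[starts[i]:ends[i]])
  })
  names(out) <- c("train", "val", "test")
  attr(out, "sizes") <- as.integer(sizes)
  out
}
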