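#' Configuration of the self-training adaptation loop
#'
#' Collects every tunable of the pipeline with its standard defaults:
#' confidence gate `tau = 0.5`, NMS IoU 0.25, `B = 10` volume bins,
#' `K = 3` anchor shapes, EMA momenta `alpha_mu = alpha_h = beta = 0.9`,
#' and the admission factor `lambda` growing linearly from 0.1 to 0.8 over
#' the `R` rounds. `R` itself, the pretraining epochs and the optimizer
#' settings are deployment-scale choices and are set here to values suited
#' to CPU-scale experiments.
#'
#' @param R Number of self-training rounds.
#' @param lam_start,lam_end Endpoints of the linear lambda schedule.
#' @param tau Pseudo-label confidence gate.
#' @param nms_iou NMS threshold for candidate cleaning.
#' @param alpha_mu,alpha_h,beta EMA update weights on the current round's
#'   estimate for the count prior, size prior and anchors. The anchor
#'   default is deliberately small: anchors re-parameterize the detection
#'   heads, so they must drift, not jump — a round's k-means shapes enter
#'   at weight `beta` per round.
#' @param K Number of anchor shapes.
#' @param B Number of volume bins.
#' @param min_cc Label volume floor in cc.
#' @param selection `"prior_guided"` (label-shift-aware) or
#'   `"top_fraction"` (conventional baseline).
#' @param top_p Fraction kept by the baseline selection.
#' @param adapt_anchors Update anchors across rounds via k-means + EMA.
#' @param update_priors Maintain the online mu/h estimates (disabled in
#'   the pure baseline arm).
#' @param epochs_pretrain Source pretraining epochs.
#' @param lr Adam learning rate for source pretraining.
#' @param lr_adapt Learning rate during the self-training rounds; smaller
#'   than `lr` so the rounds nudge the pretrained detector rather than
#'   retrain it (large steps swing borderline scores across the
#'   confidence gate and destabilize the candidate stream).
#' @param batch_size Samples per optimization step.
#' @param stride Detector feature-grid stride in voxels.
#' @param crop Training crop size in voxels, or `NULL` to train on whole
#'   volumes.
#' @param ignore_gate Score above which an unselected detection shields
#'   its neighbourhood from the negative class in target training.
#' @param anchor_min_boxes Minimum pooled pseudo-box count for an anchor
#'   update; smaller rounds carry the previous anchors.
#' @param window Sliding-window extents for inference.
#' @param seed Master seed; every stochastic component derives from it.
#' @return A list of class `"adaptation_config"`.
#' @export
adaptation_config <- function(R = 20L, lam_start = 0.1, lam_end = 0.8,
                              tau = 0.5, nms_iou = 0.25,
                              alpha_mu = 0.9, alpha_h = 0.9, beta = 0.1,
                              K = 3L, B = 10L, min_cc = 0.08,
                              selection = c("prior_guided", "top_fraction"),
                              top_p = 0.5, adapt_anchors = TRUE,
                              update_priors = NULL,
                              epochs_pretrain = 120L, lr = 1e-2,
                              lr_adapt = 3e-3,
                              batch_size = 4L, stride = 4L, crop = NULL,
                              ignore_gate = 0.1, anchor_min_boxes = 10L,
                              window = c(96L, 96L, 96L), seed = 1L) {
  selection <- match.arg(selection)
  if (R < 1) stop("R must be >= 1")
  if (is.null(update_priors)) update_priors <- selection == "prior_guided"
  cfg <- list(R = as.integer(R), lam_start = lam_start, lam_end = lam_end,
              tau = tau, nms_iou = nms_iou, alpha_mu = alpha_mu,
              alpha_h = alpha_h, beta = beta, K = as.integer(K),
              B = as.integer(B), min_cc = min_cc, selection = selection,
              top_p = top_p, adapt_anchors = adapt_anchors,
              update_priors = update_priors,
              epochs_pretrain = as.integer(epochs_pretrain), lr = lr,
              lr_adapt = lr_adapt,
              batch_size = as.integer(batch_size),
              stride = as.integer(stride), crop = crop,
              ignore_gate = ignore_gate,
              anchor_min_boxes = as.integer(anchor_min_boxes),
              window = as.integer(window), seed = as.integer(seed))
  class(cfg) <- "adaptation_config"
  cfg
}

## Mean of per-subject normalized size histograms: every subject counts
## equally regardless of how many boxes it carries. Used both for h(0)
## from the source labels and for the per-round target estimate, so the
## two are directly comparable.
subject_mean_histogram <- function(samples, sp, binning,
                                   allow_empty = FALSE) {
  hs <- lapply(samples, function(s) {
    b <- as_box_matrix(s$boxes)
    if (nrow(b) == 0L) return(NULL)
    v <- box_volume_cc(b, sp)
    b <- b[v >= binning$edges[1L], , drop = FALSE]
    if (nrow(b) == 0L) return(NULL)
    size_histogram(b, sp, binning)
  })
  hs <- hs[!vapply(hs, is.null, logical(1))]
  if (!length(hs)) {
    if (allow_empty) return(NULL)
    stop("no boxes above the volume floor in any subject")
  }
  Reduce(`+`, hs) / length(hs)
}

## Attach cached features to whole-volume samples (skipped when random
## cropping is active, since crops change every epoch).
prepare_samples <- function(samples, stride) {
  lapply(samples, function(s) {
    if (is.null(s$features)) {
      s$features <- featurize_volume(s$pet, s$ct, stride)
    }
    s
  })
}

## One pass over `samples` in a seeded shuffled order, in mini-batches.
train_epoch <- function(det, samples, anchors, cfg, epoch_seed) {
  n <- length(samples)
  ord <- with_seed(epoch_seed, sample.int(n))
  losses <- numeric(0)
  i <- 1L
  while (i <= n) {
    idx <- ord[i:min(n, i + cfg$batch_size - 1L)]
    batch <- lapply(seq_along(idx), function(j) {
      s <- samples[[idx[j]]]
      if (!is.null(cfg$crop) && any(dim(s$pet) > cfg$crop)) {
        s <- random_crop(s, cfg$crop, seed = derive_seed(epoch_seed, idx[j]))
      }
      s
    })
    det <- detector_train_step(det, batch, anchors)
    losses <- c(losses, det$last_loss)
    i <- i + cfg$batch_size
  }
  det$epoch_loss <- mean(losses)
  det
}

#' Pretrain a detector on the labeled source domain
#'
#' Supervised training with the focal + smooth-L1 detection loss, anchors
#' fixed at the source k-means shapes.
#'
#' @param det A detector object.
#' @param source_set List of labeled source samples.
#' @param anchors0 The initial [anchor_set()].
#' @param epochs Number of passes over the source set.
#' @param cfg An [adaptation_config()].
#' @return The trained detector with per-epoch mean losses in
#'   `$pretrain_losses`.
#' @export
pretrain_source <- function(det, source_set, anchors0, epochs, cfg) {
  if (length(source_set) == 0L) stop("source set is empty")
  losses <- numeric(epochs)
  if (is.null(cfg$crop)) source_set <- prepare_samples(source_set, cfg$stride)
  for (e in seq_len(epochs)) {
    det <- train_epoch(det, source_set, anchors0, cfg,
                       derive_seed(cfg$seed, 1000L + e))
    losses[e] <- det$epoch_loss
  }
  det$pretrain_losses <- losses
  det
}

## Candidate inference + cleaning for every target subject. Besides the
## tau-gated candidate sets this also keeps a "loose" set gated at the
## low ignore_gate: regions the detector has any belief in, used to shield
## plausible lesions from the negative class during sparse pseudo-label
## training (with ~1 positive per subject the background-suppression
## gradient is strong, and punishing every sub-threshold lesion response
## would collapse the target score distribution within a round or two).
target_candidates <- function(det, target_set, anchors, cfg) {
  lapply(target_set, function(s) {
    raw <- sliding_window_predict(det, s, anchors, window = cfg$window,
                                  merge_iou = cfg$nms_iou)
    list(cands = clean_candidates(raw, tau = cfg$tau, nms_iou = cfg$nms_iou),
         loose = clean_candidates(raw, tau = cfg$ignore_gate,
                                  nms_iou = cfg$nms_iou))
  })
}

#' One self-training round
#'
#' Executes the alternating scheme: (Step 1) one supervised epoch on the
#' labeled source; then a full inference pass on the target with the
#' current anchors, candidate cleaning, pseudo-label selection with the
#' round's admission factor, online prior and anchor updates; and (Step 2)
#' one supervised epoch on the pseudo-labeled target subjects. Selection
#' uses the prior state entering the round; the updated priors and anchors
#' take effect from the next round.
#'
#' @param state Round state: list with `r`, `detector`, `prior`,
#'   `anchors`, `binning`, `sp`.
#' @param source_set,target_set Sample lists.
#' @param cfg An [adaptation_config()].
#' @return The state for the next round, with the round's log entry in
#'   `$log_entry` and the selected pseudo labels in `$pseudo`.
#' @export
self_training_round <- function(state, source_set, target_set, cfg) {
  r <- state$r
  det <- state$detector
  det$lr <- cfg$lr_adapt %||% det$lr
  ## Step 1: supervised source epoch
  det <- train_epoch(det, source_set, state$anchors, cfg,
                     derive_seed(cfg$seed, 2000L + r))
  src_loss <- det$epoch_loss
  if (length(target_set) == 0L) {
    state$detector <- det
    state$r <- r + 1L
    state$pseudo <- list()
    state$log_entry <- data.frame(round = r, lambda = NA, mu = state$prior$mu,
                                  n_candidates = 0, n_pseudo = 0,
                                  src_loss = src_loss, tgt_loss = NA)
    return(state)
  }
  ## inference pass + cleaning
  inf <- target_candidates(det, target_set, state$anchors, cfg)
  cands <- lapply(inf, `[[`, "cands")
  lam <- lambda_schedule(r, cfg$R, cfg$lam_start, cfg$lam_end)
  ## selection with the priors entering the round
  pseudo <- lapply(cands, function(ci) {
    if (cfg$selection == "prior_guided") {
      sel <- select_prior_guided(ci, state$prior, state$binning, state$sp,
                                 lam)
      stopifnot(nrow(sel) <= subject_budget(state$prior, lam))
      sel
    } else {
      select_top_fraction(ci, cfg$top_p)
    }
  })
  ## online prior updates from the cleaned candidate sets; a round with no
  ## candidates at all carries the priors over unchanged
  prior <- state$prior
  if (cfg$update_priors) {
    counts <- vapply(cands, nrow, integer(1))
    if (sum(counts) > 0L) {
      prior <- update_mu(prior, counts)
      ## round histogram: mean of per-subject normalized histograms (the
      ## same estimator that initializes h from the source), so a single
      ## false-positive-rich scan cannot dominate the size prior any more
      ## than it can dominate the training set
      h_hat <- subject_mean_histogram(lapply(cands, function(ci)
        list(boxes = as_box_matrix(ci))), state$sp, state$binning,
        allow_empty = TRUE)
      if (!is.null(h_hat)) prior <- update_histogram(prior, h_hat)
    }
  }
  ## anchor adaptation from the cleaned candidate pool (the same
  ## prediction set the priors are estimated from): the quota-selected
  ## pseudo boxes concentrate in the few bins the largest-remainder
  ## allocation favours at small budgets, and k-means on that truncated
  ## pool compresses the anchors even when no shift exists. Very small
  ## pools (fewer than anchor_min_boxes) carry the anchors over.
  n_cand <- sum(vapply(cands, nrow, integer(1)))
  anchors <- if (cfg$adapt_anchors && n_cand >= cfg$anchor_min_boxes) {
    anchors_for_round(cands, state$anchors, K = cfg$K, beta = cfg$beta,
                      seed = derive_seed(cfg$seed, 3000L + r))
  } else {
    a <- state$anchors
    a$round <- a$round + 1L
    a
  }
  ## Step 2: supervised epoch on pseudo-labeled target subjects
  has_pl <- which(vapply(pseudo, nrow, integer(1)) > 0L)
  tgt_loss <- NA_real_
  if (length(has_pl)) {
    tgt_samples <- lapply(has_pl, function(i) {
      s <- target_set[[i]]
      sel <- as_box_matrix(pseudo[[i]])
      s$boxes <- sel
      ## unselected half-confident regions are plausible lesions: exclude
      ## them from the negative class rather than training against them
      loose <- as_box_matrix(inf[[i]]$loose)
      if (nrow(loose)) {
        is_sel <- duplicated(rbind(sel, loose))[-seq_len(nrow(sel))]
        if (any(!is_sel)) s$ignore_boxes <- loose[!is_sel, , drop = FALSE]
      }
      s
    })
    ## the target epoch trains against the round's updated anchors, so
    ## the heads adapt to each anchor move before it serves inference
    det <- train_epoch(det, tgt_samples, anchors, cfg,
                       derive_seed(cfg$seed, 4000L + r))
    tgt_loss <- det$epoch_loss
  }
  state$detector <- det
  state$prior <- prior
  state$anchors <- anchors
  state$pseudo <- pseudo
  state$r <- r + 1L
  state$log_entry <- data.frame(
    round = r, lambda = lam, mu = prior$mu,
    n_candidates = sum(vapply(cands, nrow, integer(1))),
    n_pseudo = sum(vapply(pseudo, nrow, integer(1))),
    src_loss = src_loss, tgt_loss = tgt_loss)
  state$h_entry <- prior$h
  state$anchor_entry <- anchors$shapes
  state
}

#' Fit a label-shift-aware adapted lesion detector
#'
#' The package's main fitting front end. Pretrains the compact detector on
#' the labeled source set (anchors initialized by k-means on the source
#' boxes; priors initialized from the source lesion count and size
#' histogram), then runs `R` alternating self-training rounds on the
#' unlabeled target set with prior-guided pseudo-label selection and EMA
#' anchor adaptation — or the conventional top-fraction baseline when
#' `cfg$selection = "top_fraction"`.
#'
#' @param source_set List of labeled source samples (see
#'   [generate_subject()] for the layout).
#' @param target_set List of unlabeled target samples (their `boxes` are
#'   never read).
#' @param cfg An [adaptation_config()].
#' @param detector Optionally a pre-built detector object; default builds
#'   a [mini_detector()].
#' @param pretrained Skip source pretraining (detector assumed trained).
#' @param binning Optionally a [size_binning()]; default
#'   `default_binning(cfg$B)`.
#' @return An object of class `"uda_detector"` with the trained detector,
#'   final anchors and priors, per-round trajectories and the
#'   configuration.
#' @export
adapt_lesion_detector <- function(source_set, target_set,
                                  cfg = adaptation_config(),
                                  detector = NULL, pretrained = FALSE,
                                  binning = NULL) {
  if (length(source_set) == 0L) stop("source set is empty")
  sp <- source_set[[1]]$spacing %||% spacing(4, 4, 5)
  binning <- binning %||% default_binning(cfg$B)
  ## strip target labels defensively: adaptation is unsupervised
  src_boxes <- do.call(rbind, lapply(source_set, function(s)
    as_box_matrix(s$boxes)))
  if (is.null(src_boxes) || nrow(src_boxes) < cfg$K) {
    stop("source set must contain at least K labeled boxes")
  }
  anchors0 <- anchor_set(
    kmeans_shapes(src_boxes, K = cfg$K, seed = derive_seed(cfg$seed, 10L)),
    round = 0L)
  mu0 <- mean(vapply(source_set, function(s) nrow(as_box_matrix(s$boxes)),
                     integer(1)))
  h0 <- subject_mean_histogram(source_set, sp, binning)
  prior0 <- size_prior(mu0, h0, cfg$alpha_mu, cfg$alpha_h)
  det <- detector %||% mini_detector(K = cfg$K, stride = cfg$stride,
                                       lr = cfg$lr,
                                       seed = derive_seed(cfg$seed, 20L))
  if (is.null(cfg$crop) && !inherits(det, "oracle_detector")) {
    source_set <- prepare_samples(source_set, cfg$stride)
    target_set <- prepare_samples(target_set, cfg$stride)
  }
  if (!pretrained && !inherits(det, "oracle_detector")) {
    det <- pretrain_source(det, source_set, anchors0, cfg$epochs_pretrain,
                           cfg)
  }
  state <- list(r = 0L, detector = det, prior = prior0, anchors = anchors0,
                binning = binning, sp = sp)
  log <- NULL
  h_traj <- list(prior0$h)
  a_traj <- list(anchors0$shapes)
  for (r in seq_len(cfg$R)) {
    state <- self_training_round(state, source_set, target_set, cfg)
    log <- rbind(log, state$log_entry)
    h_traj[[r + 1L]] <- state$prior$h
    a_traj[[r + 1L]] <- state$anchors$shapes
  }
  structure(list(
    detector = state$detector, anchors = state$anchors,
    prior = state$prior, anchors0 = anchors0, prior0 = prior0,
    binning = binning, sp = sp, config = cfg, log = log,
    h_trajectory = h_traj, anchor_trajectory = a_traj,
    pseudo = state$pseudo
  ), class = "uda_detector")
}

#' @rdname adapt_lesion_detector
#' @export
run_adaptation <- adapt_lesion_detector

#' Conventional self-training baseline
#'
#' The comparison arm: identical loop but top-50%-by-confidence selection,
#' no prior maintenance, and (by default) frozen anchors.
#'
#' @inheritParams adapt_lesion_detector
#' @param adapt_anchors Also run anchor adaptation (the intermediate arm).
#' @return An object of class `"uda_detector"`.
#' @export
run_baseline_self_training <- function(source_set, target_set,
                                       cfg = adaptation_config(),
                                       adapt_anchors = FALSE, ...) {
  cfg$selection <- "top_fraction"
  cfg$update_priors <- FALSE
  cfg$adapt_anchors <- adapt_anchors
  adapt_lesion_detector(source_set, target_set, cfg, ...)
}

#' Source-only model (no adaptation)
#'
#' Pretrains on the source and stops: the lower reference arm that
#' quantifies the domain-shift impact.
#'
#' @inheritParams adapt_lesion_detector
#' @return An object of class `"uda_detector"` with `R = 0` rounds run.
#' @export
fit_source_only <- function(source_set, cfg = adaptation_config(), ...) {
  cfg$R <- 1L # schedule needs R >= 1; no round is run below
  obj <- NULL
  sp <- source_set[[1]]$spacing %||% spacing(4, 4, 5)
  binning <- default_binning(cfg$B)
  src_boxes <- do.call(rbind, lapply(source_set, function(s)
    as_box_matrix(s$boxes)))
  anchors0 <- anchor_set(
    kmeans_shapes(src_boxes, K = cfg$K, seed = derive_seed(cfg$seed, 10L)))
  det <- mini_detector(K = cfg$K, stride = cfg$stride, lr = cfg$lr,
                         seed = derive_seed(cfg$seed, 20L))
  if (is.null(cfg$crop)) source_set <- prepare_samples(source_set, cfg$stride)
  det <- pretrain_source(det, source_set, anchors0, cfg$epochs_pretrain, cfg)
  mu0 <- mean(vapply(source_set, function(s) nrow(as_box_matrix(s$boxes)),
                     integer(1)))
  h0 <- subject_mean_histogram(source_set, sp, binning)
  structure(list(detector = det, anchors = anchors0,
                 prior = size_prior(mu0, h0, cfg$alpha_mu, cfg$alpha_h),
                 anchors0 = anchors0, binning = binning, sp = sp,
                 config = cfg, log = NULL,
                 h_trajectory = list(h0), anchor_trajectory =
                   list(anchors0$shapes)),
            class = "uda_detector")
}

## ---- S3 methods for the fitted object ----

#' @export
print.uda_detector <- function(x, ...) {
  cat("Label-shift-aware adapted lesion detector\n")
  cat("  rounds run:    ", if (is.null(x$log)) 0L else nrow(x$log), "\n")
  cat("  selection:     ", x$config$selection, "\n")
  cat("  anchors (vox):\n")
  print(round(x$anchors$shapes, 2))
  cat("  mu (lesions/subject):", format(x$prior$mu, digits = 4), "\n")
  invisible(x)
}

#' @export
summary.uda_detector <- function(object, ...) {
  cat("Adaptation summary\n==================\n")
  print(object)
  if (!is.null(object$log)) {
    cat("\nPer-round trajectory (head):\n")
    print(utils::head(object$log, 10L))
    cat("\nSize prior h (final):\n")
    print(round(object$prior$h, 3))
  }
  invisible(object)
}

#' Extract adapted parameters
#'
#' Returns the quantities the adaptation estimates: the anchor shapes and
#' the target-domain priors.
#'
#' @param object A fitted `"uda_detector"`.
#' @param ... Unused.
#' @return A list with `anchors`, `mu` and `h`.
#' @export
coef.uda_detector <- function(object, ...) {
  list(anchors = object$anchors$shapes, mu = object$prior$mu,
       h = object$prior$h)
}

#' Predict lesions on new subjects
#'
#' Runs sliding-window inference with the final adapted anchor set — the
#' only selection-stage artifact used at test time.
#'
#' @param object A fitted `"uda_detector"`.
#' @param newdata A single subject sample or a list of them.
#' @param nms Apply inference-time NMS (IoU 0.25) to the output, as any
#'   single-stage detector does; disable to inspect raw anchor outputs.
#' @param clean Additionally apply the tau confidence gate.
#' @param ... Unused.
#' @return A detections data frame (single sample) or a list of them.
#' @export
predict.uda_detector <- function(object, newdata, nms = TRUE,
                                 clean = FALSE, ...) {
  single <- !is.null(newdata$pet)
  samples <- if (single) list(newdata) else newdata
  out <- lapply(samples, function(s) {
    d <- sliding_window_predict(object$detector, s, object$anchors,
                                window = object$config$window,
                                merge_iou = object$config$nms_iou)
    if (nms && nrow(d)) d <- nms3d(d, object$config$nms_iou)
    if (clean) d <- d[d$score >= object$config$tau, , drop = FALSE]
    d
  })
  if (single) out[[1L]] else out
}

#' Plot adaptation trajectories
#'
#' @param x A fitted `"uda_detector"`.
#' @param which `"mu"` (lesions-per-subject trajectory), `"h"` (final
#'   size prior vs initial) or `"anchors"` (anchor volume trajectories).
#' @param ... Passed to the underlying plot call.
#' @export
plot.uda_detector <- function(x, which = c("mu", "h", "anchors"), ...) {
  which <- match.arg(which)
  if (is.null(x$log)) stop("no rounds were run; nothing to plot")
  if (which == "mu") {
    graphics::plot(x$log$round, x$log$mu, type = "b",
                   xlab = "round", ylab = "mu (lesions / subject)", ...)
  } else if (which == "h") {
    hh <- rbind(initial = x$h_trajectory[[1L]], final = x$prior$h)
    graphics::barplot(hh, beside = TRUE, legend.text = rownames(hh),
                      xlab = "volume bin", ylab = "fraction",
                      names.arg = seq_along(x$prior$h), ...)
  } else {
    vols <- vapply(x$anchor_trajectory, function(s)
      s[, 1] * s[, 2] * s[, 3], numeric(x$anchors$K))
    graphics::matplot(t(vols), type = "l", lty = 1,
                      xlab = "round", ylab = "anchor volume (voxels)", ...)
  }
  invisible(x)
}
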