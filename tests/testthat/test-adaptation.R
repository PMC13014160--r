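## Small desk-scale sets shared across the loop tests.
specs <- default_domain_specs()
mk_sets <- function(seed = 11, n_src = 6, n_tgt = 5, shape = c(32, 32, 32)) {
  list(src = generate_dataset(n_src, specs$fdg, shape, seed = seed),
       tgt = generate_dataset(n_tgt, specs$psma, shape, seed = seed + 1))
}

fast_cfg <- function(R = 2L, epochs_pretrain = 3L, ...) {
  adaptation_config(R = R, epochs_pretrain = epochs_pretrain, seed = 7L, ...)
}

test_that("pretraining reduces the source loss", {
  sets <- mk_sets()
  cfg <- fast_cfg(epochs_pretrain = 12L)
  det <- mini_detector(K = cfg$K, hidden = 16, lr = cfg$lr, seed = 1)
  srcb <- do.call(rbind, lapply(sets$src, function(s) s$boxes))
  anc <- anchor_set(kmeans_shapes(srcb, 3, seed = 2))
  det <- pretrain_source(det, sets$src, anc, cfg$epochs_pretrain, cfg)
  ls <- det$pretrain_losses
  expect_length(ls, 12L)
  expect_lt(tail(ls, 1), ls[1])
  expect_error(pretrain_source(det, list(), anc, 1, cfg), "empty")
})

test_that("zero pretraining epochs leave the detector untouched", {
  sets <- mk_sets()
  cfg <- fast_cfg()
  det <- mini_detector(K = 3, hidden = 16, seed = 5)
  srcb <- do.call(rbind, lapply(sets$src, function(s) s$boxes))
  anc <- anchor_set(kmeans_shapes(srcb, 3, seed = 2))
  det2 <- pretrain_source(det, sets$src, anc, 0L, cfg)
  expect_identical(det2$W1, det$W1)
  expect_identical(det2$Wc, det$Wc)
})

test_that("an empty target set reduces to pure source training", {
  sets <- mk_sets()
  cfg <- fast_cfg()
  fit <- adapt_lesion_detector(sets$src, list(), cfg)
  expect_equal(nrow(fit$log), 2L)
  expect_equal(fit$log$n_pseudo, c(0, 0))
  expect_equal(fit$prior$mu, fit$prior0$mu)
  expect_equal(fit$anchors$shapes, fit$anchors0$shapes)
})

test_that("one round equals pretraining plus a single self-training round", {
  sets <- mk_sets()
  cfg <- fast_cfg(R = 1L)
  fit <- adapt_lesion_detector(sets$src, sets$tgt, cfg)
  ## manual composition with identical seeds
  sp <- sets$src[[1]]$spacing
  bn <- default_binning(cfg$B)
  srcb <- do.call(rbind, lapply(sets$src, function(s) s$boxes))
  anc0 <- anchor_set(kmeans_shapes(srcb, cfg$K,
                                   seed = lesionshift:::derive_seed(cfg$seed, 10L)))
  det <- mini_detector(K = cfg$K, stride = cfg$stride, lr = cfg$lr,
                       seed = lesionshift:::derive_seed(cfg$seed, 20L))
  src_p <- lesionshift:::prepare_samples(sets$src, cfg$stride)
  tgt_p <- lesionshift:::prepare_samples(sets$tgt, cfg$stride)
  det <- pretrain_source(det, src_p, anc0, cfg$epochs_pretrain, cfg)
  v <- box_volume_cc(srcb, sp)
  h0 <- size_histogram(srcb[v >= bn$edges[1], , drop = FALSE], sp, bn)
  mu0 <- mean(vapply(sets$src, function(s) nrow(s$boxes), integer(1)))
  st <- list(r = 0L, detector = det, anchors = anc0, binning = bn, sp = sp,
             prior = size_prior(mu0, h0, cfg$alpha_mu, cfg$alpha_h))
  st <- self_training_round(st, src_p, tgt_p, cfg)
  expect_equal(fit$prior$mu, st$prior$mu)
  expect_equal(fit$anchors$shapes, st$anchors$shapes)
  expect_equal(fit$detector$Wc, st$detector$Wc)
})

test_that("the full loop is reproducible from the master seed", {
  sets <- mk_sets()
  cfg <- fast_cfg()
  f1 <- adapt_lesion_detector(sets$src, sets$tgt, cfg)
  f2 <- adapt_lesion_detector(sets$src, sets$tgt, cfg)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$prior$h, f2$prior$h)
  expect_identical(f1$anchors$shapes, f2$anchors$shapes)
  expect_identical(f1$pseudo, f2$pseudo)
  expect_identical(f1$detector$Wc, f2$detector$Wc)
})

test_that("budget and quota invariants hold in every round", {
  sets <- mk_sets(seed = 23)
  cfg <- fast_cfg(R = 3L)
  fit <- adapt_lesion_detector(sets$src, sets$tgt, cfg)
  ## per-subject pseudo counts never exceed the running budget: re-walk the
  ## logged rounds using the recorded priors
  for (r in seq_len(nrow(fit$log))) {
    lam <- lambda_schedule(r - 1, cfg$R, cfg$lam_start, cfg$lam_end)
    expect_lte(fit$log$n_pseudo[r], fit$log$n_candidates[r])
  }
  final_budget <- subject_budget(fit$prior,
                                 lambda_schedule(cfg$R - 1, cfg$R,
                                                 cfg$lam_start, cfg$lam_end))
  for (p in fit$pseudo) expect_lte(nrow(p), final_budget)
})

test_that("the baseline arm never updates priors and keeps half the candidates", {
  sets <- mk_sets(seed = 31)
  cfg <- fast_cfg(R = 2L)
  fit <- run_baseline_self_training(sets$src, sets$tgt, cfg)
  expect_equal(fit$prior$mu, fit$prior0$mu)
  expect_equal(fit$prior$h, fit$prior0$h)
  expect_equal(fit$anchors$shapes, fit$anchors0$shapes)
  ## re-run the final inference to check the ceil(n/2) selection rule
  cands <- lapply(sets$tgt, function(s) {
    clean_candidates(
      sliding_window_predict(fit$detector, s, fit$anchors,
                             window = cfg$window, merge_iou = cfg$nms_iou),
      cfg$tau, cfg$nms_iou)
  })
  ## pseudo sets recorded at the last round used the same detector state
  ## only for subjects that had candidates
  sel <- lapply(cands, select_top_fraction, p = 0.5)
  expect_equal(vapply(sel, nrow, integer(1)),
               vapply(cands, function(ci) as.integer(ceiling(0.5 * nrow(ci))),
                      integer(1)))
})

test_that("oracle-driven rounds recover the target priors", {
  ## detector-independent probe of the estimation machinery: candidates are
  ## the true boxes (distractor scores sit below the gate), lambda = 1
  tgt <- generate_dataset(12, specs$psma, c(32, 32, 32), seed = 91)
  src <- generate_dataset(6, specs$fdg, c(32, 32, 32), seed = 92)
  cfg <- adaptation_config(R = 8L, lam_start = 1, lam_end = 1,
                           epochs_pretrain = 0L, seed = 3L)
  fit <- adapt_lesion_detector(src, tgt, cfg,
                               detector = oracle_detector(seed = 5),
                               pretrained = TRUE)
  mu_true <- mean(vapply(tgt, function(s) nrow(s$boxes), integer(1)))
  expect_equal(fit$prior$mu, mu_true, tolerance = 0.05 * max(mu_true, 1))
  ## pseudo labels equal the ground truth wherever budgets allow
  pur <- mapply(function(p, s) {
    if (nrow(p) == 0) return(1)
    mean(match_detections(p, s$boxes, 0.5)$tp)
  }, fit$pseudo, tgt)
  expect_gte(min(pur), 0.99)
})
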