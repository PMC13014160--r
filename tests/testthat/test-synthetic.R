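specs <- default_domain_specs()

test_that("subject generation is bitwise reproducible and label-consistent", {
  s1 <- generate_subject(specs$psma, c(32, 32, 32), seed = 77)
  s2 <- generate_subject(specs$psma, c(32, 32, 32), seed = 77)
  expect_identical(s1$pet, s2$pet)
  expect_identical(s1$boxes, s2$boxes)
  ## boxes are exactly the filtered mask components
  expect_equal(s1$boxes,
               filter_small_boxes(masks_to_boxes(s1$mask), s1$spacing, 0.08),
               ignore_attr = TRUE)
  expect_equal(dim(s1$pet), dim(s1$ct))
  expect_error(generate_subject(specs$psma, c(16, 32, 32)), ">= 32")
})

test_that("a vanishing lesion rate yields empty label sets", {
  sp0 <- domain_spec("none", rate = 1e-9, vol_meanlog = 0, vol_sdlog = 0.5,
                     contrast = 3)
  s <- generate_subject(sp0, c(32, 32, 32), seed = 5)
  expect_equal(nrow(s$boxes), 0L)
  expect_true(all(s$mask == 0))
})

test_that("lesion counts follow the configured Poisson rate", {
  n <- 150
  counts <- vapply(seq_len(n), function(i) {
    with_seed <- generate_subject(specs$fdg, c(32, 32, 32), seed = 9000 + i)
    length(with_seed$lesion_cc)
  }, numeric(1))
  rate <- specs$fdg$rate
  ci <- rate + c(-1, 1) * qnorm(0.995) * sqrt(rate / n)
  expect_gt(mean(counts), ci[1])
  expect_lt(mean(counts), ci[2])
})

test_that("default specs encode the cross-tracer label shift", {
  expect_gt(specs$psma$rate, specs$fdg$rate)
  set.seed(1)
  vf <- rlnorm(1000, specs$fdg$vol_meanlog, specs$fdg$vol_sdlog)
  vp <- rlnorm(1000, specs$psma$vol_meanlog, specs$psma$vol_sdlog)
  expect_lt(median(vp), median(vf))
  ## the very-large category belongs to the source-like domain
  expect_gt(mean(vf >= 150), mean(vp >= 150))
  ## measured histogram separation on generated labels
  bn <- default_binning(10)
  sp <- spacing(4, 4, 5)
  hv <- function(spec) {
    b <- do.call(rbind, lapply(1:40, function(i)
      generate_subject(spec, c(32, 32, 32), seed = 300 + i)$boxes))
    size_histogram(b, sp, bn)
  }
  expect_gt(sum(abs(hv(specs$fdg) - hv(specs$psma))), 0.2)
})

test_that("dataset splits reproduce the published partition and are exhaustive", {
  sp <- split_dataset(369, c(0.7, 0.1, 0.2), seed = 3)
  expect_equal(lengths(sp), c(train = 258L, val = 37L, test = 74L))
  expect_equal(sort(unname(unlist(sp))), 1:369)
  sp2 <- split_dataset(10, c(0.5, 0.5, 0), seed = 1)
  expect_equal(lengths(sp2), c(train = 5L, val = 5L, test = 0L))
  for (n in c(3, 17, 100)) {
    spn <- split_dataset(n, c(0.6, 0.2, 0.2), seed = n)
    expect_equal(sort(unname(unlist(spn))), seq_len(n))
  }
  expect_error(split_dataset(2, c(0.5, 0.3, 0.2)), "smaller")
  expect_error(split_dataset(10, c(0.5, 0.3)), "three")
})

test_that("channel normalization is an idempotent z-score with a constant guard", {
  s <- generate_subject(specs$fdg, c(32, 32, 32), seed = 21)
  z <- normalize_channels(s)
  expect_lt(abs(mean(z$pet)), 1e-9)
  expect_equal(sd(as.numeric(z$pet)), 1, tolerance = 1e-6)
  z2 <- normalize_channels(z)
  expect_equal(z2$pet, z$pet, tolerance = 1e-6)
  s$ct <- array(7, dim(s$ct))
  expect_true(all(normalize_channels(s)$ct == 0))
})

test_that("random_crop translates, clips and drops truncated boxes", {
  s <- generate_subject(specs$fdg, c(40, 40, 40), seed = 13)
  full <- random_crop(s, c(40, 40, 40), seed = 1)
  expect_identical(full$pet, s$pet)
  expect_equal(full$boxes, s$boxes, ignore_attr = TRUE)
  expect_error(random_crop(s, 64), "exceeds")
  ## constructed case: box 30% inside the crop is dropped, inner box kept
  s2 <- s
  s2$pet <- s$pet; s2$mask <- NULL
  s2$boxes <- box3d(rbind(c(2, 2, 2, 8, 8, 8),      # fully inside [0,20)
                          c(17, 0, 0, 27, 10, 10))) # 70% outside
  cropped <- list()
  s3 <- s2
  ## crop [0,20)^3 deterministically by picking a volume-sized crop on a
  ## shifted sample: emulate via seeds until corner (0,0,0) (seed search is
  ## deterministic, so the test stays stable)
  corner0 <- NULL
  for (sd in 1:50) {
    cr <- random_crop(s3, c(20, 40, 40), seed = sd)
    if (identical(cr$pet[1, 1, 1], s3$pet[1, 1, 1]) &&
        identical(dim(cr$pet), c(20L, 40L, 40L)) &&
        isTRUE(all.equal(cr$pet, s3$pet[1:20, , ]))) {
      corner0 <- cr
      break
    }
  }
  expect_false(is.null(corner0))
  expect_equal(nrow(corner0$boxes), 1L)
  expect_equal(as.numeric(corner0$boxes), c(2, 2, 2, 8, 8, 8))
})

test_that("dataset generation derives per-subject seeds from the master seed", {
  d1 <- generate_dataset(3, specs$fdg, c(32, 32, 32), seed = 5)
  d2 <- generate_dataset(3, specs$fdg, c(32, 32, 32), seed = 5)
  d3 <- generate_dataset(3, specs$fdg, c(32, 32, 32), seed = 6)
  expect_identical(d1[[2]]$pet, d2[[2]]$pet)
  expect_false(identical(d1[[1]]$pet, d3[[1]]$pet))
  expect_false(identical(d1[[1]]$pet, d1[[2]]$pet))
  ## normalized by default
  expect_lt(abs(mean(d1[[1]]$pet)), 1e-9)
})
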