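test_that("segmentation recovers the rendered body up to a boundary band", {
  g <- fx_clean()
  k <- 6
  pair <- match_frames(g$recording$channels$brightfield$times,
                       g$recording$channels$donor$times)
  bf <- g$recording$channels$brightfield$frames[, , pair$bf_index[k]]
  sb <- segment_body(bf)
  expect_true(sb$valid)
  tm <- truth_maps(g$truth, k)
  band <- EBImage::dilate(tm$mask, EBImage::makeBrush(3, "box")) > 0
  shrunk <- EBImage::erode(tm$mask, EBImage::makeBrush(3, "box")) > 0
  expect_false(any(sb$mask[!band]))    # nothing beyond a 1-px outer band
  expect_true(all(sb$mask[shrunk]))    # eroded true body fully covered
})

test_that("blank frames and debris are handled", {
  blank <- matrix(1000, 64, 64)
  expect_false(segment_body(blank)$valid)
  set.seed(1)
  noisy_blank <- blank + matrix(rnorm(64 * 64, 0, 5), 64)
  expect_false(segment_body(noisy_blank)$valid)

  g <- fx_clean()
  pair <- match_frames(g$recording$channels$brightfield$times,
                       g$recording$channels$donor$times)
  bf <- g$recording$channels$brightfield$frames[, , pair$bf_index[3]]
  dusty <- bf
  dusty[5:9, 5:9] <- 200  # small dark dust blob, far from the worm
  sb <- segment_body(dusty, area_bounds = c(1000, 4000))
  tm <- truth_maps(g$truth, 3)
  expect_true(sb$valid)
  expect_false(any(sb$mask[1:12, 1:12]))   # dust rejected
  jac <- sum(sb$mask & tm$mask) / sum(sb$mask | tm$mask)
  expect_gt(jac, 0.9)
})

test_that("midline tracks the true midline for straight and bent worms", {
  # straight worm
  ps <- small_params(wave_amplitude = 0, duration = 3, seed = 5L,
                     stage_jump_interval = Inf, image_size = c(256L, 256L))
  gs <- generate_recording(ps)
  pair <- match_frames(gs$recording$channels$brightfield$times,
                       gs$recording$channels$donor$times)
  bf <- gs$recording$channels$brightfield$frames[, , pair$bf_index[2]]
  ml <- extract_midline(segment_body(bf)$mask)
  expect_true(ml$valid)
  tmid <- gs$truth$midlines[[2]]
  fit <- lm(ml$midline[, 1] ~ ml$midline[, 2])
  expect_lt(sqrt(mean(residuals(fit)^2)), 1)

  # undulating worm: Hausdorff distance to ground truth < 2 px
  g <- fx_clean()
  bf <- g$recording$channels$brightfield$frames[
    , , match_frames(g$recording$channels$brightfield$times,
                     g$recording$channels$donor$times)$bf_index[10]]
  ml <- extract_midline(segment_body(bf)$mask)
  tmid <- g$truth$midlines[[10]]
  dmat <- outer(ml$midline[, 1], tmid[, 1], `-`)^2 +
    outer(ml$midline[, 2], tmid[, 2], `-`)^2
  haus <- sqrt(max(min(apply(dmat, 1, min)), max(apply(dmat, 2, min))))
  expect_lt(haus, 2)
  expect_identical(range(ml$s), c(0, 1))
})

test_that("degenerate blobs are rejected as midline sources", {
  disc <- outer((1:80 - 40)^2, (1:80 - 40)^2, `+`) <= 20^2
  res <- extract_midline(disc)
  expect_false(res$valid)
})

test_that("segmentation and midline extraction are deterministic", {
  g <- fx_noisy()
  bf <- g$recording$channels$brightfield$frames[, , 40]
  a <- segment_body(bf); b <- segment_body(bf)
  expect_identical(a$mask, b$mask)
  expect_identical(extract_midline(a$mask)$midline,
                   extract_midline(b$mask)$midline)
})

test_that("head orientation follows the pharynx marker", {
  g <- fx_clean()
  an <- g$analysis
  # estimated body length is stable across the recording
  len <- rep(NA_real_, nrow(an$qc))
  # re-derive per-frame lengths from curvature table scale: use qc validity
  expect_gt(mean(an$qc$valid), 0.95)
  # orientation: analysis head (s=0) near the true head for >= 99% of frames
  pair <- an$pairing
  ok <- 0; tot <- 0
  for (k in seq(1, nrow(pair), by = 7)) {
    if (!an$qc$valid[k]) next
    bf <- g$recording$channels$brightfield$frames[, , pair$bf_index[k]]
    sb <- segment_body(bf); ml <- extract_midline(sb$mask)
    geom <- orient_head_tail(ml, sb$mask,
                             g$recording$channels$acceptor$frames[, , k],
                             registration = an$registrations$acceptor,
                             pixel_size = 3.125, frame_index = k)
    if (!geom$valid) next
    tmid <- g$truth$midlines[[k]]
    dh <- sum((geom$midline[1, ] - tmid[1, ])^2)
    dt <- sum((geom$midline[1, ] - tmid[200, ])^2)
    ok <- ok + (dh < dt); tot <- tot + 1
  }
  expect_gte(ok / tot, 0.99)
})

test_that("orientation falls back to the previous frame and errors without one", {
  g <- fx_clean()
  pair <- match_frames(g$recording$channels$brightfield$times,
                       g$recording$channels$donor$times)
  bf <- g$recording$channels$brightfield$frames[, , pair$bf_index[4]]
  sb <- segment_body(bf); ml <- extract_midline(sb$mask)
  acc <- g$recording$channels$acceptor$frames[, , 4]
  flat <- matrix(as.integer(median(acc)), nrow(acc), ncol(acc))  # blob erased
  g0 <- orient_head_tail(ml, sb$mask, flat, pixel_size = 3.125,
                         frame_index = 4)
  expect_false(g0$valid)
  expect_identical(g0$flags, "orientation_unknown")
  prev <- orient_head_tail(ml, sb$mask, acc,
                           registration = g$analysis$registrations$acceptor,
                           pixel_size = 3.125, frame_index = 4)
  g1 <- orient_head_tail(ml, sb$mask, flat, previous = prev,
                         pixel_size = 3.125, frame_index = 5)
  expect_true(g1$valid)
  expect_true("orientation_inherited" %in% g1$flags)
  expect_identical(g1$midline[1, ], prev$midline[1, ])
})

test_that("body length from the midline is stable over a clean recording", {
  g <- fx_clean()
  pair <- g$analysis$pairing
  lens <- vapply(seq(1, nrow(pair), by = 5), function(k) {
    bf <- g$recording$channels$brightfield$frames[, , pair$bf_index[k]]
    ml <- extract_midline(segment_body(bf)$mask)
    if (ml$valid) ml$length_px else NA_real_
  }, numeric(1))
  expect_lt(sd(lens, na.rm = TRUE) / mean(lens, na.rm = TRUE), 0.03)
})
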