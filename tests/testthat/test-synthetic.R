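test_that("parameter validation enforces the model invariants", {
  expect_error(worm_model_params(baseline_ratio = 0.8, strain_coupling = 0.1),
               "< 1")
  expect_error(worm_model_params(duration = 1), "2 full undulation periods")
  expect_error(worm_model_params(body_length = 2000,
                                 image_size = c(256L, 256L)),
               "does not fit")
  expect_error(worm_model_params(half_width_profile = function(s) s - 0.5),
               "positive")
  expect_s3_class(worm_model_params(), "worm_model_params")
})

test_that("identical seeds give bit-identical recordings and ground truth", {
  p <- small_params(duration = 3, seed = 77L)
  a <- generate_recording(p)
  b <- generate_recording(p)
  expect_identical(a$recording$channels$brightfield$frames,
                   b$recording$channels$brightfield$frames)
  expect_identical(a$recording$channels$donor$frames,
                   b$recording$channels$donor$frames)
  expect_identical(a$truth$curvature, b$truth$curvature)
  expect_identical(a$truth$midlines, b$truth$midlines)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123); r1 <- runif(3)
  set.seed(123); invisible(generate_recording(small_params(duration = 3)))
  r2 <- runif(3)
  expect_identical(r1, r2)
})

test_that("ideal channel intensities reproduce the injected ratio exactly", {
  g <- fx_clean()
  tm <- truth_maps(g$truth, 5)
  r <- tm$r[tm$mask & !is.na(tm$r)]
  I <- 1000 * (1 + 0.05 * tm$cn[tm$mask & !is.na(tm$cn)])
  E535 <- I * (1 + r) / 2
  E480 <- I * (1 - r) / 2
  expect_equal(fret_value(E535, E480), r, tolerance = 1e-12)
  # one concrete point: coupling 0.1 on baseline 0.2 at unit normalized
  # curvature gives ratio 0.3 and an ideal emission ratio of 1.3 / 0.7
  expect_equal((1 + 0.3) / (1 - 0.3), 1.3 / 0.7, tolerance = 1e-12)
})

test_that("rendered pixel values follow the generative equations exactly", {
  g <- fx_clean()
  k <- 8
  for (chn in c("donor", "acceptor")) {
    tm <- truth_maps(g$truth, k, chn)
    img <- g$recording$channels[[chn]]$frames[, , k]
    sel <- which(tm$mask & !is.na(tm$s) & tm$s > 0.3 & tm$s < 0.95)
    I <- 1000 * (1 + 0.05 * tm$cn[sel])
    ideal <- 100 + if (chn == "donor") I * (1 - tm$r[sel]) / 2
                   else I * (1 + tm$r[sel]) / 2
    expect_lt(max(abs(img[sel] - ideal)), 0.5 + 1e-9)  # count quantization
  }
})

test_that("a zero-amplitude wave gives a straight worm with no cycles", {
  p <- small_params(wave_amplitude = 0, duration = 3, seed = 5L,
                    stage_jump_interval = Inf, image_size = c(256L, 256L))
  g <- generate_recording(p)
  expect_true(all(g$truth$curvature == 0))
  ml <- g$truth$midlines[[3]]
  fit <- lm(ml[, 1] ~ ml[, 2])
  expect_lt(sd(residuals(fit)), 0.1)
  cyc <- detect_cycles(g$truth$curvature[50, ], g$truth$fl_times)
  expect_identical(cyc$n, 0L)
})

test_that("rendered body area matches the analytic disc-union area", {
  g <- fx_noisy()
  tm <- truth_maps(g$truth, 10)
  p <- g$truth$params
  analytic <- (pi / 2) * 0.035 * p$body_length * p$body_length /
    p$pixel_size^2
  expect_lt(abs(sum(tm$mask) - analytic) / analytic, 0.05)
})

test_that("ground-truth midline curvature matches the injected wave", {
  g <- fx_noisy()
  k <- 20
  ml <- g$truth$midlines[[k]]
  kap_fd <- fd_curvature(ml) / g$truth$params$pixel_size  # 1/px -> 1/um
  s <- g$truth$midline_s[2:(nrow(ml) - 1)]
  kap_true <- g$truth$params$wave_amplitude *
    sin(2 * pi * (g$truth$params$wave_number * s -
                    g$truth$params$wave_frequency * g$truth$fl_times[k]) +
          g$truth$phi0)
  inner <- s > 0.05 & s < 0.95
  expect_lt(max(abs(kap_fd[inner] - kap_true[inner])) /
              max(abs(kap_true)), 0.02)
})

test_that("the worm never leaves the frame despite stage jumps", {
  g <- fx_noisy()
  expect_gt(nrow(g$truth$jumps), 1)  # jumps were scheduled
  for (k in c(1, 30, 60, 90)) {
    tm <- truth_maps(g$truth, k)
    expect_false(any(tm$mask[1, ]) || any(tm$mask[nrow(tm$mask), ]) ||
                   any(tm$mask[, 1]) || any(tm$mask[, ncol(tm$mask)]))
  }
})

test_that("strain pairs share kinematics and differ only in fluorescence", {
  p <- small_params(duration = 3)
  pair <- make_strain_pair(p, g_test = 0.1, g_ctrl = 0.02, n_animals = 2,
                           seed = 9L)
  expect_length(pair$test, 2)
  expect_identical(pair$test[[1]]$truth$curvature,
                   pair$ctrl[[1]]$truth$curvature)
  expect_identical(pair$test[[1]]$recording$channels$brightfield$frames,
                   pair$ctrl[[1]]$recording$channels$brightfield$frames)
  expect_false(identical(pair$test[[1]]$truth$ratio,
                         pair$ctrl[[1]]$truth$ratio))
  pair2 <- make_strain_pair(p, 0.1, 0.02, 2, seed = 9L)
  expect_identical(pair$test[[2]]$recording$channels$donor$frames,
                   pair2$test[[2]]$recording$channels$donor$frames)
  expect_error(make_strain_pair(p, 0.1, 0.02, 1), "n_animals")
  expect_error(make_strain_pair(p, 0.02, 0.1, 4), "g_test > g_ctrl")
  ctrl0 <- make_strain_pair(p, 0.1, 0, 2, seed = 3L)$ctrl[[1]]
  expect_equal(ctrl0$truth$ratio[, , 1], ctrl0$truth$ratio[, , 2])
})

test_that("true cycle times sit at the curvature extrema", {
  g <- fx_noisy()
  ct <- true_cycle_times(g$truth, 50)
  tt <- g$truth$fl_times
  tr <- g$truth$curvature[50, ]
  for (pk in ct$peaks[2:3]) {
    i <- which.min(abs(tt - pk))
    expect_gt(tr[i], 0.9 * max(tr))
  }
})

test_that("trace simulation is seeded and has the generative structure", {
  p <- small_params(duration = 4)
  a <- simulate_segment_traces(p, n_segments = 10)
  b <- simulate_segment_traces(p, n_segments = 10)
  expect_identical(a$fret, b$fret)
  expect_equal(dim(a$C), c(10, length(a$times)))
  # coupling: fret regressed on C recovers g
  fitg <- coef(lm(as.vector(a$fret) ~ as.vector(a$C)))[2]
  expect_equal(unname(fitg), p$strain_coupling, tolerance = 0.05)
})
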