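test_that("quartic fits reproduce polynomial and straight midlines", {
  u <- seq(0, 1, length.out = 60)
  # a gentle quartic curve (the fit parameterizes by arc length, so exact
  # reproduction requires near-constant speed along the curve)
  pts <- cbind(3 + 5 * u^2 - 4 * u^3 + u^4, 100 * u)
  fit <- fit_midline_polynomials(pts, eval_at = c(0.3, 0.6), half_window = Inf)
  expect_lt(fit$residual_rms, 0.01)
  # straight line: zero second derivatives, zero curvature
  line <- cbind(1 + 5 * u, 2 + 3 * u)
  fl <- fit_midline_polynomials(line, half_window = Inf)
  expect_lt(max(abs(fl$d2r)), 1e-7)
  expect_lt(max(abs(fl$d2c)), 1e-7)
  expect_lt(max(curvature_profile(fl)$K), 1e-8)
  expect_error(fit_midline_polynomials(pts[1:5, ]), "at least 10")
})

test_that("a gentle sine midline is fitted within 1 px RMS", {
  x <- seq(0, 200, length.out = 120)
  pts <- cbind(20 * sin(2 * pi * x / 200), x)  # amplitude 0.1 body length
  fit <- fit_midline_polynomials(pts)
  expect_lt(fit$residual_rms, 1)
})

test_that("curvature matches analytic values for arcs and sine crests", {
  # circle arc, radius 50 px spanning ~1.2 rad: K = 1/R within 2%
  th <- seq(0, 1.2, length.out = 80)
  arc <- cbind(50 * sin(th), 50 - 50 * cos(th))
  fit <- fit_midline_polynomials(arc)
  K <- curvature_profile(fit)$K
  expect_lt(max(abs(K[10:90] - 1 / 50)) * 50, 0.02)

  # sine midline y = A sin(2 pi x / lambda): crest curvature A (2 pi/lambda)^2
  A <- 8; lam <- 150
  x <- seq(-0.3 * lam, 0.3 * lam, length.out = 120)  # one crest, centred
  pts <- cbind(A * sin(2 * pi * x / lam + pi / 2), x)
  Kc <- curvature_profile(fit_midline_polynomials(pts))$K
  K_true <- A * (2 * pi / lam)^2
  expect_lt(abs(max(Kc) - K_true) / K_true, 0.03)
})

test_that("polynomial curvature agrees with a finite-difference oracle", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    amp <- runif(1, 1, 3)
    nw <- runif(1, 0.4, 1.0)
    ph <- runif(1, 0, 2 * pi)
    wm <- wave_midline(amp, nw, ph)
    fit <- fit_midline_polynomials(wm$pts)
    ks <- curvature_profile(fit)$k_signed
    kfd <- fd_curvature(wm$pts)
    sc <- (seq_len(100) - 0.5) / 100
    sfd <- wm$s[2:(length(wm$s) - 1)]
    kfd_at <- approx(sfd, kfd, sc)$y
    inner <- sc > 0.05 & sc < 0.95
    dev <- max(abs(ks[inner] - kfd_at[inner])) / max(abs(kfd_at[inner]))
    worst <- max(worst, dev)
  }
  expect_lt(worst, 0.03)
})

test_that("side-signed normalized curvature is antisymmetric and contracted-positive", {
  g <- fx_clean()
  k <- g$analysis$kymographs
  expect_equal(k$C[, , 1] + k$C[, , 2], matrix(0, 100, dim(k$C)[2]))
  # per-segment agreement with the generative normalized curvature
  cors <- vapply(10:90, function(i)
    suppressWarnings(cor(k$C[i, , 1], g$truth$curvature[i, ],
                         use = "complete.obs")), numeric(1))
  side1_pos <- median(cors, na.rm = TRUE)
  expect_gt(abs(side1_pos), 0.99)   # one side matches +truth, the other -truth
})

test_that("the FRET index follows its defining identities", {
  expect_identical(fret_value(100, 100), 0)
  expect_identical(fret_value(300, 100), 0.5)
  expect_identical(fret_value(0, 50), -1)
  expect_true(is.na(fret_value(0, 0)))
  expect_error(fret_value(-1, 5), "non-negative")
  set.seed(3)
  for (i in 1:50) {
    a <- runif(1, 1, 1000); d <- runif(1, 1, 1000); cc <- runif(1, 1e-6, 1e6)
    expect_equal(fret_value(cc * a, cc * d), fret_value(a, d),
                 tolerance = 1e-12)
  }
})

test_that("dF/Fmin normalization matches its definition", {
  expect_equal(channel_delta_over_min(c(100, 150, 120)), c(0, 0.5, 0.2))
  expect_equal(channel_delta_over_min(rep(7, 5)), rep(0, 5))
  expect_error(channel_delta_over_min(c(0, 1, 2)), "positive")
  g <- fx_noisy()
  tr <- g$analysis$kymographs$E480[50, , 1]
  norm <- channel_delta_over_min(tr)
  expect_identical(min(norm, na.rm = TRUE), 0)
  expect_true(all(norm >= 0, na.rm = TRUE))
})

test_that("kymographs carry the traveling wave at the injected frequency", {
  g <- fx_noisy()
  k <- g$analysis$kymographs
  tt <- k$times
  f_inj <- g$truth$params$wave_frequency
  # dominant temporal frequency per segment via the periodogram
  freqs <- vapply(c(25, 50, 75), function(i) {
    x <- k$C[i, , 1]
    x[!is.finite(x)] <- 0
    x <- x - mean(x)
    sp <- Mod(fft(x))^2
    n <- length(x)
    fgrid <- (seq_len(n) - 1) / n / median(diff(tt))
    fgrid[which.max(sp[2:(n %/% 2)]) + 1]
  }, numeric(1))
  expect_true(all(abs(freqs - f_inj) < 0.1))
  # spatial wave number from the phase gradient at the drive frequency
  segs <- 20:80
  phases <- vapply(segs, function(i) {
    x <- k$C[i, , 1]; x[!is.finite(x)] <- 0
    Arg(sum(x * exp(-2i * pi * f_inj * tt)))
  }, numeric(1))
  slope <- unname(coef(lm(unwrap_phase(phases) ~ I(segs / 100)))[2])
  expect_equal(abs(slope) / (2 * pi), g$truth$params$wave_number,
               tolerance = 0.1)
  # FRET kymograph is the elementwise index of the emission kymographs
  expect_equal(k$FRET, fret_value(k$E535, k$E480))
})

test_that("kymograph assembly rejects empty input", {
  empty <- data.frame(frame = integer(), segment = integer(),
                      side = integer(), E480 = numeric(), E535 = numeric(),
                      n_pixels = integer(), excluded = logical(),
                      reason = character())
  expect_error(build_kymographs(empty, empty, 450), "no valid frames")
})
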