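test_that("normalized cross-correlation recovers known lags", {
  set.seed(8)
  x <- sin(2 * pi * seq(0, 30, by = 0.05)) + rnorm(601, 0, 0.1)
  cc <- cross_correlate(x, x, max_lag = 20)
  expect_equal(cc$peak_lag, 0L)
  expect_equal(cc$r[cc$lag == 0], 1, tolerance = 1e-6)
  expect_true(all(cc$r <= 1 + 1e-9 & cc$r >= -1 - 1e-9))
  for (k in c(3L, -7L)) {
    y <- c(rep(NA, max(k, 0)), head(x, length(x) - abs(k)),
           rep(NA, max(-k, 0)))
    y <- if (k >= 0) c(rep(NA, k), head(x, length(x) - k))
         else c(tail(x, length(x) + k), rep(NA, -k))
    expect_equal(cross_correlate(y, x, 20)$peak_lag, k)
  }
  expect_null(cross_correlate(x[1:10], x[1:10], 3))
  expect_null(cross_correlate(rep(1, 100), x[1:100], 5))
})

test_that("pearson correlation handles exact and null relationships", {
  x <- seq_len(100)
  expect_equal(pearson_correlation(2 * x + 1, x), 1)
  expect_equal(pearson_correlation(-x, x), -1)
  expect_error(pearson_correlation(x[1:10], x[1:10]), "min_n")
  expect_true(is.na(pearson_correlation(rep(1, 50), x[1:50])))
  set.seed(10)
  small <- vapply(1:200, function(i)
    abs(pearson_correlation(rnorm(1000), rnorm(1000))), numeric(1))
  expect_gte(mean(small < 0.1), 0.95)
})

test_that("cycle detection counts sinusoid periods and rejects noise", {
  tt <- seq(0, 60, by = 1 / 19.69)
  x <- sin(2 * pi * tt)
  cy <- detect_cycles(x, tt)
  expect_gte(cy$n, 58); expect_lte(cy$n, 60)
  period <- mean(diff(cy$cycles$peak_t))
  expect_lt(abs(period - 1) / 1, 0.02)
  expect_identical(detect_cycles(rep(2, 200), tt[1:200])$n, 0L)
  # high-frequency low-amplitude jitter does not change the cycle count
  xj <- x + 0.1 * sin(2 * pi * 8 * tt)
  expect_identical(detect_cycles(xj, tt)$n, cy$n)
  # pure noise below prominence: robust SD scales the threshold, so white
  # noise still yields extrema, but a flat trace yields none
  expect_identical(detect_cycles(rep(0, 300), tt[1:300])$n, 0L)
})

test_that("phase maps hit the conventions exactly and cover the cycle", {
  tt <- seq(0, 20, by = 1 / 19.69)
  x <- sin(2 * pi * tt)
  cy <- detect_cycles(x, tt)
  for (m in sample(seq_len(cy$n), 5)) {
    th <- cycle_phase(cy$cycles$start_idx[m], cy$cycles$peak_idx[m],
                      cy$cycles$end_idx[m], tt)
    expect_equal(th[cy$cycles$peak_idx[m] - cy$cycles$start_idx[m] + 1], 90)
    expect_equal(th[length(th)], 270)
    thu <- wormfret:::cycle_phase_unwrapped(cy$cycles$start_idx[m],
                                            cy$cycles$peak_idx[m],
                                            cy$cycles$end_idx[m], tt)
    expect_true(all(diff(thu) > 0))          # monotone within the cycle
    expect_lt(max(diff(sort(thu))), 25)      # no gaps in coverage
  }
})

test_that("phase-aligned curvature peaks at 90 deg and troughs at 270 deg", {
  tt <- seq(0, 60, by = 1 / 19.69)
  set.seed(2)
  x <- sin(2 * pi * tt) + rnorm(length(tt), 0, 0.05)
  cy <- detect_cycles(x, tt)
  pa <- phase_align(cy, x, tt, reference = "raw")
  expect_equal(pa$phase[which.max(pa$mean)], 90)
  expect_equal(pa$phase[which.min(pa$mean)], 270)
})

test_that("phase-aligned FRET changes follow the coupling", {
  # 0.93 Hz: not commensurate with the frame rate, so cycle phase grids
  # differ between cycles and all bins fill (as with real variable cycles)
  tt <- seq(0, 90, by = 1 / 19.69)
  set.seed(3)
  x <- sin(2 * pi * 0.93 * tt) + rnorm(length(tt), 0, 0.03)
  cy <- detect_cycles(x, tt)
  # instantaneous coupling: dFRET falls from 90 to 270 deg
  pa <- phase_align(cy, 0.1 * x, tt, reference = "delta")
  fall <- pa$mean[pa$phase >= 90 & pa$phase <= 270]
  expect_lt(mean(diff(fall), na.rm = TRUE), 0)
  expect_gt(pa$mean[pa$phase == 90], pa$mean[pa$phase == 270])
  # independent FRET: profile flat within the Monte-Carlo noise band
  indep <- rnorm(length(tt), 0.2, 0.02)
  pi0 <- phase_align(cy, indep, tt, reference = "delta")
  band <- 4 * 0.03 / sqrt(min(pi0$n[pi0$n > 0]))
  expect_lt(diff(range(pi0$mean, na.rm = TRUE)), band + 0.02)
})

test_that("quarter-cycle changes have the analytic signs and telescope exactly", {
  tt <- seq(0, 60, by = 1 / 19.69)
  x <- sin(2 * pi * tt)
  cy <- detect_cycles(x, tt)
  q <- quarter_cycle_stats(cy, 0.1 * x, x, tt)
  ms <- tapply(q$d_fret, q$quarter, mean)
  expect_gt(ms[["0-90"]], 0); expect_gt(ms[["270-360"]], 0)
  expect_lt(ms[["90-180"]], 0); expect_lt(ms[["180-270"]], 0)
  qc <- quarter_cycle_stats(cy, rep(0.3, length(tt)), x, tt)
  expect_true(all(qc$d_fret == 0))
  # telescoping: the four quarters of a complete cycle sum to end - start
  set.seed(4)
  f <- 0.2 + 0.05 * x + rnorm(length(tt), 0, 0.02)
  qf <- quarter_cycle_stats(cy, f, x, tt)
  full <- names(which(table(qf$cycle) == 4))
  sums <- tapply(qf$d_fret, qf$cycle, sum)[full]
  ids <- as.integer(full)
  expect_gt(length(ids), 50)
  ends <- f[cy$cycles$end_idx[ids]] - f[cy$cycles$start_idx[ids]]
  expect_lt(max(abs(sums - ends)), 1e-12)
})

test_that("strain comparison is calibrated and detects real effects", {
  q1 <- cohort_quarters(0.1, seed = 21, n_animals = 3, duration = 15)
  # identical cohorts: zero effect, p ~ 1
  cmp0 <- compare_strains(q1, q1)
  expect_true(all(abs(cmp0$quarters$mean_abs_dfret_test -
                        cmp0$quarters$mean_abs_dfret_ctrl) < 1e-12))
  expect_true(all(cmp0$quarters$p_dfret > 0.99))
  # a weaker-coupling cohort is separated
  q2 <- cohort_quarters(0.02, seed = 22, n_animals = 3, duration = 15)
  cmp <- compare_strains(q1, q2)
  expect_true(all(cmp$quarters$mean_abs_dfret_test >
                    cmp$quarters$mean_abs_dfret_ctrl))
  expect_true(all(cmp$quarters$p_dfret < 1e-6))
  expect_true(all(c("quarter", "p_animal") %in%
                    names(cmp$per_animal$tests)))
  one <- q1[q1$animal == 1, ]
  expect_error(compare_strains(one, q2), "at least 2 animals")
})
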