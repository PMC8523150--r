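# Shared fixtures: small synthetic recordings generated once per test run.
.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

# desk-scale geometry used throughout the unit tests: same pixel pitch as the
# full model, smaller body and field so frames stay cheap
small_params <- function(...) {
  args <- list(body_length = 450, image_size = c(192L, 192L),
               duration = 5, seed = 11L)
  over <- list(...)
  args[names(over)] <- over
  do.call(worm_model_params, args)
}

# noisy recording + full analysis
fx_noisy <- function() get_fixture("noisy", function() {
  g <- generate_recording(small_params())
  g$analysis <- suppressWarnings(analyze_recording(g$recording,
                                                   pipeline_config()))
  g
})

# noise-free recording with the fluorescence clock synchronous to brightfield
# (every fluorescence frame has a simultaneous brightfield frame), analyzed
# with pixel bookkeeping for pixel-matched audits
fx_clean <- function() get_fixture("clean", function() {
  p <- small_params(noise_sd = 0, frame_rate_fluor = 37.61 / 2,
                    fluor_start = 0)
  p$seed <- 12L
  g <- generate_recording(p)
  g$analysis <- suppressWarnings(analyze_recording(g$recording,
                                                   pipeline_config(),
                                                   keep_pixels = TRUE))
  g
})

# independent finite-difference curvature oracle on an ordered point set
# (central differences on the chord-arc parameterization)
fd_curvature <- function(pts) {
  n <- nrow(pts)
  arc <- c(0, cumsum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)))
  h1 <- arc[2:(n - 1)] - arc[1:(n - 2)]
  h2 <- arc[3:n] - arc[2:(n - 1)]
  d1 <- function(v) (v[3:n] - v[1:(n - 2)]) / (h1 + h2)
  d2 <- function(v) 2 * (h1 * v[3:n] - (h1 + h2) * v[2:(n - 1)] +
                           h2 * v[1:(n - 2)]) / (h1 * h2 * (h1 + h2))
  xp <- d1(pts[, 2]); yp <- d1(pts[, 1])
  xpp <- d2(pts[, 2]); ypp <- d2(pts[, 1])
  (xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
}

# midline of a heading-integrated curvature wave, in pixel-like units
wave_midline <- function(amp_norm, wave_number, phase = 0, L = 200,
                         npts = 400) {
  s <- seq(0, 1, length.out = npts)
  kap <- amp_norm / L * sin(2 * pi * (wave_number * s) + phase)
  dl <- L / (npts - 1)
  psi <- cumsum(c(0, (kap[-1] + kap[-npts]) / 2 * dl))
  x <- cumsum(c(0, (cos(psi[-1]) + cos(psi[-npts])) / 2 * dl))
  y <- cumsum(c(0, (sin(psi[-1]) + sin(psi[-npts])) / 2 * dl))
  list(pts = cbind(r = y, c = x), kappa = kap, s = s)
}

# trace-level quarter statistics for one simulated cohort
cohort_quarters <- function(g, seed, n_animals, duration = 20, n_segments = 8,
                            freq_sd = 0, fret_noise_sd = 0.02) {
  base <- worm_model_params(duration = duration, strain_coupling = g)
  pl <- cohort_params(base, g, n_animals, seed, freq_sd = freq_sd)
  do.call(rbind, lapply(seq_along(pl), function(i)
    analysis_quarter_stats(simulate_segment_traces(pl[[i]],
                                                   n_segments = n_segments,
                                                   fret_noise_sd = fret_noise_sd),
                           animal = i)))
}

# unwrap a phase sequence (radians) to be continuous
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}
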