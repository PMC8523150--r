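# The synthetic worm is defined in continuous coordinates and only then
# rasterized: the midline integrates the heading angle of the traveling
# curvature wave, the body is the union of discs along the midline with
# radius given by the half-width profile, and fluorescence is assigned per
# pixel from the side-signed normalized curvature at the nearest midline
# point. Geometry is therefore analytically known and ground truth is
# pixel-exact for every downstream stage.

# signed normalized curvature (kappa * L) of the wave at arc position s, time t
wave_cn <- function(p, s, t, phi0) {
  p$wave_amplitude * p$body_length *
    sin(2 * pi * (p$wave_number * s - p$wave_frequency * t) + phi0)
}

# continuous midline in micrometres, centred on its own centroid
# (emulating the tracking stage keeping the animal in the field of view)
worm_midline_um <- function(p, t, phi0, psi0, npts) {
  s <- seq(0, 1, length.out = npts)
  kappa <- wave_cn(p, s, t, phi0) / p$body_length   # 1/um, signed
  dl <- p$body_length / (npts - 1)
  kmid <- (kappa[-1] + kappa[-npts]) / 2
  psi <- psi0 + cumsum(c(0, kmid * dl))
  x <- cumsum(c(0, (cos(psi[-1]) + cos(psi[-npts])) / 2 * dl))
  y <- cumsum(c(0, (sin(psi[-1]) + sin(psi[-npts])) / 2 * dl))
  x <- x - mean(x)
  y <- y - mean(y)
  list(s = s, x = x, y = y, psi = psi, kappa = kappa)
}

# midline in 1-based (row, col) pixel coordinates of a given channel
worm_midline_px <- function(p, t, phi0, psi0, offset, shift, npts) {
  m <- worm_midline_um(p, t, phi0, psi0, npts)
  ctr <- (p$image_size + 1) / 2
  list(s = m$s,
       r = m$y / p$pixel_size + ctr[1] + offset[1] + shift[1],
       c = m$x / p$pixel_size + ctr[2] + offset[2] + shift[2],
       tr = sin(m$psi), tc = cos(m$psi),   # head->tail unit tangent
       kappa = m$kappa)
}

fluor_start_of <- function(p)
  if (is.null(p$fluor_start)) 0.5 / p$frame_rate_bf else p$fluor_start

render_npts <- function(p) max(200L, as.integer(ceiling(p$body_length / p$pixel_size * 1.25)))

# rasterize the body for one channel/frame: body mask, per-pixel nearest
# midline point, side label (+1 where cross(tangent, offset) > 0), arc s
render_geometry <- function(p, t, phi0, psi0, offset, shift = c(0, 0)) {
  m <- worm_midline_px(p, t, phi0, psi0, offset, shift, render_npts(p))
  halfw_px <- p$half_width_profile(m$s) / p$pixel_size
  radius <- max(halfw_px) + 2
  a <- cpp_assign_nearest(p$image_size[1], p$image_size[2],
                          m$r, m$c, halfw_px, radius)
  list(midline = m, halfw_px = halfw_px, mask = a$body,
       nearest = a$nearest, dist2 = a$dist2)
}

pixel_side <- function(geom) {
  idx <- which(geom$mask)
  ni <- geom$nearest[idx]
  nr <- nrow(geom$mask)
  pr <- (idx - 1) %% nr + 1
  pc <- (idx - 1) %/% nr + 1
  m <- geom$midline
  cross <- m$tc[ni] * (pr - m$r[ni]) - m$tr[ni] * (pc - m$c[ni])
  list(idx = idx, point = ni, s = m$s[ni], side = ifelse(cross >= 0, 1, -1))
}

render_bf_frame <- function(p, t, phi0, psi0, offset, noisy = TRUE) {
  g <- render_geometry(p, t, phi0, psi0, offset)
  img <- matrix(p$bf_background, p$image_size[1], p$image_size[2])
  img[g$mask] <- p$bf_body
  if (noisy && p$noise_sd > 0)
    img <- img + matrix(rnorm(length(img), 0, p$noise_sd), nrow(img))
  matrix(as.integer(round(pmax(img, 0))), nrow(img))
}

# both fluorescence channels for one frame (donor and acceptor are exposed
# simultaneously through a beamsplitter, so they share geometry except for
# their camera-path shifts)
render_fluor_frame <- function(p, t, phi0, psi0, offset, channel, noisy = TRUE) {
  shift <- if (channel == "donor") p$donor_shift else p$acceptor_shift
  g <- render_geometry(p, t, phi0, psi0, offset, shift)
  px <- pixel_side(g)
  cn_now <- wave_cn(p, px$s, t, phi0) * px$side
  cn_lag <- wave_cn(p, px$s, t - p$coupling_delay, phi0) * px$side
  r <- p$baseline_ratio + p$strain_coupling * cn_lag
  I <- p$body_intensity * (1 + p$intensity_gain * cn_now)
  val <- if (channel == "donor") I * (1 - r) / 2 else I * (1 + r) / 2
  img <- matrix(p$background_level, p$image_size[1], p$image_size[2])
  img[px$idx] <- img[px$idx] + val
  # bright pharynx marker blob near the head, present in both channels
  ip <- which.min(abs(g$midline$s - p$pharynx_s))
  prad <- p$pharynx_rel_diameter * p$body_length / p$pixel_size / 2
  br <- max(1, floor(g$midline$r[ip] - prad)):min(nrow(img), ceiling(g$midline$r[ip] + prad))
  bc <- max(1, floor(g$midline$c[ip] - prad)):min(ncol(img), ceiling(g$midline$c[ip] + prad))
  blob <- outer((br - g$midline$r[ip])^2, (bc - g$midline$c[ip])^2, `+`) <= prad^2
  img[br, bc][blob] <- img[br, bc][blob] + p$pharynx_gain * p$body_intensity
  if (noisy && p$noise_sd > 0)
    img <- img + matrix(rnorm(length(img), 0, p$noise_sd), nrow(img))
  matrix(as.integer(round(pmax(img, 0))), nrow(img))
}

draw_stage_jumps <- function(p) {
  jt <- 0; jr <- 0; jc <- 0
  if (is.finite(p$stage_jump_interval)) {
    t <- 0
    repeat {
      t <- t + p$stage_jump_interval * runif(1, 0.75, 1.25)
      if (t >= p$duration) break
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0.3, 1) * p$stage_jump_max
      jt <- c(jt, t); jr <- c(jr, rad * sin(ang)); jc <- c(jc, rad * cos(ang))
    }
  }
  data.frame(time = jt, dr = jr, dc = jc)
}

offset_at <- function(jumps, t) {
  i <- findInterval(t, jumps$time)
  c(jumps$dr[i], jumps$dc[i])
}

registration_grid <- function(p, shift) {
  margin <- 0.15 * p$image_size
  gr <- seq(margin[1], p$image_size[1] - margin[1], length.out = 5)
  gc <- seq(margin[2], p$image_size[2] - margin[2], length.out = 5)
  dst <- expand.grid(r = gr, c = gc)
  data.frame(x_src = dst$c + shift[2], y_src = dst$r + shift[1],
             x_dst = dst$c, y_dst = dst$r)
}

#' Generate a seeded synthetic three-channel recording with ground truth
#'
#' Simulates a crawling worm (see [worm_model_params()]) and renders a
#' brightfield stack plus simultaneous donor (E480) and acceptor (E535)
#' emission stacks at their respective frame rates, together with the full
#' generative ground truth: per-frame midlines, per-segment signed normalized
#' curvature and true FRET ratio, stage-motion schedule, and channel
#' registration control points. Identical parameters and seed give
#' bit-identical output.
#'
#' @param params A [worm_model_params()] object.
#' @return A list with components `recording` (class `worm_recording`) and
#'   `truth` (class `worm_truth`).
#' @export
generate_recording <- function(params) {
  p <- validate_worm_model_params(params)
  # reject ratios leaving (-1, 1) anywhere (validation bounds the worst case,
  # re-checked here against the actual wave)
  cnmax <- abs(params$wave_amplitude) * params$body_length
  if (abs(p$baseline_ratio) + abs(p$strain_coupling) * cnmax >= 1)
    stop("true FRET ratio would leave (-1, 1)")

  seed_keep <- get_rng_state()
  on.exit(restore_rng_state(seed_keep))
  set.seed(p$seed)

  phi0 <- runif(1, 0, 2 * pi)
  psi0 <- runif(1, 0, 2 * pi)
  jumps <- draw_stage_jumps(p)

  bf_times <- seq(0, p$duration, by = 1 / p$frame_rate_bf)
  fl_times <- seq(fluor_start_of(p), p$duration, by = 1 / p$frame_rate_fluor)
  nb <- length(bf_times); nf <- length(fl_times)
  H <- p$image_size[1]; W <- p$image_size[2]

  bf <- array(0L, c(H, W, nb))
  for (k in seq_len(nb))
    bf[, , k] <- render_bf_frame(p, bf_times[k], phi0, psi0,
                                 offset_at(jumps, bf_times[k]))
  donor <- array(0L, c(H, W, nf))
  acceptor <- array(0L, c(H, W, nf))
  for (k in seq_len(nf)) {
    off <- offset_at(jumps, fl_times[k])
    donor[, , k] <- render_fluor_frame(p, fl_times[k], phi0, psi0, off, "donor")
    acceptor[, , k] <- render_fluor_frame(p, fl_times[k], phi0, psi0, off, "acceptor")
  }

  rec <- structure(list(
    channels = list(
      brightfield = list(times = bf_times, frames = bf),
      donor = list(times = fl_times, frames = donor),
      acceptor = list(times = fl_times, frames = acceptor)),
    registration = list(donor = registration_grid(p, p$donor_shift),
                        acceptor = registration_grid(p, p$acceptor_shift)),
    pixel_size = p$pixel_size, image_size = p$image_size, seed = p$seed),
    class = "worm_recording")

  # ground truth at the fluorescence time base, in brightfield coordinates
  seg <- (seq_len(100) - 0.5) / 100
  midlines <- vector("list", nf)
  for (k in seq_len(nf)) {
    m <- worm_midline_px(p, fl_times[k], phi0, psi0,
                         offset_at(jumps, fl_times[k]), c(0, 0), 200L)
    midlines[[k]] <- cbind(r = m$r, c = m$c)
  }
  Cn <- sapply(fl_times, function(t) wave_cn(p, seg, t, phi0))
  Cn_lag <- sapply(fl_times, function(t) wave_cn(p, seg, t - p$coupling_delay, phi0))
  ratio <- array(NA_real_, c(100, nf, 2))
  ratio[, , 1] <- p$baseline_ratio + p$strain_coupling * Cn_lag   # side +1
  ratio[, , 2] <- p$baseline_ratio - p$strain_coupling * Cn_lag   # side -1

  truth <- structure(list(
    params = p, phi0 = phi0, psi0 = psi0, jumps = jumps,
    fl_times = fl_times, bf_times = bf_times,
    seg_centers = seg, midline_s = seq(0, 1, length.out = 200L),
    midlines = midlines, curvature = Cn, ratio = ratio),
    class = "worm_truth")

  list(recording = rec, truth = truth)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Re-render ground-truth geometry maps for one fluorescence frame
#'
#' The generative geometry is deterministic given the model parameters, so
#' per-pixel maps (body mask, dorsal/ventral side label, arc coordinate) are
#' not stored with the recording but rebuilt on demand.
#'
#' @param truth A `worm_truth` object.
#' @param frame Fluorescence frame index (1-based).
#' @param channel One of "brightfield", "donor", "acceptor" (selects the
#'   camera coordinate system).
#' @return List with `mask` (logical matrix), `side` (integer matrix,
#'   +1/-1 inside the body, 0 outside), `s` (arc coordinate matrix, NA
#'   outside), `cn` (side-signed normalized curvature matrix) and `r` (true
#'   FRET ratio per pixel, including any coupling delay).
#' @export
truth_maps <- function(truth, frame, channel = "brightfield") {
  p <- truth$params
  shift <- switch(channel, brightfield = c(0, 0), donor = p$donor_shift,
                  acceptor = p$acceptor_shift)
  t <- truth$fl_times[frame]
  g <- render_geometry(p, t, truth$phi0, truth$psi0,
                       offset_at(truth$jumps, t), shift)
  px <- pixel_side(g)
  side <- matrix(0L, nrow(g$mask), ncol(g$mask))
  side[px$idx] <- as.integer(px$side)
  smap <- matrix(NA_real_, nrow(g$mask), ncol(g$mask))
  smap[px$idx] <- px$s
  cn <- matrix(NA_real_, nrow(g$mask), ncol(g$mask))
  cn[px$idx] <- wave_cn(p, px$s, t, truth$phi0) * px$side
  rmap <- matrix(NA_real_, nrow(g$mask), ncol(g$mask))
  rmap[px$idx] <- p$baseline_ratio + p$strain_coupling *
    wave_cn(p, px$s, t - p$coupling_delay, truth$phi0) * px$side
  list(mask = g$mask, side = side, s = smap, cn = cn, r = rmap)
}

#' Ground-truth side identity of image points
#'
#' Classifies points against the stored true midline of a fluorescence frame:
#' +1 on the side where the cross product of the head-to-tail tangent and the
#' midline-to-point vector is positive, -1 on the other side.
#'
#' @param truth A `worm_truth` object.
#' @param frame Fluorescence frame index.
#' @param pts Matrix of (row, col) points.
#' @return Integer vector of +1/-1.
#' @export
true_side_of_points <- function(truth, frame, pts) {
  m <- truth$midlines[[frame]]
  tg <- rbind(m[2, ] - m[1, ], (m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]))
  apply(as.matrix(pts), 1, function(pnt) {
    d2 <- (m[, 1] - pnt[1])^2 + (m[, 2] - pnt[2])^2
    i <- which.min(d2)
    cr <- tg[i, 2] * (pnt[1] - m[i, 1]) - tg[i, 1] * (pnt[2] - m[i, 2])
    if (cr >= 0) 1L else -1L
  })
}

#' True contraction-cycle extrema times for one body segment
#'
#' Analytic peak (maximal contraction of the +1 side) and valley times of the
#' generative curvature wave at a segment centre, within the recording.
#'
#' @param truth A `worm_truth` object.
#' @param segment Segment index 1-100.
#' @return List with numeric vectors `peaks` and `valleys` (seconds).
#' @export
true_cycle_times <- function(truth, segment) {
  p <- truth$params
  sc <- truth$seg_centers[segment]
  # sin(a - 2*pi*f*t) extremal when a - 2*pi*f*t = +/- pi/2 (mod 2*pi)
  a <- 2 * pi * p$wave_number * sc + truth$phi0
  f <- p$wave_frequency
  kmax <- ceiling(f * p$duration) + 2
  k <- -2:kmax
  peaks <- (a - pi / 2 + 2 * pi * k) / (2 * pi * f)
  valleys <- (a + pi / 2 + 2 * pi * k) / (2 * pi * f)
  list(peaks = sort(peaks[peaks >= 0 & peaks <= p$duration]),
       valleys = sort(valleys[valleys >= 0 & valleys <= p$duration]))
}

#' Generate matched "test" and "control" strain cohorts
#'
#' Builds two cohorts of synthetic recordings that differ only in the
#' FRET-curvature coupling `g` and in per-animal seeds, emulating a sensor
#' strain (large coupling) and a control sensor strain (weak or zero
#' coupling). Animal `i` of both cohorts shares a seed, so the paired
#' kinematic ground truth is identical and only fluorescence differs.
#'
#' @param params Base [worm_model_params()]; `strain_coupling` and `seed` are
#'   overridden per cohort/animal.
#' @param g_test,g_ctrl Couplings for the two cohorts; requires
#'   `g_test > g_ctrl >= 0`.
#' @param n_animals Animals per cohort (>= 2).
#' @param seed Cohort-level seed from which per-animal seeds are derived.
#' @return List with elements `test` and `ctrl`, each a list of
#'   `generate_recording()` results.
#' @export
make_strain_pair <- function(params, g_test, g_ctrl, n_animals, seed = 1L,
                             freq_sd = 0.1) {
  if (!(g_test > g_ctrl && g_ctrl >= 0))
    stop("need g_test > g_ctrl >= 0")
  if (n_animals < 2)
    stop("n_animals must be >= 2 (downstream statistics need replication)")
  run <- function(g) lapply(cohort_params(params, g, n_animals, seed, freq_sd),
                            generate_recording)
  list(test = run(g_test), ctrl = run(g_ctrl))
}

#' Per-animal parameter sets for a cohort
#'
#' Derives one [worm_model_params()] per animal from a base parameter set:
#' per-animal seeds, and per-animal undulation frequencies drawn around the
#' base frequency (individual worms do not share an exact body-wave clock;
#' without this, cycle-boundary quantization is identical across animals and
#' cohort statistics become miscalibrated).
#'
#' @param params Base [worm_model_params()].
#' @param g Strain coupling for this cohort.
#' @param n_animals Number of animals.
#' @param seed Cohort seed; animal seed `i` is derived from it.
#' @param freq_sd Relative SD of the per-animal frequency (lognormal).
#' @return List of `worm_model_params`.
#' @export
cohort_params <- function(params, g, n_animals, seed = 1L, freq_sd = 0.1) {
  animal_seed <- (as.integer(seed) %% 100000L) * 10000L + seq_len(n_animals)
  lapply(seq_len(n_animals), function(i) {
    pi <- params
    pi$strain_coupling <- g
    pi$seed <- animal_seed[i]
    if (freq_sd > 0) {
      keep <- get_rng_state()
      set.seed(animal_seed[i] + 7L)
      pi$wave_frequency <- params$wave_frequency * exp(rnorm(1, 0, freq_sd))
      restore_rng_state(keep)
    }
    pi
  })
}

#' Simulate per-segment curvature and FRET traces without rendering images
#'
#' Trace-level counterpart of the generative model, for statistical work at
#' scales where rendering and re-segmenting video would add nothing: returns
#' the side-signed normalized curvature and the noisy measured FRET index for
#' each of `n_segments` body segments of the +1 side, on the fluorescence
#' time base.
#'
#' @param params A [worm_model_params()] object.
#' @param n_segments Number of segments to simulate (default 100).
#' @param fret_noise_sd Standard deviation of iid Gaussian measurement noise
#'   added to the FRET index (default 0.02, the per-sample FRET noise the
#'   imaging pipeline measures under the default pixel noise and segment
#'   sample sizes).
#' @return List with `times`, matrices `C` and `fret` (segments x time), and
#'   `params`.
#' @export
simulate_segment_traces <- function(params, n_segments = 100L,
                                    fret_noise_sd = 0.02) {
  p <- validate_worm_model_params(params)
  seed_keep <- get_rng_state()
  on.exit(restore_rng_state(seed_keep))
  set.seed(p$seed)
  phi0 <- runif(1, 0, 2 * pi)
  times <- seq(fluor_start_of(p), p$duration, by = 1 / p$frame_rate_fluor)
  seg <- (seq_len(n_segments) - 0.5) / n_segments
  C <- sapply(times, function(t) wave_cn(p, seg, t, phi0))
  Clag <- sapply(times, function(t) wave_cn(p, seg, t - p$coupling_delay, phi0))
  fret <- p$baseline_ratio + p$strain_coupling * Clag +
    matrix(rnorm(length(C), 0, fret_noise_sd), nrow(C))
  list(times = times, C = C, fret = fret, params = p)
}

#' @export
print.worm_recording <- function(x, ...) {
  cat("<worm_recording>\n")
  for (ch in names(x$channels))
    cat(sprintf("  %-11s %d frames, %.2f fps\n", ch,
                length(x$channels[[ch]]$times),
                1 / mean(diff(x$channels[[ch]]$times))))
  cat(sprintf("  %dx%d px at %g um/px, seed %d\n", x$image_size[1],
              x$image_size[2], x$pixel_size, x$seed))
  invisible(x)
}
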