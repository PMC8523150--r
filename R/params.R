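#' Parameters of the synthetic worm model
#'
#' Defines the generative model behind [generate_recording()]: an undulating
#' worm whose midline curvature is a traveling sine wave,
#' \eqn{\kappa(s,t) = \kappa_0 \sin(2\pi(\nu s - f t) + \phi_0)}, rendered as a
#' dark body on a bright brightfield background and as two fluorescence
#' channels (donor E480, acceptor E535) whose per-pixel ratio encodes a
#' strain-dependent linear coupling of the FRET index to the side-signed
#' normalized curvature.
#'
#' Normalized curvature is defined throughout the package as
#' \eqn{C = \kappa \cdot L} (dimensionless), signed per body side: positive on
#' the contracted (inner) side of a bend, negative on the stretched side. The
#' side-resolved true FRET ratio is \eqn{r = r_0 + g\,C(s, t - \tau)} and the
#' total fluorescence intensity is \eqn{I = I_0 (1 + \beta C)}, so that both
#' emission channels rise on the contracting side. Channels are
#' \eqn{E_{480} = I(1-r)/2} and \eqn{E_{535} = I(1+r)/2}, which reproduces the
#' ratiometric index \eqn{(E_{535}-E_{480})/(E_{535}+E_{480}) = r} exactly
#' before noise.
#'
#' @param body_length Body length, micrometres.
#' @param half_width_profile Function of arc position `s` in \[0,1\] returning
#'   the local body half-width in micrometres; must taper towards 0 at both
#'   ends and be positive on the open interval. Default is an elliptical
#'   profile with maximum `0.035 * body_length`.
#' @param wave_amplitude Curvature wave amplitude \eqn{\kappa_0}, 1/µm.
#' @param wave_number Undulation wave number, cycles per body length.
#' @param wave_frequency Undulation frequency \eqn{f}, Hz (the crawl cycle is
#'   about 1 Hz).
#' @param strain_coupling Coupling \eqn{g}: FRET-ratio change per unit of
#'   side-signed normalized curvature (dimensionless). The "test" sensor
#'   strain has a sizeable positive value, a "control" strain a weak or zero
#'   one.
#' @param baseline_ratio Baseline FRET index \eqn{r_0} in (-1, 1).
#' @param intensity_gain Fractional total-intensity increase \eqn{\beta} per
#'   unit positive normalized curvature (contraction brightening).
#' @param coupling_delay Temporal lag \eqn{\tau} (seconds) of the FRET
#'   response behind curvature; 0 means instantaneous coupling.
#' @param noise_sd Gaussian read-noise standard deviation, counts.
#' @param background_level Fluorescence background, counts.
#' @param body_intensity Ideal total body fluorescence \eqn{I_0}, counts.
#' @param bf_background,bf_body Brightfield background and worm body levels,
#'   counts (worm darker than background).
#' @param frame_rate_bf,frame_rate_fluor Frame rates, Hz, for the brightfield
#'   and the (simultaneous donor/acceptor) fluorescence channels.
#' @param duration Recording duration, seconds; must cover at least two full
#'   undulation periods.
#' @param fluor_start Start time of the fluorescence clock relative to the
#'   brightfield clock, seconds. The default (half a brightfield interval)
#'   desynchronizes the cameras as in a real rig; 0 with
#'   `frame_rate_fluor = frame_rate_bf / 2` makes every fluorescence frame
#'   simultaneous with a brightfield frame.
#' @param pixel_size Image scale, µm per pixel.
#' @param image_size Image height and width in pixels, length-2 integer.
#' @param stage_jump_interval Mean interval between emulated stage-motion
#'   frame translations, seconds (jittered +/-25%); `Inf` disables them.
#' @param stage_jump_max Maximum whole-frame translation per stage move, px.
#' @param pharynx_s Arc position of the bright pharynx marker blob.
#' @param pharynx_rel_diameter Blob diameter as a fraction of body length.
#' @param pharynx_gain Blob intensity relative to `body_intensity`.
#' @param donor_shift,acceptor_shift Length-2 (row, col) pixel offsets of the
#'   donor and acceptor camera coordinates relative to brightfield; recovered
#'   at analysis time from the grid control points via
#'   [register_channels()].
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   recordings.
#'
#' @return An object of class `worm_model_params` (a validated list).
#' @seealso [generate_recording()], [make_strain_pair()]
#' @export
worm_model_params <- function(body_length = 1000,
                              half_width_profile = NULL,
                              wave_amplitude = 3 / body_length,
                              wave_number = 1.0,
                              wave_frequency = 1.0,
                              strain_coupling = 0.1,
                              baseline_ratio = 0.2,
                              intensity_gain = 0.05,
                              coupling_delay = 0,
                              noise_sd = 20,
                              background_level = 100,
                              body_intensity = 1000,
                              bf_background = 1000,
                              bf_body = 300,
                              frame_rate_bf = 37.61,
                              frame_rate_fluor = 19.69,
                              duration = 30,
                              fluor_start = NULL,
                              pixel_size = 3.125,
                              image_size = c(512L, 512L),
                              stage_jump_interval = 2,
                              stage_jump_max = 10,
                              pharynx_s = 0.05,
                              pharynx_rel_diameter = 0.10,
                              pharynx_gain = 3,
                              donor_shift = c(2, -1),
                              acceptor_shift = c(-1.5, 0.5),
                              seed = 1L) {
  if (is.null(half_width_profile)) {
    wmax <- 0.035 * body_length
    half_width_profile <- function(s) wmax * sqrt(pmax(1 - (2 * s - 1)^2, 0))
  }
  p <- list(
    body_length = body_length, half_width_profile = half_width_profile,
    wave_amplitude = wave_amplitude, wave_number = wave_number,
    wave_frequency = wave_frequency, strain_coupling = strain_coupling,
    baseline_ratio = baseline_ratio, intensity_gain = intensity_gain,
    coupling_delay = coupling_delay, noise_sd = noise_sd,
    background_level = background_level, body_intensity = body_intensity,
    bf_background = bf_background, bf_body = bf_body,
    frame_rate_bf = frame_rate_bf, frame_rate_fluor = frame_rate_fluor,
    duration = duration,
    fluor_start = if (is.null(fluor_start)) 0.5 / frame_rate_bf else fluor_start,
    pixel_size = pixel_size,
    image_size = as.integer(image_size),
    stage_jump_interval = stage_jump_interval,
    stage_jump_max = stage_jump_max,
    pharynx_s = pharynx_s, pharynx_rel_diameter = pharynx_rel_diameter,
    pharynx_gain = pharynx_gain,
    donor_shift = donor_shift, acceptor_shift = acceptor_shift,
    seed = as.integer(seed)
  )
  class(p) <- "worm_model_params"
  validate_worm_model_params(p)
  p
}

validate_worm_model_params <- function(p) {
  stopifnot(inherits(p, "worm_model_params"))
  cn_max <- abs(p$wave_amplitude) * p$body_length
  if (abs(p$baseline_ratio) + abs(p$strain_coupling) * cn_max >= 1)
    stop("invalid parameters: |r0| + |g| * max|normalized curvature| must be < 1")
  if (abs(p$baseline_ratio) >= 1)
    stop("baseline_ratio must lie in (-1, 1)")
  sprobe <- seq(0.01, 0.99, by = 0.01)
  if (any(p$half_width_profile(sprobe) <= 0))
    stop("half_width_profile must be positive on the open interval (0, 1)")
  if (p$duration * p$wave_frequency < 2)
    stop("duration must cover at least 2 full undulation periods")
  if (p$duration * p$frame_rate_fluor < 2)
    stop("duration too short for the fluorescence frame rate")
  if (length(p$image_size) != 2L || any(p$image_size < 64L))
    stop("image_size must be two integers >= 64")
  # footprint probe over one wave period (the shape cycle is periodic):
  # max centred midline extent plus half-width, stage motion and blob margins
  ext <- 0
  for (tp in seq(0, 1 / max(p$wave_frequency, 1e-6), length.out = 12)) {
    s <- seq(0, 1, length.out = 100)
    kap <- p$wave_amplitude * sin(2 * pi * (p$wave_number * s -
                                              p$wave_frequency * tp))
    dl <- p$body_length / 99
    psi <- cumsum(c(0, (kap[-1] + kap[-100]) / 2 * dl))
    x <- cumsum(c(0, (cos(psi[-1]) + cos(psi[-100])) / 2 * dl))
    y <- cumsum(c(0, (sin(psi[-1]) + sin(psi[-100])) / 2 * dl))
    ext <- max(ext, abs(x - mean(x)), abs(y - mean(y)))
  }
  margin_px <- max(p$half_width_profile(sprobe)) / p$pixel_size +
    p$stage_jump_max + p$pharynx_rel_diameter * p$body_length / 2 / p$pixel_size
  if (ext / p$pixel_size + margin_px > min(p$image_size) / 2 * 0.96)
    stop("worm does not fit in the frame: increase image_size or shrink body_length")
  invisible(p)
}

#' @export
print.worm_model_params <- function(x, ...) {
  cat("<worm_model_params>\n")
  cat(sprintf("  body %g um, wave %g cycles/body @ %g Hz, amplitude k0*L = %g\n",
              x$body_length, x$wave_number, x$wave_frequency,
              x$wave_amplitude * x$body_length))
  cat(sprintf("  coupling g = %g, r0 = %g, beta = %g, delay = %g s\n",
              x$strain_coupling, x$baseline_ratio, x$intensity_gain,
              x$coupling_delay))
  cat(sprintf("  %g s at %g/%g fps, %dx%d px (%g um/px), noise sd %g, seed %d\n",
              x$duration, x$frame_rate_bf, x$frame_rate_fluor,
              x$image_size[1], x$image_size[2], x$pixel_size, x$noise_sd,
              x$seed))
  invisible(x)
}
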