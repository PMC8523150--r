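#' Fit quartic polynomials to the midline coordinates
#'
#' Fits quartic (degree-4) polynomials of the midline row and column
#' coordinates against the normalized cumulative arc-length parameter
#' \eqn{u \in [0,1]}. Because a single quartic cannot represent a full
#' undulation period, the fits are local by default: one pair of quartics per
#' evaluation point, over a window of `2 * half_window` body lengths centred
#' on it (`half_window = Inf` reproduces a single global fit). Derivatives at
#' the evaluation points come from the fitted coefficients.
#'
#' @param midline Matrix n x 2 of ordered (row, col) midline points, n >= 10.
#' @param eval_at Arc positions at which curvature will be evaluated
#'   (default: 100 segment centres).
#' @param half_window Half-width of the local fitting window in units of the
#'   normalized arc parameter.
#' @return Object of class `midline_fit`: per-evaluation-point first and
#'   second derivatives of row and column with respect to `u`, overall fit
#'   residual RMS (px), `eval_at`, `arc_length_px`.
#' @export
fit_midline_polynomials <- function(midline, eval_at = (seq_len(100) - 0.5) / 100,
                                    half_window = 0.125) {
  midline <- as.matrix(midline)
  n <- nrow(midline)
  if (n < 10) stop("need at least 10 midline points")
  arc <- c(0, cumsum(sqrt(diff(midline[, 1])^2 + diff(midline[, 2])^2)))
  total <- arc[n]
  if (total <= 0) stop("degenerate midline")
  u <- arc / total
  d1r <- d1c <- d2r <- d2c <- numeric(length(eval_at))
  res2 <- 0; nres <- 0
  # midlines are resampled to uniform arc spacing, so for a given point count
  # the per-window design matrices are identical across frames: cache their
  # pseudo-inverses (keyed on n, eval_at, half_window) unless u is non-uniform
  uniform <- max(abs(u - seq(0, 1, length.out = n))) < 5e-3
  cache <- NULL
  if (uniform) {
    key <- paste0("fit_", n, "_", length(eval_at), "_", half_window,
                  "_", signif(sum(eval_at), 12))
    cache <- .wormfret_cache[[key]]
    if (is.null(cache)) {
      uu <- seq(0, 1, length.out = n)
      cache <- lapply(eval_at, function(u0) {
        sel <- if (is.finite(half_window))
          which(uu >= u0 - half_window & uu <= u0 + half_window) else seq_len(n)
        if (length(sel) < 6) sel <- order(abs(uu - u0))[1:6]
        X <- outer(uu[sel] - u0, 0:4, `^`)
        qrX <- qr(X)
        if (qrX$rank < 5) stop("rank-deficient midline fit (degenerate midline)")
        R <- qr.R(qrX)
        pinv <- backsolve(R, t(qr.Q(qrX)))
        list(sel = sel, X = X, pinv = pinv)
      })
      .wormfret_cache[[key]] <- cache
    }
  }
  for (k in seq_along(eval_at)) {
    if (uniform) {
      w <- cache[[k]]
      sel <- w$sel; X <- w$X
      cr <- w$pinv %*% midline[sel, 1]
      cc <- w$pinv %*% midline[sel, 2]
    } else {
      u0 <- eval_at[k]
      sel <- if (is.finite(half_window))
        which(u >= u0 - half_window & u <= u0 + half_window) else seq_len(n)
      if (length(sel) < 6) sel <- order(abs(u - u0))[1:6]
      X <- outer(u[sel] - u0, 0:4, `^`)
      qrX <- qr(X)
      if (qrX$rank < 5) stop("rank-deficient midline fit (degenerate midline)")
      cr <- qr.coef(qrX, midline[sel, 1])
      cc <- qr.coef(qrX, midline[sel, 2])
    }
    d1r[k] <- cr[2]; d2r[k] <- 2 * cr[3]
    d1c[k] <- cc[2]; d2c[k] <- 2 * cc[3]
    rres <- midline[sel, 1] - X %*% cr
    cres <- midline[sel, 2] - X %*% cc
    res2 <- res2 + sum(rres^2 + cres^2); nres <- nres + length(sel)
  }
  structure(list(eval_at = eval_at, d1r = d1r, d1c = d1c, d2r = d2r,
                 d2c = d2c, residual_rms = sqrt(res2 / (2 * nres)),
                 arc_length_px = total, half_window = half_window),
            class = "midline_fit")
}

#' Curvature along the midline from the polynomial fit
#'
#' Evaluates \eqn{K = |x'y'' - y'x''| / (x'^2 + y'^2)^{3/2}} at each
#' evaluation point of a [fit_midline_polynomials()] result, with
#' \eqn{x = } column, \eqn{y = } row as functions of the arc parameter.
#' Returned in 1/µm via the pixel size. The signed value (positive where the
#' centre of curvature lies on the positive-cross-product side, i.e. side
#' label 1 of [track_sides()]) is kept alongside for side-signing.
#'
#' @param fit A `midline_fit`.
#' @param pixel_size µm per pixel.
#' @return List with `K` (unsigned, 1/µm), `k_signed` (1/µm) and `eval_at`.
#' @export
curvature_profile <- function(fit, pixel_size = 1) {
  stopifnot(inherits(fit, "midline_fit"))
  xp <- fit$d1c; yp <- fit$d1r
  xpp <- fit$d2c; ypp <- fit$d2r
  speed2 <- xp^2 + yp^2
  if (any(speed2 <= 0))
    stop("degenerate parameterization: zero speed at an evaluation point")
  k_px <- (xp * ypp - yp * xpp) / speed2^1.5   # 1/(arc px units)
  k_signed <- k_px / pixel_size
  list(K = abs(k_signed), k_signed = k_signed, eval_at = fit$eval_at)
}

#' Side-signed normalized curvature
#'
#' Converts curvature to the dimensionless normalized curvature
#' \eqn{C = \pm K L} (K in 1/µm, L the body length in µm): equal magnitude on
#' the two sides, positive on the contracted (inner) side of the bend and
#' negative on the stretched (outer) side. Side label 1 is the side where the
#' image-plane cross product of the tail-to-head axis and the
#' midline-to-centroid vector is positive, which is the inner side exactly
#' when the signed curvature is positive.
#'
#' @param k_signed Signed curvature per segment, 1/µm.
#' @param side Persistent side label, 1 or 2 (scalar or vector).
#' @param body_length Body length, µm.
#' @return Normalized curvature, same shape as `k_signed`.
#' @export
signed_normalized_curvature <- function(k_signed, side, body_length) {
  stopifnot(all(side %in% c(1, 2)))
  d <- ifelse(side == 1, 1, -1)
  d * k_signed * body_length
}

#' Ratiometric FRET index
#'
#' \eqn{\mathrm{FRET} = (E_{535} - E_{480}) / (E_{535} + E_{480})}, in
#' \[-1, 1\]. The ratio cancels any common multiplicative intensity change
#' (illumination, contraction brightening) exactly. A zero denominator gives
#' `NA`, not an error.
#'
#' @param E535,E480 Acceptor and donor emissions (non-negative; vectors,
#'   matrices or arrays of equal shape).
#' @return FRET index, same shape as the inputs.
#' @export
fret_value <- function(E535, E480) {
  if (any(E535 < 0 | E480 < 0, na.rm = TRUE))
    stop("emission values must be non-negative")
  tot <- E535 + E480
  out <- (E535 - E480) / tot
  out[!is.na(tot) & tot == 0] <- NA_real_
  out
}

#' Per-channel intensity change relative to the trace minimum
#'
#' \eqn{\Delta F / F_{min} = (F - F_{min}) / F_{min}}, used when comparing
#' single-fluorophore intensities (the ratiometric index is preferred for
#' FRET itself).
#'
#' @param trace Numeric vector (NAs ignored for the minimum).
#' @return Normalized trace, minimum exactly 0.
#' @export
channel_delta_over_min <- function(trace) {
  fmin <- min(trace, na.rm = TRUE)
  if (!is.finite(fmin) || fmin <= 0)
    stop("trace minimum must be positive for dF/Fmin normalization")
  (trace - fmin) / fmin
}

#' Assemble curvature, emission and FRET kymographs
#'
#' Builds the aligned segments x time x side matrices of normalized curvature
#' C(x,t), background-subtracted E480 and E535, and the FRET index, with a
#' shared missing-value mask, from per-frame samples and curvature profiles.
#' On forward-crawling data the traveling body wave appears as diagonal
#' banding in C(x,t).
#'
#' @param samples Row-bound [sample_fluorescence()] output over frames.
#' @param curvatures Data frame with columns `frame`, `segment` (0-based) and
#'   `k_signed` (1/µm).
#' @param body_length_um Body length used for normalization, µm.
#' @param times Named numeric vector or data.frame mapping frame index to
#'   seconds; default uses the frame index order.
#' @param n_segments Number of segments (default 100).
#' @param frames Frame indices forming the kymograph columns; defaults to
#'   the frames present in `samples`. Passing the full fluorescence frame
#'   range keeps the time base uniform (invalid frames become missing
#'   columns), which cycle detection and cross-correlation rely on.
#' @return Object of class `signal_matrix`: arrays `C`, `E480`, `E535`,
#'   `FRET` of dim (segments, frames, 2 sides), `missing` mask, `frames`,
#'   `times`.
#' @export
build_kymographs <- function(samples, curvatures, body_length_um,
                             times = NULL, n_segments = 100L, frames = NULL) {
  if (is.null(frames)) frames <- sort(unique(samples$frame))
  if (length(frames) == 0 || nrow(samples) == 0) stop("no valid frames")
  Tn <- length(frames)
  fi <- match(samples$frame, frames)
  samples <- samples[!is.na(fi), ]; fi <- fi[!is.na(fi)]
  arr <- function() array(NA_real_, c(n_segments, Tn, 2))
  E480 <- arr(); E535 <- arr(); C <- arr()
  ok <- !samples$excluded & !is.na(samples$E480)
  ii <- cbind(samples$segment + 1L, fi, samples$side)[ok, , drop = FALSE]
  E480[ii] <- samples$E480[ok]
  E535[ii] <- samples$E535[ok]
  kf <- match(curvatures$frame, frames)
  kok <- !is.na(kf) & !is.na(curvatures$k_signed)
  for (side in 1:2) {
    cc <- cbind(curvatures$segment + 1L, kf, side)[kok, , drop = FALSE]
    C[cc] <- signed_normalized_curvature(curvatures$k_signed[kok], side,
                                         body_length_um)
  }
  FRET <- fret_value(E535, E480)
  structure(list(C = C, E480 = E480, E535 = E535, FRET = FRET,
                 missing = is.na(FRET) | is.na(C), frames = frames,
                 times = if (is.null(times)) frames else
                   as.numeric(times[as.character(frames)]),
                 n_segments = n_segments),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %d segments x %d frames x 2 sides, %.1f%% missing\n",
              dim(x$C)[1], dim(x$C)[2], 100 * mean(x$missing)))
  invisible(x)
}
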