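#' Least-squares similarity registration from point correspondences
#'
#' Estimates the 2-D similarity transform (rotation, isotropic scale,
#' translation) mapping source points (fluorescence camera coordinates) onto
#' destination points (brightfield coordinates), from grid-image control
#' points, by the closed-form least-squares solution (SVD of the centred
#' cross-covariance).
#'
#' @param src,dst Matrices of corresponding points, n x 2 (row, col), n >= 3
#'   and not collinear.
#' @param residual_bound RMS residual (px) above which a `high_residual`
#'   warning flag is set.
#' @return Object of class `channel_registration`: `scale`, `angle`
#'   (radians), `R` (2 x 2 scaled rotation), `translation`, `residual_rms`,
#'   `flags`.
#' @export
register_channels <- function(src, dst, residual_bound = 1) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2, ncol(dst) == 2, nrow(src) == nrow(dst))
  n <- nrow(src)
  if (n < 3) stop("need at least 3 point correspondences")
  ms <- colMeans(src); md <- colMeans(dst)
  X <- sweep(src, 2, ms); Y <- sweep(dst, 2, md)
  svx <- svd(X)$d
  if (svx[1] <= 0 || svx[2] / svx[1] < 1e-8)
    stop("control points are collinear")
  sv <- svd(crossprod(Y, X) / n)
  S <- diag(2)
  if (det(sv$u %*% t(sv$v)) < 0) S[2, 2] <- -1
  Rm <- sv$u %*% S %*% t(sv$v)
  varx <- sum(X^2) / n
  scale <- sum(diag(S) * sv$d) / varx
  A <- scale * Rm
  tr <- md - as.vector(A %*% ms)
  fitted <- sweep(src %*% t(A), 2, tr, `+`)
  rms <- sqrt(mean(rowSums((fitted - dst)^2)))
  flags <- if (rms > residual_bound) "high_residual" else character()
  structure(list(scale = scale, angle = atan2(Rm[2, 1], Rm[1, 1]),
                 R = A, translation = tr, residual_rms = rms, flags = flags),
            class = "channel_registration")
}

#' Apply a channel registration to points
#' @param reg A `channel_registration`.
#' @param pts Matrix n x 2 of (row, col) points in source coordinates.
#' @return Matrix n x 2 in destination coordinates.
#' @export
apply_registration <- function(reg, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  sweep(pts %*% t(reg$R), 2, reg$translation, `+`)
}

#' Invert a channel registration
#' @param reg A `channel_registration`.
#' @return The inverse `channel_registration`.
#' @export
invert_registration <- function(reg) {
  Ri <- solve(reg$R)
  structure(list(scale = 1 / reg$scale, angle = -reg$angle, R = Ri,
                 translation = -as.vector(Ri %*% reg$translation),
                 residual_rms = reg$residual_rms, flags = reg$flags),
            class = "channel_registration")
}

#' Identity channel registration
#' @return A `channel_registration` that maps points onto themselves.
#' @export
identity_registration <- function() {
  structure(list(scale = 1, angle = 0, R = diag(2), translation = c(0, 0),
                 residual_rms = 0, flags = character()),
            class = "channel_registration")
}

#' @export
print.channel_registration <- function(x, ...) {
  cat(sprintf("<channel_registration> scale %.5f, angle %.4f rad, shift (%.2f, %.2f), RMS %.3f px\n",
              x$scale, x$angle, x$translation[1], x$translation[2],
              x$residual_rms))
  invisible(x)
}

#' Temporally match brightfield frames to fluorescence frames
#'
#' Fluorescence is recorded at a lower rate than brightfield, so each
#' fluorescence frame is paired with the nearest-in-time brightfield frame
#' (ties broken toward the earlier frame). Fluorescence frames whose nearest
#' brightfield frame is further away than one brightfield interval (e.g.
#' across a dropped-frame gap) are flagged unpaired.
#'
#' @param t_bf,t_fluor Strictly increasing timestamp vectors (seconds).
#' @return Data frame with columns `fluor_index`, `bf_index`, `offset`
#'   (t_fluor - t_bf, seconds) and `paired`.
#' @export
match_frames <- function(t_bf, t_fluor) {
  if (length(t_bf) == 0 || length(t_fluor) == 0)
    stop("empty timestamp list")
  if (is.unsorted(t_bf, strictly = TRUE) || is.unsorted(t_fluor, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  interval <- median(diff(t_bf))
  lo <- findInterval(t_fluor, t_bf)   # index of last t_bf <= t_fluor (0 if none)
  lo_ok <- pmax(lo, 1L)
  hi <- pmin(lo + 1L, length(t_bf))
  dlo <- abs(t_fluor - t_bf[lo_ok])
  dhi <- abs(t_bf[hi] - t_fluor)
  use_lo <- lo >= 1L & dlo <= dhi    # tie -> earlier frame
  idx <- ifelse(use_lo, lo_ok, hi)
  offset <- t_fluor - t_bf[idx]
  data.frame(fluor_index = seq_along(t_fluor), bf_index = idx,
             offset = offset, paired = abs(offset) <= interval)
}
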