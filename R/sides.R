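#' Split the body mask into its two sides
#'
#' Removes a thin band around the rasterized midline (1-px dilation by
#' default) from the body mask; the remainder must fall into exactly two
#' connected components, each spanning the body head to tail. Every body
#' pixel is also assigned to its nearest midline point, which defines both
#' the arc coordinate used for per-segment sampling (the nearest-point
#' partition is exactly the set of body-perpendicular bands of one
#' inter-point spacing) and the side membership test.
#'
#' @param geometry A valid `body_geometry` from [orient_head_tail()].
#' @param band_px Half-thickness of the removed midline band, px.
#' @param span Arc interval that each side component must cover to count as
#'   spanning head to tail.
#' @return List with logical matrices `A` and `B`, the per-pixel
#'   `nearest` midline-point index map, `s_map`, `valid` and `flags`
#'   ("split_failed" when the split does not give two spanning components).
#' @export
build_side_masks <- function(geometry, band_px = 1, span = c(0.15, 0.85)) {
  stopifnot(inherits(geometry, "body_geometry"), isTRUE(geometry$valid))
  mask <- geometry$mask
  ml <- geometry$midline
  area <- sum(mask)
  mean_hw <- area / (2 * geometry$length_px)
  radius <- 2.5 * mean_hw + 4
  # work on the body bounding box; lift results back to full frames
  midx <- which(mask, arr.ind = TRUE)
  pad <- band_px + 2
  r0 <- max(1, min(midx[, 1]) - pad); r1 <- min(nrow(mask), max(midx[, 1]) + pad)
  c0 <- max(1, min(midx[, 2]) - pad); c1 <- min(ncol(mask), max(midx[, 2]) + pad)
  cmask <- mask[r0:r1, c0:c1, drop = FALSE]
  mlr <- ml[, 1] - r0 + 1; mlc <- ml[, 2] - c0 + 1
  a <- cpp_assign_nearest(nrow(cmask), ncol(cmask), mlr, mlc,
                          numeric(1), radius)
  band <- matrix(FALSE, nrow(cmask), ncol(cmask))
  band[cbind(pmin(pmax(round(mlr), 1), nrow(cmask)),
             pmin(pmax(round(mlc), 1), ncol(cmask)))] <- TRUE
  if (band_px > 0)
    band <- EBImage::dilate(band, EBImage::makeBrush(2 * band_px + 1,
                                                     "box")) > 0
  region <- cmask & !band & a$nearest > 0
  lab <- EBImage::bwlabel(region)
  nlab <- max(lab)
  if (nlab < 2)
    return(list(valid = FALSE, flags = "split_failed"))
  svec <- geometry$s
  labidx <- which(lab > 0)
  labval <- lab[labidx]
  info <- lapply(seq_len(nlab), function(l) {
    idx <- labidx[labval == l]
    sv <- svec[a$nearest[idx]]
    list(idx = idx, n = length(idx), smin = min(sv), smax = max(sv))
  })
  spanning <- which(vapply(info, function(x)
    x$smin <= span[1] && x$smax >= span[2], logical(1)))
  if (length(spanning) != 2)
    return(list(valid = FALSE, flags = "split_failed"))
  ord <- spanning[order(vapply(info[spanning], `[[`, 0L, "n"),
                        decreasing = TRUE)]
  lift <- function(cropidx) {
    cr <- (cropidx - 1) %% nrow(cmask) + r0
    cc <- (cropidx - 1) %/% nrow(cmask) + c0
    cbind(cr, cc)
  }
  A <- matrix(FALSE, nrow(mask), ncol(mask)); A[lift(info[[ord[1]]]$idx)] <- TRUE
  B <- matrix(FALSE, nrow(mask), ncol(mask)); B[lift(info[[ord[2]]]$idx)] <- TRUE
  nearest <- matrix(0L, nrow(mask), ncol(mask))
  s_map <- matrix(NA_real_, nrow(mask), ncol(mask))
  inb <- which(a$nearest > 0 & cmask)
  li <- lift(inb)
  nearest[li] <- a$nearest[inb]
  s_map[li] <- svec[a$nearest[inb]]
  list(A = A, B = B, nearest = nearest, s_map = s_map,
       valid = TRUE, flags = character())
}

signed_angle_deg <- function(axis, v) {
  # axis, v as (row, col); angle of v relative to axis, sign = image-plane
  # cross product (x = col, y = row)
  cross <- axis[2] * v[1] - axis[1] * v[2]
  dot <- sum(axis * v)
  atan2(cross, dot) * 180 / pi
}

#' Assign persistent side labels by the angle-comparison rule
#'
#' Compares, for each side mask, the angle between the head-to-tail direction
#' of the midline and the vector from the midline to the side's mass. The
#' comparison is made in the local midline frame: every side pixel
#' contributes the angle of its offset from the nearest midline point,
#' measured relative to the local head-to-tail tangent, and the side's angle
#' is the circular mean. A side lying consistently to one lateral side of the
#' body axis scores close to +90 or -90 degrees regardless of posture, so the
#' sign gives a persistent label (side 1 = positive angle): a crawling worm
#' cannot flip its chirality within a recording, and the label only depends
#' on head/tail orientation being tracked correctly. Frames where the two
#' angles share a sign, or are separated by less than `angle_threshold`
#' degrees, are ambiguous and marked invalid. (A variant using the whole-side
#' centroid against the global tail-to-head chord is not discriminative:
#' in bent postures both centroids fall on the concave side of the midline.)
#'
#' @param side_masks Result of [build_side_masks()].
#' @param geometry The corresponding `body_geometry`.
#' @param previous Previous `side_assignment` (kept for bookkeeping; labels
#'   derive from the chirality sign and need no history).
#' @param angle_threshold Minimum angular separation, degrees.
#' @return Object of class `side_assignment`: `label_A`, `label_B` (1 or 2),
#'   `angles`, `centroid_A`, `centroid_B`, `separation`, `valid`, `reason`.
#' @export
track_sides <- function(side_masks, geometry, previous = NULL,
                        angle_threshold = 10) {
  if (!isTRUE(side_masks$valid))
    return(structure(list(valid = FALSE, reason = "split_failed"),
                     class = "side_assignment"))
  ml <- geometry$midline
  n <- nrow(ml)
  tang <- rbind(ml[2, ] - ml[1, ], ml[-1, , drop = FALSE] - ml[-n, , drop = FALSE])
  tang <- tang / sqrt(rowSums(tang^2))   # head -> tail unit tangents
  nr <- nrow(side_masks$A)
  ctrs <- lapply(list(side_masks$A, side_masks$B), function(m)
    colMeans(which(m, arr.ind = TRUE)))
  ang <- vapply(list(side_masks$A, side_masks$B), function(m) {
    idx <- which(m)
    ni <- side_masks$nearest[idx]
    pr <- (idx - 1) %% nr + 1
    pc <- (idx - 1) %/% nr + 1
    dr <- pr - ml[ni, 1]; dc <- pc - ml[ni, 2]
    nrm <- sqrt(dr^2 + dc^2)
    ok <- nrm > 0
    # local frame: x along the head->tail tangent, y its image-plane normal
    xl <- (tang[ni, 2] * dc + tang[ni, 1] * dr)[ok] / nrm[ok]
    yl <- (tang[ni, 2] * dr - tang[ni, 1] * dc)[ok] / nrm[ok]
    atan2(mean(yl), mean(xl)) * 180 / pi
  }, numeric(1))
  sep <- abs(ang[1] - ang[2])
  sep <- min(sep, 360 - sep)
  if (sign(ang[1]) == sign(ang[2]))
    return(structure(list(angles = ang, separation = sep, valid = FALSE,
                          reason = "same_side"), class = "side_assignment"))
  if (sep < angle_threshold)
    return(structure(list(angles = ang, separation = sep, valid = FALSE,
                          reason = "ambiguous_angle"),
                     class = "side_assignment"))
  la <- if (ang[1] > 0) 1L else 2L
  structure(list(label_A = la, label_B = 3L - la, angles = ang,
                 centroid_A = ctrs[[1]], centroid_B = ctrs[[2]],
                 separation = sep, valid = TRUE, reason = NA_character_),
            class = "side_assignment")
}

#' Sample background-subtracted fluorescence per segment and side
#'
#' For each of the `n_segments` body segments and each side, averages the
#' donor (E480) and acceptor (E535) counts over the pixels of the
#' body-perpendicular band (nearest-midline-point partition) intersected with
#' the side mask. Pixel coordinates are mapped from brightfield into each
#' fluorescence camera through the channel registrations and sampled
#' nearest-neighbour. The per-frame background (median of non-body pixels) is
#' subtracted per channel; samples overlapping the pharynx marker are
#' excluded, as are samples whose total emission falls below
#' `low_emission_k` times the robust background SD.
#'
#' @param geometry `body_geometry` for the frame.
#' @param side_masks Result of [build_side_masks()].
#' @param assignment `side_assignment` from [track_sides()].
#' @param donor_frame,acceptor_frame Fluorescence frames (own coordinates).
#' @param reg_donor,reg_acceptor `channel_registration`s mapping each
#'   fluorescence camera into brightfield coordinates (`NULL` = identity).
#' @param low_emission_k Low-emission exclusion multiplier.
#' @param return_pixels Attach the per-pixel linear indices (brightfield
#'   frame) and their sample keys as attribute `"pixels"`, for audits
#'   against per-pixel ground truth.
#' @return Data frame of class rows: `frame`, `segment` (0-based),
#'   `side` (persistent label 1/2), `E480`, `E535`, `n_pixels`, `excluded`,
#'   `reason`.
#' @export
sample_fluorescence <- function(geometry, side_masks, assignment,
                                donor_frame, acceptor_frame,
                                reg_donor = NULL, reg_acceptor = NULL,
                                low_emission_k = 3, return_pixels = FALSE) {
  stopifnot(isTRUE(side_masks$valid), isTRUE(assignment$valid))
  nseg <- geometry$n_segments
  idxA <- which(side_masks$A); idxB <- which(side_masks$B)
  idx <- c(idxA, idxB)
  side_lab <- c(rep(assignment$label_A, length(idxA)),
                rep(assignment$label_B, length(idxB)))
  nr <- nrow(side_masks$A)
  pr <- (idx - 1) %% nr + 1
  pc <- (idx - 1) %/% nr + 1
  # restrict to body-interior pixels: outer-boundary pixels mix body and
  # background after the sub-pixel channel registration and would bias the
  # ratio of thin samples
  bm <- geometry$mask
  interior <- bm[cbind(pmax(pr - 1, 1), pc)] & bm[cbind(pmin(pr + 1, nr), pc)] &
    bm[cbind(pr, pmax(pc - 1, 1))] & bm[cbind(pr, pmin(pc + 1, ncol(bm)))]
  idx <- idx[interior]; side_lab <- side_lab[interior]
  pr <- pr[interior]; pc <- pc[interior]
  seg <- pmin(floor(side_masks$s_map[idx] * nseg), nseg - 1L)

  grab <- function(frame, reg) {
    # bilinear sampling at the registered sub-pixel position
    pts <- cbind(pr, pc)
    if (!is.null(reg)) pts <- apply_registration(invert_registration(reg), pts)
    r0 <- floor(pts[, 1]); c0 <- floor(pts[, 2])
    fr <- pts[, 1] - r0; fc <- pts[, 2] - c0
    ok <- r0 >= 1 & r0 + 1 <= nrow(frame) & c0 >= 1 & c0 + 1 <= ncol(frame)
    val <- rep(NA_real_, nrow(pts))
    i <- which(ok)
    val[i] <- (1 - fr[i]) * (1 - fc[i]) * frame[cbind(r0[i], c0[i])] +
      (1 - fr[i]) * fc[i] * frame[cbind(r0[i], c0[i] + 1)] +
      fr[i] * (1 - fc[i]) * frame[cbind(r0[i] + 1, c0[i])] +
      fr[i] * fc[i] * frame[cbind(r0[i] + 1, c0[i] + 1)]
    list(val = val, rr = round(pts[, 1]), cc = round(pts[, 2]), ok = ok)
  }
  gd <- grab(donor_frame, reg_donor)
  ga <- grab(acceptor_frame, reg_acceptor)

  background <- function(frame, g) {
    # subsampled non-body pixels; a strided sample is ample for median/MAD
    bodymark <- matrix(FALSE, nrow(frame), ncol(frame))
    bodymark[cbind(g$rr[g$ok], g$cc[g$ok])] <- TRUE
    cand <- seq(1, length(frame), by = 7)
    bgpix <- frame[cand][!bodymark[cand]]
    c(med = median(bgpix), sd = mad(bgpix))
  }
  bgd <- background(donor_frame, gd)
  bga <- background(acceptor_frame, ga)

  # pharynx overlap evaluated in acceptor coordinates (where it was detected)
  ph <- rep(FALSE, length(idx))
  if (!is.null(geometry$pharynx) && !is.null(geometry$pharynx$mask_fluor)) {
    pmf <- geometry$pharynx$mask_fluor
    pidx <- which(pmf, arr.ind = TRUE)
    pr0 <- max(1, min(pidx[, 1]) - 4); pr1 <- min(nrow(pmf), max(pidx[, 1]) + 4)
    pc0 <- max(1, min(pidx[, 2]) - 4); pc1 <- min(ncol(pmf), max(pidx[, 2]) + 4)
    pmc <- EBImage::dilate(pmf[pr0:pr1, pc0:pc1, drop = FALSE],
                           EBImage::makeBrush(5, "disc")) > 0
    inside <- ga$ok & ga$rr >= pr0 & ga$rr <= pr1 & ga$cc >= pc0 & ga$cc <= pc1
    ph[inside] <- pmc[cbind(ga$rr[inside] - pr0 + 1, ga$cc[inside] - pc0 + 1)]
  }

  keep <- !is.na(gd$val) & !is.na(ga$val)
  nk <- 2L * nseg
  key <- (side_lab - 1L) * nseg + seg + 1L   # 1..nseg side 1, then side 2
  n_pix <- tabulate(key[keep], nbins = nk)
  sums <- rowsum(cbind(gd$val[keep], ga$val[keep], as.numeric(ph[keep])),
                 key[keep])
  grp <- as.integer(rownames(sums))
  e480 <- e535 <- ph_frac <- rep(NA_real_, nk)
  e480[grp] <- sums[, 1] / n_pix[grp] - bgd[["med"]]
  e535[grp] <- sums[, 2] / n_pix[grp] - bga[["med"]]
  ph_frac[grp] <- sums[, 3] / n_pix[grp]
  ph_frac[is.na(ph_frac)] <- 0

  out <- data.frame(frame = geometry$frame_index,
                    segment = rep(0:(nseg - 1), 2),
                    side = rep(1:2, each = nseg),
                    E480 = e480, E535 = e535, n_pixels = n_pix,
                    excluded = FALSE, reason = NA_character_)
  clip <- !is.na(out$E480) & !is.na(out$E535) & (out$E480 < 0 | out$E535 < 0)
  out$E480 <- pmax(out$E480, 0)
  out$E535 <- pmax(out$E535, 0)
  out$reason[clip] <- "negative_clipped"

  robust_sd <- sqrt(bgd["sd"]^2 + bga["sd"]^2)
  low <- !is.na(out$E480) & (out$E480 + out$E535 < low_emission_k * robust_sd)
  out$excluded[low] <- TRUE
  out$reason[low] <- "low_emission"
  out$excluded[ph_frac > 0] <- TRUE
  out$reason[ph_frac > 0] <- "pharynx"
  miss <- out$n_pixels == 0
  out$excluded[miss] <- TRUE
  out$reason[miss] <- "empty"
  out$E480[miss] <- NA_real_
  out$E535[miss] <- NA_real_
  rownames(out) <- NULL
  if (return_pixels)
    attr(out, "pixels") <- list(idx = idx[keep], key = key[keep])
  out
}
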