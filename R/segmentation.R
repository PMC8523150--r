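#' Segment the worm body from a brightfield frame
#'
#' The worm appears dark on a bright background in near-infrared brightfield,
#' so segmentation is an Otsu intensity threshold followed by selection of a
#' plausible connected component, morphological closing and hole filling.
#'
#' @param frame Numeric matrix, single brightfield frame (worm darker than
#'   background).
#' @param area_bounds Optional length-2 vector of plausible worm areas in
#'   pixels; components outside the bounds are treated as debris. Default
#'   `NULL` accepts any component at least `min_area` large, keeping the
#'   largest.
#' @param min_area Minimum credible worm area, px (default 150).
#' @param close_radius Radius of the closing brush, px.
#' @param threshold Optional fixed intensity threshold; default recomputes
#'   Otsu's threshold on this frame (illumination is stable within a
#'   recording, so callers may estimate it once).
#' @return List with `mask` (logical matrix), `valid` (logical) and `flags`
#'   (character vector; "no_component" marks an invalid frame, "ambiguous"
#'   marks multiple plausible components of which the largest was kept).
#' @export
segment_body <- function(frame, area_bounds = NULL, min_area = 150,
                         close_radius = 2, threshold = NULL) {
  stopifnot(is.matrix(frame))
  mx <- max(frame)
  if (mx <= 0 || sd(frame) == 0)
    return(list(mask = NULL, valid = FALSE, flags = "no_component"))
  thr <- if (is.null(threshold)) EBImage::otsu(frame / mx, range = c(0, 1)) * mx
         else threshold
  raw <- frame < thr
  if (!any(raw) || all(raw))
    return(list(mask = NULL, valid = FALSE, flags = "no_component"))
  # class-separability guard: on a worm frame the foreground/background
  # means are many noise SDs apart; on background-only frames the Otsu
  # threshold just splits the noise distribution
  mu_lo <- mean(frame[raw]); mu_hi <- mean(frame[!raw])
  s_w <- sqrt((sum((frame[raw] - mu_lo)^2) + sum((frame[!raw] - mu_hi)^2)) /
                length(frame))
  if (s_w > 0 && (mu_hi - mu_lo) / s_w < 5)
    return(list(mask = NULL, valid = FALSE, flags = "no_component"))
  # label only within the thresholded bounding box (plus margin)
  rws <- which(rowSums(raw) > 0); cls <- which(colSums(raw) > 0)
  b0 <- c(max(1, min(rws) - 2), max(1, min(cls) - 2))
  b1 <- c(min(nrow(raw), max(rws) + 2), min(ncol(raw), max(cls) + 2))
  rawc <- raw[b0[1]:b1[1], b0[2]:b1[2], drop = FALSE]
  labc <- EBImage::bwlabel(rawc)
  lab <- matrix(0L, nrow(raw), ncol(raw))
  lab[b0[1]:b1[1], b0[2]:b1[2]] <- labc
  areas <- tabulate(lab[lab > 0])
  lo <- if (is.null(area_bounds)) min_area else area_bounds[1]
  hi <- if (is.null(area_bounds)) Inf else area_bounds[2]
  plausible <- which(areas >= lo & areas <= hi)
  flags <- character()
  if (length(plausible) == 0)
    return(list(mask = NULL, valid = FALSE, flags = "no_component"))
  if (length(plausible) > 1) flags <- "ambiguous"
  keep <- plausible[which.max(areas[plausible])]
  mask <- lab == keep

  # refine on a cropped window: closing to smooth the boundary, fill holes
  idx <- which(mask, arr.ind = TRUE)
  pad <- close_radius + 2
  r0 <- max(1, min(idx[, 1]) - pad); r1 <- min(nrow(mask), max(idx[, 1]) + pad)
  c0 <- max(1, min(idx[, 2]) - pad); c1 <- min(ncol(mask), max(idx[, 2]) + pad)
  crop <- mask[r0:r1, c0:c1]
  brush <- EBImage::makeBrush(2 * close_radius + 1, shape = "disc")
  crop <- EBImage::fillHull(EBImage::closing(crop, brush)) > 0
  lab2 <- EBImage::bwlabel(crop)
  a2 <- tabulate(lab2[lab2 > 0])
  crop <- lab2 == which.max(a2)
  mask[] <- FALSE
  mask[r0:r1, c0:c1] <- crop
  list(mask = mask, valid = TRUE, flags = flags)
}

#' Extract the ordered midline of a segmented body
#'
#' Skeletonizes the body mask (Zhang-Suen thinning), prunes side branches by
#' keeping the longest end-to-end path, smooths the path with smoothing
#' splines of row and column against cumulative arc length, and resamples it
#' to uniform arc spacing. Orientation (which end is the head) is decided
#' later by [orient_head_tail()].
#'
#' @param mask Logical matrix from [segment_body()].
#' @param n_points Number of resampled midline points (default 200).
#' @param min_elongation Minimum squared path-length to area ratio; blobs
#'   without an elongated axis are rejected.
#' @param min_path_cover Minimum fraction of skeleton pixels on the retained
#'   path; lower values indicate unresolvable branching (coiled or
#'   self-touching postures), which flags the frame invalid.
#' @return List with `midline` (n_points x 2 matrix of row, col), `s`
#'   (uniform arc coordinate in \[0,1\]), `length_px`, `valid`, `flags`.
#' @export
extract_midline <- function(mask, n_points = 200L, min_elongation = 2,
                            min_path_cover = 0.75) {
  if (is.null(mask) || sum(mask) < 30)
    return(list(midline = NULL, valid = FALSE, flags = "no_mask"))
  idx <- which(mask, arr.ind = TRUE)
  r0 <- max(1, min(idx[, 1]) - 2); r1 <- min(nrow(mask), max(idx[, 1]) + 2)
  c0 <- max(1, min(idx[, 2]) - 2); c1 <- min(ncol(mask), max(idx[, 2]) + 2)
  crop <- mask[r0:r1, c0:c1]
  skel <- cpp_thin(matrix(as.integer(crop), nrow(crop)))
  nskel <- sum(skel)
  if (nskel < 10)
    return(list(midline = NULL, valid = FALSE, flags = "degenerate_skeleton"))
  path <- cpp_longest_path(skel)
  if (nrow(path) < 10)
    return(list(midline = NULL, valid = FALSE, flags = "degenerate_skeleton"))
  if (nrow(path) / nskel < min_path_cover)
    return(list(midline = NULL, valid = FALSE, flags = "branched_skeleton"))
  pr <- path[, 1] + r0 - 1
  pc <- path[, 2] + c0 - 1
  seglen <- sqrt(diff(pr)^2 + diff(pc)^2)
  arc <- c(0, cumsum(seglen))
  if (arc[length(arc)]^2 < min_elongation * sum(mask))
    return(list(midline = NULL, valid = FALSE, flags = "not_elongated"))

  df <- min(25, max(8, round(nrow(path) / 12)))
  fr <- smooth.spline(arc, pr, df = df)
  fc <- smooth.spline(arc, pc, df = df)
  dense <- seq(0, arc[length(arc)], length.out = 4 * n_points)
  sr <- predict(fr, dense)$y
  sc <- predict(fc, dense)$y
  # the skeleton stops short of the tapered tips: extend both ends along
  # their local tangents while still inside the mask, so the arc coordinate
  # spans the full body and body length is not underestimated
  ext_end <- function(pt, tangent) {
    out <- NULL
    for (step in seq(0.75, 30, by = 0.75)) {
      q <- pt + step * tangent
      qr <- round(q[1]); qc <- round(q[2])
      if (qr < 1 || qc < 1 || qr > nrow(mask) || qc > ncol(mask) ||
          !mask[qr, qc]) break
      out <- rbind(out, q)
    }
    out
  }
  t0v <- c(sr[1] - sr[5], sc[1] - sc[5])
  t0v <- t0v / sqrt(sum(t0v^2))
  t1v <- c(sr[length(sr)] - sr[length(sr) - 4],
           sc[length(sc)] - sc[length(sc) - 4])
  t1v <- t1v / sqrt(sum(t1v^2))
  head_ext <- ext_end(c(sr[1], sc[1]), t0v)
  tail_ext <- ext_end(c(sr[length(sr)], sc[length(sc)]), t1v)
  if (!is.null(head_ext)) {
    sr <- c(rev(head_ext[, 1]), sr); sc <- c(rev(head_ext[, 2]), sc)
  }
  if (!is.null(tail_ext)) {
    sr <- c(sr, tail_ext[, 1]); sc <- c(sc, tail_ext[, 2])
  }
  darc <- c(0, cumsum(sqrt(diff(sr)^2 + diff(sc)^2)))
  total <- darc[length(darc)]
  uni <- seq(0, total, length.out = n_points)
  list(midline = cbind(r = approx(darc, sr, uni)$y, c = approx(darc, sc, uni)$y),
       s = seq(0, 1, length.out = n_points),
       length_px = total, valid = TRUE, flags = character())
}

#' Detect the pharynx marker blob in an acceptor-channel frame
#'
#' The pharynx carries a bright fluorescent tracking marker near the head.
#' It is detected as the largest connected component brighter than
#' `gain_threshold` times the median fluorescence over the (registered) body
#' region, and must later be excluded from FRET quantification.
#'
#' @param fluor_frame Acceptor-channel frame (its own camera coordinates).
#' @param body_median Median body fluorescence used as reference.
#' @param gain_threshold Detection threshold relative to `body_median`.
#' @param min_area Minimum blob area, px.
#' @return List with `found`, `centroid` (row, col, fluorescence coords) and
#'   `mask` (logical matrix), or `found = FALSE`.
#' @export
detect_pharynx <- function(fluor_frame, body_median, gain_threshold = 2,
                           min_area = 10) {
  bright <- fluor_frame > gain_threshold * body_median
  if (!any(bright)) return(list(found = FALSE))
  lab <- EBImage::bwlabel(bright)
  areas <- tabulate(lab[lab > 0])
  if (max(areas) < min_area) return(list(found = FALSE))
  keep <- which.max(areas)
  m <- lab == keep
  idx <- which(m, arr.ind = TRUE)
  list(found = TRUE, centroid = colMeans(idx), mask = m)
}

#' Orient the midline head to tail and assemble per-frame body geometry
#'
#' The head end is the midline end nearer the bright pharynx marker detected
#' in the acceptor channel (mapped into brightfield coordinates through the
#' channel registration). If no blob is detected, the orientation of the
#' nearest previous valid frame is inherited; with no previous frame either,
#' the frame is flagged `orientation_unknown`.
#'
#' @param midline Result of [extract_midline()].
#' @param mask Body mask from [segment_body()].
#' @param acceptor_frame Acceptor-channel frame (its own coordinates).
#' @param registration [register_channels()] result mapping acceptor
#'   coordinates into brightfield coordinates (`NULL` for identity).
#' @param previous Previous valid `body_geometry`, or `NULL`.
#' @param pixel_size µm per pixel.
#' @param frame_index Frame index recorded in the geometry.
#' @param head_margin Maximum head-to-blob distance, fraction of body length.
#' @param n_segments Number of body segments (default 100).
#' @return Object of class `body_geometry`: midline ordered head to tail with
#'   arc coordinate `s` (0 = head), segment edges, body length, pharynx
#'   record, validity flags.
#' @export
orient_head_tail <- function(midline, mask, acceptor_frame,
                             registration = NULL, previous = NULL,
                             pixel_size = 3.125, frame_index = NA_integer_,
                             head_margin = 0.15, n_segments = 100L) {
  ml <- midline$midline
  flags <- character()
  pharynx <- NULL
  # median body fluorescence: body-mask pixels mapped into acceptor coords
  bidx <- which(mask, arr.ind = TRUE)
  if (nrow(bidx) > 2000) bidx <- bidx[seq(1, nrow(bidx), length.out = 2000), ]
  fl_pts <- if (is.null(registration)) bidx
            else apply_registration(invert_registration(registration), bidx)
  fr <- pmin(pmax(round(fl_pts[, 1]), 1), nrow(acceptor_frame))
  fc <- pmin(pmax(round(fl_pts[, 2]), 1), ncol(acceptor_frame))
  body_med <- median(acceptor_frame[cbind(fr, fc)])
  det <- detect_pharynx(acceptor_frame, body_med)
  oriented <- FALSE
  if (det$found) {
    ctr_bf <- if (is.null(registration)) det$centroid
              else apply_registration(registration, rbind(det$centroid))[1, ]
    d_head <- sqrt(sum((ml[1, ] - ctr_bf)^2))
    d_tail <- sqrt(sum((ml[nrow(ml), ] - ctr_bf)^2))
    if (min(d_head, d_tail) <= head_margin * midline$length_px) {
      if (d_tail < d_head) ml <- ml[nrow(ml):1, ]
      pharynx <- list(centroid_bf = ctr_bf, mask_fluor = det$mask)
      oriented <- TRUE
    }
  }
  if (!oriented) {
    if (!is.null(previous)) {
      chord <- ml[nrow(ml), ] - ml[1, ]
      pchord <- previous$midline[nrow(previous$midline), ] - previous$midline[1, ]
      if (sum(chord * pchord) < 0) ml <- ml[nrow(ml):1, ]
      pharynx <- previous$pharynx
      flags <- c(flags, "orientation_inherited")
    } else {
      return(structure(list(frame_index = frame_index, valid = FALSE,
                            flags = "orientation_unknown"),
                       class = "body_geometry"))
    }
  }
  structure(list(
    frame_index = frame_index, mask = mask, midline = ml,
    s = midline$s, segment_edges = seq(0, 1, length.out = n_segments + 1),
    n_segments = as.integer(n_segments),
    length_px = midline$length_px,
    body_length_um = midline$length_px * pixel_size,
    pixel_size = pixel_size, pharynx = pharynx,
    valid = TRUE, flags = flags), class = "body_geometry")
}
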