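#' Analysis pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default, so
#' sensitivity analyses are scriptable and configurations round-trip
#' losslessly through YAML ([write_config()] / [read_config()]).
#'
#' @param pixel_size µm per pixel.
#' @param n_segments Body segments (default 100).
#' @param angle_threshold Side-tracking minimum angular separation, degrees.
#' @param low_emission_k Low-emission exclusion multiplier (robust background
#'   SDs).
#' @param prominence_factor Cycle-detection prominence threshold, robust SDs.
#' @param min_width_s Cycle-detection minimum extremum width, seconds.
#' @param fit_residual_bound Midline-fit residual RMS (px) above which the
#'   frame's curvature is flagged.
#' @param midline_band_px Midline removal band half-thickness, px.
#' @param half_window Local quartic fit half-window, body lengths.
#' @param close_radius Segmentation closing radius, px.
#' @param min_area Minimum credible worm area, px.
#' @param area_bound_factors Plausible area bounds relative to the recording
#'   median.
#' @param head_margin Maximum pharynx-to-end distance, body lengths.
#' @param registration_residual_bound Registration RMS warning bound, px.
#' @param seed Seed for any stochastic post-processing.
#' @return Object of class `pipeline_config` (a list).
#' @export
pipeline_config <- function(pixel_size = 3.125, n_segments = 100L,
                            angle_threshold = 10, low_emission_k = 3,
                            prominence_factor = 0.5, min_width_s = 0.15,
                            fit_residual_bound = 2, midline_band_px = 1,
                            half_window = 0.125, close_radius = 2,
                            min_area = 150, area_bound_factors = c(0.5, 2),
                            head_margin = 0.15,
                            registration_residual_bound = 1, seed = 1L) {
  structure(list(pixel_size = pixel_size, n_segments = as.integer(n_segments),
                 angle_threshold = angle_threshold,
                 low_emission_k = low_emission_k,
                 prominence_factor = prominence_factor,
                 min_width_s = min_width_s,
                 fit_residual_bound = fit_residual_bound,
                 midline_band_px = midline_band_px,
                 half_window = half_window, close_radius = close_radius,
                 min_area = min_area, area_bound_factors = area_bound_factors,
                 head_margin = head_margin,
                 registration_residual_bound = registration_residual_bound,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path File path for the YAML configuration.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  vals <- yaml::yaml.load_file(path)
  do.call(pipeline_config, vals)
}

#' Run the full posture-FRET analysis on one recording
#'
#' Orchestrates the per-frame pipeline: channel registration from the grid
#' control points, temporal matching of brightfield to fluorescence frames,
#' body segmentation, midline extraction and head orientation, side-mask
#' construction and persistent side tracking, per-segment fluorescence
#' sampling, local quartic curvature, and kymograph assembly.
#'
#' @param recording A `worm_recording` (from [generate_recording()] or
#'   [read_recording()]).
#' @param config A [pipeline_config()].
#' @param verbose Print a progress line every 200 frames.
#' @param keep_pixels Keep each frame's per-sample pixel index sets
#'   (`pixel_sets`), enabling pixel-matched audits on short recordings.
#' @return Object of class `worm_analysis`: `kymographs`
#'   ([build_kymographs()] result), `samples`, `curvatures`, `assignments`,
#'   `qc` (per-frame validity with reasons), `pairing`, `registrations`,
#'   `body_length_um`, `config`.
#' @export
analyze_recording <- function(recording, config = pipeline_config(),
                              verbose = FALSE, keep_pixels = FALSE) {
  stopifnot(inherits(recording, "worm_recording"))
  ch <- recording$channels
  reg <- lapply(recording$registration, function(df)
    register_channels(cbind(df$y_src, df$x_src), cbind(df$y_dst, df$x_dst),
                      config$registration_residual_bound))
  pairing <- match_frames(ch$brightfield$times, ch$donor$times)

  # plausible worm-area bounds from a subsample of the recording
  probe <- unique(pairing$bf_index[seq(1, nrow(pairing),
                                       by = max(1, nrow(pairing) %/% 15))])
  thrs <- vapply(probe, function(i) {
    f <- ch$brightfield$frames[, , i]
    mx <- max(f)
    if (mx <= 0 || sd(f) == 0) return(NA_real_)
    EBImage::otsu(f / mx, range = c(0, 1)) * mx
  }, numeric(1))
  if (all(is.na(thrs))) stop("no valid frames")
  threshold <- median(thrs, na.rm = TRUE)
  areas <- vapply(probe, function(i) {
    sb <- segment_body(ch$brightfield$frames[, , i], min_area = config$min_area,
                       close_radius = config$close_radius, threshold = threshold)
    if (sb$valid) sum(sb$mask) else NA_real_
  }, numeric(1))
  med_area <- median(areas, na.rm = TRUE)
  bounds <- if (is.finite(med_area)) med_area * config$area_bound_factors
            else NULL

  nfl <- nrow(pairing)
  pixel_sets <- vector("list", nfl)
  label1_pixels <- vector("list", nfl)
  samples <- vector("list", nfl)
  curv <- vector("list", nfl)
  qc <- vector("list", nfl)
  assign_rec <- vector("list", nfl)
  lengths_px <- rep(NA_real_, nfl)
  prev_geom <- NULL

  for (k in seq_len(nfl)) {
    if (verbose && k %% 200 == 0) message("frame ", k, "/", nfl)
    flags <- character(); stage <- "ok"
    repeat {  # single-pass stage machine; break with `stage` describing failure
      if (!pairing$paired[k]) { stage <- "unpaired"; break }
      bf <- ch$brightfield$frames[, , pairing$bf_index[k]]
      sb <- segment_body(bf, area_bounds = bounds, min_area = config$min_area,
                         close_radius = config$close_radius,
                         threshold = threshold)
      flags <- c(flags, sb$flags)
      if (!sb$valid) { stage <- "segmentation"; break }
      ml <- extract_midline(sb$mask)
      flags <- c(flags, ml$flags)
      if (!ml$valid) { stage <- "midline"; break }
      geom <- orient_head_tail(ml, sb$mask, ch$acceptor$frames[, , k],
                               registration = reg$acceptor,
                               previous = prev_geom,
                               pixel_size = config$pixel_size,
                               frame_index = k,
                               head_margin = config$head_margin,
                               n_segments = config$n_segments)
      flags <- c(flags, geom$flags)
      if (!geom$valid) { stage <- "orientation"; break }
      prev_geom <- geom
      lengths_px[k] <- geom$length_px
      fit <- fit_midline_polynomials(geom$midline,
                                     eval_at = (seq_len(config$n_segments) - 0.5) /
                                       config$n_segments,
                                     half_window = config$half_window)
      if (fit$residual_rms > config$fit_residual_bound)
        flags <- c(flags, "fit_residual")
      kp <- curvature_profile(fit, config$pixel_size)
      curv[[k]] <- data.frame(frame = k,
                              segment = 0:(config$n_segments - 1),
                              k_signed = kp$k_signed)
      sm <- build_side_masks(geom, band_px = config$midline_band_px)
      flags <- c(flags, sm$flags)
      if (!sm$valid) { stage <- "side_split"; break }
      asg <- track_sides(sm, geom, angle_threshold = config$angle_threshold)
      if (!asg$valid) {
        flags <- c(flags, asg$reason); stage <- "side_tracking"
        assign_rec[[k]] <- data.frame(frame = k, label_A = NA_integer_,
                                      valid = FALSE, reason = asg$reason,
                                      ctrA_r = NA, ctrA_c = NA,
                                      ctrB_r = NA, ctrB_c = NA)
        break
      }
      assign_rec[[k]] <- data.frame(frame = k, label_A = asg$label_A,
                                    valid = TRUE, reason = NA_character_,
                                    ctrA_r = asg$centroid_A[1],
                                    ctrA_c = asg$centroid_A[2],
                                    ctrB_r = asg$centroid_B[1],
                                    ctrB_c = asg$centroid_B[2])
      m1 <- if (asg$label_A == 1L) sm$A else sm$B
      i1 <- which(m1)
      if (length(i1) > 80) i1 <- i1[round(seq(1, length(i1), length.out = 80))]
      label1_pixels[[k]] <- cbind((i1 - 1) %% nrow(m1) + 1,
                                  (i1 - 1) %/% nrow(m1) + 1)
      samples[[k]] <- sample_fluorescence(geom, sm, asg,
                                          ch$donor$frames[, , k],
                                          ch$acceptor$frames[, , k],
                                          reg_donor = reg$donor,
                                          reg_acceptor = reg$acceptor,
                                          low_emission_k = config$low_emission_k,
                                          return_pixels = keep_pixels)
      if (keep_pixels) {
        pixel_sets[[k]] <- attr(samples[[k]], "pixels")
        attr(samples[[k]], "pixels") <- NULL
      }
      break
    }
    qc[[k]] <- data.frame(frame = k, stage = stage,
                          valid = stage == "ok",
                          flags = paste(unique(flags), collapse = ";"))
  }

  qc <- do.call(rbind, qc)
  n_invalid <- sum(!qc$valid)
  if (n_invalid > nfl / 2)
    warning(sprintf("more than half of all frames invalid (%d / %d)",
                    n_invalid, nfl))
  samples <- do.call(rbind, samples)
  curv <- do.call(rbind, curv)
  if (is.null(samples) || nrow(samples) == 0) stop("no valid frames")
  body_length_um <- median(lengths_px, na.rm = TRUE) * config$pixel_size
  times <- setNames(ch$donor$times, seq_along(ch$donor$times))
  kymo <- build_kymographs(samples, curv, body_length_um, times = times,
                           n_segments = config$n_segments,
                           frames = seq_len(nfl))
  structure(list(kymographs = kymo, samples = samples, curvatures = curv,
                 assignments = do.call(rbind, assign_rec),
                 label1_pixels = label1_pixels,
                 pixel_sets = if (keep_pixels) pixel_sets, qc = qc,
                 pairing = pairing, registrations = reg,
                 body_length_um = body_length_um, config = config),
            class = "worm_analysis")
}

#' @export
print.worm_analysis <- function(x, ...) {
  cat(sprintf("<worm_analysis> %d/%d valid frames, body length %.0f um\n",
              sum(x$qc$valid), nrow(x$qc), x$body_length_um))
  invisible(x)
}

#' Side-tracking accuracy against ground truth
#'
#' Compares the persistent side labels of an analysis with the generator's
#' ground-truth side identity. The label-to-truth correspondence is fixed on
#' the first valid frame; a later valid frame counts as correct when its
#' labels still match that correspondence (i.e. persistence was maintained).
#'
#' @param analysis A `worm_analysis`.
#' @param truth The matching `worm_truth`.
#' @return List with `accuracy_pct` (over valid frames), `n_valid`,
#'   `n_frames`.
#' @export
evaluate_side_tracking <- function(analysis, truth) {
  asg <- analysis$assignments
  asg <- asg[!is.na(asg$label_A) & asg$valid, ]
  if (nrow(asg) == 0) return(list(accuracy_pct = NA_real_, n_valid = 0L,
                                  n_frames = nrow(analysis$qc)))
  # ground-truth side of the mask that received label 1, by majority vote
  # over its pixels (on-body pixels have a well-defined perpendicular foot
  # on the midline, unlike the bulge-displaced whole-mask centroid)
  d1 <- vapply(seq_len(nrow(asg)), function(j) {
    pts <- analysis$label1_pixels[[asg$frame[j]]]
    if (is.null(pts))
      pts <- rbind(if (asg$label_A[j] == 1L) c(asg$ctrA_r[j], asg$ctrA_c[j])
                   else c(asg$ctrB_r[j], asg$ctrB_c[j]))
    sides <- true_side_of_points(truth, asg$frame[j], pts)
    if (mean(sides) >= 0) 1L else -1L
  }, integer(1))
  list(accuracy_pct = 100 * mean(d1 == d1[1]), n_valid = nrow(asg),
       n_frames = nrow(analysis$qc))
}

#' Quarter-cycle statistics for every segment-side trace of an analysis
#'
#' Detects contraction cycles in each segment-side normalized-curvature
#' trace and extracts quarter-cycle FRET and curvature changes, pooled into
#' one long table suitable for [compare_strains()].
#'
#' @param analysis A `worm_analysis` (or a list with `C`, `FRET` matrices and
#'   `times`, e.g. from [simulate_segment_traces()]).
#' @param animal Identifier recorded in the `animal` column.
#' @param min_valid Minimum finite samples for a trace to be used.
#' @return Data frame `animal`, `trace`, `quarter`, `d_fret`, `d_curv`.
#' @export
analysis_quarter_stats <- function(analysis, animal = 1L, min_valid = 50) {
  tr <- extract_traces(analysis)
  cfg <- if (inherits(analysis, "worm_analysis")) analysis$config
         else pipeline_config()
  out <- vector("list", length(tr$traces))
  for (j in seq_along(tr$traces)) {
    C <- tr$traces[[j]]$C; FRET <- tr$traces[[j]]$fret
    if (sum(is.finite(C) & is.finite(FRET)) < min_valid) next
    cyc <- detect_cycles(C, tr$times,
                         prominence_factor = cfg$prominence_factor,
                         min_width_s = cfg$min_width_s)
    if (cyc$n == 0) next
    q <- quarter_cycle_stats(cyc, FRET, C, tr$times)
    if (nrow(q) == 0) next
    q$animal <- animal
    q$trace <- tr$ids[j]
    out[[j]] <- q
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cycle = integer(), quarter = character(),
                      d_fret = numeric(), d_curv = numeric(),
                      animal = integer(), trace = character())
  res
}

# unify trace access for worm_analysis and simulate_segment_traces output
extract_traces <- function(x) {
  if (inherits(x, "worm_analysis")) {
    k <- x$kymographs
    ids <- c(); traces <- list()
    for (side in 1:2) for (sg in seq_len(dim(k$C)[1])) {
      ids <- c(ids, sprintf("seg%03d_side%d", sg, side))
      traces[[length(traces) + 1]] <- list(C = k$C[sg, , side],
                                           fret = k$FRET[sg, , side])
    }
    list(times = k$times, traces = traces, ids = ids)
  } else {
    ids <- sprintf("seg%03d", seq_len(nrow(x$C)))
    traces <- lapply(seq_len(nrow(x$C)), function(i)
      list(C = x$C[i, ], fret = x$fret[i, ]))
    list(times = x$times, traces = traces, ids = ids)
  }
}

#' Cross-correlation of FRET against curvature for every trace
#'
#' Computes the normalized cross-correlation of each segment-side FRET trace
#' against its curvature trace and reports the per-trace peak lag, the modal
#' peak lag across traces (each segment treated as an independent sample),
#' and the pooled mean correlation function.
#'
#' @param analysis A `worm_analysis` or [simulate_segment_traces()] result.
#' @param max_lag_s Maximum lag, seconds.
#' @param min_valid Minimum finite samples per trace.
#' @return List with `peak_lags` (samples), `peak_lags_s`, `modal_lag_s`,
#'   `lag_s`, `mean_r`, `dt`.
#' @export
analysis_cross_correlation <- function(analysis, max_lag_s = 1.5,
                                       min_valid = 50) {
  tr <- extract_traces(analysis)
  dt <- median(diff(tr$times))
  max_lag <- round(max_lag_s / dt)
  peaks <- c(); rsum <- NULL; nr <- 0
  for (j in seq_along(tr$traces)) {
    C <- tr$traces[[j]]$C; FRET <- tr$traces[[j]]$fret
    if (sum(is.finite(C) & is.finite(FRET)) < min_valid) next
    cc <- cross_correlate(FRET, C, max_lag)
    if (is.null(cc)) next
    peaks <- c(peaks, cc$peak_lag)
    r <- cc$r; r[!is.finite(r)] <- 0
    rsum <- if (is.null(rsum)) r else rsum + r
    nr <- nr + 1
  }
  if (nr == 0) stop("no usable traces for cross-correlation")
  tab <- table(peaks)
  modal <- as.integer(names(tab)[which.max(tab)])
  list(peak_lags = peaks, peak_lags_s = peaks * dt, modal_lag = modal,
       modal_lag_s = modal * dt, lag_s = (-max_lag:max_lag) * dt,
       mean_r = rsum / nr, dt = dt)
}

#' Pooled phase-aligned profile over all traces of an analysis
#'
#' @param analysis A `worm_analysis` or [simulate_segment_traces()] result.
#' @param signal `"C"` (normalized curvature, raw) or `"FRET"` (change from
#'   cycle start).
#' @param n_bins Phase bins.
#' @param min_valid Minimum finite samples per trace.
#' @return List with the pooled profile data frame (`phase`, `mean`, `n`)
#'   and `n_cycles`.
#' @export
phase_profile <- function(analysis, signal = c("C", "FRET"), n_bins = 36,
                          min_valid = 50) {
  signal <- match.arg(signal)
  tr <- extract_traces(analysis)
  cfg <- if (inherits(analysis, "worm_analysis")) analysis$config
         else pipeline_config()
  acc <- numeric(n_bins); cnt <- 0 * acc; ncyc <- 0
  for (j in seq_along(tr$traces)) {
    C <- tr$traces[[j]]$C
    y <- if (signal == "C") C else tr$traces[[j]]$fret
    if (sum(is.finite(C) & is.finite(y)) < min_valid) next
    cyc <- detect_cycles(C, tr$times,
                         prominence_factor = cfg$prominence_factor,
                         min_width_s = cfg$min_width_s)
    if (cyc$n == 0) next
    pa <- phase_align(cyc, y, tr$times, n_bins = n_bins,
                      reference = if (signal == "C") "raw" else "delta")
    w <- pa$n
    acc <- acc + ifelse(w > 0, pa$mean * w, 0)
    cnt <- cnt + w
    ncyc <- ncyc + cyc$n
  }
  prof <- data.frame(phase = (seq_len(n_bins) - 1) * (360 / n_bins),
                     mean = ifelse(cnt > 0, acc / cnt, NA_real_),
                     n = as.integer(cnt))
  list(profile = prof, n_cycles = ncyc)
}

#' Pixel-matched FRET recovery audit against ground truth
#'
#' For every included sample of an analysis run with `keep_pixels = TRUE`,
#' compares the recovered ratiometric FRET value with the mean injected
#' ratio over the very pixels the sample averaged. This isolates the
#' ratiometric arithmetic, background handling and channel registration from
#' midline-registration tolerances (which are audited separately).
#'
#' @param analysis A `worm_analysis` produced with `keep_pixels = TRUE`.
#' @param truth The matching `worm_truth`.
#' @return Data frame with `frame`, `segment`, `side`, `fret`, `fret_true`,
#'   `n_pixels`, `abs_error`.
#' @export
evaluate_fret_recovery <- function(analysis, truth) {
  if (is.null(analysis$pixel_sets))
    stop("run analyze_recording with keep_pixels = TRUE")
  nseg <- analysis$config$n_segments
  out <- vector("list", length(analysis$pixel_sets))
  for (k in seq_along(analysis$pixel_sets)) {
    ps <- analysis$pixel_sets[[k]]
    if (is.null(ps)) next
    tm <- truth_maps(truth, k, "brightfield")
    rtr <- tm$r[ps$idx]
    keep <- !is.na(rtr)
    if (!any(keep)) next
    tr_mean <- rowsum(rtr[keep], ps$key[keep])
    tr_n <- tabulate(ps$key[keep], nbins = 2L * nseg)
    grp <- as.integer(rownames(tr_mean))
    sa <- analysis$samples[analysis$samples$frame == k, ]
    sa <- sa[!sa$excluded & !is.na(sa$E480), ]
    skey <- (sa$side - 1L) * nseg + sa$segment + 1L
    m <- match(skey, grp)
    ok <- !is.na(m)
    if (!any(ok)) next
    fr <- fret_value(sa$E535[ok], sa$E480[ok])
    ft <- tr_mean[m[ok], 1] / tr_n[grp[m[ok]]]
    out[[k]] <- data.frame(frame = k, segment = sa$segment[ok],
                           side = sa$side[ok], fret = fr, fret_true = ft,
                           n_pixels = sa$n_pixels[ok],
                           abs_error = abs(fr - ft))
  }
  do.call(rbind, out)
}
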