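#' Normalized cross-correlation between two traces
#'
#' Mean-subtracted, SD-normalized cross-correlation over lags
#' `-max_lag..max_lag` (in samples), with missing values removed pairwise per
#' lag, so values lie in \[-1, 1\] and are comparable across strains and
#' recordings. Positive peak lag means the first trace lags the second.
#'
#' @param x,y Numeric traces on the same time base (e.g. FRET and normalized
#'   curvature of one segment).
#' @param max_lag Maximum lag in samples.
#' @param min_overlap Minimum number of valid pairs required at every lag;
#'   traces with less usable overlap are skipped (returns `NULL`).
#' @return List with `lag`, `r` (per-lag correlation) and `peak_lag`
#'   (lag of maximum correlation, samples), or `NULL` if skipped.
#' @export
cross_correlate <- function(x, y, max_lag, min_overlap = 30) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < min_overlap) return(NULL)
  mx <- mean(x[ok]); my <- mean(y[ok])
  sx <- sqrt(mean((x[ok] - mx)^2)); sy <- sqrt(mean((y[ok] - my)^2))
  if (sx == 0 || sy == 0) return(NULL)
  xc <- x - mx; yc <- y - my
  lags <- -max_lag:max_lag
  r <- vapply(lags, function(k) {
    if (k >= 0) { xi <- (1 + k):n; yi <- 1:(n - k) }
    else { xi <- 1:(n + k); yi <- (1 - k):n }
    v <- is.finite(xc[xi]) & is.finite(yc[yi])
    if (sum(v) < min_overlap) return(NA_real_)
    mean(xc[xi][v] * yc[yi][v]) / (sx * sy)
  }, numeric(1))
  if (all(is.na(r))) return(NULL)
  list(lag = lags, r = r, peak_lag = lags[which.max(r)])
}

#' Pearson correlation between two traces
#'
#' Product-moment correlation over pairwise-complete points; `NA` when either
#' trace has zero variance, error when fewer than `min_n` pairs remain.
#'
#' @param x,y Numeric traces.
#' @param min_n Minimum number of paired points (default 30).
#' @return Correlation coefficient or `NA`.
#' @export
pearson_correlation <- function(x, y, min_n = 30) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < min_n) stop("fewer than min_n paired points")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])
}

local_extrema <- function(x) {
  n <- length(x)
  d <- diff(x)
  sgn <- sign(d)
  # collapse plateaus: carry the previous non-zero slope
  for (i in seq_along(sgn)) if (sgn[i] == 0 && i > 1) sgn[i] <- sgn[i - 1]
  turn <- diff(sgn)
  peaks <- which(turn < 0) + 1L
  valleys <- which(turn > 0) + 1L
  list(peaks = peaks, valleys = valleys)
}

peak_prominence <- function(x, peaks) {
  # standard definition: height above the higher of the two key saddles
  vapply(peaks, function(p) {
    lmin <- if (p > 1) {
      left <- x[1:(p - 1)]
      higher <- which(left >= x[p])
      lo <- if (length(higher)) max(higher) + 1L else 1L
      min(x[lo:(p - 1)])
    } else x[p]
    rmin <- if (p < length(x)) {
      right <- x[(p + 1):length(x)]
      higher <- which(right >= x[p])
      hi <- if (length(higher)) p + min(higher) - 1L else length(x)
      min(x[(p + 1):hi])
    } else x[p]
    x[p] - max(lmin, rmin)
  }, numeric(1))
}

peak_width_s <- function(x, peaks, prom, dt) {
  # width (seconds) at half prominence
  vapply(seq_along(peaks), function(i) {
    p <- peaks[i]; h <- x[p] - prom[i] / 2
    l <- p; while (l > 1 && x[l] > h) l <- l - 1
    r <- p; while (r < length(x) && x[r] > h) r <- r + 1
    (r - l) * dt
  }, numeric(1))
}

#' Detect contraction-relaxation cycles in a curvature trace
#'
#' Finds local maxima and minima of the normalized-curvature trace, rejects
#' spurious extrema whose prominence falls below `prominence_factor` times
#' the trace's robust SD or whose width at half prominence is below
#' `min_width_s`, enforces peak/valley alternation, and assembles cycles as
#' valley-to-valley spans through one peak.
#'
#' @param trace Normalized curvature trace of one segment-side (NAs are
#'   linearly interpolated internally for detection).
#' @param times Time stamps, seconds (same length as `trace`).
#' @param prominence_factor Prominence threshold as a multiple of the robust
#'   SD (1.4826 * MAD) of the trace.
#' @param min_width_s Minimum peak/valley width at half prominence, seconds.
#' @return Object of class `cycle_set`: data frame `cycles` with columns
#'   `start_idx`, `peak_idx`, `end_idx` and the corresponding times, plus
#'   `n`. Zero qualifying extrema give an empty set, not an error.
#' @export
detect_cycles <- function(trace, times, prominence_factor = 0.5,
                          min_width_s = 0.15) {
  stopifnot(length(trace) == length(times))
  empty <- structure(list(cycles = data.frame(start_idx = integer(),
                                              peak_idx = integer(),
                                              end_idx = integer(),
                                              start_t = numeric(),
                                              peak_t = numeric(),
                                              end_t = numeric()), n = 0L),
                     class = "cycle_set")
  ok <- is.finite(trace)
  if (sum(ok) < 8) return(empty)
  x <- trace
  if (any(!ok))
    x <- approx(times[ok], trace[ok], times, rule = 2)$y
  rsd <- mad(x) * 1  # mad() already scales by 1.4826
  if (rsd == 0) return(empty)
  dt <- median(diff(times))
  thr <- prominence_factor * rsd

  qual <- function(sig) {
    ex <- local_extrema(sig)$peaks
    if (!length(ex)) return(integer())
    prom <- peak_prominence(sig, ex)
    w <- peak_width_s(sig, ex, prom, dt)
    ex[prom >= thr & w >= min_width_s]
  }
  peaks <- qual(x)
  valleys <- qual(-x)
  if (!length(peaks) || length(valleys) < 2) return(empty)

  # enforce alternation: in runs of same-type extrema keep the most extreme
  ev <- rbind(data.frame(i = peaks, type = 1), data.frame(i = valleys, type = -1))
  ev <- ev[order(ev$i), ]
  kept_i <- integer(); kept_t <- integer()
  for (m in seq_len(nrow(ev))) {
    if (length(kept_t) && kept_t[length(kept_t)] == ev$type[m]) {
      last <- length(kept_i)
      if (ev$type[m] * x[ev$i[m]] > ev$type[m] * x[kept_i[last]])
        kept_i[last] <- ev$i[m]
    } else {
      kept_i <- c(kept_i, ev$i[m]); kept_t <- c(kept_t, ev$type[m])
    }
  }
  ev <- data.frame(i = kept_i, type = kept_t)
  cyc <- list()
  for (m in seq_len(nrow(ev) - 2)) {
    if (ev$type[m] == -1 && ev$type[m + 1] == 1 && ev$type[m + 2] == -1)
      cyc[[length(cyc) + 1]] <- c(ev$i[m], ev$i[m + 1], ev$i[m + 2])
  }
  if (!length(cyc)) return(empty)
  cm <- do.call(rbind, cyc)
  structure(list(cycles = data.frame(start_idx = cm[, 1], peak_idx = cm[, 2],
                                     end_idx = cm[, 3],
                                     start_t = times[cm[, 1]],
                                     peak_t = times[cm[, 2]],
                                     end_t = times[cm[, 3]]),
                 n = nrow(cm)), class = "cycle_set")
}

#' Phase of every sample within a cycle
#'
#' Piecewise-linear phase in degrees: the starting valley maps to -90
#' (i.e. 270 of the previous cycle), the peak to 90 (maximum contraction),
#' and the ending valley to 270 (maximum relaxation); 0/360 are the straight
#' postures crossed halfway. Returned in \[0, 360).
#'
#' @param start_idx,peak_idx,end_idx Cycle indices into `times`.
#' @param times Time stamps.
#' @return Numeric vector of phases for indices `start_idx:end_idx`.
#' @export
cycle_phase <- function(start_idx, peak_idx, end_idx, times) {
  cycle_phase_unwrapped(start_idx, peak_idx, end_idx, times) %% 360
}

# unwrapped phase: -90 at the starting valley, 90 at the peak, 270 at the
# ending valley (the modular phase maps both valleys to 270)
cycle_phase_unwrapped <- function(start_idx, peak_idx, end_idx, times) {
  i <- start_idx:end_idx
  t <- times[i]
  tp <- times[peak_idx]
  ifelse(i <= peak_idx,
         -90 + 180 * (t - times[start_idx]) / (tp - times[start_idx]),
         90 + 180 * (t - tp) / (times[end_idx] - tp))
}

#' Phase-aligned average of a signal over detected cycles
#'
#' Maps every sample of every cycle to its 0-360 degree phase, optionally
#' references the signal to its value at the cycle start (`reference =
#' "delta"`), and averages per phase bin.
#'
#' @param cycle_set A [detect_cycles()] result.
#' @param trace Signal on the same time base.
#' @param times Time stamps.
#' @param n_bins Number of phase bins (default 36, i.e. 10 degrees).
#' @param reference `"delta"` (change from cycle start) or `"raw"`.
#' @param min_frames Cycles spanning fewer paired frames are discarded.
#' @return Data frame `phase` (bin centre), `mean`, `n` (samples per bin).
#' @export
phase_align <- function(cycle_set, trace, times, n_bins = 36,
                        reference = c("delta", "raw"), min_frames = 4) {
  reference <- match.arg(reference)
  w <- 360 / n_bins   # bins centred on 0, w, 2w, ... (90 is a bin centre)
  acc <- numeric(n_bins); cnt <- integer(n_bins)
  cy <- cycle_set$cycles
  for (m in seq_len(nrow(cy))) {
    i <- cy$start_idx[m]:cy$end_idx[m]
    if (length(i) < min_frames) next
    th <- cycle_phase(cy$start_idx[m], cy$peak_idx[m], cy$end_idx[m], times)
    v <- trace[i]
    if (reference == "delta") {
      if (!is.finite(trace[cy$start_idx[m]])) next
      v <- v - trace[cy$start_idx[m]]
    }
    ok <- is.finite(v)
    b <- (floor((th[ok] + w / 2) / w) %% n_bins) + 1
    acc <- acc + unname(tapply(v[ok], factor(b, levels = seq_len(n_bins)),
                               sum, default = 0))
    cnt <- cnt + unname(table(factor(b, levels = seq_len(n_bins))))
  }
  data.frame(phase = (seq_len(n_bins) - 1) * w,
             mean = ifelse(cnt > 0, acc / cnt, NA_real_), n = as.integer(cnt))
}

quarter_labels <- c("0-90", "90-180", "180-270", "270-360")

#' Quarter-cycle changes in FRET and curvature
#'
#' Splits each detected cycle at the phase boundaries 0, 90, 180 and 270
#' degrees (nearest sample index; 90 is exactly the peak, the cycle
#' boundaries are the valleys at 270). For each quarter the change is the
#' signal at the quarter's last index minus the signal at its first index.
#' Quarters share boundary indices, so the four changes of a complete cycle
#' telescope exactly to the cycle's end-minus-start value. Quarters spanning
#' missing data are skipped.
#'
#' @param cycle_set A [detect_cycles()] result.
#' @param fret_trace,curv_trace Traces on the same time base.
#' @param times Time stamps.
#' @param min_frames Minimum paired frames per cycle.
#' @return Data frame with `cycle`, `quarter` (factor "0-90", "90-180",
#'   "180-270", "270-360"), `d_fret`, `d_curv`.
#' @export
quarter_cycle_stats <- function(cycle_set, fret_trace, curv_trace, times,
                                min_frames = 4) {
  cy <- cycle_set$cycles
  # quarters in phase order starting at the cycle's first sample (-90):
  # [-90,0) = "270-360", [0,90) = "0-90", [90,180) = "90-180",
  # [180,270) = "180-270"
  qlab <- quarter_labels[c(4, 1, 2, 3)]
  o_cycle <- integer(); o_q <- integer()
  o_df <- numeric(); o_dc <- numeric()
  for (m in seq_len(nrow(cy))) {
    i <- cy$start_idx[m]:cy$end_idx[m]
    if (length(i) < min_frames) next
    thu <- cycle_phase_unwrapped(cy$start_idx[m], cy$peak_idx[m],
                                 cy$end_idx[m], times)
    bnd <- vapply(c(-90, 0, 90, 180, 270), function(b)
      which.min(abs(thu - b)), integer(1))
    gi <- cy$start_idx[m] - 1L + bnd      # boundary sample indices
    fb <- fret_trace[gi]; cb <- curv_trace[gi]
    for (q in 1:4) {
      if (bnd[q + 1] <= bnd[q]) next
      if (!is.finite(fb[q]) || !is.finite(fb[q + 1]) ||
          !is.finite(cb[q]) || !is.finite(cb[q + 1])) next
      o_cycle <- c(o_cycle, m); o_q <- c(o_q, q)
      o_df <- c(o_df, fb[q + 1] - fb[q])
      o_dc <- c(o_dc, cb[q + 1] - cb[q])
    }
  }
  data.frame(cycle = o_cycle,
             quarter = factor(qlab[o_q], levels = quarter_labels),
             d_fret = o_df, d_curv = o_dc)
}

#' Compare quarter-cycle FRET statistics between two strains
#'
#' Pools quarter-cycle changes across cycles, segments and animals of each
#' cohort (each segment treated as an independent sample, as in the source
#' analysis pooling) and, per quarter, runs Welch two-sample t-tests on the
#' magnitude of the FRET change and on the per-trace correlation between
#' FRET change and curvature change. A per-animal summary (mean |dFRET| per
#' animal, t-test on animal means) is reported alongside, since pooled
#' segments are not truly independent.
#'
#' @param test_q,ctrl_q Data frames of pooled quarter stats with columns
#'   `animal`, `trace` (an identifier of the segment-side trace), `quarter`,
#'   `d_fret`, `d_curv`.
#' @param min_cycles_corr Minimum cycles per trace for a correlation
#'   coefficient.
#' @return List with `quarters` (per-quarter comparison table) and
#'   `per_animal` (animal-level summary table).
#' @export
compare_strains <- function(test_q, ctrl_q, min_cycles_corr = 5) {
  for (d in list(test_q, ctrl_q))
    if (length(unique(d$animal)) < 2)
      stop("each cohort needs at least 2 animals")
  trace_cors <- function(d) {
    out <- lapply(split(d, list(d$quarter, d$animal, d$trace), drop = TRUE),
                  function(g) {
      if (nrow(g) < min_cycles_corr) return(NULL)
      if (sd(g$d_fret) == 0 || sd(g$d_curv) == 0) return(NULL)
      data.frame(quarter = g$quarter[1], animal = g$animal[1],
                 r = cor(g$d_fret, g$d_curv))
    })
    do.call(rbind, out)
  }
  ct <- trace_cors(test_q); cc <- trace_cors(ctrl_q)
  rows <- lapply(quarter_labels, function(q) {
    a <- test_q[test_q$quarter == q, ]
    b <- ctrl_q[ctrl_q$quarter == q, ]
    tt <- t.test(abs(a$d_fret), abs(b$d_fret))   # Welch
    ra <- ct$r[ct$quarter == q]; rb <- cc$r[cc$quarter == q]
    pt <- if (length(ra) >= 2 && length(rb) >= 2)
      t.test(ra, rb)$p.value else NA_real_
    data.frame(quarter = q,
               mean_dfret_test = mean(a$d_fret),
               mean_dfret_ctrl = mean(b$d_fret),
               mean_abs_dfret_test = mean(abs(a$d_fret)),
               mean_abs_dfret_ctrl = mean(abs(b$d_fret)),
               n_test = nrow(a), n_ctrl = nrow(b),
               p_dfret = tt$p.value,
               mean_corr_test = if (length(ra)) mean(ra) else NA_real_,
               mean_corr_ctrl = if (length(rb)) mean(rb) else NA_real_,
               p_corr = pt)
  })
  per_animal <- function(d, strain) {
    ag <- aggregate(abs(d$d_fret), by = list(animal = d$animal,
                                             quarter = d$quarter), FUN = mean)
    names(ag)[3] <- "mean_abs_dfret"
    ag$strain <- strain
    ag
  }
  pa <- rbind(per_animal(test_q, "test"), per_animal(ctrl_q, "ctrl"))
  pa_tests <- lapply(quarter_labels, function(q) {
    a <- pa$mean_abs_dfret[pa$quarter == q & pa$strain == "test"]
    b <- pa$mean_abs_dfret[pa$quarter == q & pa$strain == "ctrl"]
    data.frame(quarter = q, p_animal = t.test(a, b)$p.value,
               n_animals_test = length(a), n_animals_ctrl = length(b))
  })
  list(quarters = do.call(rbind, rows),
       per_animal = list(summary = pa, tests = do.call(rbind, pa_tests)))
}
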