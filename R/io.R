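#' Write a recording bundle to disk
#'
#' Writes the three channels as multi-page 16-bit TIFF stacks
#' (`brightfield.tif`, `donor.tif`, `acceptor.tif`), a timestamp table
#' `timestamps.csv` (frame_index, channel, time_s), registration control
#' points `registration_<channel>.csv`, a JSON parameter sidecar, and — when
#' ground truth is supplied — CSVs of the true midlines, per-segment
#' normalized curvature and per-segment true FRET ratio.
#'
#' @param recording A `worm_recording`.
#' @param dir Output directory (created if missing).
#' @param truth Optional `worm_truth`.
#' @param params Optional `worm_model_params` stored as JSON.
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir, truth = NULL, params = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maxval <- 65535
  for (chn in names(recording$channels)) {
    ch <- recording$channels[[chn]]
    pages <- lapply(seq_len(dim(ch$frames)[3]), function(i)
      pmin(ch$frames[, , i], maxval) / maxval)
    tiff::writeTIFF(pages, file.path(dir, paste0(chn, ".tif")),
                    bits.per.sample = 16, compression = "none")
  }
  ts <- do.call(rbind, lapply(names(recording$channels), function(chn)
    data.frame(frame_index = seq_along(recording$channels[[chn]]$times),
               channel = chn, time_s = recording$channels[[chn]]$times)))
  write.csv(ts, file.path(dir, "timestamps.csv"), row.names = FALSE)
  for (chn in names(recording$registration))
    write.csv(recording$registration[[chn]],
              file.path(dir, paste0("registration_", chn, ".csv")),
              row.names = FALSE)
  if (!is.null(params)) {
    pl <- unclass(params)
    pl$half_width_profile <- NULL  # function; profile recorded numerically
    pl$half_width_table <- data.frame(
      s = seq(0, 1, by = 0.01),
      half_width_um = params$half_width_profile(seq(0, 1, by = 0.01)))
    jsonlite::write_json(pl, file.path(dir, "params.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(truth)) {
    ml <- do.call(rbind, lapply(seq_along(truth$midlines), function(k)
      data.frame(frame = k, s = truth$midline_s,
                 row = truth$midlines[[k]][, 1],
                 col = truth$midlines[[k]][, 2])))
    write.csv(ml, file.path(dir, "truth_midlines.csv"), row.names = FALSE)
    cv <- data.frame(frame = rep(seq_len(ncol(truth$curvature)),
                                 each = nrow(truth$curvature)),
                     segment = rep(seq_len(nrow(truth$curvature)) - 1L,
                                   ncol(truth$curvature)),
                     normalized_curvature = as.vector(truth$curvature),
                     ratio_side1 = as.vector(truth$ratio[, , 1]),
                     ratio_side2 = as.vector(truth$ratio[, , 2]))
    write.csv(cv, file.path(dir, "truth_signals.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a recording bundle written by [write_recording()]
#'
#' @param dir Bundle directory.
#' @return A `worm_recording`.
#' @export
read_recording <- function(dir) {
  need <- file.path(dir, c("brightfield.tif", "donor.tif", "acceptor.tif",
                           "timestamps.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing recording inputs: ", paste(basename(missing),
                                             collapse = ", "))
  ts <- read.csv(file.path(dir, "timestamps.csv"))
  channels <- list()
  for (chn in c("brightfield", "donor", "acceptor")) {
    pages <- tiff::readTIFF(file.path(dir, paste0(chn, ".tif")), all = TRUE)
    frames <- array(0L, c(dim(pages[[1]]), length(pages)))
    for (i in seq_along(pages))
      frames[, , i] <- as.integer(round(pages[[i]] * 65535))
    channels[[chn]] <- list(times = ts$time_s[ts$channel == chn],
                            frames = frames)
  }
  registration <- list()
  for (chn in c("donor", "acceptor")) {
    f <- file.path(dir, paste0("registration_", chn, ".csv"))
    if (file.exists(f)) registration[[chn]] <- read.csv(f)
  }
  px <- 3.125
  pf <- file.path(dir, "params.json")
  seed <- NA_integer_
  if (file.exists(pf)) {
    pj <- jsonlite::read_json(pf, simplifyVector = TRUE)
    px <- pj$pixel_size
    seed <- as.integer(pj$seed)
  }
  structure(list(channels = channels, registration = registration,
                 pixel_size = px, image_size = dim(channels$brightfield$frames)[1:2],
                 seed = seed), class = "worm_recording")
}

#' Simulate a recording bundle to disk
#'
#' Generates a synthetic recording from the given model parameters and
#' writes the full bundle (stacks, timestamps, registration points, ground
#' truth, parameter manifest).
#'
#' @param params A [worm_model_params()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(params, out_dir) {
  g <- generate_recording(params)
  write_recording(g$recording, out_dir, truth = g$truth, params = params)
  invisible(out_dir)
}

#' Analyze a recording bundle from disk
#'
#' Reads a bundle, runs [analyze_recording()], and writes kymographs (one
#' CSV matrix per quantity per side), the tidy per-segment sample table, the
#' per-frame QC table, the frame pairing, and per-quarter cycle statistics.
#'
#' @param in_dir Bundle directory.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return The `worm_analysis`, invisibly.
#' @export
run_analyze <- function(in_dir, out_dir, config = pipeline_config()) {
  rec <- read_recording(in_dir)
  if (!is.na(rec$pixel_size) && rec$pixel_size != config$pixel_size)
    config$pixel_size <- rec$pixel_size
  an <- analyze_recording(rec, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  k <- an$kymographs
  for (q in c("C", "E480", "E535", "FRET"))
    for (side in 1:2)
      write.csv(k[[q]][, , side],
                file.path(out_dir, sprintf("kymograph_%s_side%d.csv", q, side)),
                row.names = FALSE)
  write.csv(an$samples, file.path(out_dir, "segment_samples.csv"),
            row.names = FALSE)
  write.csv(an$qc, file.path(out_dir, "frame_qc.csv"), row.names = FALSE)
  write.csv(an$pairing, file.path(out_dir, "frame_pairing.csv"),
            row.names = FALSE)
  q <- analysis_quarter_stats(an)
  write.csv(q, file.path(out_dir, "quarter_cycles.csv"), row.names = FALSE)
  message(sprintf("%d/%d frames valid; outputs in %s", sum(an$qc$valid),
                  nrow(an$qc), out_dir))
  invisible(an)
}

#' Compare two cohorts of recording bundles
#'
#' Analyzes every bundle of the two cohorts, pools quarter-cycle statistics
#' and writes the strain-comparison table ([compare_strains()]).
#'
#' @param test_dirs,ctrl_dirs Character vectors of bundle directories.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return The [compare_strains()] result, invisibly.
#' @export
run_compare <- function(test_dirs, ctrl_dirs, out_dir,
                        config = pipeline_config()) {
  pool <- function(dirs) do.call(rbind, lapply(seq_along(dirs), function(i) {
    an <- analyze_recording(read_recording(dirs[i]), config)
    analysis_quarter_stats(an, animal = i)
  }))
  cmp <- compare_strains(pool(test_dirs), pool(ctrl_dirs))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cmp$quarters, file.path(out_dir, "strain_comparison.csv"),
            row.names = FALSE)
  write.csv(cmp$per_animal$summary,
            file.path(out_dir, "per_animal_summary.csv"), row.names = FALSE)
  invisible(cmp)
}
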