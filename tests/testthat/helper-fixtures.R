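# Fixture builders used across test files.

# A minimal stack built directly from matrices (no simulation): one
# transmitted + one or two fluorescence channels, any number of frames.
make_stack <- function(trans_frames, fluor_frames = NULL,
                       fluor2_frames = NULL, pixel_size = 1 / 16,
                       frame_interval = 1) {
  tf <- length(trans_frames)
  d <- dim(trans_frames[[1]])
  nch <- 1L + !is.null(fluor_frames) + !is.null(fluor2_frames)
  pix <- array(0, dim = c(d[1], d[2], nch, tf))
  for (t in seq_len(tf)) {
    pix[, , 1, t] <- trans_frames[[t]]
    if (!is.null(fluor_frames)) pix[, , 2, t] <- fluor_frames[[t]]
    if (!is.null(fluor2_frames)) pix[, , 3, t] <- fluor2_frames[[t]]
  }
  roles <- c("transmitted", rep("fluorescence", nch - 1L))
  movie_stack(pix, pixel_size, frame_interval, roles)
}

# Synthetic event table with specified speeds/mmfi, one cell.
make_events <- function(speeds, mmfi = seq_along(speeds),
                        cell_id = "cellA", size = 0.1) {
  n <- length(speeds)
  data.frame(cell_id = rep_len(cell_id, n),
             track_id = seq_len(n),
             frame = seq_len(n) - 1L,
             speed_um_s = speeds,
             mmfi_ch1 = rep_len(mmfi, n),
             size_um2 = rep_len(size, n))
}

# Observation table describing straight-line tracks with given lengths,
# spaced far apart so the linker cannot confuse them.
make_track_observations <- function(lengths, step = 0.05, spacing = 10) {
  rows <- list()
  for (k in seq_along(lengths)) {
    L <- lengths[k]
    rows[[k]] <- data.frame(
      frame = 0:(L - 1),
      x_um = spacing * (k - 1) + step * (0:(L - 1)),
      y_um = spacing * (k - 1),
      area_um2 = 0.1,
      mfi_ch1 = 100
    )
  }
  do.call(rbind, rows)
}
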