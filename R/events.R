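#' Convert tracks into frame-to-frame movement events
#'
#' The movement event ("tracked data point") is the unit of all downstream
#' statistics: one per consecutive observation pair of each track, carrying
#' the frame-to-frame speed (centroid displacement divided by the frame
#' interval), the per-channel MMFI (mean of the two bounding observations'
#' background-corrected MFIs) and the particle size (mean of the two areas).
#' A track of length L yields L - 1 events.
#'
#' @param tracks track table from [build_tracks()] or [read_tracks()].
#' @param frame_interval seconds per frame (> 0).
#' @return Event `data.frame`: `cell_id`, `track_id`, `frame` (first frame
#'   of the pair), `speed_um_s`, `mmfi_ch1` (and `mmfi_ch2` when the track
#'   table has two fluorescence channels), `size_um2`.
#' @export
compute_events <- function(tracks, frame_interval) {
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (!nrow(tracks))
    return(data.frame(cell_id = character(), track_id = integer(),
                      frame = integer(), speed_um_s = numeric(),
                      mmfi_ch1 = numeric(), size_um2 = numeric()))
  tracks <- tracks[order(tracks$cell_id, tracks$track_id, tracks$frame), ]
  key <- paste(tracks$cell_id, tracks$track_id)
  n <- nrow(tracks)
  same <- key[-1] == key[-n]
  if (any(same & (tracks$frame[-1] - tracks$frame[-n]) != 1))
    stop("tracks must be frame-contiguous (no gaps)")
  a <- which(same)          # row t of each pair; row t+1 is a + 1
  b <- a + 1L
  dx <- tracks$x_um[b] - tracks$x_um[a]
  dy <- tracks$y_um[b] - tracks$y_um[a]
  ev <- data.frame(
    cell_id = tracks$cell_id[a],
    track_id = tracks$track_id[a],
    frame = tracks$frame[a],
    speed_um_s = sqrt(dx^2 + dy^2) / frame_interval,
    mmfi_ch1 = (tracks$mfi_ch1[a] + tracks$mfi_ch1[b]) / 2,
    size_um2 = (tracks$area_um2[a] + tracks$area_um2[b]) / 2
  )
  if ("mfi_ch2" %in% names(tracks))
    ev$mmfi_ch2 <- (tracks$mfi_ch2[a] + tracks$mfi_ch2[b]) / 2
  rownames(ev) <- NULL
  ev
}

#' Attach the two-channel MMFI ratio to events
#'
#' `ratio = mmfi[numerator] / mmfi[denominator]` for events whose
#' denominator exceeds `epsilon`; events failing the guard get `NA` ratio
#' (they are excluded from ratio analyses, never silently dropped) and the
#' excluded count is reported.
#'
#' @param events event `data.frame` from [compute_events()].
#' @param numerator_channel,denominator_channel column names (e.g.
#'   `"mmfi_ch1"`, `"mmfi_ch2"`).
#' @param epsilon denominator guard (default 0; use a small positive value
#'   when background subtraction can push intensities to ~0).
#' @return `events` with an added `ratio` column and attribute
#'   `n_ratio_excluded`.
#' @export
compute_ratio <- function(events, numerator_channel = "mmfi_ch1",
                          denominator_channel = "mmfi_ch2", epsilon = 0) {
  for (ch in c(numerator_channel, denominator_channel))
    if (!ch %in% names(events))
      stop("channel column '", ch, "' missing from events")
  den <- events[[denominator_channel]]
  ok <- den > epsilon
  events$ratio <- ifelse(ok, events[[numerator_channel]] / den, NA_real_)
  n_exc <- sum(!ok)
  if (n_exc) message("compute_ratio: ", n_exc,
                     " event(s) excluded by denominator guard (<= ",
                     epsilon, ")")
  attr(events, "n_ratio_excluded") <- n_exc
  events
}

#' Normalize a fluorescence channel per cell
#'
#' Divides each event's channel value by the median of that channel over all
#' events of the same cell — a robust, scale-free normalization that makes
#' per-channel intensities comparable across bins and cells regardless of
#' expression level.
#'
#' @param events event `data.frame`.
#' @param channel column name to normalize (e.g. `"mmfi_ch1"`).
#' @return `events` with an added `norm_<channel>` column.
#' @export
normalize_channel <- function(events, channel) {
  if (!channel %in% names(events))
    stop("channel column '", channel, "' missing from events")
  if (!nrow(events) || all(!is.finite(events[[channel]])))
    stop("no finite values to normalize in ", channel)
  med <- tapply(events[[channel]], events$cell_id, stats::median,
                na.rm = TRUE)
  bad <- names(med)[med <= 0 | !is.finite(med)]
  if (length(bad))
    stop("per-cell median of ", channel, " is <= 0 for cell(s): ",
         paste(bad, collapse = ", "))
  events[[paste0("norm_", channel)]] <-
    events[[channel]] / as.numeric(med[as.character(events$cell_id)])
  events
}

#' Write / read an event table as CSV
#'
#' @param events event `data.frame`.
#' @param path CSV path.
#' @return `write_events()`: invisibly the path; `read_events()`: the
#'   `data.frame`.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
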