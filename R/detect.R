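#' Multi-channel time-lapse stack with physical calibration
#'
#' The pipeline's pixel container: a 4-d array `[row, col, channel, frame]`
#' plus the physical calibration needed to convert pixels to micrometers and
#' frames to seconds. Exactly one channel must carry the role
#' `"transmitted"` (the detection channel, dark organelles on a bright
#' background) and 0-2 channels the role `"fluorescence"`.
#'
#' @param pixels numeric array, `dim = c(rows, cols, channels, frames)`.
#' @param pixel_size um per pixel (> 0).
#' @param frame_interval seconds per frame (> 0).
#' @param channel_roles character vector, one role per channel.
#' @return A `movie_stack` object.
#' @export
movie_stack <- function(pixels, pixel_size, frame_interval, channel_roles) {
  if (length(dim(pixels)) != 4)
    stop("pixels must be a 4-d array [row, col, channel, frame]")
  if (dim(pixels)[4] < 2) stop("a movie needs at least 2 frames")
  if (pixel_size <= 0 || frame_interval <= 0)
    stop("pixel_size and frame_interval must be > 0")
  channel_roles <- as.character(channel_roles)
  if (length(channel_roles) != dim(pixels)[3])
    stop("one channel role per channel required")
  if (sum(channel_roles == "transmitted") != 1)
    stop("exactly one channel must have role 'transmitted'")
  nf <- sum(channel_roles == "fluorescence")
  if (nf > 2 || nf + 1 != length(channel_roles))
    stop("channel roles must be one 'transmitted' plus 0-2 'fluorescence'")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 channel_roles = channel_roles),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "movie_stack: %d frame(s), %d channel(s) [%s], %d x %d px, %.4f um/px, %.3g s/frame\n",
    d[4], d[3], paste(x$channel_roles, collapse = ", "),
    d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

.n_fluor <- function(stack) sum(stack$channel_roles == "fluorescence")

.frame_matrix <- function(stack, frame_index, channel) {
  d <- dim(stack$pixels)
  if (frame_index < 0 || frame_index >= d[4])
    stop("frame ", frame_index, " does not exist (movie has ", d[4],
         " frames, 0-based indexing)")
  stack$pixels[, , channel, frame_index + 1L]
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so diagonally
# adjacent labels are merged afterwards with a union-find pass.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs carrying two different labels
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right
  a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]    # down-left
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (!nrow(pairs)) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  lab[lab > 0L] <- dense[lab[lab > 0L]]
  lab
}

#' Estimate the fluorescence background of one frame
#'
#' Median intensity of the pixels outside all detected-particle masks in the
#' given frame. With no mask (no particles detected) the whole-frame median
#' is returned; if the masks cover the entire frame the global frame median
#' is used as a fallback and a warning is raised.
#'
#' @param stack a [movie_stack()].
#' @param frame_index 0-based frame index.
#' @param channel channel index into the stack (must be a fluorescence
#'   channel).
#' @param mask optional logical/integer matrix marking particle pixels
#'   (non-zero = particle); `NULL` means no particles detected.
#' @return scalar background intensity.
#' @export
estimate_background <- function(stack, frame_index, channel, mask = NULL) {
  if (channel < 1 || channel > length(stack$channel_roles) ||
      stack$channel_roles[channel] != "fluorescence")
    stop("channel ", channel, " is not a fluorescence channel")
  img <- .frame_matrix(stack, frame_index, channel)
  if (is.null(mask)) return(stats::median(img))
  outside <- img[mask == 0]
  if (!length(outside)) {
    warning("frame ", frame_index,
            " entirely covered by particle masks; using global frame median")
    return(stats::median(img))
  }
  stats::median(outside)
}

#' Detect particles in one transmitted-light frame
#'
#' Thresholds the transmitted channel (pixels darker than
#' `intensity_threshold` are foreground for `polarity = "dark"`; brighter
#' for `"bright"`), labels 8-connected components, keeps those whose area in
#' um^2 lies inside `[min_area, max_area]`, and measures for each retained
#' particle the unweighted mask centroid (um, origin at the center of the
#' top-left pixel, x along columns, y along rows) and the per-fluorescence-
#' channel background-corrected mean intensity (MFI). Output rows are sorted
#' by (y, x) for determinism.
#'
#' @param stack a [movie_stack()].
#' @param frame_index 0-based frame index.
#' @param intensity_threshold transmitted-channel threshold; `NULL` (default)
#'   picks it automatically by Otsu's method on the frame.
#' @param min_area,max_area particle area filter in um^2 (`min_area <
#'   max_area`).
#' @param polarity `"dark"` (default; pigmented organelles absorb light) or
#'   `"bright"`.
#' @param background_correction subtract the per-frame median background
#'   (outside all masks) from each MFI (default `TRUE`).
#' @return `data.frame` with columns `frame`, `x_um`, `y_um`, `area_um2`,
#'   `mfi_ch1` (and `mfi_ch2` for two-fluorophore stacks). Zero detections
#'   give an empty data.frame with the same columns.
#' @export
detect_particles <- function(stack, frame_index, intensity_threshold = NULL,
                             min_area = 0.05, max_area = 2,
                             polarity = c("dark", "bright"),
                             background_correction = TRUE) {
  stopifnot(inherits(stack, "movie_stack"))
  polarity <- match.arg(polarity)
  if (min_area >= max_area) stop("min_area must be < max_area")
  trans_ch <- which(stack$channel_roles == "transmitted")
  img <- .frame_matrix(stack, frame_index, trans_ch)
  if (is.null(intensity_threshold)) {
    rng <- range(img)
    if (diff(rng) == 0) {
      intensity_threshold <- rng[1]  # flat frame: nothing can be foreground
    } else {
      scaled <- (img - rng[1]) / diff(rng)
      intensity_threshold <- rng[1] +
        diff(rng) * EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    }
  }
  mask <- if (polarity == "dark") img < intensity_threshold
          else img > intensity_threshold
  ps <- stack$pixel_size
  px_area <- ps^2
  empty <- data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
                      area_um2 = numeric())
  nfl <- .n_fluor(stack)
  for (ch in seq_len(nfl)) empty[[paste0("mfi_ch", ch)]] <- numeric()
  if (!any(mask)) {
    message("frame ", frame_index, ": no particles detected")
    return(empty)
  }
  lab <- .label8(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes * px_area >= min_area & sizes * px_area <= max_area)
  if (!length(keep)) {
    message("frame ", frame_index, ": no particles detected (",
            length(sizes), " components rejected by area filter)")
    return(empty)
  }
  # retained-component mask drives both centroids and background estimation
  keep_lab <- lab
  keep_lab[!(lab %in% keep)] <- 0L
  idx <- which(keep_lab > 0L)
  comp <- match(keep_lab[idx], keep)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  n_px <- tabulate(comp, nbins = length(keep))
  cx <- tapply(cols, comp, mean)  # unweighted centroid, pixel units
  cy <- tapply(rows, comp, mean)
  obs <- data.frame(
    frame = rep(as.integer(frame_index), length(keep)),
    x_um = as.numeric(cx - 1) * ps,
    y_um = as.numeric(cy - 1) * ps,
    area_um2 = n_px * px_area
  )
  fl_ch <- which(stack$channel_roles == "fluorescence")
  for (k in seq_along(fl_ch)) {
    fimg <- .frame_matrix(stack, frame_index, fl_ch[k])
    bg <- if (background_correction)
      estimate_background(stack, frame_index, fl_ch[k], mask = keep_lab)
    else 0
    obs[[paste0("mfi_ch", k)]] <-
      as.numeric(tapply(fimg[idx], comp, mean)) - bg
  }
  ord <- order(obs$y_um, obs$x_um)
  obs <- obs[ord, , drop = FALSE]
  rownames(obs) <- NULL
  obs
}

#' Detect particles in every frame of a movie
#'
#' Runs [detect_particles()] on each frame and row-binds the results.
#'
#' @inheritParams detect_particles
#' @param ... passed on to [detect_particles()].
#' @return Combined observation `data.frame` over all frames.
#' @export
detect_movie <- function(stack, ...) {
  d <- dim(stack$pixels)
  obs <- vector("list", d[4])
  for (t in seq_len(d[4]))
    obs[[t]] <- suppressMessages(detect_particles(stack, t - 1L, ...))
  do.call(rbind, obs)
}

#' Write / read an observation table as CSV
#'
#' @param obs observation `data.frame` from [detect_particles()].
#' @param path CSV path.
#' @return `write_observations()`: invisibly the path;
#'   `read_observations()`: the `data.frame`.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
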