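#' Simulation configuration for synthetic organelle movies
#'
#' Bundles every knob of the synthetic time-lapse generator. Defaults mirror
#' the acquisition settings of the live-cell recordings the pipeline was
#' designed for: 16 px per micrometer, 1 frame per second, 100-frame
#' sequences of a 20 x 20 micrometer region containing ~50 pigmented
#' organelles. Motion is a per-particle two-state (static/motile) Markov
#' switch: static particles jitter with per-axis Gaussian noise, motile
#' particles perform directed runs with per-run speed drawn uniformly from
#' `motile_speed_range` and a slowly diffusing heading.
#'
#' `coupling_sign` couples each particle's fluorescence label level to its
#' probability of occupying the motile state: with `"negative"` coupling,
#' high-label particles are more often static (the membrane-recruitment
#' phenotype the pipeline is built to detect); `"positive"` is the mirror
#' image; `"none"` leaves motility independent of label. `coupling_strength`
#' in [0, 1] scales the effect from nothing to full suppression.
#'
#' @param field_size numeric length-2, field width and height in um.
#' @param n_particles number of particles.
#' @param pixel_size um per pixel (default 1/16).
#' @param frame_interval seconds between frames (default 1).
#' @param n_frames number of frames (>= 2).
#' @param particle_radius_range um, range of particle radii.
#' @param motile_fraction baseline stationary probability of the motile
#'   state, in [0, 1].
#' @param motile_speed_range um/s, range of per-run speeds.
#' @param static_jitter_sigma um, per-axis positional jitter per frame.
#' @param coupling_sign `"negative"`, `"positive"` or `"none"`.
#' @param coupling_strength dimensionless in [0, 1].
#' @param label_intensity_range arbitrary fluorescence units, per-particle
#'   label levels are drawn uniformly from this range.
#' @param cytosolic_background fluorescence units added uniformly to
#'   fluorescence channels.
#' @param noise_sigma additive Gaussian camera noise (all channels).
#' @param n_channels number of fluorescence channels (1 or 2). Channel 1
#'   carries the coupled label; channel 2 (if present) an independent label.
#' @param seed integer RNG seed; `NULL` leaves the RNG state untouched.
#' @param mean_motile_dwell frames, mean geometric dwell in the motile state.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(field_size = c(20, 20),
                              n_particles = 50,
                              pixel_size = 1 / 16,
                              frame_interval = 1.0,
                              n_frames = 100,
                              particle_radius_range = c(0.15, 0.25),
                              motile_fraction = 0.35,
                              motile_speed_range = c(0.05, 0.8),
                              static_jitter_sigma = 0.008,
                              coupling_sign = c("negative", "positive", "none"),
                              coupling_strength = 0,
                              label_intensity_range = c(200, 1000),
                              cytosolic_background = 100,
                              noise_sigma = 10,
                              n_channels = 1,
                              seed = NULL,
                              mean_motile_dwell = 10) {
  coupling_sign <- match.arg(coupling_sign)
  if (length(field_size) != 2 || any(field_size <= 0))
    stop("field_size must be two positive lengths (um)")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (n_particles < 1) stop("n_particles must be >= 1")
  if (any(particle_radius_range <= 0) ||
      particle_radius_range[1] > particle_radius_range[2])
    stop("particle_radius_range must be an increasing positive range (um)")
  if (motile_fraction < 0 || motile_fraction > 1)
    stop("motile_fraction must be in [0, 1]")
  if (any(motile_speed_range <= 0) ||
      motile_speed_range[1] > motile_speed_range[2])
    stop("motile_speed_range must lie in (0, Inf) and be increasing")
  if (static_jitter_sigma < 0) stop("static_jitter_sigma must be >= 0")
  if (coupling_strength < 0 || coupling_strength > 1)
    stop("coupling_strength must be in [0, 1]")
  if (!n_channels %in% c(1, 2)) stop("n_channels must be 1 or 2")
  if (diff(label_intensity_range) < 0 || any(label_intensity_range < 0))
    stop("label_intensity_range must be a non-negative increasing range")
  if (mean_motile_dwell < 1) stop("mean_motile_dwell must be >= 1 frame")
  structure(list(
    field_size = as.numeric(field_size),
    n_particles = as.integer(n_particles),
    pixel_size = pixel_size,
    frame_interval = frame_interval,
    n_frames = as.integer(n_frames),
    particle_radius_range = particle_radius_range,
    motile_fraction = motile_fraction,
    motile_speed_range = motile_speed_range,
    static_jitter_sigma = static_jitter_sigma,
    coupling_sign = coupling_sign,
    coupling_strength = coupling_strength,
    label_intensity_range = label_intensity_range,
    cytosolic_background = cytosolic_background,
    noise_sigma = noise_sigma,
    n_channels = as.integer(n_channels),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    mean_motile_dwell = mean_motile_dwell
  ), class = "simulation_config")
}

# Transmitted-light rendering constants: dark melanin core on a bright
# background. Arbitrary detector units, matched by the default detection
# threshold heuristics (Otsu separates the two modes whatever the values).
.TRANS_BRIGHT <- 1000
.TRANS_DARK <- 200

#' Simulate particle trajectories, states and label levels (no rendering)
#'
#' Runs only the motion and label model of [simulate_movie()], returning the
#' ground-truth table. Useful for statistical checks on the generative model
#' itself (e.g. label-motility coupling recovery) where rendering pixels
#' would be wasted work.
#'
#' @param config a [simulation_config()].
#' @return A `data.frame` with one row per particle per frame: `frame`
#'   (0-based), `particle_id`, `x_um`, `y_um`, `state` ("static"/"motile",
#'   the state governing the displacement leaving that frame),
#'   `radius_um`, `label_ch1` and (two-channel configs) `label_ch2`.
#' @export
simulate_ground_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_particles
  W <- config$field_size[1]
  H <- config$field_size[2]
  tf <- config$n_frames
  dt <- config$frame_interval

  radii <- stats::runif(n, config$particle_radius_range[1],
                        config$particle_radius_range[2])
  lr <- config$label_intensity_range
  labels1 <- stats::runif(n, lr[1], lr[2])
  labels2 <- if (config$n_channels == 2) stats::runif(n, lr[1], lr[2]) else NULL

  # label level normalized to [0,1] against the configured range, so the
  # coupling is a property of the config, not of the realized sample
  u <- if (diff(lr) > 0) (labels1 - lr[1]) / diff(lr) else rep(0.5, n)
  p_motile <- switch(config$coupling_sign,
    negative = config$motile_fraction * (1 - config$coupling_strength * u),
    positive = config$motile_fraction * (1 - config$coupling_strength * (1 - u)),
    none     = rep(config$motile_fraction, n)
  )
  p_motile <- pmin(pmax(p_motile, 0), 1)

  # non-overlapping initial placement (touching discs would merge at t = 0)
  margin <- 2 * config$pixel_size
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(5000L)) {
      cand_x <- stats::runif(1, radii[i], W - radii[i])
      cand_y <- stats::runif(1, radii[i], H - radii[i])
      if (i == 1L) { ok <- TRUE } else {
        j <- seq_len(i - 1L)
        ok <- all((cand_x - xs[j])^2 + (cand_y - ys[j])^2 >
                    (radii[i] + radii[j] + margin)^2)
      }
      if (ok) { xs[i] <- cand_x; ys[i] <- cand_y; placed <- TRUE; break }
    }
    if (!placed)
      stop("field too small to host ", n,
           " particles without initial overlap (failed at particle ", i, ")")
  }

  # two-state Markov switch with geometric dwell times; transition rates set
  # so the stationary motile occupancy equals p_motile per particle
  q_base <- 1 / config$mean_motile_dwell
  q_ms <- ifelse(p_motile >= 1, 0, q_base)                 # motile -> static
  q_sm <- ifelse(p_motile >= 1, 1,
                 pmin(1, p_motile / (1 - p_motile) * q_base)) # static -> motile

  pos_x <- matrix(0, tf, n); pos_y <- matrix(0, tf, n)
  state <- matrix("static", tf, n)
  pos_x[1, ] <- xs; pos_y[1, ] <- ys
  motile <- stats::runif(n) < p_motile
  speed <- stats::runif(n, config$motile_speed_range[1],
                        config$motile_speed_range[2])
  theta <- stats::runif(n, 0, 2 * pi)
  ang_sigma <- 0.2  # rad/frame heading diffusion within a run

  for (t in seq_len(tf)) {
    state[t, ] <- ifelse(motile, "motile", "static")
    if (t == tf) break
    dx <- stats::rnorm(n, 0, config$static_jitter_sigma)
    dy <- stats::rnorm(n, 0, config$static_jitter_sigma)
    run <- which(motile)
    if (length(run)) {
      dx[run] <- dx[run] + speed[run] * dt * cos(theta[run])
      dy[run] <- dy[run] + speed[run] * dt * sin(theta[run])
    }
    nx <- pos_x[t, ] + dx
    ny <- pos_y[t, ] + dy
    # reflecting boundary (fold back into the field, flip heading component)
    over_x <- nx < 0 | nx > W
    over_y <- ny < 0 | ny > H
    nx <- ifelse(nx < 0, -nx, nx); nx <- ifelse(nx > W, 2 * W - nx, nx)
    ny <- ifelse(ny < 0, -ny, ny); ny <- ifelse(ny > H, 2 * H - ny, ny)
    theta[over_x] <- pi - theta[over_x]
    theta[over_y] <- -theta[over_y]
    pos_x[t + 1, ] <- nx
    pos_y[t + 1, ] <- ny
    # state transitions and heading/speed refresh for new runs
    theta <- theta + stats::rnorm(n, 0, ang_sigma)
    uflip <- stats::runif(n)
    switch_on <- !motile & uflip < q_sm
    switch_off <- motile & uflip < q_ms
    if (any(switch_on)) {
      k <- which(switch_on)
      speed[k] <- stats::runif(length(k), config$motile_speed_range[1],
                               config$motile_speed_range[2])
      theta[k] <- stats::runif(length(k), 0, 2 * pi)
    }
    motile <- (motile & !switch_off) | switch_on
  }

  out <- data.frame(
    frame = rep(0:(tf - 1L), times = n),
    particle_id = rep(seq_len(n), each = tf),
    x_um = as.vector(pos_x),
    y_um = as.vector(pos_y),
    state = as.vector(state),
    radius_um = rep(radii, each = tf),
    label_ch1 = rep(labels1, each = tf)
  )
  if (!is.null(labels2)) out$label_ch2 <- rep(labels2, each = tf)
  out
}

#' Simulate a synthetic multi-channel organelle movie with ground truth
#'
#' Renders the trajectories of [simulate_ground_truth()] into a
#' [movie_stack()]: the transmitted channel shows each particle as a dark
#' disc on a bright background; each fluorescence channel shows a Gaussian
#' spot (sigma = particle radius) scaled by the particle's label level on a
#' uniform cytosolic background. Additive Gaussian noise of the configured
#' sigma is applied to every channel. Identical seeds give bit-identical
#' output.
#'
#' @param config a [simulation_config()].
#' @return list with elements `stack` (a [movie_stack()]) and `truth`
#'   (ground-truth `data.frame`, see [simulate_ground_truth()]).
#' @export
simulate_movie <- function(config) {
  truth <- simulate_ground_truth(config)
  stack <- .render_movie(config, truth)
  list(stack = stack, truth = truth)
}

#' Simulate a fixed (chemically immobilized) sample
#'
#' Identical to [simulate_movie()] with the motile fraction forced to zero:
#' every particle is static for the whole recording and the residual motion
#' is localization-scale jitter only. Used to calibrate the static-speed
#' threshold the way fixed-cell recordings are used on real data.
#'
#' @inheritParams simulate_movie
#' @return As [simulate_movie()]; every ground-truth state is `"static"`.
#' @export
simulate_fixed_sample <- function(config) {
  config$motile_fraction <- 0
  simulate_movie(config)
}

# Rasterize ground truth into a pixel stack. Consumes RNG (noise), so must be
# called in the same RNG stream as the motion simulation for reproducibility.
.render_movie <- function(config, truth) {
  ncol_px <- round(config$field_size[1] / config$pixel_size)
  nrow_px <- round(config$field_size[2] / config$pixel_size)
  tf <- config$n_frames
  nch <- 1L + config$n_channels
  roles <- c("transmitted", rep("fluorescence", config$n_channels))
  pix <- array(0, dim = c(nrow_px, ncol_px, nch, tf))
  ps <- config$pixel_size
  label_cols <- c("label_ch1", if (config$n_channels == 2) "label_ch2")

  for (t in seq_len(tf)) {
    rows_t <- truth[truth$frame == t - 1L, ]
    trans <- matrix(.TRANS_BRIGHT, nrow_px, ncol_px)
    fluo <- lapply(seq_len(config$n_channels), function(ch)
      matrix(config$cytosolic_background, nrow_px, ncol_px))
    for (k in seq_len(nrow(rows_t))) {
      x <- rows_t$x_um[k]; y <- rows_t$y_um[k]; r <- rows_t$radius_um[k]
      sig <- r
      half <- ceiling((r + 4 * sig) / ps)
      c0 <- round(x / ps) + 1L; r0 <- round(y / ps) + 1L
      cc <- max(1L, c0 - half):min(ncol_px, c0 + half)
      rr <- max(1L, r0 - half):min(nrow_px, r0 + half)
      if (!length(cc) || !length(rr)) next
      dx <- (cc - 1) * ps - x
      dy <- (rr - 1) * ps - y
      d2 <- outer(dy^2, dx^2, `+`)
      core <- d2 <= r^2
      if (any(core)) {
        sub <- trans[rr, cc, drop = FALSE]
        sub[core] <- pmin(sub[core], .TRANS_DARK)
        trans[rr, cc] <- sub
      }
      spot <- exp(-d2 / (2 * sig^2))
      for (ch in seq_len(config$n_channels)) {
        amp <- rows_t[[label_cols[ch]]][k]
        fluo[[ch]][rr, cc] <- fluo[[ch]][rr, cc] + amp * spot
      }
    }
    pix[, , 1L, t] <- trans +
      matrix(stats::rnorm(nrow_px * ncol_px, 0, config$noise_sigma),
             nrow_px, ncol_px)
    for (ch in seq_len(config$n_channels)) {
      pix[, , 1L + ch, t] <- fluo[[ch]] +
        matrix(stats::rnorm(nrow_px * ncol_px, 0, config$noise_sigma),
               nrow_px, ncol_px)
    }
  }
  movie_stack(pix, pixel_size = ps, frame_interval = config$frame_interval,
              channel_roles = roles)
}

#' Write a movie stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are channel-interleaved per frame (frame 1 channel 1, frame 1
#' channel 2, ..., frame 2 channel 1, ...). Pixels are stored as 16-bit
#' samples scaled by `intensity_scale` (recorded in the sidecar together
#' with pixel size, frame interval and channel roles), so arbitrary-unit
#' intensities survive the round trip up to 16-bit quantization.
#'
#' @param stack a [movie_stack()].
#' @param path output TIFF path; the sidecar is written next to it with the
#'   extension replaced by `.json`.
#' @return Invisibly, the sidecar path.
#' @export
write_movie <- function(stack, path) {
  stopifnot(inherits(stack, "movie_stack"))
  d <- dim(stack$pixels)
  scale <- max(stack$pixels)
  if (scale <= 0) scale <- 1
  pages <- vector("list", d[4] * d[3])
  i <- 1L
  for (t in seq_len(d[4])) for (ch in seq_len(d[3])) {
    pages[[i]] <- pmin(pmax(stack$pixels[, , ch, t] / scale, 0), 1)
    i <- i + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(list(
    pixel_size_um = stack$pixel_size,
    frame_interval_s = stack$frame_interval,
    channel_roles = stack$channel_roles,
    n_frames = d[4],
    n_channels = d[3],
    intensity_scale = scale
  ), sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}

#' Read a movie stack written by [write_movie()]
#'
#' @param path TIFF path; the JSON sidecar must sit next to it.
#' @return A [movie_stack()].
#' @export
read_movie <- function(path) {
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar))
    stop("missing sidecar ", sidecar,
         ": pixel_size and frame_interval metadata are required")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  req <- c("pixel_size_um", "frame_interval_s", "channel_roles",
           "n_frames", "n_channels", "intensity_scale")
  if (!all(req %in% names(meta)))
    stop("sidecar ", sidecar, " lacks required calibration fields: ",
         paste(setdiff(req, names(meta)), collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE)
  tf <- meta$n_frames; nch <- meta$n_channels
  if (length(pages) != tf * nch)
    stop("corrupted TIFF ", path, ": expected ", tf * nch,
         " pages, found ", length(pages))
  d1 <- dim(pages[[1]])
  pix <- array(0, dim = c(d1[1], d1[2], nch, tf))
  i <- 1L
  for (t in seq_len(tf)) for (ch in seq_len(nch)) {
    pg <- pages[[i]]
    if (!identical(dim(pg)[1:2], d1))
      stop("corrupted TIFF ", path, ": page ", i, " has mismatched shape")
    pix[, , ch, t] <- pg * meta$intensity_scale
    i <- i + 1L
  }
  movie_stack(pix, pixel_size = meta$pixel_size_um,
              frame_interval = meta$frame_interval_s,
              channel_roles = meta$channel_roles)
}

#' Write / read a ground-truth table as CSV
#'
#' @param truth ground-truth `data.frame` from [simulate_ground_truth()].
#' @param path CSV path.
#' @return `write_ground_truth()`: invisibly the path;
#'   `read_ground_truth()`: the `data.frame`.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
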