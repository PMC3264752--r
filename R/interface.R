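#' Pipeline configuration
#'
#' Central configuration for the detection, tracking and analysis stages.
#' Any field can be overridden; the rest keep defaults matched to the
#' acquisition conventions the pipeline targets (16 px/um, 1 fps, 10-frame
#' minimum track length, decile binning, 0.05 um/s default static
#' threshold).
#'
#' @param detection list: `intensity_threshold` (`NULL` = Otsu), `min_area`,
#'   `max_area` (um^2), `polarity` (`"dark"`/`"bright"`),
#'   `background_correction` (logical).
#' @param tracking list: `max_displacement` (um), `min_track_length`
#'   (frames).
#' @param analysis list: `n_bins`, `static_threshold` (um/s, used when no
#'   calibration events are supplied), `binning_variable`,
#'   `ratio_numerator`, `ratio_denominator`, `epsilon` (ratio denominator
#'   guard).
#' @param calibration list: `pixel_size` (um/px), `frame_interval` (s) —
#'   used for inputs that carry no metadata of their own.
#' @param seed integer or `NULL`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(detection = list(), tracking = list(),
                            analysis = list(), calibration = list(),
                            seed = NULL) {
  cfg <- list(
    detection = utils::modifyList(list(
      intensity_threshold = NULL, min_area = 0.05, max_area = 2,
      polarity = "dark", background_correction = TRUE), detection,
      keep.null = TRUE),
    tracking = utils::modifyList(list(
      max_displacement = 1.2, min_track_length = 10), tracking),
    analysis = utils::modifyList(list(
      n_bins = 10, static_threshold = 0.05,
      binning_variable = "mmfi_ch1",
      ratio_numerator = "mmfi_ch1", ratio_denominator = "mmfi_ch2",
      epsilon = 1e-9), analysis),
    calibration = utils::modifyList(list(
      pixel_size = 1 / 16, frame_interval = 1), calibration),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  with(cfg, {
    if (tracking$max_displacement <= 0) stop("max_displacement must be > 0")
    if (tracking$min_track_length < 2) stop("min_track_length must be >= 2")
    if (analysis$n_bins < 2) stop("n_bins must be >= 2")
    if (analysis$static_threshold <= 0) stop("static_threshold must be > 0")
    if (calibration$pixel_size <= 0 || calibration$frame_interval <= 0)
      stop("pixel_size and frame_interval must be > 0")
  })
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Keys mirror the [pipeline_config()] sections; missing keys keep their
#' defaults.
#'
#' @param path JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(detection = raw$detection %||% list(),
                  tracking = raw$tracking %||% list(),
                  analysis = raw$analysis %||% list(),
                  calibration = raw$calibration %||% list(),
                  seed = raw$seed)
}

.provenance <- function(config, seed, extra = list()) {
  c(list(package = "melanotrack",
         version = as.character(utils::packageVersion("melanotrack")),
         config_hash = rlang::hash(config),
         seed = seed), extra)
}

#' Simulate a movie and write it to disk (CLI backend)
#'
#' Writes `<out_prefix>.tif` (multi-page TIFF), `<out_prefix>.json`
#' (calibration sidecar) and `<out_prefix>_truth.csv` (ground truth).
#' Deterministic under the config seed; a missing seed is drawn once and
#' reported so the run remains reproducible.
#'
#' @param sim_config a [simulation_config()].
#' @param out_prefix output path prefix.
#' @return Invisibly, a named list of the written paths.
#' @export
cli_simulate <- function(sim_config, out_prefix) {
  stopifnot(inherits(sim_config, "simulation_config"))
  if (is.null(sim_config$seed)) {
    sim_config$seed <- sample.int(.Machine$integer.max, 1)
    message("cli_simulate: no seed supplied, generated seed ",
            sim_config$seed)
  }
  sim <- simulate_movie(sim_config)
  tif <- paste0(out_prefix, ".tif")
  write_movie(sim$stack, tif)
  truth_csv <- paste0(out_prefix, "_truth.csv")
  write_ground_truth(sim$truth, truth_csv)
  message("cli_simulate: wrote ", tif, " (+ sidecar) and ", truth_csv)
  invisible(list(tiff = tif,
                 sidecar = paste0(out_prefix, ".json"),
                 truth = truth_csv))
}

#' Detect, track and extract events from a movie on disk (CLI backend)
#'
#' Reads a TIFF + sidecar written by [cli_simulate()] (or any movie in that
#' format), runs detection over all frames, gated optimal linking, the
#' track-length filter and event extraction, and writes
#' `<out_prefix>_tracks.csv`, `<out_prefix>_events.csv` and
#' `<out_prefix>_census.json`.
#'
#' @param movie_path TIFF path (sidecar expected next to it).
#' @param config a [pipeline_config()].
#' @param out_prefix output path prefix.
#' @param cell_id cell identifier for the track/event tables; default the
#'   basename of `out_prefix`.
#' @return Invisibly, a list with the track table, event table and census.
#' @export
cli_track <- function(movie_path, config = pipeline_config(), out_prefix,
                      cell_id = basename(out_prefix)) {
  stopifnot(inherits(config, "pipeline_config"))
  stack <- read_movie(movie_path)
  det <- config$detection
  obs <- detect_movie(stack,
                      intensity_threshold = det$intensity_threshold,
                      min_area = det$min_area, max_area = det$max_area,
                      polarity = det$polarity,
                      background_correction = det$background_correction)
  tracks <- build_tracks(obs,
                         max_displacement = config$tracking$max_displacement,
                         min_track_length = config$tracking$min_track_length,
                         frame_interval = stack$frame_interval,
                         cell_id = cell_id)
  events <- compute_events(tracks, stack$frame_interval)
  census <- track_census(tracks)
  write_tracks(tracks, paste0(out_prefix, "_tracks.csv"))
  write_events(events, paste0(out_prefix, "_events.csv"))
  jsonlite::write_json(list(
    provenance = .provenance(config, config$seed,
                             list(movie = basename(movie_path))),
    n_tracks = census$n_tracks,
    n_frame_to_frame_points = census$n_frame_to_frame_points,
    n_tracks_discarded = attr(tracks, "n_discarded"),
    length_histogram = as.list(stats::setNames(
      as.integer(census$length_histogram),
      names(census$length_histogram)))
  ), paste0(out_prefix, "_census.json"), auto_unbox = TRUE, digits = NA,
     pretty = TRUE)
  message("cli_track: ", census$n_tracks, " track(s), ",
          census$n_frame_to_frame_points, " frame-to-frame point(s), ",
          attr(tracks, "n_discarded"), " short track(s) discarded")
  invisible(list(tracks = tracks, events = events, census = census))
}

#' Bin, aggregate and test event tables (CLI backend)
#'
#' Reads one event CSV per cell, calibrates the static threshold from an
#' optional fixed-sample event CSV (otherwise uses the configured default),
#' bins per cell by the configured variable, summarizes and aggregates
#' across cells, runs Kruskal-Wallis + Dunn across bins pooled by index,
#' Spearman correlation on the full scatter (binning variable vs speed) and
#' the size-vs-MMFI correlation, and writes `<out_prefix>_report.json` plus
#' `<out_prefix>_bins.csv` (flat per-cell per-bin summaries). Every
#' reported block is labeled with its provenance (pooled events vs per-cell
#' aggregation).
#'
#' @param event_files character vector of event CSV paths, one per cell.
#'   Cell ids are taken from the file names (sans extension).
#' @param config a [pipeline_config()].
#' @param fixed_event_file optional fixed-sample event CSV for threshold
#'   calibration.
#' @param out_prefix output path prefix.
#' @return Invisibly, the report list.
#' @export
cli_analyze <- function(event_files, config = pipeline_config(),
                        fixed_event_file = NULL, out_prefix) {
  stopifnot(inherits(config, "pipeline_config"))
  an <- config$analysis
  cells <- lapply(event_files, read_events)
  nch <- vapply(cells, function(e) sum(grepl("^mmfi_ch", names(e))),
                integer(1))
  if (length(unique(nch)) != 1)
    stop("mixed channel counts across event files: ",
         paste(basename(event_files), "=", nch, collapse = ", "))
  for (i in seq_along(cells))
    cells[[i]]$cell_id <- tools::file_path_sans_ext(basename(event_files[i]))
  events <- do.call(rbind, cells)
  for (cl in unique(events$cell_id))
    if (sum(events$cell_id == cl) < an$n_bins)
      stop("cell '", cl, "' has fewer events (",
           sum(events$cell_id == cl), ") than n_bins (", an$n_bins, ")")
  threshold <- if (!is.null(fixed_event_file))
    calibrate_static_threshold(read_events(fixed_event_file))
  else if (an$static_threshold == 0.05) default_static_threshold()
  else structure(list(value = an$static_threshold, source = "config",
                      n_calibration_events = 0L),
                 class = "static_threshold")
  if (an$binning_variable == "ratio" && !"ratio" %in% names(events))
    events <- compute_ratio(events, an$ratio_numerator,
                            an$ratio_denominator, an$epsilon)
  binned <- bin_by_variable(events, an$binning_variable, an$n_bins)
  summaries <- summarize_bins(binned, threshold)
  aggregate <- aggregate_cells(summaries)
  pooled <- split(binned$speed_um_s, binned$bin)
  kw <- kruskal_wallis_dunn(pooled)
  scatter <- spearman_with_ci(binned[[an$binning_variable]],
                              binned$speed_um_s)
  size_cor <- if (an$binning_variable != "size_um2")
    size_vs_mmfi(binned, if (an$binning_variable %in% names(binned) &&
                             grepl("^mmfi_ch", an$binning_variable))
                   an$binning_variable else "mmfi_ch1")
  else NULL
  # per-channel normalized intensity per ratio bin (two-fluorophore mode)
  norm_block <- NULL
  if (an$binning_variable == "ratio") {
    nb <- binned
    for (ch in c(an$ratio_numerator, an$ratio_denominator))
      nb <- normalize_channel(nb, ch)
    norm_block <- lapply(c(an$ratio_numerator, an$ratio_denominator),
      function(ch) {
        v <- split(nb[[paste0("norm_", ch)]], nb$bin)
        list(channel = ch,
             mean = vapply(v, mean, numeric(1)),
             sd = vapply(v, stats::sd, numeric(1)),
             provenance = "pooled events, per-cell median normalized")
      })
  }
  report <- list(
    provenance = .provenance(config, config$seed,
                             list(cells = vapply(cells, function(e)
                               e$cell_id[1], character(1)))),
    threshold = list(value = threshold$value, source = threshold$source,
                     n_calibration_events = threshold$n_calibration_events),
    binning = list(variable = an$binning_variable, n_bins = an$n_bins,
                   n_events = nrow(binned)),
    per_bin_aggregate = c(as.list(aggregate),
                          provenance = attr(aggregate, "provenance")),
    kruskal_wallis = list(
      statistic = kw$statistic, df = kw$df, p_value = kw$p_value,
      p_method = kw$p_method, n_per_bin = kw$n,
      dunn = kw$dunn, adjustment = kw$adjustment,
      provenance = "events pooled across cells by bin index"),
    spearman_speed = list(
      r = scatter$r, ci = scatter$ci, p_value = scatter$p_value,
      n = scatter$n, undefined = scatter$undefined,
      ci_method = scatter$ci_method,
      provenance = "pooled full scatter"),
    percent_static_overall = 100 *
      mean(classify_static(binned, threshold) == "static")
  )
  if (!is.null(size_cor))
    report$spearman_size <- list(r = size_cor$r, ci = size_cor$ci,
                                 p_value = size_cor$p_value, n = size_cor$n,
                                 undefined = size_cor$undefined,
                                 provenance = "pooled full scatter")
  if (!is.null(norm_block)) report$normalized_channels <- norm_block
  jsonlite::write_json(report, paste0(out_prefix, "_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  utils::write.csv(summaries, paste0(out_prefix, "_bins.csv"),
                   row.names = FALSE)
  message("cli_analyze: ", nrow(binned), " events, threshold ",
          signif(threshold$value, 4), " um/s (", threshold$source, ")")
  invisible(report)
}

#' Measure how many ground-truth links a tracking run recovered
#'
#' A ground-truth frame-to-frame link (particle p, frames t -> t+1) counts
#' as recovered when some track has observations within `match_radius` of
#' p's true position at both t and t+1 (the observations are necessarily
#' consecutive in the track). One observation may cover several ground-truth
#' particles: touching particles are deliberately reported as a single
#' merged component by the detector, and that component's track represents
#' the motion of each of them, so charging the linker for the merge would
#' conflate the two stages. The radius is tight (default 0.3 um, well below
#' the typical nearest-neighbour spacing) so unrelated tracks do not count.
#'
#' @param tracks track table (use `min_track_length = 2` to assess the
#'   linker itself, before the length filter).
#' @param truth ground-truth table from [simulate_ground_truth()].
#' @param match_radius um, observation-to-truth match radius (default 0.3).
#' @return list: `n_links` (ground-truth frame pairs), `n_recovered`,
#'   `recovery` (fraction).
#' @export
evaluate_link_recovery <- function(tracks, truth, match_radius = 0.3) {
  frames <- sort(unique(truth$frame))
  r2 <- match_radius^2
  # per frame: list over ground-truth particles of track ids within radius
  near <- lapply(frames, function(f) {
    gt <- truth[truth$frame == f, ]
    det <- tracks[tracks$frame == f, ]
    out <- lapply(seq_len(nrow(gt)), function(k) integer())
    if (nrow(det)) {
      d2 <- outer(gt$x_um, det$x_um, `-`)^2 + outer(gt$y_um, det$y_um, `-`)^2
      out <- lapply(seq_len(nrow(gt)), function(k)
        det$track_id[d2[k, ] <= r2])
    }
    stats::setNames(out, gt$particle_id)
  })
  n_links <- 0L
  n_rec <- 0L
  for (i in seq_len(length(frames) - 1L)) {
    a <- near[[i]]; b <- near[[i + 1L]]
    common <- intersect(names(a), names(b))
    n_links <- n_links + length(common)
    n_rec <- n_rec + sum(vapply(common, function(p)
      length(intersect(a[[p]], b[[p]])) > 0, logical(1)))
  }
  list(n_links = n_links, n_recovered = n_rec,
       recovery = if (n_links) n_rec / n_links else NA_real_)
}
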