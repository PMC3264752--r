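#' @title Gated optimal frame-to-frame linking and track assembly
#' @name track-module
#' @description Detections in consecutive frames are linked by a globally
#'   optimal gated assignment: among all one-to-one partial matchings whose
#'   every pair lies within the gating distance, the matching of maximal
#'   cardinality and, among those, minimal total squared displacement is
#'   chosen. Chained over all frame pairs this yields tracks; tracks shorter
#'   than a minimum length (default 10 frames) are discarded.
NULL

# Jonker-Volgenant style LAP solver (shortest augmenting paths with
# potentials), O(n^3). `cost` must be square and finite. Returns the column
# assigned to each row.
.solve_lap <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n)         # row potentials
  v <- numeric(n + 1)     # column potentials, index 1 = virtual column 0
  p <- integer(n + 1)     # p[j + 1]: row currently matched to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used) - 1L          # unused real columns (0-based ids)
      cur <- cost[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free + 1L]
      if (any(upd)) {
        tgt <- (free + 1L)[upd]
        minv[tgt] <- cur[upd]
        way[tgt] <- j0
      }
      sel <- which.min(minv[free + 1L])
      j1 <- free[sel]
      delta <- minv[j1 + 1L]
      usedc <- which(used)
      u[p[usedc]] <- u[p[usedc]] + delta
      v[usedc] <- v[usedc] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) assign[p[j + 1L]] <- j
  assign
}

#' Link two frames of observations by gated optimal assignment
#'
#' Computes the one-to-one partial matching between the observations of
#' frame t and frame t+1 that (a) only pairs observations whose centroid
#' displacement is at most `max_displacement`, (b) has maximal cardinality
#' among gated matchings, and (c) minimizes the total squared displacement
#' among those. Ties between equal-cost optimal matchings are broken towards
#' lexicographically smallest index pairs (implemented as an infinitesimal
#' index-rank perturbation of the costs).
#'
#' @param obs_t,obs_t1 observation `data.frame`s with columns `x_um`,
#'   `y_um` (as produced by [detect_particles()]).
#' @param max_displacement gating distance in um (> 0).
#' @return Integer matrix with columns `index_t`, `index_t1` (1-based row
#'   indices into the two inputs); zero rows when nothing can be matched.
#' @export
link_frame_pair <- function(obs_t, obs_t1, max_displacement) {
  if (max_displacement <= 0) stop("max_displacement must be > 0")
  n1 <- nrow(obs_t); n2 <- nrow(obs_t1)
  none <- matrix(integer(), 0, 2,
                 dimnames = list(NULL, c("index_t", "index_t1")))
  if (!n1 || !n2) return(none)
  gate2 <- max_displacement^2
  d2 <- outer(obs_t$x_um, obs_t1$x_um, `-`)^2 +
        outer(obs_t$y_um, obs_t1$y_um, `-`)^2
  feasible <- d2 <= gate2
  if (!any(feasible)) return(none)
  # dummy cost M: skipping a feasible pair wastes 2M > any matched cost sum,
  # so maximal cardinality is always preferred; FORBID >> M blocks gated-out
  # pairs entirely.
  M <- (min(n1, n2) + 1) * gate2
  FORBID <- 2 * M * (n1 + n2 + 1) + 1
  eps <- gate2 * 1e-10 / (n1 * n2 + 1)
  N <- n1 + n2
  cost <- matrix(FORBID, N, N)
  cc <- d2
  cc[!feasible] <- FORBID
  pert <- outer(seq_len(n1) - 1L, seq_len(n2) - 1L,
                function(i, j) i * n2 + j) * eps
  cc[feasible] <- cc[feasible] + pert[feasible]
  cost[seq_len(n1), seq_len(n2)] <- cc
  cost[seq_len(n1), (n2 + 1L):N] <- M
  cost[(n1 + 1L):N, seq_len(n2)] <- M
  cost[(n1 + 1L):N, (n2 + 1L):N] <- 0
  assign <- .solve_lap(cost)
  i <- seq_len(n1)
  j <- assign[i]
  ok <- j <= n2 & feasible[cbind(i, pmin(j, n2))]
  out <- cbind(index_t = i[ok], index_t1 = j[ok])
  out[order(out[, 1]), , drop = FALSE]
}

#' Build tracks from per-frame observations
#'
#' Chains the pairwise matchings of [link_frame_pair()] over consecutive
#' frames. An unmatched observation starts a new track; an unmatched track
#' end terminates (no gap closing, no merge/split handling). Tracks with
#' fewer than `min_track_length` observations are discarded and the count is
#' reported. Track ids are assigned in order of first appearance (frame,
#' then y, then x of the first observation).
#'
#' @param observations observation `data.frame` covering >= 2 frames
#'   (column `frame`, 0-based; a frame absent from the table simply has no
#'   detections).
#' @param max_displacement gating distance in um.
#' @param min_track_length minimum track length in frames (default 10).
#' @param frame_interval seconds per frame, used to fill the `t_s` column.
#' @param cell_id identifier of the image sequence (default `"cell1"`).
#' @return A track table `data.frame` (one row per observation): `cell_id`,
#'   `track_id`, `frame`, `t_s`, `x_um`, `y_um`, `area_um2`, `mfi_ch1`
#'   (and `mfi_ch2` when present), with attribute `n_discarded` giving the
#'   number of tracks removed by the length filter.
#' @export
build_tracks <- function(observations, max_displacement,
                         min_track_length = 10, frame_interval = 1,
                         cell_id = "cell1") {
  if (!nrow(observations) || length(unique(observations$frame)) < 2)
    stop("tracking requires observations spanning at least 2 frames")
  observations <- observations[order(observations$frame), , drop = FALSE]
  rownames(observations) <- NULL
  observations$.row <- seq_len(nrow(observations))
  frames <- seq(min(observations$frame), max(observations$frame))
  if (length(frames) < 2) stop("tracking requires at least 2 frames")
  by_frame <- lapply(frames, function(f)
    observations[observations$frame == f, , drop = FALSE])
  n_tracks <- 0L
  track_rows <- list()           # per track: row indices into `observations`
  row_ids <- lapply(by_frame, function(df) df$.row)
  # active[k] = track id owning observation k of the current frame
  start_track <- function(obs_row) {
    n_tracks <<- n_tracks + 1L
    track_rows[[n_tracks]] <<- obs_row
    n_tracks
  }
  active <- vapply(seq_len(nrow(by_frame[[1]])),
                   function(k) start_track(row_ids[[1]][k]), integer(1))
  for (t in seq_len(length(frames) - 1L)) {
    m <- link_frame_pair(by_frame[[t]], by_frame[[t + 1L]], max_displacement)
    nxt <- integer(nrow(by_frame[[t + 1L]]))
    if (nrow(m)) {
      for (r in seq_len(nrow(m))) {
        tid <- active[m[r, 1]]
        track_rows[[tid]] <- c(track_rows[[tid]], row_ids[[t + 1L]][m[r, 2]])
        nxt[m[r, 2]] <- tid
      }
    }
    for (k in which(nxt == 0L)) nxt[k] <- start_track(row_ids[[t + 1L]][k])
    active <- nxt
  }
  lens <- lengths(track_rows)
  keep <- which(lens >= min_track_length)
  n_disc <- n_tracks - length(keep)
  message("build_tracks: ", length(keep), " track(s) kept, ", n_disc,
          " discarded (< ", min_track_length, " frames)")
  observations$.row <- NULL
  if (!length(keep)) {
    out <- data.frame(cell_id = character(), track_id = integer(),
                      observations[0, , drop = FALSE], t_s = numeric())
  } else {
    # id order: first appearance (frame, then y, x of first observation)
    firsts <- t(vapply(keep, function(tid) {
      o <- observations[track_rows[[tid]][1], ]
      c(o$frame, o$y_um, o$x_um)
    }, numeric(3)))
    keep <- keep[order(firsts[, 1], firsts[, 2], firsts[, 3])]
    pieces <- lapply(seq_along(keep), function(newid) {
      o <- observations[track_rows[[keep[newid]]], , drop = FALSE]
      data.frame(cell_id = cell_id, track_id = newid, o,
                 row.names = NULL)
    })
    out <- do.call(rbind, pieces)
    out$t_s <- out$frame * frame_interval
  }
  front <- c("cell_id", "track_id", "frame", "t_s", "x_um", "y_um",
             "area_um2")
  out <- out[, c(front, setdiff(names(out), front)), drop = FALSE]
  attr(out, "n_discarded") <- n_disc
  out
}

#' Summarize a track table
#'
#' @param tracks track table from [build_tracks()].
#' @return list with `n_tracks`, `n_frame_to_frame_points` (sum over tracks
#'   of length - 1) and `length_histogram` (named table of track lengths).
#' @export
track_census <- function(tracks) {
  if (!nrow(tracks))
    return(list(n_tracks = 0L, n_frame_to_frame_points = 0L,
                length_histogram = table(integer())))
  lens <- as.integer(table(tracks$track_id))
  list(n_tracks = length(lens),
       n_frame_to_frame_points = sum(lens - 1L),
       length_histogram = table(lens))
}

#' Write / read a track table as CSV
#'
#' The track-table CSV is the interchange format between the tracking and
#' statistics stages, so tracks produced by other software can enter the
#' pipeline (required columns: `cell_id`, `track_id`, `frame`, `t_s`,
#' `x_um`, `y_um`, `area_um2`, `mfi_ch1` and optionally `mfi_ch2`).
#'
#' @param tracks track table `data.frame`.
#' @param path CSV path.
#' @return `write_tracks()`: invisibly the path; `read_tracks()`: the
#'   `data.frame`.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
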