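#' Calibrate the static-speed threshold from a fixed sample
#'
#' A fixed (chemically immobilized) sample contains no genuinely moving
#' organelle, so the maximum event speed observed in it bounds the apparent
#' motion that detection and tracking noise can produce. That maximum is
#' taken as the static threshold: classifying the calibration events against
#' it labels 100% of them static by construction.
#'
#' @param fixed_events event `data.frame` from a fixed-sample recording.
#' @return A `static_threshold` object: `value` (um/s), `source`
#'   (`"fixed_calibration"`), `n_calibration_events`.
#' @seealso [default_static_threshold()] for the 0.05 um/s literature
#'   default used when no calibration recording is available.
#' @export
calibrate_static_threshold <- function(fixed_events) {
  if (is.null(fixed_events) || !nrow(fixed_events))
    stop("calibration requested but the fixed-sample event set is empty")
  structure(list(value = max(fixed_events$speed_um_s),
                 source = "fixed_calibration",
                 n_calibration_events = nrow(fixed_events)),
            class = "static_threshold")
}

#' Default static-speed threshold (0.05 um/s)
#'
#' @return A `static_threshold` with `value = 0.05`, `source = "default"`.
#' @export
default_static_threshold <- function() {
  structure(list(value = 0.05, source = "default",
                 n_calibration_events = 0L),
            class = "static_threshold")
}

#' @export
print.static_threshold <- function(x, ...) {
  cat(sprintf("static threshold: %.4g um/s (source: %s, n = %d)\n",
              x$value, x$source, x$n_calibration_events))
  invisible(x)
}

#' Classify events as static or motile
#'
#' Static iff `speed <= threshold` — the comparison is inclusive so that a
#' sample classified against its own calibrated threshold (the maximum of
#' its speeds) comes out 100% static.
#'
#' @param events event `data.frame`.
#' @param threshold a `static_threshold` or a positive number (um/s).
#' @return character vector, `"static"` or `"motile"`, one per event.
#' @export
classify_static <- function(events, threshold) {
  thr <- if (inherits(threshold, "static_threshold")) threshold$value
         else threshold
  if (!is.numeric(thr) || thr <= 0) stop("threshold must be > 0")
  ifelse(events$speed_um_s <= thr, "static", "motile")
}

#' Bin events into equal-occupancy groups per cell
#'
#' Within each cell independently, events are stably sorted ascending by the
#' binning variable and the event of 0-based sorted rank r (of N) goes to
#' bin `floor(r * n_bins / N)`. Bin sizes therefore differ by at most one
#' and sum to N; binning per cell compensates for expression-level
#' differences between cells.
#'
#' @param events event `data.frame`.
#' @param variable column to bin by (e.g. `"mmfi_ch1"`, `"ratio"`,
#'   `"size_um2"`). Rows with `NA` in the variable are dropped (count
#'   reported).
#' @param n_bins number of bins (default 10 — deciles).
#' @return `events` (NA rows removed) with an added 0-based `bin` column
#'   and attributes `binning_variable`, `n_bins`.
#' @export
bin_by_variable <- function(events, variable, n_bins = 10) {
  if (!variable %in% names(events))
    stop("binning variable '", variable, "' missing from events")
  if (n_bins < 2) stop("n_bins must be >= 2")
  v <- events[[variable]]
  if (any(is.na(v))) {
    message("bin_by_variable: dropping ", sum(is.na(v)),
            " event(s) with NA ", variable)
    events <- events[!is.na(v), , drop = FALSE]
  }
  cells <- unique(events$cell_id)
  events$bin <- NA_integer_
  for (cl in cells) {
    sel <- which(events$cell_id == cl)
    n <- length(sel)
    if (n < n_bins)
      stop("cell '", cl, "' has only ", n, " events; at least ", n_bins,
           " are required for binning")
    ord <- order(events[[variable]][sel])   # stable: ties keep input order
    bins <- as.integer(floor((seq_len(n) - 1) * n_bins / n))
    events$bin[sel[ord]] <- bins
  }
  attr(events, "binning_variable") <- variable
  attr(events, "n_bins") <- as.integer(n_bins)
  events
}

#' Per-cell per-bin speed summaries
#'
#' For every cell and bin: the median of all event speeds, the percentage of
#' static events, and the median speed of motile events only (flagged
#' undefined — `NA` with `motile_median_defined = FALSE` — when the bin has
#' no motile event).
#'
#' @param binned events with a `bin` column from [bin_by_variable()].
#' @param threshold a `static_threshold` or number (um/s).
#' @return `data.frame` with one row per cell x bin: `cell_id`, `bin`,
#'   `n_total`, `n_motile`, `percent_static`, `median_speed_total`,
#'   `median_speed_motile`, `motile_median_defined`.
#' @export
summarize_bins <- function(binned, threshold) {
  if (!"bin" %in% names(binned)) stop("events must be binned first")
  lab <- classify_static(binned, threshold)
  keys <- unique(binned[, c("cell_id", "bin")])
  keys <- keys[order(keys$cell_id, keys$bin), ]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- binned$cell_id == keys$cell_id[i] & binned$bin == keys$bin[i]
    sp <- binned$speed_um_s[sel]
    mot <- lab[sel] == "motile"
    data.frame(
      cell_id = keys$cell_id[i],
      bin = keys$bin[i],
      n_total = length(sp),
      n_motile = sum(mot),
      percent_static = 100 * mean(!mot),
      median_speed_total = stats::median(sp),
      median_speed_motile = if (any(mot)) stats::median(sp[mot]) else NA_real_,
      motile_median_defined = any(mot)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-cell bin summaries across cells
#'
#' For each bin index: the mean and SEM (sample SD / sqrt(n_cells)) of the
#' per-cell bin medians, of the per-cell motile-only medians (cells whose
#' bin has no motile event are excluded from that aggregate), and of the
#' per-cell percent-static values. With a single cell the means are
#' returned and the SEMs are flagged undefined (`NA`).
#'
#' @param summaries output of [summarize_bins()] (possibly several cells).
#' @return `data.frame` with one row per bin: means, SEMs and the number of
#'   contributing cells for each quantity. Values carry provenance
#'   "mean of per-cell medians", distinct from pooled-event statistics.
#' @export
aggregate_cells <- function(summaries) {
  if (!nrow(summaries)) stop("no summaries to aggregate")
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                     else NA_real_
  bins <- sort(unique(summaries$bin))
  rows <- lapply(bins, function(b) {
    s <- summaries[summaries$bin == b, ]
    mm <- s$median_speed_motile[s$motile_median_defined]
    data.frame(
      bin = b,
      n_cells = nrow(s),
      mean_median_speed_total = mean(s$median_speed_total),
      sem_median_speed_total = sem(s$median_speed_total),
      mean_median_speed_motile = if (length(mm)) mean(mm) else NA_real_,
      sem_median_speed_motile = sem(mm),
      n_cells_motile = length(mm),
      mean_percent_static = mean(s$percent_static),
      sem_percent_static = sem(s$percent_static)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "provenance") <- "mean of per-cell medians (SEM = SD/sqrt(n_cells))"
  out
}

# Tie-corrected Kruskal-Wallis H from a pooled sample and group labels.
.kw_h <- function(x, g) {
  N <- length(x)
  r <- rank(x)
  rs <- tapply(r, g, sum)
  n <- tapply(r, g, length)
  h <- 12 / (N * (N + 1)) * sum(rs^2 / n) - 3 * (N + 1)
  ties <- table(x)
  tiecor <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (tiecor == 0) return(0)   # every value identical
  h / tiecor
}

#' Kruskal-Wallis test with Dunn's post test
#'
#' Tie-corrected Kruskal-Wallis H over k groups with a chi-square p value
#' (df = k - 1), or an exact permutation p (full enumeration of group
#' assignments) when the pooled sample is small (`N <= exact_limit`).
#' Dunn's post test compares every pair of groups on mean ranks of the
#' pooled ranking, with the tie-corrected variance, two-sided normal p
#' values and Bonferroni adjustment over all pairs (the conventional
#' "Dunn's post test"). Significance is reported at the 95% level.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each
#'   non-empty). For the binning workflow these are the events of each bin
#'   pooled across cells by bin index.
#' @param exact use exact permutation p for H? Default `NULL`: exact when
#'   the pooled N is at most `exact_limit`.
#' @param exact_limit largest pooled N for automatic exact enumeration
#'   (default 10).
#' @return A `stat_report` list: `method`, `statistic` (H), `df`, `p_value`,
#'   `p_method`, `n` per group, and `dunn` — a `data.frame` of pairwise
#'   comparisons (`group_a`, `group_b`, `z`, `p`, `p_adj`, `significant`)
#'   with Bonferroni-adjusted p values.
#' @export
kruskal_wallis_dunn <- function(groups, exact = NULL, exact_limit = 10) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(!lengths(groups))) stop("every group must contain at least 1 value")
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  N <- length(x)
  k <- length(groups)
  h <- .kw_h(x, g)
  if (is.null(exact)) exact <- N <= exact_limit
  if (length(unique(x)) == 1) {
    p <- 1
    p_method <- "degenerate (all values identical)"
  } else if (exact) {
    p <- .kw_exact_p(x, lengths(groups), h)
    p_method <- "exact permutation enumeration"
  } else {
    p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)
    p_method <- "chi-square approximation"
  }
  # Dunn pairwise z on mean pooled ranks with tie-corrected variance
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  sigma2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  npair <- ncol(pairs)
  dunn <- data.frame(
    group_a = pairs[1, ], group_b = pairs[2, ],
    z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(npair)) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(sigma2 * (1 / n[[a]] + 1 / n[[b]]))
    z <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    dunn$z[i] <- z
    dunn$p[i] <- 2 * stats::pnorm(-abs(z))
  }
  dunn$p_adj <- pmin(1, dunn$p * npair)   # Bonferroni over all pairs
  dunn$significant <- dunn$p_adj < 0.05
  structure(list(method = "Kruskal-Wallis with Dunn's post test",
                 statistic = h, df = k - 1, p_value = p,
                 p_method = p_method,
                 n = as.integer(lengths(groups)),
                 adjustment = "bonferroni",
                 dunn = dunn),
            class = "stat_report")
}

# Exact permutation p for Kruskal-Wallis: enumerate every split of the
# pooled values into the observed group sizes and count splits with
# H >= H_obs. Feasible for the small-N fixtures it is meant for.
.kw_exact_p <- function(x, sizes, h_obs) {
  N <- length(x)
  idx_all <- seq_len(N)
  count <- 0L
  total <- 0L
  recurse <- function(remaining, gi, assign) {
    if (gi > length(sizes)) {
      g <- factor(assign, levels = seq_along(sizes))
      h <- .kw_h(x, g)
      total <<- total + 1L
      if (h >= h_obs - 1e-9) count <<- count + 1L
      return(invisible())
    }
    picks <- utils::combn(remaining, sizes[gi], simplify = FALSE)
    # fix the smallest remaining index into the current group half the time?
    for (pk in picks) {
      a2 <- assign; a2[pk] <- gi
      recurse(setdiff(remaining, pk), gi + 1L, a2)
    }
  }
  recurse(idx_all, 1L, integer(N))
  count / total
}

#' @export
print.stat_report <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$statistic))
    cat(sprintf("  statistic = %.5g", x$statistic),
        if (!is.null(x$df)) sprintf(", df = %d", x$df) else "", "\n", sep = "")
  if (!is.null(x$r)) {
    if (isTRUE(x$undefined)) cat("  r undefined (zero variance)\n")
    else cat(sprintf("  r = %.4f, 95%% CI [%.4f, %.4f]\n",
                     x$r, x$ci[1], x$ci[2]))
  }
  if (!is.null(x$p_value)) cat(sprintf("  p = %.4g (%s)\n", x$p_value,
                                       x$p_method %||% ""))
  if (!is.null(x$dunn)) {
    cat("  Dunn post test (", x$adjustment, "-adjusted):\n", sep = "")
    print(x$dunn, row.names = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mann-Whitney (Wilcoxon rank-sum) test between two full data sets
#'
#' Two-sided test; exact for small samples without ties, normal
#' approximation with tie and continuity correction otherwise (delegated to
#' [stats::wilcox.test()]).
#'
#' @param sample_a,sample_b numeric vectors (non-empty).
#' @return A `stat_report` with `statistic` (U, for `sample_a`), `p_value`
#'   and per-sample `n`.
#' @export
mann_whitney <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b))
  structure(list(method = "Mann-Whitney U test (two-sided)",
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 p_method = if (grepl("exact", wt$method, ignore.case = TRUE))
                   "exact" else "normal approximation with tie/continuity correction",
                 n = c(length(sample_a), length(sample_b))),
            class = "stat_report")
}

#' Spearman rank correlation with a 95% confidence interval
#'
#' Tie-corrected Spearman r (Pearson correlation of midranks), two-sided p
#' via the t approximation with n - 2 degrees of freedom, and a 95% CI from
#' the Fisher z transform with variance 1.06 / (n - 3).
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return A `stat_report` with `r`, `ci` (length 2), `p_value`, `n` and an
#'   `undefined` flag (TRUE when either variable has zero variance).
#' @export
spearman_with_ci <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("Spearman correlation requires n >= 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(method = "Spearman rank correlation",
                          r = NA_real_, ci = c(NA_real_, NA_real_),
                          p_value = NA_real_, n = n, undefined = TRUE,
                          ci_method = "Fisher z, var 1.06/(n-3)"),
                     class = "stat_report"))
  r <- stats::cor(x, y, method = "spearman")
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  if (n > 3) {
    z <- atanh(max(min(r, 1 - 1e-15), -1 + 1e-15))
    se <- sqrt(1.06 / (n - 3))
    ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  structure(list(method = "Spearman rank correlation",
                 r = r, ci = ci, p_value = p, n = n, undefined = FALSE,
                 ci_method = "Fisher z, var 1.06/(n-3)"),
            class = "stat_report")
}

#' Correlate particle size with MMFI
#'
#' Spearman rank correlation (with CI) between an MMFI channel and the
#' event's particle size.
#'
#' @param events event `data.frame`.
#' @param channel MMFI column (default `"mmfi_ch1"`).
#' @return A `stat_report`, see [spearman_with_ci()].
#' @export
size_vs_mmfi <- function(events, channel = "mmfi_ch1") {
  spearman_with_ci(events[[channel]], events$size_um2)
}

#' Five-number speed distribution summary
#'
#' Median, 25th/75th and 5th/95th percentiles of event speed, using the
#' linear-interpolation percentile definition (R quantile type 7, recorded
#' in the output).
#'
#' @param events event `data.frame` (or a numeric vector of speeds).
#' @return Named list: `p05`, `p25`, `median`, `p75`, `p95`, `n`,
#'   `percentile_definition`.
#' @export
distribution_summary <- function(events) {
  sp <- if (is.data.frame(events)) events$speed_um_s else events
  if (!length(sp)) stop("at least one event required")
  q <- stats::quantile(sp, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7,
                       names = FALSE)
  list(p05 = q[1], p25 = q[2], median = q[3], p75 = q[4], p95 = q[5],
       n = length(sp),
       percentile_definition = "linear interpolation (R quantile type 7)")
}
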