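test_that("threshold calibration takes the maximum fixed-sample speed", {
  ev <- make_events(c(0.01, 0.02, 0.05))
  thr <- calibrate_static_threshold(ev)
  expect_equal(thr$value, 0.05)
  expect_equal(thr$source, "fixed_calibration")
  expect_equal(thr$n_calibration_events, 3L)
  one <- calibrate_static_threshold(make_events(0.013))
  expect_equal(one$value, 0.013)
  expect_error(calibrate_static_threshold(make_events(numeric())),
               "empty")
  def <- default_static_threshold()
  expect_equal(def$value, 0.05)
  expect_equal(def$source, "default")
})

test_that("classification is inclusive at the threshold", {
  ev <- make_events(c(0.05, 0.050001, 0.01))
  lab <- classify_static(ev, default_static_threshold())
  expect_equal(lab, c("static", "motile", "static"))
  # a sample classified against its own calibrated max is 100% static
  set.seed(4)
  ev2 <- make_events(runif(50, 0, 0.04))
  thr <- calibrate_static_threshold(ev2)
  expect_true(all(classify_static(ev2, thr) == "static"))
  expect_true(all(classify_static(make_events(c(1, 2)), 0.5) == "motile"))
})

test_that("decile binning matches the rank formula and conserves events", {
  # N = 103: oracle = enumerate floor(10 * r / 103), r = 0..102
  set.seed(6)
  for (N in c(100L, 103L, 10000L)) {
    ev <- make_events(runif(N), mmfi = runif(N))
    b <- bin_by_variable(ev, "mmfi_ch1")
    sizes <- as.integer(table(factor(b$bin, levels = 0:9)))
    oracle_sizes <- as.integer(table(factor(floor(10 * (0:(N - 1)) / N),
                                            levels = 0:9)))
    expect_equal(length(sizes), 10L)
    expect_equal(sum(sizes), N)
    expect_equal(sizes, oracle_sizes)
    expect_lte(max(sizes) - min(sizes), 1L)
    # ordering: every value in bin i <= every value in bin i + 1
    maxs <- tapply(b$mmfi_ch1, b$bin, max)
    mins <- tapply(b$mmfi_ch1, b$bin, min)
    expect_true(all(maxs[-10] <= mins[-1] + 1e-12))
  }
  # 10 distinct values -> one per bin in sorted order
  ev10 <- make_events(rep(0.1, 10), mmfi = sample(10))
  b10 <- bin_by_variable(ev10, "mmfi_ch1")
  expect_equal(b10$bin[order(b10$mmfi_ch1)], 0:9)
  expect_error(bin_by_variable(make_events(rep(0.1, 5)), "mmfi_ch1"),
               "only 5 events")
})

test_that("binning is independent per cell", {
  ev <- rbind(make_events(runif(20), mmfi = runif(20, 0, 1), cell_id = "a"),
              make_events(runif(30), mmfi = runif(30, 100, 200),
                          cell_id = "b"))
  b <- bin_by_variable(ev, "mmfi_ch1")
  for (cl in c("a", "b")) {
    sz <- table(b$bin[b$cell_id == cl])
    expect_equal(length(sz), 10L)
    expect_lte(max(sz) - min(sz), 1)
  }
})

test_that("bin summaries report medians and static percentages", {
  ev <- make_events(c(0, 0, 0.1, 0.3))
  ev$bin <- 0L
  s <- summarize_bins(ev, default_static_threshold())
  expect_equal(s$percent_static, 50)
  expect_equal(s$median_speed_total, 0.05)
  expect_equal(s$median_speed_motile, 0.2)
  expect_equal(s$n_motile, 2L)
  allstatic <- make_events(c(0.01, 0.02)); allstatic$bin <- 0L
  s2 <- summarize_bins(allstatic, default_static_threshold())
  expect_equal(s2$percent_static, 100)
  expect_false(s2$motile_median_defined)
  expect_true(is.na(s2$median_speed_motile))
})

test_that("cross-cell aggregation is mean and SEM of per-cell medians", {
  s <- data.frame(cell_id = c("a", "b"), bin = 0L, n_total = 10L,
                  n_motile = 5L, percent_static = c(50, 70),
                  median_speed_total = c(0.03, 0.05),
                  median_speed_motile = c(0.1, 0.2),
                  motile_median_defined = TRUE)
  agg <- aggregate_cells(s)
  expect_equal(agg$mean_median_speed_total, 0.04)
  expect_equal(agg$sem_median_speed_total, sd(c(0.03, 0.05)) / sqrt(2))
  expect_equal(agg$sem_median_speed_total, 0.01, tolerance = 1e-12)
  one <- aggregate_cells(s[1, ])
  expect_true(is.na(one$sem_median_speed_total))
  ident <- aggregate_cells(rbind(s[1, ], s[1, ]))
  expect_equal(ident$sem_median_speed_total, 0)
})

test_that("Kruskal-Wallis H matches the rank-sum formula, Dunn the z formula", {
  groups <- list(a = c(1.2, 3.4, 2.2, 5.0),
                 b = c(2.2, 4.1, 6.3, 1.1),
                 c = c(7.2, 5.5, 2.2, 8.8))
  rep_ <- kruskal_wallis_dunn(groups, exact = FALSE)
  expect_equal(rep_$statistic, oracle_kw_h(groups), tolerance = 1e-12)
  # base R as a second, independent route
  kw <- kruskal.test(unlist(groups),
                     rep(names(groups), lengths(groups)))
  expect_equal(rep_$statistic, unname(kw$statistic), tolerance = 1e-12)
  expect_equal(rep_$p_value, kw$p.value, tolerance = 1e-12)
  for (i in seq_len(nrow(rep_$dunn))) {
    z_oracle <- oracle_dunn_z(groups, rep_$dunn$group_a[i],
                              rep_$dunn$group_b[i])
    expect_equal(rep_$dunn$z[i], unname(z_oracle), tolerance = 1e-12)
  }
  expect_equal(rep_$dunn$p_adj, pmin(1, rep_$dunn$p * 3))
})

test_that("identical groups give H = 0 and no significant pairs", {
  g <- list(a = c(2, 2, 2), b = c(2, 2), c = c(2, 2, 2))
  rep_ <- kruskal_wallis_dunn(g)
  expect_equal(rep_$statistic, 0)
  expect_equal(rep_$p_value, 1)
  expect_false(any(rep_$dunn$significant))
})

test_that("exact Kruskal-Wallis p agrees with permutation sampling", {
  groups <- list(a = c(1, 5, 8), b = c(2, 7, 9), c = c(3, 4, 6))
  rep_ <- kruskal_wallis_dunn(groups)   # N = 9 -> exact enumeration
  expect_equal(rep_$p_method, "exact permutation enumeration")
  set.seed(8)
  p_mc <- oracle_kw_mc_p(groups, B = 20000)
  expect_lt(abs(rep_$p_value - p_mc),
            3 * sqrt(p_mc * (1 - p_mc) / 20000) + 1e-6)
})

test_that("Mann-Whitney matches exact enumeration and is symmetric", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  r1 <- mann_whitney(a, b)
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p_value, 0.1)
  expect_equal(r1$p_value, oracle_mw_exact_p(a, b))
  r2 <- mann_whitney(b, a)
  expect_equal(r2$p_value, r1$p_value)
  expect_equal(r2$statistic, length(a) * length(b) - r1$statistic)
  same <- suppressWarnings(mann_whitney(c(1, 2, 3), c(1, 2, 3)))
  expect_gt(same$p_value, 0.95)
  expect_error(mann_whitney(numeric(), 1), "non-empty")
})

test_that("Spearman handles monotone data, ties, CIs and degeneracy", {
  r1 <- spearman_with_ci(1:10, 10:1)
  expect_equal(r1$r, -1)
  expect_lt(r1$p_value, 1e-6)
  # with a tie: compare against the midrank covariance formula
  x <- c(1, 2, 3, 4, 5); y <- c(2, 2, 3, 5, 4)
  r2 <- spearman_with_ci(x, y)
  expect_equal(r2$r, oracle_spearman_r(x, y), tolerance = 1e-12)
  expect_true(r2$ci[1] <= r2$r && r2$r <= r2$ci[2])
  # published-scale check of the Fisher-z CI with variance 1.06/(n-3)
  z <- atanh(r2$r); se <- sqrt(1.06 / (length(x) - 3))
  expect_equal(r2$ci, tanh(z + c(-1, 1) * qnorm(0.975) * se))
  expect_error(spearman_with_ci(1:2, 2:1), "n >= 3")
  deg <- spearman_with_ci(rep(1, 5), 1:5)
  expect_true(deg$undefined)
  expect_true(is.na(deg$r))
})

test_that("size_vs_mmfi delegates to the Spearman machinery", {
  ev <- make_events(rep(0.1, 30), mmfi = 1:30)
  ev$size_um2 <- 31 - (1:30)   # strictly decreasing in mmfi
  r <- size_vs_mmfi(ev)
  expect_equal(r$r, -1)
  evc <- make_events(rep(0.1, 10), mmfi = 1:10)
  evc$size_um2 <- 5
  expect_true(size_vs_mmfi(evc)$undefined)
})

test_that("the five-number summary uses linear interpolation", {
  s <- distribution_summary(make_events(1:100))
  expect_equal(s$median, 50.5)
  expect_equal(s$p25, quantile(1:100, 0.25, names = FALSE))
  one <- distribution_summary(make_events(0.2))
  expect_equal(unlist(one[c("p05", "p25", "median", "p75", "p95")]),
               rep(0.2, 5), ignore_attr = TRUE)
  set.seed(10)
  v <- runif(20)
  s20 <- distribution_summary(v)
  # sort-and-interpolate oracle for type-7 percentiles
  o <- function(p) { h <- (20 - 1) * p + 1
    sv <- sort(v); sv[floor(h)] + (h - floor(h)) *
      (sv[ceiling(h)] - sv[floor(h)]) }
  expect_equal(s20$p05, o(0.05))
  expect_equal(s20$p95, o(0.95))
  expect_error(distribution_summary(numeric()), "at least one")
})
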