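test_that("identical seeds give bit-identical movies and ground truth", {
  cfg <- simulation_config(n_particles = 10, n_frames = 10,
                           field_size = c(8, 8), seed = 11)
  a <- simulate_movie(cfg)
  b <- simulate_movie(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$stack$pixels, b$stack$pixels)
})

test_that("default configuration carries the standard acquisition metadata", {
  cfg <- simulation_config(seed = 1)
  expect_equal(cfg$n_frames, 100L)
  expect_equal(cfg$frame_interval, 1.0)
  expect_equal(cfg$pixel_size, 1 / 16)
  sim <- simulate_movie(simulation_config(n_particles = 3, seed = 1))
  expect_equal(dim(sim$stack$pixels)[4], 100L)
  expect_equal(sim$stack$pixel_size, 1 / 16)
  expect_equal(sim$stack$frame_interval, 1.0)
})

test_that("motile_fraction = 0 yields only static states with bounded jitter", {
  cfg <- simulation_config(n_particles = 15, n_frames = 40,
                           field_size = c(10, 10), motile_fraction = 0,
                           seed = 3)
  gt <- simulate_ground_truth(cfg)
  expect_true(all(gt$state == "static"))
  disp <- do.call(rbind, lapply(split(gt, gt$particle_id), function(g) {
    g <- g[order(g$frame), ]
    cbind(diff(g$x_um), diff(g$y_um))
  }))
  # per-axis displacement is a difference-free N(0, sigma) step here, so
  # the Euclidean step is Rayleigh(sigma * sqrt(2)) -- tail bound at 4 sigma
  # of the step distribution
  step <- sqrt(rowSums(disp^2))
  expect_lt(max(step), 4 * sqrt(2) * cfg$static_jitter_sigma * 1.5)
})

test_that("fixed-sample simulation is the motile_fraction = 0 special case", {
  cfg <- simulation_config(n_particles = 5, n_frames = 10,
                           field_size = c(8, 8), motile_fraction = 0.8,
                           seed = 5)
  fx <- simulate_fixed_sample(cfg)
  expect_true(all(fx$truth$state == "static"))
  # tiny config: exactly one ground-truth displacement record
  tiny <- simulate_fixed_sample(simulation_config(
    n_particles = 1, n_frames = 2, field_size = c(5, 5), seed = 5))
  expect_equal(nrow(tiny$truth), 2L)  # one particle, two frames = one step
})

test_that("strong negative coupling makes high-label particles less motile", {
  cfg <- simulation_config(n_particles = 200, n_frames = 50,
                           field_size = c(45, 45),
                           coupling_sign = "negative",
                           coupling_strength = 1, seed = 17)
  gt <- simulate_ground_truth(cfg)
  frac_motile <- tapply(gt$state == "motile", gt$particle_id, mean)
  label <- tapply(gt$label_ch1, gt$particle_id, unique)
  ct <- suppressWarnings(
    cor.test(label, frac_motile, method = "spearman"))
  expect_lt(unname(ct$estimate), 0)
  expect_lt(ct$p.value, 0.001)
})

test_that("zero coupling leaves label and motility uncorrelated", {
  cfg <- simulation_config(n_particles = 200, n_frames = 50,
                           field_size = c(45, 45),
                           coupling_sign = "negative",
                           coupling_strength = 0, seed = 23)
  gt <- simulate_ground_truth(cfg)
  frac_motile <- tapply(gt$state == "motile", gt$particle_id, mean)
  label <- tapply(gt$label_ch1, gt$particle_id, unique)
  r <- suppressWarnings(cor(label, frac_motile, method = "spearman"))
  expect_lt(abs(r), 3 / sqrt(length(label)))
})

test_that("motile ground-truth speeds respect the configured range", {
  cfg <- simulation_config(n_particles = 40, n_frames = 60,
                           field_size = c(20, 20), motile_fraction = 1,
                           seed = 31)
  gt <- simulate_ground_truth(cfg)
  steps <- do.call(rbind, lapply(split(gt, gt$particle_id), function(g) {
    g <- g[order(g$frame), ]
    data.frame(speed = sqrt(diff(g$x_um)^2 + diff(g$y_um)^2) /
                 cfg$frame_interval,
               x = head(g$x_um, -1), y = head(g$y_um, -1))
  }))
  # away from reflections the step length is run speed plus jitter
  interior <- steps$x > 1 & steps$x < 19 & steps$y > 1 & steps$y < 19
  jit <- 4 * sqrt(2) * cfg$static_jitter_sigma
  expect_gt(mean(steps$speed[interior] >=
                   cfg$motile_speed_range[1] - jit &
                 steps$speed[interior] <=
                   cfg$motile_speed_range[2] + jit), 0.99)
})

test_that("particles stay inside the field and overcrowding errors", {
  cfg <- simulation_config(n_particles = 30, n_frames = 80,
                           field_size = c(12, 12), motile_fraction = 0.5,
                           seed = 37)
  gt <- simulate_ground_truth(cfg)
  expect_true(all(gt$x_um >= 0 & gt$x_um <= 12))
  expect_true(all(gt$y_um >= 0 & gt$y_um <= 12))
  expect_error(
    simulate_ground_truth(simulation_config(
      n_particles = 60, n_frames = 2, field_size = c(2, 2), seed = 1)),
    "field too small")
})

test_that("movies round-trip through TIFF + sidecar up to quantization", {
  cfg <- simulation_config(n_particles = 5, n_frames = 4,
                           field_size = c(5, 5), n_channels = 2, seed = 41)
  sim <- simulate_movie(cfg)
  tif <- withr::local_tempfile(fileext = ".tif")
  write_movie(sim$stack, tif)
  back <- read_movie(tif)
  expect_equal(back$channel_roles, sim$stack$channel_roles)
  expect_equal(back$pixel_size, sim$stack$pixel_size)
  expect_equal(back$frame_interval, sim$stack$frame_interval)
  expect_lt(max(abs(back$pixels - sim$stack$pixels)),
            max(sim$stack$pixels) / 65535 * 1.01)
  expect_error(read_movie(withr::local_tempfile(fileext = ".tif")),
               "sidecar")
})
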