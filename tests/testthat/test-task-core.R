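test_that("default schedule has the full design's counts and constraints", {
  sched <- generate_schedule(seed = 7)
  expect_equal(nrow(sched), 1080)
  expect_equal(sum(sched$trial_type == "estimation"), 320)
  counts <- dplyr::count(sched, effort, reward)
  expect_true(all(counts$n == 270))

  by_block <- split(sched, sched$block)
  expect_length(by_block, 40)
  for (b in by_block) {
    expect_equal(b$trial_type[1:3], rep("basic", 3))
    expect_equal(sum(b$trial_type == "estimation"), 8)
    est_pos <- which(b$trial_type == "estimation")
    expect_true(all(diff(est_pos) > 1))
  }
  # ten blocks per effort-by-reward cell
  block_cond <- dplyr::distinct(sched, block, effort, reward)
  expect_true(all(dplyr::count(block_cond, effort, reward)$n == 10))
})

test_that("schedules are seed-reproducible and seed-sensitive", {
  expect_identical(generate_schedule(seed = 3), generate_schedule(seed = 3))
  a <- generate_schedule(seed = 3)
  b <- generate_schedule(seed = 4)
  expect_false(identical(a$trial_type, b$trial_type) &&
                 identical(a$effort, b$effort))
})

test_that("degenerate and unsatisfiable schedules are handled", {
  cfg <- task_config(estimation_per_block = 0, basic_per_block = 27)
  all_basic <- generate_schedule(cfg, seed = 1)
  expect_true(all(all_basic$trial_type == "basic"))
  expect_equal(nrow(all_basic), 1080)

  # 13 estimation among 24 post-lead slots cannot avoid adjacency
  bad <- task_config(estimation_per_block = 13, basic_per_block = 14)
  expect_error(generate_schedule(bad, seed = 1), "unsatisfiable")
})

test_that("force-position mapping hits its calibration anchors", {
  expect_equal(force_to_position(0, "low"), 128)
  expect_equal(force_to_position(0, "high"), 128)
  expect_equal(force_to_position(0.35, "low"), 512)
  expect_equal(force_to_position(0.65, "high"), 896)
  expect_error(force_to_position(-0.1, "low"), "non-negative")
  expect_error(force_to_position(0.5, "medium"), "effort")
})

test_that("force-position mapping is strictly monotone and invertible", {
  f <- seq(0.01, 0.55, by = 0.01)   # below the clipping region
  for (eff in c("low", "high")) {
    x <- force_to_position(f, eff)
    expect_true(all(diff(x) > 0))
    back <- position_to_force(x, eff)
    expect_equal(back, f, tolerance = 1e-9)
  }
  # clipping at the screen edge
  expect_equal(force_to_position(5, "low"), 1280)
})

test_that("force response is the mean of the [2, 2.5) s window", {
  const <- force_trace(rep(5, 180))
  expect_equal(extract_force_response(const, 10), 0.5)

  step <- force_trace(c(rep(0, 120), rep(8, 60)))
  expect_equal(extract_force_response(step, 8), 1.0)

  ramp <- force_trace(seq(0, 10, length.out = 180))
  # direct arithmetic oracle: samples 121..150 at 60 Hz
  oracle <- mean(ramp$samples[121:150]) / 12
  expect_equal(extract_force_response(ramp, 12), oracle, tolerance = 1e-12)

  expect_error(extract_force_response(force_trace(rep(1, 60)), 1), "2.5 s")
})

test_that("maximum-force calibration picks the steadiest 5-s window", {
  const3 <- lapply(c(8, 10, 9), function(v) force_trace(rep(v, 600)))
  expect_equal(calibrate_max_force(const3), 10)

  set.seed(1)
  noisy_then_flat <- force_trace(c(stats::runif(300, 2, 12), rep(7, 300)))
  expect_equal(calibrate_max_force(list(noisy_then_flat,
                                        force_trace(rep(1, 600)),
                                        force_trace(rep(1, 600)))), 7)

  # brute-force window-scan oracle on random traces
  set.seed(2)
  traces <- lapply(1:3, function(i) force_trace(pmax(0, rnorm(620, 10, 2))))
  oracle <- max(vapply(traces, function(tr) {
    wlen <- 300
    offs <- 1:(length(tr$samples) - wlen + 1)
    stats_ <- vapply(offs, function(o) {
      win <- tr$samples[o:(o + wlen - 1)]
      c(stats::var(win), mean(win))
    }, numeric(2))
    stats_[2, which.min(stats_[1, ])]
  }, 0))
  expect_equal(calibrate_max_force(traces), oracle, tolerance = 1e-12)

  expect_error(calibrate_max_force(list(force_trace(rep(1, 600)))), "three")
  expect_error(calibrate_max_force(lapply(1:3, function(i)
    force_trace(rep(1, 60)))), "10 s")
})

test_that("reward decreases linearly to zero and never goes negative", {
  expect_equal(reward_points(0, "low"), 1)
  expect_equal(reward_points(192, "low"), 0)   # 0.15 * 1280
  expect_equal(reward_points(96, "low"), 0.5)
  expect_equal(reward_points(-96, "low"), 0.5)
  expect_equal(reward_points(384, "high"), 0)  # 0.30 * 1280
  expect_equal(reward_points(500, "high"), 0)

  err <- seq(-600, 600, by = 1)
  for (eff in c("low", "high")) {
    r <- reward_points(err, eff)
    expect_true(all(r >= 0))
    # non-increasing in |error| and continuous (small steps, small jumps)
    pos <- r[err >= 0]
    expect_true(all(diff(pos) <= 0))
    expect_true(max(abs(diff(r))) < 0.01)
  }
})

test_that("task configs validate their invariants and round-trip to YAML", {
  expect_error(task_config(basic_per_block = 20), "trials_per_block")
  expect_error(task_config(n_blocks = 39), "blocks_per_condition")
  expect_error(task_config(close_target_x_px = 100), "start")

  cfg <- task_config(blocks_per_condition = 5, n_blocks = 20)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_task_config(cfg, path)
  expect_equal(read_task_config(path), cfg)

  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(unknown_field = 1), bad)
  expect_error(read_task_config(bad), "unknown")
})
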