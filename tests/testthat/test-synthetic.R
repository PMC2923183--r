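test_that("Brownian steps have the stated variance and determinism", {
  scene <- simulate_brownian(50, D = 0.022, n_frames = 201, height = 600,
                             width = 600, pixel_size_um = 0.1,
                             frame_interval_s = 0.85, seed = 3,
                             margin_px = 250)
  steps <- unlist(lapply(scene$particles, function(p) c(diff(p$row), diff(p$col))))
  want <- 2 * 0.022 * 0.85 / 0.1^2          # px^2
  expect_lt(abs(var(steps) - want) / want, 0.05)   # 2e4 events

  again <- simulate_brownian(50, D = 0.022, n_frames = 201, height = 600,
                             width = 600, pixel_size_um = 0.1,
                             frame_interval_s = 0.85, seed = 3,
                             margin_px = 250)
  expect_identical(scene$particles, again$particles)

  tiny <- simulate_brownian(3, D = 1e-12, n_frames = 50, height = 64,
                            width = 64, seed = 1)
  for (p in tiny$particles) {
    expect_lt(diff(range(p$row)), 1e-3)
    expect_lt(diff(range(p$col)), 1e-3)
  }
})

test_that("positions stay in bounds under reflection", {
  scene <- simulate_brownian(10, D = 5, n_frames = 100, height = 32, width = 32,
                             pixel_size_um = 0.1, frame_interval_s = 1,
                             seed = 9, margin_px = 2)
  for (p in scene$particles) {
    expect_true(all(p$row >= 0 & p$row <= 31))
    expect_true(all(p$col >= 0 & p$col <= 31))
  }
})

test_that("loop scenarios close, miss exactly one junction detection", {
  scene <- simulate_loops_crossings("loop", seed = 2)
  p <- scene$particles[[1]]
  loop_fr <- attr(p, "loop_frames")
  entry <- loop_fr[1] + 1
  d_close <- sqrt((p$row[entry] - p$row[max(loop_fr) + 1])^2 +
                  (p$col[entry] - p$col[max(loop_fr) + 1])^2)
  expect_lt(d_close, 1)                      # closed curve
  expect_true(all(p$visible))

  miss <- simulate_loops_crossings("loop_with_missed_junction", seed = 2)
  pm <- miss$particles[[1]]
  expect_equal(sum(!pm$visible), 1)
  expect_equal(which(!pm$visible), entry)    # the junction itself

  # per-frame steps stay trackable
  expect_true(all(pmax(abs(diff(pm$row)), abs(diff(pm$col))) <= 3))
})

test_that("crossing pair meets at the designated frame", {
  scene <- simulate_loops_crossings("crossing_pair", step_px = 2,
                                    straight_steps = 8, seed = 1)
  a <- scene$particles[[1]]; b <- scene$particles[[2]]
  d <- sqrt((a$row - b$row)^2 + (a$col - b$col)^2)
  expect_lte(d[which.min(d)], 1)
  expect_equal(which.min(d) - 1, 8)          # the midpoint frame
})

test_that("persistent walks keep speed and bounds", {
  scene <- simulate_persistent(5, n_frames = 80, height = 128, width = 128,
                               speed_px = 1.5, seed = 6)
  for (p in scene$particles) {
    st <- sqrt(diff(p$row)^2 + diff(p$col)^2)
    expect_true(all(st <= 1.5 + 1e-9))
    expect_true(all(p$row >= 0 & p$row <= 127))
  }
})

test_that("rendering: background, argmax location, amplitude linearity", {
  scene0 <- simulate_brownian(1, D = 1e-9, n_frames = 2, height = 16,
                              width = 16, seed = 1)
  scene0$particles[[1]]$visible[] <- FALSE
  rp0 <- render_params(amplitude = 0.5, background_level = 0.2, gain = 0,
                       read_noise_sd = 0)
  st <- render_scene(scene0, rp0)
  expect_true(all(abs(st$frames - 0.2) < 1e-12))

  scene <- simulate_brownian(1, D = 0.01, n_frames = 4, height = 32,
                             width = 32, pixel_size_um = 0.1, seed = 5)
  st1 <- render_scene(scene, render_params(amplitude = 0.3,
                                           background_level = 0.05,
                                           gain = 0, read_noise_sd = 0))
  for (j in 1:4) {
    p <- scene$particles[[1]]
    am <- which(st1$frames[, , j] == max(st1$frames[, , j]), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(am - 1 - c(p$row[j], p$col[j]))), 1)
  }
  st2 <- render_scene(scene, render_params(amplitude = 0.6,
                                           background_level = 0.05,
                                           gain = 0, read_noise_sd = 0))
  expect_equal(max(st2$frames[, , 1]) - 0.05,
               2 * (max(st1$frames[, , 1]) - 0.05), tolerance = 1e-9)

  # same scene + params twice: bit-identical noisy stacks
  n1 <- render_scene(scene, render_params())
  n2 <- render_scene(scene, render_params())
  expect_identical(n1$frames, n2$frames)
})

test_that("match_detections: perfect, empty and id-shuffled inputs", {
  scene <- simulate_brownian(5, D = 0.02, n_frames = 15, height = 64,
                             width = 64, pixel_size_um = 0.1, seed = 8,
                             min_separation_px = 15)
  perfect <- trajectory_set(lapply(seq_along(scene$particles), function(i) {
    p <- scene$particles[[i]]
    trajectory(i, cbind(frame = p$frame, row = round(p$row), col = round(p$col)))
  }))
  mr <- match_detections(scene, perfect, tol_px = 3)
  expect_equal(mr$recall, 1)
  expect_equal(nrow(mr$matches), 5)
  expect_true(all(mr$matches$coverage == 1))

  empty <- trajectory_set(list())
  expect_equal(match_detections(scene, empty, tol_px = 3)$recall, 0)

  shuffled <- trajectory_set(lapply(seq_along(perfect$trajectories), function(k) {
    tr <- perfect$trajectories[[c(3, 1, 5, 2, 4)[k]]]
    trajectory(k * 100, tr$samples)
  }))
  expect_equal(match_detections(scene, shuffled, tol_px = 3)$recall, 1)
})

test_that("recovered_tracks unions restart fragments per particle", {
  scene <- simulate_brownian(2, D = 0.01, n_frames = 20, height = 64,
                             width = 64, pixel_size_um = 0.1, seed = 10,
                             min_separation_px = 25)
  halves <- list()
  for (i in 1:2) {
    p <- scene$particles[[i]]
    halves[[2 * i - 1]] <- trajectory(2 * i - 1,
      cbind(frame = 0:9, row = round(p$row[1:10]), col = round(p$col[1:10])))
    halves[[2 * i]] <- trajectory(2 * i,
      cbind(frame = 10:19, row = round(p$row[11:20]), col = round(p$col[11:20])))
  }
  rt <- recovered_tracks(scene, trajectory_set(halves), tol_px = 3,
                         min_coverage = 0.9)
  expect_equal(rt$fraction_recovered, 1)     # fragments union to full cover
})
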