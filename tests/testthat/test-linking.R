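test_that("shell search follows the lowest passage time, then distance", {
  det <- make_det(6, 20, 20, rbind(c(0, 10, 10), c(4, 11, 11)))
  pmap <- build_passage_map(det)
  nx <- next_position(pmap, c(10, 10), 3, 3)
  expect_equal(nx$pos, c(11, 11)); expect_equal(nx$frame, 4)

  # lowest j dominates distance: passage 2 at distance 3 beats 4 at 1
  det <- make_det(6, 20, 20, rbind(c(4, 11, 11), c(2, 13, 13)))
  pmap <- build_passage_map(det)
  nx <- next_position(pmap, c(10, 10), 1, 3)
  expect_equal(nx$pos, c(13, 13)); expect_equal(nx$frame, 2)

  expect_null(next_position(pmap, c(10, 10), 5, 3))
})

test_that("shell search equals exhaustive enumeration on random maps", {
  set.seed(55)
  for (rep in 1:40) {
    M <- 8; h <- 15; w <- 15
    n <- sample(5:25, 1)
    marks <- cbind(sample(0:(M - 1), n, TRUE), sample(0:(h - 1), n, TRUE),
                   sample(0:(w - 1), n, TRUE))
    det <- make_det(M, h, w, marks)
    pmap <- build_passage_map(det)
    pos <- c(sample(0:(h - 1), 1), sample(0:(w - 1), 1))
    t <- sample(0:(M - 2), 1)
    r <- sample(1:3, 1)
    expect_equal(next_position(pmap, pos, t, r),
                 o_next_position(pmap, pos, t, r))
  }
})

test_that("stationary targets are discarded by the length filter", {
  marks <- cbind(0:5, 4, 4)   # never moves: no passage events
  det <- make_det(6, 10, 10, marks)
  pmap <- build_passage_map(det)
  trajs <- track_from_frame(pmap, det, 0, linking_params(min_length = 3))
  expect_length(trajs, 0)
})

test_that("a clean walker is recovered with all its arrival events", {
  # deterministic path, steps of 1-2 px
  path <- cbind(frame = 0:9,
                row = c(5, 5, 6, 7, 7, 8, 9, 9, 10, 11),
                col = c(5, 6, 7, 7, 8, 9, 9, 10, 11, 11))
  det <- make_det(10, 20, 20, path)
  pmap <- build_passage_map(det)
  trajs <- track_from_frame(pmap, det, 0, linking_params())
  expect_length(trajs, 1)
  expect_equal(trajs[[1]]$samples, cbind(frame = as.numeric(path[, 1]),
                                         row = as.numeric(path[, 2]),
                                         col = as.numeric(path[, 3])))
})

test_that("a mid-stack pause is bridged as a temporal gap", {
  path <- rbind(c(0, 5, 5), c(1, 5, 6), c(2, 5, 7),
                c(3, 5, 7), c(4, 5, 7), c(5, 5, 7), c(6, 5, 7), c(7, 5, 7),
                c(8, 5, 8), c(9, 5, 9))
  det <- make_det(10, 12, 12, path)
  pmap <- build_passage_map(det)
  trajs <- track_from_frame(pmap, det, 0, linking_params())
  expect_length(trajs, 1)
  s <- trajs[[1]]$samples
  expect_equal(s[, "frame"], c(0, 1, 2, 8, 9))   # pause bridged
  expect_true(all(diff(s[, "frame"]) > 0))
  # spatial steps bounded by the shell
  expect_true(all(pmax(abs(diff(s[, "row"])), abs(diff(s[, "col"]))) <= 3))
})

test_that("every sample beyond the first is a stored passage event", {
  set.seed(66)
  maps <- array(runif(15 * 15 * 8) < 0.1, dim = c(15, 15, 8))
  det <- detection_stack(maps)
  pmap <- build_passage_map(det)
  trajs <- track_all(det, linking_params(min_length = 2))
  h <- 15
  for (tr in trajs$trajectories) {
    s <- tr$samples
    expect_true(all(diff(s[, "frame"]) > 0))
    for (i in seq_len(nrow(s))[-1]) {
      fr <- pmap$passages[[s[i, "row"] + 1 + s[i, "col"] * h]]
      expect_true(s[i, "frame"] %in% fr)
    }
    # no (frame, pixel) revisit within one trajectory
    expect_false(anyDuplicated(s) > 0)
  }
})

test_that("incrementostep >= M degenerates to a single frame-0 start", {
  set.seed(67)
  maps <- array(runif(12 * 12 * 6) < 0.15, dim = c(12, 12, 6))
  det <- detection_stack(maps)
  single <- track_all(det, linking_params(incrementostep = 0))
  degen <- track_all(det, linking_params(incrementostep = 99))
  expect_equal(length(single$trajectories), length(degen$trajectories))
  for (k in seq_along(single$trajectories))
    expect_equal(single$trajectories[[k]]$samples,
                 degen$trajectories[[k]]$samples)
})

test_that("multi-start keeps duplicate coverage of the same walker", {
  path <- cbind(0:7, 6, 4:11)          # one walker crossing the frame
  det <- make_det(8, 16, 16, path)
  trajs <- track_all(det, linking_params(incrementostep = 3, min_length = 2))
  starts <- vapply(trajs$trajectories, function(t) t$start_frame, numeric(1))
  expect_setequal(unique(starts), c(0, 3, 6))
  ids <- vapply(trajs$trajectories, function(t) t$target_id, integer(1))
  expect_false(anyDuplicated(ids) > 0)
})

test_that("two far-apart walkers give one kept trajectory each", {
  pa <- cbind(0:5, 2, 2:7)
  pb <- cbind(0:5, 14, c(14, 13, 12, 11, 10, 9))
  det <- make_det(6, 20, 20, rbind(pa, pb))
  trajs <- track_all(det, linking_params())
  expect_length(trajs$trajectories, 2)
})
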