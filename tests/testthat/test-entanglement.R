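test_that("crossings: shared samples cross, distant tracks do not", {
  a <- trajectory(1, cbind(frame = 0:2, row = c(5, 5, 5), col = 5:7))
  b <- trajectory(2, cbind(frame = 0:2, row = c(5, 5, 5), col = c(7, 6, 5)))
  cs <- find_crossings(trajectory_set(list(a, b)), 3, 3, 1)
  expect_equal(nrow(cs$pairs), 1)
  expect_length(cs$groups, 1)

  far <- trajectory(3, cbind(frame = 0:2, row = c(25, 25, 25), col = 5:7))
  cs <- find_crossings(trajectory_set(list(a, far)), 3, 3, 1)
  expect_equal(nrow(cs$pairs), 0)
  expect_length(cs$groups, 2)   # two singletons
})

test_that("crossing detection equals the all-pairs oracle", {
  set.seed(77)
  for (rep in 1:25) {
    trajs <- random_trajs(sample(3:6, 1))
    dx <- sample(0:4, 1); dy <- sample(0:4, 1); dt <- sample(0:2, 1)
    cs <- find_crossings(trajs, dx, dy, dt)
    got <- if (nrow(cs$pairs)) {
      m <- as.matrix(cs$pairs[, c("target_id_a", "target_id_b")])
      m[order(m[, 1], m[, 2]), , drop = FALSE]
    } else NULL
    want <- o_crossings(trajs, dx, dy, dt)
    if (!is.null(want)) want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(want))
  }
})

test_that("crossings are monotone in the window sizes", {
  set.seed(78)
  for (rep in 1:10) {
    trajs <- random_trajs(4)
    small <- find_crossings(trajs, 1, 1, 0)
    big <- find_crossings(trajs, 4, 4, 2)
    if (nrow(small$pairs)) {
      key <- function(df) paste(df$target_id_a, df$target_id_b)
      expect_true(all(key(small$pairs) %in% key(big$pairs)))
    } else succeed()
  }
})

test_that("paragon of a single trajectory is the trajectory plus differences", {
  a <- trajectory(1, cbind(frame = c(0, 2, 5), row = c(4, 5, 7), col = c(4, 6, 6)))
  tbl <- build_paragon(trajectory_set(list(a)), 1)
  expect_equal(tbl$frame, c(0, 2, 5))
  expect_equal(tbl$d_row, c(0, 1, 2))
  expect_equal(tbl$d_col, c(0, 2, 0))
})

test_that("paragon merges two sub-trajectories into one monotone table", {
  a <- trajectory(1, cbind(frame = 0:10, row = 5, col = 0:10))
  b <- trajectory(2, cbind(frame = 11:20, row = 5, col = 11:20))
  tbl <- build_paragon(trajectory_set(list(a, b)), c(1, 2))
  expect_equal(nrow(tbl), 21)
  expect_true(all(diff(tbl$frame) > 0))
  expect_true(all(abs(tbl$d_col) <= 1))
  expect_length(split_paragon(tbl, 3), 1)
})

test_that("exact duplicate rows from overlapping restarts are removed", {
  a <- trajectory(1, cbind(frame = 0:3, row = 2, col = 0:3))
  b <- trajectory(2, cbind(frame = 0:3, row = 2, col = 0:3))
  tbl <- build_paragon(trajectory_set(list(a, b)), c(1, 2))
  expect_equal(nrow(tbl), 8)    # distinct targets kept...
  tbl2 <- build_paragon(trajectory_set(list(a)), 1)
  expect_equal(nrow(tbl2), 4)   # ...within-target duplicates impossible
})

test_that("splicing cuts at large steps and re-bases segments", {
  a <- trajectory(1, cbind(frame = 0:9, row = 5,
                           col = c(0:4, 15:19)))     # 11-px jump at frame 5
  tbl <- build_paragon(trajectory_set(list(a)), 1)
  segs <- split_paragon(tbl, 3)
  expect_length(segs, 2)
  expect_equal(segs[[1]]$frame, 0:4)
  expect_equal(segs[[2]]$frame, 5:9)
  expect_equal(segs[[2]]$d_col[1], 0)   # re-based

  expect_length(split_paragon(build_paragon(trajectory_set(list(
    trajectory(1, cbind(frame = 0:5, row = 5, col = 0:5)))), 1), 3), 1)
})

test_that("splicing matches a direct row-by-row scan oracle", {
  set.seed(88)
  for (rep in 1:25) {
    n <- sample(5:15, 1)
    tbl <- data.frame(frame = sort(sample(0:20, n)),
                      row = sample(0:20, n, TRUE),
                      col = sample(0:20, n, TRUE),
                      target_id = sample(1:3, n, TRUE))
    tbl <- aditrack:::.paragon_diffs(tbl)
    thr <- sample(1:5, 1)
    segs <- split_paragon(tbl, thr)
    # oracle: walk rows, cut when step exceeds thr or frame repeats with
    # a different position
    cuts <- c()
    for (i in 2:n) {
      step <- max(abs(tbl$row[i] - tbl$row[i - 1]),
                  abs(tbl$col[i] - tbl$col[i - 1]))
      same_t <- tbl$frame[i] == tbl$frame[i - 1]
      if (step > thr || (same_t && step > 0)) cuts <- c(cuts, i)
    }
    expect_length(segs, length(cuts) + 1)
    expect_equal(sum(vapply(segs, nrow, integer(1))), n)
  }
})

test_that("merge validates junctions and rejects bad orders", {
  a <- trajectory(1, cbind(frame = 0:4, row = 5, col = 0:4))
  b <- trajectory(2, cbind(frame = 5:9, row = 5, col = 5:9))
  segs <- list(build_paragon(trajectory_set(list(a)), 1),
               build_paragon(trajectory_set(list(b)), 2))
  merged <- merge_segments(segs, c(1, 2), 3)
  expect_equal(nrow(merged), 10)
  expect_true(all(diff(merged$frame) > 0))
  expect_error(merge_segments(segs, c(2, 1), 3), "time order")

  c_far <- trajectory(3, cbind(frame = 5:9, row = 15, col = 15:19))
  segs2 <- list(segs[[1]], build_paragon(trajectory_set(list(c_far)), 3))
  expect_error(merge_segments(segs2, c(1, 2), 3), "threshold_paragon")
})
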