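# Phases C and H: trajectory linking on the passage-time map.  From each
# seed the tracker repeatedly searches the concentric pixel shells around
# the current position for the candidate with the smallest later passage
# time ("lowest j index" rule).  Multi-start tracking (incrementostep)
# repeats the search from equally spaced frames so loop and crossing
# segments missed by a single start are recovered as sub-trajectories.

#' Linking parameters
#'
#' @param shell_radius Maximum Chebyshev search radius in pixels (the
#'   three concentric shells of the default correspond to radius 3).  The
#'   full disc up to this radius is always searched.
#' @param incrementostep Spacing in frames between tracking restart
#'   frames; `0` (the default) means a single start from frame 0.
#' @param min_length Minimum trajectory length in samples to keep.
#' @return A `linking_params` list.
#' @export
linking_params <- function(shell_radius = 3L, incrementostep = 0L,
                           min_length = 3L) {
  shell_radius <- as.integer(shell_radius)
  incrementostep <- as.integer(incrementostep)
  min_length <- as.integer(min_length)
  stopifnot(shell_radius >= 1L, incrementostep >= 0L, min_length >= 1L)
  structure(list(shell_radius = shell_radius, incrementostep = incrementostep,
                 min_length = min_length),
            class = "linking_params")
}

#' Construct a single trajectory
#'
#' @param target_id Integer identifier.
#' @param samples Matrix with columns `frame`, `row`, `col` (0-based),
#'   frames strictly increasing.
#' @return A `trajectory`.
#' @export
trajectory <- function(target_id, samples) {
  samples <- matrix(as.numeric(samples), ncol = 3,
                    dimnames = list(NULL, c("frame", "row", "col")))
  if (nrow(samples) > 1 && any(diff(samples[, "frame"]) <= 0))
    stop("trajectory frames must be strictly increasing")
  structure(list(target_id = as.integer(target_id), samples = samples,
                 start_frame = samples[1, "frame"]),
            class = "trajectory")
}

#' Construct a trajectory set
#'
#' @param trajectories List of [trajectory()] objects with unique ids.
#' @param params The [linking_params()] used, if any.
#' @param stack_shape Optional `c(M, height, width)` of the source stack.
#' @param pixel_size_um,frame_interval_s Optional calibration carried for
#'   export and statistics.
#' @return A `trajectory_set`.
#' @export
trajectory_set <- function(trajectories, params = NULL, stack_shape = NULL,
                           pixel_size_um = NULL, frame_interval_s = NULL) {
  trajectories <- unname(trajectories)
  ids <- vapply(trajectories, function(t) t$target_id, integer(1))
  if (anyDuplicated(ids)) stop("target_ids must be unique")
  structure(list(trajectories = trajectories, params = params,
                 stack_shape = stack_shape, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  n <- length(x$trajectories)
  len <- vapply(x$trajectories, function(t) nrow(t$samples), integer(1))
  cat(sprintf("trajectory_set: %d trajectories, lengths %s\n", n,
              if (n) paste0(min(len), "..", max(len)) else "-"))
  invisible(x)
}

#' @export
as.data.frame.trajectory_set <- function(x, ...) {
  if (!length(x$trajectories))
    return(data.frame(target_id = integer(0), frame = numeric(0),
                      row = numeric(0), col = numeric(0)))
  do.call(rbind, lapply(x$trajectories, function(t)
    data.frame(target_id = t$target_id, frame = t$samples[, "frame"],
               row = t$samples[, "row"], col = t$samples[, "col"])))
}

#' Find the next trajectory position in the passage map
#'
#' Among all pixels at Chebyshev distance `1..shell_radius` from `pos`
#' (the current pixel itself excluded) that hold a passage time `j > t`,
#' returns the candidate with minimal `j`; ties on `j` are broken by
#' smaller Chebyshev distance, then by lexicographic (row, col).
#'
#' @param pmap A `passage_map` from [build_passage_map()].
#' @param pos Current 0-based `c(row, col)`.
#' @param t Current 0-based frame index.
#' @param shell_radius Maximum search radius.
#' @return `list(pos = c(row, col), frame = j)` or `NULL` when no
#'   candidate exists.
#' @export
next_position <- function(pmap, pos, t, shell_radius = 3L) {
  h <- pmap$dim[1]; w <- pmap$dim[2]
  r0 <- pos[1]; c0 <- pos[2]
  best_j <- Inf; best_d <- Inf; best_r <- Inf; best_c <- Inf
  for (dc in -shell_radius:shell_radius) {
    cc <- c0 + dc
    if (cc < 0 || cc >= w) next
    for (dr in -shell_radius:shell_radius) {
      if (dr == 0 && dc == 0) next
      rr <- r0 + dr
      if (rr < 0 || rr >= h) next
      fr <- pmap$passages[[rr + 1L + cc * h]]
      if (is.null(fr)) next
      k <- fr[fr > t]
      if (!length(k)) next
      j <- k[1]                       # lists are sorted increasing
      d <- max(abs(dr), abs(dc))
      if (j < best_j ||
          (j == best_j && (d < best_d ||
            (d == best_d && (rr < best_r || (rr == best_r && cc < best_c)))))) {
        best_j <- j; best_d <- d; best_r <- rr; best_c <- cc
      }
    }
  }
  if (!is.finite(best_j)) return(NULL)
  list(pos = c(best_r, best_c), frame = best_j)
}

#' Track all targets seeded on one frame (phase C)
#'
#' Seeds are the detection marks of frame `start`; each seed is extended
#' by repeated [next_position()] calls until no later passage time is
#' reachable.  Temporal gaps are allowed (a pause costs nothing), spatial
#' steps are bounded by `shell_radius`.  Trajectories shorter than
#' `min_length` samples are discarded.
#'
#' @param pmap A `passage_map`.
#' @param det The [detection_stack()] the map was built from.
#' @param start 0-based start frame.
#' @param params A [linking_params()].
#' @param first_id First target id to assign.
#' @return List of [trajectory()] objects.
#' @export
track_from_frame <- function(pmap, det, start = 0L, params = linking_params(),
                             first_id = 1L) {
  stopifnot(inherits(pmap, "passage_map"), inherits(det, "detection_stack"),
            start >= 0, start < pmap$n_frames)
  seeds <- detections_at(det, start)
  out <- list(); id <- as.integer(first_id)
  for (s in seq_len(nrow(seeds))) {
    pos <- as.numeric(seeds[s, ])
    t <- start
    frames <- t; rows <- pos[1]; cols <- pos[2]
    repeat {
      nx <- next_position(pmap, pos, t, params$shell_radius)
      if (is.null(nx)) break
      pos <- nx$pos; t <- nx$frame
      frames <- c(frames, t); rows <- c(rows, pos[1]); cols <- c(cols, pos[2])
    }
    if (length(frames) >= params$min_length) {
      out[[length(out) + 1L]] <-
        trajectory(id, cbind(frame = frames, row = rows, col = cols))
      id <- id + 1L
    }
  }
  out
}

#' Track a detection stack, optionally with multi-start restarts
#'
#' Runs [track_from_frame()] at start frames `0, s, 2s, ...` with
#' `s = incrementostep` (a single start from frame 0 when
#' `incrementostep` is 0 or at least `M`), all on one shared passage map.
#' Sub-trajectories from different restarts are all retained with
#' distinct ids and no deduplication: the same physical target may
#' legitimately appear as several targets across restarts.
#'
#' @param det A [detection_stack()].
#' @param params A [linking_params()].
#' @param S Difference threshold forwarded to [build_passage_map()].
#' @param pixel_size_um,frame_interval_s Optional calibration recorded in
#'   the result.
#' @return A [trajectory_set()].
#' @export
track_all <- function(det, params = linking_params(), S = 0.5,
                      pixel_size_um = NULL, frame_interval_s = NULL) {
  stopifnot(inherits(det, "detection_stack"))
  pmap <- build_passage_map(det, S)
  M <- pmap$n_frames
  starts <- if (params$incrementostep == 0L || params$incrementostep >= M) 0L
            else seq(0L, M - 1L, by = params$incrementostep)
  trajs <- list()
  for (st in starts) {
    new <- track_from_frame(pmap, det, st, params,
                            first_id = length(trajs) + 1L)
    trajs <- c(trajs, new)
  }
  trajectory_set(trajs, params = params,
                 stack_shape = c(M, pmap$dim),
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s)
}
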