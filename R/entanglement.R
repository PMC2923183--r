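# Phases E, F, I, K: crossing detection between trajectories sharing a
# hyper-volume dx * dy * dt, assembly of each crossing group into a
# time-ordered paragon table with per-row position differences, and
# splicing into continuous segments by a step-size threshold
# (threshold_paragon).  Merging segments into one final trajectory is an
# explicit, user-driven operation: the package validates, it never
# auto-merges.

#' Detect crossing trajectories (phase E)
#'
#' Trajectories `a != b` cross when some pair of samples satisfies
#' `|t_a - t_b| <= dt`, `|row_a - row_b| <= dy` and
#' `|col_a - col_b| <= dx`.  Groups are the connected components of the
#' crossing graph; non-crossing trajectories form singleton groups.
#'
#' @param trajs A [trajectory_set()].
#' @param dx,dy Spatial window half-sizes in pixels (defaults match the
#'   linking shell).
#' @param dt Temporal window in frames.
#' @return A `crossing_set` with `pairs` (data frame of witnessing sample
#'   pairs) and `groups` (list of target-id vectors).
#' @export
find_crossings <- function(trajs, dx = 3, dy = 3, dt = 1) {
  stopifnot(inherits(trajs, "trajectory_set"), dx >= 0, dy >= 0, dt >= 0)
  tl <- trajs$trajectories
  n <- length(tl)
  ids <- vapply(tl, function(t) t$target_id, integer(1))
  bb <- t(vapply(tl, function(t)
    c(min(t$samples[, "frame"]), max(t$samples[, "frame"]),
      min(t$samples[, "row"]), max(t$samples[, "row"]),
      min(t$samples[, "col"]), max(t$samples[, "col"])), numeric(6)))
  pairs <- data.frame(target_id_a = integer(0), target_id_b = integer(0),
                      frame_a = numeric(0), frame_b = numeric(0),
                      row_a = numeric(0), col_a = numeric(0),
                      row_b = numeric(0), col_b = numeric(0))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) for (a in 1:(n - 1)) for (b in (a + 1):n) {
    # bounding-box prefilter before the all-pairs sample scan
    if (bb[a, 1] > bb[b, 2] + dt || bb[b, 1] > bb[a, 2] + dt) next
    if (bb[a, 3] > bb[b, 4] + dy || bb[b, 3] > bb[a, 4] + dy) next
    if (bb[a, 5] > bb[b, 6] + dx || bb[b, 5] > bb[a, 6] + dx) next
    sa <- tl[[a]]$samples; sb <- tl[[b]]$samples
    dfr <- abs(outer(sa[, "frame"], sb[, "frame"], "-")) <= dt
    drw <- abs(outer(sa[, "row"], sb[, "row"], "-")) <= dy
    dcl <- abs(outer(sa[, "col"], sb[, "col"], "-")) <= dx
    hit <- which(dfr & drw & dcl, arr.ind = TRUE)
    if (nrow(hit)) {
      i <- hit[1, 1]; j <- hit[1, 2]
      pairs <- rbind(pairs, data.frame(
        target_id_a = ids[a], target_id_b = ids[b],
        frame_a = sa[i, "frame"], frame_b = sb[j, "frame"],
        row_a = sa[i, "row"], col_a = sa[i, "col"],
        row_b = sb[j, "row"], col_b = sb[j, "col"]))
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- lapply(split(seq_len(n), root), function(ix) ids[ix])
  names(groups) <- NULL
  structure(list(pairs = pairs, groups = groups, dx = dx, dy = dy, dt = dt),
            class = "crossing_set")
}

#' @export
print.crossing_set <- function(x, ...) {
  sizes <- lengths(x$groups)
  cat(sprintf("crossing_set: %d crossing pair(s), %d group(s) (%d non-singleton)\n",
              nrow(x$pairs), length(x$groups), sum(sizes > 1)))
  invisible(x)
}

.paragon_diffs <- function(df) {
  n <- nrow(df)
  df$d_row <- if (n) c(0, diff(df$row)) else numeric(0)
  df$d_col <- if (n) c(0, diff(df$col)) else numeric(0)
  rownames(df) <- NULL
  df
}

#' Build the paragon table of a crossing group (phase I)
#'
#' Concatenates all samples of the group's trajectories, sorts by
#' (frame, target_id), removes exact duplicate rows (redundant
#' sub-trajectories from overlapping restarts) and appends the
#' differences `d_row`, `d_col` between consecutive rows (the first row
#' gets 0, 0).
#'
#' @param trajs A [trajectory_set()].
#' @param group Vector of target ids forming the group.
#' @return A `paragon_table` data frame with columns
#'   `frame, row, col, target_id, d_row, d_col`.
#' @export
build_paragon <- function(trajs, group) {
  stopifnot(inherits(trajs, "trajectory_set"), length(group) >= 1)
  df <- as.data.frame(trajs)
  df <- df[df$target_id %in% group, c("frame", "row", "col", "target_id")]
  if (!nrow(df)) stop("group has no samples: ", paste(group, collapse = ", "))
  df <- df[order(df$frame, df$target_id), ]
  df <- df[!duplicated(df[, c("frame", "row", "col", "target_id")]), ]
  df <- .paragon_diffs(df)
  class(df) <- c("paragon_table", "data.frame")
  df
}

#' Splice a paragon table into continuous segments (phase K)
#'
#' Cuts the table before every row whose step exceeds the continuity
#' bound, `max(|d_row|, |d_col|) > threshold_paragon`, and before every
#' row that repeats the previous frame with an inconsistent position
#' (two targets claiming different places at the same time).  Each
#' returned segment is re-based: its first-row differences are zeroed.
#'
#' @param tbl A `paragon_table` from [build_paragon()].
#' @param threshold_paragon Maximum tolerated per-row step in pixels
#'   (defaults to the linking shell radius).
#' @return List of `paragon_table` segments in time order.
#' @export
split_paragon <- function(tbl, threshold_paragon = 3) {
  stopifnot(inherits(tbl, "data.frame"), threshold_paragon >= 1)
  n <- nrow(tbl)
  if (n == 0) return(list())
  step <- pmax(abs(tbl$d_row), abs(tbl$d_col))
  same_frame <- c(FALSE, diff(tbl$frame) == 0)
  moved <- c(FALSE, diff(tbl$row) != 0 | diff(tbl$col) != 0)
  cut <- (step > threshold_paragon) | (same_frame & moved)
  cut[1] <- FALSE
  seg_id <- cumsum(cut) + 1L
  lapply(split(tbl[, c("frame", "row", "col", "target_id")], seg_id),
         function(d) {
           d <- .paragon_diffs(d)
           class(d) <- c("paragon_table", "data.frame")
           d
         })
}

#' Merge validated paragon segments (user-driven)
#'
#' Concatenates segments in the given order after checking that frames
#' are monotone non-decreasing across junctions and that every junction
#' step is within `threshold_paragon`.  This is the explicit counterpart
#' of the user "validating the splicing": nothing is merged
#' automatically.
#'
#' @param segments List of `paragon_table` segments (e.g. from
#'   [split_paragon()]).
#' @param ids Indices into `segments`, in the desired time order.
#' @param threshold_paragon Maximum tolerated junction step in pixels.
#' @return A single merged `paragon_table`.
#' @export
merge_segments <- function(segments, ids = seq_along(segments),
                           threshold_paragon = 3) {
  stopifnot(length(ids) >= 1, all(ids %in% seq_along(segments)))
  parts <- segments[ids]
  for (k in seq_along(parts)[-1]) {
    prev <- parts[[k - 1]]; cur <- parts[[k]]
    if (cur$frame[1] < prev$frame[nrow(prev)])
      stop("segments ", ids[k - 1], " and ", ids[k],
           " are not in time order (frame decreases at the junction)")
    jump <- max(abs(cur$row[1] - prev$row[nrow(prev)]),
                abs(cur$col[1] - prev$col[nrow(prev)]))
    if (jump > threshold_paragon)
      stop("junction step between segments ", ids[k - 1], " and ", ids[k],
           " is ", jump, " px, above threshold_paragon = ", threshold_paragon)
  }
  df <- do.call(rbind, lapply(parts, function(d)
    d[, c("frame", "row", "col", "target_id")]))
  df <- .paragon_diffs(df)
  class(df) <- c("paragon_table", "data.frame")
  df
}
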