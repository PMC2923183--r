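# Brute-force oracles, independent of the implementation paths they check.

# sliding-window statistic with truncated borders
o_window_stat <- function(frame, m, fun) {
  nr <- nrow(frame); nc <- ncol(frame)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- max(1, i - m):min(nr, i + m)
    jj <- max(1, j - m):min(nc, j + m)
    out[i, j] <- fun(frame[ii, jj])
  }
  out
}

# 8-connected labelling by repeated neighbourhood label propagation
o_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      ii <- max(1, i - 1):min(nr, i + 1)
      jj <- max(1, j - 1):min(nc, j + 1)
      nb <- lab[ii, jj][mask[ii, jj]]
      m <- min(nb)
      if (m < lab[i, j]) { lab[i, j] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  # renumber in scan order of first occurrence
  u <- unique(lab[lab > 0])
  out <- lab
  for (k in seq_along(u)) out[lab == u[k]] <- k
  out
}

# exhaustive shell search applying the stated total order
o_next_position <- function(pmap, pos, t, shell_radius) {
  h <- pmap$dim[1]; w <- pmap$dim[2]
  cand <- NULL
  for (dr in -shell_radius:shell_radius) for (dc in -shell_radius:shell_radius) {
    if (dr == 0 && dc == 0) next
    rr <- pos[1] + dr; cc <- pos[2] + dc
    if (rr < 0 || rr >= h || cc < 0 || cc >= w) next
    fr <- pmap$passages[[rr + 1 + cc * h]]
    for (j in fr) if (j > t)
      cand <- rbind(cand, c(j, max(abs(dr), abs(dc)), rr, cc))
  }
  if (is.null(cand)) return(NULL)
  ord <- order(cand[, 1], cand[, 2], cand[, 3], cand[, 4])
  best <- cand[ord[1], ]
  list(pos = c(best[3], best[4]), frame = best[1])
}

# all-pairs crossing test by double loop over samples
o_crossings <- function(trajs, dx, dy, dt) {
  tl <- trajs$trajectories
  ids <- vapply(tl, function(t) t$target_id, integer(1))
  out <- NULL
  n <- length(tl)
  if (n > 1) for (a in 1:(n - 1)) for (b in (a + 1):n) {
    sa <- tl[[a]]$samples; sb <- tl[[b]]$samples
    hit <- FALSE
    for (i in seq_len(nrow(sa))) {
      for (k in seq_len(nrow(sb))) {
        if (abs(sa[i, "frame"] - sb[k, "frame"]) <= dt &&
            abs(sa[i, "row"] - sb[k, "row"]) <= dy &&
            abs(sa[i, "col"] - sb[k, "col"]) <= dx) { hit <- TRUE; break }
      }
      if (hit) break
    }
    if (hit) out <- rbind(out, c(ids[a], ids[b]))
  }
  out
}

# detection stack holding one mark per (frame, row, col) triple
make_det <- function(M, h, w, marks) {
  maps <- array(FALSE, dim = c(h, w, M))
  for (i in seq_len(nrow(marks)))
    maps[marks[i, 2] + 1, marks[i, 3] + 1, marks[i, 1] + 1] <- TRUE
  detection_stack(maps)
}

# random small trajectory set
random_trajs <- function(n, max_len = 8, h = 30, w = 30, M = 20) {
  trajs <- lapply(seq_len(n), function(id) {
    len <- sample(2:max_len, 1)
    frames <- sort(sample(0:(M - 1), len))
    trajectory(id, cbind(frame = frames,
                         row = sample(0:(h - 1), len, TRUE),
                         col = sample(0:(w - 1), len, TRUE)))
  })
  trajectory_set(trajs)
}
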