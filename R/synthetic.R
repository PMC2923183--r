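# Ground-truth scene simulator covering the two regimes the pipeline is
# meant for: point-like intracellular nanoparticles (Gaussian spots of a
# few pixels on a graded autofluorescence background) and cell-like blobs
# (uniform discs, lymphocyte scale).  Every stage of the pipeline is
# testable against the known tracks without any experimental data.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

.reflect <- function(x, lo, hi) {
  period <- 2 * (hi - lo)
  y <- (x - lo) %% period
  ifelse(y > (hi - lo), period - y, y) + lo
}

.new_scene <- function(particles, n_frames, height, width, pixel_size_um,
                       frame_interval_s, seed, D = NA_real_) {
  structure(list(particles = particles, n_frames = n_frames,
                 height = height, width = width,
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 seed = seed, D = D),
            class = "ground_truth_scene")
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat(sprintf("ground_truth_scene: %d particle(s), %d frame(s), %d x %d px, seed %d\n",
              length(x$particles), x$n_frames, x$height, x$width, x$seed))
  invisible(x)
}

#' Simulate Brownian ground-truth tracks
#'
#' Per-axis steps are drawn from a zero-mean normal with variance
#' `2 * D * frame_interval_s` (converted to pixels), with reflecting
#' boundaries so the particle count stays fixed.  Each frame's position
#' is visible with probability `1 - dropout_prob`, emulating
#' intermittent detection dropouts.
#'
#' @param n_particles Number of particles.
#' @param D Diffusion coefficient in um^2/s.
#' @param n_frames Number of frames `M`.
#' @param height,width Frame size in pixels.
#' @param pixel_size_um Pixel size (um); default 0.1.
#' @param frame_interval_s Frame interval (s); default 0.85.
#' @param dropout_prob Per-frame probability that a position is invisible.
#' @param seed Integer seed; all scene randomness flows from it.
#' @param init `"uniform"` scatters starting positions over the frame
#'   interior; `"clustered"` groups them around `n_clusters` centres with
#'   spread `cluster_sd_px`, reproducing locally dense regions.
#' @param n_clusters,cluster_sd_px Clustered-init geometry.
#' @param min_separation_px Minimum pairwise distance between starting
#'   positions (rejection-sampled); 0 disables.
#' @param margin_px Starting positions stay this far from the border.
#' @return A `ground_truth_scene`; each particle is a data frame with
#'   0-based `frame`, float `row`/`col` and logical `visible`.
#' @export
simulate_brownian <- function(n_particles, D, n_frames, height = 256,
                              width = 256, pixel_size_um = 0.1,
                              frame_interval_s = 0.85, dropout_prob = 0,
                              seed = 1L, init = c("uniform", "clustered"),
                              n_clusters = 4L, cluster_sd_px = 8,
                              min_separation_px = 0, margin_px = 10) {
  init <- match.arg(init)
  stopifnot(D > 0, n_particles >= 1, n_frames >= 2,
            dropout_prob >= 0, dropout_prob < 1)
  step_sd_px <- sqrt(2 * D * frame_interval_s) / pixel_size_um
  margin_px <- min(margin_px, (height - 1) / 2, (width - 1) / 2)
  .with_seed(seed, {
    lo_r <- margin_px; hi_r <- height - 1 - margin_px
    lo_c <- margin_px; hi_c <- width - 1 - margin_px
    centers <- cbind(runif(n_clusters, lo_r, hi_r), runif(n_clusters, lo_c, hi_c))
    draw1 <- function() {
      if (init == "uniform") c(runif(1, lo_r, hi_r), runif(1, lo_c, hi_c))
      else {
        k <- sample.int(n_clusters, 1)
        pmin(pmax(centers[k, ] + rnorm(2, 0, cluster_sd_px),
                  c(lo_r, lo_c)), c(hi_r, hi_c))
      }
    }
    starts <- matrix(NA_real_, n_particles, 2)
    for (i in seq_len(n_particles)) {
      for (attempt in 1:2000) {
        p <- draw1()
        if (min_separation_px <= 0 || i == 1 ||
            min(sqrt(colSums((t(starts[seq_len(i - 1), , drop = FALSE]) - p)^2))) >=
              min_separation_px) break
        if (attempt == 2000)
          stop("could not place ", n_particles,
               " particles at min_separation_px = ", min_separation_px)
      }
      starts[i, ] <- p
    }
    particles <- vector("list", n_particles)
    for (i in seq_len(n_particles)) {
      dr <- rnorm(n_frames - 1, 0, step_sd_px)
      dc <- rnorm(n_frames - 1, 0, step_sd_px)
      rows <- .reflect(starts[i, 1] + c(0, cumsum(dr)), 0, height - 1)
      cols <- .reflect(starts[i, 2] + c(0, cumsum(dc)), 0, width - 1)
      visible <- runif(n_frames) >= dropout_prob
      particles[[i]] <- data.frame(frame = 0:(n_frames - 1), row = rows,
                                   col = cols, visible = visible)
    }
    .new_scene(particles, n_frames, height, width, pixel_size_um,
               frame_interval_s, as.integer(seed), D = D)
  })
}

#' Simulate persistent random walks (cell-like motility)
#'
#' Each particle moves at constant speed with a slowly wandering heading
#' (white noise on the turning angle), occasionally entering a "loop
#' episode" of sustained curvature that closes a full circle - the
#' motility pattern of migrating cells, which produces the looping
#' trajectories the multi-start tracker is designed for.  Headings
#' reflect at the frame borders.
#'
#' @param n_particles Number of walkers.
#' @param n_frames Number of frames.
#' @param height,width Frame size in pixels.
#' @param speed_px Step length per frame in pixels (keep at or below the
#'   linking shell radius).
#' @param turn_sd Standard deviation of the per-frame heading change
#'   (radians).
#' @param loop_prob Per-frame probability of starting a loop episode.
#' @param loop_frames Duration of a loop episode; its curvature closes a
#'   full circle over this many frames.
#' @param pixel_size_um,frame_interval_s Calibration metadata.
#' @param dropout_prob Per-frame probability a position is invisible.
#' @param seed Integer seed.
#' @param min_separation_px Minimum pairwise starting distance.
#' @param margin_px Starting positions stay this far from the border.
#' @return A `ground_truth_scene`.
#' @export
simulate_persistent <- function(n_particles, n_frames, height = 256,
                                width = 256, speed_px = 1.5, turn_sd = 0.3,
                                loop_prob = 0.02, loop_frames = 15,
                                pixel_size_um = 1, frame_interval_s = 1,
                                dropout_prob = 0, seed = 1L,
                                min_separation_px = 0, margin_px = 12) {
  stopifnot(n_particles >= 1, n_frames >= 2, speed_px > 0)
  margin_px <- min(margin_px, (height - 1) / 2, (width - 1) / 2)
  .with_seed(seed, {
    lo_r <- margin_px; hi_r <- height - 1 - margin_px
    lo_c <- margin_px; hi_c <- width - 1 - margin_px
    starts <- matrix(NA_real_, n_particles, 2)
    for (i in seq_len(n_particles)) {
      for (attempt in 1:2000) {
        p <- c(runif(1, lo_r, hi_r), runif(1, lo_c, hi_c))
        if (min_separation_px <= 0 || i == 1 ||
            min(sqrt(colSums((t(starts[seq_len(i - 1), , drop = FALSE]) - p)^2))) >=
              min_separation_px) break
      }
      starts[i, ] <- p
    }
    particles <- vector("list", n_particles)
    for (i in seq_len(n_particles)) {
      r <- starts[i, 1]; c <- starts[i, 2]
      theta <- runif(1, 0, 2 * pi)
      rows <- numeric(n_frames); cols <- numeric(n_frames)
      rows[1] <- r; cols[1] <- c
      loop_left <- 0L
      for (k in 2:n_frames) {
        if (loop_left == 0L && runif(1) < loop_prob) loop_left <- loop_frames
        curv <- if (loop_left > 0L) 2 * pi / loop_frames else 0
        if (loop_left > 0L) loop_left <- loop_left - 1L
        theta <- theta + rnorm(1, 0, turn_sd) + curv
        r2 <- r + speed_px * sin(theta)
        c2 <- c + speed_px * cos(theta)
        if (r2 < 0 || r2 > height - 1) { theta <- -theta; r2 <- r }
        if (c2 < 0 || c2 > width - 1) { theta <- pi - theta; c2 <- c }
        r <- min(max(r2, 0), height - 1)
        c <- min(max(c2, 0), width - 1)
        rows[k] <- r; cols[k] <- c
      }
      visible <- runif(n_frames) >= dropout_prob
      particles[[i]] <- data.frame(frame = 0:(n_frames - 1), row = rows,
                                   col = cols, visible = visible)
    }
    .new_scene(particles, n_frames, height, width, pixel_size_um,
               frame_interval_s, as.integer(seed))
  })
}

#' Simulate deterministic loop and crossing scenarios
#'
#' Constructed geometries for the hard tracking cases: a looping
#' trajectory (the closure revisits its entry pixel), the same loop with
#' exactly one detection dropout adjacent to the closure (the case where
#' single-start tracking detours and skips the loop), and a pair of
#' linear tracks crossing at a chosen frame.
#'
#' @param scenario `"loop"`, `"loop_with_missed_junction"` or
#'   `"crossing_pair"`.
#' @param height,width Frame size in pixels.
#' @param loop_radius_px Loop radius.
#' @param step_px Path step per frame (keep at or below the linking
#'   shell radius).
#' @param straight_steps Straight-path steps before and after the loop.
#' @param pixel_size_um,frame_interval_s Calibration metadata.
#' @param seed Seed recorded in the scene (the geometry itself is
#'   deterministic; the seed drives rendering noise).
#' @return A `ground_truth_scene`.
#' @export
simulate_loops_crossings <- function(scenario = c("loop",
                                                  "loop_with_missed_junction",
                                                  "crossing_pair"),
                                     height = 64, width = 96,
                                     loop_radius_px = 8, step_px = 2,
                                     straight_steps = 8,
                                     pixel_size_um = 0.1,
                                     frame_interval_s = 1, seed = 1L) {
  scenario <- match.arg(scenario)
  if (scenario %in% c("loop", "loop_with_missed_junction")) {
    # rightward approach to the junction E, one clockwise circle tangent
    # at E (first circle step leads *away* from the approach, the closure
    # returns right next to it), then a rightward exit.  With E itself
    # undetected, the basic tracker standing just before E cannot reach
    # the early circle samples (outside the shell) but can reach the
    # late-closure samples, so it detours and skips the loop - the
    # failure mode multi-start tracking repairs.
    r0 <- height / 2 + loop_radius_px / 2
    c_entry <- width / 2
    cols_in <- seq(c_entry - straight_steps * step_px, c_entry - step_px,
                   by = step_px)
    n_circ <- ceiling(2 * pi * loop_radius_px / step_px)
    theta <- pi / 2 - seq(0, 2 * pi, length.out = n_circ + 1)[-1]
    ctr_r <- r0 - loop_radius_px
    circ_r <- ctr_r + loop_radius_px * sin(theta)
    circ_c <- c_entry + loop_radius_px * cos(theta)
    cols_out <- seq(c_entry + step_px, c_entry + straight_steps * step_px,
                    by = step_px)
    rows <- c(rep(r0, length(cols_in)), r0, circ_r, rep(r0, length(cols_out)))
    cols <- c(cols_in, c_entry, circ_c, cols_out)
    n <- length(rows)
    visible <- rep(TRUE, n)
    entry_idx <- length(cols_in) + 1L          # E, adjacent to the closure
    if (scenario == "loop_with_missed_junction")
      visible[entry_idx] <- FALSE
    p <- data.frame(frame = 0:(n - 1), row = rows, col = cols,
                    visible = visible)
    attr(p, "loop_frames") <- (entry_idx:(entry_idx + n_circ)) - 1L  # 0-based
    .new_scene(list(p), n, height, width, pixel_size_um, frame_interval_s,
               as.integer(seed))
  } else {
    # two linear tracks meeting at the frame midpoint
    n <- 2L * straight_steps + 1L
    mid <- straight_steps
    rc <- height / 2; cc <- width / 2
    p1 <- data.frame(frame = 0:(n - 1), row = rep(rc, n),
                     col = cc + step_px * ((0:(n - 1)) - mid),
                     visible = TRUE)
    p2 <- data.frame(frame = 0:(n - 1),
                     row = rc + step_px * ((0:(n - 1)) - mid),
                     col = rep(cc, n), visible = TRUE)
    .new_scene(list(p1, p2), n, height, width, pixel_size_um,
               frame_interval_s, as.integer(seed))
  }
}

#' Rendering parameters for synthetic scenes
#'
#' @param spot_sigma_px Gaussian spot standard deviation in pixels
#'   (point-like emitters); ignored when `blob_radius_px` is given.  May
#'   be a vector, recycled over particles.
#' @param blob_radius_px Disc radius for cell-like blobs; `NULL` renders
#'   Gaussian spots.  May be a vector, recycled over particles.
#' @param amplitude Peak signal above background, in \[0, 1\] units.  May
#'   be a vector, recycled over particles.
#' @param background_level Uniform background level.
#' @param background_gradient Additional left-to-right linear background
#'   ramp (autofluorescence gradient), added as
#'   `background_gradient * col / (width - 1)`.
#' @param gain Photon count at unit intensity for the shot-like Poisson
#'   noise; `0` disables shot noise.
#' @param read_noise_sd Gaussian read-noise standard deviation; `0`
#'   disables.
#' @return A `render_params` list.
#' @export
render_params <- function(spot_sigma_px = 1.5, blob_radius_px = NULL,
                          amplitude = 0.6, background_level = 0.1,
                          background_gradient = 0, gain = 200,
                          read_noise_sd = 0.01) {
  stopifnot(all(amplitude > background_level), background_level >= 0)
  structure(list(spot_sigma_px = spot_sigma_px,
                 blob_radius_px = blob_radius_px, amplitude = amplitude,
                 background_level = background_level,
                 background_gradient = background_gradient,
                 gain = gain, read_noise_sd = read_noise_sd),
            class = "render_params")
}

#' Render a ground-truth scene into an image stack
#'
#' Each visible particle is drawn at its subpixel position as an
#' isotropic Gaussian spot (nearest-pixel sampling) or a uniform disc,
#' on top of a uniform-plus-graded background; Poisson shot noise and
#' Gaussian read noise are then applied and the result clipped to
#' \[0, 1\].  The render RNG is seeded from the scene seed, so identical
#' scene + parameters give bit-identical stacks.
#'
#' @param scene A `ground_truth_scene`.
#' @param rp A [render_params()].
#' @return An [image_stack()].
#' @export
render_scene <- function(scene, rp = render_params()) {
  stopifnot(inherits(scene, "ground_truth_scene"),
            inherits(rp, "render_params"))
  h <- scene$height; w <- scene$width; M <- scene$n_frames
  bg <- matrix(rp$background_level, h, w) +
    matrix(rp$background_gradient * (0:(w - 1)) / max(w - 1, 1),
           h, w, byrow = TRUE)
  frames <- array(rep(bg, M), dim = c(h, w, M))
  use_disc <- !is.null(rp$blob_radius_px)
  np <- length(scene$particles)
  amp <- rep_len(rp$amplitude, np)
  sig <- rep_len(rp$spot_sigma_px, np)
  brad <- if (use_disc) rep_len(rp$blob_radius_px, np) else rep(NA_real_, np)
  for (pi in seq_len(np)) {
    p <- scene$particles[[pi]]
    rad <- if (use_disc) ceiling(brad[pi]) else ceiling(3 * sig[pi])
    for (k in seq_len(nrow(p))) {
      if (!p$visible[k]) next
      j <- p$frame[k] + 1L
      pr <- p$row[k]; pc <- p$col[k]
      i0 <- max(0L, floor(pr - rad)); i1 <- min(h - 1L, ceiling(pr + rad))
      j0 <- max(0L, floor(pc - rad)); j1 <- min(w - 1L, ceiling(pc + rad))
      if (i0 > i1 || j0 > j1) next
      ii <- i0:i1; jj <- j0:j1
      d2 <- outer((ii - pr)^2, (jj - pc)^2, "+")
      patch <- if (use_disc) {
        amp[pi] * (d2 <= brad[pi]^2)
      } else {
        amp[pi] * exp(-d2 / (2 * sig[pi]^2))
      }
      frames[ii + 1L, jj + 1L, j] <- frames[ii + 1L, jj + 1L, j] + patch
    }
  }
  .with_seed(scene$seed + 1L, {
    if (rp$gain > 0)
      frames[] <- rpois(length(frames), pmax(frames, 0) * rp$gain) / rp$gain
    if (rp$read_noise_sd > 0)
      frames[] <- frames + rnorm(length(frames), 0, rp$read_noise_sd)
  })
  frames[frames < 0] <- 0
  frames[frames > 1] <- 1
  image_stack(frames, pixel_size_um = scene$pixel_size_um,
              frame_interval_s = scene$frame_interval_s)
}

#' Which ground-truth tracks are recovered by (multi-start) tracking
#'
#' Mirrors the cell-tracking workflow, where one physical target is
#' legitimately represented by several sub-trajectories from different
#' restart frames that the user then merges: every trajectory is
#' assigned to the ground-truth track it overlaps best (many-to-one),
#' assignments with sample-overlap score below `min_score` are dropped,
#' and a track counts as recovered when the union of its assigned
#' sub-trajectories' in-tolerance samples spans at least
#' `min_coverage` of the stack.
#'
#' @param scene A `ground_truth_scene`.
#' @param trajs A [trajectory_set()] (typically from multi-start
#'   [track_all()]).
#' @param tol_px Matching tolerance in pixels (of the order of the
#'   target radius for extended targets).
#' @param min_score Minimum fraction of a sub-trajectory's samples that
#'   must lie within tolerance for it to count.
#' @param min_coverage Minimum covered span, as a fraction of the stack.
#' @param det Optional [detection_stack()]: restrict the denominator to
#'   tracks detected on frame 0 (one-to-one marks-to-particles).
#' @return List with `fraction_recovered`, `recovered` (logical per
#'   eligible track), `coverage` (per-track covered span fraction) and
#'   `n_eligible`.
#' @export
recovered_tracks <- function(scene, trajs, tol_px = 5, min_score = 0.5,
                             min_coverage = 0.5, det = NULL) {
  stopifnot(inherits(scene, "ground_truth_scene"),
            inherits(trajs, "trajectory_set"))
  np <- length(scene$particles)
  truth_r <- vapply(scene$particles, function(p) p$row, numeric(scene$n_frames))
  truth_c <- vapply(scene$particles, function(p) p$col, numeric(scene$n_frames))
  frames_hit <- rep(list(integer(0)), np)
  for (tr in trajs$trajectories) {
    s <- tr$samples
    fi <- s[, "frame"] + 1L
    best_b <- 0L; best_score <- -1; best_frames <- integer(0)
    for (b in seq_len(np)) {
      d <- sqrt((s[, "row"] - truth_r[fi, b])^2 +
                (s[, "col"] - truth_c[fi, b])^2)
      sc <- mean(d <= tol_px)
      if (sc > best_score) {
        best_score <- sc; best_b <- b
        best_frames <- s[d <= tol_px, "frame"]
      }
    }
    if (best_score >= min_score)
      frames_hit[[best_b]] <- c(frames_hit[[best_b]], best_frames)
  }
  coverage <- vapply(frames_hit, function(fr)
    if (length(fr)) (diff(range(fr)) + 1) / scene$n_frames else 0, numeric(1))
  eligible <- rep(TRUE, np)
  if (!is.null(det)) {
    marks <- detections_at(det, 0L)
    eligible <- rep(FALSE, np)
    if (nrow(marks)) {
      dm <- sqrt(outer(marks[, "row"], truth_r[1, ], "-")^2 +
                 outer(marks[, "col"], truth_c[1, ], "-")^2)
      repeat {
        if (all(dm > tol_px)) break
        ij <- arrayInd(which.min(dm), dim(dm))
        eligible[ij[2]] <- TRUE
        dm[ij[1], ] <- Inf; dm[, ij[2]] <- Inf
      }
    }
  }
  recovered <- coverage >= min_coverage
  list(fraction_recovered = if (sum(eligible))
         sum(recovered & eligible) / sum(eligible) else NA_real_,
       recovered = recovered[eligible], coverage = coverage[eligible],
       n_eligible = sum(eligible))
}

#' Match reconstructed trajectories to ground truth
#'
#' Scores every (trajectory, particle) pair by the fraction of the
#' trajectory's samples lying within `tol_px` (Euclidean) of the
#' particle's true position at the same frame, then assigns pairs
#' greedily one-to-one in decreasing score order, keeping scores of at
#' least `min_match_frac`.  Recall is the fraction of eligible particles
#' that received a trajectory; eligibility is "visible on frame 0", or,
#' when `det` is given, "detected on frame 0 within `tol_px`" (the
#' particles actually selected for tracking).
#'
#' @param scene The `ground_truth_scene`.
#' @param trajs A [trajectory_set()].
#' @param tol_px Matching tolerance in pixels.
#' @param min_match_frac Minimum score for a valid match.
#' @param det Optional [detection_stack()] defining frame-0 eligibility.
#' @return List with `recall`, `n_eligible`, `matches` (data frame of
#'   `particle`, `target_id`, `score`, `coverage`) and `coverage`
#'   (per-eligible-particle fraction of stack frames covered by matched
#'   samples within tolerance; 0 for unmatched).
#' @export
match_detections <- function(scene, trajs, tol_px = 3,
                             min_match_frac = 0.5, det = NULL) {
  stopifnot(inherits(scene, "ground_truth_scene"),
            inherits(trajs, "trajectory_set"), tol_px >= 1)
  np <- length(scene$particles)
  tl <- trajs$trajectories
  nt <- length(tl)
  truth_r <- vapply(scene$particles, function(p) p$row, numeric(scene$n_frames))
  truth_c <- vapply(scene$particles, function(p) p$col, numeric(scene$n_frames))
  eligible <- vapply(scene$particles, function(p) isTRUE(p$visible[1]), logical(1))
  if (!is.null(det)) {
    # a mark detects one target: assign frame-0 marks to particles
    # greedily one-to-one by distance, so a merged pair of particles
    # counts as a single detected target
    marks <- detections_at(det, 0L)
    eligible <- rep(FALSE, np)
    if (nrow(marks)) {
      dm <- sqrt(outer(marks[, "row"], truth_r[1, ], "-")^2 +
                 outer(marks[, "col"], truth_c[1, ], "-")^2)
      repeat {
        if (all(dm > tol_px)) break
        ij <- arrayInd(which.min(dm), dim(dm))
        eligible[ij[2]] <- TRUE
        dm[ij[1], ] <- Inf; dm[, ij[2]] <- Inf
      }
    }
  }
  score <- matrix(0, nt, np)
  covered <- vector("list", nt * np)
  for (a in seq_len(nt)) {
    s <- tl[[a]]$samples
    fi <- s[, "frame"] + 1L
    for (b in seq_len(np)) {
      d <- sqrt((s[, "row"] - truth_r[fi, b])^2 +
                (s[, "col"] - truth_c[fi, b])^2)
      ok <- d <= tol_px
      score[a, b] <- mean(ok)
      covered[[(b - 1L) * nt + a]] <- s[ok, "frame"]
    }
  }
  matches <- data.frame(particle = integer(0), target_id = integer(0),
                        score = numeric(0), coverage = numeric(0))
  sc <- score
  repeat {
    if (all(sc < min_match_frac)) break
    ij <- arrayInd(which.max(sc), dim(sc))
    a <- ij[1]; b <- ij[2]
    fr_ok <- covered[[(b - 1L) * nt + a]]
    # "coverage": the stretch of the stack the matched samples span
    cov <- if (length(fr_ok)) (diff(range(fr_ok)) + 1) / scene$n_frames else 0
    matches <- rbind(matches, data.frame(
      particle = b, target_id = tl[[a]]$target_id,
      score = score[a, b], coverage = cov))
    sc[a, ] <- -Inf; sc[, b] <- -Inf
  }
  cov_all <- setNames(numeric(np), seq_len(np))
  cov_all[matches$particle] <- matches$coverage
  n_eligible <- sum(eligible)
  matched_eligible <- sum(matches$particle %in% which(eligible))
  list(recall = if (n_eligible) matched_eligible / n_eligible else NA_real_,
       n_eligible = n_eligible,
       matches = matches,
       coverage = cov_all[eligible])
}
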