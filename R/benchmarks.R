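# Reproducible benchmark scenarios.  Each function builds the stated
# synthetic world, runs the pipeline on it and measures one headline
# quantity: segmentation recall on low-SNR spot images, tracking recall
# in the dense intracellular regime, track recovery in the cell-blob
# regime, diffusion-coefficient recovery end-to-end, and loop
# reconstruction by multi-start tracking plus paragon splicing.

# The user of the threshold search counts the targets they believe
# present; on dense images the exact count may not be attainable (merged
# or borderline targets), so scan the threshold grid once and, among
# counts within max_offset of the estimate, adopt the one attained over
# the longest run of levels, thresholding at that run's midpoint.  The
# near-truth count keeps the threshold fine enough to separate clustered
# particles; a deliberately coarser count would track cluster centroids
# instead of particles.
.auto_segment <- function(stack, expected, m_m = 1L, m_b = 1L,
                          single_peak = FALSE, max_offset = 5L) {
  f0 <- minimum_filter(stack$frames[, , 1], m_m)
  sc <- threshold_scan(f0)
  best_len <- 0L; best_T <- NA_real_
  for (cnt in unique(pmax(1L, expected + (-max_offset):max_offset))) {
    runs <- rle(sc$count == cnt)
    ends <- cumsum(runs$lengths)
    ok <- which(runs$values)
    if (!length(ok)) next
    k <- ok[which.max(runs$lengths[ok])]
    len <- runs$lengths[k]
    if (len > best_len) {
      best_len <- len
      first <- ends[k] - len + 1L
      best_T <- sc$threshold[first + (len - 1L) %/% 2L]
    }
  }
  if (!is.finite(best_T)) return(NULL)
  segment_stack(stack, seg_params(m_m = m_m, m_b = m_b, threshold = best_T,
                                  single_peak_per_blob = single_peak))
}

.n_visible0 <- function(scene)
  sum(vapply(scene$particles, function(p) isTRUE(p$visible[1]), logical(1)))

#' Benchmark: segmentation recall on synthetic spot stacks
#'
#' Renders stacks of 50 Gaussian spots (diameter 3-7 px, amplitude at
#' least three times the graded background, shot-like noise) on 256x256
#' frames, segments frame 0 with the four-filter chain (3x3 masks, auto
#' threshold) and reports the fraction of true spots recovered within
#' `tol_px`.
#'
#' @param n_stacks Number of independent stacks.
#' @param seed Base seed; stack `i` uses `seed + i`.
#' @param n_frames Frames per stack (recall is measured on frame 0).
#' @param tol_px Matching tolerance.
#' @return List with `recall` (mean percent), `per_stack` and `n`.
#' @export
benchmark_segmentation_recall <- function(n_stacks = 20, seed = 1L,
                                          n_frames = 5, tol_px = 3) {
  per <- numeric(n_stacks)
  for (i in seq_len(n_stacks)) {
    s <- seed + i
    scene <- simulate_brownian(50, D = 0.022, n_frames = n_frames,
                               height = 256, width = 256,
                               pixel_size_um = 0.1, frame_interval_s = 0.85,
                               seed = s, min_separation_px = 12,
                               margin_px = 12)
    rp <- .with_seed(s + 500000L, render_params(
      spot_sigma_px = runif(50, 3 / 2.355, 7 / 2.355),   # FWHM 3-7 px
      amplitude = runif(50, 0.45, 0.85),                 # >= 3x background
      background_level = 0.1, background_gradient = 0.1))
    stack <- render_scene(scene, rp)
    det <- .auto_segment(stack, 50)
    if (is.null(det)) { per[i] <- 0; next }
    m <- detections_at(det, 0L)
    truth <- t(vapply(scene$particles,
                      function(p) c(p$row[1], p$col[1]), numeric(2)))
    per[i] <- mean(apply(truth, 1, function(p) {
      nrow(m) > 0 &&
        min(sqrt((m[, "row"] - p[1])^2 + (m[, "col"] - p[2])^2)) <= tol_px
    }))
  }
  list(recall = 100 * mean(per), per_stack = 100 * per, n = n_stacks)
}

#' Benchmark: tracking recall in the dense intracellular regime
#'
#' Brownian scenes of ~40 spots in a 20x20 um field (0.1 um/px) with
#' clustered starting positions whose peak local density is about
#' 2 particles/um^2, D = 0.022 um^2/s at 0.85 s/frame, 5% detection
#' dropout.  The full segment - passage-map - track chain runs with a
#' 3 px shell, and recall is the fraction of frame-0-detected particles
#' matched one-to-one to a kept trajectory ([match_detections()]).
#'
#' @param n_scenes Number of independent scenes.
#' @param seed Base seed.
#' @param n_frames Frames per scene.
#' @param tol_px Matching tolerance.
#' @return List with `recall` (mean percent), `per_scene` and `n`.
#' @export
benchmark_dense_tracking_recall <- function(n_scenes = 10, seed = 1L,
                                            n_frames = 100, tol_px = 3) {
  per <- numeric(n_scenes)
  for (i in seq_len(n_scenes)) {
    s <- seed + i
    scene <- simulate_brownian(40, D = 0.022, n_frames = n_frames,
                               height = 200, width = 200,
                               pixel_size_um = 0.1, frame_interval_s = 0.85,
                               dropout_prob = 0.05, seed = s,
                               init = "clustered", n_clusters = 4,
                               cluster_sd_px = 9,   # peak ~2 particles/um^2
                               margin_px = 15)
    stack <- render_scene(scene, render_params(
      spot_sigma_px = 1.5, amplitude = 0.6,
      background_level = 0.1, background_gradient = 0.05))
    det <- .auto_segment(stack, .n_visible0(scene))
    if (is.null(det)) { per[i] <- 0; next }
    trajs <- track_all(det, linking_params(shell_radius = 3, min_length = 3))
    mr <- match_detections(scene, trajs, tol_px = tol_px,
                           min_match_frac = 1e-9, det = det)
    per[i] <- mr$recall
  }
  list(recall = 100 * mean(per), per_scene = 100 * per, n = n_scenes)
}

#' Benchmark: track recovery in the cell-blob regime
#'
#' Disc-shaped blobs (radius 3-5 px) performing persistent random walks
#' with occasional loops on 256x256 frames, 10% dropout.  Segmentation
#' uses the enlarged 11x11 mean/maximum masks (`m_b = 5`, one peak per
#' blob); tracking is multi-start (`incrementostep = 10`), as the cell
#' workflow prescribes, and a track counts as recovered when the union
#' of its assigned sub-trajectories covers at least half the stack
#' ([recovered_tracks()]).
#'
#' @param n_scenes Number of independent scenes.
#' @param seed Base seed.
#' @param n_frames Frames per scene.
#' @param tol_px Matching tolerance (of the order of the blob radius).
#' @return List with `recovered` (mean percent), `per_scene` and `n`.
#' @export
benchmark_cell_tracking <- function(n_scenes = 10, seed = 1L,
                                    n_frames = 60, tol_px = 5) {
  per <- numeric(n_scenes)
  for (i in seq_len(n_scenes)) {
    s <- seed + i
    scene <- simulate_persistent(15, n_frames = n_frames,
                                 height = 256, width = 256,
                                 speed_px = 1.5, turn_sd = 0.3,
                                 loop_prob = 0.02, loop_frames = 15,
                                 dropout_prob = 0.1, seed = s,
                                 min_separation_px = 25, margin_px = 15)
    rp <- .with_seed(s + 500000L, render_params(
      blob_radius_px = runif(15, 3, 5),
      amplitude = 0.6, background_level = 0.05))
    stack <- render_scene(scene, rp)
    det <- .auto_segment(stack, .n_visible0(scene), m_b = 5L,
                         single_peak = TRUE)
    if (is.null(det)) { per[i] <- 0; next }
    trajs <- track_all(det, linking_params(shell_radius = 3,
                                           incrementostep = 10))
    rt <- recovered_tracks(scene, trajs, tol_px = tol_px, det = det)
    per[i] <- rt$fraction_recovered
  }
  list(recovered = 100 * mean(per), per_scene = 100 * per, n = n_scenes)
}

#' Benchmark: end-to-end diffusion-coefficient recovery
#'
#' Simulates 20 Brownian walkers at the given `D` (0.85 s/frame,
#' 0.1 um/px, a 22x22 um field as in the intracellular experiments) for
#' `n_frames` frames, renders, segments and tracks them, computes the
#' normalized displacements of consecutive-frame detections and fits
#' the shared-D Gaussian ([fit_gaussian_D()]).  Also returns the fit on
#' the exact ground-truth displacements as the no-pipeline reference.
#'
#' @param D True diffusion coefficient (um^2/s).
#' @param seed Seed.
#' @param n_frames Number of frames.
#' @param dropout_prob Detection dropout probability.
#' @return List with `D_fit`, `D_stderr`, `D_truth_fit`, `n_samples`.
#' @export
benchmark_diffusion_recovery <- function(D = 0.022, seed = 1L,
                                         n_frames = 440,
                                         dropout_prob = 0.05) {
  scene <- simulate_brownian(20, D = D, n_frames = n_frames,
                             height = 220, width = 220,
                             pixel_size_um = 0.1, frame_interval_s = 0.85,
                             dropout_prob = dropout_prob, seed = seed,
                             min_separation_px = 15)
  stack <- render_scene(scene, render_params(
    spot_sigma_px = 1.5, amplitude = 0.6,
    background_level = 0.1, background_gradient = 0.05))
  det <- .auto_segment(stack, .n_visible0(scene))
  if (is.null(det)) stop("segmentation failed in diffusion benchmark")
  trajs <- track_all(det, linking_params())
  disp <- normalized_displacements(trajs, 0.1, 0.85, max_gap_frames = 1)
  fit <- fit_gaussian_D(disp)
  gt <- do.call(rbind, lapply(scene$particles, function(p) {
    tau <- 0.85
    data.frame(u = c(diff(p$col), diff(p$row)) * 0.1 / sqrt(tau),
               axis = rep(c("x", "y"), each = nrow(p) - 1),
               tau_s = tau)
  }))
  fit_gt <- fit_gaussian_D(gt)
  list(D_fit = fit$D, D_stderr = fit$D_stderr,
       D_truth_fit = fit_gt$D, n_samples = fit$n_samples)
}

#' Benchmark: loop reconstruction with multi-start tracking
#'
#' The missed-junction loop scenario: the detection at the loop
#' junction is absent, so single-start tracking detours and skips the
#' loop, while restarting every `incrementostep` frames rebuilds it as
#' sub-trajectories that paragon splicing assembles.  Coverage is the
#' fraction of visible ground-truth loop samples reproduced (same
#' frame, within `tol_px`).
#'
#' @param seed Seed for rendering noise.
#' @param incrementostep Restart spacing for the multi-start pass.
#' @param tol_px Matching tolerance.
#' @return List with `coverage_single`, `coverage_multi` (percent of
#'   visible loop events covered) and `n_loop_events`.
#' @export
benchmark_loop_recovery <- function(seed = 1L, incrementostep = 10,
                                    tol_px = 3) {
  scene <- simulate_loops_crossings("loop_with_missed_junction",
                                    loop_radius_px = 8, step_px = 2,
                                    straight_steps = 8, seed = seed)
  p <- scene$particles[[1]]
  loop_fr <- attr(p, "loop_frames")
  vis_loop <- loop_fr[p$visible[loop_fr + 1]]
  stack <- render_scene(scene, render_params(
    spot_sigma_px = 1.5, amplitude = 0.7, background_level = 0.08,
    gain = 400))
  det <- .auto_segment(stack, 1)
  if (is.null(det)) stop("segmentation failed in loop benchmark")
  cover <- function(df) {
    mean(vapply(vis_loop, function(f) {
      rows <- df[df$frame == f, , drop = FALSE]
      nrow(rows) > 0 &&
        any(sqrt((rows$row - p$row[f + 1])^2 +
                 (rows$col - p$col[f + 1])^2) <= tol_px)
    }, logical(1)))
  }
  single <- track_all(det, linking_params(incrementostep = 0))
  multi <- track_all(det, linking_params(incrementostep = incrementostep))
  cross <- find_crossings(multi, dx = 3, dy = 3, dt = 1)
  g <- cross$groups[[which.max(lengths(cross$groups))]]
  segs <- split_paragon(build_paragon(multi, g), threshold_paragon = 3)
  list(coverage_single = 100 * cover(as.data.frame(single)),
       coverage_multi = 100 * cover(do.call(rbind, segs)),
       n_loop_events = length(vis_loop))
}
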