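# Trajectory statistics: for Brownian motion the per-axis displacement
# over a lag tau is Gaussian with variance 2*D*tau, so the normalized
# displacements u = dx / sqrt(tau) (and dy / sqrt(tau)) are Gaussian with
# variance 2*D whatever the lag.  Consecutive detections do not always
# correspond to consecutive frames (a target may not move, or may be
# missed, for several frames); each displacement is normalized by its own
# actual lag.

#' Normalized displacements of a trajectory set
#'
#' For each pair of consecutive samples of each trajectory, emits
#' `u_x = (col_{i+1} - col_i) * pixel_size_um / sqrt(tau)` and the
#' analogous `u_y` from the row difference, with
#' `tau = (frame_{i+1} - frame_i) * frame_interval_s`.
#'
#' When positions are coarse relative to the step size (step standard
#' deviation of a pixel or more), multi-frame lags arise mostly from
#' shell-escape recaptures of the tracker rather than from genuinely
#' motionless targets, and contaminate the short-time statistics;
#' `max_gap_frames = 1` restricts the samples to consecutive-frame
#' detections (the short-time behavior the fit is meant for).
#'
#' @param trajs A [trajectory_set()].
#' @param pixel_size_um Pixel size in micrometres (defaults to the value
#'   recorded in `trajs`).
#' @param frame_interval_s Frame interval in seconds (same default rule).
#' @param max_gap_frames Maximum lag, in frames, for a displacement pair
#'   to be emitted; `Inf` (default) keeps all consecutive-sample pairs,
#'   each normalized by its own actual lag.
#' @return Data frame with columns `u` (um s^-1/2), `axis` (`"x"`/`"y"`)
#'   and `tau_s`.
#' @export
normalized_displacements <- function(trajs, pixel_size_um = NULL,
                                     frame_interval_s = NULL,
                                     max_gap_frames = Inf) {
  stopifnot(inherits(trajs, "trajectory_set"))
  if (is.null(pixel_size_um)) pixel_size_um <- trajs$pixel_size_um
  if (is.null(frame_interval_s)) frame_interval_s <- trajs$frame_interval_s
  stopifnot(is.numeric(pixel_size_um), pixel_size_um > 0,
            is.numeric(frame_interval_s), frame_interval_s > 0)
  out <- list()
  for (tr in trajs$trajectories) {
    s <- tr$samples
    if (nrow(s) < 2) next
    gap <- diff(s[, "frame"])
    keep <- gap <= max_gap_frames
    if (!any(keep)) next
    tau <- (gap * frame_interval_s)[keep]
    ux <- (diff(s[, "col"])[keep]) * pixel_size_um / sqrt(tau)
    uy <- (diff(s[, "row"])[keep]) * pixel_size_um / sqrt(tau)
    out[[length(out) + 1L]] <- data.frame(
      u = c(ux, uy), axis = rep(c("x", "y"), each = length(tau)),
      tau_s = c(tau, tau))
  }
  if (!length(out))
    return(data.frame(u = numeric(0), axis = character(0), tau_s = numeric(0)))
  do.call(rbind, out)
}

#' Global Gaussian fit of the diffusion coefficient
#'
#' Histograms the x- and y-axis normalized displacements on common bins
#' and fits, by weighted nonlinear least squares with statistical
#' (Poisson) weights `1 / max(count, 1)`, the trial function
#' `G(u) = A * exp(-u^2 / (4 D))` with per-axis amplitudes `A_x`, `A_y`
#' and a single shared `D`.
#'
#' @param samples Data frame from [normalized_displacements()]; at least
#'   50 samples spanning both axes are required.
#' @param n_bins Number of histogram bins; `NULL` (default) uses the
#'   Freedman-Diaconis rule on the pooled samples.
#' @return A `diffusion_fit` with fields `D` (um^2/s), `D_stderr`,
#'   `amplitude` (named `A_x`, `A_y`), `n_samples`, `bin_edges`,
#'   `bin_counts` (matrix, axes in rows) and the underlying `fit`.
#' @export
fit_gaussian_D <- function(samples, n_bins = NULL) {
  stopifnot(is.data.frame(samples), all(c("u", "axis") %in% names(samples)))
  u <- samples$u; axis <- as.character(samples$axis)
  if (length(u) < 50) stop("need at least 50 displacement samples, got ", length(u))
  if (!all(c("x", "y") %in% axis)) stop("samples must span both axes")
  if (max(u) - min(u) <= 0) stop("degenerate samples: zero spread")
  if (is.null(n_bins)) {
    h <- 2 * IQR(u) / length(u)^(1 / 3)      # Freedman-Diaconis
    if (h <= 0) h <- diff(range(u)) / 30
    n_bins <- max(11L, min(201L, ceiling(diff(range(u)) / h)))
  }
  # pixelated displacements are discrete; equal-width bins that are finer
  # than, or misaligned with, the elementary spacing produce comb or
  # merged histograms no Gaussian can fit -- center one bin on each atom
  uu <- sort(unique(u))
  edges <- NULL
  if (length(uu) > 1 && length(uu) <= 64) {
    g <- min(diff(uu))
    on_lattice <- g > 0 &&
      all(abs(diff(uu) / g - round(diff(uu) / g)) < 1e-6)
    if (on_lattice) {
      n_lat <- round((uu[length(uu)] - uu[1]) / g) + 1L
      edges <- seq(uu[1] - g / 2, by = g, length.out = n_lat + 1L)
      n_bins <- n_lat
    }
  }
  hist_counts <- function(edges) {
    nb <- length(edges) - 1L
    list(mids = (edges[-1] + edges[-length(edges)]) / 2,
         cx = tabulate(findInterval(u[axis == "x"], edges,
                                    rightmost.closed = TRUE), nbins = nb),
         cy = tabulate(findInterval(u[axis == "y"], edges,
                                    rightmost.closed = TRUE), nbins = nb))
  }
  if (is.null(edges)) {
    lim <- max(abs(u)) * (1 + 1e-9)
    repeat {
      edges <- seq(-lim, lim, length.out = n_bins + 1L)
      hc <- hist_counts(edges)
      tot <- hc$cx + hc$cy
      occ <- range(which(tot > 0))
      frac_empty <- mean(tot[occ[1]:occ[2]] == 0)
      if (frac_empty <= 0.25 || n_bins <= 6L) break
      n_bins <- max(6L, n_bins %/% 2L)   # comb-ridden: coarsen
    }
  }
  hc <- hist_counts(edges)
  mids <- hc$mids; cx <- hc$cx; cy <- hc$cy
  n_bins <- length(mids)
  df <- data.frame(mid = c(mids, mids), count = c(cx, cy),
                   is_x = rep(c(1, 0), each = n_bins))
  w <- 1 / pmax(df$count, 1)
  D0 <- var(u) / 2
  if (D0 <= 0) stop("degenerate samples: zero variance")
  start <- list(Ax = max(cx), Ay = max(cy), D = D0)
  fit <- tryCatch(
    nls(count ~ (is_x * Ax + (1 - is_x) * Ay) * exp(-mid^2 / (4 * D)),
        data = df, start = start, weights = w, algorithm = "port",
        lower = c(Ax = 1e-12, Ay = 1e-12, D = 1e-12),
        control = list(maxiter = 200)),
    error = function(e) stop("Gaussian fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  co <- coef(fit)
  se <- sqrt(diag(vcov(fit)))[["D"]]
  structure(list(D = unname(co[["D"]]), D_stderr = se,
                 amplitude = c(A_x = unname(co[["Ax"]]),
                               A_y = unname(co[["Ay"]])),
                 n_samples = length(u), n_bins = n_bins,
                 bin_edges = edges,
                 bin_counts = rbind(x = cx, y = cy),
                 fit = fit),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("diffusion_fit: D = %.4g +/- %.2g um^2/s (%d samples, %d bins)\n",
              x$D, x$D_stderr, x$n_samples, x$n_bins))
  invisible(x)
}
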