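# Quantitative readouts: spiral-tip tracking, rotation-frequency estimation,
# meander-pattern classification and drift-velocity estimation.
#
# The spiral tip is defined as the intersection of the V = V_iso isoline
# with its own temporal zero-change line (dV/dt = 0 between consecutive
# frames), located sub-grid by intersecting the two contour polylines.

# all pairwise intersections between two sets of polyline segments
segment_intersections <- function(A, B) {
  # A, B: matrices with columns x1, y1, x2, y2
  if (nrow(A) == 0L || nrow(B) == 0L) return(matrix(numeric(0), 0, 2))
  out <- vector("list", nrow(A))
  bx1 <- pmin(B[, 1], B[, 3]); bx2 <- pmax(B[, 1], B[, 3])
  by1 <- pmin(B[, 2], B[, 4]); by2 <- pmax(B[, 2], B[, 4])
  for (a in seq_len(nrow(A))) {
    ax1 <- min(A[a, 1], A[a, 3]); ax2 <- max(A[a, 1], A[a, 3])
    ay1 <- min(A[a, 2], A[a, 4]); ay2 <- max(A[a, 2], A[a, 4])
    cand <- which(bx1 <= ax2 & bx2 >= ax1 & by1 <= ay2 & by2 >= ay1)
    if (!length(cand)) next
    p <- A[a, 1:2]; r <- A[a, 3:4] - p
    q1 <- B[cand, 1, drop = FALSE]; q2 <- B[cand, 2, drop = FALSE]
    sx <- B[cand, 3] - B[cand, 1]; sy <- B[cand, 4] - B[cand, 2]
    denom <- r[1] * sy - r[2] * sx
    ok <- abs(denom) > 1e-14
    if (!any(ok)) next
    qpx <- q1[ok] - p[1]; qpy <- q2[ok] - p[2]
    dn <- denom[ok]
    tt <- (qpx * sy[ok] - qpy * sx[ok]) / dn
    uu <- (qpx * r[2] - qpy * r[1]) / dn
    hit <- tt >= 0 & tt <= 1 & uu >= 0 & uu <= 1
    if (any(hit))
      out[[a]] <- cbind(p[1] + tt[hit] * r[1], p[2] + tt[hit] * r[2])
  }
  pts <- do.call(rbind, out)
  if (is.null(pts)) matrix(numeric(0), 0, 2) else pts
}

contour_segments <- function(x, y, z, level) {
  cl <- contourLines(x = x, y = y, z = z, levels = level)
  if (!length(cl)) return(matrix(numeric(0), 0, 4))
  do.call(rbind, lapply(cl, function(c0) {
    n <- length(c0$x)
    if (n < 2L) return(NULL)
    cbind(c0$x[-n], c0$y[-n], c0$x[-1], c0$y[-1])
  }))
}

# cluster nearby intersection points (contour jitter) into distinct tips
cluster_points <- function(pts, eps) {
  if (nrow(pts) <= 1L) return(pts)
  used <- rep(FALSE, nrow(pts))
  out <- NULL
  for (k in seq_len(nrow(pts))) {
    if (used[k]) next
    d <- sqrt((pts[, 1] - pts[k, 1])^2 + (pts[, 2] - pts[k, 2])^2)
    grp <- !used & d < eps
    used[grp] <- TRUE
    out <- rbind(out, colMeans(pts[grp, , drop = FALSE]))
  }
  out
}

#' Locate spiral tips in a pair of consecutive voltage frames
#'
#' Intersects the `V = V_iso` isoline of the first frame with the temporal
#' zero-change line (`V2 - V1 = 0`), returning the distinct intersection
#' points (phase singularities).
#'
#' @param V1,V2 Voltage fields at consecutive frames, matrices indexed
#'   `[x, y]`.
#' @param dx Node spacing in cm.
#' @param V_iso Isoline voltage in mV (default -40).
#' @return Matrix with columns `x`, `y` (cm), one row per detected tip
#'   (possibly zero rows).
#' @export
find_tips <- function(V1, V2, dx, V_iso = -40) {
  stopifnot(all(dim(V1) == dim(V2)))
  xs <- (seq_len(nrow(V1)) - 1) * dx
  ys <- (seq_len(ncol(V1)) - 1) * dx
  iso <- contour_segments(xs, ys, V1, V_iso)
  dvz <- contour_segments(xs, ys, V2 - V1, 0)
  pts <- segment_intersections(iso, dvz)
  pts <- cluster_points(pts, eps = 3 * dx)
  colnames(pts) <- c("x", "y")
  pts
}

#' Track the spiral tip through a snapshot stack
#'
#' Applies [find_tips()] to each pair of consecutive frames and links
#' detections into a single trajectory by nearest-to-previous continuity
#' (this artifact hosts a single spiral).  Frames with no detection are
#' recorded as gaps; the trajectory is not broken.
#'
#' @param snapshots 3D array `nx x ny x n_frames` of voltage fields (e.g.
#'   the `snapshots` element of a [simulate_tissue()] result).
#' @param times Frame times in ms (length `n_frames`).
#' @param dx Node spacing in cm.
#' @param V_iso Isoline voltage in mV.
#' @return Object of class `"tip_trajectory"`: data frame with columns `t`,
#'   `x`, `y` (one row per frame with a detection), with attributes
#'   `"method"` and `"n_gaps"`.
#' @export
track_tip <- function(snapshots, times, dx, V_iso = -40) {
  stopifnot(length(dim(snapshots)) == 3L, dim(snapshots)[3] == length(times))
  nf <- length(times)
  if (nf < 2L) stop("need at least 2 frames")
  rows <- vector("list", nf - 1L)
  prev <- NULL
  gaps <- 0L
  for (k in seq_len(nf - 1L)) {
    tips <- find_tips(snapshots[, , k], snapshots[, , k + 1L], dx, V_iso)
    if (nrow(tips) == 0L) { gaps <- gaps + 1L; next }
    if (!is.null(prev) && nrow(tips) > 1L) {
      d <- sqrt((tips[, 1] - prev[1])^2 + (tips[, 2] - prev[2])^2)
      tips <- tips[which.min(d), , drop = FALSE]
    } else if (nrow(tips) > 1L) {
      # no history: prefer the most central detection
      cx <- mean(range(tips[, 1])); cy <- mean(range(tips[, 2]))
      d <- sqrt((tips[, 1] - cx)^2 + (tips[, 2] - cy)^2)
      tips <- tips[which.min(d), , drop = FALSE]
    }
    prev <- tips[1L, ]
    rows[[k]] <- data.frame(t = times[k], x = prev[1], y = prev[2])
  }
  traj <- do.call(rbind, rows)
  if (is.null(traj)) traj <- data.frame(t = numeric(0), x = numeric(0), y = numeric(0))
  structure(traj, class = c("tip_trajectory", "data.frame"),
            method = sprintf("isoline(V=%g) x zero-change line", V_iso),
            n_gaps = gaps)
}

#' @export
print.tip_trajectory <- function(x, ...) {
  cat(sprintf("<tip_trajectory> %d samples, %d gap frame(s), method: %s\n",
              nrow(x), attr(x, "n_gaps"), attr(x, "method")))
  if (nrow(x)) {
    cat(sprintf("  t in [%.1f, %.1f] ms;  x in [%.3f, %.3f] cm;  y in [%.3f, %.3f] cm\n",
                min(x$t), max(x$t), min(x$x), max(x$x), min(x$y), max(x$y)))
  }
  invisible(x)
}

#' @export
plot.tip_trajectory <- function(x, ...) {
  plot(x$x, x$y, type = "l", asp = 1, xlab = "x [cm]", ylab = "y [cm]", ...)
  points(x$x[1], x$y[1], pch = 16, col = "forestgreen")
  points(x$x[nrow(x)], x$y[nrow(x)], pch = 16, col = "firebrick")
  invisible(x)
}

#' Estimate rotation frequency from a voltage trace
#'
#' Primary method: upstroke intervals, `f = 1000 (n-1)/(t_n - t_1)` from the
#' upward crossings of `thr` (sub-sample by linear interpolation).  The
#' spectral cross-check takes the dominant periodogram peak.
#'
#' @param t Sample times in ms.
#' @param V Voltage samples in mV.
#' @param method `"upstroke"` (default) or `"spectral"`.
#' @param thr Upstroke threshold in mV (default -40).
#' @return Object of class `"freq_estimate"`: list with `f` (Hz), `method`,
#'   `window` (ms), `n_upstrokes`, `upstroke_times`.
#' @export
estimate_frequency <- function(t, V, method = c("upstroke", "spectral"),
                               thr = -40) {
  method <- match.arg(method)
  stopifnot(length(t) == length(V), length(t) >= 4L)
  i <- which(V[-1] >= thr & V[-length(V)] < thr)
  ut <- t[i] + (thr - V[i]) / (V[i + 1] - V[i]) * (t[i + 1] - t[i])
  if (method == "upstroke") {
    if (length(ut) < 3L)
      stop("insufficient data: need at least 3 upstrokes in the window, found ",
           length(ut))
    f <- 1000 * (length(ut) - 1L) / (ut[length(ut)] - ut[1L])
  } else {
    dt <- median(diff(t))
    sp <- spec.pgram(ts(V - mean(V), deltat = dt / 1000), plot = FALSE,
                     taper = 0.1, detrend = TRUE, pad = 7)
    f <- sp$freq[which.max(sp$spec)]
  }
  structure(list(f = f, method = method, window = c(min(t), max(t)),
                 n_upstrokes = length(ut), upstroke_times = ut),
            class = "freq_estimate")
}

#' @export
print.freq_estimate <- function(x, ...) {
  cat(sprintf("Rotation frequency: %.3f Hz (%s method, %d upstrokes, window %.0f-%.0f ms)\n",
              x$f, x$method, x$n_upstrokes, x$window[1], x$window[2]))
  invisible(x)
}

# split a trajectory into modulation cycles at the given boundary times
segment_cycles <- function(traj, boundaries) {
  boundaries <- sort(boundaries)
  cyc <- findInterval(traj$t, boundaries)
  keep <- cyc >= 1 & cyc < length(boundaries)
  split(traj[keep, , drop = FALSE], cyc[keep])
}

#' Classify the meander pattern of a tip trajectory
#'
#' Segments the trajectory into modulation cycles (one cycle per light
#' pulse, taken from the event log; or a fixed `period`), computes per-cycle
#' mean positions and the turning angle between consecutive per-cycle
#' displacement vectors, and labels the pattern:
#' \itemize{
#'   \item near-zero net displacement with closed orbit: `"circular"`;
#'   \item consistent displacement with near-zero turning: `"linear_drift"`;
#'   \item rotating displacement with petals pointing away from the pattern
#'     centroid: `"hypocycloid_outward"` (overdrive pacing, fp > fs);
#'   \item rotating displacement with petals pointing toward the centroid:
#'     `"epicycloid_inward"` (underdrive pacing, fp < fs).
#' }
#' Petal direction is measured by the sign of the radial excursion of each
#' cycle relative to the cycle-boundary (cusp) radius about the pattern
#' centroid.
#'
#' @param traj A `"tip_trajectory"`.
#' @param events Optional event log (`data.frame` with `t_on`) from a
#'   [simulate_tissue()] run; pulse onsets define the modulation cycles.
#' @param period Cycle length in ms, used if `events` is `NULL`.
#' @param centroid Optional reference point `c(x, y)` (cm) for petal
#'   direction (e.g. the feedback electrode); default is the trajectory
#'   centroid.
#' @return Object of class `"meander_class"`: list with `label`,
#'   `petal_count`, `drift` (cm/s vector or `NULL`), `turning_deg` (mean
#'   absolute turning angle), `radial_excursion` (mean signed petal
#'   excursion, cm) and the per-cycle positions.
#' @export
classify_meander <- function(traj, events = NULL, period = NULL,
                             centroid = NULL) {
  stopifnot(inherits(traj, "tip_trajectory"))
  if (!is.null(events) && nrow(events) >= 3L) {
    bounds <- events$t_on
  } else if (!is.null(period)) {
    bounds <- seq(min(traj$t), max(traj$t), by = period)
  } else stop("need either an event log with >= 3 pulses or a cycle period")
  if (length(bounds) < 4L) stop("need at least 3 modulation cycles")
  segs <- segment_cycles(traj, bounds)
  segs <- segs[vapply(segs, nrow, 1L) >= 2L]
  if (length(segs) < 3L) stop("trajectory too short: fewer than 3 usable cycles")

  centers <- t(vapply(segs, function(s) c(mean(s$x), mean(s$y)), numeric(2)))
  tmid <- vapply(segs, function(s) mean(s$t), numeric(1))
  disp <- diff(centers)
  step_len <- sqrt(rowSums(disp^2))
  ang <- atan2(disp[, 2], disp[, 1])
  turn <- diff(ang)
  turn <- (turn + pi) %% (2 * pi) - pi       # wrap to (-pi, pi]
  mean_turn <- mean(abs(turn)) * 180 / pi

  # scale of one cycle's orbit, to judge whether the pattern translates
  orbit_r <- mean(vapply(segs, function(s)
    mean(sqrt((s$x - mean(s$x))^2 + (s$y - mean(s$y))^2)), numeric(1)))
  net <- sqrt(sum((centers[nrow(centers), ] - centers[1, ])^2))
  path <- sum(step_len)

  if (is.null(centroid)) centroid <- colMeans(centers)
  # signed petal excursion: the petal apex of each cycle is its
  # maximum-curvature point; apices farther from the pattern centroid than
  # the cycle's median radius mean outward-pointing petals (and conversely)
  excur_k <- vapply(segs, function(s) {
    r <- sqrt((s$x - centroid[1])^2 + (s$y - centroid[2])^2)
    n <- length(r)
    if (n < 5) return(NA_real_)
    dx1 <- diff(s$x); dy1 <- diff(s$y)
    dx2 <- diff(dx1); dy2 <- diff(dy1)
    sp <- (dx1[-1]^2 + dy1[-1]^2)^1.5
    kap <- abs(dx1[-1] * dy2 - dy1[-1] * dx2) / pmax(sp, 1e-12)
    apex <- which.max(kap) + 1L
    r[apex] - median(r)
  }, numeric(1))
  excur <- mean(excur_k, na.rm = TRUE)

  label <-
    if (net < 0.5 * orbit_r && path < 2 * orbit_r) "circular"
    else if (mean_turn < 35 && net > 0.5 * path) "linear_drift"
    else if (excur > 0) "hypocycloid_outward"
    else "epicycloid_inward"

  drift <- NULL
  if (label == "linear_drift") {
    dtms <- (tmid[length(tmid)] - tmid[1])
    drift <- (centers[nrow(centers), ] - centers[1, ]) / dtms * 1000  # cm/s
  }
  structure(list(label = label, petal_count = length(segs), drift = drift,
                 turning_deg = mean_turn, radial_excursion = excur,
                 net_displacement = net, orbit_radius = orbit_r,
                 centers = centers, t_mid = tmid, centroid = centroid),
            class = "meander_class")
}

#' @export
print.meander_class <- function(x, ...) {
  cat(sprintf("Meander pattern: %s  (%d cycles, mean turning %.0f deg, radial excursion %+.4f cm)\n",
              x$label, x$petal_count, x$turning_deg, x$radial_excursion))
  if (!is.null(x$drift))
    cat(sprintf("  drift velocity: %.3f cm/s at %.0f deg\n",
                sqrt(sum(x$drift^2)), atan2(x$drift[2], x$drift[1]) * 180 / pi))
  invisible(x)
}

#' Drift velocity of a linearly drifting spiral
#'
#' Least-squares line through the per-cycle mean tip positions; speed is the
#' net displacement over the elapsed time.
#'
#' @param traj A `"tip_trajectory"`.
#' @param events,period Cycle segmentation, as in [classify_meander()].
#' @return List of class `"drift_estimate"` with `speed` (cm/s),
#'   `direction` (unit vector, or `NA` with a warning when the trajectory
#'   does not drift) and `angle_deg`.
#' @export
drift_velocity <- function(traj, events = NULL, period = NULL) {
  cls <- classify_meander(traj, events = events, period = period)
  centers <- cls$centers; tmid <- cls$t_mid
  dtms <- tmid[length(tmid)] - tmid[1]
  net_v <- (centers[nrow(centers), ] - centers[1, ]) / dtms * 1000
  speed <- sqrt(sum(net_v^2))
  if (cls$label != "linear_drift") {
    warning("trajectory is not classified as linear drift; direction undefined")
    dir <- c(NA_real_, NA_real_)
  } else dir <- net_v / speed
  structure(list(speed = speed, direction = dir,
                 angle_deg = atan2(net_v[2], net_v[1]) * 180 / pi,
                 label = cls$label),
            class = "drift_estimate")
}

#' @export
print.drift_estimate <- function(x, ...) {
  cat(sprintf("Drift: %.3f cm/s%s\n", x$speed,
              if (all(is.finite(x$direction)))
                sprintf(" at %.0f deg", x$angle_deg) else " (direction undefined)"))
  invisible(x)
}
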