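#' Configuration of the greedy track-merging algorithm
#'
#' All thresholds of the temporally greedy gap-closing procedure. Defaults
#' follow the published tracking protocol: maximum merge gap 30 frames,
#' fluctuation radius 3 px (plus-end Brownian wobble during a pause), pauses
#' up to 15 frames, net speed caps of 2 px/frame for long gaps and 5 px/frame
#' for short gaps (up to 6 frames), catastrophes bridged up to 10 px,
#' perpendicular offset cap 10 px, direction gates of 40 deg when either
#' segment is short and ~20 deg otherwise (30 deg between tracks flanking a
#' catastrophe, 90 deg fallback for the gap axis), cost base 1.03, and a
#' tubulin evidence cutoff of 20 x mean processed intensity divided by the
#' 8.8 px median gap length.
#'
#' @param dt_max maximum frame gap considered for a merge.
#' @param r_fluc fluctuation radius, px.
#' @param pause_max_frames maximum pause duration, frames.
#' @param long_gap_speed_max,short_gap_speed_max net speed caps, px/frame.
#' @param short_gap_frames_max frames defining a "short" forward gap.
#' @param catastrophe_max_dist maximum shrinkage bridged, px.
#' @param d_perp_max maximum perpendicular offset, px.
#' @param angle_small_track_deg,angle_strict_deg,angle_catastrophe_deg,catastrophe_fallback_deg
#'   direction gates, degrees.
#' @param cost_base base of the temporal cost factor
#'   \code{cost_base^t_gap * D_min}.
#' @param i_cutoff_factor,median_gap_px tubulin evidence cutoff parameters:
#'   \code{I_cutoff = i_cutoff_factor * mean(tubulin) / median_gap_px}.
#' @param min_traj_frames trajectories shorter than this are discarded after
#'   merging.
#' @return a \code{merge_config} list.
#' @export
merge_config <- function(dt_max = 30, r_fluc = 3, pause_max_frames = 15,
                         long_gap_speed_max = 2, short_gap_frames_max = 6,
                         short_gap_speed_max = 5, catastrophe_max_dist = 10,
                         d_perp_max = 10, angle_small_track_deg = 40,
                         angle_strict_deg = 20, angle_catastrophe_deg = 30,
                         catastrophe_fallback_deg = 90, cost_base = 1.03,
                         i_cutoff_factor = 20, median_gap_px = 8.8,
                         min_traj_frames = 6) {
  cfg <- as.list(environment())
  stopifnot(all(vapply(cfg, function(v) is.numeric(v) && v > 0, TRUE)))
  structure(cfg, class = "merge_config")
}

#' Tubulin evidence cutoff
#'
#' \code{I_cutoff = i_cutoff_factor * mean(processed tubulin) /
#' median_gap_px}. Isolated here because the precedence of the published
#' recipe is ambiguous; this reading is the one used throughout.
#'
#' @param processed_tubulin matrix or \code{image_stack} of processed tubulin.
#' @param config a \code{merge_config}.
#' @return the cutoff, au/px.
#' @export
i_cutoff <- function(processed_tubulin, config = merge_config()) {
  img <- if (inherits(processed_tubulin, "image_stack"))
    processed_tubulin$data else processed_tubulin
  config$i_cutoff_factor * mean(img) / config$median_gap_px
}

# bilinear interpolation at 0-based continuous positions (vectors x, y)
bilinear_interp <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  x <- pmin(pmax(x, 0), W - 1); y <- pmin(pmax(y, 0), H - 1)
  x0 <- pmin(floor(x), W - 2); y0 <- pmin(floor(y), H - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]; i01 <- img[cbind(y0 + 1, x0 + 2)]
  i10 <- img[cbind(y0 + 2, x0 + 1)]; i11 <- img[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Mean line-integral intensity along a chord
#'
#' Samples the image at ~1 px spacing along the straight chord between two
#' points, sums the interpolated intensities and divides by the chord length.
#' A zero-length chord returns the intensity at the point.
#'
#' @param image matrix (H x W) of intensities.
#' @param p1,p2 c(x, y) 0-based pixel positions.
#' @return mean intensity per pixel of chord, au/px.
#' @export
line_integral_intensity <- function(image, p1, p2) {
  d <- sqrt(sum((p2 - p1)^2))
  if (d < 1e-9) return(bilinear_interp(image, p1[1], p1[2]))
  n <- max(2L, ceiling(d) + 1L)
  ts <- seq(0, 1, length.out = n)
  xs <- p1[1] + ts * (p2[1] - p1[1])
  ys <- p1[2] + ts * (p2[2] - p1[2])
  vals <- bilinear_interp(image, xs, ys)
  # trapezoid weights so a uniform image returns its own value exactly
  wts <- rep(d / (n - 1), n); wts[c(1, n)] <- wts[c(1, n)] / 2
  sum(vals * wts) / d
}

# total-least-squares direction of a point sequence, oriented by time order
tls_direction <- function(x, y) {
  n <- length(x)
  if (n < 2) return(c(NA_real_, NA_real_))
  xc <- x - mean(x); yc <- y - mean(y)
  cv <- cbind(c(sum(xc * xc), sum(xc * yc)), c(sum(xc * yc), sum(yc * yc)))
  ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  # orient from early to late
  if (sum(ev * c(x[n] - x[1], y[n] - y[1])) < 0) ev <- -ev
  ev / sqrt(sum(ev^2))
}

angle_deg <- function(u, v) {
  d <- sum(u * v)
  acos(pmin(pmax(d, -1), 1)) * 180 / pi
}

polyline_length <- function(x, y) sum(sqrt(diff(x)^2 + diff(y)^2))

#' Merge track segments into complete trajectories
#'
#' The temporally greedy gap-closing procedure: segments are processed in
#' order of appearance; for each trajectory end, candidate later-starting
#' segments within \code{dt_max} frames are classified as zero-gap, pause,
#' forward gap or catastrophe under the geometric gates in
#' \code{\link{merge_config}}. Pauses (ends within the fluctuation radius)
#' qualify when the tubulin line integral across the gap exceeds a quarter
#' of the evidence cutoff or the ends are within ~1 px; forward gaps and
#' catastrophes must carry tubulin evidence above the full cutoff. The
#' qualifying candidate minimizing \code{cost_base^t_gap * D_min} is merged. Gaps are closed by
#' linear interpolation; trajectories shorter than \code{min_traj_frames}
#' frames are discarded.
#'
#' @param segments a \code{segment_set} data.frame (segment_id, frame, x, y)
#'   from \code{\link{link_comets}} or \code{\link{fragment_tracks}}
#'   detections (rename columns x_px/y_px to x/y).
#' @param processed_tubulin matrix, \code{image_stack}, or NULL. Without
#'   tubulin evidence only zero-gap and ~1 px pause merges are possible and a
#'   warning is raised.
#' @param config a \code{\link{merge_config}}.
#' @return data.frame (trajectory_id, frame, x, y, interpolated, gap_class)
#'   of class \code{trajectory_set}, with attributes \code{sources} (list of
#'   segment ids per trajectory) and \code{merges} (one row per accepted
#'   merge: seg_from, seg_to, t_gap, gap_class, cost).
#' @export
merge_tracks <- function(segments, processed_tubulin = NULL,
                         config = merge_config()) {
  if (nrow(segments) == 0)
    return(structure(data.frame(trajectory_id = integer(), frame = integer(),
                                x = numeric(), y = numeric(),
                                interpolated = logical(),
                                gap_class = character()),
                     class = c("trajectory_set", "data.frame")))
  if (is.null(processed_tubulin))
    warning("no tubulin evidence: only zero-gap and ~1 px pause merges possible")
  tub <- if (inherits(processed_tubulin, "image_stack"))
    processed_tubulin$data else processed_tubulin
  icut <- if (!is.null(tub)) i_cutoff(tub, config) else Inf
  tub_frame <- function(gap_mid_frame) {
    if (is.null(tub)) return(NULL)
    if (is.matrix(tub)) return(tub)
    f <- min(max(1, round(gap_mid_frame)), dim(tub)[1])
    tub[f, , ]
  }

  segs <- split(segments[, c("frame", "x", "y")], segments$segment_id)
  segs <- lapply(segs, function(s) s[order(s$frame), ])
  sid <- as.integer(names(segs))
  start_f <- vapply(segs, function(s) s$frame[1], 0)
  ord <- order(start_f)
  segs <- segs[ord]; sid <- sid[ord]; start_f <- start_f[ord]
  consumed <- logical(length(segs))

  imt_fun <- function(p_end, p_start, gap_mid) {
    img <- tub_frame(gap_mid)
    if (is.null(img)) return(NA_real_)
    line_integral_intensity(img, p_end, p_start)
  }

  trajs <- list(); sources <- list(); merges <- list()

  for (i0 in seq_along(segs)) {
    if (consumed[i0]) next
    consumed[i0] <- TRUE
    cur <- segs[[i0]]
    cur$interpolated <- FALSE
    cur$gap_class <- "none"
    src <- sid[i0]

    repeat {
      n_cur <- nrow(cur)
      p_end <- c(cur$x[n_cur], cur$y[n_cur])
      end_f <- cur$frame[n_cur]
      nfit <- min(10, n_cur)
      dir_i <- tls_direction(cur$x[(n_cur - nfit + 1):n_cur],
                             cur$y[(n_cur - nfit + 1):n_cur])
      len_i <- polyline_length(cur$x, cur$y)

      cand_idx <- which(!consumed & start_f > end_f &
                          start_f <= end_f + config$dt_max + 1)
      if (length(cand_idx) == 0) break

      pool <- list()
      merged_this_round <- FALSE
      for (jj in cand_idx) {
        sj <- segs[[jj]]
        t_gap <- sj$frame[1] - end_f - 1
        if (t_gap < 0 || t_gap > config$dt_max) next
        p_start <- c(sj$x[1], sj$y[1])
        d_ends <- sqrt(sum((p_start - p_end)^2))
        gap_mid <- (end_f + sj$frame[1]) / 2
        nfj <- min(10, nrow(sj))
        dir_j <- tls_direction(sj$x[1:nfj], sj$y[1:nfj])
        len_j <- polyline_length(sj$x, sj$y)

        # (1) zero frame gap: ends must nearly coincide
        if (t_gap == 0) {
          if (d_ends <= config$r_fluc) {
            pool[[length(pool) + 1L]] <- list(jj = jj, t_gap = 0,
                                              D_min = d_ends, imt = Inf,
                                              gap_class = "zero_gap")
          }
          next
        }

        # (5) pause: ends within the fluctuation radius, short enough gap.
        # Merged greedily (the earliest qualifying re-appearance wins — the
        # temporal prior): requires lattice evidence at a quarter of the
        # cutoff or near-coincident ends, and a compatible resumed direction.
        if (d_ends <= config$r_fluc && t_gap <= config$pause_max_frames) {
          if (len_i > 3 * config$r_fluc && len_j > 3 * config$r_fluc &&
              !anyNA(dir_i) && !anyNA(dir_j) &&
              angle_deg(dir_i, dir_j) > config$angle_small_track_deg) next
          imt <- imt_fun(p_end, p_start, gap_mid)
          ok <- d_ends <= 1 ||
            (!is.null(tub) && !is.na(imt) && imt > icut / 4)
          if (ok) {
            cur <- append_merge(cur, sj, "pause")
            merges[[length(merges) + 1L]] <-
              data.frame(seg_from = src[length(src)], seg_to = sid[jj],
                         t_gap = t_gap, gap_class = "pause",
                         cost = config$cost_base^t_gap * d_ends)
            src <- c(src, sid[jj])
            consumed[jj] <- TRUE
            merged_this_round <- TRUE
            break
          }
          next
        }

        if (anyNA(dir_i) || anyNA(dir_j)) next
        dir_ij <- (p_start - p_end) / d_ends
        backward <- sum((p_start - p_end) * dir_i) < 0

        if (!backward) {
          # (2) long segments: end of i must be i's closest point to start
          # of j (inapplicable to catastrophes, where the continuation
          # starts behind the end)
          if (len_i > 3 * config$r_fluc && len_j > 3 * config$r_fluc) {
            dists <- sqrt((cur$x - p_start[1])^2 + (cur$y - p_start[2])^2)
            if (min(dists) < dists[n_cur] - 1) next
          }
          # (3) forward-direction gates; chords below the fluctuation scale
          # carry no usable direction (as for zero-gaps), so only the track
          # directions are compared there
          small <- len_i <= 3 * config$r_fluc || len_j <= 3 * config$r_fluc
          gate <- if (small) config$angle_small_track_deg else config$angle_strict_deg
          if (angle_deg(dir_i, dir_j) > gate) next
          if (d_ends > 2 * config$r_fluc &&
              (angle_deg(dir_i, dir_ij) > gate ||
               angle_deg(dir_j, dir_ij) > gate)) next
          # (6) forward gap speed caps
          ok_speed <- d_ends <= config$long_gap_speed_max * t_gap ||
            (t_gap <= config$short_gap_frames_max &&
               d_ends <= config$short_gap_speed_max * t_gap)
          if (!ok_speed) next
          d_perp <- abs(-(p_start[1] - p_end[1]) * dir_i[2] +
                          (p_start[2] - p_end[2]) * dir_i[1])
          if (d_perp > config$d_perp_max) next
          imt <- imt_fun(p_end, p_start, gap_mid)
          pool[[length(pool) + 1L]] <- list(jj = jj, t_gap = t_gap,
                                            D_min = d_ends, imt = imt,
                                            gap_class = "forward_gap")
          next
        }

        # (4) catastrophe: continuation starts behind the end of i, track
        # directions similar, shrinkage bounded. The comet re-appears on the
        # lattice it shrank along, so the continuation must start close to
        # track i's recorded path.
        if (angle_deg(dir_i, dir_j) <= config$angle_catastrophe_deg &&
            d_ends <= config$catastrophe_max_dist &&
            min(sqrt((cur$x - p_start[1])^2 +
                     (cur$y - p_start[2])^2)) <= 2 * config$r_fluc) {
          if (d_ends > 2 * config$r_fluc) {
            # the shrink-back chord must be collinear with both tracks
            # (unsigned axis angles; the fallback bound caps the worst case)
            axis_ang <- acos(pmin(abs(sum(dir_ij * dir_i)), 1)) * 180 / pi
            axis_ang_j <- acos(pmin(abs(sum(dir_ij * dir_j)), 1)) * 180 / pi
            if (axis_ang > config$angle_catastrophe_deg ||
                axis_ang_j > config$angle_catastrophe_deg ||
                axis_ang > config$catastrophe_fallback_deg) next
          }
          d_perp <- abs(-(p_start[1] - p_end[1]) * dir_i[2] +
                          (p_start[2] - p_end[2]) * dir_i[1])
          if (d_perp > config$d_perp_max) next
          imt <- imt_fun(p_end, p_start, gap_mid)
          pool[[length(pool) + 1L]] <- list(jj = jj, t_gap = t_gap,
                                            D_min = d_ends, imt = imt,
                                            gap_class = "catastrophe")
        }
      }
      if (merged_this_round) next

      if (length(pool) == 0) break
      # tubulin evidence gate, then minimum cost
      ok <- vapply(pool, function(p)
        p$gap_class %in% c("zero_gap", "pause") ||
          (!is.null(tub) && !is.na(p$imt) && p$imt >= icut), TRUE)
      pool <- pool[ok]
      if (length(pool) == 0) break
      costs <- vapply(pool, function(p) config$cost_base^p$t_gap * p$D_min, 0)
      best <- pool[[which.min(costs)]]
      sj <- segs[[best$jj]]
      cur <- append_merge(cur, sj, best$gap_class)
      merges[[length(merges) + 1L]] <-
        data.frame(seg_from = src[length(src)], seg_to = sid[best$jj],
                   t_gap = best$t_gap, gap_class = best$gap_class,
                   cost = min(costs))
      src <- c(src, sid[best$jj])
      consumed[best$jj] <- TRUE
    }

    trajs[[length(trajs) + 1L]] <- cur
    sources[[length(sources) + 1L]] <- src
  }

  keep <- vapply(trajs, nrow, 0L) >= config$min_traj_frames
  trajs <- trajs[keep]; sources <- sources[keep]
  if (length(trajs) == 0)
    return(structure(data.frame(trajectory_id = integer(), frame = integer(),
                                x = numeric(), y = numeric(),
                                interpolated = logical(),
                                gap_class = character()),
                     class = c("trajectory_set", "data.frame")))
  res <- do.call(rbind, lapply(seq_along(trajs), function(i)
    cbind(trajectory_id = i, trajs[[i]])))
  rownames(res) <- NULL
  class(res) <- c("trajectory_set", class(res))
  attr(res, "sources") <- sources
  attr(res, "merges") <- if (length(merges)) do.call(rbind, merges) else
    data.frame(seg_from = integer(), seg_to = integer(), t_gap = integer(),
               gap_class = character(), cost = numeric())
  res
}

# close the gap between the current trajectory and segment sj by linear
# interpolation, then append sj
append_merge <- function(cur, sj, gap_class) {
  n <- nrow(cur)
  gap_frames <- (cur$frame[n] + 1):(sj$frame[1] - 1)
  sj$interpolated <- FALSE
  sj$gap_class <- "none"
  if (length(gap_frames) > 0 && gap_frames[1] <= gap_frames[length(gap_frames)]) {
    ts <- (gap_frames - cur$frame[n]) / (sj$frame[1] - cur$frame[n])
    fill <- data.frame(frame = gap_frames,
                       x = cur$x[n] + ts * (sj$x[1] - cur$x[n]),
                       y = cur$y[n] + ts * (sj$y[1] - cur$y[n]),
                       interpolated = TRUE, gap_class = gap_class)
    cur <- rbind(cur, fill)
  }
  rbind(cur, sj)
}

#' Smoothed length-versus-time series of a trajectory
#'
#' Fits smoothing splines to x(frame) and y(frame) — with the first and last
#' positions weighted higher — and accumulates the arc length of the fitted
#' path frame by frame.
#'
#' @param trajectory data.frame (frame, x, y) of ONE trajectory.
#' @param pixel_size um per px.
#' @param end_weight weight multiplier for the first/last points.
#' @return data.frame (frame, length_um). Falls back to the raw polyline arc
#'   length if the spline cannot be fit.
#' @export
measure_length_series <- function(trajectory, pixel_size = 0.13,
                                  end_weight = 10) {
  tr <- trajectory[order(trajectory$frame), ]
  n <- nrow(tr)
  stopifnot(n >= 6)
  w <- rep(1, n); w[c(1, n)] <- end_weight
  xs <- tryCatch({
    fx <- stats::smooth.spline(tr$frame, tr$x, w = w)
    fy <- stats::smooth.spline(tr$frame, tr$y, w = w)
    cbind(stats::predict(fx, tr$frame)$y, stats::predict(fy, tr$frame)$y)
  }, error = function(e) NULL)
  if (is.null(xs)) xs <- cbind(tr$x, tr$y)  # polyline fallback
  steps <- sqrt(diff(xs[, 1])^2 + diff(xs[, 2])^2)
  data.frame(frame = tr$frame, length_um = c(0, cumsum(steps)) * pixel_size)
}

#' Net plus-end speed of a trajectory
#'
#' Final smoothed length divided by the trajectory lifespan, um/min.
#' Trajectories spanning fewer than \code{min_frames} frames are excluded
#' (returns NA).
#'
#' @param trajectory data.frame (frame, x, y) of ONE trajectory.
#' @param pixel_size um per px.
#' @param frame_interval s per frame.
#' @param min_frames minimum span, frames.
#' @return net speed, um/min (NA when excluded).
#' @export
net_plus_end_speed <- function(trajectory, pixel_size = 0.13,
                               frame_interval = 2, min_frames = 50) {
  span <- diff(range(trajectory$frame))
  if (span + 1 < min_frames) return(NA_real_)
  len <- measure_length_series(trajectory, pixel_size)
  utils::tail(len$length_um, 1) / (span * frame_interval) * 60
}
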