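#' Ground-truth plus-end trajectories of a simulated network
#'
#' Converts a simulated network into tracking-style trajectories: one row per
#' (microtubule, frame) with the plus-end position in pixels, optionally with
#' Gaussian localization jitter emulating sub-pixel centroid error.
#'
#' @param network a \code{branch_network}.
#' @param pixel_size um per px.
#' @param frame_interval s per frame.
#' @param t_end last time rendered (defaults to the network's \code{t_end}).
#' @param jitter_sd localization noise sd, px (0.5 px is typical of centroid
#'   fitting at moderate signal-to-noise).
#' @param origin_px c(x, y) pixel position of the network origin.
#' @return data.frame (trajectory_id, frame, x, y) of class
#'   \code{trajectory_set}; frame 1 corresponds to time 0.
#' @export
network_to_trajectories <- function(network, pixel_size = 0.13,
                                    frame_interval = 2,
                                    t_end = network$t_end, jitter_sd = 0.5,
                                    origin_px = c(0, 0)) {
  m <- network$mts
  v <- network$params$v_pe
  n_frames <- floor(t_end / frame_interval) + 1
  out <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    f0 <- ceiling(m$birth_time[i] / frame_interval) + 1
    if (f0 > n_frames) next
    fr <- f0:n_frames
    tt <- (fr - 1) * frame_interval
    len <- v * (tt - m$birth_time[i])
    x <- (m$minus_x[i] + m$dir_x[i] * len) / pixel_size + origin_px[1]
    y <- (m$minus_y[i] + m$dir_y[i] * len) / pixel_size + origin_px[2]
    if (jitter_sd > 0) {
      x <- x + stats::rnorm(length(x), 0, jitter_sd)
      y <- y + stats::rnorm(length(y), 0, jitter_sd)
    }
    out[[i]] <- data.frame(trajectory_id = m$id[i], frame = fr, x = x, y = y)
  }
  res <- do.call(rbind, out)
  class(res) <- c("trajectory_set", class(res))
  res
}

#' Stochastic gap model for fragmenting ground-truth tracks
#'
#' Describes how EB1 comets vanish from real time-lapse data: pauses (the
#' plus-end stops and the comet disappears for up to \code{pause_max_frames}),
#' single-frame detection dropouts, and catastrophes (the end shrinks back by
#' up to \code{shrink_max_px} before regrowing).
#'
#' @param pause_rate per-frame probability of entering a pause.
#' @param pause_max_frames maximum pause duration, frames.
#' @param dropout_prob per-frame probability that a detection is missed.
#' @param jitter_sd positional jitter sd, px.
#' @param catastrophe_prob per-frame probability of a catastrophe.
#' @param shrink_max_px maximum shrinkage, px.
#' @param keep_short retain segments shorter than 3 frames (to exercise the
#'   downstream filtering).
#' @return a \code{gap_model} list.
#' @export
gap_model <- function(pause_rate = 0.02, pause_max_frames = 15,
                      dropout_prob = 0.05, jitter_sd = 1,
                      catastrophe_prob = 0.004, shrink_max_px = 10,
                      keep_short = TRUE) {
  structure(list(pause_rate = pause_rate, pause_max_frames = pause_max_frames,
                 dropout_prob = dropout_prob, jitter_sd = jitter_sd,
                 catastrophe_prob = catastrophe_prob,
                 shrink_max_px = shrink_max_px, keep_short = keep_short),
            class = "gap_model")
}

#' Fragment ground-truth trajectories into track segments
#'
#' Re-plays each trajectory's path with the stochastic gap model: during a
#' pause the plus-end holds its arc position and no comet is emitted; a
#' catastrophe moves the end backwards along the path before regrowth; a
#' dropout hides a single detection. The emitted detections are cut into
#' segments wherever one or more frames are missing.
#'
#' @param trajectories ground-truth trajectories from
#'   \code{\link{network_to_trajectories}} (built with \code{jitter_sd = 0};
#'   jitter is applied here).
#' @param model a \code{\link{gap_model}}.
#' @return list with \code{detections}: data.frame (frame, x_px, y_px, mt_id,
#'   segment_id, gap_class) where gap_class labels the break that PRECEDED
#'   the segment ("none", "pause", "forward_gap", "catastrophe"), and
#'   \code{segment_map}: data.frame (segment_id, mt_id).
#' @export
fragment_tracks <- function(trajectories, model = gap_model()) {
  seg_counter <- 0L
  det <- list(); smap <- list()
  for (tid in unique(trajectories$trajectory_id)) {
    tr <- trajectories[trajectories$trajectory_id == tid, , drop = FALSE]
    tr <- tr[order(tr$frame), ]
    n <- nrow(tr)
    if (n < 2) next
    # per-frame speed along the (straight) path
    step_px <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    v_px <- stats::median(step_px)
    total_len <- sum(step_px)
    ux <- (tr$x[n] - tr$x[1]) / total_len
    uy <- (tr$y[n] - tr$y[1]) / total_len

    s <- 0         # arc position along the path, px
    emitted <- logical(n); sx <- sy <- numeric(n)
    cls <- character(n)  # break class that caused the preceding gap
    pending_class <- "none"
    f <- 1L
    while (f <= n) {
      ev <- stats::runif(1)
      if (ev < model$pause_rate) {
        d <- sample(2:model$pause_max_frames, 1)
        f <- f + d
        s <- max(0, s - v_px)   # the tip holds its LAST EMITTED position
        pending_class <- "pause"
        next
      } else if (ev < model$pause_rate + model$catastrophe_prob) {
        shrink <- stats::runif(1, 2, model$shrink_max_px)
        s <- max(0, s - shrink)
        d <- sample(2:6, 1)
        f <- f + d
        pending_class <- "catastrophe"
        next
      }
      if (stats::runif(1) < model$dropout_prob) {
        if (pending_class == "none") pending_class <- "forward_gap"
        f <- f + 1L
        next
      }
      emitted[f] <- TRUE
      sx[f] <- tr$x[1] + ux * s + stats::rnorm(1, 0, model$jitter_sd)
      sy[f] <- tr$y[1] + uy * s + stats::rnorm(1, 0, model$jitter_sd)
      cls[f] <- pending_class
      pending_class <- "none"
      s <- s + v_px
      if (s > total_len) break
      f <- f + 1L
    }
    idx <- which(emitted)
    if (length(idx) == 0) next
    # split at missing frames
    brk <- c(0, which(diff(idx) > 1), length(idx))
    for (b in seq_len(length(brk) - 1)) {
      rows <- idx[(brk[b] + 1):brk[b + 1]]
      if (!model$keep_short && length(rows) < 3) next
      seg_counter <- seg_counter + 1L
      det[[length(det) + 1L]] <- data.frame(
        frame = tr$frame[rows], x_px = sx[rows], y_px = sy[rows],
        mt_id = tid, segment_id = seg_counter,
        gap_class = c(cls[rows[1]], rep("none", length(rows) - 1)))
      smap[[length(smap) + 1L]] <- data.frame(segment_id = seg_counter,
                                              mt_id = tid)
    }
  }
  list(detections = do.call(rbind, det), segment_map = do.call(rbind, smap))
}
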