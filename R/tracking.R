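#' Moving temporal median filter
#'
#' For every pixel and frame, subtracts the median intensity over a centered
#' temporal window (7 frames before and after for the default 15-frame
#' window) and clamps at zero. Static background cancels; moving comets
#' survive. Edges use truncated windows; a stack shorter than the window
#' raises a warning and uses truncated windows throughout.
#'
#' @param stack an \code{image_stack}.
#' @param window odd window length, frames.
#' @return filtered \code{image_stack}.
#' @export
temporal_median_filter <- function(stack, window = 15) {
  stopifnot(window %% 2 == 1)
  d <- dim(stack$data); T <- d[1]
  if (T < window) warning("stack shorter than the median window; using truncated windows")
  half <- (window - 1) / 2
  flat <- matrix(stack$data, nrow = T)   # T x (H*W)
  out <- matrix(0, T, ncol(flat))
  for (t in seq_len(T)) {
    w <- max(1, t - half):min(T, t + half)
    med <- apply(flat[w, , drop = FALSE], 2, stats::median)
    out[t, ] <- pmax(0, flat[t, ] - med)
  }
  res <- stack
  res$data <- array(out, d)
  res
}

#' Pre-process the tubulin channel
#'
#' Three steps emulating the standard treatment before gap-evidence
#' calculations: (1) spatial high-pass removing structures larger than
#' \code{struct_px} pixels (subtraction of a heavily blurred copy);
#' (2) ratio bleach correction from an exponential-plus-offset fit to the
#' mean intensity of a background region over time, using the fitted offset
#' as background; (3) subtraction of the first frame, where no microtubules
#' are present yet.
#'
#' @param stack tubulin \code{image_stack}.
#' @param background_roi list(rows, cols) indices of a specimen-free region;
#'   when NULL the darkest corner quadrant (by total intensity) is used.
#' @param struct_px size of structures removed by the high-pass, px.
#' @return processed \code{image_stack}. A non-convergent bleach fit falls
#'   back to no bleach correction with a warning.
#' @export
preprocess_tubulin <- function(stack, background_roi = NULL, struct_px = 60) {
  d <- dim(stack$data); T <- d[1]; H <- d[2]; W <- d[3]
  out <- array(0, d)
  for (t in seq_len(T)) {
    fr <- stack$data[t, , ]
    low <- gaussian_blur(fr, sigma = struct_px / 4, kernel = struct_px)
    out[t, , ] <- fr - low
  }
  if (is.null(background_roi)) {
    hh <- seq_len(floor(H / 4)); ww <- seq_len(floor(W / 4))
    corners <- list(list(rows = hh, cols = ww),
                    list(rows = hh, cols = W - rev(ww) + 1),
                    list(rows = H - rev(hh) + 1, cols = ww),
                    list(rows = H - rev(hh) + 1, cols = W - rev(ww) + 1))
    tot <- vapply(corners, function(cr) sum(stack$data[, cr$rows, cr$cols]), 0)
    background_roi <- corners[[which.min(tot)]]
  }
  if (T >= 4) {
    roi_mean <- vapply(seq_len(T), function(t)
      mean(stack$data[t, background_roi$rows, background_roi$cols]), 0)
    tt <- seq_len(T) - 1
    # direct least squares (robust to zero-residual inputs, unlike nls)
    sse <- function(par) {
      sum((roi_mean - (exp(par[1]) * exp(-tt / exp(par[2])) + par[3]))^2)
    }
    init <- c(log(max(roi_mean) - min(roi_mean) + 1e-6), log(T / 2),
              min(roi_mean))
    fit <- tryCatch(stats::optim(init, sse, control = list(maxit = 2000)),
                    error = function(e) NULL)
    if (is.null(fit) ||
        fit$value > 0.25 * sum((roi_mean - mean(roi_mean))^2)) {
      warning("bleach fit did not converge; skipping bleach correction")
    } else {
      cf <- c(a = exp(fit$par[1]), tau = exp(fit$par[2]), c0 = fit$par[3])
      pred <- cf["a"] * exp(-tt / cf["tau"]) + cf["c0"]
      # simple ratio correction with the fitted offset as background
      ratio <- (pred[1] - cf["c0"]) / pmax(pred - cf["c0"], 1e-9)
      for (t in seq_len(T)) out[t, , ] <- out[t, , ] * ratio[t]
    }
  }
  first <- out[1, , ]
  for (t in seq_len(T)) out[t, , ] <- out[t, , ] - first
  res <- stack
  res$data <- out
  res
}

#' Detect EB1 comets in a filtered stack
#'
#' Local maxima exceeding \code{threshold_sd} robust standard deviations of
#' the frame are kept; candidate maxima within one comet length of a brighter
#' candidate are suppressed (candidates are ranked on intensities quantized
#' to \code{step_sd} robust sd for stability). Positions are refined to
#' sub-pixel accuracy by an intensity centroid over a 5 x 5 window.
#'
#' @param stack filtered EB1 \code{image_stack}.
#' @param threshold_sd detection threshold in robust (MAD) sd units.
#' @param step_sd intensity quantization step for ranking, sd units.
#' @param min_sep suppression radius between detections, px.
#' @return data.frame (frame, x, y, intensity); x, y are 0-based pixel
#'   coordinates.
#' @export
detect_comets <- function(stack, threshold_sd = 12, step_sd = 2, min_sep = 5) {
  d <- dim(stack$data); T <- d[1]; H <- d[2]; W <- d[3]
  out <- list()
  for (t in seq_len(T)) {
    fr <- stack$data[t, , ]
    noise <- stats::mad(fr)
    if (noise == 0) noise <- stats::sd(fr) / 10 + 1e-12
    # elevation above the frame's robust baseline, in noise units
    thr <- stats::median(fr) + threshold_sd * noise
    # 8-neighbour local maxima (interior pixels only)
    ctr <- fr[2:(H - 1), 2:(W - 1)]
    ismax <- ctr >= thr &
      ctr >= fr[1:(H - 2), 2:(W - 1)] & ctr >= fr[3:H, 2:(W - 1)] &
      ctr >= fr[2:(H - 1), 1:(W - 2)] & ctr >= fr[2:(H - 1), 3:W] &
      ctr >= fr[1:(H - 2), 1:(W - 2)] & ctr >= fr[3:H, 3:W] &
      ctr >= fr[1:(H - 2), 3:W] & ctr >= fr[3:H, 1:(W - 2)]
    pos <- which(ismax, arr.ind = TRUE)
    if (nrow(pos) == 0) next
    ry <- pos[, 1] + 1; cx <- pos[, 2] + 1     # matrix indices in full frame
    val <- fr[cbind(ry, cx)]
    qval <- floor(val / (step_sd * noise))     # quantized rank
    ord <- order(-qval, -val)
    keep <- logical(length(ord))
    for (ii in ord) {
      if (any(keep & (fr_dist2(ry, cx, ry[ii], cx[ii]) < min_sep^2))) next
      keep[ii] <- TRUE
    }
    ry <- ry[keep]; cx <- cx[keep]
    # sub-pixel centroid in a 5x5 window
    xs <- ys <- ints <- numeric(length(ry))
    for (ii in seq_along(ry)) {
      rr <- max(1, ry[ii] - 2):min(H, ry[ii] + 2)
      cc <- max(1, cx[ii] - 2):min(W, cx[ii] + 2)
      win <- pmax(fr[rr, cc, drop = FALSE], 0)
      tot <- sum(win)
      ys[ii] <- sum(outer(rr - 1, rep(1, length(cc))) * win) / tot
      xs[ii] <- sum(outer(rep(1, length(rr)), cc - 1) * win) / tot
      ints[ii] <- fr[ry[ii], cx[ii]]
    }
    out[[t]] <- data.frame(frame = t, x = xs, y = ys, intensity = ints)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(frame = integer(), x = numeric(),
                                      y = numeric(), intensity = numeric())
  res
}

fr_dist2 <- function(ry, cx, r0, c0) (ry - r0)^2 + (cx - c0)^2

#' Link comet detections into track segments
#'
#' Greedy nearest-neighbour frame-to-frame assignment within a search
#' radius. Short spurious segments are filtered: segments shorter than
#' \code{min_len} frames whose net displacement is below 2 px or net speed
#' below 1 px/frame are discarded.
#'
#' @param detections data.frame (frame, x, y, ...) from
#'   \code{\link{detect_comets}}.
#' @param max_radius maximum frame-to-frame displacement, px.
#' @param min_len minimum segment length, frames.
#' @return data.frame (segment_id, frame, x, y) of class \code{segment_set}.
#' @export
link_comets <- function(detections, max_radius = 9, min_len = 3) {
  if (nrow(detections) == 0)
    return(structure(data.frame(segment_id = integer(), frame = integer(),
                                x = numeric(), y = numeric()),
                     class = c("segment_set", "data.frame")))
  frames <- sort(unique(detections$frame))
  # active tracks: list of data.frames being extended
  active <- list(); done <- list()
  for (f in frames) {
    dets <- detections[detections$frame == f, , drop = FALSE]
    used <- logical(nrow(dets))
    still <- logical(length(active))
    if (length(active) > 0) {
      # greedy: shortest link first
      last <- do.call(rbind, lapply(active, function(a) a[nrow(a), ]))
      cand <- which(last$frame == f - 1)
      if (length(cand) > 0 && nrow(dets) > 0) {
        dmat <- outer(seq_along(cand), seq_len(nrow(dets)),
                      Vectorize(function(i, j)
                        sqrt((last$x[cand[i]] - dets$x[j])^2 +
                             (last$y[cand[i]] - dets$y[j])^2)))
        repeat {
          mn <- which.min(dmat)
          if (length(mn) == 0 || dmat[mn] > max_radius) break
          ij <- arrayInd(mn, dim(dmat))
          ai <- cand[ij[1]]; dj <- ij[2]
          active[[ai]] <- rbind(active[[ai]],
                                data.frame(frame = f, x = dets$x[dj], y = dets$y[dj]))
          still[ai] <- TRUE; used[dj] <- TRUE
          dmat[ij[1], ] <- Inf; dmat[, ij[2]] <- Inf
        }
      }
    }
    # retire unextended tracks, start new ones
    if (length(active) > 0) {
      done <- c(done, active[!still])
      active <- active[still]
    }
    for (j in which(!used)) {
      active[[length(active) + 1L]] <-
        data.frame(frame = f, x = dets$x[j], y = dets$y[j])
    }
  }
  done <- c(done, active)
  # spurious-track filter
  keep <- vapply(done, function(a) {
    n <- nrow(a)
    if (n >= min_len) return(TRUE)
    disp <- sqrt((a$x[n] - a$x[1])^2 + (a$y[n] - a$y[1])^2)
    speed <- if (n > 1) disp / (a$frame[n] - a$frame[1]) else 0
    !(disp < 2 || speed < 1)
  }, TRUE)
  done <- done[keep]
  if (length(done) == 0)
    return(structure(data.frame(segment_id = integer(), frame = integer(),
                                x = numeric(), y = numeric()),
                     class = c("segment_set", "data.frame")))
  res <- do.call(rbind, lapply(seq_along(done), function(i)
    cbind(segment_id = i, done[[i]])))
  class(res) <- c("segment_set", class(res))
  res
}
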