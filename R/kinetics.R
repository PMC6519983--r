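#' Correct uneven illumination with a blank-field image
#'
#' Both the blank and (conceptually) the specimen image are dominated by the
#' Gaussian excitation beam falling off toward the image edges. The blank is
#' smoothed with a large Gaussian filter (kernel 110 px, sigma 30 px),
#' normalized to unit mean, and the specimen image is divided by it. Pixels
#' where the filtered blank falls below \code{eps} times its maximum are
#' masked (set NA) with a warning.
#'
#' @param image matrix (H x W) or single-frame \code{image_stack}.
#' @param blank matrix or \code{image_stack} of the specimen-free field.
#' @param sigma,kernel blank smoothing filter, px.
#' @param filter_image apply the same Gaussian filter to the specimen image
#'   before dividing (the literal recipe; exact for pure-illumination inputs
#'   regardless of image boundaries). Set FALSE to divide the raw image and
#'   preserve fine specimen structure, at the cost of boundary-induced
#'   residuals of a few percent near the corners.
#' @param eps division guard as a fraction of the filtered blank's maximum.
#' @return corrected image, same form as \code{image}.
#' @export
correct_illumination <- function(image, blank, sigma = 30, kernel = 110,
                                 filter_image = TRUE, eps = 1e-3) {
  was_stack <- inherits(image, "image_stack")
  img <- if (was_stack) image$data[1, , ] else image
  blk <- if (inherits(blank, "image_stack")) blank$data[1, , ] else blank
  stopifnot(all(dim(img) == dim(blk)))
  fb <- gaussian_blur(blk, sigma = sigma, kernel = kernel)
  bad <- fb < eps * max(fb)
  if (any(bad)) {
    warning(sum(bad), " pixels with near-zero filtered blank masked")
    fb[bad] <- NA
  }
  num <- if (filter_image) gaussian_blur(img, sigma = sigma, kernel = kernel)
         else img
  out <- num / (fb / mean(fb, na.rm = TRUE))
  if (was_stack) {
    image$data[1, , ] <- out
    image
  } else out
}

#' Tubulin intensity profile over the network hull
#'
#' Computes, for every pixel inside the convex hull of the network, its
#' cartesian distance from the network origin (normalized by the largest
#' in-hull distance) and its background-subtracted intensity normalized by
#' the mean intensity inside the hull; returns the binned profile.
#' Background is the mean intensity of all pixels outside the hull.
#'
#' @param image matrix (H x W), illumination-corrected tubulin.
#' @param hull two-column matrix of polygon vertices (x, y in 0-based px);
#'   when NULL the hull is computed from a thresholded, morphologically
#'   closed mask of the image.
#' @param origin c(x, y) network origin, 0-based px.
#' @param bins number of distance bins.
#' @return an \code{intensity_profile}: list(mid, mean_intensity, sd, n_px,
#'   hull); errors if the hull holds fewer than 10 pixels.
#' @export
tubulin_intensity_profile <- function(image, hull = NULL, origin, bins = 10) {
  H <- nrow(image); W <- ncol(image)
  if (is.null(hull)) hull <- hull_from_mask(image)
  stopifnot(is.matrix(hull), ncol(hull) == 2)
  yy <- matrix(0:(H - 1), H, W)
  xx <- matrix(0:(W - 1), H, W, byrow = TRUE)
  inside <- matrix(point_in_polygon(as.vector(xx), as.vector(yy),
                                    hull[, 1], hull[, 2]), H, W)
  if (sum(inside) < 10) stop("hull contains fewer than 10 pixels")
  background <- mean(image[!inside])
  vals <- image[inside] - background
  vals <- vals / mean(vals)
  d <- sqrt((xx[inside] - origin[1])^2 + (yy[inside] - origin[2])^2)
  dn <- d / max(d)
  brk <- seq(0, 1 + 1e-12, length.out = bins + 1)
  bin <- cut(dn, brk, include.lowest = TRUE)
  structure(list(mid = (brk[-1] + brk[-length(brk)]) / 2,
                 mean_intensity = as.numeric(tapply(vals, bin, mean)),
                 sd = as.numeric(tapply(vals, bin, stats::sd)),
                 n_px = as.integer(table(bin)),
                 norm_distance = dn, norm_intensity = vals,
                 hull = hull),
            class = "intensity_profile")
}

# convex hull of a thresholded, morphologically closed mask
hull_from_mask <- function(image, k_sd = 2, brush = 5) {
  thr <- mean(image) + k_sd * stats::sd(image)
  mask <- EBImage::closing(image > thr, EBImage::makeBrush(brush, "disc"))
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) < 3) stop("mask too small to form a hull")
  pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  pts[grDevices::chull(pts), , drop = FALSE]
}

# even-odd rule point-in-polygon, vectorized over points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i] + 1e-300) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Generate synthetic single-molecule photobleaching traces
#'
#' Each trace is a Heaviside step: \code{amplitude} before the bleach frame,
#' zero after, plus an offset and Gaussian noise.
#'
#' @param n number of traces.
#' @param amplitude pre-bleach intensity, au.
#' @param noise_sd Gaussian noise sd, au.
#' @param length trace length, frames.
#' @param bleach_frames optional integer vector of true bleach frames
#'   (default: uniform over the middle 80 percent of the trace).
#' @param offset baseline added to the whole trace, au.
#' @return list with \code{traces} (length x n matrix) and \code{truth}
#'   data.frame (trace, amplitude, bleach_frame, noise_sd, offset).
#' @export
generate_photobleach_traces <- function(n, amplitude = 2700, noise_sd = 300,
                                        length = 100, bleach_frames = NULL,
                                        offset = 0) {
  stopifnot(amplitude > 0, length >= 10)
  if (is.null(bleach_frames))
    bleach_frames <- sample(seq(ceiling(0.1 * length),
                                floor(0.9 * length)), n, replace = TRUE)
  stopifnot(length(bleach_frames) == n)
  tr <- matrix(0, length, n)
  for (i in seq_len(n)) {
    tr[, i] <- offset + amplitude * (seq_len(length) < bleach_frames[i]) +
      stats::rnorm(length, 0, noise_sd)
  }
  list(traces = tr,
       truth = data.frame(trace = seq_len(n), amplitude = amplitude,
                          bleach_frame = bleach_frames,
                          noise_sd = noise_sd, offset = offset))
}

#' Least-squares Heaviside step fit of bleaching traces
#'
#' For each trace, searches all candidate step frames, with closed-form
#' pre/post means, for the minimum residual sum of squares; the amplitude is
#' the pre-step mean minus the post-step mean. Fits explaining less than
#' \code{min_r2} of the variance, or explaining less variance than a
#' straight line (a ramp, not a step), are flagged and excluded from the
#' ensemble mean.
#'
#' @param traces matrix (frames x traces) or a single numeric trace.
#' @param min_r2 minimum variance explained to keep a fit.
#' @return list with \code{fits} data.frame (trace, amplitude, step_frame,
#'   r2, flagged) and \code{mean_amplitude}, \code{sd_amplitude} over
#'   unflagged fits.
#' @export
fit_step_amplitude <- function(traces, min_r2 = 0.5) {
  if (is.null(dim(traces))) traces <- matrix(traces, ncol = 1)
  T <- nrow(traces)
  stopifnot(T >= 10)
  fits <- data.frame(trace = seq_len(ncol(traces)), amplitude = NA_real_,
                     step_frame = NA_integer_, r2 = NA_real_,
                     flagged = FALSE)
  for (i in seq_len(ncol(traces))) {
    y <- traces[, i]
    cs <- cumsum(y); tot <- cs[T]
    k <- 2:(T - 1)           # step frame: first post-step index
    pre <- cs[k - 1] / (k - 1)
    post <- (tot - cs[k - 1]) / (T - k + 1)
    # SSE decomposition: total SS minus between-groups SS
    ssb <- (k - 1) * pre^2 + (T - k + 1) * post^2
    best <- which.max(ssb)
    sse <- sum(y^2) - ssb[best]
    sst <- sum((y - mean(y))^2)
    r2 <- 1 - sse / sst
    line_r2 <- summary(stats::lm(y ~ seq_len(T)))$r.squared
    fits$amplitude[i] <- pre[best] - post[best]
    fits$step_frame[i] <- k[best]
    fits$r2[i] <- r2
    fits$flagged[i] <- r2 < min_r2 || line_r2 > r2
  }
  ok <- !fits$flagged
  list(fits = fits,
       mean_amplitude = if (any(ok)) mean(fits$amplitude[ok]) else NA_real_,
       sd_amplitude = if (sum(ok) > 1) stats::sd(fits$amplitude[ok]) else NA_real_)
}

#' Generate a synthetic TPX2 accumulation kymograph
#'
#' A microtubule grows across the kymograph's pixel axis at
#' \code{growth_speed}; pixel p becomes lattice at frame
#' \code{ceil(p * pixel_size / (growth_speed * frame_interval))}. From its
#' arrival on, molecules accumulate as a cumulative Poisson process with
#' mean \code{rate * pixel_size} per second, on top of a constant background
#' count. Intensity is molecules times the single-molecule intensity plus
#' Gaussian noise.
#'
#' @param rate binding rate, molecules um^-1 s^-1.
#' @param single_intensity single-molecule fluorescence, au.
#' @param background_molecules constant background, molecules.
#' @param pixel_size um/px.
#' @param frame_interval s/frame.
#' @param growth_speed um/s.
#' @param n_pixels,n_frames kymograph size.
#' @param noise_sd Gaussian noise on the intensity, au.
#' @return a \code{kymograph_truth}: list(intensity [n_pixels x n_frames],
#'   molecules, arrival_frame, rate, single_intensity, background_molecules,
#'   pixel_size, frame_interval).
#' @export
generate_tpx2_kymograph <- function(rate = 0.4, single_intensity = 2700,
                                    background_molecules = 7,
                                    pixel_size = 0.16, frame_interval = 5,
                                    growth_speed = 0.09, n_pixels = 32,
                                    n_frames = 100, noise_sd = 0) {
  stopifnot(rate >= 0)
  arrival <- pmax(1L, as.integer(ceiling(((seq_len(n_pixels) - 1) * pixel_size) /
                                           (growth_speed * frame_interval))) + 1L)
  mol <- matrix(0, n_pixels, n_frames)
  for (p in seq_len(n_pixels)) {
    if (arrival[p] > n_frames) next
    nf <- n_frames - arrival[p] + 1
    inc <- stats::rpois(nf, rate * pixel_size * frame_interval)
    inc[1] <- 0  # arrival frame: lattice just appeared
    mol[p, arrival[p]:n_frames] <- background_molecules + cumsum(inc)
  }
  intensity <- mol * single_intensity
  if (noise_sd > 0)
    intensity <- intensity + stats::rnorm(length(intensity), 0, noise_sd)
  structure(list(intensity = intensity, molecules = mol,
                 arrival_frame = arrival, rate = rate,
                 single_intensity = single_intensity,
                 background_molecules = background_molecules,
                 pixel_size = pixel_size, frame_interval = frame_interval),
            class = "kymograph_truth")
}

#' Estimate the lattice binding rate from a kymograph
#'
#' For every lattice pixel, fits a least-squares line to the intensity
#' versus time over the linear accumulation window and converts the slope
#' (au/s) to molecules um^-1 s^-1 through the single-molecule intensity and
#' pixel size. A constant background offset does not affect the slopes.
#'
#' @param kymograph a \code{kymograph_truth}, or a plain matrix
#'   (pixels x frames).
#' @param single_intensity single-molecule intensity, au.
#' @param pixel_size um/px.
#' @param frame_interval s/frame.
#' @param window_policy "truth" (use the recorded lattice-arrival frame) or
#'   "detect" (first frame exceeding background + 3 noise sd).
#' @param min_window pixels with fewer usable frames are skipped.
#' @return list with \code{fits} data.frame (pixel, slope_au_s, rate, r2,
#'   n_frames) and \code{mean_rate}, \code{sd_rate} over pixels.
#' @export
estimate_binding_rate <- function(kymograph, single_intensity = 2700,
                                  pixel_size = 0.16, frame_interval = 5,
                                  window_policy = c("truth", "detect"),
                                  min_window = 5) {
  window_policy <- match.arg(window_policy)
  if (inherits(kymograph, "kymograph_truth")) {
    intensity <- kymograph$intensity
    arrival <- kymograph$arrival_frame
    single_intensity <- kymograph$single_intensity
    pixel_size <- kymograph$pixel_size
    frame_interval <- kymograph$frame_interval
  } else {
    intensity <- kymograph
    arrival <- NULL
  }
  stopifnot(single_intensity > 0)
  P <- nrow(intensity); TT <- ncol(intensity)
  if (window_policy == "detect" || is.null(arrival)) {
    base <- apply(intensity, 1, function(tr) stats::median(tr[seq_len(max(3, TT %/% 10))]))
    nz <- apply(intensity, 1, function(tr) stats::mad(diff(tr)) / sqrt(2))
    arrival <- vapply(seq_len(P), function(p) {
      w <- which(intensity[p, ] > base[p] + 3 * nz[p])
      if (length(w) == 0) TT + 1L else w[1]
    }, 0L)
  }
  fits <- data.frame(pixel = seq_len(P), slope_au_s = NA_real_,
                     rate = NA_real_, r2 = NA_real_, n_frames = 0L)
  for (p in seq_len(P)) {
    w <- arrival[p]:TT
    if (arrival[p] > TT || length(w) < min_window) next
    tt <- (w - 1) * frame_interval
    fit <- stats::lm(intensity[p, w] ~ tt)
    fits$slope_au_s[p] <- stats::coef(fit)[2]
    fits$rate[p] <- stats::coef(fit)[2] / (single_intensity * pixel_size)
    sst <- sum((intensity[p, w] - mean(intensity[p, w]))^2)
    fits$r2[p] <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else 1
    fits$n_frames[p] <- length(w)
  }
  ok <- is.finite(fits$rate)
  list(fits = fits,
       mean_rate = mean(fits$rate[ok]),
       sd_rate = stats::sd(fits$rate[ok]))
}
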