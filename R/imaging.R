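#' Image stack container
#'
#' A thin S3 wrapper around a T x H x W intensity array with the physical
#' metadata every downstream step needs: pixel size (um/px) and frame
#' interval (s).
#'
#' @param data numeric array, T x H x W (a single H x W matrix is promoted to
#'   one frame).
#' @param pixel_size um per pixel.
#' @param frame_interval seconds per frame.
#' @param channel one of "tubulin", "eb1", "tpx2", "blank".
#' @return an \code{image_stack}.
#' @export
image_stack <- function(data, pixel_size, frame_interval,
                        channel = c("tubulin", "eb1", "tpx2", "blank")) {
  channel <- match.arg(channel)
  if (is.matrix(data)) data <- array(data, c(1, dim(data)))
  stopifnot(length(dim(data)) == 3, pixel_size > 0, frame_interval > 0,
            all(is.finite(data)))
  structure(list(data = data, pixel_size = pixel_size,
                 frame_interval = frame_interval, channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack [%s]: %d frames of %d x %d px, %.3f um/px, %g s/frame\n",
              x$channel, d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Rendering configuration for synthetic microscopy
#'
#' @param psf_sigma Gaussian point-spread sigma, px.
#' @param psf_kernel blur kernel size, px.
#' @param tubulin_amp emitted intensity per um of lattice, au.
#' @param eb1_comet_length,eb1_comet_width comet FWHM along / across the
#'   growth axis, px.
#' @param eb1_amp peak comet amplitude, au.
#' @param noise_sd Gaussian read-noise sd, au (0 = noiseless).
#' @param poisson_noise apply Poisson shot noise to the signal first.
#' @param illumination "flat" or "gaussian_beam".
#' @param beam_sd_px Gaussian-beam sd when illumination is "gaussian_beam".
#' @return a \code{render_config} list.
#' @export
render_config <- function(psf_sigma = 1.5, psf_kernel = 30, tubulin_amp = 1000,
                          eb1_comet_length = 10, eb1_comet_width = 4,
                          eb1_amp = 1000, noise_sd = 0, poisson_noise = FALSE,
                          illumination = c("flat", "gaussian_beam"),
                          beam_sd_px = 120) {
  illumination <- match.arg(illumination)
  stopifnot(psf_sigma > 0, eb1_comet_length >= 1, eb1_comet_width >= 1)
  structure(list(psf_sigma = psf_sigma, psf_kernel = psf_kernel,
                 tubulin_amp = tubulin_amp,
                 eb1_comet_length = eb1_comet_length,
                 eb1_comet_width = eb1_comet_width, eb1_amp = eb1_amp,
                 noise_sd = noise_sd, poisson_noise = poisson_noise,
                 illumination = illumination, beam_sd_px = beam_sd_px),
            class = "render_config")
}

# illumination field H x W (0-based pixel coordinates, beam centered)
illumination_field <- function(H, W, config) {
  if (config$illumination == "flat") return(matrix(1, H, W))
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  yy <- matrix(0:(H - 1), H, W)
  xx <- matrix(0:(W - 1), H, W, byrow = TRUE)
  exp(-((xx - cx)^2 + (yy - cy)^2) / (2 * config$beam_sd_px^2))
}

apply_noise <- function(img, config) {
  if (config$poisson_noise) {
    img[] <- stats::rpois(length(img), pmax(img, 0))
  }
  if (config$noise_sd > 0) img <- img + stats::rnorm(length(img), 0, config$noise_sd)
  img
}

# draw anti-aliased line mass: total intensity amp_per_um * length_um spread
# over samples every ~0.25 px with bilinear splatting
splat_line <- function(img, x0, y0, x1, y1, total_intensity) {
  len_px <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  n <- max(2L, ceiling(len_px * 4) + 1L)
  ts <- seq(0, 1, length.out = n)
  xs <- x0 + ts * (x1 - x0); ys <- y0 + ts * (y1 - y0)
  splat_points(img, xs, ys, rep(total_intensity / n, n))
}

# bilinear splat of point masses at 0-based continuous positions
splat_points <- function(img, xs, ys, w) {
  H <- nrow(img); W <- ncol(img)
  inb <- xs > -1 & xs < W & ys > -1 & ys < H
  xs <- xs[inb]; ys <- ys[inb]; w <- w[inb]
  if (length(xs) == 0) return(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  for (dy in 0:1) for (dx in 0:1) {
    wx <- if (dx == 0) 1 - fx else fx
    wy <- if (dy == 0) 1 - fy else fy
    r <- y0 + dy + 1; c <- x0 + dx + 1
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    if (any(ok)) {
      idx <- cbind(r[ok], c[ok])
      add <- w[ok] * wx[ok] * wy[ok]
      # accumulate (duplicate indices must sum)
      v <- tapply(add, (idx[, 1] - 1) + (idx[, 2] - 1) * H, sum)
      lin <- as.integer(names(v)) + 1L
      img[lin] <- img[lin] + as.numeric(v)
    }
  }
  img
}

gaussian_blur <- function(img, sigma, kernel) {
  # EBImage works on x-by-y images; a plain matrix is fine since the kernel
  # is isotropic. The kernel may not exceed the image.
  r <- max(3L, as.integer(kernel) %/% 2L * 2L + 1L)
  rmax <- as.integer(min(dim(img))) - 2L
  if (rmax %% 2L == 0L) rmax <- rmax - 1L
  EBImage::gblur(img, sigma = sigma, radius = min(r, rmax),
                 boundary = "replicate")
}

#' Render the tubulin channel of a simulated network
#'
#' Each microtubule is drawn as a line of total intensity
#' \code{tubulin_amp * length_um}, blurred with the Gaussian point-spread
#' function, multiplied by the illumination field, then noise is applied.
#' Microtubules leaving the field of view are clipped with a warning.
#'
#' @param network a \code{branch_network}.
#' @param config a \code{\link{render_config}}.
#' @param times vector of times (s) at which frames are rendered.
#' @param H,W field of view, px.
#' @param pixel_size um per px.
#' @param origin_px c(x, y) pixel position of the network origin.
#' @return an \code{image_stack} (channel "tubulin").
#' @export
render_tubulin_stack <- function(network, config, times, H = 128, W = 128,
                                 pixel_size = 0.13,
                                 origin_px = c(W / 4, H / 2)) {
  stk <- array(0, c(length(times), H, W))
  illum <- illumination_field(H, W, config)
  clipped <- FALSE
  for (f in seq_along(times)) {
    t <- times[f]
    img <- matrix(0, H, W)
    m <- network$mts[network$mts$birth_time <= t, , drop = FALSE]
    len <- pmax(0, network$params$v_pe * (t - m$birth_time))
    for (i in seq_len(nrow(m))) {
      if (len[i] <= 0) next
      x0 <- m$minus_x[i] / pixel_size + origin_px[1]
      y0 <- m$minus_y[i] / pixel_size + origin_px[2]
      x1 <- x0 + m$dir_x[i] * len[i] / pixel_size
      y1 <- y0 + m$dir_y[i] * len[i] / pixel_size
      if (min(x0, x1) < 0 || max(x0, x1) > W - 1 ||
          min(y0, y1) < 0 || max(y0, y1) > H - 1) clipped <- TRUE
      img <- splat_line(img, x0, y0, x1, y1, config$tubulin_amp * len[i])
    }
    img <- gaussian_blur(img, config$psf_sigma, config$psf_kernel)
    stk[f, , ] <- apply_noise(img * illum, config)
  }
  if (clipped) warning("microtubules extend outside the field of view; clipped")
  image_stack(stk, pixel_size, if (length(times) > 1) diff(times[1:2]) else 1,
              channel = "tubulin")
}

#' Render the EB1 (plus-end comet) channel of a simulated network
#'
#' Every growing plus-end is drawn as an anisotropic Gaussian comet with the
#' long axis along the growth direction. The returned truth table records the
#' exact sub-pixel comet positions per frame.
#'
#' @inheritParams render_tubulin_stack
#' @return list with \code{stack} (an \code{image_stack}, channel "eb1") and
#'   \code{truth}: data.frame (frame, x_px, y_px, mt_id).
#' @export
render_eb1_stack <- function(network, config, times, H = 128, W = 128,
                             pixel_size = 0.13, origin_px = c(W / 4, H / 2)) {
  stk <- array(0, c(length(times), H, W))
  illum <- illumination_field(H, W, config)
  sig_l <- config$eb1_comet_length / 2.355  # FWHM -> sigma
  sig_w <- config$eb1_comet_width / 2.355
  truth <- list()
  yy <- matrix(0:(H - 1), H, W); xx <- matrix(0:(W - 1), H, W, byrow = TRUE)
  for (f in seq_along(times)) {
    t <- times[f]
    img <- matrix(0, H, W)
    pe <- plus_end_positions(network, t)
    m <- network$mts[match(pe$id, network$mts$id), ]
    px <- pe$x / pixel_size + origin_px[1]
    py <- pe$y / pixel_size + origin_px[2]
    for (i in seq_len(nrow(pe))) {
      # rotate coordinates into the comet frame
      u <- (xx - px[i]) * m$dir_x[i] + (yy - py[i]) * m$dir_y[i]
      w <- -(xx - px[i]) * m$dir_y[i] + (yy - py[i]) * m$dir_x[i]
      img <- img + config$eb1_amp * exp(-u^2 / (2 * sig_l^2) - w^2 / (2 * sig_w^2))
    }
    stk[f, , ] <- apply_noise(img * illum, config)
    truth[[f]] <- data.frame(frame = f, x_px = px, y_px = py, mt_id = pe$id)
  }
  list(stack = image_stack(stk, pixel_size,
                           if (length(times) > 1) diff(times[1:2]) else 1,
                           channel = "eb1"),
       truth = do.call(rbind, truth))
}

#' Blank illumination field image
#'
#' Single-frame Gaussian-beam field with maximum at the image center, as
#' recorded from a specimen-free field of view.
#'
#' @param H,W image size, px.
#' @param beam_sd_px beam Gaussian sd, px (\code{Inf} gives a flat field).
#' @param amp peak amplitude, au.
#' @param noise_sd optional Gaussian noise sd.
#' @return an \code{image_stack} (channel "blank").
#' @export
generate_blank_illumination <- function(H, W, beam_sd_px, amp = 1000,
                                        noise_sd = 0) {
  cfg <- render_config(illumination = if (is.finite(beam_sd_px))
    "gaussian_beam" else "flat", beam_sd_px = beam_sd_px)
  img <- amp * illumination_field(H, W, cfg)
  if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
  image_stack(img, pixel_size = 0.13, frame_interval = 1, channel = "blank")
}

#' Write / read an image stack as multi-page TIFF with sidecar metadata
#'
#' Pixel size and frame interval travel in a JSON sidecar next to the TIFF.
#'
#' @param stack an \code{image_stack}.
#' @param path output .tif path.
#' @export
write_image_stack <- function(stack, path) {
  d <- dim(stack$data)
  frames <- lapply(seq_len(d[1]), function(f) stack$data[f, , ])
  mx <- max(1, max(abs(stack$data)))
  frames <- lapply(frames, function(m) m / mx)  # tiff stores [0,1] floats
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_size_um = stack$pixel_size,
               frame_interval_s = stack$frame_interval,
               channel = stack$channel, scale = mx)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @param path path to a .tif written by \code{write_image_stack}.
#' @export
read_image_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- array(0, c(length(frames), nrow(frames[[1]]), ncol(frames[[1]])))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]] * meta$scale
  image_stack(arr, meta$pixel_size_um, meta$frame_interval_s, meta$channel)
}
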