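test_that("temporal median filter removes static structure and keeps movers", {
  T <- 21; H <- 24; W <- 24
  arr <- array(100, c(T, H, W))           # static background
  for (t in 1:T) arr[t, 10, t] <- 600     # one moving bright spot
  stk <- image_stack(arr, 0.13, 2, "eb1")
  filt <- temporal_median_filter(stk, 15)
  # background cancels
  expect_lt(max(filt$data[11, 15:24, 15:24]), 1e-9)
  # the moving spot survives
  expect_gt(filt$data[11, 10, 11], 400)
  # window = 1 gives identically zero
  z <- temporal_median_filter(stk, 1)
  expect_equal(sum(abs(z$data)), 0)
  # stack shorter than the window warns
  short <- image_stack(arr[1:5, , ], 0.13, 2, "eb1")
  expect_warning(temporal_median_filter(short, 15), "truncated")
})

test_that("tubulin preprocessing removes global bleach and flat fields", {
  set.seed(8)
  T <- 20; H <- 48; W <- 48
  base <- array(0, c(T, H, W))
  # a bright compact specimen on a decaying background
  for (t in 1:T) {
    decay <- exp(-t / 10)
    fr <- matrix(50 * decay, H, W)
    if (t >= 2) fr[20:28, 20:28] <- fr[20:28, 20:28] + 400 * decay
    base[t, , ] <- fr
  }
  stk <- image_stack(base, 0.13, 2, "tubulin")
  out <- preprocess_tubulin(stk, background_roi = list(rows = 1:10, cols = 1:10))
  # frame 1 (no specimen yet) is ~0 after first-frame subtraction
  expect_lt(max(abs(out$data[1, , ])), 1e-6)
  # specimen intensity is stationary over time after the ratio correction
  sig <- vapply(2:T, function(t) mean(out$data[t, 22:26, 22:26]), 0)
  expect_lt(diff(range(sig)) / mean(sig), 0.05)
  # a flat field is removed entirely by the high-pass
  flat <- image_stack(array(300, c(3, H, W)), 0.13, 2, "tubulin")
  outf <- preprocess_tubulin(flat)
  expect_lt(max(abs(outf$data)), 1e-6)
})

test_that("comet detection finds isolated blobs to sub-pixel accuracy", {
  cfg <- render_config(eb1_amp = 2000)
  net <- two_mt_network(t_end = 150)
  net$mts <- net$mts[1, , drop = FALSE]
  eb <- render_eb1_stack(net, cfg, times = c(50, 52), H = 96, W = 128,
                         pixel_size = 0.13, origin_px = c(10, 48))
  det <- detect_comets(eb$stack, threshold_sd = 12)
  d1 <- det[det$frame == 1, ]
  expect_equal(nrow(d1), 1)
  expect_lt(abs(d1$x - eb$truth$x_px[1]), 0.5)
  expect_lt(abs(d1$y - eb$truth$y_px[1]), 0.5)
  # blank frames yield nothing
  blank <- image_stack(array(rnorm(2 * 64 * 64, 100, 5), c(2, 64, 64)),
                       0.13, 2, "eb1")
  expect_equal(nrow(detect_comets(blank, threshold_sd = 12)), 0)
  # two well-separated comets are both found
  arr <- array(0, c(1, 64, 64))
  for (p in list(c(20, 20), c(20, 40))) {
    yy <- outer(0:63 - p[1], rep(1, 64)); xx <- outer(rep(1, 64), 0:63 - p[2])
    arr[1, , ] <- arr[1, , ] + 1000 * exp(-(yy^2 + xx^2) / (2 * 2^2))
  }
  two <- image_stack(arr, 0.13, 2, "eb1")
  expect_equal(nrow(detect_comets(two, threshold_sd = 12)), 2)
})

test_that("greedy linking reconstructs continuous and parallel tracks", {
  # one comet moving steadily
  det <- data.frame(frame = 1:20, x = 1.4 * (1:20), y = rep(10, 20))
  segs <- link_comets(det)
  expect_equal(length(unique(segs$segment_id)), 1)
  expect_equal(nrow(segs), 20)
  # two well-separated comets: two segments, no identity swaps
  det2 <- rbind(data.frame(frame = rep(1:15, 2),
                           x = c(1.4 * (1:15), 1.4 * (1:15)),
                           y = c(rep(10, 15), rep(40, 15))))
  segs2 <- link_comets(det2)
  expect_equal(length(unique(segs2$segment_id)), 2)
  for (id in unique(segs2$segment_id))
    expect_equal(length(unique(round(segs2$y[segs2$segment_id == id]))), 1)
  # short immobile clutter is filtered out
  det3 <- rbind(det, data.frame(frame = 5:6, x = c(50, 50.1), y = c(50, 50)))
  segs3 <- link_comets(det3)
  expect_equal(length(unique(segs3$segment_id)), 1)
})

test_that("line-integral intensity is exact on uniform images and discriminates lattice", {
  u <- matrix(7, 40, 40)
  expect_equal(line_integral_intensity(u, c(5, 5), c(30, 5)), 7)
  expect_equal(line_integral_intensity(u, c(5, 5), c(30, 30)), 7)  # 45 degrees
  expect_equal(line_integral_intensity(u, c(12.3, 8.1), c(12.3, 8.1)), 7)
  # on-lattice chord far exceeds off-lattice chord on a rendered image
  cfg <- render_config(tubulin_amp = 1000)
  net <- two_mt_network(t_end = 10 / 0.09)
  net$mts <- net$mts[1, , drop = FALSE]
  stk <- render_tubulin_stack(net, cfg, times = net$t_end, H = 96, W = 128,
                              pixel_size = 0.13, origin_px = c(10, 48))
  img <- stk$data[1, , ]
  on_mt <- line_integral_intensity(img, c(15, 48), c(60, 48))
  off_mt <- line_integral_intensity(img, c(15, 20), c(60, 20))
  expect_gt(on_mt, 50 * max(off_mt, 1e-6))
})

test_that("merging closes constructed pauses and prefers shorter gaps", {
  lattice <- matrix(0, 64, 96)
  lattice[31:33, 10:80] <- 30      # bright lattice along y = 32
  # collinear segments: 10 frames, 4-frame pause, 10 frames
  seg <- rbind(
    data.frame(segment_id = 1, frame = 1:10, x = 10 + 1.4 * (1:10), y = 32),
    data.frame(segment_id = 2, frame = 15:24, x = 10 + 1.4 * 10 + 1 + 1.4 * (0:9),
               y = 32))
  class(seg) <- c("segment_set", class(seg))
  tr <- merge_tracks(seg, lattice, merge_config())
  expect_equal(length(unique(tr$trajectory_id)), 1)
  mg <- attr(tr, "merges")
  expect_equal(nrow(mg), 1)
  expect_equal(mg$gap_class, "pause")
  # interpolated rows fill the gap frames
  expect_equal(sum(tr$interpolated), 4)
  expect_equal(tr$frame[tr$trajectory_id == 1], 1:24)

  # one segment passes through unchanged
  single <- seg[seg$segment_id == 1, ]
  tr1 <- merge_tracks(single, lattice, merge_config())
  expect_equal(nrow(tr1), 10)
  expect_equal(attr(tr1, "merges")$seg_from, integer(0))

  # two candidates with identical geometry: the shorter time gap wins
  segA <- rbind(
    data.frame(segment_id = 1, frame = 1:10, x = 10 + 1.4 * (1:10), y = 32),
    data.frame(segment_id = 2, frame = 13:22, x = 26 + 1.4 * (1:10), y = 32),
    data.frame(segment_id = 3, frame = 21:30, x = 26 + 1.4 * (1:10), y = 32.2))
  class(segA) <- c("segment_set", class(segA))
  trA <- merge_tracks(segA, lattice, merge_config())
  mgA <- attr(trA, "merges")
  expect_equal(mgA$seg_to[1], 2)

  # a gap chord over dark background is not merged
  segB <- rbind(
    data.frame(segment_id = 1, frame = 1:10, x = 10 + 1.4 * (1:10), y = 10),
    data.frame(segment_id = 2, frame = 16:25, x = 10 + 1.4 * 10 + 1.4 * 5 + 1.4 * (1:10),
               y = 10))
  class(segB) <- c("segment_set", class(segB))
  trB <- merge_tracks(segB, lattice, merge_config())
  expect_equal(nrow(attr(trB, "merges")), 0)
})

test_that("without fragmentation, merging is the identity on linked tracks", {
  net <- quiet_sim(sim_params(seed = 19, t_max = 300, max_mts = 4), "sequential")
  tru <- network_to_trajectories(net, jitter_sd = 0)
  none <- gap_model(pause_rate = 0, dropout_prob = 0, catastrophe_prob = 0,
                    jitter_sd = 0)
  fr <- fragment_tracks(tru, none)
  det <- fr$detections
  segs <- data.frame(segment_id = det$segment_id, frame = det$frame,
                     x = det$x_px + 96, y = det$y_px + 96)
  class(segs) <- c("segment_set", class(segs))
  tr <- merge_tracks(segs, matrix(1, 256, 384), merge_config())
  keep <- table(det$segment_id) >= 6
  expect_equal(length(unique(tr$trajectory_id)), sum(keep))
  expect_equal(nrow(attr(tr, "merges")), 0)
})

test_that("merge harness: most true pairs close, few false joins, counts match", {
  h <- merge_harness(12, seed = 5)
  expect_gt(h$frac_correct, 0.8)
  expect_lt(h$frac_false, 0.08)
  # trajectory count tracks the true MT count within 10%
  expect_lt(abs(h$n_trajs - h$n_true_mts) / h$n_true_mts, 0.1)
})

test_that("length series and net speed recover constant growth", {
  # straight noiseless growth at 1 px/frame
  tr <- data.frame(frame = 1:60, x = 10 + (1:60), y = 5)
  len <- measure_length_series(tr, pixel_size = 0.13)
  expect_equal(diff(len$length_um), rep(0.13, 59), tolerance = 1e-6)
  # net speed: 0.09 um/s at 2 s/frame = 5.4 um/min
  tr2 <- data.frame(frame = 1:60, x = 10 + 0.09 * 2 / 0.13 * (1:60), y = 5)
  expect_equal(net_plus_end_speed(tr2, 0.13, 2), 5.4, tolerance = 0.01)
  # tracks below the 50-frame span are excluded
  expect_true(is.na(net_plus_end_speed(tr2[1:49, ], 0.13, 2)))
  # stationary trajectory has ~zero length
  tr3 <- data.frame(frame = 1:60, x = 10, y = 5)
  expect_lt(max(measure_length_series(tr3, 0.13)$length_um), 1e-6)
  # an embedded 20% pause reduces the net speed accordingly
  x4 <- cumsum(c(0, ifelse(1:59 %in% 25:36, 0, 1.4)))
  tr4 <- data.frame(frame = 1:60, x = 10 + x4, y = 5)
  v4 <- net_plus_end_speed(tr4, 0.13, 2)
  expect_equal(v4, 5.4 * (47 / 59), tolerance = 0.05)
  # spline beats the raw polyline on jittered straight growth
  set.seed(23)
  tr5 <- data.frame(frame = 1:80, x = 10 + 1.4 * (1:80) + rnorm(80, 0, 1),
                    y = 5 + rnorm(80, 0, 1))
  spl <- utils::tail(measure_length_series(tr5, 0.13)$length_um, 1)
  poly <- 0.13 * sum(sqrt(diff(tr5$x)^2 + diff(tr5$y)^2))
  truth <- 0.13 * 1.4 * 79
  expect_lt(abs(spl - truth) / truth, 0.03)
  expect_gt(poly, spl)
})
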