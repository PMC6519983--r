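test_that("tubulin rendering conserves injected intensity and handles empty fields", {
  cfg <- render_config(tubulin_amp = 500)
  # lone 10-um MT fully inside the field
  net <- two_mt_network(t_end = 10 / 0.09)
  net$mts <- net$mts[1, , drop = FALSE]
  stk <- render_tubulin_stack(net, cfg, times = net$t_end, H = 128, W = 128,
                              pixel_size = 0.13, origin_px = c(20, 64))
  expect_equal(sum(stk$data[1, , ]), 500 * 10, tolerance = 0.01 * 500 * 10)
  # empty network renders background only
  net0 <- net; net0$mts <- net0$mts[0, , drop = FALSE]
  stk0 <- render_tubulin_stack(net0, cfg, times = 5, H = 32, W = 32)
  expect_equal(sum(abs(stk0$data)), 0)
  # out-of-field MT warns
  expect_warning(render_tubulin_stack(net, cfg, times = net$t_end,
                                      H = 32, W = 32, origin_px = c(16, 16)),
                 "field of view")
})

test_that("a perpendicular cut through a rendered MT is a Gaussian of the PSF width", {
  cfg <- render_config(tubulin_amp = 1000)
  net <- two_mt_network(t_end = 10 / 0.09)
  net$mts <- net$mts[1, , drop = FALSE]   # horizontal MT through y = 64
  stk <- render_tubulin_stack(net, cfg, times = net$t_end, H = 128, W = 128,
                              pixel_size = 0.13, origin_px = c(20, 64))
  cut <- stk$data[1, , 50]                # vertical profile at mid-MT
  ys <- 0:127
  mu <- sum(ys * cut) / sum(cut)
  sdv <- sqrt(sum((ys - mu)^2 * cut) / sum(cut))
  expect_equal(mu, 64, tolerance = 0.1)
  expect_equal(sdv, 1.5, tolerance = 0.15)
})

test_that("EB1 comets move at v_pe and have the configured extent", {
  cfg <- render_config(eb1_amp = 1000)
  net <- two_mt_network(t_end = 150)
  net$mts <- net$mts[1, , drop = FALSE]
  times <- seq(2, 100, by = 2)
  eb <- render_eb1_stack(net, cfg, times, H = 96, W = 128,
                         pixel_size = 0.13, origin_px = c(10, 48))
  tr <- eb$truth
  expect_equal(nrow(tr), length(times))
  # per-frame displacement: v_pe * frame_interval / pixel_size px
  expect_equal(unique(round(diff(tr$x_px), 6)), 0.09 * 2 / 0.13,
               tolerance = 1e-6)
  # comet footprint: along-axis FWHM ~ comet length config
  f <- 25
  row <- eb$stack$data[f, 49, ]  # along the growth axis (y = 48)
  half <- max(row) / 2
  fwhm <- sum(row >= half)
  expect_equal(fwhm, 10, tolerance = 2)
})

test_that("branch birth adds a comet at the recorded site position", {
  cfg <- render_config()
  net <- two_mt_network(arc_pos = 3, t1 = 60, t_end = 100)
  eb <- render_eb1_stack(net, cfg, times = c(59, 61), H = 96, W = 128,
                         pixel_size = 0.13, origin_px = c(10, 48))
  expect_equal(sum(eb$truth$frame == 1), 1)   # before the branch
  expect_equal(sum(eb$truth$frame == 2), 2)   # after
  new_comet <- eb$truth[eb$truth$frame == 2 & eb$truth$mt_id == 2, ]
  # daughter has barely grown: comet sits at the branch site
  expect_equal(new_comet$x_px, 3 / 0.13 + 10 + cos(20 * pi / 180) * 0.09 / 0.13,
               tolerance = 1e-6)
})

test_that("gap-free fragmentation returns one segment per microtubule, a partition", {
  net <- quiet_sim(sim_params(seed = 14, t_max = 400, max_mts = 6), "sequential")
  tru <- network_to_trajectories(net, jitter_sd = 0)
  none <- gap_model(pause_rate = 0, dropout_prob = 0, catastrophe_prob = 0,
                    jitter_sd = 0)
  fr <- fragment_tracks(tru, none)
  expect_equal(nrow(fr$segment_map), length(unique(tru$trajectory_id)))
  expect_equal(anyDuplicated(fr$detections[, c("mt_id", "frame")]), 0)
  # with gaps: segments partition the emitted detections disjointly
  set.seed(3)
  fr2 <- fragment_tracks(tru, gap_model())
  expect_equal(anyDuplicated(fr2$detections[, c("mt_id", "frame")]), 0)
  expect_setequal(unique(fr2$detections$segment_id), fr2$segment_map$segment_id)
})

test_that("a pause splits a track into collinear segments with nearby ends", {
  net <- two_mt_network(t_end = 200)
  net$mts <- net$mts[1, , drop = FALSE]
  tru <- network_to_trajectories(net, jitter_sd = 0)
  set.seed(41)
  # pause-only model, high rate so at least one pause occurs
  gm <- gap_model(pause_rate = 0.08, dropout_prob = 0, catastrophe_prob = 0,
                  jitter_sd = 0)
  fr <- fragment_tracks(tru, gm)
  expect_gt(nrow(fr$segment_map), 1)
  det <- fr$detections
  s1 <- det[det$segment_id == 1, ]; s2 <- det[det$segment_id == 2, ]
  gap_px <- sqrt((s2$x_px[1] - s1$x_px[nrow(s1)])^2 +
                   (s2$y_px[1] - s1$y_px[nrow(s1)])^2)
  expect_lt(gap_px, 1e-9)   # plus-end held its position (no jitter)
  expect_equal(det$gap_class[det$segment_id == 2][1], "pause")
})

test_that("a catastrophe restarts the comet behind the previous end", {
  net <- two_mt_network(t_end = 200)
  net$mts <- net$mts[1, , drop = FALSE]
  tru <- network_to_trajectories(net, jitter_sd = 0)
  set.seed(17)
  gm <- gap_model(pause_rate = 0, dropout_prob = 0, catastrophe_prob = 0.1,
                  jitter_sd = 0, shrink_max_px = 10)
  fr <- fragment_tracks(tru, gm)
  det <- fr$detections
  expect_gt(nrow(fr$segment_map), 1)
  s1 <- det[det$segment_id == 1, ]; s2 <- det[det$segment_id == 2, ]
  # start of the second segment lies behind the end of the first, along +x
  jump <- s2$x_px[1] - s1$x_px[nrow(s1)]
  expect_lt(jump, 0)
  expect_gte(jump, -10)
  expect_equal(det$gap_class[det$segment_id == 2][1], "catastrophe")
})

test_that("blank illumination follows the Gaussian-beam form", {
  bl <- generate_blank_illumination(64, 64, beam_sd_px = 40, amp = 1000)
  img <- bl$data[1, , ]
  ctr <- img[32, 32]
  corner <- img[1, 1]
  d2 <- (31.5 - 0)^2 + (31.5 - 0)^2
  expect_equal(ctr / corner, exp(d2 / (2 * 40^2)), tolerance = 0.01)
  flat <- generate_blank_illumination(16, 16, beam_sd_px = Inf, amp = 7)
  expect_true(all(abs(flat$data - 7) < 1e-12))
  # reproducible under a fixed seed with noise
  set.seed(9); a <- generate_blank_illumination(16, 16, 40, noise_sd = 5)
  set.seed(9); b <- generate_blank_illumination(16, 16, 40, noise_sd = 5)
  expect_identical(a$data, b$data)
})

test_that("photobleach traces are exact steps without noise and carry truth", {
  pb <- generate_photobleach_traces(5, amplitude = 1000, noise_sd = 0,
                                    length = 40, bleach_frames = rep(20, 5))
  expect_equal(dim(pb$traces), c(40, 5))
  expect_true(all(pb$traces[1:19, ] == 1000))
  expect_true(all(pb$traces[20:40, ] == 0))
  expect_equal(nrow(pb$truth), 5)
  set.seed(2)
  pb2 <- generate_photobleach_traces(8, length = 60)
  expect_true(all(colMeans(pb2$traces[1:5, ]) >
                    colMeans(pb2$traces[56:60, ])))
})

test_that("kymograph accumulation matches the Poisson law in ensemble mean", {
  set.seed(6)
  ky <- generate_tpx2_kymograph(rate = 0.4, single_intensity = 2700,
                                background_molecules = 7, n_pixels = 300,
                                n_frames = 60, noise_sd = 0)
  # at fixed lattice age a (frames), mean molecules = bg + rate*ps*fi*a
  age <- 30
  ok <- ky$arrival_frame + age <= 60
  vals <- ky$molecules[cbind(which(ok), ky$arrival_frame[ok] + age)]
  expected <- 7 + 0.4 * 0.16 * 5 * age
  expect_lt(abs(mean(vals) - expected) / expected, 0.1)
  # zero rate: flat at background
  ky0 <- generate_tpx2_kymograph(rate = 0, n_pixels = 8, n_frames = 30)
  on <- ky0$intensity[1, ky0$arrival_frame[1]:30]
  expect_true(all(on == 7 * 2700))
  # cumulative counts never decrease along a lattice row
  row <- ky$molecules[1, ky$arrival_frame[1]:60]
  expect_true(all(diff(row) >= 0))
})

test_that("image stacks round-trip through TIFF with metadata", {
  set.seed(1)
  stk <- image_stack(array(runif(3 * 16 * 16, 0, 500), c(3, 16, 16)),
                     pixel_size = 0.13, frame_interval = 2, channel = "eb1")
  path <- tempfile(fileext = ".tif")
  write_image_stack(stk, path)
  stk2 <- read_image_stack(path)
  expect_equal(stk2$data, stk$data, tolerance = 1e-5)
  expect_equal(stk2$pixel_size, 0.13)
  expect_equal(stk2$frame_interval, 2)
  expect_equal(stk2$channel, "eb1")
})
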