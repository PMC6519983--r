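# Shared fixtures and harnesses for the test suite. Everything is generated
# in code; no stored data.

# simulate with the per-step event-count warning muffled (expected for dense
# networks at dt = 1)
quiet_sim <- function(params, model) {
  suppressWarnings(simulate_network(params, model))
}

# hand-built two-MT network: seed along +x from the origin, daughter at a
# chosen angle branching at arc_pos um after t1 seconds
two_mt_network <- function(arc_pos = 3, t1 = 100, angle_deg = 20,
                           v_pe = 0.09, t_end = 200) {
  params <- sim_params(v_pe = v_pe, t_max = t_end)
  th <- angle_deg * pi / 180
  mts <- data.frame(
    id = 1:2, birth_time = c(0, t1),
    minus_x = c(0, arc_pos), minus_y = c(0, 0),
    dir_x = c(1, cos(th)), dir_y = c(0, sin(th)),
    mother_id = c(NA_integer_, 1L), branch_arc_pos = c(NA_real_, arc_pos))
  branchnet:::new_branch_network(params, mts, branchnet:::empty_sites(),
                                 t_end = t_end, model = "single_step")
}

# fragment -> merge -> score against the truth tables; sparse geometry keeps
# every microtubule inside the rendered field of view
merge_harness <- function(n_nets, seed, max_mts = 3, t_max = 350,
                          H = 384, W = 448, origin = c(96, 192),
                          gap = gap_model()) {
  set.seed(seed)
  correct <- 0; false_m <- 0; truth_pairs <- 0
  n_true_mts <- 0; n_trajs <- 0
  for (r in seq_len(n_nets)) {
    net <- quiet_sim(sim_params(t_max = t_max, max_mts = max_mts), "sequential")
    tru <- network_to_trajectories(net, jitter_sd = 0)
    fr <- fragment_tracks(tru, gap)
    det <- fr$detections
    # standard spurious-segment pre-filter (as in the linking stage)
    tab <- table(det$segment_id)
    keepid <- as.integer(names(tab))[tab >= 3]
    det <- det[det$segment_id %in% keepid, ]
    segs <- data.frame(segment_id = det$segment_id, frame = det$frame,
                       x = det$x_px + origin[1], y = det$y_px + origin[2])
    class(segs) <- c("segment_set", class(segs))
    tub <- suppressWarnings(render_tubulin_stack(
      net, render_config(), times = net$t_end, H = H, W = W,
      origin_px = origin))
    trajs <- merge_tracks(segs, tub$data[1, , ], merge_config())
    mg <- attr(trajs, "merges")
    sm <- fr$segment_map
    same <- sm$mt_id[match(mg$seg_from, sm$segment_id)] ==
      sm$mt_id[match(mg$seg_to, sm$segment_id)]
    correct <- correct + sum(same)
    false_m <- false_m + sum(!same)
    for (mt in unique(sm$mt_id)) {
      sid <- intersect(sm$segment_id[sm$mt_id == mt], keepid)
      truth_pairs <- truth_pairs + max(0, length(sid) - 1)
    }
    n_true_mts <- n_true_mts + length(unique(sm$mt_id[sm$segment_id %in% keepid]))
    n_trajs <- n_trajs + length(unique(trajs$trajectory_id))
  }
  list(correct = correct, false_merges = false_m, truth_pairs = truth_pairs,
       frac_correct = correct / truth_pairs,
       frac_false = false_m / (correct + false_m),
       n_true_mts = n_true_mts, n_trajs = n_trajs)
}

# simulate networks, convert to jittered truth trajectories, assign mothers;
# returns assignments with the generative truth attached
angle_harness <- function(n_nets, seed, max_mts = 18, t_max = 700,
                          jitter_sd = 0.5) {
  set.seed(seed)
  out <- list()
  for (r in seq_len(n_nets)) {
    net <- quiet_sim(sim_params(t_max = t_max, max_mts = max_mts), "sequential")
    tru <- network_to_trajectories(net, jitter_sd = jitter_sd)
    ma <- assign_mothers(tru)
    ma$true_mother <- net$mts$mother_id[match(ma$daughter_id, net$mts$id)]
    ma$network <- r
    out[[r]] <- ma
  }
  do.call(rbind, out)
}
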