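#' Assign a mother microtubule to every branched trajectory
#'
#' For each trajectory i (in order of appearance, the earliest being the
#' seed), all earlier-starting trajectories j are candidate mothers. The
#' closest recorded point of j to the start of i must predate i's start;
#' candidates are rejected when the direction dot product is too low (more
#' than \code{max_angle_deg} between daughter and mother), when the cartesian
#' or perpendicular distances exceed \code{d_max_px}, or when the daughter
#' crosses over the candidate. When the perpendicular offset is large
#' (> \code{extrap_d_perp_px}) or the tracks are nearly parallel
#' (< \code{extrap_angle_deg}), the daughter is extrapolated backwards to its
#' intersection with the mother line and the distance is re-measured there.
#' The candidate minimizing \code{D_min} is chosen (or
#' \code{D_min + 1 - N_dot} when more than \code{many_candidates} survive).
#' The branch angle is the signed angle from the mother's local direction to
#' the daughter's initial direction.
#'
#' @param trajectories a \code{trajectory_set} data.frame
#'   (trajectory_id, frame, x, y).
#' @param max_angle_deg maximum mother-daughter angle, degrees.
#' @param d_max_px maximum cartesian and perpendicular distance, px.
#' @param extrap_d_perp_px perpendicular offset triggering extrapolation, px.
#' @param extrap_angle_deg near-parallel angle triggering extrapolation, deg.
#' @param many_candidates switch to the \code{D_min + 1 - N_dot} cost above
#'   this many surviving candidates.
#' @param nfit points used per direction fit: \code{Inf} (default) fits the
#'   whole track (daughters) and all pre-start points (mothers), appropriate
#'   for straight microtubules; a finite value fits that many points nearest
#'   the branch, for curved tracks.
#' @param min_frames trajectories shorter than this are not considered as
#'   daughters (their direction estimate is too noisy); they remain
#'   candidate mothers.
#' @return data.frame (daughter_id, mother_id, angle_deg, D_min, D_perp,
#'   N_dot); \code{mother_id} is NA for unassigned (de novo) trajectories.
#' @export
assign_mothers <- function(trajectories, max_angle_deg = 150, d_max_px = 20,
                           extrap_d_perp_px = 8, extrap_angle_deg = 9,
                           many_candidates = 3, nfit = Inf, min_frames = 6) {
  ids <- unique(trajectories$trajectory_id)
  tr <- lapply(ids, function(id) {
    s <- trajectories[trajectories$trajectory_id == id, , drop = FALSE]
    s[order(s$frame), ]
  })
  starts <- vapply(tr, function(s) s$frame[1], 0)
  ord <- order(starts)
  tr <- tr[ord]; ids <- ids[ord]; starts <- starts[ord]

  res <- list()
  for (i in seq_along(tr)[-1] ) {
    ti <- tr[[i]]
    if (nrow(ti) < min_frames) next
    p0 <- c(ti$x[1], ti$y[1])
    ni <- min(nfit, nrow(ti))
    dir_i <- tls_direction(ti$x[seq_len(ni)], ti$y[seq_len(ni)])
    cands <- list()
    for (j in seq_len(i - 1)) {
      tj <- tr[[j]]
      pre <- tj[tj$frame < starts[i], , drop = FALSE]
      if (nrow(pre) < 2) next
      d2 <- (pre$x - p0[1])^2 + (pre$y - p0[2])^2
      kmin <- which.min(d2)
      D_min <- sqrt(d2[kmin])
      # mother direction near the closest point (whole pre-start track when
      # nfit = Inf; microtubules grow straight)
      if (is.finite(nfit)) {
        lo <- max(1, kmin - nfit %/% 2)
        hi <- min(nrow(pre), lo + nfit - 1)
      } else {
        lo <- 1; hi <- nrow(pre)
      }
      dir_j <- tls_direction(pre$x[lo:hi], pre$y[lo:hi])
      if (anyNA(dir_i) || anyNA(dir_j)) next
      N_dot <- sum(dir_i * dir_j)
      ang <- angle_deg(dir_i, dir_j)
      pj <- c(pre$x[kmin], pre$y[kmin])
      D_perp <- abs(-(p0[1] - pj[1]) * dir_j[2] + (p0[2] - pj[2]) * dir_j[1])
      if (ang > max_angle_deg) next
      if (D_min > d_max_px || D_perp > d_max_px) next

      # extrapolate the daughter backwards to the mother line when its start
      # lies well off the mother; skipped for near-parallel pairs (below
      # extrap_angle_deg) where the intersection is ill-conditioned
      if (D_perp > extrap_d_perp_px && ang >= extrap_angle_deg) {
        q <- line_intersect(p0, dir_i, pj, dir_j)
        if (!is.null(q)) {
          dq2 <- (pre$x - q[1])^2 + (pre$y - q[2])^2
          kq <- which.min(dq2)
          # the intersection must fall on lattice recorded before i started
          if (sqrt(dq2[kq]) <= 3) {
            D_min <- sqrt(sum((q - p0)^2))
            if (D_min > d_max_px) next
          }
        }
      }

      # crossing rejection: daughter must stay on one side of the mother line
      if (crosses_line(ti, pj, dir_j, clearance = 2, skip_px = 5)) next

      signed <- atan2(dir_j[1] * dir_i[2] - dir_j[2] * dir_i[1],
                      sum(dir_i * dir_j)) * 180 / pi
      cands[[length(cands) + 1L]] <- list(j = j, D_min = D_min,
                                          D_perp = D_perp, N_dot = N_dot,
                                          angle = signed)
    }
    if (length(cands) == 0) {
      res[[length(res) + 1L]] <- data.frame(daughter_id = ids[i],
                                            mother_id = NA_integer_,
                                            angle_deg = NA_real_,
                                            D_min = NA_real_,
                                            D_perp = NA_real_,
                                            N_dot = NA_real_)
      next
    }
    cost <- vapply(cands, function(cc)
      if (length(cands) > many_candidates) cc$D_min + 1 - cc$N_dot else cc$D_min, 0)
    best <- cands[[which.min(cost)]]
    res[[length(res) + 1L]] <- data.frame(daughter_id = ids[i],
                                          mother_id = ids[best$j],
                                          angle_deg = best$angle,
                                          D_min = best$D_min,
                                          D_perp = best$D_perp,
                                          N_dot = best$N_dot)
  }
  do.call(rbind, res)
}

# intersection of two lines given as point + direction; NULL if near-parallel
line_intersect <- function(p1, d1, p2, d2) {
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-9) return(NULL)
  t2 <- ((p1[1] - p2[1]) * d1[2] - (p1[2] - p2[2]) * d1[1]) / (-den)
  p2 + t2 * d2
}

# does trajectory ti cross the line through pj with direction dir_j?
crosses_line <- function(ti, pj, dir_j, clearance = 2, skip_px = 5) {
  dx <- ti$x - ti$x[1]; dy <- ti$y - ti$y[1]
  far <- sqrt(dx^2 + dy^2) > skip_px
  if (sum(far) < 2) return(FALSE)
  s <- -(ti$x[far] - pj[1]) * dir_j[2] + (ti$y[far] - pj[2]) * dir_j[1]
  any(s > clearance) && any(s < -clearance)
}

#' Binned probability distribution with bootstrap confidence band
#'
#' @param values numeric sample.
#' @param breaks bin edges (or a bin count; range-based edges are derived).
#' @param n_boot bootstrap resamples.
#' @param level confidence level.
#' @param seed optional RNG seed for the resampling.
#' @return a \code{distance_distribution}: list(breaks, mid, prob, ci_lo,
#'   ci_hi, n, level). Probabilities sum to 1 over the bins.
#' @export
distance_distribution <- function(values, breaks = 10, n_boot = 1000,
                                  level = 0.95, seed = NULL) {
  values <- values[is.finite(values)]
  n <- length(values)
  stopifnot(n >= 1)
  if (length(breaks) == 1)
    breaks <- seq(min(values), max(values) + 1e-12, length.out = breaks + 1)
  binfun <- function(x) {
    h <- graphics::hist(pmin(pmax(x, breaks[1]), breaks[length(breaks)]),
                        breaks = breaks, plot = FALSE)
    h$counts / length(x)
  }
  prob <- binfun(values)
  ci <- if (n >= 10) bootstrap_ci(values, binfun, n_boot, level, seed)
        else list(lo = prob, hi = prob)
  structure(list(breaks = breaks,
                 mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 prob = prob, ci_lo = ci$lo, ci_hi = ci$hi,
                 n = n, level = level),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("distance_distribution: n = %d, %d bins, %g%% bootstrap CI\n",
              x$n, length(x$prob), 100 * x$level))
  print(data.frame(bin_center = x$mid, probability = x$prob,
                   ci_lo = x$ci_lo, ci_hi = x$ci_hi))
  invisible(x)
}

#' Percentile bootstrap confidence band for a vector statistic
#'
#' @param sample numeric sample (n >= 10).
#' @param statistic function mapping a sample to a numeric vector (e.g.
#'   binned probabilities).
#' @param n_boot resamples with replacement.
#' @param level confidence level.
#' @param seed optional RNG seed.
#' @return list(estimate, lo, hi).
#' @export
bootstrap_ci <- function(sample, statistic, n_boot = 1000, level = 0.95,
                         seed = NULL) {
  n <- length(sample)
  stopifnot(n >= 10)
  if (!is.null(seed)) set.seed(seed)
  est <- statistic(sample)
  boot <- matrix(0, n_boot, length(est))
  for (b in seq_len(n_boot))
    boot[b, ] <- statistic(sample[sample.int(n, n, replace = TRUE)])
  a <- (1 - level) / 2
  list(estimate = est,
       lo = apply(boot, 2, stats::quantile, probs = a),
       hi = apply(boot, 2, stats::quantile, probs = 1 - a))
}

#' First-branch nucleation profiles
#'
#' Normalized probability histograms, with bootstrap confidence bands, of
#' the first-branch distance from the mother's minus-end, from the plus-end
#' (conventionally plotted on an inverted axis: 0 um = at the plus-end), and
#' of the fractional position along the mother.
#'
#' @param records data.frame with columns d_minus, d_plus, fraction (one row
#'   per network), e.g. from \code{\link{simulate_first_branch_ensemble}}.
#' @param bins bin count (fraction bins span [0, 1]).
#' @param n_boot,level bootstrap settings.
#' @return list of three \code{distance_distribution}s: d_minus, d_plus,
#'   fraction.
#' @export
first_branch_profile <- function(records, bins = 10, n_boot = 1000,
                                 level = 0.95) {
  records <- records[is.finite(records$fraction), , drop = FALSE]
  stopifnot(nrow(records) >= 1)
  list(
    d_minus = distance_distribution(records$d_minus, bins, n_boot, level),
    d_plus = distance_distribution(records$d_plus, bins, n_boot, level),
    fraction = distance_distribution(records$fraction,
                                     seq(0, 1, length.out = bins + 1),
                                     n_boot, level)
  )
}

#' Plus-end distance distribution from comet detections
#'
#' Pools, over frames whose comet count lies in \code{count_window}, the
#' cartesian comet distances from the network origin rescaled by the longest
#' distance in that frame.
#'
#' @param comets data.frame (frame, x, y) of detections (px or um — the
#'   normalization removes the unit).
#' @param origin c(x, y) network origin in the same units.
#' @param count_window c(min, max) comet count per qualifying frame.
#' @param bins,n_boot,level histogram settings.
#' @return a \code{distance_distribution}, or NULL when no frame qualifies.
#' @export
plus_end_distance_distribution <- function(comets, origin,
                                           count_window = c(10, 55),
                                           bins = 10, n_boot = 1000,
                                           level = 0.95) {
  pooled <- numeric()
  for (f in unique(comets$frame)) {
    cf <- comets[comets$frame == f, , drop = FALSE]
    if (nrow(cf) < count_window[1] || nrow(cf) > count_window[2]) next
    d <- sqrt((cf$x - origin[1])^2 + (cf$y - origin[2])^2)
    if (max(d) <= 0) next
    pooled <- c(pooled, d / max(d))
  }
  if (length(pooled) == 0) return(NULL)
  distance_distribution(pooled, seq(0, 1, length.out = bins + 1),
                        n_boot, level)
}

#' Normalized end distances of a simulated network
#'
#' For every microtubule count N in \code{mt_window} that the network
#' reaches, takes the instant the N-th microtubule is born and records the
#' distances of all plus- or minus-ends from the origin, normalized either
#' by the seed microtubule's length at that instant (\code{"seed"}, the
#' minus-end convention) or by the largest end distance (\code{"max"}, the
#' plus-end convention).
#'
#' @param network a \code{branch_network}.
#' @param ends "plus" or "minus".
#' @param mt_window c(min, max) microtubule counts pooled.
#' @param normalization "seed" or "max".
#' @return numeric vector of pooled normalized distances.
#' @export
network_end_distances <- function(network, ends = c("plus", "minus"),
                                  mt_window = c(10, 60),
                                  normalization = c("seed", "max")) {
  ends <- match.arg(ends); normalization <- match.arg(normalization)
  m <- network$mts[order(network$mts$birth_time), ]
  v <- network$params$v_pe
  origin <- c(m$minus_x[1], m$minus_y[1])
  pooled <- numeric()
  for (N in seq(mt_window[1], mt_window[2])) {
    if (N > nrow(m)) break
    tN <- m$birth_time[N]
    if (tN > network$t_end) break
    sub <- m[seq_len(N), ]
    if (ends == "minus") {
      px <- sub$minus_x; py <- sub$minus_y
    } else {
      len <- v * (tN - sub$birth_time)
      px <- sub$minus_x + sub$dir_x * len
      py <- sub$minus_y + sub$dir_y * len
    }
    d <- sqrt((px - origin[1])^2 + (py - origin[2])^2)
    norm <- if (normalization == "seed") v * tN else max(d)
    if (norm <= 0) next
    pooled <- c(pooled, d / norm)
  }
  pooled
}

#' Minus-end distance distribution of a simulated network ensemble
#'
#' Minus-ends are unobservable in images, so this statistic is defined on
#' simulated networks: distances of all minus-ends from the origin,
#' normalized by the seed microtubule's length (set to 1), pooled over the
#' microtubule-count window.
#'
#' @param networks a \code{branch_network} or list of them.
#' @param mt_window,bins,n_boot,level see
#'   \code{\link{network_end_distances}} / \code{\link{distance_distribution}}.
#' @return a \code{distance_distribution}.
#' @export
minus_end_distance_distribution <- function(networks, mt_window = c(10, 60),
                                            bins = 10, n_boot = 1000,
                                            level = 0.95) {
  if (inherits(networks, "branch_network")) networks <- list(networks)
  pooled <- unlist(lapply(networks, network_end_distances, ends = "minus",
                          mt_window = mt_window, normalization = "seed"))
  distance_distribution(pooled, bins, n_boot, level)
}

#' Exponential fit to microtubule counts over time
#'
#' Least-squares fit of \code{a * exp(k t)} to comet counts; returns the
#' autocatalytic nucleation rate k converted to min^-1. Falls back to a
#' log-linear fit with a warning if the nonlinear fit does not converge.
#'
#' @param counts comet/microtubule counts (>= 1).
#' @param times times, s.
#' @return rate k, min^-1.
#' @export
exponential_count_fit <- function(counts, times) {
  stopifnot(all(counts >= 1), length(counts) == length(times))
  lf <- stats::lm(log(counts) ~ times)
  k0 <- stats::coef(lf)[2]; a0 <- exp(stats::coef(lf)[1])
  # exact exponential input: the log-linear fit is already perfect and nls
  # cannot iterate on zero residuals
  if (sqrt(mean(stats::resid(lf)^2)) < 1e-10) return(unname(k0) * 60)
  fit <- tryCatch(
    stats::nls(counts ~ a * exp(k * times),
               start = list(a = a0, k = k0)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("exponential fit did not converge; using log-linear estimate")
    return(unname(k0) * 60)
  }
  unname(stats::coef(fit)["k"]) * 60
}

#' Two-sample Kolmogorov-Smirnov statistic for self-similarity
#'
#' Compares normalized end-distance distributions at an early and a late
#' stage of network growth; small values indicate the architecture is
#' preserved as the network grows.
#'
#' @param dist_early,dist_late numeric samples of normalized distances.
#' @return the KS statistic (sup-distance between empirical CDFs).
#' @export
self_similarity_ks <- function(dist_early, dist_late) {
  stopifnot(length(dist_early) > 0, length(dist_late) > 0)
  unname(suppressWarnings(
    stats::ks.test(dist_early, dist_late)$statistic))
}
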