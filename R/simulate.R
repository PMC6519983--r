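#' Simulate a branched microtubule network
#'
#' Runs the stochastic assembly of one branched network, starting at time 0
#' with a single microtubule of zero length (de novo nucleation), under one
#' of two kinetic schemes:
#' \describe{
#'   \item{single_step}{per time step dt the number of new branches is
#'     Poisson with mean \code{k * dt * L(t)}, where L(t) is the total
#'     polymer length at the start of the step. Each branch origin is uniform
#'     over the existing length and the daughter starts at zero length.}
#'   \item{sequential}{per step, \code{Poisson(k_bind * dt * L(t))} nucleation
#'     sites are deposited uniformly over the existing length; every
#'     unconsumed site then fires independently with probability
#'     \code{1 - exp(-k_branch * dt)}, consuming the site and creating a
#'     zero-length daughter at the site position.}
#' }
#' Branch angles are drawn from \code{N(angle_mean, angle_sd)} degrees with a
#' fair-coin sign applied to the rotation relative to the mother direction.
#' The simulation stops at \code{t_max} or once \code{max_mts} microtubules
#' exist, whichever is first.
#'
#' @param params a \code{\link{sim_params}} object.
#' @param model \code{"single_step"} or \code{"sequential"}.
#' @return a \code{\link{branch_network}}.
#' @examples
#' net <- simulate_network(sim_params(t_max = 400, max_mts = 30, seed = 1),
#'                         model = "sequential")
#' net
#' @export
simulate_network <- function(params, model = c("single_step", "sequential")) {
  model <- match.arg(model)
  validate_sim_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  if (model == "single_step") sim_core(params, params$k, 0, single_step = TRUE)
  else sim_core(params, params$k_bind, params$k_branch, single_step = FALSE)
}

# Shared stepping engine. In single-step mode every deposited "site" fires
# immediately; in sequential mode sites persist until consumed.
sim_core <- function(params, k_dep, k_br, single_step) {
  v <- params$v_pe; dt <- params$dt
  n_steps <- ceiling(params$t_max / dt)
  cap <- as.integer(params$max_mts)

  # MT state vectors (preallocated to max_mts)
  birth <- minus_x <- minus_y <- dir_x <- dir_y <- arcpos <- numeric(cap)
  mother <- integer(cap)
  n_mt <- 1L
  birth[1] <- 0; minus_x[1] <- 0; minus_y[1] <- 0
  theta0 <- stats::runif(1, 0, 2 * pi)   # seed orientation isotropic
  dir_x[1] <- cos(theta0); dir_y[1] <- sin(theta0)
  mother[1] <- NA_integer_; arcpos[1] <- NA_real_

  # site state (sequential only), grown geometrically
  s_cap <- 64L
  s_mt <- integer(s_cap); s_arc <- s_dep <- s_brt <- numeric(s_cap)
  n_site <- 0L; s_alive <- logical(s_cap)

  warned_coarse <- FALSE
  t <- 0
  for (step in seq_len(n_steps)) {
    idx <- seq_len(n_mt)
    len <- v * (t - birth[idx])          # current lengths (>= 0 by construction)
    L <- sum(len)

    n_new_branches <- 0L
    new_mt <- integer(0); new_arc <- numeric(0); new_site_idx <- integer(0)

    if (L > 0 && k_dep > 0) {
      mu <- k_dep * dt * L
      if (!warned_coarse && mu > 10) {
        warning("more than 10 expected events per step; decrease dt")
        warned_coarse <- TRUE
      }
      n_dep <- stats::rpois(1, mu)
      if (n_dep > 0) {
        # position uniform over total existing length
        host <- sample.int(n_mt, n_dep, replace = TRUE, prob = len)
        arc <- stats::runif(n_dep) * len[host]
        if (single_step) {
          n_new_branches <- n_dep
          new_mt <- host; new_arc <- arc
        } else {
          # deposit persistent sites
          need <- n_site + n_dep
          if (need > s_cap) {
            ncap <- max(2L * s_cap, need)
            s_mt <- c(s_mt, integer(ncap - s_cap))
            s_arc <- c(s_arc, numeric(ncap - s_cap))
            s_dep <- c(s_dep, numeric(ncap - s_cap))
            s_brt <- c(s_brt, numeric(ncap - s_cap))
            s_alive <- c(s_alive, logical(ncap - s_cap))
            s_cap <- ncap
          }
          at <- n_site + seq_len(n_dep)
          s_mt[at] <- host; s_arc[at] <- arc
          s_dep[at] <- t + dt / 2   # events occur within the step: midpoint
          s_brt[at] <- NA_real_; s_alive[at] <- TRUE
          n_site <- n_site + n_dep
        }
      }
    }

    if (!single_step && n_site > 0 && k_br > 0) {
      alive <- which(s_alive[seq_len(n_site)])
      if (length(alive) > 0) {
        fire <- alive[stats::runif(length(alive)) < (1 - exp(-k_br * dt))]
        if (length(fire) > 0) {
          n_new_branches <- length(fire)
          new_mt <- s_mt[fire]; new_arc <- s_arc[fire]
          new_site_idx <- fire
          s_alive[fire] <- FALSE
          s_brt[fire] <- t + dt / 2
        }
      }
    }

    if (n_new_branches > 0) {
      keep <- seq_len(min(n_new_branches, cap - n_mt))
      for (b in keep) {
        mid <- new_mt[b]
        ang <- stats::rnorm(1, params$angle_mean, params$angle_sd) *
          sample(c(-1, 1), 1)
        th <- atan2(dir_y[mid], dir_x[mid]) + ang * pi / 180
        j <- n_mt + 1L
        birth[j] <- t + dt / 2   # midpoint timestamp (unbiased event time)
        minus_x[j] <- minus_x[mid] + dir_x[mid] * new_arc[b]
        minus_y[j] <- minus_y[mid] + dir_y[mid] * new_arc[b]
        dir_x[j] <- cos(th); dir_y[j] <- sin(th)
        mother[j] <- mid; arcpos[j] <- new_arc[b]
        n_mt <- j
      }
      if (length(keep) < n_new_branches && length(new_site_idx) > 0) {
        # branches beyond the MT cap leave their sites unconsumed
        undo <- new_site_idx[-keep]
        s_alive[undo] <- TRUE; s_brt[undo] <- NA_real_
      }
    }

    t <- t + dt
    if (n_mt >= cap) break
  }

  idx <- seq_len(n_mt)
  mts <- data.frame(id = idx, birth_time = birth[idx],
                    minus_x = minus_x[idx], minus_y = minus_y[idx],
                    dir_x = dir_x[idx], dir_y = dir_y[idx],
                    mother_id = mother[idx], branch_arc_pos = arcpos[idx])
  sites <- if (single_step || n_site == 0) empty_sites() else {
    si <- seq_len(n_site)
    data.frame(id = si, mt_id = s_mt[si], arc_pos = s_arc[si],
               deposit_time = s_dep[si], branch_time = s_brt[si])
  }
  new_branch_network(params, mts, sites, t_end = t,
                     model = if (single_step) "single_step" else "sequential")
}

#' First-branch record of a network
#'
#' Locates the first branching event off the seed microtubule and records the
#' geometry at that instant: the seed minus-end m0, the new branch origin m1,
#' the seed plus-end p0 at the branch time t1, the distances
#' d_minus = |m0 - m1| and d_plus = |p0 - m1|, and the fractional position
#' \code{d_minus / (d_minus + d_plus)} along the mother.
#'
#' @param network a \code{branch_network} (needs at least 2 microtubules,
#'   otherwise \code{NULL} is returned).
#' @return list of class \code{first_branch_record} with fields m0, m1, p0,
#'   d_minus, d_plus, fraction, t1 — or \code{NULL} when no branch occurred.
#' @export
first_branch_record <- function(network) {
  m <- network$mts
  if (nrow(m) < 2) return(NULL)
  seed_id <- m$id[is.na(m$mother_id)]
  kids <- m[!is.na(m$mother_id), , drop = FALSE]
  first <- kids[which.min(kids$birth_time), , drop = FALSE]
  if (first$mother_id != seed_id) return(NULL)
  seed <- m[m$id == seed_id, , drop = FALSE]
  t1 <- first$birth_time
  mother_len <- network$params$v_pe * (t1 - seed$birth_time)
  m0 <- c(seed$minus_x, seed$minus_y)
  m1 <- c(first$minus_x, first$minus_y)
  p0 <- m0 + c(seed$dir_x, seed$dir_y) * mother_len
  d_minus <- sqrt(sum((m1 - m0)^2))
  d_plus <- sqrt(sum((m1 - p0)^2))
  structure(list(m0 = m0, m1 = m1, p0 = p0, d_minus = d_minus,
                 d_plus = d_plus, fraction = d_minus / (d_minus + d_plus),
                 t1 = t1),
            class = "first_branch_record")
}

#' Simulate an ensemble of first branching events
#'
#' Convenience wrapper: runs \code{n} independent simulations, each stopped
#' at the first branch (\code{max_mts = 2}), and tabulates the first-branch
#' records.
#'
#' @param params a \code{sim_params}; \code{t_max} must be long enough that
#'   essentially all replicates branch.
#' @param model \code{"single_step"} or \code{"sequential"}.
#' @param n number of replicates.
#' @return data.frame with one row per replicate: t1, d_minus, d_plus,
#'   fraction, n_mts_final (replicates that never branched have NA rows).
#' @export
simulate_first_branch_ensemble <- function(params, model, n) {
  p <- params; p$max_mts <- 2L; p$seed <- NULL
  out <- data.frame(replicate = seq_len(n), t1 = NA_real_,
                    d_minus = NA_real_, d_plus = NA_real_,
                    fraction = NA_real_, n_mts_final = NA_integer_)
  for (i in seq_len(n)) {
    net <- simulate_network(p, model)
    out$n_mts_final[i] <- nrow(net$mts)
    r <- first_branch_record(net)
    if (!is.null(r)) {
      out$t1[i] <- r$t1; out$d_minus[i] <- r$d_minus
      out$d_plus[i] <- r$d_plus; out$fraction[i] <- r$fraction
    }
  }
  out
}
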