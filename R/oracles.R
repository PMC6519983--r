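#' First-branch law of the single-step model
#'
#' On a lone mother growing at speed v_pe, branches arrive with hazard
#' \code{k * v_pe * t}, so the waiting time to the first branch is Rayleigh:
#' survival \code{S(t) = exp(-k * v_pe * t^2 / 2)}, mean time
#' \code{sqrt(pi / (2 k v_pe))} and mean mother length at the first branch
#' \code{v_pe * E[T] = sqrt(pi * v_pe / (2 k))}.
#'
#' @param params a \code{\link{sim_params}} (uses \code{k}, \code{v_pe}).
#' @return list with \code{survival} (a function of t), \code{mean_time} (s)
#'   and \code{mean_length} (um).
#' @export
first_branch_oracle_single_step <- function(params) {
  k <- params$k; v <- params$v_pe
  stopifnot(k > 0, v > 0)
  list(
    survival = function(t) exp(-k * v * t^2 / 2),
    mean_time = sqrt(pi / (2 * k * v)),
    mean_length = sqrt(pi * v / (2 * k))
  )
}

#' First-branch law of the sequential model
#'
#' Sites deposit on the lone mother at rate \code{k_bind * v_pe * u} at age u
#' and each fires at rate k_branch, so the branch intensity at time t is
#' \code{beta(t) = k_bind * v_pe * (t - (1 - exp(-k_branch t)) / k_branch)}
#' (the integral of the deposition history against the exponential firing
#' kernel, in closed form). The cumulative hazard is
#' \code{Lambda(t) = k_bind * v_pe * (t^2/2 - t/k_branch +
#' (1 - exp(-k_branch t))/k_branch^2)} and \code{S(t) = exp(-Lambda(t))}.
#' Mean time and length are computed by numerical quadrature of S. In the
#' limit \code{k_branch * t << 1} this reduces to
#' \code{S(t) = exp(-k_bind v_pe k_branch t^3 / 6)} with mean time
#' \code{(6 / (k_bind v_pe k_branch))^{1/3} Gamma(4/3)}.
#'
#' @param params a \code{sim_params} (uses \code{k_bind}, \code{k_branch},
#'   \code{v_pe}).
#' @param rel_tol quadrature relative tolerance.
#' @return list with \code{survival} (function of t), \code{mean_time} (s),
#'   \code{mean_length} (um) and \code{mean_time_smallkb} (the cubic-law
#'   limit, s).
#' @export
first_branch_oracle_sequential <- function(params, rel_tol = 1e-8) {
  kb <- params$k_bind; a <- params$k_branch; v <- params$v_pe
  stopifnot(kb > 0, a > 0, v > 0)
  Lambda <- function(t) kb * v * (t^2 / 2 - t / a + (1 - exp(-a * t)) / a^2)
  S <- function(t) exp(-Lambda(t))
  # integrate S out to where it is negligible
  t_hi <- 10 * (6 / (kb * v * a))^(1 / 3)
  while (S(t_hi) > 1e-12) t_hi <- t_hi * 2
  q <- stats::integrate(S, 0, t_hi, rel.tol = rel_tol, subdivisions = 500L)
  if (q$abs.error > max(1e-6, 10 * rel_tol * q$value))
    stop(sprintf("quadrature did not converge (abs error %.3g on %.6g)",
                 q$abs.error, q$value))
  mean_t <- q$value
  list(
    survival = S,
    mean_time = mean_t,
    mean_length = params$v_pe * mean_t,
    mean_time_smallkb = (6 / (kb * v * a))^(1 / 3) * gamma(4 / 3)
  )
}

#' Asymptotic exponential growth rate of the microtubule count
#'
#' At long times the MT count grows as \code{exp(lambda t)}. For the
#' single-step model the mean-field system dN/dt = k L, dL/dt = v_pe N gives
#' \code{lambda = sqrt(k v_pe)}. For the sequential model (S = live sites)
#' dS/dt = k_bind L - k_branch S, dN/dt = k_branch S, dL/dt = v_pe N, whose
#' characteristic equation is
#' \code{lambda^2 (lambda + k_branch) = k_bind k_branch v_pe}; the unique
#' positive root is returned.
#'
#' @param model \code{"single_step"} or \code{"sequential"}.
#' @param params a \code{sim_params}.
#' @return growth rate lambda, s^-1.
#' @export
asymptotic_growth_rate <- function(model = c("single_step", "sequential"),
                                   params) {
  model <- match.arg(model)
  v <- params$v_pe
  if (model == "single_step") return(sqrt(params$k * v))
  kb <- params$k_bind; a <- params$k_branch
  rhs <- kb * a * v
  f <- function(l) l^2 * (l + a) - rhs
  upper <- max(sqrt(kb * v), rhs^(1 / 3)) * 2 + a
  stats::uniroot(f, c(1e-12, upper), tol = 1e-14)$root
}

#' Dimensionless regime ratio of the sequential model
#'
#' Returns \code{k_branch / sqrt(k_bind * v_pe)}, the ratio of the branching
#' (activation) rate constant to the effective binding rate constant. Well
#' below 1 the branch step is rate-limiting and nucleation is biased toward
#' the mother's minus-end; well above ~100 the sequential model approaches
#' the single-step model and the bias vanishes.
#'
#' @param params a \code{sim_params}.
#' @return dimensionless ratio.
#' @export
dimensionless_ratio <- function(params) {
  stopifnot(params$k_bind > 0, params$v_pe > 0)
  params$k_branch / sqrt(params$k_bind * params$v_pe)
}

#' Minus-end bias statistic of first-branch fractional positions
#'
#' Defined as \code{1 - 2 * mean(fraction)}: 0 for positions uniform along
#' the mother, approaching 1 for extreme minus-end preference, negative for
#' plus-end preference.
#'
#' @param fraction numeric vector of fractional first-branch positions in
#'   [0, 1].
#' @return bias statistic in [-1, 1].
#' @export
bias_statistic <- function(fraction) {
  fraction <- fraction[is.finite(fraction)]
  1 - 2 * mean(fraction)
}

#' Scan network bias across the dimensionless regime ratio
#'
#' For each requested ratio \code{k_branch / sqrt(k_bind v_pe)}, co-varies
#' k_bind and k_branch so that the oracle mean first-branch mother length is
#' held at the base parameters' value (the net nucleation rate calibration),
#' simulates \code{n} first-branch replicates of the sequential model, and
#' computes the minus-end \code{\link{bias_statistic}}.
#'
#' @param ratios positive dimensionless ratios to scan.
#' @param params base \code{sim_params} whose oracle mean first-branch length
#'   is the calibration constraint.
#' @param n replicates per scan point (a warning is raised below 100).
#' @return data.frame with columns ratio, k_bind, k_branch, bias_statistic,
#'   n_networks.
#' @export
parameter_scan <- function(ratios, params, n = 500) {
  stopifnot(all(ratios > 0))
  if (n < 100) warning("fewer than 100 networks per point: bias will be noisy")
  target <- first_branch_oracle_sequential(params)$mean_length
  v <- params$v_pe
  out <- data.frame(ratio = ratios, k_bind = NA_real_, k_branch = NA_real_,
                    bias_statistic = NA_real_, n_networks = n)
  for (i in seq_along(ratios)) {
    r <- ratios[i]
    # solve for k_bind (log scale) such that mean first-branch length = target
    g <- function(log_kb) {
      kb <- exp(log_kb)
      p <- params; p$k_bind <- kb; p$k_branch <- r * sqrt(kb * v)
      first_branch_oracle_sequential(p)$mean_length - target
    }
    sol <- stats::uniroot(g, c(log(params$k_bind) - 12, log(params$k_bind) + 12),
                          tol = 1e-10)
    kb <- exp(sol$root)
    p <- params; p$k_bind <- kb; p$k_branch <- r * sqrt(kb * v)
    # keep the per-step firing probability within the accuracy guard
    while (p$dt * p$k_branch >= 0.1) p$dt <- p$dt / 2
    # horizon long enough for virtually all replicates to branch
    p$t_max <- max(params$t_max, 10 * first_branch_oracle_sequential(p)$mean_time)
    # high-k_bind points deposit > 10 sites per step on a long mother; sites
    # fire independently, so this does not degrade first-branch statistics
    ens <- suppressWarnings(simulate_first_branch_ensemble(p, "sequential", n))
    out$k_bind[i] <- kb
    out$k_branch[i] <- p$k_branch
    out$bias_statistic[i] <- bias_statistic(ens$fraction)
  }
  class(out) <- c("scan_result", class(out))
  out
}
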