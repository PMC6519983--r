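#' Kinetic and geometric parameters for branched-network simulations
#'
#' Bundles every rate and geometry parameter used by both nucleation models.
#' Defaults are the calibrated values for branching nucleation in meiotic
#' cytoplasm: a net plus-end growth speed of 0.09 um/s, a single-step
#' nucleator binding rate of 1.1e-3 molecules um^-1 s^-1, and for the
#' sequential scheme a site-deposition rate k_bind = 0.1 molecules um^-1 s^-1
#' with a per-site branching rate k_branch = 2.5e-4 s^-1. Branch angles are
#' drawn from a Gaussian with mean 0 degrees and standard deviation 9 degrees.
#'
#' @param v_pe net plus-end growth speed, um/s. Subsumes growth, pause and
#'   catastrophe phases into one constant net speed.
#' @param k single-step nucleator binding rate, molecules um^-1 s^-1.
#' @param k_bind sequential-model site deposition rate, molecules um^-1 s^-1.
#' @param k_branch sequential-model per-site branching rate, s^-1.
#' @param angle_mean,angle_sd branch-angle Gaussian, degrees. A random sign
#'   is applied to the rotation, so only the magnitude distribution matters.
#' @param dt simulation time step, s.
#' @param t_max simulation horizon, s.
#' @param max_mts stop once this many microtubules exist.
#' @param seed optional RNG seed applied at the start of a simulation.
#' @return An object of class \code{sim_params} (a validated list).
#' @examples
#' p <- sim_params(t_max = 300)
#' p$v_pe
#' @export
sim_params <- function(v_pe = 0.09, k = 1.1e-3, k_bind = 0.1,
                       k_branch = 2.5e-4, angle_mean = 0, angle_sd = 9,
                       dt = 1, t_max = 600, max_mts = 400, seed = NULL) {
  p <- list(v_pe = v_pe, k = k, k_bind = k_bind, k_branch = k_branch,
            angle_mean = angle_mean, angle_sd = angle_sd, dt = dt,
            t_max = t_max, max_mts = max_mts, seed = seed)
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(is.list(p))
  if (!is.numeric(p$v_pe) || p$v_pe <= 0) stop("v_pe must be > 0")
  for (nm in c("k", "k_bind", "k_branch", "angle_sd")) {
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0) stop(nm, " must be >= 0")
  }
  if (p$dt <= 0) stop("dt must be > 0")
  if (p$t_max <= 0) stop("t_max must be > 0")
  if (p$max_mts < 1) stop("max_mts must be >= 1")
  # step-accuracy guard: per-site branch probability must stay small per step
  if (p$dt * p$k_branch >= 0.1) stop("dt * k_branch must be < 0.1")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Branched-network simulation parameters\n")
  cat(sprintf("  v_pe     = %g um/s\n", x$v_pe))
  cat(sprintf("  k        = %g molecules/um/s (single-step)\n", x$k))
  cat(sprintf("  k_bind   = %g molecules/um/s, k_branch = %g /s (sequential)\n",
              x$k_bind, x$k_branch))
  cat(sprintf("  angles   ~ N(%g, %g) degrees\n", x$angle_mean, x$angle_sd))
  cat(sprintf("  dt = %g s, t_max = %g s, max_mts = %d\n",
              x$dt, x$t_max, as.integer(x$max_mts)))
  invisible(x)
}
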