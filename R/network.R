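#' @title Branched-network container
#' @description A \code{branch_network} holds the full state of one simulated
#' branched microtubule network: the parameter set, one row per microtubule
#' (id, birth time, minus-end position, unit growth direction, mother id and
#' the arc position of its origin on the mother), the nucleation-site table
#' (sequential model only), the end time and the model name. Microtubules are
#' straight rays growing at the constant net plus-end speed; the seed
#' microtubule (mother id \code{NA}) starts at the origin at time 0 with zero
#' length.
#' @name branch_network
NULL

new_branch_network <- function(params, mts, sites, t_end, model) {
  structure(list(params = params, mts = mts, sites = sites,
                 t_end = t_end, model = model),
            class = "branch_network")
}

empty_mts <- function() {
  data.frame(id = integer(), birth_time = numeric(),
             minus_x = numeric(), minus_y = numeric(),
             dir_x = numeric(), dir_y = numeric(),
             mother_id = integer(), branch_arc_pos = numeric())
}

empty_sites <- function() {
  data.frame(id = integer(), mt_id = integer(), arc_pos = numeric(),
             deposit_time = numeric(), branch_time = numeric())
}

#' Length of one microtubule at a time point
#'
#' @param network a \code{branch_network}.
#' @param t time, s.
#' @return numeric vector: length of every microtubule at \code{t}, um
#'   (zero before birth).
#' @export
mt_lengths <- function(network, t) {
  pmax(0, network$params$v_pe * (t - network$mts$birth_time))
}

#' Plus-end positions at a time point
#'
#' @inheritParams mt_lengths
#' @return data.frame with columns id, x, y (um) for microtubules born by t.
#' @export
plus_end_positions <- function(network, t) {
  m <- network$mts[network$mts$birth_time <= t, , drop = FALSE]
  len <- pmax(0, network$params$v_pe * (t - m$birth_time))
  data.frame(id = m$id, x = m$minus_x + m$dir_x * len,
             y = m$minus_y + m$dir_y * len)
}

#' Total polymer length of a network at a time point
#'
#' Sums v_pe * (t - birth time) over all microtubules born by \code{t}.
#'
#' @inheritParams mt_lengths
#' @return total length, um.
#' @export
total_length <- function(network, t) {
  if (t < 0) stop("t must be >= 0")
  if (t > network$t_end + 1e-9)
    stop("t exceeds the simulated horizon t_end")
  born <- network$mts$birth_time <= t
  sum(network$params$v_pe * (t - network$mts$birth_time[born]))
}

#' Check the structural invariants of a branched network
#'
#' @param network a \code{branch_network}.
#' @return character vector of violations (empty when the network is valid);
#'   each entry names the offending microtubule or site and the rule broken.
#' @export
validate_network <- function(network) {
  v <- character()
  m <- network$mts
  p <- network$params
  if (nrow(m) == 0) return(v)
  nrm <- sqrt(m$dir_x^2 + m$dir_y^2)
  bad <- which(abs(nrm - 1) > 1e-6)
  for (i in bad) v <- c(v, sprintf("MT %d: direction not unit length", m$id[i]))
  seeds <- which(is.na(m$mother_id))
  if (length(seeds) != 1)
    v <- c(v, sprintf("network: %d seed MTs (mother_id = NA), expected exactly 1",
                      length(seeds)))
  for (i in seq_len(nrow(m))) {
    if (is.na(m$mother_id[i])) next
    j <- match(m$mother_id[i], m$id)
    if (is.na(j)) {
      v <- c(v, sprintf("MT %d: mother_id %d not in network", m$id[i], m$mother_id[i]))
      next
    }
    if (m$birth_time[j] > m$birth_time[i])
      v <- c(v, sprintf("MT %d: born before its mother %d", m$id[i], m$id[j]))
    mother_len <- p$v_pe * (m$birth_time[i] - m$birth_time[j])
    if (m$branch_arc_pos[i] > mother_len + 1e-6)
      v <- c(v, sprintf("MT %d: branch_arc_pos %.3f exceeds mother length %.3f at birth",
                        m$id[i], m$branch_arc_pos[i], mother_len))
  }
  s <- network$sites
  if (!is.null(s) && nrow(s) > 0) {
    for (i in seq_len(nrow(s))) {
      j <- match(s$mt_id[i], m$id)
      if (is.na(j)) {
        v <- c(v, sprintf("site %d: host MT %d not in network", s$id[i], s$mt_id[i]))
        next
      }
      host_len <- p$v_pe * (s$deposit_time[i] - m$birth_time[j])
      if (s$arc_pos[i] > host_len + 1e-6)
        v <- c(v, sprintf("site %d: arc_pos beyond host length at deposit time", s$id[i]))
      if (!is.na(s$branch_time[i]) && s$branch_time[i] < s$deposit_time[i])
        v <- c(v, sprintf("site %d: branch_time before deposit_time", s$id[i]))
    }
  }
  v
}

#' Save a branched network to JSON
#'
#' The file carries a header stating the format version and units
#' (lengths um, times s, angles degrees) followed by the parameter set and
#' the microtubule and site tables.
#'
#' @param network a \code{branch_network}.
#' @param path output file path.
#' @export
save_network <- function(network, path) {
  obj <- list(
    header = list(format = "branchnet-network", version = "1",
                  units = list(length = "um", time = "s", angle = "deg")),
    model = network$model,
    t_end = network$t_end,
    params = network$params[setdiff(names(network$params), "seed")],
    seed = if (is.null(network$params$seed)) NULL else network$params$seed,
    mts = network$mts,
    sites = network$sites
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a branched network from JSON
#'
#' @param path file written by \code{\link{save_network}}.
#' @return a \code{branch_network}. A version-tag mismatch raises a warning
#'   and loading proceeds best-effort; a missing required field is an error
#'   naming the field.
#' @export
load_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$header) || !identical(obj$header$format, "branchnet-network"))
    stop("not a branchnet network file (missing header/format)")
  if (!identical(as.character(obj$header$version), "1"))
    warning("network file version ", obj$header$version,
            " differs from supported version 1; loading best-effort")
  for (f in c("v_pe", "dt", "t_max"))
    if (is.null(obj$params[[f]])) stop("network file missing parameter field: ", f)
  pl <- obj$params
  pl$seed <- obj$seed
  params <- sim_params(v_pe = pl$v_pe, k = pl$k, k_bind = pl$k_bind,
                       k_branch = pl$k_branch, angle_mean = pl$angle_mean,
                       angle_sd = pl$angle_sd, dt = pl$dt, t_max = pl$t_max,
                       max_mts = pl$max_mts, seed = pl$seed)
  mts <- as.data.frame(obj$mts)
  if (nrow(mts) == 0) mts <- empty_mts()
  mts$mother_id <- as.integer(mts$mother_id)
  sites <- if (is.null(obj$sites) || length(obj$sites) == 0) empty_sites()
           else as.data.frame(obj$sites)
  new_branch_network(params, mts, sites, obj$t_end, obj$model)
}

#' @export
print.branch_network <- function(x, ...) {
  cat(sprintf("branch_network (%s model): %d MTs, t_end = %g s, total length = %.2f um\n",
              x$model, nrow(x$mts), x$t_end, total_length(x, x$t_end)))
  if (!is.null(x$sites) && nrow(x$sites) > 0)
    cat(sprintf("  %d nucleation sites (%d consumed)\n", nrow(x$sites),
                sum(!is.na(x$sites$branch_time))))
  invisible(x)
}

#' @export
summary.branch_network <- function(object, ...) {
  len <- mt_lengths(object, object$t_end)
  cat(sprintf("%s model, %d MTs at t = %g s\n", object$model,
              nrow(object$mts), object$t_end))
  cat(sprintf("  total length %.2f um, mean MT length %.2f um\n",
              sum(len), mean(len)))
  cat(sprintf("  invariant violations: %d\n", length(validate_network(object))))
  invisible(object)
}

#' Plot a branched network as line segments
#'
#' @param x a \code{branch_network}.
#' @param t time at which to draw (default \code{t_end}).
#' @param ... passed to \code{plot}.
#' @export
plot.branch_network <- function(x, t = x$t_end, ...) {
  m <- x$mts[x$mts$birth_time <= t, , drop = FALSE]
  len <- pmax(0, x$params$v_pe * (t - m$birth_time))
  px <- m$minus_x + m$dir_x * len
  py <- m$minus_y + m$dir_y * len
  graphics::plot(range(c(m$minus_x, px)), range(c(m$minus_y, py)),
                 type = "n", xlab = "x (um)", ylab = "y (um)",
                 asp = 1, ...)
  graphics::segments(m$minus_x, m$minus_y, px, py,
                     col = grDevices::hcl.colors(max(8, nrow(m)), "Dark 3"))
  invisible(x)
}
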