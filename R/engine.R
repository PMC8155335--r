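#' Integrator configuration
#'
#' Settings for the DPD-adapted velocity-Verlet integrator. The scheme
#' predicts velocities with a factor \code{lambda} before evaluating the
#' velocity-dependent dissipative force and corrects with the trapezoidal
#' average afterwards. NPT uses simple isotropic weak-coupling box
#' rescaling toward a target total pressure; it is meant to set the bulk
#' density before production NVT runs, not to sample a rigorous
#' isothermal-isobaric ensemble.
#'
#' @param ensemble \code{"NVT"} or \code{"NPT"}.
#' @param dt Timestep in \eqn{\tau = d\sqrt{m/k_BT}}; default 0.01.
#' @param lambda Velocity-prediction parameter in (0, 1); default 0.65.
#' @param p_target Target total pressure for NPT (\eqn{k_BT/d^3});
#'   default 23.7, i.e. the bulk-water total pressure at density 3.
#' @param tau_p Barostat coupling time (\eqn{\tau}).
#' @param seed Integer seed for the run's single random stream.
#' @return An object of class \code{dpd_config}.
#' @export
dpd_config <- function(ensemble = c("NVT", "NPT"), dt = 0.01,
                       lambda = 0.65, p_target = 23.7, tau_p = 10,
                       seed = 1L) {
  ensemble <- match.arg(ensemble)
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be > 0")
  if (lambda <= 0 || lambda >= 1) stop("`lambda` must be in (0, 1)")
  if (tau_p <= 0) stop("`tau_p` must be > 0")
  structure(list(ensemble = ensemble, dt = dt, lambda = lambda,
                 p_target = p_target, tau_p = tau_p,
                 seed = as.integer(seed)),
            class = "dpd_config")
}

#' @export
print.dpd_config <- function(x, ...) {
  cat(sprintf("DPD integrator: %s, dt = %g tau, lambda = %g, seed = %d\n",
              x$ensemble, x$dt, x$lambda, x$seed))
  if (x$ensemble == "NPT")
    cat(sprintf("  barostat: P_target = %g kBT/d^3, tau_p = %g tau\n",
                x$p_target, x$tau_p))
  invisible(x)
}

ff_par <- function(ff, dt) {
  list(cutoff = ff$cutoff, bond_k = ff$bond_k, bond_l0 = ff$bond_l0,
       bend_k = ff$bend_k, gamma = ff$gamma, sigma = ff$sigma, dt = dt)
}

#' Compute per-bead forces
#'
#' Evaluates conservative pair forces plus bonded (bond and bending)
#' forces; optionally also the dissipative and random pair forces of the
#' DPD thermostat. Uses a linked-cell neighbour search when the box
#' admits at least three cells per edge, otherwise falls back to an
#' all-pairs loop.
#'
#' @param state A \code{dpd_state}.
#' @param ff A \code{dpd_forcefield}.
#' @param thermo Include dissipative + random forces? Default FALSE
#'   (conservative + bonded only).
#' @param dt Timestep used to scale the random force (only relevant with
#'   \code{thermo = TRUE}).
#' @param neighbours \code{"auto"}, \code{"cells"} or \code{"all-pairs"}.
#' @param seed Seed for the random force stream.
#' @return n x 3 force matrix with attribute \code{"virial"}, the sum
#'   \eqn{\sum F_{ij} \cdot r_{ij}} over conservative and bonded
#'   interactions.
#' @export
compute_forces <- function(state, ff, thermo = FALSE, dt = 0.01,
                           neighbours = c("auto", "cells", "all-pairs"),
                           seed = 1L) {
  neighbours <- match.arg(neighbours)
  use_cells <- switch(neighbours, auto = 2L, cells = 1L, `all-pairs` = 0L)
  res <- cpp_compute_forces(state$pos, state$vel, state$type, state$box,
                            ff$f, state$bonds, state$angles,
                            ff_par(ff, dt), thermo, use_cells,
                            as.integer(seed))
  structure(res$forces, virial = res$virial)
}

#' Run DPD dynamics
#'
#' Advances the state by \code{n_steps} of the DPD-adapted velocity-
#' Verlet scheme, emitting position frames and an observable time series.
#' Deterministic for a fixed seed and configuration.
#'
#' @param state A \code{dpd_state}.
#' @param ff A \code{dpd_forcefield}.
#' @param cfg A \code{dpd_config}.
#' @param n_steps Number of timesteps.
#' @param frame_stride Emit a position frame every this many steps
#'   (0 = no frames).
#' @param obs_stride Record observables every this many steps.
#' @param thermo Apply the DPD thermostat (dissipative + random forces)?
#'   Default TRUE.
#' @return A list of class \code{dpd_run} with elements \code{state}
#'   (final \code{dpd_state}), \code{traj} (a \code{dpd_traj}), and
#'   \code{obs} (data.frame: step, time, T, P_excess, P_total, L,
#'   momentum).
#' @export
dpd_run <- function(state, ff, cfg = dpd_config(), n_steps,
                    frame_stride = 0L, obs_stride = 100L, thermo = TRUE) {
  stopifnot(inherits(state, "dpd_state"), inherits(ff, "dpd_forcefield"),
            inherits(cfg, "dpd_config"))
  n_steps <- as.integer(n_steps)
  if (n_steps < 1) stop("`n_steps` must be >= 1")
  res <- cpp_run(state$pos, state$vel, state$type, state$box, ff$f,
                 state$bonds, state$angles, ff_par(ff, cfg$dt),
                 cfg$lambda, n_steps, as.integer(frame_stride),
                 as.integer(obs_stride),
                 if (cfg$ensemble == "NPT") 1L else 0L,
                 cfg$p_target, cfg$tau_p, cfg$seed, state$step, thermo)
  out_state <- state
  out_state$pos <- res$pos
  out_state$vel <- res$vel
  out_state$box <- as.numeric(res$box)
  out_state$step <- state$step + n_steps
  obs <- as.data.frame(res$obs)
  names(obs) <- c("step", "time", "T", "P_excess", "P_total", "L",
                  "momentum")
  traj <- dpd_traj(frames = res$frames,
                   boxes = res$frame_boxes,
                   steps = as.integer(res$frame_steps),
                   template = out_state)
  structure(list(state = out_state, traj = traj, obs = obs),
            class = "dpd_run")
}

#' @export
print.dpd_run <- function(x, ...) {
  cat(sprintf("DPD run to step %d: %d frames, %d observable rows\n",
              x$state$step, length(x$traj$frames), nrow(x$obs)))
  if (nrow(x$obs) > 0) {
    tail_obs <- x$obs[nrow(x$obs), ]
    cat(sprintf("  last: T = %.3f kBT, P_excess = %.3f, P_total = %.3f kBT/d^3\n",
                tail_obs$T, tail_obs$P_excess, tail_obs$P_total))
  }
  invisible(x)
}

#' Advance a state by a single timestep
#'
#' @inheritParams dpd_run
#' @return The advanced \code{dpd_state}.
#' @export
dpd_step <- function(state, ff, cfg = dpd_config(), thermo = TRUE) {
  dpd_run(state, ff, cfg, n_steps = 1L, frame_stride = 0L,
          obs_stride = 0L, thermo = thermo)$state
}

#' Trajectory container
#'
#' A lightweight list of position frames sharing the topology and bead
#' identities of a template state.
#'
#' @param frames List of n x 3 position matrices.
#' @param boxes Matrix (frames x 3) of box edges per frame.
#' @param steps Integer step index per frame.
#' @param template A \code{dpd_state} supplying types, molecule ids and
#'   topology.
#' @return An object of class \code{dpd_traj}.
#' @export
dpd_traj <- function(frames, boxes, steps, template) {
  structure(list(frames = frames, boxes = as.matrix(boxes),
                 steps = as.integer(steps), template = template),
            class = "dpd_traj")
}

#' @export
print.dpd_traj <- function(x, ...) {
  cat(sprintf("DPD trajectory: %d frames of %d beads\n",
              length(x$frames), n_beads(x$template)))
  invisible(x)
}

#' Extract one frame of a trajectory as a state
#' @param traj A \code{dpd_traj}.
#' @param i Frame index.
#' @return A \code{dpd_state} (velocities from the template).
#' @export
traj_frame <- function(traj, i) {
  st <- traj$template
  st$pos <- traj$frames[[i]]
  st$box <- as.numeric(traj$boxes[i, ])
  st$step <- traj$steps[i]
  st
}

#' Coerce simulation output to a list of states
#'
#' Accepts a \code{dpd_state}, \code{dpd_traj}, \code{dpd_run} or a list
#' of states and returns a plain list of \code{dpd_state} frames; used by
#' all analysis entry points.
#'
#' @param x State, trajectory, run result, or list of states.
#' @return List of \code{dpd_state}.
#' @export
as_frames <- function(x) {
  if (inherits(x, "dpd_state")) return(list(x))
  if (inherits(x, "dpd_run")) x <- x$traj
  if (inherits(x, "dpd_traj")) {
    if (length(x$frames) == 0) stop("trajectory has no frames")
    return(lapply(seq_along(x$frames), function(i) traj_frame(x, i)))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "dpd_state")))
    return(x)
  stop("cannot interpret input as frames (need dpd_state/dpd_traj/dpd_run)")
}

#' Virial pressure of a state
#'
#' Isotropic pressure from the global virial of the conservative and
#' bonded interactions. The excess part excludes the kinetic (ideal-gas)
#' contribution \eqn{\rho k_BT}; the published bulk value for pure water at
#' density 3 is an excess pressure in this sense.
#'
#' @param state A \code{dpd_state}.
#' @param ff A \code{dpd_forcefield}.
#' @return Named numeric: \code{P_excess} and \code{P_total}
#'   (\eqn{k_BT/d^3}).
#' @export
virial_pressure <- function(state, ff) {
  if (n_beads(state) == 0) stop("empty system")
  f <- compute_forces(state, ff, thermo = FALSE)
  v <- state$box[1] * state$box[2] * state$box[3]
  p_ex <- attr(f, "virial") / (3 * v)
  p_kin <- sum(state$vel^2) / (3 * v)
  c(P_excess = p_ex, P_total = p_ex + p_kin)
}
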