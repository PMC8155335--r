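#' Stress profile container
#'
#' Spherically binned local pressure components about the vesicle
#' centre: the normal component \eqn{P_N(r)}, the tangential component
#' \eqn{P_T(r)}, and the stress profile \eqn{s(r) = P_N(r) - P_T(r)},
#' all in \eqn{k_BT/d^3}.
#'
#' @param r Bin centres (\eqn{d}).
#' @param P_N,P_T Normal and tangential pressure (\eqn{k_BT/d^3}).
#' @param bin_width Bin width.
#' @param n_frames Frames averaged.
#' @return An object of class \code{stress_profile}.
#' @export
stress_profile <- function(r, P_N, P_T, bin_width, n_frames = 1L) {
  structure(list(r = r, P_N = P_N, P_T = P_T, s = P_N - P_T,
                 bin_width = bin_width, n_frames = n_frames),
            class = "stress_profile")
}

#' @export
print.stress_profile <- function(x, ...) {
  cat(sprintf(
    "Stress profile: %d bins of %g d, %d frame(s); s in [%.3g, %.3g] kBT/d^3\n",
    length(x$r), x$bin_width, x$n_frames, min(x$s), max(x$s)))
  invisible(x)
}

#' @export
as.data.frame.stress_profile <- function(x, ...) {
  data.frame(r = x$r, P_N = x$P_N, P_T = x$P_T, s = x$s)
}

#' @export
plot.stress_profile <- function(x, ...) {
  plot(x$r, x$s, type = "l", xlab = "r [d]", ylab = "s(r) [kBT/d^3]", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Spherical stress (pressure tensor) profile
#'
#' Computes the spherically resolved pressure tensor by the
#' Irving--Kirkwood construction: the kinetic part is binned per shell
#' from bead velocities, and each pair (and pairwise-decomposed bending)
#' force is distributed along the straight segment between the
#' interacting beads, with each piece resolved into its normal
#' (\eqn{P_N}) and tangential (\eqn{P_T}) component at the local radial
#' direction. Only conservative and bonded forces enter the
#' configurational part; dissipative and random forces average to zero.
#'
#' @param x Simulation output accepted by [as_frames()]; frames are
#'   centred per frame on the lipid centre of mass.
#' @param ff A \code{dpd_forcefield}.
#' @param bin_width Bin width (\eqn{d}); default 0.2, finer than the
#'   density binning.
#' @param r_max Outer radius; defaults to half the smallest box edge.
#' @param center \code{"lipids"} or a fixed numeric length-3 point.
#' @return A \code{stress_profile} with attribute \code{"virial_check"},
#'   the relative difference between the volume-integrated shell virial
#'   and the global virial (an internal consistency measure).
#' @export
spherical_stress_profile <- function(x, ff, bin_width = 0.2,
                                     r_max = NULL, center = "lipids") {
  frames <- as_frames(x)
  st1 <- frames[[1]]
  if (is.null(r_max)) r_max <- min(st1$box) / 2
  nb <- ceiling(r_max / bin_width)
  acc_n <- numeric(nb)
  acc_t <- numeric(nb)
  acc_nc <- numeric(nb)
  acc_tc <- numeric(nb)
  acc_vir <- 0
  prev_ctr <- NULL
  for (st in frames) {
    ctr <- if (is.numeric(center)) center else lipid_center(st)
    if (!is.null(prev_ctr) && sqrt(sum((ctr - prev_ctr)^2)) > 1)
      warning("vesicle centre drifted > 1 d between frames; ",
              "per-frame centring applied")
    prev_ctr <- ctr
    res <- cpp_stress_bin(st$pos, st$vel, st$type, st$box, ff$f,
                          st$bonds, st$angles, ff_par(ff, 0.01),
                          ctr, bin_width, nb)
    acc_n <- acc_n + res$P_N_conf + res$P_N_kin
    acc_t <- acc_t + res$P_T_conf + res$P_T_kin
    acc_nc <- acc_nc + res$P_N_conf
    acc_tc <- acc_tc + res$P_T_conf
    acc_vir <- acc_vir + res$virial
  }
  nf <- length(frames)
  r <- (seq_len(nb) - 0.5) * bin_width
  sp <- stress_profile(r, acc_n / nf, acc_t / nf, bin_width, nf)
  # volume-averaged shell pressure vs the frame-averaged global virial
  # pressure (the two agree for a homogeneous fluid)
  vol <- 4 / 3 * pi * diff((0:nb * bin_width)^3)
  p_shell <- sum((acc_nc + 2 * acc_tc) / (3 * nf) * vol) / sum(vol)
  p_global <- acc_vir / (3 * nf * prod(st1$box))
  attr(sp, "virial_check") <-
    if (p_global != 0) p_shell / p_global - 1 else NA_real_
  sp
}

#' Bilayer tension from the stress profile
#'
#' Spatial integral of the stress profile with the spherical geometric
#' weight, in analogy to the mechanical interfacial tension of a
#' spherical droplet:
#' \deqn{\Sigma = \int dr \, \left(\frac{r}{R_{mid}}\right)^2 s(r).}
#'
#' @param sp A \code{stress_profile} spanning the bilayer.
#' @param R_mid Midsurface radius (\eqn{d}).
#' @param window Integration half-width about \eqn{R_{mid}}; default 5 d
#'   (roughly the bilayer thickness). Use \code{Inf} for the full
#'   profile.
#' @return Bilayer tension \eqn{\Sigma} in \eqn{k_BT/d^2}.
#' @export
bilayer_tension <- function(sp, R_mid, window = 5) {
  sel <- abs(sp$r - R_mid) <= window
  if (!any(sel)) stop("stress profile does not cover the bilayer region")
  sum((sp$r[sel] / R_mid)^2 * sp$s[sel]) * sp$bin_width
}

#' First moment of the stress profile
#'
#' \deqn{\langle s \rangle_0 = \int dr \, (r - R_{mid}) \, s(r),}
#' evaluated at (near-)vanishing bilayer tension; the moment measures
#' the stress asymmetry between the two leaflets.
#'
#' @param sp A \code{stress_profile}.
#' @param R_mid Midsurface radius.
#' @param window Integration half-width about \eqn{R_{mid}}; default 5 d.
#' @param Sigma Optional measured tension; if supplied and
#'   \code{abs(Sigma) > tension_tol} the function refuses, since the
#'   moment is defined for the tensionless state.
#' @param tension_tol Zero-tension tolerance (\eqn{k_BT/d^2}).
#' @return The first moment in \eqn{k_BT/d^2}.
#' @export
first_moment <- function(sp, R_mid, window = 5, Sigma = NULL,
                         tension_tol = 0.1) {
  if (!is.null(Sigma) && abs(Sigma) > tension_tol)
    stop("bilayer tension |", signif(Sigma, 3), "| exceeds the ",
         "zero-tension tolerance; relax to the tensionless state first")
  sel <- abs(sp$r - R_mid) <= window
  if (!any(sel)) stop("stress profile does not cover the bilayer region")
  sum((sp$r[sel] - R_mid) * sp$s[sel]) * sp$bin_width
}

#' Spontaneous curvature from the first stress moment
#'
#' Inverts the relation between bending rigidity, midsurface radius and
#' the tensionless first moment,
#' \deqn{\langle s \rangle_0 = 2\kappa\left(\frac{1}{R_{mid}} - m\right),}
#' for the spontaneous curvature:
#' \eqn{m = 1/R_{mid} - \langle s \rangle_0 / (2\kappa)}. A vanishing
#' moment therefore gives \eqn{m = 1/R_{mid}}.
#'
#' @param moment First stress moment (\eqn{k_BT/d^2}).
#' @param kappa Bending rigidity (\eqn{k_BT}), > 0.
#' @param R_mid Midsurface radius (\eqn{d}), > 0.
#' @return Spontaneous curvature \eqn{m} in \eqn{1/d}.
#' @export
spontaneous_curvature <- function(moment, kappa, R_mid) {
  if (kappa <= 0) stop("`kappa` must be > 0")
  if (R_mid <= 0) stop("`R_mid` must be > 0")
  1 / R_mid - moment / (2 * kappa)
}

#' Area compressibility modulus
#'
#' Least-squares slope of the bilayer tension against the relative area
#' dilation near the tensionless state,
#' \eqn{\Sigma \approx K_A (A - A_0)/A_0}.
#'
#' @param dilation Relative area dilations \eqn{(A - A_0)/A_0}.
#' @param Sigma Tensions at those dilations (\eqn{k_BT/d^2}).
#' @return \eqn{K_A} in \eqn{k_BT/d^2}.
#' @export
area_compressibility <- function(dilation, Sigma) {
  if (length(dilation) != length(Sigma) || length(dilation) < 2)
    stop("need >= 2 (dilation, Sigma) points")
  if (diff(range(dilation)) < 1e-12)
    stop("degenerate dilation range")
  if (length(dilation) == 2)
    return(diff(Sigma) / diff(dilation))
  unname(stats::coef(stats::lm(Sigma ~ dilation))[2])
}

#' Bending rigidity from the area compressibility
#'
#' \deqn{\kappa = K_A \, l_{me}^2 / 48,} with membrane thickness
#' \eqn{l_{me}} (about 5 d for this lipid model at all solute
#' concentrations).
#'
#' @param K_A Area compressibility modulus (\eqn{k_BT/d^2}), > 0.
#' @param l_me Membrane thickness (\eqn{d}).
#' @return \eqn{\kappa} in \eqn{k_BT}.
#' @export
bending_rigidity <- function(K_A, l_me) {
  if (K_A <= 0) stop("`K_A` must be > 0")
  K_A * l_me^2 / 48
}

#' Find the tensionless vesicle state
#'
#' Evaluates the bilayer tension at several interior water counts and
#' linearly interpolates the zero crossing, returning the tensionless
#' interior water number \eqn{N_{W0}^{in}} and the corresponding volume
#' parameter \eqn{\nu_0 = N_{W0}^{in} / N_W^{isp}}.
#'
#' The default evaluator deflates/inflates the vesicle with
#' [set_volume()], runs short thermostatted dynamics and measures the
#' tension from the averaged stress profile; a custom \code{evaluate}
#' function (mapping an interior water count to a tension) can be
#' supplied, e.g. for testing or precomputed series.
#'
#' @param state A relaxed vesicle \code{dpd_state}.
#' @param ff A \code{dpd_forcefield}.
#' @param N_W_in_grid Interior water counts to scan (>= 3 values).
#' @param evaluate Function \code{N_W_in -> Sigma}; defaults to the
#'   simulation-based evaluator.
#' @param n_steps,n_frames Steps and averaged frames per evaluation for
#'   the default evaluator.
#' @param seed Integer seed.
#' @return List: \code{N_W0_in}, \code{nu_0}, \code{scan} (data.frame of
#'   the scanned points), and \code{state} (re-deflated to the
#'   tensionless count; NULL with a custom evaluator).
#' @export
find_tensionless <- function(state, ff, N_W_in_grid, evaluate = NULL,
                             n_steps = 2000, n_frames = 5, seed = 1L) {
  if (length(N_W_in_grid) < 3)
    stop("scan at least 3 interior water counts")
  N_W_isp <- state$meta$N_W_isp
  default_eval <- is.null(evaluate)
  if (default_eval) {
    evaluate <- function(n_w) {
      st <- set_volume(state, n_w / N_W_isp, seed = seed)
      cfg <- dpd_config("NVT", seed = seed)
      run <- dpd_run(st, ff, cfg, n_steps = n_steps,
                     frame_stride = max(1L, n_steps %/% n_frames),
                     obs_stride = 0L)
      sp <- spherical_stress_profile(run$traj, ff)
      prof <- radial_density(run$traj, types = "C")
      bilayer_tension(sp, midsurface_radius(prof))
    }
  }
  grid <- sort(N_W_in_grid)
  sig <- vapply(grid, evaluate, numeric(1))
  scan <- data.frame(N_W_in = grid, Sigma = sig)
  cross <- which(sig[-1] * sig[-length(sig)] <= 0)
  if (length(cross) == 0)
    stop("no zero crossing of Sigma in the scanned bracket [",
         min(grid), ", ", max(grid), "]; Sigma in [",
         signif(min(sig), 3), ", ", signif(max(sig), 3), "]")
  i <- cross[1]
  n0 <- grid[i] - sig[i] * (grid[i + 1] - grid[i]) / (sig[i + 1] - sig[i])
  n0 <- round(n0)
  out_state <- if (default_eval && !is.null(state$meta$idx_interior))
    set_volume(state, n0 / N_W_isp, seed = seed) else NULL
  list(N_W0_in = n0,
       nu_0 = if (is.null(N_W_isp)) NA_real_ else n0 / N_W_isp,
       scan = scan, state = out_state)
}

#' Elastic summary of a vesicle membrane
#'
#' Convenience bundle of the elastic observables: midsurface radius,
#' tension, first stress moment, area compressibility, bending rigidity
#' and spontaneous curvature.
#'
#' @param sp A \code{stress_profile} at (near-)zero tension.
#' @param chain_profile \code{radial_profile} of C beads (for
#'   \eqn{R_{mid}}).
#' @param membrane_profile \code{radial_profile} of H + C beads (for
#'   \eqn{l_{me}}); optional, defaults \eqn{l_{me} = 5}.
#' @param K_A Area compressibility modulus (\eqn{k_BT/d^2}).
#' @param tension_tol Zero-tension tolerance passed to [first_moment()].
#' @return A list of class \code{elastic_summary}.
#' @export
elastic_summary <- function(sp, chain_profile, membrane_profile = NULL,
                            K_A, tension_tol = 0.1) {
  R_mid <- midsurface_radius(chain_profile)
  l_me <- if (is.null(membrane_profile)) 5
          else membrane_thickness(membrane_profile)
  Sigma <- bilayer_tension(sp, R_mid)
  kappa <- bending_rigidity(K_A, l_me)
  mom <- first_moment(sp, R_mid, Sigma = Sigma,
                      tension_tol = tension_tol)
  m <- spontaneous_curvature(mom, kappa, R_mid)
  structure(list(R_mid = R_mid, Sigma = Sigma, first_moment = mom,
                 K_A = K_A, kappa = kappa, m = m, l_me = l_me),
            class = "elastic_summary")
}

#' @export
print.elastic_summary <- function(x, ...) {
  cat("Elastic summary (reduced units kBT, d):\n")
  cat(sprintf("  R_mid = %.3f, l_me = %.3f, Sigma = %.4f\n",
              x$R_mid, x$l_me, x$Sigma))
  cat(sprintf("  K_A = %.3f, kappa = %.3f\n", x$K_A, x$kappa))
  cat(sprintf("  first moment = %.4f, spontaneous curvature m = %.5f\n",
              x$first_moment, x$m))
  invisible(x)
}
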