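#' Bead type labels
#'
#' The coarse-grained model is built from four bead species: lipid
#' headgroup (\code{H}), lipid hydrocarbon chain (\code{C}), water
#' (\code{W}) and solute (\code{S}). All beads share the diameter
#' \code{d}, the unit of length (about 0.8 nm).
#'
#' @return Character vector \code{c("H", "C", "W", "S")}.
#' @export
bead_types <- function() c("H", "C", "W", "S")

#' Construct a DPD force field
#'
#' Bundles the pairwise conservative force parameters \eqn{f_{ij}} (in
#' \eqn{k_BT/d}) with the bonded constants of the lipid model and the
#' dissipative/random thermostat amplitudes. The conservative force is
#' soft and linear, \eqn{F(r) = f_{ij}(1 - r/d)} for \eqn{r < d} and zero
#' beyond the cutoff. The random amplitude is tied to the dissipative one
#' by the fluctuation--dissipation relation \eqn{\sigma^2 = 2\gamma k_BT}.
#'
#' @param f Symmetric 4x4 numeric matrix of force parameters with
#'   dimnames equal to \code{bead_types()}, units \eqn{k_BT/d}.
#' @param cutoff Interaction cutoff, equal to the bead diameter \code{d}.
#' @param bond_k Harmonic bond spring constant (\eqn{k_BT/d^2}).
#' @param bond_l0 Bond rest length (\eqn{d}).
#' @param bend_k Chain stiffness constant of the \eqn{k(1-\cos\phi)}
#'   bending potential (\eqn{k_BT}).
#' @param gamma Dissipative pair-force amplitude (reduced units).
#' @param kBT Thermal energy; 1 in reduced units.
#' @return An object of class \code{dpd_forcefield}.
#' @seealso [default_force_table()] for the published parameter set.
#' @export
dpd_forcefield <- function(f, cutoff = 1, bond_k = 128, bond_l0 = 0.5,
                           bend_k = 20, gamma = 4.5, kBT = 1) {
  f <- as.matrix(f)
  if (!identical(dim(f), c(4L, 4L)))
    stop("`f` must be a 4x4 matrix (bead types H, C, W, S)")
  if (is.null(dimnames(f))) dimnames(f) <- list(bead_types(), bead_types())
  if (!identical(rownames(f), bead_types()) ||
      !identical(colnames(f), bead_types()))
    stop("`f` must have dimnames H, C, W, S in that order")
  if (any(f < 0)) stop("all force parameters must be >= 0")
  if (max(abs(f - t(f))) > 1e-12) stop("`f` must be symmetric")
  if (cutoff <= 0 || bond_k < 0 || bond_l0 <= 0 || gamma < 0 || kBT <= 0)
    stop("invalid force-field constants")
  structure(
    list(f = f, cutoff = cutoff, bond_k = bond_k, bond_l0 = bond_l0,
         bend_k = bend_k, gamma = gamma, sigma = sqrt(2 * gamma * kBT),
         kBT = kBT),
    class = "dpd_forcefield")
}

#' @export
print.dpd_forcefield <- function(x, ...) {
  cat("DPD force field (units: kBT, d)\n")
  cat("Pair force parameters f_ij [kBT/d]:\n")
  print(x$f)
  cat(sprintf("cutoff = %g d | bonds: k = %g, l0 = %g | bending: k = %g\n",
              x$cutoff, x$bond_k, x$bond_l0, x$bend_k))
  cat(sprintf("thermostat: gamma = %g, sigma = %g (kBT = %g)\n",
              x$gamma, x$sigma, x$kBT))
  invisible(x)
}

#' Published force-parameter table
#'
#' Returns the force field with the published pair parameters for the
#' four-bead lipid/water/solute model. The water--solute parameter sets
#' the solvent condition: \eqn{f_{WS} = 32} for a good solvent and
#' \eqn{f_{WS} = 40} for a poor solvent, corresponding to solubilities
#' \eqn{\zeta = 25/32} and \eqn{\zeta = 25/40}.
#'
#' @param solvent_condition \code{"good"} or \code{"poor"}.
#' @param ... Passed to [dpd_forcefield()] to override bonded or
#'   thermostat constants.
#' @return A \code{dpd_forcefield}.
#' @examples
#' ff <- default_force_table("good")
#' ff$f["C", "W"]  # 75: strong chain-water repulsion drives assembly
#' @export
default_force_table <- function(solvent_condition = c("good", "poor"), ...) {
  solvent_condition <- match.arg(solvent_condition)
  f_ws <- if (solvent_condition == "good") 32 else 40
  f <- matrix(c(30, 50, 30, 15,
                50, 10, 75, 75,
                30, 75, 25, f_ws,
                15, 75, f_ws, 25),
              nrow = 4, byrow = TRUE,
              dimnames = list(bead_types(), bead_types()))
  dpd_forcefield(f, ...)
}

#' Conservative pair force magnitude
#'
#' The soft linear DPD repulsion \eqn{F(r) = f_{ij}(1 - r/d)} for
#' \eqn{r < d}, zero at and beyond the cutoff. The force acts along the
#' unit vector from bead j to bead i (repulsive).
#'
#' @param f_ij Force parameter (\eqn{k_BT/d}), must be >= 0.
#' @param r Bead-bead distance (\eqn{d}), must be >= 0. Vectorised.
#' @param cutoff Cutoff distance, default the bead diameter 1.
#' @return Force magnitude in \eqn{k_BT/d}.
#' @examples
#' pair_force_magnitude(25, 0.5)  # 12.5
#' pair_force_magnitude(25, 1.0)  # 0 at the cutoff
#' @export
pair_force_magnitude <- function(f_ij, r, cutoff = 1) {
  if (any(r < 0)) stop("distance `r` must be non-negative")
  if (any(f_ij < 0)) stop("`f_ij` must be non-negative")
  ifelse(r < cutoff, f_ij * (1 - r / cutoff), 0)
}

#' Solubility parameter of the solute
#'
#' Dimensionless ratio of the like-species force parameters to the
#' water--solute one, \eqn{\zeta = (f_{WW} + f_{SS}) / (2 f_{WS})}.
#' Decreasing \eqn{\zeta} (increasing \eqn{f_{WS}}) makes water--solute
#' contacts costlier and eventually drives liquid--liquid demixing. With
#' the published \eqn{f_{WW} = f_{SS} = 25} this reduces to
#' \eqn{25/f_{WS}}: 25/32 for the good and 25/40 for the poor solvent.
#'
#' @param f_WW,f_SS,f_WS Pair force parameters (\eqn{k_BT/d}), all > 0.
#' @return The solubility \eqn{\zeta} (dimensionless).
#' @export
solubility <- function(f_WW, f_SS, f_WS) {
  if (any(c(f_WW, f_SS, f_WS) <= 0))
    stop("all force parameters must be > 0")
  (f_WW + f_SS) / (2 * f_WS)
}

#' Lipid bead topology
#'
#' Each lipid has 15 beads: a headgroup of three H beads and two
#' hydrocarbon chains of six C beads each. Beads are numbered 1:3 (H) and
#' 4:9, 10:15 (the two chains). The chains attach to the first and third
#' head bead; consecutive chain triples (and the head-chain junctions)
#' carry the bending potential.
#'
#' @return A list with \code{n_beads}, \code{types} (length-15 character),
#'   \code{bonds} (two-column integer matrix, local indices), and
#'   \code{angles} (three-column integer matrix).
#' @export
lipid_topology <- function() {
  types <- c(rep("H", 3), rep("C", 12))
  bonds <- rbind(
    c(1L, 2L), c(2L, 3L),            # head backbone
    c(1L, 4L), cbind(4:8, 5:9),      # chain 1 off head bead 1
    c(3L, 10L), cbind(10:14, 11:15)  # chain 2 off head bead 3
  )
  angles <- rbind(
    c(1L, 4L, 5L), cbind(4:7, 5:8, 6:9),       # junction + chain 1
    c(3L, 10L, 11L), cbind(10:13, 11:14, 12:15)
  )
  storage.mode(bonds) <- "integer"
  storage.mode(angles) <- "integer"
  list(n_beads = 15L, types = types, bonds = bonds, angles = angles)
}
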