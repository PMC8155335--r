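#' Construct a DPD system state
#'
#' Holds everything needed to advance or analyse a configuration: the
#' periodic box, per-bead positions, velocities, types and molecule ids,
#' the bonded topology, and bookkeeping metadata written by the builders
#' (compartment membership, bead budgets).
#'
#' @param box Numeric length-3 edge lengths (\eqn{d}).
#' @param pos n x 3 matrix of positions; wrapped into \code{[0, L)}.
#' @param vel n x 3 matrix of velocities; defaults to a Maxwell
#'   distribution at \eqn{k_BT = 1} with zero net momentum.
#' @param type Character or integer bead types (H, C, W, S = 1..4).
#' @param mol Integer molecule ids; 0 for solvent beads.
#' @param bonds Two-column integer matrix of bonded bead pairs.
#' @param angles Three-column integer matrix of bending triples.
#' @param step Integer step counter.
#' @param meta List of builder bookkeeping (kept verbatim).
#' @return An object of class \code{dpd_state}.
#' @export
dpd_state <- function(box, pos, vel = NULL, type, mol = NULL,
                      bonds = NULL, angles = NULL, step = 0L,
                      meta = list()) {
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("`box` must be 3 positive edge lengths")
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (ncol(pos) != 3) stop("`pos` must be an n x 3 matrix")
  if (is.character(type) || is.factor(type)) {
    type <- match(as.character(type), bead_types())
    if (anyNA(type)) stop("unknown bead type label")
  }
  type <- as.integer(type)
  if (length(type) != n || any(type < 1L | type > 4L))
    stop("`type` must give one of H, C, W, S per bead")
  if (is.null(vel)) {
    vel <- matrix(stats::rnorm(3 * n), n, 3)
    vel <- sweep(vel, 2, colMeans(vel))
  }
  vel <- as.matrix(vel)
  if (!identical(dim(vel), dim(pos))) stop("`vel` must match `pos`")
  if (is.null(mol)) mol <- integer(n)
  if (is.null(bonds)) bonds <- matrix(integer(), 0, 2)
  if (is.null(angles)) angles <- matrix(integer(), 0, 3)
  storage.mode(bonds) <- "integer"
  storage.mode(angles) <- "integer"
  pos <- wrap_positions(pos, box)
  structure(
    list(box = box, pos = pos, vel = vel, type = type,
         mol = as.integer(mol), bonds = bonds, angles = angles,
         step = as.integer(step), meta = meta),
    class = "dpd_state")
}

wrap_positions <- function(pos, box) {
  for (d in 1:3) {
    pos[, d] <- pos[, d] - box[d] * floor(pos[, d] / box[d])
    pos[pos[, d] >= box[d], d] <- 0
  }
  pos
}

#' @export
print.dpd_state <- function(x, ...) {
  counts <- table(factor(bead_types()[x$type], levels = bead_types()))
  cat(sprintf("DPD state: %d beads in box %.3g x %.3g x %.3g d (step %d)\n",
              nrow(x$pos), x$box[1], x$box[2], x$box[3], x$step))
  cat("  beads by type: ",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  cat(sprintf("  %d bonds, %d angles, %d molecules\n",
              nrow(x$bonds), nrow(x$angles),
              length(unique(x$mol[x$mol > 0]))))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Number of beads in a state
#' @param state A \code{dpd_state}.
#' @return Integer bead count.
#' @export
n_beads <- function(state) nrow(state$pos)

#' Instantaneous kinetic temperature
#'
#' \eqn{k_BT = \sum m v^2 / (3N - 3)} with unit bead mass; three degrees
#' of freedom are removed for the conserved total momentum.
#'
#' @param state A \code{dpd_state}.
#' @return Temperature in units of \eqn{k_BT}.
#' @export
kinetic_temperature <- function(state) {
  n <- n_beads(state)
  sum(state$vel^2) / (3 * n - 3)
}

#' Total momentum of a state
#' @param state A \code{dpd_state}.
#' @return Numeric length-3 momentum vector (unit bead mass).
#' @export
total_momentum <- function(state) colSums(state$vel)
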