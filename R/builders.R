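#' Vesicle build specification
#'
#' Prescribes the leaflet lipid numbers, the interior water budget, the
#' exterior solute mole fraction and the box for [build_vesicle()]. The
#' interior compartment is always solute-free at build time; solutes live
#' in the exterior solution only.
#'
#' @param N_il,N_ol Inner / outer leaflet lipid counts (> 0).
#' @param N_W_isp Reference (spherical) interior water bead count; sets
#'   the volume parameter scale \eqn{\nu = N_W^{in}/N_W^{isp}}.
#' @param N_W_in Initial interior water beads; defaults to
#'   \code{N_W_isp} (\eqn{\nu = 1}).
#' @param Phi_S Exterior solute mole fraction in [0, 1].
#' @param box Numeric length-3 (or scalar) box edge lengths (\eqn{d}).
#' @param total_solvent_beads Total W + S beads (interior + exterior).
#'   Defaults to \code{round(3 * V) - 15 * (N_il + N_ol)} so the global
#'   density is the standard 3 beads per \eqn{d^3}.
#' @param area_per_lipid Initial head-shell area per lipid (\eqn{d^2})
#'   used to choose the leaflet radii.
#' @return An object of class \code{vesicle_spec}.
#' @export
vesicle_spec <- function(N_il, N_ol, N_W_isp = NULL, N_W_in = NULL,
                         Phi_S = 0, box = NULL,
                         total_solvent_beads = NULL,
                         area_per_lipid = 1.25) {
  if (N_il <= 0 || N_ol <= 0) stop("leaflet lipid counts must be > 0")
  if (Phi_S < 0 || Phi_S > 1) stop("`Phi_S` must be in [0, 1]")
  r_in <- sqrt(N_il * area_per_lipid / (4 * pi))
  r_out <- sqrt(N_ol * area_per_lipid / (4 * pi))
  if (is.null(box)) box <- rep(ceiling(2 * (r_out + 4.5)), 3)
  if (length(box) == 1) box <- rep(box, 3)
  if (is.null(N_W_isp))
    N_W_isp <- round(3 * 4 / 3 * pi * (r_in - 0.6)^3)
  if (is.null(N_W_in)) N_W_in <- N_W_isp
  v <- prod(box)
  membrane <- 15 * (N_il + N_ol)
  if (is.null(total_solvent_beads))
    total_solvent_beads <- round(3 * v) - membrane
  if (N_W_in > total_solvent_beads)
    stop("interior water exceeds the total solvent budget")
  structure(
    list(N_il = as.integer(N_il), N_ol = as.integer(N_ol),
         N_W_isp = as.integer(N_W_isp), N_W_in = as.integer(N_W_in),
         Phi_S = Phi_S, box = as.numeric(box),
         total_solvent_beads = as.integer(total_solvent_beads),
         area_per_lipid = area_per_lipid,
         asymmetry = N_ol / N_il,
         membrane_beads = as.integer(membrane)),
    class = "vesicle_spec")
}

#' @export
print.vesicle_spec <- function(x, ...) {
  cat(sprintf("Vesicle spec: N_il = %d, N_ol = %d (asymmetry %.3f)\n",
              x$N_il, x$N_ol, x$asymmetry))
  cat(sprintf("  interior water %d of reference %d (nu = %.3f), Phi_S = %g\n",
              x$N_W_in, x$N_W_isp, x$N_W_in / x$N_W_isp, x$Phi_S))
  cat(sprintf("  box %g d, solvent %d beads, membrane %d beads, total %d\n",
              x$box[1], x$total_solvent_beads, x$membrane_beads,
              x$total_solvent_beads + x$membrane_beads))
  invisible(x)
}

#' Published full-scale vesicle specification
#'
#' The reference system: 4000 inner- and 6100 outer-leaflet lipids in an
#' (80 d)^3 box with 1,440,400 solvent beads and a reference interior
#' water number of 90,400, giving 151,500 membrane beads and 1,591,900
#' beads in total.
#'
#' @param Phi_S Exterior solute mole fraction.
#' @return A \code{vesicle_spec}.
#' @export
reference_vesicle_spec <- function(Phi_S = 0) {
  vesicle_spec(N_il = 4000, N_ol = 6100, N_W_isp = 90400,
               Phi_S = Phi_S, box = 80, total_solvent_beads = 1440400)
}

# Fibonacci sphere: n approximately uniform unit vectors
fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) + 1) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# per-lipid bead layout along a local axis: axial offset s (head bead at
# 0/+0.5, chains down to -3) and tangential offset t
lipid_layout <- function() {
  s <- c(0, 0.5, 0, -(1:6) * 0.5, -(1:6) * 0.5)
  t <- c(0.25, 0, -0.25, rep(0.25, 6), rep(-0.25, 6))
  list(s = s, t = t)
}

place_lipids <- function(axes, head_pos_fun, tangent_jitter = TRUE) {
  lay <- lipid_layout()
  n <- nrow(axes)
  pos <- matrix(0, 15 * n, 3)
  for (i in seq_len(n)) {
    u <- axes[i, ]
    # tangent frame
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * u) * u
    e1 <- e1 / sqrt(sum(e1^2))
    base <- head_pos_fun(i)
    for (k in 1:15) {
      pos[15 * (i - 1) + k, ] <- base$origin + base$dir * lay$s[k] * u +
        lay$t[k] * e1
    }
  }
  pos
}

lipids_topology <- function(n_lipids, first_bead = 1L, first_mol = 1L) {
  lt <- lipid_topology()
  off <- first_bead - 1L + (seq_len(n_lipids) - 1L) * 15L
  bonds <- do.call(rbind, lapply(off, function(o) lt$bonds + o))
  angles <- do.call(rbind, lapply(off, function(o) lt$angles + o))
  list(types = rep(lt$types, n_lipids),
       mol = rep(first_mol - 1L + seq_len(n_lipids), each = 15L),
       bonds = bonds, angles = angles)
}

#' Build a bulk binary solution
#'
#' Uniform random placement of water and solute beads at total density
#' \code{rho} (standard value 3 per \eqn{d^3}), giving a uniform solution
#' with solute density \eqn{\rho_S = \rho \Phi_S}.
#'
#' @param Phi_S Solute mole fraction in [0, 1].
#' @param box Length-3 (or scalar) box edges (\eqn{d}).
#' @param rho Total bead density (\eqn{1/d^3}).
#' @param seed Optional integer seed for reproducible placement.
#' @return A \code{dpd_state}.
#' @export
build_bulk <- function(Phi_S, box, rho = 3, seed = NULL) {
  if (Phi_S < 0 || Phi_S > 1) stop("`Phi_S` must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (length(box) == 1) box <- rep(box, 3)
  n <- round(rho * prod(box))
  n_s <- round(Phi_S * n)
  pos <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
               stats::runif(n, 0, box[3]))
  type <- c(rep("S", n_s), rep("W", n - n_s))
  dpd_state(box, pos, type = type,
            meta = list(rho = rho, Phi_S = Phi_S))
}

# uniform points in the box outside radius r_min from the box centre
sample_exterior <- function(n, box, r_min) {
  out <- matrix(0, 0, 3)
  ctr <- box / 2
  while (nrow(out) < n) {
    m <- max(1000, 2 * (n - nrow(out)))
    p <- cbind(stats::runif(m, 0, box[1]), stats::runif(m, 0, box[2]),
               stats::runif(m, 0, box[3]))
    r2 <- (p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2 + (p[, 3] - ctr[3])^2
    out <- rbind(out, p[r2 > r_min^2, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# uniform points in a sphere of radius r about the box centre
sample_interior <- function(n, box, r) {
  u <- fib_sphere_random(n)
  rad <- r * stats::runif(n)^(1 / 3)
  sweep(u * rad, 2, box / 2, "+")
}

fib_sphere_random <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Assemble a spherical nanovesicle
#'
#' Places \code{N_il} lipids on an inner and \code{N_ol} lipids on an
#' outer spherical shell around the box centre, with headgroups facing
#' the interior and exterior water respectively and chains meeting at the
#' bilayer midplane. The interior is filled with exactly \code{N_W_in}
#' water beads and no solute; the exterior receives the remaining solvent
#' budget as a W/S mixture at mole fraction \code{Phi_S}. Leaflet radii
#' are chosen so the per-lipid head-shell area matches
#' \code{area_per_lipid}.
#'
#' @param spec A \code{vesicle_spec}.
#' @param seed Optional integer seed.
#' @return A \code{dpd_state} with partition bookkeeping in \code{$meta}
#'   (\code{idx_interior}, \code{idx_exterior}, counts and radii).
#' @export
build_vesicle <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "vesicle_spec"))
  if (!is.null(seed)) set.seed(seed)
  box <- spec$box
  r_in <- sqrt(spec$N_il * spec$area_per_lipid / (4 * pi))
  r_out <- sqrt(spec$N_ol * spec$area_per_lipid / (4 * pi))
  if (2 * (r_out + 4) > min(box))
    stop("box too small for the outer leaflet; enlarge the box")
  if (r_in < 3.5)
    stop("inner leaflet infeasible at this lipid count; ",
         "increase N_il or area_per_lipid")
  ctr <- box / 2

  # outer leaflet: heads outward at r_out, chains pointing inward
  ax_out <- fib_sphere(spec$N_ol)
  pos_out <- place_lipids(ax_out, function(i)
    list(origin = ctr + r_out * ax_out[i, ], dir = +1))
  # inner leaflet: heads inward at r_in, chains pointing outward
  ax_in <- fib_sphere(spec$N_il)
  pos_in <- place_lipids(ax_in, function(i)
    list(origin = ctr + r_in * ax_in[i, ], dir = -1))

  topo_out <- lipids_topology(spec$N_ol, first_bead = 1L, first_mol = 1L)
  topo_in <- lipids_topology(spec$N_il,
                             first_bead = 15L * spec$N_ol + 1L,
                             first_mol = spec$N_ol + 1L)
  n_mem <- spec$membrane_beads

  n_ext <- spec$total_solvent_beads - spec$N_W_in
  n_s <- round(spec$Phi_S * n_ext)
  r_wi <- max(1, r_in - 0.6)
  r_wo <- r_out + 0.6
  pos_int <- sample_interior(spec$N_W_in, box, r_wi)
  pos_ext <- sample_exterior(n_ext, box, r_wo)

  pos <- rbind(pos_out, pos_in, pos_int, pos_ext)
  type <- c(topo_out$types, topo_in$types,
            rep("W", spec$N_W_in),
            rep("S", n_s), rep("W", n_ext - n_s))
  mol <- c(topo_out$mol, topo_in$mol, integer(spec$N_W_in + n_ext))
  idx_int <- n_mem + seq_len(spec$N_W_in)
  idx_ext <- n_mem + spec$N_W_in + seq_len(n_ext)
  dpd_state(box, pos,
            type = type, mol = mol,
            bonds = rbind(topo_out$bonds, topo_in$bonds),
            angles = rbind(topo_out$angles, topo_in$angles),
            meta = list(spec = spec,
                        idx_interior = idx_int,
                        idx_exterior = idx_ext,
                        membrane_beads = n_mem,
                        N_W_isp = spec$N_W_isp,
                        r_head_in = r_in, r_head_out = r_out))
}

#' Set the vesicle volume parameter
#'
#' Adjusts the interior water count to \eqn{round(\nu N_W^{isp})},
#' mimicking osmotic deflation or inflation. Removed interior waters are
#' relocated to the exterior compartment (and vice versa), so the total
#' bead count is conserved.
#'
#' @param state A vesicle \code{dpd_state} from [build_vesicle()].
#' @param nu Target volume parameter (> 0).
#' @param seed Optional integer seed for the relocation positions.
#' @return The modified \code{dpd_state}.
#' @export
set_volume <- function(state, nu, seed = NULL) {
  meta <- state$meta
  if (is.null(meta$idx_interior))
    stop("state lacks vesicle bookkeeping (build with build_vesicle)")
  if (!is.null(seed)) set.seed(seed)
  if (nu <= 0) stop("`nu` must be > 0")
  target <- round(nu * meta$N_W_isp)
  idx_int <- meta$idx_interior
  idx_ext <- meta$idx_exterior
  cur <- length(idx_int)
  if (target == cur) return(state)
  r_wo <- meta$r_head_out + 0.6
  if (target < cur) {
    move <- sample(idx_int, cur - target)
    state$pos[move, ] <- sample_exterior(length(move), state$box, r_wo)
    state$type[move] <- 3L  # W stays W, now exterior
    idx_int <- setdiff(idx_int, move)
    idx_ext <- c(idx_ext, move)
  } else {
    ext_w <- idx_ext[state$type[idx_ext] == 3L]
    if (length(ext_w) < target - cur)
      stop("not enough exterior water to inflate to nu = ", nu)
    move <- sample(ext_w, target - cur)
    r_wi <- max(1, meta$r_head_in - 0.6)
    state$pos[move, ] <- sample_interior(length(move), state$box, r_wi)
    idx_ext <- setdiff(idx_ext, move)
    idx_int <- c(idx_int, move)
  }
  state$meta$idx_interior <- sort(idx_int)
  state$meta$idx_exterior <- sort(idx_ext)
  state$meta$nu <- target / meta$N_W_isp
  state
}

#' Set the exterior solute mole fraction
#'
#' Converts exterior bead identities between water and solute, leaving
#' positions untouched, until the exterior mole fraction
#' \eqn{N_S/(N_S + N_W^{ex})} is within one bead of the target. The
#' interior compartment is never touched.
#'
#' @param state A vesicle \code{dpd_state}.
#' @param Phi_S Target mole fraction in [0, 1].
#' @param seed Optional integer seed for choosing which beads convert.
#' @return The modified \code{dpd_state}.
#' @export
set_solute_fraction <- function(state, Phi_S, seed = NULL) {
  if (Phi_S < 0 || Phi_S > 1) stop("`Phi_S` must be in [0, 1]")
  idx_ext <- state$meta$idx_exterior
  if (is.null(idx_ext))
    stop("state lacks exterior bookkeeping (build with build_vesicle)")
  if (!is.null(seed)) set.seed(seed)
  n_ext <- length(idx_ext)
  target <- round(Phi_S * n_ext)
  is_s <- state$type[idx_ext] == 4L
  n_s <- sum(is_s)
  if (target > n_s) {
    conv <- sample(idx_ext[!is_s], target - n_s)
    state$type[conv] <- 4L
  } else if (target < n_s) {
    conv <- sample(idx_ext[is_s], n_s - target)
    state$type[conv] <- 3L
  }
  state$meta$Phi_S <- target / n_ext
  state
}

#' Exterior solute mole fraction of a vesicle state
#' @param state A vesicle \code{dpd_state}.
#' @return \eqn{N_S/(N_S + N_W^{ex})} over the exterior compartment.
#' @export
solute_fraction <- function(state) {
  idx_ext <- state$meta$idx_exterior
  if (is.null(idx_ext)) stop("state lacks exterior bookkeeping")
  mean(state$type[idx_ext] == 4L)
}

#' Build a slab system for coexistence runs
#'
#' A bulk W/S system in a box elongated along z, with all solute beads
#' initially confined to the central third of the z axis to seed the
#' formation of two liquid-liquid interfaces.
#'
#' @param Phi_S_total Overall solute mole fraction.
#' @param box Length-3 box; requires \code{box[3] >= 2 * box[1]}.
#' @param rho Total bead density.
#' @param seed Optional integer seed.
#' @return A \code{dpd_state}.
#' @export
build_slab <- function(Phi_S_total, box, rho = 3, seed = NULL) {
  if (length(box) != 3 || box[3] < 2 * box[1])
    stop("slab box must be elongated along z (L_z >= 2 L_x)")
  st <- build_bulk(Phi_S_total, box, rho = rho, seed = seed)
  n_s <- sum(st$type == 4L)
  if (n_s > 0) {
    zc <- box[3] / 2
    st$pos[st$type == 4L, 3] <-
      stats::runif(n_s, zc - box[3] / 6, zc + box[3] / 6)
  }
  st$meta$Phi_S_total <- Phi_S_total
  st
}

#' Build a solvated planar bilayer
#'
#' Two flat leaflets spanning the x-y plane at the box mid-height, with
#' heads facing the solvent on both sides; the remaining volume is filled
#' with water (plus solute at \code{Phi_S}) at density \code{rho}.
#' Intended as a compact test geometry for thickness and stress checks.
#'
#' @param n_per_leaflet Lipids per leaflet; placed on a square grid.
#' @param box Length-3 box; choose the cross-section so the area per
#'   lipid is near 1.25 \eqn{d^2} for a relaxed bilayer.
#' @param Phi_S Solvent solute mole fraction.
#' @param rho Solvent density.
#' @param seed Optional integer seed.
#' @return A \code{dpd_state} with \code{mol > 0} marking lipid beads.
#' @export
build_planar_bilayer <- function(n_per_leaflet, box, Phi_S = 0, rho = 3,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(box) == 1) stop("`box` must give 3 edge lengths")
  n_side <- ceiling(sqrt(n_per_leaflet))
  if (box[3] < 12)
    stop("box too shallow to solvate a bilayer (need L_z >= 12)")
  dx <- box[1] / n_side
  dy <- box[2] / n_side
  grid <- expand.grid(ix = seq_len(n_side) - 0.5,
                      iy = seq_len(n_side) - 0.5)[seq_len(n_per_leaflet), ]
  z0 <- box[3] / 2
  up <- matrix(rep(c(0, 0, 1), n_per_leaflet), ncol = 3, byrow = TRUE)
  top <- place_lipids(up, function(i)
    list(origin = c(grid$ix[i] * dx, grid$iy[i] * dy, z0 + 2.5), dir = +1))
  bot <- place_lipids(up, function(i)
    list(origin = c(grid$ix[i] * dx + dx / 2, grid$iy[i] * dy + dy / 2,
                    z0 - 2.5), dir = -1))
  topo_t <- lipids_topology(n_per_leaflet, 1L, 1L)
  topo_b <- lipids_topology(n_per_leaflet, 15L * n_per_leaflet + 1L,
                            n_per_leaflet + 1L)
  n_mem <- 30L * n_per_leaflet
  # solvent budget excludes the ~5 d bilayer slab so the far field
  # relaxes to bulk density; placement leaves a 7 d gap that the soft
  # beads close during relaxation
  n_solv <- round(rho * box[1] * box[2] * (box[3] - 5))
  n_s <- round(Phi_S * n_solv)
  zs <- stats::runif(n_solv, 0, box[3] - 7)
  zs <- ifelse(zs < z0 - 3.5, zs, zs + 7)
  solv <- cbind(stats::runif(n_solv, 0, box[1]),
                stats::runif(n_solv, 0, box[2]), zs)
  pos <- rbind(top, bot, solv)
  type <- c(topo_t$types, topo_b$types,
            rep("S", n_s), rep("W", n_solv - n_s))
  mol <- c(topo_t$mol, topo_b$mol, integer(n_solv))
  dpd_state(box, pos, type = type, mol = mol,
            bonds = rbind(topo_t$bonds, topo_b$bonds),
            angles = rbind(topo_t$angles, topo_b$angles),
            meta = list(n_per_leaflet = n_per_leaflet,
                        membrane_beads = n_mem, z_mid = z0))
}

#' Relax a freshly built state
#'
#' Short thermostatted pre-run at a reduced timestep that relieves the
#' overlaps and bond strains of random insertion before production
#' dynamics. DPD potentials are soft, so a few hundred steps suffice.
#'
#' @param state A \code{dpd_state}.
#' @param ff A \code{dpd_forcefield}.
#' @param n_steps Number of relaxation steps.
#' @param dt Relaxation timestep (smaller than production).
#' @param seed Integer seed.
#' @return The relaxed \code{dpd_state}.
#' @export
relax_state <- function(state, ff, n_steps = 500, dt = 0.005, seed = 1L) {
  cfg <- dpd_config("NVT", dt = dt, seed = seed)
  dpd_run(state, ff, cfg, n_steps = n_steps, frame_stride = 0L,
          obs_stride = 0L)$state
}
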