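#' Radial profile container
#'
#' Binned shell values about the vesicle centre: bin centres \code{r}
#' (in \eqn{d}) and shell-volume-normalised values (beads per
#' \eqn{d^3} for densities).
#'
#' @param r Bin centres.
#' @param value Shell values.
#' @param bin_width Bin width (\eqn{d}).
#' @param types Bead-type selection the profile was computed for.
#' @param n_frames Number of frames averaged.
#' @return An object of class \code{radial_profile}.
#' @export
radial_profile <- function(r, value, bin_width, types = NULL,
                           n_frames = 1L) {
  structure(list(r = r, value = value, bin_width = bin_width,
                 types = types, n_frames = n_frames),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf(
    "Radial profile (%s): %d bins of %g d, %d frame(s), max %.4g at r = %.2f d\n",
    if (is.null(x$types)) "all beads" else paste(x$types, collapse = "+"),
    length(x$r), x$bin_width, x$n_frames,
    max(x$value), x$r[which.max(x$value)]))
  invisible(x)
}

#' @export
as.data.frame.radial_profile <- function(x, ...) {
  data.frame(r = x$r, value = x$value)
}

#' @export
plot.radial_profile <- function(x, ...) {
  plot(x$r, x$value, type = "l", xlab = "r [d]",
       ylab = "shell density [1/d^3]", ...)
  invisible(x)
}

# PBC-aware centre of the lipid (H + C) beads of a frame, via the
# circular mean of each wrapped coordinate
lipid_center <- function(state) {
  sel <- state$mol > 0L
  if (!any(sel)) sel <- rep(TRUE, n_beads(state))
  vapply(1:3, function(d) {
    th <- 2 * pi * state$pos[sel, d] / state$box[d]
    ang <- atan2(mean(sin(th)), mean(cos(th)))
    (ang %% (2 * pi)) * state$box[d] / (2 * pi)
  }, numeric(1))
}

rel_radius <- function(state, center) {
  dx <- sweep(state$pos, 2, center)
  for (d in 1:3) {
    L <- state$box[d]
    dx[, d] <- dx[, d] - L * round(dx[, d] / L)
  }
  sqrt(rowSums(dx^2))
}

#' Radial density profile about the vesicle centre
#'
#' Shell histogram of the selected bead types, normalised by shell
#' volume and averaged over frames. The centre is the PBC-aware centre
#' of mass of all lipid beads of each frame (or a fixed point).
#'
#' @param x Simulation output accepted by [as_frames()].
#' @param types Character vector of bead types to select (subset of
#'   H, C, W, S); NULL selects all beads.
#' @param bin_width Bin width in \eqn{d}; default 0.25.
#' @param r_max Outer radius; defaults to half the smallest box edge.
#' @param center \code{"lipids"} (per-frame lipid centre of mass) or a
#'   fixed numeric length-3 point.
#' @return A \code{radial_profile}. Shell counts integrate back to the
#'   number of selected beads within \code{r_max}.
#' @export
radial_density <- function(x, types = NULL, bin_width = 0.25,
                           r_max = NULL, center = "lipids") {
  frames <- as_frames(x)
  st1 <- frames[[1]]
  if (is.null(r_max)) r_max <- min(st1$box) / 2
  nb <- ceiling(r_max / bin_width)
  edges <- seq(0, nb * bin_width, by = bin_width)
  sel <- if (is.null(types)) rep(TRUE, n_beads(st1))
         else st1$type %in% match(types, bead_types())
  if (!any(sel)) {
    warning("selection matches no beads; returning zero profile")
    return(radial_profile(edges[-1] - bin_width / 2, numeric(nb),
                          bin_width, types, length(frames)))
  }
  counts <- numeric(nb)
  for (st in frames) {
    ctr <- if (is.numeric(center)) center else lipid_center(st)
    r <- rel_radius(st, ctr)[sel]
    idx <- findInterval(r, edges, rightmost.closed = FALSE)
    idx <- idx[idx >= 1 & idx <= nb]
    counts <- counts + tabulate(idx, nb)
  }
  counts <- counts / length(frames)
  vol <- 4 / 3 * pi * diff(edges^3)
  radial_profile(edges[-1] - bin_width / 2, counts / vol, bin_width,
                 types, length(frames))
}

#' Bulk plateau value of a radial profile
#'
#' Mean over the outer bins where the profile has levelled off to its
#' bulk value. At full scale the plateau sets in near r = 28 d; by
#' default the outer 20 percent of the radial range is used so the rule
#' scales with system size.
#'
#' @param profile A \code{radial_profile}.
#' @param r_min Inner edge of the plateau window; default the outer 20
#'   percent of the profile range.
#' @return Scalar plateau density.
#' @export
bulk_plateau <- function(profile, r_min = NULL) {
  if (is.null(r_min)) r_min <- 0.8 * max(profile$r)
  sel <- profile$r >= r_min
  if (sum(sel) < 3)
    stop("fewer than 3 bins beyond r_min = ", signif(r_min, 4),
         "; extend the profile or lower r_min")
  mean(profile$value[sel])
}

#' Excess density profile
#'
#' Subtracts the bulk plateau density: \eqn{\Delta\rho(r) = \rho(r) -
#' \rho_b}. For an adsorbing solute the excess is peaked at the outer
#' leaflet and decays rapidly to zero in the bulk.
#'
#' @param profile A \code{radial_profile}.
#' @param rho_bulk Plateau density; computed by [bulk_plateau()] if
#'   missing.
#' @return A \code{radial_profile} of excess values, with the plateau
#'   stored as attribute \code{"rho_bulk"}.
#' @export
excess_profile <- function(profile, rho_bulk = NULL) {
  if (is.null(rho_bulk)) rho_bulk <- bulk_plateau(profile)
  out <- radial_profile(profile$r, profile$value - rho_bulk,
                        profile$bin_width, profile$types,
                        profile$n_frames)
  attr(out, "rho_bulk") <- rho_bulk
  out
}

#' Solute coverage of the outer leaflet
#'
#' Integrates the excess solute density over the exterior volume
#' (\eqn{r > R_{mid}}) and divides by the midsurface area
#' \eqn{A_0 = 4\pi R_{mid}^2}:
#' \deqn{\Gamma = \frac{1}{A_0} \sum_{r_k > R_{mid}}
#'   \Delta\rho_S(r_k) \, 4\pi r_k^2 \, \Delta r.}
#'
#' @param excess An excess \code{radial_profile} from [excess_profile()].
#' @param R_mid Midsurface radius (\eqn{d}), > 0.
#' @param r_max Upper integration limit; defaults to the profile range
#'   (callers should keep it at least 1 d inside the half box edge to
#'   avoid periodic-image contamination).
#' @return A list of class \code{coverage_result}: \code{Gamma}
#'   (beads per \eqn{d^2}), \code{R_mid}, \code{A_0}, \code{rho_S_bulk}.
#' @export
coverage <- function(excess, R_mid, r_max = NULL) {
  if (R_mid <= 0) stop("`R_mid` must be > 0")
  if (is.null(r_max)) r_max <- max(excess$r) + excess$bin_width / 2
  sel <- excess$r > R_mid & excess$r <= r_max
  a0 <- 4 * pi * R_mid^2
  gam <- sum(excess$value[sel] * 4 * pi * excess$r[sel]^2 *
             excess$bin_width) / a0
  structure(list(Gamma = gam, R_mid = R_mid, A_0 = a0,
                 rho_S_bulk = attr(excess, "rho_bulk")),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("Solute coverage: Gamma = %.4g / d^2 on A_0 = %.4g d^2 (R_mid = %.3g d)\n",
              x$Gamma, x$A_0, x$R_mid))
  if (!is.null(x$rho_S_bulk))
    cat(sprintf("  bulk solute density %.4g / d^3\n", x$rho_S_bulk))
  invisible(x)
}

#' Solute coverage of a vesicle trajectory
#'
#' Full pipeline for the coverage of the outer leaflet: chain-density
#' peak for the midsurface radius, solute-density plateau for the bulk
#' density, then the excess integral over the entire exterior volume
#' written as a mass balance,
#' \deqn{\Gamma = \frac{N_S - \rho_{S,b} V^{ex}}{A_0}, \qquad
#'   V^{ex} = V_{box} - \tfrac{4}{3}\pi R_{mid}^3,}
#' which is the exterior-volume integral of \eqn{\Delta\rho_S} and, in a
#' cubic box, also accounts for the corner regions outside the largest
#' inscribed sphere that a radially binned integral cannot reach.
#'
#' @param x Simulation output accepted by [as_frames()].
#' @param bin_width Bin width for the underlying profiles.
#' @param plateau_r_min Inner edge of the bulk plateau window; default
#'   the outer 20 percent of the radial range.
#' @return A \code{coverage_result} with the profiles attached as
#'   attributes \code{"chain_profile"} and \code{"solute_profile"}.
#' @export
vesicle_coverage <- function(x, bin_width = 0.25, plateau_r_min = NULL) {
  frames <- as_frames(x)
  st1 <- frames[[1]]
  prof_c <- radial_density(frames, types = "C", bin_width = bin_width)
  r_mid <- midsurface_radius(prof_c)
  n_s <- mean(vapply(frames, function(st) sum(st$type == 4L), numeric(1)))
  a0 <- 4 * pi * r_mid^2
  if (n_s == 0) {
    out <- structure(list(Gamma = 0, R_mid = r_mid, A_0 = a0,
                          rho_S_bulk = 0), class = "coverage_result")
    attr(out, "chain_profile") <- prof_c
    return(out)
  }
  prof_s <- radial_density(frames, types = "S", bin_width = bin_width)
  rho_b <- bulk_plateau(prof_s, r_min = plateau_r_min)
  v_ex <- prod(st1$box) - 4 / 3 * pi * r_mid^3
  out <- structure(
    list(Gamma = (n_s - rho_b * v_ex) / a0, R_mid = r_mid, A_0 = a0,
         rho_S_bulk = rho_b),
    class = "coverage_result")
  attr(out, "chain_profile") <- prof_c
  attr(out, "solute_profile") <- prof_s
  out
}

#' Midsurface radius from the chain density peak
#'
#' Locates the bilayer midsurface at the peak of the hydrophobic chain
#' density profile \eqn{\rho_C(r)}, refined by a quadratic fit through
#' the three bins around the maximum.
#'
#' @param chain_profile A \code{radial_profile} of C beads.
#' @return The midsurface radius \eqn{R_{mid}} (\eqn{d}).
#' @export
midsurface_radius <- function(chain_profile) {
  v <- chain_profile$value
  r <- chain_profile$r
  if (max(v) <= 0) stop("profile has no density peak")
  k <- which.max(v)
  # ambiguity check: another separated peak of comparable height
  peak_mask <- v > 0.8 * v[k]
  runs <- rle(peak_mask)
  if (sum(runs$values) > 1)
    stop("chain density profile is multimodal; midsurface ambiguous")
  if (diff(range(v)) < 1e-12 * max(abs(v), 1))
    stop("chain density profile is flat; midsurface ambiguous")
  if (k == 1 || k == length(v)) return(r[k])
  y <- v[(k - 1):(k + 1)]
  denom <- y[1] - 2 * y[2] + y[3]
  if (denom >= 0) return(r[k])
  r[k] + 0.5 * (y[1] - y[3]) / denom * chain_profile$bin_width
}

#' Membrane thickness from a density profile
#'
#' Full width of the region where the membrane (H + C) density exceeds
#' half its peak value, with linear interpolation at the two crossings.
#' For the relaxed bilayer this is close to the nominal thickness of
#' 5 d.
#'
#' @param profile A \code{radial_profile} of membrane beads.
#' @return Thickness \eqn{l_{me}} in \eqn{d}.
#' @export
membrane_thickness <- function(profile) {
  v <- profile$value
  r <- profile$r
  pk <- which.max(v)
  if (max(v) <= 0) stop("no bilayer in profile")
  half <- v[pk] / 2
  above <- v >= half
  if (!any(above) || sum(above) == length(v))
    stop("cannot resolve half-maximum crossings")
  lo <- min(which(above))
  hi <- max(which(above))
  r_lo <- if (lo == 1) r[1] - profile$bin_width / 2 else {
    f <- (half - v[lo - 1]) / (v[lo] - v[lo - 1])
    r[lo - 1] + f * profile$bin_width
  }
  r_hi <- if (hi == length(v)) r[hi] + profile$bin_width / 2 else {
    f <- (half - v[hi]) / (v[hi + 1] - v[hi])
    r[hi] + f * profile$bin_width
  }
  w <- r_hi - r_lo
  if (w <= 0) stop("degenerate (zero-width) density profile")
  w
}
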