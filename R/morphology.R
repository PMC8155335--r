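# Shape observables of budded vesicles: neck diameter, division
# detection, contact area.

# unwrapped lipid coordinates relative to the lipid centre (min image)
lipid_coords <- function(state, sel = NULL) {
  if (is.null(sel)) sel <- state$mol > 0L
  ctr <- lipid_center(state)
  dx <- sweep(state$pos[sel, , drop = FALSE], 2, ctr)
  for (d in 1:3) {
    L <- state$box[d]
    dx[, d] <- dx[, d] - L * round(dx[, d] / L)
  }
  dx
}

#' Outer neck diameter of a budded vesicle
#'
#' Orients the vesicle along the principal axis of the gyration tensor
#' of its lipid beads, slices it into axial slabs, takes the per-slab
#' outer diameter as twice the 95th percentile of the head-bead radial
#' distance from the axis, and returns the minimum slab diameter in the
#' interior region between the two bud centres. A closed neck is one
#' with diameter below 10 d.
#'
#' By convention the neck is only meaningful for elongated (dumbbell)
#' shapes; for near-spherical shapes (asphericity below
#' \code{aspher_min}) the minimal slab diameter is still returned but
#' flagged with \code{has_neck = FALSE}.
#'
#' @param state A \code{dpd_state} with lipid beads (\code{mol > 0}).
#' @param slab_width Axial slab width (\eqn{d}); default 1.
#' @param quantile_level Radial quantile defining the outer surface;
#'   default 0.95, robust to single protruding beads.
#' @param aspher_min Relative asphericity threshold below which the
#'   shape is treated as neckless.
#' @param closed_threshold Neck classification threshold (\eqn{d});
#'   default 10.
#' @return A list of class \code{neck_result}: \code{D_ne}, \code{state}
#'   ("open"/"closed"), \code{has_neck}, \code{axis}, \code{profile}
#'   (data.frame of slab centres and diameters).
#' @export
neck_diameter <- function(state, slab_width = 1, quantile_level = 0.95,
                          aspher_min = 0.15, closed_threshold = 10) {
  xyz <- lipid_coords(state)
  if (nrow(xyz) < 30) stop("too few lipid beads for a neck measurement")
  gyr <- crossprod(xyz) / nrow(xyz)
  eig <- eigen(gyr, symmetric = TRUE)
  axis <- eig$vectors[, 1]
  lam <- eig$values
  aspher <- (lam[1] - (lam[2] + lam[3]) / 2) / sum(lam)

  head_sel <- state$mol > 0L & state$type == 1L
  hx <- lipid_coords(state, head_sel)
  a <- drop(hx %*% axis)
  radial <- sqrt(rowSums((hx - outer(a, axis))^2))

  edges <- seq(min(a), max(a) + slab_width, by = slab_width)
  idx <- findInterval(a, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1
  diam <- rep(NA_real_, nb)
  for (k in seq_len(nb)) {
    rk <- radial[idx == k]
    if (length(rk) >= 5)
      diam[k] <- 2 * stats::quantile(rk, quantile_level, names = FALSE)
  }
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  ok <- !is.na(diam)
  profile <- data.frame(a = centers[ok], diameter = diam[ok])

  has_neck <- aspher >= aspher_min && nrow(profile) >= 3
  if (has_neck) {
    # bud centres: maximal slab diameters in the lower and upper halves
    n <- nrow(profile)
    half <- ceiling(n / 2)
    i_lo <- which.max(profile$diameter[1:half])
    i_hi <- half + which.max(profile$diameter[(half + 1):n])
    interior <- profile$diameter[i_lo:i_hi]
    d_ne <- min(interior)
  } else {
    d_ne <- min(profile$diameter)
  }
  structure(list(
    D_ne = d_ne,
    state = if (d_ne < closed_threshold) "closed" else "open",
    has_neck = has_neck, asphericity = aspher, axis = axis,
    profile = profile), class = "neck_result")
}

#' @export
print.neck_result <- function(x, ...) {
  cat(sprintf("Neck: D_ne = %.2f d (%s)%s, asphericity %.3f\n",
              x$D_ne, x$state,
              if (x$has_neck) "" else " [no neck: near-spherical shape]",
              x$asphericity))
  invisible(x)
}

#' Detect vesicle division into membrane components
#'
#' Single-linkage clustering of the lipid beads with a distance cutoff;
#' components holding less than \code{min_fraction} of the lipids are
#' ignored as debris.
#'
#' @param state A \code{dpd_state}.
#' @param cutoff Linkage cutoff (\eqn{d}); default 1.
#' @param min_fraction Minimum lipid fraction for a component to count.
#' @return List: \code{n_components}, \code{labels} (per lipid bead, 0
#'   for debris), \code{sizes} (beads per component), \code{lipids}
#'   (list of molecule-id vectors per component).
#' @export
detect_division <- function(state, cutoff = 1.0, min_fraction = 0.01) {
  sel <- which(state$mol > 0L)
  if (length(sel) == 0) stop("state has no lipid beads")
  lab <- cpp_cluster(state$pos[sel, , drop = FALSE], state$box, cutoff)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_fraction * length(sel))
  ord <- keep[order(sizes[keep], decreasing = TRUE)]
  relab <- integer(length(sizes))
  relab[ord] <- seq_along(ord)
  out_lab <- relab[lab]
  lipids <- lapply(seq_along(ord), function(k)
    sort(unique(state$mol[sel[out_lab == k]])))
  list(n_components = length(ord), labels = out_lab,
       sizes = sizes[ord], lipids = lipids)
}

#' Contact area between adhering membrane segments
#'
#' Counts outer-surface head beads of one segment that have an
#' opposing-segment head bead within \code{contact_cutoff} and converts
#' the count to an area using the mean area per head bead,
#' \eqn{A_0 / N_H} with \eqn{A_0} the segment surface area. Segments are
#' labeled either by membrane component (post-division) or by axial side
#' of the neck (pre-division).
#'
#' @param state A \code{dpd_state}.
#' @param segments Optional integer vector labeling every bead of
#'   \code{state} with a segment id (1 or 2; 0 = unused). By default
#'   segments are taken from [detect_division()] when it finds two
#'   components, else from the sign of the axial coordinate about the
#'   neck position.
#' @param contact_cutoff Head-head contact distance (\eqn{d});
#'   default 3, spanning the sandwiched solute layer.
#' @param area_per_head Mean area per head bead (\eqn{d^2}); default
#'   computed from the nominal area per lipid (1.25 \eqn{d^2} per 3 H
#'   beads).
#' @return Contact area in \eqn{d^2} (0 for well-separated or
#'   single-convex shapes).
#' @export
contact_area <- function(state, segments = NULL, contact_cutoff = 3,
                         area_per_head = 1.25 / 3) {
  head_sel <- which(state$mol > 0L & state$type == 1L)
  if (length(head_sel) == 0) stop("state has no head beads")
  if (is.null(segments)) {
    div <- detect_division(state)
    lip_sel <- which(state$mol > 0L)
    segments <- integer(n_beads(state))
    if (div$n_components >= 2) {
      segments[lip_sel] <- ifelse(div$labels %in% c(1L, 2L),
                                  div$labels, 0L)
    } else {
      nk <- neck_diameter(state)
      if (!nk$has_neck) return(0)
      xyz <- lipid_coords(state)
      a <- drop(xyz %*% nk$axis)
      a_neck <- nk$profile$a[which.min(nk$profile$diameter)]
      segments[lip_sel] <- ifelse(a > a_neck, 1L, 2L)
    }
  }
  s1 <- head_sel[segments[head_sel] == 1L]
  s2 <- head_sel[segments[head_sel] == 2L]
  if (length(s1) == 0 || length(s2) == 0)
    stop("segments must label head beads on both sides")
  p1 <- state$pos[s1, , drop = FALSE]
  p2 <- state$pos[s2, , drop = FALSE]
  n_contact <- 0L
  for (i in seq_len(nrow(p1))) {
    dx <- sweep(p2, 2, p1[i, ])
    for (d in 1:3) {
      L <- state$box[d]
      dx[, d] <- dx[, d] - L * round(dx[, d] / L)
    }
    if (any(rowSums(dx^2) <= contact_cutoff^2)) n_contact <- n_contact + 1L
  }
  n_contact * area_per_head
}

#' Morphology trace over a trajectory
#'
#' Per-frame neck diameter, open/closed classification, membrane
#' component count and contact area.
#'
#' @param x Simulation output accepted by [as_frames()].
#' @param dt Time per step (\eqn{\tau}) for the time column.
#' @param contact Also compute the contact area (slower)? Default FALSE.
#' @return data.frame: frame, step, time, D_ne, neck_state, has_neck,
#'   components, contact_area.
#' @export
morphology_trace <- function(x, dt = 0.01, contact = FALSE) {
  frames <- as_frames(x)
  rows <- lapply(seq_along(frames), function(i) {
    st <- frames[[i]]
    nk <- neck_diameter(st)
    div <- detect_division(st)
    ca <- if (contact) contact_area(st) else NA_real_
    data.frame(frame = i, step = st$step, time = st$step * dt,
               D_ne = nk$D_ne, neck_state = nk$state,
               has_neck = nk$has_neck,
               components = div$n_components, contact_area = ca)
  })
  do.call(rbind, rows)
}
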