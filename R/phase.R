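#' Coexisting mole fractions from a slab run
#'
#' Computes the z-resolved local solute mole fraction \eqn{\Phi_S(z)} in
#' slabs of width \code{slab_width}, averaged over frames, detects the
#' two liquid-liquid interfaces at the maximum-gradient positions, and
#' averages the dilute and dense plateaus away from them. The system is
#' classified as phase separated when the branch difference exceeds
#' five times the combined standard error of the plateau means.
#'
#' @param x Slab simulation output accepted by [as_frames()].
#' @param zeta Solubility of the run (recorded in the result).
#' @param slab_width Width of the z bins (\eqn{d}); default 1.
#' @param exclusion Exclusion zone on either side of each interface
#'   (\eqn{d}); default 3, to avoid interfacial broadening bias.
#' @return A list of class \code{coexistence_result}: \code{zeta},
#'   \code{Phi_dilute}, \code{Phi_dense} (NA when uniform),
#'   \code{phase_separated}, and \code{profile} (data.frame z, Phi_S).
#' @export
coexistence_from_slab <- function(x, zeta = NA_real_, slab_width = 1,
                                  exclusion = 3) {
  frames <- as_frames(x)
  st1 <- frames[[1]]
  lz <- st1$box[3]
  nb <- max(4L, floor(lz / slab_width))
  edges <- seq(0, lz, length.out = nb + 1)
  cnt_s <- cnt_t <- numeric(nb)
  for (st in frames) {
    idx <- findInterval(st$pos[, 3], edges, rightmost.closed = TRUE)
    idx[idx < 1L] <- 1L
    idx[idx > nb] <- nb
    solv <- st$type >= 3L
    cnt_t <- cnt_t + tabulate(idx[solv], nb)
    cnt_s <- cnt_s + tabulate(idx[solv & st$type == 4L], nb)
  }
  phi <- ifelse(cnt_t > 0, cnt_s / cnt_t, 0)
  z <- (edges[-1] + edges[-(nb + 1)]) / 2
  profile <- data.frame(z = z, Phi_S = phi)

  # periodic gradient; interfaces at the extreme gradients
  grad <- (phi[c(2:nb, 1)] - phi[c(nb, 1:(nb - 1))]) / (2 * lz / nb)
  i_up <- which.max(grad)
  i_dn <- which.min(grad)
  flat <- diff(range(phi)) < 1e-3 || i_up == i_dn
  if (!flat) {
    zi <- sort(c(z[i_up], z[i_dn]))
    dist_iface <- pmin(
      pmin(abs(z - zi[1]), lz - abs(z - zi[1])),
      pmin(abs(z - zi[2]), lz - abs(z - zi[2])))
    keep <- dist_iface >= exclusion
    # dense region: between the interfaces on the side containing the
    # richer slabs
    inside <- z > zi[1] & z < zi[2]
    m_in <- mean(phi[inside & keep])
    m_out <- mean(phi[!inside & keep])
    if (!is.nan(m_in) && !is.nan(m_out) && m_in < m_out)
      inside <- !inside
    dense <- phi[inside & keep]
    dilute <- phi[!inside & keep]
    if (length(dense) >= 2 && length(dilute) >= 2) {
      se <- sqrt(stats::var(dense) / length(dense) +
                 stats::var(dilute) / length(dilute))
      sep <- (mean(dense) - mean(dilute)) > 5 * se
    } else sep <- FALSE
  } else sep <- FALSE

  if (sep) {
    out <- list(zeta = zeta, Phi_dilute = mean(dilute),
                Phi_dense = mean(dense), phase_separated = TRUE,
                profile = profile)
  } else {
    out <- list(zeta = zeta, Phi_dilute = NA_real_,
                Phi_dense = NA_real_, phase_separated = FALSE,
                profile = profile)
  }
  structure(out, class = "coexistence_result")
}

#' @export
print.coexistence_result <- function(x, ...) {
  if (x$phase_separated)
    cat(sprintf(
      "Coexistence (zeta = %.4g): separated, Phi_dilute = %.4g, Phi_dense = %.4g\n",
      x$zeta, x$Phi_dilute, x$Phi_dense))
  else
    cat(sprintf("Coexistence (zeta = %.4g): uniform solution\n", x$zeta))
  invisible(x)
}

#' Classify solvent condition from a coexistence scan
#'
#' A solvent is poor when any scanned overall mole fraction phase
#' separates; the binodal estimate is the dilute branch of the lowest
#' separating point. With no separation anywhere the solvent is good.
#'
#' @param results List of \code{coexistence_result} objects, one per
#'   scanned overall mole fraction (>= 3 points).
#' @param Phi_S_total Overall mole fractions of the scan, same order.
#' @return List: \code{condition} ("good"/"poor"), \code{binodal}
#'   (dilute-branch estimate or NA), \code{scan} (data.frame).
#' @export
classify_solvent <- function(results, Phi_S_total) {
  if (length(results) < 3) stop("need >= 3 scan points")
  if (length(results) != length(Phi_S_total))
    stop("`results` and `Phi_S_total` lengths differ")
  ord <- order(Phi_S_total)
  results <- results[ord]
  Phi_S_total <- Phi_S_total[ord]
  sep <- vapply(results, function(r) r$phase_separated, logical(1))
  if (any(sep) && is.unsorted(sep[which(sep)[1]:length(sep)]))
    warning("non-monotone separation flags across the scan; ",
            "raw results returned")
  scan <- data.frame(
    Phi_S_total = Phi_S_total,
    separated = sep,
    Phi_dilute = vapply(results, function(r) r$Phi_dilute, numeric(1)),
    Phi_dense = vapply(results, function(r) r$Phi_dense, numeric(1)))
  if (any(sep)) {
    first <- which(sep)[1]
    list(condition = "poor", binodal = results[[first]]$Phi_dilute,
         scan = scan)
  } else {
    list(condition = "good", binodal = NA_real_, scan = scan)
  }
}
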