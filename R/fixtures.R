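#' Deterministic test fixtures
#'
#' Seeded generators for the small systems used throughout the test
#' suite and examples. Every fixture is built in code; no configuration
#' files or stored coordinates are involved.
#'
#' Registry:
#' \describe{
#'   \item{bulk_water}{(10 d)^3 pure water at density 3 (3000 beads).}
#'   \item{binary_bulk}{(10 d)^3 W/S solution at \eqn{\Phi_S} = 0.025.}
#'   \item{slab}{10 x 10 x 30 d slab system at overall \eqn{\Phi_S} =
#'     0.5, solutes seeded in the central third.}
#'   \item{planar_bilayer}{128 + 128 lipids in a 12.6 x 12.6 x 20 d box,
#'     solvated.}
#'   \item{mini_vesicle}{Small vesicle (180 inner / 810 outer lipids,
#'     midsurface radius near 6.5 d) in a compact box. The leaflet
#'     counts keep the leaflet separation near the bilayer thickness at
#'     this high curvature.}
#'   \item{dumbbell_shells}{Two overlapping spherical head-bead shells
#'     (radius R, centres 1.6 R apart): analytic neck geometry.}
#'   \item{separated_shells}{Two disjoint spherical shells 5 d apart:
#'     two membrane components.}
#' }
#'
#' @param name Fixture name from the registry above.
#' @param seed Integer seed; the same seed reproduces the same state
#'   bit for bit.
#' @param ... Overrides passed to the underlying builder (fixture
#'   specific).
#' @return A \code{dpd_state}.
#' @export
make_fixture <- function(name, seed = 1L, ...) {
  switch(
    name,
    bulk_water = build_bulk(0, box = 10, seed = seed, ...),
    binary_bulk = build_bulk(0.025, box = 10, seed = seed, ...),
    slab = build_slab(0.5, box = c(10, 10, 30), seed = seed, ...),
    planar_bilayer = build_planar_bilayer(
      128, box = c(sqrt(128 * 1.25), sqrt(128 * 1.25), 20),
      seed = seed, ...),
    mini_vesicle = build_vesicle(
      vesicle_spec(N_il = 180, N_ol = 810, ...), seed = seed),
    dumbbell_shells = {
      a <- list(...)
      if (is.null(a$separation_factor) && is.null(a$gap))
        a$separation_factor <- 1.6
      do.call(shell_pair_fixture, c(list(seed = seed), a))
    },
    separated_shells = {
      a <- list(...)
      if (is.null(a$separation_factor) && is.null(a$gap)) a$gap <- 5
      do.call(shell_pair_fixture, c(list(seed = seed), a))
    },
    stop("unknown fixture name: ", name)
  )
}

# two spherical head-bead shells; overlapping (separation_factor < 2)
# for neck geometry tests or disjoint (gap > 0) for component tests
shell_pair_fixture <- function(seed = 1L, R = 7, separation_factor = NULL,
                               gap = NULL, n_per_shell = 1200,
                               box = NULL) {
  set.seed(seed)
  sep <- if (!is.null(separation_factor)) separation_factor * R
         else 2 * R + gap
  if (is.null(box)) box <- rep(ceiling(2 * R + sep + 8), 3)
  if (length(box) == 1) box <- rep(box, 3)
  ctr <- box / 2
  c1 <- ctr - c(0, 0, sep / 2)
  c2 <- ctr + c(0, 0, sep / 2)
  u1 <- fib_sphere(n_per_shell)
  u2 <- fib_sphere(n_per_shell)
  keep1 <- rep(TRUE, n_per_shell)
  keep2 <- rep(TRUE, n_per_shell)
  if (sep < 2 * R) {
    # remove the shell caps inside the other sphere so the union is the
    # lens-free outer surface, as for a budded membrane
    keep1 <- rowSums(sweep(sweep(u1 * R, 2, c1, "+"), 2, c2)^2) > R^2
    keep2 <- rowSums(sweep(sweep(u2 * R, 2, c2, "+"), 2, c1)^2) > R^2
  }
  pos <- rbind(sweep(u1[keep1, ] * R, 2, c1, "+"),
               sweep(u2[keep2, ] * R, 2, c2, "+"))
  n <- nrow(pos)
  dpd_state(box, pos, vel = matrix(0, n, 3), type = rep("H", n),
            mol = seq_len(n),
            meta = list(R = R, centers = rbind(c1, c2), sep = sep))
}
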