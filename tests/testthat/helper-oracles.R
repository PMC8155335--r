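# Independent oracles and small constructors shared across test files.

# All-pairs conservative + bond forces in plain R, written independently
# of the C++ kernel: the brute-force double loop it is checked against.
oracle_forces <- function(state, ff) {
  n <- nrow(state$pos)
  f <- matrix(0, n, 3)
  vir <- 0
  box <- state$box
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dv <- state$pos[i, ] - state$pos[j, ]
      dv <- dv - box * round(dv / box)
      r <- sqrt(sum(dv^2))
      if (r < ff$cutoff && r > 0) {
        fij <- ff$f[state$type[i], state$type[j]]
        fm <- fij * (1 - r / ff$cutoff)
        fvec <- fm * dv / r
        f[i, ] <- f[i, ] + fvec
        f[j, ] <- f[j, ] - fvec
        vir <- vir + fm * r
      }
    }
  }
  if (nrow(state$bonds) > 0) {
    for (b in seq_len(nrow(state$bonds))) {
      i <- state$bonds[b, 1]; j <- state$bonds[b, 2]
      dv <- state$pos[i, ] - state$pos[j, ]
      dv <- dv - box * round(dv / box)
      r <- sqrt(sum(dv^2))
      fm <- -ff$bond_k * (r - ff$bond_l0)
      fvec <- fm * dv / r
      f[i, ] <- f[i, ] + fvec
      f[j, ] <- f[j, ] - fvec
      vir <- vir + fm * r
    }
  }
  attr(f, "virial") <- vir
  f
}

# random unit vectors (for synthetic shells)
runit_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  ph <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(ph), r * sin(ph), z)
}

# state holding n beads on a thin spherical shell of radius R
shell_state <- function(n, R, box, type = "S", seed = 1) {
  set.seed(seed)
  pos <- sweep(runit_sphere(n) * R, 2, box / 2, "+")
  dpd_state(rep(box, 3), pos, vel = matrix(0, n, 3), type = rep(type, n))
}

# synthetic stress profile: zero everywhere except a single-bin spike
spike_stress <- function(r0, value, bin_width = 0.2, r_max = 30) {
  r <- seq(bin_width / 2, r_max, by = bin_width)
  s <- numeric(length(r))
  s[which.min(abs(r - r0))] <- value
  stress_profile(r, s, numeric(length(r)), bin_width)
}

# random 3D rotation matrix
random_rotation <- function(seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

good_ff <- function(...) default_force_table("good", ...)

# the slab estimator sees the waist through an axial slab of width w,
# so the analytic sphere-sphere intersection bounds it between the
# waist circle and the circle half a slab off the waist
neck_bracket <- function(R, sep, w = 1) {
  c(lo = 2 * sqrt(R^2 - (sep / 2)^2) - 0.5,
    hi = 2 * sqrt(R^2 - (sep / 2 - w / 2)^2) + 0.5)
}
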