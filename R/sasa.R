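# Shrake-Rupley solvent accessible surface area. Each atom is expanded by
# the probe radius and covered with a deterministic quasi-uniform point set
# (golden-spiral lattice); the accessible fraction is the share of points
# not inside any other expanded atom sphere.

# n quasi-uniform points on the unit sphere (Fibonacci / golden spiral).
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent accessible surface area
#'
#' Shrake-Rupley sphere sampling with Bondi van der Waals radii. A single
#' isolated atom of radius r yields 4 * pi * (r + probe)^2 exactly (every
#' sample point is accessible); fully buried atoms yield 0.
#'
#' @param atoms a `pocket_atoms` table (or any data.frame with columns
#'   `element`, `x`, `y`, `z`).
#' @param probe probe radius in Angstrom (water = 1.4).
#' @param n_points sample points per atom sphere.
#' @return Numeric vector of SASA values in Angstrom^2, one per atom.
#' @export
compute_sasa <- function(atoms, probe = 1.4, n_points = 960) {
  pg_assert(nrow(atoms) >= 1, "need at least one atom")
  xyz <- pocket_coords(atoms)
  radii <- unname(PG_VDW[atoms$element])
  radii[is.na(radii)] <- PG_VDW_DEFAULT
  r_exp <- radii + probe
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  d2 <- as.matrix(stats::dist(xyz))^2
  out <- numeric(n)
  for (i in seq_len(n)) {
    # neighbors whose expanded spheres can reach atom i's surface
    reach <- (r_exp[i] + r_exp)^2
    nbr <- which(d2[i, ] < reach & seq_len(n) != i)
    p <- sweep(pts * r_exp[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nbr) {
      if (!any(acc)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
      acc <- acc & (dj2 >= r_exp[j]^2)
    }
    out[i] <- 4 * pi * r_exp[i]^2 * mean(acc)
  }
  out
}
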