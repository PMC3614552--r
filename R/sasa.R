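## Shrake-Rupley solvent accessible surface area.

# quasi-uniform points on the unit sphere (golden-section spiral);
# deterministic in n
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Per atom, the fraction of quasi-uniform test points on the sphere of
#' radius `radius + probe_radius` that fall inside no other atom's
#' probe-expanded sphere, times `4*pi*(radius + probe_radius)^2`.
#'
#' @param s a `mol_structure` with positive radii.
#' @param probe_radius solvent probe radius, Angstrom (default 1.4, a water
#'   molecule).
#' @param n_points number of test points per atom (default 960; more points
#'   reduce the discretization error, roughly as 1/n).
#' @return numeric vector of per-atom SASA values, Angstrom^2.
#' @export
sasa <- function(s, probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(s, "mol_structure"))
  a <- s$atoms
  if (any(is.na(a$radius) | a$radius <= 0))
    stop("every atom needs a positive radius")
  n <- nrow(a)
  pos <- cbind(a$x, a$y, a$z)
  R <- a$radius + probe_radius
  pts <- sphere_points(n_points)
  out <- numeric(n)
  d2 <- as.matrix(stats::dist(pos))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2)
    nb <- nb[nb != i]
    p <- pts * R[i]
    p <- sweep(p, 2, pos[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dx <- p[free, 1] - pos[j, 1]
      dy <- p[free, 2] - pos[j, 2]
      dz <- p[free, 3] - pos[j, 3]
      free[free] <- dx * dx + dy * dy + dz * dz >= R[j]^2
    }
    out[i] <- 4 * pi * R[i]^2 * sum(free) / n_points
  }
  out
}
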