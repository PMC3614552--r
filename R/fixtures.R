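## Seed-deterministic synthetic inputs: toy pseudo-proteins built from rigid
## residue templates on a spherical lattice, solubility tables generated
## from the linear model plus Gaussian noise, and Gaussian-well PMF curves.
## No physically realistic folds -- the descriptors depend only on
## coordinates, radii and charges, which the templates provide.

# rigid residue templates: idealized internal geometry, side chain extending
# along +z (oriented outward when placed on the sphere).  3-8 pseudo-atoms
# per residue; the charge-site atoms of ASP/GLU/LYS/ARG are present.
.residue_templates <- local({
  bb <- list(N = c(-1.45, 0.30, 0), CA = c(0, 0, 0),
             C = c(1.40, 0.40, 0), O = c(1.85, 1.50, 0.2))
  chain <- function(...) {
    # side-chain atoms stacked outward from CA along +z with small stagger
    nm <- c(...)
    out <- list()
    for (i in seq_along(nm))
      out[[nm[i]]] <- c(0.25 * (i %% 2), -0.3, 1.45 * i)
    out
  }
  branch <- function(base, nm1, nm2, z) {
    out <- list()
    out[[nm1]] <- c(base[1] - 1.1, base[2], z)
    out[[nm2]] <- c(base[1] + 1.1, base[2], z)
    out
  }
  tpl <- list(
    GLY = bb,
    ALA = c(bb, chain("CB")),
    SER = c(bb, chain("CB", "OG")),
    THR = c(bb, chain("CB", "OG1", "CG2")),
    VAL = c(bb, chain("CB", "CG1", "CG2")),
    LEU = c(bb, chain("CB", "CG", "CD1")),
    ILE = c(bb, chain("CB", "CG1", "CD1")),
    PHE = c(bb, chain("CB", "CG", "CZ")),
    ASN = c(bb, chain("CB", "CG"), branch(c(0, -0.3), "OD1", "ND2", 3.6)),
    ASP = c(bb, chain("CB", "CG"), branch(c(0, -0.3), "OD1", "OD2", 3.6)),
    GLU = c(bb, chain("CB", "CG", "CD"),
            branch(c(0.25, -0.3), "OE1", "OE2", 5.1)),
    LYS = c(bb, chain("CB", "CG", "CD", "CE", "NZ")),
    ARG = c(bb, chain("CB", "CG", "CD", "NE", "CZ"))
  )
  tpl
})

.default_composition <- c(
  GLY = 0.10, ALA = 0.12, SER = 0.08, THR = 0.07, VAL = 0.09, LEU = 0.10,
  ILE = 0.06, PHE = 0.05, ASN = 0.05, ASP = 0.07, GLU = 0.08, LYS = 0.07,
  ARG = 0.06)

# rotation matrix sending +z to the unit vector u, with spin about u
rotation_to <- function(u, spin) {
  z <- c(0, 0, 1)
  v <- c(z[2] * u[3] - z[3] * u[2], z[3] * u[1] - z[1] * u[3],
         z[1] * u[2] - z[2] * u[1])
  s <- sqrt(sum(v^2)); cth <- sum(z * u)
  R <- if (s < 1e-12) {
    if (cth > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + K + K %*% K * ((1 - cth) / s^2)
  }
  cs <- cos(spin); sn <- sin(spin)
  S <- matrix(c(cs, -sn, 0, sn, cs, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  R %*% S
}

#' Generate a toy protein structure
#'
#' Places rigid residue templates on a jittered spherical shell of radius
#' `compactness * sqrt(n_residues)` Angstrom, each oriented with its side
#' chain pointing outward (with a random spin and tilt), giving a clash-free,
#' fully solvent-exposed pseudo-protein that exercises every structure
#' descriptor.  Deterministic per seed.  The result carries no charges;
#' apply [assign_formal_charges()] (or write and re-read as PQR) before
#' charge-based descriptors.
#'
#' @param n_residues number of residues (ignored when `sequence` is given).
#' @param composition named residue-type frequency map (3-letter codes over
#'   the template set), summing to 1; default a protein-like mix.
#' @param compactness radial scale factor, Angstrom (default 2.2; the shell
#'   radius is `compactness * sqrt(n)`).  Too-small values that force severe
#'   clashes (any inter-residue atom pair overlapping by more than 50% of
#'   the summed radii) raise an error.
#' @param seed integer seed.
#' @param sequence optional explicit residue sequence (3-letter codes);
#'   overrides `n_residues` and `composition`.
#' @return a `mol_structure` (source_format "MODEL").
#' @export
make_toy_protein <- function(n_residues = 30, composition = NULL,
                             compactness = 2.2, seed = 1, sequence = NULL) {
  if (is.null(composition)) composition <- .default_composition
  if (abs(sum(composition) - 1) > 1e-6)
    stop("composition frequencies must sum to 1")
  bad <- setdiff(names(composition), names(.residue_templates))
  if (length(bad))
    stop("no template for residue(s): ", paste(bad, collapse = ", "))
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  if (is.null(sequence)) {
    if (n_residues < 1) stop("n_residues must be >= 1")
    sequence <- sample(names(composition), n_residues, replace = TRUE,
                       prob = composition)
  } else {
    sequence <- toupper(sequence)
    bad <- setdiff(sequence, names(.residue_templates))
    if (length(bad))
      stop("no template for residue(s): ", paste(bad, collapse = ", "))
    n_residues <- length(sequence)
  }
  radius <- compactness * sqrt(n_residues)
  centers <- sphere_points(n_residues) *
    (radius + stats::runif(n_residues, -0.4, 0.4))
  rows <- vector("list", n_residues)
  serial <- 0L
  for (i in seq_len(n_residues)) {
    tpl <- .residue_templates[[sequence[i]]]
    u <- centers[i, ] / sqrt(sum(centers[i, ]^2))
    # outward orientation with random spin and a small random tilt
    tilt <- stats::rnorm(3, 0, 0.08)
    u2 <- u + tilt; u2 <- u2 / sqrt(sum(u2^2))
    R <- rotation_to(u2, stats::runif(1, 0, 2 * pi))
    loc <- do.call(rbind, tpl)
    xyz <- loc %*% t(R) + matrix(centers[i, ], nrow(loc), 3, byrow = TRUE)
    el <- element_from_name(names(tpl))
    rows[[i]] <- data.frame(
      serial = serial + seq_len(nrow(loc)),
      name = names(tpl), element = el,
      resname = sequence[i], resnum = i, icode = "", chain = "A",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      radius = element_radius(el), charge = NA_real_,
      stringsAsFactors = FALSE)
    serial <- serial + nrow(loc)
  }
  atoms <- do.call(rbind, rows)
  s <- mol_structure(atoms, source_format = "MODEL")
  # severe-clash guard between residues
  if (n_residues > 1) {
    pos <- cbind(atoms$x, atoms$y, atoms$z)
    d <- as.matrix(stats::dist(pos))
    lim <- outer(atoms$radius, atoms$radius, "+") * 0.5
    same <- outer(atoms$resnum, atoms$resnum, "==")
    if (any(d < lim & !same & upper.tri(d)))
      stop("compactness too small: severe inter-residue clashes (> 50% overlap)")
  }
  s
}

#' Simulate solubilities from the linear model plus Gaussian noise
#'
#' `sol_i = c1 * desc_i + c2 * q_i + c3 + Normal(0, sigma)`, deterministic
#' per seed.  The generating model is exactly the form [fit_lr()] fits, so
#' with `sigma = 0` the coefficients are recovered to machine precision.
#'
#' @param records data.frame with a `q` column and the descriptor column.
#' @param descriptor name of the descriptor column (default "p").
#' @param c1,c2,c3 generating coefficients.
#' @param sigma noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return `records` with a `sol` column appended.
#' @export
simulate_solubility <- function(records, c1, c2, c3, sigma = 0, seed = 1,
                                descriptor = "p") {
  if (!is.data.frame(records) || is.null(records$q) ||
      is.null(records[[descriptor]]))
    stop("records must contain columns 'q' and '", descriptor, "'")
  if (sigma < 0) stop("sigma must be >= 0")
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  records$sol <- c1 * records[[descriptor]] + c2 * records$q + c3 +
    stats::rnorm(nrow(records), 0, sigma)
  records
}

#' Generate a toy PMF curve
#'
#' A Gaussian well of the given depth and location plus a soft repulsive
#' wall at the contact end, sampled on the default separation grid 15.5 to
#' 28.0 Angstrom in 0.5 Angstrom steps (26 points).  The wall is a quadratic
#' ramp that vanishes half an Angstrom past the first grid point, so a well
#' centred on a grid point keeps its exact depth there.  With `depth = 0`
#' the curve has no bound minimum.
#'
#' @param depth well depth, kJ/mol (negative for a bound minimum; 0 gives a
#'   wall-only curve).
#' @param location well position, Angstrom; must lie within the grid.
#' @param width Gaussian width, Angstrom (default 1).
#' @param grid separation grid, Angstrom.
#' @param wall_height wall value at the first grid point, kJ/mol.
#' @return a `pmf_curve`.
#' @export
make_pmf_curve <- function(depth, location, width = 1.0,
                           grid = seq(15.5, 28.0, by = 0.5),
                           wall_height = 50) {
  if (location < min(grid) || location > max(grid))
    stop("location must lie within the grid")
  well <- depth * exp(-(grid - location)^2 / (2 * width^2))
  r0 <- grid[1]
  wall <- ifelse(grid < r0 + 0.5,
                 wall_height * ((r0 + 0.5 - grid) / 0.5)^2, 0)
  pmf_curve(grid, well + wall)
}
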