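# Shared fixtures and independent brute-force oracles.  Shells are built
# once per test run (construction is deterministic).

shell_c60 <- build_goldberg_shell(1, 1, 1.42)
shell_gp32 <- build_goldberg_shell(3, 2, 1.42)

# brute-force double-loop oracles for the patch descriptors (independent of
# the vectorized implementation path)
lssc_oracle <- function(top, params) {
  pos <- top$geometry$surface
  q <- top$surface_charges
  n <- nrow(pos)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- q[i]^2
    for (j in seq_len(n)) {
      if (j == i) next
      r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (r < params$d_cut) acc <- acc + (params$r0 / r)^params$n * q[j]^2
    }
    out[i] <- acc
  }
  out
}

lsc_oracle <- function(top, params) {
  pos <- top$geometry$surface
  q <- top$surface_charges
  n <- nrow(pos)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- q[i]
    for (j in seq_len(n)) {
      if (j == i) next
      r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (r < params$d_cut) acc <- acc + (params$r0 / r)^params$n * q[j]
    }
    out[i] <- acc
  }
  out
}

dipole_oracle <- function(top, origin = NULL) {
  g <- top$geometry
  if (is.null(origin)) origin <- g$center
  pos <- rbind(g$surface, g$center)
  q <- c(top$surface_charges, top$central_charge)
  v <- c(0, 0, 0)
  for (i in seq_along(q)) v <- v + q[i] * (pos[i, ] - origin)
  sqrt(sum(v^2))
}

# ad-hoc geometry from explicit surface positions (for arithmetic examples)
point_geometry <- function(surface) {
  surface <- as.matrix(surface)
  structure(list(surface = surface, center = colMeans(surface),
                 bond_length = NA_real_, h = NA_integer_, k = NA_integer_,
                 n_surface = nrow(surface), bonds = NULL,
                 n_pentagons = NA_integer_),
            class = "shell_geometry")
}

point_topology <- function(surface, charges, central_charge = 0) {
  colloidkit:::new_topology(point_geometry(surface), charges, central_charge)
}

# minimal structure from an atom spec list
toy_structure <- function(names, resnames, resnums, xyz, chain = "A",
                          charge = NA_real_, source_format = "MODEL") {
  mol_structure(data.frame(
    serial = seq_along(names), name = names,
    element = colloidkit:::element_from_name(names),
    resname = resnames, resnum = resnums, icode = "", chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    radius = colloidkit:::element_radius(
      colloidkit:::element_from_name(names)),
    charge = charge, stringsAsFactors = FALSE), source_format)
}
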