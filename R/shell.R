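## Goldberg-polyhedron shell geometry: the coarse-grained pseudo-protein
## scaffold.  A GP(h,k) shell is the dual of the icosahedral geodesic sphere
## of frequency (h,k); every surface atom is trivalent and exactly 12 faces
## of the dual are pentagons.

#' Regular icosahedron (unit circumradius)
#'
#' @return list with `vertices` (12 x 3) and `faces` (20 x 3, 1-based,
#'   consistently oriented).
#' @keywords internal
#' @noRd
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

## Vertices of the icosahedral geodesic sphere of frequency (h,k), on the
## unit sphere.  Each icosahedron face carries a triangular-lattice master
## triangle with corners 0, h*e1+k*e2 and its 60-degree rotation; lattice
## points inside (closed triangle) map barycentrically onto the face and are
## projected to the sphere.  Duplicates on shared edges/corners are merged.
geodesic_vertices <- function(h, k) {
  ico <- icosahedron()
  e1 <- c(1, 0)
  e2 <- c(0.5, sqrt(3) / 2)
  A2 <- c(0, 0)
  B2 <- h * e1 + k * e2
  C2 <- c(-k, h + k)[1] * e1 + c(-k, h + k)[2] * e2
  M <- cbind(B2 - A2, C2 - A2)        # 2x2, columns are triangle edges
  Minv <- solve(M)
  a_rng <- seq.int(min(0L, h, -k), max(0L, h, -k))
  b_rng <- seq.int(0L, h + k)
  grid <- expand.grid(a = a_rng, b = b_rng)
  P2 <- cbind(grid$a + 0.5 * grid$b, grid$b * sqrt(3) / 2)
  wc <- P2 %*% t(Minv)                # (w2, w3); w1 = 1 - w2 - w3
  w <- cbind(1 - wc[, 1] - wc[, 2], wc[, 1], wc[, 2])
  tol <- 1e-9
  keep <- w[, 1] >= -tol & w[, 2] >= -tol & w[, 3] >= -tol
  w <- w[keep, , drop = FALSE]

  pts <- matrix(0, nrow = 20 * nrow(w), ncol = 3)
  m <- 0L
  for (f in seq_len(20)) {
    V <- ico$vertices[ico$faces[f, ], ]
    p <- w %*% V
    p <- p / sqrt(rowSums(p^2))
    pts[m + seq_len(nrow(p)), ] <- p
    m <- m + nrow(p)
  }
  pts <- pts[seq_len(m), , drop = FALSE]

  # merge coincident points (shared face corners / edge points)
  key <- apply(round(pts * 1e6), 1, paste, collapse = ",")
  pts <- pts[!duplicated(key), , drop = FALSE]
  T_num <- h * h + h * k + k * k
  if (nrow(pts) != 10 * T_num + 2)
    stop(sprintf("geodesic construction yielded %d vertices, expected %d",
                 nrow(pts), 10 * T_num + 2))
  pts
}

## Edge graph of the geodesic triangulation from mutual nearest neighbours.
## Every vertex has 6 neighbours except the 12 icosahedral corners (5); the
## gap between first- and second-shell distances is wide enough to detect
## the degree by the relative jump after the 5th neighbour.
geodesic_edges <- function(pts) {
  n <- nrow(pts)
  d2 <- as.matrix(stats::dist(pts))^2
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ])[-1L]          # drop self
    d <- sqrt(d2[i, ord])
    deg <- if (n > 6 && d[6] > 1.3 * d[5]) 5L else min(6L, n - 1L)
    nb[[i]] <- ord[seq_len(deg)]
  }
  edges <- NULL
  for (i in seq_len(n)) {
    js <- nb[[i]][nb[[i]] > i]
    js <- js[vapply(js, function(j) i %in% nb[[j]], logical(1))]
    if (length(js)) edges <- rbind(edges, cbind(i, js))
  }
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  if (!all(deg %in% c(5L, 6L)) || sum(deg == 5L) != 12L)
    stop("geodesic edge graph is not icosahedral (degree check failed)")
  edges
}

## Triangles (3-cliques) of the geodesic edge graph.
geodesic_triangles <- function(edges, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  tri <- vector("list", 2 * nrow(edges))
  m <- 0L
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    common <- intersect(adj[[i]], adj[[j]])
    for (k in common[common > j]) {
      m <- m + 1L
      tri[[m]] <- c(i, j, k)
    }
  }
  do.call(rbind, tri[seq_len(m)])
}

#' Build a Goldberg-polyhedron fullerene shell GP(h,k)
#'
#' Constructs the trivalent spherical carbon cage GP(h,k) -- the dual of the
#' icosahedral geodesic sphere of frequency (h,k) -- with `20*(h^2+h*k+k^2)`
#' surface atoms plus one atom at the geometric center.  The default GP(3,2)
#' (380 atoms) has a diameter of about 1.8 nm at carbon-carbon bond lengths,
#' comparable to a small globular protein or protein domain; the central atom
#' plays the role of a repulsive core keeping the pseudo-protein spherical
#' and can later carry charge to tune the net charge independently of the
#' surface pattern.
#'
#' After dualization the vertices are projected to a common sphere and the
#' local geometry is regularized by a fixed gradient relaxation (200
#' iterations, step `0.05 * bond_length`) with harmonic terms on the bonded
#' distances and on the ring chords (the skip-one chord of every pentagon and
#' hexagon and the para distance of every hexagon, at their flat regular-ring
#' targets).  The ring-chord terms keep hexagons from shearing, which
#' preserves the clean separation between second-neighbour (< 2.65 A) and
#' third-neighbour (> 2.65 A) distances that calibrates the patch radius.
#' Finally the shell is scaled so the mean bonded distance equals
#' `bond_length` and centred on its centroid.
#'
#' @param h,k non-negative integers indexing the Goldberg polyhedron;
#'   `h >= 1`.  GP(1,0) is the dodecahedral cage (20 atoms), GP(1,1) the
#'   truncated icosahedron (60 atoms, the C60 topology), GP(3,2) the default
#'   380-atom shell.
#' @param bond_length target mean bonded distance in Angstrom (default 1.42,
#'   a carbon-carbon aromatic bond).
#' @return an object of class `shell_geometry`: a list with `surface`
#'   (n x 3 matrix of positions, Angstrom), `center` (the central atom
#'   position, the centroid of the surface), `bond_length`, `h`, `k`,
#'   `n_surface`, `bonds` (2-column index matrix of bonded surface pairs)
#'   and `n_pentagons`.
#' @examples
#' sh <- build_goldberg_shell(1, 1)
#' sh$n_surface                      # 60
#' round(shell_diameter(sh), 1)      # about 7.1 Angstrom
#' @export
build_goldberg_shell <- function(h, k, bond_length = 1.42) {
  if (length(h) != 1 || length(k) != 1 || is.na(h) || is.na(k) ||
      h != round(h) || k != round(k))
    stop("h and k must be single non-negative integers")
  h <- as.integer(h); k <- as.integer(k)
  if (h < 1 || k < 0) stop("require h >= 1 and k >= 0")
  if (!is.numeric(bond_length) || length(bond_length) != 1 ||
      !is.finite(bond_length) || bond_length <= 0)
    stop("bond_length must be a positive number")

  pts <- geodesic_vertices(h, k)
  edges <- geodesic_edges(pts)
  tri <- geodesic_triangles(edges, nrow(pts))
  T_num <- h * h + h * k + k * k
  if (nrow(tri) != 20 * T_num)
    stop("triangulation has the wrong face count")

  # dual vertices: projected triangle centroids
  dual <- (pts[tri[, 1], ] + pts[tri[, 2], ] + pts[tri[, 3], ]) / 3
  dual <- dual / sqrt(rowSums(dual^2))

  # dual adjacency: triangles sharing an edge
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  emap <- new.env(hash = TRUE, parent = emptyenv())
  bonds <- matrix(0L, nrow = 3 * nrow(tri) / 2, ncol = 2)
  m <- 0L
  for (t in seq_len(nrow(tri))) {
    vs <- tri[t, ]
    for (pair in list(vs[c(1, 2)], vs[c(1, 3)], vs[c(2, 3)])) {
      kk <- ekey(pair[1], pair[2])
      prev <- emap[[kk]]
      if (is.null(prev)) {
        emap[[kk]] <- t
      } else {
        m <- m + 1L
        bonds[m, ] <- c(prev, t)
      }
    }
  }
  bonds <- bonds[seq_len(m), , drop = FALSE]
  if (nrow(bonds) != 3 * nrow(dual) / 2)
    stop("dual adjacency is not trivalent")

  # faces of the dual: the triangles incident to each triangulation vertex,
  # cyclically ordered along the ring (pentagon at degree-5 vertices)
  badj <- vector("list", nrow(dual))
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    badj[[i]] <- c(badj[[i]], j)
    badj[[j]] <- c(badj[[j]], i)
  }
  incident <- vector("list", nrow(pts))
  for (t in seq_len(nrow(tri)))
    for (v in tri[t, ]) incident[[v]] <- c(incident[[v]], t)
  skip1 <- vector("list", nrow(pts))
  skip2 <- vector("list", nrow(pts))
  for (v in seq_len(nrow(pts))) {
    f <- incident[[v]]
    ring <- f[1]
    while (length(ring) < length(f)) {
      nxt <- setdiff(intersect(badj[[ring[length(ring)]]], f), ring)[1]
      ring <- c(ring, nxt)
    }
    nr <- length(ring)
    idx <- seq_len(nr)
    skip1[[v]] <- cbind(ring, ring[((idx + 1) %% nr) + 1], nr)
    if (nr == 6) skip2[[v]] <- cbind(ring[1:3], ring[4:6])
  }
  skip1 <- do.call(rbind, skip1)
  skip2 <- do.call(rbind, skip2)

  # harmonic relaxation of bonds and ring chords on the sphere
  L <- bond_length
  c_pairs <- rbind(bonds, skip1[, 1:2, drop = FALSE], skip2)
  c_targ <- c(rep(L, nrow(bonds)), 2 * L * cos(pi / skip1[, 3]),
              rep(2 * L, if (is.null(skip2)) 0 else nrow(skip2)))
  c_w <- c(rep(1, nrow(bonds)), rep(0.5, nrow(skip1)),
           rep(0.25, if (is.null(skip2)) 0 else nrow(skip2)))
  blen <- function(x) sqrt(rowSums((x[bonds[, 1], ] - x[bonds[, 2], ])^2))
  dual <- dual * (L / mean(blen(dual)))
  step <- 0.05 * L
  for (it in seq_len(200)) {
    v <- dual[c_pairs[, 2], ] - dual[c_pairs[, 1], ]
    d <- sqrt(rowSums(v^2))
    f <- step * c_w * (d - c_targ) / L
    disp <- v * (f / d)
    acc <- matrix(0, nrow(dual), 3)
    for (c3 in 1:3) {
      acc[, c3] <- tabulate2(c_pairs[, 1], disp[, c3], nrow(dual)) -
        tabulate2(c_pairs[, 2], disp[, c3], nrow(dual))
    }
    dual <- dual + acc
    r <- sqrt(rowSums(dual^2))
    dual <- dual * (mean(r) / r)              # reproject to common sphere
    dual <- dual * (L / mean(blen(dual)))
  }
  dual <- dual - matrix(colMeans(dual), nrow(dual), 3, byrow = TRUE)

  # pentagon faces of the dual correspond to degree-5 triangulation vertices
  structure(list(
    surface = dual,
    center = c(0, 0, 0),
    bond_length = bond_length,
    h = h, k = k,
    n_surface = nrow(dual),
    bonds = bonds,
    n_pentagons = 12L
  ), class = "shell_geometry")
}

# weighted tabulate: sum w by integer index
tabulate2 <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @export
print.shell_geometry <- function(x, ...) {
  cat(sprintf("Goldberg shell GP(%d,%d): %d surface atoms + 1 central atom\n",
              x$h, x$k, x$n_surface))
  cat(sprintf("  bond length %.3f A (mean bonded distance %.3f A)\n",
              x$bond_length,
              mean(sqrt(rowSums((x$surface[x$bonds[, 1], ] -
                                 x$surface[x$bonds[, 2], ])^2)))))
  cat(sprintf("  diameter %.2f A\n", shell_diameter(x)))
  invisible(x)
}

#' Count shell atoms within a cutoff of each surface atom
#'
#' For every surface atom i, counts the surface atoms j (including j = i)
#' with euclidean distance strictly below `d_cut`.  The central atom is
#' excluded.  This is the neighbour count entering the local patch
#' descriptors: on the default GP(3,2) shell with 1.42 A bonds, a cutoff of
#' 2.65 A encloses exactly 10 atoms (self, the 3 bonded and the 6 second
#' neighbours) and a cutoff of 5.0 A about 30.
#'
#' @param geom a `shell_geometry`.
#' @param d_cut cutoff distance in Angstrom, > 0.
#' @return integer vector of per-surface-atom counts.
#' @export
neighbor_counts <- function(geom, d_cut) {
  stopifnot(inherits(geom, "shell_geometry"))
  if (!is.numeric(d_cut) || length(d_cut) != 1 || !is.finite(d_cut) ||
      d_cut <= 0)
    stop("d_cut must be a positive number")
  d <- as.matrix(stats::dist(geom$surface))
  as.integer(rowSums(d < d_cut))   # diagonal is 0 < d_cut: self included
}

#' Shell diameter
#'
#' Maximum pairwise distance between surface atoms, in Angstrom.
#'
#' @param geom a `shell_geometry`.
#' @export
shell_diameter <- function(geom) {
  stopifnot(inherits(geom, "shell_geometry"))
  max(stats::dist(geom$surface))
}

#' Write a shell (optionally with charges) to XYZ format
#'
#' Surface atoms are written with element "C", the central atom with "X".
#' The comment line records h, k and the bond length; if `charges` is given
#' a fifth column with the per-atom charge is appended.
#'
#' @param geom a `shell_geometry`.
#' @param path output file path.
#' @param charges optional numeric vector, one charge per surface atom plus
#'   one for the central atom (length `n_surface + 1`).
#' @return `path`, invisibly.
#' @export
write_shell_xyz <- function(geom, path, charges = NULL) {
  stopifnot(inherits(geom, "shell_geometry"))
  n <- geom$n_surface
  if (!is.null(charges) && length(charges) != n + 1)
    stop("charges must have length n_surface + 1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(n + 1), con)
  writeLines(sprintf("GP(%d,%d) bond_length=%g A%s", geom$h, geom$k,
                     geom$bond_length,
                     if (is.null(charges)) "" else " charge_column=e"), con)
  coords <- rbind(geom$surface, geom$center)
  elem <- c(rep("C", n), "X")
  if (is.null(charges)) {
    writeLines(sprintf("%s %12.6f %12.6f %12.6f", elem,
                       coords[, 1], coords[, 2], coords[, 3]), con)
  } else {
    writeLines(sprintf("%s %12.6f %12.6f %12.6f %10.6f", elem,
                       coords[, 1], coords[, 2], coords[, 3], charges), con)
  }
  invisible(path)
}
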