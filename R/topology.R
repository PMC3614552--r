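## Random protein-like charge topologies on a shell geometry, and selection
## of descriptor-diverse topology sets.

#' Construct a discretized charge distribution
#'
#' A histogram over atomic partial charge used to draw protein-like random
#' charges for pseudo-protein surfaces.  Bins are `[bin_edges[i],
#' bin_edges[i+1])`; `weights` are the relative probabilities per bin.
#'
#' @param bin_edges strictly increasing numeric vector of bin edges, e.
#' @param weights non-negative numeric vector, one per bin; normalized to
#'   sum to 1.
#' @return an object of class `charge_distribution`.
#' @export
charge_distribution <- function(bin_edges, weights) {
  if (length(bin_edges) != length(weights) + 1)
    stop("need length(bin_edges) == length(weights) + 1")
  if (length(weights) < 1) stop("empty distribution")
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  if (any(weights < 0) || !all(is.finite(weights)))
    stop("weights must be finite and non-negative")
  s <- sum(weights)
  if (s <= 0) stop("weights sum to zero")
  structure(list(bin_edges = as.numeric(bin_edges),
                 weights = as.numeric(weights) / s),
            class = "charge_distribution")
}

#' Default protein-like surface charge distribution
#'
#' A calibratable stand-in for the empirical SASA-weighted distribution of
#' Amber-type partial charges on solvent-exposed atoms of globular proteins:
#' a mixture of 60% Normal(0, 0.10), 20% Normal(+0.35, 0.15) and 20%
#' Normal(-0.35, 0.15) (e), truncated to \[-1, 1\] e and discretized in
#' 0.02 e bins.  When charged structures are available,
#' [build_charge_histogram()] regenerates a faithful empirical distribution
#' instead.
#'
#' @return a `charge_distribution`.
#' @export
default_charge_distribution <- function() {
  edges <- seq(-1, 1, by = 0.02)
  mix <- function(x) {
    0.6 * stats::pnorm(x, 0, 0.10) +
      0.2 * stats::pnorm(x, 0.35, 0.15) +
      0.2 * stats::pnorm(x, -0.35, 0.15)
  }
  w <- diff(mix(edges))
  charge_distribution(edges, w)
}

#' SASA-weighted histogram of atomic charges from real structures
#'
#' Pools all atoms of the supplied structures and tallies their partial
#' charges into a histogram where each atom contributes weight proportional
#' to its solvent accessible surface area; buried atoms (SASA = 0)
#' contribute nothing.  This emulates how a surface charge distribution is
#' extracted from a reference set of globular protein crystal structures.
#'
#' @param structures list of `mol_structure` objects with charges assigned.
#' @param sasa_values list of per-atom SASA vectors (Angstrom^2), parallel
#'   to `structures`; computed with [sasa()] if omitted.
#' @param bin_width histogram bin width in e (default 0.02).
#' @return a `charge_distribution`.
#' @export
build_charge_histogram <- function(structures, sasa_values = NULL,
                                   bin_width = 0.02) {
  if (inherits(structures, "mol_structure")) structures <- list(structures)
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be positive")
  if (is.null(sasa_values)) sasa_values <- lapply(structures, sasa)
  if (is.numeric(sasa_values)) sasa_values <- list(sasa_values)
  q <- unlist(lapply(structures, function(s) s$atoms$charge))
  a <- unlist(sasa_values)
  if (length(q) != length(a))
    stop("SASA vectors do not match the structures' atom counts")
  if (anyNA(q)) stop("every atom needs an assigned charge")
  if (all(a == 0)) stop("no solvent-exposed atoms")
  lo <- floor(min(q) / bin_width) * bin_width
  hi <- ceiling(max(q) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  idx <- findInterval(q, edges, rightmost.closed = TRUE)
  w <- tabulate2(idx, a, length(edges) - 1)
  charge_distribution(edges, w)
}

#' Draw one charge from each bin of a distribution
#' @noRd
draw_charges <- function(dist, n) {
  i <- sample.int(length(dist$weights), n, replace = TRUE,
                  prob = dist$weights)
  stats::runif(n, dist$bin_edges[i], dist$bin_edges[i + 1])
}

#' Sample a random protein-like charge topology
#'
#' Draws one charge per surface atom independently from `dist` (uniform
#' within the selected bin), then adds the uniform shift
#' `(q_target - sum(raw)) / n_surface` to every surface charge so the net
#' charge hits `q_target` exactly.  The central atom starts neutral; use
#' [set_central_charge()] to change the net charge without touching the
#' surface pattern.
#'
#' @param geom a `shell_geometry`.
#' @param dist a `charge_distribution`.
#' @param q_target target net charge, e.
#' @param seed integer seed; the draw is fully deterministic given the seed.
#' @param label optional topology label (default derived from the seed).
#' @return an object of class `topology`: list with `geometry`,
#'   `surface_charges`, `central_charge`, `q` (net charge, e), `p` (dipole
#'   magnitude about the shell center, e*Angstrom), `label`, `seed`.
#' @export
sample_topology <- function(geom, dist, q_target, seed,
                            label = sprintf("PP_seed%d", seed)) {
  stopifnot(inherits(geom, "shell_geometry"),
            inherits(dist, "charge_distribution"))
  if (!is.finite(q_target)) stop("q_target must be finite")
  seed <- as.integer(seed)
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  qs <- draw_charges(dist, geom$n_surface)
  qs <- qs + (q_target - sum(qs)) / geom$n_surface
  new_topology(geom, qs, 0, label = label, seed = seed)
}

save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

new_topology <- function(geom, surface_charges, central_charge,
                         label = "", seed = NA_integer_) {
  top <- structure(list(
    geometry = geom,
    surface_charges = as.numeric(surface_charges),
    central_charge = as.numeric(central_charge),
    q = sum(surface_charges) + central_charge,
    p = NA_real_,
    label = label,
    seed = seed
  ), class = "topology")
  top$p <- dipole_moment(top)
  top
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf(
    "topology %s on GP(%d,%d): q = %.4g e, p = %.4g eA, central charge %.4g e\n",
    x$label, x$geometry$h, x$geometry$k, x$q, x$p, x$central_charge))
  invisible(x)
}

#' Dipole moment of a charge topology
#'
#' Magnitude of `sum_i q_i * (r_i - origin)` over surface atoms plus the
#' central atom, in e*Angstrom.  The default origin is the shell center (the
#' geometric center of the surface atoms), so a central charge never
#' contributes and the dipole of a net-neutral topology is independent of
#' the origin.
#'
#' @param top a `topology`.
#' @param origin 3-vector, Angstrom; defaults to the shell center.
#' @return dipole magnitude, e*Angstrom.
#' @export
dipole_moment <- function(top, origin = NULL) {
  stopifnot(inherits(top, "topology"))
  if (is.null(origin)) origin <- top$geometry$center
  pos <- rbind(top$geometry$surface, top$geometry$center)
  qs <- c(top$surface_charges, top$central_charge)
  rel <- sweep(pos, 2, origin)
  sqrt(sum(colSums(rel * qs)^2))
}

#' Assign a charge to the central atom
#'
#' Returns a new topology whose central atom carries charge `qc`, shifting
#' the net charge by `qc - old_qc` while leaving every surface charge -- and
#' therefore every surface patch descriptor -- untouched.  Because the
#' central atom sits at the dipole origin, the dipole about the shell center
#' is unchanged too.  This is how families of topologies with identical
#' surface patterns but different net charges are built.
#'
#' @param top a `topology`.
#' @param qc new central charge, e.
#' @return a `topology`.
#' @export
set_central_charge <- function(top, qc) {
  stopifnot(inherits(top, "topology"))
  if (!is.finite(qc)) stop("qc must be finite")
  new_topology(top$geometry, top$surface_charges, qc,
               label = top$label, seed = top$seed)
}

#' Generate an ensemble of random charge topologies
#'
#' Draws `n` topologies with sequential sub-seeds `seed + 1, ..., seed + n`,
#' annotates each with its net charge, dipole moment and patch descriptors
#' (at `params`), and flags topologies whose dipole falls outside the
#' protein-like validation range \[0, 70\] e*Angstrom or whose net charge is
#' outside \[-10, 0\] e.
#'
#' @param geom a `shell_geometry`.
#' @param dist a `charge_distribution`.
#' @param n number of topologies.
#' @param q_target target net charge, e.
#' @param seed master integer seed.
#' @param params a `patch_params` for the descriptor annotation (default
#'   `patch_params()`: d_cut = 5 A, n = 0).
#' @return a list of `topology` objects (class `topology_ensemble`), each
#'   with elements `descriptors` (a `patch_profile`) and `in_range`
#'   (logical).  Use [as.data.frame()] for a summary table.
#' @export
generate_ensemble <- function(geom, dist, n, q_target, seed,
                              params = patch_params()) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  tops <- vector("list", n)
  for (i in seq_len(n)) {
    top <- sample_topology(geom, dist, q_target, seed = seed + i,
                           label = sprintf("PP%04d", i))
    top$descriptors <- summarize_patches(top, params)
    eps <- 1e-9
    top$in_range <- top$p >= -eps && top$p <= 70 + eps &&
      top$q >= -10 - eps && top$q <= eps
    tops[[i]] <- top
  }
  structure(tops, class = c("topology_ensemble", "list"))
}

#' @export
as.data.frame.topology_ensemble <- function(x, ...) {
  do.call(rbind, lapply(x, function(t) {
    d <- t$descriptors
    data.frame(label = t$label, seed = t$seed, q = t$q, p = t$p,
               mlssc = d$mlssc, mlsc = d$mlsc,
               hi_product = d$hi_product, lo_product = d$lo_product,
               in_range = isTRUE(t$in_range),
               stringsAsFactors = FALSE)
  }))
}

ensure_descriptors <- function(tops, params) {
  lapply(tops, function(t) {
    if (is.null(t$descriptors)) t$descriptors <- summarize_patches(t, params)
    t
  })
}

#' Select a descriptor-diverse topology set at fixed net charge and dipole
#'
#' From the candidates with net charge `q_target` and dipole within `p_tol`
#' of `p_target`, picks `k` topologies spread out in standardized
#' (mlssc, mlsc) space by greedy max-min (farthest point) selection, seeded
#' from the pair with the smallest and largest mlssc.  Ties are broken by
#' ascending label.  This reproduces the construction of a "varied surface
#' pattern" set: same net charge and dipole, maximal spread in hydrophobic
#' and charged patch character.
#'
#' @param cands list of `topology` objects (e.g. a `topology_ensemble`).
#' @param q_target required net charge, e (matched within 1e-6).
#' @param p_target,p_tol dipole target and tolerance, e*Angstrom.
#' @param k number of topologies to select (>= 2).
#' @param params `patch_params` used if candidates lack descriptors.
#' @return list of `k` selected `topology` objects, ordered by selection.
#' @export
select_varied_set <- function(cands, q_target, p_target, p_tol, k,
                              params = patch_params()) {
  if (k < 2) stop("k must be >= 2")
  cands <- ensure_descriptors(cands, params)
  ok <- vapply(cands, function(t) {
    abs(t$q - q_target) <= 1e-6 && abs(t$p - p_target) <= p_tol
  }, logical(1))
  elig <- cands[ok]
  if (length(elig) < k)
    stop(sprintf(
      "only %d candidates satisfy q = %g and |p - %g| <= %g; need %d",
      length(elig), q_target, p_target, p_tol, k))
  labs <- vapply(elig, function(t) t$label, character(1))
  ord <- order(labs)
  elig <- elig[ord]; labs <- labs[ord]
  m1 <- vapply(elig, function(t) t$descriptors$mlssc, numeric(1))
  m2 <- vapply(elig, function(t) t$descriptors$mlsc, numeric(1))
  z <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  X <- cbind(z(m1), z(m2))
  sel <- c(which.min(m1), which.max(m1))
  if (sel[1] == sel[2]) sel <- unique(c(sel[1], setdiff(seq_along(elig), sel[1])[1]))
  while (length(sel) < k) {
    rest <- setdiff(seq_along(elig), sel)
    dmin <- vapply(rest, function(i) {
      min(sqrt(rowSums((X[sel, , drop = FALSE] -
                        matrix(X[i, ], length(sel), 2, byrow = TRUE))^2)))
    }, numeric(1))
    # max-min; ties broken by ascending label (elig already label-sorted)
    sel <- c(sel, rest[which.max(dmin)])
  }
  elig[sel]
}

#' Select one topology per dipole bin at fixed net charge
#'
#' Filters the candidates to net charge `q_target`, then for each interval
#' in `p_bins` picks the topology whose dipole is closest to the bin
#' midpoint (ties by ascending label).  The result is ordered by ascending
#' dipole: a series that varies the dipole moment at constant net charge.
#'
#' @param cands list of `topology` objects.
#' @param q_target required net charge, e (matched within 1e-6).
#' @param p_bins list of 2-vectors `c(lo, hi)` (e*Angstrom); a candidate
#'   belongs to a bin when `lo <= p < hi`.
#' @return list of selected `topology` objects, ordered by dipole.
#' @export
select_dipole_series <- function(cands, q_target, p_bins) {
  if (is.matrix(p_bins)) p_bins <- split(p_bins, seq_len(nrow(p_bins)))
  okq <- vapply(cands, function(t) abs(t$q - q_target) <= 1e-6, logical(1))
  cq <- cands[okq]
  labs <- vapply(cq, function(t) t$label, character(1))
  ord <- order(labs); cq <- cq[ord]
  ps <- vapply(cq, function(t) t$p, numeric(1))
  sel <- integer(0)
  empty <- character(0)
  for (b in p_bins) {
    inb <- which(ps >= b[1] & ps < b[2])
    if (!length(inb)) {
      empty <- c(empty, sprintf("[%g, %g)", b[1], b[2]))
      next
    }
    mid <- (b[1] + b[2]) / 2
    sel <- c(sel, inb[which.min(abs(ps[inb] - mid))])
  }
  if (length(empty))
    stop("no candidate with q = ", q_target, " in bin(s): ",
         paste(empty, collapse = ", "))
  out <- cq[sel]
  out[order(vapply(out, function(t) t$p, numeric(1)))]
}

#' Write / read a topology as CSV plus JSON sidecar
#'
#' The CSV has columns `index, x, y, z, charge`; index 0 is the central
#' atom.  The sidecar `<path>.json` records q, p, label, seed and the shell
#' indices (h, k) and bond length so the topology can be reloaded.
#'
#' @param top a `topology`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, path) {
  stopifnot(inherits(top, "topology"))
  g <- top$geometry
  df <- data.frame(
    index = c(0L, seq_len(g$n_surface)),
    x = c(g$center[1], g$surface[, 1]),
    y = c(g$center[2], g$surface[, 2]),
    z = c(g$center[3], g$surface[, 3]),
    charge = c(top$central_charge, top$surface_charges))
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(q = top$q, p = top$p, label = top$label,
               seed = if (is.na(top$seed)) NULL else top$seed,
               h = g$h, k = g$k, bond_length = g$bond_length)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_topology
#' @param geometry optional `shell_geometry` to attach; if omitted the
#'   geometry is rebuilt from the sidecar's (h, k, bond_length) when
#'   available, else reconstructed from the stored coordinates.
#' @export
read_topology <- function(path, geometry = NULL) {
  df <- utils::read.csv(path)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else list()
  ctr <- df$index == 0
  if (is.null(geometry)) {
    if (!is.null(side$h)) {
      geometry <- build_goldberg_shell(side$h, side$k, side$bond_length)
    } else {
      surf <- as.matrix(df[!ctr, c("x", "y", "z")])
      geometry <- structure(list(
        surface = surf, center = colMeans(surf),
        bond_length = NA_real_, h = NA_integer_, k = NA_integer_,
        n_surface = nrow(surf), bonds = NULL, n_pentagons = NA_integer_),
        class = "shell_geometry")
    }
  }
  ordr <- order(df$index[!ctr])
  new_topology(geometry, df$charge[!ctr][ordr], df$charge[ctr],
               label = if (is.null(side$label)) "" else side$label,
               seed = if (is.null(side$seed)) NA_integer_ else side$seed)
}
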