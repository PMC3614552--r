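## Formal-charge model at pH 7 and the charge/dipole descriptors for real
## structures.  This is the self-contained default charging scheme; PQR
## input with force-field partial charges is the faithful alternative and
## bypasses it.

# residue -> (formal side-chain charge, preferred charge-site atom) at pH 7
.charge_sites <- list(
  ASP = list(q = -1, site = "CG"),   # carboxylate carbon
  GLU = list(q = -1, site = "CD"),
  LYS = list(q = +1, site = "NZ"),   # terminal amine nitrogen
  ARG = list(q = +1, site = "CZ")    # guanidinium carbon
)

.standard_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

.backbone_names <- c("N", "CA", "C", "O", "OXT",
                     "H", "H1", "H2", "H3", "HA", "HA2", "HA3", "HN")

is_side_chain <- function(name) !(name %in% .backbone_names)

# index (within rows) of the atom carrying a side-chain charge of the given
# residue type: the named site, else the side-chain atom nearest the
# side-chain centroid, else CB, else CA
charge_site_index <- function(res_atoms, site) {
  i <- which(res_atoms$name == site)
  if (length(i)) return(i[1])
  sc <- which(is_side_chain(res_atoms$name))
  if (length(sc)) {
    ctr <- colMeans(res_atoms[sc, c("x", "y", "z"), drop = FALSE])
    d2 <- (res_atoms$x[sc] - ctr[1])^2 + (res_atoms$y[sc] - ctr[2])^2 +
      (res_atoms$z[sc] - ctr[3])^2
    return(sc[which.min(d2)])
  }
  i <- which(res_atoms$name == "CB")
  if (length(i)) return(i[1])
  i <- which(res_atoms$name == "CA")
  if (length(i)) return(i[1])
  1L
}

#' Assign formal charges at pH 7
#'
#' The self-contained charging model: aspartate and glutamate side chains
#' carry -1 (placed on the carboxylate carbon), lysine +1 (terminal
#' nitrogen), arginine +1 (guanidinium carbon) and histidine 0; each chain's
#' N-terminus carries +1 (on N) and its C-terminus -1 (on OXT, else C).
#' All other atoms are neutral.  When a preferred charge-site atom is
#' missing the charge falls back to the side-chain atom nearest the
#' side-chain centroid, then CB, then CA.  Unknown residue names give a
#' warning and charge 0.  Structures read from PQR keep their file charges
#' and bypass this model.
#'
#' Only pH 7 is supported: the model is formal-charge bookkeeping, not pKa
#' prediction, which is exactly the arithmetic behind charge-flip mutation
#' scans (a full charge flip always changes the net charge by 2).
#'
#' @param s a `mol_structure`.
#' @param pH solution pH; must be 7.
#' @param cap_termini if TRUE the chain termini are treated as capped and
#'   carry no charge.
#' @return a `mol_structure` with the `charge` column filled.
#' @export
assign_formal_charges <- function(s, pH = 7, cap_termini = FALSE) {
  stopifnot(inherits(s, "mol_structure"))
  if (pH != 7)
    stop("only pH 7 is supported by the formal-charge model")
  if (identical(s$source_format, "PQR") && !anyNA(s$atoms$charge))
    return(s)  # PQR charges are authoritative
  a <- s$atoms
  a$charge <- 0
  key <- residue_key(a)
  groups <- split(seq_len(nrow(a)), factor(key, levels = unique(key)))
  unknown <- character(0)
  for (idx in groups) {
    resname <- a$resname[idx[1]]
    if (!(resname %in% .standard_residues)) {
      unknown <- c(unknown, resname)
      next
    }
    rule <- .charge_sites[[resname]]
    if (is.null(rule)) next
    site <- charge_site_index(a[idx, , drop = FALSE], rule$site)
    a$charge[idx[site]] <- a$charge[idx[site]] + rule$q
  }
  if (length(unknown))
    warning("unknown residue(s) left neutral: ",
            paste(unique(unknown), collapse = ", "))
  if (!cap_termini) {
    for (ch in unique(a$chain)) {
      rows <- which(a$chain == ch)
      kk <- key[rows]
      first <- rows[kk == kk[1]]
      last <- rows[kk == kk[length(kk)]]
      nt <- first[match("N", a$name[first])]
      if (is.na(nt)) nt <- first[match("CA", a$name[first])]
      if (is.na(nt)) nt <- first[1]
      a$charge[nt] <- a$charge[nt] + 1
      ct <- last[match("OXT", a$name[last])]
      if (is.na(ct)) ct <- last[match("C", a$name[last])]
      if (is.na(ct)) ct <- last[length(last)]
      a$charge[ct] <- a$charge[ct] - 1
    }
  }
  s$atoms <- a
  s
}

#' Net charge of a structure
#'
#' Sum of the per-atom charges, e.  For PQR input this is exactly the column
#' sum of the file's charge field.
#'
#' @param s a `mol_structure` with charges assigned.
#' @return net charge, e.
#' @export
net_charge <- function(s) {
  stopifnot(inherits(s, "mol_structure"))
  q <- s$atoms$charge
  if (all(is.na(q))) stop("charges not assigned; see assign_formal_charges()")
  sum(q, na.rm = TRUE)
}

#' Dipole moment of a structure
#'
#' Magnitude of `sum_i q_i (r_i - r_cm)` in e*Angstrom, with `r_cm` the
#' mass-weighted center (standard atomic masses, unit mass for unknown
#' elements).  For a net-neutral structure the value is independent of the
#' reference point; for charged species the center-of-mass convention is
#' used throughout the package.
#'
#' @param s a `mol_structure` with charges assigned.
#' @return dipole magnitude, e*Angstrom.
#' @export
structure_dipole <- function(s) {
  stopifnot(inherits(s, "mol_structure"))
  a <- s$atoms
  q <- a$charge
  if (all(is.na(q))) stop("charges not assigned; see assign_formal_charges()")
  q[is.na(q)] <- 0
  m <- element_mass(a$element)
  pos <- cbind(a$x, a$y, a$z)
  rcm <- colSums(pos * m) / sum(m)
  rel <- sweep(pos, 2, rcm)
  sqrt(sum(colSums(rel * q)^2))
}
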