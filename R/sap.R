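## Spatial aggregation propensity (SAP): a SASA- and hydrophobicity-weighted
## score for hydrophobic surface patches, plus the summary descriptors
## SAPmax (largest per-residue value) and nSAP (positive-SAP sum normalized
## by total SASA).

#' Black-Mould residue hydrophobicity scale, shifted so H(GLY) = 0
#'
#' The normalized (0..1) Black-Mould hydrophobicities with 0.501 (the
#' glycine value) subtracted, the convention used by SAP-type scores so
#' residues more hydrophobic than glycine contribute positively.  Shipped as
#' an editable table.
#'
#' @return named numeric vector over the 20 standard residues.
#' @export
hydrophobicity_scale <- function() {
  h <- c(ALA = 0.616, ARG = 0.000, ASN = 0.236, ASP = 0.028, CYS = 0.680,
         GLN = 0.251, GLU = 0.043, GLY = 0.501, HIS = 0.165, ILE = 0.943,
         LEU = 0.943, LYS = 0.283, MET = 0.738, PHE = 1.000, PRO = 0.711,
         SER = 0.359, THR = 0.450, TRP = 0.878, TYR = 0.880, VAL = 0.825)
  h - h[["GLY"]]
}

#' Fully-exposed side-chain SASA reference values
#'
#' Maximum side-chain solvent accessible surface areas (Angstrom^2) of each
#' residue type in an extended Gly-X-Gly context, used to normalize observed
#' side-chain exposures to a 0..1 fraction.  Glycine, which has no heavy
#' side-chain atoms, is assigned 1 to keep the ratio defined (its
#' hydrophobicity weight is 0, so it never contributes).  Shipped as an
#' editable table.
#'
#' @return named numeric vector over the 20 standard residues.
#' @export
max_sidechain_sasa <- function() {
  c(ALA = 67, ARG = 196, ASN = 113, ASP = 106, CYS = 104,
    GLN = 144, GLU = 138, GLY = 1, HIS = 151, ILE = 140,
    LEU = 137, LYS = 167, MET = 160, PHE = 175, PRO = 105,
    SER = 80, THR = 102, TRP = 217, TYR = 187, VAL = 117)
}

#' Spatial aggregation propensity profile
#'
#' For every atom i the atomic SAP is the sum, over side-chain atoms j
#' within `R` of atom i (own residue included), of
#' `(SASA_j / maxSASA_sidechain(res_j)) * H(res_j)`, where the reference
#' exposures come from [max_sidechain_sasa()] and H is the Black-Mould
#' hydrophobicity shifted so H(GLY) = 0.  The per-residue SAP is the mean of
#' the atomic values over the residue's atoms.  Residues missing from the
#' reference tables are excluded from the sums with a warning.
#'
#' @param s a `mol_structure`.
#' @param R patch radius, Angstrom (default 5, the radius typically used
#'   for SAP scores).
#' @param sasa_atoms optional per-atom SASA vector (computed with [sasa()]
#'   defaults if omitted).
#' @param probe_radius,n_points passed to [sasa()] when `sasa_atoms` is
#'   omitted.
#' @return a data.frame of class `sap_profile` with one row per residue:
#'   `chain`, `resnum`, `icode`, `resname`, `sap` (dimensionless) and
#'   `sasa_res` (summed atomic SASA of the residue, Angstrom^2).
#' @export
sap_profile <- function(s, R = 5.0, sasa_atoms = NULL,
                        probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(s, "mol_structure"))
  if (R <= 0) stop("R must be positive")
  a <- s$atoms
  if (is.null(sasa_atoms))
    sasa_atoms <- sasa(s, probe_radius = probe_radius, n_points = n_points)
  if (length(sasa_atoms) != nrow(a))
    stop("sasa_atoms does not match the atom count")
  hyd <- hydrophobicity_scale()
  mx <- max_sidechain_sasa()
  known <- a$resname %in% names(hyd)
  if (any(!known))
    warning("residue(s) missing from the SAP reference tables excluded: ",
            paste(unique(a$resname[!known]), collapse = ", "))
  side <- is_side_chain(a$name) & known
  pos <- cbind(a$x, a$y, a$z)
  # per-side-chain-atom contribution
  contrib <- numeric(nrow(a))
  contrib[side] <- sasa_atoms[side] / mx[a$resname[side]] *
    hyd[a$resname[side]]
  js <- which(side)
  sap_atom <- numeric(nrow(a))
  if (length(js)) {
    d2 <- outer(rowSums(pos^2), rowSums(pos[js, , drop = FALSE]^2), "+") -
      2 * pos %*% t(pos[js, , drop = FALSE])
    within <- d2 < R^2
    sap_atom <- as.numeric(within %*% contrib[js])
  }
  key <- residue_key(a)
  keyf <- factor(key, levels = unique(key))
  res <- do.call(rbind, lapply(split(seq_len(nrow(a)), keyf), function(idx) {
    data.frame(chain = a$chain[idx[1]], resnum = a$resnum[idx[1]],
               icode = a$icode[idx[1]], resname = a$resname[idx[1]],
               sap = mean(sap_atom[idx]),
               sasa_res = sum(sasa_atoms[idx]),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  class(res) <- c("sap_profile", "data.frame")
  res
}

#' SAPmax: the largest per-residue SAP value
#'
#' @param profile a `sap_profile`.
#' @return scalar (possibly negative when no residue scores above 0).
#' @export
sap_max <- function(profile) {
  stopifnot(inherits(profile, "sap_profile"))
  if (!nrow(profile)) stop("empty SAP profile")
  max(profile$sap)
}

#' nSAP: positive-SAP sum normalized by total SASA
#'
#' `sum(SAP_res[SAP_res > 0]) / sum(SASA_res)` over all residues, in
#' 1/Angstrom^2.  The normalization by the total residue SASA makes the
#' score comparable across proteins of different size (the unnormalized
#' positive-SAP sum grows with surface area).
#'
#' @param profile a `sap_profile`.
#' @return scalar, 1/Angstrom^2.
#' @export
nsap <- function(profile) {
  stopifnot(inherits(profile, "sap_profile"))
  if (!nrow(profile)) stop("empty SAP profile")
  tot <- sum(profile$sasa_res)
  if (tot <= 0) stop("total SASA is zero")
  sum(profile$sap[profile$sap > 0]) / tot
}

#' One-row descriptor record for a structure
#'
#' Computes the full descriptor set used by the solubility models: net
#' charge, dipole moment, total SASA, SAPmax and nSAP.
#'
#' @param s a `mol_structure`; formal charges are assigned when unset.
#' @param id record identifier.
#' @param sap_radius SAP patch radius, Angstrom.
#' @param probe_radius,n_points passed to [sasa()].
#' @return one-row data.frame with columns `id`, `q`, `p`, `total_sasa`,
#'   `sap_max`, `nsap`.
#' @export
descriptor_record <- function(s, id = "protein", sap_radius = 5.0,
                              probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(s, "mol_structure"))
  if (anyNA(s$atoms$charge)) s <- assign_formal_charges(s)
  sa <- sasa(s, probe_radius = probe_radius, n_points = n_points)
  prof <- sap_profile(s, R = sap_radius, sasa_atoms = sa)
  out <- data.frame(id = id, q = net_charge(s), p = structure_dipole(s),
                    total_sasa = sum(sa), sap_max = sap_max(prof),
                    nsap = nsap(prof), stringsAsFactors = FALSE)
  stopifnot(all(is.finite(unlist(out[-1]))))
  out
}
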