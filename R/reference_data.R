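## Published benchmark tables shipped with the package.  These are the
## numeric anchors the package is validated against: a reference set of
## pseudo-protein topologies with simulated association free energies, a
## single-mutation dipole-reduction scan over 22 cytokines and 3 IgG
## antibodies, and fitted linear solubility models for two literature data
## sets (18 monomeric E. coli K12 proteins, setA, and the RNase SA wild type
## plus 19 point mutants, setB).

ref_csv <- function(name) {
  path <- system.file("extdata", name, package = "colloidkit")
  if (path == "") path <- file.path("inst", "extdata", name)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference pseudo-protein topology table
#'
#' Properties of 19 reference pseudo-protein topologies organised in three
#' sets: `varHP` (12 topologies, identical net charge -2 e and dipole about
#' 18 eA, varying patch descriptors), `varQ` (one surface pattern with
#' central charges 0/-4/-8 e giving net charges -2/-6/-10 e) and `varD`
#' (net charge -2 e, dipoles from 0.65 to 72 eA).  `dg_min` is the
#' simulated association free energy (kJ/mol, the PMF minimum closest to
#' contact) with its bootstrap `error`; these values require explicit-water
#' molecular dynamics and are reference inputs here, not quantities the
#' package recomputes.
#'
#' @return data.frame with columns `set`, `name`, `q` (e), `p` (eA),
#'   `lssc_min` (e^2), `lsc_min` (e), `dg_min` (kJ/mol), `error` (kJ/mol).
#' @export
reference_pseudo_proteins <- function() ref_csv("pseudo_proteins.csv")

#' Reference single-mutation dipole-reduction scan
#'
#' For 22 cytokines and 3 IgG antibodies (PDB identifiers), the single
#' charge-flip mutation giving the largest dipole reduction, with wild-type
#' net charge `q0`, charge change `dq`, wild-type dipole `p0` and dipole
#' change `dp` (force-field charges at pH 7; in three cases -- 1HUL, 1IGT,
#' 1IGY -- the reported |dq| differs from the formal-charge value of 2).
#'
#' @return data.frame with columns `id`, `class`, `mutation`, `q0`, `dq`,
#'   `p0`, `dp`.
#' @export
reference_mutation_effects <- function() ref_csv("mutation_effects.csv")

#' Reference linear solubility models
#'
#' Fitted coefficients of `sol = c1*desc + c2*q + c3` for the two literature
#' solubility sets, for descriptors dipole moment (`p`), `nsap` and
#' `sapmax`, with `r2` and the model `p_value`; rows with descriptor
#' `ccsol` carry only the r2 of a sequence-based web predictor for
#' comparison.
#'
#' @return data.frame with columns `set`, `descriptor`, `c1`, `c2`, `c3`,
#'   `r2`, `p_value`.
#' @export
reference_solubility_models <- function() ref_csv("solubility_models.csv")
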