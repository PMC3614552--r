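## Single charge-flip mutation scan: enumerate candidate mutations of
## charged residues to the opposite charge, compute the net-charge and
## dipole changes, and pick the mutation with the largest dipole reduction.
## Under the formal-charge model every charge flip changes the net charge by
## exactly 2 e, so the dipole change is the quantity that discriminates.

.one_letter <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                 GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                 LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                 SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.three_letter <- stats::setNames(names(.one_letter), .one_letter)

# the four charge-flip swaps used by the scan; HIS is neutral at pH 7 and
# never mutated
.flip_partner <- c(ARG = "ASP", LYS = "ASP", ASP = "ARG", GLU = "ARG")

#' Enumerate candidate charge-flip mutations
#'
#' A stabilizing flip should increase the magnitude of the net charge, so
#' the direction is fixed by the wild-type net charge: if `q0 < 0` every ARG
#' and LYS is a candidate for mutation to ASP (making the protein more
#' negative); if `q0 >= 0` every ASP and GLU is a candidate for mutation to
#' ARG (more positive).  Either direction changes |q| by 2 e while offering
#' a range of dipole changes.
#'
#' @param s a `mol_structure`; formal charges are assigned when unset.
#' @param min_sasa optional minimum side-chain SASA (Angstrom^2) a residue
#'   must expose to be a candidate (surface filter, off by default).
#' @return data.frame with columns `chain`, `resnum`, `icode`, `wt`, `mut`
#'   (3-letter codes) and `label` (e.g. "R134D"); zero rows when the
#'   structure has no charged residues of the relevant types.
#' @export
enumerate_charge_flips <- function(s, min_sasa = NULL) {
  stopifnot(inherits(s, "mol_structure"))
  if (anyNA(s$atoms$charge)) s <- assign_formal_charges(s)
  a <- s$atoms
  q0 <- net_charge(s)
  wt_types <- if (q0 < 0) c("ARG", "LYS") else c("ASP", "GLU")
  key <- residue_key(a)
  keyf <- factor(key, levels = unique(key))
  first <- !duplicated(key)
  res <- data.frame(chain = a$chain[first], resnum = a$resnum[first],
                    icode = a$icode[first], wt = a$resname[first],
                    stringsAsFactors = FALSE)
  res <- res[res$wt %in% wt_types, , drop = FALSE]
  if (!is.null(min_sasa) && nrow(res)) {
    sa <- sasa(s)
    sc_sasa <- vapply(split(seq_len(nrow(a)), keyf), function(idx) {
      sum(sa[idx][is_side_chain(a$name[idx])])
    }, numeric(1))
    names(sc_sasa) <- unique(key)
    res <- res[sc_sasa[paste(res$chain, res$resnum, res$icode,
                             sep = "|")] >= min_sasa, , drop = FALSE]
  }
  if (!nrow(res))
    return(data.frame(chain = character(0), resnum = integer(0),
                      icode = character(0), wt = character(0),
                      mut = character(0), label = character(0),
                      stringsAsFactors = FALSE))
  res$mut <- .flip_partner[res$wt]
  res$label <- paste0(.one_letter[res$wt], res$resnum, .one_letter[res$mut])
  rownames(res) <- NULL
  res
}

# locate a residue by number (and optionally chain); returns atom indices
find_residue <- function(a, resnum, chain = NULL) {
  sel <- a$resnum == resnum
  if (!is.null(chain) && !is.na(chain)) sel <- sel & a$chain == chain
  which(sel)
}

#' Effect of one charge-flip mutation on net charge and dipole
#'
#' Models the mutant as the wild-type structure with the residue's formal
#' charge site sign-flipped in place: the wild-type charge is removed from
#' its site and the opposite charge placed at the mutant type's preferred
#' site rule applied to the existing atoms (positions are never rebuilt --
#' the dipole change of a charge flip is a charge-redistribution effect, and
#' the atom masses are unchanged so the mass center stays put).
#'
#' @param s a `mol_structure`; formal charges are assigned when unset.
#' @param mutation label like "R134D" (one-letter wild type, residue
#'   number, one-letter mutant), or a single row of
#'   [enumerate_charge_flips()] output.
#' @param chain chain identifier, needed only when residue numbers repeat
#'   across chains.
#' @param id structure identifier carried into the record.
#' @param class protein class label ("cytokine", "antibody" or "other").
#' @return one-row data.frame of class `mutation_effects` with columns
#'   `id`, `mutation`, `class`, `q0`, `dq`, `p0`, `dp`.
#' @export
mutation_effect <- function(s, mutation, chain = NULL, id = "protein",
                            class = "other") {
  stopifnot(inherits(s, "mol_structure"))
  if (anyNA(s$atoms$charge)) s <- assign_formal_charges(s)
  if (is.data.frame(mutation)) {
    chain <- mutation$chain[1]
    label <- mutation$label[1]
  } else label <- mutation
  m <- regmatches(label, regexec("^([A-Z])([0-9]+)([A-Z])$", label))[[1]]
  if (length(m) != 4) stop("cannot parse mutation label: ", label)
  wt3 <- .three_letter[m[2]]
  mut3 <- .three_letter[m[4]]
  resnum <- as.integer(m[3])
  if (is.na(wt3) || is.na(mut3)) stop("unknown residue code in: ", label)
  if (!(wt3 %in% names(.charge_sites)) || !(mut3 %in% names(.charge_sites)))
    stop("mutation must flip between charged residue types: ", label)

  a <- s$atoms
  idx <- find_residue(a, resnum, chain)
  if (!length(idx)) stop("residue ", resnum, " not found")
  if (length(unique(a$chain[idx])) > 1)
    stop("residue number ", resnum, " is ambiguous; give a chain")
  if (a$resname[idx[1]] != wt3)
    stop(sprintf("residue %d is %s, not %s", resnum, a$resname[idx[1]], wt3))

  q0 <- net_charge(s)
  p0 <- structure_dipole(s)
  res_atoms <- a[idx, , drop = FALSE]
  old_site <- idx[charge_site_index(res_atoms, .charge_sites[[wt3]]$site)]
  new_site <- idx[charge_site_index(res_atoms, .charge_sites[[mut3]]$site)]
  a$charge[old_site] <- a$charge[old_site] - .charge_sites[[wt3]]$q
  a$charge[new_site] <- a$charge[new_site] + .charge_sites[[mut3]]$q
  mut <- s
  mut$atoms <- a
  out <- data.frame(id = id, mutation = label, class = class,
                    q0 = q0, dq = net_charge(mut) - q0,
                    p0 = p0, dp = structure_dipole(mut) - p0,
                    stringsAsFactors = FALSE)
  class(out) <- c("mutation_effects", "data.frame")
  out
}

#' Scan all candidate charge flips of a structure
#'
#' Convenience wrapper: [enumerate_charge_flips()] then [mutation_effect()]
#' per candidate.
#'
#' @inheritParams enumerate_charge_flips
#' @inheritParams mutation_effect
#' @return `mutation_effects` data.frame, one row per candidate.
#' @export
mutation_scan <- function(s, id = "protein", class = "other",
                          min_sasa = NULL) {
  if (anyNA(s$atoms$charge)) s <- assign_formal_charges(s)
  cands <- enumerate_charge_flips(s, min_sasa = min_sasa)
  if (!nrow(cands)) {
    out <- data.frame(id = character(0), mutation = character(0),
                      class = character(0), q0 = numeric(0), dq = numeric(0),
                      p0 = numeric(0), dp = numeric(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("mutation_effects", "data.frame")
    return(out)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(cands)), function(i) {
    mutation_effect(s, cands[i, , drop = FALSE], id = id, class = class)
  }))
  class(out) <- c("mutation_effects", "data.frame")
  out
}

#' Best dipole-reducing mutation
#'
#' The candidate with the most negative dipole change; ties are broken by
#' the lowest residue number.
#'
#' @param effects a `mutation_effects` data.frame (>= 1 row).
#' @return the selected row.
#' @export
best_mutation <- function(effects) {
  if (!is.data.frame(effects) || !nrow(effects))
    stop("empty mutation-effect table")
  resnum <- as.integer(sub("^[A-Z]([0-9]+)[A-Z]$", "\\1", effects$mutation))
  ord <- order(effects$dp, resnum)
  effects[ord[1], , drop = FALSE]
}

# round half away from zero (the convention for reported integer averages;
# base round() would take 114.5 to 114)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Aggregate mutation effects per protein class
#'
#' Per class: the mean absolute dipole change (rounded half away from zero
#' to integer e*Angstrom), the maximum absolute dipole and net-charge
#' changes and the class size; plus the overall maximum dipole reduction.
#'
#' @param effects a `mutation_effects` data.frame with a `class` column.
#' @return list with `per_class` (data.frame: `class`, `n`, `mean_abs_dp`,
#'   `mean_abs_dp_raw`, `max_abs_dp`, `max_abs_dq`) and `max_reduction`
#'   (largest dipole reduction over all records, e*Angstrom, positive).
#' @export
summarize_effects <- function(effects) {
  if (!is.data.frame(effects) || !nrow(effects))
    stop("empty mutation-effect table")
  if (is.null(effects$class)) stop("records carry no class label")
  per <- do.call(rbind, lapply(split(effects, effects$class), function(g) {
    data.frame(class = g$class[1], n = nrow(g),
               mean_abs_dp = round_half_away(mean(abs(g$dp))),
               mean_abs_dp_raw = mean(abs(g$dp)),
               max_abs_dp = max(abs(g$dp)),
               max_abs_dq = max(abs(g$dq)),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  red <- -effects$dp[effects$dp < 0]
  list(per_class = per,
       max_reduction = if (length(red)) max(red) else 0)
}
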