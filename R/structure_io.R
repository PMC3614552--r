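## Molecular structures: a light atom-table container plus PDB/PQR readers
## and writers.  Coordinates in Angstrom, charges in e, radii in Angstrom.

# van der Waals radii by element (Angstrom); used when the input carries none
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

# standard atomic masses; unit mass for unknown elements
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974)

element_radius <- function(element) {
  r <- .vdw_radii[element]
  r[is.na(r)] <- 1.70
  unname(r)
}

element_mass <- function(element) {
  m <- .atomic_masses[element]
  m[is.na(m)] <- 1.0
  unname(m)
}

# derive the element from an atom name ("CA" -> C, "1HB" -> H, "NZ" -> N)
element_from_name <- function(name) {
  el <- sub("^[0-9']*", "", trimws(name))
  el <- substr(el, 1, 1)
  toupper(el)
}

#' Construct a molecular structure from an atom table
#'
#' The canonical container for real (or toy) protein structures: one row per
#' atom with identity, residue hierarchy, coordinates, radius and optional
#' partial charge.  Residues are grouped by (chain, residue number,
#' insertion code).
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resnum`, `icode`, `chain`, `x`, `y`, `z`, `radius`,
#'   `charge` (NA when unset).  Missing `element`/`radius` are filled from
#'   the atom name / element tables; a missing `icode` column defaults to
#'   `""`.
#' @param source_format one of "PDB", "PQR" or "MODEL" (built in code).
#' @return an object of class `mol_structure`.
#' @export
mol_structure <- function(atoms, source_format = "MODEL") {
  need <- c("serial", "name", "resname", "resnum", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (!nrow(atoms)) stop("empty atom table")
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$element) || anyNA(atoms$element))
    atoms$element <- element_from_name(atoms$name)
  if (is.null(atoms$radius)) atoms$radius <- element_radius(atoms$element)
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  if (any(!is.na(atoms$radius) & atoms$radius <= 0))
    stop("radii must be positive when set")
  atoms$resname <- toupper(trimws(atoms$resname))
  atoms$name <- trimws(atoms$name)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source_format = source_format),
            class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  a <- x$atoms
  nres <- nrow(unique(a[, c("chain", "resnum", "icode")]))
  cat(sprintf("mol_structure (%s): %d atoms, %d residues, %d chain(s)\n",
              x$source_format, nrow(a), nres, length(unique(a$chain))))
  if (!anyNA(a$charge))
    cat(sprintf("  net charge %.3f e\n", sum(a$charge)))
  invisible(x)
}

# residue grouping key, contiguous per (chain, resnum, icode)
residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resnum, atoms$icode, sep = "|")
}

#' Read a protein structure from a PDB file
#'
#' Parses `ATOM` records of the first model only.  Hetero groups and waters
#' are excluded unless `hetero = TRUE`.  For alternate locations the highest
#' occupancy wins, ties going to altLoc `'A'`.  Charges are left unset;
#' radii are filled from the element.
#'
#' @param path PDB file.
#' @param hetero keep HETATM records (waters are always dropped)?
#' @return a `mol_structure`.
#' @export
read_pdb <- function(path, hetero = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  # first model only
  mstart <- grep("^MODEL", lines)
  if (length(mstart) >= 1) {
    mend <- grep("^ENDMDL", lines)
    end <- if (length(mend)) mend[1] else length(lines)
    lines <- lines[seq(mstart[1], end)]
  }
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | (hetero & rec == "HETATM")
  lines <- lines[keep]
  lnum <- which(keep)
  if (!length(lines)) stop("no ATOM records in ", path)

  f <- function(a, b) trimws(substr(lines, a, b))
  num <- function(a, b, what) {
    v <- suppressWarnings(as.numeric(f(a, b)))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("malformed %s in %s at line %d", what, path, lnum[bad[1]]))
    v
  }
  atoms <- data.frame(
    serial = suppressWarnings(as.integer(f(7, 11))),
    name = f(13, 16),
    altloc = f(17, 17),
    resname = f(18, 20),
    chain = f(22, 22),
    resnum = as.integer(num(23, 26, "residue number")),
    icode = f(27, 27),
    x = num(31, 38, "x coordinate"),
    y = num(39, 46, "y coordinate"),
    z = num(47, 54, "z coordinate"),
    occupancy = suppressWarnings(as.numeric(f(55, 60))),
    element = f(77, 78),
    stringsAsFactors = FALSE)
  atoms$occupancy[!is.finite(atoms$occupancy)] <- 1
  atoms <- atoms[atoms$resname != "HOH", , drop = FALSE]
  if (!nrow(atoms)) stop("no ATOM records in ", path)
  blank <- atoms$element == ""
  atoms$element[blank] <- element_from_name(atoms$name[blank])

  # altLoc policy: highest occupancy, ties -> 'A' (then first seen)
  if (any(atoms$altloc != "")) {
    key <- paste(residue_key(atoms), atoms$name)
    pick <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
      if (length(i) == 1) return(i)
      o <- atoms$occupancy[i]
      i <- i[o == max(o)]
      if (length(i) > 1 && any(atoms$altloc[i] == "A"))
        i <- i[atoms$altloc[i] == "A"]
      i[1]
    }), use.names = FALSE)
    atoms <- atoms[sort(pick), , drop = FALSE]
  }
  atoms$altloc <- NULL
  atoms$occupancy <- NULL
  atoms$radius <- element_radius(atoms$element)
  atoms$charge <- NA_real_
  mol_structure(atoms, source_format = "PDB")
}

#' Read a protein structure from a PQR file
#'
#' PQR is whitespace-separated PDB-like text whose final two numeric fields
#' are the per-atom partial charge (e) and radius (Angstrom).  Both layouts
#' with and without a chain identifier are accepted.
#'
#' @param path PQR file.
#' @return a `mol_structure` with charges and radii set.
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lnum <- which(grepl("^(ATOM|HETATM)", lines))
  lines <- lines[lnum]
  if (!length(lines)) stop("no ATOM records in ", path)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  n <- length(toks)
  parse_row <- function(tk, ln) {
    if (length(tk) < 10)
      stop(sprintf("malformed PQR record in %s at line %d", path, ln))
    has_chain <- length(tk) >= 11 && is.na(suppressWarnings(as.numeric(tk[5])))
    o <- if (has_chain) 1L else 0L
    vals <- suppressWarnings(as.numeric(tk[(5 + o):(10 + o)]))
    if (anyNA(vals))
      stop(sprintf("malformed PQR record in %s at line %d", path, ln))
    list(serial = suppressWarnings(as.integer(tk[2])), name = tk[3],
         resname = tk[4], chain = if (has_chain) tk[5] else "A",
         resnum = as.integer(vals[1]), x = vals[2], y = vals[3],
         z = vals[4], charge = vals[5], radius = vals[6])
  }
  rows <- mapply(parse_row, toks, lnum, SIMPLIFY = FALSE)
  atoms <- data.frame(
    serial = vapply(rows, `[[`, integer(1), "serial"),
    name = vapply(rows, `[[`, character(1), "name"),
    resname = vapply(rows, `[[`, character(1), "resname"),
    chain = vapply(rows, `[[`, character(1), "chain"),
    resnum = vapply(rows, `[[`, integer(1), "resnum"),
    icode = "",
    x = vapply(rows, `[[`, numeric(1), "x"),
    y = vapply(rows, `[[`, numeric(1), "y"),
    z = vapply(rows, `[[`, numeric(1), "z"),
    charge = vapply(rows, `[[`, numeric(1), "charge"),
    radius = vapply(rows, `[[`, numeric(1), "radius"),
    stringsAsFactors = FALSE)
  atoms$element <- element_from_name(atoms$name)
  atoms <- atoms[atoms$resname != "HOH", , drop = FALSE]
  mol_structure(atoms, source_format = "PQR")
}

#' Write a structure as PQR
#'
#' @param s a `mol_structure`; atoms with unset charge are written as 0.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(s, path) {
  stopifnot(inherits(s, "mol_structure"))
  a <- s$atoms
  q <- ifelse(is.na(a$charge), 0, a$charge)
  lines <- sprintf(
    "ATOM  %5d %-4s %-4s%1s%5d    %8.3f %8.3f %8.3f %8.4f %7.4f",
    a$serial, a$name, a$resname, a$chain, a$resnum,
    a$x, a$y, a$z, q, a$radius)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a structure, auto-detecting PDB vs PQR
#'
#' Detection by file extension first (`.pqr` / `.pdb`), then by column
#' sniffing: records whose fields beyond the coordinates parse as two
#' trailing numbers (charge, radius) are treated as PQR.
#'
#' @param path input file.
#' @param format "auto" (default), "pdb" or "pqr".
#' @param hetero passed to [read_pdb()].
#' @return a `mol_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "pqr"),
                           hetero = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "pqr") "pqr"
      else if (ext %in% c("pdb", "ent")) "pdb"
      else {
        ln <- grep("^ATOM", readLines(path, n = 50, warn = FALSE),
                   value = TRUE)
        if (!length(ln)) "pdb"
        else {
          tk <- strsplit(trimws(ln[1]), "[[:space:]]+")[[1]]
          last2 <- suppressWarnings(as.numeric(tk[(length(tk) - 1):length(tk)]))
          if (length(tk) %in% c(10, 11) && !anyNA(last2)) "pqr" else "pdb"
        }
      }
  }
  if (format == "pqr") read_pqr(path) else read_pdb(path, hetero = hetero)
}
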