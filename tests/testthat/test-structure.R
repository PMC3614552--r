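pdb_line <- function(serial, name, resname, chain, resnum, x, y, z,
                     altloc = " ", occ = 1.0, element = NULL) {
  if (is.null(element)) element <- substr(trimws(name), 1, 1)
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, altloc, resname, chain, resnum, x, y, z, occ, 0.0,
          element)
}

test_that("minimal PDB files parse and malformed records fail with a line", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_line(1, "CA", "GLY", "A", 1, 1, 2, 3), path)
  s <- read_pdb(path)
  expect_s3_class(s, "mol_structure")
  expect_equal(nrow(s$atoms), 1)
  expect_true(is.na(s$atoms$charge))
  expect_equal(s$atoms[, c("x", "y", "z")],
               data.frame(x = 1, y = 2, z = 3))

  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "CA", "GLY", "A", 1, 1, 2, 3),
               "ATOM      2  CA  GLY A   2      xxxxxx   2.0   3.0"), bad)
  expect_error(read_pdb(bad), "line 2")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", empty)
  expect_error(read_pdb(empty), "no ATOM records")
})

test_that("only MODEL 1 is read and waters/hetero are excluded", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL     1",
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    "HETATM    2  ZN  ZN  A   9      1.0     1.0     1.0",
    pdb_line(3, "O", "HOH", "A", 90, 5, 5, 5),
    "ENDMDL",
    "MODEL     2",
    pdb_line(4, "CA", "GLY", "A", 1, 9, 9, 9),
    "ENDMDL"), path)
  s <- read_pdb(path)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$x, 0)
})

test_that("altLoc keeps the highest occupancy with ties to 'A'", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "SER", "A", 1, 0, 0, 0, altloc = "B", occ = 0.7),
    pdb_line(2, "CA", "SER", "A", 1, 1, 0, 0, altloc = "A", occ = 0.3),
    pdb_line(3, "CB", "SER", "A", 1, 0, 1, 0, altloc = "A", occ = 0.5),
    pdb_line(4, "CB", "SER", "A", 1, 0, 2, 0, altloc = "B", occ = 0.5)), path)
  s <- read_pdb(path)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x[s$atoms$name == "CA"], 0)   # occupancy 0.7 wins
  expect_equal(s$atoms$y[s$atoms$name == "CB"], 1)   # tie -> altLoc A
})

test_that("PQR round-trip preserves charges, radii and coordinates", {
  s <- make_toy_protein(n_residues = 8, seed = 4)
  s <- assign_formal_charges(s)
  path <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(s, path)
  back <- read_pqr(path)
  expect_equal(back$atoms$charge, s$atoms$charge, tolerance = 1e-6)
  expect_equal(back$atoms$radius, s$atoms$radius, tolerance = 1e-6)
  expect_equal(back$atoms$x, s$atoms$x, tolerance = 1e-3)
  expect_equal(net_charge(back), net_charge(s), tolerance = 1e-6)
  # PQR net charge is exactly the column sum
  expect_identical(net_charge(back), sum(back$atoms$charge))
  # auto-detection picks the PQR branch without the extension hint
  noext <- withr::local_tempfile()
  file.copy(path, noext)
  expect_identical(read_structure(noext)$source_format, "PQR")
  expect_error(read_structure("does/not/exist.pdb"), "no such file")
})

test_that("formal charges follow the pH-7 bookkeeping rules", {
  # a single ARG with capped termini: +1
  arg <- assign_formal_charges(
    make_toy_protein(sequence = "ARG", seed = 1), cap_termini = TRUE)
  expect_equal(net_charge(arg), 1)
  # the charge sits on the guanidinium carbon CZ
  expect_equal(arg$atoms$name[which(arg$atoms$charge == 1)], "CZ")

  # tripeptide D-G-R with free termini: -1 + 1 + (+1) + (-1) = 0
  dgr <- assign_formal_charges(
    make_toy_protein(sequence = c("ASP", "GLY", "ARG"), seed = 2))
  expect_equal(net_charge(dgr), 0)

  # 3 ASP + 1 LYS, capped: -3 + 1 = -2
  dk <- assign_formal_charges(
    make_toy_protein(sequence = c("ASP", "ASP", "ASP", "LYS"), seed = 3),
    cap_termini = TRUE)
  expect_equal(net_charge(dk), -2)

  # unknown residues warn and stay neutral
  unk <- toy_structure(c("C1", "C2", "C3"), "XYZ", 1,
                       rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0)))
  expect_warning(out <- assign_formal_charges(unk, cap_termini = TRUE),
                 "XYZ")
  expect_equal(net_charge(out), 0)
  expect_error(assign_formal_charges(arg, pH = 5), "pH 7")
})

test_that("missing charge-site atoms fall back to CB then CA", {
  # ARG without CZ (or any side chain beyond CB): charge lands on CB
  noCZ <- toy_structure(c("N", "CA", "CB"), "ARG", 1,
                        rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1.5, 0)))
  out <- assign_formal_charges(noCZ, cap_termini = TRUE)
  expect_equal(out$atoms$charge[out$atoms$name == "CB"], 1)
  # backbone-only residue: CA
  onlyCA <- toy_structure(c("N", "CA"), "LYS", 1,
                          rbind(c(0, 0, 0), c(1.5, 0, 0)))
  out2 <- assign_formal_charges(onlyCA, cap_termini = TRUE)
  expect_equal(out2$atoms$charge[out2$atoms$name == "CA"], 1)
})

test_that("net charge and dipole match closed forms and the oracle", {
  two <- toy_structure(c("C1", "C2"), "UNK", c(1, 2),
                       rbind(c(0, 0, 0), c(10, 0, 0)), charge = c(1, -1))
  expect_equal(net_charge(two), 0)
  expect_equal(structure_dipole(two), 10, tolerance = 1e-12)

  zero <- toy_structure(c("C1", "C2"), "UNK", c(1, 2),
                        rbind(c(0, 0, 0), c(10, 0, 0)), charge = c(0, 0))
  expect_equal(net_charge(zero), 0)
  expect_equal(structure_dipole(zero), 0)

  # random charged fixture vs direct summation about the mass center
  set.seed(9)
  n <- 40
  xyz <- matrix(rnorm(3 * n, 0, 8), ncol = 3)
  qs <- round(rnorm(n, 0, 0.5), 3)
  s <- toy_structure(sprintf("C%d", 1:n), "UNK", 1:n, xyz, charge = qs)
  m <- colloidkit:::element_mass(s$atoms$element)
  rcm <- colSums(xyz * m) / sum(m)
  v <- colSums((xyz - matrix(rcm, n, 3, byrow = TRUE)) * qs)
  expect_equal(structure_dipole(s), sqrt(sum(v^2)), tolerance = 1e-9)

  # dipole of a net-neutral structure is translation invariant
  neutral <- toy_structure(c("C1", "C2", "N1"), "UNK", 1:3,
                           rbind(c(0, 0, 0), c(4, 1, 0), c(-1, 3, 2)),
                           charge = c(0.5, 0.5, -1))
  p0 <- structure_dipole(neutral)
  set.seed(11)
  for (k in 1:3) {
    t <- neutral
    shift <- rnorm(3, 0, 30)
    t$atoms$x <- t$atoms$x + shift[1]
    t$atoms$y <- t$atoms$y + shift[2]
    t$atoms$z <- t$atoms$z + shift[3]
    expect_equal(structure_dipole(t), p0, tolerance = 1e-9)
  }
})
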