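test_that("candidate enumeration follows the net-charge direction rule", {
  # q0 < 0: every ARG and LYS -> ASP
  neg <- assign_formal_charges(make_toy_protein(
    sequence = c("ASP", "ASP", "GLU", "ARG", "GLY", "LYS", "ARG"),
    seed = 1), cap_termini = TRUE)
  expect_equal(net_charge(neg), 0)  # not negative yet: D,D,E = -3; R,K,R = +3
  negger <- assign_formal_charges(make_toy_protein(
    sequence = c("ASP", "ASP", "GLU", "GLU", "GLU", "ARG", "LYS", "ARG"),
    seed = 2), cap_termini = TRUE)
  expect_equal(net_charge(negger), -2)
  cands <- enumerate_charge_flips(negger)
  expect_equal(nrow(cands), 3)
  expect_setequal(cands$wt, c("ARG", "LYS"))
  expect_true(all(cands$mut == "ASP"))
  expect_true(all(grepl("^[RK][0-9]+D$", cands$label)))

  # q0 >= 0: every ASP and GLU -> ARG
  pos <- assign_formal_charges(make_toy_protein(
    sequence = c("ASP", "GLU", "GLU", "LYS", "LYS", "ARG", "ARG"),
    seed = 3), cap_termini = TRUE)
  expect_equal(net_charge(pos), 1)
  cands2 <- enumerate_charge_flips(pos)
  expect_equal(nrow(cands2), 3)
  expect_true(all(cands2$mut == "ARG"))

  # all-neutral structure: empty candidate list, not an error
  neutral <- assign_formal_charges(make_toy_protein(
    sequence = c("GLY", "ALA", "SER"), seed = 4), cap_termini = TRUE)
  expect_equal(nrow(enumerate_charge_flips(neutral)), 0)
})

test_that("charge flips change the net charge by exactly two", {
  s <- assign_formal_charges(make_toy_protein(
    sequence = c("ARG", "GLY", "ASP", "ASP", "ASP", "LYS"), seed = 5),
    cap_termini = TRUE)
  expect_equal(net_charge(s), -1)
  eff <- mutation_scan(s, id = "toy")
  expect_gt(nrow(eff), 0)
  expect_true(all(eff$dq == -2))        # R/K -> D direction
  expect_true(all(abs(eff$dq) == 2))
  expect_equal(eff$q0, rep(-1, nrow(eff)))

  posd <- assign_formal_charges(make_toy_protein(
    sequence = c("ASP", "LYS", "ARG", "LYS"), seed = 6), cap_termini = TRUE)
  e2 <- mutation_effect(posd, "D1R")
  expect_equal(e2$dq, 2)
})

test_that("mutation_effect validates residues and labels", {
  s <- assign_formal_charges(make_toy_protein(
    sequence = c("ARG", "GLY"), seed = 7), cap_termini = TRUE)
  expect_error(mutation_effect(s, "K1D"), "is ARG, not LYS")
  expect_error(mutation_effect(s, "R9D"), "not found")
  expect_error(mutation_effect(s, "bogus"), "cannot parse")
  expect_error(mutation_effect(s, "G2A"), "charged residue types")
})

test_that("a flipped charge at the mass center leaves the dipole unchanged", {
  # symmetric two-atom ARG stub: CZ exactly at the mass center
  s <- toy_structure(c("CZ", "CB"), "ARG", c(1, 1),
                     rbind(c(0, 0, 0), c(3, 0, 0)))
  s$atoms$charge <- c(1, 0)  # wild-type formal charge on CZ
  # move CB so the mass-weighted center coincides with CZ
  s$atoms$x <- c(0, 0)
  s$atoms$y <- c(0, 0)
  s$atoms$z <- c(0, 0)
  eff <- mutation_effect(s, "R1D")
  expect_equal(eff$dp, 0, tolerance = 1e-12)
  expect_equal(eff$dq, -2)
})

test_that("dipole changes are invariant under rigid translation", {
  s <- assign_formal_charges(make_toy_protein(
    sequence = c("ARG", "GLY", "ASP", "GLU", "GLU"), seed = 8),
    cap_termini = TRUE)
  eff <- mutation_effect(s, "R1D")
  t <- s
  t$atoms$x <- t$atoms$x + 40
  t$atoms$y <- t$atoms$y - 13
  t$atoms$z <- t$atoms$z + 7
  eff_t <- mutation_effect(t, "R1D")
  expect_equal(eff_t$dp, eff$dp, tolerance = 1e-9)
  expect_equal(eff_t$p0, eff$p0, tolerance = 1e-9)
})

test_that("best_mutation picks the largest reduction with resnum ties", {
  mk <- function(label, dp) {
    df <- data.frame(id = "x", mutation = label, class = "other",
                     q0 = 0, dq = 2, p0 = 100, dp = dp,
                     stringsAsFactors = FALSE)
    class(df) <- c("mutation_effects", "data.frame")
    df
  }
  tab <- rbind(mk("E10R", -10), mk("D5R", -40), mk("E77R", -5))
  expect_equal(best_mutation(tab)$mutation, "D5R")
  expect_equal(best_mutation(mk("E3R", -7))$mutation, "E3R")
  tie <- rbind(mk("E30R", -12), mk("D12R", -12))
  expect_equal(best_mutation(tie)$mutation, "D12R")
  # never increases the dipole if any candidate decreases it
  mixed <- rbind(mk("E2R", 25), mk("E4R", -1))
  expect_lt(best_mutation(mixed)$dp, 0)
  expect_error(best_mutation(tab[0, ]), "empty")
})

test_that("summarize_effects aggregates with half-away rounding", {
  mk <- function(dp, cls) {
    df <- data.frame(id = "x", mutation = "E1R", class = cls, q0 = 0,
                     dq = 2, p0 = 100, dp = dp, stringsAsFactors = FALSE)
    class(df) <- c("mutation_effects", "data.frame")
    df
  }
  two <- rbind(mk(-10, "other"), mk(-20, "other"))
  agg <- summarize_effects(two)
  expect_equal(agg$per_class$mean_abs_dp, 15)
  expect_equal(agg$max_reduction, 20)
  # half-away rounding: mean 114.5 reports as 115, not 114
  half <- rbind(mk(-114, "a"), mk(-115, "a"))
  expect_equal(summarize_effects(half)$per_class$mean_abs_dp, 115)
  expect_error(summarize_effects(two[0, ]), "empty")
})
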