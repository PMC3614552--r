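test_that("charge_distribution validates its inputs", {
  expect_error(charge_distribution(c(0, 1), c(0.5, 0.5)), "length")
  expect_error(charge_distribution(c(1, 0), 1), "increasing")
  expect_error(charge_distribution(c(0, 1), -1), "non-negative")
  expect_error(charge_distribution(c(0, 1), 0), "zero")
  d <- charge_distribution(c(-1, 0, 1), c(3, 1))
  expect_equal(sum(d$weights), 1, tolerance = 1e-12)
})

test_that("SASA-weighted charge histogram matches hand tallies", {
  s <- toy_structure(c("C1", "C2"), c("UNK", "UNK"), c(1, 2),
                     rbind(c(0, 0, 0), c(50, 0, 0)),
                     charge = c(0.5, -0.5))
  h <- build_charge_histogram(list(s), list(c(10, 30)), bin_width = 0.5)
  expect_equal(sum(h$weights), 1, tolerance = 1e-12)
  bin_of <- function(q) findInterval(q, h$bin_edges, rightmost.closed = TRUE)
  expect_equal(h$weights[bin_of(0.5)], 0.25, tolerance = 1e-12)
  expect_equal(h$weights[bin_of(-0.5)], 0.75, tolerance = 1e-12)

  s1 <- toy_structure("C1", "UNK", 1, rbind(c(0, 0, 0)), charge = 0.37)
  h1 <- build_charge_histogram(list(s1), list(5))
  expect_equal(max(h1$weights), 1, tolerance = 1e-12)

  expect_error(build_charge_histogram(list(s), list(c(0, 0))),
               "no solvent-exposed atoms")
})

test_that("sampled topologies hit the net-charge target exactly", {
  dist <- default_charge_distribution()
  for (seed in 1:20) {
    top <- sample_topology(shell_c60, dist, -2, seed = seed)
    expect_equal(top$q, -2, tolerance = 1e-9)
    expect_equal(sum(top$surface_charges) + top$central_charge, top$q,
                 tolerance = 1e-9)
    expect_gte(top$p, 0)
  }
  # point mass at zero: every surface charge is the uniform shift
  pm <- charge_distribution(c(-1e-12, 1e-12), 1)
  top0 <- sample_topology(shell_c60, pm, -2, seed = 1)
  expect_equal(top0$surface_charges, rep(-2 / 60, 60), tolerance = 1e-10)
})

test_that("sampling is deterministic per seed", {
  dist <- default_charge_distribution()
  a <- sample_topology(shell_c60, dist, -2, seed = 11)
  b <- sample_topology(shell_c60, dist, -2, seed = 11)
  expect_identical(a$surface_charges, b$surface_charges)
  c <- sample_topology(shell_c60, dist, -2, seed = 12)
  expect_false(identical(a$surface_charges, c$surface_charges))
})

test_that("dipole moment matches arithmetic and the brute-force oracle", {
  # +/- 0.5 e at 10 A separation: p = 0.5 * 10 = 5 eA, any origin
  two <- point_topology(rbind(c(0, 0, 0), c(10, 0, 0)), c(0.5, -0.5))
  expect_equal(dipole_moment(two), 5.0, tolerance = 1e-12)
  for (origin in list(c(1, 2, 3), c(-7, 0, 4), c(0, 0, 0)))
    expect_equal(dipole_moment(two, origin), 5.0, tolerance = 1e-9)

  # only the central charge, origin at the center: zero
  ctr <- point_topology(rbind(c(1, 0, 0), c(-1, 0, 0)), c(0, 0),
                        central_charge = -4)
  expect_equal(dipole_moment(ctr), 0, tolerance = 1e-12)

  dist <- default_charge_distribution()
  for (seed in 1:10) {
    top <- sample_topology(shell_c60, dist, -2, seed = 100 + seed)
    expect_equal(dipole_moment(top), dipole_oracle(top), tolerance = 1e-9)
  }
})

test_that("net-neutral dipoles are origin independent", {
  dist <- default_charge_distribution()
  top <- sample_topology(shell_c60, dist, 0, seed = 5)
  set.seed(42)
  for (k in 1:3) {
    origin <- rnorm(3, 0, 20)
    expect_equal(dipole_moment(top, origin), dipole_moment(top),
                 tolerance = 1e-9)
  }
})

test_that("set_central_charge shifts q but not the surface descriptors", {
  dist <- default_charge_distribution()
  top <- sample_topology(shell_gp32, dist, -2, seed = 3)
  shifted <- set_central_charge(top, -4)
  expect_equal(shifted$q, -6, tolerance = 1e-9)
  expect_identical(shifted$surface_charges, top$surface_charges)
  expect_equal(shifted$p, top$p, tolerance = 1e-12)
  again <- set_central_charge(top, -8)
  expect_equal(again$q, -10, tolerance = 1e-9)
  # patch descriptors are computed from surface charges only: bit-identical
  pp <- patch_params(5.0, 0)
  expect_identical(summarize_patches(shifted, pp)$mlssc,
                   summarize_patches(top, pp)$mlssc)
  expect_identical(summarize_patches(shifted, pp)$mlsc,
                   summarize_patches(top, pp)$mlsc)
})

test_that("ensembles are reproducible, labeled and annotated", {
  dist <- default_charge_distribution()
  e1 <- generate_ensemble(shell_c60, dist, 5, -2, seed = 40)
  e2 <- generate_ensemble(shell_c60, dist, 5, -2, seed = 40)
  df1 <- as.data.frame(e1); df2 <- as.data.frame(e2)
  expect_identical(df1, df2)
  expect_equal(df1$label, sprintf("PP%04d", 1:5))
  expect_equal(anyDuplicated(df1$mlssc), 0)
  expect_true(all(is.finite(df1$mlsc)))
  # point mass at zero with q_target 0: all dipoles vanish
  pm <- charge_distribution(c(-1e-12, 1e-12), 1)
  e0 <- generate_ensemble(shell_c60, pm, 3, 0, seed = 1)
  expect_true(all(vapply(e0, function(t) t$p, numeric(1)) < 1e-9))
  expect_true(all(vapply(e0, function(t) t$in_range, logical(1))))
})

test_that("ensemble dipoles land inside the protein-like validation range", {
  dist <- default_charge_distribution()
  ens <- generate_ensemble(shell_c60, dist, 60, -2, seed = 900)
  p <- vapply(ens, function(t) t$p, numeric(1))
  expect_gt(diff(range(p)), 5)      # a genuine spread, not a point mass
  expect_gt(mean(p >= 0 & p <= 70), 0.9)
})

test_that("select_varied_set spreads selections over descriptor space", {
  dist <- default_charge_distribution()
  ens <- generate_ensemble(shell_c60, dist, 40, -2, seed = 70)
  p <- vapply(ens, function(t) t$p, numeric(1))
  ptol <- diff(range(p)) / 2 + 1
  pmid <- mean(range(p))
  # exactly two eligible candidates, k = 2: both returned
  two <- ens[1:2]
  sel2 <- select_varied_set(two, -2, p_target = mean(sapply(two, `[[`, "p")),
                            p_tol = 100, k = 2)
  expect_setequal(vapply(sel2, `[[`, character(1), "label"),
                  vapply(two, `[[`, character(1), "label"))
  # shortfall is an error naming the counts
  expect_error(select_varied_set(ens, -2, pmid, p_tol = ptol, k = 1000),
               "need 1000")
  expect_error(select_varied_set(ens, -7, pmid, p_tol = ptol, k = 2),
               "q = -7")
  # two tight descriptor clusters, k = 2: one from each
  mk <- function(charges, label) {
    t <- colloidkit:::new_topology(point_geometry(diag(3) * 30), charges,
                                   0, label = label)
    t$q <- -2  # force eligibility on q without changing descriptors
    t
  }
  far <- list(mk(c(0.01, 0.02, 0.01), "a1"), mk(c(0.012, 0.019, 0.01), "a2"),
              mk(c(0.9, 0.9, 0.92), "b1"), mk(c(0.88, 0.91, 0.9), "b2"))
  for (i in seq_along(far)) far[[i]]$p <- 10
  sel <- select_varied_set(far, -2, p_target = 10, p_tol = 1, k = 2)
  grp <- substr(vapply(sel, `[[`, character(1), "label"), 1, 1)
  expect_setequal(grp, c("a", "b"))
})

test_that("select_dipole_series picks per-bin closest to midpoint", {
  mk <- function(p, label) {
    t <- point_topology(rbind(c(p, 0, 0), c(-p, 0, 0)), c(0.5, -0.5))
    t$label <- label
    t$q <- -2
    t
  }
  cands <- list(mk(1, "t1"), mk(18, "t2"), mk(2.2, "t3"))
  sel <- select_dipole_series(cands, -2, list(c(0, 5), c(15, 20)))
  expect_equal(vapply(sel, function(t) t$p, numeric(1)), c(2.2, 18))
  expect_error(select_dipole_series(cands, -2, list(c(40, 50))),
               "\\[40, 50\\)")
})

test_that("topology CSV round-trip preserves charges and metadata", {
  dist <- default_charge_distribution()
  top <- sample_topology(shell_c60, dist, -2, seed = 8, label = "PPx")
  path <- withr::local_tempfile(fileext = ".csv")
  write_topology(top, path)
  back <- read_topology(path, geometry = shell_c60)
  expect_equal(back$surface_charges, top$surface_charges, tolerance = 1e-12)
  expect_equal(back$q, top$q, tolerance = 1e-9)
  expect_equal(back$p, top$p, tolerance = 1e-9)
  expect_identical(back$label, "PPx")
})
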