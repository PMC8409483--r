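# RRHO/quasi-RRHO thermochemistry, degeneracy and cycle assembly

test_that("diatomic frequency matches the closed form within 0.5%", {
  dp <- make_diatomic_pair(k1 = 1000, k2 = 600, r0 = 1.4, element = "C")
  force <- compile_model_force(dp$system$E1, dp$theta)
  mn <- minimize_coords(rbind(c(0, 0, 0), c(1.45, 0.08, 0)),
                        function(x) force(x)$energy,
                        function(x) force(x)$grad, tol = 1e-8)
  fr <- hessian_frequencies(mn$coords, function(x) force(x)$grad,
                            atomic_masses(c("C", "C")))
  expect_length(fr, 1L)
  mu <- 12.011 / 2
  analytic <- sqrt(1000 * CONST$hessian_unit / mu) /
    (2 * pi * CONST$c_cm)
  expect_equal(fr, analytic, tolerance = 5e-3)
  # halving the step barely moves the result (central differences)
  fr2 <- hessian_frequencies(mn$coords, function(x) force(x)$grad,
                             atomic_masses(c("C", "C")), step = 2.5e-3)
  expect_equal(fr, fr2, tolerance = 1e-3)
})

test_that("a free atom has no vibrational modes", {
  expect_length(hessian_frequencies(matrix(0, 1, 3), identity, 12), 0L)
})

test_that("a displaced geometry is flagged as not a minimum", {
  # maximum of an inverted well: all modes imaginary
  neg <- function(x) -2 * x
  expect_error(
    hessian_frequencies(rbind(c(0, 0, 0), c(1.5, 0, 0)), neg, c(12, 12)),
    "not a minimum")
  fr <- hessian_frequencies(rbind(c(0, 0, 0), c(1.5, 0, 0)), neg,
                            c(12, 12), on_imaginary = "keep")
  expect_true(any(fr < 0))
})

test_that("harmonic vibrational free energy matches the partition function", {
  coords <- rbind(c(0, 0, 0), c(1.4, 0, 0))
  m <- c(12.011, 12.011)
  with_mode <- rrho_free_energy(100, m, coords, T = 300,
                                free_rotor_cutoff = 0)
  without <- rrho_free_energy(numeric(0), m, coords, T = 300)
  th <- CONST$h_J * CONST$c_cm * 100 / (CONST$kB_J * 300)
  RT <- CONST$R_kcal * 300
  closed <- -RT * log(exp(-th / 2) / (1 - exp(-th)))
  expect_equal(with_mode$G - without$G, closed, tolerance = 1e-6)
  expect_error(rrho_free_energy(-5, m, coords), "imaginary")
})

test_that("low modes go free-rotor below the strict 15 cm^-1 cutoff", {
  coords <- rbind(c(0, 0, 0), c(1.2, 0.3, 0), c(2.4, 0, 0))
  m <- c(12, 12, 16)
  r <- rrho_free_energy(c(10, 500), m, coords, T = 300)
  expect_equal(r$free_rotor_modes, c(TRUE, FALSE))
  r15 <- rrho_free_energy(c(15, 500), m, coords, T = 300)
  expect_equal(r15$free_rotor_modes, c(FALSE, FALSE))  # strict "<"
  r14 <- rrho_free_energy(c(14.999, 500), m, coords, T = 300)
  expect_true(r14$free_rotor_modes[1])
  # ZPE only over the harmonic modes
  expect_equal(r$zpe,
               0.5 * CONST$h_J * CONST$c_cm * 500 * CONST$N_A /
                 CONST$kcal_J, tolerance = 1e-9)
})

test_that("translational entropy reproduces Sackur-Tetrode", {
  r <- rrho_free_energy(numeric(0), masses = 39.948,
                        coords = matrix(0, 1, 3), T = 298.15, p = 1)
  # independent evaluation of the Sackur-Tetrode equation
  kT <- CONST$kB_J * 298.15
  M <- 39.948 * CONST$amu_kg
  st <- CONST$R_kcal * 1000 *
    (log((2 * pi * M * kT / CONST$h_J^2)^1.5 * kT / 101325) + 2.5)
  expect_equal(r$S_trans, st, tolerance = 1e-8)
  expect_equal(r$S_trans, 36.98, tolerance = 1e-3)   # argon, cal/mol/K
})

test_that("symmetry number and degeneracy enter with the right signs", {
  coords <- rbind(c(0, 0, 0), c(1.2, 0.3, 0), c(2.4, 0, 0))
  m <- c(12, 12, 16)
  base <- rrho_free_energy(500, m, coords, T = 300)
  sym <- rrho_free_energy(500, m, coords, T = 300, sigma_ext = 2)
  RT <- CONST$R_kcal * 300
  expect_equal(sym$G - base$G, RT * log(2), tolerance = 1e-9)
  deg <- rrho_free_energy(500, m, coords, T = 300, degeneracy = 3,
                          use_degeneracy = TRUE)
  expect_equal(deg$G - base$G, -RT * log(3), tolerance = 1e-9)
  off <- rrho_free_energy(500, m, coords, T = 300, degeneracy = 3)
  expect_equal(off$G, base$G)                      # off by default
})

test_that("Boltzmann weighting of conformer free energies behaves", {
  T <- 300
  RT <- CONST$R_kcal * T
  expect_equal(weighted_free_energy(-7.3, T), -7.3)
  G <- c(-5, -5, -5, -5)
  expect_equal(weighted_free_energy(G, T), -5 - RT * log(4),
               tolerance = 1e-10)
  set.seed(3)
  Gr <- rnorm(6)
  expect_equal(weighted_free_energy(Gr, T),
               weighted_free_energy(sample(Gr), T))
  expect_lte(weighted_free_energy(Gr, T), min(Gr))
  dom <- c(-30, rep(-10, 5))
  expect_equal(weighted_free_energy(dom, T), -30, tolerance = 1e-6)
  expect_error(weighted_free_energy(numeric(0), T), "no finite")
})

test_that("graph degeneracy equals exhaustive permutation enumeration", {
  fixtures <- c(water = "O", formaldehyde = "C=O", ammonia = "N",
                methanol = "CO", acetaldehyde = "CC=O",
                methylamine = "CN", ethane = "CC")
  for (nm in names(fixtures)) {
    mol <- smiles_to_molecule(fixtures[[nm]])
    expect_lte(n_atoms(mol), 8L)
    expect_equal(graph_degeneracy(mol),
                 count_automorphisms_exhaustive(mol), label = nm)
  }
  expect_equal(graph_degeneracy(smiles_to_molecule("CC")), 72L)
})

test_that("benzene degeneracy matches a backtracking enumeration oracle", {
  benz <- smiles_to_molecule("c1ccccc1")
  expect_equal(graph_degeneracy(benz), 12L)
  expect_equal(count_automorphisms_backtrack(benz), 12L)
  # and the two oracles agree with VF2 on an asymmetric molecule
  asym <- smiles_to_molecule("NC(=O)C")
  expect_equal(graph_degeneracy(asym),
               count_automorphisms_backtrack(asym))
})

test_that("standard-state correction gives 1.89 kcal/mol and scales with T", {
  expect_equal(standard_state_correction(298.15), 1.89, tolerance = 5e-3)
  expect_equal(standard_state_correction(298.15, volume_ratio = 1), 0)
  expect_equal(standard_state_correction(2 * 298.15),
               2 * standard_state_correction(298.15), tolerance = 1e-12)
})

test_that("the thermodynamic cycle assembles by simple addition", {
  expect_equal(assemble_solution_cycle(c(-10, -12), c(-5, -4)), -1)
  expect_equal(assemble_solution_cycle(c(0, 0), c(0, 0)), 0)
  expect_equal(assemble_solution_cycle(c(-3, -7), c(2, 2)),
               assemble_solution_cycle(c(-3, -7)) )
  expect_error(assemble_solution_cycle(c(-3, NA), c(0, 0)), "finite")
})
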