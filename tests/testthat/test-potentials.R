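# parameterized potentials, restraints and alchemical mixing

make_keto_system <- function() {
  p <- tautomer_pair("ke", smiles_to_molecule("CC=O"),
                     smiles_to_molecule("C=CO"), logK = 1)
  sys <- build_hybrid_topology(p)
  theta <- default_toy_parameters(sys$E1, sys$E2)
  x <- place_dummy_hydrogen(sys, p$t1$coords, theta, seed = 7)$coords
  list(sys = sys, theta = theta, x = x)
}

test_that("flat-bottom restraint matches its closed form", {
  kt <- kBT(300)
  r <- data.frame(i = 1L, j = 2L, r0 = 1.3, r_fb = 0.3, k = kt / 0.1)
  at <- function(d) flat_bottom_restraint_energy(
    rbind(c(0, 0, 0), c(d, 0, 0)), r)
  expect_equal(at(1.3), 0)                      # inside the well
  expect_equal(at(1.6), 0)                      # exactly at the boundary
  expect_equal(at(1.0), 0)                      # inner boundary
  expect_equal(at(1.7), 0.5 * (kt / 0.1) * 0.1^2, tolerance = 1e-12)
  expect_equal(at(1.7), 0.0298, tolerance = 1e-3)
  expect_equal(at(0.9), 0.5 * (kt / 0.1) * 0.1^2, tolerance = 1e-12)
})

test_that("restraint energy is invariant under rigid motion", {
  ks <- make_keto_system()
  x <- ks$x * 1.4                                # stretch to activate some
  th <- 0.6
  Rm <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  x2 <- x %*% Rm + matrix(rep(c(3, -1, 2), each = nrow(x)), ncol = 3)
  e1 <- flat_bottom_restraint_energy(x, ks$sys$restraints)
  e2 <- flat_bottom_restraint_energy(x2, ks$sys$restraints)
  expect_gt(e1, 0)
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("restraints cover every covalent bond with the protocol parameters", {
  # ethane-shaped system: both endstates share the same topology
  eth <- smiles_to_molecule("CC")
  b <- eth$bonds[, c("i", "j", "order")]
  sys <- list(elements = eth$elements, bonds1 = b, bonds2 = b)
  rs <- build_restraints(sys, T = 300)
  expect_equal(nrow(rs), 7L)                    # 1 C-C + 6 C-H
  is_h <- eth$elements[rs$i] == "H" | eth$elements[rs$j] == "H"
  expect_equal(sum(!is_h), 1L)
  expect_true(all(rs$r0[is_h] == 1.02))
  expect_true(all(rs$r_fb[is_h] == 0.4))
  expect_true(all(rs$r0[!is_h] == 1.3))
  expect_true(all(rs$r_fb[!is_h] == 0.3))
  kt <- kBT(300)
  expect_equal(rs$k[is_h], rep(kt / 0.2, 6), tolerance = 1e-12)
  expect_equal(rs$k[!is_h], kt / 0.1, tolerance = 1e-12)
  # no bonds -> no restraints
  empty <- list(elements = character(0),
                bonds1 = data.frame(i = integer(), j = integer(),
                                    order = integer()),
                bonds2 = data.frame(i = integer(), j = integer(),
                                    order = integer()))
  expect_equal(nrow(build_restraints(empty)), 0L)
})

test_that("alchemical energy interpolates linearly between the endstates", {
  # wells tuned so E1 = 2 and E2 = 4 at |x| = 1
  sys <- make_harmonic_pair(1, 4, 8)$system
  theta <- potential_parameters(list(well_k = c(k1 = 4, k2 = 8)))
  x <- matrix(c(1, 0, 0), 1, 3)
  expect_equal(alchemical_energy(x, 0, sys, theta)$energy, 2)
  expect_equal(alchemical_energy(x, 1, sys, theta)$energy, 4)
  expect_equal(alchemical_energy(x, 0.5, sys, theta)$energy, 3)
  expect_error(alchemical_energy(x, 1.2, sys, theta), "lambda")
  expect_error(alchemical_energy(x, -0.1, sys, theta), "lambda")
  # linearity in lambda on the full molecular system at random geometry
  ks <- make_keto_system()
  set.seed(4)
  xr <- ks$x + matrix(rnorm(length(ks$x), sd = 0.1), nrow(ks$x), 3)
  e0 <- alchemical_energy(xr, 0, ks$sys, ks$theta, gradient = FALSE)$energy
  e1 <- alchemical_energy(xr, 1, ks$sys, ks$theta, gradient = FALSE)$energy
  for (lam in c(0.25, 0.37, 0.8)) {
    el <- alchemical_energy(xr, lam, ks$sys, ks$theta,
                            gradient = FALSE)$energy
    expect_equal(el - e0, lam * (e1 - e0), tolerance = 1e-9)
  }
})

test_that("coordinate gradients match central finite differences", {
  ks <- make_keto_system()
  set.seed(9)
  x <- ks$x + matrix(rnorm(length(ks$x), sd = 0.08), nrow(ks$x), 3)
  h <- 1e-5
  for (lam in c(0, 0.37, 1)) {
    g <- alchemical_energy(x, lam, ks$sys, ks$theta)$grad
    idx <- rbind(c(1, 1), c(3, 2), c(8, 3), c(5, 1))
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; d <- idx[r, 2]
      xp <- x; xp[i, d] <- xp[i, d] + h
      xm <- x; xm[i, d] <- xm[i, d] - h
      fd <- (alchemical_energy(xp, lam, ks$sys, ks$theta,
                               gradient = FALSE)$energy -
               alchemical_energy(xm, lam, ks$sys, ks$theta,
                                 gradient = FALSE)$energy) / (2 * h)
      expect_equal(g[i, d], fd, tolerance = 1e-5 * max(1, abs(fd)))
    }
  }
})

test_that("toy potential reproduces the diatomic closed form", {
  dp <- make_diatomic_pair(k1 = 300, k2 = 600, r0 = 1.3)
  x_eq <- dp$coords0
  expect_equal(pot_energy(dp$system$E1, x_eq, dp$theta), 0)
  d <- 0.17
  x_st <- rbind(c(0, 0, 0), c(1.3 + d, 0, 0))
  expect_equal(pot_energy(dp$system$E1, x_st, dp$theta), 0.5 * 300 * d^2)
  expect_equal(pot_energy(dp$system$E2, x_st, dp$theta), 0.5 * 600 * d^2)
  # well-depth offset shifts the energy by a constant
  th2 <- dp$theta
  th2$groups$bond_D[["C-C:1"]] <- 2.5
  expect_equal(pot_energy(dp$system$E1, x_st, th2),
               0.5 * 300 * d^2 - 2.5)
})

test_that("parameter gradients match central finite differences", {
  ks <- make_keto_system()
  set.seed(13)
  x <- ks$x + matrix(rnorm(length(ks$x), sd = 0.05), nrow(ks$x), 3)
  X <- array(x, c(nrow(x), 3, 1))
  for (model in list(ks$sys$E1, ks$sys$E2)) {
    G <- pot_pgrad_many(model, X, ks$theta)
    fl <- params_flatten(ks$theta)
    h <- 1e-5
    for (nm in names(fl)) {
      fp <- fl; fp[nm] <- fp[nm] + h
      fm <- fl; fm[nm] <- fm[nm] - h
      fd <- (pot_energy(model, x, params_unflatten(fp, ks$theta)) -
               pot_energy(model, x, params_unflatten(fm, ks$theta))) /
        (2 * h)
      expect_equal(unname(G[nm, 1]), fd,
                   tolerance = 1e-6 * max(1, abs(fd)), label = nm)
    }
  }
})

test_that("missing parameters for a present bond type are an error", {
  dp <- make_diatomic_pair()
  bad <- dp$theta
  bad$groups$bond_k <- bad$groups$bond_k["C-C:2"]
  expect_error(pot_energy(dp$system$E1, dp$coords0, bad), "missing")
})

test_that("the compiled force closure matches the reference evaluation", {
  ks <- make_keto_system()
  set.seed(21)
  x <- ks$x + matrix(rnorm(length(ks$x), sd = 0.25), nrow(ks$x), 3)
  for (lam in c(0, 0.5, 1)) {
    fast <- compile_alchemical_force(ks$sys, ks$theta, lam)(x)
    ref <- alchemical_energy(x, lam, ks$sys, ks$theta)
    expect_equal(fast$energy, ref$energy, tolerance = 1e-12)
    expect_equal(fast$grad, ref$grad, tolerance = 1e-12)
  }
  hp <- make_harmonic_pair(2, 1, 4)
  xh <- matrix(rnorm(6), 2, 3)
  fast <- compile_alchemical_force(hp$system, hp$theta, 0.3)(xh)
  ref <- alchemical_energy(xh, 0.3, hp$system, hp$theta)
  expect_equal(fast$energy, ref$energy, tolerance = 1e-12)
  expect_equal(fast$grad, ref$grad, tolerance = 1e-12)
})

test_that("parameter sets serialize through the JSON schema", {
  ks <- make_keto_system()
  path <- tempfile(fileext = ".json")
  write_parameters(ks$theta, path)
  back <- read_parameters(path)
  expect_equal(params_flatten(back), params_flatten(ks$theta))
  expect_error(potential_parameters(list(a = c(x = NaN))), "non-finite")
})
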