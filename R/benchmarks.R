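# Benchmark fixtures: isotropic harmonic pair systems whose alchemical
# free energy is known in closed form, toy tautomer-like hybrid systems
# (two bonded endstates differing by the position of one hydrogen and one
# elevated bond order), and synthetic "experimental" datasets generated
# from a ground-truth parameter set.

#' Analytic harmonic pair system
#'
#' `n_atoms` particles bound isotropically to the origin with stiffness
#' `k1` in endstate 1 and `k2` in endstate 2.  The reduced free energy
#' difference is exactly `(3 n / 2) ln(k2 / k1)`, which makes the pair the
#' module-level oracle for the whole sample -> MBAR pipeline.
#'
#' @param n_atoms number of particles.
#' @param k1,k2 endstate stiffnesses, kcal/mol/A^2.
#' @param T temperature (K).
#' @return list with `system` (shaped like a hybrid system: no dummy, no
#'   restraints), `theta`, `coords0`, `analytic_df` (reduced) and
#'   `analytic_dG` (kcal/mol).
#' @export
make_harmonic_pair <- function(n_atoms = 1L, k1 = 1, k2 = 4, T = 300) {
  stopifnot(k1 > 0, k2 > 0)
  # unit-mass particles decorrelate fastest at these soft stiffnesses
  elements <- rep("H", n_atoms)
  sys <- structure(list(
    elements = elements,
    masses = atomic_masses(elements),
    dummy1 = NULL, dummy2 = NULL,
    restraints = data.frame(i = integer(), j = integer(), r0 = numeric(),
                            r_fb = numeric(), k = numeric()),
    E1 = well_model(seq_len(n_atoms), "k1", n_sup = n_atoms, id = "E1"),
    E2 = well_model(seq_len(n_atoms), "k2", n_sup = n_atoms, id = "E2"),
    pair_name = sprintf("harmonic_%g_%g", k1, k2),
    T = T
  ), class = "hybrid_system")
  df <- 1.5 * n_atoms * log(k2 / k1)
  list(system = sys,
       theta = potential_parameters(list(well_k = c(k1 = k1, k2 = k2))),
       coords0 = matrix(0, n_atoms, 3),
       analytic_df = df,
       analytic_dG = df * kBT(T))
}

# crude zigzag starting geometry for a chain + hydrogens; relaxed by the
# pre-MD minimization, it only needs to be non-degenerate
.chain_coords <- function(n_heavy, h_parent) {
  xy <- cbind((seq_len(n_heavy) - 1) * 1.4,
              0.45 * (seq_len(n_heavy) %% 2), 0)
  hxy <- NULL
  for (p in h_parent) {
    hxy <- rbind(hxy, xy[p, ] + c(0.2, -0.7, 0.7))
  }
  rbind(xy, hxy)
}

#' Construct a toy tautomer-like hybrid system
#'
#' A chain of `n_heavy` heavy atoms with a movable hydrogen on the first
#' atom (endstate 1) or the last atom (endstate 2); the elevated bond
#' order sits at the donor end in endstate 1 and migrates to the acceptor
#' end in endstate 2, mimicking the coupled proton shift and double-bond
#' migration of real tautomers without their chemistry.  Extra spectator
#' hydrogens can be attached to interior atoms.
#'
#' @param elements_heavy character vector of chain elements (first =
#'   donor, last = acceptor).
#' @param n_spectator_h hydrogens on interior chain atoms.
#' @param T temperature (K) for the restraints.
#' @param name system name.
#' @return list with `system` (a `hybrid_system`) and `coords0`.
#' @export
make_toy_pair <- function(elements_heavy = c("C", "C", "O"),
                          n_spectator_h = 1L, T = 300,
                          name = "toy_pair") {
  nh <- length(elements_heavy)
  stopifnot(nh >= 2)
  donor <- 1L; acceptor <- nh
  interior <- setdiff(seq_len(nh), c(donor, acceptor))
  n_spec <- min(n_spectator_h, length(interior))
  spec_parent <- interior[seq_len(n_spec)]
  moving_h <- nh + 1L
  spec_idx <- if (n_spec > 0) nh + 1L + seq_len(n_spec) else integer(0)
  dummy1 <- nh + n_spec + 2L
  elements <- c(elements_heavy, "H", rep("H", n_spec), "H")
  chain <- data.frame(i = seq_len(nh - 1L), j = 2:nh, order = 1L)
  spec_bonds <- if (n_spec > 0)
    data.frame(i = spec_parent, j = spec_idx, order = 1L)
  else data.frame(i = integer(), j = integer(), order = integer())
  bonds1 <- rbind(chain, spec_bonds,
                  data.frame(i = donor, j = moving_h, order = 1L))
  bonds1$order[1] <- 2L                       # elevated order at donor end
  bonds2 <- rbind(chain, spec_bonds,
                  data.frame(i = acceptor, j = dummy1, order = 1L))
  bonds2$order[nh - 1L] <- 2L                 # ... migrates to acceptor end
  sys <- structure(list(
    elements = elements,
    masses = atomic_masses(elements),
    donor = donor, acceptor = acceptor,
    dummy1 = dummy1, dummy2 = moving_h,
    interacting1 = setdiff(seq_along(elements), dummy1),
    interacting2 = setdiff(seq_along(elements), moving_h),
    bonds1 = bonds1, bonds2 = bonds2,
    pair_name = name,
    T = T
  ), class = "hybrid_system")
  sys$restraints <- build_restraints(sys, T = T)
  sys$E1 <- toy_model(elements, bonds1, atoms = sys$interacting1, id = "E1")
  sys$E2 <- toy_model(elements, bonds2, atoms = sys$interacting2, id = "E2")
  coords0 <- .chain_coords(nh, c(donor, spec_parent))
  list(system = sys, coords0 = coords0)
}

#' Generate a synthetic tautomer dataset from ground-truth parameters
#'
#' Draws `n_pairs` toy hybrid systems with varying chain length and
#' element composition, computes each pair's alchemical free energy under
#' the ground-truth parameters with the supplied protocol, and adds
#' Gaussian observation noise to form synthetic "experimental" values.
#'
#' @param n_pairs number of pairs.
#' @param noise_sd observation noise (kcal/mol).
#' @param seed master seed (system draws, sampling, noise).
#' @param protocol a [sampling_protocol()] used to generate the reference
#'   values (1 replicate is enough since noise dominates).
#' @param theta_truth ground-truth parameters; when NULL the default toy
#'   force field over the drawn systems is used.
#' @return list with `pairs` (each: `name`, `system`, `coords0`,
#'   `sampling_seed` -- the seed its reference value was sampled with,
#'   `dG_true`, `dG_exp`), `theta_truth`, `seed`.
#' @export
make_synthetic_dataset <- function(n_pairs = 30L, noise_sd = 0.5,
                                   seed = 1L,
                                   protocol = sampling_protocol(
                                     n_lambda = 11L, n_steps = 8000L,
                                     gamma = 15, stride = 25L,
                                     n_snapshots = 40L,
                                     n_replicates = 1L),
                                   theta_truth = NULL) {
  seeds <- derive_seeds(seed, 2L * n_pairs + 1L)
  # deterministic variety of chain compositions
  compositions <- list(c("C", "C", "O"), c("C", "C", "N"),
                       c("C", "N", "O"), c("N", "C", "O"),
                       c("C", "C", "C", "O"), c("C", "N", "C", "O"),
                       c("C", "C", "N", "O"), c("N", "C", "C", "O"),
                       c("C", "C", "C", "N"), c("O", "C", "C", "N"))
  pairs <- vector("list", n_pairs)
  systems <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    comp <- compositions[[(p - 1L) %% length(compositions) + 1L]]
    n_spec <- (p %/% length(compositions)) %% 2L
    tp <- make_toy_pair(comp, n_spectator_h = n_spec,
                        name = sprintf("syn_%03d", p))
    pairs[[p]] <- list(name = tp$system$pair_name, system = tp$system,
                       coords0 = tp$coords0, sampling_seed = seeds[p])
    systems[[p]] <- tp$system
  }
  if (is.null(theta_truth)) {
    models <- unlist(lapply(systems, function(s) list(s$E1, s$E2)),
                     recursive = FALSE)
    theta_truth <- default_toy_parameters(models)
  }
  for (p in seq_len(n_pairs)) {
    est <- estimate_pair_free_energy(pairs[[p]]$system, theta_truth,
                                     pairs[[p]]$coords0, protocol,
                                     seed = seeds[p])
    noise <- with_seed(seeds[n_pairs + p], stats::rnorm(1, 0, noise_sd))
    pairs[[p]]$dG_true <- est$dG
    pairs[[p]]$dG_exp <- est$dG + noise
  }
  list(pairs = pairs, theta_truth = theta_truth, seed = seed,
       noise_sd = noise_sd)
}

#' Deterministically perturb a parameter set
#'
#' Starting point for the parameter-recovery experiments: shifts the bond
#' well-depth offsets of hydrogen bond types by a geometrically decaying,
#' sign-alternating pattern `dD * (-1/2)^(i-1)` (so no two hydrogen bond
#' types receive the same shift and every donor/acceptor combination
#' carries a free-energy misfit), scales force constants by `k_scale`,
#' and shifts bond lengths by `dr0`.
#'
#' @param theta a `taut_params`.
#' @param dD leading well-depth shift (kcal/mol) on H bond types.
#' @param k_scale multiplicative factor on `bond_k`.
#' @param dr0 additive shift (A) on `bond_r0`.
#' @return perturbed `taut_params`.
#' @export
perturb_parameters <- function(theta, dD = 1.5, k_scale = 1.15,
                               dr0 = 0.02) {
  g <- theta$groups
  if (!is.null(g$bond_D)) {
    hty <- grep("H", names(g$bond_D))
    g$bond_D[hty] <- g$bond_D[hty] +
      dD * (-0.5)^(seq_along(hty) - 1)
  }
  if (!is.null(g$bond_k)) g$bond_k <- g$bond_k * k_scale
  if (!is.null(g$bond_r0)) g$bond_r0 <- g$bond_r0 + dr0
  if (!is.null(g$well_k)) g$well_k <- g$well_k * k_scale
  potential_parameters(g)
}

#' Diatomic pair with different bond stiffness at the two endstates
#'
#' One bonded atom pair whose two endstate potentials share the
#' equilibrium length but differ in stiffness (encoded as bond orders 1
#' and 2 with explicit parameters), so translation and rotation cancel
#' exactly from the endpoint difference and the classical vibrational
#' free energy difference `0.5 kT ln(k2/k1)` is the analytic reference.
#' This is the fixture behind the thermochemistry-vs-alchemical
#' consistency check.
#'
#' @param k1,k2 endstate bond stiffness (kcal/mol/A^2).
#' @param r0 shared equilibrium bond length (A); the default sits at the
#'   restraint reference so the flat-bottom restraint never activates.
#' @param element chain element for both atoms.
#' @param T temperature (K).
#' @return list with `system`, `theta`, `coords0`, `analytic_dG`
#'   (kcal/mol, classical).
#' @export
make_diatomic_pair <- function(k1 = 300, k2 = 600, r0 = 1.3,
                               element = "C", T = 300) {
  elements <- rep(element, 2)
  bonds1 <- data.frame(i = 1L, j = 2L, order = 1L)
  bonds2 <- data.frame(i = 1L, j = 2L, order = 2L)
  sys <- structure(list(
    elements = elements,
    masses = atomic_masses(elements),
    dummy1 = NULL, dummy2 = NULL,
    bonds1 = bonds1, bonds2 = bonds2,
    pair_name = sprintf("diatomic_%g_%g", k1, k2),
    T = T
  ), class = "hybrid_system")
  sys$restraints <- build_restraints(sys, T = T)
  sys$E1 <- toy_model(elements, bonds1, atoms = 1:2, id = "E1")
  sys$E2 <- toy_model(elements, bonds2, atoms = 1:2, id = "E2")
  t1 <- .bond_type(element, element, 1L)
  t2 <- .bond_type(element, element, 2L)
  theta <- potential_parameters(list(
    bond_k = stats::setNames(c(k1, k2), c(t1, t2)),
    bond_r0 = stats::setNames(c(r0, r0), c(t1, t2)),
    bond_D = stats::setNames(c(0, 0), c(t1, t2)),
    angle_k = numeric(0), angle_theta0 = numeric(0),
    rep_A = c(global = 0), rep_rho = c(global = 0.35)))
  list(system = sys,
       theta = theta,
       coords0 = rbind(c(0, 0, 0), c(r0, 0, 0)),
       analytic_dG = 0.5 * kBT(T) * log(k2 / k1))
}
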