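# Ideal-gas RRHO / quasi-RRHO thermochemistry: numerical mass-weighted
# Hessian with translation/rotation projection, harmonic-oscillator and
# free-rotor vibrational terms, symmetry-number rotation, graph-
# automorphism degeneracy, Boltzmann-weighted multi-minimum free energies
# and thermodynamic-cycle assembly.

#' Vibrational frequencies from a numerical Hessian
#'
#' Central-difference Hessian of the supplied gradient, symmetrized,
#' mass-weighted, with the 6 (5 for linear molecules, 3 for atoms)
#' translational/rotational directions projected out.  Imaginary modes are
#' returned as negative wavenumbers; a mode below -10 cm^-1 means the
#' geometry is not a minimum and raises an error unless `on_imaginary =
#' "keep"`.
#'
#' @param x_min minimized coordinates (n x 3, angstrom).
#' @param gr gradient function(x) -> n x 3 (kcal/mol/A).
#' @param masses atom masses (amu).
#' @param step finite-difference step (angstrom).
#' @param on_imaginary "error" (default) or "keep".
#' @return numeric vector of wavenumbers (cm^-1), ascending.
#' @export
hessian_frequencies <- function(x_min, gr, masses, step = 5e-3,
                                on_imaginary = c("error", "keep")) {
  on_imaginary <- match.arg(on_imaginary)
  n <- nrow(x_min)
  if (n == 1L) return(numeric(0))
  H <- matrix(0, 3 * n, 3 * n)
  for (a in seq_len(n)) {
    for (d in 1:3) {
      xp <- x_min; xp[a, d] <- xp[a, d] + step
      xm <- x_min; xm[a, d] <- xm[a, d] - step
      H[, 3 * (a - 1) + d] <- as.vector(t(gr(xp) - gr(xm))) / (2 * step)
    }
  }
  H <- (H + t(H)) / 2
  minv <- rep(1 / sqrt(masses), each = 3)
  Hmw <- H * outer(minv, minv)
  # projection vectors: rigid translations and rotations about the COM
  sm <- rep(sqrt(masses), each = 3)
  com <- colSums(x_min * masses) / sum(masses)
  xc <- sweep(x_min, 2, com)
  P <- matrix(0, 3 * n, 6)
  for (d in 1:3) P[seq(d, 3 * n, by = 3), d] <- sqrt(masses)
  axes <- diag(3)
  for (d in 1:3) {
    rot <- t(vapply(seq_len(n), function(a)
      crossprod_vec(axes[d, ], xc[a, ]) * sqrt(masses[a]), numeric(3)))
    P[, 3 + d] <- as.vector(t(rot))
  }
  qr_P <- qr(P)
  rank <- qr_P$rank                 # 5 for linear, 6 otherwise, 3 for atom
  Q <- qr.Q(qr_P)[, seq_len(rank), drop = FALSE]
  proj <- diag(3 * n) - Q %*% t(Q)
  Hp <- proj %*% Hmw %*% proj
  ev <- eigen(Hp, symmetric = TRUE)$values
  # drop the `rank` projected-out modes: those closest to zero
  ev <- sort(ev[order(abs(ev))][-seq_len(rank)])
  freqs <- sign(ev) * sqrt(abs(ev) * CONST$hessian_unit) /
    (2 * pi * CONST$c_cm)
  if (on_imaginary == "error" && any(freqs < -10))
    stopf("not a minimum: imaginary mode at %.1f cm^-1", min(freqs))
  freqs
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# principal moments of inertia, amu A^2
.inertia_moments <- function(masses, coords) {
  com <- colSums(coords * masses) / sum(masses)
  xc <- sweep(coords, 2, com)
  I <- matrix(0, 3, 3)
  for (a in seq_along(masses)) {
    r <- xc[a, ]
    I <- I + masses[a] * (sum(r^2) * diag(3) - outer(r, r))
  }
  sort(eigen(I, symmetric = TRUE)$values)
}

#' Ideal-gas (quasi-)RRHO thermochemistry for one conformation
#'
#' Translational, rigid-rotor rotational (divided by the external symmetry
#' number) and vibrational contributions to the standard-state gas-phase
#' Gibbs free energy.  Harmonic modes below `free_rotor_cutoff` (strict
#' "<") are treated as free rotors: their entropy is replaced by the
#' free-rotor entropy and they contribute neither zero-point energy nor
#' harmonic thermal energy.  `vibration_model = "classical"` substitutes
#' the classical-oscillator partition function for every harmonic mode
#' (no ZPE); this is the right reference when validating against classical
#' molecular-dynamics free energies.
#'
#' @param freqs wavenumbers (cm^-1), all > 0 (error on imaginary input).
#' @param masses atom masses (amu).
#' @param coords geometry (n x 3), for the inertia tensor.
#' @param T temperature (K).
#' @param p pressure (atm).
#' @param sigma_ext external (rotational) symmetry number.
#' @param free_rotor_cutoff wavenumber threshold (cm^-1) for the
#'   free-rotor treatment.
#' @param degeneracy graph-automorphism degeneracy D.
#' @param use_degeneracy add the -RT ln D term (off by default).
#' @param E_elec electronic (potential) energy at the minimum, kcal/mol.
#' @param vibration_model "quantum" (default) or "classical".
#' @return list of class `thermo_result`: `G` (kcal/mol), `zpe`,
#'   `G_thermal`, `S` (cal/mol/K breakdown), `freqs`, `free_rotor_modes`,
#'   `sigma_ext`, `D`, `T`, `p`.
#' @export
rrho_free_energy <- function(freqs, masses, coords, T = 300, p = 1,
                             sigma_ext = 1, free_rotor_cutoff = 15,
                             degeneracy = 1L, use_degeneracy = FALSE,
                             E_elec = 0,
                             vibration_model = c("quantum", "classical")) {
  vibration_model <- match.arg(vibration_model)
  if (any(freqs <= 0))
    stopf("imaginary or zero frequency in input (%.2f cm^-1)", min(freqs))
  stopifnot(T > 0, p > 0, sigma_ext >= 1)
  kT_J <- CONST$kB_J * T
  R <- CONST$R_kcal
  n <- length(masses)
  # translation (Sackur-Tetrode entropy), pressure in Pa
  M_kg <- sum(masses) * CONST$amu_kg
  p_Pa <- p * 101325
  q_t <- (2 * pi * M_kg * kT_J / CONST$h_J^2)^1.5 * kT_J / p_Pa
  S_t <- R * (log(q_t) + 2.5)
  H <- 2.5 * R * T                       # translational U + pV
  S <- S_t
  # rotation
  if (n > 1) {
    I <- .inertia_moments(masses, coords) * CONST$amu_kg * 1e-20
    linear <- I[1] < 1e-6 * I[3]
    if (linear) {
      q_r <- 8 * pi^2 * I[3] * kT_J / (sigma_ext * CONST$h_J^2)
      S <- S + R * (log(q_r) + 1)
      H <- H + R * T
    } else {
      q_r <- sqrt(pi) / sigma_ext *
        sqrt((8 * pi^2 * kT_J / CONST$h_J^2)^3 * prod(I))
      S <- S + R * (log(q_r) + 1.5)
      H <- H + 1.5 * R * T
    }
  }
  # vibrations
  zpe <- 0
  fr_modes <- logical(length(freqs))
  if (length(freqs) > 0) {
    theta <- CONST$h_J * CONST$c_cm * freqs / kT_J   # beta h c nu
    hcnu <- CONST$h_J * CONST$c_cm * freqs * CONST$N_A / CONST$kcal_J
    if (vibration_model == "classical") {
      S <- S + sum(R * (1 - log(theta)))
      H <- H + length(freqs) * R * T
    } else {
      fr_modes <- freqs < free_rotor_cutoff
      ho <- !fr_modes
      if (any(ho)) {
        th <- theta[ho]
        zpe <- sum(0.5 * hcnu[ho])
        H <- H + sum(R * T * th / expm1(th))
        S <- S + sum(R * (th / expm1(th) - log(-expm1(-th))))
      }
      if (any(fr_modes)) {
        # free rotor with moment mu = h / (8 pi^2 c nu)
        mu <- CONST$h_J / (8 * pi^2 * CONST$c_cm * freqs[fr_modes])
        q_fr <- sqrt(8 * pi^3 * mu * kT_J / CONST$h_J^2)
        S <- S + sum(R * (0.5 + log(q_fr)))
        H <- H + sum(0.5 * R * T)
      }
    }
  }
  G <- E_elec + zpe + H - T * S
  D <- as.integer(degeneracy)
  if (use_degeneracy) G <- G - R * T * log(D)
  structure(list(G = G, E_elec = E_elec, zpe = zpe,
                 G_thermal = G - E_elec - zpe,
                 S_total = S * 1000,            # cal/mol/K
                 S_trans = S_t * 1000,
                 freqs = sort(freqs), free_rotor_modes = fr_modes,
                 sigma_ext = sigma_ext, D = D,
                 use_degeneracy = use_degeneracy,
                 vibration_model = vibration_model, T = T, p = p),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("<thermo_result> G = %.4f kcal/mol (ZPE %.4f, thermal %.4f) at %g K, %g atm\n",
              x$G, x$zpe, x$G_thermal, x$T, x$p))
  invisible(x)
}

#' Boltzmann-weighted free energy over minimum conformations
#'
#' `G = -RT ln sum_k exp(-G_k / RT)`, evaluated with log-sum-exp.  Always
#' at or below the lowest individual conformer free energy and dominated
#' by it when the spread is large.
#'
#' @param G_list per-conformer free energies (kcal/mol).
#' @param T temperature (K).
#' @return combined free energy (kcal/mol).
#' @export
weighted_free_energy <- function(G_list, T = 300) {
  G_list <- G_list[is.finite(G_list)]
  if (length(G_list) == 0) stopf("no finite conformer free energies")
  RT <- CONST$R_kcal * T
  -RT * logsumexp(-G_list / RT)
}

#' Graph-automorphism degeneracy of a molecule
#'
#' Counts automorphisms of the molecular graph where nodes match on
#' (element, hybridization) and edges match on bond order.
#'
#' @param mol a `taut_molecule`.
#' @return integer automorphism count (>= 1).
#' @export
graph_degeneracy <- function(mol) {
  g <- mol_graph(mol)
  vc <- .vf2_colors(mol$elements, mol$hybridization)
  ord <- mol$bonds$order
  if (!is.null(mol$bonds$aromatic)) ord[mol$bonds$aromatic] <- 4L
  ec <- if (nrow(mol$bonds) > 0) as.integer(ord) else integer(0)
  as.integer(igraph::graph.count.isomorphisms.vf2(
    g, g, vertex.color1 = vc, vertex.color2 = vc,
    edge.color1 = ec, edge.color2 = ec))
}

#' Standard-state correction for gas (1 atm) -> solution (1 M)
#'
#' `dG = RT ln(V_gas / V_solution)`; the conventional molar volume ratio
#' 24.46 (ideal gas at 298.15 K over 1 L/mol) gives the usual
#' 1.89 kcal/mol at 298.15 K.
#'
#' @param T temperature (K).
#' @param volume_ratio molar volume ratio.
#' @return correction in kcal/mol.
#' @export
standard_state_correction <- function(T = 298.15, volume_ratio = 24.46) {
  stopifnot(T > 0, volume_ratio > 0)
  CONST$R_kcal * T * log(volume_ratio)
}

#' Assemble the solution-phase tautomeric free energy difference
#'
#' Thermodynamic cycle: `d_t G_solv = [G_gas(t2) + dG_S(t2)] -
#' [G_gas(t1) + dG_S(t1)]`, with the transfer free energies supplied
#' externally (e.g. from a continuum solvation calculation).
#'
#' @param G_gas length-2 numeric: gas-phase standard free energies of
#'   tautomer 1 and 2 (kcal/mol).
#' @param dG_transfer length-2 numeric: transfer free energies (kcal/mol).
#' @return tautomeric free energy difference in solution (kcal/mol).
#' @export
assemble_solution_cycle <- function(G_gas, dG_transfer = c(0, 0)) {
  if (length(G_gas) != 2 || length(dG_transfer) != 2 ||
      any(!is.finite(c(G_gas, dG_transfer))))
    stopf("need finite gas-phase and transfer terms for both tautomers")
  (G_gas[2] + dG_transfer[2]) - (G_gas[1] + dG_transfer[1])
}

#' Single-minimum thermochemistry of one potential model
#'
#' Convenience wrapper: minimize under the model, compute frequencies and
#' the (quasi-)RRHO free energy.
#'
#' @param model a potential model.
#' @param theta parameters.
#' @param coords0 starting geometry.
#' @param masses atom masses (amu).
#' @param ... passed on to [rrho_free_energy()].
#' @return a `thermo_result` with the minimized geometry attached.
#' @export
model_thermo <- function(model, theta, coords0, masses, ...) {
  force <- compile_model_force(model, theta)
  mn <- minimize_coords(coords0,
                        fn = function(x) force(x)$energy,
                        gr = function(x) force(x)$grad,
                        tol = 1e-5)
  gr <- function(x) force(x)$grad
  freqs <- hessian_frequencies(mn$coords, gr, masses)
  # torsion-free internal rotations of the bonded field can come out as
  # numerically-zero modes; drop them rather than feed 0 to the oscillator
  n_zero <- sum(freqs <= 0.5)
  freqs <- freqs[freqs > 0.5]
  res <- rrho_free_energy(freqs, masses, mn$coords, E_elec = mn$energy, ...)
  res$n_zero_modes <- n_zero
  res$coords <- mn$coords
  res
}
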