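# Configuration sampling: local minimization, BAOAB Langevin dynamics in
# package units (A, kcal/mol, amu, fs), statistical-inefficiency thinning,
# and the per-lambda alchemical sampling protocol.

#' Minimize coordinates under an energy/gradient function
#'
#' L-BFGS-B with restarts until the gradient max-norm meets `tol`.  The
#' returned geometry never has higher energy than the input.
#'
#' @param x0 starting coordinates (n x 3).
#' @param fn function(x) -> energy (kcal/mol).
#' @param gr function(x) -> n x 3 gradient.
#' @param tol gradient max-norm tolerance, kcal/mol/A.
#' @param max_rounds L-BFGS-B restarts before giving up.
#' @return list with `coords`, `energy`, `grad_norm`, `converged`.
#' @export
minimize_coords <- function(x0, fn, gr, tol = 1e-3, max_rounds = 20L) {
  n <- nrow(x0)
  e0 <- fn(x0)
  if (!is.finite(e0)) stopf("non-finite starting energy in minimization")
  par <- as.vector(x0)
  ofn <- function(p) fn(matrix(p, n, 3))
  ogr <- function(p) as.vector(gr(matrix(p, n, 3)))
  for (round in seq_len(max_rounds)) {
    res <- stats::optim(par, ofn, ogr, method = "L-BFGS-B",
                        control = list(maxit = 1000L, factr = 1,
                                       pgtol = tol / 5))
    par <- res$par
    gnorm <- max(abs(ogr(par)))
    if (gnorm <= tol) {
      x <- matrix(par, n, 3)
      if (res$value > e0) return(list(coords = x0, energy = e0,
                                      grad_norm = max(abs(ogr(as.vector(x0)))),
                                      converged = TRUE))
      return(list(coords = x, energy = res$value, grad_norm = gnorm,
                  converged = TRUE))
    }
  }
  stopf("minimization did not reach gradient tolerance %g (best %g)",
        tol, gnorm)
}

# minimize under the alchemical Hamiltonian at fixed lambda
minimize_system <- function(x0, system, lam, theta, tol = 1e-3) {
  force <- compile_alchemical_force(system, theta, lam)
  minimize_coords(
    x0,
    fn = function(x) force(x)$energy,
    gr = function(x) force(x)$grad,
    tol = tol)
}

#' Run BAOAB Langevin dynamics
#'
#' Splitting per step: half-kick (B), half-drift (A), Ornstein-Uhlenbeck
#' velocity refresh (O), half-drift (A), half-kick (B).  Initial velocities
#' are Maxwell-Boltzmann at the run temperature.  The same seed yields a
#' bitwise-identical trajectory.
#'
#' @param x0 starting coordinates (n x 3, angstrom).
#' @param force function(x) -> list(energy, grad) for the sampled
#'   Hamiltonian.
#' @param masses atom masses (amu).
#' @param T temperature (K).
#' @param gamma collision rate (1/ps).
#' @param dt time step (fs).
#' @param n_steps number of integration steps.
#' @param seed RNG seed for velocity initialization and OU noise.
#' @param stride store every `stride`-th frame.
#' @param energy_cap abort when |E| exceeds this (divergence guard).
#' @return object of class `trajectory`: `frames` (n x 3 x n_stored),
#'   `energies`, and the protocol metadata.
#' @export
run_langevin <- function(x0, force, masses, T = 300, gamma = 10, dt = 0.5,
                         n_steps = 1000L, seed = 1L, stride = 10L,
                         energy_cap = 1e8) {
  n <- nrow(x0)
  stopifnot(length(masses) == n)
  kT <- if (T == 0) 0 else kBT(T)   # T = 0: deterministic dissipative limit
  au <- CONST$accel_unit
  g_fs <- gamma / 1000          # 1/ps -> 1/fs
  c1 <- exp(-g_fs * dt)
  sd_ou <- sqrt((1 - c1^2) * kT / masses * au)     # per-atom, A/fs
  sd_mb <- sqrt(kT / masses * au)
  n_stored <- n_steps %/% stride
  frames <- array(NA_real_, c(n, 3, n_stored))
  energies <- numeric(n_stored)
  with_seed(seed, {
    v <- matrix(stats::rnorm(n * 3), n, 3) * sd_mb
    x <- x0
    fg <- force(x)
    s <- 0L
    for (step in seq_len(n_steps)) {
      v <- v - (0.5 * dt * au) * fg$grad / masses
      x <- x + (0.5 * dt) * v
      v <- c1 * v + matrix(stats::rnorm(n * 3), n, 3) * sd_ou
      x <- x + (0.5 * dt) * v
      fg <- force(x)
      if (!is.finite(fg$energy) || abs(fg$energy) > energy_cap)
        stopf("energy diverged at step %d (E = %g)", step, fg$energy)
      v <- v - (0.5 * dt * au) * fg$grad / masses
      if (step %% stride == 0L) {
        s <- s + 1L
        frames[, , s] <- x
        energies[s] <- fg$energy
      }
    }
  })
  structure(list(frames = frames, energies = energies, T = T,
                 gamma = gamma, dt = dt, n_steps = n_steps, seed = seed,
                 stride = stride),
            class = "trajectory")
}

#' Statistical inefficiency of a correlated series
#'
#' `g = 1 + 2 sum_t (1 - t/T) rho_t`, truncating the autocorrelation sum at
#' its first non-positive term.
#'
#' @param x numeric series.
#' @return statistical inefficiency g >= 1.
#' @export
statistical_inefficiency <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0 || !is.finite(stats::sd(x)))
    stopf("constant or degenerate series: autocorrelation undefined")
  xc <- x - mean(x)
  v <- mean(xc^2)
  g <- 1
  for (t in seq_len(n - 1L)) {
    rho <- mean(xc[1:(n - t)] * xc[(1 + t):n]) / v
    if (rho <= 0) break
    g <- g + 2 * (1 - t / n) * rho
  }
  max(g, 1)
}

#' Thin a trajectory to decorrelated snapshots
#'
#' Estimates the statistical inefficiency of the stored energy series,
#' keeps every ceiling(g)-th frame, then evenly subsamples to `n_target`.
#'
#' @param traj a `trajectory`.
#' @param n_target number of snapshots wanted.
#' @param burnin_fraction initial fraction of stored frames discarded
#'   before decorrelation.
#' @return list with `frames` (n x 3 x n_target), `energies`, `indices`
#'   (into the stored frames), and `g`.
#' @export
thin_snapshots <- function(traj, n_target = 300L, burnin_fraction = 0.1) {
  e <- traj$energies
  n_stored <- length(e)
  first <- max(1L, floor(n_stored * burnin_fraction) + 1L)
  keep0 <- first:n_stored
  g <- statistical_inefficiency(e[keep0])
  dec <- keep0[seq(1L, length(keep0), by = max(1L, ceiling(g)))]
  if (length(dec) < n_target)
    stopf(paste0("only %d decorrelated frames available (need %d): ",
                 "run longer or store more frames"),
          length(dec), n_target)
  idx <- dec[unique(round(seq(1L, length(dec), length.out = n_target)))]
  list(frames = traj$frames[, , idx, drop = FALSE],
       energies = traj$energies[idx], indices = idx, g = g)
}

#' Default alchemical sampling protocol
#'
#' Production defaults follow the reference protocol: 11 equidistant
#' lambda states including both endpoints, 200 ps of BAOAB Langevin
#' dynamics per state at 300 K (0.5 fs step, 10/ps collision rate),
#' 5 replicates, 300 decorrelated snapshots per state.  Tests and the
#' bundled benchmarks use much shorter runs.
#'
#' @param n_lambda number of lambda states.
#' @param n_steps MD steps per state.
#' @param T temperature (K).
#' @param gamma collision rate (1/ps).
#' @param dt time step (fs).
#' @param stride frame-storage stride.
#' @param n_snapshots decorrelated snapshots per state.
#' @param n_replicates independent repeats.
#' @param burnin_fraction stored frames discarded before thinning.
#' @param minimize_tol gradient tolerance for the pre-MD minimization.
#' @return list of class `sampling_protocol`.
#' @export
sampling_protocol <- function(n_lambda = 11L, n_steps = 400000L, T = 300,
                              gamma = 10, dt = 0.5, stride = 50L,
                              n_snapshots = 300L, n_replicates = 5L,
                              burnin_fraction = 0.1, minimize_tol = 1e-3) {
  structure(list(n_lambda = as.integer(n_lambda),
                 n_steps = as.integer(n_steps), T = T, gamma = gamma,
                 dt = dt, stride = as.integer(stride),
                 n_snapshots = as.integer(n_snapshots),
                 n_replicates = as.integer(n_replicates),
                 burnin_fraction = burnin_fraction,
                 minimize_tol = minimize_tol),
            class = "sampling_protocol")
}

#' Sample the alchemical path for a hybrid system
#'
#' For each replicate and each lambda state: (re)place the dummy hydrogen,
#' minimize under that state's Hamiltonian, run BAOAB Langevin dynamics,
#' and thin to decorrelated snapshots.  All child seeds derive
#' deterministically from `seed`, so the full campaign is reproducible
#' end to end.
#'
#' @param system a `hybrid_system` (or benchmark system of the same shape).
#' @param theta potential parameters.
#' @param coords0 starting coordinates for the superset atoms (the dummy
#'   row may be missing or arbitrary; it is placed here).
#' @param protocol a [sampling_protocol()].
#' @param seed master seed.
#' @return object of class `sampled_states`: `lambdas`, `replicates` (each
#'   with per-state snapshot arrays and seeds), `protocol`.
#' @export
sample_alchemical_path <- function(system, theta, coords0,
                                   protocol = sampling_protocol(),
                                   seed = 1L) {
  lambdas <- seq(0, 1, length.out = protocol$n_lambda)
  masses <- system$masses
  n_sup <- length(system$elements)
  seeds <- matrix(derive_seeds(seed, protocol$n_replicates *
                                 protocol$n_lambda * 2L),
                  nrow = protocol$n_replicates)
  replicates <- vector("list", protocol$n_replicates)
  for (r in seq_len(protocol$n_replicates)) {
    snaps <- vector("list", protocol$n_lambda)
    state_seeds <- integer(protocol$n_lambda)
    for (m in seq_along(lambdas)) {
      lam <- lambdas[m]
      s_place <- seeds[r, 2 * m - 1L]
      s_md <- seeds[r, 2 * m]
      x <- coords0
      if (!is.null(system$dummy1)) {
        x <- place_dummy_hydrogen(system, coords0, theta,
                                  seed = s_place)$coords
      } else if (nrow(x) < n_sup) {
        stopf("coords0 must cover all %d atoms", n_sup)
      }
      mn <- tryCatch(
        minimize_system(x, system, lam, theta, tol = protocol$minimize_tol),
        error = function(e) stopf("lambda = %.3f: %s", lam,
                                  conditionMessage(e)))
      # a window can draw an unluckily long correlation time; extend it
      # (deterministically) rather than aborting the whole campaign
      force <- compile_alchemical_force(system, theta, lam)
      n_steps <- protocol$n_steps
      th <- NULL
      for (attempt in 1:3) {
        traj <- tryCatch(
          run_langevin(mn$coords, force = force,
                       masses = masses, T = protocol$T,
                       gamma = protocol$gamma, dt = protocol$dt,
                       n_steps = n_steps,
                       seed = if (attempt == 1) s_md else
                         derive_seeds(s_md + attempt, 1L),
                       stride = protocol$stride),
          error = function(e) stopf("lambda = %.3f: %s", lam,
                                    conditionMessage(e)))
        th <- tryCatch(
          thin_snapshots(traj, n_target = protocol$n_snapshots,
                         burnin_fraction = protocol$burnin_fraction),
          error = function(e) NULL)
        if (!is.null(th)) break
        n_steps <- n_steps * 2L
      }
      if (is.null(th))
        stopf("lambda = %.3f: too few decorrelated frames even after %d steps",
              lam, n_steps %/% 2L)
      snaps[[m]] <- th
      state_seeds[m] <- s_md
    }
    replicates[[r]] <- list(snapshots = snaps, seeds = state_seeds)
  }
  structure(list(lambdas = lambdas, replicates = replicates,
                 protocol = protocol, master_seed = seed,
                 n_atoms = n_sup),
            class = "sampled_states")
}

#' @export
print.sampled_states <- function(x, ...) {
  cat(sprintf("<sampled_states> %d lambda states, %d replicates, %d snapshots/state\n",
              length(x$lambdas), length(x$replicates),
              dim(x$replicates[[1]]$snapshots[[1]]$frames)[3]))
  invisible(x)
}
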