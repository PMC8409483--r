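# Multistate reweighting: the N x M reduced-potential matrix, the MBAR
# self-consistent solver (self-consistent iteration with Newton
# acceleration, asymptotic covariance via the SVD identity), replicate
# convergence filtering, and importance-sampling reweighting of the
# estimate to perturbed potential parameters with ESS diagnostics.

#' Reduced-potential matrix for one replicate of sampled states
#'
#' `u[n, m] = beta * (E_lambda_m(x_n; theta) + E_restraint(x_n))`, rows
#' ordered by origin state then time.  Endstate energies and restraint
#' energies are cached so the matrix can be re-formed cheaply at new
#' lambda grids or perturbed parameters.  Gas-phase NVT: no
#' pressure-volume term enters the reduced potential.
#'
#' @param states a `sampled_states` object.
#' @param system the hybrid system the states were sampled from.
#' @param theta potential parameters.
#' @param T temperature (K).
#' @param replicate which replicate to use.
#' @return object of class `reduced_potentials` with fields `u` (N x M),
#'   `N_m`, `beta`, `lambdas`, `X` (stacked snapshots), `E1`, `E2`, `Er`.
#' @export
reduced_potential_matrix <- function(states, system, theta, T = 300,
                                     replicate = 1L) {
  rep <- states$replicates[[replicate]]
  M <- length(states$lambdas)
  N_m <- vapply(rep$snapshots, function(s) dim(s$frames)[3], integer(1))
  n_sup <- dim(rep$snapshots[[1]]$frames)[1]
  X <- array(NA_real_, c(n_sup, 3, sum(N_m)))
  at <- 0L
  for (m in seq_len(M)) {
    nm <- N_m[m]
    X[, , at + seq_len(nm)] <- rep$snapshots[[m]]$frames
    at <- at + nm
  }
  beta <- 1 / kBT(T)
  E1 <- pot_energy_many(system$E1, X, theta)
  E2 <- pot_energy_many(system$E2, X, theta)
  Er <- flat_bottom_restraint_many(X, system$restraints)
  u <- beta * (outer(E1, 1 - states$lambdas) + outer(E2, states$lambdas) +
                 Er)
  bad <- which(!is.finite(u), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("non-finite reduced potential at sample %d, state %d",
          bad[1, 1], bad[1, 2])
  structure(list(u = u, N_m = N_m, beta = beta, lambdas = states$lambdas,
                 origin = rep(seq_len(M), N_m), X = X,
                 E1 = E1, E2 = E2, Er = Er, T = T),
            class = "reduced_potentials")
}

# core MBAR solve on a plain matrix; returns f (f[1] = 0) and log-denominators
.mbar_solve_core <- function(u, N_m, tol = 1e-10, max_iter = 2000L) {
  M <- ncol(u)
  act <- which(N_m > 0)
  logN <- log(N_m[act])
  f <- numeric(M)
  log_denom <- function(f) {
    # logsumexp over active states of log N_k + f_k - u[, k]
    Z <- sweep(-u[, act, drop = FALSE], 2, logN + f[act], "+")
    logsumexp_rows(Z)
  }
  grad_norm <- function(f, ld) {
    W <- exp(sweep(-u[, act, drop = FALSE] - ld, 2, f[act], "+"))
    max(abs(N_m[act] * (colSums(W) - 1)))
  }
  ld <- log_denom(f)
  for (it in seq_len(max_iter)) {
    # self-consistent update
    f_new <- -apply(-u - ld, 2, logsumexp)
    f_new <- f_new - f_new[1]
    # Newton acceleration on the active states once close
    if (max(abs(f_new - f)) < 0.5 && length(act) > 1) {
      Wa <- exp(sweep(-u[, act, drop = FALSE] - ld, 2, f[act], "+"))
      omega <- sweep(Wa, 2, N_m[act], "*")
      g <- colSums(omega) - N_m[act]
      H <- diag(colSums(omega), nrow = length(act)) - crossprod(omega)
      idx <- seq_along(act)[-1]
      step <- tryCatch(solve(H[idx, idx, drop = FALSE], g[idx]),
                       error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) {
        f_try <- f
        f_try[act[idx]] <- f[act[idx]] - step
        ld_try <- log_denom(f_try)
        if (grad_norm(f_try, ld_try) < grad_norm(f_new, log_denom(f_new))) {
          f_new <- f_try
          f_new <- f_new - f_new[1]
        }
      }
    }
    ld_new <- log_denom(f_new)
    conv <- grad_norm(f_new, ld_new)
    done <- conv < tol * max(1, max(N_m))
    delta <- max(abs(f_new - f))
    f <- f_new; ld <- ld_new
    if (done || delta < 1e-14) break
  }
  if (grad_norm(f, ld) > 1e-6 * max(1, max(N_m)))
    stopf("MBAR did not converge (residual %g)", grad_norm(f, ld))
  # recompute f for all (virtual) states from the converged mixture
  f_all <- -apply(-u - ld, 2, logsumexp)
  f_all <- f_all - f_all[1]
  list(f = f_all, log_denom = ld)
}

# asymptotic covariance of the reduced free energies (SVD identity)
.mbar_covariance <- function(u, N_m, f, log_denom) {
  W <- exp(sweep(-u - log_denom, 2, f, "+"))   # N x M, columns sum to 1
  sv <- svd(W)
  S <- diag(sv$d, nrow = length(sv$d))
  V <- sv$v
  Ndiag <- diag(N_m, nrow = length(N_m))
  inner <- diag(nrow(S)) - S %*% t(V) %*% Ndiag %*% V %*% S
  isv <- svd(inner)
  pos <- isv$d > max(isv$d) * 1e-12
  inner_pinv <- isv$v[, pos, drop = FALSE] %*%
    diag(1 / isv$d[pos], nrow = sum(pos)) %*% t(isv$u[, pos, drop = FALSE])
  V %*% S %*% inner_pinv %*% S %*% t(V)
}

#' Solve the MBAR equations for a reduced-potential matrix
#'
#' Self-consistent iteration with Newton acceleration, anchored at
#' `f[1] = 0`; asymptotic uncertainty of the endpoint difference from the
#' weight-matrix covariance identity.  A complete lack of overlap between
#' neighbouring states is reported as a warning flag on the estimate.
#'
#' @param rpm a `reduced_potentials` object.
#' @param tol gradient tolerance of the self-consistent equations.
#' @return object of class `fe_estimate`: `f_hat` (dimensionless),
#'   `dG` = (f_M - f_1)/beta in kcal/mol, `sigma`, `ess` per state,
#'   `overlap_warning`.
#' @export
solve_mbar <- function(rpm, tol = 1e-10) {
  sol <- .mbar_solve_core(rpm$u, rpm$N_m, tol = tol)
  M <- ncol(rpm$u)
  Theta <- .mbar_covariance(rpm$u, rpm$N_m, sol$f, sol$log_denom)
  var_dG <- Theta[1, 1] + Theta[M, M] - 2 * Theta[1, M]
  W <- exp(sweep(-rpm$u - sol$log_denom, 2, sol$f, "+"))
  ess <- 1 / colSums(W^2)
  # neighbour-overlap heuristic: effective samples contributing to both of
  # a pair of adjacent states
  ov <- vapply(seq_len(M - 1), function(m) {
    sum(pmin(W[, m], W[, m + 1]))
  }, numeric(1))
  overlap_warning <- any(ov < 1e-6)
  sigma <- sqrt(max(var_dG, 0)) / rpm$beta
  if (overlap_warning) sigma <- max(sigma, 10 / rpm$beta)
  structure(list(f_hat = sol$f, log_denom = sol$log_denom,
                 dG = (sol$f[M] - sol$f[1]) / rpm$beta,
                 sigma = sigma,
                 ess = ess, overlap_warning = overlap_warning,
                 beta = rpm$beta, lambdas = rpm$lambdas,
                 N = sum(rpm$N_m)),
            class = "fe_estimate")
}

#' @export
print.fe_estimate <- function(x, ...) {
  cat(sprintf("<fe_estimate> dG = %.4f +/- %.4f kcal/mol (%d states, N = %d)%s\n",
              x$dG, x$sigma, length(x$f_hat), x$N,
              if (isTRUE(x$overlap_warning)) "  [overlap warning]" else ""))
  invisible(x)
}

#' Replicate convergence filter
#'
#' Passes when the sample standard deviation of the endpoint free energy
#' across independent replicates is strictly below `threshold`.
#'
#' @param dGs numeric vector of per-replicate endpoint free energies
#'   (kcal/mol), or a list of `fe_estimate` objects.
#' @param threshold kcal/mol.
#' @return list with `pass` and `std`.
#' @export
replicate_convergence_filter <- function(dGs, threshold = 0.3) {
  if (is.list(dGs)) dGs <- vapply(dGs, function(e) e$dG, numeric(1))
  if (length(dGs) < 2) stopf("need at least 2 replicates")
  s <- stats::sd(dGs)
  list(pass = s < threshold, std = s)
}

#' Reweight an MBAR estimate to perturbed potential parameters
#'
#' Appends two zero-sample virtual states, the physical endstates
#' evaluated with `theta_star`, to the converged mixture and computes the
#' perturbed endpoint free energy from the fixed mixture weights, together
#' with the Kish effective sample size of each virtual state and the
#' analytic gradient of the perturbed free energy with respect to the
#' parameters (the importance-weighted average of the parameter gradient
#' of the endstate energies).
#'
#' @param rpm the `reduced_potentials` the reference solution used.
#' @param est the converged `fe_estimate` at the reference parameters.
#' @param system the hybrid system.
#' @param theta_star perturbed parameters.
#' @param want_gradient also return d(dG)/d(theta_star) as a flat named
#'   vector.
#' @return object of class `reweighted_estimate`: `dG` (kcal/mol),
#'   `sigma`, `ess` (length 2: lambda = 0, 1), `ess_degradation`,
#'   `resample_flag` (TRUE when sigma exceeds 1 kT, or when the
#'   perturbation has cost a virtual state more than half of the
#'   effective samples the corresponding unperturbed endpoint had --
#'   importance sampling degrades past that point even while the
#'   asymptotic uncertainty still looks small), and optionally `grad`.
#' @export
reweight_free_energy <- function(rpm, est, system, theta_star,
                                 want_gradient = FALSE) {
  beta <- rpm$beta
  E1s <- pot_energy_many(system$E1, rpm$X, theta_star)
  E2s <- pot_energy_many(system$E2, rpm$X, theta_star)
  u0 <- beta * (E1s + rpm$Er)
  u1 <- beta * (E2s + rpm$Er)
  ld <- est$log_denom
  f0 <- -logsumexp(-u0 - ld)
  f1 <- -logsumexp(-u1 - ld)
  w0 <- exp(-u0 - ld + f0)
  w1 <- exp(-u1 - ld + f1)
  ess <- c(1 / sum(w0^2), 1 / sum(w1^2))
  if (any(ess < 2))
    stopf("resample required: effective sample size %.2f at a virtual state",
          min(ess))
  u_aug <- cbind(rpm$u, u0, u1)
  f_aug <- c(est$f_hat, f0, f1) - est$f_hat[1]
  N_aug <- c(rpm$N_m, 0L, 0L)
  Theta <- .mbar_covariance(u_aug, N_aug, f_aug, ld)
  M2 <- ncol(u_aug)
  var_dG <- Theta[M2 - 1, M2 - 1] + Theta[M2, M2] - 2 * Theta[M2 - 1, M2]
  sigma <- sqrt(max(var_dG, 0)) / beta
  ess_ref <- est$ess[c(1L, length(est$ess))]
  degradation <- min(ess / ess_ref)
  out <- structure(list(
    dG = (f1 - f0) / beta,
    sigma = sigma,
    ess = ess,
    ess_degradation = degradation,
    f_virtual = c(f0, f1) - est$f_hat[1],
    resample_flag = sigma > kBT(rpm$T) || degradation < 0.5,
    beta = beta
  ), class = "reweighted_estimate")
  if (want_gradient) {
    G1 <- pot_pgrad_many(system$E1, rpm$X, theta_star)
    G2 <- pot_pgrad_many(system$E2, rpm$X, theta_star)
    out$grad <- as.vector(G2 %*% w1 - G1 %*% w0)
    names(out$grad) <- rownames(G1)
  }
  out
}

#' @export
print.reweighted_estimate <- function(x, ...) {
  cat(sprintf("<reweighted_estimate> dG = %.4f +/- %.4f kcal/mol, ESS = %.1f/%.1f%s\n",
              x$dG, x$sigma, x$ess[1], x$ess[2],
              if (x$resample_flag) "  [resample advised]" else ""))
  invisible(x)
}

#' Estimate a pair's alchemical free energy with replicates
#'
#' Full protocol for one hybrid system: sample the path, form the reduced
#' potentials, solve MBAR per replicate, and apply the replicate
#' convergence filter.
#'
#' @param system a `hybrid_system`.
#' @param theta potential parameters.
#' @param coords0 starting coordinates.
#' @param protocol a [sampling_protocol()].
#' @param seed master seed.
#' @param threshold convergence-filter threshold (kcal/mol).
#' @return list with `dG` (replicate mean), `std`, `pass`, `estimates`,
#'   `states`, `rpms`.
#' @export
estimate_pair_free_energy <- function(system, theta, coords0,
                                      protocol = sampling_protocol(),
                                      seed = 1L, threshold = 0.3) {
  states <- sample_alchemical_path(system, theta, coords0, protocol, seed)
  ests <- list()
  rpms <- list()
  for (r in seq_along(states$replicates)) {
    rpms[[r]] <- reduced_potential_matrix(states, system, theta,
                                          T = protocol$T, replicate = r)
    ests[[r]] <- solve_mbar(rpms[[r]])
  }
  dGs <- vapply(ests, function(e) e$dG, numeric(1))
  filt <- if (length(dGs) >= 2) replicate_convergence_filter(dGs, threshold)
          else list(pass = NA, std = NA_real_)
  list(dG = mean(dGs), std = filt$std, pass = filt$pass,
       estimates = ests, states = states, rpms = rpms)
}
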