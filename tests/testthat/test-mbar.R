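# MBAR solver, uncertainties, replicate filter and reweighting, validated
# on exact Gaussian samples (no dynamics involved)

# reduced potentials for the 1-particle harmonic pair from exact samples
gaussian_rpm <- function(k1 = 1, k2 = 4, n_lambda = 5, n_per_state = 1500,
                         seed = 2) {
  hp <- make_harmonic_pair(1, k1, k2, T = T_BETA1)
  st <- gaussian_states(seq(0, 1, length.out = n_lambda), k1, k2,
                        n_per_state, beta = 1, seed = seed)
  list(rpm = reduced_potential_matrix(st, hp$system, hp$theta,
                                      T = T_BETA1),
       hp = hp)
}

test_that("two identical states give zero free energy difference", {
  g <- gaussian_rpm(k1 = 2, k2 = 2, n_lambda = 2, n_per_state = 800)
  est <- solve_mbar(g$rpm)
  expect_equal(est$dG, 0, tolerance = 1e-9)
  expect_lt(est$sigma, 0.1)
})

test_that("MBAR recovers the analytic Gaussian free energy difference", {
  g <- gaussian_rpm(k1 = 1, k2 = 4, n_lambda = 5, n_per_state = 1500)
  est <- solve_mbar(g$rpm)
  analytic <- 1.5 * log(4)          # reduced units, beta = 1
  expect_lt(abs(est$dG - analytic), 3 * est$sigma)
  expect_gt(est$sigma, 0)
  # weights of every state normalize to one
  W <- exp(sweep(-g$rpm$u - est$log_denom, 2, est$f_hat, "+"))
  expect_true(all(abs(colSums(W) - 1) < 1e-10))
  # ESS is bounded by the total sample count
  expect_true(all(est$ess <= est$N + 1e-9))
})

test_that("the two-state solution agrees with a BAR bisection oracle", {
  g <- gaussian_rpm(k1 = 1, k2 = 3, n_lambda = 2, n_per_state = 1200)
  est <- solve_mbar(g$rpm)
  u <- g$rpm$u
  from1 <- g$rpm$origin == 1
  wf <- u[from1, 2] - u[from1, 1]
  wr <- u[!from1, 1] - u[!from1, 2]
  df_bar <- bar_bisect(wf, wr)
  expect_equal(est$f_hat[2] - est$f_hat[1], df_bar, tolerance = 1e-6)
})

test_that("reversing the lambda grid negates the endpoint difference", {
  g <- gaussian_rpm(n_lambda = 4, n_per_state = 600)
  est <- solve_mbar(g$rpm)
  rev_rpm <- g$rpm
  M <- ncol(g$rpm$u)
  rev_rpm$u <- g$rpm$u[, M:1]
  rev_rpm$N_m <- g$rpm$N_m[M:1]
  rev_rpm$lambdas <- rev(1 - g$rpm$lambdas)
  est_rev <- solve_mbar(rev_rpm)
  expect_equal(est_rev$dG, -est$dG, tolerance = 1e-8)
})

test_that("complete distribution non-overlap raises the warning flag", {
  hp <- make_harmonic_pair(1, 1, 1, T = T_BETA1)
  hp$system$E2 <- well_model(1L, "k2", centre = c(60, 0, 0), n_sup = 1L)
  theta <- potential_parameters(list(well_k = c(k1 = 1, k2 = 1)))
  set.seed(8)
  fr1 <- array(rnorm(300), c(1, 3, 100))
  fr2 <- array(rnorm(300), c(1, 3, 100))
  fr2[1, 1, ] <- fr2[1, 1, ] + 60
  st <- structure(list(
    lambdas = c(0, 1),
    replicates = list(list(snapshots = list(list(frames = fr1),
                                            list(frames = fr2)),
                           seeds = c(1, 2))),
    protocol = NULL, master_seed = 8, n_atoms = 1L),
    class = "sampled_states")
  rpm <- reduced_potential_matrix(st, hp$system, theta, T = T_BETA1)
  est <- solve_mbar(rpm)
  expect_true(est$overlap_warning)
  expect_gt(est$sigma, 5)           # deliberately inflated
})

test_that("replicate convergence filter applies a strict threshold", {
  flat <- replicate_convergence_filter(rep(1, 5))
  expect_true(flat$pass)
  expect_equal(flat$std, 0)
  # sample std exactly at the threshold fails (strict less-than)
  at <- replicate_convergence_filter(c(0, 0.3 * sqrt(2)), threshold = 0.3)
  expect_equal(at$std, 0.3, tolerance = 1e-12)
  expect_false(at$pass)
  wide <- replicate_convergence_filter(c(1, 1, 1, 1, 2.118),
                                       threshold = 0.3)
  expect_equal(wide$std, 0.5, tolerance = 1e-3)
  expect_false(wide$pass)
  expect_error(replicate_convergence_filter(1.0), "2 replicates")
})

test_that("reweighting at the sampling parameters is the identity", {
  g <- gaussian_rpm(n_lambda = 5, n_per_state = 800)
  est <- solve_mbar(g$rpm)
  rw <- reweight_free_energy(g$rpm, est, g$hp$system, g$hp$theta)
  expect_equal(rw$dG, est$dG, tolerance = 1e-9)
  expect_true(all(is.finite(rw$ess)))
  # a single-state mixture reduces to uniform weights and ESS = N
  g1 <- gaussian_rpm(k1 = 2, k2 = 2, n_lambda = 1, n_per_state = 500)
  est1 <- solve_mbar(g1$rpm)
  rw1 <- reweight_free_energy(g1$rpm, est1, g1$hp$system, g1$hp$theta)
  expect_equal(rw1$ess, c(500, 500), tolerance = 1e-6)
})

test_that("reweighting to a mildly perturbed stiffness matches the closed form", {
  g <- gaussian_rpm(k1 = 1, k2 = 4, n_lambda = 5, n_per_state = 1500)
  est <- solve_mbar(g$rpm)
  th_star <- potential_parameters(list(well_k = c(k1 = 1, k2 = 4.4)))
  rw <- reweight_free_energy(g$rpm, est, g$hp$system, th_star)
  analytic <- 1.5 * log(4.4)
  expect_lt(abs(rw$dG - analytic), 3 * max(rw$sigma, est$sigma))
  expect_true(all(rw$ess > 100))
  expect_false(rw$resample_flag)
})

test_that("collapsing ESS triggers the resample error", {
  g <- gaussian_rpm(k1 = 1, k2 = 4, n_lambda = 3, n_per_state = 400)
  est <- solve_mbar(g$rpm)
  th_far <- potential_parameters(list(well_k = c(k1 = 1, k2 = 4000)))
  expect_error(
    reweight_free_energy(g$rpm, est, g$hp$system, th_far),
    "resample")
})

test_that("the parameter gradient of the reweighted estimate is exact", {
  g <- gaussian_rpm(k1 = 1, k2 = 4, n_lambda = 5, n_per_state = 700)
  est <- solve_mbar(g$rpm)
  th <- potential_parameters(list(well_k = c(k1 = 1.05, k2 = 4.2)))
  rw <- reweight_free_energy(g$rpm, est, g$hp$system, th,
                             want_gradient = TRUE)
  fl <- params_flatten(th)
  h <- 1e-5
  for (nm in names(fl)) {
    fp <- fl; fp[nm] <- fp[nm] + h
    fm <- fl; fm[nm] <- fm[nm] - h
    fd <- (reweight_free_energy(g$rpm, est, g$hp$system,
                                params_unflatten(fp, th))$dG -
             reweight_free_energy(g$rpm, est, g$hp$system,
                                  params_unflatten(fm, th))$dG) / (2 * h)
    expect_equal(unname(rw$grad[nm]), fd,
                 tolerance = 1e-4 * max(1, abs(fd)), label = nm)
  }
})

test_that("reduced potentials scale with beta and interpolate by lambda", {
  g <- gaussian_rpm(n_lambda = 3, n_per_state = 50)
  hp <- g$hp
  st <- gaussian_states(c(0, 0.5, 1), 1, 4, 50, beta = 1, seed = 5)
  rpm_a <- reduced_potential_matrix(st, hp$system, hp$theta, T = T_BETA1)
  rpm_b <- reduced_potential_matrix(st, hp$system, hp$theta,
                                    T = 2 * T_BETA1)
  expect_equal(rpm_b$u, rpm_a$u / 2, tolerance = 1e-12)
  # the middle column is the mean of the endpoint columns (no restraints)
  expect_equal(rpm_a$u[, 2], (rpm_a$u[, 1] + rpm_a$u[, 3]) / 2,
               tolerance = 1e-10)
})
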