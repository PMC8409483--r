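# dataset splitting, loss machinery, optimizer plumbing

test_that("the 20:20:60 split reproduces the reference sizes", {
  nm <- sprintf("tp_%d", 1:354)
  sp <- split_dataset(nm, seed = 1)
  expect_length(sp$test, 71L)
  expect_length(sp$validation, 71L)
  expect_length(sp$train, 212L)
  expect_equal(sort(c(sp$test, sp$validation, sp$train)), sort(nm))
  # determinism and disjointness over random sizes
  for (n in c(7L, 23L, 100L)) {
    nms <- sprintf("p%d", seq_len(n))
    a <- split_dataset(nms, seed = 9)
    b <- split_dataset(nms, seed = 9)
    expect_identical(a, b)
    expect_length(intersect(a$test, a$train), 0L)
    expect_length(intersect(a$test, a$validation), 0L)
    expect_equal(length(a$test) + length(a$validation) + length(a$train),
                 n)
  }
  expect_error(split_dataset(c("a", "b")), "at least 3")
})

test_that("schedules interpolate piecewise-linearly with flat extrapolation", {
  g <- schedule(c(0, 50), c(0, 1))
  expect_equal(g(0), 0)
  expect_equal(g(25), 0.5)
  expect_equal(g(50), 1)
  expect_equal(g(400), 1)
  f <- schedule(0, 0.1)
  expect_equal(f(123), 0.1)
})

# one cached toy pair shared by the loss tests below
fix_tp <- make_toy_pair(c("C", "O"), 0)
fix_theta <- default_toy_parameters(fix_tp$system$E1, fix_tp$system$E2)
fix_pd <- prepare_training_pairs(
  list(list(name = "fix", system = fix_tp$system,
            coords0 = fix_tp$coords0, dG_exp = 0)),
  fix_theta, fast_toy_protocol(), seed = 51)[[1]]

test_that("energy regularization is zero at theta and linear in a D shift", {
  reg0 <- energy_regularization(fix_pd, fix_theta)
  expect_equal(reg0$value, 0, tolerance = 1e-12)
  # shifting every bond_D by c changes each endstate energy by
  # -(n_bonds) * c, so the per-atom MAE is n_bonds * c / n_atoms
  th2 <- fix_theta
  cshift <- 0.7
  th2$groups$bond_D <- th2$groups$bond_D + cshift
  n_at <- length(fix_pd$system$elements)
  n_b1 <- nrow(fix_pd$system$E1$bonds)
  reg <- energy_regularization(fix_pd, th2, want_gradient = TRUE)
  expect_equal(reg$value, n_b1 * cshift / n_at, tolerance = 1e-10)
  # gradient against finite differences on a couple of entries
  fl <- params_flatten(th2)
  for (nm in c(grep("bond_D", names(fl), value = TRUE)[1],
               grep("bond_k", names(fl), value = TRUE)[1])) {
    h <- 1e-5
    fp <- fl; fp[nm] <- fp[nm] + h
    fm <- fl; fm[nm] <- fm[nm] - h
    fd <- (energy_regularization(fix_pd,
                                 params_unflatten(fp, th2))$value -
             energy_regularization(fix_pd,
                                   params_unflatten(fm, th2))$value) /
      (2 * h)
    expect_equal(unname(reg$grad[nm]), fd,
                 tolerance = 1e-4 * max(0.01, abs(fd)), label = nm)
  }
  # endstates_only restricts the snapshot set but stays zero at theta
  expect_equal(energy_regularization(fix_pd, fix_theta,
                                     endstates_only = TRUE)$value, 0)
})

test_that("the pair loss reduces to the squared free-energy error", {
  rw <- reweight_free_energy(fix_pd$rpm, fix_pd$est, fix_pd$system,
                             fix_theta)
  perfect <- fix_pd
  perfect$dG_exp <- rw$dG
  expect_equal(pair_loss(perfect, fix_theta, f = 0, g = 1)$value, 0,
               tolerance = 1e-12)
  off2 <- fix_pd
  off2$dG_exp <- rw$dG - 2
  expect_equal(pair_loss(off2, fix_theta, f = 0, g = 1)$value, 4,
               tolerance = 1e-9)
  # g = 0 leaves only the regularization
  expect_equal(pair_loss(fix_pd, fix_theta, f = 1, g = 0)$value, 0,
               tolerance = 1e-12)
  # loss gradient against finite differences
  pl <- pair_loss(off2, fix_theta, f = 0.1, g = 1, want_gradient = TRUE)
  fl <- params_flatten(fix_theta)
  nm <- grep("bond_D", names(fl), value = TRUE)[2]
  h <- 1e-4
  fp <- fl; fp[nm] <- fp[nm] + h
  fm <- fl; fm[nm] <- fm[nm] - h
  fd <- (pair_loss(off2, params_unflatten(fp, fix_theta), f = 0.1,
                   g = 1)$value -
           pair_loss(off2, params_unflatten(fm, fix_theta), f = 0.1,
                     g = 1)$value) / (2 * h)
  expect_equal(unname(pl$grad[nm]), fd, tolerance = 1e-3 * max(1, abs(fd)))
})

test_that("zero learning rates leave the parameters untouched", {
  pds <- list(fix_pd, fix_pd, fix_pd)
  pds[[2]]$name <- "fix2"; pds[[3]]$name <- "fix3"
  cfg <- training_config(epochs = 2L, batch_size = 2L, lr_weights = 0,
                         lr_biases = 0, auto_resample = FALSE,
                         g_schedule = schedule(0, 1), seed = 4)
  ts <- train_parameters(pds, fix_theta, cfg)
  expect_equal(params_flatten(ts$theta_final), params_flatten(fix_theta))
})

test_that("pure regularization pulls the parameters back to the reference", {
  pds <- list(fix_pd, fix_pd, fix_pd)
  pds[[2]]$name <- "fix2"; pds[[3]]$name <- "fix3"
  start <- fix_theta
  start$groups$bond_D <- start$groups$bond_D + c(1, -1, 0.5)[
    seq_along(start$groups$bond_D)]
  reg_start <- energy_regularization(pds[[1]], start)$value
  cfg <- training_config(epochs = 40L, batch_size = 3L,
                         lr_biases = 0.02, lr_weights = 0,
                         trainable = "bond_D",
                         g_schedule = schedule(0, 0),
                         f_schedule = schedule(0, 1),
                         auto_resample = FALSE, seed = 6)
  ts <- train_parameters(pds, start, cfg,
                         split = split_dataset(c("fix", "fix2", "fix3"),
                                               ratios = c(0, 0, 1),
                                               seed = 1))
  reg_end <- energy_regularization(pds[[1]], ts$theta_final)$value
  expect_lt(reg_end, 0.3 * reg_start)
  # and the training loss decreased accordingly
  h <- ts$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[2])
})
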