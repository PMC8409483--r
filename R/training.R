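# Optimization of potential parameters against experimental tautomer free
# energies.  Free energies at perturbed parameters come from reweighting
# the fixed MBAR mixture (no resimulation inside an epoch); the loss per
# pair is a scaled squared free-energy error plus a per-atom-normalized
# energy regularization; weight-like parameter groups follow AdamW,
# bias-like groups plain SGD, mirroring the optimizer split used when
# fine-tuning the final layer of machine-learned potentials.

#' Split a pair set into test / validation / training subsets
#'
#' Shuffles with the seed; the first `round(N * ratios[1])` pairs form the
#' test set, the next `round(N * ratios[2])` the validation set, the rest
#' the training set.
#'
#' @param names character vector of pair names (or a list of objects with
#'   `$name`).
#' @param ratios test/validation/training fractions summing to 1.
#' @param seed shuffle seed.
#' @return list of class `dataset_split` with `test`, `validation`,
#'   `train`, `ratios`, `seed`.
#' @export
split_dataset <- function(names, ratios = c(0.2, 0.2, 0.6), seed = 1L) {
  if (is.list(names)) names <- vapply(names, `[[`, "", "name")
  n <- length(names)
  if (n < 3) stopf("need at least 3 pairs to split")
  stopifnot(abs(sum(ratios) - 1) < 1e-9)
  perm <- with_seed(seed, sample(names))
  n_test <- round(n * ratios[1])
  n_val <- round(n * ratios[2])
  structure(list(test = perm[seq_len(n_test)],
                 validation = perm[n_test + seq_len(n_val)],
                 train = perm[(n_test + n_val + 1):n],
                 ratios = ratios, seed = seed),
            class = "dataset_split")
}

#' Piecewise-linear epoch schedule
#'
#' @param epochs breakpoint epochs.
#' @param values values at the breakpoints (constant extrapolation).
#' @return function(epoch) -> value.
#' @export
schedule <- function(epochs, values) {
  stopifnot(length(epochs) == length(values), length(epochs) >= 1)
  if (length(epochs) == 1L) return(function(e) rep(values, length(e)))
  function(e) stats::approx(epochs, values, xout = e, rule = 2)$y
}

#' Training configuration
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size (pairs per gradient update).
#' @param lr_weights AdamW learning rate for weight-like groups
#'   (force constants).
#' @param lr_biases SGD learning rate for bias-like groups (equilibrium
#'   values, well-depth offsets).
#' @param weight_decay decoupled weight decay for the AdamW group.
#' @param trainable parameter group names and/or individual flat
#'   parameter names (`group.entry`) allowed to move (NULL = all).
#' @param g_schedule schedule for the free-energy term weight g(epoch).
#' @param f_schedule schedule for the regularization weight f(epoch).
#' @param auto_resample regenerate a pair's samples at the current
#'   parameters when reweighting fails or its effective sample size has
#'   degraded below half of the unperturbed endpoint's (an uncertainty
#'   above 1 kT alone is reported but does not trigger regeneration:
#'   fresh samples at the same protocol length cannot reduce it).
#' @param seed RNG seed for shuffling.
#' @return list of class `training_config`.
#' @export
training_config <- function(epochs = 100L, batch_size = 10L,
                            lr_weights = 0.02, lr_biases = 2e-3,
                            weight_decay = 0,
                            trainable = NULL,
                            g_schedule = schedule(c(0, 50), c(0, 1)),
                            f_schedule = schedule(0, 0.1),
                            auto_resample = TRUE,
                            seed = 1L) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_weights = lr_weights, lr_biases = lr_biases,
                 weight_decay = weight_decay, trainable = trainable,
                 g_schedule = g_schedule, f_schedule = f_schedule,
                 auto_resample = auto_resample, seed = seed),
            class = "training_config")
}

#' Sample and solve the reference state for a set of pairs
#'
#' Runs the alchemical protocol for every pair at the reference
#' parameters and caches the reduced potentials and MBAR solutions that
#' reweighting needs during training.
#'
#' @param pairs list of pair entries (`name`, `system`, `coords0`,
#'   `dG_exp`), e.g. from [make_synthetic_dataset()].
#' @param theta reference parameters (samples are drawn here).
#' @param protocol a [sampling_protocol()] (1 replicate is typical for
#'   training data).
#' @param seed master seed.
#' @param reuse_pair_seeds use each pair's own `sampling_seed` (as set by
#'   [make_synthetic_dataset()]) instead of deriving fresh ones.  For
#'   synthetic-recovery experiments this makes the reference mixture
#'   share its starting basins with the campaign that generated the
#'   "experimental" values, so the two differ only by the parameter
#'   change and the observational noise -- mirroring real data, where no
#'   generation campaign (and hence no extra estimator noise) exists.
#' @return list of training-pair records (`rpm`, `est` added).
#' @export
prepare_training_pairs <- function(pairs, theta, protocol, seed = 1L,
                                   reuse_pair_seeds = FALSE) {
  seeds <- derive_seeds(seed, length(pairs))
  for (p in seq_along(pairs)) {
    if (reuse_pair_seeds && !is.null(pairs[[p]]$sampling_seed))
      seeds[p] <- pairs[[p]]$sampling_seed
    states <- sample_alchemical_path(pairs[[p]]$system, theta,
                                     pairs[[p]]$coords0, protocol,
                                     seed = seeds[p])
    rpm <- reduced_potential_matrix(states, pairs[[p]]$system, theta,
                                    T = protocol$T)
    pairs[[p]]$rpm <- rpm
    pairs[[p]]$est <- solve_mbar(rpm)
    pairs[[p]]$protocol <- protocol
    pairs[[p]]$seed <- seeds[p]
  }
  pairs
}

#' Per-atom-normalized energy regularization
#'
#' Mean absolute difference between the endstate energies at `theta_star`
#' and at the reference parameters, over every cached snapshot evaluated
#' with both endstate potentials, divided by the system's atom count.
#'
#' @param pair_data a training-pair record from
#'   [prepare_training_pairs()].
#' @param theta_star perturbed parameters.
#' @param want_gradient also return the flat parameter gradient.
#' @param endstates_only use only the snapshots sampled at lambda = 0 and
#'   lambda = 1 instead of all of them.
#' @return list with `value` (kcal/mol per atom) and optionally `grad`.
#' @export
energy_regularization <- function(pair_data, theta_star,
                                  want_gradient = FALSE,
                                  endstates_only = FALSE) {
  rpm <- pair_data$rpm
  system <- pair_data$system
  n_at <- length(system$elements)
  keep <- if (endstates_only) {
    which(rpm$origin %in% c(1L, max(rpm$origin)))
  } else seq_along(rpm$origin)
  if (length(keep) == 0) stopf("no snapshots available for regularization")
  X <- rpm$X[, , keep, drop = FALSE]
  d1 <- pot_energy_many(system$E1, X, theta_star) - rpm$E1[keep]
  d2 <- pot_energy_many(system$E2, X, theta_star) - rpm$E2[keep]
  value <- mean(c(abs(d1), abs(d2))) / n_at
  out <- list(value = value)
  if (want_gradient) {
    G1 <- pot_pgrad_many(system$E1, X, theta_star)
    G2 <- pot_pgrad_many(system$E2, X, theta_star)
    m <- 2 * length(keep)
    out$grad <- as.vector(G1 %*% sign(d1) + G2 %*% sign(d2)) / (m * n_at)
    names(out$grad) <- rownames(G1)
  }
  out
}

#' Loss for one tautomer pair at perturbed parameters
#'
#' `l = g * (dG(theta*) - dG_exp)^2 + f * regularization`, with the free
#' energy obtained by reweighting the pair's cached MBAR solution.
#'
#' @param pair_data a training-pair record.
#' @param theta_star perturbed parameters.
#' @param f regularization weight.
#' @param g free-energy weight.
#' @param want_gradient also return the flat parameter gradient.
#' @return list with `value`, `dG`, `resample_flag`, optionally `grad`.
#' @export
pair_loss <- function(pair_data, theta_star, f = 0.1, g = 1,
                      want_gradient = FALSE) {
  if (g != 0) {
    rw <- reweight_free_energy(pair_data$rpm, pair_data$est,
                               pair_data$system, theta_star,
                               want_gradient = want_gradient)
  } else {
    # pure regularization: the free-energy term (and its reweighting
    # machinery) drops out entirely
    rw <- list(dG = NA_real_, sigma = NA_real_, resample_flag = FALSE,
               ess = c(NA_real_, NA_real_))
  }
  err <- if (g != 0) rw$dG - pair_data$dG_exp else 0
  value <- g * err^2
  grad <- NULL
  if (want_gradient) {
    grad <- if (g != 0) 2 * g * err * rw$grad else
      numeric(length(params_flatten(theta_star)))
  }
  if (f != 0) {
    reg <- energy_regularization(pair_data, theta_star,
                                 want_gradient = want_gradient)
    value <- value + f * reg$value
    if (want_gradient) grad <- grad + f * reg$grad
  }
  out <- list(value = value, dG = rw$dG, sigma = rw$sigma,
              resample_flag = rw$resample_flag,
              ess_degradation = rw$ess_degradation %||% 1, ess = rw$ess)
  if (want_gradient) out$grad <- grad
  out
}

# predicted dG for a set of pairs at theta_star (reweighted)
.predict_dG <- function(pairs_data, theta_star) {
  vapply(pairs_data, function(pd)
    reweight_free_energy(pd$rpm, pd$est, pd$system, theta_star)$dG,
    numeric(1))
}

#' Train potential parameters against experimental free energies
#'
#' Per epoch: shuffle the training pairs, form minibatches, accumulate
#' the per-pair loss gradient, and update -- weight-like groups with
#' AdamW, bias-like groups with SGD.  Validation RMSE is computed by
#' reweighting every validation pair at the epoch's parameters; the
#' returned best model minimizes it.  When a pair's reweighting
#' uncertainty exceeds 1 kT (or its ESS collapses), a resample event
#' fires; with `auto_resample` the pair's samples are regenerated at the
#' current parameters.
#'
#' @param pairs_data records from [prepare_training_pairs()].
#' @param theta0 starting parameters (usually the reference parameters
#'   the samples were drawn at).
#' @param config a [training_config()].
#' @param split a [split_dataset()] result; computed from the config seed
#'   when NULL.
#' @return list of class `training_state`: `theta_best`, `theta_final`,
#'   `history` (per-epoch data.frame), `best_epoch`, `split`,
#'   `resample_events`.
#' @export
train_parameters <- function(pairs_data, theta0, config = training_config(),
                             split = NULL) {
  names_all <- vapply(pairs_data, `[[`, "", "name")
  names(pairs_data) <- names_all
  if (is.null(split)) split <- split_dataset(names_all, seed = config$seed)
  train_names <- intersect(names_all, split$train)
  val_names <- intersect(names_all, split$validation)
  flat <- params_flatten(theta0)
  n_par <- length(flat)
  group_of <- rep(names(theta0$groups), lengths(theta0$groups))
  is_weight <- group_of %in% .WEIGHT_GROUPS
  trainable <- if (is.null(config$trainable)) rep(TRUE, n_par) else
    group_of %in% config$trainable | names(flat) %in% config$trainable
  # AdamW state for the weight-like group
  m1 <- numeric(n_par); v1 <- numeric(n_par); t_adam <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- list()
  resample_events <- list()
  best <- list(rmse = Inf, theta = theta0, epoch = 0L)
  theta <- theta0
  shuffle_seeds <- derive_seeds(config$seed + 7L, max(config$epochs, 1L))
  resample_pair <- function(pd, th) {
    states <- sample_alchemical_path(pd$system, th, pd$coords0,
                                     pd$protocol, seed = pd$seed)
    pd$rpm <- reduced_potential_matrix(states, pd$system, th,
                                       T = pd$protocol$T)
    pd$est <- solve_mbar(pd$rpm)
    pd
  }
  val_metrics <- function(th) {
    if (length(val_names) == 0) return(NA_real_)
    pred <- vapply(val_names, function(nm) {
      pd <- pairs_data[[nm]]
      rw <- tryCatch(reweight_free_energy(pd$rpm, pd$est, pd$system, th),
                     error = function(e) NULL)
      if (is.null(rw) && config$auto_resample) {
        pairs_data[[nm]] <<- resample_pair(pd, th)
        resample_events[[length(resample_events) + 1L]] <<-
          list(epoch = NA_integer_, pair = nm, context = "validation")
        pd <- pairs_data[[nm]]
        rw <- reweight_free_energy(pd$rpm, pd$est, pd$system, th)
      }
      if (is.null(rw)) return(NA_real_)
      rw$dG
    }, numeric(1))
    exp_v <- vapply(pairs_data[val_names], `[[`, 0, "dG_exp")
    sqrt(mean((pred - exp_v)^2, na.rm = TRUE))
  }
  # epoch 0 record (no update yet)
  rmse0 <- val_metrics(theta)
  if (is.finite(rmse0) && rmse0 < best$rmse)
    best <- list(rmse = rmse0, theta = theta, epoch = 0L)
  history[[1]] <- data.frame(epoch = 0L, train_loss = NA_real_,
                             val_rmse = rmse0,
                             f = config$f_schedule(0),
                             g = config$g_schedule(0), n_resample = 0L)
  for (epoch in seq_len(config$epochs)) {
    f_e <- config$f_schedule(epoch)
    g_e <- config$g_schedule(epoch)
    order_e <- with_seed(shuffle_seeds[epoch], sample(train_names))
    batches <- split(order_e, ceiling(seq_along(order_e) /
                                        config$batch_size))
    epoch_loss <- 0
    n_res <- 0L
    for (batch in batches) {
      grad <- numeric(n_par)
      for (nm in batch) {
        pl <- tryCatch(
          pair_loss(pairs_data[[nm]], theta, f = f_e, g = g_e,
                    want_gradient = TRUE),
          error = function(e) e)
        # resampling with the same protocol can only cure a drift-induced
        # ESS collapse, not an intrinsic uncertainty above 1 kT -- so only
        # the former triggers regeneration
        needs_resample <- inherits(pl, "error") ||
          (pl$ess_degradation %||% 1) < 0.5
        if (needs_resample) {
          if (!config$auto_resample) {
            if (inherits(pl, "error")) stop(pl)
          } else {
            pairs_data[[nm]] <- resample_pair(pairs_data[[nm]], theta)
            n_res <- n_res + 1L
            resample_events[[length(resample_events) + 1L]] <-
              list(epoch = epoch, pair = nm)
            pl <- pair_loss(pairs_data[[nm]], theta, f = f_e, g = g_e,
                            want_gradient = TRUE)
          }
        }
        if (inherits(pl, "error")) stop(pl)
        epoch_loss <- epoch_loss + pl$value
        grad <- grad + pl$grad
      }
      if (!is.finite(sum(grad))) stopf("divergent loss gradient at epoch %d",
                                       epoch)
      grad[!trainable] <- 0
      # AdamW on weight-like entries
      wsel <- is_weight & trainable
      if (any(wsel)) {
        t_adam <- t_adam + 1L
        m1[wsel] <- b1 * m1[wsel] + (1 - b1) * grad[wsel]
        v1[wsel] <- b2 * v1[wsel] + (1 - b2) * grad[wsel]^2
        mh <- m1[wsel] / (1 - b1^t_adam)
        vh <- v1[wsel] / (1 - b2^t_adam)
        flat[wsel] <- flat[wsel] -
          config$lr_weights * (mh / (sqrt(vh) + eps) +
                                 config$weight_decay * flat[wsel])
      }
      # SGD on bias-like entries
      bsel <- (!is_weight) & trainable
      if (any(bsel)) {
        flat[bsel] <- flat[bsel] - config$lr_biases * grad[bsel]
      }
      theta <- params_unflatten(flat, theta0)
    }
    rmse <- val_metrics(theta)
    if (is.finite(rmse) && rmse < best$rmse)
      best <- list(rmse = rmse, theta = theta, epoch = epoch)
    history[[epoch + 1L]] <- data.frame(epoch = epoch,
                                        train_loss = epoch_loss,
                                        val_rmse = rmse, f = f_e, g = g_e,
                                        n_resample = n_res)
  }
  structure(list(theta_best = best$theta, theta_final = theta,
                 best_epoch = best$epoch, best_val_rmse = best$rmse,
                 history = do.call(rbind, history), split = split,
                 resample_events = resample_events,
                 pairs_data = pairs_data),
            class = "training_state")
}

#' @export
print.training_state <- function(x, ...) {
  cat(sprintf("<training_state> %d epochs, best epoch %d (val RMSE %.3f kcal/mol), %d resample events\n",
              max(x$history$epoch), x$best_epoch, x$best_val_rmse,
              length(x$resample_events)))
  invisible(x)
}

#' Evaluate predictions for a set of pairs at given parameters
#'
#' @param pairs_data training-pair records.
#' @param theta_star parameters to evaluate at (reweighted predictions).
#' @param subset optional vector of pair names.
#' @return data.frame with per-pair predictions plus `mae`/`rmse`
#'   attributes.
#' @export
evaluate_pairs <- function(pairs_data, theta_star, subset = NULL,
                           resample_if_needed = TRUE) {
  names_all <- vapply(pairs_data, `[[`, "", "name")
  names(pairs_data) <- names_all
  if (!is.null(subset)) pairs_data <- pairs_data[intersect(names_all,
                                                           subset)]
  pred <- vapply(pairs_data, function(pd) {
    rw <- tryCatch(
      reweight_free_energy(pd$rpm, pd$est, pd$system, theta_star),
      error = function(e) NULL)
    if (!is.null(rw) && rw$ess_degradation >= 0.5) return(rw$dG)
    if (!resample_if_needed || is.null(pd$protocol)) {
      if (!is.null(rw)) return(rw$dG)
      return(NA_real_)
    }
    # cached mixture cannot support this theta: sample it directly
    states <- sample_alchemical_path(pd$system, theta_star, pd$coords0,
                                     pd$protocol, seed = pd$seed)
    rpm <- reduced_potential_matrix(states, pd$system, theta_star,
                                    T = pd$protocol$T)
    solve_mbar(rpm)$dG
  }, numeric(1))
  exp_v <- vapply(pairs_data, `[[`, 0, "dG_exp")
  out <- data.frame(name = names(pairs_data), dG_pred = pred,
                    dG_exp = exp_v, row.names = NULL)
  attr(out, "mae") <- mean(abs(pred - exp_v))
  attr(out, "rmse") <- sqrt(mean((pred - exp_v)^2))
  out
}
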