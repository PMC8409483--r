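# Independent oracles used across the suite.  These deliberately avoid the
# code paths they check: the automorphism counters enumerate permutations
# directly, BAR is solved by bisection, and the Kabsch fit is a separate
# SVD implementation.

# exhaustive automorphism count: every color-preserving permutation tested
# against the (order/aromatic-colored) adjacency; only for small graphs
count_automorphisms_exhaustive <- function(mol) {
  n <- length(mol$elements)
  stopifnot(n <= 8)
  col <- paste(mol$elements, mol$hybridization)
  A <- matrix(0L, n, n)
  ord <- mol$bonds$order
  if (!is.null(mol$bonds$aromatic)) ord[mol$bonds$aromatic] <- 4L
  for (r in seq_len(nrow(mol$bonds))) {
    A[mol$bonds$i[r], mol$bonds$j[r]] <- ord[r]
    A[mol$bonds$j[r], mol$bonds$i[r]] <- ord[r]
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v)) {
      for (rest in perms(v[-k])) out[[length(out) + 1L]] <- c(v[k], rest)
    }
    out
  }
  count <- 0L
  for (p in perms(seq_len(n))) {
    if (any(col[p] != col)) next
    if (all(A[p, p] == A)) count <- count + 1L
  }
  count
}

# backtracking automorphism count with per-assignment adjacency pruning;
# handles larger graphs (benzene) without VF2
count_automorphisms_backtrack <- function(mol) {
  n <- length(mol$elements)
  col <- paste(mol$elements, mol$hybridization)
  A <- matrix(0L, n, n)
  ord <- mol$bonds$order
  if (!is.null(mol$bonds$aromatic)) ord[mol$bonds$aromatic] <- 4L
  for (r in seq_len(nrow(mol$bonds))) {
    A[mol$bonds$i[r], mol$bonds$j[r]] <- ord[r]
    A[mol$bonds$j[r], mol$bonds$i[r]] <- ord[r]
  }
  count <- 0L
  assign_next <- function(map, used) {
    v <- length(map) + 1L
    if (v > n) { count <<- count + 1L; return(invisible()) }
    for (w in seq_len(n)) {
      if (used[w] || col[w] != col[v]) next
      ok <- TRUE
      for (u in seq_len(v - 1L)) {
        if (A[v, u] != A[w, map[u]]) { ok <- FALSE; break }
      }
      if (ok) {
        used[w] <- TRUE
        assign_next(c(map, w), used)
        used[w] <- FALSE
      }
    }
  }
  assign_next(integer(0), logical(n))
  count
}

# two-state BAR solved by bisection of the Bennett self-consistency
# equation; wf/wr are forward and reverse reduced works
bar_bisect <- function(wf, wr, lo = -100, hi = 100, tol = 1e-12) {
  M <- log(length(wf) / length(wr))
  fermi <- function(x) 1 / (1 + exp(x))
  g <- function(df) sum(fermi(M + wf - df)) - sum(fermi(-M + wr + df))
  stopifnot(g(lo) * g(hi) < 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# independent Kabsch RMSD (SVD) for cross-checking pairwise_rmsd
kabsch_rmsd <- function(a, b, sel = seq_len(nrow(a))) {
  a <- a[sel, , drop = FALSE]; b <- b[sel, , drop = FALSE]
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  s <- svd(t(bc) %*% ac)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((ac - bc %*% t(R))^2)))
}

# write a simple-dialect pair table
write_pairs_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# hand-built sampled_states with i.i.d. Gaussian draws from each lambda's
# harmonic well: exact samples, no MD, for testing the estimators alone
gaussian_states <- function(lambdas, k1, k2, n_per_state, beta = 1,
                            seed = 1) {
  set.seed(seed)
  snaps <- lapply(lambdas, function(lam) {
    k <- (1 - lam) * k1 + lam * k2
    x <- array(rnorm(3 * n_per_state, sd = sqrt(1 / (beta * k))),
               c(1, 3, n_per_state))
    list(frames = x, energies = rep(NA_real_, n_per_state))
  })
  structure(list(lambdas = lambdas,
                 replicates = list(list(snapshots = snaps,
                                        seeds = rep(seed, length(lambdas)))),
                 protocol = NULL, master_seed = seed, n_atoms = 1L),
            class = "sampled_states")
}

# temperature at which kBT = 1 kcal/mol (reduced units for the harmonic
# oracles)
T_BETA1 <- 1 / tautofe::CONST$R_kcal

# short sampling protocols shared by tests
fast_toy_protocol <- function(n_replicates = 1L)
  sampling_protocol(n_lambda = 5L, n_steps = 2500L, gamma = 100,
                    stride = 10L, n_snapshots = 25L,
                    n_replicates = n_replicates)
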