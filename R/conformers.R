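# Conformer generation and RMSD-based reduction.  Embedding is
# deterministic given a seed: OpenBabel's 2D layout is lifted to 3D by
# seeded out-of-plane jitter and relaxed under the package's generic
# bonded force field; conformational variety comes from seeded random
# torsions about rotatable bonds.

#' A set of conformations of one molecule
#'
#' @param mol the `taut_molecule`.
#' @param frames list of n x 3 coordinate matrices (angstrom).
#' @param energies optional per-frame energies (kcal/mol).
#' @param seed generation seed.
#' @return object of class `conformer_set`.
#' @export
conformer_set <- function(mol, frames, energies = NULL, seed = NA_integer_) {
  stopifnot(length(frames) >= 1)
  n <- n_atoms(mol)
  for (f in frames) stopifnot(nrow(f) == n, ncol(f) == 3)
  structure(list(mol = mol, frames = frames,
                 energies = energies, seed = seed),
            class = "conformer_set")
}

#' @export
print.conformer_set <- function(x, ...) {
  cat(sprintf("<conformer_set> %s: %d frames\n",
              x$mol$smiles %||% "?", length(x$frames)))
  invisible(x)
}

# generic force field for a lone molecule
.mol_ff <- function(mol) {
  model <- toy_model(mol$elements, mol$bonds[, c("i", "j", "order")],
                     atoms = seq_len(n_atoms(mol)), id = "embed")
  theta <- default_toy_parameters(model)
  list(model = model, theta = theta)
}

# rotatable bonds: acyclic single bonds between heavy atoms of degree >= 2
.rotatable_bonds <- function(mol) {
  g <- mol_graph(mol)
  deg <- igraph::degree(g)
  out <- list()
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    i <- b$i[r]; j <- b$j[r]
    if (b$order[r] != 1L || isTRUE(b$aromatic[r])) next
    if (mol$elements[i] == "H" || mol$elements[j] == "H") next
    if (deg[i] < 2 || deg[j] < 2) next
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    comp <- igraph::components(g2)$membership
    if (comp[i] == comp[j]) next                    # ring bond
    out[[length(out) + 1L]] <- list(i = i, j = j,
                                    side = which(comp == comp[j]))
  }
  out
}

# rotate `side` atoms about the i->j axis by angle phi
.rotate_torsion <- function(x, i, j, side, phi) {
  axis <- x[j, ] - x[i, ]
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  Rm <- diag(3) + sin(phi) * K + (1 - cos(phi)) * (K %*% K)
  x[side, ] <- sweep(sweep(x[side, , drop = FALSE], 2, x[i, ]) %*% t(Rm),
                     2, x[i, ], "+")
  x
}

#' Embed a molecule in 3D
#'
#' Lifts the deterministic 2D layout to 3D with seeded out-of-plane
#' jitter and relaxes it under the generic bonded force field, which
#' restores sp3 geometry around saturated centres and resolves clashes.
#'
#' @param mol a `taut_molecule` with 2D coordinates (from
#'   [smiles_to_molecule()]).
#' @param seed RNG seed.
#' @param jitter_sd out-of-plane jitter (angstrom).
#' @return n x 3 coordinate matrix.
#' @export
embed_molecule <- function(mol, seed = 1L, jitter_sd = 0.3) {
  if (is.null(mol$coords)) stopf("molecule has no layout coordinates")
  ff <- .mol_ff(mol)
  force <- compile_model_force(ff$model, ff$theta)
  x0 <- mol$coords
  x0[, 3] <- with_seed(seed, stats::rnorm(nrow(x0), 0, jitter_sd))
  mn <- minimize_coords(x0,
                        fn = function(x) force(x)$energy,
                        gr = function(x) force(x)$grad,
                        tol = 1e-4, max_rounds = 50L)
  mn$coords
}

#' Generate conformations for a molecule
#'
#' 20 conformations are generated from seeded random torsions about the
#' rotatable bonds of an embedded base geometry (plus seeded jitter and
#' relaxation for rigid molecules); the set is reduced to 10 if the mean
#' pairwise RMSD of the 20 is below 0.5 A and to 5 if below 0.2 A.
#'
#' @param mol a `taut_molecule`.
#' @param seed RNG seed; the same seed reproduces the set exactly.
#' @param n_initial initial conformer count.
#' @return a `conformer_set` with 5, 10 or 20 frames.
#' @export
generate_conformers <- function(mol, seed = 1L, n_initial = 20L) {
  base <- tryCatch(embed_molecule(mol, seed = seed),
                   error = function(e)
                     stopf("embedding failed for %s: %s",
                           mol$smiles %||% "molecule", conditionMessage(e)))
  ff <- .mol_ff(mol)
  force <- compile_model_force(ff$model, ff$theta)
  rot <- .rotatable_bonds(mol)
  child <- derive_seeds(seed, n_initial)
  frames <- vector("list", n_initial)
  energies <- numeric(n_initial)
  for (c0 in seq_len(n_initial)) {
    x <- with_seed(child[c0], {
      xx <- base
      if (length(rot) > 0) {
        for (rb in rot) {
          xx <- .rotate_torsion(xx, rb$i, rb$j, rb$side,
                                stats::runif(1, 0, 2 * pi))
        }
      }
      xx + matrix(stats::rnorm(length(xx), 0, 0.05), nrow(xx), 3)
    })
    mn <- minimize_coords(x,
                          fn = function(z) force(z)$energy,
                          gr = function(z) force(z)$grad,
                          tol = 1e-3, max_rounds = 50L)
    frames[[c0]] <- mn$coords
    energies[c0] <- mn$energy
  }
  sel <- rmsd_selection(mol)
  rms <- utils::combn(n_initial, 2, function(p)
    pairwise_rmsd(frames[[p[1]]], frames[[p[2]]], sel))
  keep <- if (mean(rms) < 0.2) 5L else if (mean(rms) < 0.5) 10L
          else n_initial
  conformer_set(mol, frames[seq_len(keep)], energies[seq_len(keep)],
                seed = seed)
}

#' Atom selection for conformer RMSD comparisons
#'
#' Heavy atoms plus the hydrogens of the moieties whose proton position
#' matters for conformer identity: primary alcohols, imines,
#' primary/secondary amines, cyanamides and thiols (graph-pattern
#' implementation).
#'
#' @param mol a `taut_molecule`.
#' @return integer vector of atom indices.
#' @export
rmsd_selection <- function(mol) {
  el <- mol$elements
  sel <- which(el != "H")
  b <- mol$bonds
  nbrs <- function(a) c(b$j[b$i == a], b$i[b$j == a])
  has_double <- function(a) any(b$order[(b$i == a | b$j == a)] >= 2)
  for (h in which(el == "H")) {
    p <- nbrs(h)[1]
    if (is.na(p)) next
    pe <- el[p]
    heavy_nb <- setdiff(nbrs(p), which(el == "H"))
    hydro_nb <- intersect(nbrs(p), which(el == "H"))
    take <- FALSE
    if (pe == "S") take <- TRUE                                  # thiol
    if (pe == "O" && length(heavy_nb) == 1 && el[heavy_nb] == "C" &&
        sum(el[nbrs(heavy_nb)] == "H") >= 2) take <- TRUE        # prim. alcohol
    if (pe == "N") {
      if (has_double(p)) take <- TRUE                            # imine
      else if (length(heavy_nb) <= 2) take <- TRUE               # 1./2. amine
      if (any(vapply(heavy_nb, function(cc)
        el[cc] == "C" && any(b$order[(b$i == cc | b$j == cc)] == 3),
        logical(1)))) take <- TRUE                               # cyanamide
    }
    if (take) sel <- c(sel, h)
  }
  sort(unique(sel))
}

#' RMSD between two frames after optimal superposition
#'
#' Kabsch superposition (via bio3d) over the selection, then the root
#' mean square deviation over the same selection.
#'
#' @param a,b n x 3 coordinate matrices with identical atom ordering.
#' @param selection atom indices entering both the fit and the deviation
#'   (default: all atoms).
#' @return RMSD in angstrom.
#' @export
pairwise_rmsd <- function(a, b, selection = seq_len(nrow(a))) {
  stopifnot(nrow(a) == nrow(b))
  if (length(selection) == 0) stopf("empty RMSD selection")
  av <- as.vector(t(a))
  bv <- as.vector(t(b))
  xyz_idx <- as.vector(t(outer(selection, 1:3,
                               function(i, d) 3 * (i - 1) + d)))
  fitted <- bio3d::fit.xyz(fixed = av, mobile = bv,
                           fixed.inds = xyz_idx, mobile.inds = xyz_idx)
  sqrt(mean((matrix(fitted, ncol = 3, byrow = TRUE)[selection, ] -
               a[selection, ])^2) * 3)
}

#' Remove near-duplicate conformations
#'
#' Greedy pass in frame order (or a seeded random order): a frame is kept
#' iff its RMSD to every already-kept frame is at least `cutoff`.  At
#' least one frame always survives, and the operation is idempotent.
#'
#' @param set a `conformer_set`.
#' @param cutoff RMSD cutoff in angstrom.
#' @param seed optional seed to randomize the starting order.
#' @return a `conformer_set` with duplicates removed.
#' @export
deduplicate_conformers <- function(set, cutoff = 0.1, seed = NULL) {
  ord <- seq_along(set$frames)
  if (!is.null(seed)) ord <- with_seed(seed, sample(ord))
  sel <- rmsd_selection(set$mol)
  kept <- integer(0)
  for (c0 in ord) {
    dup <- any(vapply(kept, function(k)
      pairwise_rmsd(set$frames[[k]], set$frames[[c0]], sel) < cutoff,
      logical(1)))
    if (!dup) kept <- c(kept, c0)
  }
  kept <- sort(kept)
  conformer_set(set$mol, set$frames[kept],
                set$energies[kept], seed = set$seed)
}

#' Read conformers from an SDF file
#'
#' Every record must contain the same molecule; coordinates of each record
#' become one frame.
#'
#' @param path SDF file.
#' @param mol optional `taut_molecule` to attach (parsed from the first
#'   record's connectivity otherwise not available -- supply it).
#' @return a `conformer_set`.
#' @export
conformers_from_sdf <- function(path, mol) {
  sdfset <- ChemmineR::read.SDFset(path, skipErrors = TRUE)
  frames <- lapply(seq_along(sdfset@SDF), function(k) {
    ab <- ChemmineR::atomblock(sdfset[[k]])
    unname(cbind(ab[, 1], ab[, 2], if (ncol(ab) >= 3) ab[, 3] else 0))
  })
  conformer_set(mol, frames)
}
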