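# Locating the migrating proton, stereo-bond bookkeeping, and construction
# of the single-topology hybrid system with its dummy hydrogen.

# integer colors for VF2 from one or more character vectors
.vf2_colors <- function(...) {
  keys <- do.call(paste, list(..., sep = "|"))
  as.integer(factor(keys, levels = unique(keys)))
}

# all heavy-atom isomorphisms t1 -> t2 (element-matched, bond orders free);
# returns list of integer vectors idx_in_t2[idx_in_t1]
.heavy_isomorphisms <- function(t1, t2) {
  g1 <- mol_graph(t1, heavy_only = TRUE)
  g2 <- mol_graph(t2, heavy_only = TRUE)
  if (igraph::vcount(g1) != igraph::vcount(g2)) return(list())
  lev <- unique(c(igraph::V(g1)$element, igraph::V(g2)$element))
  c1 <- as.integer(factor(igraph::V(g1)$element, levels = lev))
  c2 <- as.integer(factor(igraph::V(g2)$element, levels = lev))
  maps <- igraph::graph.get.isomorphisms.vf2(g1, g2, vertex.color1 = c1,
                                             vertex.color2 = c2)
  orig1 <- igraph::V(g1)$orig
  orig2 <- igraph::V(g2)$orig
  lapply(maps, function(m) {
    out <- integer(0)
    out[orig1] <- orig2[as.integer(m)]
    out
  })
}

#' Find the single proton shift between two tautomers
#'
#' Enumerates all element-matched heavy-atom graph isomorphisms between the
#' tautomers and keeps those under which exactly one heavy atom loses a
#' hydrogen (the donor) and exactly one gains it (the acceptor), with at
#' least one bond-order rearrangement.  Candidates that differ only by a
#' molecular symmetry are collapsed to the lexicographically smallest
#' donor/acceptor pair; genuinely distinct candidates are an error.
#'
#' @param pair a [tautomer_pair()].
#' @return list with `donor`, `acceptor`, `moving_h` (atom indices in t1),
#'   and `mapping` (t1 heavy index -> t2 index).
#' @export
find_proton_shift <- function(pair) {
  t1 <- pair$t1; t2 <- pair$t2
  if (molecular_formula(t1) != molecular_formula(t2))
    stopf("tautomers differ in molecular formula (%s vs %s)",
          molecular_formula(t1), molecular_formula(t2))
  nH1 <- hydrogen_counts(t1)
  nH2 <- hydrogen_counts(t2)
  maps <- .heavy_isomorphisms(t1, t2)
  if (length(maps) == 0) stopf("heavy-atom graphs are not isomorphic")
  bond_order_key <- function(mol, map = NULL) {
    b <- mol$bonds[mol$elements[mol$bonds$i] != "H" &
                     mol$elements[mol$bonds$j] != "H", , drop = FALSE]
    i <- if (is.null(map)) b$i else map[b$i]
    j <- if (is.null(map)) b$j else map[b$j]
    sort(paste(pmin(i, j), pmax(i, j), b$order))
  }
  key2 <- bond_order_key(t2)
  candidates <- list()
  for (m in maps) {
    dH <- nH1 - nH2[m[seq_along(nH1)]]
    dH[t1$elements == "H"] <- 0L
    heavy <- which(t1$elements != "H")
    dH_heavy <- dH[heavy]
    if (sum(dH_heavy == 1L) == 1L && sum(dH_heavy == -1L) == 1L &&
        all(dH_heavy %in% c(-1L, 0L, 1L))) {
      rearranged <- !identical(bond_order_key(t1, m), key2)
      if (rearranged) {
        candidates[[length(candidates) + 1L]] <-
          list(donor = heavy[dH_heavy == 1L],
               acceptor = heavy[dH_heavy == -1L], mapping = m)
      }
    }
  }
  if (length(candidates) == 0)
    stopf("not a single-proton tautomer pair (no valid single-shift mapping)")
  da <- unique(t(vapply(candidates,
                        function(cc) c(cc$donor, cc$acceptor), numeric(2))))
  if (nrow(da) > 1) {
    # distinct donor/acceptor assignments are acceptable only if they are
    # images of each other under a symmetry of t1
    if (!.equivalent_under_automorphism(t1, da))
      stopf("not a single-proton tautomer pair (ambiguous shift: %s)",
            paste(apply(da, 1, paste, collapse = "->"), collapse = ", "))
    ord <- order(da[, 1], da[, 2])
    da <- da[ord, , drop = FALSE]
  }
  pick <- which(vapply(candidates, function(cc)
    cc$donor == da[1, 1] && cc$acceptor == da[1, 2], logical(1)))[1]
  cand <- candidates[[pick]]
  h_on_donor <- which(t1$elements == "H" &
                        (seq_along(t1$elements) %in%
                           c(t1$bonds$j[t1$bonds$i == cand$donor],
                             t1$bonds$i[t1$bonds$j == cand$donor])))
  if (length(h_on_donor) == 0) stopf("donor atom carries no hydrogen")
  list(donor = cand$donor, acceptor = cand$acceptor,
       moving_h = min(h_on_donor), mapping = cand$mapping)
}

# are all donor/acceptor rows of `da` related by an automorphism of t1?
.equivalent_under_automorphism <- function(t1, da) {
  g <- mol_graph(t1, heavy_only = TRUE)
  col <- .vf2_colors(igraph::V(g)$element, igraph::V(g)$nH)
  autos <- igraph::graph.get.isomorphisms.vf2(g, g, vertex.color1 = col,
                                              vertex.color2 = col)
  orig <- igraph::V(g)$orig
  perms <- lapply(autos, function(m) {
    p <- integer(0); p[orig] <- orig[as.integer(m)]; p
  })
  ref <- da[1, ]
  for (r in seq_len(nrow(da))[-1]) {
    hit <- any(vapply(perms, function(p)
      p[ref[1]] == da[r, 1] && p[ref[2]] == da[r, 2], logical(1)))
    if (!hit) return(FALSE)
  }
  TRUE
}

#' Does a stereo double bond change position between the tautomers?
#'
#' TRUE unless some element-matched heavy-atom isomorphism carries every
#' stereo-annotated double bond of one tautomer onto a stereo-annotated
#' double bond of the other (and vice versa).
#'
#' @param pair a [tautomer_pair()].
#' @return logical scalar.
#' @export
detect_stereobond_change <- function(pair) {
  t1 <- pair$t1; t2 <- pair$t2
  sb <- function(mol) {
    b <- mol$bonds[mol$bonds$stereo & mol$bonds$order == 2, , drop = FALSE]
    if (nrow(b) == 0) return(character(0))
    sort(paste(pmin(b$i, b$j), pmax(b$i, b$j)))
  }
  s1 <- sb(t1); s2 <- sb(t2)
  if (length(s1) == 0 && length(s2) == 0) return(FALSE)
  if (length(s1) != length(s2)) return(TRUE)
  maps <- .heavy_isomorphisms(t1, t2)
  for (m in maps) {
    b1 <- t1$bonds[t1$bonds$stereo & t1$bonds$order == 2, , drop = FALSE]
    mapped <- sort(paste(pmin(m[b1$i], m[b1$j]), pmax(m[b1$i], m[b1$j])))
    if (identical(mapped, s2)) return(FALSE)
  }
  TRUE
}

#' Build the single-topology hybrid system for a tautomer pair
#'
#' The hybrid atom list is the superset of the two endstate topologies:
#' the atoms of tautomer 1 plus one extra hydrogen bonded to the acceptor.
#' Endstate 1 interacts with every atom except that new hydrogen; endstate 2
#' interacts with every atom except the hydrogen sitting on the donor.
#' Bonded terms for endstate 2 are taken from tautomer 2's topology through
#' the heavy-atom mapping.  Flat-bottom restraints over the union of
#' covalent bonds (both tautomeric hydrogen bonds included) keep the
#' sampled species intact at every lambda.
#'
#' @param pair a [tautomer_pair()].
#' @param shift result of [find_proton_shift()]; computed when NULL.
#' @param T temperature (K) fixing the restraint force constants.
#' @return object of class `hybrid_system`; see [toy_model()] for the
#'   endstate potential objects in `$E1`/`$E2`.
#' @export
build_hybrid_topology <- function(pair, shift = NULL, T = 300) {
  t1 <- pair$t1
  if (is.null(shift)) shift <- find_proton_shift(pair)
  n <- n_atoms(t1)
  if (shift$donor == shift$acceptor) stopf("donor and acceptor coincide")
  if (any(c(shift$donor, shift$acceptor, shift$moving_h) > n) ||
      any(c(shift$donor, shift$acceptor, shift$moving_h) < 1))
    stopf("shift indices out of range")
  elements <- c(t1$elements, "H")
  dummy1 <- n + 1L          # new H on the acceptor; dummy at endstate 1
  dummy2 <- shift$moving_h  # donor H; dummy at endstate 2
  # endstate-2 bond list in superset indexing
  inv <- integer(0); inv[shift$mapping] <- seq_along(shift$mapping)
  t2 <- pair$t2
  heavy2 <- t2$bonds[t2$elements[t2$bonds$i] != "H" &
                       t2$elements[t2$bonds$j] != "H", , drop = FALSE]
  bonds2 <- data.frame(i = inv[heavy2$i], j = inv[heavy2$j],
                       order = heavy2$order)
  hbonds1 <- t1$bonds[t1$elements[t1$bonds$i] == "H" |
                        t1$elements[t1$bonds$j] == "H", , drop = FALSE]
  hb <- data.frame(i = hbonds1$i, j = hbonds1$j, order = 1L)
  keep <- !(hb$i == dummy2 | hb$j == dummy2)
  bonds2 <- rbind(bonds2, hb[keep, ],
                  data.frame(i = shift$acceptor, j = dummy1, order = 1L))
  bonds1 <- data.frame(i = t1$bonds$i, j = t1$bonds$j, order = t1$bonds$order)
  sys <- structure(list(
    elements = elements,
    masses = atomic_masses(elements),
    donor = shift$donor, acceptor = shift$acceptor,
    dummy1 = dummy1, dummy2 = dummy2,
    interacting1 = setdiff(seq_len(n + 1L), dummy1),
    interacting2 = setdiff(seq_len(n + 1L), dummy2),
    bonds1 = bonds1, bonds2 = bonds2,
    pair_name = pair$name,
    T = T
  ), class = "hybrid_system")
  sys$restraints <- build_restraints(sys, T = T)
  sys$E1 <- toy_model(elements, bonds1, atoms = sys$interacting1, id = "E1")
  sys$E2 <- toy_model(elements, bonds2, atoms = sys$interacting2, id = "E2")
  sys
}

#' @export
print.hybrid_system <- function(x, ...) {
  cat(sprintf(
    "<hybrid_system> %s: %d atoms (donor %d, acceptor %d, dummies %d/%d), %d restraints\n",
    x$pair_name %||% "?", length(x$elements), x$donor, x$acceptor,
    x$dummy1, x$dummy2, nrow(x$restraints)))
  invisible(x)
}

#' Place the dummy hydrogen on a sphere around the acceptor
#'
#' Samples `n_candidates` positions uniformly on a sphere of radius
#' `radius` centred on the acceptor (the equilibrium X-H bond length) and
#' keeps the lowest-energy one under the endstate potential in which the
#' placed hydrogen interacts, plus the restraints.  Ties break to the first
#' sampled index, so placement is deterministic given the seed.
#'
#' @param system a `hybrid_system`.
#' @param coords coordinates for tautomer-1 atoms (n x 3) or the full
#'   superset; the dummy row is (re)placed.
#' @param theta potential parameters for the endstate evaluation.
#' @param seed integer seed for the sphere sampling.
#' @param radius sphere radius in angstrom.
#' @param n_candidates number of sampled positions.
#' @return list with `coords` ((n+1) x 3) and `diagnostics` (candidate
#'   count, energies).
#' @export
place_dummy_hydrogen <- function(system, coords, theta, seed = 1L,
                                 radius = 1.02, n_candidates = 100L) {
  n_sup <- length(system$elements)
  if (nrow(coords) == n_sup - 1L) coords <- rbind(coords, 0)
  stopifnot(nrow(coords) == n_sup)
  centre <- coords[system$acceptor, ]
  if (any(!is.finite(centre))) stopf("acceptor coordinates missing")
  pts <- with_seed(seed, {
    z <- stats::runif(n_candidates, -1, 1)
    phi <- stats::runif(n_candidates, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    cbind(r * cos(phi), r * sin(phi), z) * radius
  })
  # the new hydrogen interacts in endstate 2
  energies <- vapply(seq_len(n_candidates), function(k) {
    coords[system$dummy1, ] <- centre + pts[k, ]
    pot_energy(system$E2, coords, theta) +
      flat_bottom_restraint_energy(coords, system$restraints)
  }, numeric(1))
  if (all(!is.finite(energies)))
    stopf("all dummy-placement candidate energies are non-finite")
  best <- which.min(energies)
  coords[system$dummy1, ] <- centre + pts[best, ]
  list(coords = coords,
       diagnostics = list(n_candidates = n_candidates, chosen = best,
                          energies = energies))
}
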