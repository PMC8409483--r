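# Molecular graphs: parsing from SMILES via OpenBabel (ChemmineOB), light
# perception (hybridization, formula), and igraph views used by the
# proton-shift search and the degeneracy count.

#' Construct a molecule object from explicit atoms and bonds
#'
#' Low-level constructor used by the SMILES parser and by the synthetic
#' benchmark systems.  Atom indices are 1-based.
#'
#' @param elements character vector of element symbols (explicit hydrogens).
#' @param bonds data.frame with integer columns `i`, `j`, `order` and logical
#'   column `stereo` (TRUE for a stereo-annotated double bond).
#' @param charges integer vector of formal charges (default all 0).
#' @param smiles source SMILES string, if any.
#' @param coords optional n x 3 coordinate matrix (angstrom).
#' @return object of class `taut_molecule`.
#' @export
molecule <- function(elements, bonds, charges = NULL, smiles = NA_character_,
                     coords = NULL) {
  n <- length(elements)
  stopifnot(n >= 1)
  if (is.null(charges)) charges <- integer(n)
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0) {
    stopifnot(all(c("i", "j", "order") %in% names(bonds)))
    if (is.null(bonds$stereo)) bonds$stereo <- FALSE
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stopf("bond indices out of range for %d atoms", n)
    if (any(bonds$i == bonds$j)) stopf("self-bond in bond list")
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = integer(),
                        stereo = logical())
  }
  mol <- structure(list(
    elements = as.character(elements),
    charges = as.integer(charges),
    bonds = bonds,
    hybridization = character(n),
    smiles = smiles,
    coords = coords
  ), class = "taut_molecule")
  mol$hybridization <- .perceive_hybridization(mol)
  if (n > 1 && nrow(bonds) > 0) {
    g <- mol_graph(mol)
    if (!igraph::is_connected(g))
      stopf("molecular graph is disconnected (multi-fragment input?)")
  } else if (n > 1 && nrow(bonds) == 0) {
    stopf("multi-atom molecule with no bonds")
  }
  mol
}

#' @export
print.taut_molecule <- function(x, ...) {
  cat(sprintf("<taut_molecule> %s, %d atoms, %d bonds",
              molecular_formula(x), length(x$elements), nrow(x$bonds)))
  if (!is.na(x$smiles)) cat("  [", x$smiles, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `taut_molecule`.
#' @return integer atom count (explicit hydrogens included).
#' @export
n_atoms <- function(mol) length(mol$elements)

#' Molecular formula string (Hill order)
#' @param mol a `taut_molecule`.
#' @return character scalar, e.g. `"C2H4O"`.
#' @export
molecular_formula <- function(mol) {
  tab <- table(mol$elements)
  els <- names(tab)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    if (tab[[e]] == 1L) e else paste0(e, tab[[e]])
  }, ""), collapse = "")
}

# sp/sp2/sp3 from incident bond orders; hydrogens are "s"
.perceive_hybridization <- function(mol) {
  n <- length(mol$elements)
  hyb <- rep("sp3", n)
  hyb[mol$elements == "H"] <- "s"
  if (nrow(mol$bonds) > 0) {
    for (a in which(mol$elements != "H")) {
      inc <- mol$bonds[mol$bonds$i == a | mol$bonds$j == a, "order"]
      if (any(inc >= 3) || sum(inc == 2) >= 2) hyb[a] <- "sp"
      else if (any(inc == 2)) hyb[a] <- "sp2"
    }
  }
  hyb
}

#' igraph view of a molecule
#'
#' @param mol a `taut_molecule`.
#' @param heavy_only drop hydrogens (vertex attribute `orig` keeps the
#'   original atom indices).
#' @return an igraph with vertex attributes `element`, `hyb`, `nH` (hydrogen
#'   count, heavy view only) and edge attribute `order`.
#' @export
mol_graph <- function(mol, heavy_only = FALSE) {
  n <- length(mol$elements)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(mol$bonds) > 0)
    g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
  igraph::V(g)$element <- mol$elements
  igraph::V(g)$hyb <- mol$hybridization
  igraph::V(g)$orig <- seq_len(n)
  if (nrow(mol$bonds) > 0) igraph::E(g)$order <- mol$bonds$order
  if (heavy_only) {
    hcount <- hydrogen_counts(mol)
    igraph::V(g)$nH <- hcount
    g <- igraph::induced_subgraph(g, which(mol$elements != "H"))
  }
  g
}

#' Hydrogen count attached to each atom
#' @param mol a `taut_molecule`.
#' @return integer vector over all atoms (hydrogens themselves get 0).
#' @export
hydrogen_counts <- function(mol) {
  n <- length(mol$elements)
  cnt <- integer(n)
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    if (mol$elements[b$j[r]] == "H") cnt[b$i[r]] <- cnt[b$i[r]] + 1L
    if (mol$elements[b$i[r]] == "H") cnt[b$j[r]] <- cnt[b$j[r]] + 1L
  }
  cnt
}

#' Parse a SMILES string into a molecule
#'
#' Uses OpenBabel (through ChemmineOB) to interpret the SMILES, add explicit
#' hydrogens and produce a deterministic 2D layout; the V2000 block is read
#' back with ChemmineR.  Cis/trans stereo bonds are flagged by scanning the
#' directional bond marks of the input SMILES (OpenBabel's R interface does
#' not expose bond-level stereo).
#'
#' @param smiles a SMILES string.
#' @return a `taut_molecule` with 2D coordinates attached.
#' @export
smiles_to_molecule <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  opts <- data.frame(names = c("gen2d", "h"), args = c("", ""))
  sdf_txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", smiles,
                                               options = opts)),
    error = function(e) "")
  if (!nzchar(sdf_txt) || !grepl("V2000", sdf_txt, fixed = TRUE))
    stopf("SMILES could not be parsed: '%s'", smiles)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdf_txt, tf)
  sdfset <- ChemmineR::read.SDFset(tf, skipErrors = TRUE)
  if (length(sdfset) < 1L) stopf("SMILES could not be parsed: '%s'", smiles)
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- cbind(ab[, 1], ab[, 2],
                  if (ncol(ab) >= 3) ab[, 3] else 0)
  colnames(coords) <- c("x", "y", "z")
  rownames(coords) <- NULL
  n <- length(elements)
  if (nrow(bb) > 0) {
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]), stereo = FALSE)
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = integer(),
                        stereo = logical())
  }
  charges <- integer(n)
  for (ln in grep("^M  CHG", strsplit(sdf_txt, "\n")[[1]], value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- f[1]
    for (e in seq_len(k)) charges[f[2 * e]] <- f[2 * e + 1]
  }
  st <- .stereo_double_bonds(smiles)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  if (nrow(st) > 0 && nrow(bonds) > 0) {
    bonds$stereo <- key(bonds$i, bonds$j) %in% key(st$i, st$j)
  }
  # aromatic bond flags via OpenBabel's MOL2 writer (type "ar"); kekule
  # orders are kept for valence bookkeeping, the flag for symmetry counts
  bonds$aromatic <- FALSE
  ar <- tryCatch(.aromatic_bonds(smiles), error = function(e) NULL)
  if (!is.null(ar) && nrow(ar) > 0 && nrow(bonds) > 0) {
    bonds$aromatic <- key(bonds$i, bonds$j) %in% key(ar$i, ar$j)
  }
  molecule(elements, bonds, charges = charges, smiles = smiles,
           coords = coords)
}

# aromatic bonds from the MOL2 @<TRIPOS>BOND block (atom order matches the
# SDF export since both come from the same OpenBabel molecule)
.aromatic_bonds <- function(smiles) {
  opts <- data.frame(names = "h", args = "")
  m2 <- suppressWarnings(ChemmineOB::convertFormat("SMI", "MOL2", smiles,
                                                   options = opts))
  lines <- strsplit(m2, "\n")[[1]]
  b0 <- grep("@<TRIPOS>BOND", lines, fixed = TRUE)
  if (length(b0) == 0) return(data.frame(i = integer(), j = integer()))
  out <- list()
  for (ln in lines[-seq_len(b0[1])]) {
    if (grepl("^@<TRIPOS>", ln)) break
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) >= 4 && f[4] == "ar")
      out[[length(out) + 1L]] <- data.frame(i = as.integer(f[2]),
                                            j = as.integer(f[3]))
  }
  if (length(out) == 0) return(data.frame(i = integer(), j = integer()))
  do.call(rbind, out)
}

# Minimal SMILES walk that numbers atom tokens the way OpenBabel does
# (order of appearance; added hydrogens come after) and returns the double
# bonds flanked by directional single bonds (/ or \).  Only connectivity
# relevant to stereo perception is tracked.
.stereo_double_bonds <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  i <- 1L; natom <- 0L
  prev <- NA_integer_
  stack <- integer(0)
  pend_bond <- ""          # bond symbol awaiting next atom
  ring <- list()           # ring-closure label -> c(atom, bondsym)
  bonds <- list()
  emit <- function(a, b, sym) bonds[[length(bonds) + 1L]] <<- list(a, b, sym)
  while (i <= length(chars)) {
    ch <- chars[i]
    two <- if (i < length(chars)) paste0(ch, chars[i + 1]) else ""
    if (ch == "[") {
      j <- i
      while (chars[j] != "]") j <- j + 1L
      natom <- natom + 1L
      if (!is.na(prev)) emit(prev, natom, pend_bond)
      prev <- natom; pend_bond <- ""
      i <- j + 1L
    } else if (two %in% c("Cl", "Br")) {
      natom <- natom + 1L
      if (!is.na(prev)) emit(prev, natom, pend_bond)
      prev <- natom; pend_bond <- ""
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                         "b", "c", "n", "o", "p", "s")) {
      natom <- natom + 1L
      if (!is.na(prev)) emit(prev, natom, pend_bond)
      prev <- natom; pend_bond <- ""
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pend_bond <- ch; i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") { lab <- paste0(chars[i + 1], chars[i + 2]); i <- i + 3L }
      else { lab <- ch; i <- i + 1L }
      if (is.null(ring[[lab]])) {
        ring[[lab]] <- list(prev, pend_bond)
      } else {
        sym <- if (nzchar(pend_bond)) pend_bond else ring[[lab]][[2]]
        emit(ring[[lab]][[1]], prev, sym)
        ring[[lab]] <- NULL
      }
      pend_bond <- ""
    } else {
      i <- i + 1L   # @, +, digits inside brackets handled above; skip rest
    }
  }
  if (length(bonds) == 0)
    return(data.frame(i = integer(), j = integer()))
  bm <- do.call(rbind, lapply(bonds, function(b)
    data.frame(i = b[[1]], j = b[[2]], sym = b[[3]],
               stringsAsFactors = FALSE)))
  dbl <- bm[bm$sym == "=", , drop = FALSE]
  dir_atoms <- unique(c(bm$i[bm$sym %in% c("/", "\\")],
                        bm$j[bm$sym %in% c("/", "\\")]))
  # cis/trans is defined only when each sp2 carbon carries a directional bond
  keep <- (dbl$i %in% dir_atoms) & (dbl$j %in% dir_atoms)
  dbl <- dbl[keep, c("i", "j"), drop = FALSE]
  rownames(dbl) <- NULL
  dbl
}
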