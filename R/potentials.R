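# Parameterized potentials: a differentiable bonded force field (harmonic
# bonds with well-depth offsets, harmonic angles, soft exponential
# repulsion), isotropic harmonic-well benchmark potentials, flat-bottom
# restraints, and the linear alchemical mixing of two endstate potentials.
#
# Parameters live in a named group structure ("weights"-like force
# constants, "biases"-like equilibrium values / offsets) so that training
# can select which groups are adjustable, mirroring the final-layer-only
# tuning of machine-learned potentials.

#' Create a potential parameter set
#'
#' @param groups named list of named numeric vectors.  Conventional groups
#'   for the toy force field: `bond_k`, `bond_r0`, `bond_D`, `angle_k`,
#'   `angle_theta0`, `rep_A`, `rep_rho` (and `well_k` for harmonic wells).
#' @return object of class `taut_params`.
#' @export
potential_parameters <- function(groups) {
  stopifnot(is.list(groups), length(names(groups)) == length(groups))
  for (g in names(groups)) {
    if (any(!is.finite(groups[[g]])))
      stopf("non-finite parameter in group '%s'", g)
  }
  structure(list(groups = groups), class = "taut_params")
}

# which groups behave like weight matrices vs bias vectors under training
.WEIGHT_GROUPS <- c("bond_k", "angle_k", "rep_A", "well_k")

#' @export
print.taut_params <- function(x, ...) {
  cat("<taut_params>", sum(lengths(x$groups)), "parameters in groups:",
      paste(sprintf("%s[%d]", names(x$groups), lengths(x$groups)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Flatten parameters to a named vector (canonical order)
#' @param theta a `taut_params`.
#' @return named numeric vector with names `group.entry`.
#' @export
params_flatten <- function(theta) unlist(theta$groups)

#' Rebuild a parameter object from a flat vector
#' @param flat named numeric vector from [params_flatten()].
#' @param template `taut_params` giving the group structure.
#' @return a `taut_params`.
#' @export
params_unflatten <- function(flat, template) {
  groups <- template$groups
  k <- 0L
  for (g in names(groups)) {
    m <- length(groups[[g]])
    groups[[g]][] <- flat[k + seq_len(m)]
    k <- k + m
  }
  potential_parameters(groups)
}

#' Serialize parameters to JSON (group name -> values + names)
#' @param theta a `taut_params`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(theta, path) {
  obj <- lapply(theta$groups, function(v)
    list(names = names(v), values = unname(v)))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read parameters from the JSON schema written by [write_parameters()]
#' @param path JSON file.
#' @return a `taut_params`.
#' @export
read_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  potential_parameters(lapply(obj, function(g)
    stats::setNames(as.numeric(g$values), g$names)))
}

# ---- type keys and default parameter tables ------------------------------

.bond_type <- function(e1, e2, order) {
  ab <- ifelse(e1 <= e2, paste0(e1, "-", e2), paste0(e2, "-", e1))
  paste0(ab, ":", order)
}

.angle_type <- function(eo1, ec, hybc, eo2) {
  o <- sort(c(eo1, eo2))
  sprintf("%s-%s(%s)-%s", o[1], ec, hybc, o[2])
}

.DEFAULT_R0 <- c(
  "C-H:1" = 1.09, "H-N:1" = 1.01, "H-O:1" = 0.96, "H-S:1" = 1.34,
  "H-H:1" = 0.74,
  "C-C:1" = 1.53, "C-C:2" = 1.34, "C-C:3" = 1.20,
  "C-N:1" = 1.47, "C-N:2" = 1.28, "C-N:3" = 1.16,
  "C-O:1" = 1.43, "C-O:2" = 1.22,
  "N-N:1" = 1.45, "N-N:2" = 1.25, "N-O:1" = 1.40, "N-O:2" = 1.21,
  "O-O:1" = 1.48, "C-S:1" = 1.82, "C-S:2" = 1.60, "N-S:1" = 1.70
)
.COV_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                F = 0.57, Cl = 1.02, Br = 1.20, P = 1.07)

.default_bond_r0 <- function(type) {
  if (type %in% names(.DEFAULT_R0)) return(.DEFAULT_R0[[type]])
  parts <- strsplit(type, "[-:]")[[1]]
  scale <- c("1" = 1.00, "2" = 0.87, "3" = 0.78)[parts[3]]
  (.COV_RADII[[parts[1]]] + .COV_RADII[[parts[2]]]) * scale
}

.default_bond_k <- function(type) {
  parts <- strsplit(type, "[-:]")[[1]]
  if ("H" %in% parts[1:2]) return(340)
  c("1" = 300, "2" = 500, "3" = 700)[[parts[3]]]
}

.default_theta0 <- function(type) {
  hyb <- sub(".*\\((sp3|sp2|sp|s)\\).*", "\\1", type)
  switch(hyb, sp = pi, sp2 = 120 * pi / 180, 109.47 * pi / 180)
}

#' Default toy force-field parameters for a set of potential models
#'
#' Builds a parameter object covering every bond, angle and repulsion term
#' present in the supplied models, from a small internal table of typical
#' bond lengths and stiffnesses.  Bond well-depth offsets `bond_D` start at
#' zero; they shift an endstate's energy by a constant per bond of that
#' type, which is the lever the synthetic experiments perturb.
#'
#' @param ... `toy_model` objects (or lists of them).
#' @param rep_A,rep_rho global soft-repulsion amplitude (kcal/mol) and
#'   range (angstrom).
#' @return a `taut_params`.
#' @export
default_toy_parameters <- function(..., rep_A = 100, rep_rho = 0.35) {
  models <- list(...)
  models <- unlist(lapply(models, function(m)
    if (inherits(m, "toy_model")) list(m) else m), recursive = FALSE)
  btypes <- sort(unique(unlist(lapply(models, function(m) m$bonds$type))))
  atypes <- sort(unique(unlist(lapply(models, function(m) m$angles$type))))
  potential_parameters(list(
    bond_k = stats::setNames(vapply(btypes, .default_bond_k, 1), btypes),
    bond_r0 = stats::setNames(vapply(btypes, .default_bond_r0, 1), btypes),
    bond_D = stats::setNames(rep(0, length(btypes)), btypes),
    angle_k = stats::setNames(rep(70, length(atypes)), atypes),
    angle_theta0 = stats::setNames(vapply(atypes, .default_theta0, 1),
                                   atypes),
    rep_A = c(global = rep_A),
    rep_rho = c(global = rep_rho)
  ))
}


# 3 x n_frames slice of one atom's coordinates (robust to n_frames == 1)
.fslice <- function(X, a) matrix(X[a, , ], nrow = 3)

# ---- toy bonded potential ------------------------------------------------

#' Construct a toy bonded potential model
#'
#' Energy terms, all indexed into the full (superset) coordinate array:
#' harmonic bonds `0.5 k (r - r0)^2 - D` typed by element pair and bond
#' order; harmonic angles `0.5 k (theta - theta0)^2` typed by outer
#' elements, central element and its hybridization; and a soft exponential
#' repulsion `A exp(-r / rho)` over non-bonded (1-4 and beyond) pairs of
#' the model's interacting atoms.  Energies and both gradients (coordinates
#' and parameters) are analytic.
#'
#' @param elements element symbols of the full coordinate array.
#' @param bonds data.frame `i`, `j`, `order` (superset indices).
#' @param atoms interacting atom subset (default: every atom in `bonds`,
#'   or all atoms when `bonds` is empty).
#' @param id model identifier.
#' @return object of class `toy_model`.
#' @export
toy_model <- function(elements, bonds, atoms = NULL, id = "toy") {
  n_sup <- length(elements)
  bonds <- as.data.frame(bonds)
  if (is.null(atoms)) {
    atoms <- if (nrow(bonds) > 0) sort(unique(c(bonds$i, bonds$j)))
             else seq_len(n_sup)
  }
  hyb <- .perceive_hybridization(
    structure(list(elements = elements, bonds = bonds), class = "list"))
  btype <- if (nrow(bonds) > 0)
    .bond_type(elements[bonds$i], elements[bonds$j], bonds$order)
  else character(0)
  bonds$type <- btype
  # angles: every pair of bonded neighbours around each interacting atom
  adj <- lapply(seq_len(n_sup), function(a)
    sort(c(bonds$j[bonds$i == a], bonds$i[bonds$j == a])))
  ang <- list()
  for (c0 in atoms) {
    nb <- adj[[c0]]
    if (length(nb) >= 2) {
      for (p in utils::combn(length(nb), 2, simplify = FALSE)) {
        i <- nb[p[1]]; j <- nb[p[2]]
        ang[[length(ang) + 1L]] <- data.frame(
          i = i, c = c0, j = j,
          type = .angle_type(elements[i], elements[c0], hyb[c0],
                             elements[j]))
      }
    }
  }
  angles <- if (length(ang)) do.call(rbind, ang) else
    data.frame(i = integer(), c = integer(), j = integer(),
               type = character())
  # non-bonded pairs: interacting atoms, excluding 1-2 and 1-3
  excl <- new.env()
  mark <- function(i, j) assign(paste(min(i, j), max(i, j)), TRUE, excl)
  for (r in seq_len(nrow(bonds))) mark(bonds$i[r], bonds$j[r])
  for (r in seq_len(nrow(angles))) mark(angles$i[r], angles$j[r])
  nb <- list()
  if (length(atoms) >= 2) {
    for (p in utils::combn(length(atoms), 2, simplify = FALSE)) {
      i <- atoms[p[1]]; j <- atoms[p[2]]
      if (!exists(paste(i, j), excl))
        nb[[length(nb) + 1L]] <- c(i, j)
    }
  }
  nbp <- if (length(nb)) do.call(rbind, nb) else
    matrix(integer(0), ncol = 2)
  structure(list(id = id, family = "toy", n_sup = n_sup,
                 elements = elements, atoms = atoms,
                 bonds = bonds, angles = angles, nb = nbp),
            class = "toy_model")
}

#' @export
print.toy_model <- function(x, ...) {
  cat(sprintf("<toy_model '%s'> %d atoms, %d bonds, %d angles, %d nb pairs\n",
              x$id, length(x$atoms), nrow(x$bonds), nrow(x$angles),
              nrow(x$nb)))
  invisible(x)
}

# look up vector of per-term parameters; error when a type is missing
.lookup <- function(theta, group, types) {
  v <- theta$groups[[group]][types]
  if (anyNA(v))
    stopf("missing %s parameter for type(s): %s", group,
          paste(unique(types[is.na(v)]), collapse = ", "))
  unname(v)
}

# angle geometry helper: value and (optionally) gradients
.angle_theta <- function(x, i, c0, j) {
  u <- x[i, ] - x[c0, ]; v <- x[j, ] - x[c0, ]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  cs <- sum(u * v) / (nu * nv)
  cs <- max(min(cs, 1 - 1e-12), -1 + 1e-12)
  list(theta = acos(cs), u = u, v = v, nu = nu, nv = nv, cs = cs)
}

#' Potential energy of a model at one geometry
#'
#' @param model a `toy_model` or `well_model`.
#' @param x full coordinate matrix (n_superset x 3, angstrom).
#' @param theta a `taut_params`.
#' @return energy in kcal/mol.
#' @export
pot_energy <- function(model, x, theta) UseMethod("pot_energy")

#' Coordinate gradient of a model at one geometry
#' @inheritParams pot_energy
#' @return n_superset x 3 gradient, kcal/mol/angstrom.
#' @export
pot_grad <- function(model, x, theta) UseMethod("pot_grad")

#' Energies of a model over many frames
#' @param model a potential model.
#' @param X coordinate array, n_superset x 3 x n_frames.
#' @param theta a `taut_params`.
#' @return numeric vector of energies (kcal/mol) per frame.
#' @export
pot_energy_many <- function(model, X, theta) UseMethod("pot_energy_many")

#' Parameter gradient of a model's energy over many frames
#' @inheritParams pot_energy_many
#' @return matrix n_flat_params x n_frames; rows follow
#'   [params_flatten()] order of `theta`.
#' @export
pot_pgrad_many <- function(model, X, theta) UseMethod("pot_pgrad_many")

#' @export
pot_energy.toy_model <- function(model, x, theta) {
  e <- 0
  b <- model$bonds
  if (nrow(b) > 0) {
    d <- x[b$i, , drop = FALSE] - x[b$j, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    k <- .lookup(theta, "bond_k", b$type)
    r0 <- .lookup(theta, "bond_r0", b$type)
    D <- .lookup(theta, "bond_D", b$type)
    e <- e + sum(0.5 * k * (r - r0)^2 - D)
  }
  a <- model$angles
  if (nrow(a) > 0) {
    ka <- .lookup(theta, "angle_k", a$type)
    th0 <- .lookup(theta, "angle_theta0", a$type)
    for (r in seq_len(nrow(a))) {
      g <- .angle_theta(x, a$i[r], a$c[r], a$j[r])
      e <- e + 0.5 * ka[r] * (g$theta - th0[r])^2
    }
  }
  if (nrow(model$nb) > 0) {
    A <- theta$groups$rep_A[["global"]]
    rho <- theta$groups$rep_rho[["global"]]
    d <- x[model$nb[, 1], , drop = FALSE] - x[model$nb[, 2], , drop = FALSE]
    e <- e + A * sum(exp(-sqrt(rowSums(d^2)) / rho))
  }
  e
}

#' @export
pot_grad.toy_model <- function(model, x, theta) {
  g <- matrix(0, nrow(x), 3)
  b <- model$bonds
  if (nrow(b) > 0) {
    d <- x[b$i, , drop = FALSE] - x[b$j, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    k <- .lookup(theta, "bond_k", b$type)
    r0 <- .lookup(theta, "bond_r0", b$type)
    f <- k * (r - r0) / pmax(r, 1e-12)
    gv <- d * f
    for (t in seq_len(nrow(b))) {
      g[b$i[t], ] <- g[b$i[t], ] + gv[t, ]
      g[b$j[t], ] <- g[b$j[t], ] - gv[t, ]
    }
  }
  a <- model$angles
  if (nrow(a) > 0) {
    ka <- .lookup(theta, "angle_k", a$type)
    th0 <- .lookup(theta, "angle_theta0", a$type)
    for (t in seq_len(nrow(a))) {
      ge <- .angle_theta(x, a$i[t], a$c[t], a$j[t])
      dEdth <- ka[t] * (ge$theta - th0[t])
      dth_dcs <- -1 / sqrt(max(1 - ge$cs^2, 1e-12))
      dcs_du <- ge$v / (ge$nu * ge$nv) - ge$cs * ge$u / ge$nu^2
      dcs_dv <- ge$u / (ge$nu * ge$nv) - ge$cs * ge$v / ge$nv^2
      gi <- dEdth * dth_dcs * dcs_du
      gj <- dEdth * dth_dcs * dcs_dv
      g[a$i[t], ] <- g[a$i[t], ] + gi
      g[a$j[t], ] <- g[a$j[t], ] + gj
      g[a$c[t], ] <- g[a$c[t], ] - gi - gj
    }
  }
  if (nrow(model$nb) > 0) {
    A <- theta$groups$rep_A[["global"]]
    rho <- theta$groups$rep_rho[["global"]]
    d <- x[model$nb[, 1], , drop = FALSE] - x[model$nb[, 2], , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    f <- -A * exp(-r / rho) / rho / pmax(r, 1e-12)
    gv <- d * f
    for (t in seq_len(nrow(model$nb))) {
      i <- model$nb[t, 1]; j <- model$nb[t, 2]
      g[i, ] <- g[i, ] + gv[t, ]
      g[j, ] <- g[j, ] - gv[t, ]
    }
  }
  g
}

#' @export
pot_energy_many.toy_model <- function(model, X, theta) {
  nf <- dim(X)[3]
  e <- numeric(nf)
  b <- model$bonds
  if (nrow(b) > 0) {
    k <- .lookup(theta, "bond_k", b$type)
    r0 <- .lookup(theta, "bond_r0", b$type)
    D <- .lookup(theta, "bond_D", b$type)
    for (t in seq_len(nrow(b))) {
      d <- .fslice(X, b$i[t]) - .fslice(X, b$j[t])
      r <- sqrt(colSums(d^2))
      e <- e + 0.5 * k[t] * (r - r0[t])^2 - D[t]
    }
  }
  a <- model$angles
  if (nrow(a) > 0) {
    ka <- .lookup(theta, "angle_k", a$type)
    th0 <- .lookup(theta, "angle_theta0", a$type)
    for (t in seq_len(nrow(a))) {
      u <- .fslice(X, a$i[t]) - .fslice(X, a$c[t])
      v <- .fslice(X, a$j[t]) - .fslice(X, a$c[t])
      cs <- colSums(u * v) / (sqrt(colSums(u^2)) * sqrt(colSums(v^2)))
      th <- acos(pmin(pmax(cs, -1 + 1e-12), 1 - 1e-12))
      e <- e + 0.5 * ka[t] * (th - th0[t])^2
    }
  }
  if (nrow(model$nb) > 0) {
    A <- theta$groups$rep_A[["global"]]
    rho <- theta$groups$rep_rho[["global"]]
    for (t in seq_len(nrow(model$nb))) {
      d <- .fslice(X, model$nb[t, 1]) - .fslice(X, model$nb[t, 2])
      e <- e + A * exp(-sqrt(colSums(d^2)) / rho)
    }
  }
  e
}

#' @export
pot_pgrad_many.toy_model <- function(model, X, theta) {
  nf <- dim(X)[3]
  flat <- params_flatten(theta)
  G <- matrix(0, length(flat), nf, dimnames = list(names(flat), NULL))
  b <- model$bonds
  if (nrow(b) > 0) {
    k <- .lookup(theta, "bond_k", b$type)
    r0 <- .lookup(theta, "bond_r0", b$type)
    for (t in seq_len(nrow(b))) {
      d <- .fslice(X, b$i[t]) - .fslice(X, b$j[t])
      r <- sqrt(colSums(d^2))
      ty <- b$type[t]
      G[paste0("bond_k.", ty), ] <- G[paste0("bond_k.", ty), ] +
        0.5 * (r - r0[t])^2
      G[paste0("bond_r0.", ty), ] <- G[paste0("bond_r0.", ty), ] -
        k[t] * (r - r0[t])
      G[paste0("bond_D.", ty), ] <- G[paste0("bond_D.", ty), ] - 1
    }
  }
  a <- model$angles
  if (nrow(a) > 0) {
    ka <- .lookup(theta, "angle_k", a$type)
    th0 <- .lookup(theta, "angle_theta0", a$type)
    for (t in seq_len(nrow(a))) {
      u <- .fslice(X, a$i[t]) - .fslice(X, a$c[t])
      v <- .fslice(X, a$j[t]) - .fslice(X, a$c[t])
      cs <- colSums(u * v) / (sqrt(colSums(u^2)) * sqrt(colSums(v^2)))
      th <- acos(pmin(pmax(cs, -1 + 1e-12), 1 - 1e-12))
      ty <- a$type[t]
      G[paste0("angle_k.", ty), ] <- G[paste0("angle_k.", ty), ] +
        0.5 * (th - th0[t])^2
      G[paste0("angle_theta0.", ty), ] <- G[paste0("angle_theta0.", ty), ] -
        ka[t] * (th - th0[t])
    }
  }
  if (nrow(model$nb) > 0) {
    A <- theta$groups$rep_A[["global"]]
    rho <- theta$groups$rep_rho[["global"]]
    for (t in seq_len(nrow(model$nb))) {
      d <- .fslice(X, model$nb[t, 1]) - .fslice(X, model$nb[t, 2])
      r <- sqrt(colSums(d^2))
      G["rep_A.global", ] <- G["rep_A.global", ] + exp(-r / rho)
      G["rep_rho.global", ] <- G["rep_rho.global", ] +
        A * exp(-r / rho) * r / rho^2
    }
  }
  G
}

# ---- isotropic harmonic well (benchmark oracle) --------------------------

#' Isotropic harmonic-well potential
#'
#' Every atom is bound to a fixed centre by `0.5 k |x - c|^2`; the
#' stiffness is a named entry of the `well_k` parameter group, so wells are
#' perturbable and their free energies are known in closed form.
#'
#' @param atoms atom indices bound by the well.
#' @param k_name name of this well's entry in the `well_k` group.
#' @param centre well centre (length-3, default origin).
#' @param n_sup superset atom count.
#' @param id model identifier.
#' @return object of class `well_model`.
#' @export
well_model <- function(atoms, k_name, centre = c(0, 0, 0), n_sup = max(atoms),
                       id = k_name) {
  structure(list(id = id, family = "well", atoms = atoms, k_name = k_name,
                 centre = centre, n_sup = n_sup),
            class = "well_model")
}

#' @export
pot_energy.well_model <- function(model, x, theta) {
  k <- theta$groups$well_k[[model$k_name]]
  d <- sweep(x[model$atoms, , drop = FALSE], 2, model$centre)
  0.5 * k * sum(d^2)
}

#' @export
pot_grad.well_model <- function(model, x, theta) {
  k <- theta$groups$well_k[[model$k_name]]
  g <- matrix(0, nrow(x), 3)
  g[model$atoms, ] <- k * sweep(x[model$atoms, , drop = FALSE], 2,
                                model$centre)
  g
}

#' @export
pot_energy_many.well_model <- function(model, X, theta) {
  k <- theta$groups$well_k[[model$k_name]]
  e <- numeric(dim(X)[3])
  for (a in model$atoms) {
    d <- .fslice(X, a) - model$centre
    e <- e + 0.5 * k * colSums(d^2)
  }
  e
}

#' @export
pot_pgrad_many.well_model <- function(model, X, theta) {
  flat <- params_flatten(theta)
  G <- matrix(0, length(flat), dim(X)[3],
              dimnames = list(names(flat), NULL))
  s <- numeric(dim(X)[3])
  for (a in model$atoms) {
    d <- .fslice(X, a) - model$centre
    s <- s + 0.5 * colSums(d^2)
  }
  G[paste0("well_k.", model$k_name), ] <- s
  G
}

# ---- flat-bottom restraints ----------------------------------------------

#' Build flat-bottom bond restraints for a hybrid system
#'
#' One restraint per covalent bond of the superset topology (union of both
#' endstates, so both tautomeric hydrogen bonds are restrained).
#' Heavy-heavy pairs: r0 = 1.3 A, r_fb = 0.3 A, k = kBT / 0.1 A^2;
#' X-H pairs: r0 = 1.02 A, r_fb = 0.4 A, k = kBT / 0.2 A^2.
#'
#' @param system a `hybrid_system`.
#' @param T temperature in K fixing kBT.
#' @return data.frame `i`, `j`, `r0`, `r_fb`, `k`.
#' @export
build_restraints <- function(system, T = 300) {
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  ub <- rbind(system$bonds1[, c("i", "j")], system$bonds2[, c("i", "j")])
  ub <- ub[!duplicated(key(ub$i, ub$j)), , drop = FALSE]
  if (nrow(ub) == 0)
    return(data.frame(i = integer(), j = integer(), r0 = numeric(),
                      r_fb = numeric(), k = numeric()))
  el <- system$elements
  supported <- c("C", "H", "N", "O", "S", "F", "Cl", "Br")
  bad <- !(el[ub$i] %in% supported) | !(el[ub$j] %in% supported)
  if (any(bad))
    stopf("unsupported element pair for restraints: %s",
          paste(unique(paste(el[ub$i[bad]], el[ub$j[bad]])), collapse = ", "))
  is_h <- el[ub$i] == "H" | el[ub$j] == "H"
  kt <- kBT(T)
  data.frame(i = ub$i, j = ub$j,
             r0 = ifelse(is_h, 1.02, 1.3),
             r_fb = ifelse(is_h, 0.4, 0.3),
             k = ifelse(is_h, kt / 0.2, kt / 0.1))
}

#' Flat-bottom restraint energy
#'
#' Sum over restraints of `H(|delta| - r_fb) * 0.5 k (|delta| - r_fb)^2`
#' with `delta = r_ij - r0`: zero anywhere inside the flat well of radius
#' `r_fb`, harmonic in the excess beyond it, C1-continuous at the boundary
#' (the Heaviside convention H(0) = 0 makes the boundary itself contribute
#' exactly zero).
#'
#' @param x coordinate matrix (n x 3).
#' @param restraints data.frame from [build_restraints()].
#' @return energy in kcal/mol.
#' @export
flat_bottom_restraint_energy <- function(x, restraints) {
  if (nrow(restraints) == 0) return(0)
  d <- x[restraints$i, , drop = FALSE] - x[restraints$j, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  excess <- abs(r - restraints$r0) - restraints$r_fb
  sum(ifelse(excess > 0, 0.5 * restraints$k * excess^2, 0))
}

# coordinate gradient of the restraint energy
flat_bottom_restraint_grad <- function(x, restraints) {
  g <- matrix(0, nrow(x), 3)
  if (nrow(restraints) == 0) return(g)
  d <- x[restraints$i, , drop = FALSE] - x[restraints$j, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  delta <- r - restraints$r0
  excess <- abs(delta) - restraints$r_fb
  act <- which(excess > 0)
  for (t in act) {
    f <- restraints$k[t] * excess[t] * sign(delta[t]) / max(r[t], 1e-12)
    gv <- d[t, ] * f
    g[restraints$i[t], ] <- g[restraints$i[t], ] + gv
    g[restraints$j[t], ] <- g[restraints$j[t], ] - gv
  }
  g
}

# restraint energies over many frames
flat_bottom_restraint_many <- function(X, restraints) {
  nf <- dim(X)[3]
  e <- numeric(nf)
  for (t in seq_len(nrow(restraints))) {
    d <- .fslice(X, restraints$i[t]) - .fslice(X, restraints$j[t])
    r <- sqrt(colSums(d^2))
    excess <- abs(r - restraints$r0[t]) - restraints$r_fb[t]
    e <- e + ifelse(excess > 0, 0.5 * restraints$k[t] * excess^2, 0)
  }
  e
}

# ---- alchemical mixing ---------------------------------------------------

#' Alchemical energy and gradient at a lambda value
#'
#' `E = (1 - lambda) E1 + lambda E2 + E_restraint`, each endstate evaluated
#' only over its interacting atoms (the dummy hydrogen is invisible to the
#' endstate it does not belong to) and the restraints applied identically
#' at every lambda, so they are part of the sampled Hamiltonian at every
#' state and cancel from endpoint differences through MBAR.
#'
#' @param x full coordinate matrix (n_superset x 3).
#' @param lam lambda in [0, 1].
#' @param system a `hybrid_system` (or harmonic benchmark system).
#' @param theta a `taut_params`.
#' @param gradient also return the coordinate gradient.
#' @return list with `energy` (kcal/mol) and, if requested, `grad`.
#' @export
alchemical_energy <- function(x, lam, system, theta, gradient = TRUE) {
  if (!is.finite(lam) || lam < 0 || lam > 1)
    stopf("lambda must lie in [0, 1], got %s", format(lam))
  e1 <- pot_energy(system$E1, x, theta)
  e2 <- pot_energy(system$E2, x, theta)
  er <- flat_bottom_restraint_energy(x, system$restraints)
  if (!is.finite(e1)) stopf("non-finite energy at endstate 1")
  if (!is.finite(e2)) stopf("non-finite energy at endstate 2")
  e <- (1 - lam) * e1 + lam * e2 + er
  out <- list(energy = e)
  if (gradient) {
    out$grad <- (1 - lam) * pot_grad(system$E1, x, theta) +
      lam * pot_grad(system$E2, x, theta) +
      flat_bottom_restraint_grad(x, system$restraints)
  }
  out
}

# ---- compiled force closure (hot path for MD/minimization) ---------------

# flatten one toy/well model's terms with an overall lambda weight
.collect_terms <- function(model, theta, w) {
  out <- list(bonds = NULL, angles = NULL, nb = NULL, wells = NULL,
              e_const = 0)
  if (w == 0) return(out)
  if (inherits(model, "well_model")) {
    k <- theta$groups$well_k[[model$k_name]]
    out$wells <- data.frame(a = model$atoms, k = w * k,
                            cx = model$centre[1], cy = model$centre[2],
                            cz = model$centre[3])
    return(out)
  }
  b <- model$bonds
  if (nrow(b) > 0) {
    out$bonds <- data.frame(
      i = b$i, j = b$j,
      k = w * .lookup(theta, "bond_k", b$type),
      r0 = .lookup(theta, "bond_r0", b$type))
    out$e_const <- out$e_const - w * sum(.lookup(theta, "bond_D", b$type))
  }
  a <- model$angles
  if (nrow(a) > 0) {
    out$angles <- data.frame(
      i = a$i, c = a$c, j = a$j,
      k = w * .lookup(theta, "angle_k", a$type),
      th0 = .lookup(theta, "angle_theta0", a$type))
  }
  if (nrow(model$nb) > 0) {
    out$nb <- data.frame(i = model$nb[, 1], j = model$nb[, 2],
                         A = w * theta$groups$rep_A[["global"]],
                         rho = theta$groups$rep_rho[["global"]])
  }
  out
}

#' Compile a fast force function for one alchemical state
#'
#' Merges the lambda-weighted terms of both endstate potentials and the
#' restraints into flat vectors once, returning a closure that evaluates
#' energy and gradient with vectorized arithmetic only.  Numerically
#' identical to [alchemical_energy()]; used by the samplers.
#'
#' @param system a `hybrid_system`.
#' @param theta potential parameters.
#' @param lam lambda in [0, 1].
#' @return function(x) -> list(energy, grad).
#' @export
compile_alchemical_force <- function(system, theta, lam) {
  if (!is.finite(lam) || lam < 0 || lam > 1)
    stopf("lambda must lie in [0, 1], got %s", format(lam))
  t1 <- .collect_terms(system$E1, theta, 1 - lam)
  t2 <- .collect_terms(system$E2, theta, lam)
  bonds <- rbind(t1$bonds, t2$bonds)
  angles <- rbind(t1$angles, t2$angles)
  nb <- rbind(t1$nb, t2$nb)
  wells <- rbind(t1$wells, t2$wells)
  e_const <- t1$e_const + t2$e_const
  rs <- system$restraints
  has_b <- !is.null(bonds) && nrow(bonds) > 0
  has_a <- !is.null(angles) && nrow(angles) > 0
  has_n <- !is.null(nb) && nrow(nb) > 0
  has_w <- !is.null(wells) && nrow(wells) > 0
  has_r <- !is.null(rs) && nrow(rs) > 0
  scatter <- function(idx, n) {
    # dense incidence matrix: column t adds its term gradient to row idx[t]
    S <- matrix(0, n, length(idx))
    S[cbind(idx, seq_along(idx))] <- 1
    S
  }
  n_sup <- length(system$elements)
  if (has_b) { bi <- bonds$i; bj <- bonds$j; bk <- bonds$k; br0 <- bonds$r0
               Sb <- scatter(bi, n_sup) - scatter(bj, n_sup) }
  if (has_a) { ai <- angles$i; ac <- angles$c; aj <- angles$j
               ak <- angles$k; ath0 <- angles$th0
               Sai <- scatter(ai, n_sup); Saj <- scatter(aj, n_sup)
               Sac <- scatter(ac, n_sup) }
  if (has_n) { ni <- nb$i; nj <- nb$j; nA <- nb$A; nrho <- nb$rho
               Sn <- scatter(ni, n_sup) - scatter(nj, n_sup) }
  if (has_w) { wa <- wells$a; wk <- wells$k
               wc <- as.matrix(wells[, c("cx", "cy", "cz")])
               Sw <- scatter(wa, n_sup) }
  if (has_r) { ri <- rs$i; rj <- rs$j; rr0 <- rs$r0; rfb <- rs$r_fb
               rk <- rs$k
               Sr <- scatter(ri, n_sup) - scatter(rj, n_sup) }
  function(x) {
    e <- e_const
    g <- matrix(0, n_sup, 3)
    if (has_b) {
      d <- x[bi, , drop = FALSE] - x[bj, , drop = FALSE]
      r <- sqrt(d[, 1]^2 + d[, 2]^2 + d[, 3]^2)
      dr <- r - br0
      e <- e + 0.5 * sum(bk * dr^2)
      g <- g + Sb %*% (d * (bk * dr / (r + 1e-300)))
    }
    if (has_a) {
      u <- x[ai, , drop = FALSE] - x[ac, , drop = FALSE]
      v <- x[aj, , drop = FALSE] - x[ac, , drop = FALSE]
      nu <- sqrt(u[, 1]^2 + u[, 2]^2 + u[, 3]^2)
      nv <- sqrt(v[, 1]^2 + v[, 2]^2 + v[, 3]^2)
      cs <- (u[, 1] * v[, 1] + u[, 2] * v[, 2] + u[, 3] * v[, 3]) / (nu * nv)
      cs <- pmin(pmax(cs, -1 + 1e-12), 1 - 1e-12)
      th <- acos(cs)
      e <- e + 0.5 * sum(ak * (th - ath0)^2)
      pref <- ak * (th - ath0) * (-1 / sqrt(1 - cs^2))
      gi <- pref * (v / (nu * nv) - cs * u / nu^2)
      gj <- pref * (u / (nu * nv) - cs * v / nv^2)
      g <- g + Sai %*% gi + Saj %*% gj - Sac %*% (gi + gj)
    }
    if (has_n) {
      d <- x[ni, , drop = FALSE] - x[nj, , drop = FALSE]
      r <- sqrt(d[, 1]^2 + d[, 2]^2 + d[, 3]^2)
      ex <- nA * exp(-r / nrho)
      e <- e + sum(ex)
      g <- g + Sn %*% (d * (-ex / nrho / (r + 1e-300)))
    }
    if (has_w) {
      d <- x[wa, , drop = FALSE] - wc
      e <- e + 0.5 * sum(wk * (d[, 1]^2 + d[, 2]^2 + d[, 3]^2))
      g <- g + Sw %*% (wk * d)
    }
    if (has_r) {
      d <- x[ri, , drop = FALSE] - x[rj, , drop = FALSE]
      r <- sqrt(d[, 1]^2 + d[, 2]^2 + d[, 3]^2)
      delta <- r - rr0
      excess <- abs(delta) - rfb
      act <- excess > 0
      if (any(act)) {
        e <- e + 0.5 * sum(rk[act] * excess[act]^2)
        f <- numeric(length(r))
        f[act] <- rk[act] * excess[act] * sign(delta[act]) / (r[act] + 1e-300)
        g <- g + Sr %*% (d * f)
      }
    }
    dimnames(g) <- NULL
    list(energy = e, grad = g)
  }
}

#' Compile a fast force function for a single potential model
#'
#' Same machinery as [compile_alchemical_force()] with one unmixed model
#' and no restraints.
#'
#' @param model a potential model.
#' @param theta parameters.
#' @return function(x) -> list(energy, grad).
#' @export
compile_model_force <- function(model, theta) {
  shim <- list(elements = rep("", model$n_sup), E1 = model, E2 = model,
               restraints = data.frame())
  compile_alchemical_force(shim, theta, 0)
}
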