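# parsing, filtering, proton-shift detection and hybrid-topology
# construction

test_that("logK converts to free energy with the base-10 convention", {
  R <- 0.0019872041
  expect_equal(logk_to_free_energy(0, 298.15), 0)
  expect_equal(logk_to_free_energy(1, 298.15), -R * 298.15 * log(10),
               tolerance = 1e-6)
  expect_equal(logk_to_free_energy(-1, 298.15), R * 298.15 * log(10),
               tolerance = 1e-6)
  expect_equal(logk_to_free_energy(1, 298.15), -1.364, tolerance = 1e-3)
  expect_equal(logk_to_free_energy(2, 300),
               2 * logk_to_free_energy(1, 300))
  expect_error(logk_to_free_energy(NA_real_), "finite")
})

test_that("filter rules reject by the right rule and counts sum up", {
  tab <- data.frame(
    name = c("keto_enol", "iodo", "bigk", "amide"),
    smiles1 = c("CC=O", "ICC=O", "CC(N)=O", "CC(N)=O"),
    smiles2 = c("C=CO", "IC=CO", "CC(=N)O", "CC(=N)O"),
    logK = c(-6.6, 1.0, 12, 0.5))
  path <- write_pairs_tsv(tab)
  res <- parse_and_filter_pairs(path)
  cnt <- res$report$counts
  expect_equal(unname(cnt["iodine"]), 1L)
  expect_equal(unname(cnt["logk_out_of_range"]), 1L)
  expect_equal(unname(cnt["retained"]), 2L)
  expect_equal(sum(cnt), nrow(tab))
  expect_equal(vapply(res$pairs, `[[`, "", "name"),
               c("keto_enol", "amide"))
  # switching the iodine rule off readmits the iodinated pair
  res2 <- parse_and_filter_pairs(path, filter_rules(no_iodine = FALSE))
  expect_equal(unname(res2$report$counts["retained"]), 3L)
  # element whitelist drops it again
  res3 <- parse_and_filter_pairs(
    path, filter_rules(no_iodine = FALSE,
                       element_whitelist = c("C", "H", "N", "O")))
  expect_equal(unname(res3$report$counts["element_whitelist"]), 1L)
  # blocklist by name
  res4 <- parse_and_filter_pairs(
    path, filter_rules(blocklist = "keto_enol"))
  expect_equal(unname(res4$report$counts["blocklisted"]), 1L)
  rep_path <- tempfile(fileext = ".json")
  write_filter_report(res$report, rep_path)
  parsed <- jsonlite::read_json(rep_path)
  expect_equal(parsed$n_input, 4L)
})

test_that("DataWarrior-style tables are auto-detected and rows named tp_<row>", {
  tab <- data.frame(
    `Smiles 1` = c("CC=O", "CC(N)=O", "CC=O"),
    `Smiles 2` = c("C=CO", "CC(=N)O", "C=CO"),
    `logK value` = c(-6.6, 0.5, -2),
    Solvent = c("water", "water", "hexane"),
    check.names = FALSE)
  path <- write_pairs_tsv(tab)
  res <- parse_and_filter_pairs(path)
  expect_equal(unname(res$report$counts["not_aqueous"]), 1L)
  expect_equal(res$pairs[[1]]$name, "tp_1")
  expect_equal(res$pairs[[2]]$name, "tp_2")
})

test_that("unparsable SMILES are recorded and skipped", {
  tab <- data.frame(name = c("ok", "bad"),
                    smiles1 = c("CC=O", "xyz["),
                    smiles2 = c("C=CO", "C=CO"),
                    logK = c(0, 0))
  res <- parse_and_filter_pairs(write_pairs_tsv(tab))
  expect_equal(unname(res$report$counts["unparsable"]), 1L)
  expect_equal(unname(res$report$counts["retained"]), 1L)
})

test_that("the single proton shift is located on keto/enol and 2-pyridone", {
  p <- tautomer_pair("ke", smiles_to_molecule("CC=O"),
                     smiles_to_molecule("C=CO"), logK = 1)
  sh <- find_proton_shift(p)
  expect_equal(p$t1$elements[sh$donor], "C")
  expect_equal(p$t1$elements[sh$acceptor], "O")
  expect_equal(p$t1$elements[sh$moving_h], "H")
  # 2-pyridone -> 2-hydroxypyridine: ring N loses the proton, O gains it
  p2 <- tautomer_pair("py", smiles_to_molecule("O=c1cccc[nH]1"),
                      smiles_to_molecule("Oc1ccccn1"), logK = 0)
  sh2 <- find_proton_shift(p2)
  expect_equal(p2$t1$elements[sh2$donor], "N")
  expect_equal(p2$t1$elements[sh2$acceptor], "O")
})

test_that("proton shift is mirrored when the pair direction is reversed", {
  fw <- tautomer_pair("fw", smiles_to_molecule("CC=O"),
                      smiles_to_molecule("C=CO"), logK = 1)
  bw <- tautomer_pair("bw", smiles_to_molecule("C=CO"),
                      smiles_to_molecule("CC=O"), logK = -1)
  shf <- find_proton_shift(fw)
  shb <- find_proton_shift(bw)
  # forward donor maps onto backward acceptor and vice versa
  expect_equal(shf$mapping[shf$donor], shb$acceptor)
  expect_equal(shf$mapping[shf$acceptor], shb$donor)
})

test_that("degenerate or ambiguous shifts are refused", {
  same <- tautomer_pair("same", smiles_to_molecule("CC=O"),
                        smiles_to_molecule("CC=O"), logK = 0)
  expect_error(find_proton_shift(same), "single-proton")
  diff_formula <- list(t1 = smiles_to_molecule("CC=O"),
                       t2 = smiles_to_molecule("CCC=O"))
  expect_error(find_proton_shift(diff_formula), "formula")
})

test_that("stereobond changes are detected and flip the pair direction", {
  plain <- tautomer_pair("pl", smiles_to_molecule("CCC=O"),
                         smiles_to_molecule("CC=CO"), logK = 1)
  expect_false(detect_stereobond_change(plain))
  expect_false(plain$direction_flipped)
  # enolization creates an annotated cis/trans bond -> change + flip
  st <- tautomer_pair("st", smiles_to_molecule("CCC=O"),
                      smiles_to_molecule("C/C=C/O"), logK = 1)
  expect_true(st$direction_flipped)
  expect_equal(st$logK, -1)
  expect_true(any(st$t1$bonds$stereo))
  expect_true(detect_stereobond_change(st))
  # both tautomers share the same annotated stereobond -> no change
  both <- list(t1 = smiles_to_molecule("C/C=C/C(N)=O"),
               t2 = smiles_to_molecule("C/C=C/C(=N)O"))
  expect_false(detect_stereobond_change(both))
})

test_that("hybrid topology is the superset with one extra hydrogen", {
  p <- tautomer_pair("ke", smiles_to_molecule("CC=O"),
                     smiles_to_molecule("C=CO"), logK = 1)
  expect_equal(n_atoms(p$t1), 7L)
  sys <- build_hybrid_topology(p)
  expect_equal(length(sys$elements), 8L)
  expect_equal(length(sys$interacting1), 7L)
  expect_equal(length(sys$interacting2), 7L)
  expect_false(sys$dummy1 %in% sys$interacting1)
  expect_false(sys$dummy2 %in% sys$interacting2)
  # every restraint references superset atoms; both tautomeric H bonds in
  expect_true(all(unlist(sys$restraints[, c("i", "j")]) %in%
                    seq_along(sys$elements)))
  key <- paste(pmin(sys$restraints$i, sys$restraints$j),
               pmax(sys$restraints$i, sys$restraints$j))
  expect_true(paste(min(sys$donor, sys$dummy2),
                    max(sys$donor, sys$dummy2)) %in% key)
  expect_true(paste(min(sys$acceptor, sys$dummy1),
                    max(sys$acceptor, sys$dummy1)) %in% key)
  # malformed shift
  sh <- find_proton_shift(p)
  sh$acceptor <- sh$donor
  expect_error(build_hybrid_topology(p, sh), "donor and acceptor")
})

test_that("dummy hydrogen lands on the 1.02 A sphere at the lowest-energy candidate", {
  p <- tautomer_pair("ke", smiles_to_molecule("CC=O"),
                     smiles_to_molecule("C=CO"), logK = 1)
  sys <- build_hybrid_topology(p)
  theta <- default_toy_parameters(sys$E1, sys$E2)
  pl <- place_dummy_hydrogen(sys, p$t1$coords, theta, seed = 11)
  d <- sqrt(sum((pl$coords[sys$dummy1, ] - pl$coords[sys$acceptor, ])^2))
  expect_equal(d, 1.02, tolerance = 1e-6)
  expect_equal(pl$diagnostics$n_candidates, 100L)
  expect_equal(pl$diagnostics$chosen,
               which.min(pl$diagnostics$energies))
  # chosen point beats independently-evaluated energies at its own spot
  e_chosen <- pot_energy(sys$E2, pl$coords, theta) +
    flat_bottom_restraint_energy(pl$coords, sys$restraints)
  expect_equal(e_chosen, min(pl$diagnostics$energies), tolerance = 1e-9)
  # determinism
  pl2 <- place_dummy_hydrogen(sys, p$t1$coords, theta, seed = 11)
  expect_identical(pl$coords, pl2$coords)
  # flat candidate landscape -> first-index tie-break
  hp <- make_harmonic_pair(1, 1, 4)
  hsys <- hp$system
  hsys$dummy1 <- 1L
  hsys$acceptor <- 1L
  hsys$E2 <- well_model(integer(0), "k2", n_sup = 1L)  # no terms: flat
  pl3 <- place_dummy_hydrogen(hsys, matrix(0, 1, 3), hp$theta, seed = 5)
  expect_equal(pl3$diagnostics$chosen, 1L)
})
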