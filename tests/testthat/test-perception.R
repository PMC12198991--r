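# Benson-group perception from molecular graphs and SMILES.

test_that("benzene decomposes into six aromatic CH groups", {
  gv <- perceive_groups(benzene_graph())
  expect_equal(as.numeric(gv), 6)
  expect_equal(names(gv), "C_B-(H)(C_B)2")
  # same result through the SMILES reader
  expect_equal(unclass(perceive_groups(smiles_benzene)), unclass(gv))
})

test_that("benzoic acid and succinimide match their manual decompositions", {
  ba <- perceive_groups(smiles_benzoic_acid)
  expect_mapequal(
    stats::setNames(as.numeric(ba), names(ba)),
    c("C_B-(H)(C_B)2" = 5, "C_B-(CO)(C_B)2" = 1,
      "CO-(C_B)(O)" = 1, "O-(H)(CO)" = 1))
  su <- perceive_groups(smiles_succinimide)
  expect_mapequal(
    stats::setNames(as.numeric(su), names(su)),
    c("C-(H)2(CO)(C)" = 2, "CO-(C)(N)" = 2, "N-(H)(CO)2" = 1, rsc = 1))
  # every perceived label exists in the packaged table
  for (lb in c(names(ba), names(su)))
    expect_no_error(gav_lookup(builtin_gav_table(), lb))
})

test_that("imide rings emit one ring-strain correction each", {
  ph <- perceive_groups(smiles_phthalimide)
  expect_equal(unname(unclass(ph)["rsc"]), 1)
  expect_equal(unname(unclass(ph)["N-(H)(CO)2"]), 1)
  dita <- perceive_groups(smiles_34dita)
  expect_equal(unname(unclass(dita)["rsc"]), 2)
})

test_that("both DITA isomers perceive to the expected base decomposition", {
  expected <- dita_group_vector()
  for (smi in c(smiles_34dita, smiles_35dita)) {
    gv <- perceive_groups(smi)
    expect_equal(unclass(gv), unclass(expected))
  }
})

test_that("atom conservation holds across the fixture set", {
  fixtures <- list(
    list(smi = smiles_benzene,      formula = "C6H6"),
    list(smi = smiles_benzoic_acid, formula = "C7H6O2"),
    list(smi = smiles_succinimide,  formula = "C4H5NO2"),
    list(smi = smiles_phthalimide,  formula = "C8H5NO2"),
    list(smi = smiles_o_xylene,     formula = "C8H10"),
    list(smi = smiles_mesitylene,   formula = "C9H12"),
    list(smi = smiles_34dita,       formula = "C25H12N2O10"),
    list(smi = smiles_35dita,       formula = "C25H12N2O10")
  )
  for (fx in fixtures) {
    mol <- parse_smiles(fx$smi)
    expect_formula_equal(graph_formula(mol), fx$formula)
    gv <- perceive_groups(mol)
    expect_formula_equal(formula_from_groups(gv), fx$formula)
  }
})

test_that("perception is idempotent and invariant under atom reordering", {
  mol <- parse_smiles(smiles_benzoic_acid)
  expect_equal(unclass(perceive_groups(mol)), unclass(perceive_groups(mol)))
  # reverse the atom order
  n <- nrow(mol$atoms)
  perm <- rev(seq_len(n))
  mol2 <- molecular_graph(
    mol$atoms[order(perm), , drop = FALSE],
    data.frame(i = perm[mol$bonds$i], j = perm[mol$bonds$j],
               order = mol$bonds$order))
  expect_equal(unclass(perceive_groups(mol2)), unclass(perceive_groups(mol)))
})

test_that("substitution corrections count ring-position pairs", {
  ba <- parse_smiles(smiles_benzoic_acid)
  gv <- perceive_groups(ba)
  annotated <- annotate_substitution_corrections(ba, gv)
  expect_equal(unclass(annotated), unclass(gv))   # single substituent
  ox <- parse_smiles(smiles_o_xylene)
  gvx <- annotate_substitution_corrections(ox, perceive_groups(ox))
  expect_equal(unname(unclass(gvx)["correction o-"]), 1)
  expect_false("correction m-" %in% names(gvx))
  mes <- parse_smiles(smiles_mesitylene)
  gvm <- annotate_substitution_corrections(mes, perceive_groups(mes))
  expect_equal(unname(unclass(gvm)["correction m-"]), 3)
  expect_false("correction o-" %in% names(gvm))
})

test_that("the two DITA isomers differ only in substitution corrections", {
  g34 <- annotate_substitution_corrections(
    parse_smiles(smiles_34dita), perceive_groups(smiles_34dita))
  g35 <- annotate_substitution_corrections(
    parse_smiles(smiles_35dita), perceive_groups(smiles_35dita))
  corr <- c("correction o-", "correction m-", "correction p-")
  base34 <- unclass(g34)[setdiff(names(g34), corr)]
  base35 <- unclass(g35)[setdiff(names(g35), corr)]
  expect_equal(base34, base35)
  expect_false(identical(unclass(g34)[corr], unclass(g35)[corr]))
})

test_that("graphs validate elements, valences and aromatic flags", {
  expect_error(molecular_graph(
    data.frame(element = "S", hcount = 2, aromatic = FALSE),
    data.frame(i = integer(), j = integer(), order = character())),
    "unsupported element")
  expect_error(molecular_graph(
    data.frame(element = "C", hcount = 5, aromatic = FALSE),
    data.frame(i = integer(), j = integer(), order = character())),
    "valence")
  expect_error(molecular_graph(
    data.frame(element = rep("C", 2), hcount = c(3, 3),
               aromatic = c(TRUE, FALSE)),
    data.frame(i = 1, j = 2, order = "1")),
    "aromatic")
})

test_that("graphs round-trip through the JSON contract", {
  mol <- parse_smiles(smiles_succinimide)
  path <- withr::local_tempfile(fileext = ".json")
  write_graph_json(mol, path)
  back <- read_graph_json(path)
  expect_equal(back$atoms$element, mol$atoms$element)
  expect_equal(back$atoms$hcount, mol$atoms$hcount)
  expect_equal(unclass(perceive_groups(back)),
               unclass(perceive_groups(mol)))
})
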